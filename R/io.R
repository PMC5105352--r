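#' Read and write pipeline tables
#'
#' Plain-CSV persistence for the cohort table, the parcellation scheme, the
#' effect map and the group FC table (subjects x edges with pair-label
#' headers plus a sidecar edge-index CSV).
#'
#' @param x Object to write.
#' @param path File path.
#' @name fcnets-io
NULL

#' @rdname fcnets-io
#' @export
writeCohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fcnets-io
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname fcnets-io
#' @export
writeScheme <- function(x, path) {
  reg <- x@regions
  reg$display_order <- order(displayOrder(x))
  utils::write.csv(reg, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fcnets-io
#' @export
readScheme <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  dispo <- if ("display_order" %in% names(reg)) {
    order(reg$display_order[order(reg$region_index)])
  } else NULL
  ParcellationScheme(reg[, c("region_index", "region_name", "lobe")],
                     displayOrder = dispo)
}

#' @rdname fcnets-io
#' @export
writeEffectMap <- function(x, path) {
  ef <- effectTable(x)
  idx <- edgeIndexTable((1 + sqrt(1 + 8 * nrow(ef))) / 2)
  utils::write.csv(cbind(idx[, c("edge_id", "i", "j")],
                         ef[, c("mu", "b_sex", "b_age", "b_int", "sigma")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname fcnets-io
#' @param fce An [FCExperiment].
#' @param indexPath Sidecar path for the edge index map.
#' @export
writeGroupFC <- function(fce, path, indexPath = NULL) {
  z <- groupFCMatrix(fce)
  idx <- edgeIndex(fce)
  colnames(z) <- idx$pair
  df <- cbind(data.frame(subject_id = cohortTable(fce)$subject_id,
                         stringsAsFactors = FALSE), as.data.frame(z))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(indexPath)) utils::write.csv(idx, indexPath, row.names = FALSE)
  invisible(path)
}

#' @rdname fcnets-io
#' @param cohort Cohort table aligned with the stored rows.
#' @export
readGroupFC <- function(path, cohort) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  z <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(df$subject_id, cohort$subject_id)) {
    stop("group FC rows are not aligned with the cohort", call. = FALSE)
  }
  FCExperiment(z, cohort)
}
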
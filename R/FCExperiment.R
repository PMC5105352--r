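#' FCExperiment: subjects-by-edges group FC container
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding the
#' group functional-connectivity table: one row per region-pair edge (upper
#' triangle, i < j, row-major under the display ordering), one column per
#' subject, assay `"z"` in Fisher-z units. `rowData` carries the edge index
#' map (`edge_id` 0-based, region indices `i`, `j` and the `pair` label);
#' `colData` carries the cohort table (`sex`, `age_years`, optional
#' covariates).
#'
#' @export
setClass("FCExperiment", contains = "SummarizedExperiment")

setValidity("FCExperiment", function(object) {
  msgs <- character()
  if (!"z" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'z' is required")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("edge_id", "i", "j") %in% colnames(rd))) {
    msgs <- c(msgs, "rowData must carry edge_id, i, j")
  } else {
    if (any(rd$i >= rd$j)) msgs <- c(msgs, "edge index must satisfy i < j")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sex", "age_years") %in% colnames(cd))) {
    msgs <- c(msgs, "colData must carry sex and age_years")
  } else if (!all(cd$sex %in% c("M", "F"))) {
    msgs <- c(msgs, "sex must be coded 'M'/'F'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Edge index table for R regions
#'
#' Enumerates the R(R-1)/2 unordered region pairs in upper-triangle row-major
#' order: (1,2), (1,3), ..., (1,R), (2,3), ... `edge_id` is the 0-based
#' linear index. For R = 116 this yields 6670 edges.
#'
#' @param nRegions Number of regions R (or a `ParcellationScheme`).
#' @param names Optional region names used to build the `pair` label
#'   (`"<name_i>-<name_j>"`).
#' @return data.frame with `edge_id`, `i`, `j`, `pair`.
#' @export
edgeIndexTable <- function(nRegions, names = NULL) {
  if (is(nRegions, "ParcellationScheme")) {
    names <- regionNames(nRegions)
    nRegions <- nRegions(nRegions)
  }
  R <- as.integer(nRegions)
  stopifnot(R >= 2)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- sequence((R - 1L):1L) + i
  if (is.null(names)) names <- paste0("R", seq_len(R))
  data.frame(edge_id = seq_along(i) - 1L, i = i, j = j,
             pair = paste(names[i], names[j], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Construct an FCExperiment
#'
#' @param z Numeric matrix, subjects x edges, Fisher-z units.
#' @param cohort Cohort data.frame (one row per subject; must contain
#'   `subject_id`, `sex`, `age_years`).
#' @param edgeIndex Edge index table as from [edgeIndexTable()]; inferred
#'   from the column count if omitted.
#' @return An `FCExperiment` (edges in rows, subjects in columns).
#' @export
FCExperiment <- function(z, cohort, edgeIndex = NULL) {
  z <- as.matrix(z)
  if (nrow(z) != nrow(cohort)) {
    stop("z must have one row per cohort subject", call. = FALSE)
  }
  if (is.null(edgeIndex)) {
    # smallest R whose upper triangle holds all columns; a partial edge set
    # (e.g. a simulation over an arbitrary number of edges) takes the first
    # E pairs in enumeration order
    R <- ceiling((1 + sqrt(1 + 8 * ncol(z))) / 2)
    edgeIndex <- edgeIndexTable(R)[seq_len(ncol(z)), , drop = FALSE]
    edgeIndex$edge_id <- seq_len(ncol(z)) - 1L
  }
  if (nrow(edgeIndex) != ncol(z)) {
    stop("edgeIndex rows must match the number of edge columns", call. = FALSE)
  }
  dimnames(z) <- NULL
  cd <- S4Vectors::DataFrame(cohort)
  rownames(cd) <- cohort$subject_id
  rd <- S4Vectors::DataFrame(edgeIndex)
  rownames(rd) <- edgeIndex$pair
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = t(z)), rowData = rd, colData = cd)
  new("FCExperiment", se)
}

#' @describeIn FCExperiment Subjects-by-edges Fisher-z matrix (the transpose
#'   of the stored assay, i.e. the group FC table orientation).
#' @param x An `FCExperiment`.
#' @export
groupFCMatrix <- function(x) t(SummarizedExperiment::assay(x, "z"))

#' @describeIn FCExperiment Edge index map as a plain data.frame.
#' @export
edgeIndex <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @describeIn FCExperiment Cohort table as a plain data.frame.
#' @export
cohortTable <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "FCExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  nm <- sum(cd$sex == "M")
  cat(sprintf("FCExperiment: %d edges x %d subjects (%d male, %d female)\n",
              nrow(object), ncol(object), nm, ncol(object) - nm))
  cat(sprintf("  age range: [%.1f, %.1f] years\n",
              min(cd$age_years), max(cd$age_years)))
  cat("  assay: z (Fisher-z functional connectivity)\n")
})

#' Rebuild a symmetric FC matrix from an edge vector
#'
#' Inverse of the upper-triangle row-major vectorization: places the edge
#' values back into an R x R symmetric matrix with zero diagonal.
#'
#' @param zrow Numeric vector of length R(R-1)/2.
#' @param nRegions Number of regions R.
#' @return R x R symmetric matrix.
#' @export
edgeMatrix <- function(zrow, nRegions) {
  R <- as.integer(nRegions)
  if (length(zrow) != R * (R - 1L) / 2L) {
    stop("edge vector length does not match R(R-1)/2", call. = FALSE)
  }
  m <- matrix(0, R, R)
  idx <- edgeIndexTable(R)
  m[cbind(idx$i, idx$j)] <- zrow
  m[cbind(idx$j, idx$i)] <- zrow
  m
}

#' Vectorize a symmetric FC matrix
#'
#' Upper-triangle (i < j) row-major vectorization; the exact inverse of
#' [edgeMatrix()].
#'
#' @param fc Symmetric R x R matrix.
#' @return Numeric vector of length R(R-1)/2.
#' @export
edgeVector <- function(fc) {
  idx <- edgeIndexTable(nrow(fc))
  fc[cbind(idx$i, idx$j)]
}
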
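#' Fisher z-transform with clipping
#'
#' `atanh(r)` after clipping |r| to `1 - 1e-12`, so perfectly correlated
#' pairs map to a large finite z rather than infinity. Clips are reported
#' with a warning carrying the clip count.
#'
#' @param r Correlation values in [-1, 1].
#' @return Fisher-z values.
#' @export
fisherZ <- function(r) {
  clip <- 1 - 1e-12
  nClipped <- sum(abs(r) > clip, na.rm = TRUE)
  if (nClipped > 0) {
    warning(nClipped, " correlation(s) at |r| ~ 1 clipped to ", clip,
            call. = FALSE)
  }
  atanh(pmin(pmax(r, -clip), clip))
}

#' Compute a subject's Fisher-z FC matrix
#'
#' Pearson correlation of every pair of ROI columns over the whole duration
#' of the time series (static FC, no windowing), Fisher z-transformed. The
#' diagonal is set to zero and is excluded from all downstream use.
#'
#' @param ts T x R matrix of ROI time series (T >= 3).
#' @return R x R symmetric matrix of Fisher-z values, zero diagonal.
#' @export
computeFC <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("at least 3 timepoints required", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series in region(s): ",
         paste(which(sds == 0), collapse = ", "),
         " (correlation undefined)", call. = FALSE)
  }
  r <- stats::cor(ts)
  diag(r) <- 0 # excluded downstream; keeps the clip counter honest
  z <- fisherZ(r)
  (z + t(z)) / 2
}

#' Reorder an FC matrix to the display ordering
#'
#' Permutes rows and columns of a subject FC matrix to the scheme's display
#' order (used to group regions into lobe blocks for reporting). Entry
#' (a, b) of the output equals entry (order[a], order[b]) of the input.
#'
#' @param fc R x R matrix in region-index order.
#' @param scheme A [ParcellationScheme].
#' @return Reordered matrix with the lobe boundary positions attached as
#'   attribute `"lobeBoundaries"`.
#' @export
reorderFC <- function(fc, scheme) {
  R <- nRegions(scheme)
  if (!all(dim(fc) == c(R, R))) {
    stop("fc dimensions do not match the scheme", call. = FALSE)
  }
  ord <- displayOrder(scheme)
  out <- fc[ord, ord, drop = FALSE]
  lob <- regionLobes(scheme)[ord]
  attr(out, "lobeBoundaries") <- cumsum(rle(lob)$lengths)
  out
}

#' Assemble the group FC table
#'
#' Vectorizes each subject's symmetric FC matrix (upper triangle, i < j,
#' row-major under the display ordering) and stacks subjects into the
#' subjects x edges group table. With R regions the table has R(R-1)/2
#' columns (6670 for R = 116).
#'
#' @param fcs List of R x R FC matrices, one per subject, all in display
#'   ordering.
#' @param cohort Cohort table aligned with `fcs`.
#' @param scheme Optional [ParcellationScheme] providing pair labels.
#' @return An [FCExperiment].
#' @export
buildGroupTable <- function(fcs, cohort, scheme = NULL) {
  if (length(fcs) != nrow(cohort)) {
    stop("one FC matrix per cohort subject required", call. = FALSE)
  }
  Rs <- vapply(fcs, nrow, integer(1))
  if (length(unique(Rs)) != 1) {
    stop("inconsistent region count across subjects", call. = FALSE)
  }
  R <- Rs[1]
  idx <- if (is.null(scheme)) edgeIndexTable(R) else {
    nm <- regionNames(scheme)[displayOrder(scheme)]
    edgeIndexTable(R, names = nm)
  }
  z <- t(vapply(fcs, edgeVector, numeric(R * (R - 1) / 2)))
  FCExperiment(z, cohort, idx)
}
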
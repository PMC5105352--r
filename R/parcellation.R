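#' Extract mean ROI time series from a labeled 4D volume
#'
#' Column r of the output is the unweighted mean, at each timepoint, over all
#' voxels carrying label r in the label volume. Voxels labeled 0 (background)
#' or carrying labels absent from the scheme are ignored (their count is
#' reported via a message). Volumes must already be spatially aligned; no
#' resampling is performed.
#'
#' @param volume4d 4D numeric array (x, y, z, t).
#' @param labels 3D integer array of region labels, same spatial shape.
#' @param scheme A [ParcellationScheme]; every region index must be present
#'   in `labels`.
#' @return T x R matrix of mean time series, columns in region-index order.
#' @export
parcellate <- function(volume4d, labels, scheme) {
  dv <- dim(volume4d)
  dl <- dim(labels)
  if (length(dv) != 4 || length(dl) != 3 || !all(dv[1:3] == dl)) {
    stop("volume4d must be 4D and spatially match the 3D label volume",
         call. = FALSE)
  }
  R <- nRegions(scheme)
  nT <- dv[4]
  lab <- as.integer(labels)
  known <- lab %in% seq_len(R)
  nIgnored <- sum(!known & lab != 0L)
  if (nIgnored > 0) {
    message(nIgnored, " voxel(s) with labels outside the scheme ignored")
  }
  counts <- tabulate(lab[known], nbins = R)
  if (any(counts == 0)) {
    stop("region(s) with zero voxels: ",
         paste(which(counts == 0), collapse = ", "), call. = FALSE)
  }
  nVox <- prod(dl)
  mat <- matrix(volume4d, nrow = nVox, ncol = nT)
  out <- matrix(0, nT, R)
  for (r in seq_len(R)) {
    sel <- lab == r
    out[, r] <- colMeans(mat[sel, , drop = FALSE])
  }
  colnames(out) <- regionNames(scheme)
  out
}

#' ROI-homogeneity quality control
#'
#' For each region, correlates every member voxel's time series with the
#' region-mean series (the voxel's own contribution included) and tests the
#' Pearson correlation two-sided against zero with a t-distribution on T - 2
#' degrees of freedom. Reports, per region, the fraction of voxels with
#' p < `alpha`, plus the count of regions whose fraction exceeds 0.5 — the
#' conventional "k of R regions (percent)" homogeneity summary.
#'
#' Voxels with constant series (undefined correlation) are counted as
#' non-significant and reported via a message.
#'
#' @inheritParams parcellate
#' @param alpha Per-voxel significance level.
#' @return List with `fraction` (per-region numeric vector), `nAboveHalf`,
#'   and `summary` (formatted "k of R regions (p%)" string).
#' @export
roiHomogeneity <- function(volume4d, labels, scheme, alpha = 0.05) {
  dv <- dim(volume4d)
  nT <- dv[4]
  if (nT < 4) stop("at least 4 timepoints required", call. = FALSE)
  means <- parcellate(volume4d, labels, scheme)
  R <- nRegions(scheme)
  lab <- as.integer(labels)
  mat <- matrix(volume4d, nrow = prod(dv[1:3]), ncol = nT)
  frac <- numeric(R)
  nConstant <- 0L
  for (r in seq_len(R)) {
    vox <- mat[lab == r, , drop = FALSE]
    sds <- apply(vox, 1, stats::sd)
    const <- sds == 0
    nConstant <- nConstant + sum(const)
    rr <- rep(0, nrow(vox))
    if (any(!const) && stats::sd(means[, r]) > 0) {
      rr[!const] <- as.numeric(stats::cor(t(vox[!const, , drop = FALSE]),
                                          means[, r]))
    }
    p <- corPValue(rr, nT)
    p[const] <- 1
    frac[r] <- mean(p < alpha)
  }
  if (nConstant > 0) {
    message(nConstant, " constant voxel series counted as non-significant")
  }
  k <- sum(frac > 0.5)
  list(fraction = frac, nAboveHalf = k,
       summary = sprintf("%d of %d regions (%d%%)", k, R,
                         round(100 * k / R)))
}
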
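#' Derive a reproducible substream seed
#'
#' Deterministically maps a master seed plus a sequence of integer keys to a
#' new seed below 2^31, so that independent pipeline stages (or parallel
#' subject/density/null substreams) can each seed R's RNG without any chance
#' of order-dependent results.
#'
#' @param master Integer master seed.
#' @param ... Integer keys identifying the substream (e.g. subject index,
#'   density index, null index).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, ...) {
  keys <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(master) %% m
  # multiplier kept small so x * 69069 stays well inside double precision
  for (k in c(keys, 1L)) {
    x <- (x * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Bonferroni family-wise threshold
#'
#' Computes `alpha / m` and the conventional report string in units of
#' 10^-6 truncated (not rounded) to two decimals, e.g. 0.05/6670 prints as
#' "7.49E-6".
#'
#' @param alpha Family-wise error level.
#' @param m Number of tests.
#' @return List with `threshold` (numeric), `mantissa` (truncated value in
#'   1e-6 units) and `label` (character).
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  thr <- alpha / m
  mant <- floor(thr * 1e6 * 100) / 100
  list(threshold = thr, mantissa = mant,
       label = sprintf("%.2fE-6", mant))
}

#' Round half away from zero
#'
#' Edge-count rule for proportional thresholding: `k = round(d * n_pairs)`
#' with halves rounded away from zero (R's `round()` rounds half to even).
#' @param x Non-negative numeric.
#' @return Integer vector.
#' @keywords internal
roundHalfAway <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Pearson correlation p-value from the t distribution with n - 2 d.f.
corPValue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

#' Parse a density-grid string
#'
#' Expands `"from:to:step"` (e.g. `"0.05:0.95:0.05"`) into the vector of
#' density levels, rounding away floating-point drift.
#'
#' @param x Grid string or numeric vector (returned as-is after validation).
#' @return Numeric vector of densities in (0, 1].
#' @export
parseDensityGrid <- function(x) {
  if (is.numeric(x)) {
    grid <- x
  } else {
    parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3 || anyNA(parts)) {
      stop("density grid must be numeric or 'from:to:step'", call. = FALSE)
    }
    grid <- round(seq(parts[1], parts[2], by = parts[3]), 10)
  }
  if (any(grid <= 0) || any(grid > 1)) {
    stop("density grid values must lie in (0, 1]", call. = FALSE)
  }
  grid
}
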
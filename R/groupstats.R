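#' Two-sample t-test (pooled or Welch)
#'
#' Student's pooled-variance two-sample t by default, Welch's unequal
#' variance variant optionally. Identical constant groups return t = 0,
#' p = 1; zero pooled variance with unequal means is an error (the statistic
#' is undefined).
#'
#' @param x,y Numeric samples (each n >= 2). The statistic is computed as
#'   x minus y.
#' @param variant `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p`, `meanDiff`.
#' @export
twoSampleT <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs n >= 2", call. = FALSE)
  md <- mean(x) - mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (variant == "student") {
    s2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(s2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) {
    if (md == 0) return(list(t = 0, df = df, p = 1, meanDiff = 0))
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  tt <- md / se
  list(t = tt, df = df,
       p = 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE),
       meanDiff = md)
}

# look up subject sex for a metrics table
subjectSex <- function(ids, cohort) {
  cohort$sex[match(ids, cohort$subject_id)]
}

#' Male-female comparison of a nodal graph metric
#'
#' Per node and density level, compares the metric between males and females
#' (male minus female) and computes the signed significance
#' `sign(t) * (-log10 p)`. Values passing the nodal Bonferroni gate
#' `p < alpha / R` are summed across densities into the per-node stacked
#' summary (positive stack: male > female).
#'
#' @param nodal Long nodal table from [runDensityGrid()].
#' @param cohort Cohort table.
#' @param metric `"clustering"` or `"local_efficiency"`.
#' @param alpha Nominal level; the nodal threshold is `alpha / R`.
#' @param variant t-test variant, see [twoSampleT()].
#' @return List with `perNodeDensity` (t, p, signed significance, flag) and
#'   `stack` (per-node sum of flagged signed values).
#' @export
nodalMetricComparison <- function(nodal, cohort, metric = "clustering",
                                  alpha = 0.05,
                                  variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!metric %in% colnames(nodal)) {
    stop("metric '", metric, "' not in nodal table", call. = FALSE)
  }
  sex <- subjectSex(nodal$subject_id, cohort)
  nodes <- sort(unique(nodal$node))
  densities <- sort(unique(nodal$density))
  R <- length(nodes)
  rows <- expand.grid(node = nodes, density = densities,
                      KEEP.OUT.ATTRS = FALSE)
  tt <- pp <- numeric(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    selM <- nodal$node == rows$node[k] & nodal$density == rows$density[k] &
      sex == "M"
    selF <- nodal$node == rows$node[k] & nodal$density == rows$density[k] &
      sex == "F"
    if (!any(selM) || !any(selF)) {
      stop("missing density coverage for one sex group", call. = FALSE)
    }
    r <- twoSampleT(nodal[[metric]][selM], nodal[[metric]][selF], variant)
    tt[k] <- r$t
    pp[k] <- r$p
  }
  rows$t <- tt
  rows$p <- pp
  rows$signed <- sign(tt) * (-log10(pmax(pp, 1e-300)))
  rows$flag <- pp < alpha / R
  stackVals <- vapply(nodes, function(nd) {
    sel <- rows$node == nd & rows$flag
    sum(rows$signed[sel])
  }, numeric(1))
  list(perNodeDensity = rows,
       stack = data.frame(node = nodes, stack = stackVals),
       threshold = alpha / R, metric = metric)
}

#' Male-female comparison of a global graph metric across densities
#'
#' Per density: group means, SDs, pooled t and two-sided p for one global
#' metric (e.g. `largest_component`, `C_norm`, `L_norm`, `sigma`).
#'
#' @param global Global table from [runDensityGrid()].
#' @param cohort Cohort table.
#' @param metric Column of `global` to compare.
#' @param variant t-test variant.
#' @return data.frame per density with means, SDs, t, df, p.
#' @export
globalMetricComparison <- function(global, cohort, metric,
                                   variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!metric %in% colnames(global)) {
    stop("metric '", metric, "' not in global table", call. = FALSE)
  }
  sex <- subjectSex(global$subject_id, cohort)
  densities <- sort(unique(global$density))
  out <- lapply(densities, function(d) {
    m <- global[[metric]][global$density == d & sex == "M"]
    f <- global[[metric]][global$density == d & sex == "F"]
    if (!length(m) || !length(f)) {
      stop("missing density coverage for one sex group", call. = FALSE)
    }
    ok <- is.finite(m) & !is.na(m)
    okf <- is.finite(f) & !is.na(f)
    r <- twoSampleT(m[ok], f[okf], variant)
    data.frame(density = d, mean_male = mean(m[ok]), sd_male = stats::sd(m[ok]),
               mean_female = mean(f[okf]), sd_female = stats::sd(f[okf]),
               t = r$t, df = r$df, p = r$p)
  })
  do.call(rbind, out)
}

#' Regression of graph metrics on sex and age
#'
#' Confirms t-test group differences with a covariate-adjusted model: per
#' density (and per node for nodal tables), OLS of the metric on sex + age
#' using the same design machinery as the edge regressions.
#'
#' @param metrics Global or nodal table from [runDensityGrid()].
#' @param cohort Cohort table.
#' @param metric Metric column name.
#' @return data.frame with sex and age coefficients and p-values per
#'   density (x node).
#' @export
metricRegression <- function(metrics, cohort, metric) {
  if (!metric %in% colnames(metrics)) {
    stop("metric '", metric, "' not in metrics table", call. = FALSE)
  }
  nodal <- "node" %in% colnames(metrics)
  keyCols <- if (nodal) c("density", "node") else "density"
  keys <- unique(metrics[, keyCols, drop = FALSE])
  out <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- metrics$density == keys$density[k]
    if (nodal) sel <- sel & metrics$node == keys$node[k]
    sub <- metrics[sel, , drop = FALSE]
    co <- cohort[match(sub$subject_id, cohort$subject_id), ]
    y <- sub[[metric]]
    ok <- is.finite(y)
    X <- sexAgeDesigns(co[ok, , drop = FALSE])$M4
    if (stats::sd(y[ok]) == 0) {
      row <- data.frame(beta_sex = 0, p_sex = 1, beta_age = 0, p_age = 1)
    } else {
      fit <- fitOLS(y[ok], X)
      row <- data.frame(beta_sex = fit$coefficients[["sex"]],
                        p_sex = fit$p[["sex"]],
                        beta_age = fit$coefficients[["age"]],
                        p_age = fit$p[["age"]])
    }
    cbind(keys[k, , drop = FALSE], row)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Head-motion confound checks
#'
#' Two-sample t of mean frame displacement between sexes and the Pearson
#' correlation of frame displacement with age — the two checks used to rule
#' out motion as a driver of sex/age FC effects.
#'
#' @param cohort Cohort table with a `mean_fd_mm` column.
#' @param variant t-test variant.
#' @return List with `sex_t` (t, df, p) and `age_cor` (r, p); NULL with a
#'   warning when FD is absent.
#' @export
motionChecks <- function(cohort, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!"mean_fd_mm" %in% colnames(cohort)) {
    warning("mean_fd_mm not present; motion checks skipped", call. = FALSE)
    return(NULL)
  }
  fd <- cohort$mean_fd_mm
  sexT <- twoSampleT(fd[cohort$sex == "M"], fd[cohort$sex == "F"], variant)
  r <- stats::cor(fd, cohort$age_years)
  list(sex_t = sexT,
       age_cor = list(r = r, p = corPValue(r, nrow(cohort))))
}
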
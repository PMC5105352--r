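#' Generate a synthetic cohort table
#'
#' Draws a cohort of `nMale + nFemale` subjects emulating a young-adult
#' resting-state study: sex labels, ages uniform on `[ageLow, ageHigh]`
#' (continuous years) and, optionally, seven cognition scores on the
#' age-adjusted standard scale (Normal, mean 100, SD 15 by default), total
#' intracranial volume in mm^3 (males drawn with a higher mean, mirroring the
#' strong male > female ICV contrast such cohorts show) and mean frame
#' displacement in mm (head-motion summary, drawn identically for both sexes
#' so motion is a true non-confound under the generator).
#'
#' @param nMale,nFemale Group sizes (both >= 0, total >= 3).
#' @param ageLow,ageHigh Age range in years (`ageLow < ageHigh`).
#' @param covariates Logical; add cognition_1..7, icv_mm3 and mean_fd_mm.
#' @param cognitionMean,cognitionSd Scale of the cognition scores.
#' @param cognitionSexShift Numeric length-7 vector of male-minus-female mean
#'   shifts per cognition score (default all 0).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return data.frame with `subject_id`, `sex` ("M"/"F"), `age_years` and the
#'   optional covariate columns.
#' @examples
#' cohort <- makeCohort(203, 291, seed = 1)
#' table(cohort$sex)
#' @export
makeCohort <- function(nMale, nFemale, ageLow = 22, ageHigh = 36,
                       covariates = TRUE,
                       cognitionMean = 100, cognitionSd = 15,
                       cognitionSexShift = rep(0, 7),
                       seed = 1L) {
  if (nMale < 0 || nFemale < 0) {
    stop("group sizes must be non-negative (nMale, nFemale)", call. = FALSE)
  }
  n <- nMale + nFemale
  if (n < 3) stop("cohort must contain at least 3 subjects", call. = FALSE)
  if (!(ageLow < ageHigh)) stop("ageLow must be < ageHigh", call. = FALSE)
  if (length(cognitionSexShift) != 7) {
    stop("cognitionSexShift must have length 7", call. = FALSE)
  }
  set.seed(deriveSeed(seed, 101L))
  sex <- c(rep("M", nMale), rep("F", nFemale))
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age_years = stats::runif(n, ageLow, ageHigh),
    stringsAsFactors = FALSE)
  if (covariates) {
    male <- sex == "M"
    for (k in 1:7) {
      out[[paste0("cognition_", k)]] <-
        stats::rnorm(n, cognitionMean + cognitionSexShift[k] * male,
                     cognitionSd)
    }
    # ICV ~ 12% higher in males; SDs on the scale FreeSurfer-derived ICV shows
    out$icv_mm3 <- stats::rnorm(n, ifelse(male, 1.55e6, 1.38e6), 1.1e5)
    fd <- stats::rnorm(n, 0.15, 0.04)
    out$mean_fd_mm <- pmax(fd, 0.01)
  }
  out
}

#' Build an effect map with designated non-null edges
#'
#' Assigns sex, age and sex-by-age interaction effects to disjoint random
#' subsets of the edge index set; all other edges are null. Sex effects are
#' positive (male > female) and age effects negative (higher FC in younger
#' subjects), matching the directions such cohorts exhibit. Baseline edge
#' means are drawn Normal(0.3, 0.15) on the Fisher-z scale.
#'
#' The default sex effect of 0.5 z-units at residual SD 1 was fixed by an a
#' priori power analysis: with 203/291 subjects the sex-coefficient
#' noncentrality is 0.5/sqrt(1/203 + 1/291) ~= 5.5, giving roughly 80% power
#' at the Bonferroni threshold 0.05/6670.
#'
#' @param nEdges Total number of edges.
#' @param nSexEdges,nAgeEdges,nIntEdges Counts of non-null edges per term
#'   (must sum to at most `nEdges`; the sets are disjoint).
#' @param effectSizes Named numeric vector of magnitudes: `sex` (z-units),
#'   `age` (z-units/year), `int` (z-units/year). Signs are applied by the
#'   function (sex +, age -, int as given).
#' @param noiseSd Residual standard deviation sigma_e (> 0; recycled).
#' @param seed Integer seed.
#' @return An [EffectMap].
#' @export
makeEffectMap <- function(nEdges, nSexEdges = 0, nAgeEdges = 0, nIntEdges = 0,
                          effectSizes = c(sex = 0.5, age = 0.05, int = 0.02),
                          noiseSd = 1, seed = 1L) {
  if (nSexEdges + nAgeEdges + nIntEdges > nEdges) {
    stop("non-null edge counts exceed the number of edges", call. = FALSE)
  }
  if (any(noiseSd <= 0)) stop("noiseSd must be positive", call. = FALSE)
  es <- c(sex = 0.5, age = 0.05, int = 0.02)
  es[names(effectSizes)] <- effectSizes
  set.seed(deriveSeed(seed, 202L))
  ids <- sample.int(nEdges, nSexEdges + nAgeEdges + nIntEdges) - 1L
  sexIds <- ids[seq_len(nSexEdges)]
  ageIds <- ids[nSexEdges + seq_len(nAgeEdges)]
  intIds <- ids[nSexEdges + nAgeEdges + seq_len(nIntEdges)]
  edges <- data.frame(
    edge_id = seq_len(nEdges) - 1L,
    mu = stats::rnorm(nEdges, 0.3, 0.15),
    b_sex = 0, b_age = 0, b_int = 0,
    sigma = rep_len(noiseSd, nEdges))
  edges$b_sex[edges$edge_id %in% sexIds] <- abs(es[["sex"]])
  edges$b_age[edges$edge_id %in% ageIds] <- -abs(es[["age"]])
  edges$b_int[edges$edge_id %in% intIds] <- es[["int"]]
  new("EffectMap", edges = edges,
      nonnull = list(sex = sort(sexIds), age = sort(ageIds),
                     int = sort(intIds)),
      seed = as.integer(seed))
}

#' Simulate a group FC table directly on the Fisher-z scale
#'
#' The generative inverse of the per-edge regression model: for subject s and
#' edge e,
#' `z_se = mu_e + b_sex_e * sex_s + b_age_e * age_s + b_int_e * sex_s * age_s
#'  + N(0, sigma_e^2)`,
#' with sex coded female = 0 / male = 1 and age in raw years — exactly the
#' coding the regression module fits, so planted coefficients are recovered
#' on the same scale.
#'
#' @param cohort Cohort table from [makeCohort()].
#' @param effects An [EffectMap].
#' @param seed Integer seed for the noise draw.
#' @return An [FCExperiment].
#' @export
simulateDirectZ <- function(cohort, effects, seed = 1L) {
  ef <- effectTable(effects)
  n <- nrow(cohort)
  E <- nrow(ef)
  sex <- as.numeric(cohort$sex == "M")
  age <- cohort$age_years
  mean <- outer(sex, ef$b_sex) + outer(age, ef$b_age) +
    outer(sex * age, ef$b_int)
  mean <- sweep(mean, 2, ef$mu, "+")
  set.seed(deriveSeed(seed, 303L))
  noise <- matrix(stats::rnorm(n * E), n, E)
  noise <- sweep(noise, 2, ef$sigma, "*")
  FCExperiment(mean + noise, cohort)
}

#' Simulate per-subject ROI time series with lobe-block covariance
#'
#' Draws each subject's T x R time-series matrix from a zero-mean
#' multivariate normal whose target correlation matrix has `blockR` within
#' lobe blocks, `baseR` between lobes, and an optional per-designated-edge
#' correlation shift of `sexDeltaR` added for male subjects (embedding a sex
#' effect on the correlation scale). Non-positive-definite targets are
#' repaired by linear shrinkage toward the identity (factor 0.95 per
#' iteration, at most 200 iterations) until the smallest eigenvalue exceeds
#' 1e-8.
#'
#' @param cohort Cohort table.
#' @param scheme A [ParcellationScheme] supplying the lobe blocks.
#' @param blockR Within-lobe target correlation.
#' @param baseR Between-lobe target correlation.
#' @param sexDeltaR Correlation shift added at `sexEdges` for males.
#' @param sexEdges Two-column matrix of region index pairs (i, j) receiving
#'   the shift; NULL for none.
#' @param nTimepoints Number of timepoints T (>= R + 2).
#' @param seed Integer seed.
#' @return Named list (by `subject_id`) of T x R matrices.
#' @export
simulateTimeSeries <- function(cohort, scheme, blockR = 0.3, baseR = 0.05,
                               sexDeltaR = 0, sexEdges = NULL,
                               nTimepoints = 1200, seed = 1L) {
  R <- nRegions(scheme)
  if (nTimepoints < R + 2) {
    stop("nTimepoints must be >= nRegions + 2", call. = FALSE)
  }
  lob <- regionLobes(scheme)
  target <- matrix(baseR, R, R)
  same <- outer(lob, lob, "==")
  target[same] <- blockR
  diag(target) <- 1
  chols <- list(F = NULL, M = NULL)
  for (sx in c("F", "M")) {
    tg <- target
    if (sx == "M" && !is.null(sexEdges) && nrow(sexEdges) > 0) {
      for (k in seq_len(nrow(sexEdges))) {
        i <- sexEdges[k, 1]; j <- sexEdges[k, 2]
        tg[i, j] <- tg[j, i] <- min(tg[i, j] + sexDeltaR, 0.99)
      }
    }
    iter <- 0
    while (min(eigen(tg, symmetric = TRUE, only.values = TRUE)$values) <=
           1e-8) {
      if (iter >= 200) {
        stop("target correlation not positive definite after maximum ",
             "shrinkage iterations", call. = FALSE)
      }
      tg <- 0.95 * tg + 0.05 * diag(R)
      iter <- iter + 1
    }
    chols[[sx]] <- chol(tg)
  }
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$subject_id
  for (s in seq_len(nrow(cohort))) {
    set.seed(deriveSeed(seed, 404L, s))
    zmat <- matrix(stats::rnorm(nTimepoints * R), nTimepoints, R)
    out[[s]] <- zmat %*% chols[[cohort$sex[s]]]
  }
  out
}
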
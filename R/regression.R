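#' Ordinary least squares with full diagnostics
#'
#' QR-based least squares used by every regression path in the package.
#' Returns coefficient t-tests (n - p d.f.), the overall model F against the
#' intercept-only model, and the residual sum of squares. Degenerate cases
#' follow the conventions the pipeline needs: an exactly constant response
#' gives zero slopes and a model-F p-value of 1; an exact fit (RSS = 0)
#' gives p = 0 for every nonzero coefficient.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @return List with `coefficients`, `se`, `t`, `p`, `rss`, `sigma2`,
#'   `dfResid`, `F`, `pF`.
#' @export
fitOLS <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need n > number of design columns", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  dfResid <- n - p
  sigma2 <- rss / dfResid
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tol <- 1e-12 * max(sum(y^2), 1)
  tt <- ifelse(se > 0, beta / se, ifelse(abs(beta) < sqrt(tol), 0, Inf))
  pv <- 2 * stats::pt(abs(tt), df = dfResid, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  if (p > 1) {
    Fstat <- ((tss - rss) / (p - 1)) / sigma2
    if (rss < tol) {
      pF <- if ((tss - rss) < tol) 1 else 0
      Fstat <- if ((tss - rss) < tol) 0 else Inf
    } else {
      pF <- stats::pf(Fstat, p - 1, dfResid, lower.tail = FALSE)
    }
  } else {
    Fstat <- NA_real_
    pF <- NA_real_
  }
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(as.numeric(se), colnames(X)),
       t = stats::setNames(as.numeric(tt), colnames(X)),
       p = stats::setNames(as.numeric(pv), colnames(X)),
       rss = rss, sigma2 = sigma2, dfResid = dfResid,
       F = Fstat, pF = pF)
}

# Sex/age design matrices for the five-model family.
# Sex coded female = 0 / male = 1; age in raw years unless centerAge.
sexAgeDesigns <- function(cohort, centerAge = FALSE) {
  sex <- as.numeric(cohort$sex == "M")
  age <- cohort$age_years
  if (centerAge) age <- age - mean(age)
  one <- rep(1, length(sex))
  list(
    M1 = cbind(`(Intercept)` = one),
    M2 = cbind(`(Intercept)` = one, sex = sex),
    M3 = cbind(`(Intercept)` = one, age = age),
    M4 = cbind(`(Intercept)` = one, sex = sex, age = age),
    M5 = cbind(`(Intercept)` = one, sex = sex, age = age,
               `sex:age` = sex * age))
}

# RSS of one fixed design across many responses (columns of Y), via the
# projection ||y||^2 - ||Q'y||^2. The design is shared by all edges, which is
# what makes the mass-univariate stage cheap.
projectionRSS <- function(Y, X) {
  Q <- qr.Q(qr(X))
  pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
}

# Partial-F p-value for single-term removal, vectorized over edges.
# rssFull ~ 0 needs care (noise-free responses): a removal that keeps the
# fit exact is maximally insignificant (p = 1); one that breaks it is
# maximally significant (p = 0).
dropTermP <- function(rssRed, rssFull, dfResidFull, tol) {
  delta <- rssRed - rssFull
  f <- delta / (rssFull / dfResidFull)
  p <- stats::pf(f, 1, dfResidFull, lower.tail = FALSE)
  tiny <- rssFull < tol
  p[tiny & delta < tol] <- 1
  p[tiny & delta >= tol] <- 0
  pmin(pmax(p, 0), 1)
}

#' Backward stepwise selection over the sex/age model family
#'
#' Starting from the full model (sex + age + sex:age, plus any extra
#' covariates), iteratively removes the currently least significant removable
#' term until every removable term's single-term partial-F removal p-value is
#' below `alphaRemove`. The marginality rule is enforced: sex or age are only
#' removable while sex:age is absent, so the reachable sex/age models are
#' exactly M1 (none), M2 (sex), M3 (age), M4 (sex + age), M5 (all three).
#' For single-term removal the partial F equals the squared t of that term's
#' coefficient in the larger model, so this matches a model-comparison rule.
#'
#' Ties in removal p-values are broken deterministically: the higher-order
#' term (sex:age) goes first, then the later-listed term.
#'
#' @param y Response vector (one edge's Fisher-z values across subjects).
#' @param cohort Cohort table supplying sex and age.
#' @param alphaRemove Stay/remove threshold (default 0.05).
#' @param centerAge Mean-center age before fitting.
#' @param covariates Optional matrix of extra covariate columns (removable at
#'   any time).
#' @return List with `model` ("M1".."M5"), `terms` (surviving term names),
#'   `fit` (the [fitOLS] fit of the selected model) and `path` (removal
#'   order).
#' @export
backwardSelect <- function(y, cohort, alphaRemove = 0.05, centerAge = FALSE,
                           covariates = NULL) {
  sex <- as.numeric(cohort$sex == "M")
  age <- cohort$age_years
  if (centerAge) age <- age - mean(age)
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  X <- cbind(X, sex = sex, age = age, `sex:age` = sex * age)
  terms <- setdiff(colnames(X), "(Intercept)")
  tol <- 1e-12 * max(sum(y^2), 1)
  path <- character()
  repeat {
    removable <- terms
    if ("sex:age" %in% terms) {
      removable <- setdiff(removable, c("sex", "age"))
    }
    if (!length(removable)) break
    full <- X[, c("(Intercept)", terms), drop = FALSE]
    rssFull <- projectionRSS(cbind(y), full)
    dfFull <- length(y) - ncol(full)
    pRem <- vapply(removable, function(tm) {
      red <- X[, c("(Intercept)", setdiff(terms, tm)), drop = FALSE]
      dropTermP(projectionRSS(cbind(y), red), rssFull, dfFull, tol)
    }, numeric(1))
    if (max(pRem) < alphaRemove) break
    worst <- pRem[pRem == max(pRem)]
    drop <- names(worst)[length(worst)] # later-listed on exact ties
    terms <- setdiff(terms, drop)
    path <- c(path, drop)
  }
  core <- intersect(c("sex", "age", "sex:age"), terms)
  model <- if (setequal(core, c("sex", "age", "sex:age"))) "M5"
  else if (setequal(core, c("sex", "age"))) "M4"
  else if (setequal(core, "age")) "M3"
  else if (setequal(core, "sex")) "M2"
  else "M1"
  fit <- fitOLS(y, X[, c("(Intercept)", terms), drop = FALSE])
  list(model = model, terms = terms, fit = fit, path = path)
}

# Vectorized family-path backward selection for all edges at once.
# Returns the per-edge selected model id plus the RSS of every family model.
selectFamily <- function(Y, designs, alphaRemove) {
  n <- nrow(Y)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  tol <- 1e-12 * pmax(colSums(Y^2), 1)
  rss <- sapply(designs, function(X) projectionRSS(Y, X))
  if (is.null(dim(rss))) rss <- matrix(rss, nrow = 1,
                                       dimnames = list(NULL, names(designs)))
  model <- rep("M5", ncol(Y))
  # step 1: only sex:age is removable from M5 (marginality)
  pInt <- dropTermP(rss[, "M4"], rss[, "M5"], n - 4, tol)
  inM4 <- pInt >= alphaRemove
  model[inM4] <- "M4"
  # step 2: within M4, drop the weaker of sex/age if removable
  pSexRm <- dropTermP(rss[, "M3"], rss[, "M4"], n - 3, tol)
  pAgeRm <- dropTermP(rss[, "M2"], rss[, "M4"], n - 3, tol)
  worst <- pmax(pSexRm, pAgeRm)
  act <- inM4 & worst >= alphaRemove
  # ties remove the later-listed term (age)
  toM3 <- act & (pSexRm > pAgeRm)  # sex removed, age stays
  toM2 <- act & (pSexRm <= pAgeRm) # age removed, sex stays
  model[toM3] <- "M3"
  model[toM2] <- "M2"
  # step 3: single-covariate models down to M1
  pSexOnly <- dropTermP(rss[, "M1"], rss[, "M2"], n - 2, tol)
  pAgeOnly <- dropTermP(rss[, "M1"], rss[, "M3"], n - 2, tol)
  model[toM2 & pSexOnly >= alphaRemove] <- "M1"
  model[toM3 & pAgeOnly >= alphaRemove] <- "M1"
  list(model = model, rss = rss, tss = tss, tol = tol)
}

#' Mass-univariate edge-wise regression with backward selection
#'
#' Applies [backwardSelect()]'s family path to every edge of the group FC
#' table (vectorized over edges, since all edges share the design), then
#' extracts significance: the model-level gate is the selected model's
#' overall F-test against the intercept-only model at the corrected
#' threshold, and term-level significance is read from the selected model's
#' coefficient p-values at the same threshold. Direction flags report
#' male > female for positive sex coefficients and FC-decreasing-with-age
#' for negative age coefficients.
#'
#' @param fce An [FCExperiment].
#' @param alpha Family-wise error level (default 0.05).
#' @param alphaRemove Stepwise stay/remove threshold (default 0.05).
#' @param correction `"bonferroni"` (threshold alpha / n_edges) or
#'   `"bh_fdr"` (Benjamini-Hochberg on the model F p-values and on each
#'   term's p-values).
#' @param centerAge Mean-center age before fitting.
#' @param nTests Bonferroni denominator; defaults to the number of edges.
#' @return A `MassUnivariateReport`: list with `results` (per-edge table),
#'   `counts`, `threshold`, and the settings used.
#' @export
runMassUnivariate <- function(fce, alpha = 0.05, alphaRemove = 0.05,
                              correction = c("bonferroni", "bh_fdr"),
                              centerAge = FALSE, nTests = NULL) {
  correction <- match.arg(correction)
  cohort <- cohortTable(fce)
  Y <- groupFCMatrix(fce)
  idx <- edgeIndex(fce)
  n <- nrow(Y)
  E <- ncol(Y)
  if (is.null(nTests)) nTests <- E
  designs <- sexAgeDesigns(cohort, centerAge)
  if (n <= ncol(designs$M5)) stop("need n > 4 subjects", call. = FALSE)
  sel <- selectFamily(Y, designs, alphaRemove)
  model <- sel$model

  res <- data.frame(idx,
                    model = model,
                    beta0 = NA_real_, beta_sex = NA_real_,
                    beta_age = NA_real_, beta_int = NA_real_,
                    p_sex = NA_real_, p_age = NA_real_, p_int = NA_real_,
                    F = NA_real_, p_F = NA_real_,
                    stringsAsFactors = FALSE)
  termCol <- c(sex = "beta_sex", age = "beta_age", `sex:age` = "beta_int")
  pCol <- c(sex = "p_sex", age = "p_age", `sex:age` = "p_int")
  for (m in c("M1", "M2", "M3", "M4", "M5")) {
    edges <- which(model == m)
    if (!length(edges)) next
    X <- designs[[m]]
    p <- ncol(X)
    qrX <- qr(X)
    beta <- qr.coef(qrX, Y[, edges, drop = FALSE])
    if (is.null(dim(beta))) beta <- matrix(beta, nrow = p)
    rownames(beta) <- colnames(X)
    rssm <- sel$rss[edges, m]
    dfResid <- n - p
    sigma2 <- rssm / dfResid
    XtXinv <- chol2inv(qr.R(qrX))
    res$beta0[edges] <- beta["(Intercept)", ]
    for (tm in intersect(c("sex", "age", "sex:age"), colnames(X))) {
      jj <- match(tm, colnames(X))
      se <- sqrt(pmax(sigma2 * XtXinv[jj, jj], 0))
      b <- beta[tm, ]
      tt <- ifelse(se > 0, b / se,
                   ifelse(abs(b) < sqrt(sel$tol[edges]), 0, Inf))
      res[[termCol[tm]]][edges] <- b
      res[[pCol[tm]]][edges] <-
        2 * stats::pt(abs(tt), df = dfResid, lower.tail = FALSE)
    }
    if (p > 1) {
      Fm <- ((sel$tss[edges] - rssm) / (p - 1)) / sigma2
      pF <- stats::pf(Fm, p - 1, dfResid, lower.tail = FALSE)
      tiny <- rssm < sel$tol[edges]
      delta <- sel$tss[edges] - rssm
      pF[tiny & delta < sel$tol[edges]] <- 1
      pF[tiny & delta >= sel$tol[edges]] <- 0
      res$F[edges] <- Fm
      res$p_F[edges] <- pF
    }
  }

  thr <- bonferroniThreshold(alpha, nTests)
  if (correction == "bonferroni") {
    sigModel <- !is.na(res$p_F) & res$p_F < thr$threshold
    sigTerm <- function(p) sigModel & !is.na(p) & p < thr$threshold
    res$sig_model <- sigModel
    res$sig_sex <- sigTerm(res$p_sex)
    res$sig_age <- sigTerm(res$p_age)
    res$sig_int <- sigTerm(res$p_int)
  } else {
    adjF <- rep(NA_real_, E)
    ok <- !is.na(res$p_F)
    adjF[ok] <- stats::p.adjust(res$p_F[ok], method = "BH")
    sigModel <- !is.na(adjF) & adjF < alpha
    res$sig_model <- sigModel
    for (tm in c("p_sex", "p_age", "p_int")) {
      adj <- rep(NA_real_, E)
      ok <- !is.na(res[[tm]])
      adj[ok] <- stats::p.adjust(res[[tm]][ok], method = "BH")
      res[[sub("p_", "sig_", tm)]] <- sigModel & !is.na(adj) & adj < alpha
    }
  }
  res$dir_sex <- ifelse(is.na(res$beta_sex), NA_character_,
                        ifelse(res$beta_sex > 0, "M>F", "F>M"))
  res$dir_age <- ifelse(is.na(res$beta_age), NA_character_,
                        ifelse(res$beta_age < 0, "older<younger",
                               "older>younger"))

  counts <- list(
    n_edges = E,
    models = table(factor(res$model, levels = paste0("M", 1:5))),
    models_significant = table(factor(res$model[res$sig_model],
                                      levels = paste0("M", 1:5))),
    n_significant_models = sum(res$sig_model),
    sex_male_gt_female = sum(res$sig_sex & res$beta_sex > 0, na.rm = TRUE),
    sex_female_gt_male = sum(res$sig_sex & res$beta_sex < 0, na.rm = TRUE),
    sex_male_gt_female_uncorrected =
      sum(!is.na(res$p_sex) & res$p_sex < alpha & res$beta_sex > 0),
    sex_female_gt_male_uncorrected =
      sum(!is.na(res$p_sex) & res$p_sex < alpha & res$beta_sex < 0),
    age_negative = sum(res$sig_age & res$beta_age < 0, na.rm = TRUE),
    age_positive = sum(res$sig_age & res$beta_age > 0, na.rm = TRUE),
    int_significant = sum(res$sig_int, na.rm = TRUE))

  structure(list(results = res, counts = counts, threshold = thr,
                 alpha = alpha, alphaRemove = alphaRemove,
                 correction = correction, centerAge = centerAge,
                 n = n, nTests = nTests),
            class = "MassUnivariateReport")
}

#' @export
print.MassUnivariateReport <- function(x, ...) {
  cat("Mass-univariate edge regression report\n")
  cat(sprintf("  %d edges, %d subjects; correction: %s (threshold %.3g)\n",
              x$counts$n_edges, x$n, x$correction, x$threshold$threshold))
  cat(sprintf("  significant models: %d\n", x$counts$n_significant_models))
  m <- x$counts$models_significant
  cat("  by model:", paste(sprintf("%s=%d", names(m), m), collapse = " "),
      "\n")
  cat(sprintf("  sex: male>female %d, female>male %d (corrected)\n",
              x$counts$sex_male_gt_female, x$counts$sex_female_gt_male))
  cat(sprintf("  age: negative %d, positive %d (corrected)\n",
              x$counts$age_negative, x$counts$age_positive))
  invisible(x)
}

#' Refit selected models with appended covariates
#'
#' Appends the named cohort covariates to each edge's previously selected
#' model (no re-selection of the sex/age terms) and re-extracts term
#' significance at the report's threshold, reporting which previously
#' significant sex/age edges survive and which become newly significant.
#'
#' @param report A `MassUnivariateReport`.
#' @param fce The [FCExperiment] the report was computed from.
#' @param covariates Character vector of cohort column names to append.
#' @return List with `results` (per-edge refit table) and `comparison`
#'   (survived / lost / new counts per term).
#' @export
augmentWithCovariates <- function(report, fce, covariates) {
  cohort <- cohortTable(fce)
  missing <- setdiff(covariates, colnames(cohort))
  if (length(missing)) {
    stop("covariate(s) not in cohort: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Z <- as.matrix(cohort[, covariates, drop = FALSE])
  if (any(apply(Z, 2, stats::sd) == 0)) {
    stop("zero-variance covariate(s): ",
         paste(covariates[apply(Z, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  Y <- groupFCMatrix(fce)
  n <- nrow(Y)
  designs <- sexAgeDesigns(cohort, report$centerAge)
  res <- report$results
  out <- res[, c("edge_id", "i", "j", "pair", "model")]
  out$p_sex <- out$p_age <- out$p_int <- NA_real_
  out$beta_sex <- out$beta_age <- out$beta_int <- NA_real_
  termCol <- c(sex = "beta_sex", age = "beta_age", `sex:age` = "beta_int")
  pCol <- c(sex = "p_sex", age = "p_age", `sex:age` = "p_int")
  for (m in paste0("M", 1:5)) {
    edges <- which(res$model == m)
    if (!length(edges)) next
    X <- cbind(designs[[m]], Z)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                                 qrX$pivot[seq_len(qrX$rank)])]
      stop("augmented design rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p <- ncol(X)
    beta <- qr.coef(qrX, Y[, edges, drop = FALSE])
    if (is.null(dim(beta))) beta <- matrix(beta, nrow = p)
    rownames(beta) <- colnames(X)
    Q <- qr.Q(qrX)
    rssm <- pmax(colSums(Y[, edges, drop = FALSE]^2) -
                   colSums(crossprod(Q, Y[, edges, drop = FALSE])^2), 0)
    sigma2 <- rssm / (n - p)
    XtXinv <- chol2inv(qr.R(qrX))
    for (tm in intersect(c("sex", "age", "sex:age"), colnames(X))) {
      jj <- match(tm, colnames(X))
      se <- sqrt(pmax(sigma2 * XtXinv[jj, jj], 0))
      tt <- ifelse(se > 0, beta[tm, ] / se, Inf)
      out[[termCol[tm]]][edges] <- beta[tm, ]
      out[[pCol[tm]]][edges] <-
        2 * stats::pt(abs(tt), df = n - p, lower.tail = FALSE)
    }
  }
  thr <- report$threshold$threshold
  comparison <- lapply(c(sex = "sex", age = "age", int = "int"), function(tm) {
    before <- report$results[[paste0("sig_", tm)]]
    pNew <- out[[paste0("p_", tm)]]
    after <- !is.na(pNew) & pNew < thr
    list(survived = sum(before & after), lost = sum(before & !after),
         new = sum(!before & after))
  })
  out$sig_sex <- !is.na(out$p_sex) & out$p_sex < thr
  out$sig_age <- !is.na(out$p_age) & out$p_age < thr
  out$sig_int <- !is.na(out$p_int) & out$p_int < thr
  list(results = out, comparison = comparison, covariates = covariates,
       threshold = report$threshold)
}

#' Sex-stratified per-edge age slopes
#'
#' Fits the simple regression of each edge's Fisher-z FC on age separately
#' within males and within females, with two-sided slope t-tests and
#' per-group Bonferroni flags, and counts the edges where both slopes are
#' negative with the female slope larger in magnitude (the joint-direction
#' summary of cross-sectional decline).
#'
#' @param fce An [FCExperiment].
#' @param alpha Family-wise level for the per-group Bonferroni flags.
#' @return List with `results` (per-edge slopes and p-values), `counts`
#'   (Bonferroni-significant slopes per group; joint-direction count).
#' @export
stratifiedAgeSlopes <- function(fce, alpha = 0.05) {
  cohort <- cohortTable(fce)
  Y <- groupFCMatrix(fce)
  E <- ncol(Y)
  groups <- list(male = cohort$sex == "M", female = cohort$sex == "F")
  if (any(vapply(groups, sum, numeric(1)) < 3)) {
    stop("each sex group needs at least 3 subjects", call. = FALSE)
  }
  out <- edgeIndex(fce)
  for (g in names(groups)) {
    sel <- groups[[g]]
    ng <- sum(sel)
    age <- cohort$age_years[sel]
    Yg <- Y[sel, , drop = FALSE]
    ac <- age - mean(age)
    sxx <- sum(ac^2)
    slope <- as.numeric(crossprod(ac, Yg)) / sxx
    inter <- colMeans(Yg) - slope * mean(age)
    fitted <- outer(age, slope) + matrix(inter, ng, E, byrow = TRUE)
    rss <- colSums((Yg - fitted)^2)
    sigma2 <- rss / (ng - 2)
    se <- sqrt(sigma2 / sxx)
    tol <- 1e-12 * pmax(colSums(Yg^2), 1)
    tt <- ifelse(se > 0, slope / se,
                 ifelse(abs(slope) < sqrt(tol), 0, Inf))
    pv <- 2 * stats::pt(abs(tt), df = ng - 2, lower.tail = FALSE)
    out[[paste0("slope_", g)]] <- slope
    out[[paste0("p_", g)]] <- pv
    out[[paste0("sig_", g)]] <- pv < alpha / E
  }
  jointNegative <- sum(out$slope_male < 0 & out$slope_female < 0 &
                         abs(out$slope_female) > abs(out$slope_male))
  list(results = out,
       counts = list(
         male_significant = sum(out$sig_male),
         female_significant = sum(out$sig_female),
         both_negative_female_steeper = jointNegative,
         fraction = jointNegative / E))
}

#' Direct edge-cognition correlations
#'
#' Pearson correlation of every edge's FC values with one cognitive score,
#' two-sided t-based p-values, Bonferroni control at `alpha / nTests`.
#'
#' @param fce An [FCExperiment].
#' @param score Name of the cohort score column.
#' @param alpha Family-wise level.
#' @param nTests Bonferroni denominator (defaults to the number of edges).
#' @return List with `results` (all edges) and `significant` (surviving
#'   edges only).
#' @export
edgeCognitionCorrelation <- function(fce, score, alpha = 0.05,
                                     nTests = NULL) {
  cohort <- cohortTable(fce)
  if (!score %in% colnames(cohort)) {
    stop("score '", score, "' not in cohort", call. = FALSE)
  }
  s <- cohort[[score]]
  if (stats::sd(s) == 0) stop("score is constant", call. = FALSE)
  n <- length(s)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  Y <- groupFCMatrix(fce)
  if (is.null(nTests)) nTests <- ncol(Y)
  r <- as.numeric(stats::cor(s, Y))
  p <- corPValue(r, n)
  out <- edgeIndex(fce)
  out$score <- score
  out$r <- r
  out$p <- p
  out$sig <- p < alpha / nTests
  list(results = out, significant = out[out$sig, , drop = FALSE],
       threshold = bonferroniThreshold(alpha, nTests))
}
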
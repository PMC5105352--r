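# Independent brute-force oracles. These deliberately share no code with the
# package: distances come from a queue-based BFS, clustering from explicit
# triple enumeration, components from label propagation, and OLS from the
# normal equations.

randomAdjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut[stats::runif(length(ut)) < p]] <- 1L
  A + t(A)
}

oracleBFS <- function(A, source) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in which(A[v, ] > 0)) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

oracleDistances <- function(A) {
  t(vapply(seq_len(nrow(A)), function(s) oracleBFS(A, s),
           numeric(nrow(A))))
}

oracleClustering <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] > 0) t <- t + 1
      }
    }
    2 * t / (k * (k - 1))
  }, numeric(1))
}

oracleLocalEfficiency <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    D <- oracleDistances(A[nb, nb, drop = FALSE])
    mean(1 / D[row(D) != col(D)]) # 1/Inf = 0
  }, numeric(1))
}

oraclePathLength <- function(A) {
  D <- oracleDistances(A)
  n <- nrow(A)
  n * (n - 1) / sum(1 / D[row(D) != col(D)])
}

oracleLargestComponent <- function(A) {
  n <- nrow(A)
  comp <- seq_len(n)
  e <- which(A > 0, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      a <- e[k, 1]; b <- e[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  max(table(comp))
}

oracleOLS <- function(y, X) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

degreeMultiset <- function(A) sort(rowSums(A))

isSimpleBinary <- function(A) {
  all(A %in% c(0L, 1L)) && all(diag(A) == 0) && identical(A, t(A))
}

# lm()-based backward stepwise with the marginality rule: an independent
# route to the selected model for cross-checking backwardSelect().
lmStepwiseOracle <- function(y, cohort, alphaRemove = 0.05) {
  dat <- data.frame(y = y, sex = as.numeric(cohort$sex == "M"),
                    age = cohort$age_years)
  terms <- c("sex", "age", "sex:age")
  repeat {
    removable <- if ("sex:age" %in% terms) "sex:age" else terms
    if (!length(removable)) break
    form <- stats::reformulate(c("1", terms), response = "y")
    fit <- stats::lm(form, data = dat)
    d <- stats::drop1(fit, scope = stats::reformulate(removable),
                      test = "F")
    pr <- d[["Pr(>F)"]][-1]
    names(pr) <- rownames(d)[-1]
    if (max(pr) < alphaRemove) break
    worst <- pr[pr == max(pr)]
    terms <- setdiff(terms, names(worst)[length(worst)])
  }
  if (setequal(terms, c("sex", "age", "sex:age"))) "M5"
  else if (setequal(terms, c("sex", "age"))) "M4"
  else if (setequal(terms, "age")) "M3"
  else if (setequal(terms, "sex")) "M2"
  else "M1"
}
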
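#' Proportional (density) thresholding of an FC matrix
#'
#' Retains the k = round(density * R(R-1)/2) edges with the largest Fisher-z
#' values (signed by default; set `absolute = TRUE` to rank |z|), rounding
#' halves away from zero, and returns the binary adjacency matrix. Ties at
#' the cutoff are broken by ascending (i, j) lexicographic order so the edge
#' count is exact and runs are bit-reproducible. Proportional thresholding
#' fixes the wiring cost, making graph metrics comparable across subjects.
#'
#' @param fc Symmetric R x R matrix of edge weights (Fisher-z).
#' @param density Target graph density in (0, 1].
#' @param absolute Rank by absolute weight instead of signed weight.
#' @return R x R binary adjacency matrix (0/1, zero diagonal).
#' @export
proportionalThreshold <- function(fc, density, absolute = FALSE) {
  if (density <= 0 || density > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  R <- nrow(fc)
  idx <- edgeIndexTable(R)
  w <- fc[cbind(idx$i, idx$j)]
  if (absolute) w <- abs(w)
  k <- roundHalfAway(density * nrow(idx))
  A <- matrix(0L, R, R)
  if (k > 0) {
    ord <- order(-w, idx$i, idx$j)
    keep <- ord[seq_len(k)]
    A[cbind(idx$i[keep], idx$j[keep])] <- 1L
    A[cbind(idx$j[keep], idx$i[keep])] <- 1L
  }
  A
}

#' Geodesic distance matrix of a binary graph
#'
#' Unweighted shortest-path distances by breadth-first expansion of the
#' reachability matrix; disconnected pairs keep distance Inf.
#'
#' @param adj Binary adjacency matrix.
#' @return Matrix of geodesic distances (Inf where unreachable, 0 diagonal).
#' @export
graphDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  step <- (adj > 0) * 1
  reach <- step
  k <- 1
  new <- reach == 1 & is.infinite(D)
  while (any(new) && k <= n) {
    D[new] <- k
    reach <- (reach %*% step > 0) * 1
    k <- k + 1
    new <- reach == 1 & is.infinite(D)
  }
  D
}

#' Nodal clustering coefficient
#'
#' c_i = 2 t_i / (k_i (k_i - 1)) where t_i is the number of triangles through
#' node i and k_i its degree; c_i = 0 for degree < 2. Measures how strongly a
#' node's neighbours are interconnected (functional segregation).
#'
#' @param adj Binary adjacency matrix.
#' @return Numeric vector of per-node clustering coefficients in [0, 1].
#' @export
nodalClustering <- function(adj) {
  A <- (adj > 0) * 1
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
}

#' Nodal local efficiency
#'
#' Efficiency of the subgraph induced by node i's neighbours: the mean over
#' ordered neighbour pairs of the inverse geodesic distance within that
#' induced subgraph (1/Inf = 0); e_i = 0 for degree < 2.
#'
#' @param adj Binary adjacency matrix.
#' @return Numeric vector of per-node local efficiencies in [0, 1].
#' @export
nodalLocalEfficiency <- function(adj) {
  A <- (adj > 0) * 1
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    D <- graphDistances(A[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  out
}

#' Characteristic path length (harmonic mean)
#'
#' L = P / sum over ordered pairs of 1/d, with P = R(R-1) and 1/d = 0 for
#' disconnected pairs — i.e. the harmonic mean of geodesic distances, the
#' reciprocal of global efficiency. Finite for any graph with at least one
#' edge, which is why it is used instead of the arithmetic mean when graphs
#' may be disconnected.
#'
#' @param adj Binary adjacency matrix with >= 1 edge.
#' @return Scalar L >= 1.
#' @export
characteristicPathLength <- function(adj) {
  if (sum(adj > 0) == 0) {
    stop("characteristic path length undefined for an edgeless graph",
         call. = FALSE)
  }
  D <- graphDistances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  n <- nrow(adj)
  n * (n - 1) / sum(inv)
}

#' Size of the largest connected component
#'
#' @param adj Binary adjacency matrix.
#' @return Node count of the biggest connected subgraph (1 for an edgeless
#'   graph).
#' @export
largestComponentSize <- function(adj) {
  D <- graphDistances(adj)
  as.integer(max(rowSums(is.finite(D))))
}

#' Degree-preserving rewiring nulls (Maslov-Sneppen)
#'
#' Generates an ensemble of random graphs with exactly the original degree
#' sequence by repeated double-edge swaps: two edges (a,b), (c,d) are
#' replaced by (a,d), (c,b), rejecting proposals that would create self-loops
#' or duplicate edges. Each null performs `swapsPerEdge * |E|` successful
#' swaps (attempts capped at 100x the target; a shortfall is reported with a
#' warning). A graph admitting no legal swap is returned as an unchanged copy
#' with a warning.
#'
#' @param adj Binary adjacency matrix (>= 2 edges).
#' @param nNulls Ensemble size (default 30).
#' @param swapsPerEdge Successful swaps per edge (default 10).
#' @param seed Integer seed; null k uses a derived substream so the ensemble
#'   is reproducible regardless of evaluation order.
#' @return List of `nNulls` adjacency matrices.
#' @export
rewireDegreePreserving <- function(adj, nNulls = 30, swapsPerEdge = 10,
                                   seed = 1L) {
  stopifnot(nNulls >= 1, swapsPerEdge >= 1)
  A0 <- (adj > 0) * 1L
  idx <- which(upper.tri(A0) & A0 == 1L, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2) {
    warning("graph has fewer than 2 edges; nulls returned as copies",
            call. = FALSE)
    return(replicate(nNulls, A0, simplify = FALSE))
  }
  target <- swapsPerEdge * m
  cap <- 100L * target
  out <- vector("list", nNulls)
  for (nl in seq_len(nNulls)) {
    set.seed(deriveSeed(seed, 7L, nl))
    A <- A0
    E <- idx
    succ <- 0L
    attempts <- 0L
    chunk <- 4096L
    pos <- chunk + 1L
    e1 <- e2 <- flip <- NULL
    while (succ < target && attempts < cap) {
      if (pos > chunk) { # refill proposal buffer
        e1 <- sample.int(m, chunk, replace = TRUE)
        e2 <- sample.int(m, chunk, replace = TRUE)
        flip <- stats::runif(chunk) < 0.5
        pos <- 1L
      }
      attempts <- attempts + 1L
      i1 <- e1[pos]; i2 <- e2[pos]; fl <- flip[pos]
      pos <- pos + 1L
      if (i1 == i2) next
      a <- E[i1, 1L]; b <- E[i1, 2L]
      if (fl) { c <- E[i2, 2L]; d <- E[i2, 1L] }
      else    { c <- E[i2, 1L]; d <- E[i2, 2L] }
      # propose (a,d) and (c,b)
      if (a == c || a == d || b == c || b == d) next
      if (A[a, d] == 1L || A[c, b] == 1L) next
      A[a, b] <- A[b, a] <- 0L
      A[c, d] <- A[d, c] <- 0L
      A[a, d] <- A[d, a] <- 1L
      A[c, b] <- A[b, c] <- 1L
      E[i1, ] <- c(min(a, d), max(a, d))
      E[i2, ] <- c(min(c, b), max(c, b))
      succ <- succ + 1L
    }
    if (succ < target) {
      warning(sprintf("null %d: only %d of %d swaps achieved within the attempt cap",
                      nl, succ, target), call. = FALSE)
    }
    out[[nl]] <- A
  }
  out
}

#' Small-worldness against rewiring nulls
#'
#' Computes the network clustering coefficient C (mean of nodal clustering
#' over all nodes, zero-degree nodes contributing 0) and the harmonic-mean
#' characteristic path length L for the graph and for an ensemble of
#' degree-preserving rewired nulls, and returns
#' sigma = (C / C_rand) / (L / L_rand) with C_rand, L_rand the ensemble
#' means. sigma > 1 is read as small-world organization. A triangle-free
#' null ensemble (C_rand = 0) leaves sigma NA rather than infinite.
#'
#' @inheritParams rewireDegreePreserving
#' @return List with `C`, `L`, `C_rand`, `L_rand`, `C_norm`, `L_norm`,
#'   `sigma`.
#' @export
smallWorldness <- function(adj, nNulls = 30, swapsPerEdge = 10, seed = 1L) {
  C <- mean(nodalClustering(adj))
  L <- characteristicPathLength(adj)
  nulls <- rewireDegreePreserving(adj, nNulls, swapsPerEdge, seed)
  Cr <- mean(vapply(nulls, function(a) mean(nodalClustering(a)), numeric(1)))
  Lr <- mean(vapply(nulls, characteristicPathLength, numeric(1)))
  Cn <- if (Cr > 0) C / Cr else NA_real_
  Ln <- if (Lr > 0) L / Lr else NA_real_
  sigma <- if (!is.na(Cn) && !is.na(Ln) && Ln > 0) Cn / Ln else NA_real_
  list(C = C, L = L, C_rand = Cr, L_rand = Lr,
       C_norm = Cn, L_norm = Ln, sigma = sigma)
}

#' Per-subject graph metrics across a density grid
#'
#' For every subject and every density level: proportional thresholding,
#' nodal clustering and local efficiency, network clustering coefficient C,
#' harmonic-mean characteristic path length L, largest-component size and —
#' when `nNulls > 0` — the rewiring-null normalized metrics and
#' small-worldness sigma. Randomness is confined to the null ensembles; each
#' (subject, density) pair draws from its own seed substream, so results do
#' not depend on evaluation order.
#'
#' @param fce An [FCExperiment], or a named list of R x R Fisher-z matrices.
#' @param grid Density levels (default 0.05 to 0.95 step 0.05, 19 levels).
#' @param nNulls Null-ensemble size per graph (default 30; 0 disables the
#'   small-world block).
#' @param swapsPerEdge Successful swaps per edge in each null.
#' @param seed Master seed for the null substreams.
#' @param absolute Rank edges by |z| when thresholding.
#' @return List with `nodal` (long data.frame: subject_id, density, node,
#'   clustering, local_efficiency) and `global` (per subject x density:
#'   n_edges, C, L, largest_component and, with nulls, C_rand, L_rand,
#'   C_norm, L_norm, sigma).
#' @export
runDensityGrid <- function(fce, grid = seq(0.05, 0.95, by = 0.05),
                           nNulls = 30, swapsPerEdge = 10, seed = 1L,
                           absolute = FALSE) {
  grid <- parseDensityGrid(grid)
  if (is(fce, "FCExperiment")) {
    Y <- groupFCMatrix(fce)
    R <- max(edgeIndex(fce)$j)
    mats <- lapply(seq_len(nrow(Y)), function(s) edgeMatrix(Y[s, ], R))
    names(mats) <- cohortTable(fce)$subject_id
  } else {
    mats <- fce
    R <- nrow(mats[[1]])
    if (is.null(names(mats))) names(mats) <- sprintf("S%04d", seq_along(mats))
  }
  nodalList <- list()
  globalList <- list()
  for (s in seq_along(mats)) {
    sid <- names(mats)[s]
    for (d in seq_along(grid)) {
      A <- proportionalThreshold(mats[[s]], grid[d], absolute = absolute)
      cc <- nodalClustering(A)
      le <- nodalLocalEfficiency(A)
      nodalList[[length(nodalList) + 1L]] <- data.frame(
        subject_id = sid, density = grid[d], node = seq_len(R),
        clustering = cc, local_efficiency = le,
        stringsAsFactors = FALSE)
      gl <- data.frame(
        subject_id = sid, density = grid[d],
        n_edges = sum(A) / 2,
        C = mean(cc),
        L = characteristicPathLength(A),
        largest_component = largestComponentSize(A),
        stringsAsFactors = FALSE)
      if (nNulls > 0) {
        sw <- smallWorldness(A, nNulls, swapsPerEdge,
                             seed = deriveSeed(seed, s, d))
        gl$C_rand <- sw$C_rand
        gl$L_rand <- sw$L_rand
        gl$C_norm <- sw$C_norm
        gl$L_norm <- sw$L_norm
        gl$sigma <- sw$sigma
      }
      globalList[[length(globalList) + 1L]] <- gl
    }
  }
  list(nodal = do.call(rbind, nodalList),
       global = do.call(rbind, globalList))
}
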
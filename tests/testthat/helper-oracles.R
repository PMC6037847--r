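# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: alignment scores come from explicit
# enumeration of all alignments, K2P site classes from a lookup table,
# topologies from exhaustive enumeration with least-squares branch fits.

# --- alignment enumeration oracle -------------------------------------------

# Maximum global alignment score by exhaustive recursion over all monotone
# paths, carrying the gap-run state so a run of length L costs
# open + (L-1)*extend. Only feasible for short sequences.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                open = -2, extend = -1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i == length(av) && j == length(bv)) return(0)
    best <- -Inf
    if (i < length(av) && j < length(bv)) {
      s <- if (av[i + 1] == bv[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < length(av)) {
      g <- if (last == "X") extend else open
      best <- max(best, g + rec(i + 1, j, "X"))
    }
    if (j < length(bv)) {
      g <- if (last == "Y") extend else open
      best <- max(best, g + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(0L, 0L, "M")
}

# Maximum local score: best global score over all pairs of contiguous
# substrings (empty alignment scores 0).
oracle_local_score <- function(a, b, ...) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      best <- max(best, oracle_global_score(sa, substr(b, j1, j2), ...))
    }
  }
  best
}

# --- K2P site-classification oracle -----------------------------------------

# Explicit pair lookup, independent of the package's purine/pyrimidine
# logic.
ORACLE_TRANSITIONS <- c("AG", "GA", "CT", "TC")
ORACLE_TRANSVERSIONS <- c("AC", "CA", "AT", "TA", "CG", "GC", "GT", "TG")

oracle_k2p <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  P_count <- 0L; Q_count <- 0L; n <- 0L
  for (k in seq_along(av)) {
    pair <- paste0(av[k], bv[k])
    if (!(av[k] %in% c("A", "C", "G", "T")) ||
        !(bv[k] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (pair %in% ORACLE_TRANSITIONS) P_count <- P_count + 1L
    if (pair %in% ORACLE_TRANSVERSIONS) Q_count <- Q_count + 1L
  }
  P <- P_count / n; Q <- Q_count / n
  list(P = P, Q = Q, n_sites = n,
       d = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
}

# --- exhaustive-topology NJ oracle ------------------------------------------

# All unrooted binary topologies on the given tip labels, built by
# recursive leaf insertion into every edge.
oracle_all_topologies <- function(tips) {
  n <- length(tips)
  base <- ape::read.tree(text = paste0("(", tips[1], ",", tips[2], ",",
                                       tips[3], ");"))
  trees <- list(base)
  for (k in seq(4, n)) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        tr2 <- tr
        tr2$edge.length <- rep(1, nrow(tr2$edge))
        tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = tips[k],
                    edge.length = 1, Nnode = 1L)
        class(tip) <- "phylo"
        nxt[[length(nxt) + 1L]] <- ape::bind.tree(tr2, tip, where = tr2$edge[e, 2],
                                                  position = 0.5)
      }
    }
    trees <- nxt
  }
  trees
}

# Least-squares branch lengths of a fixed topology against a distance
# matrix; returns the fitted tree and the residual sum of squares.
oracle_ls_fit <- function(topo, D) {
  tips <- topo$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  nedge <- nrow(topo$edge)
  A <- matrix(0, nrow(pairs), nedge)
  d <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    np <- ape::nodepath(topo, i, j)
    for (k in seq_len(length(np) - 1L)) {
      e <- which((topo$edge[, 1] == np[k] & topo$edge[, 2] == np[k + 1]) |
                   (topo$edge[, 1] == np[k + 1] & topo$edge[, 2] == np[k]))
      A[p, e] <- 1
    }
    d[p] <- D[tips[i], tips[j]]
  }
  fit <- stats::lm.fit(A, d)
  rss <- sum(fit$residuals^2)
  topo$edge.length <- fit$coefficients
  list(tree = topo, rss = rss)
}

# Best topology for D by exhaustive enumeration + least squares.
oracle_best_topology <- function(D) {
  tips <- rownames(D)
  topos <- oracle_all_topologies(tips)
  fits <- lapply(topos, oracle_ls_fit, D = D)
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  fits[[which.min(rss)]]
}

# Unrooted-topology equality via Robinson-Foulds distance.
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

# Random unrooted tree with positive branch lengths and its additive
# distance matrix.
random_additive_matrix <- function(n, tips = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = tips,
                   br = function(k) stats::runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)[tips, tips]
  list(tree = tr, D = D)
}

# Independent unrooted-clade oracle: a leaf set forms a clade of the
# unrooted tree iff it (or its complement) is monophyletic under the
# stored rooting; checked with ape, not with the package's bipartition
# machinery.
oracle_is_clade <- function(tree, members) {
  tips <- tree$tip.label
  if (length(members) <= 1L || length(members) >= length(tips) - 1L) {
    return(TRUE)
  }
  ape::is.monophyletic(tree, members) ||
    ape::is.monophyletic(tree, setdiff(tips, members))
}
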
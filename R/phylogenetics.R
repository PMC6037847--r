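# Kimura 2-parameter distances, neighbor-joining, bootstrap supports and
# group-discrimination assessment on unrooted trees.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura 2-parameter distance between two aligned rows
#'
#' Sites where either row carries a gap or an ambiguity code are removed
#' (pairwise deletion). Over the remaining sites, P is the proportion of
#' transitions (A<->G, C<->T), Q the proportion of transversions, and
#' \deqn{d = -\frac{1}{2} \ln[(1 - 2P - Q)\sqrt{1 - 2Q}]}
#'
#' @param row_a,row_b equal-length aligned sequences (strings, may contain
#'   \code{-} gaps and IUPAC ambiguity codes).
#' @return object of class \code{k2p} with fields \code{P}, \code{Q},
#'   \code{n_sites} and \code{d}.
#' @section Errors: no pairwise-complete sites is an error; a saturated
#'   pair (\code{1 - 2P - Q <= 0} or \code{1 - 2Q <= 0}, where the log is
#'   undefined) raises an error of class \code{seedbarcode_saturation}.
#' @examples
#' k2p_distance("ACGT", "ACGA")
#' @export
k2p_distance <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  a <- strsplit(toupper(row_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(row_b), "", fixed = TRUE)[[1]]
  comp <- k2p_site_counts(a, b)
  if (comp$n_sites == 0L) {
    stop("no pairwise-complete sites; K2P distance undefined", call. = FALSE)
  }
  P <- comp$transitions / comp$n_sites
  Q <- comp$transversions / comp$n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(structure(
      class = c("seedbarcode_saturation", "error", "condition"),
      list(message = sprintf(
        "saturated pair (P = %.4f, Q = %.4f): K2P distance undefined", P, Q),
        call = NULL)))
  }
  d <- -0.5 * log(w1 * sqrt(w2))
  structure(list(P = P, Q = Q, n_sites = comp$n_sites, d = d), class = "k2p")
}

# Site classification shared by k2p_distance and the matrix builder:
# pairwise deletion keeps only unambiguous A/C/G/T on both rows.
k2p_site_counts <- function(a, b) {
  keep <- a %in% c(PURINES, PYRIMIDINES) & b %in% c(PURINES, PYRIMIDINES)
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))
  list(n_sites = length(a), transitions = sum(ts), transversions = sum(diff & !ts))
}

#' @export
print.k2p <- function(x, ...) {
  cat(sprintf("<k2p> d = %.6f (P = %.4f, Q = %.4f, %d sites)\n",
              x$d, x$P, x$Q, x$n_sites))
  invisible(x)
}

#' Pairwise K2P distance matrix of a multiple alignment
#'
#' @param aligned named character vector of equal-length aligned rows
#'   (names are taxon ids), or a \code{matrix} of single characters with
#'   rownames.
#' @return symmetric numeric matrix with zero diagonal and taxon ids as
#'   dimnames.
#' @section Errors: a saturated pair raises an error of class
#'   \code{seedbarcode_saturation} naming the pair.
#' @export
k2p_matrix <- function(aligned) {
  rows <- as_aligned_rows(aligned)
  n <- length(rows)
  ids <- names(rows)
  chars <- lapply(rows, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]])
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(
        k2p_distance(rows[[i]], rows[[j]])$d,
        seedbarcode_saturation = function(e) {
          stop(structure(
            class = c("seedbarcode_saturation", "error", "condition"),
            list(message = paste0("saturated pair: ", ids[i], " vs ", ids[j]),
                 call = NULL)))
        })
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

as_aligned_rows <- function(aligned) {
  if (is.matrix(aligned)) {
    rows <- apply(aligned, 1L, paste, collapse = "")
    names(rows) <- rownames(aligned)
    aligned <- rows
  }
  if (!is.character(aligned) || is.null(names(aligned))) {
    stop("aligned must be a named character vector or character matrix",
         call. = FALSE)
  }
  if (length(unique(nchar(aligned))) != 1L) {
    stop("all aligned rows must have equal length", call. = FALSE)
  }
  if (anyDuplicated(names(aligned))) {
    stop("duplicate taxon ids in alignment", call. = FALSE)
  }
  as.list(aligned)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. Ties on the
#' Q-criterion (within a small numerical tolerance) are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels, where a cluster is labeled by its smallest member taxon; this
#' makes the result independent of the row order of the input matrix.
#' Negative branch length estimates are clamped to zero with the deficit
#' transferred to the sister branch, so path lengths between the joined
#' pair are preserved. The result is unrooted: the root node of the
#' returned \code{phylo} object is a trifurcation.
#'
#' @param D symmetric numeric distance matrix (>= 3 taxa, finite entries,
#'   dimnames = taxon ids).
#' @return an \pkg{ape} \code{phylo} object.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(D))) stop("distances must be finite", call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # Each active cluster holds a parenthesised newick fragment and is keyed
  # by its lexicographically smallest member label (canonical tie-break).
  frag <- labels
  key <- labels
  active <- D

  fmt <- function(x) sprintf("%.17g", x)

  while (nrow(active) > 3L) {
    m <- nrow(active)
    r <- rowSums(active)
    Q <- (m - 2) * active - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-10 * (1 + abs(qmin))
    cand <- which(Q <= qmin + tol & upper.tri(Q), arr.ind = TRUE)
    # canonical choice among numerical ties: order the candidate pairs by
    # their sorted cluster-label pair
    pair_key <- vapply(seq_len(nrow(cand)), function(k) {
      ks <- sort(c(key[cand[k, 1]], key[cand[k, 2]]))
      paste(ks, collapse = "\r")
    }, character(1))
    pick <- cand[order(pair_key)[1], ]
    i <- min(pick); j <- max(pick)
    li <- active[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- active[i, j] - li
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    dnew <- (active[i, ] + active[j, ] - active[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    active <- active[-c(i, j), -c(i, j), drop = FALSE]
    active <- rbind(cbind(active, dnew), c(dnew, 0))
    newkey <- min(key[i], key[j])
    frag <- c(frag[-c(i, j)], newfrag)
    key <- c(key[-c(i, j)], newkey)
  }

  # Final three clusters: three-point formulas around the central node.
  d12 <- active[1, 2]; d13 <- active[1, 3]; d23 <- active[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of the internal edges of an unrooted phylo
# tree. Each internal edge splits the leaves in two; the key is the sorted,
# "|"-collapsed side that does NOT contain the alphabetically smallest
# leaf, so keys are invariant to leaf order and rooting.
bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips)[1]
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- ntip + 1L
  keys <- character(0)
  nodes <- integer(0)
  for (node in seq_len(tree$Nnode) + ntip) {
    if (node == root) next
    side <- desc[[node]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next  # trivial split
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes, desc = desc)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' K2P distances for every replicate, and reports for each internal edge
#' of the full-data tree the percentage of replicates containing the same
#' bipartition. Supports are attached as \code{node.label} (rounded to
#' integer percent). Replicates in which some pair saturates are skipped
#' and counted; a warning is issued if more than 10\% are skipped.
#'
#' Replicate \code{r} draws its columns under seed \code{seed + r}, so
#' runs are reproducible and replicates independent of each other.
#'
#' @param aligned named character vector (or character matrix) of aligned
#'   rows.
#' @param n_replicates number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice, smaller values keep toy runs fast).
#' @param seed integer seed (required).
#' @param collapse_below if non-\code{NULL}, internal edges with support
#'   below this percentage are collapsed into polytomies on output
#'   (display convention; 50 is typical).
#' @return a \code{phylo} tree with \code{node.label} supports; attribute
#'   \code{n_skipped} counts skipped replicates.
#' @export
bootstrap_support <- function(aligned, n_replicates, seed,
                              collapse_below = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  rows <- as_aligned_rows(aligned)
  mat <- do.call(rbind, lapply(rows, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]))
  rownames(mat) <- names(rows)
  L <- ncol(mat)

  main_tree <- nj_tree(k2p_matrix(mat))
  bp <- bipartition_keys(main_tree)
  counts <- stats::setNames(numeric(length(bp$keys)), bp$keys)

  n_ok <- 0L
  n_skipped <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- with_seed(seed + r, sample.int(L, L, replace = TRUE))
    rep_tree <- tryCatch(
      nj_tree(k2p_matrix(mat[, cols, drop = FALSE])),
      seedbarcode_saturation = function(e) NULL,
      error = function(e) {
        if (grepl("pairwise-complete", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(rep_tree)) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_ok <- n_ok + 1L
    rk <- bipartition_keys(rep_tree)$keys
    hit <- bp$keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  if (n_ok == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  if (n_skipped > 0.1 * n_replicates) {
    warning(sprintf("%d of %d bootstrap replicates skipped (saturation)",
                    n_skipped, n_replicates), call. = FALSE)
  }
  support <- 100 * counts / n_ok

  ntip <- length(main_tree$tip.label)
  node.label <- rep("", main_tree$Nnode)
  for (k in seq_along(bp$nodes)) {
    node.label[bp$nodes[k] - ntip] <- as.character(round_half_up(support[k]))
  }
  main_tree$node.label <- node.label
  if (!is.null(collapse_below)) {
    main_tree <- collapse_low_support(main_tree, collapse_below)
  }
  attr(main_tree, "n_skipped") <- n_skipped
  main_tree
}

#' Collapse weakly supported internal edges into polytomies
#'
#' @param tree a \code{phylo} with numeric \code{node.label} supports.
#' @param threshold edges with support strictly below this percentage are
#'   collapsed.
#' @return a \code{phylo}, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  if (is.null(tree$node.label)) return(tree)
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  drop_nodes <- which(!is.na(sup) & sup < threshold) + ntip
  root <- ntip + 1L
  drop_nodes <- setdiff(drop_nodes, root)
  if (!length(drop_nodes)) return(tree)
  keep_edge <- !(tree$edge[, 2] %in% drop_nodes)
  # re-parent children of collapsed nodes upward (iterate to fixpoint)
  parent_of <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
  new_parent <- function(p) {
    while (p %in% drop_nodes) p <- parent_of[[as.character(p)]]
    p
  }
  edges <- tree$edge[keep_edge, , drop = FALSE]
  lens <- tree$edge.length[keep_edge]
  edges[, 1] <- vapply(edges[, 1], new_parent, numeric(1))
  # renumber internal nodes compactly
  kept_internal <- sort(unique(c(root, edges[edges[, 1] > ntip, 1],
                                 edges[edges[, 2] > ntip, 2])))
  remap <- stats::setNames(seq_along(kept_internal) + ntip, kept_internal)
  edges[, 1] <- remap[as.character(edges[, 1])]
  internal_child <- edges[, 2] > ntip
  edges[internal_child, 2] <- remap[as.character(edges[internal_child, 2])]
  out <- list(edge = edges, edge.length = lens,
              tip.label = tree$tip.label, Nnode = length(kept_internal),
              node.label = tree$node.label[kept_internal - ntip])
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out
}

#' Assess group discrimination on a tree
#'
#' A group (all records of one drug, or of one species) is discriminated
#' when its leaves form a clade: some bipartition of the unrooted tree
#' separates exactly that leaf set. Singleton groups are monophyletic by
#' convention. Internal edges of length \code{<= collapse_tol} are
#' collapsed before assessment: a zero-length edge carries no signal, and
#' groups of sequence-identical congeners must not appear resolved merely
#' through arbitrary join order.
#'
#' @param tree a \code{phylo}; \code{node.label} supports, if present, are
#'   reported for discriminated groups.
#' @param leaf_to_group named character vector mapping every leaf to its
#'   group.
#' @param collapse_tol edge-length tolerance for collapsing (default
#'   1e-8); set negative to disable.
#' @return data frame of class \code{discrimination_report}: \code{group},
#'   \code{n_sequences}, \code{monophyletic}, \code{support} (percent or
#'   NA), \code{overlapping_groups} (comma-separated foreign groups inside
#'   the minimal spanning clade, empty when monophyletic).
#' @export
assess_discrimination <- function(tree, leaf_to_group, collapse_tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(leaf_to_group))
  if (length(unmapped)) {
    stop("unmapped leaves: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (collapse_tol >= 0 && !is.null(tree$edge.length)) {
    # internal edges shorter than the tolerance become polytomies
    tree <- ape::di2multi(tree, tol = collapse_tol + .Machine$double.xmin)
  }
  groups <- unique(leaf_to_group[tips])
  bp <- bipartition_keys(tree)
  ntip <- length(tips)

  has_support <- !is.null(tree$node.label)
  support_of <- function(node) {
    if (!has_support) return(NA_real_)
    lab <- tree$node.label[node - ntip]
    suppressWarnings(as.numeric(lab))
  }

  # sides reachable as clades: every bipartition, both orientations
  anchor <- sort(tips)[1]
  res <- lapply(groups, function(g) {
    members <- tips[leaf_to_group[tips] == g]
    key_members <- paste(sort(members), collapse = "|")
    mono <- FALSE
    sup <- NA_real_
    if (length(members) == 1L || length(members) == ntip) {
      mono <- TRUE
    } else {
      side <- if (anchor %in% members) setdiff(tips, members) else members
      key <- paste(sort(side), collapse = "|")
      idx <- match(key, bp$keys)
      if (!is.na(idx)) {
        mono <- TRUE
        sup <- support_of(bp$nodes[idx])
      } else if (length(members) == ntip - 1L) {
        mono <- TRUE  # complement of a single leaf is always a clade
      }
    }
    overlapping <- character(0)
    if (!mono) {
      # minimal spanning clade: smallest clade (over both orientations of
      # every split, plus the whole leaf set) containing the group
      sides <- c(lapply(bp$keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]]),
                 lapply(bp$keys, function(k) setdiff(tips, strsplit(k, "|", fixed = TRUE)[[1]])),
                 list(tips))
      containing <- Filter(function(s) all(members %in% s), sides)
      sizes <- vapply(containing, length, integer(1))
      mrca_side <- containing[[which.min(sizes)]]
      foreign <- setdiff(mrca_side, members)
      overlapping <- sort(unique(leaf_to_group[foreign]))
    }
    data.frame(group = g, n_sequences = length(members),
               monophyletic = mono, support = sup,
               overlapping_groups = paste(overlapping, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("discrimination_report", "data.frame")
  out
}

#' Write a tree to a newick file
#'
#' Branch lengths and integer bootstrap supports (as internal node labels)
#' are preserved.
#'
#' @param tree a \code{phylo}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_tree_newick <- function(tree, path) {
  atomic_write(ape::write.tree(tree), path)
}

#' Center-star progressive multiple alignment
#'
#' A deliberately simple MSA for synthetic and toy data: the center
#' sequence (maximal summed pairwise alignment score) is aligned pairwise
#' to every other sequence and the pairwise alignments are merged
#' column-wise ("once a gap, always a gap"). Real study data should be
#' aligned with a dedicated MSA tool; trees built here only need the
#' trivial alignments of simulated, indel-free sequences.
#'
#' @param sequences named character vector of nucleotide strings.
#' @param scoring a \code{\link{scoring_scheme}}.
#' @return named character vector of equal-length aligned rows.
#' @export
align_center_star <- function(sequences, scoring = scoring_scheme()) {
  n <- length(sequences)
  stopifnot(n >= 2L, !is.null(names(sequences)))
  if (n == 2L) {
    aln <- align_pair(sequences[[1]], sequences[[2]], scoring = scoring)
    out <- c(aln$aligned_a, aln$aligned_b)
    names(out) <- names(sequences)
    return(out)
  }
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- align_pair(sequences[[i]], sequences[[j]], scoring = scoring)$score
      scores[i, j] <- scores[j, i] <- s
    }
  }
  center <- which.max(rowSums(scores))

  # master = gapped center sequence; rows follow the master's columns
  master <- strsplit(sequences[[center]], "", fixed = TRUE)[[1]]
  rows <- list()
  rows[[names(sequences)[center]]] <- master
  for (i in seq_len(n)) {
    if (i == center) next
    aln <- align_pair(sequences[[center]], sequences[[i]], scoring = scoring)
    ac <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    ai <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    # merge: walk master and ac together, inserting gaps as needed
    new_master <- character(0)
    new_rows <- lapply(rows, function(r) character(0))
    new_row_i <- character(0)
    p <- 1L  # position in master columns
    q <- 1L  # position in ac/ai
    repeat {
      m_res <- p <= length(master) && master[p] != "-"
      a_res <- q <= length(ac) && ac[q] != "-"
      if (p > length(master) && q > length(ac)) break
      if (p <= length(master) && master[p] == "-" && (q > length(ac) || ac[q] != "-")) {
        # master has a gap column other rows need; new row gets a gap
        new_master <- c(new_master, "-")
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], rows[[nm]][p])
        new_row_i <- c(new_row_i, "-")
        p <- p + 1L
      } else if (q <= length(ac) && ac[q] == "-") {
        # pairwise alignment inserts a gap into the center: all old rows gap
        new_master <- c(new_master, "-")
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], "-")
        new_row_i <- c(new_row_i, ai[q])
        q <- q + 1L
      } else if (m_res && a_res) {
        new_master <- c(new_master, master[p])
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], rows[[nm]][p])
        new_row_i <- c(new_row_i, ai[q])
        p <- p + 1L
        q <- q + 1L
      } else {
        stop("center-star merge failed (internal error)", call. = FALSE)
      }
    }
    master <- new_master
    rows <- new_rows
    rows[[names(sequences)[center]]] <- master
    rows[[names(sequences)[i]]] <- new_row_i
  }
  out <- vapply(rows, paste, character(1), collapse = "")
  out[names(sequences)]
}
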
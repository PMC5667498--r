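# Distance-based phylogenetics: p-distance and Kimura-2-parameter distances
# with pairwise deletion, Neighbor-Joining (Saitou-Nei) tree construction
# with deterministic tie-breaking, bootstrap bipartition support, and Newick
# output via ape `phylo` objects.

#' Kimura-2-parameter distance from transition/transversion proportions
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` where P and Q are the
#' proportions of transition and transversion sites.
#'
#' @param P,Q Transition and transversion proportions.
#' @return Distance in substitutions/site.
#' @export
k2p_from_proportions <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop("saturation error: K2P log argument <= 0", call. = FALSE)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Kimura-2-parameter distance between two aligned sequences
#'
#' Sites with `-` or `N` in either sequence are excluded (pairwise
#' deletion); transitions are A<->G and C<->T.
#'
#' @param a,b Equal-length gapped sequences.
#' @return List: distance, P, Q, sites_used.
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("input error: unequal lengths", call. = FALSE)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  use <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
  n <- sum(use)
  if (n == 0L) stop("undefined distance: no usable sites", call. = FALSE)
  av <- av[use]; bv <- bv[use]
  ts <- (av == "A" & bv == "G") | (av == "G" & bv == "A") |
        (av == "C" & bv == "T") | (av == "T" & bv == "C")
  tv <- av != bv & !ts
  P <- sum(ts) / n; Q <- sum(tv) / n
  tryCatch(
    list(distance = k2p_from_proportions(P, Q), P = P, Q = Q, sites_used = n),
    error = function(e) stop("saturation error for pair (P=", P, ", Q=", Q,
                             ")", call. = FALSE))
}

#' Pairwise distance matrix of an alignment
#'
#' @param msa An [as_msa()] alignment.
#' @param model `"p"` (p-distance, substitutions/site) or `"k2p"`.
#' @return Symmetric numeric matrix with taxa as dimnames.
#' @export
distance_matrix <- function(msa, model = c("p", "k2p")) {
  model <- match.arg(model)
  n <- length(msa)
  labs <- names(msa)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- if (model == "p") p_distance(msa[[i]], msa[[j]])$d_percent / 100
           else k2p_distance(msa[[i]], msa[[j]])$distance
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-Joining tree construction
#'
#' Standard Saitou-Nei agglomeration: at each step join the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths by the usual allocation. Ties are broken by the lexicographically
#' lowest (representative-label) pair, so the result is deterministic and
#' independent of input order. Negative branch lengths are clamped to 0 in
#' the returned tree and reported raw in the `negative_branches` attribute.
#'
#' @param D Symmetric nonnegative distance matrix with labelled dimnames
#'   (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (is.null(dimnames(D)[[1]])) stop("input error: D needs taxon labels", call. = FALSE)
  if (nrow(D) < 3L) stop("input error: need >= 3 taxa", call. = FALSE)
  if (any(D < 0) || any(abs(D - t(D)) > 1e-12))
    stop("input error: D must be symmetric and nonnegative", call. = FALSE)
  labs <- rownames(D)
  sub <- labs                 # newick fragment per active node
  rep_lab <- labs             # representative (smallest) leaf label per node
  neg <- numeric(0)
  fmt <- function(x) {
    if (x < 0) neg <<- c(neg, x)
    sprintf("%.15g", max(0, x))
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Qm <- (n - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    rep_lab <- c(rep_lab[keep], new_rep)
    dimnames(D) <- list(rep_lab, rep_lab)
  }
  # final three nodes around the last internal vertex
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(la), sub[2], fmt(lb),
                 sub[3], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branches") <- neg
  tree
}

#' Neighbor-Joining with bootstrap bipartition support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n` times, rebuilds the tree per replicate, and
#' annotates each internal edge of the original tree with the percentage of
#' replicates containing the same bipartition (stored in `node.label`).
#' Replicates in which a pair saturates (or loses all usable sites) are
#' skipped with a warning and excluded from the denominator. Deterministic
#' under a fixed seed.
#'
#' @param msa An [as_msa()] alignment with >= 4 members.
#' @param model Distance model (see [distance_matrix()]).
#' @param n Number of bootstrap replicates.
#' @param seed Optional integer seed (private stream).
#' @return `ape::phylo` with integer `node.label` supports (root label
#'   `NA`); attribute `n_skipped` counts skipped replicates.
#' @export
bootstrap_support <- function(msa, model = c("p", "k2p"), n = 1000,
                              seed = NULL) {
  model <- match.arg(model)
  if (length(msa) < 4L) stop("input error: need >= 4 members", call. = FALSE)
  tree <- neighbor_joining(distance_matrix(msa, model))
  m <- .msa_matrix(msa)
  rownames(m) <- names(msa)
  .with_seed(seed, {
    boot <- vector("list", n)
    skipped <- 0L
    for (b in seq_len(n)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- as_msa(setNames(apply(m[, idx, drop = FALSE], 1, paste,
                                       collapse = ""), rownames(m)))
      t_b <- tryCatch(neighbor_joining(distance_matrix(rep_msa, model)),
                      error = function(e) NULL)
      if (is.null(t_b)) skipped <- skipped + 1L else boot[[b]] <- t_b
    }
    if (skipped > 0L)
      warning(skipped, " bootstrap replicate(s) skipped (saturated pair)")
    boot <- Filter(Negate(is.null), boot)
    n_used <- length(boot)
    counts <- ape::prop.clades(tree, boot, rooted = FALSE)
    counts[is.na(counts)] <- 0L   # bipartition absent from every replicate
    supp <- as.integer(round(100 * pmin(counts, n_used) / n_used))
    tree$node.label <- supp
    attr(tree, "n_skipped") <- skipped
    attr(tree, "n_used") <- n_used
    tree
  })
}

#' Write / read Newick with supports as internal node labels
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`.
#'
#' @param tree An `ape::phylo`.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Assign query taxa to supported reference clusters
#'
#' Each query tip is assigned to the exemplar set with which it forms a
#' supported monophyletic group: among all bipartition sides with bootstrap
#' support at or above `threshold` that contain the query together with
#' exemplars of exactly one type, the smallest side decides the type.
#' Queries with no qualifying side are `"unassigned"`. With `threshold = 0`
#' every edge qualifies, so each query is assigned to its nearest cluster.
#'
#' @param tree Support-annotated `phylo` (see [bootstrap_support()]).
#' @param exemplars Named list of character vectors of exemplar tip labels,
#'   e.g. `list(I = ..., II = ...)`.
#' @param threshold Minimum support (0-100) for an edge to qualify.
#' @return Named character vector: type per query tip.
#' @export
cluster_membership <- function(tree, exemplars, threshold = 70) {
  tips <- tree$tip.label
  ex_all <- unlist(exemplars)
  if (!all(ex_all %in% tips))
    stop("input error: exemplar tips absent from tree", call. = FALSE)
  queries <- setdiff(tips, ex_all)
  parts <- ape::prop.part(tree)          # clades per internal node
  labels_of <- function(idx) tips[idx]
  supports <- if (!is.null(tree$node.label)) suppressWarnings(
    as.numeric(tree$node.label)) else rep(100, tree$Nnode)
  sides <- list()
  for (k in seq_along(parts)) {
    s <- supports[k]
    if (is.na(s)) s <- if (k == 1L) 100 else 0   # root side is trivial
    if (s < threshold) next
    clade <- labels_of(parts[[k]])
    sides[[length(sides) + 1L]] <- clade
    sides[[length(sides) + 1L]] <- setdiff(tips, clade)
  }
  out <- setNames(rep("unassigned", length(queries)), queries)
  for (q in queries) {
    best <- setNames(rep(Inf, length(exemplars)), names(exemplars))
    for (sd in sides) {
      if (!(q %in% sd)) next
      present <- vapply(exemplars, function(e) any(e %in% sd), logical(1))
      if (sum(present) != 1L) next
      ty <- names(exemplars)[present]
      best[ty] <- min(best[ty], length(sd))
    }
    # equally small conflicting groupings (an equidistant query) stay
    # unassigned; otherwise the tightest supported grouping wins
    if (any(is.finite(best)) && sum(best == min(best)) == 1L) {
      out[q] <- names(best)[which.min(best)]
    }
  }
  out
}
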
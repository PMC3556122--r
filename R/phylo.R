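#' Jukes-Cantor distance
#'
#' Corrects an observed proportion of differing sites \code{p} for multiple
#' substitutions: \code{d = -(3/4) * log(1 - (4/3) * p)}, in substitutions
#' per site. Defined for \code{0 <= p < 0.75}; saturated inputs error unless
#' a cap is supplied.
#'
#' @param p Numeric vector or matrix of p-distances.
#' @param cap Optional maximum distance assigned to saturated entries
#'   (\code{p >= 0.75}) instead of erroring; off (\code{NULL}) by default.
#' @return Distances with the shape of \code{p}.
#' @examples
#' jukes_cantor(0.1)   # 0.10732...
#' @export
jukes_cantor <- function(p, cap = NULL) {
  if (any(p < 0)) stop("p-distances must be non-negative")
  sat <- p >= 0.75
  if (any(sat) && is.null(cap))
    stop("p >= 0.75 is saturated under the Jukes-Cantor model")
  d <- p
  d[!sat] <- -0.75 * log(1 - (4 / 3) * p[!sat])
  if (any(sat)) d[sat] <- cap
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair (i, j) minimising
#' \code{Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)}; branch lengths
#' from the standard formulas, negative lengths clamped to zero; ties broken
#' by the lexicographically smallest index pair in the current taxon order.
#' The result is unrooted (a trifurcation at the final join).
#'
#' @param d Symmetric numeric distance matrix with row/column names (>= 2 taxa).
#' @return An [ape::phylo] tree with edge lengths in substitutions/site.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!all(is.finite(d))) stop("distances must be finite")

  # working copy; node i is represented by its newick subtree string
  D <- unname(d)
  nodes <- labels
  while (length(nodes) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bi, nodes[j], bj)
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    dk <- pmax(dk, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- D[keep, keep, drop = FALSE]
    D2 <- rbind(cbind(D2, dk), c(dk, 0))
    D <- unname(D2)
    nodes <- c(nodes[keep], new_node)
  }
  if (length(nodes) == 3L) {
    b1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
    b2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
    b3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   nodes[1L], b1, nodes[2L], b2, nodes[3L], b3)
  } else {
    b <- D[1, 2] / 2
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", nodes[1L], b, nodes[2L], b)
  }
  ape::read.tree(text = nwk)
}

#' Bootstrap support for NJ bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate (p-distance then Jukes-Cantor), and scores each internal edge of
#' the full-alignment tree by the fraction of replicates containing its
#' bipartition. Fully reproducible under \code{seed}.
#'
#' @param alignment An \code{ltr_alignment}.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param cap Saturation cap forwarded to [jukes_cantor()] (replicated
#'   columns can push p past 0.75; default 5 substitutions/site).
#' @return The NJ tree of the full alignment with \code{node.label} holding
#'   support fractions (\code{NA} on the root trifurcation).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L,
                              cap = 5) {
  main <- neighbor_joining(jukes_cantor(p_distance(alignment), cap = cap))
  ncol_a <- ncol(alignment$rows)
  set.seed(seed)
  boot <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
    rep_aln <- alignment
    rep_aln$rows <- alignment$rows[, cols, drop = FALSE]
    boot[[b]] <- neighbor_joining(jukes_cantor(p_distance(rep_aln), cap = cap))
  }
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / replicates
  support[1L] <- NA  # root trifurcation is not a bipartition
  main$node.label <- support
  attr(main, "bootstrap") <- list(replicates = replicates, seed = seed)
  main
}

#' Partition a tree into clades by cutting long internal edges
#'
#' Removes the \code{k - 1} longest internal edges (among cuts that leave
#' every resulting component with at least \code{min_clade_size} leaves);
#' the leaf sets of the resulting components are the clades. When per-leaf
#' divergences from the consensus are supplied, the most conserved
#' (lowest-divergence) clade receives the highest label (\code{clade<k>},
#' the large conserved-family analogue) and the remaining clades are
#' labelled \code{clade1, clade2, ...} in order of increasing divergence;
#' without divergences, labels are assigned by decreasing clade size with
#' the largest clade as \code{clade<k>}.
#'
#' @param tree An [ape::phylo] tree.
#' @param k Number of clades (default 3).
#' @param min_clade_size Smallest admissible clade (default 5 leaves).
#' @param divergence Optional named per-leaf divergence-from-consensus (\%).
#' @return Object of class \code{"clade_partition"}: list with
#'   \code{clades} (named character vector leaf -> label), \code{sizes},
#'   and \code{divergence} (per-clade mean \%, or \code{NULL}).
#' @export
partition_clades <- function(tree, k = 3L, min_clade_size = 5L,
                             divergence = NULL) {
  ntip <- length(tree$tip.label)
  if (k < 1L) stop("k must be >= 1")
  edges <- tree$edge
  lens <- tree$edge.length
  internal <- which(edges[, 2L] > ntip)
  cut <- integer(0)
  if (k > 1L) {
    for (e in internal[order(lens[internal], decreasing = TRUE)]) {
      trial <- c(cut, e)
      comp <- .leaf_components(tree, trial)
      if (min(tabulate(comp[seq_len(ntip)], nbins = max(comp))) >= min_clade_size &&
          length(unique(comp[seq_len(ntip)])) == length(trial) + 1L) {
        cut <- trial
        if (length(cut) == k - 1L) break
      }
    }
    if (length(cut) < k - 1L)
      stop(sprintf("cannot partition into %d clades of >= %d leaves", k,
                   min_clade_size))
  }
  comp <- .leaf_components(tree, cut)
  leaf_comp <- comp[seq_len(ntip)]
  comp_ids <- sort(unique(leaf_comp))
  members <- lapply(comp_ids, function(cid) tree$tip.label[leaf_comp == cid])

  if (!is.null(divergence)) {
    delta <- vapply(members, function(m) mean(divergence[m]), numeric(1L))
    ord <- order(delta)               # ascending divergence
    lab <- character(length(ord))
    lab[ord[1L]] <- paste0("clade", k)            # most conserved clade
    if (length(ord) > 1L)
      lab[ord[-1L]] <- paste0("clade", seq_len(length(ord) - 1L))
  } else {
    delta <- NULL
    sizes0 <- lengths(members)
    ord <- order(sizes0, decreasing = TRUE)
    lab <- character(length(ord))
    lab[ord[1L]] <- paste0("clade", k)
    if (length(ord) > 1L)
      lab[ord[-1L]] <- paste0("clade", seq_len(length(ord) - 1L))
  }
  clades <- character(ntip)
  names(clades) <- tree$tip.label
  for (ci in seq_along(members)) clades[members[[ci]]] <- lab[ci]
  sizes <- table(clades)
  div_out <- if (!is.null(delta)) stats::setNames(delta, lab)[order(lab)] else NULL
  structure(list(clades = clades, sizes = c(unclass(sizes)),
                 divergence = div_out, k = k),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("Clade partition (k = %d)\n", x$k))
  for (nm in names(x$sizes)) {
    if (!is.null(x$divergence) && nm %in% names(x$divergence))
      cat(sprintf("  %-8s %4d leaves, mean divergence from consensus %.1f%%\n",
                  nm, x$sizes[[nm]], x$divergence[[nm]]))
    else
      cat(sprintf("  %-8s %4d leaves\n", nm, x$sizes[[nm]]))
  }
  invisible(x)
}

# connected components of the tree after deleting edges `cut`;
# returns a component id per node (tips 1..ntip first)
.leaf_components <- function(tree, cut) {
  n_nodes <- max(tree$edge)
  adj <- vector("list", n_nodes)
  keep <- setdiff(seq_len(nrow(tree$edge)), cut)
  for (e in keep) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n_nodes)
  cid <- 0L
  for (s in seq_len(n_nodes)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

#' Per-clade divergence from the consensus
#'
#' Mean p-distance (in percent) between each clade's members and the
#' alignment's consensus row.
#'
#' @param alignment An \code{ltr_alignment} with a consensus row.
#' @param partition A \code{clade_partition} (or named leaf -> clade vector).
#' @return Named numeric vector, percent divergence per clade.
#' @export
clade_divergence <- function(alignment, partition) {
  clades <- if (inherits(partition, "clade_partition")) partition$clades else partition
  pcons <- .p_to_consensus(alignment)
  common <- intersect(names(pcons), names(clades))
  vapply(split(pcons[common], clades[common]), mean, numeric(1L)) * 100
}

#' Write a tree with supports to Newick
#'
#' @param tree An [ape::phylo]; \code{node.label} (support fractions) are
#'   written as internal node labels.
#' @param file Output path.
#' @export
write_tree_newick <- function(tree, file) {
  if (!is.null(tree$node.label) && is.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(tree$node.label), "",
                              format(tree$node.label, digits = 4))
  ape::write.tree(tree, file = file)
}
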
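# Small deterministic fixtures shared across test files.

rm_header <- c(
  "   SW  perc perc perc  query    position in query    matching repeat",
  "score  div. del. ins.  sequence begin end (left)     repeat   class",
  ""
)

rm_record <- function(chrom = "chr1", start = 1001L, end = 1337L,
                      strand = "+", name = "IAPLTR1_Mm", div = 1.8,
                      score = 239L) {
  sprintf("%d %.1f 0.0 0.0 %s %d %d (100000) %s %s LTR/ERVK 1 %d (0) 1",
          score, div, chrom, start, end, strand, name, end - start + 1L)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Synthetic stand-in for the two published epiallele LTR accessions: a
# 336 nt core shared with 5 substitutions (identity over shared sequence
# 331/336 = 98.51%), the longer sequence carrying a 58 nt 3' extension.
synthetic_ltr_pair <- function() {
  core <- random_dna(336L, seed = 4242L)
  chars <- strsplit(core, "", fixed = TRUE)[[1L]]
  at <- c(31L, 97L, 160L, 221L, 300L)
  for (i in at) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1L]
  list(avy_like = core,
       cabp_like = paste0(paste(chars, collapse = ""), random_dna(58L, seed = 99L)))
}

# element + downstream flank in assay orientation, containing one
# methylation-dependent site near the junction and primer-friendly flanks
assayable_element <- function(seed = 7L) {
  set.seed(seed)
  el <- random_dna(300L)
  # guarantee a clean site 60 nt before the junction, none elsewhere
  el <- gsub("ACGGCG", "ATGGTG", el, fixed = TRUE)
  substr(el, 235L, 240L) <- "ACGGCG"
  fl <- gsub("ACGGCG", "ATGGTG", random_dna(400L), fixed = TRUE)
  list(element = el, flank = fl)
}

# random additive tree on n taxa: topology by sequential random attachment,
# returns the ape tree and its exact path-length matrix
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

# brute-force least-squares quartet oracle: for 4 taxa, fit branch lengths
# for each of the 3 unrooted topologies and return the split of the best
ls_quartet_split <- function(d) {
  taxa <- rownames(d)
  splits <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  best <- NULL; best_rss <- Inf
  for (s in splits) {
    pair1 <- s; pair2 <- setdiff(1:4, s)
    # branch lengths: e1..e4 external, e5 internal
    # path(i,j) = e_i + e_j (+ e5 when i, j straddle the split)
    X <- matrix(0, 6L, 5L)
    y <- numeric(6L)
    r <- 0L
    for (i in 1:3) for (j in (i + 1):4) {
      r <- r + 1L
      X[r, i] <- 1; X[r, j] <- 1
      straddle <- (i %in% pair1) != (j %in% pair1)
      if (straddle) X[r, 5L] <- 1
      y[r] <- d[i, j]
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- sort(taxa[pair1]) }
  }
  best
}

# the unrooted split containing taxon 1's partner in a 4-taxon ape tree
nj_quartet_split <- function(tree) {
  taxa <- sort(tree$tip.label)
  for (other in taxa[-1L]) {
    pair <- c(taxa[1L], other)
    if (ape::is.monophyletic(tree, pair) ||
        ape::is.monophyletic(tree, setdiff(taxa, pair)))
      return(sort(pair))
  }
  # star tree: no internal structure
  NULL
}
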
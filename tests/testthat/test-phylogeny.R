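test_that("pairwise identity counts matches over shared sequence", {
  s <- random_dna(300L, seed = 21L)
  expect_equal(pairwise_identity(s, s), 1)

  a <- random_dna(100L, seed = 22L)
  b <- a
  substr(b, 50L, 50L) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, 50L, 50L))[1L]
  expect_equal(pairwise_identity(a, b), 0.99)

  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("the synthetic epiallele LTR pair shows 98.5% shared identity", {
  # stand-in pair built with 5 substitutions over a 336 nt shared core and
  # a 58 nt extension on one sequence (terminal overhangs excluded)
  pair <- synthetic_ltr_pair()
  ident <- pairwise_identity(pair$avy_like, pair$cabp_like)
  expect_equal(ident, 331 / 336, tolerance = 1e-9)
  expect_equal(round(100 * ident, 1), 98.5)
  # identity over the full longer sequence is much lower (~85%)
  full <- 331 / 394
  expect_lt(full, 0.86)
})

test_that("star alignment merges on consensus coordinates", {
  cons <- random_dna(120L, seed = 31L)
  aln <- star_align_to_consensus(c(e1 = cons, e2 = cons), cons)
  expect_equal(ncol(aln$rows), 120L)
  expect_false(any(aln$rows == "-"))
  expect_equal(paste(aln$consensus_row, collapse = ""), cons)

  # a 3 nt insertion opens 3 consensus-gap columns, gapped in other rows
  with_ins <- paste0(substr(cons, 1L, 60L), "TTT", substr(cons, 61L, 120L))
  aln2 <- star_align_to_consensus(c(e1 = cons, e2 = with_ins), cons)
  expect_equal(ncol(aln2$rows), 123L)
  gapcols <- which(aln2$consensus_row == "-")
  expect_length(gapcols, 3L)
  expect_equal(unname(aln2$rows["e1", gapcols]), rep("-", 3L))
  expect_equal(unname(aln2$rows["e2", gapcols]), c("T", "T", "T"))

  # unrelated sequence is excluded and reported
  junk <- random_dna(120L, seed = 32L)
  aln3 <- star_align_to_consensus(c(e1 = cons, bad = junk), cons,
                                  drop_threshold = 0.9)
  expect_equal(attr(aln3, "dropped"), "bad")
  expect_equal(rownames(aln3$rows), "e1")
})

test_that("p-distance skips gap and N columns", {
  mk_aln <- function(...) {
    seqs <- list(...)
    rows <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1L]]))
    rownames(rows) <- paste0("s", seq_along(seqs))
    structure(list(names = rownames(rows), rows = rows,
                   consensus_row = rows[1L, ]), class = "ltr_alignment")
  }
  expect_equal(p_distance(mk_aln("ACGT", "ACGT"))[1L, 2L], 0)
  expect_equal(p_distance(mk_aln("ACGT", "ACGA"))[1L, 2L], 0.25)
  expect_equal(p_distance(mk_aln("AC-T", "ACGT"))[1L, 2L], 0)
  expect_equal(p_distance(mk_aln("ACNT", "ACGT"))[1L, 2L], 0)
  expect_error(p_distance(mk_aln("----", "ACGT")), "comparable")
})

test_that("Jukes-Cantor matches its closed form and domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.1073256, tolerance = 1e-6)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_error(jukes_cantor(0.75), "saturated")
  expect_equal(jukes_cantor(0.8, cap = 5), 5)

  # monotone increasing and d >= p over the domain
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("NJ recovers additive trees exactly (least-squares quartet oracle)", {
  # 2 taxa: a single split of total length d
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2L, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- neighbor_joining(d2)
  expect_equal(sum(tr2$edge.length), 0.3)

  for (seed in 1:10) {
    fx <- random_additive_tree(4L, seed)
    tr <- neighbor_joining(fx$d)
    got <- ape::cophenetic.phylo(tr)[rownames(fx$d), colnames(fx$d)]
    expect_equal(got, fx$d, tolerance = 1e-8)
    expect_equal(nj_quartet_split(tr), ls_quartet_split(fx$d))
  }
})

test_that("NJ path lengths reproduce any additive matrix up to n = 8", {
  for (n in c(5L, 6L, 8L)) {
    for (seed in 1:3) {
      fx <- random_additive_tree(n, seed * 100L + n)
      tr <- neighbor_joining(fx$d)
      got <- ape::cophenetic.phylo(tr)[rownames(fx$d), colnames(fx$d)]
      expect_equal(got, fx$d, tolerance = 1e-8)
    }
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(99)
  for (rep in 1:5) {
    fx <- random_additive_tree(7L, rep)
    d <- fx$d + matrix(stats::runif(49, 0, 0.02), 7L)
    d <- (d + t(d)) / 2; diag(d) <- 0
    ours <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours), ape::unroot(ref))), 0)
  }
})

test_that("NJ tie-break yields a deterministic tree on equidistant taxa", {
  d <- matrix(1, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # the lexicographically smallest pair (a, b) is joined first
  expect_true(ape::is.monophyletic(t1, c("a", "b")) ||
                ape::is.monophyletic(t1, c("c", "d")))
})

test_that("Newick round trip preserves topology, lengths and supports", {
  fx <- random_additive_tree(8L, 77L)
  tr <- neighbor_joining(fx$d)
  tr$node.label <- c(NA, round(stats::runif(tr$Nnode - 1L), 3))
  tmp <- tempfile(fileext = ".nwk")
  write_tree_newick(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  m1 <- ape::cophenetic.phylo(tr)
  expect_equal(ape::cophenetic.phylo(back)[rownames(m1), colnames(m1)], m1,
               tolerance = 1e-9)
  expect_equal(as.numeric(back$node.label[-1L]),
               as.numeric(tr$node.label[-1L]))
})

test_that("bootstrap supports planted clades and is seed-reproducible", {
  cfg <- sim_config(seed = 5L, clade_spec = data.frame(
    clade = c("clade1", "clade2", "clade3"), n = c(8L, 8L, 8L),
    divergence = c(0.09, 0.13, 0.018), mean_methylation = c(70, 68, 79)))
  cons <- make_consensus(cfg)
  sim <- plant_elements(cfg, cons)
  solo <- sim$truth[sim$truth$structure != "three_prime_of_pair", ]
  seqs <- setNames(
    vapply(seq_len(nrow(solo)), function(i) {
      el <- extract_with_flanks(sim$genome, solo[i, ])
      el$sequence
    }, character(1L)), solo$id)
  aln <- star_align_to_consensus(seqs, cons)

  tr <- bootstrap_support(aln, replicates = 50L, seed = 42L)
  tr_again <- bootstrap_support(aln, replicates = 50L, seed = 42L)
  expect_identical(tr$node.label, tr_again$node.label)

  # the two clade-defining bipartitions are strongly supported
  part <- partition_clades(tr, k = 3L)
  for (cl in unique(part$clades)) {
    tips <- names(part$clades)[part$clades == cl]
    if (length(tips) < 2L) next
    node <- ape::getMRCA(tr, tips)
    mono <- ape::is.monophyletic(tr, tips)
    if (mono && node > length(tr$tip.label) + 1L) {
      sup <- tr$node.label[node - length(tr$tip.label)]
      expect_gte(sup, 0.9)
    }
  }

  # single replicate gives 0/1 supports
  tr1 <- bootstrap_support(aln, replicates = 1L, seed = 1L)
  expect_true(all(tr1$node.label[-1L] %in% c(0, 1)))
})

test_that("clade partition recovers planted memberships and labels by divergence", {
  cfg <- sim_config(seed = 17L)
  sim <- plant_elements(cfg)
  keep <- sim$truth$structure != "three_prime_of_pair"
  solo <- sim$truth[keep, ]
  seqs <- setNames(
    vapply(seq_len(nrow(solo)), function(i)
      extract_with_flanks(sim$genome, solo[i, ])$sequence, character(1L)),
    solo$id)
  aln <- star_align_to_consensus(seqs, sim$consensus)
  tr <- neighbor_joining(jukes_cantor(p_distance(aln)))
  part <- partition_clades(tr, k = 3L,
                           divergence = 100 * iapmeth:::.p_to_consensus(aln))
  expect_setequal(names(part$clades), solo$id)
  acc <- mean(part$clades[solo$id] == solo$clade)
  expect_gte(acc, 0.95)

  # labels ordered by divergence: conserved clade carries the top label
  expect_equal(names(which.min(part$divergence)), "clade3")
  expect_lt(part$divergence["clade1"], part$divergence["clade2"])

  # invariance to leaf input order
  perm <- sample(length(seqs))
  aln_p <- star_align_to_consensus(seqs[perm], sim$consensus)
  tr_p <- neighbor_joining(jukes_cantor(p_distance(aln_p)))
  part_p <- partition_clades(tr_p, k = 3L,
                             divergence = 100 * iapmeth:::.p_to_consensus(aln_p))
  expect_equal(part_p$clades[names(part$clades)], part$clades)
})

test_that("single-clade and impossible partitions behave as specified", {
  fx <- random_additive_tree(6L, 12L)
  tr <- neighbor_joining(fx$d)
  one <- partition_clades(tr, k = 1L)
  expect_equal(unname(one$sizes), 6L)
  expect_true(all(one$clades == "clade1"))
  expect_error(partition_clades(tr, k = 3L, min_clade_size = 4L), "cannot")
})

test_that("clade divergence from consensus averages member p-distances", {
  cons <- random_dna(200L, seed = 61L)
  rows <- rbind(strsplit(cons, "")[[1L]], strsplit(cons, "")[[1L]])
  rownames(rows) <- c("m1", "m2")
  aln <- structure(list(names = rownames(rows), rows = rows,
                        consensus_row = strsplit(cons, "")[[1L]]),
                   class = "ltr_alignment")
  expect_equal(unname(clade_divergence(aln, c(m1 = "c1", m2 = "c1"))), 0)

  # two members at p = 0.01 and 0.03 average to 2.0%
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1L]]
    for (i in seq_len(k)) ch[i * 7L] <- setdiff(c("A", "C", "G", "T"), ch[i * 7L])[1L]
    paste(ch, collapse = "")
  }
  aln2 <- star_align_to_consensus(c(m1 = mut(cons, 2L), m2 = mut(cons, 6L)), cons)
  expect_equal(unname(clade_divergence(aln2, c(m1 = "c1", m2 = "c1"))), 2.0)

  # binomial member simulation at rate 0.09 recovers the rate within 1 point
  set.seed(200)
  members <- setNames(
    vapply(1:50, function(i) iapmeth:::.mutate(cons, 0.09), character(1L)),
    paste0("e", 1:50))
  aln3 <- star_align_to_consensus(members, cons)
  delta <- clade_divergence(aln3, setNames(rep("c1", 50L), names(members)))
  expect_equal(unname(delta), 9.0, tolerance = 1 / 9)
})
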
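test_that("locus summaries reproduce known columns of the bundled survey", {
  tab <- iap_cobra_data()
  ls <- locus_summaries(tab)
  expect_equal(ls$r_mean[ls$locus == "IAP31"], 59)
  expect_equal(ls$n_present[ls$locus == "IAP281Y"], 7L)
  expect_true(all(ls$min <= ls$median & ls$median <= ls$max))
  expect_equal(ls$range, ls$max - ls$min)

  const <- methylation_table(matrix(70, 5L, 1L,
                                    dimnames = list(paste0("m", 1:5), "loc")))
  cs <- locus_summaries(const)
  expect_equal(cs$mean, 70)
  expect_equal(cs$sd, 0)
  expect_equal(cs$range, 0)

  two <- methylation_table(matrix(c(48, 82), 2L, 1L,
                                  dimnames = list(c("m1", "m2"), "loc")))
  expect_equal(locus_summaries(two)$range, 34)
  expect_equal(locus_summaries(two)$sd, sd(c(48, 82)))
})

test_that("per-mouse means handle masked cells and stay within 71-74", {
  tab <- iap_cobra_data()
  ms <- mouse_summaries(tab)
  expect_true(all(ms$mean >= 70.5 & ms$mean <= 74.5))
  expect_lte(attr(ms, "spread")[["range"]], 3.5)

  single <- methylation_table(tab$M[, "IAP44", drop = FALSE])
  expect_equal(mouse_summaries(single)$mean, unname(tab$M[, "IAP44"]))

  # a mouse with one masked cell averages over the remaining loci
  m1 <- ms$mean[ms$mouse == "Mouse1"]
  expect_equal(m1, mean(tab$M["Mouse1", ], na.rm = TRUE))
  expect_equal(ms$n_present[ms$mouse == "Mouse1"], 19L)
})

test_that("the grand mean averages all present cells", {
  tab <- iap_cobra_data()
  expect_equal(grand_mean(tab), 72.5, tolerance = 0.5 / 72.5)

  allfifty <- methylation_table(matrix(50, 3L, 4L,
                                       dimnames = list(paste0("m", 1:3),
                                                       paste0("l", 1:4))))
  expect_equal(grand_mean(allfifty), 50)
  four <- methylation_table(matrix(c(60, 70, 80, 90), 2L, 2L,
                                   dimnames = list(c("m1", "m2"),
                                                   c("l1", "l2"))))
  expect_equal(grand_mean(four), 75)

  ls <- locus_summaries(tab)
  expect_gte(grand_mean(tab), min(ls$mean))
  expect_lte(grand_mean(tab), max(ls$mean))
})

test_that("clade statistics average locus means and ranges per clade", {
  tab <- iap_cobra_data()
  cs <- clade_statistics(tab)
  red <- cs[cs$clade == "clade1", ]
  green <- cs[cs$clade == "clade2", ]
  black <- cs[cs$clade == "clade3", ]
  expect_equal(red$mean, 70, tolerance = 0.5 / 70)
  expect_equal(black$mean, 79, tolerance = 0.5 / 79)
  expect_equal(red$mean_range, 21, tolerance = 1 / 21)
  expect_equal(black$mean_range, 11, tolerance = 1 / 11)
  expect_gt(black$mean, max(red$mean, green$mean))

  # a one-locus clade equals that locus's own statistics
  one <- methylation_table(tab$M[, c("IAP44", "IAP506"), drop = FALSE],
                           clade = c(IAP44 = "cA", IAP506 = "cB"))
  cs1 <- clade_statistics(one)
  ls1 <- locus_summaries(one)
  expect_equal(cs1$mean[cs1$clade == "cA"], ls1$mean[ls1$locus == "IAP44"])
  expect_equal(cs1$mean_range[cs1$clade == "cA"],
               ls1$range[ls1$locus == "IAP44"])
})

test_that("ANOVA handles degenerate groups and matches base R", {
  # identical values per group with equal means: F = 0, all p = 1
  res0 <- anova_tukey(list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5)))
  expect_equal(res0$F, 0)
  expect_true(all(res0$pairwise$p_adj == 1))
  expect_equal(res0$df_between, 2L)

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(anova_tukey(list(a = c(1, 2))), "at least 2 groups")

  # cross-check against stats::aov + TukeyHSD on unbalanced groups
  set.seed(101)
  groups <- list(g1 = rnorm(7, 50, 5), g2 = rnorm(5, 55, 5),
                 g3 = rnorm(9, 62, 5))
  res <- anova_tukey(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups))))
  fit <- aov(y ~ g, df)
  expect_equal(res$F, summary(fit)[[1L]]$`F value`[1L], tolerance = 1e-10)
  expect_equal(res$p_omnibus, summary(fit)[[1L]]$`Pr(>F)`[1L],
               tolerance = 1e-10)
  thsd <- TukeyHSD(fit)$g
  expect_equal(res$pairwise$p_adj[match(rownames(thsd), res$pairwise$pair)],
               unname(thsd[, "p adj"]), tolerance = 1e-8)
})

test_that("ANOVA F and Tukey p agree with a permutation oracle", {
  # balanced 3 x 5 example with clear but not extreme separation
  groups <- list(a = c(51, 48, 53, 50, 49), b = c(55, 57, 52, 56, 54),
                 c = c(60, 58, 63, 59, 61))
  res <- anova_tukey(groups)
  y <- unlist(groups)
  g <- rep(1:3, each = 5L)
  obs_f <- res$F

  f_of <- function(lab) {
    ms <- tapply(y, lab, mean)
    ssb <- sum(5 * (ms - mean(y))^2)
    ssw <- sum((y - ms[lab])^2)
    (ssb / 2) / (ssw / 12)
  }
  q_of <- function(lab) {
    ms <- tapply(y, lab, mean)
    ssw <- sum((y - ms[lab])^2)
    se <- sqrt((ssw / 12) / 5)
    max(abs(outer(ms, ms, `-`))) / se
  }
  set.seed(77)
  B <- 1e5L
  f_ge <- 0L; q_ge_ab <- 0L
  q_obs_ab <- abs(mean(groups$b) - mean(groups$a)) /
    sqrt((sum((y - tapply(y, g, mean)[g])^2) / 12) / 5)
  for (b in seq_len(B)) {
    lab <- sample(g)
    if (f_of(lab) >= obs_f) f_ge <- f_ge + 1L
    if (q_of(lab) >= q_obs_ab) q_ge_ab <- q_ge_ab + 1L
  }
  expect_equal(res$p_omnibus, f_ge / B, tolerance = 0.01 / max(res$p_omnibus, 0.01))
  # max-T permutation p for the a-b contrast approximates its Tukey p
  p_ab <- res$pairwise$p_adj[res$pairwise$pair == "b-a"]
  expect_lt(abs(p_ab - q_ge_ab / B), 0.01)
})

test_that("ANOVA is location invariant and Tukey p dominates plain t", {
  set.seed(111)
  groups <- list(a = rnorm(6, 10, 2), b = rnorm(6, 12, 2), c = rnorm(6, 9, 2))
  res <- anova_tukey(groups)
  shifted <- lapply(groups, `+`, 100)
  expect_equal(anova_tukey(shifted)$F, res$F, tolerance = 1e-10)
  scaled <- lapply(groups, `*`, 3)
  expect_equal(anova_tukey(scaled)$F, res$F, tolerance = 1e-10)

  # Tukey-adjusted p >= unadjusted pairwise t (pooled variance) p
  ms_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) /
    (sum(lengths(groups)) - 3L)
  for (i in seq_len(nrow(res$pairwise))) {
    pr <- strsplit(res$pairwise$pair[i], "-")[[1L]]
    tt <- abs(mean(groups[[pr[1L]]]) - mean(groups[[pr[2L]]])) /
      sqrt(ms_w * (1 / 6 + 1 / 6))
    p_t <- 2 * pt(tt, df = 15L, lower.tail = FALSE)
    expect_gte(res$pairwise$p_adj[i], p_t - 1e-12)
  }
})

test_that("summaries are invariant to row and column permutation", {
  tab <- iap_cobra_data()
  set.seed(121)
  pr <- sample(nrow(tab$M)); pc <- sample(ncol(tab$M))
  perm <- methylation_table(tab$M[pr, pc], mask = tab$mask[pr, pc],
                            clade = tab$clade, sex = tab$sex)
  ls0 <- locus_summaries(tab); lsp <- locus_summaries(perm)
  expect_equal(lsp[match(ls0$locus, lsp$locus), -1L], ls0[, -1L],
               ignore_attr = TRUE)
  expect_equal(grand_mean(perm), grand_mean(tab))
  cs0 <- clade_statistics(tab); csp <- clade_statistics(perm)
  expect_equal(csp[match(cs0$clade, csp$clade), ], cs0, ignore_attr = TRUE)
})

test_that("the clade comparison on the bundled survey shows the expected pattern", {
  tab <- iap_cobra_data()
  res <- clade_anova(tab)
  pw <- res$anova$pairwise
  p_b_r <- pw$p_adj[pw$pair %in% c("clade3-clade1", "clade1-clade3")]
  p_b_g <- pw$p_adj[pw$pair %in% c("clade3-clade2", "clade2-clade3")]
  p_r_g <- pw$p_adj[pw$pair %in% c("clade2-clade1", "clade1-clade2")]
  expect_lt(p_b_r, 0.05)
  expect_lt(p_b_g, 0.05)
  expect_gt(p_r_g, 0.05)
  means <- res$anova$group_means
  expect_gt(means[["clade3"]], means[["clade1"]])
  expect_gt(means[["clade3"]], means[["clade2"]])
})
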
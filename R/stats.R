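#' Per-locus summary statistics
#'
#' Summarises each locus column of a methylation table over its present
#' (unmasked) cells: mean, median, sample standard deviation (n - 1), min,
#' max, range and interquartile range. Values are reported unrounded; a
#' rounded copy (nearest integer, the gel-report convention) is attached in
#' columns prefixed \code{r_}.
#'
#' @param table A \code{methylation_table}.
#' @return data.frame, one row per locus.
#' @export
locus_summaries <- function(table) {
  M <- table$M
  stat <- function(f) apply(M, 2L, f, na.rm = TRUE)
  out <- data.frame(
    locus = colnames(M),
    n_present = colSums(!is.na(M)),
    mean = stat(mean), median = stat(stats::median),
    sd = apply(M, 2L, stats::sd, na.rm = TRUE),
    min = stat(min), max = stat(max),
    IQR = apply(M, 2L, stats::IQR, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$range <- out$max - out$min
  for (col in c("mean", "median", "sd", "min", "max", "range"))
    out[[paste0("r_", col)]] <- round(out[[col]])
  if (!is.null(table$clade)) out$clade <- unname(table$clade[out$locus])
  rownames(out) <- NULL
  out
}

#' Per-mouse mean methylation
#'
#' Row means over present cells, plus the spread of those means across mice
#' (attribute \code{"spread"} with \code{min}, \code{max}, \code{range}).
#'
#' @param table A \code{methylation_table}.
#' @return data.frame with \code{mouse}, \code{mean}, \code{n_present}.
#' @export
mouse_summaries <- function(table) {
  M <- table$M
  out <- data.frame(
    mouse = rownames(M),
    mean = rowMeans(M, na.rm = TRUE),
    n_present = rowSums(!is.na(M)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "spread") <- c(min = min(out$mean), max = max(out$mean),
                           range = max(out$mean) - min(out$mean))
  out
}

#' Grand mean methylation
#'
#' Mean over all present cells of the table.
#'
#' @param table A \code{methylation_table}.
#' @return Numeric scalar (percent).
#' @export
grand_mean <- function(table) {
  mean(table$M, na.rm = TRUE)
}

#' Clade-level methylation statistics
#'
#' Per clade: the mean of its loci's (unrounded) locus means, the mean of
#' its loci's ranges, and the pooled within-locus standard deviation.
#'
#' @param table A \code{methylation_table} with a clade map (or supply one).
#' @param clade_map Optional named locus -> clade vector overriding the
#'   table's.
#' @return data.frame, one row per clade.
#' @export
clade_statistics <- function(table, clade_map = NULL) {
  clade <- if (!is.null(clade_map)) clade_map[colnames(table$M)] else table$clade
  if (is.null(clade)) stop("no clade map available")
  ls <- locus_summaries(table)
  ls$clade <- unname(clade[ls$locus])
  rows <- lapply(split(ls, ls$clade), function(g) {
    dfs <- g$n_present - 1L
    data.frame(clade = g$clade[1L], n_loci = nrow(g),
               mean = mean(g$mean), mean_range = mean(g$range),
               pooled_sd = sqrt(sum(dfs * g$sd^2) / sum(dfs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey-adjusted pairwise contrasts
#'
#' Fits the one-way fixed-effects ANOVA (\code{F = MS_between / MS_within}
#' from the standard sums of squares) and adjusts all pairwise group
#' contrasts by the studentized-range (Tukey HSD) procedure, using the
#' Tukey-Kramer standard error for unequal group sizes:
#' \code{q = |diff| / sqrt(MSW/2 (1/n_i + 1/n_j))} referred to the
#' studentized-range distribution with \code{(k, df_within)}.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class \code{"anova_tukey"}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p_omnibus}, \code{pairwise} (data.frame with
#'   \code{pair}, \code{diff}, \code{p_adj}, \code{significant}),
#'   \code{group_means}, \code{alpha}.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1L))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df_b <- k - 1L
  df_w <- N - k
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    f_stat <- if (ss_between == 0) 0 else Inf
    p_omni <- if (ss_between == 0) 1 else 0
  } else {
    f_stat <- (ss_between / df_b) / ms_w
    p_omni <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }
  pairs <- utils::combn(names(groups), 2L)
  pw <- data.frame(
    pair = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
    diff = means[pairs[2L, ]] - means[pairs[1L, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(ms_w / 2 * (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
  q <- abs(pw$diff) / se
  pw$p_adj <- ifelse(se == 0, ifelse(pw$diff == 0, 1, 0),
                     stats::ptukey(q, nmeans = k, df = df_w,
                                   lower.tail = FALSE))
  pw$significant <- pw$p_adj < alpha
  rownames(pw) <- NULL
  structure(list(F = f_stat, df_between = df_b, df_within = df_w,
                 p_omnibus = p_omni, pairwise = pw,
                 group_means = means, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_omnibus))
  cat("Tukey HSD pairwise contrasts:\n")
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("  %-22s diff = %7.3f   adj p = %.4f%s\n", r$pair, r$diff,
                r$p_adj, if (r$significant) " *" else ""))
  }
  invisible(x)
}

#' Clade-comparison ANOVA on per-locus means
#'
#' The clade test treats the per-locus mean methylation as the unit of
#' analysis (one value per locus, avoiding pseudo-replication across mice)
#' and compares clades by [anova_tukey()].
#'
#' @param table A \code{methylation_table} with clade annotations.
#' @param clade_map Optional locus -> clade override.
#' @param alpha Significance level.
#' @return Object of class \code{"clade_anova"} wrapping the
#'   \code{anova_tukey} result plus the clade statistics.
#' @export
clade_anova <- function(table, clade_map = NULL, alpha = 0.05) {
  clade <- if (!is.null(clade_map)) clade_map[colnames(table$M)] else table$clade
  if (is.null(clade)) stop("no clade map available")
  ls <- locus_summaries(table)
  groups <- split(ls$mean, unname(clade[ls$locus]))
  res <- anova_tukey(groups, alpha = alpha)
  structure(list(anova = res,
                 clade_stats = clade_statistics(table, clade_map),
                 unit = "per-locus mean"),
            class = "clade_anova")
}

#' @export
print.clade_anova <- function(x, ...) {
  cat("Clade methylation comparison (unit: per-locus mean)\n")
  cs <- x$clade_stats
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-8s %d loci, mean %.1f%%, average range %.1f%%\n",
                cs$clade[i], cs$n_loci[i], cs$mean[i], cs$mean_range[i]))
  print(x$anova)
  invisible(x)
}
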
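#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators, defaulted to the
#' study conditions the pipeline is meant to emulate at desk scale: a 337 nt
#' LTR consensus; three clades whose members diverge from the consensus by
#' 9.1\%, 12.9\% and 1.8\% (clade1/clade2/clade3), with the conserved clade3
#' the largest; mostly paired insertions with 5-7 kb bodies; and a 17-mice
#' methylation survey with clade mean methylation 70/68/79\%, between-locus
#' sd 7, within-locus sd 2-8, and rare limit-of-detection dropouts.
#'
#' @param seed Integer seed; every generator is fully reproducible under it.
#' @param consensus_length LTR consensus length in nt (default 337).
#' @param clade_spec data.frame with columns \code{clade}, \code{n},
#'   \code{divergence} (per-site substitution probability) and
#'   \code{mean_methylation} (percent).
#' @param paired_fraction Probability an insertion carries both LTRs.
#' @param body_length_range Internal body length range, nt.
#' @param flank_gap_range Random background gap between insertions, nt;
#'   must exceed the LTR pairing window so unlinked insertions never pair.
#' @param genome_length Optional minimum genome length (tail-padded).
#' @param n_mice,n_loci_per_clade Methylation survey dimensions.
#' @param locus_mean_sd Between-locus sd of true locus means (percent).
#' @param within_locus_sd_range Within-locus (between-mice) sd range.
#' @param lod_dropout_prob Per-cell probability of a below-LOD lane.
#' @param gel_noise_cv Coefficient of variation of multiplicative band noise.
#' @param lane_scale Median lane intensity scale (intensity units per
#'   percent of template).
#' @param lod_threshold Detection threshold on the uncut band intensity.
#' @param high_control_m True methylation of the high-methylation control.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 17L,
                       consensus_length = 337L,
                       clade_spec = data.frame(
                         clade = c("clade1", "clade2", "clade3"),
                         n = c(15L, 12L, 40L),
                         divergence = c(0.091, 0.129, 0.018),
                         mean_methylation = c(70, 68, 79)),
                       paired_fraction = 0.7,
                       body_length_range = c(5000L, 7000L),
                       flank_gap_range = c(9000L, 15000L),
                       genome_length = NULL,
                       n_mice = 17L,
                       n_loci_per_clade = 7L,
                       locus_mean_sd = 7,
                       within_locus_sd_range = c(2, 8),
                       lod_dropout_prob = 0.02,
                       gel_noise_cv = 0.05,
                       lane_scale = 50,
                       lod_threshold = 50,
                       high_control_m = 97) {
  stopifnot(paired_fraction >= 0, paired_fraction <= 1,
            lod_dropout_prob >= 0, lod_dropout_prob <= 1,
            all(clade_spec$n >= 0), all(clade_spec$divergence >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random LTR consensus
#'
#' Random sequence of the configured length carrying at least one embedded
#' \code{ACGGCG} motif on each strand orientation (so junction assays are
#' designable from either strand) and a CpG density of at least 2 per 100 nt.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return Character consensus sequence.
#' @export
make_consensus <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$consensus_length
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  put <- function(chars, motif, at) {
    m <- strsplit(motif, "")[[1L]]
    chars[at:(at + length(m) - 1L)] <- m
    chars
  }
  # site on the sense strand and (as its reverse complement) on antisense
  chars <- put(chars, "ACGGCG", max(1L, round(L * 0.45)))
  chars <- put(chars, "CGCCGT", max(8L, round(L * 0.75)))
  # top up CpG density to >= 2 per 100 nt
  need <- ceiling(2 * L / 100)
  repeat {
    cpg <- sum(chars == "C" & c(chars[-1L], "") == "G")
    if (cpg >= need) break
    at <- sample(L - 1L, 1L)
    chars[at] <- "C"; chars[at + 1L] <- "G"
  }
  paste(chars, collapse = "")
}

# per-site substitution at probability `rate` (no indels); exact = TRUE
# substitutes exactly round(L * rate) distinct sites (used for clade
# founders, so the clade-level divergence is pinned near its target while
# members keep binomial site-sampling noise)
.mutate <- function(seq, rate, exact = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- if (exact) sample(length(chars), round(length(chars) * rate))
         else which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant clade-structured LTR insertions in a toy genome
#'
#' For each clade a founder is derived from the consensus at half the clade
#' divergence rate and members accrue the other half independently, creating
#' genuine shared-derived substitutions (a real clade topology, not star
#' noise) with expected total divergence near the clade rate. Members are
#' placed in shuffled order on one contig with random unique flanks; paired
#' members receive a random internal body and an identical second LTR copy.
#' Matching RepeatMasker-format annotations carry the realized coordinates,
#' strands and divergences.
#'
#' @param config A [sim_config()].
#' @param consensus Consensus sequence; defaults to [make_consensus()].
#' @return List with \code{genome} (named contig vector),
#'   \code{annotations} (a \code{repeat_annotation}), \code{truth}
#'   (data.frame: one row per LTR copy with id, coordinates, strand,
#'   structure, clade, member and realized divergence), and
#'   \code{consensus}.
#' @export
plant_elements <- function(config = sim_config(), consensus = NULL) {
  if (is.null(consensus)) consensus <- make_consensus(config)
  set.seed(config$seed + 1L)
  L <- nchar(consensus)
  spec <- config$clade_spec

  members <- list()
  for (ci in seq_len(nrow(spec))) {
    founder <- .mutate(consensus, spec$divergence[ci] / 2, exact = TRUE)
    for (m in seq_len(spec$n[ci])) {
      members[[length(members) + 1L]] <- list(
        clade = spec$clade[ci],
        seq = .mutate(founder, spec$divergence[ci] / 2),
        paired = stats::runif(1L) < config$paired_fraction,
        strand = sample(c("+", "-"), 1L))
    }
  }
  members <- members[sample(length(members))]

  pieces <- character(0)
  pos <- 0L
  truth <- list()
  add_piece <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  for (k in seq_along(members)) {
    mb <- members[[k]]
    add_piece(.random_seq(sample(config$flank_gap_range[1L]:config$flank_gap_range[2L], 1L)))
    div <- .seq_divergence(mb$seq, consensus)
    if (mb$paired) {
      body <- .random_seq(sample(config$body_length_range[1L]:config$body_length_range[2L], 1L))
      insert <- paste0(mb$seq, body, mb$seq)
      ins_start <- pos + 1L
      add_piece(if (mb$strand == "+") insert else revcomp(insert))
      b <- nchar(body)
      left <- c(ins_start, ins_start + L - 1L)
      right <- c(ins_start + L + b, ins_start + 2L * L + b - 1L)
      structs <- if (mb$strand == "+") c("five_prime_of_pair", "three_prime_of_pair")
                 else c("three_prime_of_pair", "five_prime_of_pair")
      truth[[length(truth) + 1L]] <- data.frame(
        member = k, clade = mb$clade, strand = mb$strand,
        start = c(left[1L], right[1L]), end = c(left[2L], right[2L]),
        structure = structs, divergence = div, stringsAsFactors = FALSE)
    } else {
      ins_start <- pos + 1L
      add_piece(if (mb$strand == "+") mb$seq else revcomp(mb$seq))
      truth[[length(truth) + 1L]] <- data.frame(
        member = k, clade = mb$clade, strand = mb$strand,
        start = ins_start, end = ins_start + L - 1L,
        structure = "solo_ltr", divergence = div, stringsAsFactors = FALSE)
    }
  }
  add_piece(.random_seq(sample(config$flank_gap_range[1L]:config$flank_gap_range[2L], 1L)))
  genome <- paste(pieces, collapse = "")
  if (!is.null(config$genome_length) && nchar(genome) < config$genome_length)
    genome <- paste0(genome, .random_seq(config$genome_length - nchar(genome)))

  truth <- do.call(rbind, truth)
  truth$id <- paste0("IAP", seq_len(nrow(truth)))
  ann <- data.frame(
    score = as.integer(round((1 - truth$divergence) * L * 5)),
    percent_div = round(truth$divergence * 100, 1),
    chrom = "chr1", start = truth$start, end = truth$end,
    strand = truth$strand, repeat_name = "IAPLTR1_Mm",
    repeat_class = "LTR/ERVK", stringsAsFactors = FALSE)
  class(ann) <- c("repeat_annotation", "data.frame")
  truth$chrom <- "chr1"
  list(genome = c(chr1 = genome), annotations = ann, truth = truth,
       consensus = consensus)
}

.seq_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca != cb)
}

#' Simulate a mice-by-loci methylation survey
#'
#' Per locus, the true mean is drawn from a normal around its clade mean
#' (truncated to [0, 100]); per mouse, the observed value adds within-locus
#' noise with a locus-specific sd drawn uniformly from the configured
#' range; cells drop out independently at the LOD rate.
#'
#' @param config A [sim_config()].
#' @param clade_labels Optional character vector of clade labels per locus;
#'   defaults to \code{n_loci_per_clade} loci for each configured clade.
#' @return List with \code{table} (a \code{methylation_table}) and
#'   \code{truth} (list: \code{locus_mean}, \code{locus_sd}, \code{mask}).
#' @export
simulate_methylation <- function(config = sim_config(), clade_labels = NULL) {
  set.seed(config$seed + 2L)
  spec <- config$clade_spec
  if (is.null(clade_labels))
    clade_labels <- rep(spec$clade, each = config$n_loci_per_clade)
  n_loci <- length(clade_labels)
  loci <- paste0("locus", seq_len(n_loci))
  mice <- paste0("Mouse", seq_len(config$n_mice))
  clade_mean <- stats::setNames(spec$mean_methylation, spec$clade)[clade_labels]

  locus_mean <- .rtruncnorm(n_loci, clade_mean, config$locus_mean_sd, 0, 100)
  locus_sd <- stats::runif(n_loci, config$within_locus_sd_range[1L],
                           config$within_locus_sd_range[2L])
  M <- matrix(NA_real_, config$n_mice, n_loci, dimnames = list(mice, loci))
  for (j in seq_len(n_loci))
    M[, j] <- .rtruncnorm(config$n_mice, locus_mean[j], locus_sd[j], 0, 100)
  mask_mat <- matrix(stats::runif(length(M)) < config$lod_dropout_prob,
                     nrow(M), ncol(M), dimnames = dimnames(M))
  M_obs <- M
  M_obs[mask_mat] <- NA_real_
  tab <- methylation_table(
    M_obs,
    mask = matrix(ifelse(mask_mat, "lod", ""), nrow(M), ncol(M),
                  dimnames = dimnames(M)),
    clade = stats::setNames(clade_labels, loci))
  list(table = tab,
       truth = list(locus_mean = stats::setNames(locus_mean, loci),
                    locus_sd = stats::setNames(locus_sd, loci),
                    clade = stats::setNames(clade_labels, loci),
                    mask = mask_mat, M = M))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), if (length(mean) > 1L) mean[bad] else mean,
                             if (length(sd) > 1L) sd[bad] else sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Simulate gel band intensities from a methylation table
#'
#' Inverse model of the gel read-out: per present cell with methylation M,
#' the cut and uncut bands get intensities \code{c * M * e1} and
#' \code{c * (100 - M) * e2}, with a random per-lane scale \code{c}
#' (lognormal around \code{lane_scale}) and multiplicative lognormal noise
#' of the configured coefficient of variation (mean 1). The cut intensity
#' is split over two sub-fragment bands. Masked cells are emitted as faint
#' lanes (scale times 0.001) so the LOD rule recovers the mask; each locus
#' additionally gets an unmethylated (0\%) and a high-methylation control
#' lane.
#'
#' @param table A \code{methylation_table}.
#' @param config A [sim_config()].
#' @return data.frame of bands: \code{mouse_id}, \code{locus_id},
#'   \code{band_role} (\code{uncut}/\code{cut1}/\code{cut2}),
#'   \code{intensity}.
#' @export
simulate_gel <- function(table, config = sim_config()) {
  set.seed(config$seed + 3L)
  cv <- config$gel_noise_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(n) if (cv > 0)
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, n)
  M <- table$M
  rows <- list()
  emit <- function(mouse, locus, m, scale) {
    e <- noise(2L)
    i_cut <- scale * m * e[1L]
    i_uncut <- scale * (100 - m) * e[2L]
    split <- stats::runif(1L, 0.3, 0.7)
    rows[[length(rows) + 1L]] <<- data.frame(
      mouse_id = mouse, locus_id = locus,
      band_role = c("uncut", "cut1", "cut2"),
      intensity = c(i_uncut, i_cut * split, i_cut * (1 - split)),
      stringsAsFactors = FALSE)
  }
  for (j in colnames(M)) {
    for (i in rownames(M)) {
      if (table$mask[i, j] == "absent") next
      scale <- config$lane_scale * stats::rlnorm(1L, 0, 0.2)
      if (table$mask[i, j] == "lod") {
        true_m <- stats::runif(1L, 0, 100)  # unobservable; lane is faint
        emit(i, j, true_m, scale * 0.001)
      } else {
        emit(i, j, M[i, j], scale)
      }
    }
    scale <- config$lane_scale * stats::rlnorm(2L, 0, 0.2)
    emit("control_zero", j, 0, scale[1L])
    emit("control_high", j, config$high_control_m, scale[2L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
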
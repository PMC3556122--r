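#' Assay design configuration
#'
#' Collects the tunable CoBRA design parameters with their defaults:
#' primer lengths 18-29 nt (the range seen in published assays of this
#' family), Wallace-rule melting temperature window 45-60 degC, amplicon
#' span 150-1300 nt, a 30 nt minimum distance between the diagnostic site
#' and either primer, the two-CpG recognition string \code{ACGGCG}, a 12 nt
#' downstream cut offset, and default cycling conditions (45 cycles, 52
#' degC annealing).
#'
#' @param primer_length Integer range \code{c(min, max)}.
#' @param tm_window Numeric range (degC) for the Wallace-rule estimate.
#' @param amplicon_range Integer range (nt).
#' @param min_site_distance Minimum nt between site and each primer.
#' @param recognition Recognition string.
#' @param cut_offset Cut offset nt downstream of the site.
#' @param pcr_cycles,anneal_temp Recorded PCR conditions.
#' @param max_slide Maximum primer-window slide during the search.
#' @return A list of class \code{"assay_config"}.
#' @export
assay_config <- function(primer_length = c(18L, 29L), tm_window = c(45, 60),
                         amplicon_range = c(150L, 1300L),
                         min_site_distance = 30L, recognition = "ACGGCG",
                         cut_offset = 12L, pcr_cycles = 45L,
                         anneal_temp = 52, max_slide = 80L) {
  structure(list(primer_length = primer_length, tm_window = tm_window,
                 amplicon_range = amplicon_range,
                 min_site_distance = min_site_distance,
                 recognition = recognition, cut_offset = cut_offset,
                 pcr_cycles = pcr_cycles, anneal_temp = anneal_temp,
                 max_slide = max_slide),
            class = "assay_config")
}

#' Wallace-rule melting temperature
#'
#' \code{Tm = 2 (A + T) + 4 (G + C)} over non-degenerate bases; degenerate
#' codes contribute the mean of their expansions (Y/R count 3 degC).
#'
#' @param primer Character oligo.
#' @return Estimated Tm in degC.
#' @export
wallace_tm <- function(primer) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  sum(c(A = 2, T = 2, G = 4, C = 4, Y = 3, R = 3, N = 3)[chars], na.rm = TRUE)
}

#' Reduce a paired catalog to CoBRA candidates
#'
#' Keeps only elements with a complete insertion structure assayable at the
#' 5' junction (structure \code{five_prime_of_pair}) and drops elements
#' whose 400 nt assay flank is repetitive: either it shares an exact match
#' of at least \code{min_shared} nt with another candidate's flank, or at
#' least \code{max_repeat_cov} of it is covered by other repeat annotations.
#' Removal counts per reason are attached as attribute \code{"removed"}.
#'
#' @param catalog An \code{ltr_catalog} with structures from [pair_ltrs()].
#' @param annotations Optional \code{repeat_annotation} catalog used for the
#'   repeat-coverage test (the candidate's own footprint is excluded).
#' @param min_shared Exact shared-match threshold in nt (default 30).
#' @param max_repeat_cov Maximum tolerated repeat coverage of the flank.
#' @return Filtered \code{ltr_catalog} with attribute
#'   \code{removed = c(not_five_prime=, shared_flank=, repeat_flank=)}.
#' @export
select_candidates <- function(catalog, annotations = NULL, min_shared = 30L,
                              max_repeat_cov = 0.5) {
  df <- as.data.frame(catalog)
  is5 <- df$structure == "five_prime_of_pair"
  cand <- which(is5)
  shared <- logical(length(catalog))
  if (length(cand) > 1L) {
    kmers <- lapply(cand, function(i) .kmer_set(df$flank_up[i], min_shared))
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
      if (a >= b) next
      if (length(kmers[[a]]) && length(kmers[[b]]) &&
          any(kmers[[a]] %in% kmers[[b]])) {
        shared[cand[a]] <- TRUE; shared[cand[b]] <- TRUE
      }
    }
  }
  repeat_cov <- logical(length(catalog))
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in cand) {
      fl <- nchar(df$flank_up[i])
      if (fl == 0L) next
      if (df$strand[i] == "+") {
        lo <- df$start[i] - fl; hi <- df$start[i] - 1L
      } else {
        lo <- df$end[i] + 1L; hi <- df$end[i] + fl
      }
      same <- annotations$chrom == df$chrom[i] &
        !(annotations$start == df$start[i] & annotations$end == df$end[i])
      if (!any(same)) next
      ov <- IRanges::intersect(
        IRanges::IRanges(lo, hi),
        IRanges::reduce(IRanges::IRanges(annotations$start[same],
                                         annotations$end[same])))
      if (sum(IRanges::width(ov)) / fl >= max_repeat_cov)
        repeat_cov[i] <- TRUE
    }
  }
  keep <- is5 & !shared & !repeat_cov
  removed <- c(not_five_prime = sum(!is5),
               shared_flank = sum(is5 & shared),
               repeat_flank = sum(is5 & !shared & repeat_cov))
  out <- catalog[keep]
  class(out) <- "ltr_catalog"
  attr(out, "removed") <- removed
  out
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Design a CoBRA bisulfite-PCR assay
#'
#' Designs a primer pair on the fully-methylated bisulfite-converted
#' template formed by the element followed by its downstream assay flank:
#' the forward primer lies entirely inside the element, the reverse primer
#' entirely inside the flank (making the amplicon insertion-specific), and
#' the amplicon must contain a methylation-dependent recognition site at
#' least \code{min_site_distance} nt from each primer. Any CpG cytosine
#' falling inside a primer is degenerated to \code{Y} (forward) or \code{R}
#' (reverse), so priming is unbiased by the template's methylation state.
#'
#' @param element Element sequence in assay orientation (character), or an
#'   \code{ltr_element} (then the antisense strand of the element and of its
#'   upstream flank is assayed, per the junction-PCR design).
#' @param flank_down Flank sequence downstream of the element in assay
#'   orientation; ignored when \code{element} is an \code{ltr_element}.
#' @param config An [assay_config()].
#' @return A \code{"cobra_assay"} object, or a \code{"assay_failure"} with a
#'   \code{reason} field when no compliant primer pair exists.
#' @export
design_primers <- function(element, flank_down = NULL, config = assay_config()) {
  element_id <- NA_character_
  if (inherits(element, "ltr_element")) {
    element_id <- element$id
    flank_down <- revcomp(element$flank_up)
    element <- revcomp(element$sequence)
  }
  if (is.null(flank_down)) stop("flank_down is required")
  el_len <- nchar(element)
  fl_len <- nchar(flank_down)
  template <- paste0(element, flank_down)
  total <- el_len + fl_len

  sites <- find_methylation_dependent_sites(template, config$recognition)
  sites <- sites[sites$dependent, , drop = FALSE]
  if (nrow(sites) == 0L)
    return(.assay_failure("no methylation-dependent site", element_id))

  cpg_all <- .cpg_positions(template)
  conv <- bisulfite_convert(template, cpg_all)
  mind <- config$min_site_distance
  lens <- config$primer_length[1L]:config$primer_length[2L]

  for (s in seq_len(nrow(sites))) {
    site <- sites[s, ]
    fwd <- .find_primer(conv, anchor = min(el_len, site$start - mind),
                        direction = -1L, lo = 1L, hi = el_len,
                        lens = lens, config = config, cpg = cpg_all)
    if (is.null(fwd)) next
    rev_lo <- max(el_len + 1L, site$end + mind)
    rev <- NULL
    for (slide in 0:config$max_slide) {
      cand <- .find_primer(conv, anchor = rev_lo + slide, direction = 1L,
                           lo = el_len + 1L, hi = total, lens = lens,
                           config = config, max_slide = 0L, cpg = cpg_all)
      if (is.null(cand)) next
      amp_len <- cand$end - fwd$start + 1L
      if (amp_len < config$amplicon_range[1L]) next
      if (amp_len > config$amplicon_range[2L]) break
      rev <- cand
      break
    }
    if (is.null(rev)) next

    amp_start <- fwd$start; amp_end <- rev$end
    amplicon <- substr(template, amp_start, amp_end)
    # a CpG whose G lies past the amplicon end is not a CpG of the amplicon
    amp_cpgs <- cpg_all[cpg_all >= amp_start & cpg_all < amp_end] - amp_start + 1L
    site_rel <- c(site$start, site$end) - amp_start + 1L
    diagnostic <- which(amp_cpgs >= site_rel[1L] & amp_cpgs <= site_rel[2L])
    fwd_seq <- .degenerate(substr(conv, fwd$start, fwd$end),
                           cpg_all - fwd$start + 1L, "Y")
    rev_region <- substr(conv, rev$start, rev$end)
    rev_seq <- .degenerate(revcomp(rev_region),
                           rev$end - cpg_all + 1L, "R")
    frags <- in_silico_digest(amplicon, amp_cpgs,
                              recognition = config$recognition,
                              cut_offset = config$cut_offset)
    return(structure(list(
      element_id = element_id,
      amplicon_start = amp_start, amplicon_end = amp_end,
      amplicon = amplicon,
      forward_primer = fwd_seq, reverse_primer = rev_seq,
      forward_start = fwd$start, forward_end = fwd$end,
      reverse_start = rev$start, reverse_end = rev$end,
      cpg_sites = amp_cpgs,
      site_start = site_rel[1L], site_end = site_rel[2L],
      diagnostic_cpgs = diagnostic,
      pcr_cycles = config$pcr_cycles, anneal_temp = config$anneal_temp,
      predicted_fragments = frags,
      element_length = el_len, flank_length = fl_len
    ), class = "cobra_assay"))
  }
  # diagnose the dominant failure mode for the first site
  site <- sites[1L, ]
  if (all(strsplit(flank_down, "")[[1L]] %in% c("N", "-")))
    return(.assay_failure("no reverse primer", element_id))
  if (min(el_len, site$start - mind) < config$primer_length[1L])
    return(.assay_failure("site too close to primer", element_id))
  .assay_failure("no valid primer pair", element_id)
}

# search a primer window near `anchor`; direction -1 anchors the 3' end and
# grows leftwards (forward primer), +1 anchors the 5' end (reverse primer);
# Tm is scored on the degenerate oligo, since that is what gets synthesised
.find_primer <- function(conv, anchor, direction, lo, hi, lens, config,
                         max_slide = config$max_slide, cpg = integer(0)) {
  for (slide in 0:max_slide) {
    edge <- anchor + direction * slide  # slides away from the site
    for (len in lens) {
      if (direction < 0L) { p_end <- edge; p_start <- edge - len + 1L }
      else { p_start <- edge; p_end <- edge + len - 1L }
      if (p_start < lo || p_end > hi) next
      primer <- substr(conv, p_start, p_end)
      if (grepl("N", primer, fixed = TRUE)) next
      oligo <- if (direction < 0L)
        .degenerate(primer, cpg - p_start + 1L, "Y")
      else
        .degenerate(revcomp(primer), p_end - cpg + 1L, "R")
      tm <- wallace_tm(oligo)
      if (tm >= config$tm_window[1L] && tm <= config$tm_window[2L])
        return(list(start = p_start, end = p_end))
    }
  }
  NULL
}

.cpg_positions <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  which(chars == "C" & c(chars[-1L], "") == "G")
}

.degenerate <- function(primer, cpg_rel, code) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  idx <- cpg_rel[cpg_rel >= 1L & cpg_rel <= length(chars)]
  target <- if (code == "Y") "C" else "G"
  idx <- idx[chars[idx] == target]
  chars[idx] <- code
  paste(chars, collapse = "")
}

.assay_failure <- function(reason, element_id = NA_character_) {
  structure(list(reason = reason, element_id = element_id),
            class = "assay_failure")
}

#' @export
print.cobra_assay <- function(x, ...) {
  cat(sprintf("CoBRA assay%s\n",
              if (!is.na(x$element_id)) paste0(" for ", x$element_id) else ""))
  cat(sprintf("  forward primer: %s (Tm %.0f)\n", x$forward_primer,
              wallace_tm(x$forward_primer)))
  cat(sprintf("  reverse primer: %s (Tm %.0f)\n", x$reverse_primer,
              wallace_tm(x$reverse_primer)))
  cat(sprintf("  amplicon: %d nt, %d CpGs, diagnostic CpG(s) %s\n",
              nchar(x$amplicon), length(x$cpg_sites),
              paste(x$diagnostic_cpgs, collapse = ",")))
  cat(sprintf("  fragments (methylated): %s\n",
              paste(x$predicted_fragments, collapse = " + ")))
  invisible(x)
}

#' @export
print.assay_failure <- function(x, ...) {
  cat(sprintf("assay design failed%s: %s\n",
              if (!is.na(x$element_id)) paste0(" for ", x$element_id) else "",
              x$reason))
  invisible(x)
}

#' Independently verify an emitted assay
#'
#' Re-checks every design constraint from the raw element and flank
#' sequences, without trusting any coordinate stored in the assay: primer
#' placement (forward inside the element, reverse inside the flank), primer
#' lengths and melting temperatures, amplicon span, presence of a
#' methylation-dependent site at least the minimum distance from both
#' primers, absence of undegenerated CpG cytosines in the primers, and
#' fragment-length conservation.
#'
#' @param assay A \code{cobra_assay}.
#' @param element,flank_down Sequences in assay orientation.
#' @param config The [assay_config()] the assay was designed under.
#' @return Character vector of violated constraints (empty when compliant).
#' @export
check_assay <- function(assay, element, flank_down, config = assay_config()) {
  bad <- character(0)
  el_len <- nchar(element)
  template <- paste0(element, flank_down)
  cpg_all <- .cpg_positions(template)
  conv <- bisulfite_convert(template, cpg_all)

  if (assay$forward_start < 1L || assay$forward_end > el_len)
    bad <- c(bad, "forward primer outside element")
  if (assay$reverse_start <= el_len || assay$reverse_end > nchar(template))
    bad <- c(bad, "reverse primer outside flank")
  for (p in list(c(assay$forward_start, assay$forward_end),
                 c(assay$reverse_start, assay$reverse_end))) {
    len <- p[2L] - p[1L] + 1L
    if (len < config$primer_length[1L] || len > config$primer_length[2L])
      bad <- c(bad, "primer length out of range")
  }
  fwd_plain <- substr(conv, assay$forward_start, assay$forward_end)
  rev_plain <- revcomp(substr(conv, assay$reverse_start, assay$reverse_end))
  if (gsub("Y", "C", assay$forward_primer) != fwd_plain ||
      gsub("R", "G", assay$reverse_primer) != rev_plain)
    bad <- c(bad, "primer does not match converted template")
  for (p in c(assay$forward_primer, assay$reverse_primer)) {
    tm <- wallace_tm(p)
    if (tm < config$tm_window[1L] || tm > config$tm_window[2L])
      bad <- c(bad, "primer Tm out of window")
    chars <- strsplit(p, "")[[1L]]
    cpos <- which(chars == "C" & c(chars[-1L], "") == "G")
    if (length(cpos)) bad <- c(bad, "undegenerated CpG cytosine in primer")
  }
  amp_len <- assay$reverse_end - assay$forward_start + 1L
  if (amp_len != nchar(assay$amplicon))
    bad <- c(bad, "amplicon length inconsistent")
  if (amp_len < config$amplicon_range[1L] || amp_len > config$amplicon_range[2L])
    bad <- c(bad, "amplicon length out of range")
  sites <- find_methylation_dependent_sites(
    substr(template, assay$forward_start, assay$reverse_end),
    config$recognition)
  sites <- sites[sites$dependent, , drop = FALSE]
  fwd_len <- assay$forward_end - assay$forward_start + 1L
  rev_len <- assay$reverse_end - assay$reverse_start + 1L
  ok_site <- sites$start > fwd_len + config$min_site_distance - 1L &
    sites$end <= amp_len - rev_len - config$min_site_distance + 1L
  if (!any(ok_site))
    bad <- c(bad, "no methylation-dependent site clear of both primers")
  if (sum(assay$predicted_fragments) != amp_len)
    bad <- c(bad, "fragments do not conserve amplicon length")
  bad
}

#' Write assays as TSV and primer FASTA
#'
#' @param assays List of \code{cobra_assay} objects.
#' @param tsv,fasta Optional output paths.
#' @return data.frame of assay metadata, invisibly when written.
#' @export
write_assays <- function(assays, tsv = NULL, fasta = NULL) {
  df <- data.frame(
    element_id = vapply(assays, `[[`, character(1L), "element_id"),
    forward_primer = vapply(assays, `[[`, character(1L), "forward_primer"),
    reverse_primer = vapply(assays, `[[`, character(1L), "reverse_primer"),
    amplicon_length = vapply(assays, function(a) nchar(a$amplicon), integer(1L)),
    cycles = vapply(assays, `[[`, integer(1L), "pcr_cycles"),
    temperature = vapply(assays, `[[`, numeric(1L), "anneal_temp"),
    fragments = vapply(assays, function(a)
      paste(a$predicted_fragments, collapse = ","), character(1L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    seqs <- c(stats::setNames(df$forward_primer, paste0(df$element_id, "_F")),
              stats::setNames(df$reverse_primer, paste0(df$element_id, "_R")))
    writeLines(paste0(">", names(seqs), "\n", seqs), fasta)
  }
  invisible(df)
}
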
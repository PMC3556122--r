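#' Extract an LTR element with flanking sequence
#'
#' Pulls the element sequence plus up to \code{flank} nt of flanking sequence
#' on each side from a genome. The element sequence is reported on its own
#' strand (reverse-complemented for \code{"-"} annotations) and the flanks are
#' given in element orientation: \code{flank_up} precedes the element 5' end,
#' \code{flank_down} follows its 3' end. Flanks shorter than \code{flank}
#' (contig edges) are flagged truncated.
#'
#' @param genome A named \code{DNAStringSet}, a named character vector of
#'   contig sequences, or a FASTA file path.
#' @param annotation A single-row \code{repeat_annotation} (or any list with
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}).
#' @param flank Flank length in nt (default 400, sized for primer design).
#' @return A list of class \code{"ltr_element"} with fields \code{id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{sequence},
#'   \code{flank_up}, \code{flank_down}, \code{flank_up_truncated},
#'   \code{flank_down_truncated}, \code{structure}.
#' @export
extract_with_flanks <- function(genome, annotation, flank = 400L) {
  contigs <- .as_contigs(genome)
  chrom <- as.character(annotation$chrom)
  if (!chrom %in% names(contigs))
    stop(sprintf("sequence '%s' not found in genome", chrom))
  contig <- contigs[[chrom]]
  clen <- nchar(contig)
  start <- as.integer(annotation$start)
  end <- as.integer(annotation$end)
  if (start < 1L || end > clen)
    stop(sprintf("annotation [%d,%d] exceeds contig '%s' bounds (1,%d)",
                 start, end, chrom, clen))

  seq_fwd <- substr(contig, start, end)
  left <- substr(contig, max(1L, start - flank), start - 1L)
  right <- substr(contig, end + 1L, min(clen, end + flank))

  strand <- as.character(annotation$strand)
  if (strand == "-") {
    sequence <- revcomp(seq_fwd)
    flank_up <- revcomp(right)
    flank_down <- revcomp(left)
  } else {
    sequence <- seq_fwd
    flank_up <- left
    flank_down <- right
  }
  structure(list(
    id = if (!is.null(annotation$id)) annotation$id else NA_character_,
    chrom = chrom, start = start, end = end, strand = strand,
    sequence = sequence, flank_up = flank_up, flank_down = flank_down,
    flank_up_truncated = nchar(flank_up) < flank,
    flank_down_truncated = nchar(flank_down) < flank,
    structure = "solo_ltr", clade = NA_character_
  ), class = "ltr_element")
}

#' Build an element catalog from annotations
#'
#' Runs [extract_with_flanks()] over a set of annotations and assigns stable
#' unique identifiers \code{IAP1, IAP2, ...} in input order.
#'
#' @inheritParams extract_with_flanks
#' @param annotations A \code{repeat_annotation} data.frame.
#' @param id_prefix Identifier prefix (default \code{"IAP"}).
#' @return A list of \code{ltr_element} objects of class \code{"ltr_catalog"}.
#' @export
build_catalog <- function(genome, annotations, flank = 400L, id_prefix = "IAP") {
  contigs <- .as_contigs(genome)
  elements <- lapply(seq_len(nrow(annotations)), function(i) {
    el <- extract_with_flanks(contigs, annotations[i, ], flank = flank)
    el$id <- paste0(id_prefix, i)
    el
  })
  structure(elements, class = "ltr_catalog")
}

#' @export
print.ltr_catalog <- function(x, ...) {
  cat(sprintf("LTR element catalog: %d elements\n", length(x)))
  tab <- table(vapply(x, `[[`, character(1L), "structure"))
  for (nm in names(tab)) cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Catalog as a data.frame
#'
#' @param x An \code{ltr_catalog}.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return data.frame with one row per element (sequences included).
#' @export
as.data.frame.ltr_catalog <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    id = vapply(x, `[[`, character(1L), "id"),
    chrom = vapply(x, `[[`, character(1L), "chrom"),
    start = vapply(x, `[[`, integer(1L), "start"),
    end = vapply(x, `[[`, integer(1L), "end"),
    strand = vapply(x, `[[`, character(1L), "strand"),
    structure = vapply(x, `[[`, character(1L), "structure"),
    clade = vapply(x, `[[`, character(1L), "clade"),
    sequence = vapply(x, `[[`, character(1L), "sequence"),
    flank_up = vapply(x, `[[`, character(1L), "flank_up"),
    flank_down = vapply(x, `[[`, character(1L), "flank_down"),
    stringsAsFactors = FALSE
  )
}

#' Assign paired / solo structure to catalog elements
#'
#' Two same-strand, same-chromosome elements whose inner gap (the distance
#' between the first element's end and the second's start, minus 1) lies in
#' \code{[min_gap, max_gap]} are marked as the 5' and 3' LTRs of one
#' full-length insertion; all remaining elements are solo LTRs. Pairing is
#' greedy left-to-right along each chromosome with nearest-neighbour
#' preference (ties broken by the smaller gap), and each element joins at
#' most one pair. The default window spans the bodies of both the truncated
#' 5.4 kb and full-length 7.2 kb IAP forms.
#'
#' @param catalog An \code{ltr_catalog} (elements need not be sorted).
#' @param min_gap,max_gap Inner gap window in nt (defaults 3000 and 8000).
#' @return The catalog with \code{structure} set to \code{"five_prime_of_pair"},
#'   \code{"three_prime_of_pair"} or \code{"solo_ltr"}.
#' @export
pair_ltrs <- function(catalog, min_gap = 3000L, max_gap = 8000L) {
  df <- as.data.frame(catalog)
  ord <- order(df$chrom, df$start)
  paired <- rep(NA_integer_, length(catalog))  # index of partner
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!is.na(paired[i])) next
    best <- NA_integer_; best_gap <- Inf
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (!is.na(paired[j])) next
      if (df$chrom[j] != df$chrom[i]) break
      gap <- df$start[j] - df$end[i] - 1L
      if (gap > max_gap) break
      if (df$strand[j] != df$strand[i] || gap < min_gap) next
      if (gap < best_gap) { best <- j; best_gap <- gap }
    }
    if (!is.na(best)) { paired[i] <- best; paired[best] <- i }
  }
  for (i in seq_along(catalog)) {
    if (is.na(paired[i])) {
      catalog[[i]]$structure <- "solo_ltr"
    } else {
      j <- paired[i]
      # genomic left member is the 5' LTR on "+", the 3' LTR on "-"
      left <- df$start[i] < df$start[j]
      plus <- df$strand[i] == "+"
      catalog[[i]]$structure <- if (left == plus) "five_prime_of_pair" else "three_prime_of_pair"
    }
  }
  catalog
}

#' Naive consensus-matching genome scanner
#'
#' Locates approximate copies of a consensus sequence on both strands by
#' counting mismatches at every offset (no indels). Intended for synthetic
#' genomes whose planted copies diverge from the consensus by substitutions
#' only; it is not a general-purpose repeat finder. Overlapping hits are
#' resolved by keeping the lowest-mismatch hit in each overlap group.
#'
#' @param genome Named contig sequences (see [extract_with_flanks()]).
#' @param consensus Consensus sequence (character).
#' @param max_divergence Maximum mismatch fraction to report (default 0.2).
#' @param repeat_name,repeat_class Annotation labels applied to every hit.
#' @return A \code{repeat_annotation} data.frame; \code{percent_div} is the
#'   observed mismatch percentage against the consensus.
#' @export
scan_genome <- function(genome, consensus, max_divergence = 0.2,
                        repeat_name = "IAPLTR1_Mm", repeat_class = "LTR/ERVK") {
  contigs <- .as_contigs(genome)
  L <- nchar(consensus)
  max_mm <- floor(max_divergence * L)
  pat_f <- Biostrings::DNAString(consensus)
  pat_r <- Biostrings::reverseComplement(pat_f)
  rows <- list()
  for (chrom in names(contigs)) {
    subj <- Biostrings::DNAString(contigs[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
      if (length(hits) == 0L) next
      mm <- Biostrings::neditEndingAt(pat, subj,
                                      ending.at = IRanges::end(hits),
                                      with.indels = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = IRanges::start(hits),
        end = IRanges::end(hits), strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_annotation())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$chrom, hits$start, hits$mismatches), , drop = FALSE]
  # suppress overlapping shifted self-matches: keep best hit per overlap group
  keep <- logical(nrow(hits))
  last_end <- -1L; last_chrom <- ""; last_i <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$chrom[i] != last_chrom || hits$start[i] > last_end) {
      keep[i] <- TRUE; last_i <- i
      last_chrom <- hits$chrom[i]; last_end <- hits$end[i]
    } else if (hits$mismatches[i] < hits$mismatches[last_i]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE; last_i <- i
      last_end <- max(last_end, hits$end[i])
    }
  }
  hits <- hits[keep, , drop = FALSE]
  ann <- data.frame(
    score = as.integer(round((L - hits$mismatches) * 5)),
    percent_div = round(100 * hits$mismatches / L, 1),
    chrom = hits$chrom, start = hits$start, end = hits$end,
    strand = hits$strand, repeat_name = repeat_name,
    repeat_class = repeat_class, stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  class(ann) <- c("repeat_annotation", "data.frame")
  ann
}

#' Write a catalog to TSV and FASTA
#'
#' @param catalog An \code{ltr_catalog}.
#' @param tsv,fasta Optional output paths. The TSV holds id, coordinates,
#'   strand and structure; the FASTA holds element and flank sequences
#'   (\code{<id>}, \code{<id>_flank_up}, \code{<id>_flank_down}).
#' @return The catalog data.frame, invisibly.
#' @export
write_catalog <- function(catalog, tsv = NULL, fasta = NULL) {
  df <- as.data.frame(catalog)
  if (!is.null(tsv)) {
    utils::write.table(
      df[, c("id", "chrom", "start", "end", "strand", "structure", "clade")],
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    seqs <- c(stats::setNames(df$sequence, df$id),
              stats::setNames(df$flank_up, paste0(df$id, "_flank_up")),
              stats::setNames(df$flank_down, paste0(df$id, "_flank_down")))
    seqs <- seqs[nzchar(seqs)]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  invisible(df)
}

#' Reverse complement of a character DNA sequence
#'
#' @param x Character scalar over A/C/G/T/N (case preserved as upper).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.as_contigs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("\n", genome)) {
    set <- Biostrings::readDNAStringSet(genome)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
    return(seqs)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome contigs must be named")
    return(genome)
  }
  stop("unsupported genome representation")
}
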
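#' In-silico bisulfite conversion
#'
#' Converts every unmethylated cytosine to thymine (the PCR read-out of
#' uracil); cytosines at methylated CpG positions are protected. Only CpG
#' cytosines can be marked methylated — non-CpG cytosines always convert.
#'
#' @param sequence Character DNA sequence over \code{A,C,G,T,N}.
#' @param methylated Integer vector of 1-based positions of methylated CpG
#'   cytosines (each must be a \code{C} immediately followed by \code{G}).
#' @return Converted sequence (same length).
#' @examples
#' bisulfite_convert("ACGGCG")            # "ATGGTG"
#' bisulfite_convert("ACGGCG", c(2, 5))   # "ACGGCG"
#' @export
bisulfite_convert <- function(sequence, methylated = integer(0)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (length(methylated)) {
    methylated <- as.integer(methylated)
    bad <- methylated < 1L | methylated > length(chars) |
      chars[methylated] != "C" |
      c(chars, "")[methylated + 1L] != "G"
    if (any(bad))
      stop(sprintf("position %d is not a CpG cytosine", methylated[bad][1L]))
  }
  is_c <- chars == "C"
  is_c[methylated] <- FALSE
  chars[is_c] <- "T"
  paste(chars, collapse = "")
}

#' Find methylation-dependent restriction sites
#'
#' Scans the assayed strand for a recognition string (default \code{ACGGCG},
#' the two-CpG site used for CoBRA with BceAI) and reports, per occurrence,
#' the CpG cytosine positions inside the site. A site is methylation
#' dependent when every cytosine in the recognition string is in CpG context
#' (the G may fall just outside the site): then the site survives bisulfite
#' conversion if and only if all of its CpGs are methylated.
#'
#' @param sequence Character DNA sequence.
#' @param recognition Recognition string (default \code{"ACGGCG"}).
#' @return data.frame with columns \code{start}, \code{end} (1-based site
#'   span), \code{dependent} (logical) and list-column \code{cpg_positions}.
#' @export
find_methylation_dependent_sites <- function(sequence, recognition = "ACGGCG") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  nxt <- c(chars[-1L], "")
  hits <- Biostrings::matchPattern(recognition,
                                   Biostrings::DNAString(sequence))
  starts <- IRanges::start(hits)
  w <- nchar(recognition)
  cpg <- vector("list", length(starts))
  dependent <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + w - 1L)
    cs <- idx[chars[idx] == "C"]
    cpg[[i]] <- cs[nxt[cs] == "G"]
    dependent[i] <- length(cs) > 0L && all(nxt[cs] == "G")
  }
  out <- data.frame(start = starts, end = starts + w - 1L,
                    dependent = dependent)
  out$cpg_positions <- cpg
  out
}

#' Predict restriction fragments of a converted amplicon
#'
#' Bisulfite-converts the amplicon under the given methylation state, then
#' cuts at every recognition site that survived conversion. The cut point is
#' \code{cut_offset} nt downstream of the site's 3' end (single-strand
#' fragment model; only fragment sizes matter for band identity). A site
#' survives iff all of its CpGs were methylated, so a fully unmethylated
#' template yields a single full-length fragment.
#'
#' @param amplicon Character DNA sequence (unconverted, assayed strand).
#' @param methylated 1-based methylated CpG cytosine positions.
#' @param recognition Recognition string (default \code{"ACGGCG"}).
#' @param cut_offset Cut distance downstream of the site 3' end (default 12).
#' @return Integer vector of ordered fragment lengths (sums to
#'   \code{nchar(amplicon)}).
#' @export
in_silico_digest <- function(amplicon, methylated = integer(0),
                             recognition = "ACGGCG", cut_offset = 12L) {
  n <- nchar(amplicon)
  converted <- bisulfite_convert(amplicon, methylated)
  hits <- Biostrings::matchPattern(recognition, Biostrings::DNAString(converted))
  cuts <- IRanges::end(hits) + cut_offset
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  diff(c(0L, cuts, n))
}
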
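#' Parse RepeatMasker annotation output
#'
#' Reads the whitespace-delimited RepeatMasker \code{.out} dialect: a
#' three-line header (two column-name lines and a blank line) followed by one
#' record per repeat hit. Coordinates are kept 1-based inclusive, as printed;
#' the complementary-strand code \code{"C"} is mapped to \code{"-"}.
#'
#' @param file Path to a \code{.out} file, or a character vector of lines
#'   (treated as the file content when it has more than one element or
#'   contains a newline).
#' @return A data.frame of class \code{"repeat_annotation"} with columns
#'   \code{score}, \code{percent_div}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{repeat_name}, \code{repeat_class}.
#' @examples
#' lines <- c(rep("", 3),
#'   "239 1.8 0.0 0.0 chr1 1001 1337 (100000) + IAPLTR1_Mm LTR/ERVK 1 337 (0) 1")
#' parse_repeatmasker_out(lines)
#' @export
parse_repeatmasker_out <- function(file) {
  lines <- .as_lines(file)
  if (length(lines) < 3L)
    stop("malformed RepeatMasker output: expected a 3-line header")
  body <- lines[-(1:3)]
  body_ln <- seq_along(body) + 3L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_ln <- body_ln[keep]
  if (length(body) == 0L) return(.empty_annotation())

  fields <- strsplit(trimws(body), "[ \t]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 11L)
  if (length(bad))
    stop(sprintf("malformed RepeatMasker record at line %d: %d fields (>= 11 expected)",
                 body_ln[bad[1L]], n_fields[bad[1L]]))

  get <- function(i) vapply(fields, `[[`, character(1L), i)
  start <- suppressWarnings(as.integer(get(6L)))
  end   <- suppressWarnings(as.integer(get(7L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("non-integer coordinates in RepeatMasker record at line %d",
                 body_ln[bad[1L]]))
  strand <- get(9L)
  ok <- strand %in% c("+", "C", "-")
  if (!all(ok))
    stop(sprintf("unrecognised strand code '%s' at line %d",
                 strand[!ok][1L], body_ln[!ok][1L]))
  strand[strand == "C"] <- "-"

  ann <- data.frame(
    score        = suppressWarnings(as.integer(get(1L))),
    percent_div  = suppressWarnings(as.numeric(get(2L))),
    chrom        = get(5L),
    start        = start,
    end          = end,
    strand       = strand,
    repeat_name  = get(10L),
    repeat_class = get(11L),
    stringsAsFactors = FALSE
  )
  if (any(ann$start < 1L) || any(ann$end < ann$start))
    stop("invalid coordinates: need start >= 1 and end >= start")
  class(ann) <- c("repeat_annotation", "data.frame")
  ann
}

#' Write annotations back to the RepeatMasker .out dialect
#'
#' Inverse of [parse_repeatmasker_out()]: emits the 3-line header and one
#' whitespace-delimited record per annotation, with strand \code{"-"} written
#' as \code{"C"}. Round-tripping preserves all parsed fields.
#'
#' @param annotations A \code{repeat_annotation} data.frame.
#' @param file Optional path; if \code{NULL} the lines are returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, file = NULL) {
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  strand <- ifelse(annotations$strand == "-", "C", "+")
  len <- annotations$end - annotations$start + 1L
  recs <- sprintf("%d %.1f 0.0 0.0 %s %d %d (0) %s %s %s 1 %d (0) %d",
                  annotations$score, annotations$percent_div,
                  annotations$chrom, annotations$start, annotations$end,
                  strand, annotations$repeat_name, annotations$repeat_class,
                  len, seq_len(nrow(annotations)))
  out <- c(header, recs)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Filter a repeat catalog by subtype, length and chromosome
#'
#' Applies the catalog-reduction step used when narrowing a genome-wide
#' repeat scan to a single LTR subtype: keep records whose repeat name equals
#' \code{subtype_name}, whose span is at least \code{min_length} nt, and whose
#' sequence name is an allowed (chromosomal) one. Removal counts per criterion
#' are attached as attribute \code{"removed"}.
#'
#' @param annotations A \code{repeat_annotation} data.frame.
#' @param subtype_name Repeat name to keep, e.g. \code{"IAPLTR1_Mm"}.
#' @param min_length Minimum element span in nt (default 330).
#' @param allowed_chroms Character vector of allowed sequence names, or
#'   \code{NULL} to accept any name not matching \code{"random"} or
#'   \code{"Un"} (unplaced-contig conventions).
#' @return Filtered \code{repeat_annotation} (input order preserved) with
#'   attribute \code{removed = c(subtype=, short=, unmapped=)}.
#' @export
filter_subtype <- function(annotations, subtype_name, min_length = 330L,
                           allowed_chroms = NULL) {
  stopifnot(min_length >= 0L)
  is_subtype <- annotations$repeat_name == subtype_name
  long_enough <- (annotations$end - annotations$start + 1L) >= min_length
  if (is.null(allowed_chroms)) {
    mapped <- !grepl("random|Un", annotations$chrom)
  } else {
    mapped <- annotations$chrom %in% allowed_chroms
  }
  # removal reasons counted hierarchically: subtype first, then length, then mapping
  removed <- c(
    subtype  = sum(!is_subtype),
    short    = sum(is_subtype & !long_enough),
    unmapped = sum(is_subtype & long_enough & !mapped)
  )
  out <- annotations[is_subtype & long_enough & mapped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  class(out) <- c("repeat_annotation", "data.frame")
  out
}

#' Count sense and antisense annotations
#'
#' @param annotations A \code{repeat_annotation} data.frame.
#' @return Named integer vector \code{c(sense=, antisense=)}.
#' @export
strand_census <- function(annotations) {
  c(sense = sum(annotations$strand == "+"),
    antisense = sum(annotations$strand == "-"))
}

#' Export annotations as BED6 intervals
#'
#' Converts the 1-based inclusive annotation coordinates to BED's 0-based
#' half-open convention (\code{chromStart = start - 1}, \code{chromEnd = end}).
#'
#' @param annotations A \code{repeat_annotation} data.frame.
#' @param names Optional feature names; defaults to the repeat names.
#' @param file Optional path to write a BED file.
#' @return data.frame with BED6 columns, invisibly if written to file.
#' @export
as_bed <- function(annotations, names = NULL, file = NULL) {
  bed <- data.frame(
    chrom = annotations$chrom,
    chromStart = annotations$start - 1L,
    chromEnd = annotations$end,
    name = if (is.null(names)) annotations$repeat_name else names,
    score = annotations$score,
    strand = annotations$strand,
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(bed, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

.as_lines <- function(x) {
  if (length(x) == 1L) {
    if (!grepl("\n", x) && file.exists(x)) return(readLines(x))
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  x
}

.empty_annotation <- function() {
  ann <- data.frame(score = integer(), percent_div = numeric(),
                    chrom = character(), start = integer(), end = integer(),
                    strand = character(), repeat_name = character(),
                    repeat_class = character(), stringsAsFactors = FALSE)
  class(ann) <- c("repeat_annotation", "data.frame")
  ann
}
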
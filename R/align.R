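#' Global pairwise identity over shared sequence
#'
#' Aligns two sequences globally with affine gap costs (default: match +5 /
#' mismatch -4, the standard 65\%-target-identity nucleotide matrix, gap open
#' 12, gap extension 3) and reports the fraction of identical columns over
#' the length of shared sequence, i.e. excluding columns where either row
#' carries a terminal gap.
#'
#' @param seq_a,seq_b Character DNA sequences (non-empty).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Identity fraction in \code{[0, 1]}.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")   # 1
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 5, mismatch = -4,
                              gap_open = 12, gap_extend = 3) {
  al <- .align_pair(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
  .identity_shared(al$a, al$b)
}

.align_pair <- function(seq_a, seq_b, match = 5, mismatch = -4,
                        gap_open = 12, gap_extend = 3) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  mat <- .nuc_matrix(match, mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

.nuc_matrix <- function(match, mismatch) {
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- match
  mat["N", ] <- 0; mat[, "N"] <- 0
  mat
}

# identity over columns excluding terminal gaps in either row
.identity_shared <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  res_a <- which(ca != "-"); res_b <- which(cb != "-")
  lo <- max(res_a[1L], res_b[1L])
  hi <- min(res_a[length(res_a)], res_b[length(res_b)])
  if (hi < lo) return(0)
  idx <- lo:hi
  sum(ca[idx] == cb[idx]) / length(idx)
}

#' Consensus-anchored star alignment
#'
#' Builds a multiple alignment by aligning every element pairwise to the
#' family consensus and merging the pairwise alignments on consensus
#' coordinates. Insertions relative to the consensus open gap columns that
#' all other rows (and the consensus row) are padded through. Elements whose
#' pairwise identity to the consensus (over shared sequence) falls below
#' \code{drop_threshold} are excluded and reported in attribute
#' \code{"dropped"}. This is a deterministic stand-in for a progressive MSA,
#' adequate for intra-family LTR alignment where all members are orthologous
#' to one consensus.
#'
#' @param elements Named character vector of element sequences, an
#'   \code{ltr_catalog}, or a \code{DNAStringSet}.
#' @param consensus Consensus sequence (character, non-empty).
#' @param drop_threshold Minimum identity to the consensus (default 0.50).
#' @inheritParams pairwise_identity
#' @return Object of class \code{"ltr_alignment"}: a list with \code{names},
#'   \code{rows} (character matrix, one row per element, single-character
#'   columns over \code{A,C,G,T,N,-}), and \code{consensus_row}.
#' @export
star_align_to_consensus <- function(elements, consensus, drop_threshold = 0.5,
                                    match = 5, mismatch = -4,
                                    gap_open = 12, gap_extend = 3) {
  if (!nzchar(consensus)) stop("consensus must be non-empty")
  seqs <- .as_seqvec(elements)
  L <- nchar(consensus)
  cons_chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]

  per <- vector("list", length(seqs))
  dropped <- character(0)
  for (i in seq_along(seqs)) {
    al <- .align_pair(seqs[[i]], consensus, match, mismatch, gap_open, gap_extend)
    if (.identity_shared(al$a, al$b) < drop_threshold) {
      dropped <- c(dropped, names(seqs)[i]); per[i] <- list(NULL); next
    }
    ea <- strsplit(al$a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(al$b, "", fixed = TRUE)[[1L]]
    # residue (or gap) opposite each consensus position; insertions keyed by
    # the consensus position they follow (0 = before the first)
    res <- character(L)
    ins <- vector("list", L + 1L)
    j <- 0L
    for (k in seq_along(cb)) {
      if (cb[k] == "-") {
        ins[[j + 1L]] <- c(ins[[j + 1L]], ea[k])
      } else {
        j <- j + 1L
        res[j] <- ea[k]
      }
    }
    per[[i]] <- list(res = res, ins = ins)
  }
  keep <- !vapply(per, is.null, logical(1L))
  per <- per[keep]
  kept_names <- names(seqs)[keep]

  ins_len <- integer(L + 1L)
  for (p in per) {
    il <- lengths(p$ins)
    ins_len <- pmax(ins_len, il)
  }
  width <- L + sum(ins_len)
  n <- length(per)
  rows <- matrix("-", nrow = n, ncol = width,
                 dimnames = list(kept_names, NULL))
  cons_row <- character(width)
  col <- 0L
  col_map <- integer(L)  # merged column of each consensus position
  for (j in 0:L) {
    if (ins_len[j + 1L] > 0L) {
      block <- col + seq_len(ins_len[j + 1L])
      cons_row[block] <- "-"
      for (i in seq_len(n)) {
        v <- per[[i]]$ins[[j + 1L]]
        if (length(v)) rows[i, col + seq_along(v)] <- v
      }
      col <- col + ins_len[j + 1L]
    }
    if (j < L) {
      col <- col + 1L
      col_map[j + 1L] <- col
      cons_row[col] <- cons_chars[j + 1L]
      for (i in seq_len(n)) rows[i, col] <- per[[i]]$res[j + 1L]
    }
  }
  structure(list(names = kept_names, rows = rows, consensus_row = cons_row),
            dropped = dropped, class = "ltr_alignment")
}

#' @export
print.ltr_alignment <- function(x, ...) {
  cat(sprintf("LTR alignment: %d sequences x %d columns\n",
              nrow(x$rows), ncol(x$rows)))
  dr <- attr(x, "dropped")
  if (length(dr)) cat(sprintf("  dropped (below identity threshold): %s\n",
                              paste(dr, collapse = ", ")))
  invisible(x)
}

#' Observed-proportion (p) distance matrix
#'
#' For each pair of alignment rows, the proportion of differing sites among
#' compared columns; columns holding a gap or \code{N} in either row are
#' skipped. A pair with zero compared columns is an error.
#'
#' @param alignment An \code{ltr_alignment}.
#' @return Symmetric numeric matrix of p-distances (zero diagonal).
#' @export
p_distance <- function(alignment) {
  rows <- alignment$rows
  n <- nrow(rows)
  valid <- rows != "-" & rows != "N"
  p <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  if (n < 2L) return(p)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    m <- sum(ok)
    if (m == 0L)
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   rownames(rows)[i], rownames(rows)[j]))
    p[i, j] <- p[j, i] <- sum(rows[i, ok] != rows[j, ok]) / m
  }
  p
}

# p-distance of each row to the consensus row
.p_to_consensus <- function(alignment) {
  rows <- alignment$rows
  cons <- alignment$consensus_row
  ok_c <- cons != "-" & cons != "N"
  vapply(seq_len(nrow(rows)), function(i) {
    ok <- ok_c & rows[i, ] != "-" & rows[i, ] != "N"
    if (!any(ok)) stop("no comparable columns against consensus")
    sum(rows[i, ok] != cons[ok]) / sum(ok)
  }, numeric(1L)) |> stats::setNames(rownames(rows))
}

.as_seqvec <- function(elements) {
  if (inherits(elements, "ltr_catalog")) {
    df <- as.data.frame(elements)
    return(stats::setNames(as.list(df$sequence), df$id))
  }
  if (methods::is(elements, "DNAStringSet")) {
    return(stats::setNames(as.list(as.character(elements)), names(elements)))
  }
  if (is.character(elements)) {
    if (is.null(names(elements)))
      names(elements) <- paste0("seq", seq_along(elements))
    return(as.list(elements))
  }
  if (is.list(elements)) return(elements)
  stop("unsupported element container")
}
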
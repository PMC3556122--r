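#' Percent methylation from band intensities
#'
#' Uncut bands correspond to unmethylated template and cut bands to
#' methylated template, so \code{M = 100 * I_cut / (I_cut + I_uncut)}.
#' Scale invariant: multiplying both intensities by any positive constant
#' leaves M unchanged.
#'
#' @param i_cut,i_uncut Non-negative band intensities (vectorised); cut-band
#'   intensity should already be summed over sub-fragment bands.
#' @param digits Rounding of the reported value; \code{NULL} to return the
#'   unrounded value (default 0, matching integer gel read-outs).
#' @return Percent methylation in \code{[0, 100]}; \code{NA} where the total
#'   intensity is zero.
#' @export
percent_methylation <- function(i_cut, i_uncut, digits = 0L) {
  if (any(i_cut < 0, na.rm = TRUE) || any(i_uncut < 0, na.rm = TRUE))
    stop("band intensities must be non-negative")
  total <- i_cut + i_uncut
  m <- ifelse(total > 0, 100 * i_cut / total, NA_real_)
  if (!is.null(digits)) m <- round(m, digits)
  m
}

#' Aggregate gel lanes into per-(mouse, locus) quantitations
#'
#' Collapses a long band table (columns \code{mouse_id}, \code{locus_id},
#' \code{band_role}, \code{intensity}) into one row per lane: the uncut-band
#' intensity and the summed cut-band intensity. Band roles beginning with
#' \code{"cut"} are cut sub-fragments; \code{"uncut"} is the top band.
#' Control lanes are any whose \code{mouse_id} starts with \code{"control"}.
#'
#' @param bands data.frame of band intensities (or a TSV path).
#' @return data.frame with \code{mouse_id}, \code{locus_id}, \code{i_uncut},
#'   \code{i_cut}, \code{flag} (\code{"ok"} or \code{"control"}).
#' @export
quantify_lanes <- function(bands) {
  if (is.character(bands) && length(bands) == 1L)
    bands <- utils::read.delim(bands, stringsAsFactors = FALSE)
  need <- c("mouse_id", "locus_id", "band_role", "intensity")
  if (!all(need %in% names(bands)))
    stop("bands need columns: ", paste(need, collapse = ", "))
  key <- interaction(bands$mouse_id, bands$locus_id, drop = TRUE)
  rows <- lapply(split(bands, key), function(g) {
    data.frame(
      mouse_id = g$mouse_id[1L], locus_id = g$locus_id[1L],
      i_uncut = sum(g$intensity[g$band_role == "uncut"]),
      i_cut = sum(g$intensity[startsWith(g$band_role, "cut")]),
      flag = if (startsWith(g$mouse_id[1L], "control")) "control" else "ok",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag lanes below the limit of detection
#'
#' Lanes whose uncut (top) band is too faint for detection are below the
#' limit of detection and are excluded from the methylation matrix.
#'
#' @param lanes Lane quantitations from [quantify_lanes()].
#' @param min_band_intensity LOD threshold on the uncut-band intensity.
#' @return \code{lanes} with \code{flag} set to \code{"below_lod"} where the
#'   uncut band falls under the threshold (controls are never flagged).
#' @export
apply_lod <- function(lanes, min_band_intensity) {
  low <- lanes$i_uncut < min_band_intensity & lanes$flag != "control"
  lanes$flag[low] <- "below_lod"
  lanes
}

#' Validate digestion control lanes
#'
#' The unmethylated (0\%) control must remain essentially uncut and the
#' high-methylation control essentially fully digested at every locus;
#' failures indicate incomplete conversion or nonspecific digestion.
#'
#' @param lanes Lane quantitations including control lanes whose
#'   \code{mouse_id} is \code{"control_zero"} / \code{"control_high"}.
#' @param tol_zero Maximum percent methylation for the 0\% control (default 5).
#' @param tol_high Minimum percent methylation for the high control (default 90).
#' @return data.frame per (locus, control) with \code{m}, \code{pass},
#'   \code{message}; attribute \code{"pass"} is the overall verdict.
#' @export
validate_controls <- function(lanes, tol_zero = 5, tol_high = 90) {
  ctrl <- lanes[lanes$flag == "control", , drop = FALSE]
  loci <- unique(lanes$locus_id[lanes$flag != "control"])
  if (length(loci) == 0L) loci <- unique(ctrl$locus_id)
  rows <- list()
  for (locus in loci) {
    for (ctl in c("control_zero", "control_high")) {
      hit <- ctrl$locus_id == locus & ctrl$mouse_id == ctl
      if (!any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locus, control = ctl, m = NA_real_, pass = FALSE,
          message = "control absent", stringsAsFactors = FALSE)
        next
      }
      g <- ctrl[hit, ][1L, ]
      m <- percent_methylation(g$i_cut, g$i_uncut, digits = NULL)
      ok <- if (ctl == "control_zero") !is.na(m) && m <= tol_zero
            else !is.na(m) && m >= tol_high
      msg <- if (ok) "ok"
        else if (ctl == "control_zero")
          "incomplete-conversion/nonspecific digestion suspected"
        else "incomplete digestion suspected"
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = locus, control = ctl, m = m, pass = ok, message = msg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pass") <- all(out$pass)
  out
}

#' Assemble the mice-by-loci methylation matrix
#'
#' Builds a \code{methylation_table} from lane quantitations: one cell per
#' (mouse, locus); duplicate lanes are an error; lanes flagged below the
#' limit of detection are masked, as are structurally absent cells (a
#' Y-linked locus in female animals). Values are stored unrounded; rounding
#' happens at the presentation layer.
#'
#' @param lanes Lane quantitations (controls are ignored here).
#' @param clade_map Optional named vector locus -> clade label, or a
#'   data.frame with columns \code{locus} and \code{clade}.
#' @param sex Optional named vector mouse -> \code{"M"}/\code{"F"}.
#' @param y_linked Character vector of Y-linked loci (masked in females).
#' @return A \code{"methylation_table"}: list with numeric matrix \code{M}
#'   (mice x loci, \code{NA} where masked), character matrix \code{mask}
#'   (\code{""}, \code{"lod"} or \code{"absent"}), \code{clade}, \code{sex}.
#' @export
assemble_table <- function(lanes, clade_map = NULL, sex = NULL,
                           y_linked = character(0)) {
  data <- lanes[lanes$flag != "control", , drop = FALSE]
  if (nrow(data) == 0L)
    return(methylation_table(matrix(numeric(0), 0, 0)))
  dup <- duplicated(data[c("mouse_id", "locus_id")])
  if (any(dup))
    stop(sprintf("duplicate lane for (%s, %s)",
                 data$mouse_id[dup][1L], data$locus_id[dup][1L]))
  mice <- unique(data$mouse_id)
  loci <- unique(data$locus_id)
  M <- matrix(NA_real_, length(mice), length(loci),
              dimnames = list(mice, loci))
  mask <- matrix("absent", length(mice), length(loci),
                 dimnames = list(mice, loci))
  m_val <- percent_methylation(data$i_cut, data$i_uncut, digits = NULL)
  for (r in seq_len(nrow(data))) {
    i <- data$mouse_id[r]; j <- data$locus_id[r]
    if (data$flag[r] == "below_lod" || is.na(m_val[r])) {
      mask[i, j] <- "lod"
    } else {
      M[i, j] <- m_val[r]
      mask[i, j] <- ""
    }
  }
  if (length(y_linked) && !is.null(sex)) {
    for (j in intersect(y_linked, loci)) {
      females <- mice[sex[mice] == "F"]
      M[females, j] <- NA_real_
      mask[females, j] <- "absent"
    }
  }
  methylation_table(M, mask = mask, clade = clade_map, sex = sex)
}

#' Construct a methylation table
#'
#' @param M Numeric mice x loci matrix of percent methylation (\code{NA}
#'   at masked cells), with dimnames.
#' @param mask Optional character matrix of mask reasons (\code{""} =
#'   present, \code{"lod"}, \code{"absent"}); derived from \code{NA}s when
#'   missing.
#' @param clade Optional locus -> clade mapping (named vector or data.frame
#'   with columns \code{locus}, \code{clade}).
#' @param sex Optional mouse -> sex mapping.
#' @return A \code{"methylation_table"} object.
#' @export
methylation_table <- function(M, mask = NULL, clade = NULL, sex = NULL) {
  M <- as.matrix(M)
  if (is.null(mask)) {
    mask <- matrix(ifelse(is.na(M), "lod", ""), nrow(M), ncol(M),
                   dimnames = dimnames(M))
  }
  if (!is.null(clade) && is.data.frame(clade))
    clade <- stats::setNames(as.character(clade$clade), clade$locus)
  if (any(M < 0 | M > 100, na.rm = TRUE))
    stop("methylation values must lie in [0, 100]")
  stopifnot(all(is.na(M) == (mask != "")))
  structure(list(M = M, mask = mask,
                 clade = if (is.null(clade)) NULL else clade[colnames(M)],
                 sex = sex),
            class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat(sprintf("Methylation table: %d mice x %d loci (%d masked cells)\n",
              nrow(x$M), ncol(x$M), sum(x$mask != "")))
  if (!is.null(x$clade))
    cat("  clades:", paste(sprintf("%s=%d", names(table(x$clade)),
                                   table(x$clade)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.methylation_table <- function(object, ...) {
  cat(sprintf("Grand mean methylation: %.1f%%\n", grand_mean(object)))
  ls <- locus_summaries(object)
  cat(sprintf("Locus means: %.0f%% (min) to %.0f%% (max); ranges %d-%d%%\n",
              min(ls$mean), max(ls$mean), min(ls$range), max(ls$range)))
  invisible(locus_summaries(object))
}

#' Write / read a methylation table as wide TSV
#'
#' The wide layout mirrors a quantitated gel report: one row per mouse, one
#' column per locus, \code{LOD} marking below-detection lanes and an empty
#' cell marking structurally absent ones; an optional \code{sex} column is
#' preserved. Round trip through [read_methylation_table()] is the identity,
#' including the mask.
#'
#' @param table A \code{methylation_table}.
#' @param file Output TSV path.
#' @param digits Cell rounding; \code{NA} writes full precision.
#' @export
write_methylation_table <- function(table, file, digits = NA) {
  M <- table$M
  fmt <- function(v) ifelse(is.na(v), "",
                            if (is.na(digits)) format(v, digits = 15)
                            else as.character(round(v, digits)))
  cells <- matrix(fmt(M), nrow(M), ncol(M), dimnames = dimnames(M))
  cells[table$mask == "lod"] <- "LOD"
  df <- data.frame(mouse = rownames(M), stringsAsFactors = FALSE)
  if (!is.null(table$sex)) df$sex <- unname(table$sex[rownames(M)])
  df <- cbind(df, as.data.frame(cells, stringsAsFactors = FALSE))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_methylation_table
#' @param clade_file Optional TSV with columns \code{locus}, \code{clade}
#'   (and optionally \code{y_linked}) attaching a clade map on read.
#' @export
read_methylation_table <- function(file, clade_file = NULL) {
  df <- utils::read.delim(file, check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  sex <- NULL
  if ("sex" %in% names(df)) {
    sex <- stats::setNames(df$sex, df$mouse)
    df$sex <- NULL
  }
  loci <- setdiff(names(df), "mouse")
  cells <- as.matrix(df[loci])
  rownames(cells) <- df$mouse
  M <- suppressWarnings(apply(cells, 2L, as.numeric))
  rownames(M) <- df$mouse
  mask <- matrix("", nrow(M), ncol(M), dimnames = dimnames(M))
  mask[cells == "LOD"] <- "lod"
  mask[cells == ""] <- "absent"
  clade <- NULL
  if (!is.null(clade_file)) {
    cl <- utils::read.delim(clade_file, stringsAsFactors = FALSE)
    clade <- stats::setNames(cl$clade, cl$locus)
  }
  methylation_table(M, mask = mask, clade = clade, sex = sex)
}

#' Long-format (tidy) view of a methylation table
#'
#' @param table A \code{methylation_table}.
#' @return data.frame with \code{mouse}, \code{locus}, \code{clade},
#'   \code{methylation}, \code{mask}.
#' @export
methylation_long <- function(table) {
  M <- table$M
  out <- data.frame(
    mouse = rep(rownames(M), times = ncol(M)),
    locus = rep(colnames(M), each = nrow(M)),
    methylation = as.vector(M),
    mask = as.vector(table$mask),
    stringsAsFactors = FALSE)
  if (!is.null(table$clade)) out$clade <- unname(table$clade[out$locus])
  out
}

#' Published CoBRA survey of IAP LTR methylation in isogenic mice
#'
#' Loads the bundled percent-methylation matrix from a published CoBRA
#' survey of 21 IAPLTR1_Mm insertions (7 per phylogenetic clade) in liver
#' DNA of 17 isogenic mice, together with its locus-to-clade map. Cells
#' below the gel limit of detection are masked, as is the Y-linked locus
#' IAP281Y in the ten female animals.
#'
#' @return A \code{methylation_table} with clade and sex annotations.
#' @export
iap_cobra_data <- function() {
  dir <- system.file("extdata", package = "iapmeth")
  tab <- read_methylation_table(file.path(dir, "cobra_mouse_liver.tsv"),
                                clade_file = file.path(dir, "cobra_clades.tsv"))
  tab
}
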
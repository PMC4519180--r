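# Data model for plate-based FP screen measurements.
#
# A well record holds the replicate FP reads (mP) and raw fluorescence
# intensity reads (RFU) for one well of a 384-well screening plate, together
# with its role on the plate.  A screen plate is a collection of well
# records with unique coordinates; under the default screen layout each
# plate carries 28 positive-control wells (wild-type target protein + probe
# + DMSO) and 28 negative-control wells (non-binding W118A mutant + probe +
# DMSO) alongside the compound wells.

WELL_ROLES <- c("pos_control", "neg_control", "compound", "probe_only")

#' Create a single well record
#'
#' @param plate_id Plate identifier.
#' @param well Well coordinate (384-well convention, rows A-P, columns 1-24,
#'   e.g. `"A1"`); stored as a string, no arithmetic is performed on it.
#' @param role One of `"pos_control"`, `"neg_control"`, `"compound"`,
#'   `"probe_only"`.
#' @param fp_reads Numeric vector of replicate FP reads in mP (the plate is
#'   read several times; reads are averaged before any statistic).
#' @param compound_id Compound identifier; required for compound wells and
#'   for probe-only wells that received a compound, and must be absent
#'   (`NA`) for control wells.
#' @param intensity_reads Numeric vector of raw fluorescence intensity reads
#'   (RFU), used by the quencher counter-screen. May be empty.
#'
#' @return A list of class `"well_record"`.
#' @export
well_record <- function(plate_id, well, role, fp_reads,
                        compound_id = NA_character_,
                        intensity_reads = numeric()) {
  role <- match.arg(role, WELL_ROLES)
  fp_reads <- as.numeric(fp_reads)
  if (length(fp_reads) == 0L || !all(is.finite(fp_reads))) {
    abort_value("fp_reads must be non-empty and finite")
  }
  if (role == "compound" && is.na(compound_id)) {
    abort_integrity(sprintf("compound well %s/%s lacks a compound_id", plate_id, well))
  }
  if (role %in% c("pos_control", "neg_control") && !is.na(compound_id)) {
    abort_integrity(sprintf("control well %s/%s must not carry a compound_id", plate_id, well))
  }
  structure(
    list(plate_id = as.character(plate_id), well = as.character(well),
         role = role, compound_id = as.character(compound_id),
         fp_reads = fp_reads, intensity_reads = as.numeric(intensity_reads)),
    class = "well_record"
  )
}

#' Create a screen plate from well records
#'
#' @param plate_id Plate identifier.
#' @param wells List of [well_record()] objects.
#' @param layout_spec Optional named integer vector of expected well counts
#'   per role (e.g. `c(pos_control = 28, neg_control = 28)`); when supplied,
#'   a mismatch raises an integrity error.
#'
#' @return A list of class `"screen_plate"`.
#' @export
screen_plate <- function(plate_id, wells, layout_spec = NULL) {
  stopifnot(length(wells) > 0L)
  coords <- vapply(wells, function(w) w$well, character(1))
  if (anyDuplicated(coords)) {
    abort_integrity(sprintf("duplicate well coordinate(s) on plate %s: %s",
                            plate_id,
                            paste(unique(coords[duplicated(coords)]), collapse = ", ")))
  }
  if (!is.null(layout_spec)) {
    roles <- vapply(wells, function(w) w$role, character(1))
    for (r in names(layout_spec)) {
      if (sum(roles == r) != layout_spec[[r]]) {
        abort_integrity(sprintf("plate %s: expected %d %s wells, found %d",
                                plate_id, layout_spec[[r]], r, sum(roles == r)))
      }
    }
  }
  structure(list(plate_id = as.character(plate_id), wells = wells,
                 layout_spec = layout_spec),
            class = "screen_plate")
}

#' @export
print.screen_plate <- function(x, ...) {
  roles <- vapply(x$wells, function(w) w$role, character(1))
  cat(sprintf("<screen_plate %s: %d wells (%s)>\n", x$plate_id, length(x$wells),
              paste(sprintf("%s=%d", names(table(roles)), table(roles)),
                    collapse = ", ")))
  invisible(x)
}

#' Average the replicate FP reads of a well
#'
#' The plate reader records several consecutive reads per well; the
#' arithmetic mean is the per-well FP value used by all downstream
#' statistics.
#'
#' @param well A [well_record()] or a bare numeric vector of reads.
#' @return Mean FP in mP.
#' @export
average_reads <- function(well) {
  reads <- if (inherits(well, "well_record")) well$fp_reads else as.numeric(well)
  if (length(reads) == 0L) abort_value("no FP reads to average")
  mean(reads)
}

#' Per-well averaged values of a plate
#'
#' @param plate A [screen_plate()].
#' @return A data frame with one row per well: `well`, `role`,
#'   `compound_id`, `mean_fp` (mP), `mean_intensity` (RFU, `NA` when no
#'   intensity reads were recorded).
#' @export
well_means <- function(plate) {
  stopifnot(inherits(plate, "screen_plate"))
  data.frame(
    plate_id = plate$plate_id,
    well = vapply(plate$wells, function(w) w$well, character(1)),
    role = vapply(plate$wells, function(w) w$role, character(1)),
    compound_id = vapply(plate$wells, function(w) w$compound_id, character(1)),
    mean_fp = vapply(plate$wells, average_reads, numeric(1)),
    mean_intensity = vapply(plate$wells, function(w) {
      if (length(w$intensity_reads)) mean(w$intensity_reads) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Control and sample summary statistics for one plate
#'
#' Means and sample standard deviations (n-1 denominator) of the averaged
#' per-well FP values, split by role: positive controls, negative controls
#' and compound wells.  These are the plate-level quantities entering
#' normalized percent inhibition and the Z-score.
#'
#' @param plate A [screen_plate()].
#' @return A list of class `"plate_summary"` with elements `plate_id`,
#'   `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`, `mean_samples`,
#'   `sd_samples` (sample statistics are `NA` when the plate has fewer than
#'   two compound wells).
#' @export
summarize_plate <- function(plate) {
  wm <- well_means(plate)
  pos <- wm$mean_fp[wm$role == "pos_control"]
  neg <- wm$mean_fp[wm$role == "neg_control"]
  smp <- wm$mean_fp[wm$role == "compound"]
  if (length(pos) < 2L || length(neg) < 2L) {
    abort_controls(sprintf(
      "plate %s: need at least 2 wells per control role (found %d pos, %d neg)",
      plate$plate_id, length(pos), length(neg)))
  }
  structure(
    list(plate_id = plate$plate_id,
         mean_pos = mean(pos), sd_pos = stats::sd(pos),
         mean_neg = mean(neg), sd_neg = stats::sd(neg),
         mean_samples = if (length(smp) >= 2L) mean(smp) else NA_real_,
         sd_samples = if (length(smp) >= 2L) stats::sd(smp) else NA_real_),
    class = "plate_summary"
  )
}

PLATE_TABLE_COLUMNS <- c("plate_id", "well", "role", "compound_id",
                         "read_index", "fp_mP", "intensity_rfu")

#' Read a long-format plate table
#'
#' Expects a UTF-8 CSV with a header row and one row per
#' (plate, well, read index): columns `plate_id`, `well`, `role`,
#' `compound_id` (empty for controls), `read_index`, `fp_mP`,
#' `intensity_rfu` (may be empty).  Replicate reads are grouped per well in
#' `read_index` order.
#'
#' @param path Path to the CSV file.
#' @return A list of [screen_plate()] objects, in order of first appearance.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(plate_id = "character", well = "character",
                                        role = "character",
                                        compound_id = "character"))
  missing <- setdiff(PLATE_TABLE_COLUMNS, names(tab))
  if (length(missing)) {
    abort_format(sprintf("plate table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  key <- paste(tab$plate_id, tab$well, tab$read_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), , drop = FALSE][1L, ]
    abort_integrity(sprintf("duplicate well coordinate: plate %s well %s (read %s)",
                            dup$plate_id, dup$well, dup$read_index))
  }
  plates <- list()
  for (pid in unique(tab$plate_id)) {
    sub <- tab[tab$plate_id == pid, , drop = FALSE]
    wells <- lapply(unique(sub$well), function(wc) {
      rows <- sub[sub$well == wc, , drop = FALSE]
      rows <- rows[order(rows$read_index), , drop = FALSE]
      if (length(unique(rows$role)) != 1L ||
          length(unique(ifelse(is.na(rows$compound_id), "", rows$compound_id))) != 1L) {
        abort_integrity(sprintf("conflicting role/compound_id for plate %s well %s", pid, wc))
      }
      cid <- rows$compound_id[1L]
      if (is.null(cid) || length(cid) == 0L || is.na(cid) || cid == "") cid <- NA_character_
      intens <- rows$intensity_rfu
      intens <- intens[is.finite(intens)]
      well_record(pid, wc, rows$role[1L], rows$fp_mP,
                  compound_id = cid, intensity_reads = intens)
    })
    plates[[pid]] <- screen_plate(pid, wells)
  }
  unname(plates)
}

#' Write screen plates to a long-format plate table
#'
#' Inverse of [read_plate_table()]: a write followed by a read reproduces
#' every well record, including the order of replicate reads.
#'
#' @param plates A list of [screen_plate()] objects (or a single plate).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  if (inherits(plates, "screen_plate")) plates <- list(plates)
  rows <- lapply(plates, function(pl) {
    do.call(rbind, lapply(pl$wells, function(w) {
      n <- length(w$fp_reads)
      intens <- w$intensity_reads
      length(intens) <- n  # pad with NA
      data.frame(plate_id = pl$plate_id, well = w$well, role = w$role,
                 compound_id = ifelse(is.na(w$compound_id), "", w$compound_id),
                 read_index = seq_len(n),
                 # 17 significant digits: doubles survive the round trip
                 fp_mP = sprintf("%.17g", w$fp_reads),
                 intensity_rfu = ifelse(is.na(intens), "",
                                        sprintf("%.17g", intens)),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}
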
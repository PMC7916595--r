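# Readers and writers for every file the pipeline touches: peptide evidence
# (TSV), protein-to-complex annotation (TSV), mass-marker tables (TSV), and
# the wide/long profile matrices.  TSV means tab-separated, UTF-8, LF, no
# quoting; the long profile output is RFC-4180 CSV.

EVIDENCE_COLUMNS <- c("experiment_id", "replicate", "slice_index",
                      "protein_id", "peptide_sequence", "channel", "intensity")

empty_evidence <- function() {
  data.frame(experiment_id = character(), replicate = integer(),
             slice_index = integer(), protein_id = character(),
             peptide_sequence = character(), channel = character(),
             intensity = numeric(), stringsAsFactors = FALSE)
}

#' Read a peptide evidence table
#'
#' One row per observed peptide intensity at (experiment, replicate, slice,
#' channel).  The header must contain exactly the columns `experiment_id`,
#' `replicate`, `slice_index`, `protein_id`, `peptide_sequence`, `channel`,
#' `intensity`.  Malformed content is rejected, never coerced: an unknown
#' channel or a non-positive intensity raises an error naming the offending
#' data row.
#'
#' @param path Path to a tab-separated file.
#' @param n_slices If given, slice indices are checked against `[1, n_slices]`.
#' @return Validated evidence data frame, row order preserved.
#' @export
read_evidence <- function(path, n_slices = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(EVIDENCE_COLUMNS, names(raw))
  if (length(miss))
    stopf("evidence schema error: missing column '%s'", miss[1L])
  raw <- raw[EVIDENCE_COLUMNS]
  if (nrow(raw) == 0L) {
    warnf("evidence file '%s' has a header but no rows", path)
    return(empty_evidence())
  }
  bad_channel <- which(!raw$channel %in% c("light", "heavy"))
  if (length(bad_channel))
    stopf("evidence value error: channel '%s' at row %d (must be 'light' or 'heavy')",
          raw$channel[bad_channel[1L]], bad_channel[1L])
  replicate <- as.integer(raw$replicate)
  slice_index <- as.integer(raw$slice_index)
  intensity <- as.numeric(raw$intensity)
  for (col in list(list(replicate, "replicate"), list(slice_index, "slice_index"),
                   list(intensity, "intensity"))) {
    bad <- which(is.na(col[[1L]]))
    if (length(bad))
      stopf("evidence value error: unparseable %s at row %d", col[[2L]], bad[1L])
  }
  bad <- which(intensity <= 0)
  if (length(bad))
    stopf("evidence value error: non-positive intensity at row %d", bad[1L])
  bad <- which(slice_index < 1L | (!is.null(n_slices) & slice_index > n_slices))
  if (length(bad))
    stopf("evidence value error: slice_index out of gel bounds at row %d", bad[1L])
  data.frame(experiment_id = raw$experiment_id, replicate = replicate,
             slice_index = slice_index, protein_id = raw$protein_id,
             peptide_sequence = raw$peptide_sequence, channel = raw$channel,
             intensity = intensity, stringsAsFactors = FALSE)
}

#' Write a peptide evidence table
#'
#' @param evidence Evidence data frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  out <- evidence[EVIDENCE_COLUMNS]
  # 17 significant digits so the double round-trips exactly
  out$intensity <- sprintf("%.17g", out$intensity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-to-complex annotation table
#'
#' TSV with columns `protein_id`, `complex_id`, `module_id` (may be empty)
#' and `display_order`.  Each protein may map to at most one complex and
#' display orders must be unique within a complex.
#'
#' @param path Path to the TSV file.
#' @return Annotation data frame.
#' @export
read_complex_annotation <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "complex_id", "module_id", "display_order")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stopf("annotation schema error: missing column '%s'", miss[1L])
  ann$module_id[is.na(ann$module_id)] <- ""
  ann$display_order <- as.integer(ann$display_order)
  if (anyDuplicated(ann$protein_id))
    stopf("annotation error: protein '%s' maps to more than one complex",
          ann$protein_id[duplicated(ann$protein_id)][1L])
  for (cx in unique(ann$complex_id)) {
    ord <- ann$display_order[ann$complex_id == cx]
    if (anyDuplicated(ord))
      stopf("annotation error: duplicated display_order within complex '%s'", cx)
  }
  ann[need]
}

#' Write a protein-to-complex annotation table
#'
#' @param annotation Annotation data frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_complex_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mass-marker table
#'
#' TSV with columns `marker_name`, `mass_kda`, `peak_slice`.  At least two
#' markers are required and mass must decrease strictly with slice (the gel
#' runs from high mass at slice 1 to low mass at the bottom).
#'
#' @param path Path to the TSV file.
#' @return Marker data frame sorted by slice.
#' @export
read_marker_table <- function(path) {
  mk <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("marker_name", "mass_kda", "peak_slice")
  miss <- setdiff(need, names(mk))
  if (length(miss)) stopf("marker schema error: missing column '%s'", miss[1L])
  validate_markers(mk)
}

validate_markers <- function(mk) {
  if (nrow(mk) < 2L) stopf("at least 2 mass markers are required")
  if (anyDuplicated(mk$peak_slice)) stopf("marker slices must be distinct")
  mk <- mk[order(mk$peak_slice), , drop = FALSE]
  if (any(diff(mk$mass_kda) >= 0))
    stopf("markers are not co-monotone: mass must decrease strictly down the gel")
  rownames(mk) <- NULL
  mk
}

#' Write a mass-marker table
#'
#' @param markers Marker data frame (`marker_name`, `mass_kda`, `peak_slice`).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

profile_order <- function(profiles, annotation) {
  info <- data.frame(
    key = seq_along(profiles),
    protein_id = vapply(profiles, `[[`, "", "protein_id"),
    condition = vapply(profiles, `[[`, "", "condition"),
    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    m <- match(info$protein_id, annotation$protein_id)
    cx_rank <- match(annotation$complex_id, unique(annotation$complex_id))
    info$cx <- ifelse(is.na(m), .Machine$integer.max, cx_rank[m])
    info$ord <- ifelse(is.na(m), .Machine$integer.max, annotation$display_order[m])
  } else {
    info$cx <- 0L
    info$ord <- 0L
  }
  info[order(info$cx, info$ord, info$protein_id, info$condition), ]
}

#' Write migration profiles as a wide TSV and a long CSV
#'
#' The wide TSV has one row per profile with slice columns
#' `slice_1..slice_n` holding relative intensities in `[0, 1]` printed with
#' 4 decimals; rows are ordered by complex, then by within-complex display
#' order.  When the profiles span several conditions a `condition` column is
#' inserted after `protein_id`.  The long CSV holds
#' `protein_id, condition, slice_index, relative_intensity`.  Writing and
#' re-reading recovers values to 1e-4.
#'
#' @param profiles A `profile_set` (see [build_profiles()]) or a list of
#'   `migration_profile` objects.
#' @param annotation Annotation data frame used for row ordering (optional).
#' @param wide_path Output path of the wide TSV.
#' @param long_path Output path of the long CSV (optional).
#' @return `wide_path`, invisibly.
#' @export
write_profile_matrix <- function(profiles, annotation = NULL, wide_path,
                                 long_path = NULL) {
  profiles <- as_profile_list(profiles)
  if (!length(profiles)) {
    warnf("no profiles to write; emitting header-only files")
    writeLines(paste(c("protein_id", "condition"), collapse = "\t"), wide_path)
    if (!is.null(long_path))
      writeLines("protein_id,condition,slice_index,relative_intensity", long_path)
    return(invisible(wide_path))
  }
  lens <- vapply(profiles, function(p) length(p$values), 1L)
  if (length(unique(lens)) != 1L)
    stopf("profile length mismatch: %s", paste(unique(lens), collapse = ", "))
  n <- lens[[1L]]
  info <- profile_order(profiles, annotation)
  multi_cond <- length(unique(info$condition)) > 1L
  vals <- t(vapply(profiles[info$key], function(p) p$values, numeric(n)))
  txt <- matrix(sprintf("%.4f", vals), nrow = nrow(vals))
  wide <- data.frame(protein_id = info$protein_id, stringsAsFactors = FALSE)
  if (multi_cond) wide$condition <- info$condition
  wide <- cbind(wide, as.data.frame(txt, stringsAsFactors = FALSE))
  names(wide)[(ncol(wide) - n + 1L):ncol(wide)] <- paste0("slice_", seq_len(n))
  utils::write.table(wide, wide_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(
      protein_id = rep(info$protein_id, each = n),
      condition = rep(info$condition, each = n),
      slice_index = rep(seq_len(n), times = nrow(info)),
      relative_intensity = as.vector(t(vals)),
      stringsAsFactors = FALSE)
    utils::write.csv(long, long_path, row.names = FALSE, quote = FALSE)
  }
  invisible(wide_path)
}

#' Read a wide profile matrix back into migration profiles
#'
#' @param path Path to a wide TSV written by [write_profile_matrix()].
#' @param condition Condition label to attach when the file has no
#'   `condition` column.
#' @return List of `migration_profile` objects.
#' @export
read_profile_matrix <- function(path, condition = NA_character_) {
  wide <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                            stringsAsFactors = FALSE)
  slice_cols <- grep("^slice_", names(wide), value = TRUE)
  if (nrow(wide) == 0L) return(list())
  lapply(seq_len(nrow(wide)), function(i) {
    vals <- as.numeric(wide[i, slice_cols])
    migration_profile(
      protein_id = wide$protein_id[i],
      condition = if ("condition" %in% names(wide)) wide$condition[i] else condition,
      values = vals,
      normalized = max(vals) <= 1 + 1e-9)
  })
}
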
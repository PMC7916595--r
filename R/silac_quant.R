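# Core quantification: channel separation, representative-peptide choice,
# migration-profile construction (raw per replicate, averaged, then
# max-normalised once) and heavy/light condition ratios.

#' Construct a migration profile
#'
#' @param protein_id Protein id.
#' @param condition Condition label.
#' @param values Numeric vector of per-slice intensities (length = number of
#'   gel slices, non-negative).
#' @param normalized Whether `values` are max-normalised to `[0, 1]`.
#' @param source_peptide Representative peptide the profile was built from.
#' @param flags Character vector of diagnostic flags (e.g. `"undetected"`).
#' @return Object of class `migration_profile`.
#' @export
migration_profile <- function(protein_id, condition, values,
                              normalized = FALSE, source_peptide = NA_character_,
                              flags = character()) {
  values <- as.numeric(values)
  if (any(values < 0)) stopf("profile values must be non-negative")
  if (normalized && any(values > 0) && abs(max(values) - 1) > 1e-12)
    stopf("normalized profile must have max exactly 1")
  structure(
    list(protein_id = protein_id, condition = condition, values = values,
         normalized = isTRUE(normalized), source_peptide = source_peptide,
         flags = flags),
    class = "migration_profile")
}

#' @export
print.migration_profile <- function(x, ...) {
  cat(sprintf("<migration_profile> %s [%s], %d slices, %s, peptide %s\n",
              x$protein_id, x$condition, length(x$values),
              if (x$normalized) "normalized" else "raw",
              x$source_peptide))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "profile_set")) return(profiles$profiles)
  if (inherits(profiles, "migration_profile")) return(list(profiles))
  profiles
}

#' Split an evidence table into its SILAC channels
#'
#' @param evidence Validated evidence data frame.
#' @return List with elements `light` and `heavy`; the two row counts sum to
#'   the input and each input row appears in exactly one part.
#' @export
split_channels <- function(evidence) {
  light <- evidence[evidence$channel == "light", , drop = FALSE]
  heavy <- evidence[evidence$channel == "heavy", , drop = FALSE]
  if (nrow(light) == 0L || nrow(heavy) == 0L)
    warnf("one SILAC channel is empty (%d light, %d heavy rows)",
          nrow(light), nrow(heavy))
  list(light = light, heavy = heavy)
}

normalize_swap_map <- function(swap_map, evidence = NULL) {
  if (is.data.frame(swap_map)) return(swap_map)
  # named vector replicate -> heavy condition, single experiment
  exp_id <- unique(evidence$experiment_id) %||% "CP"
  data.frame(experiment_id = exp_id[1L],
             replicate = as.integer(names(swap_map)),
             heavy = unname(swap_map), stringsAsFactors = FALSE)
}

#' Map SILAC channels to biological conditions
#'
#' In a label-swapped design, which condition is the heavy one differs
#' between replicates; this attaches a `condition` column by looking up each
#' row's (experiment, replicate) in the swap map.
#'
#' @param evidence Evidence data frame.
#' @param swap_map Data frame (`experiment_id`, `replicate`, `heavy`) as from
#'   [scenario_swap_map()], or a named vector `replicate -> heavy condition`.
#' @param conditions The condition pair (reference first).  Defaults to the
#'   `conditions` attribute carried by the swap map.
#' @return The evidence with an added `condition` column.
#' @export
map_channels_to_conditions <- function(evidence, swap_map,
                                       conditions = attr(swap_map, "conditions")) {
  sm <- normalize_swap_map(swap_map, evidence)
  if (is.null(conditions)) {
    conditions <- unique(sm$heavy)
    if (length(conditions) != 2L)
      stopf("cannot infer the condition pair from the swap map; pass `conditions`")
  }
  if (!all(sm$heavy %in% conditions))
    stopf("swap map names a condition outside the condition pair")
  key_ev <- paste(evidence$experiment_id, evidence$replicate, sep = "\r")
  key_sm <- paste(sm$experiment_id, sm$replicate, sep = "\r")
  m <- match(key_ev, key_sm)
  if (anyNA(m)) {
    bad <- evidence[which(is.na(m))[1L], ]
    stopf("replicate %s of experiment '%s' is missing from the swap map",
          bad$replicate, bad$experiment_id)
  }
  heavy <- sm$heavy[m]
  other <- setNames(rev(conditions), conditions)
  evidence$condition <- ifelse(evidence$channel == "heavy", heavy,
                               other[heavy])
  evidence
}

#' Select the representative peptide of a protein
#'
#' Among the protein's peptides that were observed in both the light and the
#' heavy channel anywhere in the dataset, the representative is the one seen
#' in the largest number of distinct (experiment, replicate, slice, channel)
#' cells; ties are broken by larger summed intensity, then by
#' lexicographically smallest sequence.  If no peptide was seen in both
#' channels, the most frequent single-channel peptide is returned with the
#' `single-channel-representative` flag.
#'
#' @param evidence Evidence data frame (may contain several proteins).
#' @param protein_id Protein to select for; defaults to the only protein in
#'   `evidence`.
#' @return List with `peptide`, `n_cells`, `both_channels` and `flags`.
#' @export
select_representative_peptide <- function(evidence, protein_id = NULL) {
  if (!is.null(protein_id))
    evidence <- evidence[evidence$protein_id == protein_id, , drop = FALSE]
  if (nrow(evidence) == 0L)
    stopf("no evidence rows for protein '%s'", protein_id %||% "<none>")
  cell <- paste(evidence$experiment_id, evidence$replicate,
                evidence$slice_index, evidence$channel, sep = "\r")
  dedup <- !duplicated(paste(evidence$peptide_sequence, cell, sep = "\r"))
  n_cells <- table(evidence$peptide_sequence[dedup])
  sum_int <- tapply(evidence$intensity, evidence$peptide_sequence, sum)
  chans <- tapply(evidence$channel, evidence$peptide_sequence,
                  function(ch) length(unique(ch)))
  peps <- names(n_cells)
  both <- peps[chans[peps] == 2L]
  flags <- character()
  pool <- both
  if (!length(pool)) {
    pool <- peps
    flags <- "single-channel-representative"
  }
  ord <- order(-as.vector(n_cells[pool]), -as.vector(sum_int[pool]), pool)
  pick <- pool[ord[1L]]
  list(peptide = pick, n_cells = as.integer(n_cells[[pick]]),
       both_channels = pick %in% both, flags = flags)
}

#' Build a raw (unnormalised) migration profile for one replicate
#'
#' `values[s]` is the sum of the representative peptide's intensities
#' observed in (condition, replicate, slice s); slices without an
#' observation are 0.
#'
#' @param evidence Condition-mapped evidence (see
#'   [map_channels_to_conditions()]).
#' @param protein_id Protein id.
#' @param condition Condition label.
#' @param replicate Replicate number.
#' @param peptide Representative peptide sequence.
#' @param n_slices Number of gel slices.
#' @return An unnormalised `migration_profile`.
#' @export
build_raw_profile <- function(evidence, protein_id, condition, replicate,
                              peptide, n_slices) {
  if (is.null(evidence$condition))
    stopf("evidence has no condition column; run map_channels_to_conditions() first")
  rows <- evidence$protein_id == protein_id &
    evidence$condition == condition &
    evidence$replicate == replicate &
    evidence$peptide_sequence == peptide
  values <- numeric(n_slices)
  if (any(rows)) {
    sums <- tapply(evidence$intensity[rows], evidence$slice_index[rows], sum)
    values[as.integer(names(sums))] <- as.vector(sums)
  }
  migration_profile(protein_id, condition, values, normalized = FALSE,
                    source_peptide = peptide)
}

#' Average replicate profiles and max-normalise once
#'
#' Raw replicate profiles are averaged element-wise first and the mean
#' profile is then divided by its maximum, so the heatmap value 1 marks the
#' slice with the highest averaged intensity.  An all-zero mean yields an
#' all-zero profile flagged `"undetected"`.
#'
#' @param profiles List of raw `migration_profile` objects of equal length
#'   (one per replicate).
#' @return A normalised `migration_profile`.
#' @export
average_and_normalize <- function(profiles) {
  profiles <- as_profile_list(profiles)
  if (!length(profiles)) stopf("at least one replicate profile is required")
  lens <- vapply(profiles, function(p) length(p$values), 1L)
  if (length(unique(lens)) != 1L)
    stopf("replicate profiles differ in length (%s)",
          paste(unique(lens), collapse = ", "))
  mean_vals <- rowMeans(vapply(profiles, `[[`, numeric(lens[1L]), "values"))
  p1 <- profiles[[1L]]
  mx <- max(mean_vals)
  if (mx > 0) {
    migration_profile(p1$protein_id, p1$condition, mean_vals / mx,
                      normalized = TRUE, source_peptide = p1$source_peptide)
  } else {
    migration_profile(p1$protein_id, p1$condition, mean_vals,
                      normalized = TRUE, source_peptide = p1$source_peptide,
                      flags = "undetected")
  }
}

#' Build normalised migration profiles for all proteins and conditions
#'
#' For each protein the representative peptide is selected once from the
#' full evidence; per condition, raw profiles are built per replicate,
#' averaged, and max-normalised.
#'
#' @param evidence Condition-mapped evidence.
#' @param n_slices Number of gel slices.
#' @param conditions Condition labels (reference first); defaults to the
#'   order of appearance in the evidence.
#' @return A `profile_set`: list with `profiles` (named
#'   `"<protein>::<condition>"`), `representatives` (per-protein peptide and
#'   flags) and `n_slices`.
#' @export
build_profiles <- function(evidence, n_slices, conditions = NULL) {
  if (is.null(evidence$condition))
    stopf("evidence has no condition column; run map_channels_to_conditions() first")
  conditions <- conditions %||% unique(evidence$condition)
  proteins <- sort(unique(evidence$protein_id))
  replicates <- sort(unique(evidence$replicate))
  profiles <- list()
  reps_info <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    p <- proteins[i]
    sub <- evidence[evidence$protein_id == p, , drop = FALSE]
    rep_pick <- select_representative_peptide(sub)
    reps_info[[i]] <- data.frame(
      protein_id = p, peptide = rep_pick$peptide,
      n_cells = rep_pick$n_cells,
      single_channel = !rep_pick$both_channels, stringsAsFactors = FALSE)
    for (cond in conditions) {
      raw <- lapply(replicates, function(r)
        build_raw_profile(sub, p, cond, r, rep_pick$peptide, n_slices))
      profiles[[paste(p, cond, sep = "::")]] <- average_and_normalize(raw)
    }
  }
  structure(
    list(profiles = profiles,
         representatives = do.call(rbind, reps_info),
         n_slices = n_slices, conditions = conditions),
    class = "profile_set")
}

#' Extract one profile from a profile set
#'
#' @param profile_set A `profile_set` from [build_profiles()].
#' @param protein_id Protein id.
#' @param condition Condition label.
#' @return A `migration_profile`, or an error if absent.
#' @export
profile_get <- function(profile_set, protein_id, condition) {
  key <- paste(protein_id, condition, sep = "::")
  p <- profile_set$profiles[[key]]
  if (is.null(p)) stopf("no profile for %s in condition %s", protein_id, condition)
  p
}

#' Reference/perturbed abundance ratio of one protein
#'
#' Per replicate the ratio is the summed representative-peptide intensity of
#' the reference condition over that of the perturbed condition, restricted
#' to slices where at least one condition was observed, and corrected for a
#' non-unit mixing ratio.  Replicate ratios are combined by geometric mean
#' (ratios are scale quantities).  A protein with signal in only one
#' condition is flagged `absent-in-perturbed` or `absent-in-reference`
#' instead of receiving an infinite ratio.
#'
#' @param evidence Condition-mapped evidence.
#' @param protein_id Protein id.
#' @param conditions Condition pair, reference first.
#' @param peptide Representative peptide (default: selected from the
#'   protein's evidence).
#' @param mixing_ratio Reference:perturbed amount ratio of the mix.
#' @return Object of class `protein_ratio` with fields `protein_id`,
#'   `ratio` (NA when flagged), `flag`, `per_replicate`, `n_slices_used`,
#'   `source_peptide`.
#' @export
protein_ratio <- function(evidence, protein_id, conditions, peptide = NULL,
                          mixing_ratio = 1) {
  sub <- evidence[evidence$protein_id == protein_id, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("protein '%s' absent from the evidence", protein_id)
  if (is.null(sub$condition))
    stopf("evidence has no condition column; run map_channels_to_conditions() first")
  if (is.null(peptide)) peptide <- select_representative_peptide(sub)$peptide
  sub <- sub[sub$peptide_sequence == peptide, , drop = FALSE]
  ref <- conditions[[1L]]
  pert <- conditions[[2L]]
  replicates <- sort(unique(evidence$replicate))
  per_rep <- numeric(0)
  n_slices_used <- 0L
  for (r in replicates) {
    rs <- sub[sub$replicate == r, , drop = FALSE]
    if (nrow(rs) == 0L) next
    by_slice <- function(cond) {
      rows <- rs$condition == cond
      tapply(rs$intensity[rows], rs$slice_index[rows], sum)
    }
    s_ref <- by_slice(ref)
    s_pert <- by_slice(pert)
    slices <- union(names(s_ref), names(s_pert))  # slices with any signal
    n_slices_used <- n_slices_used + length(slices)
    tot_ref <- sum(s_ref)
    tot_pert <- sum(s_pert)
    if (tot_ref == 0 && tot_pert == 0) next
    per_rep <- c(per_rep, setNames((tot_ref / tot_pert) / mixing_ratio,
                                   as.character(r)))
  }
  if (!length(per_rep)) stopf("protein '%s' absent from the evidence", protein_id)
  finite <- per_rep[is.finite(per_rep) & per_rep > 0]
  if (length(finite)) {
    ratio <- geomean(finite)
    flag <- ""
  } else if (all(per_rep == Inf)) {
    ratio <- NA_real_
    flag <- "absent-in-perturbed"
  } else {
    ratio <- NA_real_
    flag <- "absent-in-reference"
  }
  structure(
    list(protein_id = protein_id, ratio = ratio, flag = flag,
         per_replicate = per_rep, n_slices_used = n_slices_used,
         source_peptide = peptide),
    class = "protein_ratio")
}

#' Reference/perturbed ratios for every protein
#'
#' @param evidence Condition-mapped evidence.
#' @param conditions Condition pair, reference first.
#' @param mixing_ratio Reference:perturbed amount ratio of the mix.
#' @return Data frame with one row per protein: `protein_id`, `ratio`,
#'   `flag`, `n_replicates`, `n_slices_used`, `source_peptide`.
#' @export
protein_ratios <- function(evidence, conditions, mixing_ratio = 1) {
  proteins <- sort(unique(evidence$protein_id))
  rows <- lapply(proteins, function(p) {
    pr <- protein_ratio(evidence, p, conditions, mixing_ratio = mixing_ratio)
    data.frame(protein_id = p, ratio = pr$ratio, flag = pr$flag,
               n_replicates = length(pr$per_replicate),
               n_slices_used = pr$n_slices_used,
               source_peptide = pr$source_peptide, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summed per-protein abundances by condition and replicate
#'
#' Sums all peptide intensities of each protein over slices and peptides,
#' per condition and replicate -- the complexome analogue of a label-free
#' per-protein quantity table, used by [lfq_log2fc_summary()].
#'
#' @param evidence Condition-mapped evidence.
#' @return Long data frame `protein_id`, `condition`, `replicate`,
#'   `abundance`.
#' @export
protein_abundances <- function(evidence) {
  if (is.null(evidence$condition))
    stopf("evidence has no condition column; run map_channels_to_conditions() first")
  key <- interaction(evidence$protein_id, evidence$condition,
                     evidence$replicate, drop = TRUE, sep = "\r")
  sums <- tapply(evidence$intensity, key, sum)
  parts <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  out <- data.frame(protein_id = parts[, 1L], condition = parts[, 2L],
                    replicate = as.integer(parts[, 3L]),
                    abundance = as.vector(sums), stringsAsFactors = FALSE)
  out[order(out$protein_id, out$condition, out$replicate), , drop = FALSE]
}
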
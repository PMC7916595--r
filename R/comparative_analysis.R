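# Comparative layer: peak detection on normalised profiles, migration-shift
# calls between conditions, complex-level fold changes, co-migration
# correlation, heatmap matrices and a label-free-style log2 fold-change
# summary.

#' Detect migration peaks in a normalised profile
#'
#' The profile is smoothed with a 3-point moving average (optional), local
#' maxima strictly greater than both neighbours and at least
#' `min_rel_height` high are kept (boundary maxima are allowed), and each
#' interior peak position is refined by parabolic interpolation over the
#' three points around the maximum.  If a calibration is supplied the peak
#' positions are also reported as apparent masses.
#'
#' @param profile A normalised `migration_profile`.
#' @param min_rel_height Minimum relative height of a reported peak.
#' @param smooth Apply the 3-point moving average before peak picking.
#' @param calibration Optional `mass_calibration` used to attach
#'   `mass_kda`.
#' @return Data frame `slice`, `rel_height`, `mass_kda` sorted by slice.
#' @export
detect_peaks <- function(profile, min_rel_height = 0.2, smooth = TRUE,
                         calibration = NULL) {
  if (!inherits(profile, "migration_profile") || !profile$normalized)
    stopf("detect_peaks requires a normalised migration_profile")
  x <- profile$values
  n <- length(x)
  empty <- data.frame(slice = numeric(), rel_height = numeric(),
                      mass_kda = numeric())
  if (all(x == 0)) return(empty)
  y <- if (smooth) {
    vapply(seq_len(n), function(i)
      mean(x[max(1L, i - 1L):min(n, i + 1L)]), 0)
  } else x
  left <- c(-Inf, y[-n])
  right <- c(y[-1L], -Inf)
  cand <- which(y > left & y > right & y >= min_rel_height)
  if (!length(cand)) return(empty)
  slice <- numeric(length(cand))
  height <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    if (i > 1L && i < n) {
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      delta <- if (denom != 0) 0.5 * (y[i - 1L] - y[i + 1L]) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      slice[j] <- i + delta
      height[j] <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * delta
    } else {
      slice[j] <- i
      height[j] <- y[i]
    }
  }
  height <- pmin(height, 1)
  out <- data.frame(slice = slice, rel_height = height,
                    mass_kda = if (is.null(calibration)) NA_real_ else
                      apparent_mass(calibration, slice))
  out[order(out$slice), , drop = FALSE]
}

#' Call gained and lost migration peaks between two conditions
#'
#' Peaks of the same protein in the reference and perturbed condition are
#' matched greedily by nearest slice within `match_tol`; unmatched perturbed
#' peaks are "gained", unmatched reference peaks "lost".
#'
#' @param reference_peaks Peak data frame of the reference condition.
#' @param perturbed_peaks Peak data frame of the perturbed condition.
#' @param match_tol Maximum slice distance for two peaks to be the same
#'   species.
#' @return List with data frames `matched` (`ref_slice`, `pert_slice`),
#'   `lost` and `gained` (rows of the respective input peak lists).
#' @export
migration_shift <- function(reference_peaks, perturbed_peaks, match_tol = 1.5) {
  nr <- nrow(reference_peaks)
  np <- nrow(perturbed_peaks)
  matched <- data.frame(ref_slice = numeric(), pert_slice = numeric())
  free_r <- seq_len(nr)
  free_p <- seq_len(np)
  while (length(free_r) && length(free_p)) {
    d <- abs(outer(reference_peaks$slice[free_r],
                   perturbed_peaks$slice[free_p], `-`))
    if (min(d) > match_tol) break
    ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
    matched <- rbind(matched, data.frame(
      ref_slice = reference_peaks$slice[free_r[ij[1L]]],
      pert_slice = perturbed_peaks$slice[free_p[ij[2L]]]))
    free_r <- free_r[-ij[1L]]
    free_p <- free_p[-ij[2L]]
  }
  list(matched = matched,
       lost = reference_peaks[free_r, , drop = FALSE],
       gained = perturbed_peaks[free_p, , drop = FALSE])
}

#' Complex-level fold change from subunit ratios
#'
#' Median and interquartile range of the finite reference/perturbed ratios
#' over a complex's subunits.  Subunits flagged absent in one condition are
#' excluded from the median (an infinity would dominate any summary) and
#' reported as counts; a complex whose every subunit is absent in the
#' perturbed condition is flagged `complex-absent`, and fewer than 3 finite
#' subunit ratios gives the `low-n` flag.
#'
#' @param ratios Data frame from [protein_ratios()].
#' @param annotation Annotation data frame.
#' @param complex_id Complex to summarise.
#' @return List `complex_id`, `median_ratio`, `q25`, `q75`, `n_finite`,
#'   `n_absent_perturbed`, `n_absent_reference`, `status`.
#' @export
complex_fold_change <- function(ratios, annotation, complex_id) {
  subunits <- annotation$protein_id[annotation$complex_id == complex_id]
  if (!length(subunits)) stopf("unknown complex '%s'", complex_id)
  rr <- ratios[ratios$protein_id %in% subunits, , drop = FALSE]
  finite <- rr$ratio[!is.na(rr$ratio) & is.finite(rr$ratio)]
  n_ap <- sum(rr$flag == "absent-in-perturbed")
  n_ar <- sum(rr$flag == "absent-in-reference")
  if (length(finite)) {
    q <- stats::quantile(finite, c(0.25, 0.5, 0.75), names = FALSE)
    status <- if (length(finite) < 3L) "low-n" else "ok"
    list(complex_id = complex_id, median_ratio = q[2L], q25 = q[1L],
         q75 = q[3L], n_finite = length(finite), n_absent_perturbed = n_ap,
         n_absent_reference = n_ar, status = status)
  } else {
    status <- if (n_ap > 0L) "complex-absent" else "no-data"
    list(complex_id = complex_id, median_ratio = NA_real_, q25 = NA_real_,
         q75 = NA_real_, n_finite = 0L, n_absent_perturbed = n_ap,
         n_absent_reference = n_ar, status = status)
  }
}

#' Co-migration score of two profiles
#'
#' Pearson correlation of two normalised migration profiles over all
#' slices, the standard complexome-profiling measure of co-migration.
#' Requires at least 5 slices where either profile is nonzero; a constant
#' profile has no defined correlation and is flagged.
#'
#' @param profile_a,profile_b Normalised `migration_profile` objects of
#'   equal length.
#' @param min_support Minimum number of slices where either profile is
#'   nonzero.
#' @return List `r` (NA when flagged), `status` (`"ok"`,
#'   `"insufficient-support"` or `"not-a-score"`) and `n_support`.
#' @export
comigration_score <- function(profile_a, profile_b, min_support = 5L) {
  for (p in list(profile_a, profile_b))
    if (!inherits(p, "migration_profile") || !p$normalized)
      stopf("comigration_score requires normalised migration_profile objects")
  a <- profile_a$values
  b <- profile_b$values
  if (length(a) != length(b)) stopf("profiles differ in length")
  support <- sum(a > 0 | b > 0)
  if (support < min_support)
    return(list(r = NA_real_, status = "insufficient-support",
                n_support = support))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, status = "not-a-score", n_support = support))
  list(r = stats::cor(a, b), status = "ok", n_support = support)
}

#' Pairwise co-migration matrix for a protein set
#'
#' @param profile_set Profiles from [build_profiles()].
#' @param proteins Protein ids to correlate.
#' @param condition Condition whose profiles are used.
#' @return Symmetric matrix of Pearson r (NA where flagged).
#' @export
comigration_matrix <- function(profile_set, proteins, condition) {
  m <- matrix(NA_real_, length(proteins), length(proteins),
              dimnames = list(proteins, proteins))
  profs <- lapply(proteins, function(p)
    tryCatch(profile_get(profile_set, p, condition), error = function(e) NULL))
  for (i in seq_along(proteins)) {
    if (is.null(profs[[i]])) next
    m[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      if (is.null(profs[[j]])) next
      m[i, j] <- m[j, i] <- comigration_score(profs[[i]], profs[[j]])$r
    }
  }
  m
}

#' Ordered heatmap matrix of normalised profiles
#'
#' Rows are proteins ordered by complex and within-complex display order;
#' values are the untransformed relative intensities in `[0, 1]`.  Proteins
#' absent from the annotation are appended as an unassigned block with a
#' warning; a protein requested explicitly but absent from the profiles is
#' an error.
#'
#' @param profile_set Profiles from [build_profiles()].
#' @param annotation Annotation data frame.
#' @param condition Condition whose profiles form the matrix.
#' @param proteins Optional explicit protein order (checked against the
#'   profiles).
#' @return Numeric matrix (proteins x slices) with an `annotation_order`
#'   attribute.
#' @export
heatmap_matrix <- function(profile_set, annotation, condition,
                           proteins = NULL) {
  have <- vapply(profile_set$profiles, function(p)
    p$condition == condition, TRUE)
  profs <- profile_set$profiles[have]
  ids <- unname(vapply(profs, `[[`, "", "protein_id"))
  if (!is.null(proteins)) {
    unknown <- setdiff(proteins, ids)
    if (length(unknown))
      stopf("protein '%s' not found among the profiles", unknown[1L])
    sel <- proteins
  } else {
    annotated <- ids[ids %in% annotation$protein_id]
    extra <- sort(ids[!ids %in% annotation$protein_id])
    ord <- order(match(annotation$protein_id[match(annotated, annotation$protein_id)],
                       annotation$protein_id))
    info <- annotation[match(annotated, annotation$protein_id), ]
    annotated <- annotated[order(match(info$complex_id, unique(annotation$complex_id)),
                                 info$display_order)]
    if (length(extra))
      warnf("%d protein(s) missing from the annotation; appended as unassigned",
            length(extra))
    sel <- c(annotated, extra)
  }
  rows <- lapply(sel, function(p) profs[[match(p, ids)]]$values)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sel, paste0("slice_", seq_len(ncol(m))))
  m
}

#' Label-free-style log2 fold-change summary per protein
#'
#' Computes `log2(mean perturbed / mean reference)` per protein from a long
#' per-protein abundance table (replicate rows allowed) and orders the
#' result by complex.  Zero mean abundances are flagged, not pseudocounted.
#'
#' @param abundances Long data frame `protein_id`, `condition`, `abundance`
#'   (optionally `replicate`).
#' @param annotation Annotation data frame.
#' @param reference Reference condition label.
#' @return Data frame `protein_id`, `complex_id`, `module_id`, `condition`,
#'   `log2fc`, `flag`, ordered by complex and display order.
#' @export
lfq_log2fc_summary <- function(abundances, annotation, reference) {
  if (!reference %in% abundances$condition)
    stopf("reference condition '%s' missing from the abundance table", reference)
  conds <- setdiff(unique(abundances$condition), reference)
  means <- function(cond) {
    sub <- abundances[abundances$condition == cond, , drop = FALSE]
    tapply(sub$abundance, sub$protein_id, mean)
  }
  ref_mean <- means(reference)
  rows <- list()
  for (cond in conds) {
    m <- means(cond)
    prots <- union(names(ref_mean), names(m))
    mr <- ifelse(prots %in% names(ref_mean), ref_mean[prots], 0)
    mp <- ifelse(prots %in% names(m), m[prots], 0)
    flag <- ifelse(mr == 0 & mp == 0, "undetected",
                   ifelse(mr == 0, "absent-in-reference",
                          ifelse(mp == 0, "absent-in-perturbed", "")))
    rows[[cond]] <- data.frame(
      protein_id = prots, condition = cond,
      log2fc = ifelse(flag == "", log2(mp / mr), NA_real_),
      flag = flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  am <- match(out$protein_id, annotation$protein_id)
  out$complex_id <- ifelse(is.na(am), "unassigned", annotation$complex_id[am])
  out$module_id <- ifelse(is.na(am), "", annotation$module_id[am])
  ord <- order(match(out$complex_id, c(unique(annotation$complex_id), "unassigned")),
               ifelse(is.na(am), .Machine$integer.max, annotation$display_order[am]),
               out$protein_id)
  out <- out[ord, c("protein_id", "complex_id", "module_id", "condition",
                    "log2fc", "flag")]
  rownames(out) <- NULL
  out
}

#' Full comparative report of a two-condition experiment
#'
#' Combines per-protein ratios, per-complex fold changes, peak detection and
#' migration-shift calls, and a co-migration matrix for a protein set of
#' interest into the tables the pipeline writes to disk.
#'
#' @param profile_set Profiles from [build_profiles()].
#' @param ratios Data frame from [protein_ratios()].
#' @param annotation Annotation data frame.
#' @param calibration A `mass_calibration`.
#' @param conditions Condition pair, reference first.
#' @param min_rel_height Peak-height threshold for [detect_peaks()].
#' @param match_tol Slice tolerance for [migration_shift()].
#' @param comigration_proteins Protein ids for the co-migration matrix
#'   (computed in the perturbed condition); NULL to skip.
#' @return Object of class `comparison_report`: list of data frames
#'   `proteins`, `complexes`, `shifts`, `comigration`.
#' @export
comparison_report <- function(profile_set, ratios, annotation, calibration,
                              conditions, min_rel_height = 0.2,
                              match_tol = 1.5, comigration_proteins = NULL) {
  ref <- conditions[[1L]]
  pert <- conditions[[2L]]
  proteins <- sort(unique(vapply(profile_set$profiles, `[[`, "", "protein_id")))
  shift_rows <- list()
  prot_rows <- list()
  for (p in proteins) {
    pk <- lapply(c(ref, pert), function(cond) {
      prof <- tryCatch(profile_get(profile_set, p, cond),
                       error = function(e) NULL)
      if (is.null(prof)) return(data.frame(slice = numeric(),
                                           rel_height = numeric(),
                                           mass_kda = numeric()))
      detect_peaks(prof, min_rel_height = min_rel_height,
                   calibration = calibration)
    })
    sh <- migration_shift(pk[[1L]], pk[[2L]], match_tol = match_tol)
    for (dir in c("lost", "gained")) {
      d <- sh[[dir]]
      if (nrow(d))
        shift_rows[[length(shift_rows) + 1L]] <- data.frame(
          protein_id = p, direction = dir, slice = d$slice,
          rel_height = d$rel_height, mass_kda = d$mass_kda,
          stringsAsFactors = FALSE)
    }
    ri <- ratios[ratios$protein_id == p, , drop = FALSE]
    am <- match(p, annotation$protein_id)
    prot_rows[[length(prot_rows) + 1L]] <- data.frame(
      protein_id = p,
      complex_id = if (is.na(am)) "unassigned" else annotation$complex_id[am],
      module_id = if (is.na(am)) "" else annotation$module_id[am],
      ratio = if (nrow(ri)) ri$ratio else NA_real_,
      flag = if (nrow(ri)) ri$flag else "no-ratio",
      source_peptide = if (nrow(ri)) ri$source_peptide else NA_character_,
      n_peaks_reference = nrow(pk[[1L]]), n_peaks_perturbed = nrow(pk[[2L]]),
      n_gained = nrow(sh$gained), n_lost = nrow(sh$lost),
      stringsAsFactors = FALSE)
  }
  prot_df <- do.call(rbind, prot_rows)
  cx_rows <- lapply(unique(annotation$complex_id), function(cx) {
    fc <- complex_fold_change(ratios, annotation, cx)
    as.data.frame(fc, stringsAsFactors = FALSE)
  })
  shifts_df <- if (length(shift_rows)) do.call(rbind, shift_rows) else
    data.frame(protein_id = character(), direction = character(),
               slice = numeric(), rel_height = numeric(),
               mass_kda = numeric(), stringsAsFactors = FALSE)
  comig_df <- NULL
  if (!is.null(comigration_proteins)) {
    cm <- comigration_matrix(profile_set, comigration_proteins, pert)
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    comig_df <- data.frame(
      protein_a = rownames(cm)[idx[, 1L]],
      protein_b = colnames(cm)[idx[, 2L]],
      condition = pert, r = cm[idx], stringsAsFactors = FALSE)
  }
  structure(
    list(proteins = prot_df, complexes = do.call(rbind, cx_rows),
         shifts = shifts_df, comigration = comig_df),
    class = "comparison_report")
}
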
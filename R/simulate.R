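# Generative model: each assembly form deposits a Gaussian band (in slice
# coordinates) at the slice position implied by its apparent mass; a
# protein's true per-slice signal in a condition is the sum over the forms
# it belongs to of abundance x stoichiometry x band weight.

#' Slice position of an assembly form on a gel
#'
#' Log-linear migration: `s = 1 + (log10(top) - log10(mass)) * (n - 1) /
#' (log10(top) - log10(bottom))`, a continuous slice coordinate that
#' decreases strictly with mass.
#'
#' @param form An [assembly_form()] or a numeric apparent mass in kDa.
#' @param gel A [gel_model()].
#' @return Continuous slice coordinate in `[1, n_slices]`.
#' @export
#' @examples
#' form_center_slice(130, gel_model())   # ~44.7
#' form_center_slice(750, gel_model())   # ~20.7
form_center_slice <- function(form, gel) {
  if (inherits(form, "assembly_form")) {
    mass <- form$apparent_mass
    label <- form$name
  } else {
    mass <- form
    label <- paste0(format(mass), " kDa")
  }
  lm10 <- log10(mass)
  tol <- 1e-5  # printed masses like 3162.3 kDa round to just past the boundary
  if (any(lm10 > gel$log10_mass_top + tol | lm10 < gel$log10_mass_bottom - tol))
    stopf("form '%s': apparent mass outside the gel's mass range [%.4g, %.4g] kDa",
          label, 10^gel$log10_mass_bottom, 10^gel$log10_mass_top)
  lm10 <- pmin(pmax(lm10, gel$log10_mass_bottom), gel$log10_mass_top)
  1 + (gel$log10_mass_top - lm10) * (gel$n_slices - 1) /
    (gel$log10_mass_top - gel$log10_mass_bottom)
}

# Discrete Gaussian band: weights over integer slices within +/- 4 sigma of
# the centre, normalised to sum to 1 so that total signal is conserved
# exactly (the conservation oracle relies on this).
slice_band <- function(center, gel, trunc_sigma = 4) {
  lo <- max(1L, as.integer(ceiling(center - trunc_sigma * gel$peak_sigma)))
  hi <- min(gel$n_slices, as.integer(floor(center + trunc_sigma * gel$peak_sigma)))
  idx <- lo:hi
  d <- stats::dnorm(idx, mean = center, sd = gel$peak_sigma)
  list(idx = idx, w = d / sum(d))
}

# True signal matrix (n_slices x 2 conditions) per protein.
protein_signals <- function(scenario) {
  prots <- scenario_proteins(scenario)
  n <- scenario$gel$n_slices
  sig <- lapply(prots, function(p)
    matrix(0, n, 2L, dimnames = list(NULL, scenario$conditions)))
  names(sig) <- prots
  for (f in scenario$forms) {
    band <- slice_band(form_center_slice(f, scenario$gel), scenario$gel)
    for (p in names(f$members)) {
      add <- outer(band$w, f$abundance[scenario$conditions] * f$members[[p]])
      sig[[p]][band$idx, ] <- sig[[p]][band$idx, ] + add
    }
  }
  sig
}

# Deterministic tryptic-looking peptide sequences (interior residues avoid
# K/R, C-terminal residue is K or R), drawn from the scenario RNG stream.
random_peptides <- function(k) {
  interior <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                "P", "Q", "S", "T", "V", "W", "Y")
  draw <- function(m) {
    vapply(seq_len(m), function(i) {
      len <- sample(7:13, 1L)
      paste0(paste(sample(interior, len, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, "")
  }
  seqs <- draw(k)
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- draw(sum(dup))
  }
  seqs
}

#' Simulate a SILAC complexome-profiling evidence table
#'
#' For each protein, `k` peptides are drawn (uniform in
#' `peptides_per_protein`) with fixed lognormal response factors shared
#' across replicates and channels.  The observed intensity of a peptide at
#' slice `s` for condition `c` in one replicate is
#' `signal(s, c) * response * mixing_share(c) * noise`, where the
#' multiplicative lognormal measurement noise is split into a component
#' common to the co-measured heavy/light pair and a channel-specific
#' residual (`noise$channel_cor`).  Observations below
#' `noise$detection_floor` are censored: the row is absent, not zero.
#' Channel labels follow each replicate's heavy-label assignment, so the
#' condition-level data are invariant under a label swap.
#'
#' @param scenario A [scenario_config()].
#' @param seed Integer seed (defaults to `scenario$seed`).  The same
#'   (scenario, seed) pair always yields the identical table.
#' @param experiment_id Experiment label written into the table.
#' @return A peptide evidence data frame with columns `experiment_id`,
#'   `replicate`, `slice_index`, `protein_id`, `peptide_sequence`,
#'   `channel`, `intensity`.
#' @export
#' @examples
#' sc <- default_scenario()
#' ev <- simulate_evidence(sc, seed = 1)
#' head(ev)
simulate_evidence <- function(scenario, seed = scenario$seed,
                              experiment_id = "CP") {
  if (!inherits(scenario, "scenario_config")) stopf("scenario_config required")
  sig <- protein_signals(scenario)
  conds <- scenario$conditions
  nrep <- length(scenario$replicates)
  share <- c(scenario$mixing_ratio, 1) / (scenario$mixing_ratio + 1)
  names(share) <- conds
  nz <- scenario$noise
  sd_common <- nz$measurement_sd * sqrt(nz$channel_cor)
  sd_chan <- nz$measurement_sd * sqrt(1 - nz$channel_cor)
  ppp <- scenario$peptides_per_protein

  out <- list()
  local_seed(seed, {
    for (p in names(sig)) {
      S <- sig[[p]]
      k <- if (ppp[1L] == ppp[2L]) ppp[1L] else sample(ppp[1L]:ppp[2L], 1L)
      response <- stats::rlnorm(k, 0, nz$response_sd)
      seqs <- random_peptides(k)
      slices <- which(rowSums(S) > 0)
      if (!length(slices)) next
      ns <- length(slices)
      for (r in seq_len(nrep)) {
        heavy <- scenario$replicates[r]
        # noise drawn indexed by condition (not channel) so that swapping
        # the heavy label only relabels channels
        common <- matrix(stats::rlnorm(k * ns, 0, sd_common), k, ns)
        chan_noise <- list(
          matrix(stats::rlnorm(k * ns, 0, sd_chan), k, ns),
          matrix(stats::rlnorm(k * ns, 0, sd_chan), k, ns))
        for (ci in 1:2) {
          cond <- conds[ci]
          base <- S[slices, ci]
          if (all(base == 0)) next
          inten <- (response %o% base) * share[[cond]] * common * chan_noise[[ci]]
          inten[, base == 0] <- 0
          keep <- inten > 0 & inten >= nz$detection_floor
          if (!any(keep)) next
          ki <- which(keep)
          pep_i <- ((ki - 1L) %% k) + 1L
          sl_i <- ((ki - 1L) %/% k) + 1L
          out[[length(out) + 1L]] <- list(
            replicate = rep.int(r, length(ki)),
            slice_index = slices[sl_i],
            protein_id = rep.int(p, length(ki)),
            peptide_sequence = seqs[pep_i],
            channel = rep.int(if (cond == heavy) "heavy" else "light",
                              length(ki)),
            intensity = inten[ki])
        }
      }
    }
  })
  if (!length(out)) {
    return(data.frame(experiment_id = character(), replicate = integer(),
                      slice_index = integer(), protein_id = character(),
                      peptide_sequence = character(), channel = character(),
                      intensity = numeric(), stringsAsFactors = FALSE))
  }
  pull <- function(field) unlist(lapply(out, `[[`, field), use.names = FALSE)
  data.frame(
    experiment_id = experiment_id,
    replicate = as.integer(pull("replicate")),
    slice_index = as.integer(pull("slice_index")),
    protein_id = pull("protein_id"),
    peptide_sequence = pull("peptide_sequence"),
    channel = pull("channel"),
    intensity = pull("intensity"),
    stringsAsFactors = FALSE)
}
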
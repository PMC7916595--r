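# Shared fixtures: tiny hand-written evidence tables, random small tables
# for oracle comparisons, and a brute-force profile oracle that re-derives
# per-slice sums with an explicit row loop, independent of the package's
# grouped implementation.

evidence_row <- function(rep, slice, protein, peptide, channel, intensity,
                         experiment = "CP") {
  data.frame(experiment_id = experiment, replicate = rep, slice_index = slice,
             protein_id = protein, peptide_sequence = peptide,
             channel = channel, intensity = intensity,
             stringsAsFactors = FALSE)
}

bind_evidence <- function(...) do.call(rbind, list(...))

random_small_evidence <- function(seed, n_rows = 50) {
  set.seed(seed)
  data.frame(
    experiment_id = "CP",
    replicate = sample(1:2, n_rows, replace = TRUE),
    slice_index = sample(1:10, n_rows, replace = TRUE),
    protein_id = sample(c("P1", "P2", "P3"), n_rows, replace = TRUE),
    peptide_sequence = sample(c("AAK", "CCK", "DDR", "EEK"), n_rows,
                              replace = TRUE),
    channel = sample(c("light", "heavy"), n_rows, replace = TRUE),
    intensity = round(stats::runif(n_rows, 1, 1000), 3),
    stringsAsFactors = FALSE)
}

# Row-loop oracle for raw profile construction.
brute_profile <- function(evidence, protein, condition, replicate, peptide,
                          n_slices) {
  v <- numeric(n_slices)
  for (i in seq_len(nrow(evidence))) {
    r <- evidence[i, ]
    if (r$protein_id == protein && r$condition == condition &&
        r$replicate == replicate && r$peptide_sequence == peptide) {
      v[r$slice_index] <- v[r$slice_index] + r$intensity
    }
  }
  v
}

# A small noise-free two-condition scenario used by the conservation and
# closed-form oracles: 3 proteins, 2 forms, no noise, no censoring,
# exactly one peptide per protein.
toy_noisefree_scenario <- function() {
  forms <- list(
    assembly_form("dimer", 1000, c(A = 2L, B = 1L), c(ref = 10, pert = 10)),
    assembly_form("mono", 100, c(A = 1L, C = 1L), c(ref = 4, pert = 8)))
  scenario_config(
    conditions = c("ref", "pert"), forms = forms,
    gel = gel_model(n_slices = 32, peak_sigma = 1),
    replicates = c("ref", "pert"), mixing_ratio = 1,
    peptides_per_protein = c(1L, 1L),
    noise = list(response_sd = 0, measurement_sd = 0, detection_floor = 0),
    seed = 7L)
}

# Independent closed-form signal for the toy scenario: explicit loops over
# forms using the stated migration/band model.
toy_expected_signal <- function(scenario, protein, condition) {
  gel <- scenario$gel
  v <- numeric(gel$n_slices)
  for (f in scenario$forms) {
    if (!protein %in% names(f$members)) next
    center <- 1 + (gel$log10_mass_top - log10(f$apparent_mass)) *
      (gel$n_slices - 1) / (gel$log10_mass_top - gel$log10_mass_bottom)
    lo <- max(1, ceiling(center - 4 * gel$peak_sigma))
    hi <- min(gel$n_slices, floor(center + 4 * gel$peak_sigma))
    d <- stats::dnorm(lo:hi, center, gel$peak_sigma)
    v[lo:hi] <- v[lo:hi] +
      f$abundance[[condition]] * f$members[[protein]] * d / sum(d)
  }
  v
}
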
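# Scenario types for the synthetic SILAC/BN-PAGE generator: assembly forms
# (a complex species with an apparent mass and per-condition abundance), the
# gel geometry, and the full scenario configuration.

#' Define an assembly form
#'
#' An assembly form is one native species on the gel: a complex, supercomplex,
#' subcomplex or free protein pool, with a single apparent molecular mass and
#' a per-condition abundance in arbitrary units.  A protein may belong to many
#' forms; its migration profile is the abundance-weighted sum of the forms'
#' migration peaks.
#'
#' @param name Form name (e.g. `"respirasome"`).
#' @param apparent_mass Apparent molecular mass in kDa (> 0).
#' @param members Named integer vector: protein id -> copies per form
#'   (stoichiometry, positive integers).
#' @param abundance Named numeric vector: condition -> abundance in arbitrary
#'   units (non-negative; 0 means the form is absent in that condition).
#' @return An object of class `assembly_form`.
#' @export
#' @examples
#' assembly_form("cII", 125,
#'   members = c(SDHA = 1, SDHB = 1, SDHC = 1, SDHD = 1),
#'   abundance = c(wt = 40, KO = 40))
assembly_form <- function(name, apparent_mass, members, abundance) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("form name must be a non-empty string")
  if (!is_scalar_number(apparent_mass) || apparent_mass <= 0)
    stopf("form '%s': apparent_mass must be a positive number (kDa)", name)
  members <- unlist(members)
  if (length(members) == 0L || is.null(names(members)) || any(!nzchar(names(members))))
    stopf("form '%s': members must be a non-empty named vector", name)
  if (any(members <= 0) || any(members != round(members)))
    stopf("form '%s': stoichiometries must be positive integers", name)
  if (anyDuplicated(names(members)))
    stopf("form '%s': duplicated member protein ids", name)
  abundance <- unlist(abundance)
  if (is.null(names(abundance)) || any(!nzchar(names(abundance))))
    stopf("form '%s': abundance must be a named (condition) vector", name)
  if (any(abundance < 0))
    stopf("form '%s': abundances must be non-negative", name)
  structure(
    list(name = name, apparent_mass = apparent_mass,
         members = setNames(as.integer(members), names(members)),
         abundance = abundance),
    class = "assembly_form")
}

#' Define the gel geometry and band shape
#'
#' The gel model maps slice index to log10 apparent mass linearly (slice 1 is
#' the top of the gel, i.e. the highest mass) and gives each native species a
#' Gaussian band profile in slice coordinates.
#'
#' @param n_slices Number of slices the lane is cut into (>= 8; default 64).
#' @param log10_mass_top log10 apparent mass (kDa) at slice 1.
#' @param log10_mass_bottom log10 apparent mass (kDa) at the last slice.
#' @param peak_sigma Gaussian band width in slices (> 0).
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(n_slices = 64L, log10_mass_top = 3.5,
                      log10_mass_bottom = 1.5, peak_sigma = 1.0) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 8L)
    stopf("n_slices must be an integer >= 8")
  if (!is_scalar_number(log10_mass_top) || !is_scalar_number(log10_mass_bottom) ||
      log10_mass_top <= log10_mass_bottom)
    stopf("log10_mass_top must exceed log10_mass_bottom")
  if (!is_scalar_number(peak_sigma) || peak_sigma <= 0)
    stopf("peak_sigma must be a positive number of slices")
  structure(
    list(n_slices = n_slices, log10_mass_top = log10_mass_top,
         log10_mass_bottom = log10_mass_bottom, peak_sigma = peak_sigma),
    class = "gel_model")
}

default_noise <- function() {
  list(response_sd = 0.3, measurement_sd = 0.2,
       detection_floor = 0.01, channel_cor = 0.9)
}

#' Assemble and validate a simulation scenario
#'
#' @param conditions Character vector of length 2: the reference condition
#'   first, the perturbed condition second (names `reference`/`perturbed` are
#'   attached).
#' @param forms List of [assembly_form()] objects; every form must carry an
#'   abundance entry for both conditions.
#' @param gel A [gel_model()].
#' @param replicates Character vector, one entry per replicate experiment,
#'   giving the condition that carries the heavy SILAC label in that
#'   replicate (a label swap is two replicates with different values).
#' @param mixing_ratio Amount ratio reference:perturbed in the mixed sample
#'   (> 0; default 1, i.e. mixed equally).
#' @param peptides_per_protein Integer range `c(min, max)`: number of
#'   detectable peptides drawn per protein.
#' @param noise List with elements `response_sd` (lognormal sigma of the
#'   fixed per-peptide response factor), `measurement_sd` (lognormal sigma
#'   per observation), `detection_floor` (intensity below which an
#'   observation is censored, i.e. dropped) and `channel_cor` (fraction of
#'   the measurement variance shared between the co-measured heavy and light
#'   channels of one peptide in one slice; see the methods vignette).
#' @param seed Default integer seed for [simulate_evidence()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(conditions, forms, gel = gel_model(), replicates,
                            mixing_ratio = 1, peptides_per_protein = c(3L, 8L),
                            noise = list(), seed = 101L) {
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stopf("conditions must be two distinct labels (reference, perturbed)")
  conditions <- setNames(as.character(conditions), c("reference", "perturbed"))
  if (!inherits(gel, "gel_model")) stopf("gel must be a gel_model")
  if (!length(forms)) stopf("at least one assembly form is required")
  forms <- lapply(forms, function(f) {
    if (!inherits(f, "assembly_form")) stopf("forms must be assembly_form objects")
    missing_cond <- setdiff(conditions, names(f$abundance))
    if (length(missing_cond))
      stopf("form '%s': no abundance for condition '%s'", f$name, missing_cond[1L])
    f$abundance <- f$abundance[conditions]
    f
  })
  if (anyDuplicated(vapply(forms, `[[`, "", "name")))
    stopf("form names must be unique")
  replicates <- as.character(replicates)
  if (length(replicates) < 1L || !all(replicates %in% conditions))
    stopf("replicates must name the heavy-labelled condition per replicate")
  if (!is_scalar_number(mixing_ratio) || mixing_ratio <= 0)
    stopf("mixing_ratio must be > 0")
  peptides_per_protein <- as.integer(peptides_per_protein)
  if (length(peptides_per_protein) != 2L || any(peptides_per_protein < 1L) ||
      peptides_per_protein[1L] > peptides_per_protein[2L])
    stopf("peptides_per_protein must be an integer range c(min, max)")
  noise <- utils::modifyList(default_noise(), noise)
  if (noise$response_sd < 0 || noise$measurement_sd < 0 || noise$detection_floor < 0)
    stopf("noise sigmas and detection_floor must be non-negative")
  if (noise$channel_cor < 0 || noise$channel_cor > 1)
    stopf("noise$channel_cor must lie in [0, 1]")
  structure(
    list(conditions = conditions, forms = forms, gel = gel,
         replicates = replicates, mixing_ratio = mixing_ratio,
         peptides_per_protein = peptides_per_protein, noise = noise,
         seed = as.integer(seed)),
    class = "scenario_config")
}

#' Subunit rosters of the simulated mitochondrial complexes
#'
#' Gene-symbol rosters used by [default_scenario()] and
#' [default_annotation()]: the 38 quantified complex I subunits (with the
#' four N-module subunits flagged), the complex III, IV, II and V subunits,
#' the three complex IV assembly factors tracked by the scenario, the large
#' and small mitoribosomal subunit rosters, and the two mitoribosome assembly
#' factors DDX28 and ERAL1.
#'
#' @return Named list of character vectors (plus `cI_N_module`, the subset of
#'   `cI` flagged as N-module).
#' @export
oxphos_rosters <- function() {
  cI <- c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
          "MT-ND6",
          "NDUFV1", "NDUFV2", "NDUFS1", "NDUFS2", "NDUFS3", "NDUFS7",
          "NDUFS8",
          "NDUFA1", "NDUFA2", "NDUFA3", "NDUFA5", "NDUFA6", "NDUFA7",
          "NDUFA8", "NDUFA9", "NDUFA10", "NDUFA11", "NDUFA12", "NDUFA13",
          "NDUFAB1",
          "NDUFB1", "NDUFB2", "NDUFB3", "NDUFB4", "NDUFB5", "NDUFB6",
          "NDUFB7", "NDUFB8", "NDUFB9", "NDUFB10", "NDUFB11")
  list(
    cI = cI,
    cI_N_module = c("NDUFV1", "NDUFV2", "NDUFS1", "NDUFA2"),
    cIII = c("UQCRC1", "UQCRC2", "MT-CYB", "CYC1", "UQCRFS1", "UQCRB",
             "UQCRQ", "UQCRH"),
    cIV = c("MT-CO1", "MT-CO2", "MT-CO3", "COX5A", "COX5B", "COX6A1",
            "COX6B1", "COX6C", "NDUFA4"),
    cIV_assembly = c("COA3", "HIGD1A", "HIGD2A"),
    cII = c("SDHA", "SDHB", "SDHC", "SDHD"),
    cV = c("ATP5F1A", "ATP5F1B", "ATP5F1C", "ATP5F1D", "ATP5F1E",
           "ATP5PB", "ATP5PD", "ATP5PO", "ATP5MC1", "ATP5ME", "ATP5MF",
           "ATP5MG"),
    mtLSU = sprintf("MRPL%d", 1:40),
    mtSSU = sprintf("MRPS%d", 1:28),
    mtRibo_assembly = c("DDX28", "ERAL1"))
}

stoich <- function(ids, copies = 1L) setNames(rep(as.integer(copies), length(ids)), ids)

#' The default wild-type versus COX4 knock-out scenario
#'
#' Encodes the assembly-state phenotype of a HEK293 COX4I1/4I2 double
#' knock-out on a 64-slice 3-12% gradient blue-native gel: all assembled
#' complex IV forms absent except a 130 kDa MT-CO1/COA3/HIGD2A intermediate;
#' complex I depleted five-fold overall with the residual signal split
#' between the I III2 supercomplex and a ~750 kDa precomplex lacking the
#' N-module; complex III shifted from supercomplexes to its free dimer;
#' complex II unchanged; complex V mildly affected with F1 subassembly
#' accumulation; mitoribosomal proteins reduced 1.75-fold and the assembly
#' factors DDX28/ERAL1 halved.  Replicate 1 carries the heavy label on the
#' wild type, replicate 2 on the knock-out (label swap).
#'
#' @return A [scenario_config()].
#' @export
#' @examples
#' sc <- default_scenario()
#' sc$gel$n_slices
default_scenario <- function() {
  r <- oxphos_rosters()
  cI_all <- stoich(r$cI)
  cI_pre <- stoich(setdiff(r$cI, r$cI_N_module))  # precomplex lacks the N-module
  cIII2 <- stoich(r$cIII, 2L)
  cIV1 <- stoich(r$cIV)
  forms <- list(
    assembly_form("respirasome_I_III2_IV", 1700,
                  c(cI_all, cIII2, cIV1), c(wt = 60, KO = 0)),
    assembly_form("I_III2", 1500, c(cI_all, cIII2), c(wt = 25, KO = 12)),
    assembly_form("cI_monomer", 1000, cI_all, c(wt = 15, KO = 0)),
    assembly_form("cI_precomplex_750k", 750, cI_pre, c(wt = 0, KO = 8)),
    assembly_form("III2_IV", 730, c(cIII2, cIV1), c(wt = 15, KO = 0)),
    assembly_form("III2", 500, cIII2, c(wt = 25, KO = 45)),
    assembly_form("cIV_monomer", 215, cIV1, c(wt = 40, KO = 0)),
    assembly_form("cIV_dimer", 430, stoich(r$cIV, 2L), c(wt = 10, KO = 0)),
    assembly_form("sub_cIV_130k", 130,
                  stoich(c("MT-CO1", "COA3", "HIGD2A")), c(wt = 0, KO = 5)),
    assembly_form("free_pool_50k", 50,
                  stoich(c("COX5B", "NDUFA4", "HIGD1A", "HIGD2A")),
                  c(wt = 5, KO = 5)),
    assembly_form("cII", 125, stoich(r$cII), c(wt = 40, KO = 40)),
    assembly_form("cV_monomer", 700, stoich(r$cV), c(wt = 80, KO = 70)),
    assembly_form("cV_dimer", 1400, stoich(r$cV, 2L), c(wt = 10, KO = 5)),
    assembly_form("F1_subassembly", 370,
                  stoich(c("ATP5F1A", "ATP5F1B", "ATP5F1C", "ATP5F1D",
                           "ATP5F1E")), c(wt = 2, KO = 8)),
    assembly_form("mtLSU", 1650, stoich(r$mtLSU), c(wt = 35, KO = 20)),
    assembly_form("mtSSU", 850, stoich(r$mtSSU), c(wt = 35, KO = 20)),
    assembly_form("DDX28_free", 55, stoich("DDX28"), c(wt = 10, KO = 5)),
    assembly_form("ERAL1_free", 48, stoich("ERAL1"), c(wt = 10, KO = 5)))
  scenario_config(
    conditions = c("wt", "KO"), forms = forms, gel = gel_model(),
    replicates = c("wt", "KO"), mixing_ratio = 1,
    peptides_per_protein = c(3L, 8L), noise = default_noise(), seed = 101L)
}

#' All proteins appearing in a scenario
#'
#' @param scenario A `scenario_config`.
#' @return Sorted character vector of protein ids.
#' @export
scenario_proteins <- function(scenario) {
  sort(unique(unlist(lapply(scenario$forms, function(f) names(f$members)))))
}

#' Replicate-to-heavy-condition swap map of a scenario
#'
#' @param scenario A `scenario_config`.
#' @param experiment_id Experiment label used in the evidence table.
#' @return Data frame with columns `experiment_id`, `replicate`, `heavy`;
#'   the scenario's condition pair is attached as attribute `conditions`.
#' @export
scenario_swap_map <- function(scenario, experiment_id = "CP") {
  structure(
    data.frame(experiment_id = experiment_id,
               replicate = seq_along(scenario$replicates),
               heavy = scenario$replicates,
               stringsAsFactors = FALSE),
    conditions = scenario$conditions)
}

#' Default protein-to-complex annotation for the simulated proteome
#'
#' @return Data frame with columns `protein_id`, `complex_id`, `module_id`
#'   (`"N"` for the complex I N-module subunits, empty otherwise) and
#'   `display_order` (heatmap row order within the complex).
#' @export
default_annotation <- function() {
  r <- oxphos_rosters()
  blocks <- list(cI = r$cI, cII = r$cII, cIII = r$cIII, cIV = r$cIV,
                 cIV.AF = r$cIV_assembly, cV = r$cV,
                 mtLSU = r$mtLSU, mtSSU = r$mtSSU,
                 mtRibo.AF = r$mtRibo_assembly)
  ann <- do.call(rbind, lapply(names(blocks), function(cx) {
    data.frame(protein_id = blocks[[cx]], complex_id = cx,
               module_id = "", display_order = seq_along(blocks[[cx]]),
               stringsAsFactors = FALSE)
  }))
  ann$module_id[ann$protein_id %in% r$cI_N_module & ann$complex_id == "cI"] <- "N"
  rownames(ann) <- NULL
  ann
}

# ---- structured-text (YAML) scenario round trip -------------------------

#' Write a scenario configuration to a YAML file
#'
#' @param scenario A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  x <- list(
    conditions = as.list(scenario$conditions),
    forms = lapply(scenario$forms, function(f) {
      list(name = f$name, apparent_mass = f$apparent_mass,
           members = as.list(f$members),
           abundance = as.list(f$abundance))
    }),
    gel = unclass(scenario$gel),
    replicates = as.list(scenario$replicates),
    mixing_ratio = scenario$mixing_ratio,
    peptides_per_protein = as.list(scenario$peptides_per_protein),
    noise = scenario$noise,
    seed = scenario$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' The file must use the top-level keys `conditions`, `forms`, `gel`,
#' `replicates`, `mixing_ratio`, `peptides_per_protein`, `noise`, `seed`.
#'
#' @param path Path to the YAML file.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("conditions", "forms", "gel", "replicates")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("scenario config: missing key '%s'", miss[1L])
  forms <- lapply(x$forms, function(f)
    assembly_form(f$name, f$apparent_mass, unlist(f$members), unlist(f$abundance)))
  gel <- do.call(gel_model, x$gel)
  scenario_config(
    conditions = unlist(x$conditions), forms = forms, gel = gel,
    replicates = unlist(x$replicates),
    mixing_ratio = x$mixing_ratio %||% 1,
    peptides_per_protein = unlist(x$peptides_per_protein %||% c(3L, 8L)),
    noise = x$noise %||% list(),
    seed = x$seed %||% 101L)
}
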
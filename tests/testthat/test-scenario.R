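test_that("default scenario encodes the knock-out phenotype", {
  sc <- default_scenario()
  expect_equal(sc$gel$n_slices, 64L)
  expect_identical(unname(sc$conditions), c("wt", "KO"))
  expect_identical(sc$replicates, c("wt", "KO"))  # label swap

  roster <- oxphos_rosters()
  total_abundance <- function(protein, condition) {
    sum(vapply(sc$forms, function(f)
      if (protein %in% names(f$members))
        f$abundance[[condition]] * f$members[[protein]] else 0, 0))
  }
  # non-N-module complex I subunits are depleted exactly fivefold
  non_n <- setdiff(roster$cI, roster$cI_N_module)
  for (p in non_n[c(1, 10, 20)]) {
    expect_equal(total_abundance(p, "wt") / total_abundance(p, "KO"), 5.0)
  }
  # N-module subunits are depleted more (they miss the 750 kDa precomplex)
  for (p in roster$cI_N_module) {
    expect_gt(total_abundance(p, "wt") / total_abundance(p, "KO"), 5.0)
  }
  # complex II unchanged
  for (p in roster$cII) {
    expect_equal(total_abundance(p, "wt") / total_abundance(p, "KO"), 1.0)
  }
  # mitoribosome reduced 1.75-fold, assembly factors halved
  expect_equal(total_abundance("MRPL1", "wt") / total_abundance("MRPL1", "KO"),
               1.75)
  expect_equal(total_abundance("DDX28", "wt") / total_abundance("DDX28", "KO"),
               2.0)
  # assembled complex IV absent in KO: MT-CO2/MT-CO3 have zero KO abundance
  expect_equal(total_abundance("MT-CO2", "KO"), 0)
  expect_equal(total_abundance("MT-CO3", "KO"), 0)
})

test_that("form positions follow the log-linear migration model", {
  gel <- gel_model()
  # closed-form evaluation of the mapping
  expected <- function(mass) 1 + (3.5 - log10(mass)) * 63 / 2
  expect_equal(form_center_slice(3162.3, gel), 1.0, tolerance = 1e-3)
  expect_equal(form_center_slice(130, gel), expected(130), tolerance = 1e-12)
  expect_equal(form_center_slice(130, gel), 44.66, tolerance = 1e-2)
  expect_equal(form_center_slice(750, gel), expected(750), tolerance = 1e-12)
  expect_equal(form_center_slice(750, gel), 20.69, tolerance = 1e-2)

  # strictly decreasing in mass
  masses <- sort(10^runif(25, gel$log10_mass_bottom, gel$log10_mass_top))
  slices <- vapply(masses, form_center_slice, 0, gel = gel)
  expect_true(all(diff(slices) < 0))

  bad <- assembly_form("too_heavy", 5000, c(X = 1L), c(wt = 1, KO = 1))
  expect_error(form_center_slice(bad, gel), "too_heavy")
})

test_that("simulation is deterministic and censoring drops rows entirely", {
  sc <- default_scenario()
  ev1 <- simulate_evidence(sc, seed = 11)
  ev2 <- simulate_evidence(sc, seed = 11)
  expect_identical(ev1, ev2)
  ev3 <- simulate_evidence(sc, seed = 12)
  expect_false(identical(ev1, ev3))

  # censored observations are absent rows, never zero-intensity rows
  expect_true(all(ev1$intensity >= sc$noise$detection_floor))
  expect_true(all(ev1$intensity > 0))

  # proteins present only in KO-absent forms yield no KO-condition rows
  mapped <- map_channels_to_conditions(ev1, scenario_swap_map(sc))
  expect_equal(sum(mapped$condition == "KO" &
                     mapped$protein_id %in% c("MT-CO2", "MT-CO3")), 0)
  # but they are present in wt
  expect_gt(sum(mapped$condition == "wt" & mapped$protein_id == "MT-CO2"), 0)
})

test_that("noise-free simulation reproduces the closed-form signal", {
  sc <- toy_noisefree_scenario()
  ev <- simulate_evidence(sc, seed = 1)
  mapped <- map_channels_to_conditions(ev, scenario_swap_map(sc))
  share <- 0.5  # 1:1 mixing
  for (p in c("A", "B", "C")) {
    for (cond in c("ref", "pert")) {
      want <- toy_expected_signal(sc, p, cond) * share
      for (r in 1:2) {
        got <- numeric(sc$gel$n_slices)
        rows <- mapped$protein_id == p & mapped$condition == cond &
          mapped$replicate == r
        got[mapped$slice_index[rows]] <- mapped$intensity[rows]
        expect_equal(got, want, tolerance = 1e-14)
      }
    }
  }
})

test_that("summed noise-free intensity conserves abundance x stoichiometry x share", {
  sc <- toy_noisefree_scenario()
  ev <- simulate_evidence(sc, seed = 3)
  mapped <- map_channels_to_conditions(ev, scenario_swap_map(sc))
  expected_total <- function(p, cond) {
    0.5 * sum(vapply(sc$forms, function(f)
      if (p %in% names(f$members))
        f$abundance[[cond]] * f$members[[p]] else 0, 0))
  }
  for (p in c("A", "B", "C")) {
    for (cond in c("ref", "pert")) {
      for (r in 1:2) {
        rows <- mapped$protein_id == p & mapped$condition == cond &
          mapped$replicate == r
        expect_equal(sum(mapped$intensity[rows]), expected_total(p, cond),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("swapping the heavy label only relabels channels", {
  sc <- default_scenario()
  sc_swapped <- sc
  sc_swapped$replicates <- rev(sc$replicates)
  ev_a <- map_channels_to_conditions(simulate_evidence(sc, seed = 5),
                                     scenario_swap_map(sc))
  ev_b <- map_channels_to_conditions(simulate_evidence(sc_swapped, seed = 5),
                                     scenario_swap_map(sc_swapped))
  drop_channel <- function(x) x[order(x$replicate, x$slice_index, x$protein_id,
                                      x$peptide_sequence, x$condition),
                                setdiff(names(x), "channel")]
  expect_equal(drop_channel(ev_a), drop_channel(ev_b),
               ignore_attr = TRUE)
  expect_false(identical(ev_a$channel, ev_b$channel))
})

test_that("a scenario survives the YAML config round trip", {
  sc <- toy_noisefree_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(sc, path)
  sc2 <- read_scenario_config(path)
  expect_identical(simulate_evidence(sc, seed = 9),
                   simulate_evidence(sc2, seed = 9))
})
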
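test_that("channel splitting partitions the evidence", {
  ev <- bind_evidence(
    evidence_row(1, 1, "P1", "AAK", "light", 1),
    evidence_row(1, 2, "P1", "AAK", "light", 2),
    evidence_row(1, 3, "P1", "AAK", "light", 3),
    evidence_row(1, 1, "P1", "AAK", "heavy", 4),
    evidence_row(1, 2, "P1", "AAK", "heavy", 5))
  parts <- split_channels(ev)
  expect_equal(nrow(parts$light), 3L)
  expect_equal(nrow(parts$heavy), 2L)
  expect_equal(nrow(parts$light) + nrow(parts$heavy), nrow(ev))
  # partition then concatenate equals the input as a multiset
  recombined <- rbind(parts$light, parts$heavy)
  key <- function(x) sort(do.call(paste, x))
  expect_identical(key(recombined), key(ev))

  all_heavy <- ev[ev$channel == "heavy", ]
  expect_warning(parts <- split_channels(all_heavy), "empty")
  expect_equal(nrow(parts$light), 0L)
})

test_that("channels map to conditions through the label-swap table", {
  ev <- bind_evidence(
    evidence_row(1, 1, "P1", "AAK", "heavy", 1),
    evidence_row(1, 1, "P1", "AAK", "light", 1),
    evidence_row(2, 1, "P1", "AAK", "heavy", 1),
    evidence_row(2, 1, "P1", "AAK", "light", 1))
  sm <- data.frame(experiment_id = "CP", replicate = 1:2,
                   heavy = c("wt", "KO"))
  mapped <- map_channels_to_conditions(ev, sm, conditions = c("wt", "KO"))
  expect_identical(mapped$condition, c("wt", "KO", "KO", "wt"))

  ev3 <- rbind(ev, evidence_row(3, 1, "P1", "AAK", "light", 1))
  expect_error(map_channels_to_conditions(ev3, sm, conditions = c("wt", "KO")),
               "replicate 3")
})

test_that("the representative peptide must be seen in both channels", {
  # A: 5 distinct cells across both channels; B: 7 cells, light only
  ev <- bind_evidence(
    evidence_row(1, 1, "P1", "AAAK", "light", 10),
    evidence_row(1, 1, "P1", "AAAK", "heavy", 10),
    evidence_row(1, 2, "P1", "AAAK", "heavy", 10),
    evidence_row(2, 1, "P1", "AAAK", "light", 10),
    evidence_row(2, 2, "P1", "AAAK", "heavy", 10),
    evidence_row(1, 1, "P1", "BBBK", "light", 99),
    evidence_row(1, 2, "P1", "BBBK", "light", 99),
    evidence_row(1, 3, "P1", "BBBK", "light", 99),
    evidence_row(1, 4, "P1", "BBBK", "light", 99),
    evidence_row(2, 1, "P1", "BBBK", "light", 99),
    evidence_row(2, 2, "P1", "BBBK", "light", 99),
    evidence_row(2, 3, "P1", "BBBK", "light", 99))
  pick <- select_representative_peptide(ev)
  expect_identical(pick$peptide, "AAAK")
  expect_equal(pick$n_cells, 5L)
  expect_true(pick$both_channels)

  # tie on cells: the larger summed intensity wins
  tie <- bind_evidence(
    evidence_row(1, 1:4, "P1", "AK", c("light", "heavy", "light", "heavy"),
                 c(100, 200, 300, 300)),
    evidence_row(1, 1:4, "P1", "BK", c("light", "heavy", "light", "heavy"),
                 c(250, 250, 250, 250)))
  expect_identical(select_representative_peptide(tie)$peptide, "BK")

  # full tie: lexicographically smallest sequence
  tie$intensity <- 1
  expect_identical(select_representative_peptide(tie)$peptide, "AK")

  # single-channel fallback is flagged
  light_only <- ev[ev$channel == "light", ]
  pick <- select_representative_peptide(light_only)
  expect_identical(pick$peptide, "BBBK")
  expect_identical(pick$flags, "single-channel-representative")

  expect_error(select_representative_peptide(ev[0, ]), "no evidence")
})

test_that("raw profiles sum the representative peptide per slice", {
  ev <- bind_evidence(
    evidence_row(1, 10, "P1", "AAK", "heavy", 200),
    evidence_row(1, 11, "P1", "AAK", "heavy", 600),
    evidence_row(1, 11, "P1", "AAK", "heavy", 50),  # re-measurement, same slice
    evidence_row(1, 11, "P1", "CCK", "heavy", 999))
  sm <- data.frame(experiment_id = "CP", replicate = 1, heavy = "wt")
  mapped <- map_channels_to_conditions(ev, sm, conditions = c("wt", "KO"))
  prof <- build_raw_profile(mapped, "P1", "wt", 1, "AAK", 16)
  want <- numeric(16)
  want[10] <- 200
  want[11] <- 650
  expect_equal(prof$values, want)
  # absent condition: all-zero vector
  prof_ko <- build_raw_profile(mapped, "P1", "KO", 1, "AAK", 16)
  expect_equal(prof_ko$values, numeric(16))
})

test_that("replicates are averaged raw and then max-normalised once", {
  p1 <- migration_profile("P1", "wt", c(2, 4, 0))
  p2 <- migration_profile("P1", "wt", c(4, 8, 0))
  avg <- average_and_normalize(list(p1, p2))
  expect_equal(avg$values, c(0.5, 1.0, 0.0))
  expect_true(avg$normalized)

  single <- average_and_normalize(list(migration_profile("P1", "wt", c(0, 5))))
  expect_equal(single$values, c(0, 1))

  zero <- average_and_normalize(list(migration_profile("P1", "wt", c(0, 0))))
  expect_true("undetected" %in% zero$flags)
  expect_equal(zero$values, c(0, 0))

  expect_error(average_and_normalize(list(p1, migration_profile("P1", "wt", 1))),
               "length")
})

test_that("profile construction matches a brute-force row loop", {
  for (seed in 1:5) {
    ev <- random_small_evidence(seed)
    sm <- data.frame(experiment_id = "CP", replicate = 1:2,
                     heavy = c("wt", "KO"))
    mapped <- map_channels_to_conditions(ev, sm, conditions = c("wt", "KO"))
    for (p in unique(mapped$protein_id)) {
      pep <- select_representative_peptide(mapped, p)$peptide
      for (cond in c("wt", "KO")) {
        for (r in 1:2) {
          got <- build_raw_profile(mapped, p, cond, r, pep, 10)$values
          expect_identical(got, brute_profile(mapped, p, cond, r, pep, 10))
        }
      }
    }
  }
})

test_that("outputs are invariant to evidence row order", {
  ev <- random_small_evidence(42)
  sm <- data.frame(experiment_id = "CP", replicate = 1:2,
                   heavy = c("wt", "KO"))
  mapped <- map_channels_to_conditions(ev, sm, conditions = c("wt", "KO"))
  set.seed(1)
  shuffled <- mapped[sample(nrow(mapped)), ]
  ps1 <- build_profiles(mapped, 10, c("wt", "KO"))
  ps2 <- build_profiles(shuffled, 10, c("wt", "KO"))
  for (key in names(ps1$profiles))
    expect_equal(ps1$profiles[[key]]$values, ps2$profiles[[key]]$values)
  r1 <- protein_ratios(mapped, c("wt", "KO"))
  r2 <- protein_ratios(shuffled, c("wt", "KO"))
  expect_equal(r1, r2)
})

test_that("every detected profile is normalised to max exactly 1", {
  run <- default_full_run(101)
  for (prof in run$profiles$profiles) {
    if (any(prof$values > 0)) {
      expect_identical(max(prof$values), 1)
    } else {
      expect_true("undetected" %in% prof$flags)
    }
  }
})

test_that("protein ratios combine replicates by geometric mean", {
  mk_rows <- function(rep, cond_int) {
    # one peptide, two slices per condition
    rbind(
      evidence_row(rep, 5, "P1", "AAK",
                   if (rep == 1) "heavy" else "light", cond_int[["wt"]] / 2),
      evidence_row(rep, 6, "P1", "AAK",
                   if (rep == 1) "heavy" else "light", cond_int[["wt"]] / 2),
      evidence_row(rep, 5, "P1", "AAK",
                   if (rep == 1) "light" else "heavy", cond_int[["KO"]] / 2),
      evidence_row(rep, 6, "P1", "AAK",
                   if (rep == 1) "light" else "heavy", cond_int[["KO"]] / 2))
  }
  sm <- data.frame(experiment_id = "CP", replicate = 1:2,
                   heavy = c("wt", "KO"))
  ev <- rbind(mk_rows(1, c(wt = 100, KO = 20)), mk_rows(2, c(wt = 100, KO = 20)))
  mapped <- map_channels_to_conditions(ev, sm, conditions = c("wt", "KO"))
  pr <- protein_ratio(mapped, "P1", c("wt", "KO"))
  expect_equal(unname(pr$per_replicate), c(5, 5))
  expect_equal(pr$ratio, 5.0)

  ev_eq <- rbind(mk_rows(1, c(wt = 80, KO = 80)), mk_rows(2, c(wt = 80, KO = 80)))
  mapped_eq <- map_channels_to_conditions(ev_eq, sm, conditions = c("wt", "KO"))
  expect_equal(protein_ratio(mapped_eq, "P1", c("wt", "KO"))$ratio, 1.0)

  # perturbed channel empty in both replicates: flagged, no numeric ratio
  ev_abs <- ev
  mapped_abs <- map_channels_to_conditions(ev_abs, sm, conditions = c("wt", "KO"))
  mapped_abs <- mapped_abs[mapped_abs$condition == "wt", ]
  pr_abs <- protein_ratio(mapped_abs, "P1", c("wt", "KO"))
  expect_identical(pr_abs$flag, "absent-in-perturbed")
  expect_true(is.na(pr_abs$ratio))

  expect_error(protein_ratio(mapped[0, ], "P1", c("wt", "KO")), "absent")
})

test_that("unchanged proteins have ratio exactly 1 in the noise-free limit", {
  sc <- toy_noisefree_scenario()
  ev <- simulate_evidence(sc, seed = 2)
  mapped <- map_channels_to_conditions(ev, scenario_swap_map(sc))
  # protein B sits only in the dimer, whose abundance is equal in both
  # conditions
  pr <- protein_ratio(mapped, "B", c("ref", "pert"))
  expect_identical(pr$ratio, 1)
  # protein C doubles: 4 -> 8
  expect_equal(protein_ratio(mapped, "C", c("ref", "pert"))$ratio, 0.5,
               tolerance = 1e-12)
})

test_that("unchanged proteins stay near ratio 1 at default noise", {
  # complex II subunits are equal in both conditions; across seeds at least
  # 95% of their recovered ratios must fall in [0.9, 1.1]
  cII <- oxphos_rosters()$cII
  ratios <- unlist(lapply(1:20, function(seed) {
    rt <- default_ratio_run(seed)
    rt$ratio[rt$protein_id %in% cII]
  }))
  expect_equal(length(ratios), 80L)
  expect_gte(mean(ratios >= 0.9 & ratios <= 1.1), 0.95)
})

test_that("label-swap and no-swap designs agree on recovered ratios", {
  sc <- default_scenario()
  sc_noswap <- sc
  sc_noswap$replicates <- c("wt", "wt")
  ev_a <- map_channels_to_conditions(simulate_evidence(sc, seed = 31),
                                     scenario_swap_map(sc))
  ev_b <- map_channels_to_conditions(simulate_evidence(sc_noswap, seed = 31),
                                     scenario_swap_map(sc_noswap))
  ra <- protein_ratios(ev_a, sc$conditions)
  rb <- protein_ratios(ev_b, sc$conditions)
  shared <- intersect(ra$protein_id[!is.na(ra$ratio)],
                      rb$protein_id[!is.na(rb$ratio)])
  la <- log(ra$ratio[match(shared, ra$protein_id)])
  lb <- log(rb$ratio[match(shared, rb$protein_id)])
  expect_gt(cor(la, lb), 0.98)
  expect_lt(median(abs(la - lb)), 0.1)
})
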
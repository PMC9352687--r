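test_that("simulate_clones honors event counts and determinism", {
  cfg0 <- simulation_config(seed = 1, n_ancestral_events = 0, n_subclones = 1,
                            n_events_per_subclone = 0)
  cl0 <- simulate_clones(cfg0)
  expect_true(all(cl0$ancestor == 2L))
  expect_true(all(cl0$subclones[[1]] == 2L))
  cfg <- simulation_config(seed = 1)
  expect_identical(simulate_clones(cfg, seed = 99), simulate_clones(cfg, seed = 99))
  # 20 seeds at 5 ancestral events: every clone deviates from diploid
  for (s in 1:20) {
    cl <- simulate_clones(simulation_config(seed = s), seed = s)
    expect_true(any(cl$ancestor != 2L))
    for (sub in cl$subclones) expect_true(any(sub != 2L))
    expect_true(all(cl$ancestor >= 0L))
    for (sub in cl$subclones) expect_true(all(sub >= 0L))
    # breakpoints snap to the 100-kb lattice
    expect_true(all(cl$segments$start %% 1e5 == 0))
    expect_true(all(cl$segments$end %% 1e5 == 0))
  }
})

test_that("expected_segment_cn mixes clones by fraction", {
  segs <- data.frame(chrom = "1", start = 0, end = 1e5)
  one <- clonal_mixture(segs, list(3L), 1)
  expect_equal(as.numeric(expected_segment_cn(one)), 3)
  half <- clonal_mixture(segs, list(2L, 4L), c(0.5, 0.5))
  expect_equal(as.numeric(expected_segment_cn(half)), 3)
  skew <- clonal_mixture(segs, list(2L, 3L), c(0.8, 0.2))
  q <- expected_segment_cn(skew)
  expect_equal(as.numeric(q), 2.2)
  expect_equal(attr(q, "tau"), 2.2)
  expect_error(clonal_mixture(segs, list(2L, 3L), c(0.5, 0.4)), "sum to 1")
})

test_that("observe_profile implements the forward mixture model", {
  segs <- data.frame(chrom = rep("1", 4), start = (0:3) * 1e5,
                     end = (1:4) * 1e5)
  dip <- clonal_mixture(segs, list(rep(2L, 4)), 1)
  p <- observe_profile(dip, 1, 0, sample_id = "d", genome = genome_model("1", 4e5))
  expect_equal(p$segments$log_ratio, rep(0, 4))
  # q = 4 in a tau = 2 tumor at alpha = 1 -> log ratio exactly 1
  mix <- clonal_mixture(segs, list(c(4L, 1L, 1L, 2L)), 1)
  p2 <- observe_profile(mix, 1, 0, sample_id = "m", genome = genome_model("1", 4e5))
  expect_equal(p2$segments$log_ratio[1], 1)
  # q = 3, tau = 2, alpha = 0.5 -> r = 1.25
  mix3 <- clonal_mixture(segs[1:2, ], list(c(3L, 1L)), 1)
  p3 <- observe_profile(mix3, 0.5, 0, sample_id = "h",
                        genome = genome_model("1", 4e5))
  expect_equal(p3$segments$log_ratio[1], log2(1.25), tolerance = 1e-12)
  # zero-noise weighted mean relative copy number is 1
  w <- p3$segments$end - p3$segments$start
  expect_equal(sum(w * 2^p3$segments$log_ratio) / sum(w), 1, tolerance = 1e-12)
  # noise is seeded deterministically
  n1 <- observe_profile(dip, 0.8, 0.1, seed = 7, sample_id = "n",
                        genome = genome_model("1", 4e5))
  n2 <- observe_profile(dip, 0.8, 0.1, seed = 7, sample_id = "n",
                        genome = genome_model("1", 4e5))
  n3 <- observe_profile(dip, 0.8, 0.1, seed = 8, sample_id = "n",
                        genome = genome_model("1", 4e5))
  expect_identical(n1$segments$log_ratio, n2$segments$log_ratio)
  expect_false(identical(n1$segments$log_ratio, n3$segments$log_ratio))
})

test_that("simulate_patient realizes both seeding modes", {
  # monoclonal with a single eventless subclone: metastasis truth = ancestor
  cfg <- simulation_config(seed = 2, n_subclones = 1,
                           n_events_per_subclone = 0, seeding = "monoclonal")
  pat <- simulate_patient(cfg, seed = 2, patient_id = "m")
  expect_identical(pat$truth$metastasis$clones[[1]],
                   simulate_clones(cfg, seed = 2)$ancestor)
  expect_identical(pat$truth$metastasis$fractions, 1)
  # polyclonal: metastasis keeps all clones, perturbed fractions
  cfgp <- simulation_config(seed = 3, seeding = "polyclonal")
  patp <- simulate_patient(cfgp, seed = 3, patient_id = "p")
  expect_length(patp$truth$metastasis$clones,
                length(patp$truth$primary$clones))
  expect_false(identical(patp$truth$metastasis$fractions,
                         patp$truth$primary$fractions))
  expect_lt(max(abs(patp$truth$metastasis$fractions -
                      patp$truth$primary$fractions)), 0.35)
  # determinism of the whole patient object
  expect_identical(simulate_patient(cfgp, seed = 3, patient_id = "p"), patp)
  # truth table carries purity within the configured range
  expect_true(all(patp$truth$samples$true_purity >= 0.4 &
                    patp$truth$samples$true_purity <= 0.9))
})

test_that("simulate_cohort writes a consistent, reproducible bundle", {
  cfg <- simulation_config(seed = 9, genome = tg(4), n_ancestral_events = 3,
                           n_subclones = 2, n_events_per_subclone = 3)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  coh1 <- simulate_cohort(cfg, n_patients_per_mode = 2, seed = 9, dir = dir1)
  coh2 <- simulate_cohort(cfg, n_patients_per_mode = 2, seed = 9, dir = dir2)
  expect_length(coh1$profiles, 8L)
  expect_identical(nrow(coh1$sample_sheet), 8L)
  expect_setequal(unique(coh1$sample_sheet$group),
                  c("polyclonal", "monoclonal"))
  # byte-identical SEG for identical seeds
  expect_identical(readLines(coh1$paths$seg), readLines(coh2$paths$seg))
  expect_identical(readLines(coh1$paths$sheet), readLines(coh2$paths$sheet))
  # round-trip: re-read profiles equal the generated ones at 6 decimals
  back <- read_seg(coh1$paths$seg, cfg$genome)
  expect_setequal(names(back), names(coh1$profiles))
  for (id in names(back)) {
    expect_equal(back[[id]]$segments$log_ratio,
                 round(coh1$profiles[[id]]$segments$log_ratio, 6))
    expect_equal(back[[id]]$segments$start, coh1$profiles[[id]]$segments$start)
  }
})

test_that("clone_with_ploidy hits the requested ploidy exactly", {
  for (tau in c(1.5, 2, 2.37, 3.8, 5)) {
    mix <- clone_with_ploidy(tau, seed = 11)
    q <- expected_segment_cn(mix)
    expect_equal(attr(q, "tau"), tau, tolerance = 1e-12)
    expect_true(all(q == floor(q)))
  }
  expect_error(clone_with_ploidy(2.3456), "integral")
})
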
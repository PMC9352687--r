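test_that("pair_distance_at matches hand arithmetic", {
  g <- genome_model("1", 200)
  # q1 = (2, 3) at (1, 2.5); q2 = (2, 2) at (1, 2); equal weights
  a <- make_profile("a", g, c("1", "1"), c(0, 100), c(100, 200),
                    log2(c(0.8, 1.2)))
  b <- make_profile("b", g, c("1", "1"), c(0, 100), c(100, 200), c(0, 0))
  h <- harmonize_pair(a, b)
  d <- pair_distance_at(h, purity_ploidy(1, 2.5), purity_ploidy(1, 2))
  expect_equal(d, 0.5 / 0.4330127018922193, tolerance = 1e-12)
  # any profile against itself at identical parameters
  hs <- harmonize_pair(a, a)
  expect_identical(pair_distance_at(hs, purity_ploidy(0.5, 2.2),
                                    purity_ploidy(0.5, 2.2)), 0)
  # symmetric under swapping profiles with their parameters
  h2 <- harmonize_pair(b, a)
  expect_equal(pair_distance_at(h2, purity_ploidy(1, 2), purity_ploidy(1, 2.5)),
               d)
})

test_that("degenerate flat-vs-flat pairs follow the stated rule", {
  g <- genome_model("1", 100)
  a <- make_profile("a", g, "1", 0, 100, 0)
  # equal flats: zero numerator, zero SD -> distance 0
  h <- harmonize_pair(a, a)
  expect_identical(pair_distance_at(h, purity_ploidy(1, 2), purity_ploidy(1, 2),
                                    normalize = FALSE), 0)
  # unequal flats: pooled SD is |m1 - m2| / 2, so d = 2 (not degenerate)
  b <- make_profile("b", g, "1", 0, 100, 0.3)
  hab <- harmonize_pair(a, b)
  expect_equal(pair_distance_at(hab, purity_ploidy(1, 2), purity_ploidy(1, 2),
                                normalize = FALSE), 2)
  # knife-edge: s below 1e-9 with numerator still above -> +Inf (excluded)
  bb <- make_profile("bb", g, "1", 0, 100, log2((2 + 1.5e-9) / 2))
  hb <- harmonize_pair(a, bb)
  expect_identical(pair_distance_at(hb, purity_ploidy(1, 2), purity_ploidy(1, 2),
                                    normalize = FALSE), Inf)
})

test_that("grid scans agree with the brute-force oracle on tiny grids", {
  grid <- search_grid(alpha_step = 0.2, tau_step = 0.5)
  for (seed in 1:3) {
    pat <- small_patient(seed, noise_sd = 0.05)
    a <- pat$observed[[1]]; b <- pat$observed[[2]]
    want <- oracle_pair_min(a, b, grid)
    ex <- pair_distance_minimize(a, b, grid, strategy = "exhaustive")
    cf <- pair_distance_minimize(a, b, grid, strategy = "coarse_to_fine")
    expect_equal(ex$d, want, tolerance = 1e-12)
    expect_equal(cf$d, want, tolerance = 1e-12)
    # argmin reproduces its own distance through the naive evaluator
    h <- harmonize_pair(a, b)
    expect_equal(pair_distance_at(h, ex$best$pp_a, ex$best$pp_b), ex$d,
                 tolerance = 1e-12)
    # exhaustive symmetry in d
    ex2 <- pair_distance_minimize(b, a, grid, strategy = "exhaustive")
    expect_equal(ex2$d, ex$d, tolerance = 1e-12)
  }
})

test_that("coarse_to_fine never beats exhaustive and records bookkeeping", {
  grid <- search_grid(alpha_step = 0.1, tau_step = 0.25)
  pat <- small_patient(7, noise_sd = 0.05)
  a <- pat$observed[[1]]; b <- pat$observed[[2]]
  ex <- pair_distance_minimize(a, b, grid, strategy = "exhaustive")
  cf <- pair_distance_minimize(a, b, grid, strategy = "coarse_to_fine")
  expect_gte(cf$d + 1e-12, ex$d)
  expect_identical(ex$strategy, "exhaustive")
  expect_identical(cf$strategy, "coarse_to_fine")
  expect_equal(ex$n_grid_evaluated,
               (length(grid$alpha) * length(grid$tau))^2)
  expect_true(cf$best$pp_a$alpha %in% grid$alpha)
  expect_true(cf$best$pp_b$tau %in% grid$tau)
})

test_that("self-distance is exactly zero on the default grid", {
  for (seed in 1:3) {
    pat <- small_patient(seed, noise_sd = 0.05)
    p <- pat$observed[[1]]
    expect_identical(pair_distance_minimize(p, p)$d, 0)
  }
})

test_that("patient_distance crosses primaries with metastases", {
  g <- genome_model("1", 100)
  mk <- function(id) make_profile(id, g, "1", 0, 100, 0)
  # injected pair distances 1..6 for a 2 x 3 design
  counter <- new.env(); counter$i <- 0
  stub <- function(a, b, ...) {
    counter$i <- counter$i + 1
    structure(list(d = counter$i,
                   best = list(pp_a = purity_ploidy(1, 2),
                               pp_b = purity_ploidy(1, 2)),
                   strategy = "stub", n_grid_evaluated = 1L,
                   sample_a = a$sample_id, sample_b = b$sample_id),
              class = "pair_distance_result")
  }
  res <- patient_distance(list(mk("p1"), mk("p2")),
                          list(mk("m1"), mk("m2"), mk("m3")),
                          patient_id = "pt", pair_fun = stub)
  expect_identical(res$n_pairs, 6L)
  expect_equal(res$mean_d, 3.5)
  expect_identical(res$pairs$sample_a,
                   rep(c("p1", "p2"), each = 3))
  # single pair: mean is that distance; identical lesions give 0
  pat <- small_patient(2)
  p <- pat$observed[[1]]
  res2 <- patient_distance(list(p), list(p), patient_id = "self")
  expect_identical(res2$mean_d, 0)
  expect_identical(res2$n_pairs, 1L)
  expect_error(patient_distance(list(), list(p)), "no primary")
})

test_that("cohort_distances validates the sheet and orders patients", {
  coh <- simulate_cohort(
    simulation_config(seed = 4, genome = tg(4), n_ancestral_events = 3,
                      n_subclones = 2, n_events_per_subclone = 3),
    n_patients_per_mode = 1, seed = 4)
  grid <- search_grid(alpha_step = 0.1, tau_step = 0.25)
  res <- cohort_distances(coh$sample_sheet, coh$profiles, grid = grid)
  expect_identical(nrow(res$patients), 2L)
  expect_identical(res$patients$patient_id,
                   sort(unique(coh$sample_sheet$patient_id)))
  expect_identical(names(res$pairs),
                   c("patient_id", "sample_a", "sample_b", "d",
                     "alpha_a", "tau_a", "alpha_b", "tau_b"))
  bad <- coh$sample_sheet
  bad$sample_id[1] <- "GHOST"
  expect_error(cohort_distances(bad, coh$profiles, grid = grid), "GHOST")
  noprim <- coh$sample_sheet[coh$sample_sheet$role == "metastasis", ]
  expect_error(cohort_distances(noprim, coh$profiles, grid = grid),
               "no primary")
})
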
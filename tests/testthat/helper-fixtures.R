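# Shared fixtures and independent oracles. Oracles deliberately use the
# naive per-point R code path (pair_distance_at / cnh_at double loops), so
# they stay independent of the vectorized/C++ scans they check.

tg <- function(n = 4, len = 1e7) toy_genome(n, len)

# quick profile builder on a given genome
make_profile <- function(id, genome, chrom, start, end, log_ratio,
                         num_mark = NA_integer_) {
  segmented_profile(id, genome, data.frame(
    chrom = chrom, start = start, end = end,
    log_ratio = log_ratio, num_mark = num_mark, stringsAsFactors = FALSE))
}

# small simulated patient for fast distance tests
small_patient <- function(seed, ...) {
  cfg <- simulation_config(seed = seed, genome = tg(4),
                           n_ancestral_events = 3, n_subclones = 2,
                           n_events_per_subclone = 3, ...)
  simulate_patient(cfg, seed = seed, patient_id = paste0("S", seed))
}

# exhaustive CNH oracle: per-point cnh_at over the whole grid, then the
# package's stated tie-break applied from scratch
oracle_cnh <- function(profile, grid) {
  vals <- expand.grid(alpha = grid$alpha, tau = grid$tau)
  vals$cnh <- mapply(function(a, t) cnh_at(profile, purity_ploidy(a, t)),
                     vals$alpha, vals$tau)
  best <- min(vals$cnh)
  ties <- vals[vals$cnh <= best + 1e-12, , drop = FALSE]
  pick <- ties[order(ties$tau, -ties$alpha)[1L], ]
  list(cnh = pick$cnh, alpha = pick$alpha, tau = pick$tau, n_ties = nrow(ties))
}

# brute-force pair-distance oracle: quadruple loop over all grid-point pairs
oracle_pair_min <- function(a, b, grid) {
  h <- harmonize_pair(a, b)
  best <- Inf
  for (t1 in grid$tau) for (a1 in grid$alpha) {
    pa <- purity_ploidy(a1, t1)
    for (t2 in grid$tau) for (a2 in grid$alpha) {
      d <- pair_distance_at(h, pa, purity_ploidy(a2, t2))
      if (d < best) best <- d
    }
  }
  best
}

# per-bp value lookup for harmonization spot checks (tiny genomes only)
bp_values <- function(profile, chrom, len) {
  v <- rep(NA_real_, len)
  s <- profile$segments[profile$segments$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(s))) v[(s$start[i] + 1):s$end[i]] <- s$log_ratio[i]
  v
}

# subclone differing from `cn` by n_events disjoint single-copy runs: every
# differing segment differs by exactly +/-1 copy, keeping the CNH mixing
# ladder in its identifiable regime (see the methods vignette)
single_copy_subclone <- function(cn, n_events = 5, seed = 1) {
  set.seed(seed)
  used <- rep(FALSE, length(cn))
  c2 <- cn
  done <- 0
  while (done < n_events) {
    i <- sample.int(length(cn) - 3, 1)
    run <- i:(i + sample.int(3, 1))
    if (any(used[run])) next
    delta <- sample(c(-1L, 1L), 1)
    if (any(c2[run] + delta < 0)) delta <- 1L
    c2[run] <- c2[run] + delta
    used[run] <- TRUE
    done <- done + 1
  }
  c2
}
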
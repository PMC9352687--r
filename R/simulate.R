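#' Simulation configuration
#'
#' The stated world of the simulator: integer-copy-number clones on a toy
#' genome, normal-cell dilution at a sampled purity, Gaussian segment-level
#' noise on the log2 ratios, and two metastatic seeding modes. Defaults: 22
#' autosomes of 10 Mb with breakpoints on a 100-kb lattice, 5 ancestral
#' events, 3 subclones with 5 private events each, purity drawn uniformly
#' from \[0.4, 0.9\], log2 noise SD 0.05, one primary and one metastasis
#' sample per patient.
#'
#' @param seed integer master seed.
#' @param genome a [genome_model()]; default [toy_genome()].
#' @param lattice breakpoint lattice in bp (event boundaries snap to it).
#' @param n_ancestral_events truncal copy-number events shared by all clones.
#' @param n_subclones number of subclones derived from the ancestor.
#' @param n_events_per_subclone private events per subclone.
#' @param purity_range length-2 vector in `[0.2, 1]`; per-sample purity is
#'   drawn uniformly from it.
#' @param noise_sd Gaussian noise SD on segment log2 ratios (log2 units).
#' @param seeding `"polyclonal"` (metastasis inherits the primary clone
#'   mixture) or `"monoclonal"` (metastasis founded by a single subclone).
#' @param n_primary,n_metastasis samples observed per lesion.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome = toy_genome(),
                              lattice = 1e5,
                              n_ancestral_events = 5L,
                              n_subclones = 3L,
                              n_events_per_subclone = 5L,
                              purity_range = c(0.4, 0.9),
                              noise_sd = 0.05,
                              seeding = c("polyclonal", "monoclonal"),
                              n_primary = 1L,
                              n_metastasis = 1L) {
  seeding <- match.arg(seeding)
  stopifnot(inherits(genome, "genome_model"))
  if (n_ancestral_events < 0 || n_subclones < 1 || n_events_per_subclone < 0) {
    stop("event/subclone counts out of range")
  }
  if (n_primary < 1 || n_metastasis < 1) stop("need >= 1 sample per lesion")
  if (length(purity_range) != 2L || purity_range[1] > purity_range[2] ||
      purity_range[1] < 0.2 || purity_range[2] > 1) {
    stop("purity_range must be within [0.2, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (lattice <= 0 || any(genome$length %% lattice != 0)) {
    stop("chromosome lengths must be multiples of the breakpoint lattice")
  }
  structure(
    list(seed = as.integer(seed), genome = genome, lattice = lattice,
         n_ancestral_events = as.integer(n_ancestral_events),
         n_subclones = as.integer(n_subclones),
         n_events_per_subclone = as.integer(n_events_per_subclone),
         purity_range = as.numeric(purity_range),
         noise_sd = as.numeric(noise_sd),
         seeding = seeding,
         n_primary = as.integer(n_primary),
         n_metastasis = as.integer(n_metastasis)),
    class = "simulation_config"
  )
}

# run expr with a temporary RNG state seeded by `seed` (Mersenne-Twister,
# R's default), restoring the caller's state afterwards
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  # gamma draws with tiny shape underflow to exact 0; keep fractions
  # strictly positive (a numerically-extinct clone, not an absent one)
  x <- pmax(x, .Machine$double.xmin)
  x / sum(x)
}

# one random copy-number event on the lattice: whole-chromosome with
# probability 0.3, otherwise an interval with uniform lattice breakpoints;
# delta uniform on {-1, +1, +2}
draw_event <- function(genome, lattice) {
  ci <- sample.int(nrow(genome), 1L)
  chrom <- genome$chrom[ci]
  nbins <- genome$length[ci] / lattice
  if (runif(1) < 0.3) {
    start <- 0; end <- genome$length[ci]
  } else {
    bp <- sort(sample.int(nbins + 1L, 2L) - 1L) * lattice
    while (bp[1L] == bp[2L]) bp <- sort(sample.int(nbins + 1L, 2L) - 1L) * lattice
    start <- bp[1L]; end <- bp[2L]
  }
  delta <- sample(c(-1L, 1L, 2L), 1L)
  list(chrom = chrom, start = start, end = end, delta = delta)
}

# copy-number vector of one clone on a fixed segmentation (data frame with
# chrom/start/end), given its event list, starting from diploid
apply_events <- function(segs, events) {
  cn <- rep(2L, nrow(segs))
  for (ev in events) {
    hit <- segs$chrom == ev$chrom & segs$start >= ev$start & segs$end <= ev$end
    cn[hit] <- cn[hit] + ev$delta
  }
  cn
}

# minimum copy number an event list yields over the event's own interval
min_cn_in <- function(events, candidate, genome, lattice) {
  evs <- c(events, list(candidate))
  bps <- sort(unique(c(0, genome$length[genome$chrom == candidate$chrom],
                       unlist(lapply(evs, function(e)
                         if (e$chrom == candidate$chrom) c(e$start, e$end))))))
  segs <- data.frame(chrom = candidate$chrom,
                     start = bps[-length(bps)], end = bps[-1L])
  cn <- apply_events(segs, evs)
  min(cn[segs$start >= candidate$start & segs$end <= candidate$end])
}

#' Simulate the clone structure of one tumor
#'
#' The ancestor is a diploid genome modified by `n_ancestral_events` random
#' events (uniform chromosome; uniform lattice breakpoints; whole-chromosome
#' events with probability 0.3; copy-number delta uniform on
#' `{-1, +1, +2}`). Each subclone adds `n_events_per_subclone` further
#' events. Events that would push a copy number below 0 are resampled
#' (bounded retries). All clones are returned on their shared union
#' segmentation.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `segments` (shared segmentation data frame), `ancestor`
#'   (integer copy numbers per segment) and `subclones` (list of integer
#'   vectors).
#' @export
simulate_clones <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(seed, {
    genome <- config$genome
    draw_valid <- function(events, n) {
      for (i in seq_len(n)) {
        for (try in seq_len(100L)) {
          cand <- draw_event(genome, config$lattice)
          if (min_cn_in(events, cand, genome, config$lattice) >= 0L) break
          if (try == 100L) stop("could not draw a non-negative copy-number event")
        }
        events <- c(events, list(cand))
      }
      events
    }
    anc_events <- draw_valid(list(), config$n_ancestral_events)
    sub_events <- lapply(seq_len(config$n_subclones), function(i) {
      draw_valid(anc_events, config$n_events_per_subclone)
    })

    all_ev <- c(anc_events, do.call(c, sub_events))
    bps <- lapply(seq_len(nrow(genome)), function(ci) {
      ch <- genome$chrom[ci]
      sort(unique(c(0, genome$length[ci],
                    unlist(lapply(all_ev, function(e)
                      if (e$chrom == ch) c(e$start, e$end))))))
    })
    segments <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
      b <- bps[[ci]]
      data.frame(chrom = genome$chrom[ci], start = b[-length(b)], end = b[-1L],
                 stringsAsFactors = FALSE)
    }))
    rownames(segments) <- NULL
    list(segments = segments,
         ancestor = apply_events(segments, anc_events),
         subclones = lapply(sub_events, function(ev) apply_events(segments, ev)))
  })
}

#' Clonal mixture
#'
#' Clones sharing a segmentation, mixed at fractions of the tumor-cell
#' compartment.
#'
#' @param segments shared segmentation data frame (`chrom`, `start`, `end`).
#' @param clones list of integer copy-number vectors (one per clone, same
#'   length as `nrow(segments)`).
#' @param fractions positive fractions summing to 1.
#' @return a `clonal_mixture` object.
#' @export
clonal_mixture <- function(segments, clones, fractions) {
  fractions <- as.numeric(fractions)
  if (length(clones) != length(fractions)) stop("one fraction per clone")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be > 0 and sum to 1")
  }
  for (cn in clones) {
    if (length(cn) != nrow(segments)) stop("clone/segmentation length mismatch")
    if (any(cn < 0)) stop("negative clone copy number")
  }
  structure(list(segments = segments, clones = clones, fractions = fractions),
            class = "clonal_mixture")
}

#' Expected copy number of a clonal mixture
#'
#' Fraction-weighted mean of the clone copy numbers per segment; the
#' attribute `tau` carries the length-weighted mean over segments (the true
#' tumor ploidy of the mixture).
#'
#' @param mixture a [clonal_mixture()].
#' @return numeric vector of per-segment expected copy numbers with
#'   attribute `tau`.
#' @export
expected_segment_cn <- function(mixture) {
  stopifnot(inherits(mixture, "clonal_mixture"))
  q <- Reduce(`+`, Map(function(cn, f) f * cn, mixture$clones, mixture$fractions))
  w <- mixture$segments$end - mixture$segments$start
  attr(q, "tau") <- sum(w * q) / sum(w)
  q
}

#' Observe a clonal mixture as a segmented log2-ratio profile
#'
#' The forward model the purity/ploidy correction inverts: with expected
#' tumor copy number `q` per segment, mixture ploidy `tau`, and purity
#' `alpha`, the relative copy number is
#' `r = (alpha*q + 2*(1-alpha)) / (alpha*tau + 2*(1-alpha))` and the
#' observed value is `log2(r)` plus Gaussian segment-level noise. At zero
#' noise the length-weighted mean relative copy number is exactly 1.
#'
#' @param mixture a [clonal_mixture()].
#' @param purity tumor purity in `[0.2, 1]`.
#' @param noise_sd Gaussian noise SD in log2 units, >= 0.
#' @param seed integer seed for the noise draw.
#' @param sample_id sample name of the resulting profile.
#' @param genome a [genome_model()]; default [toy_genome()].
#' @return a [segmented_profile()] on the mixture's segmentation.
#' @export
observe_profile <- function(mixture, purity, noise_sd = 0, seed = 1L,
                            sample_id = "sim", genome = toy_genome()) {
  stopifnot(inherits(mixture, "clonal_mixture"))
  if (purity < 0.2 || purity > 1) stop("purity must be in [0.2, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  q <- expected_segment_cn(mixture)
  tau <- attr(q, "tau")
  r <- (purity * q + 2 * (1 - purity)) / (purity * tau + 2 * (1 - purity))
  if (any(r <= 0)) {
    stop("zero relative copy number (homozygous loss at purity 1); ",
         "cannot take log2")
  }
  lr <- log2(r)
  if (noise_sd > 0) {
    lr <- lr + with_sim_seed(seed, rnorm(length(lr), 0, noise_sd))
  }
  segs <- mixture$segments
  segs$log_ratio <- lr
  segs$num_mark <- as.integer((segs$end - segs$start) %/% 1000)
  segmented_profile(sample_id, genome, segs)
}

#' Simulate one patient (primary plus metastasis)
#'
#' Draws the clone structure, assigns primary mixture fractions
#' `Dirichlet(1, ..., 1)` over ancestor and subclones, then forms the
#' metastasis truth according to the seeding mode: polyclonal seeding
#' re-draws the same clones' fractions from a concentrated Dirichlet
#' (concentration 50 times the primary fractions — a small perturbation of
#' the inherited mixture); monoclonal seeding picks one subclone uniformly
#' as the sole founder. Every requested sample is observed at an independent
#' uniform purity from `config$purity_range` with independent noise.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param patient_id identifier used to name samples (`<id>_P1`, `<id>_M1`, ...).
#' @return a `simulated_patient`: list with `patient_id`, `truth` (primary
#'   and metastasis mixtures, per-sample purity and ploidy) and `observed`
#'   (named list of [segmented_profile()]).
#' @export
simulate_patient <- function(config, seed = config$seed, patient_id = "SIM") {
  stopifnot(inherits(config, "simulation_config"))
  cl <- simulate_clones(config, seed = seed)
  with_sim_seed(seed + 500000L, {
    clones <- c(list(cl$ancestor), cl$subclones)
    frac_primary <- rdirichlet1(rep(1, length(clones)))
    mix_primary <- clonal_mixture(cl$segments, clones, frac_primary)
    if (config$seeding == "polyclonal") {
      frac_met <- rdirichlet1(50 * frac_primary)
      mix_met <- clonal_mixture(cl$segments, clones, frac_met)
    } else {
      pick <- sample.int(config$n_subclones, 1L)
      mix_met <- clonal_mixture(cl$segments, cl$subclones[pick], 1)
    }
    observe_set <- function(mix, n, tag) {
      out <- list()
      for (i in seq_len(n)) {
        alpha <- runif(1, config$purity_range[1L], config$purity_range[2L])
        sid <- sprintf("%s_%s%d", patient_id, tag, i)
        prof <- observe_profile(mix, alpha, config$noise_sd,
                                seed = sample.int(.Machine$integer.max, 1L),
                                sample_id = sid, genome = config$genome)
        out[[sid]] <- list(profile = prof, purity = alpha,
                           ploidy = attr(expected_segment_cn(mix), "tau"))
      }
      out
    }
    prim <- observe_set(mix_primary, config$n_primary, "P")
    met <- observe_set(mix_met, config$n_metastasis, "M")
    truth_tab <- do.call(rbind, lapply(c(prim, met), function(s) {
      data.frame(sample_id = s$profile$sample_id, true_purity = s$purity,
                 true_ploidy = s$ploidy, stringsAsFactors = FALSE)
    }))
    rownames(truth_tab) <- NULL
    structure(
      list(patient_id = patient_id,
           truth = list(primary = mix_primary, metastasis = mix_met,
                        samples = truth_tab, seeding = config$seeding),
           observed = c(lapply(prim, `[[`, "profile"),
                        lapply(met, `[[`, "profile"))),
      class = "simulated_patient"
    )
  })
}

#' Simulate a two-mode cohort
#'
#' `n_patients_per_mode` patients are generated under each seeding mode
#' (group labels `"polyclonal"` and `"monoclonal"`); per-patient seeds are
#' spawned deterministically from the master seed (`seed + patient index`),
#' so a cohort is reproducible patient by patient. Optionally writes the
#' canonical SEG file, the sample sheet and a ground-truth table to `dir`.
#'
#' @param config a [simulation_config()]; its `seeding` field is overridden
#'   per group.
#' @param n_patients_per_mode patients per seeding mode.
#' @param seed master seed (defaults to `config$seed`).
#' @param dir output directory, or `NULL` to skip writing files.
#' @return invisibly, a list with `profiles` (named list), `sample_sheet`,
#'   `truth`, and (when `dir` is given) `paths`.
#' @export
simulate_cohort <- function(config, n_patients_per_mode = 5L,
                            seed = config$seed, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  modes <- c("polyclonal", "monoclonal")
  profiles <- list(); sheet <- list(); truth <- list()
  idx <- 0L
  for (mode in modes) {
    cfg <- config
    cfg$seeding <- mode
    for (i in seq_len(n_patients_per_mode)) {
      idx <- idx + 1L
      pid <- sprintf("%s%03d", toupper(substr(mode, 1, 4)), i)
      pat <- simulate_patient(cfg, seed = seed + idx, patient_id = pid)
      profiles <- c(profiles, pat$observed)
      roles <- ifelse(grepl("_P\\d+$", names(pat$observed)),
                      "primary", "metastasis")
      sheet[[pid]] <- data.frame(
        sample_id = names(pat$observed), patient_id = pid,
        role = roles, group = mode, stringsAsFactors = FALSE
      )
      tt <- pat$truth$samples
      tt$mode <- mode
      truth[[pid]] <- tt
    }
  }
  sample_sheet <- do.call(rbind, sheet)
  truth_tab <- do.call(rbind, truth)
  rownames(sample_sheet) <- rownames(truth_tab) <- NULL
  out <- list(profiles = profiles, sample_sheet = sample_sheet,
              truth = truth_tab)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(seg = file.path(dir, "cohort.seg"),
                  sheet = file.path(dir, "samples.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    write_seg(profiles, paths$seg)
    write_tsv_fixed(sample_sheet, paths$sheet)
    tt <- truth_tab
    tt$true_purity <- sprintf("%.6f", tt$true_purity)
    tt$true_ploidy <- sprintf("%.6f", tt$true_ploidy)
    write_tsv_fixed(tt, paths$truth)
    out$paths <- paths
  }
  invisible(out)
}

#' Construct a clone with an exactly representable ploidy
#'
#' Builds a single clone whose length-weighted mean copy number equals
#' `tau` exactly, for parameter-recovery experiments: the genome is split
#' into 100 equal-length units, `round(100 * (tau - floor(tau)))` of which
#' (scattered randomly) carry `floor(tau) + 1` copies while the rest carry
#' `floor(tau)`. `100 * tau` must be an integer (any value on the default
#' ploidy search lattice qualifies).
#'
#' @param tau target ploidy; `100 * tau` must be integral and `tau >= 1`.
#' @param genome a [genome_model()] whose total length is a multiple of 100
#'   lattice units.
#' @param seed integer seed for the unit shuffle.
#' @return a [clonal_mixture()] with a single clone.
#' @export
clone_with_ploidy <- function(tau, genome = toy_genome(), seed = 1L) {
  if (abs(100 * tau - round(100 * tau)) > 1e-9 || tau < 1) {
    stop("tau must be >= 1 with 100 * tau integral")
  }
  total <- genome_length(genome)
  if (total %% 100 != 0) stop("genome length must be a multiple of 100 units")
  unit <- total / 100
  base <- floor(tau)
  k <- round(100 * (tau - base))
  cn_units <- rep(base, 100)
  if (k > 0) {
    cn_units[with_sim_seed(seed, sample.int(100, k))] <- base + 1
  }
  # map the 100 concatenated-genome units back to per-chromosome intervals
  bounds <- cumsum(c(0, genome$length))
  rows <- list()
  for (i in seq_len(100)) {
    u0 <- (i - 1) * unit; u1 <- i * unit
    for (ci in seq_len(nrow(genome))) {
      s <- max(u0, bounds[ci]); e <- min(u1, bounds[ci + 1])
      if (s < e) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = genome$chrom[ci], start = s - bounds[ci],
          end = e - bounds[ci], cn = cn_units[i], stringsAsFactors = FALSE
        )
      }
    }
  }
  segs <- do.call(rbind, rows)
  segs <- segs[order(match(segs$chrom, genome$chrom), segs$start), ]
  # merge adjacent equal-copy segments
  keep <- c(TRUE, !(segs$cn[-1L] == segs$cn[-nrow(segs)] &
                      segs$chrom[-1L] == segs$chrom[-nrow(segs)] &
                      segs$start[-1L] == segs$end[-nrow(segs)]))
  grp <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(segs, grp), function(g) {
    data.frame(chrom = g$chrom[1L], start = g$start[1L], end = g$end[nrow(g)],
               cn = g$cn[1L], stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  clonal_mixture(merged[, c("chrom", "start", "end")], list(merged$cn), 1)
}
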
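#' Gain/loss frequency track
#'
#' Tiles the genome into fixed-size bins and reports, per bin, the fraction
#' of samples whose covering segment calls a gain (`log_ratio >
#' gain_threshold`) or a loss (`log_ratio < loss_threshold`). A sample
#' covers a bin when one of its segments contains the bin midpoint; samples
#' not covering a bin are excluded from that bin's denominator. Thresholds
#' default to +/- 0.1, conventional practice for shallow-WGS log ratios.
#'
#' @param profiles non-empty list of [segmented_profile()] on one genome.
#' @param gain_threshold,loss_threshold log2-ratio call thresholds
#'   (`gain_threshold > 0 > loss_threshold`).
#' @param bin_size bin width in bp.
#' @return data frame: `chrom`, `start`, `end`, `n_covered`, `gain_frac`,
#'   `loss_frac`.
#' @export
aberration_frequency <- function(profiles, gain_threshold = 0.1,
                                 loss_threshold = -0.1, bin_size = 1e5) {
  if (length(profiles) == 0L) stop("no profiles")
  if (!(gain_threshold > 0) || !(loss_threshold < 0)) {
    stop("need gain_threshold > 0 > loss_threshold")
  }
  genome <- profiles[[1L]]$genome
  bins <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
    st <- seq(0, genome$length[ci] - 1, by = bin_size)
    data.frame(chrom = genome$chrom[ci], start = st,
               end = pmin(st + bin_size, genome$length[ci]),
               stringsAsFactors = FALSE)
  }))
  mid <- (bins$start + bins$end) / 2
  n_cov <- integer(nrow(bins))
  n_gain <- integer(nrow(bins))
  n_loss <- integer(nrow(bins))
  for (p in profiles) {
    for (ch in unique(p$segments$chrom)) {
      s <- p$segments[p$segments$chrom == ch, , drop = FALSE]
      sel <- which(bins$chrom == ch)
      i <- findInterval(mid[sel], s$start)
      cov <- i > 0L & mid[sel] < s$end[pmax(i, 1L)]
      lr <- s$log_ratio[pmax(i, 1L)]
      n_cov[sel] <- n_cov[sel] + cov
      n_gain[sel] <- n_gain[sel] + (cov & lr > gain_threshold)
      n_loss[sel] <- n_loss[sel] + (cov & lr < loss_threshold)
    }
  }
  if (all(n_cov == 0L)) stop("no profile covers any bin")
  bins$n_covered <- n_cov
  bins$gain_frac <- ifelse(n_cov > 0L, n_gain / n_cov, NA_real_)
  bins$loss_frac <- ifelse(n_cov > 0L, n_loss / n_cov, NA_real_)
  bins
}

#' Compare patient distances between groups
#'
#' One-way analysis of variance of `mean_d` across groups (the omnibus
#' test), with all-pairs Tukey honest-significant-difference adjusted
#' p-values when there are three or more groups. With exactly two groups
#' the pairwise row is a two-sided Wilcoxon rank-sum test instead (a rank
#' test is the natural robust pairwise companion when Tukey's studentized
#' range adds nothing over the omnibus F).
#'
#' @param patient_table data frame with columns `patient_id`, `group`,
#'   `mean_d` (e.g. `cohort_distances(...)$patients`).
#' @return a `group_comparison`: list with `groups` (per-group n, mean,
#'   median), `method`, `statistic` (F), `p_value` (omnibus) and `pairwise`
#'   (data frame: `comparison`, `diff`, `p_adj`).
#' @export
compare_groups <- function(patient_table) {
  req <- c("patient_id", "group", "mean_d")
  if (!all(req %in% names(patient_table))) {
    stop("patient table needs columns: ", paste(req, collapse = ", "))
  }
  tab <- patient_table
  tab$group <- as.character(tab$group)
  counts <- table(tab$group)
  if (length(counts) < 2L) stop("need at least 2 groups")
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop("group(s) with fewer than 2 patients: ", paste(small, collapse = ", "))
  }
  groups <- do.call(rbind, lapply(sort(names(counts), method = "radix"),
                                  function(g) {
    v <- tab$mean_d[tab$group == g]
    data.frame(group = g, n = length(v), mean_d = mean(v),
               median_d = median(v), stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL

  tab$group <- factor(tab$group)
  if (sd(tab$mean_d) == 0) {
    # all values identical: no variance anywhere, trivially no difference
    fstat <- 0; pval <- 1
    fit <- NULL
  } else {
    fit <- aov(mean_d ~ group, data = tab)
    an <- summary(fit)[[1L]]
    fstat <- an[["F value"]][1L]
    pval <- an[["Pr(>F)"]][1L]
  }

  k <- length(counts)
  if (k == 2L) {
    gl <- levels(tab$group)
    v1 <- tab$mean_d[tab$group == gl[1L]]
    v2 <- tab$mean_d[tab$group == gl[2L]]
    wt <- suppressWarnings(wilcox.test(v2, v1, exact = FALSE))
    pairwise <- data.frame(
      comparison = paste0(gl[2L], "-", gl[1L]),
      diff = mean(v2) - mean(v1),
      p_adj = wt$p.value,
      stringsAsFactors = FALSE
    )
    method <- "one-way ANOVA; pairwise Wilcoxon rank-sum (2 groups)"
  } else if (!is.null(fit)) {
    tk <- TukeyHSD(fit)$group
    pairwise <- data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
    rownames(pairwise) <- NULL
    method <- "one-way ANOVA with Tukey HSD"
  } else {
    combs <- utils::combn(sort(names(counts), method = "radix"), 2L)
    pairwise <- data.frame(
      comparison = paste0(combs[2L, ], "-", combs[1L, ]),
      diff = 0, p_adj = 1, stringsAsFactors = FALSE
    )
    method <- "one-way ANOVA with Tukey HSD"
  }
  structure(
    list(groups = groups, method = method, statistic = fstat,
         p_value = pval, pairwise = pairwise),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n  omnibus F = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Read a sample sheet
#'
#' Tab-delimited with header columns `sample_id`, `patient_id`, `role`
#' (`primary`/`metastasis`) and `group`.
#'
#' @param path path to the sheet.
#' @return data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "role", "group")
  if (!all(req %in% names(tab))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  }
  tab
}

# tab-delimited writer with fixed \n endings; numeric columns are
# serialized at 6-decimal fixed point so outputs are byte-reproducible
write_tsv_fixed <- function(tab, path, digits = 6L) {
  for (j in seq_along(tab)) {
    if (is.double(tab[[j]])) {
      tab[[j]] <- ifelse(is.finite(tab[[j]]),
                         sprintf(paste0("%.", digits, "f"), tab[[j]]),
                         as.character(tab[[j]]))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(tab), collapse = "\t"),
               do.call(paste, c(unname(as.list(tab)), sep = "\t"))),
             con, sep = "\n")
  invisible(path)
}

#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()]. Either `seg` + `sheet` point at
#' input files, or `simulate = TRUE` generates a cohort first.
#'
#' @param out_dir output directory (created if needed).
#' @param seg,sheet input SEG file and sample sheet (ignored when simulating).
#' @param simulate simulate a cohort instead of reading input files?
#' @param sim_config a [simulation_config()] used when `simulate = TRUE`.
#' @param n_patients_per_mode cohort size per seeding mode when simulating.
#' @param grid a [search_grid()].
#' @param strategy `"coarse_to_fine"` or `"exhaustive"`.
#' @param weights `"bp"` or `"markers"`.
#' @param gain_threshold,loss_threshold,bin_size see [aberration_frequency()].
#' @param autosomes_only restrict profiles to chromosomes 1-22 first?
#' @param seed integer seed (simulation).
#' @param log_level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seg = NULL, sheet = NULL,
                            simulate = is.null(seg),
                            sim_config = simulation_config(seed = seed),
                            n_patients_per_mode = 5L,
                            grid = search_grid(),
                            strategy = c("coarse_to_fine", "exhaustive"),
                            weights = c("bp", "markers"),
                            gain_threshold = 0.1, loss_threshold = -0.1,
                            bin_size = 1e5,
                            autosomes_only = TRUE,
                            seed = 1L,
                            log_level = c("info", "debug", "warning", "error")) {
  strategy <- match.arg(strategy)
  weights <- match.arg(weights)
  log_level <- match.arg(log_level)
  if (!(gain_threshold > 0) || !(loss_threshold < 0)) {
    stop("need gain_threshold > 0 > loss_threshold")
  }
  stopifnot(inherits(grid, "search_grid"))
  structure(
    list(out_dir = out_dir, seg = seg, sheet = sheet, simulate = simulate,
         sim_config = sim_config, n_patients_per_mode = n_patients_per_mode,
         grid = grid, strategy = strategy, weights = weights,
         gain_threshold = gain_threshold, loss_threshold = loss_threshold,
         bin_size = bin_size, autosomes_only = autosomes_only,
         seed = as.integer(seed), log_level = log_level),
    class = "pipeline_config"
  )
}

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

make_logger <- function(threshold) {
  lines <- character(0)
  log <- function(level, ...) {
    msg <- sprintf("[%s] %s", level, paste0(...))
    lines <<- c(lines, msg)
    if (.log_levels[[level]] >= .log_levels[[threshold]]) {
      message(msg)
    }
  }
  list(log = log, lines = function() lines)
}

#' Run the end-to-end pipeline
#'
#' Simulates or loads a cohort, restricts to autosomes, computes per-sample
#' CNH, patient-level distances, gain/loss frequency tracks and the group
#' comparison, and writes `distances.tsv`, `pairs.tsv`, `cnh.tsv`,
#' `frequency.tsv`, `comparison.tsv` and `run.log` to the output directory.
#' All tables are tab-delimited with 6-decimal fixed-point reals and are
#' byte-identical across runs with the same configuration and seed
#' (`run.log` contains timings and is excluded from that guarantee).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory tables and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  lg <- make_logger(config$log_level)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    lg$log("debug", sprintf("stage %s: %.2fs", name,
                            proc.time()[["elapsed"]] - t0))
    res
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  lg$log("info", "cnadist pipeline, package version ",
         as.character(utils::packageVersion("cnadist")))
  lg$log("info", sprintf("grid: %d alpha x %d tau points; strategy: %s",
                         length(config$grid$alpha), length(config$grid$tau),
                         config$strategy))

  inputs <- stage("load", {
    if (config$simulate) {
      cfg <- config$sim_config
      cohort <- simulate_cohort(cfg, config$n_patients_per_mode,
                                seed = config$seed)
      list(profiles = cohort$profiles, sheet = cohort$sample_sheet)
    } else {
      if (is.null(config$seg) || !file.exists(config$seg)) {
        stop("SEG file not found: ", config$seg)
      }
      sheet <- read_sample_sheet(config$sheet)
      genome <- config$sim_config$genome
      list(profiles = read_seg(config$seg, genome), sheet = sheet)
    }
  })
  profiles <- inputs$profiles
  if (config$autosomes_only) {
    profiles <- stage("autosomes", lapply(profiles, restrict_to_autosomes))
  }
  lg$log("info", sprintf("%d profiles, %d patients", length(profiles),
                         length(unique(inputs$sheet$patient_id))))

  cnh <- stage("cnh", cnh_table(profiles, config$grid,
                                weights = config$weights))
  dist <- stage("distance", cohort_distances(
    inputs$sheet, profiles, grid = config$grid, strategy = config$strategy,
    weights = config$weights))
  freq <- stage("frequency", aberration_frequency(
    profiles, config$gain_threshold, config$loss_threshold, config$bin_size))
  comparison <- stage("comparison", compare_groups(dist$patients))

  paths <- list(
    distances = file.path(config$out_dir, "distances.tsv"),
    pairs = file.path(config$out_dir, "pairs.tsv"),
    cnh = file.path(config$out_dir, "cnh.tsv"),
    frequency = file.path(config$out_dir, "frequency.tsv"),
    comparison = file.path(config$out_dir, "comparison.tsv"),
    log = file.path(config$out_dir, "run.log")
  )
  stage("write", {
    write_tsv_fixed(dist$patients, paths$distances)
    write_tsv_fixed(dist$pairs, paths$pairs)
    write_tsv_fixed(cnh, paths$cnh)
    write_tsv_fixed(freq, paths$frequency)
    comp_tab <- merge(
      comparison$groups,
      data.frame(group = comparison$groups$group,
                 omnibus_F = comparison$statistic,
                 omnibus_p = comparison$p_value),
      by = "group"
    )
    write_tsv_fixed(comp_tab, paths$comparison)
    write_tsv_fixed(comparison$pairwise,
                    file.path(config$out_dir, "pairwise.tsv"))
  })
  lg$log("info", sprintf("omnibus p = %.4g (%s)", comparison$p_value,
                         comparison$method))
  writeLines(lg$lines(), paths$log)
  invisible(list(cnh = cnh, distances = dist, frequency = freq,
                 comparison = comparison, paths = paths))
}
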
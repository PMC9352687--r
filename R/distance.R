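#' Inter-profile distance at a fixed grid-point pair
#'
#' The clonality distance between two harmonized profiles under candidate
#' purity/ploidy corrections for each: weighted mean absolute difference of
#' the corrected copy numbers divided by the weighted population standard
#' deviation of the pooled corrected values of both profiles. When the
#' pooled standard deviation vanishes (both corrected profiles flat) the
#' distance is 0 if the profiles are also equal and `+Inf` otherwise, so
#' degenerate grid points never win the minimization spuriously.
#'
#' This is the naive single-point evaluator; the grid scans in
#' [pair_distance_minimize()] must agree with it to ~1e-12.
#'
#' @param h a [harmonize_pair()] result.
#' @param pp_a,pp_b [purity_ploidy()] candidates for the two profiles.
#' @param normalize rescale each side's relative copy numbers to weighted
#'   mean 1 before correcting (see [transform_profile()]).
#' @param eps degeneracy threshold for the standard deviation and numerator.
#' @return numeric scalar, `>= 0` (possibly `Inf`).
#' @export
pair_distance_at <- function(h, pp_a, pp_b, normalize = TRUE, eps = 1e-9) {
  stopifnot(inherits(h, "harmonized_pair"))
  if (nrow(h) == 0L) stop("empty harmonization")
  w <- h$weight
  u <- relative_values(h$value_a, w, normalize)
  v <- relative_values(h$value_b, w, normalize)
  q1 <- relative_to_absolute(u, pp_a)
  q2 <- relative_to_absolute(v, pp_b)
  num <- sum(w * abs(q1 - q2)) / sum(w)
  s <- weighted_mean_std(c(q1, q2), c(w, w))$std
  if (s < eps) {
    if (num < eps) 0 else Inf
  } else {
    num / s
  }
}

#' Minimized inter-profile distance
#'
#' Minimizes [pair_distance_at()] over the 4-dimensional search space
#' `(alpha_a, tau_a, alpha_b, tau_b)` of purity and ploidy candidates for
#' both profiles, so the distance reflects clonal composition rather than
#' purity or ploidy differences between the samples.
#'
#' Two strategies:
#' * `"exhaustive"` evaluates every pair of grid points (exact; the default
#'   grid has ~8.1e8 pairs, which is supported but slow).
#' * `"coarse_to_fine"` (default) scans a strided coarse sub-grid
#'   (`coarse_alpha_stride` in alpha index, `coarse_tau_stride` in tau
#'   index, endpoints always included), then exhaustively refines the full
#'   grid within one coarse stride in all four dimensions around each of the
#'   `top_m` best coarse candidates (duplicate refinement boxes are scanned
#'   once). When the full pair count does not exceed `small_grid_pairs` the
#'   complete scan is cheaper than refining and is used directly, making the
#'   result exact.
#'
#' Tie-break: among pairs within 1e-12 of the minimum, lexicographically
#' smallest `(tau_a, -alpha_a, tau_b, -alpha_b)`.
#'
#' @param a,b [segmented_profile()] objects on the same genome.
#' @param grid a [search_grid()] (used for both samples).
#' @param strategy `"coarse_to_fine"` or `"exhaustive"`.
#' @param weights,normalize see [harmonize_pair()] and [transform_profile()].
#' @param coarse_alpha_stride,coarse_tau_stride,top_m coarse-to-fine tuning.
#' @param small_grid_pairs full-scan threshold for `"coarse_to_fine"`.
#' @param eps degeneracy threshold, see [pair_distance_at()].
#' @return a `pair_distance_result`: list with `d`, `best` (list of
#'   `pp_a`, `pp_b`), `strategy`, `n_grid_evaluated`, `sample_a`, `sample_b`.
#' @export
pair_distance_minimize <- function(a, b, grid = search_grid(),
                                   strategy = c("coarse_to_fine", "exhaustive"),
                                   weights = c("bp", "markers"),
                                   normalize = TRUE,
                                   coarse_alpha_stride = 5L,
                                   coarse_tau_stride = 25L,
                                   top_m = 5L,
                                   small_grid_pairs = 250000,
                                   eps = 1e-9) {
  strategy <- match.arg(strategy)
  weights <- match.arg(weights)
  stopifnot(inherits(grid, "search_grid"))
  if (length(grid$alpha) == 0L || length(grid$tau) == 0L) stop("empty search grid")
  h <- harmonize_pair(a, b, weights = weights)
  w <- h$weight
  u <- relative_values(h$value_a, w, normalize)
  v <- relative_values(h$value_b, w, normalize)

  scan_box <- function(ai1, ti1, ai2, ti2, bound = Inf) {
    g1 <- grid_arrays(grid$alpha[ai1], grid$tau[ti1])
    g2 <- grid_arrays(grid$alpha[ai2], grid$tau[ti2])
    res <- cpp_dist_grid_min(u, v, w,
                             g1$A, g1$B, g1$tau, g1$alpha,
                             g2$A, g2$B, g2$tau, g2$alpha,
                             eps, 1e-12, bound)
    if (res$i == 0L) return(NULL)   # nothing in the box beat the bound
    list(d = res$d,
         pp_a = c(g1$alpha[res$i], g1$tau[res$i]),
         pp_b = c(g2$alpha[res$j], g2$tau[res$j]),
         n = length(g1$A) * length(g2$A))
  }
  all_a <- seq_along(grid$alpha)
  all_t <- seq_along(grid$tau)
  G <- length(all_a) * length(all_t)

  if (strategy == "exhaustive" ||
      (strategy == "coarse_to_fine" && G * G <= small_grid_pairs)) {
    best <- scan_box(all_a, all_t, all_a, all_t)
    n_eval <- best$n
  } else {
    ca <- coarse_indices(length(all_a), coarse_alpha_stride)
    ct <- coarse_indices(length(all_t), coarse_tau_stride)
    g1 <- grid_arrays(grid$alpha[ca], grid$tau[ct])
    dmat <- cpp_dist_grid_matrix(u, v, w, g1$A, g1$B, g1$A, g1$B, eps)
    n_eval <- length(dmat)

    # top-M coarse candidate pairs (ties broken by matrix order)
    ord <- order(dmat)[seq_len(min(top_m, length(dmat)))]
    nc <- length(g1$A)
    ci <- (ord - 1L) %% nc + 1L       # sample-a coarse point
    cj <- (ord - 1L) %/% nc + 1L      # sample-b coarse point
    window <- function(idx, stride, n) {
      seq(max(1L, idx - stride), min(n, idx + stride))
    }
    # refinement boxes in full-grid index space, deduplicated
    boxes <- unique(lapply(seq_along(ord), function(m) {
      pt1 <- c(match(g1$alpha[ci[m]], grid$alpha), match(g1$tau[ci[m]], grid$tau))
      pt2 <- c(match(g1$alpha[cj[m]], grid$alpha), match(g1$tau[cj[m]], grid$tau))
      list(ai1 = window(pt1[1L], coarse_alpha_stride, length(all_a)),
           ti1 = window(pt1[2L], coarse_tau_stride, length(all_t)),
           ai2 = window(pt2[1L], coarse_alpha_stride, length(all_a)),
           ti2 = window(pt2[2L], coarse_tau_stride, length(all_t)))
    }))
    best <- NULL
    for (bx in boxes) {
      bound <- if (is.null(best)) min(dmat) else best$d
      n_eval <- n_eval +
        length(bx$ai1) * length(bx$ti1) * length(bx$ai2) * length(bx$ti2)
      cand <- scan_box(bx$ai1, bx$ti1, bx$ai2, bx$ti2, bound = bound)
      if (is.null(cand)) next
      if (is.null(best) || better_pair(cand, best)) best <- cand
    }
    if (is.null(best)) stop("internal error: refinement produced no candidate")
  }
  structure(
    list(d = best$d,
         best = list(pp_a = purity_ploidy(best$pp_a[1L], best$pp_a[2L]),
                     pp_b = purity_ploidy(best$pp_b[1L], best$pp_b[2L])),
         strategy = strategy,
         n_grid_evaluated = n_eval,
         sample_a = a$sample_id, sample_b = b$sample_id),
    class = "pair_distance_result"
  )
}

# candidate ordering used when combining refinement boxes: smaller d wins;
# within 1e-12 the lexicographically smaller (tau_a, -alpha_a, tau_b,
# -alpha_b) wins
better_pair <- function(cand, best) {
  if (is.infinite(cand$d) && is.infinite(best$d)) return(FALSE)
  if (cand$d < best$d - 1e-12) return(TRUE)
  if (cand$d > best$d + 1e-12) return(FALSE)
  ka <- c(cand$pp_a[2L], -cand$pp_a[1L], cand$pp_b[2L], -cand$pp_b[1L])
  kb <- c(best$pp_a[2L], -best$pp_a[1L], best$pp_b[2L], -best$pp_b[1L])
  for (t in 1:4) {
    if (ka[t] < kb[t]) return(TRUE)
    if (ka[t] > kb[t]) return(FALSE)
  }
  cand$d < best$d
}

#' @export
print.pair_distance_result <- function(x, ...) {
  cat(sprintf(
    "<pair_distance_result> %s vs %s: d = %.6f (%s, %d grid pairs)\n  at a: (alpha = %g, tau = %g); b: (alpha = %g, tau = %g)\n",
    x$sample_a, x$sample_b, x$d, x$strategy, x$n_grid_evaluated,
    x$best$pp_a$alpha, x$best$pp_a$tau, x$best$pp_b$alpha, x$best$pp_b$tau))
  invisible(x)
}

#' Patient-level distance
#'
#' Computes the minimized distance for every (primary, metastasis) cross
#' pair of a patient and averages them. Within-group pairs are not included:
#' the reported quantity is the primary-versus-metastasis distance.
#'
#' @param primaries,metastases non-empty lists of [segmented_profile()].
#' @param patient_id identifier carried into the result.
#' @param pair_fun the per-pair minimizer; injectable for testing, defaults
#'   to [pair_distance_minimize()].
#' @param ... passed on to `pair_fun` (grid, strategy, ...).
#' @return a `patient_distance_result`: list with `patient_id`, `n_pairs`,
#'   `mean_d` and a `pairs` data frame (`sample_a`, `sample_b`, `d`,
#'   `alpha_a`, `tau_a`, `alpha_b`, `tau_b`).
#' @export
patient_distance <- function(primaries, metastases, patient_id = "patient",
                             pair_fun = pair_distance_minimize, ...) {
  if (length(primaries) == 0L) stop("no primary profiles for ", patient_id)
  if (length(metastases) == 0L) stop("no metastasis profiles for ", patient_id)
  rows <- list()
  for (p in primaries) {
    for (m in metastases) {
      res <- pair_fun(p, m, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = res$sample_a, sample_b = res$sample_b, d = res$d,
        alpha_a = res$best$pp_a$alpha, tau_a = res$best$pp_a$tau,
        alpha_b = res$best$pp_b$alpha, tau_b = res$best$pp_b$tau,
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(
    list(patient_id = patient_id, n_pairs = nrow(pairs),
         mean_d = mean(pairs$d), pairs = pairs),
    class = "patient_distance_result"
  )
}

#' @export
print.patient_distance_result <- function(x, ...) {
  cat(sprintf("<patient_distance_result> %s: mean d = %.6f over %d pair(s)\n",
              x$patient_id, x$mean_d, x$n_pairs))
  invisible(x)
}

#' Cohort-wide patient distances
#'
#' Resolves a sample sheet against loaded profiles, computes
#' [patient_distance()] per patient and returns one row per patient with the
#' group label carried through.
#'
#' @param sample_sheet data frame with columns `sample_id`, `patient_id`,
#'   `role` (`"primary"` or `"metastasis"`) and `group`.
#' @param profiles named list of [segmented_profile()] (names = sample ids).
#' @param ... passed to [patient_distance()] (grid, strategy, ...).
#' @return list with `patients` (data frame: `patient_id`, `group`,
#'   `n_pairs`, `mean_d`, ordered by patient id) and `pairs` (per-pair
#'   detail with the minimizing purity/ploidy 4-tuple).
#' @export
cohort_distances <- function(sample_sheet, profiles, ...) {
  req <- c("sample_id", "patient_id", "role", "group")
  if (!all(req %in% names(sample_sheet))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  }
  bad_role <- setdiff(unique(sample_sheet$role), c("primary", "metastasis"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  missing <- setdiff(sample_sheet$sample_id, names(profiles))
  if (length(missing)) {
    stop("sample sheet references missing sample(s): ",
         paste(missing, collapse = ", "))
  }
  patients <- sort(unique(sample_sheet$patient_id), method = "radix")
  prow <- list(); pairrow <- list()
  for (pid in patients) {
    sheet <- sample_sheet[sample_sheet$patient_id == pid, , drop = FALSE]
    prim <- profiles[sheet$sample_id[sheet$role == "primary"]]
    met <- profiles[sheet$sample_id[sheet$role == "metastasis"]]
    if (length(prim) == 0L) stop("patient ", pid, " has no primary sample")
    if (length(met) == 0L) stop("patient ", pid, " has no metastasis sample")
    grp <- unique(sheet$group)
    if (length(grp) != 1L) stop("patient ", pid, " has inconsistent group labels")
    res <- patient_distance(prim, met, patient_id = pid, ...)
    prow[[pid]] <- data.frame(patient_id = pid, group = grp,
                              n_pairs = res$n_pairs, mean_d = res$mean_d,
                              stringsAsFactors = FALSE)
    pr <- res$pairs
    pr$patient_id <- pid
    pairrow[[pid]] <- pr
  }
  patients_tab <- do.call(rbind, prow)
  pairs_tab <- do.call(rbind, pairrow)
  rownames(patients_tab) <- rownames(pairs_tab) <- NULL
  list(patients = patients_tab,
       pairs = pairs_tab[, c("patient_id", "sample_a", "sample_b", "d",
                             "alpha_a", "tau_a", "alpha_b", "tau_b")])
}
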
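#' Distance to the nearest integer
#'
#' `|q - round(q)|`, bounded by 0.5. The per-segment building block of the
#' CNH statistic: a clean clonal profile corrected at its true purity and
#' ploidy sits on integers, so this distance measures subclonal admixture
#' and fit error.
#'
#' @param q finite numeric vector of absolute copy numbers.
#' @return numeric vector in `[0, 0.5]`.
#' @export
nearest_integer_distance <- function(q) {
  if (any(!is.finite(q))) stop("non-finite copy number")
  abs(q - round(q))
}

#' CNH at a fixed purity/ploidy candidate
#'
#' Weighted mean distance of the corrected segment copy numbers to the
#' nearest integers.
#'
#' @inheritParams transform_profile
#' @return numeric scalar in `[0, 0.5]`.
#' @export
cnh_at <- function(profile, pp, weights = c("bp", "markers"),
                   normalize = TRUE) {
  ap <- transform_profile(profile, pp, weights = weights, normalize = normalize)
  s <- ap$segments
  sum(s$weight * nearest_integer_distance(s$q)) / sum(s$weight)
}

#' Copy-number heterogeneity (CNH)
#'
#' Exhaustively evaluates [cnh_at()] over every purity/ploidy grid point and
#' returns the minimum. The minimizing `(alpha, tau)` is reported under a
#' deterministic tie-break: among candidates within `1e-12` of the minimum,
#' the smallest `tau`, then the largest `alpha` (the ridge of equivalent
#' solutions — e.g. whole-genome-doubling aliases — is a known
#' identifiability feature; `n_ties` records its size).
#'
#' @inheritParams transform_profile
#' @param grid a [search_grid()].
#' @return a `cnh_result`: list with `cnh`, `best` ([purity_ploidy()]) and
#'   `n_ties`.
#' @export
cnh_minimize <- function(profile, grid = search_grid(),
                         weights = c("bp", "markers"), normalize = TRUE) {
  stopifnot(inherits(profile, "segmented_profile"), inherits(grid, "search_grid"))
  weights <- match.arg(weights)
  if (length(grid$alpha) == 0L || length(grid$tau) == 0L) stop("empty search grid")
  w <- segment_weights(profile, weights)
  r <- relative_values(profile$segments$log_ratio, w, normalize)
  g <- grid_arrays(grid$alpha, grid$tau)

  # q[j, g] = A_g * r_j + B_g, all grid points at once
  q <- r %o% g$A
  q <- q + rep(g$B, each = length(r))
  d <- abs(q - round(q))
  cnh <- as.vector(crossprod(w, d)) / sum(w)

  best <- min(cnh)
  ties <- which(cnh <= best + 1e-12)
  pick <- ties[order(g$tau[ties], -g$alpha[ties])[1L]]
  structure(
    list(cnh = cnh[pick],
         best = purity_ploidy(g$alpha[pick], g$tau[pick]),
         n_ties = length(ties)),
    class = "cnh_result"
  )
}

#' @export
print.cnh_result <- function(x, ...) {
  cat(sprintf("<cnh_result> CNH = %.6f at (alpha = %g, tau = %g), %d tie(s)\n",
              x$cnh, x$best$alpha, x$best$tau, x$n_ties))
  invisible(x)
}

#' CNH for a collection of profiles
#'
#' @param profiles list of [segmented_profile()] objects.
#' @inheritParams cnh_minimize
#' @return data frame with columns `sample_id`, `cnh`, `alpha_hat`,
#'   `tau_hat`, `n_ties`, ordered by sample id.
#' @export
cnh_table <- function(profiles, grid = search_grid(),
                      weights = c("bp", "markers"), normalize = TRUE) {
  weights <- match.arg(weights)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  profiles <- profiles[order(ids, method = "radix")]
  rows <- lapply(profiles, function(p) {
    res <- cnh_minimize(p, grid, weights = weights, normalize = normalize)
    data.frame(sample_id = p$sample_id, cnh = res$cnh,
               alpha_hat = res$best$alpha, tau_hat = res$best$tau,
               n_ties = res$n_ties, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
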
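#' Purity x ploidy search grid
#'
#' The discretized space over which the CNH statistic and the pair distance
#' are minimized. The default reproduces the published search: purity
#' `0.20, 0.21, ..., 1.00` (81 values) by ploidy `1.50, 1.51, ..., 5.00`
#' (351 values).
#'
#' @param alpha_min,alpha_max,alpha_step purity range and step;
#'   `alpha_min >= 0.01`, `alpha_max <= 1`.
#' @param tau_min,tau_max,tau_step ploidy range and step.
#' @return a `search_grid`: list with numeric vectors `alpha` and `tau`.
#' @examples
#' g <- search_grid()
#' length(g$alpha)  # 81
#' length(g$tau)    # 351
#' @export
search_grid <- function(alpha_min = 0.20, alpha_max = 1.00, alpha_step = 0.01,
                        tau_min = 1.50, tau_max = 5.00, tau_step = 0.01) {
  if (alpha_min < 0.01) stop("alpha_min must be >= 0.01")
  if (alpha_max > 1) stop("alpha_max must be <= 1")
  if (alpha_step <= 0 || tau_step <= 0) stop("grid steps must be > 0")
  if (alpha_min > alpha_max || tau_min > tau_max) stop("grid min > max")
  if (tau_min <= 0) stop("tau_min must be > 0")
  lattice <- function(lo, hi, step) {
    n <- floor((hi - lo) / step + 1e-9)
    round(lo + step * (0:n), 12)
  }
  structure(
    list(alpha = lattice(alpha_min, alpha_max, alpha_step),
         tau = lattice(tau_min, tau_max, tau_step)),
    class = "search_grid"
  )
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf(
    "<search_grid> alpha: %d values in [%g, %g]; tau: %d values in [%g, %g] (%d points)\n",
    length(x$alpha), min(x$alpha), max(x$alpha),
    length(x$tau), min(x$tau), max(x$tau),
    length(x$alpha) * length(x$tau)))
  invisible(x)
}

# enumerate the grid as parallel vectors (alpha varies fastest) together
# with the affine transform coefficients of every grid point
grid_arrays <- function(alpha, tau) {
  nA <- length(alpha); nT <- length(tau)
  a <- rep(alpha, times = nT)
  t <- rep(tau, each = nA)
  cf <- transform_coef(a, t)
  list(alpha = a, tau = t, A = cf$A, B = cf$B)
}

# indices of a strided coarse sub-grid, endpoints always included
coarse_indices <- function(n, stride) {
  sort(unique(c(seq(1L, n, by = stride), n)))
}
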
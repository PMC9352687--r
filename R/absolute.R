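#' Candidate purity/ploidy pair
#'
#' Purity `alpha` is the fraction of tumor cells in the bulk sample (the
#' remaining `1 - alpha` normal cells are assumed diploid); ploidy `tau` is
#' the length-weighted mean copy number of the tumor genome.
#'
#' @param alpha tumor purity, in (0, 1].
#' @param tau mean tumor ploidy, > 0.
#' @return a `purity_ploidy` object.
#' @export
purity_ploidy <- function(alpha, tau) {
  alpha <- as.numeric(alpha); tau <- as.numeric(tau)
  if (length(alpha) != 1L || length(tau) != 1L ||
      !is.finite(alpha) || !is.finite(tau)) {
    stop("'alpha' and 'tau' must be finite scalars")
  }
  if (alpha <= 0 || alpha > 1) stop("purity alpha must satisfy 0 < alpha <= 1")
  if (tau <= 0) stop("ploidy tau must be > 0")
  structure(list(alpha = alpha, tau = tau), class = "purity_ploidy")
}

#' @export
print.purity_ploidy <- function(x, ...) {
  cat(sprintf("<purity_ploidy> alpha = %g, tau = %g\n", x$alpha, x$tau))
  invisible(x)
}

#' Log2 ratio to relative copy number
#'
#' `r = 2^log_ratio`: the copy number of a segment relative to the sample
#' average (the scale on which segmentation output is expressed).
#'
#' @param log_ratio finite numeric vector.
#' @return relative copy numbers, elementwise `2^log_ratio`.
#' @export
logr_to_relative <- function(log_ratio) {
  if (any(!is.finite(log_ratio))) stop("non-finite log_ratio")
  2^log_ratio
}

#' Relative to absolute copy number under a purity/ploidy candidate
#'
#' The observed relative copy number of a segment mixes tumor signal
#' (purity `alpha`, mean ploidy `tau`) with diploid normal cells, so the
#' tumor copy number is recovered by inverting that mixture:
#' \deqn{q = \frac{r\,(\alpha\tau + 2(1-\alpha)) - 2(1-\alpha)}{\alpha}.}
#' The transform is affine and strictly increasing in `r`; `r = 1` maps to
#' `q = tau` for every purity. Values are not clamped: a mis-specified
#' candidate may legitimately produce negative `q`.
#'
#' @param r relative copy number(s), >= 0.
#' @param pp a [purity_ploidy()].
#' @return absolute copy number(s) `q`.
#' @examples
#' relative_to_absolute(0.75, purity_ploidy(0.5, 2))  # 1
#' @export
relative_to_absolute <- function(r, pp) {
  stopifnot(inherits(pp, "purity_ploidy"))
  if (any(!is.finite(r)) || any(r < 0)) stop("'r' must be finite and >= 0")
  a <- pp$alpha
  (r * (a * pp$tau + 2 * (1 - a)) - 2 * (1 - a)) / a
}

# affine coefficients of the correction: q = A * r + B, vectorized over
# alpha/tau. b = 2/alpha - 2 is the normal-contamination offset.
transform_coef <- function(alpha, tau) {
  b <- 2 / alpha - 2
  list(A = tau + b, B = -b)
}

# relative copy numbers of a profile, optionally rescaled so the weighted
# mean r is exactly 1 (CBS log ratios are centered by construction; the
# rescaling removes residual off-centering before the affine correction).
relative_values <- function(log_ratio, weights, normalize = TRUE) {
  r <- 2^log_ratio
  if (normalize) {
    r <- r / (sum(weights * r) / sum(weights))
  }
  r
}

#' Transform a segmented profile to absolute copy numbers
#'
#' Applies [relative_to_absolute()] segment-wise at a candidate
#' purity/ploidy. With `normalize = TRUE` (default) the relative copy
#' numbers are first rescaled to a weighted mean of exactly 1, so the
#' profile-average segment maps to the candidate ploidy.
#'
#' @param profile a [segmented_profile()].
#' @param pp a [purity_ploidy()].
#' @param weights `"bp"` or `"markers"`, see [segment_weights()].
#' @param normalize rescale mean relative copy number to 1 first?
#' @return an `absolute_profile`: list with `sample_id`, `genome`, `pp` and
#'   a `segments` data frame (`chrom`, `start`, `end`, `q`, `weight`).
#' @export
transform_profile <- function(profile, pp, weights = c("bp", "markers"),
                              normalize = TRUE) {
  stopifnot(inherits(profile, "segmented_profile"))
  weights <- match.arg(weights)
  w <- segment_weights(profile, weights)
  r <- relative_values(profile$segments$log_ratio, w, normalize)
  q <- relative_to_absolute(r, pp)
  segs <- data.frame(
    chrom = profile$segments$chrom,
    start = profile$segments$start,
    end = profile$segments$end,
    q = q, weight = w,
    stringsAsFactors = FALSE
  )
  structure(
    list(sample_id = profile$sample_id, genome = profile$genome,
         pp = pp, segments = segs),
    class = "absolute_profile"
  )
}

#' @export
print.absolute_profile <- function(x, ...) {
  cat(sprintf(
    "<absolute_profile> %s at (alpha = %g, tau = %g): %d segments, implied ploidy %.4f\n",
    x$sample_id, x$pp$alpha, x$pp$tau, nrow(x$segments), implied_ploidy(x)))
  invisible(x)
}

#' Implied ploidy of an absolute profile
#'
#' Weight-averaged absolute copy number; a consistency check of the mean
#' ploidy semantics (a profile whose weighted mean relative copy number is 1
#' has implied ploidy exactly `tau` after the transform).
#'
#' @param abs_profile an `absolute_profile` from [transform_profile()].
#' @return numeric scalar.
#' @export
implied_ploidy <- function(abs_profile) {
  stopifnot(inherits(abs_profile, "absolute_profile"))
  s <- abs_profile$segments
  sum(s$weight * s$q) / sum(s$weight)
}
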
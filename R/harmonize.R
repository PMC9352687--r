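#' Weighted mean and population standard deviation
#'
#' The primitive behind every averaged statistic in the package: weighted
#' mean `sum(w*v)/sum(w)` and population-form weighted standard deviation
#' `sqrt(sum(w*(v - mean)^2)/sum(w))`.
#'
#' @param values numeric vector.
#' @param weights positive numeric vector of the same length.
#' @return list with elements `mean` and `std`.
#' @examples
#' weighted_mean_std(c(2, 3, 2, 2), rep(1, 4))   # mean 2.25, std ~0.433
#' @export
weighted_mean_std <- function(values, weights) {
  if (length(values) == 0L) stop("empty input to weighted_mean_std")
  if (length(values) != length(weights)) {
    stop("'values' and 'weights' must have equal length")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be finite and > 0")
  }
  w <- sum(weights)
  m <- sum(weights * values) / w
  s <- sqrt(sum(weights * (values - m)^2) / w)
  list(mean = m, std = s)
}

#' Harmonize two profiles onto common breakpoints
#'
#' Re-expresses two segmented profiles on the union of their breakpoints so
#' that segment values can be compared interval by interval. Only regions
#' covered by *both* profiles are kept; each output interval carries the
#' log2 ratios of the (unique) covering segment of each profile and a weight.
#'
#' @param a,b [segmented_profile()] objects on the same genome model.
#' @param weights `"bp"` (interval length) or `"markers"` (marker count of
#'   the covering segments, allocated proportionally to interval length and
#'   averaged between the two profiles).
#' @return a `harmonized_pair`: data frame with columns `chrom`, `start`,
#'   `end`, `value_a`, `value_b`, `weight`, plus attributes `sample_a`,
#'   `sample_b`.
#' @export
harmonize_pair <- function(a, b, weights = c("bp", "markers")) {
  weights <- match.arg(weights)
  stopifnot(inherits(a, "segmented_profile"), inherits(b, "segmented_profile"))
  if (!identical(a$genome$chrom, b$genome$chrom) ||
      !identical(a$genome$length, b$genome$length)) {
    stop("profiles are on different genome models")
  }
  wa <- segment_weights(a, weights)
  wb <- segment_weights(b, weights)
  out <- vector("list", length(a$genome$chrom))
  for (k in seq_along(a$genome$chrom)) {
    ch <- a$genome$chrom[k]
    sa <- a$segments[a$segments$chrom == ch, , drop = FALSE]
    sb <- b$segments[b$segments$chrom == ch, , drop = FALSE]
    if (nrow(sa) == 0L || nrow(sb) == 0L) next
    bp <- sort(unique(c(sa$start, sa$end, sb$start, sb$end)))
    st <- bp[-length(bp)]
    en <- bp[-1L]
    # index of the covering segment, or NA when the interval is uncovered
    ia <- findInterval(st, sa$start)
    ia[ia == 0L | en > sa$end[pmax(ia, 1L)]] <- NA_integer_
    ib <- findInterval(st, sb$start)
    ib[ib == 0L | en > sb$end[pmax(ib, 1L)]] <- NA_integer_
    keep <- !is.na(ia) & !is.na(ib)
    if (!any(keep)) next
    st <- st[keep]; en <- en[keep]; ia <- ia[keep]; ib <- ib[keep]
    len <- en - st
    if (weights == "bp") {
      w <- len
    } else {
      ra <- a$segments$end - a$segments$start
      rb <- b$segments$end - b$segments$start
      ja <- which(a$segments$chrom == ch)[ia]
      jb <- which(b$segments$chrom == ch)[ib]
      w <- (wa[ja] * len / ra[ja] + wb[jb] * len / rb[jb]) / 2
    }
    out[[k]] <- data.frame(
      chrom = ch, start = st, end = en,
      value_a = sa$log_ratio[ia], value_b = sb$log_ratio[ib],
      weight = w, stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    stop("profiles '", a$sample_id, "' and '", b$sample_id,
         "' have zero mutual coverage")
  }
  h <- do.call(rbind, out)
  rownames(h) <- NULL
  attr(h, "sample_a") <- a$sample_id
  attr(h, "sample_b") <- b$sample_id
  class(h) <- c("harmonized_pair", "data.frame")
  h
}
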
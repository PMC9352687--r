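#' Segmented copy-number profiles
#'
#' A `segmented_profile` holds one sample's segmented log2-ratio profile:
#' non-overlapping, sorted genomic segments with a log2 ratio and an optional
#' marker count each. Coordinates are internal 0-based half-open; SEG files
#' are read and written in the 1-based inclusive dialect (see [read_seg()]).
#'
#' @param sample_id sample identifier (non-empty string).
#' @param genome a [genome_model()].
#' @param segments data frame with columns `chrom`, `start`, `end`,
#'   `log_ratio` and optionally `num_mark` (positive integer or `NA`).
#'   `start`/`end` are 0-based half-open bp coordinates.
#' @return a `segmented_profile` object.
#' @export
segmented_profile <- function(sample_id, genome, segments) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("'sample_id' must be a single non-empty string")
  }
  req <- c("chrom", "start", "end", "log_ratio")
  if (!all(req %in% names(segments))) {
    stop("segments need columns: ", paste(req, collapse = ", "))
  }
  segments$chrom <- normalize_chrom(as.character(segments$chrom))
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  segments$log_ratio <- as.numeric(segments$log_ratio)
  if (is.null(segments$num_mark)) segments$num_mark <- NA_integer_
  segments <- segments[, c("chrom", "start", "end", "log_ratio", "num_mark")]

  if (nrow(segments) < 1L) stop("profile '", sample_id, "' has no segments")
  unknown <- setdiff(unique(segments$chrom), genome$chrom)
  if (length(unknown)) {
    stop("profile '", sample_id, "': unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(segments$log_ratio))) {
    stop("profile '", sample_id, "': non-finite log_ratio")
  }
  # canonical order: genome chromosome order, then start
  ord <- order(match(segments$chrom, genome$chrom), segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL

  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    len <- chrom_length_of(genome, ch)
    if (any(s$start < 0) || any(s$end > len) || any(s$start >= s$end)) {
      stop("profile '", sample_id, "', chromosome ", ch,
           ": segment outside genome or empty interval")
    }
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop("profile '", sample_id, "', chromosome ", ch,
           ": overlapping segments")
    }
  }
  structure(
    list(sample_id = sample_id, genome = genome, segments = segments),
    class = "segmented_profile"
  )
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("<segmented_profile> %s: %d segments on %d chromosome(s)\n",
              x$sample_id, nrow(x$segments), length(unique(x$segments$chrom))))
  invisible(x)
}

#' Segment weights
#'
#' The weight of a segment is its genomic length in bp (default) or its
#' marker count. Length weighting is the package default because marker
#' counts are optional in SEG input; marker weighting is available when the
#' upstream probe density should drive the averaging instead.
#'
#' @param profile a [segmented_profile()].
#' @param weights `"bp"` or `"markers"`.
#' @return numeric vector of positive weights, one per segment.
#' @export
segment_weights <- function(profile, weights = c("bp", "markers")) {
  weights <- match.arg(weights)
  s <- profile$segments
  if (weights == "bp") {
    return(s$end - s$start)
  }
  if (any(is.na(s$num_mark))) {
    stop("profile '", profile$sample_id,
         "': marker weighting requested but num_mark is missing")
  }
  if (any(s$num_mark <= 0)) {
    stop("profile '", profile$sample_id, "': non-positive marker count")
  }
  as.numeric(s$num_mark)
}

#' Read a SEG file
#'
#' Reads tab-delimited segmented copy-number data (one header row, six
#' columns: sample, chromosome, start, end, marker count, segment mean — the
#' de-facto exchange format for circular-binary-segmentation output). SEG
#' coordinates are 1-based inclusive and converted to internal 0-based
#' half-open; a `"chr"` prefix on chromosome tokens is stripped.
#'
#' @param path path to a SEG file.
#' @param genome a [genome_model()] the segments must fit in.
#' @return named list of [segmented_profile()], keyed and ordered by
#'   sample id.
#' @export
read_seg <- function(path, genome) {
  if (!file.exists(path)) stop("SEG file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("SEG file is empty (missing header): ", path)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(structure(list(), names = character(0)))

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop("malformed SEG row at line ", bad + 1L, ": expected 6 columns, got ",
         nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  start1 <- suppressWarnings(as.numeric(m[, 3L]))
  end1 <- suppressWarnings(as.numeric(m[, 4L]))
  segmean <- suppressWarnings(as.numeric(m[, 5L + 1L]))
  nmark <- suppressWarnings(as.integer(m[, 5L]))
  nmark[m[, 5L] == "NA"] <- NA_integer_
  num_bad <- which(!is.finite(start1) | !is.finite(end1) | !is.finite(segmean) |
                     (is.na(nmark) & m[, 5L] != "NA"))
  if (length(num_bad)) {
    stop("malformed SEG row at line ", num_bad[1L] + 1L,
         ": non-numeric field")
  }

  tab <- data.frame(
    sample = m[, 1L], chrom = m[, 2L],
    start = start1 - 1, end = end1,       # 1-based inclusive -> 0-based half-open
    num_mark = nmark, log_ratio = segmean,
    stringsAsFactors = FALSE
  )
  ids <- unique(tab$sample)
  out <- lapply(ids, function(id) {
    segmented_profile(id, genome, tab[tab$sample == id,
                                      c("chrom", "start", "end",
                                        "log_ratio", "num_mark")])
  })
  names(out) <- ids
  out[order(names(out), method = "radix")]
}

#' Write profiles to a SEG file
#'
#' Canonical SEG formatting: header
#' `ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean`, 1-based inclusive
#' coordinates, segment means with 6 decimal places, rows sorted by sample
#' id, chromosome (genome order) and start. Round-trips through [read_seg()]
#' byte-for-byte; note that segment means are serialized at 6 decimals, so a
#' profile is reproduced exactly iff its log ratios carry at most 6 decimals
#' (always true for re-read files).
#'
#' @param profiles a [segmented_profile()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "segmented_profile")) profiles <- list(profiles)
  header <- "ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean"
  rows <- character(0)
  if (length(profiles)) {
    ids <- vapply(profiles, function(p) p$sample_id, character(1))
    for (p in profiles[order(ids, method = "radix")]) {
      s <- p$segments   # already in canonical chromosome/start order
      rows <- c(rows, sprintf(
        "%s\t%s\t%d\t%d\t%s\t%.6f",
        p$sample_id, s$chrom, as.integer(s$start + 1), as.integer(s$end),
        ifelse(is.na(s$num_mark), "NA", as.character(s$num_mark)),
        s$log_ratio
      ))
    }
  }
  con <- file(path, open = "wb")   # fixed \n endings for byte-identity
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Restrict a profile to autosomes
#'
#' Keeps segments on chromosomes `"1" ... "22"`. The purity/ploidy
#' correction assumes contaminating normal cells contribute two copies,
#' which does not hold on sex chromosomes, so the default analysis is
#' autosome-only.
#'
#' @param profile a [segmented_profile()].
#' @return the restricted profile.
#' @export
restrict_to_autosomes <- function(profile) {
  keep <- profile$segments$chrom %in% as.character(1:22)
  if (!any(keep)) {
    stop("profile '", profile$sample_id, "': no autosomal segments")
  }
  if (all(keep)) return(profile)
  segmented_profile(profile$sample_id, profile$genome,
                    profile$segments[keep, , drop = FALSE])
}
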
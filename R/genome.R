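#' Genome models
#'
#' A genome model is the ordered set of chromosomes (name and length in bp)
#' against which all segment coordinates are validated. Chromosome names are
#' stored without a `"chr"` prefix; the declared order defines the canonical
#' sort order of all outputs.
#'
#' @param chrom character vector of unique, non-empty chromosome names.
#' @param length integer-ish vector of chromosome lengths in bp (> 0).
#' @return A `genome_model`: a data frame with columns `chrom` and `length`.
#' @examples
#' genome_model(c("1", "2"), c(2e6, 1e6))
#' @export
genome_model <- function(chrom, length) {
  chrom <- normalize_chrom(as.character(chrom))
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("'chrom' and 'length' must have equal length")
  }
  if (length(chrom) == 0L) stop("genome model needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names in genome model")
  if (any(!nzchar(chrom))) stop("empty chromosome name in genome model")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_model", "data.frame")
  )
}

# strip an optional "chr" prefix; applied on every input path, never on output
normalize_chrom <- function(x) sub("^chr", "", x)

#' Toy genome of equally sized autosomes
#'
#' A small genome used by the simulator and the test-suite: `n_chrom`
#' autosomes named `"1" ... "n_chrom"`, each `chrom_length` bp. The defaults
#' (22 autosomes of 10 Mb) keep segment harmonization small and grid searches
#' fast while preserving the autosome structure the analysis assumes.
#'
#' @param n_chrom number of autosomes.
#' @param chrom_length length of every chromosome in bp.
#' @return a [genome_model()].
#' @export
toy_genome <- function(n_chrom = 22, chrom_length = 1e7) {
  genome_model(as.character(seq_len(n_chrom)), rep(chrom_length, n_chrom))
}

#' Read a genome model from a chromosome-sizes file
#'
#' Two tab-separated columns (chromosome name, length in bp), no header —
#' the conventional `*.chrom.sizes` layout, so an hg38-style model can be
#' loaded directly.
#'
#' @param path path to a 2-column tab-delimited file.
#' @return a [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chromosome-sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  genome_model(tab$chrom, tab$length)
}

#' Total genome length in bp
#' @param genome a [genome_model()].
#' @return numeric scalar, sum of chromosome lengths.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  sum(genome$length)
}

chrom_length_of <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  genome$length[i]
}
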
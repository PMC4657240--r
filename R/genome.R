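#' Define a genome model
#'
#' A genome model fixes the coordinate system shared by every track and
#' region set in an analysis: the ordered chromosomes, their lengths, and
#' the uniform bin width used to rasterize signal. All coordinates in this
#' package are 0-based, half-open (BED convention); conversion from 1-based
#' formats happens only at I/O boundaries.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Names are the chromosome identifiers; order is preserved.
#' @param bin_size Uniform bin width in bp. Must not exceed the shortest
#'   chromosome.
#' @return An object of class `genome_model`.
#' @examples
#' gen <- genome_model(c(chr2L = 1e6, chr3R = 5e5), bin_size = 10)
#' n_bins(gen)
#' @export
genome_model <- function(chrom_lengths, bin_size = 10L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("`chrom_lengths` must be a named vector of chromosome lengths", call. = FALSE)
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("duplicate chromosome names in `chrom_lengths`", call. = FALSE)
  }
  chrom_lengths <- vapply(chrom_lengths, as.double, double(1))
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0) stop("`bin_size` must be > 0", call. = FALSE)
  if (bin_size > min(chrom_lengths)) {
    stop("`bin_size` exceeds the shortest chromosome", call. = FALSE)
  }
  structure(
    list(chrom_lengths = chrom_lengths, bin_size = bin_size),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_lengths), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp, bin ",
      x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Number of bins per chromosome
#'
#' The last bin of a chromosome may be partial; it is kept and counted as a
#' full bin.
#'
#' @param genome A [genome_model()].
#' @return Named integer vector, one entry per chromosome.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  vapply(genome$chrom_lengths, function(len) as.integer(ceiling(len / genome$bin_size)),
         integer(1))
}

# 0-based start coordinates of the bins of one chromosome
bin_starts <- function(genome, chrom) {
  nb <- n_bins(genome)[[chrom]]
  as.double(seq.int(0L, by = genome$bin_size, length.out = nb))
}

# midpoints of the bins of one chromosome (last partial bin uses its true end)
bin_midpoints <- function(genome, chrom) {
  st <- bin_starts(genome, chrom)
  en <- pmin(st + genome$bin_size, genome$chrom_lengths[[chrom]])
  (st + en) / 2
}

check_chrom <- function(chrom, genome, what = "record") {
  bad <- setdiff(unique(chrom), names(genome$chrom_lengths))
  if (length(bad) > 0) {
    stop("unknown chromosome(s) in ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
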
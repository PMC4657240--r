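#' Construct a binned signal track
#'
#' A signal track holds one numeric value per genomic bin, genome-wide. It
#' is represented as a tibble with columns `chrom`, `start` (0-based bin
#' start) and `value`, carrying the genome model and the signal semantics
#' (`raw_density`, `log2_enrichment` or `scaled`) as attributes.
#'
#' @param values Named list of numeric vectors, one per chromosome, in bin
#'   order. Each must have exactly `ceiling(chrom_length / bin_size)`
#'   entries and contain only finite values.
#' @param genome A [genome_model()].
#' @param semantics One of `"raw_density"`, `"log2_enrichment"`, `"scaled"`.
#' @return A `signal_track` tibble.
#' @export
signal_track <- function(values, genome,
                         semantics = c("raw_density", "log2_enrichment", "scaled")) {
  stopifnot(inherits(genome, "genome_model"))
  semantics <- match.arg(semantics)
  nb <- n_bins(genome)
  if (!setequal(names(values), names(nb))) {
    stop("`values` must have one element per genome chromosome", call. = FALSE)
  }
  values <- values[names(nb)]
  got <- vapply(values, length, integer(1))
  if (any(got != nb)) {
    bad <- names(nb)[got != nb][1]
    stop("wrong bin count on ", bad, ": expected ", nb[[bad]],
         ", got ", got[[bad]], call. = FALSE)
  }
  if (any(vapply(values, function(v) any(!is.finite(v)), logical(1)))) {
    stop("track values must all be finite", call. = FALSE)
  }
  tb <- tibble::tibble(
    chrom = rep(names(nb), nb),
    start = unlist(lapply(names(nb), bin_starts, genome = genome), use.names = FALSE),
    value = as.double(unlist(values, use.names = FALSE))
  )
  new_signal_track(tb, genome, semantics)
}

new_signal_track <- function(tb, genome, semantics) {
  structure(
    tb,
    genome = genome,
    semantics = semantics,
    class = c("signal_track", class(tibble::tibble()))
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> semantics =", track_semantics(x), "\n")
  NextMethod()
}

#' Genome model of a track
#' @param track A `signal_track`.
#' @return The [genome_model()] the track is binned on.
#' @export
track_genome <- function(track) attr(track, "genome", exact = TRUE)

#' Signal semantics of a track
#' @param track A `signal_track`.
#' @return `"raw_density"`, `"log2_enrichment"` or `"scaled"`.
#' @export
track_semantics <- function(track) attr(track, "semantics", exact = TRUE)

# named list of per-chromosome value vectors, in genome order
track_values <- function(track) {
  genome <- track_genome(track)
  nb <- n_bins(genome)
  ends <- cumsum(nb)
  starts <- ends - nb + 1L
  v <- track$value
  out <- lapply(seq_along(nb), function(i) v[starts[i]:ends[i]])
  names(out) <- names(nb)
  out
}

check_same_grid <- function(a, b) {
  ga <- track_genome(a); gb <- track_genome(b)
  if (!identical(ga$chrom_lengths, gb$chrom_lengths) ||
      !identical(ga$bin_size, gb$bin_size)) {
    stop("tracks are on different genome grids", call. = FALSE)
  }
  invisible(TRUE)
}

#' Genome-wide mean and maximum of a track
#'
#' Both statistics run over every bin of every chromosome; the last
#' (partial) bin of each chromosome is weighted as a full bin. These are
#' the anchors of genomic-mean/max scaling (see [scale_genomic()]).
#'
#' @param track A `signal_track`.
#' @return A one-row tibble with columns `genomic_mean` and `genomic_max`.
#' @examples
#' gen <- genome_model(c(chrA = 40), bin_size = 10)
#' tr <- signal_track(list(chrA = c(0, 1, 2, 3)), gen)
#' genomic_stats(tr)
#' @export
genomic_stats <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  tibble::tibble(genomic_mean = mean(track$value), genomic_max = max(track$value))
}

#' Transform a raw-density track to log2 scale
#'
#' Applies `log2(value + alpha)` bin-wise. Tracks already in log2 or scaled
#' semantics are returned unchanged. Used so that binding summarization is
#' always performed in log2 scale regardless of the provider's units.
#'
#' @param track A `signal_track`.
#' @param alpha Pseudocount added before the logarithm.
#' @return A `signal_track` with semantics `log2_enrichment`.
#' @export
track_log2 <- function(track, alpha = 0.5) {
  stopifnot(inherits(track, "signal_track"))
  if (track_semantics(track) != "raw_density") return(track)
  tb <- tibble::tibble(chrom = track$chrom, start = track$start,
                       value = log2(track$value + alpha))
  new_signal_track(tb, track_genome(track), "log2_enrichment")
}

#' Rescale a track to genomic-mean/max units
#'
#' Applies [scale_genomic()] bin-wise using the track's own genome-wide
#' mean and maximum, so 0 is the genomic mean and 1 the genomic maximum.
#'
#' @param track A `signal_track`.
#' @return A `signal_track` with semantics `scaled`.
#' @export
track_scale_genomic <- function(track) {
  st <- genomic_stats(track)
  tb <- tibble::tibble(
    chrom = track$chrom, start = track$start,
    value = scale_genomic(track$value, st$genomic_mean, st$genomic_max)
  )
  new_signal_track(tb, track_genome(track), "scaled")
}
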
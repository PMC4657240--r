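#' Log2 IP/input enrichment track
#'
#' The input track is first scaled so that its genome-wide total matches
#' the IP total (library-size normalization), then each bin becomes
#' `log2((ip + alpha) / (input_scaled + alpha))`. The pseudocount `alpha`
#' stabilizes bins with little or no input coverage.
#'
#' @param ip,input `signal_track`s on the same genome grid.
#' @param alpha Pseudocount in read-density units, > 0.
#' @param normalize Scale the input to the IP library size first (default).
#'   Disable when both tracks are already depth-normalized densities.
#' @return A `signal_track` with semantics `log2_enrichment`.
#' @examples
#' gen <- genome_model(c(chrA = 100), bin_size = 10)
#' ip <- signal_track(list(chrA = rep(8, 10)), gen)
#' bg <- signal_track(list(chrA = rep(4, 10)), gen)
#' genomic_stats(log2_enrichment(ip, bg))  # all bins near 1
#' @export
log2_enrichment <- function(ip, input, alpha = 0.5, normalize = TRUE) {
  stopifnot(inherits(ip, "signal_track"), inherits(input, "signal_track"))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  check_same_grid(ip, input)
  tot_ip <- sum(ip$value)
  tot_in <- sum(input$value)
  scaled_in <- if (normalize && tot_in > 0) input$value * (tot_ip / tot_in) else input$value
  tb <- tibble::tibble(
    chrom = ip$chrom, start = ip$start,
    value = log2((ip$value + alpha) / (scaled_in + alpha))
  )
  new_signal_track(tb, track_genome(ip), "log2_enrichment")
}

#' Median smoothing of a track
#'
#' Each bin is replaced by the median of all bins whose centres lie within
#' `window / 2` bp of its own centre. At chromosome ends the window is
#' truncated to the available bins.
#'
#' @param track A `signal_track`.
#' @param window Full smoothing window width in bp (default 100).
#' @return A smoothed `signal_track` with the same semantics.
#' @export
median_smooth <- function(track, window = 100) {
  stopifnot(inherits(track, "signal_track"))
  genome <- track_genome(track)
  if (window < genome$bin_size) stop("`window` must be >= bin_size", call. = FALSE)
  h <- floor((window / 2) / genome$bin_size)
  if (h == 0) return(track)
  vals <- track_values(track)
  sm <- lapply(vals, smooth_one_chrom, h = h)
  out <- signal_track(sm, genome, track_semantics(track))
  out
}

smooth_one_chrom <- function(x, h) {
  n <- length(x)
  k <- 2L * h + 1L
  if (n >= k) {
    y <- stats::runmed(x, k, endrule = "keep")
    edge <- c(seq_len(h), seq.int(n - h + 1L, n))
  } else {
    y <- x
    edge <- seq_len(n)
  }
  for (i in edge) {
    y[i] <- stats::median(x[max(1L, i - h):min(n, i + h)])
  }
  y
}

#' Call peaks by percentile thresholding
#'
#' The threshold is the given percentile of all genome bins of the
#' (smoothed) enrichment track. Peaks are maximal runs of bins strictly
#' above the threshold spanning at least `min_length` bp. The summit
#' (`centre`) is the midpoint of the bin with the maximal smoothed value
#' (leftmost on ties).
#'
#' @param track A smoothed log2-enrichment `signal_track`.
#' @param percentile Percentile (0-100, exclusive) defining the threshold.
#' @param min_length Minimum peak length in bp.
#' @return Tibble of peaks with columns `peak_id`, `chrom`, `start`, `end`,
#'   `centre`, `max_enrichment`, `mean_enrichment`, sorted by
#'   (chrom, start); attribute `threshold` records the cutoff used.
#' @export
call_peaks <- function(track, percentile = 95, min_length = 200) {
  stopifnot(inherits(track, "signal_track"))
  if (percentile <= 0 || percentile >= 100) {
    stop("`percentile` must be strictly between 0 and 100", call. = FALSE)
  }
  genome <- track_genome(track)
  if (max(track$value) == min(track$value)) {
    warning("constant track: no bin exceeds its own percentile; no peaks called")
    return(structure(empty_peaks(), threshold = NA_real_))
  }
  threshold <- stats::quantile(track$value, percentile / 100, names = FALSE, type = 7)
  vals <- track_values(track)
  peaks <- purrr::imap(vals, function(x, chr) {
    runs_above(x, threshold, chr, genome, min_length)
  })
  out <- dplyr::bind_rows(peaks)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, match(.data$chrom, names(genome$chrom_lengths)), .data$start)
    out$peak_id <- sprintf("peak_%05d", seq_len(nrow(out)))
    out <- dplyr::relocate(out, "peak_id")
  } else {
    out <- empty_peaks()
  }
  structure(out, threshold = threshold)
}

empty_peaks <- function() {
  tibble::tibble(peak_id = character(), chrom = character(), start = double(),
                 end = double(), centre = double(), max_enrichment = double(),
                 mean_enrichment = double())
}

runs_above <- function(x, threshold, chr, genome, min_length) {
  above <- x > threshold
  if (!any(above)) return(NULL)
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  bs <- genome$bin_size
  clen <- genome$chrom_lengths[[chr]]
  rows <- lapply(keep, function(j) {
    i0 <- run_start[j]; i1 <- run_end[j]
    start_bp <- (i0 - 1) * bs
    end_bp <- min(i1 * bs, clen)
    if (end_bp - start_bp < min_length) return(NULL)
    seg <- x[i0:i1]
    imax <- i0 + which.max(seg) - 1L
    bstart <- (imax - 1) * bs
    bend <- min(imax * bs, clen)
    tibble::tibble(
      chrom = chr, start = start_bp, end = end_bp,
      centre = floor((bstart + bend) / 2),
      max_enrichment = max(seg), mean_enrichment = mean(seg)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write peaks as BED6
#'
#' The name field carries `peak_id` (with the class label appended as
#' `peak_id|classK` when a `class` column is present) and the score is the
#' maximal smoothed enrichment times 100, rounded.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  name <- peaks$peak_id
  if ("class" %in% names(peaks)) name <- paste0(name, "|class", peaks$class)
  write_bed(tibble::tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = name, score = round(peaks$max_enrichment * 100), strand = "."
  ), path)
}
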
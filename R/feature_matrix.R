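#' Summarize binding of one track around a peak centre
#'
#' The per-peak binding statistic: over all runs of `n_consecutive`
#' adjacent bins lying fully inside `[centre - half_window, centre +
#' half_window)`, the maximal run mean, in log2 scale. If the window holds
#' fewer than `n_consecutive` bins, the track's genomic mean is used. With
#' `floor = TRUE` values below the genomic mean are raised to it.
#'
#' @param track A `signal_track`; raw-density tracks are log2-transformed
#'   with pseudocount `alpha` first.
#' @param chrom Chromosome of the centre.
#' @param centre Peak centre in bp (0-based).
#' @param half_window Half-width of the window in bp.
#' @param n_consecutive Run length (default 3).
#' @param floor Raise values below the genomic mean to the genomic mean.
#' @param alpha Pseudocount for log2 transform of raw tracks.
#' @return A single numeric binding value.
#' @export
summarize_binding <- function(track, chrom, centre, half_window,
                              n_consecutive = 3, floor = TRUE, alpha = 0.5) {
  stopifnot(inherits(track, "signal_track"))
  genome <- track_genome(track)
  check_chrom(chrom, genome, "summarize_binding")
  if (centre < 0 || centre >= genome$chrom_lengths[[chrom]]) {
    stop("`centre` outside chromosome ", chrom, call. = FALSE)
  }
  track <- track_log2(track, alpha)
  x <- track_values(track)[[chrom]]
  gmean <- mean(track$value)
  summarize_core(x, genome, chrom, centre, half_window, n_consecutive, floor, gmean)
}

summarize_core <- function(x, genome, chrom, centre, half_window,
                           n_consecutive, floor, gmean) {
  bs <- genome$bin_size
  n <- length(x)
  clen <- genome$chrom_lengths[[chrom]]
  lo <- centre - half_window
  hi <- centre + half_window
  i_lo <- max(1, ceiling(lo / bs) + 1)
  i_hi <- min(n, hi %/% bs)  # integer division: base floor() is shadowed by the flag
  # the last (partial) bin ends at the chromosome end, not at i*bs
  if (i_hi < n && n * bs > clen && (n - 1) * bs >= lo && clen <= hi) i_hi <- n
  m <- i_hi - i_lo + 1
  val <- if (m < n_consecutive) {
    gmean
  } else {
    w <- x[i_lo:i_hi]
    cs <- cumsum(c(0, w))
    means <- (cs[(n_consecutive + 1):(m + 1)] - cs[1:(m - n_consecutive + 1)]) / n_consecutive
    max(means)
  }
  if (floor && val < gmean) val <- gmean
  val
}

#' Build the peaks-by-datasets binding matrix
#'
#' Applies [summarize_binding()] to every (peak, dataset) pair. Datasets
#' named in `histone_datasets` use `histone_half_window`; all others use
#' `protein_half_window`. All tracks are brought to log2 scale first, and
#' the flooring rule is applied column-wise.
#'
#' @param peaks Peak tibble from [call_peaks()] (needs `peak_id`, `chrom`,
#'   `centre`).
#' @param tracks Named list of `signal_track`s sharing one genome grid.
#' @param histone_datasets Character vector naming the tracks to treat as
#'   histone modifications.
#' @param protein_half_window,histone_half_window Window half-widths in bp.
#' @param n_consecutive Run length for the summarizer.
#' @param floor Apply the genomic-mean floor.
#' @param alpha Pseudocount for log2 transform of raw tracks.
#' @return A `binding_matrix`: tibble with `peak_id` plus one numeric
#'   column per dataset; per-column metadata (genomic mean/max, window,
#'   histone flag) in attribute `column_meta`.
#' @export
build_matrix <- function(peaks, tracks, histone_datasets = character(),
                         protein_half_window = 150, histone_half_window = 250,
                         n_consecutive = 3, floor = TRUE, alpha = 0.5) {
  if (nrow(peaks) == 0) stop("empty peak list", call. = FALSE)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("`tracks` must be a named list", call. = FALSE)
  }
  genome <- track_genome(tracks[[1]])
  for (tr in tracks) check_same_grid(tracks[[1]], tr)
  cols <- vector("list", length(tracks))
  meta <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    id <- names(tracks)[i]
    tr <- track_log2(tracks[[i]], alpha)
    vals <- track_values(tr)
    gmean <- mean(tr$value)
    gmax <- max(tr$value)
    hw <- if (id %in% histone_datasets) histone_half_window else protein_half_window
    v <- vapply(seq_len(nrow(peaks)), function(j) {
      summarize_core(vals[[peaks$chrom[j]]], genome, peaks$chrom[j],
                     peaks$centre[j], hw, n_consecutive, floor, gmean)
    }, double(1))
    cols[[i]] <- v
    meta[[i]] <- tibble::tibble(dataset = id, genomic_mean = gmean,
                                genomic_max = gmax, half_window = hw,
                                is_histone = id %in% histone_datasets)
  }
  names(cols) <- names(tracks)
  out <- tibble::tibble(peak_id = peaks$peak_id, !!!cols)
  structure(out, column_meta = dplyr::bind_rows(meta),
            class = c("binding_matrix", class(tibble::tibble())))
}

#' Per-dataset metadata of a binding matrix
#' @param matrix A `binding_matrix` from [build_matrix()].
#' @return Tibble with `dataset`, `genomic_mean`, `genomic_max`,
#'   `half_window`, `is_histone`.
#' @export
column_meta <- function(matrix) attr(matrix, "column_meta", exact = TRUE)

#' Genomic-mean/max scaling
#'
#' Affine rescaling in which 0 corresponds to the genomic mean of a
#' dataset and 1 to its genomic maximum. Order-preserving and not clipped:
#' values below the mean map below 0.
#'
#' @param x Numeric values to rescale.
#' @param genomic_mean,genomic_max The dataset's genome-wide mean and
#'   maximum (see [genomic_stats()]); `genomic_max` must exceed
#'   `genomic_mean`.
#' @return Rescaled values.
#' @examples
#' scale_genomic(c(1.5, 3), genomic_mean = 1.5, genomic_max = 3)
#' @export
scale_genomic <- function(x, genomic_mean, genomic_max) {
  if (genomic_max <= genomic_mean) {
    stop("degenerate track: genomic_max must exceed genomic_mean", call. = FALSE)
  }
  (x - genomic_mean) / (genomic_max - genomic_mean)
}

#' Scale the columns of a binding matrix to genomic-mean/max units
#'
#' @param matrix A `binding_matrix`.
#' @return Tibble of the same shape with each dataset column passed through
#'   [scale_genomic()] using its column metadata.
#' @export
scale_matrix_genomic <- function(matrix) {
  meta <- column_meta(matrix)
  out <- tibble::as_tibble(matrix)
  for (i in seq_len(nrow(meta))) {
    d <- meta$dataset[i]
    out[[d]] <- scale_genomic(out[[d]], meta$genomic_mean[i], meta$genomic_max[i])
  }
  out
}
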
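# independent brute-force oracles; these deliberately avoid the code paths
# of the implementation they check

# naive truncated-window sliding median
bf_sliding_median <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, double(1))
}

# selection-based sliding median for full (interior) windows: the median of
# 2h+1 values is found by repeatedly deleting the row minimum h times, then
# taking the row minimum; edges fall back to the naive loop
bf_sliding_median_fast <- function(x, h) {
  n <- length(x)
  k <- 2L * h + 1L
  if (n < k) return(bf_sliding_median(x, h))
  M <- stats::embed(x, k)  # rows are reversed windows; order is irrelevant
  nr <- nrow(M)
  for (r in seq_len(h)) {
    jmin <- max.col(-M, ties.method = "first")
    M[cbind(seq_len(nr), jmin)] <- Inf
  }
  med <- do.call(pmin, as.data.frame(M))
  out <- numeric(n)
  out[(h + 1):(n - h)] <- med
  for (i in c(seq_len(h), seq.int(n - h + 1L, n))) {
    out[i] <- stats::median(x[max(1, i - h):min(n, i + h)])
  }
  out
}

bf_genomic_stats <- function(track) {
  vals <- unlist(lapply(unname(split(track$value, track$chrom)), identity))
  s <- 0; mx <- -Inf; n <- 0
  for (v in track$value) { s <- s + v; n <- n + 1; if (v > mx) mx <- v }
  c(mean = s / n, max = mx)
}

# run-length peak scan with an explicit state machine over bins
bf_call_peaks <- function(track, percentile = 95, min_length = 200) {
  genome <- track_genome(track)
  thr <- stats::quantile(track$value, percentile / 100, names = FALSE, type = 7)
  vals <- split(track$value, factor(track$chrom, levels = names(genome$chrom_lengths)))
  bs <- genome$bin_size
  out <- list()
  for (chr in names(vals)) {
    x <- vals[[chr]]
    clen <- genome$chrom_lengths[[chr]]
    in_run <- FALSE; i0 <- NA
    for (i in seq_len(length(x) + 1)) {
      hot <- i <= length(x) && x[i] > thr
      if (hot && !in_run) { in_run <- TRUE; i0 <- i }
      if (!hot && in_run) {
        in_run <- FALSE
        i1 <- i - 1
        sbp <- (i0 - 1) * bs
        ebp <- min(i1 * bs, clen)
        if (ebp - sbp >= min_length) {
          best <- i0
          for (j in i0:i1) if (x[j] > x[best]) best <- j
          bstart <- (best - 1) * bs; bend <- min(best * bs, clen)
          out[[length(out) + 1]] <- data.frame(
            chrom = chr, start = sbp, end = ebp,
            centre = floor((bstart + bend) / 2))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = double(), end = double(),
                      centre = double()))
  }
  do.call(rbind, out)
}

# brute-force top-n-consecutive summarizer over an explicit bin table
bf_summarize <- function(track, chrom, centre, half_window, n_consecutive = 3,
                         floor_it = TRUE) {
  genome <- track_genome(track)
  sub <- track[track$chrom == chrom, ]
  bend <- pmin(sub$start + genome$bin_size, genome$chrom_lengths[[chrom]])
  inside <- sub$start >= centre - half_window & bend <= centre + half_window
  w <- sub$value[inside]
  gmean <- mean(track$value)
  if (length(w) < n_consecutive) {
    val <- gmean
  } else {
    best <- -Inf
    for (i in seq_len(length(w) - n_consecutive + 1)) {
      m <- mean(w[i:(i + n_consecutive - 1)])
      if (m > best) best <- m
    }
    val <- best
  }
  if (floor_it && val < gmean) val <- gmean
  val
}
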
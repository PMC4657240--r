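#' Per-sequence A/T fraction
#'
#' Fraction of A or T among unambiguous bases; ambiguous bases (N etc.)
#' are excluded from both numerator and denominator.
#'
#' @param seqs A `DNAStringSet` or character vector of sequences.
#' @return Numeric vector of A/T fractions.
#' @export
at_fraction <- function(seqs) {
  seqs <- as_dna(seqs)
  f <- Biostrings::alphabetFrequency(seqs)
  at <- f[, "A"] + f[, "T"]
  acgt <- at + f[, "C"] + f[, "G"]
  at / acgt
}

as_dna <- function(x) {
  if (inherits(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
}

#' Filter control sequences to the foreground A/T range
#'
#' Keeps only controls whose per-sequence A/T fraction lies within the
#' range observed across the foreground sequences, so that base
#' composition cannot drive word enrichment.
#'
#' @param foreground,controls `DNAStringSet`s (or character vectors).
#' @return The filtered control `DNAStringSet`.
#' @export
filter_controls <- function(foreground, controls) {
  foreground <- as_dna(foreground); controls <- as_dna(controls)
  if (length(foreground) == 0) stop("empty foreground set", call. = FALSE)
  rng <- range(at_fraction(foreground))
  atc <- at_fraction(controls)
  keep <- atc >= rng[1] & atc <= rng[2]
  if (!any(keep)) {
    stop("all control sequences fall outside the foreground A/T range [",
         sprintf("%.3f, %.3f", rng[1], rng[2]),
         "]; sample controls with broader composition", call. = FALSE)
  }
  controls[keep]
}

#' K-mer word enrichment of foreground versus control sequences
#'
#' Counts overlapping k-mers in both sets, converts to per-position rates,
#' and scores each word by `log2((fg_rate + eps) / (bg_rate + eps))` with
#' a scale-free pseudocount (`eps` = 1 / positions of the smaller set) and
#' a one-sided binomial p-value for the foreground count given the control
#' rate. With `both_strands = TRUE` (default; ChIP regions are unstranded)
#' counts of a word and its reverse complement are pooled and reported
#' under the lexicographically smaller of the pair.
#'
#' @param foreground,controls `DNAStringSet`s (controls typically from
#'   [filter_controls()]).
#' @param k Word length, or vector of lengths (each reported separately).
#' @param both_strands Pool reverse-complement counts.
#' @return A `word_enrichment` tibble ranked within each `k` by descending
#'   enrichment then ascending p: `k`, `word`, `fg_count`, `bg_count`,
#'   `fg_rate`, `bg_rate`, `log2_enrichment`, `p`, `p_bonferroni`
#'   (Bonferroni over all 4^k words), `dinuc_repeat` (2-periodic word
#'   flag), `rank`.
#' @export
word_enrichment <- function(foreground, controls, k = 5, both_strands = TRUE) {
  foreground <- as_dna(foreground); controls <- as_dna(controls)
  out <- purrr::map(k, function(kk) {
    word_enrichment_one_k(foreground, controls, kk, both_strands)
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("word_enrichment", class(tibble::tibble())))
}

word_enrichment_one_k <- function(foreground, controls, k, both_strands) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (min(Biostrings::width(foreground)) < k || min(Biostrings::width(controls)) < k) {
    stop("`k` exceeds the shortest sequence", call. = FALSE)
  }
  fg <- colSums(Biostrings::oligonucleotideFrequency(foreground, width = k))
  bg <- colSums(Biostrings::oligonucleotideFrequency(controls, width = k))
  fg_pos <- sum(Biostrings::width(foreground) - k + 1)
  bg_pos <- sum(Biostrings::width(controls) - k + 1)
  words <- names(fg)
  if (both_strands) {
    # pooled count of a canonical word w is count(w) + count(revcomp(w));
    # palindromes are not double-counted
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
    can_u <- sort(unique(pmin(words, rc)))
    rc_u <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(can_u)))
    fg <- fg[can_u] + ifelse(can_u == rc_u, 0, fg[rc_u])
    bg <- bg[can_u] + ifelse(can_u == rc_u, 0, bg[rc_u])
    names(fg) <- names(bg) <- can_u
    words <- can_u
  }
  fg_rate <- fg / fg_pos
  bg_rate <- bg / bg_pos
  eps <- 1 / min(fg_pos, bg_pos)
  enr <- log2((fg_rate + eps) / (bg_rate + eps))
  # conservative control rate for the binomial test when a word is absent
  # from the controls
  p_rate <- pmin((bg + 1) / (bg_pos + 1), 1)
  p <- stats::pbinom(fg - 1, fg_pos, p_rate, lower.tail = FALSE)
  res <- tibble::tibble(
    k = k, word = words,
    fg_count = as.numeric(fg), bg_count = as.numeric(bg),
    fg_rate = as.numeric(fg_rate), bg_rate = as.numeric(bg_rate),
    log2_enrichment = as.numeric(enr), p = as.numeric(p),
    p_bonferroni = pmin(as.numeric(p) * 4^k, 1),
    dinuc_repeat = vapply(words, is_dinuc_repeat, logical(1))
  )
  res <- dplyr::arrange(res, dplyr::desc(.data$log2_enrichment), .data$p, .data$word)
  res$rank <- seq_len(nrow(res))
  res
}

# 2-periodic, non-homopolymer word (e.g. GTGTG)
is_dinuc_repeat <- function(word) {
  s <- strsplit(word, "")[[1]]
  if (length(s) < 3) return(FALSE)
  k <- length(s)
  all(s[seq_len(k - 2)] == s[seq.int(3, k)]) && s[1] != s[2]
}

#' Plot top enriched words
#'
#' @param object A `word_enrichment` tibble.
#' @param n_top Number of top-ranked words per word length to show.
#' @param ... Unused.
#' @return A ggplot bar chart of log2 enrichment for the top words.
#' @export
autoplot.word_enrichment <- function(object, n_top = 15, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$rank <= n_top)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$word, .data$log2_enrichment),
                                   .data$log2_enrichment, fill = .data$dinuc_repeat)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~k, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log2 enrichment (fg vs control)",
                  fill = "dinucleotide\nrepeat") +
    ggplot2::theme_minimal()
}
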
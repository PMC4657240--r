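#' Assign peaks to gene features
#'
#' Each peak is classified by the position of its centre with precedence
#' promoter > exon > intron > intergenic. The promoter is a strand-aware
#' window around the TSS: `promoter_window[1]` bp upstream to
#' `promoter_window[2]` bp downstream.
#'
#' @param peaks Peak tibble (needs `chrom`, `centre`).
#' @param genes A [gene_annotation()].
#' @param promoter_window Numeric `(upstream, downstream)` in bp; default
#'   (500, 100).
#' @return `peaks` with an added `feature` factor column
#'   (promoter/exon/intron/intergenic).
#' @export
assign_feature <- function(peaks, genes, promoter_window = c(500, 100)) {
  up <- promoter_window[1]; down <- promoter_window[2]
  pts <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$centre + 1, peaks$centre + 1))
  plus <- genes$strand != "-"
  prom_start <- ifelse(plus, genes$tss - up, genes$tss - down + 1)
  prom_end <- ifelse(plus, genes$tss + down, genes$tss + up + 1)  # half-open
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(prom_start, 0) + 1, pmax(prom_end, 1)))
  ex <- gene_exons(genes)
  chrom_of <- stats::setNames(genes$chrom, genes$gene_id)
  exr <- GenomicRanges::GRanges(chrom_of[ex$gene_id],
                                IRanges::IRanges(ex$start + 1, ex$end))
  span <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
  in_prom <- GenomicRanges::countOverlaps(pts, prom) > 0
  in_exon <- GenomicRanges::countOverlaps(pts, exr) > 0
  in_gene <- GenomicRanges::countOverlaps(pts, span) > 0
  feature <- dplyr::case_when(
    in_prom ~ "promoter",
    in_exon ~ "exon",
    in_gene ~ "intron",
    TRUE ~ "intergenic"
  )
  dplyr::mutate(peaks, feature = factor(feature, levels = c("promoter", "exon",
                                                            "intron", "intergenic")))
}

#' Split genes into three expression tertiles
#'
#' Genes are ranked by expression (ties broken by gene id, lexicographic)
#' and split into three rank bins whose sizes differ by at most one; any
#' remainder goes to the lower bins first.
#'
#' @param expr Tibble with `gene_id` and `value` columns.
#' @return `expr` with an added `expr_bin` factor (low/mid/high).
#' @export
expression_bins <- function(expr) {
  stopifnot(all(c("gene_id", "value") %in% names(expr)), nrow(expr) >= 3)
  ord <- order(expr$value, expr$gene_id)
  n <- nrow(expr)
  base <- n %/% 3; rem <- n %% 3
  sizes <- c(base + (rem >= 1), base + (rem >= 2), base)
  lab <- rep(c("low", "mid", "high"), times = sizes)
  out <- expr
  out$expr_bin <- factor(NA, levels = c("low", "mid", "high"))
  out$expr_bin[ord] <- lab
  out
}

#' Nearest gene by TSS distance
#'
#' Assigns to each peak the gene whose transcription start site is closest
#' to the peak centre (ties go to the lexicographically smaller gene id).
#'
#' @param peaks Peak tibble (needs `chrom`, `centre`).
#' @param genes A [gene_annotation()].
#' @return `peaks` with added `gene_id` and `tss_distance` columns.
#' @export
nearest_gene <- function(peaks, genes) {
  stopifnot(nrow(genes) >= 1)
  g <- genes[order(genes$gene_id), ]
  res <- purrr::map(seq_len(nrow(peaks)), function(i) {
    cand <- g[g$chrom == peaks$chrom[i], ]
    if (nrow(cand) == 0) cand <- g  # no same-chromosome gene: fall back to all
    d <- abs(cand$tss - peaks$centre[i])
    j <- which.min(d)
    list(gene_id = cand$gene_id[j], tss_distance = d[j])
  })
  dplyr::mutate(peaks,
                gene_id = purrr::map_chr(res, "gene_id"),
                tss_distance = purrr::map_dbl(res, "tss_distance"))
}

#' Overlap fraction with a reference set, with random-region control
#'
#' The fraction of query regions having at least 1 bp of overlap with the
#' reference, next to the same fraction for random genomic regions (RGR):
#' `n_draws` seeded sets matched to the query in count and length
#' distribution, placed uniformly on the genome.
#'
#' @param regions Query region tibble (`chrom`, `start`, `end`).
#' @param reference Reference region tibble.
#' @param genome A [genome_model()].
#' @param n_draws Number of random-region draws.
#' @param seed Seed for RGR placement.
#' @param slop Optional bp widening applied to both sides of the query
#'   regions before overlap.
#' @return One-row tibble: `fraction`, `rgr_fraction` (mean over draws),
#'   `rgr_lo`, `rgr_hi` (2.5/97.5 percentiles over draws), `n`.
#' @export
overlap_fraction <- function(regions, reference, genome, n_draws = 100,
                             seed = 1, slop = 0) {
  if (nrow(regions) == 0) stop("empty query region set", call. = FALSE)
  if (slop > 0) {
    regions <- dplyr::mutate(regions,
                             start = pmax(0, .data$start - slop),
                             end = pmin(genome$chrom_lengths[.data$chrom], .data$end + slop))
  }
  ref_gr <- regions_to_gr(reference)
  frac <- mean(GenomicRanges::countOverlaps(regions_to_gr(regions), ref_gr) > 0)
  lens <- regions$end - regions$start
  chroms <- names(genome$chrom_lengths)
  probs <- genome$chrom_lengths / sum(genome$chrom_lengths)
  rgr <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      chr <- sample(chroms, length(lens), replace = TRUE, prob = probs)
      maxs <- pmax(genome$chrom_lengths[chr] - lens, 0)
      st <- floor(stats::runif(length(lens), 0, maxs + 1))
      gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st + 1, st + lens))
      mean(GenomicRanges::countOverlaps(gr, ref_gr) > 0)
    }, double(1))
  })
  tibble::tibble(
    fraction = frac,
    rgr_fraction = mean(rgr),
    rgr_lo = stats::quantile(rgr, 0.025, names = FALSE),
    rgr_hi = stats::quantile(rgr, 0.975, names = FALSE),
    n = nrow(regions)
  )
}

#' Pairwise gene-sharing matrix between classes
#'
#' `M[i, j]` is the percentage of the genes associated with class `i` that
#' are also associated with class `j` (row-normalized, asymmetric;
#' diagonal 100).
#'
#' @param class_gene_sets Named list of character vectors of gene ids.
#' @return Numeric percentage matrix with class names on both dimensions.
#' @export
gene_overlap_matrix <- function(class_gene_sets) {
  sets <- lapply(class_gene_sets, unique)
  if (any(lengths(sets) == 0)) stop("empty gene set", call. = FALSE)
  k <- length(sets)
  M <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    M[i, j] <- 100 * length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
  }
  M
}

#' Within-class Spearman correlation of factors with an anchor factor
#'
#' For each class, rank-correlates the anchor dataset's binding values
#' with every other dataset across the class members.
#'
#' @param matrix A `binding_matrix`.
#' @param classes Tibble of (`peak_id`, `class`), e.g. from a
#'   [classify_peaks()] model.
#' @param anchor Name of the anchor dataset column (e.g. the IP factor).
#' @param adjust Apply Benjamini-Hochberg adjustment across factors within
#'   each class.
#' @return Tibble of (`class`, `dataset`, `rho`, `p`, and `p_adj` if
#'   requested). Constant columns within a class give `NA` with a warning.
#' @export
factor_correlation <- function(matrix, classes, anchor, adjust = FALSE) {
  tb <- dplyr::inner_join(tibble::as_tibble(matrix), classes, by = "peak_id")
  datasets <- setdiff(names(matrix), c("peak_id", anchor))
  if (!anchor %in% names(matrix)) stop("anchor column not in matrix", call. = FALSE)
  out <- purrr::map(sort(unique(tb$class)), function(cl) {
    sub <- tb[tb$class == cl, ]
    if (nrow(sub) < 4) {
      warning("class ", cl, " has < 4 members; skipped")
      return(NULL)
    }
    a <- sub[[anchor]]
    purrr::map(datasets, function(d) {
      y <- sub[[d]]
      if (stats::sd(a) == 0 || stats::sd(y) == 0) {
        warning("constant column in class ", cl, ": ", d)
        return(tibble::tibble(class = cl, dataset = d, rho = NA_real_, p = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(a, y, method = "spearman", exact = FALSE))
      tibble::tibble(class = cl, dataset = d, rho = unname(ct$estimate), p = ct$p.value)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (adjust && nrow(out) > 0) {
    out <- out |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  out
}

#' Developmental expression profile of a gene set
#'
#' For each gene, the change in log2 expression from the previous time
#' point; changes are averaged over the gene set per transition and the
#' profile is mean-centered so the global mean is zero.
#'
#' @param timecourse Tibble with `gene_id` plus ordered time-point columns
#'   (log2 expression).
#' @param gene_set Character vector of gene ids to profile.
#' @return Tibble of (`timepoint`, `delta`), one row per transition; the
#'   `delta` column has mean zero.
#' @export
dev_expression_profile <- function(timecourse, gene_set) {
  tp_cols <- setdiff(names(timecourse), "gene_id")
  if (length(tp_cols) < 2) stop("need >= 2 time points", call. = FALSE)
  sub <- timecourse[timecourse$gene_id %in% gene_set, ]
  if (nrow(sub) == 0) stop("no genes from `gene_set` in the table", call. = FALSE)
  X <- as.matrix(sub[, tp_cols])
  D <- X[, -1, drop = FALSE] - X[, -ncol(X), drop = FALSE]
  if (anyNA(D)) warning("missing values: genes skipped at affected transitions")
  delta <- unname(colMeans(D, na.rm = TRUE))
  tibble::tibble(timepoint = tp_cols[-1], delta = delta - mean(delta))
}

#' Fraction of regions with at least a given fold enrichment
#'
#' A region qualifies when the maximum of the (smoothed) log2 enrichment
#' track over its bins reaches `log2(fold)`.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param track A log2-enrichment `signal_track`.
#' @param fold Fold-enrichment cutoff (default 2).
#' @return The fraction of qualifying regions.
#' @export
fraction_enriched <- function(regions, track, fold = 2) {
  if (nrow(regions) == 0) stop("empty region set", call. = FALSE)
  stopifnot(inherits(track, "signal_track"))
  genome <- track_genome(track)
  check_chrom(regions$chrom, genome, "fraction_enriched")
  vals <- track_values(track)
  bs <- genome$bin_size
  mx <- vapply(seq_len(nrow(regions)), function(i) {
    x <- vals[[regions$chrom[i]]]
    i0 <- max(1, regions$start[i] %/% bs + 1)
    i1 <- min(length(x), ceiling(regions$end[i] / bs))
    max(x[i0:i1])
  }, double(1))
  mean(mx >= log2(fold))
}

#' Distance of peak centres to the nearest domain, with a comparison set
#'
#' Distance is in bp from the centre to the nearest domain edge (0 for
#' centres inside a domain). The two peak sets are compared with a
#' two-sided Mann-Whitney U test.
#'
#' @param peaks,other_peaks Peak tibbles (`chrom`, `centre`).
#' @param domains Region tibble of domains.
#' @return List with `distances`, `distances_other` (numeric vectors) and
#'   `p` (Mann-Whitney p-value).
#' @export
distance_to_domains <- function(peaks, domains, other_peaks) {
  if (nrow(domains) == 0) stop("empty domain set", call. = FALSE)
  dist_one_set <- function(p) {
    vapply(seq_len(nrow(p)), function(i) {
      dom <- domains[domains$chrom == p$chrom[i], ]
      if (nrow(dom) == 0) return(Inf)
      cc <- p$centre[i]
      min(pmax(dom$start - cc, cc - (dom$end - 1), 0))
    }, double(1))
  }
  d1 <- dist_one_set(peaks)
  d2 <- dist_one_set(other_peaks)
  p <- suppressWarnings(stats::wilcox.test(d1, d2)$p.value)
  list(distances = d1, distances_other = d2, p = p)
}

#' Per-class feature and expression composition
#'
#' Convenience summary combining [assign_feature()], [nearest_gene()] and
#' [expression_bins()]: for every class, the fraction of peaks on each
#' gene feature and the fraction of peaks whose nearest gene falls in each
#' expression tertile.
#'
#' @param peaks Peak tibble with a `class` column.
#' @param genes A [gene_annotation()].
#' @param expr Expression tibble (`gene_id`, `value`).
#' @param promoter_window Passed to [assign_feature()].
#' @return Long tibble of (`class`, `kind`, `level`, `fraction`) where
#'   `kind` is `"feature"` or `"expression"`.
#' @export
summarize_classes <- function(peaks, genes, expr, promoter_window = c(500, 100)) {
  stopifnot("class" %in% names(peaks))
  pk <- assign_feature(peaks, genes, promoter_window)
  pk <- nearest_gene(pk, genes)
  eb <- expression_bins(expr)
  pk <- dplyr::left_join(pk, eb[, c("gene_id", "expr_bin")], by = "gene_id")
  feat <- pk |>
    dplyr::count(.data$class, level = as.character(.data$feature)) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n), kind = "feature") |>
    dplyr::ungroup()
  ex <- pk |>
    dplyr::filter(!is.na(.data$expr_bin)) |>
    dplyr::count(.data$class, level = as.character(.data$expr_bin)) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n), kind = "expression") |>
    dplyr::ungroup()
  dplyr::bind_rows(feat, ex)[, c("class", "kind", "level", "n", "fraction")]
}

#' Mean scaled enrichment per class and dataset with 95% CI
#'
#' Column values are rescaled to genomic-mean/max units and averaged
#' within each class; the interval is the normal-approximation 95% CI on
#' the mean.
#'
#' @param matrix A `binding_matrix`.
#' @param classes Tibble of (`peak_id`, `class`).
#' @return Tibble of (`class`, `dataset`, `mean`, `ci_lo`, `ci_hi`, `n`).
#' @export
enrichment_summary <- function(matrix, classes) {
  scaled <- scale_matrix_genomic(matrix)
  long <- tidyr::pivot_longer(scaled, -"peak_id",
                              names_to = "dataset", values_to = "value")
  dplyr::inner_join(long, classes, by = "peak_id") |>
    dplyr::group_by(.data$class, .data$dataset) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = .data$mean - 1.96 * .data$se,
                  ci_hi = .data$mean + 1.96 * .data$se) |>
    dplyr::select("class", "dataset", "mean", "ci_lo", "ci_hi", "n")
}

# evaluate code with a private, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
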
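#' Subclassify peaks by histone-modification profile
#'
#' PCA (unit-variance scaling) on the histone columns of a binding matrix
#' followed by Ward clustering of the significant-component scores, cut
#' into `k` subclasses. The subclass with the higher mean scaled value
#' across acetylation marks (columns whose names end in "ac") is flagged
#' high-acetylation.
#'
#' @param histone_matrix A `binding_matrix` restricted to the peaks of
#'   interest; histone columns are taken from its metadata (all columns if
#'   no column is flagged as a histone modification).
#' @param k Number of subclasses (default 2).
#' @param method,n_fixed Component-selection rule for the PCA (see
#'   [select_components()]).
#' @return List with `labels` (tibble of `peak_id`, `subclass`,
#'   `high_acetyl`), `tree` (`hclust` or `NULL` when degenerate), and
#'   `acetyl_means` (mean scaled acetylation per subclass).
#' @export
subclassify_histone <- function(histone_matrix, k = 2,
                                method = c("broken_stick", "fixed", "kaiser"),
                                n_fixed = 4) {
  method <- match.arg(method)
  meta <- column_meta(histone_matrix)
  cols <- if (!is.null(meta) && any(meta$is_histone)) {
    meta$dataset[meta$is_histone]
  } else setdiff(names(histone_matrix), "peak_id")
  n <- nrow(histone_matrix)
  if (k > n) stop("`k` exceeds the number of observations", call. = FALSE)
  sub <- tibble::as_tibble(histone_matrix)[, c("peak_id", cols)]
  X <- as.matrix(sub[, cols])
  if (all(apply(X, 2, stats::var) == 0)) {
    warning("degenerate: all histone columns constant; single effective cluster")
    labels <- tibble::tibble(peak_id = sub$peak_id, subclass = 1L, high_acetyl = TRUE)
    return(list(labels = labels, tree = NULL, acetyl_means = NA_real_))
  }
  mat <- structure(sub, column_meta = meta[meta$dataset %in% cols, ],
                   class = class(histone_matrix))
  pca <- fit_pca(mat)
  ns <- select_components(pca, method = method, k = n_fixed)
  cl <- cluster_classes(pca$scores[, seq_len(ns), drop = FALSE], k)
  acetyl_cols <- grep("ac$", cols, ignore.case = TRUE, value = TRUE)
  if (length(acetyl_cols) == 0) acetyl_cols <- cols
  scaled <- scale_matrix_genomic(mat)
  ac <- rowMeans(as.matrix(scaled[, acetyl_cols, drop = FALSE]))
  means <- tapply(ac, cl$labels, mean)
  high <- as.integer(names(means)[which.max(means)])
  labels <- tibble::tibble(peak_id = sub$peak_id, subclass = cl$labels,
                           high_acetyl = cl$labels == high)
  list(labels = labels, tree = cl$tree, acetyl_means = means)
}

#' Oriented average signal profile around region centres
#'
#' Extracts the signal in `[centre - flank, centre + flank)` around each
#' eligible region, orients every region so that the flank with the larger
#' summed signal lies to the right (exact ties are not flipped), and
#' averages across regions in output bins. Used for H3K27me3
#' boundary-spreading metaprofiles around insulator-like sites.
#'
#' Eligibility: optionally only intergenic regions (centre not in any gene
#' span or promoter), and only regions whose centre lies within
#' `max_domain_distance` bp of a domain (overlap counts as distance 0).
#' Regions whose full flank extends past a chromosome end are dropped.
#'
#' @param regions Region tibble with `chrom` and `centre` (or `start`/`end`,
#'   from which centres are taken as midpoints).
#' @param track A `signal_track`, typically scaled (see
#'   [track_scale_genomic()]).
#' @param flank Flank width in bp on each side (default 10000).
#' @param out_bin Output profile bin width in bp (default 100).
#' @param domains Optional domain region tibble for the eligibility filter.
#' @param max_domain_distance Maximum centre-to-domain distance in bp.
#' @param intergenic_only Keep only intergenic centres (requires `genes`).
#' @param genes A [gene_annotation()], needed for `intergenic_only`.
#' @param orient Flip regions so the stronger flank is on the right.
#' @return An `oriented_profile`: tibble of (`position`, `mean_signal`)
#'   where `position` is the oriented offset of the output-bin midpoint
#'   from the centre; attributes `n`, `regions` (per-region orientation
#'   flag and left/right flank sums) and `region_profiles` (matrix).
#' @export
oriented_profile <- function(regions, track, flank = 10000, out_bin = 100,
                             domains = NULL, max_domain_distance = 10000,
                             intergenic_only = FALSE, genes = NULL,
                             orient = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  genome <- track_genome(track)
  if (flank < out_bin) stop("`flank` must be >= `out_bin`", call. = FALSE)
  if (!"centre" %in% names(regions)) {
    regions <- dplyr::mutate(regions, centre = floor((.data$start + .data$end) / 2))
  }
  n0 <- nrow(regions)
  dropped <- c()
  if (intergenic_only) {
    if (is.null(genes)) stop("`intergenic_only` requires `genes`", call. = FALSE)
    feat <- assign_feature(regions, genes)$feature
    regions <- regions[feat == "intergenic", ]
    dropped <- c(dropped, not_intergenic = n0 - nrow(regions))
  }
  if (!is.null(domains)) {
    n1 <- nrow(regions)
    if (n1 > 0) {
      d <- distance_to_domains(regions, domains, regions)$distances
      regions <- regions[d <= max_domain_distance, ]
    }
    dropped <- c(dropped, far_from_domain = n1 - nrow(regions))
  }
  n2 <- nrow(regions)
  fits <- regions$centre - flank >= 0 &
    regions$centre + flank <= genome$chrom_lengths[regions$chrom]
  regions <- regions[fits, ]
  dropped <- c(dropped, flank_outside = n2 - nrow(regions))
  if (nrow(regions) == 0) {
    stop("no eligible regions (dropped: ",
         paste(names(dropped), dropped, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  vals <- track_values(track)
  bs <- genome$bin_size
  n_out <- as.integer((2 * flank) %/% out_bin)
  prof <- matrix(NA_real_, nrow(regions), n_out)
  flipped <- logical(nrow(regions))
  left_sum <- right_sum <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cc <- regions$centre[i]
    x <- vals[[regions$chrom[i]]]
    idx <- seq.int(((cc - flank) %/% bs) + 1, length.out = ceiling(2 * flank / bs))
    idx <- idx[idx >= 1 & idx <= length(x)]
    m <- (idx - 1) * bs + bs / 2
    keep <- m >= cc - flank & m < cc + flank
    idx <- idx[keep]; m <- m[keep]
    j <- pmin(((m - (cc - flank)) %/% out_bin) + 1, n_out)
    row <- as.numeric(tapply(x[idx], factor(j, levels = seq_len(n_out)), mean))
    ls <- sum(x[idx][m < cc]); rs <- sum(x[idx][m >= cc])
    if (orient && ls > rs) {
      row <- rev(row)
      flipped[i] <- TRUE
      left_sum[i] <- rs; right_sum[i] <- ls
    } else {
      left_sum[i] <- ls; right_sum[i] <- rs
    }
    prof[i, ] <- row
  }
  pos <- -flank + (seq_len(n_out) - 0.5) * out_bin
  out <- tibble::tibble(position = pos, mean_signal = colMeans(prof, na.rm = TRUE))
  structure(out,
            n = nrow(regions),
            regions = tibble::tibble(chrom = regions$chrom, centre = regions$centre,
                                     flipped = flipped, left_sum = left_sum,
                                     right_sum = right_sum,
                                     asymmetry = ifelse(right_sum != 0,
                                                        left_sum / right_sum, NA_real_)),
            region_profiles = prof,
            class = c("oriented_profile", class(tibble::tibble())))
}

#' Left/right flank summary of an oriented profile
#'
#' @param profile An `oriented_profile`.
#' @return One-row tibble with the mean profile value over the left and
#'   right flanks and their ratio.
#' @export
profile_asymmetry <- function(profile) {
  left <- mean(profile$mean_signal[profile$position < 0])
  right <- mean(profile$mean_signal[profile$position >= 0])
  tibble::tibble(left_mean = left, right_mean = right, ratio = left / right)
}

#' Plot an oriented profile
#'
#' @param object An `oriented_profile`.
#' @param ... Unused.
#' @return A ggplot of mean signal against oriented position, with the
#'   centre marked.
#' @export
autoplot.oriented_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$position / 1000, .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from centre (kb, oriented)",
                  y = "mean scaled signal") +
    ggplot2::theme_minimal()
}

#' ChIP-qPCR fold enrichment with delta-delta-Cq normalization
#'
#' Per replicate and antibody, enrichment over input is
#' `E = 2^(Cq_input - Cq_IP)` (amplification efficiency fixed at 2). `E`
#' is background-normalized by the geometric mean of `E` at the two
#' control (intergenic) sites for the same antibody, condition and
#' replicate, then the target antibody is normalized to total histone H3.
#' Per site, the treated/control fold is the ratio of mean final values,
#' with a two-sided Welch t-test across replicates.
#'
#' @param table Tibble with columns `site`, `antibody` (one of `"target"`,
#'   `"H3"`, `"input"`), `condition`, `replicate`, `cq`.
#' @param control_sites Character vector of exactly two control site ids.
#' @param treated,control The two condition labels.
#' @return List with `per_replicate` (site, condition, replicate,
#'   normalized target/H3 value) and `per_site` (site, mean per condition,
#'   `fold`, `p`).
#' @export
qpcr_enrichment <- function(table, control_sites,
                            treated = "treated", control = "control") {
  stopifnot(all(c("site", "antibody", "condition", "replicate", "cq") %in% names(table)))
  if (length(control_sites) != 2) stop("need exactly two control sites", call. = FALSE)
  if (!all(control_sites %in% table$site)) {
    stop("control site(s) missing from the table", call. = FALSE)
  }
  if (any(table$cq <= 0)) stop("Cq values must be > 0", call. = FALSE)
  wide <- tidyr::pivot_wider(table, names_from = "antibody", values_from = "cq")
  for (ab in c("target", "H3", "input")) {
    if (!ab %in% names(wide) || anyNA(wide[[ab]])) {
      stop("missing ", ab, " Cq for some (site, condition, replicate)", call. = FALSE)
    }
  }
  wide <- dplyr::mutate(wide,
                        e_target = 2^(.data$input - .data$target),
                        e_h3 = 2^(.data$input - .data$H3))
  ctrl <- wide |>
    dplyr::filter(.data$site %in% control_sites) |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(ctrl_target = exp(mean(log(.data$e_target))),
                     ctrl_h3 = exp(mean(log(.data$e_h3))), .groups = "drop")
  per_rep <- wide |>
    dplyr::inner_join(ctrl, by = c("condition", "replicate")) |>
    dplyr::mutate(final = (.data$e_target / .data$ctrl_target) /
                          (.data$e_h3 / .data$ctrl_h3)) |>
    dplyr::select("site", "condition", "replicate", "final")
  per_site <- per_rep |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      mean_treated = mean(.data$final[.data$condition == treated]),
      mean_control = mean(.data$final[.data$condition == control]),
      fold = .data$mean_treated / .data$mean_control,
      p = tryCatch(
        stats::t.test(.data$final[.data$condition == treated],
                      .data$final[.data$condition == control])$p.value,
        error = function(e) NA_real_),
      .groups = "drop"
    )
  list(per_replicate = per_rep, per_site = per_site)
}
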
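#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline. `preset = "paper"`
#' pins the reference parameterization: 10 bp bins, 100 bp median
#' smoothing, 95th-percentile threshold, 200 bp minimum peak length,
#' +/-150 bp protein and +/-250 bp histone windows, four fixed PCA
#' components and nine classes.
#'
#' @param alpha Pseudocount for log2 enrichment.
#' @param smooth_window Median-smoothing window, bp.
#' @param percentile Peak-calling percentile threshold.
#' @param min_length Minimum peak length, bp.
#' @param protein_half_window,histone_half_window Summarizer half-widths, bp.
#' @param n_classes Number of classes to cut the tree into.
#' @param selection Component-selection method (see [select_components()]).
#' @param k Components for `selection = "fixed"`.
#' @param promoter_window Promoter window (upstream, downstream), bp.
#' @param rgr_draws Random-region draws for overlap controls.
#' @param seed Root seed for all pipeline randomness.
#' @param preset `NULL` or `"paper"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.5, smooth_window = 100, percentile = 95,
                            min_length = 200, protein_half_window = 150,
                            histone_half_window = 250, n_classes = 6,
                            selection = "broken_stick", k = 4,
                            promoter_window = c(500, 100), rgr_draws = 100,
                            seed = 1, preset = NULL) {
  cfg <- list(alpha = alpha, smooth_window = smooth_window,
              percentile = percentile, min_length = min_length,
              protein_half_window = protein_half_window,
              histone_half_window = histone_half_window,
              n_classes = n_classes, selection = selection, k = k,
              promoter_window = promoter_window, rgr_draws = rgr_draws,
              seed = seed, preset = preset)
  if (!is.null(preset) && preset == "paper") {
    cfg$smooth_window <- 100; cfg$percentile <- 95; cfg$min_length <- 200
    cfg$protein_half_window <- 150; cfg$histone_half_window <- 250
    cfg$selection <- "fixed"; cfg$k <- 4; cfg$n_classes <- 9
  }
  stopifnot(cfg$percentile > 0, cfg$percentile < 100, cfg$min_length > 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Peaks are called on smoothed log2 IP/input enrichment, every dataset is
#' summarized at the peak centres into a binding matrix, the matrix is
#' classified by PCA + Ward clustering, and the classes are annotated
#' against the gene models and expression table. When the input carries a
#' truth table (synthetic data), planted-element recovery and the adjusted
#' Rand index between classes and archetype labels are reported.
#'
#' @param data A `crm_sim` from [simulate_dataset()], or a path to a
#'   manifest YAML written by [write_dataset()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `peaks.bed`, `enrichment.bedgraph`, `binding_matrix.tsv`,
#'   `classes.tsv` and `report.json`.
#' @return A `crm_pipeline` list: `peaks`, `enrichment` (smoothed track),
#'   `matrix`, `model`, `class_summary`, `recovery` (or `NULL`), `report`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  if (is.character(data)) data <- load_manifest(data)
  stopifnot(inherits(data, "crm_sim"))
  enr <- log2_enrichment(data$tracks[[data$ip]], data$tracks[[data$input]],
                         alpha = config$alpha)
  sm <- median_smooth(enr, window = config$smooth_window)
  peaks <- call_peaks(sm, percentile = config$percentile,
                      min_length = config$min_length)
  if (nrow(peaks) == 0) stop("pipeline stage call_peaks: no peaks called", call. = FALSE)
  factor_tracks <- purrr::map(
    data$tracks[setdiff(names(data$tracks), data$input)],
    ~ log2_enrichment(.x, data$tracks[[data$input]], alpha = config$alpha)
  )
  mat <- build_matrix(peaks, factor_tracks,
                      histone_datasets = data$histone_datasets,
                      protein_half_window = config$protein_half_window,
                      histone_half_window = config$histone_half_window,
                      alpha = config$alpha)
  model <- classify_peaks(mat, n_classes = config$n_classes,
                          method = config$selection, k = config$k)
  peaks_cl <- dplyr::left_join(peaks, model$classes, by = "peak_id")
  cls_summary <- summarize_classes(peaks_cl, data$genes, data$expression,
                                   promoter_window = config$promoter_window)
  recovery <- if (!is.null(data$truth)) {
    evaluate_recovery(peaks_cl, data$truth)
  }
  report <- list(
    parameters = unclass(config),
    seed = data$seed,
    n_peaks = nrow(peaks),
    threshold = attr(peaks, "threshold"),
    n_significant = model$n_significant,
    class_sizes = as.list(table(model$classes$class)),
    recovery = if (!is.null(recovery)) recovery[c("sensitivity", "fdr", "ari")]
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peaks_bed(peaks_cl, file.path(out_dir, "peaks.bed"))
    write_bedgraph(sm, file.path(out_dir, "enrichment.bedgraph"))
    readr::write_tsv(tibble::as_tibble(mat), file.path(out_dir, "binding_matrix.tsv"))
    readr::write_tsv(model$classes, file.path(out_dir, "classes.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    report$paths <- file.path(out_dir, c("peaks.bed", "enrichment.bedgraph",
                                         "binding_matrix.tsv", "classes.tsv",
                                         "report.json"))
  }
  structure(list(peaks = peaks_cl, enrichment = sm, matrix = mat, model = model,
                 class_summary = cls_summary, recovery = recovery,
                 report = report),
            class = "crm_pipeline")
}

#' @export
print.crm_pipeline <- function(x, ...) {
  cat("<crm_pipeline> ", nrow(x$peaks), " peaks, ",
      x$model$n_classes, " classes\n", sep = "")
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: sensitivity %.3f, FDR %.3f, ARI %.3f\n",
                x$recovery$sensitivity, x$recovery$fdr, x$recovery$ari))
  }
  invisible(x)
}

#' Evaluate peak and class recovery against a truth table
#'
#' Sensitivity is the fraction of planted elements overlapped (any bp) by
#' at least one called peak; FDR is the fraction of called peaks that
#' overlap no planted element. The adjusted Rand index compares class
#' labels with archetype labels over the truth-matched peaks.
#'
#' @param peaks Peak tibble, optionally with a `class` column.
#' @param truth Truth tibble from [simulate_dataset()] (`chrom`, `start`,
#'   `end`, `label`).
#' @return List: `sensitivity`, `fdr`, `n_peaks`, `n_truth`, `ari` (`NA`
#'   without a `class` column), and `matched` (peaks with their truth
#'   label).
#' @export
evaluate_recovery <- function(peaks, truth) {
  pk_gr <- regions_to_gr(peaks)
  tr_gr <- regions_to_gr(truth)
  hit_truth <- GenomicRanges::countOverlaps(tr_gr, pk_gr) > 0
  ov <- GenomicRanges::findOverlaps(pk_gr, tr_gr, select = "first")
  matched <- dplyr::mutate(peaks, truth_label = ifelse(is.na(ov), NA_character_,
                                                       truth$label[ov]))
  ari <- if ("class" %in% names(peaks)) {
    ok <- !is.na(matched$truth_label)
    mclust::adjustedRandIndex(matched$class[ok], matched$truth_label[ok])
  } else NA_real_
  list(
    sensitivity = mean(hit_truth),
    fdr = mean(is.na(ov)),
    n_peaks = nrow(peaks),
    n_truth = nrow(truth),
    ari = ari,
    matched = matched
  )
}

#' Write a simulated dataset to disk with a manifest
#'
#' Emits one bedGraph per track, the gene models as GFF3, expression and
#' time-course TSVs, truth and domain BED files, a genome TSV, and a
#' `manifest.yaml` tying them together for [run_pipeline()] or the
#' command-line wrapper.
#'
#' @param sim A `crm_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "crm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  track_files <- list()
  for (d in names(sim$tracks)) {
    f <- file.path(dir, paste0(d, ".bedgraph"))
    write_bedgraph(sim$tracks[[d]], f)
    track_files[[d]] <- basename(f)
  }
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$timecourse, file.path(dir, "timecourse.tsv"))
  write_bed(dplyr::mutate(sim$truth, name = .data$label),
            file.path(dir, "truth.bed"))
  write_bed(sim$domains, file.path(dir, "h3k27me3_domains.bed"))
  readr::write_tsv(tibble::tibble(chrom = names(sim$genome$chrom_lengths),
                                  length = sim$genome$chrom_lengths),
                   file.path(dir, "genome.tsv"))
  manifest <- list(
    genome = "genome.tsv",
    bin_size = sim$genome$bin_size,
    ip = sim$ip,
    input = sim$input,
    tracks = track_files,
    histone_datasets = as.list(sim$histone_datasets),
    genes = "genes.gff3",
    expression = "expression.tsv",
    timecourse = "timecourse.tsv",
    truth = "truth.bed",
    domains = "h3k27me3_domains.bed",
    n_classes = length(unique(sim$truth$label)),
    seed = sim$seed
  )
  mf <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}

#' Load a dataset from a manifest
#'
#' Validates that every referenced file exists (erroring with the missing
#' file name before any computation), then loads tracks, gene models,
#' expression tables and region sets into the same structure
#' [simulate_dataset()] returns.
#'
#' @param path Path to a `manifest.yaml` from [write_dataset()].
#' @return A `crm_sim` list.
#' @export
load_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  rel <- function(f) file.path(dir, f)
  needed <- c(m$genome, unlist(m$tracks), m$genes, m$expression,
              m$timecourse, m$truth, m$domains)
  for (f in needed) {
    if (!is.null(f) && !file.exists(rel(f))) {
      stop("manifest references missing file: ", f, call. = FALSE)
    }
  }
  gtab <- readr::read_tsv(rel(m$genome), show_col_types = FALSE)
  genome <- genome_model(stats::setNames(gtab$length, gtab$chrom),
                         bin_size = m$bin_size)
  tracks <- purrr::imap(m$tracks, ~ load_signal_track(rel(.x), genome))
  truth_regions <- if (!is.null(m$truth)) {
    tb <- load_regions(rel(m$truth), genome)
    tibble::tibble(chrom = tb$chrom, start = tb$start, end = tb$end,
                   centre = floor((tb$start + tb$end) / 2), label = tb$name,
                   gene_id = NA_character_)
  }
  structure(list(
    tracks = tracks, ip = m$ip, input = m$input,
    histone_datasets = unlist(m$histone_datasets),
    genome = genome,
    truth = truth_regions,
    genes = load_gene_annotation(rel(m$genes), genome),
    expression = readr::read_tsv(rel(m$expression), show_col_types = FALSE),
    timecourse = if (!is.null(m$timecourse))
      readr::read_tsv(rel(m$timecourse), show_col_types = FALSE),
    domains = if (!is.null(m$domains)) load_regions(rel(m$domains), genome),
    config = NULL, seed = m$seed
  ), class = "crm_sim")
}
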
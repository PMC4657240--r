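#' Default element archetypes
#'
#' Six regulatory-element archetypes emulating the structure recovered
#' from co-binding classification: active promoters, active and inactive
#' enhancers, Polycomb response elements embedded in H3K27me3 domains, and
#' insulator-like elements that either block H3K27me3 spreading
#' (acetylation-high) or let it cross (acetylation-low).
#'
#' @return Tibble with `label`, `width` (bp), `domain` (H3K27me3 domain
#'   behaviour: none / embedded / one-sided-stops / one-sided-crosses) and
#'   `expr_class` of the nearest gene.
#' @export
default_archetypes <- function() {
  tibble::tribble(
    ~label,            ~width, ~domain,            ~expr_class,
    "PROMOTER",        500,    "none",             "high",
    "ENH_ACTIVE",      500,    "none",             "high",
    "ENH_INACTIVE",    500,    "none",             "low",
    "PRE",             500,    "embedded",         "low",
    "INS_BLOCKING",    500,    "one-sided-stops",  "mid",
    "INS_NONBLOCKING", 500,    "one-sided-crosses","mid"
  )
}

#' Default per-archetype emission amplitudes
#'
#' Expected fold signal over background for each (archetype, dataset)
#' pair, at the element. Datasets absent from the table emit background.
#' The panel mimics a compact version of a many-factor co-binding screen:
#' the IP factor (CBP) plus polymerase, GAGA factor, Pho-complex and
#' Polycomb factors, insulator proteins, replication/cohesin factors, and
#' five histone modifications.
#'
#' @return Tibble with `label`, `dataset`, `amplitude`, `type`
#'   (protein/histone).
#' @export
default_amplitudes <- function() {
  proteins <- c("CBP", "PolII", "GAF", "Pho", "Pc", "CP190", "SuHw", "Orc2", "SMC1")
  histones <- c("H3K4me1", "H3K27ac", "H3K18ac", "H3K23ac", "H3K27me3")
  amp <- rbind(
    PROMOTER        = c(8, 10, 3, 1, 1, 3, 1, 4, 4,   2, 4, 3, 1, 1),
    ENH_ACTIVE      = c(6,  2, 4, 1, 1, 1, 1, 3, 3,   6, 6, 5, 1, 1),
    ENH_INACTIVE    = c(4,  1, 2, 1, 1, 1, 1, 1, 1,   3, 1, 1, 3, 1),
    PRE             = c(12, 1, 3, 8, 6, 1, 1, 2, 2,   2, 1, 1, 1, 1),
    INS_BLOCKING    = c(5,  1, 1, 1, 1, 6, 5, 3, 5,   1, 3, 3, 2, 1),
    INS_NONBLOCKING = c(5,  1, 1, 1, 1, 6, 5, 1, 1,   1, 1, 1, 1, 1)
  )
  colnames(amp) <- c(proteins, histones)
  tibble::as_tibble(amp, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "dataset", values_to = "amplitude") |>
    dplyr::mutate(type = ifelse(.data$dataset %in% histones, "histone", "protein"))
}

#' Synthetic dataset configuration
#'
#' Desk-scale study conditions: one 5 Mb chromosome binned at 10 bp,
#' Poisson background with mean 20 reads per bin, 40 elements per
#' archetype of width 500 bp, and a 4-fold H3K27me3 elevation inside
#' repressive domains.
#'
#' @param genome_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @param lambda_bg Background Poisson mean per bin.
#' @param n_per_archetype Elements planted per archetype.
#' @param archetypes Archetype table, see [default_archetypes()].
#' @param amplitudes Amplitude table, see [default_amplitudes()].
#' @param domain_fold H3K27me3 fold elevation inside domains.
#' @param dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson noise.
#' @param margin Element-free margin at each chromosome end, bp.
#' @return A config list for [simulate_dataset()].
#' @export
sim_config <- function(genome_length = 5e6, bin_size = 10, lambda_bg = 20,
                       n_per_archetype = 40, archetypes = default_archetypes(),
                       amplitudes = default_amplitudes(), domain_fold = 4,
                       dispersion = NULL, margin = 15000) {
  list(genome_length = genome_length, bin_size = bin_size, lambda_bg = lambda_bg,
       n_per_archetype = n_per_archetype, archetypes = archetypes,
       amplitudes = amplitudes, domain_fold = domain_fold,
       dispersion = dispersion, margin = margin)
}

#' Simulate a complete multi-factor dataset with ground truth
#'
#' Plants non-overlapping elements of the configured archetypes on a
#' synthetic chromosome and emits Poisson read-density tracks for the IP
#' (CBP), the input, every protein factor and every histone modification;
#' element signal follows a Gaussian kernel (sigma = width/4, truncated at
#' the element boundary, normalized so the mean fold over the element
#' equals the configured amplitude). H3K27me3 domains are laid down per
#' archetype: embedding the PRE elements, ending at blocking insulators,
#' and crossing >= 5 kb past non-blocking ones. Gene models are placed so
#' promoter archetypes straddle a TSS and enhancer archetypes fall in
#' introns; expression values and a developmental time course follow each
#' archetype's expression class. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed.
#' @return A `crm_sim` list: `tracks` (named `signal_track` list including
#'   `input`), `ip` (name of the IP track), `histone_datasets`, `genome`,
#'   `truth` (planted elements with labels), `genes`, `expression`,
#'   `timecourse`, `domains`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  with_seed(seed, simulate_dataset_impl(config, seed))
}

simulate_dataset_impl <- function(config, seed) {
  arch <- config$archetypes
  n_each <- config$n_per_archetype
  n_total <- nrow(arch) * n_each
  L <- config$genome_length
  usable <- L - 2 * config$margin
  spacing <- usable %/% n_total
  if (spacing < 4 * max(arch$width)) {
    stop("genome too small for the requested number of elements", call. = FALSE)
  }
  genome <- genome_model(c(chrS = L), bin_size = config$bin_size)

  jitter <- floor(stats::runif(n_total, -spacing / 8, spacing / 8))
  centres <- config$margin + (seq_len(n_total) - 0.5) * spacing + jitter
  centres <- round(centres)
  labels <- rep(arch$label, length.out = n_total)  # interleaved placement
  width_of <- stats::setNames(arch$width, arch$label)
  truth <- tibble::tibble(
    chrom = "chrS",
    centre = centres,
    label = labels,
    start = centres - width_of[labels] %/% 2,
    end = centres + width_of[labels] %/% 2,
    gene_id = sprintf("g%03d", seq_len(n_total))
  )[, c("chrom", "start", "end", "centre", "label", "gene_id")]

  domains <- build_domains(truth, arch, genome)
  tracks <- build_tracks(truth, domains, config, genome)
  ga <- build_genes(truth, arch)
  expr <- build_expression(truth, arch)
  tc <- build_timecourse(truth, arch)

  structure(list(
    tracks = tracks, ip = "CBP", input = "input",
    histone_datasets = unique(config$amplitudes$dataset[config$amplitudes$type == "histone"]),
    genome = genome, truth = truth, genes = ga, expression = expr,
    timecourse = tc, domains = domains, config = config, seed = seed
  ), class = "crm_sim")
}

build_domains <- function(truth, arch, genome) {
  beh <- stats::setNames(arch$domain, arch$label)
  rows <- purrr::pmap(truth, function(chrom, start, end, centre, label, gene_id) {
    b <- beh[[label]]
    if (b == "none") return(NULL)
    if (b == "embedded") {
      tibble::tibble(chrom = chrom, start = start - 5000, end = end + 5000,
                     name = paste0("dom_", gene_id))
    } else if (b == "one-sided-stops") {
      tibble::tibble(chrom = chrom, start = centre, end = centre + 10000,
                     name = paste0("dom_", gene_id))
    } else {  # one-sided-crosses: spreading unimpeded, plateau on both flanks
      tibble::tibble(chrom = chrom, start = centre - 10000, end = centre + 10000,
                     name = paste0("dom_", gene_id))
    }
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
                start = pmax(0, .data$start),
                end = pmin(genome$chrom_lengths[.data$chrom], .data$end))
}

build_tracks <- function(truth, domains, config, genome) {
  amp <- config$amplitudes
  datasets <- unique(amp$dataset)
  nb <- n_bins(genome)[["chrS"]]
  mids <- bin_midpoints(genome, "chrS")
  lam_bg <- config$lambda_bg
  draw <- function(lambda) {
    if (is.null(config$dispersion)) stats::rpois(length(lambda), lambda)
    else stats::rnbinom(length(lambda), size = config$dispersion, mu = lambda)
  }
  # per-archetype kernel weights, normalized to mean 1 over the element
  kernel_mult <- function(amplitude, centre, width) {
    i0 <- max(1, ((centre - width %/% 2) %/% genome$bin_size) + 1)
    i1 <- min(nb, ceiling((centre + width %/% 2) / genome$bin_size))
    idx <- i0:i1
    d <- mids[idx] - centre
    s <- width / 4
    kern <- exp(-d^2 / (2 * s^2))
    kern <- kern / mean(kern)
    list(idx = idx, mult = 1 + (amplitude - 1) * kern)
  }
  tracks <- list()
  tracks$input <- signal_track(list(chrS = as.double(draw(rep(lam_bg, nb)))),
                               genome, "raw_density")
  for (d in datasets) {
    a_of <- amp[amp$dataset == d, ]
    a_map <- stats::setNames(a_of$amplitude, a_of$label)
    mult <- rep(1, nb)
    for (i in seq_len(nrow(truth))) {
      a <- a_map[[truth$label[i]]]
      if (is.na(a) || a == 1) next
      km <- kernel_mult(a, truth$centre[i], truth$end[i] - truth$start[i])
      mult[km$idx] <- pmax(mult[km$idx], km$mult)
    }
    if (d == "H3K27me3" && nrow(domains) > 0) {
      for (i in seq_len(nrow(domains))) {
        i0 <- max(1, (domains$start[i] %/% genome$bin_size) + 1)
        i1 <- min(nb, ceiling(domains$end[i] / genome$bin_size))
        mult[i0:i1] <- pmax(mult[i0:i1], config$domain_fold)
      }
    }
    tracks[[d]] <- signal_track(list(chrS = as.double(draw(lam_bg * mult))),
                                genome, "raw_density")
  }
  tracks
}

build_genes <- function(truth, arch) {
  rows <- purrr::pmap(truth, function(chrom, start, end, centre, label, gene_id) {
    if (label == "PROMOTER") {
      strand <- if (as.integer(sub("g", "", gene_id)) %% 2 == 0) "-" else "+"
      if (strand == "+") {
        g <- c(centre, centre + 2000)
        ex <- list(c(centre, centre + 400), c(centre + 1600, centre + 2000))
      } else {
        g <- c(centre - 1999, centre + 1)
        ex <- list(c(centre - 399, centre + 1), c(centre - 1999, centre - 1599))
      }
    } else if (label %in% c("ENH_ACTIVE", "ENH_INACTIVE")) {
      strand <- "+"
      g <- c(centre - 1500, centre + 2500)
      ex <- list(c(g[1], g[1] + 200), c(g[2] - 500, g[2]))
    } else {
      strand <- "+"
      g <- c(centre + 4000, centre + 6000)
      ex <- list(c(g[1], g[1] + 400), c(g[2] - 400, g[2]))
    }
    list(
      gene = tibble::tibble(gene_id = gene_id, chrom = chrom,
                            start = g[1], end = g[2], strand = strand),
      exons = tibble::tibble(gene_id = gene_id,
                             start = vapply(ex, `[`, double(1), 1),
                             end = vapply(ex, `[`, double(1), 2))
    )
  })
  gene_annotation(dplyr::bind_rows(purrr::map(rows, "gene")),
                  dplyr::bind_rows(purrr::map(rows, "exons")))
}

build_expression <- function(truth, arch) {
  cls <- stats::setNames(arch$expr_class, arch$label)[truth$label]
  lo <- c(low = 0, mid = 4, high = 8)
  tibble::tibble(
    gene_id = truth$gene_id,
    value = stats::runif(nrow(truth), lo[cls], lo[cls] + 2),
    expr_class_true = unname(cls)
  )
}

build_timecourse <- function(truth, arch, n_tp = 10) {
  cls <- stats::setNames(arch$expr_class, arch$label)[truth$label]
  late <- truth$label == "ENH_INACTIVE"  # poised elements activate late
  base <- ifelse(cls == "high", 8, ifelse(cls == "mid", 5, 1))
  X <- matrix(stats::rnorm(nrow(truth) * n_tp, sd = 0.1), nrow(truth), n_tp) + base
  ramp <- c(rep(0, n_tp - 4), cumsum(rep(0.8, 4)))
  if (any(late)) {
    X[late, ] <- X[late, ] + matrix(ramp, sum(late), n_tp, byrow = TRUE)
  }
  colnames(X) <- sprintf("tp_%02d", seq_len(n_tp))
  dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id), tibble::as_tibble(X))
}

#' Simulate foreground and control sequence sets with planted words
#'
#' Foreground sequences are i.i.d. draws from a base composition with the
#' given A/T fraction, with each configured word planted `rate` times per
#' sequence at non-overlapping positions (background chance can add
#' further occurrences). Controls are word-free draws from the same
#' composition; optionally a fraction of controls is generated at an A/T
#' content pushed outside the foreground range, to exercise the
#' composition filter.
#'
#' @param n,n_controls Number of foreground / control sequences.
#' @param length Sequence length in bp.
#' @param at Base A/T fraction (strictly between 0 and 1).
#' @param words Named numeric vector: planted word -> copies per sequence.
#' @param at_outlier_frac Fraction of controls drawn at `at` +/- 0.25.
#' @param seed Integer seed.
#' @return List of `foreground` and `controls` (`DNAStringSet`s).
#' @export
simulate_sequences <- function(n = 100, length = 500, at = 0.55,
                               words = c(GAGAG = 3), n_controls = 100,
                               at_outlier_frac = 0, seed = 1) {
  if (at <= 0 || at >= 1) stop("`at` must be strictly between 0 and 1", call. = FALSE)
  if (any(nchar(names(words)) > length)) {
    stop("planted word longer than the sequence", call. = FALSE)
  }
  with_seed(seed, {
    probs_for <- function(a) stats::setNames(c(a / 2, (1 - a) / 2, (1 - a) / 2, a / 2),
                                             c("A", "C", "G", "T"))
    rand_seq <- function(a) {
      p <- probs_for(a)
      paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
    }
    plants <- rep(names(words), times = words)
    n_slots <- max(1, base::length(plants))
    slot_len <- length %/% n_slots
    if (base::length(plants) > 0 && slot_len < 2 * max(nchar(names(words)))) {
      stop("too many planted words for the sequence length", call. = FALSE)
    }
    fg <- vapply(seq_len(n), function(i) {
      s <- strsplit(rand_seq(at), "")[[1]]
      ord <- sample(plants)
      for (j in seq_along(ord)) {
        w <- strsplit(ord[j], "")[[1]]
        lo <- (j - 1) * slot_len + 1
        hi <- j * slot_len - base::length(w)
        pos <- sample(lo:hi, 1)
        s[pos:(pos + base::length(w) - 1)] <- w
      }
      paste(s, collapse = "")
    }, character(1))
    word_free <- function(a) {
      for (try in 1:200) {
        s <- rand_seq(a)
        if (!any(vapply(names(words), grepl, logical(1), x = s, fixed = TRUE))) return(s)
      }
      stop("could not draw a word-free control; words too frequent", call. = FALSE)
    }
    n_out <- round(n_controls * at_outlier_frac)
    ctl <- character(n_controls)
    for (i in seq_len(n_controls)) {
      a <- if (i <= n_out) {
        min(max(at + ifelse(i %% 2 == 0, 0.25, -0.25), 0.02), 0.98)
      } else at
      ctl[i] <- word_free(a)
    }
    list(
      foreground = stats::setNames(Biostrings::DNAStringSet(fg),
                                   sprintf("fg_%03d", seq_len(n))),
      controls = stats::setNames(Biostrings::DNAStringSet(ctl),
                                 sprintf("ctl_%03d", seq_len(n_controls)))
    )
  })
}

#' Simulate a ChIP-qPCR Cq table with a known treated/control fold
#'
#' Generates Cq values for a test site and two intergenic control sites,
#' three antibodies (target, total H3, input), two conditions and the
#' requested replicates. The target's true enrichment at the test site is
#' multiplied by `fold` under treatment; each replicate-condition carries
#' a machine Cq offset, and every measured Cq gets Gaussian noise.
#'
#' @param fold True treated/control fold change at the test site.
#' @param sigma Gaussian Cq noise SD per measurement.
#' @param replicates Number of biological replicates.
#' @param base_enrichment Target enrichment over input at the test site
#'   (control condition).
#' @param h3_enrichment H3 enrichment over input, all sites.
#' @param seed Integer seed.
#' @return Tibble with `site`, `antibody`, `condition`, `replicate`, `cq`;
#'   control sites are `"ctrl_1"` and `"ctrl_2"`.
#' @export
simulate_qpcr <- function(fold = 2.4, sigma = 0.1, replicates = 4,
                          base_enrichment = 4, h3_enrichment = 8, seed = 1) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      site = c("site_1", "ctrl_1", "ctrl_2"),
      condition = c("treated", "control"),
      replicate = seq_len(replicates)
    )
    offset <- stats::setNames(
      stats::rnorm(2 * replicates, sd = 0.3),
      paste(rep(c("treated", "control"), each = replicates), seq_len(replicates))
    )
    rows <- purrr::pmap(grid, function(site, condition, replicate) {
      off <- offset[[paste(condition, replicate)]]
      cq_in <- 25 + off
      e_t <- if (site == "site_1") {
        base_enrichment * ifelse(condition == "treated", fold, 1)
      } else 1
      tibble::tibble(
        site = site, condition = condition, replicate = replicate,
        antibody = c("input", "target", "H3"),
        cq = c(cq_in + stats::rnorm(1, sd = sigma),
               cq_in - log2(e_t) + stats::rnorm(1, sd = sigma),
               cq_in - log2(h3_enrichment) + stats::rnorm(1, sd = sigma))
      )
    })
    dplyr::bind_rows(rows)[, c("site", "antibody", "condition", "replicate", "cq")]
  })
}
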
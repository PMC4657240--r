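#' Load a bedGraph file as a binned signal track
#'
#' Intervals are rasterized onto the genome's uniform bin grid: each bin
#' takes the value of the interval covering its midpoint; bins covered by
#' no interval are 0. Input intervals may be unsorted but must not overlap.
#'
#' @param path Path to a bedGraph file.
#' @param genome A [genome_model()] defining chromosomes and bin width.
#' @param semantics Signal semantics to record on the track.
#' @return A `signal_track`.
#' @export
load_signal_track <- function(path, genome,
                              semantics = c("raw_density", "log2_enrichment", "scaled")) {
  stopifnot(inherits(genome, "genome_model"))
  semantics <- match.arg(semantics)
  if (file.exists(path) && file.size(path) == 0) {
    return(signal_track(empty_values(genome), genome, semantics))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end   = as.double(GenomicRanges::end(gr)),
    value = as.double(S4Vectors::mcols(gr)$score),
    line  = seq_along(gr)
  )
  if (nrow(tb) == 0) {
    return(signal_track(empty_values(genome), genome, semantics))
  }
  check_chrom(tb$chrom, genome, what = basename(path))
  tb <- dplyr::arrange(tb, .data$chrom, .data$start)
  ov <- tb |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(overlaps = .data$start < dplyr::lag(.data$end, default = -Inf)) |>
    dplyr::ungroup()
  if (any(ov$overlaps)) {
    bad <- ov$line[which(ov$overlaps)[1]]
    stop("overlapping intervals in ", basename(path), " (first at record ", bad, ")",
         call. = FALSE)
  }
  vals <- empty_values(genome)
  for (chr in unique(tb$chrom)) {
    iv <- tb[tb$chrom == chr, ]
    mids <- bin_midpoints(genome, chr)
    idx <- findInterval(mids, iv$start)
    hit <- idx > 0 & mids < iv$end[pmax(idx, 1L)]
    v <- vals[[chr]]
    v[hit] <- iv$value[idx[hit]]
    vals[[chr]] <- v
  }
  signal_track(vals, genome, semantics)
}

empty_values <- function(genome) {
  nb <- n_bins(genome)
  stats::setNames(lapply(nb, function(n) numeric(n)), names(nb))
}

#' Load genomic regions from BED or GFF3
#'
#' BED coordinates are taken as-is (0-based, half-open); GFF3 features are
#' converted from 1-based inclusive. Format is inferred from the file
#' extension unless given.
#'
#' @param path Path to a BED or GFF3 file.
#' @param genome A [genome_model()]; records on unknown chromosomes are an
#'   error unless `lenient = TRUE`, in which case they are dropped with a
#'   warning.
#' @param format `"bed"`, `"gff3"` or `NULL` (infer from extension).
#' @param lenient Drop records on unknown chromosomes instead of erroring.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based, half-open).
#' @export
load_regions <- function(path, genome, format = NULL, lenient = FALSE) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3", "gtf")) "gff3" else "bed"
  }
  gr <- if (format == "gff3") {
    rtracklayer::import(path, format = "GFF3")
  } else {
    rtracklayer::import(path, format = "BED")
  }
  mc <- S4Vectors::mcols(gr)
  tb <- tibble::tibble(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1,
    end    = as.double(GenomicRanges::end(gr)),
    name   = if ("name" %in% names(mc)) as.character(mc$name) else
             if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
    score  = if ("score" %in% names(mc)) as.double(mc$score) else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(tb$end <= tb$start)) {
    stop("region with end <= start in ", basename(path), call. = FALSE)
  }
  known <- tb$chrom %in% names(genome$chrom_lengths)
  if (!all(known)) {
    if (lenient) {
      warning("dropping ", sum(!known), " record(s) on unknown chromosomes")
      tb <- tb[known, ]
    } else {
      check_chrom(tb$chrom, genome, what = basename(path))
    }
  }
  too_long <- tb$end > genome$chrom_lengths[tb$chrom]
  if (any(too_long)) {
    stop("region extends past chromosome end in ", basename(path), call. = FALSE)
  }
  tb
}

#' Write regions to a BED6 file
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  n <- nrow(regions)
  out <- tibble::tibble(
    chrom  = regions$chrom,
    start  = format(regions$start, scientific = FALSE, trim = TRUE),
    end    = format(regions$end, scientific = FALSE, trim = TRUE),
    name   = if ("name" %in% names(regions)) dplyr::coalesce(regions$name, ".") else rep(".", n),
    score  = if ("score" %in% names(regions)) dplyr::coalesce(regions$score, 0) else rep(0, n),
    strand = if ("strand" %in% names(regions)) {
      ifelse(regions$strand %in% c("+", "-"), regions$strand, ".")
    } else rep(".", n)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal-valued adjacent bins are collapsed into single intervals;
#' zero-valued runs are omitted (absence means zero on re-load).
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  genome <- track_genome(track)
  vals <- track_values(track)
  rows <- lapply(names(vals), function(chr) {
    v <- vals[[chr]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    tibble::tibble(
      chrom = chr,
      start = starts_bin[keep] * genome$bin_size,
      end   = pmin(ends_bin[keep] * genome$bin_size, genome$chrom_lengths[[chr]]),
      value = r$values[keep]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Assemble a gene annotation
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (gene span, 0-based half-open).
#' @param exons Tibble with `gene_id`, `start`, `end`; every exon must lie
#'   within its gene's span.
#' @return A tibble of genes with a computed `tss` column (0-based position
#'   of the 5' base) and the exon table attached as attribute `exons`.
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids", call. = FALSE)
  ex <- dplyr::left_join(exons, genes, by = "gene_id", suffix = c("", ".gene"))
  if (any(is.na(ex$start.gene))) stop("exon with unknown gene id", call. = FALSE)
  if (any(ex$start < ex$start.gene | ex$end > ex$end.gene)) {
    stop("exon outside its gene span", call. = FALSE)
  }
  genes <- dplyr::mutate(
    genes,
    tss = ifelse(.data$strand == "-", .data$end - 1, .data$start)
  )
  structure(genes, exons = tibble::as_tibble(exons),
            class = c("gene_annotation", class(tibble::tibble())))
}

#' Exon table of a gene annotation
#' @param genes A [gene_annotation()].
#' @return Tibble of exons (`gene_id`, `start`, `end`).
#' @export
gene_exons <- function(genes) attr(genes, "exons", exact = TRUE)

#' Load a gene annotation from GFF3
#'
#' Reads `gene` and `exon` features; exons are attached to genes through
#' their `Parent` attribute. Coordinates are converted to 0-based,
#' half-open.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [genome_model()].
#' @return A [gene_annotation()] tibble.
#' @export
load_gene_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "GFF3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- as.character(mc$ID)
  parent <- vapply(as.list(mc$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  is_gene <- type == "gene"
  genes <- tibble::tibble(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1,
    end = as.double(GenomicRanges::end(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene]
  )
  check_chrom(genes$chrom, genome, what = basename(path))
  is_exon <- type == "exon"
  exons <- tibble::tibble(
    gene_id = sub("^(transcript|mRNA):", "", parent[is_exon]),
    start = GenomicRanges::start(gr)[is_exon] - 1,
    end = as.double(GenomicRanges::end(gr))[is_exon]
  )
  gene_annotation(genes, exons)
}

#' Write a gene annotation to GFF3
#'
#' @param genes A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  ex <- gene_exons(genes)
  gene_lines <- sprintf("%s\tcrmclass\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        genes$chrom, as.integer(genes$start + 1),
                        as.integer(genes$end), genes$strand, genes$gene_id)
  chrom_of <- stats::setNames(genes$chrom, genes$gene_id)
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  exon_lines <- sprintf("%s\tcrmclass\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                        chrom_of[ex$gene_id], as.integer(ex$start + 1),
                        as.integer(ex$end), strand_of[ex$gene_id],
                        ex$gene_id, seq_len(nrow(ex)), ex$gene_id)
  writeLines(c("##gff-version 3", gene_lines, exon_lines), path)
  invisible(path)
}

# GRanges view of a (chrom, start, end) tibble; internal, 1-based conversion
regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}
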
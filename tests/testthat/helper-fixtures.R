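# shared fixtures; the default simulated dataset is expensive enough to cache
# across test files (one R session per test run)

tiny_genome <- function(len = 100, bin = 10) {
  genome_model(c(chrA = len), bin_size = bin)
}

# track over one chromosome from a plain numeric vector
vec_track <- function(x, bin = 10, semantics = "log2_enrichment", chrom = "chrA") {
  gen <- genome_model(stats::setNames(length(x) * bin, chrom), bin_size = bin)
  signal_track(stats::setNames(list(as.double(x)), chrom), gen, semantics)
}

.crm_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 11) {
  key <- paste0("sim", seed)
  if (is.null(.crm_cache[[key]])) .crm_cache[[key]] <- simulate_dataset(seed = seed)
  .crm_cache[[key]]
}

default_pipeline <- function(seed = 11) {
  key <- paste0("pl", seed)
  if (is.null(.crm_cache[[key]])) {
    .crm_cache[[key]] <- run_pipeline(default_sim(seed),
                                      pipeline_config(n_classes = 6, seed = seed))
  }
  .crm_cache[[key]]
}

small_sim <- function(seed = 3) {
  key <- paste0("small", seed)
  if (is.null(.crm_cache[[key]])) {
    .crm_cache[[key]] <- simulate_dataset(
      sim_config(genome_length = 1e6, n_per_archetype = 5), seed = seed)
  }
  .crm_cache[[key]]
}

# binding matrix built by hand for subclassification tests
make_bm <- function(df, histone_cols = setdiff(names(df), "peak_id"),
                    gmean = 0, gmax = 1) {
  cols <- setdiff(names(df), "peak_id")
  meta <- tibble::tibble(dataset = cols, genomic_mean = gmean, genomic_max = gmax,
                         half_window = 250, is_histone = cols %in% histone_cols)
  structure(tibble::as_tibble(df), column_meta = meta,
            class = c("binding_matrix", class(tibble::tibble())))
}

simple_genes <- function(genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- tibble::tibble(gene_id = genes$gene_id, start = genes$start,
                            end = genes$end)
  }
  gene_annotation(genes, exons)
}
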
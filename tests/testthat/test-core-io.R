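test_that("bedGraph rasterization expands intervals onto the bin grid", {
  gen <- genome_model(c(chrA = 100), bin_size = 50)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrA\t0\t100\t5.0", f)
  tr <- load_signal_track(f, gen)
  expect_equal(tr$value, c(5, 5))

  # value applies to the bin whose midpoint the interval covers
  gen10 <- genome_model(c(chrA = 100), bin_size = 10)
  writeLines(c("chrA\t0\t35\t2.0", "chrA\t35\t60\t7.0"), f)
  tr <- load_signal_track(f, gen10)
  expect_equal(tr$value, c(2, 2, 2, 7, 7, 7, 0, 0, 0, 0))
})

test_that("empty bedGraph yields an all-zero track", {
  gen <- genome_model(c(chrA = 100, chrB = 50), bin_size = 10)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(f)
  tr <- load_signal_track(f, gen)
  expect_equal(sum(tr$value), 0)
  expect_equal(nrow(tr), 15)
})

test_that("overlapping bedGraph intervals are a format error", {
  gen <- genome_model(c(chrA = 200), bin_size = 10)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chrA\t0\t100\t1", "chrA\t50\t150\t2"), f)
  expect_error(load_signal_track(f, gen), "overlap")
})

test_that("unknown chromosomes in inputs are rejected", {
  gen <- genome_model(c(chrA = 200), bin_size = 10)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrZ\t0\t100\t1", f)
  expect_error(load_signal_track(f, gen), "chrZ")
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrZ\t0\t100", b)
  expect_error(load_regions(b, gen), "chrZ")
  expect_warning(out <- load_regions(b, gen, lenient = TRUE), "dropping")
  expect_equal(nrow(out), 0)
})

test_that("BED is read as-is and GFF3 is converted to 0-based half-open", {
  gen <- genome_model(c(chrA = 1000), bin_size = 10)
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA\t100\t300\tr1\t0\t+", b)
  rb <- load_regions(b, gen)
  expect_equal(rb$end - rb$start, 200)
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tregion\t101\t300\t.\t+\t.\tID=r1"), g)
  rg <- load_regions(g, gen)
  expect_equal(c(rg$start, rg$end), c(100, 300))
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA\t300\t100\tr1\t0\t+", bad)
  expect_error(load_regions(bad, gen))
})

test_that("write_bed / load_regions round-trips coordinates", {
  gen <- genome_model(c(chrA = 5000, chrB = 3000), bin_size = 10)
  set.seed(42)
  st <- sort(sample(0:2400, 20))
  regions <- tibble::tibble(chrom = sample(c("chrA", "chrB"), 20, replace = TRUE),
                            start = st, end = st + sample(50:500, 20),
                            name = sprintf("r%02d", 1:20),
                            score = 1:20, strand = "+")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, f)
  back <- load_regions(f, gen)
  expect_equal(back[, c("chrom", "start", "end")],
               regions[, c("chrom", "start", "end")])
  expect_equal(back$name, regions$name)
})

test_that("rasterization conserves coverage for bin-aligned intervals", {
  gen <- genome_model(c(chrA = 1000), bin_size = 10)
  set.seed(7)
  starts <- seq(0, 900, by = 100)
  keep <- sample(c(TRUE, FALSE), length(starts), replace = TRUE)
  iv <- tibble::tibble(start = starts[keep], end = starts[keep] + 50,
                       value = round(stats::runif(sum(keep)), 2))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(sprintf("chrA\t%d\t%d\t%s", iv$start, iv$end, iv$value), f)
  tr <- load_signal_track(f, gen)
  expect_equal(sum(tr$value * 10), sum(iv$value * (iv$end - iv$start)))
})

test_that("genomic_stats matches a brute-force scan", {
  st <- genomic_stats(vec_track(c(0, 1, 2, 3)))
  expect_equal(st$genomic_mean, 1.5)
  expect_equal(st$genomic_max, 3)
  const <- genomic_stats(vec_track(rep(2.5, 8)))
  expect_equal(const$genomic_mean, const$genomic_max)
  set.seed(99)
  tr <- vec_track(stats::rnorm(1e4))
  bf <- bf_genomic_stats(tr)
  st <- genomic_stats(tr)
  expect_equal(st$genomic_mean, unname(bf["mean"]))
  expect_equal(st$genomic_max, unname(bf["max"]))
})

test_that("bedGraph write/load round-trips a track", {
  sim <- small_sim()
  tr <- sim$tracks$CBP
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- load_signal_track(f, sim$genome)
  expect_equal(back$value, tr$value)
})

test_that("gene annotation validates spans and computes strand-aware TSS", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chrA",
                          start = c(100, 500), end = c(300, 900),
                          strand = c("+", "-"))
  exons <- tibble::tibble(gene_id = c("g1", "g2"), start = c(100, 700),
                          end = c(200, 900))
  ga <- gene_annotation(genes, exons)
  expect_equal(ga$tss, c(100, 899))
  bad_ex <- tibble::tibble(gene_id = "g1", start = 50, end = 200)
  expect_error(gene_annotation(genes, bad_ex), "outside")
})

test_that("GFF3 gene annotation round-trips through write_gff3", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes, f)
  back <- load_gene_annotation(f, sim$genome)
  expect_equal(back$gene_id, sim$genes$gene_id)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$tss, sim$genes$tss)
  expect_equal(nrow(gene_exons(back)), nrow(gene_exons(sim$genes)))
})
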
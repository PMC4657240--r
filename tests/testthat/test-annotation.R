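anno_fixture <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chrA",
    start = c(1000, 5000), end = c(3000, 7000), strand = c("+", "+"))
  exons <- tibble::tibble(gene_id = c("gA", "gA", "gB"),
                          start = c(1000, 2500, 5000),
                          end = c(1400, 3000, 7000))
  gene_annotation(genes, exons)
}

test_that("feature assignment follows promoter > exon > intron > intergenic", {
  ga <- anno_fixture()
  pk <- tibble::tibble(chrom = "chrA",
                       centre = c(950, 1200, 2000, 50000, 4950))
  feat <- assign_feature(pk, ga)$feature
  expect_equal(as.character(feat),
               c("promoter",    # 50 bp upstream of gA's TSS
                 "exon", "intron", "intergenic",
                 "promoter"))   # inside gB's promoter window
  # a centre inside an exon that also lies in another gene's promoter window
  genes2 <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chrA",
                           start = c(1000, 1600), end = c(1500, 2600),
                           strand = "+")
  exons2 <- tibble::tibble(gene_id = c("g1", "g2"), start = c(1000, 1600),
                           end = c(1500, 2600))
  ga2 <- gene_annotation(genes2, exons2)
  f <- assign_feature(tibble::tibble(chrom = "chrA", centre = 1300), ga2)$feature
  expect_equal(as.character(f), "promoter")  # g2's window [1100, 1700) wins
})

test_that("minus-strand promoters extend upstream in gene orientation", {
  genes <- tibble::tibble(gene_id = "gm", chrom = "chrA", start = 1000,
                          end = 3000, strand = "-")
  ga <- gene_annotation(genes, tibble::tibble(gene_id = "gm", start = 1000, end = 3000))
  # TSS at 2999; upstream is rightward
  f <- assign_feature(tibble::tibble(chrom = "chrA", centre = c(3200, 2950, 2850)),
                      ga)$feature
  expect_equal(as.character(f), c("promoter", "promoter", "exon"))
})

test_that("expression tertiles have near-equal sizes with deterministic ties", {
  e9 <- tibble::tibble(gene_id = sprintf("g%02d", 1:9), value = (1:9) * 1.1)
  b9 <- expression_bins(e9)
  expect_equal(as.integer(table(b9$expr_bin)), c(3, 3, 3))
  e10 <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), value = 10:1)
  b10 <- expression_bins(e10)
  expect_equal(as.integer(table(b10$expr_bin)), c(4, 3, 3))
  expect_equal(as.character(b10$expr_bin[b10$gene_id == "g10"]), "low")
  ties <- tibble::tibble(gene_id = c("gc", "ga", "gb"), value = 1)
  bt <- expression_bins(ties)
  expect_equal(as.character(bt$expr_bin[order(bt$gene_id)]),
               c("low", "mid", "high"))
})

test_that("nearest gene minimizes TSS distance with id tie-breaking", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chrA",
                          start = c(1000, 5000), end = c(2000, 6000),
                          strand = "+")
  ga <- gene_annotation(genes, tibble::tibble(gene_id = c("g1", "g2"),
                                              start = c(1000, 5000),
                                              end = c(2000, 6000)))
  pk <- tibble::tibble(chrom = "chrA", centre = c(2000, 3000, 5500))
  ng <- nearest_gene(pk, ga)
  expect_equal(ng$gene_id, c("g1", "g1", "g2"))  # 3000 is equidistant: g1 wins
  expect_equal(ng$tss_distance, c(1000, 2000, 500))
  one <- nearest_gene(pk, ga[ga$gene_id == "g2", ])
  expect_true(all(one$gene_id == "g2"))
})

test_that("overlap fractions hit the trivial anchors and are order-invariant", {
  gen <- genome_model(c(chrA = 1e5), bin_size = 10)
  regions <- tibble::tibble(chrom = "chrA", start = seq(0, 9000, 1000),
                            end = seq(0, 9000, 1000) + 500)
  self <- overlap_fraction(regions, regions, gen, n_draws = 5, seed = 1)
  expect_equal(self$fraction, 1)
  far <- tibble::tibble(chrom = "chrA", start = 50000, end = 60000)
  expect_equal(overlap_fraction(regions, far, gen, n_draws = 5, seed = 1)$fraction, 0)
  expect_error(overlap_fraction(regions[0, ], far, gen), "empty")
  # reference record order and merging adjacent records do not matter
  ref <- tibble::tibble(chrom = "chrA", start = c(0, 250, 3000),
                        end = c(250, 600, 4000))
  merged <- tibble::tibble(chrom = "chrA", start = c(0, 3000), end = c(600, 4000))
  f1 <- overlap_fraction(regions, ref, gen, n_draws = 5, seed = 2)
  f2 <- overlap_fraction(regions, ref[c(3, 1, 2), ], gen, n_draws = 5, seed = 2)
  f3 <- overlap_fraction(regions, merged, gen, n_draws = 5, seed = 2)
  expect_equal(f1$fraction, f2$fraction)
  expect_equal(f1$fraction, f3$fraction)
})

test_that("random-region control converges to the reference coverage", {
  gen <- genome_model(c(chrA = 1e5), bin_size = 10)
  # reference covers 40% of the genome
  ref <- tibble::tibble(chrom = "chrA", start = seq(0, 99000, 1000),
                        end = seq(0, 99000, 1000) + 400)
  regions <- tibble::tibble(chrom = "chrA",
                            start = seq(10, 99000, length.out = 200),
                            end = seq(10, 99000, length.out = 200) + 10)
  res <- overlap_fraction(regions, ref, gen, n_draws = 50, seed = 7)
  p_hit <- (400 + 10) / 1000  # 1 bp overlap needs start within len+10 of a block
  se <- sqrt(p_hit * (1 - p_hit) / (200 * 50))
  expect_lt(abs(res$rgr_fraction - p_hit), 3 * se + 0.01)
})

test_that("gene-overlap matrix is row-normalized and asymmetric", {
  sets <- list(c1 = c("a", "b", "c", "d"), c2 = "a", c3 = c("x", "y"))
  M <- gene_overlap_matrix(sets)
  expect_equal(diag(M), c(c1 = 100, c2 = 100, c3 = 100))
  expect_equal(M["c1", "c2"], 25)
  expect_equal(M["c2", "c1"], 100)
  expect_equal(M["c1", "c3"], 0)
  expect_error(gene_overlap_matrix(list(a = "g", b = character())), "empty")
})

test_that("factor correlation is a rank statistic with proper degeneracy handling", {
  set.seed(20)
  anchor <- stats::rnorm(30)
  bm <- tibble::tibble(peak_id = sprintf("p%02d", 1:30),
                       CBP = anchor,
                       same = anchor,
                       mono = exp(anchor),
                       indep = stats::rnorm(30),
                       const = 1)
  cls <- tibble::tibble(peak_id = bm$peak_id, class = 1L)
  expect_warning(res <- factor_correlation(bm, cls, anchor = "CBP"), "constant")
  expect_equal(res$rho[res$dataset == "same"], 1)
  expect_equal(res$rho[res$dataset == "mono"], 1)
  expect_true(is.na(res$rho[res$dataset == "const"]))
  small <- tibble::tibble(peak_id = bm$peak_id[1:3], class = 1L)
  expect_warning(factor_correlation(bm[1:3, ], small, anchor = "CBP"), "< 4")
})

test_that("developmental profiles are mean-centered expression deltas", {
  tc <- tibble::tibble(gene_id = c("g1", "g2"),
                       t1 = c(1, 5), t2 = c(1, 5), t3 = c(1, 5))
  prof <- dev_expression_profile(tc, c("g1", "g2"))
  expect_equal(prof$delta, c(0, 0))
  rising <- tibble::tibble(gene_id = "g1", t1 = 0, t2 = 1, t3 = 2, t4 = 3)
  pr <- dev_expression_profile(rising, "g1")
  expect_equal(pr$delta, rep(0, 3))  # constant +1 deltas center to zero
  expect_equal(mean(dev_expression_profile(
    tibble::tibble(gene_id = "g1", t1 = 0, t2 = 3, t3 = 1), "g1")$delta), 0)
})

test_that("fraction_enriched thresholds the maximum regional enrichment", {
  x <- rep(0, 100)
  x[11:20] <- 1.5   # regions over these bins exceed log2(2)
  tr <- vec_track(x)
  all_over <- tibble::tibble(chrom = "chrA", start = c(100, 120), end = c(160, 200))
  expect_equal(fraction_enriched(all_over, tr), 1)
  zero <- tibble::tibble(chrom = "chrA", start = c(400, 600), end = c(500, 700))
  expect_equal(fraction_enriched(zero, tr), 0)
  # constructed 30%: 3 of 10 regions reach the threshold
  mixed <- tibble::tibble(chrom = "chrA",
                          start = c(100, 130, 160, seq(300, 900, 100)),
                          end = c(120, 150, 200, seq(300, 900, 100) + 50))
  expect_equal(fraction_enriched(mixed, tr), 0.3)
  expect_error(fraction_enriched(mixed[0, ], tr), "empty")
})

test_that("domain distances are edge distances with a rank-based comparison", {
  domains <- tibble::tibble(chrom = "chrA", start = c(10000, 50000),
                            end = c(20000, 60000))
  inside <- tibble::tibble(chrom = "chrA", centre = 15000)
  left <- tibble::tibble(chrom = "chrA", centre = 5000)
  res <- distance_to_domains(dplyr::bind_rows(inside, left), domains, inside)
  expect_equal(res$distances, c(0, 5000))
  set.seed(30)
  near <- tibble::tibble(chrom = "chrA",
                         centre = 20000 + round(stats::rexp(100, 1 / 2000)))
  far <- tibble::tibble(chrom = "chrA",
                        centre = 20000 + round(stats::rexp(100, 1 / 30000)))
  res2 <- distance_to_domains(near, domains, far)
  expect_lt(res2$p, 0.05)
})

test_that("class summaries produce unit-sum fractions", {
  pl <- default_pipeline()
  cs <- pl$class_summary
  sums <- cs |>
    dplyr::group_by(class, kind) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("enrichment summary gives per-class scaled means with CIs", {
  pl <- default_pipeline()
  es <- enrichment_summary(pl$matrix, pl$model$classes)
  expect_true(all(es$ci_lo <= es$mean & es$mean <= es$ci_hi))
  # the PRE-like class has the strongest scaled IP signal
  sim <- default_sim()
  rec <- pl$recovery$matched
  pre_class <- unique(rec$class[which(rec$truth_label == "PRE")])
  cbp <- es[es$dataset == "CBP", ]
  expect_equal(cbp$class[which.max(cbp$mean)], pre_class)
})
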
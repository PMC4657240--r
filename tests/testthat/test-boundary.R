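test_that("histone subclassification separates acetylation states", {
  set.seed(40)
  n <- 30
  hi <- tibble::tibble(H3K27ac = stats::rnorm(n, 3, 0.3),
                       H3K18ac = stats::rnorm(n, 2.5, 0.3),
                       H3K23ac = stats::rnorm(n, 1, 0.3),
                       H3K27me3 = stats::rnorm(n, 0.5, 0.3))
  lo <- tibble::tibble(H3K27ac = stats::rnorm(n, 0.2, 0.3),
                       H3K18ac = stats::rnorm(n, 0.2, 0.3),
                       H3K23ac = stats::rnorm(n, 1.5, 0.3),
                       H3K27me3 = stats::rnorm(n, 0.6, 0.3))
  df <- dplyr::bind_cols(tibble::tibble(peak_id = sprintf("p%02d", 1:(2 * n))),
                         dplyr::bind_rows(hi, lo))
  bm <- make_bm(df, gmean = 0, gmax = 4)
  res <- subclassify_histone(bm, k = 2)
  truth <- rep(c("hi", "lo"), each = n)
  expect_equal(mclust::adjustedRandIndex(res$labels$subclass, truth), 1)
  expect_true(all(res$labels$high_acetyl[truth == "hi"]))
  expect_false(any(res$labels$high_acetyl[truth == "lo"]))
})

test_that("histone subclassification handles degenerate inputs", {
  df <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                       H3K27ac = 1, H3K18ac = 2)
  bm <- make_bm(df, gmean = 0, gmax = 4)
  expect_error(subclassify_histone(make_bm(df[1, ]), k = 2), "exceeds")
  expect_warning(res <- subclassify_histone(bm, k = 2), "degenerate")
  expect_equal(unique(res$labels$subclass), 1L)
})

test_that("oriented profiles force the stronger flank to the right", {
  set.seed(41)
  x <- stats::rnorm(4000, 1, 0.2)
  x[2000:2400] <- x[2000:2400] + 3  # asymmetric block right of one centre
  tr <- vec_track(x, bin = 10, semantics = "scaled")
  regions <- tibble::tibble(chrom = "chrA",
                            centre = c(5000, 15000, 19800, 25000, 35000))
  pr <- oriented_profile(regions, tr, flank = 3000, out_bin = 100)
  rg <- attr(pr, "regions")
  expect_true(all(rg$right_sum >= rg$left_sum))
  expect_equal(attr(pr, "n"), 5)
  expect_equal(nrow(pr), 60)
})

test_that("flipping is a no-op for symmetric signal", {
  gen_vals <- rep(0, 2000)
  gen_vals[96:105] <- 5  # symmetric about position 1000
  tr <- vec_track(gen_vals, bin = 10, semantics = "scaled")
  regions <- tibble::tibble(chrom = "chrA", centre = 1000)
  p_or <- oriented_profile(regions, tr, flank = 500, out_bin = 100)
  p_no <- oriented_profile(regions, tr, flank = 500, out_bin = 100, orient = FALSE)
  expect_equal(p_or$mean_signal, p_no$mean_signal)
  expect_false(attr(p_or, "regions")$flipped[1])
})

test_that("re-orienting an oriented profile changes nothing", {
  set.seed(42)
  tr <- vec_track(stats::rnorm(5000), bin = 10, semantics = "scaled")
  regions <- tibble::tibble(chrom = "chrA", centre = c(12000, 25000, 38000))
  pr <- oriented_profile(regions, tr, flank = 2000, out_bin = 200)
  M <- attr(pr, "region_profiles")
  for (i in seq_len(nrow(M))) {
    half <- ncol(M) / 2
    expect_gte(sum(M[i, (half + 1):ncol(M)]), sum(M[i, 1:half]) - 1e-9)
  }
})

test_that("eligibility filters report what they dropped", {
  tr <- vec_track(rep(1, 3000), bin = 10, semantics = "scaled")
  regions <- tibble::tibble(chrom = "chrA", centre = c(100, 15000))
  domains <- tibble::tibble(chrom = "chrA", start = 29000, end = 30000)
  expect_error(oriented_profile(regions, tr, flank = 2000, domains = domains,
                                max_domain_distance = 1000),
               "far_from_domain")
})

test_that("blocking and non-blocking insulators show the expected asymmetry", {
  sim <- default_sim()
  k27 <- track_scale_genomic(log2_enrichment(sim$tracks$H3K27me3,
                                             sim$tracks$input))
  ratios <- vapply(c("INS_BLOCKING", "INS_NONBLOCKING"), function(lab) {
    tr <- sim$truth[sim$truth$label == lab, ]
    pr <- oriented_profile(tr, k27, domains = sim$domains,
                           intergenic_only = TRUE, genes = sim$genes)
    profile_asymmetry(pr)$ratio
  }, double(1))
  expect_lt(ratios[["INS_BLOCKING"]], 0.25)
  expect_gt(ratios[["INS_NONBLOCKING"]], 0.75)
})

qpcr_flat <- function(cq = 25) {
  tidyr::expand_grid(site = c("s1", "ctrl_1", "ctrl_2"),
                     antibody = c("target", "H3", "input"),
                     condition = c("treated", "control"),
                     replicate = 1:3) |>
    dplyr::mutate(cq = cq)
}

test_that("qPCR arithmetic: parity gives 1, one cycle gives exactly 2", {
  flat <- qpcr_flat()
  res <- qpcr_enrichment(flat, c("ctrl_1", "ctrl_2"))
  expect_true(all(res$per_replicate$final == 1))
  expect_true(all(res$per_site$fold == 1))
  one <- flat
  one$cq[one$site == "s1" & one$antibody == "target"] <- 24
  res1 <- qpcr_enrichment(one, c("ctrl_1", "ctrl_2"))
  expect_true(all(res1$per_replicate$final[res1$per_replicate$site == "s1"] == 2))
})

test_that("qPCR normalization cancels per-replicate machine offsets exactly", {
  tab <- simulate_qpcr(seed = 50)
  shifted <- dplyr::mutate(tab, cq = cq + ifelse(replicate == 2, 3.7, 0))
  a <- qpcr_enrichment(tab, c("ctrl_1", "ctrl_2"))
  b <- qpcr_enrichment(shifted, c("ctrl_1", "ctrl_2"))
  expect_equal(a$per_site$fold, b$per_site$fold, tolerance = 1e-12)
  expect_equal(a$per_replicate$final, b$per_replicate$final, tolerance = 1e-12)
})

test_that("qPCR input validation catches missing rows", {
  flat <- qpcr_flat()
  expect_error(qpcr_enrichment(flat, "ctrl_1"), "two control sites")
  expect_error(qpcr_enrichment(flat, c("ctrl_1", "nope")), "missing")
  no_input <- flat[!(flat$antibody == "input" & flat$site == "s1" &
                       flat$replicate == 1 & flat$condition == "treated"), ]
  expect_error(qpcr_enrichment(no_input, c("ctrl_1", "ctrl_2")), "input")
})

test_that("simulated qPCR recovers the planted fold change", {
  res <- qpcr_enrichment(simulate_qpcr(fold = 2.4, sigma = 0.1,
                                       replicates = 4, seed = 51),
                         c("ctrl_1", "ctrl_2"))
  f <- res$per_site$fold[res$per_site$site == "site_1"]
  expect_gte(f, 2.0); expect_lte(f, 2.9)
  expect_lt(res$per_site$p[res$per_site$site == "site_1"], 0.05)
})
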
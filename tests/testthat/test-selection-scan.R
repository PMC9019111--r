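test_that("core regions use the end-exclusive length convention", {
  cr <- core_region(100, 200)
  expect_equal(cr$length, 100L)
  expect_error(core_region(200, 100), "end must exceed")
})

test_that("core haplotypes are enumerated with a strict frequency threshold", {
  h <- toy_haps(matrix(0L, 3, 10), pos = c(5L, 10L, 15L))
  cs <- define_core_haplotypes(h, core_region(1, 20))
  expect_equal(nrow(cs$cores), 1L)
  expect_equal(cs$cores$frequency, 1)

  # cores at 60/39/1 of 100 with threshold 1%: "above 1%" is strict, so the
  # singleton core at exactly 1% is dropped
  g <- cbind(matrix(0L, 2, 60),
             matrix(c(1L, 0L), 2, 39),
             matrix(c(1L, 1L), 2, 1))
  cs2 <- define_core_haplotypes(toy_haps(g, pos = c(5L, 10L)),
                                core_region(1, 20), min_frequency = 0.01)
  expect_equal(nrow(cs2$cores), 2L)
  expect_equal(cs2$cores$count, c(60L, 39L))
  expect_true(is.na(cs2$assignment[100]))
  expect_error(define_core_haplotypes(toy_haps(g, pos = c(5L, 10L)),
                                      core_region(100, 200)), "empty core")
})

test_that("core labels follow focal-allele content by decreasing frequency", {
  g <- cbind(matrix(c(1L, 0L), 2, 6), matrix(c(1L, 1L), 2, 4),
             matrix(0L, 2, 2))
  focal <- list(F = c(rep(TRUE, 10), rep(FALSE, 2)))
  cs <- define_core_haplotypes(toy_haps(g, pos = 1:2), core_region(1, 5),
                               focal_alleles = focal)
  expect_equal(cs$cores$label, c("F1", "F2", "wt"))
})

test_that("EHH is 1 at the core, non-increasing, and matches the split arithmetic", {
  # 4 carriers splitting 2/2 at the first informative site
  g <- rbind(rep(0L, 4),                  # core site
             c(0L, 0L, 1L, 1L),           # first flank site: 2/2 split
             rep(0L, 4))                  # uninformative
  h <- toy_haps(g, pos = c(10L, 20L, 30L))
  cs <- define_core_haplotypes(h, core_region(5, 15))
  e <- ehh_decay(h, cs, 1L, "downstream")
  expect_equal(e$ehh, c(1 / 3, 1 / 3))

  # all carriers identical over the flank: EHH stays 1
  h2 <- toy_haps(matrix(0L, 5, 4), pos = c(10L, 20L, 30L, 40L, 50L))
  cs2 <- define_core_haplotypes(h2, core_region(5, 15))
  e2 <- ehh_decay(h2, cs2, 1L, "downstream")
  expect_true(all(e2$ehh == 1))
  expect_error(ehh_decay(toy_haps(matrix(0L, 1, 1), pos = 10L),
                         define_core_haplotypes(
                           toy_haps(matrix(0L, 1, 1), pos = 10L),
                           core_region(5, 15)), 1L), "fewer than 2")
})

test_that("singleton and non-synonymous sites are excluded from EHH partitioning", {
  # flank site carried by exactly one haplotype cohort-wide: excluded
  g <- rbind(rep(0L, 4),
             c(1L, 0L, 0L, 0L),           # cohort singleton
             rep(0L, 4))
  h <- toy_haps(g, pos = c(10L, 20L, 30L))
  cs <- define_core_haplotypes(h, core_region(5, 15))
  e <- ehh_decay(h, cs, 1L, "downstream")
  expect_true(all(e$ehh == 1))
  expect_equal(nrow(e), 1L)               # only the non-singleton site

  # missense flank site excluded via the annotation table
  ref <- toy_reference("ATGCTTTAA", offset = 100L)
  m <- gene_model("tx", "chr", "+", data.frame(start = 101, end = 109))
  g2 <- rbind(rep(0L, 4), c(1L, 1L, 0L, 0L))
  h2 <- toy_haps(g2, pos = c(90L, 104L))
  h2$sites$ref <- c("A", "C"); h2$sites$alts <- c("T", "T")
  eff <- annotate_all_sites(h2, m, ref)
  cs2 <- define_core_haplotypes(h2, core_region(85, 95))
  e_with <- ehh_decay(h2, cs2, 1L, "downstream")
  e_without <- ehh_decay(h2, cs2, 1L, "downstream", effects = eff)
  expect_equal(e_with$ehh, 1 / 3)
  expect_equal(nrow(e_without), 0L)       # the only flank site is excluded
})

test_that("EHH matches the brute-force prefix-partition oracle and is monotone", {
  set.seed(19)
  for (rep in 1:8) {
    n <- 8
    g <- rbind(matrix(0L, 1, n), matrix(rbinom(10 * n, 1, 0.4), 10, n))
    # keep only non-singleton flank rows so the oracle sees the same sites
    keep <- c(TRUE, rowSums(g[-1, , drop = FALSE]) != 1L)
    g <- g[keep, , drop = FALSE]
    h <- toy_haps(g, pos = seq(10L, by = 10L, length.out = nrow(g)))
    cs <- define_core_haplotypes(h, core_region(5, 15))
    carriers <- which(cs$assignment == 1L)
    e <- ehh_decay(h, cs, 1L, "downstream")
    oracle <- ehh_oracle(g[-1, , drop = FALSE], carriers)
    expect_equal(e$ehh, oracle)
    expect_true(all(diff(e$ehh) <= 1e-12))
    expect_true(all(e$ehh >= 0 & e$ehh <= 1))
  }
})

test_that("window homozygosity covers the three canonical cases", {
  win <- data.frame(start = 1, end = 100)
  h1 <- toy_haps(matrix(0L, 3, 5), pos = c(10L, 20L, 30L))
  expect_equal(window_homozygosity(h1, win, 1:5)$homozygosity, 1)
  h2 <- toy_haps(diag(4L), pos = c(10L, 20L, 30L, 40L))
  expect_equal(window_homozygosity(h2, win, 1:4)$homozygosity, 0)
  h3 <- toy_haps(matrix(c(0L, 0L, 1L, 1L), 1, 4), pos = 10L)
  expect_equal(window_homozygosity(h3, win, 1:4)$homozygosity, 1 / 3)
})

test_that("divergence scans count only fixed differences and merge tracts", {
  g <- matrix(0L, 10, 6)
  h <- toy_haps(g, pos = seq(100L, 1000L, by = 100L))
  win <- tile_windows(1, 1000, 250)
  scan <- divergence_region_scan(h, 1:3, 4:6, win)
  expect_true(all(scan$windows$fixed_diffs == 0L))
  expect_equal(nrow(scan$tracts), 0L)

  # 6 fixed differences planted in one tract; a within-group polymorphic
  # site in the same windows is not counted
  g2 <- matrix(0L, 10, 6)
  g2[3:8, 4:6] <- 1L                       # fixed different in group b
  g2[9, 4] <- 1L                           # polymorphic within group b
  h2 <- toy_haps(g2, pos = seq(100L, 1000L, by = 100L))
  scan2 <- divergence_region_scan(h2, 1:3, 4:6, win)
  expect_equal(nrow(scan2$tracts), 1L)
  expect_equal(scan2$tracts$fixed_diffs, 6L)
})

test_that("shared haplotype lengths follow the genetic map and censoring rules", {
  # identical pair across the analysed span: censored at the region edges
  h <- toy_haps(matrix(0L, 5, 2), pos = c(1L, 250000L, 500000L, 750000L,
                                          1000000L))
  core <- core_region(499000, 501000)
  r <- shared_haplotype_lengths(h, 1:2, core, genetic_map(1), reps = 10,
                                seed = 1)
  expect_true(all(r$censored))
  # span = core length + distances to both edges
  expected_bp <- core$length + (499000 - 1) + (1000000 - 501000 + 1)
  expect_equal(r$lengths_cM, expected_bp / 1e6)

  # pair mismatching at the first site on both flanks: little more than the
  # core length (mismatch sites shared by two haplotypes so they are not
  # cohort singletons)
  g2 <- rbind(c(0L, 1L, 1L, 0L), c(0L, 0L, 0L, 0L), c(0L, 1L, 1L, 0L))
  h2 <- toy_haps(g2, pos = c(498000L, 500000L, 502000L))
  r2 <- shared_haplotype_lengths(h2, 1:2, core, genetic_map(1), reps = 10,
                                 seed = 1)
  expect_false(any(r2$censored))
  # identity runs to 501999 downstream and from 498001 upstream
  expect_equal(r2$lengths_cM, (core$length + 1000 + 999) / 1e6)

  # one bootstrap replicate: degenerate CI at the median
  r3 <- shared_haplotype_lengths(h2, 1:2, core, reps = 1, seed = 1)
  expect_equal(unname(r3$ci[1]), r3$median_cM)
  expect_equal(unname(r3$ci[2]), r3$median_cM)
  expect_error(shared_haplotype_lengths(h2, 1L, core), ">= 2 carriers")
})

test_that("median shared length decreases with the recombination-time parameter", {
  grs <- c(2e-6, 8e-6, 3e-5, 1e-4)
  med <- vapply(seq_along(grs), function(i) {
    cfg <- small_sim_config(seed = 300L + i, gr = grs[i], n_groups = 1L)
    coh <- generate_cohort(cfg)
    idx <- which(coh$truth$group == "F1")
    shared_haplotype_lengths(coh$haps, idx, core_region(55000, 58000),
                             reps = 50, seed = 1)$median_cM
  }, numeric(1))
  expect_lt(stats::cor(grs, med, method = "spearman"), 0)
})

test_that("detection-year correlation handles collinear and flat inputs", {
  r1 <- detection_year_correlation(c(2000, 2005, 2010), c(1, 2, 3))
  expect_equal(r1$r, 1)
  r2 <- detection_year_correlation(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r2$r, 0)
  r3 <- detection_year_correlation(c(2000, 2005, 2010), c(3, 2, 1))
  expect_equal(r3$r, -1)
  r4 <- detection_year_correlation(c(2000, 2000, 2000), c(1, 2, 3))
  expect_false(r4$defined)
  expect_error(detection_year_correlation(c(1, 2), c(1, 2)), ">= 3")
})
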
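test_that("identical seeds give byte-identical cohort directories", {
  p <- simulation_params(n_samples = 2, n_germline_small = 150, n_somatic_small = 40,
                         n_germline_sv_per_type = 3, n_somatic_sv_per_type = 2,
                         seed = 101)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(p, dir = d1)
  simulate_cohort(p, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("record counts match the requested parameters", {
  co <- tiny_cohort()
  p <- co$params
  for (id in names(co$samples)) {
    tr <- co$truth$small_variants[co$truth$small_variants$sample == id, ]
    expect_equal(nrow(tr), p$n_germline_small + p$n_somatic_small)
    expect_equal(sum(tr$class == "somatic"), p$n_somatic_small)
    expect_equal(nrow(co$samples[[id]]$tumor_only), nrow(tr))
    expect_equal(nrow(co$samples[[id]]$matched_somatic), p$n_somatic_small)
    sv_tr <- co$truth$svs[co$truth$svs$sample == id, ]
    expect_equal(nrow(sv_tr), 4 * (p$n_germline_sv_per_type + p$n_somatic_sv_per_type))
  }
})

test_that("every emitted variant traces to exactly one truth row", {
  co <- tiny_cohort()
  for (id in names(co$samples)) {
    tr <- co$truth$small_variants[co$truth$small_variants$sample == id, ]
    tkey <- paste(tr$chrom, tr$pos, tr$ref, tr$alt)
    ekey <- paste(co$samples[[id]]$tumor_only$chrom, co$samples[[id]]$tumor_only$pos,
                  co$samples[[id]]$tumor_only$ref, co$samples[[id]]$tumor_only$alt)
    expect_equal(sort(ekey), sort(tkey))
    expect_equal(anyDuplicated(tkey), 0)
  }
})

test_that("with no somatic small variants every tumor-only call is germline", {
  p <- simulation_params(n_samples = 1, n_germline_small = 200, n_somatic_small = 0,
                         n_germline_sv_per_type = 2, n_somatic_sv_per_type = 1,
                         seed = 15)
  co <- simulate_cohort(p)
  expect_true(all(co$truth$small_variants$class == "germline"))
  expect_equal(nrow(co$samples$S01$matched_somatic), 0)
  lab <- label_against_ground_truth(co$samples$S01$tumor_only,
                                    co$samples$S01$matched_somatic)
  expect_true(all(lab$labeled$truth_label == "germline"))
})

test_that("somatic allele fractions center on purity/2 for clonal copy-neutral variants", {
  p <- simulation_params(n_samples = 1, purity_range = c(0.6, 0.6),
                         n_germline_small = 100, n_somatic_small = 500,
                         n_germline_sv_per_type = 1, n_somatic_sv_per_type = 1,
                         seed = 33)
  co <- simulate_cohort(p)
  som <- co$samples$S01$tumor_only[co$samples$S01$tumor_only$truth_label == "somatic", ]
  expect_equal(mean(som$allele_fraction), 0.30, tolerance = 0.02 / 0.30)
  germ <- co$samples$S01$tumor_only[co$samples$S01$tumor_only$truth_label == "germline", ]
  expect_gt(mean(germ$allele_fraction), 0.5)
})

test_that("population-database membership hits its configured rate", {
  p <- simulation_params(n_samples = 1, n_germline_small = 5000, n_somatic_small = 100,
                         n_germline_sv_per_type = 1, n_somatic_sv_per_type = 1,
                         seed = 44)
  co <- simulate_cohort(p)
  g <- co$truth$small_variants[co$truth$small_variants$class == "germline", ]
  af <- popdb_lookup(co$resources, g$chrom, g$pos, g$ref, g$alt)
  phat <- mean(af >= 0)
  ci <- 2.58 * sqrt(0.95 * 0.05 / nrow(g))  # binomial 99% CI at p = 0.95
  expect_lt(abs(phat - 0.95), ci + 1e-9)
})

test_that("an empty PON results from zero density and no germline SVs", {
  p <- simulation_params(n_samples = 1, n_germline_small = 50, n_somatic_small = 10,
                         n_germline_sv_per_type = 0, n_somatic_sv_per_type = 2,
                         pon_density_per_mbp = 0, seed = 9)
  co <- simulate_cohort(p)
  expect_equal(nrow(co$resources$pon_sv$table), 0)
  feats <- extract_sv_features(co$samples$S01$sv_calls$callerA, co$resources)
  expect_true(all(feats$pon_count_bp1 == 0))
})

test_that("changing only the seed preserves summary statistics, not identities", {
  p1 <- tiny_params()
  p2 <- tiny_params(seed = 8)
  co1 <- tiny_cohort()
  co2 <- simulate_cohort(p2)
  expect_equal(nrow(co1$truth$small_variants), nrow(co2$truth$small_variants))
  k1 <- paste(co1$truth$small_variants$chrom, co1$truth$small_variants$pos)
  k2 <- paste(co2$truth$small_variants$chrom, co2$truth$small_variants$pos)
  expect_lt(length(intersect(k1, k2)), 10)
  # germline allele fractions are purity-independent: their mean is a stable
  # summary statistic across seeds
  g1 <- co1$samples$S01$tumor_only
  g2 <- co2$samples$S01$tumor_only
  m1 <- mean(g1$allele_fraction[g1$truth_label == "germline"])
  m2 <- mean(g2$allele_fraction[g2$truth_label == "germline"])
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("germline allele fractions are diploid-consistent", {
  co <- tiny_cohort()
  g <- co$samples$S01$tumor_only[co$samples$S01$tumor_only$truth_label == "germline", ]
  # mixture at 0.5 (het) and 1.0 (hom): no mass far below 0.25
  expect_lt(mean(g$allele_fraction < 0.25), 0.05)
  expect_gt(mean(g$allele_fraction > 0.8), 0.15)
})
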
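make_cs <- function(segments, sample = "T1", purity = 0.6, ploidy = 2) {
  cn_callset(sample, purity, ploidy, segments, check = FALSE)
}

seg_df <- function(chrom, start, end, total, major = total / 2, minor = total / 2) {
  data.frame(chrom = chrom, start = start, end = end, total_cn = total,
             major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
}

test_that("negative copy-number rules: slight rounds to 0, large removes", {
  excl <- genomic_intervals("chr2", 0, 1000)  # away from the segments
  cs <- make_cs(seg_df("chr1", c(0, 1000, 2000), c(1000, 2000, 3000),
                       c(-0.3, -0.7, 2.0)))
  res <- postprocess_tumor_only(cs, excl)
  seg <- res$callset$segments
  expect_equal(nrow(seg), 2)
  expect_equal(seg$total_cn, c(0, 2.0))
  expect_equal(res$log$reason, "largely_negative")
  expect_equal(res$log$bp, 1000)
  # untouched diploid segment unchanged
  expect_equal(seg[seg$start == 2000, ]$total_cn, 2.0)
})

test_that("segments overlapping an exclusion interval are removed whole", {
  excl <- genomic_intervals("chr1", 1500, 2500)
  cs <- make_cs(seg_df("chr1", c(0, 1000, 3000), c(1000, 3000, 4000), 2))
  res <- postprocess_tumor_only(cs, excl)
  expect_equal(res$callset$segments$start, c(0, 3000))
  expect_equal(res$log$reason, "artifact_region")
  # conservation: retained + removed bp = input bp
  expect_equal(sum(res$callset$segments$end - res$callset$segments$start) +
                 sum(res$log$bp), 4000)
})

test_that("post-processing leaves no negative values and no exclusion overlap", {
  withr::with_seed(17, {
    n <- 60
    start <- seq(0, by = 1000, length.out = n)
    vals <- rnorm(n, 2, 1.5)
    cs <- make_cs(seg_df("chr1", start, start + 1000, vals))
  })
  excl <- genomic_intervals("chr1", c(5500, 30100), c(7500, 31000))
  res <- postprocess_tumor_only(cs, excl)
  seg <- res$callset$segments
  expect_true(all(seg$total_cn >= 0))
  idx <- build_interval_index(excl)
  expect_false(any(overlaps_any(idx, seg$chrom, seg$start, seg$end)))
  expect_equal(sum(seg$end - seg$start) + sum(res$log$bp), 60000)
})

test_that("removal is monotone in the exclusion list", {
  withr::with_seed(18, {
    start <- seq(0, by = 1000, length.out = 50)
    cs <- make_cs(seg_df("chr1", start, start + 1000, runif(50, 0, 4)))
  })
  small_excl <- genomic_intervals("chr1", 2000, 4000)
  big_excl <- genomic_intervals("chr1", c(2000, 20000), c(4000, 30000))
  r_small <- postprocess_tumor_only(cs, small_excl)
  r_big <- postprocess_tumor_only(cs, big_excl)
  retained <- function(r) sum(r$callset$segments$end - r$callset$segments$start)
  expect_lte(retained(r_big), retained(r_small))
})

test_that("genome state fractions are length-weighted and match a per-bp tally", {
  expect_equal(genome_state_fractions(make_cs(seg_df("chr1", 0, 100, 2.0))),
               c(deleted = 0, diploid = 1, amplified = 0))
  expect_equal(genome_state_fractions(
    make_cs(seg_df("chr1", c(0, 100), c(100, 200), c(1.0, 3.0)))),
    c(deleted = 0.5, diploid = 0, amplified = 0.5))
  expect_error(genome_state_fractions(make_cs(seg_df("chr1", 1, 1, 2)[0, ])))

  withr::with_seed(23, {
    n <- 50
    start <- cumsum(c(0, sample.int(40, n - 1, replace = TRUE)))
    end <- start + sample.int(40, n, replace = TRUE)
    keep <- c(TRUE, end[-n] <= start[-1])  # drop overlaps
    cs <- make_cs(seg_df("chr1", start[keep], end[keep],
                         runif(sum(keep), -0.2, 5)))
  })
  fr <- genome_state_fractions(cs)
  # brute force over individual base pairs
  states <- unlist(lapply(seq_len(nrow(cs$segments)), function(i) {
    rep(round(cs$segments$total_cn[i]),
        cs$segments$end[i] - cs$segments$start[i])
  }))
  expect_equal(fr[["deleted"]], mean(states < 2))
  expect_equal(fr[["diploid"]], mean(states == 2))
  expect_equal(fr[["amplified"]], mean(states > 2))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("gene-level copy number takes the largest-overlap segment", {
  cs <- make_cs(seg_df("chr1", c(0, 7000), c(7000, 20000), c(2, 4),
                       major = c(1, 3), minor = c(1, 1)))
  inside <- genomic_intervals("chr1", 1000, 2000, name = "gA")
  expect_equal(gene_level_cn(cs, inside)$major_cn, 1)
  straddle <- genomic_intervals("chr1", 0, 10000, name = "gB")  # 70% / 30%
  expect_equal(gene_level_cn(cs, straddle)$major_cn, 1)
  outside <- genomic_intervals("chr2", 0, 100, name = "gC")
  expect_true(is.na(gene_level_cn(cs, outside)$major_cn))
})

test_that("gene-level assignment matches a brute-force per-gene scan", {
  withr::with_seed(29, {
    n_seg <- 40
    start <- cumsum(c(0, sample.int(5000, n_seg - 1, replace = TRUE)))
    end <- start + sample.int(5000, n_seg, replace = TRUE)
    keep <- c(TRUE, end[-n_seg] <= start[-1])
    seg <- seg_df("chr1", start[keep], end[keep],
                  total = sample(0:5, sum(keep), replace = TRUE))
    cs <- make_cs(seg)
    gs <- sample.int(max(end), 500)
    genes <- genomic_intervals("chr1", gs, gs + sample.int(3000, 500, replace = TRUE),
                               name = sprintf("g%03d", 1:500))
  })
  got <- gene_level_cn(cs, genes)
  for (g in seq_len(nrow(genes))) {
    ov <- pmin(genes$end[g], cs$segments$end) - pmax(genes$start[g], cs$segments$start)
    ov[cs$segments$chrom != genes$chrom[g]] <- 0
    if (all(ov <= 0)) {
      expect_true(is.na(got$major_cn[g]))
    } else {
      cand <- which(ov == max(ov))
      best <- cand[which.min(cs$segments$total_cn[cand])]
      expect_equal(got$major_cn[g], cs$segments$major_cn[best])
      expect_equal(got$minor_cn[g], cs$segments$minor_cn[best])
    }
  }
})

test_that("benchmark identity limit gives r = 1 everywhere; reversal gives -1", {
  co <- tiny_cohort()
  matched <- lapply(co$samples, `[[`, "cn_matched")
  rep_id <- compare_callsets(unname(matched), unname(matched),
                             genes = co$resources$genes)
  expect_true(all(abs(rep_id$r - 1) < 1e-12))
  for (m in rep_id$metrics) expect_equal(m$tumor_only, m$matched)

  five <- lapply(1:5, function(i) {
    cn_callset(paste0("P", i), purity = i / 10, ploidy = 2,
               seg_df("chr1", 0, 1000, 2), check = FALSE)
  })
  rev5 <- lapply(1:5, function(i) {
    cn_callset(paste0("P", i), purity = (10 - 2 * i + 1) / 10, ploidy = 2,
               seg_df("chr1", 0, 1000, 2), check = FALSE)
  })
  r <- compare_callsets(five, rev5)$r
  expect_equal(unname(r[["purity"]]), -1)
})

test_that("benchmark is symmetric under swapping the two callset lists", {
  co <- tiny_cohort()
  post <- lapply(co$samples, function(s) postprocess_tumor_only(s$cn_tumor_only)$callset)
  matched <- lapply(co$samples, `[[`, "cn_matched")
  r1 <- compare_callsets(unname(post), unname(matched), genes = co$resources$genes)$r
  r2 <- compare_callsets(unname(matched), unname(post), genes = co$resources$genes)$r
  expect_equal(r1, r2)
  bad <- matched
  bad[[1]]$sample <- "nope"
  expect_error(compare_callsets(unname(post), unname(bad)), "unpaired")
})

test_that("injected negatives and artifact peaks behave as designed", {
  co <- tiny_cohort()
  inj <- co$truth$cn_injected
  expect_true(!is.null(inj) && nrow(inj) > 0)
  for (id in unique(inj$sample)) {
    res <- postprocess_tumor_only(co$samples[[id]]$cn_tumor_only)
    seg <- res$callset$segments
    for (k in which(inj$sample == id)) {
      row <- inj[k, ]
      retained <- seg[seg$chrom == row$chrom & seg$start == row$start &
                        seg$end == row$end, ]
      if (row$kind == "slight_negative") {
        expect_equal(nrow(retained), 1)
        expect_equal(retained$total_cn, 0)
      } else {
        expect_equal(nrow(retained), 0)  # largely negative / artifact removed
        expect_true(any(res$log$chrom == row$chrom & res$log$start == row$start))
      }
    }
    tot_in <- sum(co$samples[[id]]$cn_tumor_only$segments$end -
                    co$samples[[id]]$cn_tumor_only$segments$start)
    expect_equal(sum(seg$end - seg$start) + sum(res$log$bp), tot_in)
  }
})

test_that("segment tables round-trip through the on-disk format", {
  co <- tiny_cohort()
  cs <- co$samples$S03$cn_tumor_only
  path <- tempfile(fileext = ".tsv")
  write_cn_callset(cs, path)
  back <- read_cn_callset(path, check = FALSE)
  expect_equal(back$sample, cs$sample)
  expect_equal(back$purity, cs$purity, tolerance = 1e-6)
  expect_equal(nrow(back$segments), nrow(cs$segments))
  expect_equal(back$segments$total_cn, cs$segments$total_cn, tolerance = 2e-6)
})
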
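one_sv <- function(pos1, pos2, caller = "callerA", svtype = "DEL",
                   chrom = "chr1", quality = 50, orient = NULL) {
  o <- if (is.null(orient)) c("+", "-") else orient
  data.frame(chrom1 = chrom, pos1 = as.integer(pos1), orient1 = o[1],
             chrom2 = chrom, pos2 = as.integer(pos2), orient2 = o[2],
             svtype = svtype, length = pos2 - pos1,
             allele_fraction = 0.5, read_depth = 30, split_reads = 10,
             discordant_pairs = 5, caller_quality = quality, imprecise = FALSE,
             caller_id = caller, truth_label = "unknown",
             stringsAsFactors = FALSE)
}

test_that("identical calls from three callers merge into one fully-supported event", {
  calls <- rbind(one_sv(1000, 5000, "callerA", quality = 50),
                 one_sv(1000, 5000, "callerB", quality = 80),
                 one_sv(1000, 5000, "callerC", quality = 20))
  m <- merge_callsets(calls)
  expect_equal(nrow(m$events), 1)
  expect_equal(m$events$support_count, 3)
  expect_equal(m$events$caller_id, "callerB")  # highest quality representative
  expect_equal(nrow(m$members), 3)
})

test_that("calls beyond the breakpoint distance stay separate", {
  calls <- rbind(one_sv(1000, 5000, "callerA"),
                 one_sv(2500, 6500, "callerB"))
  m <- merge_callsets(calls, merge_params(max_breakpoint_distance = 1000))
  expect_equal(nrow(m$events), 2)
  m2 <- merge_callsets(calls, merge_params(max_breakpoint_distance = 1500))
  expect_equal(nrow(m2$events), 1)
})

test_that("type and strand matching gate co-clustering", {
  a <- one_sv(1000, 5000, "callerA", svtype = "DEL", orient = c("+", "-"))
  b <- one_sv(1000, 5000, "callerB", svtype = "DUP", orient = c("-", "+"))
  expect_equal(nrow(merge_callsets(rbind(a, b))$events), 2)
  loose <- merge_params(require_type_match = FALSE, require_strand_match = FALSE)
  expect_equal(nrow(merge_callsets(rbind(a, b), loose)$events), 1)
})

test_that("with distance 0 and all matching, merging is exact pair equality", {
  withr::with_seed(13, {
    calls <- random_svs(100)
  })
  m <- merge_callsets(calls, merge_params(max_breakpoint_distance = 0))
  key <- paste(calls$chrom1, calls$pos1, calls$orient1,
               calls$chrom2, calls$pos2, calls$orient2, calls$svtype)
  expect_equal(nrow(m$events), length(unique(key)))
})

test_that("merging equals the brute-force transitive-closure oracle and is caller-order invariant", {
  skip_if_not_installed("igraph")
  withr::with_seed(77, {
    calls <- random_svs(200)
    calls$pos1 <- sample.int(2e5, 200)  # dense positions to force chains
    calls$pos2 <- calls$pos1 + sample.int(3000, 200)
    calls$length <- calls$pos2 - calls$pos1
  })
  p <- merge_params(max_breakpoint_distance = 1000)
  m <- merge_callsets(calls, p)

  norm <- normalize_breakpoints(calls)
  oracle <- brute_force_clusters(norm, p)
  key <- function(df) paste(df$chrom1, df$pos1, df$chrom2, df$pos2, df$caller_id,
                            df$caller_quality)
  member_cluster <- m$members$event_id[match(key(norm), key(m$members))]
  # identical partitions: same co-membership relation
  expect_equal(outer(member_cluster, member_cluster, "=="),
               outer(oracle, oracle, "=="))

  # permutation of caller blocks leaves events unchanged
  perm <- calls[order(match(calls$caller_id, c("callerC", "callerA", "callerB"))), ]
  m2 <- merge_callsets(perm, p)
  expect_equal(m$events, m2$events)
  expect_equal(nrow(m$members), nrow(calls))
})

test_that("merging is idempotent on representatives", {
  withr::with_seed(31, calls <- random_svs(120))
  m <- merge_callsets(calls)
  reps <- m$events[, setdiff(names(m$events),
                             c("event_id", "support_count", "n_members"))]
  m2 <- merge_callsets(reps)
  expect_equal(nrow(m2$events), nrow(m$events))
  expect_equal(m2$events$pos1, m$events$pos1)
})

test_that("PON breakpoint counts equal the naive scan", {
  expect_equal(
    count_pon_near_breakpoints(one_sv(1000, 2000),
                               build_interval_index(
                                 genomic_intervals(character(0), numeric(0),
                                                   numeric(0)))),
    data.frame(pon_count_bp1 = 0L, pon_count_bp2 = 0L))

  pon_at <- build_interval_index(genomic_intervals("chr1", 1000, 1001))
  expect_gte(count_pon_near_breakpoints(one_sv(1000, 2000), pon_at)$pon_count_bp1, 1)

  withr::with_seed(55, {
    svs <- random_svs(1000)
    pon_pos <- sample.int(6e6, 5000)
    pon_chrom <- sample(c("chr1", "chr2"), 5000, replace = TRUE)
  })
  idx <- build_interval_index(genomic_intervals(pon_chrom, pon_pos, pon_pos + 1))
  got <- count_pon_near_breakpoints(svs, idx, window = 200)
  naive1 <- vapply(seq_len(1000), function(i) {
    sum(pon_chrom == svs$chrom1[i] &
          pon_pos >= svs$pos1[i] - 200 & pon_pos < svs$pos1[i] + 200)
  }, numeric(1))
  naive2 <- vapply(seq_len(1000), function(i) {
    sum(pon_chrom == svs$chrom2[i] &
          pon_pos >= svs$pos2[i] - 200 & pon_pos < svs$pos2[i] + 200)
  }, numeric(1))
  expect_equal(as.numeric(got$pon_count_bp1), naive1)
  expect_equal(as.numeric(got$pon_count_bp2), naive2)
})

test_that("SV features match an independently coded row-by-row extractor", {
  co <- tiny_cohort()
  rs <- co$resources
  svs <- co$samples$S01$sv_calls$callerA[1:25, ]
  got <- extract_sv_features(svs, rs, pon_window = 200, merge_distance = 1000)
  expect_equal(setdiff(names(got), "label"), sv_feature_names())
  expect_equal(length(sv_feature_names()), 19)

  pon <- rs$pon_sv$table
  svdb <- rs$sv_db$table
  genes <- rs$gene_features$table
  cls_rank <- c(CDS = 3, UTR = 2, intron = 1)
  for (i in seq_len(nrow(svs))) {
    near <- function(chrom, pos, d) {
      svdb$chrom == chrom & svdb$start < pos + d & svdb$end > pos - d
    }
    n1 <- near(svs$chrom1[i], svs$pos1[i], 1000)
    n2 <- near(svs$chrom2[i], svs$pos2[i], 1000)
    expect_equal(got$svdb_overlap[i], as.numeric(any(n1) && any(n2)))
    expect_equal(got$svdb_af_max[i],
                 if (any(n1 | n2)) max(svdb$af[n1 | n2]) else 0)
    expect_equal(got$pancancer_overlap[i],
                 if (any(n1 | n2)) max(svdb$pancancer[n1 | n2]) else 0)
    expect_equal(got$pon_count_bp1[i],
                 sum(pon$chrom == svs$chrom1[i] &
                       pon$start >= svs$pos1[i] - 200 &
                       pon$start < svs$pos1[i] + 200))
    gc1 <- genes$chrom == svs$chrom1[i] & genes$start < svs$pos1[i] &
      genes$end >= svs$pos1[i]
    expected_cls <- if (any(gc1)) max(cls_rank[genes$name[gc1]]) else 0
    expect_equal(got$gene_class_bp1[i], as.numeric(expected_cls))
    expect_equal(got$log_length[i],
                 if (svs$length[i] < 0) 0 else log1p(svs$length[i]))
    expect_equal(got$allele_fraction[i], svs$allele_fraction[i])
  }
  expect_true(all(got$log_length[svs$svtype == "TRA"] == 0))
})

test_that("per-caller training is deterministic and integration follows the vote rule", {
  co <- tiny_cohort()
  rs <- co$resources
  calls <- co$samples$S01$sv_calls$callerA
  tab <- extract_sv_features(calls, rs)
  three <- list(a = tab, b = tab, c = tab)
  models <- train_sv_models(three, sv_default_hyperparams(seed = 3), seed = 3)
  accs <- vapply(models, function(m) m$report$accuracy, numeric(1))
  expect_equal(accs[["a"]], accs[["b"]])
  expect_equal(accs[["b"]], accs[["c"]])

  merged <- merge_callsets(co$samples$S01$sv_calls)
  n <- nrow(merged$members)
  withr::with_seed(8, member_somatic <- runif(n) < 0.5)
  ev <- integrate_somatic_svs(merged, member_somatic)
  # independent rule replay
  for (k in seq_len(nrow(ev))) {
    ii <- merged$members$event_id == ev$event_id[k]
    votes <- length(unique(merged$members$caller_id[ii][member_somatic[ii]]))
    expect_equal(ev$somatic_votes[k], votes)
    expected <- if (votes >= 1 && (votes == ev$support_count[k] || votes >= 2)) {
      "somatic"
    } else "germline"
    expect_equal(ev$final_class[k], expected)
  }
  expect_error(integrate_somatic_svs(merged, rep(NA, n)), "unclassified")
})

test_that("vote-rule corner cases: unanimity or two-caller agreement", {
  calls <- rbind(one_sv(1000, 5000, "callerA"),
                 one_sv(1010, 5010, "callerB"),
                 one_sv(1020, 5020, "callerC"),
                 one_sv(40000, 48000, "callerA"),
                 one_sv(40010, 48010, "callerB"))
  m <- merge_callsets(calls)
  expect_equal(sort(m$events$support_count), c(2, 3))
  # support 3, votes 3 -> somatic; support 2, votes 1 -> germline
  somatic_members <- m$members$event_id == m$events$event_id[m$events$support_count == 3] |
    (m$members$caller_id == "callerA" &
       m$members$event_id == m$events$event_id[m$events$support_count == 2])
  ev <- integrate_somatic_svs(m, somatic_members)
  expect_equal(ev$final_class[ev$support_count == 3], "somatic")
  expect_equal(ev$final_class[ev$support_count == 2], "germline")
})

test_that("PON, allele fraction, depth and length carry the SV class signal", {
  co <- default_cohort()
  svp <- run_sv_pipeline(co, seed = 42)
  expected <- c("pon_count_bp1", "pon_count_bp2", "allele_fraction",
                "read_depth", "log_length")
  for (caller in names(svp$models)) {
    expect_gte(svp$models[[caller]]$report$accuracy, 0.85)
    top6 <- names(svp$models[[caller]]$importance)[1:6]
    expect_true(all(expected %in% top6), label = caller)
  }
})

test_that("somatic SV counts show no dependence on purity or provenance", {
  co <- tiny_cohort()
  svp <- run_sv_pipeline(co, seed = 5)
  fit <- stats::lm(n_somatic ~ purity, data = svp$summary)
  ci <- suppressWarnings(stats::confint(fit))["purity", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})
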
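# Shared fixtures: small simulated cohorts, cached per test run.

.fixtures <- new.env(parent = emptyenv())

tiny_params <- function(seed = 7, ...) {
  simulation_params(n_samples = 4, n_germline_small = 400, n_somatic_small = 80,
                    n_germline_sv_per_type = 6, n_somatic_sv_per_type = 4,
                    seed = seed, ...)
}

# in-memory 4-sample cohort shared by module tests
tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- simulate_cohort(tiny_params())
  .fixtures$tiny
}

# same cohort written to disk (for I/O round-trip tests)
tiny_cohort_dir <- function() {
  if (is.null(.fixtures$tiny_dir)) {
    d <- file.path(tempdir(), "tosomatic-tiny-cohort")
    write_cohort(tiny_cohort(), d)
    .fixtures$tiny_dir <- d
  }
  .fixtures$tiny_dir
}

# the reference study conditions: the full default cohort (20 samples,
# seed 42), on disk; built once and shared by the acceptance tests
default_cohort <- function() {
  if (is.null(.fixtures$default)) {
    d <- file.path(tempdir(), "tosomatic-default-cohort")
    .fixtures$default <- simulate_cohort(simulation_params(), dir = d)
  }
  .fixtures$default
}

# synthetic feature frame for classifier harness tests: `separation` shifts
# the somatic allele-fraction distribution away from germline
make_feature_frame <- function(n = 400, separation = 0.3, seed = 1,
                               features = c("allele_fraction", "total_depth",
                                            "caller_confidence")) {
  withr::with_seed(seed, {
    label <- rep(c("somatic", "germline"), length.out = n)
    df <- data.frame(label = label)
    for (f in features) df[[f]] <- rnorm(n)
    df$allele_fraction <- ifelse(label == "somatic",
                                 rnorm(n, 0.5 - separation, 0.05),
                                 rnorm(n, 0.5, 0.05))
    df
  })
}

random_svs <- function(n, seed = 1, callers = c("callerA", "callerB", "callerC")) {
  withr::with_seed(seed, {
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos1 <- sample.int(5e6, n)
    len <- sample.int(5e4, n) + 100
    data.frame(
      chrom1 = chrom, pos1 = pos1, orient1 = "+",
      chrom2 = chrom, pos2 = pos1 + len, orient2 = "-",
      svtype = "DEL", length = len,
      allele_fraction = runif(n), read_depth = rpois(n, 30),
      split_reads = rpois(n, 10), discordant_pairs = rpois(n, 8),
      caller_quality = round(runif(n, 10, 200), 1),
      imprecise = runif(n) < 0.1,
      caller_id = sample(callers, n, replace = TRUE),
      truth_label = "unknown",
      stringsAsFactors = FALSE
    )
  })
}

write_lines_tmp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent transitive-closure oracle: all-pairs relation + graph components
brute_force_clusters <- function(calls, p) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ok <- calls$chrom1[i] == calls$chrom1[j] &&
        calls$chrom2[i] == calls$chrom2[j] &&
        abs(calls$pos1[i] - calls$pos1[j]) <= p$max_breakpoint_distance &&
        abs(calls$pos2[i] - calls$pos2[j]) <= p$max_breakpoint_distance
      if (ok && p$require_type_match) ok <- calls$svtype[i] == calls$svtype[j]
      if (ok && p$require_strand_match) {
        ok <- calls$orient1[i] == calls$orient1[j] &&
          calls$orient2[i] == calls$orient2[j]
      }
      adj[i, j] <- ok
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

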
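# Deterministic synthetic-cohort generator. Emulates the statistical
# structure that the tumor-only classifiers exploit -- germline variants at
# diploid allele fractions with high population-database membership, somatic
# variants at purity-scaled fractions with cancer-catalogue enrichment,
# panel-of-normals support around germline SV breakpoints, caller-specific
# breakpoint jitter/dropout/metric noise, and copy-number profiles with
# slightly negative values and focal artifact peaks near chromosome ends --
# with full truth tables, so every downstream module can be tested against
# known ground truth without access to controlled patient data.

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions: a 20-sample
#' cohort at 0.2-0.9 purity, 5,000 germline and 500 somatic small variants
#' per sample, Poisson depth 60x matched / 30x tumor-only, database
#' membership 0.95/0.01 (population db, germline/somatic) and 0.10/0.001
#' (cancer catalogue, somatic/germline), 15 germline and 8 somatic SVs per
#' type per sample across DEL/DUP/INV/TRA with per-caller dropout and 30 bp
#' breakpoint jitter.
#'
#' @param n_samples number of tumor samples.
#' @param sex_ratio fraction of male patients.
#' @param purity_range tumor purity range (uniform draw).
#' @param n_germline_small,n_somatic_small small-variant counts per sample.
#' @param indel_fraction fraction of small variants that are indels.
#' @param depth_matched,depth_tumor_only Poisson mean depths.
#' @param af_model `"binomial"` draws observed allele fractions through
#'   binomial read sampling at the true fraction; `"exact"` writes the true
#'   fraction directly (used by the separable-limit scenario).
#' @param popdb_prob_germline,popdb_prob_somatic population-database
#'   membership probabilities by class.
#' @param cancerdb_prob_somatic,cancerdb_prob_germline cancer-catalogue
#'   membership probabilities by class.
#' @param multiallelic_prob fraction of germline variants emitted as
#'   multi-allelic sites.
#' @param n_germline_sv_per_type,n_somatic_sv_per_type SV counts per type
#'   per sample (types DEL, DUP, INV, TRA).
#' @param pon_density_per_mbp background PON breakpoints per Mbp.
#' @param pon_germline_rate probability a germline SV breakpoint gains a
#'   cluster of PON entries.
#' @param pon_mean_support mean size of such a PON cluster.
#' @param svdb_prob_germline,svdb_prob_somatic known-SV-database membership
#'   by class; `pancancer_prob_somatic`/`pancancer_prob_germline` likewise
#'   for the pan-cancer set.
#' @param caller_dropout named per-caller probabilities of missing a true SV.
#' @param breakpoint_jitter_sd per-caller breakpoint jitter (bp, sd).
#' @param cn_segments_per_chrom copy-number segments per chromosome.
#' @param cn_value_noise_sd sd of the Gaussian noise separating tumor-only
#'   from matched copy-number values.
#' @param cn_negative_prob per-sample probability of injecting one slightly
#'   negative (in (-0.5, 0)) and one largely negative (< -0.5) focal segment
#'   into the tumor-only profile.
#' @param cn_artifact_prob per-sample probability of injecting a focal
#'   artifact peak inside a chromosome-end exclusion zone.
#' @param inject_y_loss inject a somatic Y-chromosome loss into the first
#'   male tumor (intermediate Y coverage, the cohort's only expected
#'   Y-loss-suspected case).
#' @param seed master seed; every sub-generator derives its own stream.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(
    n_samples = 20,
    sex_ratio = 0.75,
    purity_range = c(0.2, 0.9),
    n_germline_small = 5000,
    n_somatic_small = 500,
    indel_fraction = 0.1,
    depth_matched = 60,
    depth_tumor_only = 30,
    af_model = c("binomial", "exact"),
    popdb_prob_germline = 0.95,
    popdb_prob_somatic = 0.01,
    cancerdb_prob_somatic = 0.10,
    cancerdb_prob_germline = 0.001,
    multiallelic_prob = 0.01,
    n_germline_sv_per_type = 15,
    n_somatic_sv_per_type = 8,
    pon_density_per_mbp = 2,
    pon_germline_rate = 0.9,
    pon_mean_support = 4,
    svdb_prob_germline = 0.5,
    svdb_prob_somatic = 0.02,
    pancancer_prob_somatic = 0.3,
    pancancer_prob_germline = 0.05,
    caller_dropout = c(callerA = 0.10, callerB = 0.15, callerC = 0.20),
    breakpoint_jitter_sd = 30,
    cn_segments_per_chrom = 8,
    cn_value_noise_sd = 0.05,
    cn_negative_prob = 0.6,
    cn_artifact_prob = 0.7,
    inject_y_loss = TRUE,
    seed = 42) {
  af_model <- match.arg(af_model)
  p <- as.list(environment())
  probs <- c(p$popdb_prob_germline, p$popdb_prob_somatic, p$cancerdb_prob_somatic,
             p$cancerdb_prob_germline, p$multiallelic_prob, p$caller_dropout,
             p$svdb_prob_germline, p$svdb_prob_somatic, p$pancancer_prob_somatic,
             p$pancancer_prob_germline, p$cn_negative_prob, p$cn_artifact_prob,
             p$sex_ratio, p$pon_germline_rate)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p$n_samples >= 1, p$n_germline_small >= 0, p$n_somatic_small >= 0,
            p$n_germline_sv_per_type >= 0, p$n_somatic_sv_per_type >= 0,
            p$purity_range[1] > 0, p$purity_range[2] <= 1)
  structure(p, class = "simulation_params")
}

#' Parameters for the separable-limit scenario
#'
#' Disjoint allele-fraction supports between classes (exact fractions:
#' germline at 0.5/1.0, somatic at purity/2 <= 0.45) and perfectly
#' separating databases (membership probabilities 1/0), under which the
#' classifiers must reach held-out accuracy 1.0 exactly.
#'
#' @param ... overrides passed to [simulation_params()].
#' @return `simulation_params`.
#' @export
separable_params <- function(...) {
  defaults <- list(
    af_model = "exact",
    popdb_prob_germline = 1, popdb_prob_somatic = 0,
    cancerdb_prob_somatic = 1, cancerdb_prob_germline = 0,
    svdb_prob_germline = 1, svdb_prob_somatic = 0,
    pancancer_prob_somatic = 1, pancancer_prob_germline = 0,
    n_samples = 6, n_germline_small = 800, n_somatic_small = 200)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

# derive an independent RNG stream seed per generator block: adjacent master
# seeds must not produce overlapping sub-streams, so the master seed is
# scrambled with large primes (kept below 2^31 - 1)
sub_seed <- function(seed, block, i = 0) {
  as.integer((as.double(seed) * 7919 + block * 104729 + i * 7907) %% 2147483647)
}

# linear genome coordinate -> (chrom, pos); chroms restricted by `chroms`
linear_to_position <- function(lin, genome, chroms = genome$chrom) {
  g <- genome[genome$chrom %in% chroms, , drop = FALSE]
  cum <- cumsum(g$length)
  idx <- findInterval(lin - 1, c(0, cum[-length(cum)]) + 0)
  idx <- pmin(pmax(idx, 1), nrow(g))
  offset <- c(0, cum[-length(cum)])[idx]
  data.frame(chrom = g$chrom[idx], pos = as.integer(lin - offset),
             stringsAsFactors = FALSE)
}

random_positions <- function(n, genome, chroms = c("chr1", "chr2", "chr3")) {
  total <- sum(genome$length[genome$chrom %in% chroms])
  lin <- sample.int(total, n, replace = FALSE)
  linear_to_position(lin, genome, chroms)
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

rand_alt <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
         USE.NAMES = FALSE)
}

sample_ids <- function(n) sprintf("S%02d", seq_len(n))

# --- per-sample small variants ---------------------------------------------

sim_small_variants_one <- function(p, sample_id, purity, genome) {
  n_g <- p$n_germline_small
  n_s <- p$n_somatic_small
  n <- n_g + n_s
  if (n == 0) {
    tv <- empty_small_variants()
    return(list(truth = tv, tumor_only = tv, matched_somatic = tv))
  }
  posn <- random_positions(n, genome)
  cls <- c(rep("germline", n_g), rep("somatic", n_s))
  is_indel <- runif(n) < p$indel_fraction
  ref <- rand_bases(n)
  alt <- rand_alt(ref)
  ins <- is_indel & runif(n) < 0.5
  del <- is_indel & !ins
  alt[ins] <- paste0(ref[ins], rand_bases(sum(ins)))
  ref[del] <- paste0(ref[del], rand_bases(sum(del)))
  alt[del] <- substr(ref[del], 1, 1)

  af_true <- numeric(n)
  hom <- runif(n_g) < 1 / 3
  af_true[seq_len(n_g)] <- ifelse(hom, 1.0, 0.5)
  af_true[n_g + seq_len(n_s)] <- purity / 2

  context <- paste0(rand_bases(n), substr(ref, 1, 1), rand_bases(n))
  hrun <- 1 + stats::rgeom(n, 0.5) + ifelse(is_indel, stats::rgeom(n, 0.4), 0)

  truth <- data.frame(
    sample = sample_id, chrom = posn$chrom, pos = posn$pos, ref = ref, alt = alt,
    vclass = variant_class(ref, alt), class = cls, af_true = af_true,
    multiallelic = FALSE, context = context, homopolymer_run = hrun,
    stringsAsFactors = FALSE
  )

  # multi-allelic sites: pair up a few germline rows at a shared position
  n_multi <- min(rbinom(1, n_g, p$multiallelic_prob), n_g %/% 2)
  if (n_multi > 0) {
    snv_g <- which(truth$class == "germline" & truth$vclass == "SNV")
    if (length(snv_g) >= 2 * n_multi) {
      pick <- sample(snv_g, 2 * n_multi)
      a <- pick[seq_len(n_multi)]
      b <- pick[n_multi + seq_len(n_multi)]
      truth$chrom[b] <- truth$chrom[a]
      truth$pos[b] <- truth$pos[a]
      truth$ref[b] <- truth$ref[a]
      truth$context[b] <- truth$context[a]
      alt_b <- mapply(function(r, a1) sample(setdiff(c("A", "C", "G", "T"), c(r, a1)), 1),
                      truth$ref[a], truth$alt[a])
      truth$alt[b] <- as.character(alt_b)
      truth$multiallelic[a] <- TRUE
      truth$multiallelic[b] <- TRUE
      truth$af_true[a] <- 0.45
      truth$af_true[b] <- 0.45
    }
  }

  emit <- function(rows, mean_depth) {
    m <- nrow(rows)
    depth <- pmax(rpois(m, mean_depth), 4)
    if (p$af_model == "binomial") {
      altc <- pmax(rbinom(m, depth, rows$af_true), 1)
      af <- altc / depth
    } else {
      af <- rows$af_true
      altc <- pmax(round(af * depth), 1)
    }
    data.frame(
      chrom = rows$chrom, pos = rows$pos, ref = rows$ref, alt = rows$alt,
      vclass = rows$vclass,
      allele_fraction = af, total_depth = depth, alt_count = altc,
      median_base_quality = round(pmin(pmax(rnorm(m, 30, 3), 10), 40), 2),
      median_mapping_quality = round(pmin(pmax(rnorm(m, 55, 5), 20), 60), 2),
      strand_balance = round(rbeta(m, 20, 20), 4),
      caller_confidence = round(pmax(rnorm(m, 6 + 0.9 * af * depth, 5), 3), 3),
      filter_pass = runif(m) < 0.97,
      multiallelic = rows$multiallelic,
      context = rows$context,
      homopolymer_run = rows$homopolymer_run,
      truth_label = rows$class,
      stringsAsFactors = FALSE
    )
  }

  tumor_only <- emit(truth, p$depth_tumor_only)
  matched_somatic <- emit(truth[truth$class == "somatic", , drop = FALSE],
                          p$depth_matched)
  o <- order(chrom_rank(truth$chrom), truth$pos)
  list(truth = truth[o, , drop = FALSE],
       tumor_only = tumor_only[o, , drop = FALSE],
       matched_somatic = matched_somatic[
         order(chrom_rank(matched_somatic$chrom), matched_somatic$pos), , drop = FALSE])
}

# --- per-sample SVs ---------------------------------------------------------

sim_svs_one <- function(p, sample_id, purity, genome) {
  types <- c("DEL", "DUP", "INV", "TRA")
  counts <- c(germline = p$n_germline_sv_per_type, somatic = p$n_somatic_sv_per_type)
  rows <- list()
  tid <- 0
  for (cls in names(counts)) {
    for (ty in types) {
      k <- counts[[cls]]
      if (k == 0) next
      if (ty == "TRA") {
        c1 <- sample(c("chr1", "chr2", "chr3"), k, replace = TRUE)
        c2 <- vapply(c1, function(x) sample(setdiff(c("chr1", "chr2", "chr3"), x), 1),
                     character(1), USE.NAMES = FALSE)
        p1 <- sample.int(45e6, k) + 1e6
        p2 <- sample.int(45e6, k) + 1e6
        o1 <- sample(c("+", "-"), k, replace = TRUE)
        o2 <- sample(c("+", "-"), k, replace = TRUE)
        len <- rep(-1, k)
      } else {
        c1 <- sample(c("chr1", "chr2", "chr3"), k, replace = TRUE)
        # germline SVs are short common polymorphisms (~2 kb), somatic
        # rearrangements are an order of magnitude larger (~50 kb): length is
        # a designed class signal
        len <- round(stats::rlnorm(k,
                                   meanlog = if (cls == "germline") log(2000) else log(50000),
                                   sdlog = if (cls == "germline") 0.6 else 0.8))
        len <- pmin(pmax(len, 100), 5e6)
        p1 <- sample.int(40e6, k) + 2e6
        p2 <- p1 + len
        c2 <- c1
        o <- type_to_orients(rep(ty, k))
        o1 <- o[, 1]; o2 <- o[, 2]
      }
      af <- if (cls == "germline") {
        ifelse(runif(k) < 1 / 3, 1.0, 0.5)
      } else rep(purity / 2, k)
      rows[[paste(cls, ty)]] <- data.frame(
        sample = sample_id, truth_id = sprintf("%s_sv%03d", sample_id, tid + seq_len(k)),
        chrom1 = c1, pos1 = as.integer(p1), orient1 = o1,
        chrom2 = c2, pos2 = as.integer(p2), orient2 = o2,
        svtype = ty, length = len, class = cls, af_true = af,
        stringsAsFactors = FALSE
      )
      tid <- tid + k
    }
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    return(list(truth = NULL, calls = stats::setNames(
      rep(list(empty_sv_calls()), length(names(p$caller_dropout))),
      names(p$caller_dropout))))
  }
  truth <- normalize_breakpoints2(truth)
  rownames(truth) <- NULL

  m <- nrow(truth)
  depth <- pmax(rpois(m, p$depth_matched), 6)
  support <- pmax(rbinom(m, depth, pmin(truth$af_true, 1)), 2)

  calls <- list()
  for (caller in names(p$caller_dropout)) {
    keep <- runif(m) >= p$caller_dropout[[caller]]
    t2 <- truth[keep, , drop = FALSE]
    k <- nrow(t2)
    sup <- support[keep]
    jit1 <- round(rnorm(k, 0, p$breakpoint_jitter_sd))
    jit2 <- round(rnorm(k, 0, p$breakpoint_jitter_sd))
    read_depth <- pmax(sup + round(rnorm(k, 0, 2)), 1)
    split_reads <- rbinom(k, read_depth, 0.6)
    cs <- data.frame(
      chrom1 = t2$chrom1, pos1 = pmax(t2$pos1 + jit1, 2L), orient1 = t2$orient1,
      chrom2 = t2$chrom2, pos2 = pmax(t2$pos2 + jit2, 2L), orient2 = t2$orient2,
      svtype = t2$svtype, length = t2$length,
      allele_fraction = if (p$af_model == "exact") t2$af_true else
        pmin(pmax(t2$af_true + rnorm(k, 0, 0.03), 0.01), 1),
      read_depth = read_depth,
      split_reads = split_reads,
      discordant_pairs = read_depth - split_reads + rpois(k, 1),
      caller_quality = round(pmax(3 * sup + rnorm(k, 0, 15), 1), 1),
      imprecise = runif(k) < 0.1,
      caller_id = caller,
      truth_label = t2$class,
      truth_id = t2$truth_id,
      stringsAsFactors = FALSE
    )
    calls[[caller]] <- normalize_breakpoints(cs)
  }
  list(truth = truth, calls = calls)
}

# normalize a truth table that uses class/af columns (same geometry rules)
normalize_breakpoints2 <- function(tr) {
  swap <- !position_leq(tr$chrom1, tr$pos1, tr$chrom2, tr$pos2)
  if (any(swap)) {
    tmp <- tr[swap, c("chrom1", "pos1", "orient1")]
    tr[swap, c("chrom1", "pos1", "orient1")] <- tr[swap, c("chrom2", "pos2", "orient2")]
    tr[swap, c("chrom2", "pos2", "orient2")] <- tmp
  }
  intra <- tr$chrom1 == tr$chrom2
  tr$length[intra] <- tr$pos2[intra] - tr$pos1[intra]
  tr$length[!intra] <- -1
  tr
}

# --- copy-number profiles ---------------------------------------------------

carve_segment <- function(seg, chrom, fs, fe, total, major, minor) {
  host <- which(seg$chrom == chrom & seg$start <= fs & seg$end >= fe)
  if (length(host) == 0) return(NULL)
  host <- host[1]
  h <- seg[host, ]
  pieces <- list()
  if (h$start < fs) {
    left <- h; left$end <- fs; pieces <- c(pieces, list(left))
  }
  focal <- h; focal$start <- fs; focal$end <- fe
  focal$total_cn <- total; focal$major_cn <- major; focal$minor_cn <- minor
  pieces <- c(pieces, list(focal))
  if (h$end > fe) {
    right <- h; right$start <- fe; pieces <- c(pieces, list(right))
  }
  out <- rbind(seg[seq_len(host - 1), , drop = FALSE],
               do.call(rbind, pieces),
               seg[setdiff(seq_len(nrow(seg)), seq_len(host)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

sim_cn_one <- function(p, sample_id, sex, purity, y_loss, genome, excl) {
  segs <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]
    L <- genome$length[ci]
    if (chrom == "chrY" && sex == "F") next
    # segment count varies per sample/chromosome; callers break segments at
    # assembly gaps, so exclusion-zone edges are forced breakpoints
    k <- max(3, rpois(1, p$cn_segments_per_chrom))
    zone_edges <- excl[excl$chrom == chrom, ]
    forced <- setdiff(sort(unique(c(zone_edges$start, zone_edges$end))), c(0, L))
    bp <- sort(unique(c(sample.int(L - 2, k - 1) + 1, forced)))
    start <- c(0, bp)
    end <- c(bp, L)
    k <- length(start)
    state <- sample(c(1, 2, 3, 4), k, replace = TRUE, prob = c(0.15, 0.6, 0.18, 0.07))
    if (chrom == "chrX" && sex == "M") state <- rep(1, k)
    if (chrom == "chrY") state <- rep(1, k)
    if (chrom == "chrY" && y_loss) state <- rep(0, k)
    minor_i <- floor(state / 2)
    major_i <- state - minor_i
    eps <- rnorm(k, 0, 0.02)
    segs[[chrom]] <- data.frame(
      chrom = chrom, start = start, end = end,
      total_cn = state + eps, major_cn = major_i + eps / 2,
      minor_cn = minor_i + eps / 2, stringsAsFactors = FALSE
    )
  }
  seg <- do.call(rbind, segs)
  rownames(seg) <- NULL
  w <- seg$end - seg$start
  matched <- cn_callset(sample_id, purity, sum(seg$total_cn * w) / sum(w), seg,
                        check = FALSE)

  # tumor-only: same profile plus value noise, negative injections and
  # artifact peaks in exclusion zones
  seg2 <- seg
  eps2 <- rnorm(nrow(seg2), 0, p$cn_value_noise_sd)
  seg2$total_cn <- seg2$total_cn + eps2
  seg2$major_cn <- seg2$major_cn + eps2 / 2
  seg2$minor_cn <- seg2$minor_cn + eps2 / 2

  injected <- list()
  excl_idx <- build_interval_index(excl)
  inject_neg <- function(seg2, value, kind) {
    for (attempt in 1:20) {
      w <- round(runif(1, 1e5, 5e5))
      chrom <- sample(c("chr1", "chr2", "chr3"), 1)
      fs <- sample.int(genome$length[genome$chrom == chrom] - w - 2, 1)
      fe <- fs + w
      if (overlaps_any(excl_idx, chrom, fs, fe)) next
      res <- carve_segment(seg2, chrom, fs, fe, value, value / 2, value / 2)
      if (is.null(res)) next
      injected[[length(injected) + 1]] <<- data.frame(
        sample = sample_id, chrom = chrom, start = fs, end = fe,
        value = value, kind = kind, stringsAsFactors = FALSE)
      return(res)
    }
    seg2
  }
  if (runif(1) < p$cn_negative_prob) {
    seg2 <- inject_neg(seg2, runif(1, -0.45, -0.05), "slight_negative")
    seg2 <- inject_neg(seg2, runif(1, -1.5, -0.6), "large_negative")
  }
  if (runif(1) < p$cn_artifact_prob) {
    zones <- excl[excl$chrom %in% c("chr1", "chr2", "chr3"), , drop = FALSE]
    z <- zones[sample.int(nrow(zones), 1), ]
    w <- round(runif(1, 2e4, 6e4))
    fs <- z$start + round(runif(1, 5e3, z$end - z$start - w - 5e3))
    fe <- fs + w
    val <- runif(1, 4, 8)
    res <- carve_segment(seg2, z$chrom, fs, fe, val, val * 0.7, val * 0.3)
    if (!is.null(res)) {
      seg2 <- res
      injected[[length(injected) + 1]] <- data.frame(
        sample = sample_id, chrom = z$chrom, start = fs, end = fe,
        value = val, kind = "artifact_peak", stringsAsFactors = FALSE)
    }
  }
  w2 <- seg2$end - seg2$start
  tumor_only <- cn_callset(
    sample_id, min(max(purity + rnorm(1, 0, 0.02), 0.05), 1),
    sum(seg2$total_cn * w2) / sum(w2), seg2, check = FALSE)
  list(matched = matched, tumor_only = tumor_only,
       injected = if (length(injected) > 0) do.call(rbind, injected) else NULL)
}

#' Simulate matched and tumor-only copy-number profiles
#'
#' The tumor-only table is the matched table plus Gaussian value noise,
#' optional slightly/largely negative focal segments (outside exclusion
#' zones) and optional focal artifact peaks placed inside chromosome-end
#' exclusion zones; every injection is recorded in the returned truth table.
#'
#' @param p `simulation_params`.
#' @param meta data.frame with columns `sample`, `sex`, `purity`, `y_loss`
#'   (as produced inside [simulate_cohort()]).
#' @return list with `profiles` (per-sample list of `matched`/`tumor_only`
#'   `cn_callset`s) and `injected` (truth table of injected segments).
#' @export
simulate_cn_profiles <- function(p, meta) {
  genome <- synthetic_genome()
  excl <- cn_exclusion_regions()
  withr::with_seed(sub_seed(p$seed, 3), {
    profiles <- lapply(seq_len(nrow(meta)), function(i) {
      sim_cn_one(p, meta$sample[i], meta$sex[i], meta$purity[i],
                 meta$y_loss[i], genome, excl)
    })
  })
  names(profiles) <- meta$sample
  injected <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(profiles, `[[`, "injected")))
  list(profiles = lapply(profiles, function(x) x[c("matched", "tumor_only")]),
       injected = injected)
}

# --- resources --------------------------------------------------------------

#' Simulate annotation resources consistent with a cohort's truth
#'
#' Population-database membership is drawn per germline variant at the
#' configured rate (0.95 by default) and per somatic variant at 0.01;
#' the cancer catalogue conversely. PON breakpoints cluster around germline
#' SV breakpoints on top of a uniform background; the known-SV database
#' holds germline (population) and somatic (pan-cancer) breakpoints at
#' their own rates. Gene features (CDS/UTR/intron on a deterministic gene
#' grid), conserved elements, repeats and cancer genes complete the set.
#'
#' @param cohort a `synthetic_cohort` (or a list with `params` and `truth`).
#' @return a `resource_set`.
#' @export
simulate_resources <- function(cohort) {
  p <- cohort$params
  genome <- synthetic_genome()
  small <- cohort$truth$small_variants
  svs <- cohort$truth$svs
  withr::with_seed(sub_seed(p$seed, 4), {
    g <- small[small$class == "germline", , drop = FALSE]
    s <- small[small$class == "somatic", , drop = FALSE]
    g_in <- runif(nrow(g)) < p$popdb_prob_germline
    s_in <- runif(nrow(s)) < p$popdb_prob_somatic
    popdb <- rbind(
      data.frame(chrom = g$chrom[g_in], pos = g$pos[g_in], ref = g$ref[g_in],
                 alt = g$alt[g_in], af = round(rbeta(sum(g_in), 0.8, 4), 4)),
      data.frame(chrom = s$chrom[s_in], pos = s$pos[s_in], ref = s$ref[s_in],
                 alt = s$alt[s_in], af = round(rbeta(sum(s_in), 1, 50), 4))
    )
    s_c <- runif(nrow(s)) < p$cancerdb_prob_somatic
    g_c <- runif(nrow(g)) < p$cancerdb_prob_germline
    cancerdb <- rbind(
      data.frame(chrom = s$chrom[s_c], pos = s$pos[s_c], ref = s$ref[s_c],
                 alt = s$alt[s_c], count = 1 + rpois(sum(s_c), 3)),
      data.frame(chrom = g$chrom[g_c], pos = g$pos[g_c], ref = g$ref[g_c],
                 alt = g$alt[g_c], count = 1 + rpois(sum(g_c), 0.5))
    )

    pon_rows <- list()
    if (!is.null(svs) && nrow(svs) > 0) {
      gsv <- svs[svs$class == "germline", , drop = FALSE]
      bps <- rbind(data.frame(chrom = gsv$chrom1, pos = gsv$pos1),
                   data.frame(chrom = gsv$chrom2, pos = gsv$pos2))
      has <- runif(nrow(bps)) < p$pon_germline_rate
      bps <- bps[has, , drop = FALSE]
      if (nrow(bps) > 0) {
        m <- 1 + rpois(nrow(bps), p$pon_mean_support - 1)
        idx <- rep(seq_len(nrow(bps)), m)
        pp <- pmax(bps$pos[idx] + round(rnorm(length(idx), 0, 50)), 1)
        pon_rows$cluster <- data.frame(chrom = bps$chrom[idx], pos = pp)
      }
    }
    n_bg <- round(p$pon_density_per_mbp * sum(genome$length) / 1e6)
    if (n_bg > 0) {
      bg <- random_positions(n_bg, genome, genome$chrom)
      pon_rows$background <- data.frame(chrom = bg$chrom, pos = bg$pos)
    }
    pon <- do.call(rbind, pon_rows)
    pon_iv <- if (is.null(pon) || nrow(pon) == 0) {
      genomic_intervals(character(0), numeric(0), numeric(0))
    } else {
      genomic_intervals(pon$chrom, pon$pos, pon$pos + 1)
    }

    svdb_rows <- list()
    if (!is.null(svs) && nrow(svs) > 0) {
      add_entries <- function(sub, prob, af_fun, pancancer) {
        inn <- runif(nrow(sub)) < prob
        sub <- sub[inn, , drop = FALSE]
        if (nrow(sub) == 0) return(NULL)
        af <- af_fun(nrow(sub))
        rbind(
          data.frame(chrom = sub$chrom1, start = pmax(sub$pos1 - 100, 0),
                     end = sub$pos1 + 100, af = af, pancancer = pancancer),
          data.frame(chrom = sub$chrom2, start = pmax(sub$pos2 - 100, 0),
                     end = sub$pos2 + 100, af = af, pancancer = pancancer)
        )
      }
      gsv <- svs[svs$class == "germline", , drop = FALSE]
      ssv <- svs[svs$class == "somatic", , drop = FALSE]
      svdb_rows$pop_g <- add_entries(gsv, p$svdb_prob_germline,
                                     function(k) round(rbeta(k, 2, 5), 4), 0)
      svdb_rows$pop_s <- add_entries(ssv, p$svdb_prob_somatic,
                                     function(k) round(rbeta(k, 1, 50), 4), 0)
      svdb_rows$pan_s <- add_entries(ssv, p$pancancer_prob_somatic,
                                     function(k) rep(0, k), 1)
      svdb_rows$pan_g <- add_entries(gsv, p$pancancer_prob_germline,
                                     function(k) rep(0, k), 1)
    }
    svdb <- do.call(rbind, Filter(Negate(is.null), svdb_rows))
    svdb_iv <- if (is.null(svdb) || nrow(svdb) == 0) {
      genomic_intervals(character(0), numeric(0), numeric(0),
                        af = numeric(0), pancancer = numeric(0))
    } else {
      genomic_intervals(svdb$chrom, svdb$start, svdb$end,
                        af = svdb$af, pancancer = svdb$pancancer)
    }

    # deterministic gene grid: one 24 kb gene per Mbp with UTR/CDS/intron
    gene_rows <- list(); feat_rows <- list()
    for (ci in which(genome$chrom != "chrY")) {
      chrom <- genome$chrom[ci]
      n_genes <- floor(genome$length[ci] / 1e6)
      gs <- (seq_len(n_genes) - 1) * 1e6 + 1e5
      gene_rows[[chrom]] <- data.frame(
        chrom = chrom, start = gs, end = gs + 24000,
        name = sprintf("%s_g%04d", chrom, seq_len(n_genes)))
      offs <- c(0, 1000, 3000, 11000, 13000, 21000, 23000)
      ends <- c(1000, 3000, 11000, 13000, 21000, 23000, 24000)
      cls <- c("UTR", "CDS", "intron", "CDS", "intron", "CDS", "UTR")
      feat_rows[[chrom]] <- data.frame(
        chrom = chrom,
        start = rep(gs, each = 7) + rep(offs, n_genes),
        end = rep(gs, each = 7) + rep(ends, n_genes),
        name = rep(cls, n_genes))
    }
    genes <- do.call(rbind, gene_rows)
    feats <- do.call(rbind, feat_rows)
    cancer_genes <- genes[seq(1, nrow(genes), by = 10), , drop = FALSE]

    rep_pos <- random_positions(2000, genome, genome$chrom)
    repeats <- genomic_intervals(rep_pos$chrom, rep_pos$pos,
                                 rep_pos$pos + round(runif(2000, 100, 800)))
    cons_pos <- random_positions(3000, genome, genome$chrom)
    conserved <- genomic_intervals(cons_pos$chrom, cons_pos$pos,
                                   cons_pos$pos + round(runif(3000, 50, 300)))

    resource_set(
      popdb = popdb, cancerdb = cancerdb, pon_sv = pon_iv, sv_db = svdb_iv,
      gene_features = genomic_intervals(feats$chrom, feats$start, feats$end,
                                        name = feats$name),
      conserved = conserved,
      cancer_genes = genomic_intervals(cancer_genes$chrom, cancer_genes$start,
                                       cancer_genes$end, name = cancer_genes$name),
      repeats = repeats,
      genes = genomic_intervals(genes$chrom, genes$start, genes$end,
                                name = genes$name)
    )
  })
}

# --- sex / purity evidence --------------------------------------------------

sim_evidence <- function(p, meta) {
  withr::with_seed(sub_seed(p$seed, 5), {
    n <- nrow(meta)
    male <- meta$sex == "M"
    x_cov <- ifelse(male, rnorm(n, 0.5, 0.02), rnorm(n, 1.0, 0.03))
    y_cov <- ifelse(male, rnorm(n, 0.5, 0.03), pmax(rnorm(n, 0.01, 0.005), 0))
    y_cov[meta$y_loss] <- runif(sum(meta$y_loss), 0.12, 0.20)
    x_expr <- ifelse(male, rnorm(n, 20, 1.5), rnorm(n, 28, 1.5))
    y_expr <- ifelse(male, rnorm(n, 25, 2), pmax(rnorm(n, 5, 1), 0))
    y_expr[meta$y_loss] <- rnorm(sum(meta$y_loss), 22, 1.5)
    meth_x <- rnorm(n, 12, 0.3)
    meth_y <- meth_x + ifelse(male, rnorm(n, -0.5, 0.3), rnorm(n, -3.5, 0.4))
    sex_evidence <- data.frame(
      sample = meta$sample, clinical_sex = meta$sex,
      x_coverage = round(x_cov, 4), y_coverage = round(y_cov, 4),
      x_expression = round(x_expr, 3), y_expression = round(y_expr, 3),
      meth_x_median = round(meth_x, 3), meth_y_median = round(meth_y, 3),
      stringsAsFactors = FALSE
    )
    clip01 <- function(x) pmin(pmax(x, 0.05), 1)
    purity_estimates <- data.frame(
      sample = meta$sample,
      pathologic = round(clip01(meta$purity + rnorm(n, 0, 0.08)), 3),
      genomic = round(clip01(meta$purity + rnorm(n, 0, 0.03)), 3),
      transcriptomic = round(clip01(meta$purity + rnorm(n, 0, 0.06)), 3),
      stringsAsFactors = FALSE
    )
    list(sex = sex_evidence, purity = purity_estimates)
  })
}

# --- master op --------------------------------------------------------------

#' Simulate a full synthetic cohort with known truth
#'
#' Generates per-sample matched and tumor-only small-variant call sets,
#' three-caller SV call sets, matched/tumor-only copy-number profiles, sex
#' and purity evidence tables, and cohort-consistent annotation resources;
#' identical seeds give byte-identical output directories.
#'
#' @param p `simulation_params`.
#' @param dir if non-NULL, write the cohort to this directory (VCFs, BEDs,
#'   segment tables, evidence and truth tables, params echo).
#' @return object of class `synthetic_cohort`: `params`, `meta` (sample,
#'   sex, purity, y_loss), `samples` (per sample: `tumor_only`,
#'   `matched_somatic`, `sv_calls` per caller, `cn_matched`,
#'   `cn_tumor_only`), `truth` (small variants, SVs, injected CN segments),
#'   `evidence` (sex, purity), `resources` and `dir`.
#' @export
simulate_cohort <- function(p = simulation_params(), dir = NULL) {
  genome <- synthetic_genome()
  ids <- sample_ids(p$n_samples)
  meta <- withr::with_seed(sub_seed(p$seed, 1), {
    sex <- ifelse(runif(p$n_samples) < p$sex_ratio, "M", "F")
    sex[1] <- "M"
    if (p$n_samples >= 2) sex[2] <- "F"
    purity <- round(runif(p$n_samples, p$purity_range[1], p$purity_range[2]), 4)
    y_loss <- rep(FALSE, p$n_samples)
    if (p$inject_y_loss) y_loss[1] <- TRUE
    data.frame(sample = ids, sex = sex, purity = purity, y_loss = y_loss,
               stringsAsFactors = FALSE)
  })

  samples <- list()
  small_truth <- list()
  sv_truth <- list()
  for (i in seq_len(p$n_samples)) {
    sm <- withr::with_seed(sub_seed(p$seed, 10, i), {
      sim_small_variants_one(p, ids[i], meta$purity[i], genome)
    })
    sv <- withr::with_seed(sub_seed(p$seed, 20, i), {
      sim_svs_one(p, ids[i], meta$purity[i], genome)
    })
    samples[[ids[i]]] <- list(tumor_only = sm$tumor_only,
                              matched_somatic = sm$matched_somatic,
                              sv_calls = sv$calls)
    small_truth[[i]] <- sm$truth
    sv_truth[[i]] <- sv$truth
  }
  cn <- simulate_cn_profiles(p, meta)
  for (id in ids) {
    samples[[id]]$cn_matched <- cn$profiles[[id]]$matched
    samples[[id]]$cn_tumor_only <- cn$profiles[[id]]$tumor_only
  }
  truth <- list(small_variants = do.call(rbind, small_truth),
                svs = do.call(rbind, Filter(Negate(is.null), sv_truth)),
                cn_injected = cn$injected)
  cohort <- structure(list(params = p, meta = meta, samples = samples,
                           truth = truth, dir = dir),
                      class = "synthetic_cohort")
  cohort$resources <- simulate_resources(cohort)
  cohort$evidence <- sim_evidence(p, meta)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (seed %d): %d small variants, %d SVs\n",
              x$params$n_samples, x$params$seed,
              nrow(x$truth$small_variants),
              if (is.null(x$truth$svs)) 0L else nrow(x$truth$svs)))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk in standard formats
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  genome <- synthetic_genome()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$params
  yaml::write_yaml(unclass(p)[setdiff(names(p), "")], file.path(dir, "params.yaml"))

  write_resources(cohort$resources, file.path(dir, "resources"), genome)

  dialects <- c(callerA = "bnd_pairs", callerB = "symbolic_end",
                callerC = "symbolic_chr2")
  for (id in names(cohort$samples)) {
    sd <- file.path(dir, "samples", id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    s <- cohort$samples[[id]]
    write_small_variants(s$tumor_only, file.path(sd, "tumor_only.vcf"), genome)
    write_small_variants(s$matched_somatic, file.path(sd, "matched_somatic.vcf"),
                         genome)
    for (caller in names(s$sv_calls)) {
      write_sv_calls(s$sv_calls[[caller]],
                     file.path(sd, paste0(caller, ".vcf")),
                     dialect = dialects[[caller]], genome = genome)
    }
    write_cn_callset(s$cn_matched, file.path(sd, "cn_matched.tsv"))
    write_cn_callset(s$cn_tumor_only, file.path(sd, "cn_tumor_only.tsv"))
  }

  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  write_tsv(cohort$truth$small_variants, file.path(td, "small_variants.tsv"))
  if (!is.null(cohort$truth$svs)) {
    write_tsv(cohort$truth$svs, file.path(td, "svs.tsv"))
  }
  if (!is.null(cohort$truth$cn_injected)) {
    write_tsv(cohort$truth$cn_injected, file.path(td, "cn_injected.tsv"))
  }
  write_tsv(cohort$meta, file.path(td, "samples.tsv"))

  ed <- file.path(dir, "evidence")
  dir.create(ed, showWarnings = FALSE)
  write_tsv(cohort$evidence$sex, file.path(ed, "sex_evidence.tsv"))
  write_tsv(cohort$evidence$purity, file.path(ed, "purity_estimates.tsv"))
  invisible(dir)
}
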
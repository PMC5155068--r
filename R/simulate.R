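# Seeded synthetic-data generator. Emulates the statistical structure of a
# SMRT Dam-methylation time course: per-read IPD mixtures at GATC sites with
# a methylated-fraction trajectory over the sampled hours, unmodified dam and
# WGA control samples, Poisson coverage, rare extreme outliers, and LC-MS /
# qPCR tables with stated noise. Every quantity is deterministic given the
# config seed.

DEFAULT_TIMEPOINTS_H <- c(8, 16, 24, 48, 72, 96, 120)

# Piecewise-linear methylated-fraction anchors per temporal pattern, defined
# at the default hours. A: flat 8-16 h then gradual increase; B: decline
# 24-72 h then recovery to 120 h; C: peak at 72 h; D: maxima at 24 h and
# 120 h; constant: high and flat (near-complete methylation).
PATTERN_ANCHORS <- list(
  A        = c(0.15, 0.15, 0.30, 0.45, 0.60, 0.78, 0.95),
  B        = c(0.90, 0.90, 0.85, 0.55, 0.20, 0.55, 0.90),
  C        = c(0.15, 0.35, 0.55, 0.75, 0.95, 0.55, 0.25),
  D        = c(0.30, 0.50, 0.95, 0.35, 0.25, 0.60, 0.90),
  constant = rep(0.92, 7L),
  none     = rep(0, 7L)
)

#' Methylated-fraction trajectory for a named temporal pattern
#'
#' @param pattern One of `"A"`, `"B"`, `"C"`, `"D"`, `"constant"`, `"none"`.
#' @param timepoints_h Hours at which to evaluate; interpolated linearly
#'   between the pattern's anchor fractions (defined at 8..120 h).
#' @return Numeric vector of fractions in \[0,1\].
#' @export
pattern_fraction <- function(pattern, timepoints_h = DEFAULT_TIMEPOINTS_H) {
  pattern <- match.arg(pattern, names(PATTERN_ANCHORS))
  anchors <- PATTERN_ANCHORS[[pattern]]
  stats::approx(DEFAULT_TIMEPOINTS_H, anchors, xout = timepoints_h,
                rule = 2)$y
}

#' Simulation configuration
#'
#' Free parameters of the synthetic study. IPDs are drawn log-normally:
#' log-IPD ~ N(`mu_unmeth`, `sigma_unmeth`) for unmethylated template
#' adenines and N(`mu_meth`, `sigma_meth`) for methylated ones, reflecting
#' that raw IPDs are positive, right-skewed, and larger opposite modified
#' bases. Coverage per stranded site is Poisson(`coverage_mean`) truncated at
#' >= 1. With probability `outlier_rate` a read's value is replaced by a
#' uniform draw on \[`outlier_floor`, `outlier_ceiling`\], exercising the
#' raw-IPD outlier cutoff of 50,000. Besides motif sites, the generator emits
#' `background_per_site` non-motif adenine positions per stranded GATC site,
#' unmethylated in every sample: these anchor the per-sample grand-mean
#' centering the way the vast excess of non-GATC adenines does in real data.
#'
#' @param genome_length Genome length in bp.
#' @param gatc_count_target Number of planted duplex GATC occurrences.
#' @param mu_unmeth,sigma_unmeth,mu_meth,sigma_meth Log-scale location/scale
#'   of the two IPD laws; `mu_meth` must exceed `mu_unmeth`.
#' @param outlier_rate Probability a read is an extreme outlier.
#' @param outlier_floor,outlier_ceiling Raw-IPD bounds of outlier draws.
#' @param coverage_mean Mean per-site coverage; the default matches the
#'   study's average fold-coverage (~67x per time point).
#' @param timepoints_h Strictly increasing hours of the time course.
#' @param pattern_mix Named proportions over A, B, C, D, constant; must sum
#'   to 1.
#' @param background_per_site Non-motif adenine positions emitted per
#'   stranded GATC site.
#' @param seed Integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       gatc_count_target = 200L,
                       mu_unmeth = 0, sigma_unmeth = 0.6,
                       mu_meth = 1.0, sigma_meth = 0.6,
                       outlier_rate = 0.005,
                       outlier_floor = 50001, outlier_ceiling = 1e6,
                       coverage_mean = 67,
                       timepoints_h = DEFAULT_TIMEPOINTS_H,
                       pattern_mix = c(A = 0.015, B = 0.015, C = 0.015,
                                       D = 0.015, constant = 0.94),
                       background_per_site = 4,
                       seed = 1L) {
  stopifnot(genome_length >= 1, gatc_count_target >= 1)
  if (mu_meth <= mu_unmeth) stop("mu_meth must exceed mu_unmeth")
  stopifnot(sigma_unmeth > 0, sigma_meth > 0)
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0,1]")
  stopifnot(outlier_floor > 0, outlier_ceiling > outlier_floor)
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  if (any(diff(timepoints_h) <= 0)) stop("timepoints_h must be strictly increasing")
  want <- c("A", "B", "C", "D", "constant")
  if (!setequal(names(pattern_mix), want)) {
    stop("pattern_mix must be named over {A,B,C,D,constant}")
  }
  pattern_mix <- pattern_mix[want]
  if (abs(sum(pattern_mix) - 1) > 1e-8) stop("pattern_mix must sum to 1")
  if (any(pattern_mix < 0)) stop("pattern_mix proportions must be non-negative")
  stopifnot(background_per_site >= 0)
  structure(
    list(genome_length = as.integer(genome_length),
         gatc_count_target = as.integer(gatc_count_target),
         mu_unmeth = mu_unmeth, sigma_unmeth = sigma_unmeth,
         mu_meth = mu_meth, sigma_meth = sigma_meth,
         outlier_rate = outlier_rate, outlier_floor = outlier_floor,
         outlier_ceiling = outlier_ceiling, coverage_mean = coverage_mean,
         timepoints_h = as.numeric(timepoints_h),
         pattern_mix = pattern_mix,
         background_per_site = background_per_site,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

derive_seed <- function(seed, k) as.integer((as.numeric(seed) * 131 + k) %% 2147483647)

#' Generate a random genome with a planted number of GATC duplexes
#'
#' Builds an approximately uniform random background purged of accidental
#' GATC occurrences, then plants exactly `gatc_count_target` non-overlapping
#' duplex GATC occurrences, one per genome block, verifying afterwards that
#' no unintended occurrence was created at a junction.
#'
#' @param length Genome length in bp; must be at least 4 times the target.
#' @param gatc_count_target Number of duplex GATC occurrences to plant.
#' @param seed Integer seed.
#' @return List with `genome` (a [genome_sequence()]), `sites` (the scanned
#'   site table, two stranded adenine sites per duplex) and `duplex_starts`
#'   (1-based match starts of the planted occurrences).
#' @export
generate_genome <- function(length, gatc_count_target, seed = 1L) {
  length <- as.integer(length); target <- as.integer(gatc_count_target)
  if (length < 4L * target) {
    stop("impossible placement density: length must be >= 4 * gatc_count_target")
  }
  set.seed(as.integer(seed))
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # purge accidental GATCs from the background
  for (iter in 1:100) {
    seqstr <- paste0(chars, collapse = "")
    starts <- motif_match_starts(seqstr, "GATC")
    if (!length(starts)) break
    for (s in starts) {
      cur <- chars[s + 1L]
      chars[s + 1L] <- sample(setdiff(c("C", "G", "T"), cur), 1L)
    }
  }
  # one planted duplex per block, at a random in-block offset
  block <- length %/% target
  offsets <- vapply(seq_len(target), function(i) {
    sample.int(block - 3L, 1L)
  }, integer(1L))
  starts <- (seq_len(target) - 1L) * block + offsets
  for (s in starts) chars[s:(s + 3L)] <- c("G", "A", "T", "C")
  # repair unintended junction occurrences without touching planted motifs
  planted <- sort(starts)
  planted_bases <- unlist(lapply(planted, function(s) s:(s + 3L)))
  for (iter in 1:100) {
    seqstr <- paste0(chars, collapse = "")
    found <- motif_match_starts(seqstr, "GATC")
    extra <- setdiff(found, planted)
    if (!length(extra)) break
    for (s in extra) {
      free <- setdiff(s:(s + 3L), planted_bases)
      j <- free[1L]
      chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
    }
  }
  seqstr <- paste0(chars, collapse = "")
  if (!identical(sort(motif_match_starts(seqstr, "GATC")), planted)) {
    stop("failed to construct genome with the requested GATC count")
  }
  genome <- genome_sequence(sprintf("sim_genome_L%d", length), seqstr)
  sites <- scan_motif(genome, "GATC", 2L, "Dam_GATC")
  list(genome = genome, sites = sites, duplex_starts = planted)
}

# Background (non-motif) adenine positions, forward strand, outside any
# planted GATC occurrence.
select_background_sites <- function(genome, duplex_starts, n, seed) {
  set.seed(derive_seed(seed, 7L))
  chars <- strsplit(genome$residues, "")[[1L]]
  blocked <- unlist(lapply(duplex_starts, function(s) s:(s + 3L)))
  cand <- setdiff(which(chars == "A"), blocked)
  if (length(cand) < n) stop("genome too small for requested background sites")
  sort(sample(cand, n))
}

#' Site truth ledger for a simulated time course
#'
#' Assigns each duplex GATC occurrence a temporal pattern drawn from the
#' configured mix (both stranded adenines of a duplex share the trajectory)
#' and records the methylated fraction at every time point. Background
#' positions carry pattern `"none"` with fraction 0 everywhere.
#'
#' @param sim Output of [generate_genome()].
#' @param config A [sim_config()].
#' @return `data.table` with one row per emitted site: `position`, `strand`,
#'   `is_motif`, `pattern_label`, and one `f_<hours>` column per time point.
#' @export
assign_site_truths <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  sites <- sim$sites
  ndup <- length(sim$duplex_starts)
  labels <- sample(names(config$pattern_mix), ndup, replace = TRUE,
                   prob = config$pattern_mix)
  # map stranded sites to their duplex (plus-strand adenine = start + 1)
  duplex_of <- findInterval(sites$position, sort(sim$duplex_starts))
  truth <- data.table::data.table(
    position = sites$position, strand = sites$strand, is_motif = TRUE,
    pattern_label = labels[duplex_of]
  )
  nbg <- round(config$background_per_site * nrow(sites))
  if (nbg > 0) {
    bg <- select_background_sites(sim$genome, sim$duplex_starts, nbg,
                                  config$seed)
    truth <- rbind(truth, data.table::data.table(
      position = bg, strand = "+", is_motif = FALSE, pattern_label = "none"
    ))
  }
  for (i in seq_along(config$timepoints_h)) {
    h <- config$timepoints_h[i]
    col <- sprintf("f_%g", h)
    fr <- vapply(truth$pattern_label, function(p) {
      pattern_fraction(p, h)
    }, numeric(1L), USE.NAMES = FALSE)
    data.table::set(truth, j = col, value = fr)
  }
  data.table::setorderv(truth, c("position", "strand"))
  truth[]
}

#' Simulate one sample's per-read IPD table
#'
#' Per site, coverage is drawn Poisson(`coverage_mean`) truncated at >= 1;
#' each read is methylated with the site's fraction at the requested time
#' (controls use fraction 0 everywhere) and its raw IPD drawn from the
#' corresponding log-normal law; with probability `outlier_rate` the value is
#' replaced by an extreme outlier draw.
#'
#' @param truths Truth ledger from [assign_site_truths()].
#' @param time_h Hour of the time course, or `NA` for a control sample.
#' @param role `"timepoint"`, `"dam_control"` or `"wga_control"`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this sample.
#' @param genome_id Genome identifier carried in the table.
#' @param sample_id Sample identifier; defaults to role/time derived.
#' @return Long-format `data.table` with columns `genome_id`, `position`,
#'   `strand`, `base`, `ipd`, `sample_id`, `role`, `time_h` (one row per
#'   read-pass per site).
#' @export
simulate_sample_ipds <- function(truths, time_h = NA, role = "timepoint",
                                 config, seed, genome_id = "sim_genome",
                                 sample_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  role <- match.arg(role, c("timepoint", "dam_control", "wga_control"))
  if (role == "timepoint") {
    col <- sprintf("f_%g", time_h)
    if (!col %in% names(truths)) {
      stop("no methylated fraction defined at time ", time_h, " h")
    }
    f <- truths[[col]]
  } else {
    f <- rep(0, nrow(truths))  # controls are fully unmethylated
    time_h <- NA_real_
  }
  if (is.null(sample_id)) {
    sample_id <- switch(role, timepoint = sprintf("t%03dh", as.integer(time_h)),
                        dam_control = "dam", wga_control = "wga")
  }
  set.seed(as.integer(seed))
  nsite <- nrow(truths)
  n <- stats::rpois(nsite, config$coverage_mean)
  while (any(n == 0L)) n[n == 0L] <- stats::rpois(sum(n == 0L), config$coverage_mean)
  total <- sum(n)
  site_idx <- rep.int(seq_len(nsite), n)
  meth <- stats::runif(total) < rep.int(f, n)
  logipd <- ifelse(meth,
                   stats::rnorm(total, config$mu_meth, config$sigma_meth),
                   stats::rnorm(total, config$mu_unmeth, config$sigma_unmeth))
  ipd <- exp(logipd)
  if (config$outlier_rate > 0) {
    is_out <- stats::runif(total) < config$outlier_rate
    ipd[is_out] <- stats::runif(sum(is_out), config$outlier_floor,
                                config$outlier_ceiling)
  }
  data.table::data.table(
    genome_id = genome_id,
    position = truths$position[site_idx],
    strand = truths$strand[site_idx],
    base = "A",
    ipd = ipd,
    sample_id = sample_id,
    role = role,
    time_h = time_h
  )
}

#' Simulate a full methylation time course
#'
#' Generates the genome, assigns site truths, and simulates one IPD table per
#' configured time point plus a dam-control and a WGA-control table (both
#' fully unmethylated, labeled separately).
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `sites` (motif table), `truths` (ledger),
#'   `ipd` (one long table over all samples), and `metadata`
#'   (`sample_id`, `role`, `time_h`).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- generate_genome(config$genome_length, config$gatc_count_target,
                         seed = config$seed)
  truths <- assign_site_truths(sim, config)
  tabs <- list()
  meta <- list()
  for (i in seq_along(config$timepoints_h)) {
    h <- config$timepoints_h[i]
    tabs[[i]] <- simulate_sample_ipds(truths, time_h = h, role = "timepoint",
                                      config = config,
                                      seed = derive_seed(config$seed, 100L + i),
                                      genome_id = sim$genome$id)
    meta[[i]] <- data.table::data.table(sample_id = tabs[[i]]$sample_id[1L],
                                        role = "timepoint", time_h = h)
  }
  k <- length(tabs)
  tabs[[k + 1L]] <- simulate_sample_ipds(truths, role = "dam_control",
                                         config = config,
                                         seed = derive_seed(config$seed, 900L),
                                         genome_id = sim$genome$id)
  tabs[[k + 2L]] <- simulate_sample_ipds(truths, role = "wga_control",
                                         config = config,
                                         seed = derive_seed(config$seed, 901L),
                                         genome_id = sim$genome$id)
  meta[[k + 1L]] <- data.table::data.table(sample_id = "dam",
                                           role = "dam_control", time_h = NA_real_)
  meta[[k + 2L]] <- data.table::data.table(sample_id = "wga",
                                           role = "wga_control", time_h = NA_real_)
  list(genome = sim$genome, sites = sim$sites, truths = truths,
       ipd = data.table::rbindlist(tabs),
       metadata = data.table::rbindlist(meta))
}

#' Simulate an LC-MS nucleobase peak-area table
#'
#' Emits peak areas for A, T, G, C and meA over replicate injections of one
#' hydrolyzed-DNA sample. Areas are consistent with the requested methylated
#' fraction of the adenine pool (meA = f, A = 1 - f of the adenine signal;
#' T, G, C equimolar) under multiplicative noise of the stated coefficient of
#' variation.
#'
#' @param true_mea_fraction True meA/(meA+A) fraction, in \[0,1\].
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_injections Number of replicate injections (>= 1).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param base_area Nominal area of one equimolar base signal.
#' @param a_dilution Dilution factor applied to the adenine injections (the
#'   emitted A rows carry `peak_area / a_dilution` and record the factor).
#' @return `data.table` with `sample_id`, `replicate`, `analyte`,
#'   `peak_area`, `dilution_factor`.
#' @export
simulate_lcms_run <- function(true_mea_fraction, noise_cv = 0.05,
                              n_injections = 3L, seed = 1L,
                              sample_id = "sample", base_area = 1e6,
                              a_dilution = 1) {
  if (true_mea_fraction < 0 || true_mea_fraction > 1) {
    stop("true_mea_fraction must lie in [0,1]")
  }
  if (noise_cv < 0 || noise_cv >= 1) stop("noise_cv must lie in [0,1)")
  if (n_injections < 1L) stop("n_injections must be >= 1")
  set.seed(as.integer(seed))
  analytes <- c("A", "T", "G", "C", "meA")
  nominal <- c(A = base_area * (1 - true_mea_fraction),
               T = base_area, G = base_area, C = base_area,
               meA = base_area * true_mea_fraction)
  rows <- lapply(seq_len(n_injections), function(r) {
    noise <- pmax(1 + stats::rnorm(length(analytes), 0, noise_cv), 0)
    area <- nominal * noise
    dil <- ifelse(analytes == "A", a_dilution, 1)
    data.table::data.table(sample_id = sample_id, replicate = r,
                           analyte = analytes, peak_area = area / dil,
                           dilution_factor = dil)
  })
  data.table::rbindlist(rows)
}

#' Simulate a qRT-PCR plate
#'
#' Emits threshold-cycle (CT) tables for WT and dam strains at the requested
#' time points, with the dam strain's CT offset by log2 of the gene's true
#' fold change (fold = 2^(CT_dam - CT_WT) under perfect doubling), plus
#' Gaussian CT noise, RNA mass and primer-efficiency columns.
#'
#' @param true_fold_changes Named positive vector, gene -> fold change
#'   (WT expression relative to dam), applied at every time point.
#' @param ct_noise_sd Standard deviation of additive CT noise.
#' @param seed Integer seed.
#' @param timepoints_h Assayed hours (default 8 and 72).
#' @param n_replicates Biological replicates per cell.
#' @param baseline_ct Nominal WT CT.
#' @param rna_mass RNA mass (ng) added per reaction.
#' @param primer_efficiency Amplification efficiency in (0, 1.2].
#' @return `data.table` with `gene`, `strain`, `time_h`, `replicate`, `ct`,
#'   `rna_mass`, `primer_efficiency`.
#' @export
simulate_qpcr_plate <- function(true_fold_changes, ct_noise_sd = 0.1,
                                seed = 1L, timepoints_h = c(8, 72),
                                n_replicates = 3L, baseline_ct = 20,
                                rna_mass = 25, primer_efficiency = 1) {
  if (is.null(names(true_fold_changes)) || any(!nzchar(names(true_fold_changes)))) {
    stop("true_fold_changes must be a named vector (gene -> fold)")
  }
  if (any(true_fold_changes <= 0)) stop("fold changes must be positive")
  if (primer_efficiency <= 0 || primer_efficiency > 1.2) {
    stop("primer_efficiency must lie in (0, 1.2]")
  }
  set.seed(as.integer(seed))
  grid <- expand.grid(gene = names(true_fold_changes),
                      strain = c("WT", "dam"), time_h = timepoints_h,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  fold <- true_fold_changes[grid$gene]
  ct0 <- baseline_ct + ifelse(grid$strain == "dam", log2(fold), 0)
  # the recorded CT is pre-normalization; relative_expression() rescales by
  # log2(1+E), so the simulated machine CT divides the target back out
  ct <- (ct0 + stats::rnorm(nrow(grid), 0, ct_noise_sd)) /
    log2(1 + primer_efficiency)
  data.table::data.table(
    gene = grid$gene, strain = grid$strain, time_h = grid$time_h,
    replicate = grid$replicate, ct = ct, rna_mass = rna_mass,
    primer_efficiency = primer_efficiency
  )
}

#' Write a table as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @param overwrite Logical.
#' @return The path, invisibly.
#' @export
write_tsv_table <- function(x, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) stop("file exists: ", path)
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
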
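# Synthetic-data generator: IPD mixture laws, outliers, pattern templates,
# determinism, truth conservation, and the LC-MS / qPCR simulators.

make_flat_truths <- function(n_sites, f, seed = 1) {
  cfg <- sim_config(genome_length = 40L * n_sites,
                    gatc_count_target = ceiling(n_sites / 2),
                    background_per_site = 0, outlier_rate = 0, seed = seed)
  sim <- generate_genome(cfg$genome_length, cfg$gatc_count_target, seed = seed)
  truths <- assign_site_truths(sim, cfg)
  truths$f_8 <- rep(f, nrow(truths))
  list(cfg = cfg, truths = truths)
}

test_that("dam-control IPDs follow the unmethylated log-normal law", {
  x <- make_flat_truths(200, 0)
  tab <- simulate_sample_ipds(x$truths, role = "dam_control",
                              config = x$cfg, seed = 5)
  expect_gte(nrow(tab), 10000)
  logs <- log(tab$ipd)
  se <- x$cfg$sigma_unmeth / sqrt(nrow(tab))
  expect_lt(abs(mean(logs) - x$cfg$mu_unmeth), 3 * se)
  expect_true(all(tab$time_h %in% NA_real_))
  expect_equal(unique(tab$role), "dam_control")
})

test_that("fully methylated sites exceed the dam control at every site", {
  x <- make_flat_truths(100, 1)
  cfg <- x$cfg
  cfg$mu_meth <- cfg$mu_unmeth + 1.5 * cfg$sigma_unmeth
  samp <- simulate_sample_ipds(x$truths, time_h = 8, role = "timepoint",
                               config = cfg, seed = 6)
  ctrl <- simulate_sample_ipds(x$truths, role = "dam_control",
                               config = cfg, seed = 7)
  by_site <- function(tab) tapply(log(tab$ipd), paste(tab$position, tab$strand), mean)
  ms <- by_site(samp); mc <- by_site(ctrl)
  common <- intersect(names(ms), names(mc))
  expect_true(all(ms[common] > mc[common]))
})

test_that("outlier injection hits the configured rate above the cutoff", {
  x <- make_flat_truths(300, 0)
  cfg <- x$cfg
  cfg$outlier_rate <- 0.01
  tab <- simulate_sample_ipds(x$truths, role = "dam_control",
                              config = cfg, seed = 8)
  n <- nrow(tab)
  frac <- mean(tab$ipd > 50000)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("pattern templates have their defining temporal shapes", {
  tp <- c(8, 16, 24, 48, 72, 96, 120)
  fA <- pattern_fraction("A", tp)
  expect_equal(fA[1], fA[2])
  expect_true(all(diff(fA[2:7]) >= 0))
  fC <- pattern_fraction("C", tp)
  expect_equal(tp[which.max(fC)], 72)
  fB <- pattern_fraction("B", tp)
  expect_lt(fB[5], fB[3])           # decline 24 -> 72 h
  expect_gt(fB[7], fB[5])           # recovery to 120 h
  fD <- pattern_fraction("D", tp)
  expect_equal(tp[which.max(fD)], 24)
  expect_gt(fD[7], fD[5])           # second rise after 72 h
  fconst <- pattern_fraction("constant", tp)
  expect_true(all(fconst == fconst[1]))
  for (p in c("A", "B", "C", "D", "constant", "none")) {
    f <- pattern_fraction(p, tp)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("the time course is seed-deterministic and truth-conserving", {
  cfg <- sim_config(genome_length = 8000, gatc_count_target = 20,
                    background_per_site = 1, seed = 9)
  sim1 <- simulate_timecourse(cfg)
  sim2 <- simulate_timecourse(cfg)
  expect_identical(sim1$ipd, sim2$ipd)
  expect_identical(sim1$truths, sim2$truths)
  # every emitted site appears exactly once in the ledger
  emitted <- unique(paste(sim1$ipd$position, sim1$ipd$strand))
  ledger <- paste(sim1$truths$position, sim1$truths$strand)
  expect_setequal(emitted, ledger)
  expect_equal(anyDuplicated(ledger), 0L)
  # dam-control truth is f = 0 everywhere by construction of the roles
  dam <- sim1$ipd[sim1$ipd$role == "dam_control"]
  expect_gt(nrow(dam), 0)
  # 7 timepoints + dam + wga
  expect_equal(nrow(sim1$metadata), 9L)
  expect_equal(sum(sim1$metadata$role == "timepoint"), 7L)
})

test_that("dam control and an f=0 timepoint are statistically exchangeable", {
  x <- make_flat_truths(150, 0)
  a <- simulate_sample_ipds(x$truths, time_h = 8, role = "timepoint",
                            config = x$cfg, seed = 21)
  b <- simulate_sample_ipds(x$truths, role = "dam_control",
                            config = x$cfg, seed = 22)
  p <- stats::ks.test(log(a$ipd), log(b$ipd))$p.value
  expect_gt(p, 0.01)
})

test_that("LC-MS simulation recovers the true fraction", {
  noiseless <- simulate_lcms_run(0.3, noise_cv = 0, n_injections = 3, seed = 1)
  expect_equal(mea_fraction(noiseless)$fraction, 0.3)
  dam <- simulate_lcms_run(0, noise_cv = 0.05, n_injections = 3, seed = 2)
  expect_equal(dam[dam$analyte == "meA"]$peak_area, rep(0, 3))
  expect_equal(mea_fraction(dam)$fraction, 0)
  # delta-method bound on the mean recovered fraction
  fr <- vapply(1:50, function(s) {
    mea_fraction(simulate_lcms_run(0.5, noise_cv = 0.05, n_injections = 9,
                                   seed = s))$fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 3 * (0.05 / sqrt(9)) * 0.5)
  expect_error(simulate_lcms_run(1.2, 0.05, 3, 1), "0,1")
})

test_that("qPCR simulation encodes fold changes as CT differences", {
  p0 <- simulate_qpcr_plate(c(gA = 1), ct_noise_sd = 0, seed = 1)
  wt <- p0[p0$strain == "WT" & p0$time_h == 8]$ct
  dam <- p0[p0$strain == "dam" & p0$time_h == 8]$ct
  expect_equal(wt, dam)
  p4 <- simulate_qpcr_plate(c(gA = 4), ct_noise_sd = 0, seed = 1)
  dct <- p4[p4$strain == "dam" & p4$time_h == 8]$ct[1] -
    p4[p4$strain == "WT" & p4$time_h == 8]$ct[1]
  expect_equal(dct, 2)
  expect_error(simulate_qpcr_plate(c(gA = -1), 0.1, 1), "positive")
})

test_that("the qPCR fold estimator is unbiased under CT noise", {
  folds <- vapply(1:1000, function(s) {
    plate <- simulate_qpcr_plate(c(g = 4), ct_noise_sd = 0.1, seed = s,
                                 timepoints_h = 8)
    relative_expression(plate, "g", 8)$fold
  }, numeric(1))
  # per-plate log2 fold ~ N(2, 0.1*sqrt(2)/sqrt(3)); 3 SE over 1000 plates
  tol <- 3 * (0.1 * sqrt(2) / sqrt(3)) / sqrt(1000)
  expect_lt(abs(mean(log2(folds)) - 2), tol)
})
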
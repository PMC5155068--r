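# Temporal-change statistics: one-way ANOVA, Kruskal-Wallis, Storey
# q-values, and significant-site selection with truth recovery.

test_that("ANOVA matches a from-scratch sum-of-squares decomposition", {
  same <- anova_site(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  got <- anova_site(groups)
  # direct SS decomposition oracle
  all_v <- unlist(groups); gm <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ss_between / 2) / (ss_within / 6)
  expect_equal(got$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, stats::pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(anova_site(list(c(1, 2))), "2 groups")
})

test_that("two-group ANOVA equals the squared pooled-variance t", {
  set.seed(5)
  for (i in 1:5) {
    a <- stats::rnorm(12); b <- stats::rnorm(15, 0.3)
    f <- anova_site(list(a, b))$statistic
    t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis matches the rank-sum formula and tie oracle", {
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), N = 9, no ties
  got <- kruskal_site(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(got$statistic, 7.2, tolerance = 1e-12)
  # rank invariance under permutation of group contents
  got2 <- kruskal_site(list(c(3, 1, 2), c(6, 4, 5), c(9, 7, 8)))
  expect_equal(got2$statistic, got$statistic)
  # tie-corrected oracle: H0 / (1 - sum(t^3 - t) / (N^3 - N))
  groups <- list(c(1, 1, 2), c(1, 2, 2))
  tied <- kruskal_site(groups)
  v <- unlist(groups); r <- rank(v); N <- length(v)
  Ri <- c(sum(r[1:3]), sum(r[4:6]))
  H0 <- 12 / (N * (N + 1)) * sum(Ri^2 / 3) - 3 * (N + 1)
  tie_tab <- table(v)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  expect_equal(tied$statistic, H0 / C, tolerance = 1e-12)
  degen <- kruskal_site(list(c(2, 2), c(2, 2)))
  expect_true(degen$tie_degenerate)
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  set.seed(8)
  p <- stats::runif(500)^1.5
  got <- storey_qvalues(p, pi0_method = "fixed", pi0 = 1)
  expect_equal(got$qvalues, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  all_one <- storey_qvalues(rep(1, 20))
  expect_equal(all_one$pi0_estimate$pi0, 1)
  expect_equal(all_one$qvalues, rep(1, 20))
  expect_error(storey_qvalues(c(0.5, 1.2)), "0,1")
})

test_that("smoother pi0 is near 1 on uniform p-values", {
  set.seed(10)
  got <- storey_qvalues(stats::runif(10000))
  expect_lt(abs(got$pi0_estimate$pi0 - 1), 0.05)
})

test_that("q-values are monotone in p and bounded by pi0", {
  set.seed(11)
  p <- c(stats::rbeta(300, 0.3, 4), stats::runif(700))
  got <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(got$qvalues[o]) >= -1e-12))
  expect_lte(max(got$qvalues), got$pi0_estimate$pi0 + 1e-12)
})

test_that("null ANOVA p-values are uniform across simulated sites", {
  set.seed(12)
  p <- vapply(1:2000, function(i) {
    groups <- lapply(1:7, function(j) stats::rnorm(10))
    anova_site(groups)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("selection thresholds and ordering follow the q-values", {
  res <- data.table::data.table(position = c(10L, 20L, 30L),
                                strand = "+",
                                q_anova = c(0.01, 0.2, 0.4))
  expect_equal(nrow(select_significant(res, 0.3)), 2L)
  expect_equal(nrow(select_significant(res, 0.05)), 1L)
  expect_equal(select_significant(res, 0.5)$position, c(10L, 20L, 30L))
})

test_that("temporal testing excludes sites missing a time point", {
  cfg <- sim_config(genome_length = 6000, gatc_count_target = 15,
                    background_per_site = 0, coverage_mean = 40, seed = 14)
  sim <- simulate_timecourse(cfg)
  # starve one site at one time point below the coverage threshold
  drop_pos <- sim$sites$position[1]
  ipd <- sim$ipd[-which(sim$ipd$position == drop_pos & sim$ipd$strand == "+" &
                          sim$ipd$sample_id == "t072h")]
  prep <- prepare_analysis(ipd, sim$sites)
  tm <- temporal_test(prep$analysis, offsets = prep$offsets)
  expect_equal(nrow(tm$excluded), 1L)
  expect_equal(tm$excluded$position, drop_pos)
  expect_equal(nrow(tm$results) + 1L, nrow(sim$sites))
})

test_that("rank tests are invariant under the monotone Box-Cox transform", {
  set.seed(15)
  groups <- lapply(1:7, function(i) stats::rlnorm(15, i / 10, 0.5))
  p_raw <- kruskal_site(groups)$p_value
  p_bc <- kruskal_site(lapply(groups, boxcox_transform,
                              params = transform_params()))$p_value
  expect_equal(p_raw, p_bc, tolerance = 1e-12)
})

test_that("temporal testing recovers changing sites on simulated truth", {
  cfg <- sim_config(genome_length = 40000, gatc_count_target = 100,
                    background_per_site = 0, seed = 16,
                    pattern_mix = c(A = 0.06, B = 0.06, C = 0.06, D = 0.06,
                                    constant = 0.76))
  sim <- simulate_timecourse(cfg)
  prep <- prepare_analysis(sim$ipd, sim$sites)
  tm <- temporal_test(prep$analysis, offsets = prep$offsets)
  sel <- select_significant(tm$results, 0.3)
  truth_key <- paste(sim$truths$position, sim$truths$strand)
  changing <- truth_key[!sim$truths$pattern_label %in% c("constant", "none")]
  sel_key <- paste(sel$position, sel$strand)
  recall <- length(intersect(sel_key, changing)) / length(changing)
  fdp <- if (nrow(sel)) length(setdiff(sel_key, changing)) / nrow(sel) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdp, 0.45)  # single replicate; the acceptance suite averages
  # parametric vs nonparametric selections are similar (Jaccard)
  sel_kw <- select_significant(tm$results, 0.3, q_col = "q_kw")
  kw_key <- paste(sel_kw$position, sel_kw$strand)
  jac <- length(intersect(sel_key, kw_key)) /
    max(1L, length(union(sel_key, kw_key)))
  expect_gte(jac, 0.6)
})
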
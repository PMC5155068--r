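# Temporal-change detection across the time course: one-way ANOVA on
# centered Box-Cox values and Kruskal-Wallis on raw values (rank tests are
# invariant under monotone transforms), with Storey q-values for FDR.

#' One-way fixed-effects ANOVA for one site
#'
#' Classical one-way F statistic across time-point groups with a p-value
#' from the F distribution. When every group has zero within-group variance
#' and equal means, F is defined as 0.
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return List with `statistic` (F), `p_value`, `df1`, `df2`,
#'   `n_per_group`.
#' @export
anova_site <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  n <- vapply(groups, length, integer(1L))
  if (any(n < 2L)) stop("each group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups); N <- length(values)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df1 = k - 1L, df2 = N - k,
                n_per_group = n))
  }
  g <- factor(rep.int(seq_len(k), n))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df1 = unname(ht$parameter[1L]), df2 = unname(ht$parameter[2L]),
       n_per_group = n)
}

#' Kruskal-Wallis rank test for one site
#'
#' Rank-based H statistic with mid-rank tie correction and a chi-square
#' p-value on k-1 degrees of freedom. All observations tied is flagged as
#' tie-degenerate (no rank information; p reported as 1).
#'
#' @param groups List of >= 2 numeric vectors with total n >= 3.
#' @return List with `statistic` (H), `p_value`, `df`, `tie_degenerate`.
#' @export
kruskal_site <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("need total n >= 3")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                tie_degenerate = TRUE))
  }
  ht <- stats::kruskal.test(groups)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), tie_degenerate = FALSE)
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 by the smoother method: pi0(lambda) =
#' #\{p > lambda\} / (n (1 - lambda)) on lambda in \{0, 0.05, ..., 0.90\},
#' smoothed by a cubic smoothing spline (df = 3) and evaluated at the
#' largest lambda, clamped to (0, 1]. q-values are the step-up
#' q_i = min over p_(j) >= p_(i) of pi0 * n * p_(j) / j, monotone in p.
#' With pi0 = 1 this reduces exactly to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p_values Vector of p-values in \[0,1\].
#' @param lambda_grid Grid for the pi0 smoother.
#' @param pi0_method `"smoother"` (default) or `"fixed"`.
#' @param pi0 Fixed pi0 value when `pi0_method = "fixed"`.
#' @return List with `qvalues` (in input order) and `pi0_estimate`
#'   (`pi0`, `lambda_grid`, `method`).
#' @export
storey_qvalues <- function(p_values, lambda_grid = seq(0, 0.90, by = 0.05),
                           pi0_method = c("smoother", "fixed"), pi0 = NULL) {
  pi0_method <- match.arg(pi0_method)
  p <- as.numeric(p_values)
  if (!length(p)) stop("need at least one p-value")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  n <- length(p)
  if (pi0_method == "fixed") {
    if (is.null(pi0) || pi0 <= 0 || pi0 > 1) stop("fixed pi0 must lie in (0,1]")
    pi0_hat <- pi0
  } else {
    pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1L))
    if (length(lambda_grid) >= 4L && stats::var(pi0_l) > 0) {
      fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
      pi0_hat <- stats::predict(fit, x = max(lambda_grid))$y
    } else {
      pi0_hat <- pi0_l[length(pi0_l)]
    }
    pi0_hat <- min(max(pi0_hat, .Machine$double.eps), 1)
  }
  o <- order(p)
  q_ord <- pi0_hat * n * p[o] / seq_len(n)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(n)
  q[o] <- q_ord
  list(qvalues = q,
       pi0_estimate = list(pi0 = pi0_hat, lambda_grid = lambda_grid,
                           method = pi0_method))
}

#' Temporal tests across all time points for every site
#'
#' Runs, per site with data at every configured time point, a one-way ANOVA
#' on the centered Box-Cox values and a Kruskal-Wallis test on the raw
#' values, then assigns Storey q-values per method. Sites missing any time
#' point are excluded from testing and listed.
#'
#' @param analysis Analysis table from [partition_by_site()].
#' @param params A [transform_params()].
#' @param offsets Optional per-sample centering offsets (see
#'   [detect_methylation()]).
#' @param timepoints_h Hours that must all be present; defaults to the
#'   distinct timepoint hours in the table.
#' @return List with `results` (per site: `position`, `strand`, `F`,
#'   `p_anova`, `q_anova`, `H`, `p_kw`, `q_kw`, `n_total`), `excluded`
#'   (sites lacking a time point), and `pi0` per method.
#' @export
temporal_test <- function(analysis, params = transform_params(),
                          offsets = NULL, timepoints_h = NULL) {
  tp_tab <- analysis[role == "timepoint"]
  if (is.null(timepoints_h)) timepoints_h <- sort(unique(tp_tab$time_h))
  if (length(timepoints_h) < 2L) stop("need >= 2 time points")
  ct <- centered_transformed_values(analysis, params, offsets)
  tp_tab <- data.table::copy(tp_tab)
  tp_tab[, .crow := match(paste(position, strand, sample_id),
                          paste(analysis$position, analysis$strand,
                                analysis$sample_id))]
  keys <- unique(tp_tab[, c("position", "strand")])
  rows <- vector("list", nrow(keys))
  excl <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- tp_tab[position == keys$position[i] & strand == keys$strand[i] &
                    status == "ok"]
    if (!setequal(sub$time_h, timepoints_h) ||
        length(unique(sub$time_h)) != nrow(sub)) {
      excl[[i]] <- keys[i]
      next
    }
    sub <- sub[order(time_h)]
    raw_groups <- sub$values
    bc_groups <- ct$centered[sub$.crow]
    a <- anova_site(bc_groups)
    kw <- kruskal_site(raw_groups)
    rows[[i]] <- data.table::data.table(
      position = keys$position[i], strand = keys$strand[i],
      F = a$statistic, p_anova = a$p_value,
      H = kw$statistic, p_kw = kw$p_value,
      n_total = sum(vapply(raw_groups, length, integer(1L))))
  }
  results <- data.table::rbindlist(rows)
  pi0 <- list()
  if (nrow(results)) {
    qa <- storey_qvalues(results$p_anova)
    qk <- storey_qvalues(results$p_kw)
    results[, q_anova := qa$qvalues]
    results[, q_kw := qk$qvalues]
    pi0 <- list(anova = qa$pi0_estimate, kruskal_wallis = qk$pi0_estimate)
    data.table::setcolorder(results, c("position", "strand", "F", "p_anova",
                                       "q_anova", "H", "p_kw", "q_kw",
                                       "n_total"))
  }
  list(results = results[], excluded = data.table::rbindlist(excl),
       pi0 = pi0)
}

#' Select temporally significant sites at an FDR threshold
#'
#' @param results Results table from [temporal_test()].
#' @param fdr FDR threshold (both 0.05 and 0.3 are used in practice).
#' @param q_col Which q-value column to threshold (`"q_anova"` default).
#' @return Sites with q < fdr, sorted by q then position.
#' @export
select_significant <- function(results, fdr, q_col = "q_anova") {
  stopifnot(fdr > 0, fdr < 1, q_col %in% names(results))
  sel <- results[results[[q_col]] < fdr]
  sel[order(sel[[q_col]], sel$position)]
}
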
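# Per-site methylation detection against the dam-mutant biological negative
# control: Welch t and Wilcoxon rank-sum tests on centered Box-Cox values,
# coverage equalization by subsampling or bootstrapping, and a cohort-level
# FDR pass (Storey q-values).

#' Welch two-sample t test for one site
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Groups in which both variances are zero are
#' flagged degenerate rather than silently returning a value.
#'
#' @param sample_values,control_values Centered transformed IPD values; each
#'   group needs n >= 2.
#' @return List with `statistic`, `p_value`, `df`, `n_sample`, `n_control`,
#'   `degenerate`.
#' @export
welch_t_site <- function(sample_values, control_values) {
  nx <- length(sample_values); ny <- length(control_values)
  if (nx < 2L || ny < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                n_sample = nx, n_control = ny, degenerate = TRUE))
  }
  if (stats::var(sample_values) == 0 && stats::var(control_values) == 0) {
    if (mean(sample_values) == mean(control_values)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  n_sample = nx, n_control = ny, degenerate = FALSE))
    }
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                n_sample = nx, n_control = ny, degenerate = TRUE))
  }
  ht <- stats::t.test(sample_values, control_values, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n_sample = nx, n_control = ny,
       degenerate = FALSE)
}

#' Wilcoxon rank-sum test for one site
#'
#' Exact two-sided p-value when the combined sample size is at most 25 and
#' there are no ties; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction.
#'
#' @param sample_values,control_values Raw or transformed values (the test is
#'   invariant under monotone transforms); each group needs n >= 1.
#' @return List with `statistic` (rank-sum W), `p_value`, `exact`, `tied`.
#' @export
wilcoxon_site <- function(sample_values, control_values) {
  nx <- length(sample_values); ny <- length(control_values)
  if (nx < 1L || ny < 1L) stop("each group needs at least one value")
  all_vals <- c(sample_values, control_values)
  if (length(unique(all_vals)) == 1L) {
    return(list(statistic = nx * ny / 2, p_value = 1, exact = FALSE,
                tied = TRUE))
  }
  has_ties <- anyDuplicated(all_vals) > 0L
  use_exact <- (nx + ny) <= 25L && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(sample_values, control_values, exact = use_exact,
                       correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = use_exact, tied = has_ties)
}

#' Coverage-equalized p-value by subsampling or bootstrapping
#'
#' Subsample mode randomly reduces the larger group (without replacement) to
#' the smaller's size and reports the median p over resamples; when coverage
#' is already equal, the plain test's p is returned with no reduction.
#' Bootstrap mode resamples both groups with replacement at equal n and
#' reports the median p. Deterministic given the seed.
#'
#' @param sample_values,control_values Value vectors.
#' @param mode `"subsample"` or `"bootstrap"`.
#' @param n_resamples Number of resampling repetitions (>= 100 for
#'   bootstrap mode).
#' @param seed Integer seed.
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @return List with `p_value` (median over resamples), `mode`,
#'   `n_resamples`, `seed`.
#' @export
equalize_coverage <- function(sample_values, control_values,
                              mode = c("subsample", "bootstrap"),
                              n_resamples = 199L, seed = 1L,
                              test = c("welch_t", "wilcoxon")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (!length(sample_values) || !length(control_values)) {
    stop("both groups must be non-empty")
  }
  if (mode == "bootstrap" && n_resamples < 100L) {
    stop("bootstrap mode needs n_resamples >= 100")
  }
  run_test <- function(x, y) {
    r <- if (test == "welch_t") welch_t_site(x, y) else wilcoxon_site(x, y)
    r$p_value
  }
  nx <- length(sample_values); ny <- length(control_values)
  n <- min(nx, ny)
  if (mode == "subsample" && nx == ny) {
    return(list(p_value = run_test(sample_values, control_values),
                mode = mode, n_resamples = 0L, seed = as.integer(seed)))
  }
  set.seed(as.integer(seed))
  ps <- vapply(seq_len(n_resamples), function(i) {
    if (mode == "subsample") {
      x <- if (nx > n) sample(sample_values, n) else sample_values
      y <- if (ny > n) sample(control_values, n) else control_values
    } else {
      x <- sample(sample_values, n, replace = TRUE)
      y <- sample(control_values, n, replace = TRUE)
    }
    run_test(x, y)
  }, numeric(1L))
  list(p_value = stats::median(ps, na.rm = TRUE), mode = mode,
       n_resamples = as.integer(n_resamples), seed = as.integer(seed))
}

# Transform and center the analysis table's values in place semantics:
# returns a list-column of centered transformed values. Offsets default to
# per-sample grand means over all cells of that sample in the table; the
# pipeline passes offsets computed over all reference positions (including
# non-motif background) instead.
centered_transformed_values <- function(analysis, params, offsets = NULL) {
  tv <- lapply(analysis$values, boxcox_transform, params = params)
  if (is.null(offsets)) {
    samples <- unique(analysis$sample_id)
    offsets <- vapply(samples, function(s) {
      mean(unlist(tv[analysis$sample_id == s], use.names = FALSE))
    }, numeric(1L))
    names(offsets) <- samples
  }
  centered <- Map(function(v, s) v - offsets[[s]], tv, analysis$sample_id)
  list(centered = centered, offsets = offsets)
}

#' Detect methylation per site against the dam-mutant control
#'
#' For every (site, non-control sample) cell present in the analysis table,
#' compares the centered Box-Cox IPD values with the dam control's values at
#' the same site, by Welch t and/or Wilcoxon tests. q-values are assigned per
#' sample cohort and per method by Storey's method, and `detected` is
#' `q < fdr`. Sites not significant in the primary pass can additionally be
#' re-tested under coverage equalization; the equalized p is recorded as a
#' confirmatory column (the final call stays with the FDR pass, which the
#' equalized re-test is not part of).
#'
#' @param analysis Analysis table from [partition_by_site()].
#' @param params A [transform_params()].
#' @param fdr FDR threshold in (0,1).
#' @param methods Character subset of `c("welch_t", "wilcoxon")`.
#' @param offsets Optional named per-sample centering offsets (transformed
#'   scale); computed from the table itself if omitted.
#' @param equalize If `TRUE`, non-significant cells are re-tested with
#'   [equalize_coverage()] (subsample mode) and the median p recorded.
#' @param n_resamples Resamples for the equalized re-test.
#' @param seed Integer seed (recorded in the output).
#' @return List with `results` (one row per site x sample x method:
#'   `position`, `strand`, `sample_id`, `method`, `statistic`, `p_value`,
#'   `q_value`, `n_sample`, `n_control`, `detected`, `p_equalized`),
#'   `summary` (tested/detected per sample and method), `offsets`, `fdr`,
#'   `seed`.
#' @export
detect_methylation <- function(analysis, params = transform_params(),
                               fdr = 0.05,
                               methods = c("welch_t", "wilcoxon"),
                               offsets = NULL, equalize = FALSE,
                               n_resamples = 199L, seed = 1L) {
  stopifnot(fdr > 0, fdr < 1)
  methods <- match.arg(methods, c("welch_t", "wilcoxon"), several.ok = TRUE)
  ctrl_ids <- unique(analysis$sample_id[analysis$role == "dam_control"])
  if (length(ctrl_ids) != 1L) {
    stop("exactly one dam_control sample is required for detection (found ",
         length(ctrl_ids), ")")
  }
  ct <- centered_transformed_values(analysis, params, offsets)
  analysis <- data.table::copy(analysis)
  analysis[, .row := .I]
  ctrl <- analysis[sample_id == ctrl_ids & status == "ok"]
  ctrl_lookup <- split(ctrl$.row, paste(ctrl$position, ctrl$strand))
  target <- analysis[sample_id != ctrl_ids]
  rows <- vector("list", nrow(target) * length(methods))
  k <- 0L
  for (i in seq_len(nrow(target))) {
    key <- paste(target$position[i], target$strand[i])
    crow <- ctrl_lookup[[key]]
    ok <- target$status[i] == "ok" && !is.null(crow)
    x <- if (ok) ct$centered[[target$.row[i]]] else numeric(0)
    y <- if (ok) ct$centered[[crow[1L]]] else numeric(0)
    for (m in methods) {
      k <- k + 1L
      if (!ok) {
        rows[[k]] <- data.table::data.table(
          position = target$position[i], strand = target$strand[i],
          sample_id = target$sample_id[i], method = m,
          statistic = NA_real_, p_value = NA_real_,
          n_sample = target$n_kept[i], n_control = NA_integer_)
        next
      }
      r <- if (m == "welch_t") welch_t_site(x, y) else wilcoxon_site(x, y)
      rows[[k]] <- data.table::data.table(
        position = target$position[i], strand = target$strand[i],
        sample_id = target$sample_id[i], method = m,
        statistic = r$statistic, p_value = r$p_value,
        n_sample = length(x), n_control = length(y))
    }
  }
  res <- data.table::rbindlist(rows)
  res[, q_value := NA_real_]
  for (s in unique(res$sample_id)) {
    for (m in methods) {
      idx <- which(res$sample_id == s & res$method == m & !is.na(res$p_value))
      if (length(idx)) {
        res$q_value[idx] <- storey_qvalues(res$p_value[idx])$qvalues
      }
    }
  }
  res[, detected := !is.na(q_value) & q_value < fdr]
  res[, p_equalized := NA_real_]
  if (equalize) {
    redo <- which(!res$detected & !is.na(res$p_value))
    for (j in redo) {
      key <- paste(res$position[j], res$strand[j])
      trow <- analysis[sample_id == res$sample_id[j] &
                         position == res$position[j] & strand == res$strand[j]]
      crow <- ctrl_lookup[[key]]
      eq <- equalize_coverage(ct$centered[[trow$.row[1L]]],
                              ct$centered[[crow[1L]]],
                              mode = "subsample", n_resamples = n_resamples,
                              seed = derive_seed(seed, j),
                              test = res$method[j])
      res$p_equalized[j] <- eq$p_value
    }
  }
  summary <- res[!is.na(p_value),
                 list(n_tested = .N, n_detected = sum(detected)),
                 by = c("sample_id", "method")]
  list(results = res[], summary = summary[], offsets = ct$offsets,
       fdr = fdr, seed = as.integer(seed))
}
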
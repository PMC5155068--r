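# IPD-ratio time courses and temporal pattern formation: per-site mean-IPD
# ratios against the dam control, Euclidean/Ward hierarchical clustering of
# significant sites, a k=4 cut, and shape-template labeling of the clusters
# as patterns A-D.

#' IPD ratio of a sample against the dam control at one site
#'
#' The arithmetic mean of the sample's raw IPDs divided by the arithmetic
#' mean of the dam control's raw IPDs at the same position; a ratio of 1
#' means the means are equal (no kinetic shift). Computed on raw values:
#' centered Box-Cox values can be negative, which would make a ratio
#' ill-defined.
#'
#' @param sample_values,control_values Raw IPD multisets (post-filtering).
#' @return Positive scalar ratio.
#' @export
ipd_ratio <- function(sample_values, control_values) {
  if (!length(sample_values) || !length(control_values)) {
    stop("both observation sets must be non-empty")
  }
  cm <- mean(control_values)
  if (cm == 0) stop("control mean is zero: corrupt input (IPDs are positive)")
  mean(sample_values) / cm
}

#' Build the sites x time points IPD-ratio matrix
#'
#' One row per selected site (ordered by genome position), one column per
#' time point in configured order. Sites with any missing (site, time) cell
#' are dropped with a warning and listed in the `dropped` attribute.
#'
#' @param analysis Analysis table from [partition_by_site()].
#' @param sites `data.frame` with `position` and `strand` of the selected
#'   (significant) sites, or a numeric vector of positions (both strands
#'   taken).
#' @param timepoints_h Column order; defaults to sorted distinct hours.
#' @param q_threshold Optional provenance: the q cutoff that selected the
#'   sites, recorded as an attribute.
#' @return Numeric matrix (rownames `position_strand`, colnames hours) with
#'   attributes `timepoints_h`, `q_threshold`, `dropped`.
#' @export
build_ratio_matrix <- function(analysis, sites, timepoints_h = NULL,
                               q_threshold = NA_real_) {
  ctrl <- analysis[role == "dam_control" & status == "ok"]
  if (!nrow(ctrl)) stop("dam control observations required for IPD ratios")
  tp <- analysis[role == "timepoint"]
  if (is.null(timepoints_h)) timepoints_h <- sort(unique(tp$time_h))
  if (is.numeric(sites) && is.null(dim(sites))) {
    sites <- unique(tp[position %in% sites, c("position", "strand")])
  }
  sites <- data.table::as.data.table(sites)[order(position, strand)]
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = length(timepoints_h),
                dimnames = list(paste(sites$position, sites$strand, sep = "_"),
                                as.character(timepoints_h)))
  ctrl_key <- paste(ctrl$position, ctrl$strand)
  for (i in seq_len(nrow(sites))) {
    ci <- match(paste(sites$position[i], sites$strand[i]), ctrl_key)
    if (is.na(ci)) next
    for (j in seq_along(timepoints_h)) {
      cell <- tp[position == sites$position[i] & strand == sites$strand[i] &
                   time_h == timepoints_h[j] & status == "ok"]
      if (nrow(cell) == 1L) {
        mat[i, j] <- ipd_ratio(cell$values[[1L]], ctrl$values[[ci]])
      }
    }
  }
  complete <- stats::complete.cases(mat)
  dropped <- rownames(mat)[!complete]
  if (length(dropped)) {
    warning(length(dropped), " site(s) dropped from the ratio matrix for ",
            "missing cells: ", paste(utils::head(dropped, 5L), collapse = ", "))
  }
  mat <- mat[complete, , drop = FALSE]
  attr(mat, "timepoints_h") <- timepoints_h
  attr(mat, "q_threshold") <- q_threshold
  attr(mat, "dropped") <- dropped
  mat
}

#' Ward hierarchical clustering of IPD-ratio trajectories
#'
#' Agglomerative clustering of site row-vectors on Euclidean distances under
#' Ward's minimum-variance criterion (Lance-Williams update on squared
#' dissimilarities, `ward.D2` convention). The greedy merge sequence picks,
#' at every step, the pair whose merge least increases the total
#' within-cluster variance.
#'
#' @param mat Ratio matrix from [build_ratio_matrix()] (>= 2 rows, finite).
#' @return An `hclust` object.
#' @export
ward_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 sites to cluster")
  if (any(!is.finite(mat))) stop("ratio matrix contains non-finite entries")
  stats::hclust(stats::dist(mat, method = "euclidean"), method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' @param hc `hclust` from [ward_cluster()].
#' @param k Number of clusters (default 4, the number of temporal patterns).
#' @return Integer cluster index (1..k) per site, named by row.
#' @export
cut_to_patterns <- function(hc, k = 4L) {
  if (k < 1L) stop("k must be >= 1")
  n <- length(hc$order)
  if (k > n) stop("k exceeds the number of sites")
  stats::cutree(hc, k = k)
}

# Shape scores of a standardized centroid trajectory against the four
# temporal templates. Index helpers pick the columns nearest the anchor
# hours so non-default time grids still score sensibly.
pattern_shape_scores <- function(centroid, timepoints_h) {
  z <- (centroid - mean(centroid)) / stats::sd(centroid)
  ix <- function(h) which.min(abs(timepoints_h - h))
  i8 <- ix(8); i16 <- ix(16); i24 <- ix(24); i72 <- ix(72)
  iT <- length(z)
  c(
    # A: flat 8-16 h, then gradual monotone increase
    A = (z[iT] - z[i16]) - abs(z[i16] - z[i8]) -
      sum(pmax(0, -diff(z[i16:iT]))),
    # B: high plateau early, net decline 24 -> 72 h, recovery to 120 h
    B = (z[i24] - z[i72]) + (z[iT] - z[i72]) - abs(z[i8] - z[i24]),
    # C: single peak at 72 h
    C = (z[i72] - z[i8]) + (z[i72] - z[iT]),
    # D: maxima at 24 h and at the end, dip around 72 h
    D = (z[i24] - z[i8]) + (z[iT] - z[i72]) + (z[i24] - z[i72])
  )
}

#' Label clusters with temporal patterns A-D
#'
#' Scores each cluster's centroid trajectory against the four shape
#' templates (A: stable 8-16 h then gradual increase; B: decline 24-72 h
#' then recovery; C: highest ratio at 72 h; D: maxima at 24 h and 120 h) and
#' assigns distinct labels by the one-to-one matching maximizing the total
#' score. With fewer than 4 clusters the best distinct labels are assigned
#' with a warning; with more than 4 clusters labels repeat (per-cluster best
#' match) with a warning.
#'
#' @param assignments Cluster index per site from [cut_to_patterns()].
#' @param mat The ratio matrix the clustering used.
#' @return `data.table` with `site` (rowname), `position`, `strand`,
#'   `cluster_index`, `pattern_label`, plus a `centroids` attribute.
#' @export
label_patterns <- function(assignments, mat) {
  timepoints_h <- attr(mat, "timepoints_h") %||%
    suppressWarnings(as.numeric(colnames(mat)))
  if (any(is.na(timepoints_h))) {
    stop("time points unavailable: matrix lacks numeric colnames/attribute")
  }
  clusters <- sort(unique(assignments))
  k <- length(clusters)
  centroids <- t(vapply(clusters, function(cl) {
    colMeans(mat[assignments == cl, , drop = FALSE])
  }, numeric(ncol(mat))))
  scores <- t(apply(centroids, 1L, pattern_shape_scores,
                    timepoints_h = timepoints_h))
  labels4 <- c("A", "B", "C", "D")
  if (k <= 4L) {
    if (k < 4L) warning("fewer than 4 clusters; assigning best distinct labels")
    perms <- all_permutations(4L)
    best <- NULL; best_total <- -Inf
    for (p in perms) {
      lab <- p[seq_len(k)]
      total <- sum(scores[cbind(seq_len(k), lab)])
      if (total > best_total) { best_total <- total; best <- lab }
    }
    cluster_label <- labels4[best]
  } else {
    warning("more than 4 clusters; pattern labels will repeat")
    cluster_label <- labels4[apply(scores, 1L, which.max)]
  }
  names(cluster_label) <- clusters
  rn <- rownames(mat)
  parts <- strsplit(rn, "_")
  out <- data.table::data.table(
    site = rn,
    position = as.integer(vapply(parts, `[[`, character(1L), 1L)),
    strand = vapply(parts, function(p) p[length(p)], character(1L)),
    cluster_index = as.integer(assignments),
    pattern_label = cluster_label[as.character(assignments)]
  )
  attr(out, "centroids") <- centroids
  attr(out, "scores") <- scores
  out[]
}

# All permutations of 1..n (n small; used for label assignment).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Export a dendrogram in Newick format with merge heights
#'
#' @param hc `hclust` from [ward_cluster()].
#' @param path Output path.
#' @param overwrite Logical.
#' @export
write_dendrogram_newick <- function(hc, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) stop("file exists: ", path)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
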
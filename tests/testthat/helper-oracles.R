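# Independent oracles and small fixture builders shared across the suite.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# Character-by-character exhaustive motif matcher (regex-free), both strands,
# forward coordinates; mirrors the scan_motif contract.
brute_force_scan <- function(residues, motif, modified_offset,
                             circular = FALSE) {
  L <- nchar(residues)
  len <- nchar(motif)
  subject <- if (circular && len > 1L) {
    paste0(residues, substr(residues, 1L, len - 1L))
  } else residues
  sub_chars <- strsplit(subject, "")[[1L]]
  match_at <- function(pattern_chars, s) {
    for (j in seq_along(pattern_chars)) {
      if (!sub_chars[s + j - 1L] %in% IUPAC_SETS[[pattern_chars[j]]]) {
        return(FALSE)
      }
    }
    TRUE
  }
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcomp_chr(motif)
    pat_chars <- strsplit(pat, "")[[1L]]
    for (s in seq_len(nchar(subject) - len + 1L)) {
      if (s > L) next
      if (match_at(pat_chars, s)) {
        pos <- if (strand == "+") s + modified_offset - 1L
               else s + (len - modified_offset)
        pos <- ((pos - 1L) %% L) + 1L
        out[[length(out) + 1L]] <- data.frame(position = pos, strand = strand)
      }
    }
  }
  if (!length(out)) return(data.frame(position = integer(0), strand = character(0)))
  df <- do.call(rbind, out)
  df[order(df$position, df$strand), , drop = FALSE]
}

# Greedy Ward (minimum increase in total within-cluster sum of squares),
# exhaustive over all cluster pairs at every step; ties broken by the
# smaller involved index. Returns the sequence of partitions (as sorted
# member lists) after each merge.
brute_force_ward <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  ess_increase <- function(a, b) {
    na <- length(a); nb <- length(b)
    ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
    (na * nb / (na + nb)) * sum((ca - cb)^2)
  }
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        cost <- ess_increase(clusters[[i]], clusters[[j]])
        if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)
  }
  partitions
}

# Canonical partition signature for comparing clusterings.
partition_signature <- function(members) {
  paste(sort(vapply(members, function(m) paste(m, collapse = ","),
                    character(1L))), collapse = "|")
}

# hclust merge table -> partition signature after each merge step.
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  merged_members <- vector("list", n - 1L)
  absorbed_singleton <- logical(n)
  absorbed_merge <- logical(n - 1L)
  out <- character(n - 1L)
  for (step in seq_len(n - 1L)) {
    get_members <- function(code) {
      if (code < 0L) {
        absorbed_singleton[-code] <<- TRUE
        -code
      } else {
        absorbed_merge[code] <<- TRUE
        merged_members[[code]]
      }
    }
    merged_members[[step]] <- sort(c(get_members(hc$merge[step, 1L]),
                                     get_members(hc$merge[step, 2L])))
    tops <- which(!absorbed_merge[seq_len(step)])
    part <- c(merged_members[tops], as.list(which(!absorbed_singleton)))
    out[step] <- partition_signature(part)
  }
  out
}

# Small deterministic analysis-table builder used by detection/temporal
# tests: n_sites null or methylated sites vs a dam control.
build_two_group_analysis <- function(n_sites, f, coverage = 50,
                                     mu_meth = 0.9, background = 4,
                                     seed = 1) {
  cfg <- sim_config(genome_length = max(4000L, 40L * n_sites),
                    gatc_count_target = ceiling(n_sites / 2),
                    mu_meth = mu_meth, coverage_mean = coverage,
                    outlier_rate = 0, background_per_site = background,
                    pattern_mix = c(A = 0, B = 0, C = 0, D = 0, constant = 1),
                    seed = seed)
  sim <- generate_genome(cfg$genome_length, cfg$gatc_count_target, seed = seed)
  truths <- assign_site_truths(sim, cfg)
  truths$f_8 <- ifelse(truths$is_motif, f, 0)
  samp <- simulate_sample_ipds(truths, time_h = 8, role = "timepoint",
                               config = cfg, seed = derive_seed2(seed, 11))
  ctrl <- simulate_sample_ipds(truths, role = "dam_control", config = cfg,
                               seed = derive_seed2(seed, 12))
  records <- rbind(samp, ctrl)
  prepare_analysis(records, sim$sites)
}

derive_seed2 <- function(seed, k) as.integer((as.numeric(seed) * 977 + k) %% 2147483647)
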
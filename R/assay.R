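# Orthogonal quantification: LC-MS methylated-adenine fraction with percent
# coefficient-of-variation error propagation and Chargaff-ratio checks, and
# qRT-PCR relative expression (2^dCT) with RNA-mass and primer-efficiency
# normalization.

# Expected [M+H]+ m/z of the nucleobase analytes, available for validating
# peak tables against the acquisition settings.
NUCLEOBASE_MZ <- c(A = 136.0618, T = 127.0502, G = 152.0567, C = 112.0505,
                   meA = 150.0774)

corrected_areas <- function(peaks, sample = NULL) {
  peaks <- data.table::as.data.table(peaks)
  if (!is.null(sample)) peaks <- peaks[sample_id == sample]
  if (!nrow(peaks)) stop("no peak rows for the requested sample")
  peaks[, corrected := peak_area * dilution_factor]
  peaks
}

#' Methylated-adenine fraction from LC-MS peak areas
#'
#' Dilution-corrects each peak area (area x dilution factor), computes
#' meA / (meA + A) per replicate injection, and averages over replicates.
#' A dam-control sample, which contains no meA, yields 0.
#'
#' @param peaks Peak table with columns `sample_id`, `replicate`, `analyte`,
#'   `peak_area`, `dilution_factor`.
#' @param sample Optional sample id filter.
#' @return List with `fraction` (replicate mean; NA with a flag when both
#'   areas are zero), `replicate_fractions`, `n_replicates`, `undefined`.
#' @export
mea_fraction <- function(peaks, sample = NULL) {
  peaks <- corrected_areas(peaks, sample)
  need <- c("A", "meA")
  if (!all(need %in% peaks$analyte)) {
    stop("peak table must contain both A and meA rows")
  }
  wide <- data.table::dcast(peaks[analyte %in% need],
                            replicate ~ analyte, value.var = "corrected")
  denom <- wide$meA + wide$A
  fr <- ifelse(denom == 0, NA_real_, wide$meA / denom)
  undefined <- all(is.na(fr))
  list(fraction = if (undefined) NA_real_ else mean(fr, na.rm = TRUE),
       replicate_fractions = fr, n_replicates = nrow(wide),
       undefined = undefined)
}

#' Percent coefficient of variation
#'
#' @param values Replicate measurements (>= 2).
#' @return 100 * sd / mean; NA with a warning when the mean is zero.
#' @export
percent_cv <- function(values) {
  if (length(values) < 2L) stop("percent CV needs >= 2 replicates")
  m <- mean(values)
  if (m == 0) {
    warning("mean is zero: percent CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Propagate percent CVs across biological samples
#'
#' Computes the percent CV of each biological sample's replicate fractions
#' and combines them by root-sum-of-squares. A plain numeric vector is
#' interpreted as already-computed component CVs.
#'
#' @param replicates List of replicate-value vectors (one per biological
#'   sample), or a numeric vector of component percent CVs.
#' @return List with `component_cv` (per sample) and `propagated`.
#' @export
propagate_cv <- function(replicates) {
  if (is.list(replicates)) {
    component <- vapply(replicates, percent_cv, numeric(1L))
  } else {
    component <- as.numeric(replicates)
  }
  list(component_cv = component,
       propagated = sqrt(sum(component^2)))
}

#' Chargaff purine/pyrimidine area ratios
#'
#' Reports the (A + meA) / T and G / C corrected-area ratios averaged over
#' replicates, flagging deviations from 1 beyond a tolerance. meA counts
#' with A in the purine total, so moving adenine signal between the A and
#' meA channels leaves the ratio unchanged.
#'
#' @param peaks Peak table (see [mea_fraction()]).
#' @param sample Optional sample id filter.
#' @param tolerance Allowed deviation from 1 before flagging.
#' @return List with `at_ratio`, `gc_ratio`, `at_flag`, `gc_flag`.
#' @export
chargaff_ratios <- function(peaks, sample = NULL, tolerance = 0.1) {
  peaks <- corrected_areas(peaks, sample)
  need <- c("A", "T", "G", "C")
  if (!all(need %in% peaks$analyte)) {
    stop("peak table must contain all four canonical bases")
  }
  tot <- peaks[, list(area = mean(corrected)), by = "analyte"]
  get <- function(a) {
    v <- tot$area[match(a, tot$analyte)]
    if (is.na(v)) 0 else v
  }
  a_all <- get("A") + get("meA")
  at <- if (get("T") == 0) NA_real_ else a_all / get("T")
  gc <- if (get("C") == 0) NA_real_ else get("G") / get("C")
  if (any(is.na(c(at, gc)))) warning("zero denominator in Chargaff ratio")
  list(at_ratio = at, gc_ratio = gc,
       at_flag = is.na(at) || abs(at - 1) > tolerance,
       gc_flag = is.na(gc) || abs(gc - 1) > tolerance)
}

adjusted_ct <- function(ct, rna_mass, primer_efficiency, ref_mass) {
  ct * log2(1 + primer_efficiency) - log2(rna_mass / ref_mass)
}

#' Relative expression (fold change) between strains from qPCR CTs
#'
#' Normalizes each threshold cycle for RNA mass (subtracting log2 of the
#' mass ratio to a common reference mass) and primer efficiency (scaling CT
#' by log2(1 + E); E = 1 is perfect doubling and leaves CT unchanged), then
#' computes fold = 2^(adjCT_dam - adjCT_WT) per replicate pair. A fold of 1
#' means equal expression (the behavior of a Dam-independent control gene).
#'
#' @param records CT table with columns `gene`, `strain`, `time_h`,
#'   `replicate`, `ct`, `rna_mass`, `primer_efficiency`.
#' @param gene Gene to evaluate.
#' @param time_h Time point to evaluate.
#' @param strains Length-2 character vector: c(numerator strain whose higher
#'   CT means lower expression, reference strain); default `c("dam", "WT")`
#'   so fold > 1 means WT expression exceeds dam.
#' @param ref_mass Reference RNA mass; defaults to the mean mass of the
#'   records used.
#' @return List with `fold` (replicate mean), `sd`, `replicate_folds`, `n`.
#' @export
relative_expression <- function(records, gene, time_h,
                                strains = c("dam", "WT"), ref_mass = NULL) {
  records <- data.table::as.data.table(records)
  # match on plain vectors: the argument names shadow column names inside a
  # data.table frame
  keep <- records$gene == gene & records$time_h == time_h
  sub <- records[which(keep)]
  for (s in strains) {
    if (!any(sub$strain == s)) {
      stop("no records for strain ", s, " of gene ", gene, " at ", time_h, " h")
    }
  }
  if (is.null(ref_mass)) ref_mass <- mean(sub$rna_mass)
  sub[, adj := adjusted_ct(ct, rna_mass, primer_efficiency, ref_mass)]
  a <- sub[strain == strains[1L]][order(replicate)]
  b <- sub[strain == strains[2L]][order(replicate)]
  n <- min(nrow(a), nrow(b))
  folds <- 2^(a$adj[seq_len(n)] - b$adj[seq_len(n)])
  list(fold = mean(folds), sd = if (n > 1L) stats::sd(folds) else NA_real_,
       replicate_folds = folds, n = n)
}

#' Per-gene, per-time fold-change table (WT vs dam)
#'
#' @param records CT table (see [relative_expression()]).
#' @param strains Strain pair passed through.
#' @return `data.table` with `gene`, `time_h`, `fold`, `sd`, `n`, `missing`
#'   (cells lacking either strain are marked missing, not dropped).
#' @export
fold_change_table <- function(records, strains = c("dam", "WT")) {
  records <- data.table::as.data.table(records)
  grid <- unique(records[, c("gene", "time_h")])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene[i]; h <- grid$time_h[i]
    sub <- records[gene == g & time_h == h]
    if (!all(strains %in% sub$strain)) {
      return(data.table::data.table(gene = g, time_h = h, fold = NA_real_,
                                    sd = NA_real_, n = 0L, missing = TRUE))
    }
    r <- relative_expression(records, g, h, strains = strains)
    data.table::data.table(gene = g, time_h = h, fold = r$fold, sd = r$sd,
                           n = r$n, missing = FALSE)
  })
  out <- data.table::rbindlist(rows)
  data.table::setorderv(out, c("gene", "time_h"))
  out[]
}
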
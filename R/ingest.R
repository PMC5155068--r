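# Ingestion of long-format per-read IPD tables: parsing with row-level
# validation, the raw-IPD outlier cutoff (50,000), the per-sample per-site
# coverage filter (>= 20), and organization into an analysis table keyed by
# (site, sample).

IPD_COLUMNS <- c("genome_id", "position", "strand", "base", "ipd", "sample_id")

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `role` (timepoint, dam_control
#'   or wga_control) and `time_h` (NA for controls).
#' @return A `data.table`.
#' @export
read_sample_metadata <- function(path) {
  meta <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c("sample_id", "role")))
  need <- c("sample_id", "role", "time_h")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("metadata missing columns: ",
                            paste(missing, collapse = ", "))
  ok <- meta$role %in% c("timepoint", "dam_control", "wga_control")
  if (any(!ok)) stop("unknown role(s): ", paste(unique(meta$role[!ok]), collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  meta$time_h <- as.numeric(meta$time_h)
  if (any(meta$role == "timepoint" & is.na(meta$time_h))) {
    stop("timepoint samples must carry time_h")
  }
  meta[]
}

#' Read a long-format per-read IPD table
#'
#' One row per read-pass per template position. Malformed rows (non-numeric
#' or non-positive IPD, missing fields, unknown sample id, out-of-bounds
#' position) are rejected, logged with their line numbers, and counted; the
#' parse continues.
#'
#' @param path TSV/CSV with header columns `genome_id`, `position`, `strand`,
#'   `base`, `ipd`, `sample_id`.
#' @param metadata Metadata table from [read_sample_metadata()]; rows whose
#'   `sample_id` is absent from it are rejected.
#' @param genome Optional [genome_sequence()] used to bound-check positions.
#' @return List with `records` (typed `data.table` joined with `role` and
#'   `time_h`), `rejected` (`line`, `reason`), and `n_rejected`.
#' @export
read_ipd_table <- function(path, metadata, genome = NULL) {
  raw <- data.table::fread(path, header = TRUE,
                           colClasses = "character", na.strings = NULL)
  missing <- setdiff(IPD_COLUMNS, names(raw))
  if (length(missing)) {
    stop("IPD table missing required columns: ", paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  reason <- character(n)
  pos <- suppressWarnings(as.integer(raw$position))
  ipd <- suppressWarnings(as.numeric(raw$ipd))
  bad_pos <- is.na(pos) | pos < 1L
  if (!is.null(genome)) bad_pos <- bad_pos | pos > genome$length
  reason[bad_pos] <- "position out of genome bounds or non-numeric"
  bad_ipd <- is.na(ipd) | ipd <= 0
  reason[bad_ipd & !nzchar(reason)] <- "non-numeric or non-positive ipd"
  bad_strand <- !raw$strand %in% c("+", "-")
  reason[bad_strand & !nzchar(reason)] <- "invalid strand"
  bad_sample <- !raw$sample_id %in% metadata$sample_id
  reason[bad_sample & !nzchar(reason)] <- "unknown sample_id"
  bad <- nzchar(reason)
  records <- data.table::data.table(
    genome_id = raw$genome_id[!bad], position = pos[!bad],
    strand = raw$strand[!bad], base = raw$base[!bad], ipd = ipd[!bad],
    sample_id = raw$sample_id[!bad]
  )
  records <- merge(records, metadata[, c("sample_id", "role", "time_h")],
                   by = "sample_id", sort = FALSE)
  data.table::setcolorder(records, c("genome_id", "position", "strand",
                                     "base", "ipd", "sample_id", "role",
                                     "time_h"))
  list(records = records[],
       rejected = data.table::data.table(line = line[bad],
                                         reason = reason[bad]),
       n_rejected = sum(bad))
}

#' Apply outlier and coverage filters to IPD observations
#'
#' Raw IPD values greater than `outlier_cutoff` are discarded as outliers
#' (applied to raw values, before any transform). Sites whose post-filter
#' coverage falls below `min_coverage` in a given sample are flagged excluded
#' for that sample (the threshold is inclusive: exactly `min_coverage` kept
#' values is enough). Filtering is per stranded site per sample.
#'
#' @param records Record table from [read_ipd_table()]`$records`, or any
#'   table with the same columns (e.g., simulator output).
#' @param outlier_cutoff Raw-IPD outlier threshold (values strictly greater
#'   are removed).
#' @param min_coverage Minimum kept coverage for a (site, sample) cell.
#' @return List with `observations` (kept rows), `cells` (per site/sample:
#'   `n_raw`, `n_kept`, `n_outliers`, `excluded`), and `report` (per sample:
#'   totals and exclusion counts).
#' @export
clean_observations <- function(records, outlier_cutoff = 50000,
                               min_coverage = 20L) {
  stopifnot(outlier_cutoff > 0, min_coverage >= 1L)
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) {
    return(list(observations = records,
                cells = data.table::data.table(),
                report = data.table::data.table()))
  }
  keyv <- c("genome_id", "position", "strand", "sample_id")
  is_out <- records$ipd > outlier_cutoff
  cells <- records[, list(
    n_raw = .N, n_kept = sum(!is_out[.I]), n_outliers = sum(is_out[.I]),
    role = role[1L], time_h = time_h[1L]
  ), by = keyv]
  cells[, excluded := n_kept < min_coverage]
  observations <- records[!is_out]
  report <- cells[, list(
    n_sites = .N,
    n_raw = sum(n_raw), n_kept = sum(n_kept), n_outliers = sum(n_outliers),
    n_excluded_sites = sum(excluded)
  ), by = "sample_id"]
  list(observations = observations[], cells = cells[], report = report[])
}

#' Partition cleaned observations into an analysis table
#'
#' Builds one row per (motif site, sample) pair: either the kept observation
#' values or an explicit missing marker (cell excluded by the coverage filter
#' or entirely absent). Positions present in the observations but absent from
#' the supplied motif site list are an error.
#'
#' @param cleaned Output of [clean_observations()]. Observations at non-motif
#'   positions must be removed by the caller beforehand (they serve centering
#'   only).
#' @param sites Motif site table from [scan_motif()].
#' @return `data.table` with columns `position`, `strand`, `sample_id`,
#'   `role`, `time_h`, `n_raw`, `n_kept`, `status` ("ok"/"missing") and
#'   list-column `values` (kept raw IPDs; empty for missing cells).
#' @export
partition_by_site <- function(cleaned, sites) {
  obs <- cleaned$observations
  cells <- data.table::copy(cleaned$cells)
  site_key <- paste(sites$position, sites$strand)
  obs_key <- paste(cells$position, cells$strand)
  unknown <- setdiff(obs_key, site_key)
  if (length(unknown)) {
    stop("observations at positions not in the motif site list: ",
         paste(utils::head(unknown, 3L), collapse = "; "))
  }
  samples <- unique(cells[, c("sample_id", "role", "time_h")])
  grid <- data.table::CJ(position = unique(sites$position), strand = c("+", "-"),
                         sample_id = samples$sample_id, unique = TRUE)
  grid <- grid[paste(position, strand) %in% site_key]
  grid <- merge(grid, samples, by = "sample_id")
  tab <- merge(grid, cells[, c("position", "strand", "sample_id", "n_raw",
                               "n_kept", "excluded")],
               by = c("position", "strand", "sample_id"), all.x = TRUE)
  tab[is.na(n_raw), `:=`(n_raw = 0L, n_kept = 0L, excluded = TRUE)]
  tab[, status := ifelse(excluded, "missing", "ok")]
  tab[, excluded := NULL]
  vals <- obs[, list(values = list(ipd)), by = c("position", "strand", "sample_id")]
  tab <- merge(tab, vals, by = c("position", "strand", "sample_id"), all.x = TRUE)
  empty <- vapply(tab$values, is.null, logical(1L))
  tab$values[empty] <- list(numeric(0))
  data.table::setorderv(tab, c("position", "strand", "sample_id"))
  tab[]
}
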
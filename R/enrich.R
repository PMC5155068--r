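# Mapping of significant sites to genes/regulatory regions and flat term
# enrichment by Fisher's exact test (raw P < 0.1, no multiple-testing
# correction, matching how the term table is thresholded).

#' Read a gene annotation table
#'
#' Accepts either a TSV with columns `gene_id`, `start`, `end`, `strand`
#' (optional `product`), or a GFF3 file (`.gff`/`.gff3`; gene features, with
#' `locus_tag`, `Name` or `ID` as the gene id).
#'
#' @param path Annotation file path.
#' @return `data.table` with `gene_id`, `start`, `end`, `strand`, `product`,
#'   sorted by start.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package; ",
           "alternatively supply a gene_id/start/end/strand TSV")
    }
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", , drop = FALSE]
    }
    id <- df$locus_tag %||% df$Name %||% df$ID
    if (is.null(id)) stop("GFF3 lacks locus_tag/Name/ID attributes")
    id <- as.character(id)
    fallback <- is.na(id) | !nzchar(id)
    if ("ID" %in% names(df)) id[fallback] <- as.character(df$ID)[fallback]
    ann <- data.table::data.table(
      gene_id = id, start = df$start, end = df$end,
      strand = as.character(df$strand),
      product = if ("product" %in% names(df)) as.character(df$product) else NA_character_
    )
  } else {
    ann <- data.table::fread(path, sep = "\t", header = TRUE)
    need <- c("gene_id", "start", "end", "strand")
    missing <- setdiff(need, names(ann))
    if (length(missing)) stop("annotation missing columns: ",
                              paste(missing, collapse = ", "))
    if (!"product" %in% names(ann)) ann[, product := NA_character_]
  }
  if (any(ann$start > ann$end)) stop("annotation with start > end")
  data.table::setorderv(ann, "start")
  ann[]
}

#' Read a term -> gene membership table
#'
#' @param path Two-column TSV (`term`, `gene`), one membership per row.
#' @return `data.table` with `term` and `gene`.
#' @export
read_term_map <- function(path) {
  tm <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("term", "gene")
  missing <- setdiff(need, names(tm))
  if (length(missing)) stop("term map missing columns: ",
                            paste(missing, collapse = ", "))
  unique(tm[, c("term", "gene")])
}

#' Map sites to genes (gene body or upstream window)
#'
#' A site maps to every gene whose span contains it, and otherwise to any
#' gene whose start lies within `upstream_window` bp downstream of the site
#' on the gene's strand (i.e., the site sits in the gene's upstream
#' regulatory region). In a divergent promoter a site can map to two genes.
#' Sites mapping to nothing are listed.
#'
#' @param sites `data.frame` with a `position` column (e.g., significant
#'   sites from [select_significant()]), or a numeric position vector.
#' @param annotations Annotation table from [read_annotations()].
#' @param upstream_window Upstream window in bp (default 300).
#' @return List with `genes` (unique mapped gene ids), `map` (`position`,
#'   `gene_id`, `where` = "body"/"upstream"), and `unmapped` positions.
#' @export
map_sites_to_genes <- function(sites, annotations, upstream_window = 300L) {
  pos <- if (is.numeric(sites)) as.integer(sites) else as.integer(sites$position)
  pos <- unique(pos)
  rows <- list()
  unmapped <- integer(0)
  for (p in pos) {
    body <- annotations[start <= p & end >= p]
    up_plus <- annotations[strand == "+" & p < start & p >= start - upstream_window]
    up_minus <- annotations[strand == "-" & p > end & p <= end + upstream_window]
    hit <- rbind(
      if (nrow(body)) data.table::data.table(position = p, gene_id = body$gene_id,
                                             where = "body"),
      if (nrow(up_plus)) data.table::data.table(position = p,
                                                gene_id = up_plus$gene_id,
                                                where = "upstream"),
      if (nrow(up_minus)) data.table::data.table(position = p,
                                                 gene_id = up_minus$gene_id,
                                                 where = "upstream")
    )
    if (is.null(hit) || !nrow(hit)) unmapped <- c(unmapped, p)
    else rows[[length(rows) + 1L]] <- hit
  }
  map <- data.table::rbindlist(rows)
  list(genes = unique(map$gene_id), map = map, unmapped = unmapped)
}

#' Fisher's exact test on a term-membership 2x2 table
#'
#' Margins-fixed hypergeometric test of `k` term members in a gene set of
#' size `n`, against `K` term members among `N` universe genes. The
#' two-sided p sums the probabilities of all tables at most as probable as
#' the observed one (point-probability method); `alternative = "greater"`
#' gives the one-sided enrichment tail.
#'
#' @param k Term members in the set.
#' @param K Term members in the universe.
#' @param n Set size.
#' @param N Universe size.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return p-value.
#' @export
fisher_exact <- function(k, K, n, N, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N ||
      (n - k) > (N - K)) {
    stop("inconsistent contingency counts")
  }
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2L)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Term enrichment of a gene set by Fisher's exact test
#'
#' One result per term with at least one set member; raw p-values are
#' thresholded at `alpha` with no multiple-testing correction. Counts and
#' per-term gene lists are emitted exactly as tested.
#'
#' @param gene_set Character vector of genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of all genes considered.
#' @param term_map Table from [read_term_map()]; must cover the universe.
#' @param alpha Significance threshold on the raw p (default 0.1).
#' @param alternative Sidedness passed to [fisher_exact()].
#' @return `data.table` sorted by p: `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `significant`, `genes` (comma-joined set members carrying the term).
#' @export
enrich_terms <- function(gene_set, universe, term_map, alpha = 0.1,
                         alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    stop("gene set member(s) absent from the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  tm <- term_map[gene %in% universe]
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(split(tm$gene, tm$term), function(members) members)
  res <- data.table::rbindlist(lapply(names(rows), function(term) {
    members <- rows[[term]]
    hit <- intersect(members, gene_set)
    if (!length(hit)) return(NULL)
    data.table::data.table(
      term = term, k = length(hit), K = length(members), n = n, N = N,
      p_value = fisher_exact(length(hit), length(members), n, N,
                             alternative = alternative),
      genes = paste(sort(hit), collapse = ",")
    )
  }))
  if (!nrow(res)) return(res)
  res[, significant := p_value < alpha]
  res[order(p_value, term)]
}
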
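# Motif scanning of methyltransferase recognition sites and inter-site gap
# statistics. Coordinates are 1-based inclusive; the recorded position of a
# site is the modified base (adenine for Dam/EcoK, the second cytosine for
# Dcm) on the forward coordinate axis, with the strand carrying the motif.

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGTN]"
)

#' Construct a genome sequence object
#'
#' @param id Sequence identifier.
#' @param residues DNA string over A/C/G/T/N (lowercase accepted, normalized
#'   to uppercase).
#' @param circular Logical; if `TRUE`, motif matches spanning the origin are
#'   reported and gap statistics include the wrap-around gap.
#' @return An object of class `genome_sequence` with fields `id`, `residues`,
#'   `circular` and `length`.
#' @export
genome_sequence <- function(id, residues, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("genome sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", residues)
  if (nzchar(bad)) {
    stop("genome contains non-DNA characters: ", substr(bad, 1L, 10L))
  }
  structure(
    list(id = id, residues = residues, circular = isTRUE(circular),
         length = nchar(residues)),
    class = "genome_sequence"
  )
}

#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file. With a single
#' record, returns one `genome_sequence`; otherwise a named list of them.
#'
#' @param path FASTA file path.
#' @param circular Logical, applied to every record.
#' @return A `genome_sequence` or a named list of them.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  out <- lapply(seq_along(set), function(i) {
    genome_sequence(ids[[i]], as.character(set[[i]]), circular = circular)
  })
  names(out) <- ids
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a genome sequence to FASTA
#'
#' @param genome A `genome_sequence`.
#' @param path Output path.
#' @param overwrite Logical; refuse to clobber an existing file unless `TRUE`.
#' @param width Line-wrap width.
#' @export
write_genome_fasta <- function(genome, path, overwrite = FALSE, width = 70L) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (file.exists(path) && !overwrite) stop("file exists: ", path)
  set <- Biostrings::DNAStringSet(genome$residues)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Built-in methyltransferase motif definitions
#'
#' Dam (GATC, adenine at offset 2), Dcm (CCWGG, second cytosine at offset 2)
#' and the bipartite M.EcoK recognition sequence AAC-N6-GTGC (adenine at
#' offset 2). Scanning a motif reports both strands, so the EcoK complement
#' GCAC-N6-GTT is found as minus-strand matches of the single pattern.
#'
#' @return Named list of `list(pattern, modified_offset)` motif definitions.
#' @export
default_motifs <- function() {
  list(
    Dam_GATC  = list(pattern = "GATC", modified_offset = 2L),
    Dcm_CCWGG = list(pattern = "CCWGG", modified_offset = 2L),
    EcoK      = list(pattern = "AACNNNNNNGTGC", modified_offset = 2L)
  )
}

iupac_regex <- function(motif) {
  chars <- strsplit(motif, "")[[1L]]
  unknown <- setdiff(chars, names(IUPAC_REGEX))
  if (length(unknown)) {
    stop("invalid IUPAC symbol(s) in motif: ", paste(unknown, collapse = ", "))
  }
  paste0(IUPAC_REGEX[chars], collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All (possibly overlapping) 1-based start positions of a fixed-length IUPAC
# pattern in a character string. A zero-width lookahead makes overlapping
# matches visible to the regex engine. Genome N is matched only by motif N.
motif_match_starts <- function(residues, motif) {
  rx <- paste0("(?=", iupac_regex(motif), ")")
  hits <- gregexpr(rx, residues, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Scan a genome for a methyltransferase recognition motif
#'
#' Finds every occurrence of an IUPAC motif on both strands. Matches of the
#' motif on the reverse strand are reported in forward coordinates with
#' `strand = "-"`. For circular genomes, matches spanning the origin are
#' included. Overlapping matches are all reported.
#'
#' @param genome A `genome_sequence`.
#' @param motif IUPAC pattern (fixed length; an N6 spacer is written as
#'   `NNNNNN`).
#' @param modified_offset 1-based index of the modified base within the motif.
#' @param motif_name Label recorded with each site.
#' @return A `data.table` of sites with columns `genome_id`, `position`
#'   (1-based forward coordinate of the modified base), `strand`,
#'   `motif_name`, `matched_text` (the matched sequence as read 5'→3' on the
#'   site's strand), sorted by (position, strand).
#' @export
scan_motif <- function(genome, motif, modified_offset, motif_name = motif) {
  stopifnot(inherits(genome, "genome_sequence"))
  motif <- toupper(motif)
  len <- nchar(motif)
  if (len < 1L) stop("motif length must be >= 1")
  modified_offset <- as.integer(modified_offset)
  if (modified_offset < 1L || modified_offset > len) {
    stop("modified_offset must lie within the motif (1..", len, ")")
  }
  L <- genome$length
  subject <- genome$residues
  if (genome$circular && len > 1L) {
    if (len - 1L > L) stop("motif longer than circular genome")
    subject <- paste0(subject, substr(genome$residues, 1L, len - 1L))
  }

  one_strand <- function(pattern, strand) {
    starts <- motif_match_starts(subject, pattern)
    starts <- starts[starts <= L]  # wrap copies beyond L are duplicates
    if (!length(starts)) return(NULL)
    txt <- substring(subject, starts, starts + len - 1L)
    if (strand == "+") {
      pos <- starts + modified_offset - 1L
    } else {
      # pattern scanned is the reverse complement of the motif; the modified
      # base, counted from the motif 5' end on the minus strand, sits at the
      # mirrored index of the forward-axis match.
      pos <- starts + (len - modified_offset)
      txt <- vapply(txt, reverse_complement, character(1L), USE.NAMES = FALSE)
    }
    pos <- ((pos - 1L) %% L) + 1L
    data.table::data.table(
      genome_id = genome$id, position = as.integer(pos), strand = strand,
      motif_name = motif_name, matched_text = txt
    )
  }

  fwd <- one_strand(motif, "+")
  rev <- one_strand(reverse_complement(motif), "-")
  sites <- data.table::rbindlist(list(fwd, rev))
  if (nrow(sites) == 0L) {
    return(data.table::data.table(
      genome_id = character(0), position = integer(0), strand = character(0),
      motif_name = character(0), matched_text = character(0)
    ))
  }
  data.table::setorderv(sites, c("position", "strand"))
  sites[]
}

#' Collapse stranded sites to duplex occurrences
#'
#' A palindromic duplex occurrence carries one modified base per strand; gap
#' statistics (the MutH strand-discrimination argument concerns duplex GATC
#' spacing) count each duplex once. The plus-strand position represents the
#' duplex; if only minus-strand sites exist, their positions are used.
#'
#' @param sites Site table from [scan_motif()].
#' @return Sorted integer vector of duplex positions.
#' @export
collapse_duplex <- function(sites) {
  stopifnot(is.data.frame(sites))
  pos <- sites$position[sites$strand == "+"]
  if (!length(pos)) pos <- sites$position
  sort(unique(as.integer(pos)))
}

#' Gaps between consecutive motif sites
#'
#' @param sites Site table from [scan_motif()], or a numeric vector of
#'   already-collapsed positions.
#' @param genome The scanned `genome_sequence` (supplies length/circularity).
#' @return Integer vector of gaps: n-1 gaps for a linear genome, n gaps
#'   (including the wrap-around) for a circular one.
#' @export
gap_lengths <- function(sites, genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  pos <- if (is.numeric(sites)) sort(unique(as.integer(sites)))
         else collapse_duplex(sites)
  if (!length(pos)) stop("no sites: gaps are undefined on an empty site list")
  gaps <- diff(pos)
  if (genome$circular) {
    gaps <- c(gaps, genome$length - pos[length(pos)] + pos[1L])
  }
  as.integer(gaps)
}

#' Count gaps exceeding a threshold
#'
#' @param gaps Integer vector from [gap_lengths()].
#' @param threshold Length in bp; gaps strictly greater are counted.
#' @return Integer count.
#' @export
count_long_gaps <- function(gaps, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  sum(gaps > threshold)
}

#' Write motif sites as BED6
#'
#' Single-base intervals in 0-based half-open BED convention
#' (`start = position - 1`, `end = position`), name = motif name, score ".".
#'
#' @param sites Site table from [scan_motif()].
#' @param path Output path.
#' @param overwrite Logical.
#' @return The path, invisibly.
#' @export
write_sites_bed <- function(sites, path, overwrite = FALSE) {
  stopifnot(is.data.frame(sites))
  if (file.exists(path) && !overwrite) stop("file exists: ", path)
  bed <- data.frame(
    chrom = sites$genome_id,
    start = sites$position - 1L,
    end = sites$position,
    name = sites$motif_name,
    score = ".",
    strand = sites$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site file back into a site table
#'
#' @param path BED file written by [write_sites_bed()].
#' @return A `data.table` with `genome_id`, `position`, `strand`, `motif_name`.
#' @export
read_sites_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.table::data.table(
    genome_id = bed[[1L]], position = as.integer(bed[[3L]]),
    strand = bed[[6L]], motif_name = bed[[4L]]
  )
}
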
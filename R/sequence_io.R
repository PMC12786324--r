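# Sequence input and TSS-anchored promoter extraction.
#
# Coordinate conventions, used everywhere downstream:
#   * genomic coordinates are 1-based inclusive (NCBI style);
#   * internal string indices are 0-based half-open;
#   * promoter positions are TSS-relative: the extracted window of length L
#     covers exactly -L .. -1, the base at -1 abuts the TSS, and the TSS base
#     itself is excluded.  0-based index i <-> relative position r = i - L.

#' Read a FASTA file into normalized sequence records
#'
#' Sequences are uppercased, U is mapped to T, and IUPAC ambiguity codes other
#' than N are collapsed to N (downstream scanners define behavior only over
#' A/C/G/T/N). Any other character is an error naming the record and offset.
#'
#' @param path path to a FASTA file (multi-record; wrapped or unwrapped lines).
#' @return a list of records, each a list with elements `id`, `sequence`,
#'   `description`.
#' @seealso [write_fasta()], [extract_promoter()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[[i]]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    s <- toupper(as.character(set[[i]]))
    if (nchar(s) == 0) stop("empty sequence for record '", id, "'")
    s <- chartr("U", "T", s)
    bad <- regexpr("[^ACGTRYSWKMBDHVN]", s)
    if (bad > 0) {
      stop("illegal character '", substr(s, bad, bad), "' in record '", id,
           "' at offset ", bad)
    }
    # collapse ambiguity codes (all but N itself) to N
    s <- chartr("RYSWKMBDHV", strrep("N", 10), s)
    list(id = id, sequence = s, description = desc)
  })
}

#' Write sequence records to FASTA
#'
#' @param records list of records as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    ids <- names(records) %||% paste0("seq", seq_along(records))
    records <- Map(function(id, s) list(id = id, sequence = s, description = ""),
                   ids, unname(records))
  }
  seqs <- vapply(records, function(r) r$sequence, character(1))
  nms <- vapply(records, function(r) {
    if (nzchar(r$description %||% "")) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract a TSS-anchored upstream promoter window
#'
#' Returns the `upstream_len` bases immediately 5' of a transcription start
#' site, written 5'→3' toward the TSS, as a `promoter_region`. On the + strand
#' this is the genomic interval `[tss_genomic - upstream_len, tss_genomic - 1]`
#' (1-based inclusive); on the − strand it is the reverse complement of
#' `[tss_genomic + 1, tss_genomic + upstream_len]`. The TSS base itself is
#' never included: the window covers TSS-relative positions `-upstream_len`
#' through `-1`.
#'
#' @param record a sequence record (list with `id` and `sequence`) from
#'   [read_fasta()], or a plain nucleotide string.
#' @param tss_genomic 1-based genomic coordinate of the TSS base.
#' @param upstream_len window length in bases (default 3000).
#' @param strand `"+"` or `"-"` (strand of the gene).
#' @param assembly_label free-text assembly tag carried into outputs.
#' @return a `promoter_region`: list with `source_id`, `tss_genomic`,
#'   `strand`, `length`, `sequence`, `assembly_label`.
#' @examples
#' rec <- list(id = "toy", sequence = "AACGT", description = "")
#' extract_promoter(rec, tss_genomic = 5, upstream_len = 4)$sequence  # "AACG"
#' @export
extract_promoter <- function(record, tss_genomic, upstream_len = 3000,
                             strand = c("+", "-"), assembly_label = "") {
  strand <- match.arg(strand)
  if (is.character(record)) record <- list(id = "seq", sequence = record)
  seqlen <- nchar(record$sequence)
  stopifnot(upstream_len >= 1, tss_genomic >= 1)
  if (strand == "+") {
    start <- tss_genomic - upstream_len   # 1-based
    end <- tss_genomic - 1
    if (start < 1) {
      stop("promoter window [", start, ", ", end, "] extends past the 5' end",
           " of '", record$id, "' (need start >= 1)")
    }
    if (end > seqlen) {
      stop("TSS coordinate ", tss_genomic, " outside sequence '", record$id,
           "' of length ", seqlen)
    }
    s <- substr(record$sequence, start, end)
  } else {
    start <- tss_genomic + 1
    end <- tss_genomic + upstream_len
    if (end > seqlen) {
      stop("promoter window [", start, ", ", end, "] extends past the 3' end",
           " of '", record$id, "' (sequence length ", seqlen, ")")
    }
    s <- revcomp(substr(record$sequence, start, end))
  }
  structure(list(source_id = record$id, tss_genomic = tss_genomic,
                 strand = strand, length = upstream_len, sequence = s,
                 assembly_label = assembly_label),
            class = "promoter_region")
}

#' Convert a TSS-relative position to a 0-based window index
#'
#' Positions in the window run `-L .. -1` (negative = upstream); the mapping is
#' `index = rel + L`.
#'
#' @param region a `promoter_region` (or its length `L` as a number).
#' @param rel TSS-relative position(s), in `[-L, -1]`.
#' @return 0-based index/indices into the promoter sequence.
#' @export
rel_to_index <- function(region, rel) {
  L <- if (inherits(region, "promoter_region")) region$length else region
  if (any(rel < -L | rel > -1)) {
    stop("TSS-relative position out of range [", -L, ", -1]: ",
         paste(rel[rel < -L | rel > -1], collapse = ", "))
  }
  rel + L
}

#' @rdname rel_to_index
#' @param index 0-based index/indices in `[0, L)`.
#' @export
index_to_rel <- function(region, index) {
  L <- if (inherits(region, "promoter_region")) region$length else region
  if (any(index < 0 | index >= L)) {
    stop("index out of range [0, ", L, "): ",
         paste(index[index < 0 | index >= L], collapse = ", "))
  }
  index - L
}

#' @export
print.promoter_region <- function(x, ...) {
  cat("TSS-anchored promoter window\n")
  cat("  source:  ", x$source_id,
      if (nzchar(x$assembly_label)) paste0(" (", x$assembly_label, ")") else "",
      "\n", sep = "")
  cat("  TSS:      position ", format(x$tss_genomic, big.mark = ","),
      " on strand ", x$strand, "\n", sep = "")
  cat("  window:   ", x$length, " bp, TSS-relative ", -x$length, " .. -1\n",
      sep = "")
  n <- min(60, x$length)
  cat("  sequence: ", substr(x$sequence, 1, n),
      if (x$length > n) "..." else "", "\n", sep = "")
  invisible(x)
}
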
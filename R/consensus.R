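# Exact/degenerate consensus-core matching for circadian motif families.
#
# Matching is position-wise over IUPAC codes in the pattern; an N in the
# *sequence* matches nothing, including a pattern N (conservative behavior on
# masked bases). The default strand mode is plus_only, reproducing the
# convention of listing positions on the + strand of the extracted promoter;
# note the Pdp1 and PER-repeat alternative pairs are reverse complements of
# each other, so those families are orientation-closed even under plus_only.

#' A consensus motif family
#'
#' @param family family label.
#' @param patterns character vector of IUPAC strings; alternatives are OR-ed
#'   and must share one width.
#' @return a `consensus_motif`.
#' @export
consensus_motif <- function(family, patterns) {
  stopifnot(is.character(family), length(family) == 1,
            is.character(patterns), length(patterns) >= 1)
  patterns <- toupper(patterns)
  for (p in patterns) {
    bad <- regexpr(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"), p)
    if (bad > 0) {
      stop("family '", family, "': illegal IUPAC code '", substr(p, bad, bad),
           "' in pattern ", p)
    }
  }
  widths <- unique(nchar(patterns))
  if (length(widths) != 1) {
    stop("family '", family, "': alternatives must share one width (got ",
         paste(nchar(patterns), collapse = "/"), ")")
  }
  structure(list(family = family, patterns = patterns, width = widths),
            class = "consensus_motif")
}

#' The six bundled circadian motif families
#'
#' Canonical E-box (CACGTG), degenerate E-box (CANNTG), D-box (TTATGYAA),
#' CRE (TGACGTCA), Pdp1 core (ATTTAT/ATAAAT) and PER-repeat core
#' (CATAC/GTATG) — the established cis-elements of the insect circadian
#' transcriptional loop (CLOCK/CYC activation via E-boxes, DBP/vrille-Pdp1
#' output loops via D-box and Pdp1 sites, CREB input via CRE).
#'
#' @param file optional path to a family config file: tab- or
#'   whitespace-separated lines `family pattern1[,pattern2...]`; `#` comments
#'   allowed. When given, the file replaces the bundled set.
#' @return named list of [consensus_motif()] objects.
#' @export
circadian_motifs <- function(file = NULL) {
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
      parts <- strsplit(l, "\\s+")[[1]]
      if (length(parts) < 2) stop("bad motif config line: ", l)
      consensus_motif(parts[1], strsplit(parts[2], ",", fixed = TRUE)[[1]])
    })
    names(out) <- vapply(out, function(m) m$family, character(1))
    return(out)
  }
  defs <- list(
    Ebox_canonical = "CACGTG",
    Ebox_degenerate = "CANNTG",
    Dbox = "TTATGYAA",
    CRE = "TGACGTCA",
    Pdp1 = c("ATTTAT", "ATAAAT"),
    PER_repeat = c("CATAC", "GTATG")
  )
  out <- Map(consensus_motif, names(defs), defs)
  names(out) <- names(defs)
  out
}

#' Compile an IUPAC pattern into a position-wise matcher
#'
#' @param iupac an IUPAC nucleotide string.
#' @return a list of allowed-base character vectors, one per position, with
#'   attribute `pattern`. A sequence base N matches no position.
#' @examples
#' m <- compile_pattern("TTATGYAA")
#' pattern_matches(m, "TTATGCAA")  # TRUE
#' pattern_matches(m, "TTATGAAA")  # FALSE
#' @export
compile_pattern <- function(iupac) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(IUPAC_SETS))
  if (length(unknown)) {
    stop("illegal IUPAC code(s): ", paste(unique(unknown), collapse = ", "))
  }
  structure(IUPAC_SETS[chars], pattern = iupac, class = "iupac_matcher")
}

#' @rdname compile_pattern
#' @param matcher a compiled matcher.
#' @param window a nucleotide string of the matcher's width.
#' @export
pattern_matches <- function(matcher, window) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(chars) != length(matcher)) return(FALSE)
  all(mapply(function(allowed, ch) ch %in% allowed, matcher, chars))
}

# Logical vector over all windows of encoded sequence `enc` matching `iupac`.
# Vectorized per pattern position; N (NA) fails every position.
iupac_window_matches <- function(iupac, enc) {
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  w <- length(chars)
  n_win <- length(enc) - w + 1
  if (n_win < 1) return(logical(0))
  ok <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    allowed <- match(IUPAC_SETS[[chars[j]]], DNA_BASES)
    b <- enc[j:(j + n_win - 1)]
    ok <- ok & !is.na(b) & (b %in% allowed)
  }
  ok
}

#' Consensus scan configuration
#'
#' @param strands `"plus_only"` (default, the reporting convention) or
#'   `"both"`.
#' @param dedup_degenerate_ebox drop any degenerate-E-box hit whose
#'   `(rel_start, strand)` coincides with a canonical-E-box hit (default TRUE;
#'   every CACGTG is also a CANNTG).
#' @return a `consensus_config` list.
#' @export
consensus_config <- function(strands = c("plus_only", "both"),
                             dedup_degenerate_ebox = TRUE) {
  strands <- match.arg(strands)
  structure(list(strands = strands,
                 dedup_degenerate_ebox = dedup_degenerate_ebox),
            class = "consensus_config")
}

#' Scan a promoter window for consensus motif cores
#'
#' Every window matching any alternative of a family yields a hit
#' (`source = "consensus"`, no scores). Under `plus_only` the patterns are
#' matched as written on the + strand; under `both`, reverse-complement
#' windows are additionally matched and reported on + strand coordinates with
#' strand `"-"`.
#'
#' @param region a `promoter_region` or plain nucleotide string.
#' @param motifs list of [consensus_motif()] (default the six bundled
#'   circadian families).
#' @param config a [consensus_config()].
#' @return a `motif_hits` data frame sorted by `rel_start` then family.
#' @export
scan_consensus <- function(region, motifs = circadian_motifs(),
                           config = consensus_config()) {
  if (is.character(region)) {
    region <- structure(list(source_id = "seq", tss_genomic = NA_integer_,
                             strand = "+", length = nchar(region),
                             sequence = region, assembly_label = ""),
                        class = "promoter_region")
  }
  if (inherits(motifs, "consensus_motif")) motifs <- list(motifs)
  L <- region$length
  enc <- seq_to_int(region$sequence)
  rows <- list()
  for (m in motifs) {
    if (m$width > L) {
      stop("family '", m$family, "' (width ", m$width,
           ") wider than promoter window (", L, " bases)")
    }
    pats <- list(`+` = m$patterns)
    if (config$strands == "both") pats[["-"]] <- revcomp(m$patterns)
    for (strand in names(pats)) {
      hit <- rep(FALSE, L - m$width + 1)
      for (p in pats[[strand]]) hit <- hit | iupac_window_matches(p, enc)
      idx <- which(hit)
      if (length(idx)) {
        rows[[length(rows) + 1]] <- data.frame(
          family = m$family, source = "consensus",
          rel_start = (idx - 1) - L, strand = strand,
          matched = substring(region$sequence, idx, idx + m$width - 1),
          raw_score = NA_real_, rel_score = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  if (config$dedup_degenerate_ebox &&
      all(c("Ebox_canonical", "Ebox_degenerate") %in%
          vapply(motifs, function(m) m$family, character(1)))) {
    canon <- out[out$family == "Ebox_canonical", c("rel_start", "strand")]
    drop <- out$family == "Ebox_degenerate" &
      paste(out$rel_start, out$strand) %in% paste(canon$rel_start, canon$strand)
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$rel_start, out$family,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  as_motif_hits(out, region)
}

#' Tally hits per motif family
#'
#' @param hits a `motif_hits` data frame.
#' @param families optional character vector fixing the families (and their
#'   order) in the output; families without hits get 0.
#' @return named integer vector of counts.
#' @export
count_by_family <- function(hits, families = NULL) {
  tab <- table(hits$family)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (!is.null(families)) {
    counts <- stats::setNames(
      vapply(families, function(f) sum(hits$family == f), integer(1)),
      families)
  }
  counts
}
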
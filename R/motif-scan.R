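#' Built-in 3'UTR cis-element motif definitions
#'
#' Regular expressions (DNA alphabet) for the cytoplasmic polyadenylation
#' element (CPE), the AAUAAA-class polyadenylation hexamer (Hex), the Pumilio
#' binding element (PBE), the Musashi binding element (MBE), and the AU-rich
#' element (ARE), with a canonical literal for each (a string matching the
#' regex, used when planting motifs into synthetic sequences). All defaults
#' are overridable: any tibble with columns `name`, `region`, `regex`,
#' `canonical_literal` works wherever a motif set is expected, and results
#' report the regex actually used.
#'
#' @return Tibble with columns name, region, regex, canonical_literal.
#' @examples
#' default_motifs()
#' @export
default_motifs <- function() {
  tibble::tribble(
    ~name,  ~region, ~regex,          ~canonical_literal,
    "CPE",  "UTR3",  "TTTTA{1,2}T",   "TTTTAAT",
    "Hex",  "UTR3",  "A[AT]TAAA",     "AATAAA",
    "PBE",  "UTR3",  "TGTA[ACGT]ATA", "TGTAAATA",
    "MBE",  "UTR3",  "[GA]T{1,3}AGT", "GTTAGT",
    "ARE",  "UTR3",  "ATTTA",         "ATTTA"
  )
}

validate_motifs <- function(motifs) {
  require_columns(motifs, c("name", "regex", "canonical_literal"), "motifs")
  for (i in seq_len(nrow(motifs))) {
    ok <- tryCatch({grepl(motifs$regex[i], "ACGT", perl = TRUE); TRUE},
                   error = function(e) FALSE)
    if (!ok) abort(sprintf("motif '%s': regex does not compile.", motifs$name[i]))
    if (!grepl(paste0("(?:", motifs$regex[i], ")"), motifs$canonical_literal[i],
               perl = TRUE)) {
      abort(sprintf("motif '%s': canonical literal does not match its regex.",
                    motifs$name[i]))
    }
  }
  invisible(motifs)
}

# Coerce UTR input (tibble, named character, DNAStringSet) to a named
# uppercase DNA character vector with U -> T.
as_utr_vector <- function(utrs, arg = "utrs") {
  if (inherits(utrs, "XStringSet")) {
    seqs <- as.character(utrs)
  } else if (is.data.frame(utrs)) {
    require_columns(utrs, c("transcript_id", "sequence"), arg)
    seqs <- setNames(as.character(utrs$sequence), utrs$transcript_id)
  } else if (is.character(utrs)) {
    if (is.null(names(utrs))) abort(sprintf("`%s` character vector must be named by transcript.", arg))
    seqs <- utrs
  } else {
    abort(sprintf("`%s` must be a tibble (transcript_id, sequence), named character vector, or DNAStringSet.", arg))
  }
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicated transcript ids in `%s`.", arg))
  }
  seqs <- chartr("u", "t", seqs)
  seqs <- chartr("U", "T", seqs)
  seqs <- toupper(seqs)
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    abort(sprintf("invalid characters in sequence record(s): %s.",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  seqs
}

# All match start offsets (1-based) and greedy match lengths of `regex` in
# each sequence, under the overlap convention: the search resumes one
# position past each match start, i.e. every offset at which a match can
# begin is counted. Implemented with a zero-width lookahead capture so one
# vectorized pass finds them all.
motif_matches <- function(seqs, regex) {
  ms <- gregexpr(paste0("(?=(", regex, "))"), seqs, perl = TRUE)
  lapply(ms, function(m) {
    if (m[1L] == -1L) {
      return(list(start = integer(0), length = integer(0)))
    }
    list(start = as.integer(m),
         length = as.integer(attr(m, "capture.length")[, 1L]))
  })
}

#' Scan UTR sequences for motif occurrences
#'
#' Counts regex matches of each motif in each sequence under the overlap
#' convention (successive searches resume one position past each match start,
#' so overlapping occurrences are all counted). `N` bases never match (the
#' motif alphabet is `A/C/G/T` character classes). Presence means
#' `count >= 1`; downstream association analyses use presence, not count.
#'
#' @param utrs UTR sequences: tibble with `transcript_id`, `sequence`; named
#'   character vector; or a `Biostrings::DNAStringSet`. `U` is normalized to
#'   `T` and case is folded.
#' @param motifs Motif definition tibble (see [default_motifs()]).
#' @param intervals If `TRUE`, include a list-column of per-match intervals
#'   (0-based, half-open, on the given strand).
#' @return Tibble: transcript_id, motif, regex, count, present
#'   (+ `intervals` when requested). Sequences are assumed to be the
#'   transcribed sense strand; no reverse-complement scanning.
#' @examples
#' scan_utrs(c(tx1 = "CCAATAAACC"), default_motifs())
#' @export
scan_utrs <- function(utrs, motifs = default_motifs(), intervals = FALSE) {
  seqs <- as_utr_vector(utrs)
  validate_motifs(motifs)
  res <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    hits <- motif_matches(seqs, motifs$regex[i])
    counts <- vapply(hits, function(h) length(h$start), integer(1))
    out <- tibble::tibble(
      transcript_id = names(seqs),
      motif = motifs$name[i],
      regex = motifs$regex[i],
      count = unname(counts),
      present = unname(counts) >= 1L
    )
    if (intervals) {
      out$intervals <- lapply(hits, function(h) {
        tibble::tibble(start = h$start - 1L, end = h$start - 1L + h$length)
      })
    }
    out
  })
  res
}

#' Presence matrix from a scan result
#'
#' @param scan Output of [scan_utrs()].
#' @return Wide tibble: transcript_id plus one logical column per motif.
#' @export
motif_presence <- function(scan) {
  require_columns(scan, c("transcript_id", "motif", "present"), "scan")
  tidyr::pivot_wider(
    dplyr::distinct(scan, .data$transcript_id, .data$motif, .data$present),
    names_from = "motif", values_from = "present"
  )
}
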
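as_read_tbl <- function(reads, arg = "reads") {
  if (is.character(reads)) {
    reads <- tibble(id = if (!is.null(names(reads))) names(reads) else
      paste0("read_", seq_along(reads)), sequence = unname(reads))
  }
  if (!is.data.frame(reads) || !all(c("id", "sequence") %in% names(reads))) {
    abort(sprintf("`%s` must be a tibble with columns id, sequence (quality optional) or a character vector.", arg))
  }
  if ("quality" %in% names(reads)) {
    qn <- !is.na(reads$quality)
    if (any(nchar(reads$quality[qn]) != nchar(reads$sequence[qn]))) {
      abort("Quality strings must match sequence lengths.")
    }
  }
  reads <- as_tibble(reads)
  reads$sequence <- toupper(reads$sequence)
  check_nt(reads$sequence, allow_n = TRUE, arg = arg)
  reads
}

# leftmost start of the longest adapter substring (length >= min_match)
# occurring in `seq`; returns c(start, length) or NULL
locate_adapter <- function(seq, adapter_subs, min_match) {
  for (L in sort(unique(nchar(adapter_subs)), decreasing = TRUE)) {
    if (L < min_match || L > nchar(seq)) next
    subs <- adapter_subs[nchar(adapter_subs) == L]
    pos <- vapply(subs, function(s) {
      p <- regexpr(s, seq, fixed = TRUE)
      if (p < 0) NA_integer_ else as.integer(p)
    }, integer(1))
    if (any(!is.na(pos))) return(c(min(pos, na.rm = TRUE), L))
  }
  NULL
}

#' Trim 3' sequencing adaptors from reads
#'
#' For each read, searches for the longest substring of the adaptor occurring
#' within the read; if that substring is longer than `min_match_len - 1`
#' bases, the read is truncated at the leftmost start of the longest
#' occurrence. Reads in which no adaptor substring of at least
#' `min_match_len` bases occurs are considered to have no adaptor and are
#' returned unchanged. Truncation is applied recursively until no qualifying
#' substring remains, so trimming is idempotent.
#'
#' @param reads Tibble with columns `id`, `sequence` (and optionally
#'   `quality`, trimmed alongside), or a character vector of sequences.
#' @param adapter Adaptor sequence (DNA).
#' @param min_match_len Shortest adaptor substring accepted as evidence
#'   (default 7, i.e. "longer than 6 nt").
#' @return The reads tibble with `sequence`/`quality` trimmed and two new
#'   columns: `adapter_found` (logical) and `match_length` (length of the
#'   first, longest match; 0 when none).
#' @export
trim_adapter <- function(reads, adapter, min_match_len = 7) {
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0) {
    abort("`adapter` must be a single non-empty sequence.")
  }
  adapter <- toupper(adapter)
  check_nt(adapter, allow_n = FALSE, arg = "adapter")
  if (min_match_len < 1 || min_match_len > nchar(adapter)) {
    abort("Need 0 < min_match_len <= nchar(adapter).")
  }
  reads <- as_read_tbl(reads)
  if (any(nchar(reads$sequence) == 0)) abort("Empty read sequence.")
  n_ad <- nchar(adapter)
  adapter_subs <- unique(unlist(lapply(min_match_len:n_ad, function(L) {
    substring(adapter, seq_len(n_ad - L + 1), seq_len(n_ad - L + 1) + L - 1)
  })))

  found <- logical(nrow(reads))
  mlen <- integer(nrow(reads))
  seqs <- reads$sequence
  quals <- if ("quality" %in% names(reads)) reads$quality else NULL
  for (r in seq_len(nrow(reads))) {
    repeat {
      hit <- locate_adapter(seqs[r], adapter_subs, min_match_len)
      if (is.null(hit)) break
      if (!found[r]) mlen[r] <- hit[2]
      found[r] <- TRUE
      seqs[r] <- substr(seqs[r], 1, hit[1] - 1)
      if (!is.null(quals) && !is.na(quals[r])) {
        quals[r] <- substr(quals[r], 1, hit[1] - 1)
      }
      if (nchar(seqs[r]) == 0) break
    }
  }
  reads$sequence <- seqs
  if (!is.null(quals)) reads$quality <- quals
  reads$adapter_found <- found
  reads$match_length <- mlen
  reads
}

phred_scores <- function(quality, offset = 33) {
  lapply(quality, function(q) utf8ToInt(q) - offset)
}

#' Qualify small-RNA reads after adaptor trimming
#'
#' Keeps trimmed reads that carry adaptor evidence (when `require_adapter`),
#' contain no ambiguous base, fall within the small-RNA length window, and
#' (when qualities are present) are not low-quality. A read is low-quality
#' when more than `max_low_quality_frac` of its bases score below
#' `min_base_quality` (Phred+33). Each rejected read is tallied under its
#' first failing reason, checked in the order: low_quality, no_adapter,
#' ambiguous, too_short, too_long.
#'
#' @param reads Output of [trim_adapter()] (needs `adapter_found` when
#'   `require_adapter = TRUE`).
#' @param min_read_len,max_read_len Retained insert length window (defaults
#'   17 and 28 nt).
#' @param require_adapter Reject reads without adaptor evidence (default
#'   TRUE, the small-RNA contract; set FALSE for mRNA tags).
#' @param max_low_quality_frac,min_base_quality Low-quality rule parameters;
#'   the filter is skipped for reads without quality strings.
#' @return A list of class `read_filter`: `$kept` (tibble of qualified
#'   reads) and `$tally` (tibble `reason`, `n` partitioning the rejects).
#' @export
filter_small_rna <- function(reads, min_read_len = 17, max_read_len = 28,
                             require_adapter = TRUE,
                             max_low_quality_frac = 0.10,
                             min_base_quality = 20) {
  if (min_read_len < 1 || min_read_len > max_read_len) {
    abort("Need 0 < min_read_len <= max_read_len.")
  }
  reads <- as_read_tbl(reads)
  if (require_adapter && !"adapter_found" %in% names(reads)) {
    abort("`reads` lacks `adapter_found`; run trim_adapter() first.")
  }
  n <- nrow(reads)
  low_q <- rep(FALSE, n)
  if ("quality" %in% names(reads)) {
    has_q <- !is.na(reads$quality) & nchar(reads$quality) > 0
    if (any(has_q)) {
      frac <- vapply(phred_scores(reads$quality[has_q]),
                     function(q) mean(q < min_base_quality), numeric(1))
      low_q[has_q] <- frac > max_low_quality_frac
    }
  }
  no_ad <- if (require_adapter) !reads$adapter_found else rep(FALSE, n)
  len <- nchar(reads$sequence)
  ambig <- grepl("N", reads$sequence, fixed = TRUE)
  reason <- dplyr::case_when(low_q ~ "low_quality",
                             no_ad ~ "no_adapter",
                             ambig ~ "ambiguous",
                             len < min_read_len ~ "too_short",
                             len > max_read_len ~ "too_long",
                             TRUE ~ NA_character_)
  tally <- tibble(reason = c("low_quality", "no_adapter", "ambiguous",
                             "too_short", "too_long")) %>%
    left_join(tibble(reason = reason[!is.na(reason)]) %>%
                dplyr::count(.data$reason), by = "reason") %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(list(kept = reads[is.na(reason), , drop = FALSE], tally = tally),
            class = "read_filter")
}

#' @method tidy read_filter
#' @export
tidy.read_filter <- function(x, ...) x$tally

#' @export
print.read_filter <- function(x, ...) {
  cat(sprintf("Qualified reads: %d kept, %d rejected\n",
              nrow(x$kept), sum(x$tally$n)))
  print(x$tally)
  invisible(x)
}

#' Count qualified reads against a transcript set
#'
#' Assigns each read to the transcripts in which it occurs on the sense
#' strand within `max_mismatch` substitutions (no indels, the short-read
#' aligner `-v` contract), at desk scale. Multi-mapped reads are split
#' fractionally across their hit transcripts by default, so total assigned
#' mass equals the number of mapped reads; alternatively all hits get a full
#' count, or multi-mapped reads are discarded.
#'
#' @param reads Qualified reads (tibble with `sequence`, or character
#'   vector).
#' @param transcripts Tibble with `id`, `sequence`, or a named character
#'   vector; ids must be unique.
#' @param max_mismatch 0 or 1 substitutions allowed (default 1).
#' @param multimap One of `"fractional"`, `"all"`, `"discard"`.
#' @return A tibble `transcript_id`, `count` (one row per transcript, input
#'   order), with attributes `mapped_reads` (reads contributing counts) and
#'   `n_reads` (input reads).
#' @export
count_reads <- function(reads, transcripts, max_mismatch = 1,
                        multimap = c("fractional", "all", "discard")) {
  multimap <- match.arg(multimap)
  if (!max_mismatch %in% c(0L, 1L)) abort("`max_mismatch` must be 0 or 1.")
  tx <- as_seq_tbl(transcripts, "transcripts")
  if (nrow(tx) == 0) abort("`transcripts` must be non-empty.")
  reads <- as_read_tbl(reads)
  counts <- setNames(numeric(nrow(tx)), tx$id)
  mapped <- 0L
  if (nrow(reads) > 0) {
    subj <- Biostrings::DNAStringSet(tx$sequence)
    seq_tab <- table(reads$sequence)
    for (s in names(seq_tab)) {
      hits <- Biostrings::vcountPattern(s, subj, max.mismatch = max_mismatch,
                                        with.indels = FALSE, fixed = TRUE) > 0
      nh <- sum(hits)
      if (nh == 0) next
      mult <- as.integer(seq_tab[[s]])
      if (multimap == "discard" && nh > 1) next
      w <- if (multimap == "fractional") 1 / nh else 1
      counts[hits] <- counts[hits] + w * mult
      mapped <- mapped + mult
    }
  }
  out <- tibble(transcript_id = tx$id, count = unname(counts))
  attr(out, "mapped_reads") <- mapped
  attr(out, "n_reads") <- nrow(reads)
  out
}
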
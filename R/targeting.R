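#' Scoring configuration for plant miRNA target prediction
#'
#' Plant miRNAs recognise their mRNA targets through near-perfect antiparallel
#' complementarity. Candidate sites are scored by a penalty scheme: 0 for a
#' Watson-Crick pair, `wobble_penalty` for a G:U wobble, `mismatch_penalty`
#' for any other pair, and `indel_penalty` per unpaired (bulged) base.
#' Penalties at miRNA seed positions (`seed_start`..`seed_end`, counted from
#' the miRNA 5' end) are multiplied by `seed_multiplier`. Sites whose total
#' penalty exceeds `score_cutoff` are discarded.
#'
#' @param mismatch_penalty Penalty for a non-wobble mismatch (default 1).
#' @param indel_penalty Penalty per inserted/deleted base (default 1).
#' @param wobble_penalty Penalty for a G:U pair (default 0.5).
#' @param seed_start,seed_end 1-based seed bounds on the miRNA (defaults 2, 7).
#' @param seed_multiplier Factor applied to penalties in the seed (default 2).
#' @param score_cutoff Maximum total penalty of a reported site (default 4).
#' @param max_indels Maximum unpaired bases tolerated per site (default 2).
#' @return A list of class `target_scoring_config`.
#' @export
target_scoring_config <- function(mismatch_penalty = 1, indel_penalty = 1,
                                  wobble_penalty = 0.5, seed_start = 2,
                                  seed_end = 7, seed_multiplier = 2,
                                  score_cutoff = 4, max_indels = 2) {
  if (any(c(mismatch_penalty, indel_penalty, wobble_penalty) < 0)) {
    abort("Penalties must be non-negative.")
  }
  if (seed_start < 1 || seed_start > seed_end) {
    abort("Seed bounds require 1 <= seed_start <= seed_end.")
  }
  if (score_cutoff < 0) abort("`score_cutoff` must be non-negative.")
  if (max_indels < 0) abort("`max_indels` must be non-negative.")
  structure(list(mismatch_penalty = mismatch_penalty,
                 indel_penalty = indel_penalty,
                 wobble_penalty = wobble_penalty,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_multiplier = seed_multiplier,
                 score_cutoff = score_cutoff,
                 max_indels = as.integer(max_indels)),
            class = "target_scoring_config")
}

NT_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, U = 3L)

encode_nt <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- NT_CODE[chars]
  if (anyNA(codes)) {
    abort(sprintf("Invalid nucleotide in %s (only A/C/G/T/U allowed).",
                  substr(x, 1, 30)))
  }
  unname(codes)
}

# 4x4 base pair cost (codes A=0,C=1,G=2,T/U=3), before seed doubling
pair_cost_matrix <- function(config) {
  m <- matrix(config$mismatch_penalty, 4, 4)
  wc <- rbind(c(1, 4), c(2, 3), c(3, 2), c(4, 1))   # A:U, C:G, G:C, U:A
  m[wc] <- 0
  m[3, 4] <- config$wobble_penalty                  # G:U
  m[4, 3] <- config$wobble_penalty                  # U:G
  m
}

#' Penalty for a single miRNA:target base pair
#'
#' @param mirna_base,target_base Single bases (A/C/G/T/U); `target_base` is the
#'   transcript base the miRNA base pairs with (antiparallel).
#' @param mirna_position 1-based position on the miRNA from its 5' end; the
#'   penalty is doubled (by `seed_multiplier`) inside the seed.
#' @param config A [target_scoring_config()].
#' @return Numeric penalty (vectorised over the inputs).
#' @examples
#' pair_penalty("A", "U", 10)  # Watson-Crick: 0
#' pair_penalty("G", "U", 10)  # wobble: 0.5
#' pair_penalty("A", "C", 4)   # seed mismatch: 2
#' @export
pair_penalty <- function(mirna_base, target_base, mirna_position,
                         config = target_scoring_config()) {
  cost <- pair_cost_matrix(config)
  n <- max(length(mirna_base), length(target_base), length(mirna_position))
  mb <- rep_len(toupper(mirna_base), n)
  tb <- rep_len(toupper(target_base), n)
  pos <- rep_len(mirna_position, n)
  mi <- NT_CODE[mb]; ti <- NT_CODE[tb]
  if (anyNA(mi) || anyNA(ti)) abort("Bases must be one of A/C/G/T/U.")
  p <- cost[cbind(mi + 1L, ti + 1L)]
  in_seed <- pos >= config$seed_start & pos <= config$seed_end
  p * ifelse(in_seed, config$seed_multiplier, 1)
}

#' Align a miRNA against a candidate target window
#'
#' Computes the minimum-total-penalty global alignment of the miRNA (5' to 3')
#' against the target window taken antiparallel (miRNA position 1 pairs with
#' the window's 3'-most base), by banded dynamic programming over
#' substitutions, G:U wobbles and up to `max_indels` unpaired bases. Gap
#' penalties are seed-doubled when the gap sits at a seed position of the
#' miRNA: an unpaired miRNA base at position i is doubled iff i is in the
#' seed; an unpaired target base inserted between miRNA positions i and i+1
#' is doubled iff i+1 is in the seed.
#'
#' @param mirna miRNA sequence, 5' to 3' (T and U equivalent).
#' @param target_window Transcript subsequence, 5' to 3' on the sense strand;
#'   its length may differ from the miRNA's by at most `max_indels`.
#' @param config A [target_scoring_config()].
#' @return An object of class `site_alignment`: a list with `score` and the
#'   three display strings `mirna_3to5`, `symbols` (`|` Watson-Crick, `o`
#'   wobble, space mismatch/gap) and `target_5to3`.
#' @examples
#' align_site("UGGAGUGUGACAAUGGUGUUUG", "CAAACACCAUUGUCACACUCCA")$score  # 0
#' @export
align_site <- function(mirna, target_window, config = target_scoring_config()) {
  m <- encode_nt(mirna)
  w <- encode_nt(target_window)
  L <- length(m); W <- length(w)
  if (L < 1 || W < 1) abort("Sequences must be non-empty.")
  if (config$seed_end > L) {
    abort("miRNA shorter than the configured seed region.")
  }
  band <- config$max_indels
  if (abs(W - L) > band) {
    abort(sprintf(
      "Window length %d incompatible with miRNA length %d under max_indels = %d.",
      W, L, band))
  }
  cost <- pair_cost_matrix(config)
  mult <- config$seed_multiplier
  in_seed <- function(i) i >= config$seed_start & i <= config$seed_end
  tr <- rev(w)  # consume the window 3'->5' so pairing order matches the miRNA

  # M[[g+1]][i+1, j+1]: best penalty for miRNA[1..i] vs window[1..j] using
  # exactly g unpaired bases (so at most `max_indels` gaps in total)
  ins_mult <- function(i) if (in_seed(i + 1)) mult else 1  # gap after miRNA pos i
  M <- lapply(0:band, function(g) matrix(Inf, L + 1, W + 1))
  for (g in 0:min(W, band)) {
    M[[g + 1]][1, g + 1] <- g * config$indel_penalty * ins_mult(0L)
  }
  for (i in seq_len(L)) {
    dmult <- if (in_seed(i)) mult else 1
    del_cost <- config$indel_penalty * dmult
    ins_cost <- config$indel_penalty * ins_mult(i)
    for (g in 0:band) {
      jlo <- max(0, i - g); jhi <- min(W, i + g)
      if (jlo > jhi) next
      for (j in jlo:jhi) {
        best <- Inf
        if (j >= 1) {
          best <- M[[g + 1]][i, j] + cost[m[i] + 1L, tr[j] + 1L] * dmult
        }
        if (g >= 1) {
          best <- min(best, M[[g]][i, j + 1] + del_cost)
          if (j >= 1) best <- min(best, M[[g]][i + 1, j] + ins_cost)
        }
        M[[g + 1]][i + 1, j + 1] <- best
      }
    }
  }
  finals <- vapply(0:band, function(g) M[[g + 1]][L + 1, W + 1], numeric(1))
  gbest <- which.min(finals) - 1L
  score <- finals[gbest + 1L]

  # traceback (diagonal preferred, then miRNA-gap, then target-gap)
  am <- character(0); as_ <- character(0); at <- character(0)
  bases <- c("A", "C", "G", "U")
  i <- L; j <- W; g <- gbest
  eq <- function(a, b) is.finite(b) && isTRUE(all.equal(a, b))
  while (i > 0 || j > 0) {
    dmult <- if (in_seed(i)) mult else 1
    here <- M[[g + 1]][i + 1, j + 1]
    if (i > 0 && j > 0 &&
        eq(here, M[[g + 1]][i, j] + cost[m[i] + 1L, tr[j] + 1L] * dmult)) {
      pc <- cost[m[i] + 1L, tr[j] + 1L]
      sym <- if (pc == 0) "|" else if (pc == config$wobble_penalty &&
                                       pc != config$mismatch_penalty) "o" else " "
      am <- c(bases[m[i] + 1L], am); at <- c(bases[tr[j] + 1L], at)
      as_ <- c(sym, as_)
      i <- i - 1; j <- j - 1
    } else if (i > 0 && g >= 1 &&
               eq(here, M[[g]][i, j + 1] + config$indel_penalty * dmult)) {
      am <- c(bases[m[i] + 1L], am); at <- c("-", at); as_ <- c(" ", as_)
      i <- i - 1; g <- g - 1
    } else {
      am <- c("-", am); at <- c(bases[tr[j] + 1L], at); as_ <- c(" ", as_)
      j <- j - 1; g <- g - 1
    }
  }
  # internal order: miRNA 5'->3', window 3'->5'; flip for display
  structure(list(score = score,
                 mirna_3to5 = paste(rev(am), collapse = ""),
                 symbols = paste(rev(as_), collapse = ""),
                 target_5to3 = paste(rev(at), collapse = ""),
                 mirna = toupper(mirna),
                 target_window = toupper(target_window)),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("miRNA:target alignment (penalty ", format(x$score), ")\n", sep = "")
  cat("  target 5' ", x$target_5to3, " 3'\n", sep = "")
  cat("            ", x$symbols, "\n", sep = "")
  cat("  miRNA  3' ", x$mirna_3to5, " 5'\n", sep = "")
  invisible(x)
}

as_seq_tbl <- function(x, arg = "sequences") {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(id = names(x), sequence = unname(x))
  }
  if (!is.data.frame(x) || !all(c("id", "sequence") %in% names(x))) {
    abort(sprintf("`%s` must be a tibble with columns id, sequence or a named character vector.", arg))
  }
  if (anyDuplicated(x$id)) abort(sprintf("Duplicate ids in `%s`.", arg))
  x <- as_tibble(x[c("id", "sequence")])
  x$sequence <- normalize_nt(x$sequence, "dna")
  check_nt(x$sequence, allow_n = FALSE, arg = arg)
  x
}

#' Predict miRNA target sites across a transcript set
#'
#' Slides each miRNA over every transcript (sense strand), aligns it against
#' windows of miRNA length +/- `max_indels` at each offset, and reports the
#' penalty-minimal sites with score at or below `score_cutoff`. Overlapping
#' candidate windows are merged, keeping the best-scoring (ties: leftmost)
#' site. Coordinates are 1-based inclusive on the transcript.
#'
#' @param mirnas,transcripts Tibbles with columns `id`, `sequence` (as
#'   returned by [read_fasta()]) or named character vectors.
#' @param config A [target_scoring_config()].
#' @return A tibble with one row per retained site: `mirna_id`,
#'   `transcript_id`, `start`, `end`, `score`, and the three alignment display
#'   strings, ordered by (transcript, start, score, miRNA).
#' @export
predict_targets <- function(mirnas, transcripts,
                            config = target_scoring_config()) {
  empty <- tibble(mirna_id = character(0), transcript_id = character(0),
                  start = integer(0), end = integer(0), score = numeric(0),
                  aln_mirna = character(0), aln_symbols = character(0),
                  aln_target = character(0))
  if ((is.data.frame(mirnas) && nrow(mirnas) == 0) || length(mirnas) == 0 ||
      (is.data.frame(transcripts) && nrow(transcripts) == 0) ||
      length(transcripts) == 0) {
    warn("Empty miRNA or transcript input; no sites predicted.")
    return(empty)
  }
  mir <- as_seq_tbl(mirnas, "mirnas")
  tx <- as_seq_tbl(transcripts, "transcripts")
  lens <- nchar(mir$sequence)
  if (any(lens < 17 | lens > 26)) {
    abort("miRNA sequences must be 17-26 nt long.")
  }
  cost <- pair_cost_matrix(config)
  tx_codes <- lapply(tx$sequence, encode_nt)
  mir_codes <- lapply(mir$sequence, encode_nt)

  rows <- list()
  for (ti in seq_len(nrow(tx))) {
    for (mi in seq_len(nrow(mir))) {
      sc <- cpp_scan_transcript(mir_codes[[mi]], tx_codes[[ti]], cost,
                                config$indel_penalty, config$seed_multiplier,
                                config$seed_start, config$seed_end,
                                config$max_indels, config$score_cutoff)
      if (nrow(sc) == 0) next
      keep <- is.finite(sc[, 3]) & sc[, 3] <= config$score_cutoff
      if (!any(keep)) next
      cand <- sc[keep, , drop = FALSE]
      merged <- merge_overlapping_sites(cand, length(mir_codes[[mi]]))
      for (r in seq_len(nrow(merged))) {
        s <- merged[r, 1]; wdt <- merged[r, 2]
        aln <- align_site(mir$sequence[mi],
                          substr(tx$sequence[ti], s, s + wdt - 1), config)
        rows[[length(rows) + 1L]] <- tibble(
          mirna_id = mir$id[mi], transcript_id = tx$id[ti],
          start = as.integer(s), end = as.integer(s + wdt - 1),
          score = aln$score, aln_mirna = aln$mirna_3to5,
          aln_symbols = aln$symbols, aln_target = aln$target_5to3)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) %>%
    arrange(.data$transcript_id, .data$start, .data$score, .data$mirna_id)
}

# cand: matrix with columns start, width, score. Clusters of mutually
# overlapping windows collapse to the best-scoring window; score ties go to
# the window with the fewest unpaired bases (width closest to the miRNA
# length `L`), then to the leftmost start.
merge_overlapping_sites <- function(cand, L) {
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  better <- function(x, y) {
    if (x[3] != y[3]) return(x[3] < y[3])
    dx <- abs(x[2] - L); dy <- abs(y[2] - L)
    if (dx != dy) return(dx < dy)
    x[1] < y[1]
  }
  out <- list()
  cur_end <- cand[1, 1] + cand[1, 2] - 1
  best <- cand[1, ]
  for (r in seq_len(nrow(cand))[-1]) {
    s <- cand[r, 1]; e <- s + cand[r, 2] - 1
    if (s <= cur_end) {
      if (better(cand[r, ], best)) best <- cand[r, ]
      cur_end <- max(cur_end, e)
    } else {
      out[[length(out) + 1L]] <- best
      best <- cand[r, ]
      cur_end <- e
    }
  }
  out[[length(out) + 1L]] <- best
  do.call(rbind, out)
}

#' Pair differentially expressed miRNAs with anti-correlated targets
#'
#' A miRNA and a predicted target are anti-correlated in a comparison when
#' both are differentially expressed and in opposite directions (the expected
#' signature of miRNA-guided repression).
#'
#' @param de_mirnas,de_mrnas Data frames with `gene_id` and `status`
#'   (`up`/`down`; rows with other statuses such as `not_de` are dropped),
#'   e.g. outputs of [call_de()]. If both carry a `comparison` column the
#'   labels must agree.
#' @param sites Predicted sites from [predict_targets()] (columns `mirna_id`,
#'   `transcript_id`).
#' @param comparison Optional comparison label stored on the output.
#' @return A tibble with one row per (miRNA, target) pair: `mirna_id`,
#'   `target_id`, `comparison`, `mirna_status`, `target_status`.
#' @export
find_anticorrelated_pairs <- function(de_mirnas, de_mrnas, sites,
                                      comparison = NULL) {
  cmp_of <- function(x) if ("comparison" %in% names(x)) unique(x$comparison) else NULL
  c1 <- cmp_of(de_mirnas); c2 <- cmp_of(de_mrnas)
  if (!is.null(c1) && !is.null(c2) &&
      (length(c1) != 1 || length(c2) != 1 || !identical(c1, c2))) {
    abort("`de_mirnas` and `de_mrnas` must come from the same single comparison.")
  }
  if (is.null(comparison)) comparison <- if (!is.null(c1)) c1 else c2 %||% NA_character_
  de1 <- dplyr::filter(de_mirnas, .data$status %in% c("up", "down"))
  de2 <- dplyr::filter(de_mrnas, .data$status %in% c("up", "down"))
  check_de_set(de1, "de_mirnas"); check_de_set(de2, "de_mrnas")
  pairs <- sites %>%
    distinct(.data$mirna_id, .data$transcript_id) %>%
    dplyr::inner_join(de1 %>% select(mirna_id = "gene_id", mirna_status = "status"),
                      by = "mirna_id") %>%
    dplyr::inner_join(de2 %>% select(transcript_id = "gene_id",
                                     target_status = "status"),
                      by = "transcript_id") %>%
    filter(.data$mirna_status != .data$target_status) %>%
    mutate(comparison = comparison) %>%
    select("mirna_id", target_id = "transcript_id", "comparison",
           "mirna_status", "target_status") %>%
    arrange(.data$mirna_id, .data$target_id)
  stopifnot(all(pairs$mirna_status != pairs$target_status))
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
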
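# Independent brute-force oracles used to validate the package's optimised
# implementations. Deliberately naive; they share no code with R/.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# --- adaptor trimming: substring enumeration, longest first, leftmost ------
oracle_trim_once <- function(seq, adapter, min_match) {
  for (L in seq(nchar(adapter), min_match)) {
    if (L > nchar(seq)) next
    starts <- integer(0)
    for (a0 in seq_len(nchar(adapter) - L + 1)) {
      sub <- substr(adapter, a0, a0 + L - 1)
      p <- regexpr(sub, seq, fixed = TRUE)
      if (p > 0) starts <- c(starts, as.integer(p))
    }
    if (length(starts) > 0) {
      return(list(seq = substr(seq, 1, min(starts) - 1), match = L))
    }
  }
  NULL
}

oracle_trim <- function(seq, adapter, min_match = 7) {
  found <- FALSE
  first_match <- 0L
  repeat {
    hit <- oracle_trim_once(seq, adapter, min_match)
    if (is.null(hit)) break
    if (!found) first_match <- hit$match
    found <- TRUE
    seq <- hit$seq
    if (nchar(seq) == 0) break
  }
  list(sequence = seq, adapter_found = found, match_length = first_match)
}

# --- miRNA:window alignment: exhaustive enumeration, <= max_indels gaps ----
oracle_pair_cost <- function(mb, tb, wobble = 0.5, mismatch = 1) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (wc[[mb]] == tb) return(0)
  if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) return(wobble)
  mismatch
}

oracle_align_score <- function(mirna, window, seed_start = 2, seed_end = 7,
                               seed_mult = 2, indel = 1, wobble = 0.5,
                               mismatch = 1, max_indels = 2) {
  m <- strsplit(gsub("U", "T", toupper(mirna)), "")[[1]]
  tr <- rev(strsplit(gsub("U", "T", toupper(window)), "")[[1]])
  L <- length(m); W <- length(tr)
  best <- Inf
  in_seed <- function(i) i >= seed_start && i <= seed_end
  rec <- function(i, j, g, acc) {
    if (acc >= best) return(invisible())
    if (i > L && j > W) {
      best <<- acc
      return(invisible())
    }
    if (i <= L && j <= W) {
      pc <- oracle_pair_cost(m[i], tr[j], wobble, mismatch) *
        (if (in_seed(i)) seed_mult else 1)
      rec(i + 1, j + 1, g, acc + pc)
    }
    if (g < max_indels && i <= L) {
      rec(i + 1, j, g + 1, acc + indel * (if (in_seed(i)) seed_mult else 1))
    }
    if (g < max_indels && j <= W) {
      # unpaired target base before consuming miRNA position i
      dbl <- i <= L && in_seed(i)
      rec(i, j + 1, g + 1, acc + indel * (if (dbl) seed_mult else 1))
    }
  }
  rec(1L, 1L, 0L, 0)
  best
}

# --- hypergeometric upper tail: direct pmf summation -----------------------
oracle_hyper_upper <- function(k, m, n, M) {
  i <- k:min(m, n)
  sum(choose(n, i) * choose(M - n, m - i)) / choose(M, m)
}

# --- read counting: exhaustive occurrence scan with <= mm substitutions ----
oracle_count_hits <- function(read, transcripts, mm = 1) {
  rl <- nchar(read)
  rch <- strsplit(read, "")[[1]]
  vapply(transcripts, function(tx) {
    if (nchar(tx) < rl) return(FALSE)
    for (s in seq_len(nchar(tx) - rl + 1)) {
      wch <- strsplit(substr(tx, s, s + rl - 1), "")[[1]]
      if (sum(wch != rch) <= mm) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# --- DE-set construction used in worked-example tests ----------------------
make_de_set <- function(n_up, n_down, prefix, comparison) {
  tibble::tibble(
    gene_id = c(sprintf("%s_up_%04d", prefix, seq_len(n_up)),
                sprintf("%s_dn_%04d", prefix, seq_len(n_down))),
    status = rep(c("up", "down"), c(n_up, n_down)),
    comparison = comparison)
}
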
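ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("trim_adapter truncates at the leftmost longest adaptor match", {
  ad10 <- substr(ADAPTER, 1, 10)
  # full adaptor present -> insert recovered exactly
  r1 <- trim_adapter(c(r1 = paste0("ACGTACGT", ad10)), ad10)
  expect_equal(r1$sequence, "ACGTACGT")
  expect_true(r1$adapter_found)
  expect_equal(r1$match_length, 10L)

  # only a 6-nt substring: below the evidence threshold, read unchanged
  r2 <- trim_adapter(c(r2 = "CCCCCTGGAATCCCCC"), ADAPTER)
  expect_equal(r2$sequence, "CCCCCTGGAATCCCCC")
  expect_false(r2$adapter_found)
  expect_equal(r2$match_length, 0L)

  # quality strings are trimmed alongside the sequence
  reads <- tibble::tibble(id = "q", sequence = paste0("ACGTACGT", ad10),
                          quality = strrep("I", 18))
  r3 <- trim_adapter(reads, ad10)
  expect_equal(nchar(r3$quality), nchar(r3$sequence))

  expect_error(trim_adapter(c(x = "ACGT"), ""), "non-empty")
  expect_error(trim_adapter(c(x = "ACGT"), "ACGTAC", min_match_len = 10),
               "min_match_len")
})

test_that("trim_adapter matches the substring-enumeration oracle", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      # mix of clean reads, planted adaptors and partial adaptors
      insert <- rand_dna(sample(10:40, 1))
      seq <- switch(sample(3, 1),
                    rand_dna(50),
                    paste0(insert, ADAPTER),
                    paste0(insert, substr(ADAPTER, 1, sample(3:15, 1))))
      got <- trim_adapter(c(x = seq), ADAPTER)
      want <- oracle_trim(seq, ADAPTER)
      expect_equal(got$sequence, want$sequence, info = seq)
      expect_equal(got$adapter_found, want$adapter_found, info = seq)
      expect_equal(got$match_length, as.integer(want$match_length), info = seq)
    }
  })
})

test_that("trim_adapter is idempotent", {
  withr::with_seed(17, {
    seqs <- vapply(1:40, function(i) {
      paste0(rand_dna(sample(17:28, 1)),
             substr(ADAPTER, 1, sample(0:21, 1)))
    }, character(1))
    once <- trim_adapter(setNames(seqs, paste0("r", 1:40)), ADAPTER)
    keep <- nchar(once$sequence) > 0
    twice <- trim_adapter(once[keep, c("id", "sequence")], ADAPTER)
    expect_equal(twice$sequence, once$sequence[keep])
    expect_false(any(twice$adapter_found))
  })
})

test_that("small-RNA qualification partitions rejects by reason", {
  ad <- ADAPTER
  reads <- tibble::tibble(
    id = paste0("r", 1:6),
    sequence = c(rand_dna(21),          # ok
                 rand_dna(16),          # too short
                 rand_dna(30),          # too long
                 paste0(rand_dna(10), "N", rand_dna(10)),  # ambiguous
                 rand_dna(21),          # no adaptor evidence
                 rand_dna(21)),         # low quality
    quality = c(strrep("I", 21), strrep("I", 16), strrep("I", 30),
                strrep("I", 21), strrep("I", 21),
                paste0(strrep("#", 10), strrep("I", 11))),
    adapter_found = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  res <- filter_small_rna(reads)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$id, "r1")
  tally <- setNames(res$tally$n, res$tally$reason)
  expect_equal(unname(tally[c("too_short", "too_long", "ambiguous",
                              "no_adapter", "low_quality")]),
               c(1L, 1L, 1L, 1L, 1L))
  # kept + rejected partitions the input
  expect_equal(nrow(res$kept) + sum(res$tally$n), nrow(reads))

  # a 16-nt insert is rejected as too short; 17 nt is kept
  r16 <- tibble::tibble(id = "a", sequence = rand_dna(16),
                        adapter_found = TRUE)
  expect_equal(filter_small_rna(r16)$tally$n[
    filter_small_rna(r16)$tally$reason == "too_short"], 1L)
  r17 <- tibble::tibble(id = "a", sequence = rand_dna(17),
                        adapter_found = TRUE)
  expect_equal(nrow(filter_small_rna(r17)$kept), 1)
  # empty input -> empty output
  empty <- filter_small_rna(tibble::tibble(id = character(0),
                                           sequence = character(0),
                                           adapter_found = logical(0)))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(sum(empty$tally$n), 0)
})

test_that("qualification counts match per-read rule enumeration", {
  withr::with_seed(31, {
    sim <- simulate_reads(c(t1 = rand_dna(300), t2 = rand_dna(300)),
                          n_reads = 150, adapter = ADAPTER, seed = 8)
    trimmed <- trim_adapter(sim$reads, ADAPTER)
    res <- filter_small_rna(trimmed)
    manual <- sum(trimmed$adapter_found &
                    !grepl("N", trimmed$sequence, fixed = TRUE) &
                    nchar(trimmed$sequence) >= 17 &
                    nchar(trimmed$sequence) <= 28)
    expect_equal(nrow(res$kept), manual)
  })
})

test_that("count_reads assigns reads within one substitution, sense only", {
  withr::with_seed(53, {
    tx <- c(t1 = rand_dna(120), t2 = rand_dna(120))
    # read equal to a 21-nt substring of exactly one transcript
    read <- substr(tx[["t1"]], 40, 60)
    got <- count_reads(c(r1 = read), tx)
    expect_equal(got$count[got$transcript_id == "t1"], 1)
    expect_equal(got$count[got$transcript_id == "t2"], 0)
    expect_equal(attr(got, "mapped_reads"), 1L)

    # two substitutions anywhere -> unmapped
    ch <- strsplit(read, "")[[1]]
    for (p in c(3, 10)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    got2 <- count_reads(c(r1 = paste(ch, collapse = "")), tx)
    expect_equal(sum(got2$count), 0)
    expect_equal(attr(got2, "mapped_reads"), 0L)

    # a read occurring in both transcripts splits fractionally
    shared <- rand_dna(21)
    tx2 <- c(t1 = paste0(shared, rand_dna(50)), t2 = paste0(rand_dna(50), shared))
    got3 <- count_reads(c(r1 = shared), tx2)
    expect_equal(got3$count, c(0.5, 0.5))
    expect_equal(count_reads(c(r1 = shared), tx2, multimap = "all")$count,
                 c(1, 1))
    expect_equal(sum(count_reads(c(r1 = shared), tx2,
                                 multimap = "discard")$count), 0)

    # antisense occurrences do not count
    anti <- oracle_revcomp(substr(tx[["t2"]], 10, 30))
    expect_equal(sum(count_reads(c(r1 = anti), tx)$count), 0)
  })
  expect_error(count_reads(c(r1 = "ACGTACGTACGTACGTAA"),
                           c(a = "ACGT", a = "ACGT")),
               "Duplicate")
  expect_error(count_reads(c(r1 = "ACGT"), c(a = "ACGTACGT"),
                           max_mismatch = 2), "0 or 1")
})

test_that("fractional counting conserves mass and matches the scan oracle", {
  withr::with_seed(71, {
    tx <- setNames(vapply(1:4, function(i) rand_dna(60), character(1)),
                   paste0("t", 1:4))
    # reads drawn from transcripts (some mutated once) plus random junk
    reads <- c(
      vapply(1:25, function(i) {
        src <- sample(4, 1)
        s <- sample(1:40, 1)
        r <- substr(tx[[src]], s, s + sample(17:20, 1))
        if (runif(1) < 0.4) {
          ch <- strsplit(r, "")[[1]]
          p <- sample(length(ch), 1)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
          r <- paste(ch, collapse = "")
        }
        r
      }, character(1)),
      vapply(1:10, function(i) rand_dna(20), character(1)))
    names(reads) <- paste0("r", seq_along(reads))
    got <- count_reads(reads, tx)
    # mass conservation under fractional assignment
    expect_equal(sum(got$count), attr(got, "mapped_reads"))
    # per-read agreement with the exhaustive occurrence scan
    expected <- setNames(numeric(4), names(tx))
    mapped <- 0L
    for (r in reads) {
      hits <- oracle_count_hits(r, tx, mm = 1)
      if (any(hits)) {
        expected[hits] <- expected[hits] + 1 / sum(hits)
        mapped <- mapped + 1L
      }
    }
    expect_equal(got$count, unname(expected))
    expect_equal(attr(got, "mapped_reads"), mapped)
  })
})
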
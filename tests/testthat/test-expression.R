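toy_counts <- function() {
  tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                 NC = c(10, 5, 0, 2),
                 CA = c(40, 100, 8, 2))
}
toy_totals <- function() {
  tibble::tibble(library = c("NC", "CA"),
                 mapped_reads = c(1e6, 250000))
}

test_that("CPM is counts scaled to the per-library mapped total", {
  cpm <- compute_cpm(toy_counts(), toy_totals())
  expect_equal(cpm$cpm[cpm$gene_id == "g1" & cpm$library == "NC"], 10)
  expect_equal(cpm$cpm[cpm$gene_id == "g2" & cpm$library == "CA"], 400)
  # 5 reads in 250k mapped -> CPM 20
  expect_equal(cpm$cpm[cpm$gene_id == "g2" & cpm$library == "NC"], 5)
  expect_equal(cpm$cpm[cpm$gene_id == "g1" & cpm$library == "CA"], 160)
  # column identity: sum of CPM = 1e6 * column sum / total
  withr::with_seed(5, {
    counts <- tibble::tibble(gene_id = sprintf("g%03d", 1:50),
                             L1 = rpois(50, 40), L2 = rpois(50, 400))
    totals <- tibble::tibble(library = c("L1", "L2"),
                             mapped_reads = c(3e5, 2e6))
    cpm2 <- compute_cpm(counts, totals)
    for (lib in c("L1", "L2")) {
      tot <- totals$mapped_reads[totals$library == lib]
      expect_equal(sum(cpm2$cpm[cpm2$library == lib]),
                   1e6 * sum(counts[[lib]]) / tot)
    }
  })
  expect_error(compute_cpm(toy_counts(),
                           tibble::tibble(library = "NC", mapped_reads = 1e6)),
               "missing")
  expect_error(compute_cpm(toy_counts(),
                           tibble::tibble(library = c("NC", "CA"),
                                          mapped_reads = c(0, 1))),
               "positive")
})

test_that("the expressed threshold is inclusive at CPM 10", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           L = c(10.0, 9.99, 0))
  totals <- tibble::tibble(library = "L", mapped_reads = 1e6)
  prof <- expression_profile(counts, totals)
  expect_true(prof$expressed[prof$gene_id == "a"])
  expect_false(prof$expressed[prof$gene_id == "b"])
  # non-expressed entries have effective expression 0
  expect_equal(prof$effective_expression[prof$gene_id == "b"], 0)
  expect_gt(prof$effective_expression[prof$gene_id == "a"], 0)
})

test_that("upper-quartile factors use the nonzero counts, interpolated", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e"),
                           L1 = c(2, 4, 8, 100, 0),
                           L2 = c(2, 4, 8, 100, 0))
  totals <- tibble::tibble(library = c("L1", "L2"),
                           mapped_reads = c(1e6, 1e6))
  prof <- expression_profile(counts, totals)
  uq <- attr(prof, "uq_factors")
  # type-7 quantile of (2, 4, 8, 100) at p = 0.75: 8 + 0.25 * 92 = 31
  expect_equal(uq$uq_factor, c(31, 31))
  # identical libraries: normalized equals raw
  expect_equal(prof$normalized, prof$count)

  # scaling one library leaves its pre-rescale quotients, and all DE calls,
  # unchanged
  counts3 <- dplyr::mutate(counts, L2 = L2 * 3)
  totals3 <- dplyr::mutate(totals,
                           mapped_reads = ifelse(library == "L2", 3e6, 1e6))
  prof3 <- expression_profile(counts3, totals3)
  uq3 <- attr(prof3, "uq_factors")
  expect_equal(uq3$uq_factor[uq3$library == "L2"], 93)
  q  <- prof$normalized / attr(prof, "uq_factors")$uq_factor[1]
  expect_equal(call_de(prof3, c("L1", "L2"))$status,
               call_de(prof, c("L1", "L2"))$status)
  expect_error(
    expression_profile(tibble::tibble(gene_id = "a", L1 = 0),
                       tibble::tibble(library = "L1", mapped_reads = 1e6)),
    "all-zero")
})

test_that("DE criteria fire exactly as specified", {
  # engineer CPMs directly: depth 1e6 makes counts == CPM, and mirrored
  # gene pairs give both libraries the same count multiset, so the UQ
  # factors are equal and normalized counts equal raw counts
  counts <- tibble::tibble(
    gene_id = c("fold4", "fold39", "onoff", "nearmiss", "bothoff",
                paste0("mirror", 1:5)),
    A = c(100, 100, 9,  9,  3, 400, 390, 41, 39, 9),
    B = c(400, 390, 41, 39, 9, 100, 100, 9,  9,  3))
  totals <- tibble::tibble(library = c("A", "B"), mapped_reads = c(1e6, 1e6))
  prof <- expression_profile(counts, totals)
  de <- call_de(prof, c("B", "A"))
  get <- function(g) de[de$gene_id == g, ]

  # ratio exactly 4.0 is DE by the fold criterion ("no less than 4 folds")
  expect_equal(get("fold4")$status, "up")
  expect_equal(get("fold4")$criterion, "fold")
  expect_equal(get("fold4")$fold_change, 4)
  # 3.9-fold expressed in both: not DE
  expect_equal(get("fold39")$status, "not_de")
  # CPM 9 vs 41: on/off criterion, up in the 41 condition (B first here)
  expect_equal(get("onoff")$status, "up")
  expect_equal(get("onoff")$criterion, "on_off")
  # CPM 9 vs 39: neither criterion
  expect_equal(get("nearmiss")$status, "not_de")
  expect_equal(get("nearmiss")$criterion, "none")
  # expressed in neither condition: never DE, whatever the noise ratio
  expect_equal(get("bothoff")$status, "not_de")

  # antisymmetry: swapping the comparison flips up/down, keeps criterion
  rev <- call_de(prof, c("A", "B"))
  flip <- c(up = "down", down = "up", not_de = "not_de")
  expect_equal(unname(flip[de$status]), rev$status)
  expect_equal(de$criterion, rev$criterion)
  expect_error(call_de(prof, c("A", "Z")), "Unknown")
})

test_that("DE calls never conflict in direction on random tables", {
  withr::with_seed(21, {
    counts <- tibble::tibble(gene_id = sprintf("g%04d", 1:300),
                             X = rnbinom(300, mu = 60, size = 2),
                             Y = rnbinom(300, mu = 60, size = 2))
    totals <- tibble::tibble(library = c("X", "Y"),
                             mapped_reads = c(1.2e6, 0.9e6))
    de <- call_de(expression_profile(counts, totals), c("X", "Y"))
    expect_true(all(de$status %in% c("up", "down", "not_de")))
    expect_true(all((de$status == "not_de") == (de$criterion == "none")))
    # fold criterion implies expressed in both -> on_off cannot also fire
    expect_false(any(de$criterion == "fold" &
                       de$fold_change < 4 & de$fold_change > 1 / 4,
                     na.rm = TRUE))
  })
})

test_that("qPCR relative expression follows 2^-ddCT with the NTC rule", {
  rec <- tibble::tibble(ct_target_sample = c(20, 21, 35),
                        ct_reference_sample = c(18, 18, 18),
                        ct_target_control = c(22, 21, 22),
                        ct_reference_control = c(20, 19, 20),
                        ct_ntc = c(NA, NA, 34))
  out <- qpcr_relative_expression(rec)
  expect_equal(out$relative_expression[1], 1)     # ddCT = 0
  expect_equal(out$relative_expression[2], 0.5)   # ddCT = 1
  expect_false(out$detected[3])                   # CT >= NTC
  expect_true(is.na(out$relative_expression[3]))
  expect_error(qpcr_relative_expression(dplyr::mutate(rec,
                                                      ct_target_sample = -1)),
               "positive")
})
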
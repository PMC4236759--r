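# DE-set sizes printed for the CA/NC vs CS/NC comparison: 2,855 and 3,297
# DE genes; 1,041 common up, 1,134 common down, none opposite. The CS
# direction split (1,703 up / 1,594 down) follows from the direction-wise
# union denominators (2,169 up, 1,808 down).
paper_ca_cs_sets <- function() {
  up_common <- sprintf("uc_%04d", 1:1041)
  dn_common <- sprintf("dc_%04d", 1:1134)
  ca <- tibble::tibble(
    gene_id = c(up_common, sprintf("cau_%04d", 1:466),
                dn_common, sprintf("cad_%04d", 1:214)),
    status = rep(c("up", "down"), c(1507, 1348)),
    comparison = "CA/NC")
  cs <- tibble::tibble(
    gene_id = c(up_common, sprintf("csu_%04d", 1:662),
                dn_common, sprintf("csd_%04d", 1:460)),
    status = rep(c("up", "down"), c(1703, 1594)),
    comparison = "CS/NC")
  list(ca = ca, cs = cs)
}

test_that("overlap partition reproduces the CA/CS worked example", {
  sets <- paper_ca_cs_sets()
  ov <- overlap_partition(sets$ca, sets$cs)
  g <- glance(ov)
  expect_equal(g$n_first, 2855)
  expect_equal(g$n_second, 3297)
  expect_equal(g$n_common, 2175)
  expect_equal(g$n_opposite, 0)
  expect_equal(round_half_up(g$pct_common_of_first, 1), 76.2)
  expect_equal(round_half_up(g$pct_common_of_second, 1), 66.0)
  expect_equal(round_half_up(g$pct_common_down_of_union, 2), 62.72)
  expect_equal(round_half_up(g$pct_common_up_of_union, 2), 47.99)
})

test_that("overlap partition handles disjoint and mirrored inputs", {
  a <- tibble::tibble(gene_id = c("a1", "a2"), status = c("up", "down"))
  b <- tibble::tibble(gene_id = c("b1", "b2"), status = c("up", "down"))
  ov <- overlap_partition(a, b)
  expect_equal(glance(ov)$n_common, 0)
  counts <- setNames(tidy(ov)$n, tidy(ov)$category)
  expect_equal(unname(counts[c("first_specific", "second_specific")]),
               c(2L, 2L))

  # mirror image under argument swap
  sets <- paper_ca_cs_sets()
  f <- glance(overlap_partition(sets$ca, sets$cs))
  r <- glance(overlap_partition(sets$cs, sets$ca))
  expect_equal(f$n_common, r$n_common)
  expect_equal(f$pct_common_of_first, r$pct_common_of_second)
  expect_equal(f$pct_specific_of_first, r$pct_specific_of_second)

  bad <- tibble::tibble(gene_id = c("x", "x"), status = c("up", "down"))
  expect_error(overlap_partition(bad, a), "both up and down")
})

test_that("overlap partition agrees with direct set algebra on random sets", {
  withr::with_seed(13, {
    pool <- sprintf("g%03d", 1:80)
    for (rep in 1:20) {
      mk <- function() {
        ids <- sample(pool, sample(10:40, 1))
        tibble::tibble(gene_id = ids,
                       status = sample(c("up", "down"), length(ids),
                                       replace = TRUE))
      }
      a <- mk(); b <- mk()
      ov <- tidy(overlap_partition(a, b))
      n <- setNames(ov$n, ov$category)
      au <- a$gene_id[a$status == "up"]; ad <- a$gene_id[a$status == "down"]
      bu <- b$gene_id[b$status == "up"]; bd <- b$gene_id[b$status == "down"]
      expect_equal(n[["common_up"]], length(intersect(au, bu)))
      expect_equal(n[["common_down"]], length(intersect(ad, bd)))
      expect_equal(n[["common_opposite"]],
                   length(union(intersect(au, bd), intersect(ad, bu))))
      expect_equal(n[["first_specific"]],
                   length(setdiff(union(au, ad), union(bu, bd))))
      # partition identity: categories seen from A sum to |A|
      expect_equal(n[["common_up"]] + n[["common_down"]] +
                     n[["common_opposite"]] + n[["first_specific"]],
                   nrow(a))
    }
  })
})

test_that("the CCA/CS comparison needs the opposite-direction category", {
  # 1,082 and 3,297 DE genes; 446 common same-direction, 11 opposite,
  # 625 and 2,840 condition-specific
  cca <- tibble::tibble(
    gene_id = c(sprintf("c_%04d", 1:446), sprintf("o_%02d", 1:11),
                sprintf("ccas_%04d", 1:625)),
    status = c(rep("up", 200), rep("down", 246), rep("up", 11),
               rep(c("up", "down"), c(300, 325))),
    comparison = "CCA/NC")
  cs <- tibble::tibble(
    gene_id = c(sprintf("c_%04d", 1:446), sprintf("o_%02d", 1:11),
                sprintf("css_%04d", 1:2840)),
    status = c(rep("up", 200), rep("down", 246), rep("down", 11),
               rep(c("up", "down"), c(1400, 1440))),
    comparison = "CS/NC")
  g <- glance(overlap_partition(cca, cs))
  expect_equal(g$n_first, 1082)
  expect_equal(g$n_second, 3297)
  expect_equal(g$n_common, 446)
  expect_equal(g$n_opposite, 11)
  expect_equal(round_half_up(g$pct_specific_of_first, 1), 57.8)
  expect_equal(round_half_up(g$pct_specific_of_second, 1), 86.1)
})

test_that("trajectory classes cover the universe exactly once", {
  first <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                          status = c("up", "up", "down", "down"),
                          comparison = "CA/NC")
  second <- tibble::tibble(gene_id = c("g1", "g2", "g5"),
                           status = c("down", "up", "up"),
                           comparison = "CCA/CA")
  calls <- classify_trajectory(first, second,
                               universe = c(paste0("g", 1:5), "g6"))
  cls <- setNames(calls$class, calls$gene_id)
  expect_equal(unname(cls[paste0("g", 1:6)]),
               c("reversed", "continued", "first_only", "first_only",
                 "second_only", "none"))
  expect_equal(sum(table(calls$class)), 6)

  # default universe is the union of DE genes
  expect_equal(sort(classify_trajectory(first, second)$gene_id),
               sort(paste0("g", 1:5)))
})

test_that("reversal summary reproduces the printed trajectory percentages", {
  # CA/NC: 1,507 up of which 1,160 reverse and 3 continue; 1,348 down of
  # which 641 reverse and 1 continues
  first <- tibble::tibble(
    gene_id = sprintf("g_%04d", 1:2855),
    status = rep(c("up", "down"), c(1507, 1348)),
    comparison = "CA/NC")
  second_status <- c(rep("down", 1160), rep("up", 3),
                     rep(NA, 1507 - 1163),
                     rep("up", 641), rep("down", 1),
                     rep(NA, 1348 - 642))
  second <- dplyr::filter(
    tibble::tibble(gene_id = first$gene_id, status = second_status,
                   comparison = "CCA/CA"),
    !is.na(status))
  rs <- reversal_summary(classify_trajectory(first, second))
  up <- rs[rs$first_status == "up", ]
  dn <- rs[rs$first_status == "down", ]
  expect_equal(up$n_first, 1507)
  expect_equal(up$n_reversed, 1160)
  expect_equal(round_half_up(up$pct_reversed, 1), 77.0)
  expect_equal(dn$n_reversed, 641)
  expect_equal(round_half_up(dn$pct_reversed, 1), 47.6)
  expect_equal(up$n_continued + dn$n_continued, 4L)
  g <- glance(rs)
  expect_equal(g$n_reversed, 1801)
  # identity: reversed + continued + dropped = first-comparison count
  expect_equal(up$n_reversed + up$n_continued + up$n_dropped, up$n_first)

  # no DE genes in the second comparison -> zero reversal
  none <- tibble::tibble(gene_id = character(0), status = character(0))
  rs0 <- reversal_summary(classify_trajectory(first, none))
  expect_equal(sum(rs0$n_reversed), 0)
  expect_equal(glance(rs0)$pct_reversed, 0)
})

test_that("reversed miRNAs link only to reversed predicted targets", {
  target_map <- tibble::tibble(mirna_id = c("m1", "m1", "m2", "m3"),
                               transcript_id = c("g1", "g2", "g3", "g9"))
  pairs <- intersect_de_with_targets(
    reversed_mrnas = c("g1", "g3"),
    reversed_mirnas = c("m1", "m3"),
    target_map = target_map)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$mirna_id, "m1")
  expect_equal(pairs$target_id, "g1")
  # empty map -> empty result
  expect_equal(nrow(intersect_de_with_targets(
    c("g1"), c("m1"),
    tibble::tibble(mirna_id = character(0),
                   transcript_id = character(0)))), 0)
})
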
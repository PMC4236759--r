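as_de_set <- function(x, arg = "de_set") {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame.", arg))
  if ("status" %in% names(x)) x <- x[x$status %in% c("up", "down"), ]
  check_de_set(x, arg)
  as_tibble(x[c("gene_id", "status")])
}

de_set_label <- function(x, default) {
  if (is.data.frame(x) && "comparison" %in% names(x) &&
      length(unique(x$comparison)) == 1) unique(x$comparison) else default
}

#' Partition two DE gene sets by direction-aware overlap
#'
#' Compares the up/down-regulated gene sets of two condition contrasts
#' (e.g. CA/NC vs CS/NC) and partitions their union into: common up, common
#' down, common-but-opposite direction, and genes specific to either
#' contrast. Derived percentages cover both the share of each contrast that
#' is common (or specific) and the direction-wise union overlap.
#'
#' @param a,b DE call tables (outputs of [call_de()], or any data frame with
#'   `gene_id` and `status`; rows with `status` other than up/down are
#'   ignored).
#' @return An object of class `overlap_summary`; see [tidy.overlap_summary()]
#'   and [glance.overlap_summary()] for tabular views.
#' @export
overlap_partition <- function(a, b) {
  label_a <- de_set_label(a, "A"); label_b <- de_set_label(b, "B")
  a <- as_de_set(a, "a"); b <- as_de_set(b, "b")
  up_a <- a$gene_id[a$status == "up"]; down_a <- a$gene_id[a$status == "down"]
  up_b <- b$gene_id[b$status == "up"]; down_b <- b$gene_id[b$status == "down"]

  common_up <- intersect(up_a, up_b)
  common_down <- intersect(down_a, down_b)
  opposite <- union(intersect(up_a, down_b), intersect(down_a, up_b))
  in_b <- union(up_b, down_b); in_a <- union(up_a, down_a)
  a_specific <- setdiff(in_a, in_b)
  b_specific <- setdiff(in_b, in_a)

  n_a <- length(in_a); n_b <- length(in_b)
  n_common <- length(common_up) + length(common_down)
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  structure(list(
    labels = c(label_a, label_b),
    counts = tibble(
      category = c("common_up", "common_down", "common_opposite",
                   "first_specific", "second_specific"),
      n = c(length(common_up), length(common_down), length(opposite),
            length(a_specific), length(b_specific))),
    genes = list(common_up = common_up, common_down = common_down,
                 common_opposite = opposite, first_specific = a_specific,
                 second_specific = b_specific),
    n_first = n_a, n_second = n_b, n_common = n_common,
    pct_common_of_first = pct(n_common, n_a),
    pct_common_of_second = pct(n_common, n_b),
    pct_specific_of_first = pct(length(a_specific), n_a),
    pct_specific_of_second = pct(length(b_specific), n_b),
    pct_common_up_of_union = pct(length(common_up), length(union(up_a, up_b))),
    pct_common_down_of_union = pct(length(common_down),
                                   length(union(down_a, down_b)))),
    class = "overlap_summary")
}

#' @rdname overlap_partition
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) {
  x$counts %>%
    mutate(pct_of_first = ifelse(x$n_first > 0, 100 * .data$n / x$n_first, NA_real_),
           pct_of_second = ifelse(x$n_second > 0, 100 * .data$n / x$n_second, NA_real_))
}

#' @rdname overlap_partition
#' @method glance overlap_summary
#' @export
glance.overlap_summary <- function(x, ...) {
  tibble(first = x$labels[1], second = x$labels[2],
         n_first = x$n_first, n_second = x$n_second, n_common = x$n_common,
         n_opposite = x$counts$n[x$counts$category == "common_opposite"],
         pct_common_of_first = x$pct_common_of_first,
         pct_common_of_second = x$pct_common_of_second,
         pct_specific_of_first = x$pct_specific_of_first,
         pct_specific_of_second = x$pct_specific_of_second,
         pct_common_up_of_union = x$pct_common_up_of_union,
         pct_common_down_of_union = x$pct_common_down_of_union)
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("DE set overlap: %s (n = %d) vs %s (n = %d)\n",
              x$labels[1], x$n_first, x$labels[2], x$n_second))
  cat(sprintf("  common same-direction: %d (%.1f%% of %s, %.1f%% of %s)\n",
              x$n_common, round_half_up(x$pct_common_of_first),
              x$labels[1], round_half_up(x$pct_common_of_second), x$labels[2]))
  print(tidy(x))
  invisible(x)
}

#' Classify per-gene expression trajectories across two successive contrasts
#'
#' Given DE calls for a first contrast (e.g. CA/NC) and a second contrast
#' taken relative to the first's endpoint (e.g. CCA/CA), each gene is
#' classified as `reversed` (DE in both, opposite directions), `continued`
#' (DE in both, same direction), `first_only`, `second_only`, or `none`.
#'
#' @param first,second DE call tables (see [overlap_partition()] for accepted
#'   forms).
#' @param universe Optional gene ids to classify; defaults to the union of DE
#'   genes of the two contrasts.
#' @return A tibble of class `trajectory_calls`: `gene_id`, `first_status`,
#'   `second_status`, `class`.
#' @export
classify_trajectory <- function(first, second, universe = NULL) {
  labels <- c(de_set_label(first, "first"), de_set_label(second, "second"))
  f <- as_de_set(first, "first"); s <- as_de_set(second, "second")
  if (is.null(universe)) universe <- union(f$gene_id, s$gene_id)
  out <- tibble(gene_id = universe) %>%
    left_join(rename(f, first_status = "status"), by = "gene_id") %>%
    left_join(rename(s, second_status = "status"), by = "gene_id") %>%
    mutate(class = case_when(
      !is.na(.data$first_status) & !is.na(.data$second_status) &
        .data$first_status != .data$second_status ~ "reversed",
      !is.na(.data$first_status) & !is.na(.data$second_status) ~ "continued",
      !is.na(.data$first_status) ~ "first_only",
      !is.na(.data$second_status) ~ "second_only",
      TRUE ~ "none"))
  attr(out, "comparisons") <- labels
  class(out) <- c("trajectory_calls", class(out))
  out
}

#' Summarise expression reversal between two successive contrasts
#'
#' For each direction of the first contrast, counts how many genes reversed
#' direction in the second contrast, continued in the same direction, or
#' dropped out of the DE set, with the corresponding percentages.
#'
#' @param calls Output of [classify_trajectory()].
#' @return A tibble of class `reversal_summary` with one row per
#'   first-contrast direction: `first_status`, `n_first`, `n_reversed`,
#'   `pct_reversed`, `n_continued`, `pct_continued`, `n_dropped`,
#'   `pct_dropped`. Overall totals are available via [glance()].
#' @export
reversal_summary <- function(calls) {
  de_first <- calls[!is.na(calls$first_status), ]
  out <- de_first %>%
    group_by(first_status = .data$first_status) %>%
    summarise(n_first = dplyr::n(),
              n_reversed = sum(.data$class == "reversed"),
              n_continued = sum(.data$class == "continued"),
              n_dropped = sum(.data$class == "first_only"),
              .groups = "drop") %>%
    mutate(pct_reversed = 100 * .data$n_reversed / .data$n_first,
           pct_continued = 100 * .data$n_continued / .data$n_first,
           pct_dropped = 100 * .data$n_dropped / .data$n_first) %>%
    select("first_status", "n_first", "n_reversed", "pct_reversed",
           "n_continued", "pct_continued", "n_dropped", "pct_dropped") %>%
    arrange(dplyr::desc(.data$first_status))
  attr(out, "comparisons") <- attr(calls, "comparisons")
  class(out) <- c("reversal_summary", class(out))
  out
}

#' @method glance reversal_summary
#' @export
glance.reversal_summary <- function(x, ...) {
  n_first <- sum(x$n_first); n_rev <- sum(x$n_reversed)
  tibble(n_de_first = n_first, n_reversed = n_rev,
         n_continued = sum(x$n_continued), n_dropped = sum(x$n_dropped),
         pct_reversed = ifelse(n_first > 0, 100 * n_rev / n_first, NA_real_))
}

#' Link reversed miRNAs to their reversed predicted targets
#'
#' Restricts a miRNA-to-target map to pairs in which both the miRNA and the
#' target mRNA belong to the reversed trajectory class, connecting the
#' microRNAome reversal to the transcriptome reversal.
#'
#' @param reversed_mrnas,reversed_mirnas Character vectors of ids (or data
#'   frames with a `gene_id` column, e.g. filtered [classify_trajectory()]
#'   output).
#' @param target_map Data frame with `mirna_id` and a target id column
#'   (`transcript_id` or `target_id`), e.g. [predict_targets()] output.
#' @return A tibble with one row per linked pair: `mirna_id`, `target_id`.
#' @export
intersect_de_with_targets <- function(reversed_mrnas, reversed_mirnas,
                                      target_map) {
  ids <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  tcol <- intersect(c("target_id", "transcript_id"), names(target_map))[1]
  if (is.na(tcol) || !"mirna_id" %in% names(target_map)) {
    abort("`target_map` needs columns `mirna_id` and `transcript_id`/`target_id`.")
  }
  target_map %>%
    select("mirna_id", target_id = dplyr::all_of(tcol)) %>%
    distinct() %>%
    filter(.data$mirna_id %in% ids(reversed_mirnas),
           .data$target_id %in% ids(reversed_mrnas)) %>%
    arrange(.data$mirna_id, .data$target_id)
}
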
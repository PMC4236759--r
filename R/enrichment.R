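#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X is the number of term-annotated genes in a random draw
#' of m genes from a universe of M genes of which n carry the term - the
#' over-representation p-value of one-sided Fisher's exact testing. Computed
#' via `stats::phyper` (log-space stable).
#'
#' @param k Observed overlap count(s).
#' @param m Size of the selected gene set.
#' @param n Number of universe genes annotated with the term.
#' @param M Universe size.
#' @return P(X >= k), vectorised over the inputs.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, m, n, M) {
  len <- max(length(k), length(m), length(n), length(M))
  k <- rep_len(k, len); m <- rep_len(m, len)
  n <- rep_len(n, len); M <- rep_len(M, len)
  if (any(k < 0 | n > M | m > M | k > pmin(m, n))) {
    abort("Need 0 <= k <= min(m, n) and m, n <= M.")
  }
  phyper(k - 1, n, M - n, m, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement; a thin validated
#' wrapper around `stats::p.adjust(method = "BH")` that preserves input
#' order.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' GO term over-representation test
#'
#' Tests every annotation term for over-representation in a gene set using
#' the hypergeometric upper tail, then applies Benjamini-Hochberg FDR across
#' all tested terms. The annotation is treated as a flat term-to-gene map
#' (no GO-graph ancestor propagation).
#'
#' @param gene_set Character vector of selected gene ids; ids outside the
#'   universe are dropped with a warning.
#' @param annotation Data frame with columns `gene_id`, `term` (one pair per
#'   row).
#' @param universe Character vector of all assayable gene ids; defaults to
#'   the annotated genes.
#' @param min_term_size Smallest annotated-gene count (within the universe)
#'   for a term to be tested (default 2).
#' @return A tibble of class `go_enrichment`, one row per tested term with
#'   k >= 1, sorted by p: `term`, `k`, `m`, `n`, `M`, `p`, `fdr`.
#' @export
enrich <- function(gene_set, annotation, universe = NULL, min_term_size = 2) {
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "term") %in% names(annotation))) {
    abort("`annotation` must have columns `gene_id` and `term`.")
  }
  annotation <- distinct(annotation, .data$gene_id, .data$term)
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  universe <- unique(as.character(universe))
  stray <- setdiff(annotation$gene_id, universe)
  if (length(stray) > 0) {
    annotation <- annotation[annotation$gene_id %in% universe, ]
  }
  gene_set <- unique(as.character(gene_set))
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d gene(s) outside the universe dropped from the gene set.",
                 length(outside)))
    gene_set <- setdiff(gene_set, outside)
  }
  if (length(gene_set) == 0) abort("Empty gene set after universe filtering.")

  M <- length(universe)
  m <- length(gene_set)
  per_term <- annotation %>%
    group_by(term = .data$term) %>%
    summarise(n = dplyr::n(),
              k = sum(.data$gene_id %in% gene_set), .groups = "drop") %>%
    filter(.data$n >= min_term_size, .data$k >= 1)
  if (nrow(per_term) == 0) {
    out <- tibble(term = character(0), k = integer(0), m = integer(0),
                  n = integer(0), M = integer(0), p = numeric(0),
                  fdr = numeric(0))
  } else {
    out <- per_term %>%
      mutate(m = m, M = M,
             p = hypergeom_upper_tail(.data$k, m, .data$n, M)) %>%
      mutate(fdr = bh_adjust(.data$p)) %>%
      select("term", "k", "m", "n", "M", "p", "fdr") %>%
      arrange(.data$p, .data$term)
  }
  class(out) <- c("go_enrichment", class(out))
  out
}

#' @method glance go_enrichment
#' @export
glance.go_enrichment <- function(x, ...) {
  tibble(n_terms_tested = nrow(x),
         n_fdr_05 = sum(x$fdr <= 0.05),
         min_p = if (nrow(x)) min(x$p) else NA_real_,
         universe_size = if (nrow(x)) x$M[1] else NA_integer_,
         gene_set_size = if (nrow(x)) x$m[1] else NA_integer_)
}
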
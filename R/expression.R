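#' Thresholds for expressed-gene and differential-expression calling
#'
#' Expression calling on tag counts uses three rule thresholds: a gene is
#' expressed in a library when its CPM (counts per million mapped reads) is
#' at least `cpm_expressed_min`; a gene is differentially expressed between
#' two conditions when either (1) both conditions express it and the ratio of
#' upper-quartile-normalized counts is at least `fold_threshold`, or (2) it
#' is not expressed (CPM below `cpm_expressed_min`) in one condition and
#' over-expressed (CPM above `cpm_overexpressed_min`) in the other.
#'
#' @param cpm_expressed_min Minimum CPM to call a gene expressed (default 10,
#'   inclusive).
#' @param cpm_overexpressed_min CPM above which a gene counts as
#'   over-expressed for the on/off criterion (default 40, exclusive).
#' @param fold_threshold Minimum normalized-count fold change (default 4,
#'   inclusive).
#' @return A list of class `de_config`.
#' @export
de_config <- function(cpm_expressed_min = 10, cpm_overexpressed_min = 40,
                      fold_threshold = 4) {
  if (!(cpm_expressed_min > 0 && cpm_expressed_min < cpm_overexpressed_min)) {
    abort("Need 0 < cpm_expressed_min < cpm_overexpressed_min.")
  }
  if (fold_threshold <= 1) abort("`fold_threshold` must exceed 1.")
  structure(list(cpm_expressed_min = cpm_expressed_min,
                 cpm_overexpressed_min = cpm_overexpressed_min,
                 fold_threshold = fold_threshold),
            class = "de_config")
}

check_count_table <- function(counts, totals) {
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `gene_id` column plus one column per library.")
  }
  libs <- setdiff(names(counts), "gene_id")
  if (length(libs) == 0) abort("`counts` has no library columns.")
  if (!is.data.frame(totals) ||
      !all(c("library", "mapped_reads") %in% names(totals))) {
    abort("`totals` must be a data frame with columns `library` and `mapped_reads`.")
  }
  missing <- setdiff(libs, totals$library)
  if (length(missing) > 0) {
    abort(sprintf("Libraries missing from `totals`: %s",
                  paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(counts[libs])
  if (any(is.na(vals)) || any(vals < 0)) {
    abort("Counts must be non-negative and non-missing.")
  }
  if (any(totals$mapped_reads[totals$library %in% libs] <= 0)) {
    abort("Mapped-read totals must be positive.")
  }
  if (anyDuplicated(counts$gene_id)) abort("Duplicate gene ids in `counts`.")
  libs
}

#' Counts per million mapped reads
#'
#' `cpm(g, lib) = count(g, lib) / mapped_reads(lib) * 1e6`. The denominator
#' is each library's total mapped reads (which may exceed the column sum,
#' since reads can map outside annotated genes).
#'
#' @param counts Wide count table: a `gene_id` column plus one numeric column
#'   per library (raw counts; fractional values from multi-mapped reads are
#'   allowed).
#' @param totals Tibble with columns `library`, `mapped_reads`.
#' @return A long tibble: `gene_id`, `library`, `count`, `cpm`.
#' @export
compute_cpm <- function(counts, totals) {
  libs <- check_count_table(counts, totals)
  long <- tidyr::pivot_longer(counts, dplyr::all_of(libs),
                              names_to = "library", values_to = "count")
  long %>%
    left_join(totals[c("library", "mapped_reads")], by = "library") %>%
    mutate(cpm = .data$count / .data$mapped_reads * 1e6) %>%
    select("gene_id", "library", "count", "cpm")
}

#' Flag expressed genes
#'
#' A gene is expressed in a library when its CPM is not less than
#' `cpm_expressed_min`; counts below that are treated as alignment noise and
#' the gene's effective expression is set to 0 downstream.
#'
#' @param profile Long tibble with a `cpm` column (from [compute_cpm()]).
#' @param config A [de_config()].
#' @return `profile` with a logical `expressed` column added.
#' @export
flag_expressed <- function(profile, config = de_config()) {
  mutate(profile, expressed = .data$cpm >= config$cpm_expressed_min)
}

#' Upper-quartile normalization of raw counts
#'
#' Each library is scaled by the 75th percentile of its nonzero gene counts
#' (linear-interpolation quantile); the quotients are then multiplied by the
#' geometric mean of the per-library factors so normalized values stay on a
#' count-like scale. Any positive rescaling constant yields identical
#' fold-change DE calls; the geometric mean merely keeps numbers readable.
#'
#' @param profile Long tibble with `gene_id`, `library`, `count` columns.
#' @return `profile` with a `normalized` column; the per-library factors are
#'   stored in the `uq_factors` attribute (tibble `library`, `uq_factor`).
#' @export
upper_quartile_normalize <- function(profile) {
  factors <- profile %>%
    filter(.data$count > 0) %>%
    group_by(.data$library) %>%
    summarise(uq_factor = quantile(.data$count, 0.75, names = FALSE, type = 7),
              .groups = "drop")
  all_libs <- unique(profile$library)
  if (!all(all_libs %in% factors$library)) {
    abort(sprintf("Library with all-zero counts cannot be normalized: %s",
                  paste(setdiff(all_libs, factors$library), collapse = ", ")))
  }
  gm <- geometric_mean(factors$uq_factor)
  out <- profile %>%
    left_join(factors, by = "library") %>%
    mutate(normalized = .data$count / .data$uq_factor * gm) %>%
    select(-"uq_factor")
  attr(out, "uq_factors") <- factors
  out
}

#' Build a full expression profile from a count table
#'
#' Convenience wrapper chaining [compute_cpm()], [flag_expressed()] and
#' [upper_quartile_normalize()], adding `effective_expression` (the
#' normalized count, or 0 where the gene is not expressed).
#'
#' @inheritParams compute_cpm
#' @param config A [de_config()].
#' @return A long tibble of class `expression_profile` with columns
#'   `gene_id`, `library`, `count`, `cpm`, `expressed`, `normalized`,
#'   `effective_expression`; attributes `uq_factors` and `config`.
#' @export
expression_profile <- function(counts, totals, config = de_config()) {
  prof <- compute_cpm(counts, totals) %>%
    flag_expressed(config) %>%
    upper_quartile_normalize() %>%
    mutate(effective_expression = ifelse(.data$expressed, .data$normalized, 0))
  uq <- attr(prof, "uq_factors")
  prof <- as_tibble(prof)
  attr(prof, "uq_factors") <- uq
  attr(prof, "totals") <- as_tibble(totals[c("library", "mapped_reads")])
  attr(prof, "config") <- config
  class(prof) <- c("expression_profile", class(prof))
  prof
}

#' @method glance expression_profile
#' @export
glance.expression_profile <- function(x, ...) {
  uq <- attr(x, "uq_factors")
  x %>%
    group_by(.data$library) %>%
    summarise(n_genes = dplyr::n(), n_expressed = sum(.data$expressed),
              .groups = "drop") %>%
    left_join(uq, by = "library") %>%
    left_join(attr(x, "totals"), by = "library")
}

#' @method tidy expression_profile
#' @export
tidy.expression_profile <- function(x, ...) as_tibble(x)

#' Call differential expression between two conditions
#'
#' Applies the two-rule DE criterion to every gene: (1) the fold rule - both
#' conditions expressed and the normalized-count ratio at least
#' `fold_threshold` (inclusive); (2) the on/off rule - CPM below
#' `cpm_expressed_min` in one condition and above `cpm_overexpressed_min` in
#' the other. `status` is `up` when the gene is higher in the first-named
#' condition.
#'
#' @param profile An [expression_profile()].
#' @param comparison Character vector of two library names, first vs second
#'   (e.g. `c("CA", "NC")` for the CA/NC contrast).
#' @param config A [de_config()]; defaults to the profile's own.
#' @return A tibble of class `de_calls`: `gene_id`, `comparison` (label
#'   `"A/B"`), `status` (`up`/`down`/`not_de`), `fold_change` (first over
#'   second where both normalized counts are positive), `criterion`
#'   (`fold`/`on_off`/`none`).
#' @export
call_de <- function(profile, comparison, config = NULL) {
  if (length(comparison) != 2) abort("`comparison` must name two libraries.")
  if (is.null(config)) config <- attr(profile, "config") %||% de_config()
  libs <- unique(profile$library)
  unknown <- setdiff(comparison, libs)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown librar%s: %s", if (length(unknown) > 1) "ies" else "y",
                  paste(unknown, collapse = ", ")))
  }
  a <- profile[profile$library == comparison[1],
               c("gene_id", "cpm", "expressed", "normalized")]
  b <- profile[profile$library == comparison[2],
               c("gene_id", "cpm", "expressed", "normalized")]
  d <- left_join(a, b, by = "gene_id", suffix = c("_a", "_b"))

  lo <- config$cpm_expressed_min
  hi <- config$cpm_overexpressed_min
  ratio <- pmax(d$normalized_a, d$normalized_b) /
    pmin(d$normalized_a, d$normalized_b)
  fold_fires <- d$expressed_a & d$expressed_b & ratio >= config$fold_threshold
  onoff_fires <- (d$cpm_a < lo & d$cpm_b > hi) | (d$cpm_b < lo & d$cpm_a > hi)

  criterion <- ifelse(fold_fires, "fold", ifelse(onoff_fires, "on_off", "none"))
  higher_a <- ifelse(criterion == "on_off", d$cpm_a > d$cpm_b,
                     d$normalized_a > d$normalized_b)
  status <- ifelse(criterion == "none", "not_de",
                   ifelse(higher_a, "up", "down"))
  fc <- ifelse(d$normalized_a > 0 & d$normalized_b > 0,
               d$normalized_a / d$normalized_b, NA_real_)
  out <- tibble(gene_id = d$gene_id,
                comparison = paste(comparison, collapse = "/"),
                status = status, fold_change = fc, criterion = criterion)
  class(out) <- c("de_calls", class(out))
  out
}

#' @method glance de_calls
#' @export
glance.de_calls <- function(x, ...) {
  tibble(comparison = unique(x$comparison),
         n_genes = nrow(x),
         n_de = sum(x$status != "not_de"),
         n_up = sum(x$status == "up"),
         n_down = sum(x$status == "down"),
         n_fold = sum(x$criterion == "fold"),
         n_on_off = sum(x$criterion == "on_off"))
}

#' Relative expression from qRT-PCR cycle thresholds
#'
#' Computes the 2^-ddCT relative concentration: dCT = CT(target) -
#' CT(reference) within each of the treated sample and the control, and the
#' relative level is 2^-(dCT_sample - dCT_control). When a no-template
#' control CT is supplied and the target CT is not below it, the target is
#' reported as not detected and the relative level is `NA`.
#'
#' @param data Data frame with columns `ct_target_sample`,
#'   `ct_reference_sample`, `ct_target_control`, `ct_reference_control`, and
#'   optionally `ct_ntc`.
#' @return `data` with columns `delta_delta_ct`, `relative_expression`,
#'   `detected` appended.
#' @examples
#' qpcr_relative_expression(tibble::tibble(
#'   ct_target_sample = 24, ct_reference_sample = 20,
#'   ct_target_control = 25, ct_reference_control = 20))
#' @export
qpcr_relative_expression <- function(data) {
  need <- c("ct_target_sample", "ct_reference_sample",
            "ct_target_control", "ct_reference_control")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns: %s", paste(need, collapse = ", ")))
  }
  cts <- as.matrix(data[need])
  if (any(is.na(cts)) || any(cts <= 0)) abort("CT values must be positive.")
  ddct <- (data$ct_target_sample - data$ct_reference_sample) -
    (data$ct_target_control - data$ct_reference_control)
  detected <- if ("ct_ntc" %in% names(data)) {
    is.na(data$ct_ntc) | data$ct_target_sample < data$ct_ntc
  } else {
    rep(TRUE, nrow(data))
  }
  data %>%
    mutate(delta_delta_ct = ddct,
           relative_expression = ifelse(detected, 2^(-ddct), NA_real_),
           detected = detected)
}
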
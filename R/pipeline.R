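#' Run the full chilling-response analysis
#'
#' Orchestrates the analysis end to end from a configuration list or YAML
#' file: expression profiling, DE calling for every configured condition
#' pair (mRNA and, when small-RNA counts are supplied, miRNA), DE-set
#' overlaps, the trajectory/reversal analysis, miRNA target prediction,
#' anti-correlation pairing, and GO enrichment of the reversed genes. Every
#' intermediate table is written as a TSV with deterministic row order, plus
#' a machine-readable run manifest, so reruns on identical inputs and
#' configuration are byte-identical.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{counts, totals}{Paths to the mRNA count table and totals
#'       sidecar (or in-memory data frames).}
#'     \item{mirna_counts, mirna_totals}{Optional small-RNA equivalents.}
#'     \item{mirnas_fasta, transcripts_fasta}{Optional FASTA paths enabling
#'       target prediction.}
#'     \item{annotation}{Optional two-column TSV `gene_id<TAB>term` enabling
#'       enrichment.}
#'     \item{comparisons}{List of ordered condition pairs, e.g.
#'       `list(c("CA","NC"), c("CCA","CA"), c("CS","NC"))`.}
#'     \item{trajectory}{Optional `list(first = c("CA","NC"), second =
#'       c("CCA","CA"))`.}
#'     \item{overlaps}{Optional list of comparison-label pairs, e.g.
#'       `list(c("CA/NC", "CS/NC"))`.}
#'     \item{de, scoring}{Optional argument lists for [de_config()] and
#'       [target_scoring_config()].}
#'   }
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages (messages never affect outputs).
#' @return Invisibly, a list with the computed objects (`profile`, `de`,
#'   `overlaps`, `trajectory`, `reversal`, `sites`, `anticorrelated`,
#'   `enrichment`, `manifest`).
#' @export
run_chilling_analysis <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_path <- function(f) file.path(outdir, f)
  stages <- character(0)
  outputs <- character(0)
  emit <- function(x, name) {
    readr::write_tsv(x, out_path(name))
    outputs <<- c(outputs, name)
  }
  slug <- function(pair) paste(pair, collapse = "_")
  as_pair <- function(p) {
    p <- unlist(p)
    if (length(p) != 2) abort("Each comparison must name exactly two conditions.")
    as.character(p)
  }

  de_cfg <- do.call(de_config, config$de %||% list())
  sc_cfg <- do.call(target_scoring_config, config$scoring %||% list())

  load_table <- function(counts, totals, what) {
    if (is.null(counts)) abort(sprintf("Configuration lacks `%s`.", what))
    if (is.data.frame(counts)) {
      list(counts = as_tibble(counts), totals = as_tibble(totals))
    } else {
      read_count_table(counts, totals)
    }
  }

  # --- expression & DE -------------------------------------------------
  tab <- load_table(config$counts, config$totals, "counts")
  say("expression: profiling %d genes x %d libraries",
      nrow(tab$counts), ncol(tab$counts) - 1)
  profile <- expression_profile(tab$counts, tab$totals, de_cfg)
  emit(as_tibble(profile), "profile.tsv")
  stages <- c(stages, "expression")

  comparisons <- lapply(config$comparisons %||%
                          list(c("CA", "NC"), c("CCA", "CA"), c("CS", "NC")),
                        as_pair)
  de <- list()
  for (p in comparisons) {
    lbl <- paste(p, collapse = "/")
    de[[lbl]] <- call_de(profile, p, de_cfg)
    emit(de[[lbl]], sprintf("de_%s.tsv", slug(p)))
  }
  stages <- c(stages, "differential_expression")

  mirna_de <- list()
  mirna_profile <- NULL
  if (!is.null(config$mirna_counts)) {
    mtab <- load_table(config$mirna_counts, config$mirna_totals, "mirna_totals")
    mirna_profile <- expression_profile(mtab$counts, mtab$totals, de_cfg)
    emit(as_tibble(mirna_profile), "mirna_profile.tsv")
    for (p in comparisons) {
      lbl <- paste(p, collapse = "/")
      mirna_de[[lbl]] <- call_de(mirna_profile, p, de_cfg)
      emit(mirna_de[[lbl]], sprintf("de_mirna_%s.tsv", slug(p)))
    }
    stages <- c(stages, "mirna_differential_expression")
  }

  # --- overlaps & trajectory ------------------------------------------
  overlaps <- list()
  for (pair in config$overlaps %||% list()) {
    pair <- unlist(pair)
    if (!all(pair %in% names(de))) {
      abort(sprintf("Overlap pair references unknown comparison(s): %s",
                    paste(setdiff(pair, names(de)), collapse = ", ")))
    }
    ov <- overlap_partition(de[[pair[1]]], de[[pair[2]]])
    key <- paste(gsub("/", "_", pair), collapse = "_vs_")
    overlaps[[key]] <- ov
    emit(tidy(ov), sprintf("overlap_%s.tsv", key))
    emit(glance(ov), sprintf("overlap_%s_summary.tsv", key))
  }
  if (length(overlaps) > 0) stages <- c(stages, "overlap")

  trajectory <- NULL; reversal <- NULL
  mirna_trajectory <- NULL
  if (!is.null(config$trajectory)) {
    tfirst <- as_pair(config$trajectory$first)
    tsecond <- as_pair(config$trajectory$second)
    lbl1 <- paste(tfirst, collapse = "/"); lbl2 <- paste(tsecond, collapse = "/")
    d1 <- de[[lbl1]] %||% call_de(profile, tfirst, de_cfg)
    d2 <- de[[lbl2]] %||% call_de(profile, tsecond, de_cfg)
    trajectory <- classify_trajectory(d1, d2) %>% arrange(.data$gene_id)
    reversal <- reversal_summary(trajectory)
    emit(as_tibble(trajectory), "trajectory.tsv")
    emit(as_tibble(reversal), "reversal_summary.tsv")
    if (length(mirna_de) > 0) {
      mirna_trajectory <- classify_trajectory(mirna_de[[lbl1]],
                                              mirna_de[[lbl2]]) %>%
        arrange(.data$gene_id)
      emit(as_tibble(mirna_trajectory), "mirna_trajectory.tsv")
      emit(as_tibble(reversal_summary(mirna_trajectory)),
           "mirna_reversal_summary.tsv")
    }
    stages <- c(stages, "trajectory")
  }

  # --- targets & anti-correlation -------------------------------------
  sites <- NULL; anticorr <- list()
  if (!is.null(config$mirnas_fasta) && !is.null(config$transcripts_fasta)) {
    mirnas <- read_fasta(config$mirnas_fasta)
    transcripts <- read_fasta(config$transcripts_fasta)
    say("targets: scanning %d miRNAs x %d transcripts",
        nrow(mirnas), nrow(transcripts))
    sites <- predict_targets(mirnas, transcripts, sc_cfg)
    emit(sites, "target_sites.tsv")
    stages <- c(stages, "target_prediction")
    if (length(mirna_de) > 0) {
      for (lbl in names(de)) {
        pairs <- find_anticorrelated_pairs(mirna_de[[lbl]], de[[lbl]], sites)
        anticorr[[lbl]] <- pairs
        emit(pairs, sprintf("anticorrelated_%s.tsv", gsub("/", "_", lbl)))
      }
      stages <- c(stages, "anticorrelation")
    }
  }

  # --- enrichment ------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotation)) {
    ann <- if (is.data.frame(config$annotation)) {
      as_tibble(config$annotation)
    } else {
      readr::read_tsv(config$annotation, col_names = c("gene_id", "term"),
                      show_col_types = FALSE)
    }
    gene_set <- if (!is.null(trajectory)) {
      trajectory$gene_id[trajectory$class == "reversed"]
    } else {
      de[[1]]$gene_id[de[[1]]$status != "not_de"]
    }
    universe <- tab$counts$gene_id
    enrichment <- enrich(gene_set, ann, universe = universe)
    emit(as_tibble(enrichment), "enrichment.tsv")
    stages <- c(stages, "enrichment")
  }

  # --- manifest --------------------------------------------------------
  input_files <- purrr::keep(config[c("counts", "totals", "mirna_counts",
                                      "mirna_totals", "mirnas_fasta",
                                      "transcripts_fasta", "annotation")],
                             is.character)
  manifest <- list(
    package = "chillseq",
    version = as.character(utils::packageVersion("chillseq")),
    config_hash = rlang::hash(config),
    inputs = lapply(input_files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    stages = stages,
    outputs = sort(outputs))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: %d stages, %d output files", length(stages), length(outputs))
  invisible(list(profile = profile, de = de, mirna_de = mirna_de,
                 overlaps = overlaps, trajectory = trajectory,
                 reversal = reversal, mirna_trajectory = mirna_trajectory,
                 sites = sites, anticorrelated = anticorr,
                 enrichment = enrichment, manifest = manifest))
}
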
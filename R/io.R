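#' Read a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param alphabet Normalise sequences to `"dna"` (U -> T, default) or
#'   `"rna"` (T -> U).
#' @return Tibble with columns `id` (first whitespace token of the header)
#'   and `sequence` (uppercase).
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    abort(sprintf("Malformed FASTA %s: %s", path, conditionMessage(e)))
                  })
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate record id in %s: %s", path,
                  ids[duplicated(ids)][1]))
  }
  tibble(id = ids,
         sequence = unname(normalize_nt(as.character(set), alphabet)))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with `id`, `sequence` or a named character vector.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.character(seqs) && !is.null(names(seqs))) {
    seqs <- tibble(id = names(seqs), sequence = unname(seqs))
  }
  lines <- unlist(purrr::map2(seqs$id, seqs$sequence, function(id, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path FASTQ file.
#' @return Tibble with columns `id`, `sequence` (uppercase DNA), `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(sprintf("Malformed FASTQ %s: %s", path, conditionMessage(e)))
    })
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate read id in %s: %s", path, ids[duplicated(ids)][1]))
  }
  quals <- unname(as.character(S4Vectors::mcols(set)$qualities))
  tibble(id = ids, sequence = unname(toupper(as.character(set))),
         quality = quals)
}

#' Write reads to FASTQ (Phred+33)
#'
#' Reads without a quality string are written with a constant high quality
#' (`I`, Q40).
#'
#' @param reads Tibble with `id`, `sequence` and optionally `quality`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else NA_character_
  qual <- ifelse(is.na(qual), strrep("I", nchar(reads$sequence)), qual)
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-library count table with its mapped-read totals
#'
#' @param path TSV with header `gene_id<TAB><lib1><TAB>...` and one row per
#'   gene.
#' @param totals_path Two-column TSV `library<TAB>mapped_reads`.
#' @return A list of class `count_table` with elements `counts` (wide
#'   tibble) and `totals`.
#' @export
read_count_table <- function(path, totals_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(counts)[1] != "gene_id") {
    abort(sprintf("%s: first column must be `gene_id`.", path))
  }
  totals <- readr::read_tsv(totals_path, show_col_types = FALSE)
  libs <- check_count_table(counts, totals)
  structure(list(counts = counts, totals = totals[c("library", "mapped_reads")],
                 libraries = libs),
            class = "count_table")
}

#' Write a count table and its totals sidecar
#'
#' @param counts Wide count tibble (`gene_id` + library columns).
#' @param totals Tibble `library`, `mapped_reads`.
#' @param path,totals_path Output TSVs.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, totals, path, totals_path) {
  readr::write_tsv(counts, path)
  readr::write_tsv(totals[c("library", "mapped_reads")], totals_path)
  invisible(path)
}
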
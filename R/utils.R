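#' Round half away from zero
#'
#' Base R's `round()` rounds half to even (76.25 -> 76.2). Printed summary
#' percentages in chilling-response reports follow conventional half-up
#' rounding (76.25 -> 76.3), so all percentage formatting in this package
#' goes through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(c(76.25, 0.05, 2.345), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# geometric mean of strictly positive values
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# shared validator: a two-column up/down DE set
check_de_set <- function(x, arg = "de_set") {
  if (!is.data.frame(x) || !all(c("gene_id", "status") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `gene_id` and `status`.", arg))
  }
  bad <- setdiff(unique(x$status), c("up", "down"))
  if (length(bad) > 0) {
    abort(sprintf("`%s` has statuses other than up/down: %s", arg,
                  paste(bad, collapse = ", ")))
  }
  both <- intersect(x$gene_id[x$status == "up"], x$gene_id[x$status == "down"])
  if (length(both) > 0) {
    abort(sprintf("`%s` lists gene(s) as both up and down: %s", arg,
                  paste(head(both, 3), collapse = ", ")))
  }
  invisible(x)
}

# normalise a nucleotide string: uppercase, RNA U -> DNA T
normalize_nt <- function(x, to = c("dna", "rna")) {
  to <- match.arg(to)
  x <- toupper(x)
  if (to == "dna") gsub("U", "T", x, fixed = TRUE) else gsub("T", "U", x, fixed = TRUE)
}

check_nt <- function(x, allow_n = TRUE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTUN]*$" else "^[ACGTU]*$"
  ok <- grepl(pat, toupper(x))
  if (!all(ok)) {
    abort(sprintf("`%s` contains non-nucleotide characters (first offender: %s)",
                  arg, x[!ok][1]))
  }
  invisible(x)
}
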
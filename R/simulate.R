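#' Configuration for the synthetic chilling-experiment generator
#'
#' Describes the study design the generator emulates: four pooled libraries
#' (NC, CA, CCA, CS), overdispersed tag counts for ~10k genes and ~150
#' miRNAs, and planted expression classes - genes DE in CA/NC that keep,
#' reverse, or continue their direction in CCA/CA, plus CS- and CCA-specific
#' genes - at a fixed planted fold change. Reversed miRNAs receive planted
#' anti-correlated mRNA targets.
#'
#' @param n_genes,n_mirnas Numbers of mRNA genes and miRNAs.
#' @param library_depths Named mapped-read totals per condition (mRNA
#'   libraries).
#' @param mirna_depths Mapped-read totals for the small-RNA libraries.
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives deterministic counts `round(mu)`.
#' @param fraction_de_ca Genes DE in CA/NC whose level then persists in CCA.
#' @param fraction_reversed Genes DE in CA/NC that return to baseline in CCA
#'   (opposite direction in CCA/CA).
#' @param fraction_continued Genes DE in CA/NC that move further in the same
#'   direction in CCA/CA.
#' @param fraction_cs_specific,fraction_cca_specific Genes DE only in CS/NC,
#'   or only in CCA/CA.
#' @param mirna_fraction_de,mirna_fraction_reversed Same roles for miRNAs.
#' @param planted_fold Planted mean ratio (>= 4, the DE fold threshold).
#' @param targets_per_mirna Planted anti-correlated mRNA targets per reversed
#'   miRNA.
#' @param planted_site_scores Alignment penalties of planted target sites.
#' @param adapter 3' sequencing adaptor used by [simulate_reads()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000, n_mirnas = 150,
                              library_depths = c(NC = 2e6, CA = 2e6,
                                                 CCA = 2e6, CS = 2e6),
                              mirna_depths = c(NC = 5e6, CA = 5e6,
                                               CCA = 5e6, CS = 5e6),
                              dispersion = 0.05,
                              fraction_de_ca = 0.03,
                              fraction_reversed = 0.053,
                              fraction_continued = 0.0005,
                              fraction_cs_specific = 0.03,
                              fraction_cca_specific = 0.01,
                              mirna_fraction_de = 0.33,
                              mirna_fraction_reversed = 0.20,
                              planted_fold = 8,
                              targets_per_mirna = 2,
                              planted_site_scores = c(0, 1, 1.5, 2, 3, 4),
                              adapter = "TGGAATTCTCGGGTGCCAAGG") {
  fr <- c(fraction_de_ca, fraction_reversed, fraction_continued,
          fraction_cs_specific, fraction_cca_specific)
  if (any(fr < 0) || sum(fr) > 1) {
    abort("Gene class fractions must be non-negative and sum to at most 1.")
  }
  if (mirna_fraction_de < 0 || mirna_fraction_reversed < 0 ||
      mirna_fraction_de + mirna_fraction_reversed > 1) {
    abort("miRNA class fractions must be non-negative and sum to at most 1.")
  }
  if (planted_fold < 4) abort("`planted_fold` must be at least 4.")
  if (any(library_depths <= 0) || any(mirna_depths <= 0)) {
    abort("Library depths must be positive.")
  }
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  structure(list(n_genes = n_genes, n_mirnas = n_mirnas,
                 library_depths = library_depths, mirna_depths = mirna_depths,
                 dispersion = dispersion, fraction_de_ca = fraction_de_ca,
                 fraction_reversed = fraction_reversed,
                 fraction_continued = fraction_continued,
                 fraction_cs_specific = fraction_cs_specific,
                 fraction_cca_specific = fraction_cca_specific,
                 mirna_fraction_de = mirna_fraction_de,
                 mirna_fraction_reversed = mirna_fraction_reversed,
                 planted_fold = planted_fold,
                 targets_per_mirna = targets_per_mirna,
                 planted_site_scores = planted_site_scores,
                 adapter = adapter),
            class = "simulation_config")
}

nb_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# lognormal truncated to [min, max]: planted baselines are background
# baselines conditioned on a detectability window
rtrunc_lnorm <- function(n, meanlog, sdlog, min, max = Inf) {
  lo <- stats::plnorm(min, meanlog, sdlog)
  hi <- stats::plnorm(max, meanlog, sdlog)
  stats::qlnorm(runif(n, lo, hi), meanlog, sdlog)
}

# assign planted classes and per-condition mean CPM for one feature table.
# Induced (up) features start low and rise into the expressed range;
# repressed (down) features start well-expressed and fall. Besides being the
# usual physiology of stress-induced genes, this keeps the upper-quartile
# statistic balanced across libraries: features leaving the upper tail in a
# stressed library are replaced by induced ones entering it.
plant_classes <- function(n, fractions, planted_fold, prefix,
                          base_meanlog, base_sdlog,
                          up_base_range, down_base_min) {
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  n_class <- vapply(fractions, function(f) round(f * n), numeric(1))
  labels <- rep("none", n)
  pool <- sample.int(n, sum(n_class))
  off <- 0
  for (cl in names(n_class)) {
    if (n_class[[cl]] > 0) {
      labels[pool[(off + 1):(off + n_class[[cl]])]] <- cl
      off <- off + n_class[[cl]]
    }
  }
  base <- rlnorm(n, base_meanlog, base_sdlog)
  planted <- labels != "none"
  dir <- ifelse(planted, sample(c(1, -1), n, replace = TRUE), 0)
  n_up <- sum(dir > 0); n_dn <- sum(dir < 0)
  base[dir > 0] <- rtrunc_lnorm(n_up, base_meanlog, base_sdlog,
                                up_base_range[1], up_base_range[2])
  base[dir < 0] <- rtrunc_lnorm(n_dn, base_meanlog, base_sdlog,
                                down_base_min)

  f <- planted_fold
  mult <- function(cond) {
    switch(cond,
      NC = rep(1, n),
      CA = ifelse(labels %in% c("de", "reversed", "continued"), f^dir, 1),
      CCA = dplyr::case_when(labels == "de" ~ f^dir,
                             labels == "reversed" ~ 1,
                             labels == "continued" ~ f^(2 * dir),
                             labels == "cca_specific" ~ f^dir,
                             TRUE ~ 1),
      CS = ifelse(labels %in% c("de", "reversed", "continued"), f^dir,
                  ifelse(labels == "cs_specific", f^dir, 1)))
  }
  means <- vapply(c("NC", "CA", "CCA", "CS"), function(cond) base * mult(cond),
                  numeric(n))
  colnames(means) <- c("NC", "CA", "CCA", "CS")
  truth_label <- dplyr::case_when(
    labels == "none" ~ "none",
    labels == "de" & dir > 0 ~ "de_up",
    labels == "de" ~ "de_down",
    labels == "reversed" & dir > 0 ~ "reversed_up_down",
    labels == "reversed" ~ "reversed_down_up",
    labels == "continued" & dir > 0 ~ "continued_up",
    labels == "continued" ~ "continued_down",
    labels == "cs_specific" & dir > 0 ~ "cs_specific_up",
    labels == "cs_specific" ~ "cs_specific_down",
    labels == "cca_specific" & dir > 0 ~ "cca_specific_up",
    TRUE ~ "cca_specific_down")
  truth <- tibble(gene_id = ids, class = truth_label,
                  direction = ifelse(dir > 0, "up",
                                     ifelse(dir < 0, "down", NA_character_)),
                  base_cpm = base,
                  fold_ca_nc = means[, "CA"] / means[, "NC"],
                  fold_cca_ca = means[, "CCA"] / means[, "CA"],
                  fold_cs_nc = means[, "CS"] / means[, "NC"])
  list(ids = ids, means = means, truth = truth)
}

#' Simulate four-condition count tables with planted truth
#'
#' Draws baseline expression from a heavy-tailed log-normal, imposes the
#' planted class structure of [simulation_config()] on the per-condition
#' means (CPM scale), and samples negative-binomial counts at the configured
#' library depths. Planted-class genes take baselines high enough to be
#' expressed in every condition, so the fold criterion is the one exercised.
#' Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_counts`: `counts`, `totals` (mRNA),
#'   `mirna_counts`, `mirna_totals`, `truth_genes`, `truth_mirnas`,
#'   `planted_pairs` (reversed miRNA to anti-correlated reversed target),
#'   `config`, `seed`.
#' @export
simulate_counts <- function(config = simulation_config(), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  withr::with_seed(seed, {
    genes <- plant_classes(
      config$n_genes,
      c(de = config$fraction_de_ca, reversed = config$fraction_reversed,
        continued = config$fraction_continued,
        cs_specific = config$fraction_cs_specific,
        cca_specific = config$fraction_cca_specific),
      config$planted_fold, "gene_",
      base_meanlog = log(6), base_sdlog = 2,
      up_base_range = c(8, 40), down_base_min = 100)
    mirnas <- plant_classes(
      config$n_mirnas,
      c(de = config$mirna_fraction_de,
        reversed = config$mirna_fraction_reversed,
        continued = 0, cs_specific = 0, cca_specific = 0),
      config$planted_fold, "mir_",
      base_meanlog = log(300), base_sdlog = 1.8,
      up_base_range = c(15, 150), down_base_min = 400)

    draw <- function(pl, depths) {
      counts <- vapply(colnames(pl$means), function(cond) {
        mu <- pl$means[, cond] * depths[[cond]] / 1e6
        nb_counts(mu, config$dispersion)
      }, numeric(length(pl$ids)))
      dplyr::bind_cols(tibble(gene_id = pl$ids), as_tibble(counts))
    }
    counts <- draw(genes, config$library_depths)
    mirna_counts <- draw(mirnas, config$mirna_depths)
    totals <- tibble(library = names(config$library_depths),
                     mapped_reads = unname(config$library_depths))
    mirna_totals <- tibble(library = names(config$mirna_depths),
                           mapped_reads = unname(config$mirna_depths))

    rev_mirs <- mirnas$truth[startsWith(mirnas$truth$class, "reversed"), ]
    pair_rows <- purrr::pmap(list(rev_mirs$gene_id, rev_mirs$direction),
      function(mid, mdir) {
        opp <- if (mdir == "up") "reversed_down_up" else "reversed_up_down"
        cand <- genes$truth$gene_id[genes$truth$class == opp]
        if (length(cand) == 0) return(NULL)
        tibble(mirna_id = mid,
               gene_id = sample(cand, min(config$targets_per_mirna,
                                          length(cand))))
      })
    planted_pairs <- bind_rows(pair_rows)

    structure(list(counts = counts, totals = totals,
                   mirna_counts = mirna_counts, mirna_totals = mirna_totals,
                   truth_genes = genes$truth,
                   truth_mirnas = rename(mirnas$truth, mirna_id = "gene_id"),
                   planted_pairs = planted_pairs,
                   config = config, seed = seed),
              class = "sim_counts")
  })
}

random_seq <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

# Mutate the perfect reverse complement of `mirna` into a site of exactly
# `score`, using non-seed, non-terminal miRNA positions (wobbles for the
# half-unit, mismatches for whole units). Verified against align_site().
construct_site <- function(mirna, score, config = target_scoring_config()) {
  L <- nchar(mirna)
  if (score < 0 || (2 * score) %% 1 != 0) {
    abort("Requested site score must be a non-negative multiple of 0.5.")
  }
  mchars <- strsplit(mirna, "")[[1]]
  free <- setdiff(2:(L - 1), config$seed_start:config$seed_end)
  n_wob <- if ((2 * score) %% 2 == 1) 1L else 0L
  n_mis <- as.integer(score - 0.5 * n_wob)
  if (n_wob + n_mis > length(free)) {
    abort(sprintf("Score %.1f unreachable for a %d-nt miRNA with non-seed edits.",
                  score, L))
  }
  wobble_ok <- free[mchars[free] %in% c("G", "T", "U")]
  if (n_wob > length(wobble_ok)) {
    abort("No non-seed G/U base available for the requested wobble.")
  }
  for (attempt in 1:25) {
    site <- strsplit(revcomp(mirna), "")[[1]]
    wpos <- if (n_wob) sample(wobble_ok, n_wob) else integer(0)
    mpos <- if (n_mis) sample(setdiff(free, wpos), n_mis) else integer(0)
    for (p in wpos) {
      # G:U wobble: pair target U with miRNA G, or target G with miRNA U
      site[L - p + 1] <- if (mchars[p] == "G") "T" else "G"
    }
    for (p in mpos) {
      avoid <- chartr("ACGT", "TGCA", mchars[p])
      if (mchars[p] == "G") avoid <- c(avoid, "T")
      if (mchars[p] %in% c("T", "U")) avoid <- c(avoid, "G")
      site[L - p + 1] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
    }
    site <- paste(site, collapse = "")
    if (isTRUE(all.equal(align_site(mirna, site, config)$score, score))) {
      return(site)
    }
  }
  abort(sprintf("Could not construct a site of score %.1f (an alternative alignment keeps scoring lower).",
                score))
}

#' Simulate miRNAs and transcripts with planted target sites
#'
#' Generates random miRNA and transcript sequences and embeds, for each
#' requested score, a target site built by mutating the miRNA's perfect
#' reverse complement until [align_site()] returns exactly that score
#' (verified at plant time). Sites are spaced so they never overlap.
#'
#' @param n_mirnas,mirna_length Number and length of miRNAs (default 20 x 21
#'   nt).
#' @param n_transcripts,transcript_length Transcript set size (default 30 x
#'   500 nt).
#' @param planted_site_scores Penalties of the planted sites; recycled over
#'   miRNAs. Scores above the prediction cutoff are planted but should not
#'   be reported by [predict_targets()].
#' @param config A [target_scoring_config()].
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_sequences`: `mirnas` and `transcripts`
#'   (tibbles `id`, `sequence`) and `sites` (planted truth: `mirna_id`,
#'   `transcript_id`, `start`, `end`, `score`).
#' @export
simulate_sequences <- function(n_mirnas = 20, mirna_length = 21,
                               n_transcripts = 30, transcript_length = 500,
                               planted_site_scores = c(0, 1, 1.5, 2, 3, 4),
                               config = target_scoring_config(), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  withr::with_seed(seed, {
    mirseq <- random_seq(n_mirnas, mirna_length)
    # guarantee a non-seed G for wobble construction
    fixpos <- setdiff(2:(mirna_length - 1),
                      config$seed_start:config$seed_end)[1]
    mirseq <- vapply(mirseq, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[fixpos] <- "G"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    mirnas <- tibble(id = sprintf("mir_%03d", seq_len(n_mirnas)),
                     sequence = mirseq)
    transcripts <- tibble(id = sprintf("tx_%03d", seq_len(n_transcripts)),
                          sequence = random_seq(n_transcripts,
                                                transcript_length))
    n_sites <- length(planted_site_scores)
    site_mir <- rep_len(seq_len(n_mirnas), n_sites)
    site_tx <- rep_len(seq_len(n_transcripts), n_sites)
    sites <- vector("list", n_sites)
    next_free <- rep(1L, n_transcripts)
    for (i in seq_len(n_sites)) {
      sc <- planted_site_scores[i]
      mir_seq <- mirnas$sequence[site_mir[i]]
      ti <- site_tx[i]
      w <- mirna_length
      start <- next_free[ti] + 10L
      if (start + w - 1 > transcript_length) {
        abort("Transcript too short for the requested number of planted sites.")
      }
      tx_seq <- transcripts$sequence[ti]
      # constructive planting, verified in context: the whole-transcript scan
      # must report exactly the planted span and score (a mutation draw can
      # accidentally admit a cheaper gapped alignment in a sub-window; such
      # draws are rejected and redrawn)
      planted_ok <- FALSE
      for (attempt in 1:30) {
        site <- construct_site(mir_seq, sc, config)
        cand <- paste0(substr(tx_seq, 1, start - 1), site,
                       substr(tx_seq, start + w, transcript_length))
        hits <- suppressWarnings(predict_targets(
          tibble(id = "m", sequence = mir_seq),
          tibble(id = "t", sequence = cand), config))
        over <- hits[hits$end >= start & hits$start <= start + w - 1, ]
        ok <- if (sc <= config$score_cutoff) {
          nrow(over) == 1 && over$start == start &&
            over$end == start + w - 1 && over$score == sc
        } else {
          nrow(over) == 0
        }
        if (ok) {
          planted_ok <- TRUE
          tx_seq <- cand
          break
        }
      }
      if (!planted_ok) {
        abort(sprintf("Could not plant a verifiable site of score %.1f.", sc))
      }
      transcripts$sequence[ti] <- tx_seq
      next_free[ti] <- start + w + 10L
      sites[[i]] <- tibble(mirna_id = mirnas$id[site_mir[i]],
                           transcript_id = transcripts$id[ti],
                           start = start, end = start + w - 1L, score = sc)
    }
    structure(list(mirnas = mirnas, transcripts = transcripts,
                   sites = bind_rows(sites), seed = seed),
              class = "sim_sequences")
  })
}

#' Simulate small-RNA sequencing reads with 3' adaptors
#'
#' Reads are transcript fragments (17-28 nt in small-RNA mode) followed by a
#' prefix of the 3' adaptor of random length (0 to the full adaptor), with
#' optional per-base substitution noise. The truth table records each read's
#' source transcript, clean insert, adaptor prefix length, and whether the
#' read carries at least 7 nt of adaptor evidence.
#'
#' @param transcripts Tibble `id`, `sequence` (or named character vector).
#' @param n_reads Number of reads.
#' @param adapter 3' adaptor sequence.
#' @param weights Optional per-transcript sampling weights (default
#'   uniform).
#' @param noise Per-base substitution probability (default 0).
#' @param insert_range Insert length range (default c(17, 28)).
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_reads`: `reads` (tibble `id`, `sequence`,
#'   `quality`) and `truth` (`id`, `transcript_id`, `insert`, `insert_len`,
#'   `adapter_len`, `has_adapter_evidence`).
#' @export
simulate_reads <- function(transcripts, n_reads = 500,
                           adapter = "TGGAATTCTCGGGTGCCAAGG", weights = NULL,
                           noise = 0, insert_range = c(17, 28), seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  tx <- as_seq_tbl(transcripts, "transcripts")
  if (is.null(weights)) weights <- rep(1, nrow(tx))
  withr::with_seed(seed, {
    src <- sample.int(nrow(tx), n_reads, replace = TRUE, prob = weights)
    ilen <- sample(insert_range[1]:insert_range[2], n_reads, replace = TRUE)
    alen <- sample(0:nchar(adapter), n_reads, replace = TRUE)
    rows <- purrr::map(seq_len(n_reads), function(i) {
      txs <- tx$sequence[src[i]]
      maxs <- nchar(txs) - ilen[i] + 1
      s <- sample.int(maxs, 1)
      insert <- substr(txs, s, s + ilen[i] - 1)
      seqr <- paste0(insert, substr(adapter, 1, alen[i]))
      if (noise > 0) {
        ch <- strsplit(seqr, "")[[1]]
        flip <- runif(length(ch)) < noise
        ch[flip] <- vapply(ch[flip], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        seqr <- paste(ch, collapse = "")
      }
      tibble(id = sprintf("read_%05d", i), transcript_id = tx$id[src[i]],
             insert = insert, insert_len = ilen[i], adapter_len = alen[i],
             sequence = seqr)
    })
    truth <- bind_rows(rows) %>%
      mutate(has_adapter_evidence = .data$adapter_len >= 7)
    reads <- truth %>%
      mutate(quality = strrep("I", nchar(.data$sequence))) %>%
      select("id", "sequence", "quality")
    structure(list(reads = reads,
                   truth = select(truth, "id", "transcript_id", "insert",
                                  "insert_len", "adapter_len",
                                  "has_adapter_evidence"),
                   seed = seed),
              class = "sim_reads")
  })
}
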
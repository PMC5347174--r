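# Synthetic coding-sequence corpora with controlled codon usage and planted
# per-bicodon enrichment, plus labelled synthetic SNP cohorts. Every pipeline
# stage can be exercised end to end against known ground truth.
#
# Sequences are ATG + i.i.d. amino acids realized as codons + one stop codon.
# Codons are drawn per amino acid from the configured usage; a planted bias
# (bicodon, corpus, factor r) reweights the A-site codon conditional on the
# P-site codon so that the target bicodon's expected relative frequency
# within its amino-acid-pair family is multiplied by r in that corpus.

#' Configuration for the synthetic corpus generator
#'
#' @param n_sequences Sequences per corpus.
#' @param mean_length Mean sequence length in codons (including the start and
#'   stop codon). Lengths are negative-binomially distributed.
#' @param length_dispersion Negative-binomial size parameter of the length
#'   distribution (larger = less dispersed).
#' @param aa_weights Optional named non-negative weights over the 20 amino
#'   acids for the interior composition (default: uniform).
#' @param codon_weights Optional named non-negative weights over the 64
#'   codons; within each amino-acid family they define the codon usage
#'   (default: uniform within each family).
#' @param planted_bias Optional data.frame with columns `bicodon` (hexamer in
#'   the universe), `corpus` (`"L"` or `"H"`) and `r` (enrichment factor
#'   >= 1).
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sequences = 2000L, mean_length = 300,
                             length_dispersion = 10, aa_weights = NULL,
                             codon_weights = NULL, planted_bias = NULL,
                             seed = 42L) {
  aa20 <- sort(setdiff(unique(.codon_env$aa), "*"))
  if (is.null(aa_weights)) {
    aa_weights <- stats::setNames(rep(1, length(aa20)), aa20)
  } else {
    if (is.null(names(aa_weights)) || !all(names(aa_weights) %in% aa20)) {
      stop("aa_weights must be named by the 20 amino-acid symbols")
    }
    full <- stats::setNames(rep(0, length(aa20)), aa20)
    full[names(aa_weights)] <- aa_weights
    aa_weights <- full
  }
  if (any(aa_weights < 0)) stop("amino-acid weights must be non-negative")
  if (sum(aa_weights) <= 0) stop("amino-acid weights must not all be zero")

  codons <- .codon_env$codons
  if (is.null(codon_weights)) {
    codon_weights <- stats::setNames(rep(1, length(codons)), codons)
  } else {
    if (is.null(names(codon_weights)) || !all(names(codon_weights) %in% codons)) {
      stop("codon_weights must be named by codons")
    }
    full <- stats::setNames(rep(0, length(codons)), codons)
    full[names(codon_weights)] <- codon_weights
    codon_weights <- full
  }
  if (any(codon_weights < 0)) stop("codon weights must be non-negative")

  if (is.null(planted_bias)) {
    planted_bias <- data.frame(bicodon = character(), corpus = character(),
                               r = numeric(), stringsAsFactors = FALSE)
  } else {
    planted_bias <- as.data.frame(planted_bias, stringsAsFactors = FALSE)
    need <- c("bicodon", "corpus", "r")
    if (!all(need %in% names(planted_bias))) {
      stop("planted_bias needs columns bicodon, corpus, r")
    }
    planted_bias$bicodon <- toupper(planted_bias$bicodon)
    bad <- !planted_bias$bicodon %in% .codon_env$universe$hexamer
    if (any(bad)) stop("planted bicodon(s) outside the universe: ",
                       paste(planted_bias$bicodon[bad], collapse = ", "))
    if (!all(planted_bias$corpus %in% c("L", "H"))) {
      stop("planted_bias$corpus must be 'L' or 'H'")
    }
    if (any(planted_bias$r < 1)) stop("enrichment factors must be >= 1")
  }

  structure(list(n_sequences = as.integer(n_sequences),
                 mean_length = mean_length,
                 length_dispersion = length_dispersion,
                 aa_weights = aa_weights, codon_weights = codon_weights,
                 planted_bias = planted_bias, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a pair of synthetic CDS corpora
#'
#' The low- and high-abundance corpora use independent sub-seeds derived from
#' `config$seed`, so resizing one corpus does not perturb the other.
#'
#' @param config A [generator_config()].
#' @return List with named character vectors `low` and `high`.
#' @examples
#' corp <- generate_corpora(generator_config(n_sequences = 5, mean_length = 20))
#' substr(corp$low[[1]], 1, 3)  # "ATG"
#' @export
generate_corpora <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  subseeds <- sample.int(2147483647L, 2L)
  set.seed(subseeds[1L])
  low <- .generate_corpus(config, "L")
  set.seed(subseeds[2L])
  high <- .generate_corpus(config, "H")
  list(low = low, high = high)
}

.generate_corpus <- function(cfg, corpus) {
  n <- cfg$n_sequences
  rules <- cfg$planted_bias[cfg$planted_bias$corpus == corpus, , drop = FALSE]
  if (nrow(rules)) {
    rules$p_codon <- substr(rules$bicodon, 1L, 3L)
    rules$a_codon <- substr(rules$bicodon, 4L, 6L)
    rules$a_aa <- translate_codon(rules$a_codon)
    rules <- rules[order(rules$a_aa, rules$p_codon, rules$a_codon), , drop = FALSE]
    # feasibility: the requested conditional mass sum(r * q) must stay < 1
    # per (P-site codon, A-site family); excess is clipped by renormalization
    aa_of <- .codon_env$aa
    for (grp in split(rules, paste(rules$p_codon, rules$a_aa))) {
      fam <- .codon_env$codons[aa_of == grp$a_aa[1L]]
      w <- cfg$codon_weights[fam]; w <- w / sum(w)
      mass <- sum(grp$r * w[grp$a_codon])
      if (mass >= 1) {
        warning("planted enrichment clipped for P-site ", grp$p_codon[1L],
                ", A-site family ", grp$a_aa[1L],
                " (requested conditional mass ", round(mass, 3), ")")
      }
    }
  }
  lens <- pmax(1L, stats::rnbinom(n, size = cfg$length_dispersion,
                                  mu = max(1, cfg$mean_length - 2)))
  maxlen <- max(lens)
  codmat <- matrix(NA_character_, nrow = n, ncol = maxlen)
  prev <- rep("ATG", n)
  aa_names <- names(cfg$aa_weights)
  for (t in seq_len(maxlen)) {
    active <- which(lens >= t)
    aa_t <- sample(aa_names, length(active), replace = TRUE,
                   prob = cfg$aa_weights)
    drawn <- .sample_codons(aa_t, prev[active], cfg, rules)
    codmat[cbind(active, t)] <- drawn
    prev[active] <- drawn
  }
  stop_cod <- .sample_codons(rep("*", n), prev, cfg, rules)
  seqs <- vapply(seq_len(n), function(i) {
    paste0("ATG", paste(codmat[i, seq_len(lens[i])], collapse = ""), stop_cod[i])
  }, character(1))
  names(seqs) <- sprintf("%s%05d", corpus, seq_len(n))
  seqs
}

# Draw one codon per element: aa[i] is the amino acid to encode, prev[i] the
# preceding (P-site) codon. Planted rules modify the conditional usage:
# the target codon's probability becomes r * q (clipped at 1 with a warning),
# the other codons share the remaining mass in their original proportions.
.sample_codons <- function(aa, prev, cfg, rules) {
  res <- character(length(aa))
  aa_of <- .codon_env$aa
  for (a in sort(unique(aa))) {
    idx <- which(aa == a)
    fam <- .codon_env$codons[aa_of == a]
    w <- cfg$codon_weights[fam]
    if (sum(w) <= 0) stop("all codon weights are zero for amino acid ", a)
    w <- w / sum(w)
    ra <- if (nrow(rules)) rules[rules$a_aa == a, , drop = FALSE] else rules
    done <- logical(length(idx))
    if (nrow(ra)) {
      for (p in unique(ra$p_codon)) {
        sel <- !done & prev[idx] == p
        if (!any(sel)) next
        sub <- ra[ra$p_codon == p, , drop = FALSE]
        w2 <- w
        q_t <- w[sub$a_codon]
        p_t <- sub$r * q_t
        if (sum(p_t) >= 1) p_t <- p_t / sum(p_t)  # clip (warned at setup)
        w2[] <- if (sum(q_t) < 1) w * (1 - sum(p_t)) / (1 - sum(q_t)) else 0
        w2[sub$a_codon] <- p_t
        res[idx[sel]] <- sample(fam, sum(sel), replace = TRUE, prob = w2)
        done <- done | sel
      }
    }
    if (any(!done)) {
      res[idx[!done]] <- sample(fam, sum(!done), replace = TRUE, prob = w)
    }
  }
  res
}

#' Configuration for the synthetic SNP cohort generator
#'
#' @param n_pathological,n_benign Number of SNPs per group.
#' @param top_quantile Pathological SNPs are drawn from candidate variants
#'   whose best |delta pi| quantile is at least this value (default 0.9, the
#'   null's top decile); benign SNPs are drawn uniformly from all candidates.
#' @param n_cds_scan How many pool sequences to scan for candidate sites.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pathological = 20L, n_benign = 60L,
                          top_quantile = 0.9, n_cds_scan = 50L, seed = 42L) {
  if (n_pathological < 1L || n_benign < 1L) stop("group sizes must be >= 1")
  if (top_quantile <= 0 || top_quantile >= 1) stop("top_quantile must be in (0,1)")
  structure(list(n_pathological = as.integer(n_pathological),
                 n_benign = as.integer(n_benign),
                 top_quantile = top_quantile,
                 n_cds_scan = as.integer(n_cds_scan),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a labelled synthetic SNP cohort
#'
#' Scans pool coding sequences for all synonymous single-base substitutions,
#' scores each candidate's best |delta pi| against the null, and samples a
#' pathological group from the top of the null and a benign group uniformly.
#'
#' @param config A [cohort_config()].
#' @param cds_pool Named character vector (or DNAStringSet) of host CDSs,
#'   e.g. the low-abundance corpus from [generate_corpora()].
#' @param bicodon_stats Data.frame from [pause_propensity()].
#' @param null_bicodon `null_distribution` from [build_null()].
#' @return List with `snps` (data.frame: `snp_id`, `cds_id`, `position`,
#'   `ref`, `alt`, `group`) and `cds` (the named subset of `cds_pool` hosting
#'   the SNPs).
#' @export
generate_cohort <- function(config, cds_pool, bicodon_stats, null_bicodon) {
  stopifnot(inherits(config, "cohort_config"))
  if (methods::is(cds_pool, "DNAStringSet")) cds_pool <- as.character(cds_pool)
  if (is.null(names(cds_pool))) {
    names(cds_pool) <- sprintf("cds%05d", seq_along(cds_pool))
  }
  set.seed(config$seed)
  pi_tab <- stats::setNames(bicodon_stats$pi, bicodon_stats$hexamer)
  scan <- cds_pool[seq_len(min(config$n_cds_scan, length(cds_pool)))]
  cand <- do.call(rbind, lapply(names(scan), function(id) {
    .snp_candidates(scan[[id]], id, pi_tab)
  }))
  if (is.null(cand) || !nrow(cand)) stop("no synonymous candidate sites found in pool")
  cand$best_z <- z_score(cand$best_abs_dpi, null_bicodon)

  top <- which(cand$best_z >= config$top_quantile)
  if (length(top) < config$n_pathological) {
    stop("pool too small: only ", length(top), " top-quantile candidates for ",
         config$n_pathological, " pathological SNPs (scan more sequences)")
  }
  path_idx <- sample(top, config$n_pathological)
  rest <- setdiff(seq_len(nrow(cand)), path_idx)
  if (length(rest) < config$n_benign) {
    stop("pool too small: only ", length(rest), " candidates left for ",
         config$n_benign, " benign SNPs")
  }
  ben_idx <- sample(rest, config$n_benign)

  pick <- cand[c(path_idx, ben_idx), , drop = FALSE]
  pick$group <- rep(c("pathological", "benign"),
                    c(config$n_pathological, config$n_benign))
  pick$snp_id <- sprintf("snp%04d", seq_len(nrow(pick)))
  snps <- data.frame(snp_id = pick$snp_id, cds_id = pick$cds_id,
                     position = pick$position, ref = pick$ref, alt = pick$alt,
                     group = pick$group, stringsAsFactors = FALSE)
  list(snps = snps, cds = cds_pool[unique(snps$cds_id)])
}

# All synonymous single-base substitutions of one CDS, with the best
# |delta pi| over the (up to two) bicodon changes of each substitution.
.snp_candidates <- function(cds, cds_id, pi_tab) {
  cds <- toupper(cds)
  m <- nchar(cds) %/% 3L
  if (m < 2L) return(NULL)
  codons <- substring(cds, seq(1L, m * 3L, 3L), seq(3L, m * 3L, 3L))
  alts <- .codon_env$syn_alts           # codon, offset, ref_base, alt_base, alt_codon
  rows <- merge(data.frame(k = seq_len(m), codon = codons,
                           stringsAsFactors = FALSE),
                alts, by = "codon")
  if (!nrow(rows)) return(NULL)
  k <- rows$k
  prev <- c(NA_character_, codons)[k]          # codon k-1
  nxt <- c(codons, NA_character_)[k + 1L]      # codon k+1
  up_from <- ifelse(is.na(prev), NA_character_, paste0(prev, rows$codon))
  up_to <- ifelse(is.na(prev), NA_character_, paste0(prev, rows$alt_codon))
  dn_from <- ifelse(is.na(nxt), NA_character_, paste0(rows$codon, nxt))
  dn_to <- ifelse(is.na(nxt), NA_character_, paste0(rows$alt_codon, nxt))
  dpi_up <- abs(pi_tab[up_to] - pi_tab[up_from])
  dpi_dn <- abs(pi_tab[dn_to] - pi_tab[dn_from])
  best <- pmax(dpi_up, dpi_dn, na.rm = TRUE)
  ok <- !is.na(best) & is.finite(best)
  if (!any(ok)) return(NULL)
  data.frame(cds_id = cds_id,
             position = (k[ok] - 1L) * 3L + rows$offset[ok],
             ref = rows$ref_base[ok], alt = rows$alt_base[ok],
             best_abs_dpi = unname(best[ok]), stringsAsFactors = FALSE)
}
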
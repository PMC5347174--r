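# Per-corpus codon/bicodon counting and the bicodon-bias statistics:
# Fisher exact p-values, codon-bias-corrected residual scores (chi-squared),
# relative synonymous bicodon usage (RSBU) and the pause propensity pi.

#' Count codons and bicodons in a coding-sequence corpus
#'
#' Sequences are read in frame 0. Bicodons are the overlapping in-frame codon
#' pairs (codon k, codon k+1). Codons containing a non-ACGT character are
#' skipped, as is any bicodon touching such a codon or having a stop codon in
#' its P-site (first) position. Sequences whose length is not a multiple of 3
#' are skipped entirely with a warning.
#'
#' @param sequences Named character vector of nucleotide sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param label Corpus tag, conventionally `"L"` (low protein abundance) or
#'   `"H"` (high).
#' @return An object of class `sample_counts`: a list with `label`,
#'   `bicodon_counts` (named integer vector over the 3,904-bicodon universe),
#'   `codon_counts` (named, all 64 codons), `aa_pair_totals` (420 pairs),
#'   `aa_totals` (20 amino acids + stop), `n_codons_total`,
#'   `n_bicodons_total` and `n_sequences`.
#' @examples
#' cc <- count_corpus(c(g1 = "ATGAGTAAGTAA"), label = "L")
#' cc$bicodon_counts[c("ATGAGT", "AGTAAG", "AAGTAA")]
#' @export
count_corpus <- function(sequences, label = "X") {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- toupper(as.character(sequences))
  n_in <- length(sequences)
  ok_len <- nchar(sequences) %% 3L == 0L & nchar(sequences) > 0L
  if (any(!ok_len)) {
    warning(sum(!ok_len), " sequence(s) skipped: length not a positive multiple of 3")
  }
  sequences <- sequences[ok_len]

  u <- .codon_env$universe
  codon_levels <- .codon_env$codons
  stops <- setdiff(codon_levels, .codon_env$sense)

  all_codons_vec <- character(0)
  all_bicodons_vec <- character(0)
  if (length(sequences)) {
    codon_lists <- lapply(sequences, function(s) {
      n <- nchar(s)
      substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    })
    all_codons_vec <- unlist(codon_lists, use.names = FALSE)
    bic <- lapply(codon_lists, function(cs) {
      if (length(cs) < 2L) return(character(0))
      paste0(cs[-length(cs)], cs[-1L])
    })
    all_bicodons_vec <- unlist(bic, use.names = FALSE)
  }

  valid_codon <- all_codons_vec %in% codon_levels
  codon_counts <- table(factor(all_codons_vec[valid_codon], levels = codon_levels))
  codon_counts <- stats::setNames(as.integer(codon_counts), codon_levels)

  # bicodons must be in the universe: both codons ACGT-only, P-site sense
  in_univ <- all_bicodons_vec %in% u$hexamer
  n_stop_p <- sum(substr(all_bicodons_vec, 1L, 3L) %in% stops)
  if (n_stop_p > 0L) {
    warning(n_stop_p, " bicodon position(s) skipped: stop codon in P-site ",
            "(internal or terminal stop)")
  }
  bicodon_counts <- table(factor(all_bicodons_vec[in_univ], levels = u$hexamer))
  bicodon_counts <- stats::setNames(as.integer(bicodon_counts), u$hexamer)

  aa_of <- .codon_env$aa
  aa_totals <- tapply(codon_counts, aa_of[codon_levels], sum)
  aa_totals <- stats::setNames(as.integer(aa_totals), names(aa_totals))
  aa_pair_totals <- tapply(bicodon_counts, u$aa_pair[match(names(bicodon_counts), u$hexamer)], sum)
  # ensure all 420 pairs present
  full_pairs <- stats::setNames(integer(length(.codon_env$pairs)), .codon_env$pairs)
  full_pairs[names(aa_pair_totals)] <- as.integer(aa_pair_totals)

  structure(list(
    label = label,
    bicodon_counts = bicodon_counts,
    codon_counts = codon_counts,
    aa_pair_totals = full_pairs,
    aa_totals = aa_totals,
    n_codons_total = sum(codon_counts),
    n_bicodons_total = sum(bicodon_counts),
    n_sequences = length(sequences),
    n_sequences_skipped = n_in - length(sequences)
  ), class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("<sample_counts> corpus", x$label, "-", x$n_sequences, "sequences,",
      x$n_codons_total, "codons,", x$n_bicodons_total, "bicodons\n")
  invisible(x)
}

#' Two-sided Fisher exact test for bicodon (or codon) counts
#'
#' Tests whether the proportion of a k-mer differs between the low- and
#' high-abundance corpora, on the 2x2 table
#' \code{rbind(c(o_L, n_L - o_L), c(o_H, n_H - o_H))}. The preference sign S
#' is +1 when the low-abundance proportion is at least as large as the
#' high-abundance one, -1 otherwise.
#'
#' @param o_L,o_H Occurrences in the low-/high-abundance corpus (vectors
#'   allowed, recycled against each other).
#' @param n_L,n_H Corresponding corpus totals (margins).
#' @return A data.frame with columns `p_value` and `S`.
#' @export
fisher_bicodon_test <- function(o_L, n_L, o_H, n_H) {
  k <- max(length(o_L), length(o_H))
  o_L <- rep_len(as.numeric(o_L), k); o_H <- rep_len(as.numeric(o_H), k)
  n_L <- rep_len(as.numeric(n_L), k); n_H <- rep_len(as.numeric(n_H), k)
  if (any(n_L == 0) || any(n_H == 0)) stop("undefined test: a corpus margin is zero")
  if (any(o_L < 0 | o_H < 0 | o_L > n_L | o_H > n_H)) {
    stop("counts must satisfy 0 <= o <= n in each corpus")
  }
  p <- numeric(k)
  for (i in seq_len(k)) {
    if (o_L[i] == 0 && o_H[i] == 0) {
      p[i] <- 1
    } else {
      tab <- matrix(c(o_L[i], n_L[i] - o_L[i], o_H[i], n_H[i] - o_H[i]),
                    nrow = 2L, byrow = TRUE)
      p[i] <- stats::fisher.test(tab)$p.value
    }
  }
  p <- pmin(p, 1)
  S <- ifelse(o_L / n_L >= o_H / n_H, 1L, -1L)
  data.frame(p_value = p, S = S)
}

#' Residual scores: bicodon deviation from the codon-usage expectation
#'
#' For each bicodon ij, the expected count under independent codon usage is
#' e_ij = f_i f_j N_p / N_tot^2. Expectations are rescaled within each
#' amino-acid-pair family so that the family's expected total matches its
#' observed total, and the chi-squared residual (o - e_hat)^2 / e_hat is
#' returned. Large residuals flag bicodon bias not explained by codon bias.
#'
#' @param counts A `sample_counts` object.
#' @return Named numeric vector of chi-squared residuals over the bicodon
#'   universe. A bicodon with zero rescaled expectation has residual 0 when
#'   unobserved and `Inf` when observed.
#' @export
residual_scores <- function(counts) {
  stopifnot(inherits(counts, "sample_counts"))
  u <- .codon_env$universe
  o <- as.numeric(counts$bicodon_counts[u$hexamer])
  f <- stats::setNames(as.numeric(counts$codon_counts), names(counts$codon_counts))
  N_tot <- as.numeric(counts$n_codons_total)
  N_p <- as.numeric(counts$n_bicodons_total)
  if (N_tot == 0 || N_p == 0) {
    return(stats::setNames(numeric(nrow(u)), u$hexamer))
  }
  e <- f[u$p_codon] * f[u$a_codon] * N_p / N_tot^2
  fam_o <- tapply(o, u$aa_pair, sum)
  fam_e <- tapply(e, u$aa_pair, sum)
  scale <- ifelse(fam_e > 0, fam_o / fam_e, 0)
  e_hat <- e * scale[u$aa_pair]
  chi2 <- numeric(length(o))
  pos <- e_hat > 0
  chi2[pos] <- (o[pos] - e_hat[pos])^2 / e_hat[pos]
  chi2[!pos & o > 0] <- Inf
  stats::setNames(as.numeric(chi2), u$hexamer)
}

#' Bicodon statistics: pause propensity, Fisher tests and residual scores
#'
#' Combines the two corpora into a per-bicodon table. RSBU (relative
#' synonymous bicodon usage) is q * o_ij / N_ap, where q is the number of
#' bicodons encoding the same amino-acid pair and N_ap the family total; the
#' pause propensity pi is RSBU in the low-abundance corpus minus RSBU in the
#' high-abundance corpus, so positive values mark bicodons preferred by lowly
#' expressed genes.
#'
#' @param counts_L,counts_H `sample_counts` for the low-/high-abundance corpus.
#' @param rsbu_denominator `"per_sample"` (default) normalizes each corpus's
#'   RSBU by that corpus's own family total, which makes pi independent of
#'   corpus size and gives each family mean RSBU 1; `"pooled"` uses the summed
#'   family total of both corpora for both terms.
#' @param fisher_background `"all"` (default) tests each bicodon's count
#'   against all other bicodons in the corpus; `"same_pair"` restricts the
#'   margin to the bicodon's amino-acid-pair family.
#' @return A data.frame (one row per universe bicodon) with columns `hexamer`,
#'   `p_codon`, `a_codon`, `aa_pair`, `o_L`, `o_H`, `rsbu_L`, `rsbu_H`, `pi`,
#'   `p_value`, `S`, `signed_log_p`, `chi2_L`, `chi2_H`, `chi2_total`.
#'   `signed_log_p` is -S*log10(p), exactly 0 when p = 1. RSBU and pi are `NA`
#'   where a family is absent from the relevant corpus.
#' @export
pause_propensity <- function(counts_L, counts_H,
                             rsbu_denominator = c("per_sample", "pooled"),
                             fisher_background = c("all", "same_pair")) {
  stopifnot(inherits(counts_L, "sample_counts"), inherits(counts_H, "sample_counts"))
  rsbu_denominator <- match.arg(rsbu_denominator)
  fisher_background <- match.arg(fisher_background)
  u <- .codon_env$universe
  o_L <- counts_L$bicodon_counts[u$hexamer]
  o_H <- counts_H$bicodon_counts[u$hexamer]
  q <- u$q
  nap_L <- counts_L$aa_pair_totals[u$aa_pair]
  nap_H <- counts_H$aa_pair_totals[u$aa_pair]

  if (rsbu_denominator == "per_sample") {
    rsbu_L <- ifelse(nap_L > 0, q * o_L / nap_L, NA_real_)
    rsbu_H <- ifelse(nap_H > 0, q * o_H / nap_H, NA_real_)
  } else {
    nap <- nap_L + nap_H
    rsbu_L <- ifelse(nap > 0, q * o_L / nap, NA_real_)
    rsbu_H <- ifelse(nap > 0, q * o_H / nap, NA_real_)
  }
  pi <- rsbu_L - rsbu_H

  if (fisher_background == "all") {
    n_L <- rep(counts_L$n_bicodons_total, nrow(u))
    n_H <- rep(counts_H$n_bicodons_total, nrow(u))
  } else {
    n_L <- nap_L
    n_H <- nap_H
  }
  p_value <- rep(NA_real_, nrow(u))
  S <- rep(NA_integer_, nrow(u))
  testable <- n_L > 0 & n_H > 0
  if (any(testable)) {
    ft <- fisher_bicodon_test(o_L[testable], n_L[testable],
                              o_H[testable], n_H[testable])
    p_value[testable] <- ft$p_value
    S[testable] <- ft$S
  }
  signed_log_p <- ifelse(is.na(p_value) | p_value == 1, 0, -S * log10(p_value))
  signed_log_p[is.na(p_value)] <- NA_real_

  chi2_L <- residual_scores(counts_L)[u$hexamer]
  chi2_H <- residual_scores(counts_H)[u$hexamer]

  data.frame(
    hexamer = u$hexamer, p_codon = u$p_codon, a_codon = u$a_codon,
    aa_pair = u$aa_pair,
    o_L = as.integer(o_L), o_H = as.integer(o_H),
    rsbu_L = rsbu_L, rsbu_H = rsbu_H, pi = pi,
    p_value = p_value, S = S, signed_log_p = signed_log_p,
    chi2_L = as.numeric(chi2_L), chi2_H = as.numeric(chi2_H),
    chi2_total = as.numeric(chi2_L + chi2_H),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Codon statistics: RSCU, differential RSCU and Fisher tests
#'
#' RSCU (relative synonymous codon usage) is s * f_i / N_a, where s is the
#' codon's degeneracy and N_a the corpus total for its amino acid; 1 means
#' unbiased usage among synonyms. The differential RSCU is the low- minus
#' high-abundance value, the codon-level analogue of the pause propensity.
#'
#' @inheritParams pause_propensity
#' @param rscu_denominator As `rsbu_denominator` in [pause_propensity()].
#' @return A data.frame with one row per codon: `codon`, `aa`, `s`, `f_L`,
#'   `f_H`, `rscu_L`, `rscu_H`, `diff_rscu`, `p_value`, `S`, `signed_log_p`.
#' @export
rscu_stats <- function(counts_L, counts_H,
                       rscu_denominator = c("per_sample", "pooled")) {
  stopifnot(inherits(counts_L, "sample_counts"), inherits(counts_H, "sample_counts"))
  rscu_denominator <- match.arg(rscu_denominator)
  codons <- .codon_env$codons
  aa <- .codon_env$aa[codons]
  s <- .codon_env$degeneracy[aa]
  f_L <- counts_L$codon_counts[codons]
  f_H <- counts_H$codon_counts[codons]
  na_L <- counts_L$aa_totals[aa]
  na_H <- counts_H$aa_totals[aa]
  if (rscu_denominator == "per_sample") {
    rscu_L <- ifelse(na_L > 0, s * f_L / na_L, NA_real_)
    rscu_H <- ifelse(na_H > 0, s * f_H / na_H, NA_real_)
  } else {
    na <- na_L + na_H
    rscu_L <- ifelse(na > 0, s * f_L / na, NA_real_)
    rscu_H <- ifelse(na > 0, s * f_H / na, NA_real_)
  }
  diff_rscu <- rscu_L - rscu_H

  p_value <- rep(NA_real_, length(codons))
  S <- rep(NA_integer_, length(codons))
  if (counts_L$n_codons_total > 0 && counts_H$n_codons_total > 0) {
    ft <- fisher_bicodon_test(f_L, counts_L$n_codons_total,
                              f_H, counts_H$n_codons_total)
    p_value <- ft$p_value
    S <- ft$S
  }
  signed_log_p <- ifelse(is.na(p_value) | p_value == 1, 0, -S * log10(p_value))
  signed_log_p[is.na(p_value)] <- NA_real_

  data.frame(
    codon = codons, aa = unname(aa), s = unname(as.integer(s)),
    f_L = as.integer(f_L), f_H = as.integer(f_H),
    rscu_L = unname(rscu_L), rscu_H = unname(rscu_H),
    diff_rscu = unname(diff_rscu),
    p_value = p_value, S = S, signed_log_p = signed_log_p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
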
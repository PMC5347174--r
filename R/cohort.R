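# Per-SNP summaries and the pathological-vs-benign group comparison.

#' Summarize variant scores per SNP
#'
#' Each SNP has one or two scored bicodon changes; the summary keeps the
#' change with the largest quantile score, breaking ties by larger
#' |delta pi| and then by lexicographic `from_hex`.
#'
#' @param scores Data.frame from [score_snps()].
#' @return A data.frame with one row per SNP: `snp_id`, `group`,
#'   `change_which`, `from_hex`, `to_hex`, `best_z_bicodon`,
#'   `best_abs_delta_pi`, `best_delta_pi`, `z_codon`, `diff_rscu`. SNPs with
#'   no scorable bicodon change carry `NA` in the bicodon columns.
#' @export
summarize_snps <- function(scores) {
  stopifnot(is.data.frame(scores))
  split_idx <- split(seq_len(nrow(scores)), scores$snp_id)
  # preserve first-appearance order of snp_id
  split_idx <- split_idx[unique(scores$snp_id)]
  rows <- lapply(split_idx, function(idx) {
    sub <- scores[idx, , drop = FALSE]
    scorable <- !is.na(sub$z_bicodon)
    if (!any(scorable)) {
      best <- sub[1L, , drop = FALSE]
      best$change_which <- NA_character_
    } else {
      cand <- sub[scorable, , drop = FALSE]
      ord <- order(-cand$z_bicodon, -cand$abs_delta_pi, cand$from_hex)
      best <- cand[ord[1L], , drop = FALSE]
    }
    data.frame(snp_id = best$snp_id, group = best$group,
               change_which = best$change_which,
               from_hex = best$from_hex, to_hex = best$to_hex,
               best_z_bicodon = best$z_bicodon,
               best_abs_delta_pi = best$abs_delta_pi,
               best_delta_pi = best$delta_pi,
               z_codon = best$z_codon, diff_rscu = best$diff_rscu,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Compare two SNP groups with the Mann-Whitney U test
#'
#' Two-sided rank test (normal approximation with tie correction and
#' continuity correction) of the chosen per-SNP or per-variant values between
#' two groups, typically pathological vs benign synonymous SNPs.
#'
#' @param summaries Data.frame from [summarize_snps()] (for `unit = "snp"`)
#'   or from [score_snps()] (for `unit = "variant"`).
#' @param measure `"bicodon"` (pause-propensity based, default) or `"codon"`
#'   (differential-RSCU based).
#' @param compare_on `"abs_delta_pi"` (default) compares the magnitudes
#'   themselves; `"z_score"` compares their null quantiles. When both groups
#'   are ranked against the same null, the two choices give identical rank
#'   tests (the quantile map is monotone).
#' @param unit `"snp"` (default, one value per SNP — the max-quantile change)
#'   or `"variant"` (one value per scored bicodon change).
#' @param groups Character vector of the two group labels to compare, in the
#'   order (group1, group2); defaults to `c("pathological", "benign")`.
#' @return An object of class `group_comparison`: list with `measure`,
#'   `compare_on`, `unit`, `n1`, `n2`, `u_statistic` (U of group1) and
#'   `p_value`.
#' @export
compare_groups <- function(summaries,
                           measure = c("bicodon", "codon"),
                           compare_on = c("abs_delta_pi", "z_score"),
                           unit = c("snp", "variant"),
                           groups = c("pathological", "benign")) {
  measure <- match.arg(measure)
  compare_on <- match.arg(compare_on)
  unit <- match.arg(unit)
  stopifnot(length(groups) == 2L)

  if (unit == "snp") {
    col <- switch(paste(measure, compare_on),
                  "bicodon abs_delta_pi" = "best_abs_delta_pi",
                  "bicodon z_score" = "best_z_bicodon",
                  "codon abs_delta_pi" = "diff_rscu",
                  "codon z_score" = "z_codon")
  } else {
    col <- switch(paste(measure, compare_on),
                  "bicodon abs_delta_pi" = "abs_delta_pi",
                  "bicodon z_score" = "z_bicodon",
                  "codon abs_delta_pi" = "diff_rscu",
                  "codon z_score" = "z_codon")
  }
  if (!col %in% names(summaries)) stop("column not found: ", col)
  val <- summaries[[col]]
  if (measure == "codon" && compare_on == "abs_delta_pi") val <- abs(val)

  x <- val[summaries$group == groups[1L] & !is.na(val)]
  y <- val[summaries$group == groups[2L] & !is.na(val)]
  if (!length(x) || !length(y)) {
    stop("both groups must be nonempty (", groups[1L], ": ", length(x),
         ", ", groups[2L], ": ", length(y), ")")
  }
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  structure(list(measure = measure, compare_on = compare_on, unit = unit,
                 groups = groups, n1 = length(x), n2 = length(y),
                 u_statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> measure =", x$measure, "on", x$compare_on,
      "per", x$unit, "\n ", x$groups[1L], "(n =", paste0(x$n1, ")"), "vs",
      x$groups[2L], "(n =", paste0(x$n2, ")"), "\n  U =",
      format(x$u_statistic), " two-sided p =", format(x$p_value), "\n")
  invisible(x)
}
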
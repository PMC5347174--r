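# End-to-end pipeline: simulate (or read) two corpora, count, compute the
# bicodon and codon statistics, build the nulls, score a SNP cohort and
# compare groups. Each stage writes its TSV products so partial runs can be
# inspected; a YAML manifest records the configuration and seed.

#' Run the full bicodon-bias analysis pipeline
#'
#' Either supply two coding-sequence corpora (and optionally a SNP table)
#' or let the synthetic generator produce corpora and a labelled cohort.
#'
#' Outputs written to `out_dir`: `corpus_low.fasta` / `corpus_high.fasta`
#' (when simulated), `bicodon_stats.tsv`, `codon_stats.tsv`, `snps.tsv` (when
#' simulated), `variant_scores.tsv`, `cohort_report.tsv`, `comparison.txt`
#' and `manifest.yaml`.
#'
#' @param out_dir Output directory (created if missing).
#' @param fasta_low,fasta_high Optional paths to the low-/high-abundance CDS
#'   FASTA files; when `NULL`, corpora are simulated from `gen_config`.
#' @param snps Optional SNP data.frame (see [read_snps()]) or path to a SNP
#'   TSV; when `NULL` and corpora are simulated, a synthetic cohort is drawn
#'   from `coh_config`.
#' @param cds Optional named character vector / DNAStringSet / FASTA path
#'   with the host CDSs of `snps` (defaults to the low-abundance corpus).
#' @param gen_config A [generator_config()].
#' @param coh_config A [cohort_config()].
#' @param rsbu_denominator,fisher_background Passed to [pause_propensity()].
#' @param compare_on,unit Passed to [compare_groups()].
#' @return A list with `bicodon_stats`, `codon_stats`, `null_bicodon`,
#'   `null_codon`, `scores`, `summaries`, `comparison_bicodon`,
#'   `comparison_codon` (the comparisons are `NULL` when no two-group cohort
#'   was scored), invisibly.
#' @export
run_pipeline <- function(out_dir,
                         fasta_low = NULL, fasta_high = NULL,
                         snps = NULL, cds = NULL,
                         gen_config = generator_config(),
                         coh_config = cohort_config(),
                         rsbu_denominator = "per_sample",
                         fisher_background = "all",
                         compare_on = "abs_delta_pi", unit = "snp") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(fasta_low) || is.null(fasta_high)
  if (simulated) {
    message("simulating corpora (", gen_config$n_sequences,
            " sequences/corpus, seed ", gen_config$seed, ")")
    corp <- generate_corpora(gen_config)
    low <- corp$low; high <- corp$high
    write_cds_fasta(low, file.path(out_dir, "corpus_low.fasta"))
    write_cds_fasta(high, file.path(out_dir, "corpus_high.fasta"))
  } else {
    low <- read_cds_fasta(fasta_low)
    high <- read_cds_fasta(fasta_high)
  }

  counts_L <- count_corpus(low, "L")
  counts_H <- count_corpus(high, "H")
  bstats <- pause_propensity(counts_L, counts_H,
                             rsbu_denominator = rsbu_denominator,
                             fisher_background = fisher_background)
  cstats <- rscu_stats(counts_L, counts_H,
                       rscu_denominator = rsbu_denominator)
  write_tsv(bstats, file.path(out_dir, "bicodon_stats.tsv"))
  write_tsv(cstats, file.path(out_dir, "codon_stats.tsv"))

  null_b <- build_null(bstats, "bicodon")
  null_c <- build_null(cstats, "codon")

  if (is.null(snps) && simulated) {
    coh <- generate_cohort(coh_config, low, bstats, null_b)
    snps <- coh$snps
    cds_set <- coh$cds
    write_tsv(snps, file.path(out_dir, "snps.tsv"))
  } else if (!is.null(snps)) {
    if (is.character(snps) && length(snps) == 1L) snps <- read_snps(snps)
    cds_set <- if (is.null(cds)) low
               else if (is.character(cds) && length(cds) == 1L && file.exists(cds))
                 read_cds_fasta(cds)
               else cds
  } else {
    snps <- NULL
    cds_set <- NULL
  }

  scores <- NULL; summaries <- NULL; cmp_b <- NULL; cmp_c <- NULL
  if (!is.null(snps)) {
    scores <- score_snps(snps, cds_set, bstats, cstats, null_b, null_c)
    summaries <- summarize_snps(scores)
    write_tsv(scores, file.path(out_dir, "variant_scores.tsv"))
    write_tsv(summaries, file.path(out_dir, "cohort_report.tsv"))
    grp <- unique(summaries$group)
    if (length(grp) == 2L) {
      grp <- if (all(c("pathological", "benign") %in% grp))
        c("pathological", "benign") else sort(grp)
      cmp_b <- compare_groups(summaries, "bicodon", compare_on, unit, grp)
      cmp_c <- compare_groups(summaries, "codon", compare_on, unit, grp)
      con <- file(file.path(out_dir, "comparison.txt"), "w")
      on.exit(close(con), add = TRUE)
      for (cmp in list(cmp_b, cmp_c)) {
        writeLines(sprintf(
          "measure=%s compare_on=%s unit=%s n_%s=%d n_%s=%d U=%.6g p=%.6g",
          cmp$measure, cmp$compare_on, cmp$unit, cmp$groups[1], cmp$n1,
          cmp$groups[2], cmp$n2, cmp$u_statistic, cmp$p_value), con)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bicodon")),
    simulated = simulated,
    generator = if (simulated) unclass(gen_config)[
      c("n_sequences", "mean_length", "length_dispersion", "seed")] else NULL,
    planted_bias = if (simulated && nrow(gen_config$planted_bias))
      gen_config$planted_bias else NULL,
    cohort = if (simulated && !is.null(snps)) unclass(coh_config) else NULL,
    options = list(rsbu_denominator = rsbu_denominator,
                   fisher_background = fisher_background,
                   compare_on = compare_on, unit = unit))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(bicodon_stats = bstats, codon_stats = cstats,
                 null_bicodon = null_b, null_codon = null_c,
                 scores = scores, summaries = summaries,
                 comparison_bicodon = cmp_b, comparison_codon = cmp_c))
}
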
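---
title: "Bicodon usage bias and pause-propensity scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bicodon usage bias and pause-propensity scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model implemented by **bicodon**, the
normalization and tie-breaking choices that were genuinely open when the
package was designed, and what the synthetic-data generator does and does not
emulate.

## The measures

Consecutive in-frame codons form overlapping **bicodons**: the codon in the
ribosomal P site followed by the codon in the A site, one hexanucleotide.
Stop codons terminate translation, so the bicodon universe admits a stop only
in the A-site position: 61 sense P-site codons times 64 A-site codons gives
3,904 bicodons covering 20 x 21 = 420 amino-acid pairs (residue:stop
included).

Given two corpora of coding sequences — low protein abundance (L) and high
(H) — the package computes per bicodon $ij$ (P-site codon $i$, A-site codon
$j$):

**Relative synonymous bicodon usage.** With $o_{ij}$ the bicodon count,
$N_{ap}$ the total count of its amino-acid-pair family and $q$ the number of
bicodons encoding that pair,

$$\mathrm{RSBU}_{ij} = q\, o_{ij} / N_{ap},$$

so unbiased usage gives RSBU = 1 and each family's RSBU values average to 1
exactly — the bicodon analogue of RSCU ($\mathrm{RSCU}_i = s f_i / N_a$ with
$s$ the codon degeneracy).

**Pause propensity.** $\pi_{ij} = \mathrm{RSBU}^L_{ij} -
\mathrm{RSBU}^H_{ij}$. Sequences encoding abundant proteins are presumed
optimized for fast elongation, so a bicodon over-represented in the
low-abundance corpus ($\pi > 0$) is read as pause-prone. $\pi$ is bounded by
$\pm q$ and antisymmetric under swapping the corpora.

**Fisher exact test.** Each bicodon's counts are tested on the 2x2 table of
(count, all other bicodons) x (L, H), two-sided. The preference sign $S$ is
+1 when the L-proportion is at least the H-proportion, and the signed log
p-value $-S \log_{10} p$ (exactly 0 at $p = 1$) summarizes direction and
strength for visualization and for the relative p-change statistic.

**Residual score.** Bicodon bias could be a shadow of codon bias. The
expected count under independent codon usage is
$e_{ij} = f_i f_j N_p / N_{tot}^2$; expectations are rescaled within each
synonymous family so that $\sum^* \hat e = \sum^* o$ (sums over the family),
and $\chi^2_{ij} = (o_{ij} - \hat e_{ij})^2 / \hat e_{ij}$ is computed per
corpus and summed, $\chi^2 = \chi^2_L + \chi^2_H$. Large values flag pair
preferences beyond what the two codons' individual frequencies explain.

## Scoring synonymous variants

A synonymous SNP sits in one codon and therefore touches up to two bicodons
(upstream: SNP codon in the A site; downstream: SNP codon in the P site).
For each change the package computes $\Delta\pi = \pi_{\text{alt}} -
\pi_{\text{ref}}$ and ranks $|\Delta\pi|$ against the **null of all
enumerable single-point synonymous variants**: unordered pairs of distinct
bicodons that encode the same amino-acid pair and differ at exactly one of
the six positions. Over the standard code there are 26,718 synonymous
bicodon variants, of which 8,497 are single-point — these form the null. The
"Z-score" is the inclusive empirical CDF value: the fraction of null values
$\le$ the observed magnitude, so the null's maximum maps to exactly 1 and
values below the minimum to 0. The codon-level analogue ranks the change in
differential RSCU against the 69 single-point synonymous codon variants.

Design choices made here, where more than one reading was defensible:

- **Absolute vs signed change.** The null and quantile scores use
  $|\Delta\pi|$; a variant is an unordered exchange and its worked magnitude
  (e.g. 1.04 for the serine wobble change AGTAAG to AGCAAG with $\pi$ 0.14
  and -0.90) is direction-free. The signed $\Delta\pi$ (ref to alt) is kept
  in the output for directional interpretation.
- **Null membership.** All 8,497 enumerable variants enter the null, not
  only those observed in the corpora; variants with an undefined $\pi$ on
  either side (family absent from a corpus) are dropped with a logged count.
  With corpora of realistic size the drop count is 0.
- **Coordinates.** SNP positions are 1-based on the CDS, as in variant
  tables; codon index is `(pos - 1) %/% 3`. Inputs must be CDS-oriented;
  strand is out of scope.

## Group comparison

Per SNP, the change with the larger quantile score is kept (ties: larger
$|\Delta\pi|$, then lexicographic hexamer), and groups are compared with the
two-sided Mann–Whitney U test on the per-SNP $|\Delta\pi|$ (normal
approximation with tie and continuity correction — standard at cohort sizes
of tens of SNPs; the test suite documents its agreement with exact
permutation enumeration: within 0.035 without ties at group sizes 4–8,
within 0.15 under heavy ties). Because the quantile map against a shared
null is strictly monotone, comparing on quantile scores instead of
magnitudes yields the identical rank test; both are exposed
(`compare_on = "abs_delta_pi" | "z_score"`), as are per-SNP vs per-variant
units.

## Open normalization questions and their defaults

- **RSBU denominator** (`rsbu_denominator`). $\pi$ subtracts RSBU values
  computed on two different corpora. The default, `per_sample`, normalizes
  each corpus by its own family total $N^X_{ap}$: each RSBU is then an
  internally normalized usage index (family mean exactly 1), $\pi$ is
  independent of corpus sizes, and the $\sum \mathrm{RSBU} = q$ identity
  holds per corpus — this is the normalization the test suite asserts. The
  alternative `pooled` divides both terms by the summed family total, making
  $\pi$ sensitive to the L:H size ratio; it is retained for sensitivity
  analysis.
- **Fisher margins** (`fisher_background`). The default `all` tests a
  bicodon's count against all other bicodons of the corpus — a
  global-proportion reading of "more frequent in L than in H". `same_pair`
  restricts the margin to the bicodon's synonymous family, testing usage
  *within* the family instead. Note that under `all`, the proportion-based
  sign $S$ can disagree with the family-normalized $\pi$ for rare
  configurations; under `same_pair` the two always agree, which the test
  suite asserts.

## Degenerate inputs and numerical conventions

- Sequences whose length is not a multiple of 3 are skipped with a warning;
  codons containing non-ACGT characters are excluded, as is any bicodon
  touching them.
- A stop codon never occupies a P site: bicodons downstream of an internal
  stop's P-site position are excluded (warned), but counting resumes at the
  next position. CDSs are not required to start with ATG or end with a stop.
- No pseudocounts anywhere. A bicodon absent from both corpora has
  $p = 1$, $S = +1$, and $\pi = 0$ if its family is present, `NA` otherwise;
  `NA` propagates to scores rather than being silently zeroed.
- $\hat e = 0$ with $o > 0$ yields an infinite residual (flagged, not
  capped); $\hat e = 0$ with $o = 0$ yields $\chi^2 = 0$.
- Empirical CDFs count ties in the lower tail (`<=`), making the quantile
  score surjective onto $\{1/n, \dots, 1\}$ on the null's own values.

## The synthetic-data generator

Corpora are generated as ATG + i.i.d. amino acids realized as codons + one
stop. Codon choice within an amino acid follows configurable weights
(default uniform); amino-acid composition is configurable (default uniform
over the 20 residues). A planted bias `(bicodon, corpus, r)` multiplies the
target bicodon's expected relative frequency *within its family* by exactly
$r$, by reweighting the A-site codon conditional on the P-site codon: the
target's conditional probability $q_t$ becomes $r q_t$ and the other codons
share the remainder proportionally. This first-order-Markov construction is
exact (no rejection sampling) and mirrors the P-to-A-site mechanism being
modelled. Requests with $r q_t \ge 1$ are clipped with a warning — e.g.
uniform usage of a 6-codon family supports $r \le 6$. Corpus L and H consume
independent sub-seeds derived from the master seed, so resizing or biasing
one corpus leaves the other's draw untouched.

Synthetic cohorts scan pool sequences for all synonymous single-base
substitutions, score each site's best $|\Delta\pi|$, then draw the
"pathological" group from candidates in the null's top decile
(`top_quantile = 0.9`) and the "benign" group uniformly from all candidates.
Every emitted record satisfies the SNP contracts (reference match, synonymy,
bounds) by construction.

The generator's default study conditions — 2,000 sequences per corpus, mean
length 300 codons (negative-binomially dispersed, size 10), enrichment
factors spanning 2–8, cohorts of 20 pathological vs 60 benign SNPs — are the
conditions under which the test suite demonstrates parameter recovery:
planted signs recovered, $|\pi|$ monotone in $r$, and a bicodon-measure
Mann–Whitney p below 0.05 with the codon measure typically uninformative.
Unit tests use smaller corpora (tens to hundreds of sequences, 25–80 codons)
where only distribution-free properties are asserted.

What the generator does **not** emulate: real human codon and codon-pair
usage (composition is uniform unless configured), gene-length and
GC-content heterogeneity, splicing signals, mRNA secondary structure, miRNA
binding sites, and actual protein-abundance distributions. Passing tests
therefore demonstrate that the estimators recover planted contrasts of the
modelled kind — not that any particular biological corpus exhibits them.

## Known limitations

- Triplets of codons (E/P/A-site context) are deliberately out of scope.
- Fisher p-values on overlapping bicodon counts treat draws as independent;
  as in the underlying methodology, p-values are used as a ranking and
  visualization device rather than as calibrated genome-wide error rates.
- The normal-approximation Mann–Whitney is inaccurate for group sizes below
  about 5 with many ties; the exact test is preferable there (the package
  targets cohorts of tens of SNPs).
- Selecting low/high-abundance gene sets from an abundance database is
  upstream of this package: inputs are whatever two corpora the user
  contrasts.
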
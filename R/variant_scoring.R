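# Mapping synonymous SNPs to their bicodon changes and scoring the change in
# pause propensity against the empirical null of all single-point synonymous
# bicodon variants.
#
# A SNP sits in one codon, and that codon belongs to (up to) two overlapping
# bicodons: one with the codon in the A-site (upstream bicodon) and one with
# it in the P-site (downstream bicodon). Both changes are scored; the
# "Z-score" here is the empirical cumulative-distribution quantile of
# |delta pi| among the 8,497 single-point synonymous variants, in [0, 1] —
# not a standardized normal deviate.

#' Construct and validate a synonymous-SNP record
#'
#' @param snp_id Identifier (e.g. an rsID).
#' @param cds_id Identifier of the host coding sequence.
#' @param position 1-based position of the substituted nucleotide on the CDS.
#' @param ref,alt Reference and alternate bases (single characters, distinct).
#' @param group Group label, e.g. `"pathological"`, `"benign"`.
#' @return A list of class `snp_record`.
#' @export
snp_record <- function(snp_id, cds_id, position, ref, alt, group = "unlabelled") {
  position <- as.integer(position)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (is.na(position) || position < 1L) stop("position must be a positive integer")
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
    stop("ref and alt must be single bases over A/C/G/T")
  }
  if (ref == alt) stop("ref and alt must differ")
  structure(list(snp_id = as.character(snp_id), cds_id = as.character(cds_id),
                 position = position, ref = ref, alt = alt,
                 group = as.character(group)),
            class = "snp_record")
}

#' Read a SNP table
#'
#' Expects a tab-separated file with header columns
#' `snp_id  cds_id  position  ref  alt  group`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with those columns, `position` integer.
#' @export
read_snps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  need <- c("snp_id", "cds_id", "position", "ref", "alt", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SNP table is missing column(s): ", paste(miss, collapse = ", "))
  df$position <- as.integer(df$position)
  df[need]
}

#' Map a synonymous SNP to its bicodon and codon changes
#'
#' @param snp A `snp_record` (or a list/one-row data.frame with the same
#'   fields).
#' @param cds The host coding sequence (character string, in-frame).
#' @return A list with `codon_index` (1-based), `from_codon`, `to_codon`, and
#'   `changes`: a data.frame of 1 or 2 rows with columns `which`
#'   (`"upstream"` = SNP codon in the A-site, `"downstream"` = SNP codon in
#'   the P-site), `from_hex`, `to_hex`. Candidates whose bicodons fall outside
#'   the universe (stop in the P-site) or outside the CDS are omitted.
#' @export
snp_to_changes <- function(snp, cds) {
  if (is.data.frame(snp)) snp <- as.list(snp[1L, ])
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length is not a multiple of 3")
  pos <- as.integer(snp$position)
  if (is.na(pos) || pos < 1L || pos > n) {
    stop("position ", snp$position, " outside CDS of length ", n)
  }
  ref <- toupper(snp$ref); alt <- toupper(snp$alt)
  if (substr(cds, pos, pos) != ref) {
    stop("reference mismatch at position ", pos, ": CDS has ",
         substr(cds, pos, pos), ", record says ", ref)
  }
  k0 <- (pos - 1L) %/% 3L                      # 0-based codon index
  codon_start <- k0 * 3L + 1L
  from_codon <- substr(cds, codon_start, codon_start + 2L)
  offset <- pos - codon_start + 1L
  to_codon <- from_codon
  substr(to_codon, offset, offset) <- alt
  if (translate_codon(from_codon) != translate_codon(to_codon)) {
    stop("substitution is not synonymous: ", from_codon, " (",
         translate_codon(from_codon), ") -> ", to_codon, " (",
         translate_codon(to_codon), ")")
  }
  n_codons <- n %/% 3L
  univ <- .codon_env$universe$hexamer
  rows <- list()
  if (k0 >= 1L) {
    prev <- substr(cds, codon_start - 3L, codon_start - 1L)
    from_hex <- paste0(prev, from_codon)
    to_hex <- paste0(prev, to_codon)
    if (from_hex %in% univ && to_hex %in% univ) {
      rows[[length(rows) + 1L]] <- data.frame(
        which = "upstream", from_hex = from_hex, to_hex = to_hex,
        stringsAsFactors = FALSE)
    }
  }
  if (k0 + 1L <= n_codons - 1L) {
    nxt <- substr(cds, codon_start + 3L, codon_start + 5L)
    from_hex <- paste0(from_codon, nxt)
    to_hex <- paste0(to_codon, nxt)
    if (from_hex %in% univ && to_hex %in% univ) {
      rows[[length(rows) + 1L]] <- data.frame(
        which = "downstream", from_hex = from_hex, to_hex = to_hex,
        stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(which = character(), from_hex = character(),
               to_hex = character(), stringsAsFactors = FALSE)
  list(codon_index = k0 + 1L, from_codon = from_codon, to_codon = to_codon,
       changes = changes)
}

#' Build the empirical null distribution of |delta pi| (or |delta RSCU|)
#'
#' Enumerates all single-point (Hamming distance 1) synonymous variants of the
#' bicodon universe (or, for `kind = "codon"`, of the 64 codons) and collects
#' the absolute change of the pause propensity (or differential RSCU) across
#' each variant. Variants with a missing value on either side are dropped with
#' a message.
#'
#' @param stats For `kind = "bicodon"`, the data.frame from
#'   [pause_propensity()]; for `kind = "codon"`, the one from [rscu_stats()].
#' @param kind `"bicodon"` or `"codon"`.
#' @return An object of class `null_distribution`: list with sorted `values`,
#'   `kind`, `n_variants` (enumerated), `n_dropped` (missing on either side).
#' @export
build_null <- function(stats, kind = c("bicodon", "codon")) {
  kind <- match.arg(kind)
  if (!is.data.frame(stats) || nrow(stats) == 0L) stop("empty stats table")
  if (kind == "bicodon") {
    if (!all(c("hexamer", "pi") %in% names(stats))) {
      stop("bicodon stats must have columns 'hexamer' and 'pi'")
    }
    ev <- enumerate_synonymous_variants(min_hamming = 1L, max_hamming = 1L)
    val <- stats$pi[match(ev$from_hex, stats$hexamer)] -
           stats$pi[match(ev$to_hex, stats$hexamer)]
  } else {
    if (!all(c("codon", "diff_rscu") %in% names(stats))) {
      stop("codon stats must have columns 'codon' and 'diff_rscu'")
    }
    ev <- .enumerate_codon_variants()
    val <- stats$diff_rscu[match(ev$from, stats$codon)] -
           stats$diff_rscu[match(ev$to, stats$codon)]
  }
  keep <- !is.na(val)
  if (any(!keep)) {
    message(sum(!keep), " of ", length(val),
            " enumerated variants dropped from the ", kind,
            " null (missing value on one side)")
  }
  structure(list(values = sort(abs(val[keep])), kind = kind,
                 n_variants = length(val), n_dropped = sum(!keep)),
            class = "null_distribution")
}

# Unordered pairs of distinct synonymous codons at Hamming distance 1.
.enumerate_codon_variants <- function() {
  codons <- .codon_env$codons
  aa <- .codon_env$aa[codons]
  fams <- split(codons, aa)
  out <- list()
  for (fam in fams) {
    if (length(fam) < 2L) next
    cb <- utils::combn(length(fam), 2L)
    from <- fam[cb[1L, ]]; to <- fam[cb[2L, ]]
    d <- hamming_distance(from, to)
    keep <- d == 1L
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(from = from[keep], to = to[keep],
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$kind, "-", length(x$values),
      "values (", x$n_dropped, "dropped )\n")
  invisible(x)
}

#' Empirical quantile score against a null distribution
#'
#' Returns the empirical cumulative-distribution value: the fraction of null
#' values less than or equal to `x` (ties counted in the lower tail, so the
#' null's maximum maps to exactly 1).
#'
#' @param x Numeric vector of non-negative magnitudes.
#' @param null A `null_distribution`.
#' @return Numeric vector of quantiles in [0, 1].
#' @export
z_score <- function(x, null) {
  stopifnot(inherits(null, "null_distribution"))
  v <- null$values
  if (!length(v)) stop("null distribution is empty")
  findInterval(x, v) / length(v)
}

#' Score a synonymous SNP
#'
#' Maps the SNP to its bicodon and codon changes and evaluates, for each
#' bicodon change, the pause-propensity change delta pi = pi(alt bicodon) -
#' pi(ref bicodon), its magnitude, the quantile of that magnitude in the
#' single-point-variant null, and the relative change of the signed log
#' Fisher p-value; plus, for the codon change, the differential-RSCU change
#' and its quantile in the codon null.
#'
#' @param snp A `snp_record` (or compatible list / one-row data.frame).
#' @param cds Host coding sequence (character).
#' @param bicodon_stats Data.frame from [pause_propensity()].
#' @param codon_stats Data.frame from [rscu_stats()].
#' @param null_bicodon,null_codon `null_distribution` objects from
#'   [build_null()].
#' @return A data.frame with one row per bicodon change: `snp_id`, `cds_id`,
#'   `group`, `codon_index`, `change_which`, `from_hex`, `to_hex`, `delta_pi`,
#'   `abs_delta_pi`, `z_bicodon`, `from_codon`, `to_codon`, `diff_rscu`
#'   (change of the differential RSCU, alt minus ref codon), `z_codon`,
#'   `rel_signed_log_p_change` (`NA` when the reference bicodon's signed log p
#'   is 0 or missing).
#' @export
score_snp <- function(snp, cds, bicodon_stats, codon_stats,
                      null_bicodon, null_codon) {
  if (is.data.frame(snp)) snp <- as.list(snp[1L, ])
  mapped <- snp_to_changes(snp, cds)
  ch <- mapped$changes

  # codon-level change (single per SNP)
  d_rscu_tab <- stats::setNames(codon_stats$diff_rscu, codon_stats$codon)
  d_rscu <- unname(d_rscu_tab[mapped$to_codon] - d_rscu_tab[mapped$from_codon])
  z_c <- if (!is.na(d_rscu)) z_score(abs(d_rscu), null_codon) else NA_real_

  if (nrow(ch) == 0L) {
    return(data.frame(
      snp_id = snp$snp_id, cds_id = snp$cds_id, group = snp$group,
      codon_index = mapped$codon_index, change_which = NA_character_,
      from_hex = NA_character_, to_hex = NA_character_,
      delta_pi = NA_real_, abs_delta_pi = NA_real_, z_bicodon = NA_real_,
      from_codon = mapped$from_codon, to_codon = mapped$to_codon,
      diff_rscu = d_rscu, z_codon = z_c,
      rel_signed_log_p_change = NA_real_, stringsAsFactors = FALSE))
  }

  pi_tab <- stats::setNames(bicodon_stats$pi, bicodon_stats$hexamer)
  slp_tab <- stats::setNames(bicodon_stats$signed_log_p, bicodon_stats$hexamer)
  delta_pi <- unname(pi_tab[ch$to_hex] - pi_tab[ch$from_hex])
  abs_dpi <- abs(delta_pi)
  z_b <- ifelse(is.na(abs_dpi), NA_real_, z_score(abs_dpi, null_bicodon))
  pv_i <- unname(slp_tab[ch$from_hex]); pv_f <- unname(slp_tab[ch$to_hex])
  rel <- ifelse(is.na(pv_i) | is.na(pv_f) | pv_i == 0, NA_real_,
                (pv_f - pv_i) / pv_i)

  data.frame(
    snp_id = snp$snp_id, cds_id = snp$cds_id, group = snp$group,
    codon_index = mapped$codon_index, change_which = ch$which,
    from_hex = ch$from_hex, to_hex = ch$to_hex,
    delta_pi = delta_pi, abs_delta_pi = abs_dpi, z_bicodon = z_b,
    from_codon = mapped$from_codon, to_codon = mapped$to_codon,
    diff_rscu = d_rscu, z_codon = z_c,
    rel_signed_log_p_change = rel, stringsAsFactors = FALSE)
}

#' Score a table of synonymous SNPs
#'
#' @param snps Data.frame as returned by [read_snps()].
#' @param cds_set Named character vector or [Biostrings::DNAStringSet] keyed
#'   by `cds_id`.
#' @inheritParams score_snp
#' @return Row-bound data.frame of [score_snp()] results.
#' @export
score_snps <- function(snps, cds_set, bicodon_stats, codon_stats,
                       null_bicodon, null_codon) {
  if (methods::is(cds_set, "DNAStringSet")) cds_set <- as.character(cds_set)
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    rec <- as.list(snps[i, ])
    idx <- match(rec$cds_id, names(cds_set))
    if (is.na(idx)) stop("unknown cds_id: ", rec$cds_id)
    cds <- cds_set[[idx]]
    out[[i]] <- score_snp(rec, cds, bicodon_stats, codon_stats,
                          null_bicodon, null_codon)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
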
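# Standard genetic code tables and combinatorics over synonymous bicodons.
#
# A bicodon is a pair of consecutive in-frame codons: the P-site codon followed
# by the A-site codon, written as one hexanucleotide. The bicodon universe used
# throughout the package has a sense codon in the P-site (nothing is translated
# after a stop) and any of the 64 codons, stop included, in the A-site:
# 61 x 64 = 3,904 hexamers covering 20 x 21 = 420 amino-acid pairs.

#' The 64 codons of the standard genetic code (DNA alphabet)
#'
#' @return Character vector of the 64 trinucleotides over A, C, G, T, in
#'   lexicographic order.
#' @export
all_codons <- function() {
  .codon_env$codons
}

#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of trinucleotides (case-insensitive).
#' @return Character vector of one-letter amino-acid symbols, with `"*"` for
#'   the three stop codons.
#' @examples
#' translate_codon(c("ATG", "TAA", "AGT"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- is.na(codon) | !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (expected 3 characters over A/C/G/T)")
  }
  unname(.codon_env$aa[codon])
}

#' Sense codons (non-stop) of the standard code
#' @return Character vector of the 61 sense codons.
#' @export
sense_codons <- function() {
  .codon_env$sense
}

#' The bicodon universe
#'
#' All hexanucleotides with a sense codon in the P-site and any codon
#' (stop allowed) in the A-site.
#'
#' @return Character vector of 3,904 hexamers.
#' @export
bicodon_universe <- function() {
  .codon_env$universe$hexamer
}

#' Tabulate the bicodon universe
#'
#' @return A data.frame with one row per bicodon in the universe: `hexamer`,
#'   `p_codon`, `a_codon`, `aa_pair` (two-letter string, `"*"` = stop in the
#'   second position) and `q`, the number of bicodons encoding the same
#'   amino-acid pair.
#' @export
bicodon_table <- function() {
  .codon_env$universe
}

#' All 420 amino-acid pairs
#'
#' The first position ranges over the 20 amino acids, the second over the 20
#' amino acids plus stop.
#'
#' @return Character vector of length 420, e.g. `"SK"`, `"M*"`.
#' @export
aa_pairs <- function() {
  .codon_env$pairs
}

#' Bicodons encoding a given amino-acid pair
#'
#' @param pair Two-character string, e.g. `"SK"`; `"*"` denotes stop and is
#'   only valid in the second position.
#' @return Character vector of hexamers; its length is the product of the two
#'   codon degeneracies.
#' @examples
#' length(bicodons_for_pair("SK"))  # 12
#' bicodons_for_pair("MW")          # single bicodon ATGTGG
#' @export
bicodons_for_pair <- function(pair) {
  pair <- toupper(as.character(pair))
  if (length(pair) != 1L || is.na(pair) || !pair %in% .codon_env$pairs) {
    stop("not a valid amino-acid pair: ", pair)
  }
  u <- .codon_env$universe
  u$hexamer[u$aa_pair == pair]
}

#' Hamming distance between two hexanucleotides
#'
#' @param b1,b2 Character vectors of equal-length nucleotide strings
#'   (recycled to a common length).
#' @return Integer vector: the number of positions at which they differ.
#' @export
hamming_distance <- function(b1, b2) {
  b1 <- toupper(as.character(b1)); b2 <- toupper(as.character(b2))
  n <- max(length(b1), length(b2))
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n)
  if (any(nchar(b1) != nchar(b2))) stop("strings must have equal length")
  m1 <- strsplit(b1, "", fixed = TRUE)
  m2 <- strsplit(b2, "", fixed = TRUE)
  as.integer(mapply(function(x, y) sum(x != y), m1, m2))
}

#' Enumerate synonymous bicodon variants
#'
#' A synonymous bicodon variant is an unordered pair of distinct bicodons
#' encoding the same amino-acid pair. Over the full universe there are 26,718
#' such pairs; 8,497 of them differ at a single nucleotide and are therefore
#' reachable by a synonymous SNP.
#'
#' @param min_hamming,max_hamming Integers in 1..6 restricting the number of
#'   differing nucleotide positions.
#' @param pairs Optional character vector of amino-acid pairs to restrict the
#'   enumeration to (default: all 420).
#' @return A data.frame with columns `from_hex`, `to_hex` (lexicographically
#'   ordered within each row), `aa_pair` and `hamming`.
#' @examples
#' nrow(enumerate_synonymous_variants())                     # 26718
#' nrow(enumerate_synonymous_variants(max_hamming = 1))      # 8497
#' nrow(enumerate_synonymous_variants(pairs = "SK"))         # 66
#' @export
enumerate_synonymous_variants <- function(min_hamming = 1L, max_hamming = 6L,
                                          pairs = NULL) {
  min_hamming <- as.integer(min_hamming); max_hamming <- as.integer(max_hamming)
  if (is.na(min_hamming) || is.na(max_hamming) ||
      min_hamming < 1L || max_hamming > 6L || min_hamming > max_hamming) {
    stop("require 1 <= min_hamming <= max_hamming <= 6")
  }
  u <- .codon_env$universe
  fams <- split(u$hexamer, u$aa_pair)
  if (!is.null(pairs)) {
    pairs <- toupper(as.character(pairs))
    missing_p <- setdiff(pairs, names(fams))
    if (length(missing_p)) stop("unknown amino-acid pair(s): ",
                                paste(missing_p, collapse = ", "))
    fams <- fams[pairs]
  }
  out <- vector("list", length(fams))
  for (k in seq_along(fams)) {
    fam <- sort(fams[[k]])
    if (length(fam) < 2L) next
    cb <- utils::combn(length(fam), 2L)
    from <- fam[cb[1L, ]]; to <- fam[cb[2L, ]]
    m <- matrix(unlist(strsplit(fam, "", fixed = TRUE), use.names = FALSE),
                nrow = length(fam), byrow = TRUE)
    d <- rowSums(m[cb[1L, ], , drop = FALSE] != m[cb[2L, ], , drop = FALSE])
    keep <- d >= min_hamming & d <= max_hamming
    if (!any(keep)) next
    out[[k]] <- data.frame(from_hex = from[keep], to_hex = to[keep],
                           aa_pair = names(fams)[k],
                           hamming = as.integer(d[keep]),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(from_hex = character(), to_hex = character(),
                      aa_pair = character(), hamming = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Codon degeneracy
#'
#' @param codon Character vector of codons.
#' @return Integer vector: the number of codons encoding the same amino acid
#'   (stop counted as a 3-codon family).
#' @export
codon_degeneracy <- function(codon) {
  aa <- translate_codon(codon)
  unname(.codon_env$degeneracy[aa])
}

# Internal lazily-free environment holding the code tables; filled at load.
.codon_env <- new.env(parent = emptyenv())

.build_code_tables <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- gsub("U", "T", names(gc_tab), fixed = TRUE)
  aa <- as.character(gc_tab)
  ord <- order(codons)
  codons <- codons[ord]; aa <- aa[ord]
  names(aa) <- codons
  sense <- codons[aa != "*"]

  p <- rep(sense, each = length(codons))
  a <- rep(codons, times = length(sense))
  hexamer <- paste0(p, a)
  aa_pair <- paste0(aa[p], aa[a])
  q <- table(aa_pair)
  universe <- data.frame(hexamer = hexamer, p_codon = p, a_codon = a,
                         aa_pair = aa_pair,
                         q = as.integer(q[aa_pair]),
                         stringsAsFactors = FALSE)
  universe <- universe[order(universe$hexamer), , drop = FALSE]
  rownames(universe) <- NULL

  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$sense <- sense
  .codon_env$universe <- universe
  .codon_env$pairs <- sort(unique(aa_pair))

  # synonymous single-base substitutions per codon:
  # codon, offset (1..3), ref_base, alt_base, alt_codon
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(codon = codons, offset = 1:3, alt_base = bases,
                      stringsAsFactors = FALSE)
  grid$ref_base <- substr(grid$codon, grid$offset, grid$offset)
  grid$alt_codon <- grid$codon
  substr(grid$alt_codon, grid$offset, grid$offset) <- grid$alt_base
  grid <- grid[grid$ref_base != grid$alt_base &
               aa[grid$codon] == aa[grid$alt_codon], , drop = FALSE]
  grid <- grid[order(grid$codon, grid$offset, grid$alt_base), , drop = FALSE]
  rownames(grid) <- NULL
  .codon_env$syn_alts <- grid[, c("codon", "offset", "ref_base",
                                  "alt_base", "alt_codon")]

  # named integer vector keyed by amino-acid symbol, incl. "*"
  deg <- table(aa)
  .codon_env$degeneracy <- stats::setNames(as.integer(deg), names(deg))
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .build_code_tables()
}
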
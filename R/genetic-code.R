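# Standard genetic code tables used throughout the package.
#
# All internal bookkeeping is in the DNA alphabet; user-facing codon labels
# are RNA (UUG, CUG, ...) to match the usual presentation of codon-usage
# statistics. Only the standard code (translation table 1) is supported.

.codon_env <- new.env(parent = emptyenv())

.build_code_tables <- function() {
  gc <- Biostrings::GENETIC_CODE  # named chr: codon (DNA) -> one-letter AA, "*" = stop
  codons <- names(gc)
  aa <- unname(gc)
  stops <- codons[aa == "*"]
  families <- split(codons, aa)
  families <- families[names(families) != "*"]
  degeneracy <- vapply(families, length, integer(1L))
  # 59 informative codons: drop stops and the two single-codon families
  informative <- sort(unlist(families[degeneracy >= 2L], use.names = FALSE))
  list(
    codons = codons,
    aa_of = gc,
    stops = stops,
    families = families,
    degeneracy = degeneracy,
    informative = informative
  )
}

.code <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- .build_code_tables()
  .codon_env$tab
}

#' Convert codon labels between DNA and RNA alphabets
#'
#' Codon-usage outputs in this package are labelled in the RNA alphabet
#' (\code{"UUG"}); sequence handling is done in DNA (\code{"TTG"}). These
#' helpers translate between the two; both accept vectors and are
#' case-insensitive.
#'
#' @param x character vector of codons (or any nucleotide strings).
#' @return character vector of the same length.
#' @examples
#' codon_to_rna("TTG")  # "UUG"
#' codon_to_dna("UUG")  # "TTG"
#' @export
codon_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname codon_to_rna
#' @export
codon_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' The 59 informative codons
#'
#' Codons entering RSCU and correspondence analysis: the 64 codons minus the
#' three stops and the single-codon families AUG (Met) and UGG (Trp).
#'
#' @param alphabet \code{"rna"} (default) or \code{"dna"} labels.
#' @return character vector of length 59, sorted.
#' @export
informative_codons <- function(alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  x <- .code()$informative
  if (alphabet == "rna") codon_to_rna(x) else x
}

# synonymous families with >= 2 members, DNA labels, named by amino acid
.degenerate_families <- function() {
  tab <- .code()
  tab$families[tab$degeneracy >= 2L]
}
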
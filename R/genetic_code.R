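#' The standard nuclear genetic code
#'
#' Builds the standard genetic code (NCBI translation table 1) used by every
#' statistic in the package: the codon-to-amino-acid map over the 64 DNA
#' triplets, the 61 sense codons, the three stop codons, the per-amino-acid
#' degeneracy \eqn{n_i} (number of synonymous codons), and the synonymous
#' families. Serine, leucine and arginine are treated as single six-fold
#' families, matching the convention that the expected count of a codon under
#' unbiased usage is the amino-acid total divided by its full degeneracy.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character over 64 codons, stops as `"*"`),
#'   `sense_codons` (61 codons, lexicographic), `stop_codons`
#'   (`TAA`, `TAG`, `TGA`), `degeneracy` (named integer over the 20
#'   amino acids), and `families` (list of codon vectors per amino acid).
#' @examples
#' gc <- standard_genetic_code()
#' gc$degeneracy[["L"]]  # leucine: 6 synonymous codons
#' @export
standard_genetic_code <- function() {
  cached <- get0(".genetic_code", envir = .codonscape_cache)
  if (!is.null(cached)) return(cached)
  tab <- as.character(Biostrings::GENETIC_CODE)
  names(tab) <- names(Biostrings::GENETIC_CODE)
  stops <- sort(names(tab)[tab == "*"])
  sense <- sort(names(tab)[tab != "*"])
  aa_of_sense <- tab[sense]
  families <- split(sense, aa_of_sense)
  degeneracy <- vapply(families, length, integer(1L))
  code <- structure(
    list(
      codon_to_aa = tab,
      sense_codons = sense,
      stop_codons = stops,
      degeneracy = degeneracy,
      families = families
    ),
    class = "genetic_code"
  )
  stopifnot(length(sense) == 61L, sum(degeneracy) == 61L,
            degeneracy[["M"]] == 1L, degeneracy[["W"]] == 1L)
  assign(".genetic_code", code, envir = .codonscape_cache)
  code
}

.codonscape_cache <- new.env(parent = emptyenv())

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code: 61 sense codons,",
      length(x$stop_codons), "stop codons,",
      length(x$degeneracy), "amino acids\n")
  invisible(x)
}

# Degeneracy classes used by Wright's ENC: number of amino acids per class.
# 2-fold: C,D,E,F,H,K,N,Q,Y (9); 3-fold: I (1); 4-fold: A,G,P,T,V (5);
# 6-fold: L,R,S (3). Met and Trp (single-codon) carry no bias information.
enc_class_sizes <- c(`2` = 9L, `3` = 1L, `4` = 5L, `6` = 3L)

#' Convert codons between DNA and RNA alphabets
#'
#' The package works internally in the DNA alphabet (T); reports and tables
#' can be rendered in the RNA alphabet (U), the convention most codon-usage
#' tables use.
#'
#' @param codons Character vector of codons (or any nucleotide strings).
#' @param alphabet `"rna"` or `"dna"`.
#' @return Character vector in the requested alphabet.
#' @examples
#' format_codons(c("TTA", "CTG"), "rna")
#' @export
format_codons <- function(codons, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "rna") chartr("Tt", "Uu", codons) else chartr("Uu", "Tt", codons)
}
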
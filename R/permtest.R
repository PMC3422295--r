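#' Position-model permutation of codon sequences
#'
#' Within each gene, independently permutes the bases at codon position 1,
#' position 2 and position 3 among the gene's internal codons (the classic
#' "position" randomisation model). The initiator ATG and the terminal stop
#' are exempt. The permutation preserves, per gene, the multiset of bases at
#' each codon position — hence GC content and GC3 are invariant — while
#' destroying any within-codon association between positions. Randomised
#' genes are returned as written and are not re-validated: internal stops
#' may appear and are tallied as stops by downstream counting.
#'
#' @param genes A `gene_set`.
#' @param seed Integer seed; the permutation is deterministic given the seed.
#' @return A `gene_set` with randomised genes (same ids, same lengths).
#' @export
permute_positions <- function(genes, seed) {
  stopifnot(inherits(genes, "gene_set"))
  set.seed(as.integer(seed))
  shuffled <- lapply(genes$genes, function(g) {
    L <- length(g)
    if (L <= 3L) return(g)   # body of 0 or 1 codon: unchanged
    body <- g[2:(L - 1L)]
    mat <- matrix(unlist(strsplit(body, "", fixed = TRUE), use.names = FALSE),
                  nrow = 3L)
    for (p in 1:3) mat[p, ] <- mat[p, sample.int(ncol(mat))]
    c(g[1L], paste0(mat[1L, ], mat[2L, ], mat[3L, ]), g[L])
  })
  out <- genes
  out$genes <- shuffled
  out
}

#' Association between codon usage bias and amino-acid composition bias
#'
#' Codon permutation analysis: compares, per codon, the observed genome-wide
#' codon total and its expectation under unbiased synonymous usage (the
#' amino-acid total divided by the degeneracy) with the same two quantities
#' measured on position-permuted sequences (averaged over replicates). Each
#' codon's 2x2 table `[[obs_total, obs_expected], [rand_total,
#' rand_expected]]` is tested with Pearson's chi-square; a significant
#' result indicates that the codon's usage bias is tied to the base
#' composition that also drives amino-acid composition (the association is
#' strongest for six-fold families, where first/second-position changes can
#' be synonymous).
#'
#' @param genes A `gene_set` (observed data).
#' @param replicates Number of permutation replicates to average (>= 1).
#' @param seed Integer seed governing all replicates.
#' @param alpha Significance level for the `significant` flag.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return An `association_result` data.frame: per sense codon, `codon`,
#'   `aa`, `obs`, `obs_expected`, `rand`, `rand_expected`, `chisq`, `p`,
#'   `significant`. Codons of amino acids absent from either dataset have
#'   `NA` statistics.
#' @export
codon_aa_association <- function(genes, replicates = 100L, seed,
                                 alpha = 0.05, correct = FALSE) {
  stopifnot(inherits(genes, "gene_set"), replicates >= 1L)
  code <- standard_genetic_code()
  obs <- count_codons(genes)
  rand_x <- numeric(61L)
  for (r in seq_len(replicates)) {
    perm <- permute_positions(genes, seed = as.integer(seed) + r)
    rand_x <- rand_x + count_codons(perm)$x
  }
  rand_x <- rand_x / replicates
  expected_of <- function(x) {
    aa <- code$codon_to_aa[names(obs$x)]
    tot <- tapply(x, aa, sum)[aa]
    unname(tot / code$degeneracy[aa])
  }
  obs_e <- expected_of(obs$x)
  rand_e <- expected_of(rand_x)
  chi2_2x2 <- function(a, b, c, d) {
    N <- a + b + c + d
    num <- abs(a * d - b * c)
    if (correct) num <- max(0, num - N / 2)
    N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  rows <- lapply(seq_along(obs$x), function(i) {
    a <- obs$x[[i]]; b <- obs_e[[i]]; cc <- rand_x[[i]]; dd <- rand_e[[i]]
    cod <- names(obs$x)[i]
    if (b == 0 || dd == 0) {
      chi <- NA_real_; p <- NA_real_
    } else {
      chi <- chi2_2x2(a, b, cc, dd)
      p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
    }
    data.frame(codon = cod, aa = unname(code$codon_to_aa[cod]),
               obs = a, obs_expected = b, rand = cc, rand_expected = dd,
               chisq = chi, p = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  out
}
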
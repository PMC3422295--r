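#' Count ordered codon pairs (codon contexts)
#'
#' Tallies adjacent in-frame codon pairs — the two codons occupying the
#' ribosomal P and A sites — within single genes (never across gene
#' boundaries). In the default exclusive mode, for a gene with codons
#' \eqn{c_1..c_L} (\eqn{c_1} = ATG, \eqn{c_L} = stop) the internal pairs
#' \eqn{(c_k, c_{k+1})}, \eqn{k = 2..L-2}, feed the 61x61 sense-pair table,
#' while the boundary pairs \eqn{(c_1, c_2)} and \eqn{(c_{L-1}, c_L)} feed
#' the start/stop boundary-context tables. In inclusive mode all pairs
#' \eqn{k = 1..L-1} are counted into a 61x64 table whose 3' columns include
#' the stop codons — the mode used for "most/least frequent context"
#' reports, where rare contexts typically end in a stop.
#'
#' @param genes A `gene_set`.
#' @param inclusive Count boundary pairs into the main table and extend the
#'   3' universe with the stop codons.
#' @return A `codon_pair_table`: list with `counts` (5' codons in rows, 3' in
#'   columns), `n_pairs`, `inclusive`, `start3` (named integer: codon
#'   immediately 3' of the initiator ATG), and `stop5` (3 x 61 matrix: codon
#'   immediately 5' of each stop).
#' @examples
#' gs <- gene_set(c(g = "ATGGAAGAAGAATAA"))
#' count_codon_pairs(gs)$counts["GAA", "GAA"]
#' @export
count_codon_pairs <- function(genes, inclusive = FALSE) {
  stopifnot(inherits(genes, "gene_set"))
  code <- standard_genetic_code()
  sense <- code$sense_codons
  col_univ <- if (inclusive) c(sense, code$stop_codons) else sense
  counts <- matrix(0L, length(sense), length(col_univ),
                   dimnames = list(sense, col_univ))
  start3 <- stats::setNames(integer(length(sense)), sense)
  stop5 <- matrix(0L, 3L, length(sense),
                  dimnames = list(code$stop_codons, sense))
  c5_parts <- vector("list", length(genes$genes))
  c3_parts <- vector("list", length(genes$genes))
  gi <- 0L
  for (g in genes$genes) {
    gi <- gi + 1L
    L <- length(g)
    if (L >= 3L) {
      s3 <- g[2L]
      if (s3 %in% sense) start3[s3] <- start3[s3] + 1L
    }
    prev <- g[L - 1L]
    if (prev %in% sense) stop5[g[L], prev] <- stop5[g[L], prev] + 1L
    ks <- if (inclusive) seq_len(L - 1L) else seq(2L, length.out = max(0L, L - 3L))
    if (length(ks)) {
      c5_parts[[gi]] <- g[ks]
      c3_parts[[gi]] <- g[ks + 1L]
    }
  }
  c5_all <- unlist(c5_parts, use.names = FALSE)
  c3_all <- unlist(c3_parts, use.names = FALSE)
  if (length(c5_all)) {
    i5 <- match(c5_all, sense)
    i3 <- match(c3_all, col_univ)
    ok <- !is.na(i5) & !is.na(i3)
    tab <- tabulate(i5[ok] + (i3[ok] - 1L) * length(sense),
                    nbins = length(sense) * length(col_univ))
    counts[] <- tab
  }
  structure(list(counts = counts, n_pairs = sum(counts),
                 inclusive = inclusive, start3 = start3, stop5 = stop5),
            class = "codon_pair_table")
}

#' @export
print.codon_pair_table <- function(x, ...) {
  cat("codon_pair_table (", if (x$inclusive) "inclusive" else "internal",
      " pairs): N = ", x$n_pairs, "\n", sep = "")
  invisible(x)
}

#' Haberman adjusted residuals of a codon-pair table
#'
#' Standardised deviation of each cell of the pair contingency table from
#' its independence expectation:
#' \deqn{r_{ij} = \frac{o_{ij} - e_{ij}}{\sqrt{e_{ij} (1 - R_i/N)(1 - C_j/N)}},
#'   \quad e_{ij} = R_i C_j / N,}
#' where \eqn{R_i}, \eqn{C_j} are row and column marginals. Under
#' independence the residuals are approximately standard normal; large
#' positive values mark over-represented contexts. Cells with zero expected
#' count are `NA`.
#'
#' @param table A `codon_pair_table` or a plain count matrix.
#' @return Numeric matrix of adjusted residuals with the same dimnames.
#' @export
adjusted_residuals <- function(table) {
  m <- if (inherits(table, "codon_pair_table")) table$counts else table
  N <- sum(m)
  if (N == 0) stop("empty pair table")
  R <- rowSums(m); C <- colSums(m)
  e <- outer(R, C) / N
  denom <- sqrt(e * outer(1 - R / N, 1 - C / N))
  res <- (m - e) / denom
  res[e == 0] <- NA_real_
  res
}

#' Relative synonymous codon pair usage (RSCPU)
#'
#' Observed codon-pair count divided by its expectation under equal usage of
#' all codon pairs encoding the same ordered amino-acid pair: for a pair
#' coding \eqn{(a, b)}, the expected count is the amino-acid-pair total
#' divided by \eqn{n_a n_b} (the product of degeneracies). RSCPU > 1 marks
#' codon pairs used more often than expected within their amino-acid pair;
#' pairs whose amino-acid pair is absent are `NA`. Within each observed
#' amino-acid pair the RSCPU values sum to \eqn{n_a n_b}.
#'
#' @param table A `codon_pair_table` (the sense-by-sense part is used).
#' @return Numeric 61x61 matrix of RSCPU values.
#' @export
rscpu <- function(table) {
  code <- standard_genetic_code()
  sense <- code$sense_codons
  m <- if (inherits(table, "codon_pair_table")) table$counts else table
  m <- m[sense, intersect(colnames(m), sense)]
  aa5 <- code$codon_to_aa[rownames(m)]
  aa3 <- code$codon_to_aa[colnames(m)]
  pair_aa <- outer(aa5, aa3, paste0)
  totals <- tapply(as.vector(m), as.vector(pair_aa), sum)
  n5 <- code$degeneracy[aa5]
  n3 <- code$degeneracy[aa3]
  expected <- matrix(totals[as.vector(pair_aa)], nrow(m), ncol(m)) /
    outer(n5, n3)
  out <- m / expected
  out[expected == 0] <- NA_real_
  dimnames(out) <- dimnames(m)
  out
}

#' Boundary contexts of start and stop codons
#'
#' Counts of the codon immediately 3' of the initiator ATG and immediately
#' 5' of each stop codon, with most- and least-frequent summaries. The
#' least-frequent codon is the minimum among codons actually observed
#' (count > 0); ties are broken lexicographically and reported.
#'
#' @param genes A `gene_set`.
#' @return A `boundary_context_table`: list with `start3` (named counts),
#'   `stop5` (3 x 61 count matrix), and `summary` (data.frame: `table`
#'   (start3 or the stop codon), `most_frequent`, `mf_count`,
#'   `least_frequent`, `lf_count`, `mf_ties`, `lf_ties`).
#' @export
boundary_contexts <- function(genes) {
  pt <- count_codon_pairs(genes, inclusive = FALSE)
  pick <- function(v) {
    v <- v[v > 0]
    if (length(v) == 0L) {
      return(data.frame(most_frequent = NA_character_, mf_count = NA_integer_,
                        least_frequent = NA_character_, lf_count = NA_integer_,
                        mf_ties = "", lf_ties = ""))
    }
    v <- v[order(names(v))]
    mf <- names(v)[v == max(v)]
    lf <- names(v)[v == min(v)]
    data.frame(most_frequent = mf[1L], mf_count = max(v),
               least_frequent = lf[1L], lf_count = min(v),
               mf_ties = paste(mf, collapse = ","),
               lf_ties = paste(lf, collapse = ","))
  }
  summ <- rbind(
    cbind(table = "start3", pick(pt$start3)),
    do.call(rbind, lapply(rownames(pt$stop5), function(st) {
      cbind(table = st, pick(pt$stop5[st, ]))
    }))
  )
  structure(list(start3 = pt$start3, stop5 = pt$stop5, summary = summ),
            class = "boundary_context_table")
}

#' Most and least frequent codon contexts
#'
#' Table-style report of the single most frequent and least frequent (among
#' observed) codon contexts of a genome. By default it uses the inclusive
#' pair table, whose 3' universe includes the stop codons, so that rare
#' contexts ending in a stop are visible.
#'
#' @param genes A `gene_set`, or a precomputed `codon_pair_table`.
#' @param inclusive Passed to [count_codon_pairs()] when `genes` is a
#'   `gene_set`.
#' @param alphabet Render codons as RNA (default, the reporting convention)
#'   or DNA.
#' @return A one-row data.frame: `frequent_context`, `frequent_count`,
#'   `rare_context`, `rare_count`.
#' @export
frequent_contexts <- function(genes, inclusive = TRUE,
                              alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  pt <- if (inherits(genes, "codon_pair_table")) genes
        else count_codon_pairs(genes, inclusive = inclusive)
  m <- pt$counts
  pos <- which(m > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("empty pair table")
  lab <- paste(rownames(m)[pos[, 1L]], colnames(m)[pos[, 2L]], sep = "-")
  cnt <- m[pos]
  ord <- order(lab)
  lab <- lab[ord]; cnt <- cnt[ord]
  data.frame(
    frequent_context = format_codons(lab[which.max(cnt)], alphabet),
    frequent_count = max(cnt),
    rare_context = format_codons(lab[which.min(cnt)], alphabet),
    rare_count = min(cnt),
    stringsAsFactors = FALSE
  )
}

#' Amino-acid pair frequencies
#'
#' Frequencies of ordered residue pairs over the same internal adjacency
#' used by [count_codon_pairs()] (exclusive mode): the codon-pair table
#' aggregated through the genetic code and normalised to sum to 1.
#'
#' @param genes A `gene_set`.
#' @return A 20x20 numeric matrix (5' residue in rows) summing to 1.
#' @export
aa_pair_frequencies <- function(genes) {
  code <- standard_genetic_code()
  pt <- count_codon_pairs(genes, inclusive = FALSE)
  aa5 <- code$codon_to_aa[rownames(pt$counts)]
  aa3 <- code$codon_to_aa[colnames(pt$counts)]
  aas <- sort(unique(unname(code$codon_to_aa[code$sense_codons])))
  out <- matrix(0, 20L, 20L, dimnames = list(aas, aas))
  agg <- tapply(as.vector(pt$counts),
                list(aa5[row(pt$counts)], aa3[col(pt$counts)]), sum)
  out[rownames(agg), colnames(agg)] <- agg
  out / sum(out)
}

#' Cluster species by codon-context residual profiles
#'
#' Hierarchical average-linkage clustering of species on the distance
#' 1 - correlation between their flattened adjusted-residual matrices
#' (computed over cells defined in both species). Species with fewer than
#' 50% defined cells are excluded with a warning. The tree summarises how
#' codon-context preferences vary across species.
#'
#' @param residuals_by_species Named list of residual matrices over an
#'   identical pair universe (e.g. outputs of [adjusted_residuals()]).
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return An `ape` `phylo` tree (leaves = included species). Write with
#'   [ape::write.tree()] for Newick output.
#' @export
context_cluster_tree <- function(residuals_by_species,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.list(residuals_by_species))
  defined <- vapply(residuals_by_species,
                    function(m) mean(!is.na(m)), numeric(1L))
  drop <- names(residuals_by_species)[defined < 0.5]
  if (length(drop)) {
    warning("excluding species with < 50% defined residual cells: ",
            paste(drop, collapse = ", "))
    residuals_by_species <- residuals_by_species[defined >= 0.5]
  }
  if (length(residuals_by_species) < 3L) {
    stop("need at least 3 species with sufficiently defined residuals")
  }
  flat <- vapply(residuals_by_species, as.vector,
                 numeric(length(residuals_by_species[[1L]])))
  cors <- stats::cor(flat, use = "pairwise.complete.obs", method = method)
  d <- stats::as.dist(1 - cors)
  ape::as.phylo(stats::hclust(d, method = "average"))
}
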
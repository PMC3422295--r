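#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for a 2x2 contingency table `[[a, b], [c, d]]`,
#' computed by summing, over all tables with the same margins, the
#' hypergeometric probabilities not exceeding that of the observed table
#' (with the usual relative tolerance guarding ties in floating point).
#' This is the summation rule base R's `fisher.test()` uses; it is
#' implemented directly here because the cross-group codon test is built on
#' it and validated against exhaustive enumeration.
#'
#' @param a,b,c,d Cell counts (row 1: `a`, `b`; row 2: `c`, `d`).
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(15, 0, 0, 7)   # 1 / choose(22, 7)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0L) return(NA_real_)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Cross-group exact test of frequent/rare codon usage
#'
#' For each sense codon, counts how many species of each group use it as a
#' frequent codon (RSCU > 1) versus a rare codon (RSCU < 1); species where
#' the codon is neutral (RSCU exactly 1, e.g. single-codon families) or
#' undefined are dropped. The resulting 2x2 table
#' `[[k1, m1], [k2, m2]]` is tested with the two-sided Fisher exact test,
#' flagging codons whose frequent/rare orientation differs significantly
#' between groups.
#'
#' @param rscu_by_species Named list of `rscu_table` objects (one per
#'   species), as returned by [rscu()].
#' @param groups Named vector mapping species names to group labels (exactly
#'   two distinct labels).
#' @param alpha Significance level for the `significant` flag.
#' @return A `group_comparison` data.frame: per codon, `codon`, `aa`, `k1`,
#'   `m1`, `k2`, `m2`, `p`, `significant`; group labels are carried in
#'   attribute `"groups"` (group 1 is the first sorted label).
#' @export
cross_group_exact_test <- function(rscu_by_species, groups, alpha = 0.05) {
  stopifnot(is.list(rscu_by_species), !is.null(names(rscu_by_species)))
  groups <- groups[names(rscu_by_species)]
  if (anyNA(groups)) stop("every species needs a group label")
  labs <- sort(unique(as.character(groups)))
  if (length(labs) != 2L) stop("exactly two groups required")
  if (min(table(groups)) < 2L) stop("need at least 2 species per group")
  code <- standard_genetic_code()
  flags <- vapply(rscu_by_species, function(rt) {
    stats::setNames(rt$flag, rt$codon)[code$sense_codons]
  }, character(61L))
  rows <- lapply(code$sense_codons, function(cod) {
    f <- flags[cod, ]
    k1 <- sum(f == "frequent" & groups == labs[1L])
    m1 <- sum(f == "rare" & groups == labs[1L])
    k2 <- sum(f == "frequent" & groups == labs[2L])
    m2 <- sum(f == "rare" & groups == labs[2L])
    p <- if ((k1 + m1) == 0L || (k2 + m2) == 0L) NA_real_ else
      fisher_exact_2x2(k1, m1, k2, m2)
    data.frame(codon = cod, aa = unname(code$codon_to_aa[cod]),
               k1 = k1, m1 = m1, k2 = k2, m2 = m2, p = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- labs
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Composition regression of the effective number of codons
#'
#' Fits the generalised linear model `enc ~ a3s + g3s + c3s + t3s` with log
#' link and Poisson variance function (quasi-likelihood, since ENC is
#' continuous), relating per-gene codon bias to silent-site base
#' composition. The four fractions sum to 1, so the model matrix with an
#' intercept is rank-deficient; by default the fit is reported as-is (R
#' aliases the last redundant term) together with the condition number of
#' the model matrix. `drop_t3s = TRUE` removes `t3s` for a full-rank
#' parameterisation in which each coefficient is a contrast against T3s.
#'
#' @param gene_table Data.frame with columns `enc`, `a3s`, `t3s`, `c3s`,
#'   `g3s` (e.g. from [gene_usage_table()]); rows with NA are dropped.
#' @param drop_t3s Drop the `t3s` term for a full-rank fit.
#' @param alpha Significance level used for the `significant` flag.
#' @return A `regression_fit`: list with `coefficients` (data.frame: `term`,
#'   `estimate`, `std_error`, `p`, `significant`), `condition_number`,
#'   `family` (`"quasipoisson(log)"`), and `fit` (the `glm` object).
#' @export
enc_regression <- function(gene_table, drop_t3s = FALSE, alpha = 0.05) {
  need <- c("enc", "a3s", "t3s", "c3s", "g3s")
  stopifnot(all(need %in% names(gene_table)))
  df <- gene_table[stats::complete.cases(gene_table[, need]), need]
  if (nrow(df) < 50L) stop("need at least 50 genes with defined ENC")
  form <- if (drop_t3s) enc ~ a3s + g3s + c3s else enc ~ a3s + g3s + c3s + t3s
  fit <- stats::glm(form, data = df,
                    family = stats::quasipoisson(link = "log"),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                      std_error = sm[, 2L], p = sm[, 4L],
                      significant = sm[, 4L] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  mm <- stats::model.matrix(fit)
  structure(list(coefficients = coefs,
                 condition_number = kappa(mm, exact = TRUE),
                 family = "quasipoisson(log)", fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("ENC ~ composition GLM (", x$family, "), condition number ",
      format(x$condition_number, digits = 4), "\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' CAI-ENC inverse-trend summary
#'
#' Pearson correlation between per-gene CAI and ENC, plus the fraction of
#' genes consistent with the inverse trend under a quadrant rule: a gene is
#' consistent when its CAI and ENC deviations from the respective medians
#' have opposite signs (genes exactly on a median are dropped from the
#' denominator).
#'
#' @param gene_table Data.frame with columns `cai` and `enc`; NA rows are
#'   dropped.
#' @return A list with `pearson_r`, `inverse_fraction`, and `n`.
#' @export
cai_enc_trend <- function(gene_table) {
  stopifnot(all(c("cai", "enc") %in% names(gene_table)))
  df <- gene_table[stats::complete.cases(gene_table[, c("cai", "enc")]),
                   c("cai", "enc")]
  if (nrow(df) < 10L) stop("need at least 10 genes with CAI and ENC")
  if (stats::sd(df$cai) == 0 || stats::sd(df$enc) == 0) {
    return(list(pearson_r = NA_real_, inverse_fraction = NA_real_,
                n = nrow(df)))
  }
  r <- stats::cor(df$cai, df$enc)
  dc <- df$cai - stats::median(df$cai)
  de <- df$enc - stats::median(df$enc)
  keep <- dc != 0 & de != 0
  list(pearson_r = r,
       inverse_fraction = mean(dc[keep] * de[keep] < 0),
       n = nrow(df))
}

#' Cluster species and codons by RSCU profiles
#'
#' Average-linkage hierarchical clustering of the species-by-codon RSCU
#' matrix using the rank-correlation distance 1 - Spearman rho (Pearson
#' available): one tree over species (rows) and one over codons (columns),
#' plus the RSCU matrix reordered by both trees — the structure behind
#' heat-map displays where GC3-rich and AT3-rich species form two blocks.
#' Codons undefined in any species, and codons with zero variance across
#' species, are dropped from the respective clusterings and reported.
#'
#' @param rscu_by_species Named list of `rscu_table` objects (>= 3 species).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list with `species_tree` and `codon_tree` (`phylo` objects),
#'   `matrix` (reordered RSCU matrix), and `dropped_codons`.
#' @export
cluster_rscu <- function(rscu_by_species, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(rscu_by_species) >= 3L)
  code <- standard_genetic_code()
  m <- t(vapply(rscu_by_species, function(rt) {
    stats::setNames(rt$rscu, rt$codon)[code$sense_codons]
  }, numeric(61L)))
  colnames(m) <- code$sense_codons
  undef <- colnames(m)[colSums(is.na(m)) > 0L]
  m <- m[, colSums(is.na(m)) == 0L, drop = FALSE]
  d_species <- stats::as.dist(1 - stats::cor(t(m), method = method))
  species_tree <- stats::hclust(d_species, method = "average")
  novar <- colnames(m)[apply(m, 2L, stats::sd) == 0]
  mc <- m[, !colnames(m) %in% novar, drop = FALSE]
  d_codon <- stats::as.dist(1 - stats::cor(mc, method = method))
  codon_tree <- stats::hclust(d_codon, method = "average")
  list(species_tree = ape::as.phylo(species_tree),
       codon_tree = ape::as.phylo(codon_tree),
       matrix = m[species_tree$order,
                  c(colnames(mc)[codon_tree$order], novar), drop = FALSE],
       dropped_codons = list(undefined = undef, zero_variance = novar))
}

#' Spearman correlation between ortholog and genome-wide mean SCUO
#'
#' Rank correlation (mid-rank ties) across species between the mean SCUO of
#' a shared ortholog set and the genome-wide mean SCUO, testing whether a
#' small ortholog sample predicts genome-wide codon usage order. The
#' p-value is exact (permutation distribution) for n <= 10 species and uses
#' the t approximation above that.
#'
#' @param ortho_scuo Numeric vector of per-species mean ortholog SCUO.
#' @param genome_scuo Numeric vector of per-species genome-wide mean SCUO
#'   (same species order).
#' @return A list with `rho`, `p`, and `n`.
#' @export
ortho_scuo_correlation <- function(ortho_scuo, genome_scuo) {
  stopifnot(length(ortho_scuo) == length(genome_scuo))
  keep <- stats::complete.cases(ortho_scuo, genome_scuo)
  x <- ortho_scuo[keep]; y <- genome_scuo[keep]
  n <- length(x)
  if (n < 5L) stop("need at least 5 species")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 10L)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
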
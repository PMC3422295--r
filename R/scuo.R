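#' Synonymous codon usage order (SCUO) of a gene
#'
#' Entropy-based codon bias measure. For each amino acid \eqn{i} with
#' degeneracy \eqn{n_i \ge 2} and count \eqn{c_i > 0}, the within-family
#' usage entropy is \eqn{H_i = -\sum_j p_{ij} \log_2 p_{ij}} with
#' \eqn{p_{ij} = x_{ij}/c_i}; its maximum is \eqn{H_i^{max} = \log_2 n_i}.
#' The normalised order \eqn{O_i = (H_i^{max} - H_i)/H_i^{max}} is averaged
#' with composition weights \eqn{F_i = c_i / \sum_i c_i}:
#' \deqn{SCUO = \sum_i F_i O_i \in [0, 1]}
#' 0 means uniform synonymous usage (no bias), 1 means a single codon per
#' family (maximal bias). Single-codon families (Met, Trp) are excluded.
#'
#' @param counts Per-gene `codon_counts` (or anything [count_codons()]
#'   accepts).
#' @return A `scuo_value`: list with `scuo` (`NA` when no multi-codon family
#'   is observed) and `per_aa` (data.frame with `aa`, `count`, `H`, `Hmax`,
#'   `O`, `F`).
#' @examples
#' scuo(c("ATG", rep("GAA", 4), "TAA"))$scuo         # fully biased Glu: 1
#' scuo(c("ATG", "GAA", "GAG", "TAA"))$scuo          # uniform Glu: 0
#' @export
scuo <- function(counts) {
  counts <- as_codon_counts(counts)
  code <- standard_genetic_code()
  multi <- names(code$degeneracy)[code$degeneracy >= 2L]
  rows <- lapply(multi, function(a) {
    x <- counts$x[code$families[[a]]]
    c_i <- sum(x)
    if (c_i == 0L) return(NULL)
    p <- x[x > 0] / c_i
    H <- -sum(p * log2(p))
    Hmax <- log2(code$degeneracy[[a]])
    data.frame(aa = a, count = c_i, H = H, Hmax = Hmax,
               O = (Hmax - H) / Hmax, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(structure(list(scuo = NA_real_, per_aa = NULL),
                     class = "scuo_value"))
  }
  rows$F <- rows$count / sum(rows$count)
  structure(list(scuo = sum(rows$F * rows$O), per_aa = rows),
            class = "scuo_value")
}

#' SCUO for every gene of a set
#'
#' @param genes A `gene_set`.
#' @return Named numeric vector of per-gene SCUO values (NA where undefined).
#' @export
scuo_genes <- function(genes) {
  stopifnot(inherits(genes, "gene_set"))
  vapply(count_codons(genes, pool = FALSE),
         function(cc) scuo(cc)$scuo, numeric(1L))
}

#' Bin SCUO values into ten 0.1-wide intervals
#'
#' Partitions genes into the ten non-overlapping SCUO intervals
#' `[0,0.1), [0.1,0.2), ..., [0.9,1.0]`. Intervals are lower-inclusive; a
#' value exactly on an edge goes to the higher bin, except 1.0 which stays in
#' bin 10 (the last bin is closed). The assignment is deterministic and
#' total over defined values.
#'
#' @param values Named numeric vector of SCUO values (NAs dropped).
#' @return A `scuo_bins` object: list with `edges`, `membership` (named
#'   integer bin index 1..10 per gene), and `summary` (data.frame per bin:
#'   `bin`, `lo`, `hi`, `n`, `mean`, `variance`), plus `values` (the defined
#'   values, for downstream tests).
#' @examples
#' b <- bin_scuo(c(g1 = 0.05, g2 = 0.1, g3 = 1.0))
#' b$membership
#' @export
bin_scuo <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no defined SCUO values")
  stopifnot(all(values >= 0 & values <= 1))
  edges <- seq(0, 1, by = 0.1)
  idx <- pmin(floor(values / 0.1) + 1L, 10L)
  summary <- do.call(rbind, lapply(1:10, function(b) {
    v <- values[idx == b]
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1L],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               variance = if (length(v) >= 2L) stats::var(v) else NA_real_)
  }))
  structure(list(edges = edges, membership = idx, summary = summary,
                 values = values),
            class = "scuo_bins")
}

#' @export
print.scuo_bins <- function(x, ...) {
  cat("scuo_bins:", length(x$values), "genes in 10 intervals\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Dunnett-T3 all-pairs comparison of SCUO across bins
#'
#' Pairwise comparison of mean SCUO between the ten SCUO intervals using
#' Dunnett's T3 modification of the Tukey-Kramer procedure, which is
#' appropriate when group sizes and variances differ. For each unordered
#' pair, the standard error is the Welch form
#' \eqn{\sqrt{s_a^2/n_a + s_b^2/n_b}}, the degrees of freedom are
#' Welch-Satterthwaite, and the critical value is the studentized-range
#' quantile at those degrees of freedom (divided by \eqn{\sqrt 2}). A pair is
#' significant when its confidence interval excludes 0. Bins with fewer than
#' 2 members are skipped and listed.
#'
#' @param bins A `scuo_bins` object.
#' @param conf_level Confidence level (default 0.95).
#' @return A `dtk_result`: list with `pairs` (data.frame: `bin_a`, `bin_b`,
#'   `diff`, `ci_lo`, `ci_hi`, `significant`) and `skipped` (bins with
#'   n < 2).
#' @export
dtk_pairwise <- function(bins, conf_level = 0.95) {
  stopifnot(inherits(bins, "scuo_bins"))
  s <- bins$summary
  usable <- s$bin[s$n >= 2L]
  skipped <- setdiff(s$bin[s$n >= 1L], usable)
  if (length(usable) < 2L) stop("need at least 2 bins with n >= 2")
  k <- length(usable)
  combs <- utils::combn(usable, 2L)
  rows <- apply(combs, 2L, function(pr) {
    a <- s[s$bin == pr[1L], ]
    b <- s[s$bin == pr[2L], ]
    se2a <- a$variance / a$n
    se2b <- b$variance / b$n
    se <- sqrt(se2a + se2b)
    diff <- a$mean - b$mean
    if (se == 0) {
      # identical degenerate groups: zero-width interval at 0
      return(data.frame(bin_a = pr[1L], bin_b = pr[2L], diff = diff,
                        ci_lo = diff, ci_hi = diff,
                        significant = diff != 0))
    }
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1L) + se2b^2 / (b$n - 1L))
    # qtukey is undefined below 2 df; floor the Welch df there (n = 2 bins)
    q <- stats::qtukey(conf_level, nmeans = k, df = max(df, 2)) / sqrt(2)
    data.frame(bin_a = pr[1L], bin_b = pr[2L], diff = diff,
               ci_lo = diff - q * se, ci_hi = diff + q * se,
               significant = (diff - q * se > 0) | (diff + q * se < 0))
  })
  structure(list(pairs = do.call(rbind, rows), skipped = skipped),
            class = "dtk_result")
}
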
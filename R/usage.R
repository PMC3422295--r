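#' Count codons in a gene set
#'
#' Tallies sense codons (and, separately, terminal stop codons) per gene or
#' pooled over a whole gene set. Counting is exact: every in-frame codon of a
#' validated gene contributes, including the initiator ATG unless
#' `drop_initiator = TRUE`. Codons containing non-ACGT characters (possible
#' under the `keep` validation policy) are ignored.
#'
#' @param genes A `gene_set`, or a character vector of codons for a single
#'   gene.
#' @param pool If `TRUE` (default) return one pooled `codon_counts`; if
#'   `FALSE`, a named list with one `codon_counts` per gene.
#' @param drop_initiator Exclude the initiator ATG from the sense tallies.
#' @return A `codon_counts` object: list with `x` (named integer over the 61
#'   sense codons), `stops` (named integer over TAA/TAG/TGA), `total_sense`,
#'   and `scope`. Or a list of such objects when `pool = FALSE`.
#' @examples
#' cc <- count_codons(c("ATG", "GAA", "GAA", "GAG", "TAA"))
#' cc$x[c("ATG", "GAA", "GAG")]
#' @export
count_codons <- function(genes, pool = TRUE, drop_initiator = FALSE) {
  code <- standard_genetic_code()
  if (is.character(genes)) {
    return(count_one(genes, code, drop_initiator, scope = "gene"))
  }
  stopifnot(inherits(genes, "gene_set"))
  if (length(genes$genes) == 0L) {
    warning("empty gene set: ", genes$species_id)
    if (pool) return(count_one(character(0), code, drop_initiator, "genome"))
    return(list())
  }
  per_gene <- lapply(genes$genes, count_one, code = code,
                     drop_initiator = drop_initiator, scope = "gene")
  if (!pool) return(per_gene)
  x <- Reduce(`+`, lapply(per_gene, `[[`, "x"))
  stops <- Reduce(`+`, lapply(per_gene, `[[`, "stops"))
  structure(list(x = x, stops = stops, total_sense = sum(x),
                 scope = "genome"),
            class = "codon_counts")
}

count_one <- function(codons, code, drop_initiator = FALSE, scope = "gene") {
  if (drop_initiator && length(codons) > 0L && codons[1L] == "ATG") {
    codons <- codons[-1L]
  }
  x <- tabulate(factor(codons, levels = code$sense_codons),
                nbins = 61L)
  names(x) <- code$sense_codons
  st <- tabulate(factor(codons, levels = code$stop_codons), nbins = 3L)
  names(st) <- code$stop_codons
  structure(list(x = x, stops = st, total_sense = sum(x), scope = scope),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts (", x$scope, "): ", x$total_sense, " sense codons, ",
      sum(x$stops), " stops\n", sep = "")
  invisible(x)
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU is the observed codon count divided by its expectation under equal
#' usage of the synonymous codons of the same amino acid:
#' \deqn{RSCU_{ij} = x_{ij} / \left(\frac{1}{n_i}\sum_j x_{ij}\right)}
#' RSCU > 1 marks codons used more often than expected (frequent), RSCU < 1
#' less often (rare). Codons of amino acids absent from the input are
#' undefined (NA), not zero, so they carry no frequent/rare vote downstream.
#'
#' @param counts A `codon_counts` object (or anything [count_codons()]
#'   accepts).
#' @return An `rscu_table`: data.frame with columns `codon`, `aa`, `count`,
#'   `rscu`, `flag` (`frequent`/`rare`/`neutral`/`undefined`), one row per
#'   sense codon in lexicographic order.
#' @examples
#' cc <- count_codons(c("ATG", "GAA", "GAA", "GAA", "GAG", "TAA"))
#' subset(rscu(cc), aa == "E")
#' @export
rscu <- function(counts) {
  counts <- as_codon_counts(counts)
  code <- standard_genetic_code()
  x <- counts$x
  aa <- code$codon_to_aa[names(x)]
  fam_tot <- as.numeric(tapply(x, aa, sum)[aa])   # strip tapply's dim
  n_i <- code$degeneracy[aa]
  val <- ifelse(fam_tot > 0, x / (fam_tot / n_i), NA_real_)
  flag <- ifelse(is.na(val), "undefined",
          ifelse(val > 1, "frequent", ifelse(val < 1, "rare", "neutral")))
  structure(
    data.frame(codon = names(x), aa = unname(aa), count = unname(x),
               rscu = unname(val), flag = unname(flag),
               stringsAsFactors = FALSE),
    class = c("rscu_table", "data.frame")
  )
}

as_codon_counts <- function(counts) {
  if (inherits(counts, "codon_counts")) return(counts)
  count_codons(counts)
}

#' Wright's effective number of codons from class homozygosities
#'
#' Combines the average homozygosity of each degeneracy class into the
#' effective number of codons:
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}
#' Values above 61 are capped at 61 (the no-bias limit); 20 is the
#' maximal-bias limit where a single codon serves each amino acid.
#'
#' @param f2,f3,f4,f6 Mean homozygosity of the 2-, 3-, 4- and 6-fold classes.
#' @return ENC in `[20, 61]`, or `NA` if any class value is missing or
#'   non-positive.
#' @examples
#' enc_wright(1, 1, 1, 1)              # 20: one codon per amino acid
#' enc_wright(1/2, 1/3, 1/4, 1/6)      # 61: uniform usage plug-in
#' @export
enc_wright <- function(f2, f3, f4, f6) {
  f <- c(f2, f3, f4, f6)
  if (anyNA(f) || any(f <= 0)) return(NA_real_)
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(val, 61)
}

#' Effective number of codons (ENC) of a gene or genome
#'
#' Wright's estimator. For each amino acid with degeneracy \eqn{n_i \ge 2}
#' and at least two counted codons, the homozygosity is estimated as
#' \deqn{\hat F = \frac{n \sum_j \hat p_j^2 - 1}{n - 1}, \quad \hat p_j = x_j/n,}
#' averaged within each degeneracy class, and combined by [enc_wright()].
#' When the single 3-fold amino acid (Ile) is unobserved, \eqn{\bar F_3} is
#' estimated as the mean of \eqn{\bar F_2} and \eqn{\bar F_4} (the usual
#' CodonW-style fallback). Amino acids whose \eqn{\hat F} is zero or
#' undefined are skipped; if a class average remains undefined or
#' non-positive the ENC is `NA` with a reason.
#'
#' @param counts A `codon_counts` (or anything [count_codons()] accepts).
#' @return An `enc_value`: list with `enc` (in `[20, 61]` or `NA`),
#'   `f_hat_by_class` (named over classes 2/3/4/6), and `reason` (`NA` when
#'   defined).
#' @examples
#' g <- c("ATG", rep(c("GAA", "GAG"), 3), "TTT", "TTC", "TAA")
#' enc(g)$enc
#' @export
enc <- function(counts) {
  counts <- as_codon_counts(counts)
  code <- standard_genetic_code()
  f_aa <- vapply(names(code$families), function(a) {
    n_i <- code$degeneracy[[a]]
    if (n_i < 2L) return(NA_real_)
    x <- counts$x[code$families[[a]]]
    n <- sum(x)
    if (n < 2L) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1L))
  deg <- code$degeneracy[names(f_aa)]
  f_class <- vapply(names(enc_class_sizes), function(k) {
    vals <- f_aa[deg == as.integer(k)]
    vals <- vals[!is.na(vals) & vals > 0]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }, numeric(1L))
  names(f_class) <- names(enc_class_sizes)
  if (is.na(f_class[["3"]]) &&
      !is.na(f_class[["2"]]) && !is.na(f_class[["4"]])) {
    f_class[["3"]] <- mean(c(f_class[["2"]], f_class[["4"]]))
  }
  enc_val <- enc_wright(f_class[["2"]], f_class[["3"]],
                        f_class[["4"]], f_class[["6"]])
  reason <- if (is.na(enc_val)) "undefined class homozygosity" else NA_character_
  structure(list(enc = enc_val, f_hat_by_class = f_class, reason = reason),
            class = "enc_value")
}

#' Codon adaptation index (CAI)
#'
#' Sharp & Li's CAI: the geometric mean, over a gene's codons, of the relative
#' adaptiveness values derived from a reference set (typically ribosomal
#' protein genes): \eqn{w_{ij} = RSCU_{ij}^{ref} / \max_j RSCU_{ij}^{ref}}.
#' Reference codons with zero count receive the conventional floor
#' `w = 0.01`; single-codon families (ATG/Met, TGG/Trp) and stop codons are
#' excluded from the geometric mean, as are codons of amino acids wholly
#' absent from the reference.
#'
#' @param counts Codon counts of the gene (or genome) being scored.
#' @param reference Codon counts of the reference gene set.
#' @return A `cai_value`: list with `cai` in `(0, 1]` (`NA` if no codon
#'   remains after exclusions) and `w` (named numeric over the sense codons;
#'   NA for excluded families).
#' @examples
#' ref <- count_codons(c("ATG", rep("GAA", 9), "GAG", "TAA"))
#' cai(count_codons(c("ATG", "GAA", "GAA", "TAA")), ref)$cai
#' @export
cai <- function(counts, reference) {
  counts <- as_codon_counts(counts)
  reference <- as_codon_counts(reference)
  if (reference$total_sense == 0L) stop("empty reference counts")
  code <- standard_genetic_code()
  ref_rscu <- rscu(reference)
  w <- pmax(ref_rscu$rscu, 0.01)
  names(w) <- ref_rscu$codon
  aa <- code$codon_to_aa[names(w)]
  w_max <- as.numeric(tapply(w, aa, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })[aa])
  w <- w / w_max                     # NA where family absent from reference
  single <- code$degeneracy[aa] < 2L
  use <- !single & !is.na(w)
  x <- counts$x[names(w)]
  L <- sum(x[use])
  cai_val <- if (L == 0L) NA_real_ else exp(sum(x[use] * log(w[use])) / L)
  structure(list(cai = cai_val, w = w), class = "cai_value")
}

#' Nucleotide composition of coding sequences
#'
#' GC content over all positions of sense codons, plus third-position base
#' fractions. The "silent" variants (`a3s`, `t3s`, `c3s`, `g3s`, `gc3s`) are
#' computed over third positions of synonymously variable codons only, i.e.
#' excluding ATG (Met) and TGG (Trp), whose third position cannot vary; plain
#' third-position fractions over all sense codons are also returned.
#' Stop codons are excluded throughout; the initiator ATG is counted (a
#' documented convention, see the package vignette).
#'
#' @param x A `codon_counts`, `gene_set`, or codon character vector.
#' @return A `composition_profile`: list with `gc`, `gc3s`, `a3s`, `t3s`,
#'   `c3s`, `g3s`, and plain `a3`, `t3`, `c3`, `g3`.
#' @examples
#' composition(c("ATG", "GCC", "GCC", "TAA"))$gc3s
#' @export
composition <- function(x) {
  counts <- as_codon_counts(x)
  code <- standard_genetic_code()
  cx <- counts$x
  codons <- names(cx)
  total_nt <- 3 * sum(cx)
  if (total_nt == 0) {
    return(structure(as.list(stats::setNames(rep(NA_real_, 10),
      c("gc", "gc3s", "a3s", "t3s", "c3s", "g3s", "a3", "t3", "c3", "g3"))),
      class = "composition_profile"))
  }
  base_mat <- vapply(c("A", "C", "G", "T"), function(b) {
    vapply(strsplit(codons, ""), function(tr) sum(tr == b), numeric(1L))
  }, numeric(length(codons)))
  gc <- sum(cx * (base_mat[, "C"] + base_mat[, "G"])) / total_nt
  third <- substr(codons, 3L, 3L)
  frac3 <- function(keep) {
    tot <- sum(cx[keep])
    if (tot == 0) return(stats::setNames(rep(NA_real_, 4), c("A", "T", "C", "G")))
    vapply(c("A", "T", "C", "G"),
           function(b) sum(cx[keep & third == b]) / tot, numeric(1L))
  }
  all_sense <- rep(TRUE, length(codons))
  syn <- !codons %in% c("ATG", "TGG")
  p3 <- frac3(all_sense)
  p3s <- frac3(syn)
  structure(list(
    gc = gc,
    gc3s = unname(p3s["C"] + p3s["G"]),
    a3s = unname(p3s["A"]), t3s = unname(p3s["T"]),
    c3s = unname(p3s["C"]), g3s = unname(p3s["G"]),
    a3 = unname(p3["A"]), t3 = unname(p3["T"]),
    c3 = unname(p3["C"]), g3 = unname(p3["G"])
  ), class = "composition_profile")
}

#' Amino-acid frequencies of a gene set
#'
#' Residue fractions over the 20 amino acids, computed from sense-codon
#' counts (terminal stops excluded).
#'
#' @param genes A `gene_set`, `codon_counts`, or codon vector.
#' @return Named numeric of length 20 summing to 1 (NaN-free only when at
#'   least one residue is present).
#' @examples
#' aa_frequencies(c("ATG", "CTG", "GAA", "TAA"))
#' @export
aa_frequencies <- function(genes) {
  counts <- as_codon_counts(genes)
  code <- standard_genetic_code()
  aa <- code$codon_to_aa[names(counts$x)]
  tot <- tapply(counts$x, aa, sum)
  tot <- tot[sort(names(code$degeneracy))]
  stats::setNames(as.numeric(tot / sum(tot)), names(tot))
}

#' Per-gene usage table
#'
#' Convenience wrapper computing, for every gene in a set, ENC, CAI (when a
#' reference is supplied), SCUO, and third-position composition — the
#' gene-level table the regression and trend analyses consume.
#'
#' @param genes A `gene_set`.
#' @param reference Optional reference `codon_counts` for CAI.
#' @return A data.frame keyed by `gene_id` with columns `n_codons`, `enc`,
#'   `cai`, `scuo`, `gc`, `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`.
#' @export
gene_usage_table <- function(genes, reference = NULL) {
  stopifnot(inherits(genes, "gene_set"))
  per <- count_codons(genes, pool = FALSE)
  rows <- lapply(names(per), function(id) {
    cc <- per[[id]]
    comp <- composition(cc)
    data.frame(
      gene_id = id,
      n_codons = cc$total_sense,
      enc = enc(cc)$enc,
      cai = if (is.null(reference)) NA_real_ else cai(cc, reference)$cai,
      scuo = scuo(cc)$scuo,
      gc = comp$gc, gc3s = comp$gc3s,
      a3s = comp$a3s, t3s = comp$t3s, c3s = comp$c3s, g3s = comp$g3s,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
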
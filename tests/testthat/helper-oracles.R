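# Independent brute-force oracles, written as naive loops over the code
# table. They deliberately share no code with the package implementations.

oracle_code_table <- function() {
  tab <- as.character(Biostrings::GENETIC_CODE)
  names(tab) <- names(Biostrings::GENETIC_CODE)
  tab
}

# RSCU by explicit per-amino-acid loops
oracle_rscu <- function(x) {
  tab <- oracle_code_table()
  sense <- sort(names(tab)[tab != "*"])
  out <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (a in unique(tab[sense])) {
    fam <- sense[tab[sense] == a]
    tot <- 0
    for (cod in fam) tot <- tot + x[[cod]]
    if (tot == 0) next
    for (cod in fam) out[[cod]] <- x[[cod]] / (tot / length(fam))
  }
  out
}

# Wright's ENC by explicit loops (same missing-class conventions)
oracle_enc <- function(x) {
  tab <- oracle_code_table()
  sense <- sort(names(tab)[tab != "*"])
  f_by_deg <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in unique(tab[sense])) {
    fam <- sense[tab[sense] == a]
    if (length(fam) < 2) next
    n <- 0
    for (cod in fam) n <- n + x[[cod]]
    if (n < 2) next
    s <- 0
    for (cod in fam) s <- s + (x[[cod]] / n)^2
    f <- (n * s - 1) / (n - 1)
    if (is.na(f) || f <= 0) next
    k <- as.character(length(fam))
    f_by_deg[[k]] <- c(f_by_deg[[k]], f)
  }
  fc <- sapply(f_by_deg, function(v) if (length(v)) mean(v) else NA_real_)
  if (is.na(fc[["3"]]) && !is.na(fc[["2"]]) && !is.na(fc[["4"]])) {
    fc[["3"]] <- (fc[["2"]] + fc[["4"]]) / 2
  }
  if (any(is.na(fc)) || any(fc <= 0)) return(NA_real_)
  min(61, 2 + 9 / fc[["2"]] + 1 / fc[["3"]] + 5 / fc[["4"]] + 3 / fc[["6"]])
}

# Composition-weighted SCUO by explicit loops
oracle_scuo <- function(x) {
  tab <- oracle_code_table()
  sense <- sort(names(tab)[tab != "*"])
  num <- 0; den <- 0
  parts <- list()
  for (a in unique(tab[sense])) {
    fam <- sense[tab[sense] == a]
    if (length(fam) < 2) next
    cnt <- 0
    for (cod in fam) cnt <- cnt + x[[cod]]
    if (cnt == 0) next
    H <- 0
    for (cod in fam) {
      p <- x[[cod]] / cnt
      if (p > 0) H <- H - p * log2(p)
    }
    O <- (log2(length(fam)) - H) / log2(length(fam))
    parts[[a]] <- c(cnt, O)
    den <- den + cnt
  }
  if (den == 0) return(NA_real_)
  for (pp in parts) num <- num + (pp[1] / den) * pp[2]
  num
}

# Two-sided Fisher p by exhaustive enumeration over all tables sharing the
# observed margins, probabilities from log-factorials.
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- r1 + r2
  ltab <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(N + 1) - lgamma(aa + 1) - lgamma(bb + 1) - lgamma(cc + 1) -
      lgamma(dd + 1)
  }
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  lp <- vapply(lo:hi, ltab, numeric(1))
  p_obs <- exp(ltab(a))
  min(1, sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]))
}

# Chi-square statistic of a contingency matrix via an explicit cell loop
oracle_chisq <- function(m) {
  N <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- rs[i] * cs[j] / N
      if (e > 0) stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# Random sense-codon count vector (named over the 61 codons)
random_counts <- function(seed, lambda_max = 30) {
  set.seed(seed)
  code <- standard_genetic_code()
  x <- rpois(61, runif(61, 2, lambda_max)) + 1L
  stats::setNames(as.integer(x), code$sense_codons)
}

counts_object <- function(x) {
  code <- standard_genetic_code()
  structure(list(x = x[code$sense_codons],
                 stops = stats::setNames(integer(3), code$stop_codons),
                 total_sense = sum(x), scope = "gene"),
            class = "codon_counts")
}

# Gene set built directly from codon vectors (no validation round trip);
# used where tests need bodies the validator would reject (e.g. the
# position-permutation null, which may contain internal stops).
raw_gene_set <- function(codon_list, species_id = "raw") {
  if (is.null(names(codon_list))) {
    names(codon_list) <- paste0("g", seq_along(codon_list))
  }
  structure(list(species_id = species_id, genes = codon_list,
                 excluded = data.frame(gene_id = character(0),
                                       reason = character(0))),
            class = "gene_set")
}

# A null genome for the permutation test: bases drawn independently per
# position, so the observed data are themselves a draw from the
# permutation null. Internal stops may occur and are left as written.
null_position_genome <- function(n_genes, n_codons, seed,
                                 p1 = rep(0.25, 4), p2 = rep(0.25, 4),
                                 p3 = rep(0.25, 4)) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  genes <- lapply(seq_len(n_genes), function(g) {
    body <- paste0(sample(bases, n_codons, TRUE, p1),
                   sample(bases, n_codons, TRUE, p2),
                   sample(bases, n_codons, TRUE, p3))
    c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1))
  })
  raw_gene_set(genes, species_id = "null")
}

# Minimal rscu_table with prescribed flags, for driving the cross-group test
flagged_rscu_table <- function(flags) {
  code <- standard_genetic_code()
  full <- stats::setNames(rep("neutral", 61), code$sense_codons)
  full[names(flags)] <- flags
  val <- ifelse(full == "frequent", 2,
         ifelse(full == "rare", 0.5, ifelse(full == "neutral", 1, NA)))
  structure(
    data.frame(codon = code$sense_codons,
               aa = unname(code$codon_to_aa[code$sense_codons]),
               count = 10L, rscu = unname(val), flag = unname(full),
               stringsAsFactors = FALSE),
    class = c("rscu_table", "data.frame"))
}
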
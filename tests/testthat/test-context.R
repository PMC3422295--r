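test_that("codon-pair counting separates internal and boundary pairs", {
  gs <- raw_gene_set(list(g = c("ATG", "GAA", "GAA", "GAA", "TAA")))
  pt <- count_codon_pairs(gs)
  expect_equal(pt$counts[["GAA", "GAA"]], 2L)
  expect_equal(pt$n_pairs, 2L)
  expect_equal(pt$start3[["GAA"]], 1L)
  expect_equal(pt$stop5["TAA", "GAA"], 1L)
  # three-codon gene contributes only boundary contexts
  pt3 <- count_codon_pairs(raw_gene_set(list(g = c("ATG", "GAT", "TAA"))))
  expect_equal(pt3$n_pairs, 0L)
  expect_equal(pt3$start3[["GAT"]], 1L)
  expect_equal(pt3$stop5["TAA", "GAT"], 1L)
  # additivity over genes
  g1 <- raw_gene_set(list(a = c("ATG", "GAA", "GAG", "GAA", "TAA")))
  g2 <- raw_gene_set(list(b = c("ATG", "CTG", "GAG", "GAA", "TGA")))
  both <- raw_gene_set(list(a = g1$genes$a, b = g2$genes$b))
  expect_equal(count_codon_pairs(both)$counts,
               count_codon_pairs(g1)$counts + count_codon_pairs(g2)$counts)
})

test_that("pair totals equal sum(L - 3) exclusive / sum(L - 1) inclusive", {
  sim <- generate_genes(make_profile("hymenoptera_like", seed = 3,
                                     length_mean = 50), 150, seed = 31)
  L <- vapply(sim$genes$genes, length, integer(1))
  expect_equal(count_codon_pairs(sim$genes)$n_pairs, sum(L - 3))
  pti <- count_codon_pairs(sim$genes, inclusive = TRUE)
  expect_equal(pti$n_pairs, sum(L - 1))
  expect_true(all(standard_genetic_code()$stop_codons %in%
                  colnames(pti$counts)))
})

test_that("adjusted residuals match the Haberman formula and independence", {
  # table exactly proportional to its margins: all residuals zero
  m <- outer(c(10, 20, 30), c(5, 15)) / 10
  expect_true(all(abs(adjusted_residuals(m)) < 1e-10))
  # 2x2 hand case: residual = sqrt(chi-square) with sign of association
  m2 <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  r2 <- adjusted_residuals(m2)
  expect_equal(r2[1, 1], 10 / sqrt(5), tolerance = 1e-12)
  expect_equal(r2[1, 2], -10 / sqrt(5), tolerance = 1e-12)
  # under independence sampling, residuals are ~ standard normal
  set.seed(8)
  pr <- outer(stats::runif(30, 0.5, 2), stats::runif(30, 0.5, 2))
  tab <- matrix(stats::rmultinom(1, 1e5, pr / sum(pr)), 30, 30)
  sd_emp <- stats::sd(adjusted_residuals(tab), na.rm = TRUE)
  expect_true(sd_emp > 0.9 && sd_emp < 1.1)
})

test_that("pair-table chi-square matches an independent cell loop", {
  sim <- generate_genes(make_profile("diptera_like", seed = 12,
                                     length_mean = 60), 100, seed = 41)
  pt <- count_codon_pairs(sim$genes)
  m <- pt$counts
  N <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / N
  stat <- sum(((m - e)^2 / e)[e > 0])
  expect_equal(stat, oracle_chisq(m), tolerance = 1e-9)
})

test_that("RSCPU normalises to the degeneracy product per amino-acid pair", {
  # hand case: all four Glu-Glu codon pairs on (GAA,GAA)
  gs <- raw_gene_set(list(g = c("ATG", "CAT", rep("GAA", 5), "CAT", "TAA")))
  pt <- count_codon_pairs(gs)
  expect_equal(rscpu(pt)[["GAA", "GAA"]], 4)
  # uniform usage within an amino-acid pair: all RSCPU = 1
  gs2 <- raw_gene_set(lapply(
    list(c("GAA", "GAA"), c("GAA", "GAG"), c("GAG", "GAA"), c("GAG", "GAG")),
    function(p) c("ATG", "CAT", p, "CAT", "TAA")))
  r2 <- rscpu(count_codon_pairs(gs2))
  expect_equal(unname(r2[c("GAA", "GAG"), c("GAA", "GAG")]),
               matrix(1, 2, 2))
  # normalisation identity on a synthetic genome
  sim <- generate_genes(make_profile("diptera_like", seed = 2,
                                     length_mean = 80), 80, seed = 51)
  pt3 <- count_codon_pairs(sim$genes)
  rv <- rscpu(pt3)
  code <- standard_genetic_code()
  aa5 <- code$codon_to_aa[rownames(rv)]
  aa3 <- code$codon_to_aa[colnames(rv)]
  key <- outer(aa5, aa3, paste0)
  sums <- tapply(as.vector(rv), as.vector(key), sum)
  prods <- tapply(as.vector(outer(code$degeneracy[aa5],
                                  code$degeneracy[aa3])),
                  as.vector(key), unique)
  defined <- names(sums)[!is.na(sums)]
  expect_equal(unname(sums[defined]), unname(prods[defined]),
               tolerance = 1e-9)
})

test_that("boundary contexts report most/least frequent codons with ties", {
  gs <- raw_gene_set(list(
    a = c("ATG", "AAA", "TAA"), b = c("ATG", "AAA", "TAA"),
    c = c("ATG", "CAT", "AAA", "TAA"), d = c("ATG", "CCC", "TAA")))
  bc <- boundary_contexts(gs)
  s <- bc$summary
  expect_equal(s$most_frequent[s$table == "TAA"], "AAA")
  expect_equal(s$mf_count[s$table == "TAA"], 3)
  expect_equal(s$least_frequent[s$table == "TAA"], "CCC")
  expect_equal(s$most_frequent[s$table == "start3"], "AAA")
  expect_equal(sum(bc$stop5["TAA", ]), 4)      # all genes end in TAA
  expect_equal(sum(bc$start3), 4)              # all genes have >= 3 codons
})

test_that("an injected stop-flanking preference is recovered at scale", {
  pr <- make_profile("uniform", seed = 5, length_mean = 25,
                     boundary_bias = list(stop5 = "AAA", start3 = "GAT",
                                          prob = 0.5))
  sim <- generate_genes(pr, 800, seed = 61)
  s <- boundary_contexts(sim$genes)$summary
  for (st in c("TAA", "TAG", "TGA")) {
    expect_equal(s$most_frequent[s$table == st], "AAA")
  }
  expect_equal(s$most_frequent[s$table == "start3"], "GAT")
})

test_that("amino-acid pair frequencies commute with the genetic code", {
  sim <- generate_genes(make_profile("hymenoptera_like", seed = 9,
                                     length_mean = 60), 60, seed = 71)
  apf <- aa_pair_frequencies(sim$genes)
  expect_equal(sum(apf), 1, tolerance = 1e-12)
  # aggregation of the codon-pair table through the code gives the same table
  pt <- count_codon_pairs(sim$genes)
  code <- standard_genetic_code()
  agg <- tapply(as.vector(pt$counts),
                list(code$codon_to_aa[rownames(pt$counts)][row(pt$counts)],
                     code$codon_to_aa[colnames(pt$counts)][col(pt$counts)]),
                sum)
  agg <- agg / sum(agg)
  expect_equal(apf[rownames(agg), colnames(agg)], agg, tolerance = 1e-12)
})

test_that("frequent-context report surfaces stop-ending rare contexts", {
  gs <- raw_gene_set(list(
    a = c("ATG", "GAA", "GAA", "GAA", "TAA"),
    b = c("ATG", "GAA", "GAA", "CCC", "TAG")))
  fc <- frequent_contexts(gs, inclusive = TRUE, alphabet = "rna")
  expect_equal(fc$frequent_context, "GAA-GAA")
  expect_equal(fc$frequent_count, 3)           # inclusive counting
  expect_true(grepl("(UAA|UAG)$", fc$rare_context) ||
              fc$rare_count == 1)
})

test_that("context clustering joins identical species and counts leaves", {
  set.seed(10)
  base <- matrix(stats::rnorm(61 * 61), 61, 61,
                 dimnames = list(standard_genetic_code()$sense_codons,
                                 standard_genetic_code()$sense_codons))
  other <- base + matrix(stats::rnorm(61 * 61, 0, 3), 61, 61)
  tr <- context_cluster_tree(list(A = base, B = base, C = other))
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  d <- ape::cophenetic.phylo(tr)
  expect_lt(d["A", "B"], d["A", "C"])
  expect_lt(d["A", "B"], 1e-10)
  # a species with mostly-undefined residuals is excluded with a warning
  sparse <- base; sparse[1:61, 1:40] <- NA
  expect_warning(
    tr2 <- context_cluster_tree(list(A = base, B = base, C = other,
                                     D = sparse)),
    "excluding")
  expect_equal(sort(tr2$tip.label), c("A", "B", "C"))
})
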
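test_that("codon counting is exact, separates stops, and pools additively", {
  cc <- count_codons(c("ATG", "GAA", "GAA", "GAG", "TAA"))
  expect_equal(unname(cc$x[c("ATG", "GAA", "GAG")]), c(1L, 2L, 1L))
  expect_equal(unname(cc$stops[["TAA"]]), 1L)
  expect_equal(cc$total_sense, 4L)
  gs <- gene_set(c(a = "ATGGAAGAGTAA", b = "ATGGAATAA"))
  per <- count_codons(gs, pool = FALSE)
  pooled <- count_codons(gs, pool = TRUE)
  expect_equal(pooled$x, per$a$x + per$b$x)
  expect_equal(pooled$stops, per$a$stops + per$b$stops)
  # pooled total equals the sum of per-gene totals on a larger synthetic set
  sim <- generate_genes(make_profile("hymenoptera_like", seed = 4,
                                     length_mean = 60), 200, seed = 11)
  per <- count_codons(sim$genes, pool = FALSE)
  expect_equal(count_codons(sim$genes)$total_sense,
               sum(vapply(per, `[[`, numeric(1), "total_sense")))
  expect_equal(count_codons(c("ATG", "GAA", "TAA"),
                            drop_initiator = TRUE)$x[["ATG"]], 0L)
})

test_that("RSCU matches hand evaluation and flags absent families undefined", {
  cc <- count_codons(c("ATG", rep("GAA", 3), "GAG", "TAA"))
  rt <- rscu(cc)
  expect_equal(rt$rscu[rt$codon == "GAA"], 1.5)
  expect_equal(rt$rscu[rt$codon == "GAG"], 0.5)
  expect_equal(rt$flag[rt$codon == "GAA"], "frequent")
  expect_equal(rt$rscu[rt$codon == "ATG"], 1)         # Met always 1
  expect_equal(rt$flag[rt$codon == "TTT"], "undefined")
  expect_true(is.na(rt$rscu[rt$codon == "TTT"]))
  # six-fold family concentrated on one codon
  rt2 <- rscu(count_codons(c("ATG", rep("CTG", 6), "TAA")))
  expect_equal(rt2$rscu[rt2$codon == "CTG"], 6)
  expect_equal(rt2$rscu[rt2$codon == "CTA"], 0)
})

test_that("RSCU values sum to the degeneracy within every counted family", {
  code <- standard_genetic_code()
  for (seed in c(1, 2, 3, 4, 5)) {
    rt <- rscu(counts_object(random_counts(seed)))
    sums <- tapply(rt$rscu, rt$aa, sum)
    expect_equal(as.numeric(sums[names(code$degeneracy)]),
                 unname(as.numeric(code$degeneracy)), tolerance = 1e-12)
  }
})

test_that("RSCU agrees with seqinr's independent implementation", {
  skip_if_not_installed("seqinr")
  sim <- generate_genes(make_profile("diptera_like", seed = 8,
                                     length_mean = 300), 5, seed = 3)
  g <- sim$genes$genes[[1]]
  ours <- rscu(count_codons(g))
  theirs <- seqinr::uco(seqinr::s2c(paste0(g, collapse = "")),
                        index = "rscu")
  names(theirs) <- toupper(names(theirs))
  for (cod in ours$codon[!is.na(ours$rscu)]) {
    expect_equal(ours$rscu[ours$codon == cod], unname(theirs[[cod]]),
                 tolerance = 1e-9)
  }
})

test_that("ENC hits Wright's boundary values and hand homozygosity", {
  # one codon per family, all class homozygosities 1 -> ENC = 20
  code <- standard_genetic_code()
  one_per_family <- unlist(lapply(code$families, function(f) rep(f[1], 3)))
  expect_equal(enc(count_codons(c("ATG", one_per_family, "TAA")))$enc, 20)
  # uniform plug-in homozygosities -> 61
  expect_equal(enc_wright(1 / 2, 1 / 3, 1 / 4, 1 / 6), 61)
  # Phe {TTT:2, TTC:2}: F2 = (4 * 0.5 - 1) / 3 = 1/3
  x <- stats::setNames(integer(61), code$sense_codons)
  x[c("TTT", "TTC")] <- 2L
  ev <- enc(counts_object(x))
  expect_equal(unname(ev$f_hat_by_class[["2"]]), 1 / 3, tolerance = 1e-12)
})

test_that("ENC stays in [20, 61] and falls as usage concentrates", {
  code <- standard_genetic_code()
  uniform <- stats::setNames(rep(60L, 61), code$sense_codons)
  single <- stats::setNames(integer(61), code$sense_codons)
  for (f in code$families) single[f[1]] <- 60L * length(f)
  encs <- vapply(seq(0, 1, by = 0.1), function(a) {
    mix <- round((1 - a) * uniform + a * single)
    enc(counts_object(mix))$enc
  }, numeric(1))
  expect_true(all(encs >= 20 & encs <= 61))
  expect_true(all(diff(encs) < 1e-9))   # monotone non-increasing
  expect_equal(encs[11], 20)
  # missing 3-fold class (no Ile): fallback keeps ENC defined
  noile <- uniform
  noile[code$families[["I"]]] <- 0L
  expect_false(is.na(enc(counts_object(noile))$enc))
})

test_that("CAI is the geometric mean of reference-derived adaptiveness", {
  ref <- count_codons(c("ATG", rep("GAA", 12), rep("GAG", 3),
                        rep("TTT", 8), rep("TTC", 2), "TAA"))
  w <- cai(count_codons(c("ATG", "GAA", "TAA")), ref)$w
  expect_equal(unname(w[["GAA"]]), 1)
  expect_equal(unname(w[["GAG"]]), 0.25)
  # gene using only maximal-w codons -> CAI = 1
  expect_equal(cai(count_codons(c("ATG", "GAA", "TTT", "TAA")), ref)$cai, 1)
  # equal counts of w = 1 and w = 0.25 -> geometric mean 0.5
  expect_equal(cai(count_codons(c("ATG", "GAA", "GAG", "TAA")), ref)$cai,
               0.5)
  # invariant to gene length at fixed codon proportions
  g1 <- c("ATG", rep(c("GAA", "GAG"), 5), "TAA")
  g2 <- c("ATG", rep(c("GAA", "GAG"), 50), "TAA")
  expect_equal(cai(count_codons(g1), ref)$cai,
               cai(count_codons(g2), ref)$cai)
  # zero-count reference codons floor at w = 0.01
  ref0 <- count_codons(c("ATG", rep("GAA", 5), "TAA"))
  expect_equal(unname(cai(count_codons(c("ATG", "GAG", "TAA")), ref0)$w[["GAG"]]),
               0.01 / 2)
})

test_that("composition partitions third positions and hits GC3 targets", {
  cp <- composition(c("ATG", "GCC", "GCC", "TAA"))
  expect_equal(cp$gc3s, 1)
  expect_equal(cp$c3s, 1)
  sim <- generate_genes(make_profile("uniform", seed = 1, length_mean = 80),
                        50, seed = 21)
  cps <- composition(count_codons(sim$genes))
  expect_equal(cps$a3s + cps$t3s + cps$c3s + cps$g3s, 1, tolerance = 1e-12)
  expect_equal(cps$a3 + cps$t3 + cps$c3 + cps$g3, 1, tolerance = 1e-12)
})

test_that("a GC3-targeted synthetic genome recovers its target composition", {
  # diptera-like tilt 0.7 with symmetric families: expected GC3s = 0.7
  pr <- make_profile("diptera_like", gc3_bias = 0.7, seed = 6,
                     length_mean = 400)
  pr$codon_weights <- lapply(standard_genetic_code()$families, function(f) {
    third <- substr(f, 3, 3)
    w <- ifelse(third %in% c("G", "C"), 0.7, 0.3)
    stats::setNames(w / sum(w), f)
  })
  sim <- generate_genes(pr, 300, seed = 13)    # ~1.2e5 codons
  gc3 <- composition(count_codons(sim$genes))$gc3s
  analytic <- local({
    code <- standard_genetic_code()
    num <- 0; den <- 0
    for (a in names(code$families)) {
      f <- code$families[[a]]
      if (code$degeneracy[[a]] < 2) next
      w <- pr$codon_weights[[a]]
      num <- num + pr$residue_freqs[[a]] *
        sum(w[substr(f, 3, 3) %in% c("G", "C")])
      den <- den + pr$residue_freqs[[a]]
    }
    num / den
  })
  expect_equal(gc3, analytic, tolerance = 0.02)
})

test_that("amino-acid frequencies recover the encoded residue distribution", {
  f <- aa_frequencies(c("ATG", "CTG", "GAA", "TAA"))
  expect_equal(unname(f[c("M", "L", "E")]), rep(1 / 3, 3))
  expect_equal(sum(f), 1)
  sim <- generate_genes(make_profile("uniform", seed = 5,
                                     length_mean = 200), 200, seed = 17)
  fr <- aa_frequencies(count_codons(sim$genes, drop_initiator = TRUE))
  truth <- sim$truth$profile$residue_freqs[names(fr)]
  expect_true(max(abs(fr - truth)) < 0.01)    # ~4e4 residues, multinomial
})

test_that("ENC, RSCU match naive-loop oracles on random counts", {
  for (seed in 1:25) {
    x <- random_counts(seed)
    cc <- counts_object(x)
    expect_equal(enc(cc)$enc, oracle_enc(x), tolerance = 1e-12)
    rt <- rscu(cc)
    expect_equal(stats::setNames(rt$rscu, rt$codon), oracle_rscu(x),
                 tolerance = 1e-12)
  }
})
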
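---
title: "Codon usage bias and codon context: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and codon context: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery of `codonscape`, the
conventions and numerical choices behind it, what the synthetic-data
generator does and does not emulate, and the package's known limitations.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Input model and validation

Every analysis starts from a set of in-frame coding sequences. A record is
accepted when it is a multiple of 3 and at least 6 nt long, contains only
A/C/G/T (U is normalised to T on input), begins with ATG, ends with one of
TAA/TAG/TGA, and has no internal stop. Each failing record is excluded with
exactly one reason, so `genes + excluded` always partitions the input.

Two validation policies deserve a note:

* **Non-ATG starts are excluded** (`no_start`). The boundary-context
  analysis is defined around the initiator ATG, so genes with alternative
  annotated starts would contaminate the 3′-of-start table.
* **Ambiguity codes reject the gene, not the base** (default). A single
  ambiguous codon cannot be tallied into the 64-cell table; under
  `policy = "keep"` the gene is retained and ambiguous codons are simply
  ignored by counting.

The genetic code is fixed to the standard nuclear code (translation table
1). Serine, leucine and arginine are treated as single six-fold families:
the expectation of a codon under unbiased usage is its amino-acid total
divided by the full degeneracy, which is the convention the RSCU, RSCPU and
SCUO definitions here share.

## Single-codon statistics

**RSCU.** `rscu()` divides observed counts by the equal-usage expectation.
Codons of amino acids absent from the input are *undefined*, not zero —
they carry no frequent/rare vote in cross-group tallies. Counting includes
the initiator ATG by default (`drop_initiator` reverses this) and tallies
terminal stops separately; stops never enter sense statistics.

**ENC.** `enc()` implements Wright's estimator
F̂ = (nΣp̂² − 1)/(n − 1) per amino acid, averaged within degeneracy
classes, combined as ENC = 2 + 9/F̂₂ + 1/F̂₃ + 5/F̂₄ + 3/F̂₆ and capped at
61. Conventions where the data are thin, chosen to match long-standing
CodonW-style behaviour: amino acids with fewer than 2 counted codons are
skipped; amino acids with F̂ = 0 are skipped (they carry no usable
homozygosity information); when the single three-fold amino acid (Ile) is
missing, 1/F̂₃ is estimated from the mean of F̂₂ and F̂₄; if any class
average is still undefined the ENC is `NA` with a reason. Note that with
finite counts the estimator slightly *undershoots* 1/k under exactly
uniform usage, so uniform inputs produce raw values just above 61 — the cap
is what makes "uniform usage ⇒ 61" exact. The uniform limit itself is
available analytically through `enc_wright(1/2, 1/3, 1/4, 1/6)`.

**CAI.** Relative adaptiveness w is derived from a reference set
(typically ribosomal protein genes): w = RSCU/max RSCU within each family,
with the conventional floor w = 0.01 for reference codons with zero count
(avoiding log 0 while still penalising them heavily). Single-codon families
(ATG, TGG) and stops are excluded from the geometric mean, as are families
wholly absent from the reference — for those not even a floor is
defensible.

**Composition.** GC is computed over all positions of sense codons
(initiator included, stops excluded); the silent fractions A3s/T3s/C3s/G3s
are computed over third positions of synonymously variable codons only
(ATG and TGG excluded, since their third position cannot vary). Plain
third-position fractions are also reported. These are documented
conventions rather than universal standards; the initiator-in, stops-out
choice is exposed through `drop_initiator` at the counting step.

## SCUO, binning and the Dunnett-T3 comparison

`scuo()` computes, per amino acid with n ≥ 2 and positive count, the
within-family entropy H (base 2; the base cancels in the ratio), the
normalised order O = (log₂n − H)/log₂n, and averages O with
composition weights F = family count / total multi-family count. The
definition used is the composition-weighted normalised entropy gap, which
maps 0 to no bias and 1 to one-codon-per-family usage. (A literal reading
of "one minus the ratio of expected to observed entropy" is inconsistent
with that range at maximal bias — the observed entropy is then 0 — so the
package implements the entropy-gap form that the SCUO literature actually
uses.)

Genes are binned into the ten 0.1-wide SCUO intervals with lower-inclusive
edges and a closed last bin: a value exactly on an edge goes up, 1.0 stays
in bin 10. This makes assignment deterministic and total.

`dtk_pairwise()` compares mean SCUO between all bin pairs with Dunnett's T3
modification of Tukey–Kramer, the appropriate choice when bin sizes and
variances differ: Welch standard error, Welch–Satterthwaite degrees of
freedom, and the studentized-range quantile at those df (divided by √2).
R's `qtukey` is undefined below 2 df, so the per-pair df is floored at 2 —
this only affects pairs involving bins of exactly 2 genes. Bins with fewer
than 2 members are skipped and reported. The comparison is run on per-bin
SCUO values with per-bin variances exposed alongside; comparing variance
contributions directly would be an alternative reading of "variance
comparison", and the per-bin variances in the `scuo_bins` summary allow it.

## Codon context

`count_codon_pairs()` tallies ordered adjacent codon pairs within genes
only. Two universes are provided:

* **exclusive** (default): internal pairs (c₂,c₃) … (c₍L−2₎,c₍L−1₎) into a
  61×61 sense table, with the start's right neighbour and the stop's left
  neighbour routed to the boundary-context tables instead;
* **inclusive**: all pairs (c₁,c₂) … (c₍L−1₎,c₎L₎) into a 61×64 table whose
  3′ columns include the stops — the mode for "most/least frequent
  context" reports, where the rarest contexts typically end in a stop.

The full 61×61 sense universe is used for residuals and RSCPU; no codon is
excluded, since no single defensible exclusion would reduce it to 60×60.
Ties in most/least-frequent reports break lexicographically and are
reported; "least frequent" means the minimum among observed (count > 0)
contexts.

**Adjusted residuals** are Haberman's:
(o − e)/√(e(1 − R/N)(1 − C/N)), approximately standard normal under
independence — the package's tests check that empirically on simulated
independent tables. **RSCPU** divides each codon pair's count by its
amino-acid-pair total over n_a·n_b, so values within an observed amino-acid
pair sum to n_a·n_b.

Cross-species context clustering flattens the residual matrices, computes
1 − Pearson correlation over cells defined in both species (a Spearman
option exists), and applies average-linkage `hclust`; species with fewer
than half their cells defined are excluded with a warning. The choice of
Pearson on residuals is a design decision — the residuals are already
standardised, so linear correlation is the natural similarity — and the
Spearman flag covers the rank-based alternative.

## Cross-group and regression analyses

**Fisher exact tests.** The per-codon cross-group table counts species with
RSCU > 1 versus RSCU < 1 in each group; neutral (RSCU exactly 1) and
undefined species are dropped. The two-sided p sums hypergeometric
probabilities not exceeding the observed table's (with the usual 1e-7
relative guard for floating-point ties). The suite verifies this against
exhaustive enumeration for every margin configuration up to N = 30 and
against `stats::fisher.test`. A chi-square alternative was considered and
rejected as the default because the printed reference values these tests
reproduce are exact probabilities.

**ENC regression.** `enc_regression()` fits
`enc ~ a3s + g3s + c3s + t3s` as a quasi-Poisson log-link GLM (IRLS
tolerance 1e-10): ENC is continuous, so the Poisson family is used as a
variance function, not a likelihood. The four fractions sum to 1, making
the intercept model rank-deficient; by default R's aliasing drops the last
term and the condition number of the model matrix is reported, while
`drop_t3s = TRUE` gives the explicit full-rank parameterisation in which
each coefficient is a contrast against T3s. Coefficient signs and
significance, not magnitudes, are the comparable surface across data sets.

**CAI–ENC trend.** Besides Pearson r, the "fraction of genes on the
inverse trend" is operationalised with a quadrant rule: a gene is
consistent when its CAI and ENC deviations from the respective medians
have opposite signs (genes exactly on a median drop out of the
denominator). This is a deliberate, documented reading of a scatter-plot
statement that has no unique formalisation.

**Spearman ortholog correlation.** Mid-rank ties; exact p for n ≤ 10,
t-approximation above (the `stats::cor.test` machinery).

## The permutation association test

`permute_positions()` shuffles, within each gene, the bases at codon
positions 1, 2 and 3 independently across the gene's internal codons,
leaving start and stop untouched. This preserves each gene's per-position
base multisets (hence GC and GC3) while destroying within-codon position
associations. Randomised genes are not re-validated: internal stops may
arise and are tallied as stops.

`codon_aa_association()` compares, per codon, observed totals and
equal-usage expectations (amino-acid total / degeneracy) against the same
quantities on randomised data (averaged over replicates; default 100), via
a 2×2 Pearson chi-square without continuity correction (a correction flag
exists).

An honest caveat, established by the package's own null simulations: the
two rows of that 2×2 are *not* independent samples — the randomised data
derive from the observed data, and the expectation columns nearly coincide
— so under a position-independent null the test is strongly conservative
(empirical type-I rate near 0 rather than the nominal 5%). It therefore
never over-claims association, and it has excellent power for the effect
it is designed to find: codon bias coupled to first/second-position
composition, which concentrates in the six-fold families (Leu/Arg/Ser)
whose synonymous structure spans those positions. The acceptance suite
demonstrates both properties.

## The synthetic-data generator

`make_profile()` defines the generative conditions: per-family codon
weights tilted along the GC3 axis (`diptera_like` toward G/C endings,
`hymenoptera_like` toward A/T, strength `gc3_bias`, default 0.7; within a
family the preferred side gets unnormalised weight `gc3_bias`, the other
side `1 − gc3_bias`), a small seeded log-normal jitter (sd 0.05) so
same-preset species differ, residue frequencies defaulting to leucine 9%,
tryptophan 1% and the remaining mass spread evenly (a realistic skew for
proteomes), and negative-binomial gene lengths (mean 400 codons,
dispersion 5 — a plausible CDS spread whose exact values are irrelevant to
correctness and recorded for reproducibility). `uniform` and
`extreme_bias` are exact presets without jitter.

`generate_genes()` draws residues i.i.d., codons from the family weights,
and appends uniform stops. Context bias multiplies the 3′ weight of listed
pairs by a boost b ≥ 1 during sequential generation, then renormalises.
One consequence worth spelling out: for a two-codon family with uniform
base weights, boost b = 3 on the homogeneous pair gives a conditional
probability of 3·0.5/(3·0.5 + 0.5) = 0.75 instead of 0.5, i.e. a
first-order RSCPU of 4 × 0.5 × 0.75 = 1.5 (chain effects push it somewhat
higher) — injected bias is recovered loudly by adjusted residuals and
clearly, but not unboundedly, by RSCPU. All randomness flows from one seed
through a fixed per-gene substream, so output is byte-identical across
runs and independent of generation order.

What the generator does **not** emulate: expression-correlated bias across
genes (every gene shares one profile), isochore/GC heterogeneity along the
genome, amino-acid composition differences between species, introns and
misannotation, and phylogenetic correlation between species beyond the
shared preset. Passing recovery tests therefore demonstrates that the
statistics measure what they claim under the stated generative model — not
that any particular biological dataset satisfies that model.

## Problem sizes and numerical settings

The test and acceptance workloads use desk-scale sizes chosen to make
sampling error comfortably smaller than the asserted tolerances: oracle
equivalences on 100 random count vectors at 1e-12 relative; Fisher
enumeration for all margins to N = 30; two-group recovery with 6 + 4
species of 150 genes (mean 120 codons); regression recovery at n = 5000
genes; permutation null over 12 genomes of 100 × 100 codons with 10
replicates; context-bias recovery at ~1e5 internal pairs; RSCU recovery at
~4e5 codons, where the ±0.05 band sits above the ~3σ multinomial envelope.
GLM convergence tolerance is 1e-10; the chi-square statistic over pair
tables matches an independent cell loop to 1e-9 relative.

## Limitations

* No expression data: CAI's reference set stands in for expression, and no
  Fop/tAI-style tRNA-adaptation measures are provided.
* The permutation chi-square is conservative by construction (above);
  treat its significant calls as strong evidence, its non-calls as weak
  evidence of absence.
* ENC is undefined for very short genes missing whole degeneracy classes;
  downstream tables carry `NA` rather than imputing.
* The cross-group test treats species as independent observations;
  phylogenetic non-independence is not modelled.
* Cluster trees are similarity summaries, not phylogenies.
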
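Package: codonscape
Title: Codon Usage Bias and Codon Context Analysis for Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide analysis of synonymous codon usage bias and codon
    context (adjacent codon-pair) patterns in sets of protein-coding
    sequences. Implements relative synonymous codon usage (RSCU), Wright's
    effective number of codons (ENC), the codon adaptation index (CAI),
    entropy-based synonymous codon usage order (SCUO) with interval binning
    and Dunnett-T3 all-pairs comparisons, third-position base composition,
    codon-pair contingency tables with Haberman adjusted residuals, relative
    synonymous codon pair usage (RSCPU), start/stop boundary contexts,
    codon-position permutation tests of the association between codon bias
    and amino-acid composition, cross-group Fisher exact tests of
    frequent/rare codon usage, composition regression of ENC, rank-correlation
    clustering of usage and context profiles, and a synthetic coding-sequence
    generator with controllable codon preference, GC3 bias and injectable
    codon-pair context bias for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
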
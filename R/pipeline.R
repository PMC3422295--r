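#' Run the full codon-usage and codon-context pipeline
#'
#' Orchestrates every analysis of the package for a set of species and
#' writes the complete report bundle to `out_dir`: per species an RSCU
#' table, amino-acid frequencies, a gene-level usage table (ENC, CAI, SCUO,
#' composition), SCUO interval bins with Dunnett-T3 pairwise comparisons,
#' the permutation association test, boundary contexts, the most/least
#' frequent codon contexts, adjusted residuals and RSCPU matrices; across
#' species a cross-group Fisher exact test (when groups are given),
#' rank-correlation cluster trees of RSCU (species and codons) and of
#' context residuals (Newick), a per-species ENC-composition regression
#' table, a CAI-ENC trend table, and a JSON run manifest with package
#' version, seeds and input checksums. Given identical inputs and seeds the
#' bundle is byte-identical across runs.
#'
#' @param species A list of species entries, each a list with `id`
#'   (unique), `cds` (FASTA path or a `gene_set`), optional `reference`
#'   (FASTA path, `gene_set`, or `codon_counts` for CAI), and optional
#'   `group` (label; exactly two labels across species enable the
#'   cross-group test).
#' @param out_dir Output directory (created if missing).
#' @param alpha Significance level used throughout.
#' @param seed Integer seed for the permutation test.
#' @param replicates Permutation replicates per species (0 skips the
#'   association test).
#' @param inclusive_contexts Use the inclusive pair universe for the
#'   most/least frequent context report (stops visible as 3' codons).
#' @param alphabet Alphabet for codon columns in the TSV reports.
#' @param strict Stop at the first failing species instead of recording and
#'   skipping it.
#' @return Invisibly, a list with `manifest` and per-species results.
#' @export
run_pipeline <- function(species, out_dir, alpha = 0.05, seed = 1L,
                         replicates = 10L, inclusive_contexts = TRUE,
                         alphabet = c("dna", "rna"), strict = FALSE) {
  alphabet <- match.arg(alphabet)
  ids <- vapply(species, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("species ids must be unique")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(...) {
    message(sprintf("[%7.2fs] ", proc.time()[["elapsed"]] - t0), ...)
  }
  as_set <- function(x, id) {
    if (inherits(x, "gene_set")) x else read_cds_fasta(x, species_id = id)
  }
  checksum <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      return(unname(tools::md5sum(x)))
    }
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    if (inherits(x, "gene_set")) write_cds_fasta(x, tmp)
    else writeLines(utils::capture.output(utils::str(x)), tmp)
    unname(tools::md5sum(tmp))
  }
  results <- list()
  failed <- character(0)
  rscu_by_species <- list()
  residuals_by_species <- list()
  groups <- stats::setNames(
    vapply(species, function(s) {
      if (is.null(s$group)) NA_character_ else as.character(s$group)
    }, character(1L)), ids)

  for (sp in species) {
    id <- sp$id
    res <- tryCatch({
      stage("species ", id, ": reading")
      gs <- as_set(sp$cds, id)
      ref <- NULL
      if (!is.null(sp$reference)) {
        ref <- if (inherits(sp$reference, "codon_counts")) sp$reference
               else count_codons(as_set(sp$reference, paste0(id, "_ref")))
      }
      pooled <- count_codons(gs)
      stage("species ", id, ": usage statistics")
      rt <- rscu(pooled)
      write_tsv_report(rt, file.path(out_dir, paste0(id, "_rscu.tsv")),
                       alphabet, codon_cols = "codon")
      aaf <- aa_frequencies(pooled)
      write_tsv_report(data.frame(aa = names(aaf), freq = unname(aaf)),
                       file.path(out_dir, paste0(id, "_aafreq.tsv")))
      gt <- gene_usage_table(gs, reference = ref)
      write_tsv_report(gt, file.path(out_dir, paste0(id, "_genes.tsv")))
      bins <- bin_scuo(stats::setNames(gt$scuo, gt$gene_id))
      write_tsv_report(bins$summary,
                       file.path(out_dir, paste0(id, "_scuo_bins.tsv")))
      dtk <- tryCatch(dtk_pairwise(bins), error = function(e) NULL)
      if (!is.null(dtk)) {
        write_tsv_report(dtk$pairs,
                         file.path(out_dir, paste0(id, "_dtk.tsv")))
      }
      assoc <- NULL
      if (replicates > 0L) {
        stage("species ", id, ": permutation association (",
              replicates, " replicates)")
        assoc <- codon_aa_association(gs, replicates = replicates,
                                      seed = seed, alpha = alpha)
        write_tsv_report(assoc,
                         file.path(out_dir, paste0(id, "_association.tsv")),
                         alphabet, codon_cols = "codon")
      }
      stage("species ", id, ": codon contexts")
      pt <- count_codon_pairs(gs, inclusive = FALSE)
      resid <- adjusted_residuals(pt)
      write_matrix_tsv(resid, file.path(out_dir, paste0(id, "_residuals.tsv")),
                       alphabet)
      write_matrix_tsv(rscpu(pt),
                       file.path(out_dir, paste0(id, "_rscpu.tsv")), alphabet)
      bc <- boundary_contexts(gs)
      write_tsv_report(bc$summary,
                       file.path(out_dir, paste0(id, "_boundary.tsv")),
                       alphabet,
                       codon_cols = c("most_frequent", "least_frequent"))
      fc <- frequent_contexts(gs, inclusive = inclusive_contexts,
                              alphabet = if (alphabet == "dna") "dna" else "rna")
      write_tsv_report(fc, file.path(out_dir, paste0(id, "_contexts.tsv")))
      rscu_by_species[[id]] <- rt
      residuals_by_species[[id]] <- resid
      list(genes = gs, pooled = pooled, rscu = rt, gene_table = gt,
           bins = bins, dtk = dtk, association = assoc, residuals = resid,
           boundary = bc)
    }, error = function(e) {
      if (strict) stop("species ", id, " failed: ", conditionMessage(e))
      warning("species ", id, " failed and was skipped: ",
              conditionMessage(e))
      failed <<- c(failed, id)
      NULL
    })
    if (!is.null(res)) results[[id]] <- res
  }
  ok <- names(results)

  stage("cross-species analyses")
  if (length(ok) >= 3L) {
    cl <- cluster_rscu(rscu_by_species[ok])
    ape::write.tree(cl$species_tree,
                    file.path(out_dir, "rscu_species_tree.nwk"))
    ape::write.tree(cl$codon_tree, file.path(out_dir, "rscu_codon_tree.nwk"))
    ctree <- context_cluster_tree(residuals_by_species[ok])
    ape::write.tree(ctree, file.path(out_dir, "context_tree.nwk"))
  }
  glab <- groups[ok]
  if (sum(!is.na(glab)) >= 4L && length(unique(stats::na.omit(glab))) == 2L) {
    gc_test <- cross_group_exact_test(rscu_by_species[ok[!is.na(glab)]],
                                      glab[!is.na(glab)], alpha = alpha)
    write_tsv_report(as.data.frame(gc_test),
                     file.path(out_dir, "group_test.tsv"),
                     alphabet, codon_cols = "codon")
  }
  reg_rows <- list()
  trend_rows <- list()
  for (id in ok) {
    gt <- results[[id]]$gene_table
    fit <- tryCatch(enc_regression(gt, alpha = alpha),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      reg_rows[[id]] <- cbind(species = id, fit$coefficients)
    }
    tr <- tryCatch(cai_enc_trend(gt), error = function(e) NULL)
    if (!is.null(tr) && !is.na(tr$pearson_r)) {
      trend_rows[[id]] <- data.frame(species = id,
                                     pearson_r = tr$pearson_r,
                                     inverse_fraction = tr$inverse_fraction,
                                     n = tr$n)
    }
  }
  if (length(reg_rows)) {
    write_tsv_report(do.call(rbind, reg_rows),
                     file.path(out_dir, "regression.tsv"))
  }
  if (length(trend_rows)) {
    write_tsv_report(do.call(rbind, trend_rows),
                     file.path(out_dir, "trend.tsv"))
  }
  manifest <- list(
    package = "codonscape",
    version = as.character(utils::packageVersion("codonscape")),
    seed = seed, alpha = alpha, replicates = replicates,
    alphabet = alphabet,
    species = lapply(species, function(s) {
      list(id = s$id, group = if (is.null(s$group)) NA else s$group,
           checksum = checksum(s$cds))
    }),
    failed = failed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage("done (", length(ok), " species, ", length(failed), " failed)")
  invisible(list(manifest = manifest, results = results))
}

#' Write a labelled numeric matrix as TSV
#'
#' @param m Matrix with dimnames (codon labels).
#' @param path Output path.
#' @param alphabet Render codon labels in DNA or RNA.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  rn <- rownames(m); cn <- colnames(m)
  if (alphabet == "rna") {
    rn <- format_codons(rn, "rna"); cn <- format_codons(cn, "rna")
  }
  df <- data.frame(codon_5prime = rn, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("codon_5prime", cn)
  write_tsv_report(df, path)
}
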
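#' Build a synthetic species codon-usage profile
#'
#' Defines the generative model for a synthetic genome: per-amino-acid
#' synonymous codon weights tilted along the GC3 axis, residue frequencies,
#' a gene-length distribution, and optional codon-pair context and boundary
#' biases. Presets encode the two qualitative regimes seen across insect
#' orders: `diptera_like` favours G/C-ending synonymous codons,
#' `hymenoptera_like` favours A/T-ending ones, `uniform` uses every
#' synonymous codon equally, and `extreme_bias` concentrates each family on
#' a single codon. Within each family a codon's unnormalised weight is
#' `gc3_bias` when its third base lies on the preferred side of the axis and
#' `1 - gc3_bias` otherwise, followed by a small seeded log-normal jitter
#' (sd 0.05) so that distinct species of the same preset differ; the jitter
#' is skipped for the exact `uniform` and `extreme_bias` presets.
#'
#' Residue frequencies default to a realistic skew: leucine 9%, tryptophan
#' 1%, the remaining 18 amino acids sharing the rest equally. Gene length
#' (in codons, excluding start/stop) is negative binomial with mean 400 and
#' dispersion 5, floored at 10.
#'
#' @param preset One of `"diptera_like"`, `"hymenoptera_like"`, `"uniform"`,
#'   `"extreme_bias"`.
#' @param gc3_bias Strength of the third-position tilt, in `[0, 1]`;
#'   ignored by `uniform` and `extreme_bias`.
#' @param seed Integer seed for the per-species jitter (and the codon choice
#'   of `extreme_bias`).
#' @param species_id Identifier attached to generated gene sets.
#' @param residue_freqs Optional named probability vector over the 20 amino
#'   acids (one-letter codes).
#' @param length_mean,length_dispersion Negative-binomial gene-length
#'   parameters (codons).
#' @param context_bias Optional list `list(pairs = <character "C5-C3">,
#'   boost = b)` with `b >= 1`: multiplies the sampling weight of the 3'
#'   codon whenever the previous codon completes a listed pair.
#' @param boundary_bias Optional list `list(start3 =, stop5 =, prob =)`:
#'   with probability `prob` the codon 3' of ATG (resp. 5' of the stop) is
#'   forced to the given codon.
#' @return A `species_profile` object.
#' @examples
#' pr <- make_profile("diptera_like", gc3_bias = 0.8, seed = 1)
#' pr$codon_weights$E
#' @export
make_profile <- function(preset = c("diptera_like", "hymenoptera_like",
                                    "uniform", "extreme_bias"),
                         gc3_bias = 0.7, seed = 1L,
                         species_id = preset[1L],
                         residue_freqs = NULL,
                         length_mean = 400, length_dispersion = 5,
                         context_bias = NULL, boundary_bias = NULL) {
  preset <- match.arg(preset)
  if (gc3_bias < 0 || gc3_bias > 1) stop("gc3_bias must be in [0, 1]")
  code <- standard_genetic_code()
  set.seed(as.integer(seed))
  codon_weights <- lapply(code$families, function(fam) {
    n <- length(fam)
    third <- substr(fam, 3L, 3L)
    w <- switch(preset,
      uniform = rep(1, n),
      extreme_bias = {
        v <- numeric(n); v[sample.int(n, 1L)] <- 1; v
      },
      diptera_like = ifelse(third %in% c("G", "C"), gc3_bias, 1 - gc3_bias),
      hymenoptera_like = ifelse(third %in% c("A", "T"), gc3_bias, 1 - gc3_bias)
    )
    if (preset %in% c("diptera_like", "hymenoptera_like")) {
      w <- w * exp(stats::rnorm(n, 0, 0.05))
    }
    stats::setNames(w / sum(w), fam)
  })
  if (is.null(residue_freqs)) {
    aas <- names(code$degeneracy)
    residue_freqs <- stats::setNames(rep(0.9 / 18, 20L), aas)
    residue_freqs[["L"]] <- 0.09
    residue_freqs[["W"]] <- 0.01
  }
  residue_freqs <- residue_freqs / sum(residue_freqs)
  if (!is.null(context_bias)) {
    stopifnot(is.list(context_bias), context_bias$boost >= 1,
              all(grepl("^[ACGT]{3}-[ACGT]{3}$", context_bias$pairs)))
  }
  structure(list(
    species_id = species_id, preset = preset, gc3_bias = gc3_bias,
    seed = as.integer(seed),
    codon_weights = codon_weights, residue_freqs = residue_freqs,
    length_mean = length_mean, length_dispersion = length_dispersion,
    context_bias = context_bias, boundary_bias = boundary_bias
  ), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("species_profile '", x$species_id, "' (", x$preset,
      ", gc3_bias = ", x$gc3_bias, ")\n", sep = "")
  invisible(x)
}

#' Analytic RSCU implied by a profile
#'
#' The RSCU a genome generated from `profile` converges to: degeneracy times
#' the codon's sampling weight within its family.
#'
#' @param profile A `species_profile`.
#' @return Named numeric over the 61 sense codons.
#' @export
profile_rscu <- function(profile) {
  code <- standard_genetic_code()
  out <- unlist(lapply(names(profile$codon_weights), function(a) {
    profile$codon_weights[[a]] * code$degeneracy[[a]]
  }))
  out[code$sense_codons]
}

#' Generate a synthetic gene set from a profile
#'
#' Draws `n_genes` coding sequences: gene length from the profile's
#' negative-binomial distribution (floored at 10 codons), residues i.i.d.
#' from the residue frequencies, codons from the per-family weights, an ATG
#' prepended and a uniformly chosen stop appended. When a context bias is
#' present, codons are drawn sequentially with the 3' weight of each listed
#' pair multiplied by the boost (then renormalised), injecting an excess of
#' those contexts; boundary biases force the codons flanking start/stop with
#' the configured probability. All randomness derives from `seed` through a
#' fixed per-gene substream, so results are independent of generation order
#' and byte-identical across runs.
#'
#' @param profile A `species_profile` from [make_profile()].
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @return A list with `genes` (a validated `gene_set`) and `truth` (a
#'   `ground_truth` list: the profile, seeds, analytic RSCU, and injected
#'   context pairs).
#' @examples
#' sim <- generate_genes(make_profile("uniform"), n_genes = 5, seed = 7)
#' length(sim$genes$genes)
#' @export
generate_genes <- function(profile, n_genes, seed) {
  stopifnot(inherits(profile, "species_profile"))
  if (n_genes < 1L) stop("n_genes must be >= 1")
  seed <- as.integer(seed)
  code <- standard_genetic_code()
  aas <- names(profile$residue_freqs)
  boost_env <- NULL
  if (!is.null(profile$context_bias)) {
    boost_env <- new.env(parent = emptyenv())
    for (p in profile$context_bias$pairs) {
      parts <- strsplit(p, "-", fixed = TRUE)[[1L]]
      key <- parts[1L]
      cur <- get0(key, envir = boost_env, ifnotfound = character(0))
      assign(key, c(cur, parts[2L]), envir = boost_env)
    }
  }
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    set.seed((seed + g * 1000003L) %% .Machine$integer.max)
    L <- max(10L, stats::rnbinom(1L, size = profile$length_dispersion,
                                 mu = profile$length_mean))
    res <- sample(aas, L, replace = TRUE, prob = profile$residue_freqs)
    if (is.null(boost_env)) {
      body <- character(L)
      for (a in unique(res)) {
        idx <- which(res == a)
        fam <- profile$codon_weights[[a]]
        body[idx] <- sample(names(fam), length(idx), replace = TRUE,
                            prob = fam)
      }
    } else {
      body <- character(L)
      for (k in seq_len(L)) {
        fam <- profile$codon_weights[[res[k]]]
        w <- fam
        if (k > 1L) {
          boosted <- get0(body[k - 1L], envir = boost_env,
                          ifnotfound = character(0))
          hit <- names(w) %in% boosted
          if (any(hit)) w[hit] <- w[hit] * profile$context_bias$boost
        }
        body[k] <- if (length(w) == 1L) names(w) else
          sample(names(w), 1L, prob = w)
      }
    }
    stop_codon <- sample(code$stop_codons, 1L)
    bb <- profile$boundary_bias
    if (!is.null(bb)) {
      if (!is.null(bb$start3) && stats::runif(1L) < bb$prob) {
        body[1L] <- bb$start3
      }
      if (!is.null(bb$stop5) && stats::runif(1L) < bb$prob) {
        body[L] <- bb$stop5
      }
    }
    genes[[g]] <- c("ATG", body, stop_codon)
  }
  ids <- sprintf("%s_g%05d", profile$species_id, seq_len(n_genes))
  gs <- structure(
    list(species_id = profile$species_id,
         genes = stats::setNames(genes, ids),
         excluded = data.frame(gene_id = character(0), reason = character(0),
                               stringsAsFactors = FALSE)),
    class = "gene_set"
  )
  truth <- structure(list(
    profile = profile, seed = seed,
    analytic_rscu = profile_rscu(profile),
    context_pairs = if (is.null(profile$context_bias)) character(0)
                    else profile$context_bias$pairs
  ), class = "ground_truth")
  list(genes = gs, truth = truth)
}

#' Simulate a gene-level ENC/composition table with a planted coefficient
#'
#' Generates per-gene silent-site base compositions (Dirichlet) and ENC
#' values following `log(enc) = intercept + beta_a3s * a3s` plus log-normal
#' noise — the ground-truth model used to validate [enc_regression()]
#' coefficient recovery.
#'
#' @param n Number of genes.
#' @param beta_a3s Planted coefficient on `a3s`.
#' @param intercept Intercept on the log scale (default `log(50)`, keeping
#'   ENC inside its natural range).
#' @param noise_sd Log-scale noise standard deviation.
#' @param seed Integer seed.
#' @return Data.frame with columns `enc`, `a3s`, `t3s`, `c3s`, `g3s`.
#' @export
simulate_enc_table <- function(n, beta_a3s = -0.4, intercept = log(50),
                               noise_sd = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  comp <- matrix(stats::rgamma(4L * n, shape = 2), ncol = 4L)
  comp <- comp / rowSums(comp)
  colnames(comp) <- c("a3s", "t3s", "c3s", "g3s")
  enc <- exp(intercept + beta_a3s * comp[, "a3s"] +
               stats::rnorm(n, 0, noise_sd))
  data.frame(enc = pmin(enc, 61), comp)
}
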
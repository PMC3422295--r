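#' Read and validate a CDS FASTA file
#'
#' Reads a multi-FASTA of coding sequences and validates each record as an
#' in-frame, start-to-stop CDS. Records are upper-cased and U is normalised
#' to T before validation. A record is accepted when its length is a multiple
#' of 3 and at least 6 nt, it contains only A/C/G/T (unless
#' `policy = "keep"`), it begins with ATG, ends with a stop codon, and has no
#' internal stop. Every input record lands in exactly one of `genes` or
#' `excluded`, the latter with a single reason.
#'
#' @param path Path to a FASTA file of nucleotide coding sequences.
#' @param policy `"reject"` (default) excludes genes containing IUPAC
#'   ambiguity codes; `"keep"` retains them (ambiguous codons are ignored by
#'   downstream counting).
#' @param species_id Identifier attached to the returned set; defaults to the
#'   file name without extension.
#' @return A `gene_set` object; see [gene_set()].
#' @seealso [gene_set()], [write_cds_fasta()], [translate_cds()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ATGGAAGAGTAA", ">g2", "ATGGAAGA"), fa)
#' gs <- read_cds_fasta(fa)
#' gs$excluded
#' @export
read_cds_fasta <- function(path, policy = c("reject", "keep"),
                           species_id = NULL) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  recs <- Biostrings::readBStringSet(path)
  seqs <- as.character(recs)
  ids <- sub("\\s.*$", "", names(recs))
  if (length(seqs) == 0L) {
    warning("empty FASTA: ", path)
  }
  gene_set(seqs, ids = ids, policy = policy, species_id = species_id)
}

#' Build a validated gene set from nucleotide sequences
#'
#' Core constructor behind [read_cds_fasta()]: validates raw nucleotide
#' strings into codonised coding sequences. Exclusion reasons (one per failed
#' record) are `ambiguous_base`, `length_not_multiple_of_3`, `too_short`,
#' `no_start`, `no_stop`, and `internal_stop`, applied in that order.
#'
#' @param seqs Character vector of nucleotide sequences (case-insensitive;
#'   U accepted and normalised to T).
#' @param ids Gene identifiers; defaults to `gene_1 ...`.
#' @param policy See [read_cds_fasta()].
#' @param species_id Identifier for the set.
#' @return An object of class `gene_set`: list with `species_id`, `genes`
#'   (named list of codon character vectors) and `excluded` (data.frame with
#'   columns `gene_id`, `reason`).
#' @examples
#' gs <- gene_set(c(g1 = "ATGGAAGAGTAA", bad = "ATGGAATAAGAGTAA"))
#' names(gs$genes)
#' gs$excluded$reason
#' @export
gene_set <- function(seqs, ids = NULL, policy = c("reject", "keep"),
                     species_id = "unnamed") {
  policy <- match.arg(policy)
  code <- standard_genetic_code()
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("gene_", seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  genes <- list()
  ex_id <- character(0)
  ex_reason <- character(0)
  for (k in seq_along(seqs)) {
    s <- chartr("u", "t", tolower(seqs[[k]]))
    s <- toupper(s)
    reason <- validate_cds(s, code, policy)
    if (is.na(reason)) {
      n <- nchar(s) %/% 3L
      genes[[ids[[k]]]] <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    } else {
      ex_id <- c(ex_id, ids[[k]])
      ex_reason <- c(ex_reason, reason)
    }
  }
  structure(
    list(species_id = species_id, genes = genes,
         excluded = data.frame(gene_id = ex_id, reason = ex_reason,
                               stringsAsFactors = FALSE)),
    class = "gene_set"
  )
}

validate_cds <- function(s, code, policy) {
  n <- nchar(s)
  if (grepl("[^ACGT]", s)) {
    if (policy == "reject" || grepl("[^ACGTRYSWKMBDHVN]", s)) {
      return("ambiguous_base")
    }
  }
  if (n %% 3L != 0L) return("length_not_multiple_of_3")
  if (n < 6L) return("too_short")
  if (substr(s, 1L, 3L) != "ATG") return("no_start")
  nc <- n %/% 3L
  codons <- substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  if (!codons[nc] %in% code$stop_codons) return("no_stop")
  if (any(codons[-nc] %in% code$stop_codons)) return("internal_stop")
  NA_character_
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$species_id, "': ", length(x$genes), " genes, ",
      nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Write a gene set to FASTA
#'
#' Writes the validated genes of a `gene_set` as a nucleotide multi-FASTA
#' (DNA alphabet). Re-reading the file with [read_cds_fasta()] recovers
#' identical codon lists.
#'
#' @param genes A `gene_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  seqs <- vapply(genes$genes, paste0, character(1L), collapse = "")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(genes$genes)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Translate a codonised coding sequence
#'
#' Standard-code translation of a validated codon vector; the terminal stop is
#' rendered as `"*"`. Downstream amino-acid statistics exclude the stop.
#'
#' @param codons Character vector of codons (one gene), or a `gene_set`
#'   (translates every gene).
#' @return A single amino-acid string, or a named character vector for a
#'   `gene_set`.
#' @examples
#' translate_cds(c("ATG", "GAA", "TAA"))
#' @export
translate_cds <- function(codons) {
  code <- standard_genetic_code()
  if (inherits(codons, "gene_set")) {
    return(vapply(codons$genes,
                  function(g) paste0(code$codon_to_aa[g], collapse = ""),
                  character(1L)))
  }
  paste0(code$codon_to_aa[codons], collapse = "")
}

#' Write a table as TSV with a schema header
#'
#' All tabular outputs of the package go through this writer: a `# columns:`
#' comment naming the schema, a header row, tab separation, no quoting.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param alphabet If `"rna"`, columns named in `codon_cols` are converted to
#'   the RNA alphabet for the report; the default `"dna"` leaves values
#'   machine-readable.
#' @param codon_cols Character vector of column names holding codons.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, alphabet = c("dna", "rna"),
                             codon_cols = character(0)) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "rna") {
    for (cc in intersect(codon_cols, names(df))) {
      df[[cc]] <- format_codons(df[[cc]], "rna")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
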
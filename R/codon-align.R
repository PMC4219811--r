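#' Construct a pairwise codon alignment
#'
#' A `codon_alignment` holds two equal-length vectors of aligned sense
#' codons with all gap, stop and ambiguous columns already removed — the
#' unit consumed by the Ka/Ks estimators.
#'
#' @param codons_a,codons_b Character vectors of codons, or single in-frame
#'   nucleotide strings (equal length, paired column by column).
#' @param pair_id Identifier carried through to estimates.
#' @param masked_codons Number of columns removed before construction.
#' @return An object of class `"codon_alignment"` with elements `pair_id`,
#'   `codons_a`, `codons_b`, `n_codons`, `masked_codons`.
#' @export
codon_alignment <- function(codons_a, codons_b, pair_id = "", masked_codons = 0L) {
  if (length(codons_a) == 1L && nchar(codons_a[1]) > 3L) {
    codons_a <- split_codons(toupper(as.character(codons_a)))
  }
  if (length(codons_b) == 1L && nchar(codons_b[1]) > 3L) {
    codons_b <- split_codons(toupper(as.character(codons_b)))
  }
  codons_a <- toupper(codons_a); codons_b <- toupper(codons_b)
  if (length(codons_a) != length(codons_b)) {
    stop("aligned codon vectors differ in length (",
         length(codons_a), " vs ", length(codons_b), ")")
  }
  if (length(codons_a) < 1L) stop("codon alignment needs at least one column")
  bad <- !(codons_a %in% SENSE_CODONS) | !(codons_b %in% SENSE_CODONS)
  if (any(bad)) {
    stop("non-sense codon(s) in alignment at column(s) ",
         paste(head(which(bad), 5), collapse = ", "))
  }
  structure(list(pair_id = pair_id,
                 codons_a = codons_a, codons_b = codons_b,
                 n_codons = length(codons_a),
                 masked_codons = as.integer(masked_codons)),
            class = "codon_alignment")
}

#' @rdname codon_alignment
#' @param x Object to coerce.
#' @export
as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  stop("cannot coerce object of class '", class(x)[1], "' to codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment", if (nzchar(x$pair_id)) paste0("'", x$pair_id, "'"),
      "-", x$n_codons, "columns,", x$masked_codons, "masked\n")
  invisible(x)
}

## translate a CDS, tolerating internal stops and ambiguity (as * / X)
.translate_aa <- function(nucleotides) {
  as.character(Biostrings::translate(Biostrings::DNAString(nucleotides),
                                     if.fuzzy.codon = "X"))
}

#' Protein-guided pairwise codon alignment
#'
#' Translates both coding sequences, aligns the proteins globally
#' (Needleman-Wunsch, BLOSUM62, gap open 11 / extend 1 — for two sequences
#' this is the pairwise equivalent of the usual progressive aligner), maps
#' the protein alignment back onto codons, and removes every column where
#' either side carries a gap, a stop codon or an ambiguous base.
#'
#' @param cds_a,cds_b In-frame coding sequences: [coding_sequence()] objects
#'   or nucleotide strings with length a multiple of 3.
#' @param pair_id Identifier for the pair; defaults to the joined sequence
#'   ids when `coding_sequence` objects are given.
#' @return A [codon_alignment()]; errors if no column survives masking.
#' @export
align_pair <- function(cds_a, cds_b, pair_id = NULL) {
  seq_a <- if (inherits(cds_a, "coding_sequence")) cds_a$nucleotides
           else toupper(as.character(cds_a))
  seq_b <- if (inherits(cds_b, "coding_sequence")) cds_b$nucleotides
           else toupper(as.character(cds_b))
  if (is.null(pair_id)) {
    id_a <- if (inherits(cds_a, "coding_sequence")) cds_a$id else "a"
    id_b <- if (inherits(cds_b, "coding_sequence")) cds_b$id else "b"
    pair_id <- paste(id_a, id_b, sep = "|")
  }
  if (nchar(seq_a) %% 3L != 0L || nchar(seq_b) %% 3L != 0L) {
    stop("coding sequences must be in frame (length a multiple of 3)")
  }
  cod_a <- split_codons(seq_a)
  cod_b <- split_codons(seq_b)
  aa_a <- .translate_aa(seq_a)
  aa_b <- .translate_aa(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  masked <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ia <- ia + 1L
    if (sub[k] != "-") ib <- ib + 1L
    if (pat[k] == "-" || sub[k] == "-") { masked <- masked + 1L; next }
    ca <- cod_a[ia]; cb <- cod_b[ib]
    if (!is_sense_codon(ca) || !is_sense_codon(cb)) {  # stop or ambiguous
      masked <- masked + 1L
      next
    }
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  if (length(keep_a) == 0L) {
    stop("degenerate alignment for pair '", pair_id,
         "': no column survives gap/stop/ambiguity masking")
  }
  codon_alignment(keep_a, keep_b, pair_id = pair_id, masked_codons = masked)
}
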
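#' @importFrom Biostrings GENETIC_CODE DNAStringSet AAStringSet readDNAStringSet
#'   writeXStringSet pairwiseAlignment alignedPattern alignedSubject translate
#'   reverseComplement PhredQuality
#' @importFrom methods as is
#' @importFrom stats rexp runif rbinom rpois setNames rnbinom
#' @importFrom utils write.table read.table head
NULL

NUCS <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

## standard genetic code (NCBI table 1); stops excluded from the sense state space
ALL_CODONS <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
ALL_CODONS <- sort(ALL_CODONS)
CODON_AA <- setNames(as.character(Biostrings::GENETIC_CODE[ALL_CODONS]), ALL_CODONS)
STOP_CODONS <- names(CODON_AA)[CODON_AA == "*"]
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
SENSE_AA <- CODON_AA[SENSE_CODONS]

is_stop_codon <- function(codon) codon %in% STOP_CODONS

is_sense_codon <- function(codon) codon %in% SENSE_CODONS

#' Is a nucleotide change a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' exchanges; the four other unordered pairs are transversions.
#'
#' @param from,to Single nucleotides (character).
#' @return Logical.
#' @keywords internal
is_transition <- function(from, to) {
  (from %in% PURINES) == (to %in% PURINES) & from != to
}

codon_chars <- function(codon) strsplit(codon, "", fixed = TRUE)[[1]]

## split an in-frame nucleotide string into its codons
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

## single-base neighbours of a codon: 9 codons (3 positions x 3 alternatives)
codon_neighbours <- function(codon) {
  ch <- codon_chars(codon)
  out <- character(0)
  pos <- integer(0)
  from <- character(0)
  to <- character(0)
  for (p in 1:3) {
    for (nt in setdiff(NUCS, ch[p])) {
      mut <- ch
      mut[p] <- nt
      out <- c(out, paste(mut, collapse = ""))
      pos <- c(pos, p)
      from <- c(from, ch[p])
      to <- c(to, nt)
    }
  }
  data.frame(codon = out, position = pos, from = from, to = to,
             transition = is_transition(from, to),
             stringsAsFactors = FALSE)
}

## codons whose amino acid is unchanged by any third-position substitution
fourfold_codons <- local({
  fam <- vapply(SENSE_CODONS, function(cd) {
    third <- paste0(substr(cd, 1, 2), NUCS)
    all(CODON_AA[third] == CODON_AA[cd])
  }, logical(1))
  SENSE_CODONS[fam]
})

## package-level cache for precomputed pathway-count tables
.od_cache <- new.env(parent = emptyenv())
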
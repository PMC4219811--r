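#' Coding sequence with identity and species tag
#'
#' @param id Sequence identifier.
#' @param nucleotides In-frame sense-codon nucleotide string (no internal
#'   stop, length a multiple of 3 and at least 102 bp).
#' @param species Species label.
#' @return An object of class `"coding_sequence"`.
#' @export
coding_sequence <- function(id, nucleotides, species = "") {
  nucleotides <- toupper(as.character(nucleotides))
  n <- nchar(nucleotides)
  if (n %% 3L != 0L) stop("CDS '", id, "': length not a multiple of 3")
  if (n < 102L) stop("CDS '", id, "': shorter than 102 bp")
  codons <- split_codons(nucleotides)
  if (any(is_stop_codon(codons))) {
    stop("CDS '", id, "': internal stop codon")
  }
  structure(list(id = id, species = species, nucleotides = nucleotides,
                 length_bp = n), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("CDS", x$id, if (nzchar(x$species)) paste0("[", x$species, "]"),
      "-", x$length_bp, "bp\n")
  invisible(x)
}

## enumerate candidate ORFs (first ATG per stop-free stretch to the next
## stop, or to the sequence end) in one reading frame of one strand
.frame_orfs <- function(seq, frame_offset) {
  n <- nchar(seq)
  usable <- n - frame_offset
  n_codons <- usable %/% 3L
  if (n_codons < 1L) return(NULL)
  starts_nt <- frame_offset + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts_nt, starts_nt + 2L)
  stop_idx <- which(codons %in% STOP_CODONS)
  seg_start <- c(1L, stop_idx + 1L)
  seg_end <- c(stop_idx - 1L, n_codons)
  out <- list()
  for (s in seq_along(seg_start)) {
    lo <- seg_start[s]; hi <- seg_end[s]
    if (lo > hi) next
    atg <- which(codons[lo:hi] == "ATG")
    if (!length(atg)) next
    first <- lo + atg[1] - 1L
    out[[length(out) + 1L]] <- list(start_codon = first, end_codon = hi,
                                    n_codons = hi - first + 1L,
                                    sequence = paste(codons[first:hi],
                                                     collapse = ""))
  }
  out
}

#' Extract the longest open reading frame per transcript
#'
#' Scans all six reading frames of each transcript for open reading frames
#' (ATG to stop, or ATG to sequence end), rejects ORFs containing any
#' ambiguous base, and emits the single longest ORF per transcript when its
#' length reaches the minimum CDS size. A 100-bp minimum means 34 codons
#' (102 bp) at codon granularity, matching the convention that observed CDS
#' lengths start at 102 bp. Ties are broken by frame index (forward frames
#' 1-3 then reverse frames 4-6), then by leftmost start.
#'
#' @param transcripts Path to a nucleotide FASTA file or a
#'   [Biostrings::DNAStringSet].
#' @param min_length_bp Minimum CDS length in bp (default 100; rounded up
#'   to whole codons).
#' @param species Species label attached to every emitted CDS.
#' @return Named list of [coding_sequence()] objects (one per transcript
#'   with a qualifying ORF); empty list with a warning on empty input.
#' @export
extract_cds <- function(transcripts, min_length_bp = 100L, species = "") {
  if (is.character(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  }
  if (length(transcripts) == 0L) {
    warning("no transcripts in input")
    return(list())
  }
  min_codons <- as.integer(ceiling(min_length_bp / 3))
  ids <- names(transcripts)
  if (is.null(ids)) ids <- sprintf("transcript%05d", seq_along(transcripts))
  ids <- sub("\\s.*$", "", ids)
  out <- list()
  for (k in seq_along(transcripts)) {
    fwd <- toupper(as.character(transcripts[[k]]))
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    best <- NULL
    frame_idx <- 0L
    for (strand_seq in list(fwd, rev)) {
      for (off in 0:2) {
        frame_idx <- frame_idx + 1L
        for (orf in .frame_orfs(strand_seq, off)) {
          if (orf$n_codons < min_codons) next
          if (grepl("[^ACGT]", orf$sequence)) next  # ambiguity: reject ORF
          better <- is.null(best) ||
            orf$n_codons > best$n_codons ||
            (orf$n_codons == best$n_codons &&
               (frame_idx < best$frame ||
                  (frame_idx == best$frame &&
                     orf$start_codon < best$start_codon)))
          if (better) {
            best <- orf
            best$frame <- frame_idx
          }
        }
      }
    }
    if (!is.null(best)) {
      out[[ids[k]]] <- coding_sequence(ids[k], best$sequence,
                                       species = species)
    }
  }
  out
}

## translated sequences of a CDS list as an AAStringSet
.cds_proteins <- function(cds_set) {
  Biostrings::AAStringSet(vapply(cds_set, function(x) {
    .translate_aa(x$nucleotides)
  }, character(1)))
}

#' Score all cross-set CDS pairs by translated global alignment
#'
#' Internal stand-in for an external translated search at desk scale:
#' every cross-set pair of CDS translations is aligned globally
#' (BLOSUM62, gap open 11 / extend 1) and the raw alignment score is
#' reported on a bit-score-like scale (raw score x 0.33, a fixed affine
#' mapping). Both hit directions are emitted with the symmetric score.
#'
#' @param set_a,set_b Lists of [coding_sequence()] objects (non-empty).
#' @param bit_scale Multiplier from raw alignment score to the reported
#'   scale.
#' @return Data frame of hit records: `query_id`, `subject_id`,
#'   `bit_score`, `e_value` (always `NA`; no extreme-value statistics are
#'   computed).
#' @export
score_pairs <- function(set_a, set_b, bit_scale = 0.33) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("score_pairs() needs two non-empty CDS sets")
  }
  prot_a <- .cds_proteins(set_a)
  ids_a <- vapply(set_a, `[[`, character(1), "id")
  ids_b <- vapply(set_b, `[[`, character(1), "id")
  scores <- matrix(0, length(set_a), length(set_b))
  for (j in seq_along(set_b)) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      prot_a, .cds_proteins(set_b[j])[[1]],
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
  }
  bits <- as.vector(scores) * bit_scale
  qa <- rep(ids_a, times = length(ids_b))
  sb <- rep(ids_b, each = length(ids_a))
  rbind(
    data.frame(query_id = qa, subject_id = sb, bit_score = bits,
               e_value = NA_real_, stringsAsFactors = FALSE),
    data.frame(query_id = sb, subject_id = qa, bit_score = bits,
               e_value = NA_real_, stringsAsFactors = FALSE))
}

#' Read a tabular hit file (BLAST outfmt 6 dialect)
#'
#' @param path Path to a 12-column tab-separated hit table (qseqid sseqid
#'   pident length mismatch gapopen qstart qend sstart send evalue
#'   bitscore).
#' @return Data frame with `query_id`, `subject_id`, `bit_score`,
#'   `e_value`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE, comment.char = "#")
  data.frame(query_id = tab$qseqid, subject_id = tab$sseqid,
             bit_score = tab$bitscore, e_value = tab$evalue,
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits above a bit-score threshold
#'
#' Discards hits below `min_bit_score`, then emits a pair (a, b) exactly
#' when b is a's unique best subject and a is b's unique best subject.
#' A query whose top score is tied between subjects is disqualified (no
#' pair emitted) — a deterministic, conservative rule. The result is a
#' partial matching: no identifier appears in two pairs.
#'
#' @param hits Data frame with `query_id`, `subject_id`, `bit_score`
#'   (both directions may be present).
#' @param min_bit_score Bit-score threshold (default 300).
#' @return Data frame of ortholog candidates: `id_a`, `id_b`, `score_ab`,
#'   `score_ba`, with `id_a < id_b` lexicographically.
#' @export
reciprocal_best_hits <- function(hits, min_bit_score = 300) {
  hits <- hits[hits$bit_score >= min_bit_score & hits$query_id !=
                 hits$subject_id, , drop = FALSE]
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  best_of <- function(df) {
    top <- max(df$bit_score)
    winners <- unique(df$subject_id[df$bit_score == top])
    if (length(winners) != 1L) return(c(NA_character_, NA_character_))
    c(winners, as.character(top))
  }
  by_query <- split(hits[c("subject_id", "bit_score")], hits$query_id)
  best <- vapply(by_query, best_of, character(2))
  best_subject <- setNames(best[1, ], colnames(best))
  best_score <- setNames(as.numeric(best[2, ]), colnames(best))
  qids <- names(best_subject)
  rows <- list()
  for (q in qids) {
    s <- best_subject[[q]]
    if (is.na(s)) next
    if (is.na(best_subject[s] %||% NA_character_)) next
    if (!identical(best_subject[[s]], q)) next
    a <- min(q, s); b <- max(q, s)
    key <- paste(a, b, sep = "\r")
    if (!is.null(rows[[key]])) next
    rows[[key]] <- data.frame(id_a = a, id_b = b,
                              score_ab = best_score[[a]],
                              score_ba = best_score[[b]],
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$id_a), , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

## case-fold and squeeze whitespace so label comparison is robust
.normalise_label <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}

#' Retain ortholog candidates whose members match the same protein
#'
#' A pair survives only when both members carry an annotation and the
#' labels are equal after case-folding and whitespace normalisation; pairs
#' with any missing annotation are dropped and counted separately.
#'
#' @param pairs Data frame from [reciprocal_best_hits()].
#' @param annotations Two-column data frame (`id`, `protein_label`) or a
#'   path to a headerless two-column TSV. May be partial.
#' @return List with `pairs` (retained candidates, plus `annotation_a`,
#'   `annotation_b` columns), `n_input`, `n_retained`,
#'   `n_missing_annotation`, `n_label_mismatch`.
#' @export
annotation_concordance_filter <- function(pairs, annotations) {
  if (is.character(annotations)) {
    annotations <- read.table(annotations, sep = "\t", header = FALSE,
                              col.names = c("id", "protein_label"),
                              stringsAsFactors = FALSE, quote = "")
  }
  lab <- .normalise_label(annotations$protein_label)
  dup <- split(lab, annotations$id)
  conflict <- names(dup)[vapply(dup, function(x) length(unique(x)) > 1,
                                logical(1))]
  if (length(conflict)) {
    stop("conflicting annotation labels for id(s): ",
         paste(head(conflict, 5), collapse = ", "))
  }
  label_of <- vapply(dup, `[[`, character(1), 1L)
  la <- label_of[pairs$id_a]
  lb <- label_of[pairs$id_b]
  missing <- is.na(la) | is.na(lb)
  mismatch <- !missing & la != lb
  keep <- !missing & !mismatch
  out <- pairs[keep, , drop = FALSE]
  out$annotation_a <- unname(la[keep])
  out$annotation_b <- unname(lb[keep])
  rownames(out) <- NULL
  list(pairs = out, n_input = nrow(pairs), n_retained = sum(keep),
       n_missing_annotation = sum(missing), n_label_mismatch = sum(mismatch))
}
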
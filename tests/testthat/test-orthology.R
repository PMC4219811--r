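test_that("longest-ORF extraction honours the codon-granular minimum", {
  dss <- function(...) Biostrings::DNAStringSet(c(...))
  # exactly one 34-codon (102 bp) ORF: emitted unchanged
  cds102 <- paste0("ATG", strrep("GCT", 33))
  t1 <- dss(tx1 = paste0(cds102, "TAA"))
  out <- extract_cds(t1)
  expect_length(out, 1)
  expect_equal(out$tx1$nucleotides, cds102)
  expect_equal(out$tx1$length_bp, 102)
  # longest ORF below 102 bp: nothing emitted
  t2 <- dss(tx2 = paste0("ATG", strrep("GCT", 32), "TAA"))
  expect_length(extract_cds(t2), 0)
  # 150 bp forward ORF vs 300 bp reverse-strand ORF: longest wins
  fwd150 <- paste0("ATG", strrep("GCT", 49), "TAA")
  rev300 <- paste0("TTA", strrep("AGC", 99), "CAT")
  out3 <- extract_cds(dss(tx3 = paste0(fwd150, rev300)))
  expect_equal(out3$tx3$length_bp, 300)
  expect_equal(out3$tx3$nucleotides, paste0("ATG", strrep("GCT", 99)))
  # ORFs containing ambiguous bases are rejected
  ambi <- paste0("ATG", strrep("GCT", 20), "GNT", strrep("GCT", 20), "TAA")
  expect_length(extract_cds(dss(tx4 = ambi)), 0)
  expect_warning(expect_length(extract_cds(dss()), 0), "no transcripts")
})

test_that("internal pair scoring is symmetric and separates true pairs", {
  set.seed(14)
  mk <- function(id, seq) coding_sequence(id, seq)
  a1 <- mk("a1", random_cds(100))
  hits_self <- score_pairs(list(a1 = a1), list(b1 = mk("b1", a1$nucleotides)))
  # identical sequences: both directions report the same (maximal) score
  s_ab <- hits_self$bit_score[hits_self$query_id == "a1"]
  s_ba <- hits_self$bit_score[hits_self$query_id == "b1"]
  expect_equal(s_ab, s_ba)
  mutated <- mk("b2", paste0(substr(a1$nucleotides, 1, 294), "TTTGGG"))
  s_mut <- score_pairs(list(a1 = a1), list(b2 = mutated))$bit_score[1]
  expect_lt(s_mut, s_ab[1])

  # empirical null: unrelated 34-codon sequences stay below the threshold
  set_a <- lapply(1:25, function(i) mk(paste0("a", i), random_cds(34)))
  set_b <- lapply(1:40, function(i) mk(paste0("b", i), random_cds(34)))
  null_hits <- score_pairs(set_a, set_b)
  expect_equal(nrow(null_hits), 2 * 25 * 40)
  expect_lt(max(null_hits$bit_score), 300)
})

test_that("reciprocal best hits follow the bidirectional unique-best rule", {
  hits <- data.frame(
    query_id = c("a1", "a1", "a2", "a2", "b1", "b2", "b1", "b2"),
    subject_id = c("b1", "b2", "b1", "b2", "a1", "a2", "a2", "a1"),
    bit_score = c(500, 310, 305, 400, 500, 400, 305, 310),
    stringsAsFactors = FALSE)
  rbh <- reciprocal_best_hits(hits)
  expect_equal(nrow(rbh), 2)
  expect_setequal(paste(rbh$id_a, rbh$id_b), c("a1 b1", "a2 b2"))

  # reciprocity violated: a1's best is b1 but b1 prefers a2
  hits2 <- data.frame(query_id = c("a1", "b1", "a2", "b1"),
                      subject_id = c("b1", "a2", "b1", "a1"),
                      bit_score = c(500, 600, 600, 500))
  expect_equal(nrow(reciprocal_best_hits(hits2)), 1)  # only (a2, b1)

  # sub-threshold tables give the empty set
  hits3 <- transform(hits, bit_score = bit_score / 2)
  expect_equal(nrow(reciprocal_best_hits(hits3)), 0)

  # tied best scores disqualify the query
  hits4 <- data.frame(query_id = c("a1", "a1", "b1", "b2"),
                      subject_id = c("b1", "b2", "a1", "a1"),
                      bit_score = c(400, 400, 400, 350))
  expect_equal(nrow(reciprocal_best_hits(hits4)), 0)

  # order independence and partial matching
  set.seed(15)
  perm <- sample(nrow(hits))
  expect_equal(reciprocal_best_hits(hits[perm, ]), reciprocal_best_hits(hits))
  ids <- c(rbh$id_a, rbh$id_b)
  expect_equal(anyDuplicated(ids), 0)
})

test_that("annotation concordance keeps only same-protein pairs", {
  pairs <- data.frame(id_a = c("a1", "a2", "a3"), id_b = c("b1", "b2", "b3"),
                      score_ab = 400, score_ba = 400,
                      stringsAsFactors = FALSE)
  ann <- data.frame(
    id = c("a1", "b1", "a2", "b2", "a3"),
    protein_label = c("tripartite motif-containing protein 2",
                      "Tripartite  motif-containing protein 2",  # spacing/case
                      "TRIM2", "TRIM45", "unpaired protein"),
    stringsAsFactors = FALSE)
  res <- annotation_concordance_filter(pairs, ann)
  expect_equal(res$n_retained, 1)
  expect_equal(res$pairs$id_a, "a1")
  expect_equal(res$n_label_mismatch, 1)      # TRIM2 vs TRIM45
  expect_equal(res$n_missing_annotation, 1)  # b3 unannotated

  conflicting <- rbind(ann, data.frame(id = "a1", protein_label = "other"))
  expect_error(annotation_concordance_filter(pairs, conflicting),
               "conflicting")
})

test_that("hit tables in tabular search format round-trip", {
  tab <- data.frame(q = c("a1", "a2"), s = c("b1", "b2"), pid = c(98, 95),
                    len = c(300, 200), mm = c(5, 9), go = 0, qs = 1,
                    qe = c(300, 200), ss = 1, se = c(300, 200),
                    ev = c(1e-50, 1e-30), bits = c(512.1, 377.4))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  hits <- read_blast_hits(path)
  expect_equal(hits$query_id, c("a1", "a2"))
  expect_equal(hits$bit_score, c(512.1, 377.4))
  expect_equal(hits$e_value, c(1e-50, 1e-30))
})
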
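#' Uniform frequencies over the 61 sense codons
#' @return Named numeric vector summing to 1.
#' @export
uniform_codon_frequencies <- function() {
  setNames(rep(1 / length(SENSE_CODONS), length(SENSE_CODONS)), SENSE_CODONS)
}

#' Codon substitution rate matrix
#'
#' Builds the 61x61 generator of the codon continuous-time Markov chain:
#' rate(i -> j) is zero when the codons differ at more than one position or
#' j is a stop codon, and otherwise proportional to the target frequency
#' `pi_j`, multiplied by `kappa` when the nucleotide change is a transition
#' and by `omega` when it is nonsynonymous. The matrix is scaled so the
#' expected number of nucleotide substitutions per site per unit branch
#' length is 1 (i.e. 3 codon-level changes per codon per unit time at
#' stationarity), and satisfies detailed balance by construction.
#'
#' @param omega Nonsynonymous/synonymous rate ratio (true Ka/Ks).
#' @param kappa Transition/transversion rate ratio.
#' @param codon_frequencies Equilibrium frequencies over sense codons
#'   (default uniform).
#' @return A 61x61 matrix with sense-codon dimnames; rows sum to 0.
#' @export
codon_rate_matrix <- function(omega, kappa, codon_frequencies = NULL) {
  if (omega < 0 || kappa <= 0) stop("omega must be >= 0 and kappa > 0")
  pi <- if (is.null(codon_frequencies)) uniform_codon_frequencies()
        else .check_codon_frequencies(codon_frequencies)
  n <- length(SENSE_CODONS)
  Q <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  for (i in seq_len(n)) {
    nb <- codon_neighbours(SENSE_CODONS[i])
    keep <- !is_stop_codon(nb$codon)
    nb <- nb[keep, , drop = FALSE]
    j <- match(nb$codon, SENSE_CODONS)
    rate <- pi[nb$codon] *
      ifelse(nb$transition, kappa, 1) *
      ifelse(CODON_AA[nb$codon] == SENSE_AA[i], 1, omega)
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))   # codon substitutions per codon per time
  if (mean_rate <= 0) stop("degenerate rate matrix (zero total rate)")
  Q * (3 / mean_rate)               # 1 nucleotide substitution/site/time
}

.check_codon_frequencies <- function(freqs) {
  if (length(freqs) != length(SENSE_CODONS)) {
    stop("codon_frequencies must have ", length(SENSE_CODONS), " entries")
  }
  if (is.null(names(freqs))) names(freqs) <- SENSE_CODONS
  if (!setequal(names(freqs), SENSE_CODONS)) {
    stop("codon_frequencies must be named by the 61 sense codons")
  }
  if (any(freqs < 0)) stop("codon_frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9) stop("codon_frequencies must sum to 1")
  freqs[SENSE_CODONS]
}

#' Simulation configuration for ortholog pair sets
#'
#' Bundles and validates the generating parameters of the codon-evolution
#' simulator: the true selection ratio `omega`, transition/transversion
#' ratio `kappa`, the nucleotide divergence `branch_length` separating the
#' two sequences of a pair (expected substitutions per site, the clock
#' distance d = 2t), codon frequencies, and a fraction of high-divergence
#' paralog contaminants.
#'
#' @param n_pairs Number of ortholog pairs to simulate.
#' @param codons_per_seq Codons per sequence (>= 34, so every sequence
#'   clears the 100-bp minimum-CDS rule).
#' @param omega True Ka/Ks of the generating process.
#' @param kappa True transition/transversion rate ratio.
#' @param branch_length Expected nucleotide substitutions per site between
#'   the two sequences of a pair. The default 0.031 is calibrated (via the
#'   matrix exponential of the default-parameter generator) so the expected
#'   synonymous divergence Ks is 0.0802, the observed transcriptome-wide
#'   mean for the oyster species pair this emulates.
#' @param codon_frequencies Equilibrium sense-codon frequencies (default
#'   uniform).
#' @param paralog_fraction Fraction of pairs generated at paralog-level
#'   divergence instead of `branch_length`.
#' @param seed Integer seed; the whole output is reproducible from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 50, codons_per_seq = 300, omega = 0.2,
                       kappa = 2, branch_length = 0.031,
                       codon_frequencies = NULL, paralog_fraction = 0,
                       seed = 1L) {
  stopifnot(n_pairs >= 1, codons_per_seq >= 34, omega > 0, kappa > 0,
            branch_length >= 0, paralog_fraction >= 0, paralog_fraction <= 1)
  freqs <- if (is.null(codon_frequencies)) uniform_codon_frequencies()
           else .check_codon_frequencies(codon_frequencies)
  structure(list(n_pairs = as.integer(n_pairs),
                 codons_per_seq = as.integer(codons_per_seq),
                 omega = omega, kappa = kappa, branch_length = branch_length,
                 codon_frequencies = freqs,
                 paralog_fraction = paralog_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve a codon sequence along a branch
#'
#' Exact simulation of the codon continuous-time Markov chain of
#' [codon_rate_matrix()]: each codon evolves independently by exponential
#' waiting times and embedded-chain jumps (no time discretisation).
#'
#' @param ancestral Codon character vector, or a single in-frame nucleotide
#'   string of sense codons.
#' @param branch_length Expected nucleotide substitutions per site (>= 0).
#' @param omega,kappa,codon_frequencies Model parameters; see
#'   [codon_rate_matrix()].
#' @param seed Optional integer seed (omit to draw from the current RNG
#'   stream).
#' @param Q Optional precomputed rate matrix (overrides the parameters).
#' @return Character vector of evolved codons, same length as `ancestral`.
#' @export
evolve_codon_sequence <- function(ancestral, branch_length, omega = 0.2,
                                  kappa = 2, codon_frequencies = NULL,
                                  seed = NULL, Q = NULL) {
  if (length(ancestral) == 1L && nchar(ancestral[1]) > 3L) {
    ancestral <- split_codons(toupper(ancestral))
  }
  ancestral <- toupper(ancestral)
  if (!all(ancestral %in% SENSE_CODONS)) {
    stop("ancestral sequence contains stop or non-sense codons")
  }
  if (!is.numeric(branch_length) || branch_length < 0) {
    stop("branch_length must be non-negative")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (branch_length == 0) return(ancestral)
  if (is.null(Q)) Q <- codon_rate_matrix(omega, kappa, codon_frequencies)
  rate_out <- -diag(Q)
  jump <- Q / rate_out
  diag(jump) <- 0
  cum_jump <- t(apply(jump, 1, cumsum))
  state <- match(ancestral, SENSE_CODONS)
  trem <- rep(branch_length, length(state))
  active <- seq_along(state)
  while (length(active) > 0L) {
    # absorbing states (no allowed move, e.g. Met/Trp at omega = 0) stay put
    active <- active[rate_out[state[active]] > 0]
    if (length(active) == 0L) break
    dt <- rexp(length(active), rate_out[state[active]])
    jumps <- dt < trem[active]
    trem[active] <- trem[active] - dt
    active <- active[jumps]
    if (length(active) == 0L) break
    m <- length(active)
    u <- runif(m)
    rows <- cum_jump[state[active], , drop = FALSE]
    state[active] <- 1L + rowSums(rows < matrix(u, nrow = m, ncol = ncol(rows)))
  }
  SENSE_CODONS[state]
}

#' Simulate a set of ortholog coding-sequence pairs with known truth
#'
#' Draws ancestral sequences from the configured codon frequencies and
#' evolves each down two independent branches of `branch_length / 2`, so a
#' pair's expected nucleotide divergence equals `branch_length`. A
#' `paralog_fraction` of pairs is generated at `paralog_branch_length`
#' divergence instead, emulating paralog contamination that the downstream
#' Ks cutoff must remove.
#'
#' @param config A [sim_config()].
#' @param paralog_branch_length Divergence of paralog pairs (>= 0.4
#'   substitutions/site, comfortably above the Ks > 0.1 exclusion).
#' @param out_dir Optional directory; when given, writes `species_A.fasta`,
#'   `species_B.fasta` (60-column wrap) and `ortholog_truth.tsv`.
#' @return List with `fasta_a`, `fasta_b` (named [Biostrings::DNAStringSet]
#'   objects; ids `<pair_id>_A` / `<pair_id>_B`) and `truth` (data frame:
#'   `pair_id`, `omega_true`, `kappa_true`, `branch_length_true`,
#'   `is_paralog`, `seed`).
#' @export
simulate_ortholog_set <- function(config, paralog_branch_length = 0.4,
                                  out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), paralog_branch_length >= 0.4)
  set.seed(config$seed)
  Q <- codon_rate_matrix(config$omega, config$kappa, config$codon_frequencies)
  n <- config$n_pairs
  is_paralog <- as.logical(rbinom(n, 1, config$paralog_fraction))
  bl <- ifelse(is_paralog, paralog_branch_length, config$branch_length)
  pair_id <- sprintf("pair%04d", seq_len(n))
  seqs_a <- character(n); seqs_b <- character(n)
  for (i in seq_len(n)) {
    anc <- sample(SENSE_CODONS, config$codons_per_seq, replace = TRUE,
                  prob = config$codon_frequencies)
    seqs_a[i] <- paste(evolve_codon_sequence(anc, bl[i] / 2, Q = Q),
                       collapse = "")
    seqs_b[i] <- paste(evolve_codon_sequence(anc, bl[i] / 2, Q = Q),
                       collapse = "")
  }
  fasta_a <- Biostrings::DNAStringSet(setNames(seqs_a, paste0(pair_id, "_A")))
  fasta_b <- Biostrings::DNAStringSet(setNames(seqs_b, paste0(pair_id, "_B")))
  truth <- data.frame(pair_id = pair_id, omega_true = config$omega,
                      kappa_true = config$kappa, branch_length_true = bl,
                      is_paralog = is_paralog, seed = config$seed,
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(fasta_a, file.path(out_dir, "species_A.fasta"),
                                width = 60L)
    Biostrings::writeXStringSet(fasta_b, file.path(out_dir, "species_B.fasta"),
                                width = 60L)
    write_tsv(truth, file.path(out_dir, "ortholog_truth.tsv"))
  }
  list(fasta_a = fasta_a, fasta_b = fasta_b, truth = truth)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate two-group variant tables with known truth
#'
#' Emits per-group variant records of the kind a variant caller produces
#' (position, ref/alt alleles, total depth, per-allele read counts, Phred
#' quality), with a configurable minority of sites violating each of the
#' downstream screening rules: multi-allelic, depth < 5, minor allele
#' frequency < 20%, quality < 30, and group-private sites. Defects are
#' assigned independently per category; the truth table flags each one, and
#' `clean` marks sites that should survive the full screen.
#'
#' @param n_sites Number of variant sites.
#' @param depth_distribution List with `mean`: Poisson mean of clean read
#'   depth (floored at 8 so rounding can never breach the depth or MAF
#'   rules for clean sites).
#' @param maf_distribution List with `min`, `max`: clean minor-allele
#'   fraction range (within \[0.3, 0.5\]).
#' @param shared_fraction Fraction of sites emitted in both group files
#'   with identical position and alleles.
#' @param defect_rates List of per-category rates: `multi_allelic`,
#'   `low_depth`, `low_maf`, `low_quality`.
#' @param seed Integer seed.
#' @param out_dir Optional directory; writes `group_A.vcf`, `group_B.vcf`
#'   (VCF v4.2 with DP and AD FORMAT fields) and `variant_truth.tsv`.
#' @return List with `records_a`, `records_b` (data frames of
#'   variant records) and `truth`.
#' @export
simulate_variant_tables <- function(n_sites,
                                    depth_distribution = list(mean = 30),
                                    maf_distribution = list(min = 0.30, max = 0.50),
                                    shared_fraction = 1,
                                    defect_rates = list(multi_allelic = 0,
                                                        low_depth = 0,
                                                        low_maf = 0,
                                                        low_quality = 0),
                                    seed = 1L, out_dir = NULL) {
  stopifnot(n_sites >= 1, shared_fraction >= 0, shared_fraction <= 1,
            maf_distribution$min >= 0.3, maf_distribution$max <= 0.5)
  rates <- list(multi_allelic = 0, low_depth = 0, low_maf = 0, low_quality = 0)
  rates[names(defect_rates)] <- defect_rates
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) < 1))
  set.seed(as.integer(seed))

  contig <- sprintf("contig%04d", (seq_len(n_sites) - 1L) %/% 100L + 1L)
  position <- ((seq_len(n_sites) - 1L) %% 100L) * 53L + 11L
  ref <- sample(NUCS, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(NUCS, r), 1L), character(1))

  shared <- as.logical(rbinom(n_sites, 1, shared_fraction))
  flag <- lapply(rates, function(r) as.logical(rbinom(n_sites, 1, r)))
  # which single group carries each quantitative defect
  defect_group <- sample(c("A", "B"), n_sites, replace = TRUE)
  private_group <- sample(c("A", "B"), n_sites, replace = TRUE)

  make_group <- function(grp) {
    depth <- pmax(8L, rpois(n_sites, depth_distribution$mean))
    maf <- runif(n_sites, maf_distribution$min, maf_distribution$max)
    qual <- round(runif(n_sites, 40, 99), 1)
    hit <- defect_group == grp
    low_depth <- flag$low_depth & hit
    depth[low_depth] <- sample(1:4, sum(low_depth), replace = TRUE)
    low_maf <- flag$low_maf & hit
    depth[low_maf & !low_depth] <- pmax(depth[low_maf & !low_depth], 10L)
    maf[low_maf] <- runif(sum(low_maf), 0.02, 0.12)
    low_qual <- flag$low_quality & hit
    qual[low_qual] <- round(runif(sum(low_qual), 3, 29), 1)
    alt_n <- pmin(pmax(1L, as.integer(round(maf * depth))), depth - 1L)
    alt_n[depth <= 1L] <- pmax(depth[depth <= 1L] - 1L, 0L)
    ref_n <- depth - alt_n
    alt_out <- alt
    ad <- paste(ref_n, alt_n, sep = ",")
    multi <- flag$multi_allelic & hit
    if (any(multi)) {
      second <- vapply(which(multi), function(i) {
        sample(setdiff(NUCS, c(ref[i], alt[i])), 1L)
      }, character(1))
      alt_out[multi] <- paste(alt[multi], second, sep = ",")
      # split the alt reads between the two alternates
      a2 <- pmax(1L, alt_n[multi] %/% 2L)
      a1 <- pmax(alt_n[multi] - a2, 1L)
      ad[multi] <- paste(ref_n[multi], a1, a2, sep = ",")
    }
    keep <- shared | (private_group == grp)
    data.frame(contig = contig, position = position, ref = ref,
               alt = alt_out, depth = depth, ad = ad, quality = qual,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  records_a <- make_group("A")
  records_b <- make_group("B")
  truth <- data.frame(site_id = sprintf("site%05d", seq_len(n_sites)),
                      contig = contig, position = position,
                      ref = ref, alt = alt, shared = shared,
                      multi_allelic = flag$multi_allelic,
                      low_depth = flag$low_depth, low_maf = flag$low_maf,
                      low_quality = flag$low_quality,
                      stringsAsFactors = FALSE)
  truth$clean <- truth$shared & !truth$multi_allelic & !truth$low_depth &
    !truth$low_maf & !truth$low_quality
  out <- list(records_a = records_a, records_b = records_b, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$vcf_a <- file.path(out_dir, "group_A.vcf")
    out$vcf_b <- file.path(out_dir, "group_B.vcf")
    write_minimal_vcf(records_a, out$vcf_a, sample_name = "groupA")
    write_minimal_vcf(records_b, out$vcf_b, sample_name = "groupB")
    write_tsv(truth, file.path(out_dir, "variant_truth.tsv"))
  }
  out
}

## minimal VCF v4.2 serialiser for simulator output (plain text, one sample)
write_minimal_vcf <- function(records, path, sample_name = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- paste(records$contig, records$position, ".", records$ref,
                records$alt, records$quality, ".", ".", "GT:DP:AD",
                paste("0/1", records$depth, records$ad, sep = ":"),
                sep = "\t")
  writeLines(c(header, body), path)
}

#' Simulate FASTQ reads with controlled defect rates
#'
#' Generates reads that are clean by construction except for independently
#' assigned defects mirroring the trimming rules: N-fraction above 5%,
#' more than 50% of bases below Q5, and length below 20.
#'
#' @param n_reads Number of reads.
#' @param defect_rates List of rates: `high_n`, `low_quality`, `short`.
#' @param read_length Clean read length (default 100).
#' @param seed Integer seed.
#' @param out_path Optional FASTQ path (Phred+33); a
#'   `<out_path>.truth.tsv` truth table is written alongside.
#' @return List with `sequences` (named character), `qualities` (Phred+33
#'   strings) and `truth` (flags per read plus `clean`).
#' @export
simulate_reads <- function(n_reads,
                           defect_rates = list(high_n = 0, low_quality = 0,
                                               short = 0),
                           read_length = 100L, seed = 1L, out_path = NULL) {
  stopifnot(n_reads >= 1, read_length >= 25)
  rates <- list(high_n = 0, low_quality = 0, short = 0)
  rates[names(defect_rates)] <- defect_rates
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) < 1))
  set.seed(as.integer(seed))
  high_n <- as.logical(rbinom(n_reads, 1, rates$high_n))
  low_q <- as.logical(rbinom(n_reads, 1, rates$low_quality))
  short <- as.logical(rbinom(n_reads, 1, rates$short))
  seqs <- character(n_reads); quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    len <- if (short[i]) sample(10:19, 1) else read_length
    bases <- sample(NUCS, len, replace = TRUE)
    n_n <- if (high_n[i]) ceiling(0.10 * len) else sample(0:floor(0.02 * len), 1)
    if (n_n > 0) bases[sample(len, n_n)] <- "N"
    q <- sample(25:40, len, replace = TRUE)
    if (low_q[i]) q[sample(len, ceiling(0.6 * len))] <- 2L
    seqs[i] <- paste(bases, collapse = "")
    quals[i] <- intToUtf8(q + 33L)
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  names(seqs) <- ids
  truth <- data.frame(read_id = ids, length = nchar(seqs),
                      high_n = high_n, low_quality = low_q, short = short,
                      stringsAsFactors = FALSE)
  truth$clean <- !high_n & !low_q & !short
  if (!is.null(out_path)) {
    write_fastq(seqs, quals, out_path)
    write_tsv(truth, paste0(out_path, ".truth.tsv"))
  }
  list(sequences = seqs, qualities = quals, truth = truth)
}

## plain Phred+33 FASTQ serialiser
write_fastq <- function(sequences, qualities, path) {
  ids <- names(sequences)
  rec <- rbind(paste0("@", ids), unname(sequences), "+", unname(qualities))
  writeLines(as.vector(rec), path)
}
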
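## schema of recognised configuration keys, defaults, and validation domains
.pipeline_schema <- list(
  seed = list(default = 1L, check = function(x) x == floor(x)),
  method = list(default = "yn", check = function(x) x %in% c("yn", "ng86")),
  n_pairs = list(default = 50L, check = function(x) x >= 1),
  codons_per_seq = list(default = 300L, check = function(x) x >= 34),
  omega = list(default = 0.2, check = function(x) x > 0),
  kappa = list(default = 2, check = function(x) x > 0),
  branch_length = list(default = 0.031, check = function(x) x >= 0),
  paralog_fraction = list(default = 0.1, check = function(x) x >= 0 && x <= 1),
  min_bit_score = list(default = 300, check = function(x) x >= 0),
  min_cds_bp = list(default = 100L, check = function(x) x >= 3),
  ks_cutoff = list(default = 0.1, check = function(x) x > 0),
  min_depth = list(default = 5L, check = function(x) x >= 0),
  min_maf = list(default = 0.20, check = function(x) x >= 0 && x <= 0.5),
  min_quality = list(default = 30, check = function(x) x >= 0),
  divergence_myr = list(default = 28.8, check = function(x) x > 0),
  mean_ks = list(default = NULL, check = function(x) is.null(x) || x >= 0),
  n_variant_sites = list(default = 1000L, check = function(x) x >= 1),
  variant_defect_rate = list(default = 0.1,
                             check = function(x) x >= 0 && x < 1),
  n_reads = list(default = 1000L, check = function(x) x >= 1),
  read_defect_rate = list(default = 0.05,
                          check = function(x) x >= 0 && x < 1))

#' Validated pipeline configuration
#'
#' Flat key-value configuration with the published thresholds as defaults
#' (bit score 300, minimum CDS 100 bp, Ks cutoff 0.1, depth 5, MAF 0.20,
#' quality 30, divergence 28.8 Myr). Unknown keys are rejected; every
#' value is checked against its domain.
#'
#' @param ... Named settings overriding the defaults (see
#'   `orthodiverge:::.pipeline_schema` for the full key list), or a single
#'   named list.
#' @param file Optional YAML file of settings; explicit arguments override
#'   file values.
#' @return An object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(..., file = NULL) {
  override <- list(...)
  if (length(override) == 1L && is.null(names(override)) &&
      is.list(override[[1]])) {
    override <- override[[1]]
  }
  from_file <- if (!is.null(file)) yaml::read_yaml(file) else list()
  settings <- from_file
  settings[names(override)] <- override
  unknown <- setdiff(names(settings), names(.pipeline_schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- lapply(.pipeline_schema, `[[`, "default")
  cfg[names(settings)] <- settings
  for (key in names(.pipeline_schema)) {
    val <- cfg[[key]]
    if (is.null(val) && is.null(.pipeline_schema[[key]]$default)) next
    if (!.pipeline_schema[[key]]$check(val)) {
      stop("configuration value out of domain: ", key, " = ", val)
    }
  }
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  result
}

#' Run the full comparative-divergence pipeline on simulated inputs
#'
#' Chains every stage in dependency order — ortholog simulation, read QC,
#' reciprocal-best-hit orthology with annotation concordance, codon
#' alignment, Ka/Ks estimation, the selection screen, neutral-rate
#' calibration — plus the two-group SNP screen, writing per-stage TSVs and
#' an aggregated report. Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `screen` (the
#'   [summarize_screen()] result), `clock`, `snp` (the [filter_variants()]
#'   summary), `readqc`, the per-stage counts, and the paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("odrun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  sim <- .stage("simulate", {
    sc <- sim_config(n_pairs = config$n_pairs,
                     codons_per_seq = config$codons_per_seq,
                     omega = config$omega, kappa = config$kappa,
                     branch_length = config$branch_length,
                     paralog_fraction = config$paralog_fraction,
                     seed = seed)
    simulate_ortholog_set(sc, out_dir = file.path(out_dir, "sim"))
  })

  readqc <- .stage("readqc", {
    dr <- config$read_defect_rate
    reads <- simulate_reads(config$n_reads,
                            defect_rates = list(high_n = dr, low_quality = dr,
                                                short = dr),
                            seed = seed + 1L,
                            out_path = file.path(out_dir, "sim", "reads.fastq"))
    trim_reads(reads, fastq_out = file.path(out_dir, "reads_trimmed.fastq"))
  })

  candidates <- .stage("orthologs", {
    cds_a <- lapply(seq_along(sim$fasta_a), function(i) {
      coding_sequence(names(sim$fasta_a)[i],
                      as.character(sim$fasta_a[[i]]), species = "A")
    })
    names(cds_a) <- names(sim$fasta_a)
    cds_b <- lapply(seq_along(sim$fasta_b), function(i) {
      coding_sequence(names(sim$fasta_b)[i],
                      as.character(sim$fasta_b[[i]]), species = "B")
    })
    names(cds_b) <- names(sim$fasta_b)
    hits <- score_pairs(cds_a, cds_b)
    pairs <- reciprocal_best_hits(hits, min_bit_score = config$min_bit_score)
    # simulated sequences carry their pair identity; annotate both members
    # with it so the concordance filter is exercised end to end
    ann <- data.frame(id = c(names(cds_a), names(cds_b)),
                      protein_label = sub("_[AB]$", "",
                                          c(names(cds_a), names(cds_b))),
                      stringsAsFactors = FALSE)
    conc <- annotation_concordance_filter(pairs, ann)
    write_tsv(conc$pairs, file.path(out_dir, "ortholog_pairs.tsv"))
    list(pairs = conc$pairs, cds_a = cds_a, cds_b = cds_b,
         n_bbh = nrow(pairs), n_concordant = conc$n_retained)
  })

  alignments <- .stage("align", {
    lapply(seq_len(nrow(candidates$pairs)), function(i) {
      a <- candidates$pairs$id_a[i]
      b <- candidates$pairs$id_b[i]
      align_pair(candidates$cds_a[[a]] %||% candidates$cds_b[[a]],
                 candidates$cds_b[[b]] %||% candidates$cds_a[[b]],
                 pair_id = sub("_[AB]$", "", a))
    })
  })

  estimates <- .stage("kaks", {
    tab <- kaks_table(alignments, method = config$method)
    write_tsv(tab, file.path(out_dir, "kaks_estimates.tsv"))
    tab
  })

  screen <- .stage("screen", {
    flt <- filter_pairs(estimates, ks_cutoff = config$ks_cutoff)
    write_tsv(flt$retained, file.path(out_dir, "screen_retained.tsv"))
    write_tsv(flt$removed, file.path(out_dir, "screen_removed.tsv"))
    summarize_screen(flt$retained, flt$removed)
  })

  clock <- .stage("clock", {
    d <- if (!is.null(config$mean_ks)) config$mean_ks else screen$mean_Ks
    if (is.na(d)) NULL else substitution_rate(d, config$divergence_myr * 1e6)
  })

  snp <- .stage("snps", {
    dr <- config$variant_defect_rate
    vt <- simulate_variant_tables(
      config$n_variant_sites, shared_fraction = 1 - dr,
      defect_rates = list(multi_allelic = dr, low_depth = dr,
                          low_maf = dr, low_quality = dr),
      seed = seed + 2L, out_dir = file.path(out_dir, "sim"))
    res <- filter_variants(vt$vcf_a, vt$vcf_b,
                           min_depth = config$min_depth,
                           min_maf = config$min_maf,
                           min_quality = config$min_quality)
    write_tsv(res$retained, file.path(out_dir, "snps_retained.tsv"))
    res$summary
  })

  report <- list(
    n_simulated_pairs = config$n_pairs,
    reads = as.list(readqc$report),
    n_bbh_pairs = candidates$n_bbh,
    n_concordant_pairs = candidates$n_concordant,
    n_aligned_pairs = length(alignments),
    screen = unclass(screen),
    clock = if (is.null(clock)) NULL else
      list(d = clock$d, t_years = clock$t_years, rate = clock$rate,
           rate_3sf = clock$rate_3sf),
    snp = lapply(unclass(snp), function(x) {
      if (is.table(x)) as.integer(x) else x
    }))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(report, list(screen_summary = screen, clock_estimate = clock,
                           snp_summary = snp, out_dir = out_dir)))
}
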
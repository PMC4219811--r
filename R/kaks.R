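#' Synonymous and nonsynonymous site counts for a codon
#'
#' Splits each of the three codon positions into a synonymous and a
#' nonsynonymous fraction, following the Nei-Gojobori mutation-opportunity
#' logic with optional transition/transversion (`kappa`) and target-codon
#' frequency weighting. For each position the three single-base neighbours
#' are weighted by `kappa` when the change is a transition and by the
#' neighbour codon's frequency when `codon_frequencies` is supplied;
#' neighbours that are stop codons get weight zero. Each position then
#' contributes exactly 1 site, split proportionally to the synonymous vs
#' nonsynonymous weight mass, so `s + n == 3` for every sense codon.
#'
#' @param codon A single sense codon (3-letter character, ACGT).
#' @param kappa Transition/transversion rate ratio used to weight mutational
#'   opportunity (default 1, the unweighted Nei-Gojobori scheme).
#' @param codon_frequencies Optional named numeric vector of equilibrium
#'   frequencies over the 61 sense codons.
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n == 3`.
#' @examples
#' count_sites("TTT")        # s = 1/3: only the third position is partly silent
#' count_sites("ATG")        # Met has no synonymous neighbour: s = 0
#' @export
count_sites <- function(codon, kappa = 1, codon_frequencies = NULL) {
  codon <- toupper(codon)
  if (!is_sense_codon(codon)) {
    stop("count_sites() requires a sense codon, got '", codon, "'")
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  nb <- codon_neighbours(codon)
  aa <- CODON_AA[codon]
  w <- ifelse(nb$transition, kappa, 1)
  if (!is.null(codon_frequencies)) {
    pi_j <- codon_frequencies[nb$codon]
    pi_j[is.na(pi_j)] <- 0          # stop codons carry no frequency
    w <- w * pi_j
  }
  w[is_stop_codon(nb$codon)] <- 0
  syn <- CODON_AA[nb$codon] == aa
  s <- 0
  for (p in 1:3) {
    sel <- nb$position == p
    tot <- sum(w[sel])
    if (tot > 0) {
      s <- s + sum(w[sel & syn]) / tot
    } else {
      # all weighted mass at this position vanished (e.g. degenerate
      # frequencies); fall back to kappa-only weights for the split
      w0 <- ifelse(nb$transition[sel], kappa, 1)
      w0[is_stop_codon(nb$codon[sel])] <- 0
      if (sum(w0) > 0) s <- s + sum(w0[syn[sel]]) / sum(w0)
    }
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged substitution counts between two codons
#'
#' Enumerates every ordering of the differing positions (1, 2 or 6 mutational
#' pathways for 1/2/3 differences), discards pathways that pass through a
#' stop codon, and averages the synonymous/nonsynonymous and
#' transition/transversion step counts over the surviving pathways with
#' equal weights (the classic Nei-Gojobori treatment).
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector with elements `sd`, `nd`, `transitions`,
#'   `transversions` and the cross-classified `sd_ts`, `sd_tv`, `nd_ts`,
#'   `nd_tv`. `sd + nd` equals the number of differing positions. All `NA`
#'   if every pathway passes through a stop codon.
#' @examples
#' count_differences("TTT", "TTC")  # one synonymous transition
#' count_differences("TTT", "GTA") # sd = 0.5, nd = 1.5 over two pathways
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!is_sense_codon(codon_a) || !is_sense_codon(codon_b)) {
    stop("count_differences() requires sense codons")
  }
  empty <- c(sd = 0, nd = 0, transitions = 0, transversions = 0,
             sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  ca <- codon_chars(codon_a); cb <- codon_chars(codon_b)
  diff_pos <- which(ca != cb)
  k <- length(diff_pos)
  if (k == 0L) return(empty)
  orderings <- switch(k,
    `1` = list(diff_pos),
    `2` = list(diff_pos, rev(diff_pos)),
    `3` = {
      p <- diff_pos
      list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
           p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
    })
  acc <- empty
  n_ok <- 0L
  for (ord in orderings) {
    cur <- ca
    path <- empty
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      cd_cur <- paste(cur, collapse = "")
      cd_nxt <- paste(nxt, collapse = "")
      if (is_stop_codon(cd_nxt)) { ok <- FALSE; break }
      ts <- is_transition(cur[pos], nxt[pos])
      syn <- CODON_AA[cd_cur] == CODON_AA[cd_nxt]
      if (syn) path["sd"] <- path["sd"] + 1 else path["nd"] <- path["nd"] + 1
      if (ts) path["transitions"] <- path["transitions"] + 1
      else path["transversions"] <- path["transversions"] + 1
      key <- paste0(if (syn) "sd" else "nd", if (ts) "_ts" else "_tv")
      path[key] <- path[key] + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + path; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) {
    out <- empty; out[] <- NA_real_
    return(out)
  }
  acc / n_ok
}

#' Multiple-hit corrected nucleotide distance
#'
#' Jukes-Cantor or Kimura two-parameter correction of an observed
#' proportion of differing sites.
#'
#' @param p Observed proportion of differing sites (JC model).
#' @param model `"JC"` or `"K80"`.
#' @param p_transition,p_transversion Observed transition and transversion
#'   proportions (K80 model; `p` is ignored when both are given).
#' @return Corrected distance, always `>= p`.
#' @examples
#' correct_distance(0.1, "JC")   # ~0.10732
#' @export
correct_distance <- function(p, model = c("JC", "K80"),
                             p_transition = NULL, p_transversion = NULL) {
  model <- match.arg(model)
  if (model == "JC") {
    if (p < 0 || p >= 0.75) {
      stop("saturation: JC correction undefined for p = ", format(p))
    }
    return(-0.75 * log(1 - 4 * p / 3))
  }
  P <- p_transition; Q <- p_transversion
  if (is.null(P) || is.null(Q)) stop("K80 needs p_transition and p_transversion")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturation: K80 correction undefined for P = ", format(P),
         ", Q = ", format(Q))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

## quiet variants used by the estimators: NA (not an error) on saturation
.jc_or_na <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}
.k80_or_na <- function(P, Q) {
  if (is.na(P) || is.na(Q)) return(NA_real_)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

## 61x61 lookup tables of pathway-averaged difference counts (built once)
diff_tables <- function() {
  if (!is.null(.od_cache$diff_tables)) return(.od_cache$diff_tables)
  n <- length(SENSE_CODONS)
  comps <- c("sd", "nd", "transitions", "transversions",
             "sd_ts", "sd_tv", "nd_ts", "nd_tv")
  tabs <- lapply(comps, function(x) {
    matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  })
  names(tabs) <- comps
  blocked <- matrix(FALSE, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- count_differences(SENSE_CODONS[i], SENSE_CODONS[j])
      if (anyNA(d)) {
        blocked[i, j] <- blocked[j, i] <- TRUE
        next
      }
      for (cmp in comps) {
        tabs[[cmp]][i, j] <- tabs[[cmp]][j, i] <- d[[cmp]]
      }
    }
  }
  tabs$blocked <- blocked
  .od_cache$diff_tables <- tabs
  tabs
}

## per-codon site counts as a 61x2 matrix for given kappa / frequencies
site_table <- function(kappa = 1, codon_frequencies = NULL) {
  key <- if (is.null(codon_frequencies) && kappa == 1) "st_k1" else NULL
  if (!is.null(key) && !is.null(.od_cache[[key]])) return(.od_cache[[key]])
  st <- t(vapply(SENSE_CODONS, count_sites, numeric(2),
                 kappa = kappa, codon_frequencies = codon_frequencies))
  if (!is.null(key)) .od_cache[[key]] <- st
  st
}

## shared bookkeeping for both estimators
.kaks_counts <- function(alignment) {
  ia <- match(alignment$codons_a, SENSE_CODONS)
  ib <- match(alignment$codons_b, SENSE_CODONS)
  if (anyNA(ia) || anyNA(ib)) {
    stop("alignment contains non-sense codons; run align_pair() masking first")
  }
  tabs <- diff_tables()
  idx <- cbind(ia, ib)
  blocked <- tabs$blocked[idx]
  if (any(blocked)) {
    warning(sum(blocked), " column(s) with all mutational pathways through ",
            "stop codons excluded from pair ", alignment$pair_id)
    idx <- idx[!blocked, , drop = FALSE]
    ia <- ia[!blocked]; ib <- ib[!blocked]
  }
  list(ia = ia, ib = ib, idx = idx, tabs = tabs,
       n_blocked = sum(blocked), n_used = length(ia))
}

.new_kaks <- function(pair_id, method, n_codons, S, N, sums, kappa_hat,
                      Ka, Ks, flags, n_blocked) {
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(
    pair_id = pair_id, method = method, n_codons = n_codons,
    S_sites = S, N_sites = N,
    Sd = sums[["sd"]], Nd = sums[["nd"]],
    Sd_ts = sums[["sd_ts"]], Sd_tv = sums[["sd_tv"]],
    Nd_ts = sums[["nd_ts"]], Nd_tv = sums[["nd_tv"]],
    transitions = sums[["transitions"]], transversions = sums[["transversions"]],
    kappa_hat = kappa_hat, Ka = Ka, Ks = Ks, omega = omega,
    flags = flags, n_blocked_columns = n_blocked
  ), class = "kaks")
}

#' Nei-Gojobori (NG86) Ka/Ks estimate for a codon alignment
#'
#' Equal-weight pathway counting with Jukes-Cantor multiple-hit correction:
#' the reference estimator against which the kappa-corrected one is checked.
#'
#' @param alignment A [codon_alignment()].
#' @return A `"kaks"` object; see [kaks()].
#' @export
estimate_kaks_ng86 <- function(alignment) {
  alignment <- as_codon_alignment(alignment)
  cc <- .kaks_counts(alignment)
  st <- site_table(1, NULL)
  S <- (sum(st[cc$ia, "s"]) + sum(st[cc$ib, "s"])) / 2
  N <- (sum(st[cc$ia, "n"]) + sum(st[cc$ib, "n"])) / 2
  comps <- c("sd", "nd", "transitions", "transversions",
             "sd_ts", "sd_tv", "nd_ts", "nd_tv")
  sums <- vapply(comps, function(cmp) sum(cc$tabs[[cmp]][cc$idx]), numeric(1))
  ps <- if (S > 0) sums[["sd"]] / S else NA_real_
  pn <- if (N > 0) sums[["nd"]] / N else NA_real_
  Ks <- .jc_or_na(ps)
  Ka <- .jc_or_na(pn)
  flags <- character(0)
  if ((!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)) {
    flags <- c(flags, "saturated")
  }
  if (!is.na(Ks) && Ks == 0) flags <- c(flags, "ks_zero")
  .new_kaks(alignment$pair_id, "NG86", cc$n_used, S, N, sums, 1,
            Ka, Ks, flags, cc$n_blocked)
}

#' Transition/transversion rate ratio from four-fold degenerate sites
#'
#' Applies the Kimura two-parameter model to the third positions of
#' alignment columns where both codons belong to a four-fold degenerate
#' family and encode the same amino acid (so every third-position change is
#' synonymous). The ratio is `2 * d_ts / d_tv` in K80 terms. Falls back to
#' `kappa = 1` with a warning when fewer than 10 informative sites exist,
#' and is capped to `[0.1, 20]`.
#'
#' @param alignment A [codon_alignment()].
#' @return A single positive number.
#' @export
estimate_kappa <- function(alignment) {
  alignment <- as_codon_alignment(alignment)
  a <- alignment$codons_a; b <- alignment$codons_b
  sel <- a %in% fourfold_codons & b %in% fourfold_codons &
    CODON_AA[a] == CODON_AA[b]
  n4 <- sum(sel)
  if (n4 < 10) {
    warning("fewer than 10 four-fold degenerate site pairs (", n4,
            "); falling back to kappa = 1")
    return(1)
  }
  t_a <- substr(a[sel], 3, 3); t_b <- substr(b[sel], 3, 3)
  diff <- t_a != t_b
  if (!any(diff)) return(1)  # no third-position divergence: no information
  ts <- diff & is_transition(t_a, t_b)
  P <- sum(ts) / n4
  Q <- sum(diff & !ts) / n4
  if (Q == 0) {
    warning("no transversions at four-fold sites; kappa capped at 20")
    return(20)
  }
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("four-fold sites saturated; falling back to kappa = 1")
    return(1)
  }
  d_ts <- -0.5 * log(w1) + 0.25 * log(w2)
  d_tv <- -0.5 * log(w2)
  kappa <- 2 * d_ts / d_tv
  if (kappa > 20) { warning("kappa capped at 20"); kappa <- 20 }
  if (kappa < 0.1) { warning("kappa floored at 0.1"); kappa <- 0.1 }
  kappa
}

## F3x4 codon frequencies: position-specific nucleotide frequencies pooled
## over both sequences, product per codon, renormalised over sense codons
f3x4_frequencies <- function(alignment) {
  codons <- c(alignment$codons_a, alignment$codons_b)
  counts <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
  for (p in 1:3) {
    tab <- table(factor(substr(codons, p, p), levels = NUCS))
    counts[p, ] <- as.numeric(tab)
  }
  if (any(counts == 0)) {
    warning("zero position-specific nucleotide frequency; adding 0.5 pseudocount")
    counts <- counts + 0.5
  }
  fr <- counts / rowSums(counts)
  pi_codon <- vapply(SENSE_CODONS, function(cd) {
    ch <- codon_chars(cd)
    fr[1, ch[1]] * fr[2, ch[2]] * fr[3, ch[3]]
  }, numeric(1))
  pi_codon / sum(pi_codon)
}

#' Kappa- and frequency-corrected (YN-style) Ka/Ks estimate
#'
#' The production estimator, in the spirit of the Yang-Nielsen approximate
#' method: the transition/transversion ratio is estimated from four-fold
#' degenerate sites, codon frequencies by F3x4, mutational-opportunity site
#' counts are weighted by both, and the Kimura two-parameter correction is
#' applied separately to the synonymous and nonsynonymous
#' transition/transversion proportions. Exact numerical agreement with any
#' particular external implementation is not claimed; the estimator is
#' validated by simulation recovery and by its `kappa = 1` /
#' uniform-frequency limiting case.
#'
#' @param alignment A [codon_alignment()].
#' @param kappa Optional fixed transition/transversion ratio (skips
#'   estimation).
#' @param codon_frequencies Optional fixed sense-codon frequencies (skips
#'   F3x4).
#' @return A `"kaks"` object; see [kaks()].
#' @export
estimate_kaks_yn <- function(alignment, kappa = NULL, codon_frequencies = NULL) {
  alignment <- as_codon_alignment(alignment)
  cc <- .kaks_counts(alignment)
  kappa_hat <- if (is.null(kappa)) estimate_kappa(alignment) else kappa
  freqs <- if (is.null(codon_frequencies)) f3x4_frequencies(alignment)
           else codon_frequencies
  st <- site_table(kappa_hat, freqs)
  S <- (sum(st[cc$ia, "s"]) + sum(st[cc$ib, "s"])) / 2
  N <- (sum(st[cc$ia, "n"]) + sum(st[cc$ib, "n"])) / 2
  comps <- c("sd", "nd", "transitions", "transversions",
             "sd_ts", "sd_tv", "nd_ts", "nd_tv")
  sums <- vapply(comps, function(cmp) sum(cc$tabs[[cmp]][cc$idx]), numeric(1))
  Ks <- if (S > 0) .k80_or_na(sums[["sd_ts"]] / S, sums[["sd_tv"]] / S)
        else NA_real_
  Ka <- if (N > 0) .k80_or_na(sums[["nd_ts"]] / N, sums[["nd_tv"]] / N)
        else NA_real_
  flags <- character(0)
  if ((S > 0 && is.na(Ks) && sums[["sd"]] > 0) ||
      (N > 0 && is.na(Ka) && sums[["nd"]] > 0)) {
    flags <- c(flags, "saturated")
  }
  if (!is.na(Ks) && Ks == 0) flags <- c(flags, "ks_zero")
  .new_kaks(alignment$pair_id, "YN", cc$n_used, S, N, sums, kappa_hat,
            Ka, Ks, flags, cc$n_blocked)
}

#' Fit a pairwise Ka/Ks estimate
#'
#' Front-end for the two counting estimators. `x` may be a
#' [codon_alignment()] or an in-frame coding sequence (with `y` its
#' partner); equal-length gap-free sequences are paired column by column.
#'
#' @param x A `codon_alignment`, or a character / `DNAString` coding
#'   sequence.
#' @param y The partner sequence when `x` is not an alignment.
#' @param method `"yn"` (kappa- and frequency-corrected, the default) or
#'   `"ng86"` (equal-weight Nei-Gojobori reference).
#' @param ... Passed to [estimate_kaks_yn()] (e.g. a fixed `kappa`).
#' @return An object of class `"kaks"`: a list carrying the site counts
#'   (`S_sites`, `N_sites`), pathway-averaged difference counts (`Sd`,
#'   `Nd` and their transition/transversion splits), `kappa_hat`, the
#'   corrected `Ka`, `Ks`, their ratio `omega`, and any `flags`
#'   (`"saturated"`, `"ks_zero"`).
#' @examples
#' a <- strrep("AAATTTGGGCCCATGTGTGAACTT", 5)
#' fit <- kaks(a, a, method = "ng86")
#' coef(fit)
#' @export
kaks <- function(x, y = NULL, method = c("yn", "ng86"), ...) {
  method <- match.arg(method)
  aln <- if (inherits(x, "codon_alignment")) x else codon_alignment(x, y)
  switch(method,
         yn = estimate_kaks_yn(aln, ...),
         ng86 = estimate_kaks_ng86(aln))
}

#' @export
print.kaks <- function(x, ...) {
  cat("Pairwise Ka/Ks estimate (", x$method, ")\n", sep = "")
  if (!is.null(x$pair_id) && nzchar(x$pair_id)) cat("  pair:     ", x$pair_id, "\n")
  cat("  codons:   ", x$n_codons, "\n")
  cat(sprintf("  sites:     S = %.2f, N = %.2f\n", x$S_sites, x$N_sites))
  cat(sprintf("  diffs:     Sd = %.2f, Nd = %.2f\n", x$Sd, x$Nd))
  cat(sprintf("  kappa_hat: %.3f\n", x$kappa_hat))
  cat(sprintf("  Ka = %s, Ks = %s, Ka/Ks = %s\n",
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$omega, digits = 4)))
  if (length(x$flags)) cat("  flags:    ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kaks <- function(object, ...) {
  c(Ka = object$Ka, Ks = object$Ks, omega = object$omega,
    kappa = object$kappa_hat)
}

#' @export
summary.kaks <- function(object, ...) {
  print(object)
  cat(sprintf("  ts/tv split: Sd = %.2f ts + %.2f tv; Nd = %.2f ts + %.2f tv\n",
              object$Sd_ts, object$Sd_tv, object$Nd_ts, object$Nd_tv))
  if (object$n_blocked_columns > 0) {
    cat("  columns excluded (all pathways through stops):",
        object$n_blocked_columns, "\n")
  }
  invisible(object)
}

#' Tabulate Ka/Ks estimates for a set of alignments
#'
#' @param alignments A list of [codon_alignment()] objects.
#' @param method Passed to [kaks()].
#' @param ... Passed to [kaks()].
#' @return A data frame with one row per pair: `pair_id`, `method`,
#'   `n_codons`, `S`, `N`, `Sd`, `Nd`, `kappa_hat`, `Ka`, `Ks`, `omega`,
#'   `flags` (semicolon-separated).
#' @export
kaks_table <- function(alignments, method = c("yn", "ng86"), ...) {
  method <- match.arg(method)
  rows <- lapply(alignments, function(aln) {
    est <- kaks(aln, method = method, ...)
    data.frame(pair_id = est$pair_id, method = est$method,
               n_codons = est$n_codons, S = est$S_sites, N = est$N_sites,
               Sd = est$Sd, Nd = est$Nd, kappa_hat = est$kappa_hat,
               Ka = est$Ka, Ks = est$Ks, omega = est$omega,
               flags = paste(est$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
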
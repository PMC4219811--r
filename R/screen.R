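#' Filter Ka/Ks estimates before the selection screen
#'
#' Applies the pre-screen exclusions in a fixed order, logging each pair
#' once under its first failing rule: (1) `Ks` strictly above `ks_cutoff`
#' (paralog exclusion); (2) `Sd == 0` or `Nd == 0` — pairs with all
#' synonymous or all nonsynonymous substitutions, for which the ratio is
#' degenerate; (3) saturation or otherwise undefined estimates.
#'
#' @param estimates Data frame from [kaks_table()] (columns `pair_id`,
#'   `Sd`, `Nd`, `Ks`, `Ka`, `omega`, `flags`), or a list of `"kaks"`
#'   objects.
#' @param ks_cutoff Synonymous-divergence exclusion threshold (default
#'   0.1, strict).
#' @return List with `retained` (data frame) and `removed` (data frame
#'   with a `reason` column: `ks_gt_cutoff`, `zero_class`, `undefined`).
#' @export
filter_pairs <- function(estimates, ks_cutoff = 0.1) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- kaks_table_from_objects(estimates)
  }
  stopifnot(all(c("pair_id", "Sd", "Nd", "Ks") %in% names(estimates)))
  if (is.null(estimates$flags)) estimates$flags <- ""
  reason <- rep(NA_character_, nrow(estimates))
  r1 <- !is.na(estimates$Ks) & estimates$Ks > ks_cutoff
  reason[r1] <- "ks_gt_cutoff"
  r2 <- is.na(reason) & !is.na(estimates$Sd) & !is.na(estimates$Nd) &
    (estimates$Sd == 0 | estimates$Nd == 0)
  reason[r2] <- "zero_class"
  r3 <- is.na(reason) &
    (grepl("saturated", estimates$flags) | is.na(estimates$Ks) |
       is.na(estimates$Ka) | is.na(estimates$omega))
  reason[r3] <- "undefined"
  removed <- estimates[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(retained = estimates[is.na(reason), , drop = FALSE],
       removed = removed)
}

## coerce a list of kaks objects to the tabular form the screen expects
kaks_table_from_objects <- function(objs) {
  do.call(rbind, lapply(objs, function(est) {
    data.frame(pair_id = est$pair_id, method = est$method,
               n_codons = est$n_codons, S = est$S_sites, N = est$N_sites,
               Sd = est$Sd, Nd = est$Nd, kappa_hat = est$kappa_hat,
               Ka = est$Ka, Ks = est$Ks, omega = est$omega,
               flags = paste(est$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Classify a pair's selection regime from its Ka/Ks ratio
#'
#' `omega > 1` is called strong positive selection, `0.5 < omega <= 1`
#' moderate positive selection (the interval is closed at 1), and
#' `omega <= 0.5` background.
#'
#' @param omega Numeric vector of defined Ka/Ks ratios, or a `"kaks"`
#'   object.
#' @return Character vector in `{"strong_positive", "moderate_positive",
#'   "background"}`.
#' @export
classify_selection <- function(omega) {
  if (inherits(omega, "kaks")) omega <- omega$omega
  if (any(is.na(omega))) {
    stop("undefined omega: pairs must pass filter_pairs() before classification")
  }
  ifelse(omega > 1, "strong_positive",
         ifelse(omega > 0.5, "moderate_positive", "background"))
}

#' Summarise a screened set of ortholog pairs
#'
#' Arithmetic means of Ka, Ks and the per-pair Ka/Ks ratio over retained
#' pairs (the mean ratio is the mean of per-pair ratios, not the ratio of
#' means), selection-class counts, and the removal tallies carried through
#' from [filter_pairs()].
#'
#' @param retained Data frame of retained estimates (from
#'   [filter_pairs()]).
#' @param removed Optional removal log (from [filter_pairs()]).
#' @param n_input Optional input-pair count (defaults to retained +
#'   removed).
#' @return An object of class `"screen_summary"`.
#' @export
summarize_screen <- function(retained, removed = NULL, n_input = NULL) {
  n_ret <- nrow(retained)
  n_ks <- if (!is.null(removed)) sum(removed$reason == "ks_gt_cutoff") else 0L
  n_zero <- if (!is.null(removed)) sum(removed$reason == "zero_class") else 0L
  n_undef <- if (!is.null(removed)) sum(removed$reason == "undefined") else 0L
  if (is.null(n_input)) n_input <- n_ret + n_ks + n_zero + n_undef
  if (n_ret > 0) {
    cls <- classify_selection(retained$omega)
    means <- c(mean_Ka = mean(retained$Ka), mean_Ks = mean(retained$Ks),
               mean_omega = mean(retained$omega))
    counts <- c(n_strong = sum(cls == "strong_positive"),
                n_moderate = sum(cls == "moderate_positive"),
                n_background = sum(cls == "background"))
  } else {
    means <- c(mean_Ka = NA_real_, mean_Ks = NA_real_, mean_omega = NA_real_)
    counts <- c(n_strong = 0L, n_moderate = 0L, n_background = 0L)
  }
  structure(c(list(n_input_pairs = n_input,
                   n_removed_ks_gt_cutoff = n_ks,
                   n_removed_zero_class = n_zero,
                   n_removed_undefined = n_undef,
                   n_retained = n_ret),
              as.list(means), as.list(counts)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Selection screen summary\n")
  cat(sprintf("  input pairs:        %d\n", x$n_input_pairs))
  cat(sprintf("  removed Ks>cutoff:  %d\n", x$n_removed_ks_gt_cutoff))
  cat(sprintf("  removed zero-class: %d\n", x$n_removed_zero_class))
  cat(sprintf("  removed undefined:  %d\n", x$n_removed_undefined))
  cat(sprintf("  retained:           %d\n", x$n_retained))
  cat(sprintf("  mean Ka / Ks / Ka-Ks ratio: %.4f / %.4f / %.4f\n",
              x$mean_Ka, x$mean_Ks, x$mean_omega))
  cat(sprintf("  strong (>1): %d, moderate (0.5,1]: %d, background: %d\n",
              x$n_strong, x$n_moderate, x$n_background))
  invisible(x)
}

#' @export
as.data.frame.screen_summary <- function(x, ...) {
  data.frame(x[ !vapply(x, is.null, logical(1)) ], stringsAsFactors = FALSE)
}
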
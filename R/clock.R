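#' Neutral substitution rate from synonymous divergence and split time
#'
#' For two lineages that diverged `t` years ago, the genetic distance `d`
#' between them accumulates over `2t` years of independent evolution, so
#' the per-year substitution rate is `r = d / (2 t)`. Here `d` is the mean
#' synonymous divergence (Ks) over retained ortholog pairs, the standard
#' neutral proxy for coding regions.
#'
#' @param d Mean synonymous distance, substitutions per site (>= 0).
#' @param t_years Divergence time in years (> 0).
#' @return An object of class `"clock_estimate"` with `d`, `t_years`,
#'   `rate` (substitutions/site/year, full precision) and `rate_3sf`
#'   (rounded to 3 significant figures).
#' @examples
#' substitution_rate(0.0802, 28.8e6)   # 1.39e-09 substitutions/site/year
#' @export
substitution_rate <- function(d, t_years) {
  if (!is.numeric(t_years) || length(t_years) != 1L || t_years <= 0) {
    stop("t_years must be a single positive number")
  }
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop("d must be a single non-negative number")
  }
  rate <- d / (2 * t_years)
  structure(list(d = d, t_years = t_years, rate = rate,
                 rate_3sf = signif(rate, 3)),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat("Neutral substitution rate calibration\n")
  cat(sprintf("  mean synonymous distance d: %g substitutions/site\n", x$d))
  cat(sprintf("  divergence time t:          %g years\n", x$t_years))
  cat(sprintf("  rate r = d / (2t):          %.3g substitutions/site/year\n",
              x$rate_3sf))
  invisible(x)
}

#' @export
as.data.frame.clock_estimate <- function(x, ...) {
  data.frame(d = x$d, t_years = x$t_years, rate = x$rate,
             rate_3sf = x$rate_3sf)
}
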
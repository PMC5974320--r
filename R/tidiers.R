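# broom-style accessors for the fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn concordance per-pair tibble with categories and flags.
#' @param x a `homoeolog_concordance` object.
#' @param ... unused.
#' @export
tidy.homoeolog_concordance <- function(x, ...) as_tibble(x$pairs)

#' @describeIn concordance one-row summary (fraction concordant, pair
#'   counts, opposite-pair count).
#' @export
glance.homoeolog_concordance <- function(x, ...) {
  tibble(fraction_concordant = x$fraction_concordant,
         n_pairs = x$n_pairs, n_total = x$n_total,
         n_discordant = sum(!x$pairs$concordant),
         n_opposite = sum(x$pairs$opposite))
}

#' @describeIn pwm_pvalue_threshold one-row summary of the threshold object.
#' @param x a `pwm_threshold` object.
#' @param ... unused.
#' @export
glance.pwm_threshold <- function(x, ...) {
  tibble(motif_id = x$motif_id, threshold = x$threshold, alpha = x$alpha,
         step = x$model$step)
}
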
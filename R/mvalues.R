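#' Convert methylation beta values to M-values
#'
#' M-values are the logit2 transform of the methylated fraction,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. All model fitting in this package
#' is done on the M-value scale; beta values are used only for the
#' variability filter in [filter_probes()].
#'
#' Values at or outside the open interval (0, 1) are clamped to
#' `[eps, 1 - eps]` with a warning, so boundary betas produce large finite
#' M-values rather than infinities.
#'
#' @param beta numeric vector of methylated fractions.
#' @param eps clamp width for boundary values.
#' @return numeric vector of M-values.
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(beta)) stop_invalid("beta must be numeric")
  out_of_range <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " beta value(s) outside (0,1) clamped to [",
            eps, ", ", 1 - eps, "]")
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m numeric vector of M-values.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}
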
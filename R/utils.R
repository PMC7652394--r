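#' Inverse logit link
#'
#' Maps a linear predictor to a probability, \eqn{x \mapsto 1/(1+e^{-x})}.
#' This is the link used by the micronucleus (MN) formation models.
#'
#' @param x Numeric vector.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' inv_logit(0)        # 0.5
#' inv_logit(-4.575)   # ~0.0102, a typical baseline per-cycle MN probability
#' @export
inv_logit <- function(x) {
  # guarded for large |x| so exp() never overflows
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' @rdname inv_logit
#' @param p Numeric vector of probabilities.
#' @export
logit <- function(p) log(p) - log1p(-p)

# log(1 + exp(x)) without overflow; used by the Bernoulli-logit log-likelihood
log1p_exp <- function(x) {
  out <- x
  small <- x < 35
  out[small] <- log1p(exp(x[small]))
  out
}

# stable log-sum-exp over a vector
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic numeric formatting shared by write_tidy and the SVG renderer
fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- ""
  out
}
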
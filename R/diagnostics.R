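# Convergence diagnostics: rank-normalized split-R-hat and a basic
# effective-sample-size estimate, plus the quantile summary used by
# summary.lineage_fit.

#' Split R-hat convergence diagnostic
#'
#' Rank-normalized split-R-hat per parameter. Each chain is split in half,
#' draws are rank-normalized across all splits, and the classic
#' between/within variance ratio is computed on the normalized values.
#' Chains that are numerically constant return 1 by convention.
#'
#' @param draws Matrix of draws (rows) by parameters (columns), or a
#'   numeric vector for a single parameter.
#' @param chain_id Integer vector assigning each row to a chain. With a
#'   single chain (or `NULL`) the diagnostic is computed on split halves
#'   of that chain, with a warning.
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(draws, chain_id = NULL) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (is.null(chain_id)) chain_id <- rep(1L, nrow(draws))
  if (length(unique(chain_id)) < 2L) {
    warning("single chain: R-hat computed on split halves", call. = FALSE)
  }
  # split every chain in half
  split_id <- integer(nrow(draws))
  nxt <- 1L
  for (ch in unique(chain_id)) {
    idx <- which(chain_id == ch)
    h <- length(idx) %/% 2L
    split_id[idx[seq_len(h)]] <- nxt
    split_id[idx[(h + 1L):length(idx)]] <- nxt + 1L
    nxt <- nxt + 2L
  }
  apply(draws, 2, function(x) split_rhat_one(x, split_id))
}

split_rhat_one <- function(x, split_id) {
  if (stats::sd(x) < 1e-12 || !all(is.finite(x))) return(1)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                      (length(x) + 1 / 4))
  m <- tapply(z, split_id, mean)
  v <- tapply(z, split_id, stats::var)
  n <- tapply(z, split_id, length)
  nbar <- mean(n)
  W <- mean(v)
  B <- nbar * stats::var(m)
  if (W < 1e-12) return(1)
  sqrt(((nbar - 1) / nbar * W + B / nbar) / W)
}

#' Effective sample size
#'
#' Crude per-parameter effective sample size from the initial positive
#' sequence of autocorrelations, averaged over chains.
#'
#' @inheritParams rhat
#' @return Named numeric vector of effective sample sizes.
#' @export
ess <- function(draws, chain_id = NULL) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (is.null(chain_id)) chain_id <- rep(1L, nrow(draws))
  apply(draws, 2, function(x) {
    if (stats::sd(x) < 1e-12) return(length(x))
    per_chain <- vapply(unique(chain_id), function(ch) {
      xc <- x[chain_id == ch]
      n <- length(xc)
      rho <- stats::acf(xc, lag.max = min(n - 1L, 200L), plot = FALSE,
                        demean = TRUE)$acf[-1]
      s <- 0
      for (r in rho) {
        if (r <= 0.05) break
        s <- s + r
      }
      n / (1 + 2 * s)
    }, numeric(1))
    sum(per_chain)
  })
}

#' Summarize posterior draws
#'
#' Per-parameter posterior median, 50% and 95% credible intervals
#' (empirical quantiles, linear interpolation), split-R-hat and effective
#' sample size.
#'
#' @inheritParams rhat
#' @return A data.frame with columns `parameter`, `median`, `q25`, `q75`,
#'   `q2.5`, `q97.5`, `rhat`, `ess`.
#' @export
summarize_draws <- function(draws, chain_id = NULL) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "par"))
  if (nrow(draws) < 4L) stop("need at least 4 draws to summarize", call. = FALSE)
  qs <- t(apply(draws, 2, stats::quantile,
                probs = c(0.5, 0.25, 0.75, 0.025, 0.975), type = 7,
                names = FALSE))
  out <- data.frame(parameter = colnames(draws) %||%
                      paste0("par", seq_len(ncol(draws))),
                    median = qs[, 1], q25 = qs[, 2], q75 = qs[, 3],
                    q2.5 = qs[, 4], q97.5 = qs[, 5],
                    rhat = suppressWarnings(rhat(draws, chain_id)),
                    ess = ess(draws, chain_id),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
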
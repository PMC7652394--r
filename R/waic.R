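# WAIC on the generalization-loss scale (nat/sample):
#   lppd_i = log mean_s exp(loglik_si)   (log-sum-exp stabilized)
#   p_i    = Var_s(loglik_si)            (n-1 denominator)
#   waic_per_sample = sum_i(-lppd_i + p_i) / n
# Smaller is better. The deviance-scale value (2 * n * waic_per_sample) is
# also carried for cross-checking against other toolchains.

#' Widely applicable information criterion
#'
#' Computes WAIC from a pointwise log-likelihood matrix (draws x
#' observations) or directly from a `lineage_fit`. Reported on the
#' generalization-loss scale in nat/sample; the conventional deviance
#' scale is included as `$waic_deviance`.
#'
#' @param x A draws-by-observations log-likelihood matrix, or a
#'   `lineage_fit`.
#' @param ... Unused.
#' @return An object of class `waic_result`: `model`, `n`,
#'   `lppd_per_sample`, `p_waic_per_sample`, `waic_per_sample`,
#'   `waic_deviance` and `pointwise` (data.frame of per-observation
#'   `lppd_i` and `p_i`).
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @param model Model name attached to the result.
#' @export
waic.matrix <- function(x, model = "model", ...) {
  if (nrow(x) < 2L) stop("WAIC variance undefined: need >= 2 draws", call. = FALSE)
  if (any(!is.finite(x))) stop("input error: non-finite log-likelihood entries",
                               call. = FALSE)
  S <- nrow(x); n <- ncol(x)
  m <- apply(x, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(x, 2, m, "-"))))
  mu <- colMeans(x)
  p_i <- colSums(sweep(x, 2, mu, "-")^2) / (S - 1)
  wps <- sum(-lppd_i + p_i) / n
  structure(list(model = model, n = n,
                 lppd_per_sample = sum(lppd_i) / n,
                 p_waic_per_sample = sum(p_i) / n,
                 waic_per_sample = wps,
                 waic_deviance = 2 * n * wps,
                 pointwise = data.frame(lppd_i = lppd_i, p_i = p_i)),
            class = "waic_result")
}

#' @rdname waic
#' @export
waic.lineage_fit <- function(x, ...) {
  waic.matrix(x$loglik, model = x$spec$name)
}

#' @export
print.waic_result <- function(x, digits = 5, ...) {
  cat(sprintf("WAIC for '%s' (n = %d):\n", x$model, x$n))
  cat(sprintf("  lppd %.5f, p_waic %.5f, waic %.5f nat/sample (deviance scale %.3f)\n",
              x$lppd_per_sample, x$p_waic_per_sample, x$waic_per_sample,
              x$waic_deviance))
  invisible(x)
}

#' Compare two WAIC results with the AIC-scale significance rule
#'
#' The per-sample WAIC difference `waic_b - waic_a` is converted to the
#' AIC (deviance) scale by multiplying by `2 * n`; a difference greater
#' than 1 on that scale is considered significant.
#'
#' @param a,b `waic_result` objects computed on the same `n` observations.
#' @param n Observation count; defaults to the common `n` of `a` and `b`.
#' @return A list with `delta_per_sample` (`waic_b - waic_a`),
#'   `delta_aic_scale` (`|delta| * n * 2`), `significant`
#'   (`delta_aic_scale > 1`) and `better` (name of the lower-WAIC model).
#' @examples
#' # the conversion used throughout: 0.00045269 nat/sample at n = 4424
#' # gives 0.00045269 * 4424 * 2 = 4.00540112 on the AIC scale
#' @export
compare_waic <- function(a, b, n = NULL) {
  if (is.null(n)) {
    if (a$n != b$n) stop("comparison error: WAICs computed on different n (",
                         a$n, " vs ", b$n, ")", call. = FALSE)
    n <- a$n
  }
  delta <- b$waic_per_sample - a$waic_per_sample
  list(delta_per_sample = delta,
       delta_aic_scale = abs(delta) * n * 2,
       significant = abs(delta) * n * 2 > 1,
       better = if (delta >= 0) a$model else b$model)
}

#' Rank models by WAIC
#'
#' Orders `waic_result`s by per-sample WAIC (ascending; ties broken by
#' model name) and reports each model's AIC-scale gap to the best.
#'
#' @param results List of `waic_result` objects on identical data.
#' @return A data.frame: `model`, `n`, `lppd_per_sample`,
#'   `p_waic_per_sample`, `waic_per_sample`, `delta_aic_scale`,
#'   `significant`.
#' @export
rank_models <- function(results) {
  if (length(results) == 0L) stop("no WAIC results to rank", call. = FALSE)
  n <- vapply(results, `[[`, 0, "n")
  if (length(unique(n)) != 1L) {
    stop("comparison error: results computed on different n", call. = FALSE)
  }
  df <- data.frame(
    model = vapply(results, `[[`, "", "model"),
    n = n,
    lppd_per_sample = vapply(results, `[[`, 0, "lppd_per_sample"),
    p_waic_per_sample = vapply(results, `[[`, 0, "p_waic_per_sample"),
    waic_per_sample = vapply(results, `[[`, 0, "waic_per_sample"),
    stringsAsFactors = FALSE)
  df <- df[order(df$waic_per_sample, df$model), , drop = FALSE]
  df$delta_aic_scale <- (df$waic_per_sample - df$waic_per_sample[1]) *
    df$n * 2
  df$significant <- df$delta_aic_scale > 1
  rownames(df) <- NULL
  df
}
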
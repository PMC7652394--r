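# Posterior-predictive quantities: per-draw MN probabilities, fold
# changes of averaged probabilities, predictive interphase-duration
# samples, quartiles/IQR, and Kolmogorov-Smirnov distances.

.cov_names <- c("SCF", "RNF", "STG", "SIS", "MN")

check_covariates <- function(covariates) {
  bad <- setdiff(names(covariates), .cov_names)
  if (length(bad) > 0L) {
    stop("covariate error: unknown covariate(s) ",
         paste(bad, collapse = ", "), "; expected a subset of ",
         paste(.cov_names, collapse = ", "), call. = FALSE)
  }
  cv <- stats::setNames(rep(0, length(.cov_names)), .cov_names)
  cv[names(covariates)] <- as.numeric(covariates)
  cv
}

# per-draw linear predictor at one covariate setting; for hierarchical
# models a fresh lineage effect is drawn per posterior draw from the
# fitted population distribution
draw_eta <- function(fit, cv) {
  draws <- fit$draws
  eta <- draws[, "b"]
  for (tm in fit$spec$terms) {
    eta <- eta + draws[, tm] * cv[[.term_cols[[tm]]]]
  }
  if (fit$spec$lineage_effect != "none") {
    tau <- draws[, "tau"]
    eta <- eta + if (fit$spec$lineage_effect == "normal") {
      stats::rnorm(length(tau), 0, tau)
    } else {
      tau * stats::rt(length(tau), df = fit$spec$student_df)
    }
  }
  eta
}

#' Posterior-predictive MN probability
#'
#' Computes the per-draw probability of micronucleus formation
#' `q = inv_logit(b + terms)` at a covariate setting, plus its posterior
#' average. For hierarchical models the lineage effect is integrated out
#' by drawing a new lineage per posterior draw.
#'
#' @param fit A `lineage_fit` of an MN-response model.
#' @param covariates Named vector/list of dummy values among `SCF`, `RNF`,
#'   `STG`, `SIS` (unset values default to 0).
#' @param seed Seed for the lineage-effect integration (hierarchical
#'   models only).
#' @return List of class `predictive_samples`: `samples` (per-draw q),
#'   `average`, `covariates`, `model`.
#' @examples
#' \donttest{
#' d <- simulate_lineages(sim_params(n_lineages = 5), seed = 1)
#' f <- fit_lineage_model(mn_model_registry()[["1_4"]], d,
#'                        chains = 2, iterations = 500, warmup = 250)
#' predict_mn_prob(f, c(SCF = 1))$average
#' }
#' @export
predict_mn_prob <- function(fit, covariates = c(), seed = 1) {
  stopifnot(inherits(fit, "lineage_fit"))
  if (fit$spec$response != "MN") {
    stop("predict_mn_prob requires an MN-response model fit", call. = FALSE)
  }
  cv <- check_covariates(covariates)
  if (fit$spec$lineage_effect != "none") set.seed(seed)
  q <- inv_logit(draw_eta(fit, cv))
  structure(list(samples = q, average = mean(q), covariates = cv,
                 model = fit$spec$name),
            class = "predictive_samples")
}

#' @export
print.predictive_samples <- function(x, ...) {
  cat(sprintf("Posterior-predictive samples from '%s' (%d draws), average %.4g\n",
              x$model, length(x$samples), x$average))
  invisible(x)
}

#' Fold change of average MN probability between two covariate settings
#'
#' The primary `ratio` divides the two averaged posterior probabilities
#' (average of q with / average of q without); the distribution of
#' per-draw ratios is returned alongside.
#'
#' @param fit A `lineage_fit` of an MN-response model.
#' @param covariates_with,covariates_without Covariate settings as in
#'   [predict_mn_prob()].
#' @param seed Passed to [predict_mn_prob()].
#' @return List with `ratio`, `average_with`, `average_without` and
#'   `per_draw_ratio`.
#' @export
mn_fold_change <- function(fit, covariates_with, covariates_without,
                           seed = 1) {
  pw <- predict_mn_prob(fit, covariates_with, seed = seed)
  po <- predict_mn_prob(fit, covariates_without, seed = seed + 1)
  if (po$average <= 0) stop("zero denominator in fold change", call. = FALSE)
  list(ratio = pw$average / po$average,
       average_with = pw$average, average_without = po$average,
       per_draw_ratio = pw$samples / po$samples)
}

#' Posterior-predictive interphase-duration samples
#'
#' Draws `m` durations from the fitted model at a covariate setting and
#' MN status: each sample picks a posterior draw (or the posterior median
#' when `integrate = FALSE`), computes the log-median `mu`, and samples
#' one duration from the model's likelihood with the requested condition's
#' scale parameter.
#'
#' @param fit A `lineage_fit` of a duration model.
#' @param covariates Named dummy values among `SCF`, `RNF`, `STG`, `SIS`.
#' @param mn_status 0 or 1: MN absent / present during the cycle.
#' @param condition Condition label selecting the scale group (one of
#'   `condition_table()$condition`); ignored when the model's scale is
#'   shared or absent.
#' @param m Number of predictive samples (default 10000).
#' @param seed RNG seed.
#' @param integrate If `TRUE` (default) integrate over the posterior; if
#'   `FALSE` plug in posterior medians.
#' @return List of class `predictive_samples` with positive duration
#'   `samples` (hours).
#' @export
predictive_durations <- function(fit, covariates = c(), mn_status = 0,
                                 condition = NULL, m = 10000, seed = 1,
                                 integrate = TRUE) {
  stopifnot(inherits(fit, "lineage_fit"))
  if (fit$spec$response != "interphase_duration") {
    stop("predictive_durations requires a duration-model fit", call. = FALSE)
  }
  cv <- check_covariates(covariates)
  cv[["MN"]] <- as.numeric(mn_status)
  set.seed(seed)
  eta_all <- draw_eta(fit, cv)
  idx <- if (integrate) {
    sample.int(length(eta_all), m, replace = TRUE)
  } else rep(1L, m)
  mu <- if (integrate) eta_all[idx] else rep(stats::median(eta_all), m)
  sc <- NULL
  if (fit$spec$sigma_grouping != "none") {
    pref <- if (fit$spec$likelihood == "gamma") "alpha" else "sigma"
    if (fit$spec$sigma_grouping == "by_condition") {
      if (is.null(condition)) {
        stop("condition label required for a by-condition scale", call. = FALSE)
      }
      col <- paste0(pref, "[", condition, "]")
      if (!col %in% colnames(fit$draws)) {
        stop("unknown condition group: ", condition, call. = FALSE)
      }
    } else col <- pref
    sc_all <- fit$draws[, col]
    sc <- if (integrate) sc_all[idx] else rep(stats::median(sc_all), m)
  }
  samples <- switch(fit$spec$likelihood,
    lognormal = stats::rlnorm(m, meanlog = mu, sdlog = sc),
    exponential = stats::rexp(m, rate = exp(-mu)),
    gamma = stats::rgamma(m, shape = sc, rate = sc * exp(-mu)))
  structure(list(samples = samples, average = mean(samples),
                 covariates = cv, condition = condition,
                 model = fit$spec$name),
            class = "predictive_samples")
}

#' Quartiles and interquartile range of duration samples
#'
#' Empirical 25/50/75 percentiles (linear interpolation) and
#' `iqr = q75 - q25`, the measure of cell-cycle variability.
#'
#' @param samples Numeric vector (>= 4 values) or a `predictive_samples`
#'   object.
#' @return Named list `q25`, `q50`, `q75`, `iqr`.
#' @export
duration_quartiles <- function(samples) {
  if (inherits(samples, "predictive_samples")) samples <- samples$samples
  if (length(samples) < 4L) stop("need at least 4 samples", call. = FALSE)
  q <- stats::quantile(samples, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(q25 = q[1], q50 = q[2], q75 = q[3], iqr = q[3] - q[1])
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Sup-distance between the empirical distribution functions of two
#' samples, with the (asymptotic) p-value. With the default predictive
#' sample sizes (10000 per side) the p-value is effectively display-only.
#'
#' @param a,b Numeric vectors or `predictive_samples` objects.
#' @return List with `D` and `p_value`.
#' @export
ks_distance <- function(a, b) {
  if (inherits(a, "predictive_samples")) a <- a$samples
  if (inherits(b, "predictive_samples")) b <- b$samples
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Posterior predictions from a lineage model fit
#'
#' Dispatches on the fitted response: MN models return per-draw MN
#' probabilities ([predict_mn_prob()]); duration models return predictive
#' duration samples ([predictive_durations()]).
#'
#' @param object A `lineage_fit`.
#' @param covariates,... Passed to the underlying prediction function.
#' @return A `predictive_samples` object.
#' @export
predict.lineage_fit <- function(object, covariates = c(), ...) {
  if (object$spec$response == "MN") {
    predict_mn_prob(object, covariates, ...)
  } else {
    predictive_durations(object, covariates, ...)
  }
}
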
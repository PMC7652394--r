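# Declarative model specifications for the two model families:
#   model 1 (MN):       MN_n ~ Bernoulli(inv_logit(b + terms + lin))
#   model 2 (duration): Int_duration_n ~ LogNormal(mu_n, sigma_c) with
#                       mu_n = b + micro*MN_n + confounders (+ lin),
#                       or exponential / gamma with mean exp(mu_n).
# Term -> covariate mapping: scf->SCF, rnf->RNF, stg->STG, sis2_3->SIS,
# micro->MN.

.term_cols <- c(scf = "SCF", rnf = "RNF", stg = "STG", sis2_3 = "SIS",
                micro = "MN")

#' Construct a model specification
#'
#' @param name Unique model name, e.g. `"1_4"` or `"2_2_gamma"`.
#' @param response `"MN"` or `"interphase_duration"`.
#' @param likelihood One of `"bernoulli_logit"`, `"lognormal"`,
#'   `"exponential"`, `"gamma"`.
#' @param terms Character subset of
#'   `c("scf", "rnf", "stg", "sis2_3", "micro")`; `micro` is only valid
#'   for the duration response.
#' @param lineage_effect `"none"`, `"normal"` or `"student_t"` per-lineage
#'   random intercepts (lineage individuality).
#' @param sigma_grouping `"by_condition"`, `"shared"` or `"none"`; the
#'   scale (log-normal sigma, gamma shape) may differ among the six
#'   experimental conditions.
#' @param student_df Degrees of freedom used when
#'   `lineage_effect = "student_t"` (fixed, default 4).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, response = c("MN", "interphase_duration"),
                       likelihood = c("bernoulli_logit", "lognormal",
                                      "exponential", "gamma"),
                       terms = character(),
                       lineage_effect = c("none", "normal", "student_t"),
                       sigma_grouping = c("none", "by_condition", "shared"),
                       student_df = 4) {
  response <- match.arg(response)
  likelihood <- match.arg(likelihood)
  lineage_effect <- match.arg(lineage_effect)
  sigma_grouping <- match.arg(sigma_grouping)
  terms <- as.character(terms)
  unknown <- setdiff(terms, names(.term_cols))
  if (length(unknown) > 0L) {
    stop("unknown model term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (response == "MN" && "micro" %in% terms) {
    stop("term 'micro' is only valid for the duration response", call. = FALSE)
  }
  if (response == "MN" && likelihood != "bernoulli_logit") {
    stop("MN response requires the bernoulli_logit likelihood", call. = FALSE)
  }
  if (response == "interphase_duration" && likelihood == "bernoulli_logit") {
    stop("duration response requires a positive-valued likelihood", call. = FALSE)
  }
  if (likelihood == "bernoulli_logit" && sigma_grouping != "none") {
    stop("bernoulli_logit has no scale parameter; sigma_grouping must be 'none'",
         call. = FALSE)
  }
  if (likelihood %in% c("lognormal", "gamma") && sigma_grouping == "none") {
    stop(likelihood, " likelihood requires a sigma_grouping of 'by_condition' or 'shared'",
         call. = FALSE)
  }
  structure(list(name = name, response = response, likelihood = likelihood,
                 terms = terms, lineage_effect = lineage_effect,
                 sigma_grouping = sigma_grouping, student_df = student_df),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s': %s ~ %s(%s)%s%s\n", x$name, x$response,
              x$likelihood,
              paste(c("b", x$terms), collapse = " + "),
              if (x$lineage_effect != "none")
                paste0(" + lin[", x$lineage_effect, "]") else "",
              switch(x$sigma_grouping,
                     by_condition = ", scale by condition",
                     shared = ", shared scale", none = "")))
  invisible(x)
}

#' Canonical registry of the six MN model structures
#'
#' The default grid crosses two linear predictors (full:
#' scf + rnf + stg + sis2_3; reduced: scf only) with three lineage-effect
#' choices (none, normal, Student-t). Names follow the convention that
#' `1_2` is the full predictor without lineage individuality and `1_4` is
#' the scf-only model without lineage individuality.
#'
#' @return Named list of six `model_spec` objects.
#' @seealso [duration_model_registry()]
#' @export
mn_model_registry <- function() {
  full <- c("scf", "rnf", "stg", "sis2_3")
  specs <- list(
    model_spec("1_1", "MN", "bernoulli_logit", full, "normal"),
    model_spec("1_2", "MN", "bernoulli_logit", full, "none"),
    model_spec("1_3", "MN", "bernoulli_logit", "scf", "normal"),
    model_spec("1_4", "MN", "bernoulli_logit", "scf", "none"),
    model_spec("1_5", "MN", "bernoulli_logit", full, "student_t"),
    model_spec("1_6", "MN", "bernoulli_logit", "scf", "student_t"))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Canonical registry of the eight interphase-duration model structures
#'
#' Six log-normal structures mirror the MN grid with `micro` (the MN
#' effect) always present: the full confounder set
#' micro + scf + rnf + stg + sis2_3 or micro alone, each with no, normal
#' or Student-t lineage effects and condition-specific sigma. `2_2` is the
#' full-confounder non-hierarchical model. Two further structures,
#' `2_2_exp` and `2_2_gamma`, keep the `2_2` linear predictor but swap the
#' likelihood for the exponential and gamma distributions (both
#' parameterized so that the mean is `exp(mu_n)`).
#'
#' @return Named list of eight `model_spec` objects.
#' @export
duration_model_registry <- function() {
  full <- c("micro", "scf", "rnf", "stg", "sis2_3")
  specs <- list(
    model_spec("2_1", "interphase_duration", "lognormal", full, "normal",
               "by_condition"),
    model_spec("2_2", "interphase_duration", "lognormal", full, "none",
               "by_condition"),
    model_spec("2_3", "interphase_duration", "lognormal", "micro", "normal",
               "by_condition"),
    model_spec("2_4", "interphase_duration", "lognormal", "micro", "none",
               "by_condition"),
    model_spec("2_5", "interphase_duration", "lognormal", full, "student_t",
               "by_condition"),
    model_spec("2_6", "interphase_duration", "lognormal", "micro",
               "student_t", "by_condition"),
    model_spec("2_2_exp", "interphase_duration", "exponential", full, "none",
               "none"),
    model_spec("2_2_gamma", "interphase_duration", "gamma", full, "none",
               "by_condition"))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Read / write a model specification as JSON
#'
#' @param path JSON file path.
#' @export
read_model_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(raw$name, raw$response, raw$likelihood,
             raw$terms %||% character(), raw$lineage_effect,
             raw$sigma_grouping, raw$student_df %||% 4)
}

#' @rdname read_model_spec
#' @param spec A `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# linear predictor for one parameter set (list) on model data
linear_predictor <- function(spec, params, data) {
  eta <- rep(params$b, data$n)
  for (tm in spec$terms) {
    eta <- eta + params[[tm]] * data[[.term_cols[[tm]]]]
  }
  if (spec$lineage_effect != "none") {
    lin <- params$lin
    if (length(lin) != length(data$lineage_ids)) {
      stop("shape error: lineage-effect vector has length ", length(lin),
           ", expected ", length(data$lineage_ids), call. = FALSE)
    }
    eta <- eta + lin[data$lineage]
  }
  eta
}

# per-record scale vector (sigma or gamma shape) for a parameter set
scale_vector <- function(spec, params, data) {
  switch(spec$sigma_grouping,
         by_condition = {
           s <- params$sigma
           if (length(s) != length(data$condition_labels)) {
             stop("shape error: expected ", length(data$condition_labels),
                  " scale parameters, got ", length(s), call. = FALSE)
           }
           s[data$condition]
         },
         shared = rep(params$sigma[1], data$n),
         none = NULL)
}

#' Pointwise log-likelihood of a parameter set
#'
#' Evaluates the log-density of every record under one parameter set. For
#' the MN response this is the Bernoulli-logit likelihood
#' `log Bernoulli(MN_n | inv_logit(eta_n))`; for durations it is
#' log-normal (`mu_n` the log-median, sigma possibly condition-specific),
#' exponential (rate `exp(-mu_n)`, mean `exp(mu_n)`) or gamma (shape
#' `alpha_c`, rate `alpha_c / exp(mu_n)`, mean `exp(mu_n)`). Records with
#' missing durations contribute 0 to duration likelihoods.
#'
#' @param spec A `model_spec`.
#' @param params Named list: `b`, one entry per active term, `sigma`
#'   (scale vector/scalar, or gamma shape) where applicable, `lin` for
#'   hierarchical specs.
#' @param data A `lineage_modeldata` from [design_matrix()].
#' @return Numeric vector of `data$n` log-densities.
#' @export
pointwise_loglik <- function(spec, params, data) {
  eta <- linear_predictor(spec, params, data)
  if (spec$likelihood == "bernoulli_logit") {
    return(data$MN * eta - log1p_exp(eta))
  }
  y <- data$duration
  obs <- data$duration_obs
  if (any(obs & y <= 0)) {
    stop("domain error: non-positive duration in data", call. = FALSE)
  }
  ll <- numeric(data$n)
  sc <- scale_vector(spec, params, data)
  yo <- y[obs]; mo <- eta[obs]
  ll[obs] <- switch(spec$likelihood,
    lognormal = stats::dlnorm(yo, meanlog = mo, sdlog = sc[obs], log = TRUE),
    exponential = -mo - yo * exp(-mo),
    gamma = stats::dgamma(yo, shape = sc[obs], rate = sc[obs] * exp(-mo),
                          log = TRUE))
  ll
}
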
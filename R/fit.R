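# Posterior sampling for any model_spec via adaptive random-walk
# Metropolis-within-Gibbs. Scalar parameters (bias, coefficients, log
# scales, log hierarchical scale) get individually tuned Gaussian
# random-walk updates; lineage random intercepts are conditionally
# independent given everything else and are updated as one vectorized
# block with per-lineage proposal scales and per-lineage accept/reject.
# Proposal scales adapt toward ~0.44 acceptance during warmup only, so
# the retained draws form a valid Markov chain.

#' Fit a lineage model by MCMC
#'
#' Draws from the posterior of a [model_spec()] given per-cell-cycle data.
#' Default priors are weakly informative: Normal(0, 10) on the bias and
#' coefficients, half-Normal(0, 5) on scale parameters (log-normal sigma,
#' gamma shape) and on the hierarchical lineage-effect scale. The
#' pointwise log-likelihood matrix needed for WAIC is computed at every
#' retained draw with [pointwise_loglik()]'s likelihoods; for duration
#' models the matrix covers only records with an observed interphase
#' duration. Fits are exactly reproducible given `seed`.
#'
#' @param spec A `model_spec`, e.g. `mn_model_registry()[["1_4"]]`.
#' @param data A `lineage_data` data.frame or a `lineage_modeldata` from
#'   [design_matrix()].
#' @param chains Number of chains (default 4).
#' @param iterations Iterations per chain including warmup (default 2000).
#' @param warmup Warmup (adaptation) iterations discarded per chain
#'   (default 1000).
#' @param seed Integer seed controlling all chains.
#' @param priors Named list overriding `coef_sd` (10), `scale_sd` (5),
#'   `tau_sd` (5).
#' @return An object of class `lineage_fit`: retained draws
#'   (`$draws`, total draws x parameters, with `$chain_id`), the pointwise
#'   log-likelihood matrix (`$loglik`), parameter names, sampler metadata,
#'   split-R-hat values and any convergence warnings. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`, `waic`.
#' @examples
#' d <- simulate_lineages(sim_params(n_lineages = 3), seed = 1)
#' f <- fit_lineage_model(mn_model_registry()[["1_4"]], d,
#'                        chains = 2, iterations = 400, warmup = 200)
#' summary(f)
#' @export
fit_lineage_model <- function(spec, data, chains = 4, iterations = 2000,
                              warmup = 1000, seed = 1, priors = list()) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(data, "lineage_data") ||
      (is.data.frame(data) && !inherits(data, "lineage_modeldata"))) {
    data <- design_matrix(data)
  }
  if (warmup >= iterations) stop("warmup must be < iterations", call. = FALSE)
  pr <- list(coef_sd = 10, scale_sd = 5, tau_sd = 5)
  pr[names(priors)] <- priors
  env <- build_fit_env(spec, data)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  chain_draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch], kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    res <- run_chain(env, spec, pr, iterations, warmup)
    chain_draws[[ch]] <- res$draws
    accept[ch] <- res$accept
  }
  draws <- do.call(rbind, chain_draws)
  if (any(!is.finite(draws))) stop("sampling error: non-finite draws", call. = FALSE)
  chain_id <- rep(seq_len(chains), each = iterations - warmup)
  rh <- rhat(draws, chain_id)
  warn <- character(0)
  core <- !grepl("^lin\\[", colnames(draws))
  if (any(rh[core] > 1.05, na.rm = TRUE)) {
    warn <- sprintf("convergence warning: split-R-hat > 1.05 for %s",
                    paste(names(which(rh[core] > 1.05)), collapse = ", "))
    warning(warn, call. = FALSE)
  }
  ll <- loglik_matrix(spec, draws, env)
  structure(list(spec = spec, data = data, draws = draws,
                 chain_id = chain_id, loglik = ll,
                 par_names = colnames(draws), rhat = rh,
                 accept_rate = mean(accept),
                 convergence_warnings = warn,
                 config = list(chains = chains, iterations = iterations,
                               warmup = warmup, seed = seed, priors = pr)),
            class = "lineage_fit")
}

# Precompute everything the samplers need: response, covariate matrix on
# the fitted observation set, condition/lineage indices, scale-group count.
build_fit_env <- function(spec, data) {
  k_terms <- spec$terms
  if (spec$response == "MN") {
    obs <- rep(TRUE, data$n)
    y <- data$MN
  } else {
    obs <- data$duration_obs
    y <- data$duration[obs]
    if (any(y <= 0)) stop("domain error: non-positive duration", call. = FALSE)
  }
  X <- cbind(b = rep(1, sum(obs)))
  for (tm in k_terms) X <- cbind(X, data[[.term_cols[[tm]]]][obs])
  colnames(X) <- c("b", k_terms)
  G <- switch(spec$sigma_grouping, by_condition = length(data$condition_labels),
              shared = 1L, none = 0L)
  list(spec = spec, y = y, logy = if (spec$response != "MN") log(y) else NULL,
       X = X, n = sum(obs), obs = obs,
       cond = if (G > 1L) data$condition[obs] else rep(1L, sum(obs)),
       G = G,
       lineage = data$lineage[obs], L = length(data$lineage_ids),
       condition_labels = data$condition_labels)
}

# total log-likelihood given linear predictor eta and scale vector (per group)
loglik_sum <- function(env, eta, scales) {
  switch(env$spec$likelihood,
         bernoulli_logit = sum(env$y * eta) - sum(log1p_exp(eta)),
         lognormal = {
           sv <- scales[env$cond]
           r <- env$logy - eta
           -sum(env$logy) - sum(log(sv)) - 0.5 * env$n * log(2 * pi) -
             sum(r * r / (2 * sv * sv))
         },
         exponential = sum(-eta - env$y * exp(-eta)),
         gamma = {
           av <- scales[env$cond]
           sum(av * log(av) - av * eta - lgamma(av) +
                 (av - 1) * env$logy - av * env$y * exp(-eta))
         })
}

# pointwise log-likelihood (on the fitted observation set) for lin updates
loglik_pointwise_env <- function(env, eta, scales) {
  switch(env$spec$likelihood,
         bernoulli_logit = env$y * eta - log1p_exp(eta),
         lognormal = {
           sv <- scales[env$cond]
           r <- env$logy - eta
           -env$logy - log(sv) - 0.5 * log(2 * pi) - r * r / (2 * sv * sv)
         },
         exponential = -eta - env$y * exp(-eta),
         gamma = {
           av <- scales[env$cond]
           av * log(av) - av * eta - lgamma(av) + (av - 1) * env$logy -
             av * env$y * exp(-eta)
         })
}

lin_prior <- function(lin, tau, spec) {
  if (spec$lineage_effect == "normal") {
    stats::dnorm(lin, 0, tau, log = TRUE)
  } else {
    stats::dt(lin / tau, df = spec$student_df, log = TRUE) - log(tau)
  }
}

run_chain <- function(env, spec, pr, iterations, warmup) {
  k <- ncol(env$X)
  G <- env$G
  hier <- spec$lineage_effect != "none"
  L <- if (hier) env$L else 0L

  # data-informed initial values, jittered per chain
  beta <- numeric(k)
  if (env$n > 0L) {
    beta[1] <- if (spec$response == "MN") {
      logit(min(max(mean(env$y), 1e-3), 1 - 1e-3))
    } else {
      mean(env$logy)
    }
  }
  beta <- beta + stats::rnorm(k, 0, 0.1)
  log_scale <- if (G > 0) {
    s0 <- stats::sd(env$logy)
    if (!is.finite(s0) || s0 < 0.05) s0 <- 0.05
    init <- if (spec$likelihood == "gamma") log(2) else log(s0)
    rep(init, G) + stats::rnorm(G, 0, 0.05)
  } else numeric(0)
  lin <- numeric(L)
  log_tau <- if (hier) log(0.5) else numeric(0)

  eta <- drop(env$X %*% beta) + if (hier) lin[env$lineage] else 0
  scales <- exp(log_scale)
  cur_ll <- loglik_sum(env, eta, scales)

  s_beta <- rep(0.1, k); s_scale <- rep(0.2, G)
  s_lin <- rep(0.3, L); s_tau <- 0.2
  acc_beta <- numeric(k); acc_scale <- numeric(G)
  acc_lin <- numeric(L); acc_tau <- 0
  n_batch <- 0L

  keep <- iterations - warmup
  P <- k + G + L + (if (hier) 1L else 0L)
  draws <- matrix(NA_real_, keep, P)
  acc_total <- 0; prop_total <- 0

  for (it in seq_len(iterations)) {
    # coefficient / bias updates
    for (j in seq_len(k)) {
      d <- stats::rnorm(1, 0, s_beta[j])
      eta_p <- eta + d * env$X[, j]
      ll_p <- loglik_sum(env, eta_p, scales)
      lr <- ll_p - cur_ll +
        stats::dnorm(beta[j] + d, 0, pr$coef_sd, log = TRUE) -
        stats::dnorm(beta[j], 0, pr$coef_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta[j] <- beta[j] + d; eta <- eta_p; cur_ll <- ll_p
        acc_beta[j] <- acc_beta[j] + 1; acc_total <- acc_total + 1
      }
      prop_total <- prop_total + 1
    }
    # scale updates (log scale with half-normal prior + Jacobian)
    for (g in seq_len(G)) {
      d <- stats::rnorm(1, 0, s_scale[g])
      ls_p <- log_scale; ls_p[g] <- ls_p[g] + d
      sc_p <- exp(ls_p)
      ll_p <- loglik_sum(env, eta, sc_p)
      lr <- ll_p - cur_ll +
        (-sc_p[g]^2 + scales[g]^2) / (2 * pr$scale_sd^2) + d
      if (log(stats::runif(1)) < lr) {
        log_scale <- ls_p; scales <- sc_p; cur_ll <- ll_p
        acc_scale[g] <- acc_scale[g] + 1; acc_total <- acc_total + 1
      }
      prop_total <- prop_total + 1
    }
    if (hier) {
      # lineage effects: conditionally independent given the rest, so one
      # vectorized proposal with per-lineage accept/reject is exact
      tau <- exp(log_tau)
      d <- stats::rnorm(L, 0, s_lin)
      lin_p <- lin + d
      eta_p <- eta + d[env$lineage]
      pw_cur <- loglik_pointwise_env(env, eta, scales)
      pw_p <- loglik_pointwise_env(env, eta_p, scales)
      by_cur <- rep(0, L); by_p <- rep(0, L)
      agg_c <- rowsum(pw_cur, env$lineage)
      agg_p <- rowsum(pw_p, env$lineage)
      idx <- as.integer(rownames(agg_c))
      by_cur[idx] <- agg_c; by_p[idx] <- agg_p
      lr <- (by_p - by_cur) + lin_prior(lin_p, tau, spec) -
        lin_prior(lin, tau, spec)
      acc <- log(stats::runif(L)) < lr
      lin[acc] <- lin_p[acc]
      acc_lin[acc] <- acc_lin[acc] + 1
      eta <- drop(env$X %*% beta) + lin[env$lineage]
      cur_ll <- loglik_sum(env, eta, scales)
      # hierarchical scale tau
      d <- stats::rnorm(1, 0, s_tau)
      lt_p <- log_tau + d
      lr <- sum(lin_prior(lin, exp(lt_p), spec)) -
        sum(lin_prior(lin, tau, spec)) +
        (-exp(lt_p)^2 + tau^2) / (2 * pr$tau_sd^2) + d
      if (log(stats::runif(1)) < lr) {
        log_tau <- lt_p
        acc_tau <- acc_tau + 1
      }
    }
    n_batch <- n_batch + 1L
    if (it <= warmup && n_batch == 50L) {
      tune <- function(s, acc) pmin(5, pmax(1e-3, s * exp(acc / 50 - 0.44)))
      s_beta <- tune(s_beta, acc_beta); s_scale <- tune(s_scale, acc_scale)
      s_lin <- tune(s_lin, acc_lin); s_tau <- tune(s_tau, acc_tau)
      acc_beta[] <- 0; acc_scale[] <- 0; acc_lin[] <- 0; acc_tau <- 0
      n_batch <- 0L
    }
    if (it > warmup) {
      draws[it - warmup, ] <- c(beta, exp(log_scale), lin,
                                if (hier) exp(log_tau))
    }
  }
  scale_pref <- if (spec$likelihood == "gamma") "alpha" else "sigma"
  scale_names <- if (G > 1L) {
    paste0(scale_pref, "[", env$condition_labels, "]")
  } else if (G == 1L) scale_pref else character(0)
  colnames(draws) <- c(colnames(env$X), scale_names,
                       if (hier) paste0("lin[", seq_len(L), "]"),
                       if (hier) "tau")
  list(draws = draws, accept = acc_total / max(prop_total, 1))
}

# pointwise log-likelihood matrix (draws x fitted observations),
# vectorized over draws
loglik_matrix <- function(spec, draws, env) {
  k <- ncol(env$X)
  beta <- draws[, seq_len(k), drop = FALSE]
  eta <- env$X %*% t(beta)                      # n x S
  if (spec$lineage_effect != "none") {
    lin_cols <- grep("^lin\\[", colnames(draws))
    eta <- eta + t(draws[, lin_cols, drop = FALSE])[env$lineage, , drop = FALSE]
  }
  S <- nrow(draws)
  if (spec$likelihood == "bernoulli_logit") {
    ll <- env$y * eta - log1p_exp(eta)
    return(t(ll))
  }
  if (env$G > 0) {
    sc_cols <- grep("^(sigma|alpha)", colnames(draws))
    sc <- t(draws[, sc_cols, drop = FALSE])[env$cond, , drop = FALSE]  # n x S
  }
  ll <- switch(spec$likelihood,
    lognormal = {
      r <- env$logy - eta
      -env$logy - log(sc) - 0.5 * log(2 * pi) - r * r / (2 * sc * sc)
    },
    exponential = -eta - env$y * exp(-eta),
    gamma = sc * log(sc) - sc * eta - lgamma(sc) + (sc - 1) * env$logy -
      sc * env$y * exp(-eta))
  t(ll)
}

#' @export
print.lineage_fit <- function(x, ...) {
  cat(sprintf("Bayesian lineage model fit: '%s' (%s, %s)\n", x$spec$name,
              x$spec$response, x$spec$likelihood))
  cat(sprintf("  %d chains x %d iterations (%d warmup); %d retained draws; %d observations\n",
              x$config$chains, x$config$iterations, x$config$warmup,
              nrow(x$draws), ncol(x$loglik)))
  core <- !grepl("^lin\\[", x$par_names)
  cat(sprintf("  mean acceptance %.2f; max split-R-hat (core params) %.3f\n",
              x$accept_rate, max(x$rhat[core], na.rm = TRUE)))
  if (length(x$convergence_warnings) > 0) {
    cat("  !", x$convergence_warnings, "\n")
  }
  invisible(x)
}

#' Posterior medians of model parameters
#'
#' @param object A `lineage_fit`.
#' @param ... Unused.
#' @return Named numeric vector of posterior medians.
#' @export
coef.lineage_fit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' Posterior summary of a lineage model fit
#'
#' Empirical quantiles (linear interpolation) of every parameter: median,
#' 50\% credible interval (25/75 percentiles), 95\% credible interval
#' (2.5/97.5 percentiles), plus split-R-hat and a crude effective sample
#' size.
#'
#' @param object A `lineage_fit`.
#' @param pars Optional character vector of parameter names to keep.
#' @param ... Unused.
#' @return A data.frame of class `summary.lineage_fit`.
#' @export
summary.lineage_fit <- function(object, pars = NULL, ...) {
  out <- summarize_draws(object$draws, object$chain_id)
  if (!is.null(pars)) out <- out[out$parameter %in% pars, , drop = FALSE]
  class(out) <- c("summary.lineage_fit", "data.frame")
  out
}

#' @export
print.summary.lineage_fit <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Plot posterior credible intervals
#'
#' Draws the Fig-5F-style interval plot: posterior median (point), 50\%
#' credible interval (thick bar) and 95\% credible interval (thin bar)
#' for each (non-lineage) parameter.
#'
#' @param x A `lineage_fit`.
#' @param pars Parameters to show (default: all except lineage effects).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lineage_fit <- function(x, pars = NULL, ...) {
  s <- summary(x)
  if (is.null(pars)) pars <- s$parameter[!grepl("^lin\\[", s$parameter)]
  s <- s[s$parameter %in% pars, , drop = FALSE]
  n <- nrow(s)
  yy <- rev(seq_len(n))
  graphics::plot(s$median, yy, xlim = range(s$q2.5, s$q97.5), pch = 16,
                 yaxt = "n", xlab = "posterior", ylab = "", ...)
  graphics::axis(2, at = yy, labels = s$parameter, las = 1)
  graphics::segments(s$q2.5, yy, s$q97.5, yy, lwd = 1)
  graphics::segments(s$q25, yy, s$q75, yy, lwd = 3, col = "red")
  graphics::points(s$median, yy, pch = 16)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
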
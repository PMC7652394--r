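# Branching-process generator for tidy live-cell lineage datasets.
#
# Within each cell cycle the causal order is MN first, then interphase
# duration given MN (micronuclei can lengthen the cycle, not the reverse);
# experimental covariates enter both linear predictors. All times are kept
# as integer frame counts internally and converted to hours on emission,
# so every emitted time is an exact multiple of the frame interval.

#' Default generator parameters
#'
#' Returns the documented default `sim_params`: per-cycle MN probability
#' follows a logit-linear model with baseline `inv_logit(b) = 0.0102` and
#' SCF coefficient 2.44 (so the per-cycle MN probability in SCF-positive
#' cells is `inv_logit(b + 2.44)` ~ 0.106); the MN effect on log interphase
#' duration is `micro = 0.820`; the remaining covariate coefficients
#' default to 0 (minor or no effects); lineage-effect standard deviations
#' default to 0 so the non-hierarchical models are correctly specified
#' (set them > 0 to exercise hierarchical fits).
#'
#' Movie length is 66 h at a 10-min frame interval. Baseline interphase
#' log-median is `log(20)` (a 20-h cell cycle, typical of the HCT116
#' background) with condition-specific log-scale sigma defaulting to 0.3;
#' mitosis has log-median `log(0.5)` (30 min) and sd 0.2. Sporadic event
#' probabilities per cycle: death 0.01, sister fusion 0.005, bi/multi-
#' nucleation 0.005, tripolar mitosis 0.003, furrow regression 0.005.
#' The fading rule (marker loss in one daughter of the first division of
#' SIS2-3 sgF11 1+x lineages) is on by default.
#'
#' @param ... Named overrides for any top-level field, e.g.
#'   `sim_params(n_lineages = 10)` or
#'   `sim_params(mn = list(b = -4, scf = 1, rnf = 0, stg = 0, sis2_3 = 0,
#'   lineage_sd = 0))`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_lineages = 50,          # lineages per condition
    movie_length = 66,        # hours
    frame_interval = 10,      # minutes (6-12 typical)
    onset_window = 22,        # hours; 1+x founders turn mCitrine+ in [0, window]
    mn = list(b = logit(0.0102), scf = 2.44, rnf = 0, stg = 0,
              sis2_3 = 0, lineage_sd = 0),
    dur = list(b = log(20), micro = 0.820, scf = 0, rnf = 0, stg = 0,
               sis2_3 = 0, lineage_sd = 0),
    sigma = stats::setNames(rep(0.3, 6), condition_table()$condition),
    mitosis = list(log_median = log(0.5), sd = 0.2),
    p_death = 0.01, p_fusion = 0.005, p_bi_multi = 0.005,
    p_tripolar = 0.003, p_regression = 0.005,
    fading = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L) {
    stop("unknown sim_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  probs <- c(p$p_death, p$p_fusion, p$p_bi_multi, p$p_tripolar,
             p$p_regression)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("parameter error: event probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(p$sigma <= 0)) stop("parameter error: sigma must be > 0", call. = FALSE)
  if (p$movie_length <= 0) stop("parameter error: movie_length must be > 0", call. = FALSE)
  if (p$frame_interval <= 0) stop("parameter error: frame_interval must be > 0", call. = FALSE)
  invisible(p)
}

#' Read / write generator parameters as JSON
#'
#' @param path JSON file path.
#' @return For `read_sim_params`, a `sim_params` object.
#' @export
read_sim_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- names(raw$sigma) %||% condition_table()$condition
  raw$sigma <- stats::setNames(as.numeric(raw$sigma), nm)
  do.call(sim_params, raw)
}

#' @rdname read_sim_params
#' @param params A `sim_params` object.
#' @export
write_sim_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a tidy lineage dataset
#'
#' Runs the branching process for `n_lineages` founders in each of the six
#' experimental conditions and emits a `lineage_data` data.frame in the
#' canonical tidy schema. The same `(params, seed)` pair always produces an
#' identical dataset.
#'
#' Per lineage: the founder appears at movie start (N+x) or at a uniform
#' random mCitrine-onset time (1+x); root-cell interphases are partial
#' (onset falls mid-cycle) and are therefore emitted without an
#' `interphase_duration`. Each subsequent cell cycle draws its MN status
#' from the logit-linear model, then its interphase duration from a
#' log-normal whose log-median depends on MN and the condition covariates,
#' then a mitotic duration; divisions spawn two daughters (three if
#' tripolar) until the movie ends. Cycles truncated by movie end are
#' emitted as censored. Sporadic death, sister-cell fusion, bi/multi-
#' nucleation and furrow regression are drawn per cycle, and in SIS2-3
#' sgF11 1+x lineages exactly one daughter of the first division loses the
#' mCitrine marker when the fading rule is on.
#'
#' @param params A `sim_params` object (see [sim_params()]).
#' @param seed Integer RNG seed.
#' @return A `lineage_data` data.frame (possibly 0-row when
#'   `n_lineages <= 0`).
#' @export
simulate_lineages <- function(params = sim_params(), seed = 1) {
  validate_sim_params(params)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  conds <- condition_table()
  frame_h <- params$frame_interval / 60
  movie_f <- floor(params$movie_length / frame_h)
  rows <- list()
  if (params$n_lineages > 0) {
    for (ci in seq_len(nrow(conds))) {
      for (li in seq_len(params$n_lineages)) {
        lid <- sprintf("%s.%s.%s.L%03d", conds$cell_line[ci],
                       conds$treatment[ci],
                       sub("\\+", "", conds$stage[ci]), li)
        rows[[length(rows) + 1L]] <-
          simulate_one_lineage(lid, conds[ci, ], params, frame_h, movie_f)
      }
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else empty_tidy()
  rownames(df) <- NULL
  class(df) <- c("lineage_data", "data.frame")
  attr(df, "provenance") <- list(source = "simulate_lineages", seed = seed)
  df
}

empty_tidy <- function() {
  df <- data.frame(lineage_id = character(), cell_id = character(),
                   parent_id = character(), cell_line = character(),
                   treatment = character(), stage = character(),
                   t_birth = numeric(), t_nebd = numeric(),
                   t_division = numeric(), interphase_duration = numeric(),
                   mitotic_duration = numeric(), micronuclei = logical(),
                   bi_multi_nuclei = logical(), death = logical(),
                   fading = logical(), tripolar = logical(),
                   regression = logical(), fused_with = character(),
                   censored = logical(), stringsAsFactors = FALSE)
  df
}

simulate_one_lineage <- function(lid, cond, params, frame_h, movie_f) {
  scf <- as.integer(cond$cell_line == "SIS2-3" & cond$treatment == "sgF11")
  rnf <- as.integer(cond$cell_line == "CTRL48" & cond$treatment == "sgF11")
  sis <- as.integer(cond$cell_line == "SIS2-3")
  stg <- as.integer(cond$stage == "N+x")
  clab <- condition_label(cond$cell_line, cond$treatment, cond$stage)
  eta_mn <- params$mn$b + params$mn$scf * scf + params$mn$rnf * rnf +
    params$mn$stg * stg + params$mn$sis2_3 * sis
  mu_base <- params$dur$b + params$dur$scf * scf + params$dur$rnf * rnf +
    params$dur$stg * stg + params$dur$sis2_3 * sis
  sigma <- params$sigma[[clab]]
  if (params$mn$lineage_sd > 0) eta_mn <- eta_mn + stats::rnorm(1, 0, params$mn$lineage_sd)
  if (params$dur$lineage_sd > 0) mu_base <- mu_base + stats::rnorm(1, 0, params$dur$lineage_sd)

  onset_f <- if (cond$stage == "1+x") {
    sample.int(max(1L, floor(params$onset_window / frame_h)), 1L) - 1L
  } else 0L
  fade_at_first_division <- params$fading && scf == 1L && cond$stage == "1+x"

  draw_frames <- function(meanlog, sdlog) {
    max(1L, as.integer(round(stats::rlnorm(1, meanlog, sdlog) / frame_h)))
  }

  recs <- list()
  emit <- function(cell_id, parent_id, t_birth, t_nebd, t_division,
                   interphase, mitotic, mn, bi, death, fading, tripolar,
                   regression, fused_with, censored) {
    recs[[length(recs) + 1L]] <<- list(
      cell_id = cell_id, parent_id = parent_id,
      t_birth = as.numeric(t_birth) * frame_h,
      t_nebd = as.numeric(t_nebd) * frame_h,
      t_division = as.numeric(t_division) * frame_h,
      interphase_duration = as.numeric(interphase) * frame_h,
      mitotic_duration = as.numeric(mitotic) * frame_h,
      micronuclei = mn, bi_multi_nuclei = bi, death = death,
      fading = fading, tripolar = tripolar, regression = regression,
      fused_with = fused_with, censored = censored)
  }

  # queue of cells awaiting simulation: birth frame + path label
  queue <- list(list(id = "a", parent = "", birth = onset_f, root = TRUE))
  first_division_done <- FALSE
  while (length(queue) > 0L) {
    cell <- queue[[1L]]; queue <- queue[-1L]
    if (cell$fade %||% FALSE) {
      # marker loss: the cell exists but is no longer observable
      emit(cell$id, cell$parent, cell$birth, NA, NA, NA, NA,
           mn = FALSE, bi = FALSE, death = FALSE, fading = TRUE,
           tripolar = FALSE, regression = FALSE, fused_with = "",
           censored = TRUE)
      next
    }
    mn <- stats::runif(1) < inv_logit(eta_mn)
    bi <- (cell$binucleate %||% FALSE) || stats::runif(1) < params$p_bi_multi
    if (stats::runif(1) < params$p_death) {
      emit(cell$id, cell$parent, cell$birth, NA, NA, NA, NA,
           mn = mn, bi = bi, death = TRUE, fading = FALSE,
           tripolar = FALSE, regression = FALSE, fused_with = "",
           censored = FALSE)
      next
    }
    int_f <- draw_frames(mu_base + params$dur$micro * mn, sigma)
    if (cell$root) {
      # onset falls mid-cycle: only the residual of the interphase is seen
      int_obs <- NA_integer_
      resid_f <- max(1L, as.integer(round(int_f * stats::runif(1))))
      nebd <- cell$birth + resid_f
    } else {
      int_obs <- int_f
      nebd <- cell$birth + int_f
    }
    if (nebd > movie_f) {
      emit(cell$id, cell$parent, cell$birth, NA, NA, NA, NA,
           mn = mn, bi = bi, death = FALSE, fading = FALSE,
           tripolar = FALSE, regression = FALSE, fused_with = "",
           censored = TRUE)
      next
    }
    mit_f <- draw_frames(params$mitosis$log_median, params$mitosis$sd)
    division <- nebd + mit_f
    if (division > movie_f) {
      emit(cell$id, cell$parent, cell$birth, nebd, NA,
           if (cell$root) NA else int_obs, NA,
           mn = mn, bi = bi, death = FALSE, fading = FALSE,
           tripolar = FALSE, regression = FALSE, fused_with = "",
           censored = TRUE)
      next
    }
    tripolar <- stats::runif(1) < params$p_tripolar
    regression <- !tripolar && stats::runif(1) < params$p_regression
    emit(cell$id, cell$parent, cell$birth, nebd, division,
         if (cell$root) NA else int_obs, mit_f,
         mn = mn, bi = bi, death = FALSE, fading = FALSE,
         tripolar = tripolar, regression = regression, fused_with = "",
         censored = FALSE)
    if (regression) {
      # cytokinesis failure: the furrow regresses into one binucleate cell
      queue[[length(queue) + 1L]] <- list(id = paste0(cell$id, "a"),
                                          parent = cell$id,
                                          birth = division, root = FALSE,
                                          binucleate = TRUE)
      next
    }
    n_daughters <- if (tripolar) 3L else 2L
    labels <- paste0(cell$id, letters[seq_len(n_daughters)])
    fade_daughter <- 0L
    if (fade_at_first_division && !first_division_done) {
      fade_daughter <- sample.int(n_daughters, 1L)
    }
    fuse <- !tripolar && stats::runif(1) < params$p_fusion
    if (fuse && fade_daughter == 0L) {
      # sister-cell fusion: both daughters merge; observation of the pair
      # ends at the fusion (the merged cell is not tracked further)
      for (k in 1:2) {
        emit(labels[k], cell$id, division, NA, NA, NA, NA,
             mn = FALSE, bi = FALSE, death = FALSE, fading = FALSE,
             tripolar = FALSE, regression = FALSE,
             fused_with = labels[3L - k], censored = TRUE)
      }
    } else {
      for (k in seq_len(n_daughters)) {
        queue[[length(queue) + 1L]] <-
          list(id = labels[k], parent = cell$id, birth = division,
               root = FALSE, fade = k == fade_daughter)
      }
    }
    if (!first_division_done) first_division_done <- TRUE
  }
  fld <- function(name) unlist(lapply(recs, `[[`, name), use.names = FALSE)
  out <- data.frame(
    lineage_id = lid, cell_id = fld("cell_id"), parent_id = fld("parent_id"),
    cell_line = cond$cell_line, treatment = cond$treatment,
    stage = cond$stage, t_birth = fld("t_birth"), t_nebd = fld("t_nebd"),
    t_division = fld("t_division"),
    interphase_duration = fld("interphase_duration"),
    mitotic_duration = fld("mitotic_duration"),
    micronuclei = fld("micronuclei"), bi_multi_nuclei = fld("bi_multi_nuclei"),
    death = fld("death"), fading = fld("fading"), tripolar = fld("tripolar"),
    regression = fld("regression"), fused_with = fld("fused_with"),
    censored = fld("censored"), stringsAsFactors = FALSE)
  out[order(out$cell_id), , drop = FALSE]
}
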
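# End-to-end orchestration: simulate (or load) -> validate -> fit model
# registries -> WAIC ranking -> posterior predictions -> sister pairs ->
# lineage-tree gallery, with a JSON manifest recording seeds, priors and
# output digests so a run can be reproduced exactly.

#' Run the full lineage-analysis pipeline
#'
#' Executes every stage on either a tidy input file or a simulated
#' dataset and writes all tables (TSV + JSON), figures (SVG) and a run
#' manifest into `out_dir`. Identical `config` (including seed) produces
#' byte-identical outputs.
#'
#' @param config A list with entries:
#'   \describe{
#'     \item{input}{path to a tidy CSV, or `NULL` to simulate;}
#'     \item{sim}{a [sim_params()] object (used when `input` is `NULL`);}
#'     \item{mn_models, duration_models}{model names from the registries
#'       (defaults `c("1_4", "1_2")` and `c("2_2", "2_2_exp", "2_2_gamma")`);}
#'     \item{sampler}{list of `chains`, `iterations`, `warmup`, `priors`;}
#'     \item{seed}{integer master seed;}
#'     \item{out_dir}{output directory;}
#'     \item{render_trees}{logical, render the SVG gallery (default
#'       `FALSE`).}
#'   }
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required", call. = FALSE)
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sampler <- config$sampler %||% list()
  chains <- sampler$chains %||% 4L
  iterations <- sampler$iterations %||% 2000L
  warmup <- sampler$warmup %||% 1000L
  priors <- sampler$priors %||% list()
  mn_names <- config$mn_models %||% c("1_4", "1_2")
  dur_names <- config$duration_models %||% c("2_2", "2_2_exp", "2_2_gamma")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  data <- stage("load", {
    if (!is.null(config$input)) {
      read_tidy(config$input)
    } else {
      sim <- config$sim %||% sim_params()
      d <- simulate_lineages(sim, seed = seed)
      write_tidy(d, file.path(out_dir, "dataset.csv"))
      d
    }
  })
  report <- stage("validate", validate_lineages(data))
  write_validation_report(report, file.path(out_dir, "validation.json"))
  if (!report$ok) {
    stop("pipeline stage 'validate' failed: dataset has ",
         nrow(report$violations), " violation(s); see validation.json",
         call. = FALSE)
  }
  trees <- stage("trees", build_trees(data))
  md <- stage("design", design_matrix(data))

  pct <- stage("abnormalities", abnormality_percentages(trees))
  write_tsv_json(pct, file.path(out_dir, "abnormality_percentages"))

  mn_reg <- mn_model_registry()
  dur_reg <- duration_model_registry()
  fits <- list()
  stage("fit", {
    for (nm in mn_names) {
      fits[[nm]] <- fit_lineage_model(mn_reg[[nm]], md, chains = chains,
                                       iterations = iterations,
                                       warmup = warmup, seed = seed,
                                       priors = priors)
    }
    for (nm in dur_names) {
      fits[[nm]] <- fit_lineage_model(dur_reg[[nm]], md, chains = chains,
                                       iterations = iterations,
                                       warmup = warmup, seed = seed,
                                       priors = priors)
    }
  })
  summaries <- lapply(fits, function(f) as.data.frame(summary(f)))
  for (nm in names(summaries)) {
    write_tsv_json(summaries[[nm]],
                   file.path(out_dir, paste0("posterior_", nm)))
  }

  waic_tables <- stage("waic", {
    w_mn <- lapply(fits[mn_names], waic)
    w_dur <- lapply(fits[dur_names], waic)
    list(mn = rank_models(w_mn), duration = rank_models(w_dur))
  })
  write_tsv_json(waic_tables$mn, file.path(out_dir, "waic_mn"))
  write_tsv_json(waic_tables$duration, file.path(out_dir, "waic_duration"))

  preds <- stage("predict", {
    f_mn <- fits[[mn_names[1]]]
    fc <- mn_fold_change(f_mn, c(SCF = 1, SIS = 1), c(), seed = seed)
    f_dur <- fits[[dur_names[1]]]
    iqr_rows <- list()
    for (cond in condition_table()$condition) {
      parts <- strsplit(cond, ":", fixed = TRUE)[[1]]
      cv <- c(SCF = as.numeric(parts[1] == "SIS2-3" & parts[2] == "sgF11"),
              RNF = as.numeric(parts[1] == "CTRL48" & parts[2] == "sgF11"),
              SIS = as.numeric(parts[1] == "SIS2-3"),
              STG = as.numeric(parts[3] == "N+x"))
      for (mn in 0:1) {
        ps <- predictive_durations(f_dur, cv, mn_status = mn,
                                   condition = cond, m = 10000,
                                   seed = seed + mn)
        q <- duration_quartiles(ps)
        iqr_rows[[length(iqr_rows) + 1L]] <- data.frame(
          condition = cond, MN = mn, q25 = q$q25, q50 = q$q50,
          q75 = q$q75, iqr = q$iqr, stringsAsFactors = FALSE)
      }
    }
    list(fold_change = fc, iqr = do.call(rbind, iqr_rows))
  })
  write_tsv_json(preds$iqr, file.path(out_dir, "predicted_iqr"))
  jsonlite::write_json(list(ratio = preds$fold_change$ratio,
                            average_with = preds$fold_change$average_with,
                            average_without = preds$fold_change$average_without),
                       file.path(out_dir, "mn_fold_change.json"),
                       auto_unbox = TRUE, digits = NA)

  pair_out <- stage("pairs", {
    pairs <- find_matched_pairs(trees)
    if (length(pairs) > 0L) {
      cmp <- compare_pairs(pairs)
      test <- tryCatch(chisq_2x2(cmp$table), error = function(e) NULL)
      k <- sum(cmp$verdicts$verdict == "MN_plus_more")
      list(comparison = cmp, test = test,
           probability = event_probability(k, cmp$n_pairs))
    } else NULL
  })
  if (!is.null(pair_out)) {
    write_tsv_json(pair_out$comparison$verdicts,
                   file.path(out_dir, "sister_pairs"))
    jsonlite::write_json(
      list(table = pair_out$comparison$table, test = pair_out$test,
           probability = pair_out$probability$all),
      file.path(out_dir, "sister_pair_test.json"),
      auto_unbox = TRUE, digits = NA)
  }

  if (isTRUE(config$render_trees)) {
    stage("trees_svg", render_gallery(trees, file.path(out_dir, "trees")))
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = seed,
    config = list(input = config$input,
                  sim = if (is.null(config$input))
                    unclass(config$sim %||% sim_params()),
                  mn_models = mn_names, duration_models = dur_names,
                  sampler = list(chains = chains, iterations = iterations,
                                 warmup = warmup, priors = priors)),
    n_records = nrow(data), n_lineages = length(trees),
    digests = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv_json <- function(df, stem) {
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(df, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(stem)
}
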
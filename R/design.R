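#' Build model covariates from a tidy dataset
#'
#' Codes each cell-cycle record into the dummy variables used by the MN
#' and interphase-duration models:
#' \itemize{
#'   \item `SCF = 1` iff (SIS2-3, sgF11) — the cell may carry a sister
#'     chromatid fusion;
#'   \item `RNF = 1` iff (CTRL48, sgF11) — repair / no fusion;
#'   \item `SIS = 1` iff cell line SIS2-3 (cell-line effect);
#'   \item `STG = 1` iff stage N+x (baseline is 1+x);
#'   \item `MN` — the per-cycle micronucleus flag.
#' }
#' Lineage and condition indices are assigned deterministically in
#' lexicographic order. Censored interphases (no observed NEBD) are masked
#' out of duration fitting but keep their MN response.
#'
#' @param data A `lineage_data` data.frame.
#' @return A list of class `lineage_modeldata`: integer vectors `SCF`,
#'   `RNF`, `SIS`, `STG`, `MN`; `lineage` and `condition` index vectors
#'   with `lineage_ids` / `condition_labels` level tables; `duration`
#'   (hours, `NA` when unobserved); `duration_obs` logical mask; `n`
#'   record count.
#' @export
design_matrix <- function(data) {
  df <- as.data.frame(data)
  if (any(df$treatment == "mCit" & df$fading)) {
    i <- which(df$treatment == "mCit" & df$fading)[1]
    stop("consistency error: mock-treated (mCit) record with fading=TRUE at row ",
         i, call. = FALSE)
  }
  sis <- as.integer(df$cell_line == "SIS2-3")
  scf <- as.integer(sis == 1L & df$treatment == "sgF11")
  rnf <- as.integer(sis == 0L & df$treatment == "sgF11")
  stg <- as.integer(df$stage == "N+x")
  lin_levels <- sort(unique(df$lineage_id))
  cond <- condition_label(df$cell_line, df$treatment, df$stage)
  cond_levels <- condition_table()$condition
  cidx <- match(cond, cond_levels)
  if (anyNA(cidx)) {
    stop("unknown condition: ", cond[which(is.na(cidx))[1]], call. = FALSE)
  }
  # a record censored at mitosis still has an observed interphase; only
  # interphases with no observed NEBD are excluded from duration fitting
  dur <- df$interphase_duration
  dur[is.na(df$t_nebd)] <- NA_real_
  structure(list(
    SCF = scf, RNF = rnf, SIS = sis, STG = stg,
    MN = as.integer(df$micronuclei),
    lineage = match(df$lineage_id, lin_levels),
    lineage_ids = lin_levels,
    condition = cidx,
    condition_labels = cond_levels,
    duration = dur,
    duration_obs = !is.na(dur),
    n = nrow(df)),
    class = "lineage_modeldata")
}

#' @export
print.lineage_modeldata <- function(x, ...) {
  cat(sprintf("Model data: %d records, %d lineages, %d conditions\n",
              x$n, length(x$lineage_ids), length(unique(x$condition))))
  cat(sprintf("  MN events: %d (%.3f per cycle); observed durations: %d\n",
              sum(x$MN), mean(x$MN), sum(x$duration_obs)))
  invisible(x)
}
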
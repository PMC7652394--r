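# Hand-built fixtures used across test files. All datasets are constructed
# in code; nothing is read from disk except files the tests write first.

# one row of the canonical tidy schema with sensible defaults
tidy_row <- function(lineage_id = "L1", cell_id = "a", parent_id = "",
                     cell_line = "CTRL48", treatment = "mCit",
                     stage = "N+x", t_birth = 0, t_nebd = NA,
                     t_division = NA, interphase_duration = NA,
                     mitotic_duration = NA, micronuclei = FALSE,
                     bi_multi_nuclei = FALSE, death = FALSE,
                     fading = FALSE, tripolar = FALSE, regression = FALSE,
                     fused_with = "", censored = FALSE) {
  data.frame(lineage_id = lineage_id, cell_id = cell_id,
             parent_id = parent_id, cell_line = cell_line,
             treatment = treatment, stage = stage, t_birth = t_birth,
             t_nebd = as.numeric(t_nebd),
             t_division = as.numeric(t_division),
             interphase_duration = as.numeric(interphase_duration),
             mitotic_duration = as.numeric(mitotic_duration),
             micronuclei = micronuclei, bi_multi_nuclei = bi_multi_nuclei,
             death = death, fading = fading, tripolar = tripolar,
             regression = regression, fused_with = fused_with,
             censored = censored, stringsAsFactors = FALSE)
}

as_lineage_data <- function(df) {
  class(df) <- c("lineage_data", "data.frame")
  df
}

# root that divides once into two daughters
mini_division <- function(lineage_id = "L1", cell_line = "CTRL48",
                          treatment = "mCit", stage = "N+x",
                          mn_a = FALSE, mn_b = FALSE, ...) {
  as_lineage_data(rbind(
    tidy_row(lineage_id, "a", "", cell_line, treatment, stage,
             t_birth = 0, t_nebd = 10, t_division = 10.5,
             mitotic_duration = 0.5),
    tidy_row(lineage_id, "aa", "a", cell_line, treatment, stage,
             t_birth = 10.5, interphase_duration = NA, censored = TRUE,
             micronuclei = mn_a),
    tidy_row(lineage_id, "ab", "a", cell_line, treatment, stage,
             t_birth = 10.5, interphase_duration = NA, censored = TRUE,
             micronuclei = mn_b)))
}

# hand-made lineage_modeldata for direct likelihood / sampler tests
fake_modeldata <- function(MN, SCF = rep(0L, length(MN)),
                           RNF = rep(0L, length(MN)),
                           SIS = rep(0L, length(MN)),
                           STG = rep(0L, length(MN)),
                           duration = rep(NA_real_, length(MN)),
                           lineage = rep(1L, length(MN)),
                           condition = rep(1L, length(MN))) {
  structure(list(SCF = as.integer(SCF), RNF = as.integer(RNF),
                 SIS = as.integer(SIS), STG = as.integer(STG),
                 MN = as.integer(MN),
                 lineage = lineage,
                 lineage_ids = paste0("L", seq_len(if (length(lineage)) max(lineage) else 0L)),
                 condition = condition,
                 condition_labels = mnlineage::condition_table()$condition,
                 duration = duration, duration_obs = !is.na(duration),
                 n = length(MN)),
            class = "lineage_modeldata")
}

# degenerate "fit" with caller-chosen draws, for prediction arithmetic
fake_fit <- function(spec, draws) {
  structure(list(spec = spec, draws = draws,
                 par_names = colnames(draws)),
            class = "lineage_fit")
}
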
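# Canonical tidy schema for per-cell-cycle live-cell records.
#
# One row = one observed cell cycle of one mCitrine-positive cell. Times are
# hours from movie start (for lineage founders, mCitrine onset defines birth).
# Event flags are stored as 0/1 in files and as logical in R.

.tidy_char_cols <- c("lineage_id", "cell_id", "parent_id", "cell_line",
                     "treatment", "stage", "fused_with")
.tidy_num_cols  <- c("t_birth", "t_nebd", "t_division",
                     "interphase_duration", "mitotic_duration")
.tidy_flag_cols <- c("micronuclei", "bi_multi_nuclei", "death", "fading",
                     "tripolar", "regression", "censored")
.tidy_cols <- c("lineage_id", "cell_id", "parent_id", "cell_line",
                "treatment", "stage", "t_birth", "t_nebd", "t_division",
                "interphase_duration", "mitotic_duration", "micronuclei",
                "bi_multi_nuclei", "death", "fading", "tripolar",
                "regression", "fused_with", "censored")

.cell_lines <- c("CTRL48", "SIS2-3")
.treatments <- c("mCit", "sgF11")
.stages     <- c("1+x", "N+x")

#' Table of the six experimental conditions
#'
#' Conditions are the cross of cell line (CTRL48, SIS2-3), treatment
#' (mCit mock, CRISPR/Cas9 sgF11) and cell-cycle stage relative to
#' mCitrine onset (1+x: fluorescence arose during the movie; N+x: already
#' fluorescent at movie start). Mock-treated cells are always N+x, giving
#' six conditions rather than eight. Rows are in the canonical
#' (lexicographic) order used for condition indices.
#'
#' @return A data.frame with columns `cell_line`, `treatment`, `stage` and
#'   `condition` (the canonical label `cell_line:treatment:stage`).
#' @export
condition_table <- function() {
  grid <- expand.grid(stage = .stages, treatment = .treatments,
                      cell_line = .cell_lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("cell_line", "treatment", "stage")]
  grid <- grid[!(grid$treatment == "mCit" & grid$stage == "1+x"), ]
  lab <- paste(grid$cell_line, grid$treatment, grid$stage, sep = ":")
  grid <- grid[order(lab), ]
  grid$condition <- sort(lab)
  rownames(grid) <- NULL
  grid
}

condition_label <- function(cell_line, treatment, stage) {
  paste(cell_line, treatment, stage, sep = ":")
}

#' Read a tidy per-cell-cycle table
#'
#' Reads a delimited text file (CSV, header row) holding one row per
#' observed cell cycle and returns a validated `lineage_data` data.frame.
#' Unknown columns are preserved. A column-mapping configuration allows
#' files with non-canonical headers to be loaded by renaming.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(lineage_id = "Lineage", micronuclei = "MN")`.
#' @param check If `TRUE` (default) run [validate_lineages()] and stop on
#'   integrity violations.
#' @return A data.frame of class `lineage_data` with the canonical columns
#'   first, flags as logical, and a `provenance` attribute recording the
#'   source path.
#' @seealso [write_tidy()], [validate_lineages()], [simulate_lineages()]
#' @export
read_tidy <- function(path, col_map = NULL, check = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  missing <- setdiff(.tidy_cols, names(raw))
  if (length(missing) > 0L) {
    stop("tidy schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- raw
  for (col in .tidy_num_cols) {
    v <- df[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("tidy parse error: column '%s' unparseable at data line %d (value '%s')",
                   col, bad[1], v[bad[1]]), call. = FALSE)
    }
    df[[col]] <- num
  }
  for (col in .tidy_flag_cols) {
    v <- df[[col]]
    flag <- v %in% c("1", "TRUE", "true", "T")
    bad <- which(!v %in% c("0", "1", "TRUE", "FALSE", "true", "false", "T", "F", ""))
    if (length(bad) > 0L) {
      stop(sprintf("tidy parse error: column '%s' not interpretable as 0/1 at data line %d",
                   col, bad[1]), call. = FALSE)
    }
    df[[col]] <- flag
  }
  key <- paste(df$lineage_id, df$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("tidy integrity error: duplicated (lineage_id, cell_id): ",
         gsub("\r", "/", d), call. = FALSE)
  }
  extra <- setdiff(names(df), .tidy_cols)
  df <- df[, c(.tidy_cols, extra)]
  class(df) <- c("lineage_data", "data.frame")
  attr(df, "provenance") <- list(source = path, read_at = format(Sys.time()))
  if (check) {
    rep <- validate_lineages(df)
    if (!rep$ok) {
      stop("tidy integrity error:\n  ",
           paste(utils::head(rep$violations$message, 5), collapse = "\n  "),
           call. = FALSE)
    }
  }
  df
}

#' Write a tidy per-cell-cycle table
#'
#' Writes the canonical CSV form: canonical column order, flags as 0/1,
#' missing values as empty fields, numbers in `%.10g` format. Writing is
#' deterministic, so `write_tidy(read_tidy(f))` reproduces a canonical
#' file byte for byte.
#'
#' @param data A `lineage_data` data.frame (or compatible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy <- function(data, path) {
  df <- as.data.frame(data)
  extra <- setdiff(names(df), .tidy_cols)
  df <- df[, c(.tidy_cols, extra)]
  out <- df
  for (col in .tidy_num_cols) out[[col]] <- fmt_num(df[[col]])
  for (col in .tidy_flag_cols) out[[col]] <- as.integer(df[[col]])
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(lapply(out, as.character)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a lineage dataset
#'
#' Checks every record-level invariant of the tidy schema and returns all
#' violations as data, never as an exception: durations positive when
#' present, time ordering `t_birth <= t_nebd <= t_division`, stage constant
#' within each lineage, fading restricted to SIS2-3 sgF11 cells, censored
#' records without a division time, parents present, path labels consistent
#' with `parent_id`, and valid factor levels.
#'
#' @param data A `lineage_data` data.frame.
#' @return An object of class `lineage_validation`: a list with `ok`
#'   (logical) and `violations` (data.frame with columns `lineage_id`,
#'   `cell_id`, `row`, `rule`, `message`).
#' @export
validate_lineages <- function(data) {
  df <- as.data.frame(data)
  v <- list()
  bad <- function(idx, rule, msg) {
    if (length(idx) == 0L) return(NULL)
    data.frame(lineage_id = df$lineage_id[idx], cell_id = df$cell_id[idx],
               row = idx, rule = rule, message = sprintf(
                 "row %d (%s/%s): %s", idx, df$lineage_id[idx],
                 df$cell_id[idx], msg), stringsAsFactors = FALSE)
  }
  v$int_pos <- bad(which(!is.na(df$interphase_duration) & df$interphase_duration <= 0),
                   "positive_interphase", "interphase_duration must be > 0")
  v$mit_pos <- bad(which(!is.na(df$mitotic_duration) & df$mitotic_duration <= 0),
                   "positive_mitosis", "mitotic_duration must be > 0")
  v$order1 <- bad(which(!is.na(df$t_nebd) & df$t_nebd < df$t_birth),
                  "time_order", "t_nebd earlier than t_birth")
  v$order2 <- bad(which(!is.na(df$t_division) & !is.na(df$t_nebd) &
                          df$t_division < df$t_nebd),
                  "time_order", "t_division earlier than t_nebd")
  v$levels <- bad(which(!(df$cell_line %in% .cell_lines) |
                          !(df$treatment %in% .treatments) |
                          !(df$stage %in% .stages)),
                  "condition_levels", "unknown cell_line/treatment/stage level")
  v$fading <- bad(which(df$fading & !(df$cell_line == "SIS2-3" & df$treatment == "sgF11")),
                  "fading_scope", "fading is only possible in SIS2-3 sgF11 cells")
  v$cens <- bad(which(df$censored & !is.na(df$t_division)),
                "censored_division", "censored record has a division time")
  stg <- tapply(df$stage, df$lineage_id, function(s) length(unique(s)))
  badlin <- names(stg)[stg > 1]
  v$stage <- bad(which(df$lineage_id %in% badlin & !duplicated(df$lineage_id)),
                 "stage_constant", "stage varies within lineage")
  # parent linkage and path-label consistency
  key <- paste(df$lineage_id, df$cell_id)
  has_parent <- !is.na(df$parent_id) & df$parent_id != ""
  pkey <- paste(df$lineage_id, df$parent_id)
  v$orphan <- bad(which(has_parent & !(pkey %in% key)),
                  "orphan", "parent_id not present in lineage")
  pathpar <- substr(df$cell_id, 1, nchar(df$cell_id) - 1L)
  v$path <- bad(which(has_parent & nchar(df$cell_id) > 1L &
                        (pkey %in% key) & pathpar != df$parent_id),
                "path_label", "cell_id path label conflicts with parent_id")
  roots <- tapply(!has_parent, df$lineage_id, sum)
  badroot <- names(roots)[roots != 1L]
  v$root <- bad(which(df$lineage_id %in% badroot & !duplicated(df$lineage_id)),
                "single_root", "lineage must have exactly one root record")
  viol <- do.call(rbind, v[!vapply(v, is.null, logical(1))])
  if (is.null(viol)) {
    viol <- data.frame(lineage_id = character(), cell_id = character(),
                       row = integer(), rule = character(),
                       message = character(), stringsAsFactors = FALSE)
  }
  rownames(viol) <- NULL
  structure(list(ok = nrow(viol) == 0L, violations = viol,
                 n_records = nrow(df),
                 n_lineages = length(unique(df$lineage_id))),
            class = "lineage_validation")
}

#' @export
print.lineage_validation <- function(x, ...) {
  cat(sprintf("Lineage dataset validation: %s (%d records, %d lineages)\n",
              if (x$ok) "OK" else "FAILED", x$n_records, x$n_lineages))
  if (!x$ok) {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    for (m in utils::head(x$violations$message, 20)) cat(" -", m, "\n")
    if (nrow(x$violations) > 20) cat(" ...\n")
  }
  invisible(x)
}

#' Export a validation report as JSON
#'
#' @param report A `lineage_validation` object.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(ok = report$ok, n_records = report$n_records,
         n_lineages = report$n_lineages, violations = report$violations),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
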
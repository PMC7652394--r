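# Lineage trees: one rooted tree per mCitrine-positive founder cell.
# Cells are identified by path labels ("a" root, "aa"/"ab" daughters, ...);
# tripolar mitoses may add a third daughter ("ac"). Fusion links connect
# coexisting cells and do not change the parent/child topology.

#' Build lineage trees from a tidy dataset
#'
#' Groups records by `lineage_id` and assembles one rooted tree per
#' lineage. Children are ordered by daughter label; `fused_with`
#' references are resolved into bidirectional fusion links.
#'
#' @param data A `lineage_data` data.frame (see [read_tidy()]).
#' @return A named list of `lineage_tree` objects, in lexicographic
#'   `lineage_id` order. Each tree is a list with elements `lineage_id`,
#'   `condition` (cell_line, treatment, stage), `records` (the lineage's
#'   rows, ordered by cell_id), `root` (root cell_id), `children` (named
#'   list cell_id -> character vector of child ids) and `fusions`
#'   (two-column character matrix of fused cell pairs).
#' @export
build_trees <- function(data) {
  df <- as.data.frame(data)
  out <- lapply(split(df, df$lineage_id), build_one_tree)
  out[order(names(out))]
}

build_one_tree <- function(recs) {
  recs <- recs[order(recs$cell_id), , drop = FALSE]
  rownames(recs) <- NULL
  has_parent <- !is.na(recs$parent_id) & recs$parent_id != ""
  root <- recs$cell_id[!has_parent]
  if (length(root) != 1L) {
    stop("topology error: lineage '", recs$lineage_id[1],
         "' has ", length(root), " root records", call. = FALSE)
  }
  orphan <- has_parent & !(recs$parent_id %in% recs$cell_id)
  if (any(orphan)) {
    stop("orphan error: lineage '", recs$lineage_id[1], "', cell '",
         recs$cell_id[which(orphan)[1]], "' has missing parent '",
         recs$parent_id[which(orphan)[1]], "'", call. = FALSE)
  }
  kids <- split(recs$cell_id[has_parent], recs$parent_id[has_parent])
  kids <- lapply(kids, sort)
  nk <- vapply(kids, length, integer(1))
  if (any(nk > 3L)) {
    stop("topology error: lineage '", recs$lineage_id[1], "', cell '",
         names(kids)[which(nk > 3L)[1]], "' has more than 3 children",
         call. = FALSE)
  }
  # cycle guard: every cell must be reachable from the root
  reach <- root
  frontier <- root
  while (length(frontier) > 0L) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    frontier <- setdiff(nxt, reach)
    reach <- c(reach, frontier)
  }
  if (length(reach) != nrow(recs)) {
    stop("topology error: lineage '", recs$lineage_id[1],
         "' contains cells unreachable from the root (cycle or broken link)",
         call. = FALSE)
  }
  fus <- which(!is.na(recs$fused_with) & recs$fused_with != "")
  fusions <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("cell", "partner")))
  if (length(fus) > 0L) {
    pairs <- t(apply(cbind(recs$cell_id[fus], recs$fused_with[fus]), 1, sort))
    fusions <- unique(pairs)
    colnames(fusions) <- c("cell", "partner")
  }
  structure(list(lineage_id = recs$lineage_id[1],
                 condition = c(cell_line = recs$cell_line[1],
                               treatment = recs$treatment[1],
                               stage = recs$stage[1]),
                 records = recs, root = root, children = kids,
                 fusions = fusions),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("Lineage tree '%s' [%s %s %s]: %d cells, %d divisions, %d fusion link(s)\n",
              x$lineage_id, x$condition[["cell_line"]],
              x$condition[["treatment"]], x$condition[["stage"]],
              nrow(x$records), length(x$children), nrow(x$fusions)))
  invisible(x)
}

.feature_names <- c("no_mitosis", "mitotic_delay", "MN", "bi_multi",
                    "death", "fading", "tripolar", "regression",
                    "cell_fusion")

#' Lineage-level abnormality features
#'
#' Summarises one lineage tree into binary abnormality flags:
#' `no_mitosis` (no cell in the tree divided during the movie),
#' `mitotic_delay` (at least one mitosis strictly longer than 2 h), and
#' presence flags for MN, bi/multi-nucleation, death, mCitrine fading,
#' tripolar mitosis, furrow regression and cell fusion.
#'
#' @param tree A `lineage_tree`.
#' @param delay_threshold Mitotic-delay threshold in hours (default 2;
#'   strict inequality).
#' @return A named logical vector over the nine features.
#' @export
lineage_features <- function(tree, delay_threshold = 2) {
  r <- tree$records
  c(no_mitosis    = !any(!is.na(r$t_division)),
    mitotic_delay = any(!is.na(r$mitotic_duration) &
                          r$mitotic_duration > delay_threshold),
    MN            = any(r$micronuclei),
    bi_multi      = any(r$bi_multi_nuclei),
    death         = any(r$death),
    fading        = any(r$fading),
    tripolar      = any(r$tripolar),
    regression    = any(r$regression),
    cell_fusion   = nrow(tree$fusions) > 0L)
}

#' Percentage of lineages with each abnormality, by condition
#'
#' For each experimental condition, computes
#' `100 * (# lineages showing the feature) / (# lineages in the condition)`
#' for the nine lineage-level features of [lineage_features()].
#'
#' @param trees A list of `lineage_tree` objects (from [build_trees()]).
#' @param delay_threshold Passed to [lineage_features()].
#' @return A data.frame with one row per non-empty condition: `condition`,
#'   `n_lineages`, and one percentage column per feature.
#' @export
abnormality_percentages <- function(trees, delay_threshold = 2) {
  if (length(trees) == 0L) stop("no trees supplied", call. = FALSE)
  feats <- t(vapply(trees, lineage_features, logical(length(.feature_names)),
                    delay_threshold = delay_threshold))
  cond <- vapply(trees, function(t) condition_label(
    t$condition[["cell_line"]], t$condition[["treatment"]],
    t$condition[["stage"]]), character(1))
  all_conds <- condition_table()$condition
  missing <- setdiff(all_conds, unique(cond))
  if (length(missing) > 0L) {
    warning("condition(s) with no lineages excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(sort(unique(cond)), function(cc) {
    sub <- feats[cond == cc, , drop = FALSE]
    pct <- as.list(100 * colMeans(sub))
    cbind(data.frame(condition = cc, n_lineages = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# descendants of `cell` (excluding the cell itself) within a tree
tree_descendants <- function(tree, cell) {
  out <- character(0)
  frontier <- tree$children[[cell]]
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- unlist(tree$children[frontier], use.names = FALSE)
  }
  out
}
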
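# Matched sister-lineage comparison: for every division whose two
# daughter subtrees differ in MN status (exactly one side ever shows MN),
# tally abnormalities on both sides and ask which sister fared worse.

#' Find matched sister pairs discordant for MN
#'
#' Scans every bipolar division in the trees and emits a pair whenever
#' exactly one of the two daughter subtrees (daughter cell included)
#' contains at least one MN-positive cell. Divisions where both or
#' neither side shows MN, and tripolar divisions, are skipped.
#'
#' @param trees List of `lineage_tree` objects.
#' @param delay_threshold Mitotic-delay threshold in hours (strict
#'   inequality; default 2).
#' @return A list of `sister_pair` objects; each records the lineage,
#'   dividing cell, the MN-positive and MN-negative daughter ids, the
#'   abnormality tally of both sides and the verdict (`MN_plus_more`,
#'   `MN_minus_more` or `tie`).
#' @export
find_matched_pairs <- function(trees, delay_threshold = 2) {
  out <- list()
  for (tree in trees) {
    for (parent in names(tree$children)) {
      kids <- tree$children[[parent]]
      if (length(kids) != 2L) next  # tripolar (or regression) divisions skipped
      side_mn <- vapply(kids, function(k) {
        cells <- c(k, tree_descendants(tree, k))
        any(tree$records$micronuclei[tree$records$cell_id %in% cells])
      }, logical(1))
      if (sum(side_mn) != 1L) next
      plus <- kids[side_mn]; minus <- kids[!side_mn]
      out[[length(out) + 1L]] <-
        make_sister_pair(tree, parent, plus, minus, delay_threshold)
    }
  }
  out
}

# abnormality tally for one daughter subtree
side_tally <- function(tree, daughter, delay_threshold) {
  cells <- c(daughter, tree_descendants(tree, daughter))
  r <- tree$records[tree$records$cell_id %in% cells, , drop = FALSE]
  fused <- nrow(tree$fusions) > 0L &&
    any(tree$fusions %in% r$cell_id)
  c(mitoses = sum(!is.na(r$t_division)),
    MN = sum(r$micronuclei),
    regression = sum(r$regression),
    fusion = as.integer(fused),
    death = sum(r$death),
    mitotic_delay = sum(!is.na(r$mitotic_duration) &
                          r$mitotic_duration > delay_threshold))
}

make_sister_pair <- function(tree, parent, plus, minus, delay_threshold) {
  tp <- side_tally(tree, plus, delay_threshold)
  tm <- side_tally(tree, minus, delay_threshold)
  # abnormality events: every count except mitoses, plus "fewer mitoses"
  # scored as one abnormality of the side that divided less; the index MN
  # that defines the pair is not itself an increased abnormality, so one
  # MN is discounted from the MN-positive side
  ab_plus <- sum(tp[-1]) - 1L + as.integer(tp[["mitoses"]] < tm[["mitoses"]])
  ab_minus <- sum(tm[-1]) + as.integer(tm[["mitoses"]] < tp[["mitoses"]])
  verdict <- if (ab_plus > ab_minus) "MN_plus_more"
             else if (ab_minus > ab_plus) "MN_minus_more" else "tie"
  structure(list(lineage_id = tree$lineage_id, division = parent,
                 mn_positive = plus, mn_negative = minus,
                 tally_plus = tp, tally_minus = tm,
                 abnormalities_plus = ab_plus,
                 abnormalities_minus = ab_minus,
                 verdict = verdict),
            class = "sister_pair")
}

#' @export
print.sister_pair <- function(x, ...) {
  cat(sprintf("Sister pair %s/%s: MN+ '%s' (%d abnormalities) vs MN- '%s' (%d) -> %s\n",
              x$lineage_id, x$division, x$mn_positive,
              x$abnormalities_plus, x$mn_negative,
              x$abnormalities_minus, x$verdict))
  invisible(x)
}

#' Compare matched sister pairs
#'
#' Scores each pair by strict majority of abnormality events (additional
#' MN beyond the index event, regression, fusion, death, mitotic delay,
#' and fewer mitoses) and builds the 2x2 table of {side, increased
#' abnormalities yes/no} counts used for the chi-square test. Ties count
#' in neither "more abnormal" cell.
#'
#' @param pairs List of `sister_pair` objects from [find_matched_pairs()].
#' @return List with `table` (2x2 integer matrix, rows MN+/MN-, columns
#'   more-abnormal / not), `verdicts` (data.frame) and `n_pairs`.
#' @export
compare_pairs <- function(pairs) {
  if (length(pairs) == 0L) stop("no sister pairs to compare", call. = FALSE)
  v <- vapply(pairs, `[[`, "", "verdict")
  n <- length(pairs)
  k_plus <- sum(v == "MN_plus_more")
  k_minus <- sum(v == "MN_minus_more")
  tab <- matrix(c(k_plus, n - k_plus, k_minus, n - k_minus),
                nrow = 2, byrow = TRUE,
                dimnames = list(side = c("MN_plus", "MN_minus"),
                                more_abnormal = c("yes", "no")))
  verdicts <- data.frame(
    lineage_id = vapply(pairs, `[[`, "", "lineage_id"),
    division = vapply(pairs, `[[`, "", "division"),
    abnormalities_plus = vapply(pairs, `[[`, 0L, "abnormalities_plus"),
    abnormalities_minus = vapply(pairs, `[[`, 0L, "abnormalities_minus"),
    verdict = v, stringsAsFactors = FALSE)
  list(table = tab, verdicts = verdicts, n_pairs = n)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree
#' of freedom; no continuity correction by default.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df` (1) and `p_value`.
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = 1L, p_value = ct$p.value)
}

#' Estimate an event probability from k successes in n trials
#'
#' Reports several standard estimators side by side: the maximum
#' likelihood estimate `k/n`, the Jeffreys posterior mean `(k+1/2)/(n+1)`,
#' the Laplace posterior mean `(k+1)/(n+2)`, and the Jeffreys posterior
#' median.
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param method Which estimate to return in `$estimate`; all four are
#'   always included in `$all`.
#' @return List with `estimate`, `method`, `k`, `n` and `all` (named
#'   vector of the four estimators).
#' @export
event_probability <- function(k, n, method = c("mle", "jeffreys_mean",
                                                "laplace_mean",
                                                "beta_median")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  all <- c(mle = k / n,
           jeffreys_mean = (k + 0.5) / (n + 1),
           laplace_mean = (k + 1) / (n + 2),
           beta_median = stats::qbeta(0.5, k + 0.5, n - k + 0.5))
  list(estimate = all[[method]], method = method, k = k, n = n, all = all)
}
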
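# three-generation lineage where MN appears only in daughter aa's subtree
discordant_lineage <- function(mn_cell = "aa", extra = NULL) {
  d <- rbind(
    tidy_row("L1", "a", "", "SIS2-3", "sgF11", "N+x", t_nebd = 18,
             t_division = 18.5, mitotic_duration = 0.5),
    tidy_row("L1", "aa", "a", "SIS2-3", "sgF11", "N+x", t_birth = 18.5,
             t_nebd = 38, t_division = 38.5, interphase_duration = 19.5,
             mitotic_duration = 0.5, micronuclei = mn_cell == "aa"),
    tidy_row("L1", "ab", "a", "SIS2-3", "sgF11", "N+x", t_birth = 18.5,
             t_nebd = 39, t_division = 39.5, interphase_duration = 20.5,
             mitotic_duration = 0.5, micronuclei = mn_cell == "ab"),
    tidy_row("L1", "aaa", "aa", "SIS2-3", "sgF11", "N+x", t_birth = 38.5,
             censored = TRUE),
    tidy_row("L1", "aab", "aa", "SIS2-3", "sgF11", "N+x", t_birth = 38.5,
             censored = TRUE),
    tidy_row("L1", "aba", "ab", "SIS2-3", "sgF11", "N+x", t_birth = 39.5,
             censored = TRUE),
    tidy_row("L1", "abb", "ab", "SIS2-3", "sgF11", "N+x", t_birth = 39.5,
             censored = TRUE))
  if (!is.null(extra)) d <- rbind(d, extra)
  as_lineage_data(d)
}

test_that("a division discordant for MN yields exactly one pair", {
  trees <- build_trees(discordant_lineage())
  pairs <- find_matched_pairs(trees)
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$mn_positive, "aa")
  expect_equal(pairs[[1]]$mn_negative, "ab")
  expect_equal(pairs[[1]]$division, "a")
})

test_that("divisions with MN on both or neither side are skipped", {
  both <- discordant_lineage()
  both$micronuclei[both$cell_id == "ab"] <- TRUE
  expect_length(find_matched_pairs(build_trees(both)), 0L)
  neither <- discordant_lineage()
  neither$micronuclei <- FALSE
  expect_length(find_matched_pairs(build_trees(neither)), 0L)
})

test_that("pair sides are disjoint and exhaust the division's descendants", {
  d <- simulate_lineages(sim_params(n_lineages = 40), seed = 17)
  trees <- build_trees(d)
  pairs <- find_matched_pairs(trees)
  expect_gt(length(pairs), 0L)
  for (pr in pairs) {
    tr <- trees[[pr$lineage_id]]
    left <- c(pr$mn_positive, mnlineage:::tree_descendants(tr, pr$mn_positive))
    right <- c(pr$mn_negative, mnlineage:::tree_descendants(tr, pr$mn_negative))
    expect_length(intersect(left, right), 0L)
    expect_setequal(c(pr$division, left, right),
                    c(pr$division,
                      mnlineage:::tree_descendants(tr, pr$division)))
  }
})

test_that("pair counts on depth-2 trees match exhaustive enumeration", {
  # depth-2 trees with per-cycle MN probability q on the 6 non-root cells:
  # each root-daughter subtree holds 3 cells, so it shows MN with
  # p = 1 - (1-q)^3 and the root division is discordant with 2 p (1-p);
  # each daughter division (leaf subtrees of 1 cell) with 2 q (1-q)
  q <- 0.2
  p_sub <- 1 - (1 - q)^3
  expected_per_tree <- 2 * p_sub * (1 - p_sub) + 2 * (2 * q * (1 - q))
  n_sim <- 400
  set.seed(77)
  count <- 0
  for (i in seq_len(n_sim)) {
    mk <- function(id, parent, mn, div, t0)
      tidy_row("L", id, parent, t_birth = t0, micronuclei = mn,
               t_nebd = if (div) t0 + 10 else NA,
               t_division = if (div) t0 + 10.5 else NA,
               interphase_duration = if (div && parent != "") 10 else NA,
               mitotic_duration = if (div) 0.5 else NA,
               censored = !div)
    mn <- runif(7) < c(0, rep(q, 6))   # root cycle MN-free for clarity
    d <- as_lineage_data(rbind(
      mk("a", "", mn[1], TRUE, 0),
      mk("aa", "a", mn[2], TRUE, 10.5), mk("ab", "a", mn[3], TRUE, 10.5),
      mk("aaa", "aa", mn[4], FALSE, 21), mk("aab", "aa", mn[5], FALSE, 21),
      mk("aba", "ab", mn[6], FALSE, 21), mk("abb", "ab", mn[7], FALSE, 21)))
    count <- count + length(find_matched_pairs(build_trees(d)))
  }
  expected <- n_sim * expected_per_tree
  se <- sqrt(n_sim * expected_per_tree)   # Poisson-scale MC error bound
  expect_lt(abs(count - expected), 4 * se)
})

test_that("verdicts follow the strict-majority abnormality rule", {
  # MN+ side has a death beyond its index MN; MN- side clean -> MN_plus_more
  extra_death <- discordant_lineage()
  extra_death$death[extra_death$cell_id == "aaa"] <- TRUE
  pr <- find_matched_pairs(build_trees(extra_death))[[1]]
  expect_equal(pr$verdict, "MN_plus_more")

  cmp <- compare_pairs(list(pr))
  expect_equal(cmp$table["MN_plus", "yes"], 1L)
  expect_equal(cmp$table["MN_minus", "yes"], 0L)

  # the index MN alone is not an increased abnormality: a clean MN+ side
  # against a death on the MN- side scores for the MN- sister
  minus_death <- discordant_lineage()
  minus_death$death[minus_death$cell_id == "aba"] <- TRUE
  pr2 <- find_matched_pairs(build_trees(minus_death))[[1]]
  expect_equal(pr2$verdict, "MN_minus_more")

  # equal tallies -> tie, counted in neither "more abnormal" cell
  balanced <- discordant_lineage()
  balanced$death[balanced$cell_id %in% c("aaa", "aba")] <- TRUE
  pr3 <- find_matched_pairs(build_trees(balanced))[[1]]
  expect_equal(pr3$verdict, "tie")

  # a second MN on the MN+ side counts as an extra abnormality
  extra_mn <- discordant_lineage()
  extra_mn$micronuclei[extra_mn$cell_id == "aaa"] <- TRUE
  pr4 <- find_matched_pairs(build_trees(extra_mn))[[1]]
  expect_equal(pr4$verdict, "MN_plus_more")
})

test_that("the 12-of-43 study table round-trips and tests as printed", {
  tab <- matrix(c(12, 31, 0, 43), nrow = 2, byrow = TRUE,
                dimnames = list(side = c("MN_plus", "MN_minus"),
                                more_abnormal = c("yes", "no")))
  res <- chisq_2x2(tab)
  expect_equal(res$statistic, 13.9459459459, tolerance = 1e-9)
  expect_equal(res$df, 1L)
  expect_lt(res$p_value, 0.001)
  # swapping the rows leaves the statistic unchanged
  expect_equal(chisq_2x2(tab[2:1, ])$statistic, res$statistic,
               tolerance = 1e-12)
})

test_that("chi-square matches a brute-force expected-counts oracle", {
  brute <- function(tab) {
    N <- sum(tab)
    stat <- 0
    for (i in 1:2) for (j in 1:2) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / N
      stat <- stat + (tab[i, j] - e)^2 / e
    }
    stat
  }
  set.seed(14)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chisq_2x2(tab)$statistic, brute(tab), tolerance = 1e-12)
  }
  expect_equal(chisq_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("event probability reports all standard estimators", {
  ep <- event_probability(12, 43)
  expect_equal(ep$estimate, 12 / 43, tolerance = 1e-12)
  expect_equal(round(ep$all[["mle"]], 4), 0.2791)
  expect_equal(ep$all[["jeffreys_mean"]], 12.5 / 44, tolerance = 1e-12)
  expect_equal(ep$all[["laplace_mean"]], 13 / 45, tolerance = 1e-12)
  expect_equal(event_probability(0, 10)$estimate, 0)
  expect_error(event_probability(5, 0), "positive")
  expect_error(event_probability(7, 5), "0 <= k <= n")
})
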
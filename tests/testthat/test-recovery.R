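# Optimized-distance scan, max-WCN control, method comparison

test_that("the scan finds a noise-free planted gradient exactly", {
  set.seed(61)
  ctr <- matrix(runif(60 * 3, -15, 15), ncol = 3)
  c0 <- 17L
  K <- 0.2 + 0.05 * sqrt(colSums((t(ctr) - ctr[c0, ])^2))
  scan <- optimized_distance_scan(ctr, K)
  expect_equal(scan$best, c0)
  expect_equal(scan$best_r_squared, 1, tolerance = 1e-12)
  expect_equal(scan$slope_sign[c0], 1)

  expect_error(optimized_distance_scan(ctr, rep(1, 60)), "constant")
  expect_error(optimized_distance_scan(ctr[1:3, ], K[1:3]), "at least 4")
})

test_that("scan ties break to the lowest residue index", {
  # mirror-symmetric geometry with mirror-symmetric rates: residues 1 and 2
  # have identical R^2 profiles
  ctr <- rbind(c(-5, 0, 0), c(5, 0, 0), c(-2, 3, 0), c(2, 3, 0),
               c(-2, -3, 0), c(2, -3, 0))
  K <- c(0.2, 0.2, 1, 1, 1.5, 1.5)
  scan <- optimized_distance_scan(ctr, K)
  tied <- which(abs(scan$r_squared - max(scan$r_squared)) < 1e-12)
  expect_gt(length(tied), 1)
  expect_equal(scan$best, min(tied))
})

test_that("the R^2 profile is invariant under rigid motions", {
  set.seed(62)
  ctr <- matrix(rnorm(40 * 3, sd = 10), ncol = 3)
  K <- rexp(40)
  base <- optimized_distance_scan(ctr, K)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  moved <- ctr %*% t(R) + matrix(c(3, -8, 12), 40, 3, byrow = TRUE)
  rot <- optimized_distance_scan(moved, K)
  expect_equal(rot$r_squared, base$r_squared, tolerance = 1e-9)
  expect_equal(rot$best, base$best)
})

test_that("max-WCN control and recovery categories behave as stated", {
  expect_equal(max_wcn_reference(c(0.2, 0.9, 0.5)), 2L)
  expect_equal(max_wcn_reference(c(0.9, 0.9)), 1L)
  expect_equal(max_wcn_reference(0.4), 1L)
  expect_error(max_wcn_reference(numeric()), "empty")

  expect_equal(recovery_category(c(0, 5, 7.5, 7.6)),
               c("exact", "neighbor", "neighbor", "miss"))
  ev <- evaluate_recovery(c(0, 5, 12))
  expect_equal(ev$exact, 1 / 3)
  expect_equal(ev$within_7.5, 2 / 3)
  expect_equal(evaluate_recovery(c(0, 0))$within_7.5, 1)
  expect_equal(evaluate_recovery(c(9, 30))$exact, 0)
})

test_that("AUC by rank statistic equals all-pairs concordance", {
  # perfect separation
  expect_equal(auc_rank(c(5, 4, 1, 0.5), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(63)
  for (i in 1:5) {
    scores <- sample(round(rnorm(80), 1))  # rounding forces ties
    labels <- runif(80) < 0.3
    if (!any(labels) || all(labels)) next
    expect_equal(auc_rank(scores, labels), auc_oracle(scores, labels))
  }
  # independent implementation cross-check
  skip_if_not_installed("pROC")
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2, 0.7, 0.1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc_rank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("method comparison builds the 2x2 table, odds ratio and Fisher p", {
  mk <- function(dists) data.frame(protein_id = seq_along(dists),
                                   distance_to_truth = dists)
  # 30/100 vs 15/100 successes
  oa <- mk(c(rep(0, 30), rep(20, 70)))
  ob <- mk(c(rep(5, 15), rep(20, 85)))
  cmp <- compare_methods(oa, ob)
  expect_equal(unname(cmp$contingency[1, ]), c(30, 70))
  expect_equal(cmp$odds_ratio, (30 * 85) / (70 * 15))
  expect_equal(cmp$odds_ratio, 2.4286, tolerance = 1e-4)
  expect_equal(cmp$p_value,
               fisher_oracle(cmp$contingency), tolerance = 1e-9)

  # symmetric table: odds ratio 1, p = 1
  sym <- compare_methods(mk(c(rep(0, 10), rep(20, 10))),
                         mk(c(rep(0, 10), rep(20, 10))))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  # zero cell triggers the Haldane-Anscombe correction
  z <- compare_methods(mk(rep(0, 5)), mk(c(0, rep(20, 4))))
  expect_equal(z$odds_ratio, (5.5 * 4.5) / (0.5 * 1.5))

  expect_error(compare_methods(oa, mk(rep(0, 3))), "mismatched")
})

test_that("Fisher p matches hypergeometric enumeration on random tables", {
  set.seed(64)
  for (i in 1:8) {
    n <- sample(20:100, 1)
    sa <- runif(n) < runif(1, 0.2, 0.8)
    sb <- runif(n) < runif(1, 0.2, 0.8)
    tab <- matrix(c(sum(sa), sum(!sa), sum(sb), sum(!sb)), 2,
                  byrow = TRUE)
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-8)
  }
})

test_that("recover_active_site reports both methods against the truth", {
  cfg <- synthetic_config(n_sites = 150, n_catalytic = 1, sigma = 0.1,
                          beta_wcn = 0, beta_rsa = 0, seed = 71)
  sim <- quiet_sim(cfg)
  ctr <- residue_centers(sim$structure)
  rec <- recover_active_site(ctr, sim$table$K, sim$table$wcn,
                             sim$annotation$index, "s1")
  expect_equal(rec$method, c("optimized_d", "max_wcn"))
  expect_equal(rec$category,
               recovery_category(rec$distance_to_truth))
  # side-chain geometry gap: distances are 0 or at least min_separation
  expect_true(all(rec$distance_to_truth == 0 |
                  rec$distance_to_truth >= cfg$min_separation - 1e-9))
  expect_length(attr(rec, "scores_optimized_d"), 150)
})
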
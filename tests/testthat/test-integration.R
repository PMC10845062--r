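test_that("cortical integration is the block mean of delta and TP1", {
  scheme <- tiny_scheme()
  n <- 5
  tp1 <- matrix(0.1, n, 6)
  delta <- matrix(0, n, 6)
  # edges touching stn_R (roi 3, 0-based): positions of (0,3),(1,3),(2,3)
  ei <- edge_index(4)
  block <- which(ei$roi_b == 3L)
  delta[, block] <- 0.2
  d <- deltacwas:::new_cohort(paste0("s", 1:n), tp1, tp1 + delta,
                              rnorm(n), rnorm(n), rep(0:1, length.out = n),
                              scheme = scheme)
  prof <- cortical_integration(d, "stn_R")
  expect_equal(prof$mean_delta, rep(0.2, n))
  expect_equal(prof$mean_tp1, rep(0.1, n))
  expect_equal(attr(prof, "n_block_edges"), 3)
  # per-edge delta values 0.1 / 0.3 / 0.2 -> arithmetic mean 0.2
  delta2 <- delta
  delta2[, block] <- rep(c(0.1, 0.3, 0.2), each = n)
  d2 <- deltacwas:::new_cohort(paste0("s", 1:n), tp1, tp1 + delta2,
                               rnorm(n), rnorm(n), rep(0:1, length.out = n),
                               scheme = scheme)
  expect_equal(cortical_integration(d2, "stn_R")$mean_delta[1],
               mean(c(0.1, 0.3, 0.2)))
  expect_error(cortical_integration(d, character(0)), "empty target")
  expect_error(cortical_integration(d, "smA"), "subcortical")
})

test_that("integration model equals the mass edge engine on a synthetic
           one-edge dataset", {
  sim <- sim_default(n = 150, seed = 41)
  d <- sim$dataset
  prof <- cortical_integration(d, c("stn_R", "rn_L"))
  rep <- fit_integration_model(prof, d)
  # build a cohort whose single edge carries the integration means
  one <- tiny_scheme()[1:2, ]
  class(one) <- c("parcellation", "data.frame")
  d1 <- deltacwas:::new_cohort(d$subject_id,
                               rsfc_tp1 = cbind(prof$mean_tp1),
                               rsfc_tp2 = cbind(prof$mean_tp1 +
                                                  prof$mean_delta),
                               symptoms_tp1 = d$symptoms_tp1,
                               symptoms_tp2 = d$symptoms_tp2,
                               sex = d$sex, scheme = one)
  res <- fit_edge_models(d1)
  want <- rep$terms
  expect_lt(abs(res$beta[1, "edge"] -
                  want$beta[want$term == "mean_delta"]), 1e-10)
  expect_lt(abs(res$beta[1, "rsfc_tp1_same_edge"] -
                  want$beta[want$term == "mean_tp1"]), 1e-10)
  expect_lt(abs(res$t[1, "edge"] - want$t[want$term == "mean_delta"]), 1e-10)
  expect_equal(res$df_resid, rep$df_resid)
})

test_that("model reports are internally consistent and planted integration
           effects are recovered", {
  scheme <- default_parcellation()
  planted <- integration_block_effects(scheme, "stn_R", effect = -0.2)
  sim <- simulate_cohort(sim_config(n_subjects = 690, seed = 19,
                                    planted_edges = planted))
  d <- sim$dataset
  prof <- cortical_integration(d, "stn_R")
  rep <- fit_integration_model(prof, d)
  # R^2-F identity and CI construction
  expect_equal(rep$f, (rep$r_squared / rep$df_model) /
                 ((1 - rep$r_squared) / rep$df_resid))
  tcrit <- qt(0.975, rep$df_resid)
  expect_equal(rep$terms$ci_lo, rep$terms$beta - tcrit * rep$terms$se)
  b <- rep$terms$beta[rep$terms$term == "mean_delta"]
  expect_lt(abs(b - (-0.2)), 3 * rep$terms$se[rep$terms$term == "mean_delta"])
  expect_lt(b, 0)
  expect_equal(rep$df_resid, 686)
})

test_that("null integration fits stay null", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_cohort(sim_config(n_subjects = 300, seed = 100 + s))
    prof <- cortical_integration(sim$dataset, "stn_R")
    rep <- fit_integration_model(prof, sim$dataset)
    tt <- rep$terms$t[rep$terms$term %in% c("mean_delta", "mean_tp1")]
    hits <- hits + sum(abs(tt) > 3)
  }
  # P(|t| > 3) ~ 0.003 under the null; 40 draws -> seeing 2+ is very unlikely
  expect_lte(hits, 1)
})

test_that("integration ratio correlates ratios with behavior and flags
           zero denominators", {
  sim <- sim_default(n = 29, seed = 77)
  d <- sim$dataset
  num <- cortical_integration(d, "stn_R")$mean_tp1
  den <- cortical_integration(d, "thalamus_middle")$mean_tp1
  behav <- 3 * (num / den) + 1       # exactly proportional
  rr <- integration_ratio(d, "stn_R", "thalamus_middle", behav)
  expect_equal(rr$r, 1, tolerance = 1e-12)
  expect_equal(rr$df, 27)            # n = 29 valid subjects
  expect_equal(rr$ratio[!rr$flagged], (num / den)[!rr$flagged])
  rr2 <- integration_ratio(d, "stn_R", "thalamus_middle", behav,
                           method = "spearman")
  expect_equal(rr2$r, 1, tolerance = 1e-12)
})

test_that("null sampling distribution of the ratio correlation", {
  sim <- sim_default(n = 29, seed = 78)
  d <- sim$dataset
  set.seed(5)
  rs <- replicate(500, {
    integration_ratio(d, "stn_R", "thalamus_middle", rnorm(29))$r
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(28 * 500))
  expect_lt(abs(sd(rs) - 1 / sqrt(28)), 0.04)
})

test_that("AUC: perfect ranking, monotone invariance, rank reversal", {
  set.seed(8)
  outcome <- rnorm(120)
  sweep0 <- roc_percentile_sweep(outcome, outcome)
  expect_true(all(sweep0$auc == 1))
  expect_false(any(sweep0$undefined))
  score <- rnorm(120)
  s1 <- roc_percentile_sweep(score, outcome)
  s2 <- roc_percentile_sweep(exp(2 * score) + 5, outcome)  # strictly monotone
  expect_identical(s1$auc, s2$auc)
  expect_equal(roc_percentile_sweep(-score, outcome)$auc, 1 - s1$auc)
})

test_that("degenerate percentiles are marked undefined, sweep continues", {
  outcome <- c(rep(1, 9), 2)
  s <- roc_percentile_sweep(rnorm(10), outcome, percentiles = c(50, 95, 100))
  expect_false(s$undefined[1])
  expect_true(s$undefined[3])        # 100th percentile: empty positive class
  expect_true(is.na(s$auc[3]))
  expect_equal(nrow(s), 3)
})
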
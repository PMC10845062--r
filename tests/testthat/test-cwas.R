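test_that("mass fit agrees with the per-edge normal-equations oracle", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 200, seed = 7,
    scheme = default_parcellation(p_cortical = 24, p_subcortical = 6)))
  d <- sim$dataset
  res <- fit_edge_models(d, edge_model_spec(standardize = FALSE))
  set.seed(7)
  edges <- sample(n_edges(d$scheme), 50)
  y <- d$symptoms_tp2
  for (e in edges) {
    X <- cbind(1, d$delta[, e], d$rsfc_tp1[, e], d$sex)
    o <- ols_oracle(X, y)
    expect_lt(max(abs(res$beta[e, ] - o$beta)), 1e-8)
    expect_lt(max(abs(res$t[e, ] - o$t)), 1e-8)
    expect_lt(max(abs(res$se[e, ] - o$se)), 1e-8)
  }
  expect_equal(res$df_resid, 196)
})

test_that("noise-free interpolation: outcome equal to delta gives beta 1", {
  scheme <- tiny_scheme()
  n <- 6
  set.seed(2)
  tp1 <- matrix(rnorm(n * 6, 0, 0.1), n, 6)
  delta <- matrix(rnorm(n * 6, 0, 0.1), n, 6)
  d <- deltacwas:::new_cohort(
    subject_id = paste0("s", 1:n), rsfc_tp1 = tp1, rsfc_tp2 = tp1 + delta,
    symptoms_tp1 = rnorm(n), symptoms_tp2 = delta[, 3], sex = rep(0:1, 3),
    scheme = scheme)
  res <- fit_edge_models(d, edge_model_spec(covariates = "sex",
                                            standardize = FALSE))
  expect_equal(unname(res$beta[3, "edge"]), 1, tolerance = 1e-10)
  # residual variance ~ 0 -> enormous t
  expect_gt(abs(res$t[3, "edge"]), 1e6)
})

test_that("standardization changes beta scale but never t or p;
           affine regressor changes rescale beta by 1/a", {
  sim <- sim_default(n = 80, seed = 21)
  d <- sim$dataset
  raw <- fit_edge_models(d, edge_model_spec(standardize = FALSE))
  std <- fit_edge_models(d, edge_model_spec(standardize = TRUE))
  expect_equal(std$t[, "edge"], raw$t[, "edge"], tolerance = 1e-10)
  # slope-term p values are invariant; the intercept's meaning changes under
  # centering, so it is excluded
  expect_equal(std$p[, -1], raw$p[, -1], tolerance = 1e-10)
  a <- 7.5
  d2 <- d
  d2$delta <- d$delta * a
  d2$rsfc_tp2 <- d$rsfc_tp1 + d2$delta
  res2 <- fit_edge_models(d2, edge_model_spec(standardize = FALSE))
  expect_equal(res2$beta[, "edge"], raw$beta[, "edge"] / a,
               tolerance = 1e-10)
  expect_equal(res2$t[, "edge"], raw$t[, "edge"], tolerance = 1e-10)
})

test_that("degenerate edges are flagged, not dropped, and excluded from m", {
  sim <- sim_default(n = 30, seed = 4)
  d <- sim$dataset
  d$delta[, 5] <- 0
  d$rsfc_tp2 <- d$rsfc_tp1 + d$delta
  res <- rowwise_bh(fit_edge_models(d), q = 0.05)
  expect_true(res$degenerate[5])
  expect_true(all(is.na(res$beta[5, ])))
  expect_equal(nrow(res$beta), n_edges(d$scheme))
  expect_true(all(is.na(res$p_adj[5, ])))
  # rows containing the degenerate edge adjust over m = P - 2 valid tests
  ei <- res$edge_index
  r <- ei$roi_a[5] + 1L
  idx <- deltacwas:::edges_incident(ei, r)
  pvec <- res$p[idx, "edge"]
  expect_equal(sum(!is.na(pvec)), n_roi(d$scheme) - 2)
  manual <- bh_oracle(pvec[!is.na(pvec)])
  is_a <- ei$roi_a[idx] == r - 1L
  got <- ifelse(is_a, res$p_adj[idx, "row_a"], res$p_adj[idx, "row_b"])
  expect_equal(got[!is.na(pvec)], manual, tolerance = 1e-12)
})

test_that("bh_adjust matches hand-applied BH and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))   # BH fixed point
  set.seed(99)
  for (rep in 1:25) {
    m <- sample(1:500, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NA handling: m counts valid tests only
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
})

test_that("row-wise BH assigns two adjusted p values per edge and
           monotonicity in q holds", {
  sim <- sim_default(n = 60, seed = 31)
  res <- fit_edge_models(sim$dataset)
  r1 <- rowwise_bh(res, q = 0.05)
  expect_true(all(r1$p_adj >= res$p[, "edge"] - 1e-12))
  expect_identical(dim(r1$p_adj), c(n_edges(sim$dataset$scheme), 2L))
  # every ROI row reproduces a direct BH over its incident edges
  ei <- r1$edge_index
  for (r in sample(n_roi(sim$dataset$scheme), 8)) {
    idx <- deltacwas:::edges_incident(ei, r)
    manual <- bh_oracle(res$p[idx, "edge"])
    is_a <- ei$roi_a[idx] == r - 1L
    got <- ifelse(is_a, r1$p_adj[idx, "row_a"], r1$p_adj[idx, "row_b"])
    expect_equal(got, manual, tolerance = 1e-12)
  }
  r2 <- rowwise_bh(res, q = 0.20)
  expect_true(all(r2$sig >= r1$sig, na.rm = TRUE))  # enlarging q adds flags
  expect_error(rowwise_bh(res, q = 0), "q must be")
  expect_error(rowwise_bh(res, q = 1.2), "q must be")
})

test_that("count_significant counts row flags filtered by sign", {
  planted <- data.frame(
    roi_a = rep("stn_R", 5),
    roi_b = c("control_L_1", "limbic_L_1", "somatomotor_L_1",
              "salience_L_1", "default_mode_L_1"),
    effect = 0.8)
  sim <- sim_default(n = 300, seed = 13, planted = planted)
  res <- rowwise_bh(fit_edge_models(sim$dataset), q = 0.001)
  expect_equal(count_significant(res, "stn_R", "positive"), 5)
  expect_equal(count_significant(res, "stn_R", "negative"), 0)
  expect_equal(count_significant(res, "stn_R", "both"), 5)
  expect_error(count_significant(res, "nope"), "unknown ROI")
  expect_error(count_significant(fit_edge_models(sim$dataset), "stn_R"),
               "rowwise_bh")
})

test_that("cross-sectional fits match a direct one-edge regression and
           find planted TP2-only effects", {
  planted <- data.frame(roi_a = "stn_R", roi_b = "somatomotor_L_1",
                        effect = -0.5)
  sim <- sim_default(n = 250, seed = 17, planted = planted)
  d <- sim$dataset
  tp2 <- fit_cross_sectional(d, "TP2", standardize = FALSE)
  tp1 <- fit_cross_sectional(d, "TP1", standardize = FALSE)
  j <- sim$truth$planted_edges$edge_pos
  o <- ols_oracle(cbind(1, d$rsfc_tp2[, j], d$sex), d$symptoms_tp2)
  expect_equal(unname(tp2$beta[j, ]), unname(o$beta), tolerance = 1e-10)
  expect_equal(tp2$df_resid, 250 - 3)
  # change planted at TP2 leaks into the TP2 level but not the TP1 level
  expect_gt(abs(tp2$t[j, "edge"]), abs(tp1$t[j, "edge"]))
})

test_that("permuted outcomes give a calibrated raw-p rate", {
  sim <- sim_default(n = 100, seed = 23)
  d <- sim$dataset
  set.seed(1)
  d$symptoms_tp2 <- sample(d$symptoms_tp2)
  res <- fit_cross_sectional(d, "TP2")
  frac <- mean(res$p[, "edge"] <= 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n_edges(d$scheme))
  expect_lt(abs(frac - 0.05), 3 * mc_se)
})

test_that("Eq.-style fit on a 690-subject cohort reports df_resid 686", {
  sim <- sim_default(n = 690, seed = 3)
  res <- fit_edge_models(sim$dataset)
  expect_equal(res$df_resid, 686)
})

test_that("extra covariates enter every edge design and match the oracle", {
  sim <- sim_default(n = 120, seed = 47)
  d <- sim$dataset
  site <- rnorm(120)
  spec <- edge_model_spec(standardize = FALSE,
                          extra_covariates = list(site = site))
  res <- fit_edge_models(d, spec)
  expect_identical(res$terms,
                   c("(Intercept)", "edge", "rsfc_tp1_same_edge", "sex",
                     "site"))
  expect_equal(res$df_resid, 120 - 5)
  e <- 101
  o <- ols_oracle(cbind(1, d$delta[, e], d$rsfc_tp1[, e], d$sex, site),
                  d$symptoms_tp2)
  expect_equal(unname(res$beta[e, ]), unname(o$beta), tolerance = 1e-8)
  expect_equal(unname(res$t[e, ]), unname(o$t), tolerance = 1e-8)
})
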
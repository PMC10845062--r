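test_that("simulation is bit-identical under a seed and differs across
           seeds", {
  a <- sim_default(n = 20, seed = 123)
  b <- sim_default(n = 20, seed = 123)
  c <- sim_default(n = 20, seed = 124)
  expect_identical(a$dataset$rsfc_tp1, b$dataset$rsfc_tp1)
  expect_identical(a$dataset$delta, b$dataset$delta)
  expect_identical(a$dataset$symptoms_tp2, b$dataset$symptoms_tp2)
  expect_false(identical(a$dataset$delta, c$dataset$delta))
})

test_that("config validation: seed mandatory, couplings bounded", {
  expect_error(sim_config(n_subjects = 10), "seed is mandatory")
  expect_error(sim_config(
    seed = 1, planted_edges = data.frame(roi_a = "stn_R",
                                         roi_b = "control_L_1",
                                         effect = 1.2)),
    "in \\(-1, 1\\)")
  expect_error(sim_config(
    seed = 1, planted_edges = data.frame(roi_a = "stn_R", roi_b = "stn_R",
                                         effect = 0.1)),
    "identical endpoints")
})

test_that("planted edge positions match the row-major edge enumeration", {
  scheme <- default_parcellation()
  cfg <- sim_config(seed = 1, planted_edges = data.frame(
    roi_a = "somatomotor_L_1", roi_b = "stn_R", effect = 0.3))
  pe <- cfg$planted_edges
  ei <- edge_index(n_roi(scheme))
  expect_equal(ei$roi_a[pe$edge_pos], pe$roi_a)  # canonical roi_a < roi_b
  expect_equal(ei$roi_b[pe$edge_pos], pe$roi_b)
  expect_lt(pe$roi_a, pe$roi_b)
})

test_that("null cohorts give uniform raw edge p-values", {
  sim <- sim_default(n = 200, seed = 300)
  res <- fit_edge_models(sim$dataset)
  set.seed(1)
  pick <- sample(n_edges(sim$dataset$scheme), 1000)
  ks <- suppressWarnings(ks.test(res$p[pick, "edge"], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("excessive clipping aborts with the dedicated condition", {
  expect_error(
    simulate_cohort(sim_config(n_subjects = 30, seed = 2,
                               baseline_sd = 1.5, delta_sd = 1.5)),
    class = "deltacwas_clip_error")
})

test_that("two-group simulation plants the configured mean shift", {
  shift <- data.frame(roi_a = "stn_R", roi_b = "control_L_1", shift = 1.5)
  sims <- lapply(1:30, function(s)
    simulate_two_group(sim_config(seed = 400 + s), group_shift = shift))
  j <- sims[[1]]$truth$group_shift$edge_pos
  diffs <- vapply(sims, function(sm) {
    d <- sm$dataset
    mean(d$rsfc_tp1[d$group == "patient", j]) -
      mean(d$rsfc_tp1[d$group == "control", j])
  }, numeric(1))
  # true shift = 1.5 * baseline_sd = 0.15; mean diff has se 0.1*sqrt(2/29)
  expect_lt(abs(mean(diffs) - 0.15), 3 * 0.1 * sqrt(2 / 29) / sqrt(30))
  expect_equal(n_subjects(sims[[1]]$dataset), 58)
  expect_null(sims[[1]]$dataset$rsfc_tp2)
})

test_that("parameter recovery: mean standardized beta across reps is within
           0.02 of the planted coupling (scaled-down reps)", {
  planted <- data.frame(roi_a = "stn_R", roi_b = "somatomotor_L_1",
                        effect = 0.5)
  betas <- vapply(1:40, function(s) {
    sim <- simulate_cohort(sim_config(n_subjects = 500, seed = 500 + s,
                                      planted_edges = planted))
    j <- sim$truth$planted_edges$edge_pos
    d <- sim$dataset
    # single-edge fit suffices for recovery of the planted coefficient
    o <- ols_oracle(cbind(1, scale(d$delta[, j]), scale(d$rsfc_tp1[, j]),
                          d$sex), scale(d$symptoms_tp2))
    o$beta[2]
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.5), 0.02)
})

test_that("timeseries mode converges to the target connectome and feeds the
           same downstream containers", {
  scheme <- default_parcellation(p_cortical = 10, p_subcortical = 2)
  sim <- simulate_cohort(sim_config(n_subjects = 2, seed = 600,
                                    scheme = scheme, mode = "timeseries",
                                    t_len = 5000))
  d <- sim$dataset
  expect_equal(dim(d$rsfc_tp1), c(2, n_edges(scheme)))
  validate_cohort(d)
  target <- sim$truth$population$tp1
  expect_lt(max(abs(d$rsfc_tp1 - target)), 0.05)
})

test_that("nearest_correlation projects to a valid correlation matrix", {
  expect_equal(nearest_correlation(diag(4)), diag(4))
  set.seed(9)
  psd <- random_corr_mat(5)
  expect_lt(max(abs(nearest_correlation(psd) - psd)), 1e-9)
  # 3x3 with a slightly negative eigenvalue
  m <- matrix(c(1, 0.9, -0.3, 0.9, 1, 0.6, -0.3, 0.6, 1), 3)
  expect_lt(min(eigen(m, symmetric = TRUE)$values), 0)
  fixed <- nearest_correlation(m)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-12)
  expect_equal(unname(diag(fixed)), rep(1, 3))
  expect_identical(fixed, t(fixed))
  expect_error(nearest_correlation(matrix(1:9, 3)), "symmetric")
  # oracle: Higham projection from the Matrix package lands at the same spot
  skip_if_not_installed("Matrix")
  np <- as.matrix(Matrix::nearPD(m, corr = TRUE)$mat)
  expect_lt(max(abs(fixed - np)), 1e-4)
})

test_that("truth record serializes with planted structure and clip rate", {
  planted <- data.frame(roi_a = "stn_R", roi_b = "limbic_L_1", effect = -0.3)
  sim <- sim_default(n = 15, seed = 700, planted = planted)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  tr <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(tr$planted_edges$effect, -0.3)
  expect_equal(tr$seed, 700)
  expect_true(tr$clip_rate <= 0.01)
  expect_match(tr$planted_edges$edge_id, "stn_R")
})
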
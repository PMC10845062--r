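# Fixtures and independent oracles shared across the suite.

# 4-ROI toy parcellation: 2 somatomotor + 1 limbic cortical, 1 subcortical.
tiny_scheme <- function() {
  parcellation(data.frame(
    roi_name   = c("smA", "smB", "limbicA", "stn_R"),
    hemisphere = c("L", "R", "bilateral", "R"),
    roi_class  = c("cortical", "cortical", "cortical", "subcortical"),
    network    = c("somatomotor", "somatomotor", "limbic", "basal_ganglia"),
    stringsAsFactors = FALSE))
}

# hand-built cohort: direct matrix construction through the simulator's
# public surface would drag in RNG; tests that need exact numbers build the
# cohort from explicit connectome pairs instead
toy_connectome <- function(values, scheme, tp) {
  ts <- NULL
  structure(list(values = values, scheme = scheme, time_point = tp,
                 fisher_z = FALSE), class = "connectome")
}

symmetrize <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1; m }

random_corr_mat <- function(p) {
  x <- matrix(rnorm(p * (p + 3)), p + 3, p)
  stats::cor(x)
}

# --- independent oracles -------------------------------------------------

# per-edge normal-equations OLS (explicit solve of X'X b = X'y); returns
# beta, se, t for one design
ols_oracle <- function(X, y) {
  xtx <- crossprod(X)
  b <- solve(xtx, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  list(beta = drop(b), se = se, t = drop(b) / se, df = df)
}

# brute-force BH by its definition: sort, i/m scaling, cumulative min
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  adj[m] <- min(scaled[m], 1)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(scaled[i], adj[i + 1], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# standard default-scheme cohort used by several files
sim_default <- function(n = 200, seed = 1, planted = NULL, ...) {
  simulate_cohort(sim_config(n_subjects = n, seed = seed,
                             planted_edges = planted, ...))
}

# flag of the edge at vector position j, read from either endpoint row
j_row_flag <- function(res, j) {
  isTRUE(res$sig[j, "row_a"]) || isTRUE(res$sig[j, "row_b"])
}

# flags of a ROI's row whose partner is subcortical
n_subcortical_flags <- function(res, roi) {
  scheme <- res$scheme
  r <- match(roi, scheme$roi_name)
  ei <- res$edge_index
  idx <- deltacwas:::edges_incident(ei, r)
  is_a <- ei$roi_a[idx] == r - 1L
  other <- ifelse(is_a, ei$roi_b[idx], ei$roi_a[idx]) + 1L
  flag <- ifelse(is_a, res$sig[idx, "row_a"], res$sig[idx, "row_b"])
  flag[is.na(flag)] <- FALSE
  sum(flag & scheme$roi_class[other] == "subcortical")
}
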
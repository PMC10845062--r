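#' Specify the edge-wise regression model
#'
#' The workhorse model regresses the symptom score at follow-up on each
#' edge's connectivity change, controlling for the same edge's baseline
#' connectivity and for sex:
#'
#' \deqn{symptoms(TP2) ~ \Delta rsFC + rsFC(TP1) + sex + intercept}
#'
#' Cross-sectional variants replace the edge regressor by the rsFC level at
#' one time point and drop the baseline covariate.
#'
#' @param outcome `"symptoms_tp2"` or `"symptoms_tp1"`.
#' @param edge_regressor `"delta"`, `"rsfc_tp1"` or `"rsfc_tp2"`.
#' @param covariates subset of `c("rsfc_tp1_same_edge", "sex")`, in order.
#' @param standardize if `TRUE` (default) the outcome and all continuous
#'   regressors are z-scored before fitting, so edge coefficients are on the
#'   standardized scale; sex stays 0/1. t and p are unaffected by this choice.
#' @param extra_covariates optional named list of extra per-subject numeric
#'   covariates (e.g. site), appended to every design.
#' @return An `edge_model_spec`.
#' @export
edge_model_spec <- function(outcome = c("symptoms_tp2", "symptoms_tp1"),
                            edge_regressor = c("delta", "rsfc_tp1", "rsfc_tp2"),
                            covariates = c("rsfc_tp1_same_edge", "sex"),
                            standardize = TRUE,
                            extra_covariates = NULL) {
  outcome <- match.arg(outcome)
  edge_regressor <- match.arg(edge_regressor)
  bad <- setdiff(covariates, c("rsfc_tp1_same_edge", "sex"))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (edge_regressor == "rsfc_tp1" && "rsfc_tp1_same_edge" %in% covariates) {
    stop("edge regressor rsfc_tp1 cannot also appear as its own covariate",
         call. = FALSE)
  }
  # canonical covariate order: same-edge baseline before sex (matches the
  # internal design-column layout)
  covariates <- intersect(c("rsfc_tp1_same_edge", "sex"), covariates)
  structure(list(outcome = outcome, edge_regressor = edge_regressor,
                 covariates = covariates, standardize = standardize,
                 extra_covariates = extra_covariates),
            class = "edge_model_spec")
}

# term names for a spec: intercept first, then edge term, then covariates
spec_terms <- function(spec) {
  c("(Intercept)", "edge", spec$covariates,
    names(spec$extra_covariates %||% list()))
}

#' Fit the edge-wise model at every edge of a cohort
#'
#' Mass-univariate ordinary least squares: one regression per edge, each with
#' its own design (the edge regressor and any same-edge baseline covariate
#' vary by edge; intercept, sex and extra covariates are shared). Each fit
#' uses a QR decomposition; coefficients, standard errors, t statistics and
#' two-sided p values are returned for every term.
#'
#' Edges whose design is rank deficient (for example a zero-variance edge
#' regressor) are flagged `degenerate` and carry `NA` statistics; they are
#' never silently dropped and are excluded from the row-wise correction's
#' test count.
#'
#' @param dataset a `cohort_dataset` with the fields the spec needs.
#' @param spec an [edge_model_spec()].
#' @return An `edge_result_table`: list with `edge_index`, `terms`, and
#'   E x K matrices `beta`, `se`, `t`, `p`; plus `df_resid`, `n`,
#'   `degenerate` (logical per edge) and the `spec`. Row-wise adjusted p
#'   values are added by [rowwise_bh()].
#' @export
fit_edge_models <- function(dataset, spec = edge_model_spec()) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            inherits(spec, "edge_model_spec"))
  y <- dataset[[spec$outcome]]
  if (is.null(y)) stop("dataset lacks outcome ", spec$outcome, call. = FALSE)
  edge_mat <- dataset[[spec$edge_regressor]]
  if (is.null(edge_mat)) {
    stop("dataset lacks edge regressor ", spec$edge_regressor, call. = FALSE)
  }
  base_mat <- NULL
  if ("rsfc_tp1_same_edge" %in% spec$covariates) {
    base_mat <- dataset$rsfc_tp1
    if (is.null(base_mat)) stop("dataset lacks rsfc_tp1", call. = FALSE)
  }
  n <- n_subjects(dataset)
  terms <- spec_terms(spec)
  k <- length(terms)
  if (n <= k) stop("need more subjects (", n, ") than regressors (", k, ")",
                   call. = FALSE)

  if (spec$standardize) {
    y <- zscale(y)
    edge_sd <- apply(edge_mat, 2L, stats::sd)
    ok <- edge_sd > 0
    edge_mat <- sweep(sweep(edge_mat, 2L, colMeans(edge_mat), "-"),
                      2L, ifelse(ok, edge_sd, 1), "/")
    if (!is.null(base_mat)) {
      base_sd <- apply(base_mat, 2L, stats::sd)
      okb <- base_sd > 0
      base_mat <- sweep(sweep(base_mat, 2L, colMeans(base_mat), "-"),
                        2L, ifelse(okb, base_sd, 1), "/")
    }
  }

  shared <- matrix(1, n, 1L)
  if ("sex" %in% spec$covariates) shared <- cbind(shared, dataset$sex)
  for (nm in names(spec$extra_covariates %||% list())) {
    v <- spec$extra_covariates[[nm]]
    if (spec$standardize && stats::sd(v) > 0) v <- zscale(v)
    shared <- cbind(shared, v)
  }

  ne <- ncol(edge_mat)
  beta <- se <- tval <- pval <- matrix(NA_real_, ne, k,
                                       dimnames = list(NULL, terms))
  degenerate <- logical(ne)
  df_resid <- n - k
  # column layout of the per-edge design: intercept, edge, [baseline], [shared
  # covariates beyond the intercept] — reordered to `terms` at the end
  has_base <- !is.null(base_mat)
  n_shared_extra <- ncol(shared) - 1L
  col_map <- c(1L,                                    # intercept
               2L,                                    # edge
               if (has_base) 3L,                      # baseline covariate
               if (n_shared_extra > 0)
                 (2L + has_base) + seq_len(n_shared_extra))
  # term order in `terms`: intercept, edge, covariates in spec order
  for (e in seq_len(ne)) {
    x_e <- edge_mat[, e]
    if (stats::sd(x_e) == 0) { degenerate[e] <- TRUE; next }
    X <- cbind(shared[, 1L], x_e,
               if (has_base) base_mat[, e],
               if (n_shared_extra > 0) shared[, -1L, drop = FALSE])
    fit <- .lm.fit(X, y)
    if (fit$rank < ncol(X)) { degenerate[e] <- TRUE; next }
    res <- fit$residuals
    sigma2 <- sum(res * res) / df_resid
    # (X'X)^{-1} from the QR factor R
    R <- qr.R(structure(list(qr = fit$qr, rank = fit$rank,
                             qraux = fit$qraux, pivot = fit$pivot),
                        class = "qr"))
    xtx_inv <- chol2inv(R)
    b <- fit$coefficients[order(fit$pivot)]
    v <- diag(xtx_inv)[order(fit$pivot)]
    s <- sqrt(sigma2 * v)
    beta[e, ] <- b[col_map]
    se[e, ] <- s[col_map]
  }
  ok <- !degenerate
  tval[ok, ] <- beta[ok, , drop = FALSE] / se[ok, , drop = FALSE]
  pval[ok, ] <- 2 * stats::pt(-abs(tval[ok, , drop = FALSE]), df_resid)

  structure(list(edge_index = dataset$edge_index,
                 edge_id = edge_ids(dataset$edge_index, dataset$scheme),
                 scheme = dataset$scheme,
                 terms = terms, beta = beta, se = se, t = tval, p = pval,
                 df_resid = df_resid, n = n, degenerate = degenerate,
                 spec = spec),
            class = "edge_result_table")
}

#' @export
print.edge_result_table <- function(x, ...) {
  cat(sprintf(
    "edge_result_table: %d edges, %d subjects, df_resid = %d, terms: %s\n",
    nrow(x$beta), x$n, x$df_resid, paste(x$terms, collapse = ", ")))
  if (any(x$degenerate)) cat(sum(x$degenerate), "degenerate edge(s)\n")
  if (!is.null(x$p_adj)) {
    cat(sprintf("row-wise BH at q = %g on term '%s': %d row-flags\n",
                x$q, x$adjusted_term, sum(x$sig, na.rm = TRUE)))
  }
  invisible(x)
}

#' Cross-sectional edge-wise association at one time point
#'
#' Regresses the concurrent symptom score on each edge's rsFC level with sex
#' as covariate (no baseline term).
#'
#' @param dataset a `cohort_dataset`
#' @param time_point `"TP1"` or `"TP2"`
#' @param standardize as in [edge_model_spec()]
#' @return An `edge_result_table`.
#' @export
fit_cross_sectional <- function(dataset, time_point = c("TP1", "TP2"),
                                standardize = TRUE) {
  time_point <- match.arg(time_point)
  spec <- edge_model_spec(
    outcome = if (time_point == "TP1") "symptoms_tp1" else "symptoms_tp2",
    edge_regressor = if (time_point == "TP1") "rsfc_tp1" else "rsfc_tp2",
    covariates = "sex", standardize = standardize)
  fit_edge_models(dataset, spec)
}

#' Benjamini-Hochberg step-up adjustment of a p-value vector
#'
#' Plain BH: sort, scale by m/i, enforce monotonicity by cumulative minimum
#' from the largest p down, cap at 1. `NA` entries (degenerate tests) are
#' excluded from the test count m and returned as `NA`.
#'
#' @param p numeric vector of raw p values (may contain `NA`)
#' @return vector of adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv)
  adj <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
  out[ok][o] <- adj
  out
}

#' ROI-row-wise false discovery rate correction
#'
#' Applies the Benjamini-Hochberg procedure independently to each row of the
#' connectivity matrix: for ROI r, the P-1 p values of edges incident to r
#' are adjusted together. Every edge (a, b) therefore carries two adjusted
#' p values, one from row a and one from row b, and all per-ROI counts and
#' summaries read the row of the ROI under report. Compared with
#' connectome-wide correction this is deliberately liberal, trading
#' family-wise stringency for sensitivity to ROIs with few associated edges
#' (such as small subcortical nuclei).
#'
#' @param results an `edge_result_table` (also works on a
#'   `group_contrast_result`)
#' @param q FDR level in (0, 1); flags use `p_adj <= q`.
#' @param term which term's p values to adjust (default the edge term for
#'   edge results; ignored for group contrasts).
#' @return The input object with `p_adj` (E x 2 matrix: columns `row_a`,
#'   `row_b`), `sig` (logical E x 2), `q` and `adjusted_term` added.
#' @export
rowwise_bh <- function(results, q = 0.05, term = "edge") {
  UseMethod("rowwise_bh")
}

#' @export
rowwise_bh.edge_result_table <- function(results, q = 0.05, term = "edge") {
  if (!term %in% results$terms) {
    stop("unknown term: ", term, call. = FALSE)
  }
  p <- results$p[, term]
  adj <- rowwise_bh_core(p, results$edge_index, nrow(results$scheme), q)
  results$p_adj <- adj$p_adj
  results$sig <- adj$sig
  results$q <- q
  results$adjusted_term <- term
  results
}

# Core row-wise machinery shared by edge results and group contrasts.
rowwise_bh_core <- function(p, ei, n_roi, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop("q must be a single value in (0, 1)", call. = FALSE)
  }
  p_adj <- matrix(NA_real_, length(p), 2L,
                  dimnames = list(NULL, c("row_a", "row_b")))
  for (r in seq_len(n_roi)) {
    idx <- edges_incident(ei, r)
    adj <- bh_adjust(p[idx])
    is_a <- ei$roi_a[idx] == r - 1L
    p_adj[idx[is_a], "row_a"] <- adj[is_a]
    p_adj[idx[!is_a], "row_b"] <- adj[!is_a]
  }
  sig <- !is.na(p_adj) & p_adj <= q
  sig[is.na(p_adj)] <- NA
  list(p_adj = p_adj, sig = sig)
}

#' Count significant edges in one ROI's row
#'
#' Number of edges incident to `roi` that are flagged in `roi`'s own row
#' after [rowwise_bh()], optionally filtered by the sign of the edge-term
#' coefficient.
#'
#' @param results an `edge_result_table` after [rowwise_bh()]
#' @param roi ROI name or 0-based roi_id
#' @param sign `"both"`, `"positive"` or `"negative"`
#' @return integer count
#' @export
count_significant <- function(results, roi,
                              sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  if (is.null(results$p_adj)) {
    stop("apply rowwise_bh() first", call. = FALSE)
  }
  pos <- resolve_rois(results$scheme, roi)
  if (length(pos) != 1L) stop("one ROI at a time", call. = FALSE)
  ei <- results$edge_index
  idx <- edges_incident(ei, pos)
  is_a <- ei$roi_a[idx] == pos - 1L
  flag <- ifelse(is_a, results$sig[idx, "row_a"], results$sig[idx, "row_b"])
  flag[is.na(flag)] <- FALSE
  b <- results$beta[idx, results$adjusted_term]
  keep <- switch(sign, both = TRUE, positive = b > 0, negative = b < 0)
  sum(flag & keep)
}

#' Long-format data frame of edge-wise results
#'
#' @param x an `edge_result_table`
#' @param ... unused
#' @return data.frame with one row per (edge, term): `edge_id`, `roi_a`,
#'   `roi_b`, `term`, `beta`, `se`, `t`, `p`, and — if [rowwise_bh()] was
#'   applied — `p_adj_row_a`, `p_adj_row_b`, `sig_row_a`, `sig_row_b` on the
#'   adjusted term's rows.
#' @export
as.data.frame.edge_result_table <- function(x, ...) {
  ne <- nrow(x$beta)
  k <- length(x$terms)
  out <- data.frame(
    edge_id = rep(x$edge_id, times = k),
    roi_a = rep(x$edge_index$roi_a, times = k),
    roi_b = rep(x$edge_index$roi_b, times = k),
    term = rep(x$terms, each = ne),
    beta = as.vector(x$beta), se = as.vector(x$se),
    t = as.vector(x$t), p = as.vector(x$p),
    stringsAsFactors = FALSE)
  if (!is.null(x$p_adj)) {
    out$p_adj_row_a <- NA_real_
    out$p_adj_row_b <- NA_real_
    out$sig_row_a <- NA
    out$sig_row_b <- NA
    sel <- out$term == x$adjusted_term
    out$p_adj_row_a[sel] <- x$p_adj[, "row_a"]
    out$p_adj_row_b[sel] <- x$p_adj[, "row_b"]
    out$sig_row_a[sel] <- x$sig[, "row_a"]
    out$sig_row_b[sel] <- x$sig[, "row_b"]
  }
  out
}
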
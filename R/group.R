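# Two-group (patients vs controls) contrasts with sex control.
#
# The group test is a main-effects ANOVA (group + sex, no interaction) run
# per edge (or on the cortical-integration scalar). With a two-level factor
# the group main effect carries one numerator df, so its Type-II F equals the
# squared t of the patient dummy in the equivalent OLS — an identity the test
# suite asserts. Only the group factor's results are reported.

#' Edge-wise group contrast (patients vs controls) with sex control
#'
#' Per edge, fits `rsfc ~ group + sex` on a single-time-point cohort and
#' reports the group main effect: F (Type II, which for this one-df term is
#' the squared dummy-coded OLS t), p, and the direction of the
#' patient-minus-control adjusted mean. Row-wise BH adjusted p values are
#' attached as in [rowwise_bh()].
#'
#' @param dataset single-time-point `cohort_dataset` with a two-level
#'   `group` field (rsFC in `rsfc_tp1`; `rsfc_tp2`/`delta` absent)
#' @param q FDR level for the row-wise correction
#' @return A `group_contrast_result`: `edge_index`, `F`, `p`, `direction`
#'   (+1 patient > control, -1 otherwise), `df_num`, `df_den`, `p_adj`
#'   (E x 2), `sig`, `q`, `degenerate`.
#' @export
fit_group_edge_anova <- function(dataset, q = 0.05) {
  check_group_cohort(dataset)
  g <- as.integer(dataset$group == "patient")
  X <- cbind(1, g, dataset$sex)
  n <- n_subjects(dataset)
  df_den <- n - ncol(X)
  y_all <- dataset$rsfc_tp1
  ne <- ncol(y_all)
  Fv <- pv <- bg <- rep(NA_real_, ne)
  degenerate <- logical(ne)
  xtx_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  if (is.null(xtx_inv)) stop("design is rank deficient (constant sex?)",
                             call. = FALSE)
  H <- xtx_inv %*% t(X)          # hat operator, shared across edges
  v_g <- xtx_inv[2, 2]
  B <- H %*% y_all               # 3 x ne coefficients
  R <- y_all - X %*% B
  rss <- colSums(R * R)
  sigma2 <- rss / df_den
  se_g <- sqrt(sigma2 * v_g)
  ok <- se_g > 0
  degenerate <- !ok
  bg[ok] <- B[2, ok]
  tg <- bg[ok] / se_g[ok]
  Fv[ok] <- tg^2
  pv[ok] <- stats::pf(Fv[ok], 1, df_den, lower.tail = FALSE)
  adj <- rowwise_bh_core(pv, dataset$edge_index, n_roi(dataset$scheme), q)
  structure(list(edge_index = dataset$edge_index,
                 edge_id = edge_ids(dataset$edge_index, dataset$scheme),
                 scheme = dataset$scheme,
                 F = Fv, p = pv, beta_group = bg,
                 direction = sign(bg),
                 df_num = 1L, df_den = df_den,
                 p_adj = adj$p_adj, sig = adj$sig, q = q,
                 degenerate = degenerate, n = n),
            class = "group_contrast_result")
}

#' @export
print.group_contrast_result <- function(x, ...) {
  cat(sprintf(
    "group_contrast_result: %d tests, F(%d, %d), %d row-flags at q = %g\n",
    length(x$F), x$df_num, x$df_den, sum(x$sig, na.rm = TRUE), x$q))
  invisible(x)
}

#' @export
rowwise_bh.group_contrast_result <- function(results, q = 0.05,
                                             term = "group") {
  adj <- rowwise_bh_core(results$p, results$edge_index,
                         n_roi(results$scheme), q)
  results$p_adj <- adj$p_adj
  results$sig <- adj$sig
  results$q <- q
  results
}

#' Group contrast of a seed set's cortical integration
#'
#' Same main-effects ANOVA (group + sex) applied to the per-subject cortical
#' integration level of a subcortical seed set.
#'
#' @param dataset single-time-point `cohort_dataset` with `group`
#' @param target_rois subcortical seed ROIs
#' @return one-row list: `F`, `p`, `df_num`, `df_den`, `direction`,
#'   `beta_group`, `target_rois`.
#' @export
integration_group_anova <- function(dataset, target_rois) {
  check_group_cohort(dataset)
  prof <- cortical_integration(dataset, target_rois)
  g <- as.integer(dataset$group == "patient")
  dat <- data.frame(y = prof$mean_tp1, g = g, sex = dataset$sex)
  fit <- stats::lm(y ~ g + sex, data = dat)
  co <- summary(fit)$coefficients
  tg <- co["g", "t value"]
  list(F = unname(tg^2),
       p = unname(co["g", "Pr(>|t|)"]),
       df_num = 1L, df_den = fit$df.residual,
       direction = unname(sign(co["g", "Estimate"])),
       beta_group = unname(co["g", "Estimate"]),
       target_rois = attr(prof, "target_rois"))
}

check_group_cohort <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(dataset$group)) stop("dataset has no group labels",
                                   call. = FALSE)
  if (length(unique(dataset$group)) < 2L) {
    stop("need two non-empty groups", call. = FALSE)
  }
  if (!is.null(dataset$rsfc_tp2)) {
    stop("group contrasts expect a single-time-point cohort", call. = FALSE)
  }
  invisible(dataset)
}
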
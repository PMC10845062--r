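#' Cortical integration of a subcortical ROI set
#'
#' The cortical integration of a subcortical seed is the mean connectivity of
#' that seed (or seed set) to all cortical ROIs. For a longitudinal cohort
#' the function returns, per subject, the mean connectivity change
#' (`mean_delta`) and the mean baseline level (`mean_tp1`) over the
#' seed-to-cortex edge block; for a single-time-point cohort only the level
#' (`mean_tp1`) is available and `mean_delta` is `NA`.
#'
#' @param dataset a `cohort_dataset`
#' @param target_rois subcortical seed ROIs (names or 0-based ids)
#' @param scheme parcellation; defaults to the dataset's own
#' @return An `integration_profile` data.frame: `subject_id`, `mean_delta`,
#'   `mean_tp1`; attributes `target_rois` (0-based ids) and `n_block_edges`
#'   (= |targets| x number of cortical ROIs).
#' @export
cortical_integration <- function(dataset, target_rois,
                                 scheme = dataset$scheme) {
  pos <- resolve_rois(scheme, target_rois)
  if (length(pos) == 0L) stop("empty target ROI set", call. = FALSE)
  if (any(scheme$roi_class[pos] != "subcortical")) {
    stop("target ROIs must be subcortical", call. = FALSE)
  }
  cort <- cortical_rois(scheme)
  if (length(cort) == 0L) stop("parcellation has no cortical ROIs",
                               call. = FALSE)
  block <- edges_between(dataset$edge_index, pos, cort)
  stopifnot(length(block) == length(pos) * length(cort))
  md <- if (!is.null(dataset$delta)) {
    rowMeans(dataset$delta[, block, drop = FALSE])
  } else rep(NA_real_, n_subjects(dataset))
  mt <- rowMeans(dataset$rsfc_tp1[, block, drop = FALSE])
  out <- data.frame(subject_id = dataset$subject_id,
                    mean_delta = md, mean_tp1 = mt,
                    stringsAsFactors = FALSE)
  attr(out, "target_rois") <- scheme$roi_id[pos]
  attr(out, "n_block_edges") <- length(block)
  class(out) <- c("integration_profile", "data.frame")
  out
}

#' Regress symptoms on the cortical-integration change of a seed set
#'
#' Ordinary least squares of the follow-up symptom score on the per-subject
#' mean cortical connectivity change of the seed set, controlling for the
#' mean baseline level and sex. With `standardize = TRUE` (default) the
#' outcome and both continuous regressors are z-scored, so coefficients are
#' standardized; sex stays 0/1.
#'
#' @param profiles an `integration_profile` from [cortical_integration()]
#' @param dataset the `cohort_dataset` the profiles came from (phenotypes)
#' @param standardize z-score outcome and continuous regressors
#' @param collinearity_kappa condition-number threshold above which a
#'   collinearity warning is recorded in the report
#' @return A `model_report`: `terms` data.frame (term, beta, se, t, p,
#'   ci_lo, ci_hi), `r_squared`, `f`, `df_model`, `df_resid`, `p_model`,
#'   `n`, `standardize`, `warnings`.
#' @export
fit_integration_model <- function(profiles, dataset, standardize = TRUE,
                                  collinearity_kappa = 1e4) {
  stopifnot(inherits(profiles, "integration_profile"))
  if (!identical(profiles$subject_id, dataset$subject_id)) {
    stop("profiles and dataset are not aligned by subject", call. = FALSE)
  }
  if (anyNA(profiles$mean_delta)) {
    stop("profiles lack mean_delta (single-time-point cohort?)",
         call. = FALSE)
  }
  y <- dataset$symptoms_tp2
  md <- profiles$mean_delta
  mt <- profiles$mean_tp1
  if (standardize) { y <- zscale(y); md <- zscale(md); mt <- zscale(mt) }
  dat <- data.frame(y = y, mean_delta = md, mean_tp1 = mt,
                    sex = dataset$sex)
  fit <- stats::lm(y ~ mean_delta + mean_tp1 + sex, data = dat)
  report <- model_report(fit, term_names = c("(Intercept)", "mean_delta",
                                             "mean_tp1", "sex"))
  report$standardize <- standardize
  kappa <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (kappa > collinearity_kappa) {
    report$warnings <- c(report$warnings,
                         sprintf("design condition number %.3g exceeds %g",
                                 kappa, collinearity_kappa))
  }
  report
}

# Build a model_report from an lm fit: per-term stats with 95% CI plus
# whole-model R^2 / F. The R^2-F identity and CI construction are asserted
# here so every report is internally consistent by construction.
model_report <- function(fit, term_names = NULL) {
  s <- summary(fit)
  co <- s$coefficients
  df_resid <- fit$df.residual
  tcrit <- stats::qt(0.975, df_resid)
  terms <- data.frame(term = term_names %||% rownames(co),
                      beta = co[, 1], se = co[, 2], t = co[, 3], p = co[, 4],
                      ci_lo = co[, 1] - tcrit * co[, 2],
                      ci_hi = co[, 1] + tcrit * co[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  df_model <- length(stats::coef(fit)) - 1L
  r2 <- s$r.squared
  f <- (r2 / df_model) / ((1 - r2) / df_resid)
  stopifnot(isTRUE(all.equal(unname(f), unname(s$fstatistic[1]),
                             tolerance = 1e-8)))
  structure(list(terms = terms, r_squared = r2, f = f,
                 df_model = df_model, df_resid = df_resid,
                 p_model = stats::pf(f, df_model, df_resid,
                                     lower.tail = FALSE),
                 n = df_resid + df_model + 1L, warnings = character(0)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report: n = %d, R^2 = %.4f, F(%d, %d) = %.3f, p = %.3g\n",
              x$n, x$r_squared, x$df_model, x$df_resid, x$f, x$p_model))
  print(x$terms, digits = 4)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Ratio of two seeds' cortical integration, correlated with behavior
#'
#' Per subject, the ratio of the cortical-integration *levels* (baseline/
#' single-session rsFC, not change) of a numerator seed set to a denominator
#' seed set, correlated with a behavioral score across subjects. Subjects
#' with (numerically) zero denominator integration are flagged and excluded;
#' the correlation df is `n_valid - 2`.
#'
#' @param dataset a `cohort_dataset`
#' @param numerator_rois,denominator_rois subcortical seed sets
#' @param behavior per-subject numeric score, aligned with the cohort
#' @param method `"pearson"` (default) or `"spearman"`
#' @param zero_tol denominators with absolute value below this are flagged
#' @return list: `ratio` (per subject, `NA` where flagged), `flagged`
#'   (logical), `r`, `p`, `df`, `method`.
#' @export
integration_ratio <- function(dataset, numerator_rois, denominator_rois,
                              behavior, method = c("pearson", "spearman"),
                              zero_tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(length(behavior) == n_subjects(dataset))
  num <- cortical_integration(dataset, numerator_rois)$mean_tp1
  den <- cortical_integration(dataset, denominator_rois)$mean_tp1
  flagged <- abs(den) < zero_tol | is.na(behavior)
  if (all(flagged)) stop("no subject has a usable denominator", call. = FALSE)
  ratio <- ifelse(flagged, NA_real_, num / den)
  ok <- !flagged
  ct <- stats::cor.test(ratio[ok], behavior[ok], method = method,
                        exact = FALSE)
  list(ratio = ratio, flagged = flagged,
       r = unname(ct$estimate), p = ct$p.value,
       df = sum(ok) - 2L, method = method)
}

#' Rank-based AUC of a score against binary labels
#'
#' Mann-Whitney formulation with midranks, so ties are averaged and the AUC
#' is exactly invariant under strictly monotone transforms of the score.
#'
#' @param score numeric vector
#' @param positive logical vector, same length
#' @return AUC in \[0, 1\]
#' @export
auc_rank <- function(score, positive) {
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive), !anyNA(score),
            !anyNA(positive))
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Percentile-sweep ROC of a score against a dichotomized outcome
#'
#' For each percentile c of the sweep (default median to 95th in 5% steps),
#' subjects whose outcome lies strictly above the c-th percentile of the
#' outcome are labeled positive, and the AUC of the score against that
#' labeling is computed. Percentiles whose dichotomization leaves a class
#' empty are reported with `auc = NA` and `undefined = TRUE`; the sweep
#' continues.
#'
#' @param score per-subject score (e.g. a seed's mean cortical connectivity
#'   change, sign-aligned so larger = more at risk)
#' @param outcome per-subject symptom score used for labeling
#' @param percentiles numeric vector in (0, 100)
#' @return data.frame: `percentile`, `threshold`, `n_pos`, `n_neg`, `auc`,
#'   `undefined`.
#' @export
roc_percentile_sweep <- function(score, outcome,
                                 percentiles = seq(50, 95, by = 5)) {
  stopifnot(length(score) == length(outcome), !anyNA(score), !anyNA(outcome))
  out <- data.frame(percentile = percentiles, threshold = NA_real_,
                    n_pos = NA_integer_, n_neg = NA_integer_,
                    auc = NA_real_, undefined = FALSE)
  for (i in seq_along(percentiles)) {
    thr <- unname(stats::quantile(outcome, percentiles[i] / 100))
    pos <- outcome > thr
    out$threshold[i] <- thr
    out$n_pos[i] <- sum(pos)
    out$n_neg[i] <- sum(!pos)
    if (any(pos) && any(!pos)) {
      out$auc[i] <- auc_rank(score, pos)
    } else {
      out$undefined[i] <- TRUE
    }
  }
  out
}
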
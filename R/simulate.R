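# Synthetic cohort generator with planted effects.
#
# Generative model (standardized scale):
#   sex_i ~ Bernoulli(0.5)
#   r_i   ~ N(0,1)                          sex-adjusted symptom factor
#   sym_i = g*(sex_i - 1/2)*2*? ... see below
#
# The follow-up symptom score is
#   sym = gamma*(sex - 0.5) + sqrt(1 - gamma^2/4) * r      (unit variance)
# optionally mixed with measurement noise and renormalized. A planted edge e
# with coupling b_e has
#   delta_e = delta_sd * ( b_e * r + sqrt(1 - b_e^2) * eps )
# so the population standardized partial coefficient of sym on delta_e
# (given sex and baseline) is b_e * sqrt(1 - gamma^2/4) — within half a
# percent of b_e at the default gamma. Null edges are pure noise. Baselines
# are population mean connectivity plus between-subject noise, TP2 = TP1 +
# delta, and all correlations are clipped to [-0.999, 0.999] with the clip
# rate monitored (> max_clip_rate aborts rather than silently distorting).

GENERATOR_VERSION <- "0.1.0"

#' Desk-scale default parcellation for simulation
#'
#' 48 cortical ROIs split over six resting-state networks (eight parcels
#' each, alternating hemispheres) plus six subcortical basal-ganglia ROIs
#' named after the seeds a basothalamo-cortical analysis reports on. A
#' desk-scale stand-in for a 256-parcel cortical atlas plus basal-ganglia
#' parcellation.
#'
#' @param p_cortical number of cortical ROIs (divided as evenly as possible
#'   over the networks)
#' @param p_subcortical number of subcortical ROIs
#' @param networks cortical network labels
#' @return a [parcellation]
#' @export
default_parcellation <- function(p_cortical = 48L, p_subcortical = 6L,
                                 networks = c("control", "default_mode",
                                              "dorsal_attention", "limbic",
                                              "salience", "somatomotor")) {
  stopifnot(p_cortical >= length(networks), p_subcortical >= 1L)
  net <- rep(networks, length.out = p_cortical)
  net <- net[order(match(net, networks))]
  hemi <- rep(c("L", "R"), length.out = p_cortical)
  cort <- data.frame(
    roi_name = paste0(net, "_", hemi, "_",
                      stats::ave(seq_len(p_cortical), net, hemi,
                                 FUN = seq_along)),
    hemisphere = hemi, roi_class = "cortical", network = net,
    stringsAsFactors = FALSE)
  sub_names <- c("stn_R", "rn_L", "thalamus_middle", "thalamus_inferior",
                 "caudate_inferior", "hippocampus_anterior")
  sub_hemi <- c("R", "L", "bilateral", "bilateral", "bilateral", "bilateral")
  if (p_subcortical > length(sub_names)) {
    extra <- paste0("subcortical_", seq_len(p_subcortical - length(sub_names)))
    sub_names <- c(sub_names, extra)
    sub_hemi <- c(sub_hemi, rep("bilateral", length(extra)))
  }
  sub <- data.frame(roi_name = sub_names[seq_len(p_subcortical)],
                    hemisphere = sub_hemi[seq_len(p_subcortical)],
                    roi_class = "subcortical", network = "basal_ganglia",
                    stringsAsFactors = FALSE)
  parcellation(rbind(cort, sub))
}

#' Simulation configuration
#'
#' @param n_subjects cohort size
#' @param scheme parcellation to simulate on (default: desk-scale 48 + 6,
#'   see [default_parcellation()])
#' @param planted_edges `NULL` or data.frame with columns `roi_a`, `roi_b`
#'   (ROI names or 0-based ids) and `effect` (standardized coupling b_e in
#'   (-1, 1)) — symptom-linked connectivity *change*
#' @param planted_tp1 same layout; couplings of baseline *levels* to the
#'   TP1 symptom factor (tests the covariate pathway)
#' @param sex_effect standardized symptom shift of the sex = 1 level versus
#'   sex = 0 (default -0.24, the scale a cohort study of painful symptoms
#'   reports for sex)
#' @param baseline_within,baseline_between population mean rsFC for
#'   within-network cortical edges and for all other edges
#' @param baseline_sd between-subject sd of baseline rsFC
#' @param delta_sd sd of connectivity change per edge
#' @param symptom_noise_sd extra measurement noise mixed into the outcome
#'   (default 0; positive values attenuate recovered couplings by
#'   `1/sqrt(1 + sd^2)`)
#' @param mode `"connectome"` (edges drawn directly) or `"timeseries"` (per
#'   subject and time point, a T x P series is drawn from a multivariate
#'   normal whose correlation is the subject's target connectome, projected
#'   to the nearest valid correlation matrix; connectomes are then built
#'   from the series)
#' @param t_len series length for `mode = "timeseries"`
#' @param seed mandatory RNG seed
#' @param clip correlations clipped to `[-clip, clip]`
#' @param max_clip_rate abort if more than this fraction of entries clip
#' @return a `sim_config`
#' @export
sim_config <- function(n_subjects = 200L, scheme = default_parcellation(),
                       planted_edges = NULL, planted_tp1 = NULL,
                       sex_effect = -0.24,
                       baseline_within = 0.3, baseline_between = 0.05,
                       baseline_sd = 0.1, delta_sd = 0.1,
                       symptom_noise_sd = 0,
                       mode = c("connectome", "timeseries"), t_len = 200L,
                       seed, clip = 0.999, max_clip_rate = 0.01) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_subjects >= 1L, baseline_sd > 0, delta_sd > 0,
            symptom_noise_sd >= 0, abs(sex_effect) < 2)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), scheme = scheme,
    planted_edges = planted_edges, planted_tp1 = planted_tp1,
    sex_effect = sex_effect, baseline_within = baseline_within,
    baseline_between = baseline_between, baseline_sd = baseline_sd,
    delta_sd = delta_sd, symptom_noise_sd = symptom_noise_sd,
    mode = mode, t_len = as.integer(t_len), seed = as.integer(seed),
    clip = clip, max_clip_rate = max_clip_rate),
    class = "sim_config")
  cfg$planted_edges <- normalize_planted(planted_edges, scheme)
  cfg$planted_tp1 <- normalize_planted(planted_tp1, scheme)
  cfg
}

# Resolve a planted-edge table to edge-vector positions; validate couplings.
normalize_planted <- function(pe, scheme) {
  if (is.null(pe)) return(NULL)
  pe <- as.data.frame(pe)
  stopifnot(all(c("roi_a", "roi_b", "effect") %in% names(pe)))
  a <- resolve_rois(scheme, pe$roi_a)
  b <- resolve_rois(scheme, pe$roi_b)
  if (any(a == b)) stop("planted edge with identical endpoints", call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (any(abs(pe$effect) >= 1)) {
    stop("planted couplings must lie in (-1, 1)", call. = FALSE)
  }
  p <- nrow(scheme)
  # row-major upper-triangle position of (lo, hi), 1-based
  pos <- (lo - 1L) * p - (lo - 1L) * lo / 2 + (hi - lo)
  if (anyDuplicated(pos)) stop("duplicated planted edge", call. = FALSE)
  data.frame(roi_a = scheme$roi_id[lo], roi_b = scheme$roi_id[hi],
             roi_a_name = scheme$roi_name[lo], roi_b_name = scheme$roi_name[hi],
             edge_pos = as.integer(pos), effect = pe$effect,
             stringsAsFactors = FALSE)
}

#' Per-edge couplings that plant a target cortical-integration effect
#'
#' Planting the same coupling b on every seed-to-cortex edge of a block of m
#' edges yields a mean-delta statistic whose standardized association with
#' the symptom score is `g*b / sqrt(b^2 + (1-b^2)/m)` with
#' `g = sqrt(1 - sex_effect^2/4)`. This helper inverts that relation: it
#' returns the planted-edge table whose block produces a cortical-integration
#' standardized coefficient of `effect`.
#'
#' @param scheme a [parcellation]
#' @param target subcortical seed ROI(s)
#' @param effect target standardized integration coefficient
#' @param sex_effect the generator's sex effect (needed for g)
#' @return data.frame suitable for `sim_config(planted_edges = ...)`
#' @export
integration_block_effects <- function(scheme, target, effect,
                                      sex_effect = -0.24) {
  pos <- resolve_rois(scheme, target)
  cort <- cortical_rois(scheme)
  m <- length(pos) * length(cort)
  g2 <- 1 - sex_effect^2 / 4
  b <- effect / sqrt(m * (g2 - effect^2) + effect^2)
  grid <- expand.grid(a = pos, b = cort)
  data.frame(roi_a = scheme$roi_name[grid$a],
             roi_b = scheme$roi_name[grid$b],
             effect = b, stringsAsFactors = FALSE)
}

# population mean edge vector: within-network cortical edges get
# baseline_within, everything else baseline_between
population_mean <- function(cfg) {
  scheme <- cfg$scheme
  ei <- edge_index(nrow(scheme))
  a <- ei$roi_a + 1L
  b <- ei$roi_b + 1L
  within <- scheme$roi_class[a] == "cortical" &
    scheme$roi_class[b] == "cortical" &
    scheme$network[a] == scheme$network[b]
  ifelse(within, cfg$baseline_within, cfg$baseline_between)
}

#' Simulate a two-time-point cohort with planted symptom-linked change
#'
#' @param config a [sim_config()]
#' @return list with `dataset` (a `cohort_dataset`) and `truth` (a
#'   `truth_record`: planted couplings, sex effect, seed, generator version,
#'   realized clip rate; in time-series mode also the per-subject target
#'   connectome vectors).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  scheme <- cfg$scheme
  e <- n_edges(scheme)

  sex <- stats::rbinom(n, 1L, 0.5)
  r_tp2 <- stats::rnorm(n)          # sex-adjusted symptom factor, TP2
  r_tp1 <- stats::rnorm(n)          # independent factor for the TP1 score
  g <- sqrt(1 - cfg$sex_effect^2 / 4)
  sym2 <- cfg$sex_effect * (sex - 0.5) + g * r_tp2
  sym1 <- cfg$sex_effect * (sex - 0.5) + g * r_tp1
  if (cfg$symptom_noise_sd > 0) {
    s <- cfg$symptom_noise_sd
    sym2 <- (sym2 + s * stats::rnorm(n)) / sqrt(1 + s^2)
    sym1 <- (sym1 + s * stats::rnorm(n)) / sqrt(1 + s^2)
  }

  mu <- population_mean(cfg)
  tp1 <- matrix(stats::rnorm(n * e), n, e)
  if (!is.null(cfg$planted_tp1)) {
    for (i in seq_len(nrow(cfg$planted_tp1))) {
      j <- cfg$planted_tp1$edge_pos[i]
      bb <- cfg$planted_tp1$effect[i]
      tp1[, j] <- bb * r_tp1 + sqrt(1 - bb^2) * tp1[, j]
    }
  }
  tp1 <- sweep(tp1 * cfg$baseline_sd, 2L, mu, "+")

  delta <- matrix(stats::rnorm(n * e), n, e)
  if (!is.null(cfg$planted_edges)) {
    for (i in seq_len(nrow(cfg$planted_edges))) {
      j <- cfg$planted_edges$edge_pos[i]
      bb <- cfg$planted_edges$effect[i]
      delta[, j] <- bb * r_tp2 + sqrt(1 - bb^2) * delta[, j]
    }
  }
  delta <- delta * cfg$delta_sd

  tp2 <- tp1 + delta
  n_clipped <- sum(abs(tp1) > cfg$clip) + sum(abs(tp2) > cfg$clip)
  clip_rate <- n_clipped / (2 * length(tp1))
  if (clip_rate > cfg$max_clip_rate) {
    stop(structure(class = c("deltacwas_clip_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("clip rate %.3f exceeds %.3f; reduce baseline_sd/",
                            "delta_sd or baseline means"),
                     clip_rate, cfg$max_clip_rate), call = NULL)))
  }
  tp1 <- pmin(pmax(tp1, -cfg$clip), cfg$clip)
  tp2 <- pmin(pmax(tp2, -cfg$clip), cfg$clip)

  population <- NULL
  if (cfg$mode == "timeseries") {
    population <- list(tp1 = tp1, tp2 = tp2)
    for (i in seq_len(n)) {
      for (tp in c("tp1", "tp2")) {
        target <- devectorize_edges(population[[tp]][i, ], diagonal = 1)
        pop <- nearest_correlation(target)
        ts <- draw_mvn_series(cfg$t_len, pop)
        cm <- build_connectome(ts, scheme, time_point = toupper(tp))
        v <- vectorize_edges(cm$values)$values
        if (tp == "tp1") tp1[i, ] <- v else tp2[i, ] <- v
      }
    }
  }

  ids <- sprintf("sub-%04d", seq_len(n))
  dataset <- new_cohort(subject_id = ids, rsfc_tp1 = tp1, rsfc_tp2 = tp2,
                        symptoms_tp1 = sym1, symptoms_tp2 = sym2,
                        sex = sex, scheme = scheme)
  truth <- structure(list(
    planted_edges = truth_edges(cfg$planted_edges),
    planted_tp1 = truth_edges(cfg$planted_tp1),
    sex_effect = cfg$sex_effect, seed = cfg$seed,
    generator_version = GENERATOR_VERSION, mode = cfg$mode,
    clip_rate = clip_rate, population = population,
    config = cfg[setdiff(names(cfg), "scheme")]),
    class = "truth_record")
  list(dataset = dataset, truth = truth)
}

truth_edges <- function(pe) {
  if (is.null(pe)) return(NULL)
  data.frame(edge_id = paste(pe$roi_a_name, pe$roi_b_name, sep = "__"),
             pe[c("roi_a", "roi_b", "edge_pos", "effect")],
             stringsAsFactors = FALSE)
}

# T draws from N(0, R); R is projected/floored upstream so chol() of the
# eigenvalue-floored factorization is safe.
draw_mvn_series <- function(t_len, R) {
  MASS::mvrnorm(n = t_len, mu = rep(0, nrow(R)), Sigma = R)
}

#' Simulate a single-session two-group cohort with planted group shifts
#'
#' Patients and controls share the population connectome; each shifted edge's
#' patient mean is moved by `shift` between-subject standard deviations
#' (pooled SD units). Symptom scores carry the sex effect only, so the group
#' factor is null on phenotypes and planted solely in connectivity.
#'
#' @param config a [sim_config()]; `n_subjects` is ignored in favor of
#'   `n_patients`/`n_controls`
#' @param group_shift `NULL` or data.frame `roi_a`, `roi_b`, `shift`
#'   (patient-minus-control mean shift in units of `baseline_sd`)
#' @param n_patients,n_controls group sizes
#' @return list with `dataset` (single-time-point `cohort_dataset` with
#'   `group`) and `truth`.
#' @export
simulate_two_group <- function(config, group_shift = NULL,
                               n_patients = 29L, n_controls = 29L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- n_patients + n_controls
  scheme <- cfg$scheme
  e <- n_edges(scheme)
  group <- c(rep("patient", n_patients), rep("control", n_controls))
  sex <- stats::rbinom(n, 1L, 0.5)
  g <- sqrt(1 - cfg$sex_effect^2 / 4)
  sym <- cfg$sex_effect * (sex - 0.5) + g * stats::rnorm(n)

  shifts <- normalize_planted(
    if (is.null(group_shift)) NULL else
      data.frame(roi_a = group_shift$roi_a, roi_b = group_shift$roi_b,
                 effect = 0, shift = group_shift$shift),
    scheme)
  if (!is.null(shifts)) shifts$shift <- group_shift$shift

  mu <- population_mean(cfg)
  rsfc <- sweep(matrix(stats::rnorm(n * e), n, e) * cfg$baseline_sd,
                2L, mu, "+")
  if (!is.null(shifts)) {
    pat <- group == "patient"
    for (i in seq_len(nrow(shifts))) {
      j <- shifts$edge_pos[i]
      rsfc[pat, j] <- rsfc[pat, j] + shifts$shift[i] * cfg$baseline_sd
    }
  }
  n_clipped <- sum(abs(rsfc) > cfg$clip)
  clip_rate <- n_clipped / length(rsfc)
  if (clip_rate > cfg$max_clip_rate) {
    stop(structure(class = c("deltacwas_clip_error", "error", "condition"),
                   list(message = sprintf("clip rate %.3f exceeds %.3f",
                                          clip_rate, cfg$max_clip_rate),
                        call = NULL)))
  }
  rsfc <- pmin(pmax(rsfc, -cfg$clip), cfg$clip)

  ids <- sprintf("sub-%04d", seq_len(n))
  dataset <- new_cohort(subject_id = ids, rsfc_tp1 = rsfc,
                        symptoms_tp1 = sym, sex = sex, group = group,
                        scheme = scheme)
  truth <- structure(list(
    group_shift = if (is.null(shifts)) NULL else
      data.frame(edge_id = paste(shifts$roi_a_name, shifts$roi_b_name,
                                 sep = "__"),
                 shifts[c("roi_a", "roi_b", "edge_pos", "shift")],
                 stringsAsFactors = FALSE),
    sex_effect = cfg$sex_effect, seed = cfg$seed,
    n_patients = n_patients, n_controls = n_controls,
    generator_version = GENERATOR_VERSION, clip_rate = clip_rate,
    config = cfg[setdiff(names(cfg), "scheme")]),
    class = "truth_record")
  list(dataset = dataset, truth = truth)
}
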
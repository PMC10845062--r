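# Cohort container: subjects x edges rsFC matrices plus phenotypes.

# Internal constructor; all user paths go through assemble_cohort() or the
# simulator, both of which end here.
new_cohort <- function(subject_id, rsfc_tp1, rsfc_tp2 = NULL,
                       symptoms_tp1 = NULL, symptoms_tp2 = NULL,
                       sex, group = NULL, scheme,
                       sex_coding = c(female = 0L, male = 1L)) {
  ei <- edge_index(nrow(scheme))
  delta <- if (!is.null(rsfc_tp2)) rsfc_tp2 - rsfc_tp1 else NULL
  x <- structure(list(
    subject_id = as.character(subject_id),
    rsfc_tp1 = rsfc_tp1, rsfc_tp2 = rsfc_tp2, delta = delta,
    symptoms_tp1 = symptoms_tp1, symptoms_tp2 = symptoms_tp2,
    sex = as.integer(sex), group = group,
    scheme = scheme, edge_index = ei, sex_coding = sex_coding),
    class = "cohort_dataset")
  validate_cohort(x)
  x
}

#' Validate the internal consistency of a cohort dataset
#'
#' Checks row-count agreement across connectivity matrices and phenotype
#' vectors, exact `delta == rsfc_tp2 - rsfc_tp1`, absence of missing values,
#' and edge-universe width. Called by every constructor; exported because it
#' is cheap and useful after manual surgery on a cohort.
#'
#' @param x a `cohort_dataset`
#' @return `x`, invisibly; errors on violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort_dataset"))
  n <- length(x$subject_id)
  if (anyDuplicated(x$subject_id)) {
    stop("duplicated subject_id", call. = FALSE)
  }
  e <- n_edges(x$scheme)
  for (f in c("rsfc_tp1", "rsfc_tp2", "delta")) {
    m <- x[[f]]
    if (is.null(m)) next
    if (nrow(m) != n) stop(f, ": row count mismatch", call. = FALSE)
    if (ncol(m) != e) stop(f, ": expected ", e, " edges, got ", ncol(m),
                           call. = FALSE)
    if (anyNA(m)) stop(f, ": missing values present", call. = FALSE)
  }
  if (!is.null(x$rsfc_tp2)) {
    if (is.null(x$delta) ||
        !isTRUE(all.equal(x$delta, x$rsfc_tp2 - x$rsfc_tp1, tolerance = 0))) {
      stop("delta must equal rsfc_tp2 - rsfc_tp1 exactly", call. = FALSE)
    }
  }
  for (f in c("symptoms_tp1", "symptoms_tp2", "sex")) {
    v <- x[[f]]
    if (is.null(v)) next
    if (length(v) != n) stop(f, ": length mismatch", call. = FALSE)
    if (anyNA(v)) stop(f, ": missing values present", call. = FALSE)
  }
  if (!all(x$sex %in% c(0L, 1L))) stop("sex must be coded 0/1", call. = FALSE)
  if (!is.null(x$group)) {
    if (length(x$group) != n) stop("group: length mismatch", call. = FALSE)
    if (!all(x$group %in% c("patient", "control"))) {
      stop("group must be 'patient' or 'control'", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d subjects, %d ROIs, %d edges, %s\n",
              length(x$subject_id), n_roi(x$scheme), n_edges(x$scheme),
              if (is.null(x$rsfc_tp2)) "single time point"
              else "two time points"))
  if (!is.null(x$group)) {
    cat("groups:", paste(names(table(x$group)), table(x$group),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a `cohort_dataset`
#' @export
n_subjects <- function(x) length(x$subject_id)

#' Assemble a longitudinal cohort from per-subject connectomes and phenotypes
#'
#' Complete-case assembly: a subject is retained only if both time-point
#' connectomes and all phenotype fields are present. No imputation is
#' performed. Dropped subjects are reported via `message()`.
#'
#' @param connectomes named list (by subject id); each element a list with
#'   components `tp1` and `tp2`, each a `connectome` (see
#'   [build_connectome()]) on the same parcellation.
#' @param phenotypes data.frame with columns `subject_id`, `sex`,
#'   `symptoms_tp1`, `symptoms_tp2` and optionally `group`. `sex` may be
#'   numeric 0/1 or a two-level character/factor; character levels are mapped
#'   by `sex_coding` (default: first level alphabetically is 0).
#' @param scheme the [parcellation] shared by all connectomes.
#' @param sex_coding named 0/1 map for character sex codes, or `NULL` to
#'   derive it alphabetically from the data.
#' @return A `cohort_dataset`.
#' @export
assemble_cohort <- function(connectomes, phenotypes, scheme,
                            sex_coding = NULL) {
  phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "symptoms_tp1", "symptoms_tp2")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  phenotypes$subject_id <- as.character(phenotypes$subject_id)
  if (anyDuplicated(phenotypes$subject_id)) {
    stop("duplicated subject_id in phenotype table", call. = FALSE)
  }

  sex_raw <- phenotypes$sex
  if (is.numeric(sex_raw)) {
    if (!all(stats::na.omit(sex_raw) %in% c(0, 1))) {
      stop("numeric sex codes must be 0/1", call. = FALSE)
    }
    sex_num <- as.integer(sex_raw)
    sex_coding <- sex_coding %||% c(`0` = 0L, `1` = 1L)
  } else {
    lev <- sort(unique(as.character(stats::na.omit(sex_raw))))
    if (is.null(sex_coding)) {
      if (length(lev) > 2L) {
        stop("sex has more than two levels: ", paste(lev, collapse = ", "),
             call. = FALSE)
      }
      sex_coding <- stats::setNames(seq_along(lev) - 1L, lev)
    }
    unknown <- setdiff(lev, names(sex_coding))
    if (length(unknown)) {
      stop("unparseable sex code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sex_num <- as.integer(sex_coding[as.character(sex_raw)])
  }

  ids <- phenotypes$subject_id
  has_conn <- vapply(ids, function(id) {
    ci <- connectomes[[id]]
    !is.null(ci) && !is.null(ci$tp1) && !is.null(ci$tp2)
  }, logical(1))
  has_pheno <- !is.na(sex_num) & !is.na(phenotypes$symptoms_tp1) &
    !is.na(phenotypes$symptoms_tp2)
  keep <- has_conn & has_pheno
  if (!any(keep)) stop("no subject has complete data", call. = FALSE)
  dropped <- ids[!keep]
  if (length(dropped)) {
    message("assemble_cohort: dropped ", length(dropped),
            " incomplete subject(s): ", paste(dropped, collapse = ", "))
  }
  message("assemble_cohort: retained ", sum(keep), " of ", length(ids),
          " subjects")

  href <- parcellation_hash(scheme)
  vec1 <- vec2 <- matrix(NA_real_, sum(keep), n_edges(scheme))
  kept_ids <- ids[keep]
  for (i in seq_along(kept_ids)) {
    ci <- connectomes[[kept_ids[i]]]
    for (tp in c("tp1", "tp2")) {
      cm <- ci[[tp]]
      stopifnot(inherits(cm, "connectome"))
      if (parcellation_hash(cm$scheme) != href) {
        stop("subject ", kept_ids[i], " ", tp,
             ": parcellation mismatch", call. = FALSE)
      }
    }
    vec1[i, ] <- vectorize_edges(ci$tp1$values)$values
    vec2[i, ] <- vectorize_edges(ci$tp2$values)$values
  }
  sel <- match(kept_ids, ids)
  new_cohort(subject_id = kept_ids, rsfc_tp1 = vec1, rsfc_tp2 = vec2,
             symptoms_tp1 = phenotypes$symptoms_tp1[sel],
             symptoms_tp2 = phenotypes$symptoms_tp2[sel],
             sex = sex_num[sel],
             group = if ("group" %in% names(phenotypes))
               as.character(phenotypes$group[sel]) else NULL,
             scheme = scheme, sex_coding = sex_coding)
}

#' Read per-subject ROI time series from a TSV/CSV file
#'
#' One file per subject per time point: T rows x P columns, header row of
#' ROI names matching the parcellation table.
#'
#' @param path file path; delimiter inferred from extension (`.csv` vs TSV).
#' @param scheme a [parcellation]; columns are checked and reordered.
#' @return numeric T x P matrix in scheme ROI order.
#' @export
read_timeseries <- function(path, scheme) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  ts <- as.matrix(tab)
  pos <- match(scheme$roi_name, colnames(ts))
  if (anyNA(pos)) {
    stop("time-series file ", path, " lacks ROI column(s): ",
         paste(scheme$roi_name[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  ts[, pos, drop = FALSE]
}
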
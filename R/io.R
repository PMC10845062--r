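# Plain-text serialization: TSV tables with JSON sidecars. Formats round-trip
# exactly enough for downstream analysis (full double precision on write).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort dataset to a directory of TSV files
#'
#' Produces `parcellation.tsv`, `phenotypes.tsv`, and wide edge tables
#' `rsfc_tp1.tsv` (+ `rsfc_tp2.tsv` for longitudinal cohorts) with a
#' `subject_id` column followed by one column per edge id (`roiA__roiB`),
#' plus a `cohort.json` sidecar recording the parcellation hash and options.
#' Delta is not written: it is recomputed exactly as TP2 - TP1 on read.
#'
#' @param dataset a `cohort_dataset`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- dataset$scheme
  write_parcellation(scheme, file.path(dir, "parcellation.tsv"))
  ph <- data.frame(subject_id = dataset$subject_id, sex = dataset$sex,
                   symptoms_tp1 = dataset$symptoms_tp1 %||%
                     rep(NA_real_, n_subjects(dataset)),
                   symptoms_tp2 = dataset$symptoms_tp2 %||%
                     rep(NA_real_, n_subjects(dataset)),
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$group)) ph$group <- dataset$group
  write_tsv(ph, file.path(dir, "phenotypes.tsv"))
  ids <- edge_ids(dataset$edge_index, scheme)
  for (f in c("rsfc_tp1", "rsfc_tp2")) {
    if (is.null(dataset[[f]])) next
    wide <- data.frame(subject_id = dataset$subject_id,
                       dataset[[f]], check.names = FALSE,
                       stringsAsFactors = FALSE)
    names(wide) <- c("subject_id", ids)
    write_tsv(wide, file.path(dir, paste0(f, ".tsv")))
  }
  sidecar <- list(parcellation_hash = parcellation_hash(scheme),
                  n_subjects = n_subjects(dataset),
                  n_edges = n_edges(scheme),
                  longitudinal = !is.null(dataset$rsfc_tp2),
                  has_group = !is.null(dataset$group),
                  written = stamp())
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort dataset written by [write_cohort()]
#' @param dir directory containing the cohort TSV files
#' @return a `cohort_dataset`
#' @export
read_cohort <- function(dir) {
  scheme <- load_parcellation(file.path(dir, "parcellation.tsv"))
  ph <- utils::read.delim(file.path(dir, "phenotypes.tsv"),
                          stringsAsFactors = FALSE)
  read_wide <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) return(NULL)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    expected <- edge_ids(edge_index(nrow(scheme)), scheme)
    if (!identical(colnames(m), expected)) {
      stop("edge columns of ", path, " do not match the parcellation",
           call. = FALSE)
    }
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  }
  tp1 <- read_wide("rsfc_tp1")
  tp2 <- read_wide("rsfc_tp2")
  s1 <- ph$symptoms_tp1
  s2 <- ph$symptoms_tp2
  new_cohort(subject_id = ph$subject_id, rsfc_tp1 = tp1, rsfc_tp2 = tp2,
             symptoms_tp1 = if (all(is.na(s1))) NULL else s1,
             symptoms_tp2 = if (all(is.na(s2))) NULL else s2,
             sex = ph$sex,
             group = if ("group" %in% names(ph)) ph$group else NULL,
             scheme = scheme)
}

#' Export edge-wise results as a long-format TSV with a JSON run manifest
#'
#' @param results an `edge_result_table` or `group_contrast_result`
#' @param path output TSV; the manifest is written next to it as
#'   `<path>.manifest.json`
#' @param seed seed to record in the manifest (if any)
#' @return `path`, invisibly
#' @export
write_edge_results <- function(results, path, seed = NULL) {
  if (inherits(results, "edge_result_table")) {
    df <- as.data.frame(results)
    manifest <- list(kind = "edge_result_table",
                     spec = unclass(results$spec), n = results$n,
                     df_resid = results$df_resid,
                     q = results$q, adjusted_term = results$adjusted_term)
  } else {
    df <- data.frame(edge_id = results$edge_id,
                     roi_a = results$edge_index$roi_a,
                     roi_b = results$edge_index$roi_b,
                     F = results$F, p = results$p,
                     p_adj_row_a = results$p_adj[, "row_a"],
                     p_adj_row_b = results$p_adj[, "row_b"],
                     sig_row_a = results$sig[, "row_a"],
                     sig_row_b = results$sig[, "row_b"],
                     direction = results$direction,
                     stringsAsFactors = FALSE)
    manifest <- list(kind = "group_contrast_result", n = results$n,
                     df_num = results$df_num, df_den = results$df_den,
                     q = results$q)
  }
  write_tsv(df, path)
  manifest$seed <- seed
  manifest$package_version <- as.character(utils::packageVersion("deltacwas"))
  manifest$r_version <- R.version.string
  manifest$written <- stamp()
  manifest$parcellation_hash <- parcellation_hash(results$scheme)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export a network frequency table as TSV
#' @param ft a `frequency_table`
#' @param path output TSV (seed ROIs as rows, networks as columns)
#' @param transpose write networks as rows instead
#' @export
write_frequency_table <- function(ft, path, transpose = FALSE) {
  m <- ft$frequency
  if (transpose) m <- t(m)
  df <- data.frame(rowname = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (transpose) "network" else "roi_name"
  write_tsv(df, path)
}

#' Export hub scores as TSV
#' @param hs data.frame from [hub_scores()]
#' @param path output TSV
#' @export
write_hub_scores <- function(hs, path) write_tsv(hs, path)

#' Export an integration model report as JSON
#' @param report a `model_report`
#' @param path output JSON
#' @export
write_model_report <- function(report, path) {
  jsonlite::write_json(
    list(terms = report$terms, r_squared = report$r_squared, f = report$f,
         df_model = report$df_model, df_resid = report$df_resid,
         p_model = report$p_model, n = report$n,
         warnings = report$warnings),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export a truth record as JSON
#' @param truth a `truth_record`
#' @param path output JSON
#' @export
write_truth <- function(truth, path) {
  tr <- unclass(truth)
  tr$population <- NULL   # bulky matrices; regenerable from the seed
  tr$config$scheme <- NULL
  jsonlite::write_json(tr, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
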
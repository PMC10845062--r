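# Aggregation of edge-wise results: network frequency tables and hub scores.

#' Network-wise frequency of significant edges for subcortical seeds
#'
#' For each subcortical seed ROI and each cortical network, the fraction of
#' the seed's possible edges to that network that are flagged significant in
#' the seed's own row after [rowwise_bh()]. The denominator of a cell is the
#' number of cortical ROIs carrying that network label; cells whose network
#' has no ROIs are reported `NA`.
#'
#' @param results an `edge_result_table` or `group_contrast_result` with
#'   row-wise adjusted p values
#' @param scheme the [parcellation] (defaults to the results' own)
#' @param rois subcortical seed ROIs; default: all subcortical ROIs
#' @param network_map optional named character vector collapsing parcellation
#'   network labels into coarser columns (e.g. 16 sub-networks to 7), applied
#'   before counting
#' @return A `frequency_table`: list of matrices `frequency`, `n_sig`,
#'   `n_total` (rows = seed ROIs, columns = networks).
#' @export
network_frequency <- function(results, scheme = results$scheme, rois = NULL,
                              network_map = NULL) {
  if (is.null(results$p_adj)) stop("apply rowwise_bh() first", call. = FALSE)
  pos <- if (is.null(rois)) subcortical_rois(scheme)
         else resolve_rois(scheme, rois)
  if (length(pos) == 0L) stop("no seed ROIs", call. = FALSE)
  nets <- scheme$network
  if (!is.null(network_map)) {
    mapped <- network_map[nets]
    nets <- ifelse(is.na(mapped), nets, mapped)
  }
  cort <- cortical_rois(scheme)
  labels <- sort(unique(nets[cort]))
  ei <- results$edge_index
  freq <- nsig <- ntot <- matrix(NA_real_, length(pos), length(labels),
                                 dimnames = list(scheme$roi_name[pos],
                                                 labels))
  for (i in seq_along(pos)) {
    r <- pos[i]
    idx <- edges_incident(ei, r)
    is_a <- ei$roi_a[idx] == r - 1L
    other <- ifelse(is_a, ei$roi_b[idx], ei$roi_a[idx]) + 1L
    flag <- ifelse(is_a, results$sig[idx, "row_a"], results$sig[idx, "row_b"])
    flag[is.na(flag)] <- FALSE
    for (j in seq_along(labels)) {
      members <- cort[nets[cort] == labels[j]]
      ntot[i, j] <- length(members)
      if (length(members) == 0L) next
      sel <- other %in% members
      nsig[i, j] <- sum(flag[sel])
      freq[i, j] <- nsig[i, j] / ntot[i, j]
    }
  }
  structure(list(frequency = freq, n_sig = nsig, n_total = ntot),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table (n_sig / n_total per seed ROI x network):\n")
  print(round(x$frequency, 3))
  invisible(x)
}

#' Signed hub scores from row-wise significant edges
#'
#' For each ROI, the number of significantly positively associated edges in
#' its row minus the number of significantly negative ones. Positive scores
#' mark hubs whose connectivity is predominantly positively associated with
#' the outcome, negative scores the reverse.
#'
#' @param results an `edge_result_table` after [rowwise_bh()]
#' @param scheme the [parcellation] (defaults to the results' own)
#' @return data.frame: `roi_id`, `roi_name`, `n_pos`, `n_neg`,
#'   `score = n_pos - n_neg`.
#' @export
hub_scores <- function(results, scheme = results$scheme) {
  if (is.null(results$p_adj)) stop("apply rowwise_bh() first", call. = FALSE)
  term <- results$adjusted_term
  ei <- results$edge_index
  out <- data.frame(roi_id = scheme$roi_id, roi_name = scheme$roi_name,
                    n_pos = 0L, n_neg = 0L, score = 0L,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(scheme))) {
    idx <- edges_incident(ei, r)
    is_a <- ei$roi_a[idx] == r - 1L
    flag <- ifelse(is_a, results$sig[idx, "row_a"], results$sig[idx, "row_b"])
    flag[is.na(flag)] <- FALSE
    b <- results$beta[idx, term]
    out$n_pos[r] <- sum(flag & b > 0)
    out$n_neg[r] <- sum(flag & b < 0)
  }
  out$score <- out$n_pos - out$n_neg
  out
}
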
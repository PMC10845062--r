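#' Construct a parcellation scheme
#'
#' A parcellation scheme lists the regions of interest (ROIs) that define the
#' edge universe of a connectome: a cortical atlas (e.g. a DiFuMo-style
#' functional parcellation, each parcel assigned to a resting-state network)
#' plus a subcortical set (e.g. basal-ganglia nuclei). ROI ids are assigned
#' contiguously from 0 in table order; the edge universe is the strict upper
#' triangle over all ROIs, `P*(P-1)/2` unordered pairs.
#'
#' @param table data.frame with columns `roi_name`, `hemisphere`
#'   (`"L"`, `"R"` or `"bilateral"`), `roi_class` (`"cortical"` or
#'   `"subcortical"`) and `network` (non-empty for every cortical ROI).
#' @return A `parcellation` object (a data.frame with a `roi_id` column
#'   prepended).
#' @examples
#' tab <- data.frame(
#'   roi_name   = c("smA", "smB", "limbicA", "stn_R"),
#'   hemisphere = c("L", "R", "bilateral", "R"),
#'   roi_class  = c("cortical", "cortical", "cortical", "subcortical"),
#'   network    = c("somatomotor", "somatomotor", "limbic", "basal_ganglia"))
#' p <- parcellation(tab)
#' n_roi(p)          # 4
#' n_edges(p)        # 6
#' @export
parcellation <- function(table) {
  required <- c("roi_name", "hemisphere", "roi_class", "network")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("parcellation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  table$roi_name <- as.character(table$roi_name)
  table$network <- as.character(table$network)
  if (anyDuplicated(table$roi_name)) {
    dup <- unique(table$roi_name[duplicated(table$roi_name)])
    stop("duplicated roi_name: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(unique(table$roi_class), c("cortical", "subcortical"))
  if (length(bad_class) > 0L) {
    stop("unknown roi_class value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  bad_hemi <- setdiff(unique(table$hemisphere), c("L", "R", "bilateral"))
  if (length(bad_hemi) > 0L) {
    stop("unknown hemisphere value(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  }
  cortical <- table$roi_class == "cortical"
  if (any(cortical & (is.na(table$network) | !nzchar(table$network)))) {
    stop("every cortical ROI needs a non-empty network label", call. = FALSE)
  }
  out <- data.frame(roi_id = seq_len(nrow(table)) - 1L,
                    table[required], stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Read a parcellation scheme from a TSV file
#'
#' @param path TSV with header columns `roi_name`, `hemisphere`, `roi_class`,
#'   `network`. Rows become ROIs in file order.
#' @return A [parcellation] object.
#' @export
load_parcellation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  parcellation(tab)
}

#' Write a parcellation scheme to a TSV file
#' @param scheme a [parcellation] object
#' @param path output file
#' @export
write_parcellation <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d ROIs (%d cortical, %d subcortical), %d edges\n",
              n_roi(x), sum(x$roi_class == "cortical"),
              sum(x$roi_class == "subcortical"), n_edges(x)))
  nets <- table(x$network[x$roi_class == "cortical"])
  if (length(nets)) {
    cat("cortical networks:",
        paste(sprintf("%s (%d)", names(nets), nets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of ROIs in a parcellation
#' @param scheme a [parcellation]
#' @return integer count
#' @export
n_roi <- function(scheme) nrow(scheme)

#' Size of the edge universe, P(P-1)/2
#' @param scheme a [parcellation]
#' @return integer number of unordered ROI pairs
#' @export
n_edges <- function(scheme) {
  p <- nrow(scheme)
  as.integer(p * (p - 1L) / 2L)
}

#' Row positions (1-based) of cortical / subcortical ROIs
#' @param scheme a [parcellation]
#' @return integer vector of row positions
#' @export
cortical_rois <- function(scheme) which(scheme$roi_class == "cortical")

#' @rdname cortical_rois
#' @export
subcortical_rois <- function(scheme) which(scheme$roi_class == "subcortical")

# Resolve ROI references (names, 0-based roi_id integers, or logical) to
# 1-based row positions; errors on anything unknown.
resolve_rois <- function(scheme, rois) {
  if (is.logical(rois)) {
    stopifnot(length(rois) == nrow(scheme))
    return(which(rois))
  }
  if (is.character(rois)) {
    pos <- match(rois, scheme$roi_name)
    if (anyNA(pos)) {
      stop("unknown ROI name(s): ", paste(rois[is.na(pos)], collapse = ", "),
           call. = FALSE)
    }
    return(pos)
  }
  if (is.numeric(rois)) {
    pos <- match(as.integer(rois), scheme$roi_id)
    if (anyNA(pos)) {
      stop("unknown roi_id(s): ", paste(rois[is.na(pos)], collapse = ", "),
           call. = FALSE)
    }
    return(pos)
  }
  stop("cannot interpret ROI selector of class ", class(rois)[1], call. = FALSE)
}

# Stable fingerprint of a parcellation (FNV-1a over the flattened table);
# used to detect scheme mismatches and recorded in run manifests.
parcellation_hash <- function(scheme) {
  fnv1a(paste(scheme$roi_name, scheme$hemisphere, scheme$roi_class,
              scheme$network, collapse = "|"))
}
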
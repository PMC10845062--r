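#' Build a Pearson-correlation connectome from ROI time series
#'
#' Computes the pairwise Pearson correlation between every pair of ROI time
#' series. Correlations are left raw ("unstandardized" connectomes); an
#' optional Fisher z-transform is available for sensitivity analyses and
#' defaults off.
#'
#' @param ts numeric T x P matrix (or data.frame) of ROI time series, one
#'   column per ROI. If it has column names they must match
#'   `scheme$roi_name` (any order is accepted and reordered to scheme order).
#' @param scheme a [parcellation] with P ROIs.
#' @param time_point `"TP1"` or `"TP2"`.
#' @param fisher_z if `TRUE`, off-diagonal entries are atanh-transformed.
#' @return A `connectome` object: list with `values` (P x P symmetric matrix,
#'   unit diagonal), `scheme`, `time_point`, `fisher_z`.
#' @export
build_connectome <- function(ts, scheme, time_point = c("TP1", "TP2"),
                             fisher_z = FALSE) {
  time_point <- match.arg(time_point)
  ts <- as.matrix(ts)
  storage.mode(ts) <- "double"
  if (!is.null(colnames(ts))) {
    pos <- match(scheme$roi_name, colnames(ts))
    if (anyNA(pos)) {
      stop("time series lacks ROI column(s): ",
           paste(scheme$roi_name[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    ts <- ts[, pos, drop = FALSE]
  } else if (ncol(ts) != nrow(scheme)) {
    stop("time series has ", ncol(ts), " columns but parcellation has ",
         nrow(scheme), " ROIs", call. = FALSE)
  }
  if (nrow(ts) < 3L) {
    stop("need at least 3 time points, got ", nrow(ts), call. = FALSE)
  }
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for ROI(s): ",
         paste(scheme$roi_name[sds == 0], collapse = ", "), call. = FALSE)
  }
  values <- stats::cor(ts)
  # cor() can return 1 +/- eps off the diagonal boundary; clamp defensively
  values[values > 1] <- 1
  values[values < -1] <- -1
  diag(values) <- 1
  if (fisher_z) {
    off <- row(values) != col(values)
    values[off] <- atanh(values[off])
  }
  dimnames(values) <- list(scheme$roi_name, scheme$roi_name)
  structure(list(values = values, scheme = scheme, time_point = time_point,
                 fisher_z = fisher_z),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome (%s): %d x %d Pearson matrix%s\n", x$time_point,
              nrow(x$values), ncol(x$values),
              if (x$fisher_z) ", Fisher z" else ""))
  invisible(x)
}

#' Connectivity change between two time points
#'
#' The longitudinal change statistic is the arithmetic difference of the two
#' connectomes, TP2 minus TP1, computed edge-wise.
#'
#' @param c1 `connectome` at TP1 (baseline)
#' @param c2 `connectome` at TP2 (follow-up)
#' @return P x P symmetric matrix of differences with zero diagonal.
#' @export
delta_connectome <- function(c1, c2) {
  stopifnot(inherits(c1, "connectome"), inherits(c2, "connectome"))
  if (!identical(dim(c1$values), dim(c2$values)) ||
      parcellation_hash(c1$scheme) != parcellation_hash(c2$scheme)) {
    stop("connectomes come from different parcellations", call. = FALSE)
  }
  if (!identical(c1$fisher_z, c2$fisher_z)) {
    stop("connectomes differ in Fisher-z setting", call. = FALSE)
  }
  d <- c2$values - c1$values
  diag(d) <- 0
  d
}

#' Vectorize the strict upper triangle of a symmetric edge matrix
#'
#' Edges are enumerated in row-major upper-triangle order:
#' (0,1), (0,2), ..., (0,P-1), (1,2), ... — the canonical unordered pair
#' (roi_a < roi_b). This ordering is the package-wide edge identity and is
#' exactly invertible via [devectorize_edges()].
#'
#' @param m P x P numeric matrix; must be symmetric within `tol`.
#' @param tol maximum tolerated absolute asymmetry (entries are averaged with
#'   the transpose before extraction).
#' @return An `edge_vector`: list with `values` (length P(P-1)/2) and
#'   `edge_index` (data.frame `roi_a`, `roi_b`, 0-based, roi_a < roi_b).
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol),
         call. = FALSE)
  }
  m <- (m + t(m)) / 2
  structure(list(values = t(m)[lower.tri(m)],
                 edge_index = edge_index(nrow(m))),
            class = "edge_vector")
}

#' @rdname vectorize_edges
#' @param v an `edge_vector` (or bare numeric of length P(P-1)/2)
#' @param diagonal value to place on the diagonal of the rebuilt matrix
#' @return `devectorize_edges`: the P x P symmetric matrix.
#' @export
devectorize_edges <- function(v, diagonal = 1) {
  values <- if (inherits(v, "edge_vector")) v$values else as.numeric(v)
  e <- length(values)
  p <- (1 + sqrt(1 + 8 * e)) / 2
  if (p != round(p)) stop("length ", e, " is not P(P-1)/2", call. = FALSE)
  p <- as.integer(p)
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- values  # row-major upper == column-major lower of t(m)
  m <- t(m)
  m <- m + t(m)
  diag(m) <- diagonal
  m
}

#' Edge enumeration for P ROIs
#'
#' @param p number of ROIs
#' @return data.frame with 0-based columns `roi_a < roi_b` in row-major
#'   upper-triangle order; one row per edge.
#' @export
edge_index <- function(p) {
  a <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  b <- unlist(lapply(seq_len(p - 1L), function(i) (i + 1L):p), use.names = FALSE)
  data.frame(roi_a = a - 1L, roi_b = b - 1L)
}

# edge ids "roiA__roiB" for an edge_index against a scheme
edge_ids <- function(ei, scheme) {
  paste(scheme$roi_name[ei$roi_a + 1L], scheme$roi_name[ei$roi_b + 1L],
        sep = "__")
}

# Positions (into the edge vector) of all edges incident to ROI at 1-based
# row position `pos`.
edges_incident <- function(ei, pos) {
  id0 <- pos - 1L
  which(ei$roi_a == id0 | ei$roi_b == id0)
}

# Positions of block edges between two ROI sets (1-based positions, disjoint).
edges_between <- function(ei, pos_a, pos_b) {
  a0 <- pos_a - 1L
  b0 <- pos_b - 1L
  which((ei$roi_a %in% a0 & ei$roi_b %in% b0) |
        (ei$roi_a %in% b0 & ei$roi_b %in% a0))
}
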
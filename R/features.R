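#' Functional-connectivity network from ROI BOLD time series
#'
#' Each ROI series is standardized to zero mean and unit variance and the
#' pairwise Pearson correlation matrix is taken as the weighted adjacency of
#' the subject's functional-connectivity (FC) network. The diagonal is set to
#' zero so self-connections never enter downstream graph metrics.
#'
#' @param series numeric matrix, `T` time points x `d` ROIs (`T >= 3`,
#'   `d >= 2`), column names = ROI labels.
#' @param roi_names optional character vector of ROI labels overriding
#'   `colnames(series)`.
#' @return an `fc_network`: symmetric `d x d` matrix of edge weights in
#'   `[-1, 1]` with zero diagonal and ROI dimnames.
#' @examples
#' ts <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("ROI", 1:4)))
#' fc <- compute_fc(ts)
#' @export
compute_fc <- function(series, roi_names = colnames(series)) {
  series <- as.matrix(series)
  if (is.null(roi_names)) roi_names <- paste0("ROI_", seq_len(ncol(series)))
  if (nrow(series) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (ncol(series) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  if (anyDuplicated(roi_names)) stop("ROI names must be unique", call. = FALSE)
  check_finite(series, "time series")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- roi_names[sds == 0]
    stop(sprintf("degenerate (zero-variance) series for ROI(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  w <- stats::cor(series)
  diag(w) <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- list(roi_names, roi_names)
  as_fc_network(w)
}

#' Construct or validate an FC network object
#'
#' @param weights symmetric numeric matrix with zero diagonal; dimnames are
#'   the ROI labels.
#' @return the validated matrix with class `fc_network`.
#' @export
as_fc_network <- function(weights) {
  weights <- as.matrix(weights)
  d <- nrow(weights)
  if (d != ncol(weights)) stop("weights must be square", call. = FALSE)
  check_finite(weights, "FC weights")
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("weights must be symmetric (tolerance 1e-12)", call. = FALSE)
  if (any(diag(weights) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (is.null(rownames(weights)))
    dimnames(weights) <- list(paste0("ROI_", seq_len(d)),
                              paste0("ROI_", seq_len(d)))
  class(weights) <- c("fc_network", class(weights))
  weights
}

#' Node degrees of an FC network
#'
#' @param fc an `fc_network`.
#' @return integer vector: number of incident nonzero edges per ROI.
#' @export
fc_degree <- function(fc) {
  rowSums(unclass(fc) != 0)
}

#' Weighted clustering coefficients of an FC network
#'
#' For node i with degree `k_i >= 2` the coefficient is
#' \deqn{CC(i) = \frac{2}{k_i(k_i-1)} \sum_{\{j,h\}} \bar w_{ij}\,\bar w_{ih}\,\bar w_{jh},}
#' the sum running over unordered pairs of neighbours of i, with all weights
#' scaled by the maximum off-diagonal connection weight
#' (\eqn{\bar w = w / \max(w)}). Nodes with fewer than two neighbours score 0.
#' On a unit-weight graph this reduces to the binary clustering coefficient
#' (closed triples over possible triples).
#'
#' Pearson FC matrices contain negative weights; the scaling presumes
#' nonnegative weights bounded by `max(w)`, so negative entries are either
#' replaced by their absolute value (default) or clipped to zero before
#' scaling. Setting `geometric = TRUE` uses the cube-root (geometric-mean)
#' triple weight instead of the plain product.
#'
#' @param fc an `fc_network`.
#' @param negative how to handle negative weights: `"abs"` (default) or
#'   `"zero"` (clip to 0).
#' @param geometric logical; use the cube root of each scaled weight in the
#'   triple product (off by default).
#' @param threshold optional proportional threshold in (0, 1]: keep only the
#'   strongest fraction of edges by absolute weight before anything else.
#'   `NULL` (default) keeps the fully weighted network.
#' @return named numeric vector of per-ROI clustering coefficients in
#'   `[0, 1]`, with attribute `modality = "edge"`.
#' @export
clustering_coefficients <- function(fc, negative = c("abs", "zero"),
                                    geometric = FALSE, threshold = NULL) {
  negative <- match.arg(negative)
  w <- unclass(as_fc_network(fc))
  d <- nrow(w)
  roi <- rownames(w)
  if (!is.null(threshold)) {
    stopifnot(threshold > 0, threshold <= 1)
    off <- abs(w[upper.tri(w)])
    if (threshold < 1) {
      cut <- stats::quantile(off, probs = 1 - threshold, names = FALSE)
      w[abs(w) < cut] <- 0
    }
  }
  if (negative == "abs") w <- abs(w) else w[w < 0] <- 0
  maxw <- max(w)
  cc <- stats::setNames(numeric(d), roi)
  if (maxw == 0) {
    warning("all-zero network: clustering coefficients set to 0", call. = FALSE)
    attr(cc, "modality") <- "edge"
    return(cc)
  }
  wbar <- w / maxw
  b <- if (geometric) wbar^(1 / 3) else wbar
  # diag(B^3)_i = sum over ordered neighbour pairs (j,h) of b_ij b_jh b_hi;
  # halving gives the unordered-pair sum of the formula above
  tri <- diag(b %*% b %*% b)
  k <- rowSums(w != 0)
  ok <- k >= 2
  cc[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  attr(cc, "modality") <- "edge"
  cc
}

#' ROI-mean node features from a density volume and an atlas
#'
#' Averages a (gray-matter) density volume within each atlas region, giving
#' one node feature per ROI. Volumes must already be co-registered in the
#' same voxel grid; label 0 is background.
#'
#' @param density numeric 3-D array of voxel densities.
#' @param atlas integer 3-D array of region labels, same shape as `density`.
#' @param label_map named integer vector or two-column data frame
#'   (`label`, `roi`) mapping atlas labels to ROI names.
#' @return named numeric vector of per-ROI mean densities with attribute
#'   `modality = "node"`.
#' @export
extract_node_features <- function(density, atlas, label_map) {
  if (!identical(dim(density), dim(atlas)))
    stop("density and atlas volumes have different dimensions", call. = FALSE)
  if (is.data.frame(label_map)) {
    lm <- stats::setNames(as.integer(label_map[[1]]), as.character(label_map[[2]]))
  } else {
    lm <- stats::setNames(as.integer(label_map), names(label_map))
  }
  check_finite(density, "density volume")
  labs <- as.integer(atlas)
  missing <- lm[!(lm %in% labs)]
  if (length(missing))
    stop(sprintf("atlas labels absent from volume: %s",
                 paste(sprintf("%s (%d)", names(missing), missing), collapse = ", ")),
         call. = FALSE)
  dens <- as.numeric(density)
  vals <- vapply(lm, function(l) mean(dens[labs == l]), numeric(1))
  out <- stats::setNames(as.numeric(vals), names(lm))
  attr(out, "modality") <- "node"
  out
}

#' Elementwise mean of a group of FC networks
#'
#' @param networks nonempty list of `fc_network` objects sharing ROI names.
#' @return an `fc_network` holding the group-average connectivity.
#' @export
group_mean_fc <- function(networks) {
  if (length(networks) == 0L) stop("empty group of networks", call. = FALSE)
  networks <- lapply(networks, as_fc_network)
  roi <- rownames(networks[[1]])
  for (nw in networks[-1]) {
    if (!identical(rownames(nw), roi))
      stop("networks have mismatched ROI names", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(networks, unclass)) / length(networks)
  as_fc_network(avg)
}

#' Strongest edges incident to one ROI
#'
#' Returns the `k` edges of `roi` with the highest connection weight,
#' sorted in decreasing weight (ties broken by partner ROI name so output
#' is deterministic).
#'
#' @param fc an `fc_network`.
#' @param roi ROI name present in the network.
#' @param k number of edges, `1 <= k <= d - 1`.
#' @param use_abs rank by absolute weight instead of signed weight.
#' @return data frame with columns `partner` and `weight`, `k` rows.
#' @export
top_k_edges <- function(fc, roi, k, use_abs = FALSE) {
  fc <- as_fc_network(fc)
  roi_names <- rownames(fc)
  if (!roi %in% roi_names)
    stop(sprintf("unknown ROI: %s", roi), call. = FALSE)
  d <- nrow(fc)
  stopifnot(k >= 1, k <= d - 1)
  w <- unclass(fc)[roi, ]
  w <- w[names(w) != roi]
  key <- if (use_abs) abs(w) else w
  ord <- order(-key, names(w))
  sel <- ord[seq_len(k)]
  data.frame(partner = names(w)[sel], weight = unname(w[sel]),
             stringsAsFactors = FALSE)
}

#' Node features directly from NIfTI volumes
#'
#' Reads a density volume and an integer atlas volume (NIfTI, via the
#' suggested RNifti package) plus a two-column label-map TSV
#' (`label`, `roi`) and returns the per-ROI mean densities. Volumes must be
#' co-registered on the same voxel grid; no resampling is attempted. A
#' packaged 116-name AAL label map ships at
#' `system.file("extdata", "aal116_labels.tsv", package = "msdmm")`.
#'
#' @param density_path path to the density NIfTI.
#' @param atlas_path path to the integer-label atlas NIfTI.
#' @param label_map_path path to the label-map TSV.
#' @return named numeric vector as [extract_node_features()].
#' @export
node_features_from_nifti <- function(density_path, atlas_path,
                                     label_map_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  density <- array(as.numeric(RNifti::readNifti(density_path)),
                   dim(RNifti::readNifti(density_path)))
  atlas_img <- RNifti::readNifti(atlas_path)
  atlas <- array(as.integer(round(as.numeric(atlas_img))), dim(atlas_img))
  lm <- utils::read.delim(label_map_path, stringsAsFactors = FALSE)
  extract_node_features(density, atlas, lm[, c("label", "roi")])
}
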
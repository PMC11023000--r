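#' Default distance-histogram bin edges
#'
#' 20 equal bins spanning 0-100 mm; distances at or beyond 100 mm are clamped
#' into the last bin.
#' @param n_bins number of bins (default 20).
#' @param d_max upper edge in mm (default 100).
#' @return numeric vector of `n_bins + 1` edges.
#' @export
default_bin_edges <- function(n_bins = 20L, d_max = 100) {
  seq(0, d_max, length.out = n_bins + 1L)
}

# internal: bin a vector of distances (mm); out-of-range clamped into last bin
.bin_distances <- function(d, edges) {
  n_bins <- length(edges) - 1L
  b <- findInterval(d, edges)
  b[b < 1L] <- 1L
  b[b > n_bins] <- n_bins
  tabulate(b, nbins = n_bins)
}

#' Bundle binary structure masks sharing one voxel grid
#'
#' @param ctv,bladder,rectum,sigmoid 3-D logical (or 0/1) arrays on the same
#'   grid; each must be non-empty.
#' @param voxel_size mm per voxel along each axis (default `c(1, 1, 1)`).
#' @param origin world coordinate (mm) of the center of voxel `[1, 1, 1]`.
#' @return list of class `structure_mask_set`.
#' @export
structure_mask_set <- function(ctv, bladder, rectum, sigmoid,
                               voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  masks <- list(ctv = ctv, bladder = bladder, rectum = rectum, sigmoid = sigmoid)
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all masks must share one grid", call. = FALSE)
  }
  for (s in names(masks)) {
    masks[[s]] <- array(as.logical(masks[[s]]), dim = dim(masks[[s]]))
    if (!any(masks[[s]])) stop(sprintf("empty structure mask: %s", s), call. = FALSE)
  }
  structure(list(masks = masks, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "structure_mask_set")
}

# internal: world coordinates (n x 3, mm) of the centers of TRUE voxels
.mask_coords <- function(mask, voxel_size, origin) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, voxel_size, `*`), 2, origin, `+`)
}

#' CTV distance histogram (distance to nearest dwell position)
#'
#' For every voxel inside the CTV, the Euclidean distance to the nearest dwell
#' position, binned into the distance histogram.
#'
#' @param ctv_mask 3-D logical array.
#' @param dwells matrix of dwell positions, `m x 3`, mm, in the mask frame.
#' @param voxel_size,origin grid geometry (mm).
#' @param bin_edges histogram edges (mm); see [default_bin_edges()].
#' @return integer vector of bin counts.
#' @export
ctv_distance_histogram <- function(ctv_mask, dwells, voxel_size = c(1, 1, 1),
                                   origin = c(0, 0, 0),
                                   bin_edges = default_bin_edges()) {
  if (!any(ctv_mask)) stop("empty structure: CTV", call. = FALSE)
  dwells <- as.matrix(dwells)
  if (nrow(dwells) == 0L || any(!is.finite(dwells))) {
    stop("dwell positions must be non-empty and finite", call. = FALSE)
  }
  xyz <- .mask_coords(ctv_mask, voxel_size, origin)
  dmin <- rep(Inf, nrow(xyz))
  for (k in seq_len(nrow(dwells))) {
    dk <- sqrt((xyz[, 1] - dwells[k, 1])^2 +
               (xyz[, 2] - dwells[k, 2])^2 +
               (xyz[, 3] - dwells[k, 3])^2)
    dmin <- pmin(dmin, dk)
  }
  .bin_distances(dmin, bin_edges)
}

#' Unsigned distance map to the CTV boundary
#'
#' Returns a volumetric image giving, for every grid voxel, the Euclidean
#' distance (mm) to the nearest CTV boundary voxel. A boundary voxel is a CTV
#' voxel with at least one non-CTV face (6-connectivity) neighbor; voxels on
#' the array edge count as adjacent to outside. The distance is unsigned:
#' zero on the boundary, positive on both sides.
#'
#' @param ctv_mask 3-D logical array, non-empty, not filling the whole grid.
#' @param voxel_size mm per voxel along each axis.
#' @return 3-D numeric array of distances in mm.
#' @export
ctv_boundary_distance_map <- function(ctv_mask, voxel_size = c(1, 1, 1)) {
  if (!any(ctv_mask)) stop("empty structure: CTV", call. = FALSE)
  b <- boundary_voxels(ctv_mask)
  if (!any(b)) stop("degenerate geometry: CTV has no boundary", call. = FALSE)
  .edt3d_cpp(as.logical(b), dim(ctv_mask), as.numeric(voxel_size))
}

#' Boundary voxels of a binary mask (6-connectivity)
#'
#' @param mask 3-D logical array.
#' @return logical array marking mask voxels with a non-mask face neighbor
#'   (out-of-grid counts as non-mask).
#' @export
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_all_inside <- function(ax, by) {
    # TRUE where the neighbor at offset `by` along axis `ax` is inside mask
    nb <- array(FALSE, dim = d)
    idx_to <- lapply(d, seq_len)
    idx_from <- idx_to
    n <- d[ax]
    if (by == 1L) { idx_to[[ax]] <- 1:(n - 1L); idx_from[[ax]] <- 2:n }
    else          { idx_to[[ax]] <- 2:n;        idx_from[[ax]] <- 1:(n - 1L) }
    nb <- do.call(`[<-`, c(list(nb), idx_to,
                           list(do.call(`[`, c(list(mask), idx_from)))))
    nb
  }
  for (ax in 1:3) {
    if (d[ax] == 1L) { interior[] <- FALSE; next }
    interior <- interior & shift_all_inside(ax, 1L) & shift_all_inside(ax, -1L)
  }
  mask & !interior
}

#' OAR distance histogram (boundary-map values inside the organ)
#'
#' Restricts a CTV boundary distance map to the voxels of an organ at risk and
#' bins the values into the distance histogram.
#'
#' @param oar_mask 3-D logical array (same grid as the map), non-empty.
#' @param boundary_map output of [ctv_boundary_distance_map()].
#' @param bin_edges histogram edges (mm).
#' @return integer vector of bin counts.
#' @export
oar_distance_histogram <- function(oar_mask, boundary_map,
                                   bin_edges = default_bin_edges()) {
  if (!identical(dim(oar_mask), dim(boundary_map))) {
    stop("mask and boundary map grids differ", call. = FALSE)
  }
  if (!any(oar_mask)) stop("empty structure: OAR", call. = FALSE)
  .bin_distances(boundary_map[oar_mask], bin_edges)
}

#' Build the 4 x 20 distance-histogram anatomy representation
#'
#' Row 1 is the CTV's histogram of voxel distances to the nearest dwell
#' position; rows 2-4 are the bladder/rectum/sigmoid histograms of unsigned
#' distance to the CTV boundary. With `normalization = "fraction"` each row is
#' divided by its sum so the networks see organ shape rather than volume;
#' `"counts"` keeps raw voxel counts (used by the consistency audit toggle).
#'
#' @param masks a [structure_mask_set()].
#' @param dwells dwell positions, `m x 3` mm.
#' @param normalization `"fraction"` (default) or `"counts"`.
#' @param bin_edges histogram edges (mm).
#' @return `anatomy_features`: a 4 x n matrix, rows named
#'   `r paste(STRUCTURES, collapse = ", ")`, with attributes `bin_edges` and
#'   `normalization`.
#' @export
build_anatomy <- function(masks, dwells, normalization = c("fraction", "counts"),
                          bin_edges = default_bin_edges()) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(masks, "structure_mask_set"))
  vs <- masks$voxel_size; or <- masks$origin
  bmap <- ctv_boundary_distance_map(masks$masks$ctv, vs)
  A <- rbind(
    ctv = ctv_distance_histogram(masks$masks$ctv, dwells, vs, or, bin_edges),
    bladder = oar_distance_histogram(masks$masks$bladder, bmap, bin_edges),
    rectum = oar_distance_histogram(masks$masks$rectum, bmap, bin_edges),
    sigmoid = oar_distance_histogram(masks$masks$sigmoid, bmap, bin_edges))
  A <- A * 1.0
  if (normalization == "fraction") A <- A / rowSums(A)
  structure(A, bin_edges = bin_edges, normalization = normalization,
            class = c("anatomy_features", "matrix", "array"))
}

#' Anatomy features from a plain matrix
#'
#' Wraps an existing 4 x n histogram matrix (e.g. read from CSV or produced by
#' the fast synthetic generator) as `anatomy_features`.
#' @param A 4 x n non-negative matrix, row order CTV, bladder, rectum, sigmoid.
#' @param bin_edges histogram edges (mm).
#' @param normalization `"fraction"` or `"counts"`.
#' @export
as_anatomy_features <- function(A, bin_edges = default_bin_edges(),
                                normalization = "fraction") {
  A <- as.matrix(A)
  stopifnot(nrow(A) == 4L, all(A >= 0))
  rownames(A) <- STRUCTURES
  structure(A, bin_edges = bin_edges, normalization = normalization,
            class = c("anatomy_features", "matrix", "array"))
}

#' Relative Frobenius distance between two anatomy representations
#'
#' `||A - B||_F / (||A||_F + ||B||_F)`, a pseudometric scaled to `[0, 1]`.
#' Pairs below 0.10 (with equal prescriptions) are treated as "similar
#' anatomies" by the consistency audit.
#'
#' @param a,b matrices of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
histogram_similarity <- function(a, b) {
  a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  stopifnot(identical(dim(a), dim(b)))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na + nb == 0) stop("similarity undefined for two all-zero matrices", call. = FALSE)
  sqrt(sum((a - b)^2)) / (na + nb)
}
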
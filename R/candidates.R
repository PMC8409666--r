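# 3D lesion candidates: 6-connected components of the binarized
# probability map, a minimum-size filter, and the 75-feature descriptor
# used by the random-forest false-positive filter.
#
# Feature layout (fixed order, 75 = 9 + 1 + 5 + 60):
#   9 location: centroid (x = row, y = column, z = slice), bounding-box
#     start x/y/z, bounding-box extent x/y/z — voxel units, 0-based
#     indices, half-open boxes;
#   1 scan-level: number of candidates in the scan (after size filtering);
#   5 shape: size in voxels; mean and SD of the eigenvalues of the
#     second-central-moment matrix of voxel coordinates in mm; axial
#     "diffusivity" (largest eigenvalue); radial (mean of the two
#     smaller) — DTI vocabulary borrowed as shape descriptors;
#   60 intensity: mean, SD, sum inside the candidate and in its 1-voxel
#     surrounding shell, for each of the 10 channels.

#' Names of the 75 candidate features, in layout order
#'
#' @return Character vector of length 75.
#' @export
feature_layout <- function() {
  loc <- c("centroid_x", "centroid_y", "centroid_z",
           "bbox_start_x", "bbox_start_y", "bbox_start_z",
           "bbox_extent_x", "bbox_extent_y", "bbox_extent_z")
  shape <- c("size_voxels", "eig_mean", "eig_sd",
             "axial_diffusivity", "radial_diffusivity")
  intens <- as.vector(vapply(GAD_CHANNELS, function(ch)
    paste0(ch, "_", c("in_mean", "in_sd", "in_sum",
                      "shell_mean", "shell_sd", "shell_sum")),
    character(6)))
  c(loc, "n_candidates", shape, intens)
}

#' 6-connected components of a binary 3D mask
#'
#' Two foreground voxels belong to the same component iff they are joined
#' by a path of face-adjacent (6-neighbourhood) voxels — diagonal contact
#' does not connect.
#'
#' @param mask logical or 0/1 3D array.
#' @return List with `labels` (integer 3D array, 0 = background,
#'   components numbered in first-voxel order), `n_components`, and
#'   `sizes` (integer vector of component voxel counts).
#' @export
connected_components_6 <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D array")
  mv <- as.vector(mask)
  if (is.numeric(mv) && any(!mv %in% c(0, 1)))
    stop("mask must be binary")
  fg <- which(mv != 0)
  labels <- array(0L, d)
  if (!length(fg))
    return(list(labels = labels, n_components = 0L, sizes = integer(0)))
  pos <- arrayInd(fg, d)
  # face-adjacent pairs along each axis: linear-index strides 1, d1, d1*d2
  strides <- c(1L, d[1], d[1] * d[2])
  edges <- integer(0)
  inset <- integer(length(mv)); inset[fg] <- seq_along(fg)
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- fg[ok] + strides[ax]
    hit <- inset[nb] > 0L
    if (any(hit))
      edges <- c(edges, rbind(inset[fg[ok]][hit], inset[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel so components are numbered by first foreground voxel
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  labels[fg] <- relab[memb]
  sizes <- tabulate(labels[fg])
  list(labels = labels, n_components = length(sizes), sizes = sizes)
}

#' Drop components smaller than the minimum lesion size
#'
#' The evaluation protocol ignores lesions below 5 voxels; the same floor
#' is applied to predicted candidates.
#'
#' @param cc result of [connected_components_6()].
#' @param min_size minimum voxel count (default 5, inclusive).
#' @return A filtered component list in the same format (relabeled
#'   consecutively), plus `kept` (original labels retained).
#' @export
filter_min_size <- function(cc, min_size = 5L) {
  if (min_size < 1L) stop("min_size must be >= 1")
  keep <- which(cc$sizes >= min_size)
  labels <- cc$labels
  relab <- integer(cc$n_components)
  relab[keep] <- seq_along(keep)
  fg <- labels > 0L
  labels[fg] <- relab[labels[fg]]
  list(labels = labels, n_components = length(keep),
       sizes = cc$sizes[keep], kept = keep)
}

# Coordinates (0-based, order x=row, y=column, z=slice) of a component's
# voxels given its array indices on the (S,R,C) grid.
.coords_xyz <- function(pos) {
  cbind(x = pos[, 2] - 1L, y = pos[, 3] - 1L, z = pos[, 1] - 1L)
}

#' Extract the 75-feature descriptor of one candidate
#'
#' @param voxels integer matrix of array indices (rows = voxels, columns =
#'   slice, row, column on the 1-based grid), one 6-connected component.
#' @param stack the `volume_stack` the candidate came from. Channels
#'   absent from the stack's configuration contribute zeros (the layout
#'   stays 75-long across contrast configurations).
#' @param n_candidates_in_scan scan-level candidate count (after size
#'   filtering); identical for all candidates of one scan.
#' @param shell_width width of the surrounding shell in face-dilation
#'   steps (default 1).
#' @return Named numeric vector of length 75, ordered per
#'   [feature_layout()].
#' @export
extract_features <- function(voxels, stack, n_candidates_in_scan,
                             shell_width = 1L) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1L)
  if (nrow(voxels) == 0L) stop("empty component")
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$data)[2:4]
  xyz <- .coords_xyz(voxels)
  cen <- colMeans(xyz)
  lo <- apply(xyz, 2, min)
  ext <- apply(xyz, 2, max) - lo + 1
  # shape tensor: second central moment of coordinates in mm
  sp_xyz <- stack$spacing[c(2, 3, 1)]      # spacing is (slice,row,col)
  mmc <- sweep(xyz, 2, cen) * rep(sp_xyz, each = nrow(xyz))
  cov3 <- crossprod(mmc) / nrow(mmc)
  ev <- sort(eigen(cov3, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  shape_feats <- c(size_voxels = nrow(xyz), eig_mean = mean(ev),
                   eig_sd = sd_pop(ev),
                   axial_diffusivity = ev[1],
                   radial_diffusivity = mean(ev[2:3]))

  comp <- array(FALSE, d)
  comp[voxels] <- TRUE
  sh <- comp
  for (i in seq_len(shell_width)) sh <- dilate6(sh)
  shell <- sh & !comp
  in_idx <- which(comp); sh_idx <- which(shell)
  intens <- numeric(0)
  for (ch in GAD_CHANNELS) {
    pos <- match(ch, stack$channels)
    if (is.na(pos)) {
      v <- rep(0, 6)
    } else {
      vol <- array(stack$data[pos, , , ], d)
      iv <- vol[in_idx]; sv <- vol[sh_idx]
      v <- c(mean(iv), if (length(iv) > 1L) stats::sd(iv) else 0, sum(iv),
             if (length(sv)) mean(sv) else 0,
             if (length(sv) > 1L) stats::sd(sv) else 0,
             if (length(sv)) sum(sv) else 0)
    }
    names(v) <- paste0(ch, "_", c("in_mean", "in_sd", "in_sum",
                                  "shell_mean", "shell_sd", "shell_sum"))
    intens <- c(intens, v)
  }
  out <- c(centroid_x = cen[["x"]], centroid_y = cen[["y"]],
           centroid_z = cen[["z"]],
           bbox_start_x = lo[["x"]], bbox_start_y = lo[["y"]],
           bbox_start_z = lo[["z"]],
           bbox_extent_x = ext[["x"]], bbox_extent_y = ext[["y"]],
           bbox_extent_z = ext[["z"]],
           n_candidates = n_candidates_in_scan,
           shape_feats, intens)
  stopifnot(identical(names(out), feature_layout()))
  out
}

# population SD (divides by n) — degenerate single-eigenvalue sets give 0
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract all candidates of a scan from a binary prediction
#'
#' Runs 6-connected component analysis on the binarized map, drops
#' components below `min_size`, and computes the 75-feature descriptor
#' for each surviving candidate.
#'
#' @param pred_mask binary 3D array (slice x row x column).
#' @param stack the scan's `volume_stack`.
#' @param min_size minimum candidate size in voxels.
#' @param shell_width shell width passed to [extract_features()].
#' @return List with `candidates` (data.frame: scan_id, component_id,
#'   then the 75 feature columns, which include `size_voxels`), `labels`
#'   (filtered label array) and `components` (list of voxel-index
#'   matrices).
#' @export
extract_candidates <- function(pred_mask, stack, min_size = 5L,
                               shell_width = 1L) {
  cc <- filter_min_size(connected_components_6(pred_mask), min_size)
  comps <- lapply(seq_len(cc$n_components), function(k)
    arrayInd(which(cc$labels == k), dim(cc$labels)))
  feats <- lapply(comps, extract_features, stack = stack,
                  n_candidates_in_scan = cc$n_components,
                  shell_width = shell_width)
  df <- if (length(feats)) {
    cbind(data.frame(scan_id = stack$scan_id,
                     component_id = seq_along(feats)),
          as.data.frame(do.call(rbind, feats)))
  } else {
    empty <- as.data.frame(matrix(numeric(0), 0, 75,
                                  dimnames = list(NULL, feature_layout())))
    cbind(data.frame(scan_id = character(0), component_id = integer(0)),
          empty)
  }
  list(candidates = df, labels = cc$labels, components = comps)
}
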
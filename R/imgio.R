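#' @importFrom stats rnorm runif rbinom quantile sd predict
#' @importFrom utils write.csv read.csv head
NULL

#' Recognised image channels
#'
#' The ten channels the segmentation model can consume: five MRI contrasts
#' (T1 post-contrast, T1 pre-contrast, FLAIR, T2, proton density) and five
#' tissue probability maps (grey matter, white matter, CSF, lateral
#' ventricles, lesion prior).
#'
#' @format Character vector of length 10.
#' @export
GAD_CHANNELS <- c("t1_post", "t1_pre", "flair", "t2", "pd",
                  "p_gm", "p_wm", "p_csf", "p_vent", "p_lesion")

.prob_channels <- c("p_gm", "p_wm", "p_csf", "p_vent", "p_lesion")

#' Declare a contrast configuration
#'
#' A contrast configuration names an ordered subset of the ten recognised
#' channels (always ending with the five probability maps in the standard
#' layouts) and fixes the channel order fed to the network.
#'
#' @param channels character vector of channel identifiers, a subset of
#'   [GAD_CHANNELS].
#' @param name short label for the configuration.
#' @return An object of class `contrast_config` with fields `name`,
#'   `channels`, `n_channels`.
#' @examples
#' contrast_config(GAD_CHANNELS, name = "full10")
#' @export
contrast_config <- function(channels, name = paste(channels, collapse = "+")) {
  channels <- as.character(channels)
  bad <- setdiff(channels, GAD_CHANNELS)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(channels))
    stop("duplicated channel in configuration")
  structure(list(name = name, channels = channels,
                 n_channels = length(channels)),
            class = "contrast_config")
}

#' @export
print.contrast_config <- function(x, ...) {
  cat("<contrast_config> ", x$name, " (", x$n_channels, " channels)\n",
      sep = "")
  cat("  ", paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Standard contrast configurations
#'
#' The input-channel combinations studied in the input-ablation experiments:
#' all use the five probability maps; the MRI contrast subset varies
#' (10, 9, 8, 7, or 6 channels), plus the five-contrast set without maps.
#'
#' @return Named list of [contrast_config()] objects.
#' @export
standard_configs <- function() {
  maps <- .prob_channels
  list(
    full10       = contrast_config(GAD_CHANNELS, "full10"),
    contrasts5   = contrast_config(c("t1_post", "t1_pre", "flair", "t2", "pd"),
                                   "contrasts5"),
    no_pd9       = contrast_config(c("t1_post", "t1_pre", "flair", "t2", maps),
                                   "no_pd9"),
    t1_flair8    = contrast_config(c("t1_post", "t1_pre", "flair", maps),
                                   "t1_flair8"),
    post_flair7  = contrast_config(c("t1_post", "flair", maps), "post_flair7"),
    post_only6   = contrast_config(c("t1_post", maps), "post_only6"),
    no_post9     = contrast_config(c("t1_pre", "flair", "t2", "pd", maps),
                                   "no_post9")
  )
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return List with `data` (3D array, slice x row x column), `spacing`
#'   (mm triple, slice spacing first) and `header` metadata.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path)
  pix <- RNifti::pixdim(img)
  list(data = unclass(img)[, , , drop = FALSE],
       spacing = as.numeric(pix[1:3]),
       header = RNifti::niftiHeader(img))
}

#' Write a 3D volume to a NIfTI file
#'
#' @param data 3D array (slice x row x column).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm, one value per array axis.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(3, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assemble a multi-channel volume stack
#'
#' Stacks per-channel 3D grids into the 4D array the model consumes,
#' in the order declared by the contrast configuration. Probability-map
#' channels are clipped to `[0, 1]`.
#'
#' @param volumes named list mapping channel identifier to 3D array
#'   (slice x row x column).
#' @param config a [contrast_config()].
#' @param mask optional binary 3D array aligned with the volumes.
#' @param spacing mm triple (slice, row, column); default `c(3, 1, 1)`.
#' @param scan_id opaque scan identifier.
#' @return A `volume_stack`: list with `channels`, `data` (4D array,
#'   channel x slice x row x column), `spacing`, `mask`, `scan_id`.
#' @export
stack_channels <- function(volumes, config, mask = NULL,
                           spacing = c(3, 1, 1), scan_id = "scan") {
  stopifnot(inherits(config, "contrast_config"))
  missing_ch <- setdiff(config$channels, names(volumes))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  shp <- dim(volumes[[config$channels[1]]])
  if (length(shp) != 3L) stop("channels must be 3D arrays")
  for (ch in config$channels) {
    if (!identical(dim(volumes[[ch]]), shp))
      stop("shape mismatch for channel '", ch, "': expected ",
           paste(shp, collapse = "x"), ", got ",
           paste(dim(volumes[[ch]]), collapse = "x"))
  }
  if (!is.null(mask) && !identical(dim(mask), shp))
    stop("mask shape does not match channel shape")
  data <- array(0, c(config$n_channels, shp))
  for (i in seq_along(config$channels)) {
    ch <- config$channels[i]
    v <- volumes[[ch]]
    if (ch %in% .prob_channels) v <- pmin(pmax(v, 0), 1)
    data[i, , , ] <- v
  }
  if (!identical(shp[2:3], c(256L, 256L)) || shp[1] != 64L) {
    # fully convolutional model: non-template geometry is legal, just unusual
    if (getOption("gadseg.warn_geometry", FALSE))
      warning("volume shape ", paste(shp, collapse = "x"),
              " differs from the 64x256x256 template grid")
  }
  structure(list(channels = config$channels, data = data,
                 spacing = as.numeric(spacing),
                 mask = mask, scan_id = scan_id),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_stack> ", x$scan_id, ": ", d[1], " channels, grid ",
      d[2], "x", d[3], "x", d[4], ", spacing ",
      paste(x$spacing, collapse = "x"), " mm",
      if (!is.null(x$mask)) paste0(", mask (", sum(x$mask), " voxels)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

#' Iterate over the 2D slices of a volume stack
#'
#' Splits the stack along the slice (3 mm) axis into the 2D multi-channel
#' images the network consumes, in ascending slice order.
#'
#' @param stack a `volume_stack`.
#' @return List of length `n_slices`; each element has `index` (1-based
#'   slice index), `image` (channel x row x column array) and `mask`
#'   (row x column binary matrix, or NULL).
#' @export
iter_slices <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$data)
  lapply(seq_len(d[2]), function(s) {
    list(index = s,
         image = array(stack$data[, s, , ], c(d[1], d[3], d[4])),
         mask = if (!is.null(stack$mask))
           matrix(stack$mask[s, , ], d[3], d[4]))
  })
}

#' Re-assemble slices into a 3D mask
#'
#' Inverse of the mask part of [iter_slices()]: stacks per-slice 2D masks
#' back into the 3D grid.
#'
#' @param slices list of 2D matrices (one per slice, in order).
#' @return 3D array (slice x row x column).
#' @export
restack_slices <- function(slices) {
  stopifnot(length(slices) >= 1L)
  d2 <- dim(slices[[1]])
  out <- array(0, c(length(slices), d2))
  for (s in seq_along(slices)) out[s, , ] <- slices[[s]]
  out
}

#' Write a volume stack to a directory as NIfTI files
#'
#' One file per channel (`<scan_id>_<channel>.nii.gz`) plus
#' `<scan_id>_mask.nii.gz` when a mask is present.
#'
#' @param stack a `volume_stack`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "volume_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(stack$channels)) {
    ch <- stack$channels[i]
    p <- file.path(dir, paste0(stack$scan_id, "_", ch, ".nii.gz"))
    write_volume(array(stack$data[i, , , ], dim(stack$data)[2:4]), p,
                 spacing = stack$spacing)
    paths[ch] <- p
  }
  if (!is.null(stack$mask)) {
    p <- file.path(dir, paste0(stack$scan_id, "_mask.nii.gz"))
    write_volume(stack$mask * 1L, p, spacing = stack$spacing)
    paths["mask"] <- p
  }
  invisible(paths)
}

#' Read a volume stack written by [write_stack()]
#'
#' @param dir directory holding the per-channel NIfTI files.
#' @param scan_id scan identifier (file-name prefix).
#' @param config a [contrast_config()] naming the channels to load.
#' @param with_mask load `<scan_id>_mask.nii.gz` if present.
#' @return A `volume_stack`.
#' @export
read_stack <- function(dir, scan_id, config = standard_configs()$full10,
                       with_mask = TRUE) {
  vols <- list()
  spacing <- NULL
  for (ch in config$channels) {
    p <- file.path(dir, paste0(scan_id, "_", ch, ".nii.gz"))
    v <- read_volume(p)
    vols[[ch]] <- v$data
    spacing <- v$spacing
  }
  mask <- NULL
  mp <- file.path(dir, paste0(scan_id, "_mask.nii.gz"))
  if (with_mask && file.exists(mp)) mask <- read_volume(mp)$data > 0.5
  stack_channels(vols, config, mask = mask, spacing = spacing,
                 scan_id = scan_id)
}
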
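# Synthetic multi-contrast brain phantoms with ground-truth enhancing
# lesions, so every pipeline stage is testable without clinical data.
#
# The brain is rendered as nested ellipsoids (CSF rim / GM / WM) with two
# lateral-ventricle ellipsoids; smoothing the tissue indicators yields the
# five probability channels (the clinical maps come from template warping,
# which is out of scope here). Ovoid lesions are anisotropic Gaussians
# thresholded to an exact voxel count; ring-enhancing lesions subtract a
# concentric core, leaving a hyperintense shell with a hypointense centre
# on post-contrast T1. Vessel-like distractor blobs — bright on both pre-
# and post-contrast T1, the classic clinical false-positive source — give
# the downstream random-forest stage real negatives to learn from.
# Per-scan, per-channel gain/offset jitter emulates non-standardized
# acquisition protocols.

.SIZE_GROUP_BOUNDS <- list("5-10" = c(5L, 10L), "11-20" = c(11L, 20L),
                           "21-50" = c(21L, 50L), "51-100" = c(51L, 100L),
                           ">100" = c(101L, 160L))

#' Lesion size groups
#'
#' The five size strata used throughout evaluation, in voxels:
#' 5-10, 11-20, 21-50, 51-100, >100 (inclusive bounds; the 5-voxel
#' minimum is the detection floor).
#'
#' @return Named list of `c(lower, upper)` integer bounds; the last group
#'   is open-ended (upper bound `Inf`).
#' @export
size_groups <- function() {
  list("5-10" = c(5, 10), "11-20" = c(11, 20), "21-50" = c(21, 50),
       "51-100" = c(51, 100), ">100" = c(101, Inf))
}

#' Phantom specification
#'
#' @param shape voxel grid as (slices, rows, columns); the default
#'   64x256x256 matches the clinical template grid, but any shape with
#'   rows/columns divisible by 16 works (the model is fully
#'   convolutional).
#' @param n_lesions number of enhancing lesions.
#' @param groups character vector (with repetition) of size-group labels
#'   from `names(size_groups())`, one per lesion; recycled to
#'   `n_lesions`. Lesion voxel counts are drawn uniformly within the
#'   group bounds.
#' @param ring_fraction proportion of lesions (of size >= 21 voxels)
#'   rendered ring-enhancing.
#' @param lesion_boost additive post-contrast T1 hyperintensity of
#'   enhancing voxels (arbitrary intensity units; tissue intensities are
#'   O(1)). Lesion contrast-to-noise is monotone in this value.
#' @param noise_sd per-channel Gaussian noise SD on the MRI contrasts.
#' @param contrast_jitter SD of the per-scan log-gain jitter per MRI
#'   contrast (protocol non-standardization).
#' @param n_distractors vessel-like bright blobs per scan (not lesions).
#' @param spacing voxel spacing in mm (slice, row, column).
#' @param seed RNG seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 256L, 256L), n_lesions = 3L,
                         groups = c("21-50", "51-100", ">100"),
                         ring_fraction = 0.25, lesion_boost = 0.5,
                         noise_sd = 0.05, contrast_jitter = 0.1,
                         n_distractors = 3L, spacing = c(3, 1, 1),
                         seed = 1L) {
  stopifnot(length(shape) == 3L, n_lesions >= 0L,
            ring_fraction >= 0, ring_fraction <= 1, noise_sd >= 0)
  if (n_lesions > 0L) {
    groups <- rep_len(groups, n_lesions)
    bad <- setdiff(groups, names(.SIZE_GROUP_BOUNDS))
    if (length(bad)) stop("unknown size group(s): ", paste(bad, collapse = ", "))
  } else groups <- character(0)
  structure(list(shape = as.integer(shape), n_lesions = as.integer(n_lesions),
                 groups = groups, ring_fraction = ring_fraction,
                 lesion_boost = lesion_boost, noise_sd = noise_sd,
                 contrast_jitter = contrast_jitter,
                 n_distractors = as.integer(n_distractors),
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared normalized ellipsoid distance on the (S,R,C) grid.
.ellipsoid_q <- function(shape, center, radii) {
  S <- shape[1]; R <- shape[2]; C <- shape[3]
  qs <- ((seq_len(S) - center[1]) / radii[1])^2
  qr <- ((seq_len(R) - center[2]) / radii[2])^2
  qc <- ((seq_len(C) - center[3]) / radii[3])^2
  outer(outer(qs, qr, "+"), qc, "+")
}

# Light separable 3-point smoothing, n passes.
.smooth3 <- function(x, passes = 2L) {
  d <- dim(x)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      lo <- x; hi <- x
      n <- d[ax]
      idx_lo <- c(1L, seq_len(n - 1L)); idx_hi <- c(seq_len(n - 1L) + 1L, n)
      if (ax == 1L) { lo <- x[idx_lo, , , drop = FALSE]
                      hi <- x[idx_hi, , , drop = FALSE] }
      if (ax == 2L) { lo <- x[, idx_lo, , drop = FALSE]
                      hi <- x[, idx_hi, , drop = FALSE] }
      if (ax == 3L) { lo <- x[, , idx_lo, drop = FALSE]
                      hi <- x[, , idx_hi, drop = FALSE] }
      x <- (lo + x + hi) / 3
    }
  }
  x
}

# One-voxel 6-connected (face) dilation.
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# Is the voxel set (logical array) one 6-connected component?
.is_connected6 <- function(m) {
  cc <- connected_components_6(m)
  cc$n_components == 1L
}

# Place one blob of exactly `n` voxels by thresholding an anisotropic
# Gaussian at a random admissible centre. Returns a logical array (and the
# core subset for ring lesions) or NULL if no placement was found.
.place_blob <- function(n, allowed, occupied, shape, ring = FALSE,
                        max_tries = 60L) {
  cand_idx <- which(allowed & !occupied)
  if (!length(cand_idx)) return(NULL)
  ar <- shape[2] / shape[1]          # slices are thicker: fewer of them
  for (tr in seq_len(max_tries)) {
    ci <- cand_idx[sample.int(length(cand_idx), 1L)]
    ctr <- arrayInd(ci, shape)
    # anisotropy mild enough that superlevel sets stay face-connected
    scale <- (n * 3)^(1 / 3)
    sig <- c(max(0.8, scale / 3), scale * runif(1, 0.7, 1.3),
             scale * runif(1, 0.7, 1.3)) / 1.6
    r <- pmin(ceiling(3 * sig) + 2L, shape %/% 2L)
    lo <- pmax(ctr - r, 1L); hi <- pmin(ctr + r, shape)
    box <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    w <- .ellipsoid_q(hi - lo + 1L, ctr - lo + 1L, sig)
    ok <- allowed[box[[1]], box[[2]], box[[3]], drop = FALSE] &
      !occupied[box[[1]], box[[2]], box[[3]], drop = FALSE]
    w[!ok] <- Inf
    n_out <- if (ring) round(1.6 * n) else n
    if (sum(is.finite(w)) < n_out) next
    ord <- order(w)[seq_len(n_out)]
    outer_m <- array(FALSE, dim(w)); outer_m[ord] <- TRUE
    if (ring) {
      core <- array(FALSE, dim(w))
      core[order(w)[seq_len(n_out - n)]] <- TRUE
      blob <- outer_m & !core
    } else {
      core <- NULL
      blob <- outer_m
    }
    if (!.is_connected6(blob)) next
    full <- array(FALSE, shape)
    full[box[[1]], box[[2]], box[[3]]] <- blob
    full_core <- NULL
    if (ring) {
      full_core <- array(FALSE, shape)
      full_core[box[[1]], box[[2]], box[[3]]] <- core
    }
    return(list(mask = full, core = full_core))
  }
  NULL
}

# Base tissue intensities per MRI contrast (arbitrary units).
.TISSUE_INTENSITY <- list(
  t1_post = c(bg = 0.02, csf = 0.15, gm = 0.50, wm = 0.70, vent = 0.15),
  t1_pre  = c(bg = 0.02, csf = 0.15, gm = 0.50, wm = 0.70, vent = 0.15),
  flair   = c(bg = 0.02, csf = 0.10, gm = 0.55, wm = 0.45, vent = 0.10),
  t2      = c(bg = 0.02, csf = 0.90, gm = 0.60, wm = 0.40, vent = 0.90),
  pd      = c(bg = 0.02, csf = 0.70, gm = 0.65, wm = 0.55, vent = 0.70)
)

#' Generate one synthetic multi-contrast phantom
#'
#' Builds a 10-channel `volume_stack` (five MRI contrasts, five tissue
#' probability maps), a ground-truth enhancing-lesion mask, and a
#' per-lesion size table. Deterministic given `spec$seed`. Enhancing
#' voxels are hyperintense on post-contrast T1 relative to pre-contrast
#' T1 and hyperintense on FLAIR/T2; ring lesions have hypointense cores
#' on post-contrast T1. Lesions are pairwise disjoint under
#' 6-connectivity (separated by at least one voxel).
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (`volume_stack`, mask attached), `mask`
#'   (logical 3D array), `sizes` (data.frame: lesion_id, size_voxels,
#'   group, type), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shp <- spec$shape
  ctr <- (shp + 1) / 2
  half <- shp / 2
  q_brain <- .ellipsoid_q(shp, ctr, half * c(0.95, 0.88, 0.82))
  q_gmwm <- .ellipsoid_q(shp, ctr, half * c(0.85, 0.78, 0.72))
  q_wm <- .ellipsoid_q(shp, ctr, half * c(0.70, 0.62, 0.56))
  voff <- half[3] * 0.14
  q_v1 <- .ellipsoid_q(shp, ctr + c(0, 0, voff),
                       half * c(0.45, 0.18, 0.08))
  q_v2 <- .ellipsoid_q(shp, ctr - c(0, 0, voff),
                       half * c(0.45, 0.18, 0.08))
  brain <- q_brain <= 1
  vent <- (q_v1 <= 1) | (q_v2 <= 1)
  wm <- (q_wm <= 1) & !vent
  gm <- (q_gmwm <= 1) & !wm & !vent
  csf <- (brain & q_gmwm > 1) | vent

  # probability channels: smoothed indicators, normalized to sum <= 1
  p_gm <- .smooth3(gm * 1); p_wm <- .smooth3(wm * 1)
  p_csf <- .smooth3(csf * 1)
  tot <- p_gm + p_wm + p_csf
  over <- tot > 1
  if (any(over)) {
    p_gm[over] <- p_gm[over] / tot[over]
    p_wm[over] <- p_wm[over] / tot[over]
    p_csf[over] <- p_csf[over] / tot[over]
  }
  p_vent <- pmin(.smooth3(vent * 1), 1)
  periv <- (pmin(q_v1, q_v2) <= 3.5) & wm
  p_lesion <- pmin(.smooth3(periv * 1, passes = 3L), 1)

  # lesions: exact sizes, disjoint with a 1-voxel margin
  mask <- array(FALSE, shp)
  occupied <- array(FALSE, shp)
  lesions <- list()
  sizes <- data.frame(lesion_id = integer(), size_voxels = integer(),
                      group = character(), type = character())
  n_ring_eligible <- 0L
  for (li in seq_len(spec$n_lesions)) {
    g <- spec$groups[li]
    b <- .SIZE_GROUP_BOUNDS[[g]]
    n <- sample(b[1]:b[2], 1L)
    ring <- n >= 21L && runif(1) < spec$ring_fraction
    blob <- .place_blob(n, allowed = wm, occupied = occupied, shape = shp,
                        ring = ring)
    if (is.null(blob))
      stop("infeasible phantom spec: could not place lesion ", li,
           " (", n, " voxels) disjointly")
    lesions[[li]] <- blob
    mask <- mask | blob$mask
    occ_new <- blob$mask
    if (!is.null(blob$core)) occ_new <- occ_new | blob$core
    occupied <- occupied | dilate6(occ_new)
    sizes <- rbind(sizes, data.frame(
      lesion_id = li, size_voxels = n, group = g,
      type = if (ring) "ring" else "ovoid"))
  }

  # distractors: bright on both T1s, never in the mask
  distract <- array(FALSE, shp)
  for (di in seq_len(spec$n_distractors)) {
    blob <- .place_blob(sample(5:15, 1L), allowed = gm | wm,
                        occupied = occupied, shape = shp)
    if (is.null(blob)) break
    distract <- distract | blob$mask
    occupied <- occupied | dilate6(blob$mask)
  }

  vols <- list()
  for (ch in names(.TISSUE_INTENSITY)) {
    v <- .TISSUE_INTENSITY[[ch]]
    img <- array(v["bg"], shp)
    img[csf] <- v["csf"]; img[gm] <- v["gm"]; img[wm] <- v["wm"]
    img[vent] <- v["vent"]
    for (li in seq_along(lesions)) {
      les <- lesions[[li]]
      whole <- les$mask
      if (!is.null(les$core)) whole <- whole | les$core
      if (ch %in% c("flair", "t2")) img[whole] <- img[whole] + 0.35
      if (ch == "t1_pre") img[whole] <- img[whole] - 0.10
      if (ch == "t1_post") {
        img[les$mask] <- img[les$mask] + spec$lesion_boost
        if (!is.null(les$core)) img[les$core] <- img[les$core] - 0.20
      }
    }
    if (ch %in% c("t1_post", "t1_pre")) img[distract] <- img[distract] + 0.5
    img <- .smooth3(img, passes = 1L)
    gain <- exp(rnorm(1, 0, spec$contrast_jitter))
    offset <- rnorm(1, 0, spec$contrast_jitter * 0.2)
    img <- gain * img + offset
    img <- img + array(rnorm(prod(shp), 0, spec$noise_sd), shp)
    vols[[ch]] <- img
  }
  vols$p_gm <- p_gm; vols$p_wm <- p_wm; vols$p_csf <- p_csf
  vols$p_vent <- p_vent; vols$p_lesion <- p_lesion

  stack <- stack_channels(vols, standard_configs()$full10, mask = mask,
                          spacing = spec$spacing,
                          scan_id = paste0("phantom_", spec$seed))
  list(stack = stack, mask = mask, sizes = sizes, spec = spec)
}

#' Generate a cohort of phantoms with per-scan count categories
#'
#' Emulates a screening population: each scan carries at least one
#' enhancing lesion with probability `lesion_prevalence` (clinical routine
#' cohorts run around 6.5%); lesion-positive scans draw their lesion count
#' uniformly from 1 to `template$n_lesions`. Per-scan seeds derive from
#' `seed`, so the cohort is reproducible.
#'
#' @param n_scans number of phantoms.
#' @param lesion_prevalence probability in `[0, 1]` that a scan has >= 1
#'   lesion.
#' @param template a [phantom_spec()] providing geometry, size groups and
#'   the maximum lesion count.
#' @param seed cohort RNG seed.
#' @return List with `phantoms` (list of [generate_phantom()] results) and
#'   `manifest` (data.frame: scan_id, n_lesions, category, seed).
#' @export
generate_cohort <- function(n_scans, lesion_prevalence = 0.065,
                            template = phantom_spec(), seed = 1L) {
  stopifnot(lesion_prevalence >= 0, lesion_prevalence <= 1, n_scans >= 1L)
  set.seed(seed)
  has <- runif(n_scans) < lesion_prevalence
  n_les <- ifelse(has, sample.int(max(1L, template$n_lesions), n_scans,
                                  replace = TRUE), 0L)
  scan_seeds <- (seed + 1000L * seq_len(n_scans)) %% .Machine$integer.max
  phantoms <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    sp <- template
    sp$n_lesions <- n_les[i]
    sp$groups <- if (n_les[i] > 0L) rep_len(template$groups, n_les[i])
                 else character(0)
    sp$seed <- as.integer(scan_seeds[i])
    phantoms[[i]] <- generate_phantom(sp)
    phantoms[[i]]$stack$scan_id <- sprintf("scan_%03d", i)
  }
  manifest <- data.frame(
    scan_id = sprintf("scan_%03d", seq_len(n_scans)),
    n_lesions = n_les,
    category = vapply(n_les, categorize_count, character(1)),
    seed = as.integer(scan_seeds))
  list(phantoms = phantoms, manifest = manifest)
}
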
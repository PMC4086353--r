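#' Segmentation parameters for threshold region growing
#'
#' Parameter bundle for lung segmentation. The lower CT-number threshold is
#' fixed at -1000 HU (air); the upper threshold defaults to -400 HU and must
#' lie in the visually-used range \[-600, -150\] HU. In-plane connectivity is
#' 4 or 8. `pleural_sliver_mm` is the maximum in-plane dilation of the lung
#' margin (at most 1 mm), used for free-breathing SPECT/CT segmentation where
#' slightly more generous margins (a thin sliver of pleura) reproduce
#' breath-hold masses; `include_atelectasis` merges flagged dependent
#' atelectasis into the lung labels.
#'
#' @param lower_hu Lower threshold in HU (fixed default -1000).
#' @param upper_hu Upper threshold in HU, in \[-600, -150\].
#' @param connectivity In-plane connectivity, 4 or 8.
#' @param pleural_sliver_mm In-plane margin dilation in mm, in \[0, 1\].
#' @param include_atelectasis Merge flagged atelectasis voxels into lungs.
#' @param upper_search If `TRUE`, the upper threshold is chosen per slice
#'   from `c(-600, -500, -400, -300, -150)` to maximise in-band area after
#'   discarding components touching the slice border (outside-body air).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(lower_hu = -1000, upper_hu = -400,
                                connectivity = 4, pleural_sliver_mm = 0,
                                include_atelectasis = FALSE,
                                upper_search = FALSE) {
  if (upper_hu < -600 || upper_hu > -150) {
    stop("`upper_hu` must lie in [-600, -150] HU", call. = FALSE)
  }
  if (lower_hu >= upper_hu) {
    stop("`lower_hu` must be below `upper_hu`", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8 (in-plane)", call. = FALSE)
  }
  if (pleural_sliver_mm < 0 || pleural_sliver_mm > 1) {
    stop("`pleural_sliver_mm` must lie in [0, 1] mm", call. = FALSE)
  }
  structure(
    list(
      lower_hu = lower_hu, upper_hu = upper_hu, connectivity = connectivity,
      pleural_sliver_mm = pleural_sliver_mm,
      include_atelectasis = isTRUE(include_atelectasis),
      upper_search = isTRUE(upper_search)
    ),
    class = "segmentation_params"
  )
}

#' Presets mirroring the two acquisition styles
#'
#' Diagnostic CT: tight margins, no sliver, no atelectasis merging.
#' SPECT/CT: 1-mm pleural sliver and atelectasis inclusion.
#'
#' @param mode `"diagnostic"` or `"spectct"`.
#' @param ... Overrides passed to [segmentation_params()].
#' @return A `segmentation_params` object.
#' @export
segmentation_preset <- function(mode = c("diagnostic", "spectct"), ...) {
  mode <- match.arg(mode)
  defaults <- if (mode == "diagnostic") {
    list(pleural_sliver_mm = 0, include_atelectasis = FALSE)
  } else {
    list(pleural_sliver_mm = 1, include_atelectasis = TRUE)
  }
  do.call(segmentation_params, utils::modifyList(defaults, list(...)))
}

# ---- flood-fill engine -----------------------------------------------------
# Vectorised frontier propagation over a logical array. Offsets are (dx,dy,dz)
# steps of -1/0/1; the frontier is dilated by all offsets each iteration and
# clipped to the admissible band until it stops growing.

shift_logical <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    if (off[i] == 0L) {
      src[[i]] <- seq_len(d[i]); dst[[i]] <- seq_len(d[i])
    } else if (off[i] == 1L) {
      src[[i]] <- seq_len(d[i] - 1L); dst[[i]] <- seq_len(d[i] - 1L) + 1L
    } else {
      src[[i]] <- seq_len(d[i] - 1L) + 1L; dst[[i]] <- seq_len(d[i] - 1L)
    }
    if (d[i] < 2L && off[i] != 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

conn_offsets <- function(connectivity, link_z = FALSE) {
  offs <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1L, 1L, 0L), c(1L, -1L, 0L),
                         c(-1L, 1L, 0L), c(-1L, -1L, 0L)))
  }
  if (link_z) offs <- c(offs, list(c(0L, 0L, 1L), c(0L, 0L, -1L)))
  offs
}

dilate_logical <- function(a, offsets) {
  out <- a
  for (off in offsets) out <- out | shift_logical(a, off)
  out
}

# Grow `seed` within `band` under the given offsets until stationary.
flood_grow <- function(band, seed, offsets) {
  reached <- seed & band
  repeat {
    grown <- reached | (dilate_logical(reached, offsets) & band)
    if (sum(grown) == sum(reached)) break
    reached <- grown
  }
  reached
}

# Label all connected components of a logical array; returns an integer array
# (0 outside) and component sizes, in labelling order.
label_components <- function(band, connectivity = 4, link_z = FALSE) {
  offsets <- conn_offsets(connectivity, link_z)
  labels <- array(0L, dim(band))
  remaining <- band
  k <- 0L
  sizes <- integer(0)
  while (any(remaining)) {
    k <- k + 1L
    seed <- array(FALSE, dim(band))
    seed[which(remaining)[1L]] <- TRUE
    comp <- flood_grow(remaining, seed, offsets)
    labels[comp] <- k
    sizes[k] <- sum(comp)
    remaining <- remaining & !comp
  }
  list(labels = labels, sizes = sizes)
}

#' Seeded threshold region growing on one trans-axial slice
#'
#' Two-dimensional region growing: the result is the union of the connected
#' components of the in-band voxels (CT number within
#' `[lower_hu, upper_hu]`) reachable from the seed points under the chosen
#' in-plane connectivity.
#'
#' @param ct_slice 2-D numeric matrix of CT numbers.
#' @param seeds Two-column matrix (or length-2 vector) of 1-based
#'   `(row, col)` seed indices; every seed must lie within the threshold
#'   band.
#' @param params A [segmentation_params()].
#' @return Logical matrix of the grown ROI.
#' @export
grow_slice_roi <- function(ct_slice, seeds, params = segmentation_params()) {
  stopifnot(is.matrix(ct_slice))
  if (is.vector(seeds)) seeds <- matrix(seeds, nrow = 1L)
  band2 <- ct_slice >= params$lower_hu & ct_slice <= params$upper_hu
  for (s in seq_len(nrow(seeds))) {
    i <- seeds[s, 1L]; j <- seeds[s, 2L]
    if (i < 1 || j < 1 || i > nrow(ct_slice) || j > ncol(ct_slice) ||
        !band2[i, j]) {
      stop(sprintf(
        "seed (%d, %d) lies outside the threshold band [%g, %g] HU",
        i, j, params$lower_hu, params$upper_hu
      ), call. = FALSE)
    }
  }
  band <- array(band2, c(dim(ct_slice), 1L))
  seed <- array(FALSE, dim(band))
  seed[cbind(seeds[, 1L], seeds[, 2L], 1L)] <- TRUE
  grown <- flood_grow(band, seed, conn_offsets(params$connectivity, link_z = FALSE))
  matrix(grown[, , 1L], nrow(ct_slice), ncol(ct_slice))
}

# Per-slice upper-threshold search: maximise in-band area after dropping
# components that touch the slice border (outside-body air).
search_upper_hu <- function(slice_hu, lower_hu, connectivity,
                            candidates = c(-600, -500, -400, -300, -150)) {
  best_upper <- candidates[1L]
  best_area <- -1L
  for (u in candidates) {
    b <- slice_hu >= lower_hu & slice_hu <= u
    if (!any(b)) next
    lab <- label_components(array(b, c(dim(b), 1L)), connectivity)$labels[, , 1L]
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    border <- setdiff(border, 0L)
    keep <- lab > 0L & !(lab %in% border)
    area <- sum(keep)
    if (area > best_area) {
      best_area <- area
      best_upper <- u
    }
  }
  best_upper
}

#' Automatic lung segmentation of a thoracic CT volume
#'
#' Slice-wise threshold region growing assembled into a whole-lung
#' segmentation. In-band voxels (within the HU threshold band) are grouped
#' into 3-D connected components (in-plane connectivity per `params`, plus
#' adjacency across neighbouring slices). The trachea / proximal bronchial
#' tree — and air outside the body — are removed as the in-band components
#' that intersect the most superior in-band slice within a midline corridor
#' (`|x - midline| < corridor`). Of the remaining components, the two largest
#' become the lungs, assigned left/right by centroid relative to the body
#' midline; a single merged candidate spanning the midline is split at the
#' midline plane. Hilar vessels and other soft tissue are excluded
#' automatically by the upper threshold. Optionally the margins are dilated
#' in-plane by up to `pleural_sliver_mm`, and flagged dependent-atelectasis
#' voxels are merged into the nearest-side lung label.
#'
#' @param ct A CT [voxel_volume()].
#' @param params A [segmentation_params()] (see [segmentation_preset()]).
#' @param atelectasis Optional logical array (same grid) or [region_mask()]
#'   carrying an `atelectasis` label, merged in when
#'   `params$include_atelectasis` is `TRUE`.
#' @param seeds Optional list with logical arrays `left` and `right` used as
#'   manual seeds instead of the automatic two-largest-components rule.
#' @param midline_x Physical x (mm) of the body midline; defaults to the
#'   grid center.
#' @param trachea_corridor_mm Half-width of the midline corridor used for
#'   trachea removal (default 25 mm).
#' @param min_component_cm3 Minimum candidate volume (default 50 cm^3).
#' @return A [region_mask()] with `left_lung` and `right_lung` labels.
#' @export
segment_lungs <- function(ct, params = segmentation_params(), atelectasis = NULL,
                          seeds = NULL, midline_x = NULL,
                          trachea_corridor_mm = 25, min_component_cm3 = 50) {
  stopifnot(inherits(ct, "voxel_volume"))
  if (ct$modality != "CT") {
    stop("lung segmentation requires a CT volume", call. = FALSE)
  }
  d <- dim(ct$data)
  sp <- ct$spacing
  xs <- axis_coords(d[1], sp[1], ct$origin[1])
  if (is.null(midline_x)) midline_x <- mean(range(xs))

  if (params$upper_search) {
    band <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      sl <- ct$data[, , k]
      u <- search_upper_hu(sl, params$lower_hu, params$connectivity)
      band[, , k] <- sl >= params$lower_hu & sl <= u
    }
  } else {
    band <- ct$data >= params$lower_hu & ct$data <= params$upper_hu
  }
  if (!any(band)) stop("no voxels within the threshold band", call. = FALSE)

  comp <- label_components(band, params$connectivity, link_z = TRUE)
  lab3 <- comp$labels

  # trachea / outside-air removal: components present on the most superior
  # in-band slice within the midline corridor
  k_top <- max(which(apply(band, 3L, any)))
  top_lab <- lab3[, , k_top]
  corridor <- abs(xs - midline_x) < trachea_corridor_mm
  trachea_ids <- setdiff(unique(as.vector(top_lab[corridor, ])), 0L)
  keep_ids <- setdiff(seq_along(comp$sizes), trachea_ids)

  vv <- voxel_cm3(ct)
  keep_ids <- keep_ids[comp$sizes[keep_ids] * vv >= min_component_cm3]
  if (!length(keep_ids)) {
    stop("no lung candidate components found after trachea removal", call. = FALSE)
  }

  if (!is.null(seeds)) {
    left_sel <- flood_grow(band & !(lab3 %in% trachea_ids), seeds$left,
                           conn_offsets(params$connectivity, link_z = TRUE))
    right_sel <- flood_grow(band & !(lab3 %in% trachea_ids), seeds$right,
                            conn_offsets(params$connectivity, link_z = TRUE))
  } else {
    ord <- keep_ids[order(comp$sizes[keep_ids], decreasing = TRUE)]
    xcoord <- array(rep(xs, times = d[2] * d[3]), d)
    centroid_x <- function(id) mean(xcoord[lab3 == id])
    if (length(ord) >= 2L) {
      c1 <- centroid_x(ord[1L]); c2 <- centroid_x(ord[2L])
      if ((c1 - midline_x) * (c2 - midline_x) < 0) {
        left_id <- if (c1 > c2) ord[1L] else ord[2L]
        right_id <- if (c1 > c2) ord[2L] else ord[1L]
        left_sel <- lab3 == left_id
        right_sel <- lab3 == right_id
      } else {
        stop("left/right assignment ambiguous: two largest candidates lie on ",
             "the same side of the midline (centroids ", round(c1), ", ",
             round(c2), " mm vs midline ", round(midline_x), " mm)",
             call. = FALSE)
      }
    } else {
      # one candidate: accept only a merged-lung component spanning the midline
      sel <- lab3 == ord[1L]
      span <- range(xcoord[sel])
      if (span[1] < midline_x && span[2] > midline_x) {
        left_sel <- sel & (xcoord > midline_x)
        right_sel <- sel & (xcoord <= midline_x)
      } else {
        stop("fewer than 2 lung candidates found", call. = FALSE)
      }
    }
  }
  if (!any(left_sel) || !any(right_sel)) {
    stop("fewer than 2 lung candidates found", call. = FALSE)
  }

  # pleural sliver: in-plane dilation by <= pleural_sliver_mm, never into the
  # other lung
  n_dil <- floor(params$pleural_sliver_mm / min(sp[1], sp[2]) + 1e-9)
  if (n_dil > 0) {
    offs <- conn_offsets(4, link_z = FALSE)
    for (i in seq_len(n_dil)) {
      left_sel <- dilate_logical(left_sel, offs) & !right_sel
      right_sel <- dilate_logical(right_sel, offs) & !left_sel
    }
  }

  if (params$include_atelectasis && !is.null(atelectasis)) {
    at <- if (inherits(atelectasis, "region_mask")) {
      mask_array(atelectasis, "atelectasis")
    } else {
      atelectasis
    }
    xcoord <- array(rep(xs, times = d[2] * d[3]), d)
    left_sel <- left_sel | (at & xcoord > midline_x)
    right_sel <- right_sel | (at & xcoord <= midline_x)
  }

  labels <- array(0L, d)
  labels[right_sel] <- 2L
  labels[left_sel] <- 1L
  region_mask(labels, sp, origin = ct$origin)
}

#' Per-lung volume from stacked trans-axial ROIs
#'
#' Default convention: volume is the sum of slice ROI areas times the slice
#' thickness. The `"interpolate"` mode integrates a piecewise-linear area
#' profile between slice centers with areas tapering to zero half a slice
#' beyond the first and last occupied slices (a contour-interpolation
#' surrogate for partial-volume apex/base slices); on smooth convex regions
#' the two agree within about 2%.
#'
#' @param mask A [region_mask()].
#' @param regions Region names; defaults to both lungs.
#' @param method `"sum"` or `"interpolate"`.
#' @return A tibble with `region`, `volume_cm3`, `n_slices`.
#' @export
lung_volume_from_rois <- function(mask, regions = c("left_lung", "right_lung"),
                                  method = c("sum", "interpolate")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "region_mask"))
  sp <- mask$spacing
  px_mm2 <- sp[1] * sp[2]
  one <- function(region) {
    sel <- mask_array(mask, region)
    if (!any(sel)) stop("region '", region, "' is empty", call. = FALSE)
    areas <- apply(sel, 3L, sum) * px_mm2   # mm^2 per slice
    occ <- which(areas > 0)
    a <- areas[occ]
    vol_mm3 <- if (method == "sum" || length(a) == 1L) {
      sum(a) * sp[3]
    } else {
      # trapezoid between centers + triangular half-slice end caps
      sum((a[-1] + a[-length(a)]) / 2) * sp[3] + (a[1] + a[length(a)]) * sp[3] / 4
    }
    tibble::tibble(region = region, volume_cm3 = vol_mm3 / 1000,
                   n_slices = length(occ))
  }
  do.call(rbind, lapply(regions, one))
}

#' Dice overlap coefficient
#'
#' @param a,b Logical arrays of equal dimension, or [region_mask()]s with
#'   `region` naming the label to compare.
#' @param region Region name when masks are given.
#' @return Dice coefficient `2|A & B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b, region = NULL) {
  if (inherits(a, "region_mask")) a <- mask_array(a, region)
  if (inherits(b, "region_mask")) b <- mask_array(b, region)
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
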
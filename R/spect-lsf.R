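#' Locate the diaphragm apex under one lung
#'
#' For every in-plane column (x, y) intersecting the lung, the inferior-most
#' lung voxel marks the lung base; the diaphragm apex is taken as the most
#' superior such base over the central portion of the lung footprint (the
#' central two-thirds by default, measured as an elliptical fraction of the
#' footprint's extent about its centroid). Restricting to the footprint core
#' keeps costophrenic recesses from dragging the estimate down and keeps
#' columns that graze the lung's anterior/posterior rim — whose inferior
#' boundary is chest wall, not diaphragm — from pushing it up.
#'
#' @param lung_mask A [region_mask()].
#' @param side `"left_lung"` or `"right_lung"`.
#' @param medial_fraction Fractional (elliptical) radius of the footprint
#'   core over which column bases are considered (default 2/3).
#' @return Apex position in mm along z (voxel-center convention).
#' @export
find_diaphragm_apex <- function(lung_mask, side = c("right_lung", "left_lung"),
                                medial_fraction = 2 / 3) {
  side <- match.arg(side)
  stopifnot(inherits(lung_mask, "region_mask"))
  sel <- mask_array(lung_mask, side)
  if (!any(sel)) stop("lung label '", side, "' is empty", call. = FALSE)
  d <- dim(sel)
  sp <- lung_mask$spacing
  xs <- axis_coords(d[1], sp[1], lung_mask$origin[1])
  ys <- axis_coords(d[2], sp[2], lung_mask$origin[2])
  zs <- axis_coords(d[3], sp[3], lung_mask$origin[3])

  footprint <- apply(sel, c(1L, 2L), any)
  fidx <- which(footprint, arr.ind = TRUE)
  fx <- xs[fidx[, 1]]
  fy <- ys[fidx[, 2]]
  ctr <- c(mean(range(fx)), mean(range(fy)))
  half_ext <- c(diff(range(fx)), diff(range(fy))) / 2
  semi <- pmax(half_ext, sp[1:2])  # guard degenerate flat footprints
  u2 <- outer(((xs - ctr[1]) / semi[1])^2, ((ys - ctr[2]) / semi[2])^2, `+`)
  core <- u2 <= medial_fraction^2

  # inferior-most occupied slice per column
  base_z <- apply(sel, c(1L, 2L), function(col) {
    w <- which(col)
    if (length(w)) zs[w[1L]] else NA_real_
  })
  base_z[!core] <- NA_real_
  if (all(is.na(base_z))) {
    stop("no lung columns within the footprint core", call. = FALSE)
  }
  max(base_z, na.rm = TRUE)
}

#' Apply supra-diaphragmatic exclusion zones
#'
#' Free-breathing SPECT/CT mis-registers liver-dome activity into the lung
#' bases. Counts below a per-side trans-axial cut-off — `margin_mm`
#' (default 15 mm, i.e. 1.5 cm) above each diaphragm apex — are excluded
#' from quantification. Retained lung voxels have center z strictly greater
#' than their side's cut-off; cut-offs may differ between sides.
#'
#' @param lung_mask A [region_mask()] with lung labels.
#' @param margin_mm Margin above each diaphragm apex in mm (>= 0).
#' @param apex_z Optional named list/vector with `left_lung` and/or
#'   `right_lung` apex overrides in mm; auto-estimated via
#'   [find_diaphragm_apex()] when absent.
#' @return List with `mask_above` (a [region_mask()] restricted to retained
#'   lung voxels), `cutoff_z` (named, mm) and `apex_z` (named, mm).
#' @export
apply_exclusion_zone <- function(lung_mask, margin_mm = 15, apex_z = NULL) {
  stopifnot(inherits(lung_mask, "region_mask"))
  if (margin_mm < 0) stop("`margin_mm` must be >= 0", call. = FALSE)
  d <- dim(lung_mask$labels)
  zs <- axis_coords(d[3], lung_mask$spacing[3], lung_mask$origin[3])
  zcoord <- array(rep(zs, each = d[1] * d[2]), d)

  sides <- c("left_lung", "right_lung")
  sides <- sides[vapply(sides, function(s) any(mask_array(lung_mask, s)), logical(1))]
  if (!length(sides)) stop("no lung labels present", call. = FALSE)
  apex <- vapply(sides, function(s) {
    if (!is.null(apex_z) && !is.null(apex_z[[s]]) && !is.na(apex_z[[s]])) {
      as.numeric(apex_z[[s]])
    } else {
      find_diaphragm_apex(lung_mask, s)
    }
  }, numeric(1))
  cutoff <- apex + margin_mm

  labels_above <- lung_mask$labels
  for (s in sides) {
    lab <- lung_mask$label_map[[s]]
    drop <- lung_mask$labels == lab & zcoord <= cutoff[[s]]
    labels_above[drop] <- 0L
    if (!any(labels_above == lab)) {
      stop("exclusion zone removes the entire ", s,
           " (cutoff ", round(cutoff[[s]], 1), " mm)", call. = FALSE)
    }
  }
  # non-lung labels are not part of the retained mask
  lung_labs <- lung_mask$label_map[sides]
  labels_above[!(labels_above %in% lung_labs)] <- 0L
  list(
    mask_above = region_mask(labels_above, lung_mask$spacing,
                             lung_mask$label_map, lung_mask$origin),
    cutoff_z = cutoff,
    apex_z = apex
  )
}

#' Cylindrical soft-tissue background VOI
#'
#' Builds the voxel mask of a cylinder aligned with z (the long VOI placed
#' along the left erector spinae muscle in the posterior abdomen). When a CT
#' volume is supplied, the VOI is validated to lie wholly in soft tissue
#' (all CT numbers within \[-100, 200\] HU).
#'
#' @param template A [voxel_volume()] or [region_mask()] defining the grid.
#' @param center_xy Cylinder axis position (x, y) in mm.
#' @param radius_mm Cylinder radius in mm (> 0).
#' @param z_extent Length-2 vector `(z_lo, z_hi)` in mm.
#' @param ct Optional CT [voxel_volume()] for the soft-tissue check.
#' @return Logical 3-D array.
#' @export
background_voi_cylinder <- function(template, center_xy, radius_mm, z_extent,
                                    ct = NULL) {
  if (radius_mm <= 0) stop("`radius_mm` must be positive", call. = FALSE)
  d <- if (inherits(template, "region_mask")) dim(template$labels) else dim(template$data)
  sp <- template$spacing
  org <- template$origin
  xs <- axis_coords(d[1], sp[1], org[1])
  ys <- axis_coords(d[2], sp[2], org[2])
  zs <- axis_coords(d[3], sp[3], org[3])
  in_xy <- outer((xs - center_xy[1])^2, (ys - center_xy[2])^2, `+`) <= radius_mm^2
  in_z <- zs >= z_extent[1] & zs <= z_extent[2]
  voi <- array(FALSE, d)
  voi[, , in_z] <- in_xy
  if (!any(voi)) stop("background VOI lies outside the volume", call. = FALSE)
  if (!is.null(ct)) {
    hu <- ct$data[voi]
    if (any(hu < -100 | hu > 200)) {
      stop("background VOI is not wholly within soft tissue ",
           "(CT numbers outside [-100, 200] HU)", call. = FALSE)
    }
  }
  voi
}

#' Background count density in a VOI
#'
#' Total SPECT counts inside the VOI divided by the VOI volume, in
#' counts/cm^3.
#'
#' @param spect A SPECT [voxel_volume()].
#' @param voi Logical 3-D array (e.g. from [background_voi_cylinder()]) or a
#'   [region_mask()] whose `background_voi` label is used.
#' @return Count density in counts/cm^3.
#' @export
background_count_density <- function(spect, voi) {
  stopifnot(inherits(spect, "voxel_volume"))
  if (inherits(voi, "region_mask")) voi <- mask_array(voi, "background_voi")
  if (!identical(dim(voi), dim(spect$data))) {
    stop("VOI does not match the SPECT grid", call. = FALSE)
  }
  n <- sum(voi)
  if (n == 0L) stop("background VOI is empty", call. = FALSE)
  sum(spect$data[voi]) / (n * voxel_cm3(spect))
}

#' Background correction and whole-lung extrapolation of lung counts
#'
#' Implements the SPECT/CT lung count chain: the lung parenchyma *tissue*
#' volume above the exclusion zone is the parenchyma mass divided by
#' 1.04 g/cm^3 (the assumed density of general soft tissue — distinct from
#' the lung mean density, since aerated lung is mostly air by volume); the
#' lung background counts are the background count density times that tissue
#' volume; corrected counts above the zone are raw counts minus background
#' (clamped at zero with a warning); dividing by the CT lung volume above
#' the zone gives the background-corrected lung mean count density, assumed
#' representative of the entire lung; multiplying by the total CT lung
#' volume extrapolates to whole-lung counts.
#'
#' @param raw_above Raw lung counts above the exclusion zone.
#' @param mass_above_g Lung parenchyma mass above the zone, g.
#' @param bg_density Background count density, counts/cm^3.
#' @param ct_vol_above CT lung volume above the zone, cm^3 (> 0).
#' @param ct_vol_total Total CT lung volume, cm^3.
#' @param tissue_density_g_cm3 Assumed soft-tissue density (default 1.04).
#' @return A one-row tibble: `tissue_vol_cm3`, `bg_counts`,
#'   `corrected_above`, `mean_count_density`, `total_lung_counts`.
#' @export
corrected_lung_counts <- function(raw_above, mass_above_g, bg_density,
                                  ct_vol_above, ct_vol_total,
                                  tissue_density_g_cm3 = 1.04) {
  if (any(c(raw_above, mass_above_g, bg_density, ct_vol_above, ct_vol_total) < 0)) {
    stop("all count, mass and volume inputs must be non-negative", call. = FALSE)
  }
  if (ct_vol_above == 0) {
    stop("CT lung volume above the exclusion zone must be positive", call. = FALSE)
  }
  tissue_vol <- mass_above_g / tissue_density_g_cm3
  bg_counts <- bg_density * tissue_vol
  corrected <- raw_above - bg_counts
  if (corrected < 0) {
    warning("background subtraction exceeds raw lung counts; clamped to 0",
            call. = FALSE)
    corrected <- 0
  }
  mean_density <- corrected / ct_vol_above
  tibble::tibble(
    tissue_vol_cm3 = tissue_vol,
    bg_counts = bg_counts,
    corrected_above = corrected,
    mean_count_density = mean_density,
    total_lung_counts = mean_density * ct_vol_total
  )
}

#' Lung shunt fraction from total lung and territory counts
#'
#' `LSF = lung / (lung + territory)` where `territory` is the
#' background-corrected count total of all target hepatic arterial
#' territories (supplied as an input; its derivation belongs to the liver
#' dosimetry workflow).
#'
#' @param total_lung_counts Whole-lung background-corrected counts.
#' @param territory_counts Target hepatic territory counts.
#' @return A one-row tibble with `method = "spectct"`, `lsf`, `lsf_pct` and
#'   the two count totals.
#' @export
spectct_lsf <- function(total_lung_counts, territory_counts) {
  if (total_lung_counts < 0 || territory_counts < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (total_lung_counts == 0 && territory_counts == 0) {
    stop("lung and territory counts are both zero; shunt fraction undefined",
         call. = FALSE)
  }
  lsf <- total_lung_counts / (total_lung_counts + territory_counts)
  tibble::tibble(
    method = "spectct", lsf = lsf, lsf_pct = 100 * lsf,
    lung_counts_total = total_lung_counts, territory_counts = territory_counts
  )
}

pick_side <- function(v, nm) if (nm %in% names(v)) unname(v[[nm]]) else NA_real_

#' Full SPECT/CT lung shunt fraction pipeline
#'
#' Orchestrates the SPECT/CT quantification on co-registered SPECT counts,
#' CT, and a lung label mask: per-side diaphragm apex detection, exclusion
#' zones `margin_mm` above the apices, background count density from a
#' soft-tissue VOI, densitovolumetry of the retained lung for the
#' mass-derived tissue volume, background subtraction, count-density
#' extrapolation to the whole lung, and the shunt fraction against the
#' supplied hepatic territory counts. With `margin_mm = NULL` the exclusion
#' zone is disabled (naive whole-lung quantification), retained for
#' comparison studies.
#'
#' @param spect SPECT [voxel_volume()] (counts).
#' @param ct Co-registered CT [voxel_volume()].
#' @param labels [region_mask()] with lung labels (and optionally a
#'   `background_voi` label).
#' @param territory_counts Background-corrected target hepatic territory
#'   counts (input; see [spectct_lsf()]).
#' @param margin_mm Exclusion-zone margin (default 15 mm); `NULL` disables.
#' @param apex_z Optional per-side apex overrides (see
#'   [apply_exclusion_zone()]).
#' @param bg_voi Background VOI: logical array, or `NULL` to use the mask's
#'   `background_voi` label.
#' @return A one-row tibble (class `lsf_result`) with the shunt fraction and
#'   all audit intermediates: raw/corrected counts above the zone, apex and
#'   cutoff positions, background density, CT volumes, parenchyma mass above
#'   the zone, mean count density.
#' @export
spect_lsf_pipeline <- function(spect, ct, labels, territory_counts,
                               margin_mm = 15, apex_z = NULL, bg_voi = NULL) {
  stopifnot(inherits(spect, "voxel_volume"), inherits(ct, "voxel_volume"),
            inherits(labels, "region_mask"))
  check_same_grid(spect, ct)
  check_same_grid(spect, labels)

  lung_all <- mask_array(labels, c("left_lung", "right_lung"))
  if (!any(lung_all)) stop("no lung labels present", call. = FALSE)

  if (is.null(bg_voi)) {
    bg_density <- background_count_density(spect, labels)
  } else {
    bg_density <- background_count_density(spect, bg_voi)
  }

  if (is.null(margin_mm)) {
    mask_above <- labels
    zone <- list(cutoff_z = c(left_lung = NA_real_, right_lung = NA_real_),
                 apex_z = c(left_lung = NA_real_, right_lung = NA_real_))
  } else {
    zone <- apply_exclusion_zone(labels, margin_mm = margin_mm, apex_z = apex_z)
    mask_above <- zone$mask_above
  }
  above <- mask_array(mask_above, c("left_lung", "right_lung"))

  dv_above <- region_densitovolumetry(ct, mask_above)
  dv_total <- region_densitovolumetry(ct, labels)
  mass_above <- dv_above$mass_g[dv_above$region == "both_lungs"]
  vol_above <- dv_above$volume_cm3[dv_above$region == "both_lungs"]
  vol_total <- dv_total$volume_cm3[dv_total$region == "both_lungs"]

  raw_above <- sum(spect$data[above])
  corr <- corrected_lung_counts(raw_above, mass_above, bg_density,
                                vol_above, vol_total)
  res <- spectct_lsf(corr$total_lung_counts, territory_counts)
  out <- tibble::tibble(
    method = "spectct",
    lsf = res$lsf,
    lsf_pct = res$lsf_pct,
    lung_counts_total = res$lung_counts_total,
    territory_counts = territory_counts,
    bg_count_density = bg_density,
    lung_counts_above_zone_raw = raw_above,
    lung_counts_above_zone_corrected = corr$corrected_above,
    lung_mean_count_density = corr$mean_count_density,
    ct_lung_volume_above_zone = vol_above,
    ct_lung_volume_total = vol_total,
    mass_above_zone_g = mass_above,
    apex_z_left = pick_side(zone$apex_z, "left_lung"),
    apex_z_right = pick_side(zone$apex_z, "right_lung"),
    cutoff_z_left = pick_side(zone$cutoff_z, "left_lung"),
    cutoff_z_right = pick_side(zone$cutoff_z, "right_lung")
  )
  class(out) <- c("lsf_result", class(out))
  out
}
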
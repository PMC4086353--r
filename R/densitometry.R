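#' Convert CT numbers to physical density
#'
#' Linear CT-number-to-density conversion used for lung CT densitometry:
#' `density = (CT number + 1000) / 1000` g/cm^3, anchored at water (0 HU,
#' 1 g/cm^3) and air (-1000 HU, 0 g/cm^3). The linearity is validated for CT
#' numbers at or below 0 HU (the lung-to-water range); positive CT numbers are
#' accepted — lung ROIs deliberately include dependent atelectasis and
#' vessels — but a warning flags them as outside the validated domain.
#'
#' @param mean_ct_number CT number(s) in Hounsfield units; must be >= -1000.
#' @return Physical density in g/cm^3, same length as the input.
#' @examples
#' hu_to_density(0)      # water, 1.0
#' hu_to_density(-802)   # inspiratory whole-lung mean, 0.198
#' @export
hu_to_density <- function(mean_ct_number) {
  if (any(!is.finite(mean_ct_number))) {
    stop("CT numbers must be finite", call. = FALSE)
  }
  if (any(mean_ct_number < -1000)) {
    stop("CT number below -1000 HU implies negative physical density", call. = FALSE)
  }
  if (any(mean_ct_number > 0)) {
    warning("CT number(s) > 0 HU: outside the validated linearity domain (<= 0 HU); ",
            "converted as-is", call. = FALSE)
  }
  (mean_ct_number + 1000) / 1000
}

#' Per-region CT densitovolumetry
#'
#' Computes, for each requested region of a label mask over a CT volume: the
#' region volume (voxel count times voxel volume), the mean CT number, the
#' mean density via [hu_to_density()], and the parenchyma mass as
#' `volume * mean density`. The mass convention is mean-then-convert — the
#' density conversion is applied to the region's *mean* CT number. Because
#' the conversion is affine this is identical to summing per-voxel masses;
#' the per-voxel sum is nevertheless reported as `mass_voxelwise_g` so the
#' equality can be audited.
#'
#' When both `left_lung` and `right_lung` are among the regions, a
#' `both_lungs` row is appended whose mass is the sum of the per-lung masses
#' and whose density is the volume-weighted mean.
#'
#' @param ct A CT [voxel_volume()].
#' @param mask A [region_mask()] on the same grid.
#' @param regions Region names to evaluate; defaults to the lung labels
#'   present in the mask (including atelectasis merged into neither lung —
#'   atelectasis voxels are counted with the lung only if the mask was built
#'   that way by [segment_lungs()]).
#' @return A tibble with one row per region: `region`, `n_voxels`,
#'   `volume_cm3`, `mean_hu`, `mean_density_g_cm3`, `mass_g`,
#'   `mass_voxelwise_g`.
#' @export
region_densitovolumetry <- function(ct, mask, regions = NULL) {
  stopifnot(inherits(ct, "voxel_volume"), inherits(mask, "region_mask"))
  if (ct$modality != "CT") {
    stop("densitovolumetry requires a CT volume", call. = FALSE)
  }
  check_same_grid(ct, mask)
  if (is.null(regions)) {
    present <- names(mask$label_map)[mask$label_map %in% unique(as.vector(mask$labels))]
    regions <- intersect(c("left_lung", "right_lung"), present)
    if (!length(regions)) {
      stop("no lung regions present in mask; supply `regions` explicitly", call. = FALSE)
    }
  }
  vv <- voxel_cm3(ct)
  one <- function(region) {
    sel <- mask_array(mask, region)
    n <- sum(sel)
    if (n == 0L) {
      stop("region '", region, "' is empty", call. = FALSE)
    }
    hu <- ct$data[sel]
    mean_hu <- mean(hu)
    dens <- suppressWarnings(hu_to_density(mean_hu))
    if (mean_hu > 0) {
      warning("region '", region, "' has mean CT number > 0 HU (",
              round(mean_hu, 1), "): outside the validated linearity domain",
              call. = FALSE)
    }
    vol <- n * vv
    tibble::tibble(
      region = region,
      n_voxels = n,
      volume_cm3 = vol,
      mean_hu = mean_hu,
      mean_density_g_cm3 = dens,
      mass_g = vol * dens,
      mass_voxelwise_g = sum(vv * suppressWarnings(hu_to_density(hu)))
    )
  }
  out <- do.call(rbind, lapply(regions, one))
  if (all(c("left_lung", "right_lung") %in% out$region)) {
    lungs <- out[out$region %in% c("left_lung", "right_lung"), ]
    vol <- sum(lungs$volume_cm3)
    mass <- sum(lungs$mass_g)
    both <- tibble::tibble(
      region = "both_lungs",
      n_voxels = sum(lungs$n_voxels),
      volume_cm3 = vol,
      mean_hu = sum(lungs$mean_hu * lungs$n_voxels) / sum(lungs$n_voxels),
      mean_density_g_cm3 = mass / vol,
      mass_g = mass,
      mass_voxelwise_g = sum(lungs$mass_voxelwise_g)
    )
    out <- rbind(out, both)
  }
  out
}

#' Water-phantom QA for CT densitometry
#'
#' Quality-assurance check of the CT-number-to-density conversion against a
#' water phantom: density is computed from the mean CT number inside a VOI
#' and compared to the expected water density of 1 g/cm^3. The signed percent
#' error is `(density - 1) / 1 * 100`.
#'
#' @param ct A CT [voxel_volume()] of the water phantom.
#' @param voi A [region_mask()] on the same grid; by default the
#'   `background_voi` label is used, or supply `region`.
#' @param region Region name of the VOI within `voi`.
#' @return A one-row tibble: `mean_hu`, `density_g_cm3`, `percent_error`.
#' @export
water_phantom_qa <- function(ct, voi, region = "background_voi") {
  stopifnot(inherits(ct, "voxel_volume"), inherits(voi, "region_mask"))
  check_same_grid(ct, voi)
  sel <- mask_array(voi, region)
  if (!any(sel)) {
    stop("water-phantom VOI is empty", call. = FALSE)
  }
  mean_hu <- mean(ct$data[sel])
  density <- suppressWarnings(hu_to_density(mean_hu))
  tibble::tibble(
    mean_hu = mean_hu,
    density_g_cm3 = density,
    percent_error = (density - 1) / 1 * 100
  )
}
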
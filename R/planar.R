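#' Anterior/posterior planar image pair
#'
#' Container for a matched pair of 2-D planar count images. The posterior
#' image must already be supplied left-right matched to the anterior frame
#' (i.e. both images share the same pixel coordinates), so ROIs can be
#' applied to both views unchanged.
#'
#' @param anterior,posterior 2-D non-negative count matrices of equal shape.
#' @param pixel_spacing Pixel spacing in mm (length 1 or 2).
#' @return An object of class `planar_pair`.
#' @export
planar_pair <- function(anterior, posterior, pixel_spacing) {
  stopifnot(is.matrix(anterior), is.matrix(posterior))
  if (!identical(dim(anterior), dim(posterior))) {
    stop("anterior and posterior images must have the same shape", call. = FALSE)
  }
  if (any(!is.finite(anterior)) || any(!is.finite(posterior)) ||
      any(anterior < 0) || any(posterior < 0)) {
    stop("planar counts must be finite and non-negative", call. = FALSE)
  }
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  structure(
    list(anterior = anterior, posterior = posterior, pixel_spacing = pixel_spacing),
    class = "planar_pair"
  )
}

#' Geometric-mean counts over a planar ROI
#'
#' The geometric mean `sqrt(sum_A * sum_P)` of the total anterior and
#' posterior counts inside an ROI. For a point source in a uniform
#' attenuator the geometric mean is independent of source depth, which is
#' why conventional shunt quantification uses it.
#'
#' @param pair A [planar_pair()].
#' @param roi Logical matrix (same shape) selecting the ROI.
#' @return Geometric-mean counts (scalar). Zero with a warning if both views
#'   contain no counts in the ROI.
#' @export
geometric_mean_counts <- function(pair, roi) {
  stopifnot(inherits(pair, "planar_pair"), is.logical(roi))
  if (!identical(dim(roi), dim(pair$anterior))) {
    stop("ROI shape does not match the planar images", call. = FALSE)
  }
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  sa <- sum(pair$anterior[roi])
  sp <- sum(pair$posterior[roi])
  if (sa == 0 && sp == 0) {
    warning("ROI contains no counts on either view; geometric mean is 0",
            call. = FALSE)
    return(0)
  }
  sqrt(sa * sp)
}

#' Simple background correction for a planar ROI
#'
#' Count-density subtraction: the background ROI's counts per pixel are
#' scaled to the target ROI's area and subtracted, per view, before the
#' geometric mean is taken. Negative corrected counts are clamped to zero
#' with a warning.
#'
#' @param roi_counts Total counts inside the target ROI (one view).
#' @param roi_area Target ROI area in pixels.
#' @param bg_counts Total counts inside the background ROI (same view).
#' @param bg_area Background ROI area in pixels (> 0).
#' @return Background-corrected counts, `>= 0`.
#' @export
background_correct_planar <- function(roi_counts, roi_area, bg_counts, bg_area) {
  if (bg_area <= 0) stop("background ROI area must be positive", call. = FALSE)
  if (roi_area <= 0) stop("target ROI area must be positive", call. = FALSE)
  corrected <- roi_counts - (bg_counts / bg_area) * roi_area
  if (corrected < 0) {
    warning("background density exceeds ROI density; corrected counts clamped to 0",
            call. = FALSE)
    corrected <- 0
  }
  corrected
}

#' Lung shunt fraction from lung and liver counts
#'
#' `LSF = lung / (lung + liver)`, the conventional formalism, with counts
#' already background-corrected and geometric-meaned.
#'
#' @param lung_counts_gm,liver_counts_gm Non-negative geometric-mean counts;
#'   not both zero.
#' @return Fraction in \[0, 1\].
#' @export
planar_lsf <- function(lung_counts_gm, liver_counts_gm) {
  if (lung_counts_gm < 0 || liver_counts_gm < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (lung_counts_gm == 0 && liver_counts_gm == 0) {
    stop("lung and liver counts are both zero; shunt fraction undefined",
         call. = FALSE)
  }
  lung_counts_gm / (lung_counts_gm + liver_counts_gm)
}

#' Conventional planar LSF workflow
#'
#' Full planar quantification: per-view background correction of the lung
#' and liver ROI counts (count-density subtraction using the background
#' ROI), geometric mean of the corrected counts across views, then the
#' lung shunt fraction. No attenuation or scatter correction is applied,
#' matching conventional methodology.
#'
#' @param pair A [planar_pair()].
#' @param rois Integer label matrix (same shape): 1 = lungs, 2 = liver,
#'   3 = background ROI; or a list of logical matrices `lung`, `liver`,
#'   `background`.
#' @return A one-row tibble with `method = "planar"`, the shunt fraction
#'   (`lsf`, and `lsf_pct`), the geometric-mean lung and liver counts, and
#'   per-view raw/corrected intermediates for audit.
#' @export
planar_lsf_from_images <- function(pair, rois) {
  stopifnot(inherits(pair, "planar_pair"))
  if (is.list(rois) && !is.matrix(rois)) {
    lung <- rois$lung; liver <- rois$liver; bg <- rois$background
  } else {
    lung <- rois == 1L; liver <- rois == 2L; bg <- rois == 3L
  }
  for (nm in c("lung", "liver", "bg")) {
    m <- get(nm)
    if (is.null(m) || !any(m)) stop(nm, " ROI is empty", call. = FALSE)
  }
  corr <- function(view) {
    img <- pair[[view]]
    bg_counts <- sum(img[bg]); bg_area <- sum(bg)
    c(
      lung = background_correct_planar(sum(img[lung]), sum(lung), bg_counts, bg_area),
      liver = background_correct_planar(sum(img[liver]), sum(liver), bg_counts, bg_area)
    )
  }
  ant <- corr("anterior")
  post <- corr("posterior")
  lung_gm <- sqrt(ant[["lung"]] * post[["lung"]])
  liver_gm <- sqrt(ant[["liver"]] * post[["liver"]])
  lsf <- planar_lsf(lung_gm, liver_gm)
  tibble::tibble(
    method = "planar",
    lsf = lsf,
    lsf_pct = 100 * lsf,
    lung_counts_gm = lung_gm,
    liver_counts_gm = liver_gm,
    lung_ant_corrected = ant[["lung"]], lung_post_corrected = post[["lung"]],
    liver_ant_corrected = ant[["liver"]], liver_post_corrected = post[["liver"]],
    lung_ant_raw = sum(pair$anterior[lung]), lung_post_raw = sum(pair$posterior[lung]),
    liver_ant_raw = sum(pair$anterior[liver]), liver_post_raw = sum(pair$posterior[liver])
  )
}

#' Derive planar ROIs from a 3-D label mask
#'
#' Projects the lung and liver labels of a [region_mask()] along the
#' anterior-posterior axis into the planar frame and builds the three
#' conventional ROIs: lungs (excluding the mediastinal midline corridor and
#' any pixel where the liver also projects), liver, and a rectangular
#' background ROI placed in soft tissue lateral to the liver.
#'
#' @param labels A [region_mask()] with lung and liver labels.
#' @param body Optional body definition for background-ROI placement: a
#'   logical 3-D array of body voxels, or a CT [voxel_volume()] from which
#'   soft tissue (> -400 HU) is taken. When absent, the projection of the
#'   mask's `background_voi` label (guaranteed soft tissue) is used as the
#'   background ROI directly.
#' @param midline_exclusion_mm Half-width of the mediastinal corridor
#'   excluded from the lung ROI (default 25 mm).
#' @return Integer matrix in the planar (x, z) frame: 1 lungs, 2 liver,
#'   3 background.
#' @export
planar_rois_from_labels <- function(labels, body = NULL, midline_exclusion_mm = 25) {
  stopifnot(inherits(labels, "region_mask"))
  lungs3 <- mask_array(labels, c("left_lung", "right_lung"))
  if ("atelectasis" %in% names(labels$label_map) &&
      any(labels$labels == labels$label_map[["atelectasis"]])) {
    lungs3 <- lungs3 | mask_array(labels, "atelectasis")
  }
  liver3 <- mask_array(labels, "liver")
  proj <- function(a) apply(a, c(1L, 3L), any)
  lung2 <- proj(lungs3)
  liver2 <- proj(liver3)
  d <- dim(lung2)
  xs <- axis_coords(d[1], labels$spacing[1], labels$origin[1])
  midline <- mean(range(xs))
  corridor <- abs(xs - midline) < midline_exclusion_mm
  lung2[corridor, ] <- FALSE
  lung2 <- lung2 & !liver2

  if (is.null(body)) {
    if (!"background_voi" %in% names(labels$label_map) ||
        !any(labels$labels == labels$label_map[["background_voi"]])) {
      stop("supply `body` (or a mask with a background_voi label) to place ",
           "the planar background ROI", call. = FALSE)
    }
    bg2 <- proj(mask_array(labels, "background_voi")) & !lung2 & !liver2
  } else {
    body3 <- if (inherits(body, "voxel_volume")) body$data > -400 else body
    body2 <- proj(body3)
    zr <- range(which(apply(liver2, 2L, any)))
    liver_x_max <- max(which(apply(liver2, 1L, any)))
    lung_x <- which(apply(lung2, 1L, any))
    bg2 <- matrix(FALSE, d[1], d[2])
    cand_x <- setdiff(seq_len(d[1]), c(which(apply(liver2, 1L, any)), lung_x))
    cand_x <- cand_x[cand_x > liver_x_max]
    if (length(cand_x)) bg2[cand_x, zr[1]:zr[2]] <- TRUE
    bg2 <- bg2 & body2 & !lung2 & !liver2
  }
  out <- matrix(0L, d[1], d[2])
  out[bg2] <- 3L
  out[liver2] <- 2L
  out[lung2] <- 1L
  out
}
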
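#' Voxel volume container
#'
#' A minimal container for a 3-D scalar voxel grid (CT numbers in Hounsfield
#' units, or SPECT counts) with its physical voxel spacing. Axis conventions
#' follow radiological stacking: dimension 1 is x (increasing toward the
#' patient's left), dimension 2 is y (anterior to posterior), dimension 3 is z
#' (inferior to superior, i.e. toward the head). Physical positions are
#' voxel-center positions, `origin + (index - 1) * spacing` in mm for 1-based
#' array indices.
#'
#' @param data 3-D numeric array. CT data must be finite; SPECT data must be
#'   finite and non-negative.
#' @param spacing Numeric length-3 vector of voxel spacings `(dx, dy, dz)` in
#'   mm, all strictly positive.
#' @param modality One of `"CT"` or `"SPECT"`.
#' @param breathing_state One of `"breath-hold"`, `"free-breathing"`,
#'   `"unknown"`. Diagnostic chest CT is acquired at inspiratory breath-hold;
#'   the CT of a SPECT/CT is acquired free-breathing.
#' @param origin Physical position (mm) of the center of voxel `[1, 1, 1]`.
#'
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, modality = c("CT", "SPECT"),
                         breathing_state = c("unknown", "breath-hold", "free-breathing"),
                         origin = c(0, 0, 0)) {
  modality <- match.arg(modality)
  breathing_state <- match.arg(breathing_state)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel dimensions in mm", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("voxel data must be finite", call. = FALSE)
  }
  if (modality == "SPECT" && any(data < 0)) {
    stop("SPECT count data must be non-negative", call. = FALSE)
  }
  structure(
    list(
      data = data, spacing = spacing, modality = modality,
      breathing_state = breathing_state, origin = as.numeric(origin)
    ),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %s, %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s)\n",
    x$modality, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$breathing_state
  ))
  invisible(x)
}

#' Labeled region mask on a voxel grid
#'
#' Integer label volume sharing a [voxel_volume()]'s grid. The default label
#' map follows the package convention: 0 background, 1 left lung, 2 right
#' lung, 3 liver / target hepatic territory, 4 background VOI, 5 dependent
#' atelectasis.
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param spacing Voxel spacing in mm, as for [voxel_volume()].
#' @param label_map Named integer vector mapping region names to label values.
#' @param origin Physical position (mm) of the center of voxel `[1, 1, 1]`.
#'
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, spacing,
                        label_map = c(
                          left_lung = 1L, right_lung = 2L, liver = 3L,
                          background_voi = 4L, atelectasis = 5L
                        ),
                        origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel dimensions in mm", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (is.null(names(label_map)) || any(!nzchar(names(label_map)))) {
    stop("`label_map` must be a fully named integer vector", call. = FALSE)
  }
  structure(
    list(labels = labels, spacing = spacing, label_map = label_map,
         origin = as.numeric(origin)),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  d <- dim(x$labels)
  present <- x$label_map[x$label_map %in% unique(as.vector(x$labels))]
  cat(sprintf(
    "<region_mask> %d x %d x %d voxels; regions: %s\n",
    d[1], d[2], d[3],
    if (length(present)) paste(names(present), collapse = ", ") else "(none)"
  ))
  invisible(x)
}

#' Voxel volume in cm^3
#'
#' @param x A `voxel_volume` or `region_mask`, or a length-3 spacing vector in mm.
#' @return Volume of one voxel in cm^3 (`dx * dy * dz / 1000`).
#' @export
voxel_cm3 <- function(x) {
  sp <- if (is.numeric(x)) x else x$spacing
  prod(sp) / 1000
}

#' Extract a logical mask for one or more regions
#'
#' @param mask A [region_mask()].
#' @param regions Character vector of region names (from the mask's label map)
#'   or integer label values.
#' @return Logical 3-D array.
#' @export
mask_array <- function(mask, regions) {
  stopifnot(inherits(mask, "region_mask"))
  if (is.character(regions)) {
    unknown <- setdiff(regions, names(mask$label_map))
    if (length(unknown)) {
      stop("unknown region(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    regions <- mask$label_map[regions]
  }
  array(mask$labels %in% as.integer(regions), dim = dim(mask$labels))
}

# Voxel-center physical coordinate along one axis (1-based index k).
axis_coords <- function(n, spacing, origin = 0) origin + (seq_len(n) - 1) * spacing

# Shared-grid check used by every cross-container operation.
check_same_grid <- function(a, b) {
  da <- if (inherits(a, "region_mask")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "region_mask")) dim(b$labels) else dim(b$data)
  if (!identical(da, db)) {
    stop("grid mismatch: array dimensions differ (",
         paste(da, collapse = "x"), " vs ", paste(db, collapse = "x"), ")",
         call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop("grid mismatch: voxel spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a volume or label mask from NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] that return the package containers.
#' Voxel spacing is taken from the NIfTI `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality to record on the returned volume.
#' @param breathing_state Breathing state to record.
#' @param label_map Label map for the returned mask (see [region_mask()]).
#' @return A [voxel_volume()] or [region_mask()].
#' @export
read_volume_nifti <- function(path, modality = c("CT", "SPECT"),
                              breathing_state = c("unknown", "breath-hold", "free-breathing")) {
  img <- RNifti::readNifti(path)
  voxel_volume(
    data = array(as.numeric(img), dim = dim(img)),
    spacing = RNifti::pixdim(img)[1:3],
    modality = match.arg(modality),
    breathing_state = match.arg(breathing_state)
  )
}

#' @rdname read_volume_nifti
#' @export
read_mask_nifti <- function(path,
                            label_map = c(
                              left_lung = 1L, right_lung = 2L, liver = 3L,
                              background_voi = 4L, atelectasis = 5L
                            )) {
  img <- RNifti::readNifti(path)
  region_mask(
    labels = array(as.integer(round(as.numeric(img))), dim = dim(img)),
    spacing = RNifti::pixdim(img)[1:3],
    label_map = label_map
  )
}

#' Write a volume or mask to NIfTI
#'
#' @param x A [voxel_volume()] or [region_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  arr <- if (inherits(x, "region_mask")) x$labels else x$data
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
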
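#' Digital thorax phantom specification
#'
#' Parameter bundle for the synthetic thorax generator. Defaults emulate an
#' inspiratory breath-hold diagnostic-CT-style thorax: two ellipsoidal lungs
#' totalling about 4 L at a lung CT number of -784 HU (density 0.216
#' g/cm^3), a soft-tissue body, a liver capped by a spherical diaphragm
#' dome under the right lung, a midline trachea, and an erector-spinae
#' background VOI. The `"freebreathing"` preset shrinks the lungs by about
#' 30% in volume, raises the lung CT number to -701 HU (density 0.299),
#' adds basal dependent atelectasis, and turns on diaphragmatic
#' mis-registration of liver-dome activity into the lung bases.
#'
#' All geometry is in physical mm so the same anatomy can be voxelised at
#' any grid resolution; halving `grid_shape` while doubling `spacing` keeps
#' the physical phantom fixed.
#'
#' @param preset `"breathhold"` or `"freebreathing"`.
#' @param ... Overrides of any spec field, by name.
#' @return A list of class `phantom_spec`. Key fields:
#' \describe{
#'   \item{grid_shape, spacing_mm}{Voxel grid (default 96 x 96 x 84 at 4 mm).}
#'   \item{lung_hu, body_hu, liver_hu}{Compartment CT numbers.}
#'   \item{lung_semiaxes_mm, lung_offset_x_mm, lung_center_y_mm,
#'     lung_center_z_mm}{Lung ellipsoid geometry.}
#'   \item{dome_radius_mm, dome_apex_z_mm}{Spherical diaphragm domes
#'     (per side, named left/right); `dome_radius_mm = 0` gives flat lung
#'     bases with a detached slab liver (used when projection overlap of
#'     lung and liver must be avoided).}
#'   \item{trachea, trachea_radius_mm, trachea_z_min_mm}{Midline trachea.}
#'   \item{atelectasis_fraction}{Fraction of basal lung voxels converted to
#'     soft-tissue dependent atelectasis.}
#'   \item{true_lsf, total_counts}{True shunt fraction and total primary
#'     (lung + liver) counts.}
#'   \item{blood_pool_bg_density}{Blood-pool background, counts per cm^3 of
#'     *tissue-equivalent* volume; each voxel receives
#'     `bg * voxel_vol * density(HU)/1.04` counts, so aerated lung carries
#'     proportionally less background than solid tissue.}
#'   \item{misregistration_mm, spill_fraction}{Basal mis-registration:
#'     `spill_fraction` of the counts in liver voxels within
#'     `misregistration_mm` of the liver top are relocated into lung voxels
#'     within `misregistration_mm` above the diaphragm apices.}
#'   \item{noise, seed}{`"none"` or `"poisson"`; the seed fixes all
#'     randomness.}
#' }
#' @export
phantom_spec <- function(preset = c("breathhold", "freebreathing"), ...) {
  preset <- match.arg(preset)
  spec <- list(
    preset = preset,
    grid_shape = c(96L, 96L, 84L),
    spacing_mm = c(4, 4, 4),
    body_semiaxes_mm = c(160, 120),
    body_z_mm = c(8, 328),
    body_hu = 40,
    liver_hu = 55,
    lung_hu = -784,
    lung_semiaxes_mm = c(52, 75, 130),
    lung_offset_x_mm = 72,
    lung_center_y_mm = 185,
    lung_center_z_mm = 190,
    dome_radius_mm = 65,
    dome_apex_z_mm = c(left = 82, right = 96),
    trachea = TRUE,
    trachea_radius_mm = 9,
    trachea_z_min_mm = 210,
    bg_voi_center_xy_mm = c(230, 275),
    bg_voi_radius_mm = 10,
    bg_voi_z_mm = c(24, 120),
    atelectasis_fraction = 0,
    true_lsf = 0.0596,
    total_counts = 3e6,
    blood_pool_bg_density = 20,
    misregistration_mm = 0,
    spill_fraction = 0.5,
    noise = "none",
    seed = 1L
  )
  if (preset == "freebreathing") {
    # ~30% lower lung volume and denser lung at free breathing
    spec$lung_hu <- -701
    spec$lung_semiaxes_mm <- spec$lung_semiaxes_mm * (2749 / 3967)^(1 / 3)
    spec$atelectasis_fraction <- 0.03
    spec$misregistration_mm <- 15
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) {
    stop("unknown phantom field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec <- utils::modifyList(spec, over)
  if (spec$true_lsf < 0 || spec$true_lsf > 1) {
    stop("`true_lsf` must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(spec$lung_hu, spec$body_hu, spec$liver_hu) < -1000)) {
    stop("compartment CT numbers must be >= -1000 HU", call. = FALSE)
  }
  if (!spec$noise %in% c("none", "poisson")) {
    stop("`noise` must be 'none' or 'poisson'", call. = FALSE)
  }
  class(spec) <- "phantom_spec"
  spec
}

#' Generate a digital thorax phantom
#'
#' Voxelises the analytic anatomy of a [phantom_spec()] (center-inclusion:
#' a voxel belongs to a solid when its center does), paints the CT by
#' compartment, distributes SPECT counts — `true_lsf` of the primary counts
#' uniformly through the lungs, the remainder uniformly through the liver,
#' plus density-weighted blood-pool background through all tissue —
#' optionally relocates basal liver counts into the lung bases
#' (mis-registration), applies Poisson noise last if requested, and records
#' a ground-truth manifest computed by direct summation of the pre-noise
#' count field.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `thorax_phantom` with elements `ct`
#'   ([voxel_volume()]), `spect` ([voxel_volume()]), `labels`
#'   ([region_mask()]: 1 left lung, 2 right lung, 3 liver, 4 background VOI,
#'   5 atelectasis), `manifest` (ground truth: masses, volumes, per-region
#'   counts, true LSF, analytic apex positions), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- as.integer(spec$grid_shape)
  sp <- spec$spacing_mm
  xs <- axis_coords(d[1], sp[1])
  ys <- axis_coords(d[2], sp[2])
  zs <- axis_coords(d[3], sp[3])
  ext <- (d - 1) * sp
  if (spec$lung_center_z_mm + spec$lung_semiaxes_mm[3] > ext[3] + sp[3] / 2 ||
      2 * (spec$lung_offset_x_mm + spec$lung_semiaxes_mm[1]) > ext[1] + sp[1]) {
    stop("lung geometry overflows the voxel grid", call. = FALSE)
  }
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  cx <- ext[1] / 2
  cy <- ext[2] / 2

  body <- ((X - cx) / spec$body_semiaxes_mm[1])^2 +
    ((Y - cy) / spec$body_semiaxes_mm[2])^2 <= 1 &
    Z >= spec$body_z_mm[1] & Z <= spec$body_z_mm[2]

  ellipsoid <- function(c3, semi) {
    ((X - c3[1]) / semi[1])^2 + ((Y - c3[2]) / semi[2])^2 +
      ((Z - c3[3]) / semi[3])^2 <= 1
  }
  lcx <- cx + spec$lung_offset_x_mm   # patient left = +x
  rcx <- cx - spec$lung_offset_x_mm
  lung_l <- ellipsoid(c(lcx, spec$lung_center_y_mm, spec$lung_center_z_mm),
                      spec$lung_semiaxes_mm)
  lung_r <- ellipsoid(c(rcx, spec$lung_center_y_mm, spec$lung_center_z_mm),
                      spec$lung_semiaxes_mm)

  apex_true <- spec$dome_apex_z_mm
  if (spec$dome_radius_mm > 0) {
    rr <- spec$dome_radius_mm
    sph <- function(cx0, apex) {
      (X - cx0)^2 + (Y - spec$lung_center_y_mm)^2 + (Z - (apex - rr))^2 <= rr^2
    }
    sph_r <- sph(rcx, apex_true[["right"]])
    sph_l <- sph(lcx, apex_true[["left"]])
    lung_r <- lung_r & !sph_r
    lung_l <- lung_l & !sph_l
    liver <- body & sph_r & !lung_r & !lung_l & Z >= 20
  } else {
    base_z <- spec$lung_center_z_mm - spec$lung_semiaxes_mm[3]
    liver <- ellipsoid(c(rcx, spec$lung_center_y_mm, base_z - 24), c(60, 60, 20)) & body
    # flat base: the diaphragm apex is the lung base plane (first occupied
    # voxel-center plane of each lung)
    apex_true <- c(left = min(Z[lung_l]), right = min(Z[lung_r]))
  }

  trachea <- array(FALSE, d)
  if (isTRUE(spec$trachea)) {
    trachea <- (X - cx)^2 + (Y - spec$lung_center_y_mm)^2 <= spec$trachea_radius_mm^2 &
      Z >= spec$trachea_z_min_mm
    lung_l <- lung_l & !trachea
    lung_r <- lung_r & !trachea
    liver <- liver & !trachea
  }

  # dependent atelectasis: convert the basal fraction of each lung to soft
  # tissue
  atel <- array(FALSE, d)
  if (spec$atelectasis_fraction > 0) {
    for (side in list(quote(lung_l), quote(lung_r))) {
      m <- eval(side)
      idx <- which(m)
      n_at <- floor(spec$atelectasis_fraction * length(idx))
      if (n_at > 0) {
        sel <- idx[order(Z[idx])][seq_len(n_at)]
        atel[sel] <- TRUE
      }
    }
    lung_l <- lung_l & !atel
    lung_r <- lung_r & !atel
  }

  bg_voi <- (X - spec$bg_voi_center_xy_mm[1])^2 +
    (Y - spec$bg_voi_center_xy_mm[2])^2 <= spec$bg_voi_radius_mm^2 &
    Z >= spec$bg_voi_z_mm[1] & Z <= spec$bg_voi_z_mm[2] &
    body & !lung_l & !lung_r & !liver & !atel & !trachea

  # ---- CT -------------------------------------------------------------
  ct_arr <- array(-1000, d)
  ct_arr[body] <- spec$body_hu
  ct_arr[liver] <- spec$liver_hu
  ct_arr[lung_l | lung_r] <- spec$lung_hu
  ct_arr[atel] <- spec$body_hu
  ct_arr[trachea & body] <- -1000

  labels <- array(0L, d)
  labels[liver] <- 3L
  labels[bg_voi] <- 4L
  labels[atel] <- 5L
  labels[lung_r] <- 2L
  labels[lung_l] <- 1L

  # ---- SPECT ----------------------------------------------------------
  vv <- voxel_cm3(sp)
  lung_any <- lung_l | lung_r
  n_lung <- sum(lung_any)
  n_liver <- sum(liver)
  if (n_lung == 0L || n_liver == 0L) {
    stop("degenerate phantom: empty lung or liver compartment", call. = FALSE)
  }
  lambda <- array(0, d)
  lambda[lung_any] <- spec$true_lsf * spec$total_counts / n_lung
  lambda[liver] <- lambda[liver] + (1 - spec$true_lsf) * spec$total_counts / n_liver
  tissue <- body & !(trachea & body)
  dens <- (ct_arr + 1000) / 1000
  bg_arr <- array(0, d)
  bg_arr[tissue] <- spec$blood_pool_bg_density * vv * dens[tissue] / 1.04
  lambda <- lambda + bg_arr

  lung_primary <- spec$true_lsf * spec$total_counts
  liver_primary <- (1 - spec$true_lsf) * spec$total_counts

  moved <- 0
  if (spec$misregistration_mm > 0 && spec$spill_fraction > 0) {
    src <- liver & Z > (max(Z[liver]) - spec$misregistration_mm)
    dst <- ((lung_l | (atel & X > cx)) & Z <= apex_true[["left"]] + spec$misregistration_mm) |
      ((lung_r | (atel & X <= cx)) & Z <= apex_true[["right"]] + spec$misregistration_mm)
    if (any(src) && any(dst)) {
      moved <- spec$spill_fraction * sum(lambda[src])
      lambda[src] <- lambda[src] * (1 - spec$spill_fraction)
      lambda[dst] <- lambda[dst] + moved / sum(dst)
    }
  }

  manifest <- list(
    true_lsf = spec$true_lsf,
    lung_primary_counts = lung_primary,
    liver_primary_counts = liver_primary,
    territory_counts = liver_primary,
    lung_bg_counts = sum(bg_arr[lung_any | atel]),
    total_bg_counts = sum(bg_arr),
    moved_counts = moved,
    total_counts_pre_noise = sum(lambda),
    lung_observed_counts = sum(lambda[lung_any | atel]),
    liver_observed_counts = sum(lambda[liver]),
    true_lung_volume_cm3 = c(
      left = sum(lung_l | (atel & X > cx)) * vv,
      right = sum(lung_r | (atel & X <= cx)) * vv,
      total = sum(lung_any | atel) * vv
    ),
    true_lung_mass_g = c(
      left = sum(vv * dens[lung_l | (atel & X > cx)]),
      right = sum(vv * dens[lung_r | (atel & X <= cx)]),
      total = sum(vv * dens[lung_any | atel])
    ),
    apex_z_mm = c(left = unname(apex_true[["left"]]),
                  right = unname(apex_true[["right"]])),
    bg_count_density = spec$blood_pool_bg_density,
    n_voxels = c(left_lung = sum(lung_l), right_lung = sum(lung_r),
                 liver = n_liver, atelectasis = sum(atel),
                 background_voi = sum(bg_voi))
  )

  spect_arr <- lambda
  if (spec$noise == "poisson") {
    spect_arr <- withr::with_seed(
      spec$seed,
      array(stats::rpois(length(lambda), lambda), d)
    )
  }

  breathing <- if (spec$preset == "breathhold") "breath-hold" else "free-breathing"
  structure(
    list(
      ct = voxel_volume(ct_arr, sp, "CT", breathing),
      spect = voxel_volume(spect_arr, sp, "SPECT", breathing),
      labels = region_mask(labels, sp),
      manifest = manifest,
      spec = spec
    ),
    class = "thorax_phantom"
  )
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf(
    "<thorax_phantom> %s preset, %s voxels; true LSF %.4f, lung mass %.0f g\n",
    x$spec$preset, paste(dim(x$ct$data), collapse = "x"),
    x$manifest$true_lsf, x$manifest$true_lung_mass_g[["total"]]
  ))
  invisible(x)
}

#' Project a SPECT volume into an anterior/posterior planar pair
#'
#' Sums counts along the anterior-posterior axis (array dimension 2; the
#' anterior detector faces low y). With attenuation enabled, each voxel's
#' contribution is attenuated exponentially along its exit path toward the
#' detector, with the per-voxel attenuation coefficient scaled by tissue
#' density: `mu = mu_water_per_mm * density(HU)`, so lung attenuates about
#' five times less than soft tissue. The posterior image is returned in the
#' anterior frame (no left-right flip). Without attenuation both views equal
#' the straight column sums and total counts are conserved.
#'
#' @param spect SPECT [voxel_volume()].
#' @param attenuation `NULL` for none, or a list with `mu_water_per_mm`
#'   (linear attenuation coefficient of water in 1/mm; about 0.0153 for the
#'   140 keV photons of Tc-99m).
#' @param ct CT [voxel_volume()] supplying the density map (required when
#'   `attenuation` is given).
#' @return A [planar_pair()] in the (x, z) frame.
#' @export
project_planar <- function(spect, attenuation = NULL, ct = NULL) {
  stopifnot(inherits(spect, "voxel_volume"))
  d <- dim(spect$data)
  if (is.null(attenuation)) {
    a <- apply(spect$data, c(1L, 3L), sum)
    return(planar_pair(a, a, spect$spacing[c(1, 3)]))
  }
  mu_w <- attenuation$mu_water_per_mm
  if (is.null(mu_w) || mu_w < 0) {
    stop("`attenuation$mu_water_per_mm` must be a non-negative coefficient",
         call. = FALSE)
  }
  if (is.null(ct)) {
    stop("attenuated projection requires the co-registered CT for the ",
         "density map", call. = FALSE)
  }
  check_same_grid(spect, ct)
  dy <- spect$spacing[2]
  mu <- mu_w * pmax(ct$data + 1000, 0) / 1000 * dy  # optical depth per voxel
  # cumulative optical depth along y, including the self half-voxel
  cs <- apply(mu, c(1L, 3L), cumsum)                 # (ny, nx, nz)
  cs <- aperm(cs, c(2L, 1L, 3L))
  tot <- cs[, d[2], , drop = FALSE][, rep(1L, d[2]), ]
  att_ant <- exp(-(cs - mu / 2))
  att_post <- exp(-(tot - cs + mu / 2))
  a <- apply(spect$data * att_ant, c(1L, 3L), sum)
  p <- apply(spect$data * att_post, c(1L, 3L), sum)
  planar_pair(a, p, spect$spacing[c(1, 3)])
}

#' Synthetic water phantom for densitometry QA
#'
#' A uniform water cylinder with optional normally distributed CT-number
#' noise whose sample mean inside the VOI is constrained to `mean_hu`
#' exactly (residuals are centred), mirroring how a scanner's water QA is
#' summarised by its measured mean CT number.
#'
#' @param mean_hu Mean CT number of water as measured (0 for ideal water).
#' @param sd_hu CT-number noise SD (0 for a perfectly uniform volume).
#' @param shape,spacing Voxel grid (default 32^3 at 4 mm).
#' @param voi_radius_mm,voi_half_height_mm Cylindrical VOI geometry.
#' @param seed RNG seed for the noise.
#' @return A list with `ct` ([voxel_volume()]) and `voi` ([region_mask()]
#'   holding a `background_voi` label), ready for [water_phantom_qa()].
#' @export
generate_water_phantom <- function(mean_hu = 0, sd_hu = 0,
                                   shape = c(32L, 32L, 32L), spacing = c(4, 4, 4),
                                   voi_radius_mm = 40, voi_half_height_mm = 40,
                                   seed = 1L) {
  d <- as.integer(shape)
  xs <- axis_coords(d[1], spacing[1])
  ys <- axis_coords(d[2], spacing[2])
  zs <- axis_coords(d[3], spacing[3])
  ctr <- (d - 1) * spacing / 2
  in_xy <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`) <= voi_radius_mm^2
  voi <- array(FALSE, d)
  voi[, , abs(zs - ctr[3]) <= voi_half_height_mm] <- in_xy
  arr <- array(mean_hu, d)
  if (sd_hu > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(sum(voi)))
    noise <- (noise - mean(noise)) / stats::sd(noise) * sd_hu
    arr[voi] <- mean_hu + noise
  }
  labels <- array(0L, d)
  labels[voi] <- 4L
  list(
    ct = voxel_volume(arr, spacing, "CT"),
    voi = region_mask(labels, spacing)
  )
}
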
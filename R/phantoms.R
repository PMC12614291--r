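# Paired pCT/CBCT phantom generation and HU preprocessing.
#
# Images are numeric matrices (rows x cols, column-major as usual in R) in
# Hounsfield units, with origin at the top-left and the image center at
# ((H+1)/2, (W+1)/2) in 1-based pixel coordinates. Generated anatomy is
# piecewise constant at air / soft-tissue / bone HU levels, mimicking rigid
# quality-assurance phantoms built from tissue- and bone-equivalent materials.

HU_AIR <- -1000
HU_CLIP <- c(-1000, 3000)

#' Anatomy specification for phantom slices
#'
#' Parameters of the randomized piecewise-constant anatomy drawn by
#' [generate_phantom_ct()]: an elliptical soft-tissue body on an air
#' background, a posterior "spine" bone disc plus optional extra bone inserts,
#' and an optional anterior air cavity.
#'
#' @param tissue_hu,bone_hu,air_hu material HU levels (defaults 40, 1000,
#'   -1000).
#' @param body_axes_frac range of body semi-axes as a fraction of the half
#'   image extent.
#' @param center_jitter_frac maximal random offset of the body center as a
#'   fraction of image extent.
#' @param n_bone number of bone structures (first is the spine disc).
#' @param bone_radius_frac range of bone radii as a fraction of the body
#'   semi-minor axis.
#' @param cavity_prob probability of inserting an air cavity.
#' @param cavity_radius_frac range of cavity radii as a fraction of the body
#'   semi-minor axis.
#' @return A list of class `anatomy_spec`.
#' @export
anatomy_spec <- function(tissue_hu = 40, bone_hu = 1000, air_hu = -1000,
                         body_axes_frac = c(0.60, 0.85),
                         center_jitter_frac = 0.04,
                         n_bone = 2L,
                         bone_radius_frac = c(0.10, 0.18),
                         cavity_prob = 0.5,
                         cavity_radius_frac = c(0.12, 0.22)) {
  structure(list(tissue_hu = tissue_hu, bone_hu = bone_hu, air_hu = air_hu,
                 body_axes_frac = body_axes_frac,
                 center_jitter_frac = center_jitter_frac,
                 n_bone = as.integer(n_bone),
                 bone_radius_frac = bone_radius_frac,
                 cavity_prob = cavity_prob,
                 cavity_radius_frac = cavity_radius_frac),
            class = "anatomy_spec")
}

# pixel-center coordinate grids for a shape
coord_grid <- function(shape) {
  H <- shape[1]; W <- shape[2]
  list(r = matrix(seq_len(H), H, W),
       c = matrix(seq_len(W), H, W, byrow = TRUE),
       center = c((H + 1) / 2, (W + 1) / 2))
}

ellipse_mask <- function(shape, center, semi_axes, grid = coord_grid(shape)) {
  ((grid$r - center[1]) / semi_axes[1])^2 +
    ((grid$c - center[2]) / semi_axes[2])^2 <= 1
}

#' Generate a piecewise-constant phantom CT slice
#'
#' Draws a randomized axial phantom slice in Hounsfield units: air background
#' at `air_hu`, an elliptical soft-tissue body, `n_bone` bone structures (a
#' posterior spine disc plus randomly placed inserts) and, with probability
#' `cavity_prob`, an anterior air cavity. All values are exactly one of the
#' configured material levels.
#'
#' @param shape integer vector `c(rows, cols)`, each >= 32.
#' @param spec an [anatomy_spec()].
#' @param seed optional integer seed; the same seed reproduces the same
#'   phantom.
#' @return A list with `ct` (HU matrix, `units` attribute `"HU"`) and
#'   `body_mask` (logical matrix of the body ellipse).
#' @export
generate_phantom_ct <- function(shape = c(32L, 32L), spec = anatomy_spec(),
                                seed = NULL) {
  stopifnot(inherits(spec, "anatomy_spec"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L)) {
    stop_param("shape must be at least 32 x 32")
  }
  with_seed_opt(seed, {
    H <- shape[1]; W <- shape[2]
    g <- coord_grid(shape)
    jit <- spec$center_jitter_frac
    center <- g$center + c(stats::runif(1, -jit, jit) * H,
                           stats::runif(1, -jit, jit) * W)
    a <- stats::runif(1, spec$body_axes_frac[1], spec$body_axes_frac[2]) * H / 2
    b <- stats::runif(1, spec$body_axes_frac[1], spec$body_axes_frac[2]) * W / 2
    body <- ellipse_mask(shape, center, c(a, b), g)

    ct <- matrix(spec$air_hu, H, W)
    ct[body] <- spec$tissue_hu

    if (spec$n_bone >= 1L) {
      # spine: disc on the posterior midline, well inside the body
      sr <- stats::runif(1, spec$bone_radius_frac[1], spec$bone_radius_frac[2]) *
        min(a, b)
      sc <- c(center[1] + 0.55 * a, center[2])
      ct[ellipse_mask(shape, sc, c(sr, sr), g) & body] <- spec$bone_hu
      if (spec$n_bone > 1L) {
        for (k in seq_len(spec$n_bone - 1L)) {
          rr <- stats::runif(1, spec$bone_radius_frac[1],
                             spec$bone_radius_frac[2]) * min(a, b) * 0.8
          ang <- stats::runif(1, 0, 2 * pi)
          cc <- center + 0.45 * c(a * sin(ang), b * cos(ang))
          ct[ellipse_mask(shape, cc, c(rr, rr), g) & body] <- spec$bone_hu
        }
      }
    }

    if (stats::runif(1) < spec$cavity_prob) {
      cr <- stats::runif(1, spec$cavity_radius_frac[1],
                         spec$cavity_radius_frac[2]) * min(a, b)
      cc <- c(center[1] - 0.40 * a, center[2] + stats::runif(1, -0.2, 0.2) * b)
      ct[ellipse_mask(shape, cc, c(cr, cr), g) & body] <- spec$air_hu
    }

    list(ct = set_units(ct, "HU"), body_mask = body)
  })
}

#' Degradation specification for CBCT simulation
#'
#' Amplitudes of the CBCT-specific degradations applied by
#' [degrade_to_cbct()], in the order: body-contour rescale, rigid shift,
#' low-frequency radial bias ("cupping"), streak artifacts, additive Gaussian
#' noise, circular field-of-view truncation.
#'
#' @param bias_amplitude cupping depth in HU: the radial bias field is
#'   \eqn{-A (1 - (r/r_{max})^2)}, i.e. maximal HU depression at the image
#'   center, fading to zero at the corners' inscribed circle.
#' @param streak_count number of straight streak lines.
#' @param streak_intensity absolute streak amplitude in HU (alternating
#'   bright/dark).
#' @param noise_sd standard deviation of additive Gaussian noise in HU.
#' @param fov_radius_frac CBCT field-of-view radius as a fraction of the half
#'   image extent; pixels outside are set to air (-1000 HU).
#' @param shift_px integer rigid shift `c(rows, cols)` simulating a couch
#'   set-up offset.
#' @param contour_scale relative body-outline magnification (e.g. 1.02
#'   simulates 2% weight gain between planning CT and CBCT).
#' @return A list of class `degradation_spec`.
#' @export
degradation_spec <- function(bias_amplitude = 60,
                             streak_count = 4L,
                             streak_intensity = 150,
                             noise_sd = 25,
                             fov_radius_frac = 0.9,
                             shift_px = c(1L, 1L),
                             contour_scale = 1.02) {
  if (bias_amplitude < 0 || streak_intensity < 0 || noise_sd < 0) {
    stop_param("degradation amplitudes must be >= 0")
  }
  if (!(fov_radius_frac > 0 && fov_radius_frac <= 1)) {
    stop_param("fov_radius_frac must lie in (0, 1]")
  }
  structure(list(bias_amplitude = bias_amplitude,
                 streak_count = as.integer(streak_count),
                 streak_intensity = streak_intensity,
                 noise_sd = noise_sd,
                 fov_radius_frac = fov_radius_frac,
                 shift_px = as.integer(round(shift_px)),
                 contour_scale = contour_scale),
            class = "degradation_spec")
}

#' Radial cupping bias field
#'
#' The low-frequency HU bias applied by [degrade_to_cbct()]:
#' \eqn{\Delta(r) = -A\,(1 - (r/r_{max})^2)} with
#' \eqn{r_{max} = \min(shape)/2}, clamped to zero beyond \eqn{r_{max}}.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param amplitude cupping depth `A` in HU.
#' @return Numeric matrix of the bias field.
#' @export
radial_bias_field <- function(shape, amplitude) {
  g <- coord_grid(shape)
  rmax <- min(shape) / 2
  r2 <- ((g$r - g$center[1])^2 + (g$c - g$center[2])^2) / rmax^2
  -amplitude * pmax(1 - r2, 0)
}

# nearest-neighbour rigid magnification about the image center; preserves the
# piecewise-constant material levels exactly
rescale_about_center <- function(img, scale, fill = HU_AIR) {
  if (scale == 1) return(img)
  H <- nrow(img); W <- ncol(img)
  g <- coord_grid(c(H, W))
  sr <- round(g$center[1] + (g$r - g$center[1]) / scale)
  sc <- round(g$center[2] + (g$c - g$center[2]) / scale)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out <- matrix(fill, H, W)
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  out
}

shift_image <- function(img, shift, fill = HU_AIR) {
  dy <- shift[1]; dx <- shift[2]
  if (dy == 0 && dx == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy; src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Degrade a CT slice into a simulated CBCT
#'
#' Applies, in a fixed documented order, the degradations that distinguish
#' cone-beam CT from fan-beam CT: (1) body-contour rescale (anatomy change
#' between scans), (2) rigid pixel shift (set-up error), (3) low-frequency
#' radial cupping bias, (4) straight streak artifacts of alternating sign,
#' (5) additive Gaussian HU noise, (6) truncation to a circular field of view
#' (outside pixels set to -1000 HU), then re-clipping to `[-1000, 3000]` HU.
#' The bias field is applied to non-air pixels only, so noise-free
#' degradations remain exactly invertible for testing. With all amplitudes
#' zero, unit contour scale, zero shift and `fov_radius_frac = 1` the input is
#' returned unchanged.
#'
#' @param ct HU matrix (planning-CT slice).
#' @param spec a [degradation_spec()].
#' @param seed optional integer seed (streak geometry and noise).
#' @return HU matrix of the simulated CBCT, `units` attribute `"HU"`.
#' @export
degrade_to_cbct <- function(ct, spec = degradation_spec(), seed = NULL) {
  stopifnot(inherits(spec, "degradation_spec"))
  assert_hu_units(ct, "ct")
  with_seed_opt(seed, {
    img <- rescale_about_center(unclass_img(ct), spec$contour_scale)
    img <- shift_image(img, spec$shift_px)

    if (spec$bias_amplitude > 0) {
      field <- radial_bias_field(dim(img), spec$bias_amplitude)
      nonair <- img > HU_AIR + 1
      img[nonair] <- img[nonair] + field[nonair]
    }

    if (spec$streak_count > 0L && spec$streak_intensity > 0) {
      g <- coord_grid(dim(img))
      for (k in seq_len(spec$streak_count)) {
        theta <- stats::runif(1, 0, pi)
        # line through a random point in the central half of the image
        p <- g$center + c(stats::runif(1, -0.25, 0.25) * nrow(img),
                          stats::runif(1, -0.25, 0.25) * ncol(img))
        d <- (g$r - p[1]) * cos(theta) + (g$c - p[2]) * sin(theta)
        img[abs(d) < 0.7] <- img[abs(d) < 0.7] +
          spec$streak_intensity * (-1)^k
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    }

    if (spec$fov_radius_frac < 1) {
      img[!fov_mask(dim(img), spec$fov_radius_frac)] <- HU_AIR
    }

    set_units(matrix(pmin(pmax(img, HU_CLIP[1]), HU_CLIP[2]),
                     nrow(img), ncol(img)), "HU")
  })
}

unclass_img <- function(x) {
  attr(x, "units") <- NULL
  x
}

#' Generate a dataset of paired pCT/CBCT slices
#'
#' Draws `n` independent phantom slices and degrades each into a simulated
#' CBCT, producing registered pairs with a shared circular field-of-view mask.
#' Per-pair seeds are derived from `seed` and recorded, so any pair can be
#' regenerated in isolation.
#'
#' @param n number of pairs (>= 1).
#' @param shape slice shape `c(rows, cols)`.
#' @param anatomy an [anatomy_spec()].
#' @param degradation a [degradation_spec()].
#' @param spacing pixel spacing `c(row_mm, col_mm)`.
#' @param seed optional integer seed.
#' @return A list of class `paired_dataset`; each element is a
#'   `paired_sample` with fields `pct`, `cbct` (HU matrices), `fov_mask`,
#'   `body_mask`, `spacing`, `unit_tag`, `seed_anatomy`, `seed_degrade`.
#' @export
make_pair_dataset <- function(n, shape = c(32L, 32L),
                              anatomy = anatomy_spec(),
                              degradation = degradation_spec(),
                              spacing = c(1, 1),
                              seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_param("n must be >= 1")
  base <- seed %||% sample.int(.Machine$integer.max, 1)
  pairs <- lapply(seq_len(n), function(i) {
    sa <- derive_seed(base, 2L * i)
    sd_ <- derive_seed(base, 2L * i + 1L)
    ph <- generate_phantom_ct(shape, anatomy, seed = sa)
    cbct <- degrade_to_cbct(ph$ct, degradation, seed = sd_)
    structure(list(pct = ph$ct, cbct = cbct,
                   fov_mask = fov_mask(shape, degradation$fov_radius_frac),
                   body_mask = ph$body_mask,
                   spacing = spacing, unit_tag = "HU",
                   seed_anatomy = sa, seed_degrade = sd_),
              class = "paired_sample")
  })
  structure(pairs, class = "paired_dataset",
            anatomy = anatomy, degradation = degradation, seed = base)
}

#' Clip and rescale Hounsfield units to normalized intensities
#'
#' Clips to `[-1000, 3000]` HU and maps affinely to `[-1, 1]`:
#' `-1000 -> -1`, `1000 -> 0`, `3000 -> +1`. Exactly inverted by [to_hu()].
#'
#' @param img numeric image (any shape) in HU, or a `paired_sample`, in which
#'   case both images of the pair are normalized and `unit_tag` updated.
#' @return Normalized image with `units` attribute `"normalized"`.
#' @export
preprocess <- function(img) UseMethod("preprocess")

#' @export
preprocess.default <- function(img) {
  v <- pmin(pmax(img, HU_CLIP[1]), HU_CLIP[2])
  set_units((v + 1000) / 2000 - 1, "normalized")
}

#' @export
preprocess.paired_sample <- function(img) {
  img$pct <- preprocess(unclass_img(img$pct))
  img$cbct <- preprocess(unclass_img(img$cbct))
  img$unit_tag <- "normalized"
  img
}

#' Map normalized intensities back to Hounsfield units
#'
#' Inverse of [preprocess()] on `[-1, 1]`: `HU = (v + 1) * 2000 - 1000`.
#'
#' @param img numeric image with values in `[-1, 1]` (a small numerical
#'   tolerance is allowed and clamped).
#' @return HU image with `units` attribute `"HU"`.
#' @export
to_hu <- function(img) {
  rng <- range(img)
  if (rng[1] < -1 - 1e-6 || rng[2] > 1 + 1e-6) {
    stop_param("to_hu() expects values in [-1, 1]; got range [",
               signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  v <- pmin(pmax(img, -1), 1)
  set_units((v + 1) * 2000 - 1000, "HU")
}

#' Circular field-of-view mask
#'
#' Filled circle of radius `radius_frac * min(shape) / 2` centered on the
#' image, delimiting the CBCT field of view within which masked metrics are
#' computed. The default 0.9 approximates a patient-style FOV; a smaller
#' fraction (e.g. 0.7) excludes peripheral set-up hardware such as a phantom
#' headrest.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param radius_frac radius as a fraction of the half image extent, in
#'   `(0, 1]`.
#' @return Logical matrix.
#' @export
fov_mask <- function(shape, radius_frac = 0.9) {
  if (!(radius_frac > 0 && radius_frac <= 1)) {
    stop_param("radius_frac must lie in (0, 1]")
  }
  g <- coord_grid(shape)
  radius <- radius_frac * min(shape) / 2
  (g$r - g$center[1])^2 + (g$c - g$center[2])^2 <= radius^2
}

#' Resample a CT volume to a target voxel spacing and center-crop in-plane
#'
#' Linearly interpolates along each axis to the requested spacing, then
#' center-crops (or pads with -1000 HU) each axial slice to `crop_size`.
#'
#' @param volume 3D HU array (rows x cols x slices).
#' @param spacing current voxel spacing in mm, length 3.
#' @param target_spacing desired spacing in mm, length 3 (default
#'   `c(1, 1, 3)`).
#' @param crop_size in-plane output size `c(rows, cols)`.
#' @return A list with `volume` (resampled, cropped 3D array) and `spacing`.
#' @export
resample_and_crop <- function(volume, spacing, target_spacing = c(1, 1, 3),
                              crop_size = c(256L, 256L)) {
  if (is.null(dim(volume)) || length(dim(volume)) != 3L) {
    stop_param("volume must be a 3D array")
  }
  if (is.null(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_param("valid voxel spacing metadata (3 positive values) is required")
  }
  out <- volume
  for (ax in 1:3) {
    n <- dim(out)[ax]
    if (n == 1L || spacing[ax] == target_spacing[ax]) next
    old_pos <- (seq_len(n) - 1) * spacing[ax]
    n_new <- max(2L, as.integer(round((n - 1) * spacing[ax] /
                                        target_spacing[ax])) + 1L)
    new_pos <- (seq_len(n_new) - 1) * target_spacing[ax]
    new_pos <- pmin(new_pos, max(old_pos))
    out <- apply(out, setdiff(1:3, ax), function(v) {
      stats::approx(old_pos, v, xout = new_pos)$y
    })
    # apply() puts the interpolated axis first; restore ordering
    out <- aperm(out, switch(ax, c(1, 2, 3), c(2, 1, 3), c(2, 3, 1)))
  }
  cropped <- vapply(seq_len(dim(out)[3]), function(k) {
    center_crop(out[, , k], crop_size, fill = HU_AIR)
  }, matrix(0, crop_size[1], crop_size[2]))
  list(volume = array(cropped, c(crop_size, dim(out)[3])),
       spacing = target_spacing)
}

center_crop <- function(img, size, fill = HU_AIR) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, size[1], size[2])
  # source and destination index ranges aligned on image centers
  r0 <- floor((H - size[1]) / 2)
  c0 <- floor((W - size[2]) / 2)
  src_r <- (max(1, r0 + 1)):(min(H, r0 + size[1]))
  src_c <- (max(1, c0 + 1)):(min(W, c0 + size[2]))
  out[src_r - r0, src_c - c0] <- img[src_r, src_c]
  out
}
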
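# Masked image-quality metrics in HU space, HU difference maps, truncated HU
# histograms, and the shared-noise latent convergence analysis.

check_mask_inputs <- function(a, b, mask) {
  assert_same_shape(a, b, c("a", "b"))
  assert_same_shape(a, mask, c("a", "mask"))
  if (!is.logical(mask)) stop_param("mask must be logical")
  if (!any(mask)) stop_param("mask is empty: no pixels to evaluate")
  invisible(TRUE)
}

#' Masked mean absolute error in HU
#'
#' Mean of `|a - b|` over the pixels where `mask` is `TRUE`. Refuses images
#' tagged as normalized; convert with [to_hu()] first.
#'
#' @param a,b HU images of identical shape.
#' @param mask logical image of the same shape with at least one `TRUE` pixel.
#' @return Scalar MAE in HU.
#' @export
masked_mae <- function(a, b, mask) {
  assert_hu_units(a, "a"); assert_hu_units(b, "b")
  check_mask_inputs(a, b, mask)
  mean(abs(a[mask] - b[mask]))
}

#' Masked peak signal-to-noise ratio in dB
#'
#' `10 * log10(data_range^2 / MSE)` with the mean squared error computed over
#' the masked pixels. The default reference range of 4000 HU is the width of
#' the clipped intensity window `[-1000, 3000]`, fixed so that scores are
#' comparable across images. Identical images return `cap` (default 100 dB)
#' rather than infinity.
#'
#' @inheritParams masked_mae
#' @param data_range reference intensity range in HU (> 0).
#' @param cap value returned when the masked MSE is zero.
#' @return Scalar PSNR in dB.
#' @export
masked_psnr <- function(a, b, mask, data_range = 4000, cap = 100) {
  assert_hu_units(a, "a"); assert_hu_units(b, "b")
  check_mask_inputs(a, b, mask)
  if (data_range <= 0) stop_param("data_range must be > 0")
  mse <- mean((a[mask] - b[mask])^2)
  if (mse == 0) return(cap)
  min(10 * log10(data_range^2 / mse), cap)
}

#' Masked zero-mean normalized cross-correlation
#'
#' Pearson-style normalized correlation over the masked pixels:
#' \eqn{\sum (a - \bar a)(b - \bar b) / (\|a - \bar a\| \|b - \bar b\|)}.
#' Invariant to affine intensity rescaling `s * a + c` with `s > 0`; lies in
#' `[-1, 1]`.
#'
#' @inheritParams masked_mae
#' @return Scalar NCC in `[-1, 1]`.
#' @export
masked_ncc <- function(a, b, mask) {
  check_mask_inputs(a, b, mask)
  av <- a[mask] - mean(a[mask])
  bv <- b[mask] - mean(b[mask])
  na <- sqrt(sum(av^2)); nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0) {
    stop_param("NCC undefined: an image is constant inside the mask")
  }
  ncc <- sum(av * bv) / (na * nb)
  min(max(ncc, -1), 1)
}

#' Signed HU difference map
#'
#' `a - b`, unmasked, for visual assessment of where a synthetic CT deviates
#' from its reference.
#'
#' @param a,b HU images of identical shape.
#' @return Signed HU image.
#' @export
hu_difference_map <- function(a, b) {
  assert_same_shape(a, b, c("a", "b"))
  set_units(unclass_img(a) - unclass_img(b), "HU")
}

#' Truncated HU histogram
#'
#' Counts pixels per HU bin over `[lower_trunc, 3000]`. Pixels below the lower
#' truncation are excluded; the default of -950 HU removes air, which would
#' otherwise dominate the counts.
#'
#' @param img HU image.
#' @param bin_width bin width in HU (> 0).
#' @param lower_trunc lower truncation in HU.
#' @return Data frame with columns `lower`, `upper`, `mid`, `count`.
#' @export
hu_histogram <- function(img, bin_width = 50, lower_trunc = -950) {
  assert_hu_units(img, "img")
  if (bin_width <= 0) stop_param("bin_width must be > 0")
  breaks <- seq(lower_trunc, HU_CLIP[2] + bin_width, by = bin_width)
  v <- img[img >= lower_trunc & img <= HU_CLIP[2]]
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(lower = breaks[-length(breaks)],
             upper = breaks[-1],
             mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             count = counts)
}

#' Latent-space convergence of a noised image pair
#'
#' Applies the forward diffusion to both images of a pair with a single shared
#' noise realization and records, per timestep, the cosine similarity and
#' Euclidean distance between the flattened noisy images. With shared noise
#' the difference is exactly \eqn{x_t - y_t = \sqrt{\bar\alpha_t}(x_0 - y_0)},
#' so the distance decays as \eqn{\sqrt{\bar\alpha_t}} and the similarity
#' approaches 1 as the noise dominates — the mechanism that lets reverse
#' sampling start from a noised CBCT instead of pure noise.
#'
#' @param x0,y0 normalized images of identical shape (e.g. preprocessed pCT
#'   and CBCT).
#' @param schedule a [make_schedule()] object.
#' @param timesteps integer timesteps in `0:n_steps` at which to evaluate.
#' @param seed optional integer seed for the shared noise draw.
#' @return Data frame with columns `t`, `alpha_bar`, `cosine_similarity`,
#'   `euclidean_distance`.
#' @export
latent_convergence_curve <- function(x0, y0, schedule,
                                     timesteps = seq(0, schedule$n_steps,
                                                     length.out = 21),
                                     seed = NULL) {
  assert_same_shape(x0, y0, c("x0", "y0"))
  stopifnot(inherits(schedule, "noise_schedule"))
  timesteps <- as.integer(round(timesteps))
  eps <- with_seed_opt(seed, array(stats::rnorm(length(x0)),
                                   dim = dim(x0) %||% length(x0)))
  rows <- lapply(timesteps, function(t) {
    xt <- as.vector(forward_diffuse(x0, t, eps, schedule))
    yt <- as.vector(forward_diffuse(y0, t, eps, schedule))
    data.frame(t = t,
               alpha_bar = alpha_bar_at(schedule, t),
               cosine_similarity =
                 sum(xt * yt) / (sqrt(sum(xt^2)) * sqrt(sum(yt^2))),
               euclidean_distance = sqrt(sum((xt - yt)^2)))
  })
  do.call(rbind, rows)
}

#' Evaluate synthetic CTs against planning CTs, alongside the CBCTs
#'
#' Computes masked MAE, PSNR and NCC for each sCT-vs-pCT pair and for the
#' corresponding CBCT-vs-pCT pair, and aggregates per image class as
#' mean +/- SD, mirroring the layout of a schedule/t_con results table.
#'
#' @param sct_set,pct_set,cbct_set aligned lists of HU matrices (or 3D arrays
#'   sliced along the third dimension), all the same length.
#' @param mask logical FOV mask applied to every slice.
#' @param data_range PSNR reference range in HU.
#' @return A list of class `sct_evaluation` with elements `per_slice` (data
#'   frame: `slice`, `image`, `mae_hu`, `psnr_db`, `ncc`, `n_pixels`) and
#'   `summary` (data frame of mean and SD per image class and metric).
#' @export
evaluate_pairs <- function(sct_set, pct_set, cbct_set, mask,
                           data_range = 4000) {
  sct_set <- as_slice_list(sct_set)
  pct_set <- as_slice_list(pct_set)
  cbct_set <- as_slice_list(cbct_set)
  n <- length(pct_set)
  if (length(sct_set) != n || length(cbct_set) != n) {
    stop_param("sct_set, pct_set and cbct_set must have equal length")
  }
  one <- function(i, img, label) {
    data.frame(slice = i, image = label,
               mae_hu = masked_mae(img, pct_set[[i]], mask),
               psnr_db = masked_psnr(img, pct_set[[i]], mask, data_range),
               ncc = masked_ncc(img, pct_set[[i]], mask),
               n_pixels = sum(mask))
  }
  per_slice <- do.call(rbind, c(
    lapply(seq_len(n), function(i) one(i, sct_set[[i]], "sCT")),
    lapply(seq_len(n), function(i) one(i, cbct_set[[i]], "CBCT"))
  ))
  agg <- function(label) {
    d <- per_slice[per_slice$image == label, ]
    data.frame(image = label,
               mae_hu = mean(d$mae_hu), mae_hu_sd = stats::sd(d$mae_hu),
               psnr_db = mean(d$psnr_db), psnr_db_sd = stats::sd(d$psnr_db),
               ncc = mean(d$ncc), ncc_sd = stats::sd(d$ncc),
               n_slices = nrow(d))
  }
  structure(list(per_slice = per_slice,
                 summary = rbind(agg("sCT"), agg("CBCT"))),
            class = "sct_evaluation")
}

as_slice_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[3]), function(k) set_units(x[, , k],
                                                            get_units(x))))
  }
  if (is.matrix(x)) return(list(x))
  stop_param("expected a list of matrices or a 3D array")
}

#' @export
print.sct_evaluation <- function(x, ...) {
  s <- x$summary
  cat("<sct_evaluation>\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s MAE %6.1f +/- %5.1f HU | PSNR %5.1f +/- %4.1f dB | NCC %.3f +/- %.3f (n=%d)\n",
                s$image[i], s$mae_hu[i], s$mae_hu_sd[i],
                s$psnr_db[i], s$psnr_db_sd[i], s$ncc[i], s$ncc_sd[i],
                s$n_slices[i]))
  }
  invisible(x)
}
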
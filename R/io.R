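# Volume, dataset and checkpoint I/O.

#' Read a CT volume from a NIfTI file
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A list with `volume` (3D HU array) and `spacing` (voxel size in mm,
#'   length 3).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop_param("malformed NIfTI file '", path, "': ",
                               conditionMessage(e))
                  })
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L || any(!is.finite(spacing[1:3])) ||
      any(spacing[1:3] <= 0)) {
    stop_param("file '", path, "' lacks valid voxel spacing metadata")
  }
  list(volume = as.array(img), spacing = as.numeric(spacing[1:3]))
}

#' Write a CT volume to a NIfTI file
#'
#' @param volume 3D HU array.
#' @param path output path (`.nii.gz` recommended).
#' @param spacing voxel size in mm, length 3.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 3)) {
  img <- RNifti::asNifti(unclass_img(volume))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save / load a generated paired dataset
#'
#' The dataset is written as a single archive together with a JSON sidecar
#' (`<path>.json`) recording the generator seed and the anatomy/degradation
#' specifications, so the archive's provenance is inspectable without loading
#' it.
#'
#' @param dataset a [make_pair_dataset()] result.
#' @param path output path (`.rds`).
#' @return The path, invisibly.
#' @export
save_pair_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "paired_dataset"))
  saveRDS(dataset, path)
  sidecar <- list(
    n_pairs = length(dataset),
    seed = attr(dataset, "seed"),
    shape = dim(dataset[[1]]$pct),
    anatomy = unclass(attr(dataset, "anatomy")),
    degradation = unclass(attr(dataset, "degradation")),
    pair_seeds = lapply(dataset, function(p) {
      list(anatomy = p$seed_anatomy, degrade = p$seed_degrade)
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_pair_dataset
#' @export
load_pair_dataset <- function(path) {
  out <- readRDS(path)
  if (!inherits(out, "paired_dataset")) {
    stop_param("'", path, "' does not contain a paired dataset")
  }
  out
}

#' Save / load a model checkpoint
#'
#' A single-file archive bundling the denoiser weights, the noise schedule and
#' the experiment configuration, preceded by a small manifest (creation time,
#' package version, parameter count, schedule kind).
#'
#' @param denoiser a [build_denoiser()] object (possibly trained).
#' @param schedule the [make_schedule()] used in training.
#' @param path output path (`.rds`).
#' @param config optional experiment configuration list to embed.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(denoiser, schedule, path, config = NULL) {
  stopifnot(inherits(denoiser, "cbct_denoiser"),
            inherits(schedule, "noise_schedule"))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "cbctdiff",
    version = as.character(utils::packageVersion("cbctdiff")),
    n_params = denoiser$n_params,
    schedule_kind = schedule$kind,
    n_steps = schedule$n_steps
  )
  saveRDS(list(manifest = manifest, denoiser = denoiser,
               schedule = schedule, config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  out <- readRDS(path)
  if (!is.list(out) || !inherits(out$denoiser, "cbct_denoiser")) {
    stop_param("'", path, "' is not a cbctdiff checkpoint")
  }
  out
}
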
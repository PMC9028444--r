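#' Dataset directory format
#'
#' A generated dataset is a directory of plain-text files:
#' `manifest.json` (counts, seeds, mesh key, augmentation settings, schema
#' version), `frame.csv` (one 208-entry voltage frame per row), `eim.csv`
#' (one flattened 16 x 16 map per row, column-major), `target.csv` (one
#' flattened 64 x 64 target per row, column-major) and `provenance.csv`
#' (phantom id, rotation shift, contact/noise settings per sample). Writes
#' are atomic: everything is staged in a temporary sibling directory that is
#' renamed into place.
#'
#' @name dataset_format
NULL

#' Write a dataset directory
#'
#' @param samples List of `eit_sample`s.
#' @param frames Optional list of `voltage_frame`s aligned with `samples`
#'   (one per un-rotated sample position; may be NULL).
#' @param manifest Named list stored as `manifest.json`; `n_samples` and
#'   `schema_version` are filled in.
#' @param path Target directory.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(samples, frames = NULL, manifest = list(), path) {
  stopifnot(length(samples) >= 1L)
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  eim_m <- t(vapply(samples, function(s) as.vector(unclass(s$eim)),
                    numeric(256)))
  tgt_m <- t(vapply(samples, function(s) as.vector(s$target), numeric(4096)))
  data.table::fwrite(data.table::as.data.table(eim_m),
                     file.path(tmp, "eim.csv"))
  data.table::fwrite(data.table::as.data.table(tgt_m),
                     file.path(tmp, "target.csv"))
  if (!is.null(frames)) {
    fr_m <- t(vapply(frames, as.numeric, numeric(208)))
    data.table::fwrite(data.table::as.data.table(fr_m),
                       file.path(tmp, "frame.csv"))
  }
  prov <- data.table::rbindlist(lapply(seq_along(samples), function(i) {
    p <- samples[[i]]$provenance
    data.frame(sample = i,
               phantom = if (is.null(p$phantom)) NA_integer_ else p$phantom,
               rotation = if (is.null(p$rotation)) 0L else p$rotation,
               phantom_seed = if (is.null(p$phantom_seed)) NA_integer_
                              else p$phantom_seed)
  }))
  data.table::fwrite(prov, file.path(tmp, "provenance.csv"))
  manifest$n_samples <- length(samples)
  manifest$schema_version <- 1L
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(path, recursive = TRUE)
  if (!file.rename(tmp, path))
    stop("could not move staged dataset into place")
  on.exit(NULL)
  invisible(path)
}

#' Read a dataset directory
#'
#' @param path Dataset directory written by [write_dataset()].
#' @return List with `samples` (list of `eit_sample`), `frames` (list of
#'   `voltage_frame` or NULL) and `manifest`.
#' @export
read_dataset <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  eim_m <- as.matrix(data.table::fread(file.path(path, "eim.csv")))
  tgt_m <- as.matrix(data.table::fread(file.path(path, "target.csv")))
  prov <- data.table::fread(file.path(path, "provenance.csv"))
  n <- nrow(eim_m)
  if (!is.null(man$n_samples) && man$n_samples != n)
    stop("manifest sample count does not match stored arrays")
  samples <- lapply(seq_len(n), function(i) {
    e <- structure(matrix(eim_m[i, ], 16L, 16L),
                   class = c("eim", "matrix", "array"))
    eit_sample(e, matrix(tgt_m[i, ], 64L, 64L),
               provenance = as.list(prov[i, ]))
  })
  frames <- NULL
  fpath <- file.path(path, "frame.csv")
  if (file.exists(fpath)) {
    fr_m <- as.matrix(data.table::fread(fpath))
    frames <- lapply(seq_len(nrow(fr_m)), function(i) voltage_frame(fr_m[i, ]))
  }
  list(samples = samples, frames = frames, manifest = man)
}

#' Generate one simulated training sample
#'
#' Draws a phantom spec, solves the forward problem with perturbed contact
#' impedances, packs the EIM, applies the three measurement-noise
#' augmentations, and rasterizes the ground truth.
#'
#' @param mesh An `eit_mesh`.
#' @param seed Integer seed; the sample is a deterministic function of
#'   (mesh, seed, options).
#' @param n_enclosures Enclosures per phantom (`NA`: uniform 1..4).
#' @param planar Force enclosures to intersect the imaging plane.
#' @param noise List of augmentation stds
#'   (`thermal`, `quant`, `gain`; 0 disables).
#' @param base_contact Base contact impedance.
#' @return An `eit_sample` with the `voltage_frame` attached as
#'   `attr(, "frame")` and the spec as `attr(, "spec")`.
#' @export
simulate_sample <- function(mesh, seed, n_enclosures = NA_integer_,
                            planar = FALSE,
                            noise = list(thermal = 1e-6, quant = 1e-8,
                                         gain = 1e-6),
                            base_contact = 1e-2) {
  set.seed(seed)
  spec <- sample_phantom_spec(mesh$radius, n_enclosures = n_enclosures,
                              planar = planar)
  spec$seed <- seed
  ph <- suppressWarnings(build_phantom(mesh, spec))
  z <- sample_contact_impedance(base_contact, spec$contact_std, mesh$n_elec)
  fr <- simulate_voltages(mesh, ph, electrode_model(mesh$n_elec, z))
  e <- build_eim(fr)
  if (noise$thermal > 0) e <- apply_thermal_jitter(e, noise$thermal)
  if (noise$quant > 0) e <- apply_quantization(e, noise$quant)
  if (noise$gain > 0) e <- apply_channel_gain(e, noise$gain)
  s <- eit_sample(e, rasterize_target(spec, mesh$radius),
                  provenance = list(phantom_seed = seed))
  attr(s, "frame") <- fr
  attr(s, "spec") <- spec
  s
}
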
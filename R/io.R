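# On-disk layout: a dataset directory holds float32 multi-page TIFFs
# (dark.tif, flat.tif, reference.tif, projections.tif, optionally
# truth_psi_re.tif / truth_psi_im.tif) plus meta.yaml with the geometry,
# angles, and the per-page affine scaling that maps stored [0,1] samples
# back to physical values (TIFF float storage is only defined on [0,1]).

frame_pack <- function(frames) {
  scales <- lapply(frames, function(m) {
    lo <- min(m); hi <- max(m)
    if (hi == lo) list(offset = lo, scale = 0) else
      list(offset = lo, scale = hi - lo)
  })
  pages <- mapply(function(m, s) {
    if (s$scale == 0) matrix(0, nrow(m), ncol(m)) else (m - s$offset) / s$scale
  }, frames, scales, SIMPLIFY = FALSE)
  list(pages = pages, scales = scales)
}

frame_unpack <- function(pages, scales) {
  mapply(function(p, s) {
    off <- as.numeric(s$offset); sc <- as.numeric(s$scale)
    p * sc + off
  }, pages, scales, SIMPLIFY = FALSE)
}

write_stack <- function(frames, path) {
  pk <- frame_pack(frames)
  tiff::writeTIFF(pk$pages, path, bits.per.sample = 32L, reduce = FALSE)
  pk$scales
}

read_stack <- function(path, scales) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frame_unpack(pages, scales)
}

num17 <- function(x) sprintf("%.17g", x)  # full double precision in YAML

#' Write a speckle dataset to a directory
#'
#' Stores all frames as float32 multi-page TIFFs with a `meta.yaml` sidecar
#' carrying geometry, angles and the value scaling of every page. The round
#' trip through [read_dataset()] is exact at float32 storage precision.
#'
#' @param dataset A `speckle_dataset` (see [simulate_dataset()]).
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "speckle_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$geometry
  meta <- list(
    geometry = list(nx = g$nx, ny = g$ny, pitch = num17(g$pitch),
                    wavelength = num17(g$wavelength),
                    L1 = num17(g$L1), L2 = num17(g$L2)),
    angles = lapply(dataset$angles, num17)
  )
  meta$scales <- list(
    dark = write_stack(list(dataset$dark), file.path(path, "dark.tif")),
    flat = write_stack(list(dataset$flat), file.path(path, "flat.tif")),
    reference = write_stack(list(dataset$reference),
                            file.path(path, "reference.tif")),
    projections = write_stack(dataset$projections,
                              file.path(path, "projections.tif"))
  )
  if (!is.null(dataset$truth) && !is.null(dataset$truth$psi)) {
    meta$scales$truth_psi_re <- write_stack(
      lapply(dataset$truth$psi, Re), file.path(path, "truth_psi_re.tif"))
    meta$scales$truth_psi_im <- write_stack(
      lapply(dataset$truth$psi, Im), file.path(path, "truth_psi_im.tif"))
  }
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a speckle dataset from a directory
#'
#' @param path Directory written by [write_dataset()] (or assembled by hand:
#'   TIFF stacks plus a `meta.yaml` sidecar).
#' @return A `speckle_dataset`.
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "meta.yaml")
  if (!file.exists(meta_path))
    stop("missing geometry sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  need <- c("nx", "ny", "pitch", "wavelength", "L1", "L2")
  absent <- setdiff(need, names(meta$geometry))
  if (length(absent))
    stop("missing geometry keys in meta.yaml: ",
         paste(absent, collapse = ", "))
  gm <- meta$geometry
  geom <- imaging_geometry(as.integer(gm$nx), as.integer(gm$ny),
                           as.numeric(gm$pitch), as.numeric(gm$wavelength),
                           as.numeric(gm$L1), as.numeric(gm$L2))
  angles <- as.numeric(unlist(meta$angles))
  if (is.unsorted(angles, strictly = TRUE))
    stop("angles in meta.yaml are not strictly increasing")
  rd <- function(name) {
    f <- file.path(path, paste0(name, ".tif"))
    if (!file.exists(f)) stop("missing frame file: ", f)
    read_stack(f, meta$scales[[name]])
  }
  frames <- list(dark = rd("dark")[[1]], flat = rd("flat")[[1]],
                 reference = rd("reference")[[1]],
                 projections = rd("projections"))
  for (nm in c("dark", "flat", "reference")) {
    fm <- frames[[nm]]
    if (!all(dim(fm) == c(geom$ny, geom$nx)))
      stop(sprintf("frame '%s' has shape %d x %d, expected %d x %d",
                   nm, nrow(fm), ncol(fm), geom$ny, geom$nx))
  }
  if (length(frames$projections) != length(angles))
    stop("projection count does not match the number of angles")
  truth <- NULL
  if (!is.null(meta$scales$truth_psi_re)) {
    re <- rd("truth_psi_re"); im <- rd("truth_psi_im")
    truth <- list(psi = mapply(function(a, b)
      matrix(complex(real = a, imaginary = b), nrow(a), ncol(a)),
      re, im, SIMPLIFY = FALSE))
  }
  structure(list(dark = frames$dark, flat = frames$flat,
                 reference = frames$reference,
                 projections = frames$projections, angles = angles,
                 geometry = geom, truth = truth),
            class = "speckle_dataset")
}

#' Write / read a 3D volume as a multi-page TIFF with a YAML sidecar
#'
#' Slices along the first array dimension become TIFF pages; the sidecar
#' (`<path>.yaml`) stores the voxel pitch and per-page value scaling.
#'
#' @param volume Real 3D array.
#' @param path Output TIFF path.
#' @param voxel_pitch Voxel size in metres.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_pitch) {
  d <- dim(volume)
  stopifnot(length(d) == 3, voxel_pitch > 0)
  slices <- lapply(seq_len(d[1]), function(i) volume[i, , ])
  scales <- write_stack(slices, path)
  yaml::write_yaml(list(voxel_pitch = num17(voxel_pitch),
                        dims = as.list(d), scales = scales),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume
#' @return For `read_volume`: list with `volume` and `voxel_pitch`.
#' @export
read_volume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  slices <- read_stack(path, meta$scales)
  d <- as.integer(unlist(meta$dims))
  vol <- array(0, dim = d)
  for (i in seq_len(d[1])) vol[i, , ] <- slices[[i]]
  list(volume = vol, voxel_pitch = as.numeric(meta$voxel_pitch))
}

#' Write a retrieved phase map as a two-channel float TIFF
#'
#' Page 1 holds the attenuation `-Re(psi)`, page 2 the unwrapped phase
#' `Im(psi)`; the sidecar records the scaling.
#'
#' @param psi Complex phase-map matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phase_map <- function(psi, path) {
  scales <- write_stack(list(-Re(psi), Im(psi)), path)
  yaml::write_yaml(list(channels = c("attenuation", "phase"),
                        scales = scales), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_phase_map
#' @return For `read_phase_map`: the complex phase-map matrix.
#' @export
read_phase_map <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  ch <- read_stack(path, meta$scales)
  matrix(complex(real = -ch[[1]], imaginary = ch[[2]]),
         nrow(ch[[1]]), ncol(ch[[1]]))
}
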
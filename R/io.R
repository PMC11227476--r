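#' Write a time-lapse stack to multi-page TIFF
#'
#' One 32-bit float TIFF per channel, pages ordered T-then-Z (frame-major),
#' plus a JSON sidecar carrying the axis sizes, voxel size and frame
#' interval so that a round trip preserves shape and calibration.
#'
#' @param stack a `timelapse_stack` or named list of \code{[T, Z, Y, X]}
#'   arrays plus `voxel_um` and `dt`.
#' @param path output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  chans <- intersect(c("nucleus", "chromatin"), names(stack))
  files <- character(0)
  meta <- list(voxel_um = stack$voxel_um, dt = stack$dt, channels = chans)
  for (ch in chans) {
    arr <- stack[[ch]]
    d <- dim(arr)
    meta[[paste0("dim_", ch)]] <- d
    ## scale to [0,1] for float TIFF, keep range in metadata
    rng <- range(arr)
    meta[[paste0("range_", ch)]] <- rng
    sc <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
    pages <- lapply(seq_len(d[1]), function(t)
      lapply(seq_len(d[2]), function(z) sc[t, z, , ]))
    pages <- unlist(pages, recursive = FALSE)
    f <- file.path(path, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
    files <- c(files, f)
  }
  jsonlite::write_json(meta, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(path, "stack.json")))
}

#' Read a time-lapse stack written by [write_stack()]
#'
#' @param path directory containing per-channel TIFFs and `stack.json`.
#' @param voxel_um,dt overrides used (with a message) when the sidecar is
#'   missing; an error is raised if calibration is available from neither.
#' @return a `timelapse_stack`-shaped list.
#' @export
read_stack <- function(path, voxel_um = NULL, dt = NULL) {
  meta_file <- file.path(path, "stack.json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file,
                                                          simplifyVector = TRUE)
          else NULL
  if (is.null(meta)) {
    if (is.null(voxel_um) || is.null(dt))
      stop("no stack.json and no voxel_um/dt override supplied")
    message("no stack metadata found; using supplied voxel_um and dt")
    chans <- sub("[.]tif$", "", basename(list.files(path, pattern = "[.]tif$")))
    meta <- list(voxel_um = voxel_um, dt = dt, channels = chans)
  }
  out <- list(voxel_um = as.numeric(meta$voxel_um), dt = as.numeric(meta$dt))
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(path, paste0(ch, ".tif")), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dch <- meta[[paste0("dim_", ch)]]
    if (is.null(dch)) {
      ## promote a bare 2D/stack TIFF to T = n_pages, Z = 1
      warning("no axis metadata for channel ", ch,
              "; promoting pages to T, Z = 1")
      dch <- c(length(pages), 1L, dim(pages[[1]]))
    }
    arr <- array(0, dch)
    k <- 1L
    for (t in seq_len(dch[1])) for (z in seq_len(dch[2])) {
      arr[t, z, , ] <- pages[[k]]; k <- k + 1L
    }
    rng <- meta[[paste0("range_", ch)]]
    if (!is.null(rng) && diff(rng) > 0) arr <- arr * diff(rng) + rng[1]
    out[[ch]] <- arr
  }
  class(out) <- "timelapse_stack"
  out
}

#' Write and read trajectory tables
#'
#' CSV with comma separator, `.` decimal, mandatory header, µm-suffixed
#' coordinate columns — the on-disk exchange format between pipeline
#' stages. Numeric columns are written with full precision via
#' [format()]'s default 15 significant digits so re-running an unchanged
#' configuration reproduces byte-identical files.
#'
#' @param tracks a `chromo_tracks` data frame.
#' @param file output CSV path.
#' @export
write_tracks <- function(tracks, file) {
  df <- as.data.frame(tracks)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_tracks
#' @param dt,dims calibration for the read tracks.
#' @export
read_tracks <- function(file, dt = 10, dims = NULL) {
  df <- utils::read.csv(file)
  if (is.null(dims)) dims <- if ("z_um" %in% names(df)) 3L else 2L
  as_chromo_tracks(df, dt = dt, dims = dims)
}

#' Serialize frame transforms to JSON (+ TIFF displacement fields)
#'
#' Affine matrices are stored row-major in a JSON list; each non-null
#' displacement field is written to a float TIFF (two pages: uy then ux).
#'
#' @param transforms list from [register_sequence()].
#' @param path output directory.
#' @export
write_transforms <- function(transforms, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  js <- lapply(seq_along(transforms), function(f) {
    tr <- transforms[[f]]
    rec <- list(frame = f, A = as.vector(t(tr$A)), b = tr$b)
    if (!is.null(tr$uy)) {
      rng <- range(c(tr$uy, tr$ux))
      sc <- if (diff(rng) > 0) diff(rng) else 1
      tiff::writeTIFF(list((tr$uy - rng[1]) / sc, (tr$ux - rng[1]) / sc),
                      file.path(path, sprintf("field_%03d.tif", f)),
                      bits.per.sample = 32L)
      rec$field <- sprintf("field_%03d.tif", f)
      rec$field_range <- rng
    }
    rec
  })
  jsonlite::write_json(js, file.path(path, "transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
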
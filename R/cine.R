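#' Cine loop container
#'
#' An ordered stack of grayscale frames with its frame rate and (isotropic)
#' pixel spacing — the raw observation every downstream stage consumes.
#'
#' @param frames List of H x W numeric matrices with intensities in
#'   `[0, 1]`, or an H x W x T array.
#' @param frame_rate_hz Frames per second (> 0).
#' @param pixel_spacing_mm Isotropic pixel spacing in mm/px (> 0).
#' @param source Optional character describing provenance.
#' @return An object of class `cine_loop` with elements `frames` (list of
#'   matrices), `frame_rate_hz`, `pixel_spacing_mm`, `source`.
#' @export
cine_loop <- function(frames, frame_rate_hz, pixel_spacing_mm,
                      source = "memory") {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 2)
    abort_arg("A cine loop needs at least 2 frames.", "urokin_argument_error")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    abort_arg("All frames must have the same dimensions.",
              "urokin_argument_error")
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  assert_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_spacing_mm = pixel_spacing_mm, source = source),
            class = "cine_loop")
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cine_loop> %d frames, %d x %d px, %.1f Hz, %.3f mm/px\n",
              length(x$frames), d[1], d[2], x$frame_rate_hz,
              x$pixel_spacing_mm))
  invisible(x)
}

n_frames <- function(cine) length(cine$frames)
frame_size <- function(cine) dim(cine$frames[[1]])

#' Save and load cine loops as image stacks
#'
#' `save_cine()` writes a cine loop as a numbered image stack (`frame_0000`
#' onward) with a `metadata.json` sidecar holding the frame rate, pixel
#' spacing and file list. TIFF frames are written as 32-bit float and round
#' trip losslessly; PNG frames are 8-bit quantised. `load_cine()` reads such
#' a stack back. Multiframe DICOM and video containers are not readable in
#' this implementation and raise an unsupported-format error; convert such
#' loops to an image stack first.
#'
#' @param cine A [cine_loop()].
#' @param dir Directory to write the stack into (created if needed).
#' @param format `"tiff"` (default, lossless) or `"png"` (8-bit).
#' @return `save_cine` returns `dir` invisibly; `load_cine` returns a
#'   [cine_loop()].
#' @export
save_cine <- function(cine, dir, format = c("tiff", "png")) {
  stopifnot(inherits(cine, "cine_loop"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") "tif" else "png"
  files <- sprintf("frame_%04d.%s", seq_len(n_frames(cine)) - 1, ext)
  for (i in seq_len(n_frames(cine))) {
    f <- pmin(pmax(cine$frames[[i]], 0), 1)
    p <- file.path(dir, files[i])
    if (format == "tiff") tiff::writeTIFF(f, p, bits.per.sample = 32L)
    else png::writePNG(f, p)
  }
  meta <- list(frame_rate_hz = cine$frame_rate_hz,
               pixel_spacing_mm = cine$pixel_spacing_mm,
               frames = files)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cine
#' @param path A stack directory containing `metadata.json`, or a path with
#'   an unsupported extension (`.dcm`, `.avi`, `.mp4`), which errors.
#' @param frame_rate_hz,pixel_spacing_mm Overrides used when the metadata
#'   sidecar lacks them.
#' @export
load_cine <- function(path, frame_rate_hz = NULL, pixel_spacing_mm = NULL) {
  if (grepl("\\.(dcm|dicom|avi|mp4|mov)$", tolower(path)))
    abort_arg(paste0("Unsupported cine format '", path, "': only numbered ",
                     "PNG/TIFF stacks with a metadata.json sidecar are ",
                     "readable; export the loop as an image stack first."),
              "urokin_format_error")
  if (!dir.exists(path))
    abort_arg(sprintf("Cine stack directory '%s' does not exist.", path),
              "urokin_io_error")
  meta_path <- file.path(path, "metadata.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  rate <- frame_rate_hz %||% meta$frame_rate_hz
  spacing <- pixel_spacing_mm %||% meta$pixel_spacing_mm
  if (is.null(rate) || is.null(spacing))
    abort_arg(paste0("Frame rate and pixel spacing not found in ",
                     "metadata.json; pass `frame_rate_hz` and ",
                     "`pixel_spacing_mm` explicitly."),
              "urokin_calibration_error")
  files <- meta$frames %||% sort(list.files(path, "^frame_.*\\.(tif|tiff|png)$"))
  if (length(files) < 2)
    abort_arg("A cine loop needs at least 2 frames.", "urokin_io_error")
  frames <- lapply(file.path(path, files), read_gray_frame)
  cine_loop(frames, rate, spacing, source = path)
}

read_gray_frame <- function(p) {
  img <- if (grepl("\\.png$", tolower(p))) png::readPNG(p)
         else tiff::readTIFF(p)
  if (length(dim(img)) == 3) {
    # collapse RGB(A) to luminance
    nc <- min(dim(img)[3], 3)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  pmin(pmax(img, 0), 1)
}
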
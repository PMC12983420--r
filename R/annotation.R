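#' Region-of-interest annotation for one cine loop
#'
#' The operator's one-time input: four rectangles (proximal, mid and distal
#' urethra, plus the pubis), the inferior pubic point (IPP), and a second
#' point defining the pubic tangent direction, all in frame-0 image
#' coordinates.
#'
#' @section Coordinate convention:
#' Image coordinates are raster pixels, 0-based, `x` = column increasing
#' rightward and `y` = row increasing downward. In anatomical display
#' orientation "inferior" corresponds to larger row index, so each
#' rectangle's *origin* — its bottom-left corner as displayed — is the
#' corner with the smallest `x` and the **largest** `y`: a rectangle
#' `(origin_x, origin_y, width, height)` spans columns
#' `[origin_x, origin_x + width]` and rows `[origin_y - height, origin_y]`.
#' The tangent point must be placed posterior to the IPP (the pelvic x-axis
#' points from IPP toward it). The one flip from raster rows to the
#' superior-positive anatomical y-axis happens in [to_pelvic()] and nowhere
#' else.
#'
#' @param rois Named list with elements `proximal`, `mid`, `distal`,
#'   `pubis`, each a numeric vector `c(origin_x_px, origin_y_px, width_px,
#'   height_px)`.
#' @param ipp_px Numeric `c(x, y)`: the inferior pubic point.
#' @param tangent_px Numeric `c(x, y)`: a point along the inferior pubic
#'   margin, posterior to the IPP.
#' @param frame_index Frame the annotation refers to (default 0).
#' @param image_size Optional `c(height_px, width_px)`; when supplied,
#'   rectangles are checked against the frame bounds.
#' @return An object of class `roi_annotation`.
#' @examples
#' ann <- default_annotation()
#' ann$rois$proximal
#' @export
roi_annotation <- function(rois, ipp_px, tangent_px, frame_index = 0,
                           image_size = NULL) {
  need <- ALL_ROIS
  missing_lab <- setdiff(need, names(rois))
  if (length(missing_lab) > 0)
    abort_arg(sprintf("Annotation is missing ROI label(s): %s.",
                      paste(missing_lab, collapse = ", ")),
              "urokin_schema_error")
  for (lab in need) {
    r <- rois[[lab]]
    if (!is.numeric(r) || length(r) != 4 || any(!is.finite(r)))
      abort_arg(sprintf("ROI '%s' must be numeric (origin_x, origin_y, width, height).",
                        lab), "urokin_schema_error")
    if (r[3] <= 0 || r[4] <= 0)
      abort_arg(sprintf("ROI '%s' must have positive width and height.", lab),
                "urokin_schema_error")
  }
  ipp_px <- as.numeric(ipp_px)
  tangent_px <- as.numeric(tangent_px)
  if (length(ipp_px) != 2 || length(tangent_px) != 2)
    abort_arg("`ipp_px` and `tangent_px` must each be length-2 (x, y).",
              "urokin_schema_error")
  if (all(ipp_px == tangent_px))
    abort_arg("The IPP and the tangent point must differ.",
              "urokin_schema_error")
  u <- unique(lapply(URETHRA_ROIS, function(l) rois[[l]]))
  if (length(u) < 3)
    abort_arg("proximal, mid and distal rectangles must be mutually distinct.",
              "urokin_schema_error")
  ann <- structure(
    list(rois = rois[need], ipp_px = ipp_px, tangent_px = tangent_px,
         frame_index = as.integer(frame_index),
         coordinate_convention = "raster-0based-origin-bottom-left"),
    class = "roi_annotation")
  if (!is.null(image_size)) check_annotation_bounds(ann, image_size)
  ann
}

check_annotation_bounds <- function(ann, image_size) {
  H <- image_size[1]; W <- image_size[2]
  for (lab in names(ann$rois)) {
    r <- ann$rois[[lab]]
    xs <- c(r[1], r[1] + r[3]); ys <- c(r[2] - r[4], r[2])
    if (min(xs) < 0 || max(xs) > W - 1 || min(ys) < 0 || max(ys) > H - 1)
      abort_arg(sprintf("ROI '%s' exceeds the %d x %d frame bounds.",
                        lab, H, W), "urokin_bounds_error")
  }
  invisible(ann)
}

# Rectangle corners (4 x 2 matrix, x then y) for bounds/warp computations.
rect_corners <- function(r) {
  cbind(c(r[1], r[1] + r[3], r[1] + r[3], r[1]),
        c(r[2], r[2], r[2] - r[4], r[2] - r[4]))
}

rect_origin <- function(r) c(r[1], r[2])

#' Default synthetic annotation
#'
#' The ROI layout used by the synthetic cine generator for a 384 x 384 px
#' scene at 0.2 mm/px: pubis anteriorly with the IPP at its inferior margin,
#' and the three urethral rectangles posterior to it, proximal (bladder
#' neck) most superior. Spacings leave room for excursions up to ~12 mm.
#'
#' @param height_px,width_px Frame size the annotation is designed for.
#' @return An `roi_annotation`.
#' @export
default_annotation <- function(height_px = 384, width_px = 384) {
  s <- c(width_px / 384, height_px / 384)
  sc <- function(x, y) c(x * s[1], y * s[2])
  rect <- function(x, y, w, h) c(x * s[1], y * s[2], w * s[1], h * s[2])
  roi_annotation(
    rois = list(
      proximal = rect(240, 100, 30, 30),
      mid      = rect(232, 190, 30, 30),
      distal   = rect(224, 280, 30, 30),
      pubis    = rect(100, 160, 40, 40)),
    ipp_px = sc(140, 164),
    tangent_px = sc(190, 174),
    image_size = c(height_px, width_px))
}

#' Write / read an ROI annotation as JSON
#'
#' The JSON schema stores the four rectangles, the IPP and tangent points,
#' the annotation frame index and an explicit `coordinate_convention`
#' string. `read_annotation(write_annotation(ann, path))` is the identity.
#'
#' @param annotation An [roi_annotation()].
#' @param path File path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns an `roi_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "roi_annotation"))
  obj <- list(
    coordinate_convention = annotation$coordinate_convention,
    frame_index = annotation$frame_index,
    rois = lapply(annotation$rois, function(r)
      list(origin_x_px = r[1], origin_y_px = r[2],
           width_px = r[3], height_px = r[4])),
    ipp_px = annotation$ipp_px,
    tangent_px = annotation$tangent_px)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @param image_size Optional `c(height, width)` bounds check on read.
#' @export
read_annotation <- function(path, image_size = NULL) {
  if (!file.exists(path))
    abort_arg(sprintf("Annotation file '%s' does not exist.", path),
              "urokin_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rois))
    abort_arg("Annotation JSON is missing the 'rois' field.",
              "urokin_schema_error")
  rois <- lapply(obj$rois, function(r) {
    need <- c("origin_x_px", "origin_y_px", "width_px", "height_px")
    if (!all(need %in% names(r)))
      abort_arg("A rectangle is missing origin/size fields.",
                "urokin_schema_error")
    as.numeric(r[need])
  })
  ann <- roi_annotation(rois, ipp_px = as.numeric(obj$ipp_px),
                        tangent_px = as.numeric(obj$tangent_px),
                        frame_index = obj$frame_index %||% 0,
                        image_size = image_size)
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Frame-0 pelvic axes from the annotation: unit x (IPP -> tangent, posterior)
# and unit y (its superior normal in raster coordinates).
annotation_axes <- function(annotation) {
  v <- annotation$tangent_px - annotation$ipp_px
  n <- sqrt(sum(v^2))
  if (n == 0)
    abort_arg("IPP and tangent point coincide; axes are degenerate.",
              "urokin_degenerate_axis_error")
  ex <- v / n
  # superior normal: with rows increasing downward, (ey, -ex) points 'up'
  ey <- c(ex[2], -ex[1])
  list(x = ex, y = ey)
}
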
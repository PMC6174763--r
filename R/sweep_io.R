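#' @title Tracked-sweep containers and IO
#'
#' @description
#' A *tracked sweep* is an ordered sequence of 2D greyscale ultrasound
#' frames, each paired with a 4x4 homogeneous tracking matrix mapping the
#' electromagnetic-tracker origin to the centre of the image (translation in
#' mm). These containers and readers define the coordinate conventions the
#' whole package relies on:
#'
#' * pixel coordinates are 0-based `(row, col)`, fractional values allowed;
#'   rectangles are half-open;
#' * the in-plane axes are +col -> +x (mm), +row -> +y (mm), the plane
#'   normal is +z, and the image centre (at the fractional pixel
#'   `((height-1)/2, (width-1)/2)`) sits at the in-plane origin — so the
#'   tracking matrix applied to `(0,0,0,1)` is the image-centre position in
#'   tracker space;
#' * masks are stored on disk as 8-bit single-channel PNG with values
#'   \{0, 255\}, mapped to \{0, 1\} in memory.
#'
#' @name sweep_io
NULL

ROT_TOL <- 1e-6

assert_grey_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix")
  if (nrow(img) < 1 || ncol(img) < 1)
    stop(what, " must have positive dimensions")
  if (!all(is.finite(img)) || min(img) < 0 || max(img) > 255)
    stop(what, " intensities must be finite and within [0, 255]")
  invisible(img)
}

assert_tracking_matrix <- function(m, what = "tracking matrix") {
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    stop(what, " must be 4x4, got ",
         if (is.matrix(m)) paste(dim(m), collapse = "x") else class(m)[1])
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-12)))
    stop(what, ": last row must be (0,0,0,1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > ROT_TOL)
    stop(what, ": rotation block is not orthonormal within tolerance ", ROT_TOL)
  if (abs(det(R) - 1) > 1e-4)
    stop(what, ": rotation block must be a proper rotation (det +1)")
  invisible(m)
}

#' Construct a tracked frame
#'
#' @param image numeric matrix of intensities in `[0, 255]`.
#' @param tracking 4x4 homogeneous tracking matrix (rotation block
#'   orthonormal, last row `(0,0,0,1)`, translation in mm).
#' @param pixel_spacing length-2 numeric, mm per pixel as `(row, col)`.
#' @return An object of class `tracked_frame`.
#' @export
tracked_frame <- function(image, tracking, pixel_spacing) {
  assert_grey_image(image)
  assert_tracking_matrix(tracking)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive numbers (mm/px row, mm/px col)")
  structure(list(image = image, tracking = tracking, pixel_spacing = pixel_spacing),
            class = "tracked_frame")
}

#' Construct a tracked sweep
#'
#' @param frames list of [tracked_frame()] objects sharing dimensions and
#'   pixel spacing; at least two.
#' @param id character identifier.
#' @return An object of class `tracked_sweep`.
#' @export
tracked_sweep <- function(frames, id = "sweep") {
  if (length(frames) < 2) stop("a tracked sweep needs at least 2 frames")
  d1 <- dim(frames[[1]]$image); s1 <- frames[[1]]$pixel_spacing
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!inherits(f, "tracked_frame")) stop("frame ", k - 1, " is not a tracked_frame")
    if (!identical(dim(f$image), d1)) stop("frame ", k - 1, " has inconsistent dimensions")
    if (max(abs(f$pixel_spacing - s1)) > 1e-12) stop("frame ", k - 1, " has inconsistent pixel spacing")
  }
  structure(list(frames = frames, id = as.character(id)), class = "tracked_sweep")
}

#' @export
print.tracked_sweep <- function(x, ...) {
  d <- dim(x$frames[[1]]$image)
  cat(sprintf("tracked_sweep '%s': %d frames of %dx%d px, spacing (%.4g, %.4g) mm/px\n",
              x$id, length(x$frames), d[1], d[2],
              x$frames[[1]]$pixel_spacing[1], x$frames[[1]]$pixel_spacing[2]))
  invisible(x)
}

#' @export
print.tracked_frame <- function(x, ...) {
  cat(sprintf("tracked_frame %dx%d px, centre at (%.2f, %.2f, %.2f) mm\n",
              nrow(x$image), ncol(x$image),
              x$tracking[1, 4], x$tracking[2, 4], x$tracking[3, 4]))
  invisible(x)
}

#' Image-centre position in tracker space
#'
#' Applies the frame's tracking matrix to the homogeneous origin
#' `(0,0,0,1)`; by the package's coordinate contract this is the position of
#' the image centre in tracker (world) coordinates, in mm.
#'
#' @param frame a [tracked_frame()].
#' @return numeric length-3 (mm).
#' @export
frame_centre_world <- function(frame) {
  as.numeric(frame$tracking %*% c(0, 0, 0, 1))[1:3]
}

#' Map a pixel to tracker-space coordinates
#'
#' Pixel `(row, col)` (0-based, fractional allowed) is mapped to in-plane mm
#' offsets from the image centre (+col is +x, +row is +y), then through the
#' tracking matrix.
#'
#' @param frame a [tracked_frame()].
#' @param row,col 0-based pixel coordinates.
#' @return numeric length-3 (mm).
#' @export
pixel_to_world <- function(frame, row, col) {
  h <- nrow(frame$image); w <- ncol(frame$image)
  if (row < 0 || row > h - 1 || col < 0 || col > w - 1)
    stop("pixel (", row, ", ", col, ") out of bounds for a ", h, "x", w, " frame")
  x <- (col - (w - 1) / 2) * frame$pixel_spacing[2]
  y <- (row - (h - 1) / 2) * frame$pixel_spacing[1]
  as.numeric(frame$tracking %*% c(x, y, 0, 1))[1:3]
}

#' Map a tracker-space point into a frame's pixel coordinates
#'
#' Inverse of [pixel_to_world()]: the world point is taken through the
#' inverse tracking transform and the in-plane mm offsets are converted to
#' 0-based fractional `(row, col)`. The out-of-plane offset (mm along the
#' frame normal) is returned alongside so callers can detect points far from
#' the image plane. Coordinates are not clipped to the frame bounds.
#'
#' @param frame a [tracked_frame()].
#' @param p numeric length-3 world point (mm).
#' @return list with `row`, `col` (0-based, fractional) and `out_of_plane_mm`.
#' @export
world_to_pixel <- function(frame, p) {
  Ti <- solve(frame$tracking)
  q <- as.numeric(Ti %*% c(p, 1))[1:3]
  h <- nrow(frame$image); w <- ncol(frame$image)
  list(row = q[2] / frame$pixel_spacing[1] + (h - 1) / 2,
       col = q[1] / frame$pixel_spacing[2] + (w - 1) / 2,
       out_of_plane_mm = q[3])
}

read_matrix_file <- function(path) {
  vals <- tryCatch(scan(path, what = numeric(), quiet = TRUE),
                   error = function(e) stop("cannot parse matrix file '", path, "': ", conditionMessage(e)))
  if (length(vals) != 16)
    stop("matrix file '", path, "' holds ", length(vals), " numbers, expected 16 (4x4 row-major)")
  matrix(vals, 4, 4, byrow = TRUE)
}

read_grey_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  round(px * 255)
}

write_grey_png <- function(img, path) {
  png::writePNG(img / 255, path)
}

#' Read a tracked sweep
#'
#' The canonical carrier is a *manifest* directory: a `sweep.json` with
#' fields `{id, pixel_spacing_mm:[row,col], frames:[{image, matrix}, ...]}`,
#' one 8-bit grey PNG per frame and one plain-text 4x4 matrix file
#' (row-major, whitespace-separated) per frame. `format = "dicom_dir"` is a
#' read-only convenience for DICOM series: the series is converted to a
#' temporary manifest with the system `python`/`pydicom` (tracking matrices
#' are taken from a `sweep.json` sidecar in the same directory when present,
#' identity otherwise) and then read the canonical way.
#'
#' @param path directory containing the sweep.
#' @param format `"manifest"` (default) or `"dicom_dir"`.
#' @return A [tracked_sweep()].
#' @export
read_sweep <- function(path, format = c("manifest", "dicom_dir")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("sweep directory '", path, "' does not exist")
  if (format == "dicom_dir") path <- dicom_to_manifest(path)
  mf <- file.path(path, "sweep.json")
  if (!file.exists(mf)) stop("manifest '", mf, "' not found")
  man <- jsonlite::fromJSON(mf, simplifyDataFrame = FALSE)
  sp <- as.numeric(man$pixel_spacing_mm)
  frames <- vector("list", length(man$frames))
  for (k in seq_along(man$frames)) {
    fr <- man$frames[[k]]
    ip <- file.path(path, fr$image); mp <- file.path(path, fr$matrix)
    if (!file.exists(ip)) stop("frame ", k - 1, ": image file '", ip, "' missing")
    if (!file.exists(mp)) stop("frame ", k - 1, ": matrix file '", mp, "' missing")
    m <- read_matrix_file(mp)
    frames[[k]] <- tryCatch(tracked_frame(read_grey_png(ip), m, sp),
                            error = function(e) stop("frame ", k - 1, ": ", conditionMessage(e)))
  }
  tracked_sweep(frames, id = if (is.null(man$id)) basename(path) else man$id)
}

#' Write a tracked sweep as a manifest directory
#'
#' @param sweep a [tracked_sweep()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(sweep$frames)
  entries <- vector("list", n)
  for (k in seq_len(n)) {
    img_name <- sprintf("f%04d.png", k - 1)
    mat_name <- sprintf("f%04d.txt", k - 1)
    write_grey_png(sweep$frames[[k]]$image, file.path(path, img_name))
    m <- sweep$frames[[k]]$tracking
    writeLines(apply(format(m, digits = 17), 1, paste, collapse = " "),
               file.path(path, mat_name))
    entries[[k]] <- list(image = img_name, matrix = mat_name)
  }
  man <- list(id = sweep$id,
              pixel_spacing_mm = sweep$frames[[1]]$pixel_spacing,
              frames = entries)
  jsonlite::write_json(man, file.path(path, "sweep.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Convert a DICOM series directory to a manifest directory via pydicom.
dicom_to_manifest <- function(path) {
  py <- Sys.which("python")
  if (py == "") stop("DICOM reading needs a system 'python' with pydicom on PATH")
  out <- tempfile("dicom_manifest_")
  script <- system.file("python", "dicom_to_manifest.py", package = "thyrosweep")
  if (script == "") stop("bundled dicom_to_manifest.py not found")
  status <- system2(py, c(script, shQuote(path), shQuote(out)), stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("DICOM conversion failed:\n", paste(status, collapse = "\n"))
  out
}

#' Write / read a stack of binary masks
#'
#' Masks are written as 8-bit single-channel PNGs (`0`/`255` on disk,
#' `0`/`1` in memory), one file per slice (`m0000.png`, ...), with a
#' `stack.json` recording the order. The round trip is lossless.
#'
#' @param masks list of 0/1 integer matrices sharing dimensions.
#' @param path directory to write to / read from.
#' @return `read_mask_stack` returns the list of masks; `write_mask_stack`
#'   returns `path` invisibly.
#' @export
write_mask_stack <- function(masks, path) {
  if (!length(masks)) stop("empty mask stack")
  d1 <- dim(masks[[1]])
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  names_out <- character(length(masks))
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    if (!identical(dim(m), d1)) stop("mask ", k - 1, " dimensions differ from mask 0")
    if (!all(m %in% c(0, 1))) stop("mask ", k - 1, " has values outside {0, 1}")
    names_out[k] <- sprintf("m%04d.png", k - 1)
    png::writePNG(m * 1.0, file.path(path, names_out[k]))
  }
  jsonlite::write_json(list(masks = names_out), file.path(path, "stack.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  sf <- file.path(path, "stack.json")
  if (!file.exists(sf)) stop("mask stack index '", sf, "' not found")
  names_in <- jsonlite::fromJSON(sf)$masks
  masks <- vector("list", length(names_in))
  d1 <- NULL
  for (k in seq_along(names_in)) {
    px <- png::readPNG(file.path(path, names_in[k]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    m <- matrix(as.integer(round(px * 255) >= 128), nrow(px), ncol(px))
    if (is.null(d1)) d1 <- dim(m)
    else if (!identical(dim(m), d1)) stop("mask ", k - 1, " dimensions differ from mask 0")
    masks[[k]] <- m
  }
  masks
}
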
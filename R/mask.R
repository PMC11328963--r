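#' Binary segmentation masks
#'
#' A binary mask is a logical matrix (`TRUE` = foreground) with class
#' `binary_mask`. Rows index image rows (y), columns index image columns (x).
#' Pixel coordinates exported in tables (centroids, laser positions) follow
#' the image convention: `x = column - 1`, `y = row - 1`, i.e. 0-based with
#' the origin at the top-left pixel.
#'
#' @param x A logical matrix; `NA` is not allowed.
#' @return A `binary_mask` object.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' mask_area(m)
#' @export
binary_mask <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  if (!is.logical(x)) {
    if (is.numeric(x)) x <- matrix(x != 0, nrow(x), ncol(x)) else
      stop("`x` must be a logical (or numeric) matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) stop("mask dimensions must be positive", call. = FALSE)
  if (anyNA(x)) stop("mask may not contain NA", call. = FALSE)
  structure(x, class = c("binary_mask", "matrix", "array"))
}

#' @rdname binary_mask
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @rdname binary_mask
#' @export
mask_width <- function(x) ncol(x)

#' @rdname binary_mask
#' @export
mask_height <- function(x) nrow(x)

#' Foreground pixel count of a mask
#' @param x A `binary_mask`.
#' @return Number of foreground pixels.
#' @export
mask_area <- function(x) sum(x)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d foreground (%.1f%%)>\n",
              mask_width(x), mask_height(x), mask_area(x),
              100 * mask_area(x) / length(x)))
  invisible(x)
}

as_logical_matrix <- function(m) {
  matrix(as.logical(m), nrow(m), ncol(m))
}

check_same_dims <- function(a, b, what = c("masks")) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop(sprintf("dimension mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Corrective-annotation masks
#'
#' User corrections of a model prediction: green marks pixels the model
#' wrongly predicted as foreground (false positives, should be background),
#' red marks pixels the model missed (false negatives, should be foreground).
#' The two sets are disjoint by construction.
#'
#' @param green,red Logical matrices of identical dimensions.
#' @return An `annotation_mask` object (list with elements `green`, `red`).
#' @export
annotation_mask <- function(green, red) {
  if (!is.matrix(green) || !is.matrix(red)) stop("`green` and `red` must be matrices", call. = FALSE)
  green <- as_logical_matrix(green)
  red <- as_logical_matrix(red)
  check_same_dims(green, red)
  if (nrow(green) < 1L || ncol(green) < 1L) stop("annotation dimensions must be positive", call. = FALSE)
  if (anyNA(green) || anyNA(red)) stop("annotation may not contain NA", call. = FALSE)
  if (any(green & red)) stop("a pixel cannot be both green and red", call. = FALSE)
  structure(list(green = green, red = red), class = "annotation_mask")
}

#' @rdname annotation_mask
#' @param x An object.
#' @export
is_annotation_mask <- function(x) inherits(x, "annotation_mask")

#' @export
print.annotation_mask <- function(x, ...) {
  cat(sprintf("<annotation_mask %d x %d px, %d green, %d red>\n",
              ncol(x$green), nrow(x$green), sum(x$green), sum(x$red)))
  invisible(x)
}

#' Read a binary mask from a PNG file
#'
#' A pixel is foreground iff it satisfies `foreground_rule`. The default
#' (`"any_nonzero"`) treats a pixel as foreground when any channel —
#' including alpha, if present — exceeds `threshold`; this is robust to the
#' palette a segmentation tool uses for its overlay colour.
#'
#' @param path Path to a PNG file (grayscale, RGB or RGBA).
#' @param foreground_rule `"any_nonzero"`, `"channel"` (use `channel`), or a
#'   function taking the decoded array and returning a logical matrix.
#' @param channel Channel index used when `foreground_rule = "channel"`.
#' @param threshold Intensity threshold on the 0–1 scale (default 0, i.e.
#'   any non-zero value).
#' @return A [binary_mask].
#' @export
read_mask <- function(path, foreground_rule = "any_nonzero", channel = NULL,
                      threshold = 0) {
  arr <- read_png_checked(path)
  fg <- if (is.function(foreground_rule)) {
    foreground_rule(arr)
  } else if (identical(foreground_rule, "any_nonzero")) {
    if (is.matrix(arr)) arr > threshold
    else Reduce(`|`, lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] > threshold))
  } else if (identical(foreground_rule, "channel")) {
    if (is.null(channel)) stop("`channel` must be given for the channel rule", call. = FALSE)
    if (is.matrix(arr)) {
      if (channel != 1L) stop("grayscale image has a single channel", call. = FALSE)
      arr > threshold
    } else {
      if (channel > dim(arr)[3]) stop("channel index out of range", call. = FALSE)
      arr[, , channel] > threshold
    }
  } else stop("unknown foreground rule", call. = FALSE)
  binary_mask(fg)
}

read_png_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  arr <- png::readPNG(path)
  d <- dim(arr)
  if (d[1] < 1L || d[2] < 1L) stop("zero-sized image", call. = FALSE)
  arr
}

#' Write a binary mask to a PNG file
#'
#' Foreground pixels are written as an opaque single colour; background is
#' fully transparent (default) or opaque black.
#'
#' @param mask A [binary_mask].
#' @param path Output path.
#' @param colour Foreground colour as an RGB triple on 0–1 (default white).
#' @param background `"transparent"` or `"black"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, colour = c(1, 1, 1),
                       background = c("transparent", "black")) {
  stopifnot(is_binary_mask(mask))
  background <- match.arg(background)
  h <- mask_height(mask); w <- mask_width(mask)
  fg <- unclass(mask)
  arr <- array(0, c(h, w, 4))
  for (k in 1:3) arr[, , k] <- ifelse(fg, colour[k], 0)
  arr[, , 4] <- if (background == "transparent") as.numeric(fg) else 1
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a corrective annotation from a PNG file
#'
#' Green pixels (within `colour_tolerance` of pure green, non-zero alpha)
#' mark false positives; red pixels mark false negatives. All other pixels
#' are unannotated. A tolerance below 128 makes green/red overlap impossible,
#' so an overlapping pixel is a hard error.
#'
#' @param path Path to an RGB(A) PNG.
#' @param colour_tolerance Per-channel tolerance on the 0–255 scale
#'   (default 30, absorbing anti-aliased stroke edges).
#' @return An [annotation_mask].
#' @export
read_annotation <- function(path, colour_tolerance = 30) {
  if (colour_tolerance < 0) stop("`colour_tolerance` must be >= 0", call. = FALSE)
  arr <- read_png_checked(path)
  if (is.matrix(arr) || dim(arr)[3] < 3L)
    stop("annotation PNG must have RGB channels", call. = FALSE)
  tol <- colour_tolerance / 255
  r <- arr[, , 1]; g <- arr[, , 2]; b <- arr[, , 3]
  a <- if (dim(arr)[3] >= 4L) arr[, , 4] else matrix(1, nrow(r), ncol(r))
  green <- r <= tol & g >= 1 - tol & b <= tol & a > 0
  red <- r >= 1 - tol & g <= tol & b <= tol & a > 0
  if (any(green & red))
    stop("pixel matches both annotation colours; lower `colour_tolerance`", call. = FALSE)
  annotation_mask(green, red)
}

#' Write a corrective annotation to a PNG file
#'
#' Green strokes are written as opaque pure green, red as opaque pure red,
#' everything else fully transparent.
#'
#' @param ann An [annotation_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(is_annotation_mask(ann))
  h <- nrow(ann$green); w <- ncol(ann$green)
  arr <- array(0, c(h, w, 4))
  arr[, , 1] <- as.numeric(ann$red)
  arr[, , 2] <- as.numeric(ann$green)
  arr[, , 4] <- as.numeric(ann$green | ann$red)
  png::writePNG(arr, path)
  invisible(path)
}

#' Apply user corrections to a prediction
#'
#' The corrected segmentation is the prediction minus the green pixels plus
#' the red pixels. Green strokes outside the prediction and red strokes
#' inside it are no-ops; their counts are attached as attributes
#' `redundant_green` and `redundant_red` for diagnostics.
#'
#' @param pred A [binary_mask] prediction.
#' @param ann An [annotation_mask] of the same dimensions.
#' @return The corrected [binary_mask].
#' @export
apply_correction <- function(pred, ann) {
  stopifnot(is_binary_mask(pred), is_annotation_mask(ann))
  check_same_dims(pred, ann$green)
  out <- binary_mask((unclass(pred) & !ann$green) | ann$red)
  attr(out, "redundant_green") <- sum(ann$green & !pred)
  attr(out, "redundant_red") <- sum(ann$red & pred)
  out
}

#' Pixel confusion counts between a prediction and a reference mask
#'
#' @param pred,truth [binary_mask] objects of identical dimensions.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn` (stored as
#'   doubles; counts can exceed the integer range when pooled over many
#'   large images).
#' @export
confusion <- function(pred, truth) {
  stopifnot(is_binary_mask(pred), is_binary_mask(truth))
  check_same_dims(pred, truth)
  p <- unclass(pred); t <- unclass(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  tibble::tibble(tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn),
                 tn = as.numeric(length(p) - tp - fp - fn))
}
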
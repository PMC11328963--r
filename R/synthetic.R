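#' Synthetic benthic scenes with exact ground truth
#'
#' The generator emulates the structure of benthic survey frames at desk
#' scale: lobed foreground blobs (unions of overlapping ellipses, mimicking
#' lobed sponge bodies) on a textured background, model predictions
#' corrupted by boundary bias, missed individuals and false-positive
#' speckles, simulated user corrections of controllable completeness, and
#' paired laser dots at a known pixel separation. Every output is
#' deterministic for a given seed and carries exact bookkeeping, so the
#' metric, measurement and calibration modules can be tested without any
#' image download.
#'
#' @param width,height Frame size in pixels.
#' @param n_blobs Number of individuals per frame.
#' @param semi_axis_range Range of the major semi-axis in pixels.
#' @param axis_ratio_range Range of minor/major axis ratio.
#' @param lobes_range Range (min, max) of ellipse lobes per blob.
#' @param rotation_range Range of blob orientation in radians.
#' @param texture_amplitude Background texture amplitude in \[0, 1\]
#'   (cosmetic only: no computation consults the image raster).
#' @param seed Integer seed; the same spec always produces the same scene.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width = 160, height = 160, n_blobs = 3,
                       semi_axis_range = c(10, 22),
                       axis_ratio_range = c(0.4, 1),
                       lobes_range = c(1, 3),
                       rotation_range = c(0, pi),
                       texture_amplitude = 0.2, seed = 1) {
  stopifnot(width > 0, height > 0, n_blobs >= 0,
            length(semi_axis_range) == 2, semi_axis_range[1] <= semi_axis_range[2],
            semi_axis_range[1] > 0,
            length(axis_ratio_range) == 2, axis_ratio_range[1] <= axis_ratio_range[2],
            axis_ratio_range[1] > 0, axis_ratio_range[2] <= 1,
            length(lobes_range) == 2, lobes_range[1] >= 1,
            lobes_range[1] <= lobes_range[2],
            texture_amplitude >= 0, texture_amplitude <= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_blobs = as.integer(n_blobs),
                 semi_axis_range = semi_axis_range,
                 axis_ratio_range = axis_ratio_range,
                 lobes_range = as.integer(lobes_range),
                 rotation_range = rotation_range,
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

runif1 <- function(range) if (range[1] == range[2]) range[1] else stats::runif(1, range[1], range[2])

# pixels inside a rotated ellipse; returns a logical full-frame matrix
rasterize_ellipse <- function(height, width, cy, cx, a, b, theta) {
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(cy) - ext); r1 <- min(height, ceiling(cy) + ext)
  c0 <- max(1L, floor(cx) - ext); c1 <- min(width, ceiling(cx) + ext)
  m <- matrix(FALSE, height, width)
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m[rows, cols] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# binary dilation by a disc of radius r (shift-union); erosion is the
# complement-dual. The (r + 0.5)^2 threshold gives the standard discrete
# approximation of a Euclidean disc (a plain r^2 cut-off under-reaches on
# diagonals, biasing ring areas low by ~10%).
disc_offsets <- function(r) {
  r <- abs(r)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= (r + 0.5)^2, , drop = FALSE]
}

shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  ci <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, ci] <- m[ri - di, ci - dj]
  out
}

dilate_disc <- function(m, r) {
  if (r <= 0) return(m)
  off <- disc_offsets(r)
  Reduce(`|`, purrr::map2(off$di, off$dj, function(di, dj) shift_matrix(m, di, dj)))
}

erode_disc <- function(m, r) {
  if (r <= 0) return(m)
  !dilate_disc(!m, r)
}

#' Generate one synthetic scene
#'
#' Blobs are placed by rejection sampling (up to 1000 attempts per blob):
#' a blob must not touch the frame border and must not touch (8-adjacency)
#' a previously placed blob, so the true region count equals `n_blobs`.
#' Infeasible packings fail deterministically rather than overlapping
#' silently.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (numeric matrix in \[0, 1\],
#'   cosmetic), `truth` (a [binary_mask]), and `blobs` (a tibble of sampled
#'   blob parameters).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    truth <- matrix(FALSE, h, w)
    occupied <- matrix(FALSE, h, w)  # truth dilated by 1: keeps blobs apart
    blobs <- list()
    for (bi in seq_len(spec$n_blobs)) {
      placed <- FALSE
      for (try in seq_len(1000)) {
        a <- runif1(spec$semi_axis_range)
        b <- a * runif1(spec$axis_ratio_range)
        theta <- runif1(spec$rotation_range)
        n_lobes <- if (spec$lobes_range[1] == spec$lobes_range[2]) spec$lobes_range[1]
                   else sample(spec$lobes_range[1]:spec$lobes_range[2], 1)
        margin <- a * 1.9 + 2
        if (w - 2 * margin < 1 || h - 2 * margin < 1) next
        cx <- stats::runif(1, 1 + margin, w - margin)
        cy <- stats::runif(1, 1 + margin, h - margin)
        blob <- rasterize_ellipse(h, w, cy, cx, a, b, theta)
        if (n_lobes > 1) {
          for (li in seq_len(n_lobes - 1)) {
            phi <- stats::runif(1, 0, 2 * pi)
            d <- stats::runif(1, 0.3, 0.8) * a
            la <- a * stats::runif(1, 0.3, 0.6)
            lb <- la * stats::runif(1, 0.5, 1)
            blob <- blob | rasterize_ellipse(h, w, cy + d * sin(phi), cx + d * cos(phi),
                                             la, lb, stats::runif(1, 0, pi))
          }
        }
        if (!any(blob)) next
        touches_border <- any(blob[1, ]) || any(blob[h, ]) || any(blob[, 1]) || any(blob[, w])
        if (touches_border || any(blob & occupied)) next
        truth <- truth | blob
        occupied <- occupied | dilate_disc(blob, 1)
        blobs[[bi]] <- tibble::tibble(blob = bi, cx = cx - 1, cy = cy - 1,
                                      a = a, b = b, theta = theta,
                                      n_lobes = n_lobes)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible packing: could not place blob after 1000 attempts", call. = FALSE)
    }
    image <- matrix(stats::runif(h * w, 0, spec$texture_amplitude), h, w)
    image[truth] <- pmin(1, image[truth] + 0.6)
    list(image = image, truth = binary_mask(truth),
         blobs = if (length(blobs)) dplyr::bind_rows(blobs) else
           tibble::tibble(blob = integer(), cx = numeric(), cy = numeric(),
                          a = numeric(), b = numeric(), theta = numeric(),
                          n_lobes = integer()))
  })
}

#' Prediction-error model for synthetic scenes
#'
#' @param boundary_radius Signed pixels: > 0 dilates the truth (systematic
#'   over-segmentation), < 0 erodes it.
#' @param speckle_fp_count Number of false-positive speckle discs added on
#'   the background.
#' @param speckle_radius Speckle disc radius in pixels.
#' @param miss_probability Probability that a whole individual is missed.
#' @param seed Integer seed.
#' @return A `corruption_spec` object.
#' @export
corruption_spec <- function(boundary_radius = 0, speckle_fp_count = 0,
                            speckle_radius = 2, miss_probability = 0, seed = 1) {
  stopifnot(miss_probability >= 0, miss_probability <= 1,
            speckle_fp_count >= 0, speckle_radius >= 1)
  structure(list(boundary_radius = as.integer(round(boundary_radius)),
                 speckle_fp_count = as.integer(speckle_fp_count),
                 speckle_radius = as.integer(speckle_radius),
                 miss_probability = miss_probability,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a truth mask into a model-like prediction
#'
#' Applies, in order: whole-blob deletion with `miss_probability`, a
#' morphological boundary change of `boundary_radius`, and
#' `speckle_fp_count` false-positive discs placed on the background
#' (disjoint from the truth). The exact confusion counts of the returned
#' prediction against the truth are computed and returned as bookkeeping —
#' the single source of truth in tests.
#'
#' @param truth A [binary_mask].
#' @param spec A [corruption_spec()].
#' @return A list with `pred` (a [binary_mask]) and `confusion` (one-row
#'   tibble `tp`/`fp`/`fn`/`tn`).
#' @export
corrupt_prediction <- function(truth, spec) {
  stopifnot(is_binary_mask(truth), inherits(spec, "corruption_spec"))
  withr::with_seed(spec$seed, {
    t_m <- unclass(truth)
    h <- nrow(t_m); w <- ncol(t_m)
    pred <- t_m
    if (spec$miss_probability > 0) {
      lab <- label_components(truth, 8)
      nreg <- n_regions(lab)
      if (nreg > 0) {
        drop <- stats::runif(nreg) < spec$miss_probability
        if (any(drop)) pred <- pred & !(matrix(drop[ifelse(lab > 0, lab, 1)], h, w) & lab > 0)
      }
    }
    if (spec$boundary_radius > 0) pred <- dilate_disc(pred, spec$boundary_radius)
    if (spec$boundary_radius < 0) pred <- erode_disc(pred, -spec$boundary_radius)
    if (spec$speckle_fp_count > 0) {
      r <- spec$speckle_radius
      for (s in seq_len(spec$speckle_fp_count)) {
        for (try in seq_len(100)) {
          cy <- stats::runif(1, 1 + r, h - r)
          cx <- stats::runif(1, 1 + r, w - r)
          disc <- rasterize_ellipse(h, w, cy, cx, r, r, 0)
          if (!any(disc & t_m)) {
            pred <- pred | disc
            break
          }
        }
      }
    }
    pred <- binary_mask(pred)
    list(pred = pred, confusion = confusion(pred, truth))
  })
}

#' Simulate user corrections of a prediction
#'
#' The simulated annotator marks each erroneous pixel independently with
#' probability `completeness`: green for false positives, red for false
#' negatives. `completeness = 1` reproduces the truth exactly under
#' [apply_correction()]; lower values emulate sloppy or partial strokes.
#'
#' @param pred,truth Dimension-matched [binary_mask] objects.
#' @param completeness Per-pixel correction probability in \[0, 1\].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An [annotation_mask].
#' @export
derive_annotation <- function(pred, truth, completeness = 1, seed = NULL) {
  stopifnot(is_binary_mask(pred), is_binary_mask(truth),
            completeness >= 0, completeness <= 1)
  check_same_dims(pred, truth)
  draw <- function() {
    fp <- unclass(pred) & !unclass(truth)
    fn <- unclass(truth) & !unclass(pred)
    keep <- function(m) {
      idx <- which(m)
      if (length(idx) && completeness < 1) {
        m[idx[stats::runif(length(idx)) > completeness]] <- FALSE
      }
      if (completeness == 0) m[] <- FALSE
      m
    }
    annotation_mask(keep(fp), keep(fn))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Training-trajectory specification
#'
#' Corruption magnitudes decay exponentially with image index
#' (`initial * exp(-i / tau)`), emulating the improvement of an
#' interactively trained model over the annotation sequence.
#'
#' @param n_images Number of images in the sequence.
#' @param scene A [scene_spec()] used for every frame (its seed is
#'   re-derived per frame).
#' @param initial A [corruption_spec()] giving the corruption magnitudes at
#'   image 0.
#' @param tau Decay constant in images (> 0).
#' @param completeness Correction completeness passed to
#'   [derive_annotation()].
#' @param seed Integer master seed; all per-frame seeds derive from it.
#' @return A `trajectory_spec` object.
#' @export
trajectory_spec <- function(n_images = 60, scene = scene_spec(),
                            initial = corruption_spec(boundary_radius = 3,
                                                      speckle_fp_count = 8,
                                                      miss_probability = 0.3),
                            tau = 8, completeness = 1, seed = 1) {
  stopifnot(n_images >= 1, tau > 0, completeness >= 0, completeness <= 1,
            inherits(scene, "scene_spec"), inherits(initial, "corruption_spec"))
  structure(list(n_images = as.integer(n_images), scene = scene,
                 initial = initial, tau = tau, completeness = completeness,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate a training sequence with decaying corruption
#'
#' @param tspec A [trajectory_spec()].
#' @return A `training_sequence` tibble with one row per image: `image_id`,
#'   `index` (0-based), list-columns `truth`, `pred`, `ann`, and the exact
#'   truth-based confusion bookkeeping `tp`, `fp`, `fn`, `tn`. Feed it
#'   directly to [evaluate_sequence()].
#' @export
generate_training_sequence <- function(tspec) {
  stopifnot(inherits(tspec, "trajectory_spec"))
  n <- tspec$n_images
  seeds <- withr::with_seed(tspec$seed,
                            matrix(sample.int(.Machine$integer.max - 1L, n * 3L), n, 3L))
  rows <- purrr::map(seq_len(n), function(i) {
    decay <- exp(-(i - 1) / tspec$tau)
    sc <- tspec$scene
    sc$seed <- seeds[i, 1]
    scene <- generate_scene(sc)
    cs <- corruption_spec(
      boundary_radius = round(tspec$initial$boundary_radius * decay),
      speckle_fp_count = round(tspec$initial$speckle_fp_count * decay),
      speckle_radius = tspec$initial$speckle_radius,
      miss_probability = tspec$initial$miss_probability * decay,
      seed = seeds[i, 2])
    corr <- corrupt_prediction(scene$truth, cs)
    ann <- derive_annotation(corr$pred, scene$truth, tspec$completeness,
                             seed = seeds[i, 3])
    tibble::tibble(image_id = sprintf("img_%04d", i - 1L), index = i - 1L,
                   image = list(scene$image), truth = list(scene$truth),
                   pred = list(corr$pred), ann = list(ann), corr$confusion)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("training_sequence", class(out))
  out
}

#' Generate a synthetic laser-dot frame
#'
#' Two rasterized discs whose centroid separation equals
#' `px_per_cm * separation_cm` (within half a pixel of rasterization
#' error), at a random near-horizontal orientation and position.
#'
#' @param px_per_cm Target scale factor.
#' @param separation_cm Physical laser separation (default 5 cm).
#' @param dot_radius Dot radius in pixels (default 3).
#' @param width,height Frame size; defaults are chosen to fit the dot pair
#'   with margin.
#' @param seed Integer seed.
#' @return A [binary_mask] with attribute `centers` (the true dot centres,
#'   0-based x/y).
#' @export
generate_laser_frame <- function(px_per_cm, separation_cm = 5, dot_radius = 3,
                                 width = NULL, height = NULL, seed = 1) {
  stopifnot(px_per_cm > 0, separation_cm > 0, dot_radius >= 1)
  d <- px_per_cm * separation_cm
  margin <- dot_radius + 3
  width <- width %||% (ceiling(d) + 8 * dot_radius + 40)
  height <- height %||% max(96, 8 * dot_radius + 40)
  withr::with_seed(seed, {
    theta <- stats::runif(1, -pi / 12, pi / 12)
    dx <- d * cos(theta); dy <- d * sin(theta)
    if (abs(dx) > width - 2 * margin - 1 || abs(dy) > height - 2 * margin - 1)
      stop("infeasible geometry: dot pair does not fit in the frame", call. = FALSE)
    x1 <- stats::runif(1, 1 + margin, width - margin - abs(dx))
    y1 <- stats::runif(1, 1 + margin + max(0, -dy), height - margin - max(0, dy))
    x2 <- x1 + dx; y2 <- y1 + dy
    m <- rasterize_ellipse(height, width, y1, x1, dot_radius, dot_radius, 0) |
         rasterize_ellipse(height, width, y2, x2, dot_radius, dot_radius, 0)
    out <- binary_mask(m)
    attr(out, "centers") <- tibble::tibble(x = c(x1, x2) - 1, y = c(y1, y2) - 1)
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the directory-tree convention the pipeline consumes — `images/`,
#' `truths/`, `predictions/`, `annotations/` and (optionally) `lasers/`
#' with matching basenames — plus a `manifest.csv` of generator parameters
#' and exact bookkeeping counts.
#'
#' @param dir Output directory (created if missing).
#' @param tspec A [trajectory_spec()].
#' @param laser_px_per_cm If non-`NULL`, a laser frame at this scale is
#'   written per image.
#' @param separation_cm,dot_radius Laser-frame parameters.
#' @return The manifest tibble, invisibly.
#' @export
simulate_dataset <- function(dir, tspec, laser_px_per_cm = NULL,
                             separation_cm = 5, dot_radius = 3) {
  seq_tab <- generate_training_sequence(tspec)
  sub <- c("images", "truths", "predictions", "annotations",
           if (!is.null(laser_px_per_cm)) "lasers")
  for (s in sub) dir.create(file.path(dir, s), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(seq_tab))) {
    id <- seq_tab$image_id[i]
    img <- seq_tab$image[[i]]
    png::writePNG(img, file.path(dir, "images", paste0(id, ".png")))
    write_mask(seq_tab$truth[[i]], file.path(dir, "truths", paste0(id, ".png")))
    write_mask(seq_tab$pred[[i]], file.path(dir, "predictions", paste0(id, ".png")))
    write_annotation(seq_tab$ann[[i]], file.path(dir, "annotations", paste0(id, ".png")))
    if (!is.null(laser_px_per_cm)) {
      lf <- generate_laser_frame(laser_px_per_cm, separation_cm, dot_radius,
                                 seed = tspec$seed + i)
      write_mask(lf, file.path(dir, "lasers", paste0(id, ".png")))
    }
  }
  manifest <- dplyr::select(seq_tab, "image_id", "index", "tp", "fp", "fn", "tn")
  manifest$seed <- tspec$seed
  manifest$tau <- tspec$tau
  manifest$completeness <- tspec$completeness
  manifest$laser_px_per_cm <- laser_px_per_cm %||% NA_real_
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
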
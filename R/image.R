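#' Load an RGB image of cooked rice
#'
#' Reads a TIFF or PNG file into a `rice_image` object: an `H x W x 3` array of
#' red/green/blue intensities on the 0--255 scale plus capture metadata. The
#' imaging protocol this supports saves 8-megapixel TIFF frames
#' (3264 x 2448), but any size is accepted; resolution is metadata, not a
#' requirement.
#'
#' Grayscale and alpha-channel images are rejected explicitly: the yellow-area
#' score is defined on three-channel colour data.
#'
#' @param path Path to a `.tiff`/`.tif` or `.png` file.
#' @return A `rice_image`: list with `pixels` (H x W x 3 array, values in
#'   0--255) and `metadata` (path, width, height).
#' @seealso [score_image()] for the full scoring pipeline.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(1, dim = c(2, 2, 3)), f)   # all-white 2x2
#' img <- load_image(f)
#' dim(img$pixels)
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_config("load_image() takes a single file path")
  }
  if (!file.exists(path)) {
    stop_input("cannot read image: no such file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      tif = ,
      tiff = tiff::readTIFF(path),
      png = png::readPNG(path),
      stop_input("unsupported image format '.", ext, "' (need TIFF or PNG): ", path)
    ),
    riceval_input_error = function(e) stop(e),
    error = function(e) {
      stop_input("unreadable image file '", path, "': ", conditionMessage(e))
    }
  )
  if (length(dim(arr)) == 2L || (length(dim(arr)) == 3L && dim(arr)[3] == 1L)) {
    stop_input("grayscale image rejected (3 RGB channels required): ", path)
  }
  if (dim(arr)[3] == 4L) {
    stop_input("image with alpha channel rejected (3 RGB channels required): ", path)
  }
  if (dim(arr)[3] != 3L) {
    stop_input("expected 3 colour channels, found ", dim(arr)[3], ": ", path)
  }
  new_rice_image(round(arr * 255),
    metadata = list(path = path, width = dim(arr)[2], height = dim(arr)[1])
  )
}

new_rice_image <- function(pixels, metadata = list()) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            all(pixels >= 0), all(pixels <= 255))
  structure(list(pixels = pixels, metadata = metadata), class = "rice_image")
}

#' Save a rice image to PNG or TIFF
#'
#' @param img A `rice_image`.
#' @param path Output path; format chosen from the extension (`.png`,
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "rice_image"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop_config("unsupported output format '.", ext, "'")
  )
  invisible(path)
}

#' @export
print.rice_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rice_image> %d x %d pixels (RGB, 0-255)\n", d[2], d[1]))
  invisible(x)
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone conversion with hue on the unit circle `[0, 1)` and red at
#' 0 (so pure yellow sits at 1/6 ~ 0.167). Achromatic pixels (max = min
#' channel) get hue 0 and saturation 0; this matters for the yellow-area rule,
#' see [yellow_mask()].
#'
#' @param img A `rice_image`.
#' @return An `hsv_image`: list of `h`, `s`, `v` matrices (same H x W as the
#'   source), each in `[0, 1]`.
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(inherits(img, "rice_image"))
  d <- dim(img$pixels)
  m <- rbind(
    as.vector(img$pixels[, , 1]),
    as.vector(img$pixels[, , 2]),
    as.vector(img$pixels[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  shape <- function(row) matrix(hsv[row, ], nrow = d[1], ncol = d[2])
  structure(
    list(h = shape(1), s = shape(2), v = shape(3), metadata = img$metadata),
    class = "hsv_image"
  )
}

#' Classify yellow pixels by hue threshold
#'
#' A pixel belongs to the yellow class when its hue is strictly below
#' `hue_threshold` (default 0.167, i.e. the red-through-yellow sector up to
#' 60 degrees). Optionally a saturation gate excludes near-achromatic pixels:
#' with the gate set, a pixel must also have saturation at or above
#' `saturation_gate` to count as yellow. The gate is disabled by default to
#' stay faithful to the original binarization rule, under which achromatic
#' pixels (hue defined as 0) classify as yellow; enabling it is the documented
#' guard against glossy-white highlights inflating the yellow class.
#'
#' @param hsv An `hsv_image` from [rgb_to_hsv()].
#' @param hue_threshold Hue cut in `(0, 1)`; default 0.167.
#' @param saturation_gate `NULL` (disabled, default) or a value in `[0, 1]`.
#' @return A `yellow_mask`: list with logical `mask` (H x W), counts
#'   `n_yellow`, `n_total`, and the thresholds used.
#' @export
yellow_mask <- function(hsv, hue_threshold = 0.167, saturation_gate = NULL) {
  stopifnot(inherits(hsv, "hsv_image"))
  if (!is.numeric(hue_threshold) || length(hue_threshold) != 1L ||
      hue_threshold <= 0 || hue_threshold >= 1) {
    stop_config("hue_threshold must be a single number in (0, 1), got ",
                format(hue_threshold))
  }
  if (!is.null(saturation_gate) &&
      (!is.numeric(saturation_gate) || length(saturation_gate) != 1L ||
       saturation_gate < 0 || saturation_gate > 1)) {
    stop_config("saturation_gate must be NULL or a single number in [0, 1]")
  }
  mask <- hsv$h < hue_threshold
  if (!is.null(saturation_gate)) {
    mask <- mask & (hsv$s >= saturation_gate)
  }
  structure(
    list(
      mask = mask,
      n_yellow = sum(mask),
      n_total = length(mask),
      hue_threshold = hue_threshold,
      saturation_gate = saturation_gate
    ),
    class = "yellow_mask"
  )
}

#' Yellow-area percentage of a classified image
#'
#' The appearance proxy: `100 * n_yellow / n_total`. Lower values mean whiter,
#' better-looking cooked rice.
#'
#' @param mask A `yellow_mask`.
#' @return Percentage in `[0, 100]`.
#' @export
yellow_area_percent <- function(mask) {
  stopifnot(inherits(mask, "yellow_mask"))
  if (mask$n_total == 0L) stop_input("empty mask: image has no pixels")
  100 * mask$n_yellow / mask$n_total
}

#' Score a cooked-rice image
#'
#' Composes [load_image()], [rgb_to_hsv()], [yellow_mask()] and
#' [yellow_area_percent()] into a single deterministic call, returning one
#' tidy row per image.
#'
#' @param path Image file path (TIFF or PNG), or a `rice_image` already in
#'   memory.
#' @param hue_threshold,saturation_gate Passed to [yellow_mask()].
#' @param roi Optional region of interest `c(row1, row2, col1, col2)`
#'   (1-based, inclusive) to crop before scoring, for frames that include
#'   container edges. Default scores the whole frame.
#' @return One-row tibble: `path`, `n_total`, `n_yellow`,
#'   `yellow_area_percent`, `hue_threshold`, `saturation_gate`.
#' @export
#' @examples
#' sim <- simulate_rice_image(width = 64, height = 48, yellow_fraction = 0.25,
#'                            seed = 1)
#' score_image(sim$image)
score_image <- function(path, hue_threshold = 0.167, saturation_gate = NULL,
                        roi = NULL) {
  img <- if (inherits(path, "rice_image")) path else load_image(path)
  if (!is.null(roi)) {
    if (length(roi) != 4L) stop_config("roi must be c(row1, row2, col1, col2)")
    d <- dim(img$pixels)
    if (roi[1] < 1 || roi[3] < 1 || roi[2] > d[1] || roi[4] > d[2] ||
        roi[1] > roi[2] || roi[3] > roi[4]) {
      stop_config("roi out of bounds for a ", d[1], " x ", d[2], " image")
    }
    img <- new_rice_image(img$pixels[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE],
                          metadata = img$metadata)
  }
  m <- yellow_mask(rgb_to_hsv(img), hue_threshold, saturation_gate)
  tibble(
    path = img$metadata$path %||% NA_character_,
    n_total = m$n_total,
    n_yellow = m$n_yellow,
    yellow_area_percent = yellow_area_percent(m),
    hue_threshold = hue_threshold,
    saturation_gate = saturation_gate %||% NA_real_
  )
}

#' Score a batch of cooked-rice images
#'
#' One row per image; use [summarise_samples()] (or the `score-image` CLI
#' subcommand) to average the protocol's repeat images per sample.
#'
#' @param paths Character vector of image paths or list of `rice_image`s.
#' @param sample Optional vector of sample identifiers, recycled against
#'   `paths`; defaults to one sample per image.
#' @inheritParams score_image
#' @return Tibble with a `sample` column plus the [score_image()] columns.
#' @export
score_images <- function(paths, sample = NULL, hue_threshold = 0.167,
                         saturation_gate = NULL, roi = NULL) {
  if (inherits(paths, "rice_image")) paths <- list(paths)
  n <- length(paths)
  if (n == 0L) stop_input("no images supplied")
  sample <- sample %||% as.character(seq_len(n))
  sample <- rep_len(as.character(sample), n)
  rows <- purrr::map(seq_len(n), function(i) {
    p <- if (is.list(paths)) paths[[i]] else paths[[i]]
    dplyr::mutate(
      score_image(p, hue_threshold, saturation_gate, roi),
      sample = sample[i], .before = 1
    )
  })
  dplyr::bind_rows(rows)
}

#' Average image scores per sample
#'
#' The imaging protocol photographs each sample four times; this collapses
#' per-image yellow-area scores to per-sample means.
#'
#' @param scores Output of [score_images()].
#' @return Tibble with one row per sample: `sample`, `n_images`,
#'   `yellow_area_percent` (mean).
#' @export
summarise_samples <- function(scores) {
  stopifnot(is.data.frame(scores), "sample" %in% names(scores))
  scores |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      yellow_area_percent = mean(.data$yellow_area_percent),
      .groups = "drop"
    )
}
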
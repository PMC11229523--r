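#' Preprocessing configuration
#'
#' Collects every tunable knob of the image pipeline that turns a raw fruit
#' photograph into a filled binary silhouette.  Defaults are tuned on the
#' package's synthetic fixtures (a dark prickly fruit on a light backdrop with
#' a cast shadow); all of them are plain numbers a user can override.
#'
#' @param saturation_gain Multiplicative gain applied to HSV saturation (> 0).
#' @param contrast_gain Multiplicative contrast stretch about the image mean
#'   (> 0; 1 leaves the image unchanged).
#' @param median_kernel Odd window size (>= 3) of the median filter used for
#'   de-pricking and salt-noise removal.  Default 5 (a 5 x 5 window).
#' @param gray_threshold Gray level in `[0, 255]` separating fruit from
#'   background and shadow.
#' @param dark_foreground If `TRUE` (default) pixels strictly darker than
#'   `gray_threshold` are foreground; if `FALSE`, strictly brighter.
#' @param canny_low,canny_high Hysteresis thresholds on the Sobel gradient
#'   magnitude (`canny_low < canny_high`).
#' @param kmeans_k Number of color clusters for K-means segmentation (>= 2).
#' @param kmeans_seed Fixed RNG seed used by K-means (reproducibility).
#' @param hsv_hue_range Closed hue interval in degrees `[0, 360]`; a range with
#'   `lo > hi` wraps around 360.
#' @param hsv_sat_range Closed saturation interval in `[0, 1]`.
#' @param segment_method One of `"gray"` (threshold the luminance directly),
#'   `"hsv"` or `"kmeans"` (color segmentation before de-shading).
#' @param gap_tolerance Maximum boundary gap (px) bridged by morphological
#'   closing before hole filling.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(saturation_gain = 1.4,
                              contrast_gain = 1.2,
                              median_kernel = 5L,
                              gray_threshold = 160L,
                              dark_foreground = TRUE,
                              canny_low = 50,
                              canny_high = 150,
                              kmeans_k = 3L,
                              kmeans_seed = 0L,
                              hsv_hue_range = c(330, 40),
                              hsv_sat_range = c(0.25, 1),
                              segment_method = c("gray", "hsv", "kmeans"),
                              gap_tolerance = 5L) {
  segment_method <- match.arg(segment_method)
  if (!is.numeric(saturation_gain) || saturation_gain <= 0 ||
      !is.numeric(contrast_gain) || contrast_gain <= 0)
    abort("saturation_gain and contrast_gain must be > 0", "invalid_config")
  if (!is_count(median_kernel) || median_kernel < 3 || median_kernel %% 2 == 0)
    abort("median_kernel must be an odd integer >= 3", "invalid_config")
  if (gray_threshold < 0 || gray_threshold > 255)
    abort("gray_threshold must lie in [0, 255]", "invalid_config")
  if (!(canny_low < canny_high))
    abort("canny_low must be < canny_high", "invalid_config")
  if (!is_count(kmeans_k) || kmeans_k < 2)
    abort("kmeans_k must be an integer >= 2", "invalid_config")
  if (length(hsv_hue_range) != 2 || any(hsv_hue_range < 0) || any(hsv_hue_range > 360))
    abort("hsv_hue_range must be two values in [0, 360]", "invalid_config")
  if (length(hsv_sat_range) != 2 || hsv_sat_range[1] > hsv_sat_range[2] ||
      any(hsv_sat_range < 0) || any(hsv_sat_range > 1))
    abort("hsv_sat_range must be an ordered interval within [0, 1]", "invalid_config")
  if (!is_count(gap_tolerance) || gap_tolerance < 1)
    abort("gap_tolerance must be a positive integer", "invalid_config")
  structure(list(
    saturation_gain = saturation_gain, contrast_gain = contrast_gain,
    median_kernel = as.integer(median_kernel),
    gray_threshold = gray_threshold, dark_foreground = isTRUE(dark_foreground),
    canny_low = canny_low, canny_high = canny_high,
    kmeans_k = as.integer(kmeans_k), kmeans_seed = as.integer(kmeans_seed),
    hsv_hue_range = as.numeric(hsv_hue_range),
    hsv_sat_range = as.numeric(hsv_sat_range),
    segment_method = segment_method,
    gap_tolerance = as.integer(gap_tolerance)
  ), class = "preprocess_config")
}

#' Read a preprocessing configuration from JSON or key=value text
#'
#' @param path File with either a JSON object or `key = value` lines; keys are
#'   the arguments of [preprocess_config()].
#' @return A `"preprocess_config"` object.
#' @export
read_preprocess_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path), "io_error")
  txt <- readLines(path, warn = FALSE)
  vals <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
    kv <- strsplit(txt, "=")
    out <- lapply(kv, function(p) {
      v <- trimws(p[2])
      v <- strsplit(v, ",")[[1]]
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        if (all(v %in% c("TRUE", "FALSE", "true", "false"))) as.logical(toupper(v)) else v
      } else num
    })
    names(out) <- trimws(vapply(kv, `[`, "", 1))
    out
  }
  do.call(preprocess_config, vals)
}

#' Adjust saturation and contrast of a color image
#'
#' Increases the color difference between fruit and background ahead of
#' segmentation.  Saturation is scaled multiplicatively in HSV space (clipped
#' to 1); contrast is an affine stretch about the global image mean, clipped
#' to `[0, 255]`.  Gains of exactly 1 leave the image untouched.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param cfg A [preprocess_config()].
#' @return Adjusted image of the same dimensions.
#' @export
adjust_color <- function(img, cfg = preprocess_config()) {
  assert_color_image(img)
  if (cfg$saturation_gain <= 0 || cfg$contrast_gain <= 0)
    abort("color gains must be > 0", "invalid_config")
  out <- img
  if (cfg$saturation_gain != 1) {
    d <- dim(out)
    hsv <- grDevices::rgb2hsv(
      r = as.vector(out[, , 1]), g = as.vector(out[, , 2]),
      b = as.vector(out[, , 3]), maxColorValue = 255
    )
    hsv["s", ] <- pmin(hsv["s", ] * cfg$saturation_gain, 1)
    hex <- grDevices::hsv(hsv["h", ], hsv["s", ], hsv["v", ])
    rgb <- grDevices::col2rgb(hex)
    out <- array(0, d)
    out[, , 1] <- matrix(rgb["red", ], d[1], d[2])
    out[, , 2] <- matrix(rgb["green", ], d[1], d[2])
    out[, , 3] <- matrix(rgb["blue", ], d[1], d[2])
  }
  if (cfg$contrast_gain != 1) {
    m <- mean(out)
    out <- clip((out - m) * cfg$contrast_gain + m, 0, 255)
  }
  out
}

#' Median filter (de-pricking / denoising)
#'
#' Sliding-window median with replicate border policy: prickles and salt
#' specks narrower than half the window vanish while the smooth fruit body is
#' preserved.
#'
#' @param img Grayscale `H x W` matrix in `[0, 255]`.
#' @param kernel Odd window size, `3 <= kernel <= min(H, W)`.
#' @return Filtered grayscale matrix.
#' @export
median_filter <- function(img, kernel = 5L) {
  assert_gray_image(img)
  if (!is_count(kernel) || kernel %% 2 == 0 || kernel < 3)
    abort("kernel must be an odd integer >= 3", "invalid_config")
  if (kernel > min(dim(img)))
    abort("kernel exceeds image dimensions", "invalid_config")
  out <- EBImage::medianFilter(img / 255, (kernel - 1L) / 2L) * 255
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Gray-level thresholding (de-shading)
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param t Threshold in `[0, 255]`.
#' @param dark_foreground If `TRUE`, foreground pixels are strictly darker
#'   than `t` (dark fruit on a light backdrop); if `FALSE`, strictly brighter.
#' @return Binary 0/1 mask of the same dimensions.
#' @export
gray_threshold <- function(img, t, dark_foreground = TRUE) {
  assert_gray_image(img)
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 255)
    abort("threshold t must lie in [0, 255]", "invalid_config")
  if (dark_foreground) as_mask(img < t) else as_mask(img > t)
}

# Sobel gradients with replicate border; returns list(gx, gy).
sobel <- function(img) {
  H <- nrow(img); W <- ncol(img)
  up    <- img[c(1, seq_len(H - 1)), , drop = FALSE]
  down  <- img[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  shl <- function(m) m[, c(seq_len(W - 1) + 1, W), drop = FALSE]  # pixel to the right
  shr <- function(m) m[, c(1, seq_len(W - 1)), drop = FALSE]      # pixel to the left
  gx <- (shl(up) + 2 * shl(img) + shl(down)) - (shr(up) + 2 * shr(img) + shr(down))
  gy <- (shr(down) + 2 * down + shl(down)) - (shr(up) + 2 * up + shl(up))
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, and hysteresis thresholding (weak edges are kept only when
#' 8-connected to a strong edge).  Edges come out as thin (<= 2 px) curves; a
#' constant image yields an empty edge map.
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param low,high Hysteresis thresholds on gradient magnitude, `low < high`.
#' @return Binary 0/1 edge mask.
#' @export
canny_edges <- function(img, low = 50, high = 150) {
  assert_gray_image(img)
  if (!(low < high)) abort("canny low must be < high", "invalid_config")
  H <- nrow(img); W <- ncol(img)
  g <- sobel(img)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(0L, H, W))
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ang %% 180
  # quantize to 0 (E-W), 45, 90 (N-S), 135 degrees
  sector <- integer(length(ang))
  sector[(ang < 22.5) | (ang >= 157.5)] <- 0L
  sector[ang >= 22.5  & ang < 67.5]  <- 45L
  sector[ang >= 67.5  & ang < 112.5] <- 90L
  sector[ang >= 112.5 & ang < 157.5] <- 135L
  sector <- matrix(sector, H, W)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mag
  ipad <- matrix(0, H + 2, W + 2)
  ipad[2:(H + 1), 2:(W + 1)] <- img
  shift <- function(p, di, dj) p[2:(H + 1) + di, 2:(W + 1) + dj]
  # Non-maximum suppression along the quantized gradient direction.  A binary
  # step yields a tied magnitude pair; the tie is broken toward the brighter
  # pixel so the edge sits on the object side of the step regardless of the
  # step's orientation (keeps edges 1 px thin and rotation-equivariant).
  nms_dir <- function(di, dj) {
    n1 <- shift(pad, di, dj); n2 <- shift(pad, -di, -dj)
    i1 <- shift(ipad, di, dj); i2 <- shift(ipad, -di, -dj)
    (mag >= n1 & mag >= n2) &
      !(mag == n1 & img < i1) & !(mag == n2 & img < i2)
  }
  keep <- (sector == 0L   & nms_dir(0, 1)) |
          (sector == 45L  & nms_dir(1, 1)) |
          (sector == 90L  & nms_dir(1, 0)) |
          (sector == 135L & nms_dir(1, -1))
  nms <- mag * keep
  strong <- nms >= high
  weak <- nms >= low
  if (!any(strong)) return(matrix(0L, H, W))
  # hysteresis: grow strong edges through weak pixels (8-connectivity)
  brush <- matrix(1, 3, 3)
  cur <- strong
  repeat {
    grown <- EBImage::dilate(cur * 1, brush) > 0
    nxt <- weak & grown
    if (sum(nxt) == sum(cur)) break
    cur <- nxt
  }
  as_mask(cur)
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(mask * 0L)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  as_mask(lab == which.max(sizes))
}

#' Trace and fill a closed boundary
#'
#' Bridges boundary gaps up to `gap_tolerance` pixels with morphological
#' closing, fills interior holes, and keeps the largest connected foreground
#' component, returning a filled, simply connected silhouette.  Already-filled
#' masks pass through (up to boundary smoothing).
#'
#' @param edges Binary edge/outline mask (e.g. from [canny_edges()]).
#' @param gap_tolerance Largest boundary gap (px) to bridge.
#' @return Filled binary 0/1 mask with exactly one foreground component.
#' @export
trace_and_fill <- function(edges, gap_tolerance = 5L) {
  assert_binary_mask(edges)
  if (sum(edges) == 0)
    abort("no closed boundary recoverable: edge map is empty", "empty_contour")
  # dilate -> fill -> erode: the dilation bridges boundary gaps up to
  # gap_tolerance px, hole filling happens while the bridge is solid, and the
  # erosion restores the boundary position (a plain morphological closing can
  # re-open a thin bridge before the interior is filled)
  bsize <- gap_tolerance + 2L
  if (bsize %% 2 == 0) bsize <- bsize + 1L
  brush <- EBImage::makeBrush(max(3L, bsize), shape = "disc")
  closed <- as_mask(EBImage::dilate(edges, brush))
  filled <- as_mask(EBImage::erode(EBImage::fillHull(closed), brush))
  filled <- largest_component(filled)
  interior <- filled & !closed
  if (sum(interior) == 0 && sum(filled) < 4 * (nrow(edges) + ncol(edges)))
    abort("no closed boundary recoverable from the edge map", "empty_contour")
  # opening removes thin protrusions (residual prickle stubs, bridge
  # artifacts) while leaving the smooth silhouette essentially unchanged
  opened <- largest_component(as_mask(EBImage::opening(filled, brush)))
  if (sum(opened) > 0) opened else filled
}

finish_mask <- function(mask) {
  mask <- largest_component(mask)
  if (sum(mask) == 0)
    abort("segmentation produced an empty mask", "empty_segmentation")
  as_mask(EBImage::fillHull(mask))
}

#' HSV color segmentation
#'
#' Marks pixels whose hue and saturation fall inside the configured intervals
#' (hue wraps at 360 when the interval is given with `lo > hi`), then keeps
#' the largest connected component and fills holes.  Cast shadows are nearly
#' gray (saturation ~ 0), so a saturation lower bound above the shadow's
#' saturation excludes them.
#'
#' @param img Color image array in `[0, 255]`.
#' @param cfg A [preprocess_config()]; uses `hsv_hue_range`, `hsv_sat_range`.
#' @return Binary 0/1 mask.
#' @export
hsv_segment <- function(img, cfg = preprocess_config()) {
  assert_color_image(img)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]), maxColorValue = 255
  )
  hue <- hsv["h", ] * 360
  sat <- hsv["s", ]
  hr <- cfg$hsv_hue_range
  hue_ok <- if (hr[1] <= hr[2]) hue >= hr[1] & hue <= hr[2]
            else hue >= hr[1] | hue <= hr[2]
  sel <- hue_ok & sat >= cfg$hsv_sat_range[1] & sat <= cfg$hsv_sat_range[2]
  mask <- matrix(as.integer(sel), nrow(img), ncol(img))
  if (sum(mask) == 0)
    abort("HSV segmentation selected no pixels", "empty_segmentation")
  finish_mask(mask)
}

#' K-means color segmentation
#'
#' Clusters pixel colors with K-means (fixed seed; pixels are presented to the
#' clusterer in a canonical sorted order, so results are reproducible and
#' equivariant under image rotation).  The background cluster is the majority
#' cluster along the image border; among the remaining clusters the fruit is
#' the one whose largest connected component covers the image center (nearest
#' centroid on ties).  The chosen component is hole-filled as in
#' [hsv_segment()].
#'
#' @param img Color image array in `[0, 255]`.
#' @param k Number of clusters (>= 2).
#' @param seed RNG seed for K-means.
#' @return Binary 0/1 mask.
#' @export
kmeans_segment <- function(img, k = 3L, seed = 0L) {
  assert_color_image(img)
  if (!is_count(k) || k < 2) abort("k must be an integer >= 2", "invalid_config")
  H <- nrow(img); W <- ncol(img)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  ux <- unique(px)
  if (nrow(ux) < k)
    abort(sprintf("image has %d distinct colors; cannot form %d clusters",
                  nrow(ux), k), "empty_segmentation")
  ord <- order(px[, 1], px[, 2], px[, 3])
  fit <- with_local_seed(seed,
    stats::kmeans(px[ord, , drop = FALSE], centers = k, nstart = 5, iter.max = 100))
  labels <- integer(nrow(px))
  labels[ord] <- fit$cluster
  lab_m <- matrix(labels, H, W)
  border <- c(lab_m[1, ], lab_m[H, ], lab_m[, 1], lab_m[, W])
  bg <- as.integer(names(which.max(table(border))))
  center <- c(round(H / 2), round(W / 2))
  best <- NULL; best_size <- -1; best_dist <- Inf
  for (cl in setdiff(seq_len(k), bg)) {
    comp <- largest_component(as_mask(lab_m == cl))
    size <- sum(comp)
    if (size == 0) next
    fg <- which(comp == 1, arr.ind = TRUE)
    covers <- comp[center[1], center[2]] == 1
    dist <- sqrt(sum((colMeans(fg) - center)^2))
    better <- if (covers && best_dist > 0) TRUE
              else if (!covers && best_dist == 0) FALSE
              else size > best_size
    if (better) {
      best <- comp; best_size <- size
      best_dist <- if (covers) 0 else dist
    }
  }
  if (is.null(best))
    abort("K-means found no non-background cluster", "empty_segmentation")
  finish_mask(best)
}

#' Full preprocessing pipeline: photograph to filled silhouette
#'
#' Composition of the pipeline stages: color adjustment, optional HSV/K-means
#' color segmentation, gray-level de-shading, median de-pricking, Canny edge
#' detection, and boundary fill.  Errors raised by a stage are re-signalled
#' with the stage name attached.
#'
#' @param img Color image array in `[0, 255]`.
#' @param cfg A [preprocess_config()].
#' @param verbose If `TRUE`, message per-stage foreground pixel counts.
#' @return Filled binary 0/1 mask with one foreground component.
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config(), verbose = FALSE) {
  assert_color_image(img)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  note <- function(name, m) {
    if (verbose) message(sprintf("%-12s foreground: %d", name, sum(m)))
    m
  }
  adj <- stage("adjust_color", adjust_color(img, cfg))
  gray <- switch(cfg$segment_method,
    gray = luminance(adj),
    hsv = {
      m <- stage("hsv_segment", hsv_segment(adj, cfg))
      note("hsv_segment", m)
      (1 - m) * 255    # foreground dark, so the de-shading threshold applies
    },
    kmeans = {
      m <- stage("kmeans_segment",
                 kmeans_segment(adj, cfg$kmeans_k, cfg$kmeans_seed))
      note("kmeans_segment", m)
      (1 - m) * 255
    }
  )
  m1 <- stage("gray_threshold",
              gray_threshold(gray, cfg$gray_threshold, cfg$dark_foreground))
  note("gray_threshold", m1)
  g2 <- stage("median_filter", median_filter(m1 * 255, cfg$median_kernel))
  md <- note("median_filter", as_mask(g2 > 127))
  ed <- stage("canny_edges", canny_edges(g2, cfg$canny_low, cfg$canny_high))
  note("canny_edges", ed)
  filled <- stage("trace_and_fill", trace_and_fill(ed, cfg$gap_tolerance))
  # The traced contour contributes component selection, gap bridging, hole
  # filling and de-pricking; the boundary itself is localized by intersecting
  # back with the de-shaded mask, whose step position is pixel-exact (an edge
  # pixel may sit on either side of the intensity step).
  out <- as_mask(filled == 1 & md == 1)
  out <- as_mask(EBImage::fillHull(largest_component(out)))
  if (sum(out) == 0)
    stop("[trace_and_fill] contour does not overlap the de-shaded mask",
         call. = FALSE)
  note("silhouette", out)
  out
}
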
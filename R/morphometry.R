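#' Camera calibration
#'
#' Pixel-to-physical-unit ratios for length and area.  The two ratios must be
#' self-consistent: `mm2_per_px` within 5% of `mm_per_px^2`.
#'
#' @param mm_per_px Millimetres per pixel (> 0).
#' @param mm2_per_px Square millimetres per pixel (> 0); defaults to
#'   `mm_per_px^2`.
#' @return An object of class `"camera_calibration"`.
#' @export
camera_calibration <- function(mm_per_px, mm2_per_px = mm_per_px^2) {
  if (!is.numeric(mm_per_px) || mm_per_px <= 0 ||
      !is.numeric(mm2_per_px) || mm2_per_px <= 0)
    abort("calibration ratios must be positive numbers", "invalid_calibration")
  if (abs(mm2_per_px - mm_per_px^2) / mm_per_px^2 >= 0.05)
    abort("length and area calibration ratios are inconsistent (> 5%)",
          "invalid_calibration")
  structure(list(mm_per_px = mm_per_px, mm2_per_px = mm2_per_px),
            class = "camera_calibration")
}

#' Reference bench calibration
#'
#' The calibration constants of the reference imaging bench this package's
#' bundled Rosa roxburghii models were built on: 0.126 mm per pixel and
#' 0.016 mm^2 per pixel (the printed ratios satisfy 0.126^2 ~ 0.0159 ~ 0.016).
#'
#' @return A `"camera_calibration"` object.
#' @export
reference_calibration <- function() camera_calibration(0.126, 0.016)

#' Read / write a camera calibration as JSON
#'
#' @param path JSON file with fields `mm_per_px` and `mm2_per_px`.
#' @param cal A `"camera_calibration"` object.
#' @return `read_calibration()` returns the validated calibration;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("calibration file not found: %s", path), "io_error")
  v <- jsonlite::fromJSON(path)
  if (is.null(v$mm_per_px)) abort("calibration JSON lacks mm_per_px", "invalid_calibration")
  if (is.null(v$mm2_per_px)) camera_calibration(v$mm_per_px)
  else camera_calibration(v$mm_per_px, v$mm2_per_px)
}

#' @rdname read_calibration
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "camera_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count foreground pixels
#'
#' @param mask Binary 0/1 mask.
#' @return Number of 1-pixels.
#' @export
count_foreground <- function(mask) {
  assert_binary_mask(mask)
  sum(mask == 1)
}

#' Convert a pixel count to an area in cm^2
#'
#' @param count Foreground pixel count (>= 0).
#' @param cal A [camera_calibration()].
#' @return Area in cm^2 (`count * mm2_per_px / 100`).
#' @export
area_cm2 <- function(count, cal) {
  stopifnot(inherits(cal, "camera_calibration"))
  if (!is.numeric(count) || any(count < 0)) abort("count must be >= 0", "domain_error")
  count * cal$mm2_per_px / 100
}

#' Longest horizontal foreground chord
#'
#' Scans every row of the mask for its longest contiguous run of foreground
#' pixels and returns the maximum over rows (ties resolved by the topmost
#' row, which does not affect the returned length).
#'
#' @param mask Non-empty binary 0/1 mask.
#' @return Chord length in pixels.
#' @export
max_chord <- function(mask) {
  assert_binary_mask(mask)
  if (sum(mask) == 0) abort("mask is empty", "empty_mask")
  run <- numeric(nrow(mask))
  best <- run
  for (j in seq_len(ncol(mask))) {
    run <- (run + 1) * mask[, j]
    best <- pmax(best, run)
  }
  max(best)
}

#' Rotate a binary mask about its centroid
#'
#' Nearest-neighbor resampling with the output canvas expanded so that no
#' foreground pixel is clipped.  Coordinates are row-major with origin at the
#' top-left; positive angles rotate counter-clockwise in the usual x = column,
#' y = up convention.
#'
#' @param mask Binary 0/1 mask.
#' @param angle_deg Rotation angle in degrees.
#' @return Rotated binary mask (possibly with different dimensions).
#' @export
rotate_mask <- function(mask, angle_deg) {
  assert_binary_mask(mask)
  if (angle_deg %% 360 == 0) return(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) return(mask)
  th <- angle_deg * pi / 180
  # centroid in (x = col, y = row) coordinates
  cx <- mean(fg[, 2]); cy <- mean(fg[, 1])
  # forward-rotate the foreground bounding box corners to size the canvas
  bb <- expand.grid(x = range(fg[, 2]), y = range(fg[, 1]))
  xr <- cos(th) * (bb$x - cx) + sin(th) * (bb$y - cy)
  yr <- -sin(th) * (bb$x - cx) + cos(th) * (bb$y - cy)
  pad <- 2
  W2 <- ceiling(diff(range(xr))) + 2 * pad + 1
  H2 <- ceiling(diff(range(yr))) + 2 * pad + 1
  cx2 <- -min(xr) + pad + 1; cy2 <- -min(yr) + pad + 1
  # inverse-map each output pixel to a source pixel
  xo <- rep(seq_len(W2), each = H2) - cx2
  yo <- rep(seq_len(H2), times = W2) - cy2
  xs <- round(cos(th) * xo - sin(th) * yo + cx)
  ys <- round(sin(th) * xo + cos(th) * yo + cy)
  ok <- xs >= 1 & xs <= ncol(mask) & ys >= 1 & ys <= nrow(mask)
  out <- matrix(0L, H2, W2)
  out[ok] <- mask[cbind(ys[ok], xs[ok])]
  out
}

#' Rotation-scan measurement of the fruit's long and short axes
#'
#' Rotates the silhouette over `[0, 180)` degrees in steps of `step_deg`; at
#' each pose the longest horizontal chord is measured.  The maximum over all
#' poses is the long-axis pixel chord `L1`, the minimum the short-axis chord
#' `L3`, and the half axes are `a = L1 * mm_per_px / 2`,
#' `b = L3 * mm_per_px / 2` (ties in the maximizing angle go to the first
#' attaining angle).  The measurement is invariant to the fruit's pose in the
#' photograph, which is the point of the method.
#'
#' @param mask Non-empty binary 0/1 mask (single filled component).
#' @param cal A [camera_calibration()].
#' @param step_deg Rotation step in degrees; must divide 180 evenly.
#' @return An object of class `"axis_measurement"`: list with `L1`, `L3`
#'   (pixel chords), `a`, `b` (half axes, mm), `theta_at_max` (deg).
#' @export
measure_axes <- function(mask, cal, step_deg = 1) {
  assert_binary_mask(mask)
  stopifnot(inherits(cal, "camera_calibration"))
  if (sum(mask) == 0) abort("mask is empty", "empty_mask")
  if (step_deg <= 0 || abs(180 / step_deg - round(180 / step_deg)) > 1e-9)
    abort("step_deg must divide 180 evenly", "invalid_config")
  angles <- seq(0, 180 - step_deg, by = step_deg)
  chords <- vapply(angles, function(a) max_chord(rotate_mask(mask, a)), numeric(1))
  i_max <- which.max(chords)
  L1 <- chords[i_max]
  L3 <- min(chords)
  structure(list(
    L1 = L1, L3 = L3,
    a = L1 * cal$mm_per_px / 2,
    b = L3 * cal$mm_per_px / 2,
    theta_at_max = angles[i_max]
  ), class = "axis_measurement")
}

#' Criterion projected area
#'
#' Arithmetic mean of the three mutually perpendicular projected areas.
#'
#' @param pa1,pa2,pa3 Projected areas in cm^2 (>= 0).
#' @return CPA in cm^2.
#' @export
compute_cpa <- function(pa1, pa2, pa3) {
  if (any(c(pa1, pa2, pa3) < 0)) abort("projected areas must be >= 0", "domain_error")
  (pa1 + pa2 + pa3) / 3
}

#' Slice-and-integrate reference area
#'
#' Reference area of a sliced outline: the sum of circular-sector areas
#' `delta_theta * pi * r^2 / 360` around a closed profile.  Used as the
#' independent bench oracle against which pixel-count areas are validated.
#'
#' @param delta_theta Step angles in degrees (> 0, summing to 360).
#' @param r Radii at each step (same length and units of choice).
#' @return Area in squared units of `r`.
#' @export
slice_integrate_area <- function(delta_theta, r) {
  if (length(delta_theta) != length(r))
    abort("delta_theta and r must have equal length", "domain_error")
  if (any(delta_theta <= 0)) abort("all step angles must be > 0", "domain_error")
  if (abs(sum(delta_theta) - 360) > 1e-9)
    abort("profile is not closed: step angles must sum to 360", "open_profile")
  sum(delta_theta * pi * r^2 / 360)
}

#' Mean relative error (percent)
#'
#' `mean(|pv - mv| / mv) * 100` between image measurements `pv` and reference
#' measurements `mv`.
#'
#' @param pv Image-derived measurements.
#' @param mv Reference measurements (> 0), same length.
#' @return MRE in percent.
#' @export
mean_relative_error <- function(pv, mv) {
  if (length(pv) != length(mv) || length(pv) < 1)
    abort("pv and mv must have equal length >= 1", "domain_error")
  if (any(mv <= 0)) abort("reference measurements must be > 0", "domain_error")
  mean(abs(pv - mv) / mv) * 100
}

#' Geometric volume approximations
#'
#' Volume of the fruit idealized as an ellipsoid of revolution about its short
#' axis (`4 pi a^2 b / 3`) or as a paraboloid-like solid (`4 pi a b^2 / 3`).
#' With the half axes in cm the volumes come out in cm^3 = ml.  Their ratio is
#' always `Vparab / Vellip = b / a`.
#'
#' @param a,b Half-long and half-short axes in cm (> 0).
#' @return Volume in ml.
#' @export
ellipsoid_volume <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) abort("axes must be > 0", "domain_error")
  4 * pi * a^2 * b / 3
}

#' @rdname ellipsoid_volume
#' @export
paraboloid_volume <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) abort("axes must be > 0", "domain_error")
  4 * pi * a * b^2 / 3
}

#' Measure one fruit from its three orthogonal views
#'
#' Computes the three projected areas (X-side, Y-side, Z-top) from foreground
#' pixel counts, the criterion projected area, and the half axes from a joint
#' rotation scan over all three views: `L1` is the global maximum chord and
#' `L3` the global minimum of the per-view short chords, i.e. the most
#' significant half-long and half-short axes across the three view ellipses.
#' Geometric volumes use the axes converted mm to cm so they land in ml.
#'
#' @param mask_x,mask_y,mask_z Binary masks of the X-side, Y-side and Z-top
#'   views.
#' @param cal A [camera_calibration()].
#' @param step_deg Rotation-scan step in degrees.
#' @param id Optional fruit identifier stored in the record.
#' @return A one-row `data.frame` in the fruit-record schema (see
#'   [write_fruit_records()]), with `mass_g` and `volume_ml` set to `NA`.
#'   Per-view axis measurements are attached as attribute `"views"`.
#' @export
measure_fruit <- function(mask_x, mask_y, mask_z, cal, step_deg = 1, id = 1L) {
  views <- list(x = mask_x, y = mask_y, z = mask_z)
  for (v in names(views)) {
    assert_binary_mask(views[[v]], arg = paste0("mask_", v))
    if (sum(views[[v]]) == 0)
      abort(sprintf("view '%s' has an empty mask", v), "empty_mask")
  }
  pa <- vapply(views, function(m) area_cm2(count_foreground(m), cal), numeric(1))
  ax <- lapply(views, measure_axes, cal = cal, step_deg = step_deg)
  L1 <- max(vapply(ax, `[[`, numeric(1), "L1"))
  L3 <- min(vapply(ax, `[[`, numeric(1), "L3"))
  a_mm <- L1 * cal$mm_per_px / 2
  b_mm <- L3 * cal$mm_per_px / 2
  rec <- data.frame(
    id = id,
    mass_g = NA_real_, volume_ml = NA_real_,
    a_mm = a_mm, b_mm = b_mm,
    pa1_cm2 = pa[["x"]], pa2_cm2 = pa[["y"]], pa3_cm2 = pa[["z"]],
    cpa_cm2 = compute_cpa(pa[["x"]], pa[["y"]], pa[["z"]]),
    v_ellip_ml = ellipsoid_volume(a_mm / 10, b_mm / 10),
    v_parab_ml = paraboloid_volume(a_mm / 10, b_mm / 10)
  )
  attr(rec, "views") <- ax
  rec
}

fruit_record_columns <- c(
  "id", "mass_g", "volume_ml", "a_mm", "b_mm",
  "pa1_cm2", "pa2_cm2", "pa3_cm2", "cpa_cm2", "v_ellip_ml", "v_parab_ml"
)

#' Read / write fruit-record tables as CSV
#'
#' The fruit-record schema has columns `id`, `mass_g`, `volume_ml`, `a_mm`,
#' `b_mm`, `pa1_cm2`, `pa2_cm2`, `pa3_cm2`, `cpa_cm2`, `v_ellip_ml`,
#' `v_parab_ml`; `mass_g` and `volume_ml` may be missing (NA) for fruits that
#' were only imaged, never weighed.
#'
#' @param records A data.frame in the fruit-record schema.
#' @param path CSV path.
#' @return `read_fruit_records()` returns the validated data.frame;
#'   `write_fruit_records()` returns `path` invisibly.
#' @export
write_fruit_records <- function(records, path) {
  miss <- setdiff(fruit_record_columns, names(records))
  if (length(miss))
    abort(paste("fruit-record table lacks columns:", paste(miss, collapse = ", ")),
          "schema_error")
  utils::write.csv(records[, fruit_record_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fruit_records
#' @export
read_fruit_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("records file not found: %s", path), "io_error")
  df <- utils::read.csv(path)
  miss <- setdiff(fruit_record_columns, names(df))
  if (length(miss))
    abort(paste("fruit-record CSV lacks columns:", paste(miss, collapse = ", ")),
          "schema_error")
  num <- setdiff(fruit_record_columns, "id")
  bad <- vapply(df[num], function(x) any(!is.na(x) & x <= 0), logical(1))
  if (any(bad))
    abort(paste("non-positive physical quantities in columns:",
                paste(num[bad], collapse = ", ")), "schema_error")
  df
}
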
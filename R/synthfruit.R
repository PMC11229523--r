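#' Specification of a rendered synthetic fruit image
#'
#' Describes one synthetic near-ellipsoidal fruit for rendering: an ellipse of
#' known semi-axes at an arbitrary in-plane pose, optionally decorated with
#' radial prickles, an offset desaturated shadow, and salt noise — the
#' nuisance structure the preprocessing pipeline must remove.  The rendered
#' ground truth (ellipse-only mask, analytic axes and area) travels with every
#' render, so downstream measurements can be checked exactly.
#'
#' @param a_px,b_px Semi-axes in pixels (`a_px >= b_px > 0`).
#' @param pose_deg In-plane rotation of the long axis, degrees CCW.
#' @param canvas `c(height, width)` in pixels; `NULL` sizes the canvas to fit
#'   the rotated ellipse, prickles and shadow with a margin.
#' @param center `c(row, col)` ellipse center; `NULL` centers it.
#' @param fruit_color,bg_color RGB triples in `[0, 255]`.
#' @param prickle_count Number of radial spikes.
#' @param prickle_len_px Spike length in px (<= 10 keeps them removable by a
#'   5 x 5 median filter).
#' @param prickle_width_px Spike base width in px (1-2).
#' @param shadow_offset `c(drow, dcol)` displacement of the cast shadow;
#'   `NULL` disables the shadow.
#' @param shadow_intensity Shadow brightness as a fraction of the background.
#' @param salt_rate Fraction of pixels hit by salt/pepper noise, in `[0, 1)`.
#' @param seed RNG seed driving prickle placement and noise.
#' @return A list of class `"fruit_image_spec"`.
#' @export
fruit_image_spec <- function(a_px = 60, b_px = 45, pose_deg = 0,
                             canvas = NULL, center = NULL,
                             fruit_color = c(180, 60, 40),
                             bg_color = c(255, 255, 255),
                             prickle_count = 28, prickle_len_px = 8,
                             prickle_width_px = 2,
                             shadow_offset = c(14, 14), shadow_intensity = 0.8,
                             salt_rate = 0.002, seed = 1L) {
  if (!(a_px >= b_px) || b_px <= 0)
    abort("need a_px >= b_px > 0", "invalid_spec")
  if (salt_rate < 0 || salt_rate >= 1)
    abort("salt_rate must lie in [0, 1)", "invalid_spec")
  if (prickle_len_px < 0 || prickle_width_px < 0 || prickle_count < 0)
    abort("prickle parameters must be >= 0", "invalid_spec")
  reach <- a_px + prickle_len_px
  need <- 2 * ceiling(reach) + 2 * max(4, if (is.null(shadow_offset)) 0
                                       else ceiling(max(abs(shadow_offset)))) + 3
  if (is.null(canvas)) canvas <- c(need, need)
  if (is.null(center)) center <- (canvas + 1) / 2
  if (center[1] - reach < 1 || center[1] + reach > canvas[1] ||
      center[2] - reach < 1 || center[2] + reach > canvas[2])
    abort("ellipse (with prickles) exceeds the canvas", "canvas_error")
  structure(list(a_px = a_px, b_px = b_px, pose_deg = pose_deg,
                 canvas = canvas, center = center,
                 fruit_color = fruit_color, bg_color = bg_color,
                 prickle_count = prickle_count,
                 prickle_len_px = prickle_len_px,
                 prickle_width_px = prickle_width_px,
                 shadow_offset = shadow_offset,
                 shadow_intensity = shadow_intensity,
                 salt_rate = salt_rate, seed = as.integer(seed)),
            class = "fruit_image_spec")
}

# 0/1 matrix of the rotated-ellipse membership test at the pixel centers
ellipse_mask <- function(canvas, center, a, b, pose_deg) {
  H <- canvas[1]; W <- canvas[2]
  th <- pose_deg * pi / 180
  x <- rep(seq_len(W), each = H) - center[2]
  y <- -(rep(seq_len(H), times = W) - center[1])   # y up, pose CCW
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), H, W)
}

#' Render a binary ellipse with analytic ground truth
#'
#' A pixel is foreground iff its center satisfies the rotated-ellipse
#' inequality.  The returned truth carries the semi-axes, pose, center and the
#' analytic area `pi * a * b`.
#'
#' @param spec A [fruit_image_spec()] (prickle/shadow/noise fields ignored).
#' @return `list(mask = <0/1 matrix>, truth = list(a_px, b_px, pose_deg,
#'   center, area_px))`.
#' @export
render_binary_ellipse <- function(spec) {
  stopifnot(inherits(spec, "fruit_image_spec"))
  mask <- ellipse_mask(spec$canvas, spec$center, spec$a_px, spec$b_px, spec$pose_deg)
  list(mask = mask,
       truth = list(a_px = spec$a_px, b_px = spec$b_px,
                    pose_deg = spec$pose_deg, center = spec$center,
                    area_px = pi * spec$a_px * spec$b_px))
}

#' Render a synthetic fruit photograph
#'
#' Draws, on a uniform background: an offset desaturated shadow ellipse, the
#' fruit ellipse, radial triangular prickle spikes in the fruit color, and
#' salt/pepper noise.  The ground-truth mask is the bare fruit ellipse —
#' prickles, shadow and noise are exactly the nuisance the pipeline must
#' strip.  Rendering is deterministic in `spec$seed`.
#'
#' @param spec A [fruit_image_spec()].
#' @return `list(img = <HxWx3 array in [0,255]>, mask = ground-truth 0/1
#'   matrix, truth = analytic truth as in [render_binary_ellipse()])`.
#' @export
render_fruit_photo <- function(spec) {
  stopifnot(inherits(spec, "fruit_image_spec"))
  base <- render_binary_ellipse(spec)
  H <- spec$canvas[1]; W <- spec$canvas[2]
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- spec$bg_color[ch]
  # shadow: same ellipse, offset, gray at shadow_intensity of the background
  if (!is.null(spec$shadow_offset)) {
    sh_center <- spec$center + spec$shadow_offset
    sh <- ellipse_mask(spec$canvas, sh_center, spec$a_px, spec$b_px, spec$pose_deg)
    sh <- sh & !base$mask
    gray <- mean(spec$bg_color) * spec$shadow_intensity
    for (ch in 1:3) { m <- img[, , ch]; m[sh == 1] <- gray; img[, , ch] <- m }
  }
  prickles <- matrix(0L, H, W)
  with_local_seed(spec$seed, {
    if (spec$prickle_count > 0 && spec$prickle_len_px > 0) {
      th0 <- spec$pose_deg * pi / 180
      # evenly spaced base angles with jitter: spikes never merge into
      # structures wider than the median filter can remove
      ang <- 2 * pi * (seq_len(spec$prickle_count) - 1 +
                       stats::runif(spec$prickle_count, -0.25, 0.25)) /
             spec$prickle_count
      for (g in ang) {
        # boundary point and outward normal of the rotated ellipse
        bx <- spec$a_px * cos(g); by <- spec$b_px * sin(g)
        nx <- cos(g) / spec$a_px; ny <- sin(g) / spec$b_px
        nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
        rot <- function(x, y) c(cos(th0) * x - sin(th0) * y,
                                sin(th0) * x + cos(th0) * y)
        p0 <- rot(bx, by); nv <- rot(nx, ny)
        pv <- c(-nv[2], nv[1])  # perpendicular to the spike axis
        for (t in seq(0, spec$prickle_len_px, by = 0.5)) {
          # taper: full width at the base, a single pixel at the tip
          w <- spec$prickle_width_px * (1 - t / spec$prickle_len_px)
          s <- if (w >= 2) c(-0.5, 0.5) else 0
          px <- p0[1] + t * nv[1] + s * pv[1]
          py <- p0[2] + t * nv[2] + s * pv[2]
          cols <- round(spec$center[2] + px)
          rows <- round(spec$center[1] - py)
          ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
          prickles[cbind(rows[ok], cols[ok])] <- 1L
        }
      }
    }
    fruit_px <- base$mask == 1 | prickles == 1
    for (ch in 1:3) { m <- img[, , ch]; m[fruit_px] <- spec$fruit_color[ch]; img[, , ch] <- m }
    if (spec$salt_rate > 0) {
      n <- round(spec$salt_rate * H * W)
      if (n > 0) {
        idx <- sample.int(H * W, n)
        val <- stats::runif(n) < 0.5
        for (ch in 1:3) { m <- img[, , ch]; m[idx] <- ifelse(val, 255, 0); img[, , ch] <- m }
      }
    }
  })
  list(img = img, mask = base$mask, truth = base$truth)
}

#' Specification of a synthetic fruit population
#'
#' Statistical twin of a graded fruit batch: half axes are drawn from normal
#' distributions, the fruit body is treated as an oblate spheroid (equatorial
#' half axis `a`, polar half axis `b`), so the top projected area is
#' `pi a^2`, the two side projected areas are both `pi a b` (independent small
#' measurement noise makes them distinct but highly correlated), mass is
#' density times ellipsoid volume with multiplicative scatter, and measured
#' volume is the paraboloid volume with its own scatter.  Default location and
#' scale parameters reproduce the reference population's summary statistics
#' (mean mass 18.01 g, mean volume 17.64 ml, axis CV ~ 10%, mass CV ~ 30%).
#' The density is solved from moment matching so that `E[M] = mass_mean_g`
#' exactly.
#'
#' @param n Number of fruits.
#' @param a_mean_mm,a_sd_mm,b_mean_mm,b_sd_mm Normal parameters of the half
#'   axes (mm); draws are rejected until `0 < b < a`.
#' @param mass_mean_g Target expected mass (g).
#' @param noise_area_side,noise_area_top Relative (CV) multiplicative Gaussian
#'   noise on the side and top projected areas.  The top view (the fruit's
#'   irregular sepal crown) departs from the ellipse idealization more than
#'   the smooth side profiles, so its default shape noise is larger.
#' @param noise_volume,noise_mass Relative (CV) multiplicative Gaussian noise
#'   on measured volume and mass.
#' @param seed RNG seed.
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(n = 60L,
                            a_mean_mm = 19.72, a_sd_mm = 2.24,
                            b_mean_mm = 14.76, b_sd_mm = 1.38,
                            mass_mean_g = 18.01,
                            noise_area_side = 0.02, noise_area_top = 0.06,
                            noise_volume = 0.22,
                            noise_mass = 0.17, seed = 1L) {
  if (!is_count(n) || n < 1) abort("n must be a positive integer", "invalid_spec")
  if (a_mean_mm <= 0 || b_mean_mm <= 0 || a_sd_mm < 0 || b_sd_mm < 0 ||
      mass_mean_g <= 0)
    abort("location/scale parameters must be positive", "invalid_spec")
  if (noise_area_side < 0 || noise_area_top < 0 || noise_volume < 0 ||
      noise_mass < 0)
    abort("noise scales must be >= 0", "invalid_spec")
  structure(list(n = as.integer(n), a_mean_mm = a_mean_mm, a_sd_mm = a_sd_mm,
                 b_mean_mm = b_mean_mm, b_sd_mm = b_sd_mm,
                 mass_mean_g = mass_mean_g,
                 noise_area_side = noise_area_side,
                 noise_area_top = noise_area_top,
                 noise_volume = noise_volume,
                 noise_mass = noise_mass, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic fruit population table
#'
#' Samples a fruit-record table per the [population_spec()] model.  With all
#' noise scales zero the generated columns satisfy the defining identities
#' exactly: `CPA = (PA1 + PA2 + PA3)/3`, `Vparab / Vellip = b / a`, and
#' `M = rho * Vellip` row-wise, where `rho` is the moment-matched density.
#'
#' @param spec A [population_spec()].
#' @return A fruit-record data.frame (see [write_fruit_records()]); the
#'   density used is attached as attribute `"density_g_ml"`.
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  # density from moment matching: E[M] = rho * 4pi/3 * E[a^2] E[b] (cm^3)
  Ea2b <- (spec$a_mean_mm^2 + spec$a_sd_mm^2) * spec$b_mean_mm / 1000  # cm^3
  rho <- spec$mass_mean_g / (4 * pi / 3 * Ea2b)
  with_local_seed(spec$seed, {
    a <- numeric(spec$n); b <- numeric(spec$n)
    for (i in seq_len(spec$n)) {
      repeat {
        ai <- stats::rnorm(1, spec$a_mean_mm, spec$a_sd_mm)
        bi <- stats::rnorm(1, spec$b_mean_mm, spec$b_sd_mm)
        if (ai > bi && bi > 0) { a[i] <- ai; b[i] <- bi; break }
      }
    }
    eps <- function(cv) if (cv == 0) rep(1, spec$n)
                        else pmax(1 + stats::rnorm(spec$n, 0, cv), 0.05)
    pa3 <- pi * a^2 / 100 * eps(spec$noise_area_top)      # top view, cm^2
    pa1 <- pi * a * b / 100 * eps(spec$noise_area_side)   # side views share axes
    pa2 <- pi * a * b / 100 * eps(spec$noise_area_side)
    v_ellip <- ellipsoid_volume(a / 10, b / 10)
    v_parab <- paraboloid_volume(a / 10, b / 10)
    m <- rho * v_ellip * eps(spec$noise_mass)
    v <- v_parab * eps(spec$noise_volume)
    rec <- data.frame(
      id = seq_len(spec$n), mass_g = m, volume_ml = v,
      a_mm = a, b_mm = b,
      pa1_cm2 = pa1, pa2_cm2 = pa2, pa3_cm2 = pa3,
      cpa_cm2 = (pa1 + pa2 + pa3) / 3,
      v_ellip_ml = v_ellip, v_parab_ml = v_parab
    )
    attr(rec, "density_g_ml") <- rho
    rec
  })
}

#' Build the three orthogonal view specs of one triaxial fruit
#'
#' For semi-axes `p >= q >= r` (px), the top (Z) view shows the two largest
#' semi-axes and the side (X/Y) views share the smallest, vertical semi-axis:
#' top = (p, q), side X = (p, r), side Y = (q, r).  All three specs share one
#' canvas size so the views can be measured jointly.
#'
#' @param semi_axes_px Numeric length-3 vector of semi-axes in pixels (any
#'   order; sorted internally).
#' @param pose_deg Pose applied to each rendered view.
#' @param ... Passed on to [fruit_image_spec()] (colors, prickles, noise...).
#' @return Named list `x`, `y`, `z` of [fruit_image_spec()] objects.
#' @export
make_three_views <- function(semi_axes_px, pose_deg = 0, ...) {
  if (length(semi_axes_px) != 3 || any(semi_axes_px <= 0))
    abort("semi_axes_px must be three positive values", "invalid_spec")
  s <- sort(semi_axes_px, decreasing = TRUE)
  p <- s[1]; q <- s[2]; r <- s[3]
  args <- list(...)
  mk <- function(a, b) do.call(fruit_image_spec,
                               c(list(a_px = a, b_px = b, pose_deg = pose_deg),
                                 args))
  tpl <- mk(p, q)                     # largest view fixes the shared canvas
  mk2 <- function(a, b) do.call(fruit_image_spec,
                                c(list(a_px = a, b_px = b, pose_deg = pose_deg,
                                       canvas = tpl$canvas), args))
  list(x = mk2(p, r), y = mk2(q, r), z = tpl)
}
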
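# Shared fixtures and independent oracles for the test suite.

cal25 <- camera_calibration(0.25)

# uniform color image
flat_image <- function(h, w, color) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- color[ch]
  img
}

# 90-degree counter-clockwise rotation of a matrix / color array
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot90_img <- function(a) {
  out <- array(0, c(dim(a)[2], dim(a)[1], 3))
  for (ch in 1:3) out[, , ch] <- rot90_mat(a[, , ch])
  out
}
rot180_mat <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

# brute-force sliding-window median with replicate border (oracle)
brute_median <- function(x, k) {
  r <- (k - 1) / 2
  H <- nrow(x); W <- ncol(x)
  out <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- pmin(pmax(i + (-r:r), 1), H)
    jj <- pmin(pmax(j + (-r:r), 1), W)
    out[i, j] <- stats::median(x[ii, jj])
  }
  out
}

# longest horizontal chord of an ellipse with semi-axes (a, b) whose major
# axis makes angle psi (deg) with the horizontal: 2ab / sqrt(a^2 sin^2 +
# b^2 cos^2) (analytic oracle for max_chord under rotation)
analytic_chord <- function(a, b, psi_deg) {
  s <- sin(psi_deg * pi / 180); co <- cos(psi_deg * pi / 180)
  2 * a * b / sqrt(a^2 * s^2 + b^2 * co^2)
}

# inner one-pixel boundary layer of a filled mask (outline fixture)
mask_outline <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(1L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  er <- mask
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    er <- er & pad[2:(H + 1) + d[1], 2:(W + 1) + d[2]]
  matrix(as.integer(mask == 1 & !er), H, W)
}
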
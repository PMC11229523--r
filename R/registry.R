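# Registry of the published Rosa roxburghii reference models and summary
# statistics bundled with the package.  Coefficients and metrics are stored as
# printed; they were fitted on 60 real fruits whose raw data are not
# distributed, so the registry is for prediction and cross-checking, not
# refitting.

reference_model_table <- function() {
  r <- function(response, form, predictors, k1, k2, k3, k4, r2, chi2, rmse)
    data.frame(response = response, form = form,
               predictors = paste(predictors, collapse = "+"),
               k1 = k1, k2 = k2, k3 = k3, k4 = k4,
               r2 = r2, chi2 = chi2, rmse = rmse,
               stringsAsFactors = FALSE)
  rbind(
    # --- dimension-based, mass (the exponential-in-a mass model was never
    #     published; its slot does not exist) ---
    r("M", "linear",      "a", -27.485, 2.307, NA, NA, 0.929, 7.26, 1.43),
    r("M", "linear",      "b", -31.952, 3.384, NA, NA, 0.759, 23.69, 2.63),
    r("M", "quadratic",   "a",   5.428, -0.960, 0.080, NA, 0.935, 6.26, 1.37),
    r("M", "quadratic",   "b",  44.588, -6.947, 0.346, NA, 0.782, 19.89, 2.50),
    r("M", "exponential", "b",   1.168, 0.183, NA, NA, 0.779, 20.28, 2.52),
    r("M", "power",       "a",   0.012, 2.446, NA, NA, 0.935, 6.29, 1.37),
    r("M", "power",       "b",   0.009, 2.805, NA, NA, 0.778, 20.95, 2.53),
    r("M", "multi2", c("a", "b"), -31.970, 1.829, 0.941, NA, 0.948, 5.38, 1.22),
    # --- dimension-based, volume ---
    r("V", "linear",      "a", -27.203, 2.271, NA, NA, 0.848, 17.48, 2.15),
    r("V", "linear",      "b", -34.525, 3.530, NA, NA, 0.778, 24.80, 2.60),
    r("V", "quadratic",   "a", -15.486, 1.108, 0.028, NA, 0.849, 17.33, 2.15),
    r("V", "quadratic",   "b",   3.190, -1.561, 0.170, NA, 0.775, 23.43, 2.57),
    r("V", "exponential", "a",   1.691, 0.117, NA, NA, 0.839, 18.51, 2.22),
    r("V", "exponential", "b",   1.031, 0.190, NA, NA, 0.776, 23.78, 2.61),
    r("V", "power",       "a",   0.012, 2.443, NA, NA, 0.846, 17.59, 2.16),
    r("V", "power",       "b",   0.007, 2.920, NA, NA, 0.782, 23.38, 2.58),
    r("V", "multi2", c("a", "b"), -34.539, 1.490, 1.540, NA, 0.896, 11.63, 1.78),
    # --- projected-area-based, mass ---
    r("M", "linear",      "PA1", -8.512, 2.793, NA, NA, 0.934, 6.94, 1.38),
    r("M", "linear",      "PA2", -7.987, 2.774, NA, NA, 0.923, 7.49, 1.48),
    r("M", "linear",      "PA3", -5.671, 1.934, NA, NA, 0.964, 3.39, 1.02),
    r("M", "linear",      "CPA", -8.109, 2.519, NA, NA, 0.978, 2.17, 0.79),
    r("M", "quadratic",   "PA1",  4.864, 0.036, 0.137, NA, 0.941, 5.92, 1.30),
    r("M", "quadratic",   "PA2",  7.561, -0.400, 0.166, NA, 0.933, 6.28, 1.39),
    r("M", "quadratic",   "PA3",  0.838, 0.861, 0.042, NA, 0.965, 3.24, 1.01),
    r("M", "quadratic",   "CPA",  0.280, 0.940, 0.071, NA, 0.981, 1.82, 0.73),
    r("M", "exponential", "PA1",  4.475, 0.143, NA, NA, 0.938, 6.07, 1.33),
    r("M", "exponential", "PA2",  4.479, 0.145, NA, NA, 0.932, 6.31, 1.39),
    r("M", "exponential", "PA3",  5.336, 0.096, NA, NA, 0.954, 4.01, 1.15),
    r("M", "exponential", "CPA",  4.620, 0.128, NA, NA, 0.976, 2.25, 0.82),
    r("M", "power",       "PA1",  0.691, 1.445, NA, NA, 0.939, 6.26, 1.32),
    r("M", "power",       "PA2",  0.696, 1.448, NA, NA, 0.929, 6.80, 1.42),
    r("M", "power",       "PA3",  0.635, 1.332, NA, NA, 0.965, 3.22, 1.01),
    r("M", "power",       "CPA",  0.620, 1.435, NA, NA, 0.981, 1.86, 0.74),
    r("M", "multi3", c("PA1", "PA2", "PA3"),
      -7.659, 0.714, 0.560, 1.114, 0.980, 27.75, 2.83),
    # --- projected-area-based, volume ---
    r("V", "linear",      "PA1", -8.618, 2.759, NA, NA, 0.858, 17.89, 2.08),
    r("V", "linear",      "PA2", -8.500, 2.783, NA, NA, 0.875, 13.96, 1.95),
    r("V", "linear",      "PA3", -5.463, 1.882, NA, NA, 0.860, 15.87, 2.07),
    r("V", "linear",      "CPA", -8.170, 2.483, NA, NA, 0.896, 12.18, 1.78),
    r("V", "quadratic",   "PA1",  0.333, 0.915, 0.092, NA, 0.861, 17.49, 2.06),
    r("V", "quadratic",   "PA2", -3.141, 1.655, 0.057, NA, 0.876, 13.86, 1.94),
    r("V", "quadratic",   "PA3", -6.582, 2.060, -0.007, NA, 0.860, 15.85, 2.07),
    r("V", "quadratic",   "CPA", -7.181, 2.297, 0.008, NA, 0.896, 12.19, 1.78),
    r("V", "exponential", "PA1",  4.327, 0.144, NA, NA, 0.857, 18.03, 2.08),
    r("V", "exponential", "PA2",  4.301, 0.146, NA, NA, 0.870, 14.85, 1.99),
    r("V", "exponential", "PA3",  5.262, 0.096, NA, NA, 0.845, 17.93, 2.17),
    r("V", "exponential", "CPA",  4.502, 0.128, NA, NA, 0.886, 13.93, 1.87),
    r("V", "power",       "PA1",  0.626, 1.476, NA, NA, 0.861, 17.51, 2.06),
    r("V", "power",       "PA2",  0.648, 1.469, NA, NA, 0.876, 13.89, 1.94),
    r("V", "power",       "PA3",  0.690, 1.289, NA, NA, 0.858, 16.11, 2.08),
    r("V", "power",       "CPA",  0.602, 1.438, NA, NA, 0.895, 12.44, 1.79),
    r("V", "multi3", c("PA1", "PA2", "PA3"),
      -8.467, 0.657, 1.294, 0.628, 0.898, 11.83, 1.76),
    # --- geometric-volume-based, mass ---
    r("M", "linear",      "V",      1.809, 0.921, NA, NA, 0.901, 9.90, 1.68),
    r("M", "linear",      "Vellip", 1.085, 0.679, NA, NA, 0.966, 3.54, 0.99),
    r("M", "linear",      "Vparab", 0.462, 0.944, NA, NA, 0.913, 8.35, 1.58),
    r("M", "quadratic",   "V",      7.128, 0.310, 0.016, NA, 0.911, 8.32, 1.59),
    r("M", "quadratic",   "Vellip", 3.159, 0.515, 0.003, NA, 0.967, 3.34, 0.98),
    r("M", "quadratic",   "Vparab", 2.981, 0.677, 0.006, NA, 0.914, 8.04, 1.57),
    r("M", "exponential", "V",      7.572, 0.047, NA, NA, 0.907, 8.46, 1.63),
    r("M", "exponential", "Vellip", 7.476, 0.034, NA, NA, 0.957, 4.04, 1.10),
    r("M", "exponential", "Vparab", 7.227, 0.047, NA, NA, 0.906, 8.51, 1.64),
    r("M", "power",       "V",      1.302, 0.917, NA, NA, 0.898, 10.38, 1.71),
    r("M", "power",       "Vellip", 0.858, 0.947, NA, NA, 0.965, 3.64, 1.00),
    r("M", "power",       "Vparab", 1.024, 0.981, NA, NA, 0.912, 4.40, 1.58),
    # --- geometric volumes as direct volume estimators (no fitted constants;
    #     the published R2 for Vellip reads 0.902 once an obvious typo in the
    #     running text is discarded) ---
    r("V", "identity", "Vellip", NA, NA, NA, NA, 0.902, 206.46, 7.95),
    r("V", "identity", "Vparab", NA, NA, NA, NA, 0.887, 17.41, 2.11)
  )
}

#' Registry of published reference models
#'
#' Every published mass/volume estimation model for Rosa roxburghii fruits
#' bundled with the package: dimension-based (half axes a, b in mm),
#' projected-area-based (PA1, PA2, PA3, CPA in cm^2) and geometric-volume
#' -based (measured V, ellipsoid Vellip and paraboloid Vparab in ml) blocks,
#' each with printed constants and goodness-of-fit metrics (R2, chi-square,
#' RMSE, and the derived accuracy phi).
#'
#' @return A data.frame with columns `response`, `form`, `predictors`,
#'   `k1..k4`, `r2`, `chi2`, `rmse`, `phi`.
#' @seealso [reference_model()] to fetch one entry as a usable model object.
#' @export
reference_models <- function() {
  tab <- reference_model_table()
  tab$phi <- (100 - tab$rmse) / 100 * 100
  tab
}

#' Fetch one reference model by key
#'
#' @param response `"M"` or `"V"`.
#' @param form One of `"linear"`, `"quadratic"`, `"exponential"`, `"power"`,
#'   `"multi2"`, `"multi3"`, `"identity"`.
#' @param predictors Predictor name(s), e.g. `"CPA"` or `c("PA1","PA2","PA3")`.
#' @return A `"fruit_model"` (source `"reference"`) usable with `predict()`.
#' @export
reference_model <- function(response, form, predictors) {
  tab <- reference_models()
  key <- paste(predictors, collapse = "+")
  hit <- tab$response == response & tab$form == form & tab$predictors == key
  if (!any(hit))
    abort(sprintf("no reference model for (%s, %s, %s)", response, form, key),
          "lookup_error")
  row <- tab[which(hit)[1], ]
  nk <- model_ncoef[[form]]
  k <- if (nk > 0) stats::setNames(as.numeric(row[paste0("k", seq_len(nk))]),
                                   paste0("k", seq_len(nk))) else numeric(0)
  new_fruit_model(response, form, predictors, k,
                  metrics = structure(list(r2 = row$r2, chi2 = row$chi2,
                                           rmse = row$rmse, phi = row$phi,
                                           n_params = nk),
                                      class = "fit_metrics"),
                  source = "reference")
}

#' Reference summary statistics of the measured fruit population
#'
#' Printed max/min/mean/sd of the eight physical characteristics over the 60
#' reference fruits (half axes in mm, areas in cm^2, mass in g, volume in ml).
#' These summaries calibrate the synthetic population generator.
#'
#' @return A data.frame with columns `parameter`, `unit`, `max`, `min`,
#'   `mean`, `sd`.
#' @export
reference_summary <- function() {
  data.frame(
    parameter = c("a", "b", "PA1", "PA2", "PA3", "CPA", "M", "V"),
    unit = c("mm", "mm", "cm2", "cm2", "cm2", "cm2", "g", "ml"),
    max  = c(25.39, 17.71, 13.82, 13.41, 18.60, 14.97, 29.89, 30),
    min  = c(15.49, 11.53,  6.39,  6.15,  8.08,  7.05, 10.15,  9),
    mean = c(19.72, 14.76,  9.49,  9.37, 12.24, 10.37, 18.01, 17.64),
    sd   = c( 2.24,  1.38,  1.85,  1.85,  2.72,  2.10,  5.38,  5.52)
  )
}

#' Reference per-category grading summaries
#'
#' Printed mass and volume summaries of the three pre-graded categories
#' (20 fruits each) used to derive the default [size_classes()].
#'
#' @return A data.frame with one row per category and parameter.
#' @export
reference_size_summary <- function() {
  data.frame(
    classification = rep(c("Large", "Medium", "Small"), each = 2),
    n = 20L,
    parameter = rep(c("mass_g", "volume_ml"), 3),
    max  = c(29.76, 30, 18.76, 20, 14.46, 17),
    min  = c(20.17, 19, 14.78, 12, 10.73,  9),
    mean = c(24.88, 23.95, 15.99, 16.45, 13.15, 12.47),
    sd   = c( 2.96,  3.51,  1.04,  2.38,  1.11,  2.03)
  )
}
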
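# Canonical predictor names and their fruit-record CSV columns.
predictor_columns <- c(
  a = "a_mm", b = "b_mm", PA1 = "pa1_cm2", PA2 = "pa2_cm2", PA3 = "pa3_cm2",
  CPA = "cpa_cm2", M = "mass_g", V = "volume_ml",
  Vellip = "v_ellip_ml", Vparab = "v_parab_ml"
)

model_arity <- c(linear = 1L, quadratic = 1L, exponential = 1L, power = 1L,
                 multi2 = 2L, multi3 = 3L, identity = 1L)

# number of fitted constants per form (identity has none)
model_ncoef <- c(linear = 2L, quadratic = 3L, exponential = 2L, power = 2L,
                 multi2 = 3L, multi3 = 4L, identity = 0L)

get_var <- function(data, name) {
  if (name %in% names(data)) return(data[[name]])
  col <- predictor_columns[[name]]
  if (!is.null(col) && col %in% names(data)) return(data[[col]])
  abort(sprintf("predictor '%s' not found in the data", name), "domain_error")
}

new_fruit_model <- function(response, form, predictors, k, metrics = NULL,
                            source = "fitted") {
  structure(list(response = response, form = form,
                 predictors = predictors, k = k,
                 metrics = metrics, source = source),
            class = "fruit_model")
}

model_formula_text <- function(m) {
  k <- signif(m$k, 6)
  p <- m$predictors
  switch(m$form,
    linear      = sprintf("%s = %g + %g*%s", m$response, k[1], k[2], p),
    quadratic   = sprintf("%s = %g + %g*%s + %g*%s^2", m$response, k[1], k[2], p, k[3], p),
    exponential = sprintf("%s = %g * exp(%g*%s)", m$response, k[1], k[2], p),
    power       = sprintf("%s = %g * %s^%g", m$response, k[1], p, k[2]),
    multi2      = sprintf("%s = %g + %g*%s + %g*%s", m$response, k[1], k[2], p[1], k[3], p[2]),
    multi3      = sprintf("%s = %g + %g*%s + %g*%s + %g*%s",
                          m$response, k[1], k[2], p[1], k[3], p[2], k[4], p[3]),
    identity    = sprintf("%s = %s (geometric)", m$response, p)
  )
}

#' @export
print.fruit_model <- function(x, ...) {
  cat(sprintf("<fruit_model [%s]> %s\n", x$source, model_formula_text(x)))
  if (!is.null(x$metrics))
    cat(sprintf("  R2 = %.3f  chi2 = %.2f  RMSE = %.2f  phi = %.2f%%\n",
                x$metrics$r2, x$metrics$chi2, x$metrics$rmse, x$metrics$phi))
  invisible(x)
}

#' Goodness-of-fit metrics
#'
#' Computes the package's four model-selection metrics: the coefficient of
#' determination `R2 = 1 - SSE/SST`, a Pearson-style chi-square
#' `sum((y - yhat)^2 / yhat)` (requires positive predictions; `NA` with a
#' warning otherwise), the root mean square error with denominator `n`
#' (response units), and the accuracy score `phi = (100 - RMSE)/100 * 100%`.
#'
#' @param y Observed responses.
#' @param y_hat Fitted/predicted responses, same length.
#' @param n_params Number of model parameters (stored, not used in RMSE).
#' @return A list of class `"fit_metrics"` with `r2`, `chi2`, `rmse`, `phi`.
#' @export
fit_metrics <- function(y, y_hat, n_params = NA_integer_) {
  if (length(y) != length(y_hat) || length(y) < 1)
    abort("y and y_hat must have equal length >= 1", "domain_error")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("R2 undefined: response has zero variance", "domain_error")
  sse <- sum((y - y_hat)^2)
  rmse <- sqrt(sse / length(y))
  chi2 <- if (all(y_hat > 0)) sum((y - y_hat)^2 / y_hat) else {
    warning("chi2 undefined for non-positive predictions; returning NA")
    NA_real_
  }
  structure(list(r2 = 1 - sse / sst, chi2 = chi2, rmse = rmse,
                 phi = (100 - rmse) / 100 * 100, n_params = n_params),
            class = "fit_metrics")
}

#' Fit a mass/volume regression model
#'
#' Fits one of the package's model forms to fruit records: `linear`
#' (`Y = k1 + k2 X`), `quadratic` (`Y = k1 + k2 X + k3 X^2`), `exponential`
#' (`Y = k1 e^{k2 X}`), `power` (`Y = k1 X^{k2}`), `multi2`
#' (`Y = k1 + k2 X1 + k3 X2`) or `multi3` (`Y = k1 + k2 X1 + k3 X2 + k4 X3`).
#' Linear-in-parameters forms use ordinary least squares; exponential and
#' power forms are true nonlinear least squares on the original response
#' scale, initialized from the log-linearized OLS fit.
#'
#' @param data Data frame with the response and predictor variables, under
#'   either canonical names (`a`, `b`, `PA1` ... `CPA`, `Vellip`, `Vparab`,
#'   `M`, `V`) or fruit-record CSV column names.
#' @param response `"M"` (mass, g) or `"V"` (volume, ml).
#' @param predictors Character vector of predictor names (length must match
#'   the form's arity).
#' @param form Model form (see above).
#' @return A `"fruit_model"` with coefficients `k1..` and training-data
#'   [fit_metrics()].
#' @export
fit_model <- function(data, response, predictors,
                      form = c("linear", "quadratic", "exponential", "power",
                               "multi2", "multi3")) {
  form <- match.arg(form)
  if (length(predictors) != model_arity[[form]])
    abort(sprintf("form '%s' takes %d predictor(s)", form, model_arity[[form]]),
          "domain_error")
  y <- get_var(data, response)
  X <- lapply(predictors, function(p) get_var(data, p))
  n <- length(y)
  if (n < model_ncoef[[form]] + 1)
    abort("too few observations for this model form", "singular_fit")
  if (form %in% c("exponential", "power") && any(y <= 0))
    abort("response must be > 0 for exponential/power forms", "domain_error")
  if (form == "power" && any(X[[1]] <= 0))
    abort("predictor must be > 0 for the power form", "domain_error")

  k <- switch(form,
    linear = , multi2 = , multi3 = {
      df <- as.data.frame(stats::setNames(X, paste0("x", seq_along(X))))
      df$y <- y
      fm <- stats::lm(y ~ ., data = df)
      if (fm$rank < length(X) + 1)
        abort("rank-deficient design: predictors are collinear", "singular_fit")
      unname(stats::coef(fm))
    },
    quadratic = {
      x <- X[[1]]
      fm <- stats::lm(y ~ x + I(x^2))
      if (fm$rank < 3) abort("rank-deficient quadratic design", "singular_fit")
      unname(stats::coef(fm))
    },
    exponential = {
      x <- X[[1]]
      init <- stats::coef(stats::lm(log(y) ~ x))
      fm <- minpack.lm::nlsLM(y ~ k1 * exp(k2 * x),
                              start = list(k1 = exp(init[[1]]), k2 = init[[2]]),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      unname(stats::coef(fm))
    },
    power = {
      x <- X[[1]]
      init <- stats::coef(stats::lm(log(y) ~ log(x)))
      fm <- minpack.lm::nlsLM(y ~ k1 * x^k2,
                              start = list(k1 = exp(init[[1]]), k2 = init[[2]]),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      unname(stats::coef(fm))
    }
  )
  names(k) <- paste0("k", seq_along(k))
  model <- new_fruit_model(response, form, predictors, k)
  y_hat <- predict(model, data)
  model$metrics <- fit_metrics(y, y_hat, n_params = length(k))
  model
}

#' Predict mass or volume from a fitted or reference model
#'
#' Evaluates the model formula exactly on new predictor values.
#'
#' @param object A `"fruit_model"`.
#' @param newdata Data frame (canonical or fruit-record column names) or named
#'   list/vector providing the model's predictors.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.fruit_model <- function(object, newdata, ...) {
  X <- lapply(object$predictors, function(p) get_var(newdata, p))
  k <- object$k
  switch(object$form,
    linear      = k[[1]] + k[[2]] * X[[1]],
    quadratic   = k[[1]] + k[[2]] * X[[1]] + k[[3]] * X[[1]]^2,
    exponential = k[[1]] * exp(k[[2]] * X[[1]]),
    power       = k[[1]] * X[[1]]^k[[2]],
    multi2      = k[[1]] + k[[2]] * X[[1]] + k[[3]] * X[[2]],
    multi3      = k[[1]] + k[[2]] * X[[1]] + k[[3]] * X[[2]] + k[[4]] * X[[3]],
    identity    = X[[1]]
  )
}

#' Rank models by goodness of fit
#'
#' Orders models by R2 descending, breaking ties by chi-square ascending and
#' then RMSE ascending; the sort is stable, so models with identical metrics
#' keep their input order.
#'
#' @param models List of `"fruit_model"` objects with metrics.
#' @return The same models, reordered best-first.
#' @export
rank_models <- function(models) {
  if (length(models) < 1) abort("need at least one model", "domain_error")
  met <- function(f) vapply(models, function(m) {
    v <- m$metrics[[f]]
    if (is.null(v) || is.na(v)) Inf else v
  }, numeric(1))
  models[order(-met("r2"), met("chi2"), met("rmse"))]
}

#' Pairwise correlations of the physical characteristics
#'
#' Pearson correlation matrix over the eight measured characteristics
#' `a, b, PA1, PA2, PA3, CPA, M, V`.
#'
#' @param records Fruit-record data.frame with at least 3 complete rows.
#' @return Symmetric 8 x 8 correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(records) {
  vars <- c("a", "b", "PA1", "PA2", "PA3", "CPA", "M", "V")
  X <- vapply(vars, function(v) get_var(records, v), numeric(nrow(records)))
  if (nrow(X) < 3) abort("need at least 3 records", "domain_error")
  if (anyNA(X)) abort("records contain missing values", "domain_error")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    abort(paste("constant column(s):", paste(vars[sds == 0], collapse = ", ")),
          "domain_error")
  stats::cor(X)
}

#' Size classes for fruit grading
#'
#' Default mass classes derived from the reference study's per-category
#' summaries (see [reference_size_summary()]): boundaries at the midpoints
#' between adjacent category extremes, outer bounds at the printed category
#' minimum and maximum.
#'
#' @param labels Class labels, small to large.
#' @param bounds Numeric vector of `length(labels) + 1` increasing mass bounds
#'   (g); class i covers `[bounds[i], bounds[i+1])`, the last class closed.
#' @return A data.frame with columns `label`, `min_g`, `max_g`.
#' @export
size_classes <- function(labels = c("Small", "Medium", "Large"),
                         bounds = c(10.73, 14.62, 19.465, 29.76)) {
  if (length(bounds) != length(labels) + 1 || is.unsorted(bounds, strictly = TRUE))
    abort("bounds must be strictly increasing, one more than labels", "invalid_config")
  data.frame(label = labels,
             min_g = bounds[-length(bounds)],
             max_g = bounds[-1])
}

#' Grade a fruit by mass
#'
#' @param mass_g Fruit mass in grams (measured, or predicted from a model when
#'   no balance reading exists).
#' @param classes A [size_classes()] table covering the expected range.
#' @return The class label.
#' @export
grade_fruit <- function(mass_g, classes = size_classes()) {
  if (!is.numeric(mass_g) || length(mass_g) != 1 || is.na(mass_g))
    abort("mass_g must be a single number", "domain_error")
  hit <- which(mass_g >= classes$min_g &
               (mass_g < classes$max_g |
                (mass_g <= classes$max_g & seq_len(nrow(classes)) == nrow(classes))))
  if (length(hit) == 0)
    abort(sprintf("mass %.2f g is outside the graded range [%.2f, %.2f]",
                  mass_g, min(classes$min_g), max(classes$max_g)), "ungradable")
  classes$label[hit[1]]
}

#' Read / write a model as JSON
#'
#' Full-precision round trip of a `"fruit_model"`: response, form, predictor
#' names, coefficients and metrics.
#'
#' @param model A `"fruit_model"`.
#' @param path JSON path.
#' @return `read_model_json()` returns the model; `write_model_json()` returns
#'   `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fruit_model"))
  out <- list(response = model$response, form = model$form,
              predictors = model$predictors,
              coefficients = as.list(model$k),
              metrics = if (is.null(model$metrics)) NULL else
                unclass(model$metrics),
              source = model$source)
  # I(17) significant digits keeps the double-precision round trip bit-exact
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path), "io_error")
  v <- jsonlite::fromJSON(path)
  k <- unlist(v$coefficients)
  metrics <- if (!is.null(v$metrics)) structure(as.list(v$metrics), class = "fit_metrics")
  new_fruit_model(v$response, v$form, unlist(v$predictors), k, metrics,
                  source = if (is.null(v$source)) "fitted" else v$source)
}

#' Fit report mirroring the reference tables
#'
#' Fits a set of model forms to the same records and returns a report table
#' with one row per model: formula, constants `k1..k4`, `R2`, `chi2`, `RMSE`.
#'
#' @param data Fruit records.
#' @param response `"M"` or `"V"`.
#' @param specs List of `list(form =, predictors =)` entries; default: every
#'   univariate form on `a` and `b` plus the two-dimension multivariate model
#'   (the dimension-based block of the reference tables).
#' @return A data.frame report; fitted models attached as attribute
#'   `"models"`.
#' @export
fit_report <- function(data, response = "M", specs = dimension_model_specs()) {
  models <- lapply(specs, function(s)
    fit_model(data, response, s$predictors, s$form))
  rows <- lapply(models, function(m) {
    k <- rep(NA_real_, 4); k[seq_along(m$k)] <- m$k
    data.frame(model = model_formula_text(m), form = m$form,
               predictors = paste(m$predictors, collapse = "+"),
               k1 = k[1], k2 = k[2], k3 = k[3], k4 = k[4],
               r2 = m$metrics$r2, chi2 = m$metrics$chi2, rmse = m$metrics$rmse)
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' @rdname fit_report
#' @export
dimension_model_specs <- function() {
  list(
    list(form = "linear", predictors = "a"),
    list(form = "linear", predictors = "b"),
    list(form = "quadratic", predictors = "a"),
    list(form = "quadratic", predictors = "b"),
    list(form = "exponential", predictors = "a"),
    list(form = "exponential", predictors = "b"),
    list(form = "power", predictors = "a"),
    list(form = "power", predictors = "b"),
    list(form = "multi2", predictors = c("a", "b"))
  )
}
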
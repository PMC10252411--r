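#' Linear dryness equations
#'
#' A dryness equation is a named linear predictor on the 0-8 sensory dryness
#' scale: an intercept plus one coefficient per chemistry variable, each in
#' the units fixed by [chemistry_units()] (in particular residual sugar in
#' mg/100 mL — evaluating the stored coefficients against sugar in g/L would
#' be off by a factor of 100, which is why readers never rescale columns).
#'
#' `cider_dryness_equation()` returns the package's built-in calibration for
#' New York ciders, fitted by PLS1 on the selected easily-measured variables
#' (residual sugar, titratable acidity, pH and the 280/320 nm absorbances):
#'
#' \deqn{y = 5.928 - 0.929 pH + 0.0687 TA - 0.425 A_{280} - 0.0395 A_{320}
#'       + 0.0005243 RS}
#'
#' @param intercept intercept on the 0-8 scale.
#' @param coefficients named numeric vector of per-variable slopes; names
#'   must be [chemistry_units()] variables.
#' @return object of class `"dryness_equation"`.
#' @examples
#' eq <- cider_dryness_equation()
#' predict_dryness(eq, data.frame(ph = 3.63, titratable_acidity = 0.55,
#'   abs280 = 0.2130, abs320 = 0.0812, residual_sugar = 691.17))
#' @export
dryness_equation <- function(intercept, coefficients) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), length(coefficients) >= 1)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named", call. = FALSE)
  unknown <- setdiff(names(coefficients), chemistry_vars())
  if (length(unknown))
    stop("unknown chemistry variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(intercept = unname(intercept), coefficients = coefficients),
            class = "dryness_equation")
}

#' @rdname dryness_equation
#' @export
cider_dryness_equation <- function() {
  dryness_equation(
    intercept = 5.928,
    coefficients = c(ph = -0.929, titratable_acidity = 0.0687,
                     abs280 = -0.425, abs320 = -0.0395,
                     residual_sugar = 0.0005243)
  )
}

#' @export
print.dryness_equation <- function(x, ...) {
  terms <- sprintf("%+.6g*%s", x$coefficients, names(x$coefficients))
  cat("dryness =", format(x$intercept), paste(terms, collapse = " "), "\n")
  invisible(x)
}

#' Predict dryness scores and ratings from chemistry
#'
#' `predict_dryness()` evaluates a [dryness_equation()] on a chemistry table
#' and (by default) clips the result to the 0-8 sensory scale.
#' `predict_rating()` converts the clipped score to a marketable category
#' with [categorize_sensory_score()] — predicted scores live on the panel's
#' sensory scale, so the sensory category bands apply.
#'
#' @param eq a [dryness_equation()].
#' @param samples data frame providing every variable named in
#'   `eq$coefficients`, in [chemistry_units()] units.
#' @param clip clip scores into `[0, 8]`? Disable to inspect the raw linear
#'   evaluation.
#' @return `predict_dryness()`: numeric scores; `predict_rating()`: ordered
#'   factor of dryness categories.
#' @examples
#' eq <- cider_dryness_equation()
#' zero <- data.frame(ph = 0.001, titratable_acidity = 0, abs280 = 0,
#'                    abs320 = 0, residual_sugar = 0)
#' # with all predictors at zero the score is the intercept, 5.928
#' @export
predict_dryness <- function(eq, samples, clip = TRUE) {
  stopifnot(inherits(eq, "dryness_equation"))
  samples <- as.data.frame(samples)
  miss <- setdiff(names(eq$coefficients), names(samples))
  if (length(miss))
    stop("samples are missing required variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  M <- as.matrix(samples[, names(eq$coefficients), drop = FALSE])
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("missing values in required variables", call. = FALSE)
  score <- drop(M %*% eq$coefficients) + eq$intercept
  if (clip) score <- pmin(pmax(score, 0), 8)
  unname(score)
}

#' @rdname predict_dryness
#' @export
predict_rating <- function(eq, samples) {
  categorize_sensory_score(predict_dryness(eq, samples, clip = TRUE))
}

#' Extract a dryness equation from a PLS1 fit
#'
#' Turns a fitted calibration into a portable [dryness_equation()] on the
#' original measurement scales. When `variable_subset` names fewer variables
#' than the fit used, the model is refitted on the subset (PLS coefficients
#' are not transferable between variable sets, so subsetting always refits
#' rather than zeroing out columns).
#'
#' @param model a [fit_pls1()] fit whose predictors are chemistry variables.
#' @param variable_subset variables to keep (default: all of the fit's).
#' @param n_factors factors for a subset refit; defaults to
#'   `min(model$n_factors, length(variable_subset))`.
#' @return a [dryness_equation()].
#' @export
make_equation <- function(model, variable_subset = NULL, n_factors = NULL) {
  stopifnot(inherits(model, "pls1_fit"))
  if (is.null(variable_subset)) variable_subset <- model$variables
  unknown <- setdiff(variable_subset, model$variables)
  if (length(unknown))
    stop("variable(s) not in the fitted model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!setequal(variable_subset, model$variables)) {
    if (is.null(n_factors))
      n_factors <- min(model$n_factors, length(variable_subset))
    model <- fit_pls1(model$X[, variable_subset, drop = FALSE], model$y,
                      n_factors = n_factors, autoscale = model$autoscale)
  }
  dryness_equation(model$intercept, model$b_raw)
}

#' Chemistry variable sets of the published dryness models
#'
#' Three nested PLS1 dryness models are in routine discussion for New York
#' ciders: model #1 uses every measured chemistry variable, model #2 the
#' variables surviving the jackknife significance screen, and model #3 the
#' "selected" set restricted to cheap routine assays (enzymatic sugar,
#' titration, pH and UV absorbances). The significance-screened set is
#' reported in two variants in the literature (one citing pH, one
#' hydroxycinnamic acid), so both presets are shipped.
#'
#' @param model `"model1"`, `"model2"`, `"model2_alt"` or `"model3"`.
#' @return character vector of chemistry variable names.
#' @export
dryness_model_variables <- function(model = c("model1", "model2",
                                              "model2_alt", "model3")) {
  model <- match.arg(model)
  switch(model,
    model1 = chemistry_vars(),
    model2 = c("residual_sugar", "ph", "abs280"),
    model2_alt = c("residual_sugar", "hydroxycinnamic", "abs280"),
    model3 = c("residual_sugar", "titratable_acidity", "abs280", "abs320",
               "ph"))
}
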
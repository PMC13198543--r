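#' Classical girth-based manual weight equations
#'
#' The conventional tape-measure equations used to benchmark the image
#' pipeline: linear formulae predicting body weight (kg) from heart girth
#' (HG, cm), optionally body length (BL, cm) and age, fitted separately for
#' a mixed-breed cohort, Swedish Red, and Swedish Holstein. Published fit
#' statistics (R-squared, mean absolute percentage error) are carried along
#' where available; one mixed-breed MAPE cell is not legible in the printed
#' source table and is stored as `NA` rather than guessed.
#'
#' @return A tibble with one row per equation: `population`, `predictors`,
#'   `intercept_kg`, `coef_hg`, `coef_bl`, `coef_age`, `r_squared`,
#'   `mape_pct`. Age units follow the original measurement campaign and the
#'   coefficient is only meaningful in those units.
#' @examples
#' manual_weight_equations() |> dplyr::filter(population == "mixed")
#' @export
manual_weight_equations <- function() {
  tibble::tribble(
    ~population,        ~predictors,      ~intercept_kg, ~coef_hg, ~coef_bl, ~coef_age, ~r_squared, ~mape_pct,
    "mixed",            "hg",             -878.3134,     7.3827,   NA,       NA,        0.85,       5.42,
    "mixed",            "hg+bl",          -1035.94,      6.2570,   2.3311,   NA,        0.87,       NA,
    "mixed",            "hg+bl+age",      -911.4412,     5.4143,   2.4066,   11.2416,   0.89,       4.47,
    "swedish_red",      "hg",             -851.8974,     7.1984,   NA,       NA,        0.69,       14.12,
    "swedish_red",      "hg+bl",          -975.8509,     6.1404,   2.0569,   NA,        0.71,       13.67,
    "swedish_red",      "hg+bl+age",      -869.3609,     5.4592,   2.0203,   11.8829,   0.72,       13.34,
    "swedish_holstein", "hg",             -891.57,       7.455,    NA,       NA,        0.90,       4.07,
    "swedish_holstein", "hg+bl",          -1065.8118,    6.7215,   1.9233,   NA,        0.91,       3.59,
    "swedish_holstein", "hg+bl+age",      -928.2627,     5.7649,   2.1257,   8.6201,    0.93,       3.55
  )
}

#' Predict body weight from a manual equation
#'
#' Evaluates `intercept + coef_hg * hg + coef_bl * bl + coef_age * age` for
#' one equation row of [manual_weight_equations()] (or any compatible
#' one-row data frame). Predictors the equation does not use are ignored;
#' predictors it requires must be supplied. Non-positive predictions are
#' returned with a warning — they flag extrapolation far outside the
#' calibration range, not plausible weights.
#'
#' @param eq One equation row.
#' @param hg_cm Heart girth in cm (vectorised).
#' @param bl_cm Body length in cm, if the equation uses it.
#' @param age Age (in the equation's original units), if used.
#' @return Numeric vector of predicted weights (kg).
#' @examples
#' eq <- manual_weight_equations() |>
#'   dplyr::filter(population == "mixed", predictors == "hg")
#' predict_manual(eq, hg_cm = 200)
#' @export
predict_manual <- function(eq, hg_cm, bl_cm = NULL, age = NULL) {
  eq <- tibble::as_tibble(eq)
  if (nrow(eq) != 1L) abort("`eq` must be a single equation row.")
  if (is.na(eq$coef_hg)) abort("Equation has no heart-girth coefficient.")
  if (missing(hg_cm) || is.null(hg_cm)) abort("Predictor `hg_cm` is required.")
  pred <- eq$intercept_kg + eq$coef_hg * hg_cm
  if (!is.na(eq$coef_bl)) {
    if (is.null(bl_cm)) abort("Equation requires predictor `bl_cm`.")
    pred <- pred + eq$coef_bl * bl_cm
  }
  if (!is.na(eq$coef_age)) {
    if (is.null(age)) abort("Equation requires predictor `age`.")
    pred <- pred + eq$coef_age * age
  }
  if (any(pred <= 0)) {
    warn("Non-positive weight predicted; input is outside the equation's plausible range.")
  }
  pred
}

#' Mean absolute percentage error
#'
#' `100 * mean(|predicted - observed| / observed)`, the accuracy summary
#' conventionally reported for manual weight equations.
#'
#' @param predicted,observed Equal-length numeric vectors; `observed` must
#'   be strictly positive.
#' @return MAPE as a percentage.
#' @examples
#' mape(c(550, 450), c(500, 500))
#' @export
mape <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.")
  }
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    abort("`observed` weights must be positive (MAPE is undefined at 0).")
  }
  100 * mean(abs(predicted - observed) / observed)
}

#' Refit a manual-style weight equation by least squares
#'
#' Ordinary least squares of observed weight on heart girth and optional
#' body length and age, returning the fitted equation in the same row
#' format as [manual_weight_equations()] together with R-squared
#' (`1 - SSres/SStot`; defined as 0 when the observed weights are
#' constant).
#'
#' @param hg_cm Heart girth (cm).
#' @param observed_kg Observed body weights (kg).
#' @param bl_cm,age Optional further predictors.
#' @param population Label stored in the returned equation row.
#' @return A list with `equation` (one-row tibble) and `r_squared`.
#' @examples
#' hg <- seq(170, 230, length.out = 50)
#' w <- 7.3827 * hg - 878.3134
#' fit_ols_weight_equation(hg, w)$r_squared
#' @export
fit_ols_weight_equation <- function(hg_cm, observed_kg, bl_cm = NULL,
                                    age = NULL, population = "refit") {
  df <- data.frame(bw = observed_kg, hg = hg_cm)
  preds <- "hg"
  if (!is.null(bl_cm)) { df$bl <- bl_cm; preds <- c(preds, "bl") }
  if (!is.null(age)) { df$age <- age; preds <- c(preds, "age") }
  if (any(!complete.cases(df))) abort("Predictors contain missing values.")
  if (nrow(df) <= length(preds) + 1L) {
    abort("Need more observations than coefficients.")
  }
  fit <- lm(stats::reformulate(preds, "bw"), data = df)
  if (any(is.na(coef(fit)))) {
    abort("Degenerate (collinear) design; cannot fit the equation.")
  }
  ss_tot <- sum((df$bw - mean(df$bw))^2)
  ss_res <- sum(fit$residuals^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - ss_res / ss_tot
  cf <- coef(fit)
  eq <- tibble::tibble(
    population = population,
    predictors = paste(preds, collapse = "+"),
    intercept_kg = unname(cf["(Intercept)"]),
    coef_hg = unname(cf["hg"]),
    coef_bl = if ("bl" %in% names(cf)) unname(cf["bl"]) else NA_real_,
    coef_age = if ("age" %in% names(cf)) unname(cf["age"]) else NA_real_,
    r_squared = r2,
    mape_pct = mape(fit$fitted.values, df$bw)
  )
  list(equation = eq, r_squared = r2, fit = fit)
}
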
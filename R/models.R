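#' Fit an ordinary-least-squares eating-quality model
#'
#' Multiple linear regression of a response (typically the IVOE sensory
#' score) on a set of objective or sensory predictors.
#'
#' @param data Data frame containing response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns; default all other
#'   numeric columns.
#' @param units Optional named character vector annotating predictor units;
#'   stored on the model so prediction-time inputs can be checked.
#' @return An `ivoe_model`: predictors, named `coefficients`, `intercept`,
#'   in-sample `r2`, `n_fit`, `units`, and the underlying `lm` fit.
#' @export
#' @examples
#' sim <- simulate_panel(n_varieties = 60, seed = 1)
#' wide <- panel_to_wide(sim$data)
#' fit_ols(wide, "IVOE", c("viscosity", "appearance", "taste"))
fit_ols <- function(data, response, predictors = NULL, units = NULL) {
  stopifnot(is.data.frame(data))
  if (!response %in% names(data)) {
    stop_input("response column '", response, "' not found")
  }
  predictors <- predictors %||%
    setdiff(names(data)[purrr::map_lgl(data, is.numeric)], response)
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    stop_input("predictor column(s) not found: ", paste(missing, collapse = ", "))
  }
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1L) {
    stop_input("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  }
  const <- predictors[purrr::map_lgl(predictors, function(v) sd(data[[v]]) == 0)]
  if (length(const)) {
    stop_input("constant predictor column(s): ", paste(const, collapse = ", "))
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) {
    bad <- predictors[is.na(coef(fit))[-1]]
    stop_input("rank-deficient design; collinear column(s): ",
               paste(bad, collapse = ", "))
  }
  cf <- coef(fit)
  # noiseless designs legitimately fit perfectly; silence summary.lm's caveat
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  new_ivoe_model(
    predictors = predictors,
    coefficients = setNames(unname(cf[-1]), predictors),
    intercept = unname(cf[1]),
    r2 = r2,
    n_fit = n,
    units = units,
    fit = fit,
    provenance = "fitted by riceval::fit_ols"
  )
}

new_ivoe_model <- function(predictors, coefficients, intercept, r2,
                           n_fit = NA_integer_, units = NULL, fit = NULL,
                           provenance = NULL) {
  stopifnot(length(coefficients) == length(predictors))
  structure(
    list(predictors = predictors, coefficients = coefficients,
         intercept = intercept, r2 = r2, n_fit = n_fit,
         units = units, fit = fit, provenance = provenance),
    class = "ivoe_model"
  )
}

#' @export
print.ivoe_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g x %s", x$coefficients, x$predictors),
                 collapse = " ")
  cat("<ivoe_model> score =", terms, sprintf("%+.4g", x$intercept), "\n")
  if (is.finite(x$r2)) cat("  R2 =", format(x$r2), "\n")
  if (!is.null(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an eating-quality model into a coefficient table
#'
#' @param x An `ivoe_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` and, for fitted (not published)
#'   models, `std.error`, `statistic`, `p.value` from the underlying fit.
#' @export
tidy.ivoe_model <- function(x, ...) {
  base <- tibble(term = c("(Intercept)", x$predictors),
                 estimate = c(x$intercept, unname(x$coefficients)))
  if (is.null(x$fit)) return(base)
  sm <- summary(x$fit)$coefficients
  dplyr::bind_cols(base, as_tibble(sm[, -1, drop = FALSE]) |>
    setNames(c("std.error", "statistic", "p.value")))
}

#' One-row model summary
#'
#' @param x An `ivoe_model`.
#' @param ... Unused.
#' @return Tibble: `r.squared`, `adj.r.squared` (NA for published constants),
#'   `nobs`, `n_predictors`.
#' @export
glance.ivoe_model <- function(x, ...) {
  adj <- if (is.null(x$fit)) NA_real_ else summary(x$fit)$adj.r.squared
  tibble(r.squared = x$r2, adj.r.squared = adj,
         nobs = x$n_fit, n_predictors = length(x$predictors))
}

#' Exhaustive best-subset model selection
#'
#' Enumerates every non-empty subset of the candidate predictors up to
#' `max_size` and fits each by least squares, reporting the best subset per
#' size and the overall winner under the chosen criterion. Because in-sample
#' R-squared is monotone in subset size, the R-squared winner is always the
#' full model; adjusted R-squared and BIC penalise size and can prefer
#' smaller subsets.
#'
#' @param data,response,predictors As in [fit_ols()].
#' @param criterion `"r2"` (default), `"adj_r2"` or `"bic"`.
#' @param max_size Largest subset size to consider (default all predictors).
#' @return Tibble (class `best_subset`): one row per size with `size`,
#'   `predictors` (list-column), `r2`, `adj_r2`, `bic`, `best` (logical,
#'   overall winner), plus attributes `criterion` and `winner` (an
#'   [fit_ols()] model for the winning subset).
#' @export
best_subset <- function(data, response, predictors = NULL,
                        criterion = c("r2", "adj_r2", "bic"),
                        max_size = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(data))
  predictors <- predictors %||%
    setdiff(names(data)[purrr::map_lgl(data, is.numeric)], response)
  p <- length(predictors)
  if (p > 20L) {
    stop_config("exhaustive enumeration is limited to 20 predictors; got ", p)
  }
  max_size <- min(max_size %||% p, p)
  y <- data[[response]]
  X <- as.matrix(data[predictors])
  n <- length(y)
  tss <- sum((y - mean(y))^2)

  per_size <- purrr::map(seq_len(max_size), function(k) {
    sets <- combn(p, k, simplify = FALSE)
    stats_k <- purrr::map(sets, function(ix) {
      Xk <- cbind(1, X[, ix, drop = FALSE])
      fit <- stats::lm.fit(Xk, y)
      rss <- sum(fit$residuals^2)
      r2 <- 1 - rss / tss
      c(r2 = r2,
        adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
        bic = n * log(rss / n) + (k + 1) * log(n))
    })
    m <- do.call(rbind, stats_k)
    best_i <- switch(criterion,
      r2 = which.max(m[, "r2"]),
      adj_r2 = which.max(m[, "adj_r2"]),
      bic = which.min(m[, "bic"])
    )
    tibble(size = k,
           predictors = list(predictors[sets[[best_i]]]),
           r2 = unname(m[best_i, "r2"]),
           adj_r2 = unname(m[best_i, "adj_r2"]),
           bic = unname(m[best_i, "bic"]))
  }) |> dplyr::bind_rows()

  win_i <- switch(criterion,
    r2 = which.max(per_size$r2),
    adj_r2 = which.max(per_size$adj_r2),
    bic = which.min(per_size$bic)
  )
  per_size$best <- seq_len(nrow(per_size)) == win_i
  winner <- fit_ols(data, response, per_size$predictors[[win_i]])
  class(per_size) <- c("best_subset", class(per_size))
  attr(per_size, "criterion") <- criterion
  attr(per_size, "winner") <- winner
  per_size
}

#' The published IVOE prediction models
#'
#' Four multiple-regression models for the integrated value of organoleptic
#' evaluation (IVOE) of cooked Geng rice, shipped with their published
#' coefficients:
#'
#' * Model 1: `0.20 viscosity + 0.35 appearance + 0.59 taste + 0.13`
#'   (R2 = 0.87) — all-sensory predictors.
#' * Model 2: `0.27 adhesiveness + 0.40 appearance + 0.67 taste - 0.35`
#'   (R2 = 0.87) — instrument adhesiveness replaces sensory viscosity.
#' * Model 3: `0.27 viscosity - 0.57 yellow_area + 0.76 taste - 0.05`
#'   (R2 = 0.86) — image yellow area replaces sensory appearance.
#' * Model 4: `0.37 adhesiveness - 0.71 yellow_area + 0.89 taste - 0.34`
#'   (R2 = 0.85) — fully objective except for taste.
#'
#' Unit conventions are annotated on each constant (sensory traits on the
#' -3..+3 scale; `adhesiveness` in gf s from [compute_tpa()];
#' `yellow_area` in percent from [yellow_area_percent()]); the source does
#' not state predictor scaling, so check your features against
#' `model$units` — [predict_ivoe()] can enforce the match.
#'
#' @param which `"model1"` .. `"model4"` (or 1..4).
#' @return An `ivoe_model` with immutable published constants.
#' @export
#' @examples
#' predict_ivoe(data.frame(adhesiveness = 0, yellow_area = 0, taste = 0),
#'              ivoe_model(4))   # the published intercept, -0.34
ivoe_model <- function(which = "model4") {
  if (is.numeric(which)) which <- paste0("model", which)
  lib <- ivoe_model_library()
  if (!which %in% names(lib)) {
    stop_config("unknown model '", which, "'; available: ",
                paste(names(lib), collapse = ", "))
  }
  lib[[which]]
}

ivoe_model_library <- function() {
  sens <- "sensory score (-3..+3)"
  list(
    model1 = new_ivoe_model(
      c("viscosity", "appearance", "taste"),
      c(viscosity = 0.20, appearance = 0.35, taste = 0.59),
      intercept = 0.13, r2 = 0.87,
      units = c(viscosity = sens, appearance = sens, taste = sens),
      provenance = "published Model 1 (sensory components only)"
    ),
    model2 = new_ivoe_model(
      c("adhesiveness", "appearance", "taste"),
      c(adhesiveness = 0.27, appearance = 0.40, taste = 0.67),
      intercept = -0.35, r2 = 0.87,
      units = c(adhesiveness = "gf s (TPA A3 magnitude)",
                appearance = sens, taste = sens),
      provenance = "published Model 2 (instrument adhesiveness)"
    ),
    model3 = new_ivoe_model(
      c("viscosity", "yellow_area", "taste"),
      c(viscosity = 0.27, yellow_area = -0.57, taste = 0.76),
      intercept = -0.05, r2 = 0.86,
      units = c(viscosity = sens, yellow_area = "percent of pixels",
                taste = sens),
      provenance = "published Model 3 (image yellow area)"
    ),
    model4 = new_ivoe_model(
      c("adhesiveness", "yellow_area", "taste"),
      c(adhesiveness = 0.37, yellow_area = -0.71, taste = 0.89),
      intercept = -0.34, r2 = 0.85,
      units = c(adhesiveness = "gf s (TPA A3 magnitude)",
                yellow_area = "percent of pixels", taste = sens),
      provenance = "published Model 4 (objective adhesiveness + yellow area)"
    )
  )
}

#' List the published models
#'
#' @return Tibble: `model`, `predictors`, `intercept`, `r2`, `provenance`.
#' @export
ivoe_models <- function() {
  lib <- ivoe_model_library()
  purrr::imap(lib, function(m, nm) {
    tibble(model = nm,
           predictors = paste(m$predictors, collapse = " + "),
           intercept = m$intercept, r2 = m$r2, provenance = m$provenance)
  }) |> dplyr::bind_rows()
}

#' Predict eating-quality scores from features
#'
#' Applies `intercept + X %*% coefficients`, vectorised over the rows of
#' `data`. All model predictors must be present; a missing one is a hard
#' error naming the column. When `units` is supplied it is compared against
#' the model's unit annotations and any mismatch is an error — the guard
#' against e.g. feeding a 0--1 yellow fraction to a model fitted on percent.
#'
#' @param data Data frame of features (one row per sample).
#' @param model An `ivoe_model` (default the fully objective published
#'   Model 4).
#' @param units Optional named character vector declaring the units of the
#'   feature columns, checked against `model$units`.
#' @return `data` with a `.pred` column appended.
#' @export
predict_ivoe <- function(data, model = ivoe_model("model4"), units = NULL) {
  stopifnot(is.data.frame(data), inherits(model, "ivoe_model"))
  missing <- setdiff(model$predictors, names(data))
  if (length(missing)) {
    stop_input("feature column(s) required by the model are missing: ",
               paste(missing, collapse = ", "))
  }
  if (!is.null(units) && !is.null(model$units)) {
    shared <- intersect(names(units), names(model$units))
    bad <- shared[units[shared] != model$units[shared]]
    if (length(bad)) {
      stop_config("unit mismatch for ", paste(bad, collapse = ", "),
                  ": features declare [",
                  paste(units[bad], collapse = "; "),
                  "] but the model expects [",
                  paste(model$units[bad], collapse = "; "), "]")
    }
  }
  X <- as.matrix(data[model$predictors])
  pred <- as.vector(model$intercept + X %*% model$coefficients)
  dplyr::mutate(as_tibble(data), .pred = pred)
}

#' Agreement between predicted and observed scores
#'
#' Reports the Pearson correlation `r` between predictions and observations,
#' its square (the calibration R-squared quoted for hold-out validation of
#' the published models), and the slope/intercept of the calibration line
#' `observed ~ predicted`. Being correlation-based, it is invariant to affine
#' transformation of the predictions; it is distinct from the fit-time
#' coefficient of determination reported by [fit_ols()].
#'
#' @param data Data frame holding both columns.
#' @param truth,estimate Column names of observed and predicted scores.
#' @return One-row tibble: `r`, `r2`, `n`, `p`, `slope`, `intercept`.
#'   Zero variance in either column gives NA values with a warning.
#' @export
evaluate_predictions <- function(data, truth, estimate = ".pred") {
  stopifnot(is.data.frame(data))
  for (col in c(truth, estimate)) {
    if (!col %in% names(data)) stop_input("column '", col, "' not found")
  }
  obs <- data[[truth]]
  pred <- data[[estimate]]
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]
  pred <- pred[ok]
  if (length(obs) < 3L) stop_input("need >= 3 complete pairs")
  if (sd(obs) == 0 || sd(pred) == 0) {
    warning("zero variance: agreement undefined", call. = FALSE)
    return(tibble(r = NA_real_, r2 = NA_real_, n = length(obs), p = NA_real_,
                  slope = NA_real_, intercept = NA_real_))
  }
  pr <- pearson(pred, obs)
  cal <- coef(lm(obs ~ pred))
  tibble(r = pr$r, r2 = pr$r^2, n = pr$n, p = pr$p,
         slope = unname(cal[2]), intercept = unname(cal[1]))
}
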
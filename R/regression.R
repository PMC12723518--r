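#' Linear regression of yield response on baseline yield
#'
#' Ordinary least squares of the per-trial percent response on the untreated
#' strip yield. A negative, significant slope indicates the treatment helps
#' most where baseline yields are low — the pattern seen for barley, maize
#' and wheat in multi-year strip-trial programmes.
#'
#' @param effects data.frame from [trial_effects()] (needs
#'   `untreated_yield` and `response_pct`); at least 3 trials.
#' @return List of class `response_fit`: `slope` (percent per t/ha),
#'   `intercept`, `slope_se`, `p_value` (two-sided t-test on the slope),
#'   `r_squared`, `n`, and the underlying `lm` fit as `model`.
#' @export
#' @examples
#' eff <- trial_effects(simulate_crop(uruguay_grain_profiles()$barley, 1))
#' linear_response_fit(eff)
linear_response_fit <- function(effects) {
  if (nrow(effects) < 3L)
    stop("need at least 3 trials for a regression", call. = FALSE)
  x <- effects$untreated_yield
  if (stats::var(x) == 0)
    stop("degenerate design: untreated yields are constant", call. = FALSE)
  fit <- stats::lm(response_pct ~ untreated_yield, data = effects)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(slope = unname(co["untreated_yield", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         slope_se = unname(co["untreated_yield", "Std. Error"]),
         p_value = unname(co["untreated_yield", "Pr(>|t|)"]),
         r_squared = sm$r.squared,
         n = nrow(effects),
         model = fit),
    class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf(
    "<response_fit> n = %d: response = %.3f %+.3f * untreated yield\n",
    x$n, x$intercept, x$slope))
  cat(sprintf("  slope se %.3f, p = %.4g, R^2 = %.3f\n",
              x$slope_se, x$p_value, x$r_squared))
  invisible(x)
}

#' Locally weighted (loess-style) smooth of yield response
#'
#' Local linear regression with tricube weights over a nearest-neighbour
#' window: at each grid point the `ceiling(span * n)` nearest trials are
#' weighted by \eqn{(1 - (d/h)^3)^3} (with \eqn{h} the window radius) and a
#' weighted straight line is fitted; its value at the grid point is the
#' smoothed response. The grid is evenly spaced over the observed baseline
#' yield range. No robustness iterations are applied.
#'
#' With `span = 1` and `kernel = "uniform"` every local fit uses all points
#' with equal weight, so the smoother degenerates to the global least
#' squares line.
#'
#' @param effects data.frame from [trial_effects()]; at least 10 trials.
#' @param span Fraction of trials in each local window, in (0, 1];
#'   default 0.75.
#' @param grid_n Number of evaluation points (default 100).
#' @param kernel `"tricube"` (default) or `"uniform"` local weights.
#' @return List of class `smooth_fit`: `grid` (strictly increasing baseline
#'   yields), `fitted` (smoothed percent responses), `span`, `kernel`, `n`.
#' @export
loess_response_fit <- function(effects, span = 0.75, grid_n = 100L,
                               kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  if (nrow(effects) < 10L)
    stop("need at least 10 trials for a local regression", call. = FALSE)
  if (span <= 0 || span > 1)
    stop("'span' must be in (0, 1]", call. = FALSE)
  x <- effects$untreated_yield
  y <- effects$response_pct
  n <- length(x)
  q <- ceiling(span * n)
  if (q < 3L)
    stop("'span' too small: local windows of ", q,
         " point(s) cannot support a linear fit", call. = FALSE)
  grid <- seq(min(x), max(x), length.out = grid_n)
  fitted <- vapply(grid, function(g) local_linear_at(g, x, y, q, kernel),
                   numeric(1))
  structure(list(grid = grid, fitted = fitted, span = span,
                 kernel = kernel, n = n),
            class = "smooth_fit")
}

local_linear_at <- function(g, x, y, q, kernel) {
  d <- abs(x - g)
  h <- sort(d, partial = q)[q]
  if (h == 0) {            # >= q points coincide with g
    return(mean(y[d == 0]))
  }
  w <- if (kernel == "tricube") {
    wi <- pmax(0, 1 - (d / h)^3)^3
    wi
  } else {
    as.numeric(d <= h)
  }
  use <- w > 0
  xs <- x[use]; ys <- y[use]; ws <- w[use]
  # weighted SDs; fall back to the weighted mean on a degenerate window
  sw <- sum(ws)
  xb <- sum(ws * xs) / sw
  sxx <- sum(ws * (xs - xb)^2)
  if (sxx <= .Machine$double.eps * max(1, xb^2))
    return(sum(ws * ys) / sw)
  yb <- sum(ws * ys) / sw
  beta <- sum(ws * (xs - xb) * (ys - yb)) / sxx
  yb + beta * (g - xb)
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf(
    "<smooth_fit> %s local linear smooth, span %.2f, n = %d, %d grid points\n",
    x$kernel, x$span, x$n, length(x$grid)))
  invisible(x)
}

#' Fixed-effects model of response by crop and year
#'
#' Fits `response_pct ~ crop + year` with both predictors as categorical
#' factors (no interaction; each trial is a single unreplicated strip pair,
#' so within-site variability cannot enter the model). Reference levels are
#' the first crop alphabetically and the earliest year. A factor with a
#' single observed level is dropped with a warning.
#'
#' @param effects data.frame from [trial_effects()] covering one or more
#'   crops and years.
#' @return List of class `crop_year_fit` with a tidy `coefficients`
#'   data.frame (`term`, `estimate`, `std_error`, `p_value`), the fitted
#'   `model`, and the `terms_used`.
#' @export
crop_year_model <- function(effects) {
  df <- data.frame(response_pct = effects$response_pct,
                   crop = factor(effects$crop),
                   year = factor(effects$year,
                                 levels = sort(unique(effects$year))))
  terms_used <- character()
  if (nlevels(df$crop) > 1L) terms_used <- c(terms_used, "crop") else
    warning("single crop present; 'crop' dropped from the model",
            call. = FALSE)
  if (nlevels(df$year) > 1L) terms_used <- c(terms_used, "year") else
    warning("single year present; 'year' dropped from the model",
            call. = FALSE)
  if (!length(terms_used))
    stop("neither crop nor year varies; nothing to model", call. = FALSE)
  form <- stats::reformulate(terms_used, response = "response_pct")
  fit <- stats::lm(form, data = df)
  co <- summary(fit)$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(co),
                                   estimate = co[, "Estimate"],
                                   std_error = co[, "Std. Error"],
                                   p_value = co[, "Pr(>|t|)"],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
         model = fit,
         terms_used = terms_used),
    class = "crop_year_fit")
}

#' @export
print.crop_year_fit <- function(x, ...) {
  cat("<crop_year_fit> response_pct ~",
      paste(x$terms_used, collapse = " + "), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Plot yield response against baseline yield
#'
#' Scatter of per-trial percent response versus untreated yield with the
#' least-squares line, the tricube local smooth, and a horizontal line at
#' zero response. Requires ggplot2.
#'
#' @param effects data.frame from [trial_effects()] (one crop).
#' @param span Span for the local smooth.
#' @return A ggplot object.
#' @export
plot_yield_response <- function(effects, span = 0.75) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  sm <- loess_response_fit(effects, span = span)
  smooth_df <- data.frame(untreated_yield = sm$grid, response_pct = sm$fitted)
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = untreated_yield, y = response_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         se = FALSE, colour = "black") +
    ggplot2::geom_line(data = smooth_df, colour = "#c0392b",
                       linewidth = 1) +
    ggplot2::labs(x = "Untreated yield (t/ha)",
                  y = "Yield response (%)")
}
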
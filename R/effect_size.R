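#' Per-trial effect sizes on the log response-ratio scale
#'
#' For each paired trial the effect size is the natural log of the response
#' ratio, \eqn{\ln(\mathrm{treated}/\mathrm{untreated})}, which is unitless
#' and symmetric around zero; the percent yield response is the
#' back-transformed per-trial ratio,
#' \eqn{(\mathrm{treated}/\mathrm{untreated} - 1)\times 100}.
#'
#' @param records data.frame of trial records (see [simulate_crop()] /
#'   [read_oft_csv()] for the schema).
#' @return The input data.frame with columns `effect_size` (ln ratio) and
#'   `response_pct` appended; row order preserved.
#' @export
#' @examples
#' recs <- data.frame(crop = "wheat", year = 2020, site_id = c("a", "b"),
#'                    untreated_yield = c(4, 2), treated_yield = c(4.4, 2.1))
#' trial_effects(recs)
trial_effects <- function(records) {
  records <- validate_oft(records)
  ratio <- records$treated_yield / records$untreated_yield
  records$effect_size <- log(ratio)
  records$response_pct <- (ratio - 1) * 100
  records
}

#' Bootstrap the overall mean effect size
#'
#' Resamples trials with replacement `n_boot` times and returns the
#' normal-approximation bootstrap interval for the mean log effect: with
#' observed mean \eqn{\bar t}, bootstrap mean \eqn{\bar t^*} and bootstrap
#' standard deviation \eqn{s^*}, the interval is the bias-corrected
#' \deqn{(2\bar t - \bar t^*) \mp z_{(1-\gamma)/2}\, s^*.}
#' This is the `"norm"` interval convention of classical bootstrap software.
#' A percentile interval is available as an alternative.
#'
#' @param effects data.frame from [trial_effects()] or a numeric vector of
#'   per-trial log effect sizes (at least 2).
#' @param n_boot Number of bootstrap replicates (>= 1000; default 10000).
#' @param conf Confidence level in (0, 1); default 0.95.
#' @param seed Integer seed for the resampling, for reproducibility.
#' @param type `"norm"` (default) or `"perc"` for the percentile interval.
#' @return List with `mean_effect`, `ci_low`, `ci_high` (all on the ln-ratio
#'   scale), `response_pct` and `ci_pct` (back-transformed to percent),
#'   `n`, `n_boot`, `conf`, `type`.
#' @export
#' @examples
#' x <- log(runif(50, 0.95, 1.35))
#' bootstrap_mean_effect(x, n_boot = 2000, seed = 7)
bootstrap_mean_effect <- function(effects, n_boot = 10000L, conf = 0.95,
                                  seed = NULL, type = c("norm", "perc")) {
  type <- match.arg(type)
  x <- if (is.data.frame(effects)) effects$effect_size else as.numeric(effects)
  if (length(x) < 2L)
    stop("need at least 2 effect sizes to bootstrap", call. = FALSE)
  if (n_boot < 1000L)
    stop("'n_boot' must be >= 1000", call. = FALSE)
  if (conf <= 0 || conf >= 1)
    stop("'conf' must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old))
    set.seed(as.integer(seed))
  }
  n <- length(x)
  boot_means <- boot_mean_draws(x, n_boot)
  t0 <- mean(x)
  if (type == "norm") {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    centre <- 2 * t0 - mean(boot_means)
    half <- z * stats::sd(boot_means)
    ci <- c(centre - half, centre + half)
  } else {
    ci <- unname(stats::quantile(boot_means,
                                 c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  list(mean_effect = t0,
       ci_low = ci[1], ci_high = ci[2],
       response_pct = (exp(t0) - 1) * 100,
       ci_pct = (exp(ci) - 1) * 100,
       n = n, n_boot = as.integer(n_boot), conf = conf, type = type)
}

# vectorised resampling: bootstrap means in chunks to bound memory
boot_mean_draws <- function(x, n_boot, chunk_cells = 2e7) {
  n <- length(x)
  per_chunk <- max(1L, floor(chunk_cells / n))
  out <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    k <- min(per_chunk, n_boot - done)
    idx <- sample.int(n, n * k, replace = TRUE)
    out[done + seq_len(k)] <- colMeans(matrix(x[idx], nrow = n, ncol = k))
    done <- done + k
  }
  out
}

#' Effectiveness: fraction of trials whose response exceeds a threshold
#'
#' For each threshold `t` (percent), returns
#' `100 * mean(response_pct > t)` — strict inequality, so trials with
#' exactly zero response do not count as effective.
#'
#' @param effects data.frame from [trial_effects()] or numeric vector of
#'   percent responses.
#' @param thresholds Numeric vector of percent thresholds (default `c(0, 10)`,
#'   the conventional "any gain" and "over 10% gain" cut-offs).
#' @return Named numeric vector of percentages, one per threshold.
#' @export
#' @examples
#' effectiveness(c(-5, 0, 5, 15))   # 50% above 0, 25% above 10
effectiveness <- function(effects, thresholds = c(0, 10)) {
  r <- if (is.data.frame(effects)) effects$response_pct else as.numeric(effects)
  if (!length(r)) stop("no effects supplied", call. = FALSE)
  out <- vapply(thresholds, function(t) 100 * mean(r > t), numeric(1))
  names(out) <- paste0("gt", thresholds)
  out
}

#' Summarise one crop's trials
#'
#' Assembles the per-crop summary: trial count, mean and range of untreated
#' and treated yields, bootstrap mean log effect with confidence interval,
#' percent yield response, and effectiveness fractions.
#'
#' Two percent-response summaries are reported, and they differ whenever
#' yields vary between trials:
#' \describe{
#'   \item{`response_pct`}{the arithmetic mean of per-trial percent
#'     responses — the average of each trial's own gain;}
#'   \item{`response_pct_ratio_of_means`}{the ratio of the mean treated to
#'     mean untreated yield, \eqn{(\bar T/\bar U - 1)\times 100} — the gain
#'     of the programme-wide average yield.}
#' }
#' The back-transformed mean log effect,
#' \eqn{(e^{\bar{\ln(T/U)}} - 1)\times 100}, is reported separately as
#' `response_pct_log_scale` together with its CI.
#'
#' @param records data.frame of trial records for a single crop (>= 2 rows).
#' @param n_boot,conf,seed,type Passed to [bootstrap_mean_effect()].
#' @param thresholds Passed to [effectiveness()].
#' @return One-row data.frame of class `crop_summary`.
#' @export
summarize_crop <- function(records, n_boot = 10000L, conf = 0.95,
                           seed = NULL, type = "norm",
                           thresholds = c(0, 10)) {
  if (nrow(records) < 2L)
    stop("need at least 2 records to summarise a crop", call. = FALSE)
  if (length(unique(records$crop)) != 1L)
    stop("records mix crops: ",
         paste(unique(records$crop), collapse = ", "),
         "; summarise one crop at a time", call. = FALSE)
  eff <- trial_effects(records)
  bt <- bootstrap_mean_effect(eff, n_boot = n_boot, conf = conf,
                              seed = seed, type = type)
  ef <- effectiveness(eff, thresholds)
  out <- data.frame(
    crop = records$crop[1],
    n_ofts = nrow(records),
    mean_untreated = mean(records$untreated_yield),
    mean_treated = mean(records$treated_yield),
    min_untreated = min(records$untreated_yield),
    max_untreated = max(records$untreated_yield),
    min_treated = min(records$treated_yield),
    max_treated = max(records$treated_yield),
    mean_effect = bt$mean_effect,
    ci_low = bt$ci_low,
    ci_high = bt$ci_high,
    response_pct = mean(eff$response_pct),
    response_pct_log_scale = bt$response_pct,
    ci_pct_low = bt$ci_pct[1],
    ci_pct_high = bt$ci_pct[2],
    response_pct_ratio_of_means =
      (mean(records$treated_yield) / mean(records$untreated_yield) - 1) * 100,
    stringsAsFactors = FALSE)
  for (nm in names(ef)) out[[paste0("effectiveness_", nm)]] <- ef[[nm]]
  class(out) <- c("crop_summary", class(out))
  out
}

#' Summarise every crop in a trial table
#'
#' @param records Trial records for one or more crops.
#' @inheritParams summarize_crop
#' @return data.frame with one [summarize_crop()] row per crop. When `seed`
#'   is given, each crop gets a distinct sub-seed derived from it.
#' @export
summarize_crops <- function(records, n_boot = 10000L, conf = 0.95,
                            seed = NULL, type = "norm",
                            thresholds = c(0, 10)) {
  crops <- unique(records$crop)
  rows <- lapply(crops, function(cr) {
    sub_seed <- if (is.null(seed)) NULL else
      (as.integer(seed) + crop_offset(cr)) %% .Machine$integer.max
    summarize_crop(records[records$crop == cr, , drop = FALSE],
                   n_boot = n_boot, conf = conf, seed = sub_seed,
                   type = type, thresholds = thresholds)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
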
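#' Build a pipeline run configuration
#'
#' Either point `oft_csv` at an existing trial table or set
#' `simulate = TRUE` to generate one from `profiles`. Economics may come
#' from the bundled Uruguayan defaults, a list of [price_cost()] objects,
#' or a CSV with columns `crop, mean_price, price_sd, product_cost,
#' application_cost` (optionally `price_unfavorable, price_normal,
#' price_favorable`).
#'
#' @param oft_csv Path to a trial CSV (see [read_oft_csv()]), or `NULL`.
#' @param simulate Generate trials from `profiles` instead of reading a file.
#' @param profiles List of [crop_profile()]s used when `simulate = TRUE`.
#' @param economics Path to an economics CSV, a list of [price_cost()]s,
#'   or `NULL` for [uruguay_price_costs()].
#' @param n_boot,conf Bootstrap settings (`n_boot >= 1000`).
#' @param seed Master seed; every random draw in the run derives from it.
#' @param span Local-regression span.
#' @param out_dir Output directory for the report files, or `NULL` to skip
#'   writing.
#' @param verbose Print stage progress to stderr.
#' @return List of class `run_config`.
#' @export
oft_config <- function(oft_csv = NULL, simulate = is.null(oft_csv),
                       profiles = uruguay_grain_profiles(),
                       economics = NULL,
                       n_boot = 10000L, conf = 0.95, seed = 1L,
                       span = 0.75, out_dir = NULL, verbose = FALSE) {
  if (is.null(oft_csv) && !isTRUE(simulate))
    stop("provide 'oft_csv' or set simulate = TRUE", call. = FALSE)
  if (n_boot < 1000L)
    stop("'n_boot' must be >= 1000", call. = FALSE)
  structure(list(oft_csv = oft_csv, simulate = isTRUE(simulate),
                 profiles = profiles, economics = economics,
                 n_boot = as.integer(n_boot), conf = conf,
                 seed = as.integer(seed), span = span,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [oft_config()]; `profiles`, when
#' present, is a block in the format of [profiles_to_yaml()].
#'
#' @param file Path to a YAML config.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  profiles <- if (!is.null(y$profiles)) {
    out <- lapply(y$profiles, function(p)
      crop_profile(p$crop_name, p$n_trials, p$untreated_mean,
                   unlist(p$untreated_range), p$mean_log_effect,
                   untreated_sd = p$untreated_sd %||% diff(unlist(p$untreated_range)) / 4,
                   between_trial_sd_log_effect =
                     p$between_trial_sd_log_effect %||% 0.12,
                   effect_yield_slope = p$effect_yield_slope %||% 0,
                   year_range = unlist(p$year_range)))
    names(out) <- vapply(out, `[[`, "", "crop_name")
    out
  } else uruguay_grain_profiles()
  oft_config(oft_csv = y$oft_csv,
             simulate = y$simulate %||% is.null(y$oft_csv),
             profiles = profiles,
             economics = y$economics,
             n_boot = y$n_boot %||% 10000L,
             conf = y$conf %||% 0.95,
             seed = y$seed %||% 1L,
             span = y$span %||% 0.75,
             out_dir = y$out_dir,
             verbose = y$verbose %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_economics <- function(economics) {
  if (is.null(economics)) return(uruguay_price_costs())
  if (is.list(economics) && all(vapply(economics, inherits, TRUE, "price_cost"))) {
    names(economics) <- vapply(economics, `[[`, "", "crop")
    return(economics)
  }
  df <- utils::read.csv(economics, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    sp <- if (all(c("price_unfavorable", "price_normal", "price_favorable")
                  %in% names(df)))
      c(df$price_unfavorable[i], df$price_normal[i], df$price_favorable[i])
    else NULL
    price_cost(df$crop[i], df$mean_price[i],
               price_sd = if ("price_sd" %in% names(df)) df$price_sd[i] else 0,
               product_cost = df$product_cost[i],
               application_cost = df$application_cost[i],
               scenario_prices = sp)
  })
  names(out) <- df$crop
  out
}

#' Run the full strip-trial analysis pipeline
#'
#' Stages: load or simulate trial records; per-trial effect sizes; per-crop
#' summaries (bootstrap mean effect, CI, effectiveness); per-crop response
#' regressions (OLS slope and local smooth); the crop-by-year fixed-effects
#' model when both factors vary; and the three-scenario break-even
#' economics for every crop present in the economics table. Crops with
#' yield data but no economics row are reported in the summaries and
#' skipped, with a warning, in the economics stage.
#'
#' All randomness (simulation and bootstrap resampling) derives from
#' `config$seed`, so a repeated run writes byte-identical reports.
#'
#' @param config A [oft_config()] (or path handled by [read_run_config()]).
#' @param stages Character subset of `c("summaries", "regression",
#'   "economics")`; default all.
#' @return Invisibly, a list with `records`, `effects`, `summaries`,
#'   `regressions`, `crop_year`, `economics`, and `files` written (if
#'   `out_dir` was set).
#' @export
run_pipeline <- function(config = oft_config(),
                         stages = c("summaries", "regression", "economics")) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  log_msg <- function(...) if (config$verbose)
    message(sprintf("[striptrials %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(...))

  records <- if (config$simulate) {
    log_msg("simulating %d crop profile(s), seed %d",
            length(config$profiles), config$seed)
    simulate_trials(config$profiles, seed = config$seed)
  } else {
    log_msg("reading trials from %s", config$oft_csv)
    read_oft_csv(config$oft_csv)
  }
  log_msg("%d trials across %d crop(s)", nrow(records),
          length(unique(records$crop)))

  effects <- trial_effects(records)
  out <- list(records = records, effects = effects)

  if ("summaries" %in% stages) {
    out$summaries <- summarize_crops(effects, n_boot = config$n_boot,
                                     conf = config$conf, seed = config$seed)
    log_msg("summaries done (%d crops)", nrow(out$summaries))
  }

  if ("regression" %in% stages) {
    crops <- unique(effects$crop)
    out$regressions <- lapply(stats::setNames(crops, crops), function(cr) {
      sub <- effects[effects$crop == cr, , drop = FALSE]
      list(linear = linear_response_fit(sub),
           smooth = loess_response_fit(sub, span = config$span))
    })
    out$crop_year <- if (length(crops) > 1L ||
                         length(unique(effects$year)) > 1L)
      crop_year_model(effects) else NULL
    log_msg("regressions done")
  }

  if ("economics" %in% stages) {
    econ <- read_economics(config$economics)
    crops <- unique(records$crop)
    missing <- setdiff(crops, names(econ))
    if (length(missing))
      warning("no economics for crop(s): ",
              paste(missing, collapse = ", "), "; skipped", call. = FALSE)
    rows <- lapply(intersect(crops, names(econ)), function(cr)
      break_even_table(records[records$crop == cr, , drop = FALSE],
                       econ[[cr]]))
    out$economics <- if (length(rows)) {
      df <- do.call(rbind, rows); rownames(df) <- NULL; df
    } else NULL
    log_msg("economics done")
  }

  if (!is.null(config$out_dir))
    out$files <- write_report(out, config)
  invisible(out)
}

# serialize the report bundle: CSVs per stage plus one full-precision JSON
write_report <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  path <- function(f) file.path(config$out_dir, f)
  write_oft_csv(out$records, path("trials.csv"))
  files <- c(files, path("trials.csv"))
  if (!is.null(out$summaries)) {
    utils::write.csv(format_summary(out$summaries), path("crop_summaries.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, path("crop_summaries.csv"))
  }
  if (!is.null(out$economics)) {
    utils::write.csv(format_economics(out$economics), path("break_even.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, path("break_even.csv"))
  }
  if (!is.null(out$crop_year)) {
    utils::write.csv(out$crop_year$coefficients, path("crop_year_model.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, path("crop_year_model.csv"))
  }
  json <- list(
    n_trials = nrow(out$records),
    crops = as.list(table(out$records$crop)),
    summaries = out$summaries,
    economics = out$economics,
    crop_year = if (!is.null(out$crop_year)) out$crop_year$coefficients,
    regressions = if (!is.null(out$regressions))
      lapply(out$regressions, function(r)
        list(slope = r$linear$slope, slope_se = r$linear$slope_se,
             p_value = r$linear$p_value, r_squared = r$linear$r_squared,
             n = r$linear$n)),
    settings = list(n_boot = config$n_boot, conf = config$conf,
                    seed = config$seed, span = config$span))
  jsonlite::write_json(json, path("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  c(files, path("report.json"))
}

# display rounding: yields 3 dp (t/ha), percentages 2 dp, money/kg 1-2 dp
format_summary <- function(s) {
  s <- as.data.frame(s)
  yld <- c("mean_untreated", "mean_treated", "min_untreated",
           "max_untreated", "min_treated", "max_treated")
  for (v in intersect(yld, names(s))) s[[v]] <- round(s[[v]], 3)
  pct <- grep("^(response_pct|ci_pct|effectiveness_)", names(s), value = TRUE)
  for (v in pct) s[[v]] <- round(s[[v]], 2)
  for (v in c("mean_effect", "ci_low", "ci_high")) s[[v]] <- round(s[[v]], 4)
  s
}

format_economics <- function(e) {
  e$price <- round(e$price, 1)
  e$total_cost <- round(e$total_cost, 1)
  e$break_even_yield <- round(e$break_even_yield, 2)
  e$chance_exceed_cost <- round(e$chance_exceed_cost, 2)
  e$net_return <- round(e$net_return, 1)
  e
}
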
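#' Simulate paired on-farm strip trials for one crop
#'
#' Draws `n_trials` paired (untreated, treated) strip-mean yields under the
#' generative model of [crop_profile()]: truncated-normal baseline yields,
#' Gaussian between-trial noise on the log response ratio, and an optional
#' linear dependence of the log effect on baseline yield. Each simulated
#' trial stands for one independent replicate of the experiment, at the
#' strip-mean level the downstream analysis consumes.
#'
#' @param profile A [crop_profile()].
#' @param seed Integer seed; fixes all randomness, so identical calls give
#'   byte-identical tables.
#' @return data.frame of trial records with columns `crop`, `year`,
#'   `site_id`, `untreated_yield`, `treated_yield` (yields in t/ha).
#' @export
#' @examples
#' prof <- uruguay_grain_profiles()$soybean
#' head(simulate_crop(prof, seed = 1))
simulate_crop <- function(profile, seed) {
  if (!inherits(profile, "crop_profile"))
    stop("'profile' must be a crop_profile object", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n <- profile$n_trials
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))

  u <- rtruncnorm(n, profile$untreated_mean, profile$untreated_sd,
                  profile$untreated_range[1], profile$untreated_range[2])
  log_eff <- profile$mean_log_effect +
    profile$effect_yield_slope * (u - profile$untreated_mean) +
    stats::rnorm(n, 0, profile$between_trial_sd_log_effect)
  years <- sample(seq(profile$year_range[1], profile$year_range[2]),
                  n, replace = TRUE)
  data.frame(
    crop = profile$crop_name,
    year = as.integer(years),
    site_id = sprintf("S%03d", seq_len(n)),
    untreated_yield = u,
    treated_yield = u * exp(log_eff),
    stringsAsFactors = FALSE)
}

# truncated normal by rejection; redraws until all values fall in [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate trials for several crops at once
#'
#' Per-crop random streams are derived deterministically from the single
#' `seed` so that adding or reordering crops does not change the draws of
#' the others.
#'
#' @param profiles List of [crop_profile()] objects, e.g.
#'   [uruguay_grain_profiles()].
#' @param seed Integer master seed.
#' @return One stacked data.frame of trial records (see [simulate_crop()]).
#' @export
simulate_trials <- function(profiles = uruguay_grain_profiles(), seed = 1L) {
  recs <- lapply(profiles, function(p) {
    sub_seed <- (as.integer(seed) + crop_offset(p$crop_name)) %% .Machine$integer.max
    simulate_crop(p, seed = sub_seed)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# stable small integer offset per crop name (sum of character codes)
crop_offset <- function(crop_name) {
  sum(utf8ToInt(crop_name)) * 131L
}

#' Read / write trial record tables
#'
#' Trial tables are plain CSV with header
#' `crop,year,site_id,untreated_yield_t_ha,treated_yield_t_ha`.
#' `read_oft_csv()` validates the schema and yield positivity on read.
#'
#' @param records data.frame of trial records.
#' @param file Path to a CSV file.
#' @return `read_oft_csv()`: a validated records data.frame with the
#'   internal column names (`untreated_yield`, `treated_yield`).
#' @export
write_oft_csv <- function(records, file) {
  records <- validate_oft(records)
  out <- records
  names(out)[names(out) == "untreated_yield"] <- "untreated_yield_t_ha"
  names(out)[names(out) == "treated_yield"] <- "treated_yield_t_ha"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_oft_csv
#' @export
read_oft_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  names(df)[names(df) == "untreated_yield_t_ha"] <- "untreated_yield"
  names(df)[names(df) == "treated_yield_t_ha"] <- "treated_yield"
  validate_oft(df)
}

#' Validate a trial record table
#'
#' Checks the schema (`crop`, `year`, `site_id`, `untreated_yield`,
#' `treated_yield`) and that every yield is strictly positive, naming the
#' offending rows otherwise.
#'
#' @param records data.frame of trial records.
#' @return The validated data.frame, invisibly unchanged.
#' @export
validate_oft <- function(records) {
  need <- c("crop", "year", "site_id", "untreated_yield", "treated_yield")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(records$untreated_yield) |
               !is.finite(records$treated_yield) |
               records$untreated_yield <= 0 | records$treated_yield <= 0)
  if (length(bad))
    stop("non-positive or missing yield in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         " (site ", records$site_id[bad[1]], ")", call. = FALSE)
  records
}
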
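# tiny record-table builders used across the suite

make_records <- function(untreated, treated, crop = "testcrop",
                         year = 2020L) {
  n <- length(untreated)
  data.frame(crop = rep_len(crop, n),
             year = rep_len(as.integer(year), n),
             site_id = sprintf("T%03d", seq_len(n)),
             untreated_yield = untreated,
             treated_yield = treated,
             stringsAsFactors = FALSE)
}

# records whose per-trial percent responses are exactly `responses`
records_with_responses <- function(responses, untreated = NULL,
                                   crop = "testcrop") {
  u <- if (is.null(untreated)) seq(2, 6, length.out = length(responses))
       else untreated
  make_records(u, u * (1 + responses / 100), crop = crop)
}

simple_profile <- function(...) {
  defaults <- list(crop_name = "sim", n_trials = 50L, untreated_mean = 4,
                   untreated_range = c(1, 8),
                   mean_log_effect = log(1.12),
                   year_range = c(2018L, 2022L))
  args <- utils::modifyList(defaults, list(...))
  do.call(crop_profile, args)
}
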
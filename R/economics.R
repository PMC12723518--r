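#' Price and cost assumptions for one crop
#'
#' Bundles the grain price and treatment cost figures the break-even
#' analysis needs: mean market price, its between-year standard deviation,
#' and the per-hectare product and application costs. Explicit scenario
#' prices may be supplied (e.g. figures published already rounded); when
#' absent they are derived as mean price −1 SD / mean / +1 SD.
#'
#' @param crop Crop label.
#' @param mean_price Mean grain price, USD per tonne.
#' @param price_sd Between-year standard deviation of the price, USD/t.
#' @param product_cost Product cost, USD per ha.
#' @param application_cost Application cost, USD per ha.
#' @param scenario_prices Optional length-3 numeric
#'   (unfavorable, normal, favorable prices, USD/t) overriding the
#'   mean±SD derivation.
#' @return Object of class `price_cost`.
#' @seealso [scenario_table()], [uruguay_price_costs()]
#' @export
price_cost <- function(crop, mean_price, price_sd = 0,
                       product_cost, application_cost,
                       scenario_prices = NULL) {
  stopifnot(length(crop) == 1L)
  vals <- c(mean_price, price_sd, product_cost, application_cost)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("prices and costs must be finite and >= 0", call. = FALSE)
  if (!is.null(scenario_prices) && length(scenario_prices) != 3L)
    stop("'scenario_prices' must give (unfavorable, normal, favorable)",
         call. = FALSE)
  structure(list(crop = crop,
                 mean_price = mean_price,
                 price_sd = price_sd,
                 product_cost = product_cost,
                 application_cost = application_cost,
                 scenario_prices = scenario_prices),
            class = "price_cost")
}

#' Default price/cost assumptions for the Uruguayan grain crops
#'
#' May mean market prices over 2015--2024 (USD/t) for soybean, rice, maize,
#' wheat and barley; a product cost of 14 USD/ha; ground application at
#' 10 USD/ha (soybean, wheat, barley) and aerial application at 17 USD/ha
#' (rice, maize). Scenario prices are stored as published (already rounded
#' to 0.1 USD/t); the implied price SD is half the favorable−unfavorable
#' spread.
#'
#' @return Named list of [price_cost()] objects.
#' @export
uruguay_price_costs <- function() {
  # crop: mean price, scenario prices (unfav, normal, fav), product, application
  tab <- list(
    soybean = list(384.2, c(304.9, 384.2, 463.6), 14, 10),
    rice    = list(216.6, c(189.1, 216.6, 244.1), 14, 17),
    maize   = list(215.2, c(179.4, 215.2, 251.1), 14, 17),
    wheat   = list(215.2, c(169.8, 215.2, 260.5), 14, 10),
    barley  = list(199.8, c(166.3, 199.8, 233.4), 14, 10))
  out <- lapply(names(tab), function(cr) {
    p <- tab[[cr]]
    price_cost(cr, mean_price = p[[1]],
               price_sd = (p[[2]][3] - p[[2]][1]) / 2,
               product_cost = p[[3]], application_cost = p[[4]],
               scenario_prices = p[[2]])
  })
  names(out) <- names(tab)
  out
}

#' Build the three price scenarios for a crop
#'
#' Constructs the unfavorable / normal / favorable sensitivity scenarios:
#' \itemize{
#'   \item unfavorable — price = mean − 1 SD, total cost inflated by 4.5%;
#'   \item normal — mean price, actual product + application cost;
#'   \item favorable — price = mean + 1 SD, actual costs.
#' }
#' Full precision is retained for computation; any rounding is for display
#' only.
#'
#' @param pc A [price_cost()].
#' @return data.frame with columns `crop`, `scenario`
#'   (`unfavorable`/`normal`/`favorable`), `price` (USD/t), `total_cost`
#'   (USD/ha).
#' @export
#' @examples
#' scenario_table(uruguay_price_costs()$soybean)
scenario_table <- function(pc) {
  stopifnot(inherits(pc, "price_cost"))
  base_cost <- pc$product_cost + pc$application_cost
  prices <- if (!is.null(pc$scenario_prices)) pc$scenario_prices else
    pc$mean_price + c(-1, 0, 1) * pc$price_sd
  data.frame(
    crop = pc$crop,
    scenario = c("unfavorable", "normal", "favorable"),
    price = prices,
    total_cost = c(base_cost * 1.045, base_cost, base_cost),
    stringsAsFactors = FALSE)
}

#' Break-even yield for a price/cost scenario
#'
#' The extra grain (kg/ha) whose sale value exactly offsets the treatment
#' cost: `total_cost / price * 1000`.
#'
#' @param scenario One row of [scenario_table()] (data.frame or list with
#'   `price` and `total_cost`), or pass `price` and `total_cost` directly.
#' @param price,total_cost Numeric alternatives to `scenario`.
#' @return Break-even yield in kg/ha (vectorised over scenario rows).
#' @export
#' @examples
#' break_even_yield(price = 384.2, total_cost = 24)  # 62.47 kg/ha
break_even_yield <- function(scenario = NULL, price = NULL,
                             total_cost = NULL) {
  if (!is.null(scenario)) {
    price <- scenario$price
    total_cost <- scenario$total_cost
  }
  if (any(price <= 0))
    stop("price must be > 0 to define a break-even yield", call. = FALSE)
  total_cost / price * 1000
}

#' Empirical CDF of per-trial yield differences
#'
#' Computes the treated − untreated yield difference for every trial,
#' converts it to kg/ha, sorts ascending, and returns the right-continuous
#' empirical distribution function F(x) = (number of differences <= x) / n.
#'
#' @param records Trial records (yields in t/ha).
#' @return Object of class `yield_diff_ecdf`: the sorted `diffs` (kg/ha),
#'   `n`, and the step function `F` (a [stats::ecdf()]).
#' @export
yield_diff_ecdf <- function(records) {
  records <- validate_oft(records)
  d <- sort((records$treated_yield - records$untreated_yield) * 1000)
  structure(list(diffs = d, n = length(d), F = stats::ecdf(d)),
            class = "yield_diff_ecdf")
}

#' @export
print.yield_diff_ecdf <- function(x, ...) {
  cat(sprintf(
    "<yield_diff_ecdf> n = %d, yield differences %.0f to %.0f kg/ha (median %.0f)\n",
    x$n, min(x$diffs), max(x$diffs), stats::median(x$diffs)))
  invisible(x)
}

#' Chance that a trial's yield gain exceeds the break-even yield
#'
#' `100 * (1 - F(break_even))`: the percentage of trials whose yield
#' difference strictly exceeds the break-even mass, i.e. the estimated
#' probability that applying the treatment in a new trial is profitable.
#' Ties at the break-even value count as not exceeding (the ECDF is
#' right-continuous).
#'
#' @param ecdf A [yield_diff_ecdf()].
#' @param break_even Break-even yield(s), kg/ha.
#' @return Percent in `[0, 100]`, vectorised over `break_even`.
#' @export
chance_exceed_cost <- function(ecdf, break_even) {
  stopifnot(inherits(ecdf, "yield_diff_ecdf"))
  100 * (1 - ecdf$F(break_even))
}

#' Net economic return of the treatment
#'
#' `(mean_treated - mean_untreated) * price - total_cost`, with yields in
#' t/ha and price in USD/t, giving USD per hectare.
#'
#' @param mean_untreated,mean_treated Mean yields, t/ha (> 0).
#' @param scenario One row of [scenario_table()], or supply `price` and
#'   `total_cost` directly.
#' @param price,total_cost Numeric alternatives to `scenario`.
#' @return Net return, USD/ha.
#' @export
#' @examples
#' net_return(2.216, 2.518, price = 384.2, total_cost = 24)  # ~92 USD/ha
net_return <- function(mean_untreated, mean_treated, scenario = NULL,
                       price = NULL, total_cost = NULL) {
  if (any(mean_untreated <= 0) || any(mean_treated <= 0))
    stop("mean yields must be > 0", call. = FALSE)
  if (!is.null(scenario)) {
    price <- scenario$price
    total_cost <- scenario$total_cost
  }
  (mean_treated - mean_untreated) * price - total_cost
}

#' Break-even table across scenarios for one crop's trials
#'
#' Combines [scenario_table()], [break_even_yield()] and
#' [chance_exceed_cost()] into the three-scenario sensitivity table for one
#' crop, and appends the net return computed from the trials' mean yields.
#'
#' @param records Trial records for a single crop.
#' @param pc The crop's [price_cost()].
#' @return data.frame with one row per scenario: `crop`, `scenario`,
#'   `price`, `total_cost`, `break_even_yield` (kg/ha),
#'   `chance_exceed_cost` (%), `net_return` (USD/ha).
#' @export
break_even_table <- function(records, pc) {
  if (length(unique(records$crop)) != 1L)
    stop("break_even_table() expects records for a single crop",
         call. = FALSE)
  sc <- scenario_table(pc)
  ec <- yield_diff_ecdf(records)
  be <- break_even_yield(sc)
  sc$break_even_yield <- be
  sc$chance_exceed_cost <- chance_exceed_cost(ec, be)
  sc$net_return <- net_return(mean(records$untreated_yield),
                              mean(records$treated_yield), sc)
  sc
}
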
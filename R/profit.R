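#' Beekeeper profit-model parameters
#'
#' The per-colony economics of a beekeeper who produces honey and rents
#' colonies for commercial highbush-blueberry pollination. Computation is on
#' the pound basis: honey revenue is price per lb times a whole-pound yield
#' (the $/kg and kg figures often quoted alongside are rounded display
#' values and do not reproduce the published cent-exact profits).
#'
#' Defaults: honey price $8.42/lb and full-season yield 59 lbs per colony
#' (survey averages for B.C. beekeepers renting colonies for pollination);
#' blueberry pollination rental fee $124/colony; seasonal operating cost
#' $400/colony; colony replacement $240 by package, $55 by split with a
#' purchased queen ($10 labour + $45 queen), $28.75 by split with an in-house
#' queen ($10 labour + $18.75 queen rearing). Honey-yield reductions after
#' pesticide exposure: 30% when sublethal effects manifest in early summer
#' (the colony is impaired all season), 7% when they manifest in the fall,
#' and 18.5% (the mid-way point) for a colony that dies in the fall, its
#' productivity having deteriorated through the season.
#'
#' @param honey_price_per_lb honey price, $/lb.
#' @param base_honey_yield_lb full-season honey yield, lbs/colony.
#' @param rental_fee blueberry pollination rental fee, $/colony.
#' @param operating_cost seasonal colony operating cost, $/colony.
#' @param replacement_cost_package cost of replacing a dead colony with a
#'   purchased package, $.
#' @param replacement_cost_split_purchased_queen cost of a split plus a
#'   purchased queen, $.
#' @param replacement_cost_split_inhouse_queen cost of a split plus an
#'   in-house queen, $.
#' @param reduction_sublethal_summer,reduction_sublethal_fall,reduction_lethal_fall
#'   fractional honey-yield reductions in `[0, 1]`; must be ordered
#'   fall-sublethal <= fall-lethal <= summer-sublethal.
#' @return A list of class `beecotox_profit_params`.
#' @export
profit_parameters <- function(honey_price_per_lb = 8.42,
                              base_honey_yield_lb = 59,
                              rental_fee = 124,
                              operating_cost = 400,
                              replacement_cost_package = 240,
                              replacement_cost_split_purchased_queen = 55,
                              replacement_cost_split_inhouse_queen = 28.75,
                              reduction_sublethal_summer = 0.30,
                              reduction_sublethal_fall = 0.07,
                              reduction_lethal_fall = 0.185) {
  p <- structure(
    list(honey_price_per_lb = honey_price_per_lb,
         base_honey_yield_lb = base_honey_yield_lb,
         rental_fee = rental_fee,
         operating_cost = operating_cost,
         replacement_cost_package = replacement_cost_package,
         replacement_cost_split_purchased_queen =
           replacement_cost_split_purchased_queen,
         replacement_cost_split_inhouse_queen =
           replacement_cost_split_inhouse_queen,
         reduction_sublethal_summer = reduction_sublethal_summer,
         reduction_sublethal_fall = reduction_sublethal_fall,
         reduction_lethal_fall = reduction_lethal_fall),
    class = "beecotox_profit_params"
  )
  validate_profit_parameters(p)
}

validate_profit_parameters <- function(p) {
  monetary <- c("honey_price_per_lb", "base_honey_yield_lb", "rental_fee",
                "operating_cost", "replacement_cost_package",
                "replacement_cost_split_purchased_queen",
                "replacement_cost_split_inhouse_queen")
  for (f in monetary) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0) {
      abort_config(f, "must be a single non-negative number")
    }
  }
  fractions <- c("reduction_sublethal_summer", "reduction_sublethal_fall",
                 "reduction_lethal_fall")
  for (f in fractions) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0 || p[[f]] > 1) {
      abort_config(f, "must be a fraction in [0, 1]")
    }
  }
  if (!(p$reduction_sublethal_fall <= p$reduction_lethal_fall &&
        p$reduction_lethal_fall <= p$reduction_sublethal_summer)) {
    abort_config("reduction fractions",
                 "must satisfy fall-sublethal <= fall-lethal <= summer-sublethal")
  }
  p
}

#' @export
print.beecotox_profit_params <- function(x, ...) {
  cat("<beecotox profit parameters>\n")
  cat(sprintf("  honey: $%.2f/lb x %d lbs; rental fee $%.2f; operating cost $%.2f\n",
              x$honey_price_per_lb, as.integer(x$base_honey_yield_lb),
              x$rental_fee, x$operating_cost))
  cat(sprintf("  replacement: package $%.2f, split+queen $%.2f, split in-house $%.2f\n",
              x$replacement_cost_package,
              x$replacement_cost_split_purchased_queen,
              x$replacement_cost_split_inhouse_queen))
  cat(sprintf("  yield reductions: summer sublethal %d%%, fall sublethal %d%%, fall lethal %.1f%%\n",
              round(100 * x$reduction_sublethal_summer),
              round(100 * x$reduction_sublethal_fall),
              100 * x$reduction_lethal_fall))
  invisible(x)
}

#' Construct an exposure scenario
#'
#' A scenario is a cell of the timing x effect x replacement grid plus a
#' health value h in `[0, 1]`. h captures indirect (behavioural and
#' physiological) colony impairment and scales down honey revenue: h = 0
#' means no indirect impact, h = 1 total loss of productivity. The grid
#' follows the study assumptions: no effect means no exposure (h = 0, no
#' replacement); a lethal effect in early summer fixes h = 1 (the colony is
#' dead for the whole production season) while a fall death leaves h free
#' (the colony produced at reduced capacity before dying); lethal effects
#' require a replacement method and sublethal effects forbid one.
#'
#' @param timing `"none"`, `"early_summer"` or `"fall"` — when symptoms are
#'   first identified.
#' @param effect `"none"`, `"sublethal"` or `"lethal"`.
#' @param replacement `"not_applicable"`, `"package"`,
#'   `"split_purchased_queen"` or `"split_inhouse_queen"`.
#' @param health h in `[0, 1]`.
#' @return A list of class `beecotox_scenario`.
#' @export
scenario <- function(timing = c("none", "early_summer", "fall"),
                     effect = c("none", "sublethal", "lethal"),
                     replacement = c("not_applicable", "package",
                                     "split_purchased_queen",
                                     "split_inhouse_queen"),
                     health = 0) {
  timing <- match.arg(timing)
  effect <- match.arg(effect)
  replacement <- match.arg(replacement)
  if (!is.numeric(health) || length(health) != 1 || is.na(health) ||
      health < 0 || health > 1) {
    abort_scenario("health must be a single value in [0, 1]")
  }
  if (effect == "none") {
    if (timing != "none" || health != 0 || replacement != "not_applicable") {
      abort_scenario(
        "effect 'none' requires timing 'none', health 0 and no replacement")
    }
  } else if (timing == "none") {
    abort_scenario("effects require a timing of 'early_summer' or 'fall'")
  }
  if (effect == "lethal" && timing == "early_summer" && health != 1) {
    abort_scenario("a summer-lethal scenario has health fixed at 1")
  }
  if (effect == "lethal" && replacement == "not_applicable") {
    abort_scenario("a lethal scenario needs a replacement method")
  }
  if (effect == "sublethal" && replacement != "not_applicable") {
    abort_scenario("a sublethal scenario takes no replacement")
  }
  structure(list(timing = timing, effect = effect,
                 replacement = replacement, health = health),
            class = "beecotox_scenario")
}

abort_scenario <- function(msg) {
  rlang::abort(paste0("invalid scenario: ", msg),
               class = "beecotox_scenario_error")
}

#' Effective honey yield under a scenario
#'
#' Applies the scenario's direct honey-production effect to the base yield
#' and rounds half-up to whole pounds (revenue is computed from whole-pound
#' crops): no effect keeps the full 59 lbs; sublethal effects reduce it by
#' 30% (summer, 41 lbs) or 7% (fall, 55 lbs); a summer death yields nothing;
#' a fall death reduces it by 18.5% (48 lbs).
#'
#' @param params a [profit_parameters()] object.
#' @param scenario a [scenario()] object.
#' @return Whole-pound yield (numeric).
#' @export
effective_honey_yield <- function(params, scenario) {
  params <- validate_profit_parameters(params)
  base <- params$base_honey_yield_lb
  reduction <- if (scenario$effect == "none") {
    0
  } else if (scenario$effect == "sublethal") {
    if (scenario$timing == "early_summer") params$reduction_sublethal_summer
    else params$reduction_sublethal_fall
  } else if (scenario$timing == "early_summer") {
    return(0)
  } else {
    params$reduction_lethal_fall
  }
  round_half_up(base * (1 - reduction))
}

replacement_cost <- function(params, replacement) {
  switch(replacement,
    not_applicable = 0,
    package = params$replacement_cost_package,
    split_purchased_queen = params$replacement_cost_split_purchased_queen,
    split_inhouse_queen = params$replacement_cost_split_inhouse_queen
  )
}

#' Per-colony profit under an exposure scenario
#'
#' Evaluates the seasonal profit
#' \deqn{\pi = (1 - h)\,P\,Q + RF_{bl} - (C_{op} + C_{rep})}
#' where P is the honey price ($/lb), Q the scenario's whole-pound effective
#' yield, h the health variable scaling honey revenue for indirect effects,
#' RF_bl the pollination rental fee, C_op the seasonal operating cost and
#' C_rep the replacement cost (0 when no replacement applies). All currency
#' is carried in integer cents, so results are exact to the cent.
#'
#' @inheritParams effective_honey_yield
#' @param health optional override of the scenario's health value (vectorised
#'   over h; used by [profit_curve()]).
#' @return Profit in dollars, exact to the cent.
#' @examples
#' colony_profit(profit_parameters(), scenario())  # 220.78
#' @export
colony_profit <- function(params, scenario, health = NULL) {
  params <- validate_profit_parameters(params)
  h <- if (is.null(health)) scenario$health else health
  if (any(h < 0 | h > 1)) {
    abort_validation("health values must lie in [0, 1]")
  }
  revenue_cents <- honey_revenue_cents(params, scenario)
  profit_cents <- to_cents(from_cents(revenue_cents) * (1 - h)) +
    to_cents(params$rental_fee) -
    to_cents(params$operating_cost) -
    to_cents(replacement_cost(params, scenario$replacement))
  from_cents(profit_cents)
}

honey_revenue_cents <- function(params, scenario) {
  yield <- effective_honey_yield(params, scenario)
  to_cents(params$honey_price_per_lb * yield)
}

#' Break-even health value
#'
#' Solves \eqn{\pi(h) = 0} for the health variable:
#' \deqn{h^* = 1 - \frac{C_{op} + C_{rep} - RF_{bl}}{P\,Q}}
#' reported half-up-rounded to 4 decimals (`h`), with the unrounded solution
#' kept alongside (`h_exact`, which zeroes the profit to within half a cent).
#' When even h = 0 is unprofitable (\eqn{h^* < 0}) the sentinel `"none (<0)"`
#' is returned; when the colony is profitable even at h = 1 (\eqn{h^* > 1})
#' the sentinel is `"any"`. Undefined when the scenario produces no honey
#' revenue.
#'
#' @inheritParams effective_honey_yield
#' @return A list with `h` (4-decimal reported value, NA for sentinel cases),
#'   `h_exact` (unrounded solution) and `label` (4-decimal string,
#'   `"none (<0)"` or `"any"`).
#' @examples
#' break_even_health(profit_parameters(),
#'                   scenario("early_summer", "sublethal"))$label # "0.2005"
#' @export
break_even_health <- function(params, scenario) {
  params <- validate_profit_parameters(params)
  revenue <- from_cents(honey_revenue_cents(params, scenario))
  if (revenue <= 0) {
    rlang::abort(
      "break-even health is undefined when the scenario has no honey revenue",
      class = "beecotox_break_even_error"
    )
  }
  fixed <- params$operating_cost +
    replacement_cost(params, scenario$replacement) - params$rental_fee
  h_exact <- 1 - fixed / revenue
  h_star <- round_half_up(h_exact, 4)
  if (h_star < 0) {
    list(h = NA_real_, h_exact = h_exact, label = "none (<0)")
  } else if (h_star > 1) {
    list(h = NA_real_, h_exact = h_exact, label = "any")
  } else {
    list(h = h_star, h_exact = h_exact, label = sprintf("%.4f", h_star))
  }
}

#' Evaluate the full scenario grid
#'
#' One row per cell of the timing x effect x replacement grid: the no-effect
#' baseline, sublethal scenarios in early summer and fall, and lethal
#' scenarios in early summer and fall under each replacement method. Each row
#' reports the effective yield, honey revenue, profit at h = 0 and h = 1, and
#' the break-even health value. Summer-lethal cells have h fixed at 1, so
#' their h = 0 profit and break-even are not applicable (NA); fall-lethal
#' cells are evaluated at both ends of h.
#'
#' @param params a [profit_parameters()] object.
#' @param replacements replacement methods to expand lethal scenarios over.
#' @return A tibble with columns `timing`, `effect`, `replacement`,
#'   `honey_yield_lb`, `honey_revenue`, `profit_h0`, `profit_h1`,
#'   `break_even_h` (numeric, NA for sentinels and n/a cells) and
#'   `break_even_label`.
#' @export
scenario_grid <- function(params = profit_parameters(),
                          replacements = c("package",
                                           "split_purchased_queen")) {
  cells <- list(scenario("none", "none"))
  for (timing in c("early_summer", "fall")) {
    cells <- c(cells, list(scenario(timing, "sublethal")))
    for (repl in replacements) {
      h <- if (timing == "early_summer") 1 else 0
      cells <- c(cells, list(scenario(timing, "lethal", repl, health = h)))
    }
  }
  rows <- lapply(cells, function(sc) {
    summer_lethal <- sc$effect == "lethal" && sc$timing == "early_summer"
    revenue <- from_cents(honey_revenue_cents(params, sc))
    be <- if (revenue > 0 && sc$effect != "none" && !summer_lethal) {
      break_even_health(params, sc)
    } else {
      list(h = NA_real_, label = "n/a")
    }
    tibble::tibble(
      timing = sc$timing, effect = sc$effect, replacement = sc$replacement,
      honey_yield_lb = effective_honey_yield(params, sc),
      honey_revenue = revenue,
      profit_h0 = if (summer_lethal) NA_real_
                  else colony_profit(params, sc, health = 0),
      profit_h1 = if (sc$effect == "none") NA_real_
                  else colony_profit(params, sc, health = 1),
      break_even_h = be$h,
      break_even_label = be$label
    )
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity analysis over parameter overrides
#'
#' Re-evaluates the scenario grid under one-at-a-time parameter overrides,
#' ceteris paribus: honey production at 10%, 50% or 90% of the full crop
#' (whole-pound yields 6, 30 and 53 lbs, applied to sublethal scenarios);
#' pollination rental fee reduced to $62 (50%) or $93 (75%) for colonies too
#' weak to earn the full fee; and colony replacement by a split with an
#' in-house queen ($28.75).
#'
#' @param params baseline [profit_parameters()].
#' @param overrides a named list of overrides, each a list with exactly one
#'   of `honey_fraction` (in (0, 1]), `rental_fee` ($) or `replacement`
#'   (a replacement method name). Defaults to the full published override set.
#' @return A tibble: the scenario grid per override, with an `override`
#'   label column prepended.
#' @export
sensitivity_analysis <- function(params = profit_parameters(),
                                 overrides = default_sensitivity_overrides()) {
  out <- lapply(names(overrides), function(label) {
    ov <- overrides[[label]]
    if (length(ov) != 1 || is.null(names(ov))) {
      abort_config("overrides",
                   sprintf("entry '%s' must name exactly one parameter", label))
    }
    key <- names(ov)[1]
    value <- ov[[1]]
    p <- params
    replacements <- c("package", "split_purchased_queen")
    if (key == "honey_fraction") {
      if (!is.numeric(value) || value <= 0 || value > 1) {
        abort_config("honey_fraction", "must lie in (0, 1]")
      }
      # the fraction replaces every direct-effect reduction: the colony
      # produces fraction x full crop whenever it produces at all
      p$reduction_sublethal_summer <- 1 - value
      p$reduction_sublethal_fall <- 1 - value
      p$reduction_lethal_fall <- 1 - value
    } else if (key == "rental_fee") {
      p$rental_fee <- value
    } else if (key == "replacement") {
      if (!value %in% c("package", "split_purchased_queen",
                        "split_inhouse_queen")) {
        abort_config("replacement", sprintf("unknown method '%s'", value))
      }
      replacements <- value
    } else {
      abort_config(key, "is not a recognised sensitivity override")
    }
    grid <- scenario_grid(p, replacements = replacements)
    tibble::tibble(override = label, grid)
  })
  dplyr::bind_rows(out)
}

#' @rdname sensitivity_analysis
#' @export
default_sensitivity_overrides <- function() {
  list(
    honey_10pct = list(honey_fraction = 0.10),
    honey_50pct = list(honey_fraction = 0.50),
    honey_90pct = list(honey_fraction = 0.90),
    rental_fee_50pct = list(rental_fee = 62),
    rental_fee_75pct = list(rental_fee = 93),
    split_inhouse_queen = list(replacement = "split_inhouse_queen")
  )
}

#' Profit as a function of the health variable
#'
#' Profit is linear in h with slope minus the scenario's honey revenue;
#' evaluating it on a grid of h values gives the line for plotting or for
#' reading off the break-even crossing.
#'
#' @inheritParams effective_honey_yield
#' @param h_grid numeric vector of health values in `[0, 1]`.
#' @return A tibble with columns `h` and `profit`.
#' @export
profit_curve <- function(params, scenario, h_grid = seq(0, 1, by = 0.05)) {
  if (any(h_grid < 0 | h_grid > 1)) {
    abort_validation("h values must lie in [0, 1]")
  }
  tibble::tibble(
    h = h_grid,
    profit = vapply(h_grid, function(h) colony_profit(params, scenario, h),
                    numeric(1))
  )
}

#' Plot profit-versus-health lines for a set of scenarios
#'
#' Convenience ggplot of [profit_curve()] lines for each scenario, with the
#' zero-profit line marked. Requires ggplot2.
#'
#' @param params a [profit_parameters()] object.
#' @param scenarios a named list of [scenario()] objects.
#' @return A ggplot object.
#' @export
plot_profit_curves <- function(params = profit_parameters(),
                               scenarios = list(
                                 `summer sublethal` = scenario("early_summer", "sublethal"),
                                 `fall sublethal` = scenario("fall", "sublethal"),
                                 `fall lethal (package)` = scenario("fall", "lethal", "package"),
                                 `fall lethal (split)` = scenario("fall", "lethal", "split_purchased_queen")
                               )) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plot_profit_curves() requires the ggplot2 package")
  }
  curves <- dplyr::bind_rows(lapply(names(scenarios), function(nm) {
    tibble::tibble(scenario = nm, profit_curve(params, scenarios[[nm]]))
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$h, y = .data$profit,
                               colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "health variable h (indirect impairment)",
                  y = "per-colony profit ($)", colour = NULL)
}
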
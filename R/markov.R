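#' Markov cohort model
#'
#' The second model part propagates the post-surgery cohort through three
#' health states - 'post-surgery, no complications', 'post-surgery, post
#' stroke' and 'dead' - in annual cycles until the whole cohort is absorbed
#' in 'dead' (or the terminal age of the life table is reached). The two
#' alive states share the same mortality: during the post-surgery excess
#' window (2 years for patients under 61 at surgery, 5 years for older
#' bands) the band-specific excess risk replaces background mortality, and
#' the age- and sex-matched life table applies thereafter. Each cycle
#' accrues life-years, quality-adjusted life-years (utility 1 without
#' complications, 0.439 post stroke) and state costs, discounted at the
#' configured annual rates. No half-cycle correction is applied: transitions
#' and rewards are taken at end of cycle.
#'
#' @name markov-model
NULL

#' Discount factor for an annual cycle
#'
#' @param rate Annual discount rate, >= 0.
#' @param cycle Cycle index (0 = time of surgery).
#' @return `(1 + rate)^(-cycle)`.
#' @examples
#' discount_factor(0.04, 1)  # 0.9615
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(all(rate >= 0), all(cycle >= 0))
  (1 + rate)^(-cycle)
}

#' Read or write a life table as CSV
#'
#' The on-disk format is a plain CSV with columns `sex`, `age`, `qx`.
#'
#' @param path File path.
#' @return `read_lifetable()` returns a validated life-table tibble.
#' @export
read_lifetable <- function(path) {
  lt <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(),
    age = readr::col_integer(),
    qx = readr::col_double()
  ))
  validate_lifetable(lt)
  lt
}

#' @rdname read_lifetable
#' @param lifetable A life-table tibble.
#' @export
write_lifetable <- function(lifetable, path) {
  validate_lifetable(lifetable)
  readr::write_csv(lifetable, path)
  invisible(path)
}

validate_lifetable <- function(lifetable) {
  needed <- c("sex", "age", "qx")
  if (!all(needed %in% names(lifetable))) {
    stop("life table needs columns sex, age, qx", call. = FALSE)
  }
  if (any(lifetable$qx < 0 | lifetable$qx > 1)) {
    stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  }
  for (s in unique(lifetable$sex)) {
    sub <- lifetable[lifetable$sex == s, ]
    ages <- sort(sub$age)
    if (!identical(as.integer(ages), as.integer(seq(min(ages), max(ages))))) {
      stop(sprintf("life table for sex '%s' has gaps or duplicate ages", s),
           call. = FALSE)
    }
    if (sub$qx[which.max(sub$age)] != 1) {
      stop(sprintf("life table for sex '%s' must end with qx = 1", s),
           call. = FALSE)
    }
  }
  invisible(lifetable)
}

lifetable_qx <- function(lifetable, sex, ages) {
  sub <- lifetable[lifetable$sex == sex, ]
  if (nrow(sub) == 0) {
    stop(sprintf("life table has no rows for sex '%s'", sex), call. = FALSE)
  }
  idx <- match(ages, sub$age)
  if (anyNA(idx)) {
    stop(sprintf("life table for sex '%s' does not cover ages %s", sex,
                 paste(ages[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  sub$qx[idx]
}

excess_band <- function(age) {
  if (age < 61) {
    list(param = "excess_mortality_lt61", window = 2L)
  } else if (age <= 70) {
    list(param = "excess_mortality_61_70", window = 5L)
  } else {
    list(param = "excess_mortality_gt70", window = 5L)
  }
}

#' Annual mortality probabilities faced by a surgical cohort
#'
#' Builds the per-cycle death probability vector for a patient of the given
#' age and sex: the age-band excess risk during its post-surgery window
#' (replacing, not adding to, background mortality; the band is fixed by age
#' at surgery), the life table thereafter. Cycle `t` uses the life-table row
#' for attained age `age + t - 1` (the age at the start of the cycle), so
#' the final cycle starts at the terminal age and has probability 1.
#'
#' @param age Age at surgery (years).
#' @param sex `"male"` or `"female"`.
#' @param lifetable A life-table tibble.
#' @param params A `param_set`.
#' @return Numeric vector of per-cycle death probabilities, one per cycle
#'   until the terminal age.
#' @export
cycle_mortality <- function(age, sex, lifetable, params) {
  stopifnot(inherits(params, "param_set"))
  terminal <- max(lifetable$age[lifetable$sex == sex])
  if (age > terminal) stop("age exceeds the life-table terminal age", call. = FALSE)
  n_cycles <- terminal - age + 1L
  start_ages <- age + seq_len(n_cycles) - 1L
  q <- lifetable_qx(lifetable, sex, start_ages)
  band <- excess_band(age)
  w <- min(band$window, n_cycles)
  q[seq_len(w)] <- param_value(params, band$param)
  q
}

# Vectorised core of the cohort run: everything downstream of the starting
# state distribution is a survival product, because both alive states share
# one mortality and there are no transitions between them.
cohort_engine <- function(p_no_complication, p_post_stroke, q, values) {
  alive0 <- p_no_complication + p_post_stroke
  n <- length(q)
  survival <- alive0 * cumprod(1 - q)
  nc_share <- if (alive0 > 0) p_no_complication / alive0 else 0

  cycles <- seq_len(n)
  v_e <- discount_factor(values[["discount_effects"]], cycles)
  v_c <- discount_factor(values[["discount_costs"]], cycles)
  u_nc <- values[["utility_no_complication"]]
  u_ps <- values[["utility_post_stroke"]]
  c_ps <- values[["cost_post_stroke_annual"]]

  occ_nc <- survival * nc_share
  occ_ps <- survival * (1 - nc_share)
  ly_t <- survival
  qaly_t <- occ_nc * u_nc + occ_ps * u_ps
  cost_t <- occ_ps * c_ps

  list(
    cycles = cycles,
    occ_nc = occ_nc, occ_ps = occ_ps, occ_dead = 1 - survival,
    ly_t = ly_t, qaly_t = qaly_t, cost_t = cost_t,
    v_e = v_e, v_c = v_c,
    life_years = sum(ly_t * v_e),
    qalys = sum(qaly_t * v_e),
    cost_state = sum(cost_t * v_c),
    life_years_undiscounted = sum(ly_t),
    qalys_undiscounted = sum(qaly_t),
    cost_state_undiscounted = sum(cost_t)
  )
}

#' Run the Markov cohort model for one starting-state distribution
#'
#' Places the decision-tree outcome into the three health states (fatal
#' strokes and other early deaths start dead, non-fatal stroke survivors
#' start post stroke, the remainder without complications) and cycles the
#' cohort until full absorption.
#'
#' @param outcome One-row tibble from [strategy_outcome()] (or any row with
#'   columns `p_stroke_nonfatal`, `p_stroke_fatal`, `p_death_other`,
#'   `p_no_complication`).
#' @param age Age at surgery.
#' @param sex `"male"` or `"female"`.
#' @param lifetable A life-table tibble covering `age` to its terminal age.
#' @param params A `param_set`.
#' @return A `cohort_trace`: a tibble with one row per cycle (cycle 0 is the
#'   starting distribution) holding state occupancies and cumulative
#'   discounted and undiscounted life-years, QALYs and state costs, with the
#'   lifetime totals in `attr(, "totals")`.
#' @export
run_cohort <- function(outcome, age, sex, lifetable, params) {
  stopifnot(inherits(params, "param_set"))
  values <- param_values(params)
  if (values[["utility_post_stroke"]] < 0 || values[["utility_no_complication"]] < 0) {
    stop("state utilities must be non-negative", call. = FALSE)
  }
  p_ps <- outcome$p_stroke_nonfatal
  p_dead <- outcome$p_stroke_fatal + outcome$p_death_other
  p_nc <- outcome$p_no_complication
  if (abs(p_ps + p_dead + p_nc - 1) > 1e-9) {
    stop("starting-state probabilities must sum to 1", call. = FALSE)
  }

  q <- cycle_mortality(age, sex, lifetable, params)
  eng <- cohort_engine(p_nc, p_ps, q, values)

  trace <- tibble::tibble(
    cycle = c(0L, eng$cycles),
    age = age + c(0L, eng$cycles),
    p_no_complication = c(p_nc, eng$occ_nc),
    p_post_stroke = c(p_ps, eng$occ_ps),
    p_dead = c(p_dead, eng$occ_dead),
    life_years = cumsum(c(0, eng$ly_t * eng$v_e)),
    qalys = cumsum(c(0, eng$qaly_t * eng$v_e)),
    cost_state = cumsum(c(0, eng$cost_t * eng$v_c)),
    life_years_undiscounted = cumsum(c(0, eng$ly_t)),
    qalys_undiscounted = cumsum(c(0, eng$qaly_t)),
    cost_state_undiscounted = cumsum(c(0, eng$cost_t))
  )
  structure(trace,
            totals = eng[c("life_years", "qalys", "cost_state",
                           "life_years_undiscounted", "qalys_undiscounted",
                           "cost_state_undiscounted")],
            class = c("cohort_trace", class(trace)))
}

#' Lifetime totals for one strategy
#'
#' Adds the decision-stage one-time costs to the discounted long-run state
#' costs of a completed cohort trace: surgery (base cost plus the major
#' adaptation increment weighted by the major-adaptation probability), the
#' diagnostic device (modified TEE strategy only), and the early event costs
#' (death, fatal stroke, acute non-fatal stroke).
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param outcome The [strategy_outcome()] row the trace was started from.
#' @param params A `param_set`.
#' @param strategy `"mp"` or `"tee"`.
#' @return A one-row tibble with `strategy`, `cost` (total discounted),
#'   `cost_decision_stage`, `cost_state`, `life_years`, `qalys`, and the
#'   undiscounted companions.
#' @export
strategy_totals <- function(trace, outcome, params, strategy = c("mp", "tee")) {
  strategy <- match.arg(strategy)
  totals <- attr(trace, "totals")
  v <- param_values(params)
  one_time <- decision_stage_cost(outcome, v, strategy)
  tibble::tibble(
    strategy = strategy,
    cost = one_time + totals$cost_state,
    cost_decision_stage = one_time,
    cost_state = totals$cost_state,
    life_years = totals$life_years,
    qalys = totals$qalys,
    life_years_undiscounted = totals$life_years_undiscounted,
    qalys_undiscounted = totals$qalys_undiscounted,
    cost_undiscounted = one_time + totals$cost_state_undiscounted
  )
}

decision_stage_cost <- function(outcome, values, strategy) {
  values[["cost_surgery_base"]] +
    (strategy == "tee") * values[["cost_tee_device"]] +
    outcome$p_major_adaptation *
      (values[["cost_surgery_major_adaptation"]] - values[["cost_surgery_base"]]) +
    outcome$p_death_other * values[["cost_death"]] +
    outcome$p_stroke_fatal * values[["cost_fatal_stroke"]] +
    outcome$p_stroke_nonfatal * values[["cost_nonfatal_stroke_acute"]]
}

#' Residual life expectancy from a life table
#'
#' Undiscounted expected life-years for a person of the given age and sex,
#' computed by the same end-of-cycle convention as the Markov engine (no
#' excess mortality applied).
#'
#' @param lifetable A life-table tibble.
#' @param sex `"male"` or `"female"`.
#' @param age Starting age.
#' @return Expected remaining life-years.
#' @export
life_expectancy <- function(lifetable, sex, age) {
  terminal <- max(lifetable$age[lifetable$sex == sex])
  start_ages <- age + seq_len(terminal - age + 1L) - 1L
  q <- lifetable_qx(lifetable, sex, start_ages)
  sum(cumprod(1 - q))
}
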
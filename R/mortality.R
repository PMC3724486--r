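#' Early (within-30-day) surgical mortality
#'
#' Early mortality enters the decision tree as a cohort-average probability,
#' typically a logistic EuroSCORE prediction calibrated to contemporary
#' practice. Because ascending-aorta atherosclerosis is treated as equivalent
#' to the extra-cardiac arteriopathy risk factor, the cohort average is split
#' into strata with and without atherosclerosis via an odds ratio, keeping the
#' prevalence-weighted average exact.
#'
#' @name early-mortality
NULL

#' Logistic surgical risk calculator
#'
#' Computes the inverse-logit of `intercept + sum(coefficient * indicator)`,
#' the form of logistic surgical risk scores such as EuroSCORE. Coefficient
#' values are user-supplied (e.g. via the `euroscore:` config block); none are
#' shipped as authoritative constants.
#'
#' @param indicators Named numeric vector of risk-factor values (binary
#'   indicators or continuous factors). Must contain every factor named in
#'   `coefficients` and nothing else.
#' @param coefficients Named numeric vector of factor coefficients, plus an
#'   `intercept` element.
#' @return Predicted early-mortality probability, strictly in (0, 1).
#' @examples
#' euroscore_logistic(c(), c(intercept = -4))  # 0.0180
#' @export
euroscore_logistic <- function(indicators, coefficients) {
  coefficients <- unlist(coefficients)
  indicators <- unlist(indicators) %||% stats::setNames(numeric(0), character(0))
  if (!"intercept" %in% names(coefficients)) {
    stop("coefficients must include an 'intercept' element", call. = FALSE)
  }
  factors <- setdiff(names(coefficients), "intercept")
  unknown <- setdiff(names(indicators), factors)
  if (length(unknown) > 0) {
    stop("unknown risk factor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(factors, names(indicators))
  if (length(missing) > 0) {
    stop("missing risk factor value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lp <- coefficients[["intercept"]] +
    sum(coefficients[factors] * indicators[factors])
  stats::plogis(lp)
}

#' Calibrate a predicted mortality risk
#'
#' Applies a proportional reduction to a predicted risk, as used to bring
#' EuroSCORE predictions (which overestimate risk in contemporary cohorts)
#' down to observed levels; the baseline calibration reduction is 71%.
#'
#' @param predicted Predicted probability, in (0, 1).
#' @param reduction Proportional reduction, in \[0, 1).
#' @return `predicted * (1 - reduction)`.
#' @examples
#' calibrate_mortality(0.0359, 0.71)  # 0.0104
#' @export
calibrate_mortality <- function(predicted, reduction) {
  if (any(predicted <= 0 | predicted >= 1)) {
    stop("'predicted' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(reduction < 0 | reduction >= 1)) {
    stop("'reduction' must lie in [0, 1)", call. = FALSE)
  }
  predicted * (1 - reduction)
}

#' Stratify average early mortality by atherosclerosis status
#'
#' Splits a cohort-average early-mortality probability into the stratum
#' without atherosclerosis and the stratum with atherosclerosis such that (i)
#' the prevalence-weighted average reproduces `m_avg` and (ii) the odds ratio
#' between the strata equals `arteriopathy_or`. The unique solution is found
#' by bisection on the no-atherosclerosis mortality (tolerance 1e-12, at most
#' 200 iterations), exploiting that the recombined average is monotone in it.
#'
#' @param m_avg Cohort-average early mortality, in (0, 1).
#' @param prevalence Atherosclerosis prevalence, in \[0, 1\].
#' @param arteriopathy_or Odds ratio for early death with vs. without
#'   atherosclerosis; must be positive.
#' @return A one-row tibble with columns `m_avg`, `prevalence`,
#'   `arteriopathy_or`, `m_no_athero`, `m_athero`.
#' @examples
#' stratify_mortality(0.0161, 0.20, 2.0)
#' @export
stratify_mortality <- function(m_avg, prevalence, arteriopathy_or) {
  if (m_avg <= 0 || m_avg >= 1) {
    stop("'m_avg' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (prevalence < 0 || prevalence > 1) {
    stop("'prevalence' must lie in [0, 1]", call. = FALSE)
  }
  if (arteriopathy_or <= 0) {
    stop("'arteriopathy_or' must be positive", call. = FALSE)
  }

  or_shift <- function(p, or) {
    odds <- or * p / (1 - p)
    odds / (1 + odds)
  }

  if (arteriopathy_or == 1) {
    m_no <- m_avg
    m_yes <- m_avg
  } else if (prevalence == 0) {
    m_no <- m_avg
    m_yes <- or_shift(m_avg, arteriopathy_or)
  } else if (prevalence == 1) {
    m_yes <- m_avg
    m_no <- or_shift(m_avg, 1 / arteriopathy_or)
  } else {
    recombined <- function(m_no) {
      (1 - prevalence) * m_no + prevalence * or_shift(m_no, arteriopathy_or)
    }
    lo <- 0
    hi <- min(m_avg / (1 - prevalence), 1 - 1e-12)
    if (recombined(hi) < m_avg) {
      stop("no feasible mortality stratification for these inputs",
           call. = FALSE)
    }
    for (iter in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (recombined(mid) < m_avg) lo <- mid else hi <- mid
      if (hi - lo < 1e-15) break
    }
    m_no <- (lo + hi) / 2
    m_yes <- or_shift(m_no, arteriopathy_or)
    if (abs(recombined(m_no) - m_avg) > 1e-10) {
      stop("mortality stratification failed to converge", call. = FALSE)
    }
  }

  tibble::tibble(m_avg = m_avg, prevalence = prevalence,
                 arteriopathy_or = arteriopathy_or,
                 m_no_athero = m_no, m_athero = m_yes)
}
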
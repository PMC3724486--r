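#' Synthetic life tables and baseline fixtures
#'
#' The Markov model consumes national age- and sex-specific all-cause
#' mortality tables. Since such tables cannot be bundled, a
#' Gompertz-Makeham generator produces structurally realistic synthetic
#' tables: a constant background hazard plus an exponentially age-increasing
#' senescent hazard, sex-differentiated so that female mortality sits below
#' male mortality at every age. The default fixture parameters are synthetic
#' constants in the range of Dutch adult mortality, not official statistics,
#' so downstream life-years and cost totals are structurally - not
#' numerically - comparable to results computed on real tables.
#'
#' @name lifetable-synth
NULL

#' Gompertz-Makeham hazard specification
#'
#' Annual death probability `q(age) = 1 - exp(-(makeham + a * exp(b * age)))`,
#' truncated to 1 at `terminal_age`.
#'
#' @param makeham Constant (age-independent) hazard component, >= 0.
#' @param gompertz_a Baseline senescent hazard, > 0.
#' @param gompertz_b Log-hazard slope per year of age, > 0.
#' @param terminal_age Age at which the death probability is forced to 1.
#' @return An object of class `gm_spec`.
#' @examples
#' gm_spec(5e-4, 2.7e-5, 0.093)
#' @export
gm_spec <- function(makeham, gompertz_a, gompertz_b, terminal_age = 110L) {
  if (makeham < 0) stop("'makeham' must be >= 0", call. = FALSE)
  if (gompertz_a <= 0) stop("'gompertz_a' must be > 0", call. = FALSE)
  if (gompertz_b <= 0) stop("'gompertz_b' must be > 0", call. = FALSE)
  if (terminal_age < 1) stop("'terminal_age' must be >= 1", call. = FALSE)
  structure(list(makeham = makeham, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b,
                 terminal_age = as.integer(terminal_age)),
            class = "gm_spec")
}

#' Annual death probabilities from a Gompertz-Makeham specification
#'
#' @param spec A [gm_spec()].
#' @param ages Integer vector of ages.
#' @return Numeric vector of annual death probabilities; 1 at and beyond the
#'   terminal age.
#' @export
gm_qx <- function(spec, ages) {
  stopifnot(inherits(spec, "gm_spec"))
  hazard <- spec$makeham + spec$gompertz_a * exp(spec$gompertz_b * ages)
  q <- 1 - exp(-hazard)
  q[ages >= spec$terminal_age] <- 1
  q
}

#' Build a synthetic two-sex life table
#'
#' @param spec_male,spec_female [gm_spec()] objects; both must share the
#'   same terminal age.
#' @return A life table tibble with columns `sex` (`"male"`/`"female"`),
#'   `age` (0 to terminal age) and `qx` (annual death probability). Checked
#'   for non-decreasing `qx` and `qx = 1` at the terminal age.
#' @examples
#' lt <- make_lifetable(gm_spec(5e-4, 2.7e-5, 0.093),
#'                      gm_spec(3e-4, 1.35e-5, 0.093))
#' @export
make_lifetable <- function(spec_male, spec_female) {
  stopifnot(inherits(spec_male, "gm_spec"), inherits(spec_female, "gm_spec"))
  if (spec_male$terminal_age != spec_female$terminal_age) {
    stop("male and female specifications must share a terminal age",
         call. = FALSE)
  }
  ages <- 0:spec_male$terminal_age
  lt <- dplyr::bind_rows(
    tibble::tibble(sex = "male", age = ages, qx = gm_qx(spec_male, ages)),
    tibble::tibble(sex = "female", age = ages, qx = gm_qx(spec_female, ages))
  )
  validate_lifetable(lt)
  lt
}

#' Default synthetic life table
#'
#' Gompertz-Makeham parameters chosen once to sit in the range of Dutch
#' adult mortality (male annual death probability about 1.2% at 65; female
#' about half the male senescent hazard), with terminal age 110.
#'
#' @return A life table tibble, see [make_lifetable()].
#' @export
default_lifetable <- function() {
  make_lifetable(gm_spec(5e-4, 2.7e-5, 0.093),
                 gm_spec(3e-4, 1.35e-5, 0.093))
}

#' Baseline patient subgroups
#'
#' The 12 analysis subgroups: both sexes at ages 55, 65 and 75, each with a
#' low and a high atherosclerosis-prevalence estimate (10/20/40% and
#' 15/30/50% across the three ages), together with subgroup-average
#' calibrated EuroSCORE early-mortality predictions.
#'
#' @return A tibble with columns `subgroup` (1-12), `sex`, `age`,
#'   `prevalence`, `euroscore_mortality`.
#' @export
default_subgroups <- function() {
  tibble::tibble(
    subgroup = 1:12,
    sex = rep(c("male", "male", "female", "female"), 3),
    age = rep(c(55L, 65L, 75L), each = 4),
    prevalence = c(0.10, 0.15, 0.10, 0.15,
                   0.20, 0.30, 0.20, 0.30,
                   0.40, 0.50, 0.40, 0.50),
    euroscore_mortality = c(0.0104, 0.0108, 0.0141, 0.0146,
                            0.0161, 0.0171, 0.0214, 0.0228,
                            0.0318, 0.0336, 0.0413, 0.0434)
  )
}

#' Bundle the baseline model inputs
#'
#' @return A list with elements `params` ([default_parameters()]),
#'   `subgroups` ([default_subgroups()]) and `lifetable`
#'   ([default_lifetable()]).
#' @export
default_fixture <- function() {
  list(params = default_parameters(),
       subgroups = default_subgroups(),
       lifetable = default_lifetable())
}

#' Select subgroups with a compact selector string
#'
#' @param subgroups A subgroup tibble, see [default_subgroups()].
#' @param selector `NULL` (all subgroups) or a character vector of
#'   `"sex:age:prevalence"` strings, e.g. `"male:65:0.2"`.
#' @return The matching rows of `subgroups`.
#' @export
select_subgroups <- function(subgroups, selector = NULL) {
  if (is.null(selector) || length(selector) == 0) {
    return(subgroups)
  }
  keys <- paste(subgroups$sex, subgroups$age, subgroups$prevalence, sep = ":")
  norm <- vapply(strsplit(selector, ":", fixed = TRUE), function(parts) {
    if (length(parts) != 3) {
      stop("selector must look like 'sex:age:prevalence'; valid subgroups: ",
           paste(keys, collapse = ", "), call. = FALSE)
    }
    paste(tolower(parts[1]), as.integer(parts[2]), as.numeric(parts[3]),
          sep = ":")
  }, character(1))
  bad <- setdiff(norm, keys)
  if (length(bad) > 0) {
    stop("unknown subgroup(s): ", paste(bad, collapse = ", "),
         "; valid subgroups: ", paste(keys, collapse = ", "), call. = FALSE)
  }
  subgroups[keys %in% norm, , drop = FALSE]
}
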
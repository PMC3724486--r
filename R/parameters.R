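#' Model parameter sets
#'
#' A parameter set couples every model input with its point value and, for
#' uncertain inputs, a sampling distribution for probabilistic sensitivity
#' analysis. [default_parameters()] returns the baseline set; the same values
#' ship as a YAML config at [default_config_path()] and round-trip through
#' [load_parameter_set()].
#'
#' The probabilities `p_death_is_stroke` (13.2%), `p_stroke_nonfatal` (80.8%)
#' and `p_stroke_embolic` (71.0%) link early surgical mortality to stroke
#' incidence; test accuracy enters through sensitivity/specificity of manual
#' palpation (31%/98%) and modified TEE (97%/80%); `rr_adaptation` (0.46) is
#' the relative risk of embolic stroke after surgical adaptation;
#' `p_major_adaptation` (2.7%) the probability that a detected atherosclerosis
#' triggers a major (costly) rather than minor adaptation. Post-surgery excess
#' mortality risks replace background mortality for 2 years (<61 yr at
#' surgery) or 5 years (older bands). Costs are in euros; costs are discounted
#' at 4.0%/yr and effects at 1.5%/yr (Dutch guideline rates).
#'
#' The two long-term stroke care costs (`cost_nonfatal_stroke_acute`,
#' `cost_post_stroke_annual`) have no published point values in the model's
#' source table; the defaults (16,000 and 10,000 euros) are synthetic
#' stand-ins in the range of Dutch stroke costing studies and are plain config
#' values a user should replace with their own cost data.
#'
#' @name parameters
NULL

param_entry <- function(value, dist = NULL) {
  list(value = value, dist = dist %||% dist_spec("fixed", value))
}

#' Baseline parameter set
#'
#' @return A `param_set` object: the baseline point values and sampling
#'   distributions for every model parameter, plus the `euroscore` block
#'   (arteriopathy odds ratio used to stratify early mortality by
#'   atherosclerosis status, and optional logistic-regression coefficients).
#' @examples
#' ps <- default_parameters()
#' param_value(ps, "sens_tee")
#' @export
default_parameters <- function() {
  # Device-cost gamma is moment-matched to mean 212 and ~95% range 184-243.
  dev_sd <- (243 - 184) / 3.92
  params <- list(
    p_death_is_stroke  = param_entry(0.132, dist_spec("beta", c(14, 92))),
    p_stroke_nonfatal  = param_entry(0.808, dist_spec("beta", c(173, 41))),
    p_stroke_embolic   = param_entry(0.710, dist_spec("beta", c(107, 44))),
    sens_mp            = param_entry(0.31, dist_spec("beta", c(33, 73))),
    spec_mp            = param_entry(0.98, dist_spec("beta", c(179, 4))),
    sens_tee           = param_entry(0.97, dist_spec("beta", c(124, 4))),
    spec_tee           = param_entry(0.80, dist_spec("beta", c(173, 44))),
    rr_adaptation      = param_entry(0.46, dist_spec("lognormal", c(-0.864, 0.392))),
    p_major_adaptation = param_entry(0.027, dist_spec("beta", c(163, 5888))),
    excess_mortality_lt61  = param_entry(0.0118, dist_spec("uniform", c(0.0082, 0.0142))),
    excess_mortality_61_70 = param_entry(0.0233, dist_spec("uniform", c(0.0195, 0.0271))),
    excess_mortality_gt70  = param_entry(0.0435, dist_spec("uniform", c(0.0349, 0.0524))),
    utility_post_stroke = param_entry(0.439, dist_spec("triangular", c(0.186, 0.439, 0.653))),
    utility_no_complication = param_entry(1),
    cost_death         = param_entry(2736, dist_spec("uniform", c(1368, 5471))),
    cost_fatal_stroke  = param_entry(2736, dist_spec("uniform", c(1368, 5471))),
    cost_tee_device    = param_entry(212, dist_spec("gamma", c((212 / dev_sd)^2, dev_sd^2 / 212))),
    cost_surgery_base  = param_entry(15628),
    cost_surgery_major_adaptation = param_entry(23886),
    cost_nonfatal_stroke_acute = param_entry(16000),
    cost_post_stroke_annual    = param_entry(10000),
    discount_costs     = param_entry(0.040),
    discount_effects   = param_entry(0.015),
    mortality_calibration_reduction = param_entry(0.71)
  )
  new_param_set(params,
                euroscore = list(arteriopathy_or = exp(0.6558917),
                                 coefficients = NULL))
}

new_param_set <- function(params, euroscore) {
  ps <- structure(list(params = params, euroscore = euroscore),
                  class = "param_set")
  validate_param_set(ps)
  ps
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %d parameters (%d uncertain)\n",
              length(x$params),
              sum(vapply(x$params, function(p) p$dist$family != "fixed", logical(1)))))
  print(parameter_table(x), n = Inf)
  invisible(x)
}

param_names <- function() names(default_parameters()$params)

prob_param_names <- function() {
  c("p_death_is_stroke", "p_stroke_nonfatal", "p_stroke_embolic",
    "sens_mp", "spec_mp", "sens_tee", "spec_tee", "p_major_adaptation",
    "excess_mortality_lt61", "excess_mortality_61_70", "excess_mortality_gt70",
    "utility_post_stroke", "utility_no_complication",
    "discount_costs", "discount_effects", "mortality_calibration_reduction")
}

validate_param_set <- function(ps) {
  for (nm in names(ps$params)) {
    v <- ps$params[[nm]]$value
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
    if (nm %in% prob_param_names() && (v < 0 || v > 1)) {
      stop(sprintf("parameter '%s' = %g is outside [0, 1]", nm, v),
           call. = FALSE)
    }
    if (startsWith(nm, "cost_") && v < 0) {
      stop(sprintf("parameter '%s' = %g must be non-negative", nm, v),
           call. = FALSE)
    }
    if (nm == "rr_adaptation" && v <= 0) {
      stop("parameter 'rr_adaptation' must be positive", call. = FALSE)
    }
  }
  or <- ps$euroscore$arteriopathy_or
  if (!is.numeric(or) || length(or) != 1 || or <= 0) {
    stop("euroscore$arteriopathy_or must be a positive number", call. = FALSE)
  }
  invisible(ps)
}

#' Extract a parameter point value
#'
#' @param ps A `param_set`.
#' @param name Parameter name.
#' @return The point value.
#' @export
param_value <- function(ps, name) {
  stopifnot(inherits(ps, "param_set"))
  if (!name %in% names(ps$params)) {
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  }
  ps$params[[name]]$value
}

#' All parameter point values as a named vector
#'
#' @param ps A `param_set`.
#' @return Named numeric vector of point values.
#' @export
param_values <- function(ps) {
  stopifnot(inherits(ps, "param_set"))
  vapply(ps$params, function(p) p$value, numeric(1))
}

#' Tabulate a parameter set
#'
#' One row per parameter with its point value and the analytic mean and 95%
#' interval of its sampling distribution.
#'
#' @param ps A `param_set`.
#' @return A tibble with columns `parameter`, `value`, `family`, `mean`,
#'   `q2.5`, `q97.5`.
#' @export
parameter_table <- function(ps) {
  stopifnot(inherits(ps, "param_set"))
  purrr::imap_dfr(ps$params, function(p, nm) {
    dplyr::bind_cols(tibble::tibble(parameter = nm, value = p$value),
                     dist_summary(p$dist))
  })
}

#' Load a parameter set from a YAML or JSON config file
#'
#' The config must contain every parameter key (see [default_parameters()]);
#' unknown keys are rejected. Each entry is either a bare number (treated as
#' fixed) or a mapping `{value: ..., dist: {family: ..., params: [...]}}`.
#' An optional `euroscore:` block carries `arteriopathy_or` and, if the user
#' wants the logistic risk calculator, named `coefficients`.
#'
#' @param config_source Path to a `.yaml`/`.yml` or `.json` file, or an
#'   already-parsed named list of the same structure.
#' @return A validated `param_set`.
#' @examples
#' ps <- load_parameter_set(default_config_path())
#' param_value(ps, "sens_mp")  # 0.31
#' @export
load_parameter_set <- function(config_source) {
  config <- if (is.character(config_source)) {
    ext <- tolower(tools::file_ext(config_source))
    if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(config_source)
    } else if (ext == "json") {
      jsonlite::fromJSON(config_source, simplifyVector = TRUE)
    } else {
      stop("config file must be .yaml, .yml or .json", call. = FALSE)
    }
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a file path or a named list", call. = FALSE)
  }

  required <- param_names()
  unknown <- setdiff(names(config), c(required, "euroscore"))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("missing config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  params <- lapply(required, function(nm) {
    entry <- config[[nm]]
    if (is.numeric(entry) && length(entry) == 1) {
      param_entry(entry)
    } else if (is.list(entry) && !is.null(entry$value)) {
      dist <- if (!is.null(entry$dist)) {
        if (is.null(entry$dist$family) || is.null(entry$dist$params)) {
          stop(sprintf("parameter '%s': dist needs 'family' and 'params'", nm),
               call. = FALSE)
        }
        dist_spec(entry$dist$family, unlist(entry$dist$params))
      }
      param_entry(as.numeric(entry$value), dist)
    } else {
      stop(sprintf("parameter '%s' must be a number or {value, dist} mapping", nm),
           call. = FALSE)
    }
  })
  names(params) <- required

  euroscore <- list(arteriopathy_or = exp(0.6558917), coefficients = NULL)
  if (!is.null(config$euroscore)) {
    bad <- setdiff(names(config$euroscore), c("arteriopathy_or", "coefficients"))
    if (length(bad) > 0) {
      stop("unknown euroscore key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(config$euroscore$arteriopathy_or)) {
      euroscore$arteriopathy_or <- as.numeric(config$euroscore$arteriopathy_or)
    }
    if (!is.null(config$euroscore$coefficients)) {
      euroscore$coefficients <- unlist(config$euroscore$coefficients)
    }
  }

  new_param_set(params, euroscore)
}

#' Path to the bundled baseline config
#'
#' @return File path of the YAML config mirroring [default_parameters()].
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "teecea",
              mustWork = TRUE)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Samples every uncertain parameter once from its distribution (fixed
#' parameters keep their value) using the current RNG stream. Parameters are
#' drawn in the fixed order of [default_parameters()], so a seeded stream
#' yields reproducible draws. A whole draw that fails validation (e.g. a
#' probability outside \[0, 1\]) is rejected and redrawn; the number of
#' rejections is recorded in the `n_rejected` attribute.
#'
#' @param ps A `param_set`.
#' @param max_attempts Upper bound on rejection-resampling attempts.
#' @return A `param_set` whose values are one joint draw.
#' @export
sample_parameters <- function(ps, max_attempts = 100) {
  stopifnot(inherits(ps, "param_set"))
  rejected <- 0L
  for (attempt in seq_len(max_attempts)) {
    draw <- ps
    for (nm in names(ps$params)) {
      draw$params[[nm]]$value <- dist_sample(ps$params[[nm]]$dist, 1)
    }
    ok <- tryCatch({validate_param_set(draw); TRUE},
                   error = function(e) FALSE)
    if (ok) {
      attr(draw, "n_rejected") <- rejected
      return(draw)
    }
    rejected <- rejected + 1L
  }
  stop("failed to draw a valid parameter set after ", max_attempts,
       " attempts", call. = FALSE)
}
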
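#' Probabilistic sensitivity analysis and cost-effectiveness outputs
#'
#' [run_psa()] propagates parameter uncertainty by Monte-Carlo simulation:
#' each draw samples every uncertain parameter once from its distribution,
#' runs both diagnostic strategies deterministically through the decision
#' tree and the Markov cohort model with that common draw, and records the
#' incremental cost and QALYs of the modified TEE strategy. Downstream
#' summaries are the ICER with its dominance quadrant ([icer()]), the
#' cost-effectiveness acceptability curve ([ceac()]) and the bivariate
#' confidence ellipse on the cost-effectiveness plane
#' ([confidence_ellipse()]).
#'
#' @name psa
NULL

#' Run a probabilistic sensitivity analysis for one subgroup
#'
#' @param params A `param_set`.
#' @param subgroup A one-row subgroup tibble (columns `sex`, `age`,
#'   `prevalence`, `euroscore_mortality`; see [default_subgroups()]).
#' @param lifetable A life-table tibble.
#' @param n_sims Number of Monte-Carlo draws.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   results.
#' @param policy Stroke-risk linkage policy, see [strategy_outcome()].
#' @return A `ce_result` object with the draw-level tibble (`$draws`, one
#'   row per simulation with per-strategy and incremental costs/QALYs),
#'   means, [icer()] summary, and the count of rejected-and-resampled
#'   invalid draws. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' fx <- default_fixture()
#' res <- run_psa(fx$params, fx$subgroups[5, ], fx$lifetable,
#'                n_sims = 200, seed = 1)
#' glance(res)
#' }
#' @export
run_psa <- function(params, subgroup, lifetable, n_sims = 5000, seed = NULL,
                    policy = c("proportional", "concentrated")) {
  policy <- match.arg(policy)
  stopifnot(inherits(params, "param_set"), n_sims >= 1, nrow(subgroup) == 1)
  if (!is.null(seed)) set.seed(seed)

  age <- subgroup$age
  sex <- subgroup$sex
  prevalence <- subgroup$prevalence
  m_avg <- subgroup$euroscore_mortality
  or <- params$euroscore$arteriopathy_or

  # The subgroup-average mortality, prevalence and odds ratio carry no
  # sampling distribution, so the stratification is draw-invariant.
  m <- stratify_mortality(m_avg, prevalence, or)

  n_rejected <- 0L
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    draw <- sample_parameters(params)
    n_rejected <- n_rejected + attr(draw, "n_rejected")
    v <- param_values(draw)
    q <- cycle_mortality(age, sex, lifetable, draw)

    res <- lapply(c(mp = "mp", tee = "tee"), function(strat) {
      sens <- if (strat == "mp") v[["sens_mp"]] else v[["sens_tee"]]
      spc <- if (strat == "mp") v[["spec_mp"]] else v[["spec_tee"]]
      out <- strategy_outcome(prevalence, sens, spc, m, draw, policy = policy)
      eng <- cohort_engine(out$p_no_complication, out$p_stroke_nonfatal, q, v)
      c(cost = decision_stage_cost(out, v, strat) + eng$cost_state,
        qalys = eng$qalys)
    })
    rows[[i]] <- c(sim = i, cost_mp = res$mp[["cost"]],
                   qalys_mp = res$mp[["qalys"]],
                   cost_tee = res$tee[["cost"]], qalys_tee = res$tee[["qalys"]])
  }
  draws <- tibble::as_tibble(do.call(rbind, rows)) %>%
    dplyr::mutate(delta_cost = .data$cost_tee - .data$cost_mp,
                  delta_qaly = .data$qalys_tee - .data$qalys_mp)

  structure(
    list(
      draws = draws,
      subgroup = subgroup,
      mean_inc_cost = mean(draws$delta_cost),
      mean_inc_qaly = mean(draws$delta_qaly),
      icer = icer(mean(draws$delta_cost), mean(draws$delta_qaly)),
      p_cost_saving_and_gain = mean(draws$delta_cost < 0 & draws$delta_qaly > 0),
      n_sims = n_sims,
      n_rejected = n_rejected,
      seed = seed,
      policy = policy
    ),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s, age %d, prevalence %.0f%% - %d draws (%d rejected)\n",
              x$subgroup$sex, x$subgroup$age, 100 * x$subgroup$prevalence,
              x$n_sims, x$n_rejected))
  print(glance(x))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `ce_result`.
#' @param ... Unused.
#' @method tidy ce_result
#' @export
tidy.ce_result <- function(x, ...) x$draws

#' @rdname run_psa
#' @method glance ce_result
#' @export
glance.ce_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mean_inc_cost = x$mean_inc_cost,
                   mean_inc_qaly = x$mean_inc_qaly),
    x$icer,
    tibble::tibble(p_cost_saving_and_gain = x$p_cost_saving_and_gain,
                   n_sims = x$n_sims, n_rejected = x$n_rejected)
  )
}

#' Incremental cost-effectiveness ratio with dominance quadrant
#'
#' The quadrant labels follow the cost-effectiveness plane with incremental
#' effects on the x-axis and incremental costs on the y-axis: `NE` (more
#' costly, more effective), `SE` (cost-saving and more effective - the new
#' strategy dominates), `NW` (more costly, less effective - dominated),
#' `SW` (cost-saving, less effective). With zero incremental effect the
#' ratio is undefined (`defined = FALSE`, `icer = NA`).
#'
#' @param delta_cost,delta_qaly Mean incremental cost (euros) and effect
#'   (QALYs); vectorised.
#' @return A tibble with columns `delta_cost`, `delta_qaly`, `icer`,
#'   `quadrant`, `defined`.
#' @examples
#' icer(100, 2)       # 50 euro/QALY, NE
#' icer(-58, 0.03)    # negative ratio, SE: dominant
#' @export
icer <- function(delta_cost, delta_qaly) {
  quadrant <- dplyr::case_when(
    delta_qaly > 0 & delta_cost < 0 ~ "SE",
    delta_qaly > 0 ~ "NE",
    delta_cost > 0 ~ "NW",
    TRUE ~ "SW"
  )
  defined <- delta_qaly != 0
  tibble::tibble(
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    icer = ifelse(defined, delta_cost / delta_qaly, NA_real_),
    quadrant = quadrant,
    defined = defined
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws with a
#' non-negative net monetary benefit (threshold x incremental effect minus
#' incremental cost). Note the vertical-axis intercept (threshold 0) counts
#' all cost-saving draws regardless of effect sign; the probability that the
#' strategy is simultaneously cost-saving *and* health-improving is reported
#' separately by [glance()] as `p_cost_saving_and_gain`.
#'
#' @param data A `ce_result` or a data frame with columns `delta_cost` and
#'   `delta_qaly`.
#' @param thresholds Numeric vector of thresholds (euros/QALY).
#' @return A tibble with columns `threshold` and `probability`.
#' @export
ceac <- function(data, thresholds = seq(0, 100000, by = 1000)) {
  draws <- as_ce_draws(data)
  tibble::tibble(
    threshold = thresholds,
    probability = vapply(thresholds, function(lambda) {
      mean(lambda * draws$delta_qaly - draws$delta_cost >= 0)
    }, numeric(1))
  )
}

as_ce_draws <- function(data) {
  if (inherits(data, "ce_result")) data <- data$draws
  if (!all(c("delta_cost", "delta_qaly") %in% names(data))) {
    stop("need columns 'delta_cost' and 'delta_qaly'", call. = FALSE)
  }
  data
}

#' Bivariate confidence ellipse on the cost-effectiveness plane
#'
#' Normal-approximation ellipse for the joint distribution of incremental
#' effects and costs: sample mean, sample covariance, and chi-square(2)
#' scaling at the requested level.
#'
#' @param data A `ce_result` or a data frame with columns `delta_cost` and
#'   `delta_qaly` (at least 3 rows).
#' @param level Coverage level in (0, 1), default 0.95.
#' @return A `ce_ellipse` list: `center` (effect, cost), `cov`, `radii`
#'   (semi-axis lengths, major first), `angle` (radians, major axis from the
#'   effect axis), `level`, and a `degenerate` flag when the covariance is
#'   singular (the ellipse collapses to a segment or point).
#' @export
confidence_ellipse <- function(data, level = 0.95) {
  stopifnot(level > 0, level < 1)
  draws <- as_ce_draws(data)
  if (nrow(draws) < 3) stop("need at least 3 draws", call. = FALSE)
  xy <- cbind(effect = draws$delta_qaly, cost = draws$delta_cost)
  center <- colMeans(xy)
  covm <- stats::cov(xy)
  eig <- eigen(covm, symmetric = TRUE)
  scale2 <- stats::qchisq(level, df = 2)
  radii <- sqrt(pmax(eig$values, 0) * scale2)
  structure(
    list(center = center, cov = covm, radii = radii,
         angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
         level = level,
         degenerate = any(eig$values <= .Machine$double.eps * max(eig$values, 1))),
    class = "ce_ellipse"
  )
}

#' Coordinates of a confidence ellipse for plotting
#'
#' @param ellipse A `ce_ellipse` from [confidence_ellipse()].
#' @param n Number of points on the boundary.
#' @return A tibble with columns `delta_qaly`, `delta_cost`.
#' @export
ellipse_coords <- function(ellipse, n = 181) {
  stopifnot(inherits(ellipse, "ce_ellipse"))
  theta <- seq(0, 2 * pi, length.out = n)
  unit <- rbind(ellipse$radii[1] * cos(theta), ellipse$radii[2] * sin(theta))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  pts <- rot %*% unit
  tibble::tibble(delta_qaly = ellipse$center[["effect"]] + pts[1, ],
                 delta_cost = ellipse$center[["cost"]] + pts[2, ])
}

#' Cost-effectiveness plane for a PSA result
#'
#' Scatter of the PSA draws with the mean point and the 95% bivariate
#' confidence ellipse, incremental effects on the x-axis and incremental
#' costs on the y-axis.
#'
#' @param object A `ce_result`.
#' @param level Ellipse coverage level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ce_result
#' @export
autoplot.ce_result <- function(object, level = 0.95, ...) {
  ell <- confidence_ellipse(object, level = level)
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_path(data = ellipse_coords(ell), colour = "black") +
    ggplot2::annotate("point", x = object$mean_inc_qaly,
                      y = object$mean_inc_cost, shape = 18, size = 3) +
    ggplot2::labs(
      x = "Incremental effects (QALYs)",
      y = "Incremental costs (€)",
      title = sprintf("Modified TEE vs manual palpation: %s, age %d, prevalence %.0f%%",
                      object$subgroup$sex, object$subgroup$age,
                      100 * object$subgroup$prevalence)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ceac_data A tibble from [ceac()], optionally with a grouping
#'   column `label` for multiple subgroups.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_data) {
  mapping <- if ("label" %in% names(ceac_data)) {
    ggplot2::aes(x = .data$threshold, y = .data$probability,
                 colour = .data$label)
  } else {
    ggplot2::aes(x = .data$threshold, y = .data$probability)
  }
  ggplot2::ggplot(ceac_data, mapping) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Cost-effectiveness threshold (€/QALY)",
                  y = "Probability cost-effective",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
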
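#' Deterministic evaluation and reporting
#'
#' [evaluate_strategies()] runs the full deterministic pipeline (mortality
#' stratification, decision tree, Markov cohort model, cost bookkeeping)
#' for every subgroup and both strategies; [compare_strategies()] derives
#' per-subgroup incremental results and ICERs; [run_deterministic()] wraps
#' both into report tables with the rounding conventions of published
#' cost-effectiveness tables (percentages to 2 decimals, euros to whole
#' units, QALYs to 2 decimals), keeping the raw values in companion
#' columns.
#'
#' @name reporting
NULL

#' Evaluate both strategies deterministically for a set of subgroups
#'
#' @param subgroups Subgroup tibble, see [default_subgroups()].
#' @param params A `param_set`.
#' @param lifetable A life-table tibble.
#' @param policy Stroke-risk linkage policy, see [strategy_outcome()].
#' @return A tibble with one row per subgroup and strategy: decision-tree
#'   probabilities plus discounted cost, life-years and QALY totals.
#' @examples
#' fx <- default_fixture()
#' evaluate_strategies(fx$subgroups[1, ], fx$params, fx$lifetable)
#' @export
evaluate_strategies <- function(subgroups, params, lifetable,
                                policy = c("proportional", "concentrated")) {
  policy <- match.arg(policy)
  outcomes <- strategy_outcomes(subgroups, params, policy = policy)
  purrr::map_dfr(seq_len(nrow(outcomes)), function(i) {
    row <- outcomes[i, ]
    trace <- run_cohort(row, age = row$age, sex = row$sex,
                        lifetable = lifetable, params = params)
    totals <- strategy_totals(trace, row, params, strategy = row$strategy)
    dplyr::bind_cols(row, totals[setdiff(names(totals), "strategy")])
  })
}

#' Incremental results of modified TEE versus manual palpation
#'
#' @param results Output of [evaluate_strategies()].
#' @return A tibble with one row per subgroup: incremental cost, incremental
#'   QALYs, the ICER with its dominance quadrant, and a `dominant` flag
#'   (cost-saving with health gain).
#' @export
compare_strategies <- function(results) {
  wide <- results %>%
    dplyr::select(dplyr::all_of(c("subgroup", "sex", "age", "prevalence",
                                  "strategy", "cost", "qalys", "life_years"))) %>%
    tidyr::pivot_wider(names_from = "strategy",
                       values_from = c("cost", "qalys", "life_years"))
  dplyr::bind_cols(
    wide,
    icer(wide$cost_tee - wide$cost_mp, wide$qalys_tee - wide$qalys_mp) %>%
      dplyr::select(-dplyr::all_of(c("delta_cost", "delta_qaly")))
  ) %>%
    dplyr::mutate(delta_cost = .data$cost_tee - .data$cost_mp,
                  delta_qaly = .data$qalys_tee - .data$qalys_mp,
                  dominant = .data$quadrant == "SE")
}

#' Deterministic report tables
#'
#' Builds the two standard report tables: per-subgroup adaptation and
#' stroke probabilities by strategy, and per-subgroup costs, QALYs and
#' incremental cost-effectiveness. Percentages are rounded to 2 decimals,
#' euros to whole units and QALYs to 2 decimals; unrounded values are kept
#' in `*_raw` companion columns. Dominant subgroups (cost-saving with
#' health gain) are marked with `"*"` in the `footnote` column.
#'
#' @inheritParams evaluate_strategies
#' @return A list of class `tee_report` with tibbles `outcomes` (adaptation
#'   and stroke probabilities), `cost_effectiveness` (costs, QALYs, ICER)
#'   and the unrounded `results`/`incremental` tibbles.
#' @export
run_deterministic <- function(subgroups, params, lifetable,
                              policy = c("proportional", "concentrated")) {
  policy <- match.arg(policy)
  results <- evaluate_strategies(subgroups, params, lifetable, policy = policy)
  incr <- compare_strategies(results)

  pct <- function(x) round(100 * x, 2)
  outcomes <- results %>%
    dplyr::transmute(
      subgroup = .data$subgroup, sex = .data$sex, age = .data$age,
      prevalence_pct = pct(.data$prevalence),
      strategy = .data$strategy,
      euroscore_mortality_pct = pct(.data$p_stroke_fatal + .data$p_death_other),
      minor_adaptation_pct = pct(.data$p_minor_adaptation_true),
      major_adaptation_pct = pct(.data$p_major_adaptation),
      stroke_nonfatal_pct = pct(.data$p_stroke_nonfatal),
      stroke_fatal_pct = pct(.data$p_stroke_fatal),
      life_years = round(.data$life_years, 2),
      minor_adaptation_raw = .data$p_minor_adaptation_true,
      major_adaptation_raw = .data$p_major_adaptation,
      stroke_nonfatal_raw = .data$p_stroke_nonfatal,
      stroke_fatal_raw = .data$p_stroke_fatal,
      life_years_raw = .data$life_years
    )

  ce <- incr %>%
    dplyr::transmute(
      subgroup = .data$subgroup, sex = .data$sex, age = .data$age,
      prevalence_pct = pct(.data$prevalence),
      cost_mp = round(.data$cost_mp), qalys_mp = round(.data$qalys_mp, 2),
      cost_tee = round(.data$cost_tee), qalys_tee = round(.data$qalys_tee, 2),
      incremental_cost = round(.data$delta_cost),
      incremental_qalys = round(.data$delta_qaly, 2),
      icer = round(.data$icer),
      footnote = ifelse(.data$dominant, "*", ""),
      quadrant = .data$quadrant,
      cost_mp_raw = .data$cost_mp, cost_tee_raw = .data$cost_tee,
      qalys_mp_raw = .data$qalys_mp, qalys_tee_raw = .data$qalys_tee,
      incremental_cost_raw = .data$delta_cost,
      incremental_qalys_raw = .data$delta_qaly,
      icer_raw = .data$icer
    )

  structure(list(outcomes = outcomes, cost_effectiveness = ce,
                 results = results, incremental = incr, policy = policy),
            class = "tee_report")
}

#' @export
print.tee_report <- function(x, ...) {
  cat("<tee_report>\nOutcome probabilities:\n")
  print(dplyr::select(x$outcomes, !dplyr::ends_with("_raw")), n = Inf)
  cat("\nCost-effectiveness:\n")
  print(dplyr::select(x$cost_effectiveness, !dplyr::ends_with("_raw")), n = Inf)
  invisible(x)
}

run_manifest <- function(params, seed = NULL, n_sims = NULL,
                         subgroups = NULL, extra = list()) {
  c(list(
    package = "teecea",
    version = as.character(utils::packageVersion("teecea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(params),
    seed = seed,
    n_sims = n_sims,
    subgroups = subgroups
  ), extra)
}

#' Write the deterministic report tables to CSV
#'
#' Writes `outcomes.csv`, `cost_effectiveness.csv` and a `manifest.json`
#' recording the package version, a hash of the parameter set and the
#' subgroups run, so every output file is traceable to one manifest.
#'
#' @param report A `tee_report` from [run_deterministic()].
#' @param out_dir Output directory (created if missing).
#' @param params The `param_set` the report was built from (hashed into the
#'   manifest).
#' @return Invisibly, the paths written.
#' @export
write_deterministic_report <- function(report, out_dir, params) {
  stopifnot(inherits(report, "tee_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    outcomes = file.path(out_dir, "outcomes.csv"),
    cost_effectiveness = file.path(out_dir, "cost_effectiveness.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(report$outcomes, paths[["outcomes"]])
  readr::write_csv(report$cost_effectiveness, paths[["cost_effectiveness"]])
  manifest <- run_manifest(params,
                           subgroups = report$outcomes$subgroup,
                           extra = list(policy = report$policy,
                                        outputs = basename(paths)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}

#' Run and export a probabilistic sensitivity analysis per subgroup
#'
#' For each selected subgroup: runs [run_psa()], writes the draw-level CSV
#' (`sim`, incremental cost, incremental QALYs), the acceptability-curve
#' CSV, and optionally cost-effectiveness-plane and CEAC figures, plus one
#' manifest for the whole run. Subgroup draws use `seed + subgroup id`, so
#' the full run is reproducible from the single seed.
#'
#' @inheritParams evaluate_strategies
#' @param n_sims Draws per subgroup.
#' @param seed Integer base seed.
#' @param thresholds Thresholds (euros/QALY) for the acceptability curve.
#' @param out_dir Output directory (created if missing).
#' @param write_plots Write PNG figures (default `TRUE`).
#' @return Invisibly, a list with the `ce_result` objects and CEAC tibbles,
#'   keyed by subgroup id.
#' @export
run_psa_report <- function(subgroups, params, lifetable, out_dir,
                           n_sims = 5000, seed = 1,
                           thresholds = seq(0, 100000, by = 1000),
                           policy = c("proportional", "concentrated"),
                           write_plots = TRUE) {
  policy <- match.arg(policy)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  ceacs <- list()
  for (i in seq_len(nrow(subgroups))) {
    sg <- subgroups[i, ]
    id <- sg$subgroup
    res <- run_psa(params, sg, lifetable, n_sims = n_sims,
                   seed = seed + id, policy = policy)
    cv <- ceac(res, thresholds)
    readr::write_csv(
      dplyr::select(res$draws, dplyr::all_of(c("sim", "delta_cost", "delta_qaly"))),
      file.path(out_dir, sprintf("draws_subgroup%02d.csv", id))
    )
    readr::write_csv(cv, file.path(out_dir, sprintf("ceac_subgroup%02d.csv", id)))
    if (write_plots) {
      ggplot2::ggsave(file.path(out_dir, sprintf("ce_plane_subgroup%02d.png", id)),
                      autoplot(res), width = 6, height = 5, dpi = 150)
      label <- sprintf("%s, age %d, prev %.0f%% (p cost-saving & gain = %.2f)",
                       sg$sex, sg$age, 100 * sg$prevalence,
                       res$p_cost_saving_and_gain)
      ggplot2::ggsave(file.path(out_dir, sprintf("ceac_subgroup%02d.png", id)),
                      plot_ceac(dplyr::mutate(cv, label = label)),
                      width = 6, height = 4, dpi = 150)
    }
    results[[as.character(id)]] <- res
    ceacs[[as.character(id)]] <- cv
  }
  manifest <- run_manifest(params, seed = seed, n_sims = n_sims,
                           subgroups = subgroups$subgroup,
                           extra = list(policy = policy,
                                        thresholds = range(thresholds)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(results = results, ceacs = ceacs))
}

#' Cost-effectiveness plane for several subgroups
#'
#' Overlays the mean incremental point and 95% confidence ellipse of each
#' PSA result on one plane.
#'
#' @param ce_results A list of `ce_result` objects.
#' @param level Ellipse coverage level.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(ce_results, level = 0.95) {
  stopifnot(length(ce_results) >= 1)
  parts <- purrr::map_dfr(ce_results, function(res) {
    label <- sprintf("%s %d yr %.0f%%", res$subgroup$sex, res$subgroup$age,
                     100 * res$subgroup$prevalence)
    dplyr::mutate(ellipse_coords(confidence_ellipse(res, level = level)),
                  label = label)
  })
  centers <- purrr::map_dfr(ce_results, function(res) {
    tibble::tibble(
      delta_qaly = res$mean_inc_qaly, delta_cost = res$mean_inc_cost,
      label = sprintf("%s %d yr %.0f%%", res$subgroup$sex, res$subgroup$age,
                      100 * res$subgroup$prevalence)
    )
  })
  ggplot2::ggplot(parts, ggplot2::aes(x = .data$delta_qaly,
                                      y = .data$delta_cost,
                                      colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = centers, shape = 18, size = 3) +
    ggplot2::labs(x = "Incremental effects (QALYs)",
                  y = "Incremental costs (€)", colour = NULL) +
    ggplot2::theme_minimal()
}
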
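#' Diagnostic decision tree
#'
#' The first model part converts atherosclerosis prevalence, diagnostic test
#' accuracy, adaptation rules and early mortality into per-strategy
#' probabilities of surgical adaptation, non-fatal stroke, fatal stroke,
#' other early death, and uncomplicated survival. These probabilities are the
#' starting-state distribution for the Markov cohort model.
#'
#' @name decision-tree
NULL

#' Joint classification probabilities of a diagnostic test
#'
#' Cross-classifies atherosclerosis status against the test result.
#'
#' @param prevalence Atherosclerosis prevalence, in \[0, 1\].
#' @param sensitivity,specificity Test accuracy, each in \[0, 1\].
#' @return A one-row tibble with joint probabilities `p_tp`, `p_fn`, `p_fp`,
#'   `p_tn` (true positive, false negative, false positive, true negative);
#'   they sum to 1 and `p_tp + p_fn` equals the prevalence.
#' @examples
#' classify_test(0.10, sensitivity = 0.97, specificity = 0.80)
#' @export
classify_test <- function(prevalence, sensitivity, specificity) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  tibble::tibble(
    prevalence = prevalence,
    sensitivity = sensitivity,
    specificity = specificity,
    p_tp = prevalence * sensitivity,
    p_fn = prevalence * (1 - sensitivity),
    p_fp = (1 - prevalence) * (1 - specificity),
    p_tn = (1 - prevalence) * specificity
  )
}

#' Surgical adaptation probabilities
#'
#' A detected atherosclerosis (true positive) leads to a major adaptation of
#' the procedure with probability `p_major` and otherwise to a minor
#' adaptation (e.g. relocating cannulation or clamp sites). A false positive
#' can only trigger a minor adaptation: a major adaptation would immediately
#' reveal the absent atherosclerosis and be aborted. Reported adaptation
#' chances (`p_minor_true`, `p_major_adapt`) cover patients with
#' atherosclerosis; false-positive minor adaptations are carried separately.
#'
#' @param classification A one-row tibble from [classify_test()].
#' @param p_major Probability of a major adaptation given detected
#'   atherosclerosis.
#' @return A one-row tibble with `p_minor_true`, `p_major_adapt`,
#'   `p_minor_fp`.
#' @examples
#' classify_test(0.10, 0.97, 0.80) |> adaptation_probs(p_major = 0.027)
#' @export
adaptation_probs <- function(classification, p_major) {
  stopifnot(p_major >= 0, p_major <= 1)
  tibble::tibble(
    p_minor_true = classification$p_tp * (1 - p_major),
    p_major_adapt = classification$p_tp * p_major,
    p_minor_fp = classification$p_fp
  )
}

# Cohort total stroke risk under a stroke-risk linkage policy.
#
# Baseline per-stratum total stroke risk is anchored to early mortality:
#   T_i = m_i * p_death_is_stroke / (1 - p_stroke_nonfatal),
# i.e. fatal strokes are the stated fraction of early deaths and total
# strokes follow from the fatal fraction. Adaptation (true positives only)
# multiplies the preventable embolic portion by rr_adaptation.
#
# policy "proportional": embolic strokes are a fixed fraction of every
#   stratum's stroke risk. policy "concentrated": all embolic strokes occur
#   in the atherosclerosis stratum (the embolic source), non-embolic strokes
#   stay stratum-proportional.
cohort_stroke_risk <- function(prevalence, sensitivity, m_no_athero, m_athero,
                               p_death_is_stroke, p_stroke_nonfatal,
                               p_stroke_embolic, rr_adaptation,
                               policy = c("proportional", "concentrated")) {
  policy <- match.arg(policy)
  k <- p_death_is_stroke / (1 - p_stroke_nonfatal)
  t_a <- m_athero * k
  t_n <- m_no_athero * k
  if (policy == "proportional") {
    t_a_adapted <- t_a * (p_stroke_embolic * rr_adaptation + (1 - p_stroke_embolic))
    prevalence * (sensitivity * t_a_adapted + (1 - sensitivity) * t_a) +
      (1 - prevalence) * t_n
  } else {
    t_bar <- prevalence * t_a + (1 - prevalence) * t_n
    emb_per_athero <- if (prevalence > 0) {
      p_stroke_embolic * t_bar / prevalence
    } else {
      0
    }
    nonemb_a <- (1 - p_stroke_embolic) * t_a
    nonemb_n <- (1 - p_stroke_embolic) * t_n
    prevalence * (sensitivity * (emb_per_athero * rr_adaptation + nonemb_a) +
                    (1 - sensitivity) * (emb_per_athero + nonemb_a)) +
      (1 - prevalence) * nonemb_n
  }
}

#' Decision-tree outcome probabilities for one strategy
#'
#' Runs the full decision tree for one diagnostic strategy: classification,
#' adaptation, and the stroke/early-death split. Total stroke risk is
#' anchored to early mortality (fatal strokes are the `p_death_is_stroke`
#' fraction of early deaths, and total strokes follow from the fatal
#' fraction `1 - p_stroke_nonfatal`); surgical adaptation in detected
#' atherosclerosis multiplies the preventable embolic portion of the stroke
#' risk by `rr_adaptation`. Other early deaths absorb the remainder of the
#' average early mortality, so total early death is strategy-invariant.
#'
#' @param prevalence Atherosclerosis prevalence.
#' @param sensitivity,specificity Accuracy of the diagnostic strategy.
#' @param mortality One-row tibble from [stratify_mortality()].
#' @param params A `param_set`.
#' @param policy Stroke-risk linkage policy: `"proportional"` (default;
#'   embolic strokes are a fixed fraction of every stratum's risk) or
#'   `"concentrated"` (embolic strokes arise only in patients with
#'   atherosclerosis).
#' @return A one-row tibble with adaptation probabilities
#'   (`p_minor_adaptation_true`, `p_major_adaptation`,
#'   `p_minor_adaptation_fp`), outcome probabilities (`p_stroke_nonfatal`,
#'   `p_stroke_fatal`, `p_death_other`, `p_no_complication`, summing to 1)
#'   and a `floored` flag set when `p_death_other` had to be floored at 0.
#' @examples
#' ps <- default_parameters()
#' m <- stratify_mortality(0.0104, 0.10, ps$euroscore$arteriopathy_or)
#' strategy_outcome(0.10, 0.97, 0.80, m, ps)
#' @export
strategy_outcome <- function(prevalence, sensitivity, specificity, mortality,
                             params, policy = c("proportional", "concentrated")) {
  policy <- match.arg(policy)
  stopifnot(inherits(params, "param_set"))
  v <- param_values(params)

  cls <- classify_test(prevalence, sensitivity, specificity)
  adapt <- adaptation_probs(cls, v[["p_major_adaptation"]])

  total_stroke <- cohort_stroke_risk(
    prevalence, sensitivity,
    m_no_athero = mortality$m_no_athero, m_athero = mortality$m_athero,
    p_death_is_stroke = v[["p_death_is_stroke"]],
    p_stroke_nonfatal = v[["p_stroke_nonfatal"]],
    p_stroke_embolic = v[["p_stroke_embolic"]],
    rr_adaptation = v[["rr_adaptation"]],
    policy = policy
  )
  p_fatal <- total_stroke * (1 - v[["p_stroke_nonfatal"]])
  p_nonfatal <- total_stroke * v[["p_stroke_nonfatal"]]
  p_other_raw <- mortality$m_avg - p_fatal
  floored <- p_other_raw < 0
  if (floored) {
    warning("other early deaths floored at 0: fatal strokes exceed average early mortality")
  }
  p_other <- max(p_other_raw, 0)
  p_none <- 1 - p_nonfatal - p_fatal - p_other

  tibble::tibble(
    prevalence = prevalence,
    sensitivity = sensitivity,
    specificity = specificity,
    p_minor_adaptation_true = adapt$p_minor_true,
    p_major_adaptation = adapt$p_major_adapt,
    p_minor_adaptation_fp = adapt$p_minor_fp,
    p_stroke_nonfatal = p_nonfatal,
    p_stroke_fatal = p_fatal,
    p_death_other = p_other,
    p_no_complication = p_none,
    floored = floored
  )
}

#' Decision-tree outcomes for subgroups under both strategies
#'
#' Maps [strategy_outcome()] over a subgroup table for the manual-palpation
#' and modified-TEE strategies, stratifying each subgroup's average early
#' mortality by atherosclerosis status first.
#'
#' @param subgroups Tibble with columns `subgroup`, `sex`, `age`,
#'   `prevalence`, `euroscore_mortality` (see [default_subgroups()]).
#' @param params A `param_set`.
#' @param policy Stroke-risk linkage policy, see [strategy_outcome()].
#' @return A tibble with one row per subgroup and strategy
#'   (`strategy` is `"mp"` or `"tee"`).
#' @export
strategy_outcomes <- function(subgroups, params,
                              policy = c("proportional", "concentrated")) {
  policy <- match.arg(policy)
  v <- param_values(params)
  accuracy <- tibble::tibble(
    strategy = c("mp", "tee"),
    sensitivity = c(v[["sens_mp"]], v[["sens_tee"]]),
    specificity = c(v[["spec_mp"]], v[["spec_tee"]])
  )
  purrr::pmap_dfr(subgroups, function(subgroup, sex, age, prevalence,
                                      euroscore_mortality, ...) {
    m <- stratify_mortality(euroscore_mortality, prevalence,
                            params$euroscore$arteriopathy_or)
    purrr::pmap_dfr(accuracy, function(strategy, sensitivity, specificity) {
      dplyr::bind_cols(
        tibble::tibble(subgroup = subgroup, sex = sex, age = age,
                       strategy = strategy),
        strategy_outcome(prevalence, sensitivity, specificity, m, params,
                         policy = policy)
      )
    })
  })
}

#' Microsimulation of the diagnostic stage
#'
#' Samples individual patients through the classification and adaptation
#' stages of the decision tree (atherosclerosis status, test result, and
#' major vs. minor adaptation for true positives). Used to reproduce
#' expected adaptation probabilities within Monte-Carlo tolerance for finite
#' cohorts. Uses the current RNG stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param n Number of simulated patients.
#' @param prevalence Atherosclerosis prevalence.
#' @param sensitivity,specificity Test accuracy.
#' @param p_major Probability of major adaptation given a true positive.
#' @return A one-row tibble with counts (`n`, `n_athero`, `n_tp`, `n_fp`,
#'   `n_major`, `n_minor_true`, `n_minor_fp`) and the corresponding cohort
#'   fractions (`p_major_adapt_hat`, `p_minor_true_hat`, `p_minor_fp_hat`).
#' @examples
#' set.seed(1)
#' simulate_patients(10000, 0.10, 0.31, 0.98, 0.027)
#' @export
simulate_patients <- function(n, prevalence, sensitivity, specificity,
                              p_major) {
  stopifnot(n >= 1)
  athero <- stats::rbinom(n, 1, prevalence) == 1
  positive <- logical(n)
  positive[athero] <- stats::rbinom(sum(athero), 1, sensitivity) == 1
  positive[!athero] <- stats::rbinom(sum(!athero), 1, 1 - specificity) == 1
  tp <- athero & positive
  fp <- !athero & positive
  major <- logical(n)
  major[tp] <- stats::rbinom(sum(tp), 1, p_major) == 1
  tibble::tibble(
    n = n,
    n_athero = sum(athero),
    n_tp = sum(tp),
    n_fp = sum(fp),
    n_major = sum(major),
    n_minor_true = sum(tp & !major),
    n_minor_fp = sum(fp),
    p_major_adapt_hat = sum(major) / n,
    p_minor_true_hat = sum(tp & !major) / n,
    p_minor_fp_hat = sum(fp) / n
  )
}
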
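# Brute-force enumeration oracle: walks the four classification cells and
# the two atherosclerosis strata explicitly and sums per-cell stroke risk.
oracle_total_stroke <- function(prev, sens, spec, m_no, m_a, v,
                                policy = "proportional") {
  k <- v[["p_death_is_stroke"]] / (1 - v[["p_stroke_nonfatal"]])
  emb <- v[["p_stroke_embolic"]]
  rr <- v[["rr_adaptation"]]
  cells <- list(
    tp = list(p = prev * sens, athero = TRUE, adapted = TRUE),
    fn = list(p = prev * (1 - sens), athero = TRUE, adapted = FALSE),
    fp = list(p = (1 - prev) * (1 - spec), athero = FALSE, adapted = FALSE),
    tn = list(p = (1 - prev) * spec, athero = FALSE, adapted = FALSE)
  )
  total <- 0
  for (cell in cells) {
    t_base <- (if (cell$athero) m_a else m_no) * k
    risk <- if (policy == "proportional") {
      if (cell$adapted) t_base * (emb * rr + (1 - emb)) else t_base
    } else {
      t_bar <- (prev * m_a + (1 - prev) * m_no) * k
      emb_part <- if (cell$athero) emb * t_bar / prev else 0
      nonemb <- (1 - emb) * t_base
      if (cell$adapted) emb_part * rr + nonemb else emb_part + nonemb
    }
    total <- total + cell$p * risk
  }
  total
}

test_that("classification probabilities are consistent joint probabilities", {
  cls <- classify_test(0.10, 0.97, 0.80)
  expect_equal(cls$p_tp, 0.097)
  expect_equal(cls$p_fp, 0.18)
  expect_equal(cls$p_tp + cls$p_fn + cls$p_fp + cls$p_tn, 1,
               tolerance = 1e-12)
  expect_equal(cls$p_tp + cls$p_fn, 0.10)

  zero <- classify_test(0, 0.97, 0.80)
  expect_equal(zero$p_tp, 0)
  expect_equal(zero$p_fn, 0)

  perfect <- classify_test(0.3, 1, 1)
  expect_equal(perfect$p_tp, 0.3)
  expect_equal(perfect$p_tn, 0.7)
})

test_that("adaptation probabilities reproduce the expected subgroup cells", {
  adapt_tee1 <- adaptation_probs(classify_test(0.10, 0.97, 0.80), 0.027)
  expect_equal(adapt_tee1$p_major_adapt, 0.10 * 0.97 * 0.027)
  expect_equal(round(100 * adapt_tee1$p_major_adapt, 2), 0.26)

  adapt_tee5 <- adaptation_probs(classify_test(0.20, 0.97, 0.80), 0.027)
  expect_equal(round(100 * adapt_tee5$p_major_adapt, 2), 0.52)

  adapt_mp1 <- adaptation_probs(classify_test(0.10, 0.31, 0.98), 0.027)
  expect_equal(round(100 * adapt_mp1$p_major_adapt, 2), 0.08)
  expect_equal(adapt_mp1$p_minor_true, 0.10 * 0.31 * 0.973)

  # without atherosclerosis there is nothing to adapt for; false-positive
  # minor adaptations remain possible but carry no cost or risk change
  none <- adaptation_probs(classify_test(0, 0.97, 0.80), 0.027)
  expect_equal(none$p_minor_true, 0)
  expect_equal(none$p_major_adapt, 0)
  expect_equal(none$p_minor_fp, 0.20)

  # major adaptations cannot exceed the detected-atherosclerosis fraction
  expect_lte(adapt_tee1$p_major_adapt, 0.10 * 0.97)
})

test_that("vectorised stroke linkage matches the enumeration oracle", {
  ps <- default_parameters()
  set.seed(91)
  for (policy in c("proportional", "concentrated")) {
    for (i in 1:25) {
      prev <- runif(1, 0.05, 0.6)
      sens <- runif(1)
      spec <- runif(1)
      m_avg <- runif(1, 0.005, 0.08)
      m <- stratify_mortality(m_avg, prev, ps$euroscore$arteriopathy_or)
      v <- param_values(ps)
      out <- strategy_outcome(prev, sens, spec, m, ps, policy = policy)
      expect_equal(out$p_stroke_nonfatal + out$p_stroke_fatal,
                   oracle_total_stroke(prev, sens, spec, m$m_no_athero,
                                       m$m_athero, v, policy),
                   tolerance = 1e-12)
    }
  }
})

test_that("outcome probabilities form a proper distribution", {
  ps <- default_parameters()
  sg <- default_subgroups()
  out <- strategy_outcomes(sg, ps)
  expect_equal(nrow(out), 24)
  sums <- out$p_stroke_nonfatal + out$p_stroke_fatal + out$p_death_other +
    out$p_no_complication
  expect_equal(sums, rep(1, 24), tolerance = 1e-12)
  expect_true(all(out[c("p_stroke_nonfatal", "p_stroke_fatal",
                        "p_death_other", "p_no_complication")] >= 0))
  expect_false(any(out$floored))
  # fatal:non-fatal split follows the configured fatal fraction
  expect_equal(out$p_stroke_fatal / (out$p_stroke_fatal + out$p_stroke_nonfatal),
               rep(1 - param_value(ps, "p_stroke_nonfatal"), 24),
               tolerance = 1e-12)
})

test_that("no-effect limits collapse the strategy difference", {
  ps <- set_value(default_parameters(), "rr_adaptation", 1)
  m <- stratify_mortality(0.0161, 0.2, ps$euroscore$arteriopathy_or)
  out_mp <- strategy_outcome(0.2, 0.31, 0.98, m, ps)
  out_tee <- strategy_outcome(0.2, 0.97, 0.80, m, ps)
  cols <- c("p_stroke_nonfatal", "p_stroke_fatal", "p_death_other",
            "p_no_complication")
  expect_equal(out_mp[cols], out_tee[cols], tolerance = 1e-12)

  ps2 <- default_parameters()
  out_a <- strategy_outcome(0.2, 0, 0.98, m, ps2)
  out_b <- strategy_outcome(0.2, 0, 0.80, m, ps2)
  expect_equal(out_a[cols], out_b[cols], tolerance = 1e-12)
})

test_that("stroke risk falls with sensitivity and rises with prevalence", {
  ps <- default_parameters()
  # hold the per-stratum mortalities fixed so prevalence only reweights the
  # strata (re-stratifying a fixed average would cancel the prevalence effect)
  total_stroke <- function(prev, sens, m_no = 0.015, m_a = 0.030) {
    m <- tibble::tibble(m_avg = prev * m_a + (1 - prev) * m_no,
                        prevalence = prev, arteriopathy_or = NA_real_,
                        m_no_athero = m_no, m_athero = m_a)
    out <- strategy_outcome(prev, sens, 0.9, m, ps)
    out$p_stroke_nonfatal + out$p_stroke_fatal
  }
  by_sens <- vapply(seq(0, 1, by = 0.2), total_stroke, numeric(1),
                    prev = 0.3)
  expect_true(all(diff(by_sens) < 0))
  by_prev <- vapply(seq(0.05, 0.6, by = 0.1), total_stroke, numeric(1),
                    sens = 0.5)
  expect_true(all(diff(by_prev) > 0))
})

test_that("a more sensitive test never increases the stroke risk", {
  set.seed(17)
  ps0 <- default_parameters()
  for (i in 1:20) {
    ps <- ps0
    ps <- set_value(ps, "rr_adaptation", runif(1, 0.1, 0.99))
    sens_lo <- runif(1, 0, 0.9)
    sens_hi <- runif(1, sens_lo, 1)
    prev <- runif(1, 0.05, 0.6)
    m <- stratify_mortality(runif(1, 0.005, 0.05), prev,
                            ps$euroscore$arteriopathy_or)
    lo <- strategy_outcome(prev, sens_hi, 0.8, m, ps)
    hi <- strategy_outcome(prev, sens_lo, 0.98, m, ps)
    expect_lte(lo$p_stroke_nonfatal + lo$p_stroke_fatal,
               hi$p_stroke_nonfatal + hi$p_stroke_fatal)
  }
})

test_that("diagnostic-stage microsimulation recovers the expected fractions", {
  set.seed(5)
  sim <- simulate_patients(20000, 0.10, 0.31, 0.98, 0.027)
  p_expected <- 0.10 * 0.31 * (1 - 0.027)
  se <- sqrt(p_expected * (1 - p_expected) / 20000)
  expect_lt(abs(sim$p_minor_true_hat - p_expected), 3 * se)
  expect_identical(sim$n_minor_true + sim$n_major, sim$n_tp)
  set.seed(5)
  sim2 <- simulate_patients(20000, 0.10, 0.31, 0.98, 0.027)
  expect_identical(sim, sim2)
})
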
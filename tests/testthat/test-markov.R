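test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0.04, 0), 1)
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  expect_equal(discount_factor(0, 0:50), rep(1, 51))
})

test_that("constant-hazard, zero-discount life expectancy matches the geometric series", {
  q <- 0.4
  ps <- default_parameters()
  ps <- set_value(ps, "discount_costs", 0)
  ps <- set_value(ps, "discount_effects", 0)
  # keep the hazard flat through the excess window too
  for (nm in c("excess_mortality_lt61", "excess_mortality_61_70",
               "excess_mortality_gt70")) {
    ps <- set_value(ps, nm, q)
  }
  lt <- constant_lifetable(q)
  trace <- run_cohort(outcome_row(p_no_complication = 1), age = 55,
                      sex = "male", lifetable = lt, params = ps)
  totals <- attr(trace, "totals")
  expect_equal(totals$life_years, (1 - q) / q, tolerance = 1e-8)
  expect_equal(totals$life_years, totals$life_years_undiscounted)
  expect_equal(totals$qalys, totals$life_years)  # utility 1 throughout
})

test_that("the cohort is conserved and absorbed monotonically", {
  fx <- default_fixture()
  out <- strategy_outcomes(fx$subgroups[c(1, 7, 12), ], fx$params)
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    trace <- run_cohort(row, row$age, row$sex, fx$lifetable, fx$params)
    occ <- trace$p_no_complication + trace$p_post_stroke + trace$p_dead
    expect_equal(occ, rep(1, nrow(trace)), tolerance = 1e-10)
    expect_true(all(diff(trace$p_dead) >= -1e-12))
    expect_equal(trace$p_dead[nrow(trace)], 1, tolerance = 1e-12)

    totals <- attr(trace, "totals")
    expect_lte(totals$life_years, totals$life_years_undiscounted)
    expect_lte(totals$qalys, totals$life_years)
    expect_lte(totals$cost_state, totals$cost_state_undiscounted)
  }
})

test_that("starting dead yields no life-years and no state costs", {
  fx <- default_fixture()
  trace <- run_cohort(outcome_row(p_no_complication = 0, p_other = 1),
                      65, "female", fx$lifetable, fx$params)
  totals <- attr(trace, "totals")
  expect_equal(totals$life_years, 0)
  expect_equal(totals$qalys, 0)
  expect_equal(totals$cost_state, 0)
})

test_that("life expectancy decreases with starting age", {
  fx <- default_fixture()
  ly_at_age <- function(age) {
    trace <- run_cohort(outcome_row(p_no_complication = 1), age, "male",
                        fx$lifetable, fx$params)
    attr(trace, "totals")$life_years_undiscounted
  }
  ly <- vapply(c(55, 60, 65, 70, 75, 85), ly_at_age, numeric(1))
  expect_true(all(diff(ly) < 0))
  # and the female table gives longer lives than the male at equal age
  trace_f <- run_cohort(outcome_row(p_no_complication = 1), 65, "female",
                        fx$lifetable, fx$params)
  trace_m <- run_cohort(outcome_row(p_no_complication = 1), 65, "male",
                        fx$lifetable, fx$params)
  expect_gt(attr(trace_f, "totals")$life_years,
            attr(trace_m, "totals")$life_years)
})

test_that("excess mortality replaces background mortality during its window", {
  ps <- default_parameters()
  lt <- default_lifetable()
  q55 <- cycle_mortality(55, "male", lt, ps)
  expect_equal(q55[1:2], rep(param_value(ps, "excess_mortality_lt61"), 2))
  expect_equal(q55[3], lt$qx[lt$sex == "male" & lt$age == 57])
  q65 <- cycle_mortality(65, "male", lt, ps)
  expect_equal(q65[1:5], rep(param_value(ps, "excess_mortality_61_70"), 5))
  q75 <- cycle_mortality(75, "female", lt, ps)
  expect_equal(q75[1:5], rep(param_value(ps, "excess_mortality_gt70"), 5))
  expect_equal(q75[length(q75)], 1)
})

test_that("strategy totals satisfy the cost bookkeeping identity", {
  ps <- default_parameters()
  for (nm in c("cost_death", "cost_fatal_stroke", "cost_nonfatal_stroke_acute",
               "cost_post_stroke_annual")) {
    ps <- set_value(ps, nm, 0)
  }
  lt <- default_lifetable()
  out <- outcome_row(p_no_complication = 0.97, p_post_stroke = 0.02,
                     p_fatal = 0.005, p_major = 0.0026)
  trace <- run_cohort(out, 55, "male", lt, ps)
  tee <- strategy_totals(trace, out, ps, "tee")
  mp <- strategy_totals(trace, out, ps, "mp")
  increment <- 0.0026 * (23886 - 15628)
  expect_equal(tee$cost, 15628 + 212 + increment)
  expect_equal(mp$cost, 15628 + increment)
  # identical traces: the incremental cost is the device cost alone
  expect_equal(tee$cost - mp$cost, 212)

  # weighted surgery cost at the published major-adaptation rate
  out_full <- outcome_row(p_no_complication = 1, p_major = 0.027)
  trace_full <- run_cohort(out_full, 55, "male", lt, ps)
  mp_full <- strategy_totals(trace_full, out_full, ps, "mp")
  expect_equal(mp_full$cost, 15628 + 0.027 * (23886 - 15628))  # ~15,851
})

test_that("life tables validate and round-trip through CSV", {
  lt <- default_lifetable()
  path <- withr::local_tempfile(fileext = ".csv")
  write_lifetable(lt, path)
  back <- read_lifetable(path)
  expect_equal(as.data.frame(back), as.data.frame(lt), tolerance = 1e-12)

  gap <- lt[-5, ]
  expect_error(run_cohort(outcome_row(), 2, "male", gap,
                          default_parameters()), "cover|gap")
  bad_terminal <- lt
  bad_terminal$qx[bad_terminal$age == 110] <- 0.9
  expect_error(write_lifetable(bad_terminal, path), "qx = 1")
})
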
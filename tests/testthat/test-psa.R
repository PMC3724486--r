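test_that("a degenerate PSA reproduces the deterministic run exactly", {
  fx <- default_fixture()
  ps <- fix_all(fx$params)
  sg <- fx$subgroups[5, ]
  res <- run_psa(ps, sg, fx$lifetable, n_sims = 4, seed = 3)
  det <- evaluate_strategies(sg, ps, fx$lifetable)
  det_mp <- det[det$strategy == "mp", ]
  det_tee <- det[det$strategy == "tee", ]
  expect_equal(res$draws$cost_mp, rep(det_mp$cost, 4))
  expect_equal(res$draws$qalys_tee, rep(det_tee$qalys, 4))
  expect_equal(res$draws$delta_cost, rep(det_tee$cost - det_mp$cost, 4))
  expect_identical(res$n_rejected, 0L)
})

test_that("seeded PSA runs are identical", {
  fx <- default_fixture()
  sg <- fx$subgroups[1, ]
  a <- run_psa(fx$params, sg, fx$lifetable, n_sims = 30, seed = 9)
  b <- run_psa(fx$params, sg, fx$lifetable, n_sims = 30, seed = 9)
  expect_identical(a$draws, b$draws)
  c <- run_psa(fx$params, sg, fx$lifetable, n_sims = 30, seed = 10)
  expect_false(identical(a$draws$delta_cost, c$draws$delta_cost))
})

test_that("PSA means stay near the deterministic point estimates", {
  fx <- default_fixture()
  sg <- fx$subgroups[5, ]
  res <- run_psa(fx$params, sg, fx$lifetable, n_sims = 5000, seed = 21)
  det <- compare_strategies(evaluate_strategies(sg, fx$params, fx$lifetable))
  # nonlinearity shifts the PSA mean, but only mildly
  expect_lt(abs(res$mean_inc_qaly - det$delta_qaly) / abs(det$delta_qaly),
            0.10)
  expect_identical(res$n_sims, 5000)
  expect_identical(nrow(res$draws), 5000L)
})

test_that("ICER ratios carry the correct dominance quadrant", {
  expect_equal(icer(100, 2)$icer, 50)
  expect_identical(icer(100, 2)$quadrant, "NE")
  r <- icer(-58, 0.03)
  expect_lt(r$icer, 0)
  expect_identical(r$quadrant, "SE")
  expect_identical(icer(0, 0.01)$quadrant, "NE")
  expect_equal(icer(0, 0.01)$icer, 0)
  u <- icer(50, 0)
  expect_false(u$defined)
  expect_true(is.na(u$icer))
  expect_identical(icer(10, -1)$quadrant, "NW")
  expect_identical(icer(-10, -1)$quadrant, "SW")
})

test_that("the acceptability curve equals a brute-force NMB count", {
  set.seed(77)
  for (rep in 1:5) {
    draws <- tibble::tibble(
      delta_cost = stats::rnorm(20, sd = 300),
      delta_qaly = stats::rnorm(20, mean = 0.01, sd = 0.05)
    )
    lambdas <- c(0, 1000, 20000, 80000)
    curve <- ceac(draws, lambdas)
    brute <- vapply(lambdas, function(l) {
      hits <- 0
      for (i in 1:20) {
        if (l * draws$delta_qaly[i] - draws$delta_cost[i] >= 0) hits <- hits + 1
      }
      hits / 20
    }, numeric(1))
    expect_identical(curve$probability, brute)
  }
})

test_that("CEAC limits match their quadrant decompositions", {
  set.seed(78)
  draws <- tibble::tibble(delta_cost = stats::rnorm(500, sd = 100),
                          delta_qaly = stats::rnorm(500, sd = 0.02))
  at0 <- ceac(draws, 0)$probability
  expect_equal(at0, mean(draws$delta_cost <= 0))
  at_inf <- ceac(draws, 1e12)$probability
  expect_equal(at_inf, mean(draws$delta_qaly > 0 |
                              (draws$delta_qaly == 0 & draws$delta_cost <= 0)))
  all_dominant <- tibble::tibble(delta_cost = -abs(stats::rnorm(50)),
                                 delta_qaly = abs(stats::rnorm(50)))
  expect_equal(ceac(all_dominant, c(0, 5000, 1e6))$probability, rep(1, 3))
})

test_that("confidence ellipses behave like bivariate-normal regions", {
  # identical draws collapse to a point
  pt <- confidence_ellipse(tibble::tibble(delta_cost = rep(5, 10),
                                          delta_qaly = rep(0.1, 10)))
  expect_true(pt$degenerate)
  expect_equal(unname(pt$radii), c(0, 0))
  expect_equal(unname(pt$center), c(0.1, 5))

  # axis-aligned uncorrelated draws give axis-aligned ellipses
  set.seed(13)
  ax <- confidence_ellipse(tibble::tibble(
    delta_qaly = stats::rnorm(5000, sd = 10),
    delta_cost = stats::rnorm(5000, sd = 0.1)
  ))
  expect_lt(abs(sin(ax$angle)), 0.05)

  # empirical coverage of the 95% region under a known bivariate normal
  set.seed(14)
  n <- 1e5
  x <- stats::rnorm(n)
  y <- 0.6 * x + stats::rnorm(n, sd = 0.8)
  draws <- tibble::tibble(delta_qaly = 0.02 + 0.01 * x,
                          delta_cost = 100 + 250 * y)
  ell <- confidence_ellipse(draws, level = 0.95)
  xy <- cbind(draws$delta_qaly, draws$delta_cost)
  d2 <- stats::mahalanobis(xy, ell$center, ell$cov)
  coverage <- mean(d2 <= stats::qchisq(0.95, 2))
  expect_gt(coverage, 0.94)
  expect_lt(coverage, 0.96)

  expect_error(confidence_ellipse(tibble::tibble(delta_cost = 1,
                                                 delta_qaly = 1)), "3")
})

test_that("tidy, glance and autoplot expose the PSA result", {
  fx <- default_fixture()
  res <- run_psa(fx$params, fx$subgroups[5, ], fx$lifetable,
                 n_sims = 50, seed = 2)
  td <- tidy(res)
  expect_identical(nrow(td), 50L)
  expect_true(all(c("delta_cost", "delta_qaly") %in% names(td)))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("mean_inc_cost", "mean_inc_qaly", "icer", "quadrant",
                    "p_cost_saving_and_gain") %in% names(gl)))
  expect_equal(gl$mean_inc_cost, mean(td$delta_cost))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_ceac(ceac(res, c(0, 20000))), "ggplot")
  expect_s3_class(plot_ce_plane(list(res)), "ggplot")
})
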
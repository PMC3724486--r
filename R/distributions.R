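#' Specify an uncertainty distribution for a model parameter
#'
#' Every uncertain quantity in the model carries a `dist_spec` describing the
#' distribution used for probabilistic sensitivity analysis. Six families are
#' supported, matching the families used for the model inputs: beta (for
#' probabilities), lognormal (for relative risks), uniform and triangular
#' (range-only inputs), gamma (costs), and `fixed` for quantities held at
#' their point value.
#'
#' @param family One of `"beta"`, `"lognormal"`, `"uniform"`, `"triangular"`,
#'   `"gamma"`, `"fixed"`.
#' @param params Numeric vector of family-specific parameters:
#'   beta `(shape1, shape2)`; lognormal `(meanlog, sdlog)` on the natural-log
#'   scale; uniform `(lower, upper)`; triangular `(lower, mode, upper)`;
#'   gamma `(shape, scale)`; fixed `(value)`.
#'
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", c(33, 73))          # manual palpation sensitivity
#' dist_spec("lognormal", c(-0.864, 0.392))  # stroke risk reduction
#' @export
dist_spec <- function(family, params) {
  family <- match.arg(family, dist_families())
  params <- as.numeric(params)
  n_expected <- c(beta = 2L, lognormal = 2L, uniform = 2L,
                  triangular = 3L, gamma = 2L, fixed = 1L)[[family]]
  if (length(params) != n_expected || anyNA(params)) {
    stop(sprintf("'%s' distribution needs %d finite parameter(s)",
                 family, n_expected), call. = FALSE)
  }
  switch(family,
    beta = if (params[1] <= 0 || params[2] <= 0)
      stop("beta shape parameters must be positive", call. = FALSE),
    lognormal = if (params[2] <= 0)
      stop("lognormal sd (log scale) must be positive", call. = FALSE),
    uniform = if (params[1] >= params[2])
      stop("uniform lower bound must be below the upper bound", call. = FALSE),
    triangular = if (params[1] > params[2] || params[2] > params[3] ||
                     params[1] >= params[3])
      stop("triangular parameters must satisfy lower <= mode <= upper, lower < upper",
           call. = FALSE),
    gamma = if (params[1] <= 0 || params[2] <= 0)
      stop("gamma shape and scale must be positive", call. = FALSE)
  )
  structure(list(family = family, params = params), class = "dist_spec")
}

dist_families <- function() {
  c("beta", "lognormal", "uniform", "triangular", "gamma", "fixed")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(format(x$params), collapse = ", ")))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Analytic mean of a distribution specification
#'
#' @param dist A [dist_spec()].
#' @return The analytic mean as a scalar.
#' @examples
#' dist_mean(dist_spec("beta", c(33, 73)))  # 0.3113, prints as 31%
#' @export
dist_mean <- function(dist) {
  stopifnot(is_dist_spec(dist))
  p <- dist$params
  switch(dist$family,
    beta       = p[1] / (p[1] + p[2]),
    lognormal  = exp(p[1] + p[2]^2 / 2),
    uniform    = (p[1] + p[2]) / 2,
    triangular = (p[1] + p[2] + p[3]) / 3,
    gamma      = p[1] * p[2],
    fixed      = p[1]
  )
}

#' Quantiles of a distribution specification
#'
#' @param dist A [dist_spec()].
#' @param probs Numeric vector of probabilities.
#' @return Numeric vector of quantiles. A `fixed` distribution is degenerate:
#'   every quantile equals the value.
#' @export
dist_quantile <- function(dist, probs) {
  stopifnot(is_dist_spec(dist), is.numeric(probs),
            all(probs >= 0 & probs <= 1))
  p <- dist$params
  switch(dist$family,
    beta       = stats::qbeta(probs, p[1], p[2]),
    lognormal  = stats::qlnorm(probs, p[1], p[2]),
    uniform    = stats::qunif(probs, p[1], p[2]),
    triangular = qtriangular(probs, p[1], p[2], p[3]),
    gamma      = stats::qgamma(probs, shape = p[1], scale = p[2]),
    fixed      = rep(p[1], length(probs))
  )
}

#' Summarise a distribution as mean and 95% interval
#'
#' Mirrors the "Value" and "Range" presentation of decision-model parameter
#' tables: the analytic mean together with the 2.5% and 97.5% quantiles.
#'
#' @param dist A [dist_spec()].
#' @return A one-row tibble with columns `family`, `mean`, `q2.5`, `q97.5`.
#' @examples
#' dist_summary(dist_spec("lognormal", c(-0.864, 0.392)))  # q2.5 = 0.196
#' @export
dist_summary <- function(dist) {
  q <- dist_quantile(dist, c(0.025, 0.975))
  tibble::tibble(family = dist$family, mean = dist_mean(dist),
                 `q2.5` = q[1], `q97.5` = q[2])
}

#' Draw random samples from a distribution specification
#'
#' Uses the current R random-number stream, so draws are reproducible under
#' `set.seed()`. A `fixed` distribution always returns its value and does not
#' advance the stream.
#'
#' @param dist A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(dist, n = 1) {
  stopifnot(is_dist_spec(dist), n >= 1)
  p <- dist$params
  switch(dist$family,
    beta       = stats::rbeta(n, p[1], p[2]),
    lognormal  = stats::rlnorm(n, p[1], p[2]),
    uniform    = stats::runif(n, p[1], p[2]),
    triangular = qtriangular(stats::runif(n), p[1], p[2], p[3]),
    gamma      = stats::rgamma(n, shape = p[1], scale = p[2]),
    fixed      = rep(p[1], n)
  )
}

# Closed-form triangular quantile function (inverse CDF); also drives the
# sampler by inverse transform. No triangular distribution ships with stats.
qtriangular <- function(prob, lower, mode, upper) {
  f_mode <- (mode - lower) / (upper - lower)
  left <- lower + sqrt(pmax(prob, 0) * (upper - lower) * (mode - lower))
  right <- upper - sqrt(pmax(1 - prob, 0) * (upper - lower) * (upper - mode))
  ifelse(prob <= f_mode, left, right)
}
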
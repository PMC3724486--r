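# Shared fixture builders for the test suite. Everything is generated in
# code; no data files are read.

# Life table with the same constant annual death probability at every age
# (except the forced 1 at the terminal age), for closed-form checks.
constant_lifetable <- function(q, terminal_age = 110L) {
  ages <- 0:terminal_age
  qx <- rep(q, length(ages))
  qx[length(qx)] <- 1
  dplyr::bind_rows(
    tibble::tibble(sex = "male", age = ages, qx = qx),
    tibble::tibble(sex = "female", age = ages, qx = qx)
  )
}

# Overwrite a parameter's point value (keeps its distribution).
set_value <- function(ps, name, value) {
  stopifnot(name %in% names(ps$params))
  ps$params[[name]]$value <- value
  ps
}

# Collapse every distribution to a point mass at its current value, turning
# the PSA into a degenerate (deterministic) analysis.
fix_all <- function(ps) {
  for (nm in names(ps$params)) {
    ps$params[[nm]]$dist <- dist_spec("fixed", ps$params[[nm]]$value)
  }
  ps
}

# The fixture defines a low and a high prevalence estimate per age; this
# labels which track a subgroup belongs to.
prevalence_track <- function(prevalence) {
  ifelse(prevalence %in% c(0.10, 0.20, 0.40), "low", "high")
}

# A decision-tree outcome row built directly from starting-state fractions,
# bypassing the tree, for Markov-engine unit tests.
outcome_row <- function(p_no_complication = 1, p_post_stroke = 0,
                        p_fatal = 0, p_other = 1 - p_no_complication -
                          p_post_stroke - p_fatal,
                        p_major = 0) {
  tibble::tibble(
    p_minor_adaptation_true = 0,
    p_major_adaptation = p_major,
    p_minor_adaptation_fp = 0,
    p_stroke_nonfatal = p_post_stroke,
    p_stroke_fatal = p_fatal,
    p_death_other = p_other,
    p_no_complication = p_no_complication
  )
}
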
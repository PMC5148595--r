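# records engineered so the pooled q values are known exactly: one subject,
# five utility bins, 10 tasks each with a chosen risky-choice count
bin_fixture <- function(counts, f_bins = c(0.2, 0.3, 0.4, 0.6, 0.7),
                        subject = 1, gender = "F", n_per_bin = 10) {
  stopifnot(length(counts) == length(f_bins))
  # task with f exactly at the bin label: x = 50 p (1 - f) / f; p = 0.2 keeps
  # x below 50 for every bin label down to f = 0.2
  p <- 0.2
  xs <- 50 * p * (1 - f_bins) / f_bins
  do.call(rbind, lapply(seq_along(f_bins), function(i) {
    data.frame(subject = subject, gender = gender, p = p, x = xs[i],
               choice = rep(c(1, 0), c(counts[i], n_per_bin - counts[i])))
  }))
}

test_that("pooled mean |q| matches hand arithmetic on a five-bin fixture", {
  # q = p_exp - f = (0.1, -0.2, 0.3, -0.1, 0.2) by construction
  counts <- round((c(0.2, 0.3, 0.4, 0.6, 0.7) + c(0.1, -0.2, 0.3, -0.1, 0.2)) * 10)
  r <- suppressWarnings(validate_choices(bin_fixture(counts)))
  fit <- quarter_law(r, scheme = "pooled")
  qs <- c(0.1, 0.2, 0.3, 0.1, 0.2)
  expect_equal(fit$mean_abs_q, mean(qs), tolerance = 1e-12)
  expect_equal(fit$sd, sd(qs), tolerance = 1e-12)
  expect_equal(fit$sem, sd(qs) / sqrt(5), tolerance = 1e-12)
  expect_equal(fit$n_units, 5L)
  expect_equal(fit$deviation_sd, abs(0.18 - 0.25) / sd(qs), tolerance = 1e-12)
})

test_that("per-subject scheme averages subject means with across-subject spread", {
  r1 <- bin_fixture(c(3, 1, 5, 5, 8))  # |q| = (.1,.2,.1,.1,.1): mean 0.12
  r2 <- bin_fixture(c(5, 6, 7, 9, 9), subject = 2, gender = "M")
  r <- suppressWarnings(validate_choices(rbind(r1, r2)))
  per <- quarter_law(r, scheme = "per_subject")
  m1 <- mean(abs(c(0.1, -0.2, 0.1, -0.1, 0.1)))
  m2 <- mean(abs(c(0.3, 0.3, 0.3, 0.3, 0.2)))
  expect_equal(per$mean_abs_q, mean(c(m1, m2)), tolerance = 1e-12)
  expect_equal(per$sd, sd(c(m1, m2)), tolerance = 1e-12)
  expect_equal(per$n_units, 2L)
})

test_that("two-value example: means (0.1, 0.3) give mean 0.2 and sd 0.1414", {
  # subject means 0.1 and 0.3 via constant q per subject
  r1 <- bin_fixture(round((c(0.2, 0.3, 0.4, 0.6, 0.7) + 0.1) * 10))
  r2 <- bin_fixture(round((c(0.2, 0.3, 0.4, 0.6, 0.7) + 0.3) * 10), subject = 2)
  r <- suppressWarnings(validate_choices(rbind(r1, r2)))
  per <- quarter_law(r, scheme = "per_subject")
  expect_equal(per$mean_abs_q, 0.2, tolerance = 1e-12)
  expect_equal(per$sd, sd(c(0.1, 0.3)), tolerance = 1e-12)
})

test_that("pooled and per-subject schemes coincide for a single subject", {
  r <- suppressWarnings(validate_choices(bin_fixture(c(3, 1, 7, 5, 9))))
  pooled <- quarter_law(r, "pooled")
  per <- quarter_law(r, "per_subject")
  expect_equal(per$mean_abs_q, pooled$mean_abs_q, tolerance = 1e-12)
})

test_that("a cohort with constant q = 0.25 in every bin has zero spread", {
  # 20 tasks per bin: counts (0.45, 0.55, 0.65, 0.85, 0.95) * 20 are integers
  counts <- (c(0.2, 0.3, 0.4, 0.6, 0.7) + 0.25) * 20
  r <- suppressWarnings(validate_choices(bin_fixture(counts, n_per_bin = 20)))
  fit <- quarter_law(r, "pooled")
  expect_equal(fit$mean_abs_q, 0.25, tolerance = 1e-12)
  expect_equal(fit$sd, 0)
})

test_that("insufficient uncensored bins raise an error", {
  r <- make_records(1:2, c("F", "M"), p = c(0.9, 0.9), x = c(1, 1),
                    choice = c(1, 1))
  expect_error(quarter_law(r, "pooled"), "insufficient data")
})

test_that("attraction factor at the f = 0.5 bin", {
  r <- make_records(1, "F", p = rep(0.5, 10), x = rep(25, 10),
                    choice = rep(c(1, 0), c(3, 7)))
  res <- attraction_at_f(r, 0.5)
  expect_equal(res$q_bar, -0.2, tolerance = 1e-12)
  expect_equal(res$N, 10L)
  r5 <- make_records(1, "F", p = rep(0.5, 4), x = rep(25, 4),
                     choice = c(1, 1, 0, 1))
  expect_equal(attraction_at_f(r5, 0.5)$q_bar, 0.25, tolerance = 1e-12)
  rc <- make_records(1, "F", p = rep(0.5, 4), x = rep(25, 4), choice = rep(1, 4))
  expect_error(attraction_at_f(rc, 0.5), "censored")
})

test_that("transition interval finds the step and identity curves", {
  mk_agg <- function(f, p_exp) {
    data.frame(f = f, N = 10, N1 = round(p_exp * 10), p_exp = p_exp,
               q = p_exp - f, censored = p_exp %in% c(0, 1))
  }
  f <- seq(0.05, 0.95, by = 0.01)
  # monotone identity curve p_exp = f crosses 0.5 and 0.75 at those labels
  a <- mk_agg(f, f)
  ti <- transition_interval(a)
  expect_equal(ti$f_lo, 0.5, tolerance = 0.011)
  expect_equal(ti$f_hi, 0.75, tolerance = 0.011)
  # step at 0.5 (EV maximizer), kept uncensored by a hair for the scan
  a2 <- mk_agg(f, ifelse(f > 0.5, 0.9, 0.1))
  ti2 <- transition_interval(a2)
  expect_equal(ti2$f_lo, 0.51, tolerance = 0.011)
  # the 3-bin moving average spreads the step over at most one extra bin
  expect_gte(ti2$f_hi, ti2$f_lo)
  expect_lte(ti2$f_hi - ti2$f_lo, 0.01 + 1e-9)
  # thresholds never reached: open result
  a3 <- mk_agg(f, rep(0.3, length(f)))
  expect_error(transition_interval(a3), NA)
  expect_true(transition_interval(a3)$open)
})

test_that("a logistic cohort's transition midpoint is recovered", {
  agents <- replicate(4, agent_spec("logistic", k = 20, midpoint = 0.55),
                      simplify = FALSE)
  coh <- generate_cohort(cohort_spec(agents, n_tasks = 2500, seed = 77))
  agg <- qdt_aggregate(coh, by = "utility")
  ti <- transition_interval(agg)
  expect_lte(abs(ti$f_lo - 0.55), 0.02)
})
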
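test_that("state normalization rescales without changing direction or phase", {
  expect_equal(unclass(qdt_state(c(1, 0, 0, 0))), as.complex(c(1, 0, 0, 0)))
  expect_equal(unclass(qdt_state(c(1, 1, 1, 1))), as.complex(rep(0.5, 4)))
  expect_equal(unclass(qdt_state(c(2i, 0, 0, 0))), as.complex(c(1i, 0, 0, 0)))
  expect_equal(sum(Mod(qdt_state(complex(real = 1:4, imaginary = 4:1)))^2), 1,
               tolerance = 1e-12)
  expect_error(qdt_state(c(0, 0, 0, 0)), "all four coefficients are zero")
  expect_error(qdt_prospect(1, c(0, 0)), "both coefficients are zero")
})

test_that("transition probabilities follow the normalized squared overlaps", {
  # state on the option-1 sector is orthogonal to any option-2 prospect
  s <- qdt_state(c(1, 0, 0, 0))
  pr <- list(qdt_prospect(1, c(1, 0)), qdt_prospect(2, c(1, 1)))
  expect_equal(transition_probabilities(s, pr), c(1, 0))
  # fully symmetric case
  s <- qdt_state(c(1, 1, 1, 1))
  pr <- list(qdt_prospect(1, c(1, 1) / sqrt(2)), qdt_prospect(2, c(1, 1) / sqrt(2)))
  expect_equal(transition_probabilities(s, pr), c(0.5, 0.5), tolerance = 1e-12)
  # orthogonal to both prospects is degenerate
  expect_error(transition_probabilities(qdt_state(c(0, 0, 1, -1)),
                                        list(qdt_prospect(1, c(1, 0)),
                                             qdt_prospect(2, c(1, 1)))),
               "degenerate transition")
})

test_that("random instances match the brute-force inner-product oracle", {
  inst <- random_qdt_instances(20, seed = 31)
  for (z in inst) {
    expect_equal(transition_probabilities(z$state, z$prospects),
                 brute_force_p(z$state, z$prospects), tolerance = 1e-12)
  }
})

test_that("decomposition reproduces the interference hand example", {
  s <- qdt_state(c(1, 1, 1, 1))
  pr <- list(qdt_prospect(1, c(1, 1) / sqrt(2)),
             qdt_prospect(2, c(1, -1) / sqrt(2)))
  d <- qdt_decompose(s, pr)
  expect_equal(d$P, 0.5, tolerance = 1e-12)
  expect_equal(d$p, c(1, 0), tolerance = 1e-12)
  expect_equal(d$f, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(d$q, c(0.5, -0.5), tolerance = 1e-12)
  alt <- check_alternation(d)
  expect_equal(alt$sum_q, 0, tolerance = 1e-12)
  expect_true(alt$satisfied)
})

test_that("single-branch prospects carry no interference", {
  s <- qdt_state(complex(real = rnorm(4), imaginary = rnorm(4)))
  pr <- list(qdt_prospect(1, c(0.8, 0)), qdt_prospect(2, c(0, 0.3)))
  d <- qdt_decompose(s, pr)
  expect_equal(d$q, c(0, 0))
  expect_true(check_alternation(d)$satisfied)
  # and p reduces to the classical modulus-squared ratio
  expect_equal(d$p, d$f, tolerance = 1e-12)
})

test_that("alternation can fail: equal-gamma prospects on the undecided state", {
  s <- qdt_state(c(1, 1, 1, 1))
  pr <- list(qdt_prospect(1, c(1, 1) / sqrt(2)), qdt_prospect(2, c(1, 1) / sqrt(2)))
  alt <- check_alternation(qdt_decompose(s, pr))
  expect_equal(alt$sum_f, 0.5, tolerance = 1e-12)
  expect_equal(alt$sum_q, 0.5, tolerance = 1e-12)
  expect_false(alt$satisfied)
})

test_that("identities hold on random instances: sums, p = f + q, phase invariance", {
  inst <- random_qdt_instances(100, seed = 57)
  for (z in inst) {
    d <- qdt_decompose(z$state, z$prospects)
    expect_equal(sum(d$p), 1, tolerance = 1e-12)
    expect_true(all(d$p >= -1e-15 & d$p <= 1 + 1e-15))
    expect_equal(d$p, d$f + d$q, tolerance = 1e-12)
    # q <= p <= 1 always; q >= -1 needs the alternation condition (f summing
    # to one), which generic random states do not satisfy
    expect_true(all(d$f >= 0) && all(d$q <= 1 + 1e-15))
    expect_equal(sum(d$q), 1 - sum(d$f), tolerance = 1e-12)
    if (abs(sum(d$f) - 1) < 1e-12) expect_true(all(abs(d$q) <= 1 + 1e-15))
    # global phase on the state leaves everything unchanged
    ph <- exp(1i * 0.7)
    d2 <- qdt_decompose(qdt_state(unclass(z$state) * ph), z$prospects)
    expect_equal(d2$p, d$p, tolerance = 1e-12)
    expect_equal(d2$q, d$q, tolerance = 1e-12)
  }
})
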
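test_that("the randomized design stays on the 18 x 50 grid", {
  tasks <- generate_tasks(1e4, "ralt", seed = 2)
  expect_true(all(tasks$p %in% seq(0.05, 0.9, by = 0.05)))
  expect_true(all(tasks$x %in% 0:49))
  expect_lte(nrow(unique(tasks[c("p", "x")])), 900L)
  expect_equal(tasks$f, 50 * tasks$p / (50 * tasks$p + tasks$x))
})

test_that("the controlled design replicates every produced bin at least 3 times", {
  tasks <- generate_tasks(300, "controlled", seed = 4, n_bins = 20)
  counts <- table(utility_bin(tasks$f))
  expect_gte(min(counts), 3)
  expect_equal(sum(counts), 300L)
  # explicit bin labels snap to reachable grid bins
  t2 <- generate_tasks(60, "controlled", seed = 4, bins = c(0.05, 0.5, 0.95))
  expect_equal(length(table(utility_bin(t2$f))), 3L)
  expect_error(generate_tasks(5, "controlled", n_bins = 10),
               "infeasible controlled design")
})

test_that("task generation is deterministic under a seed", {
  expect_identical(generate_tasks(500, "ralt", seed = 6),
                   generate_tasks(500, "ralt", seed = 6))
  expect_identical(generate_tasks(200, "controlled", seed = 6),
                   generate_tasks(200, "controlled", seed = 6))
})

test_that("simulate_choice implements each strategy", {
  t_hi <- gain_task(0.7, 15)   # f = 0.7
  t_lo <- gain_task(0.1, 40)   # f = 0.111
  expect_equal(simulate_choice(agent_spec("ev_maximizer"), t_hi), 1L)
  expect_equal(simulate_choice(agent_spec("ev_maximizer"), t_lo), 0L)
  # tie at f = 0.5 resolves to the certain option
  expect_equal(simulate_choice(agent_spec("ev_maximizer"), gain_task(0.5, 25)), 0L)
  # forced q floors the probability at 0
  expect_equal(simulate_choice(agent_spec("qdt"), gain_task(0.1, 40), q = -0.3), 0L)
  # logistic agent's empirical frequency matches the closed-form mean
  set.seed(44)
  ag <- agent_spec("logistic", k = 20, midpoint = 0.55)
  task <- gain_task(0.6, 20)   # f = 0.6
  hits <- replicate(4000, simulate_choice(ag, task))
  p_true <- plogis(20 * (0.6 - 0.55))
  expect_lte(abs(mean(hits) - p_true), 3 * sqrt(p_true * (1 - p_true) / 4000))
})

test_that("cohorts have the study's shape and are reproducible", {
  spec <- cohort_spec(seed = 10)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh), 5400L)
  expect_equal(length(unique(coh$subject)), 27L)
  expect_equal(as.vector(table(coh$gender)) / 200, c(13, 14))
  expect_identical(generate_cohort(spec), coh)
  # byte-identical CSV output
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_choices(generate_cohort(spec), f1)
  write_choices(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an EV-maximizer cohort is censored almost everywhere", {
  agents <- replicate(5, agent_spec("ev_maximizer"), simplify = FALSE)
  coh <- generate_cohort(cohort_spec(agents, seed = 14))
  agg <- qdt_aggregate(coh, by = "utility")
  # deterministic step rule: only a bin straddling f = 0.5 can escape censoring
  expect_true(all(agg$censored[abs(agg$f - 0.5) > 0.01]))
})

test_that("random-sign qdt cohorts recover mean 0 and the target |q|", {
  agents <- replicate(27, agent_spec("qdt", dist = phi_dist("triangular"),
                                     target_abs_q = 0.25,
                                     sign_model = "random_sign"),
                      simplify = FALSE)
  spec <- cohort_spec(agents, design = "controlled",
                      bins = c(0.05, 0.08, 0.12, 0.88, 0.92, 0.96), seed = 18)
  coh <- suppressWarnings(generate_cohort(spec))
  per <- qdt_aggregate(coh, by = "utility", group = "subject")
  qs <- per$q[!per$censored]
  expect_lte(abs(mean(qs)), 3 * sd(qs) / sqrt(length(qs)))
  fit <- suppressWarnings(quarter_law(coh, "per_subject"))
  expect_lte(abs(fit$mean_abs_q - 0.25), 2 * fit$sem)
})

test_that("pairwise KS separates logistic responders from random choosers", {
  # strict EV maximizers leave no uncensored bins at all (previous test), so
  # the responder group is a smooth logistic that stays in the sample; the
  # controlled design with 60 bins x 30 reps gives each subject a q sample
  # large enough for the two-sample KS test to have power (critical D at the
  # 5% level is about 1.36 * sqrt(2/60) ~ 0.25 for 60-point samples)
  agents <- c(replicate(5, agent_spec("logistic", k = 8, midpoint = 0.5),
                        simplify = FALSE),
              replicate(5, agent_spec("random", prob = 0.5), simplify = FALSE))
  coh <- generate_cohort(cohort_spec(agents,
                                     genders = rep(c("F", "M"), each = 5),
                                     design = "controlled", n_bins = 60,
                                     n_tasks = 1800, seed = 26))
  reps <- suppressWarnings(pairwise_subject_ks(coh))
  expect_gt(reps$cross$frac_below, reps$within_A$frac_below)
  expect_gt(reps$cross$frac_below, reps$within_B$frac_below)
  expect_gte(reps$cross$frac_below, 0.3)
})
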
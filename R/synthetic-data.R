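#' Specify an artificial decision maker
#'
#' Agent archetypes for cohort simulation, reflecting the strategy families
#' one observes in real subjects:
#' \describe{
#'   \item{ev_maximizer}{deterministically takes the risky option iff
#'     f(L1) > 0.5 (tie goes to the certain option, consistent with risk
#'     aversion at equal utility).}
#'   \item{logistic}{Bernoulli with probability
#'     \code{1 / (1 + exp(-k (f - midpoint)))}: a noisy threshold.}
#'   \item{threshold_risk_averse}{deterministic risky choice iff
#'     f(L1) > threshold (a conservative cut above 0.5).}
#'   \item{random}{Bernoulli with a constant probability.}
#'   \item{qdt}{chooses the risky option with probability
#'     \code{Ret[0,1](f + q)}, where the attraction factor q has magnitude
#'     drawn from a \code{\link{phi_dist}} rescaled so that E|q| equals
#'     \code{target_abs_q}, and a sign given by the sign model:
#'     \code{"sign_rule"} (negative, as the sign rule predicts for this task
#'     family, flipped to positive with probability \code{flip_prob}),
#'     \code{"random_sign"} (fair coin) or \code{"always_negative"}.}
#' }
#'
#' @param strategy one of the archetypes above.
#' @param k,midpoint logistic steepness and midpoint.
#' @param threshold risky-choice threshold on f.
#' @param prob constant risky-choice probability of the random agent.
#' @param dist a \code{\link{phi_dist}} for the qdt agent's |q| magnitudes.
#' @param target_abs_q target mean |q| in (0, 1) (default 0.25; the raw
#'   families have E|q| = 1/2, so the default rescales by 1/2).
#' @param sign_model sign model of the qdt agent.
#' @param flip_prob probability of a positive sign under \code{"sign_rule"}.
#' @return Object of class \code{agent_spec}.
#' @export
agent_spec <- function(strategy = c("qdt", "ev_maximizer", "logistic",
                                    "threshold_risk_averse", "random"),
                       k = 20, midpoint = 0.55, threshold = 0.6, prob = 0.5,
                       dist = phi_dist("triangular"), target_abs_q = 0.25,
                       sign_model = c("sign_rule", "random_sign",
                                      "always_negative"),
                       flip_prob = 0.2) {
  strategy <- match.arg(strategy)
  sign_model <- match.arg(sign_model)
  stopifnot(prob >= 0, prob <= 1, flip_prob >= 0, flip_prob <= 1,
            target_abs_q > 0, target_abs_q < 1, inherits(dist, "phi_dist"))
  structure(list(strategy = strategy, k = k, midpoint = midpoint,
                 threshold = threshold, prob = prob, dist = dist,
                 target_abs_q = target_abs_q, sign_model = sign_model,
                 flip_prob = flip_prob),
            class = "agent_spec")
}

#' Generate a list of decision tasks
#'
#' Two designs:
#' \describe{
#'   \item{ralt}{the randomized-lottery design that produced the original
#'     data: i.i.d. uniform draws from the 18 x 50 grid of win probabilities
#'     p in \{0.05, ..., 0.90\} (step 0.05) and sure amounts x in
#'     \{0, ..., 49\} (step 1), top prize y = 50.}
#'   \item{controlled}{a replication-friendly design: \code{n_bins}
#'     utility-factor bins are selected from the grid (half spread over the
#'     reachable range, half concentrated in the transition region
#'     f in [0.4, 0.7]), and tasks are drawn so every produced bin occurs at
#'     least 3 times, with task order randomized.}
#' }
#'
#' @param n number of tasks (>= 1).
#' @param design \code{"ralt"} or \code{"controlled"}.
#' @param seed optional integer seed.
#' @param n_bins number of target utility bins for the controlled design.
#' @param bins optional explicit utility-bin labels for the controlled
#'   design (each snapped to the nearest bin reachable on the grid);
#'   overrides \code{n_bins}. Useful for replication-heavy designs, e.g.
#'   bins at extreme f where censoring does not truncate the attraction
#'   factor.
#' @param bin_width utility-bin width.
#' @return data.frame of class \code{task_design} with columns \code{p},
#'   \code{x}, \code{y}, \code{f}.
#' @export
generate_tasks <- function(n, design = c("ralt", "controlled"), seed = NULL,
                           n_bins = 25, bins = NULL, bin_width = 0.01) {
  design <- match.arg(design)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(p = seq(0.05, 0.90, by = 0.05), x = 0:49)
  grid$f <- 50 * grid$p / (50 * grid$p + grid$x)
  if (design == "ralt") {
    i <- sample.int(nrow(grid), n, replace = TRUE)
    tasks <- grid[i, ]
  } else {
    grid$bin <- utility_bin(grid$f, bin_width)
    avail <- sort(unique(grid$bin))
    if (!is.null(bins)) {
      sel <- unique(vapply(bins, function(b) avail[which.min(abs(avail - b))],
                           numeric(1)))
    } else {
      trans <- avail[avail >= 0.4 & avail <= 0.7]
      pick_spread <- function(v, k) v[unique(round(seq(1, length(v), length.out = k)))]
      k_half <- ceiling(n_bins / 2)
      sel <- unique(c(pick_spread(avail, n_bins - k_half + 1L),
                      pick_spread(trans, k_half)))
      # top up with unused transition bins if de-duplication lost some
      extra <- setdiff(trans, sel)
      if (length(sel) < n_bins && length(extra)) {
        sel <- c(sel, extra[seq_len(min(n_bins - length(sel), length(extra)))])
      }
    }
    if (n < 3 * length(sel)) {
      stop(sprintf(
        "infeasible controlled design: n = %d cannot give %d bins >= 3 tasks each",
        n, length(sel)), call. = FALSE)
    }
    reps <- rep(floor(n / length(sel)), length(sel))
    short <- n - sum(reps)
    if (short > 0) reps[seq_len(short)] <- reps[seq_len(short)] + 1L
    rows <- unlist(lapply(seq_along(sel), function(i) {
      cand <- which(grid$bin == sel[i])
      cand[sample.int(length(cand), reps[i], replace = TRUE)]
    }))
    tasks <- grid[sample(rows), c("p", "x", "f")]
  }
  tasks <- data.frame(p = tasks$p, x = tasks$x, y = 50, f = tasks$f)
  rownames(tasks) <- NULL
  class(tasks) <- c("task_design", "data.frame")
  tasks
}

#' Simulate one choice
#'
#' Draws the binary decision of an agent on one task using the current RNG
#' state. For the qdt strategy a fresh attraction factor is drawn unless
#' \code{q} is supplied; \code{\link{generate_cohort}} supplies a per-bin
#' persistent q so that repeated tasks in a bin share the same attraction
#' (see the methods vignette).
#'
#' @param agent an \code{\link{agent_spec}}.
#' @param task a \code{\link{gain_task}} or any list with \code{p}, \code{x},
#'   \code{y}.
#' @param q optional attraction factor forced on a qdt agent.
#' @return 0 (certain) or 1 (risky).
#' @export
simulate_choice <- function(agent, task, q = NULL) {
  stopifnot(inherits(agent, "agent_spec"))
  f <- task$y * task$p / (task$y * task$p + task$x)
  switch(agent$strategy,
    ev_maximizer = as.integer(f > 0.5),
    logistic = stats::rbinom(1L, 1L, stats::plogis(agent$k * (f - agent$midpoint))),
    threshold_risk_averse = as.integer(f > agent$threshold),
    random = stats::rbinom(1L, 1L, agent$prob),
    qdt = {
      if (is.null(q)) q <- draw_attraction(1L, agent)
      stats::rbinom(1L, 1L, retract(f + q, 0, 1))
    }
  )
}

# n attraction factors of a qdt agent: rescaled magnitude, modelled sign
draw_attraction <- function(n, agent) {
  m <- pmin(rphi_magnitude(n, agent$dist) * agent$target_abs_q / 0.5, 1)
  s <- switch(agent$sign_model,
    always_negative = rep(-1, n),
    random_sign = sample(c(-1, 1), n, replace = TRUE),
    sign_rule = ifelse(stats::runif(n) < agent$flip_prob, 1, -1)
  )
  m * s
}

#' Specify a synthetic cohort
#'
#' @param agents list of \code{\link{agent_spec}} objects (one per subject);
#'   defaults to \code{n_agents} copies of the default qdt agent.
#' @param n_agents number of subjects when \code{agents} is NULL (default 27,
#'   the study's cohort size).
#' @param genders character vector of "F"/"M" labels, one per agent; default
#'   13 F then 14 M for 27 agents, otherwise an alternating split.
#' @param n_tasks decision tasks per agent (default 200, as in the study).
#' @param design task design, \code{"ralt"} or \code{"controlled"}.
#' @param seed master seed; per-agent substreams are derived from it.
#' @param ... passed to \code{\link{generate_tasks}} (e.g. \code{n_bins}).
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(agents = NULL, n_agents = 27, genders = NULL,
                        n_tasks = 200, design = c("ralt", "controlled"),
                        seed = 1, ...) {
  design <- match.arg(design)
  if (is.null(agents)) agents <- replicate(n_agents, agent_spec(), simplify = FALSE)
  stopifnot(length(agents) >= 1L, n_tasks >= 1L,
            all(vapply(agents, inherits, TRUE, "agent_spec")))
  n <- length(agents)
  if (is.null(genders)) {
    genders <- rep(c("F", "M"), c(floor(n / 2), ceiling(n / 2)))
  }
  stopifnot(length(genders) == n, all(genders %in% c("F", "M")))
  structure(list(agents = agents, genders = genders, n_tasks = n_tasks,
                 design = design, seed = as.integer(seed),
                 task_args = list(...)),
            class = "cohort_spec")
}

# deterministic per-agent substream seed below 2^31
agent_seed <- function(master, i) {
  (as.numeric(master) * 48271 + i * 7919) %% 2147483647 + 1
}

#' Simulate a cohort of decision makers
#'
#' For each agent a fresh task list is generated and choices are simulated
#' from the agent's strategy, using a deterministic per-agent RNG substream
#' derived from the master seed (so the same spec always yields the same
#' records, and editing one agent does not perturb the others' streams).
#' For qdt agents the attraction factor is persistent per utility bin: drawn
#' once when the agent first meets a bin and reused on repetitions, which is
#' what makes the target E|q| recoverable from repeated choice frequencies.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A choice-record data.frame (columns subject, gender, p, x,
#'   choice) valid for \code{\link{write_choices}}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", length(spec$agents))
  for (i in seq_along(spec$agents)) {
    agent <- spec$agents[[i]]
    set.seed(agent_seed(spec$seed, i))
    tasks <- do.call(generate_tasks,
                     c(list(n = spec$n_tasks, design = spec$design),
                       spec$task_args))
    if (agent$strategy == "qdt") {
      bins <- utility_bin(tasks$f)
      ub <- unique(bins)
      qtab <- stats::setNames(draw_attraction(length(ub), agent),
                              format(ub, nsmall = 2))
      prob <- retract(tasks$f + qtab[format(bins, nsmall = 2)], 0, 1)
      choice <- stats::rbinom(nrow(tasks), 1L, prob)
    } else if (agent$strategy == "ev_maximizer") {
      choice <- as.integer(tasks$f > 0.5)
    } else if (agent$strategy == "threshold_risk_averse") {
      choice <- as.integer(tasks$f > agent$threshold)
    } else if (agent$strategy == "logistic") {
      choice <- stats::rbinom(nrow(tasks), 1L,
                              stats::plogis(agent$k * (tasks$f - agent$midpoint)))
    } else {
      choice <- stats::rbinom(nrow(tasks), 1L, agent$prob)
    }
    out[[i]] <- data.frame(subject = i, gender = spec$genders[i],
                           p = tasks$p, x = tasks$x, choice = choice,
                           stringsAsFactors = FALSE)
  }
  validate_choices(do.call(rbind, out), warn_off_grid = FALSE)
}
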
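#' Decision-maker state on the two-option, two-belief basis
#'
#' A decision maker deliberating over two options (choose lottery 1 or
#' lottery 2) under an internal binary uncertainty is represented as a
#' normalized vector in the four-dimensional complex Hilbert space spanned by
#' \code{|A1B1>, |A1B2>, |A2B1>, |A2B2>}: the A register carries the option,
#' the B register the decision maker's confidence/disbelief about the setup.
#'
#' @param alpha complex (or numeric) vector of length 4: the amplitudes on
#'   \code{|A1B1>, |A1B2>, |A2B1>, |A2B2>}, in that order. Not all zero.
#'   The vector is rescaled to unit norm; a global complex phase is physically
#'   irrelevant and is preserved as given.
#' @return An object of class \code{qdt_state}: a complex length-4 vector with
#'   unit norm.
#' @examples
#' qdt_state(c(1, 1, 1, 1))        # the fully undecided state
#' qdt_state(c(2i, 0, 0, 0))       # rescaling keeps the phase
#' @export
qdt_state <- function(alpha) {
  alpha <- as.complex(alpha)
  if (length(alpha) != 4L || anyNA(alpha)) {
    stop("'alpha' must be four complex coefficients with no NA", call. = FALSE)
  }
  nrm <- sqrt(sum(Mod(alpha)^2))
  if (nrm == 0) {
    stop("invalid state: all four coefficients are zero", call. = FALSE)
  }
  structure(alpha / nrm, class = "qdt_state")
}

#' @export
print.qdt_state <- function(x, ...) {
  cat("Decision-maker state |psi> on {|A1B1>, |A1B2>, |A2B1>, |A2B2>}:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Prospect state for one of the two options
#'
#' The prospect state for option j lives entirely on the \code{|Aj B1>},
#' \code{|Aj B2>} sector: committing to option j while remaining in a
#' superposition over the belief register. Prospect states need not be
#' normalized (the transition probability normalizes over both prospects),
#' but must not be the zero vector.
#'
#' @param index 1 or 2, the option the prospect commits to.
#' @param gamma complex (or numeric) vector of length 2: amplitudes on
#'   \code{|Aj B1>} and \code{|Aj B2>}. At least one nonzero.
#' @return An object of class \code{qdt_prospect}.
#' @examples
#' qdt_prospect(1, c(1, 1) / sqrt(2))
#' qdt_prospect(2, c(1, -1) / sqrt(2))
#' @export
qdt_prospect <- function(index, gamma) {
  index <- as.integer(index)
  if (!index %in% c(1L, 2L)) stop("'index' must be 1 or 2", call. = FALSE)
  gamma <- as.complex(gamma)
  if (length(gamma) != 2L || anyNA(gamma)) {
    stop("'gamma' must be two complex coefficients with no NA", call. = FALSE)
  }
  if (all(Mod(gamma) == 0)) {
    stop("invalid prospect: both coefficients are zero", call. = FALSE)
  }
  structure(list(index = index, gamma = gamma), class = "qdt_prospect")
}

#' @export
print.qdt_prospect <- function(x, ...) {
  cat(sprintf("Prospect state |pi%d> on {|A%dB1>, |A%dB2>}:\n",
              x$index, x$index, x$index))
  print(x$gamma, ...)
  invisible(x)
}

# overlap <psi|pi_j> = sum_l conj(alpha_{j l}) gamma_l; state coefficients are
# laid out (a11, a12, a21, a22) so option j occupies positions 2j-1, 2j.
overlap <- function(state, prospect) {
  j <- prospect$index
  a <- unclass(state)[c(2L * j - 1L, 2L * j)]
  sum(Conj(a) * prospect$gamma)
}

check_prospect_pair <- function(prospects) {
  if (!is.list(prospects) || length(prospects) != 2L ||
      !inherits(prospects[[1L]], "qdt_prospect") ||
      !inherits(prospects[[2L]], "qdt_prospect")) {
    stop("'prospects' must be a list of two qdt_prospect objects", call. = FALSE)
  }
  if (prospects[[1L]]$index == prospects[[2L]]$index) {
    stop("the two prospects must commit to different options", call. = FALSE)
  }
  prospects[order(vapply(prospects, `[[`, 1L, "index"))]
}

#' Transition probabilities from a decision-maker state to the two prospects
#'
#' The probability of choosing option j is the squared overlap of the state
#' with the prospect state, normalized over the two admissible prospects:
#' \code{p_j = |<psi|pi_j>|^2 / P} with \code{P = |<psi|pi_1>|^2 +
#' |<psi|pi_2>|^2}, so the two probabilities sum to one.
#'
#' @param state a \code{\link{qdt_state}}.
#' @param prospects list of two \code{\link{qdt_prospect}} objects, one per
#'   option (any order).
#' @return Numeric vector \code{c(p1, p2)} summing to 1.
#' @export
transition_probabilities <- function(state, prospects) {
  qdt_decompose(state, prospects)$p
}

#' Decompose choice probabilities into utility and attraction factors
#'
#' The squared overlap splits into modulus-squared ("classical") terms and
#' interference cross terms. Normalized by P, the former are the utility
#' factors f and the latter the attraction factors q, with the exact identity
#' \code{p = f + q} componentwise. The attraction factor carries the
#' subjective, contextual component of the choice.
#'
#' @inheritParams transition_probabilities
#' @return Object of class \code{qdt_decomposition}: a list with numeric
#'   pairs \code{p}, \code{f}, \code{q} and the scalar normalizer \code{P}.
#' @examples
#' s <- qdt_state(c(1, 1, 1, 1))
#' pr <- list(qdt_prospect(1, c(1, 1) / sqrt(2)),
#'            qdt_prospect(2, c(1, -1) / sqrt(2)))
#' qdt_decompose(s, pr)   # p = (1, 0), f = (0.5, 0.5), q = (0.5, -0.5)
#' @export
qdt_decompose <- function(state, prospects) {
  if (!inherits(state, "qdt_state")) state <- qdt_state(state)
  prospects <- check_prospect_pair(prospects)
  a <- unclass(state)
  ov <- vapply(prospects, overlap, complex(1), state = state)
  P <- sum(Mod(ov)^2)
  if (P <= 0) {
    stop("degenerate transition: state orthogonal to both prospects (P = 0)",
         call. = FALSE)
  }
  p <- Mod(ov)^2 / P
  f <- q <- numeric(2L)
  for (j in 1:2) {
    g <- prospects[[j]]$gamma
    aj <- a[c(2L * j - 1L, 2L * j)]
    f[j] <- sum(Mod(aj)^2 * Mod(g)^2) / P
    # interference cross terms: conj(a1) g1 a2 conj(g2) + its conjugate
    q[j] <- 2 * Re(Conj(aj[1L]) * g[1L] * aj[2L] * Conj(g[2L])) / P
  }
  structure(list(p = p, f = f, q = q, P = P), class = "qdt_decomposition")
}

#' @export
print.qdt_decomposition <- function(x, digits = 4, ...) {
  cat("QDT decomposition p = f + q (normalizer P =",
      format(x$P, digits = digits), ")\n")
  m <- rbind(p = x$p, f = x$f, q = x$q)
  colnames(m) <- c("L1", "L2")
  print(round(m, digits))
  invisible(x)
}

#' Check the alternation condition on a decomposition
#'
#' The alternation conditions require each attraction factor to lie in
#' [-1, 1] and the two to sum to zero, which holds exactly when the utility
#' factors sum to one. Since the probabilities always sum to one and
#' \code{p = f + q}, the report's \code{sum_q} equals \code{1 - sum_f}.
#'
#' @param d a \code{\link{qdt_decompose}} result.
#' @param tol tolerance on \code{|q1 + q2|} for the satisfied flag.
#' @return List with \code{sum_f}, \code{sum_q} and logical \code{satisfied}.
#' @export
check_alternation <- function(d, tol = 1e-12) {
  stopifnot(inherits(d, "qdt_decomposition"), tol >= 0)
  sum_f <- sum(d$f)
  sum_q <- sum(d$q)
  list(sum_f = sum_f, sum_q = sum_q, satisfied = abs(sum_q) <= tol)
}

#' Draw random decision-maker states and prospect pairs
#'
#' Real and imaginary parts are drawn i.i.d. standard normal and normalized,
#' giving the uniform (Haar) distribution on the complex unit sphere. Used by
#' property tests and by the QDT-agent option of the cohort simulator.
#'
#' @param n number of draws.
#' @param seed optional integer seed (set before drawing when given).
#' @return List of \code{n} lists, each with elements \code{state} and
#'   \code{prospects}.
#' @export
random_qdt_instances <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n, simplify = FALSE, {
    st <- qdt_state(complex(real = rnorm(4), imaginary = rnorm(4)))
    pr <- list(
      qdt_prospect(1, complex(real = rnorm(2), imaginary = rnorm(2))),
      qdt_prospect(2, complex(real = rnorm(2), imaginary = rnorm(2)))
    )
    list(state = st, prospects = pr)
  })
}
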
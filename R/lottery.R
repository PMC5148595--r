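#' Lottery in the domain of gains
#'
#' A lottery is a finite set of non-negative monetary outcomes with
#' probabilities summing to one. In the study design the risky option is
#' \code{\{0, 1-p | y, p\}} and the certain option \code{\{x, 1\}}.
#'
#' @param payoffs numeric vector of non-negative payoffs (CHF).
#' @param probs numeric vector of probabilities, same length, summing to 1
#'   (tolerance 1e-9).
#' @return Object of class \code{lottery}.
#' @examples
#' risky   <- lottery(c(0, 50), c(0.6, 0.4))
#' certain <- lottery(10, 1)
#' @export
lottery <- function(payoffs, probs) {
  payoffs <- as.numeric(payoffs)
  probs <- as.numeric(probs)
  if (length(payoffs) != length(probs) || length(payoffs) < 1L) {
    stop("'payoffs' and 'probs' must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (anyNA(payoffs) || anyNA(probs) || any(payoffs < 0)) {
    stop("payoffs must be non-negative and free of NA (domain of gains)",
         call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(payoffs = payoffs, probs = probs), class = "lottery")
}

#' @export
print.lottery <- function(x, ...) {
  cat("Lottery {", paste(sprintf("%g CHF w.p. %g", x$payoffs, x$probs),
                         collapse = " | "), "}\n")
  invisible(x)
}

#' Expected value of a lottery
#'
#' @param lottery a \code{\link{lottery}}.
#' @return The probability-weighted sum of payoffs, in CHF.
#' @export
expected_value <- function(lottery) {
  stopifnot(inherits(lottery, "lottery"))
  sum(lottery$payoffs * lottery$probs)
}

#' Risky-vs-certain decision task
#'
#' One forced choice between the risky lottery \code{\{0, 1-p | y, p\}}
#' (win the top prize y with probability p, else nothing) and the certain
#' amount x. The experiment used y = 50 CHF, p on a 0.05 grid in
#' [0.05, 0.90] and integer x in [0, 49]; off-grid values are allowed since
#' they are well-defined tasks.
#'
#' @param p win probability of the risky option, in (0, 1].
#' @param x sure amount, CHF, with 0 <= x < y.
#' @param y top prize of the risky option, CHF (default 50).
#' @return Object of class \code{gain_task}.
#' @export
gain_task <- function(p, x, y = 50) {
  if (!is.numeric(p) || p <= 0 || p > 1) stop("'p' must be in (0, 1]", call. = FALSE)
  if (!is.numeric(x) || x < 0 || x >= y) stop("'x' must satisfy 0 <= x < y", call. = FALSE)
  structure(list(p = p, x = x, y = y), class = "gain_task")
}

#' Utility factors of a decision task
#'
#' The utility factor of the risky option is its (belief-weighted) expected
#' value normalized by the sum over both options:
#' \code{f1 = U1 exp(b U1) / (U1 exp(b U1) + U2 exp(b U2))} with
#' \code{U1 = y p}, \code{U2 = x}. For belief parameter \code{beta = 0} (the
#' default, used throughout the analysis) this is \code{y p / (y p + x)}.
#' The two factors are non-negative and sum to one.
#'
#' @param task a \code{\link{gain_task}}, or the win probability \code{p} if
#'   \code{x} is supplied.
#' @param beta non-negative belief parameter (default 0).
#' @param x,y alternative scalar interface: sure amount and top prize.
#' @return Numeric pair \code{c(f1, f2)}.
#' @examples
#' utility_factors(gain_task(0.1, 42))[1]   # 0.10638..., prints as 0.106
#' utility_factors(0.05, x = 22)[1]         # 0.10204...
#' @export
utility_factors <- function(task, beta = 0, x = NULL, y = 50) {
  if (!inherits(task, "gain_task")) {
    if (is.null(x)) stop("supply a gain_task or both 'p' and 'x'", call. = FALSE)
    task <- gain_task(task, x, y)
  }
  if (!is.numeric(beta) || beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  u <- c(task$y * task$p, task$x)
  if (sum(u) <= 0) {
    stop("undefined utility: both expected values are zero", call. = FALSE)
  }
  if (beta == 0) {
    f <- u / sum(u)
  } else {
    w <- u * exp(beta * u)
    f <- w / sum(w)
  }
  f
}

#' Sign of the attraction factor for close utility factors
#'
#' For two gain lotteries with comparable utility factors, the sign of the
#' first prospect's attraction factor is fixed by the gain factor
#' \code{g = xmax / ymax} (best payoff of L1 over best payoff of L2), the
#' risk factor \code{r = p2(ymin) / p1(xmin)} of choosing L2 (set to 0 when
#' L2's worst payoff is certain), and \code{alpha = g * r - 1}: the sign is
#' +1 when alpha > 0 and -1 when alpha <= 0 (the boundary alpha = 0 maps
#' to -1).
#'
#' @param L1,L2 \code{\link{lottery}} objects (L1 the prospect whose
#'   attraction-factor sign is sought).
#' @return List of class \code{sign_rule} with \code{g}, \code{r},
#'   \code{alpha} and \code{sign} (+1 or -1).
#' @examples
#' # the study's task family: risky {50,p | 0,1-p} vs certain {y,1}, y < 50
#' sign_rule(lottery(c(50, 0), c(0.4, 0.6)), lottery(20, 1))  # alpha = -1
#' @export
sign_rule <- function(L1, L2) {
  stopifnot(inherits(L1, "lottery"), inherits(L2, "lottery"))
  x_max <- max(L1$payoffs)
  x_min <- min(L1$payoffs)
  y_max <- max(L2$payoffs)
  y_min <- min(L2$payoffs)
  if (y_max <= 0) stop("L2 must have a positive best payoff", call. = FALSE)
  g <- x_max / y_max
  p2_ymin <- sum(L2$probs[L2$payoffs == y_min])
  if (p2_ymin >= 1) {
    r <- 0
  } else {
    p1_xmin <- sum(L1$probs[L1$payoffs == x_min])
    if (p1_xmin <= 0) {
      stop("undefined risk factor: L1 assigns probability 0 to its worst payoff",
           call. = FALSE)
    }
    r <- p2_ymin / p1_xmin
  }
  alpha <- g * r - 1
  structure(list(g = g, r = r, alpha = alpha,
                 sign = if (alpha > 0) 1L else -1L),
            class = "sign_rule")
}

#' @export
print.sign_rule <- function(x, ...) {
  cat(sprintf("gain factor g = %g, risk factor r = %g, alpha = %g => sgn q(L1) = %+d\n",
              x$g, x$r, x$alpha, x$sign))
  invisible(x)
}
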
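#' Fit the quarter-law summary of a choice dataset
#'
#' The central estimator of the package. Choice records are pooled into
#' utility-factor bins, censored aggregates (empirical frequency exactly 0 or
#' 1) are dropped, and the mean absolute attraction factor \code{mean |q|} is
#' computed under one of two schemes:
#' \describe{
#'   \item{\code{"pooled"}}{all (filtered) subjects' choices are merged before
#'     binning, giving one q per bin; the mean, sd and SEM are taken over the
#'     uncensored bins (the sample is treated as a single entity).}
#'   \item{\code{"per_subject"}}{each subject is binned and averaged on their
#'     own, giving one mean |q| per subject; the mean, sd and SEM are taken
#'     across subjects.}
#' }
#' The quarter law predicts \code{mean |q| = 0.25} in the absence of prior
#' information; the fit reports the deviation from 0.25 in units of the sd
#' and of the SEM. Sample (n-1) standard deviations are used;
#' \code{SEM = sd / sqrt(n_units)}.
#'
#' @param records validated choice records (see \code{\link{read_choices}}).
#' @param scheme \code{"pooled"} or \code{"per_subject"}.
#' @param gender optional filter: \code{"F"} or \code{"M"} restricts the fit
#'   to that group; \code{NULL} uses everyone.
#' @param bin_width utility-bin width (default 0.01).
#' @param y top prize (default 50).
#' @return Object of class \code{quarter_law}: a list with
#'   \code{mean_abs_q}, \code{sd}, \code{sem}, \code{n_units},
#'   \code{deviation_sd}, \code{deviation_sem}, \code{scheme},
#'   \code{gender}, the per-unit values (\code{unit_values}) and, for the
#'   pooled scheme, the aggregate table. A per-subject fit on a single
#'   subject returns its mean with \code{NA} spread.
#' @examples
#' set.seed(1)
#' coh <- generate_cohort(cohort_spec(n_agents = 6, seed = 11))
#' fit <- quarter_law(coh, scheme = "per_subject")
#' fit
#' summary(fit)
#' @export
quarter_law <- function(records, scheme = c("pooled", "per_subject"),
                        gender = NULL, bin_width = 0.01, y = 50) {
  scheme <- match.arg(scheme)
  records <- validate_choices(records, y = y, warn_off_grid = FALSE)
  if (!is.null(gender)) {
    if (!gender %in% c("F", "M")) stop("'gender' must be \"F\" or \"M\"", call. = FALSE)
    records <- records[records$gender == gender, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records for gender ", gender, call. = FALSE)
  }
  agg <- NULL
  if (scheme == "pooled") {
    agg <- qdt_aggregate(records, by = "utility", bin_width = bin_width, y = y)
    vals <- abs(agg$q[!agg$censored])
    if (length(vals) < 2L) {
      stop("insufficient data: fewer than 2 uncensored utility bins", call. = FALSE)
    }
  } else {
    per <- qdt_aggregate(records, by = "utility", bin_width = bin_width,
                         group = "subject", y = y)
    vals <- vapply(split(per, per$group), function(a) {
      u <- abs(a$q[!a$censored])
      if (length(u) == 0L) NA_real_ else mean(u)
    }, numeric(1))
    if (anyNA(vals)) {
      warning(sum(is.na(vals)), " subject(s) with no uncensored bins excluded")
      vals <- vals[!is.na(vals)]
    }
    if (length(vals) < 1L) {
      stop("insufficient data: no subjects with uncensored bins",
           call. = FALSE)
    }
  }
  m <- mean(vals)
  s <- stats::sd(vals)
  n <- length(vals)
  sem <- s / sqrt(n)
  structure(list(
    mean_abs_q = m, sd = s, sem = sem, n_units = n,
    deviation_sd = abs(m - 0.25) / s,
    deviation_sem = abs(m - 0.25) / sem,
    scheme = scheme, gender = if (is.null(gender)) "all" else gender,
    bin_width = bin_width, unit_values = vals, aggregates = agg
  ), class = "quarter_law")
}

#' @export
print.quarter_law <- function(x, ...) {
  cat(sprintf("Quarter-law fit (%s scheme, group: %s)\n", x$scheme, x$gender))
  cat(sprintf("  mean |q(L1)| = %.2f +/- %.2f (SEM %.2f), over %d %s\n",
              x$mean_abs_q, x$sd, x$sem, x$n_units,
              if (x$scheme == "pooled") "utility bins" else "subjects"))
  invisible(x)
}

#' @export
coef.quarter_law <- function(object, ...) {
  c(mean_abs_q = object$mean_abs_q, sd = object$sd, sem = object$sem)
}

#' @export
summary.quarter_law <- function(object, ...) {
  structure(object, class = c("summary.quarter_law", "quarter_law"))
}

#' @export
print.summary.quarter_law <- function(x, ...) {
  print.quarter_law(x)
  cat(sprintf("  deviation from 0.25: %.2f sd, %.1f SEM\n",
              x$deviation_sd, x$deviation_sem))
  # agreement at the 95% level means the gap is below ~2 (not 1) sd
  cat("  verdict (sd): ",
      if (is.na(x$deviation_sd)) "undetermined (no spread estimate)"
      else if (x$deviation_sd <= 2) "consistent with the quarter law at 95% (sd)"
      else "not consistent with the quarter law at 95% (sd)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.quarter_law <- function(x, ...) {
  agg <- x$aggregates
  if (is.null(agg)) {
    stop("plot is available for the pooled scheme (needs the aggregate table)",
         call. = FALSE)
  }
  plot(agg$f, agg$p_exp, cex = sqrt(agg$N / max(agg$N)) * 3,
       xlab = "utility factor f(L1)", ylab = "empirical p(L1)",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 1)
  abline(0.25, 1, lty = 3)
  abline(-0.25, 1, lty = 2)
  invisible(x)
}

#' Attraction factor at a given utility-factor bin
#'
#' Pools every record falling in the bin labeled \code{f0} and returns
#' \code{q_bar = p_exp - f0}. At f0 = 0.5 the two options have equal expected
#' value and the sign rule predicts a negative attraction factor for the
#' risky option (risk aversion).
#'
#' @param records validated choice records.
#' @param f0 bin label (lower edge), default 0.50.
#' @param bin_width bin width, default 0.01.
#' @param y top prize.
#' @return List with \code{q_bar} and \code{N} (tasks in the bin).
#' @export
attraction_at_f <- function(records, f0 = 0.50, bin_width = 0.01, y = 50) {
  records <- validate_choices(records, y = y, warn_off_grid = FALSE)
  f <- utility_bin(task_utility(records, y), bin_width)
  sel <- abs(f - f0) < bin_width / 2
  N <- sum(sel)
  if (N == 0L) stop("no records in the f0 bin", call. = FALSE)
  p_exp <- mean(records$choice[sel])
  if (p_exp == 0 || p_exp == 1) {
    stop("censored bin: empirical frequency is exactly 0 or 1", call. = FALSE)
  }
  list(q_bar = p_exp - f0, N = N)
}

#' Locate the preference transition along the utility factor
#'
#' A descriptive device: a 3-bin moving average of the empirical frequency
#' p_exp is scanned over the uncensored aggregates sorted by f, and the first
#' bin labels at which it reaches \code{lo_threshold} and
#' \code{hi_threshold} are reported. This summarizes where the group switches
#' from the certain to the risky option; it is a package-defined descriptor,
#' not an estimator of a published quantity.
#'
#' @param aggregates a \code{\link{qdt_aggregate}} table (pooled).
#' @param lo_threshold,hi_threshold thresholds on the smoothed p_exp
#'   (defaults 0.5 and 0.75).
#' @return List with \code{f_lo}, \code{f_hi} (NA with \code{open = TRUE}
#'   when a threshold is never reached).
#' @export
transition_interval <- function(aggregates, lo_threshold = 0.5,
                                hi_threshold = 0.75) {
  a <- aggregates[!aggregates$censored, , drop = FALSE]
  a <- a[order(a$f), , drop = FALSE]
  if (nrow(a) < 3L || min(a$f) >= 0.5 || max(a$f) <= 0.7) {
    stop("need at least 3 uncensored bins spanning f < 0.5 and f > 0.7",
         call. = FALSE)
  }
  ma <- stats::filter(a$p_exp, rep(1 / 3, 3), sides = 2)
  ma[1L] <- a$p_exp[1L]
  ma[length(ma)] <- a$p_exp[length(ma)]
  first_at <- function(th) {
    i <- which(ma >= th)
    if (length(i) == 0L) NA_real_ else a$f[min(i)]
  }
  f_lo <- first_at(lo_threshold)
  f_hi <- first_at(hi_threshold)
  if (!is.na(f_lo) && !is.na(f_hi)) f_hi <- max(f_hi, f_lo)
  list(f_lo = f_lo, f_hi = f_hi, open = is.na(f_lo) || is.na(f_hi))
}
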
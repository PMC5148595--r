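#' Clip a value into an interval
#'
#' The retract function maps z to a when z <= a, to b when z >= b, and leaves
#' it unchanged in between. It is what turns f + q into a probability: the
#' empirical choice frequency satisfies p = Ret[0,1](f + q), which is also why
#' q cannot be recovered from frequencies of exactly 0 or 1.
#'
#' @param z numeric vector.
#' @param a,b interval endpoints, a <= b.
#' @return z clipped into [a, b].
#' @examples
#' retract(c(-0.3, 0.4, 1.2), 0, 1)   # 0, 0.4, 1
#' @export
retract <- function(z, a = 0, b = 1) {
  if (!is.numeric(a) || !is.numeric(b) || a > b) {
    stop("invalid interval: need a <= b", call. = FALSE)
  }
  pmin(pmax(z, a), b)
}

# utility factor f(L1) of each record's task (beta = 0 form)
task_utility <- function(records, y = 50) {
  y * records$p / (y * records$p + records$x)
}

#' Assign utility factors to bins
#'
#' Bins are half-open intervals [k w, (k+1) w) of width w, labeled by their
#' lower edge ("rounded to the lowest w"); f = 1 goes to a closed top bin
#' labeled 1. f is rounded to 12 decimals first so that values lying at an
#' exact bin edge up to floating-point dust land in the intended bin.
#'
#' @param f numeric vector of utility factors in [0, 1].
#' @param bin_width bin width in (0, 1), default 0.01.
#' @return Numeric vector of bin lower edges.
#' @export
utility_bin <- function(f, bin_width = 0.01) {
  if (bin_width <= 0 || bin_width >= 1) stop("'bin_width' must be in (0, 1)", call. = FALSE)
  # round the ratio before flooring so exact edges (e.g. f = 0.10 stored as
  # 0.0999...9) land in their own bin; closed top bin keeps f = 1 at label 1
  k <- floor(round(f / bin_width, 6))
  pmin(round(k * bin_width, 12), 1)
}

#' Aggregate repeated decision tasks
#'
#' Pools choice records into aggregates of repeated realizations of "the same"
#' decision task and computes the empirical choice frequency of the risky
#' option per aggregate. Three notions of sameness are supported:
#' \describe{
#'   \item{\code{"utility"}}{same utility-factor bin (width \code{bin_width});
#'     the representative f of the aggregate is the bin lower edge. This is
#'     the headline aggregation.}
#'   \item{\code{"pair"}}{identical (p, x) values; f is the task's exact
#'     utility factor.}
#'   \item{\code{"neighborhood"}}{same p and sure amounts within
#'     \code{tol_x} CHF (tasks sorted by x and chained greedily); f is the
#'     mean utility factor of the members. Provided for completeness.}
#' }
#' Attraction factors q = p_exp - f are attached wherever the empirical
#' frequency is strictly between 0 and 1; aggregates at exactly 0 or 1 are
#' censored (q set to NA) because the clipping in p = Ret[0,1](f + q) makes
#' q unrecoverable there.
#'
#' @param records validated choice records.
#' @param by aggregation rule: "utility", "pair" or "neighborhood".
#' @param bin_width utility-bin width (rule "utility").
#' @param group pool across everything (\code{"none"}), per subject
#'   (\code{"subject"}) or per gender (\code{"gender"}).
#' @param tol_x sure-amount tolerance in CHF (rule "neighborhood").
#' @param y top prize (default 50).
#' @return A data.frame of class \code{qdt_aggregate} with columns
#'   \code{group} (when grouping), \code{key}, \code{f}, \code{N}, \code{N1},
#'   \code{p_exp}, \code{q}, \code{censored}.
#' @export
qdt_aggregate <- function(records, by = c("utility", "pair", "neighborhood"),
                          bin_width = 0.01,
                          group = c("none", "subject", "gender"),
                          tol_x = 3, y = 50) {
  by <- match.arg(by)
  group <- match.arg(group)
  records <- validate_choices(records, y = y, warn_off_grid = FALSE)
  f_task <- task_utility(records, y)
  if (by == "utility") {
    f_rep <- utility_bin(f_task, bin_width)
    key <- format(f_rep, nsmall = 2)
  } else if (by == "pair") {
    f_rep <- f_task
    key <- paste(records$p, records$x, sep = "|")
  } else {
    key <- neighborhood_key(records, tol_x)
    f_rep <- stats::ave(f_task, key, FUN = mean)
  }
  grp <- switch(group,
                none = rep("all", nrow(records)),
                subject = as.character(records$subject),
                gender = records$gender)
  split_key <- paste(grp, key, sep = "\r")
  idx <- split(seq_len(nrow(records)), split_key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(group = grp[i[1L]], key = key[i[1L]], f = f_rep[i[1L]],
               N = length(i), N1 = sum(records$choice[i]),
               stringsAsFactors = FALSE)
  }))
  out$p_exp <- out$N1 / out$N
  out$censored <- out$p_exp == 0 | out$p_exp == 1
  out$q <- ifelse(out$censored, NA_real_, out$p_exp - out$f)
  out <- out[order(out$group, out$f), ]
  rownames(out) <- NULL
  if (group == "none") out$group <- NULL
  class(out) <- c("qdt_aggregate", "data.frame")
  attr(out, "by") <- by
  attr(out, "bin_width") <- bin_width
  out
}

# same-p tasks whose x values chain within tol_x are pooled
neighborhood_key <- function(records, tol_x) {
  key <- character(nrow(records))
  for (pv in unique(records$p)) {
    sel <- which(records$p == pv)
    xs <- sort(unique(records$x[sel]))
    cluster <- cumsum(c(1, diff(xs) > tol_x))
    lab <- paste(pv, cluster[match(records$x[sel], xs)], sep = "~")
    key[sel] <- lab
  }
  key
}

#' @export
print.qdt_aggregate <- function(x, ...) {
  cat(sprintf("%d aggregates (by %s), %d censored, %d records\n",
              nrow(x), attr(x, "by"), sum(x$censored), sum(x$N)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, "more rows )\n")
  invisible(x)
}

#' Attach attraction factors to precomputed aggregates
#'
#' Recomputes q = p_exp - f for aggregates with 0 < p_exp < 1 and marks the
#' rest as censored. Useful when aggregates were assembled or edited outside
#' \code{\link{qdt_aggregate}}.
#'
#' @param aggregates data frame with columns \code{f}, \code{N}, \code{N1}.
#' @return The data frame with \code{p_exp}, \code{q} and \code{censored}
#'   columns (re)filled.
#' @export
attach_attraction <- function(aggregates) {
  stopifnot(all(c("f", "N", "N1") %in% names(aggregates)),
            all(aggregates$N1 >= 0), all(aggregates$N1 <= aggregates$N))
  aggregates$p_exp <- aggregates$N1 / aggregates$N
  aggregates$censored <- aggregates$p_exp == 0 | aggregates$p_exp == 1
  aggregates$q <- ifelse(aggregates$censored, NA_real_,
                         aggregates$p_exp - aggregates$f)
  aggregates
}
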
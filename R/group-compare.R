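#' Per-group attraction-factor samples
#'
#' For each level of the grouping variable, pools that group's records,
#' aggregates them by utility bin and returns the uncensored q values. With
#' \code{grouping = "subject"} this gives each individual's own q sample
#' (each subject binned and censored on their own).
#'
#' @param records validated choice records.
#' @param grouping \code{"gender"} or \code{"subject"}.
#' @param bin_width utility-bin width.
#' @param y top prize.
#' @return Named list of numeric vectors; groups with no uncensored bins are
#'   dropped with a warning.
#' @export
q_samples <- function(records, grouping = c("gender", "subject"),
                      bin_width = 0.01, y = 50) {
  grouping <- match.arg(grouping)
  agg <- qdt_aggregate(records, by = "utility", bin_width = bin_width,
                       group = grouping, y = y)
  out <- lapply(split(agg, agg$group), function(a) a$q[!a$censored])
  empty <- vapply(out, length, 1L) == 0L
  if (any(empty)) {
    warning("group(s) with no uncensored bins excluded: ",
            paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS test: the statistic is the supremum of the gap
#' between the two empirical CDFs; p-values are asymptotic (Kolmogorov
#' distribution) by default, matching the conventional tooling, with an
#' exact small-sample mode available.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param exact use the exact small-sample distribution instead of the
#'   asymptotic one.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
ks_two_samples <- function(a, b, exact = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: both samples need size >= 2", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' All-pairs subject KS comparison, split by pairing type
#'
#' Computes a KS p-value for every pair of subjects on their individual
#' q samples and splits the pairs into within-group-A, within-group-B and
#' cross-group reports. Each report carries the p-values, the fraction below
#' a threshold and a histogram over 0.05-wide p-value intervals. No
#' multiple-testing correction is applied.
#'
#' @param records validated choice records.
#' @param group_of optional named character vector mapping subject id to
#'   group label; defaults to each subject's gender from the records.
#' @param threshold p-value threshold for the "clearly distinguishable"
#'   fraction (default 0.05).
#' @param bin_width utility-bin width for the individual q samples.
#' @param y top prize.
#' @return Named list of three \code{pairing_report} objects
#'   (\code{within_A}, \code{within_B}, \code{cross}); A and B are the group
#'   labels in sort order.
#' @export
pairwise_subject_ks <- function(records, group_of = NULL, threshold = 0.05,
                                bin_width = 0.01, y = 50) {
  records <- validate_choices(records, y = y, warn_off_grid = FALSE)
  qs <- q_samples(records, "subject", bin_width = bin_width, y = y)
  qs <- qs[vapply(qs, length, 1L) >= 2L]
  subj <- names(qs)
  if (is.null(group_of)) {
    group_of <- tapply(records$gender, as.character(records$subject),
                       function(g) g[1L])
  }
  grp <- group_of[subj]
  labels <- sort(unique(unname(grp)))
  if (length(labels) != 2L) stop("need exactly two group labels", call. = FALSE)
  if (any(table(grp) < 2L)) stop("need >= 2 subjects per group", call. = FALSE)
  pairs <- utils::combn(seq_along(subj), 2L)
  pv <- apply(pairs, 2L, function(ij) {
    ks_two_samples(qs[[ij[1L]]], qs[[ij[2L]]])$p_value
  })
  type <- apply(pairs, 2L, function(ij) {
    g <- sort(grp[ij])
    if (g[1L] == g[2L]) paste0("within_", g[1L]) else "cross"
  })
  mk <- function(sel, lab) pairing_report(pv[sel], lab, threshold)
  out <- list(
    within_A = mk(type == paste0("within_", labels[1L]),
                  paste0(labels[1L], "-", labels[1L])),
    within_B = mk(type == paste0("within_", labels[2L]),
                  paste0(labels[2L], "-", labels[2L])),
    cross = mk(type == "cross", paste0(labels[1L], "-", labels[2L]))
  )
  attr(out, "labels") <- labels
  out
}

pairing_report <- function(p_values, type, threshold = 0.05) {
  structure(list(
    type = type,
    p_values = p_values,
    n_pairs = length(p_values),
    threshold = threshold,
    frac_below = mean(p_values < threshold),
    histogram = table(cut(p_values, breaks = seq(0, 1, by = 0.05),
                          include.lowest = TRUE))
  ), class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("%s pairs: %d KS tests, %.1f%% of p-values below %g\n",
              x$type, x$n_pairs, 100 * x$frac_below, x$threshold))
  invisible(x)
}

#' Compare the three p-value distributions
#'
#' KS tests between the lists of pairwise p-values themselves: within-A vs
#' cross, within-A vs within-B, and within-B vs cross. A small p-value for
#' "within-A vs within-B" means the two groups differ in how internally
#' heterogeneous they are.
#'
#' @param reports result of \code{\link{pairwise_subject_ks}}.
#' @return Named numeric vector of three KS p-values
#'   (\code{within_A_vs_cross}, \code{within_A_vs_within_B},
#'   \code{within_B_vs_cross}).
#' @export
compare_pvalue_distributions <- function(reports) {
  stopifnot(all(c("within_A", "within_B", "cross") %in% names(reports)))
  pv <- lapply(reports, `[[`, "p_values")
  if (any(vapply(pv, length, 1L) < 2L)) {
    stop("insufficient data: every report needs >= 2 p-values", call. = FALSE)
  }
  c(within_A_vs_cross = ks_two_samples(pv$within_A, pv$cross)$p_value,
    within_A_vs_within_B = ks_two_samples(pv$within_A, pv$within_B)$p_value,
    within_B_vs_cross = ks_two_samples(pv$within_B, pv$cross)$p_value)
}
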
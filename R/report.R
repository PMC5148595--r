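#' Run the full quarter-law analysis pipeline
#'
#' Executes the whole analysis on a choice-record table: design descriptives,
#' utility-bin aggregation with censoring (the p-vs-f table used for
#' plotting), quarter-law fits for the requested schemes and groups, the
#' attraction factor at the f = 0.5 bin, and (optionally) the gender
#' comparison pipeline (group-level KS test, all-pairs subject KS reports and
#' the comparison of their p-value distributions). The run is deterministic
#' for fixed inputs; when \code{out_dir} is given, machine-readable outputs
#' (JSON summary, CSV aggregate table) are written there and every number in
#' the printed report also appears in them.
#'
#' @param input a choice-record data.frame or a path to a CSV readable by
#'   \code{\link{read_choices}}.
#' @param bin_width utility-bin width.
#' @param schemes quarter-law schemes to run.
#' @param groups group filters to run (\code{"all"}, \code{"F"}, \code{"M"}).
#' @param compare_genders run the KS comparison pipeline.
#' @param ks_threshold p-value threshold for the pairing reports.
#' @param out_dir optional output directory for JSON/CSV results.
#' @param y top prize.
#' @return Object of class \code{qdt_report} (a list).
#' @export
run_full_analysis <- function(input, bin_width = 0.01,
                              schemes = c("pooled", "per_subject"),
                              groups = c("all", "F", "M"),
                              compare_genders = TRUE, ks_threshold = 0.05,
                              out_dir = NULL, y = 50) {
  records <- if (is.character(input)) read_choices(input) else
    validate_choices(input, y = y, warn_off_grid = FALSE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  groups <- match.arg(groups, c("all", "F", "M"), several.ok = TRUE)

  design <- summarize_design(records, bin_width)
  aggregates <- qdt_aggregate(records, by = "utility", bin_width = bin_width, y = y)

  fits <- list()
  for (g in groups) {
    for (s in schemes) {
      key <- paste(g, s, sep = ".")
      fits[[key]] <- tryCatch(
        quarter_law(records, scheme = s,
                    gender = if (g == "all") NULL else g,
                    bin_width = bin_width, y = y),
        error = function(e) e)
    }
  }
  failed <- vapply(fits, inherits, TRUE, "error")

  at_half <- tryCatch(attraction_at_f(records, 0.50, bin_width, y),
                      error = function(e) e)

  comparison <- NULL
  if (compare_genders && length(unique(records$gender)) == 2L) {
    qs <- q_samples(records, "gender", bin_width, y)
    comparison <- list(
      gender_ks = ks_two_samples(qs$F, qs$M),
      pairings = tryCatch(
        pairwise_subject_ks(records, threshold = ks_threshold,
                            bin_width = bin_width, y = y),
        error = function(e) e)
    )
    if (!inherits(comparison$pairings, "error")) {
      comparison$pvalue_ks <- compare_pvalue_distributions(comparison$pairings)
    }
  }

  report <- structure(list(
    design = design, aggregates = aggregates, quarter_law = fits,
    insufficient = names(fits)[failed], attraction_at_half = at_half,
    comparison = comparison
  ), class = "qdt_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$aggregates),
                   file.path(out_dir, "aggregates.csv"), row.names = FALSE)
  ok <- !vapply(report$quarter_law, inherits, TRUE, "error")
  js <- list(
    design = report$design[c("n_records", "n_subjects", "frac_pairs_once",
                             "frac_pairs_twice", "frac_pairs_le3",
                             "max_pair_count", "max_bin_count",
                             "frac_bins_exactly3")],
    quarter_law = lapply(report$quarter_law[ok], function(f)
      f[c("mean_abs_q", "sd", "sem", "n_units", "deviation_sd",
          "deviation_sem", "scheme", "gender")]),
    insufficient = report$insufficient,
    attraction_at_half = if (inherits(report$attraction_at_half, "error"))
      NULL else report$attraction_at_half
  )
  if (!is.null(report$comparison)) {
    js$gender_ks <- report$comparison$gender_ks
    if (!inherits(report$comparison$pairings, "error")) {
      js$pairings <- lapply(report$comparison$pairings, function(r)
        r[c("type", "n_pairs", "frac_below")])
      js$pvalue_ks <- as.list(report$comparison$pvalue_ks)
    }
  }
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.qdt_report <- function(x, ...) {
  print(x$design)
  cat("\n")
  for (nm in names(x$quarter_law)) {
    f <- x$quarter_law[[nm]]
    if (inherits(f, "error")) {
      cat(sprintf("Quarter-law fit %s: unavailable (%s)\n", nm,
                  conditionMessage(f)))
    } else {
      print(f)
    }
  }
  if (!inherits(x$attraction_at_half, "error")) {
    cat(sprintf("\nAttraction factor at f = 0.50: q_bar = %.2f (N = %d tasks)\n",
                x$attraction_at_half$q_bar, x$attraction_at_half$N))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("\nGender KS test on q samples: D = %.3f, p = %.3g\n",
                x$comparison$gender_ks$statistic, x$comparison$gender_ks$p_value))
    if (!inherits(x$comparison$pairings, "error")) {
      for (r in x$comparison$pairings) print(r)
    }
  }
  invisible(x)
}
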
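#' Read a choice-record table
#'
#' Reads a CSV of one-row-per-decision choice records with columns
#' \code{subject} (integer identifier), \code{gender} (\code{"F"}/\code{"M"}),
#' \code{p} (win probability of the risky option, decimal fraction),
#' \code{x} (sure amount, CHF) and \code{choice} (0 = certain option taken,
#' 1 = risky option taken). Columns are matched by name in any order; if the
#' file uses different header strings, supply \code{col_map} to translate
#' them.
#'
#' @param path path to a CSV file (or a connection).
#' @param col_map optional named character vector mapping canonical names to
#'   the file's header names, e.g.
#'   \code{c(subject = "id", gender = "sex", p = "prob", x = "sure", choice = "decision")}.
#' @return A validated \code{data.frame} with the five canonical columns,
#'   rows in file order.
#' @export
read_choices <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: no data rows", call. = FALSE)
  canonical <- c("subject", "gender", "p", "x", "choice")
  if (!is.null(col_map)) {
    if (is.null(names(col_map)) || !all(names(col_map) %in% canonical)) {
      stop("'col_map' must be named by canonical column names", call. = FALSE)
    }
    for (nm in names(col_map)) {
      idx <- match(col_map[[nm]], names(df))
      if (is.na(idx)) {
        stop(sprintf("column '%s' (mapped to '%s') not found in file",
                     col_map[[nm]], nm), call. = FALSE)
      }
      names(df)[idx] <- nm
    }
  }
  missing <- setdiff(canonical, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_choices(df[canonical])
}

#' Validate a choice-record data frame
#'
#' Enforces the record invariants: binary choice, p in (0, 1], x in [0, y).
#' Values of p or x off the nominal experimental grid (p on a 0.05 grid in
#' [0.05, 0.90], integer x in [0, 49]) raise a warning, not an error, since
#' they are still well-defined tasks.
#'
#' @param records data frame with columns subject, gender, p, x, choice.
#' @param y top prize used for the x-range check (default 50).
#' @param warn_off_grid warn when p or x lie off the nominal design grid.
#' @return The records, with numeric columns coerced.
#' @export
validate_choices <- function(records, y = 50, warn_off_grid = TRUE) {
  canonical <- c("subject", "gender", "p", "x", "choice")
  missing <- setdiff(canonical, names(records))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[canonical]
  for (col in c("p", "x", "choice")) {
    v <- records[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop(sprintf("unparsable or missing '%s' at row(s) %s", col,
                   paste(utils::head(which(is.na(v)), 5L), collapse = ", ")),
           call. = FALSE)
    }
    records[[col]] <- v
  }
  bad <- which(!records$choice %in% c(0, 1))
  if (length(bad)) {
    stop("non-binary 'choice' at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(records$gender %in% c("F", "M")))
  if (length(bad)) {
    stop("'gender' outside {F, M} at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(records$p <= 0 | records$p > 1)
  if (length(bad)) {
    stop("'p' outside (0, 1] at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(records$x < 0 | records$x >= y)
  if (length(bad)) {
    stop(sprintf("'x' outside [0, %g) at row(s) %s", y,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (warn_off_grid) {
    off_p <- abs(records$p * 20 - round(records$p * 20)) > 1e-9 |
      records$p > 0.9 + 1e-9
    off_x <- abs(records$x - round(records$x)) > 1e-9 | records$x > 49
    if (any(off_p)) warning(sum(off_p), " record(s) with p off the nominal 0.05 grid")
    if (any(off_x)) warning(sum(off_x), " record(s) with x off the nominal 0..49 grid")
  }
  records$subject <- as.integer(records$subject)
  records$choice <- as.integer(records$choice)
  records
}

#' Write a choice-record table
#'
#' Writes the canonical CSV dialect: comma separator, header row
#' \code{subject,gender,p,x,choice}, p as decimal fraction, x in CHF.
#' \code{read_choices(write_choices(r, f))} reproduces \code{r}.
#'
#' @param records validated choice records (see \code{\link{validate_choices}}).
#' @param path output path or connection.
#' @return \code{path}, invisibly.
#' @export
write_choices <- function(records, path) {
  records <- validate_choices(records, warn_off_grid = FALSE)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics of an experimental design
#'
#' Counts how often each exact (p, x) task and each utility-factor bin occurs
#' in a choice-record table, and summarizes the multiplicity distribution:
#' the fractions of (p, x) pairs offered exactly once, exactly twice and at
#' most three times, the largest pair and bin counts, and the fraction of
#' f-bins offered exactly three times. Sparse designs (many singleton pairs)
#' are what motivates aggregating by utility-factor bin instead of by exact
#' task.
#'
#' @param records validated choice records.
#' @param bin_width utility-factor bin width (default 0.01).
#' @return Object of class \code{design_summary}: a list with counts and
#'   fractions (fractions kept at full precision; the print method shows
#'   percentages to one decimal).
#' @export
summarize_design <- function(records, bin_width = 0.01) {
  records <- validate_choices(records, warn_off_grid = FALSE)
  if (nrow(records) == 0L) stop("empty dataset", call. = FALSE)
  pair_key <- paste(records$p, records$x, sep = "|")
  pair_counts <- table(pair_key)
  f <- task_utility(records)
  bin <- utility_bin(f, bin_width)
  bin_counts <- table(format(bin, nsmall = 2))
  structure(list(
    n_records = nrow(records),
    n_subjects = length(unique(records$subject)),
    pair_counts = c(pair_counts),
    bin_counts = c(bin_counts),
    frac_pairs_once = mean(pair_counts == 1L),
    frac_pairs_twice = mean(pair_counts == 2L),
    frac_pairs_le3 = mean(pair_counts <= 3L),
    max_pair_count = max(pair_counts),
    max_bin_count = max(bin_counts),
    frac_bins_exactly3 = mean(bin_counts == 3L)
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  pct <- function(z) sprintf("%.1f%%", 100 * z)
  cat("Design summary:", x$n_records, "records,", x$n_subjects, "subjects\n")
  cat("  (p, x) pairs:", length(x$pair_counts),
      sprintf("(offered once %s, twice %s, <=3 times %s, max count %d)\n",
              pct(x$frac_pairs_once), pct(x$frac_pairs_twice),
              pct(x$frac_pairs_le3), x$max_pair_count))
  cat("  f-bins:", length(x$bin_counts),
      sprintf("(exactly 3 times %s, max count %d)\n",
              pct(x$frac_bins_exactly3), x$max_bin_count))
  invisible(x)
}
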
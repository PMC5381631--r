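#' Write an acceleration summary to delimited text
#'
#' Emits the one-row layout of published cohort-acceleration tables: one
#' column per adjacent-cohort pair (headed by the recent cohort's label),
#' then `Mean`, `SE` and `Ratio mean:SE`. Missing pairs are written as
#' blank cells.
#'
#' @param summary an `accel_summary` from [summarize_ratios()].
#' @param path output path; `.tsv`/`.txt` selects tab separation.
#' @param digits decimal places (default 2, the conventional reporting
#'   precision for these ratios).
#' @param label optional row label written in a leading `dataset` column.
#' @export
write_summary <- function(summary, path, digits = 2, label = NULL) {
  stopifnot(inherits(summary, "accel_summary"))
  vals <- c(round(summary$ratios, digits),
            round(c(summary$mean, summary$se, summary$z), digits))
  nm <- c(names(summary$ratios), "Mean", "SE", "Ratio mean:SE")
  df <- as.data.frame(as.list(vals), check.names = FALSE)
  names(df) <- nm
  if (!is.null(label)) df <- cbind(dataset = label, df)
  write_delim_auto(df, path)
  invisible(path)
}

#' Read back a written acceleration summary
#'
#' @param path path written by [write_summary()].
#' @return an `accel_summary` recomputed from the stored ratios; the stored
#'   `Mean`/`SE`/`Ratio mean:SE` columns are attached as attribute
#'   `stored_stats` for comparison.
#' @export
read_summary <- function(path) {
  df <- read_delim_auto(path)
  if ("dataset" %in% names(df)) df <- df[setdiff(names(df), "dataset")]
  stat_cols <- c("Mean", "SE", "Ratio mean:SE")
  if (!all(stat_cols %in% names(df)))
    stop("not a summary file: Mean/SE/Ratio mean:SE columns missing")
  ratio_cols <- setdiff(names(df), stat_cols)
  r <- as.numeric(df[1, ratio_cols])
  names(r) <- ratio_cols
  out <- summarize_ratios(r)
  attr(out, "stored_stats") <- as.numeric(df[1, stat_cols])
  out
}
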
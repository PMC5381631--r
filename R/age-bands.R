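#' Five-year age bands
#'
#' Constructs the age-band table used throughout the package. Bands are
#' 5-year intervals `[lower, lower + 4]` in whole years; the last band may be
#' open-ended (e.g. 85+). Each band carries a representative age used
#' whenever the band must be placed on a (log) age axis: the midpoint
#' `lower + 2.5` for closed bands, and by the same convention `lower + 2.5`
#' for an open terminal band (87.5 for 85+), which keeps the log-age spacing
#' of the design points even.
#'
#' @param lower integer vector of band lower bounds (multiples of 5, >= 0),
#'   strictly increasing.
#' @param open_last logical; if `TRUE` the last band is open-ended
#'   (upper bound unbounded), otherwise all bands are closed 5-year bands.
#' @return a `data.frame` with columns `lower`, `upper` (`NA` for an open
#'   band), `label` (e.g. `"25-29"`, `"85+"`) and `rep_age`.
#' @examples
#' age_bands(seq(25, 85, 5), open_last = TRUE)
#' @export
age_bands <- function(lower, open_last = TRUE) {
  lower <- as.integer(lower)
  if (length(lower) == 0L) stop("no age bands given")
  if (any(lower < 0L) || any(lower %% 5L != 0L))
    stop("band lower bounds must be non-negative multiples of 5")
  if (is.unsorted(lower, strictly = TRUE))
    stop("band lower bounds must be strictly increasing")
  upper <- lower + 4L
  if (open_last) upper[length(upper)] <- NA_integer_
  label <- ifelse(is.na(upper), paste0(lower, "+"),
                  paste0(lower, "-", upper))
  data.frame(lower = lower, upper = upper, label = label,
             rep_age = lower + 2.5, stringsAsFactors = FALSE)
}

#' Parse age-band labels
#'
#' Accepts the label dialects found in registry tables: `"25-29"` with a
#' hyphen or en-dash, `"85+"`, and `"85 and over"` (also `"85 & over"`,
#' `"85 plus"`). Output labels are normalised to the hyphen/plus forms.
#'
#' @param labels character vector of band labels, in table order.
#' @return an age-band `data.frame` as produced by [age_bands()].
#' @examples
#' parse_age_bands(c("25-29", "30–34", "85 and over"))
#' @export
parse_age_bands <- function(labels) {
  labels <- trimws(as.character(labels))
  lower <- integer(length(labels))
  upper <- integer(length(labels))
  for (i in seq_along(labels)) {
    lab <- gsub("–|—", "-", labels[i])  # en/em dash -> hyphen
    if (grepl("^[0-9]+\\s*(\\+|plus|and over|& over)$", lab, ignore.case = TRUE)) {
      lower[i] <- as.integer(sub("^([0-9]+).*$", "\\1", lab))
      upper[i] <- NA_integer_
    } else if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", lab)) {
      parts <- as.integer(strsplit(lab, "\\s*-\\s*")[[1]])
      lower[i] <- parts[1]
      upper[i] <- parts[2]
    } else {
      stop(sprintf("unparseable age-band label '%s' (position %d)",
                   labels[i], i))
    }
  }
  validate_bands(lower, upper, labels)
}

# shared invariant checks for a parsed band set
validate_bands <- function(lower, upper, labels) {
  closed <- !is.na(upper)
  bad <- closed & (upper - lower != 4L)
  if (any(bad))
    stop(sprintf("age band '%s' is not a 5-year band", labels[which(bad)[1]]))
  if (any(is.na(upper) & seq_along(upper) != length(upper)))
    stop("an open-ended band is only allowed in terminal position")
  if (is.unsorted(lower, strictly = TRUE))
    stop("age bands must be non-overlapping and sorted ascending")
  age_bands(lower, open_last = anyNA(upper))
}

# band row lookup by lower bound; used internally
band_index <- function(bands, lower) {
  i <- match(lower, bands$lower)
  if (anyNA(i)) stop(sprintf("no band with lower bound %s",
                             paste(lower[is.na(i)], collapse = ", ")))
  i
}
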
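# Filename convention, filesystem-backed catalog and completeness reports.
# Every produced artifact is named {VARIABLE}_{LEVEL}_{YYYYMMDD}[_{TAG}].{ext}
# so a plain directory is queryable by variable, level, date and (for
# sub-daily thermal products) overpass tag.

.name_re <- paste0(
  "^([A-Z][A-Z0-9]*)_",                  # variable code
  "(LOCAL|COUNTRY|CONTINENTAL)_",        # level
  "([0-9]{8})",                          # date
  "(?:_([A-Z]+-[A-Z]+))?",               # optional overpass tag
  "\\.([A-Za-z0-9]+)$")                  # extension

#' Encode a catalog filename
#'
#' @param variable Variable code (upper-case letters/digits).
#' @param level Level code.
#' @param date A `Date`.
#' @param overpass Optional overpass tag, e.g. `"TERRA-DAY"`.
#' @param ext File extension (default `"tif"`).
#' @return Canonical filename string.
#' @examples
#' encode_name("LST", "LOCAL", as.Date("2020-01-12"), "TERRA-DAY")
#' @export
encode_name <- function(variable, level, date, overpass = NULL,
                        ext = "tif") {
  if (!grepl("^[A-Z][A-Z0-9]*$", variable))
    stop("variable code must be upper-case letters/digits", call. = FALSE)
  if (!(level %in% c("LOCAL", "COUNTRY", "CONTINENTAL")))
    stop("unknown level code", call. = FALSE)
  if (is.na(as.Date(date))) stop("invalid date", call. = FALSE)
  tag <- if (is.null(overpass) || is.na(overpass) || overpass == "") ""
         else paste0("_", toupper(overpass))
  sprintf("%s_%s_%s%s.%s", variable, level, format(as.Date(date), "%Y%m%d"),
          tag, ext)
}

#' Parse a catalog filename
#'
#' Inverse of [encode_name()]; `parse_name(encode_name(...))` recovers the
#' fields. Malformed names raise an error pointing at the first offending
#' position.
#'
#' @param filename A basename following the convention.
#' @return List with `variable`, `level`, `date`, `overpass` (`NULL` if
#'   absent) and `ext`.
#' @export
parse_name <- function(filename) {
  m <- regmatches(filename, regexec(.name_re, filename))[[1]]
  if (!length(m)) {
    parts <- strsplit(filename, "_")[[1]]
    pos <- 1L
    if (!grepl("^[A-Z][A-Z0-9]*$", parts[1])) pos <- 1L
    else if (length(parts) < 3L ||
             !(parts[2] %in% c("LOCAL", "COUNTRY", "CONTINENTAL")))
      pos <- nchar(parts[1]) + 2L
    else pos <- nchar(parts[1]) + nchar(parts[2]) + 3L
    stop(sprintf("malformed catalog name '%s' (near position %d)",
                 filename, pos), call. = FALSE)
  }
  date <- as.Date(m[4], "%Y%m%d")
  if (is.na(date))
    stop(sprintf("malformed catalog name '%s': invalid date '%s'",
                 filename, m[4]), call. = FALSE)
  list(variable = m[2], level = m[3], date = date,
       overpass = if (nzchar(m[5])) m[5] else NULL, ext = m[6])
}

#' Query a filesystem catalog
#'
#' Scans a directory for convention-named files and returns the entries
#' matching every provided filter, sorted by date (then variable, then
#' overpass); the result does not depend on filesystem listing order.
#' Unparseable filenames are skipped with a warning.
#'
#' @param root Catalog directory.
#' @param variable,level,overpass Optional exact-match filters.
#' @param from,to Optional inclusive date range.
#' @return Data frame with `path`, `variable`, `level`, `date`, `overpass`.
#' @export
query_catalog <- function(root, variable = NULL, level = NULL,
                          from = NULL, to = NULL, overpass = NULL) {
  if (!dir.exists(root)) stop("catalog root does not exist", call. = FALSE)
  files <- sort(list.files(root))
  rows <- list(); skipped <- character()
  for (f in files) {
    meta <- tryCatch(parse_name(f), error = function(e) NULL)
    if (is.null(meta)) { skipped <- c(skipped, f); next }
    if (meta$ext == "prj") next  # CRS sidecar, not a catalog entry
    rows[[length(rows) + 1L]] <- data.frame(
      path = file.path(root, f), variable = meta$variable,
      level = meta$level, date = meta$date,
      overpass = if (is.null(meta$overpass)) NA_character_
                 else meta$overpass,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("skipped %d unparseable file(s): %s", length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), variable = character(),
               level = character(), date = as.Date(character()),
               overpass = character(), stringsAsFactors = FALSE)
  if (!is.null(variable)) out <- out[out$variable == variable, ]
  if (!is.null(level)) out <- out[out$level == level, ]
  if (!is.null(overpass)) out <- out[!is.na(out$overpass) &
                                       out$overpass == overpass, ]
  if (!is.null(from)) out <- out[out$date >= as.Date(from), ]
  if (!is.null(to)) out <- out[out$date <= as.Date(to), ]
  out <- out[order(out$date, out$variable, out$overpass,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected product timeline for a cadence
#'
#' Daily products expect every day; 8-day composites start at day-of-year
#' 1, 9, ..., 361 of each year (46 windows in a year); 16-day products at
#' day 1, 17, ..., 353 (23 per year); static products expect a single
#' undated entry.
#'
#' @param cadence One of `"daily"`, `"8-day"`, `"16-day"`, `"static"`.
#' @param from,to Inclusive period.
#' @return Vector of expected `Date`s.
#' @export
expected_dates <- function(cadence = c("daily", "8-day", "16-day", "static"),
                           from, to) {
  cadence <- match.arg(cadence)
  from <- as.Date(from); to <- as.Date(to)
  if (cadence == "daily") return(seq(from, to, by = "day"))
  if (cadence == "static") return(from)
  step <- if (cadence == "8-day") 8L else 16L
  out <- as.Date(character())
  for (yr in seq(as.integer(format(from, "%Y")),
                 as.integer(format(to, "%Y")))) {
    jan1 <- as.Date(sprintf("%d-01-01", yr))
    dec31 <- as.Date(sprintf("%d-12-31", yr))
    starts <- seq(jan1, dec31, by = step)
    out <- c(out, starts)
  }
  out[out >= from & out <= to]
}

#' Catalog completeness report
#'
#' Matches the expected timeline of a product (from its cadence) against
#' the catalog entries actually present, listing missing dates.
#'
#' @param root Catalog directory.
#' @param variable,level Product identity.
#' @param cadence Product cadence, see [expected_dates()].
#' @param from,to Reporting period.
#' @param overpass Optional overpass filter.
#' @return List with `table` (data frame `date`, `present`), `n_expected`,
#'   `n_present`, `missing` (Dates).
#' @export
completeness_report <- function(root, variable, level, cadence, from, to,
                                overpass = NULL) {
  expect <- expected_dates(cadence, from, to)
  entries <- query_catalog(root, variable = variable, level = level,
                           from = from, to = to, overpass = overpass)
  present <- expect %in% entries$date
  list(table = data.frame(date = expect, present = present),
       n_expected = length(expect), n_present = sum(present),
       missing = expect[!present])
}
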
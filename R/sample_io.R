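#' isogeoloc: stable-isotope forensic geolocation
#'
#' Closed-population geographic assignment from stable hydrogen and oxygen
#' isotope ratios (\eqn{\delta^2}H, \eqn{\delta^{18}}O, per mil vs VSMOW)
#' measured in human hair and toenails.  The package covers the full desk
#' analysis: per-sample delta tables, a packaged drinking-water reference,
#' synthetic cohort simulation from published per-site summary statistics,
#' the tissue--water OLS regression battery, group-comparison statistics,
#' Gini-impurity CART classification, and holdout evaluation.
#'
#' @keywords internal
"_PACKAGE"

# canonical column layout of a sample table; empty cell = missing
SAMPLE_COLUMNS <- c("sample_id", "individual_id", "site", "location",
                    "tissue", "d2H", "d18O", "d2H_sd", "d18O_sd")

TISSUES <- c("hair", "toenail")

# sanity window for delta values, per mil vs VSMOW
DELTA_WINDOW <- c(-200, 50)

#' Convert isotope ratios to delta notation
#'
#' The delta value is the relative difference between the isotope ratio of a
#' sample and that of an international standard,
#' \deqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000,}
#' reported in per mil (permil).  The conventional definition is the bare
#' relative difference; the x1000 per-mil scaling is applied here because
#' every reported tissue and water value is in permil.
#'
#' @param sample_ratio Heavy/light isotope ratio of the sample (e.g.
#'   \eqn{^2}H/\eqn{^1}H).  Must be positive.
#' @param standard_ratio Same ratio for the standard (VSMOW).  Must be
#'   positive.
#' @return Delta value in permil.  Vectorized over both arguments.
#' @examples
#' delta_from_ratios(1.1, 1)    # 100 permil
#' delta_from_ratios(0.995, 1)  # -5 permil
#' @export
delta_from_ratios <- function(sample_ratio, standard_ratio) {
  if (any(!is.finite(sample_ratio)) || any(!is.finite(standard_ratio)) ||
      any(sample_ratio <= 0) || any(standard_ratio <= 0)) {
    stop("isotope ratios must be positive and finite", call. = FALSE)
  }
  (sample_ratio / standard_ratio - 1) * 1000
}

#' Construct a validated sample table
#'
#' A sample table is a `data.frame` (class `"sample_table"`) with one row per
#' tissue measurement: sample and individual identifiers, a site label from a
#' declared closed set, a location name that keys into the water reference
#' table, the tissue (`"hair"` or `"toenail"`), delta values in permil vs
#' VSMOW, and optional replicate standard deviations.  Missing delta values
#' are `NA` (never a sentinel number); at least one of `d2H`/`d18O` must be
#' present in every row.
#'
#' @param df Data frame with columns
#'   `sample_id, individual_id, site, location, tissue, d2H, d18O, d2H_sd,
#'   d18O_sd` (the last two optional).
#' @param sites Ordered character vector of allowed site labels.  The order
#'   is meaningful: it is the tie-break order used downstream.
#' @param delta_window Numeric length-2 sanity window (permil); delta values
#'   outside it are load errors.
#' @param provenance Optional character note recorded as an attribute
#'   (source path or generator seed).
#' @return The validated table, classed `"sample_table"`.
#' @export
sample_table <- function(df, sites = c("1", "2", "3", "4"),
                         delta_window = DELTA_WINDOW, provenance = NULL) {
  stopifnot(is.data.frame(df))
  for (col in c("d2H_sd", "d18O_sd")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[SAMPLE_COLUMNS]
  for (col in c("sample_id", "individual_id", "site", "location", "tissue")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("d2H", "d18O", "d2H_sd", "d18O_sd")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  rownames(df) <- NULL
  problems <- validate_sample_rows(df, sites, delta_window)
  if (length(problems) > 0) {
    stop("invalid sample table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(df, class = c("sample_table", "data.frame"),
            sites = sites, provenance = provenance)
}

# per-row invariant checks; returns character vector of problems with row ids
validate_sample_rows <- function(df, sites, delta_window) {
  problems <- character()
  n <- nrow(df)
  if (n == 0) return(problems)
  bad <- which(!df$tissue %in% TISSUES)
  for (i in bad) problems <- c(problems,
    sprintf("row %d: unknown tissue '%s'", i, df$tissue[i]))
  bad <- which(!df$site %in% sites)
  for (i in bad) problems <- c(problems,
    sprintf("row %d: site '%s' not in declared set {%s}", i, df$site[i],
            paste(sites, collapse = ",")))
  bad <- which(is.na(df$d2H) & is.na(df$d18O))
  for (i in bad) problems <- c(problems,
    sprintf("row %d: both d2H and d18O missing", i))
  for (col in c("d2H", "d18O")) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < delta_window[1] | v > delta_window[2]))
    for (i in bad) problems <- c(problems,
      sprintf("row %d: %s = %.1f outside sanity window [%g, %g]",
              i, col, v[i], delta_window[1], delta_window[2]))
  }
  key <- paste(df$sample_id, df$tissue, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) problems <- c(problems,
    sprintf("row %d: duplicate (sample_id, tissue) = (%s, %s)",
            i, df$sample_id[i], df$tissue[i]))
  problems
}

#' Declared site order of a sample table
#' @param table A `sample_table`.
#' @return Character vector of site labels in tie-break order.
#' @export
site_levels <- function(table) {
  s <- attr(table, "sites")
  if (is.null(s)) sort(unique(table$site)) else s
}

#' Read a sample table from CSV
#'
#' Parses the canonical sample CSV layout
#' (`sample_id,individual_id,site,location,tissue,d2H,d18O,d2H_sd,d18O_sd`).
#' Empty numeric cells become explicit missing values.  Unicode minus signs
#' (U+2212), as commonly produced by typesetting, are normalized to ASCII
#' hyphens before numeric parsing.  Rows violating the table invariants are
#' reported with their row numbers.
#'
#' @inheritParams sample_table
#' @param path CSV file path.
#' @return A validated [sample_table].
#' @export
load_samples <- function(path, sites = c("1", "2", "3", "4"),
                         delta_window = DELTA_WINDOW) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(setdiff(SAMPLE_COLUMNS, c("d2H_sd", "d18O_sd")),
                          names(raw))
  if (length(missing_cols) > 0) {
    stop("CSV lacks required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("d2H", "d18O", "d2H_sd", "d18O_sd")) {
    if (is.null(raw[[col]])) { raw[[col]] <- NA_real_; next }
    raw[[col]] <- parse_delta(raw[[col]])
  }
  sample_table(raw, sites = sites, delta_window = delta_window,
               provenance = paste0("file:", path))
}

# numeric parser tolerant of unicode minus and surrounding whitespace
parse_delta <- function(x) {
  x <- gsub("−", "-", trimws(x))
  x[x == ""] <- NA
  suppressWarnings(out <- as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("unparseable numeric value(s) at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a sample table to CSV
#'
#' Emits the canonical column layout with ASCII hyphens and empty cells for
#' missing values, so that `load_samples(write_samples(t))` reproduces `t`
#' field for field (row order preserved).
#'
#' @param table A [sample_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  out <- as.data.frame(table)
  for (col in c("d2H", "d18O", "d2H_sd", "d18O_sd")) {
    # %.17g guarantees bit-exact double round-trip through text
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged drinking-water reference table
#'
#' Location-level drinking-water delta values for the four Canadian study
#' sites (Metro Vancouver municipalities, Simcoe County / Muskoka area
#' communities, Iqaluit, and the Annapolis Valley towns), with source
#' descriptions and a provenance flag: measured tap water (`tap`), surface
#' water of the supplying body (`surface`), or modeled annual precipitation
#' from the Online Isotope Precipitation Calculator (`OIPC`).
#'
#' @param path Optional path to an alternative water CSV with columns
#'   `location,site,source_description,d2H,d18O,provenance`.
#' @return Data frame with those six columns, one row per location.
#' @export
water_references <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "water_table3.csv", package = "isogeoloc",
                        mustWork = TRUE)
  }
  refs <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("location", "site", "source_description", "d2H", "d18O", "provenance")
  missing_cols <- setdiff(need, names(refs))
  if (length(missing_cols) > 0) {
    stop("water CSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  refs$d2H <- parse_delta(refs$d2H)
  refs$d18O <- parse_delta(refs$d18O)
  if (anyDuplicated(refs$location)) {
    stop("duplicate locations in water reference table", call. = FALSE)
  }
  refs[need]
}

#' Annotate samples with their location's water values
#'
#' Left-joins a water reference table onto a sample table by `location`,
#' adding `<prefix>_d2H`, `<prefix>_d18O` and `<prefix>_provenance` columns.
#' Isotope fields of the samples are never altered and the row count is
#' unchanged.
#'
#' @param table A [sample_table].
#' @param refs Water reference data frame, as from [water_references()].
#' @param prefix Column prefix for the joined values (default `"water"`).
#' @param unmatched `"error"` (default) to fail listing unresolvable
#'   locations, or `"na"` to annotate them with missing water values (used
#'   for partial reference tables such as the OIPC subset).
#' @return The annotated table (still a `sample_table`).
#' @export
attach_water <- function(table, refs, prefix = "water",
                         unmatched = c("error", "na")) {
  stopifnot(inherits(table, "sample_table"))
  unmatched <- match.arg(unmatched)
  idx <- match(table$location, refs$location)
  if (unmatched == "error" && anyNA(idx) && nrow(table) > 0) {
    missing_loc <- sort(unique(table$location[is.na(idx)]))
    stop("locations not in water reference table: ",
         paste(missing_loc, collapse = ", "), call. = FALSE)
  }
  out <- table
  out[[paste0(prefix, "_d2H")]] <- refs$d2H[idx]
  out[[paste0(prefix, "_d18O")]] <- refs$d18O[idx]
  out[[paste0(prefix, "_provenance")]] <- refs$provenance[idx]
  attributes(out)$sites <- attr(table, "sites")
  class(out) <- class(table)
  out
}
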
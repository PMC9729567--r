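#' Simple ordinary-least-squares fit
#'
#' Closed-form simple linear regression of `y` on `x` via the normal
#' equations.  Pairs with a missing member are dropped first (pairwise
#' deletion, so each regression keeps its own realized n).  The slope
#' p-value is the two-sided t-test with n - 2 degrees of freedom;
#' `r_squared = 1 - SS_res / SS_tot` (defined as 0 when `y` is constant).
#'
#' @param x,y Numeric vectors of equal length, in permil.
#' @param x_label,y_label Variable descriptors carried into the fit.
#' @param excluded_sites Site labels excluded upstream (bookkeeping only).
#' @return A `regression_fit` list: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `x_label`, `y_label`, `excluded_sites`.  `p_value` is
#'   `NA` when n < 3 or when the fit is exact with zero slope.
#' @export
fit_ols <- function(x, y, x_label = "x", y_label = "y",
                    excluded_sites = character()) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate predictor: zero variance in x", call. = FALSE)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  ss_tot <- sum((y - ybar)^2)
  ss_res <- sum((y - (intercept + slope * x))^2)
  r_squared <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  # guard tiny negative values from floating point
  r_squared <- min(max(r_squared, 0), 1)
  p_value <- NA_real_
  if (n >= 3) {
    if (ss_res <= 0) {
      p_value <- if (slope == 0) NA_real_ else 0
    } else {
      se <- sqrt(ss_res / (n - 2) / sxx)
      p_value <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
    }
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared,
                 p_value = p_value, n = n, x_label = x_label,
                 y_label = y_label,
                 excluded_sites = as.character(excluded_sites)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  excl <- if (length(x$excluded_sites) > 0)
    paste0(" [excl. sites ", paste(x$excluded_sites, collapse = ","), "]") else ""
  cat(sprintf("%s = %.2f x %s %+0.2f, R^2 = %.2f, p = %s, n = %d%s\n",
              x$y_label, x$slope, x$x_label, x$intercept, x$r_squared,
              format.pval(x$p_value, digits = 2), x$n, excl))
  invisible(x)
}

# parse "hair:d2H" / "water:d18O" style variable selectors
parse_selector <- function(sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 ||
      !parts[1] %in% c("hair", "toenail", "water", "oipc") ||
      !parts[2] %in% c("d2H", "d18O")) {
    stop("bad variable selector '", sel,
         "' (want e.g. \"hair:d2H\", \"water:d18O\")", call. = FALSE)
  }
  list(domain = parts[1], isotope = parts[2], label = sel)
}

#' Regress one variable pair from a sample table
#'
#' Builds (x, y) pairs according to two variable selectors of the form
#' `"<domain>:<isotope>"` with domain one of `hair`, `toenail`, `water`,
#' `oipc`:
#' * tissue vs same tissue: the two isotopes of each sample;
#' * tissue vs other tissue: samples matched on `individual_id`;
#' * tissue vs `water`/`oipc`: each sample paired with its location's
#'   annotated water value (requires [attach_water()] with the matching
#'   prefix) -- an ecological regressor, constant within a location, one
#'   pair per sample.
#'
#' Samples from `excluded_sites` are dropped before pairing; missing
#' members are dropped pairwise.
#'
#' @param table A [sample_table], water-annotated where needed.
#' @param x_var,y_var Selector strings, e.g. `"water:d2H"`, `"hair:d2H"`.
#' @param excluded_sites Character site labels to exclude.
#' @return A `regression_fit` (see [fit_ols()]).
#' @export
regress_pair <- function(table, x_var, y_var, excluded_sites = character()) {
  stopifnot(inherits(table, "sample_table"))
  xs <- parse_selector(x_var); ys <- parse_selector(y_var)
  if (ys$domain %in% c("water", "oipc")) {
    stop("the response must be a tissue variable", call. = FALSE)
  }
  if (all(site_levels(table) %in% excluded_sites)) {
    stop("all sites excluded", call. = FALSE)
  }
  tab <- table[!table$site %in% excluded_sites, , drop = FALSE]
  yrows <- tab[tab$tissue == ys$domain, , drop = FALSE]
  if (xs$domain %in% c("water", "oipc")) {
    col <- paste0(xs$domain, "_", xs$isotope)
    if (is.null(yrows[[col]])) {
      stop("table lacks column '", col, "'; run attach_water() first",
           call. = FALSE)
    }
    x <- yrows[[col]]; y <- yrows[[ys$isotope]]
  } else if (xs$domain == ys$domain) {
    x <- yrows[[xs$isotope]]; y <- yrows[[ys$isotope]]
  } else {
    xrows <- tab[tab$tissue == xs$domain, , drop = FALSE]
    ids <- intersect(xrows$individual_id, yrows$individual_id)
    x <- xrows[[xs$isotope]][match(ids, xrows$individual_id)]
    y <- yrows[[ys$isotope]][match(ids, yrows$individual_id)]
  }
  if (sum(!is.na(x) & !is.na(y)) < 3) {
    stop("fewer than 3 usable pairs for ", ys$label, " ~ ", xs$label,
         call. = FALSE)
  }
  fit_ols(x, y, x_label = xs$label, y_label = ys$label,
          excluded_sites = excluded_sites)
}

#' Global Meteoric Water Line constants
#'
#' The empirical worldwide precipitation relation
#' \eqn{\delta^2H = 8 \cdot \delta^{18}O + 10}, used as an overlay /
#' comparison line for tissue data.
#'
#' @return List with `slope` (8) and `intercept` (10).
#' @export
gmwl <- function() list(slope = 8, intercept = 10)

# the 20-slot layout of the published regression battery
battery_slots <- function() {
  slot <- function(eq, x, y, excl = character())
    list(eq = eq, x = x, y = y, excluded_sites = excl)
  c(
    list(slot(1, "hair:d18O", "hair:d2H"),
         slot(2, "toenail:d18O", "toenail:d2H"),
         slot(3, "water:d2H", "hair:d2H"),
         slot(4, "water:d2H", "toenail:d2H"),
         slot(5, "water:d18O", "hair:d18O"),
         slot(6, "water:d18O", "toenail:d18O"),
         slot(7, "oipc:d2H", "hair:d2H"),
         slot(8, "oipc:d2H", "toenail:d2H"),
         slot(9, "oipc:d18O", "hair:d18O"),
         slot(10, "oipc:d18O", "toenail:d18O"),
         slot(11, "water:d2H", "hair:d2H", "3"),
         slot(12, "water:d2H", "toenail:d2H", "3"),
         slot(13, "water:d18O", "hair:d18O", "3"),
         slot(14, "water:d18O", "toenail:d18O", "3"),
         slot(15, "oipc:d2H", "hair:d2H", "3"),
         slot(16, "oipc:d2H", "toenail:d2H", "3"),
         slot(17, "oipc:d18O", "hair:d18O", "3"),
         slot(18, "oipc:d18O", "toenail:d18O", "3"),
         slot(19, "toenail:d2H", "hair:d2H"),
         slot(20, "toenail:d18O", "hair:d18O"))
  )
}

#' Run the full 20-equation regression battery
#'
#' Reproduces the published regression layout: tissue delta-2H vs delta-18O
#' (slots 1-2), tissue vs drinking water (3-6), tissue vs OIPC
#' precipitation (7-10), the water and OIPC sets with the Iqaluit site
#' (Site 3) excluded (11-18), and paired hair-vs-toenail fits (19-20).
#' Slot failures (insufficient pairs, degenerate predictor) are reported
#' per slot, never as a batch abort.
#'
#' @param table A [sample_table] containing hair and/or toenail rows.
#' @param water_refs Water reference table (default packaged fixture).
#' @param oipc_refs Reference table of OIPC precipitation values; defaults
#'   to the OIPC-provenance subset of `water_refs` (the only published
#'   per-location OIPC values).  Locations absent from it are annotated
#'   missing and drop out of the OIPC slots pairwise.
#' @return List of 20 elements named `eq1` ... `eq20`; each is either a
#'   `regression_fit` or a list with class `"regression_failure"` carrying
#'   the slot label and error `message`.
#' @export
regression_battery <- function(table, water_refs = water_references(),
                               oipc_refs = NULL) {
  stopifnot(inherits(table, "sample_table"))
  if (length(unique(table$site)) < 2) {
    warning("insufficient site spread: battery fit on fewer than 2 sites")
  }
  if (is.null(oipc_refs)) {
    oipc_refs <- water_refs[water_refs$provenance == "OIPC", , drop = FALSE]
  }
  tab <- attach_water(table, water_refs, prefix = "water", unmatched = "error")
  tab <- attach_water(tab, oipc_refs, prefix = "oipc", unmatched = "na")
  out <- lapply(battery_slots(), function(s) {
    tryCatch(
      regress_pair(tab, s$x, s$y, excluded_sites = s$excluded_sites),
      error = function(e) {
        structure(list(eq = s$eq, x_label = s$x, y_label = s$y,
                       excluded_sites = s$excluded_sites,
                       message = conditionMessage(e)),
                  class = "regression_failure")
      })
  })
  names(out) <- paste0("eq", vapply(battery_slots(), `[[`, 0, "eq"))
  out
}
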
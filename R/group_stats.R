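# complete bivariate cases of one tissue
complete_tissue <- function(table, tissue) {
  rows <- table[table$tissue == tissue & !is.na(table$d2H) &
                  !is.na(table$d18O), , drop = FALSE]
  rows
}

#' Shapiro-Wilk normality gate
#'
#' Decides between parametric and rank-based downstream tests.  A constant
#' series is reported as `"non_normal"` with `p = NA` (a point mass is not
#' Gaussian; `shapiro.test` itself refuses it), which routes degenerate
#' data to the rank test rather than erroring.
#'
#' @param values Numeric vector, 3 <= n <= 5000 after NA removal.
#' @param alpha Significance level of the gate (default 0.05).
#' @return List: `verdict` (`"normal"` / `"non_normal"`), `p_value`,
#'   `statistic` (W), `n`, `alpha`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("normality gate needs 3 <= n <= 5000, got ", n, call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(list(verdict = "non_normal", p_value = NA_real_,
                statistic = NA_real_, n = n, alpha = alpha))
  }
  sw <- stats::shapiro.test(values)
  list(verdict = if (sw$p.value < alpha) "non_normal" else "normal",
       p_value = unname(sw$p.value), statistic = unname(sw$statistic),
       n = n, alpha = alpha)
}

#' One-way MANOVA of delta values across sites
#'
#' Tests whether mean (delta-2H, delta-18O) vectors differ across sites for
#' one tissue, on complete bivariate cases.  Reports the Pillai trace with
#' its approximate F as the multivariate gate, plus the per-response
#' univariate F tests with degrees of freedom (k-1, n-k) -- the form in
#' which such results are conventionally quoted.
#'
#' @param table A [sample_table].
#' @param tissue `"hair"` or `"toenail"`.
#' @return List with `n`, `n_sites`, `multivariate` (statistic_name
#'   "Pillai trace", statistic, approx F, df1, df2, p_value) and
#'   `univariate`: a data.frame with one row per response (`response`,
#'   `statistic_name` = "univariate F", `statistic`, `df1`, `df2`,
#'   `p_value`).
#' @export
manova_by_site <- function(table, tissue = c("hair", "toenail")) {
  tissue <- match.arg(tissue)
  rows <- complete_tissue(table, tissue)
  counts <- table(rows$site)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 sites with >= 2 complete (d2H, d18O) observations",
         call. = FALSE)
  }
  site <- factor(rows$site, levels = site_levels(table))
  site <- droplevels(site)
  Y <- cbind(d2H = rows$d2H, d18O = rows$d18O)
  fit <- tryCatch(stats::manova(Y ~ site),
                  error = function(e) stop("MANOVA failed: ",
                                           conditionMessage(e), call. = FALSE))
  sm <- tryCatch(summary(fit, test = "Pillai"),
                 error = function(e) stop("singular within-group covariance",
                                          call. = FALSE))
  st <- sm$stats
  multivariate <- list(statistic_name = "Pillai trace",
                       statistic = unname(st[1, "Pillai"]),
                       approx_f = unname(st[1, "approx F"]),
                       df1 = unname(st[1, "num Df"]),
                       df2 = unname(st[1, "den Df"]),
                       p_value = unname(st[1, "Pr(>F)"]))
  av <- summary.aov(fit)
  uni <- do.call(rbind, lapply(seq_along(av), function(i) {
    a <- as.data.frame(av[[i]])
    data.frame(response = c("d2H", "d18O")[i],
               statistic_name = "univariate F",
               statistic = a[["F value"]][1],
               df1 = a[["Df"]][1], df2 = a[["Df"]][2],
               p_value = a[["Pr(>F)"]][1], stringsAsFactors = FALSE)
  }))
  rownames(uni) <- NULL
  list(tissue = tissue, n = nrow(rows), n_sites = length(counts),
       multivariate = multivariate, univariate = uni)
}

#' Tukey HSD post-hoc pairwise site comparisons
#'
#' All unordered site pairs with studentized-range adjusted p-values,
#' following a one-way ANOVA of `values` on `groups`.
#'
#' @param values Numeric vector.
#' @param groups Site labels, same length; every group needs >= 2 values.
#' @param site_order Optional ordered site labels (determines pair
#'   orientation: `mean_diff` is mean(site_b) - mean(site_a) with a before
#'   b in this order).
#' @return Data frame: `site_a`, `site_b`, `mean_diff`, `adjusted_p`.
#' @export
tukey_posthoc <- function(values, groups, site_order = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  if (is.null(site_order)) site_order <- sort(unique(groups))
  counts <- table(groups)
  if (length(counts) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("every group needs >= 2 observations; too small: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  g <- factor(groups, levels = site_order[site_order %in% groups])
  hsd <- stats::TukeyHSD(stats::aov(values ~ g))$g
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  out <- data.frame(
    # TukeyHSD labels rows "later-earlier"; reorder to a < b in site order
    site_a = vapply(pairs, `[`, "", 2),
    site_b = vapply(pairs, `[`, "", 1),
    mean_diff = hsd[, "diff"],
    adjusted_p = hsd[, "p adj"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Paired hair-vs-toenail comparison for one isotope
#'
#' Matches hair and toenail rows on `individual_id`, forms per-pair
#' differences (hair minus toenail), gates them through the Shapiro-Wilk
#' test, and applies the paired t-test if the differences look Gaussian,
#' otherwise the Wilcoxon signed-rank test (zero differences dropped,
#' average ranks for ties, exact null below 20 usable pairs, normal
#' approximation with continuity correction from 20 up).  If all
#' differences are zero the result is `mean_diff = 0` with `p = 1` (no
#' evidence of a shift; the signed-rank statistic is degenerate).
#'
#' @param table A [sample_table] containing both tissues.
#' @param isotope `"d2H"` or `"d18O"`.
#' @param alpha Gate significance level.
#' @return List of class `"paired_comparison"`: `isotope`, `n_pairs`,
#'   `mean_hair`, `mean_toenail`, `sd_hair`, `sd_toenail`, `mean_diff`,
#'   `sd_diff`, `test_used` (`"paired_t"` or `"wilcoxon"`), `p_value`,
#'   `normality` (the gate result).
#' @export
paired_compare <- function(table, isotope = c("d2H", "d18O"), alpha = 0.05) {
  isotope <- match.arg(isotope)
  stopifnot(inherits(table, "sample_table"))
  hair <- table[table$tissue == "hair" & !is.na(table[[isotope]]), ]
  toe <- table[table$tissue == "toenail" & !is.na(table[[isotope]]), ]
  ids <- intersect(hair$individual_id, toe$individual_id)
  if (length(ids) < 3) stop("fewer than 3 usable pairs", call. = FALSE)
  h <- hair[[isotope]][match(ids, hair$individual_id)]
  t_ <- toe[[isotope]][match(ids, toe$individual_id)]
  d <- h - t_
  # Shapiro-Wilk is defined for n <= 5000; gate a deterministic evenly
  # thinned subsample when there are more pairs than that
  gate_vals <- if (length(d) > 5000) {
    d[unique(round(seq(1, length(d), length.out = 5000)))]
  } else d
  gate <- normality_gate(gate_vals, alpha = alpha)
  if (all(d == 0)) {
    test_used <- "wilcoxon"; p_value <- 1
  } else if (gate$verdict == "normal") {
    test_used <- "paired_t"
    p_value <- stats::t.test(h, t_, paired = TRUE)$p.value
  } else {
    test_used <- "wilcoxon"
    nz <- d[d != 0]  # zero differences dropped
    exact <- length(nz) < 20
    p_value <- suppressWarnings(
      stats::wilcox.test(nz, exact = exact, correct = TRUE)$p.value)
  }
  structure(list(isotope = isotope, n_pairs = length(ids),
                 mean_hair = mean(h), mean_toenail = mean(t_),
                 sd_hair = stats::sd(h), sd_toenail = stats::sd(t_),
                 mean_diff = mean(h) - mean(t_), sd_diff = stats::sd(d),
                 test_used = test_used, p_value = p_value,
                 normality = gate),
            class = "paired_comparison")
}

#' Mahalanobis bivariate outlier screen
#'
#' Flags samples of one tissue whose complete (delta-2H, delta-18O) pair
#' lies far from the pooled bivariate cloud: center = mean vector,
#' scatter = sample covariance over complete cases, squared distances
#' compared to a chi-square(2) quantile (default 0.975).
#'
#' @param table A [sample_table].
#' @param tissue `"hair"` or `"toenail"`.
#' @param cutoff_quantile Chi-square quantile defining the cutoff on
#'   squared distance (default 0.975).
#' @return List of class `"outlier_report"`: `tissue`, `n`, `sample_ids`,
#'   `distance2` (named squared distances), `cutoff`, `cutoff_quantile`,
#'   `flagged` (sample ids with distance^2 > cutoff), `center`,
#'   `covariance`.
#' @export
mahalanobis_outliers <- function(table, tissue = c("hair", "toenail"),
                                 cutoff_quantile = 0.975) {
  tissue <- match.arg(tissue)
  rows <- complete_tissue(table, tissue)
  if (nrow(rows) < 5) {
    stop("need >= 5 complete bivariate observations", call. = FALSE)
  }
  X <- cbind(d2H = rows$d2H, d18O = rows$d18O)
  center <- colMeans(X)
  covmat <- stats::cov(X)
  if (!is.finite(determinant(covmat)$modulus) ||
      abs(det(covmat)) < 1e-12 * prod(diag(covmat) + 1e-300)) {
    stop("singular covariance", call. = FALSE)
  }
  d2 <- stats::mahalanobis(X, center, covmat)
  names(d2) <- rows$sample_id
  cutoff <- stats::qchisq(cutoff_quantile, df = 2)
  structure(list(tissue = tissue, n = nrow(rows),
                 sample_ids = rows$sample_id, distance2 = d2,
                 cutoff = cutoff, cutoff_quantile = cutoff_quantile,
                 flagged = rows$sample_id[d2 > cutoff],
                 center = center, covariance = covmat),
            class = "outlier_report")
}
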
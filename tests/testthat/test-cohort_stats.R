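spec <- default_cohort_spec()

test_that("normality gate behaves like a Shapiro-Wilk test at alpha", {
  withr::local_seed(11)
  verdicts <- replicate(100, normality_gate(rnorm(500))$verdict)
  expect_gte(mean(verdicts == "normal"), 0.9)   # type-I error ~ alpha
  verdicts_exp <- replicate(20, normality_gate(rexp(500))$verdict)
  expect_true(all(verdicts_exp == "non_normal"))  # power ~ 1 at this n
  # degenerate input: a point mass is routed to the rank test, documented
  expect_equal(normality_gate(rep(1, 10))$verdict, "non_normal")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("manova_by_site reports the expected dfs and matches an ANOVA oracle", {
  tab <- simulate_full_cohort(spec, seed = 3)
  res <- manova_by_site(tab, "hair")
  expect_equal(res$n, 81)  # one hair sample has missing d2H
  expect_equal(res$univariate$df1, c(3, 3))
  expect_equal(res$univariate$df2, c(77, 77))
  expect_equal(res$univariate$response, c("d2H", "d18O"))
  # univariate F equals explicit between/within sums of squares
  rows <- tab[tab$tissue == "hair" & !is.na(tab$d2H) & !is.na(tab$d18O), ]
  for (iso in c("d2H", "d18O")) {
    v <- rows[[iso]]; g <- rows$site
    grand <- mean(v); k <- length(unique(g)); n <- length(v)
    ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - grand)^2))
    ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
    f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
    expect_equal(res$univariate$statistic[res$univariate$response == iso],
                 f_oracle, tolerance = 1e-8)
  }
  expect_equal(res$multivariate$statistic_name, "Pillai trace")
  expect_lt(res$multivariate$p_value, 0.01)
})

test_that("manova F is near 1 under exchangeable site labels", {
  null_spec <- spec
  null_spec$params$mean <- ifelse(null_spec$params$isotope == "d2H", -80, 10)
  null_spec$params$sd <- 5
  null_spec$params$min <- NA_real_
  null_spec$params$max <- NA_real_
  null_spec$missingness <- null_spec$missingness[0, ]
  fs <- numeric(60)
  for (i in 1:60) {
    tab <- simulate_site_samples(null_spec, "hair", seed = 7000 + i)
    fs[i] <- manova_by_site(tab, "hair")$univariate$statistic[1]
  }
  expect_lt(abs(mean(fs) - 1), 4 * sd(fs) / sqrt(60))
})

test_that("manova rejects unusable inputs", {
  tab <- simulate_full_cohort(spec, seed = 3)
  one_site <- sample_table(as.data.frame(tab)[tab$site == "1", ],
                           sites = site_levels(tab))
  expect_error(manova_by_site(one_site, "hair"), ">= 2 sites")
})

test_that("tukey_posthoc enumerates ordered pairs and calibrates", {
  withr::local_seed(21)
  v <- rnorm(40); g <- rep(c("1", "2", "3", "4"), each = 10)
  out <- tukey_posthoc(v, g)
  expect_equal(nrow(out), 6)
  expect_true(all(out$site_a < out$site_b))
  # identical groups: adjusted p near 1
  same <- tukey_posthoc(rep(rnorm(10), 4), g)
  expect_true(all(same$adjusted_p > 0.9))
  expect_error(tukey_posthoc(c(1, 2, 3), c("a", "a", "b")), "too small")
  # the (1,4) pair has the largest standardized gap in the stated cohort:
  # it should carry the smallest adjusted p among Site-1 pairs most runs
  wins <- 0
  for (i in 1:50) {
    tab <- simulate_site_samples(spec, "hair", seed = 8000 + i)
    rows <- tab[!is.na(tab$d2H), ]
    tk <- tukey_posthoc(rows$d2H, rows$site, site_order = site_levels(tab))
    s1 <- tk[tk$site_a == "1", ]
    if (s1$site_b[which.min(s1$adjusted_p)] == "4") wins <- wins + 1
  }
  expect_gt(wins, 25)
})

test_that("paired_compare gates, tests and reports differences exactly", {
  tab <- simulate_paired_individuals(spec, 200, seed = 17)
  res <- paired_compare(tab, "d2H")
  hair <- tab[tab$tissue == "hair", ]; toe <- tab[tab$tissue == "toenail", ]
  expect_equal(res$n_pairs, 200)
  expect_equal(res$mean_diff, mean(hair$d2H) - mean(toe$d2H))
  expect_lt(res$p_value, 0.001)
  expect_true(res$test_used %in% c("paired_t", "wilcoxon"))
  # Gaussian differences normally route to the paired t-test
  expect_equal(res$test_used, if (res$normality$verdict == "normal")
    "paired_t" else "wilcoxon")
  # hair identical to toenail: zero difference, degenerate rank test
  df <- as.data.frame(tab)
  df$d2H[df$tissue == "hair"] <-
    df$d2H[df$tissue == "toenail"][match(df$individual_id[df$tissue == "hair"],
                                         df$individual_id[df$tissue == "toenail"])]
  same <- paired_compare(sample_table(df), "d2H")
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_compare(tiny_table(), "d2H"), "fewer than 3")
})

test_that("paired_compare type-I rate is near alpha under a zero offset", {
  null_spec <- spec
  null_spec$paired_offsets$mean_offset <- c(0, 0)
  rejections <- 0
  for (i in 1:100) {
    tab <- simulate_paired_individuals(null_spec, 30, seed = 9000 + i)
    if (paired_compare(tab, "d2H")$p_value < 0.05) rejections <- rejections + 1
  }
  # Binomial(100, 0.05): mean 5, sd 2.18; allow 4 sd
  expect_lte(rejections, 14)
})

test_that("mahalanobis screen matches a first-principles computation", {
  tab <- simulate_site_samples(spec, "hair", seed = 55)
  rep_ <- mahalanobis_outliers(tab, "hair")
  rows <- tab[tab$tissue == "hair" & !is.na(tab$d2H) & !is.na(tab$d18O), ]
  X <- cbind(rows$d2H, rows$d18O)
  mu <- colMeans(X); S_inv <- solve(cov(X))
  d2_oracle <- apply(X, 1, function(z) t(z - mu) %*% S_inv %*% (z - mu))
  expect_equal(unname(rep_$distance2), unname(d2_oracle), tolerance = 1e-10)
  expect_equal(rep_$cutoff, qchisq(0.975, df = 2))
  expect_true(all(rep_$distance2 >= 0))
  expect_identical(rep_$flagged,
                   rep_$sample_ids[rep_$distance2 > rep_$cutoff])
  expect_error(mahalanobis_outliers(tiny_table(), "hair"), ">= 5")
})

test_that("mahalanobis distances are affine invariant", {
  complete_spec <- spec
  complete_spec$missingness <- complete_spec$missingness[0, ]
  tab <- simulate_site_samples(complete_spec, "hair", seed = 56)
  base <- mahalanobis_outliers(tab, "hair")
  df <- as.data.frame(tab)
  hair <- df$tissue == "hair"
  # invertible affine map of the two coordinates
  A <- matrix(c(2, -1, 0.5, 3), 2)
  XY <- cbind(df$d2H[hair], df$d18O[hair]) %*% t(A)
  df$d2H[hair] <- XY[, 1] / 10      # rescale into the sanity window
  df$d18O[hair] <- XY[, 2] / 10
  trans <- mahalanobis_outliers(sample_table(df, delta_window = c(-1e6, 1e6)),
                                "hair")
  expect_equal(unname(trans$distance2), unname(base$distance2),
               tolerance = 1e-8)
})

test_that("removing a flagged outlier drops the manova df2 by one", {
  tab <- simulate_site_samples(spec, "hair", seed = 57)
  tab <- inject_outlier(tab, h2_analog())
  rep_ <- mahalanobis_outliers(tab, "hair")
  expect_true("H2x" %in% rep_$flagged)
  before <- manova_by_site(tab, "hair")$univariate$df2[1]
  kept <- sample_table(as.data.frame(tab)[!tab$sample_id %in% "H2x", ],
                       sites = site_levels(tab))
  after <- manova_by_site(kept, "hair")$univariate$df2[1]
  expect_equal(before - after, 1)
})
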
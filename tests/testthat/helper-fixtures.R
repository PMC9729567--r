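# small fixture builders and independent oracles shared across test files

# four-row well-formed table: two hair, two toenail, two paired individuals
tiny_table <- function() {
  sample_table(data.frame(
    sample_id = c("H1", "H2", "T1", "T2"),
    individual_id = c("A", "B", "A", "B"),
    site = c("1", "2", "1", "4"),
    location = c("Vancouver", "Orillia", "Vancouver", "Wolfville"),
    tissue = c("hair", "hair", "toenail", "toenail"),
    d2H = c(-82.5, -76.0, -96.0, -86.0),
    d18O = c(8.0, 10.4, 7.9, 10.8),
    d2H_sd = c(1.2, NA, 0.8, NA),
    d18O_sd = c(0.4, NA, NA, 0.9),
    stringsAsFactors = FALSE
  ))
}

# random valid sample table for property tests
random_table <- function(n, seed) {
  withr::local_seed(seed)
  sites <- c("1", "2", "3", "4")
  locs <- list(`1` = "Vancouver", `2` = "Orillia", `3` = "Iqaluit",
               `4` = "Wolfville")
  site <- sample(sites, n, replace = TRUE)
  d2H <- round(stats::runif(n, -150, 0), 13)
  d18O <- round(stats::runif(n, -20, 25), 13)
  # sprinkle missing values but never both in one row
  miss <- sample(c("none", "d2H", "d18O"), n, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  d2H[miss == "d2H"] <- NA
  d18O[miss == "d18O"] <- NA
  sample_table(data.frame(
    sample_id = paste0("S", seq_len(n)),
    individual_id = paste0("I", sample(ceiling(n / 2), n, replace = TRUE)),
    site = site,
    location = unlist(locs[site]),
    tissue = sample(c("hair", "toenail"), n, replace = TRUE),
    d2H = d2H, d18O = d18O,
    d2H_sd = NA_real_, d18O_sd = NA_real_,
    stringsAsFactors = FALSE
  ))
}

# independent brute-force split oracle: enumerates every feature and every
# midpoint threshold, computing impurities from first principles
oracle_best_split <- function(x, y) {
  y <- as.character(y)
  imp <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- as.numeric(table(lab)) / length(lab)
    1 - sum(p * p)
  }
  parent <- imp(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    for (i in seq_len(length(u) - 1)) {
      th <- (u[i] + u[i + 1]) / 2
      left <- x[, j] < th
      w <- (sum(left) * imp(y[left]) + sum(!left) * imp(y[!left])) / length(y)
      gain <- parent - w
      if (gain <= 0) next
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = colnames(x)[j], threshold = th, gain = gain)
      }
    }
  }
  best
}

# walk an isotope_tree collecting every node
collect_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node
    if (node$kind == "split") { walk(node$left); walk(node$right) }
  }
  walk(tree$root)
  out
}

# hand-built tree shaped like the published toenail model: root split on
# toenail d2H at -93 (left -> Site 1), right child split on toenail d18O at
# 9.6 (left -> Site 2, right -> Site 4)
toenail_reference_tree <- function() {
  leaf <- function(site, prop, frac) {
    list(kind = "leaf",
         class_proportions = stats::setNames(prop, c("1", "2", "3", "4")),
         sample_fraction = frac, n = round(frac * 32),
         predicted_site = site)
  }
  root <- list(kind = "split", split_feature = "toenail:d2H", threshold = -93,
               class_proportions = stats::setNames(c(.33, .28, .16, .23),
                                                   c("1", "2", "3", "4")),
               sample_fraction = 1, n = 32, predicted_site = "1", gain = 0.2,
               left = leaf("1", c(.9, .1, 0, 0), 0.33),
               right = list(kind = "split", split_feature = "toenail:d18O",
                            threshold = 9.6,
                            class_proportions = stats::setNames(
                              c(.05, .42, .21, .32), c("1", "2", "3", "4")),
                            sample_fraction = 0.67, n = 21,
                            predicted_site = "2", gain = 0.15,
                            left = leaf("2", c(0, .7, .3, 0), 0.4),
                            right = leaf("4", c(.1, 0, 0, .9), 0.27)))
  structure(list(root = root, classes = c("1", "2", "3", "4"),
                 features = c("toenail:d2H", "toenail:d18O"), n = 32,
                 config = tree_config()),
            class = "isotope_tree")
}
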
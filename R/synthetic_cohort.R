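# Per-site Gaussian parameters for the four-site Canadian cohort: mean, sd,
# min, max in permil vs VSMOW, n = samples collected per site and tissue.
# Site 1 = Metro Vancouver, 2 = Orillia area, 3 = Iqaluit, 4 = Wolfville area.
cohort_param_rows <- function() {
  rows <- rbind(
    # site tissue    isotope  mean    sd    n   min     max
    c("1", "hair",    "d2H",  -82.5, 8.25, 23, -92.7,  -58.3),
    c("2", "hair",    "d2H",  -76.2, 3.69, 25, -81.9,  -69.8),
    c("3", "hair",    "d2H",  -80.0, 2.45,  6, -83.8,  -77.0),
    c("4", "hair",    "d2H",  -72.5, 4.73, 28, -81.6,  -63.6),
    c("1", "hair",    "d18O",  8.03, 2.61, 23,   3.7,   11.1),
    c("2", "hair",    "d18O", 10.5,  2.11, 25,   5.8,   14.6),
    c("3", "hair",    "d18O", 10.8,  2.77,  6,   6.9,   14.1),
    c("4", "hair",    "d18O", 11.9,  3.63, 28,   7.2,   20.6),
    c("1", "toenail", "d2H",  -96.6, 6.94, 13, -108.0, -82.9),
    c("2", "toenail", "d2H",  -87.3, 3.13, 10, -92.1,  -82.8),
    c("3", "toenail", "d2H",  -88.5, 5.75,  6, -97.6,  -82.7),
    c("4", "toenail", "d2H",  -86.9, 4.8,  10, -92.4,  -79.7),
    c("1", "toenail", "d18O",  8.0,  2.28, 13,   4.3,   12.2),
    c("2", "toenail", "d18O",  7.8,  2.87, 10,   3.6,   12.9),
    c("3", "toenail", "d18O",  5.4,  2.85,  6,   2.3,    9.4),
    c("4", "toenail", "d18O", 10.9,  2.42, 10,   6.9,   16.5)
  )
  out <- data.frame(site = rows[, 1], tissue = rows[, 2], isotope = rows[, 3],
                    stringsAsFactors = FALSE)
  out$mean <- as.numeric(rows[, 4]); out$sd <- as.numeric(rows[, 5])
  out$n <- as.integer(rows[, 6])
  out$min <- as.numeric(rows[, 7]); out$max <- as.numeric(rows[, 8])
  out
}

#' Default cohort specification
#'
#' The stated world every downstream stage is tested against: four sites,
#' per-site/per-tissue Gaussian delta distributions with the published
#' means, standard deviations and sample counts (hair n = 23/25/6/28,
#' toenail n = 13/10/6/10), paired hair-minus-toenail offsets of
#' 13.0 +/- 8.4 permil for delta-2H and 1.5 +/- 4.6 permil for delta-18O,
#' one missing-delta-2H hair sample in Site 2 (so measurable hair delta-2H
#' n = 81), and zero within-tissue correlation between the two isotopes by
#' default.
#'
#' @param correlation Within-tissue correlation between d2H and d18O draws,
#'   in `[-1, 1]`.  Default 0 (the published per-site correlations are
#'   unknown and the tissue-level coupling is weak).
#' @param clamp If `TRUE`, draws are clamped to the published per-site
#'   min/max.  Off by default (clamping distorts means/sds).
#' @return A list of class `"cohort_spec"` with elements `sites`, `params`
#'   (per site/tissue/isotope Gaussian rows), `paired_offsets`,
#'   `correlation`, `clamp`, `missingness` and `outliers`.
#' @export
default_cohort_spec <- function(correlation = 0, clamp = FALSE) {
  stopifnot(correlation >= -1, correlation <= 1)
  spec <- list(
    sites = c("1", "2", "3", "4"),
    params = cohort_param_rows(),
    paired_offsets = data.frame(
      isotope = c("d2H", "d18O"),
      mean_offset = c(13.0, 1.5),
      sd_offset = c(8.4, 4.6),
      stringsAsFactors = FALSE
    ),
    correlation = correlation,
    clamp = clamp,
    # H52 analog: one Site-2 hair sample whose d2H could not be measured
    missingness = data.frame(site = "2", tissue = "hair", isotope = "d2H",
                             count = 1L, stringsAsFactors = FALSE),
    outliers = list()
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  p <- spec$params
  stopifnot(all(p$sd >= 0), all(p$n >= 0),
            all(is.na(p$min) | is.na(p$max) | (p$min <= p$mean & p$mean <= p$max)),
            all(spec$paired_offsets$sd_offset >= 0),
            spec$correlation >= -1, spec$correlation <= 1)
  invisible(spec)
}

# look up one (site, tissue, isotope) Gaussian parameter row
site_params <- function(spec, site, tissue, isotope) {
  p <- spec$params
  row <- p[p$site == site & p$tissue == tissue & p$isotope == isotope, ]
  if (nrow(row) != 1) {
    stop(sprintf("no parameters for (site %s, %s, %s)", site, tissue, isotope),
         call. = FALSE)
  }
  row
}

# deterministic location assignment: cycle over the site's reference
# locations in water-table order (the true sample->location mapping within
# each site is unpublished)
assign_locations <- function(site, k, refs) {
  locs <- refs$location[refs$site == site]
  if (length(locs) == 0) stop("no reference locations for site ", site)
  locs[((seq_len(k) - 1) %% length(locs)) + 1]
}

# draw k bivariate-normal (d2H, d18O) pairs for one site/tissue
draw_site_pairs <- function(spec, site, tissue, k) {
  ph <- site_params(spec, site, tissue, "d2H")
  po <- site_params(spec, site, tissue, "d18O")
  z1 <- stats::rnorm(k)
  z2 <- stats::rnorm(k)
  r <- spec$correlation
  d2H <- ph$mean + ph$sd * z1
  d18O <- po$mean + po$sd * (r * z1 + sqrt(1 - r^2) * z2)
  if (isTRUE(spec$clamp)) {
    d2H <- pmin(pmax(d2H, ph$min), ph$max)
    d18O <- pmin(pmax(d18O, po$min), po$max)
  }
  data.frame(d2H = d2H, d18O = d18O)
}

#' Simulate a single-tissue cohort
#'
#' Draws, for each site, `n` independent samples per isotope from the
#' spec's Gaussian parameters (optionally correlated within tissue,
#' optionally clamped to the published min/max), applies the spec's
#' missingness injections, and assigns locations round-robin over each
#' site's water-reference locations.  Deterministic given `seed`.
#'
#' @param spec A `cohort_spec`, e.g. [default_cohort_spec()].
#' @param tissue `"hair"` or `"toenail"`.
#' @param seed Integer seed; all randomness flows from it.
#' @param refs Water reference table used only for location assignment.
#' @param id_prefix Prefix for sample ids (default `"H"` for hair, `"T"`
#'   for toenail).
#' @return A [sample_table]; provenance records the seed.
#' @export
simulate_site_samples <- function(spec, tissue = c("hair", "toenail"), seed,
                                  refs = water_references(),
                                  id_prefix = NULL) {
  tissue <- match.arg(tissue)
  validate_cohort_spec(spec)
  if (is.null(id_prefix)) id_prefix <- if (tissue == "hair") "H" else "T"
  withr::local_seed(as.integer(seed))
  per_site <- lapply(spec$sites, function(s) {
    k <- site_params(spec, s, tissue, "d2H")$n
    if (k == 0) return(NULL)
    vals <- draw_site_pairs(spec, s, tissue, k)
    data.frame(site = s, location = assign_locations(s, k, refs), vals,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per_site)
  if (is.null(df) || nrow(df) == 0) {
    df <- data.frame(sample_id = character(), individual_id = character(),
                     site = character(), location = character(),
                     tissue = character(), d2H = numeric(), d18O = numeric(),
                     d2H_sd = numeric(), d18O_sd = numeric())
    return(sample_table(df, sites = spec$sites,
                        provenance = paste0("simulated:seed=", seed)))
  }
  df$sample_id <- paste0(id_prefix, seq_len(nrow(df)))
  df$individual_id <- paste0("I", id_prefix, seq_len(nrow(df)))
  df$tissue <- tissue
  df$d2H_sd <- NA_real_
  df$d18O_sd <- NA_real_
  m <- spec$missingness
  if (!is.null(m) && nrow(m) > 0) {
    for (i in seq_len(nrow(m))) {
      if (m$tissue[i] != tissue) next
      rows <- which(df$site == m$site[i])
      hit <- utils::head(rows, m$count[i])
      df[[m$isotope[i]]][hit] <- NA_real_
    }
  }
  sample_table(df[SAMPLE_COLUMNS], sites = spec$sites,
               provenance = paste0("simulated:seed=", seed))
}

#' Simulate paired hair/toenail individuals
#'
#' Each individual contributes two rows sharing an `individual_id`: a
#' toenail measurement drawn from the site's toenail parameters, and a hair
#' measurement constructed as toenail value plus a Gaussian offset with the
#' spec's paired-offset parameters (hair minus toenail: 13.0 +/- 8.4 permil
#' for delta-2H, 1.5 +/- 4.6 permil for delta-18O).  Deriving hair from
#' toenail makes the paired-offset statistics exact by construction.
#' Individuals are allocated to sites round-robin with weights proportional
#' to the toenail site counts.
#'
#' @inheritParams simulate_site_samples
#' @param n_pairs Number of individuals (>= 0).
#' @return A [sample_table] with `2 * n_pairs` rows.
#' @export
simulate_paired_individuals <- function(spec, n_pairs, seed,
                                        refs = water_references()) {
  validate_cohort_spec(spec)
  stopifnot(n_pairs >= 0)
  empty <- data.frame(sample_id = character(), individual_id = character(),
                      site = character(), location = character(),
                      tissue = character(), d2H = numeric(), d18O = numeric(),
                      d2H_sd = numeric(), d18O_sd = numeric())
  if (n_pairs == 0) {
    return(sample_table(empty, sites = spec$sites,
                        provenance = paste0("simulated-paired:seed=", seed)))
  }
  withr::local_seed(as.integer(seed))
  # site allocation proportional to toenail counts, deterministic
  tn <- spec$params[spec$params$tissue == "toenail" &
                      spec$params$isotope == "d2H", ]
  weights <- tn$n[match(spec$sites, tn$site)]
  if (all(weights == 0)) weights <- rep(1, length(spec$sites))
  alloc <- rep(spec$sites, times = round_allocation(weights, n_pairs))
  off <- spec$paired_offsets
  off_h <- off[off$isotope == "d2H", ]
  off_o <- off[off$isotope == "d18O", ]
  rows <- lapply(spec$sites, function(s) {
    k <- sum(alloc == s)
    if (k == 0) return(NULL)
    toe <- draw_site_pairs(spec, s, "toenail", k)
    hair <- data.frame(
      d2H = toe$d2H + stats::rnorm(k, off_h$mean_offset, off_h$sd_offset),
      d18O = toe$d18O + stats::rnorm(k, off_o$mean_offset, off_o$sd_offset)
    )
    list(site = s, toe = toe, hair = hair,
         location = assign_locations(s, k, refs))
  })
  rows <- Filter(Negate(is.null), rows)
  pieces <- list()
  counter <- 0L
  for (blk in rows) {
    k <- nrow(blk$toe)
    ids <- paste0("P", counter + seq_len(k))
    counter <- counter + k
    pieces[[length(pieces) + 1]] <- data.frame(
      sample_id = c(paste0(ids, "h"), paste0(ids, "t")),
      individual_id = c(ids, ids),
      site = blk$site, location = c(blk$location, blk$location),
      tissue = rep(c("hair", "toenail"), each = k),
      d2H = c(blk$hair$d2H, blk$toe$d2H),
      d18O = c(blk$hair$d18O, blk$toe$d18O),
      d2H_sd = NA_real_, d18O_sd = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, pieces)
  df <- df[order(df$individual_id, df$tissue), ]
  sample_table(df, sites = spec$sites,
               provenance = paste0("simulated-paired:seed=", seed))
}

# integer allocation of n among weights, largest-remainder, deterministic
round_allocation <- function(weights, n) {
  share <- weights / sum(weights) * n
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate the full two-tissue cohort
#'
#' Composite cohort with the published marginal structure: `n_pairs`
#' individuals contribute both tissues (allocated to sites in proportion to
#' the toenail counts), and tissue-only blocks top the per-site totals up
#' to the spec's hair and toenail counts (defaults: 82 hair, 39 toenail, 35
#' paired).  Hair values of paired individuals are toenail + offset, as in
#' [simulate_paired_individuals()]; tissue-only samples are drawn from the
#' site marginals.  Missingness injections are applied to tissue-only
#' samples (the published missing-delta-2H hair sample belonged to an
#' individual who gave no toenail).
#'
#' @inheritParams simulate_site_samples
#' @param n_pairs Number of two-tissue individuals (default 35).
#' @return A [sample_table].
#' @export
simulate_full_cohort <- function(spec, seed, n_pairs = 35,
                                 refs = water_references()) {
  validate_cohort_spec(spec)
  withr::local_seed(as.integer(seed))
  hair_n <- vapply(spec$sites, function(s) site_params(spec, s, "hair", "d2H")$n, 0L)
  toe_n <- vapply(spec$sites, function(s) site_params(spec, s, "toenail", "d2H")$n, 0L)
  pairs_n <- pmin(round_allocation(toe_n, n_pairs), hair_n, toe_n)
  off <- spec$paired_offsets
  off_h <- off[off$isotope == "d2H", ]; off_o <- off[off$isotope == "d18O", ]
  pieces <- list()
  pair_counter <- 0L; hair_counter <- 0L; toe_counter <- 0L
  for (i in seq_along(spec$sites)) {
    s <- spec$sites[i]
    kp <- pairs_n[i]; kh <- hair_n[i] - kp; kt <- toe_n[i] - kp
    locs <- assign_locations(s, kp + kh + kt, refs)
    if (kp > 0) {
      toe <- draw_site_pairs(spec, s, "toenail", kp)
      hair <- data.frame(
        d2H = toe$d2H + stats::rnorm(kp, off_h$mean_offset, off_h$sd_offset),
        d18O = toe$d18O + stats::rnorm(kp, off_o$mean_offset, off_o$sd_offset))
      ids <- paste0("P", pair_counter + seq_len(kp)); pair_counter <- pair_counter + kp
      pieces[[length(pieces) + 1]] <- data.frame(
        sample_id = c(paste0(ids, "h"), paste0(ids, "t")),
        individual_id = c(ids, ids), site = s,
        location = rep(locs[seq_len(kp)], 2),
        tissue = rep(c("hair", "toenail"), each = kp),
        d2H = c(hair$d2H, toe$d2H), d18O = c(hair$d18O, toe$d18O),
        d2H_sd = NA_real_, d18O_sd = NA_real_, stringsAsFactors = FALSE)
    }
    if (kh > 0) {
      vals <- draw_site_pairs(spec, s, "hair", kh)
      ids <- paste0("H", hair_counter + seq_len(kh)); hair_counter <- hair_counter + kh
      pieces[[length(pieces) + 1]] <- data.frame(
        sample_id = ids, individual_id = paste0("I", ids), site = s,
        location = locs[kp + seq_len(kh)], tissue = "hair",
        d2H = vals$d2H, d18O = vals$d18O,
        d2H_sd = NA_real_, d18O_sd = NA_real_, stringsAsFactors = FALSE)
    }
    if (kt > 0) {
      vals <- draw_site_pairs(spec, s, "toenail", kt)
      ids <- paste0("T", toe_counter + seq_len(kt)); toe_counter <- toe_counter + kt
      pieces[[length(pieces) + 1]] <- data.frame(
        sample_id = ids, individual_id = paste0("I", ids), site = s,
        location = locs[kp + kh + seq_len(kt)], tissue = "toenail",
        d2H = vals$d2H, d18O = vals$d18O,
        d2H_sd = NA_real_, d18O_sd = NA_real_, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, pieces)
  m <- spec$missingness
  if (!is.null(m) && nrow(m) > 0) {
    for (j in seq_len(nrow(m))) {
      # prefer tissue-only samples so the paired count is unaffected
      solo <- which(df$site == m$site[j] & df$tissue == m$tissue[j] &
                      !grepl("^P", df$individual_id))
      if (length(solo) == 0) {
        solo <- which(df$site == m$site[j] & df$tissue == m$tissue[j])
      }
      hit <- utils::head(solo, m$count[j])
      df[[m$isotope[j]]][hit] <- NA_real_
    }
  }
  for (lit in spec$outliers) df <- rbind(df, as.data.frame(lit)[SAMPLE_COLUMNS])
  sample_table(df[SAMPLE_COLUMNS], sites = spec$sites,
               provenance = paste0("simulated-full:seed=", seed))
}

#' Literal bivariate outlier analog
#'
#' The hair sample flagged as a multivariate outlier in the source cohort
#' (extreme-high delta-2H of -58.3 permil combined with low delta-18O of
#' 6.4 permil, Site 1).  Useful as an injectable test point for
#' [mahalanobis_outliers()].
#'
#' @param sample_id Id for the injected record (default `"H2x"`).
#' @return One-row data frame in sample-table layout.
#' @export
h2_analog <- function(sample_id = "H2x") {
  data.frame(sample_id = sample_id, individual_id = paste0("I", sample_id),
             site = "1", location = "Vancouver", tissue = "hair",
             d2H = -58.3, d18O = 6.4, d2H_sd = NA_real_, d18O_sd = NA_real_,
             stringsAsFactors = FALSE)
}

#' Inject a literal sample into a table
#'
#' Appends one fully specified sample (for example [h2_analog()]) to a
#' sample table, recording the injection in the table's provenance.
#'
#' @param table A [sample_table].
#' @param literal One-row data frame in sample-table layout.
#' @return The grown table.
#' @export
inject_outlier <- function(table, literal) {
  stopifnot(inherits(table, "sample_table"), nrow(literal) == 1)
  if (any(table$sample_id == literal$sample_id &
            table$tissue == literal$tissue)) {
    stop("duplicate (sample_id, tissue): ", literal$sample_id, call. = FALSE)
  }
  prov <- attr(table, "provenance")
  df <- rbind(as.data.frame(table), literal[SAMPLE_COLUMNS])
  sample_table(df, sites = attr(table, "sites"),
               provenance = paste(c(prov, paste0("injected:", literal$sample_id)),
                                  collapse = ";"))
}
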
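#' Gini impurity of a label multiset
#'
#' \deqn{G = 1 - \sum_i p_i^2} over the class proportions \eqn{p_i} of the
#' node; 0 for a pure node, approaching \eqn{1 - 1/k} for k balanced
#' classes.
#'
#' @param labels Nonempty vector of class labels.
#' @return Impurity in `[0, 1)`.
#' @export
gini <- function(labels) {
  if (length(labels) == 0) stop("empty label set", call. = FALSE)
  p <- tabulate(factor(labels)) / length(labels)
  1 - sum(p^2)
}

#' Build a feature matrix for one of the three classifier models
#'
#' Model 1: hair samples with features `hair:d2H`, `hair:d18O`;
#' Model 2: toenail samples with `toenail:d2H`, `toenail:d18O`;
#' Model 3: individuals contributing both tissues, feature order
#' `toenail:d2H`, `toenail:d18O`, `hair:d2H`, `hair:d18O` (toenail first;
#' the order is the split tie-break order).  Rows with any missing feature
#' are excluded before training.
#'
#' @param table A [sample_table].
#' @param model Integer 1, 2 or 3.
#' @return List of class `"feature_matrix"`: `x` (numeric matrix, named
#'   columns), `y` (factor of site labels with the table's site order as
#'   levels), `ids` (row unit ids), `model`, `features`.
#' @export
feature_matrix <- function(table, model) {
  stopifnot(inherits(table, "sample_table"), model %in% 1:3)
  sites <- site_levels(table)
  if (model %in% c(1, 2)) {
    tis <- if (model == 1) "hair" else "toenail"
    rows <- table[table$tissue == tis, , drop = FALSE]
    x <- cbind(rows$d2H, rows$d18O)
    colnames(x) <- paste0(tis, ":", c("d2H", "d18O"))
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    y <- factor(rows$site[keep], levels = sites)
    ids <- rows$sample_id[keep]
  } else {
    hair <- table[table$tissue == "hair", , drop = FALSE]
    toe <- table[table$tissue == "toenail", , drop = FALSE]
    ids <- intersect(toe$individual_id, hair$individual_id)
    hi <- match(ids, hair$individual_id); ti <- match(ids, toe$individual_id)
    x <- cbind(toe$d2H[ti], toe$d18O[ti], hair$d2H[hi], hair$d18O[hi])
    colnames(x) <- c("toenail:d2H", "toenail:d18O", "hair:d2H", "hair:d18O")
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    y <- factor(toe$site[ti][keep], levels = sites)
    ids <- ids[keep]
  }
  structure(list(x = x, y = y, ids = ids, model = model,
                 features = colnames(x)),
            class = "feature_matrix")
}

#' Tree stopping configuration
#'
#' Defaults (`min_samples_split = 5`, `max_depth = 5`,
#' `min_gini_gain = 0.01`) are chosen to yield the shallow 2-4 decision-node
#' trees appropriate for cohorts of a few dozen samples, rather than fully
#' grown trees; there is no cost-complexity pruning.
#'
#' @param min_samples_split Minimum node size eligible for splitting (>= 2).
#' @param max_depth Maximum number of split levels below the root.
#' @param min_gini_gain Minimum Gini gain for a split to be executed.
#' @return List of class `"tree_config"`.
#' @export
tree_config <- function(min_samples_split = 5, max_depth = 5,
                        min_gini_gain = 0.01) {
  stopifnot(min_samples_split >= 2, max_depth >= 0, min_gini_gain >= 0)
  structure(list(min_samples_split = min_samples_split,
                 max_depth = max_depth, min_gini_gain = min_gini_gain),
            class = "tree_config")
}

# weighted child impurity of a candidate split (left: value < threshold)
split_impurity <- function(values, y, threshold) {
  left <- values < threshold
  nl <- sum(left); nr <- sum(!left)
  (nl * gini(y[left]) + nr * gini(y[!left])) / length(y)
}

#' Best Gini split of a node
#'
#' Evaluates every candidate threshold (midpoints of consecutive distinct
#' sorted values, per feature) and returns the one maximizing Gini gain =
#' parent impurity minus size-weighted mean child impurity.  Ties are
#' broken deterministically: earlier feature in the declared order wins,
#' then the smaller threshold.  The left branch takes values strictly below
#' the threshold; equality routes right.
#'
#' @param x Numeric feature matrix (named columns).
#' @param y Class labels (factor), `length(y) == nrow(x)`.
#' @param rows Optional integer subset of rows defining the node (default
#'   all rows).
#' @param features Optional subset of feature names to consider.
#' @return `NULL` when no candidate has positive gain; otherwise a list:
#'   `feature`, `feature_index`, `threshold`, `child_impurity`, `gain`.
#' @export
best_split <- function(x, y, rows = seq_len(nrow(x)), features = colnames(x)) {
  xs <- x[rows, , drop = FALSE]
  ys <- droplevels_safe(y[rows])
  if (nrow(xs) < 2) return(NULL)
  parent <- gini(ys)
  best <- NULL
  for (j in match(features, colnames(x))) {
    v <- xs[, j]
    u <- sort(unique(v))
    if (length(u) < 2) next
    thresholds <- (u[-length(u)] + u[-1]) / 2
    for (th in thresholds) {
      ci <- split_impurity(v, ys, th)
      gain <- parent - ci
      if (gain <= 0) next
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = colnames(x)[j], feature_index = j,
                     threshold = th, child_impurity = ci, gain = gain)
      }
      # ties: earlier feature then smaller threshold already win because we
      # scan features in declared order and thresholds ascending, replacing
      # only on a strict improvement
    }
  }
  best
}

droplevels_safe <- function(y) if (is.factor(y)) y else factor(y)

#' Grow a CART classification tree
#'
#' Recursive binary partitioning by [best_split()].  A node becomes a leaf
#' when it is pure, smaller than `min_samples_split`, at `max_depth`, or
#' when the best achievable gain is below `min_gini_gain`.  Every node
#' carries its class-proportion vector over the full site set, the fraction
#' of the training set reaching it, and its predicted site (argmax of the
#' proportions, ties broken by site order).
#'
#' @param fm A [feature_matrix()] (or any list with numeric matrix `x` and
#'   factor `y`).
#' @param config A [tree_config()].
#' @return List of class `"isotope_tree"`: `root` (nested nodes), `classes`,
#'   `features`, `n`, `config`.
#' @export
grow_tree <- function(fm, config = tree_config()) {
  x <- fm$x; y <- fm$y
  if (is.null(dim(x)) || nrow(x) == 0) stop("empty feature matrix", call. = FALSE)
  stopifnot(is.factor(y), nrow(x) == length(y))
  classes <- levels(y)
  n_total <- nrow(x)
  build <- function(rows, depth) {
    ys <- y[rows]
    counts <- table(ys)
    prop <- as.numeric(counts) / length(rows)
    names(prop) <- classes
    node <- list(kind = "leaf",
                 class_proportions = prop,
                 sample_fraction = length(rows) / n_total,
                 n = length(rows),
                 predicted_site = classes[which.max(prop)])
    pure <- gini(ys) == 0
    if (pure || length(rows) < config$min_samples_split ||
        depth >= config$max_depth) {
      return(node)
    }
    sp <- best_split(x, y, rows)
    if (is.null(sp) || sp$gain < config$min_gini_gain) return(node)
    left_rows <- rows[x[rows, sp$feature_index] < sp$threshold]
    right_rows <- setdiff(rows, left_rows)
    node$kind <- "split"
    node$split_feature <- sp$feature
    node$threshold <- sp$threshold
    node$gain <- sp$gain
    node$left <- build(left_rows, depth + 1)
    node$right <- build(right_rows, depth + 1)
    node
  }
  structure(list(root = build(seq_len(n_total), 0), classes = classes,
                 features = colnames(x), n = n_total, config = config),
            class = "isotope_tree")
}

#' Predict sites for new feature rows
#'
#' Routes each row down the tree: strictly below the threshold goes left,
#' equal or above goes right.  A missing value for a feature tested on the
#' traversed path is an error.
#'
#' @param object An `isotope_tree`.
#' @param newdata Numeric matrix or data.frame whose columns include the
#'   tree's features.
#' @param ... Unused.
#' @return List: `site` (character predictions) and `proportions` (matrix,
#'   one row per input, columns = classes).
#' @export
predict.isotope_tree <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    x <- do.call(cbind, lapply(newdata, as.numeric))
    colnames(x) <- names(newdata)
  } else {
    x <- as.matrix(newdata)
  }
  if (is.null(colnames(x)) && ncol(x) == length(object$features)) {
    colnames(x) <- object$features  # positional matching when unnamed
  }
  if (!all(object$features %in% colnames(x))) {
    stop("newdata lacks features: ",
         paste(setdiff(object$features, colnames(x)), collapse = ", "),
         call. = FALSE)
  }
  route <- function(node, row) {
    if (node$kind == "leaf") return(node)
    v <- row[[node$split_feature]]
    if (is.na(v)) {
      stop("missing value for feature '", node$split_feature,
           "' on the traversed path", call. = FALSE)
    }
    if (v < node$threshold) route(node$left, row) else route(node$right, row)
  }
  leaves <- lapply(seq_len(nrow(x)), function(i) {
    row <- as.list(x[i, object$features])
    route(object$root, row)
  })
  prop <- do.call(rbind, lapply(leaves, `[[`, "class_proportions"))
  colnames(prop) <- object$classes
  list(site = vapply(leaves, `[[`, "", "predicted_site"),
       proportions = prop)
}

#' Render a tree as a text diagram
#'
#' One line per node: predicted site, class proportions as decimals (site
#' order), and the percentage of training samples reaching the node;
#' split nodes additionally show their rule.
#'
#' @param tree An `isotope_tree`.
#' @return Character scalar (also printed by `print.isotope_tree`).
#' @export
render_tree <- function(tree) {
  lines <- character()
  walk <- function(node, prefix, tag) {
    desc <- sprintf("site %s [%s] %.0f%%", node$predicted_site,
                    paste(sprintf("%.2f", node$class_proportions),
                          collapse = " "),
                    100 * node$sample_fraction)
    if (node$kind == "split") {
      desc <- sprintf("%s | split %s < %.3g", desc, node$split_feature,
                      node$threshold)
    }
    lines <<- c(lines, paste0(prefix, tag, desc))
    if (node$kind == "split") {
      walk(node$left, paste0(prefix, "  "), "< : ")
      walk(node$right, paste0(prefix, "  "), ">=: ")
    }
  }
  walk(tree$root, "", "")
  paste(lines, collapse = "\n")
}

#' @export
print.isotope_tree <- function(x, ...) {
  cat(sprintf("CART tree: %d training rows, classes {%s}\n", x$n,
              paste(x$classes, collapse = ",")))
  cat(render_tree(x), "\n")
  invisible(x)
}

#' Serialize / deserialize a tree to JSON
#'
#' `serialize_tree` emits a canonical nested-node JSON document;
#' `deserialize_tree` reconstructs an equivalent `isotope_tree`
#' (`deserialize_tree(serialize_tree(t))` reproduces `t`'s structure,
#' thresholds, proportions and fractions).
#'
#' @param tree An `isotope_tree`.
#' @param json JSON string or file path.
#' @return `serialize_tree`: a JSON string; `deserialize_tree`: an
#'   `isotope_tree`.
#' @export
serialize_tree <- function(tree) {
  jsonlite::toJSON(unclass_tree(tree), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

unclass_tree <- function(tree) {
  strip <- function(node) {
    out <- list(kind = node$kind,
                class_proportions = as.list(node$class_proportions),
                sample_fraction = node$sample_fraction,
                n = node$n,
                predicted_site = node$predicted_site)
    if (node$kind == "split") {
      out$split_feature <- node$split_feature
      out$threshold <- node$threshold
      out$gain <- node$gain
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  list(classes = as.list(tree$classes), features = as.list(tree$features),
       n = tree$n,
       config = unclass(tree$config),
       root = strip(tree$root))
}

#' @rdname serialize_tree
#' @export
deserialize_tree <- function(json) {
  obj <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) stop("malformed tree JSON: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(obj$root) || is.null(obj$classes)) {
    stop("malformed tree JSON: missing root/classes", call. = FALSE)
  }
  classes <- unlist(obj$classes)
  rebuild <- function(node) {
    prop <- unlist(node$class_proportions)
    out <- list(kind = node$kind,
                class_proportions = stats::setNames(as.numeric(prop),
                                                    names(prop)),
                sample_fraction = node$sample_fraction,
                n = node$n,
                predicted_site = node$predicted_site)
    if (identical(node$kind, "split")) {
      out$split_feature <- node$split_feature
      out$threshold <- node$threshold
      out$gain <- node$gain
      out$left <- rebuild(node$left)
      out$right <- rebuild(node$right)
    }
    out
  }
  structure(list(root = rebuild(obj$root), classes = classes,
                 features = unlist(obj$features), n = obj$n,
                 config = do.call(tree_config, obj$config)),
            class = "isotope_tree")
}
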
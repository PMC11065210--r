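#' Random-forest configuration
#'
#' Defaults follow common genebank-characterization practice: 100 trees, a
#' stratified 70/30 train/validation split, and the 15 lowest-mean-minimal-
#' depth descriptors selected.
#'
#' @param n_trees Number of trees (default 100).
#' @param train_fraction Training share, strictly in (0, 1) (default 0.7).
#' @param top_n Number of descriptors to select (default 15).
#' @param seed Integer seed.
#' @param stratify Stratify the split by class (default TRUE).
#' @return An `rf_config` object.
#' @export
rf_config <- function(n_trees = 100, train_fraction = 0.7, top_n = 15,
                      seed = 1, stratify = TRUE) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1, top_n >= 1)
  structure(list(n_trees = n_trees, train_fraction = train_fraction,
                 top_n = top_n, seed = as.integer(seed), stratify = stratify),
            class = "rf_config")
}

#' Fit a classification random forest on encoded descriptors
#'
#' Splits rows 70/30 (stratified within class by default), then fits a
#' forest of CART trees on bootstrap samples with `sqrt(p)` candidate
#' features per split (Gini impurity, unlimited depth). The split indices
#' and seed are recorded for reproducibility.
#'
#' @param x Numeric matrix from [encode_for_rf()].
#' @param labels Class label per row (accession ids, or species).
#' @param config An `rf_config`.
#' @return List of class `rf_fit`: `forest` (randomForest object),
#'   `train_idx`, `valid_idx`, `labels` (factor), `config`.
#' @export
fit_forest <- function(x, labels, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"), nrow(x) == length(labels))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  sizes <- table(y)
  if (any(sizes < 2))
    stop("class(es) with a single row: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  set.seed(config$seed)
  if (config$stratify) {
    train_idx <- sort(unlist(lapply(levels(y), function(l) {
      i <- which(y == l)
      sample(i, max(1, round(config$train_fraction * length(i))))
    }), use.names = FALSE))
  } else {
    train_idx <- sort(sample(nrow(x), round(config$train_fraction * nrow(x))))
  }
  valid_idx <- setdiff(seq_len(nrow(x)), train_idx)
  forest <- randomForest::randomForest(
    x = x[train_idx, , drop = FALSE], y = droplevels(y[train_idx]),
    ntree = config$n_trees, importance = FALSE, keep.forest = TRUE)
  structure(list(forest = forest, train_idx = train_idx,
                 valid_idx = valid_idx, labels = y, config = config),
            class = "rf_fit")
}

#' Export a fitted forest as plain tree tables
#'
#' One data.frame per tree with columns `left`, `right` (child node row
#' indices, NA at leaves) and `var` (encoded column name splitting the
#' node, NA at leaves). Hand-built forests in this format can be fed
#' straight to [minimal_depth()].
#'
#' @param fit An `rf_fit`, a randomForest object, or already a list of such
#'   tables (returned unchanged).
#' @return List of tree tables.
#' @export
forest_tree_tables <- function(fit) {
  if (is.list(fit) && !inherits(fit, c("rf_fit", "randomForest")) &&
      all(vapply(fit, is.data.frame, logical(1)))) return(fit)
  rf <- if (inherits(fit, "rf_fit")) fit$forest else fit
  vars <- rownames(rf$importance)
  lapply(seq_len(rf$ntree), function(k) {
    tr <- randomForest::getTree(rf, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    data.frame(
      left = ifelse(leaf, NA, tr[, "left daughter"]),
      right = ifelse(leaf, NA, tr[, "right daughter"]),
      var = ifelse(leaf, NA, vars[tr[, "split var"]]),
      stringsAsFactors = FALSE)
  })
}

#' Mean minimal depth of descriptors over a forest
#'
#' For each tree, a feature's minimal depth is the depth of its shallowest
#' split node (root = 0); a feature unused in a tree is assigned that
#' tree's maximum node depth + 1 (one level below the deepest leaf), which
#' penalizes unused features while keeping the average finite. One-hot
#' child columns are collapsed to their parent descriptor by the per-tree
#' minimum before averaging. Lower mean minimal depth (MDM) = more
#' important: the descriptor acts earlier in the trees and discriminates
#' accessions more strongly.
#'
#' @param fit An `rf_fit` or a list of tree tables
#'   (see [forest_tree_tables()]).
#' @param parent Named character vector mapping encoded columns to parent
#'   descriptors (from [encode_for_rf()]); defaults to identity.
#' @return List of class `minimal_depth`: `mdm` (named, ascending-unsorted),
#'   `depths` (descriptor x tree matrix), `usage` (split counts per
#'   descriptor over all trees).
#' @export
minimal_depth <- function(fit, parent = NULL) {
  trees <- forest_tree_tables(fit)
  feats <- unique(stats::na.omit(unlist(lapply(trees, `[[`, "var"))))
  if (!is.null(parent)) feats <- unique(c(feats, names(parent)))
  if (is.null(parent)) parent <- stats::setNames(feats, feats)
  parents <- unique(unname(parent))

  per_tree <- vapply(trees, function(tr) {
    depth <- tree_node_depths(tr)
    fill <- max(depth) + 1
    d <- stats::setNames(rep(fill, length(feats)), feats)
    used <- !is.na(tr$var)
    for (i in which(used)) {
      v <- tr$var[i]
      if (depth[i] < d[v]) d[v] <- depth[i]
    }
    # collapse encoded children to parents by per-tree minimum
    vapply(parents, function(p)
      min(d[names(parent)[parent == p]], na.rm = TRUE), numeric(1))
  }, numeric(length(parents)))
  per_tree <- matrix(per_tree, nrow = length(parents),
                     dimnames = list(parents, NULL))

  usage <- stats::setNames(rep(0, length(parents)), parents)
  for (tr in trees) {
    u <- table(parent[stats::na.omit(tr$var)])
    usage[names(u)] <- usage[names(u)] + as.numeric(u)
  }
  structure(list(mdm = rowMeans(per_tree), depths = per_tree, usage = usage),
            class = "minimal_depth")
}

# depth of every node of a tree table (root row 1 = depth 0)
tree_node_depths <- function(tr) {
  depth <- rep(NA_real_, nrow(tr))
  depth[1] <- 0
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    if (!is.na(tr$left[i])) {
      depth[c(tr$left[i], tr$right[i])] <- depth[i] + 1
      queue <- c(queue, tr$left[i], tr$right[i])
    }
  }
  depth
}

#' Evaluate a fitted forest: OOB error and validation confusion
#'
#' OOB error is the forest's out-of-bag misclassification rate on the
#' training rows (votes from trees whose bootstrap excluded the row). The
#' confusion matrix is computed on the 30% validation rows and
#' row-normalized over true classes; a validation class with no rows is
#' returned as NA and flagged.
#'
#' Both the validation confusion and the (finer-grained, since every
#' training row contributes) OOB confusion are returned.
#'
#' @param fit An `rf_fit`.
#' @param x The full encoded matrix used in [fit_forest()].
#' @return List: `oob_error` (fraction), `confusion` (validation, true x
#'   predicted proportions), `oob_confusion` (row-normalized),
#'   `valid_error`, `empty_classes`.
#' @export
evaluate_forest <- function(fit, x) {
  stopifnot(inherits(fit, "rf_fit"))
  rf <- fit$forest
  oob <- as.numeric(rf$err.rate[rf$ntree, "OOB"])
  oc <- rf$confusion[, setdiff(colnames(rf$confusion), "class.error"),
                     drop = FALSE]
  oc <- sweep(oc, 1, pmax(rowSums(oc), 1), "/")
  yv <- fit$labels[fit$valid_idx]
  if (length(fit$valid_idx) == 0) stop("empty validation set")
  pred <- stats::predict(rf, x[fit$valid_idx, , drop = FALSE])
  lv <- levels(fit$labels)
  cm <- table(factor(yv, levels = lv), factor(pred, levels = lv))
  n <- rowSums(cm)
  conf <- sweep(cm, 1, pmax(n, 1), "/")
  conf[n == 0, ] <- NA
  list(oob_error = oob,
       confusion = as.matrix(unclass(conf)),
       oob_confusion = as.matrix(oc),
       valid_error = mean(as.character(pred) != as.character(yv)),
       empty_classes = lv[n == 0])
}

#' Select the top descriptors by mean minimal depth
#'
#' Ascending MDM; ties broken by higher split-usage count across trees,
#' then lexicographically.
#'
#' @param md A `minimal_depth` object.
#' @param top_n How many to select (default 15); capped at the number of
#'   descriptors.
#' @return Character vector of selected descriptor names, best first.
#' @export
select_top <- function(md, top_n = 15) {
  stopifnot(inherits(md, "minimal_depth"))
  o <- order(md$mdm, -md$usage[names(md$mdm)], names(md$mdm))
  names(md$mdm)[o][seq_len(min(top_n, length(md$mdm)))]
}
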
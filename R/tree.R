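#' Fit a depth-limited classification tree
#'
#' Greedy recursive binary splitting on axis-aligned thresholds, minimizing
#' weighted Gini impurity. Candidate thresholds are the midpoints of
#' consecutive sorted unique feature values; growth stops at `max_depth`
#' (default 2, i.e., at most two splits between the root and any leaf), at a
#' pure node, when fewer than 2 rows remain, or when no split reduces
#' impurity (e.g., constant features with mixed labels, which yield a single
#' majority leaf). Ties are broken deterministically: among equal-impurity
#' splits the lowest threshold wins, then the lowest feature index; leaf
#' prediction ties go to the lexicographically first class.
#'
#' @param x Data frame or matrix of numeric features.
#' @param y Class labels (factor or character), length `nrow(x)`.
#' @param max_depth Maximum root-to-leaf distance (default 2).
#' @return A `vg_tree` object with [predict()][predict.vg_tree()], [tidy()]
#'   and print methods.
#' @export
fit_tree <- function(x, y, max_depth = 2) {
  xmat <- as.matrix(x)
  storage.mode(xmat) <- "double"
  classes <- sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  if (nrow(xmat) < 2 || length(classes) < 2) {
    if (nrow(xmat) < 1) {
      abort("need at least one row", class = "verbgen_state_error")
    }
  }
  node <- vg_grow(xmat, yi, length(classes), depth = 0,
                  max_depth = max_depth)
  structure(
    list(root = node, classes = classes,
         features = colnames(xmat) %||% paste0("x", seq_len(ncol(xmat))),
         max_depth = max_depth),
    class = "vg_tree"
  )
}

vg_gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

vg_leaf <- function(yi, n_classes) {
  counts <- tabulate(yi, nbins = n_classes)
  list(leaf = TRUE, n = length(yi), counts = counts,
       prob = counts / length(yi), class_idx = which.max(counts))
}

# Best split for one node: returns NULL or list(feature, threshold, impurity).
vg_best_split <- function(xmat, yi, n_classes) {
  n <- length(yi)
  best <- NULL
  onehot <- matrix(0, n, n_classes)
  onehot[cbind(seq_len(n), yi)] <- 1
  for (j in seq_len(ncol(xmat))) {
    ord <- order(xmat[, j])
    xs <- xmat[ord, j]
    cum <- apply(onehot[ord, , drop = FALSE], 2, cumsum)
    cut_at <- which(xs[-n] < xs[-1])
    if (length(cut_at) == 0) next
    nl <- cut_at
    nr <- n - nl
    cl <- cum[cut_at, , drop = FALSE]
    cr <- rep(cum[n, ], each = length(cut_at)) - cl
    gl <- 1 - rowSums((cl / nl)^2)
    gr <- 1 - rowSums((cr / nr)^2)
    imp <- (nl * gl + nr * gr) / n
    thr <- (xs[cut_at] + xs[cut_at + 1]) / 2
    # lowest threshold among equal-impurity splits within this feature
    k <- order(imp, thr)[1]
    cand <- list(feature = j, threshold = thr[k], impurity = imp[k])
    if (is.null(best) ||
          cand$impurity < best$impurity - 1e-12 ||
          (abs(cand$impurity - best$impurity) <= 1e-12 &&
             cand$threshold < best$threshold)) {
      best <- cand
    }
  }
  best
}

vg_grow <- function(xmat, yi, n_classes, depth, max_depth) {
  node_counts <- tabulate(yi, nbins = n_classes)
  pure <- sum(node_counts > 0) <= 1
  if (depth >= max_depth || pure || length(yi) < 2) {
    return(vg_leaf(yi, n_classes))
  }
  # Split whenever any candidate threshold exists (constant features give
  # none and fall through to a majority leaf). Gini is concave, so the
  # weighted child impurity never exceeds the node's; zero-gain splits are
  # allowed because they can enable informative grandchildren (XOR layouts).
  split <- vg_best_split(xmat, yi, n_classes)
  if (is.null(split)) {
    return(vg_leaf(yi, n_classes))
  }
  go_left <- xmat[, split$feature] <= split$threshold
  list(
    leaf = FALSE, n = length(yi),
    feature = split$feature, threshold = split$threshold,
    impurity = split$impurity,
    left = vg_grow(xmat[go_left, , drop = FALSE], yi[go_left], n_classes,
                   depth + 1, max_depth),
    right = vg_grow(xmat[!go_left, , drop = FALSE], yi[!go_left], n_classes,
                    depth + 1, max_depth)
  )
}

#' Predict from a fitted classification tree
#'
#' @param object A `vg_tree`.
#' @param newdata Data frame or matrix with the training feature columns.
#' @param type `"class"` (default) for labels, `"prob"` for the leaf
#'   class-probability matrix.
#' @param ... Unused.
#' @return Character vector of classes, or a probability matrix.
#' @export
predict.vg_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xmat <- as.matrix(newdata)
  if (!is.null(colnames(xmat)) && all(object$features %in% colnames(xmat))) {
    xmat <- xmat[, object$features, drop = FALSE]
  }
  storage.mode(xmat) <- "double"
  probs <- matrix(NA_real_, nrow(xmat), length(object$classes),
                  dimnames = list(NULL, object$classes))
  cls <- integer(nrow(xmat))
  descend <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) {
      probs[idx, ] <<- matrix(node$prob, length(idx), length(node$prob),
                              byrow = TRUE)
      cls[idx] <<- node$class_idx
      return()
    }
    go_left <- xmat[idx, node$feature] <= node$threshold
    descend(node$left, idx[go_left])
    descend(node$right, idx[!go_left])
  }
  descend(object$root, seq_len(nrow(xmat)))
  if (type == "prob") probs else object$classes[cls]
}

vg_tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(vg_tree_depth(node$left),
                                  vg_tree_depth(node$right))
}

#' @export
print.vg_tree <- function(x, ...) {
  cat(sprintf("Decision tree (max depth %d, classes: %s)\n",
              x$max_depth, paste(x$classes, collapse = ", ")))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s* n=%d -> %s (%s)\n", pad, node$n,
                  x$classes[node$class_idx],
                  paste(sprintf("%.2f", node$prob), collapse = "/")))
    } else {
      cat(sprintf("%s%s <= %.4g (n=%d)\n", pad,
                  x$features[node$feature], node$threshold, node$n))
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' @export
tidy.vg_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node, depth, path) {
    is_leaf <- node$leaf
    feat <- if (is_leaf) NA_character_ else x$features[node$feature]
    thr <- if (is_leaf) NA_real_ else node$threshold
    cls <- if (is_leaf) x$classes[node$class_idx] else NA_character_
    n_node <- node$n
    rows[[length(rows) + 1]] <<- tibble(
      depth = depth, node = path, leaf = is_leaf,
      feature = feat, threshold = thr, n = n_node, class = cls
    )
    if (!is_leaf) {
      walk(node$left, depth + 1, paste0(path, "L"))
      walk(node$right, depth + 1, paste0(path, "R"))
    }
  }
  walk(x$root, 0, "root")
  bind_rows(rows)
}
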
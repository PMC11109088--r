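# A small greedy CART-style binary classification tree (Gini impurity),
# depth-limited. The published optimum for this problem is a depth-1 rule,
# so a compact, fully specified tree keeps the learned model interpretable
# as (feature, inequality, cutpoint) rules.

gini <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  if (n == 0) return(0)
  p <- n_pos / n
  2 * p * (1 - p)
}

# best split of one feature: scan midpoints of sorted distinct values,
# minimizing the weighted Gini impurity of the two children.
best_split_feature <- function(x, y_pos, min_leaf) {
  o <- order(x)
  xs <- x[o]; ys <- y_pos[o]
  n <- length(xs)
  cum_pos <- cumsum(ys)
  n_pos <- cum_pos[n]
  # candidate split after position i (left = 1..i)
  cand <- which(diff(xs) > 0)
  cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
  if (!length(cand)) return(NULL)
  lp <- cum_pos[cand]; ln <- cand - lp
  rp <- n_pos - lp; rn <- (n - cand) - rp
  imp <- (cand * mapply(gini, lp, ln) + (n - cand) * mapply(gini, rp, rn)) / n
  i <- cand[which.min(imp)]
  list(cut = (xs[i] + xs[i + 1]) / 2, impurity = min(imp))
}

grow_tree <- function(X, y_pos, depth, max_depth, min_leaf) {
  n <- length(y_pos)
  n_pos <- sum(y_pos)
  node_imp <- gini(n_pos, n - n_pos)
  leaf <- list(type = "leaf", prob = n_pos / n, n = n)
  if (depth >= max_depth || node_imp == 0 || n < 2 * min_leaf) return(leaf)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    s <- best_split_feature(X[, j], y_pos, min_leaf)
    if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
      best <- s; best$feature <- j
    }
  }
  if (is.null(best) || best$impurity >= node_imp - 1e-12) return(leaf)
  left <- X[, best$feature] <= best$cut
  list(type = "split", feature = best$feature, cut = best$cut,
       left = grow_tree(X[left, , drop = FALSE], y_pos[left],
                        depth + 1, max_depth, min_leaf),
       right = grow_tree(X[!left, , drop = FALSE], y_pos[!left],
                         depth + 1, max_depth, min_leaf))
}

#' Fit a depth-limited classification tree
#'
#' Greedy binary CART-style splits minimizing Gini impurity, with a depth
#' cap and a minimum leaf size. Internal learner of
#' [train_threshold_tree()]; exported for direct use and testing.
#'
#' @param X numeric feature matrix (columns named)
#' @param y logical or 0/1 vector (TRUE = positive class)
#' @param max_depth maximum tree depth (default 2)
#' @param min_leaf minimum samples per leaf (default 5)
#' @return object of class `cart_tree`
#' @export
fit_cart <- function(X, y, max_depth = 2L, min_leaf = 5L) {
  X <- as.matrix(X)
  y <- as.logical(y)
  assert_that(nrow(X) == length(y), "X and y differ in length")
  assert_that(max_depth >= 1, "max_depth must be >= 1")
  root <- grow_tree(X, y, 0L, max_depth, min_leaf)
  structure(list(root = root, features = colnames(X), max_depth = max_depth),
            class = "cart_tree")
}

#' Predict with a [fit_cart()] tree
#' @param object a `cart_tree`
#' @param newdata feature matrix with the training columns
#' @param ... unused
#' @return logical vector of positive-class predictions
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  pred1 <- function(node, x) {
    while (node$type == "split")
      node <- if (x[node$feature] <= node$cut) node$left else node$right
    node$prob >= 0.5
  }
  vapply(seq_len(nrow(X)), function(i) pred1(object$root, X[i, ]), TRUE)
}

#' Flatten a tree into ordered (feature, inequality, cutpoint) rules
#' @param tree a `cart_tree`
#' @return data.frame with columns depth, feature, op, cut (split nodes in
#'   pre-order); zero rows for a stump
#' @export
tree_rules <- function(tree) {
  out <- list()
  walk <- function(node, depth) {
    if (node$type != "split") return()
    out[[length(out) + 1L]] <<- data.frame(
      depth = depth, feature = tree$features[node$feature],
      op = "<=", cut = node$cut, stringsAsFactors = FALSE)
    walk(node$left, depth + 1L)
    walk(node$right, depth + 1L)
  }
  walk(tree$root, 1L)
  if (!length(out)) return(data.frame(depth = integer(), feature = character(),
                                      op = character(), cut = numeric()))
  do.call(rbind, out)
}
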
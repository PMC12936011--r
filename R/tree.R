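# Regression trees grown by greedy variance-reduction splitting, with
# reduced-error pruning against a held-out set. Trees are nested lists:
# internal nodes {leaf=FALSE, feature, threshold, value, n, left, right},
# leaves {leaf=TRUE, value, n}. `value` is the training mean routed to the
# node (kept on internal nodes so pruning can collapse them exactly).

.leaf <- function(value, n) list(leaf = TRUE, value = value, n = n)

# Best split for one feature: candidate thresholds are midpoints of
# consecutive distinct sorted values; children must each hold >= minLeaf.
# Maximizing sum(n_child * mean_child^2) is equivalent to maximizing the
# variance reduction. Gains within a data-scaled tolerance are treated as
# exact ties and break to the lowest threshold (and, one level up, the
# lowest feature index) so tie resolution is independent of float noise.
# Returns NULL or list(threshold, score, eps).
.bestSplitFeature <- function(xf, y, minLeaf, eps) {
  n <- length(y)
  o <- order(xf)
  xs <- xf[o]; ys <- y[o]
  cs <- cumsum(ys)
  tot <- cs[n]
  i <- seq_len(n - 1L)
  valid <- (xs[i] < xs[i + 1L]) & (i >= minLeaf) & ((n - i) >= minLeaf)
  if (!any(valid)) return(NULL)
  i <- i[valid]
  score <- cs[i]^2 / i + (tot - cs[i])^2 / (n - i)
  best <- which(score >= max(score) - eps)[1L]  # tie: lowest threshold
  list(threshold = (xs[i[best]] + xs[i[best] + 1L]) / 2,
       score = score[best] - tot^2 / n)
}

.growTree <- function(X, y, idx, depth, minLeaf, maxDepth, mtry) {
  n <- length(idx)
  v <- mean(y[idx])
  if (depth >= maxDepth || n < 2L * minLeaf || all(y[idx] == y[idx[1L]]))
    return(.leaf(v, n))
  p <- ncol(X)
  feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
  eps <- 1e-10 * (sum(y[idx]^2) + 1)
  best <- NULL
  for (f in feats) {
    sp <- .bestSplitFeature(X[idx, f], y[idx], minLeaf, eps)
    if (!is.null(sp) && (is.null(best) || sp$score > best$score + eps))
      best <- list(feature = f, threshold = sp$threshold,
                   score = sp$score)
  }
  if (is.null(best) || best$score <= eps) return(.leaf(v, n))
  goLeft <- X[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = colnames(X)[best$feature],
       threshold = best$threshold, value = v, n = n,
       left = .growTree(X, y, idx[goLeft], depth + 1L, minLeaf,
                        maxDepth, mtry),
       right = .growTree(X, y, idx[!goLeft], depth + 1L, minLeaf,
                         maxDepth, mtry))
}

#' Fit a variance-reduction regression tree
#'
#' Greedy recursive partitioning: at each node the split maximizing the
#' reduction in squared error is chosen among candidate thresholds placed
#' at midpoints of consecutive distinct sorted feature values. Growth
#' stops at \code{maxDepth}, when a node holds fewer than \code{2*minLeaf}
#' cases, or when the response is constant. Ties between equal-gain splits
#' break to the lowest feature index, then the lowest threshold. With
#' \code{mtry} below the number of features a fresh random feature subset
#' is drawn at each node (the random-forest mechanism).
#'
#' @param X numeric feature matrix or data.frame (rows = cases); columns
#'   must be named.
#' @param y numeric response, \code{length(y) == nrow(X)}.
#' @param minLeaf minimum cases per leaf (default 2).
#' @param maxDepth maximum depth (default 25; root depth 0).
#' @param mtry number of features sampled per node, or \code{NULL} for all.
#' @param seed optional RNG seed (only consumed when \code{mtry} is set).
#' @return Tree as a nested list (class \code{"repTree"}).
#' @export
fitTree <- function(X, y, minLeaf = 2L, maxDepth = 25L, mtry = NULL,
                    seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (length(y) < 1L) stop("empty training set")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("features and response must be finite")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- p
  if (mtry < 1L || mtry > p) stop("mtry must be in [1, ncol(X)]")
  if (!is.null(seed)) set.seed(seed)
  tree <- .growTree(X, y, seq_len(nrow(X)), 0L, as.integer(minLeaf),
                    as.integer(maxDepth), as.integer(mtry))
  class(tree) <- c("repTree", "list")
  tree
}

#' Predict from a regression tree
#'
#' @param tree a tree from \code{\link{fitTree}} (or \code{\link{repPrune}}).
#' @param X feature matrix/data.frame with the training column names.
#' @return Numeric predictions, one per row.
#' @export
predictTree <- function(tree, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (isTRUE(node$leaf)) { out[idx] <<- node$value; return(invisible(NULL)) }
    goLeft <- X[idx, node$feature] <= node$threshold
    route(node$left, idx[goLeft])
    route(node$right, idx[!goLeft])
  }
  route(tree, seq_len(nrow(X)))
  out
}

#' Count nodes of a tree
#'
#' @param tree a fitted tree.
#' @return Total node count (internal + leaves).
#' @export
countNodes <- function(tree) {
  if (isTRUE(tree$leaf)) return(1L)
  1L + countNodes(tree$left) + countNodes(tree$right)
}

#' Reduced-error pruning
#'
#' Bottom-up pruning against a held-out set: a subtree is replaced by a
#' leaf (predicting the training mean routed to that node) whenever the
#' pruning-set squared error does not increase. The pruned tree's
#' pruning-set SSE and node count never exceed the original's.
#'
#' @param tree a tree from \code{\link{fitTree}}.
#' @param X,y the pruning set (non-empty).
#' @return The pruned tree (class \code{"repTree"}).
#' @export
repPrune <- function(tree, X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("pruning set must be non-empty")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  sseOf <- function(node, idx) {
    if (!length(idx)) return(0)
    sum((y[idx] - predictTree(node, X[idx, , drop = FALSE]))^2)
  }
  prune <- function(node, idx) {
    if (isTRUE(node$leaf)) return(node)
    goLeft <- if (length(idx)) X[idx, node$feature] <= node$threshold
              else logical(0)
    node$left <- prune(node$left, idx[goLeft])
    node$right <- prune(node$right, idx[!goLeft])
    sseSub <- sseOf(node, idx)
    sseLeaf <- if (length(idx)) sum((y[idx] - node$value)^2) else 0
    if (sseLeaf <= sseSub) return(.leaf(node$value, node$n))
    node
  }
  out <- prune(tree, seq_len(nrow(X)))
  class(out) <- c("repTree", "list")
  out
}

#' Plain-text if-then rule dump of a tree
#'
#' Mirrors the familiar \code{att <= VALUE} rule style; leaves show the
#' predicted value and the training instance count.
#'
#' @param tree a fitted tree.
#' @param digits significant digits for thresholds and values.
#' @return Character vector of lines (also printed by \code{cat} when
#'   assigned to nothing).
#' @export
treeRules <- function(tree, digits = 6) {
  lines <- character(0)
  walk <- function(node, indent) {
    pad <- strrep("|   ", indent)
    if (isTRUE(node$leaf)) {
      lines <<- c(lines, sprintf("%s-> %s (%d)", pad,
                                 signif(node$value, digits), node$n))
      return(invisible(NULL))
    }
    lines <<- c(lines, sprintf("%s%s <= %s", pad, node$feature,
                               signif(node$threshold, digits)))
    walk(node$left, indent + 1L)
    lines <<- c(lines, sprintf("%s%s > %s", pad, node$feature,
                               signif(node$threshold, digits)))
    walk(node$right, indent + 1L)
  }
  walk(tree, 0L)
  lines
}

#' Serialize a tree to JSON
#'
#' @param tree a fitted tree.
#' @return JSON string (machine-readable nested structure).
#' @export
treeToJSON <- function(tree) {
  as.character(jsonlite::toJSON(unclass(tree), auto_unbox = TRUE,
                                digits = NA))
}

#' Deserialize a tree from JSON
#'
#' @param json string produced by \code{\link{treeToJSON}}.
#' @return Tree (class \code{"repTree"}).
#' @export
treeFromJSON <- function(json) {
  tree <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    node$value <- as.numeric(node$value)
    node$n <- as.integer(node$n)
    if (!node$leaf) {
      node$threshold <- as.numeric(node$threshold)
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  out <- fix(tree)
  class(out) <- c("repTree", "list")
  out
}
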
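#' Growth controls for classification trees
#'
#' Defaults mirror the conventional CART controls: a node is not split below
#' 20 subjects, leaves keep at least 7, and a split must improve the scaled
#' cost-complexity by at least `cp` = 0.01.
#'
#' @param minsplit Minimum node size eligible for splitting.
#' @param minbucket Minimum leaf size.
#' @param cp Complexity floor during growing.
#' @param one_se If `TRUE`, pruning selects the smallest tree within one
#'   standard error of the minimum cross-validated error instead of the
#'   minimum itself.
#' @return A list of class `mood_tree_control`.
#' @export
tree_control <- function(minsplit = 20, minbucket = 7, cp = 0.01,
                         one_se = FALSE) {
  structure(list(minsplit = minsplit, minbucket = minbucket, cp = cp,
                 one_se = isTRUE(one_se)),
            class = "mood_tree_control")
}

leaf_node <- function(prevalence, share) {
  list(predicted_class = as.integer(prevalence > 0.5),
       class_prevalence = prevalence,
       population_share = share,
       split_variable = NULL, left = NULL, right = NULL)
}

# Convert an rpart fit into the package's recursive node structure.
# Convention: left child = split variable 0, right child = 1. Predicted class
# is recomputed as prevalence > 0.5 with ties to class 0.
rpart_to_node <- function(fit) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  n_root <- frame$n[1]
  internal <- which(frame$var != "<leaf>")
  # with maxcompete = 0 and maxsurrogate = 0, splits has one row per internal
  # node, in frame order
  split_of <- integer(nrow(frame))
  split_of[internal] <- seq_along(internal)
  build <- function(node_id) {
    i <- match(node_id, nodes)
    prevalence <- unname(frame$yval2[i, 3] / frame$n[i])
    share <- unname(frame$n[i] / n_root)
    if (frame$var[i] == "<leaf>") return(leaf_node(prevalence, share))
    out <- leaf_node(prevalence, share)
    out$split_variable <- as.character(frame$var[i])
    left <- build(2L * node_id)
    right <- build(2L * node_id + 1L)
    # ncat = -1: rpart's left branch is x < cutpoint (x = 0); +1 reverses
    if (fit$splits[split_of[i], "ncat"] > 0) {
      tmp <- left; left <- right; right <- tmp
    }
    out$left <- left
    out$right <- right
    out
  }
  build(1L)
}

tree_variables <- function(node) {
  if (is.null(node$split_variable)) return(character())
  unique(c(node$split_variable,
           tree_variables(node$left), tree_variables(node$right)))
}

count_leaves <- function(node) {
  if (is.null(node$split_variable)) return(1L)
  count_leaves(node$left) + count_leaves(node$right)
}

tree_depth <- function(node) {
  if (is.null(node$split_variable)) return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

rpart_fit <- function(features, labels, control, xval) {
  df <- as.data.frame(features)
  df$.y <- factor(labels, levels = c(0, 1))
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(
                 minsplit = control$minsplit, minbucket = control$minbucket,
                 cp = control$cp, xval = xval,
                 maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))
}

check_tree_inputs <- function(features, labels) {
  if (is.null(dim(features)) || nrow(features) == 0L) {
    stop("features must be a nonempty matrix or data frame", call. = FALSE)
  }
  if (length(labels) != nrow(features)) {
    stop("labels length must match nrow(features)", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  invisible(NULL)
}

#' Grow a classification tree by greedy Gini splitting
#'
#' Recursive best-split growing without pruning: at each node the variable
#' with the largest Gini impurity decrease is chosen (ties go to the earliest
#' column), stopping on purity, the minimum node size, or when no split
#' clears the complexity floor. All predictors are binary, so each variable
#' offers a single candidate cut.
#'
#' @param features n x p matrix or data frame of 0/1 predictors.
#' @param labels Binary 0/1 outcome vector of length n.
#' @param control A [tree_control()].
#' @return An object of class `mood_grown`: list with `root` (recursive node
#'   structure), `variables_used` and the underlying engine fit.
#' @export
grow_tree <- function(features, labels, control = tree_control()) {
  check_tree_inputs(features, labels)
  if (length(unique(labels)) == 1L) {
    root <- leaf_node(mean(labels), 1)
    return(structure(list(root = root, variables_used = character(),
                          engine = NULL, n = nrow(features)),
                     class = "mood_grown"))
  }
  fit <- rpart_fit(features, labels, control, xval = 0)
  root <- rpart_to_node(fit)
  structure(list(root = root, variables_used = tree_variables(root),
                 engine = fit, n = nrow(features)),
            class = "mood_grown")
}

#' Cost-complexity pruning path
#'
#' The weakest-link sequence of nested subtrees of a grown tree, from the
#' full tree down to the root leaf, with the complexity value at which each
#' tree becomes optimal. Complexity values are on the conventional scaled
#' (cp) scale: penalty per split relative to the root misclassification risk.
#'
#' @param grown A [grow_tree()] result.
#' @return List of entries `list(alpha, size, tree)` ordered by increasing
#'   alpha (decreasing size).
#' @export
complexity_path <- function(grown) {
  stopifnot(inherits(grown, "mood_grown"))
  if (is.null(grown$engine)) {
    return(list(list(alpha = Inf, size = 1L, tree = grown$root)))
  }
  cpt <- grown$engine$cptable
  lapply(rev(seq_len(nrow(cpt))), function(i) {
    pruned <- rpart::prune(grown$engine, cp = cpt[i, "CP"] * (1 + 1e-9))
    node <- rpart_to_node(pruned)
    list(alpha = unname(cpt[i, "CP"]), size = count_leaves(node), tree = node)
  })
}

#' Fit a cross-validation-pruned classification tree
#'
#' Grows a tree, computes the cost-complexity pruning path, estimates the
#' out-of-fold misclassification of every candidate complexity by k-fold
#' cross-validation, and returns the pruned tree whose complexity minimises
#' the cross-validated error (ties broken toward the smaller tree; optionally
#' the one-standard-error rule). Fold assignment draws on the current RNG
#' stream, which is the only stochastic element.
#'
#' @inheritParams grow_tree
#' @param folds Number of cross-validation folds (default 10).
#' @return An object of class `mood_tree`: `root`, `variables_used`,
#'   `cv_trace` (data frame of complexity, size, xerror, xstd),
#'   `selected_complexity`, `n`.
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(400, 1, 0.5), 100, 4,
#'             dimnames = list(NULL, paste0("s", 1:4)))
#' fit <- fit_tree(x, x[, 2])
#' fit$variables_used
#' @export
fit_tree <- function(features, labels, control = tree_control(), folds = 10) {
  check_tree_inputs(features, labels)
  if (nrow(features) < folds) stop("need n >= folds", call. = FALSE)
  if (length(unique(labels)) == 1L) {
    root <- leaf_node(mean(labels), 1)
    return(structure(list(root = root, variables_used = character(),
                          cv_trace = data.frame(complexity = Inf, size = 1L,
                                                xerror = NA_real_,
                                                xstd = NA_real_),
                          selected_complexity = Inf, n = nrow(features)),
                     class = "mood_tree"))
  }
  fit <- rpart_fit(features, labels, control, xval = folds)
  cpt <- fit$cptable
  trace <- data.frame(complexity = unname(cpt[, "CP"]),
                      size = unname(cpt[, "nsplit"]) + 1L,
                      xerror = unname(cpt[, "xerror"]),
                      xstd = unname(cpt[, "xstd"]))
  best <- min(trace$xerror)
  if (control$one_se) {
    cutoff <- best + trace$xstd[which.min(trace$xerror)]
    sel <- min(which(trace$xerror <= cutoff))
  } else {
    # cptable rows are ordered from smallest tree to largest, so the first
    # row attaining the minimum is the smallest such tree
    sel <- min(which(trace$xerror == best))
  }
  pruned <- rpart::prune(fit, cp = trace$complexity[sel] * (1 + 1e-9))
  root <- rpart_to_node(pruned)
  structure(list(root = root, variables_used = tree_variables(root),
                 cv_trace = trace, selected_complexity = trace$complexity[sel],
                 n = nrow(features)),
            class = "mood_tree")
}

#' @export
print.mood_tree <- function(x, ...) {
  cat(sprintf("mood_tree: %d leaves, depth %d, fitted on %d subjects\n",
              count_leaves(x$root), tree_depth(x$root), x$n))
  if (length(x$variables_used)) {
    cat("splits on:", paste(x$variables_used, collapse = ", "), "\n")
  } else {
    cat("single leaf (no splits)\n")
  }
  cat(render_tree_text(x), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mood_tree <- function(object, ...) {
  cat(sprintf("Cross-validation-pruned classification tree (n = %d)\n",
              object$n))
  cat(sprintf("selected complexity: %g; %d leaves; %d split variables\n",
              object$selected_complexity, count_leaves(object$root),
              length(object$variables_used)))
  cat("\ncomplexity trace (out-of-fold misclassification, relative):\n")
  print(object$cv_trace, row.names = FALSE)
  invisible(object)
}

#' Predict with a fitted tree
#'
#' Routes each row down the tree (left = split variable 0, right = 1) and
#' emits the leaf's predicted class.
#'
#' @param object A `mood_tree` (or `mood_grown`).
#' @param newdata Matrix or data frame covering the tree's split variables.
#' @param ... Unused.
#' @return Integer 0/1 vector.
#' @export
predict.mood_tree <- function(object, newdata, ...) {
  predict_node(object$root, newdata)
}

#' @export
predict.mood_grown <- function(object, newdata, ...) {
  predict_node(object$root, newdata)
}

predict_node <- function(root, newdata) {
  mat <- if (inherits(newdata, "mood_cohort")) newdata$matrix else as.matrix(newdata)
  vars <- tree_variables(root)
  missing_vars <- setdiff(vars, colnames(mat))
  if (length(missing_vars)) {
    stop("newdata lacks split variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  out <- integer(nrow(mat))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (is.null(node$split_variable)) {
      out[idx] <<- node$predicted_class
      return(invisible(NULL))
    }
    x <- mat[idx, node$split_variable]
    route(node$left, idx[x == 0])
    route(node$right, idx[x != 0])
  }
  route(root, seq_len(nrow(mat)))
  out
}

#' Render a tree as indented text
#'
#' One node per line: predicted class, class prevalence and population share
#' (both to 3 decimals), then the split variable for internal nodes. Child
#' lines are indented and prefixed with the branch label
#' (`[variable=0]` / `[variable=1]`).
#'
#' @param tree A `mood_tree`, `mood_grown`, or a bare node structure.
#' @return A single character string (lines joined by newline).
#' @export
render_tree_text <- function(tree) {
  node <- if (is.list(tree) && !is.null(tree$root)) tree$root else tree
  fmt <- function(nd, indent, label) {
    line <- sprintf("%s%s%d | %.3f | %.3f", indent, label,
                    nd$predicted_class, nd$class_prevalence,
                    nd$population_share)
    if (is.null(nd$split_variable)) return(line)
    line <- paste0(line, " | split ", nd$split_variable)
    c(line,
      fmt(nd$left, paste0(indent, "  "),
          sprintf("[%s=0] ", nd$split_variable)),
      fmt(nd$right, paste0(indent, "  "),
          sprintf("[%s=1] ", nd$split_variable)))
  }
  paste(fmt(node, "", ""), collapse = "\n")
}

node_to_plain <- function(node) {
  out <- list(predicted_class = node$predicted_class,
              class_prevalence = node$class_prevalence,
              population_share = node$population_share)
  if (!is.null(node$split_variable)) {
    out$split_variable <- node$split_variable
    out$left <- node_to_plain(node$left)
    out$right <- node_to_plain(node$right)
  }
  out
}

plain_to_node <- function(x) {
  out <- list(predicted_class = as.integer(x$predicted_class),
              class_prevalence = as.numeric(x$class_prevalence),
              population_share = as.numeric(x$population_share),
              split_variable = NULL, left = NULL, right = NULL)
  if (!is.null(x$split_variable)) {
    out$split_variable <- as.character(x$split_variable)
    out$left <- plain_to_node(x$left)
    out$right <- plain_to_node(x$right)
  }
  out
}

#' Serialize a fitted tree to a structured-text document
#'
#' Trees round-trip through YAML: nested nodes with split variable, class
#' prevalence, population share and predicted class, plus the pruning trace.
#'
#' @param tree A `mood_tree`.
#' @param path Output file path.
#' @return `write_tree`: the path, invisibly. `read_tree`: a `mood_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "mood_tree"))
  doc <- list(root = node_to_plain(tree$root),
              selected_complexity = tree$selected_complexity,
              n = tree$n,
              cv_trace = lapply(seq_len(nrow(tree$cv_trace)), function(i) {
                as.list(tree$cv_trace[i, ])
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  doc <- yaml::read_yaml(path)
  root <- plain_to_node(doc$root)
  trace <- do.call(rbind, lapply(doc$cv_trace, as.data.frame))
  structure(list(root = root, variables_used = tree_variables(root),
                 cv_trace = trace,
                 selected_complexity = as.numeric(doc$selected_complexity),
                 n = as.integer(doc$n)),
            class = "mood_tree")
}
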
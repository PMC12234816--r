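# Independent oracles used across the suite. These deliberately avoid the
# package's rule engine and tree code paths.

all_symptom_ids <- symptom_catalog()$symptom_id

# A named all-zero subject vector covering every catalogued symptom.
zero_subject <- function() {
  stats::setNames(rep(0, length(all_symptom_ids)), all_symptom_ids)
}

subject_with <- function(...) {
  s <- zero_subject()
  ids <- c(...)
  s[ids] <- 1
  s
}

# Item-level definitions per disorder, written out literally (not derived
# from the package's rule objects).
oracle_items <- list(
  mde = list(majors = c("mde_ma1", "mde_ma2"),
             minors = list(c("mde_mi3_1", "mde_mi3_2"),
                           c("mde_mi4_1", "mde_mi4_2"),
                           c("mde_mi5_1", "mde_mi5_2"),
                           c("mde_mi6_1", "mde_mi6_2"),
                           c("mde_mi7_1", "mde_mi7_2"),
                           c("mde_mi8_1", "mde_mi8_2"),
                           "mde_mi9")),
  dys = list(majors = "dys_ma",
             minors = list(c("dys_mi1_1", "dys_mi1_2"),
                           c("mde_mi4_1", "mde_mi4_2"),
                           c("mde_mi6_1", "mde_mi6_2"),
                           "dys_mi4",
                           c("mde_mi8_1", "mde_mi8_2"),
                           "dys_mi6")),
  manic = list(majors = c("man_ma1", "man_ma2", "man_ma3"),
               minors = list(c("man_mi1_1", "man_mi1_2"),
                             "man_mi2",
                             c("man_mi3_1", "man_mi3_2"),
                             c("man_mi4_1", "man_mi4_2"),
                             "man_mi5",
                             c("man_mi6_1", "man_mi6_2"),
                             "man_mi7"))
)

# Truth-table oracle: decide a diagnosis directly from an item-level pattern.
oracle_decision <- function(disorder, major_vals, minor_count) {
  if (disorder == "mde") {
    as.integer(major_vals[1] == 1 && major_vals[2] == 1 && minor_count >= 3)
  } else if (disorder == "dys") {
    as.integer(major_vals[1] == 1 && minor_count >= 2)
  } else {
    ma1 <- major_vals[1]; ma2 <- major_vals[2]; ma3 <- major_vals[3]
    if (ma3 == 0) return(0L)
    if (ma1 + ma2 == 1) as.integer(minor_count >= 3) else
      as.integer(minor_count >= 4)
  }
}

# Realize an item-level pattern as a raw symptom vector. `pick` chooses which
# constituent carries a positive OR-pair item (1, 2, or 3 = both).
realize_pattern <- function(disorder, major_vals, minor_vals, pick = 1L) {
  def <- oracle_items[[disorder]]
  s <- zero_subject()
  s[def$majors] <- major_vals
  for (i in seq_along(def$minors)) {
    if (minor_vals[i] == 1) {
      ids <- def$minors[[i]]
      on <- if (length(ids) == 1L) ids else switch(pick, ids[1], ids[2], ids)
      s[on] <- 1
    }
  }
  s
}

# Enumerate every item-level pattern of a disorder and return a data frame of
# oracle decisions plus the realized symptom matrix.
oracle_truth_table <- function(disorder, pick = 1L) {
  def <- oracle_items[[disorder]]
  nm <- length(def$majors)
  nk <- length(def$minors)
  grid <- as.matrix(expand.grid(rep(list(0:1), nm + nk)))
  subjects <- matrix(0, nrow(grid), length(all_symptom_ids),
                     dimnames = list(NULL, all_symptom_ids))
  decision <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    major_vals <- grid[r, seq_len(nm)]
    minor_vals <- grid[r, nm + seq_len(nk)]
    subjects[r, ] <- realize_pattern(disorder, major_vals, minor_vals, pick)
    decision[r] <- oracle_decision(disorder, major_vals, sum(minor_vals))
  }
  list(subjects = subjects, decision = decision)
}

# Brute-force best binary split by Gini impurity decrease.
gini_count <- function(y) {
  if (!length(y)) return(0)
  p <- mean(y)
  2 * p * (1 - p) * length(y)
}

brute_force_split <- function(x, y) {
  improvements <- vapply(seq_len(ncol(x)), function(j) {
    l <- y[x[, j] == 0]
    r <- y[x[, j] == 1]
    if (!length(l) || !length(r)) return(0)
    gini_count(y) - gini_count(l) - gini_count(r)
  }, numeric(1))
  list(best = which.max(improvements), improvements = improvements)
}

# All pruned subtrees of a node structure (each internal node either kept,
# with all combinations of pruned children, or collapsed to a leaf).
all_subtrees <- function(node) {
  collapsed <- node
  collapsed$split_variable <- NULL
  collapsed$left <- NULL
  collapsed$right <- NULL
  if (is.null(node$split_variable)) return(list(collapsed))
  out <- list(collapsed)
  for (l in all_subtrees(node$left)) {
    for (r in all_subtrees(node$right)) {
      keep <- node
      keep$left <- l
      keep$right <- r
      out <- c(out, list(keep))
    }
  }
  out
}

n_leaves <- function(node) {
  if (is.null(node$split_variable)) return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}

is_subtree_of <- function(small, big) {
  if (is.null(small$split_variable)) return(TRUE)
  if (is.null(big$split_variable)) return(FALSE)
  identical(small$split_variable, big$split_variable) &&
    is_subtree_of(small$left, big$left) &&
    is_subtree_of(small$right, big$right)
}

# Misclassification count of a node structure on data, routing manually.
node_misclass <- function(node, x, y) {
  route <- function(nd, idx) {
    if (!length(idx)) return(0L)
    if (is.null(nd$split_variable)) {
      return(sum(y[idx] != nd$predicted_class))
    }
    v <- x[idx, nd$split_variable]
    route(nd$left, idx[v == 0]) + route(nd$right, idx[v == 1])
  }
  route(node, seq_along(y))
}

# Tiny deterministic feature matrix generator for tree tests.
random_binary_matrix <- function(n, p, prob = 0.5) {
  matrix(rbinom(n * p, 1, prob), n, p,
         dimnames = list(NULL, paste0("v", seq_len(p))))
}
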
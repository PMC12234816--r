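#' Sensitivity and specificity of a binary classifier
#'
#' @param truth Binary 0/1 vector of true diagnosis status.
#' @param predicted Binary 0/1 vector of the same length.
#' @return List with `sensitivity` (TP / (TP + FN)) and `specificity`
#'   (TN / (TN + FP)); `NA` when the corresponding denominator is zero.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  pos <- truth == 1
  list(
    sensitivity = if (any(pos)) mean(predicted[pos] == 1) else NA_real_,
    specificity = if (any(!pos)) mean(predicted[!pos] == 0) else NA_real_
  )
}

# Counter-based per-replicate seed below 2^31, so any single replicate is
# reproducible in isolation from (master_seed, cell, replicate).
derive_seed <- function(master_seed, cell, replicate) {
  m <- 2147483647
  s <- (as.double(master_seed) %% m) * 48271 %% m
  as.integer((s + cell * 100003 + replicate * 613) %% m)
}

#' Cohort-size-aware growth controls
#'
#' The reference node-size floors (minimum split 20, minimum leaf 7) are
#' absolute subject counts tied to the full-scale cohort of 100,000. A
#' scaled-down cohort must scale them proportionally, otherwise the floors
#' regularise relatively harder and rare-diagnosis cells lose the deep
#' branches that encode the count-threshold rule. The complexity floor is
#' already relative to the root risk and stays at 0.01.
#'
#' @param n Cohort size the controls will be used with.
#' @param reference_n Cohort size at which the reference floors apply.
#' @return A [tree_control()].
#' @export
scaled_control <- function(n, reference_n = 1e5) {
  f <- n / reference_n
  tree_control(minsplit = max(2, round(20 * f)),
               minbucket = max(1, round(7 * f)), cp = 0.01)
}

predictor_matrix <- function(cohort, diagnoses, disorder, predictor_set) {
  if (predictor_set == "own") {
    cohort$matrix[, catalog(disorder), drop = FALSE]
  } else {
    others <- setdiff(disorder_tokens, disorder)
    extra <- do.call(cbind, diagnoses[others])
    colnames(extra) <- others
    cbind(cohort$matrix, extra)
  }
}

#' Run one simulation replicate
#'
#' Simulates a cohort, derives all three diagnoses, assembles the predictor
#' matrix (`own`: the disorder's own input symptoms; `extended`: all 34
#' symptoms plus the other two diagnoses), fits a cross-validation-pruned
#' tree to the target diagnosis and scores it on the full cohort. When the
#' diagnosis never occurs in the cohort the accuracy fields are undefined.
#'
#' @param scen A [scenario()]; its seed drives both the cohort draw and the
#'   cross-validation fold assignment.
#' @param disorder One of `"mde"`, `"dys"`, `"manic"`.
#' @param predictor_set `"own"` or `"extended"`.
#' @param control A [tree_control()]; by default [scaled_control()] for the
#'   scenario's cohort size.
#' @param return_tree If `TRUE`, attach the fitted `mood_tree` as attribute
#'   `"tree"` of the returned row.
#' @return One-row data frame: scenario fields, `disorder`, `predictor_set`,
#'   `any_diagnosis`, `diagnosis_prevalence`, `n_variables_used`,
#'   `sensitivity`, `specificity`, and list-column `variables_used`.
#' @export
run_replicate <- function(scen, disorder, predictor_set = "own",
                          control = NULL, return_tree = FALSE) {
  check_disorder(disorder)
  if (is.null(control)) control <- scaled_control(scen$n)
  if (!predictor_set %in% c("own", "extended")) {
    stop("predictor_set must be 'own' or 'extended'", call. = FALSE)
  }
  cohort <- simulate_cohort(scen)
  diagnoses <- lapply(disorder_tokens, function(d) diagnose_cohort(d, cohort))
  names(diagnoses) <- disorder_tokens
  truth <- diagnoses[[disorder]]
  any_dx <- any(truth == 1)
  row <- data.frame(n = scen$n, prevalence = scen$prevalence, phi = scen$phi,
                    seed = scen$seed, disorder = disorder,
                    predictor_set = predictor_set, any_diagnosis = any_dx,
                    diagnosis_prevalence = mean(truth),
                    n_variables_used = NA_integer_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    stringsAsFactors = FALSE)
  row$variables_used <- list(character())
  if (!any_dx) return(row)
  features <- predictor_matrix(cohort, diagnoses, disorder, predictor_set)
  tree <- fit_tree(features, truth, control)
  pred <- predict(tree, features)
  metrics <- confusion_metrics(truth, pred)
  row$n_variables_used <- length(tree$variables_used)
  row$sensitivity <- metrics$sensitivity
  row$specificity <- metrics$specificity
  row$variables_used <- list(tree$variables_used)
  if (return_tree) attr(row, "tree") <- tree
  row
}

#' Run the full simulation grid
#'
#' One replicate per (prevalence x correlation cell) x replicate x disorder x
#' predictor set, with independent per-replicate seeds derived from the
#' master seed so the table is reproducible as a whole and replicate by
#' replicate.
#'
#' @param prevalences,correlations Grid values (defaults: the study grid,
#'   prevalence in 0.05/0.1/0.3/0.5/0.7 and correlation in 0/0.1/0.4/0.7/0.9).
#' @param disorders Subset of `c("mde", "dys", "manic")`.
#' @param predictor_sets Subset of `c("own", "extended")`.
#' @param replicates Replicates per cell.
#' @param n Subjects per cohort.
#' @param master_seed Integer master seed.
#' @param control A [tree_control()]; by default [scaled_control()] for `n`.
#' @param progress If `TRUE`, log each replicate to stderr.
#' @return Data frame of replicate results (one row per replicate run).
#' @export
run_grid <- function(prevalences = c(0.05, 0.1, 0.3, 0.5, 0.7),
                     correlations = c(0, 0.1, 0.4, 0.7, 0.9),
                     disorders = "dys", predictor_sets = "own",
                     replicates = 10, n = 20000, master_seed = 1,
                     control = NULL, progress = FALSE) {
  if (!length(prevalences) || !length(correlations)) {
    stop("grid must be nonempty", call. = FALSE)
  }
  cells <- expand.grid(prevalence = prevalences, correlation = correlations,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list",
                 nrow(cells) * replicates * length(disorders) * length(predictor_sets))
  k <- 0L
  for (cell in seq_len(nrow(cells))) {
    for (rep_i in seq_len(replicates)) {
      seed <- derive_seed(master_seed, cell, rep_i)
      scen <- scenario(n, cells$prevalence[cell], cells$correlation[cell],
                       seed = seed)
      for (d in disorders) {
        for (ps in predictor_sets) {
          if (progress) {
            message(sprintf("cell %d/%d (p=%g, phi=%g) rep %d seed %d %s/%s",
                            cell, nrow(cells), scen$prevalence, scen$phi,
                            rep_i, seed, d, ps))
          }
          k <- k + 1L
          row <- run_replicate(scen, d, ps, control)
          row$replicate <- rep_i
          rows[[k]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

exceedance_thresholds <- c(0.99, 0.98, 0.97, 0.96, 0.95, 0.90, 0.85, 0.80, 0.75)

#' Marginal summary of a grid of replicate results
#'
#' Pools the replicates of a complete prevalence-by-correlation grid over one
#' margin and computes, per margin level: replicate counts, count with any
#' diagnosis, average/max/min/median number of split variables (over
#' replicates with any diagnosis), average/max/min sensitivity and
#' specificity (over replicates with defined metrics), the proportion of all
#' replicates whose `min(sensitivity, specificity)` exceeds each threshold in
#' 0.99...0.75, and per-variable usage frequencies.
#'
#' @param results A [run_grid()] table for a single disorder and predictor
#'   set.
#' @param margin `"prevalence"` or `"correlation"`.
#' @return Data frame with statistics as rows and margin levels as columns.
#' @export
summarize_grid <- function(results, margin = c("prevalence", "correlation")) {
  margin <- match.arg(margin)
  if (length(unique(results$disorder)) != 1L ||
      length(unique(results$predictor_set)) != 1L) {
    stop("results must cover exactly one disorder and predictor set",
         call. = FALSE)
  }
  have <- unique(results[, c("prevalence", "phi")])
  want <- expand.grid(prevalence = sort(unique(results$prevalence)),
                      phi = sort(unique(results$phi)),
                      KEEP.OUT.ATTRS = FALSE)
  missing_cells <- want[!paste(want$prevalence, want$phi) %in%
                          paste(have$prevalence, have$phi), , drop = FALSE]
  if (nrow(missing_cells)) {
    stop("incomplete grid; missing cells: ",
         paste(sprintf("(p=%g, phi=%g)", missing_cells$prevalence,
                       missing_cells$phi), collapse = ", "), call. = FALSE)
  }
  key <- if (margin == "prevalence") results$prevalence else results$phi
  levels_ <- sort(unique(key))
  all_vars <- sort(unique(unlist(results$variables_used)))
  col_stats <- function(lev) {
    r <- results[key == lev, ]
    dx <- r[r$any_diagnosis, ]
    ok <- dx[!is.na(dx$sensitivity) & !is.na(dx$specificity), ]
    min_ss <- pmin(r$sensitivity, r$specificity)
    min_ss[is.na(min_ss)] <- -Inf  # undefined never exceeds a threshold
    usage <- vapply(all_vars, function(v) {
      sum(vapply(r$variables_used, function(u) v %in% u, logical(1)))
    }, numeric(1))
    c("Number of simulations" = nrow(r),
      "Number of simulations with any diagnosis" = nrow(dx),
      "Average number of variables for prediction" = mean(dx$n_variables_used),
      "Max number of variables for prediction" = max_or_na(dx$n_variables_used),
      "Min number of variables for prediction" = min_or_na(dx$n_variables_used),
      "Median number of variables for prediction" = stats::median(dx$n_variables_used),
      "Average sensitivities" = mean(ok$sensitivity),
      "Average specificities" = mean(ok$specificity),
      "Max sensitivities" = max_or_na(ok$sensitivity),
      "Max specificities" = max_or_na(ok$specificity),
      "Min sensitivities" = min_or_na(ok$sensitivity),
      "Min specificities" = min_or_na(ok$specificity),
      stats::setNames(vapply(exceedance_thresholds,
                             function(thr) mean(min_ss > thr), numeric(1)),
                      sprintf("Proportion of simulations with >%.2f sen/spe",
                              exceedance_thresholds)),
      stats::setNames(usage, all_vars))
  }
  cols <- lapply(levels_, col_stats)
  out <- as.data.frame(cols,
                       col.names = sprintf("%s=%g", margin, levels_),
                       check.names = FALSE)
  out
}

max_or_na <- function(x) if (length(x)) max(x) else NA_real_
min_or_na <- function(x) if (length(x)) min(x) else NA_real_

#' Per-cell minima of diagnostic accuracy
#'
#' For each prevalence-by-correlation cell: the worst `min(sensitivity,
#' specificity)` across its replicates, the largest number of variables any
#' replicate used, and the union of variables used — the matrix view of
#' where a simplified rule still meets a given accuracy floor.
#'
#' @param results A [run_grid()] table for one disorder and predictor set.
#' @return Data frame with one row per cell.
#' @export
cell_minima <- function(results) {
  cells <- unique(results[, c("prevalence", "phi")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    r <- results[results$prevalence == cells$prevalence[i] &
                   results$phi == cells$phi[i], ]
    ok <- !is.na(r$sensitivity) & !is.na(r$specificity)
    data.frame(prevalence = cells$prevalence[i], phi = cells$phi[i],
               replicates = nrow(r), with_any_diagnosis = sum(r$any_diagnosis),
               min_sens_spec = if (any(ok)) min(pmin(r$sensitivity[ok],
                                                     r$specificity[ok])) else NA_real_,
               max_n_variables = max_or_na(r$n_variables_used[r$any_diagnosis]),
               variables = paste(sort(unique(unlist(r$variables_used))),
                                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$prevalence, out$phi), ]
}
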
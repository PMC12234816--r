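#' Simulation scenario
#'
#' Bundle of the parameters defining one simulated population: cohort size,
#' uniform marginal symptom prevalence, target pairwise phi correlation
#' within each symptom block, and the RNG seed.
#'
#' @param n Number of subjects (>= 1).
#' @param prevalence Marginal probability of each symptom, in (0, 1).
#' @param phi Target pairwise Pearson correlation between symptom indicators
#'   within a block, in `[0, 1)`. Symptoms in different blocks (depressive vs
#'   manic) are independent.
#' @param seed Integer RNG seed.
#' @return An object of class `mood_scenario`.
#' @examples
#' scenario(1000, 0.3, 0.1, seed = 1)
#' @export
scenario <- function(n, prevalence, phi, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a single count >= 1", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be a single probability in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi >= 1) {
    stop("phi must be a single correlation in [0, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n), prevalence = prevalence, phi = phi,
                 seed = as.integer(seed)),
            class = "mood_scenario")
}

#' @export
print.mood_scenario <- function(x, ...) {
  cat(sprintf("scenario: n=%d, prevalence=%g, phi=%g, seed=%d\n",
              x$n, x$prevalence, x$phi, x$seed))
  invisible(x)
}

# Phi correlation between two binaries obtained by thresholding a standard
# bivariate normal with correlation rho at the (1 - p) quantile.
phi_from_latent <- function(rho, p) {
  if (rho == 0) return(0)
  if (rho >= 1) return(1)
  t <- stats::qnorm(1 - p)
  p11 <- stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((rho * x - t) / sqrt(1 - rho^2))
  }, t, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
  (p11 - p^2) / (p * (1 - p))
}

#' Calibrate the latent Gaussian correlation for a target phi
#'
#' Finds the correlation `rho` of a standard bivariate normal such that
#' dichotomizing both coordinates at the `(1 - prevalence)` quantile yields
#' binary variables with Pearson (phi) correlation `target_phi`. Solved by
#' root finding on the orthant probability, computed by 1-D numerical
#' integration; the result matches `target_phi` to within 1e-6 and is
#' monotone in it. For equal marginals any `target_phi` in `[0, 1)` is
#' feasible.
#'
#' @param prevalence Marginal probability in (0, 1).
#' @param target_phi Target phi correlation in `[0, 1)`.
#' @return Latent correlation in `[0, 1)`.
#' @examples
#' calibrate_latent_correlation(0.5, 1 / 3)  # 0.5 (= sin(pi * phi / 2))
#' @export
calibrate_latent_correlation <- function(prevalence, target_phi) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(target_phi) || length(target_phi) != 1L ||
      target_phi < 0 || target_phi >= 1) {
    stop("target_phi must be in [0, 1)", call. = FALSE)
  }
  if (target_phi == 0) return(0)
  stats::uniroot(function(r) phi_from_latent(r, prevalence) - target_phi,
                 lower = 1e-12, upper = 1 - 1e-10, tol = 1e-12)$root
}

#' Simulate a cohort of correlated binary symptoms
#'
#' Draws `n` subjects with all 34 catalogued symptoms from a Gaussian copula:
#' within each block (20 depressive/dysthymic symptoms, 14 manic symptoms) the
#' latent normals share an exchangeable correlation calibrated so the binary
#' indicators attain the scenario's target phi; the two blocks are
#' independent. The exchangeable latent structure is realised exactly through
#' one common factor per block, `X_ij = sqrt(rho) W_block + sqrt(1 - rho)
#' E_ij`, thresholded at the `(1 - prevalence)` standard-normal quantile.
#'
#' @param scen A [scenario()].
#' @return An object of class `mood_cohort`: list with `matrix` (n x 34
#'   integer 0/1, columns named by symptom_id), `scenario`, and `block_map`.
#' @examples
#' coh <- simulate_cohort(scenario(500, 0.3, 0.1, seed = 7))
#' dim(coh$matrix)
#' @export
simulate_cohort <- function(scen) {
  stopifnot(inherits(scen, "mood_scenario"))
  blocks <- symptom_blocks()
  rho <- calibrate_latent_correlation(scen$prevalence, scen$phi)
  thr <- stats::qnorm(1 - scen$prevalence)
  n <- scen$n
  mat <- matrix(0L, n, length(blocks), dimnames = list(NULL, names(blocks)))
  set.seed(scen$seed)
  for (b in c("depressive", "manic")) {
    ids <- names(blocks)[blocks == b]
    k <- length(ids)
    w <- stats::rnorm(n)
    lat <- sqrt(rho) * w + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
    mat[, ids] <- (lat > thr) + 0L
  }
  structure(list(matrix = mat, scenario = scen, block_map = blocks),
            class = "mood_cohort")
}

#' @export
print.mood_cohort <- function(x, ...) {
  cat(sprintf("mood_cohort: %d subjects x %d symptoms (prevalence=%g, phi=%g, seed=%d)\n",
              nrow(x$matrix), ncol(x$matrix),
              x$scenario$prevalence, x$scenario$phi, x$scenario$seed))
  invisible(x)
}

mean_offdiag <- function(cmat) {
  ok <- upper.tri(cmat) & is.finite(cmat)
  if (!any(ok)) return(NA_real_)
  mean(cmat[ok])
}

#' Empirical prevalence and correlation summaries of a cohort
#'
#' Per-column prevalence plus the mean pairwise Pearson (phi) correlation
#' within each block and across blocks. Constant columns have undefined
#' correlations; they are flagged and excluded from the means.
#'
#' @param cohort A `mood_cohort` (or 0/1 matrix with symptom columns).
#' @return List with `prevalence` (named vector), `mean_phi_depressive`,
#'   `mean_phi_manic`, `mean_phi_cross`, and `degenerate` (ids of constant
#'   columns).
#' @export
empirical_stats <- function(cohort) {
  mat <- if (inherits(cohort, "mood_cohort")) cohort$matrix else as.matrix(cohort)
  if (nrow(mat) < 1L) stop("cohort is empty", call. = FALSE)
  blocks <- symptom_blocks()[colnames(mat)]
  prev <- colMeans(mat)
  degenerate <- colnames(mat)[prev %in% c(0, 1)]
  live <- setdiff(colnames(mat), degenerate)
  dep <- intersect(live, names(blocks)[blocks == "depressive"])
  man <- intersect(live, names(blocks)[blocks == "manic"])
  mean_phi <- function(ids) {
    if (length(ids) < 2L) return(NA_real_)
    mean_offdiag(stats::cor(mat[, ids]))
  }
  cross <- if (length(dep) && length(man)) {
    mean(stats::cor(mat[, dep, drop = FALSE], mat[, man, drop = FALSE]))
  } else NA_real_
  list(prevalence = prev,
       mean_phi_depressive = mean_phi(dep),
       mean_phi_manic = mean_phi(man),
       mean_phi_cross = cross,
       degenerate = degenerate)
}

#' Write / read a cohort as a flat delimited table
#'
#' The symptom matrix is written as a tab-separated table (header =
#' symptom_ids, one row per subject) with the scenario recorded in a YAML
#' sidecar (`<path>.scenario.yaml`), so cohorts can be inspected or rebuilt
#' outside the package.
#'
#' @param cohort A `mood_cohort`.
#' @param path Output file path for the table.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: a
#'   `mood_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mood_cohort"))
  utils::write.table(cohort$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(cohort$scenario), paste0(path, ".scenario.yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  mat <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  storage.mode(mat) <- "integer"
  sc <- yaml::read_yaml(paste0(path, ".scenario.yaml"))
  structure(list(matrix = mat,
                 scenario = scenario(sc$n, sc$prevalence, sc$phi, sc$seed),
                 block_map = symptom_blocks()),
            class = "mood_cohort")
}
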
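# Gaussian-copula athlete generator: quartile-matched marginals with a
# planted latent correlation structure, plus the nearest-correlation repair
# needed to make hand-specified targets feasible.

#' Model presets: registry plus marginal quartile targets
#'
#' The registry for a running condition together with the published cohort
#' quartiles of each variable, which the synthetic generator uses as marginal
#' targets. `free_model_preset()` has 18 variables, `tethered_model_preset()`
#' 23 (the tethered condition gets its own quartiles for the shared variables
#' plus the five biomechanics outputs).
#'
#' @return A tibble with columns `name`, `label`, `unit`, `category`, `q1`,
#'   `median`, `q3`.
#' @export
free_model_preset <- function() variable_table("free")

#' @rdname free_model_preset
#' @export
tethered_model_preset <- function() variable_table("tethered")

#' Nearest valid correlation matrix
#'
#' Repairs a hand-specified symmetric target into the nearest correlation
#' matrix under the Frobenius norm, by Higham's alternating projections with
#' Dykstra correction: alternately project onto the positive-semidefinite
#' cone (eigenvalue clipping) and the unit-diagonal affine set. Already-PSD
#' input is returned unchanged. Needed because planted structures written by
#' hand (e.g. one hub strongly tied to several mutually uncorrelated
#' neighbours) are often not positive semidefinite.
#'
#' @param target Symmetric matrix with unit diagonal and entries in
#'   \[-1, 1\].
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap.
#' @return A symmetric unit-diagonal matrix with smallest eigenvalue
#'   >= -1e-8.
#' @export
nearest_correlation_repair <- function(target, tol = 1e-10, max_iter = 500) {
  if (!is.matrix(target) || nrow(target) != ncol(target) ||
      max(abs(target - t(target))) > 1e-8) {
    abort("`target` must be a symmetric square matrix.",
          class = "sprintnet_error_bad_input")
  }
  if (any(abs(target) > 1 + 1e-12) || any(abs(diag(target) - 1) > 1e-12)) {
    abort("`target` must have unit diagonal and entries in [-1, 1].",
          class = "sprintnet_error_bad_input")
  }
  sym <- function(m) (m + t(m)) / 2
  if (min(eigen(sym(target), symmetric = TRUE, only.values = TRUE)$values) >= -1e-8) {
    return(target)
  }
  Y <- target
  S <- matrix(0, nrow(target), ncol(target))
  for (i in seq_len(max_iter)) {
    R <- Y - S
    e <- eigen(sym(R), symmetric = TRUE)
    X <- e$vectors %*% diag(pmax(e$values, 0), nrow(target)) %*% t(e$vectors)
    X <- sym(X)
    S <- X - R
    Y_new <- X
    diag(Y_new) <- 1
    Y_new <- pmin(pmax(Y_new, -1), 1)
    if (max(abs(Y_new - Y)) < tol) {
      Y <- Y_new
      break
    }
    Y <- Y_new
  }
  dimnames(Y) <- dimnames(target)
  Y
}

#' Planted correlation structures
#'
#' Convenience builders for generator scenarios. `structure_identity()` is
#' mutual independence. `structure_hub()` plants one designated hub variable
#' with elevated correlation `hub_c` to each named neighbour and `base_c`
#' everywhere else; the result is a *target* — [generate_athletes()] repairs
#' it to the nearest valid correlation matrix, which shrinks infeasibly
#' strong hub ties.
#'
#' @param vars Character vector of variable names (e.g. a registry's
#'   `name` column).
#' @param hub Name of the hub variable.
#' @param neighbors Names of the hub's strongly-tied neighbours.
#' @param hub_c Target |c| between hub and each neighbour.
#' @param base_c Target |c| between every other pair.
#' @return A symmetric unit-diagonal matrix over `vars`.
#' @export
structure_identity <- function(vars) {
  diag(1, length(vars)) |> `dimnames<-`(list(vars, vars))
}

#' @rdname structure_identity
#' @export
structure_hub <- function(vars, hub, neighbors, hub_c = 0.85, base_c = 0) {
  if (!hub %in% vars || !all(neighbors %in% vars) || hub %in% neighbors) {
    abort("hub and neighbors must be distinct registry variables.",
          class = "sprintnet_error_bad_input")
  }
  m <- matrix(base_c, length(vars), length(vars), dimnames = list(vars, vars))
  diag(m) <- 1
  m[hub, neighbors] <- hub_c
  m[neighbors, hub] <- hub_c
  m
}

# Piecewise-linear quantile function through (0.25, q1), (0.5, median),
# (0.75, q3), with linear tail extrapolation from the adjacent segment and a
# floor at zero (no negative times, masses or rates).
quantile_transform <- function(u, q1, med, q3) {
  lo_slope <- (med - q1) / 0.25
  hi_slope <- (q3 - med) / 0.25
  # below the median the segment through (0.25, q1)-(0.5, med) and its tail
  # extrapolation share one linear expression; likewise above the median
  x <- ifelse(u < 0.5, med + (u - 0.5) * lo_slope, med + (u - 0.5) * hi_slope)
  pmax(x, 0)
}

#' Generate a synthetic athlete table
#'
#' Draws correlated latent standard normals from a planted correlation
#' structure (Gaussian copula) and pushes each margin through a
#' piecewise-linear quantile function interpolating the preset's quartile
#' targets (0.25 -> q1, 0.5 -> median, 0.75 -> q3) with linear tail
#' extrapolation, floored at zero. Rank correlations of the output match the
#' copula exactly; Pearson correlations are attenuated slightly by the
#' nonlinear margins. The planted structure is repaired to the nearest valid
#' correlation matrix before sampling.
#'
#' A degenerate margin (q1 = q3) yields a constant column; if such a
#' variable carries planted nonzero correlation, a warning is raised because
#' that correlation cannot survive the transform.
#'
#' @param preset A preset tibble from [free_model_preset()] /
#'   [tethered_model_preset()], or any registry with `q1`, `median`, `q3`
#'   columns.
#' @param structure Optional planted correlation target over the preset's
#'   variables (default: identity, i.e. independence).
#' @param n Number of subjects (>= 3). The study cohort size is 8; property
#'   and recovery checks use 200–10000.
#' @param seed Integer seed; the same seed always yields the same table.
#' @return An `athlete_table` tibble of `n` subjects.
#' @export
generate_athletes <- function(preset, structure = NULL, n = 8, seed = NULL) {
  if (!all(c("q1", "median", "q3") %in% names(preset))) {
    abort("`preset` needs q1/median/q3 marginal targets.",
          class = "sprintnet_error_bad_input")
  }
  registry <- validate_registry(preset)
  if (any(preset$q1 > preset$median) || any(preset$median > preset$q3)) {
    abort("marginal targets must satisfy q1 <= median <= q3.",
          class = "sprintnet_error_bad_input")
  }
  if (n < 3) {
    abort("at least 3 subjects are required.",
          class = "sprintnet_error_too_few_subjects")
  }
  p <- nrow(registry)
  if (is.null(structure)) structure <- structure_identity(registry$name)
  if (!is.null(dimnames(structure))) {
    if (!setequal(rownames(structure), registry$name)) {
      abort("structure variables do not match the preset.",
            class = "sprintnet_error_mismatch")
    }
    structure <- structure[registry$name, registry$name]
  }
  if (nrow(structure) != p) {
    abort("structure dimension does not match the preset.",
          class = "sprintnet_error_mismatch")
  }
  R <- nearest_correlation_repair(structure)
  degenerate <- preset$q1 == preset$q3
  if (any(degenerate)) {
    off <- abs(R - diag(1, p))
    planted <- apply(off, 1, max) > 1e-8
    bad <- degenerate & planted
    if (any(bad)) {
      warn(paste0(
        "degenerate marginal(s) with planted correlation emitted as constant column(s): ",
        paste(registry$name[bad], collapse = ", ")
      ))
    }
  }
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  Z <- with_seed(seed, matrix(rnorm(n * p), nrow = n, ncol = p)) %*% A
  U <- stats::pnorm(Z)
  X <- vapply(seq_len(p), function(j) {
    quantile_transform(U[, j], preset$q1[j], preset$median[j], preset$q3[j])
  }, numeric(n))
  colnames(X) <- registry$name
  df <- dplyr::bind_cols(tibble(subject = paste0("S", seq_len(n))),
                         as_tibble(as.data.frame(X)))
  as_athlete_table(df, dplyr::select(registry, "name", "label", "unit", "category"))
}
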
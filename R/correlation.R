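# Pairwise correlation over subjects and the three-way strength
# classification that decides which pairs become network links.

#' Pairwise correlation matrix of an athlete table
#'
#' Computes all pairwise correlations between variables across subjects.
#' Pearson is the default (it gave the best fit for both running conditions);
#' Spearman is retained as a rank-based alternative. No multiple-testing
#' correction is applied: link selection downstream thresholds on effect size
#' |c|, not on p-values — a deliberate fidelity choice, noted as a statistical
#' limitation in the vignette.
#'
#' @param table An `athlete_table`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `corr_matrix` object: the ordered variable names, the symmetric
#'   coefficient matrix, and the method tag. `tidy()` it for a long
#'   per-pair tibble with strength classes.
#' @export
correlate_athletes <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- athlete_matrix(table)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort(
      paste0("zero-variance column(s): ",
             paste(colnames(m)[sds == 0], collapse = ", ")),
      class = "sprintnet_error_zero_variance"
    )
  }
  r <- cor(m, method = method)
  # guard against eps-scale excursions outside [-1, 1]
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  structure(
    list(variables = colnames(m), r = r, method = method,
         registry = attr(table, "registry")),
    class = "corr_matrix"
  )
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix: %d variables, method = %s>\n",
              length(x$variables), x$method))
  invisible(x)
}

#' @export
as.matrix.corr_matrix <- function(x, ...) x$r

#' Classify correlation strength
#'
#' Maps a coefficient to the three-way partition used for link selection:
#' weak if |c| < 0.3, moderate if 0.3 <= |c| < 0.7, high if |c| >= 0.7.
#' The classes are sign-symmetric and partition \[-1, 1\] exactly.
#'
#' @param c Numeric vector of coefficients in \[-1, 1\].
#' @return An ordered factor with levels weak < moderate < high.
#' @examples
#' classify_correlation(c(0.1, -0.3, 0.877820878967058))
#' @export
classify_correlation <- function(c) {
  if (any(!is.finite(c)) || any(abs(c) > 1 + 1e-12)) {
    abort("coefficients must lie in [-1, 1].",
          class = "sprintnet_error_bad_coefficient")
  }
  a <- abs(c)
  cls <- ifelse(a >= 0.7, "high", ifelse(a >= 0.3, "moderate", "weak"))
  factor(cls, levels = c("weak", "moderate", "high"), ordered = TRUE)
}

#' @method tidy corr_matrix
#' @export
tidy.corr_matrix <- function(x, ...) {
  p <- length(x$variables)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var_a = x$variables[idx[, 1]],
    var_b = x$variables[idx[, 2]],
    method = x$method,
    c = x$r[idx],
    class = classify_correlation(x$r[idx])
  )
}

#' Export a correlation matrix
#'
#' `"long"` writes the per-pair TSV (var_a, var_b, method, c, class);
#' `"matrix"` writes the square coefficient matrix as CSV with a leading
#' `variable` column.
#'
#' @param x A `corr_matrix`.
#' @param path Output path.
#' @param format `"long"` or `"matrix"`.
#' @export
write_correlations <- function(x, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "long") {
    readr::write_tsv(tidy(x), path)
  } else {
    df <- as.data.frame(x$r)
    df <- dplyr::bind_cols(tibble(variable = x$variables), df)
    readr::write_csv(df, path)
  }
  invisible(path)
}
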
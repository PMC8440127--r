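gec_predictors <- function() {
  c("sugar_utilization", "growth_15C", "growth_45C",
    "microaerobic", "facultatively_anaerobic", "obligate_anaerobic",
    "gc_content", "n_rrna", "n_trna", "n_crispr")
}

#' Build the standardized design matrix for the feature regressions
#'
#' Expands the strain table into the ten explanatory variables used by the
#' feature regressions: the sugar-utilization value, 0/1 dummies for
#' growth at 15\eqn{^\circ}C and 45\eqn{^\circ}C, three dummies for the
#' oxygen-tolerance classes, and the four genomic features (GC content,
#' rRNA, tRNA, CRISPR counts). Missing cells are replaced by the column
#' mean over the non-missing strains, and every predictor is then
#' Z-scored (mean 0, sample sd 1). Imputation precedes scaling.
#'
#' Note that when no oxygen class is missing the three class dummies sum
#' to 1 in every row and the design is exactly collinear with the
#' intercept; mean imputation does not break this (imputed rows still sum
#' to 1). See [fit_ols()] for how rank deficiency is handled, or set
#' `drop_reference_class = TRUE` to drop the `obligate_anaerobic` dummy.
#'
#' @param strains Strain table.
#' @param drop_reference_class Drop the `obligate_anaerobic` dummy to get
#'   a full-rank design (default `FALSE`: all three classes enter, as in
#'   the original ten-variable specification).
#' @return List of class `gec_design`: `X` (standardized matrix),
#'   `imputed` (named count of imputed cells per predictor), and
#'   `center`/`scale` used for Z-scoring.
#' @export
build_design <- function(strains, drop_reference_class = FALSE) {
  ox <- strains$oxygen_class
  raw <- data.frame(
    sugar_utilization = strains$sugar_utilization,
    growth_15C = as.numeric(strains$growth_15C),
    growth_45C = as.numeric(strains$growth_45C),
    microaerobic = ifelse(is.na(ox), NA_real_, as.numeric(ox == "microaerobic")),
    facultatively_anaerobic = ifelse(is.na(ox), NA_real_,
                                     as.numeric(ox == "facultatively_anaerobic")),
    obligate_anaerobic = ifelse(is.na(ox), NA_real_,
                                as.numeric(ox == "obligate_anaerobic")),
    gc_content = strains$gc_content,
    n_rrna = as.numeric(strains$n_rrna),
    n_trna = as.numeric(strains$n_trna),
    n_crispr = as.numeric(strains$n_crispr)
  )
  if (drop_reference_class) raw$obligate_anaerobic <- NULL
  all_missing <- vapply(raw, function(v) all(is.na(v)), logical(1))
  if (any(all_missing))
    abort("predictor(s) entirely missing: %s",
          paste(names(raw)[all_missing], collapse = ", "))
  imputed <- vapply(raw, function(v) sum(is.na(v)), integer(1))
  for (col in names(raw)) {
    v <- raw[[col]]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    raw[[col]] <- v
  }
  zero_var <- vapply(raw, function(v) stats::sd(v) == 0, logical(1))
  if (any(zero_var))
    abort("zero-variance predictor(s) after imputation: %s",
          paste(names(raw)[zero_var], collapse = ", "))
  X <- scale(as.matrix(raw))
  structure(list(X = X[, , drop = FALSE],
                 imputed = imputed,
                 center = attr(X, "scaled:center"),
                 scale = attr(X, "scaled:scale")),
            class = "gec_design")
}

#' Ordinary least squares with standardized predictors
#'
#' Fits `y ~ intercept + X` by least squares via the singular value
#' decomposition. For a full-rank design this is textbook OLS; for a
#' rank-deficient design (e.g. all three oxygen dummies entered together)
#' the minimum-norm least-squares solution is returned, with residual
#' degrees of freedom `n - rank` and coefficient covariance
#' \eqn{\hat\sigma^2 (X'X)^+} — the behaviour of the major Python
#' statistics stack's OLS, which this stage mirrors so that the ten-
#' variable specification can be fit as published. Set
#' `singular = "error"` to refuse rank-deficient designs instead.
#'
#' @param design A `gec_design` from [build_design()], or a plain numeric
#'   matrix of predictors (no intercept column).
#' @param y Numeric response vector.
#' @param objective Label for the response (e.g. `"genome_size"`).
#' @param singular `"minnorm"` (default) or `"error"`.
#' @param alpha Significance threshold used for starring coefficients in
#'   the printed summary (default 0.05).
#' @return Object of class `gec_ols`: coefficients (including
#'   `(Intercept)`), `p_values`, `r_squared`, `r`, `n_obs`, `rank`,
#'   `df_residual`, `fitted`, `residuals`, `imputed` counts.
#' @export
fit_ols <- function(design, y, objective = "y",
                    singular = c("minnorm", "error"), alpha = 0.05) {
  singular <- match.arg(singular)
  X <- if (inherits(design, "gec_design")) design$X else as.matrix(design)
  if (anyNA(y)) abort("objective variable '%s' has missing values", objective)
  n <- length(y)
  if (nrow(X) != n) abort("design and objective lengths differ")
  p <- ncol(X)
  if (n <= p + 1) abort("need more observations (%d) than predictors + 1 (%d)",
                        n, p + 1)
  Xi <- cbind(`(Intercept)` = 1, X)
  sv <- svd(Xi)
  tol <- max(dim(Xi)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (r < ncol(Xi) && singular == "error")
    abort(paste0("design is rank-deficient (rank %d < %d columns); the three ",
                 "oxygen dummies plus the intercept are exactly collinear — ",
                 "drop one class (drop_reference_class = TRUE) or use ",
                 "singular = 'minnorm'"), r, ncol(Xi))
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  beta <- sv$v %*% (d_inv * crossprod(sv$u, y))
  beta <- drop(beta)
  names(beta) <- colnames(Xi)
  fitted <- drop(Xi %*% beta)
  resid <- y - fitted
  df_resid <- n - r
  rss <- sum(resid^2)
  sigma2 <- rss / df_resid
  # (X'X)^+ = V D^-2 V'
  xtx_pinv <- sv$v %*% (d_inv^2 * t(sv$v))
  se <- sqrt(pmax(sigma2 * diag(xtx_pinv), 0))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_resid)
  names(pval) <- names(beta)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  structure(list(objective = objective,
                 coefficients = beta,
                 std_errors = stats::setNames(se, names(beta)),
                 p_values = pval,
                 r_squared = r2,
                 r = sqrt(max(r2, 0)),
                 n_obs = n, rank = r, df_residual = df_resid,
                 sigma = sqrt(sigma2),
                 fitted = fitted, residuals = resid,
                 alpha = alpha,
                 imputed = if (inherits(design, "gec_design"))
                   design$imputed else NULL),
            class = "gec_ols")
}

#' @export
print.gec_ols <- function(x, ...) {
  cat(sprintf("gec_ols fit: objective = %s\n", x$objective))
  cat(sprintf("  n = %d, rank = %d, R^2 = %.4f, R = %.4f\n",
              x$n_obs, x$rank, x$r_squared, x$r))
  invisible(x)
}

#' @export
summary.gec_ols <- function(object, ...) {
  keep <- names(object$coefficients) != "(Intercept)"
  tab <- data.frame(predictor = names(object$coefficients)[keep],
                    coefficient = unname(object$coefficients[keep]),
                    std_error = unname(object$std_errors[keep]),
                    p_value = unname(object$p_values[keep]),
                    significant = unname(object$p_values[keep]) <= object$alpha,
                    stringsAsFactors = FALSE)
  out <- list(objective = object$objective, table = tab,
              r_squared = object$r_squared, r = object$r,
              n_obs = object$n_obs, rank = object$rank,
              imputed = object$imputed)
  class(out) <- "summary.gec_ols"
  out
}

#' @export
print.summary.gec_ols <- function(x, ...) {
  cat(sprintf("Standardized multiple regression — objective: %s\n", x$objective))
  tab <- x$table
  tab$coefficient <- sprintf("%+.4f%s", tab$coefficient,
                             ifelse(tab$significant, " *", ""))
  tab$std_error <- sprintf("%.4f", tab$std_error)
  tab$p_value <- sprintf("%.4g", tab$p_value)
  print(tab[c("predictor", "coefficient", "std_error", "p_value")],
        row.names = FALSE)
  cat(sprintf("R^2 = %.4f, R = %.4f, n = %d (rank %d)\n",
              x$r_squared, x$r, x$n_obs, x$rank))
  if (!is.null(x$imputed) && any(x$imputed > 0))
    cat("mean-imputed cells:",
        paste(sprintf("%s=%d", names(x$imputed)[x$imputed > 0],
                      x$imputed[x$imputed > 0]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.gec_ols <- function(object, ...) object$coefficients

#' @export
residuals.gec_ols <- function(object, ...) object$residuals

#' @export
fitted.gec_ols <- function(object, ...) object$fitted

#' Predict from a fitted standardized regression
#' @param object A `gec_ols` fit.
#' @param newdata Matrix of predictors on the standardized scale (same
#'   columns as the design); omit for fitted values.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.gec_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, as.matrix(newdata))
  drop(X %*% object$coefficients)
}

#' Coefficient bar plot of a fitted regression
#'
#' Horizontal bars of the standardized coefficients, starred when
#' p <= alpha — the usual way these feature regressions are displayed.
#'
#' @param x A `gec_ols` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.gec_ols <- function(x, ...) {
  s <- summary(x)$table
  labels <- paste0(s$predictor, ifelse(s$significant, " *", ""))
  op <- graphics::par(mar = c(4, 11, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(s$coefficient), names.arg = rev(labels), horiz = TRUE,
                    las = 1, xlab = "standardized coefficient",
                    main = x$objective, ...)
  graphics::abline(v = 0)
  invisible(x)
}

#' Fit the two published feature regressions
#'
#' Fits genome size, and then the HGT-derived CDS count, on the identical
#' ten-predictor standardized design (six phenotypic + four genomic
#' features) with mean imputation of missing phenotype cells.
#'
#' @param strains Strain table.
#' @param drop_reference_class Passed to [build_design()].
#' @param singular Passed to [fit_ols()].
#' @return Named list with `gec_ols` fits `genome_size` and `n_hgt_cds`.
#' @export
run_feature_regressions <- function(strains, drop_reference_class = FALSE,
                                  singular = "minnorm") {
  design <- build_design(strains, drop_reference_class = drop_reference_class)
  list(genome_size = fit_ols(design, strains$genome_size,
                             objective = "genome_size", singular = singular),
       n_hgt_cds = fit_ols(design, strains$n_hgt_cds,
                           objective = "n_hgt_cds", singular = singular))
}
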
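#' Electrode inclusion rule for statistical analysis
#'
#' An electrode enters the regression analyses only when it was visible on
#' at least one OCT B-scan and its perceptual threshold is strictly below
#' 677 uA (the device compliance cutoff). When no perceptual threshold was
#' measured (`NA`), visibility alone decides, so purely simulated patients
#' can still be processed.
#'
#' @param site an [electrode_site()] or a list/row with `visible` and
#'   `threshold_uA`.
#' @param cutoff_uA the threshold cutoff (default 677).
#' @return logical.
#' @export
include_electrode <- function(site, cutoff_uA = 677) {
  vis <- isTRUE(as.logical(site$visible))
  thr <- site$threshold_uA
  if (is.null(thr) || is.na(thr)) return(vis)
  vis && thr < cutoff_uA
}

#' Ordinary least squares with closed-form inference
#'
#' Normal-equations OLS with an intercept, returning coefficient standard
#' errors and t-tests, the coefficient of determination R^2, and the
#' overall F-test p-value. Single-predictor input reproduces simple linear
#' regression.
#'
#' @param X data frame or matrix of predictors (no intercept column).
#' @param y response vector.
#' @return A `regression_result`: `coefficients` (term, estimate, se, t, p),
#'   `r_squared`, `f_stat`, `p_value`, `n`, `df_residual`.
#' @examples
#' x <- 1:10
#' ols_fit(data.frame(x = x), 2 * x)$coefficients$estimate  # 0, 2
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > number of predictors + 1")
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  XtX <- crossprod(M)
  Xty <- crossprod(M, y)
  beta <- drop(solve(XtX, Xty))
  fitted <- drop(M %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df_res <- n - p - 1
  sigma2 <- rss / df_res
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  f <- if (rss > 0) ((tss - rss) / p) / sigma2 else Inf
  pf_val <- if (is.finite(f)) pf(f, p, df_res, lower.tail = FALSE) else 0
  structure(list(
    coefficients = data.frame(term = colnames(M), estimate = beta, se = se,
                              t = tval, p = pval, row.names = NULL,
                              stringsAsFactors = FALSE),
    r_squared = r2, f_stat = f, p_value = pf_val, n = n,
    df_residual = df_res, fitted = fitted, residuals = resid),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R^2 = %.4f, p = %.3g\n",
              x$n, x$r_squared, x$p_value))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regress perceptual thresholds on model predictions
#'
#' Matches electrode labels between the model's per-electrode minimum
#' activation thresholds and the measured perceptual thresholds of included
#' electrodes, then regresses measured on predicted, reporting R^2 and
#' significance at alpha = 0.05.
#'
#' @param predicted a `threshold_table` from [run_array()] (its
#'   `electrode_summary` attribute is used) or a data frame with columns
#'   `electrode` and `min_threshold_uA`.
#' @param measured a `site_table` with `label`, `threshold_uA`, `visible`.
#' @param alpha significance level.
#' @return A `regression_result` with extra fields `matched` (the merged
#'   table) and `significant`.
#' @export
compare_predicted_vs_perceptual <- function(predicted, measured,
                                            alpha = 0.05) {
  pred <- if (inherits(predicted, "threshold_table"))
    electrode_summary(predicted) else as.data.frame(predicted)
  if (is.null(pred) || !all(c("electrode", "min_threshold_uA") %in%
                            names(pred)))
    stop("predicted table must carry electrode and min_threshold_uA")
  keep <- vapply(seq_len(nrow(measured)), function(i)
    include_electrode(measured[i, ]), logical(1))
  meas <- measured[keep & !is.na(measured$threshold_uA), , drop = FALSE]
  m <- merge(pred, meas, by.x = "electrode", by.y = "label")
  m <- m[!is.na(m$min_threshold_uA), , drop = FALSE]
  if (nrow(m) < 3)
    stop("fewer than 3 electrodes with matched labels between predictions ",
         "and measurements")
  fit <- ols_fit(data.frame(predicted_uA = m$min_threshold_uA),
                 m$threshold_uA)
  fit$matched <- m
  fit$significant <- fit$p_value < alpha
  fit
}
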
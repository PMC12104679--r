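#' Durbin-Watson statistic
#'
#' `sum((e_t - e_(t-1))^2) / sum(e_t^2)` over residuals in the supplied
#' (time) order. Values near 2 indicate independence; values near 0
#' positive autocorrelation.
#'
#' @param residuals Numeric vector, length >= 2.
#' @return The statistic, or `NA` (with a warning) for all-zero residuals.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need >= 2 residuals", call. = FALSE)
  denom <- sum(residuals^2)
  if (denom == 0) {
    warning("all residuals zero; Durbin-Watson undefined")
    return(NA_real_)
  }
  sum(diff(residuals)^2) / denom
}

#' Stepwise multiple regression with collinearity diagnostics
#'
#' Forward selection with backward elimination on partial-F p values
#' (equivalently the coefficient t tests): at each step the candidate with
#' the smallest entry p below `entry_p` is added, then any entered
#' predictor whose p value has risen above `removal_p` is removed.
#' Candidates that would be (near-)collinear with the current model
#' (tolerance below `tol_min`) are skipped with a warning. Reports the
#' diagnostics conventionally printed for such models: R-squared, adjusted
#' R-squared, F change at the final step, per-predictor p, tolerance
#' (`1 - R^2` of the predictor on its co-predictors), VIF (`1/tolerance`),
#' standardized coefficients (refit on z-scored data), and the
#' Durbin-Watson statistic of the residuals in row order.
#'
#' @param y Numeric response.
#' @param x Data frame (or matrix) of candidate predictors.
#' @param entry_p Entry threshold (default 0.05).
#' @param removal_p Removal threshold (default 0.10; must be >= `entry_p`
#'   to rule out cycling).
#' @param tol_min Minimum tolerance for a candidate (default 1e-8).
#' @return Object of class `stepwise_model`: `predictors` (entry order),
#'   `coefficients`, `coef_table` (beta, std beta, p, tolerance, VIF),
#'   `r2`, `adj_r2`, `f_change`, `f_change_p`, `dw`, `n`, `steps`.
#' @export
stepwise_regression <- function(y, x, entry_p = 0.05, removal_p = 0.10,
                                tol_min = 1e-8) {
  x <- as.data.frame(x)
  if (!length(y) || nrow(x) != length(y)) {
    stop("y and x must have matching rows", call. = FALSE)
  }
  if (length(y) <= ncol(x) + 1) {
    stop("need n > number of candidates + 1", call. = FALSE)
  }
  const <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    stop("constant predictor(s): ", paste(names(x)[const], collapse = ", "),
         call. = FALSE)
  }
  if (removal_p < entry_p) {
    stop("removal_p must be >= entry_p", call. = FALSE)
  }

  selected <- character(0)
  steps <- list()
  r2_of <- function(vars) {
    if (!length(vars)) return(0)
    f <- stats::lm(y ~ ., data = x[, vars, drop = FALSE])
    summary(f)$r.squared
  }
  coef_p <- function(vars) {
    f <- stats::lm(y ~ ., data = x[, vars, drop = FALSE])
    s <- summary(f)$coefficients
    stats::setNames(s[-1, 4], vars)
  }
  tolerance_of <- function(var, others) {
    if (!length(others)) return(1)
    1 - summary(stats::lm(x[[var]] ~ .,
                          data = x[, others, drop = FALSE]))$r.squared
  }

  repeat {
    ## forward step
    candidates <- setdiff(names(x), selected)
    best <- NULL; best_p <- Inf
    for (v in candidates) {
      tol <- tolerance_of(v, selected)
      if (tol < tol_min) {
        warning("candidate ", v, " skipped: tolerance ~ 0 (collinear)")
        next
      }
      p <- coef_p(c(selected, v))[[v]]
      if (p < best_p) { best <- v; best_p <- p }
    }
    if (is.null(best) || best_p >= entry_p) break
    selected <- c(selected, best)
    steps[[length(steps) + 1L]] <- list(action = "enter", var = best,
                                        p = best_p, r2 = r2_of(selected))
    ## backward sweep
    repeat {
      if (length(selected) < 2) break
      ps <- coef_p(selected)
      worst <- names(which.max(ps))
      if (ps[[worst]] <= removal_p) break
      selected <- setdiff(selected, worst)
      steps[[length(steps) + 1L]] <- list(action = "remove", var = worst,
                                          p = ps[[worst]],
                                          r2 = r2_of(selected))
    }
  }

  n <- length(y)
  if (!length(selected)) {
    fit <- stats::lm(y ~ 1)
    out <- list(predictors = character(0),
                coefficients = stats::coef(fit),
                coef_table = data.frame(term = "(Intercept)",
                                        beta = unname(stats::coef(fit)),
                                        std_beta = NA_real_, p = NA_real_,
                                        tolerance = NA_real_, vif = NA_real_,
                                        stringsAsFactors = FALSE),
                r2 = 0, adj_r2 = 0, f_change = NA_real_,
                f_change_p = NA_real_,
                dw = durbin_watson(stats::resid(fit)), n = n, steps = steps)
    class(out) <- "stepwise_model"
    return(out)
  }

  fit <- stats::lm(y ~ ., data = x[, selected, drop = FALSE])
  sm <- summary(fit)
  ## standardized betas: refit on z-scored response and predictors
  zd <- as.data.frame(scale(x[, selected, drop = FALSE]))
  zfit <- stats::lm(scale(y) ~ ., data = zd)
  std_beta <- stats::coef(zfit)[-1]
  tolv <- vapply(selected, function(v) {
    tolerance_of(v, setdiff(selected, v))
  }, numeric(1))
  r2 <- sm$r.squared
  p_now <- length(selected)
  r2_prev <- r2_of(selected[-p_now])
  f_change <- (r2 - r2_prev) / ((1 - r2) / (n - p_now - 1))
  coefs <- stats::coef(fit)
  out <- list(
    predictors = selected,
    coefficients = coefs,
    coef_table = data.frame(
      term = c("(Intercept)", selected),
      beta = unname(coefs[c("(Intercept)", selected)]),
      std_beta = c(NA_real_, unname(std_beta[selected])),
      p = c(sm$coefficients["(Intercept)", 4],
            sm$coefficients[selected, 4]),
      tolerance = c(NA_real_, unname(tolv)),
      vif = c(NA_real_, unname(1 / tolv)),
      stringsAsFactors = FALSE
    ),
    r2 = r2,
    adj_r2 = sm$adj.r.squared,
    f_change = f_change,
    f_change_p = stats::pf(f_change, 1, n - p_now - 1, lower.tail = FALSE),
    dw = durbin_watson(stats::resid(fit)),
    n = n,
    steps = steps,
    fit = fit
  )
  class(out) <- "stepwise_model"
  out
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("<stepwise_model>\n")
  if (!length(x$predictors)) {
    cat("  intercept-only model\n")
  } else {
    cat(sprintf("  R2 = %.3f, adj R2 = %.3f, F change = %.3f (p = %.4g), DW = %.3f\n",
                x$r2, x$adj_r2, x$f_change, x$f_change_p, x$dw))
    print(x$coef_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Principal component analysis on the correlation matrix
#'
#' Column-standardised PCA by eigendecomposition of the correlation matrix
#' (covariance matrix when `standardize = FALSE`). Zero-variance columns
#' are dropped with a warning.
#'
#' @param x Numeric matrix or data frame (>= 3 rows, >= 2 usable columns).
#' @param standardize Use the correlation matrix (default `TRUE`).
#' @return List of class `pca_result`: `loadings` (orthonormal columns),
#'   `scores`, `proportion` (variance per component, sums to 1),
#'   `cumulative`, `sdev`.
#' @export
pca_cor <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) {
    stop("need >= 3 observations and >= 2 variables", call. = FALSE)
  }
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("zero-variance column(s) dropped: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 variable columns remain",
                          call. = FALSE)
  }
  xc <- scale(x, center = TRUE, scale = standardize)
  C <- if (standardize) stats::cor(x) else stats::cov(x)
  eig <- eigen(C, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  out <- list(
    loadings = eig$vectors,
    scores = xc %*% eig$vectors,
    proportion = values / sum(values),
    cumulative = cumsum(values) / sum(values),
    sdev = sqrt(values)
  )
  dimnames(out$loadings) <- list(colnames(x),
                                 paste0("PC", seq_len(ncol(x))))
  colnames(out$scores) <- paste0("PC", seq_len(ncol(x)))
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n  variance proportions:",
      sprintf("%.3f", x$proportion), "\n")
  invisible(x)
}
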
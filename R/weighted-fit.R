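#' Weighted linear regression (closed-form weighted least squares)
#'
#' Fits `y ~ 1 + X (+ confounder)` by weighted least squares. Coefficient
#' standard errors use the weighted residual variance
#' `sigma^2 = sum(w * r^2) / (n - p)` and p-values come from the t
#' distribution on `n - p` degrees of freedom, so with unit weights the fit
#' reproduces ordinary least squares exactly. Integer weight `k` on a row is
#' equivalent to replicating that row `k` times as far as the coefficients
#' are concerned.
#'
#' @param y numeric response.
#' @param x numeric vector, matrix, or data.frame of independent variables.
#' @param confounder optional numeric vector/matrix of baseline covariates
#'   added to the design (adjusted for, reported like any other term).
#' @param weights observation weights in `(0, 1]` (or any positive values);
#'   `NULL` means unit weights.
#' @return An `mnv_fit` object: list with `kind = "linear"`, `coefficients`,
#'   `se`, `statistic`, `p_value`, `df_residual`, `sigma2`, `weights`,
#'   `fitted`, `residuals`, `vcov` and `terms`.
#' @export
weighted_linear_fit <- function(y, x, confounder = NULL, weights = NULL) {
  d <- build_design(y, x, confounder, weights)
  X <- d$X; y <- d$y; w <- d$w
  n <- length(y); p <- ncol(X)
  if (sum(w > 0) < p + 2L) {
    stop(sprintf(
      "need at least %d observations with positive weight for %d parameters",
      p + 2L, p
    ), call. = FALSE)
  }
  sw <- sqrt(w)
  qrX <- qr(X * sw)
  check_full_rank(qrX, colnames(X))
  beta <- qr.coef(qrX, y * sw)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df_res <- n - p
  sigma2 <- sum(w * res^2) / df_res
  XtWX_inv <- chol2inv(chol(crossprod(X * sw)))
  vcov <- sigma2 * XtWX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  new_mnv_fit(
    kind = "linear", coefficients = beta, se = se, statistic = tval,
    p_value = pval, df_residual = df_res, sigma2 = sigma2, weights = w,
    fitted = fitted, residuals = res, vcov = vcov, terms = colnames(X),
    rss = sum(w * res^2)
  )
}

#' Weighted logistic regression by iteratively reweighted least squares
#'
#' Maximizes the weighted Bernoulli log-likelihood by Fisher scoring /
#' IRLS. Convergence is declared when the largest absolute coefficient
#' change falls below `tol` (default 1e-8) within `max_iter` iterations
#' (default 50). Wald standard errors come from the inverse Fisher
#' information at the optimum; p-values are two-sided normal. Rescaling all
#' weights by a positive constant changes standard errors but leaves the
#' coefficient estimates unchanged (the score equations are scale
#' invariant in the weights).
#'
#' @inheritParams weighted_linear_fit
#' @param y binary response coded 0/1 (or logical).
#' @param tol convergence tolerance on the coefficient update.
#' @param max_iter maximum IRLS iterations.
#' @return An `mnv_fit` object with `kind = "logistic"`.
#' @export
weighted_logistic_fit <- function(y, x, confounder = NULL, weights = NULL,
                                  tol = 1e-8, max_iter = 50L) {
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop("logistic fit requires a 0/1 response", call. = FALSE)
  }
  d <- build_design(y, x, confounder, weights)
  X <- d$X; y <- d$y; w <- d$w
  pos <- w > 0
  if (length(unique(y[pos])) < 2L) {
    stop("both outcome classes must be present among positive-weight rows",
         call. = FALSE)
  }
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    wirls <- w * v
    # working response; guard v on flat regions
    z <- eta + (y - mu) / pmax(v, 1e-12)
    sw <- sqrt(wirls)
    qrX <- qr(X * sw)
    check_full_rank(qrX, colnames(X))
    beta_new <- qr.coef(qrX, z * sw)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (!all(is.finite(beta))) {
      stop("divergence in IRLS (non-finite coefficients); check for ",
           "complete separation of the classes", call. = FALSE)
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged || max(abs(beta)) > 30) {
    stop("weighted logistic fit did not converge; the classes may be ",
         "completely separated by a covariate - consider removing it or ",
         "using a penalized fit", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * sqrt(w * mu * (1 - mu)))
  vcov <- chol2inv(chol(info))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  new_mnv_fit(
    kind = "logistic", coefficients = beta, se = se, statistic = zval,
    p_value = pval, df_residual = length(y) - p, sigma2 = NA_real_,
    weights = w, fitted = mu, residuals = y - mu, vcov = vcov,
    terms = colnames(X), rss = NA_real_, iterations = it
  )
}

#' Joint F-test for a group of terms in a weighted linear fit
#'
#' Compares a full and a nested reduced weighted linear model by the usual
#' extra-sum-of-squares F statistic on the weighted residual sums of
#' squares. Both fits must use identical observations and weights.
#'
#' @param full,reduced `mnv_fit` objects of kind `"linear"`.
#' @return list with `statistic`, `df1`, `df2`, `p_value`.
#' @export
joint_f_test <- function(full, reduced) {
  stopifnot(inherits(full, "mnv_fit"), inherits(reduced, "mnv_fit"),
            full$kind == "linear", reduced$kind == "linear")
  df1 <- reduced$df_residual - full$df_residual
  if (df1 <= 0) stop("'reduced' must be nested within 'full'", call. = FALSE)
  fstat <- ((reduced$rss - full$rss) / df1) / (full$rss / full$df_residual)
  list(
    statistic = fstat, df1 = df1, df2 = full$df_residual,
    p_value = stats::pf(fstat, df1, full$df_residual, lower.tail = FALSE)
  )
}

# --- internal helpers --------------------------------------------------------

build_design <- function(y, x, confounder, weights) {
  y <- as.numeric(y)
  Xiv <- as_design_block(x, "x")
  X <- cbind(`(Intercept)` = 1, Xiv)
  if (!is.null(confounder)) {
    X <- cbind(X, as_design_block(confounder, "confounder"))
  }
  n <- length(y)
  if (nrow(X) != n) stop("design and response lengths differ", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be non-negative, finite, one per observation",
         call. = FALSE)
  }
  keep <- stats::complete.cases(X, y)
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]; y <- y[keep]; weights <- weights[keep]
  }
  list(X = X, y = y, w = weights)
}

as_design_block <- function(x, fallback) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    x <- matrix(as.numeric(x), ncol = 1L,
                dimnames = list(NULL, fallback))
  }
  if (is.null(colnames(x)) && ncol(x) > 0L) {
    colnames(x) <- paste0(fallback, seq_len(ncol(x)))
  }
  storage.mode(x) <- "double"
  x
}

check_full_rank <- function(qrX, term_names) {
  if (qrX$rank < length(term_names)) {
    bad <- term_names[qrX$pivot[seq.int(qrX$rank + 1L, length(term_names))]]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

new_mnv_fit <- function(...) {
  structure(list(...), class = "mnv_fit")
}

#' @export
print.mnv_fit <- function(x, ...) {
  cat(sprintf("weighted %s fit (%d terms, residual df = %d)\n",
              x$kind, length(x$coefficients), x$df_residual))
  tab <- data.frame(
    estimate = x$coefficients, se = x$se,
    statistic = x$statistic, p_value = x$p_value,
    row.names = x$terms
  )
  print(format(tab, digits = 4L))
  invisible(x)
}

#' @export
coef.mnv_fit <- function(object, ...) object$coefficients
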
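# Phylogenetic generalized least squares with Pagel's lambda.
#
# The error covariance among species is sigma2 * V(lambda), where V is
# the tree's Brownian-motion variance-covariance matrix and lambda
# multiplies its off-diagonal entries. beta and sigma2 have closed-form
# ML solutions given lambda, so lambda is estimated by maximizing the
# profile log-likelihood over [0, 1] (optionally a wider range). All
# linear algebra goes through a Cholesky factorization of V(lambda);
# explicit matrix inverses are never formed.

off_diag_max <- function(V) {
  d <- diag(V)
  max(abs(V - diag(d, nrow(V))))
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of \code{V} by \code{lambda},
#' leaving the diagonal untouched. \code{lambda = 1} is pure Brownian
#' motion; \code{lambda = 0} is the star tree (phylogenetic
#' independence).
#'
#' @param V Symmetric phylogenetic covariance matrix.
#' @param lambda Scalar in [0, 1], or larger if the transformed matrix
#'   remains positive definite.
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  d <- diag(V)
  Vl <- lambda * V
  diag(Vl) <- d
  if (lambda > 1) {
    ok <- !inherits(try(chol(Vl), silent = TRUE), "try-error")
    if (!ok) {
      stop("lambda = ", lambda,
           " exceeds the value at which the transformed matrix stays ",
           "positive definite", call. = FALSE)
    }
  }
  Vl
}

#' Generalized least squares fit with known covariance
#'
#' Maximum-likelihood GLS: \eqn{\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y},
#' \eqn{\hat\sigma^2 = (y-X\hat\beta)'V^{-1}(y-X\hat\beta)/n} (ML
#' divisor \eqn{n}), and the multivariate-normal log-likelihood at the
#' maximum. Solved by whitening with the Cholesky factor of \code{V}
#' followed by a QR fit.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (rows matching \code{y} and \code{V}).
#' @param V Positive-definite covariance matrix (up to the scalar
#'   \eqn{\sigma^2}).
#' @return A list with \code{beta}, \code{sigma2} (ML), \code{rss}
#'   (whitened residual sum of squares), \code{log_likelihood},
#'   \code{xtvix_inv} (the unscaled coefficient covariance
#'   \eqn{(X'V^{-1}X)^{-1}}), \code{n} and \code{k}.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("dimensions of y, X and V disagree", call. = FALSE)
  }
  U <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix V is not positive definite", call. = FALSE)
  })
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(X)) {
    drop_cols <- if (is.null(colnames(X))) "" else
      paste(" (", paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]],
                        collapse = ", "), ")", sep = "")
    stop("design matrix X is rank deficient", drop_cols, call. = FALSE)
  }
  beta <- qr.coef(qx, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  ldetV <- 2 * sum(log(diag(U)))
  ll <- -0.5 * n * log(2 * pi * sigma2) - 0.5 * ldetV - 0.5 * n
  xtvix_inv <- chol2inv(chol(crossprod(Xw)))
  dimnames(xtvix_inv) <- list(colnames(X), colnames(X))
  beta <- drop(beta)
  if (!is.null(colnames(X))) names(beta) <- colnames(X)
  list(beta = beta, sigma2 = sigma2, rss = rss,
       log_likelihood = ll, xtvix_inv = xtvix_inv, n = n, k = ncol(X))
}

#' Profile log-likelihood in lambda
#'
#' GLS log-likelihood (beta and sigma2 maximized out) at a given value
#' of Pagel's lambda.
#'
#' @inheritParams gls_fit
#' @param lambda Scalar lambda value.
#' @param V Untransformed phylogenetic covariance matrix.
#' @return Log-likelihood in nats.
#' @export
profile_loglik <- function(lambda, y, X, V) {
  gls_fit(y, X, lambda_transform(V, lambda))$log_likelihood
}

#' Fit a phylogenetic GLS regression with ML Pagel's lambda
#'
#' Estimates lambda by bounded maximization of the profile
#' log-likelihood (Brent-type search started from 5 equal sub-intervals
#' of the search range, endpoints checked explicitly; tolerance 1e-8 on
#' lambda), then computes coefficients, standard errors, t statistics,
#' one- and two-sided p-values, and an r-squared in the whitened space.
#'
#' Standard errors use the unbiased residual variance (divisor n - k)
#' even though the reported \code{sigma2} is the ML estimate (divisor
#' n). The default degrees of freedom for t tests is the number of taxa
#' (\code{"n_taxa"}); the textbook \code{"n_minus_k"} alternative is a
#' switch away, and both p-value tails are always stored.
#'
#' When V is diagonal (a star phylogeny) lambda is unidentifiable: the
#' fit then equals OLS and \code{lambda_hat} is \code{NA} with
#' \code{lambda_identifiable = FALSE}.
#'
#' @inheritParams gls_fit
#' @param lambda_mode \code{"estimate"} (default) or \code{"fixed"}.
#' @param lambda_value Lambda used when \code{lambda_mode = "fixed"}.
#' @param df_convention \code{"n_taxa"} (default, the convention used
#'   for the auk/penguin analysis) or \code{"n_minus_k"}.
#' @param tail \code{"one"} (default; directional predictions) or
#'   \code{"two"}; controls which p-value drives significance markers.
#' @param lambda_bounds Search interval for lambda, default c(0, 1).
#' @return An object of class \code{pgls_fit}.
#' @export
fit_pgls <- function(y, X, V,
                     lambda_mode = c("estimate", "fixed"),
                     lambda_value = 1,
                     df_convention = c("n_taxa", "n_minus_k"),
                     tail = c("one", "two"),
                     lambda_bounds = c(0, 1)) {
  lambda_mode <- match.arg(lambda_mode)
  df_convention <- match.arg(df_convention)
  tail <- match.arg(tail)
  X <- as.matrix(X)
  n <- length(y); k <- ncol(X)
  if (n <= k) stop("need more taxa than design-matrix columns", call. = FALSE)
  star <- off_diag_max(V) == 0
  if (star) {
    lam_hat <- NA_real_
    fit <- gls_fit(y, X, V)
    ll_ends <- c(fit$log_likelihood, fit$log_likelihood)
  } else if (lambda_mode == "fixed") {
    lam_hat <- lambda_value
    fit <- gls_fit(y, X, lambda_transform(V, lam_hat))
    ll_ends <- vapply(lambda_bounds,
                      function(l) profile_loglik(l, y, X, V), 0)
  } else {
    lo <- lambda_bounds[1]; hi <- lambda_bounds[2]
    knots <- seq(lo, hi, length.out = 6L)
    best_lam <- lo
    best_ll <- profile_loglik(lo, y, X, V)
    ll_lo <- best_ll
    ll_hi <- profile_loglik(hi, y, X, V)
    if (ll_hi > best_ll) { best_lam <- hi; best_ll <- ll_hi }
    for (i in seq_len(5L)) {
      op <- stats::optimize(profile_loglik, interval = knots[c(i, i + 1L)],
                            maximum = TRUE, tol = 1e-8,
                            y = y, X = X, V = V)
      if (op$objective > best_ll) {
        best_lam <- op$maximum
        best_ll <- op$objective
      }
    }
    lam_hat <- best_lam
    fit <- gls_fit(y, X, lambda_transform(V, lam_hat))
    ll_ends <- c(ll_lo, ll_hi)
  }
  sigma2_unbiased <- fit$rss / (n - k)
  se <- sqrt(diag(fit$xtvix_inv) * sigma2_unbiased)
  if (any(se == 0)) stop("degenerate model: zero standard error", call. = FALSE)
  tstat <- fit$beta / se
  df_used <- switch(df_convention, n_taxa = n, n_minus_k = n - k)
  p_two <- 2 * stats::pt(-abs(tstat), df = df_used)
  p_one <- stats::pt(-abs(tstat), df = df_used)
  # r-squared in the whitened space, TSS around the GLS intercept-only fit
  Vl <- if (star) V else lambda_transform(V, if (is.na(lam_hat)) 1 else lam_hat)
  r2 <- pgls_r_squared(y, X, Vl, rss = fit$rss)
  structure(list(
    lambda_hat = lam_hat,
    lambda_identifiable = !star,
    beta = fit$beta,
    se = se,
    t_stat = tstat,
    p_one_sided = p_one,
    p_two_sided = p_two,
    df_used = df_used,
    df_convention = df_convention,
    tail = tail,
    sigma2_hat = fit$sigma2,
    sigma2_unbiased = sigma2_unbiased,
    log_likelihood = fit$log_likelihood,
    loglik_at_bounds = ll_ends,
    lambda_bounds = lambda_bounds,
    r_squared = r2,
    n_taxa = n,
    k = k,
    coef_names = colnames(X)
  ), class = "pgls_fit")
}

#' Coefficient of determination for a (P)GLS fit
#'
#' \eqn{1 - RSS/TSS} computed in the whitened space: response and
#' design premultiplied by the inverse Cholesky factor of the
#' (lambda-transformed) covariance, with TSS taken around the GLS
#' intercept-only fit. Lies in [0, 1] for any model containing an
#' intercept.
#'
#' @inheritParams gls_fit
#' @param V_transformed The (lambda-transformed) covariance matrix the
#'   model was fitted under.
#' @param rss Optional precomputed whitened residual sum of squares of
#'   the full model.
#' @return Scalar r-squared.
#' @export
pgls_r_squared <- function(y, X, V_transformed, rss = NULL) {
  if (is.null(rss)) rss <- gls_fit(y, X, V_transformed)$rss
  ones <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  tss <- gls_fit(y, ones, V_transformed)$rss
  if (tss <= 1e-12 * max(1, sum(y^2))) {
    stop("degenerate response: zero total sum of squares", call. = FALSE)
  }
  1 - rss / tss
}

#' Per-coefficient t tests for a PGLS fit
#'
#' Recomputes t statistics and p-values under a chosen degrees-of-
#' freedom convention and tail, and attaches significance markers
#' (\code{**} for p < 0.01, \code{*} for p < 0.05).
#'
#' @param fit A \code{pgls_fit} object.
#' @param df_convention \code{"n_taxa"} or \code{"n_minus_k"}.
#' @param tail \code{"one"} or \code{"two"}: which p-value the markers
#'   are based on (both are returned).
#' @return A data frame with one row per coefficient: \code{variable},
#'   \code{estimate}, \code{se}, \code{t}, \code{p_one_sided},
#'   \code{p_two_sided}, \code{p} (the tail in use) and \code{marker}.
#' @export
coefficient_tests <- function(fit,
                              df_convention = fit$df_convention,
                              tail = fit$tail) {
  stopifnot(inherits(fit, "pgls_fit"))
  df_convention <- match.arg(df_convention, c("n_taxa", "n_minus_k"))
  tail <- match.arg(tail, c("one", "two"))
  if (any(fit$se == 0)) stop("degenerate model: zero standard error",
                             call. = FALSE)
  df <- switch(df_convention, n_taxa = fit$n_taxa,
               n_minus_k = fit$n_taxa - fit$k)
  tstat <- fit$beta / fit$se
  p_two <- 2 * stats::pt(-abs(tstat), df = df)
  p_one <- stats::pt(-abs(tstat), df = df)
  p <- if (tail == "one") p_one else p_two
  marker <- ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  data.frame(
    variable = fit$coef_names %||% paste0("b", seq_along(tstat) - 1L),
    estimate = unname(fit$beta),
    se = unname(fit$se),
    t = unname(tstat),
    p_one_sided = unname(p_one),
    p_two_sided = unname(p_two),
    p = unname(p),
    marker = unname(marker),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit (Pagel's lambda, ML)\n")
  if (x$lambda_identifiable) {
    cat(sprintf("  lambda = %.6f   logLik = %.4f   sigma2(ML) = %.4f\n",
                x$lambda_hat, x$log_likelihood, x$sigma2_hat))
  } else {
    cat(sprintf("  lambda unidentifiable (star covariance); logLik = %.4f\n",
                x$log_likelihood))
  }
  cat(sprintf("  r-squared = %.6f   n = %d taxa, %d coefficients, df = %d (%s)\n",
              x$r_squared, x$n_taxa, x$k, x$df_used, x$df_convention))
  tab <- coefficient_tests(x)
  tab[c("estimate", "se", "t", "p")] <-
    lapply(tab[c("estimate", "se", "t", "p")], round, digits = 6)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fully standardized (z-scored) coefficients of a PGLS fit
#'
#' Optional companion output: coefficients rescaled by the ratio of the
#' predictor's to the response's standard deviation, as in classical
#' standardized regression. The primary coefficient table reports raw
#' partial regression coefficients in response units.
#'
#' @param fit A \code{pgls_fit} object.
#' @param y,X The response and design matrix the fit was computed from.
#' @return Named numeric vector of standardized coefficients
#'   (intercept excluded).
#' @export
standardized_coefficients <- function(fit, y, X) {
  stopifnot(inherits(fit, "pgls_fit"))
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  out <- fit$beta * sds / stats::sd(y)
  out[sds > 0 & fit$coef_names != "(Intercept)"]
}
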
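#' Logistic cumulative distribution function
#'
#' \eqn{F(x) = 1/(1+e^{-x})}, computed stably for large |x|.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
logistic_cdf <- function(x) stats::plogis(x)

#' Fit a weighted binary logistic regression by IRLS
#'
#' Maximizes the weighted Bernoulli log-likelihood
#' \eqn{\sum_i w_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with
#' \eqn{p_i = F(x_i'\beta)} by iteratively reweighted least squares. The
#' covariance estimate is the inverse of the weighted information at the
#' optimum. Convergence requires a relative log-likelihood change below
#' `tol_loglik` or a maximum absolute score component below `tol_score`.
#' Complete separation (coefficients diverging past `sep_bound`) is a hard
#' error unless a small ridge is requested.
#'
#' @param design list as returned by [build_design()]: matrix `x` with
#'   intercept first, outcome `y`, weights `w`, optional `blocks`.
#' @param max_iter maximum IRLS iterations.
#' @param tol_loglik relative log-likelihood convergence tolerance.
#' @param tol_score score convergence tolerance.
#' @param sep_bound absolute coefficient bound beyond which separation is
#'   declared.
#' @param ridge optional ridge penalty (e.g. `1e-6`) applied to
#'   non-intercept coefficients instead of erroring on separation.
#' @return object of class `logit_fit`: `coef` (named, intercept first),
#'   `alpha_hat`, `beta_hat`, `cov`, `loglik`, `converged`, `n_iter`,
#'   `fitted`, `blocks`, `n`, `df`.
#' @export
fit_weighted_logit <- function(design, max_iter = 100L, tol_loglik = 1e-10,
                               tol_score = 1e-8, sep_bound = 30,
                               ridge = 0) {
  x <- design$x
  y <- design$y
  w <- design$w
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more observations than parameters")
  if (wmean(y, w) <= 0 || wmean(y, w) >= 1) stop("degenerate outcome")
  pen <- rep(ridge, p)
  pen[1L] <- 0                       # never penalize the intercept
  beta <- numeric(p)
  beta[1L] <- stats::qlogis(wmean(y, w))
  eta <- drop(x %*% beta)
  ll <- weighted_bernoulli_loglik(y, eta, w)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    score <- crossprod(x, w * (y - mu)) - pen * beta
    info <- crossprod(x, x * (w * v)) + diag(pen, p)
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("singular information matrix; check for collinear columns")
    })
    beta_new <- beta + drop(step)
    eta_new <- drop(x %*% beta_new)
    ll_new <- weighted_bernoulli_loglik(y, eta_new, w)
    # step-halving keeps IRLS monotone on difficult data
    halvings <- 0L
    while (ll_new < ll && halvings < 30L) {
      beta_new <- (beta + beta_new) / 2
      eta_new <- drop(x %*% beta_new)
      ll_new <- weighted_bernoulli_loglik(y, eta_new, w)
      halvings <- halvings + 1L
    }
    if (ridge == 0 && any(abs(beta_new[-1L]) > sep_bound)) {
      j <- which(abs(beta_new[-1L]) > sep_bound)[1L] + 1L
      stop("apparent complete separation involving column '",
           colnames(x)[j], "'")
    }
    rel <- abs(ll_new - ll) / (abs(ll_new) + 1e-10)
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    mu <- stats::plogis(eta)
    max_score <- max(abs(crossprod(x, w * (y - mu)) - pen * beta))
    if (rel < tol_loglik || max_score < tol_score) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  v <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(x, x * (w * v)) + diag(pen, p)
  covm <- solve(info)
  names(beta) <- colnames(x)
  dimnames(covm) <- list(colnames(x), colnames(x))
  structure(list(
    coef = beta,
    alpha_hat = beta[[1L]],
    beta_hat = beta[-1L],
    cov = covm,
    loglik = ll,
    converged = converged,
    n_iter = iter,
    fitted = stats::plogis(eta),
    blocks = design$blocks,
    n = n,
    df = p
  ), class = "logit_fit")
}

weighted_bernoulli_loglik <- function(y, eta, w) {
  # log p = -log(1+exp(-eta)), log(1-p) = -log(1+exp(eta)); stable in tails
  sum(w * ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                 stats::plogis(-eta, log.p = TRUE)))
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("weighted logit fit: n = %d, p = %d, loglik = %.4f, %s (%d iter)\n",
              x$n, x$df, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(coef_table(x))
  invisible(x)
}

#' Coefficient table of a logit fit
#'
#' @param fit a `logit_fit`.
#' @return data frame with term, estimate, se, z, p.
#' @export
coef_table <- function(fit) {
  se <- sqrt(diag(fit$cov))
  z <- fit$coef / se
  data.frame(
    term = names(fit$coef),
    estimate = unname(fit$coef),
    se = unname(se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
}

#' Wald chi-square test of all non-intercept coefficients
#'
#' Quadratic form \eqn{\hat\beta' V^{-1} \hat\beta} over the tested columns;
#' under the null that all tested coefficients are zero it is chi-square
#' with df equal to the number of tested columns.
#'
#' @param fit a converged `logit_fit`.
#' @param columns indices of tested columns; default all non-intercept.
#' @return list with `chi2`, `df`, `p`.
#' @export
wald_all_coefficients <- function(fit, columns = NULL) {
  if (!fit$converged) stop("fit did not converge")
  if (is.null(columns)) columns <- seq_along(fit$coef)[-1L]
  b <- fit$coef[columns]
  v <- fit$cov[columns, columns, drop = FALSE]
  vi <- tryCatch(solve(v), error = function(e) stop("singular covariance block"))
  chi2 <- drop(t(b) %*% vi %*% b)
  df <- length(columns)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Likelihood-ratio test of nested logit fits
#'
#' @param full,null `logit_fit` objects, `null` nested in `full`.
#' @return list with `chi2` (twice the log-likelihood difference), `df`
#'   (parameter difference), `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  df <- full$df - null$df
  if (df <= 0) stop("models are not nested (df <= 0)")
  chi2 <- 2 * (full$loglik - null$loglik)
  if (chi2 < -1e-8) stop("full model fits worse than null; models not nested?")
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Weighted least squares on the same design contract; used for the linear
# Blinder-Oaxaca decomposition and the identity-link limit of the engine.
fit_weighted_linear <- function(design) {
  fit <- stats::lm.wfit(design$x, design$y, design$w)
  coefs <- fit$coefficients
  if (anyNA(coefs)) stop("singular design in linear fit")
  structure(list(
    coef = coefs,
    alpha_hat = coefs[[1L]],
    beta_hat = coefs[-1L],
    blocks = design$blocks,
    n = nrow(design$x)
  ), class = "linear_fit")
}
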
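#' Fit the conditional Poisson case-crossover model
#'
#' Maximises the Poisson likelihood of daily counts with one free intercept
#' per time stratum, the stratum intercepts profiled out in closed form at
#' each step — numerically identical to a dummy-variable Poisson regression
#' on the shared parameters (and to the within-stratum multinomial
#' conditional likelihood), but far better conditioned than expanding
#' hundreds of dummy columns. Estimation is iteratively reweighted least
#' squares on stratum-centred working data, with step-halving so the profile
#' log-likelihood never decreases, run to a relative log-likelihood change
#' below `tol` or `maxit` iterations.
#'
#' Rows flagged invalid in the cross-basis (incomplete lag history) and
#' strata whose total count is zero are excluded; they carry no information
#' about the shared parameters. A design that is collinear after
#' within-stratum centring (e.g. a covariate constant inside every stratum)
#' raises an error rather than returning a silent estimate.
#'
#' @param crossbasis a [build_crossbasis()] matrix (or any numeric design
#'   matrix, optionally with a logical `"valid"` attribute).
#' @param confounders a [build_confounder_design()] matrix (or `NULL`).
#' @param counts non-negative integer daily counts, aligned with the design
#'   rows.
#' @param strata a [assign_strata()] index aligned with the design rows.
#' @param tol relative profile log-likelihood convergence tolerance
#'   (default 1e-10).
#' @param maxit iteration cap (default 100).
#' @param quasi if TRUE, inflate the covariance by the Pearson
#'   overdispersion estimate (quasi-likelihood scale); point estimates are
#'   unchanged.
#' @return An object of class `"ccfit"`: list with `coef` (named log-rate
#'   ratios), `vcov`, `deviance`, `loglik` (profile, without the `y!`
#'   constant), `n_eff`, `n_strata`, `converged`, `iter`, `scale`,
#'   `cb_cols` (names of the cross-basis columns within `coef`) and
#'   `loglik_trace`.
#' @export
fit_conditional_poisson <- function(crossbasis, confounders = NULL, counts,
                                    strata, tol = 1e-10, maxit = 100L,
                                    quasi = FALSE) {
  X_cb <- unclass(crossbasis)
  attr(X_cb, "spec") <- NULL
  valid <- attr(crossbasis, "valid")
  if (is.null(valid)) valid <- rep(TRUE, nrow(X_cb))
  X <- if (!is.null(confounders) && ncol(confounders) > 0)
    cbind(X_cb, unclass(confounders)) else X_cb
  cb_cols <- colnames(X_cb)
  y <- counts
  if (length(y) != nrow(X) || length(strata$label) != nrow(X))
    stop("counts, strata and design rows are not aligned", call. = FALSE)
  if (any(y < 0, na.rm = TRUE) || any(y != round(y), na.rm = TRUE))
    stop("counts must be non-negative integers", call. = FALSE)

  keep <- valid & !is.na(y) & stats::complete.cases(X)
  s_all <- strata$label[keep]
  # strata with zero total events contribute nothing to the likelihood
  tot <- rowsum(y[keep], s_all)
  nonzero <- rownames(tot)[tot[, 1] > 0]
  keep[keep] <- s_all %in% nonzero
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  s <- droplevels(strata$label[keep])
  n <- length(y); p <- ncol(X)
  if (n < p) stop("fewer valid observations than parameters", call. = FALSE)

  # identifiability after stratum centring
  Xc0 <- X - rowsum(X, as.integer(s))[as.integer(s), , drop = FALSE] /
    tabulate(s)[as.integer(s)]
  if (qr(Xc0)$rank < p)
    stop("design is singular after stratum centring; ",
         "some column is constant within every stratum", call. = FALSE)

  si <- as.integer(s)                    # rowsum over integer codes keeps
  Ys <- rowsum(y, si)[, 1]               # rows in code order 1..n_strata
  beta <- rep(0, p)
  eta_x <- drop(X %*% beta)
  profile_ll <- function(eta_x) {
    alpha <- log(Ys) - log(rowsum(exp(eta_x), si)[, 1])
    eta <- eta_x + alpha[si]
    sum(y * eta) - sum(Ys)               # sum(mu) = sum(Ys) at the profile
  }
  ll <- profile_ll(eta_x)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  XtWX <- NULL
  while (iter < maxit) {
    iter <- iter + 1L
    alpha <- log(Ys) - log(rowsum(exp(eta_x), si)[, 1])
    eta <- eta_x + alpha[si]
    mu <- exp(eta)
    w <- mu
    z <- eta + (y - mu) / mu
    sw <- rowsum(w, si)[, 1]
    Xc <- X - (rowsum(w * X, si) / sw)[si, , drop = FALSE]
    zc <- z - (rowsum(w * z, si)[, 1] / sw)[si]
    XtWX <- crossprod(Xc, w * Xc)
    beta_new <- tryCatch(drop(solve(XtWX, crossprod(Xc, w * zc))),
                         error = function(e)
                           stop("singular weighted design during IRLS",
                                call. = FALSE))
    # step-halving keeps the profile log-likelihood monotone
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      ll_try <- profile_ll(drop(X %*% beta_try))
      if (is.finite(ll_try) && ll_try >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) { beta_try <- beta; ll_try <- ll; break }
    }
    beta <- beta_try
    eta_x <- drop(X %*% beta)
    trace <- c(trace, ll_try)
    if (abs(ll_try - ll) < tol * (abs(ll) + 0.1)) {
      ll <- ll_try; converged <- TRUE; break
    }
    ll <- ll_try
  }
  if (!converged)
    warning("conditional Poisson fit did not converge in ", maxit, " iterations")

  # final weights at the solution for the covariance
  alpha <- log(Ys) - log(rowsum(exp(eta_x), si)[, 1])
  mu <- exp(eta_x + alpha[si])
  w <- mu
  sw <- rowsum(w, si)[, 1]
  Xc <- X - (rowsum(w * X, si) / sw)[si, , drop = FALSE]
  XtWX <- crossprod(Xc, w * Xc)
  vcov <- solve(XtWX)
  vcov <- (vcov + t(vcov)) / 2
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0))
  scale <- 1
  if (quasi) {
    df_resid <- n - p - (nlevels(s) - 0L)
    scale <- sum((y - mu)^2 / mu) / max(df_resid, 1L)
    vcov <- vcov * scale
  }
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, vcov = vcov, deviance = dev, loglik = ll,
                 n_eff = n, n_strata = nlevels(s), converged = converged,
                 iter = iter, scale = scale, cb_cols = cb_cols,
                 fitted = mu, loglik_trace = trace),
            class = "ccfit")
}

#' @export
print.ccfit <- function(x, digits = 4, ...) {
  cat("Conditional Poisson case-crossover fit\n")
  cat(sprintf("  %d days in %d informative strata; deviance %.2f; %s in %d iterations\n",
              x$n_eff, x$n_strata, x$deviance,
              if (x$converged) "converged" else "NOT converged", x$iter))
  est <- cbind(coef = x$coef, se = sqrt(diag(x$vcov)))
  print(round(est, digits))
  invisible(x)
}

#' @export
coef.ccfit <- function(object, ...) object$coef

#' @export
vcov.ccfit <- function(object, ...) object$vcov
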
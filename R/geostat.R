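#' Covariance parameters for a stream-network geostatistical model
#'
#' The covariance of the response between two sites is a sum of up to three
#' components: a tail-up exponential component (acting only between
#' flow-connected sites, weighted by confluence weights `W`), a tail-down
#' exponential component (a function of total hydrologic distance `H` for
#' all pairs), and a nugget on the diagonal. Parameters are partial sills
#' (`sigma2_*`, variance units) and ranges (`range_*`, network length
#' units).
#'
#' @param sigma2_tailup,range_tailup tail-up partial sill and range; both
#'   `NULL` to exclude the component.
#' @param sigma2_taildown,range_taildown tail-down partial sill and range.
#' @param sigma2_nugget nugget variance; always required.
#' @return A classed named numeric vector (`cov_params`). Its names define
#'   the parameter ordering used by priors, draws and information matrices.
#' @examples
#' theta <- cov_params(1, 6, 1, 6, 0.5)
#' @export
cov_params <- function(sigma2_tailup = NULL, range_tailup = NULL,
                       sigma2_taildown = NULL, range_taildown = NULL,
                       sigma2_nugget = NULL) {
  if (is.null(sigma2_nugget)) stop("the nugget component is always required")
  if (xor(is.null(sigma2_tailup), is.null(range_tailup))) {
    stop("tail-up needs both sigma2_tailup and range_tailup (or neither)")
  }
  if (xor(is.null(sigma2_taildown), is.null(range_taildown))) {
    stop("tail-down needs both sigma2_taildown and range_taildown (or neither)")
  }
  th <- c(sigma2_tailup = sigma2_tailup, range_tailup = range_tailup,
          sigma2_taildown = sigma2_taildown, range_taildown = range_taildown,
          sigma2_nugget = sigma2_nugget)
  if (any(!is.finite(th)) || any(th <= 0)) {
    stop("all covariance parameters must be positive, got: ",
         paste(names(th)[!is.finite(th) | th <= 0], collapse = ", "))
  }
  structure(th, class = "cov_params")
}

# rebuild a cov_params from a bare named/unnamed vector laid out like `template`
theta_like <- function(template, values) {
  stopifnot(length(values) == length(template))
  structure(stats::setNames(as.numeric(values), names(template)),
            class = "cov_params")
}

has_component <- function(theta, comp) {
  switch(comp,
    tailup = "sigma2_tailup" %in% names(theta),
    taildown = "sigma2_taildown" %in% names(theta),
    nugget = TRUE
  )
}

#' @export
print.cov_params <- function(x, ...) {
  cat("cov_params:", paste(names(x), signif(unclass(x), 4),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

range_scale <- function(range_convention) {
  switch(match.arg(range_convention, c("effective", "natural")),
         effective = 3, natural = 1)
}

#' Stream-network covariance matrix
#'
#' \deqn{\Sigma_{ij} = \sigma^2_{tu} W_{ij} e^{-3 H_{ij}/\alpha_{tu}}
#'   + \sigma^2_{td} e^{-3 H_{ij}/\alpha_{td}}
#'   + \sigma^2_{0} 1\{i = j\}}
#' where `W` is zero for flow-unconnected pairs, so the tail-up component
#' acts only along flow-connected paths, while the tail-down component
#' depends on total hydrologic distance alone. Under the default
#' `"effective"` range convention the factor 3 makes the range the distance
#' at which correlation drops to about 0.05; `"natural"` uses
#' \eqn{e^{-H/\alpha}}.
#'
#' @param dist a `stream_dist` (see [distance_structure()]).
#' @param theta a [cov_params()].
#' @param range_convention `"effective"` (default) or `"natural"`.
#' @return A symmetric positive-definite matrix with diagonal equal to the
#'   sum of the included sills plus the nugget.
#' @export
covariance_matrix <- function(dist, theta, range_convention = "effective") {
  k <- range_scale(range_convention)
  H <- dist$H
  m <- nrow(H)
  Sigma <- matrix(0, m, m, dimnames = dimnames(H))
  if (has_component(theta, "tailup")) {
    Sigma <- Sigma + theta[["sigma2_tailup"]] * dist$W *
      exp(-k * H / theta[["range_tailup"]])
  }
  if (has_component(theta, "taildown")) {
    Sigma <- Sigma + theta[["sigma2_taildown"]] *
      exp(-k * H / theta[["range_taildown"]])
  }
  diag(Sigma) <- diag(Sigma) + theta[["sigma2_nugget"]]
  Sigma
}

# analytic derivatives of Sigma w.r.t. each element of theta (natural scale)
covariance_derivs <- function(dist, theta, range_convention = "effective") {
  k <- range_scale(range_convention)
  H <- dist$H
  m <- nrow(H)
  derivs <- vector("list", length(theta))
  names(derivs) <- names(theta)
  if (has_component(theta, "tailup")) {
    E <- dist$W * exp(-k * H / theta[["range_tailup"]])
    derivs[["sigma2_tailup"]] <- E
    derivs[["range_tailup"]] <- theta[["sigma2_tailup"]] * E *
      (k * H / theta[["range_tailup"]]^2)
  }
  if (has_component(theta, "taildown")) {
    E <- exp(-k * H / theta[["range_taildown"]])
    derivs[["sigma2_taildown"]] <- E
    derivs[["range_taildown"]] <- theta[["sigma2_taildown"]] * E *
      (k * H / theta[["range_taildown"]]^2)
  }
  derivs[["sigma2_nugget"]] <- diag(1, m)
  derivs
}

#' Simulate Gaussian responses on a site set
#'
#' Draws `y ~ N(X beta, Sigma(theta))` using a Cholesky factor of the
#' covariance; deterministic given `seed`.
#'
#' @param dist a `stream_dist` over the sites.
#' @param theta a [cov_params()].
#' @param X design matrix (rows = sites).
#' @param beta fixed-effect vector used for the mean.
#' @param seed integer seed.
#' @param n_rep number of independent replicate draws (columns).
#' @param range_convention see [covariance_matrix()].
#' @return A numeric vector (`n_rep = 1`) or matrix with one column per
#'   replicate.
#' @export
simulate_response <- function(dist, theta, X, beta, seed = 1L, n_rep = 1L,
                              range_convention = "effective") {
  Sigma <- covariance_matrix(dist, theta, range_convention)
  L <- tryCatch(chol(Sigma), error = function(e) {
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    stop("covariance matrix is not positive definite (smallest eigenvalue ",
         signif(ev, 4), ")")
  })
  n <- nrow(Sigma)
  mu <- as.numeric(X %*% beta)
  y <- withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * n_rep), n, n_rep)
    mu + crossprod(L, z)
  })
  if (n_rep == 1L) as.numeric(y) else y
}

#' Generalised least squares fixed-effect estimates
#'
#' Computes `cov_beta = (X' Sigma^-1 X)^-1` and, when `y` is supplied, the
#' GLS estimate `beta_hat = cov_beta X' Sigma^-1 y`.
#'
#' @param X full-column-rank design matrix.
#' @param Sigma positive-definite covariance matrix.
#' @param y optional response vector.
#' @return List with `beta_hat` (or `NULL`) and `cov_beta`.
#' @export
gls_beta_cov <- function(X, Sigma, y = NULL) {
  L <- chol(Sigma)
  Xs <- backsolve(L, X, transpose = TRUE)
  XtSiX <- crossprod(Xs)
  cov_beta <- tryCatch(chol2inv(chol(XtSiX)), error = function(e) {
    stop("singular X' Sigma^-1 X: is the design matrix full rank?")
  })
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  beta_hat <- NULL
  if (!is.null(y)) {
    ys <- backsolve(L, y, transpose = TRUE)
    beta_hat <- as.numeric(cov_beta %*% crossprod(Xs, ys))
    names(beta_hat) <- colnames(X)
  }
  list(beta_hat = beta_hat, cov_beta = cov_beta)
}

# negative (restricted) log-likelihood and its analytic gradient in log-theta
neg_loglik_factory <- function(X, y, dist, method, template, range_convention) {
  n <- length(y)
  p <- ncol(X)
  reml <- method == "REML"
  nll <- function(logtheta) {
    theta <- theta_like(template, exp(logtheta))
    Sigma <- covariance_matrix(dist, theta, range_convention)
    L <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    logdet <- 2 * sum(log(diag(L)))
    Xs <- backsolve(L, X, transpose = TRUE)
    ys <- backsolve(L, y, transpose = TRUE)
    XtSiX <- crossprod(Xs)
    cXt <- tryCatch(chol(XtSiX), error = function(e) NULL)
    if (is.null(cXt)) return(1e10)
    beta <- backsolve(cXt, backsolve(cXt, crossprod(Xs, ys), transpose = TRUE))
    r <- ys - Xs %*% beta
    quad <- sum(r^2)
    val <- 0.5 * (logdet + quad + n * log(2 * pi))
    if (reml) {
      val <- val + 0.5 * (2 * sum(log(diag(cXt))) - p * log(2 * pi))
    }
    as.numeric(val)
  }
  gr <- function(logtheta) {
    theta <- theta_like(template, exp(logtheta))
    Sigma <- covariance_matrix(dist, theta, range_convention)
    L <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(L)) return(rep(0, length(logtheta)))
    Si <- chol2inv(L)
    Xs <- backsolve(L, X, transpose = TRUE)
    XtSiX <- crossprod(Xs)
    cXt <- chol(XtSiX)
    SiX <- Si %*% X
    # P = Si - SiX (X'SiX)^-1 X'Si ; Py = Si (y - X beta_gls)
    B <- t(backsolve(cXt, t(SiX), transpose = TRUE)) # SiX %*% (chol)^-1
    Q <- if (method == "REML") Si - tcrossprod(B) else Si
    beta <- backsolve(cXt, backsolve(cXt, crossprod(SiX, y), transpose = TRUE))
    Py <- as.numeric(Si %*% (y - X %*% beta))
    derivs <- covariance_derivs(dist, theta, range_convention)
    g <- vapply(seq_along(theta), function(j) {
      Sj <- derivs[[j]]
      0.5 * (sum(Q * Sj) - sum(Py * (Sj %*% Py)))
    }, numeric(1))
    g * as.numeric(theta) # chain rule to log scale
  }
  list(nll = nll, gr = gr)
}

#' Fit the geostatistical linear model by ML or REML
#'
#' Maximises the Gaussian (restricted) log-likelihood over the logarithm of
#' the covariance parameters with box bounds and multi-start L-BFGS-B,
#' returning GLS fixed effects at the optimum, the fixed-effect covariance,
#' and log-scale standard errors taken from the inverse observed information
#' of the profile objective (used to build log-normal priors from a fit).
#'
#' @param X design matrix (with intercept column if wanted).
#' @param y response vector.
#' @param dist `stream_dist` over the observation sites.
#' @param method `"REML"` (default) or `"ML"`.
#' @param components which covariance components to include.
#' @param init optional [cov_params()] initial values; by default sills
#'   split the sample variance, ranges start at the median nonzero distance
#'   and the nugget at 10% of the sample variance.
#' @param n_starts number of jittered starts (default 3).
#' @param bounds bounds for log-parameters (default `c(-20, 20)`).
#' @param reltol relative convergence tolerance (default `1e-8`).
#' @param range_convention see [covariance_matrix()].
#' @param se whether to compute log-scale standard errors (default TRUE).
#' @return An object of class `stream_model_fit` with elements `theta`,
#'   `beta_hat`, `cov_beta`, `loglik`, `logscale_se`, `converged`, `method`.
#' @export
fit_model <- function(X, y, dist, method = c("REML", "ML"),
                      components = c("tailup", "taildown", "nugget"),
                      init = NULL, n_starts = 3L, bounds = c(-20, 20),
                      reltol = 1e-8, range_convention = "effective",
                      se = TRUE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  if (n <= ncol(X)) stop("need more observations than fixed effects")
  template <- default_init(X, y, dist, components)
  if (!is.null(init)) {
    stopifnot(identical(names(init), names(template)))
    template <- init
  }
  obj <- neg_loglik_factory(X, y, dist, method, template, range_convention)
  lt0 <- log(as.numeric(template))
  starts <- list(lt0)
  if (n_starts > 1) {
    jit <- withr::with_seed(20241L, lapply(seq_len(n_starts - 1), function(i) {
      lt0 + stats::rnorm(length(lt0), 0, 0.5)
    }))
    starts <- c(starts, jit)
  }
  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj$nll, gr = obj$gr, method = "L-BFGS-B",
                   lower = bounds[1], upper = bounds[2],
                   control = list(factr = reltol / .Machine$double.eps,
                                  maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) any_conv <- TRUE
  }
  if (is.null(best)) stop("likelihood could not be evaluated at any start ",
                          "(singular covariance at initialization?)")
  theta_hat <- theta_like(template, exp(best$par))
  Sigma <- covariance_matrix(dist, theta_hat, range_convention)
  gls <- gls_beta_cov(X, Sigma, y)
  logscale_se <- rep(NA_real_, length(theta_hat))
  converged <- any_conv && best$convergence == 0
  if (se) {
    Hh <- tryCatch(stats::optimHess(best$par, obj$nll, gr = obj$gr),
                   error = function(e) NULL)
    if (!is.null(Hh)) {
      # inverse observed information with an eigenvalue floor: directions
      # with no curvature (e.g. the range of a component whose sill sits at
      # zero) get very large, not undefined, standard errors
      eg <- eigen((Hh + t(Hh)) / 2, symmetric = TRUE)
      floor_ev <- max(eg$values, 1e-8) * 1e-10
      lam <- pmax(eg$values, floor_ev)
      Vi <- eg$vectors %*% (t(eg$vectors) / lam)
      logscale_se <- sqrt(pmax(diag(Vi), 0))
    } else {
      converged <- FALSE
    }
  }
  names(logscale_se) <- names(theta_hat)
  structure(list(theta = theta_hat, beta_hat = gls$beta_hat,
                 cov_beta = gls$cov_beta, loglik = -best$value,
                 logscale_se = logscale_se, converged = converged,
                 method = method, range_convention = range_convention),
            class = "stream_model_fit")
}

default_init <- function(X, y, dist, components) {
  vy <- stats::var(y)
  n_sill <- sum(c("tailup", "taildown") %in% components) + 1
  h <- dist$H[upper.tri(dist$H)]
  med_h <- stats::median(h[h > 0])
  if (!is.finite(med_h) || med_h <= 0) med_h <- 1
  args <- list(sigma2_nugget = max(0.1 * vy, 1e-6))
  if ("tailup" %in% components) {
    args$sigma2_tailup <- vy / n_sill
    args$range_tailup <- med_h
  }
  if ("taildown" %in% components) {
    args$sigma2_taildown <- vy / n_sill
    args$range_taildown <- med_h
  }
  do.call(cov_params, args)
}

#' @export
print.stream_model_fit <- function(x, ...) {
  cat("stream_model_fit (", x$method, "), loglik = ",
      signif(x$loglik, 6), if (!x$converged) " [NOT converged]", "\n", sep = "")
  print(x$theta)
  cat("beta_hat:", paste(signif(x$beta_hat, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Expected Fisher information for the covariance parameters
#'
#' \deqn{I_{jk}(\theta) = \tfrac12 \mathrm{tr}(Q \Sigma_j Q \Sigma_k)}
#' with \eqn{\Sigma_j = \partial\Sigma/\partial\theta_j} analytic for the
#' exponential components, and `Q` either \eqn{\Sigma^{-1}} (ML form, the
#' default) or the REML projection
#' \eqn{\Sigma^{-1} - \Sigma^{-1}X(X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}}.
#'
#' @param theta a [cov_params()].
#' @param dist a `stream_dist` over the design sites.
#' @param X design matrix; required for the REML form, ignored otherwise.
#' @param form `"ML"` (default) or `"REML"`.
#' @param range_convention see [covariance_matrix()].
#' @param Sigma optionally, a precomputed covariance matrix for `theta`.
#' @return A symmetric positive-semidefinite matrix, one row/column per
#'   covariance parameter.
#' @export
fisher_information <- function(theta, dist, X = NULL, form = c("ML", "REML"),
                               range_convention = "effective", Sigma = NULL) {
  form <- match.arg(form)
  if (is.null(Sigma)) Sigma <- covariance_matrix(dist, theta, range_convention)
  L <- chol(Sigma)
  Q <- chol2inv(L)
  if (form == "REML") {
    if (is.null(X)) stop("the REML form needs the design matrix X")
    SiX <- Q %*% X
    XtSiX <- crossprod(X, SiX)
    B <- t(backsolve(chol(XtSiX), t(SiX), transpose = TRUE))
    Q <- Q - tcrossprod(B)
  }
  derivs <- covariance_derivs(dist, theta, range_convention)
  M <- lapply(derivs, function(Sj) Q %*% Sj)
  p <- length(M)
  I <- matrix(0, p, p, dimnames = list(names(theta), names(theta)))
  for (j in seq_len(p)) {
    for (k in j:p) {
      I[j, k] <- I[k, j] <- 0.5 * sum(M[[j]] * t(M[[k]]))
    }
  }
  I
}

# kriging core on precomputed blocks: Sigma_obs (n x n), Sigma_cross
# (n x q), prior variances sigma2_pred (length q)
krige_core <- function(Sigma_obs, Sigma_cross, sigma2_pred, X_obs, X_pred,
                       y_obs = NULL) {
  L <- chol(Sigma_obs)
  Xs <- backsolve(L, X_obs, transpose = TRUE)
  Cs <- backsolve(L, Sigma_cross, transpose = TRUE)
  XtSiX <- crossprod(Xs)
  cXt <- chol(XtSiX)
  # m_z = x_z - X' Si c_z, per prediction site (columns)
  Mz <- t(X_pred) - crossprod(Xs, Cs)
  Ms <- backsolve(cXt, Mz, transpose = TRUE)
  var_pred <- sigma2_pred - colSums(Cs^2) + colSums(Ms^2)
  pred <- NULL
  if (!is.null(y_obs)) {
    ys <- backsolve(L, y_obs, transpose = TRUE)
    beta <- backsolve(cXt, backsolve(cXt, crossprod(Xs, ys), transpose = TRUE))
    rs <- ys - Xs %*% beta
    pred <- as.numeric(X_pred %*% beta + crossprod(Cs, rs))
  }
  list(pred = pred, var = as.numeric(var_pred))
}

#' Universal kriging predictions and variances
#'
#' Best linear unbiased prediction under the geostatistical linear model:
#' \deqn{\hat y(s_z) = x_z'\hat\beta + c_z'\Sigma^{-1}(y - X\hat\beta)}
#' \deqn{Var(\hat y(s_z)) = \sigma_z^2 - c_z'\Sigma^{-1}c_z
#'   + m_z'(X'\Sigma^{-1}X)^{-1}m_z, \quad m_z = x_z - X'\Sigma^{-1}c_z.}
#' Variances do not require observed data, so `y_obs` may be `NULL` (as in
#' prediction-oriented design criteria).
#'
#' @param theta a [cov_params()].
#' @param dist_joint a `stream_dist` over observed and prediction sites.
#' @param obs_idx,pred_idx integer indices into `dist_joint` rows.
#' @param X_obs,X_pred design matrices for the two site groups.
#' @param y_obs optional observations.
#' @param range_convention see [covariance_matrix()].
#' @return List with `pred` (or `NULL`) and `var`.
#' @export
krige <- function(theta, dist_joint, obs_idx, pred_idx, X_obs, X_pred,
                  y_obs = NULL, range_convention = "effective") {
  Sigma <- covariance_matrix(dist_joint, theta, range_convention)
  krige_core(Sigma[obs_idx, obs_idx, drop = FALSE],
             Sigma[obs_idx, pred_idx, drop = FALSE],
             diag(Sigma)[pred_idx],
             as.matrix(X_obs), as.matrix(X_pred), y_obs)
}
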
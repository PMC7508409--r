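test_that("covariance matrix matches the closed form on the Y network", {
  net <- y_network()
  d <- distance_structure(net, y_sites())
  theta <- theta_full()
  S <- covariance_matrix(d, theta)
  expect_equal(unname(diag(S)), rep(2.5, 3)) # sum of sills + nugget
  # flow-unconnected: tail-up term zero, tail-down exp(-3*2/6) = e^-1
  expect_equal(S["s1", "s2"], exp(-1), tolerance = 1e-9)
  # flow-connected: W * e^-1 + e^-1
  expect_equal(S["s1", "s3"], sqrt(0.5) * exp(-1) + exp(-1), tolerance = 1e-9)
  # natural convention drops the factor 3
  Sn <- covariance_matrix(d, theta, range_convention = "natural")
  expect_equal(Sn["s1", "s2"], exp(-2 / 6), tolerance = 1e-9)
  expect_error(cov_params(-1, 6, 1, 6, 0.5), "positive")
})

test_that("tail-down depends on total hydrologic distance only", {
  # flow-connected and flow-unconnected pairs at equal H get equal
  # tail-down contribution
  theta_td <- cov_params(sigma2_taildown = 1.3, range_taildown = 4,
                         sigma2_nugget = 0.2)
  net <- y_network()
  d <- distance_structure(net, y_sites())
  S <- covariance_matrix(d, theta_td)
  expect_equal(S["s1", "s2"], S["s1", "s3"]) # both pairs have H = 2
})

test_that("covariance is positive definite across random instances", {
  for (s in 1:10) {
    ctx <- random_instance(s, n_per_edge = 2L)
    theta <- withr::with_seed(s, theta_like(theta_full(),
                                            exp(stats::rnorm(5, 0, 0.7))))
    S <- covariance_matrix(ctx$dist_joint, theta)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("analytic covariance derivatives match finite differences", {
  ctx <- random_instance(11, n_per_edge = 2L)
  d <- ctx$dist_joint
  theta <- theta_full()
  derivs <- streamdesign:::covariance_derivs(d, theta)
  for (j in seq_along(theta)) {
    h <- 1e-5 * theta[[j]]
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    fd <- (covariance_matrix(d, tp) - covariance_matrix(d, tm)) / (2 * h)
    expect_equal(unname(derivs[[j]]), unname(fd), tolerance = 1e-4)
  }
})

test_that("simulated responses have the requested first two moments", {
  net <- y_network()
  sites <- y_sites()
  d <- distance_structure(net, sites)
  theta <- theta_full()
  X <- cbind(1, c(0, 1, 2))
  beta <- c(3, -1)
  y1 <- simulate_response(d, theta, X, beta, seed = 4)
  expect_identical(y1, simulate_response(d, theta, X, beta, seed = 4))
  Y <- simulate_response(d, theta, X, beta, seed = 5, n_rep = 4000)
  expect_equal(unname(rowMeans(Y)), as.numeric(X %*% beta), tolerance = 0.1)
  S_hat <- stats::cov(t(Y))
  expect_equal(unname(S_hat), unname(covariance_matrix(d, theta)),
               tolerance = 0.2)
  # nugget-only degenerates to white noise
  Yn <- simulate_response(d, theta_nugget(2), X, beta, seed = 6, n_rep = 4000)
  R <- t(Yn) - rep(as.numeric(X %*% beta), each = 4000)
  expect_equal(unname(apply(R, 2, stats::var)), rep(2, 3), tolerance = 0.15)
  expect_lt(max(abs(stats::cor(R)[upper.tri(diag(3))])), 0.06)
})

test_that("GLS reduces to the sample mean under iid errors and matches a
           brute-force solve in general", {
  X <- matrix(1, 4, 1)
  g <- gls_beta_cov(X, diag(4), y = c(1, 2, 3, 4))
  expect_equal(unname(g$beta_hat), 2.5)
  expect_equal(unname(g$cov_beta[1, 1]), 0.25)
  g4 <- gls_beta_cov(X, 4 * diag(4))
  expect_equal(unname(g4$cov_beta[1, 1]), 1.0)
  withr::with_seed(8, {
    X2 <- cbind(1, stats::rnorm(6))
    A <- matrix(stats::rnorm(36), 6)
    Sg <- crossprod(A) + diag(6)
    y <- stats::rnorm(6)
  })
  g2 <- gls_beta_cov(X2, Sg, y)
  Si <- solve(Sg)
  cb <- solve(t(X2) %*% Si %*% X2)
  expect_equal(unname(g2$cov_beta), unname(cb), tolerance = 1e-10)
  expect_equal(unname(g2$beta_hat),
               as.numeric(cb %*% t(X2) %*% Si %*% y), tolerance = 1e-10)
})

test_that("REML objective equals the error-contrast likelihood up to a
           theta-free constant, and its gradient is exact", {
  ctx <- random_instance(21, n_per_edge = 2L)
  d <- ctx$dist_joint
  n <- nrow(d$H)
  withr::with_seed(3, {
    X <- cbind(1, stats::rnorm(n))
  })
  theta <- theta_full()
  y <- simulate_response(d, theta, X, c(1, 2), seed = 9)
  obj <- streamdesign:::neg_loglik_factory(X, y, d, "REML", theta, "effective")
  contrast_nll <- function(th) {
    K <- qr.Q(qr(X), complete = TRUE)[, (ncol(X) + 1):n]
    V <- t(K) %*% covariance_matrix(d, th) %*% K
    Ky <- t(K) %*% y
    as.numeric(0.5 * (determinant(V, log = TRUE)$modulus +
                        t(Ky) %*% solve(V, Ky) + (n - ncol(X)) * log(2 * pi)))
  }
  th2 <- theta_like(theta, as.numeric(theta) * c(1.3, 0.8, 0.7, 1.5, 1.1))
  diff_pkg <- obj$nll(log(as.numeric(theta))) - obj$nll(log(as.numeric(th2)))
  diff_ora <- contrast_nll(theta) - contrast_nll(th2)
  expect_equal(diff_pkg, diff_ora, tolerance = 1e-8)
  lt <- log(as.numeric(theta))
  fd <- vapply(seq_along(lt), function(j) {
    e <- replace(rep(0, length(lt)), j, 1e-6)
    (obj$nll(lt + e) - obj$nll(lt - e)) / 2e-6
  }, numeric(1))
  expect_equal(obj$gr(lt), fd, tolerance = 1e-5)
})

test_that("nugget-only fits recover the residual variance", {
  ctx <- line_ctx(seq(0, 199), components = "nugget")
  d <- streamdesign:::dist_subset(ctx$dist_joint, seq_len(200))
  X <- matrix(1, 200, 1)
  y <- simulate_response(d, theta_nugget(2), X, 0.5, seed = 31)
  fit <- fit_model(X, y, d, method = "REML", components = "nugget")
  expect_true(fit$converged)
  expect_equal(fit$theta[["sigma2_nugget"]], stats::var(y), tolerance = 0.1)
})

test_that("ML and REML estimates approach each other as n grows", {
  lay <- survey_layout(10, seed = 13)
  theta <- theta_full()
  gap_at <- function(n_use) {
    idx <- seq_len(n_use)
    d <- streamdesign:::dist_subset(lay$dist, idx)
    X <- matrix(1, n_use, 1)
    y <- simulate_response(d, theta, X, 5, seed = 77)
    ml <- fit_model(X, y, d, method = "ML", se = FALSE)
    reml <- fit_model(X, y, d, method = "REML", se = FALSE)
    mean(abs(log(as.numeric(ml$theta)) - log(as.numeric(reml$theta))))
  }
  expect_lt(gap_at(57), gap_at(18))
})

test_that("Fisher information matches closed forms and finite differences", {
  # Sigma = theta * I, n = 4: I = n / (2 theta^2)
  ctx <- line_ctx(c(0, 3, 6, 9), components = "nugget")
  d4 <- streamdesign:::dist_subset(ctx$dist_joint, 1:4)
  I <- fisher_information(theta_nugget(2), d4)
  expect_equal(unname(I[1, 1]), 4 / (2 * 4))
  # analytic vs central finite differences of the expected information,
  # I_jk = 0.5 tr(Si Sj Si Sk), via numerically differentiated Sigma
  ctxr <- random_instance(31, n_per_edge = 2L)
  theta <- theta_full()
  I_an <- fisher_information(theta, ctxr$dist_joint)
  Si <- solve(covariance_matrix(ctxr$dist_joint, theta))
  fd_deriv <- lapply(seq_along(theta), function(j) {
    h <- 1e-5 * theta[[j]]
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (covariance_matrix(ctxr$dist_joint, tp) -
       covariance_matrix(ctxr$dist_joint, tm)) / (2 * h)
  })
  I_fd <- outer(seq_along(theta), seq_along(theta),
                Vectorize(function(j, k) {
                  0.5 * sum(diag(Si %*% fd_deriv[[j]] %*% Si %*% fd_deriv[[k]]))
                }))
  expect_equal(unname(I_an), I_fd, tolerance = 1e-4)
  # symmetric PSD
  expect_equal(I_an, t(I_an))
  expect_gte(min(eigen(I_an, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # REML form with X: differs from ML form, still PSD
  X <- matrix(1, nrow(ctxr$dist_joint$H), 1)
  I_reml <- fisher_information(theta, ctxr$dist_joint, X = X, form = "REML")
  expect_gte(min(eigen(I_reml, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("information grows when a site is added", {
  for (s in 1:8) {
    ctx <- random_instance(s + 50, n_per_edge = 2L)
    m <- nrow(ctx$dist_joint$H)
    theta <- theta_full()
    idx <- withr::with_seed(s, sample(m, 6))
    I_small <- fisher_information(theta,
                                  streamdesign:::dist_subset(ctx$dist_joint, idx[1:5]))
    I_big <- fisher_information(theta,
                                streamdesign:::dist_subset(ctx$dist_joint, idx))
    expect_gte(determinant(I_big)$modulus, determinant(I_small)$modulus)
  }
})

test_that("universal kriging matches its closed forms and a brute-force
           computation", {
  # 4 iid observations, uncorrelated prediction: var = 1 + 1/4
  ctx <- line_ctx(c(0, 2, 4, 6, 100), components = "nugget")
  kr <- krige(theta_nugget(1), ctx$dist_joint, obs_idx = 1:4, pred_idx = 5,
              X_obs = matrix(1, 4, 1), X_pred = matrix(1, 1, 1),
              y_obs = c(1, 2, 3, 4))
  expect_equal(kr$var, 1.25)
  expect_equal(kr$pred, 2.5) # GLS mean
  # co-located prediction with zero nugget: exact interpolation
  net <- y_network()
  both <- data.frame(site_id = c("a", "b", "z"), edge_id = c("e1", "e2", "e1"),
                     up_dist = c(1.5, 1.5, 1.5))
  dj <- distance_structure(net, both)
  th0 <- cov_params(sigma2_tailup = 1, range_tailup = 5,
                    sigma2_taildown = 1, range_taildown = 5,
                    sigma2_nugget = 1e-12)
  kr0 <- krige(th0, dj, obs_idx = 1:2, pred_idx = 3,
               X_obs = matrix(1, 2, 1), X_pred = matrix(1, 1, 1),
               y_obs = c(2.2, 1.1))
  expect_equal(kr0$var, 0, tolerance = 1e-6)
  expect_equal(kr0$pred, 2.2, tolerance = 1e-5)
  # random instance against an independent solve()-based evaluation
  ctxr <- random_instance(61, n_per_edge = 2L, predictions = TRUE)
  theta <- theta_full()
  n <- ctxr$n_cand
  pidx <- ctxr$pred_idx
  X <- matrix(1, n, 1); Xp <- matrix(1, length(pidx), 1)
  y <- simulate_response(streamdesign:::dist_subset(ctxr$dist_joint, 1:n),
                         theta, X, 4, seed = 12)
  kr1 <- krige(theta, ctxr$dist_joint, 1:n, pidx, X, Xp, y)
  S <- covariance_matrix(ctxr$dist_joint, theta)
  So <- S[1:n, 1:n]; Si <- solve(So)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  for (k in seq_along(pidx)) {
    cz <- S[1:n, pidx[k]]
    mz <- 1 - t(X) %*% Si %*% cz
    v <- S[pidx[k], pidx[k]] - t(cz) %*% Si %*% cz +
      t(mz) %*% solve(t(X) %*% Si %*% X) %*% mz
    expect_equal(kr1$var[k], as.numeric(v), tolerance = 1e-8)
    p <- as.numeric(beta) + t(cz) %*% Si %*% (y - X %*% as.numeric(beta))
    expect_equal(kr1$pred[k], as.numeric(p), tolerance = 1e-8)
  }
})

test_that("adding an observation never inflates a kriging variance", {
  theta <- theta_full()
  for (s in 1:8) {
    ctx <- random_instance(s + 70, n_per_edge = 2L, predictions = TRUE)
    n <- ctx$n_cand
    idx <- withr::with_seed(s, sample(n, 6))
    Xp <- matrix(1, length(ctx$pred_idx), 1)
    v5 <- krige(theta, ctx$dist_joint, idx[1:5], ctx$pred_idx,
                matrix(1, 5, 1), Xp)$var
    v6 <- krige(theta, ctx$dist_joint, idx, ctx$pred_idx,
                matrix(1, 6, 1), Xp)$var
    expect_true(all(v6 <= v5 + 1e-9))
  }
})
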
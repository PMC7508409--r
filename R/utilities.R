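# package-level state: expected-utility evaluation counter and the
# user-utility registry
.sd_state <- new.env(parent = emptyenv())
.sd_state$eval_count <- 0
.sd_state$utilities <- new.env(parent = emptyenv())

#' Expected-utility evaluation counter
#'
#' Every call to [expected_utility()] increments a package-level counter by
#' one, regardless of the Monte-Carlo draw count. The counter ties the
#' optimiser's work to the computation-time model (see [cost_model()]): each
#' greedy sweep performs exactly `n_free * (N - n)` evaluations.
#'
#' @return `eval_count()`: the current count. `reset_eval_count()`: the
#'   previous count, invisibly.
#' @export
eval_count <- function() .sd_state$eval_count

#' @rdname eval_count
#' @export
reset_eval_count <- function() {
  old <- .sd_state$eval_count
  .sd_state$eval_count <- 0
  invisible(old)
}

#' Bundle a design problem: network, candidates, model and predictions
#'
#' Precomputes the joint hydrologic distance structure over the candidate
#' and prediction sites, the fixed-effect design matrices, and the
#' inter-candidate distance matrix used by space-filling criteria, so that
#' every subsequent design evaluation reduces to indexing plus small dense
#' linear algebra.
#'
#' @param net a `stream_network`.
#' @param candidates candidate site table (the `N` potential sampling
#'   locations).
#' @param fixed_effects character vector of covariate column names; an
#'   intercept is always included.
#' @param beta true fixed-effect values (intercept first) used when
#'   simulating responses, e.g. by empirical utilities. Optional otherwise.
#' @param predictions optional prediction site table (required by the
#'   kriging-variance criteria).
#' @param components covariance components of the assumed model.
#' @param range_convention see [covariance_matrix()].
#' @param fisher_form `"ML"` (default) or `"REML"` form of the information
#'   matrix used by estimation criteria.
#' @param spacefill_distance `"hydrologic"` (default) or `"euclidean"`
#'   distances for the space-filling scores.
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(net, candidates, fixed_effects = character(0),
                           beta = NULL, predictions = NULL,
                           components = c("tailup", "taildown", "nugget"),
                           range_convention = "effective",
                           fisher_form = "ML",
                           spacefill_distance = c("hydrologic", "euclidean")) {
  spacefill_distance <- match.arg(spacefill_distance)
  candidates <- validate_sites(net, candidates)
  N <- nrow(candidates)
  if (!is.null(predictions)) {
    predictions <- validate_sites(net, predictions)
    both <- rbind(
      candidates[c("site_id", "edge_id", "up_dist")],
      within(predictions[c("site_id", "edge_id", "up_dist")],
             site_id <- paste0(".pred.", site_id))
    )
    dist_joint <- distance_structure(net, both)
    pred_idx <- N + seq_len(nrow(predictions))
  } else {
    dist_joint <- distance_structure(net, candidates)
    pred_idx <- integer(0)
  }
  X_cand <- model_matrix_sites(candidates, fixed_effects)
  if (qr(X_cand)$rank < ncol(X_cand)) {
    stop("fixed-effect design matrix is rank deficient on the candidate set")
  }
  X_pred <- if (is.null(predictions)) NULL else
    model_matrix_sites(predictions, fixed_effects)
  D_space <- if (spacefill_distance == "hydrologic") {
    dist_joint$H[seq_len(N), seq_len(N), drop = FALSE]
  } else {
    if (is.null(candidates$x) || is.null(candidates$y)) {
      stop("euclidean space-filling distances need x,y candidate coordinates")
    }
    as.matrix(stats::dist(candidates[c("x", "y")]))
  }
  if (!is.null(beta)) {
    if (length(beta) != ncol(X_cand)) {
      stop("beta must have one entry per fixed-effect column (incl. intercept)")
    }
  }
  structure(list(net = net, candidates = candidates,
                 predictions = predictions,
                 fixed_effects = fixed_effects, beta = beta,
                 dist_joint = dist_joint, n_cand = N, pred_idx = pred_idx,
                 X_cand = X_cand, X_pred = X_pred, D_space = D_space,
                 components = components,
                 range_convention = range_convention,
                 fisher_form = fisher_form),
            class = "design_problem")
}

model_matrix_sites <- function(sites, fixed_effects) {
  miss <- setdiff(fixed_effects, names(sites))
  if (length(miss) > 0) {
    stop("site table lacks covariate column(s): ", paste(miss, collapse = ", "))
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(sites)))
  if (length(fixed_effects) > 0) {
    X <- cbind(X, as.matrix(sites[fixed_effects]))
  }
  X
}

#' @export
print.design_problem <- function(x, ...) {
  cat("design_problem:", x$n_cand, "candidates,",
      length(x$pred_idx), "prediction sites,",
      ncol(x$X_cand), "fixed effects\n")
  invisible(x)
}

#' Independent log-normal priors on the covariance parameters
#'
#' Each covariance parameter gets an independent log-normal prior with
#' location `meanlog` and scale `sdlog`; `sdlog = 0` denotes a point mass
#' at `exp(meanlog)`.
#'
#' @param meanlog,sdlog numeric vectors, one entry per covariance parameter
#'   (recycled if scalar); names are taken from `theta` when supplied.
#' @param theta optional [cov_params()] supplying the parameter names, with
#'   `meanlog` defaulting to `log(theta)`.
#' @return A `prior_spec` data-frame-like list.
#' @examples
#' prior_spec(theta = cov_params(1, 6, 1, 6, 0.5), sdlog = 0.5)
#' @export
prior_spec <- function(meanlog = NULL, sdlog, theta = NULL) {
  if (!is.null(theta)) {
    if (is.null(meanlog)) meanlog <- log(as.numeric(theta))
    nms <- names(theta)
  } else {
    if (is.null(names(meanlog))) stop("supply named meanlog or a theta template")
    nms <- names(meanlog)
  }
  p <- length(nms)
  meanlog <- rep_len(as.numeric(meanlog), p)
  sdlog <- rep_len(as.numeric(sdlog), p)
  if (any(sdlog < 0)) stop("sdlog must be nonnegative")
  structure(list(param = nms, meanlog = meanlog, sdlog = sdlog),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec (log-normal):\n")
  print(data.frame(param = x$param, meanlog = signif(x$meanlog, 4),
                   sdlog = signif(x$sdlog, 4)))
  invisible(x)
}

#' Log-normal priors constructed from a model fit
#'
#' Sets `meanlog` to the log of the (RE)ML covariance-parameter estimates
#' and `sdlog` to the log-scale standard errors of the fit (or a supplied
#' vector, e.g. externally reported standard errors).
#'
#' @param fit a `stream_model_fit`.
#' @param sdlog optional replacement log-scale standard errors.
#' @param sdlog_max cap on the prior log-scale spread (default 2, i.e. a
#'   weakly informative prior spanning roughly four orders of magnitude);
#'   protects against effectively flat information directions, e.g. the
#'   range of a component whose sill was estimated near zero.
#' @return A [prior_spec()].
#' @export
priors_from_fit <- function(fit, sdlog = NULL, sdlog_max = 2) {
  if (is.null(sdlog)) sdlog <- fit$logscale_se
  if (anyNA(sdlog)) stop("fit has no usable log-scale standard errors")
  prior_spec(meanlog = log(as.numeric(fit$theta)),
             sdlog = pmin(sdlog, sdlog_max), theta = fit$theta)
}

#' Draw covariance parameters from log-normal priors
#'
#' @param priors a [prior_spec()].
#' @param M number of Monte-Carlo draws.
#' @param seed integer seed; draws are deterministic given the seed.
#' @return An `M x p` matrix of positive draws, columns named by parameter.
#' @export
draw_priors <- function(priors, M, seed = 1L) {
  stopifnot(inherits(priors, "prior_spec"), M >= 1)
  p <- length(priors$param)
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(M * p), M, p)
    draws <- exp(sweep(sweep(z, 2, priors$sdlog, `*`), 2, priors$meanlog, `+`))
    colnames(draws) <- priors$param
    draws
  })
}

#' Monte-Carlo expected-utility configuration
#'
#' Fixes the utility, the prior draws and the bookkeeping shared by all
#' design evaluations in one optimisation run. The draw matrix is generated
#' once and reused for every candidate design (common random numbers), so
#' comparisons between designs are deterministic given the seed.
#'
#' @param utility one of `"D"`, `"CP"`, `"CPD"`, `"K"`, `"ED"`, `"EK"`,
#'   `"seqD"`, `"seqCP"`, `"seqED"`, `"maximin"`, `"morris_mitchell"`, or
#'   `"user:<name>"` for a registered utility.
#' @param priors a [prior_spec()] (not needed by space-filling criteria).
#' @param M Monte-Carlo draw count (forced to 1 for space-filling).
#' @param seed integer seed controlling the draws and any per-draw
#'   simulation inside empirical utilities.
#' @param draw_matrix optionally, an explicit `M x p` draw matrix.
#' @param O_t summary-statistic carrier for sequential utilities: a fixed
#'   PSD matrix or a function `theta -> matrix` rebuilt per draw.
#' @param p Morris-Mitchell weighting power (>= 1).
#' @param fit_method estimation method used inside empirical utilities.
#' @param cache_sigma cache the full joint covariance per draw (speeds up
#'   repeated design evaluations; uses `M * (N+q)^2` doubles of memory).
#' @return An `eu_config` object (an environment, so caches persist).
#' @export
eu_config <- function(utility, priors = NULL, M = 500L, seed = 1L,
                      draw_matrix = NULL, O_t = NULL, p = 2,
                      fit_method = "REML", cache_sigma = TRUE) {
  spacefill <- utility %in% c("maximin", "morris_mitchell")
  if (spacefill) M <- 1L
  if (is.null(draw_matrix) && !spacefill) {
    if (is.null(priors)) stop("eu_config needs priors or an explicit draw_matrix")
    draw_matrix <- draw_priors(priors, M, seed)
  }
  if (!is.null(draw_matrix)) {
    if (any(draw_matrix <= 0)) stop("draw_matrix rows must be positive")
    M <- nrow(draw_matrix)
  }
  if (p < 1) stop("Morris-Mitchell power p must be >= 1")
  cfg <- new.env(parent = emptyenv())
  cfg$utility <- utility
  cfg$priors <- priors
  cfg$M <- as.integer(M)
  cfg$seed <- as.integer(seed)
  cfg$draw_matrix <- draw_matrix
  cfg$O_t <- O_t
  cfg$p <- p
  cfg$fit_method <- fit_method
  cfg$cache_sigma <- isTRUE(cache_sigma)
  cfg$sigma_cache <- vector("list", M)
  cfg$n_failed_last <- 0L
  class(cfg) <- "eu_config"
  cfg
}

theta_from_draw <- function(draw) {
  structure(stats::setNames(as.numeric(draw), names(draw)),
            class = "cov_params")
}

# full joint covariance for draw m, cached inside cfg
sigma_for_draw <- function(cfg, ctx, m) {
  if (cfg$cache_sigma && !is.null(cfg$sigma_cache[[m]])) {
    return(cfg$sigma_cache[[m]])
  }
  theta <- theta_from_draw(cfg$draw_matrix[m, ])
  S <- covariance_matrix(ctx$dist_joint, theta, ctx$range_convention)
  if (cfg$cache_sigma) cfg$sigma_cache[[m]] <- S
  S
}

logdet_pd <- function(M) {
  d <- determinant(M, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' Estimation and prediction utility functions
#'
#' Per-draw design-quality criteria, all oriented so that larger is better:
#' \describe{
#'   \item{`utility_D`}{`log det(X_d' Sigma_d^-1 X_d)`, the log-determinant
#'     of the inverse GLS fixed-effect covariance.}
#'   \item{`utility_CP`}{`log det I(theta; d)`, the log-determinant of the
#'     expected Fisher information for the covariance parameters.}
#'   \item{`utility_CPD`}{their sum, targeting both parameter groups.}
#'   \item{`utility_K`}{the inverse of the summed universal-kriging
#'     variances over the prediction sites.}
#' }
#' A design whose information matrix is singular returns `-Inf` (the design
#' is rejected, not an error).
#'
#' @param design integer vector of candidate indices.
#' @param theta a [cov_params()] (or a named positive vector).
#' @param ctx a [design_problem()].
#' @param Sigma optional precomputed joint covariance over all candidate and
#'   prediction sites (as cached by the optimiser).
#' @return A single number.
#' @export
utility_D <- function(design, theta, ctx, Sigma = NULL) {
  Sd <- design_sigma(design, theta, ctx, Sigma)
  Xd <- ctx$X_cand[design, , drop = FALSE]
  L <- tryCatch(chol(Sd), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  Xs <- backsolve(L, Xd, transpose = TRUE)
  logdet_pd(crossprod(Xs))
}

design_sigma <- function(design, theta, ctx, Sigma = NULL) {
  if (!is.null(Sigma)) return(Sigma[design, design, drop = FALSE])
  covariance_matrix(dist_subset(ctx$dist_joint, design), theta,
                    ctx$range_convention)
}

#' @rdname utility_D
#' @export
utility_CP <- function(design, theta, ctx, Sigma = NULL) {
  dd <- dist_subset(ctx$dist_joint, design)
  Sd <- if (is.null(Sigma)) NULL else Sigma[design, design, drop = FALSE]
  I <- tryCatch(
    fisher_information(theta, dd,
                       X = ctx$X_cand[design, , drop = FALSE],
                       form = ctx$fisher_form,
                       range_convention = ctx$range_convention, Sigma = Sd),
    error = function(e) NULL)
  if (is.null(I)) return(-Inf)
  logdet_pd(I)
}

#' @rdname utility_D
#' @export
utility_CPD <- function(design, theta, ctx, Sigma = NULL) {
  utility_D(design, theta, ctx, Sigma) + utility_CP(design, theta, ctx, Sigma)
}

#' @rdname utility_D
#' @export
utility_K <- function(design, theta, ctx, Sigma = NULL) {
  if (length(ctx$pred_idx) == 0) {
    stop("utility_K needs prediction sites in the design_problem")
  }
  if (is.null(Sigma)) {
    Sigma <- covariance_matrix(ctx$dist_joint, theta, ctx$range_convention)
  }
  kr <- tryCatch(
    krige_core(Sigma[design, design, drop = FALSE],
               Sigma[design, ctx$pred_idx, drop = FALSE],
               diag(Sigma)[ctx$pred_idx],
               ctx$X_cand[design, , drop = FALSE], ctx$X_pred),
    error = function(e) NULL)
  if (is.null(kr)) return(-Inf)
  1 / sum(kr$var)
}

# simulate data at the design under theta, re-estimate theta, and return the
# estimation-stage utility at the estimate (the "empirical" criteria)
empirical_fit <- function(design, theta, ctx, cfg, draw_i) {
  if (is.null(ctx$beta)) {
    stop("empirical utilities need true beta values in the design_problem")
  }
  dd <- dist_subset(ctx$dist_joint, design)
  Xd <- ctx$X_cand[design, , drop = FALSE]
  sim_seed <- (cfg$seed + 7919L * draw_i) %% 2147483647L
  y <- simulate_response(dd, theta, Xd, ctx$beta, seed = sim_seed,
                         range_convention = ctx$range_convention)
  fit <- fit_model(Xd, y, dd, method = cfg$fit_method,
                   components = ctx$components, init = theta,
                   n_starts = 1L, range_convention = ctx$range_convention,
                   se = FALSE)
  if (!fit$converged) stop("empirical-utility model fit did not converge")
  fit$theta
}

#' Empirical estimation and prediction utilities
#'
#' Empirical criteria replace the drawn covariance parameters by estimates
#' obtained from data simulated at the design under the draw: `utility_ED`
#' simulates `y` at the design sites from `theta`, re-fits the covariance
#' parameters by (RE)ML, and evaluates [utility_D()] at the estimate;
#' `utility_EK` does the same for [utility_K()]. Fits that fail to converge
#' raise an error, which [expected_utility()] converts into a dropped draw.
#'
#' @inheritParams utility_D
#' @param cfg an [eu_config()] carrying the seed and fit method.
#' @param draw_i index of the Monte-Carlo draw (seeds the simulation).
#' @return A single number.
#' @export
utility_ED <- function(design, theta, ctx, cfg, draw_i = 1L) {
  theta_hat <- empirical_fit(design, theta, ctx, cfg, draw_i)
  utility_D(design, theta_hat, ctx)
}

#' @rdname utility_ED
#' @export
utility_EK <- function(design, theta, ctx, cfg, draw_i = 1L) {
  theta_hat <- empirical_fit(design, theta, ctx, cfg, draw_i)
  utility_K(design, theta_hat, ctx)
}

resolve_Ot <- function(O_t, theta, dim_needed) {
  if (is.null(O_t)) return(matrix(0, dim_needed, dim_needed))
  M <- if (is.function(O_t)) O_t(theta) else O_t
  if (!is.matrix(M) || nrow(M) != dim_needed || ncol(M) != dim_needed) {
    stop("O_t has dimension ", paste(dim(M), collapse = "x"),
         ", expected ", dim_needed, "x", dim_needed)
  }
  M
}

#' Sequential (adaptive) utility functions
#'
#' Sequential criteria add a summary statistic `O_t` carrying the
#' information already held by previously selected sites:
#' `utility_seqCP = log det(I(theta; d) + O_t)` with `O_t` on the
#' information scale (e.g. the Fisher information of the existing sites);
#' `utility_seqD = -log det(Var(beta_gls; d, theta) + O_t)` with `O_t` on
#' the covariance scale (e.g. the GLS covariance of the existing sites),
#' negated so that larger is better; `utility_seqED` is `utility_seqD`
#' evaluated at covariance parameters re-estimated from data simulated at
#' the design. With `O_t = 0` the sequential criteria reduce to their
#' static counterparts (up to the documented sign convention for `seqD`).
#'
#' @inheritParams utility_ED
#' @param O_t PSD matrix or `theta -> matrix` function; dimension must be
#'   the covariance-parameter count for `seqCP` and the fixed-effect count
#'   for `seqD`/`seqED`.
#' @return A single number.
#' @export
utility_seqCP <- function(design, theta, ctx, O_t = NULL, Sigma = NULL) {
  dd <- dist_subset(ctx$dist_joint, design)
  Sd <- if (is.null(Sigma)) NULL else Sigma[design, design, drop = FALSE]
  I <- tryCatch(
    fisher_information(theta, dd, X = ctx$X_cand[design, , drop = FALSE],
                       form = ctx$fisher_form,
                       range_convention = ctx$range_convention, Sigma = Sd),
    error = function(e) NULL)
  if (is.null(I)) return(-Inf)
  logdet_pd(I + resolve_Ot(O_t, theta, nrow(I)))
}

#' @rdname utility_seqCP
#' @export
utility_seqD <- function(design, theta, ctx, O_t = NULL, Sigma = NULL) {
  Sd <- design_sigma(design, theta, ctx, Sigma)
  Xd <- ctx$X_cand[design, , drop = FALSE]
  gl <- tryCatch(gls_beta_cov(Xd, Sd), error = function(e) NULL)
  if (is.null(gl)) return(-Inf)
  p <- ncol(Xd)
  -logdet_pd(gl$cov_beta + resolve_Ot(O_t, theta, p))
}

#' @rdname utility_seqCP
#' @export
utility_seqED <- function(design, theta, ctx, cfg, O_t = NULL, draw_i = 1L) {
  theta_hat <- empirical_fit(design, theta, ctx, cfg, draw_i)
  utility_seqD(design, theta_hat, ctx, O_t)
}

#' Space-filling design scores
#'
#' `maximin_score` is the minimum pairwise distance between design sites;
#' `morris_mitchell_score` is the negated Morris-Mitchell criterion
#' \eqn{-\phi_p = -\left[\sum_w J_w D_w^{-p}\right]^{1/p}} over the sorted
#' unique nonzero inter-site distances \eqn{D_w} with multiplicities
#' \eqn{J_w}. Both are oriented so larger is better, and both return `-Inf`
#' when two design sites coincide. As `p` grows, the Morris-Mitchell
#' ranking converges to the maximin ranking.
#'
#' @param design integer vector of candidate indices.
#' @param D distance matrix over the candidates, or a [design_problem()]
#'   (its `D_space` is used).
#' @param p weighting power, `>= 1`.
#' @return A single number.
#' @export
maximin_score <- function(design, D) {
  if (inherits(D, "design_problem")) D <- D$D_space
  if (length(design) < 2) stop("space-filling scores need n >= 2")
  d <- D[design, design][upper.tri(diag(length(design)))]
  if (any(d == 0)) return(-Inf)
  min(d)
}

#' @rdname maximin_score
#' @export
morris_mitchell_score <- function(design, D, p = 2) {
  if (inherits(D, "design_problem")) D <- D$D_space
  if (length(design) < 2) stop("space-filling scores need n >= 2")
  if (p < 1) stop("p must be >= 1")
  d <- D[design, design][upper.tri(diag(length(design)))]
  if (any(d == 0)) return(-Inf)
  tab <- table(d)
  Dw <- as.numeric(names(tab))
  Jw <- as.numeric(tab)
  -(sum(Jw * Dw^(-p)))^(1 / p)
}

#' Register a user-defined utility function
#'
#' The callable must accept `(design, theta, ctx)` and return a single
#' finite-or-`-Inf` number; it is probed at registration time on a small
#' synthetic design problem, so contract violations surface immediately.
#' Registered utilities are available to [expected_utility()] and the
#' optimiser under the name `"user:<name>"`.
#'
#' @param name short identifier.
#' @param fn the utility callable.
#' @return `name`, invisibly.
#' @export
register_user_utility <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  toy <- toy_problem()
  probe <- fn(c(1L, 2L), toy$theta, toy$ctx)
  if (!is.numeric(probe) || length(probe) != 1) {
    stop("user utility '", name, "' must return a single number; probe ",
         "returned ", class(probe)[1], " of length ", length(probe))
  }
  assign(name, fn, envir = .sd_state$utilities)
  invisible(name)
}

# minimal fixture used to probe user utilities
toy_problem <- function() {
  edges <- data.frame(edge_id = "e1", from_node = "A", to_node = "O",
                      length = 10)
  net <- build_network(edges)
  cand <- place_sites(net, n_per_edge = 4)
  ctx <- design_problem(net, cand, components = "nugget")
  list(ctx = ctx, theta = cov_params(sigma2_nugget = 1))
}

# single-draw utility dispatch
utility_eval <- function(name, design, theta, ctx, cfg, draw_i, Sigma) {
  if (startsWith(name, "user:")) {
    fn <- get0(sub("^user:", "", name), envir = .sd_state$utilities)
    if (is.null(fn)) stop("no user utility registered under '", name, "'")
    return(fn(design, theta, ctx))
  }
  switch(name,
    D = utility_D(design, theta, ctx, Sigma),
    CP = utility_CP(design, theta, ctx, Sigma),
    CPD = utility_CPD(design, theta, ctx, Sigma),
    K = utility_K(design, theta, ctx, Sigma),
    ED = utility_ED(design, theta, ctx, cfg, draw_i),
    EK = utility_EK(design, theta, ctx, cfg, draw_i),
    seqCP = utility_seqCP(design, theta, ctx, cfg$O_t, Sigma),
    seqD = utility_seqD(design, theta, ctx, cfg$O_t, Sigma),
    seqED = utility_seqED(design, theta, ctx, cfg, cfg$O_t, draw_i),
    stop("unknown utility: ", name)
  )
}

#' Monte-Carlo expected utility of a design
#'
#' Averages the per-draw utility over the configuration's shared prior draw
#' matrix. Draws whose utility computation fails (e.g. a non-convergent
#' model fit inside an empirical criterion) are dropped and counted; if
#' more than half fail the evaluation errors out. Space-filling criteria
#' ignore the draws entirely. Each call increments the evaluation counter
#' (see [eval_count()]).
#'
#' @param design integer vector of candidate indices (distinct, `n >= 1`).
#' @param cfg an [eu_config()].
#' @param ctx a [design_problem()].
#' @return The expected utility, with attribute `n_failed` giving the
#'   number of dropped draws.
#' @export
expected_utility <- function(design, cfg, ctx) {
  design <- as.integer(design)
  if (anyDuplicated(design) || length(design) < 1 ||
      any(design < 1 | design > ctx$n_cand)) {
    stop("design must be distinct candidate indices in 1..N")
  }
  .sd_state$eval_count <- .sd_state$eval_count + 1
  if (cfg$utility == "maximin") {
    return(structure(maximin_score(design, ctx$D_space), n_failed = 0L))
  }
  if (cfg$utility == "morris_mitchell") {
    return(structure(morris_mitchell_score(design, ctx$D_space, cfg$p),
                     n_failed = 0L))
  }
  vals <- rep(NA_real_, cfg$M)
  for (m in seq_len(cfg$M)) {
    theta <- theta_from_draw(cfg$draw_matrix[m, ])
    Sigma <- if (cfg$utility %in% c("D", "CP", "CPD", "K", "seqCP", "seqD")) {
      sigma_for_draw(cfg, ctx, m)
    } else NULL
    vals[m] <- tryCatch(
      utility_eval(cfg$utility, design, theta, ctx, cfg, m, Sigma),
      error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(vals))
  cfg$n_failed_last <- n_failed
  if (n_failed > cfg$M / 2) {
    stop("expected_utility: ", n_failed, " of ", cfg$M, " draws failed")
  }
  structure(mean(vals, na.rm = TRUE), n_failed = n_failed)
}
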
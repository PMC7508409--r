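# designs may not contain two co-located sites (zero hydrologic distance):
# such pairs make the tail components singular up to the nugget
valid_members <- function(ctx, design, candidate) {
  H <- ctx$dist_joint$H
  all(H[candidate, design] > 0)
}

random_start <- function(ctx, n_free, fixed, avoid_colocated = TRUE) {
  pool <- setdiff(seq_len(ctx$n_cand), fixed)
  H <- ctx$dist_joint$H
  design <- fixed
  pool <- sample(pool)
  for (c_i in pool) {
    if (length(design) - length(fixed) >= n_free) break
    if (length(design) == 0 || !avoid_colocated ||
        all(H[c_i, design] > 0)) {
      design <- c(design, c_i)
    }
  }
  if (length(design) < length(fixed) + n_free) {
    stop("could not build a starting design without co-located sites")
  }
  sort(design)
}

#' Greedy coordinate-exchange maximisation of the expected utility
#'
#' From each of `K` random starting designs, the algorithm sweeps the free
#' design points in order; for each point it evaluates all `N - n`
#' exchanges with non-member candidates and accepts the best strictly
#' improving one (ties broken by smallest candidate index). Sweeps repeat
#' until a full sweep accepts no exchange. The best design over all starts
#' is returned together with a full trace. With the shared draw matrix in
#' `cfg`, the whole procedure is deterministic given `seed`.
#'
#' Each sweep performs exactly `n_free * (N - n)` expected-utility
#' evaluations, plus one initial evaluation per start, which is what makes
#' the computation-time model of [cost_model()] predictive.
#'
#' @param ctx a [design_problem()].
#' @param n total design size (including any fixed sites).
#' @param cfg an [eu_config()].
#' @param K number of random restarts.
#' @param seed integer seed for the random starts.
#' @param fixed_sites candidate indices held in the design but never
#'   exchanged (e.g. legacy monitoring sites).
#' @return List with `design` (sorted candidate indices), `utility`, and
#'   `trace` (an `optim_trace`: per-exchange records, per-start sweep
#'   counts `L`, and the evaluation count).
#' @export
greedy_exchange <- function(ctx, n, cfg, K = 1L, seed = 1L,
                            fixed_sites = integer(0)) {
  N <- ctx$n_cand
  if (n <= 0) stop("n must be positive")
  if (n > N) stop("n exceeds the number of candidates N = ", N)
  fixed_sites <- sort(unique(as.integer(fixed_sites)))
  if (length(fixed_sites) > 0 &&
      (min(fixed_sites) < 1 || max(fixed_sites) > N)) {
    stop("fixed_sites must be candidate indices")
  }
  n_free <- n - length(fixed_sites)
  if (n_free < 0) stop("more fixed sites than design slots")
  count0 <- eval_count()
  H <- ctx$dist_joint$H
  tol <- 1e-12

  starts <- withr::with_seed(seed, {
    lapply(seq_len(K), function(k) random_start(ctx, n_free, fixed_sites))
  })

  best_design <- NULL
  best_u <- -Inf
  L <- integer(K)
  records <- list()
  for (k in seq_len(K)) {
    design <- starts[[k]]
    free_pos <- which(!design %in% fixed_sites)
    u <- as.numeric(expected_utility(design, cfg, ctx))
    records[[length(records) + 1]] <- data.frame(
      start = k, sweep = 0L, slot = 0L, site_out = NA_integer_,
      site_in = NA_integer_, utility = u, accepted = TRUE)
    sweep <- 0L
    repeat {
      sweep <- sweep + 1L
      improved_any <- FALSE
      for (pos in free_pos) {
        non_members <- setdiff(seq_len(N), design)
        best_exchange <- NA_integer_
        best_val <- u
        for (c_i in non_members) { # ascending index => smallest-index ties win
          trial <- design
          trial[pos] <- c_i
          val <- if (valid_members(ctx, trial[-pos], c_i)) {
            as.numeric(expected_utility(trial, cfg, ctx))
          } else {
            .sd_state$eval_count <- .sd_state$eval_count + 1 # counted, rejected
            -Inf
          }
          if (val > best_val + tol) {
            best_val <- val
            best_exchange <- c_i
          }
        }
        if (!is.na(best_exchange)) {
          records[[length(records) + 1]] <- data.frame(
            start = k, sweep = sweep, slot = pos,
            site_out = design[pos], site_in = best_exchange,
            utility = best_val, accepted = TRUE)
          design[pos] <- best_exchange
          u <- best_val
          improved_any <- TRUE
        }
      }
      if (!improved_any) break
    }
    L[k] <- sweep
    if (u > best_u) {
      best_u <- u
      best_design <- sort(design)
    }
  }
  trace <- structure(list(
    exchanges = do.call(rbind, records),
    L = L, K = K, n = n, n_free = n_free, N = N,
    evaluation_count = eval_count() - count0
  ), class = "optim_trace")
  list(design = best_design, utility = best_u, trace = trace)
}

#' @export
print.optim_trace <- function(x, ...) {
  cat("optim_trace: K =", x$K, "starts, sweeps L =",
      paste(x$L, collapse = ","), "| evaluations:", x$evaluation_count, "\n")
  invisible(x)
}

#' Exhaustive search over all designs of size n
#'
#' Evaluates every `choose(N, n)` design with the shared draw matrix and
#' returns the exact argmax (ties broken by lexicographic index order).
#' Intended as a small-instance oracle for the greedy optimiser.
#'
#' @inheritParams greedy_exchange
#' @param cap refuse instances with more than this many designs (checked
#'   before any evaluation).
#' @return List with `design` and `utility`.
#' @export
exhaustive_search <- function(ctx, n, cfg, cap = 1e5) {
  N <- ctx$n_cand
  if (n <= 0 || n > N) stop("n must be in 1..N")
  n_designs <- choose(N, n)
  if (n_designs > cap) {
    stop("exhaustive_search: ", format(n_designs, big.mark = ","),
         " designs exceeds the cap of ", format(cap, big.mark = ","))
  }
  H <- ctx$dist_joint$H
  best <- NULL
  best_u <- -Inf
  designs <- utils::combn(N, n)
  for (i in seq_len(ncol(designs))) {
    d <- designs[, i]
    if (n > 1 && any(H[d, d][upper.tri(diag(n))] == 0)) next
    u <- as.numeric(expected_utility(d, cfg, ctx))
    if (u > best_u) { # strict: lexicographically first optimum kept
      best_u <- u
      best <- d
    }
  }
  list(design = best, utility = best_u)
}

#' Stepwise site removal under an expected utility
#'
#' Starting from `start`, repeatedly evaluates all single-site deletions
#' and removes the site whose deletion leaves the highest expected utility,
#' until `n_final` sites remain. Priors and draws stay fixed throughout:
#' the model is not refit between steps, so this is a static (not
#' adaptive) procedure. Fixed sites are never removed. Exact ties (common
#' under space-filling scores, where many deletions leave the minimum
#' distance unchanged) are broken in favour of the more dispersed retained
#' design — the largest total pairwise distance — and then by smallest
#' dropped index, keeping the procedure deterministic.
#'
#' @param ctx a [design_problem()].
#' @param start integer vector, the initial design.
#' @param n_final target design size (`>= 1`).
#' @param cfg an [eu_config()].
#' @param fixed_sites candidate indices never removed.
#' @return List with `designs` (one per size from `|start|` down to
#'   `n_final`) and `trajectory`, a data frame of `(n, utility)`.
#' @export
drop_one_stepwise <- function(ctx, start, n_final, cfg,
                              fixed_sites = integer(0)) {
  design <- sort(unique(as.integer(start)))
  if (n_final < 1) stop("n_final must be at least 1")
  if (n_final >= length(design)) stop("n_final must be below the start size")
  u <- as.numeric(expected_utility(design, cfg, ctx))
  designs <- list(design)
  traj <- data.frame(n = length(design), utility = u)
  D <- ctx$D_space
  while (length(design) > n_final) {
    removable <- setdiff(design, fixed_sites)
    vals <- vapply(removable, function(s) {
      as.numeric(expected_utility(setdiff(design, s), cfg, ctx))
    }, numeric(1))
    best_u <- max(vals)
    tied <- removable[vals >= best_u - 1e-12]
    if (length(tied) > 1) {
      spread <- vapply(tied, function(s) {
        keep <- setdiff(design, s)
        sum(D[keep, keep])
      }, numeric(1))
      tied <- tied[spread >= max(spread) - 1e-12]
    }
    best_drop <- tied[1] # ascending order: smallest index among remaining ties
    design <- setdiff(design, best_drop)
    designs[[length(designs) + 1]] <- design
    traj <- rbind(traj, data.frame(n = length(design), utility = best_u))
  }
  list(designs = designs, trajectory = traj)
}

#' Relative efficiency of one design against a reference
#'
#' For positive-scale utilities (kriging-variance based and space-filling)
#' the efficiency is the plain ratio `U(d) / U(d_ref)`. For log-determinant
#' utilities it is the classical determinant-ratio efficiency
#' `exp((U(d) - U(d_ref)) / q)`, where `q` is the dimension of the
#' underlying information matrix (fixed-effect count for D-type, covariance
#' parameter count for CP-type, their sum for CPD). The scale used is
#' recorded in the result's attributes.
#'
#' @param design,design_ref integer index vectors.
#' @param cfg an [eu_config()].
#' @param ctx a [design_problem()].
#' @return Efficiency (1 means equal), with attributes `scale` and `q`.
#' @export
relative_efficiency <- function(design, design_ref, cfg, ctx) {
  u <- as.numeric(expected_utility(design, cfg, ctx))
  u_ref <- as.numeric(expected_utility(design_ref, cfg, ctx))
  sc <- efficiency_scale(cfg$utility, ctx)
  if (sc$type == "ratio") {
    if (u_ref == 0) stop("reference design has zero utility")
    structure(u / u_ref, scale = "ratio", q = NA_real_)
  } else {
    structure(exp((u - u_ref) / sc$q), scale = "logdet", q = sc$q)
  }
}

efficiency_scale <- function(utility, ctx) {
  p <- ncol(ctx$X_cand)
  p_cov <- 2 * sum(c("tailup", "taildown") %in% ctx$components) + 1
  switch(utility,
    K = , EK = , maximin = , morris_mitchell = list(type = "ratio"),
    D = , ED = , seqD = , seqED = list(type = "logdet", q = p),
    CP = , seqCP = list(type = "logdet", q = p_cov),
    CPD = list(type = "logdet", q = p + p_cov),
    list(type = "ratio") # user utilities: ratio, recorded in attributes
  )
}

#' Expected computation time of a greedy-exchange run
#'
#' `K * L * T_sec * n * (N - n) / (3600 * C)` hours, where `K` is the
#' number of random starts, `L` the number of sweeps until convergence,
#' `T_sec` the seconds needed for one expected-utility evaluation, `n` the
#' design size, `N` the candidate count and `C` the number of CPUs.
#'
#' @param K,L,T_sec,n,N,C see description; all positive.
#' @return Hours.
#' @examples
#' cost_model(K = 1, L = 1, T_sec = 1, n = 10, N = 110, C = 1)
#' @export
cost_model <- function(K, L, T_sec, n, N, C = 1) {
  stopifnot(K > 0, L > 0, T_sec > 0, n > 0, N > 0, C > 0)
  K * L * T_sec * n * (N - n) / (3600 * C)
}

#' Create the state object for a myopic adaptive design
#'
#' @param design0 initial design (candidate indices); adaptive designs need
#'   a pre-existing design, typically probability-based or optimal.
#' @param records initial data: data frame with columns `site` (candidate
#'   index), `y`, `step` (0 for historical data). May have repeated sites
#'   (e.g. several years of observation).
#' @param priors initial [prior_spec()].
#' @param T_steps total number of planned adaptive steps.
#' @return An `adaptive_state`.
#' @export
adaptive_state <- function(design0, records, priors, T_steps) {
  design0 <- sort(unique(as.integer(design0)))
  if (length(design0) == 0) stop("adaptive design needs a nonempty initial design")
  stopifnot(all(c("site", "y", "step") %in% names(records)))
  structure(list(t = 0L, designs = list(design0), records = records,
                 priors = priors, T_steps = as.integer(T_steps),
                 fits = list(), halted = FALSE),
            class = "adaptive_state")
}

#' Myopic adaptive design loop
#'
#' At each step the loop (1) fits the geostatistical model to all
#' accumulated data, (2) rebuilds the log-normal priors from the fit
#' (`meanlog = log theta_hat`, `sdlog` = log-scale standard errors),
#' (3) draws a fresh shared prior draw matrix, (4) builds the sequential
#' summary statistic from the existing sites per draw (when a sequential
#' utility is used), (5) runs [greedy_exchange()] for `n_add` new sites
#' with the existing sites held fixed, and (6) acquires data at the sites
#' of the augmented design — simulated from the fitted model, or supplied
#' by `data_source(site_idx, step)` (e.g. a synthetic "true" process or a
#' field campaign).
#'
#' @param state an [adaptive_state()].
#' @param ctx a [design_problem()].
#' @param n_add sites added per step.
#' @param utility utility name (`"K"` or a sequential criterion).
#' @param M Monte-Carlo draw count per step.
#' @param K_starts greedy restarts per step.
#' @param seed integer seed; per-step seeds are derived from it.
#' @param data_source `"fitted"` or a function `(site_idx, step) -> y`
#'   returning observations for the whole augmented design at that step.
#' @param fit_method `"REML"` (default) or `"ML"`.
#' @param steps how many steps to run (default: all remaining).
#' @return The updated `adaptive_state`, with `designs`, `records`, `fits`
#'   and per-step `traces` grown; `halted` is set if a model fit fails.
#' @export
adaptive_loop <- function(state, ctx, n_add, utility = "K", M = 500L,
                          K_starts = 1L, seed = 1L, data_source = "fitted",
                          fit_method = "REML", steps = NULL) {
  stopifnot(inherits(state, "adaptive_state"))
  if (is.null(steps)) steps <- state$T_steps - state$t
  traces <- list()
  for (s in seq_len(steps)) {
    t_now <- state$t + 1L
    current <- state$designs[[length(state$designs)]]
    obs_idx <- state$records$site
    Xo <- ctx$X_cand[obs_idx, , drop = FALSE]
    do <- dist_subset(ctx$dist_joint, obs_idx)
    fit <- tryCatch(
      fit_model(Xo, state$records$y, do, method = fit_method,
                components = ctx$components,
                range_convention = ctx$range_convention),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$logscale_se)) {
      warning("model fit failed at step ", t_now, "; loop halted")
      state$halted <- TRUE
      return(state)
    }
    state$fits[[t_now]] <- fit
    state$priors <- priors_from_fit(fit)
    step_seed <- (seed + 104729L * t_now) %% 2147483647L
    O_t <- sequential_summary(utility, current, fit, ctx)
    cfg <- eu_config(utility, priors = state$priors, M = M,
                     seed = step_seed, O_t = O_t)
    if (length(current) + n_add > ctx$n_cand) stop("candidate set exhausted")
    res <- greedy_exchange(ctx, n = length(current) + n_add, cfg,
                           K = K_starts, seed = step_seed,
                           fixed_sites = current)
    new_design <- res$design
    traces[[s]] <- res$trace
    y_new <- if (is.function(data_source)) {
      data_source(new_design, t_now)
    } else {
      d_new <- dist_subset(ctx$dist_joint, new_design)
      simulate_response(d_new, fit$theta,
                        ctx$X_cand[new_design, , drop = FALSE],
                        fit$beta_hat, seed = step_seed,
                        range_convention = ctx$range_convention)
    }
    state$records <- rbind(state$records,
                           data.frame(site = new_design, y = y_new,
                                      step = t_now))
    state$designs[[length(state$designs) + 1]] <- new_design
    state$t <- t_now
  }
  state$traces <- c(state$traces, traces)
  state
}

# summary statistic carried into sequential utilities: information of the
# existing sites for seqCP (information scale), GLS covariance for
# seqD/seqED (covariance scale); K-type utilities need none because the
# existing sites stay in the design
sequential_summary <- function(utility, existing, fit, ctx) {
  if (!utility %in% c("seqCP", "seqD", "seqED")) return(NULL)
  dd <- dist_subset(ctx$dist_joint, existing)
  Xe <- ctx$X_cand[existing, , drop = FALSE]
  if (utility == "seqCP") {
    function(theta) fisher_information(theta, dd, X = Xe,
                                       form = ctx$fisher_form,
                                       range_convention = ctx$range_convention)
  } else {
    function(theta) {
      S <- covariance_matrix(dd, theta, ctx$range_convention)
      gls_beta_cov(Xe, S)$cov_beta
    }
  }
}

#' Site and observation bookkeeping of a staged monitoring schedule
#'
#' For a programme that starts with `n_legacy` sites observed for
#' `initial_years` years and then adds `n_add[t]` sites at step `t`, with
#' every current site observed once per year, computes the final number of
#' sites and the total number of site-year observations.
#'
#' @param n_legacy initial (legacy) site count.
#' @param n_add vector of per-step additions.
#' @param initial_years years of historical observation before the first
#'   adaptive step.
#' @return List with `final_sites` and `site_year_obs`.
#' @examples
#' schedule_bookkeeping(200, c(50, 50), initial_years = 2)
#' @export
schedule_bookkeeping <- function(n_legacy, n_add, initial_years = 1L) {
  sizes <- n_legacy + cumsum(n_add)
  list(final_sites = n_legacy + sum(n_add),
       site_year_obs = n_legacy * initial_years + sum(sizes))
}
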
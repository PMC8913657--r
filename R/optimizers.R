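# Bound-constrained population metaheuristics behind a single minimize()
# interface.  All four kernels operate on internally normalized coordinates
# u in [0,1]^D (an affine map of the user's bounds; the search itself stays
# linear in the natural parameters).  Candidates are clipped to the box
# before every evaluation, non-finite objective values are treated as +Inf,
# and the running best is recorded after each iteration, so convergence
# histories are non-increasing by construction.

.default_hyperparameters <- list(
  wca = list(n_sr = 4, d_max = 1e-16),
  fpa = list(p_switch = 0.8, levy_exponent = 1.5),
  cs  = list(p_discovery = 0.25, levy_exponent = 1.5, step_scale = 0.01),
  cso = list(rooster_frac = 0.15, hen_frac = 0.7, mother_frac = 0.5,
             reorder_period = 10, fl_min = 0.5, fl_max = 0.9)
)

#' Optimizer configuration
#'
#' Bundles the protocol knobs shared by all four algorithms (population
#' size, iteration budget, number of independent runs, base seed) with the
#' per-algorithm hyperparameters.  The defaults `60 agents / 1800 iterations
#' / 100 runs` mirror the published plant-stem extraction protocol;
#' recovery tests and examples use much smaller budgets.
#'
#' Algorithm hyperparameters default to the original publications' values:
#' WCA with 4 rivers+sea and evaporation threshold `d_max = 1e-16`
#' (linearly decreased); FPA with switch probability 0.8 and Levy exponent
#' 1.5; CS with discovery probability 0.25, Levy flights, and step scale
#' 0.01; CSO with rooster/hen fractions 0.15/0.7, half the hens mothering,
#' and hierarchy reorder period 10.
#'
#' @param algorithm One of `"wca"`, `"fpa"`, `"cs"`, `"cso"`.
#' @param n_agents Population size (>= 2).
#' @param n_iterations Iteration budget (>= 1).
#' @param n_runs Number of independent restarts (>= 1).
#' @param seed Integer base seed; run `k` (0-based) uses `seed + k`.
#' @param hyperparameters Named list overriding algorithm defaults.
#' @return An `optimizer_config` object.
#' @export
optimizer_config <- function(algorithm = c("wca", "fpa", "cs", "cso"),
                             n_agents = 60, n_iterations = 1800,
                             n_runs = 100, seed = 1,
                             hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  n_agents <- as.integer(n_agents)
  n_iterations <- as.integer(n_iterations)
  n_runs <- as.integer(n_runs)
  if (is.na(n_agents) || n_agents < 2L) stop("n_agents must be >= 2")
  if (is.na(n_iterations) || n_iterations < 1L) {
    stop("n_iterations must be >= 1")
  }
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be >= 1")
  hp <- utils::modifyList(.default_hyperparameters[[algorithm]],
                          hyperparameters)
  structure(list(algorithm = algorithm, n_agents = n_agents,
                 n_iterations = n_iterations, n_runs = n_runs,
                 seed = as.integer(seed), hyperparameters = hp),
            class = "optimizer_config")
}

#' @export
print.optimizer_config <- function(x, ...) {
  cat(sprintf("<optimizer_config> %s: %d agents x %d iterations x %d runs, seed %d\n",
              x$algorithm, x$n_agents, x$n_iterations, x$n_runs, x$seed))
  invisible(x)
}

.check_bounds <- function(bounds) {
  if (is.matrix(bounds) && ncol(bounds) == 2L) {
    bounds <- list(lower = bounds[, 1L], upper = bounds[, 2L])
  }
  if (!is.list(bounds) || is.null(bounds$lower) || is.null(bounds$upper)) {
    stop("bounds must be list(lower=, upper=) or a two-column matrix",
         call. = FALSE)
  }
  lo <- as.numeric(bounds$lower); up <- as.numeric(bounds$upper)
  if (length(lo) != length(up) || !all(is.finite(lo)) ||
      !all(is.finite(up)) || any(lo >= up)) {
    stop("bounds must be finite with lower < upper in every dimension",
         call. = FALSE)
  }
  list(lower = lo, upper = up)
}

# Mantegna's algorithm for symmetric Levy-stable steps of index `lam`.
.levy_steps <- function(n, lam) {
  sigma <- (gamma(1 + lam) * sin(pi * lam / 2) /
              (gamma((1 + lam) / 2) * lam * 2^((lam - 1) / 2)))^(1 / lam)
  u <- stats::rnorm(n, sd = sigma)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / lam)
}

.clip01 <- function(u) pmin(pmax(u, 0), 1)

# Shared evaluation wrapper: map normalized coordinates to natural units,
# evaluate, coerce non-finite to +Inf.
.make_eval <- function(objective_fn, lower, upper) {
  span <- upper - lower
  function(u) {
    val <- tryCatch(objective_fn(lower + u * span), error = function(e) Inf)
    if (length(val) != 1L || is.na(val) || !is.finite(val)) Inf else val
  }
}

# Evaluation wrapper in natural coordinates (used by kernels that are
# scale-aware, i.e. CSO's multiplicative rooster update).
.make_eval_nat <- function(objective_fn) {
  function(x) {
    val <- tryCatch(objective_fn(x), error = function(e) Inf)
    if (length(val) != 1L || is.na(val) || !is.finite(val)) Inf else val
  }
}

#' Minimize an objective within a box (single run)
#'
#' Runs the configured algorithm once, seeded from `config$seed`: the
#' population is initialized uniformly within the bounds, every candidate
#' is clipped to the box before evaluation, an objective value that is not
#' finite is treated as `+Inf` (never returned as a best), and the best
#' objective so far is recorded after each iteration.
#'
#' @param objective_fn Function of a numeric vector returning a scalar.
#' @param bounds `list(lower=, upper=)` or a two-column `cbind(lower, upper)`
#'   matrix, finite with `lower < upper` per dimension.
#' @param config An [optimizer_config()].
#' @return A `fit_result` with fields `best_params` (natural units),
#'   `best_objective`, `convergence` (length `n_iterations`,
#'   non-increasing), `run_index`, `seed`, and `config`.
#' @examples
#' cfg <- optimizer_config("wca", n_agents = 20, n_iterations = 50, n_runs = 1)
#' res <- minimize(function(x) sum(x^2), cbind(rep(-5, 3), rep(5, 3)), cfg)
#' res$best_objective
#' @export
minimize <- function(objective_fn, bounds, config) {
  stopifnot(is.function(objective_fn), inherits(config, "optimizer_config"))
  b <- .check_bounds(bounds)
  d <- length(b$lower)
  set.seed(config$seed)
  if (config$algorithm == "cso") {
    # CSO searches in natural coordinates: its rooster update is
    # multiplicative and must see the parameters' own scales.
    out <- .opt_cso(.make_eval_nat(objective_fn), b$lower, b$upper,
                    config$n_agents, config$n_iterations,
                    config$hyperparameters)
    best_x <- out$best_u
  } else {
    evalfn <- .make_eval(objective_fn, b$lower, b$upper)
    kernel <- switch(config$algorithm, wca = .opt_wca, fpa = .opt_fpa,
                     cs = .opt_cs)
    out <- kernel(evalfn, d, config$n_agents, config$n_iterations,
                  config$hyperparameters)
    best_x <- b$lower + out$best_u * (b$upper - b$lower)
  }
  structure(list(best_params = best_x,
                 best_objective = out$best_val,
                 convergence = out$convergence,
                 run_index = 0L,
                 seed = config$seed,
                 config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s run %d (seed %d): objective %.8g after %d iterations\n",
              x$config$algorithm, x$run_index, x$seed, x$best_objective,
              length(x$convergence)))
  invisible(x)
}

#' Multi-run protocol: independent restarts with derived seeds
#'
#' Executes `config$n_runs` independent [minimize()] runs; run `k`
#' (0-based) is seeded with `config$seed + k`.  The selected result is the
#' run with the smallest best objective, ties broken by the lowest run
#' index.
#'
#' @inheritParams minimize
#' @return A `multi_run_result`: list with `runs` (all `fit_result`s) and
#'   `best` (the selected one).
#' @export
multi_run <- function(objective_fn, bounds, config) {
  stopifnot(inherits(config, "optimizer_config"))
  runs <- vector("list", config$n_runs)
  for (k in seq_len(config$n_runs) - 1L) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    cfg_k$n_runs <- 1L
    res <- minimize(objective_fn, bounds, cfg_k)
    res$run_index <- k
    runs[[k + 1L]] <- res
  }
  best_vals <- vapply(runs, function(r) r$best_objective, numeric(1))
  sel <- which.min(best_vals)  # first minimum = lowest run_index on ties
  structure(list(runs = runs, best = runs[[sel]]),
            class = "multi_run_result")
}

#' @export
print.multi_run_result <- function(x, ...) {
  vals <- vapply(x$runs, function(r) r$best_objective, numeric(1))
  cat(sprintf("<multi_run_result> %d runs, best objective %.8g (run %d)\n",
              length(vals), x$best$best_objective, x$best$run_index))
  invisible(x)
}

#' Fit a circuit model to a measured spectrum
#'
#' Convenience wrapper tying together the model registry, the summed
#' relative-error objective, and [multi_run()].  The search is conducted
#' within the model's published boundaries in natural (linear) scale;
#' `log_scale = TRUE` instead searches resistances and capacitances in
#' log10 (an identifiability aid when bounds span many decades; the lower
#' bound of each log-scaled dimension is clamped to `1e-12 * upper`).
#'
#' @param measured An [impedance_spectrum()].
#' @param model_id One of [model_ids()].
#' @param config An [optimizer_config()].
#' @param log_scale Search R and C dimensions in log10 (default `FALSE`).
#' @return A `model_fit` list: `model_id`, `best_params` (a
#'   [param_vector()]), `best_objective`, `runs` (all `fit_result`s),
#'   `best_run`, `config`.
#' @export
fit_model <- function(measured, model_id, config, log_scale = FALSE) {
  stopifnot(inherits(measured, "impedance_spectrum"))
  model_id <- match.arg(model_id, model_ids())
  spec <- model_spec(model_id)
  freq <- measured$grid$frequencies
  zm <- measured$z
  azm <- Mod(zm)
  if (any(azm == 0)) {
    stop("measured spectrum contains zero impedance", call. = FALSE)
  }
  raw_obj <- function(x) sum(Mod(.z_eval(model_id, x, freq) - zm) / azm)
  if (log_scale) {
    scaled <- spec$units != "-"
    lo <- spec$lower; up <- spec$upper
    lo[scaled] <- log10(pmax(lo[scaled], 1e-12 * up[scaled]))
    up[scaled] <- log10(up[scaled])
    obj <- function(x) {
      x[scaled] <- 10^x[scaled]
      raw_obj(x)
    }
    mr <- multi_run(obj, list(lower = lo, upper = up), config)
    for (i in seq_along(mr$runs)) {
      bp <- mr$runs[[i]]$best_params
      bp[scaled] <- 10^bp[scaled]
      # exponentiation can land an epsilon outside the linear bounds
      mr$runs[[i]]$best_params <- pmin(pmax(bp, spec$lower), spec$upper)
    }
    mr$best <- mr$runs[[mr$best$run_index + 1L]]
  } else {
    mr <- multi_run(raw_obj, list(lower = spec$lower, upper = spec$upper),
                    config)
  }
  best_pv <- param_vector(spec, mr$best$best_params)
  structure(list(model_id = model_id,
                 best_params = best_pv,
                 best_objective = mr$best$best_objective,
                 runs = mr$runs,
                 best_run = mr$best,
                 config = config),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s via %s: objective %.8g (run %d of %d)\n",
              x$model_id, x$config$algorithm, x$best_objective,
              x$best_run$run_index, length(x$runs)))
  print(x$best_params$values)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Algorithm kernels.  Contract: fn(u) with u in [0,1]^d returns finite value
# or Inf; return list(best_u, best_val, convergence).

# Water cycle algorithm (Eskandar et al. 2012).  Slot 1 is the sea, slots
# 2..n_sr are rivers, the rest streams.  Streams flow to their river (or the
# sea), rivers flow to the sea; better-performing followers swap roles with
# their leader.  Evaporation + raining re-randomizes a river's streams when
# the river closes on the sea within d_max, which shrinks linearly to 0.
.opt_wca <- function(fn, d, n_agents, n_iter, hp) {
  n_sr <- max(2L, min(as.integer(hp$n_sr), n_agents - 1L))
  d_max <- hp$d_max
  pos <- matrix(stats::runif(n_agents * d), n_agents, d)
  cost <- apply(pos, 1L, fn)
  ord <- order(cost)
  pos <- pos[ord, , drop = FALSE]
  cost <- cost[ord]
  n_streams <- n_agents - n_sr
  # flow assignment: streams divided among sea+rivers by relative cost
  cn <- cost[seq_len(n_sr)] - cost[n_sr + 1L]
  if (!all(is.finite(cn)) || sum(abs(cn)) == 0) {
    ns <- rep(floor(n_streams / n_sr), n_sr)
  } else {
    ns <- round(abs(cn) / sum(abs(cn)) * n_streams)
  }
  ns[1L] <- ns[1L] + (n_streams - sum(ns))  # remainder to the sea
  while (any(ns < 0)) {                      # repair negative allocations
    i <- which.min(ns); j <- which.max(ns)
    ns[j] <- ns[j] + ns[i]; ns[i] <- 0L
  }
  leader <- rep.int(seq_len(n_sr), times = ns)  # leader of each stream slot
  stream_idx <- n_sr + seq_len(n_streams)
  conv <- numeric(n_iter)
  best_u <- pos[1L, ]; best_val <- cost[1L]
  for (it in seq_len(n_iter)) {
    # streams flow toward their leader (sea or river)
    for (m in seq_len(n_streams)) {
      i <- stream_idx[m]; l <- leader[m]
      cand <- .clip01(pos[i, ] + stats::runif(d) * 2 * (pos[l, ] - pos[i, ]))
      cval <- fn(cand)
      pos[i, ] <- cand; cost[i] <- cval
      if (cval < cost[l]) {  # exchange stream and leader
        tmp <- pos[l, ]; pos[l, ] <- pos[i, ]; pos[i, ] <- tmp
        tmpc <- cost[l]; cost[l] <- cost[i]; cost[i] <- tmpc
      }
    }
    # rivers flow toward the sea
    if (n_sr > 1L) {
      for (l in 2L:n_sr) {
        cand <- .clip01(pos[l, ] + stats::runif(d) * 2 * (pos[1L, ] - pos[l, ]))
        cval <- fn(cand)
        pos[l, ] <- cand; cost[l] <- cval
        if (cval < cost[1L]) {
          tmp <- pos[1L, ]; pos[1L, ] <- pos[l, ]; pos[l, ] <- tmp
          tmpc <- cost[1L]; cost[1L] <- cost[l]; cost[l] <- tmpc
        }
      }
    }
    # evaporation and raining
    if (n_sr > 1L) {
      for (l in 2L:n_sr) {
        if (sqrt(sum((pos[1L, ] - pos[l, ])^2)) < d_max ||
            stats::runif(1) < 0.1) {
          mine <- stream_idx[leader == l]
          for (i in mine) {
            pos[i, ] <- stats::runif(d)
            cost[i] <- fn(pos[i, ])
          }
        }
      }
    }
    sea_streams <- stream_idx[leader == 1L]
    for (i in sea_streams) {
      if (sqrt(sum((pos[1L, ] - pos[i, ])^2)) < d_max) {
        pos[i, ] <- .clip01(pos[1L, ] + sqrt(0.1) * stats::rnorm(d))
        cost[i] <- fn(pos[i, ])
      }
    }
    d_max <- d_max - d_max / n_iter
    if (cost[1L] < best_val) {
      best_val <- cost[1L]; best_u <- pos[1L, ]
    }
    conv[it] <- best_val
  }
  list(best_u = best_u, best_val = best_val, convergence = conv)
}

# Flower pollination algorithm (Yang 2012): global pollination moves an
# agent toward the best via a Levy flight with probability p_switch,
# otherwise local pollination mixes two random agents; acceptance is greedy.
.opt_fpa <- function(fn, d, n_agents, n_iter, hp) {
  p <- hp$p_switch
  lam <- hp$levy_exponent
  pos <- matrix(stats::runif(n_agents * d), n_agents, d)
  cost <- apply(pos, 1L, fn)
  ib <- which.min(cost)
  best_u <- pos[ib, ]; best_val <- cost[ib]
  conv <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(n_agents)) {
      if (stats::runif(1) < p) {
        step <- .levy_steps(d, lam)
        cand <- pos[i, ] + step * (best_u - pos[i, ])
      } else {
        jk <- sample.int(n_agents, 2L)
        cand <- pos[i, ] + stats::runif(1) * (pos[jk[1L], ] - pos[jk[2L], ])
      }
      cand <- .clip01(cand)
      cval <- fn(cand)
      if (cval < cost[i]) {
        pos[i, ] <- cand; cost[i] <- cval
        if (cval < best_val) {
          best_val <- cval; best_u <- cand
        }
      }
    }
    conv[it] <- best_val
  }
  list(best_u = best_u, best_val = best_val, convergence = conv)
}

# Cuckoo search (Yang & Deb 2009, following the authors' reference code):
# Levy flights around the current best with step scale `step_scale` and
# same-index greedy replacement, then abandonment of a fraction
# p_discovery of nests via a random difference step.
.opt_cs <- function(fn, d, n_agents, n_iter, hp) {
  pa <- hp$p_discovery
  lam <- hp$levy_exponent
  a0 <- hp$step_scale
  pos <- matrix(stats::runif(n_agents * d), n_agents, d)
  cost <- apply(pos, 1L, fn)
  ib <- which.min(cost)
  best_u <- pos[ib, ]; best_val <- cost[ib]
  conv <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(n_agents)) {
      step <- .levy_steps(d, lam)
      cand <- .clip01(pos[i, ] + a0 * step * (pos[i, ] - best_u) *
                        stats::rnorm(d))
      cval <- fn(cand)
      if (cval < cost[i]) {
        pos[i, ] <- cand; cost[i] <- cval
      }
    }
    # discovery: abandon a fraction of nests
    keep <- matrix(stats::runif(n_agents * d) > pa, n_agents, d)
    p1 <- pos[sample.int(n_agents), , drop = FALSE]
    p2 <- pos[sample.int(n_agents), , drop = FALSE]
    newpos <- .clip01(pos + stats::runif(1) * (p1 - p2) * (!keep))
    for (i in seq_len(n_agents)) {
      if (any(newpos[i, ] != pos[i, ])) {
        cval <- fn(newpos[i, ])
        if (cval < cost[i]) {
          pos[i, ] <- newpos[i, ]; cost[i] <- cval
        }
      }
    }
    ib <- which.min(cost)
    if (cost[ib] < best_val) {
      best_val <- cost[ib]; best_u <- pos[ib, ]
    }
    conv[it] <- best_val
  }
  list(best_u = best_u, best_val = best_val, convergence = conv)
}

# Chicken swarm optimization (Meng et al. 2014): the flock is re-sorted
# every `reorder_period` iterations into roosters (best), hens (follow a
# rooster plus a random flock-mate), and chicks (follow their mother hen).
# Acceptance is greedy per agent.  Unlike the other kernels this one works
# in natural coordinates (see minimize()).
.opt_cso <- function(fn, lower, upper, n_agents, n_iter, hp) {
  d <- length(lower)
  span <- upper - lower
  clip <- function(x) pmin(pmax(x, lower), upper)
  nr <- max(1L, round(hp$rooster_frac * n_agents))
  nh <- max(1L, round(hp$hen_frac * n_agents))
  if (nr + nh >= n_agents) nh <- n_agents - nr - 1L
  if (nh < 1L) { nh <- 1L; nr <- max(1L, n_agents - 2L) }
  nc <- n_agents - nr - nh
  nm <- max(1L, round(hp$mother_frac * nh))
  eps0 <- .Machine$double.eps
  pos <- matrix(stats::runif(n_agents * d), n_agents, d)
  pos <- sweep(sweep(pos, 2L, span, "*"), 2L, lower, "+")
  cost <- apply(pos, 1L, fn)
  ib <- which.min(cost)
  best_u <- pos[ib, ]; best_val <- cost[ib]
  conv <- numeric(n_iter)
  roosters <- hens <- chicks <- integer(0)
  hen_rooster <- chick_mother <- integer(0)
  sexp <- function(x) exp(pmin(pmax(x, -50), 50))
  for (it in seq_len(n_iter)) {
    if ((it - 1L) %% hp$reorder_period == 0L) {
      ord <- order(cost)
      roosters <- ord[seq_len(nr)]
      hens <- ord[nr + seq_len(nh)]
      chicks <- if (nc > 0L) ord[nr + nh + seq_len(nc)] else integer(0)
      hen_rooster <- roosters[sample.int(nr, nh, replace = TRUE)]
      mothers <- hens[sample.int(nh, nm, replace = TRUE)]
      chick_mother <- if (nc > 0L) {
        mothers[sample.int(nm, nc, replace = TRUE)]
      } else integer(0)
    }
    for (idx in seq_len(nr)) {
      i <- roosters[idx]
      k <- if (nr > 1L) {
        pool <- setdiff(seq_len(nr), idx)
        roosters[pool[sample.int(length(pool), 1L)]]
      } else i
      sigma2 <- if (cost[i] <= cost[k]) 1 else
        sexp((cost[k] - cost[i]) / (abs(cost[i]) + eps0))
      cand <- clip(pos[i, ] * (1 + stats::rnorm(d, sd = sqrt(sigma2))))
      cval <- fn(cand)
      if (cval < cost[i]) { pos[i, ] <- cand; cost[i] <- cval }
    }
    for (idx in seq_len(nh)) {
      i <- hens[idx]
      r1 <- hen_rooster[idx]
      others <- setdiff(c(roosters, hens), c(i, r1))
      r2 <- if (length(others)) others[sample.int(length(others), 1L)] else r1
      s1 <- sexp((cost[i] - cost[r1]) / (abs(cost[i]) + eps0))
      s2 <- sexp(cost[r2] - cost[i])
      cand <- clip(pos[i, ] +
                        s1 * stats::runif(1) * (pos[r1, ] - pos[i, ]) +
                        s2 * stats::runif(1) * (pos[r2, ] - pos[i, ]))
      cval <- fn(cand)
      if (cval < cost[i]) { pos[i, ] <- cand; cost[i] <- cval }
    }
    if (nc > 0L) {
      for (idx in seq_len(nc)) {
        i <- chicks[idx]
        m <- chick_mother[idx]
        fl <- stats::runif(1, hp$fl_min, hp$fl_max)
        cand <- clip(pos[i, ] + fl * (pos[m, ] - pos[i, ]))
        cval <- fn(cand)
        if (cval < cost[i]) { pos[i, ] <- cand; cost[i] <- cval }
      }
    }
    ib <- which.min(cost)
    if (cost[ib] < best_val) {
      best_val <- cost[ib]; best_u <- pos[ib, ]
    }
    conv[it] <- best_val
  }
  list(best_u = best_u, best_val = best_val, convergence = conv)
}
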
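# Inference of hybrid MCS parameters from an observed release curve:
# sum-of-squares objective against the ensemble-mean simulated curve,
# minimized by a seeded generational genetic algorithm (tournament
# selection, blend crossover, bounded Gaussian mutation, elitism of 1).

#' Genetic-algorithm configuration
#'
#' The genome covers the hybrid MCS parameters: the exponent `nu`, the two
#' rates searched in log10 space, the step-coefficient forms `A_form` /
#' `B_form` chosen by an integer-coded gene (1 = constant, 2 = 1/k, 3 = k),
#' and a global log10 time-scale aligning simulation time units with the
#' observed units. Any gene can be fixed by collapsing its bounds to a
#' single value (e.g. `log10_tscale = c(0, 0)` pins the scale to 1).
#'
#' @param population_size number of candidates per generation (>= 2).
#' @param generations number of generations (>= 0; 0 evaluates only the
#'   random initial population).
#' @param crossover_rate,mutation_rate probabilities in `[0, 1]`.
#' @param tournament_size selection pressure (>= 2).
#' @param ensemble_size_per_candidate simulations averaged per objective
#'   evaluation (`m_runs`); 10 keeps desk-scale runtime, 50 gives
#'   reference-grade averaging.
#' @param bounds named list of length-2 numeric ranges for genes `nu`,
#'   `log10_lambda1`, `log10_lambda2`, `A_form`, `B_form`, `log10_tscale`.
#' @param seed master seed: drives the initial population, all GA draws and
#'   the common-random-number simulation seeds.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, generations = 60,
                      crossover_rate = 0.8, mutation_rate = 0.2,
                      tournament_size = 3, ensemble_size_per_candidate = 10,
                      bounds = list(nu = c(0, 2),
                                    log10_lambda1 = c(-3, 1),
                                    log10_lambda2 = c(-1, 3),
                                    A_form = c(1, 3),
                                    B_form = c(1, 3),
                                    log10_tscale = c(0, 0)),
                      seed = 1L) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (generations < 0) stop("generations must be >= 0")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  need <- c("nu", "log10_lambda1", "log10_lambda2", "A_form", "B_form",
            "log10_tscale")
  if (!all(need %in% names(bounds))) {
    stop(sprintf("bounds must name the genes %s", paste(need, collapse = ", ")))
  }
  for (nm in need) {
    b <- bounds[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2]) {
      stop(sprintf("bounds for %s must be a finite ordered pair", nm))
    }
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 ensemble_size_per_candidate = as.integer(ensemble_size_per_candidate),
                 bounds = bounds[need], seed = as.integer(seed)),
            class = "ga_config")
}

# Decode a genome vector into hybrid-MCS candidate parameters.
decode_genome <- function(g) {
  forms <- c("constant", "inv_k", "k")
  list(nu = g[["nu"]],
       lambda1 = 10^g[["log10_lambda1"]],
       lambda2 = 10^g[["log10_lambda2"]],
       A_form = forms[pmin(pmax(round(g[["A_form"]]), 1), 3)],
       B_form = forms[pmin(pmax(round(g[["B_form"]]), 1), 3)],
       tscale = 10^g[["log10_tscale"]])
}

# Build the hybrid model carried by a candidate.
candidate_model <- function(params) {
  mcs_model("hybrid", nu = params$nu, lambda1 = params$lambda1,
            lambda2 = params$lambda2, A_form = params$A_form,
            B_form = params$B_form)
}

#' Sum-of-squares objective of a candidate MCS model
#'
#' Runs `m_runs` simulations under the candidate hybrid parameters, linearly
#' interpolates each simulated trajectory at the observed time points (after
#' multiplying simulated times by the candidate's time-scale factor),
#' averages them, and returns the sum of squared deviations from the
#' observed curve.
#'
#' @param observed a [release_curve()] with at least 3 points.
#' @param candidate_params list with `nu`, `lambda1`, `lambda2`, `A_form`,
#'   `B_form` and optionally `tscale` (default 1), as produced by the GA
#'   decoder.
#' @param sim_config a [simulation_config()] providing geometry and kernel;
#'   its MCS model and seed are overridden per candidate/run.
#' @param m_runs simulations averaged (>= 1).
#' @param seed seed from which the `m_runs` simulation sub-seeds are derived.
#' @param on compare on the `"remaining"` (default) or `"fraction"` scale.
#' @return nonnegative sum of squares.
#' @export
objective_ssq <- function(observed, candidate_params, sim_config,
                          m_runs = 10, seed = 1L,
                          on = c("remaining", "fraction")) {
  on <- match.arg(on)
  stopifnot(inherits(observed, "release_curve"))
  if (length(observed$t) < 3L) stop("observed curve needs at least 3 points")
  if (m_runs < 1) stop("m_runs must be >= 1")
  if (is.null(candidate_params$tscale)) candidate_params$tscale <- 1
  seeds <- derive_seeds(seed, m_runs)
  model <- candidate_model(candidate_params)
  sim_vals <- matrix(NA_real_, length(observed$t), m_runs)
  for (j in seq_len(m_runs)) {
    cfg <- sim_config
    cfg$mcs <- model
    cfg$seed <- seeds[j]
    cur <- simulate_release(cfg)
    tt <- cur$t * candidate_params$tscale
    if (max(observed$t) > max(tt) || min(observed$t) < min(tt)) {
      stop(sprintf(
        "extrapolation error: observed times span [%g, %g] but simulated curve %d spans [%g, %g] after scaling",
        min(observed$t), max(observed$t), j, min(tt), max(tt)))
    }
    sim_vals[, j] <- stats::approx(tt, cur$N, xout = observed$t)$y
  }
  mean_sim <- rowMeans(sim_vals)
  obs <- observed$N
  if (on == "fraction") {
    mean_sim <- 1 - mean_sim / sim_config$n0
    obs <- 1 - observed$N / observed$n0
  }
  sum((obs - mean_sim)^2)
}

#' Infer hybrid MCS parameters from an observed release curve
#'
#' Generational genetic algorithm over the hybrid-MCS parameter space,
#' minimizing [objective_ssq()] between the observed curve and the
#' ensemble-mean simulated curve. Candidates are evaluated with common
#' random numbers (one fixed set of simulation sub-seeds for the whole run),
#' which makes the objective deterministic and comparisons across candidates
#' fair; the single elite is carried over unchanged, so the best objective
#' is non-increasing across generations. Candidates whose simulations cannot
#' cover the observed time range are assigned an infinite objective.
#'
#' @param observed a [release_curve()].
#' @param ga a [ga_config()].
#' @param sim_config a [simulation_config()] (geometry/kernel template).
#' @param on scale for the objective; fractional by default since observed
#'   curves are typically fractional release.
#' @return an object of class `mcs_inference`: `best_params` (decoded),
#'   `best_objective`, `generation_trace`, `init_objectives`, `evaluations`,
#'   `seed`.
#' @export
infer_mcs <- function(observed, ga, sim_config,
                      on = c("fraction", "remaining")) {
  on <- match.arg(on)
  stopifnot(inherits(ga, "ga_config"), inherits(sim_config, "simulation_config"))
  lower <- vapply(ga$bounds, `[`, numeric(1), 1L)
  upper <- vapply(ga$bounds, `[`, numeric(1), 2L)
  genes <- names(ga$bounds)
  d <- length(genes)
  seeds <- derive_seeds(ga$seed, 2L)
  crn_seed <- seeds[1]  # common random numbers for every objective evaluation
  evals <- 0L
  evaluate <- function(g) {
    names(g) <- genes
    evals <<- evals + 1L
    tryCatch(
      objective_ssq(observed, decode_genome(g), sim_config,
                    m_runs = ga$ensemble_size_per_candidate,
                    seed = crn_seed, on = on),
      error = function(e) Inf)
  }
  result <- local_seed(seeds[2], {
    pop <- t(vapply(seq_len(ga$population_size),
                    function(i) stats::runif(d, lower, upper), numeric(d)))
    colnames(pop) <- genes
    fitness <- apply(pop, 1L, evaluate)
    if (all(!is.finite(fitness))) {
      stop("inference failure: every initial candidate failed simulation")
    }
    init_objectives <- fitness
    trace <- numeric(ga$generations)
    span <- upper - lower
    for (gen in seq_len(ga$generations)) {
      elite_i <- which.min(fitness)
      new_pop <- matrix(NA_real_, ga$population_size, d,
                        dimnames = list(NULL, genes))
      new_fit <- numeric(ga$population_size)
      new_pop[1L, ] <- pop[elite_i, ]
      new_fit[1L] <- fitness[elite_i]
      tournament <- function() {
        idx <- sample.int(ga$population_size, ga$tournament_size)
        pop[idx[which.min(fitness[idx])], ]
      }
      for (i in 2:ga$population_size) {
        p1 <- tournament()
        p2 <- tournament()
        child <- if (stats::runif(1) < ga$crossover_rate) {
          alpha <- stats::runif(d, -0.25, 1.25)  # blend (BLX-alpha) crossover
          alpha * p1 + (1 - alpha) * p2
        } else p1
        mut <- stats::runif(d) < ga$mutation_rate
        if (any(mut)) {
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1 * span[mut])
        }
        new_pop[i, ] <- pmin(pmax(child, lower), upper)
        new_fit[i] <- evaluate(new_pop[i, ])
      }
      pop <- new_pop
      fitness <- new_fit
      trace[gen] <- min(fitness)
    }
    best_i <- which.min(fitness)
    list(best_genome = pop[best_i, ], best_objective = fitness[best_i],
         generation_trace = trace, init_objectives = init_objectives)
  })
  structure(list(best_params = decode_genome(result$best_genome),
                 best_genome = result$best_genome,
                 best_objective = result$best_objective,
                 generation_trace = result$generation_trace,
                 init_objectives = result$init_objectives,
                 evaluations = evals, seed = ga$seed, on = on),
            class = "mcs_inference")
}

#' @export
print.mcs_inference <- function(x, ...) {
  p <- x$best_params
  cat("mcs_inference result\n")
  cat(sprintf("  best objective (SSQ): %.6g after %d evaluations\n",
              x$best_objective, x$evaluations))
  cat(sprintf("  nu = %.4f, lambda1 = %.4g, lambda2 = %.4g\n",
              p$nu, p$lambda1, p$lambda2))
  cat(sprintf("  A_form = %s, B_form = %s, time scale = %.4g\n",
              p$A_form, p$B_form, p$tscale))
  invisible(x)
}

#' Deterministic/stochastic time shares of an MCS parameterization
#'
#' Simulates `n_runs` trajectories under the given hybrid parameters and
#' reports the average share of total simulated time contributed by the
#' deterministic (diffusion-like) and stochastic (noise) terms. The balance
#' identifies the dominant release mechanism: a diffusion-governed curve
#' yields a deterministic-dominant share, an erosion-governed one a
#' noise-dominant share.
#'
#' @param params decoded candidate parameters (as in
#'   `mcs_inference$best_params`).
#' @param sim_config a [simulation_config()] template.
#' @param n_runs replicates to average over.
#' @param seed seed for the replicate sub-seeds.
#' @return named numeric vector with components `det` and `sto` summing
#'   to 1.
#' @export
mcs_time_shares <- function(params, sim_config, n_runs = 20, seed = 1L) {
  model <- candidate_model(params)
  seeds <- derive_seeds(seed, n_runs)
  det <- 0
  sto <- 0
  for (j in seq_len(n_runs)) {
    cfg <- sim_config
    cfg$mcs <- model
    cfg$seed <- seeds[j]
    cur <- simulate_release(cfg)
    det <- det + cur$meta$time_det
    sto <- sto + cur$meta$time_sto
  }
  c(det = det / (det + sto), sto = sto / (det + sto))
}
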
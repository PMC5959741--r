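# GA inference of hybrid MCS parameters. Heavy parameter-recovery runs live
# in test-acceptance.R; these tests exercise the objective and the GA
# mechanics on purposely small problems.

hybrid_params <- function(nu = 1, lambda1 = 0.01, lambda2 = 10,
                          A_form = "inv_k", B_form = "k", tscale = 1) {
  list(nu = nu, lambda1 = lambda1, lambda2 = lambda2, A_form = A_form,
       B_form = B_form, tscale = tscale)
}

tiny_cfg <- simulation_config(n0 = 120, R0 = 7, H = 14,
                              sampler_mode = "volume_uniform")

test_that("objective_ssq matches its algebra and an interpolation oracle", {
  pars <- hybrid_params()
  m_runs <- 4
  # reproduce the candidate's own ensemble mean with the same seeds
  seeds <- mcrelease:::derive_seeds(42, m_runs)
  model <- mcs_model("hybrid", nu = pars$nu, lambda1 = pars$lambda1,
                     lambda2 = pars$lambda2, A_form = pars$A_form,
                     B_form = pars$B_form)
  runs <- lapply(seeds, function(s) {
    cfg <- tiny_cfg; cfg$mcs <- model; cfg$seed <- s
    simulate_release(cfg)
  })
  tmax <- min(sapply(runs, function(r) max(r$t)))
  times <- seq(tmax / 20, tmax * 0.95, length.out = 15)
  mean_N <- rowMeans(sapply(runs, function(r) approx(r$t, r$N, xout = times)$y))
  observed <- release_curve(times, mean_N, n0 = 120)

  expect_equal(objective_ssq(observed, pars, tiny_cfg, m_runs = m_runs,
                             seed = 42), 0)

  # shifting every observation by delta adds n * delta^2
  delta <- 3.5
  shifted <- release_curve(times, mean_N + delta, n0 = 120)
  expect_equal(objective_ssq(shifted, pars, tiny_cfg, m_runs = m_runs,
                             seed = 42), length(times) * delta^2,
               tolerance = 1e-10)

  # independent loop oracle: manual piecewise-linear interpolation + SSQ
  obs2 <- release_curve(times, mean_N * 0.9 + 1, n0 = 120)
  got <- objective_ssq(obs2, pars, tiny_cfg, m_runs = m_runs, seed = 42)
  interp_at <- function(tt, NN, x) {
    i <- findInterval(x, tt)
    w <- (x - tt[i]) / (tt[i + 1] - tt[i])
    (1 - w) * NN[i] + w * NN[i + 1]
  }
  sim_at <- sapply(runs, function(r) {
    vapply(times, function(x) interp_at(r$t, r$N, x), numeric(1))
  })
  want <- sum((obs2$N - rowMeans(sim_at))^2)
  expect_equal(got, want, tolerance = 1e-9)

  # observed times beyond the simulated span raise an extrapolation error
  far <- release_curve(c(times, max(runs[[1]]$t) * 50),
                       c(mean_N, 0), n0 = 120)
  expect_error(objective_ssq(far, pars, tiny_cfg, m_runs = 1, seed = 42),
               "extrapolation error")
})

test_that("the GA is elitist, seeded, and degenerates gracefully", {
  pars <- hybrid_params()
  obs <- simulate_release({
    cfg <- tiny_cfg
    cfg$mcs <- mcs_model("hybrid", nu = 1, lambda1 = 0.01, lambda2 = 10)
    cfg$seed <- 5
    cfg
  })
  obs <- release_curve(obs$t[-1], obs$N[-1], n0 = obs$n0)

  ga0 <- ga_config(population_size = 6, generations = 0,
                   ensemble_size_per_candidate = 2, seed = 31)
  r0 <- infer_mcs(obs, ga0, tiny_cfg)
  expect_equal(r0$best_objective, min(r0$init_objectives))
  expect_length(r0$generation_trace, 0)

  ga1 <- ga_config(population_size = 6, generations = 4,
                   ensemble_size_per_candidate = 2, seed = 31)
  r1 <- infer_mcs(obs, ga1, tiny_cfg)
  r2 <- infer_mcs(obs, ga1, tiny_cfg)
  expect_identical(r1$best_genome, r2$best_genome)     # seed determinism
  expect_identical(r1$best_objective, r2$best_objective)
  trace <- c(min(r1$init_objectives), r1$generation_trace)
  expect_true(all(diff(trace) <= 0))                   # elitism
  expect_lte(r1$best_objective, min(r1$init_objectives))
  # recorded best objective is reproducible from the recorded genome
  expect_equal(r1$best_objective,
               objective_ssq(obs, r1$best_params, tiny_cfg, m_runs = 2,
                             seed = mcrelease:::derive_seeds(31, 2)[1],
                             on = "fraction"),
               tolerance = 1e-12)
})

test_that("time shares split the simulated clock by mechanism", {
  sh_d <- mcs_time_shares(hybrid_params(lambda2 = 1e6), tiny_cfg,
                          n_runs = 5, seed = 2)
  expect_gt(sh_d[["det"]], 0.99)
  sh_e <- mcs_time_shares(hybrid_params(lambda1 = 1e6, lambda2 = 0.5),
                          tiny_cfg, n_runs = 5, seed = 2)
  expect_gt(sh_e[["sto"]], 0.99)
  expect_equal(sum(sh_d), 1)
})

test_that("ga_config validates bounds and rates", {
  expect_error(ga_config(population_size = 1), ">= 2")
  expect_error(ga_config(crossover_rate = 1.2), "rates")
  expect_error(ga_config(bounds = list(nu = c(0, 1))), "must name")
  b <- ga_config()$bounds
  b$nu <- c(2, 0)
  expect_error(ga_config(bounds = b), "ordered")
})
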
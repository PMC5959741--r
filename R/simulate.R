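# Release-simulation kernels. Two are provided: the shell-removal kernel
# (each step removes every molecule in the unit-thickness leak shell and
# shrinks R by one) and the random-walk kernel (single-occupancy lattice
# random walk with an absorbing leak shell). Both advance the simulation
# clock by Monte Carlo Micro-Steps drawn from a pluggable mcs_model.

#' Release curve container
#'
#' Holds the trajectory `(t, N(t))` of the amount of drug remaining inside
#' the matrix, either produced by a simulation or loaded from a file.
#'
#' @param t times, strictly increasing, starting at 0 for simulated curves.
#' @param N remaining counts/amounts, same length as `t`.
#' @param n0 initial amount; defaults to `N[1]`.
#' @param meta optional provenance list (config, seed, kernel ...).
#' @param strict require `N` non-increasing (simulator output); observed or
#'   noisy curves may legitimately violate this.
#' @return an object of class `release_curve` with fields `t`, `N`, `n0`,
#'   `meta`.
#' @export
release_curve <- function(t, N, n0 = N[1], meta = list(), strict = FALSE) {
  if (length(t) != length(N)) stop("`t` and `N` must have equal length")
  if (length(t) < 1L) stop("a release curve needs at least one point")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (!is.numeric(n0) || length(n0) != 1L || n0 <= 0) stop("`n0` must be > 0")
  if (strict && any(diff(N) > 0)) stop("`N` must be non-increasing")
  structure(list(t = as.numeric(t), N = as.numeric(N), n0 = n0, meta = meta),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf(
    "release_curve: %d points, t in [%g, %g], N from %g to %g (n0 = %g)\n",
    length(x$t), min(x$t), max(x$t), x$N[1], x$N[length(x$N)], x$n0))
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  data.frame(time = x$t, remaining = x$N)
}

#' Simulation configuration
#'
#' Aggregates the geometry, particle generation, kernel and MCS settings of
#' one release simulation.
#'
#' @param n0 initial number of drug molecules (> 0).
#' @param R0 initial cylinder radius in lattice units (> 1).
#' @param H axial extent; release is radial only, so `H` stays constant and,
#'   in the shell kernel, only affects point generation.
#' @param d minimum inter-molecule distance passed to
#'   [sample_cylinder_points()].
#' @param kernel `"shell"` (the classical shell-removal heuristic, default) or `"walk"`
#'   (explicit single-occupancy random walk).
#' @param mcs an [mcs_model()].
#' @param sampler_mode radial sampler, see [sample_cylinder_points()].
#' @param per_molecule shell kernel only: if `TRUE`, add one micro-step per
#'   removed molecule (evaluated at the instantaneous count as it decrements)
#'   instead of one micro-step per shell step.
#' @param max_steps safety valve on the number of kernel steps.
#' @param seed master seed; the point cloud and the stepping draws use
#'   sub-seeds derived from it.
#' @param initial_cloud optional [particle_cloud()] overriding internal point
#'   generation (geometry is then taken from the cloud).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n0 = 1745, R0 = 31, H = 2 * R0, d = 0,
                              kernel = c("shell", "walk"),
                              mcs = mcs_model("diffusion"),
                              sampler_mode = c("paper", "volume_uniform"),
                              per_molecule = FALSE,
                              max_steps = 1e6, seed = 1L,
                              initial_cloud = NULL) {
  kernel <- match.arg(kernel)
  sampler_mode <- match.arg(sampler_mode)
  stopifnot(inherits(mcs, "mcs_model"))
  if (!is.null(initial_cloud)) {
    stopifnot(inherits(initial_cloud, "particle_cloud"))
    n0 <- initial_cloud$n
    R0 <- initial_cloud$R
    H <- initial_cloud$H
  }
  if (n0 < 1 || n0 != round(n0)) stop("config error: n0 must be a positive integer")
  if (R0 <= 1) stop("config error: R0 must exceed the leak-shell thickness of 1")
  if (H <= 0) stop("config error: H must be > 0")
  if (max_steps < 1) stop("config error: max_steps must be >= 1")
  structure(list(n0 = as.integer(n0), R0 = R0, H = H, d = d, kernel = kernel,
                 mcs = mcs, sampler_mode = sampler_mode,
                 per_molecule = per_molecule, max_steps = max_steps,
                 seed = as.integer(seed), initial_cloud = initial_cloud),
            class = "simulation_config")
}

#' Remove the leak shell
#'
#' Deletes every molecule whose radial distance lies in the unit-thickness
#' leak region `(R-1)^2 <= x^2 + y^2 <= R^2` and shrinks the radius by one
#' lattice unit -- the classical shell-removal heuristic.
#'
#' @param cloud a [particle_cloud()].
#' @param R current radius (> 1); `R <= 1` signals shell exhaustion.
#' @return list with elements `cloud` (survivors), `removed` (count) and
#'   `R_new = R - 1`.
#' @export
remove_leak_shell <- function(cloud, R) {
  stopifnot(inherits(cloud, "particle_cloud"))
  if (R <= 1) stop("shell exhausted: R <= 1, the simulation must terminate")
  r2 <- cloud$points[, 1L]^2 + cloud$points[, 2L]^2
  keep <- r2 < (R - 1)^2
  survivors <- particle_cloud(cloud$points[keep, , drop = FALSE],
                              R = max(R - 1, 1 + 1e-9), H = cloud$H,
                              validate = FALSE)
  list(cloud = survivors, removed = sum(!keep), R_new = R - 1)
}

#' Random-walk lattice state
#'
#' Quantizes a continuous particle cloud onto the integer lattice (rounding,
#' with collisions pushed to the nearest free site) and builds the occupancy
#' map used by [random_walk_step()].
#'
#' @param cloud a [particle_cloud()].
#' @return an object of class `walk_state` with integer positions `pos`, the
#'   occupancy array `occ`, the (fixed) radius `R`, `H`, and count `n`.
#' @export
walk_state <- function(cloud) {
  stopifnot(inherits(cloud, "particle_cloud"))
  R <- cloud$R
  H <- cloud$H
  off <- ceiling(R) + 2L          # lattice origin offset for array indexing
  nx <- 2L * off + 1L
  nz <- ceiling(H) + 3L
  occ <- array(FALSE, dim = c(nx, nx, nz))
  pos <- matrix(0L, cloud$n, 3L)
  for (i in seq_len(cloud$n)) {
    p <- round(cloud$points[i, ])
    p[3] <- min(max(p[3], 0), ceiling(H))
    p <- find_free_site(p, occ, off, R, H)
    pos[i, ] <- p
    occ[p[1] + off + 1L, p[2] + off + 1L, p[3] + 1L] <- TRUE
  }
  structure(list(pos = pos, occ = occ, off = off, R = R, H = H, n = cloud$n),
            class = "walk_state")
}

# Nearest free interior site to integer point p (spiral search over growing
# Chebyshev shells); used only to resolve quantization collisions.
find_free_site <- function(p, occ, off, R, H) {
  for (radius in 0:3) {
    cand <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                        dz = -radius:radius)
    cand <- cand[order(abs(cand$dx) + abs(cand$dy) + abs(cand$dz)), ]
    for (j in seq_len(nrow(cand))) {
      q <- p + c(cand$dx[j], cand$dy[j], cand$dz[j])
      if (q[3] < 0 || q[3] > ceiling(H)) next
      if (q[1]^2 + q[2]^2 >= (R - 1)^2) next
      if (!occ[q[1] + off + 1L, q[2] + off + 1L, q[3] + 1L]) return(q)
    }
  }
  stop("lattice quantization failed: no free site near a molecule")
}

#' One random-walk move attempt
#'
#' Picks a molecule uniformly at random and one of its six von Neumann
#' neighbour sites uniformly. The move is performed if the target site is an
#' empty interior site, rejected if the target is occupied or restricted
#' (outside the cylinder or beyond the top/bottom faces, which do not
#' release), and the molecule is removed -- counted as released -- if the
#' target is a leak site.
#'
#' @param state a [walk_state()].
#' @param molecule,direction optional overrides (indices) for deterministic
#'   testing; by default both are drawn from the RNG.
#' @return list with the updated `state` and `event`, one of `"moved"`,
#'   `"rejected"`, `"escaped"`.
#' @export
random_walk_step <- function(state, molecule = NULL, direction = NULL) {
  stopifnot(inherits(state, "walk_state"))
  if (state$n == 0L) stop("empty lattice: no molecules left to move")
  i <- if (is.null(molecule)) sample.int(state$n, 1L) else molecule
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  d <- dirs[if (is.null(direction)) sample.int(6L, 1L) else direction, ]
  p <- state$pos[i, ]
  q <- p + d
  off <- state$off
  # axial faces do not release: moves beyond [0, H] are rejected
  if (q[3] < 0 || q[3] > ceiling(state$H)) {
    return(list(state = state, event = "rejected"))
  }
  lab <- classify_site(q[1], q[2], state$R)
  if (lab == "restricted") {
    return(list(state = state, event = "rejected"))
  }
  if (lab == "leak") {
    state$occ[p[1] + off + 1L, p[2] + off + 1L, p[3] + 1L] <- FALSE
    state$pos <- state$pos[-i, , drop = FALSE]
    state$n <- state$n - 1L
    return(list(state = state, event = "escaped"))
  }
  if (state$occ[q[1] + off + 1L, q[2] + off + 1L, q[3] + 1L]) {
    return(list(state = state, event = "rejected"))
  }
  state$occ[p[1] + off + 1L, p[2] + off + 1L, p[3] + 1L] <- FALSE
  state$occ[q[1] + off + 1L, q[2] + off + 1L, q[3] + 1L] <- TRUE
  state$pos[i, ] <- q
  list(state = state, event = "moved")
}

#' Simulate a release curve
#'
#' Runs the configured kernel until the matrix is exhausted or a stopping
#' rule fires, recording the remaining count `N` against the Monte Carlo
#' clock `t`.
#'
#' The shell kernel iterates: remove the leak shell, shrink `R` by one, then
#' advance the clock by one micro-step evaluated at the post-removal count
#' (or by one micro-step per removed molecule when `per_molecule = TRUE`).
#' It stops when `R <= 1`, `N = 0`, or `max_steps` is reached -- hence within
#' `ceiling(R0)` steps. The walk kernel advances the clock by one micro-step
#' per attempted move and records a point whenever a molecule escapes; the
#' circumscribing radius is held at `R0` (the leak shell is an absorbing
#' boundary).
#'
#' @param config a [simulation_config()].
#' @return a [release_curve()] whose `meta` carries the config, seed, kernel
#'   and the deterministic/stochastic split of total simulated time
#'   (`time_det`, `time_sto`).
#' @export
simulate_release <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 2L)
  cloud <- if (!is.null(config$initial_cloud)) config$initial_cloud
           else sample_cylinder_points(config$n0, config$R0, config$H,
                                       d = config$d,
                                       sampler_mode = config$sampler_mode,
                                       seed = seeds[1])
  local_seed(seeds[2], {
    if (config$kernel == "shell") {
      sim_shell_kernel(cloud, config)
    } else {
      sim_walk_kernel(cloud, config)
    }
  })
}

sim_shell_kernel <- function(cloud, config) {
  R <- cloud$R
  n0 <- cloud$n
  t <- 0
  N <- n0
  ts <- 0
  Ns <- n0
  k <- 0L
  time_det <- 0
  time_sto <- 0
  r2 <- cloud$points[, 1L]^2 + cloud$points[, 2L]^2
  while (R > 1 && N > 0 && k < config$max_steps) {
    k <- k + 1L
    keep <- r2 < (R - 1)^2
    removed <- N - sum(keep)
    r2 <- r2[keep]
    R <- R - 1
    if (config$per_molecule && removed > 0) {
      dt <- 0; ddet <- 0; dsto <- 0
      Ncur <- N
      for (j in seq_len(removed)) {
        Ncur <- Ncur - 1L
        s <- mcs_step(config$mcs, Ncur, k)
        dt <- dt + s$dt; ddet <- ddet + s$det; dsto <- dsto + s$sto
      }
      N <- Ncur
    } else {
      N <- N - removed
      s <- mcs_step(config$mcs, N, k)
      dt <- s$dt; ddet <- s$det; dsto <- s$sto
    }
    t <- t + dt
    time_det <- time_det + ddet
    time_sto <- time_sto + dsto
    ts <- c(ts, t)
    Ns <- c(Ns, N)
  }
  release_curve(ts, Ns, n0 = n0, strict = TRUE,
                meta = list(kernel = "shell", config = config,
                            seed = config$seed, steps = k,
                            time_det = time_det, time_sto = time_sto))
}

sim_walk_kernel <- function(cloud, config) {
  st <- walk_state(cloud)
  n0 <- st$n
  t <- 0
  ts <- 0
  Ns <- n0
  k <- 0L
  time_det <- 0
  time_sto <- 0
  while (st$n > 0L && k < config$max_steps) {
    k <- k + 1L
    res <- random_walk_step(st)
    st <- res$state
    s <- mcs_step(config$mcs, st$n, k)
    t <- t + s$dt
    time_det <- time_det + s$det
    time_sto <- time_sto + s$sto
    if (res$event == "escaped") {
      ts <- c(ts, t)
      Ns <- c(Ns, st$n)
    }
  }
  release_curve(ts, Ns, n0 = n0, strict = TRUE,
                meta = list(kernel = "walk", config = config,
                            seed = config$seed, steps = k,
                            time_det = time_det, time_sto = time_sto))
}

#' Fractional release
#'
#' Converts a remaining-amount curve to cumulative fractional release,
#' `f(t) = 1 - N(t) / n0`: the ratio of the cumulative amount released at
#' time `t` to the amount released at infinite time (taken as the initial
#' load).
#'
#' @param curve a [release_curve()].
#' @return a `release_curve` with an additional `fraction` field (values in
#'   `[0, 1]`, non-decreasing for simulator output).
#' @export
fraction_released <- function(curve) {
  stopifnot(inherits(curve, "release_curve"))
  if (is.na(curve$n0) || curve$n0 <= 0) stop("domain error: n0 must be > 0")
  curve$fraction <- 1 - curve$N / curve$n0
  curve
}
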
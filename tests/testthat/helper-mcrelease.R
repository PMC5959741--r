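# Shared fixture builders. Everything is generated in code at test time.

# Small, fast shell-kernel configuration.
small_shell_config <- function(seed = 1L, mcs = mcs_model("diffusion"), ...) {
  simulation_config(n0 = 300, R0 = 11, H = 22, mcs = mcs, seed = seed, ...)
}

# Small walk-kernel configuration (bounded step count keeps tests quick).
small_walk_config <- function(seed = 1L, mcs = mcs_model("diffusion"),
                              max_steps = 400, ...) {
  simulation_config(n0 = 60, R0 = 7, H = 10, kernel = "walk", mcs = mcs,
                    max_steps = max_steps, seed = seed, ...)
}

# Deterministic cloud on explicit coordinates.
cloud_at <- function(xyz, R = 10, H = 10) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  particle_cloud(xyz, R = R, H = H)
}
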
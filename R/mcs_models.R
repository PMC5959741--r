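# Monte Carlo Micro-Step (MCS) time models. The MCS is the increment added
# to the simulation clock per Monte Carlo event; its functional form encodes
# the physical release mechanism (diffusion, erosion, or a hybrid of both).

#' MCS time-model specification
#'
#' Three modes are supported:
#' \describe{
#'   \item{diffusion}{`MCS = 1 / N(t)`. The step grows as molecules leave,
#'     so release is fast early and slow late -- the signature of Fickian
#'     diffusion.}
#'   \item{erosion}{`MCS = |ln u| / lambda`, `u ~ U(0,1)`: exponential
#'     waiting times with rate `lambda` (the reciprocal of the polymer
#'     half-life time), modelling stochastic scission of polymer chains.}
#'   \item{hybrid}{`MCS = A(k) * (1/lambda1) * N^(-nu) + B(k) * (1/lambda2) * |ln u|`,
#'     a template combining a deterministic N-dependent term and a stochastic
#'     noise term. The step-indexed coefficients `A(k)`, `B(k)` may be
#'     constant, `1/k`, or `k` (`A_form = "inv_k"`, `B_form = "k"` reproduces
#'     the decaying-diffusion / growing-noise parameterization used for
#'     swellable matrices). Constant multipliers `A`, `B` rescale the two
#'     terms; note a constant coefficient is not separately identifiable from
#'     its rate (only `A/lambda1` and `B/lambda2` enter the step).}
#' }
#'
#' @param mode one of `"diffusion"`, `"erosion"`, `"hybrid"`.
#' @param lambda erosion rate (1/time), used by `mode = "erosion"`.
#' @param nu exponent of `N(t)` in the deterministic hybrid term.
#' @param lambda1,lambda2 hybrid rates scaling the deterministic and
#'   stochastic terms.
#' @param A_form,B_form step-index rules, one of `"constant"`, `"inv_k"`,
#'   `"k"`.
#' @param A,B constant multipliers applied on top of the form rules.
#' @return an object of class `mcs_model`.
#' @export
mcs_model <- function(mode = c("diffusion", "erosion", "hybrid"),
                      lambda = 0.1, nu = 1, lambda1 = 1, lambda2 = 1,
                      A_form = c("inv_k", "constant", "k"),
                      B_form = c("k", "constant", "inv_k"),
                      A = 1, B = 1) {
  mode <- match.arg(mode)
  A_form <- match.arg(A_form)
  B_form <- match.arg(B_form)
  if (mode == "erosion" && (!is.numeric(lambda) || lambda <= 0)) {
    stop("erosion mode requires lambda > 0")
  }
  if (mode == "hybrid") {
    if (!is.numeric(lambda1) || lambda1 <= 0) stop("hybrid mode requires lambda1 > 0")
    if (!is.numeric(lambda2) || lambda2 <= 0) stop("hybrid mode requires lambda2 > 0")
    if (!is.numeric(nu) || length(nu) != 1L) stop("`nu` must be a single real")
    if (A < 0 || B < 0) stop("`A` and `B` must be nonnegative")
  }
  structure(list(mode = mode, lambda = lambda, nu = nu,
                 lambda1 = lambda1, lambda2 = lambda2,
                 A_form = A_form, B_form = B_form, A = A, B = B),
            class = "mcs_model")
}

#' @export
print.mcs_model <- function(x, ...) {
  switch(x$mode,
    diffusion = cat("mcs_model: diffusion, MCS = 1/N(t)\n"),
    erosion = cat(sprintf("mcs_model: erosion, MCS = |ln u| / %g\n", x$lambda)),
    hybrid = cat(sprintf(
      "mcs_model: hybrid, MCS = %s A(k)/%g * N^-%g + %s B(k)/%g * |ln u| (A: %s, B: %s)\n",
      x$A, x$lambda1, x$nu, x$B, x$lambda2, x$A_form, x$B_form)))
  invisible(x)
}

# Evaluate a step-index coefficient rule at step k.
form_coef <- function(form, k) {
  switch(form, constant = 1, inv_k = 1 / k, k = k)
}

#' Diffusion micro-step
#'
#' `MCS = 1 / N(t)`: the time increment is the reciprocal of the number of
#' molecules still inside the matrix, so the clock accelerates as the matrix
#' empties.
#'
#' @param N remaining molecule count (>= 1; vectorized).
#' @return time increment(s) `1/N`.
#' @examples
#' mcs_diffusion(200)  # 0.005
#' @export
mcs_diffusion <- function(N) {
  if (any(!is.finite(N)) || any(N < 1)) {
    stop("domain error: mcs_diffusion requires N >= 1")
  }
  1 / N
}

#' Erosion micro-step
#'
#' `MCS = |ln u| / lambda` with `u ~ U(0,1)`: an exponential waiting time
#' with mean `1/lambda`, modelling random scission events of the polymer
#' matrix.
#'
#' @param lambda scission rate (> 0), reciprocal of the polymer half-life
#'   time.
#' @param u uniform draw(s) in `(0, 1]`; pass explicitly for reproducibility.
#' @return nonnegative time increment(s).
#' @examples
#' mcs_erosion(0.1, exp(-1))  # 10
#' @export
mcs_erosion <- function(lambda, u) {
  if (!is.numeric(lambda) || any(lambda <= 0)) stop("domain error: lambda must be > 0")
  if (any(u <= 0) || any(u > 1)) stop("domain error: u must lie in (0, 1]")
  abs(log(u)) / lambda
}

#' Hybrid micro-step
#'
#' `MCS = A(k) * (1/lambda1) * N^(-nu) + B(k) * (1/lambda2) * |ln u|`: a
#' deterministic diffusion-like term plus an exponential noise term, with
#' step-indexed coefficients. With `A_form = B_form = "constant"`, `B = 0`,
#' `nu = 1`, `lambda1 = 1` it reduces exactly to [mcs_diffusion()]; with
#' `A = 0` it reduces to [mcs_erosion()] at rate `lambda2`.
#'
#' @param N remaining molecule count (>= 1).
#' @param k simulation step index (>= 1).
#' @param model an `mcs_model` of mode `"hybrid"`.
#' @param u uniform draw in `(0, 1]` feeding the noise term.
#' @return time increment.
#' @examples
#' m <- mcs_model("hybrid", nu = 1, lambda1 = 1, lambda2 = 0.1)
#' mcs_hybrid(100, k = 2, model = m, u = exp(-1))  # 1/2 * 1/100 + 2 * 10
#' @export
mcs_hybrid <- function(N, k, model, u) {
  stopifnot(inherits(model, "mcs_model"))
  if (any(N < 1)) stop("domain error: mcs_hybrid requires N >= 1")
  if (any(k < 1) || any(k != round(k))) stop("domain error: k must be a positive integer")
  det <- model$A * form_coef(model$A_form, k) * N^(-model$nu) / model$lambda1
  if (model$B == 0) return(det)
  if (any(u <= 0) || any(u > 1)) stop("domain error: u must lie in (0, 1]")
  det + model$B * form_coef(model$B_form, k) * abs(log(u)) / model$lambda2
}

# One clock increment for the running simulation at step k with remaining
# count N. Draws the uniform variate internally (resampling u = 0 / u = 1,
# which would give infinite / zero erosion increments) and returns the
# deterministic and stochastic parts separately so mechanism shares can be
# audited. N = 0 end-of-run steps are clocked as if one molecule remained.
mcs_step <- function(model, N, k, log_resample = NULL) {
  Neff <- max(N, 1)
  if (model$mode == "diffusion") {
    return(list(dt = 1 / Neff, det = 1 / Neff, sto = 0))
  }
  if (model$mode == "hybrid" && model$B == 0) {
    # no draw: keeps the RNG stream identical to the pure model it reduces to
    det <- model$A * form_coef(model$A_form, k) * Neff^(-model$nu) / model$lambda1
    return(list(dt = det, det = det, sto = 0))
  }
  u <- stats::runif(1)
  while (u <= 0 || u >= 1) {
    if (!is.null(log_resample)) log_resample(u)
    u <- stats::runif(1)
  }
  if (model$mode == "erosion") {
    dt <- abs(log(u)) / model$lambda
    return(list(dt = dt, det = 0, sto = dt))
  }
  det <- model$A * form_coef(model$A_form, k) * Neff^(-model$nu) / model$lambda1
  sto <- model$B * form_coef(model$B_form, k) * abs(log(u)) / model$lambda2
  list(dt = det + sto, det = det, sto = sto)
}
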
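# Cylindrical lattice geometry: site classification, point generation,
# minimum-distance thinning, and the current matrix radius.

#' Particle cloud constructor
#'
#' A particle cloud holds the continuous (x, y, z) coordinates of the drug
#' molecules still inside the cylindrical matrix, together with the cylinder
#' geometry it was generated in. Coordinates are in lattice units (the side of
#' the unit cuboid that one molecule occupies).
#'
#' @param points numeric matrix with three columns `x`, `y`, `z` (may have
#'   zero rows).
#' @param R cylinder radius the cloud belongs to (lattice units, > 1).
#' @param H axial extent of the cylinder; `z` must lie in `[0, H]`.
#' @param validate check the containment invariants (all points interior).
#' @return an object of class `particle_cloud` with elements `points`, `R`,
#'   `H` and `n` (point count).
#' @export
particle_cloud <- function(points, R, H, validate = TRUE) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (length(points) == 0L) points <- matrix(numeric(), 0L, 3L)
  if (!is.matrix(points) || ncol(points) != 3L) {
    stop("`points` must be an n x 3 matrix of (x, y, z) coordinates")
  }
  colnames(points) <- c("x", "y", "z")
  if (!is.numeric(R) || length(R) != 1L || R <= 1) {
    stop("invalid geometry: cylinder radius R must be a single value > 1")
  }
  if (!is.numeric(H) || length(H) != 1L || H <= 0) {
    stop("invalid geometry: axial extent H must be a single value > 0")
  }
  if (validate && nrow(points) > 0L) {
    r2 <- points[, 1L]^2 + points[, 2L]^2
    if (any(r2 > (R - 1)^2 + 1e-9)) {
      stop("particle cloud invariant violated: point outside interior region")
    }
    if (any(points[, 3L] < -1e-9 | points[, 3L] > H + 1e-9)) {
      stop("particle cloud invariant violated: z outside [0, H]")
    }
  }
  structure(list(points = points, R = R, H = H, n = nrow(points)),
            class = "particle_cloud")
}

#' @export
print.particle_cloud <- function(x, ...) {
  cat(sprintf("particle_cloud: %d molecules in cylinder (R = %g, H = %g)\n",
              x$n, x$R, x$H))
  invisible(x)
}

#' Classify a lattice site of the cylinder cross-section
#'
#' Sites are partitioned by radial distance from the symmetry axis:
#' `interior` sites (`x^2 + y^2 < (R-1)^2`) can host drug molecules, `leak`
#' sites (`(R-1)^2 <= x^2 + y^2 <= R^2`) form the unit-thickness shell through
#' which drug is released, and `restricted` sites (`x^2 + y^2 > R^2`) are
#' outside the cylinder. A molecule reaching a leak site is counted as
#' released and removed.
#'
#' @param x,y site coordinates (vectorized).
#' @param R current cylinder radius; must exceed the leak-shell thickness of 1.
#' @return character vector in `c("interior", "leak", "restricted")`.
#' @examples
#' classify_site(0, 0, R = 5)     # interior
#' classify_site(4.5, 0, R = 5)   # leak
#' classify_site(6, 0, R = 5)     # restricted
#' @export
classify_site <- function(x, y, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 1) {
    stop("invalid geometry: R must be a single value > 1")
  }
  r2 <- x^2 + y^2
  out <- ifelse(r2 < (R - 1)^2, "interior",
                ifelse(r2 <= R^2, "leak", "restricted"))
  as.character(out)
}

#' Thin a point set to a minimum pairwise distance
#'
#' Greedy random thinning: repeatedly pick a random survivor, keep it, and
#' drop every remaining point strictly closer than `d` to it. The output is a
#' subset of the input in which all pairwise Euclidean distances are >= `d`.
#' Applying the operation twice with the same `d` leaves the set unchanged
#' the second time.
#'
#' @param points a `particle_cloud` or an n x 3 coordinate matrix.
#' @param d minimum pairwise distance (>= 0). `d = 0` returns the input.
#' @param seed integer seed driving the random pick order.
#' @return same type as the input (`particle_cloud` in, `particle_cloud` out).
#' @export
min_pairwise_buffer <- function(points, d, seed = 1L) {
  if (!is.numeric(d) || length(d) != 1L || d < 0) stop("`d` must be >= 0")
  is_cloud <- inherits(points, "particle_cloud")
  mat <- if (is_cloud) points$points else points
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (nrow(mat) == 0L || d == 0) {
    return(points)
  }
  keep <- local_seed(seed, thin_greedy(mat, d))
  mat <- mat[keep, , drop = FALSE]
  if (is_cloud) particle_cloud(mat, points$R, points$H) else mat
}

# Greedy thinning pass over a coordinate matrix; returns kept row indices in
# pick order. Strict inequality: only points at distance < d are dropped.
thin_greedy <- function(mat, d) {
  alive <- seq_len(nrow(mat))
  kept <- integer(0)
  d2 <- d^2
  while (length(alive) > 0L) {
    i <- alive[sample.int(length(alive), 1L)]
    kept <- c(kept, i)
    dx <- mat[alive, 1L] - mat[i, 1L]
    dy <- mat[alive, 2L] - mat[i, 2L]
    dz <- mat[alive, 3L] - mat[i, 3L]
    alive <- alive[dx^2 + dy^2 + dz^2 >= d2]
    alive <- alive[alive != i]
  }
  sort(kept)
}

#' Generate drug molecules inside the cylinder
#'
#' Draws points in the interior region of a cylinder of radius `R` and axial
#' extent `H`, optionally enforcing a minimum pairwise distance `d` by greedy
#' thinning. Two radial samplers are available: `"paper"` draws a uniform
#' angle, a uniform radius on `[0, R-1]` and a uniform `z` (the classical
#' generator for this heuristic; radially biased, density proportional to 1/r), while
#' `"volume_uniform"` uses `r = (R-1) * sqrt(u)` and is uniform per unit
#' volume. When `d > 0`, candidates are oversampled and thinned repeatedly
#' until exactly `n` survivors can be returned; if `max_attempts` rounds never
#' reach `n`, a packing-failure error reports the best achieved count.
#'
#' @param n requested number of molecules (>= 0).
#' @param R cylinder radius (> 1).
#' @param H axial extent (> 0).
#' @param d minimum pairwise distance, `0 <= d < 2R`.
#' @param sampler_mode `"paper"` (default) or `"volume_uniform"`.
#' @param seed integer seed; identical seeds give identical clouds.
#' @param max_attempts maximum oversample-and-thin rounds when `d > 0`.
#' @return a [particle_cloud()] with `n` points, all interior.
#' @export
sample_cylinder_points <- function(n, R, H, d = 0,
                                   sampler_mode = c("paper", "volume_uniform"),
                                   seed = 1L, max_attempts = 100L) {
  sampler_mode <- match.arg(sampler_mode)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("`n` must be a nonnegative integer")
  }
  if (d >= 2 * R) stop("`d` must be smaller than the cylinder diameter")
  if (n == 0L) return(particle_cloud(matrix(numeric(), 0L, 3L), R, H))
  mat <- local_seed(seed, {
    if (d == 0) {
      draw_cylinder(n, R, H, sampler_mode)
    } else {
      m <- n
      best <- 0L
      res <- NULL
      for (attempt in seq_len(max_attempts)) {
        cand <- draw_cylinder(m, R, H, sampler_mode)
        kept <- cand[thin_greedy(cand, d), , drop = FALSE]
        if (nrow(kept) >= n) {
          res <- kept[sample.int(nrow(kept), n), , drop = FALSE]
          break
        }
        best <- max(best, nrow(kept))
        # grow the candidate pool toward the shortfall, bounded so that an
        # infeasible packing exhausts attempts instead of memory
        m <- min(ceiling(m * max(1.2, n / max(nrow(kept), 1L))),
                 max(20L * n, 1000L))
      }
      if (is.null(res)) {
        stop(sprintf(
          "packing failure: could not place %d points at min distance %g (best achieved: %d)",
          n, d, best))
      }
      res
    }
  })
  particle_cloud(mat, R, H)
}

# Raw coordinate draw (no thinning); assumes the RNG is already seeded.
draw_cylinder <- function(n, R, H, sampler_mode) {
  theta <- stats::runif(n, 0, 2 * pi)
  r <- if (sampler_mode == "paper") {
    stats::runif(n, 0, R - 1)
  } else {
    (R - 1) * sqrt(stats::runif(n))
  }
  cbind(x = r * cos(theta), y = r * sin(theta), z = stats::runif(n, 0, H))
}

#' Current radius of the shrinking matrix
#'
#' The radius of the cylinder that circumscribes the remaining drug
#' molecules: the distance of the farthest point from the vertical symmetry
#' axis, `max_i sqrt(x_i^2 + y_i^2)`.
#'
#' @param cloud a nonempty [particle_cloud()].
#' @return a single nonnegative number.
#' @export
current_radius <- function(cloud) {
  stopifnot(inherits(cloud, "particle_cloud"))
  if (cloud$n == 0L) {
    stop("empty cloud: current_radius is undefined when no molecules remain")
  }
  sqrt(max(cloud$points[, 1L]^2 + cloud$points[, 2L]^2))
}

#' Write / read particle clouds as CSV
#'
#' Plain CSV with header `x,y,z`, '.' decimal separator.
#'
#' @param cloud a [particle_cloud()].
#' @param path file path.
#' @param R,H geometry to attach on read.
#' @return `read_points_csv` returns a [particle_cloud()];
#'   `write_points_csv` returns `path` invisibly.
#' @export
write_points_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "particle_cloud"))
  utils::write.csv(as.data.frame(cloud$points), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path, R, H) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("point CSV must have header x,y,z")
  }
  particle_cloud(as.matrix(df[, c("x", "y", "z")]), R, H)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All user-facing randomness funnels through
# this so that identical seeds give identical results without clobbering the
# session RNG.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k reproducible 31-bit sub-seeds from a master seed.
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max, k))
}
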
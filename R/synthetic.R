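#' Generate a synthetic neuron morphology
#'
#' Emulates the kind of tracing a laboratory deposits in repositories such as
#' NeuroMorpho: a single soma point (centre + average radius) and a set of
#' first-order neurites that wander outward as tortuous polylines, taper
#' geometrically, and bifurcate at random. It stands in for real tracings in
#' tests and examples; it does not model neurite-type statistics, spines, or
#' contact avoidance.
#'
#' Determinism: every branch draws from its own counter-derived RNG stream, so
#' adding a neurite (or deepening one branch) never perturbs the geometry of
#' the others.
#'
#' @param n_neurites number of first-order neurites (>= 0).
#' @param soma_radius soma mean radius, micrometres.
#' @param mean_segment_length mean spacing of tracing points along a neurite,
#'   micrometres.
#' @param branch_probability probability that a branch section ends in a
#'   bifurcation rather than a terminal, in `[0, 1]`.
#' @param max_depth maximum branch order (1 = unbranched).
#' @param initial_radius neurite radius at its first tracing point,
#'   micrometres.
#' @param taper_ratio per-point geometric radius taper, in `(0, 1]`
#'   (1 keeps the radius constant).
#' @param tortuosity standard deviation (radians) of the random bending
#'   applied to the growth direction at each step; 0 gives straight neurites.
#' @param points_per_section tracing points per unbranched section (min 2).
#' @param seed integer seed.
#' @param force_bifurcation if `TRUE` (default) and `branch_probability > 0`
#'   with `max_depth >= 2`, the first neurite is regrown with a forced first
#'   bifurcation when the random draw produced none.
#' @return an [swc_tracing()] object that passes [validate_tracing()].
#' @export
generate_synthetic_morphology <- function(n_neurites = 5L,
                                          soma_radius = 8,
                                          mean_segment_length = 5,
                                          branch_probability = 0.3,
                                          max_depth = 3L,
                                          initial_radius = 1.5,
                                          taper_ratio = 0.9,
                                          tortuosity = 0.25,
                                          points_per_section = 4L,
                                          seed = 1L,
                                          force_bifurcation = TRUE) {
  stopifnot(n_neurites >= 0L, soma_radius > 0, mean_segment_length > 0,
            branch_probability >= 0, branch_probability <= 1,
            max_depth >= 1L, initial_radius > 0,
            taper_ratio > 0, taper_ratio <= 1, tortuosity >= 0,
            points_per_section >= 2L)
  seed <- as.integer(seed)

  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = soma_radius, parent = -1L))
  next_id <- 2L

  # deterministic per-branch RNG stream (counter-based)
  branch_rng <- function(neurite, path_key) {
    s <- (abs(seed) %% 46000L) * 46337L + neurite * 521L + path_key
    s %% 2147483562L
  }

  grow_branch <- function(neurite, path_key, start_pos, dir, radius, depth,
                          parent_id, force_split) {
    old <- .Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(branch_rng(neurite, path_key))
    npts <- points_per_section + (depth == 1L)  # root section slightly longer
    pos <- start_pos
    d <- dir
    pid <- parent_id
    r <- radius
    for (k in seq_len(npts)) {
      step <- mean_segment_length * stats::runif(1L, 0.7, 1.3)
      if (tortuosity > 0) {
        ax <- vec_any_orthogonal(d)
        ay <- vec_cross(d, ax)
        ang <- stats::rnorm(1L, 0, tortuosity)
        phi <- stats::runif(1L, 0, 2 * pi)
        d <- vec_normalize(cos(ang) * d + sin(ang) * (cos(phi) * ax + sin(phi) * ay))
      }
      pos <- pos + step * d
      id <- next_id
      next_id <<- next_id + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, type = 3L, x = pos[1L], y = pos[2L], z = pos[3L],
        radius = r, parent = pid)
      pid <- id
      r <- r * taper_ratio
    }
    split <- depth < max_depth &&
      (force_split || stats::runif(1L) < branch_probability)
    if (split) {
      # two children in a cone around the current direction
      ax <- vec_any_orthogonal(d)
      ay <- vec_cross(d, ax)
      phi0 <- stats::runif(1L, 0, 2 * pi)
      spread <- stats::runif(1L, 0.4, 0.8)
      for (ci in 0:1) {
        phi <- phi0 + pi * ci
        cd <- vec_normalize(cos(spread) * d +
                              sin(spread) * (cos(phi) * ax + sin(phi) * ay))
        grow_branch(neurite, path_key * 2L + ci + 1L, pos, cd,
                    r, depth + 1L, pid, FALSE)
      }
      TRUE
    } else {
      FALSE
    }
  }

  run <- function(force_first) {
    rows <<- rows[1L]
    next_id <<- 2L
    any_bif <- FALSE
    for (i in seq_len(n_neurites)) {
      # initial direction from the neurite's own stream (key 0), so the
      # geometry of neurite i never depends on how many neurites exist
      old <- .Random.seed
      set.seed(branch_rng(i, 0L))
      h <- stats::runif(1L, -0.9, 0.9)
      ph <- stats::runif(1L, 0, 2 * pi)
      assign(".Random.seed", old, envir = globalenv())
      th <- acos(h)
      d0 <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      start <- soma_radius * 1.1 * d0
      rows[[length(rows) + 1L]] <<- data.frame(
        id = next_id, type = 3L, x = start[1L], y = start[2L], z = start[3L],
        radius = initial_radius, parent = 1L)
      root_id <- next_id
      next_id <<- next_id + 1L
      bif <- grow_branch(i, 1L, start, d0, initial_radius * taper_ratio, 1L,
                         root_id, force_first && i == 1L)
      any_bif <- any_bif || bif
    }
    any_bif
  }

  if (!exists(".Random.seed", envir = globalenv())) set.seed(seed)
  any_bif <- run(FALSE)
  if (force_bifurcation && n_neurites > 0L && branch_probability > 0 &&
      max_depth >= 2L && !any_bif) {
    run(TRUE)
  }
  swc_tracing(do.call(rbind, rows), strict = TRUE, quiet = TRUE)
}
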
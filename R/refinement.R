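#' Camera-distance importance field
#'
#' Maps each tracing point to an importance value (interpreted downstream as
#' a target subdivision level): maximal within `near` of the camera, 1 beyond
#' `far`, and linearly interpolated in between, so importance is
#' non-increasing in camera distance.
#'
#' @param tracing an [swc_tracing()] object.
#' @param camera_position length-3 numeric, micrometres.
#' @param max_level maximum subdivision level (>= 1).
#' @param near,far distances (micrometres) bounding the falloff; `near < far`.
#' @return named numeric vector (names = tracing point ids), values in
#'   `[1, max_level]`.
#' @export
importance_from_camera <- function(tracing, camera_position, max_level = 6,
                                   near = 10, far = 100) {
  stopifnot(inherits(tracing, "swc_tracing"), max_level >= 1)
  if (near >= far) stop("config error: near must be < far")
  pts <- tracing$points
  d <- sqrt((pts$x - camera_position[1L])^2 + (pts$y - camera_position[2L])^2 +
              (pts$z - camera_position[3L])^2)
  imp <- 1 + (max_level - 1) * pmin(1, pmax(0, (far - d) / (far - near)))
  names(imp) <- pts$id
  imp
}

# Resolve an importance spec (scalar or named-by-point-id vector) to a
# per-vertex numeric, clamped to [1, max_level].
vertex_importance <- function(mesh, importance, max_level) {
  if (length(importance) == 1L && is.null(names(importance))) {
    iv <- rep.int(as.numeric(importance), nrow(mesh$attrs))
  } else {
    iv <- unname(importance[as.character(mesh$attrs$point_id)])
    if (any(is.na(iv))) stop("importance is missing values for some tracing points")
  }
  pmin(pmax(iv, 1), max_level)
}

#' Per-patch subdivision levels from an importance field
#'
#' Each lateral quad of the coarse mesh is one tessellation patch. The outer
#' subdivision level of each patch edge is a weighted sum of the importance of
#' its two vertices, rounded half-up and clamped to `[1, max_level]`; because
#' the weights are applied in a canonical vertex order, the two patches
#' sharing an edge always receive the same outer level for it — the property
#' that keeps the refined mesh crack-free. Both inner levels equal the
#' weighted sum of the four corner importances.
#'
#' @param mesh a [generate_coarse_mesh()] object.
#' @param importance scalar (uniform) or named vector by tracing point id.
#' @param max_level clamp for levels.
#' @param outer_weight weight of the lower-indexed edge vertex (default 0.5).
#' @param inner_weights length-4 weights of the corner importances
#'   (default uniform 0.25).
#' @return list with `outer` (f x 4 integer matrix, sides v0v1, v1v2, v2v3,
#'   v3v0; NA for non-lateral faces), `inner` (length-f integer, NA for
#'   non-lateral), and `edge_levels` (named integer vector keyed by
#'   `"lo_hi"` vertex pairs).
#' @export
subdivision_levels <- function(mesh, importance, max_level = 64L,
                               outer_weight = 0.5,
                               inner_weights = rep(0.25, 4L)) {
  stopifnot(inherits(mesh, "neuro_mesh"), !is.null(mesh$patch))
  stopifnot(length(inner_weights) == 4L, abs(sum(inner_weights) - 1) < 1e-12,
            outer_weight >= 0, outer_weight <= 1)
  iv <- vertex_importance(mesh, importance, max_level)
  lat <- which(mesh$patch$kind == "lateral")
  nf <- nrow(mesh$faces)
  outer <- matrix(NA_integer_, nf, 4L)
  inner <- rep.int(NA_integer_, nf)
  ekeys <- character(0)
  elevs <- integer(0)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (f in lat) {
    vids <- mesh$faces[f, ]
    for (s in 1:4) {
      a <- vids[s]; b <- vids[if (s == 4L) 1L else s + 1L]
      lo <- min(a, b); hi <- max(a, b)
      key <- paste0(lo, "_", hi)
      lev <- env[[key]]
      if (is.null(lev)) {
        lev <- as.integer(min(max(round_half_up(
          outer_weight * iv[lo] + (1 - outer_weight) * iv[hi]), 1), max_level))
        env[[key]] <- lev
        ekeys <- c(ekeys, key)
        elevs <- c(elevs, lev)
      }
      outer[f, s] <- lev
    }
    inner[f] <- as.integer(min(max(round_half_up(sum(inner_weights * iv[vids])), 1),
                               max_level))
  }
  names(elevs) <- ekeys
  list(outer = outer, inner = inner, edge_levels = elevs)
}

#' Tessellate the unit-square patch
#'
#' CPU emulation of the hardware tessellation primitive generator: given four
#' outer (per-edge) levels and one inner level, produces a triangulation of
#' the unit square whose boundary edge `e` carries exactly `outer[e] + 1`
#' vertices, with a regular interior grid stitched to the boundary by
#' parameter-merged triangle strips. All levels 1 returns the two-triangle
#' identity; an inner level of 1 with any outer level above 1 is promoted to
#' an effective inner level of 2 (one centre vertex) so the stitching is well
#' defined.
#'
#' @param outer integer vector of 4 edge levels (sides v0v1, v1v2, v2v3,
#'   v3v0), each >= 1.
#' @param inner integer inner level >= 1 (used for both directions).
#' @return list with `coords` (data.frame `x`, `y` in `[0,1]`, `loc` in
#'   corner/edge/interior, `side` (1-4) and `j` (index along the side) for
#'   edge points, corner index in `j` for corners) and `triangles` (k x 3
#'   integer matrix, counter-clockwise in parameter space).
#' @export
tessellate_patch <- function(outer, inner) {
  outer <- as.integer(outer)
  inner <- as.integer(inner[1L])
  stopifnot(length(outer) == 4L, all(outer >= 1L), inner >= 1L)
  corners <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4L, 2L, byrow = TRUE)
  if (all(outer == 1L) && inner == 1L) {
    coords <- data.frame(x = corners[, 1L], y = corners[, 2L],
                         loc = "corner", side = NA_integer_, j = 1:4)
    return(list(coords = coords,
                triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))))
  }
  m <- if (inner == 1L) 2L else inner

  xs <- numeric(0); ys <- numeric(0)
  loc <- character(0); sides <- integer(0); jidx <- integer(0)
  addv <- function(x, y, l, s, j) {
    xs[length(xs) + 1L] <<- x; ys[length(ys) + 1L] <<- y
    loc[length(loc) + 1L] <<- l; sides[length(sides) + 1L] <<- s
    jidx[length(jidx) + 1L] <<- j
    length(xs)
  }
  cid <- integer(4L)
  for (k in 1:4) cid[k] <- addv(corners[k, 1L], corners[k, 2L], "corner", NA_integer_, k)

  # boundary chains per side (corner..edge points..corner), walk direction
  side_param <- function(s, f) {
    # point at fraction f along side s (from corner s to corner s+1)
    switch(s,
           c(f, 0),
           c(1, f),
           c(1 - f, 1),
           c(0, 1 - f))
  }
  O <- vector("list", 4L)
  pO <- vector("list", 4L)
  for (s in 1:4) {
    L <- outer[s]
    ids <- cid[s]
    ps <- 0
    if (L > 1L) {
      for (j in 1:(L - 1L)) {
        # exact fractions: use (L - j)/L form where the coordinate decreases
        p <- switch(s,
                    c(j / L, 0),
                    c(1, j / L),
                    c((L - j) / L, 1),
                    c(0, (L - j) / L))
        ids <- c(ids, addv(p[1L], p[2L], "edge", s, j))
        ps <- c(ps, j / L)
      }
    }
    ids <- c(ids, cid[if (s == 4L) 1L else s + 1L])
    ps <- c(ps, 1)
    O[[s]] <- ids
    pO[[s]] <- ps
  }

  # interior grid
  P <- matrix(0L, m - 1L, m - 1L)
  for (i in 1:(m - 1L)) for (j in 1:(m - 1L)) {
    P[i, j] <- addv(i / m, j / m, "interior", NA_integer_, NA_integer_)
  }

  tris <- list()
  addt <- function(a, b, c_) tris[[length(tris) + 1L]] <<- c(a, b, c_)

  # interior cells
  if (m >= 3L) {
    for (i in 1:(m - 2L)) for (j in 1:(m - 2L)) {
      addt(P[i, j], P[i + 1L, j], P[i + 1L, j + 1L])
      addt(P[i, j], P[i + 1L, j + 1L], P[i, j + 1L])
    }
  }

  # inner chains per side, in walk direction, inclusive of inner corners
  I <- list(
    P[1:(m - 1L), 1L],
    P[m - 1L, 1:(m - 1L)],
    P[(m - 1L):1L, m - 1L],
    P[1L, (m - 1L):1L])
  pI <- list((1:(m - 1L)) / m,
             (1:(m - 1L)) / m,
             ((1:(m - 1L)) / m),
             ((1:(m - 1L)) / m))

  for (s in 1:4) {
    o_ids <- O[[s]]; o_p <- pO[[s]]
    i_ids <- I[[s]]; i_p <- pI[[s]]
    no <- length(o_ids); ni <- length(i_ids)
    a <- 1L; b <- 1L
    while (a < no || b < ni) {
      if (a < no && (b == ni || o_p[a + 1L] <= i_p[b + 1L])) {
        addt(o_ids[a], o_ids[a + 1L], i_ids[b])
        a <- a + 1L
      } else {
        addt(o_ids[a], i_ids[b + 1L], i_ids[b])
        b <- b + 1L
      }
    }
  }

  list(coords = data.frame(x = xs, y = ys, loc = loc, side = sides, j = jidx),
       triangles = do.call(rbind, tris))
}

#' Cubic Hermite centerline point
#'
#' Smooths the neurite trajectory between two consecutive tracing points with
#' a cubic Hermite spline whose tangents are the orientation vectors scaled
#' adaptively by the segment length (`tangent_scale * |t1 - t0|`), which
#' suppresses the loop artifacts a fixed tangent magnitude produces on short
#' segments. The curve interpolates the tracing points exactly:
#' `c(0) = t0`, `c(1) = t1`.
#'
#' @param t0,t1 segment endpoint positions (length-3).
#' @param o0,o1 unit orientation vectors at the endpoints.
#' @param y longitudinal coordinate(s) in `[0, 1]` (vectorized).
#' @param tangent_scale multiplier on the adaptive tangent magnitude
#'   (default 1).
#' @return a length(y) x 3 matrix of centerline positions.
#' @export
hermite_center <- function(t0, o0, t1, o1, y, tangent_scale = 1) {
  d <- sqrt(sum((t1 - t0)^2))
  m0 <- (tangent_scale * d) * o0
  m1 <- (tangent_scale * d) * o1
  h00 <- 2 * y^3 - 3 * y^2 + 1
  h10 <- y^3 - 2 * y^2 + y
  h11 <- y^3 - y^2
  h01 <- -2 * y^3 + 3 * y^2
  cbind(h00 * t0[1L] + h10 * m0[1L] + h11 * m1[1L] + h01 * t1[1L],
        h00 * t0[2L] + h10 * m0[2L] + h11 * m1[2L] + h01 * t1[2L],
        h00 * t0[3L] + h10 * m0[3L] + h11 * m1[3L] + h01 * t1[3L])
}

# Patch record used by the evaluation routines: segment endpoints, tangents,
# radii and the four corner normals (v0,v1 on the t0 ring; v2,v3 on t1).
patch_record <- function(mesh, f) {
  vids <- mesh$faces[f, ]
  a <- mesh$attrs
  v0 <- vids[1L]; v2 <- vids[3L]
  list(vids = vids,
       t0 = c(a$cx[v0], a$cy[v0], a$cz[v0]),
       o0 = c(a$ox[v0], a$oy[v0], a$oz[v0]),
       r0 = a$radius[v0],
       t1 = c(a$cx[v2], a$cy[v2], a$cz[v2]),
       o1 = c(a$ox[v2], a$oy[v2], a$oz[v2]),
       r1 = a$radius[v2],
       normals = cbind(a$nx[vids], a$ny[vids], a$nz[vids]))
}

attr_normal <- function(a, v) c(a$nx[v], a$ny[v], a$nz[v])

#' Evaluate a refined vertex on a lateral patch
#'
#' Implements the tessellation-evaluation step for one parametric coordinate:
#' the centre point comes from the Hermite centerline at the longitudinal
#' coordinate, the radial direction from the normalized bilinear interpolation
#' of the four corner normals, the displacement magnitude from the linear
#' interpolation of the two tracing-point radii, and the vertex is
#' `v = r * n + c`, hence exactly at distance `r` from its centre.
#'
#' @param mesh a coarse mesh.
#' @param face index of a lateral face.
#' @param x,y transversal and longitudinal coordinates in `[0, 1]`
#'   (vectorized, equal length).
#' @param tangent_scale Hermite tangent multiplier.
#' @return list with `v` (n x 3 positions), `c` (n x 3 centres), `r`
#'   (displacement magnitudes), `n` (unit radial directions).
#' @export
displace_vertex <- function(mesh, face, x, y, tangent_scale = 1) {
  stopifnot(mesh$patch$kind[face] == "lateral")
  p <- patch_record(mesh, face)
  eval_patch_interior(p, x, y, tangent_scale)
}

eval_patch_interior <- function(p, x, y, tangent_scale) {
  w0 <- (1 - x) * (1 - y)
  w1 <- x * (1 - y)
  w2 <- x * y
  w3 <- (1 - x) * y
  n <- cbind(w0 * p$normals[1L, 1L] + w1 * p$normals[2L, 1L] +
               w2 * p$normals[3L, 1L] + w3 * p$normals[4L, 1L],
             w0 * p$normals[1L, 2L] + w1 * p$normals[2L, 2L] +
               w2 * p$normals[3L, 2L] + w3 * p$normals[4L, 2L],
             w0 * p$normals[1L, 3L] + w1 * p$normals[2L, 3L] +
               w2 * p$normals[3L, 3L] + w3 * p$normals[4L, 3L])
  nn <- row_norms(n)
  if (any(nn < 1e-8)) {
    # opposite corner normals cancelled; fall back to the nearer t0-ring pair
    bad <- which(nn < 1e-8)
    warning("degenerate bilinear normal on a patch; falling back to edge normals")
    for (k in bad) {
      alt <- (1 - x[k]) * p$normals[1L, ] + x[k] * p$normals[2L, ]
      n[k, ] <- alt
      nn[k] <- vec_norm(alt)
    }
  }
  n <- n / nn
  r <- (1 - y) * p$r0 + y * p$r1
  cc <- hermite_center(p$t0, p$o0, p$t1, p$o1, y, tangent_scale)
  v <- cbind(r * n[, 1L] + cc[, 1L], r * n[, 2L] + cc[, 2L], r * n[, 3L] + cc[, 3L])
  list(v = v, c = cc, r = r, n = n)
}

# Canonical evaluation of points interior to a patch edge. Both patches
# sharing an edge call these with identical integer arguments, which makes
# the generated vertex sequences bit-identical on the two sides.
# Transversal edge (section-quad ring edge): both endpoints belong to one
# tracing point; centre is that point, radius its radius.
eval_transversal_edge <- function(center, radius, n_lo, n_hi, j, L) {
  wa <- (L - j) / L
  wb <- j / L
  n <- cbind(wa * n_lo[1L] + wb * n_hi[1L],
             wa * n_lo[2L] + wb * n_hi[2L],
             wa * n_lo[3L] + wb * n_hi[3L])
  n <- n / row_norms(n)
  v <- cbind(radius * n[, 1L] + center[1L],
             radius * n[, 2L] + center[2L],
             radius * n[, 3L] + center[3L])
  list(v = v, c = matrix(center, length(j), 3L, byrow = TRUE),
       r = rep.int(radius, length(j)), n = n)
}

# Longitudinal edge (tube-direction edge between the t0 and t1 rings);
# parameter j/L measured from the t0-side endpoint.
eval_longitudinal_edge <- function(p, n_a, n_b, j, L, tangent_scale) {
  wa <- (L - j) / L
  wb <- j / L
  y <- j / L
  n <- cbind(wa * n_a[1L] + wb * n_b[1L],
             wa * n_a[2L] + wb * n_b[2L],
             wa * n_a[3L] + wb * n_b[3L])
  n <- n / row_norms(n)
  r <- wa * p$r0 + wb * p$r1
  cc <- hermite_center(p$t0, p$o0, p$t1, p$o1, y, tangent_scale)
  v <- cbind(r * n[, 1L] + cc[, 1L], r * n[, 2L] + cc[, 2L], r * n[, 3L] + cc[, 3L])
  list(v = v, c = cc, r = r, n = n)
}

#' Recompute the refined vertex sequence on one patch edge
#'
#' Diagnostic used to audit crack-freeness: recomputes, from the perspective
#' of the given face, the full ordered vertex sequence the refinement stage
#' generates on one of its edges. For the two faces sharing an edge the
#' returned positions are bit-identical (rows ordered by the canonical edge
#' direction).
#'
#' @param mesh coarse mesh.
#' @param face face index (must be a lateral patch).
#' @param side side index 1-4 (edges v0v1, v1v2, v2v3, v3v0).
#' @param levels output of [subdivision_levels()] on this mesh.
#' @param tangent_scale Hermite tangent multiplier.
#' @return an (L+1) x 3 matrix of positions in canonical edge order.
#' @export
patch_edge_vertices <- function(mesh, face, side, levels, tangent_scale = 1) {
  stopifnot(mesh$patch$kind[face] == "lateral")
  p <- patch_record(mesh, face)
  vids <- p$vids
  a <- vids[side]; b <- vids[if (side == 4L) 1L else side + 1L]
  L <- levels$outer[face, side]
  attrs <- mesh$attrs
  if (side %in% c(1L, 3L)) {
    lo <- min(a, b); hi <- max(a, b)
    ctr <- if (side == 1L) p$t0 else p$t1
    rad <- if (side == 1L) p$r0 else p$r1
    ends <- mesh$vertices[c(lo, hi), , drop = FALSE]
    if (L == 1L) return(ends)
    mid <- eval_transversal_edge(ctr, rad,
                                 attr_normal(attrs, lo),
                                 attr_normal(attrs, hi),
                                 1:(L - 1L), L)$v
    rbind(ends[1L, ], mid, ends[2L, ])
  } else {
    # canonical direction: from the t0-side endpoint to the t1-side endpoint
    v_t0 <- if (side == 2L) a else b
    v_t1 <- if (side == 2L) b else a
    ends <- mesh$vertices[c(v_t0, v_t1), , drop = FALSE]
    if (L == 1L) return(ends)
    mid <- eval_longitudinal_edge(p,
                                  attr_normal(attrs, v_t0),
                                  attr_normal(attrs, v_t1),
                                  1:(L - 1L), L, tangent_scale)$v
    rbind(ends[1L, ], mid, ends[2L, ])
  }
}

#' Refine a coarse neuron mesh (crack-free adaptive tessellation)
#'
#' CPU emulation of the three tessellation substages: per-patch subdivision
#' levels from the importance field, patch subdivision, and evaluation of the
#' new vertices on the Hermite-smoothed tube surface. Lateral quads are
#' tessellated; soma quads and ending caps pass through at base resolution,
#' but absorb any subdivided boundary rows of their refined neighbours
#' (fan-triangulated around a centre vertex when needed) so the output stays
#' closed and crack-free. Shared-edge vertices are generated once, through
#' canonical integer-parameter evaluation, and welded by exact key — adjacent
#' patches agree bit-exactly.
#'
#' @param mesh a [generate_coarse_mesh()] result.
#' @param importance scalar (uniform level) or named vector by tracing point
#'   id, e.g. from [importance_from_camera()].
#' @param max_level clamp for subdivision levels (default 64).
#' @param outer_weight,inner_weights level weights, see
#'   [subdivision_levels()].
#' @param tangent_scale Hermite tangent multiplier (default 1, adaptive:
#'   tangent magnitude proportional to segment length).
#' @return object of class `refined_mesh`: `vertices`, `faces` (triangles,
#'   outward counter-clockwise), `face_src` (coarse face index per triangle),
#'   `vertex_info` (data.frame: `src` in coarse/edge/interior/centroid, patch
#'   coordinates `x`, `y`, centre `cx,cy,cz` and displacement `r` where
#'   defined).
#' @export
refine_mesh <- function(mesh, importance = 1, max_level = 64L,
                        outer_weight = 0.5, inner_weights = rep(0.25, 4L),
                        tangent_scale = 1) {
  stopifnot(inherits(mesh, "neuro_mesh"), !is.null(mesh$patch))
  lv <- subdivision_levels(mesh, importance, max_level, outer_weight,
                           inner_weights)
  nv <- nrow(mesh$vertices)
  attrs <- mesh$attrs

  # output vertices: coarse vertices keep their ids
  pos <- vector("list", 4L * nv)
  info <- vector("list", 4L * nv)
  nout <- 0L
  addv <- function(p, src, x, y, cc, r) {
    nout <<- nout + 1L
    if (nout > length(pos)) {
      length(pos) <<- 2L * length(pos)
      length(info) <<- length(pos)
    }
    pos[[nout]] <<- p
    info[[nout]] <<- list(src = src, x = x, y = y, c = cc, r = r)
    nout
  }
  for (v in seq_len(nv)) {
    addv(mesh$vertices[v, ], "coarse", NA_real_, NA_real_,
         c(attrs$cx[v], attrs$cy[v], attrs$cz[v]), attrs$radius[v])
  }

  emap <- new.env(hash = TRUE, parent = emptyenv())
  tris <- vector("list", 4096L)
  fsrc <- vector("list", 4096L)
  ntri <- 0L
  addt <- function(tri, f) {
    ntri <<- ntri + 1L
    if (ntri > length(tris)) {
      length(tris) <<- 2L * length(tris)
      length(fsrc) <<- length(tris)
    }
    tris[[ntri]] <<- tri
    fsrc[[ntri]] <<- f
  }

  # points interior to mesh edge (a, b): canonical id list, created on demand
  edge_points <- function(f, p, side, a, b, L) {
    if (L == 1L) return(integer(0))
    if (side %in% c(1L, 3L)) {
      lo <- min(a, b); hi <- max(a, b)
      key <- paste0("T", lo, "_", hi, "_", L)
      ids <- emap[[key]]
      if (is.null(ids)) {
        ctr <- if (side == 1L) p$t0 else p$t1
        rad <- if (side == 1L) p$r0 else p$r1
        ev <- eval_transversal_edge(ctr, rad,
                                    attr_normal(attrs, lo),
                                    attr_normal(attrs, hi),
                                    1:(L - 1L), L)
        ids <- integer(L - 1L)
        for (j in 1:(L - 1L)) {
          ids[j] <- addv(ev$v[j, ], "edge", NA_real_, NA_real_, ev$c[j, ], ev$r[j])
        }
        emap[[key]] <- ids
      }
      # return in this patch's walk direction (a -> b)
      if (a == min(a, b)) ids else rev(ids)
    } else {
      v_t0 <- if (side == 2L) a else b
      v_t1 <- if (side == 2L) b else a
      key <- paste0("G", v_t0, "_", v_t1, "_", L)
      ids <- emap[[key]]
      if (is.null(ids)) {
        ev <- eval_longitudinal_edge(p,
                                     attr_normal(attrs, v_t0),
                                     attr_normal(attrs, v_t1),
                                     1:(L - 1L), L, tangent_scale)
        ids <- integer(L - 1L)
        yy <- (1:(L - 1L)) / L
        for (j in 1:(L - 1L)) {
          ids[j] <- addv(ev$v[j, ], "edge", NA_real_, yy[j], ev$c[j, ], ev$r[j])
        }
        emap[[key]] <- ids
      }
      if (side == 2L) ids else rev(ids)
    }
  }

  lat <- which(mesh$patch$kind == "lateral")
  for (f in lat) {
    p <- patch_record(mesh, f)
    vids <- p$vids
    tp <- tessellate_patch(lv$outer[f, ], lv$inner[f])
    co <- tp$coords
    gid <- integer(nrow(co))
    side_pts <- vector("list", 4L)
    for (s in 1:4) {
      a <- vids[s]; b <- vids[if (s == 4L) 1L else s + 1L]
      side_pts[[s]] <- edge_points(f, p, s, a, b, lv$outer[f, s])
    }
    int_rows <- which(co$loc == "interior")
    if (length(int_rows)) {
      ev <- eval_patch_interior(p, co$x[int_rows], co$y[int_rows], tangent_scale)
      for (k in seq_along(int_rows)) {
        gid[int_rows[k]] <- addv(ev$v[k, ], "interior", co$x[int_rows[k]],
                                 co$y[int_rows[k]], ev$c[k, ], ev$r[k])
      }
    }
    for (i in seq_len(nrow(co))) {
      if (co$loc[i] == "corner") gid[i] <- vids[co$j[i]]
      else if (co$loc[i] == "edge") gid[i] <- side_pts[[co$side[i]]][co$j[i]]
    }
    for (t in seq_len(nrow(tp$triangles))) {
      addt(gid[tp$triangles[t, ]], f)
    }
  }

  # pass-through faces: absorb refined boundary rows, fan if needed
  pass <- which(mesh$patch$kind != "lateral")
  for (f in pass) {
    vids <- mesh$faces[f, ]
    poly <- integer(0)
    for (s in 1:4) {
      a <- vids[s]; b <- vids[if (s == 4L) 1L else s + 1L]
      lo <- min(a, b); hi <- max(a, b)
      key0 <- paste0(lo, "_", hi)
      L <- lv$edge_levels[key0]
      poly <- c(poly, a)
      if (!is.na(L) && L > 1L) {
        key <- paste0("T", lo, "_", hi, "_", L)
        ids <- emap[[key]]
        if (is.null(ids)) stop("internal error: missing edge points for ", key)
        poly <- c(poly, if (a == lo) ids else rev(ids))
      }
    }
    k <- length(poly)
    if (k == 4L) {
      addt(poly[c(1L, 2L, 3L)], f)
      addt(poly[c(1L, 3L, 4L)], f)
    } else {
      ctr <- colMeans(mesh$vertices[vids, , drop = FALSE])
      cidx <- addv(ctr, "centroid", NA_real_, NA_real_, c(NA_real_, NA_real_, NA_real_),
                   NA_real_)
      for (i in seq_len(k)) {
        addt(c(cidx, poly[i], poly[if (i == k) 1L else i + 1L]), f)
      }
    }
  }

  verts <- do.call(rbind, pos[seq_len(nout)])
  im <- info[seq_len(nout)]
  vertex_info <- data.frame(
    src = vapply(im, `[[`, "", "src"),
    x = vapply(im, function(z) as.numeric(z$x), 0),
    y = vapply(im, function(z) as.numeric(z$y), 0),
    cx = vapply(im, function(z) z$c[1L], 0),
    cy = vapply(im, function(z) z$c[2L], 0),
    cz = vapply(im, function(z) z$c[3L], 0),
    r = vapply(im, function(z) as.numeric(z$r), 0))
  structure(list(vertices = verts,
                 faces = do.call(rbind, tris[seq_len(ntri)]),
                 face_src = unlist(fsrc[seq_len(ntri)]),
                 vertex_info = vertex_info,
                 levels = lv),
            class = c("refined_mesh", "neuro_mesh"))
}

#' @export
print.refined_mesh <- function(x, ...) {
  cat(sprintf("<refined_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}
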
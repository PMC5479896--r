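#' Orientation vector at a tracing point
#'
#' The orientation vector defines the plane of the cross-section quad placed
#' at a tracing point. For a standard point (one child) it bisects the parent
#' and child segment directions; at a bifurcation it bisects the two child
#' directions (independently of the parent segment); at an ending it equals
#' the incoming direction. Degenerate hairpins (bisector of two exactly
#' opposite directions) fall back to a deterministic unit vector orthogonal
#' to the parent direction.
#'
#' @param parent_dir unit vector from the parent tracing point to the current
#'   one (`NULL` only when `child_dirs` has two entries).
#' @param child_dirs list of unit vectors from the current point to each
#'   child (0, 1 or 2+ entries).
#' @return a unit 3-vector.
#' @export
orientation_vector <- function(parent_dir, child_dirs = list()) {
  nc <- length(child_dirs)
  if (nc == 0L) {
    if (is.null(parent_dir)) stop("ending point needs a parent direction")
    return(vec_normalize(parent_dir))
  }
  v <- if (nc == 1L) parent_dir + child_dirs[[1L]] else Reduce(`+`, child_dirs)
  n <- vec_norm(v)
  if (n < 1e-12) {
    ref <- if (!is.null(parent_dir)) parent_dir else child_dirs[[1L]]
    return(vec_any_orthogonal(ref))
  }
  v / n
}

#' Extra stitching vertex at a bifurcation
#'
#' Placed beyond the bifurcation cross-section at a distance equal to the
#' point radius, along the orientation vector, to close the wedge between the
#' two child tubes.
#'
#' @param point bifurcation tracing-point position.
#' @param orientation its (unit) orientation vector.
#' @param radius its radius.
#' @return the position `point + radius * orientation`.
#' @export
bifurcation_vertex <- function(point, orientation, radius) {
  point + radius * orientation
}

#' Split a bifurcation section-quad into the two child start rings
#'
#' A plane through the bifurcation point and its two children separates the
#' four section-quad corners; the quad diagonal whose endpoints lie nearer
#' that plane is selected and, together with the extra vertex, yields the two
#' child rings: diagonal v0-v2 gives `[v0,v1,v2,v']` and `[v0,v',v2,v3]`,
#' diagonal v1-v3 gives `[v0,v1,v',v3]` and `[v',v1,v2,v3]`. The choice is
#' invariant under swapping the child labels.
#'
#' @param corners 4 x 3 matrix of section-quad corner positions (cyclic
#'   order v0..v3).
#' @param bif_point bifurcation position.
#' @param child1,child2 positions of the two children tracing points.
#' @return list with `diagonal` (`c(1, 3)` or `c(2, 4)`) and `rings`, a list
#'   of two length-4 index vectors into `1:5` where index 5 denotes the extra
#'   vertex v'.
#' @export
split_bifurcation_quad <- function(corners, bif_point, child1, child2) {
  w <- vec_cross(child1 - bif_point, child2 - bif_point)
  nw <- vec_norm(w)
  if (nw < 1e-12 * max(1, vec_norm(child1 - bif_point) * vec_norm(child2 - bif_point))) {
    warning("children collinear with the bifurcation point; using diagonal v0-v2")
    diagonal <- c(1L, 3L)
  } else {
    w <- w / nw
    d <- abs(as.numeric(sweep(corners, 2L, bif_point) %*% w))
    diagonal <- if (d[1L] + d[3L] <= d[2L] + d[4L]) c(1L, 3L) else c(2L, 4L)
  }
  rings <- if (diagonal[1L] == 1L) {
    list(c(1L, 2L, 3L, 5L), c(1L, 5L, 3L, 4L))
  } else {
    list(c(1L, 2L, 5L, 4L), c(5L, 2L, 3L, 4L))
  }
  list(diagonal = diagonal, rings = rings)
}

# ring: 4 cyclically ordered vertex indices into the mesh under construction,
# counter-clockwise when viewed from the direction of travel.

# Build the next section-quad ring at position t, radius r, plane normal o,
# with in-plane rotation parallel-transported from the previous ring (the
# previous ring's first corner direction is projected into the new plane).
next_ring_frame <- function(prev_dirs, o) {
  e1 <- NULL
  for (k in seq_len(nrow(prev_dirs))) {
    w <- prev_dirs[k, ] - sum(prev_dirs[k, ] * o) * o
    if (vec_norm(w) > 1e-8) {
      e1 <- vec_normalize(w)
      ref2 <- prev_dirs[if (k == nrow(prev_dirs)) 1L else k + 1L, ]
      break
    }
  }
  if (is.null(e1)) {
    e1 <- vec_any_orthogonal(o)
    ref2 <- NULL
  }
  e2 <- vec_cross(o, e1)
  if (!is.null(ref2) && sum(ref2 * e2) < 0) e2 <- -e2
  list(e1 = e1, e2 = e2)
}

#' Generate the coarse neuron mesh from a tracing
#'
#' Runs the whole generation stage: builds and quad-pairs the tetrahedral
#' icosphere from the soma descriptor, assigns one surface quad per
#' first-order neurite, deforms the soma with the static linear FEM, sweeps
#' each neurite as a quad tube whose first ring is its (deformed) soma anchor
#' quad, stitches bifurcations with the extra-vertex split, caps endings, and
#' returns a single closed 2-manifold quad mesh. Every vertex carries the
#' position, radius and orientation vector of its associated tracing point;
#' every lateral quad knows its tracing segment, which is what the refinement
#' stage consumes.
#'
#' @param tracing an [swc_tracing()] object.
#' @param soma_level icosphere subdivision level (default 2, about 160 surface
#'   quads).
#' @param poisson Poisson's ratio for the soma FEM (default 0.3).
#' @param young nominal Young's modulus (immaterial under pure displacement
#'   constraints).
#' @return object of class `neuro_mesh`: list with `vertices` (n x 3),
#'   `faces` (f x 4 quads, outward counter-clockwise, lateral quads in patch
#'   order v0,v1 = first tracing point, v2,v3 = second), `attrs` (per-vertex
#'   data.frame: `point_id`, tracing-point `cx,cy,cz`, `radius`,
#'   orientation `ox,oy,oz`, radial normal `nx,ny,nz`), and `patch`
#'   (per-face data.frame: `kind` in soma/lateral/cap, `t0`, `t1`).
#' @export
generate_coarse_mesh <- function(tracing, soma_level = 2L, poisson = 0.3,
                                 young = 1) {
  stopifnot(inherits(tracing, "swc_tracing"))
  pts <- tracing$points
  soma <- tracing$soma
  if (!is.finite(soma$mean_radius) || soma$mean_radius <= 0) {
    stop("tracing has no usable soma descriptor")
  }
  soma_id <- soma$point_ids[1L]

  roots <- tracing$neurite_roots
  rrows <- tracing_rows(tracing, roots)
  anchors <- data.frame(root_id = roots,
                        x = pts$x[rrows], y = pts$y[rrows], z = pts$z[rrows],
                        radius = pts$radius[rrows])

  ico <- build_tet_icosphere(soma$center, soma$mean_radius, soma_level)
  ico <- pair_triangles_to_quads(ico)
  anchors <- select_neurite_quads(ico, anchors)
  ico <- deform_soma(ico, anchors, poisson = poisson, young = young)

  S <- ico$n_surface
  state <- new.env(parent = emptyenv())
  state$pos <- vector("list", 4096L)
  state$attr <- vector("list", 4096L)
  state$nv <- 0L
  state$faces <- vector("list", 4096L)
  state$patch <- vector("list", 4096L)
  state$nf <- 0L

  add_vertex <- function(pos, point_id, center, radius, orientation, normal) {
    state$nv <- state$nv + 1L
    if (state$nv > length(state$pos)) {
      length(state$pos) <- 2L * length(state$pos)
      length(state$attr) <- length(state$pos)
    }
    state$pos[[state$nv]] <- pos
    state$attr[[state$nv]] <- c(point_id, center, radius, orientation, normal)
    state$nv
  }
  add_face <- function(vids, kind, t0, t1 = NA_integer_) {
    state$nf <- state$nf + 1L
    if (state$nf > length(state$faces)) {
      length(state$faces) <- 2L * length(state$faces)
      length(state$patch) <- length(state$faces)
    }
    state$faces[[state$nf]] <- as.integer(vids)
    state$patch[[state$nf]] <- list(kind = kind, t0 = t0, t1 = t1)
    invisible(NULL)
  }

  # soma surface vertices first (ids 1..S, matching icosphere surface ids)
  for (v in seq_len(S)) {
    nrm <- vec_normalize(ico$vertices[v, ] - soma$center)
    add_vertex(ico$vertices[v, ], soma_id, soma$center, soma$mean_radius,
               nrm, nrm)
  }
  # overwrite anchor-ring vertices with their neurite-root attributes below

  anchor_quads <- if (nrow(anchors)) anchors$quad else integer(0)
  for (q in seq_len(nrow(ico$surface_quads))) {
    if (q %in% anchor_quads) next
    add_face(ico$surface_quads[q, ], "soma", soma_id)
  }

  prow <- match(pts$parent, pts$id)

  point_orientation <- function(row, parent_dir) {
    kid_rows <- tracing$children[[row]]
    cd <- lapply(kid_rows, function(k) {
      vec_normalize(as.numeric(pts[k, c("x", "y", "z")]) -
                      as.numeric(pts[row, c("x", "y", "z")]))
    })
    orientation_vector(parent_dir, cd)
  }

  walk_segment <- function(ring, ring_point_row, child_row, parent_dir) {
    # create section ring at the child, 4 laterals, then recurse at the child
    t_c <- as.numeric(pts[child_row, c("x", "y", "z")])
    r_c <- pts$radius[child_row]
    d_in <- vec_normalize(t_c - as.numeric(pts[ring_point_row, c("x", "y", "z")]))
    o_c <- point_orientation(child_row, d_in)
    t_prev <- as.numeric(pts[ring_point_row, c("x", "y", "z")])
    prev_dirs <- do.call(rbind, lapply(ring, function(v) state$pos[[v]] - t_prev))
    fr <- next_ring_frame(prev_dirs, o_c)
    radials <- rbind(fr$e1, fr$e2, -fr$e1, -fr$e2)
    new_ring <- integer(4L)
    for (k in 1:4) {
      new_ring[k] <- add_vertex(t_c + r_c * radials[k, ], pts$id[child_row],
                                t_c, r_c, o_c, radials[k, ])
    }
    for (k in 1:4) {
      k2 <- if (k == 4L) 1L else k + 1L
      add_face(c(ring[k], ring[k2], new_ring[k2], new_ring[k]),
               "lateral", pts$id[ring_point_row], pts$id[child_row])
    }
    process_point(new_ring, child_row, d_in)
  }

  process_point <- function(ring, row, parent_dir) {
    kids <- tracing$children[[row]]
    if (length(kids) == 0L) {
      add_face(ring, "cap", pts$id[row])
      return(invisible(NULL))
    }
    if (length(kids) == 1L) {
      walk_segment(ring, row, kids[1L], parent_dir)
      return(invisible(NULL))
    }
    if (length(kids) > 2L) {
      message("trifurcation at point ", pts$id[row],
              ": splitting recursively in child-id order")
    }
    t_b <- as.numeric(pts[row, c("x", "y", "z")])
    r_b <- pts$radius[row]
    remaining <- kids[order(pts$id[kids])]
    cur_ring <- ring
    while (length(remaining) > 2L) {
      res <- split_ring_for_children(cur_ring, row, remaining[1L],
                                     remaining[-1L], t_b, r_b, parent_dir)
      walk_segment(res$ring1, row, remaining[1L], parent_dir)
      cur_ring <- res$ring2
      remaining <- remaining[-1L]
    }
    res <- split_ring_for_children(cur_ring, row, remaining[1L], remaining[2L],
                                   t_b, r_b, parent_dir)
    walk_segment(res$ring1, row, remaining[1L], parent_dir)
    walk_segment(res$ring2, row, remaining[2L], parent_dir)
    invisible(NULL)
  }

  # split `ring` (vertices of the bifurcation section-quad, all attributed to
  # point `row`) for child `c1row` vs child/children `rest`; returns the two
  # child start rings with the extra vertex inserted.
  split_ring_for_children <- function(ring, row, c1row, rest, t_b, r_b,
                                      parent_dir) {
    p1 <- as.numeric(pts[c1row, c("x", "y", "z")])
    rest1 <- rest[1L]
    p2 <- if (length(rest) == 1L) as.numeric(pts[rest1, c("x", "y", "z")]) else {
      colMeans(as.matrix(pts[rest, c("x", "y", "z")]))
    }
    d1 <- vec_normalize(p1 - t_b)
    d2 <- vec_normalize(p2 - t_b)
    o <- orientation_vector(parent_dir, list(d1, d2))
    vp_pos <- bifurcation_vertex(t_b, o, r_b)
    corners <- do.call(rbind, state$pos[ring])
    sp <- suppressWarnings(split_bifurcation_quad(corners, t_b, p1, p2))
    vp <- add_vertex(vp_pos, pts$id[row], t_b, r_b, o, o)
    ids <- c(ring, vp)
    ringA <- ids[sp$rings[[1L]]]
    ringB <- ids[sp$rings[[2L]]]
    # hand each child the ring it faces (Newell normal vs child direction)
    nA <- newell_normal(do.call(rbind, state$pos[ringA]))
    nB <- newell_normal(do.call(rbind, state$pos[ringB]))
    if (sum(nA * d1) + sum(nB * d2) >= sum(nA * d2) + sum(nB * d1)) {
      list(ring1 = ringA, ring2 = ringB)
    } else {
      list(ring1 = ringB, ring2 = ringA)
    }
  }

  for (i in seq_len(nrow(anchors))) {
    root_row <- tracing_rows(tracing, anchors$root_id[i])
    frame <- ico$anchor_frames[[i]]
    qv <- ico$surface_quads[anchors$quad[i], ]
    t0 <- as.numeric(anchors[i, c("x", "y", "z")])
    r0 <- anchors$radius[i]
    o0 <- point_orientation(root_row, frame$normal)
    for (k in 1:4) {
      state$pos[[qv[k]]] <- frame$corners[k, ]
      state$attr[[qv[k]]] <- c(anchors$root_id[i], t0, r0, o0, frame$radials[k, ])
    }
    process_point(as.integer(qv), root_row, frame$normal)
  }

  verts <- do.call(rbind, state$pos[seq_len(state$nv)])
  am <- do.call(rbind, state$attr[seq_len(state$nv)])
  attrs <- data.frame(point_id = as.integer(am[, 1L]),
                      cx = am[, 2L], cy = am[, 3L], cz = am[, 4L],
                      radius = am[, 5L],
                      ox = am[, 6L], oy = am[, 7L], oz = am[, 8L],
                      nx = am[, 9L], ny = am[, 10L], nz = am[, 11L])
  faces <- do.call(rbind, state$faces[seq_len(state$nf)])
  pl <- state$patch[seq_len(state$nf)]
  patch <- data.frame(kind = vapply(pl, `[[`, "", "kind"),
                      t0 = vapply(pl, function(p) as.integer(p$t0), 0L),
                      t1 = vapply(pl, function(p) as.integer(p$t1), 0L))
  structure(list(vertices = verts, faces = faces, attrs = attrs, patch = patch,
                 anchors = anchors, soma = soma),
            class = "neuro_mesh")
}

newell_normal <- function(P) {
  n <- c(0, 0, 0)
  k <- nrow(P)
  for (i in seq_len(k)) {
    a <- P[i, ]
    b <- P[if (i == k) 1L else i + 1L, ]
    n <- n + vec_cross(a, b)
  }
  nn <- vec_norm(n)
  if (nn < 1e-300) return(c(0, 0, 0))
  n / nn
}

#' @export
print.neuro_mesh <- function(x, ...) {
  kinds <- if (!is.null(x$patch)) table(x$patch$kind) else NULL
  cat(sprintf("<neuro_mesh> %d vertices, %d faces (%d-gons)\n",
              nrow(x$vertices), nrow(x$faces), ncol(x$faces)))
  if (!is.null(kinds)) {
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "), "\n")
  }
  invisible(x)
}
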
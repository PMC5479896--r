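#' Assign neurite anchors to soma surface quads
#'
#' Each first-order neurite must own one surface quad of the soma icosphere:
#' the quad whose centroid direction (from the soma centre) is closest in
#' angle to the neurite insertion direction. The assignment is solved jointly
#' over all neurites so quads are pairwise distinct and the total angular
#' cost is minimal (exact branch-and-bound for up to 10 anchors, greedy with
#' pairwise-swap refinement beyond that). Because adjacent quads share
#' vertices — which would create conflicting boundary conditions in the FEM
#' stage — a final repair pass also enforces vertex-disjoint quads.
#'
#' @param icosphere a quad-paired [build_tet_icosphere()] object.
#' @param anchors data.frame with one row per neurite: `root_id` (tracing
#'   point id), `x`, `y`, `z` (insertion point, micrometres), `radius`
#'   (neurite start radius, micrometres).
#' @return `anchors` with an extra integer column `quad` (row index into
#'   `icosphere$surface_quads`).
#' @export
select_neurite_quads <- function(icosphere, anchors) {
  stopifnot(inherits(icosphere, "tet_icosphere"), !is.null(icosphere$surface_quads))
  if (nrow(anchors) == 0L) return(cbind(anchors, quad = integer(0)))
  quads <- icosphere$surface_quads
  nq <- nrow(quads)
  na <- nrow(anchors)
  if (na > nq) stop("more neurite anchors (", na, ") than surface quads (", nq, ")")

  ctr <- icosphere$center
  qc <- quad_centroids(icosphere$vertices, quads)
  qdir <- normalize_rows(sweep(qc, 2L, ctr))
  adir <- normalize_rows(as.matrix(anchors[, c("x", "y", "z")]) -
                           matrix(ctr, na, 3L, byrow = TRUE))
  dots <- adir %*% t(qdir)
  cost <- matrix(acos(pmin(1, pmax(-1, as.numeric(dots)))), na, nq)  # angular cost

  assign <- solve_assignment(cost, quads)
  if (is.null(assign)) {
    stop("cannot find vertex-disjoint quads for all neurites; ",
         "increase the soma subdivision level")
  }
  anchors$quad <- assign
  anchors
}

quad_centroids <- function(V, quads) {
  (V[quads[, 1L], , drop = FALSE] + V[quads[, 2L], , drop = FALSE] +
     V[quads[, 3L], , drop = FALSE] + V[quads[, 4L], , drop = FALSE]) / 4
}

# Minimal-cost assignment of anchors (rows) to vertex-disjoint quads.
# Branch-and-bound, exact on per-row candidate sets restricted to the
# cheapest max(12, 4*rows) quads (widened to all quads if that restriction
# turns out infeasible) for <= 10 rows; greedy + pairwise swaps otherwise.
# Returns NULL when no vertex-disjoint assignment exists.
solve_assignment <- function(cost, quads) {
  na <- nrow(cost)
  nq <- ncol(cost)
  bb <- function(K) {
    cand <- lapply(seq_len(na), function(i) order(cost[i, ])[seq_len(K)])
    best <- NULL
    best_cost <- Inf
    row_min <- vapply(seq_len(na), function(i) cost[i, cand[[i]][1L]], 0)
    tail_min <- rev(cumsum(rev(c(row_min, 0))))
    assign <- integer(na)
    used_v <- rep.int(FALSE, max(quads))
    nodes <- 0L
    rec <- function(i, acc) {
      nodes <<- nodes + 1L
      if (nodes > 2e6L) return()   # safety valve; greedy fallback below
      if (acc + tail_min[i] >= best_cost) return()
      if (i > na) {
        best <<- assign[seq_len(na)]
        best_cost <<- acc
        return()
      }
      for (q in cand[[i]]) {
        if (any(used_v[quads[q, ]])) next
        if (acc + cost[i, q] + tail_min[i + 1L] >= best_cost) break
        used_v[quads[q, ]] <<- TRUE
        assign[i] <<- q
        rec(i + 1L, acc + cost[i, q])
        used_v[quads[q, ]] <<- FALSE
      }
    }
    rec(1L, 0)
    best
  }
  greedy <- function() {
    ord <- order(apply(cost, 1L, min))
    assign <- rep.int(NA_integer_, na)
    used_v <- rep.int(FALSE, max(quads))
    for (i in ord) {
      ok <- which(!vapply(seq_len(nq), function(q) any(used_v[quads[q, ]]),
                          logical(1L)))
      if (length(ok) == 0L) return(NULL)
      q <- ok[which.min(cost[i, ok])]
      assign[i] <- q
      used_v[quads[q, ]] <- TRUE
    }
    repeat {
      improved <- FALSE
      for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
        if (cost[i, assign[j]] + cost[j, assign[i]] <
              cost[i, assign[i]] + cost[j, assign[j]] - 1e-15) {
          tmp <- assign[i]; assign[i] <- assign[j]; assign[j] <- tmp
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    assign
  }
  if (na <= 10L) {
    res <- bb(min(nq, max(12L, 4L * na)))
    if (is.null(res) && nq > max(12L, 4L * na)) res <- bb(nq)
    if (is.null(res)) res <- greedy()
    res
  } else {
    greedy()
  }
}

#' Deform the soma icosphere with a static linear FEM
#'
#' The volumetric icosphere is the rest configuration of an isotropic linear
#' elastic solid. Each neurite pulls the four vertices of its assigned surface
#' quad onto a planar square centred at the neurite insertion point, normal to
#' the insertion direction, with corner-to-centre distance equal to the
#' neurite start radius (so the tube cross-section is continuous at the
#' junction). These prescribed positions enter as Dirichlet constraints; all
#' remaining vertices solve the static equilibrium of linear tetrahedral
#' elements. Under pure displacement constraints the solution is independent
#' of the Young's modulus; the Poisson's ratio controls how much the rest of
#' the soma swells.
#'
#' @param icosphere quad-paired [build_tet_icosphere()] object.
#' @param anchors output of [select_neurite_quads()] (may have zero rows, in
#'   which case the icosphere is returned undeformed).
#' @param poisson Poisson's ratio, in (-1, 0.5). Default 0.3.
#' @param young nominal Young's modulus > 0 (immaterial under pure Dirichlet
#'   constraints; kept for completeness).
#' @return the icosphere with deformed `vertices`, plus `anchor_of` (integer
#'   per vertex: anchor row that constrains it, NA otherwise) and
#'   `anchor_frames` (per-anchor list: insertion point, unit normal, square
#'   corner positions in quad-vertex order).
#' @export
deform_soma <- function(icosphere, anchors, poisson = 0.3, young = 1) {
  stopifnot(inherits(icosphere, "tet_icosphere"), !is.null(icosphere$surface_quads))
  stopifnot(poisson > -1, poisson < 0.5, young > 0)
  ico <- icosphere
  nv <- nrow(ico$vertices)
  ico$anchor_of <- rep.int(NA_integer_, nv)
  ico$anchor_frames <- list()
  if (is.null(anchors) || nrow(anchors) == 0L) return(ico)
  if (is.null(anchors$quad)) stop("anchors must be assigned quads first (select_neurite_quads)")

  constrained <- integer(0)
  targets <- NULL
  for (i in seq_len(nrow(anchors))) {
    qv <- ico$surface_quads[anchors$quad[i], ]
    p <- as.numeric(anchors[i, c("x", "y", "z")])
    sq <- anchor_square(ico$vertices[qv, , drop = FALSE], p, anchors$radius[i],
                        ico$center)
    constrained <- c(constrained, qv)
    targets <- rbind(targets, sq$corners)
    ico$anchor_of[qv] <- i
    ico$anchor_frames[[i]] <- sq
  }
  if (anyDuplicated(constrained)) {
    stop("anchor quads share vertices; constraints conflict")
  }

  disp <- solve_linear_elasticity(ico$vertices, ico$tets,
                                  constrained, targets - ico$vertices[constrained, , drop = FALSE],
                                  poisson, young)
  ico$vertices <- ico$vertices + disp
  vol <- tet_signed_volumes(ico$vertices, ico$tets)
  if (any(vol <= 0)) {
    warning(sum(vol <= 0), " inverted tetrahedra after deformation")
  }
  ico
}

# Place the 4 quad vertices on a square: centred at p, normal to the insertion
# direction, corner-to-centre distance = start radius. Corners keep their
# angular order around the quad so the membrane does not twist.
anchor_square <- function(qverts, p, start_radius, soma_center) {
  u <- vec_normalize(p - soma_center)
  e1 <- vec_any_orthogonal(u)
  e2 <- vec_cross(u, e1)
  qc <- colMeans(qverts)
  rel <- sweep(qverts, 2L, qc)
  ang <- atan2(rel %*% e2, rel %*% e1)[, 1L]
  # fit target angles ang0 + k*90deg (k = 0..3) in the quad's cyclic order;
  # winding sign from the signed angular order of the quad corners
  ks <- 0:3
  dang <- diff(ang)
  wind <- if (sum(sin(dang)) >= 0) 1 else -1
  off <- Arg(mean(exp(1i * (ang - wind * ks * pi / 2))))
  tang <- off + wind * ks * pi / 2
  radials <- cos(tang) %o% e1 + sin(tang) %o% e2  # exact unit radial directions
  corners <- matrix(p, 4L, 3L, byrow = TRUE) + start_radius * radials
  list(insertion = p, normal = u, corners = corners, radials = radials)
}

# Static linear isotropic elasticity on tets with Dirichlet constraints.
# verts: n x 3 rest positions; tets: m x 4; constrained: vertex indices with
# prescribed displacement rows `u_c`. Returns n x 3 displacement field.
solve_linear_elasticity <- function(verts, tets, constrained, u_c,
                                    poisson, young) {
  n <- nrow(verts)
  m <- nrow(tets)
  E <- young
  nu <- poisson
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))

  # shape-function gradients, vectorized over elements: with edge vectors
  # e1,e2,e3 from vertex 1, grad(xi_1) = (e2 x e3)/det etc. (rows of the
  # inverse of the matrix whose columns are the edges)
  X1 <- verts[tets[, 1L], , drop = FALSE]
  e1 <- verts[tets[, 2L], , drop = FALSE] - X1
  e2 <- verts[tets[, 3L], , drop = FALSE] - X1
  e3 <- verts[tets[, 4L], , drop = FALSE] - X1
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
  detJ <- rowSums(e1 * c23)
  vol <- detJ / 6
  gN <- array(0, c(m, 4L, 3L))
  gN[, 2L, ] <- c23 / detJ
  gN[, 3L, ] <- c31 / detJ
  gN[, 4L, ] <- c12 / detJ
  gN[, 1L, ] <- -(gN[, 2L, ] + gN[, 3L, ] + gN[, 4L, ])

  # K_{ai,bj} = V (lambda dNa_i dNb_j + mu dNa_j dNb_i + mu d_ij dNa.dNb)
  nz <- 144L * m
  ii <- integer(nz); jj <- integer(nz); xx <- numeric(nz)
  pos <- 0L
  dof <- function(a, i) (tets[, a] - 1L) * 3L + i
  for (a in 1:4) for (b in 1:4) {
    dot_ab <- gN[, a, 1L] * gN[, b, 1L] + gN[, a, 2L] * gN[, b, 2L] +
      gN[, a, 3L] * gN[, b, 3L]
    for (i in 1:3) for (j in 1:3) {
      val <- vol * (lambda * gN[, a, i] * gN[, b, j] +
                      mu * gN[, a, j] * gN[, b, i] +
                      (if (i == j) mu * dot_ab else 0))
      idx <- pos + seq_len(m)
      ii[idx] <- dof(a, i)
      jj[idx] <- dof(b, j)
      xx[idx] <- val
      pos <- pos + m
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, 3L * n))

  cd <- as.integer(rbind((constrained - 1L) * 3L + 1L,
                         (constrained - 1L) * 3L + 2L,
                         (constrained - 1L) * 3L + 3L))
  uc <- as.numeric(t(u_c))
  free <- setdiff(seq_len(3L * n), cd)
  u <- numeric(3L * n)
  u[cd] <- uc
  rhs <- -K[free, cd, drop = FALSE] %*% uc
  u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  matrix(u, n, 3L, byrow = TRUE)
}

#' Sweep the Poisson's ratio and record the soma volume
#'
#' Deforms the soma once per Poisson's ratio value with a fixed anchor set and
#' measures the resulting surface volume. Lower ratios let the pulled
#' membrane swell, so the volume sequence is expected to be non-increasing in
#' the ratio.
#'
#' @param icosphere quad-paired icosphere.
#' @param anchors assigned anchors ([select_neurite_quads()]).
#' @param nu_values ascending Poisson's ratios in (-1, 0.5).
#' @return data.frame with columns `nu` and `volume` (cubic micrometres).
#' @export
poisson_sweep <- function(icosphere, anchors, nu_values) {
  stopifnot(!is.unsorted(nu_values), all(nu_values > -1), all(nu_values < 0.5))
  vols <- vapply(nu_values, function(nu) {
    d <- deform_soma(icosphere, anchors, poisson = nu)
    mesh_volume(soma_surface_mesh(d))
  }, numeric(1L))
  data.frame(nu = nu_values, volume = vols)
}

# Extract the (possibly deformed) soma surface as a quad mesh.
soma_surface_mesh <- function(icosphere) {
  stopifnot(!is.null(icosphere$surface_quads))
  S <- icosphere$n_surface
  structure(list(vertices = icosphere$vertices[seq_len(S), , drop = FALSE],
                 faces = icosphere$surface_quads),
            class = "neuro_mesh")
}
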
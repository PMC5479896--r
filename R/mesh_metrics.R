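# Faces of a mesh as a list of integer vectors (rows of a matrix, or a list
# for mixed polygon sizes).
face_list <- function(mesh) {
  f <- mesh$faces
  if (is.list(f)) return(f)
  lapply(seq_len(nrow(f)), function(i) as.integer(f[i, ]))
}

mesh_edge_table <- function(mesh) {
  fl <- face_list(mesh)
  a <- integer(0); b <- integer(0)
  from <- unlist(lapply(fl, function(v) v))
  to <- unlist(lapply(fl, function(v) c(v[-1L], v[1L])))
  data.frame(from = from, to = to)
}

#' Topology report for a surface mesh
#'
#' Computes the quantities used to certify the generated meshes: vertex,
#' edge and face counts, Euler characteristic, closedness (every edge shared
#' by exactly two faces), manifoldness with consistent orientation (the two
#' incident faces traverse the edge in opposite directions), number of
#' connected components, and — when the mesh is closed — its signed volume.
#'
#' @param mesh list with `vertices` (n x 3) and `faces` (matrix or list of
#'   integer vectors).
#' @return object of class `mesh_report`: list with `n_vertices`, `n_faces`,
#'   `n_edges`, `euler_characteristic`, `is_closed`, `is_manifold`,
#'   `n_components`, `n_boundary_edges`, `volume` (NA when open) and
#'   `flags` (character).
#' @export
is_closed_manifold <- function(mesh) {
  et <- mesh_edge_table(mesh)
  nV <- nrow(mesh$vertices)
  nF <- length(face_list(mesh))
  key <- paste0(pmin(et$from, et$to), "_", pmax(et$from, et$to))
  cnt <- table(key)
  nE <- length(cnt)
  flags <- character(0)
  closed <- all(cnt == 2L)
  over <- any(cnt > 2L)
  if (over) flags <- c(flags, "non-manifold edge (more than 2 incident faces)")
  n_boundary <- sum(cnt == 1L)
  if (n_boundary > 0L) flags <- c(flags, sprintf("%d boundary edges", n_boundary))
  # orientation consistency: for every edge seen twice, the directed versions
  # must be opposite, i.e. no directed edge repeats
  oriented <- !anyDuplicated(paste0(et$from, ">", et$to))
  if (!oriented) flags <- c(flags, "inconsistent face orientation")
  manifold <- !over && oriented

  # connected components over mesh edges (union-find)
  parent <- seq_len(nV)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(et))) {
    ra <- find(et$from[i]); rb <- find(et$to[i])
    if (ra != rb) parent[ra] <- rb
  }
  used <- unique(c(et$from, et$to))
  ncomp <- length(unique(vapply(used, find, 0L)))
  iso <- nV - length(used)
  if (iso > 0L) flags <- c(flags, sprintf("%d isolated vertices", iso))

  vol <- if (closed && manifold) mesh_volume(mesh) else NA_real_
  structure(list(n_vertices = nV, n_faces = nF, n_edges = nE,
                 euler_characteristic = nV - nE + nF,
                 is_closed = closed, is_manifold = manifold,
                 n_components = ncomp, n_boundary_edges = n_boundary,
                 volume = vol, flags = flags),
            class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf("<mesh_report> V=%d E=%d F=%d  chi=%d  closed=%s manifold=%s components=%d\n",
              x$n_vertices, x$n_edges, x$n_faces, x$euler_characteristic,
              x$is_closed, x$is_manifold, x$n_components))
  if (!is.na(x$volume)) cat(sprintf("  volume: %.6g um^3\n", x$volume))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# fan-triangulated copy of the faces (list of 3-column matrices)
triangulated_faces <- function(mesh) {
  fl <- face_list(mesh)
  out <- lapply(fl, function(v) {
    k <- length(v)
    if (k == 3L) matrix(v, 1L, 3L)
    else cbind(v[1L], v[2:(k - 1L)], v[3:k])
  })
  do.call(rbind, out)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem (signed tetrahedra against the vertex centroid) volume;
#' positive for outward-oriented faces. Quads and larger polygons are fan
#' triangulated. Errors when the mesh has boundary edges.
#'
#' @param mesh list with `vertices` and `faces`.
#' @return volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  et <- mesh_edge_table(mesh)
  key <- paste0(pmin(et$from, et$to), "_", pmax(et$from, et$to))
  if (any(table(key) != 2L)) stop("mesh_volume requires a closed mesh")
  tri <- triangulated_faces(mesh)
  V <- mesh$vertices
  ctr <- colMeans(V)
  a <- V[tri[, 1L], , drop = FALSE] - matrix(ctr, nrow(tri), 3L, byrow = TRUE)
  b <- V[tri[, 2L], , drop = FALSE] - matrix(ctr, nrow(tri), 3L, byrow = TRUE)
  c_ <- V[tri[, 3L], , drop = FALSE] - matrix(ctr, nrow(tri), 3L, byrow = TRUE)
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
        a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
        a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Squared distances from points P (n x 3) to one triangle (v0, v1, v2),
# vectorized over P (Eberly's region decomposition).
point_triangle_dist2 <- function(P, v0, v1, v2) {
  E0 <- v1 - v0
  E1 <- v2 - v0
  a <- sum(E0 * E0); b <- sum(E0 * E1); c_ <- sum(E1 * E1)
  Dx <- v0[1L] - P[, 1L]; Dy <- v0[2L] - P[, 2L]; Dz <- v0[3L] - P[, 3L]
  d <- E0[1L] * Dx + E0[2L] * Dy + E0[3L] * Dz
  e <- E1[1L] * Dx + E1[2L] * Dy + E1[3L] * Dz
  det <- a * c_ - b * b
  s <- b * e - c_ * d
  t <- b * d - a * e

  S <- numeric(nrow(P)); Tt <- numeric(nrow(P))
  inside <- (s + t <= det) & (s >= 0) & (t >= 0)
  if (any(inside)) {
    S[inside] <- s[inside] / det
    Tt[inside] <- t[inside] / det
  }
  out <- which(!inside)
  if (length(out)) {
    so <- s[out]; to <- t[out]; d_o <- d[out]; e_o <- e[out]
    Si <- numeric(length(out)); Ti <- numeric(length(out))
    low <- so + to <= det
    r1 <- low & so < 0 & to < 0                       # region 4
    r3 <- low & so < 0 & to >= 0                      # region 3
    r5 <- low & so >= 0 & to < 0                      # region 5
    r2 <- !low & so < 0                               # region 2
    r6 <- !low & so >= 0 & to < 0                     # region 6
    r1h <- !low & so >= 0 & to >= 0                   # region 1
    if (any(r1)) {
      use_s <- d_o[r1] < 0
      Si[r1] <- ifelse(use_s, clamp01(-d_o[r1] / a), 0)
      Ti[r1] <- ifelse(use_s, 0, clamp01(-e_o[r1] / c_))
    }
    if (any(r3)) { Si[r3] <- 0; Ti[r3] <- clamp01(-e_o[r3] / c_) }
    if (any(r5)) { Ti[r5] <- 0; Si[r5] <- clamp01(-d_o[r5] / a) }
    if (any(r2)) {
      tmp0 <- b + d_o[r2]; tmp1 <- c_ + e_o[r2]
      hi <- tmp1 > tmp0
      sv <- ifelse(hi, clamp01((tmp1 - tmp0) / (a - 2 * b + c_)), 0)
      tv <- ifelse(hi, 1 - sv, clamp01(-e_o[r2] / c_))
      Si[r2] <- sv; Ti[r2] <- tv
    }
    if (any(r6)) {
      tmp0 <- b + e_o[r6]; tmp1 <- a + d_o[r6]
      hi <- tmp1 > tmp0
      tv <- ifelse(hi, clamp01((tmp1 - tmp0) / (a - 2 * b + c_)), 0)
      sv <- ifelse(hi, 1 - tv, clamp01(-d_o[r6] / a))
      Si[r6] <- sv; Ti[r6] <- tv
    }
    if (any(r1h)) {
      numer <- c_ + e_o[r1h] - b - d_o[r1h]
      sv <- ifelse(numer <= 0, 0, clamp01(numer / (a - 2 * b + c_)))
      Si[r1h] <- sv; Ti[r1h] <- 1 - sv
    }
    S[out] <- Si; Tt[out] <- Ti
  }
  qx <- v0[1L] + S * E0[1L] + Tt * E1[1L] - P[, 1L]
  qy <- v0[2L] + S * E0[2L] + Tt * E1[2L] - P[, 2L]
  qz <- v0[3L] + S * E0[3L] + Tt * E1[3L] - P[, 3L]
  qx * qx + qy * qy + qz * qz
}

# Minimum distance from each point of P to the surface of `mesh`.
points_to_surface_distance <- function(P, mesh) {
  tri <- triangulated_faces(mesh)
  V <- mesh$vertices
  best <- rep.int(Inf, nrow(P))
  for (i in seq_len(nrow(tri))) {
    d2 <- point_triangle_dist2(P, V[tri[i, 1L], ], V[tri[i, 2L], ], V[tri[i, 3L], ])
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Area-weighted uniform samples on a mesh surface (deterministic given seed).
sample_mesh_surface <- function(mesh, n_samples) {
  tri <- triangulated_faces(mesh)
  V <- mesh$vertices
  e0 <- V[tri[, 2L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  e1 <- V[tri[, 3L], , drop = FALSE] - V[tri[, 1L], , drop = FALSE]
  cr <- cbind(e0[, 2L] * e1[, 3L] - e0[, 3L] * e1[, 2L],
              e0[, 3L] * e1[, 1L] - e0[, 1L] * e1[, 3L],
              e0[, 1L] * e1[, 2L] - e0[, 2L] * e1[, 1L])
  areas <- row_norms(cr) / 2
  idx <- sample.int(nrow(tri), n_samples, replace = TRUE, prob = areas)
  u <- stats::runif(n_samples)
  v <- stats::runif(n_samples)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  V[tri[idx, 1L], , drop = FALSE] + u * e0[idx, , drop = FALSE] +
    v * e1[idx, , drop = FALSE]
}

#' Sampled symmetric Hausdorff distance summary
#'
#' Draws area-weighted random samples on each surface, measures each sample's
#' exact distance to the other surface (point-to-triangle), and summarizes
#' the pooled two-sided distances as mean, maximum and minimum — the summary
#' used to compare reconstructed and reference somata. Deterministic for a
#' fixed seed.
#'
#' @param mesh_a,mesh_b surface meshes (vertices + faces).
#' @param n_samples samples per surface (default 2000).
#' @param seed RNG seed for the sampling.
#' @return object of class `distance_summary`: list with `mean`, `maximum`,
#'   `minimum` (micrometres), `n_samples`, `seed`.
#' @export
hausdorff_summary <- function(mesh_a, mesh_b, n_samples = 2000L, seed = 1L) {
  stopifnot(length(face_list(mesh_a)) > 0L, length(face_list(mesh_b)) > 0L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  Pa <- sample_mesh_surface(mesh_a, n_samples)
  Pb <- sample_mesh_surface(mesh_b, n_samples)
  da <- points_to_surface_distance(Pa, mesh_b)
  db <- points_to_surface_distance(Pb, mesh_a)
  d <- c(da, db)
  # distances below machine precision (relative to the scene scale) are
  # reconstruction noise of the point-triangle projection; report them as 0
  scale <- max(1, abs(range(mesh_a$vertices, mesh_b$vertices)))
  d[d < 1e-12 * scale] <- 0
  structure(list(mean = mean(d), maximum = max(d), minimum = min(d),
                 n_samples = n_samples, seed = seed),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> mean %.4g, max %.4g, min %.4g um (%d samples, seed %d)\n",
              x$mean, x$maximum, x$minimum, x$n_samples, x$seed))
  invisible(x)
}
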
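#' Volumetric tetrahedral icosphere
#'
#' Builds the finite-element domain used for soma reconstruction: a subdivided
#' icosahedron projected onto the sphere of the requested radius, filled with
#' tetrahedra. At subdivision level 0 the 20 surface triangles connect directly
#' to a central vertex; at level L the interior holds L radially scaled copies
#' of the surface ("shells"), the prisms between consecutive shells are split
#' into three tetrahedra each with a sorted-column diagonal rule (so shared
#' prism faces agree), and the innermost shell connects to the centre.
#'
#' @param center soma centre, length-3 numeric (micrometres).
#' @param radius sphere radius > 0 (micrometres).
#' @param subdivision_level integer >= 0; surface vertex count is
#'   `10 * 4^level + 2`.
#' @return object of class `tet_icosphere`: list with `vertices` (n x 3),
#'   `tets` (m x 4, positively oriented), `surface_triangles` (t x 3, outward
#'   counter-clockwise, indexing the first `n_surface` vertices),
#'   `surface_quads` (`NULL` until [pair_triangles_to_quads()] is applied),
#'   `n_surface`, `center`, `radius`, `subdivision_level`.
#' @export
build_tet_icosphere <- function(center = c(0, 0, 0), radius = 1,
                                subdivision_level = 0L) {
  stopifnot(length(center) == 3L, radius > 0, subdivision_level >= 0L)
  L <- as.integer(subdivision_level)
  ico <- icosahedron_surface()
  V <- ico$vertices
  Fc <- ico$faces
  if (L > 0L) {
    for (i in seq_len(L)) {
      s <- subdivide_triangles(V, Fc)
      V <- s$vertices
      Fc <- s$faces
    }
  }
  V <- V / row_norms(V)  # unit directions
  S <- nrow(V)

  layers <- L + 1L  # surface + L interior shells
  verts <- matrix(0, S * layers + 1L, 3L)
  for (k in seq_len(layers)) {
    rk <- radius * (layers - k + 1L) / layers
    verts[(k - 1L) * S + seq_len(S), ] <- V * rk
  }
  # last vertex = centre
  verts <- sweep(verts, 2L, center, "+")
  cid <- S * layers + 1L

  tets <- vector("list", layers)
  if (layers > 1L) {
    for (k in seq_len(layers - 1L)) {
      off_o <- (k - 1L) * S
      off_i <- k * S
      # per triangle, columns sorted by surface vertex index
      Fs <- t(apply(Fc, 1L, sort))
      Oi <- off_o + Fs[, 1L]; Oj <- off_o + Fs[, 2L]; Ok <- off_o + Fs[, 3L]
      Ii <- off_i + Fs[, 1L]; Ij <- off_i + Fs[, 2L]; Ik <- off_i + Fs[, 3L]
      tets[[k]] <- rbind(cbind(Oi, Oj, Ok, Ii),
                         cbind(Oj, Ok, Ii, Ij),
                         cbind(Ok, Ii, Ij, Ik))
    }
  }
  off_last <- (layers - 1L) * S
  tets[[layers]] <- cbind(off_last + Fc[, 1L], off_last + Fc[, 2L],
                          off_last + Fc[, 3L], cid)
  tets <- do.call(rbind, tets)
  dimnames(tets) <- NULL

  # enforce positive orientation
  vol6 <- tet_signed_volumes(verts, tets) * 6
  neg <- vol6 < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  if (any(tet_signed_volumes(verts, tets) <= 0)) {
    stop("degenerate tetrahedron in icosphere construction")
  }

  structure(list(vertices = verts, tets = tets, surface_triangles = Fc,
                 surface_quads = NULL, n_surface = S, center = as.numeric(center),
                 radius = radius, subdivision_level = L),
            class = "tet_icosphere")
}

icosahedron_surface <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- matrix(c(-1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
                 0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
                 t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1),
              ncol = 3L, byrow = TRUE)
  Fc <- matrix(c(1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
                 2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
                 4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
                 5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
               ncol = 3L, byrow = TRUE)
  storage.mode(Fc) <- "integer"
  list(vertices = V, faces = Fc)
}

subdivide_triangles <- function(V, Fc) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vector("list", nrow(V) + 3L * nrow(Fc))
  for (i in seq_len(nrow(V))) verts[[i]] <- V[i, ]
  nv <- nrow(V)
  midpoint <- function(a, b) {
    key <- paste0(min(a, b), "_", max(a, b))
    id <- env[[key]]
    if (!is.null(id)) return(id)
    nv <<- nv + 1L
    verts[[nv]] <<- (V[a, ] + V[b, ]) / 2
    env[[key]] <- nv
    nv
  }
  out <- matrix(0L, nrow(Fc) * 4L, 3L)
  for (f in seq_len(nrow(Fc))) {
    a <- Fc[f, 1L]; b <- Fc[f, 2L]; c_ <- Fc[f, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
    out[(f - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                        c(c_, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts[seq_len(nv)]), faces = out)
}

tet_signed_volumes <- function(verts, tets) {
  a <- verts[tets[, 1L], , drop = FALSE]
  b <- verts[tets[, 2L], , drop = FALSE] - a
  c_ <- verts[tets[, 3L], , drop = FALSE] - a
  d <- verts[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c_[, 2L] * d[, 3L] - c_[, 3L] * d[, 2L]) +
     b[, 2L] * (c_[, 3L] * d[, 1L] - c_[, 1L] * d[, 3L]) +
     b[, 3L] * (c_[, 1L] * d[, 2L] - c_[, 2L] * d[, 1L])) / 6
}

#' Pair adjacent surface triangles into quads
#'
#' Finds a perfect matching on the triangle adjacency (dual) graph of the
#' icosphere surface and merges each matched pair into a quad, preferring
#' coplanar pairs. The search is greedy on a planarity score (dot product of
#' the two triangle normals, ties broken by lowest triangle index) with full
#' backtracking, so a perfect matching is always found when one exists; the
#' surface of any icosphere admits one.
#'
#' @param icosphere a [build_tet_icosphere()] object.
#' @return the icosphere with `surface_quads` filled in (q x 4, outward
#'   counter-clockwise, one row per merged triangle pair).
#' @export
pair_triangles_to_quads <- function(icosphere) {
  stopifnot(inherits(icosphere, "tet_icosphere"))
  Fc <- icosphere$surface_triangles
  nt <- nrow(Fc)
  if (nt %% 2L != 0L) stop("odd number of surface triangles; cannot pair")
  V <- icosphere$vertices

  # adjacency via shared (sorted) edges
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  edges <- rbind(
    data.frame(f = seq_len(nt), key = ekey(Fc[, 1L], Fc[, 2L])),
    data.frame(f = seq_len(nt), key = ekey(Fc[, 2L], Fc[, 3L])),
    data.frame(f = seq_len(nt), key = ekey(Fc[, 3L], Fc[, 1L])))
  sp <- split(edges$f, edges$key)
  if (any(lengths(sp) != 2L)) stop("surface is not closed")
  pairs <- do.call(rbind, sp)  # each row: two triangles sharing an edge

  normals <- triangle_normals(V, Fc)
  score <- rowSums(normals[pairs[, 1L], , drop = FALSE] *
                     normals[pairs[, 2L], , drop = FALSE])
  nb <- vector("list", nt)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    nb[[a]] <- rbind(nb[[a]], c(b, score[i]))
    nb[[b]] <- rbind(nb[[b]], c(a, score[i]))
  }
  # order each neighbor list: best score first, lowest index on ties
  for (i in seq_len(nt)) {
    o <- order(-nb[[i]][, 2L], nb[[i]][, 1L])
    nb[[i]] <- nb[[i]][o, , drop = FALSE]
  }

  mate <- integer(nt)  # 0 = unmatched
  stack <- list()      # backtracking: records (a, b, alternatives tried)
  choice <- list()
  repeat {
    a <- match(0L, mate)
    if (is.na(a)) break
    tried <- 0L
    repeat {
      cand <- nb[[a]][, 1L]
      cand <- cand[mate[cand] == 0L]
      if (length(cand) > tried) {
        b <- cand[tried + 1L]
        mate[a] <- b
        mate[b] <- a
        stack[[length(stack) + 1L]] <- c(a, b, tried + 1L)
        break
      }
      # dead end: backtrack
      if (length(stack) == 0L) stop("no perfect quad pairing found; use a different subdivision level")
      last <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      mate[last[1L]] <- 0L
      mate[last[2L]] <- 0L
      a <- last[1L]
      tried <- last[3L]
    }
  }

  done <- rep.int(FALSE, nt)
  quads <- matrix(0L, nt / 2L, 4L)
  q <- 0L
  for (a in seq_len(nt)) {
    if (done[a]) next
    b <- mate[a]
    done[a] <- TRUE
    done[b] <- TRUE
    q <- q + 1L
    quads[q, ] <- merge_triangle_pair(Fc[a, ], Fc[b, ])
  }
  icosphere$surface_quads <- quads
  icosphere
}

triangle_normals <- function(V, Fc) {
  e1 <- V[Fc[, 2L], , drop = FALSE] - V[Fc[, 1L], , drop = FALSE]
  e2 <- V[Fc[, 3L], , drop = FALSE] - V[Fc[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n / row_norms(n)
}

# Merge ccw triangles t1, t2 sharing one edge into a ccw quad (u, q, v, p)
# where (u, v) is the shared edge directed as it appears in t1. Starting the
# cycle at u makes the standard fan triangulation (1,2,3)+(1,3,4) reproduce
# the two source triangles exactly (the fan diagonal is the shared edge).
merge_triangle_pair <- function(t1, t2) {
  shared <- intersect(t1, t2)
  if (length(shared) != 2L) stop("triangles do not share an edge")
  p <- setdiff(t1, shared)
  q <- setdiff(t2, shared)
  for (k in 1:3) {
    u <- t1[k]; v <- t1[if (k == 3L) 1L else k + 1L]
    if (u %in% shared && v %in% shared) return(c(u, q, v, p))
  }
  stop("inconsistent triangle orientation")
}

#' @export
print.tet_icosphere <- function(x, ...) {
  cat(sprintf("<tet_icosphere> level %d: %d vertices (%d surface), %d tets%s\n",
              x$subdivision_level, nrow(x$vertices), x$n_surface, nrow(x$tets),
              if (is.null(x$surface_quads)) "" else
                sprintf(", %d surface quads", nrow(x$surface_quads))))
  invisible(x)
}
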
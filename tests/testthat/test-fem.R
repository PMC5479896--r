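make_ico <- function(level = 1L, r = 1, center = c(0, 0, 0)) {
  pair_triangles_to_quads(build_tet_icosphere(center, r, level))
}

anchor_df <- function(pos, radius = 0.2) {
  data.frame(root_id = seq_len(nrow(pos)),
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             radius = rep_len(radius, nrow(pos)))
}

test_that("neurite-quad selection picks aligned, distinct quads", {
  ico <- make_ico(1L)
  qc <- neurotess:::quad_centroids(ico$vertices, ico$surface_quads)
  # one anchor exactly along a quad centroid direction gets that quad
  target <- 7L
  a <- anchor_df(matrix(1.3 * qc[target, ] / sqrt(sum(qc[target, ]^2)), 1L))
  sel <- select_neurite_quads(ico, a)
  expect_equal(sel$quad, target)

  # opposite anchors: distinct, and jointly optimal vs brute force over pairs
  ico0 <- make_ico(0L)
  a2 <- anchor_df(rbind(c(0, 0, 1.3), c(0, 0, -1.3)))
  sel2 <- select_neurite_quads(ico0, a2)
  expect_equal(length(unique(sel2$quad)), 2L)
  qc0 <- neurotess:::quad_centroids(ico0$vertices, ico0$surface_quads)
  qd <- qc0 / sqrt(rowSums(qc0^2))
  ad <- rbind(c(0, 0, 1), c(0, 0, -1))
  cost <- matrix(acos(pmin(1, pmax(-1, as.numeric(ad %*% t(qd))))), 2L, 10L)
  best <- Inf
  for (i in 1:10) for (j in 1:10) {
    if (i != j) best <- min(best, cost[1L, i] + cost[2L, j])
  }
  expect_equal(cost[1L, sel2$quad[1L]] + cost[2L, sel2$quad[2L]], best,
               tolerance = 1e-12)

  # empty anchor set passes through
  sel0 <- select_neurite_quads(ico, anchor_df(matrix(0, 0L, 3L)))
  expect_equal(nrow(sel0), 0L)
})

test_that("deformation with no anchors is the identity", {
  ico <- make_ico(1L)
  out <- deform_soma(ico, data.frame())
  expect_identical(out$vertices, ico$vertices)
})

test_that("rigid translation of the boundary translates the interior", {
  ico <- make_ico(0L)
  S <- ico$n_surface
  d <- c(0.3, -0.2, 0.7)
  disp <- neurotess:::solve_linear_elasticity(
    ico$vertices, ico$tets, seq_len(S),
    matrix(d, S, 3L, byrow = TRUE), 0.3, 1)
  expect_lt(max(abs(sweep(disp, 2L, d))), 1e-10)
})

test_that("linear patch test: affine boundary field is reproduced exactly", {
  ico <- make_ico(1L)
  S <- ico$n_surface
  A <- matrix(c(1.2, 0.1, 0, -0.05, 0.9, 0.2, 0, 0.1, 1.1), 3L, 3L)
  b <- c(0.3, -0.2, 0.5)
  affine <- function(X) t(A %*% t(X)) + matrix(b, nrow(X), 3L, byrow = TRUE)
  disp <- neurotess:::solve_linear_elasticity(
    ico$vertices, ico$tets, seq_len(S),
    affine(ico$vertices[seq_len(S), ]) - ico$vertices[seq_len(S), ], 0.25, 1)
  expect_lt(max(abs(ico$vertices + disp - affine(ico$vertices))), 1e-8)
})

test_that("solution is independent of the Young's modulus", {
  ico <- make_ico(1L)
  a <- anchor_df(rbind(c(0, 0, 1.4), c(1.2, 0.5, 0)), radius = 0.25)
  a <- select_neurite_quads(ico, a)
  d1 <- deform_soma(ico, a, poisson = 0.3, young = 1)
  d2 <- deform_soma(ico, a, poisson = 0.3, young = 10)
  expect_lt(max(abs(d1$vertices - d2$vertices)), 1e-10)
})

test_that("mirrored anchors on the mirrored domain deform mirror-symmetrically", {
  # reflect the whole elastic problem about x = 0 (vertices mirrored, tets
  # re-oriented, quad winding restored, anchors mirrored onto the same quad
  # indices): the deformed meshes must be exact mirror images
  ico <- make_ico(1L)
  a <- anchor_df(rbind(c(0.9, 0.6, 0.8), c(0.2, -0.5, 1.1)), radius = 0.2)
  a <- select_neurite_quads(ico, a)
  d1 <- deform_soma(ico, a, poisson = 0.3)

  ico2 <- ico
  ico2$vertices[, 1L] <- -ico2$vertices[, 1L]
  ico2$tets[, c(3L, 4L)] <- ico2$tets[, c(4L, 3L)]
  ico2$surface_quads <- ico2$surface_quads[, c(4L, 3L, 2L, 1L)]
  a2 <- a
  a2$x <- -a2$x
  d2 <- deform_soma(ico2, a2, poisson = 0.3)
  Vm <- d2$vertices
  Vm[, 1L] <- -Vm[, 1L]
  expect_lt(max(abs(d1$vertices - Vm)), 1e-8)
})

test_that("anchor squares sit at the insertion point with the start radius", {
  ico <- make_ico(1L, r = 8)
  a <- anchor_df(rbind(c(0, 0, 9.5), c(8.8, 2.2, 0)), radius = 1.2)
  a <- select_neurite_quads(ico, a)
  d <- deform_soma(ico, a, poisson = 0.3)
  for (i in 1:2) {
    fr <- d$anchor_frames[[i]]
    qv <- d$surface_quads[a$quad[i], ]
    expect_equal(d$vertices[qv, ], fr$corners)
    cd <- sqrt(rowSums(sweep(fr$corners, 2L, fr$insertion)^2))
    expect_lt(max(abs(cd - 1.2)), 1e-12)
    # square: side lengths all equal to radius * sqrt(2)
    side <- sqrt(rowSums((fr$corners[c(2:4, 1L), ] - fr$corners)^2))
    expect_lt(max(abs(side - 1.2 * sqrt(2))), 1e-12)
    # planar and normal to the insertion direction
    rel <- sweep(fr$corners, 2L, fr$insertion)
    expect_lt(max(abs(rel %*% fr$normal)), 1e-12)
  }
  # deformed surface still closed and manifold
  rep <- is_closed_manifold(neurotess:::soma_surface_mesh(d))
  expect_true(rep$is_closed && rep$is_manifold)
})

test_that("poisson sweep volumes are non-increasing in the Poisson ratio", {
  ico <- make_ico(1L, r = 8)
  a <- anchor_df(rbind(c(0, 0, 10), c(9.5, 3, 0), c(-4, -9, 2)), radius = 1)
  a <- select_neurite_quads(ico, a)
  nus <- c(-0.4, -0.2, 0, 0.2, 0.35, 0.45)
  ps <- poisson_sweep(ico, a, nus)
  expect_equal(ps$nu, nus)
  expect_true(all(diff(ps$volume) <= 1e-9))

  # single value gives a single pair; no anchors gives a constant volume
  ps1 <- poisson_sweep(ico, a, 0.3)
  expect_equal(nrow(ps1), 1L)
  ps0 <- poisson_sweep(ico, data.frame(), c(0, 0.3))
  expect_equal(ps0$volume[1L], ps0$volume[2L])
})
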
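test_that("orientation vectors follow the standard/bifurcation/ending rules", {
  expect_equal(orientation_vector(c(0, 0, 1), list(c(0, 0, 1))), c(0, 0, 1))
  expect_equal(orientation_vector(c(1, 0, 0), list(c(0, 1, 0))),
               c(1, 1, 0) / sqrt(2))
  # bifurcation ignores the parent direction
  o1 <- orientation_vector(c(0, 0, 1), list(c(1, 0, 0), c(0, 1, 0)))
  o2 <- orientation_vector(c(0.5, -0.3, 0.2), list(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(o1, c(1, 1, 0) / sqrt(2))
  expect_identical(o1, o2)
  # ending
  expect_equal(orientation_vector(c(0, 1, 0), list()), c(0, 1, 0))
  # hairpin: deterministic unit vector orthogonal to the parent direction
  oh <- orientation_vector(c(0, 0, 1), list(c(0, 0, -1)))
  expect_lt(abs(sum(oh * c(0, 0, 1))), 1e-12)
  expect_equal(sqrt(sum(oh^2)), 1)
})

test_that("the bifurcation extra vertex sits one radius along the orientation", {
  expect_equal(bifurcation_vertex(c(0, 0, 0), c(0, 0, 1), 2), c(0, 0, 2))
  expect_equal(bifurcation_vertex(c(1, 2, 3), c(0, 1, 0), 0), c(1, 2, 3))
  o <- c(1, 2, 2) / 3
  v <- bifurcation_vertex(c(0.5, -1, 2), o, 1.7)
  expect_equal(sqrt(sum((v - c(0.5, -1, 2))^2)), 1.7)
})

test_that("bifurcation quads split along the diagonal nearest the child plane", {
  # ring in the xy-plane, children in the xz-plane, symmetric about the
  # v0-v2 diagonal (the x axis)
  corners <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  sp <- split_bifurcation_quad(corners, c(0, 0, 0), c(3, 0, 2), c(-3, 0, 2))
  expect_equal(sp$diagonal, c(1L, 3L))
  expect_equal(sp$rings, list(c(1L, 2L, 3L, 5L), c(1L, 5L, 3L, 4L)))
  # label-order invariance
  sp2 <- split_bifurcation_quad(corners, c(0, 0, 0), c(-3, 0, 2), c(3, 0, 2))
  expect_identical(sp2, sp)
  # other diagonal when the plane contains the v1-v3 axis instead
  sp3 <- split_bifurcation_quad(corners, c(0, 0, 0), c(0, 3, 2), c(0, -3, 2))
  expect_equal(sp3$diagonal, c(2L, 4L))
  # choice matches the exhaustive minimum of the plane-distance score
  set.seed(42)
  for (k in 1:25) {
    c1 <- stats::rnorm(3); c2 <- stats::rnorm(3)
    w <- neurotess:::vec_cross(c1, c2)
    if (sqrt(sum(w^2)) < 1e-6) next
    w <- w / sqrt(sum(w^2))
    d <- abs(as.numeric(corners %*% w))
    want <- if (d[1L] + d[3L] <= d[2L] + d[4L]) c(1L, 3L) else c(2L, 4L)
    got <- split_bifurcation_quad(corners, c(0, 0, 0), c1, c2)$diagonal
    expect_equal(got, want)
  }
  # degenerate separating plane falls back with a warning
  expect_warning(
    spd <- split_bifurcation_quad(corners, c(0, 0, 0), c(0, 0, 2), c(0, 0, 4)),
    "collinear")
  expect_equal(spd$diagonal, c(1L, 3L))
})

test_that("straight tubes put section-quad corners one radius off the axis", {
  tr <- straight_tube_tracing(k = 4L, radius = 1)
  m <- generate_coarse_mesh(tr)
  tube <- which(m$attrs$point_id != 1L)
  V <- m$vertices[tube, ]
  expect_lt(max(abs(sqrt(V[, 1L]^2 + V[, 2L]^2) - 1)), 1e-12)
  # section planes are parallel (all normals along z)
  expect_lt(max(abs(m$attrs$oz[tube] - 1)), 1e-12)
})

test_that("tapering radii scale the section quads", {
  pts <- data.frame(id = 1:3, type = c(1L, 3L, 3L),
                    x = 0, y = 0, z = c(0, 9, 14),
                    radius = c(8, 2, 1), parent = c(-1L, 1L, 2L))
  m <- generate_coarse_mesh(swc_tracing(pts))
  d2 <- sqrt(rowSums(sweep(m$vertices[m$attrs$point_id == 2L, ], 2L,
                           c(0, 0, 9))^2))
  d3 <- sqrt(rowSums(sweep(m$vertices[m$attrs$point_id == 3L, ], 2L,
                           c(0, 0, 14))^2))
  expect_lt(max(abs(d2 - 2)), 1e-12)
  expect_lt(max(abs(d3 - 1)), 1e-12)
})

test_that("face census matches the closed-form construction counts", {
  soma_quads <- function(m) sum(m$patch$kind == "soma")
  for (k in c(2L, 3L, 5L)) {
    tr <- straight_tube_tracing(k = k)
    m <- suppressWarnings(generate_coarse_mesh(tr))
    expect_equal(sum(m$patch$kind == "lateral"), 4L * (k - 1L))
    expect_equal(sum(m$patch$kind == "cap"), 1L)
    # one anchor quad replaced by the tube; 4(k-1) new ring vertices
    expect_equal(nrow(m$vertices), 162L + 4L * (k - 1L))
    rep <- is_closed_manifold(m)
    expect_true(rep$is_closed && rep$is_manifold)
    expect_equal(rep$euler_characteristic, 2L)
  }
  # Y neurite: chain 2-3-4 (2 segments) + two 1-segment children at the
  # bifurcation = 4 segments -> 16 laterals, 2 caps
  tr <- y_tracing()
  m <- generate_coarse_mesh(tr)
  expect_equal(sum(m$patch$kind == "lateral"), 16L)
  expect_equal(sum(m$patch$kind == "cap"), 2L)
  rep <- is_closed_manifold(m)
  expect_true(rep$is_closed && rep$is_manifold)
  expect_equal(rep$euler_characteristic, 2L)
  expect_equal(rep$n_components, 1L)
})

test_that("soma-only tracings give the closed soma sphere", {
  f <- write_swc_lines("1 1 0 0 0 5.0 -1")
  m <- generate_coarse_mesh(read_swc(f))
  rep <- is_closed_manifold(m)
  expect_true(rep$is_closed && rep$is_manifold)
  expect_equal(rep$euler_characteristic, 2L)
  expect_equal(sum(m$patch$kind != "soma"), 0L)
  expect_equal(rep$volume, mesh_volume(m))
})

test_that("tracing positions and radii are preserved bit-exactly in attributes", {
  tr <- small_morphology(4, n_neurites = 3L)
  m <- generate_coarse_mesh(tr)
  pts <- tr$points
  for (i in which(pts$type != 1L)) {
    rows <- which(m$attrs$point_id == pts$id[i])
    expect_gt(length(rows), 0L)
    expect_identical(unique(m$attrs$cx[rows]), pts$x[i])
    expect_identical(unique(m$attrs$cy[rows]), pts$y[i])
    expect_identical(unique(m$attrs$cz[rows]), pts$z[i])
    expect_identical(unique(m$attrs$radius[rows]), pts$radius[i])
  }
  # orientation and normal attributes are unit vectors
  on <- as.matrix(m$attrs[, c("ox", "oy", "oz")])
  nn <- as.matrix(m$attrs[, c("nx", "ny", "nz")])
  expect_lt(max(abs(sqrt(rowSums(on^2)) - 1)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(nn^2)) - 1)), 1e-9)
})

test_that("strong anchor pulls report inverted interior tetrahedra", {
  # large deformations can fold interior elements; the surface pipeline
  # reports this with a count and carries on
  expect_warning(generate_coarse_mesh(small_morphology(2)), "inverted tetrahedra")
})

test_that("seeded synthetic morphologies mesh closed and manifold", {
  for (seed in 1:12) {
    tr <- small_morphology(seed, n_neurites = 1L + seed %% 4L,
                           branch_probability = c(0, 0.4, 0.8)[1L + seed %% 3L],
                           taper_ratio = c(0.85, 1)[1L + seed %% 2L])
    m <- suppressWarnings(generate_coarse_mesh(tr))
    rep <- is_closed_manifold(m)
    expect_true(rep$is_closed, info = paste("seed", seed))
    expect_true(rep$is_manifold, info = paste("seed", seed))
    expect_equal(rep$euler_characteristic, 2L, info = paste("seed", seed))
    expect_equal(rep$n_components, 1L)
  }
})

test_that("trifurcations are split recursively and stay watertight", {
  pts <- data.frame(
    id = 1:7,
    type = c(1L, 3L, 3L, 3L, 3L, 3L, 3L),
    x = c(0, 0, 0, 5, -5, 0, 0),
    y = c(0, 0, 0, 1, 1, 5, -5),
    z = c(0, 9, 14, 19, 19, 19, 19),
    radius = c(8, 1.5, 1.4, 1, 1, 1, 1),
    parent = c(-1L, 1L, 2L, 3L, 3L, 3L, 3L))
  tr <- swc_tracing(pts)
  expect_message(m <- generate_coarse_mesh(tr), "trifurcation")
  rep <- is_closed_manifold(m)
  expect_true(rep$is_closed && rep$is_manifold)
  expect_equal(rep$euler_characteristic, 2L)
  expect_equal(sum(m$patch$kind == "cap"), 4L)
})
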
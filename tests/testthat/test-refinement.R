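test_that("camera importance is maximal near, one far, monotone in distance", {
  tr <- straight_tube_tracing(k = 5L)
  cam <- as.numeric(tr$points[2L, c("x", "y", "z")])
  imp <- importance_from_camera(tr, cam, max_level = 6, near = 3, far = 20)
  expect_equal(unname(imp["2"]), 6)
  far_imp <- importance_from_camera(tr, c(0, 0, 1e5), max_level = 6,
                                    near = 3, far = 20)
  expect_true(all(far_imp == 1))
  d <- sqrt((tr$points$x - cam[1L])^2 + (tr$points$y - cam[2L])^2 +
              (tr$points$z - cam[3L])^2)
  expect_true(all(diff(imp[order(d)]) <= 1e-12))
  expect_error(importance_from_camera(tr, cam, 6, near = 20, far = 20), "near")
})

test_that("subdivision levels are weighted sums, clamped and edge-consistent", {
  tr <- y_tracing()
  m <- suppressWarnings(generate_coarse_mesh(tr))
  # constant field k -> outer k, inner k everywhere
  lv <- subdivision_levels(m, 3, max_level = 8)
  lat <- m$patch$kind == "lateral"
  expect_true(all(lv$outer[lat, ] == 3L))
  expect_true(all(lv$inner[lat] == 3L))
  # arithmetic: importances 2 and 4 with weight .5 average to outer 3
  expect_equal(neurotess:::round_half_up(0.5 * 2 + 0.5 * 4), 3)
  # shared edges get identical outer levels for random fields
  ids <- m$attrs$point_id
  set.seed(1)
  for (trial in 1:200) {
    imp <- stats::runif(length(unique(ids)), 1, 6)
    names(imp) <- unique(ids)
    lv <- subdivision_levels(m, imp, max_level = 6)
    seen <- new.env(parent = emptyenv())
    for (f in which(lat)) for (s in 1:4) {
      a <- m$faces[f, s]; b <- m$faces[f, if (s == 4L) 1L else s + 1L]
      key <- paste0(min(a, b), "_", max(a, b))
      prev <- seen[[key]]
      if (is.null(prev)) seen[[key]] <- lv$outer[f, s]
      else expect_identical(prev, lv$outer[f, s])
    }
  }
})

tri_area2 <- function(co, tris) {
  p <- cbind(co$x, co$y)
  a <- p[tris[, 1L], , drop = FALSE]
  b <- p[tris[, 2L], , drop = FALSE]
  c_ <- p[tris[, 3L], , drop = FALSE]
  (b[, 1L] - a[, 1L]) * (c_[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c_[, 1L] - a[, 1L])
}

test_that("patch tessellation covers the square without cracks or overlaps", {
  # identity level
  tp <- tessellate_patch(c(1, 1, 1, 1), 1)
  expect_equal(nrow(tp$coords), 4L)
  expect_equal(nrow(tp$triangles), 2L)
  # uniform level 2: 3x3 grid, 8 triangles
  tp <- tessellate_patch(c(2, 2, 2, 2), 2)
  expect_equal(nrow(tp$coords), 9L)
  expect_equal(nrow(tp$triangles), 8L)
  # assorted level combinations: area exactly 1, all ccw, boundary census
  cases <- list(c(1, 3, 1, 3), c(3, 1, 2, 5), c(4, 4, 4, 4), c(2, 6, 3, 1))
  inners <- c(1L, 2L, 4L, 3L)
  for (i in seq_along(cases)) {
    tp <- tessellate_patch(cases[[i]], inners[i])
    ar <- tri_area2(tp$coords, tp$triangles)
    expect_true(all(ar > 0))
    expect_lt(abs(sum(ar) / 2 - 1), 1e-12)
    expect_false(anyDuplicated(paste(tp$coords$x, tp$coords$y)) > 0)
    for (s in 1:4) {
      expect_equal(sum(tp$coords$loc == "edge" & tp$coords$side == s),
                   cases[[i]][s] - 1L)
    }
  }
})

test_that("the Hermite centerline interpolates its endpoints exactly", {
  set.seed(7)
  ok <- TRUE
  for (k in 1:2000) {
    t0 <- stats::rnorm(3); t1 <- stats::rnorm(3)
    o0 <- neurotess:::vec_normalize(stats::rnorm(3))
    o1 <- neurotess:::vec_normalize(stats::rnorm(3))
    cc <- hermite_center(t0, o0, t1, o1, c(0, 1))
    ok <- ok && identical(cc[1L, ], t0) && identical(cc[2L, ], t1)
  }
  expect_true(ok)
  # collinear unit-tangent midpoint matches the direct polynomial value
  cc <- hermite_center(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), 0.5)
  expect_equal(cc[1L, ], c(0.5, 0, 0))
  # partition of unity on the position basis functions
  y <- stats::runif(50)
  h00 <- 2 * y^3 - 3 * y^2 + 1
  h01 <- -2 * y^3 + 3 * y^2
  expect_lt(max(abs(h00 + h01 - 1)), 1e-12)
})

test_that("displaced vertices sit exactly one radius from their centre", {
  tr <- y_tracing()
  m <- suppressWarnings(generate_coarse_mesh(tr))
  lat <- which(m$patch$kind == "lateral")
  for (f in lat[c(1L, 5L, 9L)]) {
    x <- stats::runif(40)
    y <- stats::runif(40)
    ev <- displace_vertex(m, f, x, y)
    expect_lt(max(abs(sqrt(rowSums((ev$v - ev$c)^2)) - ev$r)), 1e-12)
    expect_lt(max(abs(sqrt(rowSums(ev$n^2)) - 1)), 1e-12)
    # endpoint radius identity at y = 0
    ev0 <- displace_vertex(m, f, stats::runif(10), rep(0, 10))
    p <- neurotess:::patch_record(m, f)
    expect_lt(max(abs(sqrt(rowSums(sweep(ev0$v, 2L, p$t0)^2)) - p$r0)), 1e-12)
  }
})

test_that("a straight constant-radius tube refines to an exact cylinder", {
  tr <- straight_tube_tracing(k = 4L, radius = 1)
  m <- suppressWarnings(generate_coarse_mesh(tr))
  r4 <- refine_mesh(m, importance = 4)
  lat <- which(m$patch$kind == "lateral")
  vids <- sort(unique(as.integer(r4$faces[r4$face_src %in% lat, ])))
  V <- r4$vertices[vids, ]
  expect_lt(max(abs(sqrt(V[, 1L]^2 + V[, 2L]^2) - 1)), 1e-12)
  vi <- r4$vertex_info[vids, ]
  expect_lt(max(abs(sqrt(rowSums((V - cbind(vi$cx, vi$cy, vi$cz))^2)) - vi$r)),
            1e-12)
})

test_that("uniform importance 1 reproduces the triangulated coarse mesh", {
  tr <- small_morphology(3)
  m <- suppressWarnings(generate_coarse_mesh(tr))
  r1 <- refine_mesh(m, importance = 1)
  expect_identical(r1$vertices, unname(m$vertices))
  expect_equal(nrow(r1$faces), 2L * nrow(m$faces))
  rep <- is_closed_manifold(r1)
  expect_true(rep$is_closed && rep$is_manifold)
})

test_that("uniformly refined tube counts match the closed-form census", {
  k <- 4L
  tr <- straight_tube_tracing(k = k)
  m <- suppressWarnings(generate_coarse_mesh(tr))
  for (L in 2:4) {
    rL <- refine_mesh(m, importance = L)
    lat <- which(m$patch$kind == "lateral")
    capf <- which(m$patch$kind == "cap")
    # each lateral patch: (L+1)^2 grid -> 2 L^2 triangles
    expect_equal(sum(rL$face_src %in% lat), 4L * (k - 1L) * 2L * L^2)
    # cap: fan over the subdivided 4L-gon
    expect_equal(sum(rL$face_src %in% capf), 4L * L)
    # tube vertices: k rings of 4L, plus longitudinal and interior points
    tube_v <- k * 4L * L + (k - 1L) * (4L * (L - 1L) + 4L * (L - 1L)^2)
    vids <- unique(as.integer(rL$faces[rL$face_src %in% c(lat, capf), ]))
    expect_equal(length(vids), tube_v + 1L)  # + cap centroid
    rep <- is_closed_manifold(rL)
    expect_true(rep$is_closed && rep$is_manifold)
    expect_equal(rep$euler_characteristic, 2L)
  }
  # monotone cost: triangle count non-decreasing in the uniform level
  counts <- vapply(1:4, function(L) nrow(refine_mesh(m, importance = L)$faces),
                   0L)
  expect_true(all(diff(counts) >= 0L))
})

test_that("shared patch edges refine to bit-identical vertex sequences", {
  tr <- small_morphology(5)
  m <- suppressWarnings(generate_coarse_mesh(tr))
  ids <- unique(m$attrs$point_id)
  lat <- which(m$patch$kind == "lateral")
  set.seed(2)
  for (trial in 1:20) {
    imp <- stats::runif(length(ids), 1, 6)
    names(imp) <- ids
    lv <- subdivision_levels(m, imp, max_level = 6)
    seen <- new.env(parent = emptyenv())
    for (f in lat) for (s in 1:4) {
      a <- m$faces[f, s]; b <- m$faces[f, if (s == 4L) 1L else s + 1L]
      key <- paste0(min(a, b), "_", max(a, b))
      prev <- seen[[key]]
      if (is.null(prev)) seen[[key]] <- c(f, s)
      else expect_identical(patch_edge_vertices(m, prev[1L], prev[2L], lv),
                            patch_edge_vertices(m, f, s, lv))
    }
  }
  # and the welded refined mesh is closed with a camera-driven field
  imp <- importance_from_camera(tr, c(0, 0, 30), max_level = 5, near = 5,
                                far = 80)
  rc <- refine_mesh(m, importance = imp, max_level = 5)
  rep <- is_closed_manifold(rc)
  expect_true(rep$is_closed && rep$is_manifold)
  expect_equal(rep$euler_characteristic, 2L)
  expect_equal(rep$n_components, 1L)
})

test_that("adaptive tangent scaling never stalls the centerline speed", {
  # orientation vectors arise as bisectors, so they live in the hemisphere of
  # the chord; with tangents scaled by the segment length the longitudinal
  # speed |dc/dy| stays positive, while a fixed large tangent module stalls
  # and loops on short segments
  n <- 5000L
  set.seed(11)
  chord_len <- stats::runif(n, 0.2, 2)
  rnd_dir <- function(n) {
    m <- matrix(stats::rnorm(3L * n), n, 3L)
    m / sqrt(rowSums(m^2))
  }
  prev_dir <- rnd_dir(n)   # direction arriving at t0
  next_dir <- rnd_dir(n)   # direction leaving t1
  e <- rnd_dir(n)          # chord direction
  o0 <- prev_dir + e; o0 <- o0 / sqrt(rowSums(o0^2))
  o1 <- e + next_dir; o1 <- o1 / sqrt(rowSums(o1^2))
  ys <- seq(0, 1, length.out = 65L)
  audit <- function(tangent_mag) {
    min_speed <- rep.int(Inf, n)
    min_progress <- rep.int(Inf, n)   # longitudinal component of dc/dy
    for (y in ys) {
      d00 <- 6 * y^2 - 6 * y
      d10 <- 3 * y^2 - 4 * y + 1
      d11 <- 3 * y^2 - 2 * y
      # c'(y) with t0 = 0, t1 = chord_len * e
      cp <- (-d00) * chord_len * e + d10 * tangent_mag * o0 +
        d11 * tangent_mag * o1
      min_speed <- pmin(min_speed, sqrt(rowSums(cp^2)))
      min_progress <- pmin(min_progress, rowSums(cp * e))
    }
    list(speed = min_speed, progress = min_progress)
  }
  adaptive <- audit(chord_len)          # module ~ segment length
  fixed <- audit(8)                     # fixed large module
  # adaptive: the curve never stalls nor doubles back along the chord
  expect_true(all(adaptive$speed > 1e-3 * chord_len))
  expect_true(all(adaptive$progress > -1e-9 * chord_len))
  # fixed module: a nonzero fraction of segments reverses (the loop artifact)
  expect_gt(sum(fixed$progress < -1e-6 * chord_len), 0L)
})
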
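# Fixtures are built in code; no binary data on disk.

write_swc_lines <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# soma + one straight neurite along +z, constant radius
straight_tube_tracing <- function(k = 4L, radius = 1, soma_radius = 8,
                                  step = 5) {
  z <- soma_radius + 1 + step * (0:(k - 1L))
  pts <- data.frame(id = c(1L, seq_len(k) + 1L),
                    type = c(1L, rep(3L, k)),
                    x = 0, y = 0, z = c(0, z),
                    radius = c(soma_radius, rep(radius, k)),
                    parent = c(-1L, 1L, seq_len(k - 1L) + 1L))
  swc_tracing(pts)
}

# soma + one neurite that bifurcates once (each child one segment)
y_tracing <- function(soma_radius = 8) {
  pts <- data.frame(
    id = 1:6,
    type = c(1L, 3L, 3L, 3L, 3L, 3L),
    x = c(0, 0, 0, 0, 4, -4),
    y = c(0, 0, 0, 0, 1, 1),
    z = c(0, 9, 14, 19, 24, 24),
    radius = c(soma_radius, 1.5, 1.4, 1.3, 1.0, 1.0),
    parent = c(-1L, 1L, 2L, 3L, 4L, 4L))
  swc_tracing(pts)
}

# axis-aligned cube [0,1]^3 as a closed quad mesh with outward orientation
cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(V) <- NULL
  # vertices: 1(0,0,0) 2(1,0,0) 3(0,1,0) 4(1,1,0) 5(0,0,1) 6(1,0,1) 7(0,1,1) 8(1,1,1)
  Fq <- rbind(c(1L, 3L, 4L, 2L),   # z = 0, outward -z
              c(5L, 6L, 8L, 7L),   # z = 1, outward +z
              c(1L, 2L, 6L, 5L),   # y = 0
              c(3L, 7L, 8L, 4L),   # y = 1
              c(1L, 5L, 7L, 3L),   # x = 0
              c(2L, 4L, 8L, 6L))   # x = 1
  structure(list(vertices = V * 1.0, faces = Fq), class = "neuro_mesh")
}

# triangle icosphere surface mesh of given level (unit radius, origin)
icosphere_tri_mesh <- function(level, radius = 1, center = c(0, 0, 0)) {
  ico <- build_tet_icosphere(center, radius, level)
  structure(list(vertices = ico$vertices[seq_len(ico$n_surface), , drop = FALSE],
                 faces = ico$surface_triangles),
            class = "neuro_mesh")
}

# closed-form volume of a regular icosahedron with circumradius R
icosahedron_volume <- function(R) {
  a <- 4 * R / sqrt(10 + 2 * sqrt(5))
  5 * (3 + sqrt(5)) / 12 * a^3
}

small_morphology <- function(seed, n_neurites = 3L, ...) {
  generate_synthetic_morphology(n_neurites = n_neurites, seed = seed,
                                points_per_section = 3L, ...)
}
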
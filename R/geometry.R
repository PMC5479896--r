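# Small 3-vector helpers shared across modules. All vectors are plain numeric
# length-3; point sets are n x 3 matrices in micrometres.

vec_norm <- function(v) sqrt(sum(v * v))

vec_normalize <- function(v, eps = 1e-300) {
  n <- vec_norm(v)
  if (n < eps) stop("cannot normalize a zero vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Deterministic unit vector orthogonal to u: cross with the smallest-index
# coordinate axis that is not (nearly) parallel to u.
vec_any_orthogonal <- function(u) {
  ax <- abs(u)
  axis <- which.min(ax)
  e <- c(0, 0, 0)
  e[axis] <- 1
  vec_normalize(vec_cross(u, e))
}

# Rotation matrix taking unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- vec_cross(a, b)
  s <- vec_norm(v)
  c_ <- sum(a * b)
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any orthogonal axis
    k <- vec_any_orthogonal(a)
    K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * ((1 - c_) / (s * s))
}

# rounding rule used for tessellation levels: round half away from zero
round_half_up <- function(x) floor(x + 0.5)

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-300)) stop("zero row in normalize_rows")
  m / n
}
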
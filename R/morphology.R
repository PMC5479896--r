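#' Neuron morphological tracings (SWC)
#'
#' A morphological tracing is a rooted tree of tracing points, each carrying a
#' 3D position (micrometres), a radius (micrometres) and a structure type code
#' (1 = soma, 2 = axon, 3 = basal dendrite, 4 = apical dendrite). The tree root
#' sits at the cell soma; neurites hang off it as polylines with per-point
#' thickness. SWC is the 7-column whitespace-separated text serialization of
#' such trees (id, type, x, y, z, radius, parent; parent -1 for the root) used
#' by NeuroMorpho and most tracing software.
#'
#' Two soma dialects are recognised: a single type-1 point (centre + average
#' radius) and a multi-point type-1 ring/contour, for which the soma centre is
#' the centroid of the type-1 points and the mean radius the average distance
#' from the centroid to those points.
#'
#' @param points data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (integer ids, numeric coordinates).
#' @param strict logical; if `TRUE` (default) structural defects raise errors,
#'   otherwise the object is built as-is so that [validate_tracing()] can
#'   report on it.
#' @param quiet logical; suppress the per-file parse statistics message.
#' @return An object of class `swc_tracing`: a list with elements `points`
#'   (the tracing-point table), `soma` (centre, mean radius, point ids,
#'   dialect), `neurite_roots` (ids of first-order neurite points) and
#'   `children` (adjacency list parallel to `points`).
#' @export
swc_tracing <- function(points, strict = TRUE, quiet = TRUE) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(points))) {
    stop("points must have columns ", paste(req, collapse = ", "))
  }
  points <- as.data.frame(points)[req]
  points$id <- as.integer(points$id)
  points$type <- as.integer(points$type)
  points$parent <- as.integer(points$parent)
  n <- nrow(points)
  if (n == 0L) stop("tracing has no points")
  if (anyDuplicated(points$id)) stop("structure error: duplicate point ids")

  row_of <- function(ids) match(ids, points$id)

  if (strict) {
    if (any(!is.finite(points$radius)) || any(points$radius <= 0)) {
      bad <- points$id[which(!(is.finite(points$radius) & points$radius > 0))[1L]]
      stop("validation error: non-positive radius at point ", bad)
    }
    roots <- which(points$parent == -1L)
    if (length(roots) != 1L) {
      stop("structure error: expected exactly one root, found ", length(roots))
    }
    notroot <- points$parent != -1L
    if (any(is.na(row_of(points$parent[notroot])))) {
      bad <- points$id[notroot][which(is.na(row_of(points$parent[notroot])))[1L]]
      stop("structure error: point ", bad, " names a parent that does not exist")
    }
    if (points$type[roots] != 1L) {
      stop("structure error: root point must be of soma type (1)")
    }
    # acyclicity + connectivity: walk each point to the root
    prow <- row_of(points$parent)
    depth <- rep.int(NA_integer_, n)
    depth[roots] <- 0L
    for (i in seq_len(n)) {
      if (!is.na(depth[i])) next
      chain <- integer(0)
      j <- i
      while (is.na(depth[j])) {
        if (j %in% chain) stop("structure error: cycle involving point ", points$id[j])
        chain <- c(chain, j)
        j <- prow[j]
      }
      d <- depth[j]
      for (k in rev(chain)) {
        d <- d + 1L
        depth[k] <- d
      }
    }
  }

  soma_rows <- which(points$type == 1L)
  if (strict && length(soma_rows) == 0L) stop("structure error: no soma (type 1) point")
  if (length(soma_rows) == 1L) {
    dialect <- "point"
    center <- as.numeric(points[soma_rows, c("x", "y", "z")])
    mean_radius <- points$radius[soma_rows]
  } else if (length(soma_rows) >= 2L) {
    dialect <- if (length(soma_rows) == 3L) "ring" else "contour"
    P <- as.matrix(points[soma_rows, c("x", "y", "z")])
    center <- colMeans(P)
    mean_radius <- mean(sqrt(rowSums(sweep(P, 2L, center)^2)))
    if (strict && mean_radius <= 0) {
      stop("validation error: degenerate soma contour (zero mean radius)")
    }
  } else {
    dialect <- "none"
    center <- c(NA_real_, NA_real_, NA_real_)
    mean_radius <- NA_real_
  }

  prow <- row_of(points$parent)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- prow[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  is_soma <- points$type == 1L
  parent_is_soma <- rep.int(FALSE, n)
  hasp <- which(!is.na(prow))
  parent_is_soma[hasp] <- is_soma[prow[hasp]]
  neurite_roots <- points$id[!is_soma & parent_is_soma]

  tr <- structure(list(
    points = points,
    soma = list(
      point_ids = points$id[soma_rows],
      center = as.numeric(center),
      mean_radius = mean_radius,
      dialect = dialect
    ),
    neurite_roots = as.integer(neurite_roots),
    children = children
  ), class = "swc_tracing")

  if (!quiet) {
    nb <- sum(lengths(children)[!is_soma] >= 2L)
    message(sprintf("swc: %d points, %d neurites, %d bifurcations, soma dialect '%s'",
                    n, length(neurite_roots), nb, dialect))
  }
  tr
}

#' Read an SWC morphological tracing
#'
#' Parses a 7-column SWC file ('#' comment lines allowed), validates the tree
#' structure and synthesizes the soma descriptor according to the soma dialect
#' (single point, or multi-point ring/contour whose centroid and mean centroid
#' distance define the soma). Consecutive points with bit-identical positions
#' (zero-length segments, which would break orientation-vector normalization
#' downstream) are collapsed with a warning.
#'
#' @param path path to an SWC text file.
#' @param quiet suppress the parse-statistics message.
#' @return an [swc_tracing()] object.
#' @export
read_swc <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  if (length(rows) == 0L) stop("parse error: no data lines in ", path)
  bad_len <- which(lengths(rows) != 7L)
  if (length(bad_len)) {
    stop("parse error at line ", lineno[bad_len[1L]], ": expected 7 fields, got ",
         lengths(rows)[bad_len[1L]])
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = 7L, byrow = TRUE))
  bad_num <- which(apply(m, 1L, function(r) any(!is.finite(r))))
  if (length(bad_num)) {
    stop("parse error at line ", lineno[bad_num[1L]], ": non-numeric field")
  }
  pts <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                    x = m[, 3L], y = m[, 4L], z = m[, 5L],
                    radius = m[, 6L], parent = as.integer(m[, 7L]))
  pts <- collapse_zero_segments(pts)
  swc_tracing(pts, strict = TRUE, quiet = quiet)
}

# Remove points whose position is bit-identical to their parent's, re-homing
# their children; repeats until fixed point (chains of duplicates).
collapse_zero_segments <- function(pts) {
  repeat {
    prow <- match(pts$parent, pts$id)
    dup <- which(!is.na(prow) &
                   pts$x == pts$x[prow] & pts$y == pts$y[prow] & pts$z == pts$z[prow] &
                   pts$type == pts$type[prow])
    if (length(dup) == 0L) return(pts)
    d <- dup[1L]
    warning("collapsing zero-length segment at point ", pts$id[d],
            " (identical position to its parent)", call. = FALSE)
    pts$parent[pts$parent == pts$id[d]] <- pts$parent[d]
    pts <- pts[-d, , drop = FALSE]
  }
}

#' Validate a tracing and report defects
#'
#' Report-based companion to the strict checks in [read_swc()]: lists
#' non-positive radii, consecutive duplicate positions (zero-length segments)
#' and points that are not reachable from the root. An empty report means the
#' tracing satisfies all tracing-tree invariants.
#'
#' @param tracing an [swc_tracing()] object.
#' @return an object of class `swc_validation`: list with `ok` (logical) and
#'   data.frame `issues` (columns `point_id`, `issue`).
#' @export
validate_tracing <- function(tracing) {
  stopifnot(inherits(tracing, "swc_tracing"))
  pts <- tracing$points
  issues <- list()
  bad_r <- which(!(is.finite(pts$radius) & pts$radius > 0))
  if (length(bad_r)) {
    issues[[length(issues) + 1L]] <-
      data.frame(point_id = pts$id[bad_r], issue = "non-positive radius")
  }
  prow <- match(pts$parent, pts$id)
  dup <- which(!is.na(prow) &
                 pts$x == pts$x[prow] & pts$y == pts$y[prow] & pts$z == pts$z[prow])
  if (length(dup)) {
    issues[[length(issues) + 1L]] <-
      data.frame(point_id = pts$id[dup], issue = "zero-length segment (duplicate of parent position)")
  }
  roots <- which(pts$parent == -1L)
  if (length(roots) != 1L) {
    issues[[length(issues) + 1L]] <-
      data.frame(point_id = NA_integer_, issue = sprintf("%d roots (expected 1)", length(roots)))
  }
  dangling <- which(pts$parent != -1L & is.na(prow))
  if (length(dangling)) {
    issues[[length(issues) + 1L]] <-
      data.frame(point_id = pts$id[dangling], issue = "dangling parent reference")
  }
  # reachability from the first root
  if (length(roots) >= 1L) {
    n <- nrow(pts)
    reach <- rep.int(FALSE, n)
    reach[roots[1L]] <- TRUE
    queue <- roots[1L]
    kids <- tracing$children
    while (length(queue)) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      ch <- kids[[q]]
      ch <- ch[!reach[ch]]
      reach[ch] <- TRUE
      queue <- c(queue, ch)
    }
    off <- which(!reach)
    off <- setdiff(off, dangling)
    if (length(off)) {
      issues[[length(issues) + 1L]] <-
        data.frame(point_id = pts$id[off], issue = "not reachable from root")
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(point_id = integer(0), issue = character(0))
  structure(list(ok = nrow(issues) == 0L, issues = issues), class = "swc_validation")
}

#' Write a tracing to an SWC file
#'
#' Emits the tracing-point table in standard 7-column SWC form with full
#' double precision, so that `read_swc(write_swc(t))` reproduces `t` up to id
#' ordering. Multi-point soma contours are preserved verbatim.
#'
#' @param tracing an [swc_tracing()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tracing, path) {
  stopifnot(inherits(tracing, "swc_tracing"))
  pts <- tracing$points
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   pts$id, pts$type, pts$x, pts$y, pts$z, pts$radius, pts$parent)
  writeLines(c("# SWC written by neurotess", lines), path)
  invisible(path)
}

#' @export
print.swc_tracing <- function(x, ...) {
  pts <- x$points
  nb <- sum(lengths(x$children)[pts$type != 1L] >= 2L)
  cat(sprintf("<swc_tracing> %d points, %d neurites, %d bifurcations\n",
              nrow(pts), length(x$neurite_roots), nb))
  cat(sprintf("  soma (%s): center (%.3f, %.3f, %.3f), mean radius %.3f um\n",
              x$soma$dialect, x$soma$center[1L], x$soma$center[2L], x$soma$center[3L],
              x$soma$mean_radius))
  invisible(x)
}

#' @export
print.swc_validation <- function(x, ...) {
  if (x$ok) cat("<swc_validation> ok: no issues\n")
  else {
    cat(sprintf("<swc_validation> %d issue(s):\n", nrow(x$issues)))
    print(x$issues, row.names = FALSE)
  }
  invisible(x)
}

# rows of points table for given ids
tracing_rows <- function(tracing, ids) match(ids, tracing$points$id)

tracing_position <- function(tracing, id) {
  as.numeric(tracing$points[tracing_rows(tracing, id), c("x", "y", "z")])
}
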
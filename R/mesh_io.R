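#' Write a surface mesh to OBJ, OFF or PLY
#'
#' Vertices are written with full double precision so a write/read round
#' trip reproduces the mesh exactly. Quads are kept as quads in all three
#' formats. PLY can be written as ASCII or binary little-endian.
#'
#' @param mesh list with `vertices` and `faces`.
#' @param path output path.
#' @param format one of `"obj"`, `"off"`, `"ply"`; default from the file
#'   extension.
#' @param binary logical; binary little-endian PLY (ignored for OBJ/OFF).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "off", "ply"))
  V <- mesh$vertices
  fl <- face_list(mesh)
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# OBJ written by neurotess", con)
    writeLines(sprintf("v %.17g %.17g %.17g", V[, 1L], V[, 2L], V[, 3L]), con)
    writeLines(vapply(fl, function(v) paste("f", paste(v, collapse = " ")), ""), con)
  } else if (format == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(V), length(fl)), con)
    writeLines(sprintf("%.17g %.17g %.17g", V[, 1L], V[, 2L], V[, 3L]), con)
    writeLines(vapply(fl, function(v) {
      paste(length(v), paste(v - 1L, collapse = " "))
    }, ""), con)
  } else {
    header <- c("ply",
                if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
                "comment written by neurotess",
                sprintf("element vertex %d", nrow(V)),
                "property double x", "property double y", "property double z",
                sprintf("element face %d", length(fl)),
                "property list uchar int vertex_indices",
                "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(header, con, sep = "\n")
      writeBin(as.numeric(t(V)), con, size = 8L, endian = "little")
      for (v in fl) {
        writeBin(as.raw(length(v)), con)
        writeBin(as.integer(v - 1L), con, size = 4L, endian = "little")
      }
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(header, con)
      writeLines(sprintf("%.17g %.17g %.17g", V[, 1L], V[, 2L], V[, 3L]), con)
      writeLines(vapply(fl, function(v) {
        paste(length(v), paste(v - 1L, collapse = " "))
      }, ""), con)
    }
  }
  invisible(path)
}

#' Read a surface mesh from OBJ, OFF or PLY
#'
#' @param path file path; format detected from the extension (and for PLY,
#'   ASCII vs binary little-endian from the header).
#' @return a `neuro_mesh` list with `vertices` and `faces` (matrix when all
#'   faces have equal arity, otherwise a list).
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "off", "ply"))
  if (format == "obj") {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^v ", lines, value = TRUE)
    fc <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(s) as.numeric(s[2:4])))
    faces <- lapply(strsplit(fc, "\\s+"), function(s) {
      as.integer(sub("/.*$", "", s[-1L]))
    })
  } else if (format == "off") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!grepl("OFF", lines[1L])) stop("not an OFF file")
    cnt <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
    nv <- cnt[1L]; nf <- cnt[2L]
    V <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2L + nv)]), "\\s+"),
                               function(s) as.numeric(s[1:3])))
    faces <- lapply(strsplit(trimws(lines[(3L + nv):(2L + nv + nf)]), "\\s+"),
                    function(s) {
                      k <- as.integer(s[1L])
                      as.integer(s[2:(1L + k)]) + 1L
                    })
  } else {
    faces <- NULL
    hdr <- readLines(path, n = 50L, warn = FALSE, skipNul = TRUE)
    end <- which(hdr == "end_header")[1L]
    if (is.na(end)) stop("not a PLY file (no end_header)")
    hdr <- hdr[seq_len(end)]
    binary <- any(grepl("format binary_little_endian", hdr))
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
    if (binary) {
      raw_all <- readBin(path, "raw", file.size(path))
      off <- grepRaw("end_header\n", raw_all, fixed = TRUE)
      if (length(off) == 0L) stop("malformed binary PLY header")
      con <- rawConnection(raw_all[(off + nchar("end_header\n")):length(raw_all)])
      on.exit(close(con))
      V <- matrix(readBin(con, "numeric", nv * 3L, size = 8L, endian = "little"),
                  nv, 3L, byrow = TRUE)
      faces <- vector("list", nf)
      for (i in seq_len(nf)) {
        k <- as.integer(readBin(con, "raw", 1L))
        faces[[i]] <- readBin(con, "integer", k, size = 4L, endian = "little") + 1L
      }
    } else {
      lines <- readLines(path, warn = FALSE)
      body <- lines[(end + 1L):length(lines)]
      V <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(s) as.numeric(s[1:3])))
      faces <- lapply(strsplit(trimws(body[(nv + 1L):(nv + nf)]), "\\s+"),
                      function(s) {
                        k <- as.integer(s[1L])
                        as.integer(s[2:(1L + k)]) + 1L
                      })
    }
  }
  ar <- lengths(faces)
  fm <- if (length(unique(ar)) == 1L) {
    matrix(unlist(faces), length(faces), ar[1L], byrow = TRUE)
  } else faces
  structure(list(vertices = V, faces = fm), class = "neuro_mesh")
}

#' Write / read the per-vertex attribute sidecar
#'
#' OBJ/OFF/PLY have no standard slot for the tracing attributes the
#' refinement stage needs, so they travel in a CSV keyed by vertex index:
#' tracing point id, its position (`cx,cy,cz`), radius, orientation vector
#' (`ox,oy,oz`) and radial normal (`nx,ny,nz`), written in full double
#' precision (round trips are bit-exact).
#'
#' @param mesh a coarse mesh with an `attrs` table.
#' @param path CSV path.
#' @return `path` (write) / the attribute data.frame (read), invisibly for
#'   write.
#' @export
write_mesh_attributes <- function(mesh, path) {
  a <- mesh$attrs
  lines <- c("vertex,point_id,cx,cy,cz,radius,ox,oy,oz,nx,ny,nz",
             sprintf("%d,%d,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                     seq_len(nrow(a)), a$point_id, a$cx, a$cy, a$cz, a$radius,
                     a$ox, a$oy, a$oz, a$nx, a$ny, a$nz))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mesh_attributes
#' @export
read_mesh_attributes <- function(path) {
  df <- utils::read.csv(path)
  df[order(df$vertex), setdiff(names(df), "vertex"), drop = FALSE]
}

#' Write / read the per-face patch table
#'
#' Records, for each coarse face, its kind (soma / lateral / cap) and the two
#' tracing points of its segment, so a saved coarse mesh can be reloaded and
#' refined.
#'
#' @param mesh a coarse mesh with a `patch` table.
#' @param path CSV path.
#' @export
write_patch_table <- function(mesh, path) {
  p <- mesh$patch
  lines <- c("face,kind,t0,t1",
             sprintf("%d,%s,%d,%d", seq_len(nrow(p)), p$kind, p$t0, p$t1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_patch_table
#' @export
read_patch_table <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$face), , drop = FALSE]
  data.frame(kind = df$kind, t0 = as.integer(df$t0), t1 = as.integer(df$t1))
}

# Reassemble a refinable coarse mesh from its three on-disk pieces.
assemble_coarse_mesh <- function(mesh, attrs, patch) {
  if (nrow(attrs) != nrow(mesh$vertices)) {
    stop("sidecar/mesh mismatch: ", nrow(attrs), " attribute rows for ",
         nrow(mesh$vertices), " vertices")
  }
  if (nrow(patch) != length(face_list(mesh))) {
    stop("patch-table/mesh mismatch: ", nrow(patch), " rows for ",
         length(face_list(mesh)), " faces")
  }
  structure(list(vertices = mesh$vertices, faces = mesh$faces,
                 attrs = attrs, patch = patch),
            class = "neuro_mesh")
}
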
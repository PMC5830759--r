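#' Read a triangle surface mesh from OBJ or OFF
#'
#' The format is picked from the file extension (`.obj` or `.off`). Faces with
#' more than three vertices are fan-triangulated. OFF indices are 0-based on
#' disk and converted to the package's 1-based indexing.
#'
#' @param path file path
#' @param require_closed raise a topology error if the mesh is not closed and
#'   consistently oriented
#' @return a [surface_mesh()]
#' @export
read_surface_mesh <- function(path, require_closed = FALSE) {
  if (!file.exists(path)) stop("parse-error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    obj = read_obj(path),
    off = read_off(path),
    stop("invalid-argument: unsupported surface mesh format '.", ext, "'"))
  if (require_closed && !is_closed_surface(mesh))
    stop("topology-error: surface mesh in ", path, " is not closed/oriented")
  mesh
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  verts <- list()
  faces <- list()
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) == 0 || tok[1] %in% c("", "#")) next
    if (tok[1] == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4 || any(is.na(xyz)))
        stop("parse-error: malformed vertex at line ", ln, " of ", path)
      verts[[length(verts) + 1]] <- xyz
    } else if (tok[1] == "f") {
      # face entries may be v, v/vt, v/vt/vn or v//vn; keep the vertex index
      idx <- suppressWarnings(as.integer(vapply(
        strsplit(tok[-1], "/"), function(p) p[[1]], character(1))))
      if (length(idx) < 3 || any(is.na(idx)))
        stop("parse-error: malformed face at line ", ln, " of ", path)
      for (k in seq_len(length(idx) - 2L))
        faces[[length(faces) + 1]] <- idx[c(1L, k + 1L, k + 2L)]
    }
  }
  if (length(verts) == 0) stop("parse-error: no vertices in ", path)
  surface_mesh(do.call(rbind, verts),
               if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3))
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2 || trimws(lines[1]) != "OFF")
    stop("parse-error: missing OFF header in ", path)
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "[[:space:]]+")[[1]]))
  if (length(counts) < 2 || any(is.na(counts[1:2])))
    stop("parse-error: malformed OFF count line in ", path)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf)
    stop("parse-error: truncated OFF file ", path, " (expected ",
         2 + nv + nf, " content lines, found ", length(lines), ")")
  verts <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    xyz <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + i]), "[[:space:]]+")[[1]][1:3]))
    if (any(is.na(xyz))) stop("parse-error: malformed OFF vertex at content line ", 2 + i)
    verts[i, ] <- xyz
  }
  faces <- list()
  for (i in seq_len(nf)) {
    tok <- suppressWarnings(as.integer(strsplit(trimws(lines[2 + nv + i]), "[[:space:]]+")[[1]]))
    if (length(tok) < 1 || is.na(tok[1]) || length(tok) < tok[1] + 1L || any(is.na(tok[1:(tok[1] + 1L)])))
      stop("parse-error: malformed OFF face at content line ", 2 + nv + i)
    idx <- tok[2:(tok[1] + 1L)] + 1L # 0-based on disk
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  surface_mesh(verts, if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3))
}

#' Read a TetGen-style tetrahedral mesh (.node/.ele pair)
#'
#' `path` may point at either file of the pair, or at the common basename.
#' TetGen indices are 1-based by default on disk (0-based files are detected
#' and shifted); internal indexing is 1-based. Tets are re-oriented to positive
#' signed volume if needed.
#'
#' @param path path to the `.node` file, the `.ele` file, or the basename
#' @return a [tet_mesh()]
#' @export
read_tet_mesh <- function(path) {
  base <- sub("\\.(node|ele)$", "", path)
  node_path <- paste0(base, ".node")
  ele_path <- paste0(base, ".ele")
  if (!file.exists(node_path)) stop("parse-error: file not found: ", node_path)
  if (!file.exists(ele_path)) stop("parse-error: file not found: ", ele_path)

  nl <- tetgen_rows(node_path)
  hdr <- nl[[1]]
  nv <- hdr[1]
  if (is.na(nv) || length(nl) < nv + 1)
    stop("parse-error: truncated .node file ", node_path)
  ids <- numeric(nv)
  verts <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    row <- nl[[i + 1]]
    if (length(row) < 4 || any(is.na(row[1:4])))
      stop("parse-error: malformed .node row ", i, " in ", node_path)
    ids[i] <- row[1]
    verts[i, ] <- row[2:4]
  }
  off <- if (min(ids) == 0) 1L else 0L

  el <- tetgen_rows(ele_path)
  nt <- el[[1]][1]
  if (is.na(nt) || length(el) < nt + 1)
    stop("parse-error: truncated .ele file ", ele_path)
  tets <- matrix(NA_integer_, nt, 4)
  for (i in seq_len(nt)) {
    row <- el[[i + 1]]
    if (length(row) < 5 || any(is.na(row[1:5])))
      stop("parse-error: malformed .ele row ", i, " in ", ele_path)
    tets[i, ] <- as.integer(row[2:5]) + off
  }
  v <- tet_signed_volumes(verts, tets)
  flip <- v < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tet_mesh(verts, tets)
}

tetgen_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
}

#' Write a surface mesh to OBJ or OFF
#'
#' @param mesh a [surface_mesh()]
#' @param path output path; format chosen by extension
#' @return `path`, invisibly
#' @export
write_surface_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "softsim_surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$triangles
  if (ext == "obj") {
    out <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else if (ext == "off") {
    out <- c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
             sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else stop("invalid-argument: unsupported surface mesh format '.", ext, "'")
  writeLines(out, path)
  invisible(path)
}

#' Write a tetrahedral mesh as a TetGen .node/.ele pair
#'
#' @param mesh a [tet_mesh()]
#' @param basename output path without extension; `.node` and `.ele` are added
#' @return the basename, invisibly
#' @export
write_tet_mesh <- function(mesh, basename) {
  stopifnot(inherits(mesh, "softsim_tet_mesh"))
  v <- mesh$vertices
  tt <- mesh$tets
  writeLines(c(sprintf("%d 3 0 0", nrow(v)),
               sprintf("%d %.9g %.9g %.9g", seq_len(nrow(v)), v[, 1], v[, 2], v[, 3])),
             paste0(basename, ".node"))
  writeLines(c(sprintf("%d 4 0", nrow(tt)),
               sprintf("%d %d %d %d %d", seq_len(nrow(tt)), tt[, 1], tt[, 2], tt[, 3], tt[, 4])),
             paste0(basename, ".ele"))
  invisible(basename)
}
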
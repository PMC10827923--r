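#' Read a vertex-colored mesh from PLY or OBJ
#'
#' PLY support covers ascii and binary_little_endian files with per-vertex
#' `red green blue` (uchar or float) properties. OBJ support covers the
#' common vertex-color extension `v x y z r g b`. OBJ face indices are
#' 1-based in the file and re-indexed to the package's 0-based convention.
#'
#' @param path file path.
#' @param format "ply", "obj" or "auto" (by extension).
#' @param default_gray when the file carries no colour attributes, fill with
#'   mid-gray instead of raising an error.
#' @return a `vcmesh`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj"),
                      default_gray = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (format == "ply") read_ply(path, default_gray) else
    read_obj(path, default_gray)
}

read_ply <- function(path, default_gray = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, 1L)
    if (length(line) == 0L) stop("parse error: truncated PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop("parse error: not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format: ", fmt_line)

  # parse element/property declarations in order
  elems <- list()
  cur <- NULL
  for (line in header) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (toks[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]),
                  props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      if (toks[2] == "list") {
        cur$props[[toks[5]]] <- list(list = TRUE, count_type = toks[3],
                                     type = toks[4])
      } else {
        cur$props[[toks[3]]] <- list(list = FALSE, type = toks[2])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex)) stop("parse error: PLY without vertex element")

  read_plain <- function(type, n) {
    switch(type,
      float = , float32 = readBin(con, "double", n, size = 4, endian = "little"),
      double = , float64 = readBin(con, "double", n, size = 8, endian = "little"),
      uchar = , uint8 = readBin(con, "integer", n, size = 1, signed = FALSE,
                                endian = "little"),
      char = , int8 = readBin(con, "integer", n, size = 1, endian = "little"),
      short = , int16 = readBin(con, "integer", n, size = 2, endian = "little"),
      ushort = , uint16 = readBin(con, "integer", n, size = 2, signed = FALSE,
                                  endian = "little"),
      int = , int32 = , uint = , uint32 =
        readBin(con, "integer", n, size = 4, endian = "little"),
      stop("unsupported PLY property type: ", type))
  }

  vp <- elems$vertex$props
  nv <- elems$vertex$count
  vnames <- names(vp)
  if (binary) {
    vdata <- matrix(NA_real_, nv, length(vp))
    for (i in seq_len(nv))
      for (j in seq_along(vp))
        vdata[i, j] <- read_plain(vp[[j]]$type, 1L)
    colnames(vdata) <- vnames
  } else {
    txt <- readLines(con, nv)
    vdata <- do.call(rbind, lapply(strsplit(trimws(txt), "\\s+"), as.numeric))
    colnames(vdata) <- vnames[seq_len(ncol(vdata))]
  }
  tri <- matrix(integer(0), 0, 3)
  if (!is.null(elems$face) && elems$face$count > 0L) {
    nf <- elems$face$count
    if (binary) {
      fp <- elems$face$props[[1]]
      tri <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        cnt <- read_plain(fp$count_type, 1L)
        idx <- read_plain(fp$type, cnt)
        if (cnt != 3L) stop("parse error: non-triangular PLY face")
        tri[i, ] <- idx
      }
    } else {
      txt <- readLines(con, nf)
      rows <- lapply(strsplit(trimws(txt), "\\s+"), as.integer)
      if (any(vapply(rows, `[`, 0L, 1) != 3L))
        stop("parse error: non-triangular PLY face")
      tri <- do.call(rbind, lapply(rows, function(r) r[2:4]))
    }
  }
  if (!all(c("x", "y", "z") %in% colnames(vdata)))
    stop("parse error: PLY vertex without x/y/z")
  verts <- vdata[, c("x", "y", "z"), drop = FALSE]
  has_col <- all(c("red", "green", "blue") %in% colnames(vdata))
  if (!has_col && !default_gray)
    stop("no vertex colors in ", path,
         " (set default_gray = TRUE to fill with gray)")
  cols <- if (has_col) {
    cc <- vdata[, c("red", "green", "blue"), drop = FALSE]
    ctype <- vp[["red"]]$type
    if (ctype %in% c("uchar", "uint8", "ushort", "uint16")) cc / 255 else cc
  } else matrix(0.5, nv, 3)
  vcmesh(verts, cols, tri)
}

read_obj <- function(path, default_gray = FALSE) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L) stop("parse error: OBJ without vertices")
  vt <- lapply(strsplit(trimws(sub("^v ", "", vl)), "\\s+"), as.numeric)
  ncols <- lengths(vt)
  verts <- do.call(rbind, lapply(vt, `[`, 1:3))
  has_col <- all(ncols >= 6L)
  if (!has_col && !default_gray)
    stop("no vertex colors in ", path,
         " (set default_gray = TRUE to fill with gray)")
  cols <- if (has_col) do.call(rbind, lapply(vt, `[`, 4:6)) else
    matrix(0.5, nrow(verts), 3)
  tri <- matrix(integer(0), 0, 3)
  if (length(fl) > 0L) {
    idx <- lapply(strsplit(trimws(sub("^f ", "", fl)), "\\s+"), function(toks) {
      as.integer(vapply(strsplit(toks, "/"), `[`, "", 1))
    })
    if (any(lengths(idx) != 3L)) stop("parse error: non-triangular OBJ face")
    tri <- do.call(rbind, idx) - 1L  # OBJ is 1-based
  }
  vcmesh(verts, cols, tri)
}

#' Write a vertex-colored mesh
#'
#' PLY is written as ascii with 8-bit colour quantization (uchar
#' `red green blue`, rounded, so colours round-trip within 1/255 per
#' channel); positions are written with full double precision. OBJ writes
#' the `v x y z r g b` vertex-color extension with unquantized colours and
#' 1-based face indices.
#'
#' @param mesh a `vcmesh`.
#' @param path output path.
#' @param format "ply" (default), "obj" or "auto" (by extension).
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (format == "ply") {
    n <- n_vertices(mesh); nt <- nrow(mesh$triangles)
    cols <- round(mesh$colors * 255)
    head <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "property uchar red", "property uchar green", "property uchar blue",
              sprintf("element face %d", nt),
              "property list uchar int vertex_indices",
              "end_header")
    vl <- sprintf("%.17g %.17g %.17g %d %d %d",
                  mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                  cols[, 1], cols[, 2], cols[, 3])
    fl <- if (nt > 0)
      sprintf("3 %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
              mesh$triangles[, 3]) else character(0)
    writeLines(c(head, vl, fl), path)
  } else {
    vl <- sprintf("v %.17g %.17g %.17g %.10g %.10g %.10g",
                  mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                  mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3])
    fl <- if (nrow(mesh$triangles) > 0)
      sprintf("f %d %d %d", mesh$triangles[, 1] + 1L,
              mesh$triangles[, 2] + 1L, mesh$triangles[, 3] + 1L) else character(0)
    writeLines(c(vl, fl), path)
  }
  invisible(path)
}

#' Read landmarks from a TSV file
#'
#' Expected columns: `name<TAB>x<TAB>y` (2D, pixels, origin top-left,
#' 0-based) or `name<TAB>x<TAB>y<TAB>z` (3D, mm).
#'
#' @param path file path.
#' @return data.frame with a `name` column and 2 or 3 coordinate columns.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("name", "x", "y", "z")[seq_len(ncol(df))]
  if (anyDuplicated(df$name)) stop("duplicate landmark names")
  df
}

#' Write landmarks to a TSV file
#' @param lm data.frame as returned by [read_landmarks()].
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  utils::write.table(lm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
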
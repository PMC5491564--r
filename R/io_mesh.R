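#' Read a triangle mesh from PLY, STL or OBJ
#'
#' Coordinates are taken as millimetres verbatim; no unit rescaling is
#' performed. PLY files may be ASCII or binary little-endian and may carry
#' per-vertex scalar (`quality` or `sd`) and colour (`red`/`green`/`blue`)
#' properties. STL may be ASCII or binary. OBJ uses `v`/`f` records.
#'
#' @param path file path.
#' @param format optional dialect hint, one of `"ply"`, `"stl"`, `"obj"`;
#'   by default inferred from the file extension.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("read_mesh: file not found: %s", path))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         stop(sprintf("read_mesh: unsupported format '%s'", format)))
}

#' Write a triangle mesh to PLY, STL or OBJ
#'
#' PLY is the canonical colour-carrying format (per-vertex RGB is standard
#' there); requesting colours forces PLY output. STL and OBJ carry geometry
#' only.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; the extension selects the format.
#' @param with_colours write per-vertex RGB (PLY only); requires
#'   `vertex_colour` on the mesh.
#' @param binary write binary PLY/STL instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, with_colours = FALSE, binary = FALSE) {
  validate_mesh(mesh)
  format <- tolower(tools::file_ext(path))
  if (with_colours) {
    if (is.null(mesh$vertex_colour))
      stop("write_mesh: colours requested but mesh has no vertex_colour")
    if (format != "ply")
      stop("write_mesh: per-vertex colours require PLY output")
  }
  switch(format,
         ply = write_ply(mesh, path, with_colours, binary),
         stl = if (binary) write_stl_binary(mesh, path)
               else write_stl_ascii(mesh, path),
         obj = write_obj(mesh, path),
         stop(sprintf("write_mesh: unsupported format '%s'", format)))
  invisible(path)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_raw_line <- function(con) {
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0) return(NULL)
      if (b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }
  header <- character()
  repeat {
    line <- read_raw_line(con)
    if (is.null(line)) stop("read_ply: unexpected end of header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000) stop("read_ply: header not terminated")
  }
  if (trimws(header[1]) != "ply") stop("read_ply: missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("read_ply: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("read_ply: unsupported format '%s'", fmt))

  # parse element/property declarations
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      else
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || elements$vertex$count == 0)
    stop("read_ply: file declares zero vertices")
  if (is.null(elements$face))
    stop("read_ply: no face element")

  if (fmt == "ascii") out <- read_ply_ascii(con, elements)
  else out <- read_ply_binary(con, elements)

  vp <- vapply(elements$vertex$props, function(p) p$name, "")
  vm <- out$vertex
  if (!all(c("x", "y", "z") %in% vp))
    stop("read_ply: vertex element lacks x/y/z")
  vertices <- cbind(vm[["x"]], vm[["y"]], vm[["z"]])
  scalar <- if ("quality" %in% vp) vm[["quality"]]
            else if ("sd" %in% vp) vm[["sd"]] else NULL
  colour <- if (all(c("red", "green", "blue") %in% vp)) {
    cc <- cbind(vm[["red"]], vm[["green"]], vm[["blue"]])
    storage.mode(cc) <- "integer"
    cc
  } else NULL
  faces <- out$faces
  if (any(faces != floor(faces)))
    stop("read_ply: non-integer face index")
  surface_mesh(vertices, faces + 1L, vertex_scalar = scalar,
               vertex_colour = colour)
}

ply_rtype <- function(type) {
  switch(type,
         float = , float32 = list(what = "numeric", size = 4),
         double = , float64 = list(what = "numeric", size = 8),
         char = , int8 = list(what = "integer", size = 1, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
         stop(sprintf("read_ply: unsupported property type '%s'", type)))
}

read_ply_ascii <- function(con, elements) {
  rest <- readBin(con, "raw", n = 2^30)
  lines <- strsplit(rawToChar(rest), "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1
  vertex <- NULL
  faces <- NULL
  for (el in elements) {
    take <- lines[pos:(pos + el$count - 1)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      m <- do.call(rbind, lapply(strsplit(trimws(take), "\\s+"), as.numeric))
      if (ncol(m) != length(el$props))
        stop("read_ply: vertex row width mismatch")
      vertex <- lapply(seq_along(el$props), function(i) m[, i])
      names(vertex) <- vapply(el$props, function(p) p$name, "")
    } else if (el$name == "face") {
      rows <- lapply(strsplit(trimws(take), "\\s+"), as.numeric)
      faces <- do.call(rbind, lapply(rows, function(r) {
        if (r[1] != 3) stop("read_ply: only triangle faces are supported")
        r[2:4]
      }))
    }
  }
  list(vertex = vertex, faces = faces)
}

read_ply_binary <- function(con, elements) {
  vertex <- NULL
  faces <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      listy <- any(vapply(el$props, function(p) p$list, TRUE))
      if (listy) stop("read_ply: list property on vertex element")
      n <- el$count
      cols <- lapply(el$props, function(p) numeric(n))
      names(cols) <- vapply(el$props, function(p) p$name, "")
      # fixed record: read row-wise
      types <- lapply(el$props, function(p) ply_rtype(p$type))
      for (i in seq_len(n)) {
        for (j in seq_along(el$props)) {
          t <- types[[j]]
          cols[[j]][i] <- readBin(con, t$what, n = 1, size = t$size,
                                  signed = if (t$what == "integer")
                                    isTRUE(t$signed) else TRUE,
                                  endian = "little")
        }
      }
      vertex <- cols
    } else if (el$name == "face") {
      p <- el$props[[1]]
      if (!p$list) stop("read_ply: face element lacks list property")
      ct <- ply_rtype(p$count_type)
      it <- ply_rtype(p$type)
      faces <- matrix(0, el$count, 3)
      for (i in seq_len(el$count)) {
        k <- readBin(con, ct$what, n = 1, size = ct$size,
                     signed = isTRUE(ct$signed), endian = "little")
        if (k != 3) stop("read_ply: only triangle faces are supported")
        faces[i, ] <- readBin(con, it$what, n = 3, size = it$size,
                              signed = if (it$what == "integer")
                                isTRUE(it$signed) else TRUE,
                              endian = "little")
      }
    }
  }
  list(vertex = vertex, faces = faces)
}

write_ply <- function(mesh, path, with_colours, binary) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_scalar <- !is.null(mesh$vertex_scalar)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment meshprecision",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z")
  if (has_scalar) header <- c(header, "property float quality")
  if (with_colours)
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue")
  header <- c(header,
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  f0 <- mesh$faces - 1L
  if (binary) {
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4,
               endian = "little")
      if (has_scalar)
        writeBin(as.numeric(mesh$vertex_scalar[i]), con, size = 4,
                 endian = "little")
      if (with_colours)
        writeBin(as.raw(mesh$vertex_colour[i, ]), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  } else {
    vtxt <- apply(mesh$vertices, 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " "))
    if (has_scalar)
      vtxt <- paste(vtxt, formatC(mesh$vertex_scalar, format = "g",
                                  digits = 9))
    if (with_colours)
      vtxt <- paste(vtxt, mesh$vertex_colour[, 1], mesh$vertex_colour[, 2],
                    mesh$vertex_colour[, 3])
    writeLines(vtxt, con)
    writeLines(paste(3, f0[, 1], f0[, 2], f0[, 3]), con)
  }
  invisible(path)
}

## ---- STL ----

read_stl <- function(path) {
  # heuristic: ASCII STL starts with "solid" and contains "facet"
  head <- readBin(path, "raw", n = 512)
  all_text <- all(head %in% as.raw(c(9L, 10L, 13L, 32:126)))
  is_ascii <- all_text && {
    txt <- rawToChar(head)
    grepl("^\\s*solid", txt) && grepl("facet", txt)
  }
  m <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(m) == 0) stop("read_stl: file contains zero facets")
  nf <- nrow(m) / 3
  mesh <- surface_mesh(m, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
  weld_vertices(mesh, tol = 1e-9)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vix <- grep("^\\s*vertex\\s", lines)
  if (length(vix) %% 3 != 0)
    stop("read_stl: vertex count not a multiple of 3")
  toks <- strsplit(trimws(lines[vix]), "\\s+")
  do.call(rbind, lapply(toks, function(t) as.numeric(t[2:4])))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * nf
  if (file.info(path)$size < expected)
    stop("read_stl: truncated binary STL")
  m <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)  # attribute byte count
    m[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  m
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  nrm <- cr / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid meshprecision", con)
  fmt <- function(r) paste(formatC(r, format = "e", digits = 8),
                           collapse = " ")
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %s", fmt(nrm[i, ])),
                 "    outer loop",
                 sprintf("      vertex %s", fmt(v[f[i, 1], ])),
                 sprintf("      vertex %s", fmt(v[f[i, 2], ])),
                 sprintf("      vertex %s", fmt(v[f[i, 3], ])),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid meshprecision", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  nrm <- cr / len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(nrm[i, ], v[f[i, 1], ], v[f[i, 2], ],
                          v[f[i, 3], ])), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0) stop("read_obj: file contains zero vertices")
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                             function(t) as.numeric(t[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    ix <- as.integer(vapply(strsplit(t[-1], "/"), `[`, "", 1))
    if (length(ix) != 3) stop("read_obj: only triangle faces are supported")
    if (any(ix < 0)) stop("read_obj: negative indices not supported")
    ix
  }))
  surface_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v",
                   formatC(mesh$vertices[, 1], format = "g", digits = 9),
                   formatC(mesh$vertices[, 2], format = "g", digits = 9),
                   formatC(mesh$vertices[, 3], format = "g", digits = 9)),
             con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
}
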
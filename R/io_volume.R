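#' Read a voxel volume from MetaImage (.mhd/.raw) or NIfTI
#'
#' Spacing and origin round-trip exactly; integer-typed MetaImage payloads
#' are preserved bit-exact.
#'
#' @param path path to a `.mhd`, `.nii` or `.nii.gz` file.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_volume: file not found: %s",
                                       path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") return(read_mhd(path))
  if (ext == "nii" || grepl("\\.nii\\.gz$", path, ignore.case = TRUE))
    return(read_nifti_volume(path))
  stop(sprintf("read_volume: unsupported format '%s'", ext))
}

#' Write a voxel volume to MetaImage or NIfTI
#'
#' @param volume a [voxel_volume()].
#' @param path output path; `.mhd` writes a MetaImage header plus a sibling
#'   `.raw` payload, `.nii`/`.nii.gz` writes NIfTI.
#' @param element_type MetaImage payload type: `"auto"` (MET_SHORT when all
#'   values are integers in range, MET_DOUBLE otherwise), `"short"`,
#'   `"float"` or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, element_type = "auto") {
  stopifnot(inherits(volume, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") write_mhd(volume, path, element_type)
  else if (ext == "nii" || grepl("\\.nii\\.gz$", path, ignore.case = TRUE))
    write_nifti_volume(volume, path)
  else stop(sprintf("write_volume: unsupported format '%s'", ext))
  invisible(path)
}

## ---- MetaImage ----

mhd_types <- list(
  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_INT = list(what = "integer", size = 4, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(k, default = NULL) {
    i <- match(tolower(k), tolower(trimws(keys)))
    if (is.na(i)) default else trimws(vals[i])
  }
  ndims <- as.integer(get("NDims", "3"))
  if (ndims != 3) stop("read_mhd: only 3-D volumes are supported")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", get("Position", "0 0 0")),
                                "\\s+")[[1]])
  etype <- get("ElementType", "MET_SHORT")
  tinfo <- mhd_types[[etype]]
  if (is.null(tinfo))
    stop(sprintf("read_mhd: unsupported ElementType '%s'", etype))
  msb <- identical(tolower(get("ElementByteOrderMSB",
                               get("BinaryDataByteOrderMSB", "false"))),
                   "true")
  datafile <- get("ElementDataFile")
  if (is.null(datafile)) stop("read_mhd: missing ElementDataFile")
  raw_path <- if (datafile == "LOCAL") path
              else file.path(dirname(path), datafile)
  if (!file.exists(raw_path))
    stop(sprintf("read_mhd: missing raw companion file '%s'", raw_path))
  n <- prod(dims)
  payload <- file.info(raw_path)$size
  if (payload < n * tinfo$size)
    stop(sprintf(
      "read_mhd: header declares %d voxels (%d bytes) but payload has %d bytes",
      n, n * tinfo$size, payload))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = if (msb) "big" else "little")
  voxel_volume(array(vals, dims), spacing, origin)
}

write_mhd <- function(volume, path, element_type = "auto") {
  vals <- volume$values
  if (element_type == "auto") {
    intish <- all(vals == round(vals)) && min(vals) >= -32768 &&
      max(vals) <= 32767
    element_type <- if (intish) "short" else "double"
  }
  etype <- switch(element_type, short = "MET_SHORT", float = "MET_FLOAT",
                  double = "MET_DOUBLE",
                  stop("write_mhd: unknown element_type"))
  tinfo <- mhd_types[[etype]]
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  d <- dim(vals)
  header <- c("ObjectType = Image",
              "NDims = 3",
              "BinaryData = True",
              "BinaryDataByteOrderMSB = False",
              sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
              sprintf("ElementSpacing = %.17g %.17g %.17g",
                      volume$spacing[1], volume$spacing[2],
                      volume$spacing[3]),
              sprintf("Offset = %.17g %.17g %.17g", volume$origin[1],
                      volume$origin[2], volume$origin[3]),
              sprintf("ElementType = %s", etype),
              sprintf("ElementDataFile = %s", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(vals)
  if (tinfo$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = tinfo$size, endian = "little")
}

## ---- NIfTI (via RNifti) ----

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  # RNifti uses a RAS-style affine; for the axis-aligned volumes written
  # here the translation column is the world position of voxel (1,1,1)
  voxel_volume(array(as.numeric(img), dim(img)[1:3]), spacing, origin)
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  xf <- diag(c(volume$spacing, 1))
  xf[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
}
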
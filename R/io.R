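#' Read a 3D scalar volume from file
#'
#' Reads NRRD (canonical interchange format) or NIfTI-1 volumes. The file must
#' contain a 3D array with per-axis spacing metadata; 2D images are rejected.
#' World coordinates are interpreted in mm with the origin at the centre of
#' voxel (0,0,0).
#'
#' @param path file path.
#' @param format `"nrrd"`, `"nifti"`, or `"auto"` (default: from the file
#'   extension).
#' @param quantity quantity tag for the returned volume (`"dose_Gy"`,
#'   `"cbct_number"` or `"delta_cbct"`).
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti"),
                        quantity = "cbct_number") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- resolve_format(path, format)
  parsed <- switch(format,
                   nrrd = read_nrrd(path),
                   nifti = read_nifti_file(path))
  scalar_volume(parsed$values, parsed$geometry, quantity = quantity)
}

#' Write a 3D scalar volume (or mask) to file
#'
#' @param vol a [scalar_volume()] or [structure_mask()]. Masks are written as
#'   uint8 0/1.
#' @param path output path; extension `.nrrd` or `.nii`/`.nii.gz`.
#' @param format `"auto"`, `"nrrd"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  format <- resolve_format(path, format)
  is_mask <- inherits(vol, "structure_mask")
  if (!is_mask && !inherits(vol, "scalar_volume"))
    stop("vol must be a scalar_volume or structure_mask")
  values <- if (is_mask) array(as.numeric(vol$values), dim = vol$geometry$dims)
            else vol$values
  switch(format,
         nrrd = write_nrrd(values, vol$geometry, path,
                           type = if (is_mask) "uint8" else "double"),
         nifti = write_nifti_file(values, vol$geometry, path,
                                  integer_data = is_mask))
  invisible(path)
}

#' Read a structure mask from file
#'
#' Nonzero voxels become `TRUE`.
#'
#' @inheritParams read_volume
#' @param name structure label.
#' @return A [structure_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nrrd", "nifti"),
                      name = "structure") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- resolve_format(path, format)
  parsed <- switch(format,
                   nrrd = read_nrrd(path),
                   nifti = read_nifti_file(path))
  structure_mask(parsed$values != 0, parsed$geometry, name = name)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  stop(sprintf("cannot infer format from extension of '%s'; pass format=", path))
}

## ---- NRRD (minimal NRRD0004 subset: 3D, raw or ascii encoding) ----------

write_nrrd <- function(values, geometry, path, type = c("double", "uint8"),
                       encoding = c("raw", "ascii")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  s <- geometry$spacing
  o <- geometry$origin
  header <- c(
    "NRRD0004",
    "# produced by latticeqa",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", geometry$dims[1], geometry$dims[2], geometry$dims[3]),
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)", s[1], s[2], s[3]),
    sprintf("space origin: (%.10g,%.10g,%.10g)", o[1], o[2], o[3]),
    sprintf("encoding: %s", encoding))
  if (encoding == "raw") header <- c(header, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, ""), con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(format(as.vector(values), digits = 17), con)
  } else if (type == "double") {
    writeBin(as.vector(values), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(values), con, size = 1, endian = "little")
  }
  invisible(path)
}

nrrd_type_info <- function(type) {
  switch(type,
         "double" = , "float64" = list(what = "double", size = 8, signed = TRUE),
         "float" = , "float32" = list(what = "double", size = 4, signed = TRUE),
         "uint8" = , "uchar" = , "unsigned char" =
           list(what = "integer", size = 1, signed = FALSE),
         "int8" = , "signed char" = list(what = "integer", size = 1, signed = TRUE),
         "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
         "ushort" = , "uint16" = list(what = "integer", size = 2, signed = FALSE),
         "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
         stop(sprintf("unsupported NRRD type '%s'", type)))
}

parse_nrrd_vectors <- function(text) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries dropped
  parts <- regmatches(text, gregexpr("\\(([^)]*)\\)", text))[[1]]
  lapply(parts, function(p)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]]))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop(sprintf("'%s' is not an NRRD file (bad magic '%s')", path, magic))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L)
      stop("unexpected end of NRRD header (no blank separator line)")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop(sprintf("malformed NRRD header line: '%s'", line))
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dim_n <- as.integer(fields[["dimension"]])
  if (is.na(dim_n)) stop("NRRD header missing 'dimension'")
  if (dim_n != 3L)
    stop(sprintf("only 3D volumes are supported (file is %dD)", dim_n))
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L || any(is.na(sizes)))
    stop("NRRD header 'sizes' must list 3 positive integers")
  spacing <- origin <- NULL
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    dirs <- dirs[vapply(dirs, length, 1L) == 3L]
    if (length(dirs) != 3L) stop("NRRD 'space directions' must give 3 axis vectors")
    m <- do.call(rbind, dirs)
    if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-9))
      stop("non-axis-aligned NRRD 'space directions' are not supported")
    spacing <- abs(diag(m))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (is.null(spacing) || length(spacing) != 3L || any(is.na(spacing)))
    stop("NRRD header has no usable per-axis spacing metadata")
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  } else {
    origin <- c(0, 0, 0)
  }
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  if (encoding %in% c("raw")) {
    info <- nrrd_type_info(tolower(fields[["type"]] %||% "double"))
    endian <- tolower(fields[["endian"]] %||% "little")
    vals <- readBin(con, what = info$what, n = n, size = info$size,
                    signed = if (info$size < 4) info$signed else TRUE,
                    endian = endian)
    if (length(vals) != n) stop("NRRD data block shorter than 'sizes' imply")
  } else if (encoding %in% c("ascii", "txt", "text")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
    if (length(vals) != n) stop("NRRD ascii data shorter than 'sizes' imply")
  } else {
    stop(sprintf("unsupported NRRD encoding '%s' (raw and ascii supported)", encoding))
  }
  list(values = array(as.numeric(vals), dim = sizes),
       geometry = volume_geometry(origin, spacing, sizes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- NIfTI-1 via RNifti ---------------------------------------------------

write_nifti_file <- function(values, geometry, path, integer_data = FALSE) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- geometry$spacing
  xf <- rbind(cbind(diag(geometry$spacing), geometry$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (integer_data) "uint8" else "double")
  invisible(path)
}

read_nifti_file <- function(path) {
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  if (length(dim(values)) == 4L && dim(values)[4] == 1L)
    values <- values[, , , 1, drop = TRUE]
  if (length(dim(values)) != 3L)
    stop(sprintf("only 3D volumes are supported (file is %dD)",
                 length(dim(values))))
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI file has no usable per-axis spacing metadata")
  origin <- xf[1:3, 4]
  list(values = array(as.numeric(values), dim = dim(values)),
       geometry = volume_geometry(origin, spacing, dim(values)))
}
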
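#' Read a volumetric image
#'
#' Reads a NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage (`.mhd`, `.mha`) file
#' into a [volume()]. On-disk axis order (x fastest) is permuted to the
#' package convention `(z, y, x)`; spacing and origin are taken from the
#' file metadata. Direction cosines beyond axis order are ignored: a warning
#' is emitted for oblique inputs.
#'
#' @param path path to an existing `.nii`, `.nii.gz`, `.mhd` or `.mha` file.
#' @param role role to assign to the result (see [volume()]); labels are
#'   validated to be binary.
#' @return A [volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, role = c("intensity", "probability", "label")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- vol_format(path)
  v <- switch(ext,
    nifti = read_nifti(path),
    meta  = read_metaimage(path),
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz, .mhd or .mha)", call. = FALSE)
  )
  volume(v$data, spacing = v$spacing, origin = v$origin, role = role)
}

#' Write a volumetric image
#'
#' Writes a [volume()] to NIfTI-1 or MetaImage, chosen from the file
#' extension. Label volumes are stored as unsigned 8-bit integers; intensity
#' and probability volumes as 64-bit floats by default so that write/read
#' round-trips are bit-exact.
#'
#' @param v a [volume()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#'   The parent directory must exist.
#' @param datatype on-disk scalar type for non-label volumes: `"double"`
#'   (default), `"float"` or `"int16"`. Labels always use `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = c("double", "float", "int16")) {
  stop_if_not_volume(v)
  datatype <- match.arg(datatype)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  if (v$role == "label") datatype <- "uint8"
  switch(vol_format(path),
    nifti = write_nifti(v, path, datatype),
    meta  = write_metaimage(v, path, datatype),
    stop("unsupported volume format: ", path, call. = FALSE)
  )
  invisible(path)
}

vol_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mhd|mha)$", lp)) return("meta")
  "unknown"
}

# ---- NIfTI via RNifti ------------------------------------------------------

read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path, call. = FALSE)
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- abs(xf[1:3, 1:3])
    if (any(rot - diag(diag(rot)) > 1e-4 * max(rot)))
      warning("oblique orientation ignored; axes assumed grid-aligned: ", path,
              call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  list(data = aperm(array(as.numeric(img), dim = d), c(3, 2, 1)),
       spacing = rev(sp),
       origin = c(0, 0, 0))
}

write_nifti <- function(v, path, datatype) {
  arr <- aperm(v$data, c(3, 2, 1))     # back to (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(v$spacing)
  dt <- switch(datatype, uint8 = "uint8", int16 = "int16",
               float = "float", "double")
  RNifti::writeNifti(img, path, datatype = dt)
}

# ---- MetaImage (.mhd header + .raw, or single-file .mha) -------------------
# The MetaImage format is a short "Key = Value" text header followed by (or
# pointing at) a raw little-endian voxel block, x varying fastest.

meta_types <- c(uint8 = "MET_UCHAR", int16 = "MET_SHORT",
                float = "MET_FLOAT", double = "MET_DOUBLE")

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line, call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L) stop("expected a 3D image, got ", ndims, "D: ", path, call. = FALSE)
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImage data is not supported: ", path, call. = FALSE)
  if (identical(hdr$BinaryDataByteOrderMSB, "True") ||
      identical(hdr$ElementByteOrderMSB, "True"))
    stop("big-endian MetaImage data is not supported: ", path, call. = FALSE)
  tm <- hdr$TransformMatrix
  if (!is.null(tm)) {
    m <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, 3, byrow = TRUE)
    if (any(abs(m - diag(3)) > 1e-4))
      warning("oblique orientation ignored; axes assumed grid-aligned: ", path,
              call. = FALSE)
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])        # (nx, ny, nz)
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  off <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType
  n <- prod(dims)
  read_block <- function(con) {
    switch(type,
      MET_UCHAR  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
      MET_SHORT  = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                      endian = "little")),
      MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
      MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
      stop("unsupported MetaImage ElementType: ", type, call. = FALSE))
  }
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- read_block(con)
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path, call. = FALSE)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- read_block(rcon)
  }
  if (length(vals) != n) stop("MetaImage data block is truncated: ", path, call. = FALSE)
  list(data = aperm(array(vals, dim = dims), c(3, 2, 1)),
       spacing = rev(sp), origin = rev(off))
}

write_metaimage <- function(v, path, datatype) {
  d <- dim(v$data)                       # (nz, ny, nx)
  local_data <- grepl("\\.mha$", tolower(path))
  data_file <- if (local_data) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(rev(v$origin), collapse = " ")),
    paste("ElementSpacing =", paste(rev(v$spacing), collapse = " ")),
    paste("DimSize =", paste(rev(d), collapse = " ")),
    paste("ElementType =", meta_types[[datatype]]),
    paste("ElementDataFile =", data_file)
  )
  vals <- as.vector(aperm(v$data, c(3, 2, 1)))
  write_block <- function(con) {
    switch(datatype,
      uint8  = writeBin(as.integer(vals), con, size = 1),
      int16  = writeBin(as.integer(vals), con, size = 2, endian = "little"),
      float  = writeBin(vals, con, size = 4, endian = "little"),
      double = writeBin(vals, con, size = 8, endian = "little"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local_data) {
    write_block(con)
  } else {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon), add = TRUE)
    write_block(rcon)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
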
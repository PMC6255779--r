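#' Read and write volumetric images
#'
#' Supported formats are NIfTI (`.nii`, `.nii.gz`) and uncompressed
#' single-file MetaImage (`.mha`). Voxel spacing (mm) is taken from /
#' written to the format header; the origin is stored in the NIfTI sform /
#' MetaImage `Offset`. Orientation codes beyond an axis-aligned identity
#' are not interpreted. Masks are stored as 8-bit 0/1.
#'
#' @param path file path; the extension selects the format.
#' @param mask if `TRUE`, return a [binary_mask] (values must be 0/1).
#' @param x an [image_volume] or [binary_mask].
#' @return `read_volume` returns an [image_volume] (or [binary_mask]);
#'   `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    vals <- array(as.double(vals), dim(vals))  # drop NIfTI attributes
    if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
    if (length(dim(vals)) != 3L)
      stop("expected a 3-D image: ", path, call. = FALSE)
    spacing <- abs(RNifti::pixdim(img))[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  } else if (grepl("\\.mha$", path)) {
    m <- read_mha(path)
    vals <- m$values
    spacing <- m$spacing
    origin <- m$origin
  } else {
    stop("unsupported format (use .nii, .nii.gz or .mha): ", path, call. = FALSE)
  }
  if (any(spacing <= 0)) stop("missing or invalid spacing in header", call. = FALSE)
  if (mask) {
    if (!all(vals %in% c(0, 1)))
      stop("mask file contains values other than 0/1", call. = FALSE)
    binary_mask(array(vals > 0, dim(vals)), spacing, origin)
  } else {
    image_volume(vals, spacing, origin)
  }
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("`x` must be an image_volume or binary_mask", call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    vals <- if (is_mask) array(as.integer(x$values), dim(x$values)) else x$values
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- x$spacing
    m <- diag(c(x$spacing, 1))
    m[1:3, 4] <- x$origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  } else if (grepl("\\.mha$", path)) {
    write_mha(x, path)
  } else {
    stop("unsupported format (use .nii, .nii.gz or .mha): ", path, call. = FALSE)
  }
  invisible(path)
}

# Minimal single-file MetaImage I/O (uncompressed, LOCAL data).
write_mha <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  vals <- x$values
  if (is_mask) {
    type <- "MET_UCHAR"
  } else if (all(vals == round(vals)) && max(abs(vals)) < 2^31) {
    type <- "MET_INT"
  } else {
    type <- "MET_DOUBLE"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(x$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(x$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(vals), collapse = " ")),
    paste("ElementType =", type),
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (type == "MET_UCHAR") {
    writeBin(as.raw(as.integer(vals)), con)
  } else if (type == "MET_INT") {
    writeBin(as.integer(vals), con, size = 4, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage is supported", call. = FALSE)
  if (!is.null(hdr[["CompressedData"]]) &&
      tolower(hdr[["CompressedData"]]) == "true")
    stop("compressed MetaImage is not supported", call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (is.null(hdr[["Offset"]])) c(0, 0, 0)
            else as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  n <- prod(dims)
  type <- hdr[["ElementType"]]
  vals <- switch(type,
    MET_UCHAR = as.double(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT = as.double(readBin(con, "integer", n, size = 2, endian = "little")),
    MET_INT = as.double(readBin(con, "integer", n, size = 4, endian = "little")),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported ElementType: ", type, call. = FALSE))
  list(values = array(vals, dims), spacing = spacing, origin = origin)
}
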
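#' Read a label image or displacement field
#'
#' Dispatches on extension: `.nii` / `.nii.gz` (NIfTI-1, via RNifti) or
#' `.mha` (MetaImage, local raw data). A 4D volume whose last dimension is 3
#' (or a 3-channel MetaImage) is returned as a [displacement_field()],
#' anything 3D as a [label_image()]. Spacing and origin survive round trips
#' exactly; integer labels are never resampled. World coordinates are taken
#' verbatim from the stored affine (no axis reorientation is applied).
#'
#' @param path file path.
#' @param strict passed to [label_image()] for scalar volumes.
#' @return a [label_image()] or [displacement_field()].
#' @export
read_image <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  got <- switch(ext,
                nii = read_nifti_raw(path),
                mha = read_mha_raw(path),
                stop("unsupported image extension: ", ext,
                     " (use .nii, .nii.gz or .mha)"))
  d <- dim(got$data)
  if (length(d) == 4 && d[4] == 3) {
    displacement_field(got$data, spacing = got$spacing, origin = got$origin)
  } else if (length(d) == 3) {
    label_image(got$data, spacing = got$spacing, origin = got$origin,
                strict = strict)
  } else stop("unsupported image dimensionality: ", paste(d, collapse = "x"))
}

#' Write a label image or displacement field
#'
#' @param img a [label_image()] or [displacement_field()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  is_field <- inherits(img, "displacement_field")
  switch(ext,
         nii = write_nifti_raw(img$data, img$spacing, img$origin, path,
                               integer_data = !is_field),
         mha = write_mha_raw(img$data, img$spacing, img$origin, path,
                             integer_data = !is_field),
         stop("unsupported image extension: ", ext))
  invisible(path)
}

# ---- NIfTI ------------------------------------------------------------------
# The grid-to-world affine is stored in the sform (code 2) as
# diag(spacing) + origin; images written by this package are therefore
# read back with identical metadata.

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  m <- RNifti::xform(img, useQuaternionFirst = FALSE)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  origin <- m[1:3, 4]
  arr <- array(as.vector(img), dim = dim(img))
  list(data = arr, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

write_nifti_raw <- function(arr, spacing, origin, path, integer_data = TRUE) {
  datatype <- if (integer_data && max(abs(arr)) < 32767 &&
                  all(arr == round(arr))) "int16" else "double"
  img <- RNifti::asNifti(arr, datatype = datatype)
  m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- MetaImage (.mha, local raw data) ---------------------------------------

read_mha_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only LOCAL MetaImage data is supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(dims))
  nch <- if (!is.null(hdr$ElementNumberOfChannels))
    as.integer(hdr$ElementNumberOfChannels) else 1L
  n <- prod(dims) * nch
  type <- hdr$ElementType
  vals <- switch(type,
                 MET_UCHAR = as.numeric(readBin(con, "integer", n = n, size = 1,
                                                signed = FALSE)),
                 MET_SHORT = as.numeric(readBin(con, "integer", n = n, size = 2,
                                                endian = "little")),
                 MET_INT = as.numeric(readBin(con, "integer", n = n, size = 4,
                                              endian = "little")),
                 MET_FLOAT = readBin(con, "numeric", n = n, size = 4,
                                     endian = "little"),
                 MET_DOUBLE = readBin(con, "numeric", n = n, size = 8,
                                      endian = "little"),
                 stop("unsupported MetaImage ElementType: ", type))
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  if (nch > 1L) {
    # channels interleaved fastest; reorder to (nx, ny, nz, nch)
    arr <- aperm(array(vals, dim = c(nch, dims)), c(2, 3, 4, 1))
  } else {
    arr <- array(vals, dim = dims)
  }
  list(data = arr, spacing = spacing, origin = origin)
}

write_mha_raw <- function(arr, spacing, origin, path, integer_data = TRUE) {
  d <- dim(arr)
  nch <- if (length(d) == 4) d[4] else 1L
  dims <- d[1:3]
  use_uchar <- integer_data && nch == 1L && all(arr == round(arr)) &&
    min(arr) >= 0 && max(arr) <= 255
  type <- if (use_uchar) "MET_UCHAR" else "MET_DOUBLE"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %.17g %.17g %.17g", origin[1], origin[2],
                   origin[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", spacing[1],
                   spacing[2], spacing[3]),
           sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("ElementNumberOfChannels = %d", nch),
           sprintf("ElementType = %s", type),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  vals <- if (nch > 1L) as.vector(aperm(arr, c(4, 1, 2, 3))) else as.vector(arr)
  if (use_uchar) {
    writeBin(as.integer(vals), con, size = 1)
  } else {
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}
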
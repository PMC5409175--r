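#' Read a volumetric image
#'
#' NIfTI-1 (`.nii`/`.nii.gz`) is the primary format; uncompressed
#' MetaImage (`.mha`, MET_FLOAT/MET_DOUBLE/MET_SHORT/MET_UCHAR) is also
#' supported.  The returned affine reproduces the file's voxel-to-world map
#' (0-based indices).
#'
#' @param path file path.
#' @param format `"auto"`, `"nifti"` or `"metaimage"`.
#' @param modality modality tag to attach (default from a label sidecar or
#'   `"CT"`).
#' @return an [ImageVolume-class].
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage"),
                       modality = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mha$", path, ignore.case = TRUE))
      "metaimage" else "nifti"
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path), error = function(e)
      stop("unreadable NIfTI file '", path, "': header field error: ",
           conditionMessage(e)))
    A <- structure(RNifti::xform(img, useQuaternionFirst = FALSE))
    A <- matrix(as.numeric(A), 4, 4)
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    md <- attr(img, "murtModality")
  } else {
    r <- .readMetaImage(path)
    A <- r$affine
    arr <- r$voxels
    md <- NULL
  }
  if (is.null(modality)) modality <- if (is.null(md)) "CT" else md
  imageVolume(arr, affine = A, modality = modality)
}

#' Write a volumetric image
#'
#' @param vol an [ImageVolume-class].
#' @param path output path (`.nii`, `.nii.gz` or `.mha`).
#' @export
writeVolume <- function(vol, path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    .writeMetaImage(vol, path)
    return(invisible(path))
  }
  sp <- voxelSpacing(vol)
  img <- RNifti::asNifti(vol@voxels, pixdim = sp)
  A <- vol@affine
  img <- RNifti::`sform<-`(img, structure(A, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write a StructureSet as NIfTI + JSON sidecar name map
#'
#' The label volume is stored as NIfTI; the name map as a JSON file with
#' the same stem and suffix `.labels.json` holding `{name: label, ...}`.
#'
#' @param x a [StructureSet-class].
#' @param path path to the label NIfTI.
#' @export
writeStructureSet <- function(x, path) {
  vol <- imageVolume(x@labels + 0, affine = x@affine, modality = "LABEL")
  writeVolume(vol, path)
  side <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(as.list(x@labelNames),
                       paste0(side, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeStructureSet
#' @export
readStructureSet <- function(path) {
  vol <- readVolume(path, modality = "LABEL")
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
  if (!file.exists(side)) stop("label name sidecar not found: ", side)
  nm <- jsonlite::read_json(side)
  structureSet(round(vol@voxels), affine = vol@affine,
               labelNames = unlist(nm))
}

# Minimal uncompressed MetaImage (.mha, local data) support.
.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("unreadable MetaImage '", path,
                            "': missing ElementDataFile header field")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("unreadable MetaImage '", path,
                              "': malformed header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementType", "ElementDataFile")
  for (k in need) if (is.null(hdr[[k]]))
    stop("unreadable MetaImage '", path, "': missing header field ", k)
  if (hdr$ElementDataFile != "LOCAL")
    stop("unreadable MetaImage '", path,
         "': only LOCAL ElementDataFile is supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, 3)
  off <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, 3)
  tm <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3) else diag(3)
  type <- hdr$ElementType
  n <- prod(d)
  raw <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8),
    MET_FLOAT = readBin(con, "double", n, size = 4),
    MET_SHORT = readBin(con, "integer", n, size = 2, signed = TRUE),
    MET_UCHAR = as.integer(readBin(con, "raw", n)),
    stop("unreadable MetaImage '", path, "': unsupported ElementType ", type))
  A <- diag(4)
  A[1:3, 1:3] <- tm %*% diag(sp)
  A[1:3, 4] <- off
  list(voxels = array(as.numeric(raw), dim = d), affine = A)
}

.writeMetaImage <- function(vol, path) {
  A <- vol@affine
  sp <- voxelSpacing(vol)
  tm <- A[1:3, 1:3] %*% diag(1 / sp)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("TransformMatrix =", paste(format(tm, digits = 12), collapse = " ")),
           paste("Offset =", paste(format(A[1:3, 4], digits = 12), collapse = " ")),
           paste("ElementSpacing =", paste(format(sp, digits = 12), collapse = " ")),
           paste("DimSize =", paste(dim(vol@voxels), collapse = " ")),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol@voxels), con, size = 8)
  invisible(path)
}
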
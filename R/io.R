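#' Read and write volumes
#'
#' Supported formats, chosen by extension: MetaImage (`.mha` single
#' file, or `.mhd` header with a sibling `.raw`) and NIfTI
#' (`.nii`/`.nii.gz`, via the RNifti package).  Scalar volumes are
#' stored as 32-bit float, label volumes as 32-bit integer; reading an
#' integer-typed file returns a [label_volume()] when
#' `as_labels = TRUE`.
#'
#' @param x A [volume()] or [label_volume()].
#' @param path Output path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [volume()] or [label_volume()].
#' @export
write_volume <- function(x, path) {
  is_lab <- inherits(x, "label_volume")
  data <- x$data
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required for NIfTI output")
    RNifti::writeNifti(data, path)
    return(invisible(path))
  }
  mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  if (!mha && !grepl("\\.mhd$", path, ignore.case = TRUE))
    stop("unsupported volume format: ", path)
  d <- dim(data)
  raw_name <- if (mha) "LOCAL" else
    basename(sub("\\.mhd$", ".raw", path, ignore.case = TRUE))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %g %g %g",
                   x$spacing %||% 1, x$spacing %||% 1, x$spacing %||% 1),
           sprintf("ElementType = %s", if (is_lab) "MET_INT" else
             "MET_FLOAT"),
           sprintf("ElementDataFile = %s", raw_name))
  write_payload <- function(con) {
    if (is_lab) writeBin(as.integer(data), con, size = 4L,
                         endian = "little")
    else writeBin(as.numeric(data), con, size = 4L, endian = "little")
  }
  if (mha) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    write_payload(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    write_payload(con)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param as_labels Coerce integer data to a [label_volume()].
#' @export
read_volume <- function(path, as_labels = FALSE) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required for NIfTI input")
    data <- array(as.numeric(RNifti::readNifti(path)))
    data <- array(data, dim(RNifti::readNifti(path)))
    return(if (as_labels) label_volume(data) else volume(data))
  }
  mha <- grepl("\\.mha$", path, ignore.case = TRUE)
  if (!mha && !grepl("\\.mhd$", path, ignore.case = TRUE))
    stop("unsupported volume format: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    trimws(sub("^[^=]*= *", "", ln))
  }
  d <- as.integer(strsplit(get_field("DimSize"), " +")[[1]])
  et <- get_field("ElementType")
  spacing <- as.numeric(strsplit(get_field("ElementSpacing"), " +")[[1]])[1]
  n <- prod(d)
  read_payload <- function(cc) {
    switch(et,
           MET_FLOAT = readBin(cc, numeric(), n, size = 4L,
                               endian = "little"),
           MET_DOUBLE = readBin(cc, numeric(), n, size = 8L,
                                endian = "little"),
           MET_INT = readBin(cc, integer(), n, size = 4L,
                             endian = "little"),
           MET_SHORT = readBin(cc, integer(), n, size = 2L,
                               endian = "little"),
           MET_UCHAR = as.integer(readBin(cc, "raw", n)),
           stop("unsupported ElementType: ", et))
  }
  vals <- if (mha) read_payload(con) else {
    raw_path <- file.path(dirname(path), get_field("ElementDataFile"))
    cc <- file(raw_path, "rb")
    on.exit(close(cc), add = TRUE)
    read_payload(cc)
  }
  data <- array(vals, d)
  if (as_labels || et %in% c("MET_INT", "MET_SHORT", "MET_UCHAR"))
    label_volume(data) else volume(data, spacing)
}
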
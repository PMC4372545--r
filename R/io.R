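#' Minimal NIfTI-1 volume I/O
#'
#' No NIfTI reader is available among the package's allowed dependencies, so
#' these functions implement the small subset of the NIfTI-1 standard the
#' pipeline needs: single-file (`.nii`, optionally `.nii.gz`) little-endian
#' volumes with an sform affine, float64/float32/int16/uint8 storage, and no
#' scaling, extensions, or qform quaternions.
#'
#' @name nifti_io
NULL

.NIFTI_DTYPES <- list(uint8 = list(code = 2L, bitpix = 8L),
                      int16 = list(code = 4L, bitpix = 16L),
                      int32 = list(code = 8L, bitpix = 32L),
                      float32 = list(code = 16L, bitpix = 32L),
                      float64 = list(code = 64L, bitpix = 64L))

.nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

# Serialize values into a raw header buffer at a fixed byte offset.
.poke <- function(buf, offset, values, what = c("int", "float", "raw"),
                  size = 4L) {
  what <- match.arg(what)
  bytes <- switch(what,
    int = writeBin(as.integer(values), raw(), size = size, endian = "little"),
    float = writeBin(as.numeric(values), raw(), size = 4L, endian = "little"),
    raw = as.raw(values))
  buf[(offset + 1):(offset + length(bytes))] <- bytes
  buf
}

#' Write a 3D/4D array as a NIfTI-1 volume
#'
#' @param img Numeric array with 3 or 4 dimensions.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm, or length-3 vector.
#' @param tr Repetition time in seconds (written to pixdim for 4D data).
#' @param affine Optional 4x4 voxel-to-world matrix; default diagonal from
#'   `voxel_size` with origin at voxel (0,0,0).
#' @param datatype Storage type; `"float64"` (default) round-trips exactly.
#' @return Invisibly, `path`.
#' @rdname nifti_io
#' @export
write_nifti <- function(img, path, voxel_size = 1, tr = 0, affine = NULL,
                        datatype = "float64") {
  nd <- length(dim(img))
  if (is.null(dim(img)) || !(nd %in% c(3L, 4L)))
    stop("write_nifti: 'img' must be a 3D or 4D array: ", path)
  dt <- .NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  vs <- rep(voxel_size, length.out = 3)
  if (is.null(affine)) affine <- diag(c(vs, 1))
  stopifnot(all(dim(affine) == c(4, 4)))

  h <- raw(348)
  h <- .poke(h, 0, 348L, "int")                          # sizeof_hdr
  h <- .poke(h, 40, c(nd, dim(img), rep(1L, 7L - nd)), "int", 2L)  # dim[8]
  h <- .poke(h, 70, dt$code, "int", 2L)                  # datatype
  h <- .poke(h, 72, dt$bitpix, "int", 2L)                # bitpix
  h <- .poke(h, 76, c(1, vs, if (nd == 4L) tr else 0, 0, 0, 0), "float")
  h <- .poke(h, 108, 352, "float")                       # vox_offset
  h <- .poke(h, 112, 1, "float")                         # scl_slope
  h <- .poke(h, 123, 10L, "raw")                         # xyzt_units mm|sec
  h <- .poke(h, 254, 1L, "int", 2L)                      # sform_code
  h <- .poke(h, 280, t(affine[1:3, , drop = FALSE]), "float")  # srow_x/y/z
  h <- .poke(h, 344, c(charToRaw("n+1"), as.raw(0L)), "raw")   # magic

  con <- .nii_connection(path, "wb")
  on.exit(close(con))
  writeBin(h, con)
  writeBin(raw(4), con)                                  # no extensions
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(img), con, size = dt$bitpix / 8L, endian = "little")
  } else {
    writeBin(as.integer(img), con, size = dt$bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `affine` (4x4), `voxel_size` (length 3),
#'   and `tr` (seconds; 0 when absent).
#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- .nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("read_nifti: truncated header: ", path)
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size,
                                       endian = "little")
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "numeric",
                                 n = n, size = 4, endian = "little")
  if (ri(0, 1, 4) != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  dims <- ri(40, 8, 2)
  nd <- dims[1]
  if (!(nd %in% c(3L, 4L)))
    stop("read_nifti: expected a 3D or 4D volume, got ", nd, "D: ", path)
  shape <- dims[2:(1 + nd)]
  dtcode <- ri(70, 1, 2)
  dt <- Filter(function(d) d$code == dtcode, .NIFTI_DTYPES)
  if (length(dt) == 0) stop("read_nifti: unsupported datatype code ", dtcode,
                            ": ", path)
  dt <- dt[[1]]
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  affine <- rbind(rf(280, 4), rf(296, 4), rf(312, 4), c(0, 0, 0, 1))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vals <- prod(shape)
  what <- if (dt$code %in% c(16L, 64L)) "numeric" else "integer"
  vals <- readBin(con, what, n = n_vals, size = dt$bitpix / 8L,
                  endian = "little", signed = dt$code != 2L)
  if (length(vals) < n_vals) stop("read_nifti: truncated data: ", path)
  list(data = array(vals, dim = shape), affine = affine,
       voxel_size = pixdim[2:4], tr = pixdim[5])
}

#' Tab-separated table I/O
#'
#' Thin wrappers fixing the dialect used throughout the pipeline (header
#' row, tab separator, no quoting, no row names).
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv_file` a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
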
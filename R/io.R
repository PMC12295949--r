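#' Read a CT volume (or mask) from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file and returns a [ct_volume()] carrying the
#' voxel spacing from the header (`pixdim`).
#'
#' @param path path to a NIfTI file.
#' @return A `ct_volume`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-d NIfTI volume")
  arr <- array(as.numeric(img), dim(img))   # plain array, header attrs dropped
  sp <- RNifti::pixdim(img)
  ct_volume(arr, spacing = sp[1:3])
}

#' Write a CT volume (or mask) to NIfTI
#'
#' @param vol a `ct_volume` or 3-d array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm, used when `vol` is a plain array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$data
    spacing <- vol$spacing
  } else arr <- vol
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal NPY v1.0 serialization -----------------------------------------
# The training stacks are exchanged as npy files shaped (n, H, W). Only what
# the package needs is implemented: little-endian float32/float64, C order.

.npy_magic <- as.raw(c(0x93, charToRaw("NUMPY")))

#' Write an array as an npy file
#'
#' Serializes a numeric array in NPY format version 1.0, C (row-major) order,
#' little-endian. Stacks produced by [build_stack()] round-trip with their
#' `(n, H, W)` shape.
#'
#' @param x numeric array or vector.
#' @param path output path.
#' @param dtype `"float64"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  descr <- if (dtype == "float64") "<f8" else "<f4"
  shape_str <- if (length(shape) == 1L) sprintf("(%d,)", shape) else
    sprintf("(%s)", paste(shape, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape_str)
  # total header (magic 6 + version 2 + len 2 + dict) padded to multiple of 64
  base_len <- 10L + nchar(header) + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  # C order: last axis fastest -> reverse the axes before flattening
  v <- if (is.null(dim(x)) || length(shape) == 1L) as.numeric(x) else
    as.numeric(aperm(x, rev(seq_along(shape))))
  writeBin(v, con, size = if (dtype == "float64") 8L else 4L, endian = "little")
  invisible(path)
}

#' Read an npy file
#'
#' Supports NPY v1.0/v2.0 files holding little-endian float32/float64 data in
#' either C or Fortran order.
#'
#' @param path path to an `.npy` file.
#' @return Numeric array with the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, .npy_magic)) stop("not an npy file")
  ver <- as.integer(readBin(con, "raw", 2L))
  hlen <- if (ver[1] == 1L)
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  else
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  size <- switch(descr, "<f8" = 8L, "<f4" = 4L,
                 stop("unsupported npy dtype: ", descr))
  n <- prod(shape)
  v <- readBin(con, "numeric", n, size = size, endian = "little")
  if (length(shape) <= 1L) return(v)
  if (fortran) {
    array(v, shape)
  } else {
    aperm(array(v, rev(shape)), rev(seq_along(shape)))
  }
}

#' Write preprocessed stacks for a case as npy files with a JSON index
#'
#' One npy file per stack plus a sidecar `index.json` recording the case id,
#' center slice and slice count of each file.
#'
#' @param samples output of [preprocess_case()].
#' @param dir output directory (created if missing).
#' @param case_id identifier recorded in the index.
#' @return Path to the index file, invisibly.
#' @export
write_stacks_npy <- function(samples, dir, case_id = "case") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fn <- sprintf("%s_slice%04d.npy", case_id, s$center_index)
    write_npy(s$stack, file.path(dir, fn))
    mfn <- sprintf("%s_slice%04d_mask.npy", case_id, s$center_index)
    write_npy(s$mask, file.path(dir, mfn))
    list(case_id = case_id, center_slice = s$center_index,
         n_slices = dim(s$stack)[1], stack = fn, mask = mfn)
  })
  idx_path <- file.path(dir, paste0(case_id, "_index.json"))
  jsonlite::write_json(index, idx_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(idx_path)
}
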
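#' 3D scalar volume with geometry
#'
#' Container for a Hounsfield-unit-scaled CT-like volume. Axis order is fixed
#' anatomically: x runs left to right, y posterior to anterior, z inferior to
#' superior (RAS). Files read with other orientations are reoriented on read.
#'
#' @param data 3D numeric array of intensities (HU).
#' @param spacing numeric length-3 voxel spacing in mm, all positive.
#' @param origin numeric length-3 physical position of voxel (1,1,1) in mm.
#' @return An object of class `fg_volume`.
#' @export
fg_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  if (any(dim(data) < 8)) stop("volume must be at least 8 voxels per axis")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "fg_volume")
}

#' Binary lung mask congruent with a volume
#'
#' @param data 3D logical (or 0/1) array.
#' @param spacing,origin geometry, as in [fg_volume()].
#' @param lung optional integer array of the same shape with per-lung labels
#'   (0 outside, 1 left, 2 right).
#' @return An object of class `fg_mask`.
#' @export
fg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0), lung = NULL) {
  data <- as_array3d(data)
  storage.mode(data) <- "logical"
  if (!any(data)) stop("mask is empty")
  if (!is.null(lung)) {
    lung <- as_array3d(lung)
    storage.mode(lung) <- "integer"
    stopifnot(identical(dim(lung), dim(data)))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 lung = lung),
            class = "fg_mask")
}

as_array3d <- function(x) {
  if (is.null(dim(x))) stop("expected 3D volume, got a vector")
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  if (length(dim(x)) == 4 && dim(x)[4] == 1) x <- array(x, dim(x)[1:3])
  if (length(dim(x)) != 3) stop("expected 3D volume")
  x
}

#' @exportS3Method base::print
print.fg_volume <- function(x, ...) {
  cat(sprintf("<fg_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @exportS3Method base::print
print.fg_mask <- function(x, ...) {
  cat(sprintf("<fg_mask> %s voxels, %d in mask%s\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              if (!is.null(x$lung)) ", left/right labelled" else ""))
  invisible(x)
}

#' Read a volume or mask from NIfTI or NRRD
#'
#' NIfTI files are read through RNifti and reoriented to RAS when orientation
#' metadata is present. NRRD support covers attached-header files with `raw`
#' or `gzip` encoding.
#'
#' @param path file ending in .nii, .nii.gz or .nrrd.
#' @param mask logical; return an `fg_mask` (data binarised at > 0.5)?
#' @return `fg_volume` or `fg_mask`.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    v <- read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) == 4 && dim(img)[4] == 1) img <- img[, , , 1, drop = TRUE]
    if (length(dim(img)) != 3) stop("expected 3D volume")
    orient <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
    if (!is.null(orient) && nzchar(orient) && orient != "RAS")
      RNifti::orientation(img) <- "RAS"
    sp <- abs(RNifti::pixdim(img))[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0)) stop("spacing metadata absent or invalid")
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (!inherits(xf, "try-error")) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
    v <- list(data = array(as.numeric(img), dim(img)[1:3]), spacing = sp, origin = org)
  } else stop("unsupported volume format: ", path)
  if (mask) fg_mask(v$data > 0.5, v$spacing, v$origin)
  else fg_volume(v$data, v$spacing, v$origin)
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' @param volume `fg_volume` or `fg_mask`.
#' @param path destination ending in .nii, .nii.gz or .nrrd.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  dat <- volume$data
  if (is.logical(dat)) { dat <- array(as.numeric(dat), dim(dat)) }
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(dat, volume$spacing, volume$origin, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    attr(dat, "pixdim") <- volume$spacing
    img <- RNifti::asNifti(dat, datatype = "float")
    aff <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

# Minimal NRRD (attached header, raw/gzip encodings, little endian).
read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at first blank line
  nl <- which(raw_all == as.raw(10))
  hdr_end <- NA
  prev <- 0L
  for (i in nl) {
    seg <- i - prev
    if (seg == 1L || (seg == 2L && raw_all[i - 1] == as.raw(13))) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("malformed NRRD header")
  hdr <- strsplit(rawToChar(raw_all[1:hdr_end]), "\r?\n")[[1]]
  hdr <- hdr[nzchar(hdr) & !grepl("^#", hdr) & !grepl("^NRRD", hdr)]
  fields <- list()
  for (ln in hdr) {
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 3L)) stop("expected 3D volume")
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  spacing <- rep(1, 3)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      sqrt(sum(as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])^2))
    }, numeric(1))
  } else stop("spacing metadata absent")
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  payload <- raw_all[(hdr_end + 1):length(raw_all)]
  if (identical(enc, "gzip") || identical(enc, "gz"))
    payload <- memDecompress(payload, type = "gzip")
  else if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  spec <- switch(type,
    "float" = list(what = "numeric", size = 4), "double" = list(what = "numeric", size = 8),
    "short" = list(what = "integer", size = 2), "int" = list(what = "integer", size = 4),
    "signed short" = list(what = "integer", size = 2),
    "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    stop("unsupported NRRD type: ", type))
  vals <- readBin(payload, spec$what, n = prod(sizes), size = spec$size,
                  signed = if (is.null(spec$signed)) TRUE else spec$signed,
                  endian = "little")
  list(data = array(as.numeric(vals), sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(data, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "NRRD0004\n",
    "type: float\n",
    "dimension: 3\n",
    "sizes: ", paste(dim(data), collapse = " "), "\n",
    "endian: little\n",
    "encoding: raw\n",
    "space dimension: 3\n",
    "space directions: ", paste(sprintf("(%g,%g,%g)",
      c(spacing[1], 0, 0), c(0, spacing[2], 0), c(0, 0, spacing[3])), collapse = " "), "\n",
    "space origin: ", sprintf("(%g,%g,%g)", origin[1], origin[2], origin[3]), "\n\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Resample a volume to isotropic voxels
#'
#' Resamples to `target_mm` spacing on all axes with trilinear interpolation
#' (nearest-neighbour for masks). The output shape is `round(extent/target)`
#' per axis and the origin is preserved; a volume already at the target
#' spacing is returned unchanged.
#'
#' @param volume `fg_volume` or `fg_mask`.
#' @param target_mm target spacing in mm (default 1).
#' @param is_mask force nearest-neighbour interpolation. Defaults to `TRUE`
#'   for `fg_mask` input.
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(volume, target_mm = 1, is_mask = inherits(volume, "fg_mask")) {
  if (target_mm <= 0) stop("target spacing must be positive")
  sp <- volume$spacing
  if (all(abs(sp - target_mm) < 1e-9)) return(volume)
  d <- dim(volume$data)
  outdim <- pmax(1L, as.integer(round(d * sp / target_mm)))
  tgt <- rep(target_mm, 3)
  dat <- volume$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim(dat))
  res <- cpp_resample(as.numeric(dat), d, sp, tgt, outdim, nearest = is_mask)
  res <- array(res, outdim)
  if (inherits(volume, "fg_mask")) {
    lung <- NULL
    if (!is.null(volume$lung)) {
      lr <- cpp_resample(as.numeric(volume$lung), d, sp, tgt, outdim, nearest = TRUE)
      lung <- array(as.integer(lr), outdim)
    }
    fg_mask(res > 0.5, tgt, volume$origin, lung = lung)
  } else {
    fg_volume(res, tgt, volume$origin)
  }
}
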
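# Reading and writing volumes / label fields.
#
# NIfTI: spacing is taken from the header pixdim, converted to micrometres
# using the header spatial unit; files whose unit field is unset are assumed
# to carry micrometres already. Orientation/affine information beyond the
# voxel scale is ignored: the grid-native frame is the package's coordinate
# system. TIFF stacks carry no spacing metadata, so a spacing_override is
# required for them.

#' Read a grayscale volume
#'
#' Reads a NIfTI file (.nii / .nii.gz), a multi-page TIFF, a directory of
#' per-slice TIFFs (natural filename order), or a glob of slice files.
#'
#' @param path Path to a NIfTI file, a TIFF file, a directory of TIFF slices,
#'   or a glob pattern matching slice files.
#' @param spacing_override Optional isotropic voxel spacing in µm, replacing
#'   (NIfTI) or supplying (TIFF) the header spacing.
#' @return An [mt_volume()].
#' @details Anisotropic NIfTI spacing is rejected unless `spacing_override`
#'   is given: the cylinder template and all length/angle arithmetic assume
#'   an isotropic grid.
#' @export
read_volume <- function(path, spacing_override = NULL) {
  src <- resolve_volume_source(path)
  if (src$kind == "nifti") {
    img <- RNifti::readNifti(src$path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      abort(sprintf("expected scalar 3D pixel data, got %d dimensions",
                    length(dim(arr))))
    spacing <- nifti_spacing_um(img)
    if (is.null(spacing_override)) {
      if (is.na(spacing$value))
        abort("NIfTI header spacing is invalid (non-positive); pass spacing_override")
      if (!spacing$isotropic)
        abort("anisotropic NIfTI spacing; resample upstream or pass spacing_override")
      s <- spacing$value
    } else {
      s <- spacing_override
    }
    storage.mode(arr) <- "double"
    attributes(arr) <- list(dim = dim(arr))
    return(mt_volume(arr, s))
  }
  # TIFF slice stack
  if (is.null(spacing_override))
    abort("TIFF stacks carry no spacing metadata; spacing_override (µm) is required")
  slices <- read_tiff_slices(src$paths)
  arr <- slices_to_array(slices)
  mt_volume(arr, spacing_override)
}

#' Read a binary label field
#'
#' Same sources as [read_volume()]; values are binarised by `value != 0`.
#'
#' @inheritParams read_volume
#' @return An [mt_label()].
#' @export
read_label <- function(path, spacing_override = NULL) {
  v <- read_volume(path, spacing_override)
  mt_label((v$data != 0) + 0, v$spacing)
}

#' Write a volume or label field
#'
#' NIfTI output (by extension .nii / .nii.gz) defaults to NIfTI-2, whose
#' double-precision pixdim reproduces the spacing exactly on re-read
#' (NIfTI-1 truncates pixdim to float32); pass `version = 1` for NIfTI-1.
#' TIFF output (.tif / .tiff) writes one 32-bit float page per slice and
#' drops spacing metadata.
#'
#' @param vol An [mt_volume()] or [mt_label()].
#' @param path Output path; format chosen by extension.
#' @param version NIfTI version, 1 or 2.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, version = 2) {
  stopifnot(inherits(vol, "mt_volume") || inherits(vol, "mt_label"))
  if (!dir.exists(dirname(path)))
    abort(sprintf("parent directory does not exist: %s", dirname(path)))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    arr <- vol$data
    # TIFF pages are written as 16-bit unsigned grayscale, the form scanner
    # exports take; values must be integers in [0, 65535]. Arbitrary float
    # volumes belong in NIfTI.
    if (any(arr < 0) || any(arr > 65535) || any(arr != round(arr)))
      abort("TIFF output requires integer grayscale in [0, 65535]; use NIfTI for float volumes")
    slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
    tiff::writeTIFF(slices, path, bits.per.sample = 16, reduce = FALSE)
    return(invisible(path))
  }
  arr <- vol$data
  is_label <- inherits(vol, "mt_label")
  if (is_label) storage.mode(arr) <- "integer"
  attr(arr, "pixdim") <- rep(vol$spacing, 3)
  attr(arr, "pixunits") <- "um"
  img <- RNifti::asNifti(arr, datatype = if (is_label) "uint8" else "double")
  RNifti::writeNifti(img, path, version = version,
                     datatype = if (is_label) "uint8" else "double")
  invisible(path)
}

# --- internals ---------------------------------------------------------------

resolve_volume_source <- function(path) {
  if (length(path) != 1L || !is.character(path))
    abort("`path` must be a single string")
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L)
      abort(sprintf("no TIFF slices found in directory: %s", path))
    return(list(kind = "tiff", paths = natural_sort(files)))
  }
  if (file.exists(path)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    if (ext == "nii") return(list(kind = "nifti", path = path))
    if (ext %in% c("tif", "tiff")) return(list(kind = "tiff", paths = path))
    abort(sprintf("unrecognised volume format: %s", path))
  }
  # glob of slices
  files <- Sys.glob(path)
  if (length(files) == 0L)
    abort(sprintf("file not found: %s", path))
  list(kind = "tiff", paths = natural_sort(files))
}

# natural (numeric-aware) filename ordering for slice stacks
natural_sort <- function(paths) {
  base <- basename(paths)
  toks <- regmatches(base, gregexpr("[0-9]+|[^0-9]+", base))
  width <- max(nchar(unlist(toks)))
  keys <- vapply(toks, function(t) {
    num <- grepl("^[0-9]+$", t)
    t[num] <- formatC(as.numeric(t[num]), width = width + 4, flag = "0",
                      format = "d")
    paste(t, collapse = "")
  }, character(1))
  paths[order(keys, base)]
}

read_tiff_slices <- function(paths) {
  pages <- list()
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pages <- c(pages, pg)
  }
  pages
}

slices_to_array <- function(slices) {
  slices <- lapply(slices, function(m) {
    if (length(dim(m)) == 3L) {
      if (dim(m)[3] == 1L) m <- m[, , 1] else
        abort("multi-channel TIFF slices are not scalar pixel data")
    }
    m
  })
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(m) identical(dim(m), d), logical(1))))
    abort("TIFF slices differ in shape")
  arr <- array(0, c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  arr
}

nifti_spacing_um <- function(img) {
  pd <- RNifti::pixdim(img)[1:3]
  un <- tryCatch(RNifti::pixunits(img)[1], error = function(e) "Unknown")
  mult <- switch(un,
                 "m" = 1e6, "mm" = 1e3, "um" = 1, "Unknown" = 1,
                 1)
  pd <- pd * mult
  if (any(!is.finite(pd)) || any(pd <= 0))
    return(list(value = NA_real_, isotropic = FALSE))
  iso <- diff(range(pd)) <= 1e-6 * max(pd)
  list(value = pd[1], isotropic = iso)
}
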
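#' Read a co-registered CT slice and lesion mask from disk
#'
#' 8-bit grayscale PNG is the primary format (image scaled to \[0, 1\], mask
#' binarised at > 127); single-slice NIfTI is accepted with min-max intensity
#' scaling. Image and mask must be grayscale and of identical size.
#'
#' @param image_path path to the slice image (`.png`, `.nii`, `.nii.gz`).
#' @param mask_path path to the mask.
#' @param slice_id identifier; defaults to the image file stem.
#' @return a `slice_pair`.
#' @export
read_slice_pair <- function(image_path, mask_path,
                            slice_id = sub("\\.(png|nii|nii\\.gz)$", "",
                                           basename(image_path))) {
  img <- read_gray(image_path, scale = "unit")
  msk <- read_gray(mask_path, scale = "none")
  if (!identical(dim(img), dim(msk))) {
    abort_dim("image (", paste(dim(img), collapse = "x"), ") and mask (",
              paste(dim(msk), collapse = "x"), ") sizes differ")
  }
  mask <- matrix(as.integer(msk > 127 / 255), nrow(msk), ncol(msk))
  new_slice_pair(img, mask, slice_id)
}

read_gray <- function(path, scale = c("unit", "none")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort_value("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort_value("reading NIfTI requires the RNifti package")
    }
    v <- as.array(RNifti::readNifti(path))
    v <- drop(v)
    if (length(dim(v)) != 2L) abort_dim("NIfTI input must be a single 2-d slice")
    rng <- range(v)
    if (scale == "unit" && diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
    return(matrix(as.numeric(v), nrow(v), ncol(v)))
  }
  if (!grepl("\\.png$", path)) abort_value("unsupported image format: ", path)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) {
    if (all(v[, , 1] == v[, , 2]) && all(v[, , 1] == v[, , 3])) {
      v <- v[, , 1]
    } else {
      abort_value("non-grayscale input: ", path)
    }
  }
  v
}

#' Write a slice pair as paired 8-bit grayscale PNGs
#'
#' Produces `<id>.png` and `<id>_mask.png` (mask values 0/255).
#'
#' @param pair a `slice_pair`.
#' @param dir output directory (created if absent).
#' @return the image path, invisibly.
#' @export
write_slice_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ip <- file.path(dir, paste0(pair$slice_id, ".png"))
  mp <- file.path(dir, paste0(pair$slice_id, "_mask.png"))
  png::writePNG(pair$image, ip)
  png::writePNG(pair$mask * 1.0, mp)
  invisible(ip)
}

#' Write a phantom dataset with its manifest
#'
#' Writes every pair via [write_slice_pair()] plus `manifest.csv` with
#' columns `slice_id`, `lesion_area_px`.
#'
#' @param pairs list of `slice_pair`.
#' @param dir output directory.
#' @return tibble manifest, invisibly.
#' @export
write_dataset <- function(pairs, dir) {
  purrr::walk(pairs, write_slice_pair, dir = dir)
  manifest <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(slice_id = p$slice_id, lesion_area_px = sum(p$mask))
  })
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of `slice_pair`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort_value("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  purrr::map(manifest$slice_id, function(id) {
    read_slice_pair(file.path(dir, paste0(id, ".png")),
                    file.path(dir, paste0(id, "_mask.png")),
                    slice_id = id)
  })
}

#' Export a slice pair as single-slice NIfTI volumes
#'
#' Interoperability writer: `<prefix>.nii.gz` (image) and
#' `<prefix>_mask.nii.gz` (0/1 mask). Requires the RNifti package.
#'
#' @param pair a `slice_pair`.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_slice_nifti <- function(pair, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort_value("NIfTI export requires the RNifti package")
  }
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  ip <- paste0(prefix, ".nii.gz")
  mp <- paste0(prefix, "_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(pair$image), ip)
  RNifti::writeNifti(RNifti::asNifti(pair$mask * 1.0), mp)
  invisible(c(image = ip, mask = mp))
}

#' Write a prediction (probability map + binary mask)
#'
#' The thresholded mask goes to `<prefix>_mask.png` (8-bit, 0/255); the
#' continuous probability map goes to `<prefix>_prob.tif` as 16-bit TIFF so
#' downstream users can re-threshold without quantisation loss (8-bit PNG
#' cannot carry 16-bit samples).
#'
#' @param prob numeric H x W probability matrix in \[0, 1\].
#' @param prefix output path prefix.
#' @param threshold binarisation threshold.
#' @return named character vector of the files written, invisibly.
#' @export
write_prediction <- function(prob, prefix, threshold = 0.5) {
  mask <- binarize(prob, threshold)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  mp <- paste0(prefix, "_mask.png")
  pp <- paste0(prefix, "_prob.tif")
  png::writePNG(mask * 1.0, mp)
  if (requireNamespace("tiff", quietly = TRUE)) {
    tiff::writeTIFF(prob, pp, bits.per.sample = 16L)
  } else {
    pp <- paste0(prefix, "_prob.png")
    png::writePNG(prob, pp)
  }
  invisible(c(mask = mp, prob = pp))
}
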
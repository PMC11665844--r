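#' Synthetic CT head-phantom configuration
#'
#' The phantom emulates the statistical shape of axial haemorrhage CT slices:
#' a dark background, a bright elliptical skull ring, mid-intensity
#' parenchyma with smooth low-frequency texture, and a small number of
#' low-contrast, slightly deformed elliptical lesions whose union is the
#' ground-truth mask. It stands in for clinical data in tests and examples;
#' it does not model Hounsfield radiometry, beam hardening or 3-d anatomy.
#'
#' @param size square image side in pixels, divisible by 32. Default 64
#'   (desk-scale; clinical slices are 512).
#' @param n_lesions integer `[min, max]` lesions per slice (default 1-3).
#' @param lesion_radius pixel `[min, max]` base radius (default 2-5, spanning
#'   few-pixel "tiny" lesions to larger blobs).
#' @param lesion_contrast `[min, max]` lesion-minus-parenchyma intensity gap
#'   in normalised units (default 0.08-0.25, the low-contrast regime).
#' @param noise_sigma standard deviation of additive Gaussian acquisition
#'   noise (default 0.02).
#' @param skull_thickness skull ring thickness in pixels.
#' @param lesion_perturb amplitude of the low-order harmonic radial
#'   deformation of lesion boundaries (0 gives exact discs).
#' @param seed integer seed controlling every random choice.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(size = 64L, n_lesions = c(1L, 3L),
                           lesion_radius = c(2, 5),
                           lesion_contrast = c(0.08, 0.25),
                           noise_sigma = 0.02, skull_thickness = 3L,
                           lesion_perturb = 0.15, seed = 1L) {
  check_count(size, "size")
  if (size %% 32L != 0L) abort_config("`size` must be divisible by 32, got ", size)
  check_range2(n_lesions, "n_lesions", lo = 0)
  check_range2(lesion_radius, "lesion_radius", lo = 1)
  check_range2(lesion_contrast, "lesion_contrast")
  if (lesion_contrast[1] <= 0) abort_config("`lesion_contrast` minimum must be positive")
  if (noise_sigma < 0) abort_config("`noise_sigma` must be nonnegative")
  check_count(skull_thickness, "skull_thickness")
  if (lesion_perturb < 0 || lesion_perturb >= 0.5) {
    abort_config("`lesion_perturb` must lie in [0, 0.5)")
  }
  structure(
    list(size = as.integer(size), n_lesions = as.integer(n_lesions),
         lesion_radius = as.numeric(lesion_radius),
         lesion_contrast = as.numeric(lesion_contrast),
         noise_sigma = noise_sigma, skull_thickness = as.integer(skull_thickness),
         lesion_perturb = lesion_perturb, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

new_slice_pair <- function(image, mask, slice_id) {
  stopifnot(identical(dim(image), dim(mask)))
  structure(list(image = image, mask = mask, slice_id = slice_id),
            class = "slice_pair")
}

#' @export
print.slice_pair <- function(x, ...) {
  cat(sprintf("<slice_pair %s: %d x %d, %d lesion pixels (%.2f%%)>\n",
              x$slice_id, nrow(x$image), ncol(x$image), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Generate one synthetic head-phantom slice
#'
#' Fully deterministic given `(cfg, seed)`: the image is background, skull
#' ring (intensity ~0.95), textured parenchyma (~0.45), lesions at
#' parenchyma + contrast, plus Gaussian noise, clipped to \[0, 1\]; the mask
#' is the exact union of the lesion supports, always strictly inside the
#' brain region.
#'
#' @param cfg a [phantom_config()].
#' @param seed seed for this slice (defaults to `cfg$seed`).
#' @param slice_id identifier string.
#' @return a `slice_pair` (image matrix in \[0, 1\], integer 0/1 mask).
#' @export
generate_slice <- function(cfg, seed = cfg$seed, slice_id = sprintf("slice_%06d", seed)) {
  withr::with_seed(seed, generate_slice_impl(cfg, slice_id))
}

generate_slice_impl <- function(cfg, slice_id) {
  S <- cfg$size
  cy <- cx <- (S + 1) / 2
  a <- 0.46 * S # row semi-axis of the outer skull ellipse
  b <- 0.40 * S # col semi-axis
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  rho <- sqrt(((rr - cy) / a)^2 + ((cc - cx) / b)^2)
  t_norm <- cfg$skull_thickness / min(a, b)
  inner <- 1 - t_norm

  img <- matrix(0.02, S, S)
  img[rho <= 1] <- 0.95                       # skull ring (and interior, overwritten)
  brain <- rho <= inner
  # smooth low-frequency parenchyma texture
  tex <- matrix(0, S, S)
  for (k in 1:3) {
    f <- runif(2, 0.5, 2.5)
    ph <- runif(1, 0, 2 * pi)
    tex <- tex + 0.02 * cos(2 * pi * (f[1] * rr + f[2] * cc) / S + ph)
  }
  img[brain] <- 0.45 + tex[brain]

  mask <- matrix(0L, S, S)
  n_les <- if (cfg$n_lesions[1] == cfg$n_lesions[2]) cfg$n_lesions[1] else
    sample(cfg$n_lesions[1]:cfg$n_lesions[2], 1L)
  if (n_les > 0) {
    for (i in seq_len(n_les)) {
      placed <- FALSE
      for (attempt in seq_len(100L)) {
        r0 <- runif(1, cfg$lesion_radius[1], cfg$lesion_radius[2])
        a1 <- cfg$lesion_perturb * runif(1)
        a2 <- cfg$lesion_perturb * runif(1) / 2
        ph1 <- runif(1, 0, 2 * pi)
        ph2 <- runif(1, 0, 2 * pi)
        contrast <- runif(1, cfg$lesion_contrast[1], cfg$lesion_contrast[2])
        # candidate centre anywhere in the brain interior
        cand <- which(brain)
        ctr <- cand[sample.int(length(cand), 1L)]
        crow <- (ctr - 1) %% S + 1
        ccol <- (ctr - 1) %/% S + 1
        dr <- rr - crow
        dc <- cc - ccol
        dist <- sqrt(dr^2 + dc^2)
        theta <- atan2(dc, dr)
        rad <- r0 * (1 + a1 * cos(theta + ph1) + a2 * cos(2 * theta + ph2))
        support <- dist <= rad
        if (!any(support)) next
        if (all(brain[support])) {
          mask[support] <- 1L
          img[support] <- img[support] + contrast
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rlang::abort(
          paste0("could not place a lesion of radius up to ", cfg$lesion_radius[2],
                 " px strictly inside the brain region after 100 attempts; ",
                 "size = ", S, ", skull_thickness = ", cfg$skull_thickness,
                 " leave too little interior room"),
          class = "hemoseg_generation_error"
        )
      }
    }
  }
  if (cfg$noise_sigma > 0) img <- img + matrix(rnorm(S * S, sd = cfg$noise_sigma), S, S)
  img <- pmin(pmax(img, 0), 1)
  new_slice_pair(img, mask, slice_id)
}

#' Generate a deterministic phantom dataset
#'
#' Derives one sub-seed per slice from `seed`, so
#' `generate_dataset(cfg, n)[[1]]` is identical for any `n` and the whole
#' dataset is reproducible bit-for-bit.
#'
#' @param cfg a [phantom_config()].
#' @param n number of slices (>= 1).
#' @param seed stream seed (defaults to `cfg$seed`).
#' @return list of `slice_pair` with unique deterministic `slice_id`s.
#' @export
generate_dataset <- function(cfg, n, seed = cfg$seed) {
  check_count(n, "n")
  sub_seeds <- withr::with_seed(seed, sample.int(2147483646L, n))
  purrr::map2(sub_seeds, seq_len(n), function(s, i) {
    generate_slice(cfg, seed = s, slice_id = sprintf("slice_%04d", i))
  })
}

# ---- paired geometric / photometric transforms -----------------------------

# inverse-mapping affine sampler; rows/cols are 1-based image coordinates and
# the transform maps OUTPUT pixel centres to SOURCE coordinates about the
# image centre. Out-of-support samples read as `fill`.
affine_sample <- function(img, src_rc, method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  rs <- src_rc$r; cs <- src_rc$c
  if (method == "nearest") {
    ri <- round(rs); ci <- round(cs)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, H, W)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(fill, H, W)
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  gather(r0, c0) * (1 - fr) * (1 - fc) + gather(r0 + 1, c0) * fr * (1 - fc) +
    gather(r0, c0 + 1) * (1 - fr) * fc + gather(r0 + 1, c0 + 1) * fr * fc
}

grid_rc <- function(H, W) {
  list(r = matrix(seq_len(H), H, W), c = matrix(seq_len(W), H, W, byrow = TRUE))
}

transform_pair <- function(pair, src_rc) {
  new_slice_pair(
    affine_sample(pair$image, src_rc, "bilinear", fill = 0),
    {
      m <- affine_sample(pair$mask, src_rc, "nearest", fill = 0)
      matrix(as.integer(m != 0), nrow(m), ncol(m))
    },
    pair$slice_id
  )
}

#' Paired deterministic slice transforms
#'
#' Geometric transforms are applied identically to image and mask (bilinear
#' versus nearest-neighbour interpolation, zero fill, so the mask stays
#' binary); photometric transforms touch the image only.
#'
#' @param pair a `slice_pair`.
#' @param angle rotation in degrees, counter-clockwise about the image
#'   centre (row/col coordinates).
#' @return a transformed `slice_pair`.
#' @export
rotate_pair <- function(pair, angle) {
  H <- nrow(pair$image); W <- ncol(pair$image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- angle * pi / 180
  g <- grid_rc(H, W)
  dr <- g$r - cy; dc <- g$c - cx
  # inverse rotation of the output grid
  transform_pair(pair, list(r = cy + cos(th) * dr + sin(th) * dc,
                            c = cx - sin(th) * dr + cos(th) * dc))
}

#' @rdname rotate_pair
#' @param axis `"h"` mirrors left-right (columns), `"v"` top-bottom (rows).
#' @export
flip_pair <- function(pair, axis = c("h", "v")) {
  axis <- match.arg(axis)
  if (axis == "h") {
    new_slice_pair(pair$image[, ncol(pair$image):1],
                   pair$mask[, ncol(pair$mask):1], pair$slice_id)
  } else {
    new_slice_pair(pair$image[nrow(pair$image):1, ],
                   pair$mask[nrow(pair$mask):1, ], pair$slice_id)
  }
}

#' @rdname rotate_pair
#' @param factor zoom factor (> 1 enlarges about the centre; the canvas size
#'   is unchanged, content is cropped or zero-padded as needed).
#' @export
scale_pair <- function(pair, factor) {
  if (factor <= 0) abort_value("`factor` must be positive")
  H <- nrow(pair$image); W <- ncol(pair$image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- grid_rc(H, W)
  transform_pair(pair, list(r = cy + (g$r - cy) / factor,
                            c = cx + (g$c - cx) / factor))
}

#' @rdname rotate_pair
#' @param gain linear contrast gain applied about mid-grey:
#'   `0.5 + gain * (image - 0.5)`, clipped to \[0, 1\]. Mask untouched.
#' @export
contrast_pair <- function(pair, gain) {
  img <- pmin(pmax(0.5 + gain * (pair$image - 0.5), 0), 1)
  new_slice_pair(img, pair$mask, pair$slice_id)
}

#' @rdname rotate_pair
#' @param sigma additive Gaussian noise standard deviation (image only;
#'   drawn from the current RNG state).
#' @export
noise_pair <- function(pair, sigma) {
  img <- pair$image + matrix(rnorm(length(pair$image), sd = sigma),
                             nrow(pair$image), ncol(pair$image))
  new_slice_pair(pmin(pmax(img, 0), 1), pair$mask, pair$slice_id)
}

#' Random paired augmentation
#'
#' Applies the requested subset of operations with magnitudes drawn from the
#' current RNG state (so a surrounding `set.seed()`/[withr::with_seed()]
#' makes it reproducible): rotation in +/-30 degrees, horizontal or vertical
#' flip, scaling 0.9-1.1, linear contrast gain 0.8-1.2 and additive Gaussian
#' noise (sigma 0.02). Geometric operations move image and mask together;
#' photometric ones leave the mask bit-exact.
#'
#' @param pair a `slice_pair`.
#' @param ops non-empty subset of
#'   `c("rotate", "flip", "scale", "contrast", "noise")`.
#' @param params optional list overriding the random magnitudes
#'   (`angle`, `axis`, `factor`, `gain`, `sigma`).
#' @return augmented `slice_pair`.
#' @export
augment <- function(pair, ops = c("rotate", "flip", "scale", "contrast", "noise"),
                    params = list()) {
  choices <- c("rotate", "flip", "scale", "contrast", "noise")
  if (length(ops) == 0L) abort_value("`ops` must name at least one augmentation")
  if (!all(ops %in% choices)) {
    abort_value("unknown augmentation op(s): ", paste(setdiff(ops, choices), collapse = ", "))
  }
  out <- pair
  if ("rotate" %in% ops) {
    out <- rotate_pair(out, params$angle %||% runif(1, -30, 30))
  }
  if ("flip" %in% ops) {
    out <- flip_pair(out, params$axis %||% sample(c("h", "v"), 1L))
  }
  if ("scale" %in% ops) {
    out <- scale_pair(out, params$factor %||% runif(1, 0.9, 1.1))
  }
  if ("contrast" %in% ops) {
    out <- contrast_pair(out, params$gain %||% runif(1, 0.8, 1.2))
  }
  if ("noise" %in% ops) {
    out <- noise_pair(out, params$sigma %||% 0.02)
  }
  out
}
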
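#' Parameters for the synthetic nucleus-image generator
#'
#' Describes 2D grayscale nuclei: a circular nuclear mask containing bright
#' elliptical foci on a darker background, with additive Gaussian pixel
#' noise. Focus aspect ratios are lognormal around 1; the default log-SD
#' (0.468) is calibrated so the expected analytic circularity
#' `4 * pi * A / P^2` of a focus equals 0.93 (Ramanujan perimeter,
#' solved numerically).
#'
#' @param image_size_px integer pair, image width and height (default 160).
#' @param n_foci foci per nucleus (default 12).
#' @param focus_radius_px geometric mean radius of a focus in pixels
#'   (default 8); an ellipse with aspect `rho` has semi-axes
#'   `r * sqrt(rho)` and `r / sqrt(rho)`, preserving area.
#' @param focus_aspect_log_sd log-SD of the lognormal aspect ratio
#'   (default 0.468, true mean shape factor 0.93).
#' @param background_level,focus_level intensities on a 16-bit scale
#'   (defaults 500 and 3000); `focus_level` must exceed `background_level`.
#' @param noise_sd additive Gaussian noise SD (default 100).
#' @param mask_radius_frac nuclear mask radius as a fraction of the half
#'   image size (default 0.9).
#' @param allow_overlap if `FALSE` (default), foci are placed without
#'   mutual overlap so each segmented object corresponds to one focus.
#' @param n_images number of nuclei to generate.
#' @param seed integer seed, required by [generate_nucleus_images()].
#' @return An object of class `image_gen_params`.
#' @export
image_gen_params <- function(image_size_px = c(160L, 160L), n_foci = 12L,
                             focus_radius_px = 8, focus_aspect_log_sd = 0.468,
                             background_level = 500, focus_level = 3000,
                             noise_sd = 100, mask_radius_frac = 0.9,
                             allow_overlap = FALSE,
                             n_images = 1L, seed = NULL) {
  if (length(image_size_px) == 1) image_size_px <- rep(image_size_px, 2)
  if (any(image_size_px < 16)) stop("image must be at least 16 px", call. = FALSE)
  if (n_foci < 0) stop("n_foci must be >= 0", call. = FALSE)
  if (focus_radius_px <= 0) stop("focus_radius_px must be > 0", call. = FALSE)
  if (focus_aspect_log_sd < 0) stop("focus_aspect_log_sd must be >= 0", call. = FALSE)
  if (focus_level <= background_level)
    stop("focus_level must exceed background_level", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (mask_radius_frac <= 0 || mask_radius_frac > 1)
    stop("mask_radius_frac must be in (0, 1]", call. = FALSE)
  structure(list(image_size_px = as.integer(image_size_px),
                 n_foci = as.integer(n_foci),
                 focus_radius_px = focus_radius_px,
                 focus_aspect_log_sd = focus_aspect_log_sd,
                 background_level = background_level,
                 focus_level = focus_level, noise_sd = noise_sd,
                 mask_radius_frac = mask_radius_frac,
                 allow_overlap = isTRUE(allow_overlap),
                 n_images = as.integer(n_images),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "image_gen_params")
}

## analytic circumference of an ellipse with semi-axes a, b (Ramanujan II)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Generate synthetic nucleus images with elliptical foci
#'
#' Renders each nucleus as a circular mask at `background_level` carrying
#' `n_foci` filled ellipses at `focus_level`, then adds Gaussian pixel
#' noise. Foci are placed entirely inside the mask (and, by default,
#' without mutual overlap) by bounded rejection (largest focus placed
#' first); placement failure after 2000 retries per focus is an error.
#'
#' @param params an [image_gen_params()] object with a non-`NULL` seed.
#' @return An object of class `nucleus_image_set`: a list of images, each a
#'   list with `image` (numeric matrix), `mask` (logical matrix), and
#'   `truth` (data frame of per-focus centre, semi-axes, angle, analytic
#'   `area_px`, `perimeter_px` and `shape_factor`).
#' @examples
#' imgs <- generate_nucleus_images(image_gen_params(n_images = 1, seed = 5))
#' mean(imgs[[1]]$truth$shape_factor)
#' @export
generate_nucleus_images <- function(params) {
  if (!inherits(params, "image_gen_params"))
    stop("params must be built with image_gen_params()", call. = FALSE)
  if (is.null(params$seed))
    stop("params$seed is required: generation must be reproducible", call. = FALSE)
  set.seed(params$seed)
  w <- params$image_size_px[1]; h <- params$image_size_px[2]
  cx0 <- (w + 1) / 2; cy0 <- (h + 1) / 2
  rmask <- params$mask_radius_frac * (min(w, h) - 1) / 2
  xg <- matrix(seq_len(w), w, h)
  yg <- matrix(seq_len(h), w, h, byrow = TRUE)
  mask <- (xg - cx0)^2 + (yg - cy0)^2 <= rmask^2

  out <- vector("list", params$n_images)
  for (im in seq_len(params$n_images)) {
    img <- matrix(params$background_level, w, h)
    truth <- list()
    placed <- NULL   # cx, cy, rmax per accepted focus
    # draw every focus shape first, then place largest-first: the shape
    # distribution is untouched and packing failures become rare
    rhos <- exp(stats::rnorm(params$n_foci, 0, params$focus_aspect_log_sd))
    ths <- stats::runif(params$n_foci, 0, pi)
    ord <- order(pmax(sqrt(rhos), 1 / sqrt(rhos)), decreasing = TRUE)
    for (k in seq_len(params$n_foci)) {
      rho <- rhos[ord[k]]
      a <- params$focus_radius_px * sqrt(rho)
      b <- params$focus_radius_px / sqrt(rho)
      th <- ths[ord[k]]
      rmax <- max(a, b)
      ok <- FALSE
      for (try in seq_len(2000)) {
        cx <- stats::runif(1, cx0 - rmask, cx0 + rmask)
        cy <- stats::runif(1, cy0 - rmask, cy0 + rmask)
        if (sqrt((cx - cx0)^2 + (cy - cy0)^2) + rmax + 1 > rmask) next
        if (!params$allow_overlap && !is.null(placed) &&
            any(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) <
                placed[, 3] + rmax + 2)) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place focus ", k, " inside the nuclear mask after ",
             "2000 retries; reduce n_foci or focus_radius_px", call. = FALSE)
      placed <- rbind(placed, c(cx, cy, rmax))
      # fill the rotated ellipse
      u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
      v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
      img[(u / a)^2 + (v / b)^2 <= 1] <- params$focus_level
      truth[[k]] <- data.frame(
        focus = k, cx = cx, cy = cy, a = a, b = b, angle = th,
        area_px = pi * a * b, perimeter_px = ellipse_perimeter(a, b),
        shape_factor = 4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2)
    }
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(w * h, 0, params$noise_sd), w, h)
    img[img < 0] <- 0
    out[[im]] <- list(image = img, mask = mask,
                      truth = if (length(truth)) do.call(rbind, truth) else
                        data.frame(focus = integer(0), cx = numeric(0),
                                   cy = numeric(0), a = numeric(0),
                                   b = numeric(0), angle = numeric(0),
                                   area_px = numeric(0),
                                   perimeter_px = numeric(0),
                                   shape_factor = numeric(0)))
  }
  structure(out, params = params, class = "nucleus_image_set")
}

#' @export
print.nucleus_image_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<nucleus_image_set> %d images (%dx%d px, %d foci each)\n",
              length(x), p$image_size_px[1], p$image_size_px[2], p$n_foci))
  invisible(x)
}

#' Progressively disperse the focal signal of an image
#'
#' Computational analogue of chemical focus disassembly: the image is
#' convolved with Gaussian kernels of increasing width, spreading the same
#' integrated signal over a growing area while the mask total stays
#' (approximately) constant. Used to study how the pixel-intensity
#' coefficient of variation falls as foci disassemble.
#'
#' @param image numeric matrix.
#' @param sigmas increasing blur SDs in pixels; 0 means untouched.
#' @return List of images, one per `sigmas` entry.
#' @export
disperse_signal <- function(image, sigmas) {
  lapply(sigmas, function(s) {
    if (s <= 0) return(image)
    as.matrix(EBImage::gblur(EBImage::Image(image), sigma = s))
  })
}
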
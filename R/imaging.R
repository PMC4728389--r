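#' Imaging configuration for synthetic fluorescence frames
#'
#' Geometry and noise model of the synthetic whole-animal fluorescence
#' camera. Continuous coordinates are in mm with the origin at the image's
#' top-left corner; pixel \eqn{(i, j)} (row, column, 0-based) has its centre
#' at \eqn{((j + 0.5) s, (i + 0.5) s)} with \eqn{s} the pixel size. The
#' injection site \code{center} is an \code{(x, y)} position in mm and may be
#' sub-pixel.
#'
#' @param n_px image side length (pixels, >= 32).
#' @param pixel_size mm per pixel (> 0).
#' @param center injection-site position \code{c(x, y)} in mm; defaults to
#'   the image midpoint.
#' @param psf_sigma Gaussian point-spread blur (mm, 0 disables).
#' @param noise_rel multiplicative noise s.d. (fraction of signal, >= 0).
#' @param noise_add additive noise s.d. (intensity units, >= 0).
#' @param background additive constant offset (intensity units, >= 0).
#' @param seed integer PRNG seed for the frame-noise substreams.
#' @return An object of class \code{imaging_config}.
#' @export
imaging_config <- function(n_px = 128, pixel_size = 0.2, center = NULL,
                           psf_sigma = 0, noise_rel = 0.05, noise_add = 0,
                           background = 0, seed = 1L) {
  n_px <- as.integer(check_scalar(n_px, "n_px", 32))
  pixel_size <- check_scalar(pixel_size, "pixel_size", 0, strict = TRUE)
  side <- n_px * pixel_size
  center <- center %||% c(side / 2, side / 2)
  if (length(center) != 2L || any(!is.finite(center)))
    stop_config("'center' must be a finite (x, y) pair in mm")
  if (any(center < 0) || any(center > side))
    stop_config("'center' (%.3g, %.3g) lies outside the %.3g mm image",
                center[1], center[2], side)
  structure(list(n_px = n_px, pixel_size = pixel_size,
                 center = as.numeric(center),
                 psf_sigma = check_scalar(psf_sigma, "psf_sigma", 0),
                 noise_rel = check_scalar(noise_rel, "noise_rel", 0),
                 noise_add = check_scalar(noise_add, "noise_add", 0),
                 background = check_scalar(background, "background", 0),
                 seed = as.integer(check_scalar(seed, "seed", 0))),
            class = "imaging_config")
}

# matrix of pixel-centre distances (mm) to the configured centre
.pixel_distances <- function(cfg) {
  s <- cfg$pixel_size
  xc <- (seq_len(cfg$n_px) - 0.5) * s - cfg$center[1]
  yc <- (seq_len(cfg$n_px) - 0.5) * s - cfg$center[2]
  sqrt(outer(yc^2, xc^2, "+"))
}

# separable Gaussian blur with edge renormalisation; sigma in mm
.gaussian_blur <- function(img, sigma, pixel_size) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(4 * sigma / pixel_size))
  kx <- stats::dnorm(seq(-half, half) * pixel_size, sd = sigma)
  kx <- kx / sum(kx)
  pad_conv <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (o in seq(-half, half)) {
      w <- kx[o + half + 1]
      src_rows <- pmin(pmax(seq_len(n) + o, 1L), n)  # nothing beyond edge
      valid <- (seq_len(n) + o >= 1L) & (seq_len(n) + o <= n)
      out[valid, ] <- out[valid, ] + w * m[src_rows[valid], ]
      norm[valid] <- norm[valid] + w
    }
    out / norm
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Render a noiseless synthetic fluorescence frame
#'
#' Evaluates the model concentration at every pixel-centre's distance to the
#' injection site (the intensity-to-concentration mapping is the identity on
#' the scaled-intensity axis), optionally blurs with a Gaussian PSF and adds
#' the background offset. Deterministic. At \code{t = 0} the initial profile
#' is used directly; at later times the radial solution is evaluated on a
#' dense radial grid (spacing \code{pixel_size / 4}) and interpolated to the
#' pixel distances with a natural cubic spline.
#'
#' @param src a [weibull_source()].
#' @param ic an [initial_condition()].
#' @param tr a [transport()].
#' @param t acquisition time (day, scalar >= 0).
#' @param cfg an [imaging_config()].
#' @param q a [quadrature_config()].
#' @param op optional precomputed spectral operator (internal reuse).
#' @return \code{n_px} x \code{n_px} non-negative intensity matrix.
#' @export
render_frame <- function(src, ic, tr, t, cfg, q = quadrature_config(),
                         op = NULL) {
  stopifnot(inherits(cfg, "imaging_config"))
  t <- check_scalar(t, "t", 0)
  d <- .pixel_distances(cfg)
  if (t == 0) {
    img <- matrix(initial_condition_profile(as.vector(d), ic),
                  cfg$n_px, cfg$n_px)
  } else {
    rg <- seq(0, max(d) + cfg$pixel_size, by = cfg$pixel_size / 4)
    prof <- solve_concentration(rg, t, src, ic, tr, q, op = op, drop = FALSE)
    f <- stats::splinefun(rg, prof[, 1], method = "natural")
    img <- matrix(f(as.vector(d)), cfg$n_px, cfg$n_px)
  }
  img <- .gaussian_blur(img, cfg$psf_sigma, cfg$pixel_size)
  img + cfg$background
}

#' Apply the camera noise model
#'
#' Each pixel \eqn{p} becomes
#' \eqn{\max(0,\; p (1 + \epsilon_{rel}) + \epsilon_{add})} with independent
#' Gaussian perturbations of s.d. \code{noise_rel} (multiplicative, as a
#' fraction of the signal) and \code{noise_add} (additive); negative values
#' are clipped to zero. Reproducible given \code{seed}.
#'
#' @param image non-negative intensity matrix.
#' @param cfg an [imaging_config()] supplying the noise levels.
#' @param seed optional integer; when given, seeds the RNG before drawing.
#' @return Noisy image, same dimensions, never negative.
#' @export
add_noise <- function(image, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "imaging_config"))
  if (any(image < 0)) stop_config("'image' must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(image)
  eps_rel <- if (cfg$noise_rel > 0) stats::rnorm(n, 0, cfg$noise_rel) else 0
  eps_add <- if (cfg$noise_add > 0) stats::rnorm(n, 0, cfg$noise_add) else 0
  out <- image * (1 + eps_rel) + eps_add
  matrix(pmax(out, 0), nrow(image), ncol(image))
}

#' Generate a synthetic fluorescence image stack
#'
#' Renders one frame per acquisition time from the forward model and applies
#' the noise model, each frame drawing from its own seed-derived substream
#' (\code{cfg$seed + frame index}) so stacks are bit-reproducible and frames
#' independently so. The generating parameters are embedded as ground truth.
#'
#' @param src a [weibull_source()].
#' @param ic an [initial_condition()].
#' @param tr a [transport()].
#' @param times acquisition days, non-empty, strictly increasing, >= 0.
#' @param cfg an [imaging_config()].
#' @param q a [quadrature_config()].
#' @return An object of class \code{image_stack}: list with \code{times},
#'   \code{frames} (list of matrices), \code{config}, \code{truth}.
#' @export
generate_stack <- function(src, ic, tr, times, cfg = imaging_config(),
                           q = quadrature_config()) {
  if (length(times) == 0) stop_config("'times' must be non-empty")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop_config("'times' must be non-negative and strictly increasing")
  op <- if (any(times > 0)) hankel_operator(src, ic, q) else NULL
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    clean <- render_frame(src, ic, tr, times[i], cfg, q, op = op)
    frames[[i]] <- add_noise(clean, cfg, seed = cfg$seed + i)
  }
  structure(list(times = as.numeric(times), frames = frames, config = cfg,
                 truth = list(source = src, initial = ic, transport = tr)),
            class = "image_stack")
}

#' Azimuthally averaged radial intensity profile
#'
#' Mean pixel intensity in thin annuli about the injection centre: a pixel
#' contributes to radius \eqn{r} when its centre distance lies in the
#' half-open annulus \eqn{[r - w/2, r + w/2)}. This is the extraction step
#' turning an image into intensity-versus-radius data.
#'
#' @param image intensity matrix.
#' @param center \code{c(x, y)} position of the injection site (mm).
#' @param radii nominal radii (mm) at which to report the mean intensity.
#' @param annulus_width annulus width \eqn{w} (mm, > 0).
#' @param pixel_size mm per pixel.
#' @return Named numeric vector of mean intensities, one per radius.
#' @export
extract_radial_profile <- function(image, center, radii, annulus_width,
                                   pixel_size) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  annulus_width <- check_scalar(annulus_width, "annulus_width", 0, strict = TRUE)
  pixel_size <- check_scalar(pixel_size, "pixel_size", 0, strict = TRUE)
  n <- nrow(image)
  xc <- (seq_len(n) - 0.5) * pixel_size - center[1]
  yc <- (seq_len(n) - 0.5) * pixel_size - center[2]
  d <- sqrt(outer(yc^2, xc^2, "+"))
  out <- vapply(radii, function(r) {
    sel <- d >= r - annulus_width / 2 & d < r + annulus_width / 2
    if (!any(sel))
      stop_config("annulus at r = %.4g mm (width %.4g) contains no pixel centre",
                  r, annulus_width)
    mean(image[sel])
  }, numeric(1))
  names(out) <- formatC(radii, format = "g")
  out
}

#' Locate the injection site in a frame
#'
#' Intensity-weighted centroid of the pixels above the given intensity
#' percentile of the frame; translation-equivariant and exact for
#' symmetric noiseless frames.
#'
#' @param image intensity matrix.
#' @param percentile fraction in (0, 1); pixels strictly above this quantile
#'   enter the centroid (default 0.99).
#' @param pixel_size mm per pixel.
#' @return \code{c(x, y)} centre estimate in mm.
#' @export
estimate_center <- function(image, percentile = 0.99, pixel_size) {
  stopifnot(is.matrix(image))
  pixel_size <- check_scalar(pixel_size, "pixel_size", 0, strict = TRUE)
  thr <- stats::quantile(image, percentile, names = FALSE)
  sel <- which(image > thr, arr.ind = TRUE)
  if (nrow(sel) == 0)
    stop_config("no pixel above the %.3g quantile; image is flat or degenerate",
                percentile)
  wgt <- image[sel]
  x <- (sel[, "col"] - 0.5) * pixel_size
  y <- (sel[, "row"] - 0.5) * pixel_size
  c(x = sum(wgt * x) / sum(wgt), y = sum(wgt * y) / sum(wgt))
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages (one per time); acquisition
#' times, pixel geometry, seed and the ground-truth parameters travel in a
#' JSON sidecar next to the TIFF. The round trip is lossless at 32-bit float
#' precision.
#'
#' @param stack an [generate_stack()] result.
#' @param path TIFF file path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  # TIFF storage is defined on [0,1]; store frames divided by a recorded
  # scale so intensities above 1 (noise excursions) survive the round trip
  scale <- max(1, vapply(stack$frames, max, numeric(1)))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  cfg <- stack$config
  sidecar <- list(
    times = stack$times, scale = scale,
    n_px = cfg$n_px, pixel_size = cfg$pixel_size, center = cfg$center,
    psf_sigma = cfg$psf_sigma, noise_rel = cfg$noise_rel,
    noise_add = cfg$noise_add, background = cfg$background, seed = cfg$seed,
    truth = list(source = unclass(stack$truth$source),
                 initial = unclass(stack$truth$initial),
                 transport = unclass(stack$truth$transport)),
    note = "synthetic stack; all imaging parameters are package stand-ins, no real acquisition geometry")
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF file path with its JSON sidecar alongside.
#' @return An \code{image_stack}.
#' @export
read_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path))
    stop_config("stack '%s' or its JSON sidecar is missing", path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  scale <- side$scale %||% 1
  frames <- lapply(tiff::readTIFF(path, all = TRUE), function(f) f * scale)
  cfg <- imaging_config(n_px = side$n_px, pixel_size = side$pixel_size,
                        center = side$center, psf_sigma = side$psf_sigma,
                        noise_rel = side$noise_rel, noise_add = side$noise_add,
                        background = side$background, seed = side$seed)
  truth <- if (!is.null(side$truth)) {
    list(source = do.call(weibull_source, as.list(side$truth$source)),
         initial = do.call(initial_condition, as.list(side$truth$initial)),
         transport = do.call(transport, as.list(side$truth$transport)))
  }
  structure(list(times = as.numeric(side$times), frames = frames, config = cfg,
                 truth = truth),
            class = "image_stack")
}

#' Extract radial intensity time series from a stack
#'
#' Applies [extract_radial_profile()] to every frame, producing the
#' radius-by-time observation matrix consumed by the fitting module.
#'
#' @param stack an \code{image_stack}.
#' @param radii nominal radii (mm).
#' @param annulus_width annulus width (mm); default 2 pixels.
#' @param center override the configured centre (mm), e.g. from
#'   [estimate_center()].
#' @return An [observations()] object.
#' @export
stack_observations <- function(stack, radii, annulus_width = NULL,
                               center = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  cfg <- stack$config
  annulus_width <- annulus_width %||% (2 * cfg$pixel_size)
  center <- center %||% cfg$center
  mat <- vapply(stack$frames, extract_radial_profile,
                numeric(length(radii)),
                center = center, radii = radii,
                annulus_width = annulus_width, pixel_size = cfg$pixel_size)
  mat <- matrix(mat, nrow = length(radii))
  observations(radii = radii, times = stack$times, intensities = mat)
}
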
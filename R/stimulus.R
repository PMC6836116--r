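#' Gabor stimulus parameterization
#'
#' A Gabor patch is a sinusoidal luminance carrier windowed by an isotropic
#' Gaussian envelope. The carrier wavelength `lambda = 1 / spatial_frequency`
#' (in degrees) is always derived, never stored. The defaults describe the
#' targets of the lateral-masking design: 4 cycles/degree, vertical, cosine
#' phase; the envelope sigma, not stated numerically in the source design,
#' defaults to one wavelength (0.25 deg), the classic choice in this
#' paradigm, and is configurable.
#'
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param spatial_frequency Cycles per degree (> 0).
#' @param orientation Degrees clockwise from vertical.
#' @param phase Carrier phase in radians (0 = even-symmetric cosine).
#' @param envelope_sigma Gaussian envelope sigma in degrees; default one
#'   wavelength.
#' @return An object of class `gabor_spec`.
#' @examples
#' gabor_spec(contrast = 0.09)
#' @export
gabor_spec <- function(contrast, spatial_frequency = 4, orientation = 0,
                       phase = 0, envelope_sigma = NULL) {
  if (!is.numeric(spatial_frequency) || spatial_frequency <= 0) {
    abort("`spatial_frequency` must be > 0 cycles per degree.")
  }
  if (!is.numeric(contrast) || contrast < 0 || contrast > 1) {
    abort("`contrast` must be a Michelson proportion in [0, 1].")
  }
  envelope_sigma <- envelope_sigma %||% (1 / spatial_frequency)
  if (envelope_sigma <= 0) abort("`envelope_sigma` must be > 0 degrees.")
  structure(
    list(contrast = contrast, spatial_frequency = spatial_frequency,
         orientation = orientation, phase = phase,
         envelope_sigma = envelope_sigma),
    class = "gabor_spec"
  )
}

#' @rdname gabor_spec
#' @param spec A `gabor_spec`.
#' @export
wavelength <- function(spec) {
  stopifnot(inherits(spec, "gabor_spec"))
  1 / spec$spatial_frequency
}

#' Display geometry and angular/pixel conversion
#'
#' @param arcmin_per_pixel Arcminutes subtended by one pixel (default 0.7).
#' @param mean_luminance Background level in normalized `[0, 1]` units
#'   (default 0.5, mid-grey).
#' @param image_size Square frame side in pixels. The default (687, odd so a
#'   pixel sits exactly at the frame centre) accommodates flankers out to 12
#'   wavelengths of a 4 cycles/degree carrier plus 4 envelope sigmas.
#' @return An object of class `display_geometry`.
#' @export
display_geometry <- function(arcmin_per_pixel = 0.7, mean_luminance = 0.5,
                             image_size = 687) {
  if (arcmin_per_pixel <= 0) abort("`arcmin_per_pixel` must be > 0.")
  if (mean_luminance <= 0 || mean_luminance >= 1) {
    abort("`mean_luminance` must lie strictly in (0, 1).")
  }
  if (image_size < 1 || image_size != round(image_size)) {
    abort("`image_size` must be a positive integer.")
  }
  structure(
    list(arcmin_per_pixel = arcmin_per_pixel,
         mean_luminance = mean_luminance,
         image_size = as.integer(image_size)),
    class = "display_geometry"
  )
}

#' Convert a visual angle to pixels
#'
#' `pixels = degrees * 60 / arcmin_per_pixel`, returned unrounded; rounding
#' (half away from zero) is applied only when placing stimulus centres on
#' the pixel grid.
#'
#' @param geom A [display_geometry()].
#' @param extent Visual angle in degrees (>= 0).
#' @return Pixel extent (possibly fractional).
#' @examples
#' deg_to_px(display_geometry(), 0.7 / 60)  # one pixel
#' @export
deg_to_px <- function(geom, extent) {
  stopifnot(inherits(geom, "display_geometry"))
  if (any(extent < 0)) abort("`extent` must be non-negative degrees.")
  extent * 60 / geom$arcmin_per_pixel
}

# round half away from zero (placement convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Degrees of visual angle for each pixel coordinate, centred on the frame.
pixel_grid_deg <- function(geom) {
  n <- geom$image_size
  ((seq_len(n)) - (n + 1) / 2) * geom$arcmin_per_pixel / 60
}

# Contrast-modulation field of one Gabor centred at (cx, cy) degrees.
# x runs along columns (horizontal), y along rows (vertical, downwards).
gabor_modulation <- function(spec, geom, cx = 0, cy = 0) {
  g <- pixel_grid_deg(geom)
  x <- matrix(g, geom$image_size, geom$image_size, byrow = TRUE) - cx
  y <- matrix(g, geom$image_size, geom$image_size) - cy
  th <- spec$orientation * pi / 180
  u <- x * cos(th) + y * sin(th)   # axis of luminance modulation
  spec$contrast *
    cos(2 * pi * spec$spatial_frequency * u + spec$phase) *
    exp(-(x^2 + y^2) / (2 * spec$envelope_sigma^2))
}

new_trial_frame <- function(modulation, geom, annotations) {
  lum <- geom$mean_luminance * (1 + modulation)
  if (any(lum < 0) || any(lum > 1)) {
    abort("Composed stimulus drives luminance outside [0, 1]; lower the contrasts.")
  }
  structure(list(luminance = lum, annotations = annotations, geom = geom),
            class = "trial_frame")
}

#' Render a single Gabor patch into a luminance frame
#'
#' Luminance is `mean * (1 + m)` with modulation `m = c * cos(2 pi f u +
#' phase) * exp(-(x^2 + y^2) / (2 sigma^2))`, `u` the coordinate along the
#' modulation axis. The background is exactly the mean luminance where the
#' envelope carries no energy.
#'
#' @param spec A [gabor_spec()].
#' @param geom A [display_geometry()].
#' @return A `trial_frame`: luminance matrix in `[0, 1]` plus component
#'   centre annotations.
#' @export
render_gabor <- function(spec, geom = display_geometry()) {
  stopifnot(inherits(spec, "gabor_spec"))
  new_trial_frame(
    gabor_modulation(spec, geom),
    geom,
    tibble::tibble(role = "target", x_deg = 0, y_deg = 0)
  )
}

#' Compose a lateral-masking trial frame
#'
#' Places the (optional) central target and two collinear flankers at
#' `+/- distance_lambda` carrier wavelengths vertically from the frame
#' centre. Overlapping fields add in contrast-modulation space and the
#' composite is checked against the displayable luminance range. An absent
#' target gives the blank interval of the 2AFC trial: flankers only, mean
#' luminance at the centre.
#'
#' @param target A [gabor_spec()] or `NULL` (target-absent interval).
#' @param flanker A [gabor_spec()] for the two flankers (default contrast
#'   0.6, the package's stand-in for "high contrast").
#' @param distance_lambda Centre-to-centre target-flanker distance in
#'   wavelengths of the flanker carrier (> 0).
#' @param geom A [display_geometry()]; must be large enough to contain the
#'   flanker centres.
#' @return A `trial_frame`.
#' @examples
#' frame <- compose_trial(gabor_spec(contrast = 0.09),
#'                        distance_lambda = 3)
#' @export
compose_trial <- function(target = NULL, flanker = gabor_spec(contrast = 0.6),
                          distance_lambda, geom = display_geometry()) {
  stopifnot(inherits(flanker, "gabor_spec"))
  if (distance_lambda <= 0) abort("`distance_lambda` must be > 0.")
  d_deg <- distance_lambda * wavelength(flanker)
  half_extent <- (geom$image_size - 1) / 2 * geom$arcmin_per_pixel / 60
  if (d_deg > half_extent) {
    need <- 2 * ceiling(d_deg * 60 / geom$arcmin_per_pixel) + 1
    abort(paste0("Flanker centre at ", signif(d_deg, 4), " deg falls outside ",
                 "the frame; use image_size >= ", need, " pixels."))
  }
  mod <- gabor_modulation(flanker, geom, cx = 0, cy = -d_deg) +
    gabor_modulation(flanker, geom, cx = 0, cy = d_deg)
  ann <- tibble::tibble(role = c("flanker", "flanker"),
                        x_deg = c(0, 0), y_deg = c(-d_deg, d_deg))
  if (!is.null(target)) {
    stopifnot(inherits(target, "gabor_spec"))
    mod <- mod + gabor_modulation(target, geom)
    ann <- dplyr::bind_rows(
      tibble::tibble(role = "target", x_deg = 0, y_deg = 0), ann)
  }
  new_trial_frame(mod, geom, ann)
}

#' Measured Michelson contrast of a rendered frame
#'
#' Recovers the carrier's Michelson contrast from the frame's peak luminance
#' excursion about the background: `max |L - Lmean| / Lmean`, which equals
#' `(Lmax - Lmin) / (Lmax + Lmin)` of the un-windowed carrier. (The raw frame
#' minimum is attenuated by the Gaussian envelope — the nearest carrier
#' trough sits half a wavelength from the peak — so a naive min/max ratio
#' over the frame systematically underestimates the nominal contrast for
#' narrow envelopes.)
#'
#' @param frame A `trial_frame`.
#' @return A proportion in `[0, 1]`.
#' @export
measured_contrast <- function(frame) {
  stopifnot(inherits(frame, "trial_frame"))
  m <- frame$geom$mean_luminance
  max(abs(frame$luminance - m)) / m
}

#' Export a frame as 8-bit grayscale PNG
#'
#' @param frame A `trial_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "trial_frame"))
  png::writePNG(frame$luminance, target = path, dpi = NULL)
  invisible(path)
}

#' @export
print.trial_frame <- function(x, ...) {
  cat("<trial_frame>", nrow(x$luminance), "x", ncol(x$luminance),
      "px, luminance range",
      paste(signif(range(x$luminance), 4), collapse = "-"), "\n")
  cat("  components:", paste(x$annotations$role, collapse = ", "), "\n")
  invisible(x)
}

frame_to_df <- function(frame, label = NULL) {
  g <- pixel_grid_deg(frame$geom)
  tibble::tibble(
    x_deg = rep(g, each = length(g)),
    y_deg = rep(-g, times = length(g)),   # screen y grows downwards
    luminance = as.vector(frame$luminance),
    condition = label %||% NA_character_
  )
}

#' @rdname render_gabor
#' @param object,x A `trial_frame`.
#' @param ... Unused.
#' @export
autoplot.trial_frame <- function(object, ...) {
  ggplot2::ggplot(frame_to_df(object),
                  ggplot2::aes(.data$x_deg, .data$y_deg,
                               fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "degrees", y = "degrees") +
    ggplot2::theme_minimal()
}

#' @rdname render_gabor
#' @export
plot.trial_frame <- function(x, ...) print(autoplot(x, ...))

#' Contact sheet of all conditions of a session design
#'
#' Renders the target-plus-flankers frame for every flanker distance of the
#' design (plus the baseline target-alone frame) and lays them out as a
#' faceted figure, for design validation and documentation.
#'
#' @param design A [session_design()].
#' @param target,flanker [gabor_spec()]s for the components; the target
#'   defaults to the design's maximum contrast level.
#' @param geom A [display_geometry()].
#' @return A ggplot object.
#' @export
plot_contact_sheet <- function(design = session_design(),
                               target = NULL,
                               flanker = gabor_spec(contrast = 0.6),
                               geom = display_geometry()) {
  stopifnot(inherits(design, "session_design"))
  target <- target %||% gabor_spec(contrast = max(design$contrast_levels))
  frames <- purrr::map(design$conditions, function(cond) {
    f <- if (cond == "baseline") {
      render_gabor(target, geom)
    } else {
      compose_trial(target, flanker, as.numeric(cond), geom)
    }
    lab <- if (cond == "baseline") "baseline" else paste0(cond, "λ")
    frame_to_df(f, label = lab)
  }) |> purrr::list_rbind()
  frames$condition <- factor(frames$condition, levels = unique(frames$condition))
  ggplot2::ggplot(frames, ggplot2::aes(.data$x_deg, .data$y_deg,
                                       fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "degrees", y = "degrees") +
    ggplot2::theme_minimal()
}
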
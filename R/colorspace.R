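# Color space conversions. YIQ is computed from gamma-encoded sRGB with the
# FCC/NTSC matrix (the standard YIQ definition); CIELAB goes through the
# IEC 61966-2-1 sRGB companding and the D65/2-degree white point.

# FCC/NTSC RGB -> YIQ matrix (rows: Y, I, Q)
YIQ_MATRIX <- rbind(
  Y = c(0.299,     0.587,     0.114),
  I = c(0.595716, -0.274453, -0.321263),
  Q = c(0.211456, -0.522591,  0.311135)
)

# sRGB (linear) -> XYZ, D65 white, 2-degree observer
SRGB_XYZ_MATRIX <- rbind(
  X = c(0.4124564, 0.3575761, 0.1804375),
  Y = c(0.2126729, 0.7151522, 0.0721750),
  Z = c(0.0193339, 0.1191920, 0.9503041)
)

# D65 reference white in XYZ, derived from the matrix itself (the image of
# sRGB white) so that the gray axis maps to exactly zero chroma
WHITE_D65 <- {
  w <- as.numeric(SRGB_XYZ_MATRIX %*% c(1, 1, 1))
  names(w) <- c("X", "Y", "Z")
  w
}

as_rgb_matrix <- function(rgb) {
  if (is.array(rgb) && length(dim(rgb)) == 3L) {
    d <- dim(rgb)
    list(m = matrix(rgb, ncol = 3L), dim = d)
  } else if (is.numeric(rgb) && length(rgb) == 3L) {
    list(m = matrix(rgb, ncol = 3L), dim = NULL)
  } else if (is.matrix(rgb) && ncol(rgb) == 3L) {
    list(m = rgb, dim = NULL)
  } else {
    abort_percsim("RGB input must be a 3-vector, n x 3 matrix or H x W x 3 array.",
                  "percsim_usage_error")
  }
}

check_unit_range <- function(m) {
  if (anyNA(m) || min(m) < -1e-12 || max(m) > 1 + 1e-12) {
    abort_percsim("RGB values must lie in [0, 1].", "percsim_domain_error")
  }
}

restore_shape <- function(m, shape) {
  if (is.null(shape$dim)) {
    if (nrow(m) == 1L) drop(m) else m
  } else {
    array(m, dim = shape$dim)
  }
}

#' Convert sRGB to YIQ
#'
#' Applies the FCC/NTSC linear transform per pixel to gamma-encoded sRGB
#' values. Y (luminance) stays in `[0, 1]`; I runs blue-orange in roughly
#' `[-0.596, 0.596]` and Q green-purple in roughly `[-0.523, 0.523]`.
#'
#' @param rgb a 3-vector, n x 3 matrix, or H x W x 3 array with values in
#'   `[0, 1]`.
#' @return YIQ values in the same shape as the input.
#' @export
#' @examples
#' rgb_to_yiq(c(1, 1, 1)) # c(1, 0, 0)
rgb_to_yiq <- function(rgb) {
  shape <- as_rgb_matrix(rgb)
  check_unit_range(shape$m)
  out <- shape$m %*% t(YIQ_MATRIX)
  colnames(out) <- c("Y", "I", "Q")
  restore_shape(out, shape)
}

# IEC 61966-2-1 inverse companding: gamma-encoded sRGB -> linear RGB
srgb_decompand <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

# CIE f(t) with the standard piecewise cube root
lab_f <- function(t) {
  eps <- (6 / 29)^3
  ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

#' Convert sRGB to CIELAB
#'
#' Full chain: sRGB gamma decoding (IEC 61966-2-1), linear RGB to XYZ, then
#' XYZ to L*a*b* under the D65 white point and 2-degree observer. L* spans
#' `[0, 100]`; a* runs green-red and b* blue-yellow.
#'
#' @inheritParams rgb_to_yiq
#' @return LAB values in the same shape as the input.
#' @export
#' @examples
#' rgb_to_lab(c(1, 1, 1)) # approximately c(100, 0, 0)
rgb_to_lab <- function(rgb) {
  shape <- as_rgb_matrix(rgb)
  check_unit_range(shape$m)
  xyz <- srgb_decompand(shape$m) %*% t(SRGB_XYZ_MATRIX)
  fx <- lab_f(xyz[, 1] / WHITE_D65["X"])
  fy <- lab_f(xyz[, 2] / WHITE_D65["Y"])
  fz <- lab_f(xyz[, 3] / WHITE_D65["Z"])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  restore_shape(out, shape)
}

#' Mean color vector of a patch
#'
#' Converts every pixel of the patch to the requested color space, then
#' averages per channel (convert-then-average: for the nonlinear CIELAB
#' transform this weights perceptual coordinates uniformly, unlike
#' averaging in RGB first).
#'
#' @param patch an [image_patch()] or an H x W x 3 array in `[0, 1]`.
#' @param space `"RGB"`, `"YIQ"` or `"LAB"`.
#' @param order `"convert_first"` (default) or `"average_first"`; the
#'   latter averages the RGB pixels and converts the single mean vector,
#'   exposed for sensitivity analysis.
#' @return a named 3-vector of class `"color_vector"` with the space in an
#'   attribute.
#' @export
mean_color <- function(patch, space = c("RGB", "YIQ", "LAB"),
                       order = c("convert_first", "average_first")) {
  space <- match.arg(space)
  order <- match.arg(order)
  px <- if (inherits(patch, "image_patch")) patch$pixels else patch
  m <- matrix(px, ncol = 3L)
  v <- if (order == "convert_first") {
    conv <- switch(space, RGB = m, YIQ = rgb_to_yiq(m), LAB = rgb_to_lab(m))
    colMeans(conv)
  } else {
    mu <- colMeans(m)
    switch(space, RGB = mu, YIQ = rgb_to_yiq(mu), LAB = rgb_to_lab(mu))
  }
  color_vector(v, space)
}

#' @rdname mean_color
#' @param components numeric 3-vector of color coordinates.
#' @export
color_vector <- function(components, space = c("RGB", "YIQ", "LAB")) {
  space <- match.arg(space)
  components <- as.numeric(components)
  if (length(components) != 3L || anyNA(components)) {
    abort_percsim("a color vector has exactly 3 finite components.",
                  "percsim_usage_error")
  }
  names(components) <- switch(space,
    RGB = c("R", "G", "B"), YIQ = c("Y", "I", "Q"), LAB = c("L", "a", "b"))
  structure(components, class = "color_vector", space = space)
}

color_space <- function(cv) attr(cv, "space", exact = TRUE)
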
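# Mean Delta-E (MDE): perceptual error between two LAT maps. LAT values are
# mapped to viridis colors over a fixed [s_min, s_max] scale, converted to
# CIELAB, and compared with the CIEDE2000 color-difference formula; the mean
# over points is the map error a clinician would perceive. NMSE on the raw
# values is provided as a conventional secondary metric.

#' Map LAT values to viridis colors
#'
#' Linear mapping of each value to a position on the 256-entry viridis table
#' over `range = c(s_min, s_max)`, with linear interpolation between adjacent
#' table entries. Out-of-range values are clamped to the endpoints, which is
#' what makes a restricted color range assign zero error where both compared
#' maps saturate on the same side.
#'
#' @param values numeric LAT values (ms).
#' @param range length-2 numeric, `c(s_min, s_max)` with `s_min < s_max`.
#' @return m x 3 matrix of sRGB components in `[0, 1]`.
#' @export
lat_to_color <- function(values, range) {
  if (length(range) != 2L || !(range[1] < range[2])) {
    stop("range must be c(s_min, s_max) with s_min < s_max")
  }
  t <- (values - range[1]) / (range[2] - range[1])
  t <- pmin(pmax(t, 0), 1)
  x <- t * 255
  i0 <- pmin(floor(x), 254)
  frac <- x - i0
  lo <- .viridis256[i0 + 1L, , drop = FALSE]
  hi <- .viridis256[i0 + 2L, , drop = FALSE]
  col <- lo * (1 - frac) + hi * frac
  dimnames(col) <- list(NULL, c("r", "g", "b"))
  col
}

#' Convert sRGB colors to CIELAB
#'
#' Standard pipeline: sRGB transfer function inverted to linear RGB, linear
#' transform to XYZ (D65 white), then CIELAB.
#'
#' @param rgb m x 3 matrix of sRGB components in `[0, 1]`.
#' @return m x 3 matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- matrix(as.numeric(rgb), ncol = 3L)
  if (any(rgb < -1e-9 | rgb > 1 + 1e-9)) {
    stop("sRGB components must lie in [0, 1]")
  }
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3L, 3L, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1, 1.08883)   # D65
  xyz <- sweep(xyz, 2L, white, "/")
  eps <- (6 / 29)^3
  fxyz <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(L = 116 * fxyz[, 2] - 16,
               a = 500 * (fxyz[, 1] - fxyz[, 2]),
               b = 200 * (fxyz[, 2] - fxyz[, 3]))
  lab
}

#' CIEDE2000 color difference
#'
#' The standard Delta-E 2000 formula with lightness/chroma/hue compensation
#' terms and the blue-region hue rotation; vectorised over rows.
#'
#' @param lab1,lab2 m x 3 matrices (or length-3 vectors) of CIELAB colors.
#' @param kL,kC,kH positive weighting factors (defaults 1, the recommended
#'   values).
#' @return Numeric vector of non-negative differences.
#' @export
ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  if (any(c(kL, kC, kH) <= 0)) stop("kL, kC, kH must be positive")
  lab1 <- matrix(as.numeric(lab1), ncol = 3L)
  lab2 <- matrix(as.numeric(lab2), ncol = 3L)
  if (nrow(lab1) != nrow(lab2)) stop("lab1 and lab2 must have equal rows")
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- (atan2(b1, a1p) * 180 / pi) %% 360
  h2p <- (atan2(b2, a2p) * 180 / pi) %% 360
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
                ifelse(abs(dh) <= 180, dh, dh - sign(dh) * 360))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
                ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                       ifelse(hsum < 360, hsum / 2 + 180, hsum / 2 - 180)))
  rad <- pi / 180
  T_ <- 1 - 0.17 * cos((hbp - 30) * rad) + 0.24 * cos(2 * hbp * rad) +
    0.32 * cos((3 * hbp + 6) * rad) - 0.20 * cos((4 * hbp - 63) * rad)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * dtheta * rad) * RC
  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

#' Mean Delta-E between two LAT maps
#'
#' Perceptual map error: each pair of values is rendered through the viridis
#' colormap over the fixed `range`, converted to CIELAB, and compared with
#' [ciede2000()]; the mean over points is returned. Narrowing `range`
#' focuses the metric on a LAT window of interest: points where both maps
#' saturate on the same side contribute exactly zero.
#'
#' @param estimates,truth numeric vectors of equal length (ms).
#' @param range colormap range `c(s_min, s_max)`.
#' @param kL,kC,kH CIEDE2000 weighting factors (default 1).
#' @return Non-negative scalar MDE.
#' @export
mde <- function(estimates, truth, range, kL = 1, kC = 1, kH = 1) {
  if (length(estimates) != length(truth)) {
    stop("estimates and truth must have equal length")
  }
  if (!length(truth)) stop("cannot average over an empty map")
  mean(ciede2000(srgb_to_lab(lat_to_color(estimates, range)),
                 srgb_to_lab(lat_to_color(truth, range)),
                 kL = kL, kC = kC, kH = kH))
}

#' Normalised mean squared error
#'
#' `sum((est - truth)^2) / sum((truth - mean(truth))^2)`: residual sum of
#' squares over the centred total sum of squares, so predicting the mean of
#' the truth everywhere scores exactly 1.
#'
#' @param estimates,truth numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
nmse <- function(estimates, truth) {
  if (length(estimates) != length(truth)) {
    stop("estimates and truth must have equal length")
  }
  denom <- sum((truth - mean(truth))^2)
  if (denom == 0) stop("zero-variance ground truth")
  sum((estimates - truth)^2) / denom
}
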
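# Ten-property particle morphology, computed on a single segmented particle.
#
# Conventions (fixed so that every documented fixed point is exact):
#  * grayscale = unweighted mean of the R, G, B planes;
#  * perimeter = crack boundary: number of exposed unit pixel edges, outer
#    contour plus every hole contour;
#  * convex perimeter = perimeter of the convex hull of the pixel *corner*
#    points, so roughness = perimeter / convex perimeter is exactly 1 for a
#    filled axis-aligned rectangle and >= 1 always;
#  * Length = maximum of 36 Feret (caliper) measurements of the corner point
#    set, at 0, 5, ..., 175 degrees;
#  * sigma intensity uses the population (n) denominator;
#  * Sobel edge gradient = mean un-normalised 3x3 Sobel magnitude over the
#    one-pixel outside border of the mask, clamped to [0, 255].

.grayscale <- function(pixels) {
  (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
}

# shift a matrix by (dr, dc), padding with `fill`
.shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.dilate8 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out | .shiftMat(mask, dr, dc)
  out
}

#' Construct a ParticleImage
#'
#' @param pixels numeric `h x w x 3` array with values in \[0, 255\], or an
#'   `h x w` grayscale matrix (replicated over the three channels).
#' @param pixelSizeUm micrometres per pixel (default 0.554, a 10x objective).
#' @return A [ParticleImage-class].
#' @examples
#' img <- ParticleImage(array(230, c(32, 32, 3)))
#' @export
ParticleImage <- function(pixels, pixelSizeUm = 0.554) {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  new("ParticleImage", pixels = pixels, pixelSizeUm = pixelSizeUm)
}

#' Segment the particle in a brightfield frame
#'
#' Foreground is every pixel with grayscale (mean of R, G, B) strictly below
#' `threshold` (dark object on a bright background). The largest 8-connected
#' component is kept; interior holes are preserved, not filled, so that the
#' perimeter and roughness properties can include hole edges.
#'
#' @param image a [ParticleImage-class].
#' @param threshold grayscale level; default 200 of 255.
#' @return A [ParticleMask-class] with `areaPx` and `holeCount` filled in.
#' @examples
#' px <- matrix(230, 40, 40); px[10:30, 10:30] <- 90
#' mask <- segmentParticle(ParticleImage(px))
#' mask@areaPx
#' @export
segmentParticle <- function(image, threshold = 200) {
  stopifnot(is(image, "ParticleImage"))
  fg <- .grayscale(image@pixels) < threshold
  if (!any(fg))
    stop("no particle: no pixel below threshold ", threshold)
  lab <- cg_label(fg, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  new("ParticleMask", mask = mask, areaPx = sum(mask),
      holeCount = .countHoles(mask))
}

# interior background components: 4-connected background regions that do not
# touch the frame border (complementary connectivity to the 8-connected mask)
.countHoles <- function(mask) {
  bg <- !mask
  lab <- cg_label(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  interior <- setdiff(unique(lab[lab > 0L]), border)
  length(interior)
}

#' Grayscale and colour statistics over the particle
#'
#' Intensity is the mean particle grayscale (grayscale sum over the number of
#' particle pixels); sigma intensity is the population standard deviation of
#' the particle's grayscale values; average blue is the mean of the blue
#' plane over the mask; the two ratios divide the mean red plane by the mean
#' blue (resp. green) plane.
#'
#' @param image a [ParticleImage-class].
#' @param mask a [ParticleMask-class].
#' @return Named list: `intensity`, `sigmaIntensity`, `averageBlue`,
#'   `ratioRedBlue`, `ratioRedGreen`.
#' @export
intensityStats <- function(image, mask) {
  m <- mask@mask
  r <- image@pixels[, , 1][m]
  g <- image@pixels[, , 2][m]
  b <- image@pixels[, , 3][m]
  gray <- (r + g + b) / 3
  mb <- mean(b); mg <- mean(g)
  if (mb == 0 || mg == 0)
    stop("undefined ratio: average ", if (mb == 0) "blue" else "green",
         " is zero over the particle")
  list(intensity = mean(gray),
       sigmaIntensity = sqrt(mean((gray - mean(gray))^2)),
       averageBlue = mb,
       ratioRedBlue = mean(r) / mb,
       ratioRedGreen = mean(r) / mg)
}

#' Area-based diameter
#'
#' Diameter of the circle whose area equals the particle's pixel area:
#' `2 * sqrt(areaPx / pi) * pixelSizeUm`.
#'
#' @param mask a [ParticleMask-class] (or a bare logical matrix).
#' @param pixelSizeUm micrometres per pixel.
#' @return ABD diameter in micrometres.
#' @export
abdDiameter <- function(mask, pixelSizeUm) {
  area <- if (is(mask, "ParticleMask")) mask@areaPx else sum(mask)
  stopifnot(area >= 1)
  2 * sqrt(area / pi) * pixelSizeUm
}

# corner points (x = col +- 0.5, y = row +- 0.5) of the mask's boundary
# pixels; interior pixels cannot contribute hull vertices
.maskCorners <- function(m) {
  interior <- .shiftMat(m, 1, 0) & .shiftMat(m, -1, 0) &
    .shiftMat(m, 0, 1) & .shiftMat(m, 0, -1) & m
  idx <- which(m & !interior, arr.ind = TRUE)
  if (!nrow(idx)) idx <- which(m, arr.ind = TRUE)
  x <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5)
  y <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5)
  cbind(x = x, y = y)
}

.hullPoints <- function(m) {
  pts <- .maskCorners(m)
  pts[grDevices::chull(pts), , drop = FALSE]
}

#' Feret length over 36 directions
#'
#' Caliper (Feret) extent of the mask's pixel-corner point set, measured at
#' 36 orientations evenly spaced over a half turn (0 to 175 degrees in steps
#' of 5); returns the maximum, scaled to micrometres.
#'
#' @param mask a [ParticleMask-class] or logical matrix.
#' @param pixelSizeUm micrometres per pixel.
#' @return Length in micrometres.
#' @export
feretLength <- function(mask, pixelSizeUm) {
  m <- if (is(mask, "ParticleMask")) mask@mask else mask
  hull <- .hullPoints(m)
  theta <- seq(0, 175, by = 5) * pi / 180
  ext <- vapply(theta, function(a) {
    p <- hull[, 1] * cos(a) + hull[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  max(ext) * pixelSizeUm
}

# total crack-boundary length in pixel units: one unit per exposed pixel edge
.crackPerimeterPx <- function(m) {
  sum(m & !.shiftMat(m, 1, 0)) + sum(m & !.shiftMat(m, -1, 0)) +
    sum(m & !.shiftMat(m, 0, 1)) + sum(m & !.shiftMat(m, 0, -1))
}

#' Perimeter and roughness
#'
#' Perimeter is the total crack-boundary length: the number of exposed unit
#' pixel edges on the outer contour plus the edges of every interior hole,
#' scaled to micrometres. Roughness is the ratio of this perimeter to the
#' perimeter of the convex hull of the mask's pixel-corner points; it is
#' exactly 1 for a filled convex (axis-aligned rectangular) mask and > 1 for
#' non-convex outlines or masks with holes.
#'
#' @param mask a [ParticleMask-class] or logical matrix.
#' @param pixelSizeUm micrometres per pixel.
#' @return Named list: `perimeter` (um), `roughness` (dimensionless, >= 1).
#' @export
perimeterRoughness <- function(mask, pixelSizeUm) {
  m <- if (is(mask, "ParticleMask")) mask@mask else mask
  crack <- .crackPerimeterPx(m)
  hull <- .hullPoints(m)
  h <- rbind(hull, hull[1, , drop = FALSE])
  convex <- sum(sqrt(diff(h[, 1])^2 + diff(h[, 2])^2))
  list(perimeter = crack * pixelSizeUm, roughness = crack / convex)
}

#' Mean Sobel magnitude over the particle's outside border
#'
#' Applies the 3x3 Sobel operator to the grayscale image and averages the
#' gradient magnitude `sqrt(gx^2 + gy^2)`, clamped per pixel to \[0, 255\]
#' (8-bit convolution output), over the one-pixel outside border of the mask
#' (its 8-connected dilation minus the mask). An ideal vertical step of
#' height `h` therefore yields a border response of `4 h` (up to the 255
#' clamp). If the mask touches the frame edge the border is truncated to the
#' available pixels, with a warning.
#'
#' @param image a [ParticleImage-class].
#' @param mask a [ParticleMask-class].
#' @return Edge gradient in \[0, 255\].
#' @export
edgeGradient <- function(image, mask) {
  m <- mask@mask
  gray <- .grayscale(image@pixels)
  border <- .dilate8(m) & !m
  # Sobel is undefined on the one-pixel frame ring; drop those border pixels
  ring <- matrix(FALSE, nrow(m), ncol(m))
  ring[c(1, nrow(m)), ] <- TRUE; ring[, c(1, ncol(m))] <- TRUE
  if (any(m & ring))
    warning("mask touches the frame edge; border truncated")
  border <- border & !ring
  if (!any(border)) {
    warning("no valid border pixels inside the frame")
    return(0)
  }
  gx <- (.shiftMat(gray, -1, -1, 0) + 2 * .shiftMat(gray, 0, -1, 0) +
         .shiftMat(gray, 1, -1, 0)) -
        (.shiftMat(gray, -1, 1, 0) + 2 * .shiftMat(gray, 0, 1, 0) +
         .shiftMat(gray, 1, 1, 0))
  gy <- (.shiftMat(gray, -1, -1, 0) + 2 * .shiftMat(gray, -1, 0, 0) +
         .shiftMat(gray, -1, 1, 0)) -
        (.shiftMat(gray, 1, -1, 0) + 2 * .shiftMat(gray, 1, 0, 0) +
         .shiftMat(gray, 1, 1, 0))
  # 8-bit convolution output: clamp per pixel, then average over the border
  mag <- pmin(sqrt(gx^2 + gy^2), 255)
  mean(mag[border])
}

#' Extract the ten particle properties from one frame
#'
#' Segments the frame at `threshold` and computes all ten canonical
#' properties on the same mask. Sizes are in micrometres, signal properties
#' in 8-bit levels.
#'
#' @param image a [ParticleImage-class].
#' @param threshold segmentation grayscale threshold (default 200).
#' @return Named numeric vector over [cgFeatureNames()].
#' @examples
#' px <- matrix(230, 40, 40); px[10:30, 10:30] <- 90
#' extractFeatures(ParticleImage(px))
#' @export
extractFeatures <- function(image, threshold = 200) {
  mask <- segmentParticle(image, threshold)
  px <- image@pixelSizeUm
  st <- intensityStats(image, mask)
  pr <- perimeterRoughness(mask, px)
  out <- c(averageBlue = st$averageBlue,
           diameterABD = abdDiameter(mask, px),
           edgeGradient = edgeGradient(image, mask),
           intensity = st$intensity,
           length = feretLength(mask, px),
           perimeter = pr$perimeter,
           ratioRedBlue = st$ratioRedBlue,
           ratioRedGreen = st$ratioRedGreen,
           roughness = pr$roughness,
           sigmaIntensity = st$sigmaIntensity)
  out[cgFeatureNames()]
}
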
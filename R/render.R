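# Synthetic brightfield particle renderer.
#
# A colony is a union of jittered filled disks (one per cell) chained along a
# randomly oriented elliptical envelope, with optional interior holes carved
# inside cells (drives roughness) and an optional semi-transparent halo ramp
# around the colony (drives the Sobel edge gradient). The background is a
# fixed bright level with mild Gaussian pixel noise, so the default global
# dark-object threshold segments the particle trivially.

.BG_LEVEL <- 230
.BG_NOISE_SD <- 3

# uniform draw from a latent range, widened about its midpoint by overlapScale
.drawLatent <- function(rng, overlapScale = 0) {
  mid <- mean(rng)
  u <- stats::runif(1, rng[1], rng[2])
  mid + (u - mid) * (1 + overlapScale)
}

# RGB triple with grayscale g and channel-mean ratios red/blue, red/green
.colorFromTargets <- function(g, rb, rg) {
  r <- 3 * g / (1 + 1 / rb + 1 / rg)
  c(r, r / rg, r / rb)
}

.paintDisk <- function(mask, cx, cy, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  mask[rows, cols] <- mask[rows, cols] | (d2 <= r^2)
  mask
}

# cells are drawn slightly larger than their placement spacing (a mucilage
# envelope), which closes most curvilinear pores between touching cells
.DRAW_FACTOR <- 1.3

# chain cells inside a rotated ellipse until the union reaches targetAreaPx
.placeColony <- function(side, targetAreaPx, aPx, bPx, rCellPx, maxCells) {
  cx0 <- side / 2; cy0 <- side / 2
  theta <- stats::runif(1, 0, pi)
  ct <- cos(theta); st <- sin(theta)
  inEllipse <- function(x, y) {
    u <- (x - cx0) * ct + (y - cy0) * st
    v <- -(x - cx0) * st + (y - cy0) * ct
    (u / aPx)^2 + (v / bPx)^2 <= 1
  }
  mask <- matrix(FALSE, side, side)
  rDraw <- .DRAW_FACTOR * rCellPx
  # spine along the major axis guarantees the full caliper extent
  sx <- seq(-(aPx - rCellPx), aPx - rCellPx, by = 1.05 * rCellPx)
  centers <- cbind(cx0 + sx * ct - stats::rnorm(length(sx), 0, 0.3 * rCellPx) * st,
                   cy0 + sx * st + stats::rnorm(length(sx), 0, 0.3 * rCellPx) * ct)
  for (i in seq_len(nrow(centers)))
    mask <- .paintDisk(mask, centers[i, 1], centers[i, 2], rDraw)
  area <- sum(mask)
  attempts <- 0L
  maxAttempts <- 40L * maxCells
  minGain <- 0.08 * pi * rDraw^2
  while (area < targetAreaPx && nrow(centers) < maxCells &&
         attempts < maxAttempts) {
    attempts <- attempts + 1L
    j <- sample.int(nrow(centers), 1)
    ang <- stats::runif(1, 0, 2 * pi)
    d <- stats::runif(1, 0.7, 1.1) * rCellPx
    x <- centers[j, 1] + d * cos(ang); y <- centers[j, 2] + d * sin(ang)
    if (!inEllipse(x, y)) next
    r0 <- max(1L, floor(y - rDraw)); r1 <- min(side, ceiling(y + rDraw))
    c0 <- max(1L, floor(x - rDraw)); c1 <- min(side, ceiling(x + rDraw))
    rows <- r0:r1; cols <- c0:c1
    disk <- outer((rows - y)^2, (cols - x)^2, "+") <= rDraw^2
    sub <- mask[rows, cols]
    gain <- sum(disk & !sub)
    if (gain < minGain) next      # interior candidate: adds no new area
    centers <- rbind(centers, c(x, y))
    mask[rows, cols] <- sub | disk
    area <- area + gain
  }
  list(mask = mask, centers = centers)
}

.carveHoles <- function(mask, centers, rCellPx, holeFraction) {
  if (holeFraction <= 0 || nrow(centers) == 0L) return(mask)
  nHoles <- stats::rbinom(1, nrow(centers), holeFraction)
  if (nHoles == 0L) return(mask)
  pick <- sample.int(nrow(centers), nHoles, replace = TRUE)
  for (j in pick) {
    hr <- stats::runif(1, 0.35, 0.5) * rCellPx
    off <- stats::runif(1, 0, 0.25 * rCellPx)
    ang <- stats::runif(1, 0, 2 * pi)
    hx <- centers[j, 1] + off * cos(ang); hy <- centers[j, 2] + off * sin(ang)
    nr <- nrow(mask)
    r0 <- max(1L, floor(hy - hr)); r1 <- min(nr, ceiling(hy + hr))
    c0 <- max(1L, floor(hx - hr)); c1 <- min(ncol(mask), ceiling(hx + hr))
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - hy)^2, (cols - hx)^2, "+")
    mask[rows, cols] <- mask[rows, cols] & !(d2 <= hr^2)
  }
  mask
}

# exterior background: the 4-connected background region(s) touching the
# frame border; interior holes are excluded
.exteriorBackground <- function(mask) {
  lab <- cg_label(!mask, 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  borderIds <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  matrix(lab %in% setdiff(borderIds, 0L), nr, nc)
}

# Chebyshev distance (1..w) from the mask over the exterior background only:
# interior holes keep the plain background level so they survive thresholding
.exteriorRamp <- function(mask, exterior, w) {
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  frontier <- mask
  for (k in seq_len(w)) {
    frontier <- .dilate8(frontier)
    newpix <- frontier & exterior & is.na(d)
    d[newpix] <- k
  }
  d
}

# depth 1..dIn inward from the *exterior* boundary only (hole edges keep the
# core shading, so holes stay sharp while the outline is halo-softened)
.interiorDepth <- function(mask, exterior, dIn) {
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  frontier <- exterior
  remaining <- mask
  for (k in seq_len(dIn)) {
    frontier <- .dilate8(frontier) & remaining
    d[frontier] <- k
    remaining <- remaining & !frontier
    if (!any(frontier)) break
  }
  d
}

#' Render one synthetic particle
#'
#' Draws the particle's latent signal and size targets from the profile's
#' latent ranges (widened by `overlapScale`), chains cell disks inside an
#' elliptical colony envelope until the target projected area is reached,
#' carves interior holes, applies the halo ramp, and composes the 8-bit RGB
#' frame over a noisy bright background. Uses the current RNG state; seed the
#' generator (or pass `seed`) for reproducibility.
#'
#' @param profile a [MorphProfile-class].
#' @param pixelSizeUm micrometres per pixel.
#' @param imageSidePx frame side in pixels.
#' @param overlapScale within-class variance inflation (0 = baseline).
#' @param seed optional integer; when given, seeds the RNG first.
#' @return List with elements `image` (a [ParticleImage-class]) and
#'   `classLabel`.
#' @examples
#' p <- defaultProfiles()[["Cryptomonas"]]
#' frame <- renderParticle(p, imageSidePx = 64, seed = 1)
#' @export
renderParticle <- function(profile, pixelSizeUm = 0.554, imageSidePx = 300,
                           overlapScale = 0, seed = NULL) {
  stopifnot(is(profile, "MorphProfile"))
  if (!is.null(seed)) set.seed(seed)
  lat <- profile@latent
  ov <- overlapScale
  g <- .drawLatent(lat$intensity, ov)
  rb <- .drawLatent(lat$ratioRedBlue, ov)
  rg <- .drawLatent(lat$ratioRedGreen, ov)
  sigma <- max(0, .drawLatent(lat$sigmaIntensity, ov))
  abd <- .drawLatent(lat$diameterABD, ov)
  side <- imageSidePx
  rCellPx <- stats::runif(1, profile@cellRadiusUm[1],
                          profile@cellRadiusUm[2]) / pixelSizeUm
  targetAreaPx <- pi * (abd / 2 / pixelSizeUm)^2
  single <- profile@nCells[2] <= 1
  if (single) {
    aPx <- bPx <- abd / 2 / pixelSizeUm
  } else {
    hasLen <- !is.null(lat$length) && !is.null(profile@envelope$length)
    extentUm <- if (hasLen) .drawLatent(lat$length, ov)
                else abd * stats::runif(1, 1.1, 1.3)
    aPx <- extentUm / 2 / pixelSizeUm - rCellPx
    # the ellipse must hold the target area at a packing fraction ~0.5
    aPx <- max(aPx, sqrt(targetAreaPx / (pi * 0.52)))
    bPx <- max(1.5 * rCellPx, targetAreaPx / (0.52 * pi * aPx))
    if (bPx > aPx) bPx <- aPx
  }
  w <- round(profile@haloStrength)
  if (aPx + rCellPx + w + 3 > side / 2)
    stop("particle exceeds frame: enlarge imageSidePx (need > ",
         ceiling(2 * (aPx + rCellPx + w + 3)), " px)")
  if (single) {
    mask <- .paintDisk(matrix(FALSE, side, side), side / 2, side / 2, aPx)
    centers <- matrix(c(side / 2, side / 2), 1)
  } else {
    col <- .placeColony(side, targetAreaPx, aPx, bPx, rCellPx,
                        maxCells = 2000L)
    mask <- col$mask; centers <- col$centers
  }
  mask <- .carveHoles(mask, centers, rCellPx, profile@holeFraction)
  color <- .colorFromTargets(g, rb, rg)
  noiseBg <- matrix(stats::rnorm(side * side, 0, .BG_NOISE_SD), side, side)
  noiseFg <- matrix(stats::rnorm(side * side, 0, sigma), side, side)
  px <- array(0, c(side, side, 3))
  # semi-transparent halo: a bright exterior ramp (kept just above the
  # default segmentation threshold, so the mask itself is unchanged) plus an
  # interior rim that brightens the outermost particle rings achromatically
  # toward the threshold; the rim is what softens the Sobel border response
  exterior <- if (w > 0) .exteriorBackground(mask) else NULL
  rampOut <- if (w > 0) .exteriorRamp(mask, exterior, w) else NULL
  dIn <- if (w > 0) min(3L, w) else 0L
  rimIn <- if (dIn > 0) .interiorDepth(mask, exterior, dIn) else NULL
  rimTop <- 192
  for (ch in 1:3) {
    plane <- .BG_LEVEL + noiseBg
    if (!is.null(rampOut)) {
      rampPix <- !is.na(rampOut)
      plane[rampPix] <- 200 + (.BG_LEVEL - 200) * rampOut[rampPix] / (w + 1) +
        noiseBg[rampPix]
    }
    plane[mask] <- color[ch] + noiseFg[mask]
    if (!is.null(rimIn)) {
      rimPix <- !is.na(rimIn)
      # gray level rises to rimTop at the boundary ring and falls back to
      # the core level at depth dIn + 1
      lift <- (rimTop - g) * (dIn + 1 - rimIn[rimPix]) / dIn
      plane[rimPix] <- color[ch] + pmax(lift, 0) + noiseFg[rimPix]
    }
    plane[mask] <- pmin(pmax(plane[mask], 3), 197)
    px[, , ch] <- pmin(pmax(plane, 0), 255)
  }
  px <- round(px)
  list(image = ParticleImage(px, pixelSizeUm), classLabel = profile@classLabel)
}
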
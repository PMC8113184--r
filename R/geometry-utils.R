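# Low-level 2D polygon primitives shared by the morphometry engine and the
# phantom generator. Contours are two-column matrices of (x, y) in nm; they
# are stored unclosed (first vertex not repeated) and treated as closed.

.asContour <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop("contour must have two columns (x, y)")
  storage.mode(m) <- "double"
  # drop an explicit closing vertex
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

.polyAreaSigned <- function(xy) {
  # pracma::polyarea returns the signed shoelace area for open contours
  pracma::polyarea(xy[, 1L], xy[, 2L])
}

.polyArea <- function(xy) abs(.polyAreaSigned(xy))

.polyCentroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

.pointsInPolygon <- function(pts, contour) {
  pts <- matrix(pts, ncol = 2L)
  as.logical(pracma::inpolygon(pts[, 1L], pts[, 2L],
                               contour[, 1L], contour[, 2L],
                               boundary = TRUE))
}

# Parameters t > 0 at which the ray origin + t*dir crosses the closed
# contour, sorted ascending. An edge is crossed iff its endpoints straddle
# the ray's supporting line under a half-open sign rule (s >= 0 counts as
# the positive side), which counts a crossing through a shared vertex
# exactly once and a tangent vertex touch exactly twice — parity is always
# preserved.
.rayCrossings <- function(origin, dir, contour) {
  p <- contour
  q <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  wpx <- p[, 1L] - origin[1L]; wpy <- p[, 2L] - origin[2L]
  wqx <- q[, 1L] - origin[1L]; wqy <- q[, 2L] - origin[2L]
  sp <- dir[1L] * wpy - dir[2L] * wpx   # cross(dir, vertex - origin)
  sq <- dir[1L] * wqy - dir[2L] * wqx
  cross <- (sp < 0) != (sq < 0)
  if (!any(cross)) return(numeric())
  ex <- wqx - wpx; ey <- wqy - wpy
  denom <- (dir[1L] * ey - dir[2L] * ex)[cross]
  t <- (wpx[cross] * ey[cross] - wpy[cross] * ex[cross]) / denom
  sort(t[t > 0])
}

# Total length of the ray (origin + t*dir, t in [0, tmax]) lying inside the
# region bounded by the closed contour, by crossing parity.
.rayInsideLength <- function(origin, dir, contour, tmax = Inf,
                             insideAtOrigin = NULL) {
  ts <- .rayCrossings(origin, dir, contour)
  inside <- if (is.null(insideAtOrigin))
    .pointsInPolygon(origin, contour) else insideAtOrigin
  bounds <- c(0, ts, tmax)
  # membership alternates starting at `inside` on [0, t1)
  seg <- diff(bounds)
  state <- rep(c(inside, !inside), length.out = length(seg))
  sum(seg[state])
}

# Minimal distance from each point (rows of pts) to the closed contour.
.distToContour <- function(pts, contour) {
  p <- contour
  q <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  ex <- q[, 1L] - p[, 1L]; ey <- q[, 2L] - p[, 2L]
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  apply(matrix(pts, ncol = 2L), 1L, function(pt) {
    tt <- ((pt[1L] - p[, 1L]) * ex + (pt[2L] - p[, 2L]) * ey) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dx <- p[, 1L] + tt * ex - pt[1L]
    dy <- p[, 2L] + tt * ey - pt[2L]
    sqrt(min(dx^2 + dy^2))
  })
}

# Interior point of a (possibly non-star-shaped) polygon maximising the
# clearance to the boundary: coarse grid search with one refinement pass.
# Fallback ray origin when the area centroid falls outside the lumen.
.poleOfInaccessibility <- function(contour, n = 24L) {
  bb <- apply(contour, 2L, range)
  best <- NULL; bestd <- -Inf
  span <- c(bb[2L, 1L] - bb[1L, 1L], bb[2L, 2L] - bb[1L, 2L])
  center <- colMeans(bb)
  for (pass in 1:2) {
    xs <- seq(center[1L] - span[1L] / 2, center[1L] + span[1L] / 2, length.out = n)
    ys <- seq(center[2L] - span[2L] / 2, center[2L] + span[2L] / 2, length.out = n)
    g <- as.matrix(expand.grid(xs, ys))
    keep <- .pointsInPolygon(g, contour)
    if (any(keep)) {
      g <- g[keep, , drop = FALSE]
      d <- .distToContour(g, contour)
      if (max(d) > bestd) { bestd <- max(d); best <- g[which.max(d), ] }
    }
    # refine around the current best
    center <- if (is.null(best)) center else best
    span <- span / (n / 3)
  }
  if (is.null(best)) stop("could not find an interior point of the contour")
  best
}

# Union length of angular intervals on the circle [0, 2*pi).
.angularUnion <- function(intervals) {
  if (!length(intervals)) return(0)
  segs <- list()
  for (iv in intervals) {
    a <- iv[1L] %% (2 * pi); w <- min(iv[2L] - iv[1L], 2 * pi)
    if (w >= 2 * pi - 1e-12) return(2 * pi)
    b <- a + w
    if (b <= 2 * pi) segs[[length(segs) + 1L]] <- c(a, b)
    else {
      segs[[length(segs) + 1L]] <- c(a, 2 * pi)
      segs[[length(segs) + 1L]] <- c(0, b - 2 * pi)
    }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1L]), , drop = FALSE]
  tot <- 0; curA <- m[1L, 1L]; curB <- m[1L, 2L]
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    if (m[i, 1L] <= curB) curB <- max(curB, m[i, 2L])
    else { tot <- tot + curB - curA; curA <- m[i, 1L]; curB <- m[i, 2L] }
  }
  tot + curB - curA
}

# Angular interval subtended by a polygon's vertices as seen from `center`,
# robust to wrap-around: the occupied arc is the complement of the largest
# angular gap between consecutive sorted vertex angles.
.angularSpan <- function(coords, center) {
  ang <- sort(atan2(coords[, 2L] - center[2L], coords[, 1L] - center[1L]) %% (2 * pi))
  if (length(ang) < 2L) return(c(ang[1L], ang[1L]))
  gaps <- diff(c(ang, ang[1L] + 2 * pi))
  k <- which.max(gaps)
  start <- ang[if (k == length(ang)) 1L else k + 1L]
  span <- 2 * pi - gaps[k]
  c(start, start + span)
}

# Closed regular-sampled contour from a radial function r(theta) around a
# center point; used by the phantom generator.
.radialContour <- function(center, rfun, nVertices = 128L, theta0 = 0) {
  th <- theta0 + seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  r <- rfun(th)
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}
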
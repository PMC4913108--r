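#' Euclidean chord distance between two 3-D points
#'
#' @param p,q Numeric length-3 vectors, millimetres.
#' @return Distance in millimetres. Note this is the straight-line chord,
#'   not the along-scalp arc; the two are reported side by side by
#'   [probe_layout()].
#' @examples
#' point_distance(c(-16, 16, 71), c(-17, 20, 62))  # sqrt(98) ~ 9.90 mm
#' @export
point_distance <- function(p, q) {
  stopifnot(length(p) == 3, length(q) == 3, all(is.finite(c(p, q))))
  sqrt(sum((p - q)^2))
}

#' Read the packaged 10-20/10-10 electrode coordinate fixture
#'
#' An idealized spherical-head layout (synthetic stand-in for digitized
#' MNI positions): positions constructed from the standard 10-20
#' arc-fraction scheme on a 92 mm sphere centred at the origin, with 10-10
#' intermediate sites by spherical interpolation.
#'
#' @param path Optional alternative CSV (columns `label`, `x`, `y`, `z`).
#' @return Tibble with `label`, `x`, `y`, `z` in millimetres.
#' @export
electrode_positions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "electrodes_1020_synthetic.csv",
                                package = "nvcoupling")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Least-squares sphere through labelled scalp points
#'
#' Algebraic (Coope) fit: linear least squares for centre and radius of the
#' sphere minimizing `| |p - c|^2 - R^2 |`.
#'
#' @param coords Data frame with columns `x`, `y`, `z` (mm).
#' @return List with `center` (length 3) and `radius` (mm).
#' @export
fit_scalp_sphere <- function(coords) {
  p <- as.matrix(coords[c("x", "y", "z")])
  a <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(a, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  list(center = unname(center), radius = unname(radius))
}

#' Place points along a great-circle scalp arc
#'
#' Projects `a` and `b` onto the sphere and returns the points at the given
#' along-arc distances from `a` toward `b` on their great circle.
#'
#' @param sphere List with `center`, `radius` (see [fit_scalp_sphere()]).
#' @param a,b Length-3 points (mm); must not be antipodal.
#' @param arc_offsets Arc lengths from `a`, millimetres; each must not
#'   exceed the a-to-b arc length.
#' @return Matrix with one row per offset, columns `x`, `y`, `z`.
#' @export
arc_place <- function(sphere, a, b, arc_offsets) {
  u <- (a - sphere$center)
  v <- (b - sphere$center)
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  cosang <- sum(u * v)
  if (cosang < -1 + 1e-9) {
    abort("`a` and `b` are antipodal: arc undefined.",
          class = "nvc_invalid_argument")
  }
  w <- v - cosang * u
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) {
    abort("`a` and `b` coincide on the sphere.", class = "nvc_invalid_argument")
  }
  w <- w / wn
  arc_ab <- sphere$radius * acos(pmin(pmax(cosang, -1), 1))
  if (any(arc_offsets > arc_ab + 1e-9)) {
    abort("arc offset exceeds the a-to-b arc length.",
          class = "nvc_invalid_argument")
  }
  ang <- arc_offsets / sphere$radius
  out <- t(vapply(ang, function(th) {
    sphere$center + sphere$radius * (cos(th) * u + sin(th) * w)
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Along-arc distance between two points on a sphere
#'
#' @inheritParams arc_place
#' @param p,q Length-3 points (mm), projected onto the sphere.
#' @return Arc length in millimetres (always >= the chord distance).
#' @export
arc_distance <- function(sphere, p, q) {
  u <- (p - sphere$center)
  v <- (q - sphere$center)
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  sphere$radius * acos(pmin(pmax(sum(u * v), -1), 1))
}

#' Collinear NIRS probe layout along the F3-Cz scalp arc
#'
#' Builds the three-optode layout used for joint imaging over the middle
#' cerebral artery territory: the source sits on the FC1-to-Cz arc
#' `source_offset` mm from FC1, and the short- and long-separation
#' detectors sit on the source-to-F3 arc at the requested separations
#' (defaults 8 mm and 30 mm).
#'
#' @param electrodes Coordinate tibble (default the packaged fixture).
#' @param source_offset mm from FC1 toward Cz for the source (default 15).
#' @param separations mm along-arc source-to-detector separations,
#'   `c(short, long)` (default `c(8, 30)`).
#' @return A list of class `nvc_probe_layout`: `points` tibble (label, x,
#'   y, z, role), `separations` tibble (pair, chord_mm, arc_mm), and the
#'   fitted `sphere`.
#' @export
probe_layout <- function(electrodes = electrode_positions(),
                         source_offset = 15, separations = c(8, 30)) {
  stopifnot(length(separations) == 2, all(separations > 0),
            separations[1] < separations[2])
  sphere <- fit_scalp_sphere(electrodes)
  get <- function(lab) {
    r <- electrodes[electrodes$label == lab, ]
    if (nrow(r) != 1) {
      abort(sprintf("anchor '%s' missing from electrode table", lab),
            class = "nvc_invalid_argument")
    }
    c(r$x, r$y, r$z)
  }
  f3 <- get("F3"); cz <- get("Cz"); fc1 <- get("FC1")
  src <- arc_place(sphere, fc1, cz, source_offset)[1, ]
  dets <- arc_place(sphere, src, f3, separations)
  pts <- tibble::tibble(
    label = c("F3", "Cz", "FC1", "source", "short_detector", "long_detector"),
    x = c(f3[1], cz[1], fc1[1], src[1], dets[1, 1], dets[2, 1]),
    y = c(f3[2], cz[2], fc1[2], src[2], dets[1, 2], dets[2, 2]),
    z = c(f3[3], cz[3], fc1[3], src[3], dets[1, 3], dets[2, 3]),
    role = c("anchor", "anchor", "anchor", "source", "detector", "detector"))
  seps <- tibble::tibble(
    pair = c("source-short", "source-long"),
    chord_mm = c(point_distance(src, dets[1, ]),
                 point_distance(src, dets[2, ])),
    arc_mm = c(arc_distance(sphere, src, dets[1, ]),
               arc_distance(sphere, src, dets[2, ])))
  structure(list(points = pts, separations = seps, sphere = sphere),
            class = "nvc_probe_layout")
}

#' @export
print.nvc_probe_layout <- function(x, ...) {
  cat(sprintf("<nvc_probe_layout> sphere R = %.1f mm\n", x$sphere$radius))
  print(x$separations)
  invisible(x)
}
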
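# Internal geometry and convention helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cardinal quadrant of azimuth angles
#'
#' Azimuth is measured from +X (geographic north) toward east. With the
#' package frame (X = north, Y = west, Z = up, right-handed) east is -Y, so
#' `az = atan2(-y, x)`. Quadrants are half-open 90-degree sectors centred on
#' the cardinal axes: N = \[-45, 45) degrees, E = \[45, 135), S = \[135, 225),
#' W = \[225, 315).
#'
#' @param x,y horizontal coordinates (m) in the root frame.
#' @return factor with levels `N`, `E`, `S`, `W`.
#' @export
#' @examples
#' quadrant_of(c(1, 0, -1, 0), c(0, -1, 0, 1))  # N E S W
quadrant_of <- function(x, y) {
  az <- atan2(-y, x) * 180 / pi        # degrees in (-180, 180]
  az <- (az + 360) %% 360              # [0, 360)
  idx <- (floor((az + 45) / 90) %% 4) + 1
  factor(c("N", "E", "S", "W")[idx], levels = c("N", "E", "S", "W"))
}

# unit vector
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction vector", call. = FALSE)
  v / n
}

# deterministic orthonormal basis (u, v) of the plane perpendicular to w
.perp_basis <- function(w) {
  w <- .unit(w)
  e <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(c(w[2] * e[3] - w[3] * e[2],
               w[3] * e[1] - w[1] * e[3],
               w[1] * e[2] - w[2] * e[1]))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, v = v, w = w)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotate vector v about unit axis k by angle theta (Rodrigues)
.rotate_about <- function(v, k, theta) {
  k <- .unit(k)
  v * cos(theta) + .cross3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

# polygon area by the shoelace formula (columns x, y)
.polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# small deterministic checksum of a config list (hex string)
.config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  b <- utf8ToInt(as.character(js))
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%08x", h)
}

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
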
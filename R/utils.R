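# Internal helpers shared across modules.

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @keywords internal
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[abs(y + 180) < 1e-12] <- 180
  y
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Dihedral angle over four points (rows or length-3 vectors), degrees in
# (-180, 180], IUPAC sign convention.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# Angle at vertex b between rays b->a and b->c, degrees in [0, 180].
angle3 <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Rotation matrix for a right-handed rotation of `deg` degrees about unit
# axis `u` (Rodrigues form).
rotation_matrix <- function(u, deg) {
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
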
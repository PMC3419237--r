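#' Resonance field for an effective g-value
#'
#' Standard resonance condition `B = h nu / (g muB)` with CODATA constants,
#' returned in mT.
#'
#' @param g_eff effective g-value (> 0); vectorised.
#' @param frequency_GHz microwave frequency in GHz (> 0).
#' @return Resonance field(s), mT.
#' @export
#' @examples
#' resonance_field(2.0023, 9.67)   # X-band, free-electron-like g
resonance_field <- function(g_eff, frequency_GHz) {
  if (any(!is.finite(g_eff)) || any(g_eff <= 0))
    stop("'g_eff' must be positive")
  if (!is.finite(frequency_GHz) || frequency_GHz <= 0)
    stop("'frequency_GHz' must be positive")
  1e3 * .PLANCK_H * frequency_GHz * 1e9 / (g_eff * .BOHR_MAGNETON)
}

#' Convert a resonance field back to a g-value
#'
#' Inverse of [resonance_field()].
#'
#' @param field_mT resonance field, mT (> 0); vectorised.
#' @inheritParams resonance_field
#' @return g-value(s).
#' @export
field_to_g <- function(field_mT, frequency_GHz) {
  if (any(!is.finite(field_mT)) || any(field_mT <= 0))
    stop("'field_mT' must be positive")
  if (!is.finite(frequency_GHz) || frequency_GHz <= 0)
    stop("'frequency_GHz' must be positive")
  1e3 * .PLANCK_H * frequency_GHz * 1e9 / (field_mT * .BOHR_MAGNETON)
}

#' Effective g-value along a direction
#'
#' `g(n) = sqrt(sum(g_i^2 n_i^2))` for a unit vector `n` expressed in the
#' g-tensor principal frame.
#'
#' @param direction unit 3-vector (checked to 1e-9).
#' @param g a `spin_system` or a numeric length-3 vector of principal values.
#' @return Effective g-value.
#' @export
effective_g <- function(direction, g) {
  if (inherits(g, "spin_system")) g <- g$g
  direction <- as.numeric(direction)
  if (length(direction) != 3L || abs(sum(direction^2) - 1) > 1e-9)
    stop("'direction' must be a unit 3-vector")
  sqrt(sum(g^2 * direction^2))
}

## Deterministic equal-area orientation grid over one octant: the solid
## angle element is d(cos theta) d(phi), so a uniform midpoint grid in
## u = cos(theta) in [0,1] and phi in [0, pi/2] carries equal weights.
.orientation_grid <- function(n) {
  if (n < 100L) stop("orientation_count must be at least 100")
  nu <- max(2L, round(sqrt(n)))
  nphi <- max(2L, ceiling(n / nu))
  u <- (seq_len(nu) - 0.5) / nu
  phi <- (seq_len(nphi) - 0.5) * (pi / 2) / nphi
  gr <- expand.grid(u = u, phi = phi)
  st <- sqrt(1 - gr$u^2)
  cbind(nx = st * cos(gr$phi), ny = st * sin(gr$phi), nz = gr$u)
}

#' Simulate a powder EPR spectrum
#'
#' First-derivative field-swept powder pattern for an S = 1/2 system with
#' anisotropic g and first-order hyperfine splittings, averaged over a
#' deterministic equal-area orientation grid on one octant. Hyperfine
#' principal frames are taken collinear with the g frame; per orientation
#' the effective splitting of nucleus i is
#' `a_i(n) = sqrt(sum_k (A_ik n_k)^2)` and each transition is shifted by
#' `m_i a_i(n)` from the Zeeman resonance field. The Gaussian peak-to-peak
#' width is interpolated as `dB(n)^2 = sum_k n_k^2 dB_k^2`. The output is
#' normalised to `max(|intensity|) = 1`.
#'
#' @param system a [spin_system()].
#' @param frequency_GHz microwave frequency, GHz.
#' @param field_range optional `c(min, max)` in mT; when omitted the grid
#'   auto-ranges to (min resonance - 10 widths, max resonance + 10 widths).
#' @param n_points number of field points (>= 256; default 4096).
#' @param orientations number of orientations in the octant grid
#'   (>= 100; default 2000).
#' @return An [epr_spectrum()] with metadata recording the simulation inputs.
#' @export
#' @examples
#' sp <- powder_spectrum(preset_spin_system("mv_carp_R2ii"), 9.67,
#'                       n_points = 1024, orientations = 400)
powder_spectrum <- function(system, frequency_GHz, field_range = NULL,
                            n_points = 4096, orientations = 2000) {
  stopifnot(inherits(system, "spin_system"))
  if (n_points < 256L) stop("n_points must be at least 256")
  dirs <- .orientation_grid(orientations)
  nx2 <- dirs[, 1]^2; ny2 <- dirs[, 2]^2; nz2 <- dirs[, 3]^2
  g <- system$g
  geff <- sqrt(g[1]^2 * nx2 + g[2]^2 * ny2 + g[3]^2 * nz2)
  b0 <- resonance_field(geff, frequency_GHz)

  nhf <- length(system$hyperfine)
  if (nhf) {
    amat <- vapply(system$hyperfine, function(h)
      .GAUSS_TO_MT * sqrt(h$A[1]^2 * nx2 + h$A[2]^2 * ny2 + h$A[3]^2 * nz2),
      numeric(nrow(dirs)))                      # orientations x nuclei, mT
    mlist <- lapply(system$hyperfine, function(h) seq(-h$I, h$I, by = 1))
    mgrid <- as.matrix(expand.grid(mlist))      # transitions x nuclei
    centers <- b0 + amat %*% t(mgrid)           # orientations x transitions
  } else {
    centers <- matrix(b0, ncol = 1L)
  }

  lw <- .GAUSS_TO_MT * system$linewidth
  ## sigma of the underlying Gaussian absorption: peak-to-peak width of its
  ## derivative equals 2*sigma
  sigma <- sqrt(lw[1]^2 * nx2 + lw[2]^2 * ny2 + lw[3]^2 * nz2) / 2

  if (is.null(field_range)) {
    field_range <- c(max(min(centers) - 10 * max(lw), 1e-3),
                     max(centers) + 10 * max(lw))
  } else {
    if (length(field_range) != 2L || field_range[1] >= field_range[2])
      stop("'field_range' must be c(min, max) with min < max")
    if (min(centers) < field_range[1] + 5 * max(lw) ||
        max(centers) > field_range[2] - 5 * max(lw))
      warning("resonance fields within 5 linewidths of the field-range edges; ",
              "spectrum may be truncated")
  }
  field <- seq(field_range[1], field_range[2], length.out = n_points)
  df <- field[2] - field[1]
  y <- numeric(n_points)
  w <- 1 / length(centers)
  cut <- 8  # Gaussian support cut-off, in sigma

  for (o in seq_len(nrow(centers))) {
    s <- sigma[o]
    inv2 <- 1 / (2 * s^2)
    for (tr in seq_len(ncol(centers))) {
      b <- centers[o, tr]
      i1 <- max(1L, ceiling((b - cut * s - field_range[1]) / df) + 1L)
      i2 <- min(n_points, floor((b + cut * s - field_range[1]) / df) + 1L)
      if (i1 > i2) next
      x <- field[i1:i2] - b
      y[i1:i2] <- y[i1:i2] - w * x * exp(-x^2 * inv2) / s^3
    }
  }
  m <- max(abs(y))
  if (m == 0) stop("empty spectrum: no resonance inside the field grid")
  epr_spectrum(field, y / m, frequency_GHz = frequency_GHz,
               meta = list(system = system$name,
                           orientations = nrow(dirs),
                           simulated = "powder_spectrum"))
}
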
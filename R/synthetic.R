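# Synthetic-data generators for titration series and CPMG dispersion
# curves. These emulate the statistical structure the analysis stages
# assume (fast-exchange line broadening with planted binding sites;
# two-state dispersion with Gaussian noise) so the whole pipeline is
# testable with known ground truth.

#' Bound fraction of substrate under single-site binding
#'
#' Exact single-site solution for the fraction of substrate bound when a
#' titrant is added at molar ratio `ratio` to substrate at total
#' concentration `s_total` with dissociation constant `kd` (all molar).
#'
#' @param ratio titrant:substrate molar ratio(s).
#' @param s_total total substrate concentration (M).
#' @param kd dissociation constant (M).
#' @return bound fraction(s) in `[0, 1)`.
#' @export
bound_fraction <- function(ratio, s_total, kd) {
  stopifnot_scalar(s_total, "s_total", positive = TRUE)
  stopifnot_scalar(kd, "kd", positive = TRUE)
  l <- ratio * s_total
  b <- s_total + l + kd
  cpx <- (b - sqrt(b^2 - 4 * s_total * l)) / 2
  cpx / s_total
}

#' Specification of a synthetic titration series
#'
#' Defines a substrate sequence, planted binding regions, the titration
#' ladder and the noise/broadening model from which
#' [generate_titration()] draws a peak-table series.
#'
#' The generative model: at molar ratio r the bound fraction f_b follows
#' single-site binding with dissociation constant `kd`; residues inside a
#' planted site acquire an extra bound-state relaxation
#' depth * `delta_r2_max` so that I/I0 = R2free / (R2free + f_b * dR2),
#' with multiplicative Gaussian intensity noise; chemical shift
#' perturbations grow as f_b * csp_max inside sites and are zero outside.
#'
#' @param sequence substrate amino-acid string.
#' @param sites planted binding regions: data frame with `start`, `end`,
#'   `depth` columns (or a list of `c(start, end, depth)`), `depth` in
#'   (0, 1]. Sites must lie within the sequence and not overlap.
#' @param ratios strictly increasing titrant:substrate molar ratios.
#' @param noise_sd relative (multiplicative) intensity noise sd; >= 0.
#' @param csp_max length-2 numeric `c(h = , n = )`: maximal 1H and 15N
#'   shift changes (ppm) at full saturation inside a site.
#' @param kd dissociation constant anchoring the bound fraction (M);
#'   default 47e-6, the measured affinity of the tandem
#'   PPIase-substrate-binding construct for its unfolded substrate.
#' @param s_total total substrate concentration (M); default 100 uM,
#'   a typical NMR titration concentration.
#' @param r2_free free-state amide linewidth parameter (s^-1).
#' @param delta_r2_max full-depth bound-state extra broadening (s^-1).
#' @param seed integer RNG seed; recorded in all outputs.
#' @return object of class `titration_spec`.
#' @export
titration_spec <- function(sequence, sites = list(),
                           ratios = c(0.1, 0.2, 0.5, 1, 2),
                           noise_sd = 0.02,
                           csp_max = c(h = 0.03, n = 0.15),
                           kd = 47e-6, s_total = 100e-6,
                           r2_free = 10, delta_r2_max = 200,
                           seed = 1L) {
  aa <- split_sequence(sequence)
  n <- length(aa)
  if (is.data.frame(sites)) {
    sdf <- sites
  } else if (length(sites) == 0L) {
    sdf <- data.frame(start = integer(), end = integer(), depth = numeric())
  } else {
    sdf <- do.call(rbind, lapply(sites, function(s)
      data.frame(start = s[[1L]], end = s[[2L]], depth = s[[3L]])))
  }
  if (nrow(sdf) > 0) {
    if (any(sdf$start < 1 | sdf$end > n | sdf$start > sdf$end))
      stop("planted sites must lie within the sequence bounds")
    if (any(sdf$depth <= 0 | sdf$depth > 1))
      stop("site depth must be in (0, 1]")
    sdf <- sdf[order(sdf$start), , drop = FALSE]
    if (nrow(sdf) > 1 && any(sdf$start[-1L] <= sdf$end[-nrow(sdf)]))
      stop("planted sites must not overlap")
  }
  if (length(ratios) < 1L || any(diff(ratios) <= 0))
    stop("'ratios' must be strictly increasing")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(sequence = paste(aa, collapse = ""), sites = sdf,
                 ratios = ratios, noise_sd = noise_sd,
                 csp_max = c(h = unname(csp_max[1L]), n = unname(csp_max[2L])),
                 kd = kd, s_total = s_total, r2_free = r2_free,
                 delta_r2_max = delta_r2_max, seed = as.integer(seed)),
            class = "titration_spec")
}

#' Generate a synthetic titration peak-table series
#'
#' Draws a `titration_series`: a free-state reference peak table and one
#' table per titration ratio, under the fast-exchange broadening model
#' described in [titration_spec()]. Prolines carry no backbone amide and
#' are emitted with `assigned = FALSE` and `NA` observables. With
#' `noise_sd = 0` the output is an exact, bit-reproducible function of the
#' spec; ground truth (the planted sites) is carried alongside.
#'
#' @param spec a [titration_spec()].
#' @return object of class `titration_series`: list with `reference`
#'   (data frame `residue`, `aa`, `d1h_ppm`, `d15n_ppm`, `intensity`,
#'   `assigned`), `points` (named list of like tables keyed by ratio),
#'   `sites` (ground truth) and `spec`.
#' @export
generate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  aa <- split_sequence(spec$sequence)
  n <- length(aa)
  assigned <- aa != "P"
  in_site <- rep(FALSE, n)
  depth <- rep(0, n)
  if (nrow(spec$sites) > 0) {
    for (i in seq_len(nrow(spec$sites))) {
      idx <- spec$sites$start[i]:spec$sites$end[i]
      in_site[idx] <- TRUE
      depth[idx] <- spec$sites$depth[i]
    }
  }
  with_seed(spec$seed, {
    d1h0 <- round(8.2 + stats::runif(n, -0.6, 0.6), 4)
    d15n0 <- round(118 + stats::runif(n, -7, 7), 4)
    mk <- function(d1h, d15n, intensity) {
      data.frame(residue = seq_len(n), aa = aa,
                 d1h_ppm = ifelse(assigned, d1h, NA_real_),
                 d15n_ppm = ifelse(assigned, d15n, NA_real_),
                 intensity = ifelse(assigned, intensity, NA_real_),
                 assigned = assigned, stringsAsFactors = FALSE)
    }
    reference <- mk(d1h0, d15n0, rep(1, n))
    points <- lapply(spec$ratios, function(r) {
      fb <- bound_fraction(r, spec$s_total, spec$kd)
      dr2 <- depth * spec$delta_r2_max
      ratio_true <- spec$r2_free / (spec$r2_free + fb * dr2)
      noise <- if (spec$noise_sd > 0)
        1 + stats::rnorm(n, 0, spec$noise_sd) else rep(1, n)
      mk(d1h0 + ifelse(in_site, fb * spec$csp_max[["h"]], 0),
         d15n0 + ifelse(in_site, fb * spec$csp_max[["n"]], 0),
         pmax(ratio_true * noise, 0))
    })
    names(points) <- as.character(spec$ratios)
    structure(list(reference = reference, points = points,
                   sites = spec$sites, spec = spec),
              class = "titration_series")
  })
}

#' Specification of a synthetic CPMG dispersion curve
#'
#' @param r2_0 plateau relaxation rate at infinite refocusing frequency
#'   (s^-1); > 0.
#' @param kex two-state exchange rate constant (s^-1); > 0.
#' @param phi exchange amplitude pa*pb*delta_omega^2 (s^-2); >= 0.
#' @param nu_grid CPMG refocusing frequencies (Hz), all > 0; defaults to
#'   16 log-spaced points in [25, 1000] Hz.
#' @param noise_sd additive Gaussian noise on R2eff (s^-1); >= 0.
#' @param seed integer RNG seed.
#' @return object of class `dispersion_spec`.
#' @export
dispersion_spec <- function(r2_0, kex, phi,
                            nu_grid = exp(seq(log(25), log(1000),
                                              length.out = 16)),
                            noise_sd = 0, seed = 1L) {
  stopifnot_scalar(r2_0, "r2_0", positive = TRUE)
  stopifnot_scalar(kex, "kex", positive = TRUE)
  stopifnot_scalar(phi, "phi")
  if (phi < 0) stop("'phi' must be >= 0")
  if (any(nu_grid <= 0)) stop("all CPMG frequencies must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(r2_0 = r2_0, kex = kex, phi = phi, nu_grid = nu_grid,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dispersion_spec")
}

#' Generate a synthetic CPMG dispersion curve
#'
#' Forward-models R2eff(nu) under two-state fast exchange and adds
#' Gaussian noise. The expression here is written independently of
#' [meiboom_r2eff()] (exponential form of tanh) so the two can be checked
#' against each other without sharing a code path.
#'
#' @param spec a [dispersion_spec()].
#' @return data frame of class `dispersion_curve` with columns
#'   `nu_cpmg_hz`, `r2eff` and, when `noise_sd > 0`, `sd`; the generating
#'   spec is attached as attribute `spec`.
#' @export
generate_dispersion <- function(spec) {
  stopifnot(inherits(spec, "dispersion_spec"))
  nu <- spec$nu_grid
  x <- spec$kex / (4 * nu)
  tanh_x <- (1 - exp(-2 * x)) / (1 + exp(-2 * x))
  r2 <- spec$r2_0 + (spec$phi / spec$kex) * (1 - tanh_x / x)
  out <- data.frame(nu_cpmg_hz = nu, r2eff = r2)
  if (spec$noise_sd > 0) {
    out$r2eff <- with_seed(spec$seed,
                           r2 + stats::rnorm(length(nu), 0, spec$noise_sd))
    out$sd <- rep(spec$noise_sd, length(nu))
  }
  attr(out, "spec") <- spec
  class(out) <- c("dispersion_curve", "data.frame")
  out
}
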
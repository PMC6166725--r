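# Two-state fast-exchange CPMG relaxation dispersion analysis: R2eff
# conversion, the Meiboom model, multi-start least-squares fitting with
# flat-vs-exchange model selection, and the fast-exchange regime check.

#' Effective transverse relaxation rate from peak intensities
#'
#' Standard constant-time CPMG conversion
#' R2eff = -(1/T_relax) * ln(I/I0). An intensity above the reference
#' (possible under noise) yields a negative rate and a warning.
#'
#' @param i peak intensity at a given CPMG frequency; > 0.
#' @param i0 reference intensity (no CPMG block); > 0.
#' @param t_relax constant relaxation delay (s); default 0.050.
#' @return R2eff in s^-1.
#' @export
r2eff_from_intensities <- function(i, i0, t_relax = 0.050) {
  if (any(i <= 0) || any(i0 <= 0)) stop("intensities must be > 0")
  stopifnot_scalar(t_relax, "t_relax", positive = TRUE)
  if (any(i > i0))
    warning("intensity above reference; negative R2eff (noise?)")
  -log(i / i0) / t_relax
}

#' Meiboom fast-exchange dispersion model
#'
#' Effective transverse relaxation rate under two-state fast exchange:
#' \deqn{R_2^{eff}(\nu) = R_2^0 + \frac{\Phi}{k_{ex}}\left[1 -
#'   \frac{4\nu}{k_{ex}} \tanh\frac{k_{ex}}{4\nu}\right]}
#' where \eqn{\Phi = p_a p_b \delta\omega^2}. The curve decays
#' monotonically from \eqn{R_2^0 + \Phi/k_{ex}} at \eqn{\nu \to 0} to
#' \eqn{R_2^0} at \eqn{\nu \to \infty}. Only \eqn{R_2^0}, \eqn{k_{ex}}
#' and \eqn{\Phi} are identifiable in this regime; the populations and
#' shift difference inside \eqn{\Phi} are not separable.
#'
#' @param r2_0 plateau rate (s^-1).
#' @param kex exchange rate constant (s^-1); > 0.
#' @param phi exchange amplitude (s^-2); >= 0.
#' @param nu CPMG refocusing frequency (Hz); > 0. Vectorised.
#' @return R2eff in s^-1.
#' @export
#' @examples
#' meiboom_r2eff(15, 740, 2000, 50) # ~16.97 s^-1
meiboom_r2eff <- function(r2_0, kex, phi, nu) {
  if (any(kex <= 0)) stop("'kex' must be > 0")
  if (any(nu <= 0)) stop("'nu' must be > 0")
  r2_0 + (phi / kex) * (1 - (4 * nu / kex) * tanh(kex / (4 * nu)))
}

#' Fit the Meiboom model to a dispersion curve
#'
#' Weighted least squares over (R2^0, kex, Phi) with multi-start
#' initialisation of kex (the model is weakly identifiable at fast
#' exchange), plus a flat (no-exchange) fit, and an F-test verdict
#' between them. The exchange model is only reported as selected when the
#' dispersion is statistically distinguishable from flat; a curve with no
#' exchange must not yield a spurious kex.
#'
#' @param curve data frame with columns `nu_cpmg_hz`, `r2eff` and
#'   optionally `sd` (per-point uncertainty used as weights), e.g. from
#'   [generate_dispersion()] or [read_dispersion_table()].
#' @param kex_starts multi-start grid for kex (s^-1).
#' @param alpha significance level of the flat-vs-exchange F-test.
#' @param uncertainty `"covariance"` (default) or `"bootstrap"`
#'   (residual resampling, seeded).
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return object of class `exchange_fit`: list with `r2_0`, `kex`,
#'   `phi`, `se` (named standard errors), `rss`, `flat` (list `r2_0`,
#'   `rss`), `f_stat`, `p_value`, `model` ("exchange" or "flat"),
#'   `n`, `fitted` (function of nu).
#' @export
fit_dispersion <- function(curve, kex_starts = c(50, 200, 740, 2000, 5000),
                           alpha = 0.05,
                           uncertainty = c("covariance", "bootstrap"),
                           n_boot = 200, seed = 1L) {
  uncertainty <- match.arg(uncertainty)
  nu <- curve$nu_cpmg_hz
  r2 <- curve$r2eff
  if (length(unique(nu)) < 4L)
    stop("at least 4 distinct CPMG frequencies are required")
  w <- if (!is.null(curve$sd) && all(is.finite(curve$sd)) && all(curve$sd > 0))
    1 / curve$sd^2 else rep(1, length(nu))
  n <- length(nu)

  # flat (no-exchange) model: weighted mean
  r2_flat <- sum(w * r2) / sum(w)
  rss_flat <- sum(w * (r2 - r2_flat)^2)

  # initial phi from the observed dispersion amplitude, floored so the
  # kex gradient never vanishes at the start (flat data would otherwise
  # give a singular Jacobian)
  amp <- max(r2[which.min(nu)] - r2[which.max(nu)], 0.1)
  dat <- data.frame(nu = nu, r2 = r2)
  best <- NULL
  for (k0 in kex_starts) {
    st <- list(r2_0 = max(min(r2), 1e-3), kex = k0, phi = amp * k0)
    fit <- tryCatch(
      minpack.lm::nlsLM(r2 ~ meiboom_r2eff(r2_0, kex, phi, nu),
                        data = dat, start = st, weights = w,
                        lower = c(1e-6, 1e-6, 0), upper = c(100, 1e5, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (!is.null(best)) {
    co <- stats::coef(best)
    rss_ex <- stats::deviance(best)
  } else {
    # bounded quasi-Newton fallback from the same multi-start grid
    obj <- function(p) sum(w * (r2 - meiboom_r2eff(p[1L], p[2L], p[3L], nu))^2)
    fits <- lapply(kex_starts, function(k0)
      tryCatch(stats::optim(c(max(min(r2), 1e-3), k0, amp * k0), obj,
                            method = "L-BFGS-B",
                            lower = c(1e-6, 1e-6, 0), upper = c(100, 1e5, Inf)),
               error = function(e) NULL))
    fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
    if (length(fits) == 0L)
      stop("dispersion fit failed to converge from every start")
    ob <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
    co <- stats::setNames(ob$par, c("r2_0", "kex", "phi"))
    rss_ex <- ob$value
  }

  # F-test between the nested flat (1 parameter) and exchange (3) fits.
  scale_eps <- 1e-10 * max(1, sum(w * r2^2))
  if (rss_flat <= scale_eps) {
    f_stat <- 0; p_value <- 1
  } else if (rss_ex <= scale_eps) {
    f_stat <- Inf; p_value <- 0
  } else {
    f_stat <- ((rss_flat - rss_ex) / 2) / (rss_ex / (n - 3))
    p_value <- stats::pf(f_stat, 2, n - 3, lower.tail = FALSE)
  }
  model <- if (is.finite(p_value) && p_value < alpha) "exchange" else "flat"

  se <- c(r2_0 = NA_real_, kex = NA_real_, phi = NA_real_)
  if (uncertainty == "covariance") {
    sm <- if (is.null(best)) NULL else
      tryCatch(summary(best)$coefficients[, "Std. Error"],
               error = function(e) NULL)
    if (!is.null(sm)) se[names(sm)] <- sm
  } else {
    fit_vals <- meiboom_r2eff(co[["r2_0"]], co[["kex"]], co[["phi"]], nu)
    res <- r2 - fit_vals
    boots <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        rb <- fit_vals + sample(res, n, replace = TRUE)
        fb <- tryCatch(
          minpack.lm::nlsLM(rb ~ meiboom_r2eff(r2_0, kex, phi, nu),
                            data = cbind(dat, rb = rb),
                            start = as.list(co), weights = w,
                            lower = c(1e-6, 1e-6, 0),
                            upper = c(100, 1e5, Inf)),
          error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, 3) else stats::coef(fb)
      }, numeric(3)))
    })
    se <- apply(boots, 2, stats::sd, na.rm = TRUE)
    names(se) <- c("r2_0", "kex", "phi")
  }

  structure(list(r2_0 = unname(co[["r2_0"]]), kex = unname(co[["kex"]]),
                 phi = unname(co[["phi"]]), se = se,
                 rss = rss_ex,
                 flat = list(r2_0 = r2_flat, rss = rss_flat),
                 f_stat = f_stat, p_value = p_value, model = model,
                 n = n,
                 fitted = function(nu) meiboom_r2eff(co[["r2_0"]],
                                                     co[["kex"]],
                                                     co[["phi"]], nu)),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Two-state fast-exchange dispersion fit (Meiboom model)\n")
  cat(sprintf("  selected model: %s (F = %.3g, p = %.3g)\n",
              x$model, x$f_stat, x$p_value))
  cat(sprintf("  R2^0 = %.3f s^-1 (se %.3g)\n", x$r2_0, x$se[["r2_0"]]))
  cat(sprintf("  kex  = %.1f s^-1 (se %.3g)\n", x$kex, x$se[["kex"]]))
  cat(sprintf("  Phi  = %.1f s^-2 (se %.3g)\n", x$phi, x$se[["phi"]]))
  cat(sprintf("  flat R2^0 = %.3f s^-1; RSS exchange %.4g, flat %.4g (n = %d)\n",
              x$flat$r2_0, x$rss, x$flat$rss, x$n))
  invisible(x)
}

#' Fast-exchange regime check
#'
#' The fast-exchange limit requires the shift difference between the
#' exchanging states to be small against the exchange rate. The 15N shift
#' difference in ppm is converted to Hz at the nucleus Larmor frequency
#' (spectrometer 1H frequency times the gyromagnetic frequency ratio) and
#' compared with kex. Two comparison modes are provided, because the
#' ppm-to-rate comparison is convention-dependent: `"angular"` converts
#' delta-omega to angular units (fast iff kex >= 2*pi*dw_hz) and
#' `"direct"` compares Hz to s^-1 without the 2*pi (fast iff
#' kex >= dw_hz). Neither convention is asserted as canonical.
#'
#' @param kex fitted exchange rate (s^-1).
#' @param delta_omega_ppm expected shift difference between states (ppm).
#' @param field_mhz spectrometer 1H frequency (MHz); default 800.
#' @param nucleus_ratio gyromagnetic frequency ratio of the observed
#'   nucleus to 1H; default 0.101329118 (15N).
#' @param mode `"angular"` (default) or `"direct"`.
#' @return list `delta_omega_hz`, `kex`, `ratio` (kex over the converted
#'   shift difference), `mode`, `verdict` ("fast" or "not-fast").
#' @export
#' @examples
#' regime_check(740, 0.8, field_mhz = 800) # fast
regime_check <- function(kex, delta_omega_ppm, field_mhz = 800,
                         nucleus_ratio = 0.101329118,
                         mode = c("angular", "direct")) {
  mode <- match.arg(mode)
  stopifnot_scalar(kex, "kex", positive = TRUE)
  stopifnot_scalar(field_mhz, "field_mhz", positive = TRUE)
  if (delta_omega_ppm < 0) stop("'delta_omega_ppm' must be >= 0")
  dw_hz <- delta_omega_ppm * field_mhz * nucleus_ratio
  denom <- if (mode == "angular") 2 * pi * dw_hz else dw_hz
  ratio <- if (denom == 0) Inf else kex / denom
  list(delta_omega_hz = dw_hz, kex = kex, ratio = ratio, mode = mode,
       verdict = if (ratio >= 1) "fast" else "not-fast")
}
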
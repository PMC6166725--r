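test_that("combined CSP matches the weighted two-nucleus form", {
  expect_equal(csp(8.0, 118, 8.0, 118), 0)
  # hand evaluation: sqrt(0.030^2 + (0.10/5)^2) = 0.036056
  expect_equal(csp(8.0, 118.0, 8.030, 118.10), sqrt(0.030^2 + 0.02^2),
               tolerance = 1e-12)
  expect_equal(csp(8.0, 118.0, 8.030, 118.10), 0.036056, tolerance = 1e-4)
  # single-axis nitrogen case: 0.5 ppm / 5 = 0.1 exactly
  expect_equal(csp(8.0, 118.0, 8.0, 118.5), 0.1)
  # invariant to exchanging free/bound labels
  expect_equal(csp(8.0, 118, 8.1, 119), csp(8.1, 119, 8.0, 118))
})

test_that("CSP classification uses the mapping thresholds", {
  expect_equal(as.character(classify_csp(c(0.010, 0.020, 0.030))),
               c("below", "moderate", "strong"))
  # boundary values fall in the lower class (thresholds are exceeded, not met)
  expect_equal(as.character(classify_csp(c(0.015, 0.025))),
               c("below", "moderate"))
  expect_error(classify_csp(-0.01), "non-negative")
})

test_that("intensity ratios recover the generative closed form", {
  spec <- titration_spec(random_sequence(40, 3),
                         sites = list(c(10, 16, 0.8)), noise_sd = 0, seed = 3)
  ser <- generate_titration(spec)
  rt <- intensity_ratios(ser, 2)
  fb <- bound_fraction(2, spec$s_total, spec$kd)
  expected_in <- spec$r2_free / (spec$r2_free + fb * 0.8 * spec$delta_r2_max)
  scored <- !rt$missing
  expect_equal(rt$ratio[scored & rt$residue >= 10 & rt$residue <= 16],
               rep(expected_in, sum(scored & rt$residue >= 10 &
                                    rt$residue <= 16)),
               tolerance = 1e-12)
  expect_equal(unique(rt$ratio[scored & (rt$residue < 10 | rt$residue > 16)]),
               1)
  expect_true(all(rt$missing[rt$aa == "P"]))
})

test_that("hand-built ratio tables give the expected ratios", {
  ref <- data.frame(residue = 1:4, aa = c("A", "G", "L", "V"),
                    intensity = c(2, 2, 2, 2), assigned = TRUE)
  pt <- ref; pt$intensity <- c(2, 1, 2, 2)
  ser <- structure(list(reference = ref, points = list("1" = pt)),
                   class = "titration_series")
  rt <- intensity_ratios(ser, 1)
  expect_equal(rt$ratio, c(1, 0.5, 1, 1))
  ref0 <- ref; ref0$intensity[2] <- 0
  ser0 <- structure(list(reference = ref0, points = list("1" = pt)),
                    class = "titration_series")
  expect_error(intensity_ratios(ser0, 1), "zero reference")
})

test_that("run-length rule accepts five significant residues, rejects four", {
  mk <- function(sig_res, n = 30, missing_res = integer()) {
    ratio <- rep(1, n)
    ratio[sig_res] <- 0.2
    ratio <- ratio + seq(-0.001, 0.001, length.out = n)  # break ties
    missing <- seq_len(n) %in% missing_res
    ratio[missing] <- NA
    data.frame(residue = seq_len(n), ratio = ratio, missing = missing)
  }
  expect_equal(nrow(call_binding_sites(mk(11:14))), 0)  # run of 4: no site
  s5 <- call_binding_sites(mk(11:15))                   # run of 5: one site
  expect_equal(nrow(s5), 1)
  expect_equal(c(s5$start, s5$end, s5$n_scored), c(11, 15, 5))
})

test_that("missing residues bridge a run without counting toward it", {
  # significant at 251-254 and 256-259 with 255 missing (a proline):
  # one site 251-259 when bridging, none in strict mode (runs of 4)
  n <- 20
  ratio <- rep(1, n); ratio[c(4:7, 9:12)] <- 0.2; ratio[8] <- NA
  ratio <- ratio + seq(-0.001, 0.001, length.out = n)
  rt <- data.frame(residue = 248:267, ratio = ratio,
                   missing = is.na(ratio))
  bridged <- call_binding_sites(rt, bridge_missing = TRUE)
  expect_equal(nrow(bridged), 1)
  expect_equal(c(bridged$start, bridged$end), c(251, 259))
  expect_equal(bridged$n_scored, 8)
  expect_equal(nrow(call_binding_sites(rt, bridge_missing = FALSE)), 0)
})

test_that("site calling is monotone in the fixed significance cutoff", {
  pl <- planted_titration(17, noise_sd = 0.03)
  rt <- intensity_ratios(generate_titration(pl$spec), 2)
  loose <- call_binding_sites(rt, significance = "fixed", cutoff = 0.8)
  strict <- call_binding_sites(rt, significance = "fixed", cutoff = 0.5)
  in_sites <- function(sites) {
    v <- rep(FALSE, 60)
    for (i in seq_len(nrow(sites))) v[sites$start[i]:sites$end[i]] <- TRUE
    v
  }
  # relaxing the threshold never removes called residues
  expect_true(all(in_sites(loose) | !in_sites(strict)))
})

test_that("preference comparison ranks sites by planted depth asymmetry", {
  s <- random_sequence(60, 29)
  mk_ser <- function(d1, d2) generate_titration(titration_spec(
    s, sites = list(c(10, 16, d1), c(40, 46, d2)), noise_sd = 0, seed = 29))
  ra <- intensity_ratios(mk_ser(0.9, 0.3), 2)
  rb <- intensity_ratios(mk_ser(0.3, 0.9), 2)
  sites <- data.frame(start = c(10, 40), end = c(16, 46))
  pref <- compare_preference(ra, rb, sites, labels = c("PPD", "SBD"))
  expect_equal(pref$preferred_by[pref$start == 10], "PPD")
  expect_equal(pref$preferred_by[pref$start == 40], "SBD")
  # identical profiles give zero differences
  same <- compare_preference(ra, ra, sites)
  expect_equal(same$difference, c(0, 0))
})
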
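test_that("titration generator honours the no-binding null", {
  spec <- titration_spec(random_sequence(30, 2), sites = list(), noise_sd = 0,
                         seed = 2)
  ser <- generate_titration(spec)
  for (r in names(ser$points)) {
    rt <- intensity_ratios(ser, r)
    expect_equal(rt$ratio[!rt$missing], rep(1, sum(!rt$missing)))
    pt <- ser$points[[r]]
    ok <- ser$reference$assigned
    expect_equal(csp(ser$reference$d1h_ppm[ok], ser$reference$d15n_ppm[ok],
                     pt$d1h_ppm[ok], pt$d15n_ppm[ok]),
                 rep(0, sum(ok)))
  }
})

test_that("planted full-depth sites broaden below all out-of-site residues", {
  spec <- titration_spec(random_sequence(40, 4), sites = list(c(10, 16, 1)),
                         ratios = c(0.5, 1, 2, 5), noise_sd = 0, seed = 4)
  ser <- generate_titration(spec)
  for (r in names(ser$points)) {
    rt <- intensity_ratios(ser, r)
    scored <- !rt$missing
    inside <- scored & rt$residue >= 10 & rt$residue <= 16
    outside <- scored & !inside
    expect_lt(max(rt$ratio[inside]), min(rt$ratio[outside]))
  }
})

test_that("generators are reproducible for a fixed seed and spec", {
  spec <- titration_spec(random_sequence(40, 6), sites = list(c(10, 16, 0.8)),
                         noise_sd = 0.02, seed = 42)
  a <- generate_titration(spec)
  b <- generate_titration(spec)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_titration_tsv(a, f1); write_titration_tsv(b, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical tables

  dsp <- dispersion_spec(15, 740, 2000, noise_sd = 0.3, seed = 42)
  expect_identical(generate_dispersion(dsp), generate_dispersion(dsp))
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1); invisible(generate_dispersion(dsp)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("generator errors on invalid specs", {
  expect_error(titration_spec("AAAAA", sites = list(c(2, 8, 0.5))), "bounds")
  expect_error(titration_spec(random_sequence(30, 1),
                              sites = list(c(2, 8, 0.5), c(5, 12, 0.5))),
               "overlap")
  expect_error(titration_spec("AAAAAAA", sites = list(c(2, 4, 1.5))), "depth")
  expect_error(titration_spec("AAAAAAA", ratios = c(1, 0.5)), "increasing")
  expect_error(dispersion_spec(15, 740, 2000, nu_grid = c(-5, 50)), "> 0")
  expect_error(dispersion_spec(15, -1, 2000), "kex")
})

test_that("dispersion generator reproduces the two-state forward model", {
  # no-exchange limit: flat at r2_0
  flat <- generate_dispersion(dispersion_spec(15, 740, 0))
  expect_equal(flat$r2eff, rep(15, 16))
  # frozen hand-evaluated point of the dispersion expression
  one <- generate_dispersion(dispersion_spec(15, 740, 2000, nu_grid = 50))
  expect_equal(one$r2eff, 16.97314, tolerance = 1e-6)
  # fast-pulsing limit approaches the plateau
  hi <- generate_dispersion(dispersion_spec(15, 740, 2000, nu_grid = 1e5))
  expect_lt(abs(hi$r2eff - 15), 1e-3)
  # generator and model function agree to machine precision (independent
  # transcriptions of the same expression)
  sp <- dispersion_spec(12.3, 512, 1750)
  expect_equal(generate_dispersion(sp)$r2eff,
               meiboom_r2eff(12.3, 512, 1750, sp$nu_grid),
               tolerance = 1e-14)
})

test_that("peptide scan ensembles have one model per window plus the start", {
  spec <- peptide_scan_spec(step = 0.5)
  ens <- generate_peptide_scan(spec)
  expect_equal(length(ens$xyz), 174 / 0.5 + 1)  # arc/step windows + initial
  fr <- attr(ens, "frames")
  for (m in c(1L, 100L, nrow(fr))) {
    target <- if (m == 1L) spec$schedule$start_omega else fr$center_deg[m]
    expect_equal(measure_omega(ens, 3, model = m), target, tolerance = 1e-6)
  }
  # degenerate schedule: single model at the start angle
  single <- generate_peptide_scan(peptide_scan_spec(start_omega = -174,
                                                    end_omega = -174))
  expect_equal(length(single$xyz), 1)
  expect_equal(measure_omega(single, 3), -174, tolerance = 1e-6)
})

test_that("ensembles survive a PDB write/read round trip", {
  spec <- peptide_scan_spec(start_omega = -174, end_omega = -170, step = 0.5)
  ens <- generate_peptide_scan(spec)
  f <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, f)
  back <- read_pdb_ensemble(f)
  expect_equal(length(back$xyz), length(ens$xyz))
  expect_identical(back$atoms$elety, ens$atoms$elety)
  expect_identical(back$atoms$resno, ens$atoms$resno)
  fr <- attr(ens, "frames")
  # file precision is the PDB fixed format's 0.001 A, so re-measured
  # torsions match the window centers to ~0.05 degrees
  for (m in seq_along(back$xyz)) {
    target <- if (m == 1L) spec$schedule$start_omega else fr$center_deg[m]
    expect_equal(measure_omega(back, 3, model = m), target, tolerance = 0.05)
  }
  expect_error(peptide_scan_spec(proline_index = 1), "preceding")
})
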
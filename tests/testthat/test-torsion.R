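test_that("schedule arithmetic reproduces the trajectory bookkeeping", {
  cw <- build_schedule(torsion_schedule(-174, 0, 0.2, 2, "clockwise"))
  expect_equal(nrow(cw), 870)                        # 174 deg / 0.2 deg
  expect_equal(max(cw$time_ps), 1740)                # 1.74 ns
  expect_equal(attr(cw, "arc_deg"), 174)
  # the clockwise path passes through the syn geometry at 0.84 ns
  i90 <- which(abs(cw$center_deg - (-90)) < 1e-9)
  expect_equal(cw$time_ps[i90], 840)

  ccw <- build_schedule(torsion_schedule(-174, 0, 0.2, 2, "counterclockwise"))
  expect_equal(nrow(ccw), 930)                       # complementary 186 deg
  expect_equal(max(ccw$time_ps), 1860)               # 1.86 ns
  expect_true(any(abs(ccw$center_deg - 180) < 1e-9)) # passes +/-180
  expect_false(any(abs(ccw$center_deg - (-90)) < 1e-9))

  # the two arcs complement to a full turn for any endpoints
  for (ep in list(c(-174, 0), c(10, 170), c(-30, 150))) {
    a1 <- attr(build_schedule(torsion_schedule(ep[1], ep[2], 0.5,
                                               direction = "clockwise")),
               "arc_deg")
    a2 <- attr(build_schedule(torsion_schedule(ep[1], ep[2], 0.5,
                                               direction = "counterclockwise")),
               "arc_deg")
    expect_equal(a1 + a2, 360)
  }

  expect_equal(nrow(build_schedule(torsion_schedule(-90, -90))), 0)
  expect_error(build_schedule(torsion_schedule(-174, 0, step = 0.7)),
               "not divisible")
  expect_error(torsion_schedule(-200, 0), "-180")
})

test_that("omega measurement matches planar trans/cis constructions", {
  # planar zig-zag: N(i)-CA(i)-C(i)-N(i+1)-CA(i+1) all in one plane
  mk <- function(ca2) {
    atoms <- data.frame(eleno = 1:5,
                        elety = c("CA", "C", "N", "CA", "C"),
                        resid = "GLY", chain = "A",
                        resno = c(1, 1, 2, 2, 2))
    xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0), ca2,
                 c(5, 1.2, 0))
    structure(list(atoms = atoms, xyz = list(xyz)), class = "pdb_ensemble")
  }
  expect_equal(measure_omega(mk(c(3.7, 1.2, 0)), 2), 180)  # trans
  expect_equal(measure_omega(mk(c(1.6, 2.2, 0)), 2), 0)    # cis
  ens <- generate_peptide_scan(peptide_scan_spec(start_omega = -97,
                                                 end_omega = -97))
  expect_equal(measure_omega(ens, 3), -97, tolerance = 1e-6)
})

test_that("segment rotation is an exact isometry that moves only omega", {
  ens <- generate_peptide_scan(peptide_scan_spec(start_omega = -174,
                                                 end_omega = -174))
  om0 <- measure_omega(ens, 3)
  # identity and inverse composition
  expect_equal(rotate_segment(ens, 3, 0)$xyz[[1]], ens$xyz[[1]])
  back <- rotate_segment(rotate_segment(ens, 3, 10), 3, -10)
  expect_lt(max(abs(back$xyz[[1]] - ens$xyz[[1]])), 1e-6)
  # +84 from -174 lands on the syn geometry at -90
  expect_equal(measure_omega(rotate_segment(ens, 3, 84), 3), -90,
               tolerance = 1e-9)
  # arbitrary set/measure round trips
  for (target in c(-160, -97, -45.5, 0.2, 120)) {
    e2 <- rotate_segment(ens, 3, target - om0)
    expect_equal(measure_omega(e2, 3), target, tolerance = 1e-3)
  }
  # all pairwise distances inside the moving and the fixed set survive
  e2 <- rotate_segment(ens, 3, 84)
  moving <- which(ens$atoms$chain == "A" & ens$atoms$resno < 3)
  fixed <- setdiff(seq_len(nrow(ens$atoms)), moving)
  expect_lt(max(abs(dist(ens$xyz[[1]][moving, ]) -
                    dist(e2$xyz[[1]][moving, ]))), 1e-6)
  expect_lt(max(abs(dist(ens$xyz[[1]][fixed, ]) -
                    dist(e2$xyz[[1]][fixed, ]))), 1e-6)
})

test_that("hydrogen-bond geometry is exact and rigid-motion invariant", {
  g <- hbond_geometry(c(0, 0, 1.01), c(0, 0, 0), c(0, 0, -2))
  expect_equal(g$d_ho, 2)
  expect_equal(g$theta_nho, 180)
  g90 <- hbond_geometry(c(1, 0, 0), c(0, 0, 0), c(0, 2.2, 0))
  expect_equal(g90$theta_nho, 90)
  # random congruent motions leave both observables unchanged
  set.seed(31)
  for (i in 1:10) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    t0 <- rnorm(3, sd = 10)
    tr <- function(p) as.numeric(R %*% p + t0)
    g2 <- hbond_geometry(tr(c(0, 0, 1.01)), tr(c(0, 0, 0)), tr(c(0.3, 0.4, -2)))
    g1 <- hbond_geometry(c(0, 0, 1.01), c(0, 0, 0), c(0.3, 0.4, -2))
    expect_equal(g2$d_ho, g1$d_ho, tolerance = 1e-9)
    expect_equal(g2$theta_nho, g1$theta_nho, tolerance = 1e-9)
  }
  expect_error(hbond_geometry(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0)),
               "coincident")
})

test_that("hydrogen-bond classification applies both geometric criteria", {
  expect_equal(classify_hbond(2.1, 152), "strong")  # syn-state geometry
  expect_equal(classify_hbond(4.3, 134), "none")    # trans-state geometry
  expect_equal(classify_hbond(2.49, 130), "strong") # boundary: just inside
  expect_equal(classify_hbond(2.51, 179), "none")   # distance alone fails
  expect_equal(classify_hbond(2.0, 129.9), "none")  # angle alone fails
  # the distance criterion alone rules out the trans geometry at any
  # angle threshold in the plausible range
  for (amin in seq(130, 152, by = 2)) {
    expect_equal(classify_hbond(2.1, 152, angle_min = amin), "strong")
    expect_equal(classify_hbond(4.3, 134, angle_min = amin), "none")
  }
})

test_that("scan tracking finds the encounter the construction plants", {
  spec <- peptide_scan_spec()  # -174 -> 0 clockwise, contact at -90
  ens <- generate_peptide_scan(spec)
  tr <- track_scan(ens, donor = "B:1", acceptor = "A:2:O", proline_index = 3)
  expect_equal(nrow(tr$frames), length(ens$xyz))
  # closest approach happens at the contact window (0.84 ns), at the
  # planted contact distance
  imin <- which.min(tr$frames$d_ho_A)
  expect_equal(tr$frames$time_ns[imin], 0.84, tolerance = 0.002)
  expect_equal(tr$frames$omega_deg[imin], -90, tolerance = 0.2)
  expect_equal(tr$frames$d_ho_A[imin], spec$contact_distance,
               tolerance = 1e-6)
  # independent closed form for the first strong frame: the acceptor O
  # rides a circle of radius r about the C-N axis and the probe sits
  # contact_distance radially beyond it, so d(delta)^2 = (r+c)^2 + r^2
  # - 2 r (r+c) cos(delta); solve d = 2.5 A for the approach angle
  xyz <- ens$xyz[[1]]
  i_o <- which(ens$atoms$resno == 2 & ens$atoms$elety == "O" &
               ens$atoms$chain == "A")
  i_c <- which(ens$atoms$resno == 2 & ens$atoms$elety == "C" &
               ens$atoms$chain == "A")
  i_n <- which(ens$atoms$resno == 3 & ens$atoms$elety == "N" &
               ens$atoms$chain == "A")
  ax <- xyz[i_n, ] - xyz[i_c, ]; ax <- ax / sqrt(sum(ax^2))
  v <- xyz[i_o, ] - xyz[i_c, ]
  r <- sqrt(sum((v - sum(v * ax) * ax)^2))
  cc <- spec$contact_distance
  delta_star <- acos((( r + cc)^2 + r^2 - 2.5^2) / (2 * r * (r + cc))) *
    180 / pi
  t_pred <- (840 - ceiling(delta_star / 0.2) * 0.2 / 0.2 * 2) / 1000
  expect_equal(tr$frames$time_ns[min(which(tr$frames$hbond == "strong"))],
               t_pred, tolerance = 0.01)
  expect_equal(tr$first_strong_ns, t_pred, tolerance = 0.01)
  # a probe parked far away never forms the bond
  far <- peptide_scan_spec(acceptor_site = list(N = c(50, 50, 51.01),
                                                H = c(50, 50, 50)))
  tr_far <- track_scan(generate_peptide_scan(far), donor = "B:1",
                       acceptor = "A:2:O", proline_index = 3)
  expect_true(all(tr_far$frames$hbond == "none"))
  expect_true(is.na(tr_far$first_strong_ns))
})

test_that("tracking is deterministic and guards schedule mismatches", {
  ens <- generate_peptide_scan(peptide_scan_spec(step = 1))
  t1 <- track_scan(ens, "B:1", "A:2:O", 3)
  t2 <- track_scan(ens, "B:1", "A:2:O", 3)
  expect_identical(t1, t2)
  short <- build_schedule(torsion_schedule(-174, 0, 1), include_initial = TRUE)
  short <- short[1:10, ]
  expect_error(track_scan(ens, "B:1", "A:2:O", 3, schedule = short),
               "models")
  expect_warning(tt <- track_scan(ens, "B:1", "A:2:O", 3, schedule = short,
                                  on_mismatch = "truncate"), "truncat")
  expect_equal(nrow(tt$frames), 10)
})
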
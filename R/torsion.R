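# Kinematic omega-torsion scan machinery: restraint-center schedules,
# dihedral measurement, rigid rotation about the peptide C-N bond,
# hydrogen-bond geometry and classification, and per-frame tracking of a
# driven conformer ensemble.

#' Omega-restraint schedule specification
#'
#' Describes a torsion-drive schedule in which the restraint center of
#' the peptidyl-prolyl omega angle advances by `step` degrees every
#' `dwell` picoseconds from `start_omega` to `end_omega`. Direction
#' semantics are anchored operationally: `"clockwise"` traverses the arc
#' of increasing omega (for the canonical trans-to-cis endpoints
#' -174 to 0 degrees, the 174-degree arc through -90, the twisted
#' syn geometry), `"counterclockwise"` the complementary arc through
#' +/-180 degrees. The restraint force constant is carried as metadata
#' only; the kinematic scan places omega exactly at each center.
#'
#' @param start_omega,end_omega schedule endpoints in degrees, each in
#'   (-180, 180].
#' @param step degrees per window; > 0 (default 0.2).
#' @param dwell picoseconds per window; > 0 (default 2).
#' @param direction `"clockwise"` or `"counterclockwise"`.
#' @param restraint_k restraint force constant, kcal/mol/rad^2 (metadata).
#' @return object of class `torsion_schedule`.
#' @export
torsion_schedule <- function(start_omega = -174, end_omega = 0, step = 0.2,
                             dwell = 2,
                             direction = c("clockwise", "counterclockwise"),
                             restraint_k = 50) {
  direction <- match.arg(direction)
  stopifnot_scalar(step, "step", positive = TRUE)
  stopifnot_scalar(dwell, "dwell", positive = TRUE)
  for (v in c(start_omega, end_omega))
    if (v <= -180 || v > 180)
      stop("schedule endpoints must lie in (-180, 180]")
  structure(list(start_omega = start_omega, end_omega = end_omega,
                 step = step, dwell = dwell, direction = direction,
                 restraint_k = restraint_k),
            class = "torsion_schedule")
}

schedule_arc <- function(schedule) {
  d <- (schedule$end_omega - schedule$start_omega) %% 360
  if (schedule$direction == "clockwise") d else (360 - d) %% 360
}

#' Build the window table of a torsion schedule
#'
#' Expands a [torsion_schedule()] into its windows: window index, time at
#' the end of the window (ps) and the restraint center (degrees, wrapped
#' into (-180, 180]). Window `i` has its center `i * step` degrees along
#' the arc from the start, reached at time `i * dwell`; the total
#' trajectory time is therefore `windows * dwell`. Identical endpoints
#' yield an empty schedule.
#'
#' @param schedule a [torsion_schedule()].
#' @param include_initial prepend a window-0 row (time 0, center at
#'   `start_omega`)? Default `FALSE`.
#' @return data frame `window`, `time_ps`, `center_deg`, with the arc
#'   length (degrees) as attribute `arc_deg`.
#' @export
#' @examples
#' s <- torsion_schedule(-174, 0, step = 0.2, dwell = 2)
#' nrow(build_schedule(s)) # 870 windows -> 1.74 ns
build_schedule <- function(schedule, include_initial = FALSE) {
  stopifnot(inherits(schedule, "torsion_schedule"))
  arc <- schedule_arc(schedule)
  nwin <- arc / schedule$step
  if (abs(nwin - round(nwin)) > 1e-6)
    stop(sprintf("arc of %g degrees is not divisible by step %g",
                 arc, schedule$step))
  nwin <- as.integer(round(nwin))
  sgn <- if (schedule$direction == "clockwise") 1 else -1
  win <- seq_len(nwin)
  if (nwin == 0L) win <- integer(0)
  centers <- wrap_angle(schedule$start_omega + sgn * win * schedule$step)
  out <- data.frame(window = win,
                    time_ps = win * schedule$dwell,
                    center_deg = centers)
  if (include_initial)
    out <- rbind(data.frame(window = 0L, time_ps = 0,
                            center_deg = schedule$start_omega), out)
  attr(out, "arc_deg") <- arc
  out
}

# --- atom selection helpers -------------------------------------------------

# select one atom index in an ensemble by chain, residue number and name
atom_index <- function(ens, chain, resno, elety) {
  hit <- which(ens$atoms$chain == chain & ens$atoms$resno == resno &
               ens$atoms$elety == elety)
  if (length(hit) != 1L)
    stop(sprintf("atom %s:%s:%s matched %d atoms", chain, resno, elety,
                 length(hit)))
  hit
}

# parse "chain:resno[:atom]" selection strings
parse_selection <- function(spec, default_atom = NULL) {
  parts <- strsplit(spec, ":")[[1L]]
  if (length(parts) == 2L && !is.null(default_atom))
    parts <- c(parts, default_atom)
  if (length(parts) != 3L)
    stop(sprintf("selection '%s' is not of the form chain:resno:atom", spec))
  list(chain = parts[1L], resno = as.integer(parts[2L]), elety = parts[3L])
}

model_coords <- function(ens, model = 1L) {
  if (model < 1L || model > length(ens$xyz))
    stop(sprintf("model %d not in ensemble of %d models", model,
                 length(ens$xyz)))
  ens$xyz[[model]]
}

#' Measure the omega dihedral of a peptidyl bond
#'
#' The omega torsion of the peptide bond preceding residue `residue`:
#' CA(i-1)-C(i-1)-N(i)-CA(i), in degrees in (-180, 180]. ~180 is trans,
#' ~0 cis, ~+/-90 the twisted syn geometry.
#'
#' @param ens a conformer ensemble (see [generate_peptide_scan()] /
#'   [read_pdb_ensemble()]).
#' @param residue residue number whose preceding peptide bond is measured
#'   (must have a preceding residue in the same chain).
#' @param model model index; default 1.
#' @param chain chain identifier; default `"A"`.
#' @return omega in degrees.
#' @export
measure_omega <- function(ens, residue, model = 1L, chain = "A") {
  xyz <- model_coords(ens, model)
  i <- c(atom_index(ens, chain, residue - 1L, "CA"),
         atom_index(ens, chain, residue - 1L, "C"),
         atom_index(ens, chain, residue, "N"),
         atom_index(ens, chain, residue, "CA"))
  dihedral4(xyz[i[1L], ], xyz[i[2L], ], xyz[i[3L], ], xyz[i[4L], ])
}

#' Rigidly rotate the N-terminal segment about a peptide C-N bond
#'
#' Rotates all atoms N-terminal of the peptide bond preceding `residue`
#' (residues 1 .. residue-1 of the chain, including the carbonyl oxygen
#' of the preceding residue) rigidly about the C(i-1)-N(i) axis by
#' `delta_deg` degrees. The measured omega changes by exactly
#' `delta_deg` (mod 360); all internal distances within the moving and
#' the fixed set are preserved.
#'
#' @param ens conformer ensemble.
#' @param residue residue whose preceding bond is the rotation axis.
#' @param delta_deg rotation in degrees (sign follows the measured omega).
#' @param model model index to transform.
#' @param chain chain identifier of the peptide.
#' @return the ensemble with the transformed model.
#' @export
rotate_segment <- function(ens, residue, delta_deg, model = 1L, chain = "A") {
  xyz <- model_coords(ens, model)
  i_c <- atom_index(ens, chain, residue - 1L, "C")
  i_n <- atom_index(ens, chain, residue, "N")
  p_c <- xyz[i_c, ]
  axis <- xyz[i_n, ] - p_c
  if (vnorm(axis) < 1e-9) stop("bond atoms are coincident")
  moving <- which(ens$atoms$chain == chain & ens$atoms$resno < residue)
  # sign convention: a right-handed rotation of the N-terminal set about
  # the C->N direction increases the measured dihedral by delta
  R <- rotation_matrix(unit(axis), delta_deg)
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, p_c) %*% t(R),
                         2, p_c, `+`)
  ens$xyz[[model]] <- xyz
  ens
}

#' Hydrogen-bond geometry of a donor-acceptor pair
#'
#' @param donor_n,donor_h,acceptor_o length-3 coordinates (Angstrom) of
#'   the donor nitrogen, donor amide proton and acceptor carbonyl oxygen.
#' @return list `d_ho` (H...O distance, Angstrom) and `theta_nho`
#'   (N-H...O angle at the proton, degrees).
#' @export
#' @examples
#' hbond_geometry(c(0, 0, 1.01), c(0, 0, 0), c(0, 0, -2)) # 2 A, 180 deg
hbond_geometry <- function(donor_n, donor_h, acceptor_o) {
  d <- vnorm(acceptor_o - donor_h)
  if (d < 1e-9 || vnorm(donor_n - donor_h) < 1e-9)
    stop("coincident atoms in hydrogen-bond geometry")
  list(d_ho = d, theta_nho = angle3(donor_n, donor_h, acceptor_o))
}

#' Classify a hydrogen bond from its geometry
#'
#' A strong hydrogen bond requires a short proton-acceptor distance
#' (< 2.5 Angstrom) and a near-linear N-H...O arrangement (angle at the
#' proton at least `angle_min`, default 130 degrees).
#'
#' @param d_ho H...O distance (Angstrom).
#' @param theta_nho N-H...O angle (degrees).
#' @param d_max distance criterion (Angstrom); default 2.5.
#' @param angle_min angle criterion (degrees); default 130.
#' @return `"strong"` or `"none"` (vectorised).
#' @export
#' @examples
#' classify_hbond(2.1, 152) # "strong" (syn-state geometry)
#' classify_hbond(4.3, 134) # "none"   (trans-state geometry)
classify_hbond <- function(d_ho, theta_nho, d_max = 2.5, angle_min = 130) {
  if (any(d_ho <= 0)) stop("'d_ho' must be > 0")
  if (any(theta_nho < 0 | theta_nho > 180)) stop("'theta_nho' out of [0, 180]")
  ifelse(d_ho < d_max & theta_nho >= angle_min, "strong", "none")
}

#' Track hydrogen-bond geometry along a driven torsion scan
#'
#' Walks a conformer ensemble aligned with a torsion schedule and records,
#' per frame: time, the measured omega of the scanned peptidyl bond, the
#' donor-acceptor hydrogen-bond geometry and its classification. Also
#' reports the first time (if any) at which the bond classifies strong.
#'
#' @param ens conformer ensemble, e.g. from [generate_peptide_scan()] or
#'   [read_pdb_ensemble()].
#' @param donor selection `"chain:resno"` of the donor residue (atoms `N`
#'   and `H` are used), e.g. `"B:1"` for the fixed probe site.
#' @param acceptor selection `"chain:resno[:atom]"` of the acceptor atom;
#'   the atom defaults to the carbonyl `O`.
#' @param proline_index residue number carrying the scanned
#'   peptidyl-prolyl bond (the omega measured is that of its preceding
#'   bond).
#' @param schedule a [torsion_schedule()] or a window table from
#'   [build_schedule()]. When `NULL`, the table attached to the ensemble
#'   by the generator is used. An ensemble holding one model more than
#'   the schedule has windows is assumed to lead with the initial
#'   (window 0) structure.
#' @param on_mismatch `"error"` (default) or `"truncate"` when the model
#'   count still disagrees with the schedule (truncates to the shorter,
#'   with a warning).
#' @param d_max,angle_min hydrogen-bond criteria, see [classify_hbond()].
#' @param chain chain identifier of the scanned peptide; default `"A"`.
#' @return list with `frames` (data frame `time_ns`, `omega_deg`,
#'   `d_ho_A`, `theta_deg`, `hbond`) and `first_strong_ns` (`NA` if the
#'   bond never forms).
#' @export
track_scan <- function(ens, donor, acceptor, proline_index,
                       schedule = NULL, on_mismatch = c("error", "truncate"),
                       d_max = 2.5, angle_min = 130, chain = "A") {
  on_mismatch <- match.arg(on_mismatch)
  if (is.null(schedule)) schedule <- attr(ens, "frames")
  if (is.null(schedule)) stop("no schedule supplied and none attached")
  if (inherits(schedule, "torsion_schedule"))
    schedule <- build_schedule(schedule)
  n_models <- length(ens$xyz)
  if (n_models == nrow(schedule) + 1L && !any(schedule$window == 0L)) {
    # leading model is the unrotated initial structure (window 0, t = 0)
    schedule <- rbind(data.frame(window = 0L, time_ps = 0,
                                 center_deg = NA_real_), schedule)
  }
  if (n_models != nrow(schedule)) {
    msg <- sprintf("ensemble has %d models but schedule %d windows",
                   n_models, nrow(schedule))
    if (on_mismatch == "error") stop(msg)
    warning(paste(msg, "- truncating"))
    m <- min(n_models, nrow(schedule))
    schedule <- schedule[seq_len(m), , drop = FALSE]
    n_models <- m
  }
  dn <- parse_selection(paste0(donor, ":N"))
  dh <- parse_selection(paste0(donor, ":H"))
  ac <- parse_selection(acceptor, default_atom = "O")
  i_n <- atom_index(ens, dn$chain, dn$resno, "N")
  i_h <- atom_index(ens, dh$chain, dh$resno, "H")
  i_o <- atom_index(ens, ac$chain, ac$resno, ac$elety)
  rows <- lapply(seq_len(n_models), function(m) {
    xyz <- ens$xyz[[m]]
    g <- hbond_geometry(xyz[i_n, ], xyz[i_h, ], xyz[i_o, ])
    data.frame(time_ns = schedule$time_ps[m] / 1000,
               omega_deg = measure_omega(ens, proline_index, model = m,
                                         chain = chain),
               d_ho_A = g$d_ho, theta_deg = g$theta_nho,
               hbond = classify_hbond(g$d_ho, g$theta_nho,
                                      d_max = d_max, angle_min = angle_min),
               stringsAsFactors = FALSE)
  })
  frames <- do.call(rbind, rows)
  strong <- which(frames$hbond == "strong")
  list(frames = frames,
       first_strong_ns = if (length(strong)) frames$time_ns[strong[1L]]
                         else NA_real_)
}
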
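# Idealized-backbone peptide construction, the kinematic omega-scan
# ensemble generator, and multi-model PDB input/output.

# Ideal backbone internal coordinates (Angstrom / degrees). Any
# internally consistent set serves, since only relative geometry is
# analysed downstream.
.geom <- list(
  b_n_ca = 1.46, b_ca_c = 1.52, b_c_n = 1.33, b_c_o = 1.23, b_n_h = 1.01,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_c_n_h = 119.0,
  phi = -140, psi = 130)

# NeRF atom placement: position d such that |c-d| = bond,
# angle(b,c,d) = angle and dihedral(a,b,c,d) = tors (degrees).
place_atom <- function(a, b, c, bond, angle, tors) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- angle * pi / 180
  t <- tors * pi / 180
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(t), bond * sin(ang) * sin(t))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

#' Specification of a kinematic peptidyl-prolyl omega scan
#'
#' Describes a short idealized peptide whose peptidyl-prolyl omega
#' torsion is driven through a restraint-center schedule, plus a fixed
#' probe site representing the catalytic backbone amide (donor N-H) of
#' the receptor. [generate_peptide_scan()] realises it as a multi-model
#' conformer ensemble.
#'
#' By default the probe is placed so that it meets the carbonyl oxygen
#' of the residue preceding the proline at `contact_omega` (the twisted
#' syn geometry, -90 degrees): the probe proton sits `contact_distance`
#' Angstrom radially out from that oxygen's rotation circle, collinear
#' with its nitrogen, so the H...O distance is minimal exactly at the
#' contact window and grows smoothly away from it.
#'
#' @param n_residues number of peptide residues (>= 2).
#' @param proline_index residue carrying the scanned peptidyl-prolyl
#'   bond; must have a preceding residue (2 .. n_residues).
#' @param start_omega,end_omega,step,dwell,direction schedule parameters,
#'   see [torsion_schedule()].
#' @param contact_omega omega (degrees) at which the probe meets the
#'   acceptor oxygen; default -90.
#' @param contact_distance closest H...O approach (Angstrom); default 2.2.
#' @param acceptor_site optional fixed probe coordinates overriding the
#'   automatic placement: list with length-3 numeric `N` and `H`.
#' @return object of class `peptide_scan_spec`.
#' @export
peptide_scan_spec <- function(n_residues = 5, proline_index = 3,
                              start_omega = -174, end_omega = 0,
                              step = 0.2, dwell = 2,
                              direction = c("clockwise", "counterclockwise"),
                              contact_omega = -90, contact_distance = 2.2,
                              acceptor_site = NULL) {
  direction <- match.arg(direction)
  if (n_residues < 2L) stop("'n_residues' must be >= 2")
  if (proline_index < 2L || proline_index > n_residues)
    stop("'proline_index' must have a preceding residue in the chain")
  sched <- torsion_schedule(start_omega, end_omega, step = step,
                            dwell = dwell, direction = direction)
  structure(list(n_residues = as.integer(n_residues),
                 proline_index = as.integer(proline_index),
                 schedule = sched, contact_omega = contact_omega,
                 contact_distance = contact_distance,
                 acceptor_site = acceptor_site),
            class = "peptide_scan_spec")
}

# build an all-trans idealized backbone; returns list(atoms, xyz-matrix)
build_backbone <- function(n_residues, proline_index) {
  g <- .geom
  N <- vector("list", n_residues); CA <- N; C <- N; O <- N; H <- N
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  C[[1L]] <- CA[[1L]] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in 2:n_residues) {
    N[[i]] <- place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                         g$b_c_n, g$a_ca_c_n, g$psi)
    CA[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                          g$b_n_ca, g$a_c_n_ca, 180)
    C[[i]] <- place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                         g$b_ca_c, g$a_n_ca_c, g$phi)
    if (i != proline_index)
      H[[i]] <- place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                           g$b_n_h, g$a_c_n_h, 0)
  }
  for (i in seq_len(n_residues))
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         g$b_c_o, g$a_ca_c_o, g$psi + 180)
  atoms <- list(); xyz <- list()
  for (i in seq_len(n_residues)) {
    resid <- if (i == proline_index) "PRO" else "GLY"
    add <- function(name, pos) {
      atoms[[length(atoms) + 1L]] <<- data.frame(
        elety = name, resid = resid, chain = "A", resno = i,
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <<- pos
    }
    add("N", N[[i]])
    if (!is.null(H[[i]])) add("H", H[[i]])
    add("CA", CA[[i]])
    add("C", C[[i]])
    add("O", O[[i]])
  }
  atoms <- do.call(rbind, atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  list(atoms = atoms[, c("eleno", "elety", "resid", "chain", "resno")],
       xyz = do.call(rbind, xyz))
}

new_ensemble <- function(atoms, xyz_list) {
  structure(list(atoms = atoms, xyz = xyz_list), class = "pdb_ensemble")
}

#' @export
print.pdb_ensemble <- function(x, ...) {
  cat(sprintf("pdb_ensemble: %d models, %d atoms, chains %s\n",
              length(x$xyz), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Generate a driven peptidyl-prolyl omega-scan conformer ensemble
#'
#' Builds an idealized all-trans backbone, sets the scanned omega to
#' `start_omega`, and emits one model per schedule window with omega set
#' exactly to the window's restraint center by rigid rotation of the
#' N-terminal segment about the peptide C-N bond, preceded by the
#' initial (window 0) structure. The receptor probe site (chain `B`,
#' residue 1, atoms `N`/`H`) is fixed across models. The window table
#' (including the window-0 row) is attached as attribute `"frames"`, the
#' spec as `"spec"`.
#'
#' @param spec a [peptide_scan_spec()].
#' @return object of class `pdb_ensemble`: list with `atoms` (data frame
#'   `eleno`, `elety`, `resid`, `chain`, `resno`) and `xyz` (list of
#'   n_atoms x 3 coordinate matrices, one per model).
#' @export
generate_peptide_scan <- function(spec) {
  stopifnot(inherits(spec, "peptide_scan_spec"))
  p <- spec$proline_index
  sched <- spec$schedule
  base <- build_backbone(spec$n_residues, p)
  ens0 <- new_ensemble(base$atoms, list(base$xyz))
  # rotate the all-trans chain onto the schedule start
  om0 <- measure_omega(ens0, p)
  ens0 <- rotate_segment(ens0, p, wrap_angle(sched$start_omega - om0))

  # fixed probe site: meets the preceding residue's carbonyl O at the
  # contact omega, radially off the rotation axis
  if (is.null(spec$acceptor_site)) {
    tmp <- rotate_segment(ens0, p,
                          wrap_angle(spec$contact_omega - sched$start_omega))
    xyz <- tmp$xyz[[1L]]
    o_c <- xyz[atom_index(tmp, "A", p - 1L, "O"), ]
    p_c <- xyz[atom_index(tmp, "A", p - 1L, "C"), ]
    ax <- unit(xyz[atom_index(tmp, "A", p, "N"), ] - p_c)
    foot <- p_c + sum((o_c - p_c) * ax) * ax
    u <- unit(o_c - foot)
    probe_h <- o_c + spec$contact_distance * u
    probe_n <- probe_h + .geom$b_n_h * u
  } else {
    probe_n <- spec$acceptor_site$N
    probe_h <- spec$acceptor_site$H
  }
  atoms <- rbind(ens0$atoms,
                 data.frame(eleno = nrow(ens0$atoms) + 1:2,
                            elety = c("N", "H"), resid = "PRB",
                            chain = "B", resno = 1L,
                            stringsAsFactors = FALSE))
  base_xyz <- rbind(ens0$xyz[[1L]], probe_n, probe_h)
  rownames(base_xyz) <- NULL
  ens <- new_ensemble(atoms, list(base_xyz))

  frames <- build_schedule(sched, include_initial = TRUE)
  models <- lapply(seq_len(nrow(frames)), function(i) {
    delta <- wrap_angle(frames$center_deg[i] - sched$start_omega)
    rotate_segment(ens, p, delta)$xyz[[1L]]
  })
  out <- new_ensemble(atoms, models)
  attr(out, "frames") <- frames
  attr(out, "spec") <- spec
  out
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Standard MODEL/ENDMDL records with atom names N, H, CA, C, O.
#' Coordinates carry the PDB fixed-format precision (0.001 Angstrom).
#'
#' @param ens a `pdb_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- ens$atoms
  name4 <- ifelse(nchar(a$elety) < 4L,
                  sprintf("%-4s", paste0(" ", a$elety)), a$elety)
  for (m in seq_along(ens$xyz)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$xyz[[m]]
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$eleno, name4, a$resid, a$chain, a$resno,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0,
      substr(a$elety, 1L, 1L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a conformer ensemble
#'
#' @param path PDB file with MODEL/ENDMDL records (a single-model file
#'   yields a one-model ensemble).
#' @return a `pdb_ensemble`.
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                      resid = pdb$atom$resid, chain = pdb$atom$chain,
                      resno = pdb$atom$resno, stringsAsFactors = FALSE)
  xyz <- lapply(seq_len(nrow(pdb$xyz)), function(m)
    matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE))
  new_ensemble(atoms, xyz)
}
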
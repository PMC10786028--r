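# Multi-model trajectory analysis: backbone hydrogen bonds (DSSP-style
# electrostatic criterion), H-bond breaking/reforming event matrices,
# pairwise Kabsch-superposed RMSD matrices, and painting per-residue labels
# into the B-factor column.

#' Construct an ordered series of structural models
#'
#' @param atoms Data.frame with columns `elety` (atom name), `resid` (residue
#'   name), `chain`, `resno` (residue number); one row per atom, shared by all
#'   models.
#' @param xyz Numeric matrix, one row per model, `3 * nrow(atoms)` columns
#'   (x1, y1, z1, x2, ...).
#' @return A `model_series` object.
#' @export
model_series <- function(atoms, xyz) {
  xyz <- matrix(xyz, ncol = 3L * nrow(atoms))
  stopifnot(ncol(xyz) == 3L * nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz), class = "model_series")
}

#' @export
print.model_series <- function(x, ...) {
  cat("model_series:", nrow(x$xyz), "model(s),", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

#' Read an ordered model series from PDB file(s)
#'
#' A single path may contain multiple MODEL records; several paths are read in
#' the given order (or reordered by `index`) and must share an identical
#' (chain, residue, atom-name) set.
#'
#' @param paths One or more PDB paths.
#' @param index Optional integer vector reordering `paths`.
#' @return A [model_series()].
#' @export
read_model_series <- function(paths, index = NULL) {
  if (!is.null(index)) paths <- paths[index]
  read_one <- function(p) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    keep <- pdb$atom$type == "ATOM"
    cols <- as.vector(t(outer(which(keep), c(2L, 1L, 0L),
                              function(i, o) 3L * i - o)))
    list(atoms = pdb$atom[keep, c("elety", "resid", "chain", "resno")],
         xyz = matrix(pdb$xyz, ncol = ncol(pdb$xyz))[, cols, drop = FALSE])
  }
  parts <- lapply(paths, read_one)
  key <- function(a) paste(a$chain, a$resno, a$elety)
  ref <- key(parts[[1L]]$atoms)
  for (i in seq_along(parts)[-1L]) {
    k <- key(parts[[i]]$atoms)
    if (length(k) != length(ref) || any(k != ref)) {
      bad <- if (length(k) != length(ref)) "atom counts differ"
             else paste("first mismatch:", ref[which(k != ref)[1L]], "vs",
                        k[which(k != ref)[1L]])
      stop("inconsistent atom sets across models (", paths[i], "): ", bad)
    }
  }
  rownames(parts[[1L]]$atoms) <- NULL
  model_series(parts[[1L]]$atoms, do.call(rbind, lapply(parts, `[[`, "xyz")))
}

#' Write a model series as a multi-model PDB file
#'
#' @param series A [model_series()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_model_series <- function(series, path) {
  a <- series$atoms
  bio3d::write.pdb(file = path, xyz = series$xyz, resno = a$resno,
                   resid = a$resid, elety = a$elety,
                   chain = if (all(is.na(a$chain))) "A" else a$chain)
  invisible(path)
}

#' Coordinates of one model as an n_atoms x 3 matrix
#'
#' @param series A [model_series()].
#' @param model Model index.
#' @return Numeric matrix, one row per atom.
#' @export
model_coords <- function(series, model = 1L) {
  matrix(series$xyz[model, ], ncol = 3L, byrow = TRUE)
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# NeRF atom placement: position D at distance r from C, angle theta (deg) at
# C between B-C-D, torsion chi (deg) for A-B-C-D.
nerf_place <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- unitv(C - B)
  n <- unitv(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build a polypeptide backbone from dihedral angles
#'
#' Places N, CA, C, O atoms with standard bond geometry (N-CA 1.458, CA-C
#' 1.525, C-N 1.329, C=O 1.231 A; omega fixed at 180 deg). Useful as a
#' geometry fixture: an ideal alpha-helix is `phi = -57`, `psi = -47`.
#'
#' @param phi,psi Backbone dihedrals in degrees, one per residue (`phi[1]` and
#'   the last `psi` are not used).
#' @param resid Residue name for all residues (default `"ALA"`).
#' @param chain Chain identifier.
#' @return A single-model [model_series()].
#' @export
build_chain <- function(phi, psi, resid = "ALA", chain = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  coord <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)  # N, CA, C, O per residue
  ri <- function(i, what) 4L * (i - 1L) + match(what, c("N", "CA", "C", "O"))
  # first residue placed along canonical axes
  coord[ri(1L, "N"), ] <- c(0, 0, 0)
  coord[ri(1L, "CA"), ] <- c(1.458, 0, 0)
  coord[ri(1L, "C"), ] <- nerf_place(c(0, 1, 0), coord[ri(1L, "N"), ],
                                     coord[ri(1L, "CA"), ], 1.525, 111.2, psi[1L] - 120)
  for (i in 2L:n) {
    Np  <- coord[ri(i - 1L, "N"), ]; CAp <- coord[ri(i - 1L, "CA"), ]
    Cp  <- coord[ri(i - 1L, "C"), ]
    coord[ri(i, "N"), ]  <- nerf_place(Np, CAp, Cp, 1.329, 116.2, psi[i - 1L])
    coord[ri(i, "CA"), ] <- nerf_place(CAp, Cp, coord[ri(i, "N"), ], 1.458, 121.7, 180)
    coord[ri(i, "C"), ]  <- nerf_place(Cp, coord[ri(i, "N"), ],
                                       coord[ri(i, "CA"), ], 1.525, 111.2, phi[i])
  }
  for (i in 1L:n) {  # carbonyl O in the peptide plane
    ref <- if (i < n) coord[ri(i + 1L, "N"), ] else coord[ri(i, "N"), ]
    Ca <- coord[ri(i, "CA"), ]; Cc <- coord[ri(i, "C"), ]
    if (i < n) {
      bis <- unitv(unitv(Ca - Cc) + unitv(ref - Cc))
      coord[ri(i, "O"), ] <- Cc - 1.231 * bis
    } else {
      coord[ri(i, "O"), ] <- nerf_place(coord[ri(i, "N"), ], Ca, Cc, 1.231, 120.5, 180)
    }
  }
  atoms <- data.frame(elety = rep(c("N", "CA", "C", "O"), n),
                      resid = resid, chain = chain,
                      resno = rep(seq_len(n), each = 4L),
                      stringsAsFactors = FALSE)
  model_series(atoms, as.vector(t(coord)))
}

#' Ideal alpha-helix model
#'
#' @param n_res Number of residues.
#' @param phi,psi Helical dihedrals in degrees.
#' @return A single-model [model_series()].
#' @export
build_helix_model <- function(n_res, phi = -57, psi = -47) {
  build_chain(rep(phi, n_res), rep(psi, n_res))
}

#' Synthetic helix -> unwound -> helix trajectory
#'
#' Linear dihedral interpolation between helical (`-57, -47`) and extended
#' (`-139, 135`) angles for the residues in `unwind`, peaking mid-trajectory:
#' model 1 and the last model are the intact helix, the middle model is
#' maximally unwound.
#'
#' @param n_res Helix length in residues.
#' @param n_models Number of trajectory steps (odd recommended).
#' @param unwind Integer vector of residues to unwind (default: central third).
#' @return A [model_series()] of `n_models` models.
#' @export
build_unwinding_trajectory <- function(n_res = 18L, n_models = 9L,
                                       unwind = NULL) {
  if (is.null(unwind))
    unwind <- seq.int(floor(n_res / 3) + 1L, ceiling(2 * n_res / 3))
  frac <- 1 - abs(2 * (seq_len(n_models) - 1L) / (n_models - 1L) - 1)
  models <- lapply(frac, function(f) {
    phi <- rep(-57, n_res); psi <- rep(-47, n_res)
    phi[unwind] <- -57 + f * (-139 - (-57))
    psi[unwind] <- -47 + f * (135 - (-47))
    build_chain(phi, psi)
  })
  model_series(models[[1L]]$atoms,
               do.call(rbind, lapply(models, `[[`, "xyz")))
}

# geometric amide-H placement: in plane, opposite the bisector of
# C(i-1)-N and CA-N, 1.02 A from N
place_amide_h <- function(N, CA, Cprev) {
  N + 1.02 * unitv(-(unitv(Cprev - N) + unitv(CA - N)))
}

#' Backbone hydrogen bonds of one model
#'
#' Detects donor (N-H) to acceptor (C=O) backbone hydrogen bonds between
#' residues of `window`. Amide hydrogens are always placed geometrically
#' (1.02 A from N, in-plane opposite the C(i-1)/CA bisector) so the criterion
#' is identical whether or not the file contains hydrogens. The default
#' criterion is the DSSP electrostatic energy
#' `E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol with a
#' bond when `E < energy_cutoff`; `criterion = "geometric"` instead requires
#' H...O < 2.5 A and an N-H...O angle > 120 deg. Prolines are never donors,
#' nor are chain-first residues (no preceding carbonyl to place H); pairs
#' closer than two residues in sequence are excluded.
#'
#' @param series A [model_series()].
#' @param window Integer vector of residue numbers to analyze.
#' @param model Model index within the series (default 1).
#' @param criterion `"dssp"` or `"geometric"`.
#' @param energy_cutoff DSSP energy cutoff in kcal/mol (default -0.5).
#' @return Data.frame with columns `donor`, `acceptor` (residue numbers).
#' @export
backbone_hbonds <- function(series, window = NULL, model = 1L,
                            criterion = c("dssp", "geometric"),
                            energy_cutoff = -0.5) {
  criterion <- match.arg(criterion)
  a <- series$atoms
  xyz <- model_coords(series, model)
  if (is.null(window)) window <- sort(unique(a$resno))

  get_atom <- function(res, ety) {
    i <- which(a$resno == res & a$elety == ety)
    if (length(i) != 1L) return(NULL)
    xyz[i, ]
  }
  residues <- sort(unique(a$resno[a$resno %in% window]))
  bb <- lapply(setNames(residues, residues), function(r) {
    at <- list(N = get_atom(r, "N"), CA = get_atom(r, "CA"),
               C = get_atom(r, "C"), O = get_atom(r, "O"))
    if (any(vapply(at, is.null, logical(1)))) {
      warning("residue ", r, " lacks backbone atoms; skipped")
      return(NULL)
    }
    at$resid <- a$resid[which(a$resno == r)[1L]]
    at
  })
  residues <- residues[!vapply(bb, is.null, logical(1))]
  bb <- bb[as.character(residues)]

  pairs <- list()
  for (don in residues) {
    d <- bb[[as.character(don)]]
    if (d$resid == "PRO") next
    Cprev <- get_atom(don - 1L, "C")
    if (is.null(Cprev)) next
    H <- place_amide_h(d$N, d$CA, Cprev)
    for (acc in residues) {
      if (abs(don - acc) < 2L) next
      ac <- bb[[as.character(acc)]]
      bonded <- if (criterion == "dssp") {
        E <- 27.888 * (1 / vnorm(ac$O - d$N) + 1 / vnorm(ac$C - H) -
                       1 / vnorm(ac$O - H) - 1 / vnorm(ac$C - d$N))
        E < energy_cutoff
      } else {
        dHO <- vnorm(ac$O - H)
        ang <- acos(sum(unitv(H - d$N) * unitv(ac$O - H))) # 180 - NHO angle
        dHO < 2.5 && (180 - ang * 180 / pi) > 120
      }
      if (bonded) pairs[[length(pairs) + 1L]] <- c(don, acc)
    }
  }
  if (!length(pairs))
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  out <- as.data.frame(do.call(rbind, pairs))
  names(out) <- c("donor", "acceptor")
  out
}

#' Hydrogen-bond presence and breaking events along a trajectory
#'
#' Evaluates [backbone_hbonds()] at every step; any pair observed in at least
#' one model becomes a row of the presence matrix. Breaking events are
#' present-to-absent transitions between adjacent steps, reforming events the
#' reverse.
#'
#' @param series A [model_series()] with `>= 2` models.
#' @param window Residue numbers to analyze.
#' @param ... Passed to [backbone_hbonds()].
#' @return `hbond_events` list: `presence` (logical matrix, pairs x steps),
#'   `breaking` and `reforming` (data.frames with `pair`, `step_from`,
#'   `step_to`).
#' @export
hbond_event_matrix <- function(series, window = NULL, ...) {
  n_models <- nrow(series$xyz)
  if (n_models < 2L) stop("need at least 2 models")
  sets <- lapply(seq_len(n_models), function(m) {
    hb <- backbone_hbonds(series, window, model = m, ...)
    paste0(hb$donor, "->", hb$acceptor)
  })
  pairs <- sort(unique(unlist(sets)))
  presence <- vapply(sets, function(s) pairs %in% s, logical(length(pairs)))
  presence <- matrix(presence, nrow = length(pairs),
                     dimnames = list(pairs, paste0("step", seq_len(n_models))))
  events <- function(from_state, to_state) {
    ev <- which(presence[, -n_models, drop = FALSE] == from_state &
                presence[, -1L, drop = FALSE] == to_state, arr.ind = TRUE)
    data.frame(pair = pairs[ev[, 1L]], step_from = as.integer(ev[, 2L]),
               step_to = as.integer(ev[, 2L] + 1L), stringsAsFactors = FALSE)
  }
  structure(list(presence = presence,
                 breaking = events(TRUE, FALSE),
                 reforming = events(FALSE, TRUE)),
            class = "hbond_events")
}

#' @export
print.hbond_events <- function(x, ...) {
  cat("backbone H-bond events:", nrow(x$presence), "pairs over",
      ncol(x$presence), "steps;", nrow(x$breaking), "breaking,",
      nrow(x$reforming), "reforming\n")
  invisible(x)
}

#' Pairwise C-alpha RMSD matrix over a residue window
#'
#' Each model pair is optimally superposed (Kabsch least-squares) on the
#' window's C-alpha atoms before computing RMSD on those same atoms.
#'
#' @param series A [model_series()] with `>= 2` models.
#' @param window Residue numbers of the analyzed region.
#' @param normalize If `TRUE`, divide by the matrix maximum (max entry = 1).
#' @param fit_window Residues used for superposition (defaults to `window`).
#' @return Symmetric matrix with zero diagonal, in Angstrom (or unitless if
#'   normalized).
#' @export
rmsd_matrix <- function(series, window = NULL, normalize = FALSE,
                        fit_window = window) {
  a <- series$atoms
  if (is.null(window)) window <- sort(unique(a$resno))
  if (is.null(fit_window)) fit_window <- window
  ca_sel <- which(a$elety == "CA" & a$resno %in% window)
  fit_sel <- which(a$elety == "CA" & a$resno %in% fit_window)
  if (length(fit_sel) < 3L)
    stop("need at least 3 C-alpha atoms for superposition, found ",
         length(fit_sel))
  n_models <- nrow(series$xyz)
  if (n_models < 2L) stop("need at least 2 models")
  xyz_idx <- function(sel) as.vector(t(outer(sel, c(2L, 1L, 0L),
                                             function(i, o) 3L * i - o)))
  ca_xyz <- series$xyz[, xyz_idx(ca_sel), drop = FALSE]

  m <- matrix(0, n_models, n_models)
  for (i in seq_len(n_models - 1L)) for (j in (i + 1L):n_models) {
    # rotation/translation from the fit window, RMSD measured on the window
    moved <- bio3d::fit.xyz(fixed = series$xyz[i, ], mobile = series$xyz[j, ],
                            fixed.inds = xyz_idx(fit_sel),
                            mobile.inds = xyz_idx(fit_sel))
    dev <- matrix(ca_xyz[i, ] - moved[xyz_idx(ca_sel)], ncol = 3L, byrow = TRUE)
    m[i, j] <- m[j, i] <- sqrt(mean(rowSums(dev^2)))
  }
  if (normalize && max(m) > 0) m <- m / max(m)
  m
}

#' Paint per-residue labels into the B-factor column
#'
#' Writes small integer labels (e.g. cluster assignments) into the B-factor
#' of every atom of each residue; residues without a label receive the
#' sentinel -1. Labels for residues absent from the model are skipped with a
#' warning.
#'
#' @param pdb A bio3d `pdb` object, a PDB path, or a [model_series()] (first
#'   model used).
#' @param labels Named numeric vector (names = residue numbers) or data.frame
#'   with columns `residue` and `label`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
paint_labels <- function(pdb, labels, path) {
  if (is.data.frame(labels))
    labels <- setNames(labels$label, labels$residue)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  if (inherits(pdb, "model_series")) {
    a <- pdb$atoms
    resno <- a$resno
    lab <- labels[as.character(resno)]
    lab[is.na(lab)] <- -1
    missing_res <- setdiff(names(labels), as.character(unique(resno)))
    if (length(missing_res))
      warning("label residue(s) not in model, skipped: ",
              paste(missing_res, collapse = ", "))
    bio3d::write.pdb(file = path, xyz = pdb$xyz[1L, ], resno = resno,
                     resid = a$resid, elety = a$elety,
                     chain = if (all(is.na(a$chain))) "A" else a$chain,
                     b = lab)
  } else {
    resno <- pdb$atom$resno
    lab <- labels[as.character(resno)]
    lab[is.na(lab)] <- -1
    missing_res <- setdiff(names(labels), as.character(unique(resno)))
    if (length(missing_res))
      warning("label residue(s) not in model, skipped: ",
              paste(missing_res, collapse = ", "))
    pdb$atom$b <- lab
    bio3d::write.pdb(pdb, file = path)
  }
  invisible(path)
}
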
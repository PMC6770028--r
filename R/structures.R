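# Molecular data model: ligand poses in a shared receptor frame, plus the
# receptor-side carboxylate anchor used for alignment.

#' Construct a ligand pose
#'
#' A ligand pose is one docked conformer of one compound, expressed in the
#' shared receptor coordinate frame. Atoms carry element, Cartesian position
#' (Angstrom), formal charge and (once assigned) a partial point charge.
#' Bond orders use the SDF convention (1, 2, 3; 4 = aromatic).
#'
#' @param compound_id character scalar identifying the compound.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `formal_charge` (default 0) and `charge` (partial charge,
#'   default `NA`).
#' @param bonds data.frame with columns `i`, `j`, `order` (may have 0 rows).
#' @param pose_index integer pose number within the compound's docking run.
#' @param frame_id identifier of the shared receptor frame.
#' @return An object of class `ligand_pose`.
#' @export
ligand_pose <- function(compound_id, atoms, bonds = NULL,
                        pose_index = 1L, frame_id = "receptor") {
  stopifnot(is.character(compound_id), length(compound_id) == 1L)
  atoms <- as.data.frame(atoms)
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stopf("pose '%s': atoms must have columns %s", compound_id,
          paste(req, collapse = ", "))
  }
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stopf("pose '%s': non-finite atom coordinates", compound_id)
  }
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(), order = integer())
  bonds <- as.data.frame(bonds)[, c("i", "j", "order"), drop = FALSE]
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  n <- nrow(atoms)
  if (nrow(bonds) && (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))) {
    stopf("pose '%s': bond indices out of range", compound_id)
  }
  pose <- structure(
    list(compound_id = compound_id, pose_index = as.integer(pose_index),
         atoms = atoms, bonds = bonds, frame_id = frame_id),
    class = "ligand_pose")
  pose$atoms$atom_class <- classify_atoms(pose)
  pose
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s (pose %d): %d atoms, %d bonds, net charge %+d\n",
              x$compound_id, x$pose_index, nrow(x$atoms), nrow(x$bonds),
              sum(x$atoms$formal_charge)))
  invisible(x)
}

# Atom classes used by the force-field parameter table and the alignment
# rules. Hybridisation is inferred from bond orders (4 = aromatic).
classify_atoms <- function(pose) {
  a <- pose$atoms
  b <- pose$bonds
  n <- nrow(a)
  maxord <- rep(1L, n)
  arom <- rep(FALSE, n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      o <- b$order[k]
      if (o == 4L) {
        arom[b$i[k]] <- arom[b$j[k]] <- TRUE
      } else {
        maxord[b$i[k]] <- max(maxord[b$i[k]], o)
        maxord[b$j[k]] <- max(maxord[b$j[k]], o)
      }
    }
  }
  el <- toupper(a$element)
  cls <- rep("other", n)
  cls[el == "H"] <- "H"
  cls[el == "C" & maxord == 1L & !arom] <- "sp3-C"
  cls[el == "C" & (maxord >= 2L) & !arom] <- "sp2-C"
  cls[el == "C" & arom] <- "aromatic-C"
  cls[el == "N" & a$formal_charge > 0] <- "N-cationic"
  cls[el == "N" & a$formal_charge <= 0] <- "N-neutral"
  cls[el == "O"] <- "O"
  cls[el == "S"] <- "S"
  cls[el %in% c("F", "CL", "BR", "I")] <- "halogen"
  cls
}

# Hybridisation labels (sp3/sp2/sp) used by the PEOE parameter table.
atom_hybridisation <- function(pose) {
  a <- pose$atoms
  b <- pose$bonds
  n <- nrow(a)
  hyb <- rep("sp3", n)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      o <- b$order[k]
      idx <- c(b$i[k], b$j[k])
      if (o == 4L || o == 2L) hyb[idx] <- ifelse(hyb[idx] == "sp", "sp", "sp2")
      if (o == 3L) hyb[idx] <- "sp"
    }
  }
  hyb
}

atom_coords <- function(pose) as.matrix(pose$atoms[, c("x", "y", "z")])

heavy_atoms <- function(pose) which(toupper(pose$atoms$element) != "H")

net_formal_charge <- function(pose) sum(pose$atoms$formal_charge)

#' Read ligand poses from an SDF or MOL2 file
#'
#' SDF records are parsed with ChemmineR; MOL2 with bio3d. Records whose
#' coordinates are flat in z (2D depictions) are rejected with a warning;
#' unparseable records are skipped with a message naming the record.
#'
#' Per-record data fields `COMPOUND_ID`, `POSE_INDEX`, `PARTIAL_CHARGES`
#' and `FORMAL_CHARGES` (whitespace-separated, one value per atom) are
#' honoured when present; otherwise the compound id is the molecule name and
#' pose indices are assigned sequentially per compound.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sdf"` or `"mol2"`.
#' @return A list of [ligand_pose] objects.
#' @export
read_poses <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     stopf("cannot infer format of '%s'; pass format=", path))
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "sdf") read_poses_sdf(path) else read_poses_mol2(path)
}

read_poses_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  poses <- list()
  counter <- new.env(parent = emptyenv())
  for (r in seq_along(ChemmineR::sdfid(sdfs))) {
    rec <- sdfs[[r]]
    name <- ChemmineR::sdfid(sdfs)[r]
    ab <- ChemmineR::atomblock(rec)
    bb <- ChemmineR::bondblock(rec)
    db <- ChemmineR::datablock(rec)
    elements <- sub("_\\d+$", "", rownames(ab))
    xyz <- ab[, 1:3, drop = FALSE]
    if (nrow(xyz) == 0L) {
      message(sprintf("skipping empty record '%s'", name)); next
    }
    if (all(abs(xyz[, 3]) < 1e-8)) {
      warnf("record '%s' has 2D-only coordinates; rejected", name); next
    }
    nb <- if (is.null(dim(bb))) 0L else nrow(bb)
    bonds <- if (nb) {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    n <- nrow(xyz)
    cid <- if ("COMPOUND_ID" %in% names(db)) unname(db[["COMPOUND_ID"]]) else name
    fchg <- if ("FORMAL_CHARGES" %in% names(db)) {
      as.integer(strsplit(trimws(db[["FORMAL_CHARGES"]]), "\\s+")[[1]])
    } else rep(0L, n)
    pchg <- if ("PARTIAL_CHARGES" %in% names(db)) {
      v <- strsplit(trimws(db[["PARTIAL_CHARGES"]]), "\\s+")[[1]]
      ifelse(v == "NA", NA_real_, suppressWarnings(as.numeric(v)))
    } else rep(NA_real_, n)
    if (length(fchg) != n || length(pchg) != n) {
      message(sprintf("skipping record '%s': charge field length mismatch", name))
      next
    }
    idx <- if ("POSE_INDEX" %in% names(db)) {
      as.integer(db[["POSE_INDEX"]])
    } else {
      k <- (get0(cid, envir = counter, ifnotfound = 0L)) + 1L
      assign(cid, k, envir = counter)
      k
    }
    atoms <- data.frame(element = elements, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], formal_charge = fchg, charge = pchg)
    poses[[length(poses) + 1L]] <-
      ligand_pose(cid, atoms, bonds, pose_index = idx)
  }
  poses
}

read_poses_mol2 <- function(path) {
  m <- bio3d::read.mol2(path)
  recs <- if (inherits(m, "mol2")) list(m) else m
  lapply(seq_along(recs), function(r) {
    mm <- recs[[r]]
    at <- mm$atom
    elements <- sub("\\..*$", "", at$elety)
    bonds <- if (!is.null(mm$bond) && nrow(mm$bond)) {
      ord <- mm$bond$type
      ordn <- suppressWarnings(as.integer(ord))
      ordn[tolower(ord) %in% c("ar", "am")] <- c(4L, 1L)[match(
        tolower(ord[tolower(ord) %in% c("ar", "am")]), c("ar", "am"))]
      ordn[is.na(ordn)] <- 1L
      data.frame(i = as.integer(mm$bond$origin),
                 j = as.integer(mm$bond$target), order = ordn)
    } else NULL
    atoms <- data.frame(element = elements, x = at$x, y = at$y, z = at$z,
                        formal_charge = 0L,
                        charge = if (!is.null(at$charge)) at$charge else NA_real_)
    nm <- mm$name %||% sprintf("mol2_%d", r)
    ligand_pose(as.character(nm), atoms, bonds, pose_index = r)
  })
}

#' Write ligand poses to an SDF file
#'
#' V2000 SDF via ChemmineR, with partial/formal charges and pose metadata in
#' data fields (`PARTIAL_CHARGES`, `FORMAL_CHARGES`, `COMPOUND_ID`,
#' `POSE_INDEX`) so that [read_poses] round-trips them.
#'
#' @param poses list of [ligand_pose].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path) {
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    n <- nrow(p$atoms)
    nb <- nrow(p$bonds)
    lines <- c(
      p$compound_id, "  comfa", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              p$atoms$x, p$atoms$y, p$atoms$z, p$atoms$element),
      if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                      p$bonds$i, p$bonds$j, p$bonds$order),
      "M  END",
      "> <COMPOUND_ID>", p$compound_id, "",
      "> <POSE_INDEX>", as.character(p$pose_index), "",
      "> <FORMAL_CHARGES>",
      paste(p$atoms$formal_charge, collapse = " "), "",
      "> <PARTIAL_CHARGES>",
      paste(ifelse(is.na(p$atoms$charge), "NA",
                   sprintf("%.6f", p$atoms$charge)), collapse = " "), "",
      "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Locate the receptor carboxylate anchor
#'
#' Finds the side-chain carboxylate oxygen pair of an aspartate (OD1/OD2) or
#' glutamate (OE1/OE2) residue in a receptor PDB file. For the dopamine D2
#' receptor this is the conserved Asp114 (Ballesteros-Weinstein 3.32) that
#' salt-bridges the protonatable nitrogen of orthosteric ligands.
#'
#' @param receptor_pdb path to a PDB file.
#' @param chain chain identifier (`NA` matches any chain).
#' @param resno residue number.
#' @param resname residue name, `"ASP"` or `"GLU"`.
#' @return An `anchor_site`: the two oxygen positions and a residue label.
#' @export
locate_anchor <- function(receptor_pdb, chain = NA, resno, resname = "ASP") {
  pdb <- bio3d::read.pdb(receptor_pdb)
  at <- pdb$atom
  sel <- at$resno == resno & toupper(at$resid) == toupper(resname)
  if (!is.na(chain)) sel <- sel & at$chain == chain
  onames <- if (toupper(resname) == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
  rows <- at[sel & at$elety %in% onames, , drop = FALSE]
  if (nrow(rows) != 2L) {
    stopf("residue %s%s:%s with atoms %s/%s not found in %s",
          ifelse(is.na(chain), "", paste0(chain, ":")), resno, resname,
          onames[1], onames[2], receptor_pdb)
  }
  o1 <- as.numeric(rows[rows$elety == onames[1], c("x", "y", "z")])
  o2 <- as.numeric(rows[rows$elety == onames[2], c("x", "y", "z")])
  anchor_site(o1, o2, sprintf("%s%d", resname, resno))
}

#' @rdname locate_anchor
#' @param o1,o2 numeric length-3 positions of the two carboxylate oxygens.
#' @param residue_label label such as `"ASP114"`.
#' @export
anchor_site <- function(o1, o2, residue_label = "anchor") {
  o1 <- as.numeric(o1); o2 <- as.numeric(o2)
  stopifnot(length(o1) == 3L, length(o2) == 3L)
  d <- sqrt(sum((o1 - o2)^2))
  if (d > 2.5) {
    stopf("carboxylate oxygens %.2f Angstrom apart (> 2.5): not one carboxylate",
          d)
  }
  structure(list(o1 = o1, o2 = o2, residue_label = residue_label),
            class = "anchor_site")
}
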
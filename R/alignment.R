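# Docking-pose selection by the salt-bridge alignment criterion: the
# protonatable nitrogen of each ligand must contact the conserved receptor
# aspartate; one representative pose per compound is retained.

#' Find protonatable nitrogens
#'
#' Returns indices of nitrogens carrying formal charge +1; if none exist,
#' falls back to neutral sp3 amine nitrogens that are neither amide
#' (bonded to a carbonyl carbon) nor aniline-type (bonded to an aromatic
#' carbon). Indices are returned in ascending order.
#'
#' @param pose a [ligand_pose].
#' @return integer vector of atom indices (may be empty: compound is then
#'   un-alignable).
#' @export
find_protonatable_nitrogens <- function(pose) {
  a <- pose$atoms
  el <- toupper(a$element)
  cationic <- which(el == "N" & a$formal_charge > 0)
  if (length(cationic)) return(sort(cationic))
  b <- pose$bonds
  neighbours <- function(i) {
    c(b$j[b$i == i], b$i[b$j == i])
  }
  cand <- integer(0)
  hyb <- atom_hybridisation(pose)
  cls <- a$atom_class
  for (i in which(el == "N" & a$formal_charge == 0)) {
    if (hyb[i] != "sp3") next
    nb <- neighbours(i)
    amide <- any(vapply(nb, function(j) {
      if (el[j] != "C") return(FALSE)
      jj <- neighbours(j)
      any(el[jj] == "O" & vapply(jj, function(k) {
        any((b$i == j & b$j == k | b$i == k & b$j == j) & b$order == 2L)
      }, logical(1)))
    }, logical(1)))
    aniline <- any(cls[nb] == "aromatic-C")
    if (!amide && !aniline) cand <- c(cand, i)
  }
  sort(cand)
}

# Minimum distance from any protonatable N of `pose` to either anchor oxygen.
anchor_distance <- function(pose, anchor) {
  nid <- find_protonatable_nitrogens(pose)
  if (!length(nid)) return(Inf)
  xyz <- atom_coords(pose)[nid, , drop = FALSE]
  d1 <- sqrt(rowSums((xyz - matrix(anchor$o1, length(nid), 3, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((xyz - matrix(anchor$o2, length(nid), 3, byrow = TRUE))^2))
  min(d1, d2)
}

#' Salt-bridge pose filter
#'
#' A pose passes when the minimum distance from any of its protonatable
#' nitrogens to either carboxylate oxygen of the anchor is at most
#' `max_dist` (default 4.0 Angstrom, a typical salt-bridge cutoff).
#'
#' @param poses list of [ligand_pose] in the anchor frame.
#' @param anchor an [anchor_site].
#' @param max_dist distance cutoff in Angstrom.
#' @return the passing poses, with the achieved distance in attribute
#'   `"distances"`.
#' @export
salt_bridge_filter <- function(poses, anchor, max_dist = 4.0) {
  if (!length(poses)) return(list())
  d <- vapply(poses, anchor_distance, numeric(1), anchor = anchor)
  keep <- which(d <= max_dist)
  out <- poses[keep]
  attr(out, "distances") <- d[keep]
  out
}

# Fraction of reference heavy atoms with a same-class atom of `pose` within
# 1.5 Angstrom ("superposition of chemically equivalent moieties" made
# operational).
overlap_score <- function(pose, reference, tol = 1.5) {
  ref_idx <- heavy_atoms(reference)
  if (!length(ref_idx)) return(0)
  rc <- atom_coords(reference)[ref_idx, , drop = FALSE]
  rcls <- reference$atoms$atom_class[ref_idx]
  pidx <- heavy_atoms(pose)
  pc <- atom_coords(pose)[pidx, , drop = FALSE]
  pcls <- pose$atoms$atom_class[pidx]
  hits <- vapply(seq_along(ref_idx), function(m) {
    same <- which(pcls == rcls[m])
    if (!length(same)) return(FALSE)
    min(sqrt(rowSums((pc[same, , drop = FALSE] -
      matrix(rc[m, ], length(same), 3, byrow = TRUE))^2))) <= tol
  }, logical(1))
  mean(hits)
}

#' Select the representative pose of a compound
#'
#' Deterministic selection among poses that already passed the salt-bridge
#' filter: minimise anchor-nitrogen distance, break ties by maximal
#' heavy-atom overlap with the reference pose (the selected pose of the most
#' active compound of the same family), then by smallest pose index.
#'
#' @param poses list of passing [ligand_pose] of one compound.
#' @param anchor an [anchor_site].
#' @param reference optional reference [ligand_pose].
#' @return the selected [ligand_pose].
#' @export
select_representative_pose <- function(poses, anchor, reference = NULL) {
  if (!length(poses)) stopf("no passing pose to select from")
  d <- vapply(poses, anchor_distance, numeric(1), anchor = anchor)
  ov <- if (is.null(reference)) rep(0, length(poses)) else
    vapply(poses, overlap_score, numeric(1), reference = reference)
  pid <- vapply(poses, function(p) p$pose_index, integer(1))
  ord <- order(round(d, 9), -round(ov, 9), pid)
  poses[[ord[1]]]
}

#' Assemble the aligned dataset
#'
#' Applies the salt-bridge filter per compound, selects one representative
#' pose each (using the most active compound of each family, processed in
#' decreasing activity order, as overlap reference), and joins activities.
#' Compounds without a qualifying pose are dropped and reported in the
#' `dropped` component rather than force-aligned.
#'
#' @param poses list of [ligand_pose] (multiple poses per compound allowed).
#' @param activities activity data.frame (`compound_id`, `pic50`, optional
#'   `family`).
#' @param anchor an [anchor_site].
#' @param max_dist salt-bridge cutoff in Angstrom.
#' @return An `aligned_dataset`: one pose per compound, activities, anchor,
#'   and a `dropped` data.frame with reasons.
#' @export
build_aligned_dataset <- function(poses, activities, anchor, max_dist = 4.0) {
  activities <- as.data.frame(activities)
  if (is.null(activities$family)) activities$family <- "all"
  ids <- vapply(poses, function(p) p$compound_id, character(1))
  frame_ids <- unique(vapply(poses, function(p) as.character(p$frame_id), character(1)))
  if (length(frame_ids) > 1L) {
    stopf("poses come from different frames: %s", paste(frame_ids, collapse = ", "))
  }
  act <- activities[activities$compound_id %in% ids, , drop = FALSE]
  act <- act[order(-act$pic50), , drop = FALSE]
  selected <- list()
  refs <- list()   # per-family reference pose
  dropped <- data.frame(compound_id = character(0), reason = character(0))
  for (r in seq_len(nrow(act))) {
    cid <- as.character(act$compound_id[r])
    fam <- as.character(act$family[r])
    cand <- poses[ids == cid]
    if (!any(vapply(cand, function(p) length(find_protonatable_nitrogens(p)) > 0,
                    logical(1)))) {
      dropped <- rbind(dropped, data.frame(compound_id = cid,
                                           reason = "no protonatable nitrogen"))
      next
    }
    pass <- salt_bridge_filter(cand, anchor, max_dist)
    if (!length(pass)) {
      dropped <- rbind(dropped, data.frame(compound_id = cid,
                                           reason = sprintf("no pose within %.1f A of anchor", max_dist)))
      next
    }
    sel <- select_representative_pose(pass, anchor, reference = refs[[fam]])
    if (is.null(refs[[fam]])) refs[[fam]] <- sel
    selected[[cid]] <- sel
  }
  keep <- activities$compound_id %in% names(selected)
  out_act <- activities[keep, , drop = FALSE]
  structure(list(poses = selected[as.character(out_act$compound_id)],
                 activities = out_act, anchor = anchor,
                 max_dist = max_dist, dropped = dropped),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> %d compounds aligned (%d dropped), anchor %s\n",
              length(x$poses), nrow(x$dropped), x$anchor$residue_label))
  invisible(x)
}
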
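# Point-charge assignment: Gasteiger-Marsili PEOE sigma charges plus an
# optional simple-Hueckel pi term (the "Gasteiger-Hueckel" scheme).

# PEOE electronegativity parameters chi(q) = a + b q + c q^2 (eV), by
# element and hybridisation (Gasteiger & Marsili 1980 published set).
peoe_param_table <- function() {
  tab <- rbind(
    c("H",  "sp3",  7.17,  6.24, -0.56),
    c("C",  "sp3",  7.98,  9.18,  1.88),
    c("C",  "sp2",  8.79,  9.32,  1.51),
    c("C",  "sp",  10.39,  9.45,  0.73),
    c("N",  "sp3", 11.54, 10.82,  1.36),
    c("N",  "sp2", 12.87, 11.15,  0.85),
    c("N",  "sp",  15.68, 11.70, -0.27),
    c("O",  "sp3", 14.18, 12.92,  1.39),
    c("O",  "sp2", 17.07, 13.79,  0.47),
    c("F",  "sp3", 14.66, 13.85,  2.31),
    c("CL", "sp3", 11.00,  9.69,  1.35),
    c("BR", "sp3", 10.08,  8.47,  1.16),
    c("I",  "sp3",  9.90,  7.96,  0.96),
    c("S",  "sp3", 10.14,  9.13,  1.38),
    c("S",  "sp2", 10.14,  9.13,  1.38),
    c("P",  "sp3",  8.90,  8.24,  0.96))
  data.frame(element = tab[, 1], hyb = tab[, 2],
             a = as.numeric(tab[, 3]), b = as.numeric(tab[, 4]),
             cc = as.numeric(tab[, 5]))
}

#' Gasteiger (PEOE) sigma charges
#'
#' Iterative partial equalisation of orbital electronegativity. Per bond and
#' iteration k, charge `(chi_high - chi_low) / chi_plus_low * damping^k`
#' flows onto the less electronegative atom, where `chi_plus_low` is the
#' cation electronegativity of that atom (20.02 eV for hydrogen). Charges
#' are seeded with `seed_charges` (by default the formal charges) and total
#' charge is conserved exactly.
#'
#' @param pose a [ligand_pose] with bonds and formal charges set.
#' @param iterations number of damped PEOE iterations.
#' @param damping per-iteration damping factor.
#' @param seed_charges optional numeric start charges (defaults to formal
#'   charges).
#' @return numeric vector of sigma charges, one per atom.
#' @export
gasteiger_sigma_charges <- function(pose, iterations = 8L, damping = 0.5,
                                    seed_charges = NULL) {
  a <- pose$atoms
  n <- nrow(a)
  hyb <- atom_hybridisation(pose)
  el <- toupper(a$element)
  tab <- peoe_param_table()
  key <- paste(el, hyb)
  hit <- match(key, paste(tab$element, tab$hyb))
  # fall back to the element's sp3 row where no hybrid-specific row exists
  miss <- is.na(hit)
  hit[miss] <- match(paste(el[miss], "sp3"), paste(tab$element, tab$hyb))
  if (anyNA(hit)) {
    stopf("no PEOE electronegativity parameters for atom(s): %s",
          paste(unique(el[is.na(hit)]), collapse = ", "))
  }
  pa <- tab$a[hit]; pb <- tab$b[hit]; pc <- tab$cc[hit]
  chi_plus <- ifelse(el == "H", 20.02, pa + pb + pc)
  q <- if (is.null(seed_charges)) as.numeric(a$formal_charge) else as.numeric(seed_charges)
  stopifnot(length(q) == n)
  bi <- pose$bonds$i; bj <- pose$bonds$j
  if (!length(bi)) return(q)
  for (k in seq_len(iterations)) {
    chi <- pa + pb * q + pc * q^2
    dchi <- chi[bj] - chi[bi]
    denom <- ifelse(dchi > 0, chi_plus[bi], chi_plus[bj])
    dq <- (abs(dchi) / denom) * damping^k
    # charge flows onto the less electronegative end of each bond
    flow_i <- ifelse(dchi > 0, dq, -dq)
    dq_atom <- numeric(n)
    for (m in seq_along(bi)) {
      dq_atom[bi[m]] <- dq_atom[bi[m]] + flow_i[m]
      dq_atom[bj[m]] <- dq_atom[bj[m]] - flow_i[m]
    }
    q <- q + dq_atom
  }
  q
}

# Hueckel heteroatom parameters: coulomb increment h (alpha + h*beta) and
# the number of pi electrons z the atom donates, by donor type.
huckel_site_params <- function(el, two_e, cationic) {
  if (el == "C") return(c(h = 0.0, z = 1))
  if (el == "N" && cationic) return(c(h = 2.0, z = 2))
  if (el == "N" && two_e) return(c(h = 1.5, z = 2))
  if (el == "N") return(c(h = 0.5, z = 1))
  if (el == "O" && two_e) return(c(h = 2.0, z = 2))
  if (el == "O") return(c(h = 1.0, z = 1))
  if (el == "S") return(c(h = 1.3, z = 2))
  c(h = NA_real_, z = NA_real_)
}

#' Simple Hueckel pi-charge increments
#'
#' Detects conjugated fragments (atoms in double/triple/aromatic bonds plus
#' directly attached lone-pair donors N/O/S), builds the topological Hueckel
#' matrix with standard heteroatom parameters, fills orbitals by electron
#' count (degenerate shells are occupied uniformly) and returns per-atom
#' pi-charge increments. Increments over a fragment sum to the fragment's
#' net formal charge; fragments with an odd (open-shell) electron count are
#' skipped with a warning.
#'
#' @param pose a [ligand_pose].
#' @return numeric vector of pi increments, one per atom (0 outside
#'   conjugated fragments).
#' @export
huckel_pi_charges <- function(pose) {
  a <- pose$atoms
  b <- pose$bonds
  n <- nrow(a)
  inc <- numeric(n)
  attr(inc, "pi_atoms") <- integer(0)
  if (!nrow(b)) return(inc)
  el <- toupper(a$element)
  in_multi <- rep(FALSE, n)
  mb <- b[b$order %in% c(2L, 3L, 4L), , drop = FALSE]
  in_multi[c(mb$i, mb$j)] <- TRUE
  # lone-pair donors singly bonded to a pi atom
  donor <- rep(FALSE, n)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L) next
    for (pair in list(c(b$i[k], b$j[k]), c(b$j[k], b$i[k]))) {
      u <- pair[1]; v <- pair[2]
      if (!in_multi[u] && in_multi[v] && el[u] %in% c("N", "O", "S")) {
        donor[u] <- TRUE
      }
    }
  }
  pi_atoms <- which(in_multi | donor)
  processed <- integer(0)
  if (!length(pi_atoms)) {
    attr(inc, "pi_atoms") <- processed
    return(inc)
  }
  # connected components over bonds joining two pi atoms
  comp <- rep(NA_integer_, n)
  nextc <- 0L
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(b))) {
    if (b$i[k] %in% pi_atoms && b$j[k] %in% pi_atoms) {
      adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
      adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
    }
  }
  for (s in pi_atoms) {
    if (!is.na(comp[s])) next
    nextc <- nextc + 1L
    stack <- s
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[u])) next
      comp[u] <- nextc
      stack <- c(stack, adj[[u]][is.na(comp[adj[[u]]])])
    }
  }
  for (f in seq_len(nextc)) {
    mem <- which(comp == f)
    if (length(mem) < 2L) next
    hz <- t(vapply(mem, function(i) {
      huckel_site_params(el[i], donor[i], a$formal_charge[i] > 0)
    }, c(h = 0, z = 0)))
    if (anyNA(hz)) {
      warnf("conjugated fragment with unparameterised atom(s) skipped")
      next
    }
    net <- sum(a$formal_charge[mem])
    nelec <- sum(hz[, "z"]) - net
    if (nelec %% 2 != 0 || nelec < 0) {
      warnf("open-shell pi fragment (%g electrons) skipped", nelec)
      next
    }
    m <- length(mem)
    H <- matrix(0, m, m)
    diag(H) <- hz[, "h"]
    for (k in seq_len(nrow(b))) {
      ii <- match(b$i[k], mem); jj <- match(b$j[k], mem)
      if (is.na(ii) || is.na(jj)) next
      pairk <- sort(c(el[b$i[k]], el[b$j[k]]))
      kXY <- if (all(pairk == c("C", "C"))) 1.0
        else if (all(pairk == c("C", "N"))) 0.9
        else if (all(pairk == c("C", "O"))) if (b$order[k] >= 2) 1.0 else 0.8
        else if (all(pairk == c("C", "S"))) 0.7
        else 0.8
      H[ii, jj] <- H[jj, ii] <- kXY
    }
    eig <- eigen(H, symmetric = TRUE)
    # orbital energies alpha + lambda*beta, beta < 0: fill largest lambda first
    lam <- eig$values
    vec <- eig$vectors
    pop <- numeric(m)
    remaining <- nelec
    groups <- split(seq_len(m), round(lam, 8))
    for (g in rev(groups)) {        # descending lambda
      if (remaining <= 0) break
      cap <- 2 * length(g)
      fill <- min(remaining, cap)
      occ_per_orb <- fill / length(g)
      sq <- vec[, g, drop = FALSE]^2
      pop <- pop + rowSums(sq) * occ_per_orb
      remaining <- remaining - fill
    }
    inc[mem] <- hz[, "z"] - pop
    processed <- c(processed, mem)
  }
  attr(inc, "pi_atoms") <- processed
  inc
}

#' Assign point charges to a pose
#'
#' `method = "peoe"` (the tested default) assigns plain Gasteiger sigma
#' charges seeded with formal charges. `method = "gh"` adds the simple
#' Hueckel pi increments; formal charges carried by pi-system atoms are then
#' allocated to the pi step (their sigma seed is 0), so total charge remains
#' the sum of formal charges in both modes.
#'
#' @inheritParams gasteiger_sigma_charges
#' @param method `"peoe"` or `"gh"`.
#' @return the pose with `atoms$charge` populated.
#' @export
assign_charges <- function(pose, method = c("peoe", "gh"),
                           iterations = 8L, damping = 0.5) {
  method <- match.arg(method)
  if (method == "peoe") {
    q <- gasteiger_sigma_charges(pose, iterations, damping)
  } else {
    pi_inc <- huckel_pi_charges(pose)
    seed <- as.numeric(pose$atoms$formal_charge)
    seed[attr(pi_inc, "pi_atoms")] <- 0
    q <- gasteiger_sigma_charges(pose, iterations, damping,
                                 seed_charges = seed) + as.numeric(pi_inc)
  }
  tot <- sum(q)
  if (abs(tot - net_formal_charge(pose)) > 1e-6) {
    stopf("charge conservation violated on '%s': sum %.8f vs net formal %d",
          pose$compound_id, tot, net_formal_charge(pose))
  }
  pose$atoms$charge <- q
  pose
}
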
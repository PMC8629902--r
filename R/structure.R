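# Protein-DNA structure handling and contact enumeration.

PROTEIN_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL")
DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DI", "A", "C", "G", "T", "U")
WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD")
ION_RESIDUES <- c("ZN", "NA", "CL", "MG", "K", "CA", "MN", "FE", "CU")

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                 S = 32.06, ZN = 65.38)

.element_of <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  guess <- toupper(substr(trimws(elety), 1L, 1L))
  ifelse(is.na(el) | el == "", guess, el)
}

#' Read a protein-DNA complex from a PDB file
#'
#' Parses ATOM/HETATM records via `bio3d::read.pdb`, partitions residues into
#' protein and DNA by residue dictionary, and drops waters and monoatomic
#' ions (reported via `message()`).
#'
#' @param path PDB file path.
#' @return object of class `"zf_structure"`: list with `atoms` (data.frame:
#'   `eleno`, `elety`, `element`, `resid`, `resno`, `chain`, `x`, `y`, `z`,
#'   `role`) and `path`.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  atoms <- data.frame(eleno = a$eleno, elety = trimws(a$elety),
                      element = .element_of(a$elesy, a$elety),
                      resid = trimws(a$resid), resno = a$resno,
                      chain = a$chain, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  role <- rep(NA_character_, nrow(atoms))
  role[atoms$resid %in% PROTEIN_RESIDUES] <- "protein"
  role[atoms$resid %in% DNA_RESIDUES] <- "dna"
  drop_w <- atoms$resid %in% WATER_RESIDUES
  drop_i <- atoms$resid %in% ION_RESIDUES
  if (any(drop_w)) message("dropped ", sum(drop_w), " water atom(s)")
  if (any(drop_i)) message("dropped ", sum(drop_i), " ion atom(s)")
  unknown <- is.na(role) & !drop_w & !drop_i
  if (any(unknown))
    message("dropped ", sum(unknown), " atom(s) with unrecognised residue: ",
            paste(unique(atoms$resid[unknown]), collapse = ", "))
  atoms <- atoms[!is.na(role), , drop = FALSE]
  atoms$role <- role[!is.na(role)]
  if (!any(atoms$role == "protein"))
    stop("no protein chain found in '", path, "'", call. = FALSE)
  if (!any(atoms$role == "dna"))
    stop("no DNA chain found in '", path, "'", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path), class = "zf_structure")
}

#' @export
print.zf_structure <- function(x, ...) {
  cat("<zf_structure> ", sum(x$atoms$role == "protein"), " protein / ",
      sum(x$atoms$role == "dna"), " DNA atoms\n", sep = "")
  invisible(x)
}

#' Geometric contact criteria
#'
#' Defaults: hydrogen bond, donor-acceptor N/O heavy-atom distance <= 3.5 A
#' (with a D-H...A angle >= 120 degrees required only when the structure
#' contains hydrogens); electrostatic, protein cationic N to DNA phosphate O
#' <= 4.0 A; hydrophobic, apolar carbon pair <= 4.5 A; cation-pi, cationic
#' group to base-ring centroid <= 6.0 A.
#'
#' @param hbond_dist,elec_dist,hydrophobic_dist,cation_pi_dist cutoffs in
#'   Angstrom.
#' @param hbond_angle minimum donor-H-acceptor angle in degrees.
#' @return named list of parameters.
#' @export
contact_params <- function(hbond_dist = 3.5, elec_dist = 4.0,
                           hydrophobic_dist = 4.5, cation_pi_dist = 6.0,
                           hbond_angle = 120) {
  list(hbond_dist = hbond_dist, elec_dist = elec_dist,
       hydrophobic_dist = hydrophobic_dist, cation_pi_dist = cation_pi_dist,
       hbond_angle = hbond_angle)
}

# atom typing ----------------------------------------------------------------

PROT_CATION_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                          HIS = c("ND1", "NE2"))
DNA_PHOSPHATE_O <- c("OP1", "OP2", "O1P", "O2P")
DNA_RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
DNA_APOLAR_C <- c("C1'", "C2'", "C3'", "C4'", "C5'", "C7", "C5M")

.is_cation <- function(atoms) {
  out <- logical(nrow(atoms))
  for (res in names(PROT_CATION_ATOMS))
    out <- out | (atoms$resid == res & atoms$elety %in% PROT_CATION_ATOMS[[res]])
  out
}

.is_apolar_protein_c <- function(atoms) {
  atoms$element == "C" & !(atoms$elety %in% c("C", "CA")) &
    !(atoms$resid == "ARG" & atoms$elety == "CZ")
}

.is_apolar_dna_c <- function(atoms) {
  atoms$element == "C" & atoms$elety %in% DNA_APOLAR_C
}

.pair_dist <- function(atoms, i, j) {
  sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
       (atoms$z[i] - atoms$z[j])^2)
}

# candidate protein/DNA atom index pairs within `cutoff`
.candidates_naive <- function(atoms, cutoff) {
  pi_ <- which(atoms$role == "protein")
  di_ <- which(atoms$role == "dna")
  if (!length(pi_) || !length(di_))
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  pm <- as.matrix(atoms[pi_, c("x", "y", "z")])
  dm <- as.matrix(atoms[di_, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(dm^2), `+`) - 2 * pm %*% t(dm)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  data.frame(i = pi_[hit[, 1]], j = di_[hit[, 2]],
             d = sqrt(d2[hit]))
}

.candidates_cell <- function(atoms, cutoff) {
  pi_ <- which(atoms$role == "protein")
  di_ <- which(atoms$role == "dna")
  if (!length(pi_) || !length(di_))
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  key <- function(ix, iy, iz) paste(ix, iy, iz, sep = ",")
  cx <- floor(atoms$x / cutoff); cy <- floor(atoms$y / cutoff)
  cz <- floor(atoms$z / cutoff)
  dna_cells <- split(di_, key(cx[di_], cy[di_], cz[di_]))
  res_i <- integer(); res_j <- integer(); res_d <- numeric()
  for (i in pi_) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      js <- dna_cells[[key(cx[i] + dx, cy[i] + dy, cz[i] + dz)]]
      if (is.null(js)) next
      dd <- sqrt((atoms$x[js] - atoms$x[i])^2 +
                 (atoms$y[js] - atoms$y[i])^2 +
                 (atoms$z[js] - atoms$z[i])^2)
      keep <- dd <= cutoff
      if (any(keep)) {
        res_i <- c(res_i, rep(i, sum(keep)))
        res_j <- c(res_j, js[keep])
        res_d <- c(res_d, dd[keep])
      }
    }
  }
  data.frame(i = res_i, j = res_j, d = res_d)
}

.hbond_angle_ok <- function(atoms, i, j, min_angle) {
  hs <- which(atoms$element == "H")
  if (!length(hs)) return(TRUE)
  for (donor in c(i, j)) {
    acc <- if (donor == i) j else i
    near <- hs[atoms$resno[hs] == atoms$resno[donor] &
               atoms$role[hs] == atoms$role[donor]]
    near <- near[vapply(near, function(h) .pair_dist(atoms, donor, h) <= 1.25,
                        logical(1))]
    for (h in near) {
      dh <- c(atoms$x[donor] - atoms$x[h], atoms$y[donor] - atoms$y[h],
              atoms$z[donor] - atoms$z[h])
      ah <- c(atoms$x[acc] - atoms$x[h], atoms$y[acc] - atoms$y[h],
              atoms$z[acc] - atoms$z[h])
      cosang <- sum(dh * ah) / (sqrt(sum(dh^2)) * sqrt(sum(ah^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= min_angle) return(TRUE)
    }
  }
  # donors present but no hydrogen attached to either partner: fall back to
  # the distance-only criterion for this pair
  has_local_h <- any(atoms$element[hs] == "H" &
                     (atoms$resno[hs] %in% atoms$resno[c(i, j)]))
  !has_local_h
}

#' Detect protein-DNA contacts
#'
#' Enumerates hydrogen-bond, electrostatic, hydrophobic and cation-pi
#' contacts between protein and DNA atoms under the geometric criteria in
#' [contact_params()]. When one atom pair satisfies several categories the
#' precedence is hydrogen_bond > electrostatic > hydrophobic (cation-pi is
#' evaluated between a cationic group and a base-ring centroid, so it never
#' shares an atom-pair key). The result is sorted deterministically by
#' (protein residue, DNA residue, category, atoms).
#'
#' @param structure a `"zf_structure"`.
#' @param params criteria from [contact_params()].
#' @param method neighbour search: `"cell"` (linked cells, default) or
#'   `"naive"` (all pairs); both give identical results and the naive scan
#'   serves as the oracle in tests.
#' @return data.frame with `category`, `protein_resno`, `protein_resid`,
#'   `protein_atom`, `dna_resno`, `dna_resid`, `dna_atom`, `distance`.
#' @export
detect_contacts <- function(structure, params = contact_params(),
                            method = c("cell", "naive")) {
  method <- match.arg(method)
  atoms <- structure$atoms
  cutoff <- max(params$hbond_dist, params$elec_dist, params$hydrophobic_dist)
  cand <- if (method == "cell") .candidates_cell(atoms, cutoff)
          else .candidates_naive(atoms, cutoff)
  rows <- list()
  if (nrow(cand)) {
    is_no <- atoms$element %in% c("N", "O")
    cation <- .is_cation(atoms)
    apolar_p <- .is_apolar_protein_c(atoms)
    apolar_d <- .is_apolar_dna_c(atoms)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]; d <- cand$d[k]
      if (atoms$element[i] == "H" || atoms$element[j] == "H") next
      cat_ <- NULL
      if (is_no[i] && is_no[j] && d <= params$hbond_dist &&
          .hbond_angle_ok(atoms, i, j, params$hbond_angle)) {
        cat_ <- "hydrogen_bond"
      } else if (cation[i] && atoms$elety[j] %in% DNA_PHOSPHATE_O &&
                 d <= params$elec_dist) {
        cat_ <- "electrostatic"
      } else if (apolar_p[i] && apolar_d[j] && d <= params$hydrophobic_dist) {
        cat_ <- "hydrophobic"
      }
      if (is.null(cat_)) next
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_, protein_resno = atoms$resno[i],
        protein_resid = atoms$resid[i], protein_atom = atoms$elety[i],
        dna_resno = atoms$resno[j], dna_resid = atoms$resid[j],
        dna_atom = atoms$elety[j], distance = d, stringsAsFactors = FALSE)
    }
  }
  rows <- c(rows, .cation_pi_contacts(atoms, params))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), protein_resno = integer(),
               protein_resid = character(), protein_atom = character(),
               dna_resno = integer(), dna_resid = character(),
               dna_atom = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  ord <- order(out$protein_resno, out$dna_resno, out$category,
               out$protein_atom, out$dna_atom, out$distance)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cation_pi_contacts <- function(atoms, params) {
  rows <- list()
  cation <- which(.is_cation(atoms) & atoms$role == "protein")
  if (!length(cation)) return(rows)
  dna <- atoms[atoms$role == "dna", , drop = FALSE]
  for (rn in unique(dna$resno)) {
    ring <- dna[dna$resno == rn & dna$elety %in% DNA_RING_ATOMS, ,
                drop = FALSE]
    if (nrow(ring) < 5L) next
    cen <- c(mean(ring$x), mean(ring$y), mean(ring$z))
    for (i in cation) {
      d <- sqrt((atoms$x[i] - cen[1])^2 + (atoms$y[i] - cen[2])^2 +
                (atoms$z[i] - cen[3])^2)
      if (d <= params$cation_pi_dist)
        rows[[length(rows) + 1L]] <- data.frame(
          category = "cation_pi", protein_resno = atoms$resno[i],
          protein_resid = atoms$resid[i], protein_atom = atoms$elety[i],
          dna_resno = rn, dna_resid = ring$resid[1], dna_atom = "ring",
          distance = d, stringsAsFactors = FALSE)
    }
  }
  rows
}

CONTACT_CATEGORIES <- c("hydrogen_bond", "electrostatic", "hydrophobic",
                        "cation_pi")

#' Tally contacts per zinc finger
#'
#' Assigns each contact's protein residue to a finger via the architecture;
#' inter-ZF residues go to the nearest finger by sequence distance (ties to
#' the N-terminal one) and are additionally flagged in `n_from_linker`.
#'
#' @param contacts data.frame from [detect_contacts()].
#' @param architecture a [zf_architecture()].
#' @return object of class `"bond_tally"`: data.frame with one row per
#'   finger, a count column per category, `total` and `n_from_linker`;
#'   attribute `grand_total`.
#' @export
per_zf_bond_tally <- function(contacts, architecture) {
  zfs <- architecture$zfs
  nzf <- length(zfs)
  starts <- vapply(zfs, `[[`, integer(1), "start")
  ends <- vapply(zfs, `[[`, integer(1), "end")
  tal <- matrix(0L, nrow = nzf, ncol = length(CONTACT_CATEGORIES),
                dimnames = list(NULL, CONTACT_CATEGORIES))
  linker <- integer(nzf)
  z <- architecture$domains[architecture$domains$name == "Z", ]
  for (k in seq_len(nrow(contacts))) {
    p <- contacts$protein_resno[k]
    if (p < z$start || p > z$end)
      stop("contact residue ", p, " outside the Z domain", call. = FALSE)
    inside <- which(p >= starts & p <= ends)
    if (length(inside)) {
      zi <- inside[1]
    } else {
      dist <- pmin(abs(p - starts), abs(p - ends))
      zi <- which.min(dist)  # which.min takes the first (N-terminal) tie
      linker[zi] <- linker[zi] + 1L
    }
    tal[zi, contacts$category[k]] <- tal[zi, contacts$category[k]] + 1L
  }
  out <- data.frame(zf = seq_len(nzf), tal, total = rowSums(tal),
                    n_from_linker = linker)
  attr(out, "grand_total") <- sum(tal)
  class(out) <- c("bond_tally", class(out))
  out
}

#' Net change in per-finger bond counts versus a reference tally
#'
#' @param tally,reference `"bond_tally"` objects on the same architecture.
#' @return data.frame with `zf`, `total`, `reference_total`, `net_change`;
#'   attribute `net_total` is the grand-total difference.
#' @export
tally_net_change <- function(tally, reference) {
  stopifnot(nrow(tally) == nrow(reference))
  out <- data.frame(zf = tally$zf, total = tally$total,
                    reference_total = reference$total,
                    net_change = tally$total - reference$total)
  attr(out, "net_total") <- sum(out$net_change)
  out
}

.contact_keys <- function(contacts) {
  paste(contacts$protein_resno, contacts$protein_atom,
        contacts$dna_resno, contacts$dna_atom, contacts$category,
        sep = "|")
}

#' Bonds lost and gained between a reference and a variant contact set
#'
#' Contacts are keyed on (protein residue + atom, DNA residue + atom,
#' category); both inputs must share a residue-numbering frame.
#'
#' @param reference,variant contact data.frames from [detect_contacts()].
#' @return list with `lost` (in reference only) and `gained` (in variant
#'   only) data.frames; the two key sets are disjoint.
#' @export
bond_diff <- function(reference, variant) {
  kr <- .contact_keys(reference); kv <- .contact_keys(variant)
  list(lost = reference[!(kr %in% kv), , drop = FALSE],
       gained = variant[!(kv %in% kr), , drop = FALSE])
}

.centroid <- function(atoms, weighting) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (!nrow(atoms)) stop("empty selection", call. = FALSE)
  w <- if (weighting == "mass") {
    m <- ATOMIC_MASS[atoms$element]
    m[is.na(m)] <- mean(ATOMIC_MASS[c("C", "N", "O")])
    m
  } else rep(1, nrow(atoms))
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z)) / sum(w)
}

#' Distance between a protein selection centroid and a DNA centroid
#'
#' Mass-weighted heavy-atom centroids; the distance is internal to the
#' structure so no superposition is needed and it is invariant under rigid
#' transforms.
#'
#' @param structure a `"zf_structure"`.
#' @param protein_resno residue numbers to include (default: all protein
#'   residues). Pass a finger's `start:end` range to get a ZF centroid.
#' @param dna_resno DNA residue numbers (default: all).
#' @param weighting `"mass"` or `"geometric"`.
#' @return distance in Angstrom.
#' @export
centroid_distance <- function(structure, protein_resno = NULL,
                              dna_resno = NULL,
                              weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  a <- structure$atoms
  p <- a[a$role == "protein" &
         (if (is.null(protein_resno)) TRUE else a$resno %in% protein_resno), ,
         drop = FALSE]
  d <- a[a$role == "dna" &
         (if (is.null(dna_resno)) TRUE else a$resno %in% dna_resno), ,
         drop = FALSE]
  cp <- .centroid(p, weighting)
  cd <- .centroid(d, weighting)
  sqrt(sum((cp - cd)^2))
}

#' Net centroid shift of a variant relative to a reference structure
#'
#' `d(variant) - d(reference)`: positive values mean the selection moved
#' away from the DNA.
#'
#' @param variant,reference `"zf_structure"` objects sharing residue
#'   numbering.
#' @inheritParams centroid_distance
#' @return signed shift in Angstrom.
#' @export
net_shift <- function(variant, reference, protein_resno = NULL,
                      dna_resno = NULL, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  centroid_distance(variant, protein_resno, dna_resno, weighting) -
    centroid_distance(reference, protein_resno, dna_resno, weighting)
}

#' Classify a folding free-energy change
#'
#' `ddg` is the mutant-minus-wild-type change in folding free energy
#' (kcal/mol): values above 0.5 are destabilising, below -0.5 stabilising,
#' the band between is neutral. The energies themselves are consumed as
#' inputs (they come from an external energy function), only the threshold
#' classification is applied.
#'
#' @param ddg numeric vector of free-energy changes in kcal/mol.
#' @return data.frame with `ddg` and `label`.
#' @export
classify_stability <- function(ddg) {
  if (any(!is.finite(ddg))) stop("ddg must be finite", call. = FALSE)
  label <- ifelse(ddg > 0.5, "destabilising",
                  ifelse(ddg < -0.5, "stabilising", "neutral"))
  data.frame(ddg = ddg, label = label, stringsAsFactors = FALSE)
}
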
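# Seeded synthetic-data generators: architectures/sequences, mutation
# catalogues, structure pairs with planted contacts, noisy trajectories.
# All generators are pure functions of (spec, seed).

# amino acids that cannot seed a spurious C2H2 motif
.BACKGROUND_AA <- setdiff(AA_ALPHABET, c("C", "H"))

#' Generate a synthetic tandem zinc-finger protein
#'
#' Builds an amino-acid sequence containing `n_zf` ideal C2H2 fingers
#' (C-x2-C-x12-H-x4-H) separated by linkers, with an invariant Leu planted
#' at helix +4; background residues never contain Cys/His, so
#' [detect_zf_motifs()] recovers exactly the planted fingers.
#'
#' @param n_zf number of fingers (>= 1).
#' @param linker linker length between fingers (>= 1).
#' @param nterm,cterm lengths of the N-/C-terminal tails.
#' @param seed RNG seed.
#' @return list with `sequence` (string), `architecture`
#'   ([zf_architecture()], sequence attached) and `planted` (data.frame of
#'   planted anchor coordinates).
#' @export
synth_architecture <- function(n_zf = 3L, linker = 6L, nterm = 12L,
                               cterm = 12L, seed = 0L) {
  if (n_zf < 1L) stop("n_zf must be >= 1", call. = FALSE)
  if (linker < 1L) stop("linker length must be >= 1", call. = FALSE)
  set.seed(seed)
  bg <- function(n) sample(.BACKGROUND_AA, n, replace = TRUE)
  s <- character(0)
  planted <- data.frame(index = integer(), c1 = integer(), c2 = integer(),
                        h1 = integer(), h2 = integer())
  s <- c(s, bg(nterm))
  for (k in seq_len(n_zf)) {
    c1 <- length(s) + 1L
    unit <- c("C", bg(2L), "C", bg(12L), "H", bg(4L), "H")
    unit[4L + 10L] <- "L"  # helix +4 = h1 - 3
    s <- c(s, unit)
    planted <- rbind(planted, data.frame(index = k, c1 = c1, c2 = c1 + 3L,
                                         h1 = c1 + 16L, h2 = c1 + 21L))
    if (k < n_zf) s <- c(s, bg(linker))
  }
  s <- c(s, bg(cterm))
  seq_str <- paste(s, collapse = "")
  arch <- architecture_from_sequence(seq_str, name = "synthetic")
  list(sequence = seq_str, architecture = arch, planted = planted)
}

#' Synthetic CTCF-like sequence consistent with the shipped architecture
#'
#' The true human CTCF sequence is not bundled; this generator builds a
#' 727-residue stand-in that carries the architecture's Cys/His anchors, an
#' invariant Leu/Met at every helix +4, and the canonical residues discussed
#' for this protein (R339, K365, R377, G420, R448, S354, R457, Y226, R603,
#' T204), over a random Cys/His-free background. It is synthetic by
#' construction and labelled as such; motif detection and helix mapping on
#' it reproduce the real anchor geometry exactly.
#'
#' @param architecture the [ctcf_architecture()] (or compatible).
#' @param seed RNG seed for the background residues.
#' @return amino-acid string of length `architecture$protein_length`.
#' @export
ctcf_synthetic_sequence <- function(architecture, seed = 0L) {
  set.seed(seed)
  L <- architecture$protein_length
  s <- sample(.BACKGROUND_AA, L, replace = TRUE)
  for (zf in architecture$zfs) {
    s[c(zf$c1, zf$c2)] <- "C"
    s[zf$h1] <- "H"
    s[zf$h2] <- if (zf$zf_type == "C2HC") "C" else "H"
    # invariant hydrophobic at +4 (Met in a couple of fingers, Leu elsewhere)
    s[zf$h1 - 3L] <- if (zf$index %in% c(7L, 10L)) "M" else "L"
  }
  fixed <- c(`204` = "T", `226` = "Y", `339` = "R", `354` = "S", `365` = "K",
             `377` = "R", `420` = "G", `448` = "R", `457` = "R", `603` = "R")
  s[as.integer(names(fixed))] <- unname(fixed)
  paste(s, collapse = "")
}

#' Specification for a synthetic mutation catalogue
#'
#' @param architecture a [zf_architecture()] with a sequence attached.
#' @param n number of records (>= 1).
#' @param origin `"somatic"` or `"snp"`.
#' @param multipliers named per-domain rate multipliers (`N`, `Z`, `C`; all
#'   > 0). Residue positions are drawn with per-residue weight equal to the
#'   multiplier of the residue's domain, so a domain's expected O/E ratio
#'   equals its multiplier divided by the length-weighted mean multiplier.
#' @param class_mix named proportions over [variant_classes()] (sums to 1).
#'   Classes are apportioned exactly (largest remainder), so the realised
#'   composition equals the planted mix.
#' @param tstv planted transition/transversion ratio for single-nucleotide
#'   substitutions.
#' @param impact_mean,impact_sd impact scores are drawn from a normal with
#'   these moments and clipped to \[0, 1\].
#' @param class_weights optional named weights over position classes
#'   (`coordinating`, `key_dna`, `conserved_hydrophobic`, `other_intra`,
#'   `inter_zf`) reshaping where Z-domain positions fall.
#' @param zf_weights optional numeric vector (one weight per finger)
#'   reshaping which finger Z-domain intra-finger positions fall in.
#' @param tissues named sampling weights for tissue labels.
#' @param seed RNG seed.
#' @return list of class `"catalog_spec"`.
#' @export
catalog_spec <- function(architecture, n = 500L, origin = "somatic",
                         multipliers = c(N = 1, Z = 1, C = 1),
                         class_mix = c(missense = 1),
                         tstv = 2.0, impact_mean = 0.8, impact_sd = 0.35,
                         class_weights = NULL, zf_weights = NULL,
                         tissues = c(endometrium = 0.30, breast = 0.18,
                                     blood = 0.22, colon = 0.15, lung = 0.15),
                         seed = 0L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (any(multipliers <= 0)) stop("multipliers must be > 0", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class mix must sum to 1", call. = FALSE)
  if (!all(names(class_mix) %in% variant_classes()))
    stop("unknown class in mix", call. = FALSE)
  structure(list(architecture = architecture, n = as.integer(n),
                 origin = origin, multipliers = multipliers,
                 class_mix = class_mix, tstv = tstv,
                 impact_mean = impact_mean, impact_sd = impact_sd,
                 class_weights = class_weights, zf_weights = zf_weights,
                 tissues = tissues, seed = as.integer(seed)),
            class = "catalog_spec")
}

# exact apportionment of n over proportions (largest remainder)
.apportion <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

.residue_weights <- function(spec) {
  arch <- spec$architecture
  L <- arch$protein_length
  mp <- map_residue(arch, seq_len(L))
  w <- spec$multipliers[mp$domain]
  w <- as.numeric(w)
  if (!is.null(spec$class_weights)) {
    inz <- mp$domain == "Z"
    cw <- spec$class_weights
    for (k in names(cw)) {
      sel <- inz & mp$class == k
      # weight per residue so each class's expected share equals its weight
      if (any(sel)) w[sel] <- w[sel] * cw[[k]] / sum(sel)
    }
  }
  if (!is.null(spec$zf_weights)) {
    for (k in seq_along(spec$zf_weights)) {
      sel <- !is.na(mp$zf_index) & mp$zf_index == k
      if (any(sel)) w[sel] <- w[sel] * spec$zf_weights[k] / sum(sel)
    }
  }
  w
}

#' Generate a synthetic mutation/SNP catalogue
#'
#' Residue positions are drawn with per-domain rate multipliers (optionally
#' reshaped by position-class or per-finger weights), variant classes are
#' apportioned exactly to the planted mix, single-nucleotide substitutions
#' follow the planted Ts/Tv ratio, and impact scores come from a clipped
#' normal. Ground truth sufficient to predict every downstream statistic is
#' attached as the `"ground_truth"` attribute.
#'
#' @param spec a [catalog_spec()].
#' @return catalogue data.frame (see [validate_catalog()]) with a
#'   `"ground_truth"` attribute.
#' @export
synth_catalog <- function(spec) {
  stopifnot(inherits(spec, "catalog_spec"))
  set.seed(spec$seed)
  arch <- spec$architecture
  seq_chars <- strsplit(arch$sequence %||%
                          stop("architecture needs a sequence"), "")[[1]]
  n <- spec$n
  counts <- .apportion(n, spec$class_mix)
  classes <- sample(rep(names(counts), counts))
  w <- .residue_weights(spec)
  pos <- sample.int(arch$protein_length, n, replace = TRUE, prob = w)
  ref <- seq_chars[pos]
  p_ts <- spec$tstv / (1 + spec$tstv)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    cpos <- 3L * pos[i] - sample(0:2, 1L)
    alt <- switch(cls,
      missense = sample(setdiff(AA_ALPHABET, c(ref[i], "*")), 1L),
      nonsense = "*",
      frameshift = paste0("fs*", sample(2:40, 1L)),
      synonymous = ref[i],
      splice = NA_character_,
      inframe_indel = "del",
      other = "?")
    cdna <- switch(cls,
      splice = sprintf("c.%d+%dG>T", cpos, sample(1:5, 1L)),
      frameshift = sprintf("c.%ddel", cpos),
      inframe_indel = sprintf("c.%d_%ddel", cpos, cpos + 2L),
      other = NA_character_,
      {  # substitutions: missense / nonsense / synonymous
        rb <- sample(c("A", "C", "G", "T"), 1L)
        ab <- if (stats::runif(1) < p_ts) ts_partner[[rb]]
              else sample(setdiff(c("A", "C", "G", "T"),
                                  c(rb, ts_partner[[rb]])), 1L)
        sprintf("c.%d%s>%s", cpos, rb, ab)
      })
    pchg <- switch(cls,
      splice = "?",
      other = "?",
      paste0(ref[i], pos[i], alt))
    records[[i]] <- data.frame(
      protein_change = pchg,
      cdna_change = cdna,
      residue_pos = if (cls %in% c("splice", "other")) NA_integer_ else pos[i],
      ref_aa = if (cls %in% c("splice", "other")) NA_character_ else ref[i],
      alt_descriptor = if (cls %in% c("splice", "other")) "?" else alt,
      variant_class = cls,
      tissue = sample(names(spec$tissues), 1L, prob = spec$tissues),
      origin = spec$origin,
      impact_score = if (cls == "missense")
        min(1, max(0, stats::rnorm(1, spec$impact_mean, spec$impact_sd)))
        else NA_real_,
      source = "synthetic",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(spec = spec, class_counts = counts,
                                    p_transition = p_ts)
  out
}

# -- synthetic structures -----------------------------------------------------

#' Plan one planted protein-DNA contact per row
#'
#' @param zf finger indices (into the architecture used for tallies).
#' @param category contact categories (`hydrogen_bond`, `electrostatic`,
#'   `hydrophobic`, `cation_pi`).
#' @return data.frame plan for [synth_structure_pair()].
#' @export
contact_plan <- function(zf, category) {
  if (!all(category %in% CONTACT_CATEGORIES))
    stop("unknown contact category", call. = FALSE)
  data.frame(zf = as.integer(zf), category = as.character(category),
             stringsAsFactors = FALSE)
}

# geometry of one planted contact site; site centres sit on a wide lattice so
# sites can never interact across the 6 A maximum cutoff
.site_atoms <- function(plan_row, site_index, protein_resno, dna_resno) {
  org <- c(20 * site_index, 0, 0)
  cat_ <- plan_row$category
  p <- list(); d <- list()
  add <- function(lst, elety, element, resid, resno, xyz, role)
    c(lst, list(data.frame(elety = elety, element = element, resid = resid,
                           resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
                           role = role, stringsAsFactors = FALSE)))
  if (cat_ == "hydrogen_bond") {
    p <- add(p, "OG", "O", "SER", protein_resno, org + c(0, 0, 2.9), "protein")
    d <- add(d, "N3", "N", "DT", dna_resno, org, "dna")
  } else if (cat_ == "electrostatic") {
    p <- add(p, "NZ", "N", "LYS", protein_resno, org + c(0, 0, 3.8), "protein")
    d <- add(d, "OP1", "O", "DT", dna_resno, org, "dna")
  } else if (cat_ == "hydrophobic") {
    p <- add(p, "CD1", "C", "LEU", protein_resno, org + c(0, 0, 4.2), "protein")
    d <- add(d, "C5'", "C", "DT", dna_resno, org, "dna")
  } else {  # cation_pi: pyrimidine six-ring, cation 5 A above its centroid
    ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
    ring_elem <- substr(ring_names, 1, 1)
    for (a in seq_along(ring_names)) {
      ang <- 2 * pi * (a - 1) / 6
      d <- add(d, ring_names[a], ring_elem[a], "DT", dna_resno,
               org + 1.39 * c(cos(ang), sin(ang), 0), "dna")
    }
    p <- add(p, "NH1", "N", "ARG", protein_resno, org + c(0, 0, 5.0),
             "protein")
  }
  rbind(do.call(rbind, p), do.call(rbind, d))
}

.structure_from_plan <- function(plan, architecture, site_of) {
  zfs <- architecture$zfs
  used <- integer(length(zfs))
  rows <- list()
  for (k in seq_len(nrow(plan))) {
    zi <- plan$zf[k]
    used[zi] <- used[zi] + 1L
    protein_resno <- zfs[[zi]]$start + (used[zi] - 1L) %%
      (zfs[[zi]]$end - zfs[[zi]]$start + 1L)
    rows[[k]] <- .site_atoms(plan[k, ], site_of[k], protein_resno,
                             dna_resno = site_of[k])
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$chain <- ifelse(atoms$role == "protein", "A", "B")
  structure(list(atoms = atoms, path = NA_character_),
            class = "zf_structure")
}

#' Generate a wild-type/variant structure pair with planted contacts
#'
#' Builds toy protein-DNA structures in which [detect_contacts()] under the
#' default criteria returns exactly the planted contact sets. The variant
#' shares coordinates (and contact keys) with the reference for all common
#' plan rows, loses the rows in `lose` and gains the rows in `gain`, so
#' [bond_diff()] recovers the planted diff exactly.
#'
#' @param plan reference [contact_plan()].
#' @param lose integer indices of `plan` rows absent from the variant.
#' @param gain [contact_plan()] of additional variant contacts.
#' @param architecture a [zf_architecture()]; planted protein residues are
#'   placed inside the requested fingers.
#' @param seed unused placeholder for interface symmetry (construction is
#'   deterministic).
#' @return list with `reference` and `variant` (`"zf_structure"`), and the
#'   effective `reference_plan` / `variant_plan`.
#' @export
synth_structure_pair <- function(plan, lose = integer(0), gain = NULL,
                                 architecture = ctcf_architecture(FALSE),
                                 seed = 0L) {
  if (length(lose) && any(lose < 1L | lose > nrow(plan)))
    stop("'lose' indexes outside the plan", call. = FALSE)
  full <- plan
  if (!is.null(gain) && nrow(gain)) full <- rbind(plan, gain)
  site_of <- seq_len(nrow(full))  # stable site per union row
  ref_rows <- seq_len(nrow(plan))
  var_rows <- c(setdiff(seq_len(nrow(plan)), lose),
                if (!is.null(gain) && nrow(gain))
                  nrow(plan) + seq_len(nrow(gain)))
  reference <- .structure_from_plan(full[ref_rows, , drop = FALSE],
                                    architecture, site_of[ref_rows])
  variant <- .structure_from_plan(full[var_rows, , drop = FALSE],
                                  architecture, site_of[var_rows])
  list(reference = reference, variant = variant,
       reference_plan = full[ref_rows, , drop = FALSE],
       variant_plan = full[var_rows, , drop = FALSE])
}

#' Write a structure to a PDB file
#'
#' @param structure a `"zf_structure"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  traj <- list(atoms = a, xyz = matrix(as.numeric(t(as.matrix(
    a[, c("x", "y", "z")]))), nrow = 1L))
  # single frame: write without MODEL wrapper
  con <- file(path, "w")
  on.exit(close(con))
  name4 <- ifelse(nchar(a$elety) < 4L, sprintf(" %-3s", a$elety), a$elety)
  writeLines(sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, 1, 0, a$element), con)
  writeLines("END", con)
  invisible(path)
}

#' Generate a synthetic trajectory: reference + Gaussian positional noise
#'
#' Frame i adds i.i.d. Gaussian noise (per-residue standard deviation
#' `sigma`, per coordinate) to the reference coordinates; with
#' `rigid = TRUE` a random rotation + translation is additionally applied to
#' each frame, which superposition-based metrics must undo.
#'
#' @param reference a `"zf_structure"`, or a roster data.frame with columns
#'   `elety`, `resid`, `resno`, `chain`, `x`, `y`, `z`.
#' @param sigma noise SD in Angstrom: scalar, or one value per residue
#'   (matched to the roster's unique `resno` in order).
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval, ps.
#' @param t0 first timestamp, ps.
#' @param rigid add a random rigid motion per frame.
#' @param seed RNG seed.
#' @return a `"zf_trajectory"`.
#' @export
synth_trajectory <- function(reference, sigma = 0.5, n_frames = 100L,
                             dt = 2, t0 = 0, rigid = FALSE, seed = 0L) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  a <- if (inherits(reference, "zf_structure")) reference$atoms else reference
  set.seed(seed)
  res <- unique(a$resno)
  sig_res <- if (length(sigma) == 1L) rep(sigma, length(res)) else sigma
  if (length(sig_res) != length(res))
    stop("sigma must be scalar or one value per residue", call. = FALSE)
  sig_atom <- sig_res[match(a$resno, res)]
  ref_xyz <- as.matrix(a[, c("x", "y", "z")])
  n_at <- nrow(a)
  xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3L * n_at)
  for (f in seq_len(n_frames)) {
    fr <- ref_xyz + matrix(stats::rnorm(3L * n_at, 0, sig_atom),
                           ncol = 3L)
    if (rigid) {
      ang <- stats::runif(3, 0, 2 * pi)
      rot <- .euler_rotation(ang[1], ang[2], ang[3])
      fr <- sweep(fr %*% rot, 2, stats::runif(3, -20, 20), `+`)
    }
    xyz[f, ] <- as.numeric(t(fr))
  }
  structure(list(atoms = a[, c("elety", "resid", "resno", "chain")],
                 xyz = xyz, dt = dt, t0 = t0,
                 times = t0 + dt * (seq_len(n_frames) - 1L)),
            class = "zf_trajectory")
}

.euler_rotation <- function(a, b, c) {
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}

#' A small helical toy protein-DNA reference structure
#'
#' Deterministic backbone-only toy complex used as a trajectory reference:
#' `n_res` protein residues (N, CA, C, O each) along a helix-like curve plus
#' a short straight DNA strand.
#'
#' @param n_res protein residues.
#' @return a `"zf_structure"`.
#' @export
toy_reference_structure <- function(n_res = 20L) {
  rows <- list()
  k <- 0L
  for (r in seq_len(n_res)) {
    base <- c(2.5 * cos(r / 2), 2.5 * sin(r / 2), 1.5 * r)
    offs <- list(N = c(0, 0, 0), CA = c(1.2, 0.3, 0.2),
                 C = c(2.2, -0.3, 0.5), O = c(2.6, -1.2, 0.1))
    for (nm in names(offs)) {
      k <- k + 1L
      rows[[k]] <- data.frame(eleno = k, elety = nm,
                              element = substr(nm, 1, 1), resid = "ALA",
                              resno = r, chain = "A",
                              x = base[1] + offs[[nm]][1],
                              y = base[2] + offs[[nm]][2],
                              z = base[3] + offs[[nm]][3],
                              role = "protein", stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(6L)) {
    k <- k + 1L
    rows[[k]] <- data.frame(eleno = k, elety = "P", element = "P",
                            resid = "DT", resno = n_res + r, chain = "B",
                            x = 12, y = 0, z = 3 * r, role = "dna",
                            stringsAsFactors = FALSE)
  }
  structure(list(atoms = do.call(rbind, rows), path = NA_character_),
            class = "zf_structure")
}
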
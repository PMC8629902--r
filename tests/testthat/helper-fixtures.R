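# Shared fixtures, all built in code.

# small hand-written catalogue
make_records <- function(changes, cdna = NULL, origin = "somatic",
                         tissue = "blood", score = NA_real_) {
  n <- length(changes)
  cdna <- cdna %||% rep(NA_character_, n)
  rows <- lapply(seq_len(n), function(i) {
    p <- parse_protein_change(changes[i])
    data.frame(protein_change = format_protein_change(p),
               cdna_change = cdna[i], residue_pos = p$residue_pos,
               ref_aa = p$ref_aa, alt_descriptor = p$alt,
               variant_class = classify_variant(p, cdna[i]),
               tissue = tissue, origin = origin,
               impact_score = score, source = "test",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_catalog_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# textbook chi-square oracle for a goodness-of-fit / contingency table
chisq_oracle <- function(obs, exp) sum((obs - exp)^2 / exp)

contingency_expected <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

# brute-force Mann-Whitney U: count of (a > b) pairs + half-ties
u_oracle <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact paired signed-rank p by enumerating all sign assignments
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# rotation-grid brute force for minimum RMSD over proper rotations
grid_rmsd_oracle <- function(mobile, reference, step_deg = 10) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  step <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- alphas
  for (a in alphas) for (b in betas) for (g in gammas) {
    rot <- zfmut:::.euler_rotation(a, b, g)
    best <- min(best, rmsd_xyz(m0 %*% rot, r0))
  }
  best
}

contact_keys <- function(contacts) {
  paste(contacts$category, contacts$protein_resno, contacts$protein_atom,
        contacts$dna_resno, contacts$dna_atom, sep = "|")
}

# a random protein/DNA atom cloud for contact-search property tests
random_cloud_structure <- function(n_protein = 25L, n_dna = 25L,
                                   box = 20) {
  mk <- function(n, role) {
    if (role == "protein") {
      pool <- data.frame(
        elety = c("OG", "NZ", "CD1", "NH1", "CB", "CA", "C"),
        element = c("O", "N", "C", "N", "C", "C", "C"),
        resid = c("SER", "LYS", "LEU", "ARG", "ALA", "ALA", "ALA"),
        stringsAsFactors = FALSE)
    } else {
      pool <- data.frame(
        elety = c("N3", "OP1", "C5'", "O2", "P", "C1'"),
        element = c("N", "O", "C", "O", "P", "C"),
        resid = c("DT", "DA", "DG", "DC", "DT", "DA"),
        stringsAsFactors = FALSE)
    }
    pick <- sample(nrow(pool), n, replace = TRUE)
    data.frame(eleno = seq_len(n), elety = pool$elety[pick],
               element = pool$element[pick], resid = pool$resid[pick],
               resno = sample(1:8, n, replace = TRUE),
               chain = if (role == "protein") "A" else "B",
               x = runif(n, 0, box), y = runif(n, 0, box),
               z = runif(n, 0, box), role = role,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(n_protein, "protein"), mk(n_dna, "dna"))
  atoms$eleno <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, path = NA_character_),
            class = "zf_structure")
}

# rigid transform applied to a structure
transform_structure <- function(s, angles = c(0.3, 1.1, -0.7),
                                shift = c(5, -3, 12)) {
  rot <- zfmut:::.euler_rotation(angles[1], angles[2], angles[3])
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% rot
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}
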
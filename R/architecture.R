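# Protein architecture: N/Z/C domains, zinc fingers, helix coordinates.
#
# A zinc finger here follows the C2H2 (or C2HC) grammar
#   C-x(2,4)-C-x(12)-H-x(3,5)-H
# with the DNA-binding helix numbered -6..-1, +1..+6 (no 0) over the 12
# residues immediately N-terminal to the first coordinating His, so that the
# +6 residue directly precedes that His.

HELIX_COORDS <- c(-6:-1, 1:6)

#' Construct a zinc-finger record
#'
#' @param index 1-based finger index within the array.
#' @param c1,c2 residue positions of the two coordinating cysteines.
#' @param h1,h2 residue positions of the two coordinating His residues
#'   (`h2` is a Cys for C2HC fingers).
#' @param zf_type `"C2H2"` or `"C2HC"`.
#' @return list of class `"zinc_finger"` with `start`/`end` (= `c1`/`h2`) and
#'   a `helix_map` from [assign_helix_coordinates()].
#' @export
zinc_finger <- function(index, c1, c2, h1, h2, zf_type = c("C2H2", "C2HC")) {
  zf_type <- match.arg(zf_type)
  stopifnot(c1 < c2, c2 < h1, h1 < h2)
  zf <- structure(list(index = as.integer(index), start = as.integer(c1),
                       end = as.integer(h2), c1 = as.integer(c1),
                       c2 = as.integer(c2), h1 = as.integer(h1),
                       h2 = as.integer(h2), zf_type = zf_type),
                  class = "zinc_finger")
  zf$helix_map <- assign_helix_coordinates(zf)
  zf
}

#' Assign DNA-binding helix coordinates to a zinc finger
#'
#' The 12 helix positions -6..-1, +1..+6 (there is no position 0) cover the
#' residues `h1 - 12` to `h1 - 1`: the `+6` residue is immediately N-terminal
#' to the first coordinating His. If the window would reach back past the
#' second cysteine into the finger's Cys-side, the map is truncated with a
#' warning.
#'
#' @param zf a `"zinc_finger"` (or any list with `c2` and `h1`).
#' @return named integer vector: names are residue positions, values helix
#'   coordinates.
#' @export
assign_helix_coordinates <- function(zf) {
  res <- (zf$h1 - 12L):(zf$h1 - 1L)
  coords <- HELIX_COORDS
  if (res[1] <= zf$c2) {
    keep <- res > zf$c2
    warning("helix window truncated: anchors closer than 12 residues",
            call. = FALSE)
    res <- res[keep]; coords <- coords[keep]
  }
  stats::setNames(coords, res)
}

#' Construct a protein architecture
#'
#' Domains must tile `1..protein_length` without gaps or overlap, and every
#' zinc finger must lie inside the `Z` domain.
#'
#' @param protein_length protein length in residues.
#' @param domains data.frame with columns `name` (from `N`, `Z`, `C`),
#'   `start`, `end` (1-based inclusive).
#' @param zfs list of [zinc_finger()] objects, N- to C-terminal.
#' @param name optional protein name.
#' @param sequence optional amino-acid sequence of length `protein_length`.
#' @return object of class `"zf_architecture"`.
#' @export
zf_architecture <- function(protein_length, domains, zfs, name = NULL,
                            sequence = NULL) {
  domains <- domains[order(domains$start), , drop = FALSE]
  if (domains$start[1] != 1L ||
      domains$end[nrow(domains)] != protein_length ||
      (nrow(domains) > 1L &&
       any(domains$start[-1] != domains$end[-nrow(domains)] + 1L)))
    stop("domains must tile 1..protein_length without overlap", call. = FALSE)
  if (any(!domains$name %in% c("N", "Z", "C")))
    stop("domain names must be N, Z or C", call. = FALSE)
  z <- domains[domains$name == "Z", ]
  for (zf in zfs)
    if (zf$start < z$start || zf$end > z$end)
      stop("ZF", zf$index, " lies outside the Z domain", call. = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != protein_length)
      stop("sequence length does not match protein_length", call. = FALSE)
  }
  structure(list(protein_length = as.integer(protein_length),
                 domains = domains, zfs = zfs, name = name,
                 sequence = sequence),
            class = "zf_architecture")
}

#' @export
print.zf_architecture <- function(x, ...) {
  cat("<zf_architecture>", x$name %||% "", " length", x$protein_length,
      "aa;", length(x$zfs), "ZFs\n")
  invisible(x)
}

#' Lengths of the N/Z/C domains
#' @param architecture a `"zf_architecture"`.
#' @return named integer vector of amino-acid lengths.
#' @export
domain_lengths <- function(architecture) {
  d <- architecture$domains
  stats::setNames(d$end - d$start + 1L, d$name)
}

#' Detect C2H2/C2HC zinc-finger motifs in a protein sequence
#'
#' Scans left to right for `C-x(2,4)-C-x(12)-H-x(3,5)-[HC]`; overlapping
#' candidates are resolved greedily (leftmost match, shortest spacers), and
#' matching resumes after each accepted motif, so detected fingers never
#' overlap.
#'
#' @param sequence amino-acid string (or `Biostrings`-style object coerced
#'   with `as.character`).
#' @return list of [zinc_finger()] objects (empty if none).
#' @export
detect_zf_motifs <- function(sequence) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(s)
  zfs <- list(); i <- 1L; idx <- 0L
  while (i <= n) {
    if (s[i] != "C") { i <- i + 1L; next }
    hit <- NULL
    for (g1 in 2:4) {
      c2 <- i + g1 + 1L
      if (c2 > n || s[c2] != "C") next
      h1 <- c2 + 13L
      if (h1 > n || s[h1] != "H") next
      for (g2 in 3:5) {
        h2 <- h1 + g2 + 1L
        if (h2 > n || !(s[h2] %in% c("H", "C"))) next
        hit <- list(c1 = i, c2 = c2, h1 = h1, h2 = h2,
                    type = if (s[h2] == "H") "C2H2" else "C2HC")
        break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) { i <- i + 1L; next }
    idx <- idx + 1L
    zfs[[idx]] <- zinc_finger(idx, hit$c1, hit$c2, hit$h1, hit$h2, hit$type)
    i <- hit$h2 + 1L
  }
  zfs
}

#' Build an architecture around detected motifs
#'
#' Convenience wrapper: detects fingers in `sequence` and wraps them in a
#' [zf_architecture()] whose Z domain spans the first to last finger (with
#' `margin` residues of padding where available).
#'
#' @param sequence amino-acid string.
#' @param name optional name.
#' @param margin residues of Z-domain padding around the outermost fingers.
#' @return a `"zf_architecture"`, or error if no motif is found.
#' @export
architecture_from_sequence <- function(sequence, name = NULL, margin = 2L) {
  zfs <- detect_zf_motifs(sequence)
  if (!length(zfs)) stop("no zinc-finger motif detected", call. = FALSE)
  L <- nchar(sequence)
  zs <- max(1L, zfs[[1]]$start - margin)
  ze <- min(L, zfs[[length(zfs)]]$end + margin)
  doms <- data.frame(name = c("N", "Z", "C"),
                     start = c(1L, zs, ze + 1L),
                     end = c(zs - 1L, ze, L))
  doms <- doms[doms$start <= doms$end, , drop = FALSE]
  zf_architecture(L, doms, zfs, name = name, sequence = sequence)
}

#' Map a residue position to domain, finger, helix coordinate and class
#'
#' Position classes: `coordinating` (Cys/His anchors), `key_dna` (helix
#' positions -1, +2, +3, +6), `conserved_hydrophobic` (helix +4, the
#' invariant Leu/Met), `other_intra` (any other residue inside a finger),
#' `inter_zf` (Z-domain residues in no finger). Residues outside the Z
#' domain have no finger, helix coordinate or class.
#'
#' @param architecture a `"zf_architecture"`.
#' @param residue_pos integer position(s), 1-based.
#' @return data.frame with columns `residue_pos`, `domain`, `zf_index`,
#'   `helix`, `class` (one row per input position).
#' @export
map_residue <- function(architecture, residue_pos) {
  L <- architecture$protein_length
  if (any(residue_pos < 1L | residue_pos > L))
    stop("residue position out of range 1..", L, call. = FALSE)
  d <- architecture$domains
  out <- data.frame(residue_pos = as.integer(residue_pos),
                    domain = NA_character_, zf_index = NA_integer_,
                    helix = NA_integer_, class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(residue_pos)) {
    p <- residue_pos[i]
    out$domain[i] <- d$name[d$start <= p & d$end >= p][1]
    if (out$domain[i] != "Z") next
    out$class[i] <- "inter_zf"
    for (zf in architecture$zfs) {
      if (p < zf$start || p > zf$end) next
      out$zf_index[i] <- zf$index
      if (p %in% c(zf$c1, zf$c2, zf$h1, zf$h2)) {
        out$class[i] <- "coordinating"
      } else {
        hm <- zf$helix_map
        k <- match(as.character(p), names(hm))
        if (!is.na(k)) {
          out$helix[i] <- hm[[k]]
          out$class[i] <- if (hm[[k]] %in% c(-1L, 2L, 3L, 6L)) "key_dna"
            else if (hm[[k]] == 4L) "conserved_hydrophobic"
            else "other_intra"
        } else out$class[i] <- "other_intra"
      }
      break
    }
  }
  out
}

#' Align all fingers over the 12 helix columns
#'
#' @param architecture a `"zf_architecture"` with a sequence attached (or
#'   pass `sequence`).
#' @param sequence optional amino-acid string overriding the attached one.
#' @return character matrix, one row per finger (`ZF1`, ...), columns the
#'   helix coordinates `-6`..`+6`.
#' @export
build_zf_alignment <- function(architecture, sequence = NULL) {
  seq <- sequence %||% architecture$sequence
  if (is.null(seq)) stop("no sequence available for alignment", call. = FALSE)
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  zfs <- architecture$zfs
  aln <- matrix(NA_character_, nrow = length(zfs), ncol = 12L,
                dimnames = list(paste0("ZF", vapply(zfs, `[[`, 1L, "index")),
                                as.character(HELIX_COORDS)))
  for (r in seq_along(zfs)) {
    hm <- zfs[[r]]$helix_map
    if (length(hm) != 12L)
      stop("ZF", zfs[[r]]$index, " has an incomplete helix map",
           call. = FALSE)
    aln[r, ] <- s[as.integer(names(hm))]
  }
  aln
}

#' Read an architecture from a YAML or JSON config
#'
#' The config lists `name`, `length`, `domains` (name/start/end) and `zfs`
#' (index/c1/c2/h1/h2/type).
#'
#' @param path config path (`.yaml`/`.yml` or `.json`).
#' @return a `"zf_architecture"`.
#' @export
read_architecture <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  doms <- as.data.frame(cfg$domains, stringsAsFactors = FALSE)
  zfs <- lapply(seq_along(cfg$zfs$index %||% cfg$zfs), function(i) {
    z <- if (is.data.frame(cfg$zfs)) as.list(cfg$zfs[i, ]) else cfg$zfs[[i]]
    zinc_finger(z$index, z$c1, z$c2, z$h1, z$h2, z$type %||% "C2H2")
  })
  zf_architecture(cfg$length, doms, zfs, name = cfg$name)
}

#' The shipped CTCF zinc-finger architecture
#'
#' An 11-finger architecture for human CTCF (727 aa) with per-finger Cys/His
#' anchors; anchor positions are versioned in
#' `inst/extdata/ctcf_zf_architecture.yaml`. The helix-coordinate rule
#' reproduces the canonical residue assignments L309 = ZF2 +4, R339 = ZF3
#' +6, K365 = ZF4 +3, G420 = ZF6 +2, with R377 falling in the ZF4/ZF5
#' linker.
#'
#' @param with_sequence attach the synthetic CTCF-like sequence from
#'   [ctcf_synthetic_sequence()] (needed for alignment/logo operations).
#' @param seed seed for the synthetic sequence backbone.
#' @return a `"zf_architecture"`.
#' @export
ctcf_architecture <- function(with_sequence = TRUE, seed = 0L) {
  path <- system.file("extdata", "ctcf_zf_architecture.yaml",
                      package = "zfmut", mustWork = TRUE)
  arch <- read_architecture(path)
  if (with_sequence)
    arch$sequence <- ctcf_synthetic_sequence(arch, seed = seed)
  arch
}
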
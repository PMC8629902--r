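# HGVS-style protein (p.) and cDNA (c.) change parsing.

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V", Ter = "*")

AA1 <- names(AA3)
names(AA1) <- unname(AA3)

.aa_to_one <- function(tok) {
  if (nchar(tok) == 1L && tok %in% c(unname(AA3), "*")) return(tok)
  hit <- AA3[match(tok, names(AA3))]
  if (is.na(hit)) NA_character_ else unname(hit)
}

#' Parse an HGVS protein change
#'
#' Accepts `"p."`-prefixed or bare strings in one- or three-letter amino-acid
#' notation, e.g. `"p.R339Q"`, `"T204fs*26"`, `"p.Arg339Gln"`, `"p.R457*"`,
#' `"p.L309="`. The alternate descriptor is canonicalised to one-letter form;
#' frameshifts keep their `fs` (and optional `*N` extension) suffix.
#'
#' @param text a single HGVS p. string.
#' @return An object of class `"hgvs_p"`: a list with `ref_aa` (one-letter),
#'   `residue_pos` (integer, 1-based) and `alt` (one-letter amino acid, `"*"`,
#'   `"="`, `"fs"`/`"fs*N"`, `"del"`, `"dup"`, `"ins"`, `"delins"` or `"?"`).
#' @seealso [format_protein_change()], [classify_variant()]
#' @examples
#' parse_protein_change("p.Arg339Gln")
#' parse_protein_change("T204fs*26")
#' @export
parse_protein_change <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("protein change must be a single non-empty string", call. = FALSE)
  x <- trimws(sub("^p\\.", "", trimws(text)))
  if (x == "?")
    return(structure(list(ref_aa = NA_character_, residue_pos = NA_integer_,
                          alt = "?"), class = "hgvs_p"))
  m <- regexec("^([A-Z][a-z]{2}|[A-Z*])(\\d+)(.*)$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L)
    stop("malformed protein change: '", text, "'", call. = FALSE)
  ref <- .aa_to_one(parts[2])
  if (is.na(ref))
    stop("malformed protein change: unknown reference residue '",
         parts[2], "' in '", text, "'", call. = FALSE)
  pos <- as.integer(parts[3])
  alt <- .parse_alt_descriptor(parts[4], text)
  structure(list(ref_aa = ref, residue_pos = pos, alt = alt),
            class = "hgvs_p")
}

.parse_alt_descriptor <- function(rest, text) {
  rest <- trimws(rest)
  if (rest == "" || rest == "=") return(if (rest == "") "=" else "=")
  # range forms such as T204_K205del: keep the indel keyword
  if (grepl("^_[A-Za-z]*\\d+", rest))
    rest <- sub("^_[A-Za-z]*\\d+", "", rest)
  low <- tolower(rest)
  if (grepl("^fs", low)) {
    ext <- sub("^fs", "", low)
    ext <- sub("^ter", "*", ext)
    if (ext == "") return("fs")
    if (grepl("^\\*\\d+$", ext)) return(paste0("fs", ext))
    stop("malformed frameshift descriptor '", rest, "' in '", text, "'",
         call. = FALSE)
  }
  if (low %in% c("delins")) return("delins")
  if (grepl("^delins", low)) return("delins")
  if (grepl("^del", low)) return("del")
  if (grepl("^dup", low)) return("dup")
  if (grepl("^ins", low)) return("ins")
  if (rest %in% c("*", "Ter", "X")) return("*")
  one <- .aa_to_one(rest)
  if (!is.na(one)) return(one)
  stop("malformed protein change: unknown alternate descriptor '",
       rest, "' in '", text, "'", call. = FALSE)
}

#' Format a parsed protein change canonically
#'
#' The canonical form is one-letter, unprefixed (e.g. `"R339Q"`,
#' `"T204fs*26"`); `format(parse(x))` is a fixed point of the parser.
#'
#' @param x an `"hgvs_p"` object from [parse_protein_change()].
#' @return character scalar.
#' @export
format_protein_change <- function(x) {
  stopifnot(inherits(x, "hgvs_p"))
  if (identical(x$alt, "?")) return("?")
  alt <- if (x$alt == "=") "=" else x$alt
  paste0(x$ref_aa, x$residue_pos, alt)
}

#' @export
print.hgvs_p <- function(x, ...) {
  cat("<hgvs_p> ", format_protein_change(x), "\n", sep = "")
  invisible(x)
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine exchanges; the
#' classification is symmetric in (ref, alt).
#'
#' @param ref,alt single nucleotides in `A`, `C`, `G`, `T`.
#' @return `"transition"` or `"transversion"`.
#' @export
substitution_kind <- function(ref, alt) {
  bases <- c(ref, alt)
  if (!all(bases %in% c(PURINES, PYRIMIDINES)))
    stop("nucleotides must be one of A, C, G, T", call. = FALSE)
  if (ref == alt) stop("ref and alt nucleotides are identical", call. = FALSE)
  if (all(bases %in% PURINES) || all(bases %in% PYRIMIDINES))
    "transition" else "transversion"
}

#' Parse an HGVS cDNA change
#'
#' Single-nucleotide substitutions (`"c.100G>A"`) yield a substitution event
#' with its transition/transversion kind; indels, duplications and intronic
#' (splice-region) changes yield a non-substitution marker that downstream
#' Ts/Tv statistics exclude.
#'
#' @param text a single HGVS c. string.
#' @return A list of class `"hgvs_c"`. For substitutions: `kind =
#'   "substitution"`, `cdna_pos`, `ref_base`, `alt_base`, `sub_kind`
#'   (`"transition"`/`"transversion"`). Otherwise `kind = "non_substitution"`
#'   with a `reason` (`"indel"`, `"dup"`, `"splice"`, ...).
#' @export
parse_cdna_change <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("cDNA change must be a single non-empty string", call. = FALSE)
  x <- trimws(sub("^c\\.", "", trimws(text)))
  m <- regexec("^(\\d+)([ACGT])>([ACGT])$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) > 0L) {
    ref <- parts[3]; alt <- parts[4]
    return(structure(list(kind = "substitution",
                          cdna_pos = as.integer(parts[2]),
                          ref_base = ref, alt_base = alt,
                          sub_kind = substitution_kind(ref, alt)),
                     class = "hgvs_c"))
  }
  # intronic / splice-region coordinates carry +/- offsets
  if (grepl("^\\d+[+-]\\d+", x))
    return(structure(list(kind = "non_substitution", reason = "splice"),
                     class = "hgvs_c"))
  reason <- if (grepl("delins", x)) "indel"
    else if (grepl("del", x)) "indel"
    else if (grepl("ins", x)) "indel"
    else if (grepl("dup", x)) "dup"
    else NA_character_
  if (is.na(reason))
    stop("malformed cDNA change: '", text, "'", call. = FALSE)
  structure(list(kind = "non_substitution", reason = reason),
            class = "hgvs_c")
}

#' Classify a parsed variant
#'
#' Deterministically assigns one of `missense`, `nonsense`, `frameshift`,
#' `synonymous`, `splice`, `inframe_indel` or `other`. Splice calls come from
#' an intronic cDNA change (or an unknown `p.?` protein consequence with such
#' a cDNA change); everything unrecognised falls back to `other`.
#'
#' @param p an `"hgvs_p"` object (or string, parsed on the fly).
#' @param cdna optional `"hgvs_c"` object or c. string.
#' @return character scalar, one of the classes above.
#' @export
classify_variant <- function(p, cdna = NULL) {
  if (is.character(p)) p <- parse_protein_change(p)
  if (is.character(cdna) && !is.na(cdna) && nzchar(cdna))
    cdna <- tryCatch(parse_cdna_change(cdna), error = function(e) NULL)
  if (!is.null(cdna) && inherits(cdna, "hgvs_c") &&
      cdna$kind == "non_substitution" && identical(cdna$reason, "splice"))
    return("splice")
  alt <- p$alt
  if (identical(alt, "?")) return("other")
  if (grepl("^fs", alt)) return("frameshift")
  if (alt == "*") return("nonsense")
  if (alt == "=" || identical(alt, p$ref_aa)) return("synonymous")
  if (alt %in% c("del", "dup", "ins", "delins")) return("inframe_indel")
  if (nchar(alt) == 1L && alt %in% unname(AA3) && alt != "*") return("missense")
  "other"
}

#' Variant classes recognised by the package
#' @return character vector of the exhaustive class labels.
#' @export
variant_classes <- function() {
  c("missense", "nonsense", "frameshift", "synonymous", "splice",
    "inframe_indel", "other")
}
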
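# Sequence-logo column frequencies and information content (bits).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

# colour classes as commonly rendered for ZF logos (metadata only)
AA_COLOR_CLASS <- c(
  G = "hydrophobic", A = "hydrophobic", V = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", P = "hydrophobic", W = "hydrophobic", F = "hydrophobic",
  M = "hydrophobic",
  S = "polar", T = "polar", Y = "polar", C = "polar",
  Q = "polar_amide", N = "polar_amide",
  K = "basic", R = "basic", H = "basic",
  D = "acidic", E = "acidic")

#' Information content of an alignment column
#'
#' `IC = log2(20) - H` with `H = -sum(p * log2 p)` (and `0 log 0 = 0`), so an
#' invariant column reaches the ceiling `log2(20) ~ 4.32` bits and a uniform
#' column has 0 bits. With `correction = TRUE` the WebLogo small-sample
#' adjustment `e_n = (1/ln 2) * 19/(2n)` is subtracted and the result floored
#' at 0.
#'
#' @param freqs numeric vector of amino-acid frequencies summing to 1.
#' @param n_seq number of sequences (required when `correction = TRUE`).
#' @param correction apply the small-sample correction.
#' @return information content in bits.
#' @export
information_content <- function(freqs, n_seq = NULL, correction = FALSE) {
  if (any(freqs < 0)) stop("negative frequency", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1", call. = FALSE)
  p <- freqs[freqs > 0]
  h <- -sum(p * log2(p))
  ic <- log2(20) - h
  if (correction) {
    if (is.null(n_seq)) stop("n_seq required for the small-sample correction",
                             call. = FALSE)
    ic <- max(0, ic - (1 / log(2)) * (19 / (2 * n_seq)))
  }
  ic
}

#' Logo matrix for a zinc-finger helix alignment
#'
#' Per-column amino-acid frequencies, information content in bits and letter
#' heights (`frequency * IC`, so the stack height per column equals the
#' column's IC).
#'
#' @param alignment character matrix from [build_zf_alignment()] (rows =
#'   sequences, columns = positions, single letters, no gaps).
#' @param correction apply the WebLogo small-sample correction with
#'   `n = nrow(alignment)`.
#' @return object of class `"logo_matrix"`: list with `freq` (20 x ncol
#'   matrix), `ic` (bits per column), `heights`, `n_seq`, `columns` and the
#'   rendering `color_class` map.
#' @export
logo_matrix <- function(alignment, correction = FALSE) {
  if (!is.matrix(alignment) || any(is.na(alignment)))
    stop("alignment must be a complete character matrix", call. = FALSE)
  if (any(nchar(alignment) != 1L))
    stop("alignment entries must be single letters", call. = FALSE)
  bad <- !(alignment %in% AA_ALPHABET)
  if (any(bad))
    stop("non-standard amino acid(s): ",
         paste(unique(alignment[bad]), collapse = ", "), call. = FALSE)
  n <- nrow(alignment)
  freq <- apply(alignment, 2, function(col) {
    tab <- table(factor(col, levels = AA_ALPHABET))
    as.numeric(tab) / n
  })
  rownames(freq) <- AA_ALPHABET
  ic <- apply(freq, 2, information_content, n_seq = n,
              correction = correction)
  heights <- sweep(freq, 2, ic, `*`)
  structure(list(freq = freq, ic = ic, heights = heights, n_seq = n,
                 columns = colnames(alignment),
                 color_class = AA_COLOR_CLASS),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("<logo_matrix> ", ncol(x$freq), " columns, ", x$n_seq,
      " sequences; IC range [", round(min(x$ic), 3), ", ",
      round(max(x$ic), 3), "] bits\n", sep = "")
  invisible(x)
}

#' Write a logo matrix as tidy TSV
#'
#' One row per (column, amino acid) with frequency and letter height.
#'
#' @param logo a `"logo_matrix"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  cols <- logo$columns %||% as.character(seq_len(ncol(logo$freq)))
  long <- do.call(rbind, lapply(seq_along(cols), function(j) {
    data.frame(column = cols[j], aa = AA_ALPHABET,
               freq = logo$freq[, j], height = logo$heights[, j],
               ic = logo$ic[j], stringsAsFactors = FALSE)
  }))
  long <- long[long$freq > 0, , drop = FALSE]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
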
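# Mutation/SNP catalogue I/O and statistics.

CATALOG_COLUMNS <- c("protein_change", "cdna_change", "residue_pos", "ref_aa",
                     "alt_descriptor", "variant_class", "tissue", "origin",
                     "impact_score", "source")

.empty_catalog <- function() {
  df <- data.frame(protein_change = character(), cdna_change = character(),
                   residue_pos = integer(), ref_aa = character(),
                   alt_descriptor = character(), variant_class = character(),
                   tissue = character(), origin = character(),
                   impact_score = numeric(), source = character(),
                   stringsAsFactors = FALSE)
  df
}

.parse_catalog_row <- function(protein_change, cdna_change) {
  p <- parse_protein_change(protein_change)
  cls <- classify_variant(p, cdna_change)
  list(residue_pos = p$residue_pos, ref_aa = p$ref_aa,
       alt_descriptor = p$alt, variant_class = cls,
       protein_change = format_protein_change(p))
}

#' Read a delimited mutation/SNP catalogue
#'
#' Reads a TSV/CSV table with a header row, parses and classifies every
#' record, and validates it. Lines starting with `#` are ignored. Column
#' names are remapped through `mapping`, so arbitrary source tables can be
#' read; `protein_change` is the only required column.
#'
#' @param path path to a UTF-8 delimited file. The delimiter is inferred from
#'   the extension (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param mapping named character vector/list mapping canonical column names
#'   (`protein_change`, `cdna_change`, `tissue`, `origin`, `impact_score`,
#'   `source`) to column names in the file. Unmapped optional columns are
#'   filled with `NA`.
#' @param origin default origin (`"somatic"` or `"snp"`) used when the file
#'   has no origin column.
#' @param strict if `TRUE` (default) any malformed row aborts with a
#'   row-numbered error; if `FALSE` malformed rows are dropped, reported via
#'   `message()`, and returned in the `"rejected"` attribute.
#' @param sep field separator override.
#' @return a catalogue `data.frame` (see [validate_catalog()] for the column
#'   contract), with attributes `n_read` (rows in file) and `rejected`
#'   (data.frame of row numbers and reasons, permissive mode only).
#' @export
read_catalog <- function(path, mapping = NULL, origin = "somatic",
                         strict = TRUE, sep = NULL) {
  if (!file.exists(path)) stop("cannot read catalogue: '", path, "'",
                               call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  mapping <- as.list(mapping %||% list())
  pick <- function(canon) {
    src <- mapping[[canon]] %||% canon
    if (src %in% names(raw)) raw[[src]] else rep(NA, nrow(raw))
  }
  if (!((mapping[["protein_change"]] %||% "protein_change") %in% names(raw)))
    stop("required column '", mapping[["protein_change"]] %||% "protein_change",
         "' missing from ", path, call. = FALSE)

  pc <- as.character(pick("protein_change"))
  cc <- as.character(pick("cdna_change"))
  ti <- as.character(pick("tissue"))
  og <- as.character(pick("origin"))
  sc <- suppressWarnings(as.numeric(pick("impact_score")))
  so <- as.character(pick("source"))
  rows <- vector("list", length(pc))
  rej_row <- integer(); rej_reason <- character()
  for (i in seq_along(pc)) {
    parsed <- tryCatch(.parse_catalog_row(pc[i], cc[i]),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      if (strict)
        stop("row ", i, ": ", conditionMessage(parsed), call. = FALSE)
      rej_row <- c(rej_row, i)
      rej_reason <- c(rej_reason, conditionMessage(parsed))
      next
    }
    rows[[i]] <- data.frame(
      protein_change = parsed$protein_change,
      cdna_change = if (is.na(cc[i])) NA_character_ else cc[i],
      residue_pos = parsed$residue_pos,
      ref_aa = parsed$ref_aa,
      alt_descriptor = parsed$alt_descriptor,
      variant_class = parsed$variant_class,
      tissue = if (is.na(ti[i])) NA_character_ else ti[i],
      origin = if (is.na(og[i])) origin else og[i],
      impact_score = sc[i],
      source = if (is.na(so[i])) NA_character_ else so[i],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else .empty_catalog()
  rejected <- data.frame(row = rej_row, reason = rej_reason,
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L)
    message(nrow(rejected), " row(s) rejected: rows ",
            paste(rejected$row, collapse = ", "))
  rownames(out) <- NULL
  validate_catalog(out)
  attr(out, "n_read") <- length(pc)
  attr(out, "rejected") <- rejected
  out
}

#' Write a catalogue to TSV
#' @param records catalogue data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path) {
  utils::write.table(records[, CATALOG_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a catalogue data.frame
#'
#' Checks the column contract, that impact scores lie in \[0, 1\], that every
#' variant class is one of [variant_classes()], that the class is consistent
#' with the alternate descriptor, and (when an architecture is supplied) that
#' residue positions lie within the protein.
#'
#' @param records catalogue data.frame.
#' @param architecture optional [zf_architecture()] for bounds checking.
#' @return `records`, invisibly.
#' @export
validate_catalog <- function(records, architecture = NULL) {
  miss <- setdiff(CATALOG_COLUMNS, names(records))
  if (length(miss))
    stop("catalogue is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- is.na(records$impact_score) |
    (records$impact_score >= 0 & records$impact_score <= 1)
  if (!all(ok))
    stop("impact_score outside [0, 1] at row(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  bad <- !(records$variant_class %in% variant_classes())
  if (any(bad))
    stop("unknown variant class at row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  fs <- grepl("^fs", records$alt_descriptor)
  if (any(fs & records$variant_class != "frameshift"))
    stop("alt descriptor 'fs' inconsistent with variant class", call. = FALSE)
  ns <- records$alt_descriptor == "*" & !is.na(records$alt_descriptor)
  if (any(ns & records$variant_class != "nonsense"))
    stop("alt descriptor '*' inconsistent with variant class", call. = FALSE)
  if (!is.null(architecture)) {
    pos <- records$residue_pos
    bad <- !is.na(pos) & (pos < 1L | pos > architecture$protein_length)
    if (any(bad))
      stop("residue position outside protein (length ",
           architecture$protein_length, ") at row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Recurrently mutated sites
#'
#' Counts records per site and returns those reaching `threshold`, sorted by
#' count (ties by position). At `level = "residue"` all alternate alleles at a
#' position are pooled (the default; recurrence in this field is usually
#' quoted per residue); `level = "allele"` distinguishes alternates.
#'
#' @param records catalogue data.frame.
#' @param threshold minimum count (default 10).
#' @param level `"residue"` or `"allele"`.
#' @return data.frame with `site` and `count`, count-descending.
#' @export
recurrence_table <- function(records, threshold = 10L,
                             level = c("residue", "allele")) {
  level <- match.arg(level)
  if (nrow(records) == 0L) stop("empty catalogue", call. = FALSE)
  if (threshold < 1L) stop("threshold must be >= 1", call. = FALSE)
  key <- if (level == "residue")
    paste0(records$ref_aa, records$residue_pos)
  else records$protein_change
  tab <- table(key)
  keep <- tab[tab >= threshold]
  out <- data.frame(site = names(keep), count = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$site), , drop = FALSE]
}

#' Catalogue composition by variant class or tissue
#'
#' @param records catalogue data.frame.
#' @param by `"variant_class"` or `"tissue"`.
#' @return data.frame with `level`, `count`, `proportion` (sums to 1) and an
#'   `n` attribute.
#' @export
composition <- function(records, by = c("variant_class", "tissue")) {
  by <- match.arg(by)
  if (nrow(records) == 0L) stop("empty catalogue", call. = FALSE)
  tab <- table(records[[by]])
  out <- data.frame(level = names(tab), count = as.integer(tab),
                    proportion = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$level), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- sum(tab)
  out
}

#' Fraction of inactivating mutations (20/20 rule)
#'
#' Inactivating = nonsense + frameshift (optionally + splice). The
#' tumour-suppressor 20/20 heuristic is exceeded when the fraction is
#' strictly greater than 0.20.
#'
#' @param records catalogue data.frame (somatic records; filter beforehand or
#'   set `origin_filter`).
#' @param include_splice count splice variants as inactivating too.
#' @param origin_filter if non-`NULL`, keep only records with this origin.
#' @return list with `fraction`, `exceeds_rule`, `n_inactivating`, `n`.
#' @export
twenty_twenty <- function(records, include_splice = FALSE,
                          origin_filter = NULL) {
  if (!is.null(origin_filter))
    records <- records[records$origin == origin_filter, , drop = FALSE]
  if (nrow(records) == 0L) stop("empty catalogue", call. = FALSE)
  inact <- c("nonsense", "frameshift", if (include_splice) "splice")
  k <- sum(records$variant_class %in% inact)
  f <- k / nrow(records)
  list(fraction = f, exceeds_rule = f > 0.20, n_inactivating = k,
       n = nrow(records))
}

.substitutions <- function(records) {
  kinds <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    cc <- records$cdna_change[i]
    if (is.na(cc) || !nzchar(cc)) { kinds[i] <- "missing"; next }
    ev <- tryCatch(parse_cdna_change(cc), error = function(e) NULL)
    kinds[i] <- if (is.null(ev)) "missing"
      else if (ev$kind == "substitution") ev$sub_kind else "non_substitution"
  }
  kinds
}

#' Transition/transversion ratio
#'
#' Only single-nucleotide substitutions with valid c. notation enter the
#' ratio; records lacking usable cDNA notation are excluded and counted.
#'
#' @param records catalogue data.frame.
#' @return list with `n_transition`, `n_transversion`, `n_excluded`, `ratio`
#'   (`NA` with a warning if there are no transversions).
#' @export
tstv_ratio <- function(records) {
  kinds <- .substitutions(records)
  n_ts <- sum(kinds == "transition")
  n_tv <- sum(kinds == "transversion")
  n_ex <- sum(kinds %in% c("missing", "non_substitution"))
  ratio <- if (n_tv == 0L) {
    warning("no transversions: Ts/Tv ratio undefined", call. = FALSE)
    NA_real_
  } else n_ts / n_tv
  list(n_transition = n_ts, n_transversion = n_tv, n_excluded = n_ex,
       ratio = ratio)
}

#' Compare Ts/Tv composition between two catalogues
#'
#' Builds the 2x2 table (group x transition/transversion) and applies the
#' chi-square test of independence, by default without Yates continuity
#' correction so the statistic equals the textbook sum((O-E)^2/E).
#'
#' @param somatic,snp catalogue data.frames.
#' @param correct apply Yates continuity correction.
#' @return list with `table` (2x2 counts), `chi_square`, `df`, `p_value`.
#' @export
compare_tstv <- function(somatic, snp, correct = FALSE) {
  ka <- .substitutions(somatic); kb <- .substitutions(snp)
  tab <- rbind(somatic = c(transition = sum(ka == "transition"),
                           transversion = sum(ka == "transversion")),
               snp = c(transition = sum(kb == "transition"),
                       transversion = sum(kb == "transversion")))
  if (any(rowSums(tab) == 0L))
    stop("each group needs at least one substitution", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, chi_square = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value)
}

#' Compare impact-score distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test: exact when the smaller group has at most
#' `exact_max` observations and there are no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param scores_a,scores_b numeric vectors of scores in \[0, 1\].
#' @param exact_max largest small-group size for the exact null (default 8).
#' @return list with per-group `mean`/`sd`/`n`, `U` and `p_value`.
#' @export
compare_impact_scores <- function(scores_a, scores_b, exact_max = 8L) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (!length(scores_a) || !length(scores_b))
    stop("each group needs at least one score", call. = FALSE)
  if (any(c(scores_a, scores_b) < 0 | c(scores_a, scores_b) > 1))
    stop("impact scores must lie in [0, 1]", call. = FALSE)
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0L
  exact <- min(length(scores_a), length(scores_b)) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, exact = exact, correct = FALSE))
  list(group_a = list(mean = mean(scores_a), sd = stats::sd(scores_a),
                      n = length(scores_a)),
       group_b = list(mean = mean(scores_b), sd = stats::sd(scores_b),
                      n = length(scores_b)),
       U = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
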
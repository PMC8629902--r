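# End-to-end report bundle: catalogue statistics, enrichment, logo, and
# (optionally) structure metrics, written as figure-shaped TSVs + JSON.

#' Assemble and validate a pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param catalog path to a catalogue TSV/CSV, or `NULL` to generate a
#'   synthetic somatic catalogue.
#' @param snp_catalog optional second catalogue of SNP records for the
#'   somatic-vs-SNP comparisons.
#' @param architecture path to an architecture YAML/JSON, or `"ctcf"`
#'   (default) for the shipped config.
#' @param origin origin filter applied to `catalog` (`"somatic"`, `"snp"`,
#'   or `NULL` for all records).
#' @param recurrence_threshold recurrence count threshold.
#' @param pdb,pdb_reference optional structure (and reference) PDB paths for
#'   contact tallies.
#' @param seed seed used when generating synthetic inputs.
#' @param mapping column mapping forwarded to [read_catalog()].
#' @return validated config list of class `"zfmut_config"`.
#' @export
run_config <- function(out_dir, catalog = NULL, snp_catalog = NULL,
                       architecture = "ctcf", origin = "somatic",
                       recurrence_threshold = 10L, pdb = NULL,
                       pdb_reference = NULL, seed = 0L, mapping = NULL) {
  for (p in c(catalog, snp_catalog, pdb, pdb_reference))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: '", p, "'", call. = FALSE)
  if (!identical(architecture, "ctcf") && !file.exists(architecture))
    stop("architecture config not found: '", architecture, "'",
         call. = FALSE)
  if (recurrence_threshold < 1L)
    stop("recurrence threshold must be >= 1", call. = FALSE)
  structure(list(out_dir = out_dir, catalog = catalog,
                 snp_catalog = snp_catalog, architecture = architecture,
                 origin = origin,
                 recurrence_threshold = as.integer(recurrence_threshold),
                 pdb = pdb, pdb_reference = pdb_reference,
                 seed = as.integer(seed), mapping = mapping),
            class = "zfmut_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full catalogue/enrichment/logo pipeline
#'
#' Reads (or synthesises) the inputs, computes every catalogue-level
#' statistic, writes figure-shaped TSV tables into the output directory and
#' a `summary.json` holding every statistic together with its input row
#' counts, the package version and a config hash. Deterministic given the
#' config and seed.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "zfmut_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  arch <- if (identical(config$architecture, "ctcf"))
    ctcf_architecture(seed = config$seed)
  else read_architecture(config$architecture)

  records <- if (is.null(config$catalog)) {
    synth_catalog(catalog_spec(
      arch, n = 600L, origin = "somatic",
      multipliers = c(N = 0.63, Z = 1.47, C = 0.65),
      class_mix = c(missense = 0.46, nonsense = 0.21, frameshift = 0.19,
                    splice = 0.05, synonymous = 0.05, other = 0.04),
      tstv = 1.19, impact_mean = 0.80, impact_sd = 0.35,
      seed = config$seed))
  } else read_catalog(config$catalog, mapping = config$mapping)
  if (!is.null(config$origin))
    records <- records[records$origin == config$origin, , drop = FALSE]
  validate_catalog(records, arch)

  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  comp_class <- composition(records, "variant_class")
  comp_tissue <- composition(records, "tissue")
  recur <- recurrence_table(records, config$recurrence_threshold)
  tt <- twenty_twenty(records)
  tstv <- suppressWarnings(tstv_ratio(records))
  enr <- domain_enrichment(records, arch)
  sens <- domain_enrichment_sensitivity(records, arch)
  zf_freq <- per_zf_frequency(records, arch)
  pos_freq <- per_position_frequency(records, arch)
  aln <- build_zf_alignment(arch)
  logo <- logo_matrix(aln)

  files <- c(wtsv(comp_class, "fig1b_types.tsv"),
             wtsv(comp_tissue, "fig1c_tissues.tsv"),
             wtsv(recur, "fig1a_recurrence.tsv"),
             wtsv(enr, "fig1d_enrichment.tsv"),
             wtsv(sens, "fig1d_enrichment_sensitivity.tsv"),
             wtsv(zf_freq, "fig1e_zf_frequency.tsv"),
             wtsv(pos_freq$by_class, "fig1g_position_classes.tsv"),
             wtsv(pos_freq$by_position, "fig1g_position_frequency.tsv"))
  write_logo_tsv(logo, file.path(config$out_dir, "fig1f_logo.tsv"))
  files <- c(files, "fig1f_logo.tsv")

  summary <- list(
    package_version = as.character(utils::packageVersion("zfmut")),
    config_hash = .config_hash(config),
    seed = config$seed,
    n_records = nrow(records),
    composition = list(variant_class = comp_class, tissue = comp_tissue),
    twenty_twenty = tt,
    tstv = tstv,
    enrichment = enr,
    per_zf = list(table = zf_freq, mean_pct = attr(zf_freq, "mean_pct")),
    position_classes = pos_freq$by_class,
    logo_ic = list(columns = logo$columns, bits = as.numeric(logo$ic),
                   max_bits = log2(20)))

  if (!is.null(config$snp_catalog)) {
    snp <- read_catalog(config$snp_catalog, mapping = config$mapping,
                        origin = "snp")
    summary$snp_comparison <- list(
      tstv_test = compare_tstv(records, snp),
      impact_test = compare_impact_scores(
        records$impact_score[!is.na(records$impact_score)],
        snp$impact_score[!is.na(snp$impact_score)]),
      snp_enrichment = domain_enrichment(snp, arch))
  }

  if (!is.null(config$pdb)) {
    s <- read_structure(config$pdb)
    contacts <- detect_contacts(s)
    tally <- per_zf_bond_tally(contacts, arch)
    files <- c(files, wtsv(as.data.frame(tally), "table1_tally.tsv"))
    summary$contacts <- list(n = nrow(contacts),
                             grand_total = attr(tally, "grand_total"))
    if (!is.null(config$pdb_reference)) {
      ref <- read_structure(config$pdb_reference)
      ref_tally <- per_zf_bond_tally(detect_contacts(ref), arch)
      nc <- tally_net_change(tally, ref_tally)
      files <- c(files, wtsv(nc, "table1_net_change.tsv"))
      summary$contacts$net_total <- attr(nc, "net_total")
    }
  }

  summary$files <- files
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
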
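# File readers/writers and the end-to-end report runner.
#
# Dialects: abundance tables are CSV (comma, dot decimal, UTF-8); OTU,
# taxonomy and metadata tables are TSV in the Mothur/QIIME-classic flavor
# (a leading "#OTU ID" header is tolerated on read). Every writer emits a
# leading comment line with a short config fingerprint; readers skip and
# preserve comment lines.

ABUNDANCE_COLS <- c("sample_id", "treatment", "replicate", "day", "phase",
                    "gene", "copies_per_g_dw", "n_pos_droplets",
                    "n_total_droplets")

write_with_header <- function(df, path, sep, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# plasmidfate config_hash=%s", hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Write / read an abundance table (CSV)
#'
#' The on-disk format has columns `sample_id`, `treatment`, `replicate`,
#' `day`, `phase`, `gene`, `copies_per_g_dw`, `n_pos_droplets`,
#' `n_total_droplets` (plus any extras, preserved), and a leading `#` comment
#' line carrying a config fingerprint. On read, records are validated:
#' required columns present, concentrations numeric and non-negative, and
#' the (treatment, replicate, day, gene) key unique.
#'
#' @param abundance Abundance data frame.
#' @param path File path.
#' @param hash Fingerprint written into the header comment.
#' @return `read_abundance_csv` returns the validated data frame.
#' @export
write_abundance_csv <- function(abundance, path, hash = fnv1a_hash(abundance)) {
  missing <- setdiff(ABUNDANCE_COLS, names(abundance))
  if (length(missing) > 0)
    stop_values("abundance table lacks columns: %s",
                paste(missing, collapse = ", "))
  write_with_header(abundance, path, ",", hash)
  invisible(path)
}

#' @rdname write_abundance_csv
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(ABUNDANCE_COLS, names(df))
  if (length(missing) > 0)
    stop_values("missing required columns: %s", paste(missing, collapse = ", "))
  if (!is.numeric(df$copies_per_g_dw))
    stop_values("copies_per_g_dw must be numeric")
  if (any(df$copies_per_g_dw < 0, na.rm = TRUE))
    stop_values("copies_per_g_dw must be >= 0")
  key <- paste(df$treatment, df$replicate, df$day, df$gene, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    stop_values("duplicate (treatment, replicate, day, gene) key: %s",
                dup[1])
  df
}

#' Write / read OTU-table inputs (TSV triplet)
#'
#' Writes the count matrix (`#OTU ID` header, rows = OTUs), the taxonomy
#' table (`otu_id` plus a rank-prefixed lineage string
#' `k__...;p__...;c__...;o__...;f__...;g__...`) and the sample metadata as
#' three TSV files. `read_otu_inputs` cross-validates them (every counted
#' OTU has taxonomy, every sample has metadata, counts integral and
#' non-negative) and returns an [otu_table()].
#'
#' @param otu An [otu_table()].
#' @param otu_path,tax_path,meta_path File paths.
#' @return `read_otu_inputs` returns an [otu_table()].
#' @export
write_otu_tsv <- function(otu, otu_path, tax_path, meta_path) {
  hash <- fnv1a_hash(otu$counts)
  cdf <- data.frame(`#OTU ID` = rownames(otu$counts), otu$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_with_header(cdf, otu_path, "\t", hash)
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  lineage <- apply(otu$taxonomy[, TAX_RANKS], 1, function(r)
    paste0(prefixes, ifelse(is.na(r) | r == "unclassified", "", r),
           collapse = ";"))
  tdf <- data.frame(otu_id = otu$taxonomy$otu_id, lineage = lineage,
                    stringsAsFactors = FALSE)
  write_with_header(tdf, tax_path, "\t", hash)
  write_with_header(otu$metadata, meta_path, "\t", hash)
  invisible(c(otu_path, tax_path, meta_path))
}

#' @rdname write_otu_tsv
#' @export
read_otu_inputs <- function(otu_path, tax_path, meta_path) {
  lines <- readLines(otu_path, encoding = "UTF-8")
  lines <- lines[!grepl("^#(?!OTU)", lines, perl = TRUE)]
  cdf <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("#OTU ID", "otu_id", "OTU_ID"), names(cdf))[1]
  if (is.na(id_col)) stop_values("OTU file lacks an '#OTU ID' column")
  counts <- as.matrix(cdf[, setdiff(names(cdf), id_col), drop = FALSE])
  rownames(counts) <- cdf[[id_col]]
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_values("counts must be non-negative integers")
  storage.mode(counts) <- "integer"

  tdf <- utils::read.delim(tax_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  taxonomy <- parse_lineages(tdf$otu_id, tdf$lineage)
  meta <- utils::read.delim(meta_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  orphan <- setdiff(rownames(counts), taxonomy$otu_id)
  if (length(orphan) > 0)
    stop_values("OTUs missing from taxonomy: %s",
                paste(utils::head(orphan, 5), collapse = ", "))
  otu_table(counts, taxonomy, meta)
}

#' Parse rank-prefixed lineage strings
#'
#' Converts `k__Bacteria;p__Firmicutes;...;g__Bacillus` strings into a
#' six-rank taxonomy data frame. Empty or missing ranks become
#' `"unclassified"`; lineages shorter than six ranks are right-padded, and
#' longer ones truncated at genus.
#'
#' @param otu_ids Character vector of OTU ids.
#' @param lineages Character vector of lineage strings.
#' @return Taxonomy data frame (`otu_id` + six rank columns).
#' @export
parse_lineages <- function(otu_ids, lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  ranks <- t(vapply(parts, function(p) {
    p <- sub("^[kpcofg]__", "", trimws(p))
    p[p == ""] <- "unclassified"
    length(p) <- 6L
    p[is.na(p)] <- "unclassified"
    p
  }, character(6)))
  df <- data.frame(otu_id = otu_ids, ranks, stringsAsFactors = FALSE)
  names(df) <- c("otu_id", TAX_RANKS)
  df
}

#' Write the ground-truth sidecar of a simulated experiment
#'
#' @param experiment A `compost_experiment` from [make_experiment()].
#' @param path Output JSON path.
#' @export
write_truth_json <- function(experiment, path) {
  jsonlite::write_json(experiment$truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file of [synthetic_config()] arguments (unknown keys are
#' rejected) and returns the validated configuration. The
#' `community_template` key, if present, must be a path to a TSV with the
#' template columns; otherwise the default template is used.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$community_template) && is.character(raw$community_template)) {
    raw$community_template <- utils::read.delim(raw$community_template,
                                                stringsAsFactors = FALSE)
  }
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop_values("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(synthetic_config, raw)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes every stage on a simulated or loaded experiment: biphasic decay
#' fits with D-values, removal efficiencies at the thermophilic- and
#' maturation-phase boundaries, the spread-potential time series, alpha
#' diversity with group comparison, Bray-Curtis / PCoA ordination, PERMANOVA
#' over sample groups, and the genus host-range summary. Results are
#' returned as a list and, when `outdir` is given, written as TSV files plus
#' a machine-readable `report.json` recording configuration, seed and
#' package version. Identical config and seed give identical outputs.
#'
#' @param experiment A `compost_experiment`, or `NULL` to simulate one from
#'   `cfg`.
#' @param cfg A [synthetic_config()] (used when `experiment` is `NULL`).
#' @param breakpoint_day Breakpoint for the decay fits.
#' @param copies_per_cell Divisor for the spread potential.
#' @param n_permutations PERMANOVA permutations.
#' @param outdir Optional output directory.
#' @return A list of class `compost_report` with elements `decay`,
#'   `removal`, `sp`, `sp_summary`, `alpha`, `alpha_comparison`,
#'   `bray_curtis`, `pcoa`, `permanova`, `host_range`, `top_genera`,
#'   `config_hash`, `seed`.
#' @export
run_report <- function(experiment = NULL, cfg = synthetic_config(),
                       breakpoint_day = 15, copies_per_cell = 4,
                       n_permutations = 999, outdir = NULL) {
  if (is.null(experiment)) experiment <- make_experiment(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_values("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  ab <- experiment$abundance
  cfg <- experiment$config %||% cfg
  decay <- stage("decay", fit_decay_table(ab, breakpoint_day))
  removal <- stage("removal", {
    rows <- list()
    for (tr in unique(ab$treatment)) for (g in c("dsRed", "gfp")) {
      sub <- ab[ab$treatment == tr & ab$gene == g, ]
      c0 <- mean(sub$copies_per_g_dw[sub$day == 0], na.rm = TRUE)
      for (ph in c("TP", "MP")) {
        in_ph <- sub[sub$phase == ph, ]
        if (nrow(in_ph) == 0L) next
        dmax <- max(in_ph$day)
        ct <- mean(in_ph$copies_per_g_dw[in_ph$day == dmax], na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, gene = g, phase_end = ph, day = dmax,
          removal_pct = removal_efficiency(c0, ct),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  sp <- stage("spread_potential", sp_timeseries(ab, copies_per_cell))
  alpha <- stage("alpha_diversity", alpha_diversity_table(experiment$otu))
  alpha_cmp <- stage("alpha_comparison",
                     compare_alpha_groups(alpha))
  bc <- stage("bray_curtis", bray_curtis(experiment$otu$counts))
  ord <- stage("pcoa", pcoa(bc))
  perm <- stage("permanova",
                permanova(bc, experiment$otu$metadata$group,
                          n_permutations, seed = cfg$seed + 2L))
  hr <- stage("host_range", host_range_summary(genus_sets(experiment$otu)))
  topg <- stage("top_genera",
                top_n_matrix(aggregate_taxonomy(experiment$otu, "genus"), 30))
  hash <- fnv1a_hash(list(cfg$seed, cfg$sampling_days, cfg$treatments))
  report <- structure(list(
    decay = decay, removal = removal, sp = sp, sp_summary = sp_summary(sp),
    alpha = alpha, alpha_comparison = alpha_cmp, bray_curtis = bc,
    pcoa = ord, permanova = perm, host_range = hr, top_genera = topg,
    config_hash = hash, seed = cfg$seed
  ), class = "compost_report")
  if (!is.null(outdir)) write_report(report, experiment, outdir)
  report
}

write_report <- function(report, experiment, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  h <- report$config_hash
  write_abundance_csv(experiment$abundance,
                      file.path(outdir, "abundance.csv"), h)
  write_otu_tsv(experiment$otu, file.path(outdir, "otu_counts.tsv"),
                file.path(outdir, "taxonomy.tsv"),
                file.path(outdir, "sample_metadata.tsv"))
  write_with_header(report$decay, file.path(outdir, "decay_fits.tsv"), "\t", h)
  write_with_header(report$removal,
                    file.path(outdir, "removal_efficiency.tsv"), "\t", h)
  write_with_header(report$sp, file.path(outdir, "spread_potential.tsv"),
                    "\t", h)
  write_with_header(report$alpha, file.path(outdir, "alpha_diversity.tsv"),
                    "\t", h)
  coords <- data.frame(sample_id = rownames(report$pcoa$coordinates),
                       report$pcoa$coordinates, stringsAsFactors = FALSE)
  write_with_header(coords, file.path(outdir, "pcoa_coordinates.tsv"), "\t", h)
  summary <- list(
    package_version = as.character(utils::packageVersion("plasmidfate")),
    seed = report$seed,
    config_hash = h,
    d_value_summary = attr(report$decay, "d_value_summary"),
    sp_summary = report$sp_summary,
    permanova = unclass(report$permanova),
    host_range = list(sizes = report$host_range$sizes,
                      unique = report$host_range$unique_counts,
                      core_n = length(report$host_range$core),
                      shared_pct_union = report$host_range$shared_pct_union)
  )
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.compost_report <- function(x, ...) {
  cat("plasmidfate pipeline report\n")
  cat(sprintf("  decay fits: %d rows; PERMANOVA p = %.4g; core genera: %d\n",
              nrow(x$decay), x$permanova$p_value, length(x$host_range$core)))
  invisible(x)
}
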
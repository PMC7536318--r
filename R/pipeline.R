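#' Pipeline configuration
#'
#' Collects the knobs of every stage in one declarative object. Defaults
#' follow the survey protocol the package implements: screening E-value
#' cutoff 1e-3 (inclusive) for external domain tables, 0.5 bits/column for
#' the internal profile screen, the canonical hgcA/hgcB motifs, adjacency
#' pairing (gene gap 1, 500 bp, same strand), a 2.0 mL/L normoxic oxygen
#' boundary, and NJ placement with a 0.75 clade consensus and a 0.95
#' long-branch quantile.
#'
#' @param screen_source `"internal"` or `"domain_table"`.
#' @param domain_table Path to a per-domain table when
#'   `screen_source = "domain_table"`.
#' @param e_threshold,bits_per_column_threshold Screen cutoffs.
#' @param motif_patterns Named character vector of motif pattern texts.
#' @param max_gene_gap,max_bp_gap,require_same_strand Pairing parameters.
#' @param redox_threshold Normoxic O2 boundary (mL/L).
#' @param run_placement Run NJ placement/taxonomy (default TRUE when a
#'   reference set is available).
#' @param consensus_threshold,long_branch_quantile,bootstrap_replicates
#'   Placement parameters.
#' @param per_locus_abundance Also emit per-locus abundance records.
#' @param seed Seed for stochastic stages (bootstrap).
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the report tables there.
#' @return List of class `hgc_pipeline_config`.
#' @export
pipeline_config <- function(screen_source = c("internal", "domain_table"),
                            domain_table = NULL,
                            e_threshold = 1e-3,
                            bits_per_column_threshold = 0.5,
                            motif_patterns = c(hgcA = "NVWCA(A/G/S)GK",
                                               hgcB = "C(M/I)EC(G/S)(A/G)C"),
                            max_gene_gap = 1L, max_bp_gap = 500L,
                            require_same_strand = TRUE,
                            redox_threshold = 2.0,
                            run_placement = TRUE,
                            consensus_threshold = 0.75,
                            long_branch_quantile = 0.95,
                            bootstrap_replicates = 0,
                            per_locus_abundance = FALSE,
                            seed = 1L,
                            out_dir = NULL) {
  screen_source <- match.arg(screen_source)
  structure(as.list(environment()), class = "hgc_pipeline_config")
}

#' Run the full hgc marker-mining pipeline
#'
#' Executes screen -> verify -> call loci -> abundance -> zone summary /
#' fraction enrichment -> placement, and returns a run report whose stage
#' counts are mutually consistent (candidates >= verified >= genes in
#' loci). Identical inputs, configuration and seed give identical reports.
#'
#' @param catalog An `hgc_catalog`.
#' @param counts Optional `hgc_counts`; abundance stages are skipped when
#'   absent.
#' @param metadata Optional metadata data.frame; zone and enrichment stages
#'   are skipped when absent.
#' @param refs Optional reference set for placement (default the bundled
#'   synthetic set when placement is enabled).
#' @param profiles Screen profiles for the internal source (default
#'   [default_profiles()]).
#' @param config An `hgc_pipeline_config`.
#' @return List of class `hgc_run_report`: `n_genes`, `n_candidates`,
#'   `n_verified`, `candidates`, `verified`, `loci`, `locus_summary`,
#'   `abundance`, `zone_summary`, `enrichment`, `assignments`, and
#'   `provenance` (config echo, package version, seed).
#' @export
run_pipeline <- function(catalog, counts = NULL, metadata = NULL,
                         refs = NULL, profiles = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "hgc_pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(),
                                                            "%H:%M:%S"), name))
  motifs <- lapply(config$motif_patterns, compile_motif)
  names(motifs) <- names(config$motif_patterns)

  stage("screen")
  if (config$screen_source == "internal") {
    if (is.null(profiles)) profiles <- default_profiles()
    candidates <- screen_candidates(
      catalog, profiles = profiles,
      bits_per_column_threshold = config$bits_per_column_threshold)
  } else {
    candidates <- screen_candidates(
      catalog, domain_table = config$domain_table,
      e_threshold = config$e_threshold)
  }

  report <- list(
    n_genes = nrow(catalog$genes),
    n_candidates = nrow(candidates),
    candidates = candidates)

  if (!nrow(candidates)) {
    warning("no candidate hits; downstream stages skipped")
    report$n_verified <- 0L
    report$verified <- candidates
    report$loci <- NULL
    report$provenance <- .provenance(config)
    class(report) <- "hgc_run_report"
    return(report)
  }

  stage("verify")
  verified <- verify_candidates(candidates, catalog, motifs)
  report$n_verified <- nrow(verified)
  report$verified <- verified

  stage("call_loci")
  loci <- call_loci(verified, catalog,
                    max_gene_gap = config$max_gene_gap,
                    max_bp_gap = config$max_bp_gap,
                    require_same_strand = config$require_same_strand)
  report$loci <- loci
  report$locus_summary <- summarize_loci(loci)

  if (!is.null(counts) && nrow(loci)) {
    stage("abundance")
    report$abundance <- compute_abundance(counts, loci, per_locus = FALSE)
    if (config$per_locus_abundance)
      report$abundance_per_locus <- compute_abundance(counts, loci,
                                                      per_locus = TRUE)
    if (!is.null(metadata)) {
      zones <- classify_redox(metadata,
                              threshold_mL_per_L = config$redox_threshold)
      report$zone_summary <- summarize_by_zone(report$abundance, zones)
      report$enrichment <- tryCatch(
        fraction_enrichment(report$abundance, metadata),
        warning = function(w) NULL)
    }
  }

  if (config$run_placement && nrow(loci)) {
    stage("place")
    if (is.null(refs)) refs <- default_reference_set()
    report$assignments <- place_loci(
      loci, catalog, refs,
      consensus_threshold = config$consensus_threshold,
      long_branch_quantile = config$long_branch_quantile)
  }

  report$provenance <- .provenance(config)
  class(report) <- "hgc_run_report"

  if (!is.null(config$out_dir)) .write_report(report, catalog, config$out_dir)
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  report
}

.provenance <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  list(config = cfg,
       package_version = as.character(utils::packageVersion("hgcminer")),
       seed = config$seed)
}

.write_report <- function(report, catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$candidates) && nrow(report$candidates))
    .write_tsv(report$candidates, file.path(dir, "candidates.tsv"))
  if (!is.null(report$verified) && nrow(report$verified))
    .write_tsv(report$verified, file.path(dir, "verified.tsv"))
  if (!is.null(report$loci) && nrow(report$loci)) {
    write_loci(report$loci, file.path(dir, "loci.tsv"))
    write_loci_gff3(report$loci, catalog, file.path(dir, "loci.gff3"))
  }
  if (!is.null(report$abundance))
    .write_tsv(report$abundance, file.path(dir, "abundance.tsv"))
  if (!is.null(report$zone_summary))
    write_zone_summary(report$zone_summary, file.path(dir, "zone_summary.tsv"))
  if (!is.null(report$enrichment) && nrow(report$enrichment))
    .write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(report$assignments) && nrow(report$assignments)) {
    .write_tsv(report$assignments, file.path(dir, "assignments.tsv"))
    trees <- attr(report$assignments, "trees")
    for (mn in names(trees))
      ape::write.tree(trees[[mn]], file.path(dir, paste0("tree_", mn, ".nwk")))
  }
  jsonlite::write_json(report_as_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Serialise a run report to a JSON-ready structure
#'
#' Stable, deterministic representation used for the machine-readable
#' report; two identical runs serialise identically.
#'
#' @param report An `hgc_run_report`.
#' @return A plain list.
#' @export
report_as_json <- function(report) {
  ls <- report$locus_summary
  list(
    n_genes = report$n_genes,
    n_candidates = report$n_candidates,
    n_verified = report$n_verified,
    locus_counts = if (!is.null(ls)) as.list(ls$category_counts),
    n_loci = if (!is.null(ls)) ls$n_loci,
    n_hgcA_genes = if (!is.null(ls)) ls$n_hgcA_genes,
    n_hgcB_genes = if (!is.null(ls)) ls$n_hgcB_genes,
    motif_combinations = if (!is.null(ls)) ls$motif_combinations,
    zone_summary = report$zone_summary,
    enrichment = report$enrichment,
    assignments = if (!is.null(report$assignments))
      as.data.frame(report$assignments),
    provenance = report$provenance)
}

#' @export
print.hgc_run_report <- function(x, ...) {
  cat("hgc pipeline run:", x$n_genes, "genes screened\n")
  cat("  candidates:", x$n_candidates, "| verified:", x$n_verified, "\n")
  if (!is.null(x$locus_summary)) print(x$locus_summary)
  if (!is.null(x$zone_summary)) {
    cat("  zone summary (1e-3 % units):\n")
    print(x$zone_summary, row.names = FALSE)
  }
  invisible(x)
}
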
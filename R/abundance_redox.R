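#' Classify samples into redox zones from oxygen measurements
#'
#' Water-column samples fall into three categories: normoxic (detected O2 at
#' or above the threshold, boundary inclusive), hypoxic (detected O2 below
#' the threshold) and anoxic (no detectable O2). The anoxic call rests
#' solely on the explicit detection flag, never on a numeric zero.
#'
#' @param meta Metadata data.frame from [load_sample_metadata()] (or any
#'   frame with `o2_detected` and `o2_mL_per_L`).
#' @param threshold_mL_per_L Normoxic boundary in mL O2 per litre
#'   (default 2.0).
#' @return Character vector (`"normoxic"`, `"hypoxic"`, `"anoxic"`) named by
#'   `sample_id` when present.
#' @examples
#' m <- data.frame(sample_id = c("a", "b", "c"),
#'                 o2_detected = c(TRUE, TRUE, FALSE),
#'                 o2_mL_per_L = c(2.0, 0.5, NA))
#' classify_redox(m)
#' @export
classify_redox <- function(meta, threshold_mL_per_L = 2.0) {
  zone <- ifelse(!meta$o2_detected, "anoxic",
          ifelse(meta$o2_mL_per_L >= threshold_mL_per_L,
                 "normoxic", "hypoxic"))
  if (!is.null(meta$sample_id)) names(zone) <- meta$sample_id
  zone
}

#' Compute per-sample relative abundance of hgc loci
#'
#' The statistic is reads mapped to the locus's member genes divided by the
#' sample's total annotated reads, expressed as a percentage. No gene-length
#' normalisation is applied by default — the survey statistic is a pure read
#' ratio; a per-kilobase mode exists for sensitivity analysis only.
#'
#' @param counts An `hgc_counts` object.
#' @param loci data.frame from [call_loci()].
#' @param catalog Required only when `per_kb = TRUE`, to supply gene lengths.
#' @param per_locus When `TRUE`, one record per locus per sample; otherwise a
#'   single summed record per sample (aggregate key `"all_hgc"`).
#' @param per_kb Divide each gene's reads by its length in kb before
#'   summing (default `FALSE`).
#' @return data.frame with `sample_id`, `locus_name`,
#'   `relative_abundance_pct` and `display_units_1e3`
#'   (`relative_abundance_pct * 1e3`, the conventional display unit).
#' @export
compute_abundance <- function(counts, loci, catalog = NULL,
                              per_locus = FALSE, per_kb = FALSE) {
  stopifnot(inherits(counts, "hgc_counts"))
  member <- function(lc) stats::na.omit(c(lc$hgcA_gene_id, lc$hgcB_gene_id))
  genes <- unique(unlist(lapply(seq_len(nrow(loci)), function(i)
    member(loci[i, ]))))
  missing <- setdiff(genes, rownames(counts$counts))
  if (length(missing))
    stop("locus gene(s) missing from count matrix: ",
         paste(missing, collapse = ", "))
  weight <- function(gids) {
    m <- counts$counts[gids, , drop = FALSE]
    if (per_kb) {
      if (is.null(catalog)) stop("per_kb mode needs `catalog`")
      g <- catalog$genes; rownames(g) <- g$gene_id
      kb <- (g[gids, "end_bp"] - g[gids, "start_bp"] + 1) / 1000
      m <- m / kb
    }
    colSums(m)
  }
  samples <- colnames(counts$counts)
  if (per_locus) {
    recs <- lapply(seq_len(nrow(loci)), function(i) {
      s <- weight(member(loci[i, ]))
      data.frame(sample_id = samples, locus_name = loci$locus_name[i],
                 relative_abundance_pct = 100 * s / counts$totals[samples],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
  } else {
    s <- if (length(genes)) weight(genes) else setNames(rep(0, length(samples)),
                                                        samples)
    out <- data.frame(sample_id = samples, locus_name = "all_hgc",
                      relative_abundance_pct = 100 * s / counts$totals[samples],
                      stringsAsFactors = FALSE)
  }
  out$display_units_1e3 <- out$relative_abundance_pct * 1e3
  rownames(out) <- NULL
  out
}

#' Summarise summed hgc abundance by redox zone
#'
#' @param records Summed abundance records (one row per sample) from
#'   [compute_abundance()] with `per_locus = FALSE`.
#' @param zones Named character vector mapping every `sample_id` to a redox
#'   zone, as from [classify_redox()].
#' @return data.frame with one row per occupied zone plus an `all` row:
#'   `zone`, `n_samples`, `mean`, `sd`, `min`, `max` in display units
#'   (1e-3 %), and `degenerate_n` flagging single-sample zones whose sd is
#'   reported as 0. sd uses the n-1 denominator. Zones with no samples are
#'   omitted with a warning.
#' @export
summarize_by_zone <- function(records, zones) {
  miss <- setdiff(records$sample_id, names(zones))
  if (length(miss)) stop("no zone for sample(s): ",
                         paste(miss, collapse = ", "))
  z <- zones[records$sample_id]
  x <- records$display_units_1e3
  one <- function(label, v) data.frame(
    zone = label, n_samples = length(v), mean = mean(v),
    sd = if (length(v) > 1) sd(v) else 0,
    min = min(v), max = max(v), degenerate_n = length(v) < 2,
    stringsAsFactors = FALSE)
  zl <- c("normoxic", "hypoxic", "anoxic")
  absent <- setdiff(zl, unique(z))
  if (length(absent))
    warning("zone(s) with 0 samples omitted: ", paste(absent, collapse = ", "))
  rows <- lapply(intersect(zl, unique(z)), function(zz) one(zz, x[z == zz]))
  out <- do.call(rbind, c(rows, list(one("all", x))))
  rownames(out) <- NULL
  out
}

#' Particle-fraction enrichment of hgc abundance
#'
#' Compares particle-associated metagenomes (capture filter `capture_um`,
#' no pre-filter) to free-living metagenomes (capture `fraction_um` after a
#' `capture_um` pre-filter) collected at the same station, date and depth,
#' and reports the abundance fold-ratio per matched pair.
#'
#' @param records Summed abundance records (one row per sample).
#' @param metadata Metadata data.frame.
#' @param pairing_keys Columns defining a matched pair
#'   (default station, date, depth_m). Matching is exact.
#' @param capture_um Particle-fraction filter pore size (default 3).
#' @param fraction_um Free-living capture pore size (default 0.2).
#' @return data.frame with the pairing keys, both sample ids, both
#'   abundances (display units), `ratio`
#'   (particle / free-living) and `undefined` (TRUE when the free-living
#'   abundance is 0; `ratio` is then `NA`, never infinity). Empty with a
#'   warning when no pairs match.
#' @export
fraction_enrichment <- function(records, metadata,
                                pairing_keys = c("station", "date", "depth_m"),
                                capture_um = 3, fraction_um = 0.2) {
  ab <- setNames(records$display_units_1e3, records$sample_id)
  md <- metadata[metadata$sample_id %in% names(ab), , drop = FALSE]
  part <- md[md$filter_um == capture_um & is.na(md$prefilter_um), ,
             drop = FALSE]
  free <- md[md$filter_um == fraction_um &
             !is.na(md$prefilter_um) & md$prefilter_um == capture_um, ,
             drop = FALSE]
  empty <- data.frame(matrix(nrow = 0, ncol = length(pairing_keys) + 5,
                             dimnames = list(NULL, c(pairing_keys,
                               "particle_sample", "freeliving_sample",
                               "particle_abundance", "freeliving_abundance",
                               "ratio"))))
  if (!nrow(part) || !nrow(free)) {
    warning("no matched filter-fraction pairs")
    empty$undefined <- logical()
    return(empty)
  }
  m <- merge(part[, c(pairing_keys, "sample_id")],
             free[, c(pairing_keys, "sample_id")],
             by = pairing_keys, suffixes = c("_particle", "_freeliving"))
  if (!nrow(m)) {
    warning("no matched filter-fraction pairs")
    empty$undefined <- logical()
    return(empty)
  }
  num <- unname(ab[m$sample_id_particle])
  den <- unname(ab[m$sample_id_freeliving])
  out <- data.frame(m[pairing_keys],
                    particle_sample = m$sample_id_particle,
                    freeliving_sample = m$sample_id_freeliving,
                    particle_abundance = num,
                    freeliving_abundance = den,
                    ratio = ifelse(den > 0, num / den, NA_real_),
                    undefined = den == 0,
                    stringsAsFactors = FALSE)
  out[order(out$particle_sample), ]
}

#' Rarefaction curve of hgc gene detection
#'
#' Subsamples a sample's reads without replacement (a multivariate
#' hypergeometric draw over the gene count vector — the expectation is
#' identical to subsampling raw reads) and counts how many hgc member genes
#' are detected with at least one read at each depth, averaged over
#' replicates.
#'
#' @param counts An `hgc_counts` object.
#' @param loci data.frame from [call_loci()].
#' @param sample_id Sample to rarefy.
#' @param depths Integer vector of subsampling depths, each at most the
#'   sample's total annotated reads.
#' @param replicates Replicates per depth (default 10).
#' @param seed RNG seed; the curve is deterministic for a fixed seed.
#' @return data.frame with `depth`, `mean_detected`, `sd_detected`.
#' @export
rarefaction <- function(counts, loci, sample_id, depths, replicates = 10,
                        seed = 1L) {
  stopifnot(inherits(counts, "hgc_counts"))
  if (!sample_id %in% colnames(counts$counts))
    stop("unknown sample: ", sample_id)
  genes <- unique(stats::na.omit(c(loci$hgcA_gene_id, loci$hgcB_gene_id)))
  missing <- setdiff(genes, rownames(counts$counts))
  if (length(missing))
    stop("locus gene(s) missing from count matrix: ",
         paste(missing, collapse = ", "))
  k <- counts$counts[genes, sample_id]
  N <- counts$totals[[sample_id]]
  if (any(depths > N))
    stop("depth exceeds total_annotated_reads (", N, ")")
  if (any(depths < 0)) stop("depths must be >= 0")
  .with_seed(seed, {
    rows <- lapply(depths, function(d) {
      det <- vapply(seq_len(replicates), function(r) {
        x <- .rmvhyper(k, N, d)
        sum(x >= 1)
      }, 0)
      data.frame(depth = d, mean_detected = mean(det),
                 sd_detected = if (replicates > 1) sd(det) else 0)
    })
    do.call(rbind, rows)
  })
}

# One multivariate hypergeometric draw: d reads taken without replacement
# from a pool of N reads of which k[i] belong to gene i (the remainder is a
# single background class). Sequential conditional hypergeometric draws.
.rmvhyper <- function(k, N, d) {
  x <- integer(length(k))
  rem_N <- N; rem_d <- d
  for (i in seq_along(k)) {
    if (rem_d == 0) break
    x[i] <- rhyper(1, k[i], rem_N - k[i], rem_d)
    rem_N <- rem_N - k[i]
    rem_d <- rem_d - x[i]
  }
  x
}

#' Write a zone summary table
#' @param summary data.frame from [summarize_by_zone()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_zone_summary <- function(summary, path) {
  .write_tsv(summary, path)
  invisible(path)
}
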
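#' Load a predicted-protein gene catalog with contig coordinates
#'
#' Joins an amino-acid FASTA of predicted proteins to a gene-coordinate table
#' and derives per-contig gene ranks and edge-truncation flags. Coordinates
#' are 1-based and inclusive (GFF3 convention); all downstream arithmetic
#' assumes this.
#'
#' @param protein_fasta Path to an amino-acid FASTA file. The first
#'   whitespace-delimited token of each header is the `gene_id`.
#' @param coords_table Path to either a GFF3 file (CDS features whose `ID`
#'   attribute is the `gene_id`; contig lengths from `##sequence-region`
#'   pragmas) or a tab-delimited table with columns `gene_id`, `contig_id`,
#'   `start`, `end`, `strand`, `partial` and optionally `contig_length`.
#'   `partial` uses the two-character gene-caller convention: `"10"` =
#'   5'-truncated, `"01"` = 3'-truncated, `"11"` = both, `"00"`/empty = none.
#'
#' @details When `contig_length` is absent it is inferred as the maximum
#'   gene `end` on each contig. When the `partial` column is absent or empty
#'   the truncation flags fall back to coincidence with a contig boundary
#'   (`start == 1` or `end == contig length`): edge-truncated open reading
#'   frames are exactly what assembled-metagenome gene callers flag at
#'   contig extremities, and the lone-hgcA argument rests on that flag.
#'
#' @return A list with class `hgc_catalog`:
#'   \describe{
#'     \item{genes}{data.frame with one row per gene: `gene_id`, `contig_id`,
#'       `start_bp`, `end_bp`, `strand`, `gene_index` (0-based rank along the
#'       contig, ascending `start_bp`), `aa_sequence`, `partial5`, `partial3`.}
#'     \item{contigs}{data.frame with `contig_id`, `length_bp`, `n_genes`.}
#'   }
#' @examples
#' fx <- build_locus_catalog(n_paired = 1, n_lone_hgcA = 1, n_lone_hgcB = 1,
#'                           n_decoys = 2, n_background = 2)
#' td <- tempfile(); dir.create(td)
#' write_gene_catalog(fx, file.path(td, "cat.faa"), file.path(td, "coords.tsv"))
#' cat2 <- load_gene_catalog(file.path(td, "cat.faa"), file.path(td, "coords.tsv"))
#' nrow(cat2$genes)
#' @export
load_gene_catalog <- function(protein_fasta, coords_table) {
  seqs <- Biostrings::readAAStringSet(protein_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  coords <- if (grepl("\\.gff3?$", coords_table, ignore.case = TRUE)) {
    .read_coords_gff3(coords_table)
  } else {
    .read_coords_tsv(coords_table)
  }
  if (anyDuplicated(coords$gene_id))
    stop("duplicate gene_id in coordinate table: ",
         paste(unique(coords$gene_id[duplicated(coords$gene_id)]),
               collapse = ", "))
  missing <- setdiff(ids, coords$gene_id)
  if (length(missing))
    stop("genes in FASTA absent from coordinates: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(coords$gene_id, ids)
  if (length(extra)) {
    warning(length(extra), " coordinate rows without a FASTA record dropped")
    coords <- coords[!coords$gene_id %in% extra, , drop = FALSE]
  }
  coords <- coords[match(ids, coords$gene_id), , drop = FALSE]

  aa <- as.character(seqs)
  names(aa) <- ids
  if (any(!nzchar(aa))) stop("empty amino-acid sequence for gene(s): ",
                             paste(ids[!nzchar(aa)], collapse = ", "))

  # contig lengths: explicit column when present, else max(end) per contig
  if (is.null(coords$contig_length) || all(is.na(coords$contig_length))) {
    len <- tapply(coords$end, coords$contig_id, max)
  } else {
    len <- tapply(coords$contig_length, coords$contig_id,
                  function(x) unique(x[!is.na(x)])[1])
  }
  clen <- as.numeric(len[coords$contig_id])
  bad <- which(coords$end > clen | coords$start < 1 | coords$end < coords$start)
  if (length(bad))
    stop("coordinates outside contig bounds for: ",
         paste(coords$gene_id[bad], collapse = ", "))
  if (!all(coords$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  has_partial <- !is.null(coords$partial) && any(!is.na(coords$partial))
  if (has_partial) {
    p <- ifelse(is.na(coords$partial), "00",
                formatC(coords$partial, width = 2, flag = "0"))
    partial5 <- substr(p, 1, 1) == "1"
    partial3 <- substr(p, 2, 2) == "1"
  } else {
    partial5 <- coords$start == 1
    partial3 <- coords$end == clen
  }

  genes <- data.frame(
    gene_id = coords$gene_id,
    contig_id = coords$contig_id,
    start_bp = as.integer(coords$start),
    end_bp = as.integer(coords$end),
    strand = coords$strand,
    aa_sequence = unname(aa[coords$gene_id]),
    partial5 = partial5,
    partial3 = partial3,
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$contig_id, genes$start_bp, genes$gene_id), ]
  genes$gene_index <- unlist(lapply(
    split(seq_len(nrow(genes)), genes$contig_id)[unique(genes$contig_id)],
    function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(genes) <- NULL

  contigs <- data.frame(
    contig_id = names(len),
    length_bp = as.integer(unname(len)),
    stringsAsFactors = FALSE
  )
  tab <- table(genes$contig_id)
  contigs$n_genes <- as.integer(tab[contigs$contig_id])
  contigs <- contigs[order(contigs$contig_id), ]
  rownames(contigs) <- NULL

  structure(list(genes = genes, contigs = contigs), class = "hgc_catalog")
}

.read_coords_tsv <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("coordinate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$partial)) df$partial <- NA_character_
  df$partial <- as.character(df$partial)
  df
}

.read_coords_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer package; ",
         "use the tab-delimited coordinate format instead")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  df <- as.data.frame(gr)
  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) {
    # fall back to ##sequence-region pragmas when seqinfo carries no lengths
    pr <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(pr)) {
      f <- strsplit(trimws(pr), "\\s+")
      sl <- setNames(vapply(f, function(x) as.numeric(x[4]), 0),
                     vapply(f, function(x) x[2], ""))
    }
  }
  data.frame(
    gene_id = as.character(df$ID),
    contig_id = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    partial = if (!is.null(df$partial)) as.character(df$partial)
              else NA_character_,
    contig_length = as.numeric(sl[as.character(df$seqnames)]),
    stringsAsFactors = FALSE
  )
}

#' Write a gene catalog back to FASTA + coordinate TSV
#'
#' Inverse of [load_gene_catalog()]; writing then re-loading yields an
#' identical catalog.
#'
#' @param catalog An `hgc_catalog` as returned by [load_gene_catalog()] or
#'   [build_locus_catalog()].
#' @param fasta_path,coords_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gene_catalog <- function(catalog, fasta_path, coords_path) {
  g <- catalog$genes
  seqs <- Biostrings::AAStringSet(setNames(g$aa_sequence, g$gene_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  cl <- setNames(catalog$contigs$length_bp, catalog$contigs$contig_id)
  .write_tsv(data.frame(
    gene_id = g$gene_id, contig_id = g$contig_id,
    start = g$start_bp, end = g$end_bp, strand = g$strand,
    partial = paste0(as.integer(g$partial5), as.integer(g$partial3)),
    contig_length = as.integer(cl[g$contig_id]),
    stringsAsFactors = FALSE
  ), coords_path)
  invisible(c(fasta_path, coords_path))
}

#' Load a per-sample gene read-count matrix
#'
#' @param counts_tsv Tab-delimited table: first column `gene_id`, remaining
#'   columns one per sample, non-negative integer read counts.
#' @param totals_tsv Tab-delimited table with columns `sample_id` and
#'   `total_annotated_reads` (the per-sample denominator of the relative
#'   abundance statistic).
#' @return An `hgc_counts` object: list with `counts` (genes x samples
#'   integer matrix) and `totals` (named numeric vector).
#' @export
load_count_data <- function(counts_tsv, totals_tsv) {
  cdf <- .read_tsv(counts_tsv)
  if (names(cdf)[1] != "gene_id") stop("first column of counts must be gene_id")
  tdf <- .read_tsv(totals_tsv)
  if (!all(c("sample_id", "total_annotated_reads") %in% names(tdf)))
    stop("totals table needs columns sample_id, total_annotated_reads")
  m <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(m) <- cdf$gene_id
  storage.mode(m) <- "double"
  totals <- setNames(as.numeric(tdf$total_annotated_reads), tdf$sample_id)
  if (!setequal(colnames(m), names(totals)))
    stop("sample columns in counts and totals disagree")
  totals <- totals[colnames(m)]
  count_matrix(m, totals)
}

#' Construct and validate a count matrix
#'
#' @param counts Numeric genes x samples matrix with dimnames.
#' @param totals Named numeric vector of per-sample total annotated reads.
#' @return An `hgc_counts` object.
#' @export
count_matrix <- function(counts, totals) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix must carry gene and sample dimnames")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (!setequal(colnames(counts), names(totals)))
    stop("sample names of counts and totals disagree")
  totals <- totals[colnames(counts)]
  if (any(is.na(totals)) || any(totals <= 0))
    stop("every sample needs a positive total_annotated_reads")
  over <- which(apply(counts, 2, max) > totals)
  if (length(over))
    stop("count exceeds total_annotated_reads in sample(s): ",
         paste(colnames(counts)[over], collapse = ", "))
  structure(list(counts = counts, totals = totals), class = "hgc_counts")
}

#' Write a count matrix to counts + totals TSVs
#' @param cm An `hgc_counts` object.
#' @param counts_tsv,totals_tsv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_count_data <- function(cm, counts_tsv, totals_tsv) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, counts_tsv)
  .write_tsv(data.frame(sample_id = names(cm$totals),
                        total_annotated_reads = unname(cm$totals)),
             totals_tsv)
  invisible(c(counts_tsv, totals_tsv))
}

#' Load a sample metadata table
#'
#' One row per metagenome: station, date, depth, oxygen status, and the
#' filtration descriptors that drive redox and size-fraction stratification.
#' Oxygen non-detection is an explicit boolean column (`o2_detected`), never
#' inferred from a 0.0 value: instruments differ in detection limit, and the
#' anoxic category means "no detectable O2", not "O2 == 0".
#'
#' @param metadata_tsv Tab-delimited table with columns `sample_id`,
#'   `station`, `date` (ISO), `depth_m`, `o2_detected`, `o2_mL_per_L`,
#'   `filter_um`, `prefilter_um` (may be empty), `dataset`.
#' @return data.frame with typed columns; `o2_mL_per_L` is `NA` whenever
#'   `o2_detected` is `FALSE`, and `prefilter_um` is `NA` when absent.
#' @export
load_sample_metadata <- function(metadata_tsv) {
  df <- .read_tsv(metadata_tsv)
  need <- c("sample_id", "station", "date", "depth_m", "o2_detected",
            "o2_mL_per_L", "filter_um", "prefilter_um", "dataset")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  det <- toupper(trimws(as.character(df$o2_detected)))
  o2_detected <- det %in% c("TRUE", "T", "YES", "1")
  bad <- !det %in% c("TRUE", "T", "YES", "1", "FALSE", "F", "NO", "0")
  if (any(bad)) stop("unparseable o2_detected in row(s): ",
                     paste(which(bad), collapse = ", "))
  o2 <- suppressWarnings(as.numeric(df$o2_mL_per_L))
  bad <- o2_detected & (is.na(o2) | o2 < 0)
  if (any(bad))
    stop("unparseable O2 value for detected sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  o2[!o2_detected] <- NA_real_
  data.frame(
    sample_id = as.character(df$sample_id),
    station = as.character(df$station),
    date = as.character(df$date),
    depth_m = as.numeric(df$depth_m),
    o2_detected = o2_detected,
    o2_mL_per_L = o2,
    filter_um = as.numeric(df$filter_um),
    prefilter_um = suppressWarnings(as.numeric(df$prefilter_um)),
    dataset = as.character(df$dataset),
    stringsAsFactors = FALSE
  )
}

#' Write a sample metadata table
#' @param meta data.frame as returned by [load_sample_metadata()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- meta
  out$o2_detected <- ifelse(meta$o2_detected, "TRUE", "FALSE")
  .write_tsv(out, path)
  invisible(path)
}
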
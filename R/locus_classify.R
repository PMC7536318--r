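#' Call hgc loci from verified candidates by contig co-location
#'
#' Pairs verified hgcA and hgcB genes found side-by-side on the same contig
#' into `paired_cluster` loci; the remainder become `hgcA_only` loci (with
#' an edge-truncation flag, since lone hgcA genes in assembled metagenomes
#' are typically cut off at a contig extremity, which explains the missing
#' hgcB) or `hgcB_only` loci (with a centrality flag). "Side-by-side" is
#' operationalised as adjacent gene ranks (`max_gene_gap`), a bounded
#' intergenic distance (`max_bp_gap`) and, by default, equal strands;
#' pairing is greedy by ascending intergenic distance with each gene used at
#' most once, which resolves one hgcA flanked by two hgcB candidates
#' deterministically and matches operon biology.
#'
#' @param verified data.frame from [verify_candidates()].
#' @param catalog,contigs The `hgc_catalog` (or its `genes`/`contigs`
#'   components) the hits refer to. `contigs` may be omitted when `catalog`
#'   is a full `hgc_catalog`.
#' @param max_gene_gap Maximum difference in gene rank along the contig
#'   (default 1 = adjacent genes).
#' @param max_bp_gap Maximum intergenic distance in bp (default 500).
#' @param require_same_strand Require equal strands for pairing (default
#'   TRUE). hgcB orientation relative to hgcA is recorded but never used as
#'   a pairing filter.
#' @param name_prefix Prefix for ordinal locus names (default `"HGC"`).
#'   Paired clusters are named first (sorted by contig then position), then
#'   lone hgcA, then lone hgcB, with zero-padded ordinals.
#' @return data.frame of locus calls: `locus_name`, `category`
#'   (`paired_cluster`/`hgcA_only`/`hgcB_only`), `hgcA_gene_id`,
#'   `hgcB_gene_id`, `contig_id`, `hgcA_motif`, `hgcB_motif`,
#'   `hgcA_truncated_at_edge`, `hgcB_central`, `hgcB_orientation`.
#' @export
call_loci <- function(verified, catalog, contigs = NULL,
                      max_gene_gap = 1L, max_bp_gap = 500L,
                      require_same_strand = TRUE, name_prefix = "HGC") {
  g <- if (inherits(catalog, "hgc_catalog")) catalog$genes else catalog
  ct <- if (inherits(catalog, "hgc_catalog")) catalog$contigs else contigs
  missing <- setdiff(verified$gene_id, g$gene_id)
  if (length(missing))
    stop("verified hit(s) reference genes absent from catalog: ",
         paste(missing, collapse = ", "))

  empty <- data.frame(
    locus_name = character(), category = character(),
    hgcA_gene_id = character(), hgcB_gene_id = character(),
    contig_id = character(), hgcA_motif = character(),
    hgcB_motif = character(), hgcA_truncated_at_edge = logical(),
    hgcB_central = logical(), hgcB_orientation = character(),
    stringsAsFactors = FALSE)
  if (!nrow(verified)) return(empty)

  # a gene verified for both targets is kept only for its higher-scoring one
  v <- verified[order(verified$gene_id,
                      -ifelse(is.na(verified$screen_score), 0,
                              verified$screen_score)), ]
  dup <- duplicated(v$gene_id)
  if (any(dup)) v <- v[!dup, , drop = FALSE]

  rownames(g) <- g$gene_id
  n_on_contig <- table(g$contig_id)
  ainfo <- v[v$target == "hgcA", , drop = FALSE]
  binfo <- v[v$target == "hgcB", , drop = FALSE]

  # candidate pairs on shared contigs
  pairs <- NULL
  if (nrow(ainfo) && nrow(binfo)) {
    cand <- merge(
      data.frame(a = ainfo$gene_id,
                 contig_id = g[ainfo$gene_id, "contig_id"],
                 stringsAsFactors = FALSE),
      data.frame(b = binfo$gene_id,
                 contig_id = g[binfo$gene_id, "contig_id"],
                 stringsAsFactors = FALSE),
      by = "contig_id")
    if (nrow(cand)) {
      ga <- g[cand$a, ]; gb <- g[cand$b, ]
      gap_idx <- abs(ga$gene_index - gb$gene_index)
      inter <- pmax(pmax(ga$start_bp, gb$start_bp) -
                    pmin(ga$end_bp, gb$end_bp) - 1L, 0L)
      ok <- gap_idx <= max_gene_gap & inter <= max_bp_gap
      if (require_same_strand) ok <- ok & ga$strand == gb$strand
      cand <- cand[ok, , drop = FALSE]
      inter <- inter[ok]
      if (nrow(cand)) {
        # greedy by ascending intergenic distance, deterministic tie-break
        ordx <- order(inter, cand$a, cand$b)
        used <- character()
        sel <- logical(nrow(cand))
        for (i in ordx) {
          if (cand$a[i] %in% used || cand$b[i] %in% used) next
          sel[i] <- TRUE
          used <- c(used, cand$a[i], cand$b[i])
        }
        pairs <- cand[sel, , drop = FALSE]
      }
    }
  }

  loci <- list()
  paired_genes <- character()
  if (!is.null(pairs) && nrow(pairs)) {
    ga <- g[pairs$a, ]; gb <- g[pairs$b, ]
    ori <- ifelse(ga$strand == "+",
                  ifelse(gb$start_bp > ga$start_bp, "downstream", "upstream"),
                  ifelse(gb$start_bp < ga$start_bp, "downstream", "upstream"))
    ma <- setNames(ainfo$motif_match, ainfo$gene_id)
    mb <- setNames(binfo$motif_match, binfo$gene_id)
    df <- data.frame(
      category = "paired_cluster",
      hgcA_gene_id = pairs$a, hgcB_gene_id = pairs$b,
      contig_id = pairs$contig_id,
      hgcA_motif = unname(ma[pairs$a]), hgcB_motif = unname(mb[pairs$b]),
      hgcA_truncated_at_edge = ga$partial5 | ga$partial3,
      hgcB_central = NA,
      hgcB_orientation = ori,
      sort_bp = pmin(ga$start_bp, gb$start_bp),
      stringsAsFactors = FALSE)
    loci$paired <- df[order(df$contig_id, df$sort_bp), ]
    paired_genes <- c(pairs$a, pairs$b)
  }

  lone_a <- ainfo[!ainfo$gene_id %in% paired_genes, , drop = FALSE]
  if (nrow(lone_a)) {
    ga <- g[lone_a$gene_id, ]
    df <- data.frame(
      category = "hgcA_only",
      hgcA_gene_id = lone_a$gene_id, hgcB_gene_id = NA_character_,
      contig_id = ga$contig_id,
      hgcA_motif = lone_a$motif_match, hgcB_motif = NA_character_,
      hgcA_truncated_at_edge = ga$partial5 | ga$partial3,
      hgcB_central = NA,
      hgcB_orientation = NA_character_,
      sort_bp = ga$start_bp,
      stringsAsFactors = FALSE)
    loci$lone_a <- df[order(df$contig_id, df$sort_bp), ]
  }

  lone_b <- binfo[!binfo$gene_id %in% paired_genes, , drop = FALSE]
  if (nrow(lone_b)) {
    gb <- g[lone_b$gene_id, ]
    at_edge <- gb$partial5 | gb$partial3 |
      gb$gene_index == 0L |
      gb$gene_index == as.integer(n_on_contig[gb$contig_id]) - 1L
    df <- data.frame(
      category = "hgcB_only",
      hgcA_gene_id = NA_character_, hgcB_gene_id = lone_b$gene_id,
      contig_id = gb$contig_id,
      hgcA_motif = NA_character_, hgcB_motif = lone_b$motif_match,
      hgcA_truncated_at_edge = NA,
      hgcB_central = !at_edge,
      hgcB_orientation = NA_character_,
      sort_bp = gb$start_bp,
      stringsAsFactors = FALSE)
    loci$lone_b <- df[order(df$contig_id, df$sort_bp), ]
  }

  out <- do.call(rbind, loci)
  if (is.null(out) || !nrow(out)) return(empty)
  out$sort_bp <- NULL
  width <- max(2L, nchar(nrow(out)))
  out <- cbind(locus_name = sprintf("%s-%0*d", name_prefix, width,
                                    seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise called loci
#'
#' @param loci data.frame from [call_loci()].
#' @return List of class `hgc_locus_summary`: `n_loci`, `category_counts`,
#'   `n_hgcA_genes`, `n_hgcB_genes`, `motif_combinations` (paired clusters
#'   only), `n_lone_hgcA_truncated`, `n_lone_hgcB_central`.
#' @export
summarize_loci <- function(loci) {
  cats <- c("paired_cluster", "hgcA_only", "hgcB_only")
  cc <- table(factor(loci$category, levels = cats))
  pc <- loci[loci$category == "paired_cluster", , drop = FALSE]
  combos <- if (nrow(pc)) {
    agg <- aggregate(list(n = pc$locus_name),
                     by = list(hgcA_motif = pc$hgcA_motif,
                               hgcB_motif = pc$hgcB_motif),
                     FUN = length)
    agg[order(agg$hgcA_motif, agg$hgcB_motif), ]
  } else {
    data.frame(hgcA_motif = character(), hgcB_motif = character(),
               n = integer(), stringsAsFactors = FALSE)
  }
  structure(list(
    n_loci = nrow(loci),
    category_counts = cc,
    n_hgcA_genes = sum(!is.na(loci$hgcA_gene_id)),
    n_hgcB_genes = sum(!is.na(loci$hgcB_gene_id)),
    motif_combinations = combos,
    n_lone_hgcA_truncated = sum(loci$category == "hgcA_only" &
                                loci$hgcA_truncated_at_edge, na.rm = TRUE),
    n_lone_hgcB_central = sum(loci$category == "hgcB_only" &
                              loci$hgcB_central, na.rm = TRUE)
  ), class = "hgc_locus_summary")
}

#' @export
print.hgc_locus_summary <- function(x, ...) {
  cat("hgc locus summary:", x$n_loci, "loci\n")
  cat(sprintf("  paired clusters: %d | lone hgcA: %d | lone hgcB: %d\n",
              x$category_counts[["paired_cluster"]],
              x$category_counts[["hgcA_only"]],
              x$category_counts[["hgcB_only"]]))
  cat(sprintf("  distinct hgcA genes: %d | hgcB genes: %d\n",
              x$n_hgcA_genes, x$n_hgcB_genes))
  if (nrow(x$motif_combinations)) {
    cat("  motif combinations (paired clusters):\n")
    print(x$motif_combinations, row.names = FALSE)
  }
  invisible(x)
}

#' Write loci as TSV
#' @param loci data.frame from [call_loci()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_loci <- function(loci, path) {
  .write_tsv(loci, path)
  invisible(path)
}

#' Write called loci as a GFF3 feature track
#'
#' Emits one `gene` feature per member gene, tagged with the locus name and
#' category.
#'
#' @param loci data.frame from [call_loci()].
#' @param catalog The `hgc_catalog` supplying coordinates.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_loci_gff3 <- function(loci, catalog, path) {
  g <- catalog$genes
  rownames(g) <- g$gene_id
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(loci))) {
    for (role in c("hgcA", "hgcB")) {
      gid <- loci[[paste0(role, "_gene_id")]][i]
      if (is.na(gid)) next
      gg <- g[gid, ]
      lines <- c(lines, sprintf(
        "%s\thgcminer\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus=%s;role=%s;category=%s",
        gg$contig_id, gg$start_bp, gg$end_bp, gg$strand,
        gid, loci$locus_name[i], role, loci$category[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
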
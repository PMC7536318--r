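# Synthetic consensus-like seed sequences (not database records). The hgcA
# seed carries the cap-helix motif NVWCAAGK at positions 61-68; the hgcB
# seed carries the ferredoxin motif CMECGAC at positions 31-37; neither
# contains a spurious occurrence of either motif.
.hgcA_consensus <- paste0(
  "KHQMNVRHHKHIFQEMEHIGYWSRDMWRTNNGHTCYKWGSVRNCMYWLMCECEQTHDGKA",
  "NVWCAAGK",
  "TRCCTNEMDRWRMNQTYQCYVYIGICAQELLTQTYLWVWDDSDFMNFFAHKCVCYYYLPRWSDPHQRKFAYSSAFFRHGQPH")
.hgcB_consensus <- paste0(
  "VCPKYSQHVQRNAFAAQSLRKSHSMRPRKA",
  "CMECGAC",
  "KAHRINHCKDAKIRAVYQFTQPECSMYVQQTGYAQWWCAPMAHCQYKWTADHE")
.hgcA_motif_span <- 61:68
.hgcB_motif_span <- 31:37

# Mutate a sequence at `rate` per residue, never touching `protect`ed
# positions (the motif columns of true positives stay intact so that ground
# truth remains exactly the motif test).
.mutate_seq <- function(seq, rate, protect = integer()) {
  aa <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(aa)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) aa[i] <- sample(setdiff(.AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

# Ensure a sequence contains no occurrence of either motif except at
# `allowed` start positions (for its own target's motif); spurious windows
# are broken by substituting their first residue.
.strip_spurious_motifs <- function(seq, motifs, allow_target = NULL,
                                   allowed_starts = integer()) {
  repeat {
    dirty <- FALSE
    for (tg in names(motifs)) {
      sc <- scan_motif(motifs[[tg]], seq)
      bad <- if (identical(tg, allow_target))
        sc$start[!sc$start %in% allowed_starts] else sc$start
      if (length(bad)) {
        aa <- strsplit(seq, "")[[1]]
        cur <- aa[bad[1]]
        aa[bad[1]] <- sample(setdiff(.AA20, c(cur, "N", "C")), 1)
        seq <- paste(aa, collapse = "")
        dirty <- TRUE
      }
    }
    if (!dirty) return(seq)
  }
}

.random_protein <- function(len) paste(sample(.AA20, len, TRUE), collapse = "")

# Overwrite a motif window with a given variant string.
.set_motif <- function(seq, variant, at) {
  aa <- strsplit(seq, "")[[1]]
  aa[at + seq_len(nchar(variant)) - 1L] <- strsplit(variant, "")[[1]]
  paste(aa, collapse = "")
}

#' Default motif-variant plan for paired clusters
#'
#' Nine paired clusters: most carry the common NVWCAAGK + CMECGAC
#' combination; clusters 1 and 9 carry NVWCASGK + CIECGAC and cluster 7
#' carries NVWCAAGK + CIECGAC, mirroring the variant census of the Baltic
#' survey this generator emulates.
#'
#' @param n_paired Number of paired clusters.
#' @return data.frame with `hgcA_motif`, `hgcB_motif`, one row per cluster.
#' @export
default_pair_motif_plan <- function(n_paired = 9) {
  plan <- data.frame(hgcA_motif = rep("NVWCAAGK", n_paired),
                     hgcB_motif = rep("CMECGAC", n_paired),
                     stringsAsFactors = FALSE)
  if (n_paired >= 1) { plan$hgcA_motif[1] <- "NVWCASGK"
                       plan$hgcB_motif[1] <- "CIECGAC" }
  if (n_paired >= 9) { plan$hgcA_motif[9] <- "NVWCASGK"
                       plan$hgcB_motif[9] <- "CIECGAC" }
  if (n_paired >= 7) { plan$hgcB_motif[7] <- "CIECGAC" }
  plan
}

#' Build the deterministic locus-census catalog
#'
#' Generates a synthetic predicted-protein catalog whose ground truth
#' reproduces the canonical brackish-survey locus census: paired
#' same-strand hgcA+hgcB clusters on shared contigs, lone hgcA genes
#' truncated at a contig edge, lone centrally placed hgcB genes, plus
#' profile-similar motif-broken decoys and random-composition background
#' genes. Two invocations with identical arguments produce byte-identical
#' output (the generator runs under a fixed internal seed and restores the
#' caller's RNG state).
#'
#' @param n_paired Paired hgcAB clusters (default 9).
#' @param n_lone_hgcA Lone edge-truncated hgcA genes (default 13).
#' @param n_lone_hgcB Lone central hgcB genes (default 3).
#' @param pair_motifs Motif plan data.frame
#'   (default [default_pair_motif_plan()]).
#' @param n_decoys Motif-broken decoys derived from the consensus seeds
#'   (default 100).
#' @param n_background Random background proteins (default 100).
#' @param mutation_rate Per-residue substitution rate applied to true
#'   positives and decoys outside protected motif columns (default 0.08).
#' @param seed Internal seed (default 1009); change only to generate a
#'   different but equally deterministic catalog.
#' @return A list of class `hgc_catalog` with `genes` and `contigs` (as
#'   [load_gene_catalog()] returns) plus `ground_truth`: list with `genes`
#'   (data.frame `gene_id`, `role` in hgcA/hgcB/decoy/background,
#'   `locus_id`, `category`, `motif`) and `loci` (data.frame `locus_id`,
#'   `category`, `hgcA_motif`, `hgcB_motif`).
#' @export
build_locus_catalog <- function(n_paired = 9, n_lone_hgcA = 13,
                                n_lone_hgcB = 3,
                                pair_motifs = default_pair_motif_plan(n_paired),
                                n_decoys = 100, n_background = 100,
                                mutation_rate = 0.08, seed = 1009L) {
  .with_seed(seed,
    .generate_catalog(n_paired, n_lone_hgcA, n_lone_hgcB, pair_motifs,
                      n_decoys, n_background, mutation_rate))
}

.generate_catalog <- function(n_paired, n_lone_hgcA, n_lone_hgcB,
                              pair_motifs, n_decoys, n_background,
                              mutation_rate) {
  motifs <- hgc_motifs()
  genes <- list(); gt <- list(); contigs <- list()
  gid <- 0L
  next_gene_id <- function() { gid <<- gid + 1L; sprintf("G%05d", gid) }

  make_hgcA <- function(variant) {
    s <- .mutate_seq(.hgcA_consensus, mutation_rate, .hgcA_motif_span)
    s <- .set_motif(s, variant, .hgcA_motif_span[1])
    .strip_spurious_motifs(s, motifs, "hgcA", .hgcA_motif_span[1])
  }
  make_hgcB <- function(variant) {
    s <- .mutate_seq(.hgcB_consensus, mutation_rate, .hgcB_motif_span)
    s <- .set_motif(s, variant, .hgcB_motif_span[1])
    .strip_spurious_motifs(s, motifs, "hgcB", .hgcB_motif_span[1])
  }
  make_background <- function() {
    .strip_spurious_motifs(.random_protein(sample(100:200, 1)), motifs)
  }

  add_contig <- function(cid, seqs, roles, loci_ids, cats, mots,
                         edge5 = FALSE, edge3 = FALSE) {
    # lay genes left to right with ~60 bp intergenic gaps; edge5/edge3 pin
    # the first/last gene to the contig boundary (truncated ORF)
    lens <- nchar(seqs) * 3L
    n <- length(seqs)
    starts <- integer(n); ends <- integer(n)
    pos <- if (edge5) 1L else 101L
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + lens[i] - 1L
      pos <- ends[i] + 61L
    }
    clen <- if (edge3) ends[n] else ends[n] + 100L
    strand <- rep(sample(c("+", "-"), 1), n)
    ids <- vapply(seq_len(n), function(i) next_gene_id(), "")
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = ids, contig_id = cid, start_bp = starts, end_bp = ends,
      strand = strand, aa_sequence = seqs,
      partial5 = c(edge5, rep(FALSE, n - 1L)),
      partial3 = c(rep(FALSE, n - 1L), edge3),
      stringsAsFactors = FALSE)
    contigs[[length(contigs) + 1L]] <<- data.frame(
      contig_id = cid, length_bp = clen, n_genes = n,
      stringsAsFactors = FALSE)
    gt[[length(gt) + 1L]] <<- data.frame(
      gene_id = ids, role = roles, locus_id = loci_ids, category = cats,
      motif = mots, stringsAsFactors = FALSE)
    ids
  }

  gt_loci <- list()
  # paired clusters: bg, hgcA, hgcB, bg on one contig, same strand
  for (i in seq_len(n_paired)) {
    lid <- sprintf("TRUE-P%02d", i)
    va <- pair_motifs$hgcA_motif[i]; vb <- pair_motifs$hgcB_motif[i]
    add_contig(sprintf("CTG-P%02d", i),
               c(make_background(), make_hgcA(va), make_hgcB(vb),
                 make_background()),
               c("background", "hgcA", "hgcB", "background"),
               c(NA, lid, lid, NA),
               c(NA, "paired_cluster", "paired_cluster", NA),
               c(NA, va, vb, NA))
    gt_loci[[lid]] <- data.frame(locus_id = lid, category = "paired_cluster",
                                 hgcA_motif = va, hgcB_motif = vb,
                                 stringsAsFactors = FALSE)
  }
  # lone hgcA, truncated at a contig edge (alternating 5'/3')
  for (i in seq_len(n_lone_hgcA)) {
    lid <- sprintf("TRUE-A%02d", i)
    full <- make_hgcA("NVWCAAGK")
    if (i %% 2 == 0) {
      tr <- substr(full, 1, 100)          # 3'-truncated, motif at 61-68 kept
      seqs <- c(make_background(), tr)
      roles <- c("background", "hgcA")
      add_contig(sprintf("CTG-A%02d", i), seqs, roles,
                 c(NA, lid), c(NA, "hgcA_only"), c(NA, "NVWCAAGK"),
                 edge3 = TRUE)
    } else {
      tr <- substr(full, 40, nchar(full)) # 5'-truncated, motif at 22-29
      seqs <- c(tr, make_background())
      roles <- c("hgcA", "background")
      add_contig(sprintf("CTG-A%02d", i), seqs, roles,
                 c(lid, NA), c("hgcA_only", NA), c("NVWCAAGK", NA),
                 edge5 = TRUE)
    }
    gt_loci[[lid]] <- data.frame(locus_id = lid, category = "hgcA_only",
                                 hgcA_motif = "NVWCAAGK",
                                 hgcB_motif = NA_character_,
                                 stringsAsFactors = FALSE)
  }
  # lone hgcB, central on its contig
  for (i in seq_len(n_lone_hgcB)) {
    lid <- sprintf("TRUE-B%02d", i)
    add_contig(sprintf("CTG-B%02d", i),
               c(make_background(), make_hgcB("CMECGAC"), make_background()),
               c("background", "hgcB", "background"),
               c(NA, lid, NA), c(NA, "hgcB_only", NA),
               c(NA, "CMECGAC", NA))
    gt_loci[[lid]] <- data.frame(locus_id = lid, category = "hgcB_only",
                                 hgcA_motif = NA_character_,
                                 hgcB_motif = "CMECGAC",
                                 stringsAsFactors = FALSE)
  }
  # decoys: consensus-derived, motif broken at one position
  for (i in seq_len(n_decoys)) {
    if (i %% 2 == 1) {
      s <- .mutate_seq(.hgcA_consensus, 0.10, .hgcA_motif_span)
      s <- .set_motif(s, "NVWCATGK", .hgcA_motif_span[1])  # T breaks pos 6
    } else {
      s <- .mutate_seq(.hgcB_consensus, 0.10, .hgcB_motif_span)
      s <- .set_motif(s, "CLECGAC", .hgcB_motif_span[1])   # L breaks pos 2
    }
    s <- .strip_spurious_motifs(s, motifs)
    add_contig(sprintf("CTG-D%03d", i), s, "decoy", NA, NA, NA)
  }
  # random background genes on their own contigs
  for (i in seq_len(n_background)) {
    add_contig(sprintf("CTG-N%03d", i), make_background(), "background",
               NA, NA, NA)
  }

  genes <- do.call(rbind, genes)
  genes <- genes[order(genes$contig_id, genes$start_bp, genes$gene_id), ]
  genes$gene_index <- unlist(lapply(
    split(seq_len(nrow(genes)), genes$contig_id)[unique(genes$contig_id)],
    function(ii) seq_along(ii) - 1L), use.names = FALSE)
  genes <- genes[, c("gene_id", "contig_id", "start_bp", "end_bp", "strand",
                     "aa_sequence", "partial5", "partial3", "gene_index")]
  rownames(genes) <- NULL
  contigs <- do.call(rbind, contigs)
  contigs <- contigs[order(contigs$contig_id), ]
  rownames(contigs) <- NULL
  gt_genes <- do.call(rbind, gt)
  gt_genes <- gt_genes[match(genes$gene_id, gt_genes$gene_id), ]
  rownames(gt_genes) <- NULL

  structure(list(
    genes = genes, contigs = contigs,
    ground_truth = list(genes = gt_genes,
                        loci = do.call(rbind, unname(gt_loci)))),
    class = "hgc_catalog")
}

#' Configuration for a synthetic metagenome survey
#'
#' Defaults emulate the statistical structure of the brackish water-column
#' survey the package targets: 65 normoxic, 9 hypoxic and 7 anoxic
#' free-living samples; summed hgc abundance of 0.05, 1.0 and 2.1 (in
#' 1e-3 % of total annotated reads) per zone; 6 particle/free-living sample
#' pairs in anoxic water with a 5-fold particle enrichment;
#' negative-binomial counts (overdispersed, size 5) over 1e6 annotated
#' reads per sample.
#'
#' @param seed Mandatory RNG seed; every random choice derives from it.
#' @param n_normoxic,n_hypoxic,n_anoxic Free-living samples per zone.
#' @param zone_effect Named numeric: expected summed hgc abundance per zone
#'   in 1e-3 % units.
#' @param particle_enrichment Multiplier on hgc abundance for
#'   particle-fraction (3 um) samples (>= 1).
#' @param n_fraction_pairs Matched particle/free-living pairs (anoxic).
#' @param dispersion Negative-binomial size parameter.
#' @param total_reads Total annotated reads per sample.
#' @param n_paired,n_lone_hgcA,n_lone_hgcB,n_decoys,n_background,mutation_rate
#'   Passed to the catalog generator.
#' @return List of class `hgc_survey_config`.
#' @export
survey_config <- function(seed,
                          n_normoxic = 65, n_hypoxic = 9, n_anoxic = 7,
                          zone_effect = c(normoxic = 0.05, hypoxic = 1.0,
                                          anoxic = 2.1),
                          particle_enrichment = 5,
                          n_fraction_pairs = 6,
                          dispersion = 5,
                          total_reads = 1e6,
                          n_paired = 9, n_lone_hgcA = 13, n_lone_hgcB = 3,
                          n_decoys = 100, n_background = 100,
                          mutation_rate = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(particle_enrichment >= 1, mutation_rate >= 0, mutation_rate <= 0.3,
            all(zone_effect >= 0), total_reads >= 1)
  structure(as.list(environment()), class = "hgc_survey_config")
}

#' Simulate a synthetic metagenome survey
#'
#' Generates a gene catalog (true hgc loci with motif-preserving mutation
#' noise, decoys, background), sample metadata with zone-consistent oxygen
#' values and filtration descriptors, and a negative-binomial read-count
#' matrix in which the expected summed hgc abundance per sample equals the
#' configured zone effect, multiplied by the particle-enrichment factor for
#' 3 um samples. All randomness derives from `config$seed`; identical
#' configurations give identical surveys.
#'
#' @param config An `hgc_survey_config` from [survey_config()].
#' @return List with `catalog` (an `hgc_catalog` with ground truth),
#'   `counts` (`hgc_counts`), `metadata` (data.frame), and `ground_truth`
#'   (catalog ground truth plus `zones`, the intended zone per sample, and
#'   the echoed `config`).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "hgc_survey_config"))
  cf <- config
  exp_reads <- max(cf$zone_effect) * cf$particle_enrichment *
    cf$total_reads / 1e5
  if (exp_reads > 0.5 * cf$total_reads)
    stop("infeasible config: expected hgc reads approach total reads")
  .with_seed(cf$seed, {
    catalog <- .generate_catalog(cf$n_paired, cf$n_lone_hgcA, cf$n_lone_hgcB,
                                 default_pair_motif_plan(cf$n_paired),
                                 cf$n_decoys, cf$n_background,
                                 cf$mutation_rate)
    gt <- catalog$ground_truth
    hgc_genes <- gt$genes$gene_id[gt$genes$role %in% c("hgcA", "hgcB")]
    other <- setdiff(catalog$genes$gene_id, hgc_genes)

    mk_samples <- function(zone, n, filter_um, prefilter_um, station, depth) {
      if (n == 0) return(NULL)
      data.frame(
        station = station, depth_m = depth,
        zone = zone,
        o2_detected = zone != "anoxic",
        o2_mL_per_L = switch(zone,
          normoxic = round(runif(n, 2, 8), 2),
          hypoxic = round(runif(n, 0.05, 1.9), 2),
          anoxic = NA_real_),
        filter_um = filter_um, prefilter_um = prefilter_um,
        stringsAsFactors = FALSE)
    }
    stations <- sprintf("ST%02d", 1:13)
    pick <- function(n) sample(stations, n, replace = TRUE)
    md <- rbind(
      mk_samples("normoxic", cf$n_normoxic, 0.2, NA,
                 pick(cf$n_normoxic), round(runif(cf$n_normoxic, 2, 60))),
      mk_samples("hypoxic", cf$n_hypoxic, 0.2, NA,
                 pick(cf$n_hypoxic), round(runif(cf$n_hypoxic, 60, 120))),
      mk_samples("anoxic", cf$n_anoxic, 0.2, NA,
                 pick(cf$n_anoxic), round(runif(cf$n_anoxic, 120, 240))))
    if (cf$n_fraction_pairs > 0) {
      st <- pick(cf$n_fraction_pairs)
      dp <- round(runif(cf$n_fraction_pairs, 120, 240)) +
        seq_len(cf$n_fraction_pairs) / 10  # unique pairing depth
      p1 <- mk_samples("anoxic", cf$n_fraction_pairs, 3, NA, st, dp)
      p2 <- mk_samples("anoxic", cf$n_fraction_pairs, 0.2, 3, st, dp)
      md <- rbind(md, p1, p2)
    }
    md$sample_id <- sprintf("SMP%03d", seq_len(nrow(md)))
    md$date <- "2014-06-15"
    md$dataset <- "synthetic_survey"
    md <- md[, c("sample_id", "station", "date", "depth_m", "o2_detected",
                 "o2_mL_per_L", "filter_um", "prefilter_um", "dataset",
                 "zone")]

    n_hgc <- length(hgc_genes)
    counts <- matrix(0, nrow = nrow(catalog$genes), ncol = nrow(md),
                     dimnames = list(catalog$genes$gene_id, md$sample_id))
    for (s in seq_len(nrow(md))) {
      eff <- cf$zone_effect[[md$zone[s]]]
      enr <- if (md$filter_um[s] == 3) cf$particle_enrichment else 1
      mu_total <- eff * enr * cf$total_reads / 1e5
      counts[hgc_genes, s] <- rnbinom(n_hgc, mu = mu_total / n_hgc,
                                      size = cf$dispersion)
      counts[other, s] <- rpois(length(other), 2)
    }
    totals <- setNames(rep(cf$total_reads, nrow(md)), md$sample_id)
    zones <- setNames(md$zone, md$sample_id)
    md$zone <- NULL

    list(catalog = catalog,
         counts = count_matrix(counts, totals),
         metadata = md,
         ground_truth = c(catalog$ground_truth,
                          list(zones = zones, config = cf)))
  })
}

#' Write a simulated survey to the on-disk formats the loaders consume
#'
#' Emits protein FASTA + coordinate TSV, counts + totals TSVs, metadata TSV
#' and a ground-truth JSON.
#'
#' @param survey List from [simulate_survey()] (or an `hgc_catalog` plus
#'   counts/metadata assembled by hand).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    protein_fasta = file.path(dir, "catalog.faa"),
    coords = file.path(dir, "coords.tsv"),
    counts = file.path(dir, "counts.tsv"),
    totals = file.path(dir, "totals.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_gene_catalog(survey$catalog, paths["protein_fasta"], paths["coords"])
  write_count_data(survey$counts, paths["counts"], paths["totals"])
  write_sample_metadata(survey$metadata, paths["metadata"])
  gt <- survey$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(paths)
}
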
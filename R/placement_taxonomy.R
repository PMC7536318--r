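#' Load a labelled hgcAB reference set
#'
#' @param hgcA_fasta,hgcB_fasta Paths to amino-acid FASTAs of reference hgcA
#'   and hgcB sequences keyed by `ref_id` (either may be `NULL`; an entry
#'   needs at least one sequence). When both are present for an entry, a
#'   concatenated hgcA+hgcB sequence is derived for cluster-mode placement.
#' @param taxonomy_tsv Tab-delimited table with columns `ref_id`, `domain`,
#'   `phylum`, `class`, `order`, `family`, `genus` (deeper ranks may be
#'   empty).
#' @return data.frame with `ref_id`, the six rank columns, `hgcA_seq`,
#'   `hgcB_seq`, `concat_seq` (NA when unavailable). Sequences without a
#'   taxonomy row are dropped with a warning; duplicated `ref_id`s are an
#'   error.
#' @export
load_reference_set <- function(hgcA_fasta = NULL, hgcB_fasta = NULL,
                               taxonomy_tsv) {
  tax <- .read_tsv(taxonomy_tsv)
  need <- c("ref_id", "domain", "phylum", "class", "order", "family", "genus")
  miss <- setdiff(need, names(tax))
  if (length(miss)) stop("taxonomy lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tax$ref_id)) stop("duplicate ref_id in taxonomy")
  read1 <- function(p) {
    if (is.null(p)) return(character())
    ss <- Biostrings::readAAStringSet(p)
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids)) stop("duplicate ref_id in ", p)
    setNames(as.character(ss), ids)
  }
  a <- read1(hgcA_fasta)
  b <- read1(hgcB_fasta)
  ids <- union(names(a), names(b))
  if (!length(ids)) stop("no reference sequences supplied")
  unlab <- setdiff(ids, tax$ref_id)
  if (length(unlab)) {
    warning(length(unlab), " reference sequence(s) lack taxonomy, dropped: ",
            paste(unlab, collapse = ", "))
    ids <- setdiff(ids, unlab)
  }
  tax <- tax[match(ids, tax$ref_id), , drop = FALSE]
  out <- data.frame(tax[, need, drop = FALSE],
                    hgcA_seq = ifelse(ids %in% names(a), a[ids], NA),
                    hgcB_seq = ifelse(ids %in% names(b), b[ids], NA),
                    stringsAsFactors = FALSE)
  out$concat_seq <- ifelse(!is.na(out$hgcA_seq) & !is.na(out$hgcB_seq),
                           paste0(out$hgcA_seq, out$hgcB_seq), NA)
  rownames(out) <- NULL
  out
}

#' Bundled synthetic hgcAB reference set
#'
#' Loads the synthetic 20-entry labelled reference set shipped with the
#' package (consensus-derived sequences, not database records).
#' @return data.frame as from [load_reference_set()].
#' @export
default_reference_set <- function() {
  load_reference_set(
    hgcA_fasta = system.file("extdata", "synthetic_ref_hgcA.faa",
                             package = "hgcminer"),
    hgcB_fasta = system.file("extdata", "synthetic_ref_hgcB.faa",
                             package = "hgcminer"),
    taxonomy_tsv = system.file("extdata", "synthetic_ref_taxonomy.tsv",
                               package = "hgcminer"))
}

#' Pairwise Poisson-corrected amino-acid distances
#'
#' Every pair is globally aligned with affine gap penalties (BLOSUM62,
#' gap open 10, extend 1); `p` is the fraction of mismatches among aligned
#' non-gap columns and the evolutionary distance is the Poisson correction
#' `d = -ln(1 - p)`, capped at `d_max` once `p >= 1 - exp(-d_max)`.
#'
#' @param queries Named character vector of query sequences.
#' @param refs Named character vector of reference sequences.
#' @param ref_dm Optional precomputed reference-vs-reference distance matrix
#'   (as returned by a previous call, subset to the reference labels) to
#'   avoid re-aligning a fixed reference panel.
#' @param d_max Distance cap (default 5). A pair with zero aligned columns
#'   gets `d_max` with a warning.
#' @return Symmetric numeric matrix over `c(names(queries), names(refs))`
#'   with zero diagonal.
#' @export
compute_distances <- function(queries, refs = NULL, ref_dm = NULL,
                              d_max = 5) {
  seqs <- c(queries, refs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))) ||
      anyDuplicated(names(seqs)))
    stop("sequences must have unique non-empty names")
  if (any(!nzchar(seqs))) stop("empty sequence(s)")
  labs <- names(seqs)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  done <- matrix(FALSE, n, n)
  diag(done) <- TRUE
  if (!is.null(ref_dm)) {
    rl <- intersect(rownames(ref_dm), labs)
    D[rl, rl] <- ref_dm[rl, rl]
    done[cbind(match(rep(rl, length(rl)), labs),
               match(rep(rl, each = length(rl)), labs))] <- TRUE
  }
  need <- which(upper.tri(done) & !done, arr.ind = TRUE)
  if (nrow(need)) {
    d <- .pair_distances(seqs[need[, 1]], seqs[need[, 2]], d_max)
    D[need] <- d
    D[need[, c(2, 1), drop = FALSE]] <- d
  }
  D
}

# vectorised pairwise alignment + Poisson-corrected distance
.pair_distances <- function(s1, s2, d_max) {
  p1 <- Biostrings::AAStringSet(unname(s1))
  p2 <- Biostrings::AAStringSet(unname(s2))
  aln <- Biostrings::pairwiseAlignment(
    p1, p2, substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1, type = "global")
  ap <- as.character(Biostrings::alignedPattern(aln))
  as <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(ap), function(i) {
    a <- strsplit(ap[i], "")[[1]]
    b <- strsplit(as[i], "")[[1]]
    ok <- a != "-" & b != "-"
    ncol_aln <- sum(ok)
    if (ncol_aln == 0) {
      warning("pair with zero aligned columns; distance set to d_max")
      return(d_max)
    }
    p <- sum(a[ok] != b[ok]) / ncol_aln
    if (p >= 1 - exp(-d_max)) d_max else -log(1 - p)
  }, 0)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' ties broken lexicographically on the label pair (a joined node carries
#' its lexicographically smallest leaf label). Negative branch lengths are
#' clamped to 0 with the deficit moved to the sibling branch, preserving the
#' pair's path length. On an additive matrix NJ recovers the generating
#' topology and path lengths exactly (no clamping triggers).
#'
#' Optional bootstrap support: columns of a supplied reference alignment
#' are resampled with replacement, per-replicate Poisson-corrected
#' p-distances are computed from the resampled columns, trees are rebuilt
#' and per-edge split frequencies recorded.
#'
#' @param dm Symmetric distance matrix with dimnames (>= 3 labels).
#' @param bootstrap_replicates Number of replicates (default 0 = none).
#' @param seed RNG seed for bootstrap resampling.
#' @param alignment Named character vector of equal-length gapped sequences
#'   covering all labels; required when `bootstrap_replicates > 0`.
#' @return An [ape::phylo] tree (unrooted, basal trifurcation). With
#'   bootstrap, internal `node.label`s carry split support in `[0, 1]`.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- nj_tree(d)
#' @export
nj_tree <- function(dm, bootstrap_replicates = 0, seed = 1L,
                    alignment = NULL) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix needs dimnames")
  if (nrow(dm) < 3) stop("need at least 3 labels")
  tr <- ape::read.tree(text = .nj_newick(dm))
  if (bootstrap_replicates > 0) {
    if (is.null(alignment))
      stop("bootstrap requires `alignment` (equal-length gapped sequences)")
    if (!all(rownames(dm) %in% names(alignment)))
      stop("alignment must cover every distance-matrix label")
    aln <- do.call(rbind, strsplit(toupper(alignment[rownames(dm)]), ""))
    if (length(unique(nchar(alignment[rownames(dm)]))) != 1)
      stop("ragged alignment")
    boots <- .with_seed(seed, lapply(seq_len(bootstrap_replicates),
      function(r) {
        cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
        sub <- aln[, cols, drop = FALSE]
        d <- .alignment_pdist(sub)
        dimnames(d) <- dimnames(dm)
        ape::read.tree(text = .nj_newick(d))
      }))
    cl <- ape::prop.clades(tr, boots, rooted = FALSE)
    cl[is.na(cl)] <- 0
    tr$node.label <- formatC(cl / bootstrap_replicates, format = "f",
                             digits = 3)
  }
  tr
}

# Poisson-corrected p-distances from a character alignment matrix
.alignment_pdist <- function(m, d_max = 5) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    p <- if (any(ok)) sum(m[i, ok] != m[j, ok]) / sum(ok) else 1
    D[i, j] <- D[j, i] <- if (p >= 1 - exp(-d_max)) d_max else -log(1 - p)
  }
  D
}

# NJ agglomeration emitting a Newick string
.nj_newick <- function(d) {
  labs <- rownames(d)
  frag <- labs           # newick fragment per active node
  key <- labs            # lexicographic tie-break key (smallest leaf label)
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
    sel <- cand[order(pk)[1], ]
    i <- sel[[1]]; j <- sel[[2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }
  la <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  lb <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  lc <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  sprintf("(%s:%s,%s:%s,%s:%s);",
          frag[1], fmt(la), frag[2], fmt(lb), frag[3], fmt(lc))
}

#' Assign taxonomy to query leaves of a placement tree
#'
#' For each query: the nearest reference by patristic distance; the deepest
#' lineage supported by clade consensus — in the smallest query-containing
#' split of the unrooted tree holding at least two reference leaves, ranks
#' are kept from domain downward while at least `consensus_threshold` of the
#' clade's references agree, and the lineage is truncated at the first
#' disagreeing rank (`"unidentified"` when even the domain disagrees); and a
#' long-branch caution flag set when the query's terminal branch exceeds the
#' `long_branch_quantile` of reference terminal branch lengths, in which
#' case the assigned lineage is suffixed `"-like"` (fine-rank placement of
#' such queries is unreliable). A query at (numerically) zero patristic
#' distance from a reference simply inherits that reference's full lineage.
#'
#' @param tree [ape::phylo] containing all query and reference leaves.
#' @param dm Distance matrix used to build the tree (unused for patristic
#'   distances, retained for nearest-reference reporting consistency checks).
#' @param refs Reference data.frame from [load_reference_set()].
#' @param query_labels Character vector of query leaf labels.
#' @param consensus_threshold Rank-agreement fraction (default 0.75).
#' @param long_branch_quantile Quantile of reference terminal branch lengths
#'   above which a query is flagged (default 0.95).
#' @return data.frame with `locus_name`, `nearest_ref_id`,
#'   `nearest_distance`, `assigned_lineage`, `like_flag`,
#'   `consensus_fraction`.
#' @export
assign_taxonomy <- function(tree, dm, refs, query_labels,
                            consensus_threshold = 0.75,
                            long_branch_quantile = 0.95) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  absent <- setdiff(query_labels, tips)
  if (length(absent)) stop("query leaves absent from tree: ",
                           paste(absent, collapse = ", "))
  ref_ids <- intersect(tips, refs$ref_id)
  if (length(ref_ids) < 2) stop("tree must contain >= 2 reference leaves")
  pat <- stats::cophenetic(tree)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  lin <- refs[match(ref_ids, refs$ref_id), ranks, drop = FALSE]
  rownames(lin) <- ref_ids

  term_len <- setNames(
    tree$edge.length[match(seq_along(tips), tree$edge[, 2])], tips)
  lb_cut <- quantile(term_len[ref_ids], long_branch_quantile, names = FALSE)

  splits <- .query_side_splits(tree)

  rows <- lapply(query_labels, function(q) {
    pd <- pat[q, ref_ids]
    nearest <- ref_ids[order(pd, ref_ids)[1]]
    ndist <- unname(pd[nearest])
    like <- unname(term_len[q] > lb_cut)

    if (ndist <= 1e-9) {
      linq <- unlist(lin[nearest, ])
      keep <- linq[!is.na(linq) & nzchar(linq)]
      lineage <- paste(keep, collapse = ";")
      cfrac <- 1
    } else {
      side <- .smallest_query_clade(splits, tips, q, ref_ids)
      clade_refs <- intersect(side, ref_ids)
      kept <- character()
      cfrac <- 0
      for (rk in ranks) {
        v <- lin[clade_refs, rk]
        v <- v[!is.na(v) & nzchar(v)]
        if (!length(v)) break
        tb <- sort(table(v), decreasing = TRUE)
        frac <- tb[1] / length(clade_refs)
        if (frac >= consensus_threshold) {
          kept <- c(kept, names(tb)[1])
          cfrac <- unname(frac)
        } else break
      }
      lineage <- if (length(kept)) paste(kept, collapse = ";")
                 else "unidentified"
    }
    if (like && lineage != "unidentified")
      lineage <- paste0(lineage, "-like")
    data.frame(locus_name = q, nearest_ref_id = nearest,
               nearest_distance = ndist, assigned_lineage = lineage,
               like_flag = like, consensus_fraction = cfrac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# All edge-induced bipartitions of an unrooted tree, as tip-label sets of
# the child side of each edge.
.query_side_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder edge traversal resolves children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e)
    tree$tip.label[desc[[tree$edge[e, 2]]]])
}

# Smallest query-containing side over all edges (and the full tip set),
# holding >= 2 reference leaves; ties broken lexicographically.
.smallest_query_clade <- function(splits, tips, q, ref_ids) {
  cands <- lapply(splits, function(s)
    if (q %in% s) s else setdiff(tips, s))
  cands <- c(cands, list(tips))
  nref <- vapply(cands, function(s) length(intersect(s, ref_ids)), 0L)
  cands <- cands[nref >= 2]
  sizes <- vapply(cands, length, 0L)
  keykey <- vapply(cands, function(s) paste(sort(s), collapse = "\r"), "")
  cands[[order(sizes, keykey)[1]]]
}

#' Place called loci against the reference set and assign taxonomy
#'
#' Convenience wrapper mirroring the survey workflow: paired clusters are
#' placed with concatenated hgcA+hgcB sequences against references carrying
#' both genes; lone hgcA loci in hgcA mode; lone hgcB loci in hgcB mode.
#' Each mode aligns queries and references, builds an NJ tree and assigns
#' lineages.
#'
#' @param loci data.frame from [call_loci()].
#' @param catalog The `hgc_catalog` supplying query sequences.
#' @param refs Reference set from [load_reference_set()] (default the
#'   bundled synthetic set).
#' @param consensus_threshold,long_branch_quantile Passed to
#'   [assign_taxonomy()].
#' @details For a workflow built on an externally computed tree, read it
#'   with [ape::read.tree()] and call [assign_taxonomy()] directly.
#' @return data.frame of assignments across all modes, with a `mode` column;
#'   attribute `trees` holds the per-mode [ape::phylo] objects.
#' @export
place_loci <- function(loci, catalog, refs = default_reference_set(),
                       consensus_threshold = 0.75,
                       long_branch_quantile = 0.95) {
  g <- catalog$genes
  rownames(g) <- g$gene_id
  modes <- list(
    concat = list(sel = loci$category == "paired_cluster",
                  refseq = setNames(refs$concat_seq, refs$ref_id),
                  qseq = function(lc) paste0(g[lc$hgcA_gene_id, "aa_sequence"],
                                             g[lc$hgcB_gene_id, "aa_sequence"])),
    hgcA = list(sel = loci$category == "hgcA_only",
                refseq = setNames(refs$hgcA_seq, refs$ref_id),
                qseq = function(lc) g[lc$hgcA_gene_id, "aa_sequence"]),
    hgcB = list(sel = loci$category == "hgcB_only",
                refseq = setNames(refs$hgcB_seq, refs$ref_id),
                qseq = function(lc) g[lc$hgcB_gene_id, "aa_sequence"])
  )
  out <- list(); trees <- list()
  for (mn in names(modes)) {
    md <- modes[[mn]]
    sub <- loci[md$sel, , drop = FALSE]
    if (!nrow(sub)) next
    rs <- md$refseq[!is.na(md$refseq)]
    if (length(rs) < 2) {
      warning("mode ", mn, ": fewer than 2 reference sequences, skipped")
      next
    }
    qs <- setNames(md$qseq(sub), sub$locus_name)
    dm <- compute_distances(qs, rs)
    tr <- nj_tree(dm)
    asg <- assign_taxonomy(tr, dm, refs, names(qs),
                           consensus_threshold = consensus_threshold,
                           long_branch_quantile = long_branch_quantile)
    asg$mode <- mn
    out[[mn]] <- asg
    trees[[mn]] <- tr
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_name = character(), nearest_ref_id = character(),
               nearest_distance = numeric(), assigned_lineage = character(),
               like_flag = logical(), consensus_fraction = numeric(),
               mode = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "trees") <- trees
  res
}
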
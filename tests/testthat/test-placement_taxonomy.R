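data(BLOSUM62, package = "Biostrings", envir = environment())

test_that("bundled reference set loads with full lineages", {
  refs <- default_reference_set()
  expect_equal(nrow(refs), 20)
  expect_true(all(nzchar(refs$domain)))
  expect_true(all(!is.na(refs$concat_seq)))
  expect_equal(nchar(refs$concat_seq),
               nchar(refs$hgcA_seq) + nchar(refs$hgcB_seq))
})

test_that("reference loader drops unlabelled entries and rejects duplicates", {
  td <- withr::local_tempdir()
  writeLines(c(">r1", "MKLV", ">r2", "MNPQ"), file.path(td, "a.faa"))
  writeLines(c("ref_id\tdomain\tphylum\tclass\torder\tfamily\tgenus",
               "r1\tBacteria\tP\tC\tO\tF\tG"), file.path(td, "tax.tsv"))
  expect_warning(refs <- load_reference_set(file.path(td, "a.faa"),
                                            taxonomy_tsv = file.path(td, "tax.tsv")),
                 "r2")
  expect_equal(refs$ref_id, "r1")
  # hgcA-only entry is valid; concat absent
  expect_true(is.na(refs$hgcB_seq))
  expect_true(is.na(refs$concat_seq))
  writeLines(c("ref_id\tdomain\tphylum\tclass\torder\tfamily\tgenus",
               "r1\tBacteria\tP\tC\tO\tF\tG",
               "r1\tBacteria\tP\tC\tO\tF\tG"), file.path(td, "dup.tsv"))
  expect_error(load_reference_set(file.path(td, "a.faa"),
                                  taxonomy_tsv = file.path(td, "dup.tsv")),
               "duplicate")
})

test_that("Poisson-corrected distances follow the stated formula", {
  s <- random_protein(100)
  # identical sequences at distance zero
  d0 <- compute_distances(c(q = s), c(r = s))
  expect_equal(d0["q", "r"], 0)
  # one substitution among 100 aligned columns
  aa <- strsplit(s, "")[[1]]
  aa[50] <- setdiff(AA20, aa[50])[1]
  s2 <- paste(aa, collapse = "")
  d1 <- compute_distances(c(q = s), c(r = s2))
  expect_equal(d1["q", "r"], -log(0.99), tolerance = 1e-12)
  # symmetry and zero diagonal
  set.seed(5)
  seqs <- setNames(replicate(4, random_protein(80)), paste0("x", 1:4))
  D <- compute_distances(seqs)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  # unrelated random sequences saturate at the cap
  expect_true(all(D[upper.tri(D)] <= 5))
})

test_that("distances agree with an independent Gotoh alignment oracle", {
  set.seed(42)
  base <- random_protein(60)
  mk_variant <- function(nsub, indel = FALSE) {
    aa <- strsplit(base, "")[[1]]
    pos <- sample(60, nsub)
    for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1)
    if (indel) aa <- aa[-(25:27)]
    paste(aa, collapse = "")
  }
  seqs <- c(v1 = base, v2 = mk_variant(3), v3 = mk_variant(6),
            v4 = mk_variant(4, indel = TRUE), v5 = mk_variant(8))
  D <- compute_distances(seqs)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j],
                 oracle_pdist(seqs[[i]], seqs[[j]], BLOSUM62),
                 tolerance = 1e-9,
                 info = paste(names(seqs)[i], names(seqs)[j]))
  }
})

test_that("precomputed reference distances are reused verbatim", {
  set.seed(8)
  refs <- setNames(replicate(3, random_protein(50)), paste0("r", 1:3))
  q <- c(q1 = random_protein(50))
  ref_dm <- compute_distances(refs)
  D <- compute_distances(q, refs, ref_dm = ref_dm)
  expect_equal(D[names(refs), names(refs)], ref_dm)
  full <- compute_distances(q, refs)
  expect_equal(D, full)
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "3 labels")
})

test_that("NJ recovers additive five-taxon trees against the exhaustive-topology oracle", {
  set.seed(77)
  labs <- c("t1", "t2", "t3", "t4", "t5")
  for (rep in 1:10) {
    gen <- random_additive_dm(labs)
    tr <- nj_tree(gen$dm)
    # path-length matrix reproduced to near machine precision
    expect_equal(stats::cophenetic(tr)[labs, labs], gen$dm,
                 tolerance = 1e-9)
    # topology matches the unique zero-residual topology over all 15
    best <- oracle_nj5(gen$dm)
    expect_lt(best$resid, 1e-18)
    cherries <- list(sort(labs[best$tp$ch1]), sort(labs[best$tp$ch2]))
    splits <- ape::prop.part(ape::unroot(tr))
    split_sets <- lapply(splits, function(s) sort(attr(splits, "labels")[s]))
    for (ch in cherries) {
      found <- any(vapply(split_sets, function(s)
        identical(s, ch) || identical(s, sort(setdiff(labs, ch))), TRUE))
      expect_true(found, info = paste("cherry", paste(ch, collapse = "+"),
                                      "replicate", rep))
    }
  }
})

test_that("NJ agrees with the ape reference implementation on random matrices", {
  set.seed(31)
  labs <- paste0("x", 1:8)
  gen <- random_additive_dm(labs)
  ours <- nj_tree(gen$dm)
  theirs <- ape::nj(as.dist(gen$dm))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
               ignore_attr = TRUE)
  expect_equal(stats::cophenetic(ours)[labs, labs],
               stats::cophenetic(theirs)[labs, labs], tolerance = 1e-8)
})

test_that("NJ trees are invariant to label order", {
  set.seed(19)
  labs <- paste0("s", 1:6)
  gen <- random_additive_dm(labs)
  tr1 <- nj_tree(gen$dm)
  perm <- sample(labs)
  tr2 <- nj_tree(gen$dm[perm, perm])
  expect_equal(stats::cophenetic(tr1)[labs, labs],
               stats::cophenetic(tr2)[labs, labs], tolerance = 1e-9)
})

test_that("bootstrap support is reported per edge and deterministic", {
  set.seed(4)
  base <- random_protein(120)
  mut <- function(s, n) {
    aa <- strsplit(s, "")[[1]]
    for (p in sample(length(aa), n)) aa[p] <- sample(setdiff(AA20, aa[p]), 1)
    paste(aa, collapse = "")
  }
  c1 <- mut(base, 6)
  aln <- c(a1 = mut(c1, 2), a2 = mut(c1, 2),
           b1 = mut(base, 30), b2 = mut(base, 30), out = mut(base, 60))
  m <- do.call(rbind, strsplit(aln, ""))
  D <- matrix(0, 5, 5, dimnames = list(names(aln), names(aln)))
  for (i in 1:4) for (j in (i + 1):5) {
    p <- mean(m[i, ] != m[j, ])
    D[i, j] <- D[j, i] <- -log(1 - p)
  }
  tr <- nj_tree(D, bootstrap_replicates = 50, seed = 6, alignment = aln)
  expect_length(tr$node.label, tr$Nnode)
  supp <- suppressWarnings(as.numeric(tr$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 1))
  # the tight a1+a2 cherry should be strongly supported
  expect_true(any(supp >= 0.8))
  tr2 <- nj_tree(D, bootstrap_replicates = 50, seed = 6, alignment = aln)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(nj_tree(D, bootstrap_replicates = 10), "alignment")
})

test_that("zero-distance queries inherit the reference's full lineage", {
  refs <- default_reference_set()
  rs <- setNames(refs$concat_seq, refs$ref_id)
  q <- c(Q1 = unname(rs["SYNREF05"]))
  dm <- compute_distances(q, rs)
  tr <- nj_tree(dm)
  asg <- assign_taxonomy(tr, dm, refs, "Q1")
  expect_equal(asg$nearest_ref_id, "SYNREF05")
  expect_equal(asg$nearest_distance, 0)
  r5 <- refs[refs$ref_id == "SYNREF05", ]
  expect_equal(asg$assigned_lineage,
               paste(r5$domain, r5$phylum, r5$class, r5$order, r5$family,
                     r5$genus, sep = ";"))
  expect_false(asg$like_flag)
  expect_equal(asg$consensus_fraction, 1)
  expect_error(assign_taxonomy(tr, dm, refs, "ghost"), "ghost")
})

test_that("long-branch queries get the -like caution suffix", {
  refs <- default_reference_set()
  rs <- setNames(refs$concat_seq, refs$ref_id)
  set.seed(12)
  # heavily mutated query: related but far from everything
  aa <- strsplit(rs[["SYNREF01"]], "")[[1]]
  for (p in sample(length(aa), round(0.4 * length(aa))))
    aa[p] <- sample(setdiff(AA20, aa[p]), 1)
  q <- c(QLB = paste(aa, collapse = ""))
  dm <- compute_distances(q, rs)
  tr <- nj_tree(dm)
  asg <- assign_taxonomy(tr, dm, refs, "QLB")
  expect_true(asg$like_flag)
  expect_match(asg$assigned_lineage, "(-like|unidentified)")
})

test_that("conflicting clades truncate the lineage above the disagreeing rank", {
  # the query's smallest >= 2-reference clade holds one P1 and one P2
  # reference: the domain agrees, the phylum splits 50/50
  tax <- data.frame(
    ref_id = c("rA", "rB", "rC", "rD"),
    domain = "Bacteria",
    phylum = c("P1", "P1", "P2", "P2"),
    class = c("C1", "C1", "C2", "C2"), order = "O", family = "F",
    genus = "G", stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = paste0(
    "((rA:0.1,rC:0.1):0.2,(q:0.1,(rB:0.1,rD:0.1):0.1):0.1);"))
  dm <- stats::cophenetic(tr)
  asg <- assign_taxonomy(tr, dm, tax, "q", consensus_threshold = 0.75)
  expect_equal(asg$assigned_lineage, "Bacteria")
  expect_false(grepl("P1|P2", asg$assigned_lineage))
  # domain-level disagreement leaves the query unidentified
  tax2 <- tax
  tax2$domain <- c("Bacteria", "Bacteria", "Archaea", "Archaea")
  asg2 <- assign_taxonomy(tr, dm, tax2, "q", consensus_threshold = 0.75)
  expect_equal(asg2$assigned_lineage, "unidentified")
})

test_that("taxonomy assignment is invariant to reference input order", {
  refs <- default_reference_set()
  rs <- setNames(refs$concat_seq, refs$ref_id)
  set.seed(3)
  aa <- strsplit(rs[["SYNREF10"]], "")[[1]]
  for (p in sample(length(aa), 8)) aa[p] <- sample(setdiff(AA20, aa[p]), 1)
  q <- c(QX = paste(aa, collapse = ""))
  dm <- compute_distances(q, rs)
  tr <- nj_tree(dm)
  a1 <- assign_taxonomy(tr, dm, refs, "QX")
  refs2 <- refs[rev(seq_len(nrow(refs))), ]
  a2 <- assign_taxonomy(tr, dm, refs2, "QX")
  expect_equal(a1, a2)
})
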
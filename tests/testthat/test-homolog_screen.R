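test_that("motif patterns compile into position sets", {
  mA <- compile_motif("NVWCA(A/G/S)GK")
  expect_length(mA$positions, 8)
  expect_setequal(mA$positions[[6]], c("A", "G", "S"))
  expect_equal(mA$positions[[1]], "N")
  mB <- compile_motif("C(M/I)EC(G/S)(A/G)C")
  expect_length(mB$positions, 7)
  expect_equal(sum(vapply(mB$positions, length, 0L) > 1), 3)
  expect_equal(compile_motif("A")$positions, list("A"))
})

test_that("motif compilation rejects malformed patterns", {
  expect_error(compile_motif("NV()GK"), "empty")
  expect_error(compile_motif("NV(/)GK"), "empty")
  expect_error(compile_motif("NVB"), "non-residue")   # B is not an amino acid
  expect_error(compile_motif("NV1K"), "non-residue")
  expect_error(compile_motif(""), "non-empty")
})

test_that("motif scanning finds all and only matching windows", {
  mA <- hgc_motifs()$hgcA
  hit <- scan_motif(mA, "GGNVWCAAGKGG")
  expect_equal(hit$start, 3)
  expect_equal(hit$match, "NVWCAAGK")
  expect_equal(nrow(scan_motif(mA, "GGNVWCATGKGG")), 0)  # T not in {A,G,S}
  # X matches nothing
  expect_equal(nrow(scan_motif(mA, "GGNVWCAXGKGG")), 0)
  expect_equal(nrow(scan_motif(mA, "NVWCAAG")), 0)       # shorter than motif
  # overlapping / multiple occurrences, ascending starts
  two <- scan_motif(mA, "NVWCAAGKXXNVWCASGK")
  expect_equal(two$start, c(1, 11))
  expect_equal(two$match, c("NVWCAAGK", "NVWCASGK"))
})

test_that("motif scan agrees with the exhaustive window oracle on random sequences", {
  motifs <- hgc_motifs()
  set.seed(101)
  for (i in 1:200) {
    s <- random_protein(60)
    # salt some sequences with a planted motif to exercise the match branch
    if (i %% 5 == 0) s <- paste0(substr(s, 1, 20), "NVWCASGK",
                                 substr(s, 29, 60))
    for (m in motifs) {
      expect_equal(scan_motif(m, s)$start, oracle_scan(m$positions, s),
                   info = paste("seq", i, m$name))
    }
  }
})

test_that("profile columns follow the stated pseudocount smoothing", {
  # column observed A,A with alpha = 0.1 and uniform background 0.05:
  # score(A) = log2((2.1/4.0)/0.05)
  p <- build_profile(c(a = "AC", b = "AC"), target = "hgcA")
  expect_equal(unname(p$scores["A", 1]), log2((2.1 / 4.0) / 0.05))
  expect_equal(unname(p$scores["C", 2]), log2((2.1 / 4.0) / 0.05))
  # unobserved residue in the column
  expect_equal(unname(p$scores["W", 1]), log2((0.1 / 4.0) / 0.05))
  # exponentiated odds times background sum to 1 per column
  odds <- 2^p$scores * p$background
  expect_equal(unname(colSums(odds)), rep(1, p$length), tolerance = 1e-9)
})

test_that("majority-gap columns are dropped and ragged alignments rejected", {
  p <- build_profile(c(a = "A-C", b = "A-C", c = "AGC"), target = "hgcB")
  expect_equal(p$length, 2)                      # middle column 2/3 gaps
  p2 <- build_profile(c(a = "A--", b = "A--"), target = "hgcB")
  expect_equal(p2$length, 1)                     # all-gap columns dropped
  expect_error(build_profile(c(a = "AC", b = "ACD")), "ragged")
  expect_error(build_profile(c(a = "AC")), ">= 2")
})

test_that("identical-sequence profile scores its consensus maximally", {
  p <- build_profile(c(a = "ACDE", b = "ACDE"), target = "hgcA")
  for (j in 1:4) {
    col <- p$scores[, j]
    expect_gt(max(col), 0)
    expect_equal(names(which.max(col)), strsplit("ACDE", "")[[1]][j])
  }
})

test_that("internal screen separates spike-ins and decoys from background", {
  fx <- build_locus_catalog(n_paired = 2, n_lone_hgcA = 2, n_lone_hgcB = 1,
                            n_decoys = 10, n_background = 10)
  hits <- screen_candidates(fx, profiles = default_profiles())
  gt <- fx$ground_truth$genes
  true_ids <- gt$gene_id[gt$role %in% c("hgcA", "hgcB")]
  decoy_ids <- gt$gene_id[gt$role == "decoy"]
  bg_ids <- gt$gene_id[gt$role == "background"]
  expect_true(all(true_ids %in% hits$gene_id))     # every spike-in recovered
  expect_true(all(decoy_ids %in% hits$gene_id))    # profile-similar decoys hit
  expect_false(any(bg_ids %in% hits$gene_id))      # background rejected
  # screen is invariant to catalog row order
  shuf <- fx
  set.seed(1)
  shuf$genes <- shuf$genes[sample(nrow(shuf$genes)), ]
  hits2 <- screen_candidates(shuf, profiles = default_profiles())
  expect_equal(hits2, hits)
  # empty catalog
  empty <- fx
  empty$genes <- fx$genes[0, ]
  expect_equal(nrow(screen_candidates(empty, profiles = default_profiles())), 0)
})

test_that("domain-table screen applies the inclusive E-value boundary", {
  td <- withr::local_tempdir()
  tbl <- file.path(td, "dom.tbl")
  writeLines(c(
    "# hmmsearch per-domain output",
    "#         ----- full seq -----",
    "g1 - 150 hgcA_profile - 120 1e-3 55.0 0.1 1 1 1e-4 1e-3 50.0 0.1 1 120 1 120 1 120 0.9 -",
    "g2 - 150 hgcA_profile - 120 2e-3 40.0 0.1 1 1 2e-4 2e-3 38.0 0.1 1 120 1 120 1 120 0.9 -",
    "g3 - 90 hgcB_profile - 80 5e-8 70.0 0.0 1 1 5e-9 5e-8 69.0 0.0 1 80 1 80 1 80 0.95 -"),
    tbl)
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"), contig_id = "c1",
    start_bp = c(1, 500, 1000), end_bp = c(450, 950, 1270),
    strand = "+", aa_sequence = c("MK", "MN", "MQ"),
    partial5 = FALSE, partial3 = FALSE, gene_index = 0:2,
    stringsAsFactors = FALSE)
  cat <- structure(list(genes = genes), class = "hgc_catalog")
  hits <- screen_candidates(cat, domain_table = tbl)
  expect_setequal(hits$gene_id, c("g1", "g3"))   # 1e-3 kept, 2e-3 dropped
  expect_equal(hits$target[hits$gene_id == "g3"], "hgcB")
  expect_equal(hits$screen_source, rep("domain_table", 2))
})

test_that("domain-table parser flags malformed rows and unknown profiles", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.tbl")
  writeLines(c("g1 - 150 hgcA_profile - 120"), bad)  # too few fields
  expect_error(parse_domain_table(bad), "line 1")
  nonnum <- file.path(td, "nonnum.tbl")
  writeLines(c("g1 - 150 hgcA_profile - 120 xx 55.0"), nonnum)
  expect_error(parse_domain_table(nonnum), "non-numeric")
  unk <- file.path(td, "unk.tbl")
  writeLines(c("g1 - 150 someOtherGene - 120 1e-9 80.0"), unk)
  genes <- data.frame(
    gene_id = "g1", contig_id = "c1", start_bp = 1, end_bp = 450,
    strand = "+", aa_sequence = "MK", partial5 = FALSE, partial3 = FALSE,
    gene_index = 0L, stringsAsFactors = FALSE)
  cat <- structure(list(genes = genes), class = "hgc_catalog")
  expect_warning(hits <- screen_candidates(cat, domain_table = unk),
                 "unknown profile")
  expect_equal(nrow(hits), 0)
})

test_that("verification keeps exactly the motif-bearing candidates", {
  fx <- build_locus_catalog(n_paired = 2, n_lone_hgcA = 2, n_lone_hgcB = 1,
                            n_decoys = 10, n_background = 5)
  hits <- screen_candidates(fx, profiles = default_profiles())
  ver <- verify_candidates(hits, fx)
  gt <- fx$ground_truth$genes
  expect_setequal(ver$gene_id, gt$gene_id[gt$role %in% c("hgcA", "hgcB")])
  expect_true(all(ver$verified))
  expect_true(all(!is.na(ver$motif_match)))
  # target labels match ground-truth roles
  roles <- setNames(gt$role, gt$gene_id)
  expect_equal(unname(roles[ver$gene_id]), ver$target)
  # summary accounts for the dropped decoys
  s <- attr(ver, "verification_summary")
  expect_equal(s$n_input, nrow(hits))
  expect_equal(s$n_verified + s$n_dropped, s$n_input)
  # verification is idempotent and output is a subset of input
  ver2 <- verify_candidates(ver, fx)
  expect_equal(ver2[names(ver)], ver[names(ver)], ignore_attr = TRUE)
  expect_true(all(ver$gene_id %in% hits$gene_id))
  # hit referencing an unknown gene is a hard error
  bad <- hits[1, ]; bad$gene_id <- "nope"
  expect_error(verify_candidates(bad, fx), "nope")
})

test_that("leftmost motif occurrence is the one recorded", {
  genes <- data.frame(
    gene_id = "g1", contig_id = "c1", start_bp = 1, end_bp = 120,
    strand = "+",
    aa_sequence = "MMNVWCASGKMMMMNVWCAAGKMM",
    partial5 = FALSE, partial3 = FALSE, gene_index = 0L,
    stringsAsFactors = FALSE)
  cat <- structure(list(genes = genes), class = "hgc_catalog")
  hits <- data.frame(gene_id = "g1", target = "hgcA", screen_score = 10,
                     e_value = NA_real_, screen_source = "internal",
                     motif_match = NA_character_,
                     motif_position = NA_integer_, verified = FALSE,
                     stringsAsFactors = FALSE)
  ver <- verify_candidates(hits, cat)
  expect_equal(ver$motif_match, "NVWCASGK")
  expect_equal(ver$motif_position, 3L)
})
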
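#' Compile a degenerate amino-acid motif pattern
#'
#' Patterns use single residue letters with parenthesised slash-separated
#' alternatives, e.g. the hgcA cap-helix motif `"NVWCA(A/G/S)GK"` and the
#' hgcB ferredoxin motif `"C(M/I)EC(G/S)(A/G)C"`.
#'
#' @param pattern_text Pattern string.
#' @param name Optional motif name; defaults to the pattern text.
#' @return An `hgc_motif`: list with `name` and `positions`, a list of
#'   allowed-residue character vectors (one per motif position).
#' @examples
#' m <- compile_motif("NVWCA(A/G/S)GK")
#' length(m$positions)       # 8
#' m$positions[[6]]          # A G S
#' @export
compile_motif <- function(pattern_text, name = pattern_text) {
  if (!is.character(pattern_text) || length(pattern_text) != 1 ||
      !nzchar(pattern_text))
    stop("pattern_text must be a non-empty string")
  toks <- regmatches(pattern_text,
                     gregexpr("\\(([^)]*)\\)|.", pattern_text))[[1]]
  positions <- lapply(toks, function(tk) {
    if (startsWith(tk, "(")) {
      inner <- substr(tk, 2, nchar(tk) - 1)
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      alts <- alts[nzchar(alts)]
      if (!length(inner) || !nchar(inner) || !length(alts))
        stop("empty alternative group in motif pattern")
      alts
    } else tk
  })
  res <- unlist(positions)
  bad <- setdiff(res, .AA20)
  if (length(bad))
    stop("non-residue character(s) in motif pattern: ",
         paste(bad, collapse = ", "))
  structure(list(name = name, positions = positions), class = "hgc_motif")
}

#' Scan a sequence for all occurrences of a degenerate motif
#'
#' Slides the motif across the sequence and reports every window in which
#' each residue belongs to its allowed set. The ambiguity code `X` matches
#' nothing (conservative: an ambiguous residue never verifies a motif).
#'
#' @param motif An `hgc_motif` from [compile_motif()].
#' @param seq Amino-acid string.
#' @return data.frame with `start` (1-based, ascending) and `match` (the
#'   matched substring); zero rows when there is no match.
#' @examples
#' scan_motif(compile_motif("NVWCA(A/G/S)GK"), "GGNVWCAAGKGG")
#' @export
scan_motif <- function(motif, seq) {
  stopifnot(inherits(motif, "hgc_motif"))
  aa <- strsplit(toupper(seq), "")[[1]]
  L <- length(motif$positions)
  n <- length(aa)
  empty <- data.frame(start = integer(), match = character(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L))
    ok <- ok & (aa[k:(n - L + k)] %in% motif$positions[[k]])
  starts <- which(ok)
  if (!length(starts)) return(empty)
  data.frame(
    start = starts,
    match = vapply(starts,
                   function(s) paste(aa[s:(s + L - 1L)], collapse = ""), ""),
    stringsAsFactors = FALSE
  )
}

#' The canonical hgcA/hgcB verification motifs
#'
#' The cap-helix motif of the corrinoid protein HgcA, `NVWCA(A/G/S)GK`, and
#' the ferredoxin motif of HgcB, `C(M/I)EC(G/S)(A/G)C`.
#'
#' @return Named list of two `hgc_motif` objects (`hgcA`, `hgcB`).
#' @export
hgc_motifs <- function() {
  list(hgcA = compile_motif("NVWCA(A/G/S)GK", name = "hgcA"),
       hgcB = compile_motif("C(M/I)EC(G/S)(A/G)C", name = "hgcB"))
}

#' Build a position-specific log-odds profile from a reference alignment
#'
#' Columns with more than 50% gaps are dropped; residue frequencies are
#' Laplace-smoothed with pseudocount `alpha` per residue and converted to
#' log2 odds against the background, so a column observed as `A`,`A` in a
#' two-sequence alignment scores `log2(((2 + alpha) / (2 + 20 * alpha)) /
#' background["A"])` bits for `A`.
#'
#' @param reference_alignment Path to an aligned amino-acid FASTA, or an
#'   `AAStringSet` / named character vector of equal-length gapped sequences
#'   (gap characters `-` or `.`).
#' @param target `"hgcA"` or `"hgcB"` label carried on the profile.
#' @param alpha Pseudocount per residue (default 0.1).
#' @param background Named per-residue background frequencies; default
#'   uniform 1/20.
#' @return An `hgc_profile`: list with `target`, `scores` (20 x L bit-score
#'   matrix, rows = residues), `background`, `length`.
#' @export
build_profile <- function(reference_alignment, target = c("hgcA", "hgcB"),
                          alpha = 0.1,
                          background = setNames(rep(1 / 20, 20), .AA20)) {
  target <- match.arg(target)
  if (is.character(reference_alignment) && length(reference_alignment) == 1 &&
      file.exists(reference_alignment)) {
    reference_alignment <- Biostrings::readAAStringSet(reference_alignment)
  }
  seqs <- toupper(as.character(reference_alignment))
  if (length(seqs) < 2) stop("need >= 2 aligned sequences")
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: sequences differ in length")
  m <- do.call(rbind, strsplit(seqs, ""))
  m[m == "."] <- "-"
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= 0.5)
  if (!length(keep)) stop("all alignment columns are majority-gap")
  m <- m[, keep, drop = FALSE]
  background <- background[.AA20]
  scores <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = .AA20))
    p <- (as.numeric(cnt) + alpha) / (length(col) + 20 * alpha)
    log2(p / background)
  }, numeric(20))
  rownames(scores) <- .AA20
  structure(list(target = target, scores = scores,
                 background = background, length = ncol(scores)),
            class = "hgc_profile")
}

# Best ungapped window of `seq` against a profile. When the sequence is at
# least as long as the profile, full profile-length windows slide along the
# sequence; a shorter (e.g. edge-truncated) sequence instead slides along
# the profile and the score is normalised by the overlap length. Unknown
# residues (X) contribute 0 bits.
.best_window_score <- function(seq, profile) {
  aa <- strsplit(toupper(seq), "")[[1]]
  n <- length(aa)
  L <- profile$length
  idx <- match(aa, .AA20)
  S <- profile$scores[idx, , drop = FALSE]   # n x L, NA rows for X
  S[is.na(S)] <- 0
  if (n >= L) {
    nw <- n - L + 1L
    rows <- outer(seq_len(nw), 0:(L - 1L), `+`)
    v <- S[cbind(as.vector(rows), rep(seq_len(L), each = nw))]
    win <- rowSums(matrix(v, nw, L))
    o <- which.max(win)
    list(score = win[o], per_column = win[o] / L, start = o, overlap = L)
  } else {
    nw <- L - n + 1L
    cols <- outer(seq_len(nw), 0:(n - 1L), `+`)
    v <- S[cbind(rep(seq_len(n), each = nw), as.vector(cols))]
    win <- rowSums(matrix(v, nw, n))
    o <- which.max(win)
    list(score = win[o], per_column = win[o] / n, start = 1L, overlap = n)
  }
}

#' Parse a profile-HMM per-domain search table
#'
#' Reads the whitespace-delimited per-domain tabular output dialect of
#' `hmmsearch --domtblout` (`#`-prefixed comment lines ignored): column 1 is
#' the target (gene) name, column 4 the query profile name, column 7 the
#' full-sequence E-value, column 8 the full-sequence bit score.
#'
#' @param path Path to the table.
#' @return data.frame with `gene_id`, `profile`, `e_value`, `score`.
#' @export
parse_domain_table <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(keep))
    return(data.frame(gene_id = character(), profile = character(),
                      e_value = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 8)
      stop("malformed domain-table row at line ", i,
           ": expected >= 8 fields, got ", length(f))
    ev <- suppressWarnings(as.numeric(f[7]))
    sc <- suppressWarnings(as.numeric(f[8]))
    if (is.na(ev) || is.na(sc))
      stop("malformed domain-table row at line ", i,
           ": non-numeric E-value or score")
    data.frame(gene_id = f[1], profile = f[4], e_value = ev, score = sc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen a gene catalog for hgcA/hgcB candidates
#'
#' Two mutually exclusive screen sources: an internal position-specific
#' log-odds profile with ungapped sliding-window scoring, or an externally
#' computed profile-HMM per-domain table. The external path keeps rows with
#' full-sequence E-value at or below `e_threshold` (boundary inclusive); the
#' internal path keeps genes whose best window scores at least
#' `bits_per_column_threshold` bits per profile column. Candidates are
#' unverified: motif verification is a separate step
#' ([verify_candidates()]).
#'
#' @param catalog An `hgc_catalog`.
#' @param profiles Named list of `hgc_profile` objects (`hgcA`, `hgcB`) for
#'   the internal screen, or `NULL`.
#' @param domain_table Path to a per-domain table, or `NULL`. Profile names
#'   in the table must contain `hgcA` or `hgcB` (case-insensitive) to map to
#'   a target; unknown names are skipped with a warning.
#' @param e_threshold Full-sequence E-value cutoff, inclusive (default 1e-3).
#' @param bits_per_column_threshold Internal-screen cutoff in bits per
#'   profile column (default 0.5).
#' @return data.frame of candidate hits: `gene_id`, `target`, `screen_score`
#'   (bits), `e_value`, `screen_source`, `motif_match`, `motif_position`,
#'   `verified` (all `FALSE` here). A gene may hit both targets and then
#'   yields two rows.
#' @export
screen_candidates <- function(catalog, profiles = NULL, domain_table = NULL,
                              e_threshold = 1e-3,
                              bits_per_column_threshold = 0.5) {
  if (is.null(profiles) == is.null(domain_table))
    stop("provide exactly one of `profiles` (internal screen) or ",
         "`domain_table` (external table)")
  empty <- data.frame(gene_id = character(), target = character(),
                      screen_score = numeric(), e_value = numeric(),
                      screen_source = character(), motif_match = character(),
                      motif_position = integer(), verified = logical(),
                      stringsAsFactors = FALSE)
  g <- catalog$genes
  if (!nrow(g)) return(empty)

  if (!is.null(domain_table)) {
    tab <- parse_domain_table(domain_table)
    if (!nrow(tab)) return(empty)
    tgt <- ifelse(grepl("hgcA", tab$profile, ignore.case = TRUE), "hgcA",
           ifelse(grepl("hgcB", tab$profile, ignore.case = TRUE), "hgcB",
                  NA_character_))
    if (anyNA(tgt)) {
      warning("unknown profile name(s) skipped: ",
              paste(unique(tab$profile[is.na(tgt)]), collapse = ", "))
    }
    keep <- !is.na(tgt) & tab$e_value <= e_threshold
    tab <- tab[keep, , drop = FALSE]; tgt <- tgt[keep]
    if (!nrow(tab)) return(empty)
    hits <- data.frame(gene_id = tab$gene_id, target = tgt,
                       screen_score = tab$score, e_value = tab$e_value,
                       screen_source = "domain_table",
                       motif_match = NA_character_,
                       motif_position = NA_integer_, verified = FALSE,
                       stringsAsFactors = FALSE)
    # one row per (gene, target): keep the best E-value
    hits <- hits[order(hits$e_value), ]
    hits <- hits[!duplicated(hits[c("gene_id", "target")]), ]
  } else {
    stopifnot(all(vapply(profiles, inherits, TRUE, "hgc_profile")))
    res <- lapply(names(profiles), function(tg) {
      pr <- profiles[[tg]]
      sc <- lapply(g$aa_sequence, .best_window_score, profile = pr)
      per_col <- vapply(sc, `[[`, 0, "per_column")
      tot <- vapply(sc, `[[`, 0, "score")
      keep <- per_col >= bits_per_column_threshold
      data.frame(gene_id = g$gene_id[keep], target = tg,
                 screen_score = tot[keep], e_value = NA_real_,
                 screen_source = "internal",
                 motif_match = NA_character_,
                 motif_position = NA_integer_, verified = FALSE,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, res)
  }
  hits <- hits[order(hits$gene_id, hits$target), ]
  rownames(hits) <- NULL
  hits
}

#' Verify candidate hits against the degenerate motifs
#'
#' A candidate is verified iff [scan_motif()] finds at least one occurrence
#' of its target's motif in the gene sequence; the leftmost match is
#' recorded. Unverified hits are dropped from the returned set but tallied
#' in the `verification_summary` attribute. Verification is idempotent.
#'
#' @param hits data.frame from [screen_candidates()].
#' @param catalog The `hgc_catalog` the hits refer to.
#' @param motifs Named list of `hgc_motif`s per target; default
#'   [hgc_motifs()].
#' @return The verified subset of `hits` with `motif_match`,
#'   `motif_position` and `verified = TRUE` filled in, plus attribute
#'   `verification_summary` (list: `n_input`, `n_verified`, `n_dropped`,
#'   `dropped_by_target`).
#' @export
verify_candidates <- function(hits, catalog, motifs = hgc_motifs()) {
  g <- catalog$genes
  missing <- setdiff(hits$gene_id, g$gene_id)
  if (length(missing))
    stop("hit(s) reference genes absent from catalog: ",
         paste(missing, collapse = ", "))
  seqs <- setNames(g$aa_sequence, g$gene_id)
  out <- hits
  for (i in seq_len(nrow(out))) {
    m <- motifs[[out$target[i]]]
    if (is.null(m)) stop("no motif supplied for target ", out$target[i])
    sc <- scan_motif(m, seqs[[out$gene_id[i]]])
    if (nrow(sc)) {
      out$motif_match[i] <- sc$match[1]
      out$motif_position[i] <- sc$start[1]
      out$verified[i] <- TRUE
    } else {
      out$verified[i] <- FALSE
    }
  }
  verified <- out[out$verified, , drop = FALSE]
  rownames(verified) <- NULL
  dropped <- out[!out$verified, , drop = FALSE]
  attr(verified, "verification_summary") <- list(
    n_input = nrow(hits),
    n_verified = nrow(verified),
    n_dropped = nrow(dropped),
    dropped_by_target = table(factor(dropped$target,
                                     levels = names(motifs)))
  )
  verified
}

#' Default bundled reference profiles
#'
#' Builds the hgcA and hgcB position-specific log-odds profiles from the
#' synthetic reference alignments bundled with the package.
#'
#' @return Named list of two `hgc_profile`s.
#' @export
default_profiles <- function() {
  list(
    hgcA = build_profile(system.file("extdata",
             "synthetic_hgcA_ref_alignment.afa", package = "hgcminer"),
             target = "hgcA"),
    hgcB = build_profile(system.file("extdata",
             "synthetic_hgcB_ref_alignment.afa", package = "hgcminer"),
             target = "hgcB")
  )
}
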
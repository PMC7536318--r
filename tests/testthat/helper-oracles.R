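# Independent oracles used across the suite. These re-derive expected
# values by brute force / closed form and never call the code paths they
# check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# exhaustive all-window motif scan: set membership at every offset
oracle_scan <- function(position_sets, seq) {
  aa <- strsplit(seq, "")[[1]]
  L <- length(position_sets)
  n <- length(aa)
  if (n < L) return(integer())
  found <- integer()
  for (s in seq_len(n - L + 1)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(aa[s + k - 1] %in% position_sets[[k]])) { ok <- FALSE; break }
    }
    if (ok) found <- c(found, s)
  }
  found
}

# Gotoh global alignment with affine gaps (open+extend charged on the first
# gap residue), returning the optimal score and one optimal alignment via
# traceback. Independent dynamic-programming reimplementation.
oracle_align <- function(s1, s2, submat, gap_open = 10, gap_extend = 1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  # ptr*: the state (1=M, 2=Ix, 3=Iy) the cell was reached from
  ptrM <- matrix(0L, n + 1, m + 1); ptrX <- ptrM; ptrY <- ptrM
  for (i in 2:(n + 1)) {
    Ix[i, 1] <- -(gap_open + gap_extend * (i - 1))
    ptrX[i, 1] <- if (i == 2) 1L else 2L
  }
  for (j in 2:(m + 1)) {
    Iy[1, j] <- -(gap_open + gap_extend * (j - 1))
    ptrY[1, j] <- if (j == 2) 1L else 3L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      cand <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s; ptrM[i, j] <- k
      cand <- c(M[i - 1, j] - gap_open - gap_extend,
                Ix[i - 1, j] - gap_extend)
      k <- which.max(cand)
      Ix[i, j] <- cand[k]; ptrX[i, j] <- c(1L, 2L)[k]
      cand <- c(M[i, j - 1] - gap_open - gap_extend,
                Iy[i, j - 1] - gap_extend)
      k <- which.max(cand)
      Iy[i, j] <- cand[k]; ptrY[i, j] <- c(1L, 3L)[k]
    }
  }
  ends <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(ends)
  score <- ends[state]
  i <- n + 1; j <- m + 1
  A <- character(); B <- character()
  while (i > 1 || j > 1) {
    if (state == 1) {
      A <- c(a[i - 1], A); B <- c(b[j - 1], B)
      state <- ptrM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2) {
      A <- c(a[i - 1], A); B <- c("-", B)
      state <- ptrX[i, j]; i <- i - 1
    } else {
      A <- c("-", A); B <- c(b[j - 1], B)
      state <- ptrY[i, j]; j <- j - 1
    }
  }
  list(score = score, aligned1 = paste(A, collapse = ""),
       aligned2 = paste(B, collapse = ""))
}

oracle_pdist <- function(s1, s2, submat, d_max = 5) {
  al <- oracle_align(s1, s2, submat)
  a <- strsplit(al$aligned1, "")[[1]]; b <- strsplit(al$aligned2, "")[[1]]
  ok <- a != "-" & b != "-"
  p <- sum(a[ok] != b[ok]) / sum(ok)
  if (p >= 1 - exp(-d_max)) d_max else -log(1 - p)
}

# All 15 labelled unrooted 5-taxon topologies as cherry pairs {i,j},{k,l}
# (the fifth taxon attaches to the central node). Least-squares branch fit
# against the 10 pairwise distances identifies the generating topology by
# zero residual.
oracle_nj5 <- function(dm) {
  labs <- rownames(dm)
  stopifnot(length(labs) == 5)
  pairs <- combn(5, 2)
  topos <- list()
  for (c1 in seq_len(ncol(pairs))) {
    rest <- setdiff(1:5, pairs[, c1])
    sub <- combn(rest, 2)
    for (c2 in seq_len(ncol(sub))) {
      key <- paste(sort(c(paste(sort(pairs[, c1]), collapse = ","),
                          paste(sort(sub[, c2]), collapse = ","))),
                   collapse = "|")
      topos[[key]] <- list(ch1 = pairs[, c1], ch2 = sub[, c2],
                           lone = setdiff(1:5, c(pairs[, c1], sub[, c2])))
    }
  }
  # branch order: t1..t5 terminal, e1 = cherry1 node to center,
  # e2 = cherry2 node to center
  best <- NULL
  for (key in names(topos)) {
    tp <- topos[[key]]
    path <- function(i, j) {
      v <- numeric(7)
      v[i] <- 1; v[j] <- 1
      in1 <- function(x) x %in% tp$ch1
      in2 <- function(x) x %in% tp$ch2
      seg <- function(x) if (in1(x)) 1 else if (in2(x)) 2 else 0
      si <- seg(i); sj <- seg(j)
      if (si != sj || si == 0) {
        if (si == 1 || sj == 1) v[6] <- 1
        if (si == 2 || sj == 2) v[7] <- 1
      }
      v
    }
    X <- NULL; y <- NULL
    for (i in 1:4) for (j in (i + 1):5) {
      X <- rbind(X, path(i, j)); y <- c(y, dm[i, j])
    }
    fit <- qr.solve(crossprod(X), crossprod(X, y))
    resid <- sum((X %*% fit - y)^2)
    if (is.null(best) || resid < best$resid)
      best <- list(key = key, resid = resid, branches = fit, tp = tp,
                   labs = labs)
  }
  best
}

# expected number of genes detected when d of N reads are drawn without
# replacement: sum_i 1 - C(N - k_i, d) / C(N, d)
oracle_rarefaction_expectation <- function(k, N, d) {
  sum(1 - exp(lchoose(N - k, d) - lchoose(N, d)))
}

# random unrooted binary tree on n labelled taxa with uniform(0.1, 1)
# branch lengths; returns its additive distance matrix
random_additive_dm <- function(labs) {
  n <- length(labs)
  tr <- ape::rtree(n, rooted = FALSE, tip.label = labs,
                   br = function(k) runif(k, 0.1, 1))
  d <- stats::cophenetic(tr)[labs, labs]
  list(tree = tr, dm = d)
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")
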
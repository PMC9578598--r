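# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

randProt <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste0(sample(aa, n, replace = TRUE), collapse = "")
}

# --- global alignment oracle: enumerate every alignment of two short strings,
# score with match +1 / mismatch -1 and affine gap runs costing open + len*ext,
# and return the best score plus the identities achievable at that score.
enumerateAlignments <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  out <- list()
  rec <- function(i, j, cols) {
    if (i > length(A) && j > length(B)) {
      out[[length(out) + 1L]] <<- cols
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, c(cols, paste0(A[i], B[j])))
    if (i <= length(A)) rec(i + 1L, j, c(cols, paste0(A[i], "-")))
    if (j <= length(B)) rec(i, j + 1L, c(cols, paste0("-", B[j])))
  }
  rec(1L, 1L, character(0))
  out
}

scoreAlignment <- function(cols, open = 2, ext = 1) {
  x <- substr(cols, 1, 1); y <- substr(cols, 2, 2)
  sub <- sum(x != "-" & y != "-" & x == y) - sum(x != "-" & y != "-" & x != y)
  gapCost <- 0
  for (ch in list(x, y)) {
    r <- rle(ch == "-")
    runs <- r$lengths[r$values]
    gapCost <- gapCost + sum(open + runs * ext)
  }
  sub - gapCost
}

identityOfAlignment <- function(cols) {
  x <- substr(cols, 1, 1); y <- substr(cols, 2, 2)
  100 * sum(x == y & x != "-") / length(cols)
}

bruteGlobalAlign <- function(a, b) {
  alns <- enumerateAlignments(a, b)
  scores <- vapply(alns, scoreAlignment, numeric(1))
  best <- max(scores)
  ids <- vapply(alns[scores == best], identityOfAlignment, numeric(1))
  list(score = best, identities = sort(unique(round(ids, 6))))
}

# --- six-frame ORF oracle: walk every ATG on both strands codon by codon.
bruteOrfs <- function(seq, minLenNt) {
  res <- list()
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (start in seq_len(n)) {
      if (substr(s, start, start + 2) != "ATG") next
      pos <- start
      repeat {
        cod <- substr(s, pos, pos + 2)
        if (nchar(cod) < 3) break
        if (cod %in% c("TAA", "TAG", "TGA")) {
          len <- pos + 3 - start
          if (len >= minLenNt) {
            a <- start; b <- pos + 2
            if (strand == "-") { t <- n - b + 1; b <- n - a + 1; a <- t }
            res[[length(res) + 1L]] <-
              data.frame(start = a, end = b, frame = (start - 1) %% 3,
                         strand = strand)
          }
          break
        }
        pos <- pos + 3
      }
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), strand = character(0)))
  res <- do.call(rbind, res)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- exhaustive k-mer uniqueness oracle
bruteUniqueMask <- function(transcripts, k) {
  allK <- unlist(lapply(transcripts, function(s) {
    n <- nchar(s)
    if (n < k) character(0) else substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  counts <- table(allK)
  lapply(transcripts, function(s) {
    n <- nchar(s)
    mask <- logical(n)
    if (n >= k) for (i in 1:(n - k + 1)) {
      if (counts[[substring(s, i, i + k - 1)]] == 1L)
        mask[i:(i + k - 1)] <- TRUE
    }
    mask
  })
}

# --- all-offset Hamming placement oracle
brutePlacements <- function(reads, transcripts, maxMm) {
  rows <- list()
  for (r in names(reads)) {
    rd <- strsplit(reads[[r]], "")[[1]]
    L <- length(rd)
    for (t in names(transcripts)) {
      tx <- strsplit(transcripts[[t]], "")[[1]]
      if (length(tx) < L) next
      for (p in 1:(length(tx) - L + 1)) {
        mm <- sum(tx[p:(p + L - 1)] != rd)
        if (mm <= maxMm)
          rows[[length(rows) + 1L]] <-
            data.frame(read = r, transcript = t, pos = p, mismatches = mm)
      }
    }
  }
  if (!length(rows))
    return(data.frame(read = character(0), transcript = character(0),
                      pos = integer(0), mismatches = integer(0)))
  do.call(rbind, rows)
}

bruteClassify <- function(placements, allReads, maxMm) {
  vapply(allReads, function(r) {
    d <- placements[placements$read == r & placements$mismatches <= maxMm, ]
    if (nrow(d) == 0) return("unassigned")
    tied <- unique(d$transcript[d$mismatches == min(d$mismatches)])
    if (length(tied) == 1) "unique" else "shared"
  }, character(1))
}

# --- every-offset primer-site oracle (IUPAC in the primer)
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

brutePrimerSites <- function(template, primer, maxMm, require3 = TRUE) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  rows <- list()
  for (str in c("+", "-")) {
    q <- strsplit(if (str == "+") primer else rc, "")[[1]]
    tp <- strsplit(template, "")[[1]]
    p <- length(q)
    if (length(tp) < p) next
    for (o in 1:(length(tp) - p + 1)) {
      w <- tp[o:(o + p - 1)]
      match <- mapply(function(b, code) b %in% IUPAC_ORACLE[[code]], w, q)
      mm <- sum(!match)
      i3 <- if (str == "+") p else 1
      if (mm <= maxMm && (!require3 || match[i3]))
        rows[[length(rows) + 1L]] <-
          data.frame(start = o, end = o + p - 1, strand = str, mismatches = mm)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- per-window PWM scoring oracle
brutePwmScore <- function(seq, counts, background = rep(0.25, 4)) {
  L <- ncol(counts)
  n <- nchar(seq)
  N <- colSums(counts)
  w <- counts
  for (i in 1:4) for (j in 1:L)
    w[i, j] <- log2((counts[i, j] + 0.5 * background[i]) /
                      ((N[j] + 0.5) * background[i]))
  bases <- c("A", "C", "G", "T")
  scoreWin <- function(win) {
    s <- 0
    for (j in 1:L) {
      b <- match(substr(win, j, j), bases)
      s <- s + if (is.na(b)) min(w[, j]) else w[b, j]
    }
    s
  }
  fwd <- vapply(1:(n - L + 1),
                function(o) scoreWin(substr(seq, o, o + L - 1)), numeric(1))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- vapply(1:(n - L + 1),
                function(o) scoreWin(rc(substr(seq, o, o + L - 1))), numeric(1))
  list(fwd = fwd, rev = rev,
       lo = sum(apply(w, 2, min)), hi = sum(apply(w, 2, max)))
}

# substitute protein residues at a given per-position rate
mutateProtein <- function(protein, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- strsplit(protein, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(aa, x[i]), 1)
  paste0(x, collapse = "")
}
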
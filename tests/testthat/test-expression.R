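# Unique k-mer masks, read placement/classification, RPK/TPM, QC, SAM import.

test_that("identical paralogs have empty masks; a single difference unmasks k windows", {
  tx <- randSeq(200)
  m <- uniqueKmerMask(c(a = tx, b = tx), k = 15)
  expect_false(any(m$a)); expect_false(any(m$b))

  a <- paste0("AAAAT", strrep("ACGG", 10))
  b <- paste0("AAAAC", strrep("ACGG", 10))
  m2 <- uniqueKmerMask(c(a = a, b = b), k = 5)
  # unique positions are exactly those covered by 5-mers spanning position 5
  expect_equal(which(m2$a), 1:9)
  expect_equal(which(m2$b), 1:9)
})

test_that("uniqueKmerMask equals the exhaustive k-mer counting oracle", {
  set.seed(41)
  for (i in 1:25) {
    a <- randSeq(200)
    b <- mutateSequence(a, 0.03)
    txs <- c(x = a, y = b)
    expect_identical(uniqueKmerMask(txs, k = 7), bruteUniqueMask(txs, 7))
  }
  expect_warning(uniqueKmerMask(c(a = "ACGTACGTAC", b = randSeq(100)), k = 31),
                 "shorter than k")
})

test_that("placeReads classifies planted unique and shared reads", {
  set.seed(42)
  shared <- randSeq(150)
  txA <- paste0(randSeq(120), shared)
  txB <- paste0(randSeq(120), shared)
  txs <- c(A = txA, B = txB)
  uniqueRead <- substr(txA, 10, 89)    # inside A's private region
  sharedRead <- substr(shared, 20, 99) # inside the common suffix
  pl <- placeReads(c(u = uniqueRead, s = sharedRead), txs)
  cls <- pl$classes
  expect_equal(cls$class[cls$read == "u"], "unique")
  expect_equal(cls$transcript[cls$read == "u"], "A")
  expect_equal(cls$class[cls$read == "s"], "shared")
  junk <- paste0(strrep("A", 40), strrep("C", 40))
  expect_equal(placeReads(c(j = junk), txs)$classes$class, "unassigned")
})

test_that("placeReads agrees with the brute-force Hamming oracle", {
  set.seed(43)
  txs <- c(g1 = randSeq(400), g2 = NA)
  txs["g2"] <- mutateSequence(txs[["g1"]], 0.07)
  sim <- simulateReads(txs, c(0.5, 0.5), 300, 60, errRate = 0.01, seed = 44)
  got <- placeReads(sim$reads, txs, maxMm = 2)
  oracle <- brutePlacements(sim$reads, txs, maxMm = 2)
  ord <- function(d) {
    d <- d[order(d$read, d$transcript, d$pos), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(got$placements), ord(oracle))
  oc <- bruteClassify(oracle, names(sim$reads), 2)
  expect_equal(setNames(got$classes$class, got$classes$read), oc)
  # partition property: every read is in exactly one class
  expect_equal(sum(table(got$classes$class)), length(sim$reads))
})

test_that("quantifyParalogs computes RPK and TPM by their definitions", {
  # counts 10/10, lengths 1000/2000, no shared reads
  txs <- c(a = randSeq(1000), b = randSeq(2000))
  cls <- data.frame(
    read = sprintf("r%02d", 1:20),
    class = "unique",
    transcript = rep(c("a", "b"), each = 10),
    mismatches = 0L)
  placed <- list(placements = data.frame(read = cls$read,
                                         transcript = cls$transcript,
                                         pos = 1L, mismatches = 0L),
                 classes = cls)
  masks <- list(a = rep(TRUE, 1000), b = rep(TRUE, 2000))
  q <- quantifyParalogs(placed, txs, masks)
  expect_equal(q$tpm, c(666666.67, 333333.33), tolerance = 1e-6)
  expect_equal(sum(q$tpm), 1e6)

  # 8 unique reads over 4000 bp of discriminating sequence -> RPK 2.0
  txs8 <- c(a = randSeq(1000), b = randSeq(4000))
  cls8 <- cls[1:8, ]; cls8$transcript <- "b"
  placed8 <- list(placements = data.frame(read = cls8$read, transcript = "b",
                                          pos = 1L, mismatches = 0L),
                  classes = cls8)
  q8 <- quantifyParalogs(placed8, txs8, list(a = rep(FALSE, 1000),
                                             b = rep(TRUE, 4000)))
  expect_equal(q8$rpk[q8$gene == "b"], 2.0)
  # the full-length denominator stays available
  qf <- quantifyParalogs(placed8, txs8, list(a = rep(FALSE, 1000),
                                             b = rep(TRUE, 4000)),
                         rpkDenominator = "full")
  expect_equal(qf$rpk[qf$gene == "b"], 2.0)
})

test_that("TPM sums to 1e6 over random count/length configurations", {
  set.seed(45)
  for (i in 1:100) {
    nG <- sample(2:5, 1)
    lens <- sample(500:3000, nG)
    counts <- rpois(nG, 40)
    genes <- paste0("g", seq_len(nG))
    if (all(counts == 0)) counts[1] <- 1
    reads <- sprintf("r%03d", seq_len(sum(counts)))
    cls <- data.frame(read = reads, class = "unique",
                      transcript = rep(genes, counts), mismatches = 0L)
    placed <- list(placements = data.frame(read = reads,
                                           transcript = cls$transcript,
                                           pos = 1L, mismatches = 0L),
                   classes = cls)
    txs <- setNames(vapply(lens, randSeq, character(1)), genes)
    masks <- setNames(lapply(lens, function(l) rep(TRUE, l)), genes)
    q <- quantifyParalogs(placed, txs, masks)
    expect_equal(sum(q$tpm), 1e6, tolerance = 1e-6)
    expect_true(all(q$effectiveCount >= q$uniqueCount))
  }
})

test_that("shared reads are apportioned by unique-read rates; zero counts warn", {
  txs <- c(a = randSeq(1000), b = randSeq(1000))
  masks <- list(a = rep(TRUE, 1000), b = rep(TRUE, 1000))
  mkPlaced <- function(nA, nB, nShared) {
    ids <- sprintf("r%03d", seq_len(nA + nB + nShared))
    cls <- data.frame(read = ids,
                      class = c(rep("unique", nA + nB), rep("shared", nShared)),
                      transcript = c(rep("a", nA), rep("b", nB),
                                     rep(NA, nShared)),
                      mismatches = 0L)
    sharedIds <- ids[cls$class == "shared"]
    pl <- rbind(
      data.frame(read = ids[cls$class == "unique"],
                 transcript = cls$transcript[cls$class == "unique"],
                 pos = 1L, mismatches = 0L),
      data.frame(read = rep(sharedIds, each = 2),
                 transcript = rep(c("a", "b"), length(sharedIds)),
                 pos = 1L, mismatches = 0L))
    list(placements = pl, classes = cls)
  }
  q <- quantifyParalogs(mkPlaced(30, 10, 8), txs, masks)
  expect_equal(q$sharedCount, c(6, 2))           # 3:1 unique-rate split
  expect_equal(q$effectiveCount, c(36, 12))
  # monotonicity: more unique reads for a never lower its effective count
  q2 <- quantifyParalogs(mkPlaced(40, 10, 8), txs, masks)
  expect_gt(q2$effectiveCount[1], q$effectiveCount[1])
  # all-zero: zero TPM with a warning, no division by zero
  expect_warning(q0 <- quantifyParalogs(
    list(placements = data.frame(read = character(0), transcript = character(0),
                                 pos = integer(0), mismatches = integer(0)),
         classes = data.frame(read = character(0), class = character(0),
                              transcript = character(0),
                              mismatches = integer(0))),
    txs, masks), "zero")
  expect_equal(q0$tpm, c(0, 0))
})

test_that("qcFilterReads drops low-quality and N-rich reads at binomial rates", {
  reads <- setNames(replicate(50, randSeq(50)), sprintf("r%d", 1:50))
  quals <- setNames(rep(strrep("I", 50), 50), names(reads))  # Phred 40
  r <- qcFilterReads(reads, quals)
  expect_equal(r$report$nKept, 50)

  nRead <- paste0(strrep("N", 25), randSeq(25))
  r2 <- qcFilterReads(c(reads, bad = nRead), c(quals, bad = strrep("I", 50)))
  expect_equal(r2$report$nDroppedN, 1)
  expect_false("bad" %in% names(r2$reads))

  set.seed(46)
  n <- 1000
  lowIdx <- runif(n) < 0.05
  quals3 <- ifelse(lowIdx, strrep("#", 50), strrep("I", 50))  # Phred 2 vs 40
  reads3 <- setNames(replicate(n, randSeq(50)), sprintf("q%d", 1:n))
  names(quals3) <- names(reads3)
  r3 <- qcFilterReads(reads3, quals3)
  dropped <- r3$report$nIn - r3$report$nKept
  expect_lt(abs(dropped - sum(lowIdx)), 1e-9)  # exact here: deterministic rule
  expect_lt(abs(sum(lowIdx) / n - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("the SAM importer reproduces seed-and-verify placements", {
  set.seed(47)
  txs <- c(g1 = randSeq(300), g2 = NA)
  txs["g2"] <- mutateSequence(txs[["g1"]], 0.08)
  sim <- simulateReads(txs, c(0.5, 0.5), 40, 60, errRate = 0, seed = 48)
  native <- placeReads(sim$reads, txs, maxMm = 2)
  sam <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", names(txs), nchar(txs)))
  body <- with(native$placements, sprintf(
    "%s\t0\t%s\t%d\t60\t60M\t*\t0\t0\t%s\t*\tNM:i:%d",
    read, transcript, pos, unname(sim$reads[read]), mismatches))
  writeLines(c(hdr, body), sam)
  imported <- readSamPlacements(sam)
  ord <- function(d) {
    d <- d[order(d$read, d$transcript, d$pos), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(imported), ord(native$placements))
})
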
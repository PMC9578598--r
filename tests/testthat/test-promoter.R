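# Promoter extraction, cross-species alignment maps, JASPAR parsing,
# PWM scanning and conserved-site calling.

toyMotif <- function() {
  m <- rbind(A = c(12, 0, 0, 12, 0, 0),
             C = c(0, 12, 0, 0, 0, 12),
             G = c(0, 0, 12, 0, 0, 0),
             T = c(0, 0, 0, 0, 12, 0))
  list(id = "TOY1", name = "toy", matrix = m)  # consensus ACGATC
}

test_that("extractUpstream obeys strand and clips at contig edges", {
  set.seed(61)
  contig <- randSeq(8000)
  exP <- GenomicRanges::GRanges("c", IRanges::IRanges(5001, 5600), strand = "+")
  gm <- GeneModel("g", exP, roles = "N-term")
  expect_identical(extractUpstream(contig, gm, 1000),
                   substr(contig, 4001, 5000))
  exM <- GenomicRanges::GRanges("c", IRanges::IRanges(2001, 2600), strand = "-")
  gmM <- GeneModel("gm", exM, roles = "N-term")
  expect_identical(extractUpstream(contig, gmM, 1000),
                   revComp(substr(contig, 2601, 3600)))
  exEdge <- GenomicRanges::GRanges("c", IRanges::IRanges(401, 900), strand = "+")
  expect_warning(p <- extractUpstream(contig, GeneModel("e", exEdge), 1000),
                 "truncated")
  expect_equal(nchar(p), 400)
  exZero <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 300), strand = "+")
  expect_error(extractUpstream(contig, GeneModel("z", exZero), 1000), "edge")
})

test_that("alignToReference reports identity and a monotone column map", {
  set.seed(62)
  ref <- randSeq(800)
  proms <- c(human = ref, twin = ref,
             diverged = mutateSequence(ref, 0.10, seed = 63))
  al <- alignToReference(proms, "human")
  expect_equal(al$species$twin$identity, 100)
  expect_equal(al$species$twin$map, seq_len(800))
  expect_lt(abs(al$species$diverged$identity - 90), 2)
  m <- al$species$diverged$map
  expect_true(all(diff(m[!is.na(m)]) > 0))  # strictly increasing
  expect_error(alignToReference(proms, "mouse"), "reference")
})

test_that("readJasparMatrices parses headers and enforces the row contract", {
  jf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">MA0001.1 FOXTEST",
               "A  [ 10  0  0  5 ]",
               "C  [  0 10  0  5 ]",
               "G  [  0  0 10  0 ]",
               "T  [  0  0  0  0 ]",
               ">MA0002.1",
               "A [ 1 2 3 4 ]",
               "C [ 1 2 3 4 ]",
               "G [ 1 2 3 4 ]",
               "T [ 1 2 3 4 ]"), jf)
  ms <- readJasparMatrices(jf)
  expect_equal(names(ms), c("MA0001.1", "MA0002.1"))
  expect_equal(ms[[1]]$name, "FOXTEST")
  expect_equal(ms[[2]]$name, "")
  expect_equal(unname(colSums(ms[[1]]$matrix)), c(10, 10, 10, 10))
  writeLines(c(">MX bad", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), jf)
  expect_error(readJasparMatrices(jf), "ragged")
  writeLines(c(">MX bad", "A [ 1 2 3 4 ]", "G [ 1 2 3 4 ]", "C [ 1 2 3 4 ]",
               "T [ 1 2 3 4 ]"), jf)
  expect_error(readJasparMatrices(jf), "order")
})

test_that("pwmScan scores a planted consensus at relative score 1", {
  set.seed(64)
  motif <- toyMotif()
  bg <- randSeq(300)
  seq <- paste0(substr(bg, 1, 150), "ACGATC", substr(bg, 151, 300))
  hits <- pwmScan(seq, motif, minRelScore = 0.999)
  expect_true(any(hits$start == 151 & hits$strand == "+" &
                    abs(hits$relScore - 1) < 1e-9))
  # reverse-complement embedding: same footprint, minus strand
  seqRc <- paste0(substr(bg, 1, 150), revComp("ACGATC"), substr(bg, 151, 300))
  hitsRc <- pwmScan(seqRc, motif, minRelScore = 0.999)
  expect_true(any(hitsRc$start == 151 & hitsRc$strand == "-"))
  expect_equal(nrow(pwmScan("ACG", motif)), 0)  # shorter than motif
})

test_that("pwmScan equals brute-force window scoring everywhere", {
  set.seed(65)
  motif <- toyMotif()
  for (i in 1:5) {
    s <- randSeq(300)
    got <- pwmScan(s, motif, minRelScore = 0.001)
    oracle <- brutePwmScore(s, motif$matrix)
    fwd <- got[got$strand == "+", ]
    expect_equal(fwd$score, oracle$fwd[fwd$start], tolerance = 1e-9)
    rev <- got[got$strand == "-", ]
    expect_equal(rev$score, oracle$rev[rev$start], tolerance = 1e-9)
    # relative-score normalization against the achievable range
    expect_equal(fwd$relScore,
                 (oracle$fwd[fwd$start] - oracle$lo) / (oracle$hi - oracle$lo),
                 tolerance = 1e-9)
  }
})

test_that("embedding k consensus copies yields k top-scoring planted hits", {
  set.seed(66)
  motif <- toyMotif()
  bgParts <- replicate(4, randSeq(120))
  seq <- paste0(bgParts[1], "ACGATC", bgParts[2], "ACGATC", bgParts[3],
                "ACGATC", bgParts[4])
  planted <- c(121, 247, 373)
  hits <- pwmScan(seq, motif, minRelScore = 0.999)
  expect_gte(nrow(hits), 3)
  expect_true(all(planted %in% hits$start))
})

test_that("conservedSites projects footprints and applies the overlap rule", {
  set.seed(67)
  motif <- toyMotif()
  ref <- paste0(randSeq(200), "ACGATC", randSeq(194))
  proms <- c(human = ref, chimp = ref, rhesus = ref, baboon = ref)
  al <- alignToReference(proms, "human")
  hits <- lapply(proms, pwmScan, pfm = motif, minRelScore = 0.95)
  cons <- conservedSites(hits, al)
  expect_true(nrow(cons) >= 1 && all(hits$human$start %in% cons$start))

  # scrambling the motif in one species breaks conservation
  scr <- proms
  substr(scr["baboon"], 201, 206) <- "TTTTTT"
  hits2 <- lapply(scr, pwmScan, pfm = motif, minRelScore = 0.95)
  al2 <- alignToReference(scr, "human")
  cons2 <- conservedSites(hits2, al2)
  expect_false(any(cons2$start == 201 & cons2$strand == "+"))

  # monotonicity: dropping a species never shrinks the conserved set
  fewer <- conservedSites(hits2[c("human", "chimp", "rhesus")], al2)
  expect_true(all(paste(cons2$start, cons2$strand) %in%
                    paste(fewer$start, fewer$strand)))
  expect_error(conservedSites(hits, alignToReference(proms[1:2], "human")),
               "missing")
})

test_that("a shifted but half-overlapping hit still counts as conserved", {
  motif <- toyMotif()
  refHit <- data.frame(motif = "TOY1", start = 101, end = 106, strand = "+",
                       score = 1, relScore = 1)
  spHit <- data.frame(motif = "TOY1", start = 104, end = 109, strand = "+",
                      score = 1, relScore = 1)
  al <- list(reference = "human",
             species = list(human = list(identity = 100, map = 1:300),
                            chimp = list(identity = 100, map = 1:300)))
  cons <- conservedSites(list(human = refHit, chimp = spHit), al)
  expect_equal(nrow(cons), 1)  # 3/6 overlap meets the 50% rule
  spFar <- transform(spHit, start = 105, end = 110)
  cons2 <- conservedSites(list(human = refHit, chimp = spFar), al)
  expect_equal(nrow(cons2), 0)  # 2/6 overlap fails
})

test_that("signal tracks average over a region by overlap width", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr7\t0\t100\tpk1\t10", "chr7\t100\t200\tpk2\t30"), bed)
  tr <- readSignalTrack(bed)
  region <- GenomicRanges::GRanges("chr7", IRanges::IRanges(51, 150))
  expect_equal(meanSignalOver(tr, region), (50 * 10 + 50 * 30) / 100)
  outside <- GenomicRanges::GRanges("chr7", IRanges::IRanges(1000, 1100))
  expect_true(is.na(meanSignalOver(tr, outside)))
})
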
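# Marker anchoring, alignment identity, ORF/PTS/SEA/TM-PDZ feature
# detection, criteria-based gene calling and cluster metrics.

test_that("regionIdentity matches hand alignments and is symmetric", {
  expect_equal(regionIdentity("ACGTACGT", "ACGTACGT")$identity, 100)
  expect_equal(regionIdentity("ACGT", "ACGA")$identity, 75)
  expect_error(regionIdentity("", "ACGT"))
  set.seed(21)
  for (i in 1:25) {
    a <- randSeq(sample(10:40, 1)); b <- randSeq(sample(10:40, 1))
    expect_equal(regionIdentity(a, b)$identity, regionIdentity(b, a)$identity,
                 tolerance = 1e-9)
  }
})

test_that("regionIdentity agrees with exhaustive alignment enumeration", {
  set.seed(22)
  for (i in 1:40) {
    a <- randSeq(5); b <- randSeq(5)
    got <- regionIdentity(a, b, mode = "global")
    oracle <- bruteGlobalAlign(a, b)
    expect_equal(got$score, oracle$score)
    expect_true(any(abs(got$identity - oracle$identities) < 1e-6))
  }
})

test_that("locateMarker places verbatim and mutated markers, rejects absent ones", {
  set.seed(23)
  marker <- randSeq(400)
  contig <- paste0(randSeq(500), marker, randSeq(700))
  hit <- locateMarker(contig, marker)
  expect_equal(hit$start, 501)
  expect_equal(hit$end, 900)
  expect_equal(hit$identity, 100)

  mutated <- paste0(randSeq(500), mutateSequence(marker, 0.05, seed = 2),
                    randSeq(700))
  hit2 <- locateMarker(mutated, marker)
  expect_lte(abs(hit2$start - 501), 2)
  expect_gte(hit2$identity, 90)
  expect_error(locateMarker(randSeq(2000), marker), "marker not found")
})

test_that("findOrfs equals the brute-force six-frame scan", {
  orf <- "ATGAAAATGGGGTTTCCCAAACCCGGGTTTACCTAG"  # nested in-frame ATG at +7
  r <- findOrfs(paste0(strrep("C", 22), orf, strrep("C", 8)), minLenNt = 30)
  expect_equal(nrow(r), 2)  # outer ORF and the nested in-frame ATG
  expect_true(all(r$strand == "+"))
  expect_equal(r$start, c(23, 29))
  expect_equal(r$end, c(58, 58))
  expect_equal(nrow(findOrfs(strrep("C", 60), minLenNt = 30)), 0)  # no ATG
  set.seed(24)
  for (i in 1:50) {
    s <- randSeq(300)
    expect_equal(findOrfs(s, minLenNt = 30), bruteOrfs(s, 30))
  }
})

test_that("ptsScan measures windowed P/T/S density and merges runs", {
  # shorter than the window: empty result, not an error
  expect_equal(nrow(ptsScan("TTSPPA", window = 10)), 0)
  expect_equal(nrow(ptsScan(strrep("G", 300))), 0)
  arr <- strrep("ITTTETTSHSTPSFTSS", 50)
  seg <- ptsScan(arr)
  expect_equal(nrow(seg), 1)
  expect_gt((seg$end - seg$start + 1) / nchar(arr), 0.95)
  expect_equal(seg$fraction, 13 / 17, tolerance = 0.02)
})

test_that("ptsScan hand example: window 6 over TTSPPA gives fraction 5/6", {
  # window size below 10 violates the contract; check the contract instead,
  # then the same arithmetic through a 10-residue window
  expect_error(ptsScan("TTSPPA", window = 6), "window")
  seg <- ptsScan(strrep("TTSPPA", 5), window = 10, minFrac = 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 1)
  expect_equal(seg$end, 30)
  expect_equal(seg$fraction, 25 / 30)
})

test_that("detectSea finds embedded references at the right identity", {
  set.seed(25)
  ref <- randProt(120)
  prot <- paste0(randProt(150), ref, randProt(150))
  hit <- detectSea(prot, ref)
  expect_equal(hit$identity, 100)
  expect_equal(hit$start, 151)

  diverged <- paste0(randProt(150), mutateProtein(ref, 0.4), randProt(150))
  hit2 <- detectSea(diverged, ref, minIdentity = 30)
  expect_false(is.null(hit2))
  expect_lt(abs(hit2$identity - 60), 8)

  expect_null(detectSea(randProt(500), ref))
  expect_error(detectSea(prot, character(0)), "empty")
})

test_that("detectCtermFeatures finds the hydrophobic window and the PDZ motif", {
  set.seed(26)
  hydrophilic <- strrep("DEKR", 20)
  prot <- paste0(hydrophilic, strrep("L", 19), hydrophilic, "ETSL")
  feat <- detectCtermFeatures(prot)
  expect_equal(unname(feat$tm), c(81, 99))
  expect_true(feat$pdz)
  expect_false(detectCtermFeatures(paste0(prot, "G"))$pdz)   # ...TSG: Phi violated
  expect_true(detectCtermFeatures(paste0(hydrophilic, "XTSL"))$pdz)  # T at -2, L at 0
  expect_error(detectCtermFeatures("SHORT"), ">= 25")
  # PDZ decision equals the regular-expression oracle
  for (i in 1:1000) {
    p <- randProt(30)
    expect_equal(detectCtermFeatures(p)$pdz,
                 grepl("[ST].[LIVFM]$", p))
  }
})

test_that("callMucinGenes recovers planted genes and their PTS exons", {
  spec <- clusterSpec(nGenes = 2, repeatCounts = c(40, 90),
                      intergenicLengths = 2469, ntermLength = 200,
                      ctermLength = 400, markerLengths = c(600, 600),
                      flankLengths = c(200, 200), seed = 101)
  res <- buildClusterGenome(spec)
  tr <- res$truth
  a5 <- locateMarker(res$contig, tr$markerSeqs["marker5"])
  a3 <- locateMarker(res$contig, tr$markerSeqs["marker3"])
  cand <- callMucinGenes(res$contig, list(marker5 = a5, marker3 = a3))
  expect_length(cand, 2)
  for (i in 1:2) {
    got <- modelExons(cand[[i]]$model)
    planted <- modelExons(tr$models[[i]])
    expect_true(all(abs(start(got) - start(planted)) <= 5))
    expect_true(all(abs(end(got) - end(planted)) <= 5))
    expect_false(is.null(cand[[i]]$sea))
    expect_true(cand[[i]]$pdz)
  }
  expect_error(callMucinGenes(res$contig, list(marker5 = a5)), "anchors")
})

test_that("near-duplicate flanking sequence collapses adjacent candidates", {
  spec <- clusterSpec(nGenes = 2, repeatCounts = c(40, 90),
                      paralogIdentity = 0.99, intergenicLengths = 2469,
                      ntermLength = 200, ctermLength = 400,
                      markerLengths = c(600, 600), flankLengths = c(200, 200),
                      seed = 102)
  res <- buildClusterGenome(spec)
  a5 <- locateMarker(res$contig, res$truth$markerSeqs["marker5"])
  a3 <- locateMarker(res$contig, res$truth$markerSeqs["marker3"])
  cand <- callMucinGenes(res$contig, list(marker5 = a5, marker3 = a3))
  expect_length(cand, 1)
  expect_length(cand[[1]]$mergedFrom, 1)
})

test_that("a marker-only contig yields no candidates", {
  set.seed(27)
  m5 <- randSeq(400); m3 <- randSeq(400)
  contig <- paste0(m5, randSeq(3000), m3)
  a5 <- locateMarker(contig, m5)
  a3 <- locateMarker(contig, m3)
  expect_length(callMucinGenes(contig, list(marker5 = a5, marker3 = a3)), 0)
})

test_that("clusterMetrics reproduces planted span and intergenic distances", {
  mk <- function(id, s, e) {
    GeneModel(id, GenomicRanges::GRanges("c", IRanges::IRanges(s, e),
                                         strand = "+"), roles = "other")
  }
  # genes spanning [1001, 154000] give the 153.0 kbp cluster span
  m <- clusterMetrics(list(mk("g1", 1001, 10000), mk("g2", 12470, 154000)))
  expect_equal(m$spanKbp, 153.0)
  expect_equal(unname(m$intergenicBp), 2469)
  one <- clusterMetrics(list(mk("solo", 11, 1000)))
  expect_equal(one$spanKbp, 1.0)
  expect_length(one$intergenicBp, 0)
  expect_error(clusterMetrics(list()), "empty")
})

test_that("conservationVsTime regresses identity decay on divergence time", {
  set.seed(28)
  anc <- randSeq(2000)
  same <- data.frame(speciesPair = c("p1", "p2"), region = "N-term",
                     seqA = anc, seqB = anc)
  r <- conservationVsTime(same, c(p1 = 10, p2 = 30))
  expect_equal(r$points$identity, c(100, 100))
  expect_equal(unname(r$slopes["N-term"]), 0)

  times <- c(a = 5, b = 15, c = 30)
  decay <- data.frame(speciesPair = names(times), region = "C-term",
                      seqA = anc,
                      seqB = vapply(times / 100, function(rt)
                        mutateSequence(anc, rt, seed = round(rt * 1000)),
                        character(1)))
  r2 <- conservationVsTime(decay, times)
  expect_lt(unname(r2$slopes["C-term"]), 0)
  expect_equal(r2$points$time, sort(times), ignore_attr = TRUE)

  single <- conservationVsTime(same[1, ], c(p1 = 10))
  expect_true(is.na(single$slopes))
  expect_error(conservationVsTime(same, c(p1 = 10)), "missing divergence")
})
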
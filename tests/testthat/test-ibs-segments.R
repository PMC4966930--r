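# IBS states, shared-segment detection and ics(Th).

test_that("IBS states implement maximum allele matching (all 9 genotype combinations)", {
  map <- GeneticMap("1", sprintf("s%d", 1:9), 0:8)
  a <- as.integer(rep(0:2, each = 3))
  b <- as.integer(rep(0:2, times = 3))
  g <- tinyGenotypes(map, x = a, y = b)
  tr <- ibsStates(g, "x", "y")
  oracle <- mapply(function(da, db)
    matchingIbsOracle(dosageToPair(da), dosageToPair(db)), a, b)
  expect_equal(tr@state, as.integer(oracle))
  # spot checks of the definition cases
  byCombo <- setNames(tr@state, paste(a, b))
  expect_equal(unname(byCombo[c("0 0", "0 1", "0 2", "1 1")]),
               c(2L, 1L, 0L, 2L))
})

test_that("a sample against itself is IBS 2 everywhere and ICS equals the map length", {
  g <- panelGenotypes(smallPanel(), panelDonors(smallPanel())[1:2])
  s <- sampleIds(g)[1L]
  tr <- ibsStates(g, s, s)
  expect_true(all(tr@state == 2L))
  iv <- icsPair(g, s, s, th = 5)
  expect_equal(icsValue(iv), totalMapLength(smallMap()))
})

test_that("missing loci are dropped from the track and samples must share a map", {
  map <- tinyMap(3L)
  g <- tinyGenotypes(map, a = as.integer(c(0, NA, 2, 1, 1, 0)),
                     b = as.integer(c(0, 1, NA, 1, 2, 0)))
  tr <- ibsStates(g, "a", "b")
  expect_equal(tr@locusIndex, c(1L, 4L, 5L, 6L))
  other <- tinyGenotypes(tinyMap(3L, spacing = 2), c2 = rep(1L, 6L))
  expect_error(ibsStates(g, "a", "c2", y = other), "different maps")
  expect_error(ibsStates(g, "zz", "b"), "unknown sample")
})

test_that("the worked ten-SNP example yields segments 1-4 and 8-10, excluding isolated sharing", {
  states <- as.integer(strsplit("2212010221", "")[[1]])
  # dosages realizing those IBS states on ten equally spaced SNPs
  a <- integer(10); b <- integer(10)
  a[states == 2L] <- 1L; b[states == 2L] <- 1L
  a[states == 1L] <- 0L; b[states == 1L] <- 1L
  a[states == 0L] <- 0L; b[states == 0L] <- 2L
  map <- GeneticMap("1", sprintf("s%d", 1:10), as.numeric(0:9))
  g <- tinyGenotypes(map, a = a, b = b)
  tr <- ibsStates(g, "a", "b")
  expect_equal(tr@state, states)
  segs <- detectSharedSegments(tr, map)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$firstIndex, c(1L, 8L))
  expect_equal(segs$lastIndex, c(4L, 10L))
  expect_equal(segs$nSnps, c(4L, 3L))
  expect_equal(segs$lengthCM, c(3, 2))
  # the isolated sixth SNP (state 1) is not a segment
  expect_false(any(segs$firstIndex == 6L))
})

test_that("segment detection matches the brute-force enumerator on random instances", {
  map <- tinyMap(25L)
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(2:50, 1L)
    idx <- sort(sample(nLoci(map), n))
    states <- as.integer(sample(0:2, n, replace = TRUE,
                                prob = c(0.3, 0.4, 0.3)))
    tr <- new("IbsTrack", state = states, locusIndex = idx,
              chrom = map@chrom[idx], samples = c("a", "b"))
    got <- detectSharedSegments(tr, map)
    want <- bruteForceSegments(states, idx, map)
    expect_equal(got[c("chrom", "firstIndex", "lastIndex", "nSnps",
                       "lengthCM")],
                 want, ignore_attr = TRUE)
  }
})

test_that("segments never span chromosomes and empty/all-zero tracks give none", {
  map <- tinyMap(4L)  # chrom breaks between index 4 and 5
  tr <- new("IbsTrack", state = rep(2L, 8L), locusIndex = 1:8,
            chrom = map@chrom, samples = c("a", "b"))
  segs <- detectSharedSegments(tr, map)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$chrom, c("1", "2"))
  zero <- new("IbsTrack", state = rep(0L, 8L), locusIndex = 1:8,
              chrom = map@chrom, samples = c("a", "b"))
  expect_equal(nrow(detectSharedSegments(zero, map)), 0L)
  empty <- new("IbsTrack", state = integer(), locusIndex = integer(),
               chrom = character(), samples = c("a", "b"))
  expect_equal(nrow(detectSharedSegments(empty, map)), 0L)
})

test_that("ics(Th) filters strictly and is non-increasing in Th", {
  segs <- data.frame(lengthCM = c(5, 3))
  expect_equal(icsFromSegments(segs, 4), 5)
  expect_equal(icsFromSegments(segs, 5), 0)   # strictly greater than
  expect_equal(icsFromSegments(segs, 0), 8)
  expect_error(icsFromSegments(segs, -1), "non-negative")
  set.seed(11)
  r <- data.frame(lengthCM = rexp(40, 1 / 10))
  vals <- vapply(seq(0, 60, by = 2), function(th)
    icsFromSegments(r, th), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals <= vals[1L]))
})

test_that("masking loci can merge but never split shared runs", {
  map <- tinyMap(25L)
  set.seed(303)
  for (rep in 1:50) {
    a <- as.integer(sample(0:2, nLoci(map), replace = TRUE))
    b <- as.integer(sample(0:2, nLoci(map), replace = TRUE))
    g <- tinyGenotypes(map, a = a, b = b)
    full <- detectSharedSegments(ibsStates(g, "a", "b"), map)
    drop <- sample(nLoci(map), 3L)
    a2 <- a; a2[drop] <- NA
    g2 <- tinyGenotypes(map, a = a2, b = b)
    masked <- detectSharedSegments(ibsStates(g2, "a", "b"), map)
    # every fully-called run that avoided the mask must survive intact
    # inside some masked-run: count of segments can only shrink or stay
    untouched <- full[full$firstIndex > max(drop) |
                      full$lastIndex < min(drop), , drop = FALSE]
    for (k in seq_len(nrow(untouched))) {
      hit <- masked$firstIndex <= untouched$firstIndex[k] &
        masked$lastIndex >= untouched$lastIndex[k] &
        masked$chrom == untouched$chrom[k]
      expect_true(any(hit))
    }
  }
})

test_that("icsPair composes the pipeline and annotates threshold and group", {
  g <- panelGenotypes(smallPanel(), panelDonors(smallPanel())[1:2])
  s <- sampleIds(g)
  iv <- icsPair(g, s[1L], s[2L], th = 4, group = "C")
  expect_s4_class(iv, "IcsValue")
  expect_equal(iv@threshold, 4)
  expect_equal(iv@group, "C")
  expect_gte(icsValue(iv), 0)
  expect_lte(icsValue(iv), totalMapLength(smallMap()))
  # matches manual composition
  segs <- detectSharedSegments(ibsStates(g, s[1L], s[2L]), smallMap())
  expect_equal(icsValue(iv), icsFromSegments(segs, 4))
})

test_that("segment export writes the BED-like TSV columns", {
  segs <- data.frame(chrom = "1", firstSnp = "s1", lastSnp = "s4",
                     firstIndex = 1L, lastIndex = 4L, nSnps = 4L,
                     lengthCM = 3.0)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSegmentsTSV(segs, f)
  back <- read.delim(f)
  expect_equal(back$lengthCM, 3.0)
  expect_equal(colnames(back),
               c("chrom", "firstSnp", "lastSnp", "nSnps", "lengthCM"))
})
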
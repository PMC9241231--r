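test_that("motif models validate and consensus construction is correct", {
  m <- consensusMotif("UGCAUG", strength = 0.85)
  expect_s4_class(m, "MotifModel")
  expect_equal(colSums(m@pwm), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(m@pwm["U", 1]), 0.85)
  expect_equal(unname(m@pwm["A", 1]), 0.05)
  expect_error(motifModel(matrix(0.3, 4, 2,
    dimnames = list(c("A", "C", "G", "U"), NULL))), "sum to 1")
  expect_error(consensusMotif("UGN"), "must not contain N")
})

test_that("degenerate background composition yields a homopolymer", {
  withr::with_seed(1, {
    expect_equal(sampleBackground(7, c(A = 1, C = 0, G = 0, U = 0)),
      "AAAAAAA")
  })
})

test_that("uniform background concentrates near equal base frequencies", {
  withr::with_seed(2, {
    s <- sampleBackground(1e5)
    freq <- table(strsplit(s, "")[[1]]) / 1e5
    expect_true(all(abs(freq - 0.25) < 0.01))
  })
})

test_that("background draws are seed-reproducible", {
  a <- withr::with_seed(9, sampleBackground(50))
  b <- withr::with_seed(9, sampleBackground(50))
  expect_identical(a, b)
})

test_that("deterministic motifs are planted exactly once at the reported spot", {
  det <- consensusMotif("UGCAUG", strength = 1)
  withr::with_seed(3, {
    for (i in 1:10) {
      bg <- sampleBackground(40, c(A = 0.5, C = 0.5, G = 0, U = 0))
      pl <- plantMotif(bg, det)
      expect_equal(substr(pl$seq, pl$pos, pl$pos + 5), "UGCAUG")
      # background has no G/U, so the only UGCAUG is the planted one
      expect_equal(length(gregexpr("UGCAUG", pl$seq)[[1]]), 1)
      expect_true(pl$pos >= 1 && pl$pos <= 35)
    }
  })
})

test_that("planted positions are uniform over valid offsets", {
  det <- consensusMotif("GG", strength = 1)
  withr::with_seed(4, {
    pos <- vapply(1:4000, function(i) {
      plantMotif(sampleBackground(11), det)$pos
    }, integer(1))
  })
  # 10 valid offsets; chi-square against uniform
  tab <- table(factor(pos, levels = 1:10))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("motif as wide as the sequence replaces it wholly", {
  det <- consensusMotif("ACGU", strength = 1)
  out <- withr::with_seed(5, plantMotif("GGGG", det))
  expect_equal(out$seq, "ACGU")
  expect_equal(out$pos, 1L)
})

test_that("mononucleotide shuffle preserves base counts exactly", {
  withr::with_seed(6, {
    s <- randomRNA(60)
    sh <- shuffleSequence(s, "shuffle")
    expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  })
})

test_that("dinucleotide shuffle preserves all adjacent-pair counts", {
  withr::with_seed(7, {
    for (s in c("ACGUACGU", randomRNA(50), randomRNA(101),
      "ACACACACAU")) {
      sh <- shuffleSequence(s, "dinucleotide_shuffle")
      expect_equal(dinucCounts(sh), dinucCounts(s))
      expect_equal(nchar(sh), nchar(s))
    }
    # shuffles are not systematically the identity
    long <- randomRNA(101)
    expect_false(identical(shuffleSequence(long, "dinucleotide_shuffle"),
      long))
  })
})

test_that("single-symbol sequences are fixed points of both shuffles", {
  expect_equal(shuffleSequence("AAAA", "shuffle"), "AAAA")
  expect_equal(shuffleSequence("AAAA", "dinucleotide_shuffle"), "AAAA")
})

test_that("generated datasets have the configured size, balance and truth", {
  cfg <- simulationConfig(100, 100, seqLength = 31,
    motif = consensusMotif("UGCAUG", 1), seed = 5)
  d <- generateDataset(cfg)
  expect_equal(length(d), 200)
  expect_equal(sum(labels(d) == 1L), 100)
  expect_equal(sum(labels(d) == 0L), 100)
  tr <- truthTable(d)
  expect_equal(nrow(tr), 200)
  expect_true(all(tr$plantedPos[tr$label == 1] >= 1))
  expect_true(all(tr$plantedPos[tr$label == 0] == -1))
  expect_true(all(Biostrings::width(sequences(d)) == 31))
  # generator speaks RNA: no T anywhere
  expect_false(any(grepl("T", as.character(sequences(d)))))
  # seed determinism
  d2 <- generateDataset(cfg)
  expect_identical(as.character(sequences(d)), as.character(sequences(d2)))
})

test_that("a string-match oracle separates deterministic-motif data", {
  # an 8-nt deterministic motif is vanishingly rare by chance, so the
  # exact-substring classifier is essentially perfect
  cfg <- simulationConfig(60, 60, seqLength = 60,
    motif = consensusMotif("UGCAUGAC", 1),
    negativeMode = "background", seed = 8)
  d <- generateDataset(cfg)
  score <- as.numeric(grepl("UGCAUGAC", as.character(sequences(d))))
  expect_equal(aucRank(score, labels(d)), 1.0)
})

test_that("a motif identical to background carries no signal", {
  flat <- motifModel(matrix(0.25, 4, 6,
    dimnames = list(c("A", "C", "G", "U"), NULL)), "flat")
  cfg <- simulationConfig(150, 150, seqLength = 31, motif = flat,
    negativeMode = "background", seed = 9)
  d <- generateDataset(cfg)
  # composition-based score: AUC compatible with chance
  gc <- vapply(as.character(sequences(d)), function(s) {
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expect_lt(abs(aucRank(gc, labels(d)) - 0.5), 0.08)
})

test_that("generated FASTA round-trips through the paired reader", {
  d <- generateDataset(simulationConfig(8, 6, seqLength = 25,
    motif = consensusMotif("UGCAUG", 1), seed = 10))
  tmp <- tempfile()
  files <- writeDatasetFasta(d, tmp)
  back <- readFastaPair(paste0(tmp, ".positives.fa"),
    paste0(tmp, ".negatives.fa"))
  expect_equal(length(back), 14)
  expect_equal(labels(back), labels(d))
  expect_identical(as.character(sequences(back)),
    as.character(sequences(d)))
  unlink(files)
})
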
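test_that("consensus_to_pwm builds smoothed one-hot columns", {
  m0 <- consensus_to_pwm("ACAAAG", pseudocount = 0)
  expect_s3_class(m0, "motif")
  expect_equal(motif_length(m0), 6)
  expect_equal(unname(m0$matrix[, 1]), c(1, 0, 0, 0))

  m <- consensus_to_pwm("ACAAAG", pseudocount = 0.4)
  # (1 + 0.4 * 0.25) / (1 + 0.4) for the consensus base
  expect_equal(unname(m$matrix["A", 1]), 1.1 / 1.4)
  expect_equal(unname(m$matrix["C", 1]), 0.1 / 1.4)
  expect_equal(colSums(m$matrix), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_equal(motif_length(consensus_to_pwm("CTTTGT", pseudocount = 0.5)), 6)
  expect_error(consensus_to_pwm("ACXAAG"), "position 3")
  expect_error(consensus_to_pwm(""), "non-empty")
})

test_that("motif construction enforces distribution invariants", {
  bad <- matrix(c(0.5, 0.5, 0.1, 0), 4, 1)
  expect_error(new_motif("x", bad), "sum to 1")
  expect_error(new_motif("x", matrix(0.25, 4, 4), background = c(1, 0, 0, 0)),
               "background")
  expect_error(new_motif("x", matrix(0.25, 4, 4), pseudocount = -1),
               "pseudocount")
})

test_that("parse_transfac handles the count-matrix dialect", {
  expect_length(parse_transfac(character(0)), 0)
  expect_length(parse_transfac(""), 0)

  motifs <- suppressMessages(parse_transfac(transfac_fixture()))
  expect_length(motifs, 2)
  expect_equal(motifs[[1]]$name, "motif_acgt")
  expect_equal(motif_length(motifs[[1]]), 4)
  expect_equal(motif_consensus(motifs[[1]]), "ACGT")
  # counts (10,0,0,0) with pc = 0 become a clean one-hot
  expect_equal(unname(motifs[[1]]$matrix[, 1]), c(1, 0, 0, 0))
  # second record: mixed counts normalise to probabilities
  expect_equal(motifs[[2]]$name, "sox_half")
  expect_equal(unname(motifs[[2]]$matrix["A", 1]), 0.8)
  expect_equal(motif_consensus(motifs[[2]]), "ACAATG")

  expect_error(parse_transfac(c("ID x", "P0 A C G T", "01 1 2 3")),
               "4 numeric fields")
  expect_error(parse_transfac(c("ID x", "P0 A C G T", "01 0 0 0 0")),
               "all counts zero")
})

test_that("TRANSFAC round-trip preserves column argmaxes", {
  set.seed(11)
  for (i in 1:5) {
    counts <- matrix(sample(0:20, 4 * 8, replace = TRUE), 4, 8)
    counts[cbind(sample(1:4, 8, replace = TRUE), 1:8)] <- 30  # clear argmax
    probs <- sweep(counts, 2, colSums(counts), "/")
    m <- new_motif(paste0("rt", i), probs)
    reparsed <- parse_transfac(write_transfac(list(m)))[[1]]
    expect_equal(motif_consensus(reparsed), motif_consensus(m))
  }
})

test_that("the shipped synthetic SOX half-site fixtures parse", {
  path <- system.file("extdata", "sox_half_sites_synthetic.transfac",
                      package = "dimerscreen")
  motifs <- parse_transfac(path, is_file = TRUE)
  expect_length(motifs, 2)
  expect_equal(motif_consensus(motifs[[1]]), "ACAAAG")
  expect_equal(motif_consensus(motifs[[2]]), "ACAATG")
  expect_equal(motif_length(motifs[[1]]), 6)
})

test_that("reverse_complement_motif is the rc involution", {
  m <- consensus_to_pwm("ACAAAG", pseudocount = 0.3)
  expect_equal(motif_consensus(reverse_complement_motif(m)), "CTTTGT")
  back <- reverse_complement_motif(reverse_complement_motif(m))
  expect_equal(back$matrix, m$matrix)

  a1 <- consensus_to_pwm("AAAA")  # minimum length 4
  expect_equal(motif_consensus(reverse_complement_motif(a1)), "TTTT")
})

test_that("log_odds_score matches per-position arithmetic", {
  m0 <- consensus_to_pwm("ACAAAG", pseudocount = 0)
  # each matched position contributes log2(1 / 0.25) = 2 bits
  expect_equal(log_odds_score(m0, "ACAAAG"), 12)
  expect_equal(max_score(m0), 12)

  m <- consensus_to_pwm("ACAAAG", pseudocount = 0.4)
  site <- "ACTAAG"  # one mismatch
  expect_equal(log_odds_score(m, site),
               brute_force_log_odds(m$matrix, m$background, site))
  expect_error(log_odds_score(m, "ACAAA"), "length")
})

test_that("consensus attains the maximum achievable score", {
  set.seed(21)
  for (i in 1:10) {
    cons <- random_dna(sample(4:9, 1))
    m <- consensus_to_pwm(cons, pseudocount = runif(1, 0, 2))
    expect_equal(log_odds_score(m, motif_consensus(m)), max_score(m))
  }
})

test_that("scan_sequence finds both-strand matches in plus coordinates", {
  m <- consensus_to_pwm("CATTGT")
  hits <- scan_sequence("probe", "CCGAACAATGGAAGCATTGTTGCC", m, max_score(m))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(4, 14))
  expect_equal(hits$end, c(10, 20))
  expect_equal(hits$strand, c("-", "+"))
  expect_equal(hits$site, c("CATTGT", "CATTGT"))
  expect_equal(hits$score, c(12, 12))

  expect_equal(nrow(scan_sequence("x", "", m, 0)), 0)
  expect_equal(nrow(scan_sequence("x", "CAT", m, 0)), 0)   # shorter than motif
  expect_error(scan_sequence("x", "CATTGT", m, Inf), "finite")
})

test_that("ambiguity characters never match", {
  m <- consensus_to_pwm("CATTGT")
  expect_equal(nrow(scan_sequence("x", "CANTGTCATTGT", m, max_score(m))), 1)
  expect_equal(nrow(scan_sequence("x", "NNNNNNNN", m, -100)), 0)
})

test_that("scanning is strand-symmetric", {
  m <- consensus_to_pwm("ACAATG", pseudocount = 0.5)
  thr <- default_threshold(m, 0.6)
  set.seed(31)
  for (i in 1:10) {
    seq <- random_dna(50)
    fwd <- scan_sequence("s", seq, m, thr)
    rev <- scan_sequence("s", revcomp_str(seq), m, thr)
    # mirror: start' = L_seq - end, strand flipped
    mirrored <- data.frame(start = 50 - rev$end, end = 50 - rev$start,
                           strand = chartr("+-", "-+", rev$strand),
                           score = rev$score, site = rev$site,
                           stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$strand, mirrored$strand)
    expect_equal(fwd$score, mirrored$score, tolerance = 1e-12)
    expect_equal(fwd$site, mirrored$site)
  }
})

test_that("scan agrees with a naive consensus matcher at the max threshold", {
  m <- consensus_to_pwm("ACAATG")
  set.seed(41)
  for (i in 1:10) {
    seq <- random_dna(80)
    got <- scan_sequence("s", seq, m, max_score(m))
    want <- naive_consensus_scan(seq, "ACAATG")
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})
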
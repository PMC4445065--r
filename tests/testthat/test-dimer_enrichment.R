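probe <- "CCGAACAATGGAAGCATTGTTGCC"
half <- consensus_to_pwm("ACAATG", name = "SOX_half")

test_that("enumerate_configurations covers canonical classes without duplicates", {
  m <- consensus_to_pwm("ACAAAG")
  expect_length(enumerate_configurations(list(m), 0), 3)
  expect_length(enumerate_configurations(list(m), 50), 153)
  expect_error(enumerate_configurations(list(), 5), "non-empty")

  m2 <- consensus_to_pwm("CTTTTG", name = "other")
  cfgs <- enumerate_configurations(list(m, m2), 2)
  # self-pairs: 2 motifs x 3 orientations x 3 spacers; distinct pair: 4 x 3
  expect_length(cfgs, 2 * 3 * 3 + 4 * 3)
  keys <- vapply(cfgs, function(c)
    paste(c$motif_a$name, c$motif_b$name, c$orientation, c$spacer),
    character(1))
  expect_false(any(duplicated(keys)))
})

test_that("find_dimer_instances detects the palindromic probe element", {
  cfg4 <- dimer_config(half, orientation = "inverted", spacer = 4)
  inst <- find_dimer_instances(probe, cfg4)
  expect_equal(nrow(inst), 1)
  expect_equal(inst$start, 4)
  expect_equal(inst$end, 20)
  expect_equal(c(inst$strand_first, inst$strand_second), c("+", "-"))
  expect_equal(nchar(inst$gap), 4)

  cfg5 <- dimer_config(half, orientation = "inverted", spacer = 5)
  expect_equal(nrow(find_dimer_instances(probe, cfg5)), 0)
  expect_equal(nrow(find_dimer_instances("", cfg4)), 0)
})

test_that("direct and everted arrangements are matched on both strands", {
  # direct: ACAATG-nn-ACAATG on plus, and its rc (a -- arrangement)
  seq_pp <- paste0("TTTT", "ACAATG", "GG", "ACAATG", "TTTT")
  cfg <- dimer_config(half, orientation = "direct", spacer = 2)
  expect_equal(nrow(find_dimer_instances(seq_pp, cfg)), 1)
  expect_equal(nrow(find_dimer_instances(revcomp_str(seq_pp), cfg)), 1)
  # everted: tail-to-tail = rc(half) then half
  seq_ev <- paste0("TTTT", "CATTGT", "GG", "ACAATG", "TTTT")
  cfg_ev <- dimer_config(half, orientation = "everted", spacer = 2)
  expect_equal(nrow(find_dimer_instances(seq_ev, cfg_ev)), 1)
  expect_equal(nrow(find_dimer_instances(seq_ev, cfg)), 0)
})

test_that("count_regions_with_instance counts region-level indicators", {
  cfg <- dimer_config(half, orientation = "inverted", spacer = 4)
  empty <- region_set("empty", data.frame(sequence_id = character(0),
                                          start = integer(0),
                                          end = integer(0),
                                          sequence = character(0)),
                      "foreground")
  expect_equal(count_regions_with_instance(empty, cfg), 0)

  sim <- simulate_region_sets(10, 0, length = 120, config = cfg,
                              plant_rate = 1, seed = 7)
  expect_equal(count_regions_with_instance(sim$foreground, cfg), 10)

  short <- region_set("short", data.frame(sequence_id = "s", start = 0,
                                          end = 8, sequence = "ACAATGGG"),
                      "foreground")
  expect_equal(count_regions_with_instance(short, cfg), 0)
})

test_that("enrichment_test equals brute-force hypergeometric enumeration", {
  expect_equal(enrichment_test(3, 5, 1, 5), 66 / 252)
  expect_equal(enrichment_test(1, 1, 0, 1), 0.5)
  expect_equal(enrichment_test(0, 5, 3, 5), 1)

  for (n_fg in 1:6) for (n_ctrl in 1:6) {
    if (n_fg + n_ctrl > 12) next
    for (k_fg in 0:n_fg) for (k_ctrl in 0:n_ctrl) {
      expect_equal(enrichment_test(k_fg, n_fg, k_ctrl, n_ctrl),
                   brute_force_enrichment_p(k_fg, n_fg, k_ctrl, n_ctrl),
                   tolerance = 1e-12)
    }
  }
  expect_error(enrichment_test(3, 2, 0, 5), "0 <= k <= n")
  expect_error(enrichment_test(0, 0, 0, 5), "positive")
})

test_that("p_raw is monotone decreasing in k_fg at fixed margins", {
  for (k in 0:9) {
    expect_gte(enrichment_test(k, 10, 5, 20),
               enrichment_test(k + 1, 10, 5, 20))
  }
})

test_that("bonferroni_correct multiplies and caps", {
  expect_equal(bonferroni_correct(0.01, 1), 0.01)
  expect_equal(bonferroni_correct(0.5, 3), 1)
  expect_equal(bonferroni_correct(0.0002, 153), 0.0306)
  expect_error(bonferroni_correct(0.5, 0), "n_tests")
  expect_error(bonferroni_correct(1.5, 2), "p_raw")
})

test_that("spacing_profile ranks the planted spacer first", {
  cfg <- dimer_config(half, orientation = "inverted", spacer = 4)
  sim <- simulate_region_sets(60, 120, length = 200, config = cfg,
                              plant_rate = 0.5, seed = 13)
  prof <- spacing_profile(sim$foreground, sim$control, half,
                          orientation = "inverted", max_spacer = 10)
  expect_equal(nrow(prof), 11)
  expect_equal(prof$spacer, 0:10)
  expect_equal(prof$spacer[which.min(prof$p_adj)], 4)
  expect_true(all(prof$p_raw <= prof$p_adj))
  expect_true(all(prof$p_adj <= 1))
  # expectation is the control rate scaled to the foreground size
  expect_equal(prof$expected_fg, prof$k_ctrl / prof$n_ctrl * prof$n_fg)
})

test_that("spacing_profile on an empty foreground yields zero counts", {
  cfg <- dimer_config(half, orientation = "inverted", spacer = 4)
  sim <- simulate_region_sets(0, 10, length = 100, config = cfg,
                              plant_rate = 0, seed = 3)
  prof <- spacing_profile(sim$foreground, sim$control, half,
                          orientation = "inverted", max_spacer = 3)
  expect_equal(nrow(prof), 4)
  expect_true(all(prof$k_fg == 0))
})

test_that("counts are invariant under reverse-complementing every region", {
  cfg <- dimer_config(half, orientation = "inverted", spacer = 4)
  sim <- simulate_region_sets(30, 0, length = 150, config = cfg,
                              plant_rate = 0.6, seed = 17)
  fg <- sim$foreground
  rc_regions <- fg$regions
  rc_regions$sequence <- vapply(rc_regions$sequence, revcomp_str,
                                character(1), USE.NAMES = FALSE)
  fg_rc <- region_set("rc", rc_regions, "foreground")
  for (o in c("direct", "inverted", "everted")) {
    for (s in c(0, 4)) {
      c2 <- dimer_config(half, orientation = o, spacer = s)
      expect_equal(count_regions_with_instance(fg_rc, c2),
                   count_regions_with_instance(fg, c2),
                   info = paste(o, s))
    }
  }
})
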
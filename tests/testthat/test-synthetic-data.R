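test_that("copy-number gradient follows the closed form", {
  sc <- toy_scenario(L = 4e6)   # symmetric genome, R = 2
  g <- sc$genome
  expect_equal(copy_number_baseline(g$ori_bp, sc), 2)
  expect_equal(copy_number_baseline(g$ter_bp, sc), 1)
  expect_equal(copy_number_baseline(1e6, sc), sqrt(2), tolerance = 1e-6)
  expect_equal(copy_number_baseline(3e6, sc), sqrt(2), tolerance = 1e-6)
  b <- copy_number_baseline(seq(0, g$length_bp - 1, by = 997), sc)
  expect_true(all(b >= 1 & b <= 2))
})

test_that("stalling enrichment profile honors strength, shape and condition", {
  g <- circular_genome(10000, ter_bp = 5000)
  ann <- gene_regions(c("up", "dn"), c(1000, 6000), c(2000, 7000),
                      c("+", "-"), "gene", g)
  base <- simulation_scenario(g, ann, n_fragments = 10)
  expect_equal(stall_enrichment_profile(base), rep(1, 10000))

  sc <- simulation_scenario(g, ann, n_fragments = 10,
    stall_table = data.frame(id = "up", strength = 4, shape = "uniform"),
    condition_multiplier = 3)
  e <- stall_enrichment_profile(sc, "helicase_present")
  expect_true(all(e[1001:2000] == 5))
  expect_true(all(e[-(1001:2000)] == 1))
  ed <- stall_enrichment_profile(sc, "helicase_depleted")
  expect_true(all(ed[1001:2000] == 13))   # 1 + 4*3

  # three-prime ramp: ~1 at the TSS, ~9 at the 3' base, gene mean exactly 5
  scr <- simulation_scenario(g, ann, n_fragments = 10,
    stall_table = data.frame(id = "up", strength = 4,
                             shape = "three_prime_ramp"))
  er <- stall_enrichment_profile(scr, "helicase_present")
  gene <- er[1001:2000]
  expect_equal(gene[1], 1 + 4 * 2 * 0.5 / 1000)            # ~1
  expect_equal(gene[1000], 1 + 4 * 2 * 999.5 / 1000)       # ~9
  expect_equal(mean(gene), 5)
  # oracle: direct evaluation of the ramp formula at each base
  expect_equal(gene, 1 + 4 * 2 * (seq_len(1000) - 0.5) / 1000)

  # minus-strand gene ramps toward decreasing coordinate
  scm <- simulation_scenario(g, ann, n_fragments = 10,
    stall_table = data.frame(id = "dn", strength = 4,
                             shape = "three_prime_ramp"))
  em <- stall_enrichment_profile(scm, "helicase_present")[6001:7000]
  expect_true(em[1] > em[1000])

  expect_error(
    simulation_scenario(g, ann, n_fragments = 10,
      stall_table = data.frame(id = "nope", strength = 1,
                               shape = "uniform")),
    "absent from annotation")
})

test_that("sample simulation is seeded, mass-conserving and well-calibrated", {
  sc <- toy_scenario(L = 1e5, n_genes = 10, n_fragments = 20000,
                     ori_ter_ratio = 1)
  a <- simulate_chip_sample(sc, "ip", "helicase_present", seed = 99)
  b <- simulate_chip_sample(sc, "ip", "helicase_present", seed = 99)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$track$values, b$track$values)
  c2 <- simulate_chip_sample(sc, "ip", "helicase_present", seed = 100)
  expect_false(identical(a$fragments, c2$fragments))

  # conservation: coverage sum equals total fragment length
  expect_equal(sum(a$track$values), sum(a$fragments$end - a$fragments$start))

  # flat scenario: genome-wide mean depth matches n*E[len]/L within 3 SE
  mean_len <- mean(a$fragments$end - a$fragments$start)
  expected <- sc$n_fragments * 250 / sc$genome$length_bp
  se <- sc$n_fragments * 100 / sqrt(sc$n_fragments) / sc$genome$length_bp
  expect_lt(abs(mean(a$track$values) - expected), 3 * se + 1e-9)

  zero <- simulation_scenario(sc$genome, sc$annotation, n_fragments = 0)
  expect_equal(sum(simulate_chip_sample(zero, "ip")$track$values), 0)
})

test_that("implanted enrichment is recovered as an ip/input depth ratio", {
  # one 2-kb gene with s = 9 uniform at flat copy number; the
  # background-normalized ip/input ratio at the gene should be ~10
  g <- circular_genome(2e5)
  ann <- gene_regions("target", 50000, 52000, "+", "gene", g)
  sc <- simulation_scenario(g, ann, ori_ter_ratio = 1,
    stall_table = data.frame(id = "target", strength = 9,
                             shape = "uniform"),
    n_fragments = 200000, seed = 5)
  ip <- simulate_chip_sample(sc, "ip", "helicase_present")$track
  input <- simulate_chip_sample(sc, "input", "helicase_present")$track
  gene_ratio <- mean(ip$values[50001:52000]) / mean(input$values[50001:52000])
  genome_ratio <- median(ip$values) / median(input$values)
  expect_lt(abs(gene_ratio / genome_ratio - 10) / 10, 0.15)
})

test_that("expected gene signal increases with stall strength", {
  g <- circular_genome(1e5)
  ann <- gene_regions("t", 40000, 42000, "+", "gene", g)
  mk <- function(s) {
    sc <- simulation_scenario(g, ann, ori_ter_ratio = 1,
      stall_table = data.frame(id = "t", strength = s, shape = "uniform"),
      n_fragments = 50000)
    tr <- simulate_chip_sample(sc, "ip", "helicase_present", seed = 1)$track
    mean(tr$values[40001:42000])
  }
  m <- vapply(c(0, 2, 6, 12), mk, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("mock samples see stickiness but not stalling", {
  g <- circular_genome(1e5)
  ann <- gene_regions("t", 40000, 42000, "+", "gene", g)
  sc <- simulation_scenario(g, ann, ori_ter_ratio = 1,
    stall_table = data.frame(id = "t", strength = 9, shape = "uniform"),
    mock_sticky = data.frame(start = 70000, end = 72000, stickiness = 9),
    n_fragments = 100000)
  mock <- simulate_chip_sample(sc, "mock", "helicase_depleted", seed = 2)$track
  ip <- simulate_chip_sample(sc, "ip", "helicase_depleted", seed = 2)$track
  # the mock is enriched at the sticky interval, flat at the stall gene
  expect_gt(mean(mock$values[70001:72000]), 3 * mean(mock$values[1:2000]))
  expect_lt(mean(mock$values[40001:42000]),
            2 * mean(mock$values[1:2000]))
  # the ip sees both
  expect_gt(mean(ip$values[40001:42000]), 3 * mean(ip$values[1:2000]))
  expect_gt(mean(ip$values[70001:72000]), 3 * mean(ip$values[1:2000]))
})

test_that("qPCR simulation inverts the amplification law", {
  ab <- data.frame(locus = c("t", "t", "yhaX", "yhaX"),
                   fraction = c("chip", "input", "chip", "input"),
                   abundance = c(0.04, 0.01, 0.02, 0.02))
  ct <- simulate_qpcr(qpcr_design(ab, efficiency = 2, ct_noise_sd = 0))
  plate <- qpcr_plate(ct, efficiency = 2, reference = "yhaX")
  expect_equal(fold_enrichment(plate, "t"), 4)

  # quadrupling abundance lowers Ct by exactly 2 cycles at E = 2
  ab2 <- ab; ab2$abundance[1] <- ab$abundance[1] * 4
  ct2 <- simulate_qpcr(qpcr_design(ab2, efficiency = 2, ct_noise_sd = 0))
  expect_equal(ct$ct[1] - ct2$ct[1], 2)

  # identical abundances everywhere -> fold enrichment 1
  ab3 <- ab; ab3$abundance <- 0.05
  ct3 <- simulate_qpcr(qpcr_design(ab3, ct_noise_sd = 0))
  expect_equal(fold_enrichment(qpcr_plate(ct3), "t"), 1)

  expect_error(qpcr_design(data.frame(locus = "x", fraction = "chip",
                                      abundance = -1)), "positive")
})

test_that("input coverage recovers the designed log2 gradient slope", {
  sc <- toy_scenario(L = 1e6, n_genes = 10, n_fragments = 300000)
  tr <- simulate_chip_sample(sc, "input", "helicase_present")$track
  g <- sc$genome
  bin <- 10000
  starts <- seq(0, g$length_bp - bin, by = bin)
  mids <- starts + bin / 2
  covm <- vapply(starts, function(s) mean(tr$values[(s + 1):(s + bin)]),
                 numeric(1))
  arcs <- c(right = 5e5, left = 5e5)
  d <- distance_from_ori(mids, g)
  x <- 1 - d / 5e5
  fit <- lm(log2(covm) ~ x)
  expect_lt(abs(unname(coef(fit)[2]) - 1), 0.1)
})
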
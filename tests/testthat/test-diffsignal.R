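mk_track <- function(values, g, ...) coverage_track(values, g, ...)

test_that("depth scaling equalizes means and zeroes matched subtractions", {
  g <- circular_genome(100, ter_bp = 50)
  a <- mk_track(rep(10, 100), g); b <- mk_track(rep(20, 100), g)
  sc <- scale_to_common_depth(list(a, b))
  expect_equal(mean(sc[[1]]$values), mean(sc[[2]]$values))
  expect_equal(mean(sc[[1]]$values), 15)

  one <- scale_to_common_depth(list(a), target_mean = 7)
  expect_equal(mean(one[[1]]$values), 7)

  # same shape at different depth: scaling then subtracting gives zero
  shape <- sin(seq(0, 2 * pi, length.out = 100)) + 2
  t1 <- mk_track(shape, g); t2 <- mk_track(3 * shape, g)
  sc2 <- scale_to_common_depth(list(t1, t2))
  expect_equal(normalize_chip(sc2[[1]], sc2[[2]])$values, rep(0, 100))

  expect_error(scale_to_common_depth(list(mk_track(rep(0, 100), g))),
               "nonpositive")
})

test_that("subtraction normalizations are per-base and keep negatives", {
  g <- circular_genome(100, ter_bp = 50)
  ip <- mk_track(rep(7, 100), g); input <- mk_track(rep(3, 100), g)
  expect_equal(normalize_chip(ip, input)$values, rep(4, 100))
  expect_equal(normalize_chip(ip, ip)$values, rep(0, 100))

  spike <- rep(0, 100); spike[40:45] <- 10
  n <- normalize_chip(mk_track(3 + spike, g), mk_track(rep(3, 100), g))
  expect_equal(n$values, spike)

  # mock correction removes shared sticky peaks, keeps specific ones
  sticky <- rep(0, 100); sticky[10:12] <- 5
  norm_ip <- mk_track(spike + sticky, g)
  norm_mock <- mk_track(sticky, g)
  mc <- mock_correct(norm_ip, norm_mock)
  expect_equal(mc$values, spike)
  expect_equal(mock_correct(norm_ip, mk_track(rep(0, 100), g))$values,
               norm_ip$values)

  # differential keeps sign: higher in 'present' goes negative
  d <- differential(mk_track(rep(0, 100), g), mk_track(spike, g))
  expect_equal(d$values, -spike)
  expect_equal(d$condition, "depleted-minus-present")

  g2 <- circular_genome(200, ter_bp = 100)
  expect_error(normalize_chip(ip, mk_track(rep(1, 200), g2)),
               "different genomes")
})

test_that("normalization chain commutes with scalar rescaling", {
  g <- circular_genome(300, ter_bp = 150)
  set.seed(8)
  vals <- lapply(1:4, function(i) rpois(300, 20))
  tr <- lapply(vals, mk_track, g = g)
  out1 <- differential(normalize_chip(tr[[1]], tr[[2]]),
                       normalize_chip(tr[[3]], tr[[4]]))
  tr_scaled <- lapply(vals, function(v) mk_track(2.5 * v, g))
  out2 <- differential(normalize_chip(tr_scaled[[1]], tr_scaled[[2]]),
                       normalize_chip(tr_scaled[[3]], tr_scaled[[4]]))
  expect_equal(out2$values, 2.5 * out1$values)
})

test_that("region quantification matches a brute-force modular scan", {
  g <- circular_genome(10, ter_bp = 5)
  tr <- mk_track(c(0, 0, 0, 2, 4, 6, 0, 0, 0, 0), g)
  q <- quantify_regions(tr, gene_regions("r", 3, 6, "+", "gene", g))
  expect_equal(q$max_signal, 6)
  expect_equal(q$mean_signal, 4)
  expect_equal(q$auc, 12)
  expect_equal(q$nauc, 4)
  expect_equal(q$nauc * q$length, q$auc)

  zero <- quantify_regions(mk_track(rep(0, 10), g),
                           gene_regions("r", 3, 6, "+", "gene", g))
  expect_true(all(c(zero$max_signal, zero$auc) == 0))

  # wrapping region across the coordinate origin
  ones <- mk_track(rep(1, 10), g)
  qw <- quantify_regions(ones, gene_regions("w", 8, 13, "+", "gene", g))
  expect_equal(qw$auc, 5)
  expect_equal(qw$max_signal, 1)

  set.seed(21)
  for (i in 1:30) {
    L <- sample(20:100, 1)
    gg <- circular_genome(L, ter_bp = L %/% 2)
    v <- round(rnorm(L), 3)
    s <- sample(0:(L - 1), 1); len <- sample(1:L, 1)
    q1 <- quantify_regions(mk_track(v, gg),
                           gene_regions("x", s, s + len, "+", "gene", gg))
    o <- brute_quantify(v, s, s + len, L)
    expect_equal(q1$max_signal, o$max)
    expect_equal(q1$auc, o$auc)
    expect_equal(q1$nauc, o$nauc)
  }
})

test_that("two-zone background converges on flagged peak-free windows", {
  g <- circular_genome(2e6, ter_bp = 1e6)
  # constant track: both zones equal the constant, nothing flagged
  bgc <- estimate_background(mk_track(rep(4, 2e6), g))
  expect_equal(bgc$proximal_bg, 4)
  expect_equal(bgc$distal_bg, 4)
  expect_false(any(bgc$windows$flagged))

  # constant 10 with one 2-kb block at 100 in a distal window:
  # oracle (hand computation): distal median 10, block window flagged at
  # 100 > 50, background = mean of remaining windows = 10
  v <- rep(10, 2e6); v[500001:502000] <- 100
  bg <- estimate_background(mk_track(v, g))
  expect_equal(bg$distal_bg, 10)
  expect_equal(bg$proximal_bg, 10)
  flagged <- bg$windows[bg$windows$flagged, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$zone, "distal")
  expect_true(flagged$start <= 500000 && flagged$end >= 502000)

  # copy-number gradient raises the proximal zone background
  sc <- simulation_scenario(g, gene_regions("g1", 0, 10, "+", "gene", g),
                            ori_ter_ratio = 2, n_fragments = 10)
  grad <- 10 * copy_number_baseline(0:(2e6 - 1), sc) / 2
  bgg <- estimate_background(mk_track(grad, g))
  expect_gt(bgg$proximal_bg, bgg$distal_bg)

  expect_error(estimate_background(mk_track(rep(1, 100),
                                            circular_genome(100))),
               "shorter than two windows")
})

test_that("peak calling uses a strict fold threshold with zone lookup", {
  g <- circular_genome(2e6, ter_bp = 1e6)
  regs <- gene_regions(c("prox", "called", "boundary"),
                       c(100000, 600000, 800000),
                       c(102000, 602000, 802000), "+", "gene", g)
  v <- rep(0, 2e6)
  v[100001:102000] <- 60   # proximal zone, bg 20 -> fold 3
  v[600001:602000] <- 60   # distal zone, bg 10 -> fold 6
  v[800001:802000] <- 50   # distal zone, fold exactly 5
  q <- quantify_regions(mk_track(v, g), regs)
  bg <- structure(list(proximal_bg = 20, distal_bg = 10,
                       window_bp = 1e5, proximal_bp = 3e5, threshold = 5),
                  class = "background_model")
  pk <- call_peaks(q, bg, g)
  expect_equal(pk$zone, c("proximal", "distal", "distal"))
  expect_equal(pk$fold_over_background, c(3, 6, 5))
  expect_equal(pk$called, c(FALSE, TRUE, FALSE))  # 5 is NOT > 5

  bad <- bg; bad$distal_bg <- 0
  expect_error(call_peaks(q, bad, g), "nonpositive")
})

test_that("calls at a higher threshold are a subset of lower-threshold calls", {
  g <- circular_genome(2e6, ter_bp = 1e6)
  set.seed(31)
  v <- rexp(2e6, rate = 1)
  spots <- sample(seq(1, 2e6 - 2000, by = 2000), 30)
  for (s in spots) v[s:(s + 500)] <- v[s:(s + 500)] + rexp(1, 1 / 20)
  regs <- gene_regions(paste0("r", seq_along(spots)), spots - 1,
                       spots - 1 + 2000, "+", "gene", g)
  tr <- mk_track(v, g)
  q <- quantify_regions(tr, regs)
  bg <- estimate_background(tr)
  c5 <- call_peaks(q, bg, g, threshold = 5)
  c6 <- call_peaks(q, bg, g, threshold = 6)
  expect_true(all(c6$id[c6$called] %in% c5$id[c5$called]))
})

test_that("association vectors correlate by the product-moment formula", {
  expect_equal(correlate(c(1, 2, 3), 2 * c(1, 2, 3) + 1), 1)
  expect_equal(correlate(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")

  g <- circular_genome(1000, ter_bp = 500)
  q <- quantify_regions(mk_track(seq_len(1000) / 100, g),
                        gene_regions(c("a", "b", "c"), c(0, 300, 600),
                                     c(100, 400, 700), "+", "gene", g))
  v <- association_vector(q)
  expect_equal(names(v), c("a", "b", "c"))
  expect_equal(unname(v), q$max_signal)
})

test_that("region tables round-trip through the delimited writer", {
  g <- circular_genome(1000, ter_bp = 500)
  q <- quantify_regions(mk_track(rnorm(1000), g),
                        gene_regions(c("a", "b"), c(0, 300), c(100, 400),
                                     "+", "gene", g))
  p <- tempfile(fileext = ".tsv")
  write_region_table(q, p, params = list(threshold = 5))
  back <- read_region_table(p)
  expect_equal(back$id, q$id)
  expect_equal(back$auc, q$auc, tolerance = 1e-9)
  expect_true(startsWith(readLines(p, 1), "# repliconflict"))
})
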
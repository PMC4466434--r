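# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-base membership scans) so they share no code with
# the implementations they check.

# Coverage at each base by scanning every fragment for membership.
brute_pileup <- function(fragments, L) {
  v <- numeric(L)
  for (k in seq_len(nrow(fragments))) {
    s <- fragments$start[k] %% L
    len <- fragments$end[k] - fragments$start[k]
    for (j in seq_len(len)) {
      pos <- (s + j - 1) %% L
      v[pos + 1] <- v[pos + 1] + 1
    }
  }
  v
}

# Region statistics by per-base modular scan.
brute_quantify <- function(values, start, end, L) {
  len <- end - start
  rv <- numeric(len)
  for (j in seq_len(len)) rv[j] <- values[((start + j - 1) %% L) + 1]
  list(max = max(rv), mean = mean(rv), auc = sum(rv), nauc = sum(rv) / len)
}

random_fragments <- function(n, L) {
  data.frame(start = sample.int(L, n, replace = TRUE) - 1,
             end = 0) -> f
  f$end <- f$start + sample.int(min(L, 50), n, replace = TRUE)
  f
}

toy_genome <- function(L = 4e6, ori = 0, ter = 2e6) {
  circular_genome(L, ori, ter)
}

# A small genome + annotation + scenario for fast simulation tests.
toy_scenario <- function(L = 2e5, n_genes = 20, gene_len = 2000,
                         gap = 1000, n_fragments = 50000, seed = 11, ...) {
  g <- circular_genome(L)
  ann <- synthetic_annotation(g, n_genes = n_genes, gene_len = gene_len,
                              gap = gap, seed = seed)
  simulation_scenario(g, ann, n_fragments = n_fragments, seed = seed, ...)
}

# Deterministic S-shaped arc fully inside a 256x256 image.
toy_arc <- function(n_points = 120, lane_width_px = 7) {
  x <- seq(40, 216, length.out = 9)
  y <- 128 + 60 * sin(seq(0, pi, length.out = 9))
  arc_model(cbind(x, y), lane_width_px = lane_width_px,
            n_points = n_points)
}
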
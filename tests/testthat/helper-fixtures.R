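# shared fixture builders; everything is generated in code

# a random small alignment instance within the brute-force guard; values are
# quarter-integers so squared differences and their sums are exact in binary
# and cost comparisons against the oracle can demand bit equality
random_instance <- function(max_M = 10, max_N = 5) {
  N <- sample(2:max_N, 1)
  M <- N + sample(0:(max_M - max_N), 1)
  list(X = list(times = seq_len(M), values = round(4 * rnorm(M)) / 4),
       Y = list(times = seq_len(N), values = round(4 * rnorm(N)) / 4))
}

# noiseless series on an exact polynomial
poly_series <- function(coefs, t = seq(0, 4, length.out = 20),
                        gene = "poly", group = "g") {
  y <- coefs[1] + coefs[2] * t + coefs[3] * t^2 +
    if (length(coefs) > 3) coefs[4] * t^3 else 0
  raw_series(t, y, gene, group)
}

# interp_series directly from values (already-uniform grid)
as_interp <- function(values, times = seq_along(values)) {
  structure(list(times = times, values = values, K = length(values),
                 gene_id = "fix", group = "fix"),
            class = "interp_series")
}

# planted three-cluster shift-profile matrix
planted_profiles <- function(per_cluster = 8, N = 20, sep = 4, sd = 0.3) {
  shapes <- list(rep(0, N), seq(0, sep, length.out = N),
                 sep * sin(pi * seq_len(N) / N))
  mat <- do.call(rbind, lapply(seq_along(shapes), function(k)
    t(replicate(per_cluster, shapes[[k]] + rnorm(N, sd = sd)))))
  rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  list(profiles = mat,
       truth = rep(seq_along(shapes), each = per_cluster))
}
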
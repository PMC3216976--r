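# Small builders shared across test files. Fixtures are constructed in
# code; nothing is read from disk.

beta_mat <- function(values, n_probes, n_samples,
                     probes = sprintf("p%02d", seq_len(n_probes)),
                     samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_probes, n_samples, dimnames = list(probes, samples))
}

meta_df <- function(samples, groups, weeks = NA_integer_, batches = "b1") {
  data.frame(sample_id = samples, group = groups,
             gestational_week = weeks, batch = batches,
             stringsAsFactors = FALSE)
}

anno_df <- function(probes, chromosome = "1", cgi = "CGI",
                    genes = paste0("G_", probes), tss = -200L) {
  data.frame(probe_id = probes, gene_symbol = genes,
             chromosome = chromosome, cgi = cgi, tss_distance = tss,
             stringsAsFactors = FALSE)
}

small_config <- function(seed = 1L, n_probes = 2000L, n_progressive = 50L,
                         n_variable_third = 30L, ...) {
  simulation_config(seed = seed, n_probes = n_probes,
                    n_progressive = n_progressive,
                    n_variable_third = n_variable_third, ...)
}

# Independent brute-force Benjamini-Hochberg step-up: sort, apply
# (m/rank) * p, take the running minimum from the largest rank down.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
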
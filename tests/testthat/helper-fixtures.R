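# Shared fixtures and independent oracles.

# One-locus profile tibble.
prof <- function(offset, value, locus_id = "L1", condition = "c",
                 replicate = "1") {
  tibble::tibble(locus_id = locus_id, condition = condition,
                 replicate = as.character(replicate),
                 offset = as.integer(offset), value = value)
}

# Independent Pearson oracle: raw sum formula, no call to cor().
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Brute-force probe placement: walk the window position by position.
enumerate_placements <- function(window_start, window_end, probe_len, step,
                                 offset = 0L) {
  starts <- integer(0)
  s <- window_start + offset
  while (s + probe_len <= window_end) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

tiny_loci <- function(n = 3L, width = 2000L) {
  make_loci(sprintf("L%d", seq_len(n)), tss = 1000L + (seq_len(n) - 1L) * 4000L,
            window_width = width)
}

# Noise-free config for oracle-equivalence tests.
quiet_cfg <- function(...) {
  sim_config(sigma_channel = 0, sigma_replicate = 0, fuzz_sd = 0, ...)
}
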
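# shared fixture builders; everything is generated in code at test time

# a fixed near-haploid stemline: disomic X, 14, 18, 21 (modal 27)
nh_reference_karyotype <- function(sex = "XX") {
  apply_gains(haploid_baseline(sex), c("X", "14", "18", "21"))
}

# clone with a single explicit state on one chromosome, diploid elsewhere
karyotype_with_state <- function(chrom, n_a, n_b, sex = "XX") {
  k <- diploid_karyotype(sex)
  k$states[k$states$chrom == chrom, c("n_a", "n_b")] <- c(n_a, n_b)
  k
}

# random karyotype with arbitrary nonnegative states, for property tests
random_karyotype <- function(seed, max_copies = 3) {
  withr::with_seed(seed, {
    st <- data.frame(chrom = chromosome_levels(),
                     n_a = sample(0:max_copies, 24, replace = TRUE),
                     n_b = sample(0:max_copies, 24, replace = TRUE),
                     stringsAsFactors = FALSE)
  })
  st[st$chrom == "Y", c("n_a", "n_b")] <- c(0L, 0L)
  hypokaryo:::new_clone_karyotype(st, "XX")
}

# independent binomial pmf for the brute-force origin-classification oracle
brute_force_origin <- function(alt, depth, x, prior = c(1, 1, 1) / 3) {
  log_pmf <- function(k, n, p) {
    if (p == 0) return(if (k == 0) 0 else -Inf)
    if (p == 1) return(if (k == n) 0 else -Inf)
    lchoose(n, k) + k * log(p) + (n - k) * log(1 - p)
  }
  hyps <- origin_hypotheses()
  ll <- vapply(hyps, function(h) log_pmf(alt, depth, predicted_maf(h, x)), 0)
  w <- exp(ll - max(ll)) * prior
  w / sum(w)
}
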
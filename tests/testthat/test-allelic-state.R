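test_that("expected_signal reproduces the mixture algebra", {
  # balanced heterodisomy: BAF 1/2, LRR 0 at any purity
  for (x in c(0, 0.3, 0.8, 1)) {
    es <- expected_signal(1, 1, x)
    expect_equal(es$baf, 0.5, tolerance = 1e-12)
    expect_equal(es$lrr, 0, tolerance = 1e-12)
  }
  # monosomy with the B allele on the lost homologue: (1-x)/(2-x)
  xs <- seq(0, 1, by = 0.05)
  es <- expected_signal(1, 0, 0.8)
  expect_equal(es$baf, (1 - 0.8) / (2 - 0.8), tolerance = 1e-12)
  for (x in xs) {
    expect_equal(expected_signal(1, 0, x)$baf, (1 - x) / (2 - x),
                 tolerance = 1e-12)
  }
  # copy-neutral LOH is invisible in LRR
  es20 <- expected_signal(2, 0, 0.8)
  expect_equal(es20$baf, 0.1, tolerance = 1e-12)
  expect_equal(es20$lrr, 0, tolerance = 1e-12)
  # homologue-swap symmetry: BAFs sum to 1, LRR identical
  for (s in 1:20) {
    st <- withr::with_seed(s, sample(0:4, 2))
    x <- withr::with_seed(s + 100, stats::runif(1))
    if (sum(st) == 0 && x == 1) next
    a <- expected_signal(st[1], st[2], x)
    b <- expected_signal(st[2], st[1], x)
    expect_equal(a$baf + b$baf, 1, tolerance = 1e-12)
    expect_equal(a$lrr, b$lrr, tolerance = 1e-12)
  }
  expect_error(expected_signal(0, 0, 1), "undefined")
})

test_that("noiseless full-purity profiles recover every candidate state", {
  states <- candidate_states(4, include_nullisomy = FALSE)
  for (i in seq_len(nrow(states))) {
    k <- karyotype_with_state("7", states$n_a[i], states$n_b[i])
    prof <- simulate_snp_array(sample_mixture(k, normal_fraction = 0),
                               probes_per_chrom = 80, noise_sd = 0, seed = i)
    call <- call_chromosome(prof, "7", x = 1, min_probes = 50)
    expect_identical(c(call$n_a, call$n_b),
                     c(max(states$n_a[i], states$n_b[i]),
                       min(states$n_a[i], states$n_b[i])),
                     info = sprintf("state (%d,%d)", states$n_a[i], states$n_b[i]))
    expect_false(call$cin_flag)
  }
})

test_that("purity is recovered from hypodiploid profiles", {
  for (x in c(0.6, 0.95)) {
    hits <- vapply(1:15, function(s) {
      k <- make_hypodiploid_karyotype("NH", "XX", seed = s)
      prof <- simulate_snp_array(sample_mixture(k, normal_fraction = 1 - x),
                                 seed = s + 100)
      abs(estimate_purity(prof)$purity - x) <= 0.05
    }, TRUE)
    expect_gte(mean(hits), 0.9)
  }
  # pure-normal profile (x = 0): estimate collapses to the identifiability
  # floor (within the +/-0.05 recovery tolerance; see the methods vignette)
  prof0 <- simulate_snp_array(sample_mixture(diploid_karyotype("XX"),
                                             normal_fraction = 1),
                              seed = 5)
  expect_lte(estimate_purity(prof0)$purity, 0.05)
  expect_error(estimate_purity(prof0[prof0$genotype != "AB", ]), "AB probes")
})

test_that("LOH and copy-neutral LOH are called from the het band", {
  # doubled monosomy at x = 0.9: LOH with LRR ~ 0
  k <- karyotype_with_state("5", 2, 0)
  prof <- simulate_snp_array(sample_mixture(k, normal_fraction = 0.1), seed = 1)
  call <- call_chromosome(prof, "5", x = 0.9)
  expect_true(call$loh)
  expect_identical(c(call$n_a, call$n_b), c(2L, 0L))
  expect_lt(abs(mean(prof$lrr[prof$chrom == "5"])), 0.05)
  # heterodisomy: no LOH, no CIN
  call2 <- call_chromosome(prof, "8", x = 0.9)
  expect_false(call2$loh)
  expect_false(call2$cin_flag)
  expect_identical(c(call2$n_a, call2$n_b), c(1L, 1L))
  # too few probes -> no call
  small <- prof[prof$chrom == "5", ][1:30, ]
  attr(small, "sex") <- "XX"
  expect_false(call_chromosome(small, "5", x = 0.9)$called)
})

test_that("unresolvable cell mixtures raise the instability flag", {
  # 50/50 mix of 1 and 2 copies of chromosome 9: no integer state fits
  k1 <- karyotype_with_state("9", 1, 0)
  k2 <- karyotype_with_state("9", 2, 0)
  m <- sample_mixture(list(k1, k2), weights = c(0.5, 0.5),
                      normal_fraction = 0.1)
  prof <- simulate_snp_array(m, seed = 4)
  call <- call_chromosome(prof, "9", x = 0.9)
  expect_true(call$cin_flag)
  # the clean chromosomes of the same profile stay unflagged
  call_clean <- call_chromosome(prof, "12", x = 0.9)
  expect_false(call_clean$cin_flag)
})

test_that("masked hypodiploidy round-trips through doubling", {
  hits <- founder_hits <- ctrl_hits <- 0
  n_seeds <- 12
  for (s in 1:n_seeds) {
    stem <- make_hypodiploid_karyotype("NH", "XX", seed = s)
    prof <- simulate_snp_array(sample_mixture(double_clone(stem),
                                              normal_fraction = 0.05),
                               seed = s + 300)
    g <- call_genome(prof)
    hits <- hits + isTRUE(g$masked_hypodiploid)
    founder_hits <- founder_hits +
      (isTRUE(g$masked_hypodiploid) &&
         g$inferred_founder_modal == modal_number(stem))
    ctrl <- make_hyperdiploid_karyotype("XX", 8, seed = s)
    gc <- call_genome(simulate_snp_array(sample_mixture(ctrl,
                                                        normal_fraction = 0.05),
                                         seed = s + 600))
    ctrl_hits <- ctrl_hits + !isTRUE(gc$masked_hypodiploid)
  }
  expect_gte(hits, n_seeds - 1)
  expect_gte(founder_hits, n_seeds - 1)
  expect_identical(ctrl_hits, n_seeds)
  # an undoubled hypodiploid is not "masked"
  g_nh <- call_genome(simulate_snp_array(
    sample_mixture(make_hypodiploid_karyotype("NH", "XX", seed = 7),
                   normal_fraction = 0.05), seed = 99))
  expect_false(g_nh$masked_hypodiploid)
  expect_true(is.na(g_nh$inferred_founder_modal))
  # diploid profile: not masked either
  g_dip <- call_genome(simulate_snp_array(
    sample_mixture(diploid_karyotype("XX"), normal_fraction = 0.3), seed = 42))
  expect_false(g_dip$masked_hypodiploid)
})

test_that("cin_summary counts flagged chromosomes", {
  calls <- data.frame(chrom = as.character(1:24), n_a = 1L, n_b = 1L,
                      total = 2L, loh = FALSE, fit_score = 0.001,
                      cin_flag = FALSE, called = TRUE, n_probes = 150L,
                      n_ab = 45L)
  expect_identical(cin_summary(calls), 0)
  calls$cin_flag[3] <- TRUE
  expect_equal(cin_summary(calls), 1 / 24)
  expect_error(cin_summary(calls[calls$called == FALSE, ]), "no called")
})
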
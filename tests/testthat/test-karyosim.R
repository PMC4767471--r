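test_that("hypodiploid generator respects subgroup ranges and retention weights", {
  for (s in 1:20) {
    m_nh <- modal_number(make_hypodiploid_karyotype("NH", "XX", seed = s))
    m_hol <- modal_number(make_hypodiploid_karyotype("HoL", "XY", seed = s))
    m_hoh <- modal_number(make_hypodiploid_karyotype("HoH", "XX", seed = s))
    expect_true(m_nh >= 25 && m_nh <= 30)
    expect_true(m_hol >= 31 && m_hol <= 39)
    expect_true(m_hoh >= 40 && m_hoh <= 44)
  }
  # chromosome 1 disomic in every HoL draw (retention weight 1)
  for (s in 1:10) {
    k <- make_hypodiploid_karyotype("HoL", "XY", seed = s)
    expect_identical(chromosome_totals(k)[["1"]], 2L)
    # non-retained chromosomes are monosomic with LOH
    st <- k$states
    mono <- st$n_a + st$n_b == 1
    expect_true(all(pmin(st$n_a, st$n_b)[mono] == 0))
  }
  # chromosome 21 retained in most NH draws (weight 0.95)
  dis21 <- vapply(1:40, function(s)
    chromosome_totals(make_hypodiploid_karyotype("NH", "XX", seed = s))[["21"]] >= 2,
    TRUE)
  expect_gte(mean(dis21), 0.8)
  expect_error(make_hypodiploid_karyotype("NT", "XX", seed = 1))
})

test_that("doubling doubles the modal number and preserves homozygosity", {
  for (s in 1:25) {
    k <- random_karyotype(seed = s)
    d <- double_clone(k)
    expect_identical(modal_number(d), 2L * modal_number(k))
    expect_identical(d$states$n_a, 2L * k$states$n_a)
    # monosomies become copy-neutral LOH: min stays 0, total becomes 2
    mono <- k$states$n_a + k$states$n_b == 1
    expect_true(all(pmin(d$states$n_a, d$states$n_b)[mono] == 0))
    expect_true(all((d$states$n_a + d$states$n_b)[mono] == 2))
  }
})

test_that("CIN cell population has the predicted deviation rate", {
  k <- double_clone(nh_reference_karyotype())
  # zero rate: single clone identical to the founder
  cells0 <- apply_cin(k, 0, 100, seed = 1)
  expect_length(cells0, 1)
  expect_identical(cells0[[1]]$karyotype$states, k$states)
  expect_equal(cells0[[1]]$fraction, 1)
  # fraction of deviating cells ~ 1 - (1 - r)^n_changeable
  n_present <- sum(chromosome_totals(k) > 0)
  cells <- apply_cin(k, 0.1, 500, seed = 2)
  fr <- vapply(cells, `[[`, 0, "fraction")
  expect_equal(sum(fr), 1)
  same <- vapply(cells, function(cc)
    identical(cc$karyotype$states, k$states), TRUE)
  dev_frac <- 1 - sum(fr[same])
  expected <- 1 - 0.9^n_present
  se <- sqrt(expected * (1 - expected) / 500)
  expect_lt(abs(dev_frac - expected), 4 * se)
  # per-chromosome copy variance > 0 for most chromosomes at rate 0.05
  cells2 <- apply_cin(k, 0.05, 500, seed = 3)
  tot_mat <- vapply(cells2, function(cc) chromosome_totals(cc$karyotype),
                    numeric(24))
  frac2 <- vapply(cells2, `[[`, 0, "fraction")
  v <- apply(tot_mat, 1, function(t) sum(frac2 * (t - sum(frac2 * t))^2))
  expect_gte(mean(v[chromosome_totals(k) > 0] > 0), 0.8)
  expect_error(apply_cin(k, 0.1, 0, seed = 1), "n_cells")
})

test_that("SNP-array signal matches the mixture model", {
  # pure normal: AB probes at 0.5, LRR at 0 on every chromosome
  m0 <- sample_mixture(diploid_karyotype("XX"), normal_fraction = 0)
  prof0 <- simulate_snp_array(m0, noise_sd = 0.03, seed = 1)
  for (ch in unique(prof0$chrom)) {
    sub <- prof0[prof0$chrom == ch, ]
    ab <- sub$baf[sub$genotype == "AB"]
    expect_lt(abs(mean(ab) - 0.5), 4 * 0.03 / sqrt(length(ab)))
    expect_lt(abs(mean(sub$lrr)), 4 * 0.03 / sqrt(nrow(sub)))
  }
  # full-purity monosomy: het band absent, AB probes split to ~0/1
  m1 <- sample_mixture(karyotype_with_state("4", 1, 0), normal_fraction = 0)
  prof1 <- simulate_snp_array(m1, noise_sd = 0.01, seed = 2)
  ab4 <- prof1$baf[prof1$chrom == "4" & prof1$genotype == "AB"]
  expect_equal(mean(ab4 >= 0.25 & ab4 <= 0.75), 0)
  # mixture arithmetic: x = 0.8, state (1,0), B retained -> BAF 5/6
  es <- expected_signal(0, 1, 0.8)
  expect_equal(es$baf, (0.8 + 0.2) / (0.8 + 0.4), tolerance = 1e-12)
  expect_equal(es$baf, 1 / (2 - 0.8), tolerance = 1e-12)
  prof2 <- simulate_snp_array(sample_mixture(karyotype_with_state("4", 1, 0),
                                             normal_fraction = 0.2),
                              noise_sd = 0.02, seed = 3)
  ab <- prof2$baf[prof2$chrom == "4" & prof2$genotype == "AB"]
  upper <- ab[ab > 0.5]  # probes whose B allele sits on the retained homologue
  expect_lt(abs(mean(upper) - 5 / 6), 0.02)
  # reproducibility: same seed, identical output
  expect_identical(simulate_snp_array(m1, seed = 9),
                   simulate_snp_array(m1, seed = 9))
  expect_error(sample_mixture(list()), "empty mixture")
})

test_that("variant read simulator follows the predicted MAF", {
  v1 <- simulate_variant_reads(1, "acquired_monosomic", depth = 50,
                               n_variants = 20, seed = 1)
  expect_true(all(v1$alt_reads == 50))
  v0 <- simulate_variant_reads(0, "constitutional_lost", depth = 100,
                               n_variants = 2000, seed = 2)
  expect_lt(abs(mean(v0$alt_reads / v0$depth) - 0.5),
            3 * sqrt(0.25 / 100) / sqrt(2000))
  # law of large numbers at n = 10,000 against the model expectation
  v <- simulate_variant_reads(0.8, "acquired_monosomic", depth = 200,
                              n_variants = 10000, seed = 3)
  p <- predicted_maf("acquired_monosomic", 0.8)
  se <- sqrt(p * (1 - p) / 200) / sqrt(10000)
  expect_lt(abs(mean(v$alt_reads / v$depth) - p), 3 * se)
  expect_equal(p, 2 / 3, tolerance = 1e-12)
  expect_error(simulate_variant_reads(0.8, "somatic", seed = 1))
})

test_that("diagnosis/relapse pair generator enforces overlap structure", {
  pr <- simulate_dx_relapse_pair("ancestral", 50, 8, 84, seed = 1)
  cmp <- compare_samples(pr$dx, pr$relapse)
  expect_equal(cmp[c("shared", "dx_unique", "rel_unique")],
               list(shared = 50L, dx_unique = 8L, rel_unique = 84L),
               ignore_attr = TRUE)
  idp <- simulate_dx_relapse_pair("identical", 10, seed = 2)
  expect_setequal(idp$dx$alterations, idp$relapse$alterations)
  mj <- simulate_dx_relapse_pair("major", 20, 0, 5, seed = 3)
  expect_true(all(mj$dx$alterations %in% mj$relapse$alterations))
  expect_error(simulate_dx_relapse_pair("major", 20, 3, 5, seed = 4),
               "inconsistent")
  expect_error(simulate_dx_relapse_pair("identical", 10, 0, 1, seed = 5),
               "inconsistent")
})

test_that("expression simulator encodes gene dosage", {
  nh <- nh_reference_karyotype()
  # null: no group differences in expectation
  sim0 <- simulate_expression(list(NH = nh, ctrl = diploid_karyotype("XX")),
                              n_samples = c(30, 30), dosage_exponent = 0,
                              seed = 1)
  g1 <- rowMeans(sim0$counts[, sim0$groups == "NH"])
  g2 <- rowMeans(sim0$counts[, sim0$groups == "ctrl"])
  expect_lt(abs(mean(g1) - mean(g2)), 3)
  # linear dosage: monosomic chromosomes halve, disomic unchanged
  sim1 <- simulate_expression(list(NH = nh, ctrl = diploid_karyotype("XX")),
                              n_samples = c(40, 40), dosage_exponent = 1,
                              seed = 2)
  mono_genes <- sim1$genes$chrom %in% c("3", "4", "5")
  di_genes <- sim1$genes$chrom %in% c("14", "18", "21")
  m_nh <- rowMeans(sim1$counts[, sim1$groups == "NH"])
  m_ct <- rowMeans(sim1$counts[, sim1$groups == "ctrl"])
  expect_equal(mean(m_ct[mono_genes] / m_nh[mono_genes]), 2, tolerance = 0.1)
  expect_equal(mean(m_ct[di_genes] / m_nh[di_genes]), 1, tolerance = 0.1)
})

test_that("methylation simulator stays in [0,1] and responds to copy effect", {
  nh <- nh_reference_karyotype()
  sim <- simulate_methylation(list(NH = nh, ctrl = diploid_karyotype("XX")),
                              n_samples = c(5, 5), copy_effect = 0.5, seed = 1)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  # monosomic chromosomes shifted down in the NH group
  mono_genes <- sim$genes$chrom %in% c("3", "4", "5")
  d <- rowMeans(sim$beta[, sim$groups == "NH"]) -
    rowMeans(sim$beta[, sim$groups == "ctrl"])
  expect_lt(mean(d[mono_genes]), -0.02)
  expect_equal(sim$copy_number["4", 1], 1)
  expect_equal(sim$copy_number["21", 1], 2)
})

test_that("profile and karyotype writers round-trip", {
  k <- nh_reference_karyotype("XY")
  prof <- simulate_snp_array(sample_mixture(k, normal_fraction = 0.2),
                             probes_per_chrom = 60, seed = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_snp_profile(prof, tf)
  back <- read_snp_profile(tf)
  expect_equal(attr(back, "sex"), "XY")
  expect_equal(back$baf, prof$baf, tolerance = 1e-9)
  expect_identical(back$chrom, prof$chrom)
  kf <- withr::local_tempfile(fileext = ".json")
  write_karyotype_json(k, kf)
  expect_identical(read_karyotype_json(kf)$states, k$states)
})
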
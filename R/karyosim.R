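#' Default per-chromosome disomy retention weights
#'
#' Probability that a chromosome is retained in the heterodisomic state when
#' drawing a hypodiploid stemline. Near-haploid clones preferentially retain
#' the sex chromosomes, 14, 18, and 21; low-hypodiploid clones additionally
#' retain 1 (essentially always), 5, 6, 8, 10, 11, and 19. The `"sex"` entry
#' governs the sex-chromosome pair as a unit. Weights are fully overridable
#' via the `weights` argument of [make_hypodiploid_karyotype()].
#'
#' @param subgroup One of `"NH"`, `"HoL"`, `"HoH"`.
#' @return Named numeric vector over the 22 autosomes plus `"sex"`.
#' @export
retention_weights <- function(subgroup = c("NH", "HoL", "HoH")) {
  subgroup <- match.arg(subgroup)
  w <- stats::setNames(rep(0.05, 23), c(as.character(1:22), "sex"))
  w[c("14", "18", "21", "sex")] <- c(0.8, 0.7, 0.95, 0.9)
  if (subgroup %in% c("HoL", "HoH")) {
    w["1"] <- 1.0
    w[c("5", "6", "8", "10", "11", "19")] <- 0.6
  }
  if (subgroup == "HoH") {
    # HoH needs ~17-21 retained chromosomes; lift the background so the
    # rejection sampler lands in 40-44 without distorting the favored set.
    w <- pmax(w, 0.8)
    w["1"] <- 1.0
    w["21"] <- 0.95
  }
  w
}

.subgroup_range <- function(subgroup) {
  switch(subgroup, NH = c(25L, 30L), HoL = c(31L, 39L), HoH = c(40L, 44L),
         stop("unknown subgroup '", subgroup, "'"))
}

#' Draw a random hypodiploid stemline karyotype
#'
#' Retained chromosomes are heterodisomic (1,1); everything else is monosomic
#' with complete loss of heterozygosity, per the relative-to-haploid model of
#' hypodiploid clones. Retention is Bernoulli per chromosome with
#' subgroup-specific weights, and draws are rejected until the modal number
#' falls in the subgroup's range (NH 25-30, HoL 31-39, HoH 40-44). For XY
#' individuals, retaining the sex pair keeps one X and one Y.
#'
#' @param subgroup `"NH"`, `"HoL"`, or `"HoH"`.
#' @param sex `"XX"` or `"XY"`.
#' @param seed Integer seed (mandatory; the generator has no hidden RNG state).
#' @param weights Optional replacement for [retention_weights()].
#' @param max_tries Rejection-sampling cap.
#' @return A `clone_karyotype`.
#' @export
make_hypodiploid_karyotype <- function(subgroup = c("NH", "HoL", "HoH"),
                                       sex = c("XX", "XY"), seed,
                                       weights = NULL, max_tries = 10000L) {
  subgroup <- match.arg(subgroup)
  sex <- match.arg(sex)
  rng <- .subgroup_range(subgroup)
  if (is.null(weights)) weights <- retention_weights(subgroup)
  stopifnot(setequal(names(weights), c(as.character(1:22), "sex")),
            all(weights >= 0), all(weights <= 1))
  result <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(max_tries)) {
      keep <- stats::runif(23) < weights
      names(keep) <- names(weights)
      k <- haploid_baseline(sex)
      st <- k$states
      for (a in as.character(1:22)) if (keep[[a]]) {
        st[st$chrom == a, c("n_a", "n_b")] <- c(1L, 1L)
      }
      if (keep[["sex"]]) {
        if (sex == "XX") st[st$chrom == "X", c("n_a", "n_b")] <- c(1L, 1L)
        else st[st$chrom == "Y", c("n_a", "n_b")] <- c(1L, 0L)
      }
      k <- new_clone_karyotype(st, sex)
      m <- modal_number(k)
      if (m >= rng[1] && m <= rng[2]) {
        result <- k
        break
      }
    }
  })
  if (is.null(result))
    stop("could not draw a karyotype in the ", subgroup,
         " range; check the retention weights")
  result
}

#' Draw a true high-hyperdiploid karyotype (control)
#'
#' Gains are added to a normal diploid as extra copies of already
#' heterodisomic chromosomes (trisomies 2+1), so no chromosome shows loss of
#' heterozygosity. This is the genuine high-hyperdiploid configuration that a
#' doubled hypodiploid clone can be mistaken for; it serves as the negative
#' control for masked-hypodiploidy inference.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param n_gains Number of distinct trisomic chromosomes (default 8, modal 54).
#' @param seed Integer seed.
#' @return A `clone_karyotype`.
#' @export
make_hyperdiploid_karyotype <- function(sex = c("XX", "XY"), n_gains = 8L, seed) {
  sex <- match.arg(sex)
  favored <- c("4", "6", "10", "14", "17", "18", "21", "X")
  pool <- c(as.character(1:22), "X")
  prob <- stats::setNames(rep(1, length(pool)), pool)
  prob[favored] <- 8
  withr::with_seed(seed, {
    gained <- sample(pool, n_gains, prob = prob[pool])
  })
  k <- diploid_karyotype(sex)
  st <- k$states
  for (g in gained) {
    i <- match(g, st$chrom)
    st$n_a[i] <- st$n_a[i] + 1L
  }
  new_clone_karyotype(st, sex)
}

#' Simulate cell-to-cell chromosomal instability
#'
#' Models ongoing whole-chromosome mis-segregation in an unstable clone: each
#' cell independently deviates from the founding karyotype `k` on each
#' chromosome with probability `change_rate`. The direction of deviation
#' (gain or loss of one copy) is drawn once per chromosome per call,
#' reflecting that under clonal selection the deviating cells for a given
#' chromosome expand in a consistent direction; whether an individual cell
#' deviates remains independent across cells and chromosomes. Gains duplicate
#' an existing homologue chosen proportionally to its copy number; losses
#' remove a copy the same way, with the total floored at zero. Chromosomes
#' absent from `k` never change.
#'
#' @param k Founding `clone_karyotype`.
#' @param change_rate Per-cell, per-chromosome deviation probability in [0,1].
#' @param n_cells Number of cells to draw (>= 1).
#' @param seed Integer seed.
#' @return List of `list(karyotype = <clone_karyotype>, fraction = <numeric>)`
#'   over the distinct cell karyotypes; fractions sum to 1.
#' @export
apply_cin <- function(k, change_rate, n_cells, seed) {
  stopifnot(inherits(k, "clone_karyotype"),
            change_rate >= 0, change_rate <= 1)
  if (n_cells < 1) stop("n_cells must be >= 1")
  n_chrom <- nrow(k$states)
  base_a <- k$states$n_a
  base_b <- k$states$n_b
  tot <- base_a + base_b
  withr::with_seed(seed, {
    direction <- sample(c(1L, -1L), n_chrom, replace = TRUE)
    A <- matrix(base_a, n_cells, n_chrom, byrow = TRUE)
    B <- matrix(base_b, n_cells, n_chrom, byrow = TRUE)
    change <- matrix(stats::runif(n_cells * n_chrom) < change_rate,
                     n_cells, n_chrom)
    change[, tot == 0] <- FALSE
    for (j in which(colSums(change) > 0)) {
      cells <- which(change[, j])
      # pick the affected homologue proportionally to its copy number
      on_a <- stats::runif(length(cells)) < base_a[j] / tot[j]
      if (direction[j] == 1L) {
        A[cells[on_a], j] <- A[cells[on_a], j] + 1L
        B[cells[!on_a], j] <- B[cells[!on_a], j] + 1L
      } else {
        A[cells[on_a], j] <- pmax(A[cells[on_a], j] - 1L, 0L)
        B[cells[!on_a], j] <- pmax(B[cells[!on_a], j] - 1L, 0L)
      }
    }
  })
  keys <- apply(cbind(A, B), 1, paste, collapse = ",")
  tab <- table(keys)
  out <- vector("list", length(tab))
  uniq <- match(names(tab), keys)
  for (i in seq_along(uniq)) {
    st <- k$states
    st$n_a <- as.integer(A[uniq[i], ])
    st$n_b <- as.integer(B[uniq[i], ])
    out[[i]] <- list(karyotype = new_clone_karyotype(st, k$sex),
                     fraction = as.numeric(tab[i]) / n_cells)
  }
  out
}

#' Construct a clone/normal sample mixture
#'
#' @param clones A single `clone_karyotype` or a list of them.
#' @param weights Relative weights of the clones among leukemic cells
#'   (recycled, normalized internally).
#' @param normal_fraction Fraction of normal diploid cells in [0,1]; tumor
#'   purity is `1 - normal_fraction`.
#' @return A `sample_mixture` object.
#' @export
sample_mixture <- function(clones, weights = 1, normal_fraction = 0) {
  if (inherits(clones, "clone_karyotype")) clones <- list(clones)
  if (!length(clones)) stop("empty mixture: at least one clone required")
  stopifnot(all(vapply(clones, inherits, TRUE, "clone_karyotype")),
            normal_fraction >= 0, normal_fraction <= 1)
  sexes <- unique(vapply(clones, `[[`, "", "sex"))
  if (length(sexes) != 1L) stop("all clones in a mixture must share sex")
  weights <- rep_len(weights, length(clones))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid clone weights")
  fractions <- weights / sum(weights) * (1 - normal_fraction)
  structure(list(clones = clones, fractions = fractions,
                 normal_fraction = normal_fraction, sex = sexes),
            class = "sample_mixture")
}

#' Mixture from a set of CIN cells
#'
#' Convenience wrapper turning the output of [apply_cin()] into a
#' [sample_mixture()] with a given normal-cell fraction.
#'
#' @param cells Output of [apply_cin()].
#' @param normal_fraction Normal diploid cell fraction.
#' @return A `sample_mixture`.
#' @export
mixture_from_cells <- function(cells, normal_fraction = 0) {
  sample_mixture(lapply(cells, `[[`, "karyotype"),
                 weights = vapply(cells, `[[`, 0, "fraction"),
                 normal_fraction = normal_fraction)
}

#' Tumor purity of a mixture
#'
#' @param m A `sample_mixture`.
#' @return `1 - normal_fraction`.
#' @export
purity <- function(m) {
  stopifnot(inherits(m, "sample_mixture"))
  1 - m$normal_fraction
}

.mixture_mean_copies <- function(m) {
  # clone-fraction-weighted homologue copies per chromosome (fractions sum
  # to the purity x, so these enter the signal formulas directly)
  a <- b <- numeric(24)
  for (i in seq_along(m$clones)) {
    a <- a + m$fractions[i] * m$clones[[i]]$states$n_a
    b <- b + m$fractions[i] * m$clones[[i]]$states$n_b
  }
  data.frame(chrom = chromosome_levels(), a = a, b = b,
             stringsAsFactors = FALSE)
}

.normal_copies <- function(sex) {
  nc <- stats::setNames(rep(2, 24), chromosome_levels())
  if (sex == "XX") nc["Y"] <- 0 else nc[c("X", "Y")] <- 1
  nc
}

#' Simulate a SNP-array profile for a clone/normal mixture
#'
#' Probes are evenly spaced per chromosome. For a germline-heterozygous (AB)
#' probe on a chromosome with clone-weighted homologue copies (a, b) and
#' purity x, the noiseless B-allele frequency is
#' `(sum_c f_c b_c + (1 - x)) / (sum_c f_c (a_c + b_c) + 2 (1 - x))` with the
#' B allele assigned to either germline homologue with probability 1/2, and
#' the log R ratio is `log2` of the same total-copy denominator over the
#' normal reference copy number (2 for autosomes; 1 for X and Y in XY
#' individuals, whose sex chromosomes carry only homozygous probes).
#' Truncated Gaussian noise is added to BAF (clipped to [0,1]) and Gaussian
#' noise to LRR.
#'
#' @param m A `sample_mixture`.
#' @param probes_per_chrom Probes per chromosome (default 150).
#' @param het_fraction Fraction of probes that are germline AB where the
#'   germline is diploid (default 0.3).
#' @param noise_sd Gaussian noise SD for both BAF and LRR (default 0.03).
#' @param seed Integer seed.
#' @return A `snp_array_profile`: data frame with columns `chrom`, `pos`,
#'   `genotype`, `baf`, `lrr`, plus a `sex` attribute.
#' @export
simulate_snp_array <- function(m, probes_per_chrom = 150, het_fraction = 0.3,
                               noise_sd = 0.03, seed) {
  stopifnot(inherits(m, "sample_mixture"),
            probes_per_chrom >= 1, het_fraction > 0, het_fraction < 1,
            noise_sd >= 0)
  mix <- .mixture_mean_copies(m)
  nf <- m$normal_fraction
  norm <- .normal_copies(m$sex)
  lens <- chromosome_lengths()
  out <- vector("list", 24)
  withr::with_seed(seed, {
    for (i in seq_len(24)) {
      chrom <- mix$chrom[i]
      denom <- mix$a[i] + mix$b[i] + nf * norm[[chrom]]
      if (denom <= 0 || norm[[chrom]] == 0) next  # chromosome absent
      pos <- round(seq_len(probes_per_chrom) *
                     lens[[chrom]] / (probes_per_chrom + 1))
      if (norm[[chrom]] == 2) {
        geno <- sample(c("AB", "AA", "BB"), probes_per_chrom, replace = TRUE,
                       prob = c(het_fraction, (1 - het_fraction) / 2,
                                (1 - het_fraction) / 2))
      } else {
        geno <- sample(c("AA", "BB"), probes_per_chrom, replace = TRUE)
      }
      # B-allele copy count contributed by clones and normal cells
      b_on_a <- stats::runif(probes_per_chrom) < 0.5
      b_clone <- ifelse(geno == "AB", ifelse(b_on_a, mix$a[i], mix$b[i]),
                        ifelse(geno == "BB", mix$a[i] + mix$b[i], 0))
      b_norm <- ifelse(geno == "AB", 1,
                       ifelse(geno == "BB", norm[[chrom]], 0)) * nf
      baf <- (b_clone + b_norm) / denom
      lrr <- log2(denom / norm[[chrom]])
      baf_obs <- pmin(pmax(baf + stats::rnorm(probes_per_chrom, 0, noise_sd), 0), 1)
      lrr_obs <- lrr + stats::rnorm(probes_per_chrom, 0, noise_sd)
      out[[i]] <- data.frame(chrom = chrom, pos = pos, genotype = geno,
                             baf = baf_obs, lrr = lrr_obs,
                             stringsAsFactors = FALSE)
    }
  })
  profile <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(profile) <- NULL
  structure(profile, sex = m$sex, class = c("snp_array_profile", "data.frame"))
}

#' Simulate variant read counts under an origin hypothesis
#'
#' Alternate-allele counts are Binomial(depth, p) with p the predicted mutant
#' allele fraction of the hypothesis at purity x (see [predicted_maf()]).
#' The generating hypothesis is recorded as ground truth.
#'
#' @param x Tumor purity in [0,1].
#' @param hypothesis One of [origin_hypotheses()].
#' @param depth Read depth (>= 1).
#' @param n_variants Number of variants to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `chrom`, `alt_reads`, `depth`,
#'   `true_hypothesis`, and the annotation flag columns (all `FALSE`).
#' @export
simulate_variant_reads <- function(x, hypothesis, depth = 200, n_variants = 1000,
                                   seed) {
  stopifnot(x >= 0, x <= 1, depth >= 1, n_variants >= 1)
  hypothesis <- match.arg(hypothesis, origin_hypotheses())
  p <- predicted_maf(hypothesis, x)
  withr::with_seed(seed, {
    alt <- stats::rbinom(n_variants, depth, p)
  })
  data.frame(gene = sprintf("gene%04d", seq_len(n_variants)),
             chrom = "1",
             alt_reads = alt, depth = as.integer(depth),
             true_hypothesis = hypothesis,
             synonymous = FALSE, predicted_neutral = FALSE,
             in_population_db = FALSE, cosmic_somatic_tp53 = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate a diagnosis/relapse alteration-set pair
#'
#' Builds two alteration sets with an exact requested overlap structure:
#' `ancestral` pairs carry alterations unique to both time points (the
#' relapse arose from a clone ancestral to the major diagnostic clone),
#' `major` pairs have relapse-only unique alterations (relapse developed from
#' the major diagnostic clone), and `identical` pairs share everything.
#'
#' @param relationship `"ancestral"`, `"major"`, or `"identical"`.
#' @param n_shared Alterations common to both samples (> 0).
#' @param n_dx_unique Alterations unique to diagnosis.
#' @param n_rel_unique Alterations unique to relapse.
#' @param seed Integer seed (alteration identifiers are shuffled).
#' @param patient Patient label carried by both sets.
#' @return List with `dx` and `relapse` [alteration_set()] objects.
#' @export
simulate_dx_relapse_pair <- function(relationship = c("ancestral", "major", "identical"),
                                     n_shared, n_dx_unique = 0, n_rel_unique = 0,
                                     seed, patient = "case") {
  relationship <- match.arg(relationship)
  stopifnot(n_shared >= 0, n_dx_unique >= 0, n_rel_unique >= 0)
  ok <- switch(relationship,
               ancestral = n_shared > 0 && n_dx_unique > 0 && n_rel_unique > 0,
               major = n_shared > 0 && n_dx_unique == 0 && n_rel_unique > 0,
               identical = n_shared > 0 && n_dx_unique == 0 && n_rel_unique == 0)
  if (!ok)
    stop("counts (shared=", n_shared, ", dx_unique=", n_dx_unique,
         ", rel_unique=", n_rel_unique, ") are inconsistent with a '",
         relationship, "' relationship")
  total <- n_shared + n_dx_unique + n_rel_unique
  ids <- sprintf("alt%05d", seq_len(total))
  withr::with_seed(seed, ids <- sample(ids))
  shared <- ids[seq_len(n_shared)]
  dx_u <- ids[n_shared + seq_len(n_dx_unique)]
  rel_u <- ids[n_shared + n_dx_unique + seq_len(n_rel_unique)]
  list(dx = alteration_set(patient, "diagnosis", c(shared, dx_u)),
       relapse = alteration_set(patient, "relapse", c(shared, rel_u)))
}

.group_setup <- function(karyotypes, n_samples) {
  if (inherits(karyotypes, "clone_karyotype")) karyotypes <- list(karyotypes)
  if (is.null(names(karyotypes)) || any(!nzchar(names(karyotypes))))
    names(karyotypes) <- paste0("group", seq_along(karyotypes))
  n_samples <- rep_len(n_samples, length(karyotypes))
  groups <- factor(rep(names(karyotypes), n_samples),
                   levels = names(karyotypes))
  list(karyotypes = karyotypes, groups = groups)
}

#' Simulate an expression count matrix with gene-dosage effects
#'
#' Counts are negative binomial with mean
#' `baseline_mean * (copy_number / 2) ^ dosage_exponent`, where the copy
#' number is the total copies of the gene's chromosome in the sample group's
#' karyotype. `dosage_exponent = 0` is the no-dosage-effect null;
#' `dosage_exponent = 1` is proportional dosage (a monosomy halves the mean).
#'
#' @param karyotypes Named list of `clone_karyotype`, one per sample group
#'   (use [diploid_karyotype()] for controls).
#' @param n_samples Samples per group (recycled).
#' @param genes_per_chrom Genes per chromosome (default 20).
#' @param baseline_mean Diploid mean count (default 100).
#' @param dispersion Negative-binomial dispersion (> 0; variance
#'   `mu + dispersion * mu^2`).
#' @param dosage_exponent Dosage effect exponent (default 1).
#' @param seed Integer seed.
#' @param chroms Chromosomes to place genes on (default autosomes + X).
#' @return List with `counts` (genes x samples matrix), `genes` (data frame
#'   `gene`, `chrom`) and `groups` (factor per sample).
#' @export
simulate_expression <- function(karyotypes, n_samples, genes_per_chrom = 20,
                                baseline_mean = 100, dispersion = 0.1,
                                dosage_exponent = 1, seed,
                                chroms = c(as.character(1:22), "X")) {
  stopifnot(dispersion > 0, genes_per_chrom >= 1, baseline_mean > 0)
  gs <- .group_setup(karyotypes, n_samples)
  genes <- data.frame(
    gene = sprintf("g_%s_%02d", rep(chroms, each = genes_per_chrom),
                   rep(seq_len(genes_per_chrom), length(chroms))),
    chrom = rep(chroms, each = genes_per_chrom), stringsAsFactors = FALSE)
  cn <- vapply(gs$karyotypes,
               function(k) chromosome_totals(k)[genes$chrom], numeric(nrow(genes)))
  mu <- baseline_mean * (cn / 2)^dosage_exponent  # genes x groups
  mu[cn == 0] <- 0
  n_tot <- length(gs$groups)
  counts <- matrix(0L, nrow(genes), n_tot,
                   dimnames = list(genes$gene,
                                   paste0(as.character(gs$groups), "_",
                                          stats::ave(seq_len(n_tot),
                                                     gs$groups, FUN = seq_along))))
  withr::with_seed(seed, {
    for (j in seq_len(n_tot)) {
      mu_j <- mu[, as.integer(gs$groups[j])]
      counts[, j] <- stats::rnbinom(nrow(genes), mu = mu_j, size = 1 / dispersion)
    }
  })
  list(counts = counts, genes = genes, groups = gs$groups)
}

#' Simulate a methylation beta matrix
#'
#' Per-gene beta values follow a logistic model on the logit scale:
#' `beta = plogis(baseline_g + group_shift * (group index - 1) +
#' copy_effect * (copy_number - 2) + noise)`. `copy_effect = 0` reproduces
#' the no-copy-number-association null; a nonzero `group_shift` induces
#' subtype-specific methylation clustering independent of dosage.
#'
#' @inheritParams simulate_expression
#' @param group_shift Logit-scale shift per group index beyond the first.
#' @param copy_effect Logit-scale shift per copy deviating from 2.
#' @param noise_sd Logit-scale Gaussian noise SD (default 0.3).
#' @param baseline_sd SD of per-gene logit baselines (default 1).
#' @return List with `beta` (genes x samples matrix in [0,1]), `genes`,
#'   `groups`, and `copy_number` (chromosome x sample matrix of true totals).
#' @export
simulate_methylation <- function(karyotypes, n_samples, genes_per_chrom = 20,
                                 group_shift = 0, copy_effect = 0,
                                 noise_sd = 0.3, baseline_sd = 1, seed,
                                 chroms = c(as.character(1:22), "X")) {
  stopifnot(noise_sd >= 0, genes_per_chrom >= 1)
  gs <- .group_setup(karyotypes, n_samples)
  genes <- data.frame(
    gene = sprintf("m_%s_%02d", rep(chroms, each = genes_per_chrom),
                   rep(seq_len(genes_per_chrom), length(chroms))),
    chrom = rep(chroms, each = genes_per_chrom), stringsAsFactors = FALSE)
  cn_group <- vapply(gs$karyotypes,
                     function(k) chromosome_totals(k)[chroms], numeric(length(chroms)))
  rownames(cn_group) <- chroms
  n_tot <- length(gs$groups)
  cn_sample <- cn_group[, as.integer(gs$groups), drop = FALSE]
  colnames(cn_sample) <- paste0(as.character(gs$groups), "_",
                                stats::ave(seq_len(n_tot), gs$groups,
                                           FUN = seq_along))
  withr::with_seed(seed, {
    base <- stats::rnorm(nrow(genes), 0, baseline_sd)
    logit <- matrix(base, nrow(genes), n_tot) +
      matrix(group_shift * (as.integer(gs$groups) - 1), nrow(genes), n_tot,
             byrow = TRUE) +
      copy_effect * (cn_sample[genes$chrom, , drop = FALSE] - 2) +
      matrix(stats::rnorm(nrow(genes) * n_tot, 0, noise_sd), nrow(genes))
  })
  beta <- stats::plogis(logit)
  dimnames(beta) <- list(genes$gene, colnames(cn_sample))
  list(beta = beta, genes = genes, groups = gs$groups, copy_number = cn_sample)
}
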
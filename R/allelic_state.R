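#' Expected SNP-array signal for an allele-specific state in a mixture
#'
#' For a clone with `n_a` + `n_b` homologue copies at purity `x` mixed with
#' normal cells carrying `normal_copies` copies, the expected B-allele
#' frequency of a germline-heterozygous probe with B on homologue b is
#' `(x n_b + (1 - x) normal_copies / 2) / (x (n_a + n_b) + (1 - x)
#' normal_copies)` and the expected log R ratio is `log2` of the denominator
#' over `normal_copies`. With `normal_copies = 2` these reduce to the
#' familiar monosomic-chromosome mutant-allele-fraction expectations:
#' `(1 - x)/(2 - x)` for a variant on the lost homologue and `1/(2 - x)` on
#' the retained one.
#'
#' @param n_a,n_b Homologue copy numbers (>= 0; vectorized).
#' @param x Tumor purity in [0,1].
#' @param normal_copies Copies contributed by a normal cell (2 for autosomes,
#'   1 for X/Y in XY individuals).
#' @return List with components `baf` and `lrr`.
#' @export
expected_signal <- function(n_a, n_b, x, normal_copies = 2) {
  stopifnot(all(n_a >= 0), all(n_b >= 0), x >= 0, x <= 1)
  denom <- x * (n_a + n_b) + (1 - x) * normal_copies
  if (any(denom <= 0))
    stop("total copy number 0 at purity 1: B-allele frequency undefined")
  list(baf = (x * n_b + (1 - x) * normal_copies / 2) / denom,
       lrr = log2(denom / normal_copies))
}

#' Candidate allele-specific states
#'
#' All states (n_a, n_b) with `0 <= n_b <= n_a <= max_copies` (homologue
#' labels are interchangeable, so only the sorted representative is kept).
#'
#' @param max_copies Maximum homologue copies (default 4).
#' @param include_nullisomy Keep the (0,0) state (default `TRUE`).
#' @return Data frame with columns `n_a`, `n_b`.
#' @export
candidate_states <- function(max_copies = 4, include_nullisomy = TRUE) {
  grid <- expand.grid(n_b = 0:max_copies, n_a = 0:max_copies)
  grid <- grid[grid$n_b <= grid$n_a, c("n_a", "n_b")]
  if (!include_nullisomy) grid <- grid[grid$n_a + grid$n_b > 0, ]
  rownames(grid) <- NULL
  grid
}

.profile_chrom_summaries <- function(profile, min_ab_probes) {
  sex <- attr(profile, "sex")
  if (is.null(sex)) sex <- "XX"
  norm <- .normal_copies(sex)
  chroms <- unique(profile$chrom)
  res <- lapply(chroms, function(ch) {
    sub <- profile[profile$chrom == ch, ]
    ab <- sub$baf[sub$genotype == "AB"]
    if (norm[[ch]] != 2 || length(ab) < min_ab_probes) return(NULL)
    data.frame(chrom = ch,
               med_mbaf = stats::median(pmax(ab, 1 - ab)),
               med_lrr = stats::median(sub$lrr),
               noise = stats::mad(sub$lrr), stringsAsFactors = FALSE)
  })
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

#' Estimate tumor purity from a SNP-array profile
#'
#' Grid search over purity values: for each candidate purity, each
#' chromosome's median mirrored heterozygous-probe BAF and median LRR are
#' matched against the nearest integer allele-specific state, and the purity
#' minimizing the total squared deviation is returned. Exact ties go to the
#' smaller purity. Chromosomes without at least `min_ab_probes`
#' germline-heterozygous probes (including male sex chromosomes) are
#' excluded from the fit.
#'
#' @param profile A `snp_array_profile` data frame.
#' @param grid_step Purity grid spacing (default 0.01).
#' @param min_ab_probes Minimum AB probes per contributing chromosome.
#' @param max_copies Candidate-state bound passed to [candidate_states()].
#' @return List with `purity` (the estimate), `score` (its objective value)
#'   and `grid` (data frame of all evaluated purities).
#' @export
estimate_purity <- function(profile, grid_step = 0.01, min_ab_probes = 20,
                            max_copies = 4) {
  summ <- .profile_chrom_summaries(profile, min_ab_probes)
  if (is.null(summ) || !nrow(summ))
    stop("no chromosome with enough germline-AB probes to estimate purity")
  states <- candidate_states(max_copies)
  hi <- pmax(states$n_a, states$n_b)
  tot <- states$n_a + states$n_b
  xs <- seq(0, 1, by = grid_step)
  score <- vapply(xs, function(x) {
    denom <- x * tot + (1 - x) * 2
    ok <- denom > 0
    mbaf <- (x * hi[ok] + (1 - x)) / denom[ok]
    lrr <- log2(denom[ok] / 2)
    s <- 0
    for (i in seq_len(nrow(summ))) {
      # the observed mirrored-BAF median carries a half-normal folding bias
      # of ~0.675 sd when the two allelic bands coincide at 0.5; fold the
      # expectation the same way (noise estimated from the LRR spread)
      mbaf_folded <- 0.5 + sqrt((mbaf - 0.5)^2 + (0.675 * summ$noise[i])^2)
      s <- s + min((summ$med_mbaf[i] - mbaf_folded)^2 +
                     (summ$med_lrr[i] - lrr)^2)
    }
    s
  }, 0)
  best <- which.min(score)  # first minimum = smallest purity on ties
  list(purity = xs[best], score = score[best],
       grid = data.frame(x = xs, score = score))
}

#' Call the allele-specific state of one chromosome
#'
#' Fits every candidate integer state by equal-weighted mean squared
#' deviation of the observed heterozygous-probe BAF (against the nearer of
#' the state's two allelic bands) and of all probes' LRR from the mixture
#' expectations at purity `x`. Whole-chromosome LOH is declared when the
#' heterozygous band is empty: the fraction of germline-AB probes with BAF in
#' [0.25, 0.75] falls below `het_band_floor`. A fit score above
#' `fit_threshold` flags the chromosome as inconsistent with any single
#' integer state — the signature of cell-to-cell copy-number heterogeneity
#' (chromosomal instability) or an unresolved subclone.
#'
#' @param profile A `snp_array_profile`.
#' @param chrom Chromosome label.
#' @param x Tumor purity.
#' @param candidates Data frame of candidate states (default
#'   [candidate_states()]).
#' @param fit_threshold Goodness-of-fit ceiling for a clean call (default
#'   0.003, the null calibration at `noise_sd` 0.03 and 150 probes; see the
#'   methods vignette).
#' @param het_band_floor LOH threshold on the het-band fraction (default 0.05).
#' @param min_probes Minimum probes for a call (default 50).
#' @return One-row data frame: `chrom`, `n_a`, `n_b`, `total`, `loh`,
#'   `fit_score`, `cin_flag`, `called`, `n_probes`, `n_ab`.
#' @export
call_chromosome <- function(profile, chrom, x, candidates = candidate_states(),
                            fit_threshold = 0.003, het_band_floor = 0.05,
                            min_probes = 50) {
  stopifnot(nrow(candidates) >= 1, x >= 0, x <= 1)
  sex <- attr(profile, "sex")
  if (is.null(sex)) sex <- "XX"
  nc <- .normal_copies(sex)[[chrom]]
  sub <- profile[profile$chrom == chrom, ]
  no_call <- data.frame(chrom = chrom, n_a = NA_integer_, n_b = NA_integer_,
                        total = NA_integer_, loh = NA, fit_score = NA_real_,
                        cin_flag = NA, called = FALSE,
                        n_probes = nrow(sub),
                        n_ab = sum(sub$genotype == "AB"),
                        stringsAsFactors = FALSE)
  if (nrow(sub) < min_probes) return(no_call)
  ab <- sub$baf[sub$genotype == "AB"]
  lrr <- sub$lrr
  tot <- candidates$n_a + candidates$n_b
  denom <- x * tot + (1 - x) * nc
  scores <- rep(Inf, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (denom[i] <= 0) next
    lrr_exp <- log2(denom[i] / nc)
    mse <- mean((lrr - lrr_exp)^2)
    if (length(ab) && nc == 2) {
      band_hi <- (x * pmax(candidates$n_a[i], candidates$n_b[i]) + (1 - x)) / denom[i]
      mse <- mse + mean(pmin((ab - band_hi)^2, (ab - (1 - band_hi))^2))
    }
    scores[i] <- mse
  }
  if (all(!is.finite(scores))) return(no_call)
  # parsimony tie-break: best score, then smallest total, then most balanced
  ord <- order(scores, tot, -pmin(candidates$n_a, candidates$n_b))
  best <- ord[1]
  loh <- if (length(ab) >= 1 && nc == 2) {
    mean(ab >= 0.25 & ab <= 0.75) < het_band_floor
  } else NA
  data.frame(chrom = chrom,
             n_a = as.integer(candidates$n_a[best]),
             n_b = as.integer(candidates$n_b[best]),
             total = as.integer(tot[best]),
             loh = loh,
             fit_score = scores[best],
             cin_flag = scores[best] > fit_threshold,
             called = TRUE,
             n_probes = nrow(sub),
             n_ab = length(ab),
             stringsAsFactors = FALSE)
}

#' Genome-wide allele-specific calls, purity and masked-hypodiploidy inference
#'
#' Runs [estimate_purity()] (unless `x` is supplied), [call_chromosome()] on
#' every chromosome in the profile, then [infer_masked_hypodiploidy()] and
#' [cin_summary()].
#'
#' @param profile A `snp_array_profile`.
#' @param x Tumor purity; `NULL` (default) estimates it from the profile.
#' @param ... Passed to [call_chromosome()].
#' @param min_loh_chroms Passed to [infer_masked_hypodiploidy()].
#' @return A `genome_call` list: `calls` (per-chromosome data frame),
#'   `purity`, `purity_estimated`, `masked_hypodiploid`,
#'   `inferred_founder_modal`, `cin_fraction`.
#' @export
call_genome <- function(profile, x = NULL, ..., min_loh_chroms = 8) {
  estimated <- is.null(x)
  if (estimated) x <- estimate_purity(profile)$purity
  chroms <- unique(profile$chrom)
  calls <- do.call(rbind, lapply(chroms, function(ch)
    call_chromosome(profile, ch, x, ...)))
  masked <- infer_masked_hypodiploidy(calls, min_loh_chroms = min_loh_chroms)
  structure(list(calls = calls, purity = x, purity_estimated = estimated,
                 masked_hypodiploid = masked$masked,
                 inferred_founder_modal = masked$founder_modal,
                 cin_fraction = cin_summary(calls)),
            class = "genome_call")
}

#' Infer masked hypodiploidy (a doubled hypodiploid founder)
#'
#' A genome is called masked-hypodiploid when (a) at least `min_loh_chroms`
#' chromosomes show whole-chromosome LOH at total copy number >= 2 — the
#' copy-neutral LOH signature left behind when a monosomy doubles — and
#' (b) every called total is even, or the odd ones carry the
#' chromosomal-instability flag. The founder modal number is the sum of
#' halved totals (rounded for flagged chromosomes), i.e. the pre-doubling
#' chromosome count.
#'
#' @param calls Per-chromosome calls data frame (from [call_genome()]'s
#'   `calls` element), or a `genome_call`.
#' @param min_loh_chroms Minimum copy-neutral-LOH chromosomes (default 8).
#' @return List with `masked` (logical) and `founder_modal` (integer or `NA`).
#' @export
infer_masked_hypodiploidy <- function(calls, min_loh_chroms = 8) {
  if (inherits(calls, "genome_call")) calls <- calls$calls
  ok <- calls[calls$called, ]
  if (nrow(ok) < 20)
    stop("insufficient chromosome calls (", nrow(ok), " < 20)")
  loh_doubled <- !is.na(ok$loh) & ok$loh & ok$total >= 2
  odd <- ok$total %% 2L == 1L
  masked <- sum(loh_doubled) >= min_loh_chroms && all(!odd | ok$cin_flag)
  founder <- NA_integer_
  if (masked) {
    clean <- !ok$cin_flag
    founder <- as.integer(sum(ok$total[clean] / 2) +
                            sum(floor(ok$total[!clean] / 2 + 0.5)))
  }
  list(masked = masked, founder_modal = founder)
}

#' Fraction of chromosomes flagged as unstable
#'
#' @param calls Per-chromosome calls data frame or a `genome_call`.
#' @return Fraction in [0,1] of called chromosomes with `cin_flag`.
#' @export
cin_summary <- function(calls) {
  if (inherits(calls, "genome_call")) calls <- calls$calls
  ok <- calls[calls$called, ]
  if (!nrow(ok)) stop("no called chromosomes")
  mean(ok$cin_flag)
}

#' @export
print.genome_call <- function(x, ...) {
  cat(sprintf("<genome_call> purity %.2f%s, %d chromosomes called\n",
              x$purity, if (x$purity_estimated) " (estimated)" else "",
              sum(x$calls$called)))
  cat(sprintf("  masked hypodiploidy: %s%s\n", x$masked_hypodiploid,
              if (isTRUE(x$masked_hypodiploid))
                sprintf(" (inferred founder modal %d)", x$inferred_founder_modal)
              else ""))
  cat(sprintf("  unstable (CIN-flagged) chromosomes: %.0f%%\n",
              100 * x$cin_fraction))
  invisible(x)
}
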
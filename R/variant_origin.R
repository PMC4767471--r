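#' Origin hypotheses for a variant on a monosomic chromosome
#'
#' In a sample with leukemic-cell fraction x and normal fraction 1 - x, a
#' variant on a chromosome that is monosomic in the clone can be (i) acquired
#' by the clone, (ii) a constitutional heterozygous variant on the homologue
#' the clone lost, or (iii) constitutional on the retained homologue.
#'
#' @return Character vector of the three hypothesis labels.
#' @export
origin_hypotheses <- function() {
  c("acquired_monosomic", "constitutional_lost", "constitutional_retained")
}

#' Predicted mutant allele fraction under an origin hypothesis
#'
#' At purity x the clone contributes x mutant-capable copies of a monosomic
#' chromosome and the normal cells 2(1 - x), so the expected mutant allele
#' fractions are `x / (x + 2(1 - x))` for acquired mutations,
#' `(1 - x) / (x + 2(1 - x))` for constitutional variants on the lost
#' homologue, and `(x + (1 - x)) / (x + 2(1 - x)) = 1 / (2 - x)` on the
#' retained homologue (the clone plus one normal copy carry the variant).
#' The identity acquired + lost = retained holds for every x.
#'
#' @param hypothesis One of [origin_hypotheses()].
#' @param x Tumor purity in [0,1] (vectorized).
#' @return Expected mutant allele fraction(s).
#' @export
predicted_maf <- function(hypothesis, x) {
  hypothesis <- match.arg(hypothesis, origin_hypotheses())
  stopifnot(all(x >= 0), all(x <= 1))
  denom <- x + 2 * (1 - x)
  switch(hypothesis,
         acquired_monosomic = x / denom,
         constitutional_lost = (1 - x) / denom,
         constitutional_retained = (x + (1 - x)) / denom)
}

#' Classify variant origin from read counts
#'
#' Binomial posterior over the three origin hypotheses:
#' `posterior(h) propto prior(h) * Binomial(alt_reads | depth,
#' predicted_maf(h, x))`. At purity near 0.5 the acquired and
#' constitutional-lost expectations coincide (both 1/3), so calls are marked
#' degenerate when `|x - 0.5| < degenerate_eps`. The model assumes the
#' chromosome is monosomic in the clone and diploid in normal cells; other
#' copy states are outside its scope and should be routed through
#' [expected_signal()] rather than silently extending these formulas.
#'
#' @param alt_reads,depth Integer vectors of mutant and total read counts.
#' @param x Tumor purity in [0,1].
#' @param prior Prior over the three hypotheses in the order of
#'   [origin_hypotheses()] (default uniform).
#' @param degenerate_eps Half-width of the degenerate purity window (0.02).
#' @return Data frame with one row per variant: `hypothesis`, the three
#'   posterior columns (`p_acquired`, `p_lost`, `p_retained`), and
#'   `degenerate`.
#' @export
classify_origin <- function(alt_reads, depth, x, prior = c(1, 1, 1) / 3,
                            degenerate_eps = 0.02) {
  if (x < 0 || x > 1) stop("purity x must be in [0,1]")
  stopifnot(length(prior) == 3, all(prior >= 0), sum(prior) > 0,
            all(depth >= 1), all(alt_reads >= 0), all(alt_reads <= depth))
  prior <- prior / sum(prior)
  p_h <- vapply(origin_hypotheses(), predicted_maf, 0, x = x)
  loglik <- vapply(p_h, function(p)
    stats::dbinom(alt_reads, depth, p, log = TRUE), numeric(length(alt_reads)))
  loglik <- matrix(loglik, ncol = 3)
  logpost <- sweep(loglik, 2, log(prior), `+`)
  logpost <- logpost - apply(logpost, 1, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  data.frame(hypothesis = origin_hypotheses()[max.col(post, ties.method = "first")],
             p_acquired = post[, 1], p_lost = post[, 2], p_retained = post[, 3],
             degenerate = abs(x - 0.5) < degenerate_eps,
             stringsAsFactors = FALSE)
}

#' Filter a variant table (exome filtering cascade)
#'
#' Drops records flagged synonymous, predicted neutral, or present in
#' population databases — except TP53 variants reported as somatic in
#' COSMIC, which are always kept regardless of the other flags.
#'
#' @param records Data frame with logical columns `synonymous`,
#'   `predicted_neutral`, `in_population_db`, `cosmic_somatic_tp53`.
#' @return The surviving rows of `records`.
#' @export
filter_variants <- function(records) {
  needed <- c("synonymous", "predicted_neutral", "in_population_db",
              "cosmic_somatic_tp53")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("missing flag columns: ", paste(missing, collapse = ", "))
  if (!nrow(records)) return(records)
  drop <- (records$synonymous | records$predicted_neutral |
             records$in_population_db) & !records$cosmic_somatic_tp53
  records[!drop, , drop = FALSE]
}
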
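#' Chromosome labels used throughout the package
#'
#' The 22 autosomes plus X and Y, in karyotype order.
#'
#' @return Character vector of length 24.
#' @export
chromosome_levels <- function() c(as.character(1:22), "X", "Y")

#' Approximate chromosome lengths (bp)
#'
#' Rounded GRCh37 chromosome lengths, used only to place evenly spaced
#' synthetic SNP-array probes; no inference step depends on real probe maps.
#'
#' @return Named numeric vector (bp) over [chromosome_levels()].
#' @export
chromosome_lengths <- function() {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 102, 90, 81, 78, 59, 63, 48, 51, 155, 59)
  stats::setNames(mb * 1e6, chromosome_levels())
}

new_clone_karyotype <- function(states, sex) {
  stopifnot(is.data.frame(states),
            all(c("chrom", "n_a", "n_b") %in% names(states)))
  if (!identical(as.character(states$chrom), chromosome_levels()))
    stop("states must contain one row per chromosome, in karyotype order")
  if (any(states$n_a < 0) || any(states$n_b < 0))
    stop("homologue copy numbers must be >= 0")
  if (!sex %in% c("XX", "XY")) stop("sex must be 'XX' or 'XY'")
  structure(list(states = states, sex = sex), class = "clone_karyotype")
}

#' Haploid baseline karyotype
#'
#' One copy of each autosome plus one X, which is the reference state of the
#' relative-to-haploid notation used for near-haploid and low-hypodiploid
#' clones: every chromosome not explicitly gained is monosomic with complete
#' loss of heterozygosity. Y is absent until gained explicitly.
#'
#' @param sex Constitutional sex, `"XX"` or `"XY"`.
#' @return A `clone_karyotype`.
#' @export
haploid_baseline <- function(sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  states <- data.frame(chrom = chromosome_levels(),
                       n_a = c(rep(1L, 22), 1L, 0L),
                       n_b = 0L,
                       stringsAsFactors = FALSE)
  new_clone_karyotype(states, sex)
}

#' Normal diploid karyotype
#'
#' @param sex Constitutional sex, `"XX"` or `"XY"`.
#' @return A `clone_karyotype` with every autosome heterodisomic (1,1) and
#'   sex chromosomes per `sex`.
#' @export
diploid_karyotype <- function(sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  states <- data.frame(chrom = chromosome_levels(),
                       n_a = 1L, n_b = 1L, stringsAsFactors = FALSE)
  if (sex == "XX") {
    states[states$chrom == "Y", c("n_a", "n_b")] <- c(0L, 0L)
  } else {
    states[states$chrom == "X", c("n_a", "n_b")] <- c(1L, 0L)
    states[states$chrom == "Y", c("n_a", "n_b")] <- c(1L, 0L)
  }
  new_clone_karyotype(states, sex)
}

#' Apply whole-chromosome gains to a karyotype
#'
#' Gains follow the relative-to-haploid convention: the first gain of a
#' single-copy autosome adds the second (distinct) homologue, producing a
#' heterodisomy (1,1); further gains duplicate an arbitrary homologue
#' (homologue identity of extra copies is not recoverable from the notation).
#' `"X"` gains behave the same for XX individuals; for XY individuals an X
#' gain duplicates the single X, and `"Y"` gains add Y copies. Y gains in an
#' XX individual are rejected.
#'
#' @param k A `clone_karyotype`.
#' @param gains Character vector of chromosome labels, one entry per gain
#'   (repeat a label for repeated gains), e.g. `c("X", "21")`.
#' @return The modified `clone_karyotype`.
#' @export
apply_gains <- function(k, gains) {
  stopifnot(inherits(k, "clone_karyotype"))
  gains <- toupper(as.character(gains))
  bad <- setdiff(gains, chromosome_levels())
  if (length(bad)) stop("unknown chromosome in gains: ", paste(bad, collapse = ", "))
  st <- k$states
  for (g in gains) {
    i <- match(g, st$chrom)
    if (g == "Y") {
      if (k$sex == "XX") stop("cannot gain Y in an XX individual")
      st$n_a[i] <- st$n_a[i] + 1L
    } else if (g == "X" && k$sex == "XY") {
      st$n_a[i] <- st$n_a[i] + 1L
    } else if (st$n_a[i] == 1L && st$n_b[i] == 0L) {
      st$n_b[i] <- 1L  # first gain restores the second homologue
    } else {
      st$n_a[i] <- st$n_a[i] + 1L
    }
  }
  new_clone_karyotype(st, k$sex)
}

#' Modal chromosome number
#'
#' @param k A `clone_karyotype`.
#' @return Integer, the total chromosome count (sum of all homologue copies).
#' @export
modal_number <- function(k) {
  stopifnot(inherits(k, "clone_karyotype"))
  as.integer(sum(k$states$n_a) + sum(k$states$n_b))
}

#' Total copies per chromosome
#'
#' @param k A `clone_karyotype`.
#' @return Named integer vector over [chromosome_levels()].
#' @export
chromosome_totals <- function(k) {
  stopifnot(inherits(k, "clone_karyotype"))
  stats::setNames(as.integer(k$states$n_a + k$states$n_b), k$states$chrom)
}

#' Double a clone (stemline duplication)
#'
#' Every homologue copy number doubles, so the modal number doubles exactly
#' and a pre-doubling monosomy becomes a copy-neutral loss of heterozygosity
#' (2+0): two identical copies, no heterozygous band, log R ratio near zero.
#' This is the "idemx2" clone of hypodiploid karyotype descriptions and the
#' mechanism behind masked hypodiploidy.
#'
#' @param k A `clone_karyotype`.
#' @return The doubled `clone_karyotype`.
#' @export
double_clone <- function(k) {
  stopifnot(inherits(k, "clone_karyotype"))
  st <- k$states
  st$n_a <- 2L * st$n_a
  st$n_b <- 2L * st$n_b
  new_clone_karyotype(st, k$sex)
}

#' Classify the hypodiploid subgroup from a modal number
#'
#' Modal-number ranges: 25-30 near-haploid (NH), 31-39 low hypodiploid (HoL),
#' 40-44 high hypodiploid (HoH), 45 its own category, and 46 or more
#' diploid-or-higher (where doubled clones land). Modal numbers below 25 are
#' outside the catalogue and raise an error.
#'
#' @param modal Integer modal chromosome number (vectorized).
#' @return Character vector of subgroup labels.
#' @export
classify_subgroup <- function(modal) {
  modal <- as.integer(modal)
  if (any(is.na(modal)) || any(modal < 1)) stop("modal must be a positive integer")
  if (any(modal < 25))
    stop("modal number ", paste(modal[modal < 25], collapse = ", "),
         " is below the near-haploid range (25); out of catalogue")
  cut_points <- c(25, 31, 40, 45, 46)
  labels <- c("NH", "HoL", "HoH", "modal45", "diploid-or-higher")
  labels[findInterval(modal, cut_points)]
}

#' @export
print.clone_karyotype <- function(x, ...) {
  tot <- chromosome_totals(x)
  dis <- names(tot)[tot >= 2]
  cat(sprintf("<clone_karyotype> sex %s, modal %d\n", x$sex, modal_number(x)))
  cat("  chromosomes with >= 2 copies:",
      if (length(dis)) paste(dis, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
format.clone_karyotype <- function(x, ...) {
  paste(x$states$n_a, x$states$n_b, sep = "+", collapse = ";")
}
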
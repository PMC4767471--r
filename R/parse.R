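#' Parse a relative-to-haploid karyotype string
#'
#' Parses the compact notation used for near-haploid and low-hypodiploid
#' clones, where copy numbers are given relative to the haploid level: the
#' baseline is 22 single-copy autosomes plus one X, every chromosome not
#' listed as gained is monosomic with complete loss of heterozygosity, gains
#' are written `+<chrom>`, clones are separated by `/`, and a doubled clone
#' is written as its claimed modal number followed by `idemx2`, e.g.
#' `"25, X, +X, +21/50, idemx2"`.
#'
#' A leading numeric token is the claimed modal number and is checked against
#' the computed one; a mismatch is an error reporting both numbers. Strings
#' containing structural ISCN tokens (add/del/der/dic/mar/inc, ranges,
#' losses) are outside this dialect and raise a complex-karyotype error.
#'
#' @param text Karyotype string.
#' @param sex Constitutional sex, `"XX"` or `"XY"`.
#' @return A list with elements `stemline` (a `clone_karyotype`), `doubled`
#'   (a `clone_karyotype` or `NULL`), `modal` (stemline modal number) and
#'   `subgroup` (see [classify_subgroup()]).
#' @export
parse_relative_karyotype <- function(text, sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("karyotype string must be a non-empty character scalar")
  clones <- strsplit(text, "/", fixed = TRUE)[[1]]
  stem <- .parse_clone_tokens(clones[[1]], sex)
  doubled <- NULL
  if (length(clones) >= 2L) {
    if (length(clones) > 2L) stop("complex karyotype: more than two clones")
    doubled <- .parse_doubled_tokens(clones[[2]], stem$karyotype)
  }
  modal <- modal_number(stem$karyotype)
  list(stemline = stem$karyotype,
       doubled = doubled,
       modal = modal,
       subgroup = if (modal >= 25) classify_subgroup(modal) else NA_character_)
}

.tokenize_clone <- function(s) {
  toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty clone description")
  pat <- paste0("add|del|der|dic|mar|inc|ider|idic|\\?|~|-|", "–", "|", "−")
  structural <- grepl(pat, toks, ignore.case = TRUE)
  if (any(structural))
    stop("complex karyotype: structural or range tokens not in the ",
         "relative-to-haploid dialect: ", paste(toks[structural], collapse = ", "))
  toks
}

.parse_clone_tokens <- function(s, sex) {
  toks <- .tokenize_clone(s)
  claimed <- NA_integer_
  if (grepl("^[0-9]+$", toks[[1]])) {
    claimed <- as.integer(toks[[1]])
    toks <- toks[-1]
  }
  gains <- character(0)
  seen_sex <- FALSE
  for (tk in toks) {
    up <- toupper(tk)
    if (up == "X") {
      seen_sex <- TRUE
    } else if (up == "Y") {
      stop("malformed token 'Y': the haploid baseline lists X; ",
           "Y enters only as a gain '+Y'")
    } else if (grepl("^\\+([0-9]+|X|Y)$", up)) {
      chrom <- sub("^\\+", "", up)
      if (!chrom %in% chromosome_levels())
        stop("malformed token '", tk, "': unknown chromosome")
      gains <- c(gains, chrom)
    } else {
      stop("malformed token '", tk, "'")
    }
  }
  k <- apply_gains(haploid_baseline(sex), gains)
  if (!is.na(claimed) && claimed != modal_number(k))
    stop(sprintf("claimed modal number %d does not match computed %d",
                 claimed, modal_number(k)))
  list(karyotype = k, claimed = claimed, seen_sex = seen_sex)
}

.parse_doubled_tokens <- function(s, stemline) {
  toks <- .tokenize_clone(s)
  claimed <- NA_integer_
  if (grepl("^[0-9]+$", toks[[1]])) {
    claimed <- as.integer(toks[[1]])
    toks <- toks[-1]
  }
  if (!identical(toupper(toks), "IDEMX2"))
    stop("complex karyotype: second clone must be '<modal>, idemx2'")
  k <- double_clone(stemline)
  if (!is.na(claimed) && claimed != modal_number(k))
    stop(sprintf("claimed doubled modal number %d does not match computed %d",
                 claimed, modal_number(k)))
  k
}
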
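#' Write / read a SNP-array profile as tab-delimited text
#'
#' Columns: chrom, pos, genotype, baf, lrr. The constitutional sex is stored
#' in a `# sex=XX` header comment so round trips preserve it.
#'
#' @param profile A `snp_array_profile`.
#' @param path Output file.
#' @export
write_snp_profile <- function(profile, path) {
  sex <- attr(profile, "sex")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sex=", if (is.null(sex)) "XX" else sex), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname write_snp_profile
#' @return `read_snp_profile` returns the `snp_array_profile`.
#' @export
read_snp_profile <- function(path) {
  first <- readLines(path, n = 1)
  sex <- if (grepl("^# sex=", first)) sub("^# sex=", "", first) else "XX"
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  structure(df, sex = sex, class = c("snp_array_profile", "data.frame"))
}

#' Write / read a variant table as tab-delimited text
#'
#' @param variants Data frame of variant records.
#' @param path File path.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write / read a karyotype as JSON
#'
#' @param k A `clone_karyotype`.
#' @param path File path.
#' @export
write_karyotype_json <- function(k, path) {
  stopifnot(inherits(k, "clone_karyotype"))
  jsonlite::write_json(list(sex = k$sex, states = k$states), path,
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname write_karyotype_json
#' @export
read_karyotype_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- as.data.frame(obj$states, stringsAsFactors = FALSE)
  st$chrom <- as.character(st$chrom)
  st$n_a <- as.integer(st$n_a)
  st$n_b <- as.integer(st$n_b)
  new_clone_karyotype(st, obj$sex)
}

#' Write a genome call as JSON
#'
#' @param g A `genome_call`.
#' @param path File path.
#' @export
write_genome_call_json <- function(g, path) {
  stopifnot(inherits(g, "genome_call"))
  jsonlite::write_json(
    list(purity = g$purity, purity_estimated = g$purity_estimated,
         masked_hypodiploid = g$masked_hypodiploid,
         inferred_founder_modal = g$inferred_founder_modal,
         cin_fraction = g$cin_fraction, calls = g$calls),
    path, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Write a genes x samples matrix as TSV with a gene column
#'
#' @param mat Numeric matrix with rownames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
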
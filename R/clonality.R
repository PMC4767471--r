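#' Construct an alteration set for one sample
#'
#' Alterations (mutations and copy-number changes) are opaque identifiers
#' compared by exact equality; mutations and imbalances share one identifier
#' space. Subclonal alterations carry a flag and are included in comparisons
#' by default.
#'
#' @param patient Patient label.
#' @param time_point `"diagnosis"` or `"relapse"`.
#' @param alterations Character vector of unique identifiers.
#' @param subclonal Logical vector marking subclonal alterations (recycled).
#' @return An `alteration_set`.
#' @export
alteration_set <- function(patient, time_point = c("diagnosis", "relapse"),
                           alterations = character(0), subclonal = FALSE) {
  time_point <- match.arg(time_point)
  alterations <- as.character(alterations)
  if (anyDuplicated(alterations))
    stop("alteration identifiers must be unique within a sample")
  structure(list(patient = patient, time_point = time_point,
                 alterations = alterations,
                 subclonal = rep_len(as.logical(subclonal),
                                     length(alterations))),
            class = "alteration_set")
}

#' Compare diagnosis and relapse alteration sets
#'
#' @param dx,rel `alteration_set`s from the same patient (enforced).
#' @param include_subclonal Include subclonal alterations (default `TRUE`).
#' @return List with counts `shared`, `dx_unique`, `rel_unique` and the
#'   corresponding identifier vectors.
#' @export
compare_samples <- function(dx, rel, include_subclonal = TRUE) {
  stopifnot(inherits(dx, "alteration_set"), inherits(rel, "alteration_set"))
  if (!identical(dx$patient, rel$patient))
    stop("patient labels differ: '", dx$patient, "' vs '", rel$patient, "'")
  a <- dx$alterations
  b <- rel$alterations
  if (!include_subclonal) {
    a <- a[!dx$subclonal]
    b <- b[!rel$subclonal]
  }
  list(shared = length(intersect(a, b)),
       dx_unique = length(setdiff(a, b)),
       rel_unique = length(setdiff(b, a)),
       shared_ids = intersect(a, b),
       dx_unique_ids = setdiff(a, b),
       rel_unique_ids = setdiff(b, a))
}

#' Classify the genetic relationship of a diagnosis/relapse pair
#'
#' Category logic, applied in order of precedence: no shared alterations is
#' `unrelated`; unique alterations at both time points means the relapse
#' arose from a clone ancestral to the major diagnostic clone
#' (`ancestral_clone`); unique alterations only at relapse is compatible
#' with evolution from the major diagnostic clone (`major_clone`); no unique
#' alterations on either side is `identical`. A relapse that is a strict
#' subset of the diagnosis has no natural category in this scheme and is
#' reported as `backward_subset` rather than forced into one.
#'
#' @param shared,dx_unique,rel_unique Nonnegative counts, or a list with
#'   those elements (e.g. from [compare_samples()]) as the first argument.
#' @return List with the three counts and `label`.
#' @export
classify_relationship <- function(shared, dx_unique = NULL, rel_unique = NULL) {
  if (is.list(shared)) {
    cmp <- shared
    shared <- cmp$shared; dx_unique <- cmp$dx_unique; rel_unique <- cmp$rel_unique
  }
  stopifnot(shared >= 0, dx_unique >= 0, rel_unique >= 0)
  label <- if (shared == 0) "unrelated"
  else if (dx_unique > 0 && rel_unique > 0) "ancestral_clone"
  else if (dx_unique == 0 && rel_unique > 0) "major_clone"
  else if (dx_unique > 0 && rel_unique == 0) "backward_subset"
  else "identical"
  list(shared = shared, dx_unique = dx_unique, rel_unique = rel_unique,
       label = label)
}

#' Mutation-burden difference between relapse and diagnosis
#'
#' @param dx,rel `alteration_set`s.
#' @return Signed integer `|rel| - |dx|`; positive when the relapse harbors
#'   more alterations.
#' @export
mutation_burden_delta <- function(dx, rel) {
  stopifnot(inherits(dx, "alteration_set"), inherits(rel, "alteration_set"))
  length(rel$alterations) - length(dx$alterations)
}
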
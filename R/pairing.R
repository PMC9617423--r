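#' Group paired women into exact-age strata
#'
#' Collects the women appearing in a cohort's pair list into strata of
#' identical integer age, the building block of the age-preserving random
#' re-pairing. Strata are returned in ascending age order; within a
#' stratum, members keep the order in which their pairs appear.
#'
#' @param cohort A [paired_cohort()] (or derived cohort) whose paired women
#'   all have a non-missing integer age.
#' @return A list of strata, each a list with `age` (integer) and
#'   `member_ids` (character vector of female ids).
#' @export
build_strata <- function(cohort) {
  pairs <- cohort$pairs
  if (nrow(pairs) == 0L) return(list())
  part <- cohort$participants
  f_age <- part$age[match(pairs$female_id, part$id)]
  if (anyNA(f_age))
    stop(sprintf("build_strata: missing female age for: %s",
                 paste(pairs$female_id[is.na(f_age)], collapse = ", ")))
  ages <- sort(unique(f_age))
  lapply(ages, function(a) {
    list(age = as.integer(a), member_ids = pairs$female_id[f_age == a])
  })
}

#' Exact-age-matched random re-pairing
#'
#' Builds the permutation null for spousal similarity: within each stratum
#' of women sharing an exact integer age, the women are permuted uniformly
#' at random and reassigned to that stratum's husbands in their original
#' pair order. Every husband therefore receives a partner of exactly his
#' original wife's age — the joint (male age, female age) distribution is
#' preserved — while any couple-specific association beyond age is
#' destroyed. By chance a re-paired couple may coincide with an original
#' spouse pair; such coincidences are kept, not rejected. Women whose age
#' is unique in the cohort necessarily keep their original partner.
#'
#' Strata are processed in ascending age order with a single seeded
#' generator, so identical `(cohort, seed)` always produce the identical
#' re-pairing.
#'
#' @param cohort A [paired_cohort()] with `origin = "spouse"` pairs and
#'   complete female ages.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [paired_cohort()] with the same participants and a new pair
#'   list with `origin = "randomized"`.
#' @examples
#' coh <- generate_cohort(default_config(), seed = 1)
#' rnd <- exact_age_shuffle(coh, seed = 2)
#' table(rnd$pairs$origin)
#' @export
exact_age_shuffle <- function(cohort, seed = NULL) {
  pairs <- cohort$pairs
  if (nrow(pairs) && any(pairs$origin != "spouse"))
    stop("exact_age_shuffle: input pairs must have origin = 'spouse'")
  strata <- build_strata(cohort)
  new_female <- pairs$female_id
  with_seed(seed, {
    for (st in strata) {
      idx <- match(st$member_ids, pairs$female_id)
      k <- length(idx)
      new_female[idx] <- st$member_ids[sample.int(k)]
    }
    new_pairs <- data.frame(male_id = pairs$male_id,
                            female_id = new_female,
                            origin = if (nrow(pairs)) "randomized" else character(0),
                            stringsAsFactors = FALSE)
    out <- cohort
    out$pairs <- new_pairs
    out
  })
}
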
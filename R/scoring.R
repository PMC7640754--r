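# Rubric scoring: system (i) first choice, system (ii) incremental weighted
# score over the first four suggestions.
#
# The weighted score is a sequential update: S1 is the first suggestion's
# target value; each later suggestion k (up to the fourth) raises the running
# score by a fraction f_k of the upward difference between the score it would
# earn as a first choice and the running score.  Downward differences never
# contribute, so a perfect first choice is unimprovable and later noise is
# inert.

#' First-choice score of category sequences
#'
#' @param categories Character vector: the category of the first suggestion of
#'   each record (\code{"no_id"} or \code{NA} for an empty record).
#' @param scheme A \code{\link{weight_scheme}}.
#' @return Numeric rubric points: the target value of the first suggestion at
#'   position 1; 0 for records with no suggestions.
#' @examples
#' first_choice_score(c("species_correct", "misleading", "no_id"))
#' @export
first_choice_score <- function(categories, scheme = weight_scheme()) {
  categories[is.na(categories)] <- "no_id"
  target_value(categories, 1L, scheme)
}

#' Incremental weighted score of one category sequence
#'
#' Applies the sequential update over up to four ranked suggestions: with
#' target values \eqn{v_k} at positions \eqn{k} and fractions
#' \eqn{f = (0.50, 0.25, 0.13)},
#' \deqn{S_1 = v_1, \quad S_k = S_{k-1} + f_k \max(0, v_k - S_{k-1}).}
#' Suggestions beyond position 4 are ignored; an empty sequence scores 0.
#'
#' @param categories Character vector of category labels in rank order
#'   (possibly empty).
#' @param scheme A \code{\link{weight_scheme}}.
#' @return A single numeric rubric score.
#' @examples
#' weighted_score(c("unknown", "species_correct"))          # 50
#' weighted_score(c("misleading", "species_correct"))       # 47.5
#' weighted_score(c("family_correct", "species_correct"))   # 75
#' @export
weighted_score <- function(categories, scheme = weight_scheme()) {
  categories <- categories[!is.na(categories)]
  if (!length(categories)) return(0)
  k <- min(length(categories), 4L)
  v <- target_value(categories[seq_len(k)], seq_len(k), scheme)
  s <- v[1L]
  if (k > 1L)
    for (i in 2L:k)
      s <- s + scheme$increment_fractions[i - 1L] * max(0, v[i] - s)
  s
}

#' Score every identification record
#'
#' Computes, for each (tool, sample, replicate) attempt, its first-choice
#' score, its weighted score over the first four suggestions, the category
#' and name of its first suggestion, and whether it returned any
#' identification at all.
#'
#' @param records A \code{"taxid_records"} data frame
#'   (see \code{\link{as_records}}).
#' @param scheme A \code{\link{weight_scheme}}.
#' @return Data frame with one row per record: \code{tool}, \code{sample},
#'   \code{replicate}, \code{first_category}, \code{first_name},
#'   \code{no_id}, \code{first_choice}, \code{weighted}.
#' @export
score_records <- function(records, scheme = weight_scheme()) {
  records <- as_records(records)
  key <- paste(records$tool, records$sample, records$replicate, sep = "\r")
  ids <- !duplicated(key)
  rec <- data.frame(tool = records$tool[ids],
                    sample = records$sample[ids],
                    replicate = records$replicate[ids],
                    stringsAsFactors = FALSE)
  idx <- match(key, key[ids])

  # target-value matrix: one row per record, columns = positions 1..4
  n <- nrow(rec)
  tv <- matrix(NA_real_, n, 4L)
  nm <- matrix(NA_character_, n, 1L)
  use <- records$position >= 1L & records$position <= 4L
  tv[cbind(idx[use], records$position[use])] <-
    target_value(records$category[use], records$position[use], scheme)
  first <- records$position == 1L
  first_cat <- rep("no_id", n)
  first_cat[idx[first]] <- records$category[first]
  first_name <- rep("", n)
  first_name[idx[first]] <- records$suggested_name[first]

  s <- tv[, 1L]
  s[is.na(s)] <- 0          # empty record scores 0
  fc <- s
  for (k in 2L:4L) {
    up <- pmax(0, tv[, k] - s)
    up[is.na(up)] <- 0
    s <- s + scheme$increment_fractions[k - 1L] * up
  }

  rec$first_category <- first_cat
  rec$first_name <- first_name
  rec$no_id <- first_cat == "no_id"
  rec$first_choice <- fc
  rec$weighted <- s
  rec
}
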
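# Replicate consistency: scoring system (iii).
#
# Inconsistency I counts, across the replicate identifications of one sample
# by one tool, the number of distinct families named by the first suggestion
# of each replicate -- every "irrelevant" replicate (unknown, misleading,
# no-id, or an unresolvable name) counting as its own singleton family -- and
# adds 0.2 for each additional distinct genus+species combination within a
# family.  Consistency is C = R - I; with the study design of R = 5
# replicates, I lies in [1, 5] and C in [0, 4].

#' Inconsistency over the replicates of one tool-sample pair
#'
#' @param family Character vector, one entry per replicate: the family of the
#'   replicate's first suggestion, or \code{NA} for an irrelevant replicate
#'   (misleading / unknown / no identification).
#' @param genus,species Character vectors parallel to \code{family}: the
#'   genus and species binomial of the first suggestion (ignored for
#'   irrelevant entries).
#' @return The inconsistency \code{I}: distinct-family count (irrelevant
#'   entries each counting once) plus 0.2 per extra distinct genus+species
#'   combination within a family.
#' @examples
#' inconsistency(rep("Fagaceae", 5), rep("Quercus", 5),
#'               rep("Quercus robur", 5))            # 1
#' inconsistency(paste0("F", 1:5), paste0("G", 1:5),
#'               paste0("G", 1:5, " x"))             # 5
#' @export
inconsistency <- function(family, genus = family, species = family) {
  r <- length(family)
  if (r == 0L) stop("no replicates supplied", call. = FALSE)
  stopifnot(length(genus) == r, length(species) == r)
  irrelevant <- is.na(family)
  fams <- family[!irrelevant]
  i <- length(unique(fams)) + sum(irrelevant)
  extra <- 0L
  for (f in unique(fams)) {
    in_f <- !irrelevant & family == f
    combos <- unique(paste(genus[in_f], species[in_f], sep = "\r"))
    extra <- extra + (length(combos) - 1L)
  }
  i + 0.2 * extra
}

#' Consistency score from an inconsistency value
#'
#' \code{C = R - I}; the study design of \code{R = 5} replicates gives the
#' published 0-4 scale.
#'
#' @param I Inconsistency value(s) from \code{\link{inconsistency}}.
#' @param R Number of replicates (default 5).
#' @param normalized If \code{TRUE}, return \code{C / (R - 1)} for
#'   comparison across designs with different replicate numbers.
#' @return Numeric consistency score(s).
#' @export
consistency_score <- function(I, R = 5L, normalized = FALSE) {
  if (any(I < 1)) stop("inconsistency must be >= 1", call. = FALSE)
  C <- R - I
  if (normalized) C / (R - 1) else C
}

#' Per tool-sample consistency table
#'
#' Derives, for every (tool, sample) pair, the inconsistency \code{I} and
#' consistency \code{C} over its replicates.  The "identified" taxon of a
#' replicate is its first suggestion; replicates whose first suggestion is
#' \code{unknown}, \code{misleading} or \code{no_id}, or whose name cannot be
#' resolved in the taxonomy, are counted as irrelevant singleton families.  A
#' \code{similar_family} (or any other taxon-bearing) suggestion contributes
#' the family its name resolves to.
#'
#' @param records A \code{"taxid_records"} data frame.
#' @param taxonomy Taxonomy data frame used to resolve suggested names.
#' @param n_replicates Expected replicates per (tool, sample); pairs with
#'   fewer are still scored (over the replicates present) but flagged.
#' @return Data frame with columns \code{tool}, \code{sample},
#'   \code{n_replicates}, \code{inconsistency_I}, \code{consistency_C},
#'   \code{complete}.
#' @export
consistency_table <- function(records, taxonomy, n_replicates = 5L) {
  scored <- score_records(records)
  res <- resolve_names(scored$first_name, taxonomy)
  fam <- res$family
  gen <- res$genus
  irrelevant <- scored$first_category %in% .IRRELEVANT_CATEGORIES |
    is.na(fam)
  fam[irrelevant] <- NA_character_

  key <- paste(scored$tool, scored$sample, sep = "\r")
  groups <- split(seq_len(nrow(scored)), key)
  out <- data.frame(
    tool = vapply(groups, function(i) scored$tool[i[1L]], character(1)),
    sample = vapply(groups, function(i) scored$sample[i[1L]], character(1)),
    n_replicates = lengths(groups),
    inconsistency_I = vapply(groups, function(i)
      inconsistency(fam[i], gen[i], scored$first_name[i]), numeric(1)),
    stringsAsFactors = FALSE)
  out$consistency_C <- consistency_score(out$inconsistency_I,
                                         R = out$n_replicates)
  out$complete <- out$n_replicates == n_replicates
  out <- out[order(out$tool, out$sample), ]
  rownames(out) <- NULL
  out
}
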
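# Match-category vocabulary and rubric point values.
#
# The vocabulary is closed: every suggestion carries exactly one of these
# labels, either computed objectively from the taxonomy (classify_exact) or
# supplied as an expert annotation for the subjective categories.

.CATEGORY_VALUES <- c(
  species_correct = 100,
  very_close      = 95,
  small_genus     = 90,
  genus_correct   = 80,
  similar_genus   = 70,
  family_correct  = 50,
  similar_family  = 40,
  good_try        = 15,   # printed range 10-20; midpoint default, see scheme
  unknown         = 0,
  misleading      = -5,   # position-dependent: -5 / -4 / -2, see target_value
  no_id           = 0
)

# Categories whose suggestion, taken at face value, names the wrong family
# (or no usable taxon at all).  similar_family is deliberately excluded: it
# scores in the "similar" band and is not counted as wrong.
.WRONG_CATEGORIES <- c("good_try", "unknown", "misleading")

# Categories treated as "irrelevant" when counting distinct families across
# replicates: they carry no credible family assignment.
.IRRELEVANT_CATEGORIES <- c("unknown", "misleading", "no_id")

#' Match categories of the identification rubric
#'
#' The closed vocabulary of taxonomic-match outcomes.  Objective categories
#' (\code{species_correct}, \code{genus_correct}, \code{family_correct},
#' \code{unknown}, \code{no_id}) can be derived from a reference taxonomy via
#' \code{\link{classify_exact}}; the remaining categories encode expert
#' judgements ("very close", "similar genus", "good try", "misleading") and
#' must be supplied as annotations in the input data.
#'
#' @return Character vector of the eleven category labels.
#' @seealso \code{\link{rubric_values}}, \code{\link{target_value}}
#' @export
match_categories <- function() names(.CATEGORY_VALUES)

#' Base rubric point values
#'
#' Position-independent base values of each match category, from 100 (correct
#' to species) down to -5 (totally misleading at first choice).  The
#' position-dependent values of \code{misleading} and a configurable
#' \code{good_try} value are handled by \code{\link{target_value}} through a
#' \code{\link{weight_scheme}}.
#'
#' @return Named numeric vector of rubric points.
#' @export
rubric_values <- function() .CATEGORY_VALUES

#' Weighting scheme for the incremental weighted score
#'
#' Bundles the tunable constants of the scoring rubric: the increment
#' fractions applied to the second, third and fourth suggestions (50, 25 and
#' 13 per cent of the upward difference, exactly as printed -- the fourth is
#' 0.13, not 0.125), the position-dependent penalty for a totally misleading
#' suggestion (-5/-4/-2 at positions 1/2/3, carried as -2 beyond), and the
#' value awarded to a "good try" (printed as a 10-20 range; midpoint 15 by
#' default).
#'
#' @param increment_fractions Numeric length-3 vector of fractions for
#'   positions 2-4; must be strictly decreasing and inside (0, 1).
#' @param misleading_values Numeric length-3 vector of rubric points for a
#'   misleading suggestion at positions 1-3.
#' @param good_try Rubric points for the \code{good_try} category, in
#'   \code{[10, 20]}.
#' @return An object of class \code{"weight_scheme"}.
#' @examples
#' weight_scheme()
#' weight_scheme(good_try = 20)
#' @export
weight_scheme <- function(increment_fractions = c(0.50, 0.25, 0.13),
                          misleading_values = c(-5, -4, -2),
                          good_try = 15) {
  stopifnot(length(increment_fractions) == 3,
            all(diff(increment_fractions) < 0),
            all(increment_fractions > 0 & increment_fractions < 1),
            length(misleading_values) == 3)
  if (good_try < 10 || good_try > 20)
    stop("'good_try' must lie in [10, 20] (printed range of the rubric)")
  structure(list(increment_fractions = increment_fractions,
                 misleading_values = misleading_values,
                 good_try = good_try),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Rubric weight scheme\n")
  cat("  increment fractions (pos 2-4):",
      paste(format(x$increment_fractions), collapse = ", "), "\n")
  cat("  misleading values  (pos 1-3):",
      paste(format(x$misleading_values), collapse = ", "), "\n")
  cat("  good_try value:", x$good_try, "\n")
  invisible(x)
}

#' Rubric target value of a category at a given position
#'
#' The point value a suggestion "would score if it were the first choice".
#' For all categories except \code{misleading} the value is independent of
#' position; \code{misleading} scores -5, -4 or -2 at positions 1, 2 and 3
#' (and -2 beyond position 3).
#'
#' @param category Character vector of category labels.
#' @param position Integer vector of suggestion positions (>= 1); recycled
#'   against \code{category}.
#' @param scheme A \code{\link{weight_scheme}}.
#' @return Numeric vector of rubric points.
#' @examples
#' target_value("genus_correct", 1)   # 80
#' target_value("misleading", 2)      # -4
#' target_value("species_correct", 3) # 100
#' @export
target_value <- function(category, position = 1L, scheme = weight_scheme()) {
  category <- validate_categories(category)
  n <- max(length(category), length(position))
  category <- rep_len(category, n)
  position <- rep_len(as.integer(position), n)
  if (any(position < 1L)) stop("'position' must be >= 1")
  v <- unname(.CATEGORY_VALUES[category])
  v[category == "good_try"] <- scheme$good_try
  mis <- category == "misleading"
  v[mis] <- scheme$misleading_values[pmin(position[mis], 3L)]
  v
}

# Case-insensitive parse of category labels; anything outside the closed
# vocabulary is an error, never silently mapped.
validate_categories <- function(x, context = NULL) {
  x <- as.character(x)
  lx <- tolower(x)
  bad <- !(lx %in% names(.CATEGORY_VALUES))
  if (any(bad)) {
    where <- if (is.null(context)) which(bad) else context[bad]
    stop(sprintf("unknown match category %s (row %s)",
                 paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(utils::head(where, 5L), collapse = ", ")),
         call. = FALSE)
  }
  lx
}
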
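# Independent oracles and small fixture builders, written as direct
# transcriptions of the scoring rules -- deliberately scalar and naive, and
# kept separate from the package's vectorised implementations.

# Literal transcription of the incremental weighted-score rule: score the
# first choice from the rubric column, then let each of the next three
# suggestions close a fixed fraction of any upward gap to its own
# first-choice value.  Misleading is worth -5/-4/-2 at positions 1/2/3
# (and -2 after).
oracle_weighted <- function(cats, good_try = 15) {
  base <- c(species_correct = 100, very_close = 95, small_genus = 90,
            genus_correct = 80, similar_genus = 70, family_correct = 50,
            similar_family = 40, good_try = good_try, unknown = 0,
            misleading = -5, no_id = 0)
  mis <- c(-5, -4, -2)
  frac <- c(NA, 0.50, 0.25, 0.13)
  if (length(cats) == 0) return(0)
  s <- 0
  for (k in seq_along(cats)) {
    if (k > 4) break
    v <- if (cats[k] == "misleading") mis[min(k, 3)] else base[[cats[k]]]
    if (k == 1) s <- v
    else if (v > s) s <- s + frac[k] * (v - s)
  }
  s
}

# Independent Pearson chi-square for a 2x2 of (successes, failures) per
# group, via the classic observed-vs-expected sum (no continuity
# correction).
oracle_pearson_2x2 <- function(a, n1, b, n2) {
  obs <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - exp)^2 / exp)
}

# Build a records data frame from a list of category runs, one element per
# replicate; "no_id" or an empty vector encodes a no-identification attempt.
# Names are left empty unless supplied.
make_records <- function(runs, tool = "toolA", sample = "S1",
                         names = NULL) {
  rows <- list()
  for (r in seq_along(runs)) {
    cats <- runs[[r]]
    if (length(cats) == 0 || identical(cats, "no_id")) {
      rows[[r]] <- data.frame(tool = tool, sample = sample, replicate = r,
                              position = 0L, suggested_name = "",
                              category = "no_id",
                              stringsAsFactors = FALSE)
    } else {
      nm <- if (is.null(names)) rep("", length(cats)) else names[[r]]
      rows[[r]] <- data.frame(tool = tool, sample = sample, replicate = r,
                              position = seq_along(cats),
                              suggested_name = nm, category = cats,
                              stringsAsFactors = FALSE)
    }
  }
  as_records(do.call(rbind, rows))
}

# Tiny three-family taxonomy used across the IO and consistency tests.
tiny_taxonomy <- function() {
  as_taxonomy(data.frame(
    species = c("Quercus robur", "Quercus cerris", "Fagus sylvatica",
                "Bellis perennis", "Leucanthemum vulgare",
                "Poa annua", "Poa trivialis"),
    genus = c("Quercus", "Quercus", "Fagus", "Bellis", "Leucanthemum",
              "Poa", "Poa"),
    family = c("Fagaceae", "Fagaceae", "Fagaceae", "Asteraceae",
               "Asteraceae", "Poaceae", "Poaceae"),
    stringsAsFactors = FALSE))
}

extdata <- function(file) {
  system.file("extdata", file, package = "taxideval", mustWork = TRUE)
}
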
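# Seeded synthetic-data generator.
#
# Emulates the study design -- a panel of identification tools, each run
# several times on each of a set of reference samples -- with a per-tool
# multinomial distribution over first-choice outcome categories and a single
# replicate-dependence parameter rho: each replicate repeats the previous
# replicate's suggestion run verbatim with probability rho, otherwise
# redraws independently.  Per-(tool, sample) random substreams are derived
# from the root seed by counter, so adding a tool or sample never perturbs
# the records already generated for others.

#' Tool outcome profile
#'
#' @param tool_id Tool identifier.
#' @param category_probabilities Named numeric vector over (a subset of) the
#'   category vocabulary (\code{\link{match_categories}}), summing to 1: the
#'   multinomial law of the first-choice outcome.  \code{no_id} probability
#'   is the chance of an attempt with no suggestions.
#' @param n_suggestions_law Numeric vector of probabilities for a record
#'   holding 1, 2, 3 or 4 suggestions (given at least one); filler
#'   suggestions after the first are unrelated taxa annotated
#'   \code{unknown}.
#' @param rho Replicate-dependence in \code{[0, 1]}: probability that a
#'   replicate repeats the previous replicate verbatim rather than
#'   redrawing.  \code{rho = 1} makes all replicates of a sample identical;
#'   \code{rho = 0} makes them i.i.d.
#' @return Object of class \code{"tool_profile"}.
#' @export
tool_profile <- function(tool_id, category_probabilities,
                         n_suggestions_law = c(0.4, 0.3, 0.2, 0.1),
                         rho = 0.5) {
  p <- category_probabilities
  if (is.null(names(p)) || !all(names(p) %in% match_categories()))
    stop("category_probabilities must be named with category labels",
         call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("category probabilities must be >= 0 and sum to 1", call. = FALSE)
  if (length(n_suggestions_law) != 4L || any(n_suggestions_law < 0) ||
      abs(sum(n_suggestions_law) - 1) > 1e-9)
    stop("n_suggestions_law must be 4 probabilities summing to 1",
         call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  full <- stats::setNames(numeric(length(match_categories())),
                          match_categories())
  full[names(p)] <- p
  structure(list(tool_id = as.character(tool_id),
                 category_probabilities = full,
                 n_suggestions_law = n_suggestions_law,
                 rho = rho),
            class = "tool_profile")
}

#' Default panel of nine tool profiles
#'
#' A panel spanning the performance range observed across real plant
#' identification apps: first-choice species accuracy from under 5 per cent
#' to near 60 per cent, misleading rates from a few per cent to over half,
#' and replicate dependence increasing with accuracy.  Tool ids are
#' \code{tool1} (strongest) to \code{tool9} (weakest).
#'
#' @return Named list of nine \code{\link{tool_profile}} objects.
#' @export
default_tool_profiles <- function() {
  # rows: species_correct, very_close, small_genus, genus_correct,
  #       similar_genus, family_correct, similar_family, good_try,
  #       unknown, misleading, no_id
  p <- rbind(
    tool1 = c(.57, .04, .04, .05, .02, .01, .02, .04, .13, .03, .05),
    tool2 = c(.46, .03, .03, .04, .03, .05, .03, .04, .12, .07, .10),
    tool3 = c(.45, .04, .03, .04, .06, .09, .04, .05, .09, .08, .03),
    tool4 = c(.35, .08, .05, .07, .05, .08, .04, .03, .05, .04, .16),
    tool5 = c(.39, .04, .03, .03, .03, .03, .05, .10, .15, .11, .04),
    tool6 = c(.24, .05, .04, .05, .04, .05, .05, .06, .08, .32, .02),
    tool7 = c(.01, .06, .05, .06, .08, .09, .06, .10, .19, .25, .05),
    tool8 = c(.03, .05, .04, .05, .03, .03, .04, .06, .07, .57, .03),
    tool9 = c(.01, .02, .02, .03, .06, .10, .05, .09, .17, .40, .05))
  colnames(p) <- match_categories()
  rho <- c(.60, .55, .50, .55, .40, .35, .30, .25, .30)
  lapply(stats::setNames(rownames(p), rownames(p)), function(t)
    tool_profile(t, p[t, ], rho = rho[match(t, rownames(p))]))
}

#' Simulation configuration
#'
#' @param n_families,genera_per_family,species_per_genus Taxonomy sizes
#'   (all >= 1; \code{species_per_genus >= 2} and
#'   \code{genera_per_family >= 2} are needed for genus- and family-level
#'   sibling suggestions).
#' @param n_samples Number of reference samples (drawn without replacement
#'   from the species pool).
#' @param n_replicates Replicates per tool-sample pair (default 5, the
#'   study design).
#' @param part_counts,type_counts Named integer vectors partitioning the
#'   samples by plant part and plant type; must each sum to
#'   \code{n_samples}.  Defaults mirror the study's 38-sample composition.
#' @param seed Root seed fixing the full output stream.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_families = 20L, genera_per_family = 3L,
                       species_per_genus = 3L, n_samples = 38L,
                       n_replicates = 5L,
                       part_counts = NULL, type_counts = NULL,
                       seed = 1L) {
  stopifnot(n_families >= 1, genera_per_family >= 2, species_per_genus >= 2,
            n_samples >= 1, n_replicates >= 1)
  n_species <- n_families * genera_per_family * species_per_genus
  if (n_samples > n_species)
    stop("n_samples (", n_samples, ") exceeds number of species (",
         n_species, ") and sampling is without replacement", call. = FALSE)
  if (is.null(part_counts))
    part_counts <- allocate_counts(c(flower = 12, fruit = 3, leaf = 10,
                                     plant = 13), n_samples)
  if (is.null(type_counts))
    type_counts <- allocate_counts(c(herb = 24, monocot = 7, woody = 7),
                                   n_samples)
  if (sum(part_counts) != n_samples || sum(type_counts) != n_samples)
    stop("part_counts and type_counts must each sum to n_samples",
         call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 n_samples = as.integer(n_samples),
                 n_replicates = as.integer(n_replicates),
                 part_counts = part_counts, type_counts = type_counts,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder allocation of reference proportions to a new total
allocate_counts <- function(ref, total) {
  q <- ref / sum(ref) * total
  base <- floor(q)
  short <- total - sum(base)
  if (short > 0) {
    add <- order(q - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(ref))
}

# deterministic substream seed per (tool index, sample index); kept below
# 2^31 - 1.  Constants are arbitrary large coprimes.
substream_seed <- function(seed, tool_idx, sample_idx) {
  as.integer((abs(seed) * 48271 + tool_idx * 962087 + sample_idx * 69621 +
                tool_idx * sample_idx * 101) %% 2147483629)
}

#' Generate a synthetic taxonomy
#'
#' A balanced taxonomy of \code{n_families x genera_per_family x
#' species_per_genus} synthetic binomials (\code{"Genus007 sp2"} style),
#' deterministic given the configuration (no randomness involved).
#'
#' @param config A \code{\link{sim_config}}.
#' @return Taxonomy data frame with columns \code{species}, \code{genus},
#'   \code{family}.
#' @export
generate_taxonomy <- function(config) {
  fam <- sprintf("Family%02d", seq_len(config$n_families))
  g_per_f <- config$genera_per_family
  s_per_g <- config$species_per_genus
  genus <- sprintf("Genus%03d", seq_len(config$n_families * g_per_f))
  df <- data.frame(
    family = rep(fam, each = g_per_f * s_per_g),
    genus = rep(genus, each = s_per_g),
    stringsAsFactors = FALSE)
  df$species <- paste0(df$genus, " sp", rep(seq_len(s_per_g),
                                            times = length(genus)))
  as_taxonomy(df[c("species", "genus", "family")])
}

#' Generate synthetic sample metadata
#'
#' Draws \code{n_samples} reference species without replacement and assigns
#' plant part and plant type labels with the configured subset counts,
#' shuffled under the seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @param taxonomy Output of \code{\link{generate_taxonomy}}.
#' @return Metadata data frame (see \code{\link{read_sample_metadata}}).
#' @export
generate_samples <- function(config, taxonomy = generate_taxonomy(config)) {
  set.seed(substream_seed(config$seed, 0L, 0L))
  species <- sample(taxonomy$species, config$n_samples)
  data.frame(
    sample = sprintf("S%02d", seq_len(config$n_samples)),
    species = species,
    plant_part = sample(rep(names(config$part_counts), config$part_counts)),
    plant_type = sample(rep(names(config$type_counts), config$type_counts)),
    stringsAsFactors = FALSE)
}

# Draw the first suggestion's name for an outcome category, relative to the
# reference species.  Objective categories are exact by construction; the
# subjective categories are generated directly as annotations with a
# plausible carrier taxon (a congener, confamilial or unrelated species).
draw_name <- function(category, ref_species, taxonomy) {
  i <- match(ref_species, taxonomy$species)
  ref_genus <- taxonomy$genus[i]
  ref_family <- taxonomy$family[i]
  pick <- function(pool) if (length(pool)) pool[sample.int(length(pool), 1L)]
  else ref_species
  switch(category,
    species_correct = ,
    very_close = ref_species,
    small_genus = ,
    genus_correct = pick(taxonomy$species[taxonomy$genus == ref_genus &
                                            taxonomy$species != ref_species]),
    similar_genus = ,
    family_correct = pick(taxonomy$species[taxonomy$family == ref_family &
                                             taxonomy$genus != ref_genus]),
    similar_family = ,
    good_try = ,
    unknown = ,
    misleading = pick(taxonomy$species[taxonomy$family != ref_family]),
    no_id = "")
}

# Simulate one tool-sample pair: a list of n_replicates suggestion runs,
# each a list(position, suggested_name, category) of parallel vectors.
# Plain lists (not data frames) keep the generator fast enough for
# simulation studies with thousands of pipeline runs.
simulate_pair <- function(profile, ref_species, taxonomy, n_replicates) {
  p <- profile$category_probabilities
  cats <- names(p)
  draw_run <- function() {
    outcome <- cats[sample.int(length(cats), 1L, prob = p)]
    if (outcome == "no_id")
      return(list(position = 0L, suggested_name = "", category = "no_id"))
    k <- sample.int(4L, 1L, prob = profile$n_suggestions_law)
    name1 <- draw_name(outcome, ref_species, taxonomy)
    if (k == 1L)
      return(list(position = 1L, suggested_name = name1,
                  category = outcome))
    fillers <- vapply(seq_len(k - 1L), function(j)
      draw_name("unknown", ref_species, taxonomy), character(1))
    list(position = seq_len(k),
         suggested_name = c(name1, fillers),
         category = c(outcome, rep("unknown", k - 1L)))
  }
  runs <- vector("list", n_replicates)
  runs[[1L]] <- draw_run()
  if (n_replicates > 1L) for (r in 2L:n_replicates) {
    runs[[r]] <- if (stats::runif(1L) < profile$rho) runs[[r - 1L]]
    else draw_run()
  }
  runs
}

#' Simulate identification records
#'
#' Generates the full records table for a panel of tools on a sample set:
#' replicate 1 of each tool-sample pair draws an outcome category from the
#' tool's multinomial profile and builds a concrete suggestion run for it;
#' each later replicate repeats the previous one verbatim with probability
#' \code{rho}, otherwise redraws.
#'
#' @param profiles List of \code{\link{tool_profile}} objects.
#' @param samples Sample metadata (see \code{\link{generate_samples}}).
#' @param taxonomy Taxonomy data frame.
#' @param config A \code{\link{sim_config}} (supplies \code{n_replicates}
#'   and the root \code{seed}).
#' @return A validated \code{"taxid_records"} data frame.
#' @export
simulate_records <- function(profiles, samples, taxonomy, config) {
  n_pairs <- length(profiles) * nrow(samples)
  tool_v <- sample_v <- vector("list", n_pairs)
  rep_v <- pos_v <- name_v <- cat_v <- vector("list", n_pairs)
  ci <- 0L
  for (ti in seq_along(profiles)) {
    profile <- profiles[[ti]]
    for (si in seq_len(nrow(samples))) {
      set.seed(substream_seed(config$seed, ti, si))
      runs <- simulate_pair(profile, samples$species[si], taxonomy,
                            config$n_replicates)
      len <- vapply(runs, function(r) length(r$position), integer(1))
      ci <- ci + 1L
      tool_v[[ci]] <- rep(profile$tool_id, sum(len))
      sample_v[[ci]] <- rep(samples$sample[si], sum(len))
      rep_v[[ci]] <- rep(seq_along(runs), len)
      pos_v[[ci]] <- unlist(lapply(runs, `[[`, "position"))
      name_v[[ci]] <- unlist(lapply(runs, `[[`, "suggested_name"))
      cat_v[[ci]] <- unlist(lapply(runs, `[[`, "category"))
    }
  }
  as_records(data.frame(tool = unlist(tool_v), sample = unlist(sample_v),
                        replicate = unlist(rep_v), position = unlist(pos_v),
                        suggested_name = unlist(name_v),
                        category = unlist(cat_v),
                        stringsAsFactors = FALSE))
}

#' Recover a tool profile from simulated records
#'
#' Estimates the first-choice outcome multinomial from the first replicate
#' of every sample (always a fresh draw), and the replicate-dependence
#' \code{rho} from the fraction of adjacent-replicate outcome repeats,
#' corrected for the chance repeat rate implied by the estimated multinomial:
#' with observed adjacent match rate \eqn{\hat p} and chance rate
#' \eqn{\hat q = \sum_c \hat p_c^2}, \eqn{\hat\rho = (\hat p - \hat q) /
#' (1 - \hat q)}.
#'
#' @param records Records of a single tool (a \code{"taxid_records"} data
#'   frame filtered to one tool).
#' @return List with \code{category_probabilities} (named over the full
#'   vocabulary) and \code{rho}.
#' @export
recover_profile <- function(records) {
  scored <- score_records(records)
  if (length(unique(scored$tool)) != 1L)
    stop("records must come from a single tool", call. = FALSE)
  if (max(scored$replicate) < 2L)
    stop("need at least two replicates per sample to estimate rho",
         call. = FALSE)
  first_rep <- scored[scored$replicate == 1L, ]
  p_hat <- stats::setNames(numeric(length(match_categories())),
                           match_categories())
  tab <- table(first_rep$first_category) / nrow(first_rep)
  p_hat[names(tab)] <- as.numeric(tab)

  scored <- scored[order(scored$sample, scored$replicate), ]
  same_sample <- scored$sample[-1L] == scored$sample[-nrow(scored)]
  match_cat <- scored$first_category[-1L] == scored$first_category[-nrow(scored)]
  p_match <- mean(match_cat[same_sample])
  q_hat <- sum(p_hat^2)
  rho_hat <- if (q_hat >= 1) 1 else (p_match - q_hat) / (1 - q_hat)
  list(category_probabilities = p_hat,
       rho = min(1, max(0, rho_hat)))
}
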
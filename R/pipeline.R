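# End-to-end evaluation: records -> scores -> per-sample means -> subset
# tables with ranks and compact letter displays -> accuracy/error metrics ->
# consistency table -> concordance of subset rankings.

#' Run the full evaluation pipeline
#'
#' Orchestrates every stage of the evaluation on a records table (read from
#' files or simulated): rubric scoring, per-sample means, per-subset mean
#' tables with rankings and Kruskal-Wallis/Bonferroni letter groupings for
#' both scoring systems, the accuracy/error metric table, the replicate
#' consistency table, and Kendall's concordance of the per-subset tool
#' rankings.  The pipeline is a pure composition of the exported module
#' functions: the same inputs always yield the same report.
#'
#' @param records A \code{"taxid_records"} data frame, or \code{NULL} to
#'   simulate one from \code{config} and \code{profiles}.
#' @param taxonomy,metadata Taxonomy and sample metadata (required with
#'   \code{records}; generated when simulating).
#' @param config A \code{\link{sim_config}}; required when \code{records}
#'   is \code{NULL}, otherwise only its \code{n_replicates} is consulted
#'   (default 5).
#' @param profiles Tool profiles for simulation
#'   (default \code{\link{default_tool_profiles}()}).
#' @param scheme A \code{\link{weight_scheme}}.
#' @param alpha Significance level for letter displays.
#' @return Object of class \code{"taxideval_report"}: a list with elements
#'   \code{scored}, \code{first_choice}, \code{weighted},
#'   \code{consistency} (each a list of subset means, ranks, letters),
#'   \code{metrics}, \code{concordance}, \code{n_evaluations} and
#'   \code{alpha}.
#' @examples
#' rep <- run_pipeline(config = sim_config(seed = 42))
#' print(rep)
#' @export
run_pipeline <- function(records = NULL, taxonomy = NULL, metadata = NULL,
                         config = NULL, profiles = default_tool_profiles(),
                         scheme = weight_scheme(), alpha = 0.05) {
  if (is.null(records)) {
    if (is.null(config))
      stop("either records or a sim_config must be supplied", call. = FALSE)
    taxonomy <- generate_taxonomy(config)
    metadata <- generate_samples(config, taxonomy)
    records <- simulate_records(profiles, metadata, taxonomy, config)
  } else {
    if (is.null(taxonomy) || is.null(metadata))
      stop("taxonomy and metadata are required with records", call. = FALSE)
    records <- as_records(records)
  }
  n_replicates <- if (!is.null(config)) config$n_replicates else 5L
  missing_meta <- setdiff(unique(records$sample), metadata$sample)
  if (length(missing_meta))
    stop("records reference sample(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)

  scored <- score_records(records, scheme)
  cons <- consistency_table(records, taxonomy, n_replicates)
  if (any(!cons$complete))
    warning(sum(!cons$complete), " tool-sample pair(s) have fewer than ",
            n_replicates, " replicates; evaluated as-is", call. = FALSE)

  score_block <- function(per_sample) {
    parts <- subset_means(per_sample, metadata, "plant_part")
    types <- subset_means(per_sample, metadata, "plant_type")
    means <- cbind(parts$means[, setdiff(colnames(parts$means), "Average"),
                               drop = FALSE],
                   types$means)
    ranks <- cbind(parts$ranks, types$ranks)
    letters <- pairwise_letters(per_sample$score, per_sample$tool, alpha)
    list(means = means, ranks = ranks,
         n = c(parts$n, types$n),
         letters = letters,
         omnibus = attr(letters, "omnibus"))
  }

  fc <- score_block(per_sample_scores(scored, "first_choice"))
  wt <- score_block(per_sample_scores(scored, "weighted"))
  cons_ps <- data.frame(tool = cons$tool, sample = cons$sample,
                        n = cons$n_replicates, score = cons$consistency_C,
                        stringsAsFactors = FALSE)
  cs <- score_block(cons_ps)

  subset_cols <- setdiff(colnames(fc$means), "Average")
  structure(list(scored = scored,
                 consistency_by_sample = cons,
                 first_choice = fc, weighted = wt, consistency = cs,
                 metrics = metric_table(scored),
                 concordance = kendall_w(t(fc$ranks[, subset_cols])),
                 n_evaluations = nrow(cons),
                 n_observations = nrow(scored),
                 alpha = alpha),
            class = "taxideval_report")
}

# paper-style rounding: half-up at the formatting layer only
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_means_table <- function(block, digits = 0) {
  m <- block$means
  ord <- order(-m[, "Average"])
  m <- m[ord, , drop = FALSE]
  ranks <- block$ranks[ord, , drop = FALSE]
  lets <- block$letters$letters[match(rownames(m), block$letters$group)]
  cells <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  cell_fmt <- if (digits == 0) function(v) sprintf("%d", as.integer(v))
  else function(v) sprintf(paste0("%.", digits, "f"), v)
  for (j in colnames(m)) {
    val <- round_half_up(m[, j], if (j == "Average") 1 else digits)
    cells[, j] <- if (j == "Average") sprintf("%.1f", val)
    else sprintf("%s (%g)", cell_fmt(val), ranks[, j])
  }
  cells <- cbind(cells, letters = lets)
  avg <- round_half_up(colMeans(block$means), 1)
  cells <- rbind(cells, Average = c(sprintf("%.1f", avg), ""))
  cells <- rbind(cells, `N samples` = c(as.character(block$n),
                                        as.character(sum(block$n) / 2), ""))
  cells
}

#' @export
print.taxideval_report <- function(x, ...) {
  cat("Taxonomic identification tool evaluation\n")
  cat(sprintf("  %d tools, %d tool-sample evaluations, %d observations\n\n",
              nrow(x$metrics), x$n_evaluations, x$n_observations))

  cat("First-choice scores by subset (rank in parentheses):\n")
  print(format_means_table(x$first_choice), quote = FALSE, right = TRUE)
  cat(sprintf("\n  Kruskal-Wallis H = %.2f, df = %d, p = %.3g\n",
              x$first_choice$omnibus$H, x$first_choice$omnibus$df,
              x$first_choice$omnibus$p.value))
  cat(sprintf("  Kendall's W over subset rankings = %.3f (p = %.3g)\n\n",
              x$concordance$W, x$concordance$p.value))

  cat("Accuracy and error percentages (all observations):\n")
  mt <- x$metrics
  mt[-1] <- lapply(mt[-1], function(v) sprintf("%d", round_half_up(v)))
  print(mt, row.names = FALSE)

  cat("\nConsistency C by subset (rank in parentheses):\n")
  print(format_means_table(x$consistency, digits = 1), quote = FALSE,
        right = TRUE)
  invisible(x)
}

#' @export
summary.taxideval_report <- function(object, ...) {
  fc <- object$first_choice
  out <- data.frame(
    tool = rownames(fc$means),
    first_choice = fc$means[, "Average"],
    weighted = object$weighted$means[rownames(fc$means), "Average"],
    consistency = object$consistency$means[rownames(fc$means), "Average"],
    letters = fc$letters$letters[match(rownames(fc$means),
                                       fc$letters$group)],
    stringsAsFactors = FALSE)
  out <- out[order(-out$first_choice), ]
  rownames(out) <- NULL
  out
}

#' Write an evaluation report to disk
#'
#' Serializes the report tables as CSV files: subset means with ranks and
#' letters for both scoring systems and consistency, the metric table, the
#' per-(tool, sample) consistency values, and a one-row summary with the
#' omnibus and concordance statistics.
#'
#' @param report A \code{"taxideval_report"}.
#' @param dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  blocks <- list(first_choice = report$first_choice,
                 weighted = report$weighted,
                 consistency = report$consistency)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    df <- data.frame(tool = rownames(b$means), b$means,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df$letters <- b$letters$letters[match(df$tool, b$letters$group)]
    p <- file.path(dir, paste0(nm, "_subset_means.csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "metrics.csv")
  utils::write.csv(report$metrics, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "consistency_by_sample.csv")
  utils::write.csv(report$consistency_by_sample, p, row.names = FALSE)
  paths <- c(paths, p)
  smry <- data.frame(kw_H = report$first_choice$omnibus$H,
                     kw_p = report$first_choice$omnibus$p.value,
                     kendall_W = report$concordance$W,
                     kendall_p = report$concordance$p.value,
                     n_evaluations = report$n_evaluations,
                     n_observations = report$n_observations)
  p <- file.path(dir, "summary.csv")
  utils::write.csv(smry, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
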
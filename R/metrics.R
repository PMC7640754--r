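# Aggregation of scored records into per-tool and per-subset report tables:
# per-sample means (the observation unit for the between-tool tests),
# subset means with rankings, accuracy thresholds and error rates.

#' Per-sample mean scores
#'
#' Averages the chosen score over the replicates of each (tool, sample)
#' pair.  These per-sample means are the observation unit for the
#' Kruskal-Wallis comparisons between tools (9 tools x 38 samples = 342
#' observations in the study design).
#'
#' @param scored Output of \code{\link{score_records}}.
#' @param score \code{"first_choice"}, \code{"weighted"}, or the name of any
#'   numeric column of \code{scored}.
#' @return Data frame with columns \code{tool}, \code{sample}, \code{n},
#'   \code{score}.
#' @export
per_sample_scores <- function(scored, score = c("first_choice", "weighted")) {
  score <- score[1L]
  if (!score %in% names(scored))
    stop("no column ", sQuote(score), " in scored records", call. = FALSE)
  key <- paste(scored$tool, scored$sample, sep = "\r")
  agg <- rowsum(cbind(n = rep(1, nrow(scored)), sum = scored[[score]]), key)
  first <- match(rownames(agg), key)
  out <- data.frame(tool = scored$tool[first], sample = scored$sample[first],
                    n = as.integer(agg[, "n"]),
                    score = agg[, "sum"] / agg[, "n"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$tool, out$sample), ]
  rownames(out) <- NULL
  out
}

# rank 1 = highest value; ties get average ranks
rank_desc <- function(x) rank(-x, ties.method = "average")

#' Per-subset mean scores with rankings
#'
#' Averages per-sample scores within subsets of samples (by plant part, by
#' plant type, or overall) for each tool, and ranks the tools within every
#' subset (rank 1 = highest mean; average ranks on ties).  The overall mean
#' is the sample-count-weighted mean of the subset means for any partition.
#'
#' @param per_sample Output of \code{\link{per_sample_scores}} (or the
#'   consistency table with its score column renamed to \code{score}).
#' @param metadata Sample metadata (see \code{\link{read_sample_metadata}}).
#' @param grouping \code{"plant_part"}, \code{"plant_type"} or
#'   \code{"overall"}.
#' @return List with \code{means} (tools x subsets matrix, plus an
#'   \code{Average} column over all samples), \code{ranks} (same shape,
#'   excluding the Average column for \code{"overall"}), and \code{n} (named
#'   sample counts per subset).
#' @export
subset_means <- function(per_sample, metadata,
                         grouping = c("plant_part", "plant_type",
                                      "overall")) {
  grouping <- match.arg(grouping)
  missing_meta <- setdiff(unique(per_sample$sample), metadata$sample)
  if (length(missing_meta))
    stop("sample(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  group <- if (grouping == "overall") rep("Average", nrow(metadata)) else
    metadata[[grouping]]
  g <- group[match(per_sample$sample, metadata$sample)]

  tools <- sort(unique(per_sample$tool))
  subsets <- if (grouping == "plant_part")
    c("flower", "fruit", "leaf", "plant")
  else if (grouping == "plant_type") c("herb", "monocot", "woody")
  else "Average"
  subsets <- intersect(subsets, unique(g))

  means <- matrix(NA_real_, length(tools), length(subsets) + 1L,
                  dimnames = list(tools, c(subsets, "Average")))
  for (s in subsets) {
    sel <- g == s
    m <- tapply(per_sample$score[sel], per_sample$tool[sel], mean)
    means[names(m), s] <- m
  }
  overall <- tapply(per_sample$score, per_sample$tool, mean)
  means[names(overall), "Average"] <- overall
  if (grouping == "overall") means <- means[, "Average", drop = FALSE]

  ranks <- apply(means[, setdiff(colnames(means), if (grouping != "overall")
    "Average" else character(0)), drop = FALSE], 2L, rank_desc)
  n <- table(group[match(unique(per_sample$sample), metadata$sample)])
  list(means = means, ranks = as.matrix(ranks), n = c(n))
}

#' Sample-count-weighted pooled mean
#'
#' Reconstructs an overall mean from subset means and their sample counts;
#' refuses silently inconsistent inputs when the expected total is known
#' (subset counts must partition the sample set).
#'
#' @param means Numeric vector of subset means.
#' @param n Integer vector of subset sample counts.
#' @param total Expected total sample count, or \code{NULL} to skip the check.
#' @return The pooled mean \code{sum(means * n) / sum(n)}.
#' @examples
#' pooled_mean(c(76, 67, 62, 71), c(12, 3, 10, 13), total = 38)
#' @export
pooled_mean <- function(means, n, total = NULL) {
  stopifnot(length(means) == length(n), all(n >= 0))
  if (!is.null(total) && sum(n) != total)
    stop("subset counts sum to ", sum(n), ", expected ", total,
         " -- inconsistent partition", call. = FALSE)
  sum(means * n) / sum(n)
}

#' Accuracy threshold percentages
#'
#' Percentage of all replicate observations of one tool whose first-choice
#' score equals 100, is at least 80, and is at least 50 ("correct to
#' species", "correct or near-correct to genus", "correct to family or
#' better").  The three percentages are nested by construction.
#'
#' @param first_choice Numeric vector of first-choice scores (all replicate
#'   observations of one tool; 190 in the study design).
#' @return Named numeric vector \code{c(pct_eq_100, pct_ge_80, pct_ge_50)}.
#' @export
accuracy_thresholds <- function(first_choice) {
  n <- length(first_choice)
  if (!n) stop("no observations", call. = FALSE)
  100 * c(pct_eq_100 = sum(first_choice == 100),
          pct_ge_80 = sum(first_choice >= 80),
          pct_ge_50 = sum(first_choice >= 50)) / n
}

#' Misleading and wrong-family error rates
#'
#' \code{pct_mad} is the percentage of all observations scored below zero
#' (totally misleading first choice).  \code{pct_wrong} is the percentage of
#' observations whose first suggestion named an incorrect family or worse
#' (categories good_try, unknown, misleading), among the observations that
#' returned any identification; \code{similar_family} is not counted as
#' wrong, and no-id attempts are excluded from the denominator.
#'
#' @param scored Rows of \code{\link{score_records}} output for one tool.
#' @return Named numeric vector \code{c(pct_mad, pct_wrong)};
#'   \code{pct_wrong} is \code{NaN} when no observation returned an
#'   identification.
#' @export
error_rates <- function(scored) {
  n <- nrow(scored)
  if (!n) stop("no observations", call. = FALSE)
  returned <- !scored$no_id
  wrong <- returned & scored$first_category %in% .WRONG_CATEGORIES
  c(pct_mad = 100 * sum(scored$first_choice < 0) / n,
    pct_wrong = 100 * sum(wrong) / sum(returned))
}

#' Per-tool accuracy and error table
#'
#' The accuracy/error summary over all replicate observations: the three
#' accuracy thresholds plus the two error rates, one row per tool, ordered
#' by decreasing \code{pct_eq_100}.
#'
#' @param scored Output of \code{\link{score_records}}.
#' @return Data frame with columns \code{tool}, \code{pct_eq_100},
#'   \code{pct_ge_80}, \code{pct_ge_50}, \code{pct_mad}, \code{pct_wrong}.
#' @export
metric_table <- function(scored) {
  tools <- sort(unique(scored$tool))
  rows <- lapply(tools, function(t) {
    s <- scored[scored$tool == t, ]
    c(accuracy_thresholds(s$first_choice), error_rates(s))
  })
  out <- data.frame(tool = tools, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_eq_100, out$tool), ]
  rownames(out) <- NULL
  out
}
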
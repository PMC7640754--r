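# Nonparametric comparison suite: Kruskal-Wallis omnibus tests, Dunn-style
# post-hoc z tests with Bonferroni correction and a compact letter display,
# the (n-1) chi-square test for two proportions, and Kendall's coefficient
# of concordance.  Scores from the rubric deviate strongly from normality,
# so only rank-based tests are appropriate.

#' Kruskal-Wallis test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on k - 1 degrees of freedom.
#'
#' @param x Numeric observations.
#' @param g Grouping vector (coerced to factor), same length as \code{x}.
#' @return List with \code{H}, \code{df} and \code{p.value}.
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(g) == 0L)) stop("empty group", call. = FALSE)
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Dunn post-hoc z tests on pooled ranks
#'
#' Pairwise comparisons of mean pooled ranks after a Kruskal-Wallis test:
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\Big(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\Big)
#'   \Big(\frac{1}{n_i} + \frac{1}{n_j}\Big)}},}
#' with the tie correction in the pooled variance.  Two-sided p-values are
#' Bonferroni-multiplied by the number of pairs and capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @return Data frame with one row per unordered pair: \code{group1},
#'   \code{group2}, \code{z}, \code{p.value}, \code{p.adjusted}.
#' @export
dunn_posthoc <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  v <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  z <- (rbar[pairs[1L, ]] - rbar[pairs[2L, ]]) /
    sqrt(v * (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = levels(g)[pairs[1L, ]],
             group2 = levels(g)[pairs[2L, ]],
             z = as.numeric(z), p.value = as.numeric(p),
             p.adjusted = pmin(1, as.numeric(p) * ncol(pairs)),
             stringsAsFactors = FALSE)
}

# Compact letter display by insert-and-absorb over a symmetric logical
# "not significantly different" matrix.  Guarantees: two groups share a
# letter if and only if nonsig[i, j] is TRUE.
cld_from_nonsig <- function(nonsig, order_by = NULL) {
  k <- nrow(nonsig)
  cols <- list(seq_len(k))
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    if (nonsig[i, j]) next
    new_cols <- list()
    for (s in cols) {
      if (all(c(i, j) %in% s))
        new_cols <- c(new_cols, list(setdiff(s, i)), list(setdiff(s, j)))
      else new_cols <- c(new_cols, list(s))
    }
    # absorb columns contained in another (keep one copy of duplicates)
    new_cols <- unique(lapply(new_cols, sort))
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      if (!keep[a]) next
      for (b in seq_along(new_cols))
        if (a != b && keep[b] && all(new_cols[[a]] %in% new_cols[[b]])) {
          keep[a] <- FALSE
          break
        }
    }
    cols <- new_cols[keep]
  }
  # stable letter order: by best (lowest) order_by value among members
  if (!is.null(order_by)) {
    key <- vapply(cols, function(s) min(order_by[s]), numeric(1))
    cols <- cols[order(key)]
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- character(k)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters_pool[ci])
  out
}

#' Compact letter display from Kruskal-Wallis post-hoc comparisons
#'
#' Runs \code{\link{dunn_posthoc}} and assigns letters such that two groups
#' share a letter exactly when their Bonferroni-adjusted p-value is at least
#' \code{alpha}.  Letters are ordered so that \code{"a"} contains the group
#' with the highest mean value.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns \code{group}, \code{mean}, \code{letters},
#'   plus attributes \code{"dunn"} (the pairwise table) and \code{"omnibus"}
#'   (the Kruskal-Wallis result).
#' @examples
#' x <- c(rnorm(20), rnorm(20, 5), rnorm(20, 10))
#' g <- rep(c("low", "mid", "high"), each = 20)
#' pairwise_letters(x, g)
#' @export
pairwise_letters <- function(x, g, alpha = 0.05) {
  g <- factor(g)
  k <- nlevels(g)
  means <- tapply(x, g, mean)
  if (k == 1L) {
    out <- data.frame(group = levels(g), mean = as.numeric(means),
                      letters = "a", stringsAsFactors = FALSE)
    return(out)
  }
  dunn <- dunn_posthoc(x, g)
  nonsig <- matrix(TRUE, k, k, dimnames = list(levels(g), levels(g)))
  i1 <- match(dunn$group1, levels(g))
  i2 <- match(dunn$group2, levels(g))
  nonsig[cbind(i1, i2)] <- dunn$p.adjusted >= alpha
  nonsig[cbind(i2, i1)] <- dunn$p.adjusted >= alpha
  lets <- cld_from_nonsig(nonsig, order_by = rank(-means))
  out <- data.frame(group = levels(g), mean = as.numeric(means),
                    letters = lets, stringsAsFactors = FALSE)
  attr(out, "dunn") <- dunn
  attr(out, "omnibus") <- kruskal_wallis(x, g)
  out
}

#' (n-1) chi-square test for two proportions
#'
#' Pearson's chi-square statistic on the 2x2 table of successes and failures,
#' without continuity correction, scaled by \code{(N - 1) / N} -- the test
#' recommended for comparing two proportions at modest sample sizes.  The
#' p-value is from the chi-square distribution with 1 degree of freedom.
#'
#' @param a,n1 Successes and trials in the first group.
#' @param b,n2 Successes and trials in the second group.
#' @return List with \code{statistic}, \code{pearson} (the unscaled
#'   statistic) and \code{p.value}.  Degenerate margins (no successes or no
#'   failures overall) give statistic 0 and p-value 1.
#' @examples
#' n_minus_1_chi2(30, 50, 20, 50)  # Pearson 4.0 scaled to 3.96
#' @export
n_minus_1_chi2 <- function(a, n1, b, n2) {
  stopifnot(a >= 0, b >= 0, a <= n1, b <= n2)
  N <- n1 + n2
  if (N < 2) stop("need at least two observations in total", call. = FALSE)
  s <- a + b
  if (s == 0 || s == N)
    return(list(statistic = 0, pearson = 0, p.value = 1))
  pearson <- N * (a * (n2 - b) - b * (n1 - a))^2 / (s * (N - s) * n1 * n2)
  statistic <- (N - 1) / N * pearson
  list(statistic = statistic, pearson = pearson,
       p.value = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Kendall's coefficient of concordance
#'
#' Agreement of m rankings (judges) of n objects, with the standard tie
#' correction:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j},}
#' where S is the sum of squared deviations of the object rank sums from
#' their mean and \eqn{T_j = \sum (t^3 - t)} over the tie groups of judge j.
#' Significance uses \eqn{\chi^2 = m (n - 1) W} on n - 1 degrees of freedom.
#'
#' @param rank_matrix Numeric matrix, judges in rows, objects in columns;
#'   each row a ranking of the n objects (ties as average ranks).  Rows that
#'   are raw scores rather than ranks are ranked internally (highest value =
#'   rank 1) when \code{rank_rows = TRUE}.
#' @param rank_rows Rank each row before computing (default \code{FALSE}:
#'   rows are already rankings).
#' @return Object of class \code{"kendall_w"}: list with \code{W}, \code{m},
#'   \code{n}, \code{chi2}, \code{df}, \code{p.value}.
#' @examples
#' r <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3))
#' kendall_w(r)
#' @export
kendall_w <- function(rank_matrix, rank_rows = FALSE) {
  rank_matrix <- as.matrix(rank_matrix)
  m <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  if (m < 2L || n < 2L)
    stop("need at least two judges and two objects", call. = FALSE)
  if (rank_rows)
    rank_matrix <- t(apply(rank_matrix, 1L, rank_desc))
  if (!all(abs(rowSums(rank_matrix) - n * (n + 1) / 2) < 1e-8))
    stop("each row must be a ranking of the n objects", call. = FALSE)
  s_sums <- colSums(rank_matrix)
  S <- sum((s_sums - m * (n + 1) / 2)^2)
  T_j <- apply(rank_matrix, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(T_j)
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  structure(list(W = W, m = m, n = n, chi2 = chi2, df = n - 1L,
                 p.value = stats::pchisq(chi2, n - 1, lower.tail = FALSE)),
            class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf(
    "Kendall's coefficient of concordance\n  W = %.3f (m = %d judges, n = %d objects)\n  chi-squared = %.2f, df = %d, p = %.3g\n",
    x$W, x$m, x$n, x$chi2, x$df, x$p.value))
  invisible(x)
}
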
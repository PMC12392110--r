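#' Significance stars for p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `"ns"`
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (the sum of the probabilities
#' of all tables with the observed margins that are no more probable
#' than the observed one) and the sample odds ratio `ad / bc`
#' (`Inf` when `bc = 0`).
#'
#' @param table 2x2 matrix of non-negative integer counts, or the four
#'   counts `a, b, c, d` (row-wise).
#' @return a list with `p.value`, `odds.ratio`, and `stars`.
#' @examples
#' fisherExact(matrix(c(10, 8, 1, 26), 2, byrow = TRUE))
#' @export
fisherExact <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0) ||
      any(table != round(table))) {
    stop("a 2x2 table of non-negative integer counts is required",
         call. = FALSE)
  }
  if (sum(table) == 0) {
    stop("data error: all-zero contingency table", call. = FALSE)
  }
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  bc <- table[1, 2] * table[2, 1]
  or <- if (bc == 0) Inf else table[1, 1] * table[2, 2] / bc
  list(p.value = p, odds.ratio = or, stars = significanceStars(p))
}

#' Kruskal-Wallis omnibus test across groups
#'
#' Rank-based H statistic with tie correction. By default the p-value
#' comes from the chi-squared approximation with `k - 1` degrees of
#' freedom (the conventional choice); with `exact = TRUE` the p-value is
#' the exact permutation tail probability `P(H* >= H)` obtained by
#' enumerating every assignment of the pooled observations to the group
#' sizes (feasible for small samples, say total n <= 10). When all
#' observations are equal, H is 0 and p is 1 (not NaN).
#'
#' @param groups list of >= 2 numeric vectors (each non-empty).
#' @param exact compute the exact permutation p-value instead of the
#'   chi-squared approximation.
#' @return a list with `statistic` (H), `df`, and `p.value`.
#' @export
kruskalWallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("at least 2 groups are required", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 1)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (isTRUE(exact)) {
    p <- kwExactPermutationP(x, sizes, H)
  }
  list(statistic = H, df = unname(kt$parameter), p.value = p)
}

# tie-corrected H computed directly from the rank formula
kwStatistic <- function(x, assign, k) {
  N <- length(x)
  r <- rank(x)
  H <- 0
  for (gi in seq_len(k)) {
    ri <- r[assign == gi]
    H <- H + length(ri) * (mean(ri) - (N + 1) / 2)^2
  }
  H <- 12 * H / (N * (N + 1))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H / corr else 0
}

# enumerate all assignments of the pooled sample to the group sizes and
# return P(H* >= H_obs)
kwExactPermutationP <- function(x, sizes, Hobs) {
  n <- length(x)
  k <- length(sizes)
  ge <- 0L; tot <- 0L
  recurse <- function(remaining, gi, assign) {
    if (gi == k) {
      assign[remaining] <- k
      H <- kwStatistic(x, assign, k)
      tot <<- tot + 1L
      if (H >= Hobs - 1e-12) ge <<- ge + 1L
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (p in picks) {
      a2 <- assign
      a2[p] <- gi
      recurse(setdiff(remaining, p), gi + 1L, a2)
    }
  }
  recurse(seq_len(n), 1L, integer(n))
  ge / tot
}

#' Dunn's post hoc test with Holm-Bonferroni correction
#'
#' Pairwise z-statistics from the pooled ranks with tie correction:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) * (1/ni + 1/nj))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups; two-sided normal
#' p-values; Holm-Bonferroni step-down adjustment over the explicitly
#' requested family of pairs.
#'
#' @param groups named list of numeric vectors.
#' @param pairs list of length-2 character vectors naming the tested
#'   pairs; default all pairs.
#' @return a list of class `GroupComparisonResult` with `omnibus` (the
#'   [kruskalWallis()] result) and `pairwise` (data.frame: pair, z,
#'   p_raw, p_adj, stars).
#' @export
dunnHolm <- function(groups, pairs = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a named list", call. = FALSE)
  }
  if (is.null(pairs)) {
    cmb <- utils::combn(names(groups), 2, simplify = FALSE)
    pairs <- cmb
  }
  for (pr in pairs) {
    if (length(pr) != 2 || !all(pr %in% names(groups))) {
      stop("unknown group label in pairs: ",
           paste(setdiff(unlist(pairs), names(groups)), collapse = ", "),
           call. = FALSE)
    }
  }
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  g <- rep(names(groups), sizes)
  N <- length(x)
  r <- rank(x)
  meanRank <- tapply(r, factor(g, levels = names(groups)), mean)
  ties <- table(x)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieTerm
  res <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(s2 * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se > 0) (meanRank[[i]] - meanRank[[j]]) / se else 0
    data.frame(pair = paste(i, j, sep = " vs "), z = z,
               p_raw = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, res)
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "holm")
  pw$stars <- significanceStars(pw$p_adj)
  rownames(pw) <- NULL
  structure(list(omnibus = kruskalWallis(unname(groups)), pairwise = pw),
            class = "GroupComparisonResult")
}

#' @export
print.GroupComparisonResult <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p.value))
  cat("Dunn's post hoc (Holm-Bonferroni adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Compare one SLE metric across groups
#'
#' Runs the Kruskal-Wallis omnibus test and Dunn's post hoc with
#' Holm-Bonferroni correction on one metric column of a (slice- or
#' animal-level) metric table. Rows with a missing metric value are
#' excluded with a message stating the count.
#'
#' @param metrics metric data.frame (see [computeSleMetrics()] and
#'   [aggregateMetrics()]).
#' @param metric column name, e.g. `"fraction"`, `"mean_duration_s"`,
#'   `"rate_per_min"`, `"spike_freq_hz"`.
#' @param group_by grouping column (default `"treatment"`).
#' @param pairs explicit family of tested pairs (default all).
#' @return a `GroupComparisonResult` (see [dunnHolm()]).
#' @export
compareMetricAcrossGroups <- function(metrics, metric,
                                      group_by = "treatment",
                                      pairs = NULL) {
  if (!metric %in% names(metrics)) {
    stop("schema error: metric column '", metric, "' not found",
         call. = FALSE)
  }
  if (!group_by %in% names(metrics)) {
    stop("schema error: grouping column '", group_by, "' not found",
         call. = FALSE)
  }
  vals <- metrics[[metric]]
  miss <- is.na(vals)
  if (any(miss)) {
    message(sum(miss), " row(s) with missing '", metric, "' excluded")
  }
  d <- metrics[!miss, ]
  groups <- split(d[[metric]], d[[group_by]])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2) {
    stop("fewer than 2 groups with data for '", metric, "'",
         call. = FALSE)
  }
  if (!is.null(pairs)) {
    keep <- unique(unlist(pairs))
    missingGroups <- setdiff(keep, names(groups))
    if (length(missingGroups) > 0) {
      stop("unknown group label in pairs: ",
           paste(missingGroups, collapse = ", "), call. = FALSE)
    }
  }
  dunnHolm(groups, pairs)
}
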
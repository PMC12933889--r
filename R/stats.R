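#' @title Nonparametric descriptor-comparison statistics
#' @description Group comparison of descriptor distributions: the
#'   Kruskal-Wallis omnibus test (base R), Dunn's post-hoc z tests on pooled
#'   ranks with tie correction and Bonferroni adjustment, Cohen's d effect
#'   sizes with pooled standard deviation, and Spearman trend correlation.
#'   Differences are conventionally called significant below p = 0.05.
#' @name groupstats
NULL

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("Need a named list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("Groups must be named", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("Empty group", call. = FALSE)
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    stop("Non-finite values in groups", call. = FALSE)
  }
  groups
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction; p from the chi-squared
#' approximation (delegated to [stats::kruskal.test()]).
#'
#' @param groups named list of numeric vectors.
#' @return list `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from the pooled ranks of all groups,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie correction \eqn{T = \sum (t^3 - t) / (12 (N - 1))}; two-sided
#' normal p-values multiplied by the number of group pairs and capped at 1.
#'
#' @param groups named list of numeric vectors.
#' @return list with symmetric matrices `z`, `p_adj` and the raw `p`.
#' @export
dunn_bonferroni <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  z <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  m <- k * (k - 1) / 2
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    zij <- (rbar[i] - rbar[j]) / se
    z[i, j] <- zij; z[j, i] <- -zij
    pij <- 2 * stats::pnorm(-abs(zij))
    p[i, j] <- p[j, i] <- pij
  }
  p_adj <- pmin(p * m, 1)
  diag(p_adj) <- 1
  list(z = z, p = p, p_adj = p_adj, n_comparisons = m)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled (not averaged) standard deviation; no small-sample correction.
#'
#' @param a,b numeric vectors of length >= 2.
#' @return signed effect size (first argument minus second).
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("Both samples need length >= 2", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("Zero pooled standard deviation", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_trend <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("Need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Constant input vector: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Full group comparison for one descriptor
#'
#' Omnibus Kruskal-Wallis test, Dunn-Bonferroni pairwise p-values, Cohen's d
#' matrix and group medians.
#'
#' @param groups named list of numeric vectors (one per dataset).
#' @return object of class `comparison_result`.
#' @export
compare_groups <- function(groups) {
  groups <- check_groups(groups)
  kw <- kruskal_wallis(groups)
  dunn <- dunn_bonferroni(groups)
  k <- length(groups)
  d <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    dij <- tryCatch(cohens_d(groups[[i]], groups[[j]]),
                    error = function(e) NA_real_)
    d[i, j] <- dij; d[j, i] <- -dij
  }
  structure(list(kw_H = kw$H, kw_p = kw$p, pairwise_p_adj = dunn$p_adj,
                 dunn_z = dunn$z, cohens_d = d,
                 medians = vapply(groups, stats::median, numeric(1)),
                 n = lengths(groups)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d groups, Kruskal-Wallis H = %.3f, p = %.3g\n",
              length(x$medians), x$kw_H, x$kw_p))
  cat("medians:\n"); print(round(x$medians, 4))
  invisible(x)
}

#' Long-format comparison table across descriptors
#'
#' Runs [compare_groups()] for each requested descriptor column of a
#' descriptor table grouped by a label column.
#'
#' @param tab data.frame (e.g. from [descriptor_table()]).
#' @param descriptors character vector of descriptor column names.
#' @param group_col grouping column (default `"source_tag"`).
#' @return data.frame `descriptor`, `group_a`, `group_b`, `median_a`,
#'   `median_b`, `p_adj`, `d`, plus an omnibus table attribute (`"omnibus"`).
#' @export
comparison_table <- function(tab, descriptors, group_col = "source_tag") {
  stopifnot(group_col %in% names(tab), all(descriptors %in% names(tab)))
  rows <- list(); omni <- list()
  for (dsc in descriptors) {
    groups <- split(tab[[dsc]], tab[[group_col]])
    cr <- compare_groups(groups)
    omni[[length(omni) + 1L]] <- data.frame(
      descriptor = dsc, kw_H = cr$kw_H, kw_p = cr$kw_p,
      stringsAsFactors = FALSE)
    nms <- names(cr$medians)
    for (i in seq_along(nms)[-length(nms)]) for (j in (i + 1L):length(nms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = dsc, group_a = nms[i], group_b = nms[j],
        median_a = cr$medians[i], median_b = cr$medians[j],
        p_adj = cr$pairwise_p_adj[i, j], d = cr$cohens_d[i, j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omnibus") <- do.call(rbind, omni)
  out
}
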
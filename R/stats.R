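#' Remove outliers beyond k standard deviations from the mean
#'
#' Single pass: mean and sample SD are computed on the full input and values
#' with \code{|x - mean| > k * SD} are dropped (strict inequality, so values
#' exactly at the boundary are retained). Order is preserved. This is applied
#' once, on the raw group values, before any testing.
#'
#' @param x numeric vector (n >= 3 for a defined rule).
#' @param k SD multiple (default 2).
#' @return list(values = retained values, removed = indices of removed
#'   values, n_removed). With n < 3 the input is returned unchanged with a
#'   warning.
#' @examples
#' removeOutliers(c(rep(1, 9), 100))
#' @export
removeOutliers <- function(x, k = 2) {
  if (length(x) < 3L) {
    warning("fewer than 3 values; outlier rule not applied")
    return(list(values = x, removed = integer(0), n_removed = 0L))
  }
  m <- mean(x); s <- sd(x)
  drop <- which(abs(x - m) > k * s)
  list(values = if (length(drop)) x[-drop] else x, removed = drop,
       n_removed = length(drop))
}

#' Mean and standard error of the mean
#'
#' @param x numeric vector (n >= 1).
#' @return list(mean, sem, n). SEM is sample SD / sqrt(n); for n = 1 it is
#'   \code{NA} (flagged undefined).
#' @examples
#' meanSem(c(2, 4, 6)) # mean 4, sem 2/sqrt(3)
#' @export
meanSem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty input")
  list(mean = mean(x), sem = if (n > 1L) sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Student's t-test between two groups
#'
#' Unpaired: classical pooled-variance two-sample Student t (not Welch).
#' Paired: one-sample t on the differences. Two-sided p from the t
#' distribution. When both groups are constant with equal means, p = 1 by
#' convention.
#'
#' @param a,b numeric vectors (equal length when \code{paired}).
#' @param paired logical.
#' @return list(statistic, df, p_value, paired, summaries = per-group
#'   \code{\link{meanSem}}).
#' @examples
#' tTestGroups(c(1, 2, 3), c(4, 5, 6))
#' @export
tTestGroups <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired test requires equal lengths")
  degenerate <- if (paired) sd(a - b) == 0 else
    sd(a) == 0 && sd(b) == 0
  if (isTRUE(degenerate)) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- list(statistic = 0, parameter = if (paired) length(a) - 1 else
                   length(a) + length(b) - 2, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = if (paired) length(a) - 1 else
                   length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    tt <- t.test(a, b, paired = paired, var.equal = TRUE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), paired = paired,
       summaries = list(a = meanSem(a), b = meanSem(b)))
}

#' One-way ANOVA with Bonferroni post hoc pairwise comparisons
#'
#' Classical F = MS_between / MS_within via \code{stats::aov}. Post hoc:
#' pairwise pooled-variance Student t-tests with Bonferroni correction
#' (raw p x number of comparisons, capped at 1). When all group means are
#' identical, F = 0 and p = 1.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list(F, df, p_value, pairwise = data.frame(group1, group2, p_raw,
#'   p_bonferroni), summaries).
#' @export
anovaOneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs n >= 2")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  names(groups) <- nm
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, vapply(groups, length, 1L)), levels = nm)
  sb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  if (sb <= .Machine$double.eps * sum(y^2)) {
    f <- 0; p <- 1
  } else {
    fit <- summary(aov(y ~ g))[[1L]]
    f <- fit$`F value`[1L]
    p <- fit$`Pr(>F)`[1L]
  }
  pairs <- utils::combn(nm, 2)
  m <- ncol(pairs)
  p_raw <- vapply(seq_len(m), function(k)
    tTestGroups(groups[[pairs[1, k]]], groups[[pairs[2, k]]])$p_value, 0)
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p_raw = p_raw,
                         p_bonferroni = pmin(p_raw * m, 1))
  list(F = f, df = c(df1, df2), p_value = p, pairwise = pairwise,
       summaries = lapply(groups, meanSem))
}

#' Exact two-sided Fisher test for a 2x2 contingency table
#'
#' Enumerates, with log-factorials, every table compatible with the observed
#' margins; the two-sided p-value is the sum of hypergeometric point
#' probabilities not exceeding that of the observed table (the
#' point-probability rule, ties included). Degenerate tables (an all-zero
#' row or column) give p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no), or the count \code{a} when \code{b}, \code{c}
#'   and \code{d} are given.
#' @param b,c,d optional remaining cells when \code{table} is the scalar
#'   \code{a}.
#' @return list(p_value, table, point_probability).
#' @examples
#' fisherExact(matrix(c(2, 13, 9, 2), 2, byrow = TRUE))$p_value # ~0.0009
#' @export
fisherExact <- function(table, b = NULL, c = NULL, d = NULL) {
  tb <- if (is.null(b)) as.matrix(table) else
    matrix(base::c(table, b, c, d), 2, 2, byrow = TRUE)
  if (!all(dim(tb) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tb < 0) || any(tb != round(tb)))
    stop("counts must be non-negative integers")
  if (sum(tb) == 0) stop("at least one nonzero margin is required")
  a <- tb[1, 1]
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ])
  c1 <- sum(tb[, 1]); n <- sum(tb)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n)
    return(list(p_value = 1, table = tb,
                point_probability = 1))
  lp <- function(x) {
    # log hypergeometric point probability of table with [1,1] cell = x
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lp(support)
  lobs <- lp(a)
  p <- sum(exp(logp[logp <= lobs + 1e-7]))
  list(p_value = min(1, p), table = tb, point_probability = exp(lobs))
}
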
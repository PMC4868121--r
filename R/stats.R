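# Statistics layer: empirical p-values, normalized density, exact binomial
# tail, Goodman-Kruskal gamma with shuffle p, partial rank correlation,
# and Holm's step-down adjustment.

#' Empirical p-value from a simulated null
#'
#' \eqn{p = (n + 1) / (m + 1)} where n is the number of simulants at least
#' as extreme as the observation (ties count as extreme) and m is the
#' number of simulants. The smallest attainable value is 1/(m + 1); the
#' p-value can never be 0.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of simulated statistics (nonempty).
#' @param tail \code{"greater"} (count simulants >= observed) or
#'   \code{"less"}.
#' @return An object of class \code{empirical_test}: list with
#'   \code{observed}, \code{n_extreme}, \code{m}, \code{p}, \code{tail}.
#' @export
empirical_p <- function(observed, null_values, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  null_values <- null_values[!is.na(null_values)]
  m <- length(null_values)
  if (m == 0) stop("empty null distribution")
  n_extreme <- if (tail == "greater") sum(null_values >= observed)
               else sum(null_values <= observed)
  structure(list(observed = observed, n_extreme = n_extreme, m = m,
                 p = (n_extreme + 1) / (m + 1), tail = tail),
            class = "empirical_test")
}

#' @export
print.empirical_test <- function(x, ...) {
  cat(sprintf("empirical test (tail=%s): observed %.6g, %d/%d simulants as extreme, p = %.4g\n",
              x$tail, x$observed, x$n_extreme, x$m, x$p))
  invisible(x)
}

#' Normalized density against a simulated null
#'
#' ND = (observed - null mean) / null mean: the fractional excess of the
#' observed density over its dinucleotide-controlled expectation. ND of -1
#' means the observed density is 0 while the expectation is positive. Both
#' enrichment and depletion empirical p-values are reported.
#'
#' @param observed Observed density (fraction).
#' @param null_values Simulated densities.
#' @return An object of class \code{density_result}: list with
#'   \code{observed}, \code{null_mean}, \code{nd}, \code{p_enrich},
#'   \code{p_depletion}, \code{m}. \code{nd} is \code{NA} when the null
#'   mean is not positive.
#' @export
normalized_density <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  mu <- mean(null_values)
  nd <- if (!is.finite(mu) || mu <= 0) NA_real_ else (observed - mu) / mu
  structure(list(observed = observed, null_mean = mu, nd = nd,
                 p_enrich = empirical_p(observed, null_values, "greater")$p,
                 p_depletion = empirical_p(observed, null_values, "less")$p,
                 m = length(null_values)),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("density %.5g vs null mean %.5g: ND = %.4g (enrich p = %.4g, depletion p = %.4g, m = %d)\n",
              x$observed, x$null_mean, x$nd, x$p_enrich, x$p_depletion, x$m))
  invisible(x)
}

#' Exact upper-tail binomial probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, p_0)}.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Success probability.
#' @return Probability.
#' @examples
#' binomial_exact_p(7, 10, 24 / 84)
#' @export
binomial_exact_p <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

.gamma_statistic <- function(x, y) {
  tab <- table(x, y)
  nr <- nrow(tab); nc <- ncol(tab)
  if (nr < 2 || nc < 2) return(list(gamma = NA_real_, C = 0, D = 0))
  # cumulative sums over strictly-greater / strictly-smaller row-col blocks
  below_right <- matrix(0, nr, nc)  # sum of tab[i'>i, j'>j]
  below_left <- matrix(0, nr, nc)   # sum of tab[i'>i, j'<j]
  for (i in seq_len(nr - 1)) {
    rows <- (i + 1):nr
    rs <- colSums(tab[rows, , drop = FALSE])
    cs_right <- rev(cumsum(rev(rs)))        # sum over j' >= j
    below_right[i, ] <- c(cs_right[-1], 0)  # j' > j
    cs_left <- cumsum(rs)
    below_left[i, ] <- c(0, cs_left[-nc])   # j' < j
  }
  C <- sum(tab * below_right)
  D <- sum(tab * below_left)
  g <- if (C + D == 0) NA_real_ else (C - D) / (C + D)
  list(gamma = g, C = C, D = D)
}

#' Goodman-Kruskal gamma with a shuffle-based empirical p-value
#'
#' Gamma is (C - D)/(C + D) over untied pairs, a rank association measure
#' robust to heavy ties. The null is built by shuffling one vector
#' \code{n_shuffles} times; one-tailed empirical p-values in both
#' directions and a two-tailed p on |gamma| are reported, since the tail
#' of interest varies between enrichment and depletion analyses.
#'
#' @param x,y Ordinal vectors of equal length (>= 2).
#' @param n_shuffles Number of shuffles (0 skips the p-value).
#' @param seed Optional integer seed.
#' @return List with \code{gamma}, \code{C}, \code{D}, and (when shuffled)
#'   \code{p_greater}, \code{p_less}, \code{p_two}. \code{gamma} is
#'   \code{NA} when all pairs are tied.
#' @export
gk_gamma <- function(x, y, n_shuffles = 10000, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  obs <- .gamma_statistic(x, y)
  res <- obs
  if (n_shuffles > 0 && !is.na(obs$gamma)) {
    null <- .with_seed(seed,
      vapply(seq_len(n_shuffles),
             function(i) .gamma_statistic(x, sample(y))$gamma, numeric(1)))
    res$p_greater <- empirical_p(obs$gamma, null, "greater")$p
    res$p_less <- empirical_p(obs$gamma, null, "less")$p
    res$p_two <- empirical_p(abs(obs$gamma), abs(null), "greater")$p
  }
  res
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms the three vectors and computes
#' \eqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#' \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}, with a two-sided p-value from the
#' t approximation on n - 3 degrees of freedom. A constant control reduces
#' to the plain rank correlation.
#'
#' @param x,y Numeric vectors.
#' @param control Numeric vector to partial out.
#' @return List with \code{statistic}, \code{p}, \code{n}.
#' @export
partial_rank_correlation <- function(x, y, control) {
  n <- length(x)
  stopifnot(length(y) == n, length(control) == n, n >= 4)
  rx <- rank(x); ry <- rank(y); rz <- rank(control)
  r2 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  rxy <- r2(rx, ry); rxz <- r2(rx, rz); ryz <- r2(ry, rz)
  if (abs(rxz) >= 1 || abs(ryz) >= 1)
    return(list(statistic = NA_real_, p = NA_real_, n = n))
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  df <- n - 3
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(statistic = r, p = p, n = n)
}

#' Holm step-down multiple testing adjustment
#'
#' Adjusted p for the i-th smallest raw p is
#' \eqn{\max_{j \le i} \min(1, (n - j + 1) p_{(j)})}: the step-down
#' Bonferroni with enforced monotonicity, capped at 1.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  p <- p_values
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  ok <- !is.na(p)
  n <- sum(ok)
  if (n <= 1) return(p)
  q <- p[ok]
  o <- order(q)
  adj <- cummax(pmin(1, (n - seq_len(n) + 1) * q[o]))
  q[o] <- adj
  p[ok] <- q
  p
}

#' Rank trend against exon number with small-class exclusion
#'
#' Correlates a per-data-point statistic with (family-averaged, hence
#' possibly fractional) exon number. Data points whose rounded exon-number
#' class has fewer than \code{min_class_size} members are excluded, since
#' sparse classes contribute disproportionate noise to rank trends. Both
#' Spearman's rho and Goodman-Kruskal gamma (with a shuffle p when
#' \code{n_shuffles > 0}) are reported.
#'
#' @param x Numeric statistic per data point (e.g. density or ND).
#' @param exon_number Exon number per data point.
#' @param min_class_size Minimum class occupancy (default 50).
#' @param n_shuffles Shuffles for the gamma empirical p (0 skips it).
#' @param seed Optional integer seed.
#' @return List with \code{n_used}, \code{rho}, \code{p_rho},
#'   \code{gamma} and (when shuffled) \code{p_gamma_greater},
#'   \code{p_gamma_less}.
#' @export
exon_number_trend <- function(x, exon_number, min_class_size = 50,
                              n_shuffles = 0, seed = NULL) {
  stopifnot(length(x) == length(exon_number))
  cls <- round(exon_number)
  keep <- cls %in% as.integer(names(which(table(cls) >= min_class_size)))
  xs <- x[keep]
  es <- exon_number[keep]
  if (length(xs) < 4)
    return(list(n_used = length(xs), rho = NA_real_, p_rho = NA_real_,
                gamma = NA_real_))
  ct <- suppressWarnings(stats::cor.test(xs, es, method = "spearman",
                                         exact = FALSE))
  g <- gk_gamma(xs, es, n_shuffles = n_shuffles, seed = seed)
  out <- list(n_used = length(xs), rho = unname(ct$estimate),
              p_rho = ct$p.value, gamma = g$gamma)
  if (n_shuffles > 0) {
    out$p_gamma_greater <- g$p_greater
    out$p_gamma_less <- g$p_less
  }
  out
}
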
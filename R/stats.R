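#' Range normalization to [0, 1]
#'
#' `(x - min) / (max - min)`: the observed minimum maps to 0 and the maximum
#' to 1. Order statistics are preserved; applying it to data already spanning
#' [0, 1] with observed endpoints 0 and 1 is the identity.
#'
#' @param x numeric vector with at least 2 distinct finite values.
#' @return numeric vector in [0, 1].
#' @examples
#' range_normalize(c(2, 4, 6))
#' @export
range_normalize <- function(x) {
  if (any(!is.finite(x))) stop("values must be finite")
  r <- range(x)
  if (r[1] == r[2]) stop("cannot range-normalize constant input")
  (x - r[1]) / (r[2] - r[1])
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with the standard tie correction,
#' \eqn{H = \left[\frac{12}{N(N+1)}\sum_j R_j^2/n_j - 3(N+1)\right] / C} with
#' \eqn{C = 1 - \sum(t^3 - t)/(N^3 - N)}, compared against a chi-square
#' reference with `k - 1` df.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `statistic` (H), `df`, `p_value`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4))) # H = 2.4
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) < 2L) stop("all values identical; H is degenerate")
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  df <- length(groups) - 1L
  list(statistic = H, df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE), n = N)
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' All pairwise mean-rank comparisons following a Kruskal-Wallis test. The z
#' statistic for groups i, j uses the pooled ranks and the tie-corrected
#' standard error
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#' \frac{\sum(t^3-t)}{12(N-1)}\right)\left(\frac{1}{n_i}+\frac{1}{n_j}\right)}}.
#' Two-sided p-values are Bonferroni-adjusted over the family of pairs:
#' `p_adj = min(1, p * n_pairs)`.
#'
#' @param groups named or unnamed list of numeric vectors (>= 3 groups for a
#'   meaningful family).
#' @return data frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups) {
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  if (k < 3L) stop("Dunn post hoc needs at least 3 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  nms <- names(groups) %||% paste0("g", seq_len(k))
  if (is.null(names(groups))) names(groups) <- nms
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) < 2L) stop("all values identical; ranks are degenerate")
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  nj <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(group1 = nms[pairs[1, ]], group2 = nms[pairs[2, ]],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (m in seq_len(n_pairs)) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nj[i] + 1 / nj[j]))
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$z[m] <- z
    out$p[m] <- p
    out$p_adj[m] <- min(1, p * n_pairs)
  }
  out
}

#' Ordered quantile normalization (rank-based inverse normal transform)
#'
#' Maps values to normal scores \eqn{\Phi^{-1}((r - 0.5)/n)} where r is the
#' (average-tie) rank. The transform is monotone in the input and yields an
#' approximately standard-normal shape for continuous data.
#'
#' @param x numeric vector, length >= 3.
#' @return numeric vector of normal scores.
#' @export
ordered_quantile_normalize <- function(x) {
  if (length(x) < 3L) stop("need at least 3 values")
  if (any(!is.finite(x))) stop("values must be finite")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / length(x))
}

#' Per-distance unpalatability correlations and their distance regression
#'
#' For every pattern statistic and viewing distance, computes the Pearson
#' product-moment correlation R between the species-median statistic
#' (ordered-quantile normalized) and the range-normalized unpalatability u,
#' then fits an ordinary least-squares line through the per-distance R values
#' for each statistic, reporting slope, r-squared, F and p — the summary that
#' shows whether a statistic's association with chemical defence decays with
#' viewing distance.
#'
#' @param records tidy pattern-record table (see [distance_profile()]): one
#'   row per individual x distance with columns `species`, `unpalatability`,
#'   `distance_cm` and the four metric columns.
#' @param metrics which record columns to analyse.
#' @return list with `correlations` (metric, distance_cm, R, n_species) and
#'   `regressions` (metric, slope, intercept, r_squared, F, df1, df2,
#'   p_value).
#' @export
distance_correlation_regression <- function(records,
    metrics = c("lum_boldness", "col_boldness",
                "lum_detectability", "col_detectability")) {
  needed <- c("species", "unpalatability", "distance_cm", metrics)
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records are missing columns: ",
                         paste(miss, collapse = ", "))
  distances <- sort(unique(records$distance_cm))
  sp_u <- tapply(records$unpalatability, records$species, function(v) v[1])
  if (length(sp_u) < 4L) stop("need at least 4 species")
  u_norm <- range_normalize(as.numeric(sp_u))
  names(u_norm) <- names(sp_u)

  cor_rows <- list()
  for (m in metrics) {
    for (d in distances) {
      sub <- records[records$distance_cm == d, ]
      med <- tapply(sub[[m]], sub$species, stats::median, na.rm = TRUE)
      med <- med[names(u_norm)]
      if (length(unique(stats::na.omit(med))) < 2L) {
        warning(sprintf("constant species medians for %s at %g cm; R undefined, distance dropped",
                        m, d))
        next
      }
      ok <- is.finite(med)
      R <- stats::cor(ordered_quantile_normalize(med[ok]), u_norm[ok])
      cor_rows[[length(cor_rows) + 1L]] <-
        data.frame(metric = m, distance_cm = d, R = R, n_species = sum(ok),
                   stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cor_rows)

  reg_rows <- list()
  for (m in metrics) {
    sub <- correlations[correlations$metric == m, ]
    if (nrow(sub) < 3L) {
      warning("fewer than 3 usable distances for ", m, "; regression refused")
      next
    }
    fit <- stats::lm(R ~ distance_cm, data = sub)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      metric = m,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
      p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  list(correlations = correlations, regressions = do.call(rbind, reg_rows))
}

#' Permutation band for a Pearson correlation
#'
#' Two-sided Monte-Carlo null band for `cor(x, y)` obtained by permuting `y`.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_perm number of permutations (default 999).
#' @param level band coverage (default 0.95).
#' @param seed optional RNG seed.
#' @return named numeric `c(lower=, upper=)` quantiles of the permuted R.
#' @export
pearson_permutation_band <- function(x, y, n_perm = 999, level = 0.95,
                                     seed = NULL) {
  stopifnot(length(x) == length(y))
  with_seed(seed, {
    r <- replicate(n_perm, stats::cor(x, sample(y)))
    a <- (1 - level) / 2
    q <- stats::quantile(r, c(a, 1 - a), names = FALSE)
    c(lower = q[1], upper = q[2])
  })
}
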
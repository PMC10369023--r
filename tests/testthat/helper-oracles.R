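# Independent oracles, deliberately written along different code paths than
# the package implementation.

# General n-receptor chromatic delta-S as the classical ratio of pairwise
# sums: dS^2 = sum_{i<j} (prod_{k != i,j} e_k^2) (df_i - df_j)^2 /
#              sum_i prod_{k != i} e_k^2
oracle_chromatic_ds <- function(q_a, q_b, e) {
  n <- length(e)
  df <- log(q_a) - log(q_b)
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + prod(e[-c(i, j)]^2) * (df[i] - df[j])^2
    }
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i]^2), numeric(1)))
  sqrt(num / den)
}

# Two- and three-receptor closed forms written out explicitly.
oracle_ds_dichromat <- function(q_a, q_b, e) {
  df <- log(q_a / q_b)
  abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)
}

oracle_ds_trichromat <- function(q_a, q_b, e) {
  df <- log(q_a / q_b)
  num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
    e[3]^2 * (df[1] - df[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

# Brute-force Kruskal-Wallis H with tie correction, following the textbook
# formula step by step.
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(j) sum(r[g == j])^2 / sum(g == j),
               numeric(1))) - 3 * (N + 1)
  tie_tab <- table(x)
  H / (1 - sum(tie_tab^3 - tie_tab) / (N^3 - N))
}

# Brute-force Dunn z for one pair (i, j).
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  sigma2 <- (N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))) *
    (1 / sum(g == i) + 1 / sum(g == j))
  (mean(r[g == i]) - mean(r[g == j])) / sqrt(sigma2)
}

# Frequency-weight CoV by literal expansion: repeat each value w times and
# take population sd / mean. Only valid for integer weights.
oracle_weighted_cov <- function(values, weights) {
  x <- rep(values, times = weights)
  m <- mean(x)
  sqrt(mean((x - m)^2)) / m
}

# Brute-force LEIA on a small image: double loop over blocks, forward
# neighbours right/down/down-right/down-left, block centre membership at
# offset ceiling(b/2).
oracle_leia <- function(stack, e, omega, mask, b) {
  nc <- dim(stack)[3] - 1L
  nbr <- nrow(mask) %/% b
  nbc <- ncol(mask) %/% b
  bm <- array(NA_real_, c(nbr, nbc, nc + 1L))
  for (I in seq_len(nbr)) for (J in seq_len(nbc)) for (ch in seq_len(nc + 1L)) {
    px <- stack[((I - 1) * b + 1):(I * b), ((J - 1) * b + 1):(J * b), ch]
    inm <- mask[((I - 1) * b + 1):(I * b), ((J - 1) * b + 1):(J * b)]
    bm[I, J, ch] <- if (any(inm)) mean(px[inm]) else NA_real_
  }
  co <- ceiling(b / 2)
  inm <- function(I, J) {
    I >= 1 && I <= nbr && J >= 1 && J <= nbc &&
      mask[(I - 1) * b + co, (J - 1) * b + co]
  }
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  out <- NULL
  for (I in seq_len(nbr)) for (J in seq_len(nbc)) {
    if (!inm(I, J)) next
    chs <- c(); achs <- c()
    for (o in offs) {
      I2 <- I + o[1]; J2 <- J + o[2]
      if (!inm(I2, J2)) next
      qa <- bm[I, J, seq_len(nc)]; qb <- bm[I2, J2, seq_len(nc)]
      chs <- c(chs, oracle_chromatic_ds(qa, qb, e))
      achs <- c(achs, abs(log(bm[I, J, nc + 1] / bm[I2, J2, nc + 1])) / omega)
    }
    if (!length(chs)) next
    out <- rbind(out, data.frame(row = I, col = J, chromatic = mean(chs),
                                 achromatic = mean(achs), weight = length(chs)))
  }
  out
}

# Small random scene helper shared across tests.
tiny_stack <- function(h = 8, w = 8, nc = 3, seed = 1, lo = 0.2, hi = 1) {
  set.seed(seed)
  array(runif(h * w * (nc + 1), lo, hi), c(h, w, nc + 1))
}
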
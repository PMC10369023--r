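#' Mixed-model tests of defence class and viewing distance
#'
#' Fits random-intercept linear mixed models to a pattern-record table, with
#' species as the random effect throughout:
#' \itemize{
#'   \item within each defence class: `t(response) ~ factor(distance_cm) +
#'     (1 | species)` — does the statistic change across the distance grid?
#'   \item at each distance: `t(response) ~ defence_class + (1 | species)` —
#'     do defence classes differ at that distance?
#' }
#' where `t()` is the response transform (default square root, applied to
#' these skewed, non-negative CoV statistics). Returns a type-III-style
#' F table for the single fixed-effect term of each model.
#'
#' Denominator degrees of freedom use a Satterthwaite approximation by
#' default (implemented in-package for the random-intercept case; see the
#' methods vignette) or the simple residual method (`N - p`). A singular fit
#' (species variance estimated at zero) falls back to a fixed-effects ANOVA
#' with a logged note.
#'
#' @param records tidy record table (see [distance_profile()]).
#' @param response which metric column to model.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @return data frame with columns `test`, `group`, `F`, `df1`, `df2`,
#'   `p_value`, `method`.
#' @export
lmm_class_distance <- function(records, response = "lum_detectability",
                               transform = c("sqrt", "none"),
                               df_method = c("satterthwaite", "residual")) {
  transform <- match.arg(transform)
  df_method <- match.arg(df_method)
  needed <- c("species", "defence_class", "distance_cm", response)
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records are missing columns: ",
                         paste(miss, collapse = ", "))
  y_all <- records[[response]]
  if (transform == "sqrt") {
    if (any(y_all < 0, na.rm = TRUE))
      stop("sqrt transform requires a non-negative response")
    y_all <- sqrt(y_all)
  }
  dat <- data.frame(y = y_all,
                    species = factor(records$species),
                    defence_class = factor(records$defence_class),
                    distance_cm = factor(records$distance_cm))
  dat <- dat[stats::complete.cases(dat), ]

  rows <- list()
  for (cl in levels(dat$defence_class)) {
    sub <- droplevels(dat[dat$defence_class == cl, ])
    if (nlevels(sub$species) < 2L || nlevels(sub$distance_cm) < 2L) next
    ft <- fit_term_f(sub, "distance_cm", df_method)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(test = "distance_within_class", group = cl,
                       stringsAsFactors = FALSE), ft)
  }
  for (d in levels(dat$distance_cm)) {
    sub <- droplevels(dat[dat$distance_cm == d, ])
    if (nlevels(sub$species) < 2L || nlevels(sub$defence_class) < 2L) next
    ncl <- table(sub$defence_class[!duplicated(sub$species)])
    if (any(ncl < 2L)) {
      message("distance ", d, ": fewer than 2 species in some class; ",
              "class comparison still fitted, interpret with care")
    }
    ft <- fit_term_f(sub, "defence_class", df_method)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(test = "class_at_distance", group = d,
                       stringsAsFactors = FALSE), ft)
  }
  do.call(rbind, rows)
}

# F test for the single fixed term of y ~ term + (1 | species).
fit_term_f <- function(dat, term, df_method) {
  form <- stats::as.formula(paste("y ~", term, "+ (1 | species)"))
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    message("singular mixed fit (species variance ~ 0); ",
            "falling back to fixed-effects ANOVA")
    lfit <- stats::lm(stats::as.formula(paste("y ~", term)), data = dat)
    a <- stats::anova(lfit)
    return(data.frame(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                      p_value = a$`Pr(>F)`[1], method = "fixed_anova",
                      stringsAsFactors = FALSE))
  }
  X <- stats::model.matrix(stats::as.formula(paste("y ~", term)), dat)
  beta <- lme4::fixef(fit)
  q <- ncol(X) - 1L
  L <- cbind(matrix(0, q, 1), diag(q))
  vc <- lme4::VarCorr(fit)
  vp <- c(as.numeric(vc$species), stats::sigma(fit)^2)

  mach <- ri_machinery(dat$y, X, dat$species)
  C_hat <- mach$C_fun(vp)
  Phi <- L %*% C_hat %*% t(L)
  Lb <- drop(L %*% beta)
  Fstat <- drop(crossprod(Lb, solve(Phi, Lb))) / q

  if (df_method == "residual") {
    df2 <- length(dat$y) - ncol(X)
    return(data.frame(F = Fstat, df1 = q, df2 = df2,
                      p_value = stats::pf(Fstat, q, df2, lower.tail = FALSE),
                      method = "lmm_residual", stringsAsFactors = FALSE))
  }

  df2 <- tryCatch(satterthwaite_df(L, vp, mach), error = function(e) NA_real_)
  if (!is.finite(df2) || df2 <= 0) {
    df2 <- length(dat$y) - ncol(X)
    method <- "lmm_residual_fallback"
  } else method <- "lmm_satterthwaite"
  data.frame(F = Fstat, df1 = q, df2 = df2,
             p_value = stats::pf(Fstat, q, df2, lower.tail = FALSE),
             method = method, stringsAsFactors = FALSE)
}

# Closed-form GLS pieces for a single random-intercept model.
# vp = c(sigma_b^2, sigma^2); V_i = s2 I + sb2 J within each group.
ri_machinery <- function(y, X, g) {
  g <- factor(g)
  idx <- split(seq_along(y), g)
  Xg <- lapply(idx, function(i) X[i, , drop = FALSE])
  yg <- lapply(idx, function(i) y[i])
  XtX_g <- lapply(Xg, crossprod)
  Xt1_g <- lapply(Xg, colSums)
  yty_g <- vapply(yg, function(v) sum(v^2), numeric(1))
  y1_g <- vapply(yg, sum, numeric(1))
  Xty_g <- mapply(function(Xi, yi) drop(crossprod(Xi, yi)),
                  Xg, yg, SIMPLIFY = FALSE)
  ni <- lengths(idx)
  p <- ncol(X)

  pieces <- function(vp) {
    sb2 <- vp[1]; s2 <- vp[2]
    XtViX <- matrix(0, p, p)
    XtViy <- numeric(p)
    ytViy <- 0
    logdetV <- 0
    for (k in seq_along(idx)) {
      ck <- sb2 / (s2 + ni[k] * sb2)
      XtViX <- XtViX + (XtX_g[[k]] - ck * tcrossprod(Xt1_g[[k]])) / s2
      XtViy <- XtViy + (Xty_g[[k]] - ck * Xt1_g[[k]] * y1_g[k]) / s2
      ytViy <- ytViy + (yty_g[k] - ck * y1_g[k]^2) / s2
      logdetV <- logdetV + (ni[k] - 1) * log(s2) + log(s2 + ni[k] * sb2)
    }
    list(XtViX = XtViX, XtViy = XtViy, ytViy = ytViy, logdetV = logdetV)
  }

  list(
    C_fun = function(vp) solve(pieces(vp)$XtViX),
    reml_ll = function(vp) {
      if (vp[2] <= 0) return(-Inf)
      pz <- pieces(vp)
      beta <- solve(pz$XtViX, pz$XtViy)
      quad <- pz$ytViy - drop(crossprod(beta, pz$XtViy))
      -0.5 * (pz$logdetV + determinant(pz$XtViX)$modulus + quad)
    })
}

# Satterthwaite denominator df for the multi-df contrast L, following the
# eigendecomposition-of-Phi construction: per-eigenvector 1-df Satterthwaite
# df combined via nu = 2E / (E - q), E = sum nu_d / (nu_d - 2).
satterthwaite_df <- function(L, vp, mach) {
  W <- solve(-numDeriv::hessian(mach$reml_ll, vp))
  C_hat <- mach$C_fun(vp)
  Phi <- L %*% C_hat %*% t(L)
  q <- nrow(L)
  ev <- eigen(Phi, symmetric = TRUE)
  nu <- numeric(q)
  for (d in seq_len(q)) {
    ell <- drop(crossprod(ev$vectors[, d], L))
    f_d <- function(v) drop(ell %*% mach$C_fun(v) %*% ell)
    gr <- numDeriv::grad(f_d, vp)
    denom <- drop(crossprod(gr, W %*% gr))
    nu[d] <- if (denom > 0) 2 * ev$values[d]^2 / denom else Inf
  }
  usable <- nu > 2
  if (!any(usable)) return(NA_real_)
  E <- sum(nu[usable] / (nu[usable] - 2))
  if (E <= q) return(1e7) # effectively infinite df
  2 * E / (E - q)
}
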
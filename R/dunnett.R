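## Many-to-one (Dunnett) comparisons with Monte Carlo critical values.

#' Monte Carlo critical value for the two-sided Dunnett max-|t| statistic
#'
#' Simulates the null distribution of `max_i |t_i|` for many-to-one
#' comparisons under homogeneous variance: group means are drawn as
#' independent normals with variances `1/n_i`, the pooled variance as
#' `chi^2_df / df`, and the usual t statistics formed against the control.
#' Seeded, hence reproducible and testable.
#'
#' @param n integer vector of group sizes, control first.
#' @param df residual degrees of freedom (`sum(n) - length(n)`).
#' @param alpha familywise two-sided level (default 0.05).
#' @param n_mc Monte Carlo replicates (default 1e5).
#' @param seed RNG seed.
#' @return List with `crit` (the 1 - alpha quantile of max |t|) and
#'   `max_t` (the simulated null sample, for p-value interpolation).
#' @export
dunnett_critical <- function(n, df, alpha = 0.05, n_mc = 1e5, seed = 1) {
  if (length(n) < 2L || any(n < 2L)) stop("need >= 2 groups with n >= 2 each")
  k <- length(n) - 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m0 <- stats::rnorm(n_mc, sd = sqrt(1 / n[1]))
  s <- sqrt(stats::rchisq(n_mc, df) / df)
  maxt <- rep(0, n_mc)
  for (i in seq_len(k)) {
    mi <- stats::rnorm(n_mc, sd = sqrt(1 / n[i + 1L]))
    ti <- abs(mi - m0) / (s * sqrt(1 / n[i + 1L] + 1 / n[1]))
    maxt <- pmax(maxt, ti)
  }
  list(crit = stats::quantile(maxt, 1 - alpha, names = FALSE), max_t = maxt)
}

#' One-way ANOVA with Dunnett's post-test against a control group
#'
#' Two-sided many-to-one comparisons assuming homogeneous variance. The
#' pooled-variance t statistic of each group against the control is referred
#' to a seeded Monte Carlo null of the max-|t| statistic
#' ([dunnett_critical()]); adjusted p-values are the null exceedance
#' probabilities. A one-way ANOVA F-test is reported alongside.
#'
#' @param values numeric response (e.g. relative mRNA levels).
#' @param groups group labels, same length as `values`.
#' @param control control-group label (default `"normoxia"`).
#' @param alpha familywise level (default 0.05).
#' @param n_mc Monte Carlo replicates for the null (default 1e5).
#' @param seed RNG seed for the Monte Carlo null.
#' @return Object of class `dunnett_test`: data frame `comparisons`
#'   (`group`, `diff`, `t`, `p_adj`, `significant`), plus `anova_F`,
#'   `anova_p`, `crit`, `alpha`, `control`.
#' @export
dunnett_vs_control <- function(values, groups, control = "normoxia",
                               alpha = 0.05, n_mc = 1e5, seed = 1) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group '", control, "' not present")
  sp <- split(as.numeric(values), groups)
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2")
  if (length(sp) < 2L) stop("need the control plus at least one other group")
  others <- setdiff(names(sp), control)
  n <- c(ns[control], ns[others])
  N <- sum(ns); kg <- length(sp)
  df <- N - kg
  means <- vapply(sp, mean, numeric(1))
  s2 <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1))) / df

  ## one-way ANOVA F
  grand <- mean(unlist(sp, use.names = FALSE))
  ssb <- sum(ns * (means - grand)^2)
  Fstat <- (ssb / (kg - 1)) / s2
  Fp <- stats::pf(Fstat, kg - 1, df, lower.tail = FALSE)

  mc <- dunnett_critical(n, df, alpha = alpha, n_mc = n_mc, seed = seed)
  tstat <- (means[others] - means[control]) /
    sqrt(s2 * (1 / ns[others] + 1 / ns[control]))
  p_adj <- vapply(abs(tstat), function(tt) mean(mc$max_t >= tt), numeric(1))
  comp <- data.frame(group = others,
                     diff = means[others] - means[control],
                     t = as.numeric(tstat),
                     p_adj = p_adj,
                     significant = p_adj < alpha,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(comparisons = comp, anova_F = Fstat, anova_p = Fp,
                 crit = mc$crit, alpha = alpha, control = control,
                 df = df, pooled_sd = sqrt(s2)),
            class = "dunnett_test")
}

#' @export
print.dunnett_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g (df = %d)\n",
              x$anova_F, x$anova_p, x$df))
  cat(sprintf("Dunnett two-sided vs '%s' (alpha = %g, |t| crit = %.3f):\n",
              x$control, x$alpha, x$crit))
  print(x$comparisons, digits = 4)
  invisible(x)
}
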
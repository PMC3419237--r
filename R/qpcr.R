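## qPCR: Cp calling, per-reaction efficiency, efficiency-corrected relative
## quantification against an exogenous external standard (mw2060).

.as_curve <- function(curve) {
  if (is.data.frame(curve)) {
    if (!all(c("cycle", "fluorescence") %in% names(curve)))
      stop("curve data frame needs columns 'cycle' and 'fluorescence'")
    list(cycle = as.numeric(curve$cycle),
         fluorescence = as.numeric(curve$fluorescence))
  } else if (is.numeric(curve)) {
    list(cycle = seq_along(curve), fluorescence = as.numeric(curve))
  } else stop("'curve' must be a numeric vector or a data frame")
}

#' Call the crossing point (Cp) of an amplification curve
#'
#' Second-derivative-maximum Cp. The curve is smoothed with a
#' Savitzky-Golay filter (window 5, order 2) and the second-derivative
#' maximum is localised from the same filter's curvature estimate; the
#' sub-cycle position is then refined by fitting a four-parameter logistic
#' (baseline + plateau sigmoid) around the transition and taking the
#' model's closed-form second-derivative maximum
#' `c0 - s * log(2 + sqrt(3))`, which removes the discretisation bias a
#' sampled curvature maximum carries at unit cycle spacing. If the sigmoid
#' fit fails the spline-interpolated curvature maximum is used instead.
#' Invariant to multiplicative rescaling of the fluorescence and
#' equivariant under cycle shifts.
#'
#' @param curve numeric fluorescence vector (cycles 1..n) or a data frame
#'   with columns `cycle` and `fluorescence`; at least 20 cycles.
#' @param min_rise minimum fold-rise of the plateau over baseline for the
#'   curve to count as amplified (default 3).
#' @return Cp, in (sub-)cycles.
#' @export
call_cp <- function(curve, min_rise = 3) {
  cv <- .as_curve(curve)
  y <- cv$fluorescence; cyc <- cv$cycle
  if (length(y) < 20L) stop("amplification curve needs at least 20 cycles")
  if (any(y < 0)) stop("negative fluorescence")
  base <- stats::median(y[seq_len(5L)])
  if (base <= 0) base <- max(base, 1e-12)
  if (max(y) < min_rise * base)
    stop("no amplification detected (rise below ", min_rise, "-fold over baseline)")
  ys <- signal::sgolayfilt(y, p = 2, n = 5)
  d2 <- signal::sgolayfilt(y, p = 2, n = 5, m = 2)
  interior <- 3:(length(y) - 2L)  # SG endpoints are extrapolations
  i0 <- interior[which.max(d2[interior])]
  if (i0 <= min(cyc) + 1 || i0 >= max(cyc) - 2)
    stop("no amplification detected (second-derivative maximum at curve edge)")

  ## sub-cycle refinement: local sigmoid model with analytic SDM
  amp <- max(ys) - min(ys)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ b + a / (1 + exp(-(cyc - c0) / s)),
    start = list(b = min(ys), a = amp, c0 = cyc[i0] + 1.3, s = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    if (cf[["a"]] > 0 && cf[["s"]] > 0.05 && cf[["s"]] < 10) {
      cp <- cf[["c0"]] - cf[["s"]] * log(2 + sqrt(3))
      if (cp > min(cyc) && cp < max(cyc)) return(cp)
    }
  }
  sp <- stats::spline(cyc[interior], d2[interior], n = 50L * length(interior))
  sp$x[which.max(sp$y)]
}

#' Per-reaction amplification efficiency
#'
#' Sliding-window estimate in the LinReg spirit: after subtracting a
#' baseline (mean of the first five cycles), the best window of 4-6
#' consecutive cycles within the exponential phase is chosen by maximum
#' R-squared of the regression of log10 fluorescence on cycle, and
#' `E = 10^slope`. When the curve has reached its plateau, the regression
#' uses plateau-corrected values `W / (1 - W / plateau)` -- exactly
#' exponential for a logistic curve -- so the bend below the plateau does
#' not bias the slope downwards. Efficiencies outside (1, 2.1] are flagged
#' as `NA`.
#'
#' @inheritParams call_cp
#' @param window_sizes candidate window lengths (default `4:6`).
#' @return Efficiency E (fold per cycle), or `NA` with a warning when the
#'   estimate falls outside (1, 2.1].
#' @export
estimate_efficiency <- function(curve, window_sizes = 4:6) {
  cv <- .as_curve(curve)
  y <- cv$fluorescence; cyc <- cv$cycle
  if (length(y) < 20L) stop("amplification curve needs at least 20 cycles")
  base <- mean(y[seq_len(5L)])
  w <- y - base
  top <- max(w)
  n <- length(w)
  if (top <= 0) stop("no exponential phase present")
  noise <- max(stats::sd(y[seq_len(5L)]), 1e-12)
  ## plateau reached if the curve has flattened by its end; only then is the
  ## logistic plateau correction valid
  plateaued <- (w[n] - w[n - 3L]) < 0.05 * top
  lo <- max(3 * noise, 1e-3 * top)
  usable <- which(w > lo & w < 0.5 * top)
  if (length(usable) < min(window_sizes)) stop("no exponential phase present")
  ly <- if (plateaued) log10(w[usable] / (1 - w[usable] / top))
        else log10(w[usable])
  cx <- cyc[usable]
  best <- list(r2 = -Inf, slope = NA_real_)
  for (k in window_sizes) {
    if (length(usable) < k) next
    for (i in seq_len(length(usable) - k + 1L)) {
      idx <- i:(i + k - 1L)
      if (any(diff(cx[idx]) != 1)) next  # windows must be consecutive cycles
      fit <- stats::lm.fit(cbind(1, cx[idx]), ly[idx])
      res <- fit$residuals
      tss <- sum((ly[idx] - mean(ly[idx]))^2)
      r2 <- if (tss > 0) 1 - sum(res^2) / tss else -Inf
      if (r2 > best$r2) best <- list(r2 = r2, slope = fit$coefficients[2])
    }
  }
  if (!is.finite(best$slope)) stop("no exponential phase present")
  E <- unname(10^best$slope)
  if (E <= 1 || E > 2.1) {
    warning("estimated efficiency ", format(E, digits = 3),
            " outside (1, 2.1]; flagged as NA")
    return(NA_real_)
  }
  E
}

#' Mean efficiency over reactions
#'
#' Mean of per-reaction efficiencies, silently excluding flagged (`NA`)
#' values; the per-gene, per-tissue mean is what enters relative
#' quantification.
#'
#' @param curves list of amplification curves (see [estimate_efficiency()]).
#' @return Mean efficiency.
#' @export
mean_efficiency <- function(curves) {
  es <- vapply(curves, function(cv)
    tryCatch(suppressWarnings(estimate_efficiency(cv)),
             error = function(e) NA_real_), numeric(1))
  if (all(is.na(es))) stop("no usable efficiency estimates")
  mean(es, na.rm = TRUE)
}

#' Efficiency-corrected relative mRNA level
#'
#' `E_std^Cp_std / E_tar^Cp_tar`, normalising the target gene to the
#' exogenous external standard spiked at a fixed amount per mg tissue.
#' Efficiencies are the per-primer-pair, per-tissue means; Cp values are
#' means of duplicate reactions.
#'
#' @param E_std,E_tar amplification efficiencies in (1, 2.1].
#' @param Cp_std,Cp_tar crossing points (cycles).
#' @return Dimensionless relative level; vectorised.
#' @export
#' @examples
#' relative_level(2, 20, 2, 21)   # 0.5
relative_level <- function(E_std, Cp_std, E_tar, Cp_tar) {
  if (any(E_std <= 1 | E_std > 2.1) || any(E_tar <= 1 | E_tar > 2.1))
    stop("efficiencies must lie in (1, 2.1]")
  exp(Cp_std * log(E_std) - Cp_tar * log(E_tar))
}

#' Relative levels for a whole Cp table
#'
#' Averages duplicate Cp values (flagging pairs that differ by more than
#' one cycle), joins the tissue-matched primer efficiencies and normalises
#' every target gene to the external standard within each sample.
#'
#' @param cp_table data frame with columns `sample_id`, `group`, `tissue`,
#'   `gene`, `cp1`, `cp2` (one row per sample x gene; `cp2` may be `NA` for
#'   singleton reactions).
#' @param efficiencies data frame with columns `gene`, `tissue`, `E`.
#' @param normalizer name of the external-standard gene (default
#'   `"mw2060"`); must be present for every sample.
#' @return Data frame `sample_id`, `group`, `tissue`, `gene`, `level`,
#'   `flagged` (discordant duplicates in target or normaliser).
#' @export
qpcr_relative_levels <- function(cp_table, efficiencies,
                                 normalizer = "mw2060") {
  need <- c("sample_id", "group", "tissue", "gene", "cp1", "cp2")
  if (!all(need %in% names(cp_table)))
    stop("cp_table needs columns: ", paste(need, collapse = ", "))
  if (!all(c("gene", "tissue", "E") %in% names(efficiencies)))
    stop("efficiencies needs columns gene, tissue, E")
  cp <- cp_table
  cps <- cbind(cp$cp1, cp$cp2)
  if (any(cps <= 0 | cps >= 42, na.rm = TRUE))
    warning("Cp values outside (0, 42); check the cycler run length")
  cp$cp_mean <- rowMeans(cps, na.rm = TRUE)
  cp$flagged <- !is.na(cp$cp2) & abs(cp$cp1 - cp$cp2) >= 1

  ekey <- paste(efficiencies$gene, efficiencies$tissue, sep = "\r")
  getE <- function(gene, tissue) {
    i <- match(paste(gene, tissue, sep = "\r"), ekey)
    if (any(is.na(i)))
      stop("missing efficiency for ",
           paste(unique(paste(gene, tissue)[is.na(i)]), collapse = ", "))
    efficiencies$E[i]
  }

  std <- cp[cp$gene == normalizer, ]
  if (!nrow(std)) stop("normalizer gene '", normalizer, "' absent from cp_table")
  skey <- paste(std$sample_id, std$tissue, sep = "\r")
  tar <- cp[cp$gene != normalizer, ]
  i <- match(paste(tar$sample_id, tar$tissue, sep = "\r"), skey)
  if (any(is.na(i)))
    stop("normalizer '", normalizer, "' missing for sample(s): ",
         paste(unique(tar$sample_id[is.na(i)]), collapse = ", "))
  E_std <- getE(normalizer, tar$tissue)
  E_tar <- getE(tar$gene, tar$tissue)
  lv <- relative_level(E_std, std$cp_mean[i], E_tar, tar$cp_mean)
  data.frame(sample_id = tar$sample_id, group = tar$group,
             tissue = tar$tissue, gene = tar$gene, level = lv,
             flagged = tar$flagged | std$flagged[i],
             stringsAsFactors = FALSE)
}

#' Group mean and standard error
#'
#' @param levels data frame of relative levels (e.g. from
#'   [qpcr_relative_levels()]).
#' @param value name of the value column (default `"level"`).
#' @param group name of the grouping column (default `"group"`).
#' @return Data frame with `group`, `n`, `mean`, `sem` (NA for n = 1).
#' @export
group_summary <- function(levels, value = "level", group = "group") {
  if (!all(c(value, group) %in% names(levels)))
    stop("columns '", value, "' and '", group, "' required")
  sp <- split(levels[[value]], levels[[group]])
  if (any(vapply(sp, length, integer(1)) == 0L)) stop("empty group")
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
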
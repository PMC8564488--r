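#' Per-gene two-group fit
#'
#' Ordinary least squares for the simple two-group design: per gene the log2
#' fold change (case minus control mean), pooled within-group variance,
#' residual degrees of freedom and the standard-error unit
#' `sqrt(1/n_case + 1/n_control)`. Genes with missing values are dropped from
#' the fit (with a message).
#'
#' @param study an [expression_study()] on the log2 scale.
#' @param ctr a [contrast()]; both labels need >= 2 samples in the study.
#' @return data.frame with columns `gene`, `log2_fc`, `s2`, plus attributes
#'   `df_resid`, `se_unit`, `n_case`, `n_control`.
#' @export
fit_two_group <- function(study, ctr) {
  stopifnot(inherits(study, "expression_study"), inherits(ctr, "contrast"))
  case_cols <- names(study$phenotype)[study$phenotype == ctr$case_label]
  ctrl_cols <- names(study$phenotype)[study$phenotype == ctr$control_label]
  if (length(case_cols) < 2)
    stop(sprintf("group '%s' has fewer than 2 samples", ctr$case_label),
         call. = FALSE)
  if (length(ctrl_cols) < 2)
    stop(sprintf("group '%s' has fewer than 2 samples", ctr$control_label),
         call. = FALSE)
  x <- study$values[, c(case_cols, ctrl_cols), drop = FALSE]
  miss <- rowSums(is.na(x)) > 0
  if (any(miss)) {
    message(sprintf("study %s: dropped %d gene(s) with missing values",
                    study$study_id, sum(miss)))
    x <- x[!miss, , drop = FALSE]
  }
  n1 <- length(case_cols); n2 <- length(ctrl_cols)
  xc <- x[, seq_len(n1), drop = FALSE]
  xk <- x[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xk)
  ss1 <- rowSums((xc - m1)^2); ss2 <- rowSums((xk - m2)^2)
  df_resid <- n1 + n2 - 2L
  out <- data.frame(gene = rownames(x), log2_fc = m1 - m2,
                    s2 = (ss1 + ss2) / df_resid,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_resid") <- df_resid
  attr(out, "se_unit") <- sqrt(1 / n1 + 1 / n2)
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  out
}

# Invert trigamma(d0/2) = v by monotone bisection for d0 in (0.1, 500].
# Returns Inf when v is below trigamma(250) (no positive excess variability)
# and the lower cap when v exceeds trigamma(0.05).
trigamma_inverse_d0 <- function(v) {
  lo <- 0.1; hi <- 500
  if (v <= trigamma(hi / 2)) return(Inf)
  if (v >= trigamma(lo / 2)) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > v) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits the hierarchical variance model in which sample variances follow a
#' scaled F distribution around a prior variance `s0_sq` with prior degrees
#' of freedom `d0`, by moment matching on `log(s2)`: the mean and variance of
#' `log(s2)` are equated to their closed forms under the model
#' (`Var[log s2] = trigamma(df/2) + trigamma(d0/2)`), and `d0` is recovered
#' by inverting the trigamma equation. When the observed variance of
#' `log(s2)` does not exceed the `df`-only sampling term, `d0 = Inf` is
#' declared and the prior variance is moment-matched on the raw scale
#' (`s0_sq = mean(s2)`, exact when the variances are identical). With fewer
#' than 10 genes with positive variance, moderation is skipped (`d0 = 0`)
#' with a warning.
#'
#' @param s2 per-gene sample variances.
#' @param df_resid residual degrees of freedom (scalar).
#' @return list with `d0`, `s0_sq` and `s2_post`, the posterior variances
#'   `(d0*s0_sq + df_resid*s2) / (d0 + df_resid)`.
#' @export
ebayes_moderate <- function(s2, df_resid) {
  df_resid <- df_resid[1]
  pos <- is.finite(s2) & s2 > 0
  if (sum(pos) < 10) {
    warning("fewer than 10 genes with positive variance; moderation skipped (d0 = 0)")
    return(list(d0 = 0, s0_sq = NA_real_, s2_post = s2))
  }
  z <- log(s2[pos])
  mz <- mean(z)
  vz <- var(z)
  excess <- vz - trigamma(df_resid / 2)
  d0 <- trigamma_inverse_d0(excess)
  if (is.infinite(d0)) {
    s0_sq <- mean(s2[pos])
    s2_post <- rep(s0_sq, length(s2))
  } else {
    s0_sq <- exp(mz - digamma(df_resid / 2) + log(df_resid / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
}

#' Moderated t-statistics and p-values
#'
#' `t_mod = log2_fc / (sqrt(s2_post) * se_unit)` referred to a Student-t
#' distribution with `df_total = df_resid + d0` degrees of freedom (standard
#' normal when `df_total` is infinite). Degenerate zero posterior variances
#' give p = 0 for a non-zero fold change and p = 1 otherwise.
#'
#' @param log2_fc,s2_post per-gene effect and posterior variance.
#' @param se_unit standard-error unit from [fit_two_group()].
#' @param df_total total degrees of freedom.
#' @return data.frame with `t_mod` and `p`.
#' @export
moderated_t <- function(log2_fc, s2_post, se_unit, df_total) {
  se <- sqrt(s2_post) * se_unit
  t_mod <- ifelse(se > 0, log2_fc / se,
                  ifelse(log2_fc == 0, 0, sign(log2_fc) * Inf))
  p <- ifelse(is.finite(t_mod),
              2 * pt(-abs(t_mod), df = df_total),
              0)
  p[t_mod == 0 & se == 0] <- 1
  data.frame(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector; input is validated to lie in
#' [0, 1].
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Per-study moderated differential expression
#'
#' The full within-study stage: two-group fit, empirical-Bayes variance
#' moderation, moderated t-statistics and BH adjustment.
#'
#' @param study an [expression_study()] (log2 scale, normalized).
#' @param ctr a [contrast()].
#' @param moderate set `FALSE` to force `d0 = 0` (classical pooled t-test).
#' @return a `de_result` data.frame with columns `gene`, `log2_fc`, `s2`,
#'   `s2_post`, `t_mod`, `df_total`, `p`, `p_adj`; attributes `study_id`,
#'   `d0`, `s0_sq`, `df_resid`, `se_unit`.
#' @export
run_de <- function(study, ctr, moderate = TRUE) {
  fit <- fit_two_group(study, ctr)
  df_resid <- attr(fit, "df_resid")
  se_unit <- attr(fit, "se_unit")
  if (moderate) {
    eb <- ebayes_moderate(fit$s2, df_resid)
  } else {
    eb <- list(d0 = 0, s0_sq = NA_real_, s2_post = fit$s2)
  }
  df_total <- df_resid + eb$d0
  mt <- moderated_t(fit$log2_fc, eb$s2_post, se_unit, df_total)
  out <- data.frame(gene = fit$gene, log2_fc = fit$log2_fc, s2 = fit$s2,
                    s2_post = eb$s2_post, t_mod = mt$t_mod,
                    df_total = df_total, p = mt$p,
                    p_adj = bh_adjust(mt$p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "study_id") <- study$study_id
  attr(out, "d0") <- eb$d0
  attr(out, "s0_sq") <- eb$s0_sq
  attr(out, "df_resid") <- df_resid
  attr(out, "se_unit") <- se_unit
  class(out) <- c("de_result", "data.frame")
  out
}
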
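#' Per-group sample of a per-cell metric
#'
#' @param label Group label (e.g. `"CTRL"`).
#' @param values Per-cell metric values.
#' @param n_hearts Number of hearts contributing cells (carried through for
#'   reporting only; tests operate at the cell level).
#' @return A `group_sample` list.
#' @export
group_sample <- function(label, values, n_hearts = NA_integer_) {
  values <- as.numeric(values)
  abort_if(any(!is.finite(values)), "metric values must be finite")
  structure(list(label = label, values = values,
                 n_cells = length(values), n_hearts = n_hearts),
            class = "group_sample")
}

.sample_values <- function(x) {
  if (inherits(x, "group_sample")) x$values else as.numeric(x)
}

#' Welch's unequal-variance t test for a group-mean difference
#'
#' @param a,b Numeric vectors or [group_sample()]s.
#' @return List: `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`.
#' @export
welch_test <- function(a, b) {
  a <- .sample_values(a); b <- .sample_values(b)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted step-down multiplication with cumulative-max monotonization,
#' returned in the original order, with verdicts at `alpha`.
#'
#' @param p_values Raw p-values.
#' @param alpha Significance level.
#' @return List: `adjusted`, `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}

#' Two one-sided tests (TOST) for equivalence with relative bounds
#'
#' Relevance bounds are set to `relative_bound` times the magnitude of the
#' control-group mean: the effect (treated minus control mean) is tested
#' against `-Delta_L` from below and `+Delta_U` from above with one-sided
#' Welch t tests. The groups are equivalent when both one-sided tests reject
#' at `alpha` - equivalently, when the `1 - 2 alpha` confidence interval of
#' the effect lies inside `(-Delta_L, Delta_U)`.
#'
#' Note that anchoring the margin on the observed control mean makes the
#' margin itself random; at the exact equivalence boundary this is mildly
#' anti-conservative. Pass fixed `bounds` (e.g. from a known reference
#' level) where strict size control matters, as the calibration
#' simulations do.
#'
#' @param control,treated Numeric vectors or [group_sample()]s; the bounds
#'   anchor on the control mean.
#' @param relative_bound Relative relevance threshold (0.30 = 30%).
#' @param alpha One-sided level.
#' @param bounds Optional fixed margin overriding the relative computation:
#'   a single positive number `delta` (bounds `(-delta, +delta)`).
#' @return List of class `equivalence_result`: `delta_lower`, `delta_upper`,
#'   `effect`, `ci` (1 - 2 alpha), `p_lower`, `p_upper`, `alpha`,
#'   `equivalent`, `control_mean`.
#' @export
tost_equivalence <- function(control, treated, relative_bound = 0.30,
                             alpha = 0.05, bounds = NULL) {
  a <- .sample_values(control); b <- .sample_values(treated)
  abort_if(length(a) < 2 || length(b) < 2,
           "need at least two cells per group")
  m_a <- mean(a)
  delta <- if (!is.null(bounds)) {
    abort_if(bounds <= 0, "fixed bound must be positive")
    bounds
  } else {
    abort_if(m_a == 0,
             "control mean is zero: relative equivalence bounds undefined")
    relative_bound * abs(m_a)
  }
  effect <- mean(b) - m_a
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se <- sqrt(va + vb)
  abort_if(se == 0, "zero variance in both groups: t tests undefined")
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_upper <- stats::pt((effect - delta) / se, df)              # H0: effect >= +Delta_U
  p_lower <- stats::pt((effect + delta) / se, df, lower.tail = FALSE)  # H0: effect <= -Delta_L
  tcrit <- stats::qt(1 - alpha, df)
  ci <- c(effect - tcrit * se, effect + tcrit * se)
  structure(list(delta_lower = -delta, delta_upper = delta,
                 effect = effect, ci = ci,
                 p_lower = p_lower, p_upper = p_upper, alpha = alpha,
                 equivalent = max(p_lower, p_upper) < alpha,
                 control_mean = m_a, relative_bound = relative_bound),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "<equivalence_result> effect %.4g, CI [%.4g, %.4g], bounds (%.4g, %.4g)\n  p_lower = %.3g, p_upper = %.3g -> %s\n",
    x$effect, x$ci[1], x$ci[2], x$delta_lower, x$delta_upper,
    x$p_lower, x$p_upper,
    if (x$equivalent) "EQUIVALENT" else "not equivalent"))
  invisible(x)
}

#' Mean of technical replicates
#'
#' The per-isolation representative value is the mean of the technical
#' replicate counts (five in the study's counting protocol).
#'
#' @param values Replicate measurements.
#' @return Their mean.
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  abort_if(length(values) < 1 || any(!is.finite(values)),
           "need at least one finite replicate")
  mean(values)
}

#' Pearson correlation of two paired per-cell metrics
#'
#' @param x,y Paired numeric vectors.
#' @return List: `r`, `p` (two-sided), `n`.
#' @export
correlate <- function(x, y) {
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Upper bound on troponin release and damage fraction
#'
#' With supernatant troponin below the assay detection limit, the released
#' amount is at most `detection_limit * volume`; relative to the total heart
#' troponin content this bounds the fraction of damaged cardiomyocytes.
#'
#' @param detection_limit Assay detection limit, ug/L.
#' @param volume Storage-solution volume, L.
#' @param total_content Total troponin content per heart, ug (optional).
#' @return List of class `troponin_estimate`: `detection_limit`, `volume`,
#'   `released_upper_bound` (ug), `total_content`,
#'   `damage_fraction_upper_bound` (NA without `total_content`).
#' @export
troponin_release_bound <- function(detection_limit, volume,
                                   total_content = NULL) {
  abort_if(detection_limit < 0, "detection limit must be >= 0")
  abort_if(volume <= 0, "volume must be positive")
  bound <- detection_limit * volume
  frac <- NA_real_
  if (!is.null(total_content)) {
    abort_if(total_content <= 0, "total content must be positive")
    frac <- bound / total_content
  }
  structure(list(detection_limit = detection_limit, volume = volume,
                 released_upper_bound = bound,
                 total_content = total_content %||% NA_real_,
                 damage_fraction_upper_bound = frac),
            class = "troponin_estimate")
}

#' Welch + TOST table over a tidy per-cell metric data frame
#'
#' For every metric, compares each non-control group against the control:
#' Welch two-sided p (Holm-adjusted across the comparisons of that metric
#' when more than one), and the TOST verdict with relative bounds.
#'
#' @param data Data frame with columns `group`, `metric`, `value`.
#' @param control Control group label.
#' @param relative_bound,alpha TOST parameters.
#' @return Data frame, one row per metric and comparison group.
#' @export
equivalence_table <- function(data, control = "CTRL",
                              relative_bound = 0.30, alpha = 0.05) {
  stopifnot(all(c("group", "metric", "value") %in% names(data)))
  abort_if(!control %in% data$group, "control group '%s' absent", control)
  out <- NULL
  for (m in unique(data$metric)) {
    dm <- data[data$metric == m, ]
    ctrl <- dm$value[dm$group == control]
    others <- setdiff(unique(dm$group), control)
    rows <- lapply(others, function(g) {
      trt <- dm$value[dm$group == g]
      wt <- welch_test(ctrl, trt)
      eq <- tost_equivalence(ctrl, trt, relative_bound, alpha)
      data.frame(metric = m, group = g, control = control,
                 n_control = length(ctrl), n_group = length(trt),
                 control_mean = wt$mean_a, group_mean = wt$mean_b,
                 effect = eq$effect, welch_p = wt$p,
                 tost_p = max(eq$p_lower, eq$p_upper),
                 equivalent = eq$equivalent)
    })
    block <- do.call(rbind, rows)
    block$welch_p_holm <- holm_bonferroni(block$welch_p, alpha)$adjusted
    out <- rbind(out, block)
  }
  rownames(out) <- NULL
  out
}
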
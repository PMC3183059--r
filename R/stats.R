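## Group comparisons used in developmental respirometry: one-way ANOVA with
## the Student-Newman-Keuls (SNK) step-down multiple-comparison procedure,
## one-sample t tests against zero, and titration dose selection.
##
## SNK: groups are ordered by mean; the pair spanning r ranks is compared
## through the studentized range q = |m_i - m_j| / sqrt(MSE / n_h) against
## q(alpha, r, df_error), with n_h the harmonic mean of the pair's sizes.
## A span declared non-significant blocks every pair inside it from being
## tested (the non-testing rule), so declared groups are contiguous.

#' One-way ANOVA with Student-Newman-Keuls post hoc comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2),
#'   or a data frame with columns `value` and `group`.
#' @param alpha family significance level (default 0.05).
#' @return A `group_comparison` object: per-group summary (`n`, `mean`,
#'   `sem`), ANOVA `F`/`p`, the pairwise table (`q`, `r` ranks spanned,
#'   `critical_q`, `tested`, `significant`), a symmetric significance
#'   matrix, homogeneous-subset letters, and a `degenerate` flag (zero
#'   within-group variance with unequal means).
#' @export
anova_snk <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2)
    abort("need at least 2 groups", "fluxdeconv_input_error")
  ns <- lengths(groups)
  if (any(ns < 2))
    abort("every group needs n >= 2", "fluxdeconv_input_error")
  labels <- names(groups) %||% as.character(seq_along(groups))
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(labels, ns), levels = labels))
  fit <- aov(value ~ group, data = dat)
  ## near-zero residual variance is detected and flagged below; silence the
  ## stock perfect-fit warning so degenerate inputs surface through the flag
  an <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  Fval <- an["group", "F value"]
  pval <- an["group", "Pr(>F)"]
  means <- vapply(groups, mean, 0)
  sems <- vapply(groups, function(v) sd(v) / sqrt(length(v)), 0)
  tot_var <- var(dat$value)
  degenerate <- !is.finite(Fval) ||
    (tot_var > 0 && mse <= 1e-10 * tot_var) ||
    (tot_var == 0)
  if (degenerate && mse <= 1e-10 * tot_var) {
    Fval <- if (var(means) > 0) Inf else NaN
    pval <- if (var(means) > 0) 0 else NA_real_
  }

  ord <- order(means)
  k <- length(groups)
  m_s <- means[ord]
  n_s <- ns[ord]
  lab_s <- labels[ord]

  pairs <- list()
  false_spans <- list()   # non-significant spans; their interiors are blocked
  sig <- matrix(FALSE, k, k, dimnames = list(lab_s, lab_s))
  for (r in k:2) {
    for (i in 1:(k - r + 1)) {
      j <- i + r - 1
      blocked <- any(vapply(false_spans, function(s)
        s[1] <= i && j <= s[2], TRUE))
      n_h <- 2 / (1 / n_s[i] + 1 / n_s[j])
      se <- sqrt(mse / n_h)
      d <- m_s[j] - m_s[i]
      q <- if (d == 0) 0 else if (se == 0) Inf else d / se
      crit <- qtukey(1 - alpha, nmeans = r, df = max(df_err, 1))
      significant <- !blocked && q >= crit
      if (!blocked && q < crit) false_spans <- c(false_spans, list(c(i, j)))
      sig[i, j] <- sig[j, i] <- significant
      pairs[[length(pairs) + 1]] <- data.frame(
        group1 = lab_s[i], group2 = lab_s[j], diff = d, q = q, r = r,
        critical_q = crit, tested = !blocked, significant = significant,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)

  ## homogeneous subsets: maximal runs of sorted means with no significant
  ## pair inside; SNK blocking keeps these contiguous
  subsets <- list()
  for (i in 1:k) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    subsets[[i]] <- c(i, j)
  }
  subsets <- unique(subsets)
  keep <- vapply(seq_along(subsets), function(a)
    !any(vapply(seq_along(subsets), function(b)
      a != b && subsets[[b]][1] <= subsets[[a]][1] &&
        subsets[[a]][2] <= subsets[[b]][2], TRUE)), TRUE)
  subsets <- subsets[keep]
  letters_s <- setNames(rep("", k), lab_s)
  for (s in seq_along(subsets)) {
    idx <- subsets[[s]][1]:subsets[[s]][2]
    letters_s[idx] <- paste0(letters_s[idx], letters[s])
  }

  structure(list(
    summary = data.frame(group = labels, n = as.integer(ns), mean = means,
                         sem = sems, row.names = NULL,
                         stringsAsFactors = FALSE),
    anova = list(F = Fval, df = c(k - 1, df_err), p = pval),
    alpha = alpha, mse = mse,
    pairs = pairs, significance = sig,
    letters = letters_s[labels],
    degenerate = degenerate
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p,
              if (x$degenerate) "  [degenerate: zero within-group variance]"
              else ""))
  s <- x$summary
  s$mean <- signif(s$mean, 4)
  s$sem <- signif(s$sem, 3)
  s$letters <- x$letters[s$group]
  print(s, row.names = FALSE)
  nsig <- sum(x$pairs$significant)
  cat(sprintf("SNK at alpha = %g: %d of %d pairs significant\n",
              x$alpha, nsig, nrow(x$pairs)))
  invisible(x)
}

#' Does a significant pair exist between two groups?
#'
#' @param comparison a [anova_snk()] result.
#' @param group1,group2 group labels.
#' @return Logical.
#' @export
is_significant_pair <- function(comparison, group1, group2) {
  comparison$significance[as.character(group1), as.character(group2)]
}

#' One-sample t test of mean zero
#'
#' @param values numeric, n >= 2, non-zero variance.
#' @param alpha significance level.
#' @return List: `t`, `df`, `p`, `significant`, `mean`, `n`.
#' @export
t_test_vs_zero <- function(values, alpha = 0.05) {
  if (length(values) < 2)
    abort("need n >= 2 for a t test", "fluxdeconv_input_error")
  if (var(values) == 0)
    abort("zero variance: t statistic undefined", "fluxdeconv_input_error")
  tt <- t.test(values, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha,
       mean = mean(values), n = length(values))
}

#' Select the working dose from a titration curve
#'
#' Among non-lethal doses, returns the smallest dose whose absolute
#' respiration change is within `tolerance` of the non-lethal maximum --
#' the concentration producing the maximum change in respiration without
#' inducing death.
#'
#' @param curve a `titration_curve` (data frame with `dose`, `response`,
#'   `dead`).
#' @param tolerance relative tolerance on the maximal response (default
#'   0.05).
#' @return Selected dose, with attribute `response`.
#' @export
select_titration_dose <- function(curve, tolerance = 0.05) {
  if (nrow(curve) < 2)
    abort("need at least 2 titration doses", "fluxdeconv_input_error")
  alive <- curve[!curve$dead, , drop = FALSE]
  if (nrow(alive) == 0)
    abort("all doses lethal: no usable concentration",
          "fluxdeconv_input_error")
  if (all(is.na(alive$response)))
    abort("no responses recorded", "fluxdeconv_input_error")
  resp <- abs(alive$response)
  top <- max(resp, na.rm = TRUE)
  ok <- which(resp >= (1 - tolerance) * top)
  pick <- ok[which.min(alive$dose[ok])]
  structure(alive$dose[pick], response = alive$response[pick])
}
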
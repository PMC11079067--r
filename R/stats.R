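## Predictor-evaluation battery: logistic screening, stepwise selection,
## ROC/AUC with Youden cutoffs, paired AUC comparison, group comparisons.

logistic_row <- function(fit, term, variable, n, analysis, status = "ok") {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co))
    return(data.frame(variable = variable, n = n, odds_ratio = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, analysis = analysis,
                      status = "dropped"))
  b <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  data.frame(variable = variable, n = n,
             odds_ratio = exp(b),
             ci_low = exp(b - stats::qnorm(0.975) * se),
             ci_high = exp(b + stats::qnorm(0.975) * se),
             p_value = co[term, "Pr(>|z|)"],
             analysis = analysis, status = status)
}

fit_logistic <- function(df) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, separation = sep)
}

#' Univariate logistic screening of one predictor of hearing preservation
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 x` with Wald
#' inference: odds ratio `exp(b1)`, 95% CI `exp(b1 +/- 1.96 se)` and Wald p.
#' Incomplete cases (missing predictor, e.g. a disappeared wave) are dropped
#' and the analysed `n` reported. Degenerate inputs are handled explicitly:
#' a zero-variance predictor carries no information (OR 1, p 1, status
#' `"degenerate"`); complete separation is flagged (status `"separation"`)
#' rather than reported as an exploded estimate.
#'
#' @param x Numeric predictor vector.
#' @param y Binary outcome (logical or 0/1); both classes must be present
#'   among complete cases.
#' @param variable Name used in the result row.
#' @return One-row data frame: `variable`, `n`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `analysis = "univariate"`, `status`.
#' @export
univariate_logistic <- function(x, y, variable = deparse(substitute(x))) {
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep])
  y <- as.integer(as.logical(y[keep]))
  if (length(unique(y)) < 2)
    stop_config("outcome has a single class among the %d complete cases",
                length(y))
  if (length(unique(x)) < 2)
    return(data.frame(variable = variable, n = length(y), odds_ratio = 1,
                      ci_low = NA_real_, ci_high = NA_real_, p_value = 1,
                      analysis = "univariate", status = "degenerate"))
  res <- fit_logistic(data.frame(y = y, x = x))
  logistic_row(res$fit, "x", variable, length(y), "univariate",
               if (res$separation) "separation" else "ok")
}

#' Stepwise multivariate logistic model over pre-screened candidates
#'
#' Takes the candidates that passed the univariate screen (p <= `alpha`) and
#' selects independent predictors by Wald-p-driven stepwise selection:
#' backward elimination from the full model, repeatedly removing the variable
#' with the largest p > `alpha` (default), or forward addition of the most
#' significant remaining variable. Aliased (perfectly collinear) candidates
#' are dropped up front. Complete cases across all candidates are used and
#' the analysed `n` reported.
#'
#' @param data Data frame containing the candidate columns.
#' @param outcome Binary outcome vector (or the name of a column in `data`).
#' @param candidates Character vector of candidate column names (>= 1).
#' @param direction `"backward"` (default) or `"forward"`.
#' @param alpha Stay/entry threshold on the Wald p-value (default 0.05).
#' @return Data frame with one row per surviving variable (layout of
#'   [univariate_logistic()], `analysis = "multivariate"`); zero rows if no
#'   variable survives. Attribute `"dropped"` lists eliminated variables.
#' @export
multivariate_stepwise <- function(data, outcome, candidates,
                                  direction = c("backward", "forward"),
                                  alpha = 0.05) {
  direction <- match.arg(direction)
  if (length(candidates) < 1) stop_config("need at least one candidate")
  if (is.character(outcome) && length(outcome) == 1) outcome <- data[[outcome]]
  df <- data[, candidates, drop = FALSE]
  keep <- stats::complete.cases(df, outcome)
  df <- df[keep, , drop = FALSE]
  y <- as.integer(as.logical(outcome[keep]))
  n <- length(y)
  if (length(unique(y)) < 2)
    stop_config("outcome has a single class among the %d complete cases", n)

  # drop aliased/constant candidates (duplicated predictors etc.)
  full <- fit_logistic(cbind(data.frame(y = y), df))
  aliased <- names(which(is.na(stats::coef(full$fit))))
  vars <- setdiff(candidates, aliased)
  vars <- vars[vapply(vars, function(v) length(unique(df[[v]])) > 1, TRUE)]
  dropped <- setdiff(candidates, vars)

  wald_p <- function(fit, vs) {
    co <- summary(fit)$coefficients
    p <- stats::setNames(rep(NA_real_, length(vs)), vs)
    hit <- intersect(vs, rownames(co))
    p[hit] <- co[hit, "Pr(>|z|)"]
    p
  }

  if (direction == "backward") {
    while (length(vars) > 0) {
      res <- fit_logistic(cbind(data.frame(y = y), df[, vars, drop = FALSE]))
      p <- wald_p(res$fit, vars)
      worst <- which.max(ifelse(is.na(p), Inf, p))
      if (any(is.na(p))) {
        dropped <- c(dropped, vars[which(is.na(p))[1]])
        vars <- vars[-which(is.na(p))[1]]
        next
      }
      if (p[worst] <= alpha) break
      dropped <- c(dropped, vars[worst])
      vars <- vars[-worst]
    }
  } else {
    chosen <- character()
    repeat {
      remaining <- setdiff(vars, chosen)
      if (!length(remaining)) break
      cand_p <- vapply(remaining, function(v) {
        res <- fit_logistic(cbind(data.frame(y = y),
                                  df[, c(chosen, v), drop = FALSE]))
        wald_p(res$fit, v)
      }, 0)
      best <- which.min(cand_p)
      if (!is.finite(cand_p[best]) || cand_p[best] > alpha) break
      chosen <- c(chosen, remaining[best])
    }
    dropped <- c(dropped, setdiff(vars, chosen))
    vars <- chosen
  }

  if (!length(vars)) {
    out <- data.frame(variable = character(), n = integer(),
                      odds_ratio = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_value = numeric(),
                      analysis = character(), status = character())
    attr(out, "dropped") <- dropped
    return(out)
  }
  res <- fit_logistic(cbind(data.frame(y = y), df[, vars, drop = FALSE]))
  status <- if (res$separation) "separation" else "ok"
  out <- do.call(rbind, lapply(vars, function(v)
    logistic_row(res$fit, v, v, n, "multivariate", status)))
  attr(out, "dropped") <- dropped
  out
}

#' ROC analysis with AUC and Youden-optimal cutoff
#'
#' The AUC is the rank (Mann-Whitney) statistic with ties counted half —
#' identical to the trapezoidal area under the empirical ROC curve.
#' Orientation is fixed (higher score treated as indicating the positive
#' class) and the AUC reported as-is, so values below 0.5 indicate a
#' negatively oriented predictor. The cutoff maximizes Youden's
#' J = sensitivity + specificity - 1 over all observed score values, calling
#' positive `score >= cutoff` when AUC >= 0.5 and `score <= cutoff`
#' otherwise; among ties the lowest cutoff is returned.
#'
#' @param score Numeric predictor.
#' @param y Binary outcome; both classes required among complete cases.
#' @param variable Name used in the result.
#' @return Object of class `baep_roc`: list with `variable`, `auc`,
#'   `cutoff`, `sensitivity` and `specificity` (percent), `youden`,
#'   `direction` (`">="` or `"<="`), `n_pos`, `n_neg`, and `curve`
#'   (data frame of threshold, sensitivity, specificity for plotting).
#' @export
roc_analysis <- function(score, y, variable = deparse(substitute(score))) {
  keep <- stats::complete.cases(score, y)
  score <- as.numeric(score[keep])
  y <- as.logical(y[keep])
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_config("both outcome classes must be present (got %d pos / %d neg)",
                n_pos, n_neg)
  r <- rank(score)  # midranks: ties half-counted
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thresholds <- sort(unique(score))
  ge <- auc >= 0.5
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    call_pos <- if (ge) score >= thresholds[i] else score <= thresholds[i]
    sens[i] <- mean(call_pos[y])
    spec[i] <- mean(!call_pos[!y])
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-9)[1]  # lowest threshold among (near-)ties
  structure(list(variable = variable, auc = auc,
                 cutoff = thresholds[best],
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 youden = j[best],
                 direction = if (ge) ">=" else "<=",
                 n_pos = n_pos, n_neg = n_neg,
                 curve = data.frame(threshold = thresholds,
                                    sensitivity = sens, specificity = spec)),
            class = "baep_roc")
}

#' @export
print.baep_roc <- function(x, ...) {
  cat(sprintf("ROC %s: AUC %.3f, cutoff %s %.4g (sens %.1f%%, spec %.1f%%), %d pos / %d neg\n",
              x$variable, x$auc, x$direction, x$cutoff,
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

## DeLong placement values for one score. Rows: cases; value: fraction of
## controls it beats (ties half).
delong_placements <- function(score, y) {
  pos <- score[y]
  neg <- score[!y]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(xi) mean(psi(xi, neg)), 0)
  v01 <- vapply(neg, function(yj) mean(psi(pos, yj)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Two-sided test of equal AUCs for two predictors measured on the same
#' subjects with the same outcome, using DeLong's placement-value covariance
#' estimate, which accounts for the pairing. If the estimated variance of
#' the AUC difference is zero (e.g. the scores are identical or monotone
#' transforms of each other), the difference is exactly zero and p = 1.
#'
#' @param score_a,score_b Numeric predictors on the same subjects.
#' @param y Binary outcome.
#' @return Object of class `baep_auc_test`: list with `auc_a`, `auc_b`,
#'   `auc_diff`, `statistic` (z), `p_value`, `n_pos`, `n_neg`.
#' @export
compare_aucs <- function(score_a, score_b, y) {
  keep <- stats::complete.cases(score_a, score_b, y)
  a <- as.numeric(score_a[keep])
  b <- as.numeric(score_b[keep])
  y <- as.logical(y[keep])
  m <- sum(y)
  n <- sum(!y)
  if (m == 0 || n == 0)
    stop_config("both outcome classes must be present")
  pa <- delong_placements(a, y)
  pb <- delong_placements(b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(d) <= .Machine$double.eps^0.5) 1 else 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = d,
                 statistic = z, p_value = p, n_pos = m, n_neg = n),
            class = "baep_auc_test")
}

#' @export
print.baep_auc_test <- function(x, ...) {
  cat(sprintf("Paired AUC comparison: %.3f vs %.3f (z = %.3f, p = %.4g)\n",
              x$auc_a, x$auc_b, x$statistic, x$p_value))
  invisible(x)
}

## Paired t-test robust to the zero-variance degenerate case (identical
## paired samples have t = 0, p = 1 rather than an error).
paired_t <- function(a, b) {
  d <- a - b
  d <- d[is.finite(d)]
  if (length(d) < 2 || stats::sd(d) == 0)
    return(list(statistic = 0, df = length(d) - 1, p_value = 1))
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

one_way_anova <- function(value, group) {
  keep <- is.finite(value) & !is.na(group)
  value <- value[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  if (stats::var(tapply(value, group, mean)) == 0)
    return(list(statistic = 0, df = nlevels(group) - 1, p_value = 1))
  fit <- stats::aov(value ~ group)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], df = s[["Df"]][1],
       p_value = s[["Pr(>F)"]][1])
}

#' Audiometric group comparisons
#'
#' The standard battery on a cohort's audiometry: paired t-tests of pre- vs
#' postoperative PTA and WRS on each ear, paired t-tests of the affected- vs
#' healthy-side pre-to-post changes, and one-way ANOVA of the affected-side
#' changes across postoperative AAO-HNS classes (>= 3 groups).
#'
#' @param hearing Data frame in the [cohort_hearing()] layout with both
#'   sides.
#' @return Data frame: `comparison`, `method`, `statistic`, `df`, `p_value`.
#' @export
group_comparisons <- function(hearing) {
  wide <- function(side, stage, col) {
    rows <- hearing[hearing$side == side & hearing$stage == stage, ]
    rows[[col]][order(rows$patient_id)]
  }
  out <- list()
  add <- function(name, method, res) {
    out[[length(out) + 1L]] <<- data.frame(
      comparison = name, method = method,
      statistic = res$statistic, df = res$df, p_value = res$p_value)
  }
  for (side in c("affected", "healthy")) {
    for (col in c("pta_db", "wrs_pct")) {
      add(sprintf("%s %s pre vs post", side, col), "paired t",
          paired_t(wide(side, "post", col), wide(side, "pre", col)))
    }
  }
  for (col in c("pta_db", "wrs_pct")) {
    ch_aff <- wide("affected", "post", col) - wide("affected", "pre", col)
    ch_hea <- wide("healthy", "post", col) - wide("healthy", "pre", col)
    add(sprintf("change %s affected vs healthy", col), "paired t",
        paired_t(ch_aff, ch_hea))
  }
  aff_pre <- hearing[hearing$side == "affected" & hearing$stage == "pre", ]
  aff_post <- hearing[hearing$side == "affected" & hearing$stage == "post", ]
  ord <- order(aff_post$patient_id)
  cls <- classify_aao_hns(aff_post$pta_db[ord], aff_post$wrs_pct[ord])$aao_class
  for (col in c("pta_db", "wrs_pct")) {
    ch <- wide("affected", "post", col) - wide("affected", "pre", col)
    add(sprintf("change %s across postop AAO-HNS classes", col),
        "one-way ANOVA", one_way_anova(ch, cls))
  }
  do.call(rbind, out)
}
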
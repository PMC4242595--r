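#' Immunohistochemistry staining index
#'
#' Scores the proportion of protein-expressing tumor cells on the ordinal
#' scale 0 (no positive cells), 1 (up to 5%), 2 (6-25%), 3 (26-50%),
#' 4 (51-75%), 5 (over 75%) -- fractional percentages in the 5-6 gap fall
#' in bin 2 (right-closed bins) -- and combines it with the intensity grade
#' (0 none, 1 weak, 2 moderate, 3 strong). The staining index is the
#' product of the two (range 0-15; the standard immunoreactive-score
#' construction; a sum variant is available), and patients are
#' dichotomized high when the index reaches `cutoff` (default 5).
#'
#' @param proportion_pct percentage of positive tumor cells, in \[0, 100\]
#'   (vectorized).
#' @param intensity_grade intensity grade in {0, 1, 2, 3}.
#' @param method `"product"` (default) or `"sum"`.
#' @param cutoff minimum index of the high-expression group.
#' @return data frame of class `staining_score`: proportion_pct,
#'   proportion_score, intensity_grade, staining_index, group
#'   (factor low/high).
#' @export
staining_index <- function(proportion_pct, intensity_grade,
                           method = c("product", "sum"), cutoff = 5) {
  method <- match.arg(method)
  if (any(!is.finite(proportion_pct)) || any(proportion_pct < 0) ||
      any(proportion_pct > 100))
    stopf("`proportion_pct` must lie in [0, 100]")
  if (any(!intensity_grade %in% 0:3))
    stopf("`intensity_grade` must be 0, 1, 2 or 3")
  score <- ifelse(proportion_pct == 0, 0L,
                  findInterval(proportion_pct, c(0, 5, 25, 50, 75),
                               left.open = TRUE))
  idx <- switch(method,
                product = score * intensity_grade,
                sum = score + intensity_grade)
  res <- data.frame(
    proportion_pct = proportion_pct, proportion_score = score,
    intensity_grade = as.integer(intensity_grade), staining_index = idx,
    group = factor(ifelse(idx >= cutoff, "high", "low"),
                   levels = c("low", "high"))
  )
  class(res) <- c("staining_score", "data.frame")
  res
}

#' Clinicopathologic association tests
#'
#' Pairwise marker-marker and marker-sex associations by Fisher's exact
#' test (2 x 2), and marker-vs-T-stage plus sex-vs-T-stage associations by
#' Pearson's chi-square on the 2 x 3 table without continuity correction.
#'
#' @param cohort data frame with `sex`, `t_stage` and one `<marker>_group`
#'   factor column per marker.
#' @param markers marker names (default ALDH2, CCNE1, SMAD3).
#' @return data frame: var1, var2, test, p.
#' @export
association_tests <- function(cohort,
                              markers = c("ALDH2", "CCNE1", "SMAD3")) {
  gcol <- function(m) cohort[[paste0(m, "_group")]]
  for (m in markers)
    if (is.null(gcol(m))) stopf("missing column `%s_group`", m)
  rows <- list()
  add <- function(v1, v2, test, p)
    rows[[length(rows) + 1]] <<- data.frame(var1 = v1, var2 = v2,
                                            test = test, p = p,
                                            stringsAsFactors = FALSE)
  cmb <- utils::combn(markers, 2)
  for (j in seq_len(ncol(cmb))) {
    t22 <- table(gcol(cmb[1, j]), gcol(cmb[2, j]))
    add(cmb[1, j], cmb[2, j], "fisher", fisher.test(t22)$p.value)
  }
  for (m in markers) {
    add(m, "sex", "fisher",
        fisher.test(table(gcol(m), cohort$sex))$p.value)
    add(m, "t_stage", "chisq",
        chisq_p(table(gcol(m), cohort$t_stage)))
  }
  add("sex", "t_stage", "chisq",
      chisq_p(table(cohort$sex, cohort$t_stage)))
  do.call(rbind, rows)
}

# Pearson chi-square without continuity correction; refuse degenerate tables
#' @noRd
chisq_p <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2))
    stopf("chi-square refused: contingency table has an empty row or column")
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group, honoring right censoring.
#'
#' @param records data frame with `time` (> 0) and `event` (0/1).
#' @param group grouping column name in `records`, or a vector.
#' @return object of class `km_fit`: the `survfit` fit and a tidy step
#'   table (group, time, n_risk, n_event, n_censor, surv).
#' @export
kaplan_meier <- function(records, group = NULL) {
  g <- resolve_group(records, group)
  if (any(records$time <= 0)) stopf("survival times must be positive")
  sf <- survival::survfit(survival::Surv(time, event) ~ g,
                          data = cbind(records, g = g))
  grp <- if (is.null(sf$strata)) rep(levels(factor(g))[1], length(sf$time))
         else rep(sub("^g=", "", names(sf$strata)), sf$strata)
  tab <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv, stringsAsFactors = FALSE)
  structure(list(survfit = sf, table = tab), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$survfit)
  invisible(x)
}

#' @noRd
resolve_group <- function(records, group) {
  g <- if (is.null(group)) rep("all", nrow(records))
       else if (length(group) == 1 && is.character(group))
         records[[group]]
       else group
  if (is.null(g)) stopf("grouping column not found")
  factor(g)
}

#' Log-rank (Mantel-Haenszel) comparison of two survival curves
#'
#' @param records data frame with `time` and `event`.
#' @param group two-level grouping column name or vector.
#' @return list: statistic (1-df chi-square), df, p.
#' @export
logrank_test <- function(records, group) {
  g <- droplevels(resolve_group(records, group))
  if (nlevels(g) < 2) stopf("log-rank needs two groups")
  if (sum(records$event) < 1) stopf("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(records, g = g))
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Efron ties
#'
#' Wald-based summaries of a (possibly multivariate) proportional-hazards
#' model. T stage enters as a factor with T3 the reference level, so the
#' reported contrasts are T1-vs-T3 and T2-vs-T3; age is continuous.
#' Non-convergence and monotone-likelihood (infinite coefficient)
#' diagnostics are captured rather than silently ignored.
#'
#' @param records data frame with `time`, `event` and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `table` (term, coef, hr, ci_lo,
#'   ci_hi, se, p), `loglik`, `converged`, `messages`, and the underlying
#'   `coxph` fit.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(records)))
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stopf("missing covariate column(s): %s",
                          paste(miss, collapse = ", "))
  dat <- records[, c("time", "event", covariates)]
  for (v in covariates) {
    if (length(unique(dat[[v]])) < 2)
      stopf("covariate `%s` is constant", v)
    if (v == "t_stage")
      dat[[v]] <- stats::relevel(factor(dat[[v]]), ref = "T3")
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  msgs <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = dat, ties = ties),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  npar <- length(stats::coef(fit))
  if (sum(dat$event) < npar)
    stopf("fewer events (%d) than coefficients (%d)", sum(dat$event), npar)
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = exp(s$coefficients[, "coef"]),
    ci_lo = exp(s$coefficients[, "coef"] - 1.96 * s$coefficients[, "se(coef)"]),
    ci_hi = exp(s$coefficients[, "coef"] + 1.96 * s$coefficients[, "se(coef)"]),
    se = s$coefficients[, "se(coef)"],
    p = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik[2],
                 converged = !any(grepl("converge|infinite|beta may be",
                                        msgs)),
                 messages = msgs, fit = fit, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), log partial likelihood %.3f%s\n",
              x$ties, x$loglik,
              if (x$converged) "" else " [convergence flagged]"))
  df <- x$table
  df$hr <- sprintf("%.3g (%.3g-%.3g)", df$hr, df$ci_lo, df$ci_hi)
  print(df[, c("term", "coef", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Univariate and multivariate Cox tables for a marker cohort
#'
#' Fits one univariate model per covariate and one joint multivariate
#' model, the layout used to report independent prognostic factors.
#'
#' @inheritParams cox_fit
#' @return list with `univariate` (named list of [cox_fit()] results) and
#'   `multivariate` (one [cox_fit()]).
#' @export
cox_table <- function(records,
                      covariates = c("sex", "age", "t_stage",
                                     "ALDH2_group", "CCNE1_group",
                                     "SMAD3_group"),
                      ties = "efron") {
  uni <- lapply(covariates, function(v) cox_fit(records, v, ties = ties))
  names(uni) <- covariates
  list(univariate = uni,
       multivariate = cox_fit(records, covariates, ties = ties))
}

#' Combined-marker risk stratification
#'
#' Defines the combined high-risk stratum -- ALDH2 low together with CCNE1
#' high and SMAD3 high -- against all remaining patients, and compares the
#' two strata by Kaplan-Meier and log-rank. Records with a missing marker
#' group are excluded and reported.
#'
#' @param records clinical data frame with `ALDH2_group`, `CCNE1_group`,
#'   `SMAD3_group`, `time`, `event`.
#' @return list: `strata` (factor `high_risk` / `other` per retained
#'   record), `n_excluded`, `km` ([kaplan_meier()]), `logrank`
#'   ([logrank_test()]).
#' @export
marker_combination <- function(records) {
  need <- c("ALDH2_group", "CCNE1_group", "SMAD3_group")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("missing marker column(s): %s",
                          paste(miss, collapse = ", "))
  ok <- stats::complete.cases(records[, need])
  n_excluded <- sum(!ok)
  rec <- records[ok, , drop = FALSE]
  hr <- rec$ALDH2_group == "low" & rec$CCNE1_group == "high" &
    rec$SMAD3_group == "high"
  strata <- factor(ifelse(hr, "high_risk", "other"),
                   levels = c("other", "high_risk"))
  if (nlevels(droplevels(strata)) < 2)
    stopf("all patients fall in one combined-marker stratum; comparison refused")
  list(strata = strata, n_excluded = n_excluded,
       km = kaplan_meier(rec, strata),
       logrank = logrank_test(rec, strata))
}
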
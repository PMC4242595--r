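# 2x2 two-sided Fisher p by hypergeometric enumeration
fisher_enum <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(m, k)
  pr <- dhyper(supp, m, n, k)
  sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

km5 <- data.frame(time = c(2, 4, 6, 8, 9), event = c(1, 0, 1, 1, 0))

test_that("proportion scores fall in the documented right-closed bins", {
  pct <- c(0, 3, 5, 5.5, 6, 25, 26, 50, 60, 75, 76, 100)
  sc <- staining_index(pct, rep(1, length(pct)))
  expect_equal(sc$proportion_score, c(0, 1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5))
})

test_that("the index is score times intensity, dichotomized at five", {
  sc <- staining_index(c(10, 10, 80, 0), c(2, 3, 1, 3))
  expect_equal(sc$staining_index, c(4, 6, 5, 0))
  expect_equal(as.character(sc$group), c("low", "high", "high", "low"))
  ss <- staining_index(c(30, 3), c(2, 1), method = "sum")
  expect_equal(ss$staining_index, c(5, 2))
  expect_equal(as.character(ss$group), c("high", "low"))
})

test_that("staining inputs are validated", {
  expect_error(staining_index(101, 1), "\\[0, 100\\]")
  expect_error(staining_index(50, 4), "0, 1, 2 or 3")
})

test_that("association table covers all pairs with the right tests", {
  set.seed(41)
  n <- 40
  coh <- data.frame(
    sex = sample(c("male", "female"), n, TRUE),
    t_stage = sample(c("T1", "T2", "T3"), n, TRUE),
    ALDH2_group = factor(rep(c("low", "high"), each = n / 2)),
    CCNE1_group = factor(rep(c("low", "high", "high", "low"), n / 4)),
    SMAD3_group = factor(sample(c("low", "high"), n, TRUE))
  )
  res <- association_tests(coh)
  expect_equal(nrow(res), 10)                      # 3 pairs + 3x2 + 1
  expect_equal(sum(res$test == "fisher"), 6)
  expect_equal(sum(res$test == "chisq"), 4)
  # marker-marker Fisher p equals hypergeometric enumeration
  t22 <- table(coh$ALDH2_group, coh$CCNE1_group)
  p_hand <- fisher_enum(t22)
  expect_equal(res$p[res$var1 == "ALDH2" & res$var2 == "CCNE1"], p_hand,
               tolerance = 1e-10)
  # marker-vs-T chi-square equals the hand Pearson statistic, df = 2
  t23 <- table(coh$ALDH2_group, coh$t_stage)
  e <- outer(rowSums(t23), colSums(t23)) / sum(t23)
  x2 <- sum((t23 - e)^2 / e)
  expect_equal(res$p[res$var1 == "ALDH2" & res$var2 == "t_stage"],
               pchisq(x2, 2, lower.tail = FALSE))
})

test_that("degenerate contingency tables are refused, not mangled", {
  tab <- matrix(c(5, 0, 7, 0), 2, 2)               # empty second row
  expect_error(tagdge:::chisq_p(tab), "empty row or column")
  # an empty level is dropped first, then the 2x2 test proceeds
  tab3 <- cbind(matrix(c(3, 4, 5, 6), 2, 2), c(0, 0))
  expect_equal(tagdge:::chisq_p(tab3),
               suppressWarnings(chisq.test(tab3[, 1:2],
                                           correct = FALSE)$p.value))
})

test_that("the product-limit curve matches the hand computation", {
  km <- kaplan_meier(km5)
  ev <- km$table[km$table$n_event > 0, ]
  expect_equal(ev$time, c(2, 6, 8))
  expect_equal(ev$n_risk, c(5, 3, 2))
  expect_equal(ev$surv, c(4 / 5, 8 / 15, 4 / 15))
  expect_error(kaplan_meier(data.frame(time = c(0, 1), event = c(1, 1))),
               "positive")
})

test_that("grouped curves are estimated within each group only", {
  rec <- rbind(cbind(km5, g = "A"),
               data.frame(time = c(1, 3), event = c(1, 1), g = "B"))
  km <- kaplan_meier(rec, "g")
  a <- km$table[km$table$group == "A" & km$table$n_event > 0, ]
  expect_equal(a$surv, c(4 / 5, 8 / 15, 4 / 15))
  b <- km$table[km$table$group == "B", ]
  expect_equal(b$surv, c(1 / 2, 0))
})

test_that("log-rank equals the observed-minus-expected formula", {
  set.seed(42)
  n <- 40
  rec <- data.frame(time = round(rexp(n, 0.1) + 1),
                    event = rbinom(n, 1, 0.7),
                    g = rep(c("A", "B"), n / 2))
  lr <- logrank_test(rec, "g")
  expect_equal(lr$statistic,
               logrank_oracle(rec$time, rec$event, rec$g == "B"),
               tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))
})

test_that("the log-rank p-value agrees with a permutation null", {
  set.seed(43)
  n <- 30
  rec <- data.frame(time = round(rexp(n, 0.1) + 1),
                    event = rbinom(n, 1, 0.8),
                    g = rep(c("A", "B"), n / 2))
  lr <- logrank_test(rec, "g")
  p_perm <- logrank_perm_p(rec$time, rec$event, rec$g == "B")
  expect_equal(lr$p, p_perm, tolerance = 0.02 / lr$p)
})

test_that("log-rank refuses one group or zero events", {
  expect_error(logrank_test(cbind(km5, g = "A"), "g"), "two groups")
  rec <- data.frame(time = 1:4, event = 0, g = c("A", "A", "B", "B"))
  expect_error(logrank_test(rec, "g"), "at least one event")
})

test_that("a single-covariate Efron fit maximizes the partial likelihood", {
  set.seed(44)
  n <- 80
  x <- rep(0:1, n / 2)
  tm <- round(rexp(n, 0.05 * exp(x)) + 1)
  ev <- rbinom(n, 1, 0.8)
  rec <- data.frame(time = tm, event = ev, x = x)
  fit <- cox_fit(rec, "x")
  b_hat <- efron_grid_max(tm, ev, x)
  expect_equal(fit$table$coef, b_hat, tolerance = 1e-3)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_equal(fit$table$ci_lo,
               exp(fit$table$coef - 1.96 * fit$table$se))
  expect_equal(fit$table$ci_hi,
               exp(fit$table$coef + 1.96 * fit$table$se))
  expect_true(fit$converged)
  # breslow ties give a (slightly) different estimate but the same object
  fb <- cox_fit(rec, "x", ties = "breslow")
  expect_s3_class(fb, "cox_fit")
})

test_that("T stage enters as a factor with the T3 reference", {
  set.seed(45)
  n <- 90
  rec <- data.frame(time = round(rexp(n, 0.05) + 1),
                    event = rbinom(n, 1, 0.7),
                    t_stage = sample(c("T1", "T2", "T3"), n, TRUE))
  fit <- cox_fit(rec, "t_stage")
  expect_setequal(fit$table$term, c("t_stageT1", "t_stageT2"))
})

test_that("unusable Cox inputs are refused with clear messages", {
  rec <- data.frame(time = c(3, 5, 7, 9), event = c(1, 0, 1, 0),
                    x = c(1, 1, 1, 1), y = c(0, 1, 0, 1))
  expect_error(cox_fit(rec, "x"), "constant")
  expect_error(cox_fit(rec, "z"), "missing covariate")
  rec2 <- data.frame(time = c(3, 5, 7, 9), event = c(1, 0, 0, 0),
                     a = c(0, 1, 0, 1), b = c(1, 0, 0, 1))
  expect_error(cox_fit(rec2, c("a", "b")), "fewer events")
})

test_that("the Cox table fits one model per covariate plus a joint model", {
  set.seed(46)
  n <- 100
  rec <- data.frame(
    time = round(rexp(n, 0.05) + 1), event = rbinom(n, 1, 0.7),
    sex = sample(c("male", "female"), n, TRUE),
    age = round(runif(n, 40, 85)),
    t_stage = sample(c("T1", "T2", "T3"), n, TRUE),
    ALDH2_group = sample(c("low", "high"), n, TRUE),
    CCNE1_group = sample(c("low", "high"), n, TRUE),
    SMAD3_group = sample(c("low", "high"), n, TRUE)
  )
  ct <- cox_table(rec)
  expect_named(ct$univariate, c("sex", "age", "t_stage", "ALDH2_group",
                                "CCNE1_group", "SMAD3_group"))
  expect_equal(nrow(ct$univariate$age$table), 1)
  expect_equal(nrow(ct$multivariate$table), 7)     # 2 T-stage contrasts
  expect_equal(ct$univariate$age$table$coef,
               unname(coef(survival::coxph(
                 survival::Surv(time, event) ~ age, data = rec))))
})

test_that("the combined stratum is ALDH2-low with both others high", {
  rec <- data.frame(
    time = c(2, 3, 4, 5, 6, 7), event = c(1, 1, 0, 1, 1, 0),
    ALDH2_group = c("low", "low", "high", "low", NA, "low"),
    CCNE1_group = c("high", "high", "high", "low", "high", "high"),
    SMAD3_group = c("high", "high", "high", "high", "high", "low")
  )
  mc <- marker_combination(rec)
  expect_equal(mc$n_excluded, 1)
  expect_equal(as.character(mc$strata),
               c("high_risk", "high_risk", "other", "other", "other"))
  one <- data.frame(time = 1:3, event = c(1, 1, 0),
                    ALDH2_group = "low", CCNE1_group = "high",
                    SMAD3_group = "high")
  expect_error(marker_combination(one), "one combined-marker stratum")
  expect_error(marker_combination(one[, 1:3]), "missing marker")
})
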
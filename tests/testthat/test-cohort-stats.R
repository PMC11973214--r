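mkTable <- function(groups, scores, ages = NULL) {
  n <- length(scores)
  data.frame(age = if (is.null(ages)) rep(70, n) + seq_len(n) %% 7 else ages,
             group = groups, AS = scores, stringsAsFactors = FALSE)
}

test_that("score-age fits reproduce exact lines and the closed-form R^2", {
  ages <- seq(60, 90, length.out = 30)
  f <- fitScoreVsAge(data.frame(age = ages, AS = 2 * (ages - 60)), "AS")
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  f0 <- fitScoreVsAge(data.frame(age = ages, AS = rep(1.3, 30)), "AS")
  expect_equal(f0$slope, 0)
  expect_equal(f0$r2, 0)

  set.seed(100)
  y <- (ages <- runif(100, 60, 90)) - 60 + rnorm(100, sd = 4)
  rec <- data.frame(age = ages, AS = y)
  f <- fitScoreVsAge(rec, "AS")
  sst <- sum((y - mean(y))^2)
  sse <- sum(residuals(lm(AS ~ age, rec))^2)
  expect_equal(f$r2, 1 - sse / sst, tolerance = 1e-10)
  expect_error(fitScoreVsAge(data.frame(age = rep(70, 5), AS = rnorm(5)),
                             "AS"), "zero variance")
})

test_that("ANCOVA adjustment removes the age effect and centers CN at zero", {
  # no age effect: adjustment reduces to CN-mean centering
  set.seed(3)
  tab <- mkTable(rep(c("CN", "CDR0.5"), each = 20),
                 c(rnorm(20, 1), rnorm(20, 3)))
  adj <- ancovaAdjust(tab, "AS")
  cn <- tab$group == "CN"
  expect_equal(mean(adj$AS.adj[cn]), 0, tolerance = 1e-10)
  # beta_age is ~0 here, so adjusted = raw - mean(CN raw) up to the fit noise
  fitBeta <- coef(lm(AS ~ age + group, tab))["age"]
  expect_equal(adj$AS.adj,
               as.numeric(tab$AS - fitBeta * (tab$age - mean(tab$age[cn])) -
                          mean((tab$AS - fitBeta * (tab$age - mean(tab$age[cn])))[cn])),
               tolerance = 1e-12)

  # pure age confound: groups differ only through age, score = age
  ages <- c(runif(30, 60, 70), runif(30, 75, 85))
  tab <- data.frame(age = ages, group = rep(c("CN", "CDR1"), each = 30),
                    AS = ages)
  adj <- ancovaAdjust(tab, "AS")
  means <- tapply(adj$AS.adj, adj$group, mean)
  expect_lt(max(abs(means)), 1e-8)

  # CN mean of adjusted scores is zero for arbitrary input
  set.seed(71)
  tab <- mkTable(sample(c("CN", "CDR0", "CDR1"), 60, TRUE), rnorm(60),
                 ages = runif(60, 60, 90))
  adj <- ancovaAdjust(tab, "AS")
  expect_equal(mean(adj$AS.adj[tab$group == "CN"]), 0, tolerance = 1e-10)

  expect_error(ancovaAdjust(mkTable(rep("CDR1", 10), rnorm(10)), "AS"),
               "CN")
})

test_that("pairwise tests: identical groups, planted effects and exclusions", {
  x <- c(rnorm(20, sd = 1))
  tab <- mkTable(rep(c("CN", "CDR0"), each = 20), c(x, x))
  res <- pairwiseTests(tab, "AS")
  expect_equal(res$cohenD, 0)
  expect_equal(res$p, 1)
  expect_equal(res$significance, "ns")

  set.seed(2024)
  tab <- mkTable(rep(c("CN", "CDR1"), each = 200),
                 c(rnorm(200, 0), rnorm(200, 0.8)))
  res <- pairwiseTests(tab, "AS")
  expect_gte(abs(res$cohenD), 0.6)
  expect_lte(abs(res$cohenD), 1.0)
  expect_lt(res$pBonf, 0.0001)

  # undersized groups are excluded with a notice, not a crash
  tab <- mkTable(c(rep("CN", 20), rep("CDR0", 20), rep("CDR2", 4)),
                 rnorm(44), ages = runif(44, 60, 90))
  expect_message(res <- pairwiseTests(tab, "AS"), "CDR2")
  expect_false(any(res$group1 == "CDR2" | res$group2 == "CDR2"))
  expect_equal(nrow(res), 1)
})

test_that("Bonferroni correction dominates the raw p and caps at one", {
  set.seed(7)
  tab <- mkTable(sample(c("CN", "CDR0", "CDR0.5", "CDR1"), 120, TRUE),
                 rnorm(120), ages = runif(120, 60, 90))
  res <- pairwiseTests(tab, "AS")
  expect_equal(nrow(res), 6)
  expect_true(all(res$pBonf >= res$p))
  expect_true(all(res$pBonf <= 1))
  expect_equal(res$pBonf, pmin(1, res$p * 6))
})

test_that("Cohen's d is antisymmetric and banded per the effect-size scheme", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  expect_equal(cohensD(x, y), -cohensD(y, x), tolerance = 1e-12)
  expect_equal(effectSizeBand(c(-0.40, -0.70, -0.95)),
               c("medium", "large", "very large"))
  expect_equal(effectSizeBand(0.35), "medium")   # closed left endpoint
  expect_equal(effectSizeBand(0.65), "large")
  expect_equal(effectSizeBand(0.9), "very large")
  expect_equal(effectSizeBand(0), "none")
  expect_equal(effectSizeBand(0.3499), "none")
})

test_that("significance bands follow the annotation legend boundaries", {
  # band edges are inclusive on the small side: p = 0.05 is "*", 0.01 "**"
  expect_equal(significanceBand(c(0.06, 0.05, 0.01, 0.001, 1e-4, 1e-5)),
               c("ns", "*", "**", "***", "****", "****"))
})

test_that("the raw-p rejection rate is calibrated under the null", {
  set.seed(314)
  rej <- 0L
  nrep <- 1000
  for (r in seq_len(nrep)) {
    p <- t.test(rnorm(30), rnorm(30))$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  rate <- rej / nrep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted group offsets keep their ordering after ANCOVA adjustment", {
  set.seed(88)
  groups <- rep(c("CN", "CDR0", "CDR0.5", "CDR1"), each = 40)
  offs <- c(CN = 0, CDR0 = 0.3, `CDR0.5` = 0.6, CDR1 = 1.0)
  ages <- c(runif(40, 60, 90), runif(120, 68, 88))
  tab <- data.frame(age = ages, group = groups,
                    ADS = 0.02 * (ages - 60) + offs[groups] +
                          rnorm(160, sd = 0.15))
  adj <- ancovaAdjust(tab, "ADS")
  means <- tapply(adj$ADS.adj, factor(adj$group, levels = names(offs)), mean)
  expect_true(all(diff(means) > 0))
})
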
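sim_logit_records <- function(n, beta_season = 0, base = -1.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  year <- sample(paste0("y", 1:3), n, TRUE)
  season <- sample(c("first", "second"), n, TRUE)
  age <- sample(c("1yr", "2yr"), n, TRUE)
  eta <- base + (year == "y2") * 0.3 + (year == "y3") * -0.2 +
    (season == "second") * beta_season
  y <- rbinom(n, 1, plogis(eta))
  data.frame(doe_id = paste0("D", seq_len(n)), parity = 1, outcome = y,
             year = year, season = season, age_class = age,
             stringsAsFactors = FALSE)
}

test_that("intercept-only and 2x2 fits match closed-form maximum likelihood", {
  # a factor with no usable contrasts is refused outright
  rec <- data.frame(doe_id = paste0("D", 1:100), parity = 1,
                    outcome = c(rep(1, 30), rep(0, 70)),
                    year = "y1", season = "s1", age_class = "a1")
  expect_error(suppressWarnings(fit_logistic(rec, 1, factors = "year")),
               "no usable factors")
  # intercept-only maximum likelihood closed form
  f0 <- glm(outcome ~ 1, binomial, rec)
  expect_equal(unname(coef(f0)), log(30 / 70), tolerance = 1e-8)

  # a 2-level factor: coefficient equals the log odds difference
  rec2 <- data.frame(
    doe_id = paste0("D", 1:200), parity = 1,
    outcome = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90)),
    year = "y1", season = rep(c("s1", "s0"), each = 100), age_class = "a1")
  fit2 <- suppressWarnings(fit_logistic(rec2, 1, factors = "season",
                                        reference_levels = list(season = "s0")))
  beta <- fit2$coefficients[["seasons1"]]
  expect_equal(beta, log((20 / 80) / (10 / 90)), tolerance = 1e-7)
  expect_equal(unname(plogis(fit2$coefficients[["(Intercept)"]])), 0.1,
               tolerance = 1e-7)
  expect_error(fit_logistic(transform(rec2, outcome = 0), 1, "season"),
               "constant")
})

test_that("odds ratios reproduce the 2x2 cross-product ratio exactly", {
  # a = 10 events / 90 non-events at level B; c = 20 / 80 at reference A
  rec <- data.frame(
    doe_id = paste0("D", 1:200), parity = 1,
    outcome = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90)),
    year = "y1", season = rep(c("A", "B"), each = 100), age_class = "a1")
  fit <- suppressWarnings(fit_logistic(rec, 1, factors = "season"))
  ors <- odds_ratios(fit)
  expect_equal(ors$or[ors$level == "A"], 1)
  expect_true(ors$reference[ors$level == "A"])
  expect_equal(ors$or[ors$level == "B"], (10 * 80) / (90 * 20),
               tolerance = 1e-10)

  # property: random tables without zero cells
  set.seed(70)
  for (i in 1:25) {
    a <- sample(5:40, 1); b <- sample(5:40, 1)
    c <- sample(5:40, 1); d <- sample(5:40, 1)
    reci <- data.frame(
      doe_id = paste0("D", seq_len(a + b + c + d)), parity = 1,
      outcome = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
      year = "y1",
      season = c(rep("lvl1", a + b), rep("lvl0", c + d)),
      age_class = "a1")
    fiti <- suppressWarnings(
      fit_logistic(reci, 1, "season", reference_levels = list(season = "lvl0")))
    expect_equal(odds_ratios(fiti)$or[2], (a * d) / (b * c), tolerance = 1e-8)
  }
})

test_that("confidence intervals are symmetric around the OR on the log scale", {
  rec <- sim_logit_records(800, beta_season = -0.4, seed = 71)
  fit <- fit_logistic(rec, 1)
  ors <- odds_ratios(fit, level = 0.95)
  nr <- ors[!ors$reference, ]
  expect_equal(log(nr$ci_high) - log(nr$or), log(nr$or) - log(nr$ci_low),
               tolerance = 1e-10)
})

test_that("reference recoding shifts coefficients but not factor p-values", {
  rec <- sim_logit_records(1500, beta_season = -0.4, seed = 72)
  f1 <- fit_logistic(rec, 1)
  f2 <- fit_logistic(rec, 1, reference_levels = list(year = "y2"))
  p1 <- factor_test(f1, "year")
  p2 <- factor_test(f2, "year")
  expect_equal(p1, p2, tolerance = 1e-8)
  # recoding maps coefficients by subtraction
  b1 <- f1$coefficients
  b2 <- f2$coefficients
  expect_equal(unname(b2[["yeary3"]]), unname(b1[["yeary3"]] - b1[["yeary2"]]),
               tolerance = 1e-6)
})

test_that("single-contrast Wald test equals the squared z-test", {
  rec <- sim_logit_records(1000, beta_season = -0.5, seed = 73)
  fit <- fit_logistic(rec, 1, factors = "season")
  p_wald <- factor_test(fit, "season")
  z <- fit$coefficients[["seasonsecond"]] /
    sqrt(fit$cov_matrix["seasonsecond", "seasonsecond"])
  expect_equal(p_wald, 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("Wald and likelihood-ratio tests agree on well-behaved data", {
  rec <- sim_logit_records(2000, beta_season = -0.5, seed = 74)
  fit <- fit_logistic(rec, 1)
  pw <- factor_test(fit, "season", "wald")
  pl <- factor_test(fit, "season", "lrt")
  expect_lt(abs(log(pw) - log(pl)), abs(log(pw)) * 0.2 + 0.05)
})

test_that("the factor Wald test holds its type-I error rate", {
  set.seed(75)
  rejections <- vapply(1:500, function(i) {
    rec <- sim_logit_records(500, beta_season = 0)
    fit <- fit_logistic(rec, 1, factors = c("season", "age_class"))
    factor_test(fit, "season") < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("a protective cold-season effect is recovered directionally", {
  set.seed(76)
  below_one <- vapply(1:40, function(i) {
    rec <- sim_logit_records(4000, beta_season = -0.2)
    fit <- fit_logistic(rec, 1)
    ors <- odds_ratios(fit)
    ors$or[ors$factor == "season" & ors$level == "second"] < 1
  }, logical(1))
  expect_gte(mean(below_one), 0.95)
})

test_that("the merged risk table covers all traits with per-factor p-values", {
  set.seed(77)
  recs <- do.call(rbind, lapply(1:3, function(t) {
    r <- sim_logit_records(600, beta_season = -0.3)
    r$parity <- t
    r$doe_id <- paste0(r$doe_id, "_", t)
    r
  }))
  rt <- risk_table(recs, traits = 1:3)
  expect_setequal(unique(rt$table$trait), 1:3)
  expect_true(all(c("year", "season", "age_class") %in% rt$table$factor))
  expect_equal(sum(!is.na(rt$table$p_value)), 9)   # 3 factors x 3 traits
  # round trip
  tsv <- tempfile(fileext = ".tsv")
  write_risk_table(rt, tsv)
  back <- read_risk_table(tsv)
  expect_equal(back$or, rt$table$or, tolerance = 1e-9)

  # a failed trait is reported, others still present
  recs2 <- rbind(recs, transform(sim_logit_records(50), parity = 4, outcome = 0))
  rt2 <- suppressWarnings(risk_table(recs2, traits = c(1, 4)))
  expect_true("4" %in% names(rt2$failed))
  expect_true(1 %in% rt2$table$trait)
})
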
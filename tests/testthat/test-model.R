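make_structure <- function(rec, ped, spec) {
  suppressWarnings(build_mme_structure(rec, ped, spec))
}

test_that("design structure does its dimensional bookkeeping", {
  ped <- pedigree(paste0("A", 1:5), c("0", "0", "0", "A1", "A1"),
                  c("0", "0", "0", "A2", "A3"))
  rec <- data.frame(doe_id = c("A3", "A4", "A5"), parity = 1,
                    outcome = c(0, 1, 0),
                    year = c("y1", "y1", "y2"), season = "s1", age_class = "a1")
  spec <- model_spec(traits = 1, scale = "threshold", factors = "year")
  str <- make_structure(rec, ped, spec)
  expect_equal(str$n, 3)
  expect_equal(str$q, 5)
  expect_equal(length(str$col_labels[[1]]), 2)   # year fully coded: 2 columns
  expect_equal(sum(str$animal_doe >= 0), 3)      # 3 record slots, 5 bv slots

  # doe missing from the pedigree is named in the error
  bad <- rbind(rec, data.frame(doe_id = "ZZ", parity = 1, outcome = 1,
                               year = "y1", season = "s1", age_class = "a1"))
  expect_error(build_mme_structure(bad, ped, spec), "ZZ")
})

test_that("single-level factors are dropped with a warning", {
  ped <- founder_pedigree(30)
  rec <- flat_records(ped$animal, rep(c(0, 1), 15))
  spec <- model_spec(traits = 1, scale = "threshold",
                     factors = c("year", "season"))
  expect_warning(build_mme_structure(rec, ped, spec), "fewer than 2")
})

test_that("multivariate structures keep per-trait record counts", {
  set.seed(8)
  ped <- founder_pedigree(50)
  recs <- do.call(rbind, lapply(1:3, function(t) {
    ids <- sample(ped$animal, 50 - 10 * t)
    flat_records(ids, rbinom(length(ids), 1, 0.3), parity = t)
  }))
  str <- make_structure(recs, ped, model_spec())
  for (t in 1:3) {
    expect_equal(sum(str$miss[, t] == 0), 50 - 10 * t)
  }
})

test_that("all-one or all-zero threshold outcomes raise a separation error", {
  ped <- founder_pedigree(20)
  rec <- flat_records(ped$animal, rep(1, 20))
  expect_error(build_mme_structure(rec, ped, model_spec(traits = 1)),
               "separation")
})

test_that("chain bookkeeping retains (n_iter - burn_in) / thin draws", {
  expect_equal(gibbs_config(200000, 20000, 100)$n_keep, 1800)
  expect_error(gibbs_config(100, 90, 20), "fewer than 2")
  ped <- founder_pedigree(40)
  set.seed(2)
  rec <- flat_records(ped$animal, rbinom(40, 1, 0.4))
  fit <- suppressWarnings(run_gibbs(rec, ped, model_spec(traits = 1),
                                    gibbs_config(600, 100, 7, seed = 1)))
  expect_equal(fit$n_kept, (600 - 100) %/% 7)
  expect_equal(nrow(fit$G0_draws), fit$n_kept)
})

test_that("runs are reproducible under a fixed seed", {
  ped <- founder_pedigree(30)
  set.seed(3)
  rec <- flat_records(ped$animal, rbinom(30, 1, 0.3))
  f1 <- suppressWarnings(run_gibbs(rec, ped, model_spec(traits = 1),
                                   gibbs_config(500, 0, 1, seed = 42)))
  f2 <- suppressWarnings(run_gibbs(rec, ped, model_spec(traits = 1),
                                   gibbs_config(500, 0, 1, seed = 42)))
  expect_identical(f1$G0_draws, f2$G0_draws)
  expect_identical(f1$R0_draws, f2$R0_draws)
  expect_identical(f1$a_mean, f2$a_mean)
})

test_that("liability draws honour the truncation contract and moments", {
  # outcome 1 at threshold 0: draws strictly positive
  x <- .cg_rtnorm(5000, 0, 1, 0, TRUE)
  expect_true(all(x > 0))
  y <- .cg_rtnorm(5000, 0, 1, 0, FALSE)
  expect_true(all(y <= 0))

  # truncated-normal mean identity E[l | l > 0] = mu + phi(mu)/Phi(mu)
  for (mu in c(-1.5, 0, 0.8)) {
    d <- .cg_rtnorm(1e5, mu, 1, 0, TRUE)
    expected <- mu + dnorm(mu) / pnorm(mu)
    expect_lt(abs(mean(d) - expected), 3 * sd(d) / sqrt(length(d)))
  }
  # far-tail robustness
  far <- .cg_rtnorm(2000, -8, 1, 0, TRUE)
  expect_true(all(is.finite(far)) && all(far > 0))
})

test_that("missing traits are augmented from the Gaussian conditional", {
  # trait 1 linear observed pins the residual; trait 2 missing is drawn
  # untruncated from N(rho * e1, 1 - rho^2)
  ped <- founder_pedigree(5)
  y1 <- c(1.2, -0.4, 0.3, 2.0, -1.5)
  rec <- flat_records(ped$animal, y1)
  str <- make_structure(rec, ped, model_spec(traits = 1:2, scale = "linear"))
  st <- init_state(str)
  rho <- 0.6
  st$R0 <- matrix(c(1, rho, rho, 1), 2)
  set.seed(9)
  draws <- replicate(4000, sample_liabilities(st, str)$L[, 2])
  expect_equal(rowMeans(draws), rho * y1, tolerance = 0.1)
  expect_equal(unname(apply(draws, 1, var)), rep(1 - rho^2, 5),
               tolerance = 0.12)
})

test_that("location full conditionals match closed forms", {
  # single founder, single record, known variances:
  # E[a | rest] = (s2a / (s2a + s2e)) * (y - x'b)
  y <- 1.4
  ped2 <- founder_pedigree(1)
  rec2 <- flat_records(ped2$animal, y)
  spec2 <- model_spec(traits = 1, scale = "linear", factors = character(0))
  str2 <- build_mme_structure(rec2, ped2, spec2)
  st2 <- init_state(str2)
  st2$G0 <- matrix(0.3, 1, 1)
  st2$R0 <- matrix(0.7, 1, 1)
  set.seed(11)
  draws2 <- replicate(8000, .cg_step_location(st2, str2, TRUE)$a[1, 1])
  shrink <- 0.3 / (0.3 + 0.7)
  expect_equal(mean(draws2), shrink * y, tolerance = 0.02)
  expect_equal(var(draws2), shrink * 0.7, tolerance = 0.05)

  # fixed-effect conjugacy: n records at one level, no genetic term ->
  # mean = level residual mean, variance = s2e / n
  n <- 50
  ped3 <- founder_pedigree(n)
  set.seed(12)
  yy <- rnorm(n, 2, 1)
  rec3 <- flat_records(ped3$animal, yy)
  spec3 <- model_spec(traits = 1, scale = "linear", genetic = FALSE)
  str3 <- make_structure(rec3, ped3, spec3)
  st3 <- init_state(str3)
  st3$G0 <- matrix(0, 1, 1)
  st3$R0 <- matrix(0.8, 1, 1)
  draws3 <- replicate(6000, .cg_step_location(st3, str3, FALSE)$b[[1]][1])
  expect_equal(mean(draws3), mean(yy), tolerance = 0.02)
  expect_equal(var(draws3), 0.8 / n, tolerance = 0.06)
})

test_that("prior-only breeding values are N(0, G0) with no records and A = I", {
  ped <- founder_pedigree(400)
  # one dummy record on one animal keeps the structure non-empty; inspect
  # the other 399 animals, whose full conditional is the prior
  rec <- flat_records(ped$animal[1], 0.5)
  spec <- model_spec(traits = 1, scale = "linear", factors = character(0))
  str <- build_mme_structure(rec, ped, spec)
  st <- init_state(str)
  st$G0 <- matrix(0.4, 1, 1)
  set.seed(13)
  out <- .cg_step_location(st, str, TRUE)
  prior_draws <- out$a[2:400, 1]
  expect_lt(abs(mean(prior_draws)), 3 * sqrt(0.4 / 399))
  expect_lt(abs(var(prior_draws) - 0.4), 3 * 0.4 * sqrt(2 / 398))
})

test_that("G0 full conditional matches the scaled inverse chi-square closed form", {
  # univariate, A = I, Jeffreys prior (nu = 0, S = 0), fixed a:
  # sigma2_a | a ~ (a'a) / chisq(q)
  q <- 60
  ped <- founder_pedigree(q)
  rec <- flat_records(ped$animal[1], 0.5)
  spec <- model_spec(traits = 1, scale = "linear", factors = character(0),
                     nu_a = 0, S_a = matrix(0, 1, 1))
  str <- build_mme_structure(rec, ped, spec)
  st <- init_state(str)
  set.seed(14)
  st$a <- matrix(rnorm(q, 0, 0.5), q, 1)
  ss <- sum(st$a^2)
  draws <- replicate(10000, sample_G0(st, str)$G0[1, 1])
  u <- pchisq(ss / draws, df = q)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("genetic cross-products agree with the dense algebraic oracle", {
  set.seed(15)
  ped <- random_pedigree(50)
  rec <- flat_records(ped$animal[1:10], rbinom(10, 1, 0.5))
  spec <- model_spec(traits = 1:2, scale = "linear")
  str <- make_structure(rec, ped, spec)
  st <- init_state(str)
  st$a <- matrix(rnorm(100), 50, 2)
  M <- .cg_genetic_crossprod(st, str)
  Ainv <- as.matrix(relationship_inverse(ped))
  M_oracle <- t(st$a) %*% Ainv %*% st$a
  expect_lt(max(abs(M - M_oracle)), 1e-10)
})

test_that("R0 identification pin produces exactly unit threshold diagonals", {
  set.seed(16)
  ped <- founder_pedigree(80)
  rec <- do.call(rbind, lapply(1:2, function(t) {
    flat_records(ped$animal, rbinom(80, 1, 0.4), parity = t)
  }))
  str <- make_structure(rec, ped, model_spec(traits = 1:2))
  st <- init_state(str)
  st$E <- matrix(rnorm(160), 80, 2)
  out <- sample_R0(st, str, rescale = TRUE)
  expect_equal(diag(out$R0), c(1, 1))
  free <- sample_R0(st, str, rescale = FALSE)
  expect_false(isTRUE(all.equal(diag(free$R0), c(1, 1))))
})

test_that("univariate linear residual draws match the conjugate closed form", {
  # fixed residual vector, Jeffreys prior: sigma2_e | e ~ (e'e) / chisq(n)
  n <- 80
  ped <- founder_pedigree(n)
  set.seed(17)
  e <- rnorm(n)
  rec <- flat_records(ped$animal, e)
  spec <- model_spec(traits = 1, scale = "linear", factors = character(0),
                     nu_e = 0, S_e = matrix(0, 1, 1))
  str <- build_mme_structure(rec, ped, spec)
  st <- init_state(str)
  st$E <- matrix(e, n, 1)
  draws <- replicate(10000, sample_R0(st, str)$R0[1, 1])
  u <- pchisq(sum(e^2) / draws, df = n)
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("retained draws carry no negative variances and unit threshold residuals", {
  sim <- small_herd(seed = 71, n_does = 150)
  fit <- run_gibbs(sim$records, sim$pedigree, model_spec(),
                   gibbs_config(800, 200, 5, seed = 3))
  k <- 3
  gdiag <- fit$G0_draws[, (0:2) * 3 + 1:3]
  rdiag <- fit$R0_draws[, (0:2) * 3 + 1:3]
  expect_true(all(gdiag > 0))
  expect_equal(unname(rdiag), matrix(1, nrow(rdiag), 3))
})

test_that("probit limit: with no genetic variance the intercept matches the incidence", {
  set.seed(18)
  n <- 800
  ped <- founder_pedigree(n)
  y <- rbinom(n, 1, 0.3)
  rec <- flat_records(ped$animal, y)
  spec <- model_spec(traits = 1, scale = "threshold", factors = "year",
                     genetic = FALSE)
  fit <- suppressWarnings(run_gibbs(rec, ped, spec, gibbs_config(4000, 500, 5, seed = 4)))
  b_draws <- fit$b_mean[[1]]   # posterior mean intercept (identified scale)
  expect_equal(unname(pnorm(b_draws)), mean(y), tolerance = 0.03)
})
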
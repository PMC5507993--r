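test_that("collinearity screen behaves on orthogonal, duplicated and correlated designs", {
  set.seed(31)
  n <- 60
  # near-orthogonal balanced +-1 design: all condition indexes 1, no flags
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  x3 <- rep(c(-1, 1, 1, -1), n / 4)
  orth <- tibble::tibble(outcome = rep(0:1, n / 2),
                         a = x1, b = x2, c = x3)
  sc <- screen_collinearity(orth, c("a", "b", "c"))
  expect_true(all(abs(sc$condition_indexes - 1) < 1e-8))
  expect_length(sc$flags, 0L)
  # each variable's proportions sum to one across dimensions
  expect_equal(unname(colSums(sc$variance_proportions)),
               rep(1, 4), tolerance = 1e-8)
  expect_true(all(diff(sc$condition_indexes) >= 0))

  # an exactly duplicated predictor is flagged with infinite condition index
  dup <- tibble::tibble(outcome = rep(0:1, 20), a = rnorm(40))
  dup$b <- dup$a
  sd2 <- screen_collinearity(dup, c("a", "b"))
  expect_true(is.infinite(max(sd2$condition_indexes)))
  expect_gte(length(sd2$flags), 1L)
  flagged_vars <- unlist(lapply(sd2$flags, `[[`, "variables"))
  expect_true(all(c("a", "b") %in% flagged_vars))

  # a moderately correlated pair stays below 30 and is not flagged
  a <- rnorm(200)
  cor_df <- tibble::tibble(outcome = rep(0:1, 100), a = a + 3,
                           b = a + 3 + rnorm(200, sd = 0.6))
  sc3 <- screen_collinearity(cor_df, c("a", "b"))
  expect_lt(max(sc3$condition_indexes), 30)
  expect_length(sc3$flags, 0L)
})

test_that("the x*ln(x) linearity test keeps linear logits and flags curvature", {
  set.seed(42)
  n <- 300
  keep <- 0L; flag <- 0L
  reps <- 200
  for (r in 1:reps) {
    x <- rexp(n, 1 / 5) + 0.5
    y_lin <- rbinom(n, 1, plogis(-1 + 0.25 * x))
    p_lin <- test_logit_linearity(
      tibble::tibble(outcome = y_lin, x = x), "x")$p_values
    if (p_lin > 0.05) keep <- keep + 1L
    y_quad <- rbinom(n, 1, plogis(-2.5 + 1.2 * (x - 5)^2 / 5))
    p_quad <- test_logit_linearity(
      tibble::tibble(outcome = y_quad, x = x), "x")$p_values
    if (p_quad <= 0.05) flag <- flag + 1L
  }
  expect_gte(keep / reps, 0.90)   # size: linear logits rarely rejected
  expect_gte(flag / reps, 0.80)   # power: strong curvature detected
})

test_that("linearity test shifts zero-valued predictors and rejects negatives", {
  df <- tibble::tibble(outcome = rep(0:1, 30),
                       x = rep(c(0, 1, 2, 4, 5, 7), 10))
  res <- test_logit_linearity(df, "x")
  expect_equal(unname(res$shifts["x"]), 1)
  df$x[1] <- -2
  expect_error(test_logit_linearity(df, "x"), "positive")
})

test_that("z-score outlier screen flags exactly the planted case", {
  same <- tibble::tibble(outcome = rep(0:1, 10), x = rep(2, 20), y = rep(3, 20))
  expect_length(screen_outliers(same, c("x", "y")), 0L)

  set.seed(8)
  x <- rnorm(300)
  x[137] <- mean(x[-137]) + 5 * sd(x[-137])
  df <- tibble::tibble(outcome = rep(0:1, 150), x = x)
  expect_equal(screen_outliers(df, "x"), 137L)

  # |z| exactly at the threshold is not flagged (strict inequality)
  set.seed(9)
  x2 <- rnorm(50)
  df2 <- tibble::tibble(outcome = rep(0:1, 25), x = x2)
  zmax <- max(abs((x2 - mean(x2)) / sd(x2)))
  expect_length(screen_outliers(df2, "x", threshold = zmax), 0L)
  expect_length(screen_outliers(df2, "x", threshold = zmax * 0.999), 1L)
})

test_that("zero-pass SOP cases are dropped; UOP ones retained", {
  cases <- tibble::tibble(outcome = c(1L, 1L, 0L, 1L, 0L),
                          total_passes = c(0L, 0L, 0L, 4L, 2L))
  kept <- drop_zero_pass_sop(cases)
  expect_equal(nrow(kept), 3L)
  expect_true(all(!(kept$outcome == 1 & kept$total_passes == 0)))
  full <- tibble::tibble(outcome = c(1L, 0L), total_passes = c(3L, 5L))
  expect_equal(drop_zero_pass_sop(full), full)
})

test_that("metric rescaling multiplies by 10 once and preserves the fit", {
  cases <- tibble::tibble(outcome = rep(0:1, 30),
                          total_passes = rpois(60, 10),
                          density = runif(60, 0, 0.25),
                          clustering = runif(60, 0, 0.3),
                          centralization = runif(60, 0, 0.5))
  r <- rescale_metrics(cases)
  expect_equal(r$density, cases$density * 10)
  expect_equal(r$total_passes, cases$total_passes)
  expect_error(rescale_metrics(r), "twice")

  fit_raw <- fit_logistic(cases, "density")
  fit_res <- fit_logistic(r, "density")
  expect_equal(unname(fit_res$coef["density"]),
               unname(fit_raw$coef["density"]) / 10, tolerance = 1e-8)
  expect_equal(fit_res$loglik, fit_raw$loglik, tolerance = 1e-10)
})

test_that("logistic fit matches closed forms and an independent ML oracle", {
  # balanced outcome, intercept only: beta0 = 0, odds ratio 1
  bal <- tibble::tibble(outcome = rep(0:1, 25))
  f0 <- fit_logistic(bal, character(0))
  expect_equal(unname(f0$coef[1]), 0, tolerance = 1e-12)
  expect_equal(unname(f0$odds_ratio[1]), 1, tolerance = 1e-12)

  # single binary predictor: beta = log cross-product ratio of the 2x2 table
  tab <- c(a = 18, b = 7, c = 9, d = 21)  # x=1: a success/b fail; x=0: c/d
  df <- tibble::tibble(
    outcome = c(rep(1, tab["a"]), rep(0, tab["b"]),
                rep(1, tab["c"]), rep(0, tab["d"])),
    x = c(rep(1, tab["a"] + tab["b"]), rep(0, tab["c"] + tab["d"])))
  f1 <- fit_logistic(df, "x")
  expect_equal(unname(f1$coef["x"]),
               log((tab["a"] * tab["d"]) / (tab["b"] * tab["c"])),
               tolerance = 1e-8, ignore_attr = TRUE)

  # small random designs: IRLS agrees with Nelder-Mead ML to 1e-5
  set.seed(12)
  for (r in 1:5) {
    n <- 50
    X <- cbind(1, rnorm(n), runif(n))
    y <- rbinom(n, 1, plogis(X %*% c(-0.3, 0.8, -1)))
    d <- tibble::tibble(outcome = y, x1 = X[, 2], x2 = X[, 3])
    fit <- fit_logistic(d, c("x1", "x2"))
    oracle <- logistic_ml_oracle(y, X)
    expect_equal(unname(fit$coef), oracle, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("planted coefficients are recovered within 3 standard errors", {
  set.seed(777)
  truth <- c(-0.6, 0.08, -1.3)
  cases <- simulate_cases(5000, coef = truth)
  cases10 <- rescale_metrics(cases)
  fit <- fit_logistic(cases10, c("total_passes", "density"))
  est <- unname(fit$coef)
  se <- unname(fit$se)
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("separation is detected and loudly reported", {
  set.seed(3)
  df <- tibble::tibble(outcome = rep(c(0L, 1L), each = 10),
                       x = c(rnorm(10, -4), rnorm(10, 4)))
  w <- capture_warnings(fit <- fit_logistic(df, "x"))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation)
  # diagnostics remain usable: the toy data classify perfectly
  expect_equal(fit$classification$pct_overall, 100)
  expect_equal(fit$classification$pct_uop, 100)
  expect_equal(fit$classification$pct_sop, 100)
})

test_that("hierarchical blocks nest and their G statistics are additive", {
  cases <- demo_cases()
  sc <- screen_cases(cases)
  hf <- hierarchical_fit(sc$cases)
  expect_gte(hf$block2$loglik, hf$block1$loglik)
  expect_gte(hf$block1$loglik, hf$block1$loglik_null)
  expect_equal(hf$block2$G, hf$block1$G + hf$improvement$G,
               tolerance = 1e-8)
  expect_equal(hf$improvement$df, 3L)
})

test_that("rescaling a predictor by k divides its beta by k and fixes all else", {
  cases <- demo_cases()
  sc <- screen_cases(cases)
  k <- 4
  scaled <- sc$cases
  scaled$total_passes <- scaled$total_passes * k
  f1 <- fit_logistic(sc$cases, c("total_passes", "density"))
  f2 <- fit_logistic(scaled, c("total_passes", "density"))
  expect_equal(unname(f2$coef["total_passes"]),
               unname(f1$coef["total_passes"]) / k, tolerance = 1e-8)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-10)
  expect_equal(f2$G, f1$G, tolerance = 1e-8)
  expect_equal(f2$nagelkerke_r2, f1$nagelkerke_r2, tolerance = 1e-8)
  expect_equal(f2$hl_chi2, f1$hl_chi2, tolerance = 1e-6)
  expect_equal(f2$classification$pct_overall, f1$classification$pct_overall)
})

test_that("Hosmer-Lemeshow uses groups-2 df and degrades gracefully", {
  cases <- demo_cases()
  sc <- screen_cases(cases)
  fit <- fit_logistic(sc$cases, c("total_passes", "density"))
  hl <- hosmer_lemeshow(fit, groups = 10)
  expect_equal(hl$df, 8L)
  expect_true(hl$chi2 >= 0)

  # a constant fit has a single distinct fitted value: df collapses
  f0 <- fit_logistic(tibble::tibble(outcome = rep(0:1, 20)), character(0))
  hl0 <- hosmer_lemeshow(f0, groups = 10)
  expect_equal(hl0$df, 0L)

  # two distinct fitted values: merged bins, reduced df
  df2 <- tibble::tibble(outcome = rbinom(200, 1, 0.5),
                        x = rep(0:1, each = 100))
  f2 <- fit_logistic(df2, "x")
  hl2 <- hosmer_lemeshow(f2, groups = 10)
  expect_lt(hl2$df, 8L)
})

test_that("Hosmer-Lemeshow p-values are near-uniform under a correct model", {
  set.seed(2026)
  reps <- 400
  pv <- numeric(reps)
  for (r in 1:reps) {
    n <- 1000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
    fit <- fit_logistic(tibble::tibble(outcome = y, x = x), "x")
    pv[r] <- fit$hl_p
  }
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  # no gross excess of small p-values either
  expect_lt(mean(pv < 0.05), 0.10)
})

test_that("Nagelkerke r2 follows its closed form and limits", {
  mk <- function(ll0, ll1, n) list(loglik = ll1, loglik_null = ll0, n = n)
  expect_equal(nagelkerke_r2(mk(-60, -60, 100)), 0)
  expect_gt(nagelkerke_r2(mk(-60, -1e-9, 100)), 0.999)
  ll0 <- -19.2; ll1 <- -14.7; n <- 30
  hand <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(nagelkerke_r2(mk(ll0, ll1, n)), hand)
  # against a fitted model
  cases <- demo_cases()
  fit <- fit_logistic(screen_cases(cases)$cases, "density")
  hand2 <- (1 - exp(2 * (fit$loglik_null - fit$loglik) / fit$n)) /
    (1 - exp(2 * fit$loglik_null / fit$n))
  expect_equal(fit$nagelkerke_r2, hand2)
})

test_that("classification table matches manual counts", {
  # hand-checkable 10-case fixture
  fit <- list(fitted = c(0.9, 0.8, 0.7, 0.6, 0.55, 0.45, 0.4, 0.3, 0.2, 0.1),
              y = c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0))
  ct <- classification_table(fit, cutoff = 0.5)
  # predicted 1 for the first five: correct for cases 1,2,4; predicted 0
  # for the last five: correct for 7,8,10
  expect_equal(unname(ct$table["1", "1"]), 3)
  expect_equal(unname(ct$table["0", "0"]), 3)
  expect_equal(ct$pct_sop, 60)
  expect_equal(ct$pct_uop, 60)
  expect_equal(ct$pct_overall, 60)

  # constant-only model on 60/40 data predicts the majority class
  df <- tibble::tibble(outcome = rep(c(0L, 1L), c(60, 40)))
  f0 <- fit_logistic(df, character(0))
  ct0 <- f0$classification
  expect_equal(ct0$pct_uop, 100)
  expect_equal(ct0$pct_sop, 0)
  expect_equal(ct0$pct_overall, 60)
})

test_that("model report renders Table-style output and round-trips as JSON", {
  or <- odds_ratio(0.079, 0.034)
  expect_equal(round(or$odds_ratio, 3), 1.082)

  cases <- demo_cases()
  sc <- screen_cases(cases)
  hf <- hierarchical_fit(sc$cases)
  path <- withr::local_tempfile(fileext = ".json")
  rep <- model_report(sc$report, hf, path = path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$block2$beta, unname(hf$block2$coef))
  expect_equal(back$block2$nagelkerke_r2, hf$block2$nagelkerke_r2)
  expect_equal(back$improvement$G, hf$improvement$G)
  for (blk in c("block1", "block2")) {
    expect_true(all(c("G", "nagelkerke_r2", "hl_chi2", "classification") %in%
                      names(back[[blk]])))
  }
  expect_true(any(grepl("Exp\\(b\\)", rep$text)))
  # odds ratios and CI ordering
  expect_true(all(hf$block2$ci95[, "lower"] < hf$block2$odds_ratio))
  expect_true(all(hf$block2$odds_ratio < hf$block2$ci95[, "upper"]))
})
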
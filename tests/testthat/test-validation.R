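t11 <- load_fixture("table11_fda_descriptors")

test_that("paired metrics reproduce the printed regression evaluation", {
  mw <- paired_metrics(paired_series(t11$mw_exp, t11$mw_pred))
  expect_equal(mw$n, 63)
  expect_within(mw$rmse, 0.230, 0.005)
  expect_within(mw$mae, 0.152, 0.005)
  expect_within(mw$rmse_baseline, 72.469, 0.005)
  tpsa <- paired_metrics(paired_series(t11$tpsa_exp, t11$tpsa_pred))
  expect_within(tpsa$pearson_r, 0.995, 0.005)
  expect_within(tpsa$mae, 2.712, 0.005)
  # LogP pairs only exist for the 20 drugs with experimental data
  lp <- paired_metrics(paired_series(t11$logp_exp, t11$logp_pred))
  expect_equal(lp$n, 20)
  expect_equal(lp$n_excluded, 43)
  expect_within(lp$pearson_r, 0.645, 0.005)
})

test_that("improvement over the mean-only baseline matches the printed %", {
  impr <- vapply(list(c("mw_exp", "mw_pred"), c("tpsa_exp", "tpsa_pred"),
                      c("mr_exp", "mr_pred")), function(cols)
    paired_metrics(paired_series(t11[[cols[1]]],
                                 t11[[cols[2]]]))$improvement_fraction,
    numeric(1))
  expect_within(100 * impr, c(99.68, 85.80, 66.93), 0.1)
})

test_that("degenerate paired series behave as documented", {
  y <- c(1, 2, 3, 4, 5)
  ident <- paired_metrics(paired_series(y, y))
  expect_exact(ident$rmse, 0)
  expect_exact(ident$mae, 0)
  expect_exact(ident$pearson_r, 1)
  expect_exact(ident$improvement_fraction, 1)
  base <- paired_metrics(paired_series(y, rep(mean(y), 5)))
  expect_exact(base$rmse, base$rmse_baseline)
  expect_exact(base$improvement_fraction, 0)
  flat <- paired_metrics(paired_series(rep(2, 4), c(1, 2, 3, 4)))
  expect_exact(flat$rmse_baseline, 0)
  expect_true(is.na(flat$improvement_fraction))
  expect_error(paired_metrics(paired_series(1, 1)), "at least 2")
})

test_that("metrics agree with a per-element loop oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    ye <- rnorm(n); yp <- ye + rnorm(n, sd = 0.3)
    m <- paired_metrics(paired_series(ye, yp))
    sse <- 0; sae <- 0; ssd <- 0
    for (j in seq_len(n)) {
      sse <- sse + (ye[j] - yp[j])^2
      sae <- sae + abs(ye[j] - yp[j])
      ssd <- ssd + (ye[j] - sum(ye) / n)^2
    }
    expect_equal(m$rmse, sqrt(sse / n), tolerance = 1e-12)
    expect_equal(m$mae, sae / n, tolerance = 1e-12)
    expect_equal(m$rmse_baseline, sqrt(ssd / n), tolerance = 1e-12)
    expect_equal(m$r2, 1 - sse / ssd, tolerance = 1e-12)
    expect_gte(m$rmse, m$mae)   # Jensen
  }
})

test_that("linear fits match the printed coefficient tables", {
  tpsa <- linear_fit(paired_series(t11$tpsa_exp, t11$tpsa_pred),
                     direction = "exp_on_pred")
  expect_within(tpsa$slope, 1.012, 0.005)
  expect_within(tpsa$pearson_r, 0.995, 0.005)
  expect_within(tpsa$ci_slope, c(0.988, 1.037), 0.005)
  mw <- linear_fit(paired_series(t11$mw_exp, t11$mw_pred))
  expect_within(mw$slope, 1.000, 0.005)
  expect_within(mw$intercept, 0.159, 0.005)
  # LogP regressed the other way round (predicted on experimental)
  lp <- linear_fit(paired_series(t11$logp_exp, t11$logp_pred),
                   direction = "pred_on_exp")
  expect_within(lp$slope, 0.481, 0.005)
  lp2 <- linear_fit(paired_series(t11$logp_exp, t11$logp_molinsp_molsoft),
                    direction = "pred_on_exp")
  expect_within(lp2$slope, 0.603, 0.005)
  expect_within(lp2$pearson_r, 0.750, 0.005)
})

test_that("noiseless and simulated fits recover known parameters", {
  x <- 1:5
  exact <- linear_fit(paired_series(2 * x + 1, x), direction = "exp_on_pred")
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  expect_equal(exact$intercept, 1, tolerance = 1e-10)
  expect_equal(diff(exact$ci_slope), 0, tolerance = 1e-8)
  set.seed(99)
  rho <- 0.8
  z <- rnorm(200); e <- rnorm(200)
  a <- z; b <- rho * z + sqrt(1 - rho^2) * e
  fit <- linear_fit(paired_series(a, b))
  expect_equal(fit$pearson_r, rho, tolerance = 0.08)
  expect_error(linear_fit(paired_series(1:5, rep(3, 5))), "zero variance")
})

test_that("confusion matrices tally the reference toxicity calls", {
  t14 <- load_fixture("table14_admet_expvspred")
  herg <- confusion(t14$herg_exp, t14$herg_pred, positive_label = "positive")
  expect_equal(herg$n, 13)
  expect_equal(c(herg$tp, herg$fn, herg$tn, herg$fp), c(5, 1, 5, 2))
  expect_within(herg$se, 0.833, 5e-4)
  expect_within(herg$sp, 0.714, 5e-4)
  expect_within(herg$acc, 0.769, 5e-4)
  ames <- confusion(t14$ames_exp, t14$ames_pred, positive_label = "positive")
  expect_equal(ames$se, 1.00)
  # counts partition the experimental classes after exclusion
  for (param in c("ames", "carcinogenicity", "herg", "hepatotoxicity")) {
    e <- t14[[paste0(param, "_exp")]]
    r <- confusion(e, t14[[paste0(param, "_pred")]], "positive")
    expect_equal(r$tp + r$fn, sum(e == "positive", na.rm = TRUE))
    expect_equal(r$tn + r$fp, sum(e == "negative", na.rm = TRUE))
    expect_equal(r$n + r$n_excluded, 63)
  }
})

test_that("every published endpoint model metric is reproduced", {
  t14 <- load_fixture("table14_admet_expvspred")
  expected <- list(  # published SE / SP / ACC per endpoint model
    bioavailability = c(0.714, 0.600, 0.674),
    ppb             = c(0.700, 0.909, 0.738),
    carcinogenicity = c(0.625, 0.682, 0.667),
    hepatotoxicity  = c(0.500, 0.625, 0.550),
    ames            = c(1.000, 0.604, 0.611))
  positive <- c(bioavailability = "high", ppb = "high",
                carcinogenicity = "positive", hepatotoxicity = "positive",
                ames = "positive")
  for (p in names(expected)) {
    r <- confusion(t14[[paste0(p, "_exp")]], t14[[paste0(p, "_pred")]],
                   positive[[p]])
    expect_within(c(r$se, r$sp, r$acc), expected[[p]], 5e-4)
  }
  # clearance badly under-detects positives, which is why it is excluded
  # from the screen
  cl <- confusion(t14$clearance_exp, t14$clearance_pred, "high")
  expect_within(cl$se, 0.0714, 5e-4)
  expect_lt(cl$se, 0.5)
})

test_that("confusion handles perfect agreement and absent classes", {
  p <- confusion(c("a", "a", "b"), c("a", "a", "b"), "a")
  expect_exact(c(p$se, p$sp, p$acc), c(1, 1, 1))
  noneg <- confusion(c("a", "a"), c("a", "b"), "b")
  expect_true(is.na(noneg$se))   # positive class absent, not 0/0
  expect_error(confusion(c(NA, NA), c("a", "b"), "a"), "no rows")
})
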
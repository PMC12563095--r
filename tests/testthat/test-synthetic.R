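test_that("generators are byte-identical across runs at a fixed seed", {
  cfg <- sim_config(n_compounds = 50, seed = 77)
  expect_identical(gen_descriptor_tables(cfg), gen_descriptor_tables(cfg))
  expect_identical(gen_qual_tables(cfg), gen_qual_tables(cfg))
  expect_identical(gen_docking_set(cfg), gen_docking_set(cfg))
  expect_error(sim_config(n_compounds = 10), "seed")
  expect_error(sim_config(n_platforms = 0, seed = 1), "n_platforms")
})

test_that("noise-free tables recover the truth exactly through consensus", {
  cfg <- sim_config(n_compounds = 40, n_platforms = 5,
                    platform_noise_sd = c(MW = 0, TPSA = 0, MR = 0,
                                          LogP = 0, nRB = 0, nHA = 0,
                                          nHD = 0, nRings = 0, nRigidB = 0,
                                          nAtoms = 0),
                    missing_rate = 0, seed = 5)
  sim <- gen_descriptor_tables(cfg)
  mwp <- sim$platforms[sim$platforms$descriptor == "MW", ]
  cons <- tapply(mwp$value, mwp$compound_id, consensus_mean)
  expect_equal(as.numeric(cons[sim$truth$compound_id]), sim$truth$MW,
               tolerance = 1e-12)
})

test_that("a platform that is always missing never affects the consensus", {
  base <- sim_config(n_compounds = 60, n_platforms = 4,
                     missing_rate = c(1, 0, 0, 0), seed = 13)
  sim <- gen_descriptor_tables(base)
  mwp <- sim$platforms[sim$platforms$descriptor == "MW", ]
  expect_true(all(is.na(mwp$value[mwp$platform == "P1"])))
  with_p1 <- tapply(mwp$value, mwp$compound_id, function(v)
    mean(v, na.rm = TRUE))
  without <- tapply(mwp$value[mwp$platform != "P1"],
                    mwp$compound_id[mwp$platform != "P1"],
                    function(v) mean(v, na.rm = TRUE))
  expect_equal(with_p1[names(without)], without)
})

test_that("consensus beats a single platform on noisy descriptor tables", {
  sim <- gen_descriptor_tables(sim_config(n_compounds = 1000,
                                          n_platforms = 8, seed = 101))
  lp <- sim$platforms[sim$platforms$descriptor == "LogP", ]
  truth <- setNames(sim$truth$LogP, sim$truth$compound_id)
  cons <- tapply(lp$value, lp$compound_id, function(v)
    if (all(is.na(v))) NA else mean(v, na.rm = TRUE))
  cons_err <- mean(abs(cons[names(truth)] - truth), na.rm = TRUE)
  single <- lp[lp$platform == "P3", ]
  single_err <- mean(abs(single$value - truth[single$compound_id]),
                     na.rm = TRUE)
  expect_lt(cons_err, single_err)
})

test_that("majority vote beats a single platform on flipped call tables", {
  cfg <- sim_config(n_compounds = 1000, n_platforms = 6,
                    call_flip_rate = 0.2, seed = 19)
  sim <- gen_qual_tables(cfg, parameters = "ames")
  calls <- sim$platforms
  truth <- setNames(sim$truth$ames, sim$truth$compound_id)
  cons <- vapply(sim$truth$compound_id, function(id) {
    v <- calls[calls$compound_id == id, ]
    majority_vote(setNames(v$call, v$platform), parameter = "ames",
                  tiebreak_platforms = c("P1", "P2"))$consensus
  }, "")
  acc_cons <- mean(cons == truth)
  acc_single <- mean(calls$call[calls$platform == "P4"] == truth)
  expect_gt(acc_cons, acc_single)
  expect_gt(acc_cons, 0.9)   # 6 voters at 80% accuracy
})

test_that("two disagreeing platforms tie at the binomial rate", {
  cfg <- sim_config(n_compounds = 1500, n_platforms = 2,
                    call_flip_rate = 0.5, seed = 23)
  sim <- gen_qual_tables(cfg, parameters = "pgp_substrate")
  calls <- sim$platforms
  ties <- vapply(sim$truth$compound_id, function(id) {
    v <- calls[calls$compound_id == id, ]
    majority_vote(setNames(v$call, v$platform),
                  parameter = "pgp_substrate",
                  tiebreak_platforms = c("P1", "P2"))$tie_broken
  }, logical(1))
  # binary calls, each correct w.p. 0.5: disagreement probability 1/2
  expect_equal(mean(ties), 0.5, tolerance = 0.05)
})

test_that("flip-free call tables are recovered perfectly", {
  cfg <- sim_config(n_compounds = 30, n_platforms = 4, call_flip_rate = 0,
                    seed = 3)
  sim <- gen_qual_tables(cfg, parameters = c("hia", "herg"))
  for (param in c("hia", "herg")) {
    sub <- sim$platforms[sim$platforms$parameter == param, ]
    cons <- vapply(sim$truth$compound_id, function(id) {
      v <- sub[sub$compound_id == id, ]
      majority_vote(setNames(v$call, v$platform), parameter = param)$consensus
    }, "")
    expect_equal(unname(cons), sim$truth[[param]])
  }
})

test_that("docking sets expose the benchmark shape and null behaviour", {
  cfg <- sim_config(seed = 55)     # defaults: 30 actives among 302 decoys
  ds <- gen_docking_set(cfg)
  expect_equal(nrow(ds), 332)
  expect_equal(sum(ds$is_active), 30)
  er <- enrichment_factor(ds$is_active, 0.10, scores = ds$score)
  expect_equal(er$n_total, 332)
  expect_equal(er$actives_total, 30)
  expect_equal(er$n_top, 33)

  # no separation: AUC ~ 0.5, EF ~ 1 over replicates
  aucs <- efs <- numeric(30)
  for (i in 1:30) {
    d0 <- gen_docking_set(sim_config(score_separation = 0, seed = 100 + i))
    aucs[i] <- roc_auc(d0$score, d0$is_active)
    efs[i] <- enrichment_factor(d0$is_active, 0.10)$ef
  }
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  expect_equal(mean(efs), 1, tolerance = 0.35)

  # large separation: near-perfect ranking hits the EF upper bound
  dbig <- gen_docking_set(sim_config(score_separation = 10, seed = 7))
  expect_equal(roc_auc(dbig$score, dbig$is_active), 1, tolerance = 1e-6)
  expect_equal(enrichment_factor(dbig$is_active, 0.10)$ef,
               (30 / 33) / (30 / 332), tolerance = 1e-6)
})

test_that("generated tables survive the platform-table round trip", {
  sim <- gen_descriptor_tables(sim_config(n_compounds = 6, n_platforms = 2,
                                          seed = 31))
  # assemble a platform.parameter header table from the MW slice
  mw <- sim$platforms[sim$platforms$descriptor == "MW", ]
  df <- data.frame(compound_id = sim$truth$compound_id,
                   `P1.MW` = mw$value[mw$platform == "P1"][
                     match(sim$truth$compound_id,
                           mw$compound_id[mw$platform == "P1"])],
                   `P2.MW` = mw$value[mw$platform == "P2"][
                     match(sim$truth$compound_id,
                           mw$compound_id[mw$platform == "P2"])],
                   check.names = FALSE)
  recs <- read_platform_table(write_platform_csv(df))
  expect_length(recs, 6)
  got <- vapply(recs, function(r) r$platform_values$value[1], numeric(1))
  expect_equal(got, df$`P1.MW`, tolerance = 1e-6)
})
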
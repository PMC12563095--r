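test_that("majority vote reproduces the printed consensus calls", {
  plats <- c("PreADMET", "SwissADME", "AdmetLab3", "pkSCM", "Deep-PK",
             "admetSAR3")
  t4 <- load_fixture("table4_adme_calls")
  for (i in seq_len(nrow(t4))) {
    calls <- setNames(unlist(t4[i, plats]), plats)
    got <- majority_vote(calls, parameter = t4$parameter[i])
    expect_equal(got$consensus, t4$consensus_printed[i],
                 label = paste("table4", t4$parameter[i]))
  }
  t5 <- load_fixture("table5_tox_calls")
  plats5 <- c("PreADMET", "TEST", "AdmetLab3", "pkSCM", "Deep-PK",
              "admetSAR3")
  for (i in seq_len(nrow(t5))) {
    calls <- setNames(unlist(t5[i, plats5]), plats5)
    got <- majority_vote(calls, parameter = t5$parameter[i])
    expect_equal(got$consensus, t5$consensus_printed[i],
                 label = paste("table5", t5$parameter[i]))
  }
})

test_that("ties fall back to the configured tie-break platforms", {
  v <- majority_vote(c(AdmetLab3 = "positive", pkSCM = "negative"),
                     parameter = "ames")
  expect_equal(v$consensus, "positive")
  expect_true(v$tie_broken)
  # still tied within the tie-break subset: first configured platform wins
  v2 <- majority_vote(c(AdmetLab3 = "positive", `Deep-PK` = "negative"),
                      parameter = "ames")
  expect_equal(v2$consensus, "positive")
  expect_true(v2$tie_broken)
  expect_error(majority_vote(c(A = NA, B = NA)), "all platform calls missing")
  expect_error(majority_vote(c(A = "banana"), parameter = "ames"),
               "vocabulary")
})

test_that("majority vote ignores platform order and missing calls", {
  calls <- c(P1 = "high", P2 = "low", P3 = "high", P4 = "high")
  base <- majority_vote(calls, parameter = "hia")
  set.seed(3)
  for (i in 1:10) {
    perm <- sample(calls)
    expect_equal(majority_vote(perm, parameter = "hia")$consensus,
                 base$consensus)
  }
  expect_equal(majority_vote(c(calls, P5 = NA), parameter = "hia")$consensus,
               base$consensus)
})

test_that("category scoring reproduces every printed score bit-exactly", {
  t6 <- load_fixture("table6_druglikeness")
  for (i in seq_len(nrow(t6))) {
    s <- druglikeness_score(unlist(t6[i, c("lipinski", "ghose", "veber",
                                           "egan", "muegge", "mddr_like")]),
                            t6$qed[i])
    expect_exact(s$score, t6$score[i])
  }
  t7 <- load_fixture("table7_medchem")
  for (i in seq_len(nrow(t7))) {
    s <- medchem_score(unlist(t7[i, c("leadlikeness", "gsk", "pains",
                                      "brenk")]))
    expect_exact(s$score, t7$score[i])
  }
  t8 <- load_fixture("table8_bioavailability")
  for (i in seq_len(nrow(t8))) {
    s <- bioavailability_score(t8$caco2[i], t8$hia[i], t8$mdck[i],
                               t8$pgp_substrate[i], t8$pgp_inhibitor[i])
    expect_exact(s$score, t8$score[i])
    # the printed overall high/low call equals the threshold decision
    expect_equal(s$passed, t8$overall[i] == "high")
  }
  t10 <- load_fixture("table10_toxicity")
  for (i in seq_len(nrow(t10))) {
    s <- toxicity_score(t10$ames[i], t10$carcinogenicity[i], t10$herg[i],
                        t10$hepatotoxicity[i])
    expect_exact(s$score, t10$score[i])
  }
})

test_that("worked single-compound scores match the printed rows", {
  expect_exact(druglikeness_score(rep("pass", 6), 0.671)$score, 6.671)
  expect_exact(druglikeness_score(c("pass", "pass", "pass", "pass", "pass",
                                    "mid-structure"), 0.928)$score, 5.928)
  expect_exact(druglikeness_score(c("1 violation", "fail", "pass", "pass",
                                    "pass", "pass"), 0.428)$score, 4.928)
  expect_exact(medchem_score(rep("pass", 4))$score, 4)
  expect_exact(medchem_score(c("fail", "fail", "pass", "pass"))$score, 2)
  expect_exact(medchem_score(rep("fail", 4))$score, 0)
  expect_exact(bioavailability_score("high", "high", "high", "no", "no")$score,
               5)
  expect_exact(bioavailability_score("high", "high", "high", "yes",
                                     "yes")$score, 4)
  expect_exact(bioavailability_score("moderate", "high", "moderate", "yes",
                                     "no")$score, 2)
  expect_exact(toxicity_score("negative", "negative", "inactive",
                              "negative")$score, 4)
  expect_exact(toxicity_score("negative", "negative", "inactive",
                              "positive")$score, 3)
  expect_exact(toxicity_score("positive", "positive", "active",
                              "positive")$score, 0)
  expect_true(distribution_pass("low")$passed)
  expect_false(distribution_pass("high")$passed)
  expect_error(distribution_pass(NA), "ppb")
})

test_that("improving a permeability call never lowers the score", {
  lv <- c("low", "moderate", "high")
  for (c1 in 1:2) for (h in 1:2) for (m in 1:2)
    for (s in c("yes", "no")) for (i in c("yes", "no")) {
      base <- bioavailability_score(lv[c1], lv[h], lv[m], s, i)$score
      expect_gte(bioavailability_score(lv[c1 + 1], lv[h], lv[m], s, i)$score,
                 base)
      expect_gte(bioavailability_score(lv[c1], lv[h + 1], lv[m], s, i)$score,
                 base)
      expect_gte(bioavailability_score(lv[c1], lv[h], lv[m + 1], s, i)$score,
                 base)
    }
  # documented exception: becoming an inhibitor while not a substrate
  # lowers the combination score 2 -> 1
  expect_lt(bioavailability_score("high", "high", "high", "no", "yes")$score,
            bioavailability_score("high", "high", "high", "no", "no")$score)
})

test_that("screening the reference score tables selects 39 of 63 drugs", {
  scr <- admet_screen(load_fixture("table6_druglikeness"),
                      load_fixture("table7_medchem"),
                      load_fixture("table8_bioavailability"),
                      load_fixture("table9_distribution"),
                      load_fixture("table10_toxicity"))
  expect_equal(attr(scr, "n"), 63)
  expect_equal(sum(scr$selected), 39)
  # per-category pass counts implied by the printed tables
  sm <- summary(scr)
  expect_equal(unname(sm$category_passes),
               c(52, 43, 39, 26, 21))
  # determinism: identical rerun gives identical results
  scr2 <- admet_screen(load_fixture("table6_druglikeness"),
                       load_fixture("table7_medchem"),
                       load_fixture("table8_bioavailability"),
                       load_fixture("table9_distribution"),
                       load_fixture("table10_toxicity"))
  expect_identical(as.data.frame(scr), as.data.frame(scr2))
  expect_error(admet_screen(load_fixture("table6_druglikeness")[-1, ],
                            load_fixture("table7_medchem")[1:5, ],
                            load_fixture("table8_bioavailability"),
                            load_fixture("table9_distribution"),
                            load_fixture("table10_toxicity")),
               "missing a category")
})

test_that("membership-list selection reproduces the printed 14 compounds", {
  t15 <- load_fixture("table15_hits")
  hs <- hit_selection(as.list(t15))
  expect_equal(sum(hs$selected), 14)
  t16 <- load_fixture("table16_selected")
  expect_setequal(normalize_compound_id(hs$compound_id[hs$selected]),
                  normalize_compound_id(t16$id))
  # a 3-hit compound is selected with its violated categories implied
  tki8 <- hs[normalize_compound_id(hs$compound_id) == "TKI8", ]
  expect_equal(tki8$hits, 3)
  expect_true(tki8$selected)
})
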
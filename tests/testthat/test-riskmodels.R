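score_to_cat_ref <- function(s, cut) {
  if (s < cut[1]) 1L else if (s < cut[2]) 2L else 3L
}

test_that("MIPI score follows its published linear form", {
  k <- mipi_constants()$mipi
  # age 65, ECOG 1, LDH at its ULN, WBC 7.0e9/L (= 7000 per 1e6/L)
  res <- mipi_score(age = 65, ecog = 1, ldh = 240, ldh_uln = 240, wbc = 7.0)
  expect_equal(res$score, k$age * 65 + k$wbc * log10(7000))
  expect_equal(res$category, score_to_cat_ref(res$score, k$cut))

  # all terms vanish: age 0, ECOG 0, LDH = ULN, WBC 1e6/L = 0.001e9/L
  expect_equal(mipi_score(0, 0, 100, 100, 0.001)$score, 0)

  # ECOG >= 2 adds exactly the ECOG coefficient
  a <- mipi_score(60, 1, 200, 240, 8)
  b <- mipi_score(60, 2, 200, 240, 8)
  expect_equal(b$score - a$score, k$ecog)
  # and ECOG 3 scores the same as ECOG 2 (indicator, not linear)
  expect_equal(mipi_score(60, 3, 200, 240, 8)$score, b$score)

  expect_error(mipi_score(60, 0, -5, 240, 8), "positive")
  expect_error(mipi_score(60, 0, 200, 240, 0), "positive")
})

test_that("MIPI-b adds the Ki-67 term with its own cutpoints", {
  k <- mipi_constants()$mipi_b
  base <- mipi_b_score(65, 1, 240, 240, 7, ki67 = 0)
  expect_equal(base$score, mipi_score(65, 1, 240, 240, 7)$score)
  a <- mipi_b_score(60, 0, 200, 240, 8, 30)
  b <- mipi_b_score(60, 0, 200, 240, 8, 31)
  expect_equal(b$score - a$score, k$ki67)
  expect_error(mipi_b_score(60, 0, 200, 240, 8, 140), "0, 100")
  # category distribution shifts upward from low to high Ki-67
  set.seed(1)
  n <- 300
  age <- rnorm(n, 64, 10); ecog <- sample(0:2, n, TRUE)
  ldh <- rlnorm(n, log(220), 0.3); wbc <- rlnorm(n, log(7), 0.4)
  lo <- mipi_b_score(age, ecog, ldh, 240, wbc, runif(n, 0, 10))$category
  hi <- mipi_b_score(age, ecog, ldh, 240, wbc, runif(n, 80, 100))$category
  expect_gt(mean(hi), mean(lo))
  for (kcat in 1:3)   # stochastic dominance of the category distribution
    expect_lte(mean(hi <= kcat), mean(lo <= kcat))
})

test_that("MIPI scores increase in age, LDH ratio, WBC and Ki-67", {
  base <- list(age = 60, ecog = 1, ldh = 200, uln = 240, wbc = 7, ki67 = 30)
  s0 <- mipi_b_score(base$age, base$ecog, base$ldh, base$uln, base$wbc, base$ki67)$score
  expect_gt(mipi_b_score(61, base$ecog, base$ldh, base$uln, base$wbc, base$ki67)$score, s0)
  expect_gt(mipi_b_score(base$age, base$ecog, 260, base$uln, base$wbc, base$ki67)$score, s0)
  expect_gt(mipi_b_score(base$age, base$ecog, base$ldh, base$uln, 9, base$ki67)$score, s0)
  expect_gt(mipi_b_score(base$age, base$ecog, base$ldh, base$uln, base$wbc, 40)$score, s0)
})

test_that("metabolic risk reproduces the category definitions at boundaries", {
  cfg3 <- signature_config(3.55, 3.5, 3)
  cfg2 <- signature_config(3.55, 3.5, 2)
  expect_equal(as.character(metabolic_risk(4.2, 3.8, cfg2)), "high")
  expect_equal(as.character(metabolic_risk(4.2, 3.8, cfg3)), "high")
  expect_equal(as.character(metabolic_risk(3.0, 3.8, cfg2)), "low")
  expect_equal(as.character(metabolic_risk(3.0, 3.8, cfg3)), "intermediate")
  # values exactly on both cutoffs count as below: low in both models
  expect_equal(as.character(metabolic_risk(3.55, 3.5, cfg3)), "low")
  expect_equal(as.character(metabolic_risk(3.55, 3.5, cfg2)), "low")
  expect_error(metabolic_risk(NaN, 3, cfg3), "finite")
})

test_that("two-category risk equals the three-category model with intermediate collapsed", {
  cfg3 <- signature_config(3.55, 3.5, 3)
  cfg2 <- signature_config(3.55, 3.5, 2)
  g <- expand.grid(suv = seq(1, 6, length.out = 100),
                   ent = seq(1, 6, length.out = 100))
  r3 <- metabolic_risk(g$suv, g$ent, cfg3)
  r2 <- metabolic_risk(g$suv, g$ent, cfg2)
  collapsed <- factor(ifelse(r3 == "high", "high", "low"), c("low", "high"))
  expect_identical(r2, collapsed)
})

test_that("MIPI modification reproduces the full 9-cell mapping with caps", {
  cases <- expand.grid(mipi = 1:3, met = c("low", "intermediate", "high"),
                       stringsAsFactors = FALSE)
  got <- modify_mipi(cases$mipi, cases$met)
  want <- c(1, 1, 2,    # low: -1 floored at 1
            1, 2, 3,    # intermediate: unchanged
            2, 3, 3)    # high: +1 capped at 3
  want <- c(`1_low` = 1, `2_low` = 1, `3_low` = 2,
            `1_intermediate` = 1, `2_intermediate` = 2, `3_intermediate` = 3,
            `1_high` = 2, `2_high` = 3, `3_high` = 3)
  expect_equal(got, unname(want[paste(cases$mipi, cases$met, sep = "_")]))
  expect_true(all(got %in% 1:3))
  # monotone: raising metabolic risk never lowers the modified category
  for (m in 1:3) {
    expect_lte(modify_mipi(m, "low"), modify_mipi(m, "intermediate"))
    expect_lte(modify_mipi(m, "intermediate"), modify_mipi(m, "high"))
  }
  expect_error(modify_mipi(4, "low"), "1, 2 or 3")
  expect_error(modify_mipi(2, "none"), "invalid metabolic")
})

test_that("risk profiles join 1:1 and exercise the modification truth table", {
  # nine patients hitting all (mipi_cat x metabolic) combinations;
  # with ECOG 0, LDH = ULN and WBC 7e9/L the score is
  # 0.03535 * age + 0.9393 * log10(7000), so ages 40 / 65 / 80 land in
  # categories 1 / 2 / 3 (cutpoints 5.7 and 6.2)
  mipi_target <- rep(1:3, each = 3)
  age <- rep(c(40, 65, 80), each = 3)
  suv <- rep(c(3.0, 3.0, 4.0), 3)       # low/intermediate/high drivers
  ent <- rep(c(3.0, 4.0, 4.0), 3)
  patients <- data.frame(
    patient_id = paste0("P", 1:9), age = age, ecog = 0,
    wbc = 7, ldh = 240, ldh_uln = 240, ki67 = 20,
    ann_arbor = 4, blastoid = FALSE, scanner = "A",
    pfs_months = 30, progressed = FALSE)
  feats <- data.frame(patient_id = paste0("P", 1:9),
                      suv_mean = suv, entropy = ent)
  prof <- build_risk_profiles(feats, patients, signature_config(3.55, 3.5, 3))
  expect_equal(prof$mipi_cat, mipi_target)
  expect_equal(as.character(prof$metabolic_risk),
               rep(c("low", "intermediate", "high"), 3))
  expect_equal(prof$mipi_m_cat,
               modify_mipi(prof$mipi_cat, prof$metabolic_risk))
  expect_equal(prof$mipi_m_cat, c(1, 1, 2, 1, 2, 3, 2, 3, 3))
  # deterministic re-run
  expect_identical(prof, build_risk_profiles(feats, patients,
                                             signature_config(3.55, 3.5, 3)))
  # unmatched ids error
  bad <- feats; bad$patient_id[1] <- "QX"
  expect_error(build_risk_profiles(bad, patients, signature_config()), "QX")
})

test_that("the 2-year PFS event flag derives from time and progression", {
  expect_identical(derive_pfs2y(c(10, 30, 24, 10), c(TRUE, TRUE, TRUE, FALSE)),
                   c(TRUE, FALSE, TRUE, FALSE))
})
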
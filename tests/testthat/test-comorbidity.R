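test_that("patient profiles are the union of codes across encounters", {
  enc <- enc_bind(
    enc_row("p1", "e1", "2020-01-01", "F32.9"),
    enc_row("p1", "e2", "2020-02-01", c("F32.9", "F41.9")),
    enc_row("p2", "e3", "2020-02-01", character(0))
  )
  prof <- patient_code_profiles(enc)
  expect_equal(prof$codes[prof$patient_id == "p1"][[1]], c("F329", "F419"))
  expect_equal(prof$codes[prof$patient_id == "p2"][[1]], character(0))
  expect_false("p3" %in% prof$patient_id)

  # brute-force oracle on a random 5-patient fixture
  withr::with_seed(13, {
    pool <- c("F329", "F419", "J069", "R509", "Z915")
    enc2 <- enc_bind(lapply(1:20, function(i) {
      enc_row(paste0("q", sample(1:5, 1)), paste0("e", i),
              as.Date("2020-01-01") + i, sample(pool, sample(0:3, 1)))
    }))
  })
  prof2 <- patient_code_profiles(enc2)
  for (p in unique(enc2$patient_id)) {
    oracle <- sort(unique(unlist(
      enc2$icd10_codes[enc2$patient_id == p]
    )))
    expect_equal(prof2$codes[prof2$patient_id == p][[1]], oracle)
  }
})

test_that("conditional probability covers never/always co-occurrence and errors", {
  expect_equal(conditional_probability(0, 20), 0)
  expect_equal(conditional_probability(20, 20), 1)
  expect_equal(conditional_probability(5, 20), 0.25)
  expect_error(conditional_probability(1, 0), "undefined")
  expect_error(conditional_probability(5, 4), "n_AB")
})

test_that("chi-square matches the closed form and the reference implementation", {
  r <- chi_square_2x2(10, 20, 30, 40)
  expect_equal(r$statistic, 100 * (10 * 40 - 20 * 30)^2 /
                 (30 * 70 * 40 * 60), tolerance = 1e-12)
  expect_equal(r$statistic, 0.79365079, tolerance = 1e-6)

  ind <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)

  withr::with_seed(17, {
    for (i in 1:50) {
      tab <- matrix(sample(1:500, 4), 2)
      mine <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
    }
  })

  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Bonferroni adjustment scales by the family size and caps at 1", {
  expect_equal(bonferroni_adjust(0.01, m = 55), 0.55)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1.0)
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
  withr::with_seed(19, {
    p <- runif(40)
    adj <- bonferroni_adjust(p, m = 60)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[adj < 1]), order(p[adj < 1]))
  })
})

test_that("scan statistics equal hand counts on a three-code toy corpus", {
  # 10 patients; cases carry R45851. Hand-tallied:
  #   F329: n_B = 4, n_AB = 3 -> P(A|B) = 0.75
  #   J069: n_B = 5, n_AB = 1 -> P(A|B) = 0.2
  #   R509: n_B = 2, n_AB = 0 -> P(A|B) = 0
  codes_by_patient <- list(
    p01 = c("R45851", "F329"), p02 = c("R45851", "F329", "J069"),
    p03 = c("R45851", "F329"), p04 = "F329",
    p05 = "J069", p06 = "J069", p07 = c("J069", "R509"),
    p08 = "R509", p09 = "J069", p10 = character(0)
  )
  enc <- enc_bind(purrr::imap(codes_by_patient, function(cd, p) {
    enc_row(p, paste0("e", p), "2020-06-01", cd)
  }))
  lab <- label_patients(enc, suicidality_cs)
  scan <- comorbidity_scan(enc, lab, suicidality_cs,
                           min_patients = 1, top_k = Inf)
  expect_equal(scan$code, c("F329", "J069", "R509"))
  expect_equal(scan$n_B, c(4, 5, 2))
  expect_equal(scan$n_AB, c(3, 1, 0))
  expect_equal(scan$p_A_given_B, c(0.75, 0.2, 0))
  expect_equal(scan$p_B_given_A, c(1, 1 / 3, 0))
  # chi-square of F329: table [[3,0],[1,6]] among 10 patients, 3 cases
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(3, 0, 1, 6), 2, byrow = TRUE),
                      correct = FALSE)
  )
  expect_equal(scan$chi2[1], unname(ref$statistic), tolerance = 1e-9)
})

test_that("scan respects the rare-code filter on either n_B or n_AB", {
  enc <- enc_bind(
    enc_row("p1", "e1", "2020-01-01", c("R45851", "F329")),
    enc_row("p2", "e2", "2020-01-01", "F329"),
    enc_row("p3", "e3", "2020-01-01", "F329"),
    enc_row("p4", "e4", "2020-01-01", "J069"),
    enc_row("p5", "e5", "2020-01-01", character(0))
  )
  lab <- label_patients(enc, suicidality_cs)
  by_nb <- comorbidity_scan(enc, lab, suicidality_cs,
                            min_patients = 3, top_k = Inf)
  expect_equal(by_nb$code, "F329")
  by_nab <- comorbidity_scan(enc, lab, suicidality_cs, min_patients = 1,
                             rare_filter = "n_AB", top_k = Inf)
  expect_equal(by_nab$code, "F329")  # J069 has n_AB = 0
})

test_that("a stratum with zero cases yields zero conditionals and no significance", {
  enc <- enc_bind(
    enc_row("p1", "e1", "2020-01-01", "F329", sex = "male"),
    enc_row("p2", "e2", "2020-01-01", c("F329", "J069"), sex = "male")
  )
  lab <- label_patients(enc, suicidality_cs)
  scan <- comorbidity_scan(enc, lab, suicidality_cs, min_patients = 1,
                           top_k = Inf)
  expect_true(all(scan$p_A_given_B == 0))
  expect_true(all(!scan$significant))
  # and an empty stratum warns and returns no rows
  expect_warning(
    out <- comorbidity_scan(enc, lab, suicidality_cs,
                            stratum = stratum_spec(sex = "female")),
    "Empty stratum"
  )
  expect_equal(nrow(out), 0)
})

test_that("scan is invariant under permutation of encounter order", {
  d <- simulate_ehr(test_sim_config(n_patients = 600, seed = 2))
  lab <- label_patients(d$encounters, suicidality_cs)
  s1 <- comorbidity_scan(d$encounters, lab, suicidality_cs,
                         min_patients = 5)
  withr::with_seed(1, {
    perm <- sample(nrow(d$encounters))
  })
  s2 <- comorbidity_scan(d$encounters[perm, ], lab, suicidality_cs,
                         min_patients = 5)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("with no filters the scan equals a brute-force co-occurrence tally", {
  withr::with_seed(23, {
    pool <- c("F329", "F419", "J069", "R509", "K529", "R45851", "Z915")
    enc <- enc_bind(lapply(1:120, function(i) {
      enc_row(paste0("p", sample(1:40, 1)), paste0("e", i),
              as.Date("2020-01-01") + sample(0:700, 1),
              sample(pool, sample(0:3, 1)))
    }))
  })
  lab <- label_patients(enc, suicidality_cs)
  scan <- comorbidity_scan(enc, lab, suicidality_cs,
                           min_patients = 1, top_k = Inf)
  # oracle: pairwise tally over patients
  prof <- patient_code_profiles(enc)
  case_ids <- lab$patient_id[lab$is_case]
  all_codes <- sort(unique(unlist(prof$codes)))
  cand <- setdiff(all_codes, c("R45851", "Z915"))
  for (cd in cand) {
    has <- vapply(prof$codes, function(x) cd %in% x, logical(1))
    n_b <- sum(has)
    n_ab <- sum(has & prof$patient_id %in% case_ids)
    row <- scan[scan$code == cd, ]
    expect_equal(row$n_B, n_b)
    expect_equal(row$n_AB, n_ab)
    expect_equal(row$p_A_given_B, n_ab / n_b)
  }
  expect_setequal(scan$code, cand)
})

test_that("every scan row is Bayes-consistent", {
  d <- simulate_ehr(test_sim_config(n_patients = 800, seed = 3))
  lab <- label_patients(d$encounters, suicidality_cs)
  scan <- comorbidity_scan(d$encounters, lab, suicidality_cs,
                           min_patients = 5)
  n <- attr(scan, "n_patients")
  n_cases <- attr(scan, "n_cases")
  # P(A|B) P(B) = P(B|A) P(A), all computed from the same counts
  lhs <- scan$p_A_given_B * scan$n_B / n
  rhs <- scan$p_B_given_A * n_cases / n
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("top-k selection ranks by conditional, then support, then code", {
  enc <- enc_bind(
    enc_row("p1", "e1", "2020-01-01", c("R45851", "AAA", "BBB")),
    enc_row("p2", "e2", "2020-01-01", c("R45851", "AAA", "BBB", "CCC")),
    enc_row("p3", "e3", "2020-01-01", c("AAA", "CCC")),
    enc_row("p4", "e4", "2020-01-01", "AAA")
  )
  lab <- label_patients(enc, suicidality_cs)
  scan <- comorbidity_scan(enc, lab, suicidality_cs, min_patients = 1,
                           top_k = 2)
  # BBB: 2/2 = 1.0; CCC: 1/2 = 0.5; AAA: 2/4 = 0.5 but larger n_B
  expect_equal(scan$code, c("BBB", "AAA"))
})

test_that("the union of significant codes deduplicates with provenance", {
  grid <- tibble::tibble(
    age_group = c("all", "all", "children_6_11"),
    sex = c("all", "female", "all"),
    subtype = "any",
    code = c("F329", "F329", "F419"),
    n_B = c(100L, 60L, 40L), n_AB = c(30L, 20L, 10L),
    p_A_given_B = c(0.3, 1 / 3, 0.25),
    p_B_given_A = c(0.5, 0.5, 0.2),
    chi2 = 10, p_value = 0.001, p_bonferroni = 0.01,
    significant = c(TRUE, TRUE, TRUE)
  )
  u <- significant_union(grid)
  expect_equal(nrow(u), 2)
  f329 <- u[u$code == "F329", ]
  expect_equal(f329$n_strata, 2L)
  expect_setequal(f329$strata[[1]], c("all/all/any", "all/female/any"))
  expect_equal(significant_union(dplyr::mutate(grid, significant = FALSE))$code,
               character(0))
})

test_that("DSM-5 categorization is first-match-wins over ordered patterns", {
  mp <- read_dsm5_mapping()
  expect_equal(dsm5_categorize("F649", mp), "gender_dysphoria")
  expect_equal(dsm5_categorize("F639", mp), "disruptive_impulse_conduct")
  expect_equal(dsm5_categorize("F605", mp), "personality")
  expect_equal(dsm5_categorize("F329", mp), "depressive")
  expect_equal(dsm5_categorize("F29", mp), "schizophrenia_spectrum")
  expect_equal(dsm5_categorize("J069", mp), NA_character_)
})

test_that("DSM-5 category statistics count patients, both conditional directions", {
  enc <- enc_bind(
    enc_row("p1", "e1", "2020-01-01", c("R45851", "F329")),
    enc_row("p2", "e2", "2020-01-01", "F329"),
    enc_row("p3", "e3", "2020-01-01", c("F419", "J069")),
    enc_row("p4", "e4", "2020-01-01", "J069")
  )
  lab <- label_patients(enc, suicidality_cs)
  st <- suppressMessages(
    dsm5_category_stats(enc, lab, read_dsm5_mapping())
  )
  dep <- st[st$category == "depressive", ]
  expect_equal(dep$prevalence, 0.5)
  expect_equal(dep$p_case_given_category, 0.5)
  expect_equal(dep$p_category_given_case, 1)
  anx <- st[st$category == "anxiety", ]
  expect_equal(anx$p_case_given_category, 0)
  expect_equal(attr(st, "n_unmapped_codes"), 2L)  # J069 and R45851

  # a category held only by cases has conditional probability 1
  all_map <- structure(
    tibble::tibble(pattern = "*", category = "anything"),
    class = c("dsm5_mapping", class(tibble::tibble()))
  )
  st2 <- dsm5_category_stats(enc, lab, all_map)
  expect_equal(st2$prevalence, 1)  # every patient has >= 1 code here
})
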
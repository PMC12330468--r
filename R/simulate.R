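#' Default planted comorbidity specification
#'
#' Each row plants one ICD-10 code with a marginal patient-level prevalence
#' and a target conditional probability of latent suicidality given the
#' code. The defaults emulate the conditional-probability profile reported
#' for a large pediatric ED population: personality disorder and gender
#' dysphoria codes are rare but carry conditionals above 40%, bipolar,
#' schizophrenia-spectrum and depressive codes sit in the low-to-mid 30s,
#' and anxiety is common with a milder association.
#'
#' @return Tibble with columns `code`, `prevalence`,
#'   `target_p_suicidality`.
#' @export
default_comorbidity_specs <- function() {
  tibble(
    code = c("F329", "F419", "F319", "F209", "F648", "F603"),
    prevalence = c(0.091, 0.156, 0.010, 0.008, 0.006, 0.003),
    target_p_suicidality = c(0.339, 0.100, 0.361, 0.324, 0.429, 0.442)
  )
}

# Background ED diagnosis codes with no suicidality association: they give
# the comorbidity screen a realistic null candidate pool.
default_noise_codes <- function() {
  c(
    J069 = 0.18, R509 = 0.12, J45909 = 0.08, S0990XA = 0.07, R51 = 0.06,
    S9340XA = 0.06, R1084 = 0.05, R112 = 0.05, A09 = 0.04, K529 = 0.03
  )
}

#' Configure the synthetic EHR generator
#'
#' Returns a validated configuration for [simulate_ehr()]. The defaults
#' describe a six-year pediatric ED study window: ~60k patients aged 6–18,
#' ~1.52 encounters per patient, 2.9% baseline latent suicidality, planted
#' mental-health comorbidities with conditional probabilities of suicidality
#' between 10% and 44% ([default_comorbidity_specs()]), and a documentation
#' sensitivity of 0.5 — only about half of truly suicidal patients ever
#' receive a suicidality ICD-10 code, the under-reporting the matching
#' method is designed to expose. Case demographics are skewed female and
#' adolescent via `case_p_female` / `case_p_adolescent`.
#'
#' @param n_patients Number of patients.
#' @param date_range ISO date pair: study window, half-open.
#' @param age_range Integer age bounds (inclusive).
#' @param p_female,case_p_female Probability a patient is female, for
#'   latent non-cases and latent cases respectively.
#' @param p_adolescent,case_p_adolescent Probability a patient is an
#'   adolescent (12–18) rather than a child (6–11), by latent status.
#' @param race_distribution Named probability vector over race categories
#'   (must sum to 1).
#' @param mean_extra_encounters Poisson mean of encounters beyond the first.
#' @param comorbidity_specs Tibble as [default_comorbidity_specs()]. Codes
#'   must be distinct and outside the suicidality codeset.
#' @param noise_code_prevalence Named prevalence vector of association-free
#'   background codes.
#' @param baseline_p_suicidality Latent suicidality probability for patients
#'   with no planted comorbidity.
#' @param documentation_sensitivity Probability a latent-suicidality patient
#'   receives a suicidality ICD-10 code.
#' @param subtype_mix Named probabilities that a documented case carries
#'   each subtype (`ideation`, `self_harm`, `attempt`); memberships are
#'   drawn independently and a case with none drawn defaults to ideation.
#' @param unintentional_injury_codes Codes for harm without documented
#'   intent, emitted preferentially among latent-suicidality patients.
#' @param injury_base_rate Per-patient probability of an unintentional
#'   injury code for latent non-cases.
#' @param injury_rate_ratio Relative rate of injury codes among latent
#'   cases.
#' @param note_type_distribution Named probability vector (sums to 1) over
#'   supplementary note bundles accompanying the always-present ED note;
#'   the level `"none"` means ED note only.
#' @param codeset The suicidality [codeset()] used to emit documented case
#'   codes.
#' @param seed Integer RNG seed: identical configs give identical datasets.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 59866,
                       date_range = c("2016-06-01", "2022-06-01"),
                       age_range = c(6L, 18L),
                       p_female = 0.477,
                       case_p_female = 0.69,
                       p_adolescent = 0.47,
                       case_p_adolescent = 0.88,
                       race_distribution = c(
                         asian = 0.06, black = 0.22, hispanic = 0.12,
                         other = 0.05, unknown = 0.10, white = 0.45
                       ),
                       mean_extra_encounters = 0.52,
                       comorbidity_specs = default_comorbidity_specs(),
                       noise_code_prevalence = default_noise_codes(),
                       baseline_p_suicidality = 0.029,
                       documentation_sensitivity = 0.5,
                       subtype_mix = c(
                         ideation = 0.86, self_harm = 0.39, attempt = 0.067
                       ),
                       unintentional_injury_codes = c("T391X1A", "S51812A"),
                       injury_base_rate = 0.01,
                       injury_rate_ratio = 5,
                       note_type_distribution = c(
                         none = 0.70, discharge_summary = 0.20,
                         psychiatric_note = 0.10
                       ),
                       codeset = default_suicidality_codeset(),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    date_range = as.Date(date_range),
    age_range = as.integer(age_range),
    p_female = p_female, case_p_female = case_p_female,
    p_adolescent = p_adolescent, case_p_adolescent = case_p_adolescent,
    race_distribution = race_distribution,
    mean_extra_encounters = mean_extra_encounters,
    comorbidity_specs = as_tibble(comorbidity_specs),
    noise_code_prevalence = noise_code_prevalence,
    baseline_p_suicidality = baseline_p_suicidality,
    documentation_sensitivity = documentation_sensitivity,
    subtype_mix = subtype_mix,
    unintentional_injury_codes = normalize_icd10(unintentional_injury_codes),
    injury_base_rate = injury_base_rate,
    injury_rate_ratio = injury_rate_ratio,
    note_type_distribution = note_type_distribution,
    codeset = codeset,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$p_female, cfg$case_p_female, cfg$p_adolescent, cfg$case_p_adolescent,
    cfg$baseline_p_suicidality, cfg$documentation_sensitivity,
    cfg$subtype_mix, cfg$injury_base_rate,
    cfg$comorbidity_specs$prevalence, cfg$noise_code_prevalence
  )
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities in a sim_config must lie in [0, 1].")
  }
  if (abs(sum(cfg$race_distribution) - 1) > 1e-9) {
    abort("`race_distribution` must sum to 1.")
  }
  if (abs(sum(cfg$note_type_distribution) - 1) > 1e-9) {
    abort("`note_type_distribution` must sum to 1.")
  }
  if (cfg$n_patients < 1) abort("`n_patients` must be positive.")
  if (cfg$date_range[1] >= cfg$date_range[2]) {
    abort("`date_range` must satisfy start < end.")
  }
  if (cfg$age_range[1] > cfg$age_range[2] || cfg$age_range[1] < 0) {
    abort("`age_range` must be an ordered pair of nonnegative ages.")
  }
  if (cfg$mean_extra_encounters < 0) {
    abort("`mean_extra_encounters` must be nonnegative.")
  }
  specs <- cfg$comorbidity_specs
  if (nrow(specs) > 0) {
    specs$code <- normalize_icd10(specs$code)
    if (anyDuplicated(specs$code)) {
      abort("Comorbidity codes must be distinct.")
    }
    planted <- c(specs$code, names(cfg$noise_code_prevalence),
                 cfg$unintentional_injury_codes)
    bad <- planted[in_codeset(planted, cfg$codeset)]
    if (length(bad) > 0) {
      abort(paste0(
        "Planted code(s) belong to the suicidality codeset: ",
        paste(unique(bad), collapse = ", ")
      ))
    }
    off <- specs$code[specs$target_p_suicidality <= 0 |
                        specs$target_p_suicidality >= 1]
    if (length(off) > 0) {
      abort(paste0(
        "Unsatisfiable target conditional probability for code(s): ",
        paste(off, collapse = ", "),
        " (targets must lie strictly in (0, 1))."
      ))
    }
    if (nrow(specs) > 12) {
      abort(paste0(
        "At most 12 comorbidity specs are supported (coefficients are ",
        "solved by exact enumeration over flag combinations)."
      ))
    }
    cfg$comorbidity_specs <- specs
  }
  if (cfg$baseline_p_suicidality <= 0 || cfg$baseline_p_suicidality >= 1) {
    abort("`baseline_p_suicidality` must lie strictly in (0, 1).")
  }
  cfg
}

#' Solve the latent-suicidality logistic coefficients
#'
#' The generator draws latent suicidality from a logistic model on the
#' independent planted comorbidity flags. This inverse step finds the
#' intercept and per-code log-odds such that the *marginal* conditional
#' probability \eqn{P(\mathrm{latent} \mid \mathrm{flag}_j = 1)} —
#' marginalizing over the other flags — equals each spec's target. The
#' intercept is exactly `qlogis(baseline)` (patients with no planted flag);
#' each coefficient is found by 1-D root finding, sweeping to joint
#' convergence because the marginals couple through flag co-occurrence.
#'
#' @param config A [sim_config()].
#' @param tol Joint convergence tolerance on the achieved conditionals.
#' @param max_sweeps Sweep cap; non-convergence raises an error carrying the
#'   worst offending code and residual.
#' @return List with `intercept` (log-odds) and `coefficients` (named
#'   per-code log-odds).
#' @export
solve_comorbidity_coefficients <- function(config, tol = 1e-9,
                                           max_sweeps = 100L) {
  stopifnot(inherits(config, "sim_config"))
  specs <- config$comorbidity_specs
  b0 <- qlogis(config$baseline_p_suicidality)
  m <- nrow(specs)
  if (m == 0) {
    return(list(intercept = b0, coefficients = setNames(numeric(0),
                                                        character(0))))
  }
  prev <- specs$prevalence
  target <- specs$target_p_suicidality
  beta <- rep(0, m)

  # Marginal P(latent | flag_j = 1) by exact enumeration over other flags.
  marginal_j <- function(beta, j) {
    others <- setdiff(seq_len(m), j)
    if (length(others) == 0) {
      return(plogis(b0 + beta[j]))
    }
    combos <- as.matrix(expand.grid(rep(list(0:1), length(others))))
    w <- apply(combos, 1, function(s) {
      prod(ifelse(s == 1, prev[others], 1 - prev[others]))
    })
    eta <- b0 + beta[j] + combos %*% beta[others]
    sum(w * plogis(eta))
  }

  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(m)) {
      f <- function(bj) {
        bb <- beta
        bb[j] <- bj
        marginal_j(bb, j) - target[j]
      }
      beta[j] <- uniroot(f, lower = -40, upper = 40, tol = 1e-12)$root
    }
    resid <- vapply(seq_len(m), function(j) {
      abs(marginal_j(beta, j) - target[j])
    }, numeric(1))
    if (max(resid) < tol) {
      return(list(
        intercept = b0,
        coefficients = setNames(beta, specs$code)
      ))
    }
  }
  worst <- which.max(resid)
  abort(paste0(
    "Coefficient solver did not converge after ", max_sweeps,
    " sweeps; worst residual ", format(resid[worst], digits = 3),
    " for code ", specs$code[worst], "."
  ))
}

#' Generate a synthetic ED encounter dataset
#'
#' Draws a seeded population under the generative model described in the
#' package vignette: independent planted comorbidity flags; latent
#' suicidality from a logistic model whose coefficients
#' ([solve_comorbidity_coefficients()]) reproduce the configured
#' conditional probabilities; a documented-suicidality indicator equal to
#' latent AND Bernoulli(documentation sensitivity); demographics with a
#' configurable female/adolescent skew among latent cases; 1 + Poisson
#' encounters per patient clustered around an anchor date; comorbidity,
#' noise, unintentional-injury and documented suicidality codes plus note
#' types scattered across the encounters. Ground truth
#' (`latent_suicidality`) lives only in the patients table, never in the
#' code lists: an undocumented case is indistinguishable from a non-case in
#' the encounters table, by construction.
#'
#' @param config A [sim_config()].
#' @return Object of class `"synthetic_ehr"`: list with `patients`
#'   (`patient_id`, `sex`, `race`, `birth_year`, `latent_suicidality`,
#'   `documented`, one `has_<code>` flag per planted comorbidity),
#'   `encounters` (study-format encounter tibble), `coefficients`, and
#'   `config`. Deterministic given `config$seed`.
#' @export
simulate_ehr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  coefs <- solve_comorbidity_coefficients(config)
  withr::with_seed(config$seed, simulate_ehr_impl(config, coefs))
}

simulate_ehr_impl <- function(cfg, coefs) {
  n <- cfg$n_patients
  specs <- cfg$comorbidity_specs
  m <- nrow(specs)

  patient_id <- sprintf("P%07d", seq_len(n))
  race <- sample(names(cfg$race_distribution), n, replace = TRUE,
                 prob = cfg$race_distribution)

  flags <- matrix(0L, nrow = n, ncol = m)
  if (m > 0) {
    for (j in seq_len(m)) {
      flags[, j] <- rbinom(n, 1L, specs$prevalence[j])
    }
    colnames(flags) <- specs$code
  }
  eta <- coefs$intercept +
    if (m > 0) as.vector(flags %*% coefs$coefficients) else 0
  latent <- runif(n) < plogis(eta)
  documented <- latent & (runif(n) < cfg$documentation_sensitivity)

  female <- runif(n) < ifelse(latent, cfg$case_p_female, cfg$p_female)
  sex <- ifelse(female, "female", "male")
  adolescent <- runif(n) <
    ifelse(latent, cfg$case_p_adolescent, cfg$p_adolescent)
  lo <- cfg$age_range[1]
  hi <- cfg$age_range[2]
  split_age <- min(max(12L, lo + 1L), hi)  # children < split <= adolescents
  age <- ifelse(
    adolescent,
    sample(seq(split_age, hi), n, replace = TRUE),
    sample(seq(lo, split_age - 1L), n, replace = TRUE)
  )

  n_enc <- 1L + rpois(n, cfg$mean_extra_encounters)
  total_enc <- sum(n_enc)
  window <- as.integer(cfg$date_range[2] - cfg$date_range[1])
  anchor <- cfg$date_range[1] + floor(runif(n) * window)
  birth_year <- as.integer(format(anchor, "%Y")) - age

  pat_row <- rep(seq_len(n), n_enc)
  jitter <- as.integer(floor(runif(total_enc) * 181)) - 90L
  dates <- anchor[pat_row] + jitter
  dates <- pmax(pmin(dates, cfg$date_range[2] - 1L), cfg$date_range[1])
  enc_id <- sprintf("E%08d", seq_len(total_enc))
  first_enc <- cumsum(c(1L, n_enc[-n]))  # index of each patient's first row

  # ---- code placement -------------------------------------------------
  # Each planted/noise/injury code lands on one uniformly chosen encounter
  # of its patient; documented suicidality codes land on one encounter.
  assign_code <- list()
  place <- function(pat_idx, code_vec) {
    off <- as.integer(floor(runif(length(pat_idx)) * n_enc[pat_idx]))
    tibble(enc = first_enc[pat_idx] + off, code = code_vec)
  }
  if (m > 0) {
    for (j in seq_len(m)) {
      idx <- which(flags[, j] == 1L)
      if (length(idx) > 0) {
        assign_code[[length(assign_code) + 1L]] <-
          place(idx, rep(specs$code[j], length(idx)))
      }
    }
  }
  for (code in names(cfg$noise_code_prevalence)) {
    idx <- which(runif(n) < cfg$noise_code_prevalence[[code]])
    if (length(idx) > 0) {
      assign_code[[length(assign_code) + 1L]] <-
        place(idx, rep(normalize_icd10(code), length(idx)))
    }
  }
  p_injury <- pmin(1, cfg$injury_base_rate *
                     ifelse(latent, cfg$injury_rate_ratio, 1))
  idx <- which(runif(n) < p_injury)
  if (length(idx) > 0 && length(cfg$unintentional_injury_codes) > 0) {
    assign_code[[length(assign_code) + 1L]] <- place(
      idx,
      sample(cfg$unintentional_injury_codes, length(idx), replace = TRUE)
    )
  }

  # Documented suicidality: draw subtype memberships, default to ideation.
  doc_idx <- which(documented)
  if (length(doc_idx) > 0) {
    nd <- length(doc_idx)
    has_ide <- runif(nd) < cfg$subtype_mix[["ideation"]]
    has_sh <- runif(nd) < cfg$subtype_mix[["self_harm"]]
    has_att <- runif(nd) < cfg$subtype_mix[["attempt"]]
    none <- !(has_ide | has_sh | has_att)
    has_ide[none] <- TRUE
    sub <- cfg$codeset$subtypes
    draw <- function(pool, k) sample(pool, k, replace = TRUE)
    case_enc_off <- as.integer(floor(runif(nd) * n_enc[doc_idx]))
    case_enc <- first_enc[doc_idx] + case_enc_off
    if (any(has_ide)) {
      assign_code[[length(assign_code) + 1L]] <- tibble(
        enc = case_enc[has_ide],
        code = draw(sub$ideation, sum(has_ide))
      )
    }
    if (any(has_sh)) {
      assign_code[[length(assign_code) + 1L]] <- tibble(
        enc = case_enc[has_sh],
        code = draw(sub$self_harm, sum(has_sh))
      )
    }
    if (any(has_att)) {
      assign_code[[length(assign_code) + 1L]] <- tibble(
        enc = case_enc[has_att],
        code = draw(sub$attempt, sum(has_att))
      )
    }
  }

  codes_long <- if (length(assign_code) > 0) {
    bind_rows(assign_code)
  } else {
    tibble(enc = integer(0), code = character(0))
  }
  code_lists <- rep(list(character(0)), total_enc)
  if (nrow(codes_long) > 0) {
    grouped <- split(codes_long$code, codes_long$enc)
    code_lists[as.integer(names(grouped))] <-
      lapply(grouped, function(x) sort(unique(x)))
  }

  bundle <- sample(names(cfg$note_type_distribution), total_enc,
                   replace = TRUE, prob = cfg$note_type_distribution)
  note_lists <- lapply(bundle, function(b) {
    if (b == "none") "ED note" else c("ED note", b)
  })

  encounters <- tibble(
    patient_id = patient_id[pat_row],
    encounter_id = enc_id,
    date = dates,
    age_at_visit = age[pat_row],
    sex = sex[pat_row],
    race = race[pat_row],
    icd10_codes = code_lists,
    note_types = note_lists
  )

  patients <- tibble(
    patient_id = patient_id,
    sex = sex,
    race = race,
    birth_year = birth_year,
    latent_suicidality = latent,
    documented = documented
  )
  if (m > 0) {
    flag_df <- as_tibble(as.data.frame(flags == 1L))
    names(flag_df) <- paste0("has_", specs$code)
    patients <- dplyr::bind_cols(patients, flag_df)
  }

  structure(
    list(patients = patients, encounters = encounters,
         coefficients = coefs, config = cfg),
    class = "synthetic_ehr"
  )
}

#' @export
print.synthetic_ehr <- function(x, ...) {
  cat("<synthetic_ehr> ", nrow(x$patients), " patients, ",
      nrow(x$encounters), " encounters\n", sep = "")
  cat("  latent suicidality: ",
      sprintf("%.1f%%", 100 * mean(x$patients$latent_suicidality)),
      "; documented: ",
      sprintf("%.1f%%", 100 * mean(x$patients$documented)), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits an encounters table and a separate, clearly named ground-truth
#' patients table (`patients_ground_truth.*`), so pipeline stages reading
#' encounters cannot accidentally consume the latent labels. CSV joins the
#' `icd10_codes` / `note_types` lists with `";"`; JSON-lines keeps them as
#' arrays. Both round-trip losslessly through [read_ehr_dataset()].
#'
#' @param dataset A `"synthetic_ehr"` object.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"jsonl"`.
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(dataset, dir, format = c("csv", "jsonl")) {
  stopifnot(inherits(dataset, "synthetic_ehr"))
  format <- match.arg(format)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) abort(paste0("Cannot create output directory: ", dir))

  enc <- dataset$encounters
  pat <- dataset$patients
  if (format == "csv") {
    enc_flat <- enc %>%
      mutate(
        date = format(.data$date, "%Y-%m-%d"),
        icd10_codes = vapply(.data$icd10_codes, paste, "", collapse = ";"),
        note_types = vapply(.data$note_types, paste, "", collapse = ";")
      )
    write.csv(enc_flat, file.path(dir, "encounters.csv"),
              row.names = FALSE)
    write.csv(pat, file.path(dir, "patients_ground_truth.csv"),
              row.names = FALSE)
  } else {
    enc_j <- enc %>% mutate(date = format(.data$date, "%Y-%m-%d"))
    con <- file(file.path(dir, "encounters.jsonl"), open = "w")
    jsonlite::stream_out(enc_j, con, verbose = FALSE)
    close(con)
    con <- file(file.path(dir, "patients_ground_truth.jsonl"), open = "w")
    jsonlite::stream_out(pat, con, verbose = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read a dataset written by [write_ehr_dataset()]
#'
#' @param dir Directory containing the files.
#' @param format `"csv"` or `"jsonl"`.
#' @return List with `encounters` and `patients` tibbles.
#' @export
read_ehr_dataset <- function(dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  split_field <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE), function(v) v[v != ""])
  }
  if (format == "csv") {
    enc_path <- file.path(dir, "encounters.csv")
    pat_path <- file.path(dir, "patients_ground_truth.csv")
    if (!file.exists(enc_path)) {
      abort(paste0("Encounters file not found: ", enc_path))
    }
    enc <- as_tibble(read.csv(enc_path, colClasses = "character"))
    enc <- enc %>%
      mutate(
        date = as.Date(.data$date),
        age_at_visit = as.integer(.data$age_at_visit),
        icd10_codes = split_field(.data$icd10_codes),
        note_types = split_field(.data$note_types)
      )
    pat <- as_tibble(read.csv(pat_path, colClasses = "character"))
    logi <- c("latent_suicidality", "documented",
              grep("^has_", names(pat), value = TRUE))
    pat <- pat %>%
      mutate(
        across(any_of(logi), ~ .x == "TRUE"),
        birth_year = as.integer(.data$birth_year)
      )
  } else {
    enc_path <- file.path(dir, "encounters.jsonl")
    pat_path <- file.path(dir, "patients_ground_truth.jsonl")
    if (!file.exists(enc_path)) {
      abort(paste0("Encounters file not found: ", enc_path))
    }
    enc <- as_tibble(jsonlite::stream_in(file(enc_path), verbose = FALSE))
    fix_list <- function(col) {
      lapply(col, function(v) if (length(v) == 0) character(0) else
        as.character(v))
    }
    enc <- enc %>%
      mutate(
        date = as.Date(.data$date),
        age_at_visit = as.integer(.data$age_at_visit),
        icd10_codes = fix_list(.data$icd10_codes),
        note_types = fix_list(.data$note_types)
      )
    pat <- as_tibble(jsonlite::stream_in(file(pat_path), verbose = FALSE))
    pat$birth_year <- as.integer(pat$birth_year)
  }
  list(encounters = enc, patients = pat)
}
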
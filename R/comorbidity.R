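#' Per-patient diagnosis-code profiles
#'
#' The unit of co-occurrence for the comorbidity screen is the patient over
#' the whole study period: a patient's profile is the union of all codes
#' across their encounters.
#'
#' @param encounters Encounter tibble (see [label_patients()]).
#' @return Tibble `patient_id`, `codes` (list-column of sorted unique
#'   codes). Patients with no encounters are absent.
#' @export
patient_code_profiles <- function(encounters) {
  check_encounters(encounters)
  pats <- sort(unique(encounters$patient_id))
  long_pid <- rep(encounters$patient_id, lengths(encounters$icd10_codes))
  long_code <- as.character(unlist(encounters$icd10_codes,
                                   use.names = FALSE))
  spl <- split(long_code, factor(long_pid, levels = pats))
  tibble(
    patient_id = pats,
    codes = unname(lapply(spl, function(x) sort(unique(x))))
  )
}

#' Conditional probability of one diagnosis given another
#'
#' \eqn{P(A \mid B) = P(A \cap B) / P(B)}, computed from patient counts:
#' `n_AB` patients carrying both the phenotype A and code B, over `n_B`
#' patients carrying B. 0 means the pair never co-occurs; 1 means B never
#' appears without A.
#'
#' @param n_AB,n_B Nonnegative counts, `n_AB <= n_B`, `n_B > 0` (callers
#'   must pre-filter codes nobody carries).
#' @return `n_AB / n_B`, vectorized.
#' @export
conditional_probability <- function(n_AB, n_B) {
  if (any(n_B <= 0)) {
    abort("`n_B` must be positive: P(A|B) is undefined when nobody has B.")
  }
  if (any(n_AB < 0 | n_AB > n_B)) {
    abort("`n_AB` must satisfy 0 <= n_AB <= n_B.")
  }
  n_AB / n_B
}

#' Pearson chi-square test on a 2x2 table
#'
#' Tests independence of phenotype status and code presence on the table
#' `[[a, b], [c, d]]` (rows: phenotype yes/no; columns: code yes/no),
#' without continuity correction, df = 1. Closed form
#' \eqn{N (ad - bc)^2 / (r_1 r_2 c_1 c_2)}.
#'
#' @param a,b,c,d Nonnegative cell counts.
#' @return Named list `statistic`, `p_value` (upper tail, df = 1).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- as.numeric(c(a, b, c, d))  # doubles: (ad-bc)^2 overflows int
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  if (length(counts) != 4 || any(counts < 0)) {
    abort("Cell counts must be four nonnegative numbers.")
  }
  n <- sum(counts)
  if (n <= 0) abort("The 2x2 table must contain at least one observation.")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    abort("Chi-square test undefined: a row or column margin is zero.")
  }
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni adjustment with an explicit family size
#'
#' Multiplies each p-value by the family size `m` and caps at 1. `m` may
#' exceed `length(p)`: the screening pipeline corrects each stratum's tests
#' for the total number of (code, stratum) comparisons performed in the
#' run.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size, `m >= length(p)`.
#' @return Adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  if (m < length(p)) {
    abort("Family size `m` must be at least `length(p)`.")
  }
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Define a stratum for the comorbidity screen
#'
#' @param age_group `"all"`, `"children_6_11"` or `"adolescents_12_18"`.
#' @param sex `"all"`, `"male"` or `"female"`.
#' @param subtype `"any"` or one of the codeset's subtype labels.
#' @return A one-row stratum tibble.
#' @export
stratum_spec <- function(age_group = "all", sex = "all", subtype = "any") {
  age_group <- match.arg(age_group,
                         c("all", "children_6_11", "adolescents_12_18"))
  sex <- match.arg(sex, c("all", "male", "female"))
  tibble(age_group = age_group, sex = sex, subtype = subtype)
}

# Patient-level demographics derived from each patient's first encounter.
patient_demographics <- function(encounters) {
  o <- order(encounters$date, encounters$encounter_id)
  keep <- o[!duplicated(encounters$patient_id[o])]
  out <- tibble(
    patient_id = encounters$patient_id[keep],
    sex = encounters$sex[keep],
    age_first = encounters$age_at_visit[keep]
  )
  out$age_group <- if_else(out$age_first <= 11L,
                           "children_6_11", "adolescents_12_18")
  out[order(out$patient_id), ]
}

#' Screen comorbidity codes for association with the phenotype
#'
#' For one stratum: restricts to the stratum's patients, takes every
#' observed code outside the phenotype codeset as a candidate B, drops rare
#' codes (`n_B < min_patients` by default; the filter can instead be applied
#' to `n_AB`), computes \eqn{P(A \mid B)} for each, keeps the `top_k`
#' highest (ties broken by larger `n_B`, then code), and chi-square-tests
#' each retained code's 2x2 table with a Bonferroni correction over
#' `m_family` tests (defaulting to the tests performed here; the grid
#' wrapper [comorbidity_scan_grid()] passes the run-wide family size).
#'
#' With `subtype != "any"`, the phenotype A is restricted to patients whose
#' case label includes that subtype.
#'
#' @param encounters Encounter tibble.
#' @param labels Patient labels from [label_patients()].
#' @param cs The phenotype [codeset()].
#' @param stratum One-row tibble from [stratum_spec()].
#' @param min_patients Rare-code threshold (default 20 patients).
#' @param rare_filter Apply the threshold to `"n_B"` (patients carrying the
#'   code; default) or `"n_AB"` (case patients carrying it).
#' @param top_k Codes retained per stratum (default 20; `Inf` keeps all).
#' @param alpha Significance level on the Bonferroni-adjusted p-value.
#' @param m_family Bonferroni family size override.
#' @return Tibble, one row per retained code: stratum columns, `code`,
#'   `n_B`, `n_AB`, `p_A_given_B`, `p_B_given_A`, `chi2`, `p_value`,
#'   `p_bonferroni`, `significant`; plus attributes `n_patients`, `n_cases`
#'   and `m_family`. Empty strata return zero rows with a warning.
#' @export
comorbidity_scan <- function(encounters, labels, cs,
                             stratum = stratum_spec(),
                             min_patients = 20L,
                             rare_filter = c("n_B", "n_AB"),
                             top_k = 20L,
                             alpha = 0.05,
                             m_family = NULL) {
  rare_filter <- match.arg(rare_filter)
  stopifnot(inherits(cs, "codeset"), nrow(stratum) == 1)
  if (min_patients < 1) abort("`min_patients` must be >= 1.")
  if (top_k < 1) abort("`top_k` must be >= 1.")

  demo <- patient_demographics(encounters)
  keep <- demo
  if (stratum$age_group != "all") {
    keep <- filter(keep, .data$age_group == stratum$age_group)
  }
  if (stratum$sex != "all") {
    keep <- filter(keep, .data$sex == stratum$sex)
  }
  empty <- dplyr::bind_cols(
    stratum[integer(0), ],
    tibble(
      code = character(0), n_B = integer(0), n_AB = integer(0),
      p_A_given_B = numeric(0), p_B_given_A = numeric(0),
      chi2 = numeric(0), p_value = numeric(0), p_bonferroni = numeric(0),
      significant = logical(0)
    )
  )
  if (nrow(keep) == 0) {
    warn(paste0("Empty stratum: ", format_stratum(stratum)))
    return(structure(empty, n_patients = 0L, n_cases = 0L, m_family = 0L))
  }

  lab <- labels %>% semi_join(keep, by = "patient_id")
  case_ids <- if (stratum$subtype == "any") {
    lab$patient_id[lab$is_case]
  } else {
    lab$patient_id[
      vapply(lab$subtypes, function(s) stratum$subtype %in% s, logical(1))
    ]
  }
  profiles <- patient_code_profiles(encounters) %>%
    semi_join(keep, by = "patient_id")
  n_total <- nrow(keep)
  n_cases <- length(case_ids)

  long <- tibble(
    patient_id = rep(profiles$patient_id, lengths(profiles$codes)),
    code = as.character(unlist(profiles$codes))
  )
  if (nrow(long) > 0) {
    long <- long %>% filter(!in_codeset(.data$code, cs))
  }
  counts <- long %>%
    mutate(is_case = .data$patient_id %in% case_ids) %>%
    group_by(.data$code) %>%
    summarise(
      n_B = dplyr::n(),
      n_AB = sum(.data$is_case),
      .groups = "drop"
    )
  counts <- switch(
    rare_filter,
    n_B = filter(counts, .data$n_B >= min_patients),
    n_AB = filter(counts, .data$n_AB >= min_patients)
  )
  if (nrow(counts) == 0) {
    return(structure(empty, n_patients = n_total, n_cases = n_cases,
                     m_family = as.integer(m_family %||% 0L)))
  }

  res <- counts %>%
    mutate(
      p_A_given_B = conditional_probability(.data$n_AB, .data$n_B),
      p_B_given_A = if (n_cases > 0) .data$n_AB / n_cases else 0
    ) %>%
    arrange(desc(.data$p_A_given_B), desc(.data$n_B), .data$code) %>%
    head(n = if (is.finite(top_k)) top_k else nrow(counts))

  test <- purrr::pmap(
    list(res$n_AB, res$n_B),
    function(n_ab, n_b) {
      a <- n_ab
      b <- n_cases - n_ab
      cc <- n_b - n_ab
      d <- n_total - n_cases - n_b + n_ab
      if (min(a + b, cc + d, a + cc, b + d) == 0) {
        list(statistic = NA_real_, p_value = NA_real_)
      } else {
        chi_square_2x2(a, b, cc, d)
      }
    }
  )
  res$chi2 <- vapply(test, `[[`, numeric(1), "statistic")
  res$p_value <- vapply(test, `[[`, numeric(1), "p_value")
  m <- as.integer(m_family %||% sum(!is.na(res$p_value)))
  res$p_bonferroni <- ifelse(
    is.na(res$p_value), NA_real_,
    bonferroni_adjust(ifelse(is.na(res$p_value), 0, res$p_value),
                      m = max(m, nrow(res)))
  )
  res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha

  out <- dplyr::bind_cols(stratum[rep(1, nrow(res)), ], res)
  structure(as_tibble(out), n_patients = n_total, n_cases = n_cases,
            m_family = m)
}

format_stratum <- function(s) {
  paste(s$age_group, s$sex, s$subtype, sep = "/")
}

#' Run the comorbidity screen over a grid of strata
#'
#' Default strata mirror a one-factor-at-a-time stratification: the overall
#' population plus each age group, each sex, and each phenotype subtype.
#' The Bonferroni family is the total number of (code, stratum) tests
#' actually performed across all strata in the run; the family size is
#' recorded in the `m_family` attribute for audit.
#'
#' @inheritParams comorbidity_scan
#' @param strata Tibble of stratum rows (as [stratum_spec()]); `NULL` for
#'   the default margins grid.
#' @return Tibble of stacked scan rows with run-wide Bonferroni
#'   correction; attribute `m_family`.
#' @export
comorbidity_scan_grid <- function(encounters, labels, cs,
                                  strata = NULL,
                                  min_patients = 20L,
                                  rare_filter = c("n_B", "n_AB"),
                                  top_k = 20L,
                                  alpha = 0.05) {
  rare_filter <- match.arg(rare_filter)
  if (is.null(strata)) {
    strata <- bind_rows(
      stratum_spec("all", "all", "any"),
      stratum_spec("children_6_11", "all", "any"),
      stratum_spec("adolescents_12_18", "all", "any"),
      stratum_spec("all", "male", "any"),
      stratum_spec("all", "female", "any"),
      !!!lapply(names(cs$subtypes), function(s) {
        stratum_spec("all", "all", s)
      })
    )
  }
  raw <- lapply(seq_len(nrow(strata)), function(i) {
    comorbidity_scan(
      encounters, labels, cs, stratum = strata[i, ],
      min_patients = min_patients, rare_filter = rare_filter,
      top_k = top_k, alpha = alpha, m_family = NULL
    )
  })
  combined <- bind_rows(raw)
  m <- sum(!is.na(combined$p_value))
  if (nrow(combined) > 0) {
    combined$p_bonferroni <- ifelse(
      is.na(combined$p_value), NA_real_,
      bonferroni_adjust(ifelse(is.na(combined$p_value), 0,
                               combined$p_value),
                        m = max(m, nrow(combined)))
    )
    combined$significant <- !is.na(combined$p_bonferroni) &
      combined$p_bonferroni < alpha
  }
  structure(combined, m_family = m)
}

#' Union of codes significant in at least one stratum
#'
#' @param scan_results Output of [comorbidity_scan_grid()] (or stacked
#'   [comorbidity_scan()] rows).
#' @return Tibble `code`, `n_strata`, `strata` (list-column of
#'   "age/sex/subtype" provenance strings), `max_p_A_given_B`; one row per
#'   code, sorted by descending `max_p_A_given_B`.
#' @export
significant_union <- function(scan_results) {
  sig <- filter(scan_results, .data$significant)
  if (nrow(sig) == 0) {
    return(tibble(
      code = character(0), n_strata = integer(0), strata = list(),
      max_p_A_given_B = numeric(0)
    ))
  }
  sig %>%
    mutate(stratum = paste(.data$age_group, .data$sex, .data$subtype,
                           sep = "/")) %>%
    group_by(.data$code) %>%
    summarise(
      n_strata = dplyr::n(),
      strata = list(sort(unique(.data$stratum))),
      max_p_A_given_B = max(.data$p_A_given_B),
      .groups = "drop"
    ) %>%
    arrange(desc(.data$max_p_A_given_B), .data$code)
}
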
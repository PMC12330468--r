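#' Read an ordered DSM-5 category mapping
#'
#' The file is an ordered JSON array of `{pattern, category}` objects with
#' first-match-wins semantics: a code is assigned the category of the first
#' pattern it matches (so `F63*` listed before `F6*` carves
#' impulse-control codes out of the personality block). Patterns follow the
#' codeset convention: normalized, optional trailing `"*"` for prefix
#' match.
#'
#' @param path Path to the JSON mapping file; defaults to the packaged
#'   mapping, which covers the common pediatric mental-health categories
#'   via ICD-10 F-chapter ranges (anxiety F40–F41, depressive F32–F34,
#'   bipolar F30–F31, schizophrenia spectrum F20–F29, ADHD F90,
#'   trauma/stressor F43, gender dysphoria F64, personality F60–F69
#'   excluding F63/F64, disruptive/impulse F63 + F91, and others). The
#'   crosswalk is deliberately user-replaceable: DSM-5 prints no official
#'   ICD-10 mapping.
#' @return Tibble of class `"dsm5_mapping"`: ordered `pattern`, `category`.
#' @export
read_dsm5_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dsm5_mapping.json",
                                package = "phenomatch", mustWork = TRUE)
  if (!file.exists(path)) {
    abort(paste0("DSM-5 mapping file not found: ", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.data.frame(raw) || !all(c("pattern", "category") %in% names(raw))) {
    abort(paste0(
      "DSM-5 mapping file ", path,
      " must be an array of {pattern, category} objects."
    ))
  }
  out <- as_tibble(raw) %>%
    mutate(pattern = normalize_icd10(.data$pattern))
  class(out) <- c("dsm5_mapping", class(out))
  out
}

#' Map ICD-10 codes to DSM-5 categories
#'
#' @param codes Character vector of normalized codes.
#' @param mapping A [read_dsm5_mapping()] tibble.
#' @return Character vector of categories, `NA` where no pattern matches.
#' @export
dsm5_categorize <- function(codes, mapping) {
  out <- rep(NA_character_, length(codes))
  unresolved <- seq_along(codes)
  for (i in seq_len(nrow(mapping))) {
    if (length(unresolved) == 0) break
    hit <- match_patterns(codes[unresolved], mapping$pattern[i])
    out[unresolved[hit]] <- mapping$category[i]
    unresolved <- unresolved[!hit]
  }
  out
}

#' Prevalence and conditional probabilities by DSM-5 category
#'
#' A patient "has" a category if any code in their study-period profile
#' maps to it. For each category the function reports its prevalence in
#' the population and both conditional directions against the phenotype:
#' \eqn{P(\mathrm{case} \mid \mathrm{category})} (how predictive the
#' category is) and \eqn{P(\mathrm{category} \mid \mathrm{case})} (how
#' common the category is among cases).
#'
#' @param encounters Encounter tibble.
#' @param labels Patient labels from [label_patients()].
#' @param mapping A [read_dsm5_mapping()] tibble.
#' @return Tibble `category`, `n_patients`, `prevalence`,
#'   `p_case_given_category`, `p_category_given_case`; attribute
#'   `n_unmapped_codes` counts distinct profile codes no pattern covered.
#' @export
dsm5_category_stats <- function(encounters, labels, mapping) {
  profiles <- patient_code_profiles(encounters)
  n_total <- nrow(profiles)
  n_cases <- sum(labels$is_case)
  case_ids <- labels$patient_id[labels$is_case]

  long <- tibble(
    patient_id = rep(profiles$patient_id, lengths(profiles$codes)),
    code = as.character(unlist(profiles$codes))
  )
  long$category <- dsm5_categorize(long$code, mapping)
  n_unmapped <- dplyr::n_distinct(long$code[is.na(long$category)])
  long <- filter(long, !is.na(.data$category))

  out <- long %>%
    distinct(.data$patient_id, .data$category) %>%
    mutate(is_case = .data$patient_id %in% case_ids) %>%
    group_by(.data$category) %>%
    summarise(
      n_patients = dplyr::n(),
      n_case_patients = sum(.data$is_case),
      .groups = "drop"
    ) %>%
    mutate(
      prevalence = .data$n_patients / n_total,
      p_case_given_category = conditional_probability(
        .data$n_case_patients, .data$n_patients
      ),
      p_category_given_case = if (n_cases > 0) {
        .data$n_case_patients / n_cases
      } else {
        0
      }
    ) %>%
    arrange(desc(.data$p_case_given_category), .data$category)
  if (n_unmapped > 0) {
    inform(paste0(n_unmapped, " distinct code(s) matched no DSM-5 pattern",
                  " and were ignored."))
  }
  structure(out, n_unmapped_codes = n_unmapped)
}
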
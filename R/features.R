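#' Split encounters into case units and comparator units
#'
#' Propensity modeling operates on encounter units. The case cohort is
#' every case-defining encounter of a case patient (their other encounters
#' are excluded); the comparator cohort is every encounter of every
#' non-case patient. A patient therefore never contributes units to both
#' groups.
#'
#' @param encounters Encounter tibble.
#' @param labels Patient labels from [label_patients()].
#' @param cs The phenotype [codeset()] (identifies case-defining
#'   encounters).
#' @param case_index_only Restrict case units to each case's index
#'   encounter (sensitivity analysis). Default `FALSE`: all case-defining
#'   encounters contribute.
#' @param comparator_last_only Restrict comparator units to each
#'   comparator's final encounter. Default `FALSE`: all encounters.
#' @return Tibble: encounter columns plus `label` (1 case unit, 0
#'   comparator unit).
#' @export
build_units <- function(encounters, labels, cs,
                        case_index_only = FALSE,
                        comparator_last_only = FALSE) {
  check_encounters(encounters)
  if (nrow(encounters) == 0) {
    return(mutate(encounters, label = integer(0)))
  }
  case_ids <- labels$patient_id[labels$is_case]
  is_case_pat <- encounters$patient_id %in% case_ids
  defines <- rowSums(subtype_hits(encounters$icd10_codes, cs)) > 0
  case_units <- encounters[is_case_pat & defines, , drop = FALSE]
  if (case_index_only && nrow(case_units) > 0) {
    case_units <- case_units %>%
      group_by(.data$patient_id) %>%
      arrange(.data$date, .data$encounter_id, .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
  }
  comp_units <- encounters[!is_case_pat, , drop = FALSE]
  if (comparator_last_only && nrow(comp_units) > 0) {
    comp_units <- comp_units %>%
      group_by(.data$patient_id) %>%
      arrange(desc(.data$date), desc(.data$encounter_id),
              .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
  }
  bind_rows(
    mutate(case_units, label = 1L),
    mutate(comp_units, label = 0L)
  )
}

#' Assemble the propensity feature matrix
#'
#' Builds the unit-by-variable matrix for propensity modeling. Blocks, in
#' fixed order (alphabetical within block):
#'
#' * **demographics** — `age_adolescent` (age at visit ≥ 12), `sex_female`,
#'   and race one-hots with the alphabetically first observed level as the
#'   dropped reference; `"unknown"` race is its own level (EHR missingness
#'   is informative).
#' * **utilization** — `n_prior_visits` (the patient's encounters dated up
#'   to the unit encounter) and `n_note_types` (distinct note types seen
#'   over the same window).
#' * **dsm5** — one indicator per mapped category.
#' * **codes** — one indicator per significant comorbidity code.
#'
#' Indicators and counts aggregate the patient's history cumulatively:
#' an observation contributes to a unit iff its encounter date is on or
#' before the unit date (`include_unit_encounter = FALSE` switches to
#' strictly-before). Codes matching the phenotype codeset are stripped
#' before any feature is computed, so the case label can never leak into
#' the covariates.
#'
#' @param encounters Encounter tibble (the full study history, used to
#'   accumulate features).
#' @param labels Patient labels from [label_patients()].
#' @param cs The phenotype [codeset()].
#' @param mapping A [read_dsm5_mapping()] tibble.
#' @param significant_codes Character vector of codes from
#'   [significant_union()] (may be empty). Must not intersect the
#'   phenotype codeset.
#' @param include_unit_encounter Logical; see above. Default `TRUE` (the
#'   diagnosis motivating the visit is recorded at that visit).
#' @param drop_constant Drop zero-variance columns (they are always
#'   reported via the `constant_features` attribute). Default `FALSE`.
#' @inheritParams build_units
#' @return Object of class `"feature_matrix"`: list with `units`
#'   (`patient_id`, `encounter_id`, `date`, `label`), numeric matrix `x`,
#'   `feature_names`, `blocks` (named character of block membership), and
#'   `reference_levels`.
#' @export
assemble_features <- function(encounters, labels, cs, mapping,
                              significant_codes = character(0),
                              include_unit_encounter = TRUE,
                              case_index_only = FALSE,
                              comparator_last_only = FALSE,
                              drop_constant = FALSE) {
  significant_codes <- if (length(significant_codes) > 0) {
    normalize_icd10(significant_codes)
  } else {
    character(0)
  }
  bad <- significant_codes[in_codeset(significant_codes, cs)]
  if (length(bad) > 0) {
    abort(paste0(
      "Phenotype codeset code(s) may not be used as features: ",
      paste(unique(bad), collapse = ", ")
    ))
  }

  units <- build_units(encounters, labels, cs,
                       case_index_only = case_index_only,
                       comparator_last_only = comparator_last_only)
  if (nrow(units) == 0) abort("No units to featurize.")

  # Leakage guard: the phenotype's own codes never reach the features.
  hist <- encounters %>%
    semi_join(units, by = "patient_id") %>%
    mutate(icd10_codes = lapply(.data$icd10_codes, function(cd) {
      cd[!in_codeset(cd, cs)]
    }))

  cmp <- if (include_unit_encounter) `<=` else `<`

  # --- demographics ----------------------------------------------------
  races <- sort(unique(hist$race))
  race_ref <- races[1]
  demo <- tibble(
    age_adolescent = as.numeric(units$age_at_visit >= 12),
    sex_female = as.numeric(units$sex == "female")
  )
  for (r in setdiff(races, race_ref)) {
    demo[[paste0("race_", r)]] <- as.numeric(units$race == r)
  }
  demo <- demo[, sort(names(demo)), drop = FALSE]

  # --- utilization -----------------------------------------------------
  pat_dates <- split(hist$date, hist$patient_id)
  pat_idx <- match(units$patient_id, names(pat_dates))
  n_prior <- vapply(seq_len(nrow(units)), function(i) {
    sum(cmp(pat_dates[[pat_idx[i]]], units$date[i]))
  }, numeric(1))

  note_long <- tibble(
    patient_id = rep(hist$patient_id, lengths(hist$note_types)),
    date = rep(hist$date, lengths(hist$note_types)),
    item = as.character(unlist(hist$note_types))
  )
  n_notes <- count_distinct_by_date(note_long, units, cmp)
  util <- tibble(n_note_types = n_notes, n_prior_visits = n_prior)

  # --- cumulative indicators (DSM-5 categories + significant codes) ----
  code_long <- tibble(
    patient_id = rep(hist$patient_id, lengths(hist$icd10_codes)),
    date = rep(hist$date, lengths(hist$icd10_codes)),
    code = as.character(unlist(hist$icd10_codes))
  )
  cat_long <- code_long %>%
    mutate(item = dsm5_categorize(.data$code, mapping)) %>%
    filter(!is.na(.data$item)) %>%
    select("patient_id", "date", "item")
  categories <- sort(unique(mapping$category))
  dsm5 <- indicator_block(cat_long, units, categories, cmp, "dsm5_")

  sig_long <- code_long %>%
    filter(.data$code %in% significant_codes) %>%
    rename(item = "code") %>%
    select("patient_id", "date", "item")
  codes <- indicator_block(sig_long, units, sort(significant_codes), cmp,
                           "code_")

  blocks <- c(
    setNames(rep("demographics", ncol(demo)), names(demo)),
    setNames(rep("utilization", ncol(util)), names(util)),
    setNames(rep("dsm5", ncol(dsm5)), names(dsm5)),
    setNames(rep("codes", ncol(codes)), names(codes))
  )
  x <- as.matrix(dplyr::bind_cols(demo, util, dsm5, codes))
  rownames(x) <- NULL

  constant <- colnames(x)[apply(x, 2, function(v) length(unique(v)) == 1)]
  if (length(constant) > 0) {
    inform(paste0(
      "Constant feature column(s): ", paste(constant, collapse = ", "),
      if (drop_constant) " (dropped)" else " (kept)"
    ))
    if (drop_constant) {
      x <- x[, setdiff(colnames(x), constant), drop = FALSE]
      blocks <- blocks[colnames(x)]
    }
  }

  structure(
    list(
      units = units %>%
        select("patient_id", "encounter_id", "date", "label"),
      x = x,
      feature_names = colnames(x),
      blocks = blocks,
      reference_levels = c(race = race_ref, sex = "male",
                           age_group = "children"),
      constant_features = constant
    ),
    class = "feature_matrix"
  )
}

# Indicator = 1 iff the item was first observed on/before (or strictly
# before, per `cmp`) the unit date.
indicator_block <- function(long, units, items, cmp, prefix) {
  out <- tibble(.rows = nrow(units))
  if (length(items) == 0) return(out)
  firsts <- long %>%
    group_by(.data$patient_id, .data$item) %>%
    summarise(first_date = min(.data$date), .groups = "drop")
  for (it in items) {
    f <- firsts %>% filter(.data$item == it)
    fd <- f$first_date[match(units$patient_id, f$patient_id)]
    col <- !is.na(fd) & cmp(fd, units$date)
    out[[paste0(prefix, it)]] <- as.numeric(col)
  }
  out
}

# Distinct items (note types) observed up to each unit's date.
count_distinct_by_date <- function(long, units, cmp) {
  if (nrow(long) == 0) return(rep(0, nrow(units)))
  firsts <- long %>%
    group_by(.data$patient_id, .data$item) %>%
    summarise(first_date = min(.data$date), .groups = "drop")
  by_pat <- split(firsts$first_date, firsts$patient_id)
  idx <- match(units$patient_id, names(by_pat))
  vapply(seq_len(nrow(units)), function(i) {
    if (is.na(idx[i])) 0 else sum(cmp(by_pat[[idx[i]]], units$date[i]))
  }, numeric(1))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " units x ", ncol(x$x),
      " features\n", sep = "")
  cat("  cases: ", sum(x$units$label == 1), "; comparators: ",
      sum(x$units$label == 0), "\n", sep = "")
  cat("  blocks: ", paste(unique(x$blocks), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a feature matrix into one tibble
#'
#' @param x A `"feature_matrix"`.
#' @param ... Unused.
#' @return Tibble: unit identifiers, `label`, then one column per feature.
#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(x$units, as_tibble(as.data.frame(x$x)))
}
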
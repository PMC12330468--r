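# Compact constructors for hand-built encounter fixtures.

enc_row <- function(patient, id, date, codes = character(0),
                    age = 14L, sex = "female", race = "white",
                    notes = "ED note") {
  tibble::tibble(
    patient_id = patient,
    encounter_id = id,
    date = as.Date(date),
    age_at_visit = as.integer(age),
    sex = sex,
    race = race,
    icd10_codes = list(normalize_icd10(codes)),
    note_types = list(notes)
  )
}

enc_bind <- function(...) dplyr::bind_rows(...)

suicidality_cs <- default_suicidality_codeset()

# Small, fast simulation config for unit tests.
test_sim_config <- function(n_patients = 2000, seed = 42, ...) {
  sim_config(n_patients = n_patients, seed = seed, ...)
}

# Encounter counts as printed in the source cohort-characteristics table;
# used to check that percentage recomputation reproduces the printed
# figures exactly.
table1_counts <- function() {
  tibble::tribble(
    ~row,        ~column,     ~count,
    "total",     "all",       90980L,
    "age_6_11",  "all",       47253L,
    "age_12_18", "all",       43727L,
    "male",      "all",       47045L,
    "female",    "all",       43929L,  # male+female fall 6 short of total
                                       # (unreported sex)
    "total",     "cases",     2638L,
    "age_6_11",  "cases",     310L,
    "age_12_18", "cases",     2328L,
    "male",      "cases",     813L,
    "female",    "cases",     1825L,
    "total",     "ideation",  2275L,
    "age_6_11",  "ideation",  266L,
    "age_12_18", "ideation",  2009L,
    "male",      "ideation",  707L,
    "female",    "ideation",  1568L,
    "total",     "self_harm", 1030L,
    "age_6_11",  "self_harm", 69L,
    "age_12_18", "self_harm", 961L,
    "male",      "self_harm", 222L,
    "female",    "self_harm", 808L,
    "total",     "attempt",   177L,
    "age_6_11",  "attempt",   5L,
    "age_12_18", "attempt",   172L,
    "male",      "attempt",   37L,
    "female",    "attempt",   140L
  )
}

# Hand-buildable feature_matrix for direct PSM tests.
manual_feature_matrix <- function(x, label,
                                  patient_id = paste0("P", seq_len(nrow(x))),
                                  encounter_id = paste0("E", seq_len(nrow(x)))) {
  structure(
    list(
      units = tibble::tibble(
        patient_id = patient_id,
        encounter_id = encounter_id,
        date = as.Date("2020-01-01") + seq_len(nrow(x)),
        label = as.integer(label)
      ),
      x = x,
      feature_names = colnames(x),
      blocks = stats::setNames(rep("codes", ncol(x)), colnames(x)),
      reference_levels = character(0),
      constant_features = character(0)
    ),
    class = "feature_matrix"
  )
}
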
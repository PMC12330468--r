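#' Normalize an ICD-10 code or code pattern
#'
#' ICD-10 codes appear in EHR extracts in several dialects ("T14.91XA",
#' "t14.91xa ", "T1491XA"). All package functions operate on the normalized
#' form: uppercase, dot removed, surrounding whitespace stripped. A trailing
#' `"*"` (prefix-match marker in codeset and mapping files) is preserved.
#'
#' @param x Character vector of raw codes or patterns.
#' @return Character vector of normalized codes. Idempotent:
#'   `normalize_icd10(normalize_icd10(x))` equals `normalize_icd10(x)`.
#' @examples
#' normalize_icd10(c("T14.91XA", "r45.851 "))
#' @export
normalize_icd10 <- function(x) {
  if (!is.character(x)) {
    abort("`x` must be a character vector of ICD-10 codes.")
  }
  out <- toupper(gsub(".", "", trimws(x), fixed = TRUE))
  if (any(is.na(out) | out == "")) {
    abort("ICD-10 codes must be nonempty strings (blank or NA input).")
  }
  out
}

#' Construct a phenotype codeset
#'
#' A codeset names the ICD-10 code patterns defining a phenotype, split into
#' severity subtypes. The packaged suicidality default
#' ([default_suicidality_codeset()]) carries `ideation`, `self_harm` and
#' `attempt`. A pattern is a normalized code, optionally suffixed `"*"` for
#' prefix matching; matching is otherwise exact, so `Z915` does not match
#' `Z9151`.
#'
#' @param subtypes Named list of character vectors of code patterns, one
#'   element per subtype.
#' @param name Codeset name.
#' @param allow_overlap Permit the same pattern in several subtypes. Default
#'   `FALSE`: overlap is usually a codeset-file mistake.
#' @return An object of class `"codeset"`.
#' @seealso [read_codeset()], [classify_codes()]
#' @export
codeset <- function(subtypes, name = "codeset", allow_overlap = FALSE) {
  if (!is.list(subtypes) || is.null(names(subtypes)) ||
      any(names(subtypes) == "")) {
    abort("`subtypes` must be a named list of character pattern vectors.")
  }
  subtypes <- lapply(subtypes, function(p) {
    if (length(p) == 0) {
      abort("Each codeset subtype must contain at least one pattern.")
    }
    normalize_icd10(as.character(p))
  })
  if (!allow_overlap) {
    all_pat <- unlist(subtypes, use.names = FALSE)
    dup <- unique(all_pat[duplicated(all_pat)])
    if (length(dup) > 0) {
      abort(paste0(
        "Pattern(s) appear in more than one subtype: ",
        paste(dup, collapse = ", "),
        ". Set `allow_overlap = TRUE` if intentional."
      ))
    }
  }
  structure(
    list(name = name, subtypes = subtypes, allow_overlap = allow_overlap),
    class = "codeset"
  )
}

#' @export
print.codeset <- function(x, ...) {
  cat("<codeset> ", x$name, "\n", sep = "")
  for (s in names(x$subtypes)) {
    pats <- x$subtypes[[s]]
    cat("  ", s, " (", length(pats), "): ",
        paste(head(pats, 8), collapse = ", "),
        if (length(pats) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read a codeset definition file
#'
#' The file is JSON with fields `name`, optional `allow_overlap`, and
#' `subtypes`, a map from subtype label to an array of code patterns. The
#' packaged suicidality definition (see [default_suicidality_codeset()]) is
#' the template. Self-harm codesets in the field run to over a thousand
#' codes; users extend the packaged file (which ships the personal-history
#' codes printed in the primary sources) with their own patterns, e.g.
#' prefix patterns like `"X71*"`.
#'
#' @param path Path to a JSON codeset file.
#' @return A [codeset()].
#' @export
read_codeset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Codeset file not found: ", path))
  }
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$subtypes) || length(spec$subtypes) == 0) {
    abort(paste0("Codeset file ", path, " has no `subtypes` section."))
  }
  empty <- names(spec$subtypes)[vapply(spec$subtypes, length, 1L) == 0]
  if (length(empty) > 0) {
    abort(paste0(
      "Codeset file ", path, ": subtype(s) with no patterns: ",
      paste(empty, collapse = ", ")
    ))
  }
  codeset(
    subtypes = as.list(spec$subtypes),
    name = spec$name %||% basename(path),
    allow_overlap = isTRUE(spec$allow_overlap)
  )
}

#' The packaged suicidality case definition
#'
#' Three severity subtypes: suicidal ideation is documented only for the
#' present encounter (`R45.851` — ICD-10 has no history-of-ideation code);
#' suicide attempt has four codes (`T14.91` and its initial/subsequent/
#' sequela encounter forms); self-harm is represented by its four
#' personal-history codes (`R45.88`, `Z91.5`, `Z91.51`, `Z91.52`). The full
#' self-harm family is far larger (≈1,400 codes); extend the packaged file
#' with additional patterns for production surveillance use.
#'
#' @return A [codeset()].
#' @export
default_suicidality_codeset <- function() {
  read_codeset(
    system.file("extdata", "suicidality_codeset.json", package = "phenomatch",
                mustWork = TRUE)
  )
}

# TRUE for each code that matches >= 1 pattern (exact, or prefix for "*").
match_patterns <- function(codes, patterns) {
  if (length(codes) == 0) return(logical(0))
  star <- endsWith(patterns, "*")
  exact <- patterns[!star]
  prefix <- sub("\\*$", "", patterns[star])
  hit <- codes %in% exact
  for (p in prefix) {
    hit <- hit | startsWith(codes, p)
  }
  hit
}

#' Classify a set of diagnosis codes against a codeset
#'
#' A subtype is assigned iff any code matches any of its patterns. Adding
#' codes can only add subtypes (monotone).
#'
#' @param codes Character vector of normalized ICD-10 codes (one encounter's
#'   diagnosis list).
#' @param cs A [codeset()].
#' @return Character vector: the matching subtype labels (possibly empty).
#' @examples
#' classify_codes(c("T1491XD", "Z9151"), default_suicidality_codeset())
#' @export
classify_codes <- function(codes, cs) {
  stopifnot(inherits(cs, "codeset"))
  hits <- vapply(
    cs$subtypes,
    function(p) any(match_patterns(codes, p)),
    logical(1)
  )
  names(cs$subtypes)[hits]
}

# TRUE per code: does it belong to the codeset (any subtype)?
in_codeset <- function(codes, cs) {
  match_patterns(codes, unlist(cs$subtypes, use.names = FALSE))
}

# Encounter-by-subtype logical matrix; vectorized over the long code list
# so per-encounter classification never loops in R.
subtype_hits <- function(icd10_codes, cs) {
  n <- length(icd10_codes)
  m <- matrix(FALSE, nrow = n, ncol = length(cs$subtypes),
              dimnames = list(NULL, names(cs$subtypes)))
  code <- as.character(unlist(icd10_codes, use.names = FALSE))
  if (length(code) > 0) {
    enc_i <- rep.int(seq_len(n), lengths(icd10_codes))
    for (s in names(cs$subtypes)) {
      hit <- match_patterns(code, cs$subtypes[[s]])
      if (any(hit)) m[unique(enc_i[hit]), s] <- TRUE
    }
  }
  m
}

#' Label patients against a case definition
#'
#' A patient is a case iff any of their encounters carries a code matching
#' any subtype. Subtypes accumulate over all encounters; the index date is
#' the earliest case-defining encounter. History-of codes count at any
#' encounter.
#'
#' @param encounters Encounter tibble with columns `patient_id`,
#'   `encounter_id`, `date`, and list-column `icd10_codes` (normalized).
#' @param cs A [codeset()].
#' @return Tibble with one row per patient: `patient_id`, `is_case`,
#'   `subtypes` (list-column of subtype labels), `index_date` (`NA` for
#'   non-cases).
#' @export
label_patients <- function(encounters, cs) {
  check_encounters(encounters)
  stopifnot(inherits(cs, "codeset"))
  if (nrow(encounters) == 0) {
    abort("`encounters` must contain at least one encounter.")
  }
  m <- subtype_hits(encounters$icd10_codes, cs)
  hit <- rowSums(m) > 0
  pid <- encounters$patient_id
  pats <- sort(unique(pid))

  # per-patient subtype union, via the long (patient, subtype) pairs
  flat <- as.vector(m)
  sub_long <- split(
    rep(colnames(m), each = nrow(m))[flat],
    factor(rep(pid, ncol(m))[flat], levels = pats)
  )
  index_num <- if (any(hit)) {
    as.vector(tapply(as.numeric(encounters$date[hit]),
                     factor(pid[hit], levels = pats), min))
  } else {
    rep(NA_real_, length(pats))
  }
  tibble(
    patient_id = pats,
    is_case = pats %in% pid[hit],
    subtypes = unname(lapply(sub_long, function(s) sort(unique(s)))),
    index_date = as.Date(index_num, origin = "1970-01-01")
  )
}

#' Select the study population
#'
#' Keeps encounters whose age at visit lies in `age_range` (inclusive both
#' ends), whose date lies in `[date_range[1], date_range[2])` (half-open:
#' a study window quoted as "June 2016 to June 2022" includes the start day
#' and excludes the end day), and which carry the required note type
#' (presence of an ED note identifies an ED visit).
#'
#' @param encounters Encounter tibble (see [label_patients()]) with
#'   `age_at_visit` and list-column `note_types`.
#' @param age_range Integer pair, default `c(6, 18)`.
#' @param date_range Date (or ISO string) pair.
#' @param required_note_type Note type that must be present; `NULL` disables
#'   the filter. Default `"ED note"`.
#' @return The filtered encounter tibble. Idempotent and order-independent.
#' @export
select_study_population <- function(encounters,
                                    age_range = c(6L, 18L),
                                    date_range,
                                    required_note_type = "ED note") {
  check_encounters(encounters)
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    abort("`age_range` must be an ordered pair of ages.")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      date_range[1] >= date_range[2]) {
    abort("`date_range` must be an ordered pair of dates (start < end).")
  }
  keep <- encounters$age_at_visit >= age_range[1] &
    encounters$age_at_visit <= age_range[2] &
    encounters$date >= date_range[1] &
    encounters$date < date_range[2]
  if (!is.null(required_note_type)) {
    keep <- keep & vapply(
      encounters$note_types,
      function(nt) required_note_type %in% nt,
      logical(1)
    )
  }
  encounters[keep, , drop = FALSE]
}

# Shared structural validation for encounter tibbles.
check_encounters <- function(encounters) {
  need <- c("patient_id", "encounter_id", "date", "icd10_codes")
  missing <- setdiff(need, names(encounters))
  if (length(missing) > 0) {
    abort(paste0(
      "`encounters` is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!is.list(encounters$icd10_codes)) {
    abort("`encounters$icd10_codes` must be a list-column of character vectors.")
  }
  invisible(encounters)
}
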
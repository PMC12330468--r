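round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Build a cohort characteristics table from cell counts
#'
#' Given encounter counts per demographic row (`total`, `age_6_11`,
#' `age_12_18`, `male`, `female`) and cohort column (`all`, `cases`, and
#' one column per subtype), validates internal consistency (age rows and
#' sex rows each sum to the total row in every column) and computes column
#' percentages, rounded half-up to one decimal for display with the raw
#' proportion retained.
#'
#' @param counts Tibble with columns `row`, `column`, `count`.
#' @return Tibble of class `"cohort_table"`: `row`, `column`, `count`,
#'   `proportion`, `pct`.
#' @export
cohort_table <- function(counts) {
  need <- c("row", "column", "count")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have columns row, column, count.")
  }
  if (any(counts$count < 0)) abort("Counts must be nonnegative.")
  wide <- tidyr::pivot_wider(counts, names_from = "column",
                             values_from = "count")
  rows <- wide$row
  for (col in setdiff(names(wide), "row")) {
    v <- setNames(wide[[col]], rows)
    if (!all(c("total", "age_6_11", "age_12_18", "male", "female") %in%
             rows)) {
      abort("Rows must include total, age_6_11, age_12_18, male, female.")
    }
    if (v[["age_6_11"]] + v[["age_12_18"]] != v[["total"]]) {
      abort(paste0("Age rows do not sum to total in column ", col, "."))
    }
    # Sex rows may fall short of the total (unreported sex) but never
    # exceed it.
    if (v[["male"]] + v[["female"]] > v[["total"]]) {
      abort(paste0("Sex rows exceed the total in column ", col, "."))
    }
  }
  totals <- counts %>%
    filter(.data$row == "total") %>%
    select("column", total = "count")
  out <- counts %>%
    left_join(totals, by = "column") %>%
    mutate(
      proportion = if_else(.data$total > 0,
                           .data$count / .data$total, 0),
      pct = round_half_up(100 * .data$proportion, 1)
    ) %>%
    select("row", "column", "count", "proportion", "pct")
  class(out) <- c("cohort_table", class(out))
  out
}

#' Encounter-level cohort characteristics
#'
#' Counts ED encounters by demographic rows (total, age 6–11, age 12–18,
#' male, female) for the overall population, the suicidality cases, and
#' each severity subtype (an encounter contributes to every subtype its
#' codes match), with column percentages.
#'
#' @param encounters Encounter tibble.
#' @param cs The phenotype [codeset()].
#' @return A [cohort_table()].
#' @export
summarize_cohort <- function(encounters, cs) {
  check_encounters(encounters)
  m <- subtype_hits(encounters$icd10_codes, cs)
  cols <- c(
    list(all = rep(TRUE, nrow(encounters)), cases = rowSums(m) > 0),
    lapply(setNames(colnames(m), colnames(m)), function(s) m[, s])
  )
  rows <- list(
    total = rep(TRUE, nrow(encounters)),
    age_6_11 = encounters$age_at_visit <= 11,
    age_12_18 = encounters$age_at_visit >= 12,
    male = encounters$sex == "male",
    female = encounters$sex == "female"
  )
  counts <- tidyr::expand_grid(
    row = names(rows), column = names(cols)
  ) %>%
    mutate(count = purrr::map2_int(
      .data$row, .data$column,
      function(r, cl) sum(rows[[r]] & cols[[cl]])
    ))
  cohort_table(counts)
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' \eqn{z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p} the pooled proportion.
#'
#' @param x1,n1 Successes and size of group 1.
#' @param x2,n2 Successes and size of group 2.
#' @return Named list `z`, `p_value`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    abort("Need 0 <= x <= n with n > 0 in both groups.")
  }
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    abort("Degenerate test: pooled proportion is 0 or 1.")
  }
  z <- (x1 / n1 - x2 / n2) /
    sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Odds ratio with Woolf confidence interval
#'
#' For the 2x2 table `[[a, b], [c, d]]`: OR = ad/bc with interval
#' \eqn{\exp(\ln\mathrm{OR} \pm z_{\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d})}.
#' When any cell is zero, 0.5 is added to every cell (Haldane–Anscombe)
#' and the result is flagged via the `continuity_corrected` attribute.
#'
#' @param a,b,c,d Nonnegative cell counts.
#' @param conf_level Confidence level, default 0.95.
#' @return Named list `or`, `lo`, `hi`.
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("Cell counts must be nonnegative.")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- counts[1] * counts[4] / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(or = or, lo = or * exp(-zq * se), hi = or * exp(zq * se)),
    continuity_corrected = corrected
  )
}

#' Enrichment of ground-truth suicidality among matched comparators
#'
#' The headline check of the matching method: matched comparators are all
#' undiagnosed by construction, yet if the comorbidity profile carries
#' signal, their *latent* (ground-truth) suicidality prevalence should far
#' exceed the comparator-pool baseline. Ground truth comes from the
#' synthetic generator's patients table, or from a chart-review
#' adjudication file with the same two columns.
#'
#' @param pairs A [match_nearest()] result.
#' @param truth Tibble `patient_id`, `latent_suicidality` (logical).
#' @param reference Tibble of the comparator-pool patients to compare
#'   against, same columns (typically all non-case patients).
#' @return One-row tibble: `n_matched`, `prevalence_matched`,
#'   `n_reference`, `prevalence_reference`, `ratio`, `z`, `p_value`,
#'   `odds_ratio`, `or_lo`, `or_hi`, `n_excluded` (matched patients with
#'   no truth label, dropped with a warning).
#' @export
enrichment_report <- function(pairs, truth, reference) {
  stopifnot(inherits(pairs, "matched_pairs"))
  matched_pat <- unique(pairs$comparator_patient_id)
  known <- matched_pat %in% truth$patient_id
  if (any(!known)) {
    warn(paste0(sum(!known), " matched patient(s) lack a truth label",
                " and were excluded."))
  }
  matched_pat <- matched_pat[known]
  if (length(matched_pat) == 0) abort("No matched patients with truth labels.")
  m_lat <- truth$latent_suicidality[match(matched_pat, truth$patient_id)]
  ref <- reference %>% filter(!is.na(.data$latent_suicidality))

  x2 <- sum(m_lat); n2 <- length(m_lat)
  x1 <- sum(ref$latent_suicidality); n1 <- nrow(ref)
  zt <- two_proportion_z(x2, n2, x1, n1)
  or <- odds_ratio_ci(x2, n2 - x2, x1, n1 - x1)
  tibble(
    n_matched = n2,
    prevalence_matched = x2 / n2,
    n_reference = n1,
    prevalence_reference = x1 / n1,
    ratio = (x2 / n2) / (x1 / n1),
    z = zt$z,
    p_value = zt$p_value,
    odds_ratio = or$or,
    or_lo = or$lo,
    or_hi = or$hi,
    n_excluded = sum(!known)
  )
}

#' Configure an end-to-end pipeline run
#'
#' @param sim A [sim_config()] describing the synthetic dataset (or `NULL`
#'   when `encounters` are supplied directly to [run_pipeline()]).
#' @param codeset_path Optional path to a codeset JSON (default: packaged
#'   suicidality definition).
#' @param dsm5_path Optional path to a DSM-5 mapping JSON (default:
#'   packaged mapping).
#' @param min_patients,top_k,alpha Comorbidity-screen settings.
#' @param k,caliper Matching settings.
#' @param seed Seed recorded in the manifest (the simulation seed comes
#'   from `sim`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            codeset_path = NULL,
                            dsm5_path = NULL,
                            min_patients = 20L,
                            top_k = 20L,
                            alpha = 0.05,
                            k = 1L,
                            caliper = NULL,
                            seed = 1L) {
  structure(
    list(
      sim = sim, codeset_path = codeset_path, dsm5_path = dsm5_path,
      min_patients = min_patients, top_k = top_k, alpha = alpha,
      k = k, caliper = caliper, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline failed at stage [", name, "]: ",
                 conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' simulate → label cases → comorbidity screen → featurize → fit + match →
#' evaluate. When `out_dir` is given, every intermediate artifact is
#' written as CSV plus a JSON manifest (config, seed, package and R
#' versions, declared matching assumptions) sufficient for an exact rerun.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List (invisible when writing): `dataset`, `labels`, `scan`,
#'   `significant`, `features`, `fit`, `pairs`, `balance`, `scores`,
#'   `cohort`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cs <- stage("define-cases", {
    if (is.null(config$codeset_path)) {
      default_suicidality_codeset()
    } else {
      read_codeset(config$codeset_path)
    }
  })
  mapping <- stage("define-cases", read_dsm5_mapping(config$dsm5_path))

  dataset <- stage("simulate", simulate_ehr(config$sim))
  encounters <- dataset$encounters

  labels <- stage("define-cases", label_patients(encounters, cs))
  cohort <- stage("define-cases", summarize_cohort(encounters, cs))

  scan <- stage("comorbidity", comorbidity_scan_grid(
    encounters, labels, cs,
    min_patients = config$min_patients, top_k = config$top_k,
    alpha = config$alpha
  ))
  sig <- stage("comorbidity", significant_union(scan))
  dsm5 <- stage("comorbidity",
                suppressMessages(dsm5_category_stats(encounters, labels,
                                                     mapping)))

  fm <- stage("featurize", suppressMessages(assemble_features(
    encounters, labels, cs, mapping, significant_codes = sig$code
  )))
  fit <- stage("match", fit_propensity(fm))
  pairs <- stage("match", match_nearest(fit, k = config$k,
                                        caliper = config$caliper))
  balance <- stage("evaluate", balance_report(fm, pairs))
  scores <- stage("evaluate", score_distribution(fit, pairs))

  truth <- dataset$patients %>%
    select("patient_id", "latent_suicidality")
  reference <- truth %>%
    anti_join(filter(labels, .data$is_case), by = "patient_id")
  enrichment <- stage("evaluate",
                      enrichment_report(pairs, truth, reference))

  manifest <- list(
    package = "phenomatch",
    package_version = as.character(utils::packageVersion("phenomatch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    sim_seed = config$sim$seed,
    n_patients = config$sim$n_patients,
    screen = list(
      min_patients = config$min_patients, top_k = config$top_k,
      alpha = config$alpha,
      bonferroni_family = attr(scan, "m_family")
    ),
    matching = list(
      k = config$k,
      caliper = config$caliper,
      replacement = FALSE,
      case_order = "descending logit",
      regularization = "l2(1e-6)"
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(
    dataset = dataset, labels = labels, scan = scan, significant = sig,
    dsm5 = dsm5, features = fm, fit = fit, pairs = pairs,
    balance = balance, scores = scores, cohort = cohort,
    enrichment = enrichment, manifest = manifest
  )

  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir))
    write_ehr_dataset(dataset, out_dir, format = "csv")
    wr <- function(df, name) {
      write.csv(flatten_lists(df), file.path(out_dir, name),
                row.names = FALSE)
    }
    wr(labels, "labels.csv")
    wr(as_tibble(scan), "comorbidity_scan.csv")
    wr(sig, "significant_codes.csv")
    wr(as_tibble(dsm5), "dsm5_stats.csv")
    wr(as_tibble(pairs), "matched_pairs.csv")
    wr(as_tibble(balance), "balance.csv")
    wr(scores$fractions, "score_fractions.csv")
    wr(scores$histogram, "score_histogram.csv")
    wr(as_tibble(cohort), "cohort_table.csv")
    wr(enrichment, "enrichment.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    return(invisible(result))
  }
  result
}

flatten_lists <- function(df) {
  df <- as_tibble(df)
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], paste, "", collapse = ";")
    }
  }
  df
}
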
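#' Log-odds transform
#'
#' `logit(p) = ln(p / (1 - p))`. Matching distances are measured on the
#' logit scale, where propensity scores near 0 and 1 are spread out.
#'
#' @param p Probabilities strictly inside (0, 1).
#' @return Log-odds, vectorized.
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    abort("`logit` requires 0 < p < 1.")
  }
  log(p / (1 - p))
}

#' Fit the propensity model
#'
#' Logistic regression of the case label on the feature matrix, fit by
#' iteratively reweighted least squares. The default adds a tiny ridge
#' penalty (`l2`, lambda = 1e-6, intercept unpenalized) that leaves the
#' estimates at the maximum-likelihood solution for practical purposes
#' while keeping the fit finite when one-hot EHR covariates produce
#' near-separation. `regularization = "none"` gives the exact MLE and
#' raises an explicit error when perfect separation makes it diverge.
#' Zero-variance columns get coefficient 0 and are excluded from the
#' normal equations.
#'
#' @param fm A [assemble_features()] `"feature_matrix"` with at least one
#'   case and one comparator.
#' @param regularization `"l2"` (default) or `"none"`.
#' @param lambda Ridge penalty for `"l2"`.
#' @param max_iter IRLS iteration cap.
#' @param tol Relative change in penalized log-likelihood declaring
#'   convergence.
#' @return Object of class `"propensity_fit"`: `coefficients` (named,
#'   including `(Intercept)`), `scores`, `logits` (aligned with
#'   `fm$units`), `units`, `converged`, `n_iter`, `loglik`, `lambda`.
#' @export
fit_propensity <- function(fm, regularization = c("l2", "none"),
                           lambda = 1e-6, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"))
  regularization <- match.arg(regularization)
  if (regularization == "none") lambda <- 0
  y <- fm$units$label
  if (length(unique(y)) < 2) {
    abort("Need at least one case and one comparator to fit.")
  }

  keep <- apply(fm$x, 2, function(v) length(unique(v)) > 1)
  xk <- fm$x[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, xk)
  p_all <- ncol(X)
  pen <- c(0, rep(lambda, p_all - 1))  # intercept unpenalized

  beta <- rep(0, p_all)
  beta[1] <- qlogis(max(min(mean(y), 1 - 1e-12), 1e-12))
  pen_ll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * w, X) + diag(pen, p_all)
    b <- crossprod(X * w, z)
    beta_new <- tryCatch(
      as.vector(solve(A, b)),
      error = function(e) {
        abort(paste0(
          "Propensity fit failed (singular system): ",
          conditionMessage(e)
        ))
      }
    )
    if (lambda == 0 && max(abs(beta_new)) > 30) {
      abort(paste0(
        "Perfect separation suspected (coefficients diverging). ",
        "Refit with regularization = \"l2\"."
      ))
    }
    ll_new <- pen_ll(beta_new)
    # step-halving keeps IRLS monotone near saturation
    step <- 1
    while (ll_new < ll_old - 1e-12 && step > 1e-4) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      ll_new <- pen_ll(beta_new)
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }

  coefs <- setNames(rep(0, ncol(fm$x) + 1),
                    c("(Intercept)", colnames(fm$x)))
  coefs[colnames(X)] <- beta
  eta <- as.vector(X %*% beta)
  scores <- plogis(eta)
  structure(
    list(
      coefficients = coefs,
      scores = scores,
      logits = eta,
      units = fm$units,
      converged = converged,
      n_iter = n_iter,
      loglik = ll_old + sum(pen * beta^2) / 2,
      lambda = lambda,
      feature_names = fm$feature_names
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> ", length(x$scores), " units, ",
      length(x$coefficients) - 1, " features",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  mean score, cases: ",
      sprintf("%.3f", mean(x$scores[x$units$label == 1])),
      "; comparators: ",
      sprintf("%.3f", mean(x$scores[x$units$label == 0])), "\n", sep = "")
  invisible(x)
}

#' @method tidy propensity_fit
#' @export
tidy.propensity_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance propensity_fit
#' @export
glance.propensity_fit <- function(x, ...) {
  tibble(
    n_units = length(x$scores),
    n_cases = sum(x$units$label == 1),
    logLik = x$loglik,
    converged = x$converged,
    n_iter = x$n_iter,
    lambda = x$lambda
  )
}

#' Greedy nearest-neighbour matching in logit space
#'
#' Cases are processed in descending logit order (hardest-to-match first, a
#' documented deterministic convention); each is matched to its `k` nearest
#' not-yet-used comparators by absolute logit difference. Distance ties are
#' broken by comparator encounter id. With a caliper, pairs beyond the
#' threshold are dropped and the case recorded as unmatched.
#'
#' @param fit A [fit_propensity()] result.
#' @param k Comparators per case (default 1).
#' @param caliper Maximum allowed |logit difference|, or `NULL` (default:
#'   no caliper).
#' @param replacement Allow a comparator to serve several cases. Default
#'   `FALSE`.
#' @param seed Unused (the algorithm is deterministic); accepted so run
#'   manifests can carry a uniform seed argument.
#' @return Object of class `"matched_pairs"`: tibble with
#'   `case_encounter_id`, `case_patient_id`, `comparator_encounter_id`,
#'   `comparator_patient_id`, `distance`; attributes `unmatched_cases`,
#'   `caliper`, `k`, `replacement`.
#' @export
match_nearest <- function(fit, k = 1L, caliper = NULL,
                          replacement = FALSE, seed = NULL) {
  stopifnot(inherits(fit, "propensity_fit"))
  if (k < 1) abort("`k` must be >= 1.")
  if (!is.null(caliper) && caliper < 0) {
    abort("`caliper` must be nonnegative.")
  }

  is_case <- fit$units$label == 1
  cases <- tibble(
    encounter_id = fit$units$encounter_id[is_case],
    patient_id = fit$units$patient_id[is_case],
    logit = fit$logits[is_case]
  ) %>% arrange(desc(.data$logit), .data$encounter_id)
  comps <- tibble(
    encounter_id = fit$units$encounter_id[!is_case],
    patient_id = fit$units$patient_id[!is_case],
    logit = fit$logits[!is_case]
  ) %>% arrange(.data$logit, .data$encounter_id)

  nc <- nrow(comps)
  alive <- rep(TRUE, nc)
  # Runs of exactly equal logits (identical covariate profiles are common
  # in EHR one-hots). Within a run, ids ascend; a per-run pointer to the
  # first alive member makes "smallest id at minimal distance" O(1).
  run_id <- cumsum(c(TRUE, diff(comps$logit) != 0))
  run_first <- match(unique(run_id), run_id)
  run_ptr <- run_first

  first_alive_in_run <- function(r) {
    p <- if (replacement) run_first[r] else run_ptr[r]
    last <- if (r < length(run_first)) run_first[r + 1L] - 1L else nc
    while (p <= last && !alive[p]) p <- p + 1L
    if (!replacement) run_ptr[r] <<- p
    if (p <= last) p else 0L
  }

  pairs <- vector("list", nrow(cases))
  unmatched <- character(0)

  for (i in seq_len(nrow(cases))) {
    target <- cases$logit[i]
    pos <- findInterval(target, comps$logit)
    consumed <- integer(0)
    for (pick in seq_len(k)) {
      lo <- pos
      hi <- pos + 1L
      while (lo >= 1L && !alive[lo]) lo <- lo - 1L
      while (hi <= nc && !alive[hi]) hi <- hi + 1L
      if (lo < 1L && hi > nc) break
      d_lo <- if (lo >= 1L) abs(comps$logit[lo] - target) else Inf
      d_hi <- if (hi <= nc) abs(comps$logit[hi] - target) else Inf
      cand <- integer(0)
      if (d_lo <= d_hi) cand <- c(cand, first_alive_in_run(run_id[lo]))
      if (d_hi <= d_lo) cand <- c(cand, first_alive_in_run(run_id[hi]))
      cand <- cand[cand > 0L]
      chosen <- cand[order(comps$encounter_id[cand])][1]
      if (!is.null(caliper) &&
          abs(comps$logit[chosen] - target) > caliper) {
        break  # nearest already beyond the caliper; so is everything else
      }
      alive[chosen] <- FALSE
      consumed <- c(consumed, chosen)
    }
    if (replacement) alive[consumed] <- TRUE
    if (length(consumed) == 0) {
      unmatched <- c(unmatched, cases$encounter_id[i])
      next
    }
    pairs[[i]] <- tibble(
      case_encounter_id = cases$encounter_id[i],
      case_patient_id = cases$patient_id[i],
      comparator_encounter_id = comps$encounter_id[consumed],
      comparator_patient_id = comps$patient_id[consumed],
      distance = abs(comps$logit[consumed] - target)
    )
  }
  out <- bind_rows(pairs)
  if (nrow(out) == 0) {
    out <- tibble(
      case_encounter_id = character(0), case_patient_id = character(0),
      comparator_encounter_id = character(0),
      comparator_patient_id = character(0), distance = numeric(0)
    )
  }
  if (!replacement && anyDuplicated(out$comparator_encounter_id) > 0) {
    abort("Internal error: comparator reused without replacement.")
  }
  structure(
    out,
    class = c("matched_pairs", class(out)),
    unmatched_cases = unmatched,
    caliper = caliper,
    k = k,
    replacement = replacement
  )
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference (SMD) per feature:
#' (mean cases − mean comparators) / pooled SD, with pooled SD
#' \eqn{\sqrt{(s^2_1 + s^2_0)/2}}. A zero pooled SD gives SMD 0 when the
#' means agree and `Inf` (flagged) otherwise. "Before" uses all units;
#' "after" uses the matched case and comparator units. |SMD| < 0.1 is the
#' conventional balance threshold.
#'
#' @param fm The [assemble_features()] matrix the model was fit on.
#' @param pairs A [match_nearest()] result.
#' @return Tibble of class `"balance_report"`: `feature`, `smd_before`,
#'   `smd_after`; attribute `summary` holds max/mean absolute SMDs.
#' @export
balance_report <- function(fm, pairs) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(pairs, "matched_pairs"))
  if (nrow(pairs) == 0) abort("`pairs` contains no matched pairs.")
  smd <- function(x1, x0) {
    s <- sqrt((var(x1) + var(x0)) / 2)
    d <- mean(x1) - mean(x0)
    if (is.na(s) || s == 0) {
      if (abs(d) < 1e-12) 0 else Inf
    } else {
      d / s
    }
  }
  lab <- fm$units$label
  before <- apply(fm$x, 2, function(v) smd(v[lab == 1], v[lab == 0]))
  case_rows <- fm$units$encounter_id %in% pairs$case_encounter_id
  comp_rows <- fm$units$encounter_id %in% pairs$comparator_encounter_id
  after <- apply(fm$x, 2, function(v) smd(v[case_rows], v[comp_rows]))
  out <- tibble(
    feature = colnames(fm$x),
    smd_before = unname(before),
    smd_after = unname(after)
  )
  finite <- function(v) v[is.finite(v)]
  structure(
    out,
    class = c("balance_report", class(out)),
    summary = c(
      max_abs_before = max(abs(finite(out$smd_before))),
      mean_abs_before = mean(abs(finite(out$smd_before))),
      max_abs_after = max(abs(finite(out$smd_after))),
      mean_abs_after = mean(abs(finite(out$smd_after)))
    )
  )
}

#' Score distributions and threshold fractions
#'
#' Bins propensity scores on \[0, 1\] per group (cases vs comparators),
#' before matching (all units) and — when `pairs` is supplied — after
#' (matched units only), and reports the fraction of each group at or
#' above / below each threshold. The defaults (0.9 and 0.5) summarize how
#' concentrated cases are at high scores and how far matching pulls the
#' comparator mass up from low scores.
#'
#' @param fit A [fit_propensity()] result.
#' @param pairs Optional [match_nearest()] result.
#' @param bin_width Histogram bin width (default 0.05).
#' @param thresholds Numeric thresholds (default `c(0.5, 0.9)`).
#' @return Object of class `"score_distribution"`: list with `histogram`
#'   (`phase`, `group`, `bin_lo`, `bin_hi`, `count`) and `fractions`
#'   (`phase`, `group`, `threshold`, `frac_ge`, `frac_lt`).
#' @export
score_distribution <- function(fit, pairs = NULL, bin_width = 0.05,
                               thresholds = c(0.5, 0.9)) {
  stopifnot(inherits(fit, "propensity_fit"))
  if (bin_width <= 0 || bin_width > 1) {
    abort("`bin_width` must lie in (0, 1].")
  }
  breaks <- unique(c(seq(0, 1, by = bin_width), 1))
  one_group <- function(scores, phase, group) {
    bins <- cut(scores, breaks = breaks, include.lowest = TRUE,
                right = FALSE)
    hist <- tibble(
      phase = phase, group = group,
      bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
      count = as.integer(table(bins))
    )
    fr <- tibble(
      phase = phase, group = group, threshold = thresholds,
      frac_ge = vapply(thresholds, function(t) mean(scores >= t),
                       numeric(1)),
      frac_lt = vapply(thresholds, function(t) mean(scores < t),
                       numeric(1))
    )
    list(hist = hist, fr = fr)
  }
  lab <- fit$units$label
  parts <- list(
    one_group(fit$scores[lab == 1], "before", "case"),
    one_group(fit$scores[lab == 0], "before", "comparator")
  )
  if (!is.null(pairs)) {
    stopifnot(inherits(pairs, "matched_pairs"))
    case_rows <- fit$units$encounter_id %in% pairs$case_encounter_id
    comp_rows <- fit$units$encounter_id %in% pairs$comparator_encounter_id
    parts <- c(parts, list(
      one_group(fit$scores[case_rows], "after", "case"),
      one_group(fit$scores[comp_rows], "after", "comparator")
    ))
  }
  structure(
    list(
      histogram = bind_rows(lapply(parts, `[[`, "hist")),
      fractions = bind_rows(lapply(parts, `[[`, "fr"))
    ),
    class = "score_distribution"
  )
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("<score_distribution>\n")
  print(x$fractions)
  invisible(x)
}

#' Plot a score distribution
#'
#' Mirrored histograms of propensity scores per group, faceted by phase
#' (before/after matching) when matched units are present.
#'
#' @param object A [score_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot score_distribution
#' @export
autoplot.score_distribution <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(
    x = .data$bin_lo + (.data$bin_hi - .data$bin_lo) / 2,
    y = .data$count, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge", width = 0.045) +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "propensity score", y = "units", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot covariate balance (love plot)
#'
#' @param object A [balance_report()].
#' @param threshold Reference |SMD| line (default 0.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot balance_report
#' @export
autoplot.balance_report <- function(object, threshold = 0.1, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("smd_before", "smd_after"),
    names_to = "phase", values_to = "smd", names_prefix = "smd_"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = abs(.data$smd), y = .data$feature, colour = .data$phase
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
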
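## Study orchestration: derived variables, descriptive table, staged
## association tables, tiered mediation models, and sensitivity analyses,
## assembled into a reproducible structured report.

#' Dichotomize a score at a cut point
#'
#' Returns 1 where \code{score >= cutpoint}, 0 below; missing values
#' propagate.  Used to derive the binary high-conduct-problems exposure
#' (symptom score of four or more) and hazardous-drinking outcome
#' (alcohol-screening score of eight or more).
#'
#' @param score numeric vector.
#' @param cutpoint threshold (at-or-above codes 1).
#' @param range optional declared \code{c(min, max)} of the score; a cut
#'   point outside it is a configuration error.
#' @return integer 0/1 vector with \code{NA}s preserved.
#' @export
dichotomize <- function(score, cutpoint, range = NULL) {
  if (!is.null(range) && (cutpoint < range[1] || cutpoint > range[2]))
    stop("cut point ", cutpoint, " lies outside the declared range [",
         range[1], ", ", range[2], "]")
  as.integer(score >= cutpoint)
}

#' Descriptive statistics table
#'
#' Per analysis column: percentage with a Wald (or Wilson) confidence
#' interval for binary variables, mean with a normal interval for numeric
#' ones, computed on observed cells with the n used reported.  A
#' degenerate flag marks all-0/all-1 binary columns whose Wald interval
#' collapses.
#'
#' @param cohort data frame.
#' @param roles a \code{\link{cohort_roles}} object.
#' @param conf confidence level.
#' @param method \code{"wald"} (default) or \code{"wilson"} for binary
#'   proportions.
#' @return a data frame: variable, role, measure, n, estimate, lower,
#'   upper, degenerate.
#' @export
descriptive_table <- function(cohort, roles, conf = 0.95,
                              method = c("wald", "wilson")) {
  method <- match.arg(method)
  check_roles(cohort, roles)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(role_vars(roles), function(nm) {
    x <- cohort[[nm]][!is.na(cohort[[nm]])]
    n <- length(x)
    if (is_binary_col(cohort[[nm]])) {
      p <- mean(x)
      if (method == "wald") {
        half <- z * sqrt(p * (1 - p) / n)
        lo <- p - half; hi <- p + half
      } else {
        den <- 1 + z^2 / n
        ctr <- (p + z^2 / (2 * n)) / den
        half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
        lo <- ctr - half; hi <- ctr + half
      }
      data.frame(variable = nm, role = role_of(roles, nm),
                 measure = "percent", n = n, estimate = 100 * p,
                 lower = 100 * max(lo, 0), upper = 100 * min(hi, 1),
                 degenerate = p %in% c(0, 1), stringsAsFactors = FALSE)
    } else {
      mu <- mean(x); se <- stats::sd(x) / sqrt(n)
      data.frame(variable = nm, role = role_of(roles, nm),
                 measure = "mean", n = n, estimate = mu,
                 lower = mu - z * se, upper = mu + z * se,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Build a study configuration
#'
#' Collects everything \code{\link{run_study}} needs: the cohort and its
#' role map, the comorbidity confounders that enter only the widest
#' adjustment tier, the mediation settings, and which sections to run.
#' The three built-in tiers mirror staged confounder adjustment:
#' unadjusted; baseline + intermediate confounders; additionally adjusted
#' for comorbidity.
#'
#' @param cohort data frame.
#' @param roles a \code{\link{cohort_roles}} object.
#' @param outcomes binary outcomes to mediate (default: all binary
#'   outcome columns).
#' @param numeric_outcomes numeric outcomes for the dimensional
#'   sensitivity analysis (default: all numeric outcome columns).
#' @param comorbidity list with elements \code{baseline} and
#'   \code{intermediate} naming the comorbidity confounders.
#' @param single_mediator mediator for the single-mediator sensitivity
#'   analysis (default: the last, temporally latest, mediator).
#' @param copies,B,m,iterations,seed mediation and imputation settings.
#' @param include named logical vector switching report sections.
#' @param strict escalate bootstrap failure warnings to errors.
#' @return a \code{study_config} list.
#' @export
study_config <- function(cohort, roles, outcomes = NULL,
                         numeric_outcomes = NULL,
                         comorbidity = list(baseline = character(),
                                            intermediate = character()),
                         single_mediator = NULL,
                         copies = 100, B = 50, m = 40, iterations = 10,
                         seed = 1L,
                         include = c(descriptive = TRUE, associations = TRUE,
                                     mediation = TRUE, single_mediator = TRUE,
                                     complete_case = TRUE,
                                     numeric_outcomes = TRUE),
                         strict = FALSE) {
  check_roles(cohort, roles)
  binary_out <- roles$outcomes[vapply(roles$outcomes, function(nm)
    is_binary_col(cohort[[nm]]), logical(1))]
  if (is.null(outcomes)) outcomes <- binary_out
  if (is.null(numeric_outcomes))
    numeric_outcomes <- setdiff(roles$outcomes, binary_out)
  if (!all(outcomes %in% roles$outcomes))
    stop("outcomes must be declared outcome columns")
  if (!all(comorbidity$baseline %in% roles$baseline) ||
      !all(comorbidity$intermediate %in% roles$intermediate))
    stop("comorbidity variables must be declared confounders")
  if (is.null(single_mediator))
    single_mediator <- roles$mediators[length(roles$mediators)]
  defaults <- c(descriptive = TRUE, associations = TRUE, mediation = TRUE,
                single_mediator = TRUE, complete_case = TRUE,
                numeric_outcomes = TRUE)
  defaults[names(include)] <- include
  structure(list(cohort = cohort, roles = roles, outcomes = outcomes,
                 numeric_outcomes = numeric_outcomes,
                 comorbidity = comorbidity, single_mediator = single_mediator,
                 copies = copies, B = B, m = m, iterations = iterations,
                 seed = seed, include = defaults, strict = strict),
            class = "study_config")
}

## the three built-in adjustment tiers
study_tiers <- function(roles, comorbidity) {
  list(
    unadjusted = list(baseline = character(), intermediate = character()),
    adjusted = list(baseline = setdiff(roles$baseline, comorbidity$baseline),
                    intermediate = setdiff(roles$intermediate,
                                           comorbidity$intermediate)),
    comorbidity = list(baseline = roles$baseline,
                       intermediate = roles$intermediate)
  )
}

skipped <- function(reason) list(skipped = TRUE, reason = reason)

#' Run the full study pipeline
#'
#' Executes, in order: the descriptive table; staged exposure-mediator
#' associations (unadjusted, baseline-adjusted, additionally adjusted for
#' the baseline comorbidity confounder); staged mediator-outcome
#' associations (unadjusted; exposure + baseline + intermediate
#' confounders; additionally comorbidity; additionally all mediators);
#' tiered three-mediator g-formula mediation per outcome; and the
#' sensitivity analyses (single-mediator model, complete-case versus
#' imputed comparison, numeric dimensional outcomes).  When the cohort
#' has missing cells and \code{m >= 2}, associations and mediation are
#' pooled across chained-equation imputations by Rubin's rules; otherwise
#' they run on the (complete) cohort directly.  All randomness derives
#' from the configuration seed, so a rerun reproduces the report exactly.
#'
#' @param config a \code{\link{study_config}} object.
#' @return an object of class \code{study_report}; sections not requested
#'   (or not runnable) are marked skipped with a reason.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- config$cohort
  roles <- config$roles
  inc <- config$include
  tiers <- study_tiers(roles, config$comorbidity)
  analysis_vars <- role_vars(roles)
  has_missing <- anyNA(cohort[analysis_vars])
  use_imputation <- has_missing && config$m >= 2
  report <- list()

  imp <- NULL
  if (use_imputation)
    imp <- impute_chained(cohort, m = config$m,
                          iterations = config$iterations,
                          seed = derive_seed(config$seed, 777L))

  report$descriptive <- if (!inc[["descriptive"]]) skipped("not requested")
    else descriptive_table(cohort, roles)

  if (inc[["associations"]]) {
    em_pairs <- data.frame(predictor = roles$exposure,
                           outcome = roles$mediators,
                           stringsAsFactors = FALSE)
    em_stages <- list(
      unadjusted = character(),
      baseline = tiers$adjusted$baseline,
      baseline_comorbidity = c(tiers$adjusted$baseline,
                               config$comorbidity$baseline))
    mo_pairs <- expand.grid(predictor = roles$mediators,
                            outcome = config$outcomes,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mo_stages <- mediator_outcome_stages(roles, tiers, config$comorbidity)
    report$exposure_mediator <-
      staged_associations(cohort, imp, em_pairs, em_stages)
    report$mediator_outcome <-
      staged_associations(cohort, imp, mo_pairs, mo_stages)
  } else {
    report$exposure_mediator <- skipped("not requested")
    report$mediator_outcome <- skipped("not requested")
  }

  report$mediation <- if (!inc[["mediation"]]) skipped("not requested")
    else mediation_section(cohort, imp, roles, config$outcomes, tiers, config)

  report$sensitivity <- list(
    single_mediator = if (!inc[["single_mediator"]]) skipped("not requested")
      else single_mediator_section(cohort, imp, roles, config, tiers),
    complete_case = if (!inc[["complete_case"]]) skipped("not requested")
      else if (!has_missing) skipped("no missing cells in the cohort")
      else complete_case_section(cohort, imp, roles, config, tiers),
    numeric_outcomes = if (!inc[["numeric_outcomes"]]) skipped("not requested")
      else if (!length(config$numeric_outcomes))
        skipped("no numeric outcomes declared")
      else mediation_section(cohort, imp, roles, config$numeric_outcomes,
                             tiers[c("adjusted", "comorbidity")], config)
  )

  report$meta <- list(
    seed = config$seed, n = nrow(cohort),
    n_complete = sum(stats::complete.cases(cohort[analysis_vars])),
    imputed = use_imputation, m = if (use_imputation) config$m else 0L,
    copies = config$copies, B = config$B,
    mediator_order = roles$mediators,
    package_version = as.character(utils::packageVersion("gcmediate")))
  structure(report, class = "study_report")
}

mediator_outcome_stages <- function(roles, tiers, comorbidity) {
  base_adj <- c(roles$exposure, tiers$adjusted$baseline,
                tiers$adjusted$intermediate)
  list(
    unadjusted = character(),
    adjusted = base_adj,
    comorbidity = c(base_adj, comorbidity$baseline, comorbidity$intermediate),
    all_mediators = c(base_adj, comorbidity$baseline,
                      comorbidity$intermediate, roles$mediators))
}

## association table, Rubin-pooled over imputations when present
staged_associations <- function(cohort, imp, pairs, stages) {
  if (is.null(imp)) return(association_table(cohort, pairs, stages))
  tabs <- lapply(imp$completed, association_table, pairs = pairs,
                 stages = stages)
  out <- tabs[[1L]]
  for (i in seq_len(nrow(out))) {
    ests <- vapply(tabs, function(t) t$estimate[i], numeric(1))
    los <- vapply(tabs, function(t) t$lower[i], numeric(1))
    if (anyNA(ests)) { out$note[i] <- "failed in >=1 imputation"; next }
    ## binary outcomes pool on the log-odds scale, numeric on the identity
    binary_out <- is_binary_col(cohort[[out$outcome[i]]])
    pts <- if (binary_out) log(ests) else ests
    ses <- if (binary_out) (log(ests) - log(los)) / 1.96
           else (ests - los) / 1.96
    pr <- pool_rubin(pts, ses)
    z <- pr$estimate / pr$se
    out$estimate[i] <- if (binary_out) exp(pr$estimate) else pr$estimate
    out$lower[i] <- if (binary_out) exp(pr$lower) else pr$lower
    out$upper[i] <- if (binary_out) exp(pr$upper) else pr$upper
    out$p[i] <- 2 * stats::pnorm(-abs(z))
    out$p_formatted[i] <- format_p(out$p[i])
    out$note[i] <- sprintf("rubin-pooled over m=%d imputations", imp$m)
  }
  out
}

mediation_row <- function(est, outcome, tier) {
  ci <- est$ci
  data.frame(outcome = outcome, tier = tier, effect = ci$effect,
             estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
             pm = ifelse(ci$effect == "NIE", est$pm, NA_real_),
             scale = est$scale, stringsAsFactors = FALSE)
}

mediation_section <- function(cohort, imp, roles, outcomes, tiers, config) {
  rows <- list()
  for (out in outcomes) {
    for (tn in names(tiers)) {
      tier <- tiers[[tn]]
      est <- tryCatch({
        if (!is.null(imp))
          pooled_mediation(cohort, roles, out, m = config$m, B = config$B,
                           copies = config$copies,
                           iterations = config$iterations,
                           seed = derive_seed(config$seed, 31L),
                           baseline = tier$baseline,
                           intermediate = tier$intermediate,
                           strict = config$strict,
                           imputations = imp)
        else
          bootstrap_effects(cohort, roles, out, B = config$B,
                            copies = config$copies,
                            seed = derive_seed(config$seed, 31L),
                            baseline = tier$baseline,
                            intermediate = tier$intermediate,
                            strict = config$strict)
      }, error = function(e) e)
      rows[[paste(out, tn)]] <- if (inherits(est, "error"))
        data.frame(outcome = out, tier = tn, effect = NA_character_,
                   estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                   pm = NA_real_, scale = conditionMessage(est),
                   stringsAsFactors = FALSE)
      else mediation_row(est, out, tn)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

single_mediator_section <- function(cohort, imp, roles, config, tiers) {
  tier <- tiers$adjusted
  data <- if (!is.null(imp)) imp$completed[[1L]] else cohort
  note <- if (!is.null(imp)) "first completed data set" else "analysis cohort"
  rows <- lapply(config$outcomes, function(out) {
    est <- single_mediator_effects(data, roles, out, config$single_mediator,
                                   copies = config$copies, B = config$B,
                                   seed = derive_seed(config$seed, 41L),
                                   baseline = tier$baseline,
                                   intermediate = tier$intermediate,
                                   strict = config$strict)
    mediation_row(est, out, "adjusted")
  })
  list(primary_mediator = config$single_mediator, data = note,
       table = do.call(rbind, rows))
}

complete_case_section <- function(cohort, imp, roles, config, tiers) {
  tier <- tiers$adjusted
  lapply(stats::setNames(nm = config$outcomes), function(out) {
    tryCatch(
      complete_case_comparison(cohort, roles, out, m = config$m,
                               B = config$B, copies = config$copies,
                               iterations = config$iterations,
                               seed = derive_seed(config$seed, 51L),
                               baseline = tier$baseline,
                               intermediate = tier$intermediate,
                               imputations = imp),
      error = function(e) skipped(conditionMessage(e)))
  })
}

#' Complete-case versus imputed-data comparison
#'
#' Reruns the mediation analysis on the listwise-complete rows and on
#' Rubin-pooled chained-equation imputations of the full cohort, giving
#' side-by-side estimates and sample sizes.  With no missing cells the
#' two arms are identical by construction.  Refuses to run the
#' complete-case arm when the complete-case n is below ten times the
#' largest model's coefficient count.
#'
#' @inheritParams pooled_mediation
#' @param imputations optional pre-computed \code{imputation_set} reused
#'   for the imputed arm.
#' @return a list: \code{complete_case} and \code{imputed}
#'   \code{mediation_estimates}, plus \code{n_complete} and \code{n}.
#' @export
complete_case_comparison <- function(cohort, roles, outcome, m = 40, B = 50,
                                     copies = 100, iterations = 10, seed = 1L,
                                     baseline = roles$baseline,
                                     intermediate = roles$intermediate,
                                     imputations = NULL) {
  vars <- c(roles$exposure, baseline, intermediate, roles$mediators, outcome)
  cc <- stats::complete.cases(cohort[vars])
  n_cc <- sum(cc)
  n_par <- 2L + length(baseline) + length(intermediate) +
    length(roles$mediators)
  if (n_cc < 10L * n_par)
    stop("complete-case n (", n_cc, ") below 10 x coefficient count (",
         10L * n_par, "); refusing the complete-case analysis")
  cc_est <- bootstrap_effects(cohort[cc, , drop = FALSE], roles, outcome,
                              B = B, copies = copies,
                              seed = derive_seed(seed, 1L),
                              baseline = baseline,
                              intermediate = intermediate)
  imp_est <- if (!anyNA(cohort[vars])) cc_est
    else pooled_mediation(cohort, roles, outcome, m = m, B = B,
                          copies = copies, iterations = iterations,
                          seed = derive_seed(seed, 2L),
                          baseline = baseline, intermediate = intermediate,
                          imputations = imputations)
  list(complete_case = cc_est, imputed = imp_est, n_complete = n_cc,
       n = nrow(cohort))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  secs <- setdiff(names(x), "meta")
  for (s in secs) {
    v <- x[[s]]
    status <- if (is.list(v) && isTRUE(v$skipped))
      paste0("skipped (", v$reason, ")") else "present"
    cat(sprintf("  %-18s %s\n", s, status))
  }
  cat(sprintf("  n = %d (complete %d), seed = %s\n", x$meta$n,
              x$meta$n_complete, format(x$meta$seed)))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits \code{report.json} (full machine-readable report) plus CSV
#' tables for the descriptive, association and mediation sections.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  jsonpath <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_report(report), jsonpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, jsonpath)
  tabs <- list(table1 = report$descriptive,
               exposure_mediator = report$exposure_mediator,
               mediator_outcome = report$mediator_outcome,
               mediation = report$mediation)
  for (nm in names(tabs)) {
    if (is.data.frame(tabs[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

unclass_report <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_report))
  x
}
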
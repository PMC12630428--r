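#' gcmediate: counterfactual mediation by parametric g-computation
#'
#' Tools to estimate total, natural direct, and natural indirect effects of
#' a binary exposure through a block of mediators with baseline and
#' intermediate confounders, via the parametric g-formula with Monte Carlo
#' counterfactual simulation, an exact enumeration oracle, bootstrap
#' confidence intervals, chained-equations multiple imputation with Rubin
#' pooling, and a calibrated synthetic birth-cohort generator.
#'
#' @keywords internal
#' @aliases gcmediate-package
"_PACKAGE"

## ---- seed streams -----------------------------------------------------

## One root seed; deterministic per-task substreams.  Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

logit <- stats::qlogis
## hot path in simulation; marginally less careful than plogis at the
## extremes but exact where probabilities are representable
expit <- function(x) 1 / (1 + exp(-x))

odds <- function(p) p / (1 - p)

or_from_p <- function(p1, p0) odds(p1) / odds(p0)

## ---- variable roles ---------------------------------------------------

#' Declare the analysis roles of cohort columns
#'
#' A role map ties each analysis column to one of the five roles the
#' mediation machinery recognises: baseline confounder, exposure,
#' intermediate (exposure-induced) confounder, mediator, or outcome.
#' Mediators are ordered; the order is the sequential simulation order.
#'
#' @param exposure name of the binary exposure column.
#' @param baseline character vector of baseline confounder columns.
#' @param intermediate character vector of intermediate confounder columns
#'   (post-exposure variables that confound mediator-outcome paths), in
#'   generation order.
#' @param mediators character vector of mediator columns in temporal order.
#' @param outcomes character vector of outcome columns.
#' @return an object of class \code{cohort_roles} (a named list).
#' @export
cohort_roles <- function(exposure, baseline = character(), intermediate = character(),
                         mediators, outcomes) {
  stopifnot(length(exposure) == 1L, length(mediators) >= 1L, length(outcomes) >= 1L)
  all_vars <- c(exposure, baseline, intermediate, mediators, outcomes)
  if (anyDuplicated(all_vars))
    stop("each column may carry exactly one role; duplicated: ",
         paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  structure(list(exposure = exposure, baseline = baseline,
                 intermediate = intermediate, mediators = mediators,
                 outcomes = outcomes),
            class = "cohort_roles")
}

role_vars <- function(roles, outcome = NULL) {
  c(roles$exposure, roles$baseline, roles$intermediate, roles$mediators,
    if (is.null(outcome)) roles$outcomes else outcome)
}

check_roles <- function(cohort, roles, outcome = NULL) {
  vars <- role_vars(roles, outcome)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns required by the role map: ",
         paste(missing_cols, collapse = ", "))
  invisible(vars)
}

is_binary_col <- function(x) {
  v <- unique(x[!is.na(x)])
  length(v) <= 2L && all(v %in% c(0, 1))
}

## ---- cohort i/o -------------------------------------------------------

#' Write a cohort to CSV with a JSON role side-car
#'
#' Missing cells are written as empty fields.  The side-car (same prefix,
#' extension \code{.roles.json}) records the role and type tag of every
#' analysis column so that a cohort round-trips losslessly.
#'
#' @param cohort data frame, one row per participant.
#' @param roles a \code{\link{cohort_roles}} object.
#' @param prefix output path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.roles.json}.
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, roles, prefix) {
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".roles.json")
  utils::write.csv(cohort, csv, row.names = FALSE, na = "")
  vars <- role_vars(roles)
  meta <- list(
    columns = lapply(stats::setNames(nm = names(cohort)), function(nm) {
      list(role = role_of(roles, nm),
           type = if (is_binary_col(cohort[[nm]])) "binary" else "numeric")
    }),
    mediator_order = roles$mediators,
    intermediate_order = roles$intermediate,
    exposure = roles$exposure,
    outcomes = roles$outcomes
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, roles = side))
}

role_of <- function(roles, nm) {
  if (nm == roles$exposure) return("exposure")
  if (nm %in% roles$baseline) return("baseline_confounder")
  if (nm %in% roles$intermediate) return("intermediate_confounder")
  if (nm %in% roles$mediators) return("mediator")
  if (nm %in% roles$outcomes) return("outcome")
  "auxiliary"
}

#' Read a cohort written by \code{write_cohort}
#'
#' @param prefix path prefix used when writing.
#' @return a list with elements \code{cohort} (data frame) and
#'   \code{roles} (a \code{cohort_roles} object).
#' @export
read_cohort <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  side <- paste0(prefix, ".roles.json")
  cohort <- utils::read.csv(csv, na.strings = "")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  cols <- meta$columns
  baseline <- names(Filter(function(x) x$role == "baseline_confounder", cols))
  roles <- cohort_roles(
    exposure = meta$exposure,
    baseline = baseline,
    intermediate = meta$intermediate_order,
    mediators = meta$mediator_order,
    outcomes = meta$outcomes
  )
  list(cohort = cohort, roles = roles)
}
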
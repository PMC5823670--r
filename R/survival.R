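#' Apply survival-analysis exclusions
#'
#' Removes patients who died within one month of surgery (or of
#' post-operative complications) and patients who received neoadjuvant
#' therapy before the primary intervention.
#'
#' @param clinical clinical table with logical columns `died_within_month`
#'   and `neoadjuvant`.
#' @return the analysis cohort (retained rows); removed counts are reported
#'   via `message()` and attached as attribute `"removed"`.
#' @export
apply_exclusions <- function(clinical) {
  stopifnot_cols(clinical, c("died_within_month", "neoadjuvant"))
  early <- clinical$died_within_month
  neo <- clinical$neoadjuvant
  out <- clinical[!early & !neo, , drop = FALSE]
  removed <- c(died_within_month = sum(early),
               neoadjuvant = sum(neo & !early))
  message(sprintf("excluded %d early-death and %d neoadjuvant patients",
                  removed[1], removed[2]))
  attr(out, "removed") <- removed
  out
}

#' Build the eight survival analysis groups
#'
#' The standard design: OS for the pooled cohort in stages I-IV and I-III,
#' then PFS for pooled, colon-only and rectal-only patients, each in stages
#' I-IV and I-III.
#'
#' @param cohort analysis cohort (after [apply_exclusions()]) with
#'   `patient_id`, `cancer_type` (`CC`/`RC`), `stage` (`I`-`IV`).
#' @return named list of eight groups, each a list with `endpoint`
#'   (`"os"`/`"pfs"`), `types`, `stages`, and `patients` (ids).
#' @export
build_groups <- function(cohort) {
  stopifnot_cols(cohort, c("patient_id", "cancer_type", "stage"))
  defs <- list(
    OS_pooled_I_IV = list("os", c("CC", "RC"), c("I", "II", "III", "IV")),
    OS_pooled_I_III = list("os", c("CC", "RC"), c("I", "II", "III")),
    PFS_pooled_I_IV = list("pfs", c("CC", "RC"), c("I", "II", "III", "IV")),
    PFS_pooled_I_III = list("pfs", c("CC", "RC"), c("I", "II", "III")),
    PFS_CC_I_IV = list("pfs", "CC", c("I", "II", "III", "IV")),
    PFS_CC_I_III = list("pfs", "CC", c("I", "II", "III")),
    PFS_RC_I_IV = list("pfs", "RC", c("I", "II", "III", "IV")),
    PFS_RC_I_III = list("pfs", "RC", c("I", "II", "III")))
  out <- lapply(defs, function(d) {
    ids <- cohort$patient_id[cohort$cancer_type %in% d[[2]] &
                               cohort$stage %in% d[[3]]]
    list(endpoint = d[[1]], types = d[[2]], stages = d[[3]], patients = ids)
  })
  empty <- names(out)[vapply(out, function(g) !length(g$patients), logical(1))]
  if (length(empty))
    stop("insufficient data: empty group(s) ", paste(empty, collapse = ", "),
         call. = FALSE)
  out
}

#' Penalized Cox selection of cluster covariates
#'
#' Fits an elastic-net proportional-hazards model over a regularization path
#' (glmnet) and reports the covariates with non-zero coefficients at the
#' selected penalty. The default penalty rule minimizes
#' `deviance + df * log(n_events)` (a BIC) along the path; cross-validated
#' partial likelihood (10-fold) is available via `rule` and consumes random
#' numbers for fold assignment.
#'
#' @param covariates numeric matrix, patients x covariates.
#' @param time,event aligned outcome vectors (events coded 0/1).
#' @param alpha elastic-net mixing parameter in (0, 1\]; 1 = lasso.
#' @param rule penalty selection: `"bic"` (default), `"cv.min"`, `"cv.1se"`.
#' @param nfolds folds for the CV rules.
#' @return data.frame `cluster`, `coefficient`, `selected`, with the chosen
#'   `lambda` and any dropped constant columns as attributes.
#' @export
lasso_cox <- function(covariates, time, event, alpha = 1,
                      rule = c("bic", "cv.min", "cv.1se"), nfolds = 10) {
  rule <- match.arg(rule)
  stopifnot(nrow(covariates) == length(time), length(time) == length(event))
  if (sum(event) == 0) stop("no events in group", call. = FALSE)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  const <- apply(x, 2, function(v) length(unique(v)) <= 1L)
  if (any(const)) {
    warning("dropping all-constant covariate(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  # exact duplicates: the lasso keeps one of such a group; make that
  # deterministic by fitting the first column only
  dup <- if (ncol(x) > 1) duplicated(t(x)) else FALSE
  dup_names <- colnames(x)[dup]
  if (length(dup_names)) {
    warning("duplicated covariate column(s) represented by their first ",
            "copy: ", paste(dup_names, collapse = ", "), call. = FALSE)
    x <- x[, !dup, drop = FALSE]
  }
  empty <- data.frame(cluster = character(0), coefficient = numeric(0),
                      selected = logical(0))
  if (!ncol(x)) return(empty)
  real_cols <- colnames(x)
  if (ncol(x) == 1L) # glmnet needs >= 2 columns; pad with an inert zero
    x <- cbind(x, ".pad0" = 0)
  y <- survival::Surv(time, event)
  beta <- switch(rule,
    bic = {
      fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha)
      dev <- (1 - fit$dev.ratio) * fit$nulldev
      bic <- dev + fit$df * log(sum(event))
      as.matrix(fit$beta)[, which.min(bic)]
    },
    {
      cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha,
                              nfolds = nfolds)
      s <- if (rule == "cv.min") "lambda.min" else "lambda.1se"
      stats::setNames(as.matrix(stats::coef(cv, s = s))[, 1], colnames(x))
    })
  out <- data.frame(cluster = real_cols,
                    coefficient = unname(beta[real_cols]),
                    selected = unname(beta[real_cols] != 0),
                    stringsAsFactors = FALSE)
  if (length(dup_names))
    out <- rbind(out, data.frame(cluster = dup_names, coefficient = 0,
                                 selected = FALSE, stringsAsFactors = FALSE))
  attr(out, "rule") <- rule
  out
}

#' Refit selected clusters one at a time
#'
#' For each selected cluster, an unpenalized single-covariate Cox model
#' yields the hazard ratio (with a Wald p), and a two-group log-rank test on
#' carrier status yields the primary p-value. A Benjamini-Hochberg column is
#' reported for reference; selection never uses it. Clusters with no
#' carriers (or all carriers) among the analyzed patients are reported as
#' degenerate, not fitted.
#'
#' @param selected character vector of covariate (cluster) names.
#' @param covariates patients x covariates matrix.
#' @param time,event aligned outcome vectors.
#' @return data.frame `cluster`, `n_carriers`, `hazard_ratio`, `logrank_p`,
#'   `wald_p`, `bh_q`, `degenerate`.
#' @export
refit_cox <- function(selected, covariates, time, event) {
  stopifnot(length(selected) > 0)
  rows <- lapply(selected, function(s) {
    carrier <- covariates[, s]
    n_car <- sum(carrier != 0)
    if (n_car == 0 || n_car == length(carrier))
      return(data.frame(cluster = s, n_carriers = n_car,
                        hazard_ratio = NA_real_, logrank_p = NA_real_,
                        wald_p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    fit <- survival::coxph(survival::Surv(time, event) ~ carrier)
    sm <- summary(fit)
    lr <- survival::survdiff(survival::Surv(time, event) ~ carrier)
    data.frame(cluster = s, n_carriers = n_car,
               hazard_ratio = unname(exp(stats::coef(fit))),
               logrank_p = stats::pchisq(lr$chisq, df = 1,
                                         lower.tail = FALSE),
               wald_p = unname(sm$coefficients[1, "Pr(>|z|)"]),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$logrank_p, method = "BH")
  out[, c("cluster", "n_carriers", "hazard_ratio", "logrank_p", "wald_p",
          "bh_q", "degenerate")]
}

#' Two-stage survival analysis across the eight groups
#'
#' For each group from [build_groups()]: restrict the covariate matrix to
#' the group's patients, select covariates with [lasso_cox()], then refit
#' each selected cluster with [refit_cox()].
#'
#' @param covariates patients x clusters matrix (rownames = patient ids),
#'   e.g. from [cluster_covariates()].
#' @param clinical clinical table (exclusions are applied here).
#' @param ... passed to [lasso_cox()].
#' @return list of class `survival_results`: `results` (one data.frame with
#'   a `group` column), `selection` (per-group lasso tables), `groups`.
#' @export
run_survival <- function(covariates, clinical, ...) {
  cohort <- apply_exclusions(clinical)
  groups <- build_groups(cohort)
  results <- list()
  selection <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    ids <- intersect(g$patients, rownames(covariates))
    cl <- cohort[match(ids, cohort$patient_id), ]
    x <- covariates[ids, , drop = FALSE]
    time <- if (g$endpoint == "os") cl$os_time else cl$pfs_time
    event <- if (g$endpoint == "os") cl$os_event else cl$pfs_event
    sel <- tryCatch(suppressWarnings(lasso_cox(x, time, event, ...)),
                    error = function(e) NULL)
    selection[[gname]] <- sel
    picked <- sel$cluster[sel$selected]
    if (length(picked)) {
      r <- refit_cox(picked, x, time, event)
      r$lasso_coefficient <- sel$coefficient[match(r$cluster, sel$cluster)]
      results[[gname]] <- cbind(group = gname, r)
    }
  }
  structure(list(results = if (length(results))
    do.call(rbind, c(results, make.row.names = FALSE)) else NULL,
    selection = selection, groups = groups),
    class = "survival_results")
}

#' Kaplan-Meier curves by carrier status
#'
#' @param time,event outcome vectors.
#' @param carrier 0/1 carrier indicator.
#' @param main plot title.
#' @param file optional PDF path; when given the plot is written there.
#' @return the `survfit` object, invisibly.
#' @export
plot_km <- function(time, event, carrier, main = "", file = NULL) {
  grp <- factor(ifelse(carrier != 0, "carrier", "non-carrier"))
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  if (!is.null(file)) {
    grDevices::pdf(file)
    on.exit(grDevices::dev.off())
  }
  plot(fit, col = c("red", "black"), xlab = "time (months)",
       ylab = "survival", main = main)
  graphics::legend("topright", levels(grp), col = c("red", "black"), lty = 1)
  invisible(fit)
}
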
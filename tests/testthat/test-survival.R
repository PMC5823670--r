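make_clinical <- function(n = 100, seed = 1, stages = NULL, types = NULL) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%03d", 1:n),
    cancer_type = types %||% sample(c("CC", "RC"), n, TRUE),
    stage = stages %||% sample(c("I", "II", "III", "IV"), n, TRUE),
    os_time = rexp(n, 0.02), os_event = rbinom(n, 1, 0.6),
    pfs_time = rexp(n, 0.03), pfs_event = rbinom(n, 1, 0.6),
    died_within_month = FALSE, neoadjuvant = FALSE,
    stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exclusion flags remove exactly the flagged patients", {
  cl <- make_clinical(200)
  cl$died_within_month[1:24] <- TRUE
  cl$neoadjuvant[25:28] <- TRUE
  out <- suppressMessages(apply_exclusions(cl))
  expect_equal(nrow(out), 172)
  expect_equal(unname(attr(out, "removed")),
               c(24L, 4L), ignore_attr = TRUE)
  clean <- make_clinical(50)
  expect_equal(suppressMessages(apply_exclusions(clean)),
               clean, ignore_attr = TRUE)
})

test_that("the eight analysis groups partition as designed", {
  cl <- make_clinical(300, seed = 3)
  g <- build_groups(cl)
  expect_named(g, c("OS_pooled_I_IV", "OS_pooled_I_III", "PFS_pooled_I_IV",
                    "PFS_pooled_I_III", "PFS_CC_I_IV", "PFS_CC_I_III",
                    "PFS_RC_I_IV", "PFS_RC_I_III"))
  stage4 <- cl$patient_id[cl$stage == "IV"]
  for (nm in grep("I_III", names(g), value = TRUE))
    expect_length(intersect(g[[nm]]$patients, stage4), 0)
  expect_setequal(c(g$PFS_CC_I_IV$patients, g$PFS_RC_I_IV$patients),
                  g$PFS_pooled_I_IV$patients)
  # brute-force size check
  expect_equal(length(g$PFS_CC_I_III$patients),
               sum(cl$cancer_type == "CC" & cl$stage != "IV"))
  expect_equal(length(g$OS_pooled_I_IV$patients), 300)
})

test_that("an empty analysis group signals insufficient data", {
  cl <- make_clinical(30, types = "CC", stages = "IV")
  expect_error(build_groups(cl), "insufficient data")
})

sim_surv <- function(x, hr, n, seed, lambda = log(2) / 60) {
  set.seed(seed)
  h <- lambda * hr^x[, 1]
  t <- rexp(n, h)
  cens <- runif(n, 12, 120)
  list(time = pmin(t, cens), event = as.integer(t <= cens))
}

test_that("lasso keeps at most one of a duplicated covariate pair", {
  set.seed(42)
  n <- 300
  x <- cbind(a = rbinom(n, 1, 0.15), noise = rbinom(n, 1, 0.15))
  x <- cbind(x, b = x[, "a"])  # duplicate of the causal column
  o <- sim_surv(x, hr = 3, n = n, seed = 7)
  expect_warning(sel <- lasso_cox(x, o$time, o$event), "duplicated")
  expect_setequal(sel$cluster, c("a", "b", "noise"))
  expect_lte(sum(sel$selected[sel$cluster %in% c("a", "b")]), 1)
  expect_true(any(sel$selected[sel$cluster %in% c("a", "b")]))
})

test_that("all-constant covariates are dropped and never change results", {
  set.seed(43)
  n <- 250
  x <- cbind(a = rbinom(n, 1, 0.2), c = rbinom(n, 1, 0.2))
  o <- sim_surv(x, hr = 2.5, n = n, seed = 8)
  base <- lasso_cox(x, o$time, o$event)
  expect_warning(aug <- lasso_cox(cbind(x, zero = 0L), o$time, o$event),
                 "all-constant")
  expect_equal(base$coefficient, aug$coefficient[aug$cluster != "zero"],
               tolerance = 1e-10)
  expect_error(lasso_cox(x, o$time, rep(0L, n)), "no events")
})

test_that("selected support is stable across elastic-net mixing values", {
  set.seed(44)
  n <- 400
  x <- cbind(hot = rbinom(n, 1, 0.12),
             n1 = rbinom(n, 1, 0.12), n2 = rbinom(n, 1, 0.12))
  o <- sim_surv(x, hr = 3, n = n, seed = 9)
  for (a in c(0.2, 0.5, 1.0)) {
    sel <- lasso_cox(x, o$time, o$event, alpha = a)
    expect_true(sel$selected[sel$cluster == "hot"],
                label = sprintf("hot selected at alpha=%.1f", a))
  }
})

test_that("single-covariate refit matches a grid-maximized partial likelihood", {
  set.seed(45)
  n <- 50
  x <- cbind(a = rbinom(n, 1, 0.3))
  o <- sim_surv(x, hr = 2.2, n = n, seed = 10)
  # break ties so Breslow and Efron agree exactly
  o$time <- o$time + runif(n, 0, 1e-6)
  fit <- refit_cox("a", x, o$time, o$event)
  oracle_hr <- cox_grid_hr(o$time, o$event, x[, 1])
  expect_equal(log(fit$hazard_ratio), log(oracle_hr), tolerance = 0.01)
  expect_false(fit$degenerate)
  expect_true(fit$logrank_p >= 0 && fit$logrank_p <= 1)
})

test_that("refit hazard ratio converges to 1 for a null covariate", {
  set.seed(46)
  n <- 2000
  x <- cbind(a = rbinom(n, 1, 0.3))
  o <- sim_surv(x, hr = 1, n = n, seed = 11)
  fit <- refit_cox("a", x, o$time, o$event)
  expect_equal(fit$hazard_ratio, 1, tolerance = 0.15)
})

test_that("degenerate carrier patterns are reported, not fitted", {
  set.seed(47)
  n <- 60
  x <- cbind(a = rbinom(n, 1, 0.3), none = 0L, all = 1L)
  o <- sim_surv(x, hr = 2, n = n, seed = 12)
  fit <- refit_cox(c("none", "all"), x, o$time, o$event)
  expect_true(all(fit$degenerate))
  expect_true(all(is.na(fit$hazard_ratio)))
})

test_that("the two-stage pipeline recovers a planted hotspot end to end", {
  spec <- cohort_spec(n_patients = 250, seed = 55,
                      hotspots = list(planted_hotspot("G001", 600L, 0.12, 3.0)))
  co <- generate_cohort(spec)
  covariates <- co$truth$carriers
  sr <- suppressMessages(run_survival(covariates, co$clinical))
  os_rows <- sr$results[sr$results$group == "OS_pooled_I_IV", ]
  expect_true("G001:600" %in% os_rows$cluster)
  expect_gt(os_rows$hazard_ratio[os_rows$cluster == "G001:600"], 1.5)
})

test_that("Kaplan-Meier export writes a plot file", {
  set.seed(48)
  n <- 80
  x <- rbinom(n, 1, 0.3)
  o <- sim_surv(cbind(x), hr = 2, n = n, seed = 13)
  f <- withr::local_tempfile(fileext = ".pdf")
  fit <- plot_km(o$time, o$event, x, main = "carrier vs non-carrier",
                 file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_s3_class(fit, "survfit")
})
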
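# Per-patient derived quantities (lesion/fellow ratios, LogMAR, disc
# swelling class) and the cohort statistical battery: group comparisons,
# univariate screening, multivariate OLS and the published prediction
# equation for the PCT lesion/fellow ratio.

# Published multivariate model for the lesion/fellow ratio of average PCT.
PCT_RATIO_MODEL <- c(
  intercept = 1.1398,
  rnfl_ratio = -0.230,
  disc_swelling = -0.0674,
  refraction = -0.017,
  age = 0.002,
  male = 0.001
)

#' Published coefficients of the PCT-ratio prediction model
#' @return Named numeric vector (intercept, rnfl_ratio, disc_swelling,
#'   refraction, age, male).
#' @export
pct_ratio_coefficients <- function() PCT_RATIO_MODEL

#' Lesion/fellow ratio
#'
#' Within-subject normalisation: the lesion-eye value divided by the
#' fellow-eye value removes inter-individual baseline variation.
#'
#' @param lesion_value,fellow_value Measurements (um); `fellow_value > 0`.
#' @return `lesion_value / fellow_value`.
#' @export
compute_lf_ratio <- function(lesion_value, fellow_value) {
  if (any(!is.finite(fellow_value)) || any(fellow_value <= 0)) {
    pct_stop("pctopo_spec_error", "fellow-eye value must be positive")
  }
  lesion_value / fellow_value
}

#' Convert visual acuity to LogMAR
#'
#' `LogMAR = log10(1 / decimal acuity)`.  Accepts decimal acuity (e.g.
#' `0.5`), Snellen strings (`"20/40"`, `"6/12"`), or category strings
#' resolved through `lookup`.
#'
#' @param acuity Numeric decimal acuity or character Snellen/category.
#' @param lookup Named LogMAR values for non-optotype categories
#'   (default: counting fingers 2.0, hand motion 2.3, light perception
#'   2.7, no light perception 3.0).
#' @return LogMAR value(s).
#' @export
snellen_to_logmar <- function(acuity,
                              lookup = c(CF = 2.0, HM = 2.3,
                                         LP = 2.7, NLP = 3.0)) {
  one <- function(a) {
    if (is.character(a)) {
      a <- trimws(a)
      if (a %in% names(lookup)) return(unname(lookup[a]))
      if (grepl("^[0-9.]+/[0-9.]+$", a)) {
        parts <- as.numeric(strsplit(a, "/", fixed = TRUE)[[1L]])
        a <- parts[1L] / parts[2L]
      } else {
        a <- suppressWarnings(as.numeric(a))
        if (is.na(a)) {
          pct_stop("pctopo_spec_error",
                   "unrecognised acuity category; extend `lookup` to resolve it")
        }
      }
    }
    if (!is.finite(a) || a <= 0) {
      pct_stop("pctopo_spec_error", "acuity must be positive")
    }
    log10(1 / a)
  }
  vapply(as.list(acuity), one, numeric(1L))
}

#' Classify an eye as optic papillitis or retrobulbar neuritis
#'
#' Disc swelling is read off the RNFL: a lesion eye whose average RNFL is
#' at least `threshold` times the fellow eye's (default 1.10, i.e. >= 10%
#' thicker) is classed optic papillitis (OP), otherwise retrobulbar
#' neuritis (RN).
#'
#' @param rnfl_lesion,rnfl_fellow Average RNFL thickness (um), positive.
#' @param threshold Ratio boundary, inclusive (default 1.10).
#' @return Character vector of `"OP"` / `"RN"`.
#' @export
classify_group <- function(rnfl_lesion, rnfl_fellow, threshold = 1.10) {
  if (any(rnfl_lesion <= 0) || any(rnfl_fellow <= 0)) {
    pct_stop("pctopo_spec_error", "RNFL thicknesses must be positive")
  }
  ifelse(rnfl_lesion / rnfl_fellow >= threshold, "OP", "RN")
}

#' Evaluate the published PCT-ratio prediction equation
#'
#' `L/F ratio of PCT = 1.1398 - 0.230 * rnfl_ratio - 0.0674 * swelling
#'  - 0.017 * refraction + 0.002 * age + 0.001 * male`, with the published
#' coefficients stored as named constants.
#'
#' @param rnfl_ratio Lesion/fellow ratio of average RNFL.
#' @param disc_swelling Logical / 0-1: disc swelling observed.
#' @param refraction Spherical-equivalent refraction of the lesion eye (D).
#' @param age Age in years.
#' @param male Logical / 0-1.
#' @return Predicted lesion/fellow ratio of average PCT.
#' @export
predict_pct_ratio <- function(rnfl_ratio, disc_swelling, refraction,
                              age, male) {
  b <- PCT_RATIO_MODEL
  b[["intercept"]] +
    b[["rnfl_ratio"]] * rnfl_ratio +
    b[["disc_swelling"]] * as.numeric(disc_swelling) +
    b[["refraction"]] * refraction +
    b[["age"]] * age +
    b[["male"]] * as.numeric(male)
}

#' Add derived analysis columns to a cohort table
#'
#' Adds `pct_ratio`, `tem_pct_ratio`, `rnfl_ratio`, `tem_rnfl_ratio`
#' (lesion/fellow), `disc_swelling` (group == OP) and `male` indicators.
#'
#' @param records Cohort data.frame (see [cohort_columns()]).
#' @return The augmented data.frame.
#' @export
augment_cohort <- function(records) {
  records$pct_ratio <- compute_lf_ratio(records$pct_lesion,
                                        records$pct_fellow)
  records$tem_pct_ratio <- compute_lf_ratio(records$tem_pct_lesion,
                                            records$tem_pct_fellow)
  records$rnfl_ratio <- compute_lf_ratio(records$rnfl_lesion,
                                         records$rnfl_fellow)
  records$tem_rnfl_ratio <- compute_lf_ratio(records$tem_rnfl_lesion,
                                             records$tem_rnfl_fellow)
  records$disc_swelling <- as.integer(records$group == "OP")
  records$male <- as.integer(records$gender == "M")
  records
}

#' Compare a variable between groups
#'
#' Pooled-variance two-sample t test for continuous variables between the
#' two groups; one-way ANOVA for more than two groups; Fisher's exact
#' test for 2 x 2 contingency tables and the chi-square test otherwise.
#' All p-values are two-sided.
#'
#' @param records Cohort data.frame.
#' @param variable Column to compare.
#' @param kind `"t_test"`, `"anova"` or `"exact"`.
#' @param group_var Grouping column (default `"group"`).
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(records, variable,
                           kind = c("t_test", "anova", "exact"),
                           group_var = "group") {
  kind <- match.arg(kind)
  if (!variable %in% names(records)) {
    pct_stop("pctopo_schema_error", "variable '%s' not found", variable)
  }
  x <- records[[variable]]
  g <- factor(records[[group_var]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (kind == "t_test") {
    if (nlevels(g) != 2L || any(table(g) < 2L)) {
      pct_stop("pctopo_stats_error", "t test needs two groups of size >= 2")
    }
    if (all(vapply(split(x, g), stats::var, numeric(1L)) == 0)) {
      pct_stop("pctopo_stats_error",
               "degenerate (zero) variance in both groups")
    }
    ht <- stats::t.test(x ~ g, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "two-sample t test (pooled variance)")
  } else if (kind == "anova") {
    if (any(table(g) < 2L)) {
      pct_stop("pctopo_stats_error", "ANOVA needs group sizes >= 2")
    }
    if (stats::var(x) == 0) {
      pct_stop("pctopo_stats_error", "degenerate (zero) variance")
    }
    a <- stats::anova(stats::aov(x ~ g))
    list(statistic = a$`F value`[1L], p_value = a$`Pr(>F)`[1L],
         method = "one-way ANOVA")
  } else {
    tab <- table(x, g)
    if (all(dim(tab) == 2L)) {
      ht <- stats::fisher.test(tab)
      list(statistic = unname(ht$estimate), p_value = ht$p.value,
           method = "Fisher's exact test")
    } else {
      ht <- stats::chisq.test(tab)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "chi-square test")
    }
  }
}

#' Ordinary least-squares regression on cohort columns
#'
#' Fits `outcome ~ covariates` by OLS with listwise deletion of
#' incomplete records; coefficient p-values are two-sided t tests.
#'
#' @param records Cohort data.frame (usually after [augment_cohort()]).
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate column names;
#'   character/factor columns are expanded to dummies.
#' @return A `regression_result`: `terms` (term, estimate, p_value),
#'   `intercept`, `r_square`, `n_used`, `outcome`.
#' @export
fit_regression <- function(records, outcome, covariates) {
  miss <- setdiff(c(outcome, covariates), names(records))
  if (length(miss)) {
    pct_stop("pctopo_schema_error", "column(s) not found: %s",
             paste(miss, collapse = ", "))
  }
  d <- records[, c(outcome, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + 1L) {
    pct_stop("pctopo_stats_error",
             "need more than %d complete records to fit %d covariates, have %d",
             length(covariates) + 1L, length(covariates), n)
  }
  fml <- stats::reformulate(covariates, response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  if (any(sm$aliased)) {
    pct_stop("pctopo_stats_error",
             "rank-deficient design; collinear term(s): %s",
             paste(names(sm$aliased)[sm$aliased], collapse = ", "))
  }
  ct <- sm$coefficients
  terms <- data.frame(term = rownames(ct)[-1L],
                      estimate = unname(ct[-1L, 1L]),
                      p_value = unname(ct[-1L, 4L]))
  structure(list(outcome = outcome, terms = terms,
                 intercept = unname(ct[1L, 1L]),
                 intercept_p = unname(ct[1L, 4L]),
                 r_square = sm$r.squared,
                 n_used = n, fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, digits = 4L, ...) {
  cat(sprintf("OLS regression of %s (n = %d, R-square = %.4f)\n",
              x$outcome, x$n_used, x$r_square))
  tab <- rbind(
    data.frame(term = "(Intercept)", estimate = x$intercept,
               p_value = x$intercept_p),
    x$terms)
  tab$estimate <- signif(tab$estimate, digits)
  tab$p_value <- signif(tab$p_value, 3L)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Univariate p-value of a single candidate covariate (overall F when the
# candidate expands to several dummies).
univariate_p <- function(records, outcome, candidate) {
  r <- fit_regression(records, outcome, candidate)
  if (nrow(r$terms) == 1L) r$terms$p_value
  else {
    a <- stats::anova(r$fit)
    a$`Pr(>F)`[1L]
  }
}

#' Univariate screening followed by a multivariate fit
#'
#' Each candidate is first fit alone against the outcome; candidates with
#' univariate `p <= alpha` survive, the forced covariates (default age and
#' gender, which are controlled for regardless of their univariate
#' p-values) are added, and the multivariate model is fit on the
#' survivors.  With no surviving candidate the forced-covariate-only
#' model is returned with a warning.
#'
#' @param records Cohort data.frame (after [augment_cohort()]).
#' @param outcome Outcome column.
#' @param candidates Candidate covariate columns.
#' @param alpha Screening threshold (default 0.05).
#' @param forced Covariates always carried into the multivariate model.
#' @return A `regression_result` with an extra `screen` data.frame
#'   (candidate, univariate estimate, p, selected).
#' @export
screen_then_fit <- function(records, outcome, candidates, alpha = 0.05,
                            forced = c("age", "gender")) {
  if (!length(candidates)) {
    pct_stop("pctopo_spec_error", "no candidate covariates supplied")
  }
  screen <- do.call(rbind, lapply(candidates, function(cv) {
    r <- fit_regression(records, outcome, cv)
    data.frame(candidate = cv,
               estimate = r$terms$estimate[1L],
               p_value = univariate_p(records, outcome, cv))
  }))
  screen$selected <- screen$p_value <= alpha
  survivors <- screen$candidate[screen$selected]
  if (!length(survivors)) {
    warning("no candidate survived univariate screening; fitting forced covariates only",
            call. = FALSE)
  }
  covs <- unique(c(setdiff(survivors, forced), forced))
  res <- fit_regression(records, outcome, covs)
  res$screen <- screen
  res
}
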
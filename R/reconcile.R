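# Two-observer repeat-measurement protocol: each observer measures every
# image three times (one-week intervals); observer means that disagree by
# more than 10% trigger a third reviewer, and the final estimate is the
# mean of the two closest observer means.

#' Average one observer's three repeat measurements
#'
#' @param repeats Numeric vector of exactly three thickness values (um).
#' @return Their arithmetic mean.
#' @export
aggregate_repeats <- function(repeats) {
  if (length(repeats) != 3L || !is.numeric(repeats) ||
      any(!is.finite(repeats))) {
    pct_stop("pctopo_spec_error",
             "exactly three finite repeat measurements are required, got %d",
             length(repeats))
  }
  mean(repeats)
}

#' Reconcile two observers' mean measurements
#'
#' The disagreement fraction is `|m1 - m2| / mean(m1, m2)`.  At or below
#' the threshold (default 10%) the final value is the mean of the two
#' observer means and no third reviewer is consulted.  Above it,
#' `third_source` is called for an independent third mean and the final
#' value is the mean of the two closest of the three; if the third value
#' is exactly equidistant from both, all three are averaged.
#'
#' @param mean_1,mean_2 Observer means (um), positive.
#' @param third_source Function of no arguments returning the third
#'   reviewer's mean; only called when needed.
#' @param threshold Disagreement threshold (default 0.10).
#' @return A `measurement_session` with `final_um`,
#'   `disagreement_fraction`, `third_um` (NA when unused) and an `audit`
#'   string naming the rule that fired.
#' @export
reconcile <- function(mean_1, mean_2, third_source = NULL,
                      threshold = 0.10) {
  if (!is_number(mean_1) || !is_number(mean_2) || mean_1 <= 0 || mean_2 <= 0) {
    pct_stop("pctopo_spec_error", "observer means must be positive numbers")
  }
  disagreement <- abs(mean_1 - mean_2) / mean(c(mean_1, mean_2))
  if (disagreement <= threshold) {
    return(structure(list(
      observer_means = c(mean_1, mean_2), third_um = NA_real_,
      final_um = mean(c(mean_1, mean_2)),
      disagreement_fraction = disagreement,
      audit = "agreement: mean of two observers"
    ), class = "measurement_session"))
  }
  if (is.null(third_source)) {
    pct_stop("pctopo_reconcile_error",
             "observers disagree by %.1f%% (> %.0f%%) and no third reviewer is available",
             100 * disagreement, 100 * threshold)
  }
  third <- tryCatch(third_source(), error = function(e) {
    pct_stop("pctopo_reconcile_error",
             "unresolved session: third reviewer failed (%s)",
             conditionMessage(e))
  })
  if (!is_number(third) || third <= 0) {
    pct_stop("pctopo_reconcile_error",
             "unresolved session: third reviewer returned an invalid mean")
  }
  d13 <- abs(mean_1 - third)
  d23 <- abs(mean_2 - third)
  d12 <- abs(mean_1 - mean_2)
  dmin <- min(d12, d13, d23)
  final <- if (d13 == d23 && d13 <= d12) {
    audit <- "third equidistant: mean of all three"
    mean(c(mean_1, mean_2, third))
  } else if (d13 == dmin) {
    audit <- "closest pair: observer 1 and third"
    mean(c(mean_1, third))
  } else if (d23 == dmin) {
    audit <- "closest pair: observer 2 and third"
    mean(c(mean_2, third))
  } else {
    audit <- "closest pair: the two primary observers"
    mean(c(mean_1, mean_2))
  }
  structure(list(
    observer_means = c(mean_1, mean_2), third_um = third,
    final_um = final, disagreement_fraction = disagreement,
    audit = audit
  ), class = "measurement_session")
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf("<measurement_session> final %.2f um (disagreement %.2f%%; %s)\n",
              x$final_um, 100 * x$disagreement_fraction, x$audit))
  invisible(x)
}

#' Run the full session for two observers' raw repeats
#'
#' Convenience wrapper: averages each observer's three repeats with
#' [aggregate_repeats()] and reconciles the two means.
#'
#' @param repeats_1,repeats_2 Each observer's three repeats (um).
#' @inheritParams reconcile
#' @return A `measurement_session`.
#' @export
reconcile_repeats <- function(repeats_1, repeats_2, third_source = NULL,
                              threshold = 0.10) {
  reconcile(aggregate_repeats(repeats_1), aggregate_repeats(repeats_2),
            third_source = third_source, threshold = threshold)
}

#' Append a measurement session to a JSON-lines audit log
#'
#' @param session A `measurement_session`.
#' @param path Log file path (one JSON object per line).
#' @param image_id Identifier of the measured image.
#' @return Invisibly, `path`.
#' @export
log_session <- function(session, path, image_id = NA_character_) {
  rec <- list(image_id = image_id,
              observer_means_um = session$observer_means,
              third_um = session$third_um,
              final_um = session$final_um,
              disagreement_fraction = session$disagreement_fraction,
              audit = session$audit)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
      "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
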
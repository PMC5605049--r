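# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers can distinguish error families.
pct_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pctopo_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; `seed` must fit in a 32-bit integer.
with_seed <- function(seed, expr) {
  if (!is_number(seed) || abs(seed) >= 2^31) {
    pct_stop("pctopo_spec_error", "seed must be a finite 32-bit integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Normal draws truncated to [lower, upper] by inverse-CDF sampling.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) {
    pct_stop("pctopo_spec_error",
             "empty truncation interval [%g, %g] for N(%g, %g)",
             lower, upper, mean, sd)
  }
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Solve for the pre-truncation mean of a truncated normal whose observed
# (post-truncation) mean should equal `target`; reported group moments are
# observed moments, so generators draw from the solved distribution.
solve_trunc_mean <- function(target, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0 || (!is.finite(lower) && !is.finite(upper))) return(target)
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 interval = target + c(-6, 6) * sd, tol = 1e-10)$root
}

rnorm_trunc_mean <- function(n, target_mean, sd, lower = -Inf, upper = Inf) {
  rnorm_trunc(n, solve_trunc_mean(target_mean, sd, lower, upper), sd,
              lower, upper)
}

# Solve (mu, sigma) of a truncated normal so that both the observed mean
# and the observed SD match their targets (used for one-sided
# truncations, where the observed SD is always attainable by inflating
# sigma).  Falls back to mean-only matching when no bracket is found.
solve_trunc_moments <- function(target_mean, target_sd, lower = -Inf,
                                upper = Inf) {
  trunc_sd <- function(sig) {
    mu <- solve_trunc_mean(target_mean, sig, lower, upper)
    a <- (lower - mu) / sig
    b <- (upper - mu) / sig
    z <- stats::pnorm(b) - stats::pnorm(a)
    la <- stats::dnorm(a); lb <- stats::dnorm(b)
    m1 <- (la - lb) / z
    aa <- if (is.finite(a)) a * la else 0
    bb <- if (is.finite(b)) b * lb else 0
    sig * sqrt(1 + (aa - bb) / z - m1^2)
  }
  if (trunc_sd(target_sd) >= target_sd - 1e-12) {
    return(c(mean = solve_trunc_mean(target_mean, target_sd, lower, upper),
             sd = target_sd))
  }
  hi <- target_sd
  for (i in 1:30) {
    hi <- hi * 1.4
    if (trunc_sd(hi) >= target_sd) break
  }
  if (trunc_sd(hi) < target_sd) {
    return(c(mean = solve_trunc_mean(target_mean, target_sd, lower, upper),
             sd = target_sd))
  }
  sig <- stats::uniroot(function(s) trunc_sd(s) - target_sd,
                        interval = c(target_sd, hi), tol = 1e-10)$root
  c(mean = solve_trunc_mean(target_mean, sig, lower, upper), sd = sig)
}

rnorm_trunc_moments <- function(n, target_mean, target_sd,
                                lower = -Inf, upper = Inf) {
  par <- solve_trunc_moments(target_mean, target_sd, lower, upper)
  rnorm_trunc(n, par[["mean"]], par[["sd"]], lower, upper)
}

# Polyline coercion: an n x 2 numeric matrix of (x, y) vertices.
as_polyline <- function(p, what = "polyline") {
  if (is.list(p) && !is.data.frame(p)) p <- do.call(rbind, lapply(p, unlist))
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || nrow(p) < 1L || anyNA(p)) {
    pct_stop("pctopo_schema_error", "%s must be an n x 2 numeric matrix", what)
  }
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

check_x_monotone <- function(p, what = "polyline") {
  dx <- diff(p[, 1L])
  if (any(dx <= 0) && any(dx >= 0) && !(all(dx > 0) || all(dx < 0))) {
    pct_stop("pctopo_annotation_error",
             "%s is not x-monotone; re-annotate with one axial value per lateral position",
             what)
  }
  if (p[1L, 1L] > p[nrow(p), 1L]) p <- p[nrow(p):1L, , drop = FALSE]
  p
}
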
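#' Interval-censored observations of per-read conversion tract length
#'
#' Under the per-molecule tract model, a read converts exactly the variants
#' whose distance from the cut is at most its (unobserved) tract length L.
#' The calls therefore censor L into an interval: L is at least the furthest
#' converted distance and less than the nearest unconverted distance beyond
#' it. Reads whose pattern violates nesting (an unconverted site nearer than
#' a converted one) do not admit this reading and are handled per
#' `nonnested`.
#'
#' @param matrix A `read_call_matrix`.
#' @param variant_specs Optional variant table with `id` and
#'   `tract_distance`; defaults to the one stored in the matrix.
#' @param nonnested `"exclude"` (default): drop non-nested reads, reporting
#'   their count; `"relax"`: keep them, censoring L by the furthest converted
#'   distance and the nearest unconverted distance beyond it.
#' @return A list with `intervals` (data frame `lower`, `upper`, `n`; `upper`
#'   may be `Inf`), `n_reads` (informative reads used), `n_nonnested`, and
#'   `n_uninformative` (reads with all calls ambiguous).
#' @export
tract_intervals <- function(matrix, variant_specs = NULL,
                            nonnested = c("exclude", "relax")) {
  nonnested <- match.arg(nonnested)
  calls <- matrix$calls
  v <- if (is.null(variant_specs)) matrix$variants else as.data.frame(variant_specs)
  if (is.null(v$tract_distance)) stop("variant_specs must carry tract_distance")
  v <- v[order(v$tract_distance), , drop = FALSE]
  calls <- calls[, v$id, drop = FALSE]
  d <- v$tract_distance

  lower <- upper <- numeric(nrow(calls))
  keep <- logical(nrow(calls))
  n_nonnested <- 0L; n_uninf <- 0L
  for (r in seq_len(nrow(calls))) {
    cv <- d[calls[r, ] == "converted"]
    uc <- d[calls[r, ] == "unconverted"]
    if (length(cv) == 0 && length(uc) == 0) { n_uninf <- n_uninf + 1L; next }
    nested <- length(cv) == 0 || length(uc) == 0 || max(cv) < min(uc)
    if (!nested) {
      n_nonnested <- n_nonnested + 1L
      if (nonnested == "exclude") next
    }
    a <- if (length(cv)) max(cv) else 0
    beyond <- uc[uc > a]
    b <- if (length(beyond)) min(beyond) else Inf
    lower[r] <- a; upper[r] <- b; keep[r] <- TRUE
  }
  iv <- data.frame(lower = lower[keep], upper = upper[keep])
  if (nrow(iv) == 0) {
    return(list(intervals = data.frame(lower = numeric(), upper = numeric(),
                                       n = integer()),
                n_reads = 0L, n_nonnested = n_nonnested,
                n_uninformative = n_uninf))
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(iv))),
                          by = iv[c("lower", "upper")], FUN = sum)
  list(intervals = agg[order(agg$lower, agg$upper), , drop = FALSE],
       n_reads = sum(keep), n_nonnested = n_nonnested,
       n_uninformative = n_uninf)
}

# log-likelihood of continuation probability p for aggregated intervals:
# each read contributes log(S(a) - S(b)) with S(d) = p^d, i.e.
# a*log(p) + log(1 - p^(b-a)) (the second term vanishes for b = Inf).
.tract_loglik <- function(p, intervals) {
  a <- intervals$lower; b <- intervals$upper; n <- intervals$n
  term <- a * log(p)
  fin <- is.finite(b)
  term[fin] <- term[fin] + log1p(-p^(b[fin] - a[fin]))
  sum(n * term)
}

#' Fit the geometric conversion-tract-length model
#'
#' Maximum-likelihood fit of a geometric tract-length model to a read call
#' matrix. The model: copying of donor sequence proceeds outward from the
#' double-strand break and continues past each nucleotide with probability
#' `p`, so the tract survival function is `S(d) = p^d` — the probability that
#' a variant `d` nt from the cut is incorporated. Each read censors its tract
#' length into an interval (see [tract_intervals()]) and contributes
#' `S(lower) - S(upper)` to the likelihood; all-converted and all-unconverted
#' reads enter as right- and left-censored intervals. The optimum is located
#' to a log-likelihood tolerance below 1e-8; the 95% confidence interval is
#' obtained by profile likelihood.
#'
#' @param matrix A `read_call_matrix` from [build_matrix()] or
#'   [truth_matrix()].
#' @param variant_specs Optional variant table with `id`, `tract_distance`.
#' @param family Tract-length family; `"geometric"` is currently the only
#'   member, named so that heavier-tailed families can be added.
#' @param nonnested Handling of reads violating nesting; see
#'   [tract_intervals()].
#' @param level Confidence level for the profile interval (default 0.95).
#' @return An object of class `tract_fit` with components `p` (MLE of the
#'   per-nucleotide continuation probability), `logLik`, `ci`,
#'   `non_identifiable` (TRUE when the MLE sits on the parameter boundary),
#'   `n_reads`, `n_nonnested`, `intervals`, `profile` (empirical
#'   [conversion_profile()] of the matrix, for diagnostics), and `family`.
#' @examples
#' cfg <- sim_config(seed = 1, n_reads = 300, error_rate = 0)
#' sim <- simulate_reads(cfg)
#' fit <- fit_tract_model(truth_matrix(sim))
#' coef(fit); confint(fit)
#' predict(fit, c(45, 300, 696))
#' @export
fit_tract_model <- function(matrix, variant_specs = NULL,
                            family = "geometric",
                            nonnested = c("exclude", "relax"),
                            level = 0.95) {
  family <- match.arg(family)
  nonnested <- match.arg(nonnested)
  ti <- tract_intervals(matrix, variant_specs, nonnested = nonnested)
  iv <- ti$intervals
  if (nrow(iv) == 0 || ti$n_reads == 0)
    stop("no informative reads to fit the tract model")

  eps <- 1e-9
  opt <- optimize(.tract_loglik, interval = c(eps, 1 - eps), intervals = iv,
                  maximum = TRUE, tol = 1e-12)
  p_hat <- opt$maximum
  ll_hat <- opt$objective
  non_ident <- p_hat > 1 - 1e-6 || p_hat < 1e-6 ||
    all(!is.finite(iv$upper)) || all(iv$lower == 0)
  if (all(!is.finite(iv$upper))) { p_hat <- 1 - eps; ll_hat <- 0 }

  # profile-likelihood interval: p with loglik within qchisq(level, 1)/2
  drop <- qchisq(level, df = 1) / 2
  f <- function(p) .tract_loglik(p, iv) - (ll_hat - drop)
  lo <- if (f(eps) >= 0 || non_ident && p_hat < 0.5) eps else
    uniroot(f, c(eps, p_hat), tol = 1e-10)$root
  hi <- if (non_ident && p_hat > 0.5) 1 else if (f(1 - eps) >= 0) 1 else
    uniroot(f, c(p_hat, 1 - eps), tol = 1e-10)$root

  prof <- tryCatch(conversion_profile(matrix, variant_specs),
                   error = function(e) NULL)
  structure(list(family = family, p = p_hat, logLik = ll_hat,
                 ci = c(lower = lo, upper = hi), level = level,
                 non_identifiable = non_ident,
                 n_reads = ti$n_reads, n_nonnested = ti$n_nonnested,
                 n_uninformative = ti$n_uninformative,
                 nonnested = nonnested, intervals = iv, profile = prof,
                 call = match.call()),
            class = "tract_fit")
}

#' @export
print.tract_fit <- function(x, digits = 4, ...) {
  cat("Geometric conversion-tract model\n")
  cat(sprintf("  p (per-nt continuation) = %.*f   [%d%% profile CI %.*f-%.*f]\n",
              digits, x$p, round(100 * x$level), digits, x$ci[1], digits,
              x$ci[2]))
  cat(sprintf("  log-likelihood %.3f on %d read(s)", x$logLik, x$n_reads))
  if (x$n_nonnested > 0)
    cat(sprintf("  (%d non-nested read(s) %s)", x$n_nonnested,
                if (x$nonnested == "exclude") "excluded" else "relaxed"))
  cat("\n")
  if (x$non_identifiable)
    cat("  WARNING: parameter at boundary; p is not identifiable from these calls\n")
  invisible(x)
}

#' @export
coef.tract_fit <- function(object, ...) c(p = object$p)

#' @export
logLik.tract_fit <- function(object, ...) {
  structure(object$logLik, df = 1L, nobs = object$n_reads, class = "logLik")
}

#' @export
confint.tract_fit <- function(object, parm = "p", level = 0.95, ...) {
  if (abs(level - object$level) < 1e-12) {
    ci <- object$ci
  } else {
    drop <- qchisq(level, df = 1) / 2
    eps <- 1e-9
    f <- function(p) .tract_loglik(p, object$intervals) - (object$logLik - drop)
    lo <- if (f(eps) >= 0) eps else uniroot(f, c(eps, object$p), tol = 1e-10)$root
    hi <- if (object$non_identifiable && object$p > 0.5) 1
          else if (f(1 - eps) >= 0) 1
          else uniroot(f, c(object$p, 1 - eps), tol = 1e-10)$root
    ci <- c(lo, hi)
  }
  m <- matrix(ci, 1, 2, dimnames = list("p", sprintf("%.1f %%",
              100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  m
}

#' Predicted conversion probability at a distance
#'
#' @param object A `tract_fit`.
#' @param newdata Numeric vector of distances (nt), or a data frame with a
#'   `tract_distance` column; defaults to the fitted profile's distances.
#' @param ... Unused.
#' @return Numeric vector `S(d) = p^d`, the probability that a variant `d` nt
#'   from the cut is converted.
#' @export
predict.tract_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$profile$tract_distance
       else if (is.data.frame(newdata)) newdata$tract_distance
       else as.numeric(newdata)
  if (is.null(d)) stop("no distances to predict at")
  setNames(object$p^d, d)
}

#' @export
residuals.tract_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  prof <- object$profile
  if (is.null(prof)) stop("fit carries no empirical profile")
  fitted <- object$p^prof$tract_distance
  r <- prof$frequency - fitted
  if (type == "pearson") {
    se <- sqrt(fitted * (1 - fitted) / pmax(prof$n_called, 1))
    r <- r / ifelse(se > 0, se, NA_real_)
  }
  setNames(r, prof$variant_id)
}

#' Simulate call matrices from a fitted tract model
#'
#' Draws new reads under the fitted geometric model at the fitted variant
#' distances (nested incorporation, no sequencing error or ambiguity) and
#' returns ground-truth call matrices, e.g. for parametric-bootstrap checks.
#'
#' @param object A `tract_fit`.
#' @param nsim Number of matrices.
#' @param seed Optional RNG seed.
#' @param n_reads Reads per simulated matrix (default: as fitted).
#' @param ... Unused.
#' @return A list of `read_call_matrix` objects of length `nsim`.
#' @export
simulate.tract_fit <- function(object, nsim = 1, seed = NULL,
                               n_reads = object$n_reads, ...) {
  d <- object$profile$tract_distance
  ids <- object$profile$variant_id
  if (is.null(d)) stop("fit carries no variant distances")
  run <- function() {
    L <- rgeom(n_reads, prob = 1 - object$p)
    conv <- outer(L, d, ">=")
    calls <- matrix(ifelse(conv, "converted", "unconverted"),
                    n_reads, length(d),
                    dimnames = list(paste0("sim_", seq_len(n_reads)), ids))
    structure(list(calls = calls, identity = rep(1, n_reads),
                   strand = rep("+", n_reads),
                   variants = data.frame(id = ids, tract_distance = d),
                   qc = list(n_input = n_reads, n_pass = n_reads, n_fail = 0L)),
              class = "read_call_matrix")
  }
  out <- if (is.null(seed)) replicate(nsim, run(), simplify = FALSE)
         else with_seed(seed, replicate(nsim, run(), simplify = FALSE))
  if (nsim == 1) out[[1]] else out
}

#' @export
summary.tract_fit <- function(object, ...) {
  prof <- object$profile
  tab <- NULL
  if (!is.null(prof)) {
    tab <- data.frame(variant_id = prof$variant_id,
                      tract_distance = prof$tract_distance,
                      observed = prof$frequency,
                      fitted = object$p^prof$tract_distance)
  }
  structure(list(fit = object, comparison = tab,
                 half_distance = log(0.5) / log(object$p)),
            class = "summary.tract_fit")
}

#' @export
print.summary.tract_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  tract half-distance (S = 0.5): %.0f nt\n", x$half_distance))
  if (!is.null(x$comparison)) {
    cat("  observed vs fitted conversion frequency:\n")
    print(transform(x$comparison, observed = round(observed, 3),
                    fitted = round(fitted, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.tract_fit <- function(x, xlim = NULL, ...) {
  prof <- x$profile
  dmax <- if (!is.null(prof)) max(prof$tract_distance) else
    ceiling(log(0.01) / log(x$p))
  if (is.null(xlim)) xlim <- c(0, 1.1 * dmax)
  d <- seq(xlim[1], xlim[2], length.out = 200)
  plot(d, x$p^d, type = "l", ylim = c(0, 1),
       xlab = "distance from cut (nt)",
       ylab = "conversion probability S(d)", ...)
  lines(d, x$ci[1]^d, lty = 3)
  lines(d, x$ci[2]^d, lty = 3)
  if (!is.null(prof))
    points(prof$tract_distance, prof$frequency, pch = 19)
  legend("topright", bty = "n",
         legend = c(sprintf("fit: p = %.4f", x$p), "profile-CI envelope",
                    if (!is.null(prof)) "observed frequency"),
         lty = c(1, 3, NA), pch = c(NA, NA, if (!is.null(prof)) 19))
  invisible(x)
}

#' Write a tract-model fit as JSON
#' @param fit A `tract_fit`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  jsonlite::write_json(
    list(family = fit$family, p = fit$p, logLik = fit$logLik,
         ci = as.list(fit$ci), level = fit$level,
         non_identifiable = fit$non_identifiable,
         n_reads = fit$n_reads, n_nonnested = fit$n_nonnested),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
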
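#' Per-variant conversion frequency profile
#'
#' The core decay statistic: for each designed variant, the fraction of
#' amplicon reads carrying the donor allele, as a function of the variant's
#' distance from the double-strand break. By default the denominator is the
#' number of non-ambiguous calls at that site (truncated reads do not count
#' as unconverted); `denominator = "total"` divides by the fixed number of
#' reads in the matrix instead, the convention of dividing every count by the
#' total number of sequenced clones.
#'
#' @param matrix A `read_call_matrix` from [build_matrix()] or
#'   [truth_matrix()].
#' @param variant_specs Optional variant table carrying `id` and
#'   `tract_distance`; defaults to the one stored in the matrix.
#' @param denominator `"called"` (default) or `"total"`.
#' @param summary_distance_nt Distance D for the profile summary: the
#'   minimum and pooled frequency among variants closer than D (default 300).
#' @return A data frame of class `conversion_profile` with columns
#'   `variant_id`, `tract_distance`, `n_converted`, `n_called`, `frequency`
#'   (NA when no calls), ordered by distance. The summary is attached as
#'   attribute `"summary"` (list `min_frequency_below_D`,
#'   `pooled_frequency_below_D`, `distance_nt`).
#' @export
conversion_profile <- function(matrix, variant_specs = NULL,
                               denominator = c("called", "total"),
                               summary_distance_nt = 300) {
  denominator <- match.arg(denominator)
  calls <- matrix$calls
  if (is.null(calls) || nrow(calls) == 0) stop("empty call matrix")
  v <- if (is.null(variant_specs)) matrix$variants else as.data.frame(variant_specs)
  if (is.null(v$tract_distance))
    stop("variant_specs must carry tract_distance")
  v <- v[order(v$tract_distance), , drop = FALSE]
  calls <- calls[, v$id, drop = FALSE]
  n_conv <- colSums(calls == "converted")
  n_called <- colSums(calls != "ambiguous")
  denom <- if (denominator == "called") n_called else rep(nrow(calls), ncol(calls))
  freq <- ifelse(denom > 0, n_conv / denom, NA_real_)
  out <- data.frame(variant_id = v$id, tract_distance = v$tract_distance,
                    n_converted = as.integer(n_conv),
                    n_called = as.integer(n_called),
                    frequency = freq, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  near <- out$tract_distance < summary_distance_nt
  attr(out, "summary") <- list(
    distance_nt = summary_distance_nt,
    min_frequency_below_D =
      if (any(near & !is.na(out$frequency))) min(out$frequency[near], na.rm = TRUE)
      else NA_real_,
    pooled_frequency_below_D =
      if (any(near) && sum(denom[near]) > 0) sum(n_conv[near]) / sum(denom[near])
      else NA_real_
  )
  attr(out, "denominator") <- denominator
  class(out) <- c("conversion_profile", "data.frame")
  out
}

#' @export
print.conversion_profile <- function(x, ...) {
  cat("Conversion-tract profile (denominator: ", attr(x, "denominator"),
      ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  s <- attr(x, "summary")
  cat(sprintf("min / pooled frequency below %d nt: %s / %s\n",
              s$distance_nt,
              formatC(s$min_frequency_below_D, digits = 3, format = "f"),
              formatC(s$pooled_frequency_below_D, digits = 3, format = "f")))
  invisible(x)
}

#' Conditional co-occurrence of variant conversions
#'
#' Cell (i, j) is the probability that variant j is converted given that
#' variant i is converted, computed over reads where both calls are
#' non-ambiguous. Under a per-molecule conversion tract, conversion of a far
#' variant implies conversion of all nearer ones, so P(near | far) should sit
#' at 1 while P(far | near) decays — the linkage structure visible in the
#' conditional heatmap.
#'
#' @param matrix A `read_call_matrix`.
#' @return A K x K numeric matrix of class `cooccurrence_matrix` (rows:
#'   conditioning variant i; columns: variant j), `NA` where the conditioning
#'   set is empty. Variants are ordered by tract distance when known.
#' @export
cooccurrence <- function(matrix) {
  calls <- matrix$calls
  if (is.null(calls) || nrow(calls) == 0) stop("empty call matrix")
  v <- matrix$variants
  if (!is.null(v$tract_distance))
    calls <- calls[, v$id[order(v$tract_distance)], drop = FALSE]
  K <- ncol(calls)
  conv <- calls == "converted"
  called <- calls != "ambiguous"
  out <- matrix(NA_real_, K, K, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(K)) {
    cond <- conv[, i]
    for (j in seq_len(K)) {
      ok <- cond & called[, j]
      if (any(ok)) out[i, j] <- mean(conv[ok, j])
    }
  }
  structure(out, class = c("cooccurrence_matrix", "matrix", "array"))
}

#' @export
print.cooccurrence_matrix <- function(x, digits = 3, ...) {
  cat("Conditional co-occurrence P(column converted | row converted):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
plot.cooccurrence_matrix <- function(x, ...) {
  m <- unclass(x)
  K <- ncol(m)
  graphics::image(seq_len(K), seq_len(K), t(m[K:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE,
                  xlab = "variant j (converted?)",
                  ylab = "conditioning variant i",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  axis(1, at = seq_len(K), labels = colnames(m))
  axis(2, at = seq_len(K), labels = rev(rownames(m)), las = 2)
  invisible(x)
}

#' Clone recombination-rate report
#'
#' Summarises a clone genotyping screen: the percentage of single-cell clones
#' carrying the intended recombination event, with an exact (Clopper-Pearson)
#' 95% binomial confidence interval. Percentages are rounded half-up to one
#' decimal for display (so 10/24 prints as 41.7%).
#'
#' @param n_positive Number of clones with the intended edit.
#' @param n_total Total clones genotyped (> 0).
#' @return An object of class `clone_report`: list with `n_positive`,
#'   `n_total`, `rate` (exact fraction), `rate_percent` (rounded, one
#'   decimal) and `conf_int` (95% Clopper-Pearson bounds on the rate).
#' @export
clone_report <- function(n_positive, n_total) {
  if (length(n_total) != 1 || is.na(n_total) || n_total <= 0)
    stop("n_total must be a positive integer")
  if (n_positive < 0 || n_positive > n_total)
    stop("n_positive must lie in [0, n_total]")
  ci <- binom.test(n_positive, n_total)$conf.int
  structure(list(n_positive = as.integer(n_positive),
                 n_total = as.integer(n_total),
                 rate = n_positive / n_total,
                 rate_percent = round_half_up(100 * n_positive / n_total, 1),
                 conf_int = as.numeric(ci)),
            class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf("Recombination rate: %d/%d = %.1f%% (95%% CI %.1f-%.1f%%)\n",
              x$n_positive, x$n_total, x$rate_percent,
              100 * x$conf_int[1], 100 * x$conf_int[2]))
  invisible(x)
}

#' Write a conversion profile to TSV
#' @param profile A `conversion_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  write.table(as.data.frame(profile), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
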
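#' Discard burn-in from a trace
#'
#' Removes the first `floor(fraction * N)` samples, where N is the current
#' sample count, and marks the trace. A second application is refused unless
#' `force = TRUE`, so the conventional 20% rule cannot be applied twice by
#' accident.
#'
#' @param trace a [chronogram_trace].
#' @param fraction burn-in fraction in `[0, 1)` (default 0.2).
#' @param force allow re-application.
#' @return the trimmed [chronogram_trace].
#' @export
apply_burn_in <- function(trace, fraction = 0.2, force = FALSE) {
  stopifnot(inherits(trace, "chronogram_trace"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction >= 1)
    abort_hgt("burn-in fraction must be in [0, 1)", "hgtclock_value_error")
  if (isTRUE(trace$burnin_applied) && !force)
    abort_hgt("burn-in has already been applied to this trace; pass force = TRUE to trim again",
              "hgtclock_value_error")
  n <- length(trace$samples)
  drop <- floor(fraction * n)
  out <- subset_trace(trace, seq_len(n)[seq_len(n) > drop])
  out$burnin_applied <- TRUE
  out$burnin_fraction <- fraction
  out
}

#' Highest-posterior-density interval of a sample of ages
#'
#' The empirical HPD: among all windows of `k = ceiling(level * n)`
#' consecutive order statistics, the minimum-width window; ties are broken by
#' the lowest lower bound.
#'
#' @param ages numeric vector or `age_trace` (>= 2 values).
#' @param level interval mass in (0, 1), default 0.95.
#' @return named numeric `c(lower = , upper = )` in Ma.
#' @export
hpd_interval <- function(ages, level = 0.95) {
  x <- as_ages(ages)
  if (length(x) < 2L)
    abort_hgt("need at least 2 samples for an HPD interval",
              "hgtclock_insufficient_samples")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    abort_hgt("HPD level must be in (0, 1)", "hgtclock_value_error")
  x <- sort(x)
  n <- length(x)
  k <- ceiling(level * n)
  widths <- x[k:n] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)   # which.min returns the first (lowest) minimum
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Median of a sample of ages
#'
#' Sample median; the mean of the two central order statistics for even n.
#'
#' @param ages numeric vector or `age_trace` (>= 1 value).
#' @return median in Ma.
#' @export
median_age <- function(ages) {
  x <- as_ages(ages)
  if (length(x) == 0L)
    abort_hgt("need at least 1 sample for a median",
              "hgtclock_insufficient_samples")
  stats::median(x)
}

#' Probability that node A is older than node B
#'
#' In paired mode (the default, appropriate for two age traces extracted from
#' the same posterior) the probability is the fraction of samples with
#' age A > age B; ties are counted separately and excluded from the
#' numerator. In unpaired mode, for independent traces, the cross-product
#' estimate `#(a_i > b_j) / (nA * nB)` is computed.
#'
#' @param a,b numeric vectors or `age_trace` objects.
#' @param paired logical, default `TRUE`.
#' @param name label for the result.
#' @return an object of class `"hypothesis_result"`: list with `name`,
#'   `node_a`, `node_b`, `probability`, `n` (pair count), `ties`.
#' @export
prob_older <- function(a, b, paired = TRUE, name = NULL) {
  node_a <- if (inherits(a, "age_trace")) a$name else "A"
  node_b <- if (inherits(b, "age_trace")) b$name else "B"
  av <- as_ages(a); bv <- as_ages(b)
  if (paired) {
    if (length(av) != length(bv))
      abort_hgt(sprintf("paired mode needs equal lengths (got %d and %d)",
                        length(av), length(bv)), "hgtclock_pairing_error")
    n <- length(av)
    gt <- sum(av > bv)
    ties <- sum(av == bv)
  } else {
    bs <- sort(bv)
    # counts of b strictly below / at-or-below each a, via order statistics;
    # double arithmetic: pair counts overflow 32-bit integers quickly
    lt <- findInterval(av, bs, left.open = TRUE)
    le <- findInterval(av, bs)
    n <- as.numeric(length(av)) * length(bv)
    gt <- sum(as.numeric(lt))
    ties <- sum(as.numeric(le - lt))
  }
  structure(list(name = name %||% sprintf("%s_older_than_%s", node_a, node_b),
                 node_a = node_a, node_b = node_b,
                 probability = gt / n, n = n, ties = ties),
            class = "hypothesis_result")
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat(sprintf("<hypothesis> P(age %s > age %s) = %.4f  (n = %d, ties = %d)\n",
              x$node_a, x$node_b, x$probability, x$n, x$ties))
  invisible(x)
}

#' Per-clade divergence-date summary of a trace
#'
#' One row per clade definition, in input order: sample count, median age,
#' and HPD bounds. The trace is expected to be burn-in-trimmed (and
#' HGT-filtered where the model demands it) before summarizing.
#'
#' @param trace a [chronogram_trace].
#' @param clades list of [clade_definition] objects.
#' @param level HPD level (default 0.95).
#' @param strict monophyly requirement per sample.
#' @return data frame with columns `node`, `n`, `median_ma`, `hpd_lower_ma`,
#'   `hpd_upper_ma`, `level`.
#' @export
summarize_model <- function(trace, clades, level = 0.95, strict = TRUE) {
  stopifnot(inherits(trace, "chronogram_trace"))
  if (inherits(clades, "clade_definition")) clades <- list(clades)
  rows <- vector("list", length(clades))
  errs <- character(0)
  for (i in seq_along(clades)) {
    rows[[i]] <- tryCatch({
      at <- clade_age_trace(trace, clades[[i]], strict = strict)
      h <- hpd_interval(at, level = level)
      data.frame(node = clades[[i]]$name, n = length(at$ages),
                 median_ma = median_age(at),
                 hpd_lower_ma = h[["lower"]], hpd_upper_ma = h[["upper"]],
                 level = level, stringsAsFactors = FALSE)
    }, hgtclock_error = function(e) {
      errs <<- c(errs, sprintf("%s: %s", clades[[i]]$name,
                               conditionMessage(e)))
      NULL
    })
  }
  if (length(errs) > 0L)
    abort_hgt(paste0("summary failed for ", length(errs), " clade(s):\n  ",
                     paste(errs, collapse = "\n  ")),
              "hgtclock_summary_error")
  do.call(rbind, rows)
}

#' Percent reduction in HPD width between two summaries of the same node
#'
#' `100 * (1 - width_constrained / width_unconstrained)`; negative when the
#' interval widened, 100 when the constrained interval has zero width.
#'
#' @param unconstrained,constrained numeric `c(lower, upper)` pairs, or
#'   single rows of [summarize_model()] output.
#' @return percent reduction.
#' @export
hpd_width_reduction <- function(unconstrained, constrained) {
  w <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      x$hpd_upper_ma - x$hpd_lower_ma
    } else {
      x <- as.numeric(x)
      stopifnot(length(x) == 2L)
      max(x) - min(x)
    }
  }
  wu <- w(unconstrained); wc <- w(constrained)
  if (wu == 0)
    abort_hgt("unconstrained interval has zero width; reduction undefined",
              "hgtclock_value_error")
  100 * (1 - wc / wu)
}
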
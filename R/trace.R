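#' Posterior traces of chronograms
#'
#' A `chronogram_trace` is the ordered collection of dated trees saved by one
#' dating run: one chronogram per saved MCMC point, all sharing a leaf set.
#' The trace remembers how many points it originally held (`n_saved`) and
#' whether burn-in has been applied.
#'
#' @param samples list of [chronogram] objects sharing an identical leaf set.
#' @param source character label recording provenance (file name, simulator
#'   seed, ...).
#' @param burnin_applied logical; has burn-in trimming already happened?
#' @param burnin_fraction fraction used, if applied.
#' @return an object of class `"chronogram_trace"`.
#' @export
chronogram_trace <- function(samples, source = "<in memory>",
                             burnin_applied = FALSE,
                             burnin_fraction = NA_real_) {
  if (length(samples) == 0L)
    abort_hgt("a trace must hold at least one chronogram",
              "hgtclock_empty_trace")
  if (!all(vapply(samples, inherits, logical(1), "chronogram")))
    abort_hgt("`samples` must be a list of chronogram objects",
              "hgtclock_type_error")
  ref <- sort(samples[[1L]]$phy$tip.label)
  for (i in seq_along(samples)) {
    if (!identical(sort(samples[[i]]$phy$tip.label), ref))
      abort_hgt(sprintf("sample %d has a different leaf set than sample 1", i),
                "hgtclock_leafset_mismatch")
  }
  structure(list(samples = samples, n_saved = length(samples),
                 source = source, burnin_applied = burnin_applied,
                 burnin_fraction = burnin_fraction),
            class = "chronogram_trace")
}

#' @export
print.chronogram_trace <- function(x, ...) {
  cat(sprintf("<chronogram_trace> %d samples (%d saved), %d tips, source: %s\n",
              length(x$samples), x$n_saved,
              ape::Ntip(x$samples[[1L]]$phy), x$source))
  cat(if (isTRUE(x$burnin_applied))
        sprintf("  burn-in applied (fraction %.3g)\n", x$burnin_fraction)
      else "  burn-in not applied\n")
  invisible(x)
}

#' Number of samples currently in a trace
#' @param x a `chronogram_trace`.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "chronogram_trace"))
  length(x$samples)
}

#' Read a datedist trace (one newick chronogram per line)
#'
#' Parses the newline-delimited newick dialect written by Bayesian dating
#' software: each line is one dated tree of the posterior, with branch
#' lengths as durations (Ma), so node ages are path sums down to the leaves.
#' A leading non-tree line (e.g. a sample count) is tolerated and skipped.
#'
#' @param file path to a datedist file, or `NULL` if `text` is given.
#' @param text optional character vector of lines, instead of a file.
#' @param on_violation passed to [chronogram()]: `"reject"` non-ultrametric
#'   trees or `"repair"` them by mean leaf path sums.
#' @param tol relative ultrametricity tolerance.
#' @param source label stored on the trace (defaults to the file name).
#' @return a [chronogram_trace].
#' @export
read_datedist <- function(file = NULL, text = NULL,
                          on_violation = c("reject", "repair"),
                          tol = 1e-6, source = NULL) {
  on_violation <- match.arg(on_violation)
  if (is.null(text)) {
    if (is.null(file))
      abort_hgt("supply `file` or `text`", "hgtclock_value_error")
    text <- readLines(file, warn = FALSE)
    source <- source %||% file
  }
  source <- source %||% "<text>"
  lines <- text[nzchar(trimws(text))]
  line_no <- seq_along(text)[nzchar(trimws(text))]
  if (length(lines) > 0L && !grepl("\\(", lines[1L])) {
    lines <- lines[-1L]          # header (e.g. a tree count)
    line_no <- line_no[-1L]
  }
  if (length(lines) == 0L)
    abort_hgt("no tree lines found in datedist input", "hgtclock_empty_trace")
  samples <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    phy <- tryCatch(ape::read.tree(text = lines[i]),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy) || !inherits(phy, "phylo"))
      abort_hgt(sprintf("malformed newick at line %d of %s",
                        line_no[i], source),
                "hgtclock_parse_error", line = line_no[i])
    samples[[i]] <- tryCatch(
      chronogram(phy, on_violation = on_violation, tol = tol),
      hgtclock_error = function(e) {
        abort_hgt(sprintf("line %d of %s: %s", line_no[i], source,
                          conditionMessage(e)),
                  class(e)[1L], line = line_no[i])
      })
  }
  chronogram_trace(samples, source = source)
}

#' Write a trace in the datedist dialect
#'
#' One newick tree per line, branch lengths recomputed from node ages so the
#' file round-trips through [read_datedist()] exactly.
#'
#' @param trace a [chronogram_trace].
#' @param file output path; `NULL` returns the lines invisibly instead.
#' @return invisibly, the character vector of lines written.
#' @export
write_datedist <- function(trace, file = NULL) {
  stopifnot(inherits(trace, "chronogram_trace"))
  lines <- vapply(trace$samples, function(s)
    ape::write.tree(as_dated_phylo(s), digits = 15), character(1))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# Subset the samples of a trace, preserving metadata and order.
subset_trace <- function(trace, idx) {
  out <- trace
  out$samples <- trace$samples[idx]
  out
}
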
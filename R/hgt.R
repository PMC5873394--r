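#' HGT relative time constraints
#'
#' A horizontal gene transfer from a donor lineage into a recipient lineage
#' requires the donor node to be strictly older than the recipient node. For
#' a transfer "from within" a donor clade the weakest safe reading is that
#' the donor clade's crown predates the recipient clade's crown, so both node
#' references default to crown selectors; either side can be overridden by
#' passing a [clade_definition] with a `stem` selector.
#'
#' @param name constraint name (e.g. `"SahH"`).
#' @param donor,recipient [clade_definition] objects.
#' @return an object of class `"hgt_constraint"`.
#' @export
hgt_constraint <- function(name, donor, recipient) {
  stopifnot(inherits(donor, "clade_definition"),
            inherits(recipient, "clade_definition"))
  if (setequal(donor$tips, recipient$tips) &&
      donor$selector == recipient$selector)
    abort_hgt(sprintf("constraint '%s': donor and recipient resolve to the same node",
                      name), "hgtclock_invalid_constraint")
  structure(list(name = as.character(name), donor = donor,
                 recipient = recipient),
            class = "hgt_constraint")
}

#' @export
print.hgt_constraint <- function(x, ...) {
  cat(sprintf("<hgt_constraint> %s: age(%s %s) > age(%s %s)\n", x$name,
              x$donor$selector, x$donor$name,
              x$recipient$selector, x$recipient$name))
  invisible(x)
}

#' Read HGT constraints from TSV
#'
#' Columns (no header): name, donor clade name, donor selector
#' (`crown`|`stem`), recipient clade name, recipient selector. Clade names
#' are looked up in `clades` (as returned by [read_clade_file()]); the
#' selector column overrides the clade's own selector.
#'
#' @param file path to the TSV file.
#' @param clades named list of [clade_definition] objects.
#' @return named list of [hgt_constraint] objects.
#' @export
read_constraint_file <- function(file, clades) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "",
                          col.names = c("name", "donor", "donor_selector",
                                        "recipient", "recipient_selector"))
  pick <- function(nm, sel) {
    if (!nm %in% names(clades))
      abort_hgt(sprintf("constraint references unknown clade '%s'", nm),
                "hgtclock_unknown_taxon")
    cl <- clades[[nm]]
    clade_definition(cl$name, cl$tips, sel)
  }
  out <- lapply(seq_len(nrow(df)), function(i)
    hgt_constraint(df$name[i],
                   pick(df$donor[i], df$donor_selector[i]),
                   pick(df$recipient[i], df$recipient_selector[i])))
  names(out) <- df$name
  out
}

#' Evaluate one constraint on one chronogram sample
#'
#' @param x a [chronogram].
#' @param constraint an [hgt_constraint].
#' @param strict monophyly requirement passed to [resolve_node()].
#' @return `TRUE` iff age(donor node) > age(recipient node), strictly; exact
#'   equality is `FALSE`.
#' @export
evaluate_constraint <- function(x, constraint, strict = TRUE) {
  stopifnot(inherits(constraint, "hgt_constraint"))
  dn <- tryCatch(resolve_node(x, constraint$donor, strict = strict),
                 hgtclock_error = function(e)
                   abort_hgt(sprintf("constraint '%s' (donor): %s",
                                     constraint$name, conditionMessage(e)),
                             class(e)[1L]))
  rn <- tryCatch(resolve_node(x, constraint$recipient, strict = strict),
                 hgtclock_error = function(e)
                   abort_hgt(sprintf("constraint '%s' (recipient): %s",
                                     constraint$name, conditionMessage(e)),
                             class(e)[1L]))
  if (dn == rn)
    abort_hgt(sprintf("constraint '%s': donor and recipient resolve to the same node in this sample",
                      constraint$name), "hgtclock_invalid_constraint")
  x$ages[dn] > x$ages[rn]
}

#' Conditional post-sampling of a posterior trace under HGT constraints
#'
#' Keeps exactly the samples in which every constraint holds (logical AND),
#' preserving sample order -- the rejection step that turns an unconstrained
#' posterior into an HGT-constrained one. The acceptance rate is reported
#' relative to the (post burn-in) sample count of the input trace. Zero
#' accepted samples is a prominent warning, not an error.
#'
#' @param trace a [chronogram_trace], normally already burn-in-trimmed (see
#'   [apply_burn_in()]); set `assume_trimmed = TRUE` to filter an untrimmed
#'   trace deliberately.
#' @param constraints list of [hgt_constraint] objects (may be empty).
#' @param strict monophyly requirement per sample.
#' @param assume_trimmed opt out of the burn-in precondition.
#' @return list with elements `result` (class `"hgt_filter_result"`: ordered
#'   `accepted` indices, `acceptance_rate`, `n_total`, named
#'   `per_constraint` satisfaction counts) and `trace` (the filtered
#'   [chronogram_trace]; zero samples allowed).
#' @export
filter_trace <- function(trace, constraints, strict = TRUE,
                         assume_trimmed = FALSE) {
  stopifnot(inherits(trace, "chronogram_trace"))
  if (!isTRUE(trace$burnin_applied) && !assume_trimmed)
    abort_hgt("trace has not been burn-in-trimmed; call apply_burn_in() first or pass assume_trimmed = TRUE",
              "hgtclock_value_error")
  if (inherits(constraints, "hgt_constraint")) constraints <- list(constraints)
  n <- length(trace$samples)
  sat <- matrix(TRUE, nrow = n, ncol = length(constraints))
  for (j in seq_along(constraints)) {
    sat[, j] <- vapply(trace$samples, evaluate_constraint, logical(1),
                       constraint = constraints[[j]], strict = strict)
  }
  ok <- if (ncol(sat) == 0L) rep(TRUE, n) else rowSums(sat) == ncol(sat)
  accepted <- which(ok)
  per_con <- colSums(sat)
  names(per_con) <- vapply(constraints, `[[`, character(1), "name")
  result <- structure(
    list(accepted = accepted,
         acceptance_rate = length(accepted) / n,
         n_total = n, per_constraint = per_con),
    class = "hgt_filter_result")
  out <- subset_trace(trace, accepted)
  if (length(accepted) == 0L)
    warn_hgt("no posterior samples satisfy the HGT constraints; the filtered trace is empty",
             "hgtclock_empty_filter")
  list(result = result, trace = out)
}

#' @export
print.hgt_filter_result <- function(x, ...) {
  cat(sprintf("<hgt_filter_result> %d / %d samples accepted (rate %.4f)\n",
              length(x$accepted), x$n_total, x$acceptance_rate))
  if (length(x$per_constraint))
    for (nm in names(x$per_constraint))
      cat(sprintf("  %s satisfied in %d samples\n", nm, x$per_constraint[[nm]]))
  invisible(x)
}
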
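#' Hard node-age calibrations
#'
#' A calibration attaches a hard maximum and/or minimum age (Ma) to the crown
#' MRCA of a pair of taxa (the two-taxon convention of common dating
#' software) or to a named clade. In the calibration-file dialect the first
#' column pair is "upper limit" = maximum age and "lower limit" = minimum
#' age, with `-1` as the no-bound sentinel: fossil minima have upper `-1`,
#' geochemical maxima have lower `-1`.
#'
#' @param label human-readable label.
#' @param taxon_a,taxon_b leaf labels whose MRCA is calibrated (a single
#'   taxon repeated is allowed), or pass `clade` instead.
#' @param max_age maximum age in Ma (`NA` or `-1` = no bound).
#' @param min_age minimum age in Ma (`NA` or `-1` = no bound).
#' @param clade optional [clade_definition] to calibrate instead of a pair.
#' @return an object of class `"calibration"`.
#' @export
calibration <- function(label, taxon_a = NULL, taxon_b = taxon_a,
                        max_age = NA_real_, min_age = NA_real_,
                        clade = NULL) {
  max_age <- sentinel_na(max_age)
  min_age <- sentinel_na(min_age)
  if (!is.na(max_age) && !is.na(min_age) && max_age < min_age)
    abort_hgt(sprintf("calibration '%s': maximum age %.6g Ma < minimum age %.6g Ma",
                      label, max_age, min_age), "hgtclock_value_error")
  if (is.null(clade)) {
    if (is.null(taxon_a))
      abort_hgt("supply a taxon pair or a clade definition",
                "hgtclock_value_error")
    clade <- clade_definition(label, unique(c(taxon_a, taxon_b)), "crown")
  }
  structure(list(label = as.character(label), clade = clade,
                 max_age = max_age, min_age = min_age),
            class = "calibration")
}

sentinel_na <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 1L) abort_hgt("age limits must be scalars",
                                 "hgtclock_value_error")
  if (!is.na(x) && x == -1) NA_real_ else x
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %s: [%s, %s] Ma on crown {%s}\n", x$label,
              ifelse(is.na(x$min_age), "-", format(x$min_age)),
              ifelse(is.na(x$max_age), "-", format(x$max_age)),
              paste(x$clade$tips, collapse = ", ")))
  invisible(x)
}

#' Read a calibration file
#'
#' Dialect: first line is the calibration count; each subsequent line is
#' `taxonA taxonB upper lower` (whitespace-delimited), where upper/lower are
#' the maximum/minimum node age in Ma and `-1` means no bound.
#'
#' @param file path, or `text` lines.
#' @param text optional character vector instead of a file.
#' @return list of [calibration] objects.
#' @export
read_calibration_file <- function(file = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  lines <- trimws(text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    abort_hgt("empty calibration file", "hgtclock_format_error")
  count <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(count))
    abort_hgt("first line of a calibration file must be the calibration count",
              "hgtclock_format_error")
  body <- lines[-1L]
  if (length(body) != count)
    abort_hgt(sprintf("calibration count mismatch: header says %d, file has %d line(s)",
                      count, length(body)), "hgtclock_format_error")
  lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "[ \t]+")[[1L]]
    if (length(f) != 4L)
      abort_hgt(sprintf("calibration line %d: expected 'taxonA taxonB upper lower', got %d field(s)",
                        i, length(f)), "hgtclock_format_error")
    lim <- suppressWarnings(as.numeric(f[3:4]))
    if (anyNA(lim))
      abort_hgt(sprintf("calibration line %d: non-numeric age limit", i),
                "hgtclock_format_error")
    calibration(label = paste(f[1L], f[2L], sep = "+"),
                taxon_a = f[1L], taxon_b = f[2L],
                max_age = lim[1L], min_age = lim[2L])
  })
}

#' Write calibrations in the same dialect read by [read_calibration_file()]
#' @param calibrations list of [calibration] objects (two-taxon form).
#' @param file optional output path.
#' @return invisibly, the lines.
#' @export
write_calibration_file <- function(calibrations, file = NULL) {
  fmt <- function(x) if (is.na(x)) "-1" else format(x, scientific = FALSE)
  lines <- c(as.character(length(calibrations)),
             vapply(calibrations, function(cal) {
               tips <- cal$clade$tips
               paste(tips[1L], tips[min(2L, length(tips))],
                     fmt(cal$max_age), fmt(cal$min_age))
             }, character(1)))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Root-age priors
#'
#' `"flat"` is uniform between an older and a younger hard bound; `"gamma"`
#' is a gamma distribution parameterized by mean and SD (shape = mean^2/SD^2,
#' scale = SD^2/mean), which keeps ages positive; `"normal"` is a normal with
#' the given mean and SD. Only the flat prior imposes hard bounds that
#' [check_sample()] audits.
#'
#' @param shape `"flat"`, `"gamma"` or `"normal"`.
#' @param older,younger flat bounds in Ma (older > younger).
#' @param mean,sd gamma/normal parameters in Ma.
#' @return an object of class `"root_prior"`.
#' @export
root_prior <- function(shape = c("flat", "gamma", "normal"),
                       older = NULL, younger = NULL,
                       mean = NULL, sd = NULL) {
  shape <- match.arg(shape)
  if (shape == "flat") {
    if (is.null(older) || is.null(younger) || older <= younger)
      abort_hgt("flat root prior needs older > younger bounds (Ma)",
                "hgtclock_value_error")
    out <- list(shape = shape, older = older, younger = younger)
  } else {
    if (is.null(mean) || is.null(sd) || mean <= 0 || sd <= 0)
      abort_hgt(sprintf("%s root prior needs mean > 0 and sd > 0", shape),
                "hgtclock_value_error")
    out <- list(shape = shape, mean = mean, sd = sd)
  }
  structure(out, class = "root_prior")
}

#' @export
print.root_prior <- function(x, ...) {
  cat(if (x$shape == "flat")
        sprintf("<root_prior> flat on [%.6g, %.6g] Ma\n", x$younger, x$older)
      else sprintf("<root_prior> %s(mean %.6g Ma, sd %.6g Ma)\n",
                   x$shape, x$mean, x$sd))
  invisible(x)
}

#' Audit one chronogram sample against hard calibration bounds
#'
#' Reports a violation for every calibrated node whose age exceeds its
#' maximum or falls below its minimum, and (for a flat root prior) a root age
#' outside the flat bounds. Gamma/normal root priors impose no hard bound and
#' never generate violations.
#'
#' @param x a [chronogram].
#' @param calibrations list of [calibration] objects.
#' @param prior optional [root_prior].
#' @param strict monophyly requirement passed to [resolve_node()]; defaults
#'   to `FALSE` because a two-taxon calibration names a node by its MRCA, not
#'   a claimed monophyletic group.
#' @return data frame with columns `label`, `node_age`, `bound`
#'   (`"max"`, `"min"`, `"root_flat"`), `limit`; zero rows when clean.
#' @export
check_sample <- function(x, calibrations = list(), prior = NULL,
                         strict = FALSE) {
  stopifnot(inherits(x, "chronogram"))
  rows <- list()
  for (cal in calibrations) {
    age <- x$ages[resolve_node(x, cal$clade, strict = strict)]
    if (!is.na(cal$max_age) && age > cal$max_age)
      rows[[length(rows) + 1L]] <- data.frame(
        label = cal$label, node_age = age, bound = "max",
        limit = cal$max_age, stringsAsFactors = FALSE)
    if (!is.na(cal$min_age) && age < cal$min_age)
      rows[[length(rows) + 1L]] <- data.frame(
        label = cal$label, node_age = age, bound = "min",
        limit = cal$min_age, stringsAsFactors = FALSE)
  }
  if (!is.null(prior) && prior$shape == "flat") {
    ra <- root_age(x)
    if (ra > prior$older || ra < prior$younger)
      rows[[length(rows) + 1L]] <- data.frame(
        label = "root", node_age = ra, bound = "root_flat",
        limit = if (ra > prior$older) prior$older else prior$younger,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    data.frame(label = character(0), node_age = numeric(0),
               bound = character(0), limit = numeric(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
}

#' Mechanical prerequisite check for an index HGT
#'
#' An HGT can propagate absolute time information ("index HGT") when (i) the
#' transfer topology is well resolved within the donor lineage, (ii) donor
#' and recipient clade phylogenies are congruent with their species trees,
#' and (iii) an absolute date calibration is associated with the donor or
#' (ideally) the recipient crown group. Criteria (i) and (ii) concern gene
#' trees this package does not see, so they are emitted as unconditional
#' documentation notices; criterion (iii) is evaluated against the supplied
#' calibrations: a calibration is "associated with" a clade when all its
#' taxa fall inside the clade's leaf set.
#'
#' @param constraint an [hgt_constraint].
#' @param calibrations list of [calibration] objects.
#' @return data frame with columns `level` (`"note"`, `"info"`, `"warning"`),
#'   `criterion`, `message`.
#' @export
check_index_hgt <- function(constraint, calibrations = list()) {
  stopifnot(inherits(constraint, "hgt_constraint"))
  donor <- constraint$donor; recipient <- constraint$recipient
  if (setequal(donor$tips, recipient$tips))
    abort_hgt(sprintf("constraint '%s': donor and recipient clades are identical",
                      constraint$name), "hgtclock_invalid_constraint")
  inside <- function(cal, clade) all(cal$clade$tips %in% clade$tips)
  don_cal <- any(vapply(calibrations, inside, logical(1), clade = donor))
  rec_cal <- any(vapply(calibrations, inside, logical(1), clade = recipient))
  rows <- data.frame(
    level = c("note", "note"),
    criterion = c("i", "ii"),
    message = c("verify that the transfer topology is well supported within the donor lineage (gene-tree evidence, not checked here)",
                "verify that donor and recipient clade phylogenies are congruent with the species tree (gene-tree evidence, not checked here)"),
    stringsAsFactors = FALSE)
  if (!don_cal && !rec_cal) {
    rows <- rbind(rows, data.frame(
      level = "warning", criterion = "iii",
      message = sprintf("constraint '%s': neither the donor nor the recipient crown group contains a calibrated node; the HGT cannot propagate absolute time information",
                        constraint$name), stringsAsFactors = FALSE))
  } else if (don_cal && !rec_cal) {
    rows <- rbind(rows, data.frame(
      level = "info", criterion = "iii",
      message = sprintf("constraint '%s': only the donor side is calibrated; a recipient-side calibration is preferable",
                        constraint$name), stringsAsFactors = FALSE))
  }
  rows
}
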
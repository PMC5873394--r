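#' Bundled synthetic phototroph example
#'
#' A synthetic 18-taxon chronogram emulating the clade structure of the
#' phototroph dating analyses (Cyanobacteria with Gloeobacter basal,
#' Melainabacteria and Sericytochromatia outgroups, green non-sulfur bacteria
#' nested in Chloroflexi, green sulfur bacteria with Ignavibacteria and
#' Bacteroidetes, one Alphaproteobacterium), with node ages set to the
#' published Model-D medians where a published value exists. It is a
#' generated stand-in, not study data: use it to seed
#' [simulate_posterior_trace()] for worked examples and tests. Ships with
#' matching clade definitions, the SahH and BchH constraint tables, and
#' calibration files for both akinete minimum ages.
#'
#' @return list with elements `truth` (a [chronogram]), `clades` (named list
#'   of [clade_definition]), `constraints` (named list of [hgt_constraint]:
#'   SahH, BchH), `calibrations_1200`, `calibrations_1600` (lists of
#'   [calibration]).
#' @export
phototroph_example <- function() {
  ext <- function(f) system.file("extdata", f, package = "hgtclock",
                                 mustWork = TRUE)
  truth <- chronogram(ape::read.tree(ext("phototroph_example.tree")))
  clades <- read_clade_file(ext("phototroph_clades.tsv"))
  constraints <- read_constraint_file(ext("phototroph_constraints.tsv"),
                                      clades)
  list(truth = truth,
       clades = clades,
       constraints = constraints,
       calibrations_1200 = read_calibration_file(ext("calibrations_akinete1200.txt")),
       calibrations_1600 = read_calibration_file(ext("calibrations_akinete1600.txt")))
}
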
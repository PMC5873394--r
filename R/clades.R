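#' Clade definitions: named leaf sets with a crown/stem selector
#'
#' A clade is a named set of leaf labels plus a selector: `"crown"` picks the
#' most recent common ancestor (MRCA) of the leaves; `"stem"` picks the
#' parent of that MRCA, i.e. the divergence from the clade's sister lineage.
#' Stem age is therefore always older than crown age.
#'
#' @param name clade name.
#' @param tips character vector of leaf labels (non-empty, unique).
#' @param selector `"crown"` (default) or `"stem"`.
#' @return an object of class `"clade_definition"`.
#' @export
clade_definition <- function(name, tips, selector = c("crown", "stem")) {
  selector <- match.arg(selector)
  tips <- unique(as.character(tips))
  if (length(tips) == 0L || any(!nzchar(tips)))
    abort_hgt("a clade needs at least one non-empty leaf label",
              "hgtclock_value_error")
  structure(list(name = as.character(name), tips = tips, selector = selector),
            class = "clade_definition")
}

#' @export
print.clade_definition <- function(x, ...) {
  cat(sprintf("<clade> %s [%s] %d tips: %s\n", x$name, x$selector,
              length(x$tips), paste(utils::head(x$tips, 5), collapse = ", ")))
  invisible(x)
}

#' Read clade definitions from TSV
#'
#' Expected columns (no header): name, selector (`crown`|`stem`),
#' comma-separated leaf labels.
#'
#' @param file path to the TSV file.
#' @return named list of [clade_definition] objects.
#' @export
read_clade_file <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "selector", "tips"),
                          comment.char = "#", quote = "")
  out <- lapply(seq_len(nrow(df)), function(i)
    clade_definition(df$name[i], strsplit(df$tips[i], ",")[[1L]],
                     df$selector[i]))
  names(out) <- df$name
  out
}

# Tips descended from an internal node (or the tip itself).
tips_under <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- phangorn_descendants(phy, node)
  phy$tip.label[kids[kids <= ntip]]
}

# All descendants of `node` (tips and internal), via edge traversal.
phangorn_descendants <- function(phy, node) {
  out <- integer(0)
  stack <- node
  edge <- phy$edge
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ch <- edge[edge[, 1L] == v, 2L]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > ape::Ntip(phy)])
  }
  out
}

node_parent <- function(phy, node) {
  i <- match(node, phy$edge[, 2L])
  if (is.na(i)) NA_integer_ else phy$edge[i, 1L]
}

#' Resolve a clade definition to a node of one chronogram sample
#'
#' `crown` resolves to the MRCA of the clade's leaves; `stem` to the parent
#' of that MRCA. By default the leaf set must be monophyletic in this sample
#' (the MRCA subtends exactly the clade's leaves); set `strict = FALSE` to
#' fall back to the MRCA regardless.
#'
#' @param x a [chronogram].
#' @param clade a [clade_definition].
#' @param strict require monophyly (default `TRUE`).
#' @return integer node id (in `phylo` numbering).
#' @export
resolve_node <- function(x, clade, strict = TRUE) {
  stopifnot(inherits(x, "chronogram"), inherits(clade, "clade_definition"))
  phy <- x$phy
  missing <- setdiff(clade$tips, phy$tip.label)
  if (length(missing) > 0L)
    abort_hgt(sprintf("clade '%s' references leaf label(s) absent from the tree: %s",
                      clade$name, paste(missing, collapse = ", ")),
              "hgtclock_unknown_taxon")
  mrca <- if (length(clade$tips) == 1L) {
    match(clade$tips, phy$tip.label)
  } else {
    ape::getMRCA(phy, clade$tips)
  }
  if (strict && length(clade$tips) > 1L) {
    sub <- tips_under(phy, mrca)
    if (!setequal(sub, clade$tips))
      abort_hgt(sprintf(
        "clade '%s' is not monophyletic in this sample (MRCA subtends %d leaves, clade has %d); use strict = FALSE to accept the MRCA",
        clade$name, length(sub), length(clade$tips)),
        "hgtclock_not_monophyletic")
  }
  if (clade$selector == "stem") {
    if (mrca == root_node(phy))
      abort_hgt(sprintf("clade '%s': crown MRCA is the root, so no stem node exists",
                        clade$name), "hgtclock_no_stem")
    mrca <- node_parent(phy, mrca)
  }
  as.integer(mrca)
}

#' Extract the per-sample age of a clade's node across a trace
#'
#' Applies [resolve_node()] to every sample and returns the ages in sample
#' order. Errors in individual samples are re-raised annotated with the
#' sample index.
#'
#' @param trace a [chronogram_trace].
#' @param clade a [clade_definition].
#' @param strict require monophyly per sample (default `TRUE`).
#' @return an `age_trace`: list with `name` and numeric `ages` (Ma).
#' @export
clade_age_trace <- function(trace, clade, strict = TRUE) {
  stopifnot(inherits(trace, "chronogram_trace"))
  ages <- vapply(seq_along(trace$samples), function(i) {
    tryCatch({
      s <- trace$samples[[i]]
      s$ages[resolve_node(s, clade, strict = strict)]
    }, hgtclock_error = function(e) {
      abort_hgt(sprintf("sample %d: %s", i, conditionMessage(e)),
                class(e)[1L], sample = i)
    })
  }, numeric(1))
  age_trace(clade$name, ages)
}

#' @rdname clade_age_trace
#' @param name node name carried by the age trace.
#' @export
age_trace <- function(name, ages) {
  ages <- as.numeric(ages)
  if (any(ages < 0))
    abort_hgt("ages must be non-negative", "hgtclock_value_error")
  structure(list(name = as.character(name), ages = ages), class = "age_trace")
}

#' @export
print.age_trace <- function(x, ...) {
  cat(sprintf("<age_trace> %s: %d samples, median %.4g Ma\n",
              x$name, length(x$ages), stats::median(x$ages)))
  invisible(x)
}

# Accept an age_trace or a bare numeric vector.
as_ages <- function(x) {
  if (inherits(x, "age_trace")) x$ages else as.numeric(x)
}
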
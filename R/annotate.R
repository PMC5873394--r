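#' Write a summary-annotated tree
#'
#' Renders per-node summary values on a fixed topology. The newick form uses
#' median ages as node ages (branch lengths become differences of medians, so
#' path sums reproduce the medians and the output round-trips through
#' [read_datedist()]). The NEXUS form additionally carries FigTree-compatible
#' bracketed comments `[&median=..,hpd_lower=..,hpd_upper=..]` on every
#' internal node.
#'
#' @param phy a rooted `phylo` topology.
#' @param rows data frame with one row per internal node: columns `node_id`
#'   (internal node ids in `phylo` numbering), `median_ma`, and for NEXUS
#'   `hpd_lower_ma`, `hpd_upper_ma`.
#' @param format `"newick"` or `"nexus"`.
#' @param file optional output path.
#' @return invisibly, the character vector of lines.
#' @export
write_annotated_tree <- function(phy, rows, format = c("newick", "nexus"),
                                 file = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(phy, "phylo"))
  ntip <- ape::Ntip(phy)
  internal <- ntip + seq_len(phy$Nnode)
  if (!all(c("node_id", "median_ma") %in% names(rows)))
    abort_hgt("`rows` needs columns node_id and median_ma",
              "hgtclock_annotation_mismatch")
  if (!setequal(rows$node_id, internal))
    abort_hgt(sprintf(
      "summary rows must cover each internal node exactly once (%d internal nodes, %d distinct rows)",
      length(internal), length(unique(rows$node_id))),
      "hgtclock_annotation_mismatch")
  ages <- numeric(ntip + phy$Nnode)
  ages[rows$node_id] <- rows$median_ma
  chron <- new_chronogram(phy, ages)   # validates ordering of the medians

  lines <- if (format == "newick") {
    ape::write.tree(as_dated_phylo(chron), digits = 15)
  } else {
    has_hpd <- all(c("hpd_lower_ma", "hpd_upper_ma") %in% names(rows))
    ann <- rep("", ntip + phy$Nnode)
    for (i in seq_len(nrow(rows))) {
      v <- rows$node_id[i]
      ann[v] <- if (has_hpd)
        sprintf("[&median=%.15g,hpd_lower=%.15g,hpd_upper=%.15g]",
                rows$median_ma[i], rows$hpd_lower_ma[i], rows$hpd_upper_ma[i])
      else sprintf("[&median=%.15g]", rows$median_ma[i])
    }
    nwk <- newick_with_comments(phy, ages, ann)
    c("#NEXUS", "begin trees;",
      paste0("\ttree SUMMARY = [&R] ", nwk), "end;")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# Recursive newick writer with per-node comment strings.
newick_with_comments <- function(phy, ages, ann) {
  ntip <- ape::Ntip(phy)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  rec <- function(v, parent_age) {
    bl <- if (is.na(parent_age)) "" else
      sprintf(":%.15g", parent_age - ages[v])
    if (v <= ntip) return(paste0(phy$tip.label[v], ann[v], bl))
    kids <- children[[as.character(v)]]
    paste0("(", paste(vapply(kids, rec, character(1), parent_age = ages[v]),
                      collapse = ","),
           ")", ann[v], bl)
  }
  paste0(rec(ntip + 1L, NA_real_), ";")
}
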
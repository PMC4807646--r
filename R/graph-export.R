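#' Render a regression graph as DOT text
#'
#' Boxes are emitted as DOT clusters; with `rankdir = RL` the background
#' (context) boxes appear on the right and the ultimate-response box on the
#' left, matching the conventional right-to-left reading of regression
#' graphs. Arrows are solid and directed; within-box response edges are
#' dashed and undirected; context full lines are solid and undirected.
#'
#' @param g A [regression_graph()].
#' @param fit_annotations Optional named list mapping `"from->to"` edge keys
#'   to label strings (e.g. `"0.46 (0.17, 0.76); p=0.002"`).
#' @return A single string of DOT source.
#' @export
to_dot <- function(g, fit_annotations = NULL) {
  lines <- c("digraph regression_graph {", "  rankdir=RL;",
             "  node [shape=ellipse];")
  boxes <- sort(unique(g$box))
  for (b in boxes) {
    members <- g$nodes[g$box[g$nodes] == b]
    kind <- g$kind[[members[[1L]]]]
    lines <- c(lines,
               sprintf("  subgraph cluster_box%d {", b),
               sprintf("    label=\"box %d (%s)\";", b, kind),
               paste0("    \"", members, "\";"),
               "  }")
  }
  lab <- function(from, to) {
    key <- paste0(from, "->", to)
    if (!is.null(fit_annotations) && !is.null(fit_annotations[[key]]))
      sprintf(" [label=\"%s\"]", fit_annotations[[key]]) else ""
  }
  for (i in seq_len(nrow(g$arrows)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;",
                              g$arrows[i, 1L], g$arrows[i, 2L],
                              lab(g$arrows[i, 1L], g$arrows[i, 2L])))
  for (i in seq_len(nrow(g$dashed)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [dir=none, style=dashed];",
                              g$dashed[i, 1L], g$dashed[i, 2L]))
  for (i in seq_len(nrow(g$full)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [dir=none, style=solid, constraint=false];",
                              g$full[i, 1L], g$full[i, 2L]))
  paste(c(lines, "}"), collapse = "\n")
}

#' Parse the edge list back out of DOT text emitted by [to_dot()]
#'
#' A convenience for round-trip checks; only understands the subset of DOT
#' this package writes.
#'
#' @param dot DOT source string from [to_dot()].
#' @return A list with `arrows`, `dashed`, `full` two-column matrices.
#' @export
parse_dot_edges <- function(dot) {
  lines <- strsplit(dot, "\n", fixed = TRUE)[[1L]]
  edge_re <- "^\\s*\"([^\"]+)\"\\s*->\\s*\"([^\"]+)\"\\s*(\\[[^]]*\\])?;"
  m <- regmatches(lines, regexec(edge_re, lines))
  arrows <- dashed <- full <- matrix(character(0), ncol = 2L,
                                     dimnames = list(NULL, c("from", "to")))
  for (hit in m) {
    if (length(hit) == 0L) next
    from <- hit[[2L]]; to <- hit[[3L]]; attrs <- hit[[4L]]
    row <- matrix(c(from, to), ncol = 2L)
    if (grepl("style=dashed", attrs)) dashed <- rbind(dashed, row)
    else if (grepl("dir=none", attrs)) full <- rbind(full, row)
    else arrows <- rbind(arrows, row)
  }
  list(arrows = arrows, dashed = canonical_pairs(dashed),
       full = canonical_pairs(full))
}

#' Export a regression graph to GraphML
#'
#' Nodes carry `box` and `kind` attributes; edges carry `kind`
#' (`arrow`/`dashed`/`full`) and, when `fit` is supplied, `beta`, `ci_low`,
#' `ci_high` and `p` attributes taken from the fitted node models.
#'
#' @param g A [regression_graph()].
#' @param path Output file path.
#' @param fit Optional `sequence_fit` whose models annotate the arrows.
#' @return `path`, invisibly.
#' @export
to_graphml <- function(g, path, fit = NULL) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           '<key id="box" for="node" attr.name="box" attr.type="int"/>',
           '<key id="nkind" for="node" attr.name="kind" attr.type="string"/>',
           '<key id="ekind" for="edge" attr.name="kind" attr.type="string"/>',
           '<key id="beta" for="edge" attr.name="beta" attr.type="double"/>',
           '<key id="ci_low" for="edge" attr.name="ci_low" attr.type="double"/>',
           '<key id="ci_high" for="edge" attr.name="ci_high" attr.type="double"/>',
           '<key id="p" for="edge" attr.name="p" attr.type="double"/>',
           '<graph edgedefault="directed">')
  for (nd in g$nodes)
    out <- c(out, sprintf('<node id="%s"><data key="box">%d</data><data key="nkind">%s</data></node>',
                          esc(nd), g$box[[nd]], g$kind[[nd]]))
  arrow_stats <- function(from, to) {
    if (is.null(fit)) return("")
    mod <- fit$models[[to]]
    if (is.null(mod)) return("")
    hit <- which(vapply(mod$terms, function(tm)
      tm$kind == "main" && identical(tm$variables, from), logical(1)))
    if (!length(hit)) return("")
    i <- hit[[1L]]
    sprintf('<data key="beta">%.10g</data><data key="ci_low">%.10g</data><data key="ci_high">%.10g</data><data key="p">%.10g</data>',
            mod$beta[i], mod$ci_low[i], mod$ci_high[i], mod$p[i])
  }
  emit_edges <- function(mat, kind) {
    for (i in seq_len(nrow(mat))) {
      extra <- if (kind == "arrow") arrow_stats(mat[i, 1L], mat[i, 2L]) else ""
      out <<- c(out, sprintf('<edge source="%s" target="%s"><data key="ekind">%s</data>%s</edge>',
                             esc(mat[i, 1L]), esc(mat[i, 2L]), kind, extra))
    }
  }
  emit_edges(g$arrows, "arrow")
  emit_edges(g$dashed, "dashed")
  emit_edges(g$full, "full")
  writeLines(c(out, "</graph>", "</graphml>"), path)
  invisible(path)
}
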
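#' Read a Lotka-Volterra system from disk
#'
#' Accepts either a headerless delimited matrix file (CSV or TSV, one row per
#' species, delimiter inferred from the extension) with an optional companion
#' growth-rate file, or a single JSON document
#' `{"A": [[...]], "b": [...], "labels": [...]}`. When no growth rates are
#' supplied they default to all ones, the convention used by all the worked
#' examples.
#'
#' @param path Path to the matrix file (`.csv`/`.tsv`/`.txt`) or JSON
#'   document (`.json`).
#' @param b_path Optional path to a delimited growth-rate vector.
#' @return A list with elements `A` (matrix), `b` (vector) and `labels`
#'   (character, defaulting to `"1".."n"`).
#' @export
read_system <- function(path, b_path = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.null(doc$A)) abort(sprintf("%s: JSON document lacks an \"A\" field.", path))
    A <- as_interaction_matrix(doc$A, sprintf("%s:A", path))
    b <- as_growth_rates(doc$b %||% 1, nrow(A), sprintf("%s:b", path))
    labels <- doc$labels %||% as.character(seq_len(nrow(A)))
  } else {
    A <- as.matrix(read_delim_matrix(path))
    A <- as_interaction_matrix(A, path)
    b <- if (!is.null(b_path)) {
      bv <- unlist(read_delim_matrix(b_path), use.names = FALSE)
      as_growth_rates(bv, nrow(A), b_path)
    } else {
      rep(1, nrow(A))
    }
    labels <- as.character(seq_len(nrow(A)))
  }
  if (length(labels) != nrow(A)) abort(sprintf("%s: labels length mismatch.", path))
  list(A = A, b = b, labels = labels)
}

read_delim_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  delim <- if (ext %in% c("tsv", "txt")) "\t" else ","
  # base strtod parsing is correctly rounded, so write/read round trips of
  # %.17g output are bit-exact
  chr <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  num <- matrix(suppressWarnings(as.numeric(as.matrix(chr))),
                nrow = nrow(chr))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, , drop = TRUE]
    abort(sprintf("%s: non-numeric or missing entry at row %d, column %d.",
                  path, bad[[1L]], bad[[2L]]))
  }
  num
}

#' Write a Lotka-Volterra system to disk
#'
#' Writes the system both ways: a JSON document at `<stem>.json` and a
#' headerless CSV matrix at `<stem>.csv` with growth rates at `<stem>_b.csv`.
#' Numbers are serialized at full double precision so a write-read round trip
#' is exact.
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled).
#' @param stem Output path without extension.
#' @param labels Optional species labels (default `"1".."n"`).
#' @return Invisibly, the character vector of files written.
#' @export
write_system <- function(A, b = 1, stem, labels = NULL) {
  A <- as_interaction_matrix(A)
  b <- as_growth_rates(b, nrow(A))
  labels <- labels %||% as.character(seq_len(nrow(A)))
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(
    list(A = A, b = b, labels = labels),
    json_path, digits = I(17), auto_unbox = FALSE
  )
  csv_path <- paste0(stem, ".csv")
  writeLines(apply(A, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  }), csv_path)
  b_path <- paste0(stem, "_b.csv")
  writeLines(sprintf("%.17g", b), b_path)
  invisible(c(json_path, csv_path, b_path))
}

#' Export an invasion graph to DOT or GraphML
#'
#' Writes the graph with community labels of the form `"(1,2,3)"`. In DOT
#' output, edges belonging to a cycle (any strongly connected component of
#' size above one) are coloured red.
#'
#' @param g An `lv_igraph`.
#' @param path Output file; format from the extension (`.dot`/`.gv` or
#'   `.graphml`).
#' @param include_empty Draw the empty-community node (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_ig <- function(g, path, include_empty = TRUE) {
  stopifnot(inherits(g, "lv_igraph"))
  nodes <- g$nodes
  edges <- g$edges
  if (!include_empty) {
    nodes <- nodes[nodes$dim > 0L, ]
    edges <- edges[edges$from %in% nodes$label & edges$to %in% nodes$label, ]
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dot", "gv")) {
    comp <- igraph::components(g$graph, mode = "strong")
    member <- setNames(comp$membership, g$nodes$label)
    scc_size <- tabulate(comp$membership, nbins = comp$no)
    lines <- c("digraph IG {", "  rankdir=BT;")
    for (lb in nodes$label) {
      lines <- c(lines, sprintf("  \"%s\";", lb))
    }
    if (nrow(edges) > 0L) {
      for (r in seq_len(nrow(edges))) {
        f <- edges$from[r]; t <- edges$to[r]
        cyclic <- member[[f]] == member[[t]] && scc_size[member[[f]]] > 1L
        attr <- if (cyclic) " [color=red]" else ""
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", f, t, attr))
      }
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else if (ext == "graphml") {
    gg <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                        directed = TRUE,
                                        vertices = nodes["label"])
    igraph::write_graph(gg, path, format = "graphml")
  } else {
    abort(sprintf("unsupported graph format: .%s (use .dot or .graphml)", ext))
  }
  invisible(path)
}

#' Export a community catalog
#'
#' Writes the catalog as JSON (per-community abundances, invasion rates and
#' the rejected communities with reasons) and optionally as a TSV table with
#' one row per (community, species) pair.
#'
#' @param catalog An `lv_catalog`.
#' @param json_path Output JSON file.
#' @param tsv_path Optional output TSV file (the [tidy()] long table).
#' @return Invisibly, the files written.
#' @export
write_catalog <- function(catalog, json_path, tsv_path = NULL) {
  stopifnot(inherits(catalog, "lv_catalog"))
  doc <- list(
    n = attr(catalog, "n"),
    b = attr(catalog, "b"),
    admissible = purrr::map(seq_len(nrow(catalog)), function(i) {
      list(community = catalog$community[[i]],
           label = catalog$label[i],
           u = catalog$u[[i]],
           rates = catalog$rates[[i]])
    }),
    rejected = purrr::map(seq_len(nrow(attr(catalog, "rejected"))), function(i) {
      rj <- attr(catalog, "rejected")
      list(community = rj$community[[i]], label = rj$label[i],
           reason = rj$reason[i])
    })
  )
  jsonlite::write_json(doc, json_path, digits = NA, auto_unbox = TRUE)
  written <- json_path
  if (!is.null(tsv_path)) {
    readr::write_tsv(tidy(catalog), tsv_path)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
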
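#' Merge target lists with per-source provenance
#'
#' Unions gene/protein symbol lists (e.g. network-pharmacology predictions
#' and TPP-significant proteins), normalizing symbols to uppercase and
#' recording which sources contributed each one, so intersections are
#' derivable.
#'
#' @param ... Named character vectors of symbols (or a single named list).
#' @return Tibble of `symbol`, `sources` (comma-separated), `n_sources`.
#' @examples
#' merge_target_lists(pred = c("TNF", "ADAM17"), tpp = c("Adam17", "NFKB1"))
#' @export
merge_target_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  if (length(lists) == 0) {
    abort("need at least one target list", class = "tppshift_input_error")
  }
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("list", seq_along(lists))
  }
  rows <- purrr::imap(lists, function(symbols, src) {
    tibble::tibble(symbol = unique(normalize_symbol(symbols)), source = src)
  }) |> dplyr::bind_rows()
  rows <- dplyr::filter(rows, nzchar(.data$symbol))
  if (nrow(rows) == 0) {
    warn("all target lists are empty")
    return(tibble::tibble(symbol = character(), sources = character(),
                          n_sources = integer()))
  }
  rows |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(sources = paste(unique(.data$source), collapse = ","),
                     n_sources = dplyr::n_distinct(.data$source),
                     .groups = "drop") |>
    dplyr::arrange(.data$symbol)
}

normalize_symbol <- function(x) toupper(trimws(as.character(x)))

#' Build an interaction network from an edge list
#'
#' Undirected simple graph: symbols are uppercased, self-loops dropped,
#' duplicate and reversed edges collapsed. Nodes beyond the edge list can
#' be supplied so that isolates are representable.
#'
#' @param edges Data frame whose first two columns are interacting
#'   symbols (extra columns, e.g. confidence scores, are ignored).
#' @param nodes Optional character vector of additional node symbols.
#' @return A `tpp_network` object wrapping an igraph graph.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("`edges` must be a data frame with two symbol columns",
          class = "tppshift_input_error")
  }
  a <- normalize_symbol(edges[[1]])
  b <- normalize_symbol(edges[[2]])
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  vertices <- unique(c(a, b, normalize_symbol(nodes %||% character())))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b)[a != b, , drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = vertices))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g), class = "tpp_network")
}

#' @export
print.tpp_network <- function(x, ...) {
  cat(sprintf("<tpp_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Edge and node accessors
#'
#' @param network A `tpp_network`.
#' @return `network_edges()`: tibble of `from`, `to`;
#'   `network_nodes()`: character vector of node symbols.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "tpp_network"))
  e <- igraph::as_data_frame(network$graph, what = "edges")
  tibble::tibble(from = e$from, to = e$to)
}

#' @rdname network_edges
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "tpp_network"))
  igraph::V(network$graph)$name
}

#' Rank network nodes by degree
#'
#' Degree centrality (number of incident edges) per node, sorted in
#' descending order with alphabetical tie-breaking for determinism; the
#' top row is the hub target.
#'
#' @param network A `tpp_network` (or an edge-list data frame, which is
#'   converted first).
#' @return Tibble of `symbol`, `degree`, sorted.
#' @export
degree_ranking <- function(network) {
  if (is.data.frame(network)) network <- interaction_network(network)
  stopifnot(inherits(network, "tpp_network"))
  if (igraph::vcount(network$graph) == 0) {
    abort("network is empty", class = "tppshift_input_error")
  }
  deg <- igraph::degree(network$graph)
  tibble::tibble(symbol = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$symbol)
}

#' Remove unconnected nodes
#'
#' Drops all degree-0 nodes, mirroring the usual "eliminate proteins
#' without connections" step before interaction-network analysis.
#' Idempotent.
#'
#' @param network A `tpp_network`.
#' @return A `tpp_network` in which every node has degree >= 1.
#' @export
isolate_filter <- function(network) {
  stopifnot(inherits(network, "tpp_network"))
  g <- network$graph
  iso <- igraph::V(g)[igraph::degree(g) == 0]
  structure(list(graph = igraph::delete_vertices(g, iso)),
            class = "tpp_network")
}

#' Flag stable binders from docking scores
#'
#' A compound is flagged as a stable binder when its XP GScore is strictly
#' below `xp_max` or its MM-GBSA binding free energy is strictly below
#' `dg_max` kcal/mol (lower = more stable; both inequalities strict, so
#' scores exactly at a threshold are not flagged).
#'
#' @param records Data frame with numeric `xp_gscore` and
#'   `mmgbsa_dg_bind` columns.
#' @param xp_max XP GScore threshold (default -6).
#' @param dg_max MM-GBSA dG Bind threshold in kcal/mol (default -30).
#' @return `records` with logical columns `xp_pass`, `dg_pass`,
#'   `stable_binding`.
#' @export
docking_threshold_filter <- function(records, xp_max = -6, dg_max = -30) {
  for (col in c("xp_gscore", "mmgbsa_dg_bind")) {
    if (!col %in% names(records) || !is.numeric(records[[col]])) {
      abort(sprintf("records need a numeric `%s` column", col),
            class = "tppshift_validation_error")
    }
  }
  if (any(is.na(records$xp_gscore) & is.na(records$mmgbsa_dg_bind))) {
    abort("records with both docking scores missing cannot be classified",
          class = "tppshift_validation_error")
  }
  records |>
    dplyr::mutate(xp_pass = !is.na(.data$xp_gscore) & .data$xp_gscore < xp_max,
                  dg_pass = !is.na(.data$mmgbsa_dg_bind) &
                    .data$mmgbsa_dg_bind < dg_max,
                  stable_binding = .data$xp_pass | .data$dg_pass)
}

#' Read an interaction edge list
#'
#' Two-column (or more; extras ignored) TSV of interacting symbols.
#'
#' @param path File path.
#' @return Tibble with `from` and `to` columns.
#' @export
read_edge_list <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(d) < 2) {
    abort("edge list needs at least two columns", class = "tppshift_input_error")
  }
  tibble::tibble(from = as.character(d[[1]]), to = as.character(d[[2]]))
}

#' Read a plain-text target list
#'
#' One symbol per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_target_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
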
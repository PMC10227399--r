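# Subgraph querying: one-hop neighborhoods around queried entities,
# progressive degree filtering (the manual "slider" workflow: filter at
# rising thresholds, watching local degrees shrink as nodes drop out),
# heatmap matrices of edge weights, and provenance recall.

#' Neighbor subgraph for queried entities
#'
#' Resolves each query name to every node carrying that canonical (so an
#' ambiguous name hits all its types), collects the anchors plus their
#' neighbors, and induces the subgraph: every graph edge with both endpoints
#' in the node set is retained.
#'
#' @param g Graph from [build_graph()].
#' @param query Character vector of canonical entity names (normalized with
#'   [normalize_term()] before lookup).
#' @param hops Neighborhood radius, default 1.
#' @return Object of class `litnet_subgraph`: list with `graph` (the induced
#'   [igraph::igraph]) and `anchors` (resolved anchor node names).
#' @export
neighbor_subgraph <- function(g, query, hops = 1L) {
  q <- normalize_term(query)
  anchors <- integer(0)
  for (i in seq_along(q)) {
    hit <- which(igraph::V(g)$canonical == q[i])
    if (length(hit) == 0L) {
      cand <- unique(igraph::V(g)$canonical)
      d <- utils::adist(q[i], cand)
      near <- cand[d <= 2]
      stop("query name not in graph: '", query[i], "'",
           if (length(near) > 0L)
             paste0(" (did you mean: ", paste(utils::head(near, 5),
                                              collapse = ", "), "?)"),
           call. = FALSE)
    }
    anchors <- c(anchors, hit)
  }
  anchors <- unique(anchors)
  nodes <- unique(unlist(igraph::ego(g, order = hops, nodes = anchors)))
  sub <- igraph::induced_subgraph(g, nodes)
  structure(list(graph = sub,
                 anchors = igraph::V(g)$name[anchors]),
            class = "litnet_subgraph")
}

#' Local degrees within a subgraph
#'
#' @param s A `litnet_subgraph`.
#' @return Named integer vector: degree of each node counted over the
#'   subgraph's own edges only.
#' @export
local_degree <- function(s) {
  stopifnot(inherits(s, "litnet_subgraph"))
  d <- igraph::degree(s$graph)
  stats::setNames(as.integer(d), igraph::V(s$graph)$name)
}

#' @export
print.litnet_subgraph <- function(x, ...) {
  cat("<subgraph> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges; anchors: ",
      paste(x$anchors, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Filter a subgraph by local degree
#'
#' Single pass: every non-protected node whose local degree in the INPUT
#' subgraph falls below `min_degree` is removed, dangling edges are dropped,
#' and local degrees are recomputed -- so surviving nodes can end up below
#' the threshold afterwards, which is exactly the shrinking-degree behavior
#' of progressive manual filtering. Call repeatedly with rising thresholds
#' for the progressive workflow, or set `iterate = TRUE` for the
#' k-core-style fixed point.
#'
#' @param s A `litnet_subgraph`.
#' @param min_degree Threshold; nodes with local degree < `min_degree` are
#'   removed.
#' @param protect_anchors Keep anchor nodes regardless of degree (default
#'   `TRUE`, so queried entities never vanish from their own query).
#' @param iterate Re-apply until no node is below threshold.
#' @return The filtered `litnet_subgraph`.
#' @export
filter_by_degree <- function(s, min_degree, protect_anchors = TRUE,
                             iterate = FALSE) {
  stopifnot(inherits(s, "litnet_subgraph"), min_degree >= 0)
  repeat {
    deg <- igraph::degree(s$graph)
    keep <- deg >= min_degree
    if (protect_anchors) {
      keep <- keep | igraph::V(s$graph)$name %in% s$anchors
    }
    if (all(keep)) break
    sub <- igraph::induced_subgraph(s$graph, which(keep))
    s <- structure(list(graph = sub,
                        anchors = intersect(s$anchors,
                                            igraph::V(sub)$name)),
                   class = "litnet_subgraph")
    if (!iterate) break
  }
  s
}

#' Edge-weight heatmap matrix for a subgraph
#'
#' Rows are the subgraph's nodes of one entity type, columns of another,
#' both sorted lexicographically; each cell holds the connecting edge's
#' weight (or 0 when no edge exists). `values = "degree"` instead fills
#' existing-edge cells with the product of the two endpoints' local degrees,
#' the node-degree reading of the heatmap.
#'
#' @param s A `litnet_subgraph`.
#' @param row_type,col_type Distinct entity types present in the subgraph.
#' @param values `"weight"` (default) or `"degree"`.
#' @return Numeric matrix with canonical names as dimnames.
#' @export
heatmap_matrix <- function(s, row_type, col_type,
                           values = c("weight", "degree")) {
  stopifnot(inherits(s, "litnet_subgraph"))
  values <- match.arg(values)
  if (row_type == col_type) {
    stop("row_type and col_type must differ", call. = FALSE)
  }
  g <- s$graph
  rows <- sort(igraph::V(g)$canonical[igraph::V(g)$etype == row_type],
               method = "radix")
  cols <- sort(igraph::V(g)$canonical[igraph::V(g)$etype == col_type],
               method = "radix")
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("entity type absent from subgraph: ",
         if (length(rows) == 0L) row_type else col_type, call. = FALSE)
  }
  mat <- matrix(0, length(rows), length(cols),
                dimnames = list(rows, cols))
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_data_frame(g, what = "edges")
    vname <- igraph::V(g)$name
    vcan <- stats::setNames(igraph::V(g)$canonical, vname)
    vtyp <- stats::setNames(igraph::V(g)$etype, vname)
    deg <- stats::setNames(igraph::degree(g), vname)
    for (i in seq_len(nrow(el))) {
      a <- el$from[i]; b <- el$to[i]
      if (vtyp[[a]] == row_type && vtyp[[b]] == col_type) {
        r <- vcan[[a]]; cc <- vcan[[b]]
      } else if (vtyp[[b]] == row_type && vtyp[[a]] == col_type) {
        r <- vcan[[b]]; cc <- vcan[[a]]
      } else next
      mat[r, cc] <- if (values == "weight") el$weight[i] else
        deg[[a]] * deg[[b]]
    }
  }
  mat
}

#' Write a heatmap matrix as labelled CSV
#'
#' @param mat Matrix from [heatmap_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(mat, path) {
  utils::write.table(
    cbind(data.frame(entity = rownames(mat), stringsAsFactors = FALSE),
          as.data.frame(mat)),
    path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Recall the supporting paragraphs of an edge
#'
#' Returns the full text and citation metadata of every paragraph recorded
#' as provenance for an edge, in corpus order -- the batch equivalent of
#' clicking an edge to see its supporting literature.
#'
#' @param g Graph from [build_graph()].
#' @param a,b Canonical names of the edge's endpoints.
#' @param corpus The corpus the graph was mined from (list of
#'   [document()]).
#' @param a_type,b_type Optional entity types to disambiguate names present
#'   under several types.
#' @param include_abstract Must match the setting used when mining, so
#'   paragraph indices resolve to the same text.
#' @return `data.frame` with columns `doc_id`, `para_index`, `text`,
#'   `title`, `journal`, `pub_date`, `doi`. Zero rows for edges with empty
#'   provenance (strain edges). Provenance paragraphs missing from the
#'   supplied corpus are dropped with a warning.
#' @export
recall_provenance <- function(g, a, b, corpus, a_type = NULL, b_type = NULL,
                              include_abstract = FALSE) {
  va <- resolve_node(g, a, a_type)
  vb <- resolve_node(g, b, b_type)
  eid <- igraph::get_edge_ids(g, c(va, vb))
  if (eid == 0L) {
    stop("no edge between '", a, "' and '", b, "'", call. = FALSE)
  }
  prov <- igraph::E(g)$provenance[[eid]]
  if (NROW(prov) == 0L) {
    return(data.frame(doc_id = character(), para_index = integer(),
                      text = character(), title = character(),
                      journal = character(), pub_date = character(),
                      doi = character(), stringsAsFactors = FALSE))
  }
  stream <- paragraph_stream(corpus, include_abstract)
  key <- paste(stream$doc_id, stream$index, sep = "\r")
  want <- paste(prov$doc_id, prov$para_index, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    warning("corpus is missing ", sum(is.na(idx)),
            " provenance paragraph(s); returning partial result",
            call. = FALSE)
  }
  hit <- sort(idx[!is.na(idx)])  # corpus order
  docs <- stats::setNames(corpus, vapply(corpus, `[[`, character(1),
                                         "doc_id"))
  meta <- lapply(stream$doc_id[hit], function(id) docs[[id]])
  data.frame(doc_id = stream$doc_id[hit], para_index = stream$index[hit],
             text = stream$text[hit],
             title = vapply(meta, `[[`, character(1), "title"),
             journal = vapply(meta, function(d) d$meta$journal, character(1)),
             pub_date = vapply(meta, function(d) d$meta$pub_date,
                               character(1)),
             doi = vapply(meta, function(d) d$meta$doi, character(1)),
             stringsAsFactors = FALSE)
}

resolve_node <- function(g, canonical, etype = NULL) {
  q <- normalize_term(canonical)
  hit <- which(igraph::V(g)$canonical == q &
                 (if (is.null(etype)) TRUE else igraph::V(g)$etype == etype))
  if (length(hit) == 0L) stop("node not in graph: ", canonical,
                              call. = FALSE)
  if (length(hit) > 1L) {
    stop("node name ambiguous across types (give a_type/b_type): ",
         canonical, call. = FALSE)
  }
  hit
}

.litnet_type_colors <- c(gene = "#4daf4a", chemical = "#ffd92f",
                         property = "#377eb8", strain = "#ff7f00")

#' Plot a queried subgraph
#'
#' Static export of the subgraph with the conventional type coloring: genes
#' green, chemicals yellow, properties blue, strains orange. Layout is
#' Fruchterman-Reingold with a fixed internal seed, so repeated plots of the
#' same subgraph are identical.
#'
#' @param x A `litnet_subgraph`.
#' @param vertex_label Label nodes with canonical names (default `TRUE`).
#' @param ... Passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.litnet_subgraph <- function(x, vertex_label = TRUE, ...) {
  g <- x$graph
  cols <- .litnet_type_colors[igraph::V(g)$etype]
  lay <- withr_seed_layout(g)
  igraph::plot.igraph(
    g, layout = lay, vertex.color = cols,
    vertex.label = if (vertex_label) igraph::V(g)$canonical else NA,
    vertex.size = 8, edge.width = 1 + log1p(igraph::E(g)$weight), ...)
  graphics::legend("topleft", legend = names(.litnet_type_colors),
                   pt.bg = .litnet_type_colors, pch = 21, bty = "n")
  invisible(x)
}

# deterministic layout without disturbing the caller's RNG state
withr_seed_layout <- function(g) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(42L)
  igraph::layout_with_fr(g)
}
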
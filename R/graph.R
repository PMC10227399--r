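# Materialization of the undirected multipartite network. Nodes are
# (canonical, etype) pairs -- the same string may exist as both a gene and a
# chemical without merging -- and edges carry the mined weight, association
# attributes and paragraph provenance. Strain-chemical edges come from a
# manually curated table, not from mining.

node_name <- function(canonical, etype) paste(canonical, etype, sep = "|")

#' Build the multipartite co-occurrence graph
#'
#' One node per entity appearing in at least one retained edge (optionally
#' every mentioned entity), one undirected edge per retained scored pair
#' with weight, LLR, significance, direction and paragraph provenance
#' attached as attributes. The graph itself is undirected; direction classes
#' are annotations only.
#'
#' @param counts `cooc_counts` object the pairs were scored from.
#' @param assoc Result of [decide_edges()] on the same counts.
#' @param mode `"permissive"` (default) retains every scored pair with its
#'   significance flag; `"significant_only"` retains only significant pairs.
#' @param include_isolated Also add nodes for mentioned entities that end up
#'   with no retained edge (default `FALSE`).
#' @return An undirected [igraph::igraph] graph; vertex attributes
#'   `canonical`, `etype`; edge attributes `relation`, `weight`, `llr`,
#'   `significant`, `direction`, `provenance` (list of data frames),
#'   `provenance_count`.
#' @export
build_graph <- function(counts, assoc, mode = c("permissive",
                                                "significant_only"),
                        include_isolated = FALSE) {
  stopifnot(inherits(counts, "cooc_counts"))
  mode <- match.arg(mode)
  if (mode == "significant_only") {
    assoc <- assoc[assoc$significant, , drop = FALSE]
  }
  if (nrow(assoc) > 0L) {
    pk <- pair_prov_key(assoc)
    miss <- !pk %in% names(counts$provenance)
    if (any(miss)) {
      stop("association results not present in counts: ",
           paste(assoc$entity_a[miss], assoc$entity_g[miss], sep = "~",
                 collapse = ", "), call. = FALSE)
    }
    edges <- data.frame(
      from = node_name(assoc$entity_a, assoc$type_a),
      to = node_name(assoc$entity_g, assoc$type_g),
      relation = assoc$relation, weight = assoc$weight, llr = assoc$llr,
      significant = assoc$significant, direction = assoc$direction,
      provenance_count = assoc$pair_occ, stringsAsFactors = FALSE)
    prov <- unname(counts$provenance[pk])
  } else {
    edges <- data.frame(from = character(), to = character(),
                        relation = character(), weight = integer(),
                        llr = numeric(), significant = logical(),
                        direction = character(), provenance_count = integer(),
                        stringsAsFactors = FALSE)
    prov <- list()
  }
  if (include_isolated) {
    vdf <- counts$entities
  } else {
    keep <- unique(c(edges$from, edges$to))
    ek <- node_name(counts$entities$canonical, counts$entities$etype)
    vdf <- counts$entities[ek %in% keep, , drop = FALSE]
  }
  vertices <- data.frame(name = node_name(vdf$canonical, vdf$etype),
                         canonical = vdf$canonical, etype = vdf$etype,
                         stringsAsFactors = FALSE)
  vertices <- vertices[order(vertices$name, method = "radix"), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  if (nrow(edges) > 0L) igraph::E(g)$provenance <- prov
  g
}

pair_prov_key <- function(assoc) {
  k1 <- entity_key(assoc$entity_a, assoc$type_a)
  k2 <- entity_key(assoc$entity_g, assoc$type_g)
  paste(pmin(k1, k2), pmax(k1, k2), sep = "\n")
}

#' Add manually curated strain-chemical edges
#'
#' Strain nodes and their constituent-chemical edges come from a curated
#' table (e.g. the chemical profiles reported for a panel of cultivars), not
#' from text mining: each row adds one strain_chemical edge of weight 1 with
#' no association attributes. Chemicals absent from the graph are created.
#' Duplicate rows collapse to a single edge.
#'
#' @param g Graph from [build_graph()].
#' @param table Data frame with columns `strain`, `chemical`, or path to a
#'   two-column TSV (no header).
#' @return The augmented graph.
#' @export
add_strain_edges <- function(g, table) {
  if (is.character(table)) {
    if (!file.exists(table)) stop("strain table not found: ", table,
                                  call. = FALSE)
    table <- utils::read.table(table, sep = "\t", header = FALSE, quote = "",
                               comment.char = "", stringsAsFactors = FALSE,
                               col.names = c("strain", "chemical"))
  }
  stopifnot(all(c("strain", "chemical") %in% names(table)))
  strain <- normalize_term(table$strain)
  chem <- normalize_term(table$chemical)
  bad <- !nzchar(strain) | !nzchar(chem)
  if (any(bad)) {
    stop("malformed strain table row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  keep <- !duplicated(paste(strain, chem, sep = "\r"))
  strain <- strain[keep]; chem <- chem[keep]
  new_nodes <- setdiff(c(node_name(strain, "strain"),
                         node_name(chem, "chemical")),
                       igraph::V(g)$name)
  if (length(new_nodes) > 0L) {
    parts <- strsplit(new_nodes, "|", fixed = TRUE)
    g <- igraph::add_vertices(
      g, length(new_nodes), name = new_nodes,
      canonical = vapply(parts, `[`, character(1), 1L),
      etype = vapply(parts, `[`, character(1), 2L))
  }
  sn <- node_name(strain, "strain")
  cn <- node_name(chem, "chemical")
  # idempotent: skip pairs already connected
  existing <- igraph::as_edgelist(g)
  if (nrow(existing) > 0L) {
    have <- paste(pmin(existing[, 1], existing[, 2]),
                  pmax(existing[, 1], existing[, 2]), sep = "\n")
    want <- paste(pmin(sn, cn), pmax(sn, cn), sep = "\n")
    newrow <- !want %in% have
    sn <- sn[newrow]; cn <- cn[newrow]
  }
  if (length(sn) == 0L) return(g)
  g <- igraph::add_edges(g, rbind(sn, cn), relation = "strain_chemical",
                         weight = 1L, llr = NA_real_, significant = NA,
                         direction = NA_character_, provenance_count = 0L)
  # empty provenance for strain edges
  ne <- igraph::ecount(g)
  idx <- seq.int(ne - length(sn) + 1L, ne)
  empty_prov <- data.frame(doc_id = character(), para_index = integer(),
                           stringsAsFactors = FALSE)
  prov <- if ("provenance" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$provenance
  } else {
    vector("list", ne)
  }
  for (i in idx) prov[[i]] <- empty_prov
  igraph::E(g)$provenance <- prov
  g
}

#' Network summary from node and edge counts
#'
#' The summary arithmetic: total node count as the sum of the per-type
#' counts, and average degree 2|E|/|V| (every edge contributes two endpoint
#' slots), also rounded to the nearest integer for reporting.
#'
#' @param node_count_by_type Named integer vector of node counts per entity
#'   type.
#' @param edge_count Number of edges.
#' @return List of class `litnet_summary` with `node_count`,
#'   `node_count_by_type`, `edge_count`, `average_degree`,
#'   `average_degree_rounded`.
#' @export
network_summary <- function(node_count_by_type, edge_count) {
  node_count <- sum(node_count_by_type)
  avg <- if (node_count > 0) 2 * edge_count / node_count else 0
  structure(list(node_count = as.integer(node_count),
                 node_count_by_type = node_count_by_type,
                 edge_count = as.integer(edge_count),
                 average_degree = avg,
                 average_degree_rounded = as.integer(round(avg))),
            class = "litnet_summary")
}

#' @export
print.litnet_summary <- function(x, ...) {
  cat("Network summary\n")
  cat("  nodes:", x$node_count)
  if (length(x$node_count_by_type) > 0L) {
    cat(" (", paste(names(x$node_count_by_type), x$node_count_by_type,
                    sep = " ", collapse = ", "), ")", sep = "")
  }
  cat("\n  edges:", x$edge_count, "\n")
  cat("  average degree:", format(x$average_degree, digits = 4),
      "(rounded:", paste0(x$average_degree_rounded, ")"), "\n")
  invisible(x)
}

#' Summarize a built graph
#'
#' @param g Graph from [build_graph()].
#' @return A [network_summary()] computed from the graph's typed node counts
#'   and edge count.
#' @export
graph_summary <- function(g) {
  if (igraph::vcount(g) == 0L) {
    return(network_summary(stats::setNames(integer(), character()), 0L))
  }
  by_type <- table(igraph::V(g)$etype)
  network_summary(stats::setNames(as.integer(by_type), names(by_type)),
                  igraph::ecount(g))
}

#' Export a network to disk
#'
#' Writes GraphML (provenance collapsed to `doc:index` strings), an
#' edge-list TSV, and a JSON dump including the provenance paragraph keys.
#'
#' @param g Graph from [build_graph()].
#' @param dir Output directory (created if needed).
#' @param name Base file name, default `"network"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_network <- function(g, dir, name = "network") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(graphml = file.path(dir, paste0(name, ".graphml")),
             edges = file.path(dir, paste0(name, "_edges.tsv")),
             json = file.path(dir, paste0(name, ".json")))
  gx <- g
  prov_strings <- prov_to_strings(g)
  if (!is.null(prov_strings)) {
    gx <- igraph::delete_edge_attr(gx, "provenance")
    igraph::E(gx)$provenance <- prov_strings
  }
  if (igraph::ecount(gx) > 0L) {
    igraph::E(gx)$significant <- as.integer(igraph::E(gx)$significant)
    igraph::E(gx)$direction <- ifelse(is.na(igraph::E(gx)$direction), "",
                                      igraph::E(gx)$direction)
  }
  igraph::write_graph(gx, paths[["graphml"]], format = "graphml")
  el <- igraph::as_data_frame(gx, what = "edges")
  utils::write.table(el, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- igraph::as_data_frame(gx, what = "vertices")
  jsonlite::write_json(list(nodes = nodes, edges = el), paths[["json"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

prov_to_strings <- function(g) {
  if (igraph::ecount(g) == 0L ||
      !"provenance" %in% igraph::edge_attr_names(g)) {
    return(NULL)
  }
  vapply(igraph::E(g)$provenance, function(df) {
    if (NROW(df) == 0L) "" else
      paste(df$doc_id, df$para_index, sep = ":", collapse = ";")
  }, character(1))
}
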
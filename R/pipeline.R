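# End-to-end pipeline: ingest -> language filter -> tag -> count -> test ->
# build -> summarize, with one configuration object, structured stage
# logging to stderr, and a reproducibility manifest.

#' Pipeline configuration
#'
#' Every tunable of the pipeline with its documented default. Unknown keys
#' are rejected.
#'
#' @param stopword_ratio_min English-filter stopword fraction threshold
#'   (default 0.15).
#' @param english_filter Apply the language filter (default `TRUE`).
#' @param include_abstract Treat abstracts as co-occurrence paragraphs
#'   (default `FALSE`: full-text body only).
#' @param alpha LLR significance level (default 0.05).
#' @param tau Direction-class conditional-probability threshold (default
#'   0.8).
#' @param min_pair_count Minimum paragraph co-occurrence count for scoring
#'   (default 1).
#' @param correction Multiple-testing correction: `"none"` (default) or
#'   `"bonferroni"`.
#' @param mode Edge retention: `"permissive"` (default; non-significant
#'   pairs keep their edge, flagged) or `"significant_only"`.
#' @param include_isolated_entities Add mentioned but edge-less entities as
#'   isolated nodes (default `FALSE`).
#' @param protect_anchors Keep queried nodes during degree filtering
#'   (default `TRUE`).
#' @param hops Query neighborhood radius (default 1).
#' @param embedding_dim,embedding_window,embedding_min_count,embedding_epochs
#'   Skip-gram training parameters (defaults 100, 5, 5, 5).
#' @param embedding_bigram_min_count Bigram-merge frequency threshold
#'   (default 20).
#' @param expansion_threshold Cosine-similarity radius for lexicon
#'   expansion (default 0.7).
#' @param expansion_top_k Neighbors per seed (default 10).
#' @param seed Seed for every stochastic stage (default 1).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stopword_ratio_min = 0.15,
                            english_filter = TRUE,
                            include_abstract = FALSE,
                            alpha = 0.05, tau = 0.8, min_pair_count = 1L,
                            correction = "none", mode = "permissive",
                            include_isolated_entities = FALSE,
                            protect_anchors = TRUE, hops = 1L,
                            embedding_dim = 100L, embedding_window = 5L,
                            embedding_min_count = 5L, embedding_epochs = 5L,
                            embedding_bigram_min_count = 20L,
                            expansion_threshold = 0.7,
                            expansion_top_k = 10L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$tau > 0, cfg$tau <= 1,
            cfg$min_pair_count >= 0,
            cfg$mode %in% c("permissive", "significant_only"),
            cfg$correction %in% c("none", "bonferroni"))
  structure(cfg, class = "pipeline_config")
}

#' Update a configuration, rejecting unknown keys
#'
#' @param config A [pipeline_config()].
#' @param ... Named overrides.
#' @return The updated configuration.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "pipeline_config"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(dots)) config[[k]] <- dots[[k]]
  do.call(pipeline_config, unclass(config))
}

stage_log <- function(stage, ...) {
  message(sprintf("[litnet] %-10s %s", stage, paste0(...)))
}

#' Mine a multipartite co-occurrence network from a corpus
#'
#' The package's main entry point. Runs the full pipeline: English
#' filtering, paragraph streaming, dictionary tagging, paragraph-level
#' co-occurrence counting, LLR scoring with direction classification, graph
#' construction, optional manual strain edges, and the network summary.
#'
#' @param corpus List of [document()] objects, or path to a JSONL corpus
#'   (see [read_corpus()]).
#' @param lexicon Lexicon data frame (see [as_lexicon()]), or path to a
#'   lexicon TSV, or a list/vector of either to be concatenated.
#' @param config A [pipeline_config()].
#' @param strain_table Optional `(strain, chemical)` data frame or TSV path
#'   of manually curated strain constituents.
#' @param output_dir Optional directory: writes graph exports
#'   (GraphML/TSV/JSON), the association report, a summary JSON and a run
#'   manifest (configuration, input checksums, versions).
#' @return Object of class `litnet`: list with `graph` (igraph),
#'   `summary` ([network_summary()]), `associations` ([decide_edges()]
#'   table), `counts` (`cooc_counts`), `corpus` (retained documents) and
#'   `config`.
#' @export
mine_network <- function(corpus, lexicon, config = pipeline_config(),
                         strain_table = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- character(0)
  if (is.character(corpus)) {
    inputs["corpus"] <- corpus
    stage_log("ingest", "reading corpus from ", corpus)
    corpus <- read_corpus(corpus)
  }
  if (is.character(lexicon) || (is.list(lexicon) && !is.data.frame(lexicon))) {
    lexs <- lapply(seq_along(lexicon), function(i) {
      l <- lexicon[[i]]
      if (is.character(l)) {
        inputs[[paste0("lexicon_", i)]] <<- l
        load_lexicon(l)
      } else as_lexicon(l)
    })
    lexicon <- as_lexicon(do.call(rbind, lapply(lexs, as.data.frame)))
  } else {
    lexicon <- as_lexicon(lexicon)
  }
  if (is.character(strain_table)) inputs["strain_table"] <- strain_table
  stage_log("ingest", length(corpus), " documents, ", nrow(lexicon),
            " lexicon entries")
  if (config$english_filter) {
    keep <- vapply(corpus, is_english, logical(1),
                   stopword_ratio_min = config$stopword_ratio_min)
    stage_log("language", sum(keep), "/", length(keep),
              " documents retained as English")
    corpus <- corpus[keep]
  }
  stream <- paragraph_stream(corpus, config$include_abstract)
  stage_log("stream", nrow(stream), " paragraphs")
  mentions <- extract_mentions(stream, lexicon)
  stage_log("match", nrow(mentions), " entity mention records")
  counts <- counts_from_mentions(mentions, nrow(stream))
  stage_log("count", nrow(counts$pairs), " admissible co-occurring pairs")
  assoc <- decide_edges(counts, alpha = config$alpha, tau = config$tau,
                        min_pair_count = config$min_pair_count,
                        correction = config$correction)
  stage_log("test", sum(assoc$significant), "/", nrow(assoc),
            " pairs significant at alpha = ", config$alpha)
  graph <- build_graph(counts, assoc, mode = config$mode,
                       include_isolated = config$include_isolated_entities)
  if (!is.null(strain_table)) {
    graph <- add_strain_edges(graph, strain_table)
    stage_log("strains", "manual strain edges added")
  }
  summ <- graph_summary(graph)
  stage_log("summary", summ$node_count, " nodes, ", summ$edge_count,
            " edges, average degree ",
            format(summ$average_degree, digits = 4))
  net <- structure(list(graph = graph, summary = summ,
                        associations = assoc, counts = counts,
                        corpus = corpus, config = config),
                   class = "litnet")
  if (!is.null(output_dir)) {
    write_outputs(net, output_dir, inputs)
  }
  net
}

write_outputs <- function(net, output_dir, inputs = character(0)) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_network(net$graph, output_dir)
  write_association_report(net$associations,
                           file.path(output_dir, "associations.tsv"))
  jsonlite::write_json(
    list(node_count = net$summary$node_count,
         node_count_by_type = as.list(net$summary$node_count_by_type),
         edge_count = net$summary$edge_count,
         average_degree = net$summary$average_degree,
         average_degree_rounded = net$summary$average_degree_rounded),
    file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  checksums <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(unlist(inputs)))
  } else list()
  jsonlite::write_json(
    list(config = unclass(net$config), input_md5 = checksums,
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("litnet")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(output_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.litnet <- function(x, ...) {
  cat("Multipartite literature co-occurrence network\n")
  print(x$summary)
  cat("  corpus:", length(x$corpus), "documents,", x$counts$N,
      "paragraphs\n")
  invisible(x)
}

#' Summarize a mined network
#'
#' @param object A `litnet` object from [mine_network()].
#' @param top_n Number of heaviest edges to display, default 5.
#' @param ... Unused.
#' @return `object$summary` augmented with the heaviest edges, class
#'   `summary.litnet`.
#' @export
summary.litnet <- function(object, top_n = 5L, ...) {
  a <- object$associations
  top <- a[order(-a$weight, a$entity_a, a$entity_g), , drop = FALSE]
  top <- utils::head(top[, c("entity_a", "entity_g", "relation", "weight",
                             "llr", "significant", "direction")], top_n)
  structure(list(network = object$summary, top_edges = top,
                 n_documents = length(object$corpus),
                 n_paragraphs = object$counts$N),
            class = "summary.litnet")
}

#' @export
print.summary.litnet <- function(x, ...) {
  print(x$network)
  cat("  corpus:", x$n_documents, "documents,", x$n_paragraphs,
      "paragraphs\n")
  if (nrow(x$top_edges) > 0L) {
    cat("  heaviest edges:\n")
    print(x$top_edges, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot a mined network
#'
#' @param x A `litnet` object.
#' @param ... Passed to [plot.litnet_subgraph()].
#' @return `x`, invisibly.
#' @export
plot.litnet <- function(x, ...) {
  s <- structure(list(graph = x$graph, anchors = character(0)),
                 class = "litnet_subgraph")
  plot(s, ...)
  invisible(x)
}

#' Query a mined network
#'
#' Convenience wrapper: one-hop (by default) neighbor subgraph around the
#' queried canonical names, optionally degree-filtered.
#'
#' @param net A `litnet` object.
#' @param nodes Character vector of canonical entity names.
#' @param min_degree Optional local-degree filter applied after extraction.
#' @return A `litnet_subgraph`.
#' @export
query_network <- function(net, nodes, min_degree = 0L) {
  stopifnot(inherits(net, "litnet"))
  s <- neighbor_subgraph(net$graph, nodes, hops = net$config$hops)
  if (min_degree > 0L) {
    s <- filter_by_degree(s, min_degree,
                          protect_anchors = net$config$protect_anchors)
  }
  s
}
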
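# Pathway analysis: hypergeometric over-representation plus a topology
# "impact" score from relative betweenness centrality of the hit compounds.

#' Construct a pathway graph
#'
#' Undirected, unweighted compound graph; may be disconnected. Self-loops
#' are rejected.
#'
#' @param name pathway name.
#' @param edges data frame (or 2-column matrix) of `source`, `target`
#'   compound ids; may have zero rows.
#' @param nodes optional extra isolated node ids.
#' @return a `pathway_graph` with fields `name`, `nodes`, `edges`.
#' @export
pathway_graph <- function(name, edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    names(edges)[1:2] <- c("source", "target")
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (any(edges$source == edges$target)) {
      stop("self-loop in pathway '", name, "'")
    }
  } else {
    edges <- data.frame(source = character(0), target = character(0))
  }
  all_nodes <- unique(c(if (nrow(edges)) c(edges$source, edges$target),
                        as.character(nodes)))
  if (!length(all_nodes)) stop("pathway '", name, "' has no nodes")
  structure(list(name = name, nodes = all_nodes,
                 edges = edges[, 1:2, drop = FALSE]),
            class = "pathway_graph")
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least `k` pathway
#' compounds among the `n` hit compounds, from a universe of `N` compounds
#' of which `K` belong to the pathway.
#'
#' @param hits character vector of hit compound ids.
#' @param pathway_nodes compound ids of the pathway (subset of universe).
#' @param universe the reference compound set.
#' @return the raw upper-tail p-value (1 when there is no overlap).
#' @export
hypergeom_enrichment <- function(hits, pathway_nodes, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  pathway_nodes <- unique(as.character(pathway_nodes))
  hits <- unique(as.character(hits))
  if (!all(pathway_nodes %in% universe)) {
    stop("pathway nodes must be a subset of the universe")
  }
  if (!all(hits %in% universe)) {
    stop("hits must be a subset of the universe")
  }
  k <- length(intersect(hits, pathway_nodes))
  if (k == 0) return(1)
  K <- length(pathway_nodes); n <- length(hits); N <- length(universe)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Relative betweenness centrality of pathway compounds
#'
#' Betweenness centrality per node on the undirected, unweighted graph
#' (all-pairs shortest paths), normalized so the importances sum to 1.
#' When every node has zero betweenness (no node lies between any other
#' pair, e.g. a complete graph or isolated pairs) the importance falls
#' back to uniform.
#'
#' @param pg a `pathway_graph`.
#' @return named numeric vector of importances in `[0, 1]` summing to 1.
#' @export
#' @examples
#' pg <- pathway_graph("chain", data.frame(source = c("A", "B"),
#'                                         target = c("B", "C")))
#' relative_betweenness(pg)
relative_betweenness <- function(pg) {
  stopifnot(inherits(pg, "pathway_graph"))
  g <- igraph::graph_from_data_frame(pg$edges, directed = FALSE,
                                     vertices = pg$nodes)
  bc <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  if (sum(bc) == 0) {
    imp <- rep(1 / length(pg$nodes), length(pg$nodes))
    names(imp) <- pg$nodes
    return(imp)
  }
  bc[pg$nodes] / sum(bc)
}

#' Topology impact of a hit set on a pathway
#'
#' Sum of the relative betweenness importances of the hit compounds that
#' belong to the pathway; 1 when every node is hit, 0 when none is.
#'
#' @param pg a `pathway_graph`.
#' @param hits compound ids.
#' @return impact in `[0, 1]`.
#' @export
pathway_impact <- function(pg, hits) {
  imp <- relative_betweenness(pg)
  sum(imp[intersect(pg$nodes, as.character(hits))])
}

#' Pathway analysis over a library (enrichment + topology impact)
#'
#' For every pathway: hypergeometric over-representation of the hit
#' compounds, topology impact from relative betweenness centrality, and
#' Holm and BH adjusted p-values across the library. The returned table is
#' sorted by raw p and carries the bubble-plot coordinates (x = impact,
#' y = -log10 raw p).
#'
#' @param hits character vector of affected-compound ids.
#' @param library list of `pathway_graph`s.
#' @param universe reference compound set; defaults to the union of all
#'   library compounds. Hits outside the universe are dropped with a
#'   warning.
#' @return a `pathway_results` data frame: `pathway`, `n_pathway`,
#'   `n_hits`, `raw_p`, `impact`, `holm_p`, `fdr_p`, `neg_log10_p`.
#' @export
metpa <- function(hits, library, universe = NULL) {
  if (!length(library)) stop("pathway library is empty")
  stopifnot(all(vapply(library, inherits, TRUE, "pathway_graph")))
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(library, `[[`, "nodes")))
  }
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    warning("dropping hit compound(s) absent from the universe: ",
            paste(outside, collapse = ", "))
    hits <- setdiff(hits, outside)
  }
  res <- do.call(rbind, lapply(library, function(pg) {
    in_path <- intersect(pg$nodes, universe)
    data.frame(pathway = pg$name,
               n_pathway = length(in_path),
               n_hits = length(intersect(hits, in_path)),
               raw_p = hypergeom_enrichment(hits, in_path, universe),
               impact = pathway_impact(pg, hits))
  }))
  res$holm_p <- stats::p.adjust(res$raw_p, method = "holm")
  res$fdr_p <- stats::p.adjust(res$raw_p, method = "BH")
  res$neg_log10_p <- -log10(res$raw_p)
  res <- res[order(res$raw_p, -res$impact), ]
  rownames(res) <- NULL
  class(res) <- c("pathway_results", "data.frame")
  res
}

#' Bundled toy pathway library
#'
#' Six small literature-shaped compound graphs (a linear degradation chain,
#' a cycle, a star around a hub, a branched tree, a dense clique with a
#' tail, and a two-component pathway) over common polar-extract
#' metabolites. Intended for tests and demonstrations; real pathway
#' libraries are read from edge-list CSVs via [read_pathway_library()].
#'
#' @return list of `pathway_graph`s.
#' @export
toy_pathway_library <- function() {
  ed <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2])
  }
  list(
    pathway_graph("branched-chain amino acid degradation",
                  ed("valine", "ketoisovalerate", "ketoisovalerate", "isobutyryl-CoA",
                     "isobutyryl-CoA", "methylmalonate", "leucine", "ketoisocaproate",
                     "ketoisocaproate", "isovaleryl-CoA")),
    pathway_graph("tca cycle",
                  ed("citrate", "isocitrate", "isocitrate", "oxoglutarate",
                     "oxoglutarate", "succinate", "succinate", "fumarate",
                     "fumarate", "malate", "malate", "oxaloacetate",
                     "oxaloacetate", "citrate")),
    pathway_graph("glycine-serine-threonine metabolism",
                  ed("glycine", "serine", "glycine", "betaine",
                     "glycine", "dimethylglycine", "glycine", "creatine",
                     "serine", "pyruvate")),
    pathway_graph("alanine-aspartate-glutamate metabolism",
                  ed("alanine", "pyruvate", "pyruvate", "oxaloacetate",
                     "oxaloacetate", "aspartate", "aspartate", "asparagine",
                     "glutamate", "glutamine", "glutamate", "oxoglutarate",
                     "oxoglutarate", "pyruvate")),
    pathway_graph("purine metabolism",
                  ed("amp", "adenosine", "adenosine", "inosine",
                     "inosine", "hypoxanthine", "amp", "inosine",
                     "amp", "atp", "atp", "adenosine")),
    pathway_graph("osmolyte metabolism",
                  ed("choline", "betaine", "betaine", "dimethylglycine",
                     "myo-inositol", "scyllo-inositol"))
  )
}

#' Read a pathway library from edge-list CSV files
#'
#' The index CSV has columns `pathway`, `file`, and optionally `name`;
#' each referenced file is a two-column CSV (`source`, `target`) with one
#' edge per row. File paths are taken relative to the index.
#'
#' @param index_path path to the index CSV.
#' @return list of `pathway_graph`s.
#' @export
read_pathway_library <- function(index_path) {
  if (!file.exists(index_path)) stop("pathway index not found: ", index_path)
  idx <- utils::read.csv(index_path, stringsAsFactors = FALSE)
  if (!all(c("pathway", "file") %in% names(idx))) {
    stop("pathway index must have columns: pathway, file")
  }
  root <- dirname(index_path)
  lapply(seq_len(nrow(idx)), function(i) {
    f <- file.path(root, idx$file[i])
    if (!file.exists(f)) stop("pathway edge list not found: ", f)
    pathway_graph(idx$name[i] %||% idx$pathway[i], utils::read.csv(f))
  })
}
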
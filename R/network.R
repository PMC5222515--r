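# Bipartite compound-target / target-pathway networks, degree statistics,
# herb aggregation and Jun-Chen-Zuo-Shi role classification.

#' Construct a bipartite network
#'
#' A typed two-part graph: the left part holds e.g. compounds, the right
#' part targets (or targets and pathways). Edges connect parts only; an
#' edge inside one part is rejected. Nodes may be declared without edges
#' (isolates), and compound nodes can carry herb membership metadata.
#'
#' @param edges data.frame with columns `left`, `right` (may have 0 rows).
#' @param left_kind,right_kind node-kind labels, e.g. `"compound"`,
#'   `"target"`.
#' @param left_nodes,right_nodes optional character vectors declaring the
#'   node sets (defaults to the endpoints appearing in `edges`).
#' @param herb_id optional named character vector mapping left-node ids to
#'   herb identifiers.
#' @return an object of class `bipartite_net` wrapping an igraph graph
#'   whose vertices carry `kind` and (left part) `herb_id` attributes.
#' @export
#' @examples
#' net <- bipartite_network(data.frame(left = c("c1", "c2", "c2"),
#'                                     right = c("t1", "t1", "t2")),
#'                          "compound", "target")
#' network_summary(net)
bipartite_network <- function(edges, left_kind, right_kind,
                              left_nodes = NULL, right_nodes = NULL,
                              herb_id = NULL) {
  if (!all(c("left", "right") %in% names(edges))) {
    stop_validation("`edges` needs columns left and right")
  }
  edges$left <- as.character(edges$left)
  edges$right <- as.character(edges$right)
  left_nodes <- unique(c(as.character(left_nodes %||% character()), edges$left))
  right_nodes <- unique(c(as.character(right_nodes %||% character()), edges$right))
  clash <- intersect(left_nodes, right_nodes)
  if (length(clash)) {
    stop_validation("node id(s) appear in both parts: ",
                    paste(clash, collapse = ", "))
  }
  if (nrow(edges)) {
    dup <- duplicated(paste(edges$left, edges$right, sep = "\r"))
    if (any(dup)) {
      warning("collapsing ", sum(dup), " duplicate edge(s)")
      edges <- edges[!dup, , drop = FALSE]
    }
  }
  vertices <- data.frame(
    name = c(left_nodes, right_nodes),
    kind = c(rep(left_kind, length(left_nodes)),
             rep(right_kind, length(right_nodes))),
    type = c(rep(FALSE, length(left_nodes)), rep(TRUE, length(right_nodes))),
    stringsAsFactors = FALSE
  )
  vertices$herb_id <- rep(NA_character_, nrow(vertices))
  if (!is.null(herb_id)) {
    idx <- match(vertices$name, names(herb_id))
    vertices$herb_id <- ifelse(is.na(idx), NA_character_, unname(herb_id)[idx])
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("left", "right"), drop = FALSE],
    directed = FALSE, vertices = vertices
  )
  structure(list(graph = g, left_kind = left_kind, right_kind = right_kind),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("bipartite_net: %d %s + %d %s nodes, %d edges\n",
              s$n_left, x$left_kind, s$n_right, x$right_kind, s$n_edges))
  invisible(x)
}

net_vertices <- function(net) {
  data.frame(
    name = igraph::V(net$graph)$name,
    kind = igraph::V(net$graph)$kind,
    type = igraph::V(net$graph)$type,
    herb_id = igraph::V(net$graph)$herb_id,
    stringsAsFactors = FALSE
  )
}

net_edges <- function(net) {
  e <- igraph::as_edgelist(net$graph)
  v <- net_vertices(net)
  if (!nrow(e)) {
    return(data.frame(left = character(), right = character(),
                      stringsAsFactors = FALSE))
  }
  # orient each edge left-part first
  is_left1 <- !v$type[match(e[, 1], v$name)]
  data.frame(left = ifelse(is_left1, e[, 1], e[, 2]),
             right = ifelse(is_left1, e[, 2], e[, 1]),
             stringsAsFactors = FALSE)
}

#' Node degree in a bipartite network
#'
#' @param net a `bipartite_net`.
#' @param node_id node identifier.
#' @return non-negative integer edge count.
#' @export
node_degree <- function(net, node_id) {
  stopifnot(inherits(net, "bipartite_net"))
  if (!node_id %in% igraph::V(net$graph)$name) {
    stop_validation("unknown node: ", node_id)
  }
  as.integer(igraph::degree(net$graph, node_id))
}

#' Summary counts for a bipartite network
#'
#' @param net a `bipartite_net`.
#' @return list with `n_nodes`, `n_edges`, `n_left`, `n_right`,
#'   `mean_degree_left`, `mean_degree_right`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  v <- net_vertices(net)
  n_left <- sum(!v$type); n_right <- sum(v$type)
  n_edges <- igraph::ecount(net$graph)
  list(n_nodes = nrow(v), n_edges = n_edges,
       n_left = n_left, n_right = n_right,
       mean_degree_left = if (n_left) n_edges / n_left else 0,
       mean_degree_right = if (n_right) n_edges / n_right else 0)
}

#' Build the compound-target network
#'
#' Connects each candidate compound to its accepted targets. Compounds with
#' no accepted target are excluded from the graph and listed in the dropped
#' report; targets appear only when incident to at least one edge.
#' Duplicate accepted pairs are collapsed.
#'
#' @param candidates compound table (rows are the candidate compounds).
#' @param accepted accepted interaction pairs (`compound_id`, `target_id`),
#'   e.g. the output of [consensus_filter()].
#' @return list with `network` (a `bipartite_net` whose compound nodes
#'   carry `herb_id`) and `dropped` (character vector of isolated
#'   compound ids).
#' @export
build_ct_network <- function(candidates, accepted) {
  unknown <- setdiff(unique(accepted$compound_id), candidates$compound_id)
  if (length(unknown)) {
    stop_validation("accepted pair references unknown compound(s): ",
                    paste(unknown, collapse = ", "))
  }
  connected <- intersect(candidates$compound_id, accepted$compound_id)
  dropped <- setdiff(candidates$compound_id, connected)
  edges <- data.frame(left = accepted$compound_id,
                      right = accepted$target_id,
                      stringsAsFactors = FALSE)
  herb <- setNames(candidates$herb_id, candidates$compound_id)
  net <- bipartite_network(edges, "compound", "target",
                           left_nodes = connected, herb_id = herb)
  list(network = net, dropped = dropped)
}

#' Per-herb aggregates over the compound-target network
#'
#' For every herb with at least one surviving compound node: the number of
#' active compounds, the summed compound degrees and the mean number of
#' targets per compound (the herb's polypharmacology level).
#'
#' @param net a compound-target `bipartite_net` whose compound nodes carry
#'   `herb_id`.
#' @return data.frame with `herb_id`, `n_active_compounds`, `total_degree`,
#'   `mean_targets_per_compound`, sorted by (`n_active_compounds`,
#'   `total_degree`) descending.
#' @export
herb_aggregates <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  v <- net_vertices(net)
  left <- v[!v$type, , drop = FALSE]
  if (nrow(left) && anyNA(left$herb_id)) {
    stop_validation("compound node(s) missing herb_id: ",
                    paste(left$name[is.na(left$herb_id)], collapse = ", "))
  }
  deg <- igraph::degree(net$graph, left$name)
  agg <- if (nrow(left)) {
    do.call(rbind, lapply(split(seq_len(nrow(left)), left$herb_id), function(i) {
      data.frame(herb_id = left$herb_id[i[1]],
                 n_active_compounds = length(i),
                 total_degree = as.integer(sum(deg[i])),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(herb_id = character(), n_active_compounds = integer(),
               total_degree = integer(), stringsAsFactors = FALSE)
  }
  agg$mean_targets_per_compound <-
    ifelse(agg$n_active_compounds > 0, agg$total_degree / agg$n_active_compounds, 0)
  ord <- order(-agg$n_active_compounds, -agg$total_degree, agg$herb_id)
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Classify herbs into Jun / Chen / Zuo-Shi roles
#'
#' Formalizes the traditional prescription-role reading of the
#' compound-target network: herbs are ranked by active-compound count with
#' total degree as tie-breaker; the top herb is the monarch (jun), the next
#' `floor(chen_fraction * n_herbs)` herbs are ministers (chen) and the
#' remainder are assistants/guides (zuo_shi, merged into one tier).
#' Remaining ties are broken lexicographically by herb id and flagged.
#'
#' @param aggs herb aggregates from [herb_aggregates()].
#' @param chen_fraction fraction of herbs in the minister tier (default
#'   0.35, which yields a 1 / 7 / 12 split for 20 herbs).
#' @return data.frame with `herb_id`, `role` (`jun`, `chen`, `zuo_shi`),
#'   `rank` and `tied`.
#' @export
classify_roles <- function(aggs, chen_fraction = 0.35) {
  if (!nrow(aggs)) stop_validation("need at least one herb aggregate")
  if (chen_fraction < 0 || chen_fraction > 1) {
    stop_config("chen_fraction must lie in [0, 1]")
  }
  ord <- order(-aggs$n_active_compounds, -aggs$total_degree, aggs$herb_id)
  aggs <- aggs[ord, , drop = FALSE]
  key <- paste(aggs$n_active_compounds, aggs$total_degree)
  tied <- key %in% key[duplicated(key)]
  h <- nrow(aggs)
  n_chen <- min(h - 1L, as.integer(floor(chen_fraction * h + 1e-9)))
  role <- rep("zuo_shi", h)
  role[1L] <- "jun"
  if (n_chen > 0 && h > 1) role[seq(2L, 1L + n_chen)] <- "chen"
  data.frame(herb_id = aggs$herb_id, role = role, rank = seq_len(h),
             tied = tied, stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the target-pathway network
#'
#' Connects each target to every pathway (gene set) containing it. Targets
#' belonging to no pathway are excluded from the node set.
#'
#' @param targets character vector of target ids.
#' @param pathways a [gene_set_collection()] of pathway memberships.
#' @return list with `network` (a `bipartite_net`, targets left / pathways
#'   right), `multi_pathway_targets` (targets in two or more pathways) and
#'   `n_multi_pathway`.
#' @export
build_tp_network <- function(targets, pathways) {
  stopifnot(inherits(pathways, "gene_set_collection"))
  targets <- unique(as.character(targets))
  edges <- do.call(rbind, lapply(names(pathways$sets), function(p) {
    hit <- intersect(targets, pathways$sets[[p]])
    if (!length(hit)) return(NULL)
    data.frame(left = hit, right = p, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(left = character(), right = character(),
                        stringsAsFactors = FALSE)
  }
  net <- bipartite_network(edges, "target", "pathway")
  n_path <- table(edges$left)
  multi <- names(n_path)[n_path >= 2]
  list(network = net, multi_pathway_targets = sort(multi),
       n_multi_pathway = length(multi))
}

#' Write a bipartite network to SIF or GraphML
#'
#' SIF lines are `left <TAB> relation <TAB> right`; isolated nodes are
#' written as single-field lines, the convention Cytoscape accepts.
#' GraphML (via igraph) carries the `kind` and `herb_id` node attributes.
#' [read_network()] reproduces the node and edge sets exactly.
#'
#' @param net a `bipartite_net`.
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @param relation SIF relation label (default `"binds"`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml"),
                          relation = "binds") {
  stopifnot(inherits(net, "bipartite_net"))
  format <- match.arg(format)
  if (format == "sif") {
    e <- net_edges(net)
    v <- net_vertices(net)
    isolated <- setdiff(v$name, c(e$left, e$right))
    lines <- c(if (nrow(e)) paste(e$left, relation, e$right, sep = "\t"),
               isolated)
    writeLines(lines %||% character(), path, useBytes = TRUE)
  } else {
    g <- net$graph
    # GraphML has no NA notion; encode absent herb_id as empty string
    igraph::V(g)$herb_id <- ifelse(is.na(igraph::V(g)$herb_id), "",
                                   igraph::V(g)$herb_id)
    igraph::V(g)$part <- ifelse(igraph::V(g)$type, "right", "left")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a bipartite network written by [write_network()]
#'
#' @param path input path.
#' @param format `"sif"` or `"graphml"`.
#' @param left_kind,right_kind node-kind labels for SIF input (GraphML
#'   carries them as attributes).
#' @return a `bipartite_net`.
#' @export
read_network <- function(path, format = c("sif", "graphml"),
                         left_kind = "compound", right_kind = "target") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("file not found: ", path)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    triples <- parts[lengths(parts) >= 3L]
    singles <- unlist(parts[lengths(parts) == 1L])
    edges <- data.frame(
      left = vapply(triples, `[[`, character(1), 1L),
      right = vapply(triples, `[[`, character(1), 3L),
      stringsAsFactors = FALSE
    )
    # isolated nodes: part known only from edge membership; unseen singles
    # default to the left part
    right_iso <- character()
    left_iso <- setdiff(singles, c(edges$left, edges$right))
    bipartite_network(edges, left_kind, right_kind,
                      left_nodes = c(unique(edges$left), left_iso),
                      right_nodes = c(unique(edges$right), right_iso))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    v_part <- igraph::V(g)$part
    v_kind <- igraph::V(g)$kind
    herb <- igraph::V(g)$herb_id
    if (is.null(herb)) herb <- rep(NA_character_, igraph::vcount(g))
    herb[!is.na(herb) & herb == ""] <- NA_character_
    e <- igraph::as_edgelist(g)
    is_left <- v_part == "left"
    nm <- igraph::V(g)$name
    if (nrow(e)) {
      left1 <- is_left[match(e[, 1], nm)]
      edges <- data.frame(left = ifelse(left1, e[, 1], e[, 2]),
                          right = ifelse(left1, e[, 2], e[, 1]),
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(left = character(), right = character(),
                          stringsAsFactors = FALSE)
    }
    bipartite_network(edges,
                      left_kind = if (any(is_left)) v_kind[is_left][1] else left_kind,
                      right_kind = if (any(!is_left)) v_kind[!is_left][1] else right_kind,
                      left_nodes = nm[is_left], right_nodes = nm[!is_left],
                      herb_id = setNames(herb, nm))
  }
}
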
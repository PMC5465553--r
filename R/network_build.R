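# Reaction graphs: nodes are merged reactions (identical metabolite sets),
# edges join nodes sharing a non-currency metabolite. Host and microbial
# graphs are merged through interface metabolites and every node gets a layer
# number: its within-subnetwork hop count from the interface frontier.

#' Build a metabolic reaction graph from a database
#'
#' Reactions with identical metabolite sets are merged into a single node
#' (id = lexicographically smallest member reaction id). Two nodes are
#' connected iff they share at least one non-currency metabolite; the shared
#' metabolites label the edge. Nodes left without any edge are dropped.
#'
#' @param db a `reaction_db`.
#' @param cutoff currency cutoff: metabolites in `cutoff` or more reactions
#'   form no edges.
#' @return a `metabolic_graph`: list with `nodes` (data.frame `node_id`,
#'   `subnetwork` plus list-columns `member_reaction_ids`, `metabolite_ids`),
#'   `edges` (data.frame `from`, `to`, list-column `shared`), `graph`
#'   (igraph), `currency_cutoff`, `currency_set`, `reaction_nodes`
#'   (named map reaction id -> node id, merged-away and isolated reactions
#'   included with NA for the latter).
#' @export
build_graph <- function(db, cutoff) {
  stopifnot(inherits(db, "reaction_db"))
  if (length(db$reactions) == 0) stop("empty database", call. = FALSE)
  currency <- currency_metabolites(db, cutoff)

  keys <- vapply(db$reactions,
                 function(x) paste(sort(unique(x)), collapse = "\r"), "")
  groups <- split(names(db$reactions), keys)
  node_ids <- vapply(groups, function(g) min(g), "")
  nodes <- data.frame(node_id = unname(node_ids), stringsAsFactors = FALSE)
  nodes$member_reaction_ids <- I(lapply(groups, sort))
  nodes$metabolite_ids <- I(lapply(groups, function(g)
    sort(unique(db$reactions[[g[[1]]]]))))
  nodes$subnetwork <- db$source_label
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- nodes$node_id

  # edges through shared non-currency metabolites
  inc <- data.frame(
    metabolite = unlist(nodes$metabolite_ids, use.names = FALSE),
    node = rep(nodes$node_id, lengths(nodes$metabolite_ids)),
    stringsAsFactors = FALSE)
  inc <- inc[!inc$metabolite %in% currency, , drop = FALSE]
  pair_list <- lapply(split(inc$node, inc$metabolite), function(users) {
    if (length(users) < 2) return(NULL)
    users <- sort(users)
    p <- t(combn(users, 2))
    data.frame(from = p[, 1], to = p[, 2], stringsAsFactors = FALSE)
  })
  met_of_pair <- rep(names(pair_list),
                     vapply(pair_list, function(d) NROW(d), 0L))
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) {
    edges <- data.frame(from = character(), to = character())
    edges$shared <- I(list())
  } else {
    key <- paste(pairs$from, pairs$to, sep = "\r")
    shared <- split(met_of_pair, key)
    uk <- sort(names(shared))
    fr <- vapply(strsplit(uk, "\r", fixed = TRUE), `[[`, "", 1L)
    to <- vapply(strsplit(uk, "\r", fixed = TRUE), `[[`, "", 2L)
    edges <- data.frame(from = fr, to = to, stringsAsFactors = FALSE)
    edges$shared <- I(lapply(shared[uk], sort))
  }

  keep <- nodes$node_id %in% c(edges$from, edges$to)
  nodes <- nodes[keep, , drop = FALSE]

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = nodes$node_id)
  reaction_nodes <- setNames(rep(NA_character_, length(db$reactions)),
                             names(db$reactions))
  for (i in seq_len(nrow(nodes)))
    reaction_nodes[nodes$member_reaction_ids[[i]]] <- nodes$node_id[i]

  structure(list(nodes = nodes, edges = edges, graph = g,
                 currency_cutoff = cutoff, currency_set = currency,
                 reaction_nodes = reaction_nodes,
                 subnetwork = db$source_label),
            class = "metabolic_graph")
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat(sprintf("<metabolic_graph: %s> %d nodes, %d edges (currency cutoff %d, %d currency metabolites)\n",
              x$subnetwork, nrow(x$nodes), nrow(x$edges),
              x$currency_cutoff, length(x$currency_set)))
  invisible(x)
}

#' Default interface-metabolite id mapping
#'
#' Names the three major ruminal volatile fatty acids and the twenty
#' universal amino acids in the id dialect of the synthetic databases.
#' Override when a database uses other ids.
#'
#' @return list with character vectors `vfa` (3 ids) and `amino_acids`
#'   (20 ids), named by compound.
#' @export
default_interface_ids <- function() {
  aa <- c(alanine = "AA_ALA", arginine = "AA_ARG", asparagine = "AA_ASN",
          aspartate = "AA_ASP", cysteine = "AA_CYS", glutamate = "AA_GLU",
          glutamine = "AA_GLN", glycine = "AA_GLY", histidine = "AA_HIS",
          isoleucine = "AA_ILE", leucine = "AA_LEU", lysine = "AA_LYS",
          methionine = "AA_MET", phenylalanine = "AA_PHE", proline = "AA_PRO",
          serine = "AA_SER", threonine = "AA_THR", tryptophan = "AA_TRP",
          tyrosine = "AA_TYR", valine = "AA_VAL")
  list(vfa = c(acetate = "ACETATE", propionate = "PROPIONATE",
               butyrate = "BUTYRATE"),
       amino_acids = aa)
}

#' Construct an interface-metabolite set
#'
#' Interface metabolites are compounds plausibly transferred from the rumen
#' microbes to the host. `VFA` is the three most abundant ruminal volatile
#' fatty acids; `VFA_AA` adds the twenty universal amino acids (23 compounds);
#' `ALL` is read from a caller-supplied id list (one id per line).
#'
#' @param name one of `"VFA"`, `"VFA_AA"`, `"ALL"`, `"custom"`.
#' @param db_host,db_microbial the two databases, used to check that mapped
#'   ids resolve.
#' @param all_list_path path to the id list for `ALL`/`custom`.
#' @param id_map name -> metabolite-id mapping, see
#'   [default_interface_ids()].
#' @return an `interface_set`: list with `name` and sorted `metabolite_ids`.
#' @export
make_interface_set <- function(name = c("VFA", "VFA_AA", "ALL", "custom"),
                               db_host, db_microbial,
                               all_list_path = NULL,
                               id_map = default_interface_ids()) {
  name <- match.arg(name)
  if (name %in% c("VFA", "VFA_AA")) {
    ids <- id_map$vfa
    if (name == "VFA_AA") ids <- c(ids, id_map$amino_acids)
    known <- union(db_host$metabolites$metabolite_id,
                   db_microbial$metabolites$metabolite_id)
    missing <- ids[!ids %in% known]
    if (length(missing))
      stop_id("interface metabolite id(s) not found in either database: %s",
              paste0(names(missing), "=", missing))
  } else {
    if (is.null(all_list_path))
      stop("the ALL/custom interface set requires a metabolite-id list file",
           call. = FALSE)
    ids <- readLines(all_list_path)
    ids <- ids[nzchar(trimws(ids))]
  }
  structure(list(name = name, metabolite_ids = sort(unique(unname(ids)))),
            class = "interface_set")
}

#' Merge the host and microbial graphs through interface metabolites
#'
#' Creates a cross-network edge between every (host node, microbial node)
#' pair that both use a common interface metabolite. Interface usage is
#' evaluated on the nodes' full metabolite sets, so a metabolite excluded as
#' currency within a subnetwork still forms interface edges. Layers are
#' assigned with [assign_layers()].
#'
#' @param host,microbial `metabolic_graph`s built at the same currency
#'   cutoff.
#' @param iface an `interface_set`.
#' @return a `merged_network`: list with `host`, `microbial`,
#'   `interface_edges` (data.frame `host_node`, `microbial_node`,
#'   `metabolite`), `layer` (named integer vector over all nodes, `NA` for
#'   nodes with no path to the other subnetwork), `interface_set`.
#' @export
merge_networks <- function(host, microbial, iface) {
  stopifnot(inherits(host, "metabolic_graph"),
            inherits(microbial, "metabolic_graph"),
            inherits(iface, "interface_set"))
  if (length(iface$metabolite_ids) == 0)
    stop("empty interface set", call. = FALSE)
  if (host$currency_cutoff != microbial$currency_cutoff)
    stop("host and microbial graphs built at different currency cutoffs",
         call. = FALSE)
  users <- function(gr, met) {
    hit <- vapply(gr$nodes$metabolite_ids, function(s) met %in% s, logical(1))
    gr$nodes$node_id[hit]
  }
  ie <- lapply(iface$metabolite_ids, function(met) {
    h <- users(host, met); m <- users(microbial, met)
    if (!length(h) || !length(m)) return(NULL)
    expand.grid(host_node = h, microbial_node = m, metabolite = met,
                stringsAsFactors = FALSE)
  })
  interface_edges <- do.call(rbind, ie)
  if (is.null(interface_edges))
    interface_edges <- data.frame(host_node = character(),
                                  microbial_node = character(),
                                  metabolite = character())
  interface_edges <-
    interface_edges[order(interface_edges$host_node,
                          interface_edges$microbial_node,
                          interface_edges$metabolite), , drop = FALSE]
  rownames(interface_edges) <- NULL
  m <- structure(list(host = host, microbial = microbial,
                      interface_edges = interface_edges,
                      interface_set = iface, layer = NULL),
                 class = "merged_network")
  m$layer <- assign_layers(m)
  m
}

#' Assign layer numbers to every node of a merged network
#'
#' A node's layer is its shortest-path distance to the other subnetwork
#' minus one: nodes using an interface metabolite (i.e. incident to an
#' interface edge) sit at layer 0 and distances grow outward through
#' within-subnetwork edges. Nodes with no path to the interface frontier get
#' `NA` and are excluded from layer statistics downstream.
#'
#' @param m a `merged_network`.
#' @return named integer vector over all host and microbial node ids.
#' @export
assign_layers <- function(m) {
  stopifnot(inherits(m, "merged_network"))
  one_side <- function(gr, frontier) {
    ids <- gr$nodes$node_id
    lay <- setNames(rep(NA_integer_, length(ids)), ids)
    frontier <- intersect(frontier, ids)
    if (!length(frontier)) return(lay)
    d <- igraph::distances(gr$graph, v = frontier, to = igraph::V(gr$graph))
    dmin <- apply(d, 2, min)
    reach <- is.finite(dmin)
    lay[colnames(d)[reach]] <- as.integer(dmin[reach])
    lay
  }
  c(one_side(m$host, unique(m$interface_edges$host_node)),
    one_side(m$microbial, unique(m$interface_edges$microbial_node)))
}

#' @export
print.merged_network <- function(x, ...) {
  cat(sprintf("<merged_network: %s> %d host + %d microbial nodes, %d interface edges; layers 0-%s (%d unreachable)\n",
              x$interface_set$name, nrow(x$host$nodes),
              nrow(x$microbial$nodes), nrow(x$interface_edges),
              if (all(is.na(x$layer))) "NA" else max(x$layer, na.rm = TRUE),
              sum(is.na(x$layer))))
  invisible(x)
}

#' Export a graph as node/edge tables and GraphML
#'
#' @param gr a `metabolic_graph`.
#' @param dir output directory.
#' @param layers optional named layer vector to join onto the node table.
#' @return `dir`, invisibly.
#' @export
export_graph <- function(gr, dir, layers = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- data.frame(node_id = gr$nodes$node_id,
                   subnetwork = gr$nodes$subnetwork,
                   layer = if (is.null(layers)) NA_integer_
                           else unname(layers[gr$nodes$node_id]),
                   degree = unname(igraph::degree(gr$graph)[gr$nodes$node_id]))
  write.table(nt, file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  et <- data.frame(from = gr$edges$from, to = gr$edges$to,
                   shared_metabolites = vapply(gr$edges$shared,
                                               paste, "", collapse = ";"))
  write.table(et, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(gr$graph, file.path(dir, "graph.graphml"),
                      format = "graphml")
  invisible(dir)
}
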
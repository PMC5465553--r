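# Diet-shift simulation: compound vectors (metabolite-indexed read mass,
# rescaled to 100,000) and a simulated-annealing search for read-to-node
# distributions whose compound vector approaches a target, under an
# unconstrained single-read move rule (swap1) or an edge-constrained paired
# move rule (swap2, a proxy for genomic linkage of enzymes).

#' Raw compound vector of a read distribution
#'
#' Entry for metabolite c = total reads on nodes whose reaction uses c.
#' Metabolites used by no counted node get 0. Linear in the counts.
#'
#' @param node_counts named read counts over graph nodes.
#' @param graph a `metabolic_graph`.
#' @return named numeric vector over all metabolites appearing in the
#'   graph's nodes, class `compound_vector` with `scale = "raw"`.
#' @export
compound_vector <- function(node_counts, graph) {
  bad <- setdiff(names(node_counts), graph$nodes$node_id)
  if (length(bad)) stop_id("unknown node id(s): %s", bad)
  mets <- sort(unique(unlist(graph$nodes$metabolite_ids)))
  v <- setNames(numeric(length(mets)), mets)
  for (nid in names(node_counts)) {
    if (node_counts[[nid]] == 0) next
    v[graph$nodes[nid, "metabolite_ids"][[1]]] <-
      v[graph$nodes[nid, "metabolite_ids"][[1]]] + node_counts[[nid]]
  }
  structure(v, scale = "raw", class = c("compound_vector", "numeric"))
}

#' Rescale a compound vector to total 100,000
#'
#' @param v a raw (or already scaled) `compound_vector` with positive sum.
#' @return the vector scaled so its entries sum to 100,000; idempotent.
#' @export
scale_vector <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("zero compound vector cannot be scaled", call. = FALSE)
  out <- v * (100000 / s)
  attr(out, "scale") <- "scaled"
  out
}

#' Scaled target compound vector of one diet
#'
#' Sums node read counts across the diet's animals (the raw compound
#' vector of the diet's pooled reads) and rescales to total 100,000.
#'
#' @param cm a raw `count_matrix`.
#' @param graph a `metabolic_graph`.
#' @param diet which diet to average.
#' @return a scaled `compound_vector`.
#' @export
make_target <- function(cm, graph, diet = "CONC") {
  cols <- which(cm$diet == diet)
  if (length(cols) == 0) stop(sprintf("no animals in diet %s", diet),
                              call. = FALSE)
  common <- intersect(rownames(cm$counts), graph$nodes$node_id)
  pooled <- rowSums(cm$counts[common, cols, drop = FALSE])
  scale_vector(compound_vector(pooled, graph))
}

#' Annealing configuration
#'
#' @param move_rule `"swap1"` (move single reads anywhere) or `"swap2"`
#'   (move a read off each endpoint of a source edge onto the endpoints of
#'   a destination edge).
#' @param iterations chain length.
#' @param initial_temperature,cooling_factor geometric schedule
#'   `T_k = T0 * alpha^k`.
#' @param restarts independent chains per start; the best-ever state across
#'   each chain is kept and the chain closest to the target wins.
#' @param seed master seed; restart sub-seeds are derived from it.
#' @return list of class `annealing_config`.
#' @export
annealing_config <- function(move_rule = c("swap1", "swap2"),
                             iterations = 20000L,
                             initial_temperature = 1.0,
                             cooling_factor = 0.9995,
                             restarts = 10L, seed = 1L) {
  move_rule <- match.arg(move_rule)
  stopifnot(iterations >= 1, restarts >= 1,
            cooling_factor > 0, cooling_factor < 1)
  structure(list(move_rule = move_rule, iterations = as.integer(iterations),
                 initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "annealing_config")
}

# 0-based metabolite index lists and edge matrix for the C++ chain
anneal_inputs <- function(graph, node_ids) {
  mets <- sort(unique(unlist(graph$nodes$metabolite_ids)))
  node_mets <- lapply(node_ids, function(nid)
    match(graph$nodes[nid, "metabolite_ids"][[1]], mets) - 1L)
  e <- graph$edges
  keep <- e$from %in% node_ids & e$to %in% node_ids
  edges <- cbind(match(e$from[keep], node_ids),
                 match(e$to[keep], node_ids)) - 1L
  if (!nrow(edges)) edges <- matrix(integer(), ncol = 2)
  list(mets = mets, node_mets = node_mets, edges = edges)
}

#' Propose one annealing move
#'
#' `swap1` moves one read from a node drawn proportionally to its count to
#' a uniformly chosen node. `swap2` draws a source edge whose endpoints
#' both hold a read and a destination edge, moving one read across each
#' endpoint pair. Total reads are conserved.
#'
#' @param counts named integer counts over nodes.
#' @param rule `"swap1"` or `"swap2"`.
#' @param graph `metabolic_graph` (required for `swap2`).
#' @return the candidate count vector.
#' @export
propose_move <- function(counts, rule = c("swap1", "swap2"), graph = NULL) {
  rule <- match.arg(rule)
  n <- length(counts)
  if (rule == "swap1") {
    if (sum(counts) < 1) stop("no reads to move", call. = FALSE)
    src <- sample.int(n, 1, prob = counts)
    dst <- sample.int(n, 1)
    counts[src] <- counts[src] - 1L
    counts[dst] <- counts[dst] + 1L
  } else {
    stopifnot(!is.null(graph))
    e <- graph$edges
    keep <- e$from %in% names(counts) & e$to %in% names(counts)
    e <- e[keep, , drop = FALSE]
    ok <- counts[e$from] > 0 & counts[e$to] > 0
    if (!any(ok)) stop("no edge joins two nodes that both hold reads",
                       call. = FALSE)
    se <- sample(which(ok), 1)
    de <- sample.int(nrow(e), 1)
    src <- c(e$from[se], e$to[se]); dst <- c(e$from[de], e$to[de])
    if (runif(1) < 0.5) src <- rev(src)
    if (runif(1) < 0.5) dst <- rev(dst)
    for (k in 1:2) {
      counts[src[k]] <- counts[src[k]] - 1L
      counts[dst[k]] <- counts[dst[k]] + 1L
    }
  }
  counts
}

#' Simulated-annealing search for a read distribution matching a target
#'
#' Minimizes the Euclidean distance between the state's scaled compound
#' vector and `target` by Metropolis-accepted single-read (`swap1`) or
#' edge-paired (`swap2`) moves under geometric cooling. Runs
#' `cfg$restarts` independent chains from the same start (sub-seeds
#' derived from `cfg$seed`) and returns the chain whose best-ever state is
#' closest to the target.
#'
#' @param start_counts named integer counts over graph nodes (> 0 total).
#' @param target a scaled `compound_vector` over the graph's metabolites.
#' @param cfg an [annealing_config()].
#' @param graph the `metabolic_graph`.
#' @return an `annealing_result`: `counts` (best state), `objective`
#'   (its compound distance to target), `initial_objective`, `trajectory`
#'   (best-so-far, winning chain), `restart_objectives`.
#' @export
anneal <- function(start_counts, target, cfg, graph) {
  stopifnot(inherits(cfg, "annealing_config"), sum(start_counts) > 0)
  node_ids <- names(start_counts)
  ai <- anneal_inputs(graph, node_ids)
  tv <- setNames(numeric(length(ai$mets)), ai$mets)
  tv[intersect(names(target), ai$mets)] <-
    target[intersect(names(target), ai$mets)]
  if (cfg$move_rule == "swap2" && nrow(ai$edges) == 0)
    stop("swap2 requires at least one edge among the counted nodes",
         call. = FALSE)
  chains <- lapply(seq_len(cfg$restarts), function(r) {
    with_seed(derive_subseed(cfg$seed, r), {
      anneal_chain_cpp(as.integer(start_counts), ai$node_mets,
                       length(ai$mets), unname(tv), cfg$iterations,
                       cfg$initial_temperature, cfg$cooling_factor,
                       if (cfg$move_rule == "swap1") 1L else 2L,
                       ai$edges, max(1L, cfg$iterations %/% 200L))
    })
  })
  objs <- vapply(chains, `[[`, 0, "best_objective")
  best <- chains[[which.min(objs)]]
  stopifnot(sum(best$counts) == sum(start_counts))
  # the chain maintains the objective incrementally through large
  # near-cancelling sums; recompute the reported distances directly
  exact_dist <- function(counts) {
    v <- scale_vector(compound_vector(setNames(counts, node_ids), graph))
    sqrt(sum((as.numeric(v) - as.numeric(tv[names(v)]))^2))
  }
  structure(list(counts = setNames(best$counts, node_ids),
                 objective = exact_dist(best$counts),
                 initial_objective = exact_dist(start_counts),
                 trajectory = best$trajectory,
                 restart_objectives = objs,
                 move_rule = cfg$move_rule),
            class = "annealing_result")
}

#' @export
print.annealing_result <- function(x, ...) {
  cat(sprintf("<annealing_result: %s> objective %.4g (from %.4g; best of %d restarts)\n",
              x$move_rule, x$objective, x$initial_objective,
              length(x$restart_objectives)))
  invisible(x)
}

#' Full diet-shift simulation experiment
#'
#' For each FORG animal, each target diet (the pooled CONC compound vector
#' simulates the diet shift, the pooled FORG vector simulates staying) and
#' each move rule, runs best-of-restarts annealing from that animal's read
#' distribution. Reports all pairwise compound and node-profile distances
#' among the per-condition best simulations, alongside the real animals'
#' pairwise distances.
#'
#' @param cm a raw `count_matrix`.
#' @param graph the microbial `metabolic_graph`.
#' @param cfg an [annealing_config()] (its `move_rule` is ignored; both
#'   rules are run).
#' @param move_rules move rules to run.
#' @param target_diets target diets to run.
#' @return list with `runs` (per start x condition: final objective),
#'   `pairwise` (per condition: simulated pairwise compound and node
#'   distances), `real_pairwise` (the FORG animals' own distances), and
#'   `results` (the annealing_result objects).
#' @export
diet_shift_experiment <- function(cm, graph, cfg,
                                  move_rules = c("swap1", "swap2"),
                                  target_diets = c("CONC", "FORG")) {
  stopifnot(inherits(cm, "count_matrix"), !cm$normalized)
  common <- intersect(rownames(cm$counts), graph$nodes$node_id)
  m <- cm$counts[common, , drop = FALSE]
  starts <- colnames(m)[cm$diet == "FORG"]
  targets <- lapply(setNames(target_diets, target_diets),
                    function(d) make_target(cm, graph, d))
  results <- list(); runs <- list(); pairwise <- list()
  for (rule in move_rules) {
    for (td in target_diets) {
      cond <- paste(rule, td, sep = "_")
      res <- lapply(starts, function(a) {
        c2 <- cfg
        c2$move_rule <- rule
        c2$seed <- derive_subseed(cfg$seed, match(a, starts),
                                  match(rule, move_rules),
                                  match(td, target_diets))
        anneal(m[, a], targets[[td]], c2, graph)
      })
      names(res) <- starts
      results[[cond]] <- res
      runs[[cond]] <- data.frame(
        start_animal = starts, condition = td, move_rule = rule,
        final_compound_dist = vapply(res, `[[`, 0, "objective"),
        row.names = NULL)
      sim_counts <- vapply(res, `[[`, numeric(nrow(m)), "counts")
      cd <- compound_distance_matrix(sim_counts, graph, targets[[td]])
      nd <- as.matrix(dist(t(apply(sim_counts + 0, 2, profile_vector))))
      idx <- which(upper.tri(cd), arr.ind = TRUE)
      pairwise[[cond]] <- data.frame(
        a = starts[idx[, 1]], b = starts[idx[, 2]],
        condition = td, move_rule = rule,
        compound_dist = cd[idx], node_dist = nd[idx],
        row.names = NULL)
    }
  }
  real_cd <- compound_distance_matrix(m[, starts, drop = FALSE], graph)
  real_nd <- as.matrix(dist(t(apply(m[, starts, drop = FALSE], 2,
                                    profile_vector))))
  idx <- which(upper.tri(real_cd), arr.ind = TRUE)
  real_pairwise <- data.frame(
    a = starts[idx[, 1]], b = starts[idx[, 2]],
    compound_dist = real_cd[idx], node_dist = real_nd[idx],
    row.names = NULL)
  list(runs = do.call(rbind, runs), pairwise = do.call(rbind, pairwise),
       real_pairwise = real_pairwise, results = results)
}

# pairwise Euclidean distances between scaled compound vectors of columns
compound_distance_matrix <- function(count_cols, graph, target = NULL) {
  vs <- lapply(seq_len(ncol(count_cols)), function(j)
    scale_vector(compound_vector(count_cols[, j], graph)))
  mat <- do.call(cbind, vs)
  as.matrix(dist(t(mat)))
}
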
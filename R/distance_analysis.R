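# Profile-distance analysis: unit-length per-animal abundance vectors,
# pairwise Euclidean distances for nodes and OTUs, a proportional
# read-reassignment null, and the node-vs-OTU distance correlation.

#' Unit-length abundance profile
#'
#' `v_i = r_i / sqrt(sum_j r_j^2)`: counts scaled to a Euclidean unit
#' vector, so pairwise distances depend only on composition.
#'
#' @param counts non-negative count vector with at least one positive
#'   entry.
#' @return numeric vector of unit Euclidean norm.
#' @export
profile_vector <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  nrm <- sqrt(sum(counts^2))
  if (nrm == 0) stop("all-zero count vector has no profile", call. = FALSE)
  counts / nrm
}

#' Pairwise Euclidean distances between animal profiles
#'
#' Columns of the count matrix are converted to unit profiles
#' ([profile_vector()]) and all pairwise Euclidean distances computed.
#' Entries lie in [0, sqrt(2)] for non-negative unit vectors.
#'
#' @param counts feature x animal count matrix.
#' @param diet optional named diet labels; adds a pair-class table
#'   (FORG-FORG, CONC-CONC, FORG-CONC).
#' @return list of class `distance_matrix` with `d` (symmetric matrix),
#'   `pairs` (long-format data.frame `a`, `b`, `class`, `distance`).
#' @export
pairwise_distances <- function(counts, diet = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2, !is.null(colnames(counts)))
  profiles <- apply(counts, 2, profile_vector)
  d <- as.matrix(dist(t(profiles)))
  ids <- colnames(counts)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                      distance = d[idx], stringsAsFactors = FALSE)
  if (!is.null(diet)) {
    da <- diet[pairs$a]; dbb <- diet[pairs$b]
    pairs$class <- ifelse(da == dbb, paste0(da, "-", dbb), "FORG-CONC")
  }
  structure(list(d = d, pairs = pairs), class = "distance_matrix")
}

#' Proportional read-reassignment null for profile distances
#'
#' Within each diet, every node's pooled reads are multinomially
#' reassigned to that diet's animals with probabilities proportional to
#' their original mapped totals, and pairwise distances recomputed. The
#' per-replicate minimum and maximum within-diet distances describe how
#' much distance pure sampling noise can generate.
#'
#' @param cm a raw `count_matrix`.
#' @param n_rep number of replicates.
#' @param seed RNG seed.
#' @param keep_matrices retain the per-replicate reassigned count matrices
#'   (needed for [node_otu_correlation()] nulls).
#' @return list with `extremes` (data.frame `rep`, `diet`, `min`, `max`)
#'   and optionally `matrices` (list of reassigned count matrices).
#' @export
reassignment_null <- function(cm, n_rep = 100L, seed = NULL,
                              keep_matrices = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), !cm$normalized)
  diets <- unique(cm$diet)
  for (d in diets) {
    if (sum(cm$diet == d) < 2)
      stop(sprintf("diet %s has a single animal; distances undefined", d),
           call. = FALSE)
  }
  with_seed(seed, {
    mats <- if (keep_matrices) vector("list", n_rep) else NULL
    rows <- vector("list", n_rep * length(diets))
    k <- 0L
    for (r in seq_len(n_rep)) {
      newm <- cm$counts
      for (d in diets) {
        cols <- diet_columns(cm, d)
        pooled <- rowSums(cm$counts[, cols, drop = FALSE])
        prob <- cm$mapped_totals[cols]
        reassigned <- t(vapply(pooled, function(ct)
          as.integer(rmultinom(1, ct, prob)), integer(length(cols))))
        newm[, cols] <- reassigned
      }
      if (keep_matrices) mats[[r]] <- newm
      dm <- pairwise_distances(newm, cm$diet)
      for (d in diets) {
        within <- dm$pairs$distance[dm$pairs$class == paste0(d, "-", d)]
        k <- k + 1L
        rows[[k]] <- data.frame(rep = r, diet = d,
                                min = min(within), max = max(within))
      }
    }
    out <- list(extremes = do.call(rbind, rows))
    if (keep_matrices) out$matrices <- mats
    out
  })
}

#' Node-vs-OTU distance correlation with a reassignment null
#'
#' Pearson correlation between node-profile and OTU-profile pairwise
#' distances over the within-diet animal pairs, compared to correlations
#' from jointly reassigned node and OTU matrices.
#'
#' @param dm_nodes,dm_otus `distance_matrix` objects (from
#'   [pairwise_distances()] with diet labels) over the same animals.
#' @param null_node_matrices,null_otu_matrices lists of reassigned count
#'   matrices from [reassignment_null()] (`keep_matrices = TRUE`) on the
#'   node and OTU tables; `NULL` skips the null.
#' @param diet named diet labels (for recomputing pair classes on nulls).
#' @param within_diet restrict to within-diet pairs (default) or use all
#'   pairs.
#' @return list with `r`, `null_r`, `p_value` (add-one, one-sided:
#'   fraction of null correlations at least as large).
#' @export
node_otu_correlation <- function(dm_nodes, dm_otus,
                                 null_node_matrices = NULL,
                                 null_otu_matrices = NULL,
                                 diet = NULL, within_diet = TRUE) {
  if (!identical(rownames(dm_nodes$d), rownames(dm_otus$d)))
    stop("node and OTU distance matrices cover different animals",
         call. = FALSE)
  pair_r <- function(pn, po) {
    stopifnot(all(pn$a == po$a), all(pn$b == po$b))
    sel <- if (within_diet && !is.null(pn$class))
      pn$class != "FORG-CONC" else rep(TRUE, nrow(pn))
    x <- pn$distance[sel]; y <- po$distance[sel]
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero variance in distances; correlation undefined")
      return(NA_real_)
    }
    cor(x, y)
  }
  r <- pair_r(dm_nodes$pairs, dm_otus$pairs)
  null_r <- NULL; p <- NA_real_
  if (!is.null(null_node_matrices)) {
    stopifnot(length(null_node_matrices) == length(null_otu_matrices))
    null_r <- vapply(seq_along(null_node_matrices), function(i) {
      dn <- pairwise_distances(null_node_matrices[[i]], diet)
      do_ <- pairwise_distances(null_otu_matrices[[i]], diet)
      pair_r(dn$pairs, do_$pairs)
    }, 0)
    if (!is.na(r)) p <- add_one_pvalue(null_r, r, absolute = FALSE)
  }
  list(r = r, null_r = null_r, p_value = p)
}
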
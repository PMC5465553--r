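# Diet-contrast statistics on node x animal count matrices: per-million
# normalization, the zero/one/log-normal three-state mixture with LRT,
# per-node rank-sum tests with FDR, read-randomization nulls for layer and
# network-statistic contrasts, presence/absence analysis, the per-node
# variance contrast with depth-equalized resampling, and the VFA
# concentration correlation.

#' Construct a node x animal count matrix
#'
#' @param counts integer matrix, rows = nodes, columns = animals.
#' @param diet character vector over animals (`"FORG"` / `"CONC"`).
#' @param mapped_totals per-animal total mapped reads (>= column sums);
#'   defaults to the column sums.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, diet, mapped_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            length(diet) == ncol(counts),
            length(mapped_totals) == ncol(counts))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(colSums(counts) > mapped_totals + 1e-9))
    stop("column sums exceed mapped totals", call. = FALSE)
  structure(list(counts = counts,
                 diet = setNames(as.character(diet), colnames(counts)),
                 mapped_totals = setNames(as.numeric(mapped_totals),
                                          colnames(counts)),
                 normalized = FALSE),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix%s> %d nodes x %d animals (%s)\n",
              if (x$normalized) " (normalized)" else "",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$diet)), table(x$diet)),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write a count matrix as TSV
#'
#' The TSV carries nodes as rows and animals as columns (first column
#' `node_id`); diet labels and mapped totals come from a metadata
#' data.frame with columns `animal_id`, `diet`, `mapped_total`.
#'
#' @param path TSV path.
#' @param metadata sample metadata data.frame.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path, metadata) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  meta <- metadata[match(colnames(m), metadata$animal_id), ]
  count_matrix(m, meta$diet, meta$mapped_total)
}

#' @rdname read_count_matrix
#' @param cm a `count_matrix`.
#' @export
write_count_matrix <- function(cm, path) {
  d <- data.frame(node_id = rownames(cm$counts), cm$counts,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-million normalization
#'
#' Scales each animal's node counts to reads per node per 10^6 mapped
#' reads: `value = count * 1e6 / mapped_total`.
#'
#' @param cm a raw `count_matrix`.
#' @return the normalized `count_matrix`.
#' @export
normalize_counts <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$mapped_totals <= 0))
    stop("zero mapped total", call. = FALSE)
  out <- cm
  out$counts <- sweep(cm$counts, 2, cm$mapped_totals, "/") * 1e6
  out$raw <- cm$counts
  out$normalized <- TRUE
  out
}

diet_columns <- function(cm, diet) which(cm$diet == diet)

#' Fit the three-state read-density distribution
#'
#' Mixture over nodes: a point mass at zero reads (weight `p0`), a point
#' mass at one read (`p1`), and, for nodes with two or more reads, a
#' log-normal truncated to (1, Inf) with weight `1 - p0 - p1`. `p0` and
#' `p1` are the empirical fractions; `meanlog`/`sdlog` come from numerical
#' maximum likelihood on the values above one.
#'
#' @param x numeric vector of per-node read counts (one entry per node;
#'   the zero state is `x == 0`, the one-read state is `0 < x <= 1`, and
#'   the log-normal component is fit to the values above 1 — for integer
#'   counts, exactly the nodes with two or more reads).
#' @return object of class `three_state_fit` with `p0`, `p1`, `meanlog`,
#'   `sdlog`, `loglik`, `n`.
#' @export
fit_three_state <- function(x) {
  stopifnot(length(x) >= 10, all(x >= 0))
  n <- length(x)
  n0 <- sum(x == 0); n1 <- sum(x > 0 & x <= 1)
  y <- x[x > 1]
  p0 <- n0 / n; p1 <- n1 / n
  ll_disc <- (if (n0) n0 * log(p0) else 0) + (if (n1) n1 * log(p1) else 0) +
    (if (length(y)) length(y) * log(1 - p0 - p1) else 0)
  if (length(y) == 0) {
    return(structure(list(p0 = p0, p1 = p1, meanlog = NA_real_,
                          sdlog = NA_real_, loglik = ll_disc, n = n),
                     class = "three_state_fit"))
  }
  if (length(unique(y)) < 3)
    stop("fewer than 3 distinct values above 1; cannot fit the log-normal component",
         call. = FALSE)
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    -sum(dlnorm(y, m, s, log = TRUE)) +
      length(y) * log1p(-plnorm(1, m, s))
  }
  init <- c(mean(log(y)), log(max(sd(log(y)), 1e-3)))
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  structure(list(p0 = p0, p1 = p1, meanlog = opt$par[1],
                 sdlog = exp(opt$par[2]),
                 loglik = ll_disc - opt$value, n = n),
            class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  cat(sprintf("<three_state_fit> p0=%.3f p1=%.3f meanlog=%.3f sdlog=%.3f loglik=%.2f (n=%d)\n",
              x$p0, x$p1, x$meanlog, x$sdlog, x$loglik, x$n))
  invisible(x)
}

#' Likelihood-ratio test for diet-specific read-density distributions
#'
#' Compares the sum of the per-diet three-state log-likelihoods to the
#' log-likelihood of a single pooled fit: `LR = 2 (ll_forg + ll_conc -
#' ll_pooled)`, chi-square distributed under the null. The default df of 4
#' counts the free parameters gained by splitting (two fits of 4 parameters
#' against one); `df = 5` reproduces the convention of reporting one extra
#' degree.
#'
#' @param fit_forg,fit_conc,fit_pooled `three_state_fit`s on the FORG,
#'   CONC and pooled count vectors.
#' @param df chi-square degrees of freedom.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt_diets <- function(fit_forg, fit_conc, fit_pooled, df = 4) {
  stat <- max(0, 2 * (fit_forg$loglik + fit_conc$loglik - fit_pooled$loglik))
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Per-node differential-abundance tests
#'
#' Two-sample Wilcoxon rank-sum test per node on normalized counts,
#' Benjamini-Hochberg corrected; direction is the sign of the FORG - CONC
#' mean difference. Nodes with no reads anywhere are skipped.
#'
#' @param nc a normalized `count_matrix`.
#' @param alpha FDR level used for the `significant` flag.
#' @return data.frame with `node_id`, `W`, `p_value`, `q_value`,
#'   `direction` (`"FORG"`, `"CONC"`, `"none"`), `significant`.
#' @export
per_node_tests <- function(nc, alpha = 0.05) {
  stopifnot(inherits(nc, "count_matrix"), nc$normalized)
  f <- diet_columns(nc, "FORG"); c_ <- diet_columns(nc, "CONC")
  stopifnot(length(f) >= 2, length(c_) >= 2)
  keep <- rowSums(nc$counts) > 0
  m <- nc$counts[keep, , drop = FALSE]
  res <- t(apply(m, 1, function(v) {
    if (all(v == v[1])) return(c(NA_real_, 1))
    wt <- suppressWarnings(wilcox.test(v[f], v[c_]))
    c(wt$statistic, wt$p.value)
  }))
  q <- p.adjust(res[, 2], method = "BH")
  dirn <- ifelse(rowMeans(m[, f, drop = FALSE]) >
                   rowMeans(m[, c_, drop = FALSE]), "FORG",
                 ifelse(rowMeans(m[, f, drop = FALSE]) <
                          rowMeans(m[, c_, drop = FALSE]), "CONC", "none"))
  data.frame(node_id = rownames(m), W = res[, 1], p_value = res[, 2],
             q_value = q, direction = dirn,
             significant = q < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Read-randomization null: pool per-node reads over both diets and assign
# each read independently to the pseudo-FORG group with probability
# n_forg / n_total (a binomial split of every node's pooled mass). Returns a
# nodes x n_rand matrix pair.
randomized_split <- function(pooled, n_forg, n_total, n_rand) {
  p <- n_forg / n_total
  forg <- matrix(rbinom(length(pooled) * n_rand, rep(pooled, n_rand), p),
                 nrow = length(pooled))
  list(forg = forg, conc = matrix(rep(pooled, n_rand),
                                  nrow = length(pooled)) - forg)
}

weighted_mean_cols <- function(stat, w) {
  colSums(stat * w) / colSums(w)
}

new_randomization_result <- function(observed, null, n_rand) {
  structure(list(observed = observed, null = null,
                 max_abs_null = max(abs(null)),
                 p_value = add_one_pvalue(null, observed),
                 n_rand = n_rand),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> observed=%.4g max|null|=%.4g P=%.4g (n_rand=%d)\n",
              x$observed, x$max_abs_null, x$p_value, x$n_rand))
  invisible(x)
}

#' Diet contrast in read-weighted mean layer
#'
#' Observed statistic: (read-weighted mean layer of the FORG reads) minus
#' (CONC), reads on unlayered nodes excluded. The null pools the mapped
#' reads across diets and randomly reassigns each pooled read to a
#' pseudo-FORG / pseudo-CONC group of the original expected sizes,
#' recomputing the difference `n_rand` times.
#'
#' @param cm a raw `count_matrix`.
#' @param layers named layer vector from [assign_layers()].
#' @param n_rand number of randomizations.
#' @param seed RNG seed.
#' @return a `randomization_result` (observed, null sample, max |null|,
#'   add-one P-value).
#' @export
mean_layer_test <- function(cm, layers, n_rand = 1000L, seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"), !cm$normalized)
  lay <- layers[rownames(cm$counts)]
  keep <- !is.na(lay)
  m <- cm$counts[keep, , drop = FALSE]
  lay <- as.numeric(lay[keep])
  f <- diet_columns(cm, "FORG"); c_ <- diet_columns(cm, "CONC")
  rf <- rowSums(m[, f, drop = FALSE]); rc <- rowSums(m[, c_, drop = FALSE])
  if (sum(rf) + sum(rc) == 0) stop("no reads on layered nodes", call. = FALSE)
  observed <- sum(lay * rf) / sum(rf) - sum(lay * rc) / sum(rc)
  with_seed(seed, {
    sp <- randomized_split(rf + rc, sum(rf), sum(rf) + sum(rc), n_rand)
    null <- weighted_mean_cols(lay, sp$forg) - weighted_mean_cols(lay, sp$conc)
    new_randomization_result(observed, null, n_rand)
  })
}

#' Per-node network statistics
#'
#' `carbon_sum` is the total carbon atoms over the node's metabolite set;
#' `betweenness` is the total number of all-pairs shortest paths passing
#' through the node (a raw path count, not the fractional Brandes value);
#' `degree` is the edge count; `clustering` the local triangle density
#' (0 for degree < 2).
#'
#' @param graph a `metabolic_graph`.
#' @param stat statistic name.
#' @param db the `reaction_db` (needed for `carbon_sum`).
#' @return named numeric vector over graph nodes.
#' @export
node_statistic <- function(graph,
                           stat = c("carbon_sum", "betweenness", "degree",
                                    "clustering"),
                           db = NULL) {
  stat <- match.arg(stat)
  ids <- graph$nodes$node_id
  switch(stat,
    carbon_sum = {
      if (is.null(db)) stop("carbon_sum needs the reaction database",
                            call. = FALSE)
      cc <- setNames(db$metabolites$carbon_count,
                     db$metabolites$metabolite_id)
      setNames(vapply(graph$nodes$metabolite_ids,
                      function(s) sum(cc[s]), 0), ids)
    },
    degree = igraph::degree(graph$graph)[ids],
    clustering = {
      tr <- igraph::transitivity(graph$graph, type = "local",
                                 vids = ids, isolates = "zero")
      setNames(ifelse(is.nan(tr), 0, tr), ids)
    },
    betweenness = betweenness_path_count(graph$graph)[ids]
  )
}

# Raw shortest-path-count betweenness: B(v) = sum over unordered pairs
# (s,t), s,t != v, of sigma_sv * sigma_vt where d(s,v) + d(v,t) = d(s,t).
# sigma = number of shortest paths, from a per-source BFS layer recursion.
betweenness_path_count <- function(g) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  d <- igraph::distances(g)
  adj <- igraph::as_adj_list(g)
  sig <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in seq_len(n)) {
    sig[s, s] <- 1
    ds <- d[s, ]
    fin <- which(is.finite(ds) & ds > 0)
    for (u in fin[order(ds[fin])]) {
      nb <- as.integer(adj[[u]])
      pred <- nb[ds[nb] == ds[u] - 1]
      sig[s, u] <- sum(sig[s, pred])
    }
  }
  B <- numeric(n)
  for (v in seq_len(n)) {
    thr <- outer(d[, v], d[v, ], "+")
    ok <- is.finite(thr) & thr == d
    ok[v, ] <- FALSE; ok[, v] <- FALSE; diag(ok) <- FALSE
    contrib <- outer(sig[, v], sig[v, ]) * ok
    B[v] <- sum(contrib) / 2
  }
  setNames(B, ids)
}

#' Diet contrast in a read-weighted network statistic
#'
#' Observed statistic: difference between the diets in the read-weighted
#' mean of a per-node network statistic, weights being each diet's summed
#' normalized read counts. Significance from the same pooled-read
#' randomization null as [mean_layer_test()].
#'
#' @param cm a raw `count_matrix`.
#' @param graph the microbial `metabolic_graph`.
#' @param stat one of `"carbon_sum"`, `"betweenness"`, `"degree"`,
#'   `"clustering"`.
#' @param db `reaction_db` for `carbon_sum`.
#' @param n_rand,seed randomization controls.
#' @param weighted_mean if `FALSE`, use the unnormalized mean of
#'   weight x statistic products instead of the weighted mean.
#' @return a `randomization_result`.
#' @export
network_stat_contrast <- function(cm, graph, stat, db = NULL,
                                  n_rand = 1000L, seed = NULL,
                                  weighted_mean = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), !cm$normalized)
  s <- node_statistic(graph, stat, db)
  common <- intersect(rownames(cm$counts), names(s))
  m <- cm$counts[common, , drop = FALSE]
  s <- as.numeric(s[common])
  f <- diet_columns(cm, "FORG"); c_ <- diet_columns(cm, "CONC")
  nm <- sweep(m, 2, cm$mapped_totals, "/") * 1e6
  wf <- rowSums(nm[, f, drop = FALSE]); wc <- rowSums(nm[, c_, drop = FALSE])
  agg <- if (weighted_mean) {
    function(w) sum(s * w) / sum(w)
  } else {
    function(w) mean(s * w)
  }
  observed <- agg(wf) - agg(wc)
  rf <- rowSums(m[, f, drop = FALSE]); rc <- rowSums(m[, c_, drop = FALSE])
  with_seed(seed, {
    sp <- randomized_split(rf + rc, sum(rf), sum(rf) + sum(rc), n_rand)
    null <- if (weighted_mean) {
      weighted_mean_cols(s, sp$forg) - weighted_mean_cols(s, sp$conc)
    } else {
      colMeans(s * sp$forg) - colMeans(s * sp$conc)
    }
    new_randomization_result(observed, null, n_rand)
  })
}

#' Read count vs network layer correlation
#'
#' Per diet: the Pearson correlation across nodes between summed normalized
#' read count and layer number; the per-layer proportion of each diet's
#' mapped reads (summing to 1); and, when per-node test results are
#' supplied, the per-layer proportion of differentially abundant nodes.
#'
#' @param nc a normalized `count_matrix`.
#' @param layers named layer vector.
#' @param tests optional output of [per_node_tests()].
#' @return list with `correlation` (named by diet), `layer_proportions`
#'   (data.frame `layer`, `FORG`, `CONC`), and `differential_by_layer`.
#' @export
layer_correlation <- function(nc, layers, tests = NULL) {
  stopifnot(inherits(nc, "count_matrix"), nc$normalized)
  lay <- layers[rownames(nc$counts)]
  keep <- !is.na(lay)
  m <- nc$counts[keep, , drop = FALSE]
  lay <- as.numeric(lay[keep])
  if (length(unique(lay)) < 3) stop("fewer than 3 layers", call. = FALSE)
  f <- diet_columns(nc, "FORG"); c_ <- diet_columns(nc, "CONC")
  vf <- rowSums(m[, f, drop = FALSE]); vc <- rowSums(m[, c_, drop = FALSE])
  corr <- c(FORG = cor(vf, lay), CONC = cor(vc, lay))
  levs <- sort(unique(lay))
  prop <- data.frame(
    layer = levs,
    FORG = vapply(levs, function(L) sum(vf[lay == L]) / sum(vf), 0),
    CONC = vapply(levs, function(L) sum(vc[lay == L]) / sum(vc), 0))
  diffl <- NULL
  if (!is.null(tests)) {
    sig <- setNames(tests$significant, tests$node_id)
    node_sig <- sig[rownames(m)]; node_sig[is.na(node_sig)] <- FALSE
    diffl <- data.frame(
      layer = levs,
      prop_differential = vapply(levs, function(L)
        mean(node_sig[lay == L]), 0))
  }
  list(correlation = corr, layer_proportions = prop,
       differential_by_layer = diffl)
}

#' Presence/absence analysis of nodes between diets
#'
#' Classifies nodes observed in either diet as shared or diet-exclusive.
#' For each exclusive node, a randomization P-value asks how often all of
#' its pooled reads would land in one diet when each read is assigned to an
#' animal with probability proportional to that animal's mapped total.
#'
#' @param cm a raw `count_matrix`.
#' @param n_rand randomizations per exclusive node.
#' @param seed RNG seed.
#' @param alpha significance level for the exclusive-node counts.
#' @return list with `n_observed`, `n_shared`, `n_forg_only`,
#'   `n_conc_only`, `n_forg_significant`, `n_conc_significant`,
#'   `mean_reads_forg_only`, `mean_reads_conc_only`,
#'   `max_reads_differential`, and the per-node `exclusive` table.
#' @export
presence_absence <- function(cm, n_rand = 1000L, seed = NULL, alpha = 0.01) {
  stopifnot(inherits(cm, "count_matrix"), !cm$normalized)
  f <- diet_columns(cm, "FORG"); c_ <- diet_columns(cm, "CONC")
  rf <- rowSums(cm$counts[, f, drop = FALSE])
  rc <- rowSums(cm$counts[, c_, drop = FALSE])
  observed <- rf + rc > 0
  shared <- observed & rf > 0 & rc > 0
  forg_only <- observed & rc == 0
  conc_only <- observed & rf == 0
  p_forg <- sum(cm$mapped_totals[f]) / sum(cm$mapped_totals)
  excl <- data.frame(node_id = rownames(cm$counts)[forg_only | conc_only],
                     diet = ifelse(forg_only[forg_only | conc_only],
                                   "FORG", "CONC"),
                     reads = (rf + rc)[forg_only | conc_only],
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    excl$p_value <- vapply(seq_len(nrow(excl)), function(i) {
      p <- if (excl$diet[i] == "FORG") p_forg else 1 - p_forg
      draws <- rbinom(n_rand, excl$reads[i], p)
      (sum(draws == excl$reads[i]) + 1) / (n_rand + 1)
    }, 0)
    list(n_observed = sum(observed), n_shared = sum(shared),
         n_forg_only = sum(forg_only), n_conc_only = sum(conc_only),
         n_forg_significant = sum(excl$diet == "FORG" &
                                    excl$p_value < alpha),
         n_conc_significant = sum(excl$diet == "CONC" &
                                    excl$p_value < alpha),
         mean_reads_forg_only = mean(excl$reads[excl$diet == "FORG"]),
         mean_reads_conc_only = mean(excl$reads[excl$diet == "CONC"]),
         max_reads_differential = if (nrow(excl)) max(excl$reads) else NA,
         exclusive = excl)
  })
}

# draw k reads without replacement from a node-count vector
# (multivariate hypergeometric via sequential rhyper)
draw_without_replacement <- function(counts, k) {
  total <- sum(counts)
  out <- integer(length(counts))
  remaining <- total
  for (i in seq_along(counts)) {
    if (k <= 0) break
    x <- rhyper(1, counts[i], remaining - counts[i], k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - counts[i]
  }
  out
}

#' Diet contrast in inter-animal read-count variance
#'
#' Per node, the across-animal variance of normalized counts within each
#' diet; the two diets' variance vectors are compared with a paired
#' Wilcoxon (Mann-Whitney) test. Because unequal sequencing depth inflates
#' variance, the test is repeated on depth-equalized datasets in which
#' `subsample_reads` mapped reads are drawn per animal without replacement
#' (with replacement, flagged, for animals with fewer reads).
#'
#' @param cm a raw `count_matrix`.
#' @param subsample_reads reads drawn per animal per replicate.
#' @param n_rep number of resampled datasets.
#' @param seed RNG seed.
#' @return list with `p_value` (observed paired test),
#'   `resampled_p` (length `n_rep`), `with_replacement` (flagged animals),
#'   `var_forg`, `var_conc`.
#' @export
variance_contrast <- function(cm, subsample_reads = 100000L, n_rep = 1000L,
                              seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"), !cm$normalized)
  f <- diet_columns(cm, "FORG"); c_ <- diet_columns(cm, "CONC")
  stopifnot(length(f) >= 2, length(c_) >= 2)
  nc <- normalize_counts(cm)
  vf <- apply(nc$counts[, f, drop = FALSE], 1, var)
  vc <- apply(nc$counts[, c_, drop = FALSE], 1, var)
  keep <- vf + vc > 0
  paired_p <- function(a, b) {
    if (all(a == b)) return(1)  # no paired differences to rank
    suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  }
  p_obs <- paired_p(vf[keep], vc[keep])
  col_tot <- colSums(cm$counts)
  flagged <- colnames(cm$counts)[col_tot < subsample_reads]
  with_seed(seed, {
    ps <- vapply(seq_len(n_rep), function(r) {
      sub <- apply(cm$counts, 2, function(col) {
        if (sum(col) >= subsample_reads) {
          draw_without_replacement(col, subsample_reads)
        } else {
          as.integer(rmultinom(1, subsample_reads,
                               prob = col + 1e-12))
        }
      })
      subn <- sub / subsample_reads * 1e6
      v1 <- apply(subn[, f, drop = FALSE], 1, var)
      v2 <- apply(subn[, c_, drop = FALSE], 1, var)
      k <- v1 + v2 > 0
      paired_p(v1[k], v2[k])
    }, 0)
    list(p_value = p_obs, resampled_p = ps, with_replacement = flagged,
         var_forg = vf, var_conc = vc)
  })
}

#' VFA concentration vs mapped-read correlation
#'
#' For each volatile fatty acid, the per-animal fraction of uniquely
#' mapped reads landing on nodes whose reaction uses the VFA is correlated
#' (Spearman, one-sided) with the measured ruminal concentration.
#'
#' @param cm a raw `count_matrix` (unique assignments).
#' @param vfa_node_map named list: VFA name -> character vector of node ids
#'   using it.
#' @param vfa_concentrations data.frame with `animal_id` and one column per
#'   VFA (animals may be missing).
#' @param alternative passed to [stats::cor.test()] (default `"greater"`,
#'   the one-sided reporting convention).
#' @return data.frame with `vfa`, `n_nodes`, `n_animals`, `rho`, `p_value`.
#' @export
vfa_correlation <- function(cm, vfa_node_map, vfa_concentrations,
                            alternative = "greater") {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  rows <- lapply(names(vfa_node_map), function(v) {
    nodes <- intersect(vfa_node_map[[v]], rownames(cm$counts))
    frac <- colSums(cm$counts[nodes, , drop = FALSE]) / totals
    conc <- vfa_concentrations[[v]][
      match(names(frac), vfa_concentrations$animal_id)]
    ok <- !is.na(conc)
    if (sum(ok) < 5) stop("fewer than 5 paired observations", call. = FALSE)
    if (length(unique(conc[ok])) < 2 || length(unique(frac[ok])) < 2) {
      warning(sprintf("constant values for %s; correlation undefined", v))
      return(data.frame(vfa = v, n_nodes = length(nodes),
                        n_animals = sum(ok), rho = NA_real_,
                        p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(frac[ok], conc[ok], method = "spearman",
                                    alternative = alternative))
    data.frame(vfa = v, n_nodes = length(nodes), n_animals = sum(ok),
               rho = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}
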
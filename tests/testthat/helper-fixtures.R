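# In-code fixtures and independent oracles shared across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- tiny databases -------------------------------------------------------

tiny_metabolites <- function() {
  data.frame(
    metabolite_id = c("A", "B", "C", "D", "ACETATE", "PROPIONATE",
                      "BUTYRATE"),
    name = c("a", "b", "c", "d", "acetate", "propionate", "butyrate"),
    carbon_count = c(3L, 4L, 5L, 6L, 2L, 3L, 4L))
}

tiny_enzyme <- function(reactions, residues = NULL) {
  list(residues = residues %||%
         paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = ""),
       reaction_ids = reactions)
}

tiny_microbial_db <- function() {
  reaction_db(
    tiny_metabolites(),
    list(R1 = c("A", "B"), R2 = c("B", "C"), R3 = c("A", "B"),
         R4 = c("ACETATE", "C"), R5 = c("C", "D")),
    list(E1 = tiny_enzyme(c("R1")), E2 = tiny_enzyme(c("R2"))),
    "microbial")
}

tiny_host_db <- function() {
  reaction_db(
    tiny_metabolites(),
    list(H1 = c("ACETATE", "A"), H2 = c("A", "B")),
    list(), "host")
}

tiny_merged <- function(cutoff = 25, iface_name = "VFA") {
  dbm <- tiny_microbial_db(); dbh <- tiny_host_db()
  gm <- build_graph(dbm, cutoff); gh <- build_graph(dbh, cutoff)
  ifs <- make_interface_set(iface_name, dbh, dbm)
  merge_networks(gh, gm, ifs)
}

# Random small database pair whose graphs stay mostly connected; used for
# property-style tests over many seeds.
random_db_pair <- function(seed, n_mets = 14, n_rx = 18, n_host_rx = 8) {
  set.seed(seed)
  ids <- c("ACETATE", "PROPIONATE", "BUTYRATE",
           sprintf("M%02d", seq_len(n_mets)))
  mets <- data.frame(metabolite_id = ids, name = ids,
                     carbon_count = sample(1:10, length(ids), TRUE))
  draw <- function(n, prefix, iface_p) {
    out <- lapply(seq_len(n), function(i) {
      base <- sample(ids[-(1:3)], sample(2:3, 1))
      unique(c(base, ids[1:3][runif(3) < iface_p]))
    })
    names(out) <- sprintf("%s%02d", prefix, seq_len(n))
    out
  }
  list(microbial = reaction_db(mets, draw(n_rx, "RXN", 0.15), list(),
                               "microbial"),
       host = reaction_db(mets, draw(n_host_rx, "HRX", 0.3), list(),
                          "host"))
}

# --- layering oracle: plain queue BFS from the interface frontier ---------

bfs_layers_oracle <- function(graph_obj, frontier) {
  ids <- graph_obj$nodes$node_id
  adj <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(graph_obj$edges))) {
    a <- graph_obj$edges$from[i]; b <- graph_obj$edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lay <- setNames(rep(NA_integer_, length(ids)), ids)
  frontier <- intersect(frontier, ids)
  lay[frontier] <- 0L
  queue <- frontier
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.na(lay[w])) {
        lay[w] <- lay[u] + 1L
        queue <- c(queue, w)
      }
    }
  }
  lay
}

merged_layers_oracle <- function(m) {
  c(bfs_layers_oracle(m$host, unique(m$interface_edges$host_node)),
    bfs_layers_oracle(m$microbial, unique(m$interface_edges$microbial_node)))
}

# --- Smith-Waterman oracle: plain-R full-matrix Gotoh DP ------------------
# Same scoring and traceback conventions as the package aligner
# (BLOSUM62; gap of length L costs open + L * ext; best cell = first
# maximum scanning rows then columns; preference diagonal, then
# gap-in-subject, then gap-in-query), written independently as three full
# matrices with an explicit traceback loop.

sw_oracle <- function(a, b, open = 11, ext = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (open + ext), E[i + 1, j] - ext)
      F_[i + 1, j + 1] <- max(H[i, j + 1] - (open + ext), F_[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + S[av[i], bv[j]],
                             E[i + 1, j + 1], F_[i + 1, j + 1])
    }
  }
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) for (j in 1:m) {
    if (H[i + 1, j + 1] > best) { best <- H[i + 1, j + 1]; bi <- i; bj <- j }
  }
  matches <- 0; aln_len <- 0
  a_lo <- bi; a_hi <- bi
  if (best > 0) {
    i <- bi; j <- bj; state <- "H"
    repeat {
      if (state == "H") {
        h <- H[i + 1, j + 1]
        if (h <= 0) break
        if (h == H[i, j] + S[av[i], bv[j]]) {
          aln_len <- aln_len + 1
          if (av[i] == bv[j]) matches <- matches + 1
          a_lo <- i; i <- i - 1; j <- j - 1
        } else if (h == F_[i + 1, j + 1]) state <- "F" else state <- "E"
      } else if (state == "F") {
        aln_len <- aln_len + 1
        a_lo <- i
        from_h <- F_[i + 1, j + 1] == H[i, j + 1] - (open + ext)
        i <- i - 1
        if (from_h) state <- "H"
      } else {
        aln_len <- aln_len + 1
        from_h <- E[i + 1, j + 1] == H[i + 1, j] - (open + ext)
        j <- j - 1
        if (from_h) state <- "H"
      }
    }
  }
  list(score = best,
       identity = if (aln_len > 0) matches / aln_len else 0,
       coverage = if (best > 0) (a_hi - a_lo + 1) / n else 0)
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

# mutate k distinct positions of a peptide to different residues
mutate_peptide <- function(x, k) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(x, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
  paste(ch, collapse = "")
}

# --- betweenness oracle: explicit shortest-path enumeration ---------------

betweenness_enumeration_oracle <- function(g) {
  ids <- igraph::V(g)$name
  n <- length(ids)
  B <- setNames(numeric(n), ids)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
      if (length(sp) == 0) next
      for (path in sp) {
        inner <- setdiff(as.integer(path), c(s, t))
        B[ids[inner]] <- B[ids[inner]] + 1
      }
    }
  }
  B
}

# --- count-matrix fixture --------------------------------------------------

toy_count_matrix <- function(counts, n_forg = NULL, mapped_totals = NULL) {
  counts <- as.matrix(counts)
  n_forg <- n_forg %||% (ncol(counts) %/% 2)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("N%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("A%02d", seq_len(ncol(counts)))
  diet <- rep(c("FORG", "CONC"), c(n_forg, ncol(counts) - n_forg))
  count_matrix(counts, diet,
               mapped_totals %||% pmax(colSums(counts), 1))
}

# small scenario for fast end-to-end generation
small_scenario <- function(seed = 7L, ...) {
  scenario_config(reads_per_animal = 20000L, seed = seed, ...)
}

# Toy 3-node graph with known metabolite sets for the annealing tests.
toy_shift_graph <- function() {
  mets <- data.frame(metabolite_id = c("A", "B", "C", "D"),
                     name = letters[1:4], carbon_count = 1L)
  db <- reaction_db(mets,
                    list(R1 = c("A", "B"), R2 = c("B", "C"),
                         R3 = c("C", "D")),
                    list(), "microbial")
  build_graph(db, 100)
}

# independent brute-force optimum: enumerate every distribution of `total`
# reads over the nodes and minimize the scaled compound distance
brute_force_optimum <- function(graph, total, target) {
  ids <- graph$nodes$node_id
  grid <- expand.grid(rep(list(0:total), length(ids)))
  grid <- grid[rowSums(grid) == total, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    counts <- setNames(as.integer(grid[i, ]), ids)
    v <- scale_vector(compound_vector(counts, graph))
    d <- sqrt(sum((as.numeric(v) - as.numeric(target[names(v)]))^2))
    best <- min(best, d)
  }
  best
}

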
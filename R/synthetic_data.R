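# Synthetic two-diet feeding-trial data: a reaction database pair
# (microbial + host), per-animal reads or node counts with diet-specific
# read-density structure, and an OTU table. The generator reproduces the
# statistical features the downstream analyses assume: per-node
# zero/one/log-normal read densities with diet-specific parameters, a
# configurable shift of one diet's reads toward low-layer nodes, higher
# inter-animal dispersion in that diet, and a subset of animals sharing a
# degenerate few-nodes-dominate profile.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a desk-scale analogue of a 16-animal two-diet trial:
#' 8 forage (FORG) + 8 concentrate (CONC) animals, 50,000 mapped reads per
#' animal, a 300-metabolite / 400-reaction microbial database with a
#' currency-metabolite tier broad enough that occurrence cutoffs of
#' 25/50/100 all bite, and interface metabolites (3 VFAs + 20 amino acids)
#' used by both networks. Per-diet read densities follow the
#' zero/one/log-normal mixture; the CONC diet gets a log-linear read shift
#' toward low-layer nodes (`layer_bias`), larger animal-to-animal
#' dispersion, and `n_degenerate` animals sharing a profile dominated by
#' `n_degenerate_nodes` nodes.
#'
#' @param n_metabolites,n_reactions,n_host_reactions,n_enzymes database
#'   sizes (metabolite count includes the 23 interface compounds).
#' @param currency_fraction fraction of metabolites designated currency
#'   (reused across many reactions).
#' @param carbon_range inclusive range of random carbon counts.
#' @param n_animals_per_diet animals per diet group.
#' @param reads_per_animal mapped reads per animal.
#' @param p0,p1 zero- and one-read state probabilities (shared).
#' @param meanlog_forg,meanlog_conc,sdlog_forg,sdlog_conc per-diet
#'   log-normal read-density parameters.
#' @param layer_bias log-fold depletion per layer applied to CONC node
#'   intensities (positive values shift CONC reads toward layer 0).
#' @param dispersion_forg,dispersion_conc sd of per-animal log-normal
#'   intensity noise.
#' @param n_degenerate number of CONC animals sharing the degenerate
#'   profile; `degenerate_dominance` is the intensity fraction their
#'   `n_degenerate_nodes` spike nodes absorb.
#' @param n_otus,otu_reads_per_animal,otu_diet_effect OTU table controls.
#' @param substitution_rate per-base substitution rate in generated reads.
#' @param seed master seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_metabolites = 300L, n_reactions = 400L,
                            n_host_reactions = 60L, n_enzymes = 450L,
                            currency_fraction = 0.05,
                            carbon_range = c(1L, 12L),
                            n_animals_per_diet = 8L,
                            reads_per_animal = 50000L,
                            p0 = 0.30, p1 = 0.08,
                            meanlog_forg = 3.7, meanlog_conc = 3.99,
                            sdlog_forg = 1.70, sdlog_conc = 1.64,
                            layer_bias = 0.5,
                            dispersion_forg = 0.2, dispersion_conc = 0.6,
                            n_degenerate = 3L, degenerate_dominance = 0.7,
                            n_degenerate_nodes = 5L,
                            n_otus = 150L, otu_reads_per_animal = 20000L,
                            otu_diet_effect = 1.0,
                            substitution_rate = 0,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_metabolites >= 50, cfg$n_reactions >= 20,
            cfg$p0 >= 0, cfg$p1 >= 0, cfg$p0 + cfg$p1 < 1,
            cfg$currency_fraction >= 0, cfg$currency_fraction <= 1,
            cfg$n_degenerate <= cfg$n_animals_per_diet)
  structure(cfg, class = "scenario_config")
}

interface_metabolite_table <- function() {
  ids <- default_interface_ids()
  data.frame(metabolite_id = unname(c(ids$vfa, ids$amino_acids)),
             name = names(c(ids$vfa, ids$amino_acids)),
             carbon_count = c(2L, 3L, 4L,  # acetate, propionate, butyrate
                              3L, 6L, 4L, 4L, 3L, 5L, 5L, 2L, 6L, 6L,
                              6L, 6L, 5L, 9L, 5L, 3L, 4L, 11L, 9L, 5L),
             stringsAsFactors = FALSE)
}

random_enzyme_residues <- function(n, len_range = c(130L, 400L)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
}

#' Generate the synthetic microbial and host reaction databases
#'
#' Reactions draw 2-6 generic metabolites each; a designated currency tier
#' is reused with graded probabilities so that occurrence cutoffs of
#' 25/50/100 remove nested currency sets; the 23 interface metabolites are
#' used by both networks. Enzymes (130-400 residues, random sequence)
#' cover every microbial reaction. Deterministic under `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return list with `microbial` and `host` `reaction_db`s (the host
#'   database includes butyrate so the butyrate pseudo-reaction attaches).
#' @export
gen_reaction_db <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(derive_subseed(cfg$seed, 101L), {
    iface <- interface_metabolite_table()
    n_generic <- cfg$n_metabolites - nrow(iface)
    if (n_generic < 30) stop("infeasible scenario: too few metabolites",
                             call. = FALSE)
    generic <- data.frame(
      metabolite_id = sprintf("M%04d", seq_len(n_generic)),
      name = sprintf("compound %d", seq_len(n_generic)),
      carbon_count = sample(cfg$carbon_range[1]:cfg$carbon_range[2],
                            n_generic, replace = TRUE),
      stringsAsFactors = FALSE)
    mets <- rbind(iface, generic)
    n_cur <- max(3L, round(cfg$currency_fraction * cfg$n_metabolites))
    currency_ids <- generic$metabolite_id[seq_len(n_cur)]
    # graded reuse so different occurrence cutoffs bite differently
    cur_prob <- seq(0.08, 0.5, length.out = n_cur)
    plain_ids <- setdiff(generic$metabolite_id, currency_ids)
    vfa_ids <- iface$metabolite_id[1:3]
    aa_ids <- iface$metabolite_id[-(1:3)]

    draw_reactions <- function(n, prefix, cur_p, vfa_p, aa_p) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        base <- sample(plain_ids, sample(2:4, 1))
        cur <- currency_ids[runif(n_cur) < cur_p]
        vfa <- vfa_ids[runif(3) < vfa_p]
        aa <- aa_ids[runif(20) < aa_p]
        out[[i]] <- unique(c(base, cur, vfa, aa))
      }
      names(out) <- sprintf("%s%04d", prefix, seq_len(n))
      out
    }
    # currency reuse is graded so the 25/50/100 cutoffs remove nested sets;
    # the host network uses the tier sparingly (it is small enough that no
    # metabolite reaches the cutoffs within it)
    rx_m <- draw_reactions(cfg$n_reactions, "RXN", cur_prob, 0.015, 0.006)
    rx_h <- draw_reactions(cfg$n_host_reactions, "HRX", 0.03, 0.10, 0.05)

    residues <- random_enzyme_residues(cfg$n_enzymes)
    rx_for_enzyme <- c(names(rx_m),
                       sample(names(rx_m), cfg$n_enzymes - cfg$n_reactions,
                              replace = TRUE))
    enzymes <- lapply(seq_len(cfg$n_enzymes), function(i) {
      rid <- rx_for_enzyme[i]
      if (runif(1) < 0.08) rid <- unique(c(rid, sample(names(rx_m), 1)))
      list(residues = residues[i], reaction_ids = rid)
    })
    names(enzymes) <- sprintf("ENZ%04d", seq_len(cfg$n_enzymes))

    microbial <- reaction_db(mets, rx_m, enzymes, "microbial")
    host <- reaction_db(mets, rx_h, list(), "host")
    host <- add_butyrate_pseudoreaction(host)
    list(microbial = microbial, host = host)
  })
}

# Per-diet base intensities over layered nodes. Zero/one/log-normal state
# is drawn once per node (shared across diets, so presence/absence is
# mostly shared); the log-normal value uses a common standard-normal draw
# scaled by each diet's (meanlog, sdlog), so the density differs by diet.
# "One-read" nodes get an intensity whose expected multinomial count is
# about one read.
gen_base_intensities <- function(node_ids, layers, cfg, seed) {
  with_seed(seed, {
    n <- length(node_ids)
    state <- sample(c("zero", "one", "ln"), n, replace = TRUE,
                    prob = c(cfg$p0, cfg$p1, 1 - cfg$p0 - cfg$p1))
    z <- rnorm(n)
    val <- function(meanlog, sdlog) {
      v <- numeric(n)
      v[state == "ln"] <- exp(meanlog + sdlog * z[state == "ln"])
      v[state == "one"] <- sum(v) / cfg$reads_per_animal
      v
    }
    lay <- as.numeric(layers[node_ids])
    lay[is.na(lay)] <- max(c(lay, 1), na.rm = TRUE)
    forg <- val(cfg$meanlog_forg, cfg$sdlog_forg)
    conc <- val(cfg$meanlog_conc, cfg$sdlog_conc) *
      exp(-cfg$layer_bias * lay)
    list(FORG = setNames(forg, node_ids), CONC = setNames(conc, node_ids),
         state = setNames(state, node_ids))
  })
}

#' Generate the synthetic node and OTU count matrices
#'
#' Node intensities follow the per-diet three-state densities of `cfg`,
#' with the CONC intensities tilted toward low-layer nodes
#' (`layer_bias`), larger CONC animal-level dispersion, and
#' `n_degenerate` CONC animals sharing a spike profile dominated by a few
#' nodes. Per-animal counts are multinomial draws of
#' `reads_per_animal`. The OTU matrix gets an independent diet effect for
#' the distance-correlation analyses.
#'
#' @param db the microbial `reaction_db` (unused directly; kept for
#'   interface symmetry).
#' @param merged a `merged_network` providing microbial node ids and
#'   layers.
#' @param cfg a [scenario_config()].
#' @return list with `cm` (node `count_matrix`), `otu` (OTU count matrix),
#'   `diet`, `base_intensities`, `degenerate_animals`.
#' @export
gen_count_matrix <- function(db, merged, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  node_ids <- merged$microbial$nodes$node_id
  layers <- merged$layer
  base <- gen_base_intensities(node_ids, layers, cfg,
                               derive_subseed(cfg$seed, 201L))
  n_f <- cfg$n_animals_per_diet; n_c <- cfg$n_animals_per_diet
  animals <- c(sprintf("F%02d", seq_len(n_f)), sprintf("C%02d", seq_len(n_c)))
  diet <- setNames(rep(c("FORG", "CONC"), c(n_f, n_c)), animals)
  degenerate <- tail(animals[diet == "CONC"], cfg$n_degenerate)
  with_seed(derive_subseed(cfg$seed, 202L), {
    spike_nodes <- sample(node_ids, cfg$n_degenerate_nodes,
                          prob = 1 / (1 + as.numeric(
                            ifelse(is.na(layers[node_ids]), 5,
                                   layers[node_ids]))))
    spike <- setNames(numeric(length(node_ids)), node_ids)
    spike[spike_nodes] <- exp(rnorm(cfg$n_degenerate_nodes, 0, 0.3))
    counts <- matrix(0L, length(node_ids), length(animals),
                     dimnames = list(node_ids, animals))
    for (a in animals) {
      d <- diet[[a]]
      disp <- if (d == "FORG") cfg$dispersion_forg else cfg$dispersion_conc
      intens <- base[[d]] * exp(rnorm(length(node_ids), 0, disp))
      if (a %in% degenerate) {
        intens <- (1 - cfg$degenerate_dominance) * intens / sum(intens) +
          cfg$degenerate_dominance * spike / sum(spike) *
          exp(rnorm(1, 0, 0.05))
      }
      counts[, a] <- as.integer(rmultinom(1, cfg$reads_per_animal, intens))
    }
    otu_ids <- sprintf("OTU%03d", seq_len(cfg$n_otus))
    otu_base <- exp(rnorm(cfg$n_otus, 0, 1.5))
    otu_shift <- exp(rnorm(cfg$n_otus, 0, cfg$otu_diet_effect))
    otu <- matrix(0L, cfg$n_otus, length(animals),
                  dimnames = list(otu_ids, animals))
    for (a in animals) {
      mult <- if (diet[[a]] == "CONC") otu_shift else 1
      intens <- otu_base * mult * exp(rnorm(cfg$n_otus, 0, 0.3))
      otu[, a] <- as.integer(rmultinom(1, cfg$otu_reads_per_animal, intens))
    }
    list(cm = count_matrix(counts, diet,
                           mapped_totals = rep(cfg$reads_per_animal,
                                               length(animals))),
         otu = otu, diet = diet, base_intensities = base,
         degenerate_animals = degenerate)
  })
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

back_translate <- function(residues, codons) {
  aa <- strsplit(residues, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(r) {
    opts <- codons[[r]]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

#' Generate paired FASTQ reads per animal with a truth table
#'
#' Fragments are drawn from back-translated enzyme nucleotide sequences in
#' proportion to each animal's node intensities; 100 bp mates are read
#' from the two fragment ends (fragment length ~ Normal(309, 30) clipped
#' to [210, 420] and to the enzyme length). Substitutions are applied at
#' `cfg$substitution_rate`; qualities are constant phred 40 unless a
#' low-quality run is planted downstream.
#'
#' @param db the microbial `reaction_db`.
#' @param graph the microbial `metabolic_graph`.
#' @param cfg a [scenario_config()].
#' @param out_dir directory for `<animal>_1.fastq` / `<animal>_2.fastq`.
#' @param n_pairs pairs per animal (default `cfg$reads_per_animal`).
#' @param animals animal ids to generate (default 2, one per diet —
#'   read-level data is for mapper validation, not the full trial).
#' @return data.frame truth table: `animal`, `read_id`, `node_id`,
#'   `enzyme_id`; FASTQ files as a side effect.
#' @export
gen_reads <- function(db, graph, cfg, out_dir,
                      n_pairs = cfg$reads_per_animal,
                      animals = c(FORG = "F01", CONC = "C01")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  codons <- codon_table()
  # nodes must carry an enzyme via a member reaction
  node_enzymes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    rids <- graph$nodes$member_reaction_ids[[i]]
    eids <- names(db$enzymes)[vapply(db$enzymes, function(e)
      any(e$reaction_ids %in% rids), logical(1))]
    eids
  })
  names(node_enzymes) <- graph$nodes$node_id
  usable <- names(node_enzymes)[lengths(node_enzymes) > 0]
  truth <- list()
  with_seed(derive_subseed(cfg$seed, 301L), {
    nt_cache <- new.env(parent = emptyenv())
    enzyme_nt <- function(eid) {
      if (is.null(nt_cache[[eid]]))
        nt_cache[[eid]] <- back_translate(db$enzymes[[eid]]$residues, codons)
      nt_cache[[eid]]
    }
    base <- gen_base_intensities(usable, rep(0L, length(usable)) |>
                                   setNames(usable), cfg,
                                 derive_subseed(cfg$seed, 302L))
    for (k in seq_along(animals)) {
      a <- animals[[k]]; d <- names(animals)[k]
      intens <- base[[d]] + 1e-9
      node_draw <- sample(usable, n_pairs, replace = TRUE, prob = intens)
      r1 <- r2 <- character(n_pairs)
      ids <- sprintf("%s_read%06d", a, seq_len(n_pairs))
      src_enz <- character(n_pairs)
      for (i in seq_len(n_pairs)) {
        eid <- sample(node_enzymes[[node_draw[i]]], 1)
        src_enz[i] <- eid
        nt <- enzyme_nt(eid)
        L <- nchar(nt)
        fl <- min(max(210L, round(rnorm(1, 309, 30))), 420L, L)
        st <- sample.int(L - fl + 1L, 1)
        frag <- substr(nt, st, st + fl - 1L)
        m1 <- substr(frag, 1L, 100L)
        m2 <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(substr(frag, fl - 99L, fl))))
        if (cfg$substitution_rate > 0) {
          m1 <- mutate_seq(m1, cfg$substitution_rate)
          m2 <- mutate_seq(m2, cfg$substitution_rate)
        }
        r1[i] <- m1; r2[i] <- m2
      }
      qual <- strrep("I", 100L)  # phred 40
      fq <- function(path, seqs) {
        writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                          substr(qual, 1, nchar(seqs))), path)
      }
      fq(file.path(out_dir, paste0(a, "_1.fastq")), r1)
      fq(file.path(out_dir, paste0(a, "_2.fastq")), r2)
      truth[[a]] <- data.frame(animal = a, read_id = ids,
                               node_id = node_draw, enzyme_id = src_enz,
                               stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(truth, list(make.row.names = FALSE)))
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  paste(ch, collapse = "")
}
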
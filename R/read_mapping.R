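# Translated-read mapping: quality trimming, six-frame ORF extraction,
# seeded Smith-Waterman alignment of translated ORFs against the enzyme
# database, and multi-hit resolution down to network nodes.

#' Mapping parameter set
#'
#' Defaults follow standard short-read functional profiling practice:
#' reads are truncated at the first run of `trim_run` bases under phred
#' `trim_q`, pairs are dropped when either mate has mean quality below
#' `min_mean_q` or fewer than `min_len_nt` bases, both mates must carry a
#' translated ORF of at least `min_orf_residues` residues, and a hit
#' requires `required_words` shared `word_length`-mers, amino-acid identity
#' above `identity_threshold` and coverage of more than
#' `coverage_threshold` of the ORF. Identity/coverage comparisons are
#' strict (`>`) by default; set `strict = FALSE` for `>=`.
#'
#' @param identity_threshold,coverage_threshold fractions in (0, 1].
#' @param word_length,required_words seed screen: number of identical words
#'   of this length required before alignment.
#' @param min_orf_residues minimum translated ORF length.
#' @param trim_q,trim_run quality-truncation rule.
#' @param min_mean_q,min_len_nt pair-level quality filters.
#' @param gap_open,gap_extend affine gap penalties (BLOSUM62 scoring).
#' @param strict use strict inequality for the identity/coverage thresholds.
#' @return list of class `mapping_params`.
#' @export
mapping_params <- function(identity_threshold = 0.80,
                           coverage_threshold = 0.80,
                           word_length = 7L, required_words = 2L,
                           min_orf_residues = 30L,
                           trim_q = 15L, trim_run = 3L,
                           min_mean_q = 25, min_len_nt = 85L,
                           gap_open = 11, gap_extend = 1,
                           strict = TRUE) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1,
            word_length >= 1, required_words >= 1, min_orf_residues >= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 word_length = as.integer(word_length),
                 required_words = as.integer(required_words),
                 min_orf_residues = as.integer(min_orf_residues),
                 trim_q = as.integer(trim_q), trim_run = as.integer(trim_run),
                 min_mean_q = min_mean_q, min_len_nt = as.integer(min_len_nt),
                 gap_open = gap_open, gap_extend = gap_extend,
                 strict = strict),
            class = "mapping_params")
}

# BLOSUM62 with residues indexed for the C++ core; cached per session.
.aligner_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.aligner_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aligner_cache$mat <- e$BLOSUM62
    .aligner_cache$alphabet <- rownames(e$BLOSUM62)
  }
  .aligner_cache$mat
}

encode_peptide <- function(x) {
  mat <- blosum62()
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], .aligner_cache$alphabet)
  idx[is.na(idx)] <- match("X", .aligner_cache$alphabet)
  idx
}

#' Smith-Waterman local alignment of two peptides
#'
#' Affine-gap local alignment under BLOSUM62. Identity is the fraction of
#' identical residues over all aligned columns (gap columns count as
#' mismatches); coverage is the fraction of the query consumed by the
#' aligned region.
#'
#' @param query,subject amino-acid strings.
#' @param params a [mapping_params()] (gap penalties).
#' @return list with `score`, `identity`, `coverage`, `matches`, `aln_len`
#'   and 1-based query/subject span.
#' @export
sw_align <- function(query, subject, params = mapping_params()) {
  res <- sw_align_cpp(encode_peptide(query), encode_peptide(subject),
                      blosum62(), params$gap_open, params$gap_extend)
  res
}

distinct_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

shared_word_count <- function(a, b, k) {
  length(intersect(distinct_kmers(a, k), distinct_kmers(b, k)))
}

#' Align a translated ORF against one enzyme sequence
#'
#' A hit requires (i) at least `required_words` distinct shared
#' `word_length`-mers between ORF and enzyme (the seed screen), (ii)
#' alignment identity above the identity threshold and (iii) an aligned
#' span covering more than the coverage threshold of the ORF.
#'
#' @param orf peptide string (>= `min_orf_residues` residues).
#' @param enzyme an enzyme entry from a `reaction_db` (list with
#'   `residues`) or a plain residue string.
#' @param params a [mapping_params()].
#' @return `NULL` when there is no hit, else list with `identity`,
#'   `coverage`, `score`.
#' @export
align_orf <- function(orf, enzyme, params = mapping_params()) {
  residues <- if (is.list(enzyme)) enzyme$residues else enzyme
  if (shared_word_count(orf, residues, params$word_length) <
      params$required_words) return(NULL)
  res <- sw_align(orf, residues, params)
  pass <- if (params$strict) {
    res$identity > params$identity_threshold &&
      res$coverage > params$coverage_threshold
  } else {
    res$identity >= params$identity_threshold &&
      res$coverage >= params$coverage_threshold
  }
  if (!pass) return(NULL)
  res
}

truncate_at_low_quality <- function(qual, trim_q, trim_run) {
  low <- qual < trim_q
  n <- length(low)
  if (n < trim_run) return(n)
  run <- low
  if (trim_run > 1) {
    for (k in seq_len(trim_run - 1)) {
      run <- run & c(low[-seq_len(k)], rep(FALSE, k))
    }
  }
  first <- which(run)
  if (length(first) == 0) n else first[1] - 1L
}

#' Quality-filter one read pair
#'
#' Each mate is truncated at the start of the first run of `trim_run`
#' consecutive bases with phred quality below `trim_q` (the run itself is
#' removed); the pair is then discarded when either mate has mean quality
#' below `min_mean_q` or fewer than `min_len_nt` bases.
#'
#' @param pair list with `seq1`, `qual1`, `seq2`, `qual2` (sequences as
#'   strings, qualities as integer phred vectors of matching length).
#' @param params a [mapping_params()].
#' @return the truncated pair with `status = "pass"`, or
#'   `status = "discarded"`, `reason = "quality"`.
#' @export
quality_filter <- function(pair, params = mapping_params()) {
  stopifnot(nchar(pair$seq1) == length(pair$qual1),
            nchar(pair$seq2) == length(pair$qual2))
  out <- pair
  for (m in 1:2) {
    sq <- pair[[paste0("seq", m)]]; qq <- pair[[paste0("qual", m)]]
    keep <- truncate_at_low_quality(qq, params$trim_q, params$trim_run)
    out[[paste0("seq", m)]] <- substr(sq, 1L, keep)
    out[[paste0("qual", m)]] <- qq[seq_len(keep)]
  }
  ok <- function(m) {
    q <- out[[paste0("qual", m)]]
    length(q) >= params$min_len_nt && mean(q) >= params$min_mean_q
  }
  if (!ok(1) || !ok(2)) {
    out$status <- "discarded"; out$reason <- "quality"
  } else {
    out$status <- "pass"; out$reason <- NA_character_
  }
  out
}

translate_six_frames <- function(seq) {
  if (grepl("[^ACGTNacgtn]", seq))
    stop("non-ACGTN character in read sequence", call. = FALSE)
  s <- Biostrings::DNAString(toupper(seq))
  rc <- Biostrings::reverseComplement(s)
  out <- character(0)
  for (strand in list(s, rc)) {
    n <- length(strand)
    for (f in 0:2) {
      len <- 3L * ((n - f) %/% 3L)
      if (len < 3L) next
      sub <- Biostrings::subseq(strand, start = f + 1L, width = len)
      out <- c(out, as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
    }
  }
  out
}

#' Extract qualifying six-frame ORFs from a read pair
#'
#' Each mate is translated in all six reading frames; ORFs are maximal
#' stop-free runs. The pair survives only when both mates carry at least
#' one ORF of `min_orf_residues` residues; all qualifying ORFs per mate
#' are retained as alignment candidates.
#'
#' @param pair quality-passed pair (list with `seq1`, `seq2`).
#' @param params a [mapping_params()].
#' @return list with `status`, and on pass `orfs1`, `orfs2` (character
#'   vectors); on failure `reason = "no_orf"`.
#' @export
six_frame_orfs <- function(pair, params = mapping_params()) {
  orfs_of <- function(seq) {
    pieces <- unlist(strsplit(translate_six_frames(seq), "*", fixed = TRUE))
    pieces[nchar(pieces) >= params$min_orf_residues]
  }
  o1 <- orfs_of(pair$seq1); o2 <- orfs_of(pair$seq2)
  if (length(o1) == 0 || length(o2) == 0) {
    list(status = "discarded", reason = "no_orf")
  } else {
    list(status = "pass", orfs1 = o1, orfs2 = o2)
  }
}

#' Resolve per-mate enzyme hits into a node assignment
#'
#' Let S be the reaction-id sets of all hit enzymes across both mates. If
#' the two mates share no reaction at all the pair is discarded as
#' `discordant_pair`. If the sets are neither identical nor totally ordered
#' by inclusion the pair is discarded as `unrelated_multi`. Otherwise the
#' pair is assigned to the node(s) of the minimal set: one node gives
#' `UNIQUE`, several give `MULTI` (tallied separately downstream).
#'
#' @param hits_mate1,hits_mate2 character vectors of hit enzyme ids (one
#'   per mate; empty means no hit for that mate).
#' @param db the `reaction_db` the enzymes belong to.
#' @param reaction_nodes optional named map reaction id -> node id (from
#'   [build_graph()]); when omitted, assignment stays at reaction level.
#' @return list with `status` (`UNIQUE`, `MULTI`, `DISCARDED`), `reason`,
#'   `reaction_ids` (minimal set) and `node_ids`.
#' @export
resolve_assignment <- function(hits_mate1, hits_mate2, db,
                               reaction_nodes = NULL) {
  discarded <- function(reason)
    list(status = "DISCARDED", reason = reason,
         reaction_ids = character(), node_ids = character())
  if (length(hits_mate1) == 0 || length(hits_mate2) == 0)
    return(discarded("no_hit"))
  rset <- function(eids) lapply(eids, function(e)
    sort(unique(db$enzymes[[e]]$reaction_ids)))
  sets1 <- rset(hits_mate1); sets2 <- rset(hits_mate2)
  if (length(intersect(unlist(sets1), unlist(sets2))) == 0)
    return(discarded("discordant_pair"))
  sets <- unique(c(sets1, sets2))
  sets <- sets[order(lengths(sets))]
  for (i in seq_along(sets)[-1]) {
    if (!all(sets[[i - 1]] %in% sets[[i]]))
      return(discarded("unrelated_multi"))
  }
  minimal <- sets[[1]]
  node_ids <- character()
  if (!is.null(reaction_nodes)) {
    node_ids <- sort(unique(reaction_nodes[minimal]))
    node_ids <- node_ids[!is.na(node_ids)]
    if (length(node_ids) == 0) return(discarded("no_hit"))
    status <- if (length(node_ids) == 1L) "UNIQUE" else "MULTI"
  } else {
    status <- if (length(minimal) == 1L) "UNIQUE" else "MULTI"
    node_ids <- minimal
  }
  list(status = status, reason = NA_character_,
       reaction_ids = minimal, node_ids = node_ids)
}

# hash index: distinct word -> integer vector of enzyme indices
build_word_index <- function(residues, k) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(residues)) {
    for (w in distinct_kmers(residues[i], k)) {
      idx[[w]] <- c(idx[[w]], i)
    }
  }
  idx
}

candidate_enzymes <- function(orf, index, k, required) {
  words <- distinct_kmers(orf, k)
  hits <- unlist(lapply(words, function(w) index[[w]]), use.names = FALSE)
  if (is.null(hits) || length(hits) == 0) return(integer())
  tab <- tabulate(hits)
  which(tab >= required)
}

mate_hits <- function(orfs, enzyme_ids, residues, index, params) {
  hits <- character()
  for (orf in orfs) {
    cand <- candidate_enzymes(orf, index, params$word_length,
                              params$required_words)
    for (ci in cand) {
      if (!is.null(align_orf(orf, residues[ci], params)))
        hits <- c(hits, enzyme_ids[ci])
    }
  }
  sort(unique(hits))
}

read_fastq_pairs <- function(fastq1, fastq2) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq2))
  if (length(r1) != length(r2))
    stop("mate FASTQ files differ in read count", call. = FALSE)
  q1 <- as(Biostrings::quality(r1), "IntegerList")
  q2 <- as(Biostrings::quality(r2), "IntegerList")
  lapply(seq_along(r1), function(i) {
    list(read_id = sub("\\s.*$", "", names(r1)[i]),
         seq1 = as.character(r1[[i]]), qual1 = q1[[i]],
         seq2 = as.character(r2[[i]]), qual2 = q2[[i]])
  })
}

#' Map one sample's paired reads onto network nodes
#'
#' Runs quality filtering, six-frame ORF extraction, seeded
#' Smith-Waterman alignment against the enzyme database and multi-hit
#' resolution, and tallies uniquely assigned pairs per node.
#'
#' @param fastq1,fastq2 paths to the two mate FASTQ files (phred+33).
#' @param db the microbial `reaction_db`.
#' @param graph a `metabolic_graph` built from `db` (provides the
#'   reaction -> node map).
#' @param params a [mapping_params()].
#' @param sample_id label for the summary row.
#' @param host_hits optional precomputed count of reads matching the host
#'   genome, passed through to the summary.
#' @return list with `counts` (named integer vector over graph nodes,
#'   unique assignments only), `summary` (totals: raw, valid-ORF, node-hit
#'   pairs with percentage of valid-ORF pairs, multi-hit pairs, discard
#'   breakdown) and `assignments` (per-read data.frame).
#' @export
map_sample <- function(fastq1, fastq2, db, graph, params = mapping_params(),
                       sample_id = NULL, host_hits = NA_integer_) {
  pairs <- read_fastq_pairs(fastq1, fastq2)
  residues <- vapply(db$enzymes, `[[`, "", "residues")
  enzyme_ids <- names(db$enzymes)
  index <- build_word_index(residues, params$word_length)
  counts <- setNames(integer(nrow(graph$nodes)), graph$nodes$node_id)
  status <- reason <- nodes <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- quality_filter(pairs[[i]], params)
    if (p$status == "discarded") {
      status[i] <- "DISCARDED"; reason[i] <- "quality"; next
    }
    o <- six_frame_orfs(p, params)
    if (o$status == "discarded") {
      status[i] <- "DISCARDED"; reason[i] <- "no_orf"; next
    }
    h1 <- mate_hits(o$orfs1, enzyme_ids, residues, index, params)
    h2 <- mate_hits(o$orfs2, enzyme_ids, residues, index, params)
    a <- resolve_assignment(h1, h2, db, graph$reaction_nodes)
    status[i] <- a$status
    reason[i] <- if (is.null(a$reason)) NA_character_ else a$reason
    nodes[i] <- paste(a$node_ids, collapse = ";")
    if (a$status == "UNIQUE") counts[a$node_ids] <- counts[a$node_ids] + 1L
  }
  raw <- length(pairs)
  disc <- table(factor(reason[status == "DISCARDED"],
                       levels = c("quality", "no_orf", "no_hit",
                                  "unrelated_multi", "discordant_pair")))
  valid <- raw - disc[["quality"]] - disc[["no_orf"]]
  unique_n <- sum(status == "UNIQUE")
  multi_n <- sum(status == "MULTI")
  summary <- list(sample_id = sample_id %||% NA_character_,
                  raw_pairs = raw, valid_orf_pairs = valid,
                  node_hit_pairs = unique_n,
                  pct_node_hits = mapping_percentage(unique_n, valid),
                  multi_pairs = multi_n,
                  host_hits = host_hits,
                  discarded = as.integer(disc))
  names(summary$discarded) <- names(disc)
  list(counts = counts, summary = summary,
       assignments = data.frame(
         read_id = vapply(pairs, `[[`, "", "read_id"),
         status = status, reason = reason, nodes = nodes,
         stringsAsFactors = FALSE))
}

#' Percentage of valid-ORF pairs hitting nodes
#'
#' `hits / valid * 100`, reported to two decimals as in per-sample mapping
#' summaries.
#'
#' @param hits number of node-hit pairs.
#' @param valid number of valid-ORF pairs (the denominator).
#' @return numeric percentage rounded to 2 decimal places.
#' @export
mapping_percentage <- function(hits, valid) {
  if (valid == 0) return(0)
  round(hits / valid * 100, 2)
}

#' Generate pseudo-read pairs from the enzyme database
#'
#' Each pseudo-pair is two `segment_len`-residue windows drawn from one
#' enzyme, separated by an unsequenced insert of exactly `insert_len`
#' residues. Sampling is uniform over all valid (enzyme, offset)
#' combinations.
#'
#' @param db a `reaction_db` with enzymes of at least
#'   `2 * segment_len + insert_len` residues.
#' @param n_pairs number of pairs.
#' @param segment_len,insert_len segment and insert lengths (residues).
#' @param seed RNG seed.
#' @return data.frame with `pair_id`, `enzyme_id`, `offset` (1-based start
#'   of the first segment), `seg1`, `seg2`.
#' @export
generate_pseudo_reads <- function(db, n_pairs = 20000L, segment_len = 30L,
                                  insert_len = 70L, seed = NULL) {
  span <- 2L * segment_len + insert_len
  lens <- vapply(db$enzymes, function(e) nchar(e$residues), 0L)
  eligible <- names(lens)[lens >= span]
  if (length(eligible) == 0)
    stop(sprintf("no enzyme with >= %d residues", span), call. = FALSE)
  n_off <- lens[eligible] - span + 1L
  cum <- cumsum(as.numeric(n_off))
  with_seed(seed, {
    pick <- ceiling(runif(n_pairs) * cum[length(cum)])
    ei <- findInterval(pick - 0.5, c(0, cum))
    offset <- as.integer(pick - c(0, cum)[ei])
    enzyme_id <- eligible[ei]
    seg1 <- seg2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      res <- db$enzymes[[enzyme_id[i]]]$residues
      seg1[i] <- substr(res, offset[i], offset[i] + segment_len - 1L)
      seg2[i] <- substr(res, offset[i] + segment_len + insert_len,
                        offset[i] + span - 1L)
    }
    data.frame(pair_id = sprintf("pseudo_%05d", seq_len(n_pairs)),
               enzyme_id = enzyme_id, offset = offset,
               seg1 = seg1, seg2 = seg2, stringsAsFactors = FALSE)
  })
}

#' Validate the mapper with database-derived pseudo-reads
#'
#' Aligns each pseudo-pair against the database with its source enzyme
#' omitted, then reports, per identity threshold: the fraction of pairs
#' mapped, the unique:multi ratio, and the fraction of mapped pairs whose
#' assigned reaction set excludes every reaction of the source enzyme
#' ("incorrect nodes"). Alignments are computed once and the threshold
#' sweep applied to the recorded identities.
#'
#' @param pseudo_reads output of [generate_pseudo_reads()].
#' @param db the `reaction_db` searched.
#' @param identity_grid identity thresholds to sweep.
#' @param params a [mapping_params()] (its identity threshold is ignored in
#'   favor of the grid).
#' @return data.frame with one row per threshold: `identity_threshold`,
#'   `n_hit_pairs` (both mates hit >= 1 enzyme), `n_mapped`, `frac_mapped`,
#'   `n_unique`, `n_multi`, `unique_multi_ratio`, `n_incorrect_node`,
#'   `frac_incorrect_node`.
#' @export
validate_mapping <- function(pseudo_reads, db,
                             identity_grid = c(0.80, 0.85, 0.90, 0.95),
                             params = mapping_params()) {
  residues <- vapply(db$enzymes, `[[`, "", "residues")
  enzyme_ids <- names(db$enzymes)
  index <- build_word_index(residues, params$word_length)
  n <- nrow(pseudo_reads)
  # record all seed-passing alignments once
  aln <- vector("list", n)
  for (i in seq_len(n)) {
    src <- pseudo_reads$enzyme_id[i]
    rec <- list()
    for (m in 1:2) {
      seg <- pseudo_reads[[paste0("seg", m)]][i]
      cand <- candidate_enzymes(seg, index, params$word_length,
                                params$required_words)
      cand <- cand[enzyme_ids[cand] != src]
      for (ci in cand) {
        r <- sw_align(seg, residues[ci], params)
        rec[[length(rec) + 1L]] <- list(mate = m, enzyme = enzyme_ids[ci],
                                        identity = r$identity,
                                        coverage = r$coverage)
      }
    }
    aln[[i]] <- rec
  }
  src_sets <- lapply(pseudo_reads$enzyme_id, function(e)
    db$enzymes[[e]]$reaction_ids)
  out <- lapply(identity_grid, function(thr) {
    n_unique <- n_multi <- n_bad <- n_hit <- 0L
    for (i in seq_len(n)) {
      rec <- aln[[i]]
      keep <- vapply(rec, function(r)
        r$identity > thr && r$coverage > params$coverage_threshold,
        logical(1))
      rec <- rec[keep]
      h1 <- unique(vapply(rec[vapply(rec, `[[`, 0, "mate") == 1],
                          `[[`, "", "enzyme"))
      h2 <- unique(vapply(rec[vapply(rec, `[[`, 0, "mate") == 2],
                          `[[`, "", "enzyme"))
      if (length(h1) && length(h2)) n_hit <- n_hit + 1L
      a <- resolve_assignment(h1, h2, db)
      if (a$status == "UNIQUE") n_unique <- n_unique + 1L
      if (a$status == "MULTI") n_multi <- n_multi + 1L
      if (a$status %in% c("UNIQUE", "MULTI") &&
          length(intersect(a$reaction_ids, src_sets[[i]])) == 0)
        n_bad <- n_bad + 1L
    }
    mapped <- n_unique + n_multi
    data.frame(identity_threshold = thr,
               n_hit_pairs = n_hit,
               n_mapped = mapped, frac_mapped = mapped / n,
               n_unique = n_unique, n_multi = n_multi,
               unique_multi_ratio = if (n_multi > 0) n_unique / n_multi
                                    else NA_real_,
               n_incorrect_node = n_bad,
               frac_incorrect_node = if (mapped > 0) n_bad / mapped
                                     else NA_real_)
  })
  do.call(rbind, out)
}
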
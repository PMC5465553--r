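make_pair <- function(seq1, qual1, seq2 = seq1, qual2 = qual1) {
  list(read_id = "p1", seq1 = seq1, qual1 = qual1,
       seq2 = seq2, qual2 = qual2)
}

test_that("quality truncation removes the first low-quality run and filters short/poor pairs", {
  p <- mapping_params()
  good <- make_pair(strrep("ACGT", 25), rep(40L, 100))
  out <- quality_filter(good, p)
  expect_equal(out$status, "pass")
  expect_equal(nchar(out$seq1), 100L)

  # run of three q14 starting at base 90 -> truncated to 89, still passes
  q <- rep(40L, 100); q[90:92] <- 14L
  out <- quality_filter(make_pair(strrep("ACGT", 25), q), p)
  expect_equal(out$status, "pass")
  expect_equal(nchar(out$seq1), 89L)
  expect_length(out$qual1, 89L)

  # truncation to 80 bases (< 85) discards the whole pair even when the
  # other mate is pristine
  q2 <- rep(40L, 100); q2[81:83] <- 10L
  out <- quality_filter(make_pair(strrep("ACGT", 25), q2,
                                  strrep("ACGT", 25), rep(40L, 100)), p)
  expect_equal(out$status, "discarded")
  expect_equal(out$reason, "quality")

  # low mean quality discards even at full length
  out <- quality_filter(make_pair(strrep("ACGT", 25), rep(20L, 100)), p)
  expect_equal(out$status, "discarded")

  # two low-quality bases followed by a good one do not trigger truncation
  q3 <- rep(40L, 100); q3[50:51] <- 10L
  out <- quality_filter(make_pair(strrep("ACGT", 25), q3), p)
  expect_equal(nchar(out$seq1), 100L)
})

test_that("six-frame ORF extraction keeps pairs with >= 30 residues on both mates", {
  p <- mapping_params()
  # 100 nt with no stops in frame 1: TTC codons (Phe) -> 33-residue ORF
  clean <- paste0(strrep("TTC", 33), "T")
  o <- six_frame_orfs(list(seq1 = clean, seq2 = clean), p)
  expect_equal(o$status, "pass")
  expect_true(any(nchar(o$orfs1) == 33))

  # an 87-nt mate can carry at most 29 residues in any frame, so its best
  # ORF always fails the >= 30 rule; a pair survives only when BOTH mates
  # qualify
  short87 <- strrep("TTC", 29)
  o <- six_frame_orfs(list(seq1 = short87, seq2 = short87), p)
  expect_equal(o$status, "discarded")
  expect_equal(o$reason, "no_orf")
  o <- six_frame_orfs(list(seq1 = clean, seq2 = short87), p)
  expect_equal(o$status, "discarded")
  expect_equal(o$reason, "no_orf")
  expect_error(six_frame_orfs(list(seq1 = "ACGTX", seq2 = clean), p),
               "non-ACGTN")
})

test_that("alignment hits require two shared words, identity and coverage above threshold", {
  p <- mapping_params()
  enz <- random_peptide(120)
  orf <- substr(enz, 21, 53)  # 33-residue exact substring
  set.seed(42)
  h <- align_orf(orf, enz, p)
  expect_equal(h$identity, 1.0)
  expect_equal(h$coverage, 1.0)

  # 8 of 33 residues substituted at interior positions spaced so that no
  # >80%-coverage window clears 80% identity -> no hit
  ch <- strsplit(orf, "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (pos in c(2, 6, 10, 14, 18, 22, 26, 30))
    ch[pos] <- setdiff(aa, ch[pos])[1]
  mut <- paste(ch, collapse = "")
  expect_null(align_orf(mut, enz, p))
  # the independent DP oracle agrees the best local identity is below 0.80
  expect_lt(sw_oracle(mut, enz)$identity, 0.80)

  # a single shared 7-mer fails the seed screen regardless of identity
  one_word <- paste0(substr(enz, 21, 27), random_peptide(26))
  expect_equal(rumennet:::shared_word_count(one_word, enz, 7), 1L)
  expect_null(align_orf(one_word, enz, p))
})

test_that("the aligner agrees with the plain-R dynamic-programming oracle", {
  set.seed(7)
  for (i in 1:60) {
    a <- random_peptide(sample(30:60, 1))
    b <- if (runif(1) < 0.5) random_peptide(sample(30:60, 1))
         else mutate_peptide(a, sample(1:10, 1))
    mine <- sw_align(a, b)
    oracle <- sw_oracle(a, b)
    expect_equal(mine$score, oracle$score)
    expect_equal(mine$identity, oracle$identity)
    expect_equal(mine$coverage, oracle$coverage)
  }
})

test_that("multi-hit resolution follows the reaction-set inclusion rules", {
  mets <- tiny_metabolites()
  rx <- list(R1 = c("A", "B"), R2 = c("B", "C"), R3 = c("C", "D"))
  enz <- list(Ea = tiny_enzyme("R1"), Eb = tiny_enzyme("R1"),
              Ec = tiny_enzyme(c("R1", "R2")), Ed = tiny_enzyme("R3"),
              Ee = tiny_enzyme(c("R2", "R3")))
  db <- reaction_db(mets, rx, enz, "microbial")

  # both mates hit two enzymes catalyzing exactly {R1} -> UNIQUE
  a <- resolve_assignment(c("Ea", "Eb"), c("Ea", "Eb"), db)
  expect_equal(a$status, "UNIQUE")
  expect_equal(a$reaction_ids, "R1")

  # {R1,R2} and {R1} are nested -> assigned to the minimal set {R1}
  a <- resolve_assignment(c("Ec", "Ea"), "Ec", db)
  expect_equal(a$status, "UNIQUE")
  expect_equal(a$reaction_ids, "R1")

  # mates hitting disjoint reactions -> discordant pair
  a <- resolve_assignment("Ea", "Ed", db)
  expect_equal(a$status, "DISCARDED")
  expect_equal(a$reason, "discordant_pair")

  # incomparable sets {R1,R2} vs {R2,R3} -> unrelated multi
  a <- resolve_assignment(c("Ec", "Ee"), c("Ec", "Ee"), db)
  expect_equal(a$status, "DISCARDED")
  expect_equal(a$reason, "unrelated_multi")

  # a minimal set with two reactions is MULTI at reaction level
  a <- resolve_assignment("Ec", "Ec", db)
  expect_equal(a$status, "MULTI")
  expect_setequal(a$reaction_ids, c("R1", "R2"))

  # ... but UNIQUE when those reactions merged into one node
  rn <- c(R1 = "R1", R2 = "R1", R3 = "R3")
  a <- resolve_assignment("Ec", "Ec", db, reaction_nodes = rn)
  expect_equal(a$status, "UNIQUE")
  expect_equal(a$node_ids, "R1")

  # no hits on one mate -> no_hit
  expect_equal(resolve_assignment("Ea", character(), db)$reason, "no_hit")
})

test_that("pseudo-read generation covers valid offsets and records provenance", {
  mets <- tiny_metabolites()
  res130 <- random_peptide(130)
  res200 <- random_peptide(200)
  db <- reaction_db(mets, list(R1 = "A", R2 = "B"),
                    list(E1 = list(residues = res130, reaction_ids = "R1"),
                         E2 = list(residues = res200, reaction_ids = "R2")),
                    "microbial")
  pr <- generate_pseudo_reads(db, n_pairs = 300, seed = 5)
  expect_equal(nrow(pr), 300L)
  # an enzyme of exactly 130 residues admits only offset 1
  expect_true(all(pr$offset[pr$enzyme_id == "E1"] == 1L))
  expect_true(all(pr$offset[pr$enzyme_id == "E2"] <= 71L))
  # segments are the 30-mers at offset and offset + 100
  i <- which(pr$enzyme_id == "E2")[1]
  expect_equal(pr$seg1[i], substr(res200, pr$offset[i], pr$offset[i] + 29))
  expect_equal(pr$seg2[i],
               substr(res200, pr$offset[i] + 100, pr$offset[i] + 129))
  # short-enzyme-only database errors
  db_short <- reaction_db(mets, list(R1 = "A"),
                          list(E1 = list(residues = random_peptide(100),
                                         reaction_ids = "R1")), "microbial")
  expect_error(generate_pseudo_reads(db_short, 10), "130")
  # unmutated pseudo-reads with the source retained map back to it:
  # a duplicate of the source under another id keeps them mapping
  db_dup <- reaction_db(mets, list(R1 = "A", R2 = "B"),
                        list(E1 = list(residues = res200,
                                       reaction_ids = "R1"),
                             E1b = list(residues = res200,
                                        reaction_ids = "R1"),
                             E2 = list(residues = random_peptide(200),
                                       reaction_ids = "R2")),
                        "microbial")
  pr2 <- generate_pseudo_reads(db_dup, n_pairs = 50, seed = 6)
  v <- validate_mapping(pr2[pr2$enzyme_id %in% c("E1", "E1b"), ], db_dup,
                        identity_grid = 0.80)
  expect_equal(v$frac_mapped, 1)
  expect_equal(v$frac_incorrect_node, 0)
})

test_that("pseudo-read validation: dissimilar databases map nothing; ambiguity hurts at high identity", {
  mets <- tiny_metabolites()
  set.seed(11)
  # 20 mutually unrelated enzymes: with the source omitted nothing maps
  enz <- setNames(lapply(1:20, function(i)
    list(residues = random_peptide(150), reaction_ids = "R1")),
    sprintf("E%02d", 1:20))
  db <- reaction_db(mets, list(R1 = "A"), enz, "microbial")
  pr <- generate_pseudo_reads(db, n_pairs = 60, seed = 2)
  v <- validate_mapping(pr, db, identity_grid = 0.80)
  expect_equal(v$frac_mapped, 0)

  # database ambiguity: source A, B ~95% identical to A with a different
  # reaction, C ~85% identical with A's reaction. At 0.80 both B and C hit
  # (incomparable sets -> discarded); at 0.90 only B hits -> incorrect
  # node. The incorrect fraction therefore grows with the threshold.
  resA <- random_peptide(200)
  resB <- mutate_peptide(resA, 10)   # ~95% identity
  resC <- mutate_peptide(resA, 30)   # ~85% identity
  db2 <- reaction_db(mets, list(R1 = "A", R2 = "B"),
                     list(EA = list(residues = resA, reaction_ids = "R1"),
                          EB = list(residues = resB, reaction_ids = "R2"),
                          EC = list(residues = resC, reaction_ids = "R1")),
                     "microbial")
  pr2 <- generate_pseudo_reads(db2, n_pairs = 120, seed = 3)
  pr2 <- pr2[pr2$enzyme_id == "EA", ]
  v2 <- validate_mapping(pr2, db2, identity_grid = c(0.80, 0.90))
  bad80 <- v2$n_incorrect_node[v2$identity_threshold == 0.80]
  bad90 <- v2$n_incorrect_node[v2$identity_threshold == 0.90]
  # at 0.90 the same-reaction member rarely passes, so the near-identical
  # wrong-reaction twin wins alone; at 0.80 both pass and the ambiguity is
  # detected and discarded instead of mis-assigned
  expect_gt(bad90, bad80)
  expect_equal(v2$frac_incorrect_node[v2$identity_threshold == 0.90], 1)
  # lowering the identity threshold never lowers the seed+threshold hit
  # count (the screen is monotone; assignments may still become discards)
  v3 <- validate_mapping(pr2, db2, identity_grid = c(0.95, 0.90, 0.85, 0.80))
  expect_true(all(diff(v3$n_hit_pairs[order(-v3$identity_threshold)]) >= 0))
})

test_that("map_sample conserves reads across outcome classes and matches planted truth", {
  cfg <- scenario_config(n_metabolites = 120L, n_reactions = 60L,
                         n_host_reactions = 15L, n_enzymes = 70L,
                         reads_per_animal = 2000L, seed = 3L)
  dbs <- gen_reaction_db(cfg)
  gm <- build_graph(dbs$microbial, 50)
  dir <- withr::local_tempdir()
  truth <- gen_reads(dbs$microbial, gm, cfg, dir, n_pairs = 120,
                     animals = c(FORG = "F01"))
  res <- map_sample(file.path(dir, "F01_1.fastq"),
                    file.path(dir, "F01_2.fastq"),
                    dbs$microbial, gm, sample_id = "F01")
  s <- res$summary
  expect_equal(s$raw_pairs, 120L)
  # conservation: all outcomes partition the raw pairs
  expect_equal(sum(s$discarded) + s$node_hit_pairs + s$multi_pairs,
               s$raw_pairs)
  expect_equal(s$valid_orf_pairs,
               s$raw_pairs - s$discarded[["quality"]] -
                 s$discarded[["no_orf"]])
  expect_equal(s$pct_node_hits,
               round(s$node_hit_pairs / s$valid_orf_pairs * 100, 2))
  # unique assignments agree with the truth table
  asn <- res$assignments
  m <- merge(asn[asn$status == "UNIQUE", ], truth, by = "read_id")
  expect_gt(nrow(m), 0)
  expect_true(mean(m$nodes == m$node_id) >= 0.99)
  expect_equal(sum(res$counts), s$node_hit_pairs)
})

test_that("empty FASTQ input yields a zero column and zero totals", {
  db <- tiny_microbial_db()
  g <- build_graph(db, 25)
  f1 <- withr::local_tempfile(lines = character())
  f2 <- withr::local_tempfile(lines = character())
  res <- map_sample(f1, f2, db, g)
  expect_true(all(res$counts == 0L))
  expect_equal(res$summary$raw_pairs, 0L)
  expect_equal(res$summary$pct_node_hits, 0)
})
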
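# Reaction database: metabolites with carbon counts, reactions as metabolite
# sets, enzyme sequences cross-referenced to the reactions they catalyze.
# The on-disk dialect is three flat files per database directory:
#   metabolites.tsv  metabolite_id  name  carbon_count
#   reactions.tsv    reaction_id    metabolite_ids (semicolon-joined)
#   enzymes.fasta    >enzyme_id reactions=R1;R2

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

new_reaction_db <- function(metabolites, reactions, enzymes, source_label) {
  db <- structure(
    list(metabolites = metabolites, reactions = reactions,
         enzymes = enzymes, source_label = source_label),
    class = "reaction_db")
  validate_reaction_db(db)
}

#' Assemble a reaction database from in-memory components
#'
#' @param metabolites data.frame with columns `metabolite_id`, `name`,
#'   `carbon_count`.
#' @param reactions named list: reaction id -> character vector of metabolite
#'   ids (each set non-empty).
#' @param enzymes named list: enzyme id -> list with `residues` (amino-acid
#'   string, >= 30 residues, stop-free) and `reaction_ids` (non-empty).
#' @param source_label `"host"` or `"microbial"`.
#' @return a validated `reaction_db` object. Metabolite occurrence counts
#'   (number of distinct reactions using each metabolite) are recomputed.
#' @export
reaction_db <- function(metabolites, reactions, enzymes = list(),
                        source_label = c("microbial", "host")) {
  source_label <- match.arg(source_label)
  metabolites$metabolite_id <- as.character(metabolites$metabolite_id)
  metabolites$carbon_count <- as.integer(metabolites$carbon_count)
  new_reaction_db(metabolites, reactions, enzymes, source_label)
}

validate_reaction_db <- function(db) {
  m <- db$metabolites
  stopifnot(is.data.frame(m),
            all(c("metabolite_id", "name", "carbon_count") %in% names(m)))
  if (anyDuplicated(m$metabolite_id))
    stop_id("duplicate metabolite id(s): %s",
            m$metabolite_id[duplicated(m$metabolite_id)])
  if (any(is.na(m$carbon_count)) || any(m$carbon_count < 0))
    stop("carbon_count must be a non-negative integer", call. = FALSE)

  rids <- names(db$reactions)
  if (length(db$reactions) && (is.null(rids) || anyDuplicated(rids)))
    stop_id("duplicate or missing reaction id(s): %s",
            rids[duplicated(rids)])
  ref_mets <- unique(unlist(db$reactions, use.names = FALSE))
  bad <- setdiff(ref_mets, m$metabolite_id)
  if (length(bad))
    stop_id("reaction references unknown metabolite id(s): %s", bad)
  if (any(lengths(db$reactions) == 0))
    stop_id("reaction(s) with empty metabolite set: %s",
            rids[lengths(db$reactions) == 0])

  eids <- names(db$enzymes)
  if (length(db$enzymes) && (is.null(eids) || anyDuplicated(eids)))
    stop_id("duplicate or missing enzyme id(s): %s", eids[duplicated(eids)])
  for (eid in eids) {
    e <- db$enzymes[[eid]]
    if (length(e$reaction_ids) == 0)
      stop(sprintf("enzyme %s has an empty reaction list", eid),
           call. = FALSE)
    bad <- setdiff(e$reaction_ids, rids)
    if (length(bad))
      stop_id(paste0("enzyme ", eid,
                     " references unknown reaction id(s): %s"), bad)
    if (nchar(e$residues) < 30)
      stop(sprintf("enzyme %s has fewer than 30 residues", eid),
           call. = FALSE)
    if (grepl("\\*", e$residues))
      stop(sprintf("enzyme %s contains a stop character", eid), call. = FALSE)
  }

  # deterministic iteration order + recomputed occurrence
  if (length(db$reactions))
    db$reactions <- db$reactions[order(names(db$reactions))]
  if (length(db$enzymes))
    db$enzymes <- db$enzymes[order(names(db$enzymes))]
  m <- m[order(m$metabolite_id), , drop = FALSE]
  occ <- table(unlist(lapply(db$reactions, unique), use.names = FALSE))
  m$occurrence <- as.integer(occ[m$metabolite_id])
  m$occurrence[is.na(m$occurrence)] <- 0L
  rownames(m) <- m$metabolite_id
  db$metabolites <- m
  db
}

#' Load a reaction database from flat files
#'
#' @param metabolite_table_path TSV with header
#'   `metabolite_id  name  carbon_count`.
#' @param reaction_table_path TSV with header `reaction_id  metabolite_ids`
#'   (semicolon-joined metabolite ids).
#' @param enzyme_fasta_path FASTA whose description field carries
#'   `reactions=<id>[;<id>...]`; `NULL` for an enzyme-free database.
#' @param source_label `"host"` or `"microbial"`.
#' @return a validated `reaction_db`.
#' @export
load_database <- function(metabolite_table_path, reaction_table_path,
                          enzyme_fasta_path = NULL,
                          source_label = c("microbial", "host")) {
  source_label <- match.arg(source_label)
  mets <- read.delim(metabolite_table_path, stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "integer"))
  rx <- read.delim(reaction_table_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (anyDuplicated(rx$reaction_id))
    stop_id("duplicate reaction id(s): %s",
            rx$reaction_id[duplicated(rx$reaction_id)])
  reactions <- setNames(strsplit(rx$metabolite_ids, ";", fixed = TRUE),
                        rx$reaction_id)
  enzymes <- list()
  if (!is.null(enzyme_fasta_path)) {
    aa <- Biostrings::readAAStringSet(enzyme_fasta_path)
    hdr <- names(aa)
    ids <- sub("\\s.*$", "", hdr)
    rx_field <- regmatches(hdr, regexpr("reactions=[^ ]+", hdr))
    if (length(rx_field) != length(hdr))
      stop("enzyme FASTA header(s) missing the reactions= field",
           call. = FALSE)
    rsets <- strsplit(sub("^reactions=", "", rx_field), ";", fixed = TRUE)
    enzymes <- setNames(
      lapply(seq_along(aa), function(i)
        list(residues = as.character(aa[[i]]), reaction_ids = rsets[[i]])),
      ids)
  }
  new_reaction_db(mets, reactions, enzymes, source_label)
}

#' Write a reaction database to flat files
#'
#' Inverse of [load_database()]: emits `metabolites.tsv`, `reactions.tsv` and
#' (when enzymes are present) `enzymes.fasta` under `dir`.
#'
#' @param db a `reaction_db`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- db$metabolites[, c("metabolite_id", "name", "carbon_count")]
  write.table(m, file.path(dir, "metabolites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rx <- data.frame(
    reaction_id = names(db$reactions),
    metabolite_ids = vapply(db$reactions,
                            function(x) paste(sort(x), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(db$enzymes)) {
    lines <- unlist(lapply(names(db$enzymes), function(eid) {
      e <- db$enzymes[[eid]]
      c(sprintf(">%s reactions=%s", eid,
                paste(sort(e$reaction_ids), collapse = ";")),
        e$residues)
    }))
    writeLines(lines, file.path(dir, "enzymes.fasta"))
  }
  invisible(dir)
}

#' Currency metabolites at an occurrence cutoff
#'
#' A currency metabolite is one taking part in `cutoff` or more reactions
#' (water, ATP, ...); such metabolites are excluded from edge formation
#' because they link unrelated reactions.
#'
#' @param db a `reaction_db`.
#' @param cutoff positive integer; a metabolite with occurrence >= `cutoff`
#'   is classified as currency.
#' @return character vector of metabolite ids (sorted).
#' @export
currency_metabolites <- function(db, cutoff) {
  stopifnot(length(cutoff) == 1L, cutoff >= 1)
  m <- db$metabolites
  sort(m$metabolite_id[m$occurrence >= cutoff])
}

#' Add the butyrate-uptake pseudo-reaction to a host database
#'
#' Appends a single enzyme-free reaction converting butyrate to butyryl-CoA,
#' representing the host's absorption of microbially produced butyrate.
#' Idempotent: if a reaction with exactly that metabolite pair exists,
#' the database is returned unchanged. Missing metabolites are created
#' (butyrate 4 carbons, butyryl-CoA 25).
#'
#' @param host_db a `reaction_db` with `source_label == "host"`.
#' @param butyrate_id,butyryl_coa_id metabolite ids to use.
#' @param reaction_id id for the pseudo-reaction.
#' @return the augmented `reaction_db`.
#' @export
add_butyrate_pseudoreaction <- function(host_db,
                                        butyrate_id = "BUTYRATE",
                                        butyryl_coa_id = "BUTYRYL_COA",
                                        reaction_id = "RXN_BUTYRATE_PSEUDO") {
  stopifnot(inherits(host_db, "reaction_db"))
  if (host_db$source_label != "host")
    stop("pseudo-reaction is host-specific; source_label must be 'host'",
         call. = FALSE)
  target <- sort(c(butyrate_id, butyryl_coa_id))
  already <- any(vapply(host_db$reactions,
                        function(x) identical(sort(unique(x)), target),
                        logical(1)))
  if (already) return(host_db)
  m <- host_db$metabolites
  if (!butyrate_id %in% m$metabolite_id)
    m <- rbind(m[, 1:3],
               data.frame(metabolite_id = butyrate_id, name = "butyrate",
                          carbon_count = 4L))
  if (!butyryl_coa_id %in% m$metabolite_id)
    m <- rbind(m[, c("metabolite_id", "name", "carbon_count")],
               data.frame(metabolite_id = butyryl_coa_id,
                          name = "butyryl-CoA", carbon_count = 25L))
  reactions <- host_db$reactions
  if (reaction_id %in% names(reactions))
    stop(sprintf("reaction id %s already in use", reaction_id), call. = FALSE)
  reactions[[reaction_id]] <- c(butyrate_id, butyryl_coa_id)
  new_reaction_db(m[, c("metabolite_id", "name", "carbon_count")],
                  reactions, host_db$enzymes, host_db$source_label)
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf("<reaction_db: %s> %d metabolites, %d reactions, %d enzymes\n",
              x$source_label, nrow(x$metabolites), length(x$reactions),
              length(x$enzymes)))
  invisible(x)
}
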
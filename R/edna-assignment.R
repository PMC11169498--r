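# eDNA metabarcoding curation: amplicon length windows, read-abundance
# filtering, and identity-based taxonomic rank assignment against an
# expected-species checklist. Operates on OTU hit tables (one row per
# BLAST-style hit); sequence processing itself (denoising, clustering,
# alignment) happens upstream.

# expected amplicon length windows (bp) per mitochondrial marker
MARKER_LENGTH_WINDOWS <- list(`12S` = c(135L, 139L), `16S` = c(130L, 134L))

#' Amplicon length filter
#'
#' Keep an OTU only if its sequence length lies inside the closed expected
#' window of its marker: 135-139 bp for 12S, 130-134 bp for 16S.
#'
#' @param length_bp integer sequence length(s).
#' @param marker `"12S"` or `"16S"` (recycled).
#' @return logical keep/discard vector.
#' @export
length_filter <- function(length_bp, marker) {
  marker <- as.character(marker)
  bad <- setdiff(unique(marker), names(MARKER_LENGTH_WINDOWS))
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  lo <- vapply(marker, function(m) MARKER_LENGTH_WINDOWS[[m]][1], integer(1))
  hi <- vapply(marker, function(m) MARKER_LENGTH_WINDOWS[[m]][2], integer(1))
  length_bp >= lo & length_bp <= hi
}

#' Read-abundance filter
#'
#' Strict rule: keep only OTUs with more than `min_reads` reads (default
#' > 5). In `"reads_and_relabund"` mode the OTU must additionally exceed
#' `min_rel_abund` of its sample's total reads (default 0.5%).
#'
#' @param read_count integer read counts.
#' @param sample_total total reads of the OTU's sample (only used in
#'   relative-abundance mode).
#' @param mode `"reads"` (default, strict count rule) or
#'   `"reads_and_relabund"`.
#' @param min_reads strict lower bound (exclusive).
#' @param min_rel_abund relative-abundance lower bound (exclusive).
#' @return logical keep/discard vector.
#' @export
abundance_filter <- function(read_count, sample_total = NULL,
                             mode = c("reads", "reads_and_relabund"),
                             min_reads = 5L, min_rel_abund = 0.005) {
  mode <- match.arg(mode)
  stopifnot(all(read_count >= 0))
  keep <- read_count > min_reads
  if (mode == "reads_and_relabund") {
    if (is.null(sample_total)) stop("sample_total required in relative-abundance mode")
    keep <- keep & (read_count / sample_total > min_rel_abund)
  }
  keep
}

genus_of <- function(taxon) {
  vapply(strsplit(trimws(taxon), "\\s+"), `[`, character(1), 1)
}

check_taxon_names <- function(taxon) {
  ok <- grepl("^[A-Za-z][A-Za-z.-]*( [A-Za-z.()'-]+)*$", trimws(taxon))
  if (!all(ok)) {
    stop("malformed taxon name(s): ",
         paste(unique(taxon[!ok]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Assign a taxon and rank to one OTU from its hit list
#'
#' Hits below 90% identity or 90% query coverage are discarded first. Then:
#' if the best remaining identity is >= 98% the OTU is assigned at species
#' level when the best-matching species (preferring a checklist species
#' among equal-identity ties) is expected in the study region, and at genus
#' level otherwise; best identities in \[90, 98) always give a genus
#' assignment; no qualifying hit rejects the OTU. Ties at >= 98% where no
#' tied species is expected resolve to the genus of the alphabetically
#' first tied taxon.
#'
#' @param hits `data.frame` with `taxon`, `pct_identity`, `pct_coverage`
#'   for one OTU.
#' @param checklist character vector of expected binomial species names.
#' @param min_identity,min_coverage pre-filter floors (default 90).
#' @param species_identity species-level identity threshold (default 98).
#' @return one-row `data.frame`: `rank` (`species`/`genus`/`rejected`),
#'   `taxon`, `rule`, `identity`.
#' @export
assign_taxon <- function(hits, checklist, min_identity = 90,
                         min_coverage = 90, species_identity = 98) {
  if (nrow(hits)) check_taxon_names(hits$taxon)
  check_taxon_names(checklist)
  ok <- hits$pct_identity >= min_identity & hits$pct_coverage >= min_coverage
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(rank = "rejected", taxon = NA_character_,
                      rule = "no_qualifying_hit", identity = NA_real_,
                      stringsAsFactors = FALSE))
  }
  top <- max(hits$pct_identity)
  tied <- sort(unique(hits$taxon[hits$pct_identity == top]))
  if (top >= species_identity) {
    expected <- tied[tied %in% checklist]
    if (length(expected)) {
      rule <- if (length(tied) > 1) "species_expected_tiebreak" else "species_expected"
      return(data.frame(rank = "species", taxon = expected[1], rule = rule,
                        identity = top, stringsAsFactors = FALSE))
    }
    return(data.frame(rank = "genus", taxon = genus_of(tied[1]),
                      rule = "genus_unexpected_species", identity = top,
                      stringsAsFactors = FALSE))
  }
  data.frame(rank = "genus", taxon = genus_of(tied[1]),
             rule = "genus_identity_window", identity = top,
             stringsAsFactors = FALSE)
}

#' Curate an OTU hit table
#'
#' Applies the curation pipeline in order -- amplicon length window, read
#' abundance, identity-based rank assignment -- and aggregates the unique
#' assigned taxa overall and per water-body class. An OTU failing an early
#' filter never reaches assignment; every input OTU appears exactly once in
#' the output with the rule that decided it.
#'
#' @param otus `data.frame` with one row per hit: `otu_id`, `marker`,
#'   `length_bp`, `reads`, `sample_id`, `water_class`, `taxon`,
#'   `pct_identity`, `pct_coverage`.
#' @param checklist character vector of expected species.
#' @param mode abundance-filter mode, see [abundance_filter()].
#' @return list with `assignments` (one row per OTU: `otu_id`, `rank`,
#'   `taxon`, `rule`, `identity`, `water_class`), `taxa` (unique assigned
#'   taxa), `taxa_by_class` (named list), and `summary`
#'   (`data.frame(n_taxa, n_species_rank)`).
#' @export
curate_edna <- function(otus, checklist, mode = c("reads", "reads_and_relabund")) {
  mode <- match.arg(mode)
  req <- c("otu_id", "marker", "length_bp", "reads", "sample_id",
           "water_class", "taxon", "pct_identity", "pct_coverage")
  if (!all(req %in% names(otus))) {
    stop("hit table must have columns: ", paste(req, collapse = ", "))
  }
  if (!nrow(otus)) {
    empty <- data.frame(otu_id = character(), rank = character(),
                        taxon = character(), rule = character(),
                        identity = numeric(), water_class = character())
    return(list(assignments = empty, taxa = character(),
                taxa_by_class = list(),
                summary = data.frame(n_taxa = 0L, n_species_rank = 0L)))
  }
  sample_totals <- tapply(otus$reads[!duplicated(otus$otu_id)],
                          otus$sample_id[!duplicated(otus$otu_id)], sum)
  rows <- lapply(split(otus, otus$otu_id), function(h) {
    base <- data.frame(otu_id = h$otu_id[1], water_class = h$water_class[1],
                       stringsAsFactors = FALSE)
    if (!length_filter(h$length_bp[1], h$marker[1])) {
      return(cbind(base, data.frame(rank = "rejected", taxon = NA_character_,
                                    rule = "length_window", identity = NA_real_)))
    }
    if (!abundance_filter(h$reads[1],
                          sample_total = unname(sample_totals[h$sample_id[1]]),
                          mode = mode)) {
      return(cbind(base, data.frame(rank = "rejected", taxon = NA_character_,
                                    rule = "low_abundance", identity = NA_real_)))
    }
    cbind(base, assign_taxon(h, checklist))
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  assignments <- assignments[, c("otu_id", "rank", "taxon", "rule",
                                 "identity", "water_class")]
  assigned <- assignments[assignments$rank != "rejected", , drop = FALSE]
  taxa <- sort(unique(assigned$taxon))
  taxa_by_class <- lapply(split(assigned$taxon, assigned$water_class),
                          function(x) sort(unique(x)))
  species_taxa <- unique(assigned$taxon[assigned$rank == "species"])
  list(assignments = assignments, taxa = taxa, taxa_by_class = taxa_by_class,
       summary = data.frame(n_taxa = length(taxa),
                            n_species_rank = length(species_taxa)))
}

#' Read an OTU hit table from CSV
#'
#' One row per BLAST-style hit with the columns [curate_edna()] requires.
#'
#' @param path CSV file path.
#' @return `data.frame` of hits.
#' @export
read_otu_table <- function(path) {
  otus <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("otu_id", "marker", "length_bp", "reads", "sample_id",
           "water_class", "taxon", "pct_identity", "pct_coverage")
  if (!all(req %in% names(otus))) {
    stop("hit table must have columns: ", paste(req, collapse = ", "))
  }
  otus
}

#' Read an expected-species checklist (one species per line)
#'
#' @param path text file path; blank lines and `#` comments ignored.
#' @return character vector of species names.
#' @export
read_checklist <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
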
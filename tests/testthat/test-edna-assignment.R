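checklist <- c("Panthera onca", "Tapirus terrestris", "Mazama rufa",
               "Akodon montensis", "Holochilus chacarius")

test_that("amplicon length windows are marker-specific and closed", {
  expect_true(length_filter(137L, "12S"))
  expect_true(length_filter(135L, "12S"))
  expect_true(length_filter(139L, "12S"))
  expect_false(length_filter(134L, "12S"))
  expect_false(length_filter(140L, "12S"))
  expect_true(length_filter(134L, "16S"))
  expect_true(length_filter(130L, "16S"))
  expect_false(length_filter(135L, "16S"))
  expect_error(length_filter(137L, "COI"), "unknown marker")
})

test_that("the read-abundance rule is a strict > 5 count", {
  expect_true(abundance_filter(6L))
  expect_false(abundance_filter(5L))
  expect_false(abundance_filter(0L))
  # optional conjunction mode also enforces 0.5% relative abundance
  expect_true(abundance_filter(6L, sample_total = 100,
                               mode = "reads_and_relabund"))
  expect_false(abundance_filter(6L, sample_total = 10000,
                                mode = "reads_and_relabund"))
})

test_that("taxonomic assignment fires the documented rule paths", {
  # (1) >= 98% to an expected species -> species
  r1 <- assign_taxon(otu_hit("o1", "Panthera onca", 99.1), checklist)
  expect_equal(r1$rank, "species")
  expect_equal(r1$taxon, "Panthera onca")
  expect_equal(r1$rule, "species_expected")
  # (2) >= 98% but species not expected -> genus
  r2 <- assign_taxon(otu_hit("o2", "Panthera leo", 98.4), checklist)
  expect_equal(r2$rank, "genus")
  expect_equal(r2$taxon, "Panthera")
  expect_equal(r2$rule, "genus_unexpected_species")
  # (3) tie at >= 98%, one expected -> the checklist species
  tie <- rbind(otu_hit("o3", "Mazama americana", 99.0),
               otu_hit("o3", "Mazama rufa", 99.0))
  r3 <- assign_taxon(tie, checklist)
  expect_equal(r3$rank, "species")
  expect_equal(r3$taxon, "Mazama rufa")
  expect_equal(r3$rule, "species_expected_tiebreak")
  # (4) identity in [90, 98) -> genus
  r4 <- assign_taxon(otu_hit("o4", "Tapirus terrestris", 95.0), checklist)
  expect_equal(r4$rank, "genus")
  expect_equal(r4$taxon, "Tapirus")
  expect_equal(r4$rule, "genus_identity_window")
  # (5) below the 90% floor -> rejected
  r5 <- assign_taxon(otu_hit("o5", "Akodon montensis", 89.9), checklist)
  expect_equal(r5$rank, "rejected")
  expect_equal(r5$rule, "no_qualifying_hit")
})

test_that("coverage below 90% disqualifies a hit and ties resolve alphabetically", {
  low_cov <- otu_hit("o6", "Panthera onca", 99.5, coverage = 80)
  expect_equal(assign_taxon(low_cov, checklist)$rank, "rejected")
  # tie at >= 98%, neither expected: genus of alphabetically first taxon
  tie <- rbind(otu_hit("o7", "Puma concolor", 98.6),
               otu_hit("o7", "Leopardus wiedii", 98.6))
  r <- assign_taxon(tie, checklist)
  expect_equal(r$rank, "genus")
  expect_equal(r$taxon, "Leopardus")
  expect_error(assign_taxon(otu_hit("o8", "??bad name", 99), checklist),
               "malformed")
})

test_that("curation enforces the filter order and reports every OTU once", {
  otus <- rbind(
    otu_hit("oA", "Panthera onca", 99.5, length_bp = 120L), # fails length
    otu_hit("oB", "Panthera onca", 99.5, reads = 3L),       # fails abundance
    otu_hit("oC", "Panthera onca", 99.5))                    # assigned
  res <- curate_edna(otus, checklist)
  expect_equal(nrow(res$assignments), 3)
  expect_equal(res$assignments$rule[res$assignments$otu_id == "oA"],
               "length_window") # never reached assignment
  expect_equal(res$assignments$rule[res$assignments$otu_id == "oB"],
               "low_abundance")
  expect_equal(res$assignments$rank[res$assignments$otu_id == "oC"], "species")
  expect_equal(res$summary$n_taxa, 1)
})

test_that("an engineered table yields 23 taxa with 16 at species rank", {
  sp <- sprintf("Genus%s species%s", letters[1:16], letters[1:16])
  genus_only <- sprintf("Othergenus%s speciesa", letters[1:7])
  rows <- list()
  for (i in seq_along(sp)) {
    rows[[length(rows) + 1]] <- otu_hit(sprintf("sp_otu%02d", i), sp[i], 99.0,
                                        sample_id = "W01")
  }
  for (i in seq_along(genus_only)) {
    rows[[length(rows) + 1]] <- otu_hit(sprintf("g_otu%02d", i), genus_only[i],
                                        94.0, sample_id = "W02",
                                        water_class = "running")
  }
  otus <- do.call(rbind, rows)
  res <- curate_edna(otus, checklist = sp)
  expect_equal(res$summary$n_taxa, 23)
  expect_equal(res$summary$n_species_rank, 16)
  expect_setequal(names(res$taxa_by_class), c("still", "running"))
  expect_equal(length(res$taxa_by_class$running), 7)
})

test_that("raising the identity floor never adds assignments", {
  set.seed(131)
  for (rep in 1:100) {
    otus <- random_otu_table(sample(5:15, 1))
    lo <- curate_edna(otus, checklist)
    # tighten the floor by re-running assignment with a higher threshold
    assigned_at <- function(floor) {
      keep <- otus[length_filter(otus$length_bp, otus$marker) &
                     abundance_filter(otus$reads), , drop = FALSE]
      if (!nrow(keep)) return(character(0))
      ids <- unique(keep$otu_id)
      ids[vapply(ids, function(id) {
        assign_taxon(keep[keep$otu_id == id, ], checklist,
                     min_identity = floor)$rank != "rejected"
      }, logical(1))]
    }
    expect_true(all(assigned_at(95) %in% assigned_at(90)))
    # every input OTU appears exactly once
    expect_setequal(lo$assignments$otu_id, unique(otus$otu_id))
    expect_equal(anyDuplicated(lo$assignments$otu_id), 0)
  }
})

test_that("curation is deterministic and total on empty input", {
  set.seed(133)
  otus <- random_otu_table(10)
  expect_identical(curate_edna(otus, checklist), curate_edna(otus, checklist))
  empty <- curate_edna(otus[0, ], checklist)
  expect_equal(nrow(empty$assignments), 0)
  expect_equal(empty$summary$n_taxa, 0)
})

test_that("hit tables read from CSV with schema validation", {
  set.seed(135)
  otus <- random_otu_table(5)
  path <- tempfile(fileext = ".csv")
  write.csv(otus, path, row.names = FALSE)
  back <- read_otu_table(path)
  expect_equal(nrow(back), nrow(otus))
  expect_identical(curate_edna(back, checklist)$summary,
                   curate_edna(otus, checklist)$summary)
  bad <- tempfile(fileext = ".csv")
  write.csv(otus[, -1], bad, row.names = FALSE)
  expect_error(read_otu_table(bad), "must have columns")
  unlink(c(path, bad))
})

test_that("checklists read one species per line with comments ignored", {
  path <- tempfile()
  writeLines(c("# expected species", "Panthera onca", "", "Tapirus terrestris"),
             path)
  expect_equal(read_checklist(path), c("Panthera onca", "Tapirus terrestris"))
  unlink(path)
})
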
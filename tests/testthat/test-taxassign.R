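hit_row <- function(query = "q1", taxon = "t001", pident = 99, bitscore = 200,
                    qcov = 95) {
  tibble::tibble(query_id = query, taxon_id = taxon, pident = pident,
                 length = 97L, mismatch = 1L, gapopen = 0L, qstart = 1L,
                 qend = 97L, sstart = 1L, send = 97L, evalue = 0,
                 bitscore = bitscore, qcov = qcov)
}

test_that("hit files round-trip and are validated on parse", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  hits <- dplyr::bind_rows(hit_row(taxon = "t001"), hit_row(taxon = "t002"),
                           hit_row(taxon = "t003", bitscore = 150))
  write_hits(hits, tmp)
  back <- parse_hits(tmp)
  expect_equal(nrow(back), 3)
  expect_equal(back$bitscore, hits$bitscore)

  # empty file
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_hits(empty)), 0)

  # unknown taxon_id dropped with a message when a lineage table is given
  lineage <- generate_reference_db(2, seed = 1)[, c("taxon_id", tax_ranks())]
  expect_message(kept <- parse_hits(tmp, lineage), "unknown taxon")
  expect_equal(nrow(kept), 2)   # t003 is absent from a 2-species db

  # malformed row errors with a line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(rep("x", 13), collapse = "\t")), bad)
  expect_error(parse_hits(bad), "line 1")
})

test_that("hit filtering applies the top-2% window and inclusive thresholds", {
  hits <- dplyr::bind_rows(
    hit_row(taxon = "a", bitscore = 200),
    hit_row(taxon = "b", bitscore = 197),
    hit_row(taxon = "c", bitscore = 195))
  kept <- filter_hits(hits)
  expect_setequal(kept$taxon_id, c("a", "b"))   # cutoff 200 * 0.98 = 196

  # identity strictly below 98 is excluded; exactly 90% coverage retained
  expect_equal(nrow(filter_hits(hit_row(pident = 97.9))), 0)
  expect_equal(nrow(filter_hits(hit_row(pident = 98))), 1)
  expect_equal(nrow(filter_hits(hit_row(qcov = 90))), 1)
  expect_equal(nrow(filter_hits(hit_row(qcov = 89.9))), 0)

  # invariant to rescaling all bit-scores by a positive constant
  scaled <- dplyr::mutate(hits, bitscore = bitscore * 7.3)
  expect_equal(filter_hits(scaled)$taxon_id, kept$taxon_id)

  # output is a subset of the input; empty input passes through
  expect_true(all(kept$bitscore %in% hits$bitscore))
  expect_equal(nrow(filter_hits(hits[0, ])), 0)
})

test_that("MLCA worked examples resolve as specified", {
  # 5 unique lineages: all Muridae (5/5), 4/5 genus Apodemus (0.8 accepted),
  # best species only 2/5 (0.4 rejected) -> genus Apodemus
  l <- make_lineage(
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus flavicollis"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus agrarius"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Micromys", "Micromys minutus"))
  l$genus[2] <- "Apodemus"; l$species[2] <- "Apodemus uralensis"  # keep 5 unique
  res <- mlca(l)
  expect_true(res$assigned)
  expect_equal(res$rank, "genus")
  expect_equal(res$taxon, "Apodemus")
  expect_equal(res$species, "")

  # single unique lineage: assigned in full (single-hit rule)
  single <- make_lineage(c("Eukaryota", "Chordata", "Mammalia", "Rodentia",
                           "Cricetidae", "Microtus", "Microtus agrestis"))
  res1 <- mlca(single)
  expect_equal(res1$rank, "species")
  expect_equal(res1$taxon, "Microtus agrestis")

  # agreement only at class: shallower than order -> unassigned
  split_orders <- make_lineage(
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus"),
    c("Eukaryota", "Chordata", "Mammalia", "Carnivora", "Canidae", "Vulpes", "Vulpes vulpes"))
  expect_false(mlca(split_orders)$assigned)

  # empty hit set -> unassigned
  expect_false(mlca(make_lineage()[0, ])$assigned)
})

test_that("duplicate lineages do not over-weight the vote", {
  dup <- make_lineage(
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus sylvaticus"),
    c("Eukaryota", "Chordata", "Mammalia", "Rodentia", "Muridae", "Apodemus", "Apodemus flavicollis"))
  # 2 unique lineages: species share 1/2 < 0.8 even though 3/4 raw hits agree
  expect_equal(mlca(dup)$rank, "genus")
})

test_that("MLCA equals the brute-force prefix-vote oracle on fuzzed hit sets", {
  set.seed(1234)
  for (i in 1:300) {
    l <- random_lineage_set(sample.int(8, 1))
    got <- mlca(l)
    want <- oracle_mlca(l)
    expect_equal(got$assigned, want$assigned, info = paste("case", i))
    if (want$assigned) {
      expect_equal(got$rank, want$rank, info = paste("case", i))
      expect_equal(got$taxon, want$taxon, info = paste("case", i))
    }
  }
})

test_that("raising the agreement threshold never deepens the assignment", {
  set.seed(99)
  depth_of <- function(res) {
    if (!res$assigned) 0L else match(res$rank, tax_ranks())
  }
  for (i in 1:50) {
    l <- random_lineage_set(sample.int(8, 1))
    depths <- vapply(c(0.55, 0.7, 0.8, 0.9, 1),
                     function(a) depth_of(mlca(l, agreement = a)), integer(1))
    expect_true(all(diff(depths) <= 0), info = paste("case", i))
  }
})

test_that("assigned counts sum per taxon and conserve totals", {
  asg <- dplyr::bind_rows(
    mlca(make_lineage(c("Eukaryota", "Chordata", "Amphibia", "Anura",
                        "Ranidae", "Rana", "Rana temporaria"))),
    mlca(make_lineage(c("Eukaryota", "Chordata", "Amphibia", "Anura",
                        "Ranidae", "Rana", "Rana temporaria"))),
    mlca(make_lineage()[0, ]))
  asg$query_id <- c("q1", "q2", "q3")
  cl <- tibble::tibble(
    cluster_id = c("q1", "q2", "q3"),
    sequence = c("AAAA", "CCCC", "GGGG"),
    size = c(60L, 50L, 7L),
    sample_counts = list(c(S1 = 60L), c(S1 = 50L), c(S1 = 7L)))
  prof <- assign_counts(asg, cl)
  expect_equal(prof$reads[prof$taxon == "Rana temporaria"], 110L)
  expect_equal(prof$reads[prof$taxon == "unassigned"], 7L)
  expect_equal(sum(prof$reads), sum(cl$size))   # count conservation

  # all queries unassigned
  asg2 <- asg
  asg2$assigned <- FALSE
  asg2$taxon <- NA_character_
  prof2 <- assign_counts(asg2, cl)
  expect_equal(prof2$taxon, "unassigned")
  expect_equal(prof2$reads, sum(cl$size))

  # a query without a cluster record is a consistency error
  expect_error(assign_counts(dplyr::mutate(asg, query_id = c("q1", "qX", "q3")), cl),
               "without cluster")
})

test_that("hit-table shortcut recovers truth counts exactly", {
  db <- generate_reference_db(24, seed = 21)
  cfg <- sim_config(n_samples = 4, seed = 21,
                    reads_per_sample = c(meanlog = log(1000), sdlog = 0.2))
  truth <- sim_truth_table(db, cfg)
  sim <- simulate_hit_tables(db, truth, seed = 21)
  asg <- assign_taxa(sim$hits, db[, c("taxon_id", tax_ranks())])
  expect_true(all(asg$assigned))
  prof <- assign_counts(asg, sim$clusters)
  merged <- dplyr::inner_join(
    prof, truth$counts |>
      dplyr::group_by(sample_id, taxon) |>
      dplyr::summarise(truth_reads = sum(reads), .groups = "drop"),
    by = c("sample_id", "taxon"))
  expect_equal(nrow(merged), nrow(prof))
  expect_equal(merged$reads, merged$truth_reads)
})

test_that("built-in scorer ranks the true template first", {
  db <- generate_reference_db(12, seed = 33)
  cl <- make_clusters(db$sequence[c(3, 7)], c(100, 50))
  hits <- align_clusters(cl, db, min_report_identity = 0)
  top <- hits |>
    dplyr::group_by(query_id) |>
    dplyr::slice_max(bitscore, n = 1)
  expect_equal(sort(db$taxon_id[c(3, 7)]), sort(top$taxon_id))
  expect_true(all(top$pident == 100))
  expect_true(all(top$qcov == 100))
})
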
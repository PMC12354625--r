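prof_row <- function(sample_id, taxon, reads) {
  tibble::tibble(sample_id = sample_id, taxon = taxon, reads = reads)
}

test_that("controls, unassigned reads and empty samples are removed", {
  p <- dplyr::bind_rows(
    prof_row("S1", c("Vulpes vulpes", "Maylandia zebra", "unassigned"),
             c(5000, 300, 120)),
    prof_row("S2", c("Maylandia zebra", "unassigned"), c(200, 50)))
  expect_message(out <- remove_nontarget(p), "S2")
  expect_equal(unique(out$sample_id), "S1")
  expect_equal(out$taxon, "Vulpes vulpes")

  clean <- prof_row("S1", c("Vulpes vulpes", "Rana temporaria"), c(100, 50))
  expect_equal(remove_nontarget(clean), clean)
})

test_that("noise threshold removes strictly-below-0.1% taxa", {
  # total 50,000: threshold is 50 reads; 49 goes, 50 stays
  p <- prof_row("S1", c("A", "B", "C"), c(49901, 49, 50))
  out <- apply_noise_threshold(p)
  expect_setequal(out$taxon, c("A", "C"))

  single <- prof_row("S1", "A", 7)
  expect_equal(apply_noise_threshold(single), single)

  all_big <- prof_row("S1", c("A", "B"), c(600, 400))
  expect_equal(apply_noise_threshold(all_big), all_big)
})

test_that("ambiguous species roll up to the configured higher taxon", {
  p <- prof_row("S1", c("Anas platyrhynchos", "Anas crecca", "Vulpes vulpes"),
                c(30, 20, 900))
  out <- rollup_ambiguous(p, list(Anatidae = c("Anas platyrhynchos", "Anas crecca")))
  expect_equal(out$reads[out$taxon == "Anatidae"], 50)
  expect_false(any(grepl("^Anas ", out$taxon)))

  expect_equal(rollup_ambiguous(p, list()), p)

  lineage <- generate_reference_db(24, seed = 1)
  expect_error(
    rollup_ambiguous(p, list(Anatidae = c("Anas imaginaria")), lineage = lineage),
    "missing from the lineage")
})

test_that("host identification takes the most-abundant candidate with a floor", {
  p <- prof_row("S1", c("Vulpes vulpes", "Microtus agrestis", "Homo sapiens"),
                c(12000, 900, 40))
  h <- identify_host(p)
  expect_equal(h$dna_host, "Vulpes vulpes")
  expect_true(h$dominant)

  # no candidate host present: indeterminate
  h2 <- identify_host(prof_row("S1", "Microtus agrestis", 300))
  expect_true(is.na(h2$dna_host))

  # candidate below the host-read floor: indeterminate
  h3 <- identify_host(prof_row("S1", c("Martes martes", "Rana temporaria"),
                               c(60, 3000)))
  expect_true(is.na(h3$dna_host))

  # the larger candidate wins even when both hosts occur
  h4 <- identify_host(prof_row("S1", c("Martes martes", "Vulpes vulpes"),
                               c(9000, 700)))
  expect_equal(h4$dna_host, "Martes martes")
})

test_that("host/contaminant subtraction keeps the other predator as diet", {
  p <- dplyr::bind_rows(
    prof_row("S1", c("Vulpes vulpes", "Rana temporaria", "Homo sapiens",
                     "Martes martes"), c(12000, 600, 40, 800)),
    prof_row("S2", c("Microtus agrestis"), 300))   # indeterminate
  h <- identify_host(p)
  expect_message(out <- subtract_host_and_contaminants(p, h), "S2")
  expect_setequal(out$prey$taxon, c("Rana temporaria", "Martes martes"))
  expect_equal(out$samples$sample_id, "S1")
})

test_that("the 100-read minimum removes the sub-threshold woodcock detection", {
  prey <- prof_row("S1", c("Scolopax rusticola", "Rana temporaria"), c(92, 600))
  out <- apply_min_reads(prey)
  expect_false("Scolopax rusticola" %in% out$taxon)

  at <- prof_row("S1", "Apodemus sylvaticus", 100)
  expect_equal(apply_min_reads(at), at)

  all_ok <- prof_row("S1", c("A", "B"), c(150, 100))
  expect_equal(apply_min_reads(all_ok), all_ok)
})

test_that("%FOO counts samples containing a taxon, with group aggregates", {
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:24),
                            dna_host = "Vulpes vulpes")
  prey <- prof_row(sprintf("S%02d", 1:12), "Martes martes", 500)
  f <- foo(prey, samples, by = "predator")
  expect_equal(f$foo[f$taxon == "Martes martes"], 50)
  expect_equal(f$n_samples, 24)

  # absent taxon via a group aggregate containing no occurrences
  f2 <- foo(prey, samples, by = "combined",
            taxon_groups = list(birds = "Phasianus colchicus"))
  expect_equal(f2$foo[f2$taxon == "birds"], 0)

  # a sample counts once for a group even with two member taxa present
  prey3 <- dplyr::bind_rows(
    prof_row("S01", c("Microtus agrestis", "Apodemus sylvaticus"), c(200, 150)),
    prof_row("S02", "Microtus agrestis", 200))
  f3 <- foo(prey3, samples, by = "combined",
            taxon_groups = list(`small mammals` = c("Microtus agrestis",
                                                    "Apodemus sylvaticus")))
  expect_equal(f3$n_present[f3$taxon == "small mammals"], 2)
})

test_that("RRA is the pooled read proportion and sums to one per group", {
  samples <- tibble::tibble(sample_id = c("S1", "S2"), dna_host = "Vulpes vulpes")
  prey <- dplyr::bind_rows(prof_row("S1", "Rana temporaria", 750),
                           prof_row("S2", "Cervus elaphus", 250))
  r <- rra(prey, samples, by = "predator")
  expect_equal(r$rra[r$taxon == "Rana temporaria"], 0.75)
  expect_equal(r$rra[r$taxon == "Cervus elaphus"], 0.25)
  expect_equal(sum(r$rra), 1, tolerance = 1e-9)

  # single taxon
  r1 <- rra(prof_row("S1", "Rana temporaria", 123), samples, by = "combined")
  expect_equal(r1$rra, 1)

  # per-sample-mean variant weights samples equally
  r2 <- rra(dplyr::bind_rows(prof_row("S1", c("A", "B"), c(900, 100)),
                             prof_row("S2", c("A", "B"), c(100, 900))),
            samples, by = "combined", per_sample_mean = TRUE)
  expect_equal(r2$rra[r2$taxon == "A"], 0.5)

  # zero prey reads: reported missing
  r3 <- rra(prey[0, ], samples, by = "combined")
  expect_true(is.na(r3$rra))
})

test_that("field-vs-DNA confusion reproduces the misidentification arithmetic", {
  # 24 DNA pine marten of which 8 field-labelled fox; 24 DNA fox of which 6
  # field-labelled pine marten
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:48),
    dna_host = rep(c("Martes martes", "Vulpes vulpes"), each = 24),
    field_label = c(rep("Vulpes vulpes", 8), rep("Martes martes", 16),
                    rep("Martes martes", 6), rep("Vulpes vulpes", 18)))
  conf <- host_confusion(samples)
  rates <- conf$rates
  expect_equal(round(rates$misid_pct[rates$species == "Martes martes"], 1), 33.3)
  expect_equal(rates$misid_pct[rates$species == "Vulpes vulpes"], 25)
  # marginals equal group sample counts
  marg <- conf$table |>
    dplyr::group_by(dna_host) |>
    dplyr::summarise(n = sum(n))
  expect_equal(marg$n, c(24L, 24L))

  # perfect labels: 0% everywhere and a diagonal table
  perfect <- dplyr::mutate(samples, field_label = dna_host)
  conf2 <- host_confusion(perfect)
  expect_true(all(conf2$rates$misid_pct == 0))
  off <- conf2$table[conf2$table$field_label != conf2$table$dna_host, ]
  expect_true(all(off$n == 0))
})

test_that("richness and the woodland:open ratio are computed over distinct prey", {
  samples <- tibble::tibble(sample_id = c("S1", "S2"), dna_host = "Martes martes")
  prey <- dplyr::bind_rows(
    prof_row("S1", c("w1", "w2", "w3"), c(200, 150, 100)),
    prof_row("S2", c("w4", "w5", "w6", "w7", "o1", "o2", "o3", "x1"),
             rep(120, 8)))
  habitat <- tibble::tibble(
    taxon = c(paste0("w", 1:7), paste0("o", 1:3)),
    habitat_class = rep(c("woodland", "open"), c(7, 3)))
  expect_message(rh <- richness_and_habitat(prey, samples, habitat), "x1")
  expect_equal(rh$per_sample$richness, c(3L, 8L))
  expect_equal(rh$group_richness$richness, 11L)
  # 7 woodland vs 3 open distinct species -> 70:30 (the unknown taxon is other)
  expect_equal(rh$habitat_ratio$pct_woodland, 70)
  expect_equal(rh$habitat_ratio$pct_open, 30)

  # sample with no prey keeps richness 0
  s3 <- tibble::tibble(sample_id = "S3", dna_host = "Martes martes")
  rh0 <- suppressMessages(richness_and_habitat(prey[0, ], s3, habitat))
  expect_equal(rh0$per_sample$richness, 0L)
})

test_that("diet summary object tidies, glances and plots", {
  samples <- tibble::tibble(sample_id = c("S1", "S2"),
                            dna_host = c("Vulpes vulpes", "Martes martes"))
  manifest <- tibble::tibble(sample_id = c("S1", "S2"),
                             field_label = c("Vulpes vulpes", "Vulpes vulpes"))
  prey <- dplyr::bind_rows(
    prof_row("S1", c("Rana temporaria", "Cervus elaphus"), c(700, 300)),
    prof_row("S2", "Microtus agrestis", 400))
  ds <- summarize_diet(prey, samples, manifest = manifest,
                       habitat = tibble::tibble(
                         taxon = c("Rana temporaria", "Cervus elaphus",
                                   "Microtus agrestis"),
                         habitat_class = c("aquatic", "open", "open")))
  td <- tidy(ds)
  expect_true(all(c("group", "taxon", "statistic", "value") %in% names(td)))
  expect_true(all(td$value[td$statistic == "foo"] >= 0 &
                    td$value[td$statistic == "foo"] <= 100, na.rm = TRUE))
  gl <- glance(ds)
  expect_equal(gl$n_samples, 2L)
  expect_equal(gl$misid_pct, 50)   # one of two dna hosts mislabelled
  expect_s3_class(autoplot(ds), "ggplot")
  expect_s3_class(autoplot(ds, type = "rra"), "ggplot")
})
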
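#' Simulate per-query alignment-hit tables from a ground truth
#'
#' A shortcut around read emission, preprocessing and alignment: every
#' (sample, taxon) pair in the truth table becomes one query cluster whose
#' size is the true read count, with a top self-hit (identity >= 98%,
#' coverage >= 90%) and lower-scoring decoy hits to related taxa (congeners,
#' then confamilials) whose bit-scores fall strictly outside the top-2%
#' window, so the true taxon wins the consensus. Taxa listed in
#' `ambiguous_taxa` instead receive all their congeners *inside* the window
#' at species-level identity, so the majority-LCA vote legitimately stops at
#' genus. Deterministic given the seed.
#'
#' @param db Reference database tibble.
#' @param truth Truth list from [sim_truth_table()] (only `counts` is used).
#' @param identity_noise Spread (percent identity) of the self-hit below
#'   100%.
#' @param ambiguous_taxa Character vector of species names to render
#'   ambiguous at species rank.
#' @param seed Integer seed.
#' @return List with `clusters` (a cluster tibble usable by
#'   [assign_counts()]) and `hits` (hit tibble in the package dialect).
#' @export
simulate_hit_tables <- function(db, truth, identity_noise = 0.5,
                                ambiguous_taxa = character(0), seed = 1L) {
  counts <- truth$counts
  bad <- setdiff(unique(counts$taxon), db$species)
  if (length(bad) > 0) {
    abort(sprintf("truth refers to taxa absent from the database: %s",
                  paste(bad, collapse = ", ")))
  }
  with_seed(derive_seed(seed, 7L), {
    counts$query_id <- sprintf("%s|%s", counts$sample_id,
                               db$taxon_id[match(counts$taxon, db$species)])
    agg <- counts |>
      group_by(.data$query_id, .data$taxon) |>
      summarise(size = sum(.data$reads), .groups = "drop")
    clusters <- tibble(
      cluster_id = agg$query_id,
      sequence = db$sequence[match(agg$taxon, db$species)],
      size = as.integer(agg$size),
      sample_counts = lapply(seq_len(nrow(agg)), function(i) {
        sub <- counts[counts$query_id == agg$query_id[i], ]
        setNames(as.integer(sub$reads), sub$sample_id)
      }))
    hits <- lapply(seq_len(nrow(agg)), function(i) {
      t_row <- db[match(agg$taxon[i], db$species), ]
      top_bs <- 170 + runif(1, 0, 20)
      self <- tibble(query_id = agg$query_id[i], taxon_id = t_row$taxon_id,
                     pident = min(100, 100 - abs(stats::rnorm(1, 0, identity_noise))),
                     bitscore = top_bs, qcov = runif(1, 92, 100))
      congeners <- db[db$genus == t_row$genus & db$taxon_id != t_row$taxon_id, ]
      confam <- db[db$family == t_row$family & db$genus != t_row$genus, ]
      decoys <- NULL
      if (agg$taxon[i] %in% ambiguous_taxa && nrow(congeners) > 0) {
        # congeners inside the top-2% window at assignable identity
        decoys <- tibble(query_id = agg$query_id[i],
                         taxon_id = congeners$taxon_id,
                         pident = runif(nrow(congeners), 98, 99.5),
                         bitscore = top_bs * runif(nrow(congeners), 0.985, 0.999),
                         qcov = runif(nrow(congeners), 92, 100))
      } else {
        rel <- dplyr::bind_rows(congeners, confam)
        if (nrow(rel) > 0) {
          decoys <- tibble(query_id = agg$query_id[i],
                           taxon_id = rel$taxon_id,
                           pident = runif(nrow(rel), 88, 96),
                           bitscore = top_bs * runif(nrow(rel), 0.80, 0.97),
                           qcov = runif(nrow(rel), 88, 100))
        }
      }
      dplyr::bind_rows(self, decoys)
    })
    hits <- dplyr::bind_rows(hits) |>
      mutate(length = 97L, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = 97L, sstart = 1L, send = 97L, evalue = 0) |>
      select(dplyr::all_of(BLAST_COLS)) |>
      arrange(.data$query_id, desc(.data$bitscore), .data$taxon_id)
    list(clusters = clusters, hits = hits)
  })
}

#' Write simulated hit tables as one BLAST tabular file per sample
#'
#' @param sim Result of [simulate_hit_tables()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_hit_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample_of <- sub("\\|.*$", "", sim$hits$query_id)
  for (sid in unique(sample_of)) {
    write_hits(sim$hits[sample_of == sid, ],
               file.path(dir, paste0(sid, "_hits.tsv")))
  }
  invisible(dir)
}
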
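# Shared fixture builders and independent oracles.

RANKS <- tax_ranks()

make_clusters <- function(seqs, sizes, sample_id = "S1") {
  cl <- tibble::tibble(
    cluster_id = sprintf("q%02d", seq_along(seqs)),
    sequence = seqs,
    size = as.integer(sizes),
    sample_counts = lapply(sizes, function(s) {
      stats::setNames(as.integer(s), sample_id)
    })
  )
  cl[order(-cl$size, cl$sequence), ]
}

make_lineage <- function(...) {
  # each argument: character vector of up to 7 rank names, top-down
  rows <- lapply(list(...), function(v) {
    v <- c(v, rep("", length(RANKS) - length(v)))
    stats::setNames(as.list(v), RANKS)
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# Brute-force majority-LCA oracle: enumerate every rank prefix of every
# unique lineage and keep the deepest prefix whose share of unique lineages
# reaches the agreement threshold.
oracle_mlca <- function(lineages, agreement = 0.8, min_rank = "order") {
  uniq <- unique(lineages[, RANKS])
  uniq[is.na(uniq)] <- ""
  n <- nrow(uniq)
  best_depth <- 0L
  best <- rep("", length(RANKS))
  if (n > 0) {
    for (i in seq_len(n)) {
      for (d in seq_along(RANKS)) {
        pr <- unlist(uniq[i, seq_len(d)], use.names = FALSE)
        if (any(pr == "")) break
        match_pr <- vapply(seq_len(n), function(j) {
          all(unlist(uniq[j, seq_len(d)], use.names = FALSE) == pr)
        }, logical(1))
        if (mean(match_pr) >= agreement - 1e-9 && d > best_depth) {
          best_depth <- d
          best <- c(pr, rep("", length(RANKS) - d))
        }
      }
    }
  }
  if (best_depth < match(min_rank, RANKS)) {
    return(list(assigned = FALSE, rank = NA_character_, taxon = NA_character_))
  }
  list(assigned = TRUE, rank = RANKS[best_depth], taxon = best[best_depth])
}

# Random lineage sets over a small fixed taxonomy, for fuzzing the MLCA
# against the oracle. Some lineages are truncated at genus to exercise
# partially resolved references.
random_lineage_set <- function(n, truncate_prob = 0.15) {
  pick <- function(x) x[sample.int(length(x), 1)]
  make_one <- function() {
    cl <- pick(c("Mammalia", "Aves"))
    or <- pick(paste0(cl, c("_ord1", "_ord2")))
    fa <- pick(paste0(or, c("_famA", "_famB")))
    ge <- pick(paste0(fa, c("_gen1", "_gen2", "_gen3")))
    sp <- pick(paste0(ge, c("_sp1", "_sp2")))
    v <- c("Eukaryota", "Chordata", cl, or, fa, ge, sp)
    if (stats::runif(1) < truncate_prob) v[7] <- ""
    v
  }
  m <- t(vapply(seq_len(n), function(i) make_one(), character(7)))
  colnames(m) <- RANKS
  tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
}

# A tiny reference db + noise-free dataset reused by several test files.
small_dataset <- function(n_samples = 4, seed = 42, noise_free = TRUE,
                          depth_meanlog = log(2000)) {
  db <- generate_reference_db(24, seed = seed)
  cfg <- sim_config(
    n_samples = n_samples, seed = seed,
    reads_per_sample = c(meanlog = depth_meanlog, sdlog = 0.3),
    substitution_error_rate = if (noise_free) 0 else 1e-3,
    chimera_rate = if (noise_free) 0 else 5e-3,
    contamination_fraction = if (noise_free) 0 else 0.01
  )
  list(db = db, cfg = cfg, ds = generate_scat_dataset(db, cfg))
}

# Truth-side reference computation: apply the canonical diet filters
# directly to true template counts (no sequences involved).
truth_diet <- function(truth, cfg, params = pipeline_config()) {
  profiles <- truth$counts |>
    dplyr::select(sample_id, taxon, reads)
  prof <- suppressMessages(
    remove_nontarget(profiles, control_taxa = cfg$control_taxon))
  prof <- apply_noise_threshold(prof, params$noise_fraction)
  hosts <- identify_host(prof, candidate_hosts = names(cfg$host_mix),
                         min_host_reads = params$min_host_reads)
  sub <- suppressMessages(subtract_host_and_contaminants(
    prof, hosts, contaminant_taxa = cfg$contaminant_taxon))
  prey <- apply_min_reads(sub$prey, params$min_reads)
  list(prey = prey, samples = sub$samples, hosts = hosts)
}
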
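#' Default per-predator prey profiles
#'
#' Inclusion probability (chance a scat from that predator contains the taxon)
#' and a relative read weight (Dirichlet concentration; higher weight means a
#' larger expected share of the prey reads) for each candidate prey taxon.
#' Defaults describe a fox / pine marten breeding-season diet in an afforested
#' peatland: voles, wood mice and shrews dominate marten scats; deer carrion,
#' frogs and pine marten DNA itself are prominent in fox scats. The other
#' predator appears as a diet/contact item, never as a host.
#'
#' @return Named list (one element per candidate host) of tibbles with columns
#'   `taxon`, `incl_prob`, `weight`.
#' @export
default_prey_profiles <- function() {
  marten <- tibble(
    taxon = c("Microtus agrestis", "Apodemus sylvaticus", "Apodemus flavicollis",
              "Myodes glareolus", "Sorex araneus", "Rana temporaria",
              "Cervus elaphus", "Fringilla coelebs", "Emberiza schoeniclus",
              "Phasianus colchicus", "Anas platyrhynchos", "Columba palumbus",
              "Vulpes vulpes", "Zootoca vivipara"),
    incl_prob = c(0.64, 0.42, 0.15, 0.20, 0.20, 0.30,
                  0.08, 0.15, 0.20, 0.10, 0.08, 0.08, 0.16, 0.04),
    weight = c(2.5, 2.5, 2, 2, 1.5, 2.5, 2, 1.5, 3, 1.5, 1.5, 1.5, 1.5, 1)
  )
  fox <- tibble(
    taxon = c("Cervus elaphus", "Rana temporaria", "Martes martes",
              "Microtus agrestis", "Apodemus sylvaticus", "Oryctolagus cuniculus",
              "Phasianus colchicus", "Lagopus lagopus", "Emberiza citrinella",
              "Zootoca vivipara"),
    incl_prob = c(0.46, 0.30, 0.50, 0.21, 0.13, 0.06, 0.06, 0.04, 0.04, 0.02),
    weight = c(3, 3.5, 3, 1.5, 1.5, 1.5, 1.5, 1.5, 1, 1)
  )
  list("Martes martes" = marten, "Vulpes vulpes" = fox)
}

#' Configuration for the scat-sample simulator
#'
#' All probabilities are per the stated unit: `misid_rate` per sample,
#' `substitution_error_rate` per base, `chimera_rate` per read,
#' `contamination_fraction` / `control_fraction` per read (expected fraction
#' of reads that are human contamination or positive-control carry-over).
#'
#' @param n_samples Number of scat samples.
#' @param host_mix Named numeric: probability each candidate host deposited a
#'   scat. Names are species present in the reference database.
#' @param misid_rate Probability the field label differs from the true host.
#' @param prey_profiles Named list of per-host prey tibbles
#'   (see [default_prey_profiles()]).
#' @param reads_per_sample Named numeric `c(meanlog=, sdlog=)` of the
#'   log-normal sequencing depth per sample.
#' @param host_fraction_range Range the host's read fraction is drawn from
#'   (uniform); kept above any single prey taxon's expected share so the host
#'   dominates the sample.
#' @param prey_concentration Multiplier on the prey `weight` column giving the
#'   Dirichlet concentration used to draw prey read fractions.
#' @param substitution_error_rate Per-base substitution probability.
#' @param chimera_rate Per-read probability of emitting an additional bimeric
#'   read (single-crossover concatenation of two templates in the sample).
#' @param contamination_fraction Expected fraction of human reads.
#' @param control_fraction Expected fraction of positive-control reads.
#' @param contaminant_taxon,control_taxon Species names of the contaminant and
#'   the positive-control spike.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 48,
                       host_mix = c("Vulpes vulpes" = 0.5, "Martes martes" = 0.5),
                       misid_rate = 0.29,
                       prey_profiles = default_prey_profiles(),
                       reads_per_sample = c(meanlog = log(10000), sdlog = 0.6),
                       host_fraction_range = c(0.55, 0.9),
                       prey_concentration = 2,
                       substitution_error_rate = 1e-3,
                       chimera_rate = 5e-3,
                       contamination_fraction = 0.01,
                       control_fraction = 0.003,
                       contaminant_taxon = "Homo sapiens",
                       control_taxon = "Maylandia zebra",
                       seed = 1L) {
  probs <- c(misid_rate, substitution_error_rate, chimera_rate,
             contamination_fraction, control_fraction, host_mix)
  if (any(probs < 0 | probs > 1)) {
    abort("all rates, fractions and host_mix entries must lie in [0, 1].")
  }
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  if (!all(c("meanlog", "sdlog") %in% names(reads_per_sample)) ||
      reads_per_sample[["sdlog"]] <= 0 || reads_per_sample[["meanlog"]] <= 0) {
    abort("`reads_per_sample` needs positive `meanlog` and `sdlog`.")
  }
  if (abs(sum(host_mix) - 1) > 1e-8) host_mix <- host_mix / sum(host_mix)
  structure(list(
    n_samples = as.integer(n_samples), host_mix = host_mix,
    misid_rate = misid_rate, prey_profiles = prey_profiles,
    reads_per_sample = reads_per_sample,
    host_fraction_range = host_fraction_range,
    prey_concentration = prey_concentration,
    substitution_error_rate = substitution_error_rate,
    chimera_rate = chimera_rate,
    contamination_fraction = contamination_fraction,
    control_fraction = control_fraction,
    contaminant_taxon = contaminant_taxon, control_taxon = control_taxon,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_cfg_against_db <- function(db, cfg) {
  need <- c(names(cfg$host_mix),
            unlist(lapply(cfg$prey_profiles, function(p) p$taxon), use.names = FALSE),
            cfg$contaminant_taxon, cfg$control_taxon)
  missing <- setdiff(unique(need), db$species)
  if (length(missing) > 0) {
    abort(sprintf("configuration references taxa absent from the reference database: %s",
                  paste(missing, collapse = ", ")))
  }
  hosts <- names(cfg$host_mix)
  bad <- names(which(!names(cfg$prey_profiles) %in% hosts))
  if (length(setdiff(hosts, names(cfg$prey_profiles))) > 0) {
    abort("every host in `host_mix` needs a prey profile.")
  }
  invisible(TRUE)
}

#' Draw the ground-truth composition of a scat dataset
#'
#' Samples host identity, field label, per-taxon template read counts,
#' contamination, control spikes and the bimera count for every scat, without
#' emitting any sequences. This is the generative model the read emitter
#' realises; it is exposed so tests and calibration can Monte-Carlo the
#' expected composition cheaply.
#'
#' @param db Reference database tibble from [generate_reference_db()].
#' @param cfg A [sim_config()].
#' @return List with tibbles `samples` (sample_id, true_host, field_label,
#'   n_template_reads, n_chimera) and `counts` (sample_id, taxon, role,
#'   reads), where `role` is one of host / prey / contamination / control.
#' @export
sim_truth_table <- function(db, cfg) {
  check_cfg_against_db(db, cfg)
  hosts <- names(cfg$host_mix)
  per_sample <- lapply(seq_len(cfg$n_samples), function(i) {
    with_seed(derive_seed(cfg$seed, 1000L + i), {
      sid <- sprintf("S%03d", i)
      true_host <- sample(hosts, 1, prob = cfg$host_mix)
      field_label <- true_host
      if (runif(1) < cfg$misid_rate && length(hosts) > 1) {
        field_label <- sample(setdiff(hosts, true_host), 1)
      }
      n <- max(200L, as.integer(round(rlnorm(1, cfg$reads_per_sample[["meanlog"]],
                                             cfg$reads_per_sample[["sdlog"]]))))
      n_contam <- rbinom(1, n, cfg$contamination_fraction)
      n_control <- rbinom(1, n, cfg$control_fraction)
      n_body <- n - n_contam - n_control
      host_frac <- runif(1, cfg$host_fraction_range[1], cfg$host_fraction_range[2])
      profile <- cfg$prey_profiles[[true_host]]
      profile <- profile[profile$taxon != true_host, , drop = FALSE]
      included <- profile[runif(nrow(profile)) < profile$incl_prob, , drop = FALSE]
      n_host <- as.integer(round(host_frac * n_body))
      n_prey_pool <- n_body - n_host
      if (nrow(included) == 0) {
        n_host <- n_body
        prey_counts <- integer(0)
      } else {
        frac <- stats::rgamma(nrow(included),
                              shape = included$weight * cfg$prey_concentration)
        frac <- frac / sum(frac)
        prey_counts <- as.integer(rmultinom(1, n_prey_pool, frac))
      }
      counts <- tibble(
        sample_id = sid,
        taxon = c(true_host, included$taxon,
                  cfg$contaminant_taxon, cfg$control_taxon),
        role = c("host", rep("prey", nrow(included)), "contamination", "control"),
        reads = c(n_host, prey_counts, n_contam, n_control)
      )
      counts <- counts[counts$reads > 0, , drop = FALSE]
      n_chimera <- rbinom(1, n, cfg$chimera_rate)
      list(sample = tibble(sample_id = sid, true_host = true_host,
                           field_label = field_label,
                           n_template_reads = sum(counts$reads),
                           n_chimera = n_chimera),
           counts = counts)
    })
  })
  list(samples = dplyr::bind_rows(lapply(per_sample, `[[`, "sample")),
       counts = dplyr::bind_rows(lapply(per_sample, `[[`, "counts")))
}

mutate_reads <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads[1])
  n_mut <- rbinom(length(reads), L, rate)
  idx <- which(n_mut > 0)
  if (length(idx) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE), use.names = FALSE),
                nrow = length(idx), byrow = TRUE)
  rows <- rep(seq_along(idx), n_mut[idx])
  cols <- unlist(lapply(n_mut[idx], function(m) sample.int(L, m)), use.names = FALSE)
  lin <- (cols - 1L) * length(idx) + rows
  cur <- match(mat[lin], bases)
  mat[lin] <- bases[((cur - 1L + sample.int(3, length(lin), replace = TRUE)) %% 4L) + 1L]
  reads[idx] <- apply(mat, 1, paste, collapse = "")
  reads
}

emit_sample_reads <- function(counts, seqs_by_taxon, n_chimera, error_rate, seed) {
  with_seed(seed, {
    templates <- seqs_by_taxon[counts$taxon]
    reads <- rep(unname(templates), counts$reads)
    if (n_chimera > 0 && nrow(counts) >= 2) {
      L <- nchar(templates[[1]])
      chim <- vapply(seq_len(n_chimera), function(j) {
        pair <- sample(seq_len(nrow(counts)), 2, prob = counts$reads)
        k <- sample.int(L - 1L, 1)
        paste0(substr(templates[[pair[1]]], 1, k),
               substr(templates[[pair[2]]], k + 1, L))
      }, character(1))
      reads <- c(reads, chim)
    }
    mutate_reads(reads, error_rate)
  })
}

#' Simulate a full scat metabarcoding dataset
#'
#' Realises [sim_truth_table()] as per-sample reads: each template read is its
#' reference sequence with i.i.d. substitutions; bimeric reads are
#' single-crossover concatenations of two templates present in the sample;
#' human contamination and positive-control spikes are emitted like any other
#' template. Identical `db` + `cfg` (including seed) reproduce the dataset
#' byte-for-byte.
#'
#' @inheritParams sim_truth_table
#' @return List of class `scat_dataset`: `reads` (tibble sample_id, read_id,
#'   sequence), `manifest` (sample_id, field_label, season, habitat),
#'   `truth` (see [sim_truth_table()]), plus the `db` and `config` used.
#' @export
#' @examples
#' db <- generate_reference_db(8, seed = 1)
#' ds <- generate_scat_dataset(db, sim_config(n_samples = 2, seed = 1,
#'   reads_per_sample = c(meanlog = log(300), sdlog = 0.1)))
#' dplyr::count(ds$reads, sample_id)
generate_scat_dataset <- function(db, cfg) {
  check_cfg_against_db(db, cfg)
  truth <- sim_truth_table(db, cfg)
  seqs_by_taxon <- setNames(db$sequence, db$species)
  reads <- lapply(seq_len(nrow(truth$samples)), function(i) {
    s <- truth$samples[i, ]
    counts <- truth$counts[truth$counts$sample_id == s$sample_id, , drop = FALSE]
    rs <- emit_sample_reads(counts, seqs_by_taxon, s$n_chimera,
                            cfg$substitution_error_rate,
                            derive_seed(cfg$seed, 2000L + i))
    tibble(sample_id = s$sample_id,
           read_id = sprintf("%s_r%06d", s$sample_id, seq_along(rs)),
           sequence = rs)
  })
  manifest <- with_seed(derive_seed(cfg$seed, 3L), {
    tibble(sample_id = truth$samples$sample_id,
           field_label = truth$samples$field_label,
           season = sample(c("spring", "summer"), nrow(truth$samples), replace = TRUE),
           habitat = sample(c("bog", "forest", "forest_edge"),
                            nrow(truth$samples), replace = TRUE))
  })
  structure(list(reads = dplyr::bind_rows(reads), manifest = manifest,
                 truth = truth, db = db, config = cfg),
            class = "scat_dataset")
}

#' @export
print.scat_dataset <- function(x, ...) {
  cat(sprintf("<scat_dataset> %d samples, %d reads, %d reference taxa\n",
              nrow(x$truth$samples), nrow(x$reads), nrow(x$db)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One FASTA per sample (`<sample_id>.fasta`), a tab-separated `manifest.tsv`,
#' the reference FASTA + lineage table, and the ground truth as CSV.
#'
#' @param ds A `scat_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scat_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(ds$reads$sample_id)) {
    sub <- ds$reads[ds$reads$sample_id == sid, ]
    seqs <- Biostrings::DNAStringSet(setNames(sub$sequence, sub$read_id))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(sid, ".fasta")), width = 120L)
  }
  readr::write_tsv(ds$manifest, file.path(dir, "manifest.tsv"))
  write_reference_db(ds$db, file.path(dir, "reference.fasta"),
                     file.path(dir, "lineage.tsv"))
  readr::write_csv(ds$truth$samples, file.path(dir, "truth_samples.csv"))
  readr::write_csv(ds$truth$counts, file.path(dir, "truth_counts.csv"))
  invisible(dir)
}
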
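#' Pipeline configuration
#'
#' Collects every stage parameter with its literature default: minimum
#' cluster size 3; UNOISE alpha 2; bimera parent skew 16; top-2% bit-score
#' window; >= 90% query coverage; >= 98% identity; 80% lineage agreement;
#' assignments above order unassigned; 0.1% per-sample noise threshold;
#' 100-read per-sample per-taxon minimum. Any field can be overridden.
#'
#' @param min_cluster_size Minimum dereplicated cluster size retained.
#' @param alpha,max_distance Denoising parameters (see [denoise()]).
#' @param min_parent_skew Bimera parent/query abundance skew
#'   (see [remove_chimeras()]).
#' @param bitscore_window,min_coverage,min_identity Hit-filter thresholds
#'   (see [filter_hits()]).
#' @param agreement,min_rank Consensus parameters (see [mlca()]).
#' @param noise_fraction Per-sample noise threshold (see
#'   [apply_noise_threshold()]).
#' @param min_reads Per-sample per-taxon minimum read count
#'   (see [apply_min_reads()]).
#' @param candidate_hosts Candidate host species.
#' @param min_host_reads Host-read floor (see [identify_host()]).
#' @param contaminant_taxa,control_taxa Contaminant and positive-control
#'   species.
#' @param ambiguous_groups Named list of species sets rolled up to a higher
#'   taxon (see [rollup_ambiguous()]).
#' @param taxon_groups Named list of prey-group aggregates; `NULL` means
#'   derive [default_taxon_groups()] from the lineage table.
#' @param seed Integer seed (only used when the pipeline itself simulates).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cluster_size = 3, alpha = 2,
                            max_distance = Inf, min_parent_skew = 16,
                            bitscore_window = 0.02, min_coverage = 90,
                            min_identity = 98, agreement = 0.8,
                            min_rank = "order", noise_fraction = 0.001,
                            min_reads = 100,
                            candidate_hosts = c("Vulpes vulpes", "Martes martes"),
                            min_host_reads = 100,
                            contaminant_taxa = "Homo sapiens",
                            control_taxa = "Maylandia zebra",
                            ambiguous_groups = list(),
                            taxon_groups = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full scat-diet pipeline
#'
#' Canonical stage order: dereplicate -> minimum-cluster-size filter ->
#' denoise -> bimera removal -> alignment (built-in scorer, unless
#' precomputed hits are supplied) -> hit filtering + majority-LCA ->
#' count propagation -> control/unassigned removal -> noise threshold ->
#' ambiguous roll-up -> host confirmation -> host/contaminant subtraction ->
#' minimum-read threshold -> diet summaries. Re-running with identical
#' inputs and config reproduces the outputs exactly.
#'
#' @param dataset A `scat_dataset` from [generate_scat_dataset()], or a list
#'   with `reads` (tibble sample_id/sequence), `manifest`, and a reference
#'   `db` tibble.
#' @param config A [pipeline_config()].
#' @param hits Optional precomputed hit tibble (skips the built-in aligner);
#'   must reference the pipeline's cluster ids, or be paired with
#'   `clusters`.
#' @param clusters Optional precomputed cluster tibble (skips
#'   preprocessing; used with `hits`, e.g. from [simulate_hit_tables()]).
#' @param out_dir Optional directory: all result tables are written as CSV
#'   together with a JSON run manifest (seed, parameters, per-stage record
#'   counts).
#' @return List of class `scatdiet_result`: `clusters`, `hits`,
#'   `assignments`, `profiles` (post-assignment counts), `hosts`, `prey`,
#'   `samples`, `summary` (a [summarize_diet()] object) and `stage_counts`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), hits = NULL,
                         clusters = NULL, out_dir = NULL) {
  db <- dataset$db
  lineage <- db[, c("taxon_id", TAX_RANKS)]
  stage <- list()
  if (is.null(clusters)) {
    cl <- dereplicate(dataset$reads[, c("sample_id", "sequence")])
    stage$reads_in <- nrow(dataset$reads)
    stage$clusters_derep <- nrow(cl)
    cl <- filter_small_clusters(cl, config$min_cluster_size)
    stage$clusters_minsize <- nrow(cl)
    cl <- denoise(cl, alpha = config$alpha, max_distance = config$max_distance)
    stage$clusters_denoised <- nrow(cl)
    cl <- remove_chimeras(cl, min_parent_skew = config$min_parent_skew)
    stage$clusters_nonchimeric <- nrow(cl)
  } else {
    cl <- clusters
    stage$clusters_precomputed <- nrow(cl)
  }
  if (is.null(hits)) {
    hits <- align_clusters(cl, db)
  }
  stage$hits <- nrow(hits)
  assignments <- assign_taxa(hits, lineage,
                             bitscore_window = config$bitscore_window,
                             min_coverage = config$min_coverage,
                             min_identity = config$min_identity,
                             agreement = config$agreement,
                             min_rank = config$min_rank)
  # clusters with no reported hits at all are unassigned too
  no_hit <- setdiff(cl$cluster_id, assignments$query_id)
  if (length(no_hit) > 0) {
    empty <- mlca(tibble(), agreement = config$agreement,
                  min_rank = config$min_rank)
    assignments <- dplyr::bind_rows(
      assignments,
      dplyr::bind_cols(tibble(query_id = no_hit),
                       empty[rep(1, length(no_hit)), ]))
  }
  stage$queries_assigned <- sum(assignments$assigned)
  profiles <- assign_counts(assignments, cl)
  stage$profile_rows <- nrow(profiles)
  prof <- remove_nontarget(profiles, control_taxa = config$control_taxa)
  stage$profile_rows_after_controls <- nrow(prof)
  prof <- apply_noise_threshold(prof, config$noise_fraction)
  stage$profile_rows_after_noise <- nrow(prof)
  prof <- rollup_ambiguous(prof, config$ambiguous_groups, lineage = db)
  hosts <- identify_host(prof, candidate_hosts = config$candidate_hosts,
                         min_host_reads = config$min_host_reads)
  stage$samples_determinate <- sum(!is.na(hosts$dna_host))
  sub <- subtract_host_and_contaminants(prof, hosts,
                                        contaminant_taxa = config$contaminant_taxa)
  prey <- apply_min_reads(sub$prey, config$min_reads)
  stage$prey_rows <- nrow(prey)
  tg <- config$taxon_groups %||% default_taxon_groups(db)
  habitat <- tibble(taxon = db$species, habitat_class = db$habitat_class)
  summary <- summarize_diet(prey, sub$samples, manifest = dataset$manifest,
                            habitat = habitat, taxon_groups = tg)
  res <- structure(list(clusters = cl, hits = hits, assignments = assignments,
                        profiles = profiles, hosts = hosts, prey = prey,
                        samples = sub$samples, summary = summary,
                        stage_counts = stage, config = config),
                   class = "scatdiet_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.scatdiet_result <- function(x, ...) {
  cat("<scatdiet_result>\n")
  counts <- unlist(x$stage_counts)
  cat(paste(sprintf("  %-28s %d", names(counts), counts), collapse = "\n"), "\n")
  invisible(x)
}

#' Write all pipeline result tables and the run manifest
#'
#' @param res A `scatdiet_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$profiles, file.path(dir, "assigned_counts.csv"))
  readr::write_csv(res$hosts, file.path(dir, "hosts.csv"))
  readr::write_csv(res$prey, file.path(dir, "prey_profiles.csv"))
  readr::write_csv(res$summary$foo, file.path(dir, "foo.csv"))
  readr::write_csv(res$summary$rra, file.path(dir, "rra.csv"))
  if (!is.null(res$summary$confusion)) {
    readr::write_csv(res$summary$confusion$table, file.path(dir, "confusion.csv"))
    readr::write_csv(res$summary$confusion$rates,
                     file.path(dir, "misidentification.csv"))
  }
  readr::write_csv(res$summary$richness, file.path(dir, "richness.csv"))
  readr::write_csv(res$summary$habitat_ratio, file.path(dir, "habitat_ratio.csv"))
  cfg <- res$config
  cfg$taxon_groups <- NULL
  cfg <- lapply(cfg, function(v) {
    if (is.numeric(v) && any(!is.finite(v))) as.character(v) else v
  })
  manifest <- list(
    package = "scatdiet",
    version = as.character(utils::packageVersion("scatdiet")),
    parameters = cfg[!vapply(cfg, is.null, logical(1))],
    stage_counts = res$stage_counts
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
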
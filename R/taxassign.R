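## BLAST tabular dialect used throughout: the 12 standard outfmt-6 columns
## with the subject id holding a taxon_id from the lineage table, plus an
## appended 13th column, percent query coverage (alignment length / query
## length * 100).
BLAST_COLS <- c("query_id", "taxon_id", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore", "qcov")

#' Read alignment hits in the package's BLAST tabular dialect
#'
#' Parses a headerless tab-separated hit file (standard outfmt-6 columns with
#' an appended percent-query-coverage column; subject ids are taxon ids).
#' Rows referring to taxon ids absent from `lineage` are dropped with a
#' message; malformed rows raise an error naming the first bad line.
#'
#' @param path Hit file path.
#' @param lineage Optional lineage tibble (taxon_id + seven ranks) used to
#'   validate subject ids.
#' @return Tibble of hits with columns `query_id`, `taxon_id`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `qcov`.
#' @export
parse_hits <- function(path, lineage = NULL) {
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = BLAST_COLS,
                    col_types = "ccdiiiiiiiddd", progress = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed hit row at line %d of %s", prob$row[1], path))
  }
  num <- c("pident", "bitscore", "qcov")
  bad <- which(!stats::complete.cases(raw[, num]) |
                 raw$pident < 0 | raw$pident > 100 |
                 raw$qcov < 0 | raw$qcov > 100 | raw$bitscore <= 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed hit row at line %d of %s", bad[1], path))
  }
  if (!is.null(lineage)) {
    unknown <- !raw$taxon_id %in% lineage$taxon_id
    if (any(unknown)) {
      inform(sprintf("parse_hits: dropped %d hit(s) with unknown taxon ids",
                     sum(unknown)))
      raw <- raw[!unknown, , drop = FALSE]
    }
  }
  raw
}

#' Write hits in the BLAST tabular dialect
#'
#' @param hits Hit tibble (see [parse_hits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, BLAST_COLS], path, col_names = FALSE)
  invisible(path)
}

#' Filter hits by bit-score window, coverage and identity
#'
#' Per query, retains hits whose bit-score lies within the top `100 *
#' bitscore_window` percent of that query's best bit-score (inclusive), with
#' at least `min_coverage` percent query coverage and at least `min_identity`
#' percent identity. All three thresholds are inclusive.
#'
#' @param hits Hit tibble; may contain several queries.
#' @param bitscore_window Fractional window below the per-query maximum
#'   bit-score (default 0.02, i.e. the top 2%).
#' @param min_coverage Minimum percent query coverage (default 90).
#' @param min_identity Minimum percent identity (default 98).
#' @return The retained hits, same columns as the input.
#' @export
#' @examples
#' h <- tibble::tibble(query_id = "q", taxon_id = c("a", "b", "c"),
#'                     pident = 99, qcov = 95, bitscore = c(200, 197, 195))
#' filter_hits(h)$taxon_id   # cutoff 196: "a" and "b" survive
filter_hits <- function(hits, bitscore_window = 0.02, min_coverage = 90,
                        min_identity = 98) {
  assert_cols(hits, c("query_id", "bitscore", "pident", "qcov"))
  if (nrow(hits) == 0) return(hits)
  hits |>
    group_by(.data$query_id) |>
    filter(.data$bitscore >= (1 - bitscore_window) * max(.data$bitscore)) |>
    ungroup() |>
    filter(.data$qcov >= min_coverage, .data$pident >= min_identity)
}

#' Majority lowest-common-ancestor consensus over candidate lineages
#'
#' Deduplicates the candidate lineages and walks the seven ranks top-down: at
#' each rank the modal taxon among lineages consistent with the accepted
#' prefix is accepted when its share of *all* unique lineages reaches
#' `agreement`; the walk stops at the first rank that fails (a tie for the
#' modal taxon also stops it). The assignment is the deepest accepted prefix;
#' a single unique lineage is assigned in full. Assignments resolving only
#' above `min_rank` (default `"order"`) are returned as unassigned.
#'
#' @param lineages Tibble with the seven rank columns (one row per hit or
#'   unique lineage; duplicates are removed internally). Ranks may be empty
#'   strings below the resolution of a reference entry.
#' @param agreement Required agreement fraction among unique lineages
#'   (default 0.8).
#' @param min_rank Shallowest rank an assignment may stop at and still count
#'   as assigned.
#' @return A one-row tibble: `assigned` (logical), `rank`, `taxon`, and the
#'   seven rank columns truncated at the accepted depth (empty beyond it).
#' @export
mlca <- function(lineages, agreement = 0.8, min_rank = "order") {
  if (!min_rank %in% TAX_RANKS) abort("`min_rank` must be a taxonomic rank name.")
  if (agreement <= 0 || agreement > 1) abort("`agreement` must lie in (0, 1].")
  out_lineage <- setNames(rep("", length(TAX_RANKS)), TAX_RANKS)
  unassigned <- tibble(assigned = FALSE, rank = NA_character_,
                       taxon = NA_character_, !!!as.list(out_lineage))
  if (nrow(lineages) == 0) return(unassigned)
  uniq <- distinct(lineages[, TAX_RANKS])
  uniq[is.na(uniq)] <- ""
  n <- nrow(uniq)
  keep <- rep(TRUE, n)
  depth <- 0L
  for (r in TAX_RANKS) {
    vals <- uniq[[r]][keep]
    vals <- vals[vals != ""]
    if (length(vals) == 0) break
    tab <- table(vals)
    top <- max(tab)
    modal <- names(tab)[tab == top]
    if (length(modal) > 1) break                  # modal tie: stop descent
    if (top / n < agreement - 1e-9) break         # share over ALL unique lineages
    depth <- depth + 1L
    out_lineage[[r]] <- modal
    keep <- keep & uniq[[r]] == modal
  }
  min_depth <- match(min_rank, TAX_RANKS)
  if (depth < min_depth) return(unassigned)
  tibble(assigned = TRUE, rank = TAX_RANKS[depth],
         taxon = out_lineage[[TAX_RANKS[depth]]], !!!as.list(out_lineage))
}

#' Assign taxonomy to every query via hit filtering + MLCA
#'
#' Convenience wrapper: joins lineages onto the hits, applies [filter_hits()]
#' per query, then [mlca()] per query. Queries whose hits are all filtered
#' out, or whose consensus resolves above `min_rank`, come back unassigned.
#'
#' @param hits Hit tibble (see [parse_hits()]).
#' @param lineage Lineage tibble with `taxon_id` and the seven rank columns.
#' @param bitscore_window,min_coverage,min_identity See [filter_hits()].
#' @param agreement,min_rank See [mlca()].
#' @return Tibble with one row per query: `query_id`, `assigned`, `rank`,
#'   `taxon` and the truncated rank columns.
#' @export
assign_taxa <- function(hits, lineage, bitscore_window = 0.02,
                        min_coverage = 90, min_identity = 98,
                        agreement = 0.8, min_rank = "order") {
  assert_cols(lineage, c("taxon_id", TAX_RANKS))
  queries <- unique(hits$query_id)
  kept <- filter_hits(hits, bitscore_window, min_coverage, min_identity) |>
    left_join(lineage[, c("taxon_id", TAX_RANKS)], by = "taxon_id")
  per_query <- split(kept, factor(kept$query_id, levels = queries))
  res <- dplyr::bind_rows(lapply(per_query, mlca,
                                 agreement = agreement, min_rank = min_rank))
  res$query_id <- queries
  relocate(res, "query_id")
}

#' Propagate cluster read counts to assigned taxa
#'
#' For each sample, read counts of all queries assigned to the same
#' taxonomic identity are summed; unassigned queries accumulate under the
#' explicit `"unassigned"` bucket. Every assigned query must have a cluster
#' record (its per-sample read counts).
#'
#' @param assignments Tibble from [assign_taxa()].
#' @param clusters Cluster tibble whose `cluster_id` matches
#'   `assignments$query_id`.
#' @return Profile tibble: `sample_id`, `taxon`, `rank`, `reads`, where
#'   `taxon` is `"unassigned"` (rank `NA`) for the unassigned bucket.
#' @export
assign_counts <- function(assignments, clusters) {
  missing <- setdiff(assignments$query_id, clusters$cluster_id)
  if (length(missing) > 0) {
    abort(sprintf("assignments refer to queries without cluster records: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  counts <- cluster_sample_counts(clusters) |>
    inner_join(assignments[, c("query_id", "assigned", "rank", "taxon")],
               by = c(cluster_id = "query_id")) |>
    mutate(taxon = if_else(.data$assigned, .data$taxon, "unassigned"),
           rank = if_else(.data$assigned, .data$rank, NA_character_))
  counts |>
    group_by(.data$sample_id, .data$taxon, .data$rank) |>
    summarise(reads = sum(.data$reads), .groups = "drop") |>
    arrange(.data$sample_id, desc(.data$reads))
}

#' Score clusters against a reference database (built-in aligner)
#'
#' A deliberately simple global scorer so end-to-end runs need no external
#' aligner: for each centroid/reference pair the Levenshtein distance d gives
#' percent identity `100 * (1 - d / L)` (L the longer length), coverage
#' `100 * min(lengths) / query length`, and a surrogate bit-score `2 *
#' (L - d)` that is monotone in alignment quality. Pairs below
#' `min_report_identity` are not reported (they could never pass the hit
#' filter). Precomputed BLAST tabular files are the primary input path for
#' real data; this scorer exists for simulation and testing.
#'
#' @param clusters Cluster tibble.
#' @param db Reference database tibble.
#' @param min_report_identity Do not report pairs below this percent identity
#'   (default 75).
#' @return Hit tibble in the package dialect.
#' @export
align_clusters <- function(clusters, db, min_report_identity = 75) {
  empty_hits <- tibble(!!!setNames(rep(list(character(0)), 2), BLAST_COLS[1:2]),
                       !!!setNames(rep(list(numeric(0)), 11), BLAST_COLS[-(1:2)]))
  if (nrow(clusters) == 0 || nrow(db) == 0) return(empty_hits)
  d <- adist(clusters$sequence, db$sequence)
  lq <- nchar(clusters$sequence)
  ls <- nchar(db$sequence)
  L <- outer(lq, ls, pmax)
  pident <- 100 * (1 - d / L)
  qcov <- 100 * outer(lq, ls, pmin) / lq
  keep <- which(pident >= min_report_identity, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty_hits)
  i <- keep[, 1]; j <- keep[, 2]
  tibble(query_id = clusters$cluster_id[i],
         taxon_id = db$taxon_id[j],
         pident = pident[keep],
         length = as.integer(L[keep]),
         mismatch = as.integer(d[keep]),
         gapopen = 0L, qstart = 1L, qend = as.integer(lq[i]),
         sstart = 1L, send = as.integer(ls[j]),
         evalue = 0, bitscore = 2 * (L[keep] - d[keep]),
         qcov = qcov[keep]) |>
    arrange(.data$query_id, desc(.data$bitscore), .data$taxon_id)
}
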
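## Clusters are kept as a tibble: cluster_id, sequence, size (total reads),
## and sample_counts, a list-column of named integer vectors (reads per
## sample). All preprocess stages take and return this shape, ordered by
## decreasing size with ties broken lexicographically on the sequence.

order_clusters <- function(clusters) {
  clusters <- clusters[order(-clusters$size, clusters$sequence), , drop = FALSE]
  clusters$cluster_id <- sprintf("cl%05d", seq_len(nrow(clusters)))
  clusters
}

empty_clusters <- function() {
  tibble(cluster_id = character(), sequence = character(),
         size = integer(), sample_counts = list())
}

#' Dereplicate reads into unique-sequence clusters
#'
#' Collapses reads at 100% identity and length: one cluster per distinct
#' sequence, pooled across samples, with per-sample membership counts
#' retained. Reads containing characters other than A/C/G/T are rejected
#' (their number is reported via a message). Output is ordered by decreasing
#' cluster size, ties broken lexicographically by sequence.
#'
#' @param reads Tibble with columns `sample_id` and `sequence` (one row per
#'   read).
#' @return Cluster tibble: `cluster_id`, `sequence`, `size`, and
#'   `sample_counts` (list-column of named per-sample read counts).
#' @export
#' @examples
#' reads <- tibble::tibble(sample_id = "S1",
#'                         sequence = c("ACGT", "ACGT", "ACGT", "ACGA"))
#' dereplicate(reads)
dereplicate <- function(reads) {
  assert_cols(reads, c("sample_id", "sequence"))
  if (nrow(reads) == 0) return(empty_clusters())
  ok <- grepl("^[ACGT]+$", reads$sequence)
  if (any(!ok)) {
    inform(sprintf("dereplicate: rejected %d read(s) with non-ACGT characters",
                   sum(!ok)))
    reads <- reads[ok, , drop = FALSE]
  }
  if (nrow(reads) == 0) return(empty_clusters())
  tab <- reads |>
    count(.data$sequence, .data$sample_id, name = "reads")
  f <- factor(tab$sequence)
  sizes <- as.integer(rowsum(tab$reads, f))
  counts <- split(setNames(as.integer(tab$reads), tab$sample_id), f)
  out <- tibble(sequence = levels(f), size = sizes,
                sample_counts = unname(counts))
  order_clusters(out)
}

#' Remove clusters below a minimum size
#'
#' Clusters represented by fewer than `min_size` reads are omitted from
#' further processing (default 3, i.e. singletons and doubletons are
#' discarded). Input order is preserved.
#'
#' @param clusters Cluster tibble from [dereplicate()].
#' @param min_size Minimum read count a cluster must reach to be retained
#'   (inclusive).
#' @return Filtered cluster tibble.
#' @export
filter_small_clusters <- function(clusters, min_size = 3) {
  if (min_size < 1) abort("`min_size` must be >= 1.")
  clusters[clusters$size >= min_size, , drop = FALSE]
}

unoise_beta <- function(d, alpha) 1 / 2^(alpha * d + 1)

#' Denoise clusters with the UNOISE abundance-skew rule
#'
#' Greedy centroid pass in decreasing-size order: a cluster of size `s` at
#' edit distance `d >= 1` (Levenshtein) from an already-accepted centroid of
#' size `S` is merged into it when `s / S <= beta(d)` with
#' `beta(d) = 1 / 2^(alpha * d + 1)`; sizes and per-sample counts add to the
#' centroid. All cluster sizes are retained — there is no minimum-size
#' rejection inside this step. With `alpha` large the skew curve forbids all
#' merges and the pass is the identity.
#'
#' @param clusters Cluster tibble.
#' @param alpha Skew steepness (default 2); larger values merge less.
#' @param max_distance Optional cap on the merge distance (default `Inf`).
#' @return Denoised cluster tibble, re-ordered by merged size.
#' @export
#' @examples
#' cl <- tibble::tibble(cluster_id = c("a", "b"),
#'                      sequence = c("ACGTACGT", "ACGTACGA"),
#'                      size = c(100L, 5L),
#'                      sample_counts = list(c(S1 = 100L), c(S1 = 5L)))
#' denoise(cl)$size   # 105: the rare 1-off variant merges into the centroid
denoise <- function(clusters, alpha = 2, max_distance = Inf) {
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (nrow(clusters) <= 1) return(clusters)
  clusters <- clusters[order(-clusters$size, clusters$sequence), , drop = FALSE]
  cen_seq <- character(0)
  cen_size <- numeric(0)        # accumulated size, used for the skew ratio
  cen_counts <- list()
  for (i in seq_len(nrow(clusters))) {
    s <- clusters$size[i]
    merged <- FALSE
    if (length(cen_seq) > 0) {
      d <- as.numeric(adist(clusters$sequence[i], cen_seq))
      ok <- d >= 1 & d <= max_distance & (s / cen_size) <= unoise_beta(d, alpha)
      j <- which(ok)[1]
      if (!is.na(j)) {
        cen_size[j] <- cen_size[j] + s
        add <- clusters$sample_counts[[i]]
        cur <- cen_counts[[j]]
        all_s <- union(names(cur), names(add))
        cen_counts[[j]] <- setNames(
          as.integer(ifelse(is.na(cur[all_s]), 0L, cur[all_s]) +
                     ifelse(is.na(add[all_s]), 0L, add[all_s])), all_s)
        merged <- TRUE
      }
    }
    if (!merged) {
      cen_seq <- c(cen_seq, clusters$sequence[i])
      cen_size <- c(cen_size, s)
      cen_counts <- c(cen_counts, clusters$sample_counts[i])
    }
  }
  order_clusters(tibble(sequence = cen_seq, size = as.integer(cen_size),
                        sample_counts = cen_counts))
}

#' Remove de-novo bimeras (two-parent chimeras)
#'
#' A cluster Q is flagged chimeric and removed iff two distinct, previously
#' accepted clusters P1 and P2 exist, each at least `min_parent_skew` times
#' more abundant than Q, together with a crossover position k
#' (1 <= k < len(Q)) such that Q equals P1's prefix up to k followed by P2's
#' suffix from k+1 (exact matches; Q equals neither parent). Clusters are
#' examined in decreasing-abundance order and only non-flagged clusters can
#' act as parents. Non-flagged clusters pass through unchanged.
#'
#' @param clusters Denoised cluster tibble.
#' @param min_parent_skew Minimum parent/query abundance ratio (default 16).
#' @return Cluster tibble without flagged bimeras.
#' @export
remove_chimeras <- function(clusters, min_parent_skew = 16) {
  if (min_parent_skew < 1) abort("`min_parent_skew` must be >= 1.")
  n <- nrow(clusters)
  if (n < 3) return(clusters)
  ord <- order(-clusters$size, clusters$sequence)
  clusters <- clusters[ord, , drop = FALSE]
  keep <- logical(n)
  accepted <- integer(0)
  for (i in seq_len(n)) {
    q <- clusters$sequence[i]
    Lq <- nchar(q)
    cand <- accepted[clusters$size[accepted] >= min_parent_skew * clusters$size[i]]
    flagged <- FALSE
    if (length(cand) >= 2) {
      ps <- clusters$sequence[cand]
      # longest exact shared prefix / suffix with each candidate parent
      pref <- common_prefix_len(q, ps)
      suff <- common_suffix_len(q, ps)
      # valid crossover needs pref(P1) >= k >= Lq - suff(P2), 1 <= k < Lq
      best_suff <- max(suff)
      ok <- pmin(pref, Lq - 1L) + best_suff >= Lq & pref >= 1L
      # exclude using the same candidate as both parents
      for (a in which(ok)) {
        other <- suff[-a]
        if (length(other) > 0 &&
            pmin(pref[a], Lq - 1L) + max(other) >= Lq && max(other) >= 1L) {
          flagged <- TRUE
          break
        }
      }
    }
    if (!flagged) {
      keep[i] <- TRUE
      accepted <- c(accepted, i)
    }
  }
  clusters[keep, , drop = FALSE]
}

common_prefix_len <- function(q, refs) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  vapply(strsplit(refs, "", fixed = TRUE), function(r) {
    m <- min(length(qc), length(r))
    neq <- which(qc[seq_len(m)] != r[seq_len(m)])
    if (length(neq) == 0) m else neq[1] - 1L
  }, integer(1))
}

common_suffix_len <- function(q, refs) {
  qc <- rev(strsplit(q, "", fixed = TRUE)[[1]])
  vapply(strsplit(refs, "", fixed = TRUE), function(r) {
    r <- rev(r)
    m <- min(length(qc), length(r))
    neq <- which(qc[seq_len(m)] != r[seq_len(m)])
    if (length(neq) == 0) m else neq[1] - 1L
  }, integer(1))
}

#' Write cluster centroids as size-annotated FASTA
#'
#' Records are named `<cluster_id>;size=<n>` in the usual amplicon
#' convention; a per-sample count table can be written alongside.
#'
#' @param clusters Cluster tibble.
#' @param fasta_path Output FASTA path.
#' @param counts_path Optional CSV path for the long per-sample count table.
#' @return Paths, invisibly.
#' @export
write_clusters <- function(clusters, fasta_path, counts_path = NULL) {
  nm <- sprintf("%s;size=%d", clusters$cluster_id, clusters$size)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(clusters$sequence, nm)),
    fasta_path, width = 120L)
  if (!is.null(counts_path)) {
    readr::write_csv(cluster_sample_counts(clusters), counts_path)
  }
  invisible(c(fasta = fasta_path, counts = counts_path))
}

#' Long per-sample count table for a cluster tibble
#'
#' @param clusters Cluster tibble.
#' @return Tibble `cluster_id`, `sample_id`, `reads`.
#' @export
cluster_sample_counts <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(tibble(cluster_id = character(), sample_id = character(),
                  reads = integer()))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(clusters)), function(i) {
    sc <- clusters$sample_counts[[i]]
    tibble(cluster_id = clusters$cluster_id[i],
           sample_id = names(sc), reads = as.integer(sc))
  }))
}
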
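## Profiles are long tibbles: sample_id, taxon, reads (plus optional rank /
## dna_host columns, which every filter passes through untouched).

#' Remove positive controls, unassigned reads and empty samples
#'
#' Deletes rows belonging to configured control taxa and the unassigned
#' bucket; samples left with no taxonomically assignable reads are dropped
#' (reported via a message).
#'
#' @param profiles Profile tibble (`sample_id`, `taxon`, `reads`, ...).
#' @param control_taxa Taxa used as positive controls.
#' @param unassigned_label Label of the unassigned bucket.
#' @return Filtered profile tibble.
#' @export
remove_nontarget <- function(profiles, control_taxa = "Maylandia zebra",
                             unassigned_label = "unassigned") {
  assert_cols(profiles, c("sample_id", "taxon", "reads"))
  before <- unique(profiles$sample_id)
  out <- profiles |>
    filter(!.data$taxon %in% control_taxa,
           .data$taxon != unassigned_label,
           .data$reads > 0)
  dropped <- setdiff(before, unique(out$sample_id))
  if (length(dropped) > 0) {
    inform(sprintf(
      "remove_nontarget: dropped %d sample(s) with no assignable reads: %s",
      length(dropped), paste(dropped, collapse = ", ")))
  }
  out
}

#' Remove low-frequency taxa with a per-sample noise threshold
#'
#' Taxa with fewer reads than `noise_fraction` of that sample's total (taken
#' before this filter) are removed; a count exactly at the threshold is
#' retained. Zero-total samples pass through unchanged.
#'
#' @param profiles Profile tibble.
#' @param noise_fraction Fraction of the per-sample total below which a
#'   taxon's reads count as noise (default 0.001, i.e. 0.1%).
#' @return Filtered profile tibble.
#' @export
apply_noise_threshold <- function(profiles, noise_fraction = 0.001) {
  if (noise_fraction <= 0 || noise_fraction >= 1) {
    abort("`noise_fraction` must lie in (0, 1).")
  }
  profiles |>
    group_by(.data$sample_id) |>
    filter(.data$reads >= noise_fraction * sum(.data$reads)) |>
    ungroup()
}

#' Roll ambiguous species up to a higher taxon
#'
#' Species the marker cannot distinguish reliably (e.g. ducks within
#' Anatidae) are re-labelled to a configured higher taxon and their reads
#' summed per sample.
#'
#' @param profiles Profile tibble.
#' @param ambiguous_groups Named list: replacement taxon name -> character
#'   vector of member species.
#' @param lineage Optional lineage tibble; when given, group members absent
#'   from it raise a configuration error.
#' @return Profile tibble with members merged.
#' @export
#' @examples
#' p <- tibble::tibble(sample_id = "S1",
#'                     taxon = c("Anas platyrhynchos", "Anas crecca"),
#'                     reads = c(30, 20))
#' rollup_ambiguous(p, list(Anatidae = c("Anas platyrhynchos", "Anas crecca")))
rollup_ambiguous <- function(profiles, ambiguous_groups, lineage = NULL) {
  if (length(ambiguous_groups) == 0) return(profiles)
  members <- unlist(ambiguous_groups, use.names = FALSE)
  if (!is.null(lineage)) {
    unknown <- setdiff(members, lineage$species)
    if (length(unknown) > 0) {
      abort(sprintf("ambiguous-group members missing from the lineage table: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  map <- setNames(rep(names(ambiguous_groups),
                      lengths(ambiguous_groups)), members)
  profiles |>
    mutate(taxon = if_else(.data$taxon %in% members,
                           unname(map[.data$taxon]), .data$taxon)) |>
    group_by(across(dplyr::any_of(c("sample_id", "dna_host", "taxon")))) |>
    summarise(reads = sum(.data$reads), .groups = "drop")
}

#' Confirm the depositing host species from read counts
#'
#' The DNA-confirmed host is the candidate host with the largest read count
#' in the sample, provided it reaches `min_host_reads`; otherwise the sample
#' is indeterminate (`dna_host` NA) and should be removed from analysis.
#' Hosts are generally, but not necessarily, the most abundant taxon
#' overall; `dominant` reports whether the chosen host is the per-sample
#' maximum.
#'
#' @param profiles Profile tibble.
#' @param candidate_hosts Candidate host species (default red fox and pine
#'   marten).
#' @param min_host_reads Host-read floor below which a sample is
#'   indeterminate (default 100).
#' @return Tibble: `sample_id`, `dna_host` (NA when indeterminate),
#'   `host_reads`, `dominant`.
#' @export
identify_host <- function(profiles,
                          candidate_hosts = c("Vulpes vulpes", "Martes martes"),
                          min_host_reads = 100) {
  if (length(candidate_hosts) == 0) abort("`candidate_hosts` must be nonempty.")
  universe <- distinct(profiles, .data$sample_id)
  best_cand <- profiles |>
    filter(.data$taxon %in% candidate_hosts) |>
    group_by(.data$sample_id) |>
    arrange(desc(.data$reads), .data$taxon, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("sample_id", dna_host = "taxon", host_reads = "reads")
  max_reads <- profiles |>
    group_by(.data$sample_id) |>
    summarise(max_reads = max(.data$reads), .groups = "drop")
  universe |>
    left_join(best_cand, by = "sample_id") |>
    left_join(max_reads, by = "sample_id") |>
    mutate(host_reads = dplyr::coalesce(.data$host_reads, 0),
           dominant = .data$host_reads >= .data$max_reads,
           dna_host = if_else(.data$host_reads >= min_host_reads,
                              .data$dna_host, NA_character_)) |>
    select("sample_id", "dna_host", "host_reads", "dominant")
}

#' Subtract host and contaminant reads, keeping everything else as diet
#'
#' Removes the confirmed host taxon and contaminant taxa (default: human)
#' from each determinate sample; indeterminate samples are dropped with a
#' message. The *other* candidate predator's DNA is deliberately retained —
#' it is a reported diet/contact item. Samples whose profile is empty after
#' subtraction stay in the returned sample set (they contribute zeros to
#' FOO).
#'
#' @param profiles Profile tibble.
#' @param hosts Host table from [identify_host()].
#' @param contaminant_taxa Contaminant taxa to delete (default human).
#' @return List: `prey` (profile tibble with a `dna_host` column) and
#'   `samples` (retained sample_id + dna_host, the FOO denominator).
#' @export
subtract_host_and_contaminants <- function(profiles, hosts,
                                           contaminant_taxa = "Homo sapiens") {
  indet <- hosts$sample_id[is.na(hosts$dna_host)]
  if (length(indet) > 0) {
    inform(sprintf(
      "subtract_host_and_contaminants: removed %d indeterminate sample(s): %s",
      length(indet), paste(indet, collapse = ", ")))
  }
  samples <- hosts |> filter(!is.na(.data$dna_host)) |>
    select("sample_id", "dna_host")
  prey <- profiles |>
    inner_join(samples, by = "sample_id") |>
    filter(.data$taxon != .data$dna_host,
           !.data$taxon %in% contaminant_taxa)
  list(prey = prey, samples = samples)
}

#' Apply the per-sample minimum read threshold
#'
#' Per-sample per-taxon counts strictly below `min_reads` are removed; a
#' count exactly at the threshold is retained.
#'
#' @param prey Prey profile tibble.
#' @param min_reads Minimum reads per taxon per sample (default 100).
#' @return Filtered prey profile tibble.
#' @export
apply_min_reads <- function(prey, min_reads = 100) {
  if (min_reads < 1) abort("`min_reads` must be >= 1.")
  filter(prey, .data$reads >= min_reads)
}

#' Default prey-group aggregates derived from a lineage table
#'
#' Small mammals are rodents plus shrews and allies (orders Rodentia and
#' Eulipotyphla); birds are class Aves; passerines order Passeriformes.
#' Member lists include the species, genus and family names of qualifying
#' lineages so rolled-up (genus- or family-level) diet labels still match.
#'
#' @param lineage Lineage tibble with the seven rank columns.
#' @return Named list of member-name character vectors.
#' @export
default_taxon_groups <- function(lineage) {
  pick <- function(rows) {
    unique(c(rows$species, rows$genus, rows$family))
  }
  list(
    `small mammals` = pick(lineage[lineage$order %in%
                                     c("Rodentia", "Eulipotyphla"), ]),
    birds = unique(unlist(lineage[lineage$class == "Aves",
                                  c("species", "genus", "family", "order")],
                          use.names = FALSE)),
    passerines = pick(lineage[lineage$order == "Passeriformes", ])
  )
}

group_iter <- function(samples, by) {
  if (identical(by, "combined")) {
    list(combined = samples$sample_id)
  } else {
    split(samples$sample_id, samples$dna_host)
  }
}

#' Percent frequency of occurrence (%FOO)
#'
#' `%FOO(taxon, group) = 100 * (# samples in the group containing the taxon)
#' / (# samples in the group)`. Group aggregates (`taxon_groups`) count a
#' sample once if any member taxon occurs. Samples with an empty prey
#' profile still count in the denominator.
#'
#' @param prey Prey profile tibble (from
#'   [subtract_host_and_contaminants()], after [apply_min_reads()]).
#' @param samples Sample table (`sample_id`, `dna_host`) defining the
#'   denominator.
#' @param by `"predator"` (per DNA-confirmed host) or `"combined"`.
#' @param taxon_groups Optional named list of member-name vectors; each
#'   group is reported as an extra taxon row.
#' @return Tibble: `group`, `taxon`, `n_samples`, `n_present`, `foo`
#'   (percent).
#' @export
foo <- function(prey, samples, by = c("predator", "combined"),
                taxon_groups = NULL) {
  by <- match.arg(by)
  groups <- group_iter(samples, by)
  res <- lapply(names(groups), function(g) {
    sids <- groups[[g]]
    n <- length(sids)
    sub <- prey[prey$sample_id %in% sids & prey$reads > 0, ]
    base <- sub |>
      distinct(.data$sample_id, .data$taxon) |>
      count(.data$taxon, name = "n_present")
    agg <- NULL
    if (length(taxon_groups %||% list()) > 0) {
      agg <- dplyr::bind_rows(lapply(names(taxon_groups), function(tg) {
        tibble(taxon = tg,
               n_present = dplyr::n_distinct(
                 sub$sample_id[sub$taxon %in% taxon_groups[[tg]]]))
      }))
    }
    dplyr::bind_rows(base, agg) |>
      mutate(group = g, n_samples = n,
             foo = if (n > 0) 100 * .data$n_present / n else NA_real_)
  })
  dplyr::bind_rows(res) |>
    select("group", "taxon", "n_samples", "n_present", "foo") |>
    arrange(.data$group, desc(.data$foo), .data$taxon)
}

#' Relative read abundance (RRA)
#'
#' Pooled-reads definition (default): `RRA(taxon, group) = sum of the
#' taxon's reads over the group's samples / sum of all prey reads over the
#' group's samples`; values sum to 1 per group. With `per_sample_mean =
#' TRUE` the per-sample read proportions are averaged instead. Groups with
#' zero prey reads are reported as missing.
#'
#' @inheritParams foo
#' @param per_sample_mean Average per-sample proportions instead of pooling
#'   reads.
#' @return Tibble: `group`, `taxon`, `reads`, `rra` (proportion in `[0,1]`);
#'   `taxon_groups` rows are appended like in [foo()].
#' @export
rra <- function(prey, samples, by = c("predator", "combined"),
                taxon_groups = NULL, per_sample_mean = FALSE) {
  by <- match.arg(by)
  groups <- group_iter(samples, by)
  res <- lapply(names(groups), function(g) {
    sub <- prey[prey$sample_id %in% groups[[g]], ]
    if (nrow(sub) == 0 || sum(sub$reads) == 0) {
      return(tibble(group = g, taxon = NA_character_, reads = 0, rra = NA_real_))
    }
    if (per_sample_mean) {
      per <- sub |>
        group_by(.data$sample_id) |>
        mutate(p = .data$reads / sum(.data$reads)) |>
        ungroup()
      n_s <- dplyr::n_distinct(sub$sample_id)
      base <- per |>
        group_by(.data$taxon) |>
        summarise(reads = sum(.data$reads), rra = sum(.data$p) / n_s,
                  .groups = "drop")
    } else {
      total <- sum(sub$reads)
      base <- sub |>
        group_by(.data$taxon) |>
        summarise(reads = sum(.data$reads), .groups = "drop") |>
        mutate(rra = .data$reads / total)
    }
    agg <- NULL
    if (length(taxon_groups %||% list()) > 0) {
      agg <- dplyr::bind_rows(lapply(names(taxon_groups), function(tg) {
        m <- base[base$taxon %in% taxon_groups[[tg]], ]
        tibble(taxon = tg, reads = sum(m$reads), rra = sum(m$rra))
      }))
    }
    dplyr::bind_rows(base, agg) |> mutate(group = g)
  })
  dplyr::bind_rows(res) |>
    select("group", "taxon", "reads", "rra") |>
    arrange(.data$group, desc(.data$rra), .data$taxon)
}

#' Field-label versus DNA-host confusion
#'
#' Cross-tabulates field identification against the molecular host and
#' reports, per species, the percentage of its scats (by DNA) that were
#' misidentified in the field.
#'
#' @param samples Tibble with `sample_id`, `field_label`, `dna_host`
#'   (determinate samples only).
#' @return List of class `host_confusion`: `table` (long crosstab
#'   `field_label` x `dna_host` with `n`) and `rates` (`species`,
#'   `n_samples`, `n_misidentified`, `misid_pct`).
#' @export
host_confusion <- function(samples) {
  assert_cols(samples, c("sample_id", "field_label", "dna_host"))
  lv <- sort(unique(c(samples$field_label, samples$dna_host)))
  tab <- samples |>
    count(field_label = factor(.data$field_label, lv),
          dna_host = factor(.data$dna_host, lv), .drop = FALSE,
          name = "n") |>
    mutate(field_label = as.character(.data$field_label),
           dna_host = as.character(.data$dna_host))
  rates <- samples |>
    group_by(species = .data$dna_host) |>
    summarise(n_samples = n(),
              n_misidentified = sum(.data$field_label != .data$dna_host),
              .groups = "drop") |>
    mutate(misid_pct = 100 * .data$n_misidentified / .data$n_samples)
  structure(list(table = tab, rates = rates), class = "host_confusion")
}

#' @export
print.host_confusion <- function(x, ...) {
  cat("<host_confusion>\n")
  print(tidyr::pivot_wider(x$table, names_from = "dna_host", values_from = "n"))
  print(x$rates)
  invisible(x)
}

#' Prey richness and woodland:open habitat ratio
#'
#' Per-sample richness is the number of distinct prey taxa detected; group
#' richness the number of distinct prey taxa across a predator's samples.
#' The habitat ratio classifies the distinct prey taxa of each group as
#' woodland or open (taxa classified aquatic/none/unknown are excluded) and
#' normalises to percentages.
#'
#' @inheritParams foo
#' @param habitat Tibble `taxon`, `habitat_class` (woodland / open /
#'   aquatic / none). Prey taxa missing from it are counted as "other" and
#'   reported via a message.
#' @return List: `per_sample` (`sample_id`, `dna_host`, `richness`),
#'   `group_richness` (`group`, `richness`), `habitat_ratio` (`group`,
#'   `n_woodland`, `n_open`, `pct_woodland`, `pct_open`).
#' @export
richness_and_habitat <- function(prey, samples, habitat,
                                 by = c("predator", "combined")) {
  by <- match.arg(by)
  per_sample <- samples |>
    left_join(prey |> filter(.data$reads > 0) |>
                distinct(.data$sample_id, .data$taxon) |>
                count(.data$sample_id, name = "richness"),
              by = "sample_id") |>
    mutate(richness = dplyr::coalesce(.data$richness, 0L))
  groups <- group_iter(samples, by)
  group_richness <- dplyr::bind_rows(lapply(names(groups), function(g) {
    tibble(group = g,
           richness = dplyr::n_distinct(
             prey$taxon[prey$sample_id %in% groups[[g]] & prey$reads > 0]))
  }))
  unknown <- setdiff(unique(prey$taxon), habitat$taxon)
  if (length(unknown) > 0) {
    inform(sprintf("richness_and_habitat: %d taxa without habitat class counted as 'other': %s",
                   length(unknown), paste(unknown, collapse = ", ")))
  }
  habitat_ratio <- dplyr::bind_rows(lapply(names(groups), function(g) {
    taxa <- unique(prey$taxon[prey$sample_id %in% groups[[g]] & prey$reads > 0])
    cls <- habitat$habitat_class[match(taxa, habitat$taxon)]
    nw <- sum(cls == "woodland", na.rm = TRUE)
    no <- sum(cls == "open", na.rm = TRUE)
    tibble(group = g, n_woodland = nw, n_open = no,
           pct_woodland = if (nw + no > 0) 100 * nw / (nw + no) else NA_real_,
           pct_open = if (nw + no > 0) 100 * no / (nw + no) else NA_real_)
  }))
  list(per_sample = per_sample, group_richness = group_richness,
       habitat_ratio = habitat_ratio)
}
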
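#' Summarise predator diet from filtered prey profiles
#'
#' Bundles the headline outputs — %FOO and RRA per predator and combined,
#' the field-vs-DNA host confusion, per-sample and per-group prey richness,
#' and the woodland:open habitat ratio — into one object with [tidy()],
#' [glance()] and [ggplot2::autoplot()] methods.
#'
#' @param prey Filtered prey profile tibble.
#' @param samples Sample table (`sample_id`, `dna_host`).
#' @param manifest Manifest tibble with `sample_id` and `field_label` (for
#'   the confusion matrix); optional.
#' @param habitat Habitat table (`taxon`, `habitat_class`); optional.
#' @param taxon_groups Named list of group-aggregate member vectors
#'   (see [default_taxon_groups()]); optional.
#' @return Object of class `diet_summary`.
#' @export
summarize_diet <- function(prey, samples, manifest = NULL, habitat = NULL,
                           taxon_groups = NULL) {
  foo_pred <- foo(prey, samples, by = "predator", taxon_groups = taxon_groups)
  foo_comb <- foo(prey, samples, by = "combined", taxon_groups = taxon_groups)
  rra_pred <- rra(prey, samples, by = "predator", taxon_groups = taxon_groups)
  rra_comb <- rra(prey, samples, by = "combined", taxon_groups = taxon_groups)
  confusion <- NULL
  if (!is.null(manifest)) {
    lab <- samples |>
      inner_join(manifest[, c("sample_id", "field_label")], by = "sample_id")
    confusion <- host_confusion(lab)
  }
  rich <- NULL
  if (!is.null(habitat)) {
    rich <- suppressMessages(richness_and_habitat(prey, samples, habitat))
  } else {
    rich <- richness_and_habitat(prey, samples,
                                 tibble(taxon = character(),
                                        habitat_class = character()))
  }
  structure(list(
    foo = dplyr::bind_rows(foo_pred, foo_comb),
    rra = dplyr::bind_rows(rra_pred, rra_comb),
    confusion = confusion,
    richness = rich$per_sample,
    group_richness = rich$group_richness,
    habitat_ratio = rich$habitat_ratio,
    samples = samples
  ), class = "diet_summary")
}

#' @export
print.diet_summary <- function(x, ...) {
  cat(sprintf("<diet_summary> %d samples, %d prey taxa\n",
              nrow(x$samples),
              dplyr::n_distinct(x$foo$taxon[x$foo$n_present > 0])))
  cat("Top taxa by combined %FOO:\n")
  print(head(x$foo[x$foo$group == "combined", ], 8))
  invisible(x)
}

#' Tidy a diet summary into one long table
#'
#' @param x A `diet_summary`.
#' @param ... Unused.
#' @return Tibble `group`, `taxon`, `statistic` (`foo` in percent, `rra` as
#'   a proportion), `value`.
#' @method tidy diet_summary
#' @export
tidy.diet_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$foo |> select("group", "taxon", value = "foo") |>
      mutate(statistic = "foo"),
    x$rra |> select("group", "taxon", value = "rra") |>
      mutate(statistic = "rra")
  ) |>
    relocate("group", "taxon", "statistic", "value")
}

#' One-row overview of a diet summary
#'
#' @inheritParams tidy.diet_summary
#' @return One-row tibble: sample count, number of prey taxa, mean
#'   per-sample richness, and overall field-misidentification percent (NA
#'   when no manifest was supplied).
#' @method glance diet_summary
#' @export
glance.diet_summary <- function(x, ...) {
  misid <- NA_real_
  if (!is.null(x$confusion)) {
    r <- x$confusion$rates
    misid <- 100 * sum(r$n_misidentified) / sum(r$n_samples)
  }
  tibble(n_samples = nrow(x$samples),
         n_prey_taxa = dplyr::n_distinct(x$foo$taxon[x$foo$n_present > 0]),
         mean_richness = mean(x$richness$richness),
         misid_pct = misid)
}

#' Plot a diet summary
#'
#' `type = "foo"` draws per-predator %FOO as a dot plot; `type = "rra"`
#' stacked relative read abundances per predator; `type = "richness"`
#' per-sample prey richness by predator.
#'
#' @param object A `diet_summary`.
#' @param type One of `"foo"`, `"rra"`, `"richness"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diet_summary
#' @export
autoplot.diet_summary <- function(object, type = c("foo", "rra", "richness"),
                                  ...) {
  type <- match.arg(type)
  if (type == "foo") {
    d <- object$foo |> filter(.data$group != "combined", .data$n_present > 0)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$foo,
                                    y = stats::reorder(.data$taxon, .data$foo),
                                    colour = .data$group)) +
      ggplot2::geom_point(size = 2.5) +
      ggplot2::labs(x = "%FOO", y = NULL, colour = "Predator (DNA host)") +
      ggplot2::theme_minimal()
  } else if (type == "rra") {
    d <- object$rra |> filter(.data$group != "combined", .data$rra > 0)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$rra,
                                    fill = .data$taxon)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::labs(x = NULL, y = "Relative read abundance", fill = "Taxon") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$richness,
                    ggplot2::aes(x = .data$dna_host, y = .data$richness)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "Predator (DNA host)", y = "Prey richness per scat") +
      ggplot2::theme_minimal()
  }
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot
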
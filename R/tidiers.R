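#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' One row per (species, feature) test with estimates, the Welch t
#' statistic, raw and BH-adjusted p-values and the significance flag.
#'
#' @param x An `xci_enrichment` from [test_enrichment()].
#' @param ... Unused.
#' @method tidy xci_enrichment
#' @export
tidy.xci_enrichment <- function(x, ...) {
  as_tibble(x) |>
    mutate(estimate = .data$mean_escape - .data$mean_subject) |>
    select(
      "species", "feature", "estimate", "mean_escape", "mean_subject",
      "n_escape", "n_subject", statistic = "t_stat", p.value = "p",
      "p_adj", "significant", "untestable"
    )
}

#' @describeIn tidy.xci_enrichment One-row summary: tests run, testable
#'   tests, significant tests at the configured cutoff.
#' @method glance xci_enrichment
#' @export
glance.xci_enrichment <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_testable = sum(!x$untestable),
    n_significant = sum(x$significant, na.rm = TRUE),
    p_adj_cut = attr(x, "p_adj_cut") %||% 0.01
  )
}

#' Tidy a species clustering
#'
#' The merge-height table: one row per agglomeration step with the
#' complete-linkage height and the member species of the merged cluster.
#'
#' @param x An `xci_tree` from [cluster_species()].
#' @param ... Unused.
#' @method tidy xci_tree
#' @export
tidy.xci_tree <- function(x, ...) {
  x$merges
}

#' @describeIn tidy.xci_tree One-row summary: leaf count and tree height.
#' @method glance xci_tree
#' @export
glance.xci_tree <- function(x, ...) {
  tibble(
    n_species = length(x$labels),
    height = max(x$hclust$height),
    newick = x$newick
  )
}

#' Tidy a call table
#'
#' Call tables are already tibbles; `tidy()` returns them unclassed, and
#' `glance()` summarises the status composition.
#'
#' @param x An `xci_calls` tibble.
#' @param ... Unused.
#' @method tidy xci_calls
#' @export
tidy.xci_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "xci_calls")
  out
}

#' @describeIn tidy.xci_calls Status counts and fractions for one call
#'   table.
#' @method glance xci_calls
#' @export
glance.xci_calls <- function(x, ...) {
  called <- x$status != "no_call"
  tibble(
    n_genes = nrow(x),
    n_called = sum(called),
    fraction_escape = mean(x$status[called] == "escape"),
    fraction_variable = mean(x$status[called] == "variable_escape"),
    fraction_subject = mean(x$status[called] == "subject")
  )
}
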
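#' Merge per-dataset call tables into a gene x dataset status matrix
#'
#' Genes are matched across datasets by symbol, controlling only for
#' capitalisation changes across species (`Kdm6a` and `KDM6A` share a
#' row); the first-seen spelling is preserved as the display name.  Calls
#' absent from a dataset are missing (`NA`), distinct from an explicit
#' `no_call`.  The same gene appearing twice within one dataset is
#' deduplicated when statuses agree and is an error when they conflict.
#'
#' @param ... Call-table tibbles (see [write_call_table()]), or a single
#'   list of them.
#'
#' @return A wide tibble with columns `gene`, `gene_key` and one status
#'   column per dataset, carrying a `"datasets"` attribute mapping dataset
#'   to species.
#' @export
merge_calls <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  long <- bind_rows(tabs)
  check_status(long$status)
  long <- long |>
    mutate(gene_key = toupper(.data$gene)) |>
    distinct(.data$gene_key, .data$dataset, .data$status, .keep_all = TRUE)
  dup <- long |>
    count(.data$gene_key, .data$dataset) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "conflicting statuses for gene ", dup$gene_key[1],
      " in dataset ", dup$dataset[1]
    ))
  }
  dataset_map <- long |> distinct(.data$dataset, .data$species)
  names_map <- long |>
    distinct(.data$gene_key, .keep_all = TRUE) |>
    select("gene_key", "gene")
  out <- long |>
    select("gene_key", "dataset", "status") |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "status") |>
    left_join(names_map, by = "gene_key") |>
    relocate("gene", "gene_key") |>
    arrange(.data$gene_key)
  attr(out, "datasets") <- dataset_map
  out
}

#' Define a species group for conservation analysis
#'
#' Conservation is assessed within groups of datasets (e.g. primates on
#' one platform versus all mammals) so that over-represented clades do not
#' bias the result.  When a species contributes several datasets, the
#' first dataset in `datasets` order with a call for a given gene is used,
#' so the vector doubles as the priority list.
#'
#' @param name Group label.
#' @param datasets Character vector of dataset identifiers in priority
#'   order.
#'
#' @return An `xci_group` list.
#' @export
xci_group <- function(name, datasets) {
  stopifnot(is.character(datasets), length(datasets) > 0)
  structure(list(name = name, datasets = datasets), class = "xci_group")
}

# one status per species for one group: first non-missing dataset by priority
select_group_statuses <- function(matrix, group) {
  dataset_map <- attr(matrix, "datasets")
  if (is.null(dataset_map)) abort("matrix lacks its dataset-to-species map")
  missing_ds <- setdiff(group$datasets, dataset_map$dataset)
  if (length(missing_ds) > 0) {
    abort(paste0(
      "group '", group$name, "' names unknown dataset(s): ",
      paste(missing_ds, collapse = ", ")
    ))
  }
  ds <- group$datasets
  sp <- dataset_map$species[match(ds, dataset_map$dataset)]
  long <- matrix |>
    select("gene", "gene_key", all_of(ds)) |>
    tidyr::pivot_longer(all_of(ds), names_to = "dataset", values_to = "status") |>
    mutate(
      species = sp[match(.data$dataset, ds)],
      priority = match(.data$dataset, ds)
    ) |>
    filter(!is.na(.data$status)) |>
    arrange(.data$gene_key, .data$species, .data$priority) |>
    distinct(.data$gene_key, .data$species, .keep_all = TRUE)
  long
}

#' Classify cross-species conservation of XCI status
#'
#' Within one species group, each gene's statuses across species fall into
#' one category: `insufficient` (fewer than `min_species` informative
#' species — explicit `no_call`s are not informative), `conserved_escape`
#' / `conserved_subject` (every informative species agrees), and the
#' discordance categories: `discordant_multi` when at least two species
#' escape and at least two are subject (the frequent-discordance rule),
#' `discordant_single` when exactly one species holds the minority status,
#' and `mixed_variable` otherwise (variable-escape cells count a species
#' as informative but as neither escape nor subject).
#'
#' @param matrix Merged matrix from [merge_calls()].
#' @param group An [xci_group()].
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for
#'   defaults (`min_species = 4`).
#'
#' @return A tibble with one row per gene: `gene`, `gene_key`,
#'   `n_informative_species`, `n_escape`, `n_subject`, `n_variable`,
#'   `category`.
#' @export
classify_conservation <- function(matrix, group, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  long <- select_group_statuses(matrix, group) |>
    filter(.data$status != "no_call")
  counts <- long |>
    summarise(
      n_informative_species = dplyr::n(),
      n_escape = sum(.data$status == "escape"),
      n_subject = sum(.data$status == "subject"),
      n_variable = sum(.data$status == "variable_escape"),
      .by = c("gene", "gene_key")
    )
  # genes with calls in no dataset of the group still get a row
  all_genes <- matrix |> select("gene", "gene_key")
  counts <- all_genes |>
    left_join(counts, by = c("gene", "gene_key")) |>
    mutate(across(
      c("n_informative_species", "n_escape", "n_subject", "n_variable"),
      ~ as.integer(tidyr::replace_na(.x, 0L))
    ))
  counts |>
    mutate(category = case_when(
      .data$n_informative_species < th$min_species ~ "insufficient",
      .data$n_escape == .data$n_informative_species ~ "conserved_escape",
      .data$n_subject == .data$n_informative_species ~ "conserved_subject",
      .data$n_escape >= 2 & .data$n_subject >= 2 ~ "discordant_multi",
      pmin(.data$n_escape, .data$n_subject) == 1 ~ "discordant_single",
      .default = "mixed_variable"
    ))
}

#' Summarise conservation within a species group
#'
#' Over genes informative in at least `min_species` species of the group,
#' reports the fraction with completely conserved XCI status, the count
#' per category, and conservation split by usual status: among genes
#' usually subject (more than `usual_frac` of informative species subject)
#' the fraction with every informative species subject, and the mirrored
#' quantity for genes usually escaping.
#'
#' @inheritParams classify_conservation
#' @param usual_frac Fraction of informative species defining the "usual"
#'   status of a gene (default 0.75).
#'
#' @return A one-row tibble: `group`, `n_genes`, `fraction_conserved`,
#'   `fraction_usual_subject_conserved`, `fraction_usual_escape_conserved`,
#'   plus one `n_<category>` count column per category.
#' @export
summarize_conservation <- function(matrix, group, thresholds = NULL,
                                   usual_frac = 0.75) {
  th <- as_thresholds(thresholds)
  cls <- classify_conservation(matrix, group, th)
  informative <- filter(cls, .data$category != "insufficient")
  if (nrow(informative) == 0) {
    abort(paste0("group '", group$name, "' has no gene informative in ",
                 th$min_species, "+ species"))
  }
  usual_subject <- filter(
    informative, .data$n_subject > usual_frac * .data$n_informative_species
  )
  usual_escape <- filter(
    informative, .data$n_escape > usual_frac * .data$n_informative_species
  )
  counts <- informative |>
    count(.data$category) |>
    tidyr::pivot_wider(
      names_from = "category", values_from = "n", names_prefix = "n_"
    )
  tibble(
    group = group$name,
    n_genes = nrow(informative),
    fraction_conserved = mean(informative$category %in%
      c("conserved_escape", "conserved_subject")),
    fraction_usual_subject_conserved = if (nrow(usual_subject) > 0) {
      mean(usual_subject$category == "conserved_subject")
    } else {
      NA_real_
    },
    fraction_usual_escape_conserved = if (nrow(usual_escape) > 0) {
      mean(usual_escape$category == "conserved_escape")
    } else {
      NA_real_
    }
  ) |>
    bind_cols(counts)
}

#' Consensus status per gene within a group
#'
#' Collapses each gene's informative statuses to the escape-ish
#' (escape or variable escape) versus subject dichotomy used for domain
#' and transition analysis, and takes the majority across informative
#' species; ties and uninformative genes yield `NA`.
#'
#' @inheritParams classify_conservation
#'
#' @return Tibble `gene`, `gene_key`, `consensus` in
#'   `{"escape_ish", "subject", NA}`.
#' @export
consensus_status <- function(matrix, group, thresholds = NULL) {
  long <- select_group_statuses(matrix, group) |>
    filter(.data$status != "no_call") |>
    mutate(collapsed = ifelse(.data$status == "subject", "subject", "escape_ish"))
  cons <- long |>
    summarise(
      n_esc = sum(.data$collapsed == "escape_ish"),
      n_sub = sum(.data$collapsed == "subject"),
      .by = c("gene", "gene_key")
    ) |>
    mutate(consensus = case_when(
      .data$n_esc > .data$n_sub ~ "escape_ish",
      .data$n_sub > .data$n_esc ~ "subject",
      .default = NA_character_
    )) |>
    select("gene", "gene_key", "consensus")
  matrix |>
    select("gene", "gene_key") |>
    left_join(cons, by = c("gene", "gene_key"))
}

#' Detect XCI status transitions along the chromosome
#'
#' Orders genes by reference coordinate, collapses statuses to escape-ish
#' versus subject, skips genes without a consensus, and emits one
#' transition per adjacent pair with differing collapsed status.  A
#' transition is near a TAD boundary when a boundary (a TAD start or end)
#' lies between the two genes or within either gene body.
#'
#' @param genes Tibble with `gene`, `chrom`, `start`, `end` (gene body,
#'   0-based half-open) and `consensus` (from [consensus_status()], joined
#'   on by the caller) in `{"escape_ish", "subject", NA}`.
#' @param tads Tibble of TAD intervals (`chrom`, `start`, `end`); their
#'   start and end coordinates are the boundaries.  `NULL` to skip the TAD
#'   annotation (`near_tad` all `NA`).
#'
#' @return Tibble with one row per transition: `chrom`, `left_gene`,
#'   `right_gene`, `boundary_start`, `boundary_end` (the span from the
#'   start of the left gene to the end of the right gene), `left_block`,
#'   `right_block`, `near_tad`.
#' @export
detect_transitions <- function(genes, tads = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "end", "consensus") %in% names(genes)))
  called <- genes |>
    filter(!is.na(.data$consensus)) |>
    arrange(.data$chrom, .data$start)
  if (nrow(called) < 2) {
    return(tibble(
      chrom = character(), left_gene = character(), right_gene = character(),
      boundary_start = integer(), boundary_end = integer(),
      left_block = character(), right_block = character(), near_tad = logical()
    ))
  }
  boundaries <- if (!is.null(tads)) {
    tibble(chrom = rep(tads$chrom, 2), pos = c(tads$start, tads$end))
  } else {
    NULL
  }
  left <- called[-nrow(called), ]
  right <- called[-1, ]
  keep <- left$chrom == right$chrom & left$consensus != right$consensus
  out <- tibble(
    chrom = left$chrom[keep],
    left_gene = left$gene[keep],
    right_gene = right$gene[keep],
    boundary_start = left$start[keep],
    boundary_end = right$end[keep],
    left_block = left$consensus[keep],
    right_block = right$consensus[keep]
  )
  out$near_tad <- if (is.null(boundaries)) {
    rep(NA, nrow(out))
  } else {
    purrr::pmap_lgl(
      out[, c("chrom", "boundary_start", "boundary_end")],
      function(chrom, boundary_start, boundary_end) {
        any(boundaries$chrom == chrom &
          boundaries$pos >= boundary_start &
          boundaries$pos <= boundary_end)
      }
    )
  }
  out
}

#' Find clustered discordant genes
#'
#' Genes whose XCI status changes in several species tend to cluster into
#' domains.  Over the informative genes ordered by reference coordinate
#' (insufficient genes dropped), this reports every maximal run of at
#' least `min_genes` consecutive genes classified `discordant_multi`.
#'
#' @param categories Output of [classify_conservation()] joined to gene
#'   coordinates (`chrom`, `start`, `end`).
#' @param min_genes Minimum run length to report (default 2).
#'
#' @return Tibble with one row per domain: `domain`, `chrom`, `start`,
#'   `end`, `n_genes`, `genes` (comma-separated members).
#' @export
find_discordant_domains <- function(categories, min_genes = 2L) {
  need <- c("gene", "chrom", "start", "end", "category")
  stopifnot(all(need %in% names(categories)))
  informative <- categories |>
    filter(.data$category != "insufficient") |>
    arrange(.data$chrom, .data$start)
  empty <- tibble(
    domain = integer(), chrom = character(), start = integer(),
    end = integer(), n_genes = integer(), genes = character()
  )
  if (nrow(informative) == 0) return(empty)
  is_disc <- informative$category == "discordant_multi"
  # new run whenever the discordance flag flips or the chromosome changes
  run_id <- cumsum(c(TRUE, diff(as.integer(is_disc)) != 0 |
    informative$chrom[-1] != informative$chrom[-nrow(informative)]))
  informative |>
    mutate(run = run_id, disc = is_disc) |>
    filter(.data$disc) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_genes = dplyr::n(),
      genes = paste(.data$gene, collapse = ","),
      .by = "run"
    ) |>
    filter(.data$n_genes >= min_genes) |>
    mutate(domain = dplyr::row_number()) |>
    select("domain", "chrom", "start", "end", "n_genes", "genes")
}
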
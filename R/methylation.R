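#' Mean CpG-island methylation per sample
#'
#' Computes, for every island x sample pair, the unweighted mean of the
#' per-site methylation fractions whose position falls inside the island
#' (`[start, end)`, so a site exactly at the end coordinate is excluded).
#' Islands with no overlapping site in a sample are uninformative for that
#' sample and are simply absent from the result.
#'
#' @param sites Methylation track tibble with columns `chrom`, `start`
#'   (0-based site position), `meth` (fraction in `[0, 1]`), `sample`, and
#'   optionally `sex` and `coverage`.
#' @param islands CpG-island tibble with columns `chrom`, `start`, `end`,
#'   `name` (e.g. from [read_intervals()]).
#' @param min_sites Minimum contributing sites per island per sample; pairs
#'   below this are dropped (relevant for sparse RRBS tracks).
#'
#' @return A tibble with columns `island`, `sample`, (`sex` if supplied),
#'   `mean_meth`, `n_sites`.
#' @export
island_methylation <- function(sites, islands, min_sites = 1L) {
  need <- c("chrom", "start", "meth", "sample")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("sites lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  hits <- overlap_pairs(
    sites$chrom, sites$start, sites$start + 1L,
    islands$chrom, islands$start, islands$end
  )
  if (nrow(hits) == 0) {
    out <- tibble(
      island = character(), sample = character(),
      mean_meth = double(), n_sites = integer()
    )
    if ("sex" %in% names(sites)) out$sex <- character()
    return(out)
  }
  joined <- sites[hits$q, intersect(c("sample", "sex", "meth"), names(sites))]
  joined$island <- islands$name[hits$s]
  grp <- intersect(c("island", "sample", "sex"), names(joined))
  joined |>
    summarise(
      mean_meth = mean(.data$meth),
      n_sites = dplyr::n(),
      .by = all_of(grp)
    ) |>
    filter(.data$n_sites >= min_sites)
}

#' Annotate CpG islands to transcription start sites
#'
#' Links each TSS to the single closest island whose nearest edge lies
#' within `window` bp of the TSS position (distance 0 when the TSS falls
#' inside the island).  TSSs with no island in range are unlinked and
#' absent from the result.  Distinct TSSs of one gene may link to distinct
#' islands, so genes with alternative promoters can carry more than one
#' link.
#'
#' @param islands Island tibble (`chrom`, `start`, `end`, `name`).
#' @param tss TSS tibble with columns `gene`, `transcript_id`, `chrom`,
#'   `position` (0-based), `strand`.
#' @param window Maximum TSS-to-island-edge distance in bp (default 2 kb).
#'
#' @return A tibble with one row per linked TSS: `gene`, `transcript_id`,
#'   `chrom`, `position`, `strand`, `island`, `island_start`, `island_end`,
#'   `distance`.
#' @export
match_island_to_tss <- function(islands, tss, window = 2000L) {
  stopifnot(all(c("gene", "chrom", "position") %in% names(tss)))
  if (!"transcript_id" %in% names(tss)) tss$transcript_id <- tss$gene
  if (!"strand" %in% names(tss)) tss$strand <- "+"
  rows <- purrr::pmap(
    list(
      tss$gene, tss$transcript_id, tss$chrom, tss$position, tss$strand
    ),
    function(gene, txid, chrom, position, strand) {
      same <- islands[islands$chrom == chrom, , drop = FALSE]
      if (nrow(same) == 0) return(NULL)
      # distance to nearest edge of the half-open interval; 0 inside
      d <- pmax(same$start - position, position - (same$end - 1L), 0L)
      in_range <- which(d <= window)
      if (length(in_range) == 0) return(NULL)
      best <- in_range[which.min(d[in_range])]
      tibble(
        gene = gene, transcript_id = txid, chrom = chrom,
        position = position, strand = strand,
        island = same$name[best],
        island_start = same$start[best], island_end = same$end[best],
        distance = as.integer(d[best])
      )
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      gene = character(), transcript_id = character(), chrom = character(),
      position = integer(), strand = character(), island = character(),
      island_start = integer(), island_end = integer(), distance = integer()
    )
  }
  out
}

#' Mean island methylation from 450k-style probe betas
#'
#' Averages the beta values of promoter-associated probes sharing an
#' annotated CpG island, per sample, excluding missing betas (never
#' imputing them).  Islands with no informative promoter probe for a
#' sample are absent from the result.
#'
#' @param probes Long probe tibble from [read_probe_table()], optionally
#'   with a `sex` column joined on.
#' @param min_sites Minimum contributing probes per island per sample.
#'
#' @return As [island_methylation()]: `island`, `sample`, (`sex`),
#'   `mean_meth`, `n_sites`.
#' @export
probe_island_methylation <- function(probes, min_sites = 1L) {
  grp <- intersect(c("island", "sample", "sex"), names(probes))
  probes |>
    filter(.data$promoter, !is.na(.data$island), nzchar(.data$island),
           !is.na(.data$beta)) |>
    summarise(
      mean_meth = mean(.data$beta),
      n_sites = dplyr::n(),
      .by = all_of(grp)
    ) |>
    filter(.data$n_sites >= min_sites)
}

#' Filter islands hypermethylated in males
#'
#' Promoter islands on the X should be unmethylated in males; an island
#' methylated on the active X can never be seen to escape by methylation,
#' so islands for which more than `male_frac` of informative males have a
#' mean at or above `male_meth_cut` (15% by default) are discarded as
#' uninformative.  With no male data the filter cannot run; all islands
#' are kept and flagged (`male_filter_applied = FALSE`).
#'
#' @param island_meths Output of [island_methylation()] or
#'   [probe_island_methylation()] including a `sex` column (`"M"`/`"F"`).
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for defaults.
#'
#' @return A tibble with one row per island: `island`, `n_males`,
#'   `fraction_hypermeth_males`, `keep`, `male_filter_applied`.
#' @export
male_hypermethylation_filter <- function(island_meths, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  males <- filter(island_meths, .data$sex == "M")
  all_islands <- unique(island_meths$island)
  if (nrow(males) == 0) {
    return(tibble(
      island = all_islands, n_males = 0L,
      fraction_hypermeth_males = NA_real_,
      keep = TRUE, male_filter_applied = FALSE
    ))
  }
  verdict <- males |>
    summarise(
      n_males = dplyr::n(),
      fraction_hypermeth_males = mean(.data$mean_meth >= th$male_meth_cut),
      .by = "island"
    ) |>
    mutate(
      keep = .data$fraction_hypermeth_males <= th$male_frac, # strict > discards
      male_filter_applied = TRUE
    )
  # islands informative only in females never had male evidence against them
  no_male <- setdiff(all_islands, verdict$island)
  if (length(no_male) > 0) {
    verdict <- bind_rows(verdict, tibble(
      island = no_male, n_males = 0L,
      fraction_hypermeth_males = NA_real_,
      keep = TRUE, male_filter_applied = FALSE
    ))
  }
  verdict
}

#' Classify one female island methylation level
#'
#' Total function partitioning `[0, 1]` into the four methylation classes:
#' below 10% escape, 10-15% uncallable (a buffer zone lowering the chance
#' of miscalls), 15-60% subject, above 60% hypermethylated.
#'
#' @param mean_meth Numeric vector of island mean methylation fractions.
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for defaults.
#'
#' @return Character vector in
#'   `{"escape", "uncallable", "subject", "hypermethylated"}`.
#' @examples
#' classify_island_methylation(c(0.05, 0.12, 0.38, 0.7))
#' @export
classify_island_methylation <- function(mean_meth, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  stopifnot(all(mean_meth >= 0 & mean_meth <= 1, na.rm = TRUE))
  case_when(
    mean_meth < th$meth_escape_max ~ "escape",
    mean_meth < th$meth_subject_min ~ "uncallable",
    mean_meth <= th$meth_subject_max ~ "subject",
    .default = "hypermethylated"
  )
}

#' Gene-level XCI calls from promoter island methylation
#'
#' Runs the full methylation calling path: apply the male filter, classify
#' each female sample's island mean, and aggregate to genes through the
#' island-TSS links.  Informative samples are those classified escape or
#' subject (uncallable and hypermethylated samples carry no status); with
#' `f` the escape fraction among informative samples, a gene is
#' `variable_escape` when `min(f, 1 - f) >= variable_frac`, otherwise the
#' majority status.  Genes whose island has no informative sample are
#' `no_call` with reason `all_uncallable`, `hypermethylated` or
#' `male_hypermethylated` (island discarded by the male filter).  When a
#' gene's TSSs link to several islands, the island informative in the most
#' samples (ties: smallest TSS distance, then name) provides the gene
#' call; per-island calls are attached as the `"islands"` attribute.
#'
#' @param island_meths Island x sample means with `sex`, from
#'   [island_methylation()] or [probe_island_methylation()].
#' @param links Island-TSS links from [match_island_to_tss()].
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for defaults.
#' @param species,dataset Labels stamped on the output call table.
#'
#' @return A call-table tibble (one row per gene) with attribute
#'   `"islands"` holding the per-(gene, island) calls.
#' @export
call_genes_methylation <- function(island_meths, links, thresholds = NULL,
                                   species = "unknown", dataset = "meth") {
  th <- as_thresholds(thresholds)
  verdict <- male_hypermethylation_filter(island_meths, th)

  females <- island_meths |>
    filter(.data$sex == "F") |>
    mutate(class = classify_island_methylation(.data$mean_meth, th))

  link_tab <- links |>
    distinct(.data$gene, .data$island, .data$distance) |>
    summarise(distance = min(.data$distance), .by = c("gene", "island"))

  per_island <- link_tab |>
    inner_join(verdict, by = "island") |>
    left_join(
      females |>
        summarise(
          n_informative = sum(.data$class %in% c("escape", "subject")),
          n_escape = sum(.data$class == "escape"),
          n_uncallable = sum(.data$class == "uncallable"),
          n_hyper = sum(.data$class == "hypermethylated"),
          n_samples = dplyr::n(),
          .by = "island"
        ),
      by = "island"
    ) |>
    mutate(across(
      c("n_informative", "n_escape", "n_uncallable", "n_hyper", "n_samples"),
      ~ tidyr::replace_na(.x, 0L)
    )) |>
    mutate(
      fraction_escape = ifelse(.data$n_informative > 0,
        .data$n_escape / .data$n_informative, NA_real_
      ),
      fraction_subject = 1 - .data$fraction_escape,
      status = case_when(
        !.data$keep ~ "no_call",
        .data$n_informative == 0 ~ "no_call",
        pmin(.data$fraction_escape, .data$fraction_subject) >= th$variable_frac ~
          "variable_escape",
        .data$fraction_escape > 0.5 ~ "escape",
        .default = "subject"
      ),
      reason = case_when(
        !.data$keep ~ "male_hypermethylated",
        .data$status != "no_call" ~ NA_character_,
        .data$n_hyper >= .data$n_uncallable & .data$n_hyper > 0 ~ "hypermethylated",
        .data$n_uncallable > 0 ~ "all_uncallable",
        .default = "no_informative_samples"
      ),
      n_informative = as.integer(.data$n_informative)
    )

  gene_calls <- per_island |>
    arrange(
      .data$gene, desc(.data$n_informative), .data$distance, .data$island
    ) |>
    distinct(.data$gene, .keep_all = TRUE) |>
    mutate(species = species, dataset = dataset) |>
    select(all_of(call_table_cols)) |>
    arrange(.data$gene) |>
    new_xci_calls()
  attr(gene_calls, "islands") <- per_island
  gene_calls
}

#' Per-island methylation means by sex
#'
#' The female-versus-male view of island methylation that underlies
#' threshold diagnostics: per island, the unweighted mean of informative
#' sample means within each sex (missing when a sex has no data).
#'
#' @param island_meths Island x sample means including `sex`.
#'
#' @return A tibble with columns `island`, `female_mean`, `male_mean`,
#'   `n_female`, `n_male`.
#' @export
sex_mean_comparison <- function(island_meths) {
  island_meths |>
    summarise(
      female_mean = ifelse(any(.data$sex == "F"),
        mean(.data$mean_meth[.data$sex == "F"]), NA_real_
      ),
      male_mean = ifelse(any(.data$sex == "M"),
        mean(.data$mean_meth[.data$sex == "M"]), NA_real_
      ),
      n_female = sum(.data$sex == "F"),
      n_male = sum(.data$sex == "M"),
      .by = "island"
    )
}
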
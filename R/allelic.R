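#' Clopper-Pearson confidence interval for a binomial proportion
#'
#' Exact two-sided interval from the beta quantiles of the binomial tails,
#' vectorised over observations.  Used on the Xi-read fraction
#' `p = xi / (xi + xa)`; exact coverage matters because Xi read counts at
#' silenced genes are very small.
#'
#' @param x Number of successes (Xi reads).
#' @param n Number of trials (total reads).
#' @param alpha Two-sided test size; the interval has level `1 - alpha`.
#'
#' @return A tibble with columns `ci_low` and `ci_high`.
#' @examples
#' clopper_pearson(2, 100)
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  stopifnot(all(x >= 0), all(n >= x))
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble(ci_low = lo, ci_high = hi)
}

#' Call XCI status per SNP from Xi/Xa read counts
#'
#' Tests each SNP's Xi-read fraction against the escape threshold with an
#' exact binomial model: a gene on the inactive X is called escaping when
#' its Xi/Xa expression ratio is significantly over `tau_ratio` (default
#' 0.1) and subject when significantly under.  On the read-fraction scale
#' the ratio threshold maps to `p0 = tau / (1 + tau)` (0.1/1.1 for the
#' default), and the two-sided `1 - alpha` Clopper-Pearson interval for
#' `xi / (xi + xa)` decides the call: `ci_low > p0` is escape, `ci_high <
#' p0` is subject, and SNPs whose interval crosses the threshold get no
#' call.  SNPs under `depth_min` total reads (or under `qual_min` quality,
#' when a `quality` column is present) are filtered before testing.
#'
#' @param counts Tibble of per-SNP allelic counts with columns `chrom`,
#'   `pos`, `gene`, `sample`, `xi_reads`, `xa_reads` and optionally
#'   `quality`.
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for defaults.
#'
#' @return The input with added columns `xi_fraction`, `ratio` (Xi/Xa,
#'   `Inf` when `xa_reads` is 0), `ci_low`, `ci_high`, `status` and
#'   `reason` (`insufficient_depth`, `low_quality`, `crosses_threshold` or
#'   `NA` for called SNPs).
#' @examples
#' counts <- tibble::tibble(
#'   chrom = "chrX", pos = c(100L, 200L), gene = c("G1", "G2"),
#'   sample = "s1", xi_reads = c(2L, 20L), xa_reads = c(98L, 80L)
#' )
#' call_snps(counts)
#' @export
call_snps <- function(counts, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  need <- c("chrom", "pos", "gene", "sample", "xi_reads", "xa_reads")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("counts lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(counts$xi_reads < 0 | counts$xa_reads < 0, na.rm = TRUE)) {
    abort("negative read counts")
  }
  p0 <- th$tau_ratio / (1 + th$tau_ratio)
  n <- counts$xi_reads + counts$xa_reads
  ci <- clopper_pearson(counts$xi_reads, pmax(n, 1L), alpha = th$alpha)
  low_depth <- n < th$depth_min
  low_qual <- if ("quality" %in% names(counts)) {
    !is.na(counts$quality) & counts$quality < th$qual_min
  } else {
    rep(FALSE, nrow(counts))
  }
  status <- case_when(
    low_depth | low_qual ~ "no_call",
    ci$ci_low > p0 ~ "escape",
    ci$ci_high < p0 ~ "subject",
    .default = "no_call"
  )
  reason <- case_when(
    low_depth ~ "insufficient_depth",
    low_qual ~ "low_quality",
    status == "no_call" ~ "crosses_threshold",
    .default = NA_character_
  )
  counts |>
    mutate(
      xi_fraction = .data$xi_reads / pmax(n, 1L),
      ratio = ifelse(.data$xa_reads > 0, .data$xi_reads / .data$xa_reads, Inf),
      ci_low = ifelse(n > 0, ci$ci_low, NA_real_),
      ci_high = ifelse(n > 0, ci$ci_high, NA_real_),
      status = status,
      reason = reason
    )
}

#' Assess skewing of Xi choice per sample
#'
#' Allelic XCI calls require samples in which most cells inactivated the
#' same X.  Such skewing shows up as the majority of genes having an Xi/Xa
#' expression ratio below the escape threshold.  Per sample, each gene's
#' ratio is the mean Xi/Xa ratio over its depth-passing SNPs; the sample is
#' flagged skewed when the fraction of genes below `tau_ratio` exceeds
#' `skew_frac` (strict majority by default).
#'
#' @inheritParams call_snps
#'
#' @return A tibble with one row per sample: `sample`,
#'   `n_informative_genes`, `fraction_below_threshold`, `skewed`.
#' @export
assess_skew <- function(counts, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  passing <- counts |>
    filter(.data$xi_reads + .data$xa_reads >= th$depth_min)
  if (nrow(passing) == 0) abort("no SNPs pass the depth filter in any sample")
  passing |>
    mutate(ratio = ifelse(.data$xa_reads > 0, .data$xi_reads / .data$xa_reads, Inf)) |>
    summarise(ratio = mean(.data$ratio), .by = c("sample", "gene")) |>
    summarise(
      n_informative_genes = dplyr::n(),
      fraction_below_threshold = mean(.data$ratio < th$tau_ratio),
      .by = "sample"
    ) |>
    mutate(skewed = .data$fraction_below_threshold > th$skew_frac)
}

#' Gene-level XCI calls from allelic expression
#'
#' Aggregates per-SNP calls to per-sample calls (majority status among a
#' sample's called SNPs; ties or all-`no_call` leave the sample
#' uninformative) and per-sample calls to a gene call: with `f` the
#' fraction of informative samples escaping, a gene is `variable_escape`
#' when `min(f, 1 - f) >= variable_frac` (at least 33% of informative
#' samples with each status, by default), otherwise the majority status.
#' Genes with no informative sample are `no_call`.  Input should be
#' restricted to skewed samples (see [assess_skew()]).
#'
#' @inheritParams call_snps
#' @param species,dataset Labels stamped on the output call table.
#' @param pool_snps If `TRUE`, pool Xi and Xa reads across a sample's SNPs
#'   into one binomial test per (gene, sample) instead of majority-voting
#'   per-SNP calls.
#'
#' @return A call-table tibble (see [write_call_table()]) with one row per
#'   gene.
#' @export
call_genes_allelic <- function(counts, thresholds = NULL,
                               species = "unknown", dataset = "allelic",
                               pool_snps = FALSE) {
  th <- as_thresholds(thresholds)
  if (pool_snps) {
    counts <- counts |>
      filter(.data$xi_reads + .data$xa_reads >= th$depth_min) |>
      summarise(
        chrom = .data$chrom[1], pos = .data$pos[1],
        xi_reads = sum(.data$xi_reads), xa_reads = sum(.data$xa_reads),
        .by = c("gene", "sample")
      )
  }
  snp_calls <- call_snps(counts, th)

  sample_calls <- snp_calls |>
    filter(.data$status %in% c("escape", "subject")) |>
    summarise(
      n_escape = sum(.data$status == "escape"),
      n_subject = sum(.data$status == "subject"),
      .by = c("gene", "sample")
    ) |>
    filter(.data$n_escape != .data$n_subject) |> # ties are uninformative
    mutate(sample_status = ifelse(.data$n_escape > .data$n_subject,
      "escape", "subject"
    ))

  gene_calls <- sample_calls |>
    summarise(
      n_informative = dplyr::n(),
      fraction_escape = mean(.data$sample_status == "escape"),
      .by = "gene"
    ) |>
    mutate(
      fraction_subject = 1 - .data$fraction_escape,
      status = case_when(
        pmin(.data$fraction_escape, .data$fraction_subject) >= th$variable_frac ~
          "variable_escape",
        .data$fraction_escape > 0.5 ~ "escape",
        .default = "subject"
      ),
      reason = NA_character_
    )

  uncalled <- setdiff(unique(counts$gene), gene_calls$gene)
  if (length(uncalled) > 0) {
    gene_calls <- bind_rows(gene_calls, tibble(
      gene = uncalled, n_informative = 0L,
      fraction_escape = NA_real_, fraction_subject = NA_real_,
      status = "no_call", reason = "no_informative_samples"
    ))
  }

  gene_calls |>
    mutate(species = species, dataset = dataset) |>
    select(all_of(call_table_cols)) |>
    arrange(.data$gene) |>
    new_xci_calls()
}

# light S3 wrapper so call tables get autoplot()/print() affordances while
# remaining ordinary tibbles
new_xci_calls <- function(x) {
  class(x) <- unique(c("xci_calls", class(x)))
  x
}
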
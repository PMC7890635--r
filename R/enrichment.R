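#' Count repeat elements near genes
#'
#' Counts repeats of each class whose interval intersects a window anchored
#' on each gene, either symmetrically around its CpG island
#' (`mode = "around_island"`, the default: `[start - window, end + window)`)
#' or over the strand-aware `window` bp upstream of its TSS
#' (`mode = "upstream_of_tss"`: `[pos - window, pos)` on `+`, `[pos, pos +
#' window)` on `-`).  Any intersection counts; overlap is never fractional.
#'
#' @param anchors For `around_island`: tibble with `gene`, `chrom`,
#'   `start`, `end`.  For `upstream_of_tss`: tibble with `gene`, `chrom`,
#'   `position`, `strand`.
#' @param repeats Repeat tibble from [read_intervals()] with
#'   `repeat_class`.
#' @param window Window size in bp (default 15 kb).
#' @param mode Counting mode, see above.
#'
#' @return Tibble `gene`, `repeat_class`, `count`, complete over every
#'   anchor gene x observed repeat class (zero-filled).
#' @export
count_repeats <- function(anchors, repeats, window = 15000L,
                          mode = c("around_island", "upstream_of_tss")) {
  mode <- tryCatch(match.arg(mode),
    error = function(e) abort(paste0("unknown mode: ", mode[1]))
  )
  if (mode == "around_island") {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(anchors)))
    win <- tibble(
      gene = anchors$gene, chrom = anchors$chrom,
      start = pmax(anchors$start - window, 0L),
      end = anchors$end + window
    )
  } else {
    stopifnot(all(c("gene", "chrom", "position", "strand") %in% names(anchors)))
    win <- tibble(
      gene = anchors$gene, chrom = anchors$chrom,
      start = ifelse(anchors$strand == "-",
        anchors$position,
        pmax(anchors$position - window, 0L)
      ),
      end = ifelse(anchors$strand == "-",
        anchors$position + window,
        anchors$position
      )
    )
  }
  classes <- sort(unique(repeats$repeat_class))
  hits <- overlap_pairs(
    win$chrom, win$start, win$end,
    repeats$chrom, repeats$start, repeats$end
  )
  counted <- tibble(
    gene = win$gene[hits$q],
    repeat_class = repeats$repeat_class[hits$s]
  ) |>
    count(.data$gene, .data$repeat_class, name = "count")
  tidyr::expand_grid(gene = unique(win$gene), repeat_class = classes) |>
    left_join(counted, by = c("gene", "repeat_class")) |>
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)))
}

# shared bin-counting rule: bins with probability strictly above `prob`
# intersecting [start, end)
count_bins_over <- function(bins, chrom, start, end, prob) {
  if (any(bins$value < 0 | bins$value > 1, na.rm = TRUE)) {
    abort("CTCF bin probability outside [0, 1]")
  }
  over <- bins[!is.na(bins$value) & bins$value > prob, , drop = FALSE]
  hits <- overlap_pairs(chrom, start, end, over$chrom, over$start, over$end)
  counts <- integer(length(chrom))
  if (nrow(hits) > 0) {
    tab <- table(hits$q)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

#' Count predicted CTCF-bound bins near TSSs
#'
#' Counts the 200-bp prediction bins with a CTCF-binding probability
#' strictly over `prob` (50% by default) that intersect the `window` bp on
#' either side of each TSS (`[pos - window, pos + window)`).  Bins are
#' consumed as provided (including any overlap between adjacent bins).
#'
#' @param bins Probability track tibble (`chrom`, `start`, `end`, `value`
#'   in `[0, 1]`), e.g. from [read_intervals()] with the bedgraph dialect.
#' @param tss TSS tibble with `gene`, `chrom`, `position`.
#' @param window Half-window around the TSS in bp (default 4 kb).
#' @param prob Probability cutoff (strict).
#'
#' @return Tibble `gene`, `ctcf_bins`.
#' @export
count_ctcf_bins <- function(bins, tss, window = 4000L, prob = 0.5) {
  stopifnot(all(c("gene", "chrom", "position") %in% names(tss)))
  tibble(
    gene = tss$gene,
    ctcf_bins = count_bins_over(
      bins, tss$chrom, pmax(tss$position - window, 0L),
      tss$position + window, prob
    )
  )
}

#' Predicted CTCF bins per arbitrary region
#'
#' The same counting rule as [count_ctcf_bins()] applied to explicit
#' regions, e.g. the intervals between consecutive genes of a discordant
#' domain.  Regions must be non-overlapping.
#'
#' @param regions Tibble `name`, `chrom`, `start`, `end`.
#' @inheritParams count_ctcf_bins
#'
#' @return Tibble `name`, `chrom`, `start`, `end`, `ctcf_bins`.
#' @export
region_ctcf_profile <- function(regions, bins, prob = 0.5) {
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(regions)))
  self <- overlap_pairs(
    regions$chrom, regions$start, regions$end,
    regions$chrom, regions$start, regions$end
  )
  if (any(self$q != self$s)) {
    bad <- self[self$q != self$s, ][1, ]
    abort(paste0(
      "overlapping regions: ", regions$name[bad$q], " and ", regions$name[bad$s]
    ))
  }
  regions |>
    mutate(ctcf_bins = count_bins_over(
      bins, regions$chrom, regions$start, regions$end, prob
    ))
}

#' Female/male ATAC signal ratio at TSSs
#'
#' Accessible chromatin around escaping promoters is expected on both X
#' chromosomes in females but only one in males.  Per TSS, each sample's
#' coverage values within `window` bp up- and downstream
#' (`[pos - window, pos + window)`) are averaged; the ratio is the mean of
#' female sample means over the mean of male sample means.  Genes whose
#' male mean is zero (or with signal in only one sex) are excluded with a
#' reason rather than returning an undefined ratio.
#'
#' @param tracks Coverage tibble (`chrom`, `start`, `end`, `value`,
#'   `sample`, `sex`, optional `tissue`).
#' @param tss TSS tibble with `gene`, `chrom`, `position`.
#' @param window Half-window in bp (default 250).
#'
#' @return Tibble `gene`, `female_mean`, `male_mean`, `atac_fm`,
#'   `excluded`, `reason`.
#' @export
atac_fm_ratio <- function(tracks, tss, window = 250L) {
  stopifnot(all(c("chrom", "start", "end", "value", "sample", "sex") %in%
    names(tracks)))
  win_start <- pmax(tss$position - window, 0L)
  win_end <- tss$position + window
  hits <- overlap_pairs(
    tss$chrom, win_start, win_end,
    tracks$chrom, tracks$start, tracks$end
  )
  per_sample <- tibble(
    gene = tss$gene[hits$q],
    sample = tracks$sample[hits$s],
    sex = tracks$sex[hits$s],
    value = tracks$value[hits$s]
  ) |>
    summarise(cov = mean(.data$value), .by = c("gene", "sample", "sex"))
  by_sex <- per_sample |>
    summarise(mean_cov = mean(.data$cov), .by = c("gene", "sex")) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "mean_cov")
  for (col in c("F", "M")) if (!col %in% names(by_sex)) by_sex[[col]] <- NA_real_
  tibble(gene = unique(tss$gene)) |>
    left_join(by_sex, by = "gene") |>
    mutate(
      female_mean = .data$F, male_mean = .data$M,
      excluded = is.na(.data$F) | is.na(.data$M) | .data$M == 0,
      reason = case_when(
        is.na(.data$F) ~ "no_female_signal",
        is.na(.data$M) ~ "no_male_signal",
        .data$M == 0 ~ "male_mean_zero",
        .default = NA_character_
      ),
      atac_fm = ifelse(.data$excluded, NA_real_, .data$F / .data$M)
    ) |>
    select("gene", "female_mean", "male_mean", "atac_fm", "excluded", "reason")
}

#' CpG-island sequence characteristics
#'
#' Length, GC fraction and the Gardiner-Garden CpG observed/expected ratio
#' `(#CG * length) / (#C * #G)` (0 when C or G is absent) for each island
#' sequence.
#'
#' @param islands Tibble with `name`, `start`, `end` and `seq` (the island
#'   sequence, which must be at least `end - start` long).
#'
#' @return Tibble `name`, `island_length`, `island_gc`, `island_cpg_oe`.
#' @export
island_characteristics <- function(islands) {
  stopifnot(all(c("name", "start", "end", "seq") %in% names(islands)))
  len <- islands$end - islands$start
  if (any(nchar(islands$seq) < len)) {
    short <- which(nchar(islands$seq) < len)[1]
    abort(paste0("sequence shorter than island for ", islands$name[short]))
  }
  seqs <- toupper(substr(islands$seq, 1, len))
  n_c <- stringr::str_count(seqs, "C")
  n_g <- stringr::str_count(seqs, "G")
  n_cg <- stringr::str_count(seqs, "CG")
  tibble(
    name = islands$name,
    island_length = len,
    island_gc = (n_c + n_g) / len,
    island_cpg_oe = ifelse(n_c == 0 | n_g == 0, 0, n_cg * len / (n_c * n_g))
  )
}

#' Test features for enrichment between escape and subject genes
#'
#' Per (species, feature), a Welch two-sided t-test compares the feature
#' values of genes escaping XCI against genes subject to XCI (variably
#' escaping genes are excluded from the two-group comparison).  P-values
#' are Benjamini-Hochberg adjusted across all testable features within
#' each species, and significance means adjusted p below `p_adj_cut`
#' (0.01 by default).  A group with fewer than two values leaves that
#' feature untestable, with no p-value emitted.
#'
#' @param values Long tibble of per-gene feature values: `gene`,
#'   `species`, `feature`, `value`.
#' @param calls Call table(s) supplying `gene`, `species`, `status`.
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for
#'   defaults.
#'
#' @return An `xci_enrichment` tibble: `species`, `feature`, `n_escape`,
#'   `n_subject`, `mean_escape`, `mean_subject`, `t_stat`, `p`, `p_adj`,
#'   `significant`, `untestable`.
#' @export
test_enrichment <- function(values, calls, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  stopifnot(all(c("gene", "species", "feature", "value") %in% names(values)))
  joined <- values |>
    inner_join(
      calls |> select("gene", "species", "status"),
      by = c("gene", "species")
    ) |>
    filter(.data$status %in% c("escape", "subject"), is.finite(.data$value))
  welch <- function(e, s) {
    if (length(e) < 2 || length(s) < 2) {
      return(c(t = NA_real_, p = NA_real_))
    }
    if (stats::sd(e) == 0 && stats::sd(s) == 0) {
      # degenerate: both groups constant, so the t denominator vanishes
      if (mean(e) == mean(s)) return(c(t = 0, p = 1))
      return(c(t = sign(mean(e) - mean(s)) * Inf, p = 0))
    }
    fit <- t.test(e, s) # Welch by default
    c(t = unname(fit$statistic), p = fit$p.value)
  }
  res <- joined |>
    summarise(
      n_escape = sum(.data$status == "escape"),
      n_subject = sum(.data$status == "subject"),
      mean_escape = mean(.data$value[.data$status == "escape"]),
      mean_subject = mean(.data$value[.data$status == "subject"]),
      t_stat = welch(
        .data$value[.data$status == "escape"],
        .data$value[.data$status == "subject"]
      )[["t"]],
      p = welch(
        .data$value[.data$status == "escape"],
        .data$value[.data$status == "subject"]
      )[["p"]],
      .by = c("species", "feature")
    ) |>
    mutate(untestable = .data$n_escape < 2 | .data$n_subject < 2) |>
    mutate(
      p_adj = ifelse(.data$untestable, NA_real_, p.adjust(
        ifelse(.data$untestable, NA, .data$p),
        method = "BH"
      )),
      .by = "species"
    ) |>
    mutate(significant = !is.na(.data$p_adj) & .data$p_adj < th$p_adj_cut)
  class(res) <- unique(c("xci_enrichment", class(res)))
  attr(res, "p_adj_cut") <- th$p_adj_cut
  res
}
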
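#' Run the full XCI pipeline on a simulated cohort
#'
#' End-to-end orchestration: simulate a cohort, make methylation-based
#' calls per species, allelic-expression calls for the first species
#' (restricted to its skewed samples), merge calls across datasets,
#' classify conservation within the configured species groups, detect
#' status transitions against the planted TADs, find discordant domains,
#' test repeat / CTCF / ATAC enrichment by status, and cluster species.
#' Every table written carries the configuration hash in a `#` header
#' comment, and the whole run is deterministic given the config seed.
#'
#' @param out_dir Output directory; created if needed.  `NULL` skips all
#'   file output.
#' @param sim Cohort configuration from [sim_config()].
#' @param thresholds Thresholds from [xci_thresholds()]; `NULL` for
#'   defaults.
#' @param groups List of [xci_group()]s; by default one group per clade
#'   half ("clade_a") plus all datasets ("all_species").
#'
#' @return An `xci_pipeline` list: `cohort`, `calls` (per-dataset list),
#'   `matrix`, `conservation` (per group: categories and summary),
#'   `transitions`, `domains`, `enrichment`, `tree`, `files`.
#' @export
run_xci_pipeline <- function(out_dir = NULL, sim = sim_config(),
                             thresholds = NULL, groups = NULL) {
  th <- as_thresholds(thresholds)
  cohort <- simulate_xci_cohort(sim)
  ann <- cohort$annotations
  species <- sim_species_names(sim)
  cfg_hash <- paste0("config_hash: ", rlang::hash(list(sim, th)))

  links <- match_island_to_tss(ann$islands, ann$tss, window = th$island_tss_window)

  meth_calls <- purrr::map(species, function(sp) {
    sites <- cohort$methylation |> filter(.data$species == sp)
    meths <- island_methylation(sites, ann$islands, min_sites = th$min_sites)
    call_genes_methylation(meths, links, th,
      species = sp, dataset = paste0(sp, "_meth")
    )
  })
  names(meth_calls) <- paste0(species, "_meth")

  skew <- assess_skew(cohort$allelic, th)
  skewed_counts <- cohort$allelic |>
    semi_join(filter(skew, .data$skewed), by = "sample")
  allelic_calls <- call_genes_allelic(
    skewed_counts, th,
    species = species[1], dataset = paste0(species[1], "_allelic")
  )

  calls <- c(meth_calls, list(allelic_calls))
  names(calls)[length(calls)] <- paste0(species[1], "_allelic")
  mat <- merge_calls(calls)

  if (is.null(groups)) {
    clade_a <- species[seq_len(ceiling(length(species) / 2))]
    groups <- list(
      xci_group("clade_a", paste0(clade_a, "_meth")),
      xci_group("all_species", paste0(species, "_meth"))
    )
  }
  conservation <- purrr::map(groups, function(g) {
    list(
      group = g,
      categories = classify_conservation(mat, g, th),
      summary = summarize_conservation(mat, g, th)
    )
  })
  names(conservation) <- purrr::map_chr(groups, "name")

  main_group <- groups[[length(groups)]]
  coords <- ann$genes |> select("gene", "chrom", "start", "end")
  cons <- consensus_status(mat, main_group, th) |>
    left_join(coords, by = "gene")
  transitions <- detect_transitions(cons, ann$tads)
  categories_xy <- conservation[[main_group$name]]$categories |>
    left_join(coords, by = "gene")
  domains <- find_discordant_domains(categories_xy)

  isl <- ann$islands |> mutate(gene = sub("^cgi_", "", .data$name))
  feature_values <- bind_rows(
    purrr::map(species, function(sp) {
      bind_rows(
        count_repeats(
          isl, filter(cohort$repeats, .data$species == sp),
          window = th$repeat_window
        ) |>
          transmute(
            gene = .data$gene, species = sp,
            feature = .data$repeat_class, value = as.numeric(.data$count)
          ),
        count_ctcf_bins(
          filter(cohort$ctcf, .data$species == sp), ann$tss,
          window = th$ctcf_window, prob = th$ctcf_prob
        ) |>
          transmute(
            gene = .data$gene, species = sp,
            feature = "ctcf_bins", value = as.numeric(.data$ctcf_bins)
          ),
        atac_fm_ratio(
          filter(cohort$atac, .data$species == sp), ann$tss,
          window = th$atac_window
        ) |>
          filter(!.data$excluded) |>
          transmute(
            gene = .data$gene, species = sp,
            feature = "atac_fm", value = .data$atac_fm
          )
      )
    })
  )
  all_meth_calls <- bind_rows(meth_calls)
  enrichment <- test_enrichment(feature_values, all_meth_calls, th)

  enc <- encode_calls(mat |> select(-any_of(paste0(species[1], "_allelic"))), th)
  tree <- cluster_species(gower_distance(enc))

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "inputs"))
    for (nm in names(calls)) {
      f <- file.path(out_dir, paste0("calls_", nm, ".tsv"))
      write_call_table(calls[[nm]], f, comment = cfg_hash)
      files <- c(files, f)
    }
    write_with_hash <- function(df, name) {
      f <- file.path(out_dir, name)
      writeLines(paste("#", cfg_hash), f)
      readr::write_tsv(df, f, append = TRUE, col_names = TRUE)
      files <<- c(files, f)
    }
    write_with_hash(mat, "call_matrix.tsv")
    for (nm in names(conservation)) {
      write_with_hash(conservation[[nm]]$categories, paste0("conservation_", nm, ".tsv"))
      write_with_hash(conservation[[nm]]$summary, paste0("summary_", nm, ".tsv"))
    }
    write_with_hash(transitions, "transitions.tsv")
    write_with_hash(domains, "discordant_domains.tsv")
    write_with_hash(as_tibble(enrichment), "enrichment.tsv")
    writeLines(tree$newick, file.path(out_dir, "species_tree.nwk"))
    files <- c(files, file.path(out_dir, "species_tree.nwk"))
  }

  out <- list(
    cohort = cohort, calls = calls, matrix = mat,
    conservation = conservation, transitions = transitions,
    domains = domains, enrichment = enrichment, tree = tree,
    files = files
  )
  class(out) <- "xci_pipeline"
  out
}

#' @export
print.xci_pipeline <- function(x, ...) {
  cat("XCI pipeline run\n")
  cat("  datasets     :", length(x$calls), "\n")
  cat("  genes merged :", nrow(x$matrix), "\n")
  for (nm in names(x$conservation)) {
    s <- x$conservation[[nm]]$summary
    cat(sprintf(
      "  %-12s : %.1f%% conserved over %d genes\n",
      nm, 100 * s$fraction_conserved, s$n_genes
    ))
  }
  cat("  transitions  :", nrow(x$transitions),
      sprintf("(%d near TAD boundaries)", sum(x$transitions$near_tad, na.rm = TRUE)), "\n")
  cat("  domains      :", nrow(x$domains), "discordant\n")
  invisible(x)
}
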
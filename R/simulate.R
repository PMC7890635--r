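#' Configuration for the synthetic multi-species XCI cohort
#'
#' Defines the statistical structure of a simulated cohort: one synthetic
#' X chromosome (`chrXsim`) with evenly spaced genes, a shared core of XCI
#' statuses across species plus lineage-specific escape domains, and
#' per-assay methylation, allelic-count and feature tracks with known
#' ground truth.  Defaults emulate the field's reported structure: ~12% of
#' X-linked genes escaping XCI with escape genes clustered into domains, a
#' mouse-like outlier species with ~5% escape and a 27% mean island
#' methylation at subject genes versus 38% in the other species, escape
#' islands under 10% methylation, low male methylation except a
#' hypermethylated island fraction over 60% in both sexes, and Xi/Xa
#' expression ratios far below/above the 0.1 threshold for subject/escape
#' genes in skewed samples.
#'
#' @param n_species Number of species (the last one is the mouse-like
#'   outlier when `mouse_like = TRUE`).
#' @param n_genes Genes per species along `chrXsim`, spaced 100 kb apart.
#' @param n_samples_per_sex Methylation (and ATAC) samples per sex.
#' @param escape_fraction,variable_fraction Fractions of genes escaping /
#'   variably escaping in the shared core.
#' @param mouse_like,mouse_like_escape_fraction Whether to include the
#'   outlier species, and its (smaller) escape fraction.
#' @param subject_female_meth_mean,mouse_like_subject_meth_mean,escape_female_meth_mean,male_meth_mean
#'   Mean island methylation fractions by status, sex and species kind.
#' @param hypermeth_fraction,hypermeth_mean Fraction of islands
#'   hypermethylated in both sexes, and their mean methylation.
#' @param meth_noise_concentration Beta-distribution concentration for
#'   island-level sample means (larger = tighter around the mean).
#' @param coverage_mean Mean per-CpG read coverage (Poisson).
#' @param cpg_spacing CpG spacing within islands, bp.
#' @param island_halfwidth Island extends this far either side of the TSS.
#' @param assay One of `"wgbs"`, `"rrbs"`, `"array450k"`; see
#'   [degrade_to_assay()].
#' @param rrbs_retention,array_retention Fraction of CpGs kept by the
#'   sparse assays.
#' @param n_allelic_samples,skew_fraction Allelic-expression samples for
#'   the first species and the fraction of them with skewed Xi choice.
#' @param read_depth_mean Mean total reads per SNP (Poisson).
#' @param snps_per_gene SNPs per gene in the allelic tables.
#' @param xi_fraction_escape_mean,xi_fraction_subject_mean Mean Xi-read
#'   fraction for escape / subject genes in skewed samples.
#' @param domain_size_genes Genes per planted escape domain.
#' @param lineage_domains Number of extra escape domains private to the
#'   first-half clade of species (planted discordance).
#' @param repeat_base_rate Poisson mean repeat count per gene and class.
#' @param enrichment_factors Named list: per repeat class, multipliers
#'   `c(escape = ..., subject = ...)` applied to `repeat_base_rate`.
#' @param ctcf_shape_escape,ctcf_shape_subject Beta shapes `(a, b)` for
#'   CTCF bin probabilities at escape / subject TSSs.
#' @param atac_fm_escape,atac_fm_subject True female/male ATAC ratio by
#'   status.
#' @param seed Integer seed; a fixed seed makes the whole cohort
#'   byte-identical across runs.
#'
#' @return A validated `xci_sim_config` list.
#' @export
sim_config <- function(n_species = 8L,
                       n_genes = 300L,
                       n_samples_per_sex = 4L,
                       escape_fraction = 0.12,
                       variable_fraction = 0.05,
                       mouse_like = TRUE,
                       mouse_like_escape_fraction = 0.05,
                       subject_female_meth_mean = 0.38,
                       mouse_like_subject_meth_mean = 0.27,
                       escape_female_meth_mean = 0.05,
                       male_meth_mean = 0.03,
                       hypermeth_fraction = 0.1,
                       hypermeth_mean = 0.80,
                       meth_noise_concentration = 60,
                       coverage_mean = 30,
                       cpg_spacing = 50L,
                       island_halfwidth = 500L,
                       assay = c("wgbs", "rrbs", "array450k"),
                       rrbs_retention = 0.15,
                       array_retention = 0.10,
                       n_allelic_samples = 5L,
                       skew_fraction = 1.0,
                       read_depth_mean = 100,
                       snps_per_gene = 2L,
                       xi_fraction_escape_mean = 0.25,
                       xi_fraction_subject_mean = 0.01,
                       domain_size_genes = 4L,
                       lineage_domains = 2L,
                       repeat_base_rate = 5,
                       enrichment_factors = list(
                         LINE = c(escape = 1, subject = 2),
                         LTR = c(escape = 2, subject = 1),
                         SINE = c(escape = 1, subject = 1),
                         DNA = c(escape = 1, subject = 1),
                         snRNA = c(escape = 1, subject = 1)
                       ),
                       ctcf_shape_escape = c(3, 2),
                       ctcf_shape_subject = c(1.5, 3.5),
                       atac_fm_escape = 2.0,
                       atac_fm_subject = 1.0,
                       seed = 1L) {
  assay <- match.arg(assay)
  cfg <- as.list(environment())
  fracs <- c(
    cfg$escape_fraction, cfg$variable_fraction, cfg$mouse_like_escape_fraction,
    cfg$subject_female_meth_mean, cfg$mouse_like_subject_meth_mean,
    cfg$escape_female_meth_mean, cfg$male_meth_mean, cfg$hypermeth_fraction,
    cfg$hypermeth_mean, cfg$rrbs_retention, cfg$array_retention,
    cfg$skew_fraction, cfg$xi_fraction_escape_mean, cfg$xi_fraction_subject_mean
  )
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (cfg$n_genes < 1) abort("n_genes must be >= 1")
  if (cfg$n_species < 1) abort("n_species must be >= 1")
  if (cfg$meth_noise_concentration <= 0) abort("concentration must be > 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "xci_sim_config")
}

sim_species_names <- function(cfg) {
  sprintf("species%02d", seq_len(cfg$n_species))
}

# gene geometry on the single synthetic chromosome: TSS every 100 kb,
# 20 kb gene bodies on the + strand, one CpG island centred on each TSS
sim_annotations <- function(cfg) {
  gene <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  tss_pos <- as.integer(seq_len(cfg$n_genes)) * 100000L
  tss <- tibble(
    gene = gene, transcript_id = paste0(gene, ".1"),
    chrom = "chrXsim", position = tss_pos, strand = "+"
  )
  genes <- tibble(
    gene = gene, chrom = "chrXsim",
    start = tss_pos, end = tss_pos + 20000L, strand = "+"
  )
  islands <- tibble(
    chrom = "chrXsim",
    start = tss_pos - cfg$island_halfwidth,
    end = tss_pos + cfg$island_halfwidth,
    name = paste0("cgi_", gene)
  )
  list(tss = tss, genes = genes, islands = islands)
}

# shared-core + lineage-domain ground truth; escape genes come in
# consecutive domains of domain_size_genes
sim_truth <- function(cfg) {
  n <- cfg$n_genes
  species <- sim_species_names(cfg)
  gene <- sprintf("GENE%03d", seq_len(n))

  n_escape <- round(cfg$escape_fraction * n)
  n_domains <- max(ceiling(n_escape / cfg$domain_size_genes), 0)
  slots <- floor(n / max(cfg$domain_size_genes, 1))
  need <- n_domains + cfg$lineage_domains
  if (need > slots) abort("too many domains for n_genes; increase n_genes")
  picked <- sample(seq_len(slots), need)
  domain_genes <- function(slot) {
    lo <- (slot - 1L) * cfg$domain_size_genes + 1L
    seq(lo, min(lo + cfg$domain_size_genes - 1L, n))
  }
  core_escape <- unlist(lapply(picked[seq_len(n_domains)], domain_genes))
  core_escape <- head(core_escape, n_escape)
  lineage_idx <- if (cfg$lineage_domains > 0) {
    picked[n_domains + seq_len(cfg$lineage_domains)]
  } else {
    integer()
  }
  lineage_genes <- lapply(lineage_idx, domain_genes)

  base <- rep("subject", n)
  base[core_escape] <- "escape"
  n_var <- round(cfg$variable_fraction * n)
  var_pool <- setdiff(which(base == "subject"), unlist(lineage_genes))
  var_idx <- sample(var_pool, min(n_var, length(var_pool)))
  base[var_idx] <- "variable_escape"

  domain_id <- rep(NA_character_, n)
  for (k in seq_along(picked[seq_len(n_domains)])) {
    domain_id[domain_genes(picked[k])] <- paste0("core_domain_", k)
  }
  for (k in seq_along(lineage_genes)) {
    domain_id[lineage_genes[[k]]] <- paste0("lineage_domain_", k)
  }

  clade_a <- species[seq_len(ceiling(length(species) / 2))]
  mouse_sp <- if (cfg$mouse_like && cfg$n_species > 1) species[cfg$n_species] else NA

  truth <- tidyr::expand_grid(gene = gene, species = species) |>
    mutate(
      idx = match(.data$gene, .env$gene),
      true_status = base[.data$idx],
      domain_id = domain_id[.data$idx]
    )
  # clade-private escape domains: escape in the first-half clade only
  lg <- unlist(lineage_genes)
  if (length(lg) > 0) {
    truth <- truth |>
      mutate(true_status = ifelse(
        .data$idx %in% lg,
        ifelse(.data$species %in% clade_a, "escape", "subject"),
        .data$true_status
      ))
  }
  # the outlier species silences most core escape genes
  if (!is.na(mouse_sp)) {
    keep_n <- round(cfg$mouse_like_escape_fraction * n)
    keep <- head(core_escape, keep_n)
    drop <- setdiff(core_escape, keep)
    truth <- truth |>
      mutate(true_status = ifelse(
        .data$species == mouse_sp & .data$idx %in% drop,
        "subject", .data$true_status
      ))
  }
  # hypermethylated islands: a per-species random draw outside planted
  # domains, so planted structure stays identifiable in every species
  hyper_pool <- setdiff(seq_len(n), c(unlist(lineage_genes), core_escape))
  n_hyper <- round(cfg$hypermeth_fraction * n)
  hyper <- purrr::map(species, function(sp) {
    tibble(species = sp, idx = sample(hyper_pool, min(n_hyper, length(hyper_pool))))
  }) |>
    bind_rows() |>
    mutate(island_hypermeth = TRUE)
  truth |>
    left_join(hyper, by = c("species", "idx")) |>
    mutate(island_hypermeth = tidyr::replace_na(.data$island_hypermeth, FALSE)) |>
    select("gene", "species", "true_status", "domain_id", "island_hypermeth")
}

# draw beta island means then binomial per-CpG observed fractions
sim_methylation <- function(cfg, ann, truth) {
  species <- sim_species_names(cfg)
  mouse_sp <- if (cfg$mouse_like && cfg$n_species > 1) species[cfg$n_species] else NA
  samples <- tibble(
    sex = rep(c("F", "M"), each = cfg$n_samples_per_sex),
    sample = paste0(
      "meth_", rep(c("F", "M"), each = cfg$n_samples_per_sex),
      rep(seq_len(cfg$n_samples_per_sex), 2)
    )
  )

  grid <- truth |>
    tidyr::expand_grid(samples) |>
    mutate(
      subject_mean = ifelse(!is.na(mouse_sp) & .data$species == mouse_sp,
        cfg$mouse_like_subject_meth_mean, cfg$subject_female_meth_mean
      ),
      # variable escape is a per-sample coin flip between the two states
      sample_state = case_when(
        .data$island_hypermeth ~ "hyper",
        .data$sex == "M" ~ "male_low",
        .data$true_status == "escape" ~ "escape",
        .data$true_status == "subject" ~ "subject",
        runif(dplyr::n()) < 0.5 ~ "escape",
        .default = "subject"
      ),
      target_mean = case_when(
        .data$sample_state == "hyper" ~ cfg$hypermeth_mean,
        .data$sample_state == "male_low" ~ cfg$male_meth_mean,
        .data$sample_state == "escape" ~ cfg$escape_female_meth_mean,
        .default = .data$subject_mean
      ),
      island_mean = rbeta(
        dplyr::n(),
        .data$target_mean * cfg$meth_noise_concentration,
        (1 - .data$target_mean) * cfg$meth_noise_concentration
      )
    )

  n_cpg <- max(1L, (2L * cfg$island_halfwidth) %/% cfg$cpg_spacing)
  tss_pos <- ann$tss$position[match(grid$gene, ann$tss$gene)]
  sites <- grid |>
    mutate(tss_pos = tss_pos) |>
    tidyr::expand_grid(cpg = seq_len(n_cpg)) |>
    mutate(
      start = .data$tss_pos - cfg$island_halfwidth +
        (.data$cpg - 1L) * cfg$cpg_spacing,
      coverage = pmax(rpois(dplyr::n(), cfg$coverage_mean), 1L),
      meth = rbinom(dplyr::n(), .data$coverage, .data$island_mean) / .data$coverage,
      chrom = "chrXsim"
    ) |>
    select(
      "species", "sample", "sex", "chrom", "start", "meth", "coverage", "gene"
    ) |>
    mutate(end = .data$start + 2L, .after = "start")
  degrade_to_assay(sites, cfg$assay,
    rrbs_retention = cfg$rrbs_retention,
    array_retention = cfg$array_retention
  )
}

#' Thin a methylation track to an assay's sparsity
#'
#' WGBS keeps every CpG; RRBS keeps a random subset of CpGs that differs
#' from sample to sample; the 450k array keeps one fixed position subset
#' shared by all samples (probes are the same in every sample).
#'
#' @param sites Methylation site tibble (`chrom`, `start`, `sample`, ...).
#' @param assay `"wgbs"`, `"rrbs"` or `"array450k"`.
#' @param rrbs_retention,array_retention Fraction of CpGs retained.
#'
#' @return The thinned site tibble.
#' @export
degrade_to_assay <- function(sites, assay = c("wgbs", "rrbs", "array450k"),
                             rrbs_retention = 0.15, array_retention = 0.10) {
  assay <- match.arg(assay)
  if (assay == "wgbs") return(sites)
  if (assay == "rrbs") {
    return(sites |> filter(runif(dplyr::n()) < rrbs_retention))
  }
  positions <- unique(sites$start)
  kept <- sample(positions, max(1L, round(array_retention * length(positions))))
  sites |> filter(.data$start %in% kept)
}

# Xi/Xa read counts for the first species, skewed samples binomial around
# the status-specific Xi fraction, unskewed samples balanced at 0.5
sim_allelic <- function(cfg, ann, truth) {
  sp <- sim_species_names(cfg)[1]
  tr <- truth |> filter(.data$species == sp)
  n_skew <- round(cfg$skew_fraction * cfg$n_allelic_samples)
  samples <- tibble(
    sample = sprintf("rna_%02d", seq_len(cfg$n_allelic_samples)),
    skewed = seq_len(cfg$n_allelic_samples) <= n_skew
  )
  tr |>
    tidyr::expand_grid(samples) |>
    tidyr::expand_grid(snp = seq_len(cfg$snps_per_gene)) |>
    mutate(
      pos = ann$tss$position[match(.data$gene, ann$tss$gene)] + 5000L +
        1000L * .data$snp,
      xi_p = case_when(
        !.data$skewed ~ 0.5,
        .data$true_status == "escape" ~ cfg$xi_fraction_escape_mean,
        .data$true_status == "subject" ~ cfg$xi_fraction_subject_mean,
        runif(dplyr::n()) < 0.5 ~ cfg$xi_fraction_escape_mean,
        .default = cfg$xi_fraction_subject_mean
      ),
      depth = rpois(dplyr::n(), cfg$read_depth_mean),
      xi_reads = rbinom(dplyr::n(), .data$depth, .data$xi_p),
      xa_reads = .data$depth - .data$xi_reads,
      chrom = "chrXsim",
      species = sp
    ) |>
    select(
      "chrom", "pos", "gene", "species", "sample", "xi_reads", "xa_reads"
    )
}

# repeat elements placed inside the 15 kb island windows at class- and
# status-specific Poisson rates
sim_repeats <- function(cfg, ann, truth, window = 15000L, width = 300L) {
  status_tab <- truth |>
    distinct(.data$gene, .data$species, .data$true_status)
  isl <- ann$islands |>
    mutate(gene = sub("^cgi_", "", .data$name))
  grid <- status_tab |>
    left_join(isl, by = "gene") |>
    tidyr::expand_grid(repeat_class = names(cfg$enrichment_factors)) |>
    mutate(
      factor = purrr::map2_dbl(
        .data$repeat_class, .data$true_status,
        function(cl, st) {
          f <- cfg$enrichment_factors[[cl]]
          if (st == "escape") f[["escape"]] else if (st == "subject") {
            f[["subject"]]
          } else {
            mean(f)
          }
        }
      ),
      count = rpois(dplyr::n(), cfg$repeat_base_rate * .data$factor)
    )
  expanded <- grid |>
    filter(.data$count > 0) |>
    tidyr::uncount(.data$count)
  expanded |>
    mutate(
      rstart = as.integer(floor(runif(
        dplyr::n(),
        pmax(.data$start - window + width, 0),
        .data$end + window - width
      ))),
      rend = .data$rstart + width
    ) |>
    transmute(
      species = .data$species, chrom = .data$chrom,
      start = .data$rstart, end = .data$rend,
      name = paste0(.data$repeat_class, "_elem"),
      repeat_class = .data$repeat_class,
      gene = .data$gene
    )
}

# non-overlapping 200 bp probability bins tiling +/- 4 kb of every TSS
sim_ctcf <- function(cfg, ann, truth, window = 4000L, bin = 200L) {
  status_tab <- truth |> distinct(.data$gene, .data$species, .data$true_status)
  n_bins <- (2L * window) %/% bin
  status_tab |>
    mutate(tss = ann$tss$position[match(.data$gene, ann$tss$gene)]) |>
    tidyr::expand_grid(b = seq_len(n_bins)) |>
    mutate(
      start = .data$tss - window + (.data$b - 1L) * bin,
      end = .data$start + bin,
      value = ifelse(
        .data$true_status == "escape",
        rbeta(dplyr::n(), cfg$ctcf_shape_escape[1], cfg$ctcf_shape_escape[2]),
        rbeta(dplyr::n(), cfg$ctcf_shape_subject[1], cfg$ctcf_shape_subject[2])
      ),
      chrom = "chrXsim"
    ) |>
    select("species", "chrom", "start", "end", "value")
}

# per-sample ATAC coverage over +/- 250 bp of each TSS; female signal at
# escape genes carries the configured F/M enrichment
sim_atac <- function(cfg, ann, truth, window = 250L) {
  status_tab <- truth |> distinct(.data$gene, .data$species, .data$true_status)
  samples <- tibble(
    sample = c(
      paste0("atac_F", seq_len(cfg$n_samples_per_sex)),
      paste0("atac_M", seq_len(cfg$n_samples_per_sex))
    ),
    sex = rep(c("F", "M"), each = cfg$n_samples_per_sex)
  )
  status_tab |>
    mutate(tss = ann$tss$position[match(.data$gene, ann$tss$gene)]) |>
    tidyr::expand_grid(samples) |>
    mutate(
      fm = ifelse(.data$true_status == "escape",
        cfg$atac_fm_escape, cfg$atac_fm_subject
      ),
      mu = ifelse(.data$sex == "F", .data$fm, 1.0),
      value = stats::rgamma(dplyr::n(), shape = 20, rate = 20 / .data$mu),
      chrom = "chrXsim",
      start = .data$tss - window,
      end = .data$tss + window
    ) |>
    select("species", "sample", "sex", "chrom", "start", "end", "value")
}

#' Simulate a complete multi-species XCI cohort
#'
#' Generates annotations (TSSs, gene bodies, CpG islands, TADs spanning
#' the planted escape domains), per-species ground-truth XCI statuses,
#' methylation tracks for every sample, allelic Xi/Xa read counts for the
#' first species, and repeat / CTCF-probability / ATAC feature tracks,
#' all deterministic under the config seed.  Ground truth is emitted for
#' validation only; no calling stage reads it.
#'
#' @param config An [sim_config()] object (default configuration if
#'   `NULL`).
#' @param components Which data layers to generate besides annotations and
#'   ground truth; subsets make targeted simulations much cheaper.
#'
#' @return An `xci_cohort` list with elements `config`, `annotations`
#'   (`tss`, `genes`, `islands`, `tads`), `truth`, and the requested
#'   components among `methylation`, `allelic`, `repeats`, `ctcf`, `atac`.
#' @examples
#' cohort <- simulate_xci_cohort(sim_config(n_genes = 40, n_species = 4, seed = 7))
#' dplyr::count(cohort$truth, species, true_status)
#' @export
simulate_xci_cohort <- function(config = NULL,
                                components = c(
                                  "methylation", "allelic", "repeats",
                                  "ctcf", "atac"
                                )) {
  cfg <- if (is.null(config)) sim_config() else config
  if (!inherits(cfg, "xci_sim_config")) abort("config must come from sim_config()")
  components <- intersect(
    components, c("methylation", "allelic", "repeats", "ctcf", "atac")
  )
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  ann <- sim_annotations(cfg)
  truth <- sim_truth(cfg)
  # TADs spanning each planted domain: boundaries fall between the genes
  # flanking the domain
  domain_members <- truth |>
    filter(!is.na(.data$domain_id)) |>
    distinct(.data$gene, .data$domain_id)
  domains <- if (nrow(domain_members) == 0) {
    tibble(
      domain_id = character(), start = integer(), end = integer(),
      chrom = character()
    )
  } else {
    domain_members |>
      mutate(pos = ann$tss$position[match(.data$gene, ann$tss$gene)]) |>
      summarise(
        start = min(.data$pos) - 50000L, end = max(.data$pos) + 70000L,
        .by = "domain_id"
      ) |>
      mutate(chrom = "chrXsim")
  }
  ann$tads <- domains |> select("chrom", "start", "end", name = "domain_id")
  out <- list(config = cfg, annotations = ann, truth = truth)
  makers <- list(
    methylation = sim_methylation, allelic = sim_allelic,
    repeats = sim_repeats, ctcf = sim_ctcf, atac = sim_atac
  )
  for (comp in names(makers)) {
    if (comp %in% components) out[[comp]] <- makers[[comp]](cfg, ann, truth)
  }
  class(out) <- "xci_cohort"
  out
}

#' @export
print.xci_cohort <- function(x, ...) {
  cat("Synthetic XCI cohort\n")
  cat("  species :", paste(sim_species_names(x$config), collapse = ", "), "\n")
  cat("  genes   :", x$config$n_genes, "on chrXsim\n")
  cat("  assay   :", x$config$assay, "\n")
  cat("  seed    :", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the same plain-text formats the readers consume: BED for islands,
#' TSSs, gene bodies and TADs; one bedGraph per methylation and ATAC
#' sample; a bedGraph for the CTCF probability track; a RepeatMasker-style
#' `.out` table per species; TSV allelic counts; and the ground-truth TSV
#' (for validation only).
#'
#' @param cohort An `xci_cohort` from [simulate_xci_cohort()].
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cohort$annotations
  write_bed <- function(df, path, cols) {
    readr::write_tsv(df[, cols], file.path(dir, path), col_names = FALSE)
  }
  write_bed(ann$islands, "islands.bed", c("chrom", "start", "end", "name"))
  ann$tss |>
    mutate(end = .data$position + 1L, score = 0L) |>
    select("chrom", start = "position", "end", name = "gene", "score", "strand") |>
    readr::write_tsv(file.path(dir, "tss.bed"), col_names = FALSE)
  write_bed(ann$genes, "genes.bed", c("chrom", "start", "end", "gene"))
  write_bed(ann$tads, "tads.bed", c("chrom", "start", "end", "name"))
  readr::write_tsv(cohort$truth, file.path(dir, "ground_truth.tsv"))
  if (!is.null(cohort$allelic)) {
    readr::write_tsv(cohort$allelic, file.path(dir, "allelic_counts.tsv"))
  }
  for (sp in unique(cohort$methylation$species)) {
    spd <- file.path(dir, sp)
    dir.create(spd, showWarnings = FALSE)
    sp_sites <- cohort$methylation |> filter(.data$species == sp)
    for (sm in unique(sp_sites$sample)) {
      sp_sites |>
        filter(.data$sample == sm) |>
        select("chrom", "start", "end", "meth") |>
        readr::write_tsv(
          file.path(spd, paste0(sm, ".meth.bedgraph")),
          col_names = FALSE
        )
    }
    # minimal RepeatMasker .out dialect: header rows then the 15 columns
    rep_sp <- if (is.null(cohort$repeats)) NULL else {
      cohort$repeats |> filter(.data$species == sp)
    }
    out_path <- file.path(spd, "repeats.out")
    if (!is.null(rep_sp)) {
    header <- c(
      "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
      "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
      ""
    )
    body <- sprintf(
      "  %d  0.0  0.0  0.0  %s  %d  %d  (0)  +  %s  %s/unk  1  %d  (0)  %d",
      1000L, rep_sp$chrom, rep_sp$start + 1L, rep_sp$end, rep_sp$name,
      rep_sp$repeat_class, rep_sp$end - rep_sp$start, seq_len(nrow(rep_sp))
    )
    writeLines(c(header, body), out_path)
    }
    if (!is.null(cohort$ctcf)) {
      cohort$ctcf |>
        filter(.data$species == sp) |>
        select("chrom", "start", "end", "value") |>
        readr::write_tsv(file.path(spd, "ctcf.bedgraph"), col_names = FALSE)
    }
    atac_sp <- if (is.null(cohort$atac)) NULL else {
      cohort$atac |> filter(.data$species == sp)
    }
    for (sm in unique(atac_sp$sample)) {
      atac_sp |>
        filter(.data$sample == sm) |>
        select("chrom", "start", "end", "value") |>
        readr::write_tsv(
          file.path(spd, paste0(sm, ".atac.bedgraph")),
          col_names = FALSE
        )
    }
  }
  invisible(dir)
}
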
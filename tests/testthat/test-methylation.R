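toy_islands <- tibble::tibble(
  chrom = "chrX", start = c(1000L, 5000L), end = c(1400L, 5400L),
  name = c("cgi_A", "cgi_B")
)

test_that("island means are unweighted and respect half-open bounds", {
  sites <- tibble::tibble(
    chrom = "chrX", start = c(1000L, 1100L, 1200L, 1400L),
    meth = c(0.0, 0.2, 0.4, 1.0), sample = "s1", sex = "F"
  )
  got <- island_methylation(sites, toy_islands)
  expect_equal(nrow(got), 1) # site at 1400 is outside [1000, 1400)
  expect_equal(got$mean_meth, 0.2)
  expect_equal(got$n_sites, 3L)
  # no overlap -> island absent, not an error
  empty <- island_methylation(
    tibble::tibble(chrom = "chrX", start = 9000L, meth = 0.5, sample = "s1"),
    toy_islands
  )
  expect_equal(nrow(empty), 0)
})

test_that("TSSs link to the nearest island within 2 kb", {
  islands <- tibble::tibble(
    chrom = "chrX", start = c(9500L, 12500L), end = c(9800L, 12800L),
    name = c("near", "far")
  )
  tss <- tibble::tibble(
    gene = "G1", transcript_id = "G1.1", chrom = "chrX",
    position = 10000L, strand = "+"
  )
  got <- match_island_to_tss(islands, tss)
  expect_equal(got$island, "near")
  expect_equal(got$distance, 201L) # 10000 - (9800 - 1)
  # an island edge just past the window leaves the TSS unlinked
  lone <- match_island_to_tss(
    tibble::tibble(chrom = "chrX", start = 12002L, end = 12300L, name = "out"),
    tss
  )
  expect_equal(nrow(lone), 0)
  inside <- match_island_to_tss(
    tibble::tibble(chrom = "chrX", start = 9900L, end = 10200L, name = "in"),
    tss
  )
  expect_equal(inside$distance, 0L)
})

test_that("two TSSs of one gene can link to two different islands", {
  islands <- tibble::tibble(
    chrom = "chrX", start = c(10000L, 70000L), end = c(10500L, 70500L),
    name = c("cgi_up", "cgi_down")
  )
  tss <- tibble::tibble(
    gene = "UBA1", transcript_id = c("t1", "t2"), chrom = "chrX",
    position = c(10100L, 70100L), strand = "+"
  )
  got <- match_island_to_tss(islands, tss)
  expect_equal(nrow(got), 2)
  expect_setequal(got$island, c("cgi_up", "cgi_down"))
})

test_that("probe island means average available promoter betas only", {
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    chrom = "chrX", position = 1:4, island = "cgi_A",
    promoter = c(TRUE, TRUE, TRUE, FALSE),
    sample = "s1",
    beta = c(0.1, 0.3, NA, 0.9)
  )
  got <- probe_island_methylation(probes)
  expect_equal(got$mean_meth, 0.2) # (0.1 + 0.3) / 2, NA excluded, p4 flagged out
  expect_equal(got$n_sites, 2L)
  none <- probe_island_methylation(dplyr::mutate(probes, promoter = FALSE))
  expect_equal(nrow(none), 0)
})

test_that("male hypermethylation discards islands above the strict majority", {
  mk <- function(meths) {
    tibble::tibble(
      island = "cgi_A", sample = paste0("m", seq_along(meths)),
      sex = "M", mean_meth = meths, n_sites = 10L
    )
  }
  expect_true(male_hypermethylation_filter(mk(c(0.05, 0.08, 0.20)))$keep)
  expect_false(male_hypermethylation_filter(mk(c(0.20, 0.30)))$keep)
  # exactly half is not over half
  expect_true(male_hypermethylation_filter(mk(c(0.16, 0.05)))$keep)
  no_males <- male_hypermethylation_filter(
    tibble::tibble(island = "cgi_A", sample = "f1", sex = "F",
                   mean_meth = 0.4, n_sites = 10L)
  )
  expect_true(no_males$keep)
  expect_false(no_males$male_filter_applied)
})

test_that("the four methylation classes partition [0, 1] at 10/15/60%", {
  grid <- c(0, 0.05, 0.0999, 0.10, 0.12, 0.1499, 0.15, 0.38, 0.60, 0.6001, 0.8, 1)
  got <- classify_island_methylation(grid)
  expect_equal(got, c(
    "escape", "escape", "escape",
    "uncallable", "uncallable", "uncallable",
    "subject", "subject", "subject",
    "hypermethylated", "hypermethylated", "hypermethylated"
  ))
  # total on a dense grid: every value lands in exactly one class
  dense <- seq(0, 1, by = 0.001)
  expect_false(any(is.na(classify_island_methylation(dense))))
})

test_that("gene calls aggregate female sample classes with the 33% rule", {
  links <- tibble::tibble(
    gene = "G1", transcript_id = "G1.1", chrom = "chrX", position = 1200L,
    strand = "+", island = "cgi_A", island_start = 1000L,
    island_end = 1400L, distance = 0L
  )
  mk <- function(female_meths) {
    tibble::tibble(
      island = "cgi_A",
      sample = paste0("f", seq_along(female_meths)),
      sex = "F", mean_meth = female_meths, n_sites = 10L
    )
  }
  one <- call_genes_methylation(mk(0.05), links)
  expect_equal(one$status, "escape") # single-sample species still callable
  mixed <- call_genes_methylation(mk(c(0.05, 0.06, 0.40)), links)
  expect_equal(mixed$status, "variable_escape")
  unc <- call_genes_methylation(mk(c(0.12, 0.13)), links)
  expect_equal(unc$status, "no_call")
  expect_equal(unc$reason, "all_uncallable")
  hyper <- call_genes_methylation(mk(c(0.9, 0.8)), links)
  expect_equal(hyper$reason, "hypermethylated")
})

test_that("male-hypermethylated islands yield no_call regardless of females", {
  links <- tibble::tibble(
    gene = "G1", transcript_id = "G1.1", chrom = "chrX", position = 1200L,
    strand = "+", island = "cgi_A", island_start = 1000L,
    island_end = 1400L, distance = 0L
  )
  meths <- tibble::tibble(
    island = "cgi_A",
    sample = c("f1", "f2", "m1", "m2"),
    sex = c("F", "F", "M", "M"),
    mean_meth = c(0.05, 0.06, 0.4, 0.5),
    n_sites = 10L
  )
  got <- call_genes_methylation(meths, links)
  expect_equal(got$status, "no_call")
  expect_equal(got$reason, "male_hypermethylated")
})

test_that("sex means are computed per island with missing sexes tolerated", {
  meths <- tibble::tibble(
    island = c("cgi_A", "cgi_A", "cgi_A", "cgi_B"),
    sample = c("f1", "f2", "m1", "f1"),
    sex = c("F", "F", "M", "F"),
    mean_meth = c(0.4, 0.36, 0.02, 0.5),
    n_sites = 10L
  )
  got <- sex_mean_comparison(meths)
  a <- got[got$island == "cgi_A", ]
  expect_equal(a$female_mean, 0.38)
  expect_equal(a$male_mean, 0.02)
  b <- got[got$island == "cgi_B", ]
  expect_true(is.na(b$male_mean))
})

test_that("methylation calls recover ground truth on the synthetic cohort", {
  cohort <- default_cohort()
  calls <- default_meth_calls()
  truth <- cohort$truth
  hits <- purrr::map_dbl(unique(truth$species), function(sp) {
    tr <- dplyr::filter(
      truth, species == sp, !island_hypermeth,
      true_status %in% c("escape", "subject")
    )
    joined <- dplyr::inner_join(
      calls[[paste0(sp, "_meth")]], tr,
      by = "gene"
    )
    mean(joined$status == joined$true_status)
  })
  expect_true(all(hits >= 0.95))
})

test_that("allelic and methylation calls agree on shared genes", {
  meth <- default_meth_calls()$species01_meth
  allelic <- default_allelic_calls()
  both <- dplyr::inner_join(
    dplyr::filter(meth, status != "no_call"),
    dplyr::filter(allelic, status != "no_call"),
    by = "gene", suffix = c("_meth", "_rna")
  )
  expect_gt(nrow(both), 100)
  expect_gte(mean(both$status_meth == both$status_rna), 0.90)
})
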
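test_that("repeat counting honours windows, modes and strand", {
  island <- tibble::tibble(
    gene = "G1", chrom = "chrX", start = 10000L, end = 11000L
  )
  reps <- tibble::tibble(
    chrom = "chrX",
    start = c(2000L, 20000L, 26500L),
    end = c(3000L, 21000L, 27000L),
    repeat_class = "LINE"
  )
  got <- count_repeats(island, reps, window = 15000L)
  # window [-5000, 26000): the first two overlap, 26500 starts past the end
  expect_equal(got$count, 2L)

  tss_plus <- tibble::tibble(
    gene = "G1", chrom = "chrX", position = 30000L, strand = "+"
  )
  tss_minus <- dplyr::mutate(tss_plus, strand = "-")
  up <- tibble::tibble(
    chrom = "chrX", start = 16000L, end = 16500L, repeat_class = "LINE"
  )
  down <- tibble::tibble(
    chrom = "chrX", start = 40000L, end = 40500L, repeat_class = "LINE"
  )
  expect_equal(
    count_repeats(tss_plus, up, mode = "upstream_of_tss")$count, 1L
  )
  expect_equal(
    count_repeats(tss_plus, down, mode = "upstream_of_tss")$count, 0L
  )
  # on the minus strand upstream flips to [pos, pos + w)
  expect_equal(
    count_repeats(tss_minus, down, mode = "upstream_of_tss")$count, 1L
  )
  expect_error(count_repeats(island, reps, mode = "sideways"), "unknown mode")
})

test_that("windowed counts are invariant to record order and track chunking", {
  set.seed(31)
  islands <- tibble::tibble(
    gene = paste0("G", 1:10), chrom = "chrX",
    start = (1:10) * 50000L, end = (1:10) * 50000L + 1000L
  )
  reps <- tibble::tibble(
    chrom = "chrX",
    start = sort(sample(1:600000, 200)),
    end = 0L, repeat_class = sample(c("LINE", "SINE"), 200, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + 300L)
  base <- count_repeats(islands, reps)
  shuffled <- count_repeats(islands, reps[sample(nrow(reps)), ])
  expect_equal(base, shuffled)
  split_cat <- dplyr::bind_rows(reps[1:77, ], reps[78:200, ])
  expect_equal(count_repeats(islands, split_cat), base)
})

test_that("CTCF bins count strictly above 50% within 4 kb of the TSS", {
  tss <- tibble::tibble(gene = "G1", chrom = "chrX", position = 10000L)
  bins <- tibble::tibble(
    chrom = "chrX",
    start = c(8000L, 8200L, 8400L, 50000L),
    end = c(8200L, 8400L, 8600L, 50200L),
    value = c(0.6, 0.4, 0.55, 0.99)
  )
  expect_equal(count_ctcf_bins(bins, tss)$ctcf_bins, 2L)
  # exactly 0.5 is not over 50%
  at_half <- dplyr::mutate(bins, value = 0.5)
  expect_equal(count_ctcf_bins(at_half, tss)$ctcf_bins, 0L)
  expect_error(
    count_ctcf_bins(dplyr::mutate(bins, value = value * 2), tss),
    "outside"
  )
})

test_that("region profiles reuse the bin rule and reject overlapping regions", {
  bins <- tibble::tibble(
    chrom = "chrX", start = c(100L, 300L), end = c(300L, 500L),
    value = c(0.7, 0.9)
  )
  regions <- tibble::tibble(
    name = c("r1", "r2"), chrom = "chrX",
    start = c(0L, 1000L), end = c(600L, 2000L)
  )
  got <- region_ctcf_profile(regions, bins)
  expect_equal(got$ctcf_bins, c(2L, 0L))
  # a region edge bisecting a bin still counts the bin
  part <- tibble::tibble(name = "r", chrom = "chrX", start = 0L, end = 200L)
  expect_equal(region_ctcf_profile(part, bins)$ctcf_bins, 1L)
  bad <- tibble::tibble(
    name = c("a", "b"), chrom = "chrX", start = c(0L, 50L), end = c(100L, 150L)
  )
  expect_error(region_ctcf_profile(bad, bins), "overlapping")
})

test_that("ATAC ratios average within sex before dividing", {
  tss <- tibble::tibble(gene = "G1", chrom = "chrX", position = 1000L)
  mk_track <- function(sample, sex, value) {
    tibble::tibble(
      chrom = "chrX", start = 750L, end = 1250L, value = value,
      sample = sample, sex = sex
    )
  }
  got <- atac_fm_ratio(
    dplyr::bind_rows(
      mk_track("f1", "F", 1.0), mk_track("f2", "F", 3.0), mk_track("m1", "M", 2.0)
    ),
    tss
  )
  expect_equal(got$atac_fm, 1.0) # mean(F) = 2, mean(M) = 2
  zero <- atac_fm_ratio(
    dplyr::bind_rows(mk_track("f1", "F", 1.0), mk_track("m1", "M", 0.0)),
    tss
  )
  expect_true(zero$excluded)
  expect_equal(zero$reason, "male_mean_zero")
})

test_that("island characteristics match the dinucleotide formula", {
  islands <- tibble::tibble(
    name = c("a", "b", "c"),
    start = 0L, end = 4L,
    seq = c("CGCG", "ATAT", "GCGC")
  )
  got <- island_characteristics(islands)
  expect_equal(got$island_length, c(4L, 4L, 4L))
  expect_equal(got$island_gc, c(1, 0, 1))
  expect_equal(got$island_cpg_oe, c(2, 0, 1))
  short <- tibble::tibble(name = "s", start = 0L, end = 10L, seq = "ACGT")
  expect_error(island_characteristics(short), "shorter")
})

test_that("enrichment testing is Welch + BH within species", {
  set.seed(5)
  genes <- paste0("G", 1:60)
  calls <- toy_calls(
    genes, rep(c("escape", "subject"), each = 30),
    species = "sp1", dataset = "d1"
  )
  values <- dplyr::bind_rows(
    tibble::tibble(
      gene = genes, species = "sp1", feature = "LINE",
      value = c(rnorm(30, 5, 1), rnorm(30, 10, 2))
    ),
    tibble::tibble(
      gene = genes, species = "sp1", feature = "SINE",
      value = rnorm(60, 5, 1)
    )
  )
  got <- test_enrichment(values, calls)
  line <- got[got$feature == "LINE", ]
  # Welch oracle on the same values
  e <- values$value[values$feature == "LINE"][1:30]
  s <- values$value[values$feature == "LINE"][31:60]
  oracle <- t.test(e, s)
  expect_equal(line$t_stat, unname(oracle$statistic))
  expect_equal(line$p, oracle$p.value)
  expect_equal(got$p_adj, p.adjust(got$p, "BH"))
  expect_true(line$significant)
  expect_false(got[got$feature == "SINE", ]$significant)
})

test_that("degenerate groups are untestable or exactly null", {
  genes <- paste0("G", 1:10)
  calls <- toy_calls(genes, c("escape", rep("subject", 9)))
  values <- tibble::tibble(
    gene = genes, species = "sp1", feature = "LINE", value = rnorm(10)
  )
  got <- test_enrichment(values, calls)
  expect_true(got$untestable)
  expect_true(is.na(got$p_adj))
  # identical constant groups: t = 0, p = 1
  calls2 <- toy_calls(genes, rep(c("escape", "subject"), each = 5))
  const <- dplyr::mutate(values, value = 3)
  got2 <- test_enrichment(const, calls2)
  expect_equal(got2$t_stat, 0)
  expect_equal(got2$p, 1)
  # variable-escape genes never enter the two-group comparison
  calls3 <- toy_calls(genes, c(rep("escape", 3), rep("subject", 3),
    rep("variable_escape", 4)))
  got3 <- test_enrichment(values, calls3)
  expect_equal(got3$n_escape + got3$n_subject, 6L)
})

test_that("BH adjustment equals the step-up oracle on random p-vectors", {
  set.seed(77)
  for (i in 1:40) {
    p <- runif(sample(1:100, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
  expect_equal(
    p.adjust(c(0.001, 0.02, 0.04, 0.05), "BH"),
    bh_oracle(c(0.001, 0.02, 0.04, 0.05))
  )
})

test_that("tidy and glance summarise enrichment results", {
  genes <- paste0("G", 1:20)
  calls <- toy_calls(genes, rep(c("escape", "subject"), each = 10))
  set.seed(2)
  values <- tibble::tibble(
    gene = genes, species = "sp1", feature = "LINE",
    value = c(rnorm(10, 2), rnorm(10, 8))
  )
  res <- test_enrichment(values, calls)
  td <- tidy(res)
  expect_named(
    td,
    c(
      "species", "feature", "estimate", "mean_escape", "mean_subject",
      "n_escape", "n_subject", "statistic", "p.value", "p_adj",
      "significant", "untestable"
    )
  )
  gl <- glance(res)
  expect_equal(gl$n_tests, 1L)
  expect_equal(gl$p_adj_cut, 0.01)
})
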
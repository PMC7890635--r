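test_that("merge matches genes case-insensitively and keeps gaps missing", {
  human <- toy_calls(c("KDM6A", "XIST"), c("escape", "subject"),
    species = "human", dataset = "human_wgbs"
  )
  mouse <- toy_calls(c("Kdm6a"), c("escape"),
    species = "mouse", dataset = "mouse_wgbs"
  )
  mat <- merge_calls(human, mouse)
  expect_equal(nrow(mat), 2)
  kdm <- mat[mat$gene_key == "KDM6A", ]
  expect_equal(kdm$human_wgbs, "escape")
  expect_equal(kdm$mouse_wgbs, "escape")
  expect_true(is.na(mat[mat$gene_key == "XIST", ]$mouse_wgbs))
  # duplicates: same status deduplicated, conflicting is an error
  expect_silent(merge_calls(dplyr::bind_rows(human, human[1, ]), mouse))
  conflict <- human[1, ]
  conflict$status <- "subject"
  expect_error(merge_calls(dplyr::bind_rows(human, conflict)), "conflicting")
})

test_that("conservation categories follow the multi-species rules", {
  mk_matrix <- function(statuses) {
    tabs <- purrr::imap(statuses, function(st, i) {
      toy_calls("G1", st,
        species = paste0("sp", i), dataset = paste0("sp", i, "_ds")
      )
    })
    merge_calls(tabs)
  }
  grp <- function(n) xci_group("g", paste0("sp", seq_len(n), "_ds"))
  cat1 <- function(statuses) {
    classify_conservation(mk_matrix(statuses), grp(length(statuses)))$category
  }
  expect_equal(cat1(c("escape", "escape", "subject", "subject")), "discordant_multi")
  expect_equal(cat1(rep("subject", 5)), "conserved_subject")
  expect_equal(cat1(rep("escape", 4)), "conserved_escape")
  expect_equal(cat1(c("escape", "escape", "subject")), "insufficient")
  expect_equal(cat1(c("escape", "subject", "subject", "subject")), "discordant_single")
  expect_equal(
    cat1(c("variable_escape", "escape", "escape", "escape")), "mixed_variable"
  )
  # variable cells count as informative but as neither escape nor subject
  expect_equal(
    cat1(c("variable_escape", "escape", "escape", "subject", "subject")),
    "discordant_multi"
  )
  # no_call cells are not informative
  expect_equal(cat1(c("no_call", "escape", "escape", "escape")), "insufficient")
})

test_that("category assignment is exhaustive and mutually exclusive", {
  set.seed(99)
  statuses <- c("escape", "variable_escape", "subject", "no_call")
  for (i in 1:50) {
    n <- sample(1:8, 1)
    st <- sample(statuses, n, replace = TRUE)
    tabs <- purrr::imap(st, function(s, j) {
      toy_calls("G1", s, species = paste0("sp", j), dataset = paste0("d", j))
    })
    got <- classify_conservation(
      merge_calls(tabs), xci_group("g", paste0("d", seq_len(n)))
    )
    expect_equal(nrow(got), 1)
    expect_true(got$category %in% c(
      "insufficient", "conserved_escape", "conserved_subject",
      "discordant_multi", "discordant_single", "mixed_variable"
    ))
  }
})

test_that("species with several datasets contribute one call by priority", {
  arr <- toy_calls("G1", "escape", species = "human", dataset = "human_450k")
  wgbs <- toy_calls("G1", "subject", species = "human", dataset = "human_wgbs")
  others <- purrr::map(1:3, function(i) {
    toy_calls("G1", "escape", species = paste0("sp", i), dataset = paste0("d", i))
  })
  mat <- merge_calls(c(list(arr, wgbs), others))
  prefer_array <- classify_conservation(
    mat, xci_group("g", c("human_450k", "human_wgbs", "d1", "d2", "d3"))
  )
  expect_equal(prefer_array$category, "conserved_escape")
  prefer_wgbs <- classify_conservation(
    mat, xci_group("g", c("human_wgbs", "human_450k", "d1", "d2", "d3"))
  )
  expect_equal(prefer_wgbs$category, "discordant_single")
})

test_that("group summaries report conserved fractions and usual-status splits", {
  genes <- paste0("G", 1:4)
  tabs <- purrr::map(1:4, function(i) {
    st <- c("subject", "subject", "subject", if (i <= 2) "escape" else "subject")
    toy_calls(genes, st, species = paste0("sp", i), dataset = paste0("d", i))
  })
  # G4 is escape in 2 of 4 species -> discordant_multi; G1-G3 conserved subject
  mat <- merge_calls(tabs)
  got <- summarize_conservation(mat, xci_group("g", paste0("d", 1:4)))
  expect_equal(got$n_genes, 4)
  expect_equal(got$fraction_conserved, 0.75)
  expect_equal(got$n_conserved_subject, 3L)
  expect_equal(got$n_discordant_multi, 1L)
  expect_equal(got$fraction_usual_subject_conserved, 1) # G4 is 50/50, not usual
  expect_error(
    summarize_conservation(mat, xci_group("empty", character(0))),
    "length"
  )
})

test_that("transition count equals the sign changes of the collapsed track", {
  mk_genes <- function(statuses) {
    n <- length(statuses)
    tibble::tibble(
      gene = paste0("G", seq_len(n)), chrom = "chrXsim",
      start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
      consensus = statuses
    )
  }
  t1 <- detect_transitions(mk_genes(
    c("escape_ish", "escape_ish", "subject", "subject")
  ))
  expect_equal(nrow(t1), 1)
  t2 <- detect_transitions(mk_genes(c("escape_ish", "subject", "escape_ish")))
  expect_equal(nrow(t2), 2)
  # oracle: direct scan over random status sequences (NA genes skipped)
  set.seed(17)
  for (i in 1:25) {
    st <- sample(c("escape_ish", "subject", NA), sample(2:30, 1), replace = TRUE)
    got <- detect_transitions(mk_genes(st))
    kept <- st[!is.na(st)]
    oracle <- if (length(kept) < 2) 0 else sum(kept[-1] != kept[-length(kept)])
    expect_equal(nrow(got), oracle)
  }
})

test_that("transitions are annotated near TAD boundaries by the gene rule", {
  genes <- tibble::tibble(
    gene = c("A", "B", "C"), chrom = "chrXsim",
    start = c(1000L, 10000L, 20000L), end = c(2000L, 11000L, 21000L),
    consensus = c("escape_ish", "subject", "escape_ish")
  )
  # one TAD boundary between A and B (at 5,000), none between B and C
  tads <- tibble::tibble(chrom = "chrXsim", start = 5000L, end = 8000L)
  got <- detect_transitions(genes, tads)
  expect_equal(got$near_tad, c(TRUE, FALSE))
  # a boundary inside C's gene body marks the B-C transition too
  tads2 <- tibble::tibble(chrom = "chrXsim", start = 5000L, end = 20500L)
  expect_equal(detect_transitions(genes, tads2)$near_tad, c(TRUE, TRUE))
})

test_that("discordant domains are maximal runs of adjacent discordant genes", {
  mk_cat <- function(categories) {
    n <- length(categories)
    tibble::tibble(
      gene = paste0("G", seq_len(n)), gene_key = paste0("G", seq_len(n)),
      chrom = "chrXsim", start = seq_len(n) * 1000L,
      end = seq_len(n) * 1000L + 500L,
      category = categories
    )
  }
  got <- find_discordant_domains(mk_cat(c(
    "conserved_subject", "discordant_multi", "discordant_multi",
    "discordant_multi", "conserved_subject"
  )))
  expect_equal(nrow(got), 1)
  expect_equal(got$n_genes, 3L)
  expect_equal(got$genes, "G2,G3,G4")
  # discordant genes separated by a conserved gene do not merge
  none <- find_discordant_domains(mk_cat(c(
    "discordant_multi", "conserved_subject", "discordant_multi"
  )))
  expect_equal(nrow(none), 0)
  # insufficient genes are dropped before adjacency is judged
  bridged <- find_discordant_domains(mk_cat(c(
    "discordant_multi", "insufficient", "discordant_multi"
  )))
  expect_equal(nrow(bridged), 1)
  expect_equal(find_discordant_domains(mk_cat(character(0))) |> nrow(), 0)
})
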
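# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the reference synthetic cohort: default study conditions, seed 1
default_cohort <- function() {
  memo("default_cohort", simulate_xci_cohort(sim_config(seed = 1)))
}

# methylation calls for every species of the reference cohort
default_meth_calls <- function() {
  memo("default_meth_calls", {
    cohort <- default_cohort()
    ann <- cohort$annotations
    links <- match_island_to_tss(ann$islands, ann$tss)
    sp <- unique(cohort$truth$species)
    calls <- lapply(sp, function(s) {
      sites <- dplyr::filter(cohort$methylation, species == s)
      meths <- island_methylation(sites, ann$islands)
      call_genes_methylation(meths, links, species = s, dataset = paste0(s, "_meth"))
    })
    names(calls) <- paste0(sp, "_meth")
    calls
  })
}

# allelic calls for the first species, restricted to its skewed samples
default_allelic_calls <- function() {
  memo("default_allelic_calls", {
    cohort <- default_cohort()
    skew <- assess_skew(cohort$allelic)
    skewed <- dplyr::semi_join(
      cohort$allelic, dplyr::filter(skew, skewed),
      by = "sample"
    )
    call_genes_allelic(skewed, species = "species01", dataset = "species01_allelic")
  })
}

# hand-written tiny call table
toy_calls <- function(genes, statuses, species = "sp1", dataset = "ds1") {
  tibble::tibble(
    gene = genes, species = species, dataset = dataset,
    status = statuses, reason = NA_character_,
    n_informative = 5L,
    fraction_escape = ifelse(statuses == "escape", 1,
      ifelse(statuses == "variable_escape", 0.5, 0)
    ),
    fraction_subject = ifelse(statuses == "subject", 1,
      ifelse(statuses == "variable_escape", 0.5, 0)
    )
  )
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# brute-force agglomerative complete-linkage clustering; returns the
# sorted member sets and the height of every merge
complete_linkage_oracle <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric()
  members <- character()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    heights <- c(heights, best[1])
    members <- c(members, paste(merged, collapse = ","))
    clusters[[i]] <- merged
    clusters[[j]] <- NULL
  }
  tibble::tibble(height = heights, members = members)
}
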
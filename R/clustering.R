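#' Encode XCI calls numerically for clustering
#'
#' Transforms a merged gene x dataset status matrix into the numeric
#' encoding used for species clustering: escape 0, variable escape 0.5,
#' subject 1; `no_call` and absent cells become missing.
#'
#' @param matrix Merged matrix from [merge_calls()] (columns beyond
#'   `gene`/`gene_key` are datasets), or any tibble of status columns.
#' @param thresholds Thresholds from [xci_thresholds()] (supplies the
#'   encoding); `NULL` for defaults.
#'
#' @return A numeric matrix, datasets in rows, genes in columns.
#' @export
encode_calls <- function(matrix, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  ds_cols <- setdiff(names(matrix), c("gene", "gene_key"))
  status <- as.matrix(matrix[, ds_cols, drop = FALSE])
  known <- c(names(th$encoding), "no_call")
  bad <- setdiff(unique(status[!is.na(status)]), known)
  if (length(bad) > 0) abort(paste0("unknown XCI status: '", bad[1], "'"))
  enc <- th$encoding[status]
  dim(enc) <- dim(status)
  m <- t(enc)
  rownames(m) <- ds_cols
  colnames(m) <- matrix$gene_key
  m
}

#' Gower distance between species call profiles
#'
#' For each pair of rows, the mean over genes non-missing in both of
#' `|x_i - x_j|` (the encoded calls already live on a unit range, so the
#' range normalisation is 1).  Genes missing in either member of a pair
#' are dropped pairwise.  Distances are symmetric, zero on the diagonal
#' and bounded in `[0, 1]`; the triangle inequality is not guaranteed
#' under pairwise deletion.
#'
#' @param m Numeric matrix from [encode_calls()] (rows = species/datasets).
#'
#' @return A symmetric distance matrix with zero diagonal.
#' @export
gower_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(shared)) {
        abort(paste0(
          "no shared genes between ", rownames(m)[i], " and ", rownames(m)[j]
        ))
      }
      d[i, j] <- d[j, i] <- mean(abs(m[i, shared] - m[j, shared]))
    }
  }
  d
}

#' Cluster species by XCI call profile
#'
#' Agglomerative clustering of the Gower distances with complete linkage.
#' Rows are pre-sorted by name so linkage ties resolve deterministically
#' (lowest name lexicographically first).
#'
#' @param d Symmetric distance matrix from [gower_distance()].
#'
#' @return An `xci_tree`: list with the `hclust` fit (`$hclust`), the
#'   Newick serialisation with branch lengths derived from merge heights
#'   (`$newick`) and the merge-height table (`$merges`).
#' @export
cluster_species <- function(d) {
  if (!isTRUE(all.equal(d, t(d)))) abort("distance matrix is not symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(d), method = "complete")
  phy <- ape::as.phylo(hc)
  merges <- tibble(
    step = seq_along(hc$height),
    height = hc$height,
    members = vapply(seq_along(hc$height), function(k) {
      paste(sort(rownames(d)[merge_members(hc, k)]), collapse = ",")
    }, character(1))
  )
  out <- list(
    hclust = hc,
    newick = ape::write.tree(phy),
    merges = merges,
    labels = rownames(d)
  )
  class(out) <- "xci_tree"
  out
}

# leaves under merge step k of an hclust fit
merge_members <- function(hc, k) {
  mrg <- hc$merge
  grab <- function(i) {
    if (i < 0) return(-i)
    c(grab(mrg[i, 1]), grab(mrg[i, 2]))
  }
  grab(k)
}

#' @export
print.xci_tree <- function(x, ...) {
  cat("XCI species clustering (Gower distance, complete linkage)\n")
  cat("  species:", paste(x$labels, collapse = ", "), "\n")
  cat("  newick :", x$newick, "\n")
  invisible(x)
}

#' Height at which two species merge
#'
#' The cophenetic distance between two leaves of the clustering, i.e. the
#' complete-linkage height of their first common cluster.
#'
#' @param tree An `xci_tree` from [cluster_species()].
#' @param a,b Species labels.
#'
#' @return A single merge height.
#' @export
merge_height <- function(tree, a, b) {
  cd <- as.matrix(stats::cophenetic(tree$hclust))
  if (!all(c(a, b) %in% rownames(cd))) abort("unknown species label")
  cd[a, b]
}
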
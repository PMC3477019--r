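#' Pairwise evolutionary distances with complete deletion
#'
#' Computes a distance matrix from an aligned sequence set after *complete
#' deletion*: every alignment column containing a gap (`-`) or an ambiguous
#' base (`N`) in any sequence is removed globally before distances are
#' computed. Distances are substitutions per site under the chosen model:
#' `"p-distance"` (raw proportion of differing sites), `"jc69"`
#' (Jukes-Cantor) or `"k2p"` (Kimura two-parameter).
#'
#' @param alignment A [Biostrings::DNAStringSet] or named character vector of
#'   equal-length aligned sequences (>= 2 taxa).
#' @param model One of `"p-distance"`, `"jc69"`, `"k2p"`.
#' @return A [stats::dist] object with taxa as labels; the number of
#'   alignment columns used is attached as attribute `n_sites`.
#' @export
compute_distance_matrix <- function(alignment,
                                    model = c("p-distance", "jc69", "k2p")) {
  model <- match.arg(model)
  v <- as_seq_vector(alignment)
  if (length(v) < 2L) abort("need at least 2 taxa")
  if (anyDuplicated(names(v))) abort("taxon ids must be unique")
  lens <- nchar(v)
  if (length(unique(lens)) != 1L) {
    abort("aligned sequences must all have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(unname(v)), "", fixed = TRUE))
  rownames(mat) <- names(v)
  keep <- !apply(mat == "-" | mat == "N", 2, any)  # complete deletion
  if (!any(keep)) abort("no alignment columns survive complete deletion")
  mat <- mat[, keep, drop = FALSE]
  bin <- ape::as.DNAbin(tolower(mat))
  ape_model <- c("p-distance" = "raw", "jc69" = "JC69", "k2p" = "K80")[[model]]
  d <- ape::dist.dna(bin, model = ape_model, pairwise.deletion = FALSE)
  if (any(!is.finite(d))) {
    dm <- as.matrix(d)
    bad <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)[1, ]
    abort(paste0("distance undefined under ", model, " for pair ",
                 rownames(dm)[bad[1]], " / ", colnames(dm)[bad[2]],
                 " (too divergent)"))
  }
  attr(d, "n_sites") <- ncol(mat)
  d
}

#' Distance matrix as a tidy tibble
#'
#' @param dm A [stats::dist] object.
#' @return A tibble of the unique pairs: `taxon_a`, `taxon_b`, `distance`.
#' @export
dist_to_tibble <- function(dm) {
  m <- as.matrix(dm)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    taxon_a = rownames(m)[idx[, 1]],
    taxon_b = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a distance matrix; the result is
#' unrooted with branch lengths in the units of the input distances.
#' Negative branch lengths (which NJ can produce on non-additive input) are
#' clamped to zero with a warning.
#'
#' @param dm A [stats::dist] object (or symmetric matrix) over >= 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
build_nj_tree <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 3L) abort("neighbor joining needs at least 3 taxa")
  phy <- ape::nj(as.dist(m))
  if (any(phy$edge.length < 0)) {
    warn("negative NJ branch length(s) clamped to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phy
}

#' UPGMA tree
#'
#' Rooted ultrametric tree by average-linkage hierarchical clustering
#' (unweighted pair-group method with arithmetic mean); every leaf sits at
#' the same depth and the root height is half the largest cluster distance.
#'
#' @param dm A [stats::dist] object (or symmetric matrix) over >= 2 taxa.
#' @return A rooted [ape::phylo] tree.
#' @export
build_upgma_tree <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 2L) abort("UPGMA needs at least 2 taxa")
  hc <- hclust(as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a distance tree
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds a tree per
#' replicate, and records for each internal edge of the point-estimate tree
#' the percentage of replicate trees containing the same bipartition.
#' Supports are attached as `node.label` (the root label is empty).
#' A replicate whose resampled columns all die in complete deletion is
#' redrawn (up to 100 retries, then an error).
#'
#' @param alignment Aligned sequences as in [compute_distance_matrix()].
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param builder `"nj"` or `"upgma"`.
#' @param model Distance model, as in [compute_distance_matrix()].
#' @param seed Integer seed; the same seed reproduces identical supports.
#' @return An [ape::phylo] tree with `node.label` holding percent supports.
#' @export
bootstrap_support <- function(alignment, n_reps = 100L,
                              builder = c("nj", "upgma"),
                              model = c("p-distance", "jc69", "k2p"),
                              seed = 1L) {
  builder <- match.arg(builder)
  model <- match.arg(model)
  stopifnot(n_reps >= 1L)
  v <- as_seq_vector(alignment)
  build <- if (builder == "nj") build_nj_tree else build_upgma_tree
  point <- build(compute_distance_matrix(v, model = model))
  chars <- do.call(rbind, strsplit(toupper(unname(v)), "", fixed = TRUE))
  rownames(chars) <- names(v)
  n_col <- ncol(chars)
  rep_trees <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      for (try in seq_len(100L)) {
        cols <- sample.int(n_col, n_col, replace = TRUE)
        res <- tryCatch({
          aln <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
          suppressWarnings(build(compute_distance_matrix(aln, model = model)))
        }, error = function(e) NULL)
        if (!is.null(res)) return(res)
      }
      abort("bootstrap replicate failed repeatedly (no usable columns)")
    })
  })
  counts <- ape::prop.clades(point, rep_trees, rooted = ape::is.rooted(point))
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / n_reps)
  labels <- as.character(supp)
  labels[1] <- ""  # root of the (possibly arbitrarily rooted) tree
  point$node.label <- labels
  point
}

#' Mean distance of each taxon to a reference taxon
#'
#' Support for divergence-based exclusion of ortholog candidates: flags taxa
#' whose distance to a named reference exceeds a threshold.
#'
#' @param dm A [stats::dist] object.
#' @param reference Taxon id to compare against.
#' @param max_distance Optional threshold; taxa strictly above it are
#'   flagged `diverged = TRUE`.
#' @return A tibble `taxon`, `distance_to_reference`, `diverged`.
#' @export
divergence_from_reference <- function(dm, reference, max_distance = Inf) {
  m <- as.matrix(dm)
  if (reference %!in% rownames(m)) {
    abort(paste0("reference taxon '", reference, "' not in distance matrix"))
  }
  d <- m[reference, ]
  tibble(
    taxon = names(d), distance_to_reference = unname(d),
    diverged = unname(d) > max_distance
  ) |>
    filter(.data$taxon != reference)
}

#' Write a tree to Newick
#'
#' Branch lengths are included; bootstrap supports (if present) are written
#' as internal node labels.
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
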
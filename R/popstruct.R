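#' Variance-standardized genomic relationship matrix
#'
#' Each site's dosage column is centred by `2p` and scaled by
#' `sqrt(2p(1-p))` (`p` = frequency of the counted allele); the
#' relationship matrix is the cross-product over sites divided by the
#' number of polymorphic sites used. `mode = "centered"` skips the
#' variance scaling (VanRaden denominator `sum 2p(1-p)` instead).
#' Monomorphic sites are skipped.
#'
#' @param genotypes a complete (imputed) [geno_matrix()].
#' @param mode `"variance-standardized"` or `"centered"`.
#' @return A samples-by-samples matrix of class `rel_matrix` with
#'   attribute `builder`.
#' @export
relationship_matrix <- function(genotypes,
                                mode = c("variance-standardized",
                                         "centered")) {
  mode <- match.arg(mode)
  g <- genotypes$geno
  if (anyNA(g)) stop("relationship_matrix needs complete genotypes",
                     call. = FALSE)
  p <- rowMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic", call. = FALSE)
  g <- g[poly, , drop = FALSE]; p <- p[poly]
  cent <- g - 2 * p
  k <- if (mode == "variance-standardized") {
    z <- cent / sqrt(2 * p * (1 - p))
    crossprod(z) / nrow(z)
  } else {
    crossprod(cent) / sum(2 * p * (1 - p))
  }
  dimnames(k) <- list(genotypes$samples, genotypes$samples)
  structure(k, class = c("rel_matrix", "matrix", "array"), builder = mode)
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the relationship matrix; sample coordinates are
#' eigenvectors scaled by the square root of their (nonnegative)
#' eigenvalues. Sign convention: within each component, the loading of
#' largest magnitude is positive. Requesting more components than the
#' matrix rank truncates with a warning.
#'
#' @param relmat a [relationship_matrix()].
#' @param k number of components.
#' @return A list of class `pca_result`: `coords` (tibble, one row per
#'   sample: `sample_id`, `PC1`...), `explained` (variance fractions),
#'   `values` (eigenvalues).
#' @export
pca <- function(relmat, k = 10L) {
  eig <- eigen(unclass(relmat), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  rank <- sum(vals > max(vals) * 1e-10)
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank,
            "; truncating")
    k <- rank
  }
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  sgn <- apply(vec, 2, function(v) sign(v[which.max(abs(v))]))
  vec <- sweep(vec, 2, ifelse(sgn == 0, 1, sgn), `*`)
  coords <- sweep(vec, 2, sqrt(vals[seq_len(k)]), `*`)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(
      coords = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(relmat)),
        tibble::as_tibble(coords)
      ),
      explained = vals[seq_len(k)] / sum(vals),
      values = vals
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$explained)
  cat(sprintf("<pca_result> %d samples, %d components (%.1f%% variance)\n",
              nrow(x$coords), k, 100 * sum(x$explained)))
  invisible(x)
}

#' Allele-sharing distance matrix
#'
#' `d(i, j) = 1 - shared alleles / (2 x compared sites)`, where two
#' genotypes share `2 - |g_i - g_j|` alleles at a site. Missing cells are
#' excluded pairwise.
#'
#' @param genotypes a [geno_matrix()].
#' @return A symmetric `dist`-compatible matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(genotypes) {
  g <- genotypes$geno
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(genotypes$samples,
                                       genotypes$samples))
  ok <- !is.na(g)
  gz <- g; gz[!ok] <- 0L
  # sum |gi - gj| decomposes over dosage indicator columns
  for (i in seq_len(n - 1)) {
    cols <- (i + 1):n
    diffs <- abs(gz[, cols, drop = FALSE] - gz[, i])
    diffs[!(ok[, cols, drop = FALSE] & ok[, i])] <- NA
    share <- colMeans(2 - diffs, na.rm = TRUE)
    d[i, cols] <- d[cols, i] <- 1 - share / 2
  }
  d[is.nan(d)] <- NA
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via \pkg{ape}), followed by a
#' post-pass that clamps negative branch lengths to zero and moves the
#' deficit onto the sister branch so path lengths through the parent node
#' are preserved.
#'
#' @param distances symmetric numeric matrix (or `dist`), n >= 3 leaves.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (nrow(d) < 3) stop("need at least 3 leaves", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

# Zero out negative edges, adding the deficit to the sister edge sharing
# the same parent node (Kuhner-Felsenstein style correction).
clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
    }
    if (all(tr$edge.length >= 0)) break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Assign samples to subpopulations from principal components
#'
#' K-means on the top principal components (20 restarts under a fixed
#' seed). Membership proportions are inverse-distance weights to the
#' cluster centroids, normalized across clusters; a sample whose top
#' proportion falls below `admixture_threshold` is labelled `MIXED`.
#' When per-sample latitudes and a wild indicator are supplied, clusters
#' are mapped to `WILD` (majority-wild cluster) and `NR`/`HR`/`SR` by
#' decreasing mean latitude; otherwise clusters are labelled `C1`...`Ck`.
#'
#' @param pcs a `pca_result` or a numeric matrix of coordinates.
#' @param k number of clusters (default 4).
#' @param admixture_threshold `MIXED` when the top membership proportion
#'   is below this value (default 0.55).
#' @param seed integer seed for the restarts.
#' @param n_pcs number of leading components used.
#' @param latitude optional per-sample latitude for label mapping.
#' @param is_wild optional per-sample logical wild-accession flag.
#' @return A tibble (`sample_id`, `cluster`, `label`, `max_prop`, and one
#'   `prop_*` column per cluster).
#' @export
assign_groups <- function(pcs, k = 4L, admixture_threshold = 0.55,
                          seed = 1L, n_pcs = 3L,
                          latitude = NULL, is_wild = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (inherits(pcs, "pca_result")) {
    ids <- pcs$coords$sample_id
    x <- as.matrix(pcs$coords[, -1, drop = FALSE])
  } else {
    x <- as.matrix(pcs)
    ids <- rownames(x) %||% sprintf("S%04d", seq_len(nrow(x)))
  }
  x <- x[, seq_len(min(n_pcs, ncol(x))), drop = FALSE]
  km <- with_op_seed(seed, "assign_groups",
                     stats::kmeans(x, centers = k, nstart = 20L))
  dists <- vapply(seq_len(k), function(j) {
    sqrt(rowSums(sweep(x, 2, km$centers[j, ], `-`)^2))
  }, numeric(nrow(x)))
  w <- 1 / pmax(dists, 1e-12)
  props <- w / rowSums(w)

  labels <- paste0("C", seq_len(k))
  if (!is.null(latitude)) {
    lab <- rep(NA_character_, k)
    if (!is.null(is_wild)) {
      wild_frac <- vapply(seq_len(k),
                          function(j) mean(is_wild[km$cluster == j]),
                          numeric(1))
      wild_cl <- which.max(wild_frac)
      if (wild_frac[wild_cl] > 0.5) lab[wild_cl] <- "WILD"
    }
    rest <- which(is.na(lab))
    mean_lat <- vapply(rest,
                       function(j) mean(latitude[km$cluster == j]),
                       numeric(1))
    lr_names <- c("NR", "HR", "SR", paste0("C", seq_len(k)))[
      seq_along(rest)]
    lab[rest[order(mean_lat, decreasing = TRUE)]] <- lr_names
    labels <- lab
  }

  top <- apply(props, 1, max)
  out <- tibble::tibble(
    sample_id = ids,
    cluster = km$cluster,
    label = ifelse(top < admixture_threshold, "MIXED",
                   labels[km$cluster]),
    max_prop = top
  )
  colnames(props) <- paste0("prop_", labels)
  dplyr::bind_cols(out, tibble::as_tibble(props))
}
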
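#' Pairwise correlation of TCM spectra
#'
#' The similarity metric of the chemotyping dendrogram: the product-moment
#' correlation between two individuals' fingerprints. Because correlation is
#' invariant to per-individual affine rescaling it compares spectral shapes,
#' not amounts. Spearman rank correlation is available as an option.
#'
#' @param specs list of `tcm_spectrum` objects (or an individuals-by-bins
#'   matrix) with identical bin labels; at least two individuals.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return an object of class `similarity_matrix`: list with `ids` and `r`
#'   (symmetric correlation matrix, unit diagonal).
#' @export
correlation_matrix <- function(specs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (is.matrix(specs)) specs else tcm_matrix(specs)
  if (nrow(m) < 2L) stopf("need at least two spectra")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stopf("correlation undefined for zero-variance spectrum of individual '%s'",
          rownames(m)[which(v == 0)[1]])
  }
  r <- stats::cor(t(m), method = method)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(ids = rownames(m), r = r, method = method),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("Similarity matrix (%s correlation): %d individuals, off-diagonal r in [%.3f, %.3f]\n",
              x$method, length(x$ids), min(off), max(off)))
  invisible(x)
}

# Lexicographic comparison of two merge candidates' id-pair keys.
pair_before <- function(a, b) {
  if (a[1] != b[1]) a[1] < b[1] else a[2] < b[2]
}

#' Agglomerative dendrogram on correlation distance
#'
#' Hierarchical clustering of individuals on the distance `d = 1 - r`, where
#' `r` is the correlation similarity. Linkages: average (UPGMA, default),
#' complete, single; all three are monotone, so merge heights never decrease.
#' Ties in the minimum inter-cluster distance are broken by the
#' lexicographically smallest pair of cluster keys (a cluster's key is its
#' smallest member id), which makes the tree invariant to input order.
#'
#' The result inherits from `hclust`, so `plot()`, `stats::cutree()`,
#' `as.dendrogram()` and `ape::as.phylo()` all apply.
#'
#' @param sim a [correlation_matrix()] result.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of class `c("chemo_dendrogram", "hclust")`.
#' @export
build_dendrogram <- function(sim, linkage = c("average", "complete", "single")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  linkage <- match.arg(linkage)
  r <- sim$r
  if (!isTRUE(all.equal(r, t(r)))) stopf("similarity matrix is not symmetric")
  d <- 1 - r
  ids <- sim$ids
  n <- length(ids)
  if (n < 2L) stopf("need at least two individuals")

  members <- lapply(seq_len(n), identity)   # original indices per active cluster
  codes <- -seq_len(n)                      # hclust merge codes
  keys <- ids                               # smallest member id per cluster
  linker <- switch(linkage, average = mean, complete = max, single = min)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dij <- linker(d[members[[i]], members[[j]]])
        key <- sort(c(keys[i], keys[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 && pair_before(key, best$key))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    ci <- codes[best$i]; cj <- codes[best$j]
    merge[step, ] <- if (keys[best$i] <= keys[best$j]) c(ci, cj) else c(cj, ci)
    height[step] <- best$d
    members[[best$i]] <- c(members[[best$i]], members[[best$j]])
    keys[best$i] <- min(keys[best$i], keys[best$j])
    codes[best$i] <- step
    members[[best$j]] <- NULL
    keys <- keys[-best$j]
    codes <- codes[-best$j]
  }

  leaf_order <- function(k) {
    unlist(lapply(merge[k, ], function(code) {
      if (code < 0) -code else leaf_order(code)
    }))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1L), labels = ids,
                 method = linkage, dist.method = "1 - correlation",
                 call = match.call()),
            class = c("chemo_dendrogram", "hclust"))
}

#' @export
print.chemo_dendrogram <- function(x, ...) {
  cat(sprintf("Chemotype dendrogram: %d individuals, %s linkage on 1 - r, merge heights %.3f-%.3f\n",
              length(x$labels), x$method, min(x$height), max(x$height)))
  invisible(x)
}

#' Cut the dendrogram at a similarity threshold
#'
#' Chemo-groups are the maximal subtrees whose internal merge heights are all
#' at most `1 - threshold`; the published analysis used an (arbitrary)
#' similarity cut-off of 0.3. Group labels CG1, CG2, ... are assigned by
#' first appearance in individual order.
#'
#' @param dend a [build_dendrogram()] result.
#' @param threshold similarity in `[-1, 1]`; default 0.3.
#' @return an object of class `chemo_groups`: list with `threshold`,
#'   `assignment` (named character vector id -> group label) and `groups`
#'   (list of member ids per label).
#' @export
cut_groups <- function(dend, threshold = 0.3) {
  stopifnot(inherits(dend, "chemo_dendrogram"))
  if (!is_number(threshold) || threshold < -1 || threshold > 1) {
    stopf("threshold must lie in [-1, 1]")
  }
  h <- 1 - threshold
  n <- length(dend$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of <- integer(n - 1L)  # representative leaf of each merge row
  for (k in seq_len(n - 1L)) {
    reps <- vapply(dend$merge[k, ], function(code) {
      if (code < 0) -code else cluster_of[code]
    }, integer(1))
    if (dend$height[k] <= h) {
      parent[find(reps[2])] <- find(reps[1])
    }
    cluster_of[k] <- reps[1]
  }
  root <- vapply(seq_len(n), find, integer(1))
  first <- !duplicated(root)
  labels_map <- stats::setNames(paste0("CG", seq_len(sum(first))), root[first])
  assignment <- stats::setNames(unname(labels_map[as.character(root)]), dend$labels)
  structure(list(threshold = threshold, assignment = assignment,
                 groups = split(names(assignment), assignment)),
            class = "chemo_groups")
}

#' @export
print.chemo_groups <- function(x, ...) {
  cat(sprintf("Chemo-groups at similarity threshold %.3g: %d groups over %d individuals\n",
              x$threshold, length(x$groups), length(x$assignment)))
  sizes <- lengths(x$groups)
  for (g in names(x$groups)) cat(sprintf("  %s: %d\n", g, sizes[[g]]))
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are in correlation-distance units (`1 - r`).
#' @param dend a [build_dendrogram()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "chemo_dendrogram"))
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Principal component analysis of TCM spectra
#'
#' Column-centred (no variance scaling) PCA of the individuals-by-bins
#' fingerprint matrix, used to adjudicate dendrogram groupings: groups merged
#' by correlation may still separate in PC space, and apparent splits may
#' collapse.
#'
#' @param specs list of `tcm_spectrum` objects or an individuals-by-bins
#'   matrix.
#' @param n_components number of components to retain; truncated (with a
#'   warning) if it exceeds the available rank.
#' @return an object of class `tcm_pca`: list with `ids`, `scores`,
#'   `loadings`, `explained_variance` (per retained component) and
#'   `total_variance` (of the centred matrix).
#' @export
tcm_pca <- function(specs, n_components = 2L) {
  m <- if (is.matrix(specs)) specs else tcm_matrix(specs)
  if (nrow(m) < 2L) stopf("need at least two spectra")
  if (!is_count(n_components)) stopf("n_components must be a count >= 1")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  avail <- length(p$sdev)
  k <- min(n_components, avail)
  if (k < n_components) {
    warnf("n_components = %d exceeds the available rank %d; truncated",
          n_components, avail)
  }
  ev <- p$sdev^2
  structure(list(ids = rownames(m),
                 scores = p$x[, seq_len(k), drop = FALSE],
                 loadings = p$rotation[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 total_variance = sum(ev),
                 center = p$center),
            class = "tcm_pca")
}

#' @export
print.tcm_pca <- function(x, ...) {
  prop <- x$explained_variance / x$total_variance
  cat(sprintf("PCA of TCM spectra: %d individuals, %d components (%s of variance)\n",
              length(x$ids), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * prop), collapse = " + ")))
  invisible(x)
}

#' @export
plot.tcm_pca <- function(x, labels = NULL, dims = c(1L, 2L), ...) {
  s <- x$scores[, dims, drop = FALSE]
  col <- if (is.null(labels)) 1L else as.integer(factor(labels[x$ids]))
  graphics::plot(s, col = col, pch = 19,
                 xlab = sprintf("PC%d", dims[1]), ylab = sprintf("PC%d", dims[2]), ...)
  invisible(x)
}

#' Separation of labelled groups in PC space
#'
#' For every pair of groups, the separation ratio is the distance between
#' group centroids in the first `dims` principal components divided by the
#' pooled mean within-group distance to centroid. Pairs with ratio at least
#' `s_sep` are called `"separated"`, at most `s_overlap` `"overlapping"`, and
#' `"indeterminate"` otherwise. A coincident pair of point groups has ratio 0.
#'
#' @param pca a [tcm_pca()] result.
#' @param labels named character vector: individual id -> group label. Ids
#'   absent from `labels` are ignored; each used group needs >= 1 member.
#' @param dims number of leading components to use (default 2).
#' @param s_sep,s_overlap classification thresholds (defaults 2 and 1).
#' @return data.frame with one row per group pair: `group_a`, `group_b`,
#'   `centroid_distance`, `within_distance`, `ratio`, `status`.
#' @export
group_separation <- function(pca, labels, dims = 2L, s_sep = 2, s_overlap = 1) {
  stopifnot(inherits(pca, "tcm_pca"))
  if (is.null(names(labels))) stopf("labels must be a named vector")
  ids <- intersect(pca$ids, names(labels))
  if (length(ids) < 2L) stopf("need at least two labelled individuals with PCA scores")
  dims <- min(as.integer(dims), ncol(pca$scores))
  s <- pca$scores[ids, seq_len(dims), drop = FALSE]
  grp <- labels[ids]
  glev <- unique(grp)
  if (length(glev) < 2L) stopf("need at least two groups")
  centroids <- t(vapply(glev, function(g) colMeans(s[grp == g, , drop = FALSE]),
                        numeric(dims)))
  within <- lapply(glev, function(g) {
    x <- s[grp == g, , drop = FALSE]
    sqrt(rowSums((x - matrix(centroids[match(g, glev), ], nrow(x), dims,
                             byrow = TRUE))^2))
  })
  names(within) <- glev
  pairs <- utils::combn(glev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dc <- sqrt(sum((centroids[match(a, glev), ] - centroids[match(b, glev), ])^2))
    wd <- mean(c(within[[a]], within[[b]]))
    ratio <- if (wd == 0) { if (dc == 0) 0 else Inf } else dc / wd
    status <- if (ratio >= s_sep) "separated"
              else if (ratio <= s_overlap) "overlapping"
              else "indeterminate"
    data.frame(group_a = a, group_b = b, centroid_distance = dc,
               within_distance = wd, ratio = ratio, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a similarity matrix as TSV
#' @param sim a [correlation_matrix()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(individual_id = sim$ids, sim$r, check.names = FALSE)
  write_stamped_tsv(df, path, config_fingerprint(sim$method))
}
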
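as_label_vector <- function(x, what) {
  if (inherits(x, "chemo_groups")) return(x$assignment)
  if (inherits(x, "phylogroup_assignment")) return(x$assignment)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stopf("%s must be a named label vector (or a chemo_groups/phylogroup_assignment object)",
          what)
  }
  stats::setNames(as.character(x), names(x))
}

#' Cross-tabulate two labelings of the same individuals
#'
#' Builds the contingency table of co-scored individuals; ids present in only
#' one labeling are excluded and reported, never silently dropped. Row and
#' column categories are ordered by first appearance.
#'
#' @param a,b named label vectors (id -> group), or `chemo_groups` /
#'   `phylogroup_assignment` objects.
#' @return an object of class `crosstab`: list with `counts` (matrix),
#'   `margins` (row/col sums), `n` (co-scored individuals), `excluded_a`,
#'   `excluded_b`.
#' @export
crosstab <- function(a, b) {
  a <- as_label_vector(a, "a")
  b <- as_label_vector(b, "b")
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) stopf("no individual is present in both labelings")
  fa <- factor(a[shared], levels = unique(a[shared]))
  fb <- factor(b[shared], levels = unique(b[shared]))
  counts <- unclass(table(fa, fb))
  names(dimnames(counts)) <- NULL
  structure(list(counts = counts,
                 margins = list(rows = rowSums(counts), cols = colSums(counts)),
                 n = length(shared),
                 excluded_a = setdiff(names(a), shared),
                 excluded_b = setdiff(names(b), shared)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("Cross-tabulation of %d co-scored individuals", x$n))
  nex <- length(x$excluded_a) + length(x$excluded_b)
  if (nex) cat(sprintf(" (%d ids present in only one labeling excluded)", nex))
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Mapping cardinality of row groups onto column groups
#'
#' For each row group of a cross-tabulation, its cardinality is the number of
#' column groups it intersects. Reported as fractions of row groups mapping
#' to exactly 1, exactly 2, and 3 or more column groups (the bins generalize
#' the published single / two / several breakdown), plus the per-group
#' detail.
#'
#' @param ct a [crosstab()] result.
#' @return list with `fractions` (named numeric: `one`, `two`,
#'   `three_plus`; sums to 1) and `detail` (data.frame group/cardinality).
#' @export
mapping_cardinality <- function(ct) {
  stopifnot(inherits(ct, "crosstab"))
  card <- apply(ct$counts > 0, 1, sum)
  fractions <- c(one = mean(card == 1), two = mean(card == 2),
                 three_plus = mean(card >= 3))
  list(fractions = fractions,
       detail = data.frame(group = rownames(ct$counts),
                           cardinality = as.integer(card),
                           stringsAsFactors = FALSE))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same individuals: 1 for identical partitions (up to relabelling),
#' expectation 0 under random labels. Only co-scored ids enter. When both
#' partitions consist of a single group the index is taken as 1 (the
#' partitions are identical); this convention resolves the 0/0 case of the
#' pair-counting formula.
#'
#' @param a,b named label vectors or group objects, as in [crosstab()].
#' @return numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  a <- as_label_vector(a, "a")
  b <- as_label_vector(b, "b")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 2L) stopf("need at least two co-scored individuals")
  x <- a[shared]
  y <- b[shared]
  if (length(unique(x)) == 1L && length(unique(y)) == 1L) return(1)
  mclust::adjustedRandIndex(x, y)
}

#' Screen for chemo-group/phylogroup exceptions
#'
#' Flags the two disagreement patterns between chemical and genetic
#' groupings and adjudicates each on principal-component scores with
#' [group_separation()]:
#' \describe{
#'   \item{split phylogroup}{one phylogroup spans two or more chemo-groups.
#'     If the chemo-subgroups overlap in PC space the split is adjudicated
#'     `"not-differentiated"` (an artifact of the similarity cut); if they
#'     separate, `"differentiated"` (a real within-phylogroup chemical
#'     difference); otherwise `"indeterminate"`.}
#'   \item{shared chemistry}{one chemo-group spans two or more phylogroups.
#'     If the phylogroup subclouds separate in PC space the sharing is
#'     adjudicated `"convergent"` (distinct chemistries merged by the
#'     dendrogram cut); if they overlap and the phylogroups are adjacent on a
#'     supplied tree (their tips are jointly monophyletic),
#'     `"single-origin-candidate"`; if they overlap without a tree
#'     (or are not adjacent), `"unresolved-shared"`; otherwise
#'     `"indeterminate"`.}
#' }
#'
#' @param groups a [cut_groups()] result.
#' @param phylo a [phylogroup_assignment()] (or named label vector).
#' @param pca a [tcm_pca()] result covering the co-scored individuals.
#' @param tree optional `ape::phylo` tree with phylogroup-labelled tips used
#'   to judge relatedness for shared-chemistry overlaps.
#' @param dims,s_sep,s_overlap passed to [group_separation()].
#' @return data.frame with columns `type`, `unit` (the phylogroup or
#'   chemo-group flagged), `members` (comma-separated counterpart labels),
#'   `ratio`, `status`; zero rows when the groupings are concordant.
#' @export
exception_screen <- function(groups, phylo, pca, tree = NULL,
                             dims = 2L, s_sep = 2, s_overlap = 1) {
  stopifnot(inherits(groups, "chemo_groups"), inherits(pca, "tcm_pca"))
  chem <- groups$assignment
  gen <- as_label_vector(phylo, "phylo")
  ids <- intersect(names(chem), names(gen))
  if (length(ids) < 2L) stopf("need at least two co-scored individuals")
  missing_pca <- setdiff(ids, pca$ids)
  if (length(missing_pca)) {
    stopf("PCA result lacks scores for: %s", paste(missing_pca, collapse = ", "))
  }
  chem <- chem[ids]
  gen <- gen[ids]
  rows <- list()

  adjudicate <- function(sub_labels) {
    sep <- group_separation(pca, sub_labels, dims = dims,
                            s_sep = s_sep, s_overlap = s_overlap)
    # one pooled judgement across all involved pairs: worst-case ratio rules
    if (all(sep$status == "separated")) "separated"
    else if (all(sep$status == "overlapping")) "overlapping"
    else "indeterminate"
  }
  mean_ratio <- function(sub_labels) {
    sep <- group_separation(pca, sub_labels, dims = dims,
                            s_sep = s_sep, s_overlap = s_overlap)
    mean(sep$ratio[is.finite(sep$ratio)])
  }

  for (pg in unique(gen)) {
    members <- ids[gen == pg]
    cgs <- unique(chem[members])
    if (length(cgs) >= 2L) {
      sub <- chem[members]
      verdict <- adjudicate(sub)
      status <- switch(verdict,
                       overlapping = "not-differentiated",
                       separated = "differentiated",
                       "indeterminate")
      rows[[length(rows) + 1L]] <- data.frame(
        type = "split_phylogroup", unit = pg,
        members = paste(sort(cgs), collapse = ","),
        ratio = mean_ratio(sub), status = status, stringsAsFactors = FALSE)
    }
  }
  for (cg in unique(chem)) {
    members <- ids[chem == cg]
    pgs <- unique(gen[members])
    if (length(pgs) >= 2L) {
      sub <- gen[members]
      verdict <- adjudicate(sub)
      status <- if (verdict == "separated") {
        "convergent"
      } else if (verdict == "overlapping") {
        if (!is.null(tree) && phylogroups_adjacent(tree, gen, pgs)) {
          "single-origin-candidate"
        } else "unresolved-shared"
      } else "indeterminate"
      rows[[length(rows) + 1L]] <- data.frame(
        type = "shared_chemistry", unit = cg,
        members = paste(sort(pgs), collapse = ","),
        ratio = mean_ratio(sub), status = status, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(type = character(), unit = character(),
                      members = character(), ratio = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# TRUE when the tips of the given phylogroups are jointly monophyletic on the
# tree: their MRCA's clade contains no other tips at all.
phylogroups_adjacent <- function(tree, assignment, pgs) {
  tips <- names(assignment)[assignment %in% pgs]
  tips <- intersect(tree$tip.label, tips)
  if (length(tips) < 2L) return(FALSE)
  mrca <- ape::getMRCA(tree, tips)
  if (is.null(mrca)) return(FALSE)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  length(setdiff(clade_tips, tips)) == 0L
}

#' Full chemical/genetic concordance report
#'
#' Bundles the cross-tabulation of chemo-groups against phylogroups, the
#' mapping-cardinality fractions in both directions, the adjusted Rand index,
#' and the adjudicated exception list. The numeric summaries (ARI, cardinality
#' fractions) are this package's operationalization of concordance; the
#' published analysis stated the patterns verbally.
#'
#' @param groups a [cut_groups()] result.
#' @param phylo a [phylogroup_assignment()] or named label vector.
#' @param pca a [tcm_pca()] result for exception adjudication.
#' @param tree optional phylogroup-labelled `ape::phylo` tree.
#' @param ... passed to [exception_screen()].
#' @return an object of class `concordance_report`: list with `crosstab`,
#'   `cardinality_chemo_to_phylo`, `cardinality_phylo_to_chemo`,
#'   `agreement_index`, `exceptions`, `excluded`.
#' @export
concordance_report <- function(groups, phylo, pca, tree = NULL, ...) {
  ct <- crosstab(groups, phylo)
  gen <- as_label_vector(phylo, "phylo")
  tc <- crosstab(gen, groups)
  structure(list(
    crosstab = ct,
    cardinality_chemo_to_phylo = mapping_cardinality(ct),
    cardinality_phylo_to_chemo = mapping_cardinality(tc),
    agreement_index = adjusted_rand(groups, phylo),
    exceptions = exception_screen(groups, phylo, pca, tree = tree, ...),
    excluded = list(chemo_only = ct$excluded_a, phylo_only = ct$excluded_b)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  print(x$crosstab)
  f <- x$cardinality_phylo_to_chemo$fractions
  cat(sprintf("Phylogroups mapping to 1 / 2 / >=3 chemo-groups: %.0f%% / %.0f%% / %.0f%%\n",
              100 * f["one"], 100 * f["two"], 100 * f["three_plus"]))
  g <- x$cardinality_chemo_to_phylo$fractions
  cat(sprintf("Chemo-groups mapping to 1 / 2 / >=3 phylogroups: %.0f%% / %.0f%% / %.0f%%\n",
              100 * g["one"], 100 * g["two"], 100 * g["three_plus"]))
  cat(sprintf("Adjusted Rand index: %.3f\n", x$agreement_index))
  if (nrow(x$exceptions)) {
    cat("Exceptions:\n")
    print(x$exceptions)
  } else {
    cat("No exceptions: groupings are concordant.\n")
  }
  invisible(x)
}

#' @export
summary.concordance_report <- function(object, ...) {
  print(object)
  invisible(object)
}

report_to_list <- function(report) {
  list(
    n_co_scored = report$crosstab$n,
    counts = as.data.frame(as.table(report$crosstab$counts)),
    agreement_index = report$agreement_index,
    cardinality_chemo_to_phylo = as.list(report$cardinality_chemo_to_phylo$fractions),
    cardinality_phylo_to_chemo = as.list(report$cardinality_phylo_to_chemo$fractions),
    exceptions = report$exceptions,
    excluded = report$excluded)
}

#' Write a concordance report as JSON (plus a TSV crosstab)
#'
#' @param report a [concordance_report()] result.
#' @param json_path output JSON file.
#' @param crosstab_path optional TSV for the contingency table.
#' @return invisibly, `json_path`.
#' @export
write_concordance <- function(report, json_path, crosstab_path = NULL) {
  stopifnot(inherits(report, "concordance_report"))
  payload <- c(list(chemotax_version = chemotax_version()), report_to_list(report))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(crosstab_path)) {
    df <- data.frame(chemo_group = rownames(report$crosstab$counts),
                     report$crosstab$counts, check.names = FALSE)
    write_stamped_tsv(df, crosstab_path)
  }
  invisible(json_path)
}
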
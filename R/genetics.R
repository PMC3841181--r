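GENE_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-", "?")

#' Construct and validate a gene partition
#'
#' An aligned set of sequences for one gene. All sequences must have equal
#' length and use the nucleotide alphabet (IUPAC ambiguity codes, `-` for
#' gaps, `?` for missing). Protein-coding partitions (COI, ANT by default)
#' are checked for internal stop codons in the stated reading frame; COI is
#' translated with the invertebrate mitochondrial code (TGA = Trp), nuclear
#' genes with the standard code.
#'
#' @param gene gene name (e.g. `"COI"`, `"16S"`, `"ANT"`).
#' @param sequences named character vector of aligned sequences.
#' @param coding whether to run the stop-codon check; defaults to TRUE for
#'   COI and ANT.
#' @param frame reading frame offset (1, 2 or 3).
#' @return an object of class `gene_partition`: list with `gene`,
#'   `sequences`, `length`.
#' @export
gene_partition <- function(gene, sequences, coding = gene %in% c("COI", "ANT"),
                           frame = 1L) {
  if (!is_string(gene)) stopf("gene must be a non-empty string")
  if (length(sequences) == 0L || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stopf("sequences must be a non-empty, fully named character vector")
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stopf("gene '%s': ragged alignment (sequence lengths %s)", gene,
          paste(sort(unique(lens)), collapse = ", "))
  }
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
  bad <- setdiff(chars, GENE_ALPHABET)
  if (length(bad)) stopf("gene '%s': illegal characters: %s", gene,
                         paste(bad, collapse = " "))
  if (isTRUE(coding)) {
    if (!frame %in% 1:3) stopf("frame must be 1, 2 or 3")
    stops <- stop_codons(gene)
    for (id in names(sequences)) {
      s <- substring(sequences[[id]], frame)
      n_codon <- nchar(s) %/% 3L
      if (n_codon > 1L) {
        codons <- substring(s, 3L * (seq_len(n_codon - 1L) - 1L) + 1L,
                            3L * (seq_len(n_codon - 1L)))
        hit <- which(codons %in% stops)
        if (length(hit)) {
          stopf("gene '%s', individual '%s': internal stop codon %s at codon %d",
                gene, id, codons[hit[1]], hit[1])
        }
      }
    }
  }
  structure(list(gene = gene, sequences = sequences,
                 length = unname(lens[1]), coding = isTRUE(coding)),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("Gene partition %s: %d sequences x %d columns%s\n", x$gene,
              length(x$sequences), x$length,
              if (x$coding) " (protein-coding)" else ""))
  invisible(x)
}

#' Read an aligned FASTA file as a gene partition
#' @param gene gene name.
#' @param path FASTA file.
#' @param ... passed to [gene_partition()].
#' @return a [gene_partition()].
#' @export
read_gene_partition <- function(gene, path, ...) {
  ss <- Biostrings::readBStringSet(path)
  gene_partition(gene, stats::setNames(as.character(ss), names(ss)), ...)
}

#' Write a gene partition (or concatenated alignment) as FASTA
#' @param x a `gene_partition` or `concatenated_alignment`.
#' @param path output FASTA.
#' @return invisibly, `path`.
#' @export
write_alignment_fasta <- function(x, path) {
  seqs <- if (inherits(x, "gene_partition")) x$sequences
          else if (inherits(x, "concatenated_alignment")) x$sequences
          else stopf("x must be a gene_partition or concatenated_alignment")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Concatenate gene partitions with a minimum-gene inclusion rule
#'
#' Joins per-gene alignments column-wise per individual. Individuals present
#' in fewer than `min_genes` partitions are excluded (and reported in the
#' exclusion manifest); genes absent for an included individual are padded
#' with `?`, and existing alignment gaps (`-`) are preserved — both are
#' treated as missing data downstream. The combined length always equals the
#' sum of the partition lengths.
#'
#' @param partitions list of [gene_partition()] objects.
#' @param min_genes minimum number of partitions an individual must carry
#'   (default 2, i.e. two of three genes).
#' @return an object of class `concatenated_alignment`: list with `ids`,
#'   `sequences`, `boundaries` (data.frame gene/start/end), `total_length`,
#'   `excluded` (manifest data.frame), `min_genes`.
#' @export
concatenate_partitions <- function(partitions, min_genes = 2L) {
  if (inherits(partitions, "gene_partition")) partitions <- list(partitions)
  if (length(partitions) == 0L) stopf("need at least one partition")
  ok <- vapply(partitions, inherits, logical(1), "gene_partition")
  if (!all(ok)) stopf("all elements must be gene_partition objects")
  genes <- vapply(partitions, `[[`, character(1), "gene")
  if (anyDuplicated(genes)) stopf("duplicated gene partitions: %s",
                                  paste(genes[duplicated(genes)], collapse = ", "))
  if (!is_count(min_genes)) stopf("min_genes must be a count >= 1")
  all_ids <- unique(unlist(lapply(partitions, function(p) names(p$sequences))))
  n_genes <- vapply(all_ids, function(id) {
    sum(vapply(partitions, function(p) id %in% names(p$sequences), logical(1)))
  }, integer(1))
  keep <- n_genes >= min_genes
  excluded <- data.frame(
    individual_id = all_ids[!keep], n_genes = unname(n_genes[!keep]),
    genes = vapply(all_ids[!keep], function(id) {
      paste(genes[vapply(partitions, function(p) id %in% names(p$sequences),
                         logical(1))], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  ids <- all_ids[keep]
  if (length(ids) == 0L) stopf("no individual satisfies the %d-gene inclusion rule",
                               min_genes)
  lens <- vapply(partitions, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  boundaries <- data.frame(gene = genes, start = c(1L, utils::head(ends, -1) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  sequences <- vapply(ids, function(id) {
    paste(vapply(partitions, function(p) {
      if (id %in% names(p$sequences)) p$sequences[[id]]
      else strrep("?", p$length)
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(ids = ids, sequences = sequences, boundaries = boundaries,
                 total_length = sum(lens), excluded = excluded,
                 min_genes = as.integer(min_genes)),
            class = "concatenated_alignment")
}

#' @export
print.concatenated_alignment <- function(x, ...) {
  cat(sprintf("Concatenated alignment: %d individuals x %d characters (%s); %d excluded by the %d-gene rule\n",
              length(x$ids), x$total_length,
              paste(sprintf("%s: %d", x$boundaries$gene,
                            x$boundaries$end - x$boundaries$start + 1L),
                    collapse = "; "),
              nrow(x$excluded), x$min_genes))
  invisible(x)
}

IUPAC_PAIR <- c("AC" = "M", "AG" = "R", "AT" = "W",
                "CG" = "S", "CT" = "Y", "GT" = "K")

#' Code heterozygous SNP sites as IUPAC ambiguities
#'
#' Replaces each listed site with the two-base IUPAC ambiguity code
#' (A/G = R, C/T = Y, A/C = M, G/T = K, A/T = W, C/G = S). The site must
#' currently hold an unambiguous base, so re-applying the coding raises an
#' error rather than silently double-coding.
#'
#' @param seq a single sequence string.
#' @param het_sites data.frame with columns `position` (1-based), `base1`,
#'   `base2`.
#' @return the recoded sequence string.
#' @export
code_ambiguity <- function(seq, het_sites) {
  if (!is_string(seq)) stopf("seq must be a single sequence string")
  if (is.null(het_sites) || nrow(as.data.frame(het_sites)) == 0L) return(seq)
  het_sites <- as.data.frame(het_sites)
  if (!all(c("position", "base1", "base2") %in% names(het_sites))) {
    stopf("het_sites needs columns position, base1, base2")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(het_sites))) {
    pos <- het_sites$position[i]
    b1 <- toupper(het_sites$base1[i]); b2 <- toupper(het_sites$base2[i])
    if (!is_count(pos) || pos > length(chars)) stopf("position %s outside sequence", pos)
    if (!b1 %in% c("A", "C", "G", "T") || !b2 %in% c("A", "C", "G", "T")) {
      stopf("bases must be A, C, G or T")
    }
    if (b1 == b2) stopf("site %d: identical bases '%s' have no two-base ambiguity code",
                        pos, b1)
    if (!chars[pos] %in% c("A", "C", "G", "T")) {
      stopf("site %d already holds non-unambiguous base '%s'; refusing to re-code",
            pos, chars[pos])
    }
    key <- paste(sort(c(b1, b2)), collapse = "")
    chars[pos] <- IUPAC_PAIR[[key]]
  }
  paste(chars, collapse = "")
}

#' Describe an MCMC tree-sampling plan
#'
#' @param n_runs independent runs.
#' @param n_generations generations per run.
#' @param sample_freq generations between samples; must divide
#'   `n_generations`.
#' @param burnin_frac fraction of each run's samples discarded (0 <= f < 1).
#' @param include_generation_zero whether the state at generation 0 is
#'   sampled (TRUE for the common MrBayes convention).
#' @return an object of class `tree_sample_plan`.
#' @export
tree_sample_plan <- function(n_runs, n_generations, sample_freq,
                             burnin_frac = 0.1, include_generation_zero = TRUE) {
  if (!is_count(n_runs) || !is_count(n_generations) || !is_count(sample_freq)) {
    stopf("n_runs, n_generations and sample_freq must be counts >= 1")
  }
  if (n_generations %% sample_freq != 0) {
    stopf("sample_freq %d does not divide n_generations %d evenly",
          sample_freq, n_generations)
  }
  if (!is_number(burnin_frac) || burnin_frac < 0 || burnin_frac >= 1) {
    stopf("burnin_frac must satisfy 0 <= f < 1")
  }
  if (!is_flag(include_generation_zero)) stopf("include_generation_zero must be TRUE/FALSE")
  structure(list(n_runs = n_runs, n_generations = n_generations,
                 sample_freq = sample_freq, burnin_frac = burnin_frac,
                 include_generation_zero = include_generation_zero),
            class = "tree_sample_plan")
}

#' Count trees retained after burn-in
#'
#' Per run, `n_generations / sample_freq` samples are drawn (plus one for
#' generation zero when included); `floor(burnin_frac * samples)` are
#' discarded per run; the retained total is summed over runs.
#'
#' @param plan a [tree_sample_plan()].
#' @return an object of class `posterior_accounting`: list with
#'   `samples_per_run`, `discarded_per_run`, `retained_per_run`, `retained`.
#' @export
posterior_sample_accounting <- function(plan) {
  stopifnot(inherits(plan, "tree_sample_plan"))
  samples <- plan$n_generations / plan$sample_freq +
    as.integer(plan$include_generation_zero)
  discarded <- floor(plan$burnin_frac * samples)
  retained_per_run <- samples - discarded
  structure(list(samples_per_run = samples, discarded_per_run = discarded,
                 retained_per_run = retained_per_run,
                 retained = plan$n_runs * retained_per_run, plan = plan),
            class = "posterior_accounting")
}

#' @export
print.posterior_accounting <- function(x, ...) {
  cat(sprintf("Posterior sample accounting: %d runs x %s samples, %s discarded per run -> %s retained\n",
              x$plan$n_runs, format(x$samples_per_run, big.mark = ","),
              format(x$discarded_per_run, big.mark = ","),
              format(x$retained, big.mark = ",")))
  invisible(x)
}

#' Per-individual phylogroup labels
#'
#' @param assignment named character vector: individual id -> phylogroup.
#' @param nuclear_cluster optional named character vector: individual id ->
#'   nuclear cluster label.
#' @param source `"provided"` or `"distance_threshold"`.
#' @return an object of class `phylogroup_assignment`.
#' @export
phylogroup_assignment <- function(assignment, nuclear_cluster = NULL,
                                  source = "provided") {
  if (length(assignment) == 0L || is.null(names(assignment)) ||
      any(!nzchar(names(assignment)))) {
    stopf("assignment must be a non-empty named character vector")
  }
  if (any(is.na(assignment)) || any(!nzchar(assignment))) {
    stopf("phylogroup labels must be non-empty for every scored individual")
  }
  if (!is.null(nuclear_cluster) && is.null(names(nuclear_cluster))) {
    stopf("nuclear_cluster must be named")
  }
  structure(list(assignment = assignment, nuclear_cluster = nuclear_cluster,
                 source = source),
            class = "phylogroup_assignment")
}

#' @export
print.phylogroup_assignment <- function(x, ...) {
  cat(sprintf("Phylogroup assignment (%s): %d individuals, %d phylogroups%s\n",
              x$source, length(x$assignment), length(unique(x$assignment)),
              if (is.null(x$nuclear_cluster)) "" else
                sprintf(", %d nuclear clusters",
                        length(unique(x$nuclear_cluster)))))
  invisible(x)
}

# Proportion of differing sites among shared unambiguous (A/C/G/T) sites.
p_distance_matrix <- function(partition, min_shared = 50L) {
  seqs <- partition$sequences
  ids <- names(seqs)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  informative <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- informative[i, ] & informative[j, ]
      if (sum(shared) < min_shared) {
        stopf("individuals '%s' and '%s' share only %d unambiguous sites (< %d)",
              ids[i], ids[j], sum(shared), min_shared)
      }
      d[i, j] <- d[j, i] <- mean(m[i, shared] != m[j, shared])
    }
  }
  d
}

#' Assign phylogroups from labels or by distance clustering
#'
#' `method = "provided"` validates that the supplied labels cover every
#' individual in the alignment and passes them through. `method =
#' "distance_threshold"` clusters individuals by single linkage on pairwise
#' p-distance (computed over shared unambiguous sites, requiring at least
#' `min_shared` of them per pair): phylogroups are the connected components
#' of the graph joining pairs with distance at most `threshold`. Labels PG1,
#' PG2, ... follow first-member appearance.
#'
#' @param partition a [gene_partition()].
#' @param method `"provided"` or `"distance_threshold"`.
#' @param threshold substitutions per site (distance mode).
#' @param labels named character vector (provided mode).
#' @param min_shared minimum shared unambiguous sites per pair.
#' @return a [phylogroup_assignment()].
#' @export
assign_phylogroups <- function(partition,
                               method = c("distance_threshold", "provided"),
                               threshold = 0.05, labels = NULL,
                               min_shared = 50L) {
  stopifnot(inherits(partition, "gene_partition"))
  method <- match.arg(method)
  ids <- names(partition$sequences)
  if (method == "provided") {
    if (is.null(labels)) stopf("provided mode needs labels")
    missing_ids <- setdiff(ids, names(labels))
    if (length(missing_ids)) stopf("labels missing for: %s",
                                   paste(missing_ids, collapse = ", "))
    return(phylogroup_assignment(labels[ids], source = "provided"))
  }
  if (!is_number(threshold) || threshold < 0) stopf("threshold must be >= 0")
  d <- p_distance_matrix(partition, min_shared = min_shared)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  first <- !duplicated(root)
  lab_map <- stats::setNames(paste0("PG", seq_len(sum(first))), root[first])
  phylogroup_assignment(stats::setNames(unname(lab_map[as.character(root)]), ids),
                        source = "distance_threshold")
}

#' Read a phylogroup table
#'
#' TSV with columns `individual_id`, `phylogroup` and optionally
#' `nuclear_cluster`.
#' @param path TSV file.
#' @return a [phylogroup_assignment()].
#' @export
read_phylogroups <- function(path) {
  df <- read_stamped_tsv(path)
  if (!all(c("individual_id", "phylogroup") %in% names(df))) {
    stopf("'%s' must have columns individual_id, phylogroup", path)
  }
  nuc <- NULL
  if ("nuclear_cluster" %in% names(df) && !all(is.na(df$nuclear_cluster))) {
    nuc <- stats::setNames(as.character(df$nuclear_cluster), df$individual_id)
  }
  phylogroup_assignment(stats::setNames(as.character(df$phylogroup),
                                        df$individual_id),
                        nuclear_cluster = nuc, source = "provided")
}

#' Write a phylogroup table
#' @param x a [phylogroup_assignment()].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_phylogroups <- function(x, path) {
  stopifnot(inherits(x, "phylogroup_assignment"))
  df <- data.frame(individual_id = names(x$assignment),
                   phylogroup = unname(x$assignment),
                   stringsAsFactors = FALSE)
  if (!is.null(x$nuclear_cluster)) {
    df$nuclear_cluster <- unname(x$nuclear_cluster[df$individual_id])
  }
  write_stamped_tsv(df, path)
}

#' Read a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()].
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("malformed Newick in '%s': %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("malformed Newick in '%s'", path)
  tree
}

#' Annotate tree tips with phylogroup labels
#'
#' Every tip found in the assignment is annotated; tips absent from it are
#' reported, not treated as errors.
#'
#' @param tree an `ape::phylo` tree.
#' @param assignment a [phylogroup_assignment()].
#' @return an object of class `annotated_tree`: list with `tree`,
#'   `tip_phylogroup` (named vector over matched tips) and `unmatched`.
#' @export
annotate_tree_tips <- function(tree, assignment) {
  stopifnot(inherits(tree, "phylo"), inherits(assignment, "phylogroup_assignment"))
  matched <- intersect(tree$tip.label, names(assignment$assignment))
  structure(list(tree = tree,
                 tip_phylogroup = assignment$assignment[matched],
                 unmatched = setdiff(tree$tip.label, matched)),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("Annotated tree: %d tips, %d annotated, %d unmatched\n",
              length(x$tree$tip.label), length(x$tip_phylogroup),
              length(x$unmatched)))
  invisible(x)
}
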
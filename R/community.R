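#' OTU count table with taxonomy and sample metadata
#'
#' Container for sorted-pool 16S amplicon data: a non-negative integer count
#' matrix (OTUs x samples), a taxonomy table with one ordered lineage per
#' OTU (domain through genus; unresolved ranks as `"unclassified"`), and
#' per-sample metadata.
#'
#' @param counts Integer matrix, rows = OTUs (rownames = OTU ids),
#'   columns = samples (colnames = sample ids).
#' @param taxonomy Data frame with columns `otu_id`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`, covering every row of `counts`.
#' @param metadata Data frame with a `sample_id` column covering every
#'   column of `counts`; typically also `group`, `treatment`, `phase`,
#'   `replicate`.
#' @return A list of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy, metadata) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_values("counts must have OTU rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_values("counts must be non-negative integers")
  missing_tax <- setdiff(rownames(counts), taxonomy$otu_id)
  if (length(missing_tax) > 0)
    stop_values("OTUs without taxonomy: %s",
                paste(utils::head(missing_tax, 5), collapse = ", "))
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta) > 0)
    stop_values("samples without metadata: %s",
                paste(utils::head(missing_meta, 5), collapse = ", "))
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu_id), ]
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  rownames(taxonomy) <- rownames(metadata) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (total reads %d)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Alpha diversity of one sample
#'
#' Computes, from the formulas (no external diversity package is called):
#' \itemize{
#'   \item `sobs`: number of observed OTUs;
#'   \item `chao1`: bias-corrected Chao1, `sobs + n1 (n1 - 1) / (2 (n2 + 1))`
#'     with `n1`, `n2` the singleton and doubleton counts;
#'   \item `ace`: abundance-based coverage estimator with rare cutoff 10
#'     (falls back to Chao1 when every rare OTU is a singleton);
#'   \item `shannon`: Shannon entropy in nats, `-sum p_i log p_i`;
#'   \item `simpson`: Simpson dominance, `sum p_i^2` (low = diverse);
#'   \item `goods_coverage`: Good's coverage, `1 - n1 / N`.
#' }
#'
#' @param counts Non-negative integer vector of OTU counts for one sample.
#' @return One-row data frame with the six indices.
#' @examples
#' alpha_diversity(c(10, 10, 10, 10))
#' @export
alpha_diversity <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop_values("sample has no reads")
  N <- sum(counts)
  sobs <- length(counts)
  n1 <- sum(counts == 1)
  n2 <- sum(counts == 2)
  chao1 <- sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
  p <- counts / N
  shannon <- -sum(p * log(p))
  simpson <- sum(p^2)
  goods <- 1 - n1 / N
  # ACE, rare cutoff 10
  rare <- counts[counts <= 10]
  abund <- counts[counts > 10]
  s_rare <- length(rare)
  n_rare <- sum(rare)
  if (s_rare == 0L) {
    ace <- length(abund)
  } else {
    c_ace <- 1 - n1 / n_rare
    if (c_ace <= 0) {
      ace <- chao1  # all rare OTUs are singletons; coverage undefined
    } else {
      fi <- tabulate(rare, nbins = 10)
      gamma2 <- max(
        s_rare / c_ace * sum(seq_len(10) * (seq_len(10) - 1) * fi) /
          (n_rare * (n_rare - 1)) - 1, 0)
      ace <- length(abund) + s_rare / c_ace + n1 / c_ace * gamma2
    }
  }
  data.frame(sobs = sobs, chao1 = chao1, ace = ace, shannon = shannon,
             simpson = simpson, goods_coverage = goods)
}

#' Alpha diversity for every sample of an OTU table
#'
#' @param otu An [otu_table()].
#' @return Data frame with one row per sample (metadata columns prepended).
#' @export
alpha_diversity_table <- function(otu) {
  idx <- do.call(rbind, lapply(seq_len(ncol(otu$counts)),
                               function(j) alpha_diversity(otu$counts[, j])))
  cbind(otu$metadata, idx)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between all sample pairs of
#' a counts (or relative abundance) matrix.
#'
#' @param mat Numeric matrix, rows = taxa, columns = samples, each column
#'   with a positive total.
#' @return Symmetric matrix of dissimilarities in `[0, 1]`, zero diagonal.
#' @examples
#' bray_curtis(cbind(a = c(1, 1), b = c(1, 0)))  # d(a,b) = 1/3
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_values("need at least 2 samples")
  tot <- colSums(mat)
  if (any(tot <= 0)) stop_values("every sample needs a positive total")
  num <- as.matrix(stats::dist(t(mat), method = "manhattan"))
  den <- outer(tot, tot, `+`)
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(colnames(mat), colnames(mat))
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by the
#' square roots of the positive eigenvalues. Negative eigenvalues (possible
#' for non-Euclidean dissimilarities such as Bray-Curtis) are reported
#' unchanged, and excluded from the axes and from the denominator of the
#' variance-explained proportions. For a deterministic orientation, each
#' axis is flipped so its largest-magnitude coordinate is positive.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes Number of axes to retain (capped at the number of positive
#'   eigenvalues).
#' @return A list of class `pcoa_result`: `coordinates` (samples x axes,
#'   column-centered), `eigenvalues` (all, decreasing), `proportion`
#'   (variance explained per retained axis, relative to the positive
#'   eigenvalue sum).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop_values("dissimilarity matrix must be square and symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  k <- min(n_axes, sum(pos))
  if (k == 0L) {
    coords <- matrix(0, n, max(1L, n_axes))
  } else {
    coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
    if (n_axes > k)
      coords <- cbind(coords, matrix(0, n, n_axes - k))
    for (ax in seq_len(k)) {
      if (coords[which.max(abs(coords[, ax])), ax] < 0)
        coords[, ax] <- -coords[, ax]
    }
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos_sum <- sum(e$values[e$values > 0])
  prop <- if (pos_sum > 0) {
    pmax(e$values[seq_len(ncol(coords))], 0) / pos_sum
  } else rep(0, ncol(coords))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 proportion = prop), class = "pcoa_result")
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components (Anderson's pseudo-F) and obtains a p-value by
#' seeded random permutation of the group labels:
#' `p = (#{F_perm >= F_obs} + 1) / (n_permutations + 1)`.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample (at least two groups, no empty
#'   group).
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return A list of class `permanova_result`: `pseudo_f`, `r_squared`,
#'   `p_value`, `df_among`, `df_within`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop_values("one group label per sample required")
  if (nlevels(groups) < 2L) stop_values("need at least 2 groups")
  if (any(table(groups) == 0L)) stop_values("empty group")
  if (n_permutations < 99L) stop_values("use at least 99 permutations")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      if (length(i) > 1L)
        s <- s + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    s
  }
  a <- nlevels(groups)
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  ssw_obs <- ss_within(groups)
  r2 <- (ss_total - ssw_obs) / ss_total
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      f_stat(groups[sample.int(n)]) >= f_obs
    }, logical(1)))
  })
  structure(list(pseudo_f = f_obs, r_squared = r2,
                 p_value = (exceed + 1) / (n_permutations + 1),
                 df_among = a - 1, df_within = n - a,
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df_among, x$df_within, x$pseudo_f, x$r_squared, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums counts over OTUs sharing the same label at the requested rank.
#' OTUs unresolved at that rank are labelled by their nearest resolved
#' coarser rank with a rank prefix (e.g. an OTU classified only to family
#' Bacillaceae aggregates at genus level as `"f__Bacillaceae"`), so
#' family-level "genera" participate in host-range sets; OTUs with no
#' resolved rank at all fall into `"unclassified"`. Per-sample totals are
#' preserved.
#'
#' @param otu An [otu_table()].
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Numeric matrix, rows = taxa at `rank`, columns = samples.
#' @export
aggregate_taxonomy <- function(otu, rank) {
  if (!rank %in% TAX_RANKS) stop_values("unknown rank '%s'", rank)
  labels <- taxon_labels(otu$taxonomy, rank)
  rs <- rowsum(otu$counts, group = labels)
  rs[order(rownames(rs)), , drop = FALSE]
}

# Label each OTU at `rank`, backing off to the nearest resolved coarser rank
# with a prefix (p__/c__/o__/f__) when the rank itself is unclassified.
taxon_labels <- function(taxonomy, rank) {
  ri <- match(rank, TAX_RANKS)
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  vapply(seq_len(nrow(taxonomy)), function(i) {
    val <- taxonomy[[rank]][i]
    if (!is.na(val) && val != "unclassified" && !grepl("^unclassified", val))
      return(val)
    for (j in rev(seq_len(ri - 1))) {
      v <- taxonomy[[TAX_RANKS[j]]][i]
      if (!is.na(v) && v != "unclassified")
        return(paste0(prefixes[j], v))
    }
    "unclassified"
  }, character(1))
}

#' Relative abundance per sample
#'
#' @param mat Counts matrix (taxa x samples) with positive column totals.
#' @return Matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(mat) {
  tot <- colSums(mat)
  if (any(tot <= 0)) stop_values("every sample needs a positive total")
  sweep(mat, 2, tot, `/`)
}

#' Host-range set summary (shared / unique / core genera)
#'
#' Given genus presence sets per group (e.g. per composting phase or per
#' treatment), computes pairwise shared counts, per-group unique counts
#' (genera in one group and no other), the core set (intersection of all
#' groups), and the shared percentage under both candidate denominators:
#' the union of all groups and each group's own size.
#'
#' @param sets Named list (>= 2 entries) of character vectors.
#' @return A list of class `host_range_summary`: `sets`, `sizes`,
#'   `pairwise_shared` (matrix), `unique_counts`, `core`,
#'   `shared_pct_union` (`100 |core| / |union|`), `shared_pct_per_group`
#'   (`100 |core| / |group|`).
#' @examples
#' host_range_summary(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
host_range_summary <- function(sets) {
  if (length(sets) < 2L) stop_values("need at least 2 groups")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_values("sets must be named")
  sets <- lapply(sets, unique)
  gs <- names(sets)
  shared <- matrix(0L, length(sets), length(sets), dimnames = list(gs, gs))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    shared[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  core <- Reduce(intersect, sets)
  un <- Reduce(union, sets)
  uniq <- vapply(seq_along(sets), function(i)
    length(setdiff(sets[[i]], Reduce(union, sets[-i]))), integer(1))
  names(uniq) <- gs
  structure(list(
    sets = sets,
    sizes = vapply(sets, length, integer(1)),
    pairwise_shared = shared,
    unique_counts = uniq,
    core = sort(core),
    shared_pct_union = 100 * length(core) / length(un),
    shared_pct_per_group = 100 * length(core) / vapply(sets, length, integer(1))
  ), class = "host_range_summary")
}

#' Genus presence sets per sample group
#'
#' Convenience helper building the input of [host_range_summary()] from an
#' OTU table: genera (with the unresolved-rank labelling of
#' [aggregate_taxonomy()]) present with at least `min_count` reads summed
#' within each metadata group.
#'
#' @param otu An [otu_table()].
#' @param group_var Metadata column to group samples by (default `"group"`).
#' @param min_count Minimum summed count for presence (default 1).
#' @return Named list of genus character vectors.
#' @export
genus_sets <- function(otu, group_var = "group", min_count = 1) {
  gmat <- aggregate_taxonomy(otu, "genus")
  groups <- otu$metadata[[group_var]]
  if (is.null(groups)) stop_values("metadata column '%s' not found", group_var)
  out <- lapply(split(seq_len(ncol(gmat)), groups), function(j) {
    tot <- rowSums(gmat[, j, drop = FALSE])
    rownames(gmat)[tot >= min_count]
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Top-N taxa relative-abundance matrix
#'
#' Ranks taxa by mean relative abundance across samples (ties broken
#' lexicographically by taxon name), keeps the top `n`, and sums the
#' remainder into an `"Other"` row so every column still sums to 1.
#'
#' @param mat Counts or relative-abundance matrix (taxa x samples).
#' @param n Number of taxa to keep.
#' @return Relative-abundance matrix with at most `n + 1` rows.
#' @export
top_n_matrix <- function(mat, n = 30) {
  if (n < 1) stop_values("n must be >= 1")
  rel <- relative_abundance(mat)
  mean_ab <- rowMeans(rel)
  ord <- order(-mean_ab, rownames(rel))
  keep <- ord[seq_len(min(n, nrow(rel)))]
  top <- rel[keep, , drop = FALSE]
  if (length(keep) < nrow(rel)) {
    other <- colSums(rel[-keep, , drop = FALSE])
    top <- rbind(top, Other = other)
  }
  top
}

#' Compare alpha diversity between groups with compact letter display
#'
#' One-way ANOVA per diversity index followed by Tukey HSD (used here as the
#' post-hoc test; Duncan's multiple range test, common in composting papers,
#' is not distribution-matched but orders groups the same way, and the
#' substitution is flagged in the output). Groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param alpha_df Output of [alpha_diversity_table()] (or any data frame
#'   with a grouping column and numeric index columns).
#' @param group_var Grouping column name.
#' @param indices Index columns to test.
#' @param alpha Significance level for the letter display.
#' @return A list of class `alpha_comparison`: per index, the group means,
#'   standard deviations, ANOVA p and letters; plus `posthoc = "TukeyHSD"`.
#' @export
compare_alpha_groups <- function(alpha_df, group_var = "group",
                                 indices = c("sobs", "chao1", "ace",
                                             "shannon", "simpson",
                                             "goods_coverage"),
                                 alpha = 0.05) {
  groups <- as.factor(alpha_df[[group_var]])
  if (nlevels(groups) < 2L) stop_values("need at least 2 groups")
  if (any(table(groups) < 2L)) stop_values("every group needs >= 2 replicates")
  res <- lapply(indices, function(ix) {
    vals <- alpha_df[[ix]]
    cmp <- compare_groups(vals, groups)
    nonsig <- build_nonsig_pairs(cmp$pairwise, levels(groups), alpha)
    letters <- letter_display(levels(groups),
                              order(-cmp$means$mean), nonsig)
    data.frame(index = ix, group = cmp$means$group, mean = cmp$means$mean,
               sd = cmp$means$sd, anova_p = cmp$anova_p,
               letters = letters[cmp$means$group],
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, res), posthoc = "TukeyHSD",
                 alpha = alpha), class = "alpha_comparison")
}

# Group labels may themselves contain "-" (e.g. "CT-TP"), so comparisons are
# matched against the full candidate strings rather than split on the dash.
build_nonsig_pairs <- function(pairwise, levels, alpha) {
  m <- matrix(TRUE, length(levels), length(levels),
              dimnames = list(levels, levels))
  for (i in seq_along(levels)) for (j in seq_along(levels)) {
    if (i >= j) next
    cand <- c(paste(levels[i], levels[j], sep = "-"),
              paste(levels[j], levels[i], sep = "-"))
    row <- which(pairwise$comparison %in% cand)
    if (length(row) >= 1L) {
      ns <- pairwise$p_adj[row[1]] >= alpha
      m[i, j] <- m[j, i] <- ns
    }
  }
  m
}

# Insert-and-absorb compact letter display: groups connected in the
# non-significance graph share a letter.
letter_display <- function(groups, order_idx, nonsig) {
  ordered <- groups[order_idx]
  cols <- list()
  for (g in ordered) {
    placed <- FALSE
    for (ci in seq_along(cols)) {
      if (all(nonsig[g, cols[[ci]]])) {
        cols[[ci]] <- c(cols[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) cols[[length(cols) + 1L]] <- g
  }
  # absorb columns fully contained in another
  keep <- rep(TRUE, length(cols))
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    if (i != j && keep[i] && keep[j] && all(cols[[i]] %in% cols[[j]]))
      keep[i] <- FALSE
  }
  cols <- cols[keep]
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) lab[g] <- paste0(lab[g], letters[ci])
  }
  lab
}

#' Seeded rarefaction to even depth
#'
#' Optional subsampling of every sample, without replacement, to a common
#' depth (the minimum column total by default). Not applied by default
#' anywhere in the pipeline.
#'
#' @param otu An [otu_table()].
#' @param depth Target depth; defaults to the minimum sample total.
#' @param seed Integer seed.
#' @return A rarefied [otu_table()].
#' @export
rarefy_table <- function(otu, depth = NULL, seed = 1L) {
  depth <- depth %||% min(colSums(otu$counts))
  if (any(colSums(otu$counts) < depth))
    stop_values("a sample has fewer than %d reads", depth)
  counts <- with_seed(seed, {
    apply(otu$counts, 2, function(x) {
      reads <- rep(seq_along(x), x)
      keep <- sample(reads, depth)
      tabulate(keep, nbins = length(x))
    })
  })
  rownames(counts) <- rownames(otu$counts)
  otu_table(counts, otu$taxonomy, otu$metadata)
}
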
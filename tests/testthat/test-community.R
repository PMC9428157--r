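random_counts <- function(n_max = 60) {
  n <- sample(5:n_max, 1)
  counts <- rnbinom(n, mu = 10^runif(1, 0.3, 2.5), size = 0.7)
  if (sum(counts) == 0) counts[1] <- 1
  counts
}

test_that("alpha diversity matches closed forms on hand-checkable communities", {
  a <- alpha_diversity(c(10, 10, 10, 10))
  expect_equal(a$sobs, 4)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$simpson, 0.25, tolerance = 1e-12)
  b <- alpha_diversity(c(1, 1, 2, 3))
  expect_equal(b$chao1, 4.5)
  expect_equal(b$goods_coverage, 1 - 2 / 7, tolerance = 1e-12)
  expect_error(alpha_diversity(c(0, 0)), "no reads")
})

test_that("alpha indices equal an independent brute-force evaluation", {
  withr::with_seed(81, {
    for (i in 1:500) {
      counts <- random_counts()
      got <- alpha_diversity(counts)
      want <- oracle_alpha(counts)
      for (ix in names(want)) {
        expect_equal(got[[ix]], unname(want[[ix]]), tolerance = 1e-10,
                     label = sprintf("%s (case %d)", ix, i))
      }
    }
  })
})

test_that("alpha indices agree with vegan on representative communities", {
  withr::with_seed(82, {
    for (i in 1:20) {
      counts <- random_counts()
      got <- alpha_diversity(counts)
      expect_equal(got$shannon, vegan::diversity(counts, "shannon"),
                   tolerance = 1e-10)
      expect_equal(got$simpson, 1 - vegan::diversity(counts, "simpson"),
                   tolerance = 1e-10)
      er <- vegan::estimateR(counts)
      expect_equal(got$chao1, unname(er["S.chao1"]), tolerance = 1e-8)
      expect_equal(got$ace, unname(er["S.ACE"]), tolerance = 1e-8)
    }
  })
})

test_that("Chao1 is at least Sobs, with equality iff no singletons", {
  withr::with_seed(83, {
    for (i in 1:100) {
      counts <- random_counts()
      a <- alpha_diversity(counts)
      expect_gte(a$chao1, a$sobs)
      # the bias-corrected form adds n1(n1-1)/(2(n2+1)): zero for n1 <= 1
      if (sum(counts == 1) <= 1) expect_equal(a$chao1, a$sobs)
      else expect_gt(a$chao1, a$sobs)
    }
  })
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  m <- cbind(a = c(1, 1), b = c(1, 0))
  expect_equal(bray_curtis(m)["a", "b"], 1 / 3)
  same <- cbind(x = c(3, 2, 1), y = c(3, 2, 1))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disjoint <- cbind(x = c(5, 0), y = c(0, 7))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(1, 1))), "positive total")
  withr::with_seed(84, {
    mat <- matrix(rpois(80, 5), nrow = 10)
    colnames(mat) <- paste0("s", 1:8)
    mat[, colSums(mat) == 0][1] <- 1
    got <- bray_curtis(mat)
    want <- as.matrix(vegan::vegdist(t(mat), "bray"))
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_equal(got["s1", "s2"], oracle_bray(mat[, 1], mat[, 2]),
                 tolerance = 1e-12)
  })
})

test_that("PCoA round-trips Euclidean configurations and handles edge cases", {
  # two samples at distance d sit at +/- d/2 on the first axis
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2, 1)
  expect_equal(unname(sort(p2$coordinates[, 1])), c(-1.5, 1.5),
               tolerance = 1e-10)
  # Euclidean distances of known 2-D points are reproduced up to rotation
  withr::with_seed(85, {
    pts <- matrix(rnorm(20), ncol = 2)
    d <- as.matrix(dist(pts))
    p <- pcoa(d, 2)
    expect_lt(procrustes_error(p$coordinates, pts), 1e-8)
    expect_equal(colMeans(p$coordinates), c(PCo1 = 0, PCo2 = 0),
                 tolerance = 1e-10)
    expect_true(all(p$proportion >= 0 & p$proportion <= 1))
  })
  z <- matrix(0, 3, 3)
  expect_true(all(pcoa(z, 2)$coordinates == 0))
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(asym), "symmetric")
})

test_that("PCoA axis orientation is deterministic", {
  withr::with_seed(86, {
    mat <- matrix(rpois(60, 8), nrow = 10)
    colnames(mat) <- paste0("s", 1:6)
    d <- bray_curtis(mat)
    p1 <- pcoa(d, 3)
    p2 <- pcoa(d, 3)
    expect_identical(p1$coordinates, p2$coordinates)
    for (ax in 1:3) {
      co <- p1$coordinates[, ax]
      expect_gt(co[which.max(abs(co))], 0)
    }
  })
})

test_that("PERMANOVA pseudo-F and R2 match vegan and the brute-force oracle", {
  withr::with_seed(87, {
    mat <- matrix(rpois(120, 10), nrow = 15)
    colnames(mat) <- paste0("s", 1:8)
    d <- bray_curtis(mat)
    g <- rep(c("x", "y"), each = 4)
    got <- permanova(d, g, n_permutations = 199, seed = 2)
    expect_equal(got$pseudo_f, oracle_pseudo_f(d, g), tolerance = 1e-10)
    av <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
    expect_equal(got$pseudo_f, av$F[1], tolerance = 1e-8)
    expect_equal(got$r_squared, av$R2[1], tolerance = 1e-8)
  })
})

test_that("PERMANOVA permutation p matches exhaustive enumeration at n = 6", {
  withr::with_seed(88, {
    mat <- matrix(rpois(60, 10), nrow = 10)
    colnames(mat) <- paste0("s", 1:6)
    d <- bray_curtis(mat)
    g <- rep(c("x", "y"), each = 3)
    f_obs <- oracle_pseudo_f(d, g)
    perms <- expand.grid(rep(list(1:6), 6))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
    f_all <- apply(perms, 1, function(p) oracle_pseudo_f(d, g[unlist(p)]))
    p_exact <- mean(f_all >= f_obs - 1e-12)
    got <- permanova(d, g, n_permutations = 9999, seed = 3)
    expect_lt(abs(got$p_value - p_exact), 0.02)
  })
})

test_that("PERMANOVA attains its minimal p on perfectly separated duplicates", {
  # 6 identical samples per group: only a partition-preserving permutation
  # ties the observed F, and none is drawn under this seed
  mat <- cbind(matrix(c(10, 0, 0), 3, 6), matrix(c(0, 10, 0), 3, 6))
  colnames(mat) <- paste0("s", 1:12)
  d <- bray_curtis(mat)
  got <- permanova(d, rep(c("a", "b"), each = 6), n_permutations = 99,
                   seed = 1)
  expect_equal(got$p_value, 1 / 100)
  expect_error(permanova(d, rep("a", 12), 99), "2 groups")
  expect_error(permanova(d, rep(c("a", "b"), each = 6), 10), "99")
})

test_that("taxonomic aggregation preserves totals and matches group-by oracle", {
  cfg <- small_config()
  otu <- simulate_transconjugant_table(cfg, seed = 4)
  phy <- aggregate_taxonomy(otu, "phylum")
  expect_equal(colSums(phy), colSums(otu$counts))
  gen <- aggregate_taxonomy(otu, "genus")
  expect_equal(colSums(gen), colSums(otu$counts))
  # unresolved genera carry the family-prefixed label
  expect_true("f__Bacillaceae" %in% rownames(gen))
  # brute-force group-by
  labels <- plasmidfate:::taxon_labels(otu$taxonomy, "phylum")
  for (lab in unique(labels)) {
    manual <- colSums(otu$counts[labels == lab, , drop = FALSE])
    expect_equal(unname(phy[lab, ]), unname(manual))
  }
  expect_error(aggregate_taxonomy(otu, "kingdom"), "unknown rank")
  # single-phylum table collapses to the column sums
  tpl <- flat_template(n_other = 0, p_firmicutes = 1)
  otu1 <- simulate_transconjugant_table(
    synthetic_config(community_template = tpl, seq_depth = 300,
                     n_replicates = 2), seed = 1)
  phy1 <- aggregate_taxonomy(otu1, "phylum")
  expect_equal(nrow(phy1), 1)
  expect_equal(unname(phy1[1, ]), unname(colSums(otu1$counts)))
})

test_that("relative abundances are proper compositions", {
  withr::with_seed(89, {
    mat <- matrix(rpois(50, 6) + 1, nrow = 10)
    colnames(mat) <- paste0("s", 1:5)
    rel <- relative_abundance(mat)
    expect_equal(unname(colSums(rel)), rep(1, 5), tolerance = 1e-12)
    expect_equal(rel, sweep(mat, 2, colSums(mat), "/"))
  })
  one <- matrix(5, 1, 2, dimnames = list("t", c("a", "b")))
  expect_true(all(relative_abundance(one) == 1))
  expect_error(relative_abundance(matrix(0, 2, 2)), "positive total")
})

test_that("host-range sets compute shared, unique and core genera", {
  hr <- host_range_summary(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(hr$pairwise_shared["A", "B"], 2L)
  expect_equal(unname(hr$unique_counts), c(1L, 1L))
  expect_equal(hr$core, c("b", "c"))
  expect_equal(hr$shared_pct_union, 100 * 2 / 4)
  same <- host_range_summary(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unname(same$unique_counts), c(0L, 0L))
  expect_equal(same$core, c("x", "y"))
  expect_error(host_range_summary(list(A = "a")), "2 groups")
  # consistency with brute-force set algebra on random sets
  withr::with_seed(90, {
    for (i in 1:20) {
      pool <- paste0("g", 1:30)
      sets <- lapply(1:3, function(j) sample(pool, sample(5:20, 1)))
      names(sets) <- c("P", "Q", "R")
      hr <- host_range_summary(sets)
      expect_equal(hr$core,
                   sort(intersect(intersect(sets$P, sets$Q), sets$R)))
      expect_equal(unname(hr$unique_counts["P"]),
                   length(setdiff(sets$P, union(sets$Q, sets$R))))
      # shared + unique decomposition for the pair (P, Q) against P
      expect_equal(hr$pairwise_shared["P", "Q"] +
                     length(setdiff(sets$P, sets$Q)), length(unique(sets$P)))
      expect_true(all(hr$core %in% sets$P))
    }
  })
})

test_that("top-N matrix ranks by mean relative abundance with Other filling to 1", {
  withr::with_seed(91, {
    mat <- matrix(rpois(200, 8), nrow = 40)
    rownames(mat) <- sprintf("g%02d", 1:40)
    colnames(mat) <- paste0("s", 1:5)
    mat[rowSums(mat) == 0, 1] <- 1
    top <- top_n_matrix(mat, 10)
    expect_equal(nrow(top), 11)
    expect_equal(unname(colSums(top)), rep(1, 5), tolerance = 1e-12)
    rel <- sweep(mat, 2, colSums(mat), "/")
    want <- rownames(rel)[order(-rowMeans(rel), rownames(rel))][1:10]
    expect_equal(rownames(top)[1:10], want)
  })
  small <- matrix(1:10, nrow = 5,
                  dimnames = list(paste0("g", 1:5), c("a", "b")))
  expect_equal(nrow(top_n_matrix(small, 30)), 5)  # no padding, no Other
})

test_that("alpha group comparison produces coherent letter displays", {
  df <- data.frame(
    group = rep(c("lo", "mid", "hi"), each = 3),
    sobs = c(10, 11, 12, 50, 51, 52, 100, 101, 102)
  )
  cmp <- compare_alpha_groups(df, indices = "sobs")
  letters <- cmp$table$letters
  expect_equal(length(unique(letters)), 3)  # all separated
  df2 <- data.frame(group = rep(c("a", "b"), each = 3),
                    sobs = c(10, 12, 11, 11, 10, 12))
  cmp2 <- compare_alpha_groups(df2, indices = "sobs")
  expect_equal(unique(cmp2$table$letters), "a")  # one shared letter
  expect_error(compare_alpha_groups(df[1:3, ], indices = "sobs"), "2 groups")
})

test_that("rarefaction is seeded, even-depth and reproducible", {
  cfg <- small_config()
  otu <- simulate_transconjugant_table(cfg, seed = 6)
  r1 <- rarefy_table(otu, depth = 500, seed = 2)
  r2 <- rarefy_table(otu, depth = 500, seed = 2)
  expect_true(all(colSums(r1$counts) == 500))
  expect_identical(r1$counts, r2$counts)
  expect_true(all(r1$counts <= otu$counts))
  expect_error(rarefy_table(otu, depth = 10^9), "fewer")
})
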
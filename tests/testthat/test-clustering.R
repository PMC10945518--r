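mk_profile <- function(counts, offsets = -1000:1000) {
  structure(tibble::tibble(offset = offsets, count = counts),
            tf_name = "T", n_motif_bp = sum(counts),
            class = c("motif_profile", class(tibble::tibble())))
}

test_that("symmetrization averages halves, trims to 60 bp, and normalizes", {
  counts <- integer(2001)
  counts[1001] <- 10L                       # offset 0
  counts[1001 + 10] <- 4L; counts[1001 - 10] <- 2L
  counts[1001 + 70] <- 9L                   # beyond 60: must not influence
  p <- mk_profile(counts)
  half <- symmetrize_profile(p)
  expect_length(half, 61L)
  # before normalization: half[11] = (4 + 2)/2 = 3, half[1] = 10
  expect_equal(half[11], 3 / 10)
  expect_equal(half[1], 1)
  expect_equal(min(half), 0)
  # symmetric profile: half equals either side
  counts2 <- integer(2001)
  counts2[1001 + (-60:60)] <- rep(c(1L, 5L), length.out = 121)
  sym_c <- counts2
  sym_c[1001 - (1:60)] <- sym_c[1001 + (1:60)]
  p2 <- mk_profile(sym_c)
  expect_equal(symmetrize_profile(p2),
               normalize_profile(sym_c[1001 + (0:60)]))
})

test_that("quality filter rejects under-represented and asymmetric profiles", {
  set.seed(83)
  sym_counts <- integer(2001)
  sym_counts[1001 + (0:73)] <- 5L + (0:73) %% 7L
  sym_counts[1001 - (1:73)] <- sym_counts[1001 + (1:73)]
  sym_counts[1001] <- 20L
  asym <- integer(2001)
  asym[1001 + (1:73)] <- 10L
  asym[1001 - (1:73)] <- sample(0:2, 73, replace = TRUE)
  profs <- tibble::tibble(
    tf_name = c("good", "thin", "skew"),
    profile = list(mk_profile(sym_counts), mk_profile(sym_counts), mk_profile(asym)),
    nr_motif_bp = c(10000L, 499L, 10000L)
  )
  qf <- quality_filter(profs)
  expect_equal(qf$kept$tf_name, "good")
  expect_equal(qf$rejected$reason[qf$rejected$tf_name == "thin"], "nr_bp")
  expect_equal(qf$rejected$reason[qf$rejected$tf_name == "skew"], "symmetry")
})

test_that("k-medoids partitions well-separated blobs and respects edge cases", {
  set.seed(97)
  blob1 <- matrix(rnorm(12, 0, 0.1), ncol = 2)
  blob2 <- matrix(rnorm(12, 5, 0.1), ncol = 2)
  pts <- rbind(blob1, blob2)
  fit <- kmedoids_cluster(pts, k = 2)
  expect_equal(length(unique(fit$cluster[1:6])), 1L)
  expect_equal(length(unique(fit$cluster[7:12])), 1L)
  expect_false(fit$cluster[1] == fit$cluster[7])
  # brute-force optimal medoid pair on these 12 points
  d <- as.matrix(dist(pts))
  combos <- utils::combn(12, 2)
  costs <- apply(combos, 2, function(id) sum(pmin(d[, id[1]], d[, id[2]])))
  expect_equal(fit$objective, min(costs), tolerance = 1e-9)
  # k = 1 medoid minimizes total distance; k = n gives zero cost
  f1 <- kmedoids_cluster(pts, k = 1)
  expect_equal(f1$objective, min(colSums(d)), tolerance = 1e-9)
  fn <- kmedoids_cluster(pts, k = 12)
  expect_equal(fn$objective, 0)
  expect_error(kmedoids_cluster(pts, k = 13), "k must be")
})

test_that("silhouette widths match the textbook formula", {
  set.seed(101)
  pts <- rbind(matrix(rnorm(20, 0, 0.5), ncol = 2),
               matrix(rnorm(20, 4, 0.5), ncol = 2),
               matrix(rnorm(20, c(0, 8), 0.5), ncol = 2))
  fit <- kmedoids_cluster(pts, k = 3)
  expect_equal(fit$silhouette, brute_silhouette(pts, fit$cluster),
               tolerance = 1e-9)
})

test_that("outlier removal relabels low-silhouette members only", {
  pts <- rbind(matrix(rnorm(16, 0, 0.05), ncol = 2),
               matrix(rnorm(16, 3, 0.05), ncol = 2),
               c(1.5, 1.5))  # equidistant point
  fit <- kmedoids_cluster(pts, k = 2)
  out <- remove_outliers(fit, max_sil = 0.25)
  expect_true(out$outlier[17])
  expect_true(is.na(out$cluster[17]))
  expect_true(all(!out$outlier[1:16]))
  expect_equal(out$silhouette, fit$silhouette)  # computed once, before removal
  none <- remove_outliers(fit, max_sil = -1)
  expect_false(any(none$outlier))
  one <- fit; one$cluster <- rep(1L, nrow(pts))
  expect_error(remove_outliers(one, 0.25), "single cluster")
})

test_that("t-SNE embedding is reproducible and keeps duplicates together", {
  tpl <- template_half_profiles(8, noise_sd = 0.05, seed = 5)
  e1 <- embed_profiles(tpl$X, seed = 42, perplexity = 5)
  e2 <- embed_profiles(tpl$X, seed = 42, perplexity = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(24L, 2L))
  X2 <- rbind(tpl$X, tpl$X[1, , drop = FALSE])
  e3 <- embed_profiles(X2, seed = 42, perplexity = 5)
  d_dup <- sqrt(sum((e3[1, ] - e3[25, ])^2))
  dall <- as.matrix(dist(e3))
  expect_lt(d_dup, median(dall[upper.tri(dall)]))
  expect_error(embed_profiles(tpl$X[1:3, ]), "at least 4")
})

test_that("planted template structure is recovered across seeds (ARI >= 0.9)", {
  aris <- vapply(1:10, function(s) {
    tpl <- template_half_profiles(20, noise_sd = 0.08, seed = s)
    emb <- embed_profiles(tpl$X, seed = s, perplexity = 10)
    fit <- kmedoids_cluster(emb, k = 3)
    mclust::adjustedRandIndex(fit$cluster, tpl$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("the clustering pipeline is deterministic end to end", {
  set.seed(7)
  base <- template_half_profiles(6, noise_sd = 0.05, seed = 2)
  profs <- tibble::tibble(
    tf_name = sprintf("T%02d", 1:18),
    profile = lapply(1:18, function(i) {
      counts <- integer(2001)
      v <- as.integer(round(base$X[i, ] * 50))
      counts[1001 + (0:60)] <- v
      counts[1001 - (1:60)] <- v[-1]
      mk_profile(counts)
    }),
    nr_motif_bp = 10000L
  )
  c1 <- cluster_profiles(profs, k = 3, seed = 99, perplexity = 5)
  c2 <- cluster_profiles(profs, k = 3, seed = 99, perplexity = 5)
  expect_identical(tidy(c1), tidy(c2))
  expect_identical(c1$embedding, c2$embedding)
  keep <- !is.na(c1$assignments$cluster)
  expect_gte(mclust::adjustedRandIndex(c1$assignments$cluster[keep],
                                       base$truth[keep]), 0.9)
})
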
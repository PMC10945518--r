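#' Symmetry correlation of a motif profile
#'
#' Pearson correlation between counts at offsets `+1..+half` and the mirrored
#' `-1..-half` (default half = 73, the full nucleosomal halves). Because of
#' the nucleosome's two-fold symmetry, profiles built from many motifs on
#' both strands should be near-symmetric; low values flag unreliable
#' profiles.
#'
#' @param profile `motif_profile` tibble.
#' @param half half-width in bp.
#' @return Pearson correlation (NA when either half is constant).
#' @export
profile_symmetry <- function(profile, half = 73L) {
  plus <- profile$count[match(1:half, profile$offset)]
  minus <- profile$count[match(-(1:half), profile$offset)]
  if (stats::sd(plus) == 0 || stats::sd(minus) == 0) return(NA_real_)
  stats::cor(plus, minus)
}

#' Quality-filter motif profiles before clustering
#'
#' Removes under-represented profiles (fewer than `min_nr_bp` motif bases on
#' nucleosome regions, default 500) and asymmetric ones (symmetry correlation
#' below `min_sym_pcc`, default 0.4).
#'
#' @param profiles tibble with columns `tf_name`, `profile` (list column of
#'   `motif_profile` tibbles) and `nr_motif_bp`; extra key columns such as
#'   `cell_line` are carried through.
#' @param min_nr_bp minimum motif bases on NRs.
#' @param min_sym_pcc minimum symmetry correlation.
#' @return list with `kept` (filtered tibble, plus a `symmetry_pcc` column)
#'   and `rejected` (tibble of keys with a `reason` column: `"nr_bp"` or
#'   `"symmetry"`).
#' @export
quality_filter <- function(profiles, min_nr_bp = 500L, min_sym_pcc = 0.4) {
  sym <- map_dbl(profiles$profile, profile_symmetry)
  out <- mutate(profiles, symmetry_pcc = sym)
  fail_bp <- out$nr_motif_bp < min_nr_bp
  fail_sym <- !fail_bp & (is.na(sym) | sym < min_sym_pcc)
  rejected <- out[fail_bp | fail_sym, , drop = FALSE]
  rejected$reason <- ifelse(fail_bp[fail_bp | fail_sym], "nr_bp", "symmetry")
  list(kept = out[!(fail_bp | fail_sym), , drop = FALSE],
       rejected = select(rejected, -"profile"))
}

#' Fold a profile into a normalized half-profile
#'
#' Averages the two nucleosomal halves (`half[i] = (X(+i) + X(-i)) / 2`,
#' `half[0] = X(0)`) over offsets 0..60 — the entry/exit region beyond
#' +-60 bp is excluded because MNase cleavage bias distorts it — then
#' min-max normalizes to `[0, 1]` so shape rather than amplitude drives
#' clustering.
#'
#' @param profile `motif_profile` tibble.
#' @param half_max outermost offset retained (default 60).
#' @return numeric vector of length `half_max + 1` in `[0, 1]`.
#' @export
symmetrize_profile <- function(profile, half_max = 60L) {
  x0 <- profile$count[match(0L, profile$offset)]
  plus <- profile$count[match(1:half_max, profile$offset)]
  minus <- profile$count[match(-(1:half_max), profile$offset)]
  normalize_profile(c(x0, (plus + minus) / 2))
}

#' Embed half-profiles in two dimensions with t-SNE
#'
#' Exact t-SNE (theta = 0) on the Euclidean distances between half-profiles;
#' perplexity is reduced automatically when fewer than `3 * perplexity + 1`
#' profiles are supplied. Deterministic for a fixed seed.
#'
#' @param half_profiles numeric matrix, one row per profile.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @return matrix `n x 2` of embedding coordinates.
#' @export
embed_profiles <- function(half_profiles, seed = 1234L, perplexity = 30) {
  n <- nrow(half_profiles)
  if (is.null(n) || n < 4L) abort("need at least 4 profiles to embed")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  fit <- Rtsne::Rtsne(half_profiles, dims = 2L, perplexity = perplexity,
                      theta = 0, pca = FALSE, max_iter = 1000L,
                      check_duplicates = FALSE, verbose = FALSE)
  fit$Y
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' k-medoids clustering (PAM)
#'
#' Partitioning-around-medoids on Euclidean distances: build phase then swap
#' phase until no improving swap; medoids are input points. PAM is
#' deterministic; the `seed` argument is accepted for interface symmetry with
#' [embed_profiles()].
#'
#' @param points numeric matrix (rows = observations).
#' @param k number of clusters (default 6).
#' @param seed unused (PAM is deterministic); kept for provenance.
#' @return list with `cluster` (integer assignments), `medoid_idx` (row
#'   indices of the medoids), `silhouette` (per-point widths, NA for k = 1)
#'   and `objective` (total distance to assigned medoids).
#' @export
kmedoids_cluster <- function(points, k = 6L, seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) abort("k must be <= number of points")
  if (k == n) {
    return(list(cluster = seq_len(n), medoid_idx = seq_len(n),
                silhouette = rep(NA_real_, n), objective = 0))
  }
  fit <- cluster::pam(points, k = k, metric = "euclidean", keep.diss = TRUE)
  sil <- rep(NA_real_, n)
  if (k >= 2L) {
    # silhouette() on the raw partition keeps observations in input order
    sil <- cluster::silhouette(fit$clustering, fit$diss)[, "sil_width"]
  }
  list(cluster = unname(fit$clustering),
       medoid_idx = unname(fit$id.med),
       silhouette = unname(sil),
       objective = sum(apply(
         as.matrix(fit$diss)[, fit$id.med, drop = FALSE], 1L, min)))
}

#' Flag low-silhouette cluster members as outliers
#'
#' Members with silhouette width at or below `max_sil` (default 0.25) are
#' relabelled `NA` (outlier); survivors keep the silhouettes computed before
#' removal.
#'
#' @param fit result of [kmedoids_cluster()] (needs >= 2 clusters).
#' @param max_sil silhouette threshold.
#' @return `fit` with an added logical `outlier` vector and `cluster` set to
#'   `NA` for outliers.
#' @export
remove_outliers <- function(fit, max_sil = 0.25) {
  if (length(unique(fit$cluster[!is.na(fit$cluster)])) < 2L) {
    abort("silhouette undefined for a single cluster")
  }
  out <- fit$silhouette <= max_sil
  fit$outlier <- out
  fit$cluster[out] <- NA_integer_
  fit
}

#' Cluster TF binding-motif profiles by nucleosomal binding mode
#'
#' The full clustering pipeline: quality filter, fold to normalized
#' half-profiles (offsets 0..60), 2-D t-SNE embedding, k-medoids with k = 6,
#' silhouette-based outlier removal.
#'
#' @inheritParams quality_filter
#' @param k number of clusters.
#' @param seed embedding seed.
#' @param perplexity t-SNE perplexity.
#' @param max_sil silhouette threshold for outliers.
#' @param embed cluster on the 2-D embedding (default, as in the reference
#'   procedure) or directly on the 61-D half-profiles (`embed = FALSE`).
#' @return object of class `nuc_clusters`: list with `assignments` (tibble of
#'   keys, cluster, silhouette, outlier), `half_profiles` (matrix), `embedding`
#'   (matrix or NULL), `medoid_idx`, `rejected`, `params`.
#' @export
cluster_profiles <- function(profiles, k = 6L, seed = 1234L, perplexity = 30,
                             min_nr_bp = 500L, min_sym_pcc = 0.4,
                             max_sil = 0.25, embed = TRUE) {
  qf <- quality_filter(profiles, min_nr_bp, min_sym_pcc)
  kept <- qf$kept
  if (nrow(kept) < k) abort("no clusterable profiles (fewer kept than k)")
  hp <- do.call(rbind, lapply(kept$profile, symmetrize_profile))
  emb <- if (embed) embed_profiles(hp, seed, perplexity) else NULL
  fit <- kmedoids_cluster(if (embed) emb else hp, k = k)
  fit <- remove_outliers(fit, max_sil)
  keys <- select(kept, -"profile")
  assignments <- mutate(keys,
                        cluster = fit$cluster,
                        silhouette = fit$silhouette,
                        outlier = fit$outlier)
  structure(list(assignments = assignments, half_profiles = hp,
                 embedding = emb, medoid_idx = fit$medoid_idx,
                 rejected = qf$rejected,
                 params = list(k = k, seed = seed, perplexity = perplexity,
                               min_nr_bp = min_nr_bp,
                               min_sym_pcc = min_sym_pcc,
                               max_sil = max_sil, embed = embed)),
            class = "nuc_clusters")
}

#' @export
print.nuc_clusters <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf(
    "<nuc_clusters> %d profiles, k = %d, %d outlier(s), %d rejected by QC\n",
    n, x$params$k, sum(x$assignments$outlier), nrow(x$rejected)))
  invisible(x)
}
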
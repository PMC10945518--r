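# shared fixtures and independent oracles

itbl <- function(chrom, start, end, ...) interval_tbl(chrom, start, end, ...)

tiny_genome <- function(...) {
  seqs <- c(...)
  genome_model(setNames(nchar(seqs), names(seqs)), seqs)
}

random_genome <- function(len, chrom = "chr1") {
  s <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  tiny_genome(setNames(s, chrom))
}

# brute-force per-base overlap count for one query interval
brute_overlap_bp <- function(qs, qe, targets) {
  if (nrow(targets) == 0L) return(0L)
  covered <- logical(qe - qs)
  for (i in seq_len(nrow(targets))) {
    lo <- max(qs, targets$start[i]); hi <- min(qe, targets$end[i])
    if (lo < hi) covered[(lo - qs + 1L):(hi - qs)] <- TRUE
  }
  sum(covered)
}

# brute-force evaluation of the smoothed dyad count at one coordinate
brute_smooth_at <- function(i, pos, cnt, h) {
  sum(cnt * triweight_kernel(i - pos, h)) / h
}

# brute-force local maxima: positions with D strictly above both flanking
# distinct values (plateau -> lowest coordinate), then greedy min-sep by height
brute_maxima <- function(pos, D, min_sep) {
  keep <- integer(0)
  n <- length(D)
  cand_pos <- numeric(0); cand_h <- numeric(0)
  for (i in seq_len(n)) {
    if (D[i] <= 0) next
    j <- i - 1L
    while (j >= 1L && D[j] == D[i]) j <- j - 1L
    k <- i + 1L
    # plateau: only its first position is the candidate
    if (i > 1L && D[i - 1L] == D[i]) next
    while (k <= n && D[k] == D[i]) k <- k + 1L
    left_ok <- j < 1L || D[j] < D[i]
    right_ok <- k > n || D[k] < D[i]
    if (left_ok && right_ok) {
      cand_pos <- c(cand_pos, pos[i]); cand_h <- c(cand_h, D[i])
    }
  }
  ord <- order(-cand_h, cand_pos)
  for (i in ord) {
    if (all(abs(keep - cand_pos[i]) >= min_sep)) keep <- c(keep, cand_pos[i])
  }
  sort(keep)
}

# random PFM with a strong consensus
random_pfm <- function(L, name = "TFX", strong = 85, weak = 5) {
  cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(weak, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(cons, rownames(m)), seq_len(L))] <- strong
  structure(list(tf_name = name, id = name, matrix = m,
                 consensus = paste0(cons, collapse = "")), class = "pfm")
}

# exhaustive enumeration of the PWM score null distribution on the rounded
# integer grid (independent of the DP convolution)
enumerate_pvalue <- function(pwm, score_int, granularity = 1e-3) {
  M <- round(pwm$matrix / granularity)
  L <- ncol(M)
  bg <- pwm$background
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (l in seq_len(L)) {
    sc <- sc + M[cbind(words[, l], l)]
    pr <- pr * bg[words[, l]]
  }
  vapply(score_int, function(s) sum(pr[sc >= s]), numeric(1))
}

# pair-counting ROC oracle
brute_roc_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# threshold-sweep PR oracle (step area)
brute_pr_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  n_pos <- sum(labels)
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

brute_max_mcc <- function(scores, labels) {
  best <- -Inf
  for (t in unique(scores)) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
    best <- max(best, mcc)
  }
  best
}

# silhouette widths by the textbook formula
brute_silhouette <- function(points, cluster) {
  d <- as.matrix(dist(points))
  vapply(seq_along(cluster), function(i) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_along(cluster) != i]) else 0
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(k) mean(d[i, cluster == k]), numeric(1)))
    if (sum(own) == 1L) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

# template half-profiles for planted-structure clustering tests
template_half_profiles <- function(n_per, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  offs <- 0:60
  shapes <- list(
    end = as.numeric(offs >= 50),                  # end binder (toward SHL 5-6)
    dyad = as.numeric(offs <= 16),                 # dyad binder (SHL 0-1.5)
    shl3 = exp(-(offs - 31)^2 / 50)                # SHL ~3 binder
  )
  X <- do.call(rbind, lapply(shapes, function(s) {
    t(replicate(n_per, pmax(s + rnorm(61, 0, noise_sd), 0)))
  }))
  list(X = X, truth = rep(seq_along(shapes), each = n_per))
}
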
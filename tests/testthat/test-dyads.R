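test_that("dyad counting uses fragment midpoints and the 146-148 length filter", {
  expect_equal(count_dyads(itbl("chr1", 100, 247))$pos, 173L)
  expect_equal(nrow(count_dyads(itbl("chr1", 100, 250))), 0L)  # length 150
  two <- count_dyads(itbl(c("chr1", "chr1"), c(100, 100), c(247, 247)))
  expect_equal(two$count, 2L)
})

test_that("triweight smoothing matches direct evaluation of the kernel formula", {
  raw <- tibble::tibble(chrom = "chr1", pos = 1000L, count = 4L)
  sm <- smooth_counts(raw, h = 15)
  expect_equal(sm$D[sm$pos == 1000], 4 / 15, tolerance = 1e-12)
  expect_equal(sm$D[sm$pos == 1007], 4 * (1 - (7 / 15)^2)^3 / 15, tolerance = 1e-12)
  expect_equal(sm$D[sm$pos == 1015], 0)
  expect_error(smooth_counts(raw, h = 0), "h")
})

test_that("smoothing equals the brute-force double loop on random sparse counts", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(1:40, 1)
    pos <- sort(sample(50:9999, n))  # clear of the chromosome-start clip
    cnt <- sample(1:20, n, replace = TRUE)
    raw <- tibble::tibble(chrom = "c", pos = pos, count = cnt)
    h <- sample(c(5, 15, 31), 1)
    sm <- smooth_counts(raw, h)
    probe <- sample(sm$pos, min(20, nrow(sm)))
    for (i in probe) {
      expect_equal(sm$D[match(i, sm$pos)], brute_smooth_at(i, pos, cnt, h),
                   tolerance = 1e-12)
    }
    # linear mass scaling over the kernel support
    ksum <- sum(triweight_kernel(-h:h, h))
    expect_equal(sum(sm$D), sum(cnt) * ksum / h, tolerance = 1e-9)
  }
})

test_that("local maxima search honors height, plateaus, and min separation", {
  mk <- function(pos, count) tibble::tibble(chrom = "c", pos = pos, count = count)
  # single bump
  sm <- smooth_counts(mk(500L, 5L), 15)
  expect_equal(find_local_maxima(sm, 150)$pos, 500L)
  # two bumps closer than min_sep: taller one survives
  sm2 <- smooth_counts(mk(c(500L, 600L), c(3L, 5L)), 15)
  expect_equal(find_local_maxima(sm2, 150)$pos, 600L)
  expect_equal(sort(find_local_maxima(sm2, 50)$pos), c(500L, 600L))
  # plateau -> lowest coordinate (equal counts 30 bp apart make a flat top)
  raw3 <- mk(c(500L, 504L), c(4L, 4L))
  sm3 <- smooth_counts(raw3, 15)
  mx3 <- find_local_maxima(sm3, 150)
  expect_equal(mx3$pos, min(sm3$pos[sm3$D == max(sm3$D)]))
  # all-zero / empty track
  expect_equal(nrow(find_local_maxima(sm[0, ], 150)), 0L)
})

test_that("local maxima agree with a brute-force scan oracle on random tracks", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    pos <- sort(sample(0:4999, n))
    cnt <- sample(1:15, n, replace = TRUE)
    raw <- tibble::tibble(chrom = "c", pos = pos, count = cnt)
    sm <- smooth_counts(raw, 15)
    for (ms in c(50L, 150L)) {
      got <- find_local_maxima(sm, ms)$pos
      # oracle needs the full contiguous track: evaluate islands jointly
      d <- dplyr::arrange(sm, pos)
      expect_equal(sort(got), brute_maxima(d$pos, d$D, ms))
    }
  }
})

test_that("representative dyad selection follows count > proximity > coordinate", {
  mx <- tibble::tibble(chrom = "c", pos = 1000L)
  mk <- function(pos, count) tibble::tibble(chrom = "c", pos = pos, count = count)
  expect_equal(select_representative_dyads(mk(c(990L, 1010L), c(5L, 3L)), mx)$pos, 990L)
  expect_equal(select_representative_dyads(mk(c(995L, 1003L), c(4L, 4L)), mx)$pos, 1003L)
  expect_equal(select_representative_dyads(mk(c(997L, 1003L), c(4L, 4L)), mx)$pos, 997L)
  # window without raw dyads yields nothing
  expect_equal(nrow(select_representative_dyads(mk(2000L, 1L), mx)), 0L)
})

test_that("nucleosome regions are 147 bp dyad-centered windows, clipped", {
  g <- genome_model(c(c = 5000L))
  nr <- nucleosome_regions(tibble::tibble(chrom = "c", pos = 1000L), g)
  expect_equal(c(nr$start, nr$end), c(927L, 1074L))
  expect_equal(nr$end - nr$start, 147L)
  nr2 <- nucleosome_regions(tibble::tibble(chrom = "c", pos = 10L), g)
  expect_equal(c(nr2$start, nr2$end), c(0L, 84L))
  expect_equal(nrow(nucleosome_regions(tibble::tibble(chrom = character(),
                                                      pos = integer()), g)), 0L)
})

test_that("occupancy profile is mean fragment coverage per dyad", {
  dy <- tibble::tibble(chrom = "c", pos = 1000L)
  occ <- occupancy_profile(itbl("c", 927, 1074), dy, flank = 100)
  expect_equal(occ$occupancy[abs(occ$offset) <= 73], rep(1, 147))
  expect_equal(occ$occupancy[occ$offset == 80], 0)
  # no fragments -> all zero
  occ0 <- occupancy_profile(itbl(character(), integer(), integer()), dy, flank = 50)
  expect_equal(occ0$occupancy, rep(0, 101))
  # mean over dyads: fragment covering only the first of two dyads
  dy2 <- tibble::tibble(chrom = "c", pos = c(1000L, 5000L))
  occ2 <- occupancy_profile(itbl("c", 927, 1074), dy2, flank = 50)
  expect_equal(occ2$occupancy[occ2$offset == 0], 0.5)
  expect_error(occupancy_profile(itbl("c", 0, 147),
                                 tibble::tibble(chrom = character(), pos = integer())),
               "no dyads")
})

test_that("representative dyads from the full protocol stay >= 90 bp apart", {
  set.seed(31)
  centers <- seq(300, 9700, by = 120)  # deliberately crowded placements
  n <- 12 * length(centers)
  mid <- rep(centers, each = 12) + round(rnorm(n, 0, 8))
  frags <- itbl("c", mid - 73L, mid + 74L)
  dm <- call_dyads(frags)
  expect_true(all(diff(dm$pos) >= 90))
})

test_that("dyads are recovered from jittered fragments around planted positions", {
  set.seed(5)
  planted <- seq(300, 29700, by = 200) + sample(-10:10, 148, replace = TRUE)
  mid <- rep(planted, each = 25) + round(rnorm(25 * length(planted), 0, 8))
  len <- sample(146:148, length(mid), replace = TRUE)
  frags <- itbl("c", mid - len %/% 2L, mid - len %/% 2L + len)
  dm <- call_dyads(frags)
  near <- vapply(dm$pos, function(p) min(abs(planted - p)), numeric(1))
  expect_gte(mean(near <= 20), 0.9)
  rec <- vapply(planted, function(p) min(abs(dm$pos - p)), numeric(1))
  expect_gte(mean(rec <= 20), 0.8)
})
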
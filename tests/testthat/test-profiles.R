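mk_dyads <- function(pos, chrom = "c") tibble::tibble(chrom = chrom, pos = as.integer(pos))

mk_hits <- function(start, end, chrom = "c", tf = "T1") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 strand = "+", tf_name = tf)
}

test_that("profiles count hit bases at offsets from the closest dyad", {
  p <- build_profile(mk_hits(5010, 5020), mk_dyads(5000), flank = 1000)
  expect_equal(p$count[p$offset %in% 10:19], rep(1L, 10))
  expect_equal(sum(p$count), 10L)
  expect_equal(attr(p, "n_motif_bp"), 10L)
  # closest-dyad assignment by hit midpoint
  p2 <- build_profile(mk_hits(5086, 5094), mk_dyads(c(5000, 5200)), flank = 1000)
  expect_equal(sum(p2$count[p2$offset %in% 86:93]), 8L)  # assigned to 5000
  # exact midpoint tie -> lower-coordinate dyad
  p3 <- build_profile(mk_hits(5096, 5104), mk_dyads(c(5000, 5200)), flank = 1000)
  expect_equal(sum(p3$count[p3$offset > 0]), 8L)
  expect_error(build_profile(mk_hits(0, 8), mk_dyads(integer(0))), "empty dyad map")
})

test_that("profile mass within the flank is conserved", {
  set.seed(61)
  dy <- mk_dyads(sort(sample(2000:48000, 30)))
  st <- sample(0:49990, 200)
  hits <- mk_hits(st, st + 8)
  p <- build_profile(hits, dy, flank = 1000)
  mids <- st + 4L
  near <- vapply(mids, function(m) min(abs(dy$pos - m)), numeric(1))
  # every base of a hit whose bases all fall within the flank is counted
  expect_equal(sum(p$count),
               sum(vapply(seq_along(st), function(i) {
                 dd <- dy$pos[which.min(abs(dy$pos - mids[i]) + 1e-9 * (dy$pos > mids[i]))]
                 sum(abs((st[i]:(st[i] + 7)) - dd) <= 1000)
               }, numeric(1))))
})

test_that("min-max normalization maps profiles onto [0, 1]", {
  expect_equal(normalize_profile(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_profile(c(5, 5, 5)), c(0, 0, 0))
  set.seed(3)
  x <- rnorm(100)
  nx <- normalize_profile(x)
  expect_equal(range(nx), c(0, 1))
})

test_that("occupancy correlation reproduces the toy Pearson example", {
  prof <- tibble::tibble(offset = -2:2, count = c(1, 2, 3, 4, 5))
  occ <- tibble::tibble(offset = -2:2, occupancy = c(1, 2, 3, 5, 4))
  out <- occupancy_correlation(prof, occ, flank = 2)
  expect_equal(out$pcc, 0.9)
  expect_equal(out$n, 5L)
  # perfect and perfectly inverted profiles
  occ2 <- tibble::tibble(offset = -2:2, occupancy = c(1, 2, 3, 4, 5))
  expect_equal(occupancy_correlation(prof, occ2, 2)$pcc, 1)
  occ3 <- tibble::tibble(offset = -2:2, occupancy = 6 - c(1, 2, 3, 4, 5))
  expect_equal(occupancy_correlation(prof, occ3, 2)$pcc, -1)
  occ4 <- tibble::tibble(offset = -2:2, occupancy = rep(2, 5))
  expect_error(occupancy_correlation(prof, occ4, 2), "constant")
})

test_that("SHL windows convert to bp offsets at 73/7 bp per turn", {
  expect_equal(length(shl_to_offsets(0, 1.5)), 33L)
  expect_equal(max(shl_to_offsets(0, 1.5)), 16L)
  end_off <- shl_to_offsets(5.5, 7)
  expect_equal(length(end_off), 34L)
  expect_equal(range(abs(end_off)), c(57L, 73L))
  expect_equal(shl_to_offsets(0, 0), 0L)
  expect_error(shl_to_offsets(0, 7.5), "<= 7")
})

test_that("end/dyad ratio summarizes the SHL windows", {
  uni <- tibble::tibble(offset = -1000:1000, count = 1L)
  expect_equal(end_dyad_ratio(uni), 34 / 33)
  ends <- tibble::tibble(offset = -1000:1000,
                         count = as.integer(abs(-1000:1000) %in% 57:73))
  expect_error(end_dyad_ratio(ends), "zero")
  expect_equal(end_dyad_ratio(ends, inf_on_zero = TRUE), Inf)
  ctr <- tibble::tibble(offset = -1000:1000,
                        count = as.integer(abs(-1000:1000) <= 16))
  expect_equal(end_dyad_ratio(ctr), 0)
})

test_that("symmetric planting gives near-perfect half-profile symmetry", {
  set.seed(71)
  dy <- mk_dyads(seq(5000, 95000, by = 1000))
  offs <- sample(c(-60:-10, 10:60), 400, replace = TRUE)
  host <- sample(dy$pos, 400, replace = TRUE)
  st <- host + c(offs, -offs) - 4L   # mirror every placement
  hits <- mk_hits(st, st + 8L)
  p <- build_profile(hits, dy, flank = 1000)
  expect_gt(profile_symmetry(p), 0.95)
})
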
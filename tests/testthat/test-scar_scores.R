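test_that("LOH counting follows the long-segment and whole-chromosome rules", {
  expect_equal(compute_loh(balanced_profile(), toy3), 0)

  # one 20 Mb and one 10 Mb LOH segment: only the long one counts
  p <- make_profile(seg("chr1", 1, 5e6, 2, 1, 1),
                    seg("chr1", 10e6, 30e6 - 1, 1, 1, 0),     # 20 Mb
                    seg("chr1", 60e6, 70e6 - 1, 1, 1, 0),     # 10 Mb
                    seg("chr1", 75e6, 100e6, 2, 1, 1))
  expect_equal(compute_loh(p, toy3), 1)

  # LOH spanning the whole chromosome is excluded
  w <- make_profile(seg("chr1", 1, 100e6, 1, 1, 0))
  expect_equal(compute_loh(w, toy3), 0)

  # ... also when the whole-chromosome region is split into abutting pieces
  w2 <- make_profile(seg("chr1", 1, 40e6, 1, 1, 0),
                     seg("chr1", 40e6 + 1, 100e6, 2, 2, 0))
  expect_equal(compute_loh(w2, toy3), 0)

  # homozygous deletion (total 0) is not an LOH event
  hd <- make_profile(seg("chr1", 10e6, 40e6, 0, 0, 0))
  expect_equal(compute_loh(hd, toy3), 0)
})

test_that("TAI requires imbalance, length, telomere contact and an intact
          centromere relation", {
  expect_equal(compute_tai(balanced_profile(), toy3), 0)

  # 20 Mb imbalanced segment at the p-terminus
  p <- make_profile(seg("chr1", 1, 20e6, 3, 2, 1))
  expect_equal(compute_tai(p, toy3), 1)

  # identical segment placed interstitially does not count
  p2 <- make_profile(seg("chr1", 5e6, 25e6 - 1, 3, 2, 1))
  expect_equal(compute_tai(p2, toy3), 0)

  # q-terminal contact also counts
  p3 <- make_profile(seg("chr1", 80e6, 100e6, 3, 2, 1))
  expect_equal(compute_tai(p3, toy3), 1)

  # crossing the centromere disqualifies
  p4 <- make_profile(seg("chr1", 1, 60e6, 3, 2, 1))
  expect_equal(compute_tai(p4, toy3), 0)

  # too short (10 Mb < 11 Mb) does not count
  p5 <- make_profile(seg("chr1", 1, 10e6, 3, 2, 1))
  expect_equal(compute_tai(p5, toy3), 0)

  # telomere tolerance admits near-terminal segments
  p6 <- make_profile(seg("chr1", 50e3, 20e6, 3, 2, 1))
  expect_equal(compute_tai(p6, toy3), 0)
  expect_equal(compute_tai(p6, toy3, telomere_tolerance = 1e5), 1)
})

test_that("LST counts large-scale junctions after smoothing", {
  expect_equal(compute_lst(balanced_profile(), toy3), 0)

  # two adjacent 20 Mb segments of different state on one arm
  p <- make_profile(seg("chr1", 1, 20e6, 2, 1, 1),
                    seg("chr1", 20e6 + 1, 40e6, 4, 2, 2))
  expect_equal(compute_lst(p, toy3), 1)

  # a 2 Mb interruption between same-state flanks is smoothed away
  p2 <- make_profile(seg("chr1", 1, 20e6, 2, 1, 1),
                     seg("chr1", 20e6 + 1, 22e6, 4, 2, 2),
                     seg("chr1", 22e6 + 1, 42e6, 2, 1, 1))
  expect_equal(compute_lst(p2, toy3), 0)

  # ... but different-state flanks still yield one junction across it
  p3 <- make_profile(seg("chr1", 1, 20e6, 2, 1, 1),
                     seg("chr1", 20e6 + 1, 22e6, 3, 2, 1),
                     seg("chr1", 22e6 + 1, 42e6, 4, 2, 2))
  expect_equal(compute_lst(p3, toy3), 1)

  # junctions across a gap wider than the smoothing scale do not count
  p4 <- make_profile(seg("chr1", 1, 20e6, 2, 1, 1),
                     seg("chr1", 24e6 + 2, 44e6, 4, 2, 2))
  expect_equal(compute_lst(p4, toy3), 0)

  # a segment crossing the centromere is clipped per arm: state change on
  # the p side only is one junction, not two
  p5 <- make_profile(seg("chr1", 1, 20e6, 2, 1, 1),
                     seg("chr1", 20e6 + 1, 70e6, 4, 2, 2),
                     seg("chr1", 70e6 + 1, 100e6, 4, 2, 2))
  expect_equal(compute_lst(p5, toy3), 1)
})

test_that("the HRD score is the sum of the three components", {
  r0 <- compute_hrd_score(balanced_profile(), toy3)
  expect_equal(unlist(r0[, c("tai", "lst", "loh", "hrd_score")]),
               c(tai = 0, lst = 0, loh = 0, hrd_score = 0))

  # engineered profile: 2 TAI + 1 LST + 3 LOH = HRD score 6
  p <- make_profile(
    seg("chr1", 1, 12e6, 3, 2, 1),                 # TAI at chr1 p-terminus
    seg("chr1", 20e6, 36e6 - 1, 1, 1, 0),          # 16 Mb LOH, interstitial
    seg("chr1", 84e6 + 1, 100e6, 3, 2, 1),         # TAI at chr1 q-terminus
    seg("chr2", 10e6, 22e6 - 1, 2, 1, 1),          # LST pair ...
    seg("chr2", 22e6, 34e6 - 1, 4, 2, 2),          # ... one junction
    seg("chr2", 60e6, 76e6 - 1, 1, 1, 0),          # 16 Mb LOH
    seg("chr3", 10e6, 26e6 - 1, 1, 1, 0)           # 16 Mb LOH
  )
  r <- compute_hrd_score(p, toy3)
  expect_equal(r$tai, 2)
  expect_equal(r$lst, 1)
  expect_equal(r$loh, 3)
  expect_equal(r$hrd_score, 6)

  # definitional: total always equals the sum of separately computed parts
  set.seed(11)
  for (i in 1:5) {
    rp <- random_profile()
    rr <- compute_hrd_score(rp, toy3)
    expect_equal(rr$hrd_score,
                 compute_tai(rp, toy3) + compute_lst(rp, toy3) +
                   compute_loh(rp, toy3))
  }
})

test_that("components agree exactly with the brute-force rule enumerators", {
  set.seed(101)
  for (i in 1:40) {
    p <- random_profile()
    expect_equal(compute_tai(p, toy3), oracle_tai(p, toy3), info = i)
    expect_equal(compute_lst(p, toy3), oracle_lst(p, toy3), info = i)
    expect_equal(compute_loh(p, toy3), oracle_loh(p, toy3), info = i)
  }
})

test_that("scores are invariant to chromosome relabelling order and to
          terminus-preserving translation", {
  set.seed(33)
  p <- random_profile()
  # permute row order (processing order must not matter)
  df <- as.data.frame(p)
  shuffled <- segment_profile(df[sample(nrow(df)), ], toy3)
  expect_equal(compute_hrd_score(shuffled, toy3)[, -1],
               compute_hrd_score(p, toy3)[, -1])

  # shift an interstitial event; scores unchanged while relations hold
  base <- make_profile(seg("chr1", 10e6, 26e6 - 1, 1, 1, 0))
  for (offset in c(-3e6, 2e6, 8e6)) {
    moved <- make_profile(seg("chr1", 10e6 + offset, 26e6 - 1 + offset,
                              1, 1, 0))
    expect_equal(compute_hrd_score(moved, toy3)[, -1],
                 compute_hrd_score(base, toy3)[, -1])
  }
})

test_that("adding one isolated qualifying LOH segment increments loh only", {
  set.seed(55)
  base <- make_profile(seg("chr1", 1, 12e6, 3, 2, 1),
                       seg("chr2", 10e6, 22e6 - 1, 2, 1, 1),
                       seg("chr2", 22e6, 34e6 - 1, 4, 2, 2))
  before <- compute_hrd_score(base, toy3)
  with_loh <- make_profile(seg("chr1", 1, 12e6, 3, 2, 1),
                           seg("chr2", 10e6, 22e6 - 1, 2, 1, 1),
                           seg("chr2", 22e6, 34e6 - 1, 4, 2, 2),
                           seg("chr3", 20e6, 36e6 - 1, 1, 1, 0))
  after <- compute_hrd_score(with_loh, toy3)
  expect_equal(after$loh, before$loh + 1)
  expect_equal(after$tai, before$tai)
  expect_equal(after$lst, before$lst)
})
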
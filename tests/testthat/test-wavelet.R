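test_that("single-level Haar decomposition matches the filter-bank oracle", {
  # hand-checkable 2x2 case: [[1,2],[3,4]] row-wise
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  s <- dwt2(m)
  expect_equal(as.numeric(s$ll), 5)
  expect_equal(as.numeric(s$hh), 0)
  expect_equal(as.numeric(s$lh), -1)  # high-pass along width, first - second
  expect_equal(as.numeric(s$hl), -2)  # high-pass along height
  # independent separable filter-bank oracle on random sizes
  for (seed in 1:5) {
    x <- rand_image(8, 12, seed = seed)[, , 1]
    s <- dwt2(x)
    o <- haar_oracle(x)
    for (b in c("ll", "lh", "hl", "hh"))
      expect_equal(as.numeric(s[[b]]), as.numeric(o[[b]]), tolerance = 1e-12)
  }
  # constant image: ll doubles the value, details vanish
  s <- dwt2(matrix(0.3, 6, 6))
  expect_equal(as.numeric(s$ll), rep(0.6, 9))
  expect_true(all(abs(c(s$lh, s$hl, s$hh)) < 1e-15))
})

test_that("dwt2/idwt2 are exact inverses and preserve energy", {
  sizes <- c(16L, 32L, 64L, 256L)
  worst_rec <- 0; worst_en <- 0
  for (k in 1:25) for (n in sizes) {
    x <- rand_image(n, seed = 1000L + 17L * k + n)
    s <- dwt2(x)
    worst_rec <- max(worst_rec, max(abs(idwt2(s) - x)))
    en <- sum(vapply(s[c("ll", "lh", "hl", "hh")], function(b) sum(b^2), numeric(1)))
    worst_en <- max(worst_en, abs(en - sum(x^2)) / sum(x^2))
  }
  expect_lt(worst_rec, 1e-5)
  expect_lt(worst_en, 1e-6)
  # both directions
  s <- dwt2(rand_image(10, seed = 2))
  s2 <- dwt2(idwt2(s))
  for (b in c("ll", "lh", "hl", "hh"))
    expect_equal(s2[[b]], s[[b]], tolerance = 1e-10)
  # all-zero stack inverts to an all-zero image
  z <- dwt2(matrix(0, 4, 4))
  expect_true(all(idwt2(z) == 0))
})

test_that("the transform is linear", {
  x <- rand_image(12, seed = 5); y <- rand_image(12, seed = 6)
  sx <- dwt2(x); sy <- dwt2(y); sc <- dwt2(2.5 * x - 1.25 * y)
  for (b in c("ll", "lh", "hl", "hh"))
    expect_equal(sc[[b]], 2.5 * sx[[b]] - 1.25 * sy[[b]], tolerance = 1e-12)
})

test_that("odd dimensions are rejected with the offending axis named", {
  expect_error(dwt2(matrix(0, 5, 4)), "height")
  expect_error(dwt2(matrix(0, 4, 7)), "width")
  expect_error(dwt_multilevel(matrix(0, 254, 254), 2), "at most 1 level")
})

test_that("multi-level decomposition halves per level and conserves energy", {
  x <- rand_image(32, seed = 9)
  ml <- dwt_multilevel(x, 3)
  for (k in 1:3) expect_equal(dim(ml[[k]]$ll)[1:2], c(32, 32) / 2^k)
  # level 1 equals the single-level transform
  s1 <- dwt2(x)
  for (b in c("ll", "lh", "hl", "hh")) expect_equal(ml[[1]][[b]], s1[[b]])
  # level k+1 decomposes level k's ll
  s2 <- dwt2(ml[[1]]$ll)
  for (b in c("ll", "lh", "hl", "hh")) expect_equal(ml[[2]][[b]], s2[[b]])
  # total energy: final ll plus all detail bands
  en <- sum(ml[[3]]$ll^2) +
    sum(vapply(ml, function(s) sum(s$lh^2) + sum(s$hl^2) + sum(s$hh^2), numeric(1)))
  expect_lt(abs(en - sum(x^2)) / sum(x^2), 1e-5)
  # 8x8 constant at 3 levels: final ll is 1x1 with value 8c
  mlc <- dwt_multilevel(matrix(0.25, 8, 8), 3)
  expect_equal(dim(mlc[[3]]$ll)[1:2], c(1, 1))
  expect_equal(as.numeric(mlc[[3]]$ll), 8 * 0.25)
})

test_that("sub-band packing is the frozen (ll, lh, hl, hh) channel order and inverts", {
  x <- rand_image(4, 4, c = 1, seed = 3)
  s <- dwt2(x)
  p <- pack_subbands(s)
  expect_equal(dim(p), c(2, 2, 4))
  expect_equal(p[, , 1], s$ll[, , 1])
  expect_equal(p[, , 2], s$lh[, , 1])
  expect_equal(p[, , 3], s$hl[, , 1])
  expect_equal(p[, , 4], s$hh[, , 1])
  u <- unpack_subbands(p)
  for (b in c("ll", "lh", "hl", "hh")) expect_identical(u[[b]], s[[b]])
  # multi-channel: blocks of C per band
  x3 <- rand_image(8, 8, c = 3, seed = 4)
  p3 <- pack_subbands(dwt2(x3))
  expect_equal(dim(p3), c(4, 4, 12))
  u3 <- unpack_subbands(p3)
  expect_equal(u3$hl, dwt2(x3)$hl)
  # constant image: channel 1 is 2c, detail channels zero
  pc <- pack_subbands(dwt2(matrix(0.4, 6, 6)))
  expect_equal(as.numeric(pc[, , 1]), rep(0.8, 9))
  expect_true(all(pc[, , 2:4] == 0))
})

test_that("mismatched sub-band shapes are rejected", {
  s <- dwt2(rand_image(8, seed = 1))
  s$hh <- s$hh[1:2, , , drop = FALSE]
  expect_error(idwt2(s), "differ")
  expect_error(unpack_subbands(rand_image(4, 4, c = 6, seed = 1)), "multiple of 4")
})
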
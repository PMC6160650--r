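test_that("the BH step-up rule declares exactly the computed set", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.09, 0.2, 0.5, 0.9, 0.95, 1.0)
  res <- fdr_bh(p, 0.05)
  # exhaustive k-scan: largest k with p_(k) <= k q / m is k = 2 here
  expect_identical(res$significant, bh_oracle(p, 0.05))
  expect_equal(res$n_significant, 2L)
  expect_equal(res$threshold, 0.008)
  expect_identical(res$significant,
                   stats::p.adjust(p, "BH") <= 0.05)

  expect_equal(fdr_bh(rep(1, 20), 0.05)$n_significant, 0L)
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 0), 0.05), "lie in")
  expect_error(fdr_bh(c(0.5, 0.2), 1.5), "q must")
})

test_that("BH matches the oracle and p.adjust on random vectors and is monotone in q", {
  withr::with_seed(41, {
    for (i in 1:300) {
      m <- sample(5:120, 1)
      p <- stats::runif(m)^sample(c(1, 2, 3), 1)
      p[p == 0] <- 1e-12
      q <- stats::runif(1, 0.01, 0.2)
      res <- fdr_bh(p, q)
      expect_identical(res$significant, bh_oracle(p, q))
      expect_identical(res$significant, stats::p.adjust(p, "BH") <= q)
      # monotone: a larger q never declares fewer voxels
      res2 <- fdr_bh(p, min(q * 2, 0.99))
      expect_true(all(res$significant <= res2$significant))
    }
  })
})

test_that("duplicating every p-value scales the declared set proportionally", {
  withr::with_seed(42, p <- stats::runif(40)^2)
  one <- fdr_bh(p, 0.05)$significant
  two <- fdr_bh(c(p, p), 0.05)$significant
  expect_identical(two, c(one2 <- bh_oracle(c(p, p), 0.05)))
  # the doubled vector declares each copy identically
  expect_identical(two[1:40], two[41:80])
  # and at least as many in proportion (BH is scale-stable upward here)
  expect_gte(sum(two) / 80, sum(one) / 40)
})

make_zmap <- function(z_arr, vox = c(1.5, 1.5, 1.5)) {
  d <- dim(z_arr)
  aff <- diag(c(vox, 1)); aff[1:3, 4] <- -vox * (d - 1) / 2
  structure(list(t = z_arr, p = z_arr, z = z_arr, df = 10,
                 contrast = list(name = "test"),
                 mask_idx = seq_along(z_arr), grid = d, affine = aff,
                 voxel_size_mm = vox), class = "stat_map")
}

test_that("connected components split and merge correctly by connectivity", {
  d <- c(8, 8, 3)
  m <- array(0L, d)
  # blob A: 5 voxels, face-connected; blob B: 3 voxels joined only
  # diagonally, so it fragments under 6-connectivity
  m[2:4, 2, 1] <- 1L; m[3, 3, 1] <- 1L; m[3, 4, 1] <- 1L
  m[5, 6, 1] <- 1L; m[6, 7, 1] <- 1L; m[7, 8, 1] <- 1L
  z <- array(0, d); z[m == 1L] <- seq_len(sum(m))
  zm <- make_zmap(z)
  msk <- region_mask(m, "sig", zm$affine, zm$voxel_size_mm)
  ct26 <- extract_clusters(msk, zm, 26L)
  expect_equal(sort(ct26$table$size_voxels), c(3, 5))
  # under 6-connectivity the diagonal touch at (3,4)-(?) stays two blobs,
  # and blob B itself splits at its diagonal joint
  ct6 <- extract_clusters(msk, zm, 6L)
  expect_gt(nrow(ct6$table), nrow(ct26$table))
  expect_error(extract_clusters(msk, zm, 10L), "connectivity")
})

test_that("cluster reporting mirrors the standard table conventions", {
  d <- c(10, 10, 10)
  m <- array(0L, d)
  m[2:3, 2, 2] <- 1L          # cluster of 2
  m[7, 7, 7] <- 1L            # singleton
  z <- array(NA_real_, d)
  z[2, 2, 2] <- 3.0; z[3, 2, 2] <- 4.2; z[7, 7, 7] <- 5.0
  zm <- make_zmap(z)
  msk <- region_mask(m, "sig", zm$affine, zm$voxel_size_mm)
  ct <- extract_clusters(msk, zm, 26L)
  expect_equal(ct$table$size_voxels, c(2, 1))          # sorted descending
  expect_equal(ct$table$peak_z, c(4.2, 5.0))
  # world coordinate of the singleton: 0-based index 6 at 1.5mm, centred
  expect_equal(ct$table$x_mm[2], (7 - 1) * 1.5 - 1.5 * 9 / 2)
  expect_equal(ct$table$size_ml, voxels_to_ml(c(2, 1)))
  # 2,203 voxels at 1.5mm iso report as 7.4 ml
  expect_equal(round(voxels_to_ml(2203), 1), 7.4)
  # clusters partition the mask
  expect_equal(sum(ct$table$size_voxels), sum(m))
  expect_identical(sort(which(ct$labels > 0)), which(m == 1L))
  # empty mask: empty table
  empty <- region_mask(array(0L, d), "sig", zm$affine, zm$voxel_size_mm)
  expect_equal(nrow(extract_clusters(empty, zm)$table), 0)
})

test_that("region overlap is an intersection", {
  d <- c(22, 22, 22)
  withr::with_seed(43, {
    a <- array(as.integer(stats::runif(prod(d)) < 0.3), d)
    b <- array(as.integer(stats::runif(prod(d)) < 0.4), d)
  })
  ma <- region_mask(a, "A"); mb <- region_mask(b, "B")
  ov <- region_overlap(ma, mb)
  expect_identical(ov$data, array(as.integer(a & b), d))
  # idempotence and disjointness
  expect_identical(region_overlap(ma, ma)$data, ma$data)
  expect_equal(sum(region_overlap(ma, region_mask(1L - a, "notA"))$data), 0)
  # independent densities multiply (Monte Carlo)
  expect_lt(abs(mean(ov$data) - 0.12), 0.02)
  # grid mismatch rejected
  expect_error(region_overlap(ma, region_mask(array(0L, c(5, 5, 5)))),
               "same grid")
})
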
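test_that("judgment_matrix validates reciprocity, diagonal, and scale", {
  expect_error(judgment_matrix(matrix(1, 2, 3)), class = "les_schema_error")
  expect_error(judgment_matrix(matrix(c(1, 2, 2, 1), 2)),
               class = "les_value_error")  # not reciprocal
  expect_error(judgment_matrix(matrix(c(2, 2, 0.5, 1), 2)),
               class = "les_value_error")  # diagonal != 1
  expect_warning(judgment_matrix(matrix(c(1, 20, 1/20, 1), 2)),
                 "Saaty")
  expect_s3_class(judgment_matrix(matrix(c(1, 3, 1/3, 1), 2)),
                  "judgment_matrix")
})

test_that("judgment_from_weights builds exact ratio matrices", {
  m <- judgment_from_weights(weight_vector(c(0.5, 0.3, 0.2)))
  expect_equal(m[1, 2], 5 / 3)
  expect_equal(m[2, 1], 3 / 5)
  expect_equal(unname(diag(unclass(m))), rep(1, 3))
  expect_equal(consistency(m)$cr, 0, tolerance = 1e-12)
  expect_error(judgment_from_weights(c(0.5, 0.5, 0)),
               class = "les_value_error")
})

test_that("the eigenvector recovers generating weights exactly at zero noise", {
  w <- weight_vector(c(S1 = 0.3341, S2 = 0.3780, S3 = 0.2879) / 1.0000)
  pe <- principal_eigen(judgment_from_weights(w))
  expect_equal(as.numeric(pe$weights), as.numeric(w), tolerance = 1e-9)
  expect_equal(pe$lambda_max, 3, tolerance = 1e-9)
})

test_that("principal_eigen matches closed forms on consistent matrices", {
  m2 <- judgment_matrix(matrix(c(1, 2, 1/2, 1), 2, byrow = TRUE))
  pe2 <- principal_eigen(m2)
  expect_equal(as.numeric(pe2$weights), c(2/3, 1/3), tolerance = 1e-12)
  expect_equal(pe2$lambda_max, 2, tolerance = 1e-12)

  pe3 <- principal_eigen(consistent3())
  expect_equal(as.numeric(pe3$weights), c(4, 2, 1) / 7, tolerance = 1e-12)
  expect_equal(pe3$lambda_max, 3, tolerance = 1e-12)
  # geometric-mean extractor agrees on consistent matrices
  pg <- principal_eigen(consistent3(), method = "geometric")
  expect_equal(as.numeric(pg$weights), c(4, 2, 1) / 7, tolerance = 1e-12)
})

test_that("power iteration agrees with the dense eigendecomposition oracle", {
  for (n in 2:10) {
    w <- rand_weights(n, seed = n)
    for (pert in c(0, 0.15, 0.5)) {
      m <- judgment_from_weights(w, perturbation = pert, seed = 7 * n)
      pe <- principal_eigen(m)
      or <- eigen_oracle(m)
      expect_equal(pe$lambda_max, or$lambda_max, tolerance = 1e-8)
      expect_equal(as.numeric(pe$weights), or$weights, tolerance = 1e-8)
      expect_gte(pe$lambda_max, n - 1e-9)
    }
  }
})

test_that("an inconsistent matrix has lambda_max > n and CR > 0", {
  m <- inconsistent3()
  or <- eigen_oracle(m)
  expect_gt(or$lambda_max, 3)
  rep <- consistency(m)
  expect_equal(rep$lambda_max, or$lambda_max, tolerance = 1e-8)
  expect_equal(rep$ci, (or$lambda_max - 3) / 2, tolerance = 1e-8)
  expect_equal(rep$ri, 0.58)
  expect_gt(rep$cr, 0)
})

test_that("order-2 matrices are always consistent; order > 10 unsupported", {
  m2 <- judgment_matrix(matrix(c(1, 7, 1/7, 1), 2))
  rep <- consistency(m2)
  expect_equal(rep$cr, 0)
  expect_true(rep$consistent)
  w11 <- rand_weights(11, seed = 1)
  expect_error(consistency(judgment_from_weights(w11)),
               class = "les_value_error")
  # extendable via a supplied RI table
  expect_silent(consistency(judgment_from_weights(w11),
                            ri_table = c(landsec:::RI_TABLE, 1.51)))
})

test_that("consistency metrics are permutation invariant, weights equivariant", {
  w <- rand_weights(5, seed = 21)
  m <- judgment_from_weights(w, perturbation = 0.3, seed = 5)
  rep <- consistency(m)
  pe <- principal_eigen(m)
  for (s in 1:3) {
    p <- landsec:::with_seed(s, sample(5))
    mp <- suppressWarnings(judgment_matrix(unclass(m)[p, p],
                                           labels = rownames(m)[p]))
    repp <- consistency(mp)
    expect_equal(repp$lambda_max, rep$lambda_max, tolerance = 1e-9)
    expect_equal(repp$cr, rep$cr, tolerance = 1e-9)
    expect_equal(as.numeric(principal_eigen(mp)$weights),
                 as.numeric(pe$weights)[p], tolerance = 1e-9)
  }
})

test_that("hierarchical_weights follows the product rule", {
  top <- judgment_from_weights(weight_vector(rep(1/3, 3),
                                             labels = c("S1", "S2", "S3")))
  groups <- list(
    S1 = judgment_from_weights(weight_vector(rep(1/6, 6),
                                             labels = paste0("S1", 1:6))),
    S2 = judgment_from_weights(weight_vector(rep(1/6, 6),
                                             labels = paste0("S2", 1:6))),
    S3 = judgment_from_weights(weight_vector(rep(1/5, 5),
                                             labels = paste0("S3", 1:5))))
  hw <- hierarchical_weights(top, groups)
  expect_equal(sum(hw$global), 1, tolerance = 1e-9)
  expect_equal(unname(hw$global[paste0("S1", 1:6)]), rep(1/18, 6),
               tolerance = 1e-9)
  expect_equal(unname(hw$global[paste0("S3", 1:5)]), rep(1/15, 5),
               tolerance = 1e-9)
})

test_that("weights reconstructed from the published table keep per-group order", {
  b <- generate_study_like_bundle(seed = 1)
  hw <- hierarchical_weights(b$judgments$top,
                             b$judgments[c("S1", "S2", "S3")])
  expect_equal(sum(hw$global), 1, tolerance = 1e-9)
  expect_equal(as.numeric(hw$main), c(0.3341, 0.3780, 0.2879),
               tolerance = 1e-6)
  tab2 <- load_fixture("table2_weights")
  # within every group the published rank order is preserved
  for (g in c("S1", "S2", "S3")) {
    sub <- tab2[tab2$group == g, ]
    expect_equal(order(-hw$global[sub$id]), order(sub$rank))
  }
  # global extremes match the published rank column
  expect_equal(names(which.max(hw$global)), "S31")
  expect_equal(names(which.min(hw$global)), "S26")
})

test_that("inconsistent matrices are rejected unless forced", {
  top <- inconsistent3()
  dimnames(top) <- list(c("S1", "S2", "S3"), c("S1", "S2", "S3"))
  groups <- lapply(stats::setNames(nm = c("S1", "S2", "S3")), function(g)
    judgment_from_weights(weight_vector(rep(1/3, 3),
                                        labels = paste0(g, 1:3))))
  err <- tryCatch(hierarchical_weights(top, groups), condition = identity)
  expect_s3_class(err, "les_consistency_error")
  expect_s3_class(err$report, "consistency_report")
  expect_silent(hierarchical_weights(top, groups, force = TRUE))
})

test_that("judgment matrices round-trip through CSV and JSON", {
  m <- judgment_from_weights(rand_weights(4, seed = 9), 0.1, seed = 2)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_judgment(m, path)
    expect_equal(unclass(read_judgment(path)), unclass(m),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # upper-triangular elicitation completed by reciprocity
  path <- withr::local_tempfile(fileext = ".csv")
  half <- unclass(m)
  half[lower.tri(half)] <- NA
  utils::write.csv(as.data.frame(half), path, row.names = FALSE)
  expect_equal(unclass(read_judgment(path, auto_complete = TRUE)),
               unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
})
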
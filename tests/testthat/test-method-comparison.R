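make_cells <- function(classes_by_method) {
  # two drugs x one polymer x two loadings per method
  grid <- expand.grid(drug = c("D1", "D2"), polymer = "P",
                      drug_loading = c(0.2, 0.4), stringsAsFactors = FALSE)
  do.call(rbind, lapply(names(classes_by_method), function(m) {
    g <- grid
    g$method <- m
    g$class <- classes_by_method[[m]]
    g
  }))
}

test_that("class encoding is ordinal by default and grid-checked", {
  cells <- make_cells(list(SD = c("A", "A", "AA", "AC"),
                           QC = c("A", "A", "A", "A")))
  mat <- encode_class_matrix(cells)
  expect_equal(dim(mat), c(2, 4))
  expect_equal(sort(unname(mat["SD", ])), c(0, 1, 2, 2))
  expect_true(all(mat["QC", ] == 2))

  # two methods differing in one cell differ in exactly one column
  cells2 <- make_cells(list(SD = c("A", "A", "AA", "AC"),
                            AD = c("A", "A", "A", "AC")))
  mat2 <- encode_class_matrix(cells2)
  expect_equal(sum(mat2["SD", ] != mat2["AD", ]), 1)

  # incomplete grids are rejected with the missing cell named
  expect_error(encode_class_matrix(cells[-1, ]), "missing cell")

  oh <- encode_class_matrix(cells, encoding = "onehot")
  expect_equal(ncol(oh), 12)
  expect_true(all(rowSums(oh) == 4))
})

test_that("PCA ratios match an independent eigendecomposition", {
  set.seed(31)
  m <- matrix(stats::rnorm(64), 8, 8,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:8)))
  res <- pca_screen(m)
  oracle <- eigen(stats::cor(m), symmetric = TRUE)$values
  expect_equal(res$all_ratios, oracle / sum(oracle), tolerance = 1e-9)
  expect_equal(sum(res$all_ratios), 1, tolerance = 1e-9)
  # loadings are orthonormal; ratios are non-increasing and in [0,1]
  expect_equal(crossprod(res$loadings), diag(res$n_components),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(res$explained_variance_ratio) <= 1e-12))
  expect_true(all(res$explained_variance_ratio >= 0 &
                    res$explained_variance_ratio <= 1))
  # full-rank reconstruction of the standardized matrix
  z <- scale(m)
  expect_equal(res$scores %*% t(res$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate structures are handled explicitly", {
  # two perfectly correlated columns: PC1 explains everything
  x <- stats::rnorm(10)
  m <- cbind(a = x, b = 2 * x + 1)
  rownames(m) <- paste0("r", 1:10)
  res <- pca_screen(m)
  expect_equal(res$explained_variance_ratio[1], 1, tolerance = 1e-12)
  # constant columns are dropped with a warning
  m2 <- cbind(m, cst = rep(1, 10))
  expect_warning(res2 <- pca_screen(m2), "zero-variance")
  expect_equal(res2$dropped, "cst")
  # all-constant matrices are degenerate
  expect_error(suppressWarnings(
    pca_screen(cbind(a = rep(1, 5), b = rep(2, 5), c = x[1:5]))),
    "non-degenerate")
  expect_error(pca_screen(m, n_components = 50), "must not exceed")
})

test_that("PCA is invariant to row permutation up to row order", {
  set.seed(13)
  m <- matrix(stats::rnorm(40), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  res <- pca_screen(m, n_components = 2)
  perm <- sample(8)
  res_p <- pca_screen(m[perm, ], n_components = 2)
  expect_equal(res_p$scores[rownames(res$scores), ], res$scores,
               tolerance = 1e-8)
  expect_equal(res_p$explained_variance_ratio,
               res$explained_variance_ratio, tolerance = 1e-10)
})

test_that("proximity report ranks the reference first and respects ties", {
  set.seed(17)
  m <- matrix(stats::rnorm(30), 6, 5,
              dimnames = list(c("SD", "AD", "QC", "FC", "X", "Y"),
                              paste0("c", 1:5)))
  res <- pca_screen(m, n_components = 2)
  pr <- proximity_report(res, "SD")
  expect_equal(pr$method[1], "SD")
  expect_equal(pr$distance[1], 0)
  expect_true(all(diff(pr$distance) >= 0))
  # a duplicated reference row ties at distance zero
  m2 <- rbind(m, SD2 = m["SD", ])
  res2 <- pca_screen(m2, n_components = 2)
  pr2 <- proximity_report(res2, "SD")
  expect_equal(pr2$distance[pr2$method %in% c("SD", "SD2")], c(0, 0),
               tolerance = 1e-10)
  expect_error(proximity_report(res, "nope"), "not found")
})

test_that("the method with the smallest planted bias sits nearest the reference", {
  spec <- small_campaign_spec(biases = c(FC_RT = -0.3, FC_RP = -0.2,
                                         QC = 0.3, AD = -0.05, SD = 0))
  camp <- make_campaign(spec)
  cl <- classify_campaign(camp$observations, bundled_compounds)
  mat <- encode_class_matrix(cl$cells)
  # direct Euclidean check on the encoding, then through PCA
  d_enc <- sqrt(rowSums(sweep(mat, 2, mat["SD", ])^2))
  expect_equal(names(which.min(d_enc[names(d_enc) != "SD"])), "AD")
  res <- suppressWarnings(pca_screen(mat, n_components = 2))
  pr <- proximity_report(res, "SD")
  expect_equal(pr$method[2], "AD")
})
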
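test_that("min-max normalization parameters record per-feature limits", {
  feats <- tibble::tibble(id = c("a", "b", "c"),
                          f1 = c(2, 4, 6), f2 = c(1, 1, 1))
  params <- fit_normalization(feats)
  expect_equal(params$z_min[params$feature == "f1"], 2)
  expect_equal(params$z_max[params$feature == "f1"], 6)
  expect_true(params$degenerate[params$feature == "f2"])
  expect_false(params$degenerate[params$feature == "f1"])

  single <- fit_normalization(tibble::tibble(id = "a", f1 = 3, f2 = -1))
  expect_true(all(single$degenerate))
  expect_error(fit_normalization(tibble::tibble(id = character(),
                                                f1 = numeric())), "empty")
})

test_that("normalization maps min to 0, max to 1, midpoint to 0.5", {
  feats <- tibble::tibble(id = c("a", "b", "c"),
                          f1 = c(2, 4, 6), f2 = c(-1, 0, 3))
  params <- fit_normalization(feats)
  norm <- apply_normalization(feats, params)
  expect_equal(norm$f1, c(0, 0.5, 1))
  expect_equal(norm$f2[c(1, 3)], c(0, 1))

  # fit on one set, applied to another: clipped into [0, 1]
  other <- tibble::tibble(id = "z", f1 = 100, f2 = -100)
  clipped <- apply_normalization(other, params)
  expect_equal(clipped$f1, 1)
  expect_equal(clipped$f2, 0)

  # degenerate features map to 0
  deg <- fit_normalization(tibble::tibble(id = c("a", "b"), f = c(5, 5)))
  expect_equal(apply_normalization(tibble::tibble(id = "a", f = 5), deg)$f, 0)

  expect_error(
    apply_normalization(tibble::tibble(id = "a", other = 1), params),
    "schema")
})

test_that("normalization fit-and-applied to the same set stays in [0,1]", {
  withr::with_seed(53, {
    feats <- tibble::as_tibble(
      matrix(rnorm(40 * 8, sd = 10), 40, 8,
             dimnames = list(NULL, paste0("f", 1:8))))
  })
  feats <- dplyr::bind_cols(tibble::tibble(id = paste0("p", 1:40)), feats)
  norm <- apply_normalization(feats, fit_normalization(feats))
  m <- as.matrix(norm[, -1])
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(apply(m, 2, min)), rep(0, 8))
  expect_equal(unname(apply(m, 2, max)), rep(1, 8))
})

test_that("pair differences are signed or absolute as requested", {
  a <- c(f1 = 0.2, f2 = 0.7)
  b <- c(f1 = 0.5, f2 = 0.1)
  expect_equal(unname(pair_difference(a, b, "signed")), c(-0.3, 0.6))
  expect_equal(pair_difference(a, a, "signed"), c(f1 = 0, f2 = 0))
  expect_equal(pair_difference(a, a, "absolute"), c(f1 = 0, f2 = 0))
  expect_equal(pair_difference(a, b, "absolute"),
               pair_difference(b, a, "absolute"))
  expect_error(pair_difference(a, c(x = 1, y = 2)), "schemas")
})

test_that("design matrix drops degenerate features but keeps all rows", {
  withr::with_seed(59, {
    feats <- tibble::as_tibble(
      matrix(runif(4 * 6), 4, 6, dimnames = list(NULL, paste0("f", 1:6))))
  })
  feats$f3 <- 0.5  # constant -> degenerate
  feats <- dplyr::bind_cols(tibble::tibble(id = paste0("p", 1:4)), feats)
  pairs <- tibble::tibble(id_a = c("p1", "p2", "p3"),
                          id_b = c("p2", "p3", "p4"),
                          label = c(1L, 0L, 1L))
  design <- suppressMessages(build_design_matrix(pairs, feats))
  expect_equal(nrow(design), 3L)
  expect_false("f3" %in% names(design))
  expect_equal(ncol(design), 3L + 5L)
  expect_equal(design$label, pairs$label)

  # self-pair gives a zero row
  self <- suppressMessages(build_design_matrix(
    tibble::tibble(id_a = "p1", id_b = "p1", label = 0L), feats))
  expect_equal(unname(unlist(self[1, -(1:3)])), rep(0, 5))

  # unknown protein: pair dropped with a message
  expect_message(
    d2 <- build_design_matrix(
      tibble::tibble(id_a = c("p1", "pX"), id_b = c("p2", "p1"),
                     label = c(1L, 0L)), feats),
    "missing")
  expect_equal(nrow(d2), 1L)
})

test_that("absolute-mode design matrix is symmetric under pair swap", {
  withr::with_seed(61, {
    feats <- tibble::as_tibble(
      matrix(runif(6 * 5), 6, 5, dimnames = list(NULL, paste0("f", 1:5))))
  })
  feats <- dplyr::bind_cols(tibble::tibble(id = paste0("p", 1:6)), feats)
  pairs <- tibble::tibble(id_a = c("p1", "p3", "p5"),
                          id_b = c("p2", "p4", "p6"),
                          label = c(1L, 0L, 1L))
  swapped <- tibble::tibble(id_a = pairs$id_b, id_b = pairs$id_a,
                            label = pairs$label)
  d1 <- build_design_matrix(pairs, feats, mode = "absolute")
  d2 <- build_design_matrix(swapped, feats, mode = "absolute")
  expect_equal(d1[, -(1:2)], d2[, -(1:2)])
})
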
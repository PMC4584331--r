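make_two_cluster_gsm <- function(seed, n = 200L, d = 12L, sep = 4) {
  set.seed(seed)
  centers <- rbind(rnorm(d), rnorm(d) + sep)
  grp <- rep(1:2, each = n / 2L)
  vals <- centers[grp, ] + matrix(rnorm(n * d, sd = 0.3), n)
  dimnames(vals) <- list(sprintf("G%03d", seq_len(n)), sprintf("S%02d", seq_len(d)))
  list(m = gene_sample_matrix(vals, "log_expression", centralized = TRUE), grp = grp)
}

test_that("training is deterministic and reduces quantization error", {
  fix <- make_two_cluster_gsm(1)
  m1 <- train_som(fix$m, 8, 8, epochs = 15, seed = 3)
  m2 <- train_som(fix$m, 8, 8, epochs = 15, seed = 3)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$bmu, m2$bmu)
  expect_lte(m1$qe[length(m1$qe)], m1$qe[1L])
  expect_equal(ncol(m1$codebook), 12L)
  expect_true(all(is.finite(m1$codebook)))
})

test_that("well-separated gene clusters land in disjoint grid regions", {
  fix <- make_two_cluster_gsm(2)
  model <- train_som(fix$m, 8, 8, epochs = 15, seed = 3)
  co <- unit_coords <- cbind((model$bmu %/% 8), (model$bmu %% 8))
  u1 <- unique(model$bmu[fix$grp == 1L])
  u2 <- unique(model$bmu[fix$grp == 2L])
  expect_length(intersect(u1, u2), 0L)
  # topology: same-cluster BMU grid distance < cross-cluster
  gd <- as.matrix(dist(co))
  same <- outer(fix$grp, fix$grp, "==")
  diag(same) <- NA
  expect_lt(mean(gd[which(same)]), mean(gd[which(!same)]))
  # prototypes: between-region distance exceeds within-region spread
  p1 <- model$codebook[u1 + 1L, , drop = FALSE]
  p2 <- model$codebook[u2 + 1L, , drop = FALSE]
  between <- sqrt(sum((colMeans(p1) - colMeans(p2))^2))
  within <- max(dist(p1), dist(p2))
  expect_gt(between, within)
})

test_that("identical genes collapse onto a single unit with zero error", {
  vals <- matrix(0.4, 50, 6, dimnames = list(sprintf("G%03d", 1:50), sprintf("S%02d", 1:6)))
  model <- train_som(gene_sample_matrix(vals, "methylation_beta"), 4, 4,
                     epochs = 10, seed = 1)
  expect_length(unique(model$bmu), 1L)
  expect_lt(model$qe[length(model$qe)], 1e-6)
})

test_that("assign_bmu is the exact argmin with lowest-index tie break", {
  set.seed(4)
  cb <- matrix(rnorm(10 * 5), 10)
  colnames(cb) <- sprintf("S%02d", 1:5)
  cb[8L, ] <- cb[4L, ]                       # exact tie between units 3 and 7
  model <- fake_model(cb, 2, 5)
  expect_equal(assign_bmu(model, cb[6L, ]), 5L)
  expect_equal(assign_bmu(model, cb[4L, ]), 3L)   # tie -> lowest index
  expect_error(assign_bmu(model, rnorm(4)), "length")
  # brute-force oracle over random queries
  for (i in 1:100) {
    v <- rnorm(5)
    d2 <- apply(cb, 1L, function(w) sum((w - v)^2))
    expect_identical(assign_bmu(model, v), which.min(d2) - 1L)
  }
})

test_that("sample portraits are row-major reshapes of codebook columns", {
  fix <- make_two_cluster_gsm(5)
  model <- train_som(centralize(fix$m), 6, 9, epochs = 10, seed = 2)
  p <- sample_portrait(model, "S03")
  expect_equal(dim(p), c(6L, 9L))
  expect_equal(as.vector(t(p)), unname(model$codebook[, "S03"]))
  expect_error(sample_portrait(model, "nope"), "unknown sample")
  # centralized input: prototypes are means of zero-mean gene rows
  expect_lt(max(abs(rowMeans(model$codebook))), 0.02)
})

test_that("map_gene_group conserves counts and flags unknown genes", {
  fix <- make_two_cluster_gsm(6)
  model <- train_som(fix$m, 6, 6, epochs = 10, seed = 2)
  g1 <- names(model$bmu)[1L]
  occ <- map_gene_group(model, g1)
  expect_equal(nrow(occ$coords), 1L)
  expect_equal(unname(coord_to_unit(occ$coords[1L, "row"], occ$coords[1L, "col"], 6L)),
               unname(model$bmu[g1]))
  all_occ <- map_gene_group(model, names(model$bmu))
  expect_equal(sum(all_occ$counts), 200L)
  expect_warning(sk <- map_gene_group(model, c(g1, "NOPE")), "skipped")
  expect_equal(sk$n_skipped, 1L)
  warns <- testthat::capture_warnings(map_gene_group(model, "NOPE"))
  expect_true(any(grepl("no genes", warns)))
})

test_that("training commutes with sample permutation and stored BMUs are optimal", {
  fix <- make_two_cluster_gsm(7, n = 120L, d = 10L)
  perm <- c(3L, 1L, 10L, 5L, 2L, 7L, 4L, 9L, 6L, 8L)
  m_perm <- gene_sample_matrix(fix$m$values[, perm], "log_expression",
                               centralized = TRUE)
  a <- train_som(fix$m, 6, 6, epochs = 10, seed = 9)
  b <- train_som(m_perm, 6, 6, epochs = 10, seed = 9)
  expect_equal(b$codebook, a$codebook[, perm], tolerance = 1e-8)
  expect_equal(a$bmu, b$bmu, tolerance = 0)
  # every stored BMU minimizes the distance (exhaustive scan)
  for (g in sample(names(a$bmu), 25L)) {
    d2 <- apply(a$codebook, 1L, function(w) sum((w - a$data[g, ])^2))
    expect_identical(unname(a$bmu[g]), which.min(d2) - 1L)
  }
  expect_error(train_som(tiny_gsm(matrix(c(0.1, NA, 0.3, 0.4), 2)), 4, 4),
               "finite")
})

test_that("SOM serialization round-trips through plain text", {
  fix <- make_two_cluster_gsm(8, n = 60L, d = 6L)
  model <- train_som(fix$m, 5, 5, epochs = 8, seed = 2)
  dir <- withr::local_tempdir()
  save_som(model, dir)
  back <- load_som(dir)
  expect_equal(back$codebook, model$codebook)
  expect_identical(back$bmu, model$bmu)
  expect_identical(back$data, model$data)
  expect_equal(back$grid_rows, model$grid_rows)
  expect_equal(back$qe, model$qe)
})
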
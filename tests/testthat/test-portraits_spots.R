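# one trained cohort shared by most tests in this file
ch <- small_cohort(seed = 41, n_genes = 400L, n_per_class = 25L, modules = list(
  module_spec("up", 50L, "TUM", +0.3, +1.0, "positive"),
  module_spec("dn", 50L, "TUM", -0.3, 0.0, "met_only")
))
dmet <- centralize(ch$met)
model <- train_som(dmet, 15, 15, epochs = 20, seed = 41)

test_that("class-mean portraits average member samples and conserve the global mean", {
  cls <- ch$met_ann[colnames(model$codebook)]
  one <- names(which(cls == "TUM"))[1L]
  ann1 <- ch$met_ann
  ann1[one] <- "SOLO"
  expect_equal(class_mean_portrait(model, ann1, "SOLO"),
               sample_portrait(model, one))
  p_ref <- class_mean_portrait(model, ch$met_ann, "REF")
  p_tum <- class_mean_portrait(model, ch$met_ann, "TUM")
  n_ref <- sum(cls == "REF"); n_tum <- sum(cls == "TUM")
  global <- matrix(rowMeans(model$codebook), model$grid_rows, model$grid_cols,
                   byrow = TRUE)
  expect_equal((n_ref * p_ref + n_tum * p_tum) / (n_ref + n_tum), global,
               tolerance = 1e-12)
  expect_error(class_mean_portrait(model, ch$met_ann, "nope"), "unknown class")
})

test_that("planted-module regions are hot in the class-mean portrait and variance map", {
  p_tum <- class_mean_portrait(model, ch$met_ann, "TUM")
  occ <- map_gene_group(model, ch$truth$module_genes$up)
  vals <- p_tum[cbind(occ$coords[, "row"] + 1L, occ$coords[, "col"] + 1L)]
  expect_true(all(vals > quantile(p_tum, 0.9)))
  vm <- variance_map(model)
  expect_true(all(vm[cbind(occ$coords[, "row"] + 1L, occ$coords[, "col"] + 1L)] >
                    median(vm)))
  # oracle: per-unit population variance recomputed directly
  direct <- apply(model$codebook, 1L, function(w) mean((w - mean(w))^2))
  expect_equal(as.vector(t(vm)), direct, tolerance = 1e-12)
  # constant prototype has zero variance
  cb <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  cb[2L, ] <- 7
  expect_equal(variance_map(fake_model(cb, 2, 2))[1L, 2L], 0)
})

test_that("overview spot masks honor the quantile and amplitude rules", {
  expect_error(overview_spot_map(model, q = 0.4), "q must satisfy")
  # constant model: no strict exceedance, empty mask
  cbc <- matrix(1, 9, 4, dimnames = list(NULL, sprintf("S%d", 1:4)))
  expect_false(any(overview_spot_map(fake_model(cbc, 3, 3), "high")))
  # q -> 1 limit: at most one unit per sample in the pure quantile rule
  m_hi <- overview_spot_map(model, "high", q = 0.995, min_amplitude = 0)
  expect_lte(sum(m_hi), ncol(model$codebook))
  expect_gte(sum(m_hi), 1L)
  # amplitude floor only removes units relative to the pure rule
  pure <- overview_spot_map(model, "high", min_amplitude = 0)
  floored <- overview_spot_map(model, "high")
  expect_true(all(which(floored) %in% which(pure)))
})

test_that("detect_spots segments 8-connected components above min_units", {
  mask <- matrix(FALSE, 15, 15)
  mask[2:4, 2:4] <- TRUE
  spots <- detect_spots(mask, model)
  expect_length(spots, 1L)
  expect_equal(spots[[1L]]$n_units, 9L)

  mask[10:12, 10:12] <- TRUE
  mask[7, 7] <- TRUE                       # below min_units, dropped
  spots <- detect_spots(mask, model, min_units = 4L)
  expect_length(spots, 2L)
  # diagonal touch merges under 8-connectivity
  mask2 <- matrix(FALSE, 15, 15)
  mask2[2:3, 2:3] <- TRUE
  mask2[4, 4] <- TRUE
  expect_equal(detect_spots(mask2, model, min_units = 1L)[[1L]]$n_units, 5L)

  expect_length(detect_spots(matrix(FALSE, 15, 15), model), 0L)
  expect_error(detect_spots(matrix(TRUE, 3, 3), model), "mask shape")
})

test_that("spot modules carry the genes and profiles of their region", {
  spots <- c(
    detect_spots(overview_spot_map(model, "high"), model, polarity = "high"),
    detect_spots(overview_spot_map(model, "low"), model, polarity = "low")
  )
  expect_gte(length(spots), 2L)
  # labels in decreasing size order per tail
  sizes <- vapply(spots[vapply(spots, `[[`, character(1L), "polarity") == "high"],
                  `[[`, integer(1L), "n_units")
  expect_true(all(diff(sizes) <= 0))
  # unit-disjointness within a tail and gene containment in the mask
  mask <- overview_spot_map(model, "high")
  high <- spots[vapply(spots, `[[`, character(1L), "polarity") == "high"]
  units_seen <- integer(0)
  for (sp in high) {
    u <- coord_to_unit(sp$units[, "row"], sp$units[, "col"], model$grid_cols)
    expect_length(intersect(units_seen, u), 0L)
    units_seen <- c(units_seen, u)
    expect_true(all(model$bmu[sp$genes] %in% (which(as.vector(t(mask))) - 1L)))
    # profile equals the mean over member genes (two-loop oracle)
    expect_equal(sp$sample_profile,
                 colMeans(model$data[sp$genes, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("spot_profile summarizes per class with a brute-force oracle", {
  spots <- detect_spots(overview_spot_map(model, "high"), model)
  # work with the spot matching the planted hypermethylation module
  jac_up <- vapply(spots, function(s) jaccard(s$genes, ch$truth$module_genes$up),
                   numeric(1L))
  sp <- spots[[which.max(jac_up)]]
  prof <- spot_profile(sp, ch$met_ann)
  cls <- ch$met_ann[names(sp$sample_profile)]
  for (l in unique(cls)) {
    v <- sp$sample_profile[cls == l]
    expect_equal(prof$mean[prof$class == l], mean(v), tolerance = 1e-12)
    expect_equal(prof$sd[prof$class == l], sd(v), tolerance = 1e-12)
  }
  # planted +0.3 beta shift shows up in the class profile (raw scale)
  raw_spot <- sp
  raw_spot$sample_profile <- colMeans(ch$met$values[sp$genes, , drop = FALSE])
  rp <- spot_profile(raw_spot, ch$met_ann)
  dshift <- rp$mean[rp$class == "TUM"] - rp$mean[rp$class == "REF"]
  expect_equal(dshift, 0.3, tolerance = 0.05)
  # one-gene spot with one-sample classes returns the raw gene values
  g1 <- sp$genes[1L]
  solo <- sp
  solo$genes <- g1
  solo$n_genes <- 1L
  solo$sample_profile <- model$data[g1, ]
  ann_solo <- sample_annotation(names(solo$sample_profile),
                                names(solo$sample_profile))
  ps <- spot_profile(solo, ann_solo)
  expect_equal(ps$mean, unname(model$data[g1, ]))
})

test_that("cross_map self-maps onto the spot's own region and scores concentration", {
  spots <- detect_spots(overview_spot_map(model, "high"), model)
  sp <- spots[[which.max(vapply(spots, `[[`, integer(1L), "n_genes"))]]
  pairs <- match_genes(gene_ids(ch$met), gene_ids(ch$met))
  self <- cross_map(sp, model, pairs, other_spots = spots)
  expect_equal(self$n_mapped, sp$n_genes)
  expect_equal(self$fraction_mapped, 1)
  own_units <- coord_to_unit(sp$units[, "row"], sp$units[, "col"], model$grid_cols)
  occ_units <- coord_to_unit(self$coords[, "row"], self$coords[, "col"], model$grid_cols)
  expect_true(all(occ_units %in% own_units))
  expect_equal(unname(self$spot_overlap[sp$label]), sp$n_genes)
  expect_error(cross_map(sp, model, data.frame()), "empty gene pairing")
  expect_warning(
    none <- cross_map(sp, model, data.frame(gene_a = "X", gene_b = "Y")),
    "no spot gene"
  )
  expect_equal(none$n_mapped, 0L)
})

test_that("a coupled module concentrates in the expression SOM; random sets do not", {
  dexp <- centralize(ch$exp)
  emodel <- train_som(dexp, 15, 15, epochs = 20, seed = 42)
  spots <- detect_spots(overview_spot_map(model, "high"), model)
  # the 'up' module is positively coupled: find its spot
  jac <- vapply(spots, function(sp) jaccard(sp$genes, ch$truth$module_genes$up),
                numeric(1L))
  sp <- spots[[which.max(jac)]]
  pairs <- match_genes(gene_ids(ch$met), gene_ids(ch$exp))
  cm <- cross_map(sp, emodel, pairs)
  expect_lt(cm$concentration, 0.2)
  # permutation oracle: random same-size background sets are less concentrated
  set.seed(99)
  bg <- names(ch$truth$gene_module)[ch$truth$gene_module == "background"]
  rand_conc <- replicate(100, {
    fake <- sp
    fake$genes <- sample(bg, sp$n_genes)
    cross_map(fake, emodel, pairs)$concentration
  })
  expect_gte(mean(rand_conc > cm$concentration), 0.95)
})
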
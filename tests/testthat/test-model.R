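test_that("build_aggregation_adjacency binarizes, keeps similarity grids, normalizes rows", {
  sp_assoc <- relation_spec("x", "drug", "protein")
  sp_sim <- relation_spec("s", "drug", "drug", similarity = TRUE, symmetric = TRUE)
  expect_equal(build_aggregation_adjacency(matrix(c(0, 0, 0.7, 0), 2, 2), sp_assoc),
               matrix(c(0, 0, 1, 0), 2, 2))
  expect_equal(build_aggregation_adjacency(matrix(c(0, 0.5, 0.5, 0), 2, 2), sp_sim),
               matrix(c(0, 1, 1, 0), 2, 2))
  z <- matrix(0, 3, 3)
  expect_equal(build_aggregation_adjacency(z, sp_assoc), z)
  # generic rows have unit Euclidean norm
  A <- build_aggregation_adjacency(matrix(runif(12) > 0.5, 3, 4) * 1, sp_assoc)
  nz <- rowSums(A^2) > 0
  expect_equal(rowSums(A^2)[nz], rep(1, sum(nz)), tolerance = 1e-12)
})

test_that("aggregation matches an explicit per-relation loop", {
  kg <- toy_kg(n = 4, seed = 5)
  cfg <- toy_train_config()
  params <- init_params(kg, cfg)
  Y <- aggregate_neighborhoods(kg, params)
  # oracle: explicit loop over relations and orientations
  Ahat <- probkg:::make_ahat(kg, "row")
  for (a in names(kg$catalog$types)) {
    want <- matrix(0, 4, cfg$d0)
    for (r in names(kg$specs)) {
      s <- kg$specs[[r]]
      if (s$source == a) want <- want + Ahat[[r]] %*% params$X[[s$target]] %*% params$Wr[[r]]
      if (s$target == a && s$source != a) {
        want <- want + t(Ahat[[r]]) %*% params$X[[s$source]] %*% params$Wr[[r]]
      }
    }
    expect_equal(Y[[a]], want, tolerance = 1e-12, info = a)
  }
  # zero relation weights kill the aggregation
  params0 <- params
  params0$Wr <- lapply(params0$Wr, function(w) w * 0)
  expect_true(all(abs(unlist(aggregate_neighborhoods(kg, params0))) < 1e-14))
})

test_that("embedding rows are unit-norm (or zero) and match step-by-step recomputation", {
  set.seed(8)
  Y <- matrix(rnorm(8), 4, 2); X <- matrix(rnorm(8), 4, 2)
  W1 <- matrix(rnorm(12), 4, 3)
  Z <- embed_nodes(Y, X, W1)
  want <- pmax(cbind(Y, X) %*% W1, 0)
  for (i in 1:4) {
    nv <- sqrt(sum(want[i, ]^2))
    if (nv > 0) want[i, ] <- want[i, ] / nv
  }
  expect_equal(Z, want, tolerance = 1e-12)
  nrm <- sqrt(rowSums(Z^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-6))
  expect_true(all(embed_nodes(Y, X, W1 * 0) == 0))
})

test_that("reconstruct is the projected bilinear form; tied projections give symmetry", {
  I4 <- diag(4)
  expect_equal(reconstruct(I4, I4, I4, I4), I4)
  set.seed(3)
  Z <- row_normalize(matrix(rnorm(20), 5, 4))
  G <- matrix(rnorm(12), 4, 3)
  R <- reconstruct(Z, G, G, Z)
  expect_equal(R, t(R), tolerance = 1e-8)
  # quadruple-loop recomputation
  Zb <- row_normalize(matrix(rnorm(12), 3, 4))
  H <- matrix(rnorm(12), 4, 3)
  R2 <- reconstruct(Z, G, H, Zb)
  want <- matrix(0, 5, 3)
  for (i in 1:5) for (j in 1:3) {
    for (u in 1:3) {
      want[i, j] <- want[i, j] + sum(Z[i, ] * G[, u]) * sum(Zb[j, ] * H[, u])
    }
  }
  expect_equal(R2, want, tolerance = 1e-10)
})

test_that("loss weights: indicator, unobserved entries, and the algebraic identity", {
  specs <- default_relation_specs()
  P <- matrix(c(0, 0.5, 0.9, 0), 2, 2)
  C <- matrix(c(0L, 0L, 3L, 0L), 2, 2)
  expect_equal(loss_weight_matrix(C, P, specs$drug_drug), matrix(1, 2, 2))
  M <- loss_weight_matrix(C, P, specs$drug_protein, alpha = 0, beta = 0)
  expect_equal(M[P == 0], c(1, 1))
  # when P came from the probability map, M simplifies to sigmoid(C + beta)
  set.seed(10)
  for (k in 1:1000) {
    cc <- rpois(1, 4); al <- rnorm(1); be <- rnorm(1)
    Pk <- matrix(sigmoid(cc + al)); Ck <- matrix(cc)
    Mk <- loss_weight_matrix(Ck, Pk, specs$drug_protein, alpha = al, beta = be)
    expect_equal(Mk[1, 1], sigmoid(cc + be), tolerance = 1e-12)
    # range contract up to the roundoff of the composed formula
    expect_true(Mk[1, 1] >= sigmoid(be) - 1e-9 && Mk[1, 1] < 1)
  }
})

test_that("objective equals the elementwise double-sum oracle for all variants", {
  kg <- toy_kg(n = 4, seed = 6, alpha = -0.3, beta = 0.2)
  kg <- mask_entries(kg, which(kg$P$protein_disease > 0, arr.ind = TRUE)[1, , drop = FALSE])
  cfg <- toy_train_config()
  params <- init_params(kg, cfg)
  for (variant in c("full", "og", "rp", "rw", "rpw")) {
    mats <- probkg:::training_matrices(kg, variant, seed = cfg$seed, norm = "row")
    want <- oracle_objective(params, kg, mats$targets, mats$weights, cfg$lambda)
    expect_equal(objective(params, kg, cfg, variant = variant), want,
                 tolerance = 1e-10, info = variant)
  }
  expect_error(control_objective("nope", params, kg, cfg))
  # invariant to relation ordering
  perm <- rev(names(kg$specs))
  kg2 <- kg
  kg2$specs <- kg$specs[perm]; kg2$P <- kg$P[perm]
  expect_equal(objective(params, kg, cfg), objective(params, kg2, cfg), tolerance = 1e-10)
  # weights == 1 (og on an unmasked graph, lambda 0) reduces to plain SSE
  kg_u <- toy_kg(n = 4, seed = 6, alpha = -0.3, beta = 0.2)
  params_u <- init_params(kg_u, cfg)
  mats <- probkg:::training_matrices(kg_u, "og", seed = cfg$seed, norm = "row")
  fwd <- probkg:::kg_forward(params_u, kg_u, probkg:::make_ahat(kg_u, "row"), norm = "row")
  plain <- sum(vapply(names(kg_u$specs), function(r) {
    sum((fwd$recon[[r]] - mats$targets[[r]])^2)
  }, 0))
  cfg0 <- cfg; cfg0$lambda <- 0
  expect_equal(objective(params_u, kg_u, cfg0, variant = "og"), plain, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  kg <- toy_kg(n = 3, seed = 15, alpha = 0.1, beta = -0.1)
  cfg <- train_config(d0 = 4, d1 = 3, k = 3, lambda = 1e-2, seed = 2)
  params <- init_params(kg, cfg)
  mats <- probkg:::training_matrices(kg, "full", seed = cfg$seed, norm = "row")
  Ahat <- probkg:::make_ahat(kg, "row")
  fwd <- probkg:::kg_forward(params, kg, Ahat, norm = "row")
  gr <- probkg:::kg_backward(params, kg, fwd, mats, cfg$lambda, Ahat, "row")
  f_of <- function(p) {
    fw <- probkg:::kg_forward(p, kg, Ahat, norm = "row")
    probkg:::loss_value(p, kg, fw, mats, cfg$lambda)
  }
  h <- 1e-5
  check_block <- function(get, set, gmat, label) {
    m <- get(params)
    idx <- cbind(sample(nrow(m), 6, replace = TRUE), sample(ncol(m), 6, replace = TRUE))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      pp <- set(params, i, j, h); pm <- set(params, i, j, -h)
      num <- (f_of(pp) - f_of(pm)) / (2 * h)
      expect_equal(gmat[i, j], num, tolerance = 1e-5, info = paste(label, i, j))
    }
  }
  set.seed(99)
  check_block(function(p) p$X$protein,
              function(p, i, j, d) { p$X$protein[i, j] <- p$X$protein[i, j] + d; p },
              gr$X$protein, "X_protein")
  check_block(function(p) p$Wr$drug_protein,
              function(p, i, j, d) { p$Wr$drug_protein[i, j] <- p$Wr$drug_protein[i, j] + d; p },
              gr$Wr$drug_protein, "W_dp")
  check_block(function(p) p$W1,
              function(p, i, j, d) { p$W1[i, j] <- p$W1[i, j] + d; p },
              gr$W1, "W1")
  check_block(function(p) p$G$protein_disease,
              function(p, i, j, d) { p$G$protein_disease[i, j] <- p$G$protein_disease[i, j] + d; p },
              gr$G$protein_disease, "G_pd")
  check_block(function(p) p$H$protein_disease,
              function(p, i, j, d) { p$H$protein_disease[i, j] <- p$H$protein_disease[i, j] + d; p },
              gr$H$protein_disease, "H_pd")
  # tied symmetric projection accumulates both sides
  check_block(function(p) p$G$protein_protein,
              function(p, i, j, d) { p$G$protein_protein[i, j] <- p$G$protein_protein[i, j] + d; p },
              gr$G$protein_protein, "G_pp_tied")
})

test_that("randomized probabilities and weights honour their range contracts", {
  kg <- toy_kg(n = 6, seed = 33, alpha = 0.5, beta = -0.5)
  rnd <- randomized_edge_probabilities(kg, seed = 4)
  for (r in c("drug_protein", "drug_disease", "protein_disease")) {
    obs <- kg$P[[r]] > 0
    expect_true(all(rnd$P[[r]][obs] >= sigmoid(kg$alpha)))
    expect_true(all(rnd$P[[r]][obs] < 1))
    expect_true(all(rnd$P[[r]][!obs] == 0))
  }
  # non-literature grids unchanged (observed association edges stay 1)
  expect_identical(rnd$P$drug_drug, kg$P$drug_drug)
  expect_identical(rnd$P$drug_similarity, kg$P$drug_similarity)
  Mp <- randomized_weight_matrices(kg, rnd)
  for (r in c("drug_protein", "drug_disease", "protein_disease")) {
    obs <- kg$P[[r]] > 0
    expect_true(all(Mp[[r]][obs] >= sigmoid(kg$beta)))
    expect_true(all(Mp[[r]][obs] < 1))
    expect_true(all(Mp[[r]][!obs] == 1))
  }
  expect_true(all(Mp$drug_drug == 1))
  # cached draws reproduce under the same seed
  rnd2 <- randomized_edge_probabilities(kg, seed = 4)
  expect_identical(rnd$P, rnd2$P)
  expect_identical(rnd$u2, rnd2$u2)
})

test_that("training is seeded, decreasing on a toy world, and identity at 0 epochs", {
  kg <- toy_kg(n = 5, seed = 21)
  cfg0 <- toy_train_config(); cfg0$epochs <- 0
  fit0 <- train_model(kg, cfg0)
  expect_equal(fit0$params, init_params(kg, cfg0))
  expect_length(fit0$loss_history, 0)

  cfg <- toy_train_config(); cfg$epochs <- 60; cfg$lr <- 1e-2
  fit1 <- train_model(kg, cfg)
  fit2 <- train_model(kg, cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_lt(utils::tail(fit1$loss_history, 1), fit1$loss_history[1])
  # prediction equals reconstruct on the fitted embeddings
  pred <- predict_tda(fit1, kg)
  expect_equal(dim(pred), dim(kg$P$protein_disease))
  fwd <- probkg:::kg_forward(fit1$params, kg, probkg:::make_ahat(kg, "row"), norm = "row")
  expect_equal(pred, fwd$recon$protein_disease)
  # symmetric-relation reconstruction is symmetric
  expect_equal(fwd$recon$protein_protein, t(fwd$recon$protein_protein), tolerance = 1e-8)
  expect_equal(fwd$recon$drug_similarity, t(fwd$recon$drug_similarity), tolerance = 1e-8)
})

test_that("validation-based early stopping returns the best-epoch parameters", {
  kg <- toy_kg(n = 5, seed = 22)
  obs <- which(kg$P$protein_disease > 0, arr.ind = TRUE)
  val_pairs <- obs[1:2, , drop = FALSE]
  neg <- which(kg$P$protein_disease == 0, arr.ind = TRUE)[1:2, , drop = FALSE]
  kg_m <- mask_entries(kg, val_pairs)
  idx <- c(val_pairs[, 1] + (val_pairs[, 2] - 1) * nrow(kg$P$protein_disease),
           neg[, 1] + (neg[, 2] - 1) * nrow(kg$P$protein_disease))
  cfg <- toy_train_config()
  cfg$epochs <- 40; cfg$patience <- 5; cfg$lr <- 1e-2
  cfg$val_idx <- idx; cfg$val_labels <- c(1, 1, 0, 0)
  fit <- train_model(kg_m, cfg)
  expect_false(is.null(fit$val_history))
  expect_equal(max(fit$val_history), fit$val_history[fit$best_epoch])
  # fit round-trips through the archive
  f <- withr::local_tempfile(fileext = ".rds")
  write_fit(fit, f)
  expect_equal(read_fit(f)$params, fit$params)
})
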
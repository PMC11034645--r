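# Relation-specific graph embedding with weighted reconstruction.
#
# Forward pass per entity type a:
#   Y_a   = sum over relations touching a of  Ahat_r X_b W_r
#   Z~_a  = ReLU([Y_a | X_a] W1),   Z_a = rownorm(Z~_a)
# and per relation r the reconstruction Z_a G_r H_r' Z_b'. The objective is
# the weighted squared reconstruction error against the probabilistic
# adjacencies plus l2 regularization. Gradients are derived by hand and
# verified against finite differences in the test suite; training is
# full-batch Adam. Symmetric relations tie G_r = H_r.

#' Training configuration
#'
#' @param d0,d1,k embedding dimensions: initial embeddings (`d0`), projected
#'   node embeddings (`d1`), and relation projection rank (`k`).
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs (full-batch).
#' @param lambda l2 regularization strength on all parameters.
#' @param seed RNG seed controlling initialization and any randomized
#'   control draws.
#' @param patience early-stopping patience (epochs without validation AUPR
#'   improvement); ignored when no validation entries are given.
#' @param variant objective variant: `"full"` or one of the controls
#'   `"og"`, `"rp"`, `"rw"`, `"rpw"`.
#' @param norm normalization mode for aggregation adjacencies and
#'   embeddings: `"row"` (row-wise Euclidean, default) or `"frobenius"`.
#' @param tda_relation relation whose reconstruction is the prediction
#'   target (default `"protein_disease"`).
#' @param val_idx,val_labels optional validation entries: linear indices
#'   into the TDA matrix and their binary labels. Entries used for
#'   validation (and testing) must have been removed from the graph with
#'   [mask_entries()] so they carry loss weight 0.
#' @return a `train_config` list.
#' @export
train_config <- function(d0 = 128, d1 = 64, k = 64, lr = 2e-3, epochs = 1000,
                         lambda = 1e-4, seed = 1, patience = 50,
                         variant = "full", norm = c("row", "frobenius"),
                         tda_relation = "protein_disease",
                         val_idx = NULL, val_labels = NULL) {
  stopifnot(d0 > 0, d1 > 0, k > 0, lambda >= 0, epochs >= 0)
  variant <- match.arg(variant, c("full", "og", "rp", "rw", "rpw"))
  structure(list(d0 = d0, d1 = d1, k = k, lr = lr, epochs = epochs,
                 lambda = lambda, seed = seed, patience = patience,
                 variant = variant, norm = match.arg(norm),
                 tda_relation = tda_relation,
                 val_idx = val_idx, val_labels = val_labels),
            class = "train_config")
}

#' Normalized aggregation adjacency
#'
#' Similarity relations keep their probability grid; all other relations are
#' binarized (positive entries to 1). The result is then normalized: each
#' row scaled to unit Euclidean norm (`norm = "row"`, zero rows stay zero),
#' or the whole grid scaled by its Frobenius norm.
#'
#' @param P probabilistic adjacency matrix.
#' @param spec the relation's [relation_spec()].
#' @param norm `"row"` or `"frobenius"`.
#' @return the normalized adjacency.
#' @export
build_aggregation_adjacency <- function(P, spec, norm = "row") {
  A <- if (spec$similarity) P else (P > 0) * 1
  normalize_grid(A, norm)
}

normalize_grid <- function(x, norm) {
  if (norm == "row") return(row_normalize(x))
  n <- sqrt(sum(x^2))
  if (n > 0) x / n else x
}

# contributions feeding each entity type's aggregation: both orientations of
# bipartite relations; self relations contribute once in source orientation
relation_contributions <- function(specs) {
  contrib <- list()
  for (r in names(specs)) {
    s <- specs[[r]]
    contrib[[s$source]] <- c(contrib[[s$source]],
                             list(list(relation = r, from = s$target, rev = FALSE)))
    if (s$target != s$source) {
      contrib[[s$target]] <- c(contrib[[s$target]],
                               list(list(relation = r, from = s$source, rev = TRUE)))
    }
  }
  contrib
}

#' Initialize model parameters
#'
#' Seeded Gaussian initialization with scale `1/sqrt(dim)` for every grid.
#' Symmetric relations carry a single tied projection matrix (`H_r = G_r`).
#'
#' @param kg a `prob_kg`.
#' @param config a [train_config()].
#' @return a `model_params` object.
#' @export
init_params <- function(kg, config) {
  set.seed(config$seed)
  d0 <- config$d0; d1 <- config$d1; k <- config$k
  gmat <- function(n, m, scale) matrix(stats::rnorm(n * m, sd = scale), n, m)
  X <- lapply(kg$catalog$types, function(ids) gmat(length(ids), d0, 1 / sqrt(d0)))
  Wr <- lapply(kg$specs, function(s) gmat(d0, d0, 1 / sqrt(d0)))
  W1 <- gmat(2L * d0, d1, 1 / sqrt(2 * d0))
  G <- lapply(kg$specs, function(s) gmat(d1, k, 1 / sqrt(d1)))
  H <- lapply(kg$specs, function(s) if (s$symmetric) NULL else gmat(d1, k, 1 / sqrt(d1)))
  structure(list(X = X, Wr = Wr, W1 = W1, G = G, H = H,
                 dims = list(d0 = d0, d1 = d1, k = k)),
            class = "model_params")
}

param_H <- function(params, kg, r) {
  if (kg$specs[[r]]$symmetric) params$G[[r]] else params$H[[r]]
}

#' Aggregate neighborhood information
#'
#' Computes, for every entity type `a`, the aggregated matrix
#' `Y_a = sum_r Ahat_r X_b W_r` over all relations touching `a` (the
#' transpose of `Ahat_r` is used when `a` is the relation's target side).
#'
#' @param kg a `prob_kg`.
#' @param params a `model_params`.
#' @param Ahat optional precomputed list of normalized adjacencies.
#' @param norm normalization mode when `Ahat` is not supplied.
#' @return named list of aggregated matrices, one per entity type.
#' @export
aggregate_neighborhoods <- function(kg, params, Ahat = NULL, norm = "row") {
  if (is.null(Ahat)) {
    Ahat <- lapply(names(kg$specs), function(r) {
      build_aggregation_adjacency(kg$P[[r]], kg$specs[[r]], norm)
    })
    names(Ahat) <- names(kg$specs)
  }
  contrib <- relation_contributions(kg$specs)
  Y <- list()
  for (a in names(kg$catalog$types)) {
    acc <- matrix(0, length(kg$catalog$types[[a]]), params$dims$d0)
    for (cn in contrib[[a]] %||% list()) {
      M <- if (cn$rev) t(Ahat[[cn$relation]]) else Ahat[[cn$relation]]
      acc <- acc + M %*% params$X[[cn$from]] %*% params$Wr[[cn$relation]]
    }
    Y[[a]] <- acc
  }
  Y
}

#' Project aggregated information to node embeddings
#'
#' `Z~ = ReLU([Y | X] W1)` followed by normalization (row-wise Euclidean by
#' default; all-zero rows stay zero).
#'
#' @param Y aggregated matrix for one entity type.
#' @param X the type's initial embedding matrix.
#' @param W1 shared projection matrix (`2 d0 x d1`).
#' @param norm `"row"` or `"frobenius"`.
#' @return embedding matrix with unit-norm (or zero) rows.
#' @export
embed_nodes <- function(Y, X, W1, norm = "row") {
  Ztil <- pmax(cbind(Y, X) %*% W1, 0)
  normalize_grid(Ztil, norm)
}

#' Reconstruct a relation's score grid
#'
#' @param Za,Zb node embeddings of the relation's endpoint types.
#' @param Gr,Hr projection pair (`d1 x k`); pass the same matrix twice for
#'   symmetric relations.
#' @return the score grid `Za Gr Hr' Zb'`.
#' @export
reconstruct <- function(Za, Gr, Hr, Zb) {
  (Za %*% Gr) %*% t(Zb %*% Hr)
}

#' Literature-informed loss weight matrix
#'
#' `M[i,j] = ((sigmoid(C+beta) - 1) / sigmoid(C+alpha)) * P[i,j] * 1_Rc + 1`.
#' For non-literature relations this is an all-ones grid; unobserved entries
#' get weight 1; and for observed entries whose probability came from the
#' count map, the weight simplifies to `sigmoid(C + beta)`.
#'
#' @param C count matrix (ignored for non-literature relations).
#' @param P probabilistic adjacency.
#' @param spec the relation's [relation_spec()].
#' @param alpha,beta hyperparameters.
#' @return the weight grid.
#' @export
loss_weight_matrix <- function(C, P, spec, alpha = 0, beta = 0) {
  if (!spec$literature) return(matrix(1, nrow(P), ncol(P)))
  ((sigmoid(C + beta) - 1) / sigmoid(C + alpha)) * P + 1
}

#' Cached randomized edge probabilities (ablation controls)
#'
#' For every literature relation, draws one uniform sample per entry from
#' `[sigmoid(alpha), 1)` (the range the count-based probability can take)
#' and uses it at observed entries; unobserved entries stay 0 and all other
#' relations keep their grids. Draws are made once and cached, together with
#' an independent second grid used by [randomized_weight_matrices()].
#'
#' @param kg a `prob_kg`.
#' @param seed RNG seed for the offline draws.
#' @return list with `P` (randomized adjacencies), `u1`, `u2` (cached draws).
#' @export
randomized_edge_probabilities <- function(kg, seed) {
  set.seed(seed)
  lo1 <- sigmoid(kg$alpha)
  P <- kg$P; u1 <- list(); u2 <- list()
  for (r in names(kg$specs)) {
    if (!kg$specs[[r]]$literature) next
    d <- dim(kg$P[[r]])
    u1[[r]] <- matrix(stats::runif(prod(d), lo1, 1), d[1], d[2])
    u2[[r]] <- matrix(stats::runif(prod(d), sigmoid(kg$beta), 1), d[1], d[2])
    obs <- kg$P[[r]] > 0
    Pp <- matrix(0, d[1], d[2])
    Pp[obs] <- u1[[r]][obs]
    P[[r]] <- Pp
  }
  list(P = P, u1 = u1, u2 = u2)
}

#' Randomized loss weight matrices (ablation controls)
#'
#' `M'[i,j] = ((u2 - 1) / u1) * P'[i,j] * 1_Rc + 1` with the same cached
#' `u1` draw that produced `P'` and an independent cached `u2`; observed
#' literature entries therefore reduce to `u2 in [sigmoid(beta), 1)` and
#' everything else to 1.
#'
#' @param kg a `prob_kg`.
#' @param rnd result of [randomized_edge_probabilities()].
#' @return named list of weight grids, one per relation.
#' @export
randomized_weight_matrices <- function(kg, rnd) {
  M <- list()
  for (r in names(kg$specs)) {
    if (kg$specs[[r]]$literature) {
      M[[r]] <- ((rnd$u2[[r]] - 1) / rnd$u1[[r]]) * rnd$P[[r]] + 1
    } else {
      M[[r]] <- matrix(1, nrow(kg$P[[r]]), ncol(kg$P[[r]]))
    }
  }
  M
}

# target and weight grids per objective variant, with masked entries at
# weight zero (they are excluded from both the target and the loss)
training_matrices <- function(kg, variant = "full", seed = 1, norm = "row") {
  rnd <- NULL
  if (variant %in% c("rp", "rw", "rpw")) {
    rnd <- randomized_edge_probabilities(kg, seed)
  }
  targets <- list(); weights <- list()
  for (r in names(kg$specs)) {
    spec <- kg$specs[[r]]
    targets[[r]] <- switch(variant,
      og = if (spec$similarity) kg$P[[r]] else (kg$P[[r]] > 0) * 1,
      rp = , rpw = rnd$P[[r]],
      kg$P[[r]])
    weights[[r]] <- switch(variant,
      og = matrix(1, nrow(kg$P[[r]]), ncol(kg$P[[r]])),
      rw = , rpw = randomized_weight_matrices(kg, rnd)[[r]],
      loss_weight_matrix(kg$C[[r]], kg$P[[r]], spec, kg$alpha, kg$beta))
    if (!is.null(kg$mask) && !is.null(kg$mask[[r]])) {
      weights[[r]][kg$mask[[r]]] <- 0
    }
  }
  list(targets = targets, weights = weights)
}

kg_forward <- function(params, kg, Ahat, norm = "row") {
  Y <- aggregate_neighborhoods(kg, params, Ahat = Ahat)
  Cc <- list(); Ztil <- list(); Z <- list()
  for (a in names(Y)) {
    Cc[[a]] <- cbind(Y[[a]], params$X[[a]])
    Ztil[[a]] <- pmax(Cc[[a]] %*% params$W1, 0)
    Z[[a]] <- normalize_grid(Ztil[[a]], norm)
  }
  recon <- list(); ZaG <- list(); ZbH <- list()
  for (r in names(kg$specs)) {
    s <- kg$specs[[r]]
    ZaG[[r]] <- Z[[s$source]] %*% params$G[[r]]
    ZbH[[r]] <- Z[[s$target]] %*% param_H(params, kg, r)
    recon[[r]] <- ZaG[[r]] %*% t(ZbH[[r]])
  }
  list(Y = Y, Cc = Cc, Ztil = Ztil, Z = Z, recon = recon, ZaG = ZaG, ZbH = ZbH)
}

reg_blocks <- function(params, kg) {
  blocks <- c(params$X, params$Wr, list(W1 = params$W1), params$G,
              Filter(Negate(is.null), params$H))
  blocks
}

loss_value <- function(params, kg, fwd, mats, lambda) {
  loss <- 0
  for (r in names(kg$specs)) {
    loss <- loss + sum(((fwd$recon[[r]] - mats$targets[[r]]) * mats$weights[[r]])^2)
  }
  if (lambda > 0) {
    loss <- loss + lambda * sum(vapply(reg_blocks(params, kg),
                                       function(b) sum(b^2), 0))
  }
  loss
}

#' Objective value of the (control) reconstruction loss
#'
#' The weighted squared reconstruction error over all relations plus l2
#' regularization; `variant` selects the full objective or one of the four
#' ablation controls (`og`: unweighted reconstruction of the binarized
#' graph; `rp`: randomized probabilities; `rw`: randomized weights; `rpw`:
#' both randomized). Masked entries carry weight 0.
#'
#' @param params a `model_params`.
#' @param kg a `prob_kg`.
#' @param config a [train_config()]; its `seed` fixes the cached randomized
#'   draws of the control variants.
#' @param variant overrides `config$variant` when given.
#' @return scalar loss.
#' @export
objective <- function(params, kg, config, variant = NULL) {
  variant <- variant %||% config$variant
  mats <- training_matrices(kg, variant, seed = config$seed, norm = config$norm)
  Ahat <- make_ahat(kg, config$norm)
  fwd <- kg_forward(params, kg, Ahat, norm = config$norm)
  val <- loss_value(params, kg, fwd, mats, config$lambda)
  if (!is.finite(val)) stop_probkg("non-finite objective (variant '%s')", variant)
  val
}

#' Control objective for the ablation variants
#'
#' @param variant one of `"og"`, `"rp"`, `"rw"`, `"rpw"`.
#' @inheritParams objective
#' @return scalar loss.
#' @export
control_objective <- function(variant, params, kg, config) {
  variant <- match.arg(variant, c("og", "rp", "rw", "rpw"))
  objective(params, kg, config, variant = variant)
}

make_ahat <- function(kg, norm = "row") {
  Ahat <- lapply(names(kg$specs), function(r) {
    build_aggregation_adjacency(kg$P[[r]], kg$specs[[r]], norm)
  })
  stats::setNames(Ahat, names(kg$specs))
}

kg_backward <- function(params, kg, fwd, mats, lambda, Ahat, norm) {
  d0 <- params$dims$d0
  types <- names(kg$catalog$types)
  gX <- lapply(params$X, function(m) matrix(0, nrow(m), ncol(m)))
  gW <- lapply(params$Wr, function(m) matrix(0, nrow(m), ncol(m)))
  gW1 <- matrix(0, nrow(params$W1), ncol(params$W1))
  gG <- lapply(params$G, function(m) matrix(0, nrow(m), ncol(m)))
  gH <- lapply(params$H, function(m) if (is.null(m)) NULL else matrix(0, nrow(m), ncol(m)))
  dZ <- lapply(fwd$Z, function(m) matrix(0, nrow(m), ncol(m)))
  loss <- 0
  for (r in names(kg$specs)) {
    s <- kg$specs[[r]]
    D <- fwd$recon[[r]] - mats$targets[[r]]
    DW <- D * mats$weights[[r]]
    loss <- loss + sum(DW^2)
    E <- 2 * DW * mats$weights[[r]]
    G <- params$G[[r]]; H <- param_H(params, kg, r)
    dZ[[s$source]] <- dZ[[s$source]] + E %*% fwd$ZbH[[r]] %*% t(G)
    dZ[[s$target]] <- dZ[[s$target]] + t(E) %*% fwd$ZaG[[r]] %*% t(H)
    dG <- t(fwd$Z[[s$source]]) %*% E %*% fwd$ZbH[[r]]
    dH <- t(fwd$Z[[s$target]]) %*% t(E) %*% fwd$ZaG[[r]]
    if (s$symmetric) {
      gG[[r]] <- gG[[r]] + dG + dH
    } else {
      gG[[r]] <- gG[[r]] + dG
      gH[[r]] <- gH[[r]] + dH
    }
  }
  dY <- list()
  for (a in types) {
    Z <- fwd$Z[[a]]; Ztil <- fwd$Ztil[[a]]
    if (norm == "row") {
      nrm <- sqrt(rowSums(Ztil^2))
      dot <- rowSums(dZ[[a]] * Z)
      dZtil <- dZ[[a]] - dot * Z
      nz <- nrm > 0
      dZtil[nz, ] <- dZtil[nz, , drop = FALSE] / nrm[nz]
      dZtil[!nz, ] <- 0
    } else {
      nrm <- sqrt(sum(Ztil^2))
      if (nrm > 0) {
        dZtil <- (dZ[[a]] - sum(dZ[[a]] * Z) * Z) / nrm
      } else {
        dZtil <- dZ[[a]] * 0
      }
    }
    dPre <- dZtil * (Ztil > 0)
    gW1 <- gW1 + t(fwd$Cc[[a]]) %*% dPre
    dCc <- dPre %*% t(params$W1)
    dY[[a]] <- dCc[, seq_len(d0), drop = FALSE]
    gX[[a]] <- gX[[a]] + dCc[, d0 + seq_len(d0), drop = FALSE]
  }
  contrib <- relation_contributions(kg$specs)
  for (a in types) {
    for (cn in contrib[[a]] %||% list()) {
      M <- if (cn$rev) t(Ahat[[cn$relation]]) else Ahat[[cn$relation]]
      W <- params$Wr[[cn$relation]]
      MtdY <- t(M) %*% dY[[a]]
      gX[[cn$from]] <- gX[[cn$from]] + MtdY %*% t(W)
      gW[[cn$relation]] <- gW[[cn$relation]] + t(params$X[[cn$from]]) %*% MtdY
    }
  }
  if (lambda > 0) {
    loss <- loss + lambda * sum(vapply(reg_blocks(params, kg), function(b) sum(b^2), 0))
    gX <- Map(function(g, p) g + 2 * lambda * p, gX, params$X)
    gW <- Map(function(g, p) g + 2 * lambda * p, gW, params$Wr)
    gW1 <- gW1 + 2 * lambda * params$W1
    gG <- Map(function(g, p) g + 2 * lambda * p, gG, params$G)
    gH <- Map(function(g, p) if (is.null(p)) NULL else g + 2 * lambda * p, gH, params$H)
  }
  list(loss = loss, X = gX, Wr = gW, W1 = gW1, G = gG, H = gH)
}

params_flatten <- function(params) {
  c(params$X, params$Wr, list(W1 = params$W1), params$G,
    Filter(Negate(is.null), params$H))
}

grads_as_list <- function(grads, params) {
  c(grads$X, grads$Wr, list(W1 = grads$W1), grads$G,
    grads$H[!vapply(params$H, is.null, TRUE)])
}

#' Train the embedding model
#'
#' Full-batch Adam on the (control-)weighted reconstruction objective.
#' Deterministic given `config$seed`. When validation entries are supplied,
#' the validation AUPR is tracked per epoch and the parameters from the best
#' validation epoch are returned (early stop after `patience` epochs without
#' improvement); otherwise the final parameters are returned.
#'
#' @param kg a `prob_kg`; test/validation entries must already have been
#'   removed with [mask_entries()].
#' @param config a [train_config()].
#' @return an object of class `kg_fit` with elements `params`,
#'   `loss_history`, `val_history` (AUPR per epoch or NULL), `best_epoch`,
#'   and `config`.
#' @export
train_model <- function(kg, config) {
  mats <- training_matrices(kg, config$variant, seed = config$seed, norm = config$norm)
  Ahat <- make_ahat(kg, config$norm)
  params <- init_params(kg, config)
  use_val <- !is.null(config$val_idx) && length(config$val_idx) > 0
  if (use_val && length(unique(config$val_labels)) < 2) use_val <- FALSE
  m <- NULL; v <- NULL
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_history <- numeric(0); val_history <- numeric(0)
  best_val <- -Inf; best_params <- params; best_epoch <- 0L; stall <- 0L
  tda <- config$tda_relation
  if (config$epochs > 0) {
    for (epoch in seq_len(config$epochs)) {
      fwd <- kg_forward(params, kg, Ahat, norm = config$norm)
      gr <- kg_backward(params, kg, fwd, mats, config$lambda, Ahat, config$norm)
      if (!is.finite(gr$loss)) {
        stop_probkg("training diverged at epoch %d (non-finite loss)", epoch)
      }
      loss_history <- c(loss_history, gr$loss)
      if (use_val) {
        sc <- fwd$recon[[tda]][config$val_idx]
        va <- aupr(sc, config$val_labels)
        val_history <- c(val_history, va)
        if (va > best_val) {
          best_val <- va; best_params <- params; best_epoch <- epoch; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      }
      plist <- params_flatten(params)
      glist <- grads_as_list(gr, params)
      if (is.null(m)) {
        m <- lapply(glist, function(g) g * 0)
        v <- m
      }
      t_ <- epoch
      for (idx in seq_along(plist)) {
        g <- glist[[idx]]
        m[[idx]] <- b1 * m[[idx]] + (1 - b1) * g
        v[[idx]] <- b2 * v[[idx]] + (1 - b2) * g^2
        mhat <- m[[idx]] / (1 - b1^t_)
        vhat <- v[[idx]] / (1 - b2^t_)
        plist[[idx]] <- plist[[idx]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
      params <- params_unflatten(plist, params, kg)
    }
  }
  out_params <- if (use_val && best_epoch > 0) best_params else params
  structure(list(params = out_params, loss_history = loss_history,
                 val_history = if (use_val) val_history else NULL,
                 best_epoch = if (use_val) best_epoch else length(loss_history),
                 config = config),
            class = "kg_fit")
}

params_unflatten <- function(plist, params, kg) {
  nt <- length(params$X); nr <- length(params$Wr)
  params$X <- plist[seq_len(nt)]
  params$Wr <- plist[nt + seq_len(nr)]
  params$W1 <- plist[[nt + nr + 1L]]
  params$G <- plist[nt + nr + 1L + seq_len(nr)]
  names(params$X) <- names(kg$catalog$types)
  names(params$Wr) <- names(params$G) <- names(kg$specs)
  free_H <- !vapply(params$H, is.null, TRUE)
  if (any(free_H)) {
    params$H[free_H] <- plist[nt + 2L * nr + 1L + seq_len(sum(free_H))]
  }
  params
}

#' @export
print.kg_fit <- function(x, ...) {
  cat(sprintf("<kg_fit> %d epochs, final loss %.4g", length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  if (!is.null(x$val_history)) {
    cat(sprintf(", best val AUPR %.4f @ epoch %d", max(x$val_history), x$best_epoch))
  }
  cat("\n")
  invisible(x)
}

#' Predict target-disease association scores
#'
#' Returns the reconstructed score grid of the target-disease relation
#' (rows = proteins, columns = diseases), unclipped.
#'
#' @param params a trained `model_params` (or a `kg_fit`).
#' @param kg the `prob_kg` used for training.
#' @param relation relation to reconstruct.
#' @param norm normalization mode (must match training).
#' @return numeric score matrix.
#' @export
predict_tda <- function(params, kg, relation = "protein_disease", norm = "row") {
  if (inherits(params, "kg_fit")) {
    norm <- params$config$norm
    params <- params$params
  }
  fwd <- kg_forward(params, kg, make_ahat(kg, norm), norm = norm)
  fwd$recon[[relation]]
}

#' Serialize trained parameters
#'
#' Writes all parameter grids and a manifest (dimensions, seed, config) to a
#' single RDS archive.
#'
#' @param fit a `kg_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) readRDS(path)
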
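# Desk-scale synthetic worlds: a planted low-rank association structure over
# the four entity types, two-rate Poisson co-occurrence counts correlated
# with the true links, dense similarity networks from the same latent
# factors, and a toy corpus whose dictionary counts recover the planted
# counts. Everything is a pure function of (spec, seed).

#' Specification of a synthetic knowledge-graph world
#'
#' @param n_drug,n_protein,n_disease,n_side_effect entities per type.
#' @param rank latent factor rank of the planted structure.
#' @param density association density per non-similarity relation (fraction
#'   of pairs that are true links).
#' @param lambda1,lambda0 Poisson co-occurrence rates for true links and
#'   non-links (`lambda1 > lambda0 >= 0`), making literature evidence
#'   informative.
#' @param holdout fraction of true target-disease links withheld from the
#'   observed graph (their counts are zeroed too).
#' @param alpha,beta probability/weight hyperparameters of the graph.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drug = 60, n_protein = 60, n_disease = 60,
                           n_side_effect = 60, rank = 4, density = 0.15,
                           lambda1 = 8, lambda0 = 0.5, holdout = 0.1,
                           alpha = 0, beta = 0, seed = 1) {
  stopifnot(lambda1 > lambda0, lambda0 >= 0, density >= 0, density < 1,
            holdout >= 0, holdout < 1)
  if (rank >= min(n_drug, n_protein, n_disease, n_side_effect)) {
    stop_probkg("rank must be smaller than the smallest entity count")
  }
  structure(list(n = c(drug = n_drug, protein = n_protein, disease = n_disease,
                       side_effect = n_side_effect),
                 rank = rank, density = density, lambda1 = lambda1,
                 lambda0 = lambda0, holdout = holdout, alpha = alpha,
                 beta = beta, seed = seed),
            class = "synthetic_spec")
}

entity_ids <- function(type, n) {
  # fixed-width ids with a terminal letter so no id is a substring of another
  sprintf("%s%04dx", c(drug = "drg", protein = "prt", disease = "dis",
                       side_effect = "sfx")[[type]], seq_len(n))
}

#' Generate a synthetic probabilistic knowledge graph
#'
#' Latent factors are drawn per entity; a pair is a true link when the
#' factor inner product exceeds the density-calibrated quantile of its
#' relation's score distribution. The observed graph is the set of true
#' links minus a held-out fraction of target-disease positives (whose
#' counts are zeroed as well, mirroring [mask_entries()] semantics).
#' Co-occurrence counts follow the two-rate Poisson model, and similarity
#' grids are cosine similarities of the factors affinely mapped to `[0, 1]`
#' with unit diagonal.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `kg` (the observed `prob_kg` with literature
#'   probabilities assigned), `truth` (named list of true-link matrices),
#'   and `holdout` (two-column index matrix of withheld target-disease
#'   positives).
#' @export
generate_prob_kg <- function(spec) {
  set.seed(spec$seed)
  types <- names(spec$n)
  ids <- stats::setNames(lapply(types, function(t) entity_ids(t, spec$n[[t]])), types)
  synonyms <- stats::setNames(as.list(unlist(ids, use.names = FALSE)),
                              unlist(ids, use.names = FALSE))
  catalog <- entity_catalog(ids, synonyms = synonyms)
  F_ <- stats::setNames(lapply(types, function(t) {
    matrix(stats::rnorm(spec$n[[t]] * spec$rank), spec$n[[t]], spec$rank)
  }), types)
  specs <- default_relation_specs()
  truth <- list(); P <- list(); C <- list()
  for (r in names(specs)) {
    s <- specs[[r]]
    Fa <- F_[[s$source]]; Fb <- F_[[s$target]]
    S <- Fa %*% t(Fb)
    if (s$similarity) {
      nf <- sqrt(rowSums(Fa^2))
      Sim <- (S / outer(nf, nf) + 1) / 2
      diag(Sim) <- 1
      Sim <- (Sim + t(Sim)) / 2
      P[[r]] <- Sim
      truth[[r]] <- Sim
      next
    }
    if (s$symmetric) {
      S <- (S + t(S)) / 2
      diag(S) <- -Inf  # no self links
    }
    if (spec$density == 0) {
      L <- matrix(0, nrow(S), ncol(S))
    } else {
      thr <- stats::quantile(S[is.finite(S)], 1 - spec$density)
      L <- (S > thr) * 1
    }
    if (s$symmetric) L <- pmax(L, t(L))
    truth[[r]] <- L
    P[[r]] <- L
    if (s$literature) {
      Cm <- matrix(stats::rpois(length(L), ifelse(L > 0, spec$lambda1, spec$lambda0)),
                   nrow(L), ncol(L))
      C[[r]] <- Cm
    }
  }
  # withhold a fraction of true target-disease links from the observed graph
  tda <- "protein_disease"
  pos <- which(truth[[tda]] == 1)
  n_hold <- round(spec$holdout * length(pos))
  hold_idx <- if (n_hold > 0) sort(sample(pos, n_hold)) else integer(0)
  hold <- cbind(row = ((hold_idx - 1) %% nrow(truth[[tda]])) + 1,
                col = ((hold_idx - 1) %/% nrow(truth[[tda]])) + 1)
  P[[tda]][hold_idx] <- 0
  C[[tda]][hold_idx] <- 0L
  kg <- new_prob_kg(catalog, specs, P, C, spec$alpha, spec$beta)
  kg <- assign_edge_probabilities(kg, C)
  list(kg = kg, truth = truth, holdout = hold)
}

#' Generate a toy literature corpus for a relation's true links
#'
#' Emits `docs_per_link` documents per true link, each containing both
#' entities' names plus distractor text; no document mentions more than one
#' pair, so [count_cooccurrence()] on the output recovers exactly
#' `docs_per_link` for true links and 0 elsewhere.
#'
#' @param catalog an [entity_catalog()].
#' @param truth binary true-link matrix for the relation.
#' @param spec the relation's [relation_spec()].
#' @param docs_per_link documents emitted per true link.
#' @param seed RNG seed for the distractor text.
#' @return character vector of documents.
#' @export
generate_corpus <- function(catalog, truth, spec, docs_per_link = 1, seed = 1) {
  set.seed(seed)
  if (docs_per_link <= 0) return(character(0))
  idx <- which(truth == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  fillers <- c("study", "reports", "evidence", "for", "modulation", "of",
               "signaling", "observed", "in", "patients", "cohort", "assay")
  docs <- character(0)
  for (k in seq_len(nrow(idx))) {
    a <- catalog$types[[spec$source]][idx[k, 1]]
    b <- catalog$types[[spec$target]][idx[k, 2]]
    for (d in seq_len(docs_per_link)) {
      pad <- paste(sample(fillers, 5, replace = TRUE), collapse = " ")
      docs <- c(docs, paste(a, pad, b, "."))
    }
  }
  docs
}

#' Planted-structure recovery experiment
#'
#' Generates a synthetic world, trains the requested objective variants on
#' the same observed graph, and scores the held-out target-disease links
#' against all unobserved pairs (held-out AUROC / AUPR). Seeded end-to-end.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [train_config()]; its seed and variant fields are
#'   overridden per run.
#' @param variants objective variants to train.
#' @return named list of `eval_report`s (with `fit` attached as an
#'   attribute per variant).
#' @export
recovery_experiment <- function(spec, config = train_config(),
                                variants = "full") {
  world <- generate_prob_kg(spec)
  # held-out entries leave the loss entirely (weight 0), per the anti-leakage rule
  kg <- mask_entries(world$kg, world$holdout)
  tda_truth <- world$truth$protein_disease
  observed <- kg$P$protein_disease > 0
  test_idx <- which(!observed)  # held-out positives + true negatives
  labels <- tda_truth
  out <- list()
  for (v in variants) {
    cfg <- config
    cfg$variant <- v
    cfg$seed <- config$seed
    fit <- train_model(kg, cfg)
    pred <- predict_tda(fit, kg)
    rep_ <- eval_report(pred, (observed) * 1, C_tda = kg$C$protein_disease,
                        test_idx = test_idx, labels = labels)
    attr(rep_, "fit") <- fit
    out[[v]] <- rep_
  }
  out
}

#' Write a synthetic world to loader-compatible files
#'
#' Emits the same TSV edge lists, dictionary and corpus formats the package
#' loaders consume, plus a relation manifest (YAML).
#'
#' @param world result of [generate_prob_kg()].
#' @param dir output directory.
#' @param docs_per_link documents per true target-disease link in the
#'   emitted corpus.
#' @return `dir`, invisibly.
#' @export
write_synthetic_world <- function(world, dir, docs_per_link = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kg <- world$kg
  manifest <- list()
  for (r in names(kg$specs)) {
    s <- kg$specs[[r]]
    f <- file.path(dir, paste0("edges_", r, ".tsv"))
    if (s$similarity) {
      idx <- which(upper.tri(kg$P[[r]], diag = TRUE), arr.ind = TRUE)
      lines <- paste(kg$catalog$types[[s$source]][idx[, 1]],
                     kg$catalog$types[[s$target]][idx[, 2]],
                     format_full(kg$P[[r]][idx]), sep = "\t")
      writeLines(c("source\ttarget\tvalue", lines), f)
    } else {
      idx <- which(kg$P[[r]] > 0, arr.ind = TRUE)
      lines <- paste(kg$catalog$types[[s$source]][idx[, 1]],
                     kg$catalog$types[[s$target]][idx[, 2]], sep = "\t")
      writeLines(c("source\ttarget", lines), f)
    }
    manifest[[r]] <- list(file = basename(f), source = s$source, target = s$target,
                          literature = s$literature, similarity = s$similarity,
                          symmetric = s$symmetric)
  }
  yaml::write_yaml(manifest, file.path(dir, "relations.yaml"))
  syn <- kg$catalog$synonyms
  writeLines(c("entity_id\tsynonym",
               unlist(lapply(names(syn), function(id) paste(id, syn[[id]], sep = "\t")))),
             file.path(dir, "dictionary.tsv"))
  corpus <- generate_corpus(kg$catalog, world$truth$protein_disease,
                            kg$specs$protein_disease, docs_per_link = docs_per_link)
  writeLines(corpus, file.path(dir, "corpus.txt"))
  writeLines(c("i\tj", paste(world$holdout[, 1], world$holdout[, 2], sep = "\t")),
             file.path(dir, "holdout_protein_disease.tsv"))
  write_probkg(kg, file.path(dir, "kg"))
  invisible(dir)
}
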
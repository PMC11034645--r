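#' Entity catalog
#'
#' An ordered catalog of unique entity identifiers per entity type
#' (`drug`, `protein`, `disease`, `side_effect`), optionally carrying a
#' synonym dictionary used for literature matching.
#'
#' @param ... named character vectors, one per entity type, e.g.
#'   `drug = c("DB0001", ...)`. Identifiers must be unique within a type.
#' @param synonyms optional named list mapping entity identifier to a
#'   character vector of text synonyms (non-empty strings).
#' @return an object of class `entity_catalog` with elements `types`
#'   (named list of identifier vectors) and `synonyms`.
#' @export
entity_catalog <- function(..., synonyms = NULL) {
  types <- list(...)
  if (length(types) == 1L && is.list(types[[1]]) && is.null(names(types)[1])) {
    types <- types[[1]]
  }
  if (is.null(names(types)) || any(!nzchar(names(types)))) {
    stop_probkg("entity types must be named")
  }
  for (t in names(types)) {
    ids <- as.character(types[[t]])
    if (anyDuplicated(ids)) {
      stop_probkg("duplicate identifiers within entity type '%s'", t)
    }
    types[[t]] <- ids
  }
  if (!is.null(synonyms)) {
    all_ids <- unlist(types, use.names = FALSE)
    bad <- setdiff(names(synonyms), all_ids)
    if (length(bad)) stop_probkg("synonyms given for unknown entity: %s", bad[1])
    for (s in synonyms) {
      if (any(!nzchar(s))) stop_probkg("empty synonym string")
    }
  }
  structure(list(types = types, synonyms = synonyms), class = "entity_catalog")
}

#' @export
print.entity_catalog <- function(x, ...) {
  cat("<entity_catalog>\n")
  for (t in names(x$types)) cat(sprintf("  %-12s %d entities\n", t, length(x$types[[t]])))
  if (!is.null(x$synonyms)) cat(sprintf("  synonyms for %d entities\n", length(x$synonyms)))
  invisible(x)
}

#' Look up entity indices
#'
#' @param catalog an [entity_catalog()].
#' @param type entity type name.
#' @param ids character vector of identifiers.
#' @return integer indices into the ordered identifier list.
#' @export
entity_index <- function(catalog, type, ids) {
  idx <- match(ids, catalog$types[[type]])
  if (anyNA(idx)) {
    stop_probkg("unknown %s identifier: %s", type, ids[which(is.na(idx))[1]])
  }
  idx
}

#' Relation specification
#'
#' Describes one relation type of the knowledge graph: its endpoint entity
#' types and its membership in the similarity set (dense, value-weighted
#' relations such as drug structural or protein sequence similarity), the
#' literature set (relations whose edge probabilities and loss weights
#' incorporate co-occurrence counts), and the symmetric set.
#'
#' @param name relation name (used as a key throughout).
#' @param source,target endpoint entity types.
#' @param literature is the relation in the literature-weighted set R_c?
#' @param similarity is the relation one of the two dense similarity
#'   networks (R_s)?
#' @param symmetric does the adjacency equal its transpose?
#' @return an object of class `relation_spec`.
#' @export
relation_spec <- function(name, source, target, literature = FALSE,
                          similarity = FALSE, symmetric = FALSE) {
  if (similarity && literature) {
    stop_probkg("relation '%s': similarity and literature sets are mutually exclusive", name)
  }
  if (similarity && (!symmetric || source != target)) {
    stop_probkg("relation '%s': similarity relations must be symmetric with equal endpoint types", name)
  }
  if (symmetric && source != target) {
    stop_probkg("relation '%s': symmetric relations need equal endpoint types", name)
  }
  structure(list(name = name, source = source, target = target,
                 literature = literature, similarity = similarity,
                 symmetric = symmetric),
            class = "relation_spec")
}

#' @export
print.relation_spec <- function(x, ...) {
  tags <- c(if (x$literature) "literature", if (x$similarity) "similarity",
            if (x$symmetric) "symmetric")
  cat(sprintf("<relation_spec> %s: %s -> %s %s\n", x$name, x$source, x$target,
              if (length(tags)) paste0("[", paste(tags, collapse = ","), "]") else ""))
  invisible(x)
}

#' The default heterogeneous relation set
#'
#' Eight relation types over drugs, proteins, diseases and side effects:
#' four association/interaction networks, three literature-weighted
#' association relations (drug-protein, drug-disease, protein-disease) and
#' the two dense similarity networks.
#'
#' @return named list of [relation_spec()] objects.
#' @export
default_relation_specs <- function() {
  specs <- list(
    relation_spec("drug_drug",        "drug",    "drug",    symmetric = TRUE),
    relation_spec("protein_protein",  "protein", "protein", symmetric = TRUE),
    relation_spec("drug_protein",     "drug",    "protein", literature = TRUE),
    relation_spec("drug_disease",     "drug",    "disease", literature = TRUE),
    relation_spec("protein_disease",  "protein", "disease", literature = TRUE),
    relation_spec("drug_side_effect", "drug",    "side_effect"),
    relation_spec("drug_similarity",    "drug",    "drug",    similarity = TRUE, symmetric = TRUE),
    relation_spec("protein_similarity", "protein", "protein", similarity = TRUE, symmetric = TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

new_prob_kg <- function(catalog, specs, P, C, alpha, beta, mask = NULL) {
  P <- lapply(P, function(m) { storage.mode(m) <- "double"; m })
  C <- lapply(C, function(m) { storage.mode(m) <- "integer"; m })
  structure(list(catalog = catalog, specs = specs, P = P, C = C,
                 alpha = alpha, beta = beta, mask = mask),
            class = "prob_kg")
}

#' @export
print.prob_kg <- function(x, ...) {
  cat("<prob_kg>\n")
  for (r in names(x$specs)) {
    s <- x$specs[[r]]
    nobs <- sum(x$P[[r]] > 0)
    cat(sprintf("  %-18s %s->%s  %dx%d, %d nonzero%s\n", r, s$source, s$target,
                nrow(x$P[[r]]), ncol(x$P[[r]]), nobs,
                if (s$literature) sprintf(", counts in [%d, %d]", min(x$C[[r]]), max(x$C[[r]])) else ""))
  }
  cat(sprintf("  alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

kg_dims <- function(kg, spec) {
  c(length(kg$catalog$types[[spec$source]]), length(kg$catalog$types[[spec$target]]))
}

#' Observed-entry mask of a relation
#'
#' Similarity relations are dense (every pair is an edge), so every entry is
#' observed; other relations are observed exactly where the probabilistic
#' adjacency is nonzero.
#'
#' @param kg a `prob_kg`.
#' @param relation relation name.
#' @return logical matrix.
#' @export
observed_entries <- function(kg, relation) {
  spec <- kg$specs[[relation]]
  if (spec$similarity) {
    matrix(TRUE, nrow(kg$P[[relation]]), ncol(kg$P[[relation]]))
  } else {
    kg$P[[relation]] > 0
  }
}

#' Load per-relation edge lists into a knowledge graph
#'
#' Reads one TSV edge list per relation (header `source<TAB>target[<TAB>value]`),
#' producing binary adjacencies for association/interaction relations and
#' value-weighted grids for similarity relations. Duplicate edges are
#' deduplicated; symmetric relations are symmetrized (an entry is present if
#' either orientation is listed, duplicate similarity values keep the
#' maximum). Co-occurrence matrices start at zero; attach them with
#' [assign_edge_probabilities()].
#'
#' @param edge_files named list/character vector mapping relation name to a
#'   TSV file path. Relations without a file get an all-zero adjacency.
#' @param catalog an [entity_catalog()].
#' @param specs named list of [relation_spec()]s.
#' @param alpha,beta hyperparameters of the probability (alpha) and loss
#'   weight (beta) maps; observed zero-evidence edges get floor
#'   `sigmoid(alpha)` once probabilities are assigned.
#' @return a `prob_kg` with binary/similarity adjacencies and zero counts.
#' @export
load_networks <- function(edge_files, catalog, specs, alpha = 0, beta = 0) {
  P <- list(); C <- list()
  for (r in names(specs)) {
    spec <- specs[[r]]
    d <- c(length(catalog$types[[spec$source]]), length(catalog$types[[spec$target]]))
    A <- matrix(0, d[1], d[2])
    f <- edge_files[[r]]
    if (!is.null(f)) {
      tab <- utils::read.delim(f, header = TRUE, colClasses = "character",
                               check.names = FALSE)
      if (ncol(tab) < 2) stop_probkg("relation '%s': edge list needs >= 2 columns", r)
      if (nrow(tab) > 0) {
        i <- match(tab[[1]], catalog$types[[spec$source]])
        j <- match(tab[[2]], catalog$types[[spec$target]])
        if (anyNA(i) || anyNA(j)) {
          bad <- which(is.na(i) | is.na(j))[1]
          stop_probkg("relation '%s', line %d: unknown entity '%s'/'%s'",
                      r, bad + 1L, tab[[1]][bad], tab[[2]][bad])
        }
        if (spec$similarity) {
          if (ncol(tab) < 3) stop_probkg("relation '%s': similarity edges need a value column", r)
          v <- as.numeric(tab[[3]])
          if (anyNA(v) || any(v < 0 | v > 1)) {
            bad <- which(is.na(v) | v < 0 | v > 1)[1]
            stop_probkg("relation '%s', line %d: similarity value outside [0,1]", r, bad + 1L)
          }
          for (kk in seq_along(i)) {
            A[i[kk], j[kk]] <- max(A[i[kk], j[kk]], v[kk])
          }
        } else {
          A[cbind(i, j)] <- 1
        }
      }
    }
    if (spec$symmetric) A <- pmax(A, t(A))
    if (spec$similarity) diag(A) <- 1
    P[[r]] <- A
    if (spec$literature) C[[r]] <- matrix(0L, d[1], d[2])
  }
  new_prob_kg(catalog, specs, P, C, alpha, beta)
}

#' Edge probability of a single pair
#'
#' Probability assigned to one edge: 0 if the pair is unobserved; the
#' supplied similarity value for similarity relations; `sigmoid(count + alpha)`
#' for observed literature-weighted relations; and 1 for all other observed
#' relations (the indicator zeroes the literature term).
#'
#' @param count non-negative co-occurrence count.
#' @param observed was the pair observed in the biological networks?
#' @param spec a [relation_spec()].
#' @param alpha hyperparameter shifting the count before the sigmoid.
#' @param similarity_value similarity score in `[0,1]`; required for
#'   similarity relations.
#' @return a probability in `[0,1]`.
#' @export
edge_probability <- function(count, observed, spec, alpha = 0,
                             similarity_value = NULL) {
  if (count < 0) stop_probkg("negative co-occurrence count")
  if (!observed) return(0)
  if (spec$similarity) {
    if (is.null(similarity_value)) {
      stop_probkg("similarity relation '%s' needs a similarity_value", spec$name)
    }
    return(similarity_value)
  }
  if (spec$literature) return(sigmoid(count + alpha))
  1
}

#' Assign literature-informed edge probabilities
#'
#' Replaces every observed entry of every relation by its edge probability:
#' literature-weighted relations get `sigmoid(C + alpha)`, other association
#' relations stay at 1, similarity relations keep their similarity scores.
#' Unobserved entries remain 0. Counts are stored on the graph for loss
#' weighting.
#'
#' @param kg a `prob_kg` (as from [load_networks()]).
#' @param cooccurrence named list of count matrices, one per literature
#'   relation.
#' @return the updated `prob_kg`.
#' @export
assign_edge_probabilities <- function(kg, cooccurrence) {
  for (r in names(kg$specs)) {
    spec <- kg$specs[[r]]
    if (!spec$literature) next
    Cm <- cooccurrence[[r]]
    if (is.null(Cm)) stop_probkg("missing co-occurrence matrix for literature relation '%s'", r)
    if (!all(dim(Cm) == dim(kg$P[[r]]))) {
      stop_probkg("co-occurrence shape mismatch for relation '%s'", r)
    }
    if (any(Cm < 0)) stop_probkg("negative co-occurrence count in relation '%s'", r)
    obs <- kg$P[[r]] > 0
    Pnew <- matrix(0, nrow(Cm), ncol(Cm))
    Pnew[obs] <- sigmoid(Cm[obs] + kg$alpha)
    kg$P[[r]] <- Pnew
    kg$C[[r]] <- Cm
  }
  kg
}

#' Mask held-out association entries against leakage
#'
#' Zeroes both the edge probability and the co-occurrence count of the given
#' entries, so that no information about them (network or literature) enters
#' the model, and records the mask on the graph so the training objective can
#' also exclude them from the loss (weight 0).
#'
#' @param kg a `prob_kg`.
#' @param pairs two-column integer matrix of (source index, target index)
#'   pairs; may have zero rows.
#' @param relation relation to mask; default the target-disease association.
#' @return the masked `prob_kg`.
#' @export
mask_entries <- function(kg, pairs, relation = "protein_disease") {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  d <- dim(kg$P[[relation]])
  if (nrow(pairs) > 0) {
    if (any(pairs[, 1] < 1 | pairs[, 1] > d[1] | pairs[, 2] < 1 | pairs[, 2] > d[2])) {
      stop_probkg("mask index out of range for relation '%s'", relation)
    }
    kg$P[[relation]][pairs] <- 0
    if (!is.null(kg$C[[relation]])) kg$C[[relation]][pairs] <- 0L
  }
  m <- kg$mask %||% list()
  mm <- m[[relation]] %||% matrix(FALSE, d[1], d[2])
  if (nrow(pairs) > 0) mm[pairs] <- TRUE
  m[[relation]] <- mm
  kg$mask <- m
  kg
}

#' Serialize a knowledge graph to a directory of text files
#'
#' Writes the catalog, relation specification table, per-relation sparse
#' coordinate TSVs (probability and count), and hyperparameters. The
#' round-trip through [read_probkg()] is bit-exact.
#'
#' @param kg a `prob_kg`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_probkg <- function(kg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_lines <- character(0)
  for (t in names(kg$catalog$types)) {
    cat_lines <- c(cat_lines, paste(t, kg$catalog$types[[t]], sep = "\t"))
  }
  writeLines(c("type\tid", cat_lines), file.path(dir, "catalog.tsv"))
  if (!is.null(kg$catalog$synonyms)) {
    syn <- kg$catalog$synonyms
    lines <- unlist(lapply(names(syn), function(id) paste(id, syn[[id]], sep = "\t")))
    writeLines(c("entity_id\tsynonym", lines), file.path(dir, "synonyms.tsv"))
  }
  meta <- list(alpha = kg$alpha, beta = kg$beta,
               relations = lapply(kg$specs, function(s) {
                 s[c("name", "source", "target", "literature", "similarity", "symmetric")]
               }))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (r in names(kg$specs)) {
    Pm <- kg$P[[r]]
    Cm <- kg$C[[r]]
    keep <- Pm != 0
    if (!is.null(Cm)) keep <- keep | (Cm != 0)  # counts exist beyond observed edges
    nz <- which(keep, arr.ind = TRUE)
    lines <- if (nrow(nz) > 0) {
      vals <- format_full(Pm[nz])
      cnts <- if (!is.null(Cm)) Cm[nz] else rep(0L, nrow(nz))
      paste(nz[, 1], nz[, 2], vals, cnts, sep = "\t")
    } else character(0)
    writeLines(c("i\tj\tp\tc", lines), file.path(dir, paste0("relation_", r, ".tsv")))
    if (!is.null(kg$mask) && !is.null(kg$mask[[r]])) {
      mi <- which(kg$mask[[r]], arr.ind = TRUE)
      writeLines(c("i\tj", paste(mi[, 1], mi[, 2], sep = "\t")),
                 file.path(dir, paste0("mask_", r, ".tsv")))
    }
  }
  invisible(dir)
}

#' Read a knowledge graph written by [write_probkg()]
#'
#' @param dir directory produced by [write_probkg()].
#' @return a `prob_kg`.
#' @export
read_probkg <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  cat_tab <- utils::read.delim(file.path(dir, "catalog.tsv"), colClasses = "character")
  types <- split(cat_tab$id, factor(cat_tab$type, levels = unique(cat_tab$type)))
  synonyms <- NULL
  syn_path <- file.path(dir, "synonyms.tsv")
  if (file.exists(syn_path)) {
    st <- utils::read.delim(syn_path, colClasses = "character")
    synonyms <- split(st$synonym, factor(st$entity_id, levels = unique(st$entity_id)))
  }
  catalog <- entity_catalog(types, synonyms = synonyms)
  specs <- lapply(meta$relations, function(s) {
    relation_spec(s$name, s$source, s$target, literature = isTRUE(s$literature),
                  similarity = isTRUE(s$similarity), symmetric = isTRUE(s$symmetric))
  })
  specs <- stats::setNames(specs, vapply(specs, `[[`, "", "name"))
  P <- list(); C <- list(); mask <- NULL
  for (r in names(specs)) {
    spec <- specs[[r]]
    d <- c(length(types[[spec$source]]), length(types[[spec$target]]))
    tab <- utils::read.delim(file.path(dir, paste0("relation_", r, ".tsv")))
    Pm <- matrix(0, d[1], d[2])
    if (nrow(tab) > 0) Pm[cbind(tab$i, tab$j)] <- tab$p
    P[[r]] <- Pm
    if (spec$literature) {
      Cm <- matrix(0L, d[1], d[2])
      if (nrow(tab) > 0) Cm[cbind(tab$i, tab$j)] <- as.integer(tab$c)
      C[[r]] <- Cm
    }
    mpath <- file.path(dir, paste0("mask_", r, ".tsv"))
    if (file.exists(mpath)) {
      mt <- utils::read.delim(mpath)
      mm <- matrix(FALSE, d[1], d[2])
      if (nrow(mt) > 0) mm[cbind(mt$i, mt$j)] <- TRUE
      mask <- c(mask, stats::setNames(list(mm), r))
    }
  }
  new_prob_kg(catalog, specs, P, C, as.numeric(meta$alpha), as.numeric(meta$beta),
              mask = mask)
}
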
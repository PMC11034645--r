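# Independent oracles used by the dual-route checks. These deliberately use
# different algorithms (brute-force pair counting, threshold sweeps, naive
# scans, finite differences) from the implementation paths they verify.

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# naive per-synonym substring scan (matching contract of the automaton)
oracle_match <- function(synonyms, text, min_length = 3) {
  text <- tolower(text)
  hits <- character(0)
  for (id in names(synonyms)) {
    for (s in synonyms[[id]]) {
      if (nchar(s) >= min_length && grepl(tolower(s), text, fixed = TRUE)) {
        hits <- c(hits, id)
        break
      }
    }
  }
  sort(unique(hits))
}

oracle_cooccurrence <- function(corpus, synonyms, ids_a, ids_b, min_length = 3) {
  C <- matrix(0L, length(ids_a), length(ids_b))
  for (doc in corpus) {
    m <- oracle_match(synonyms, doc, min_length)
    for (i in seq_along(ids_a)) {
      for (j in seq_along(ids_b)) {
        if (ids_a[i] %in% m && ids_b[j] %in% m) C[i, j] <- C[i, j] + 1L
      }
    }
  }
  C
}

# reference local alignment score via Biostrings (independent C code); the
# gap convention is aligned by shifting the opening penalty
oracle_sw <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM50",
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
    scoreOnly = TRUE))
}

# elementwise double-sum objective oracle (no matrix algebra reuse)
oracle_objective <- function(params, kg, targets, weights, lambda, norm = "row") {
  Ahat <- list()
  for (r in names(kg$specs)) {
    s <- kg$specs[[r]]
    A <- if (s$similarity) kg$P[[r]] else (kg$P[[r]] > 0) * 1
    if (norm == "row") {
      for (i in seq_len(nrow(A))) {
        nv <- sqrt(sum(A[i, ]^2))
        if (nv > 0) A[i, ] <- A[i, ] / nv
      }
    } else {
      nv <- sqrt(sum(A^2)); if (nv > 0) A <- A / nv
    }
    Ahat[[r]] <- A
  }
  Z <- list()
  for (a in names(kg$catalog$types)) {
    n_a <- length(kg$catalog$types[[a]])
    Y <- matrix(0, n_a, params$dims$d0)
    for (r in names(kg$specs)) {
      s <- kg$specs[[r]]
      if (s$source == a) Y <- Y + Ahat[[r]] %*% params$X[[s$target]] %*% params$Wr[[r]]
      if (s$target == a && s$source != a) {
        Y <- Y + t(Ahat[[r]]) %*% params$X[[s$source]] %*% params$Wr[[r]]
      }
    }
    Zt <- pmax(cbind(Y, params$X[[a]]) %*% params$W1, 0)
    if (norm == "row") {
      for (i in seq_len(nrow(Zt))) {
        nv <- sqrt(sum(Zt[i, ]^2))
        if (nv > 0) Zt[i, ] <- Zt[i, ] / nv
      }
    } else {
      nv <- sqrt(sum(Zt^2)); if (nv > 0) Zt <- Zt / nv
    }
    Z[[a]] <- Zt
  }
  loss <- 0
  for (r in names(kg$specs)) {
    s <- kg$specs[[r]]
    H <- if (s$symmetric) params$G[[r]] else params$H[[r]]
    R <- Z[[s$source]] %*% params$G[[r]] %*% t(H) %*% t(Z[[s$target]])
    for (i in seq_len(nrow(R))) {
      for (j in seq_len(ncol(R))) {
        loss <- loss + ((R[i, j] - targets[[r]][i, j]) * weights[[r]][i, j])^2
      }
    }
  }
  blocks <- c(params$X, params$Wr, list(params$W1), params$G,
              Filter(Negate(is.null), params$H))
  loss + lambda * sum(vapply(blocks, function(b) sum(b^2), 0))
}
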
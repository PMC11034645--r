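# Fixtures built in code at test time (no stored binaries).

toy_catalog <- function(n = 4) {
  entity_catalog(
    drug = paste0("d", seq_len(n)),
    protein = paste0("p", seq_len(n)),
    disease = paste0("s", seq_len(n)),
    side_effect = paste0("e", seq_len(n))
  )
}

# small random knowledge graph over the full default relation set
toy_kg <- function(n = 5, seed = 42, alpha = 0, beta = 0, density = 0.4) {
  set.seed(seed)
  catalog <- entity_catalog(
    drug = paste0("d", seq_len(n)),
    protein = paste0("p", seq_len(n)),
    disease = paste0("s", seq_len(n)),
    side_effect = paste0("e", seq_len(n))
  )
  specs <- default_relation_specs()
  P <- list(); C <- list()
  for (r in names(specs)) {
    s <- specs[[r]]
    if (s$similarity) {
      M <- matrix(runif(n * n), n, n)
      M <- (M + t(M)) / 2
      diag(M) <- 1
      P[[r]] <- M
      next
    }
    A <- matrix(rbinom(n * n, 1, density), n, n)
    if (s$symmetric) {
      A <- pmax(A, t(A)); diag(A) <- 0
    }
    P[[r]] <- A
    if (s$literature) C[[r]] <- matrix(rpois(n * n, 2), n, n)
  }
  kg <- probkg:::new_prob_kg(catalog, specs, P, C, alpha, beta)
  assign_edge_probabilities(kg, C)
}

toy_train_config <- function(...) {
  train_config(d0 = 8, d1 = 6, k = 5, lambda = 1e-3, epochs = 5, seed = 7, ...)
}

write_edge_file <- function(path, rows, header = c("source", "target")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
}
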
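# Multi-pattern dictionary matching over a text corpus. The matcher is a
# classic Aho-Corasick automaton (trie + failure links) over lowercased
# characters; behaviour is required to be identical to a naive per-synonym
# substring scan, which the test suite enforces with an independent oracle.

ac_build <- function(patterns) {
  children <- list(integer(0))
  out <- list(integer(0))
  for (p in seq_along(patterns)) {
    chars <- strsplit(patterns[[p]], "", fixed = TRUE)[[1]]
    s <- 1L
    for (ch in chars) {
      nxt <- children[[s]][ch]
      if (is.na(nxt)) {
        children[[length(children) + 1L]] <- integer(0)
        out[[length(children)]] <- integer(0)
        nxt <- length(children)
        children[[s]][ch] <- nxt
      }
      s <- as.integer(nxt)
    }
    out[[s]] <- c(out[[s]], p)
  }
  fail <- rep(1L, length(children))
  queue <- as.integer(children[[1]])
  head <- 1L
  while (head <= length(queue)) {
    s <- queue[head]; head <- head + 1L
    kids <- children[[s]]
    for (ci in seq_along(kids)) {
      ch <- names(kids)[ci]
      tnode <- kids[[ci]]
      queue <- c(queue, tnode)
      f <- fail[s]
      while (f != 1L && is.na(children[[f]][ch])) f <- fail[f]
      cand <- children[[f]][ch]
      fail[tnode] <- if (!is.na(cand) && cand != tnode) as.integer(cand) else 1L
      out[[tnode]] <- c(out[[tnode]], out[[fail[tnode]]])
    }
  }
  list(children = children, fail = fail, out = out, n_patterns = length(patterns))
}

ac_scan <- function(ac, text) {
  chars <- strsplit(tolower(text), "", fixed = TRUE)[[1]]
  s <- 1L
  hits <- logical(ac$n_patterns)
  children <- ac$children; fail <- ac$fail; out <- ac$out
  for (ch in chars) {
    while (s != 1L && is.na(children[[s]][ch])) s <- fail[s]
    nxt <- children[[s]][ch]
    if (!is.na(nxt)) s <- as.integer(nxt)
    o <- out[[s]]
    if (length(o)) hits[o] <- TRUE
  }
  which(hits)
}

#' Build a dictionary matcher from a catalog's synonyms
#'
#' Compiles all entity synonyms (case-insensitive, substring semantics) into
#' a multi-pattern automaton. Substring matching can overmatch very short
#' names, so synonyms shorter than `min_length` characters are dropped.
#'
#' @param catalog an [entity_catalog()] with a synonym dictionary.
#' @param min_length minimum synonym length kept for matching (default 3).
#' @return an object of class `name_matcher`.
#' @export
build_name_matcher <- function(catalog, min_length = 3) {
  if (is.null(catalog$synonyms) || length(catalog$synonyms) == 0) {
    stop_probkg("catalog has no synonym dictionary")
  }
  ids <- character(0); syns <- character(0)
  for (id in names(catalog$synonyms)) {
    s <- catalog$synonyms[[id]]
    if (any(!nzchar(s))) stop_probkg("empty synonym for entity '%s'", id)
    keep <- nchar(s) >= min_length
    ids <- c(ids, rep(id, sum(keep)))
    syns <- c(syns, tolower(s[keep]))
  }
  if (!length(syns)) stop_probkg("no synonyms of length >= %d", min_length)
  type_of <- character(0)
  for (t in names(catalog$types)) {
    type_of[catalog$types[[t]]] <- t
  }
  structure(list(ac = ac_build(syns), entity = ids, type = type_of[ids],
                 patterns = syns),
            class = "name_matcher")
}

#' Entities mentioned in one document
#'
#' @param matcher a [build_name_matcher()] object.
#' @param text a document.
#' @return data.frame with columns `entity` and `type`, one row per distinct
#'   matched entity.
#' @export
match_entities <- function(matcher, text) {
  hit <- ac_scan(matcher$ac, text)
  ents <- unique(matcher$entity[hit])
  data.frame(entity = ents, type = matcher$type[match(ents, matcher$entity)],
             stringsAsFactors = FALSE)
}

#' Document-level co-occurrence counts for a relation
#'
#' `C[i, j]` is the number of documents in which entity `i` (of the
#' relation's source type) and entity `j` (target type) are both mentioned;
#' a document contributes at most 1 per pair regardless of how often either
#' name occurs in it.
#'
#' @param corpus character vector of documents (one document per element),
#'   or a path to a corpus file (one document per line) or a directory of
#'   `.txt` files.
#' @param matcher a [build_name_matcher()].
#' @param spec the literature [relation_spec()] being counted.
#' @param catalog the [entity_catalog()].
#' @return integer count matrix of shape (n source entities, n target entities).
#' @export
count_cooccurrence <- function(corpus, matcher, spec, catalog) {
  if (!spec$literature) stop_probkg("relation '%s' is not literature-weighted", spec$name)
  corpus <- read_corpus(corpus)
  n_a <- length(catalog$types[[spec$source]])
  n_b <- length(catalog$types[[spec$target]])
  Cm <- matrix(0L, n_a, n_b)
  for (doc in corpus) {
    m <- match_entities(matcher, doc)
    ia <- match(m$entity[m$type == spec$source], catalog$types[[spec$source]])
    ib <- match(m$entity[m$type == spec$target], catalog$types[[spec$target]])
    if (length(ia) && length(ib)) {
      grid <- expand.grid(i = ia, j = ib)
      Cm[cbind(grid$i, grid$j)] <- Cm[cbind(grid$i, grid$j)] + 1L
    }
  }
  Cm
}

read_corpus <- function(corpus) {
  if (is.character(corpus) && length(corpus) == 1 && dir.exists(corpus)) {
    files <- sort(list.files(corpus, pattern = "\\.txt$", full.names = TRUE))
    return(vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = "\n"), ""))
  }
  if (is.character(corpus) && length(corpus) == 1 && file.exists(corpus)) {
    return(readLines(corpus, warn = FALSE))
  }
  as.character(corpus)
}

#' Read an entity-name dictionary
#'
#' TSV with header `entity_id<TAB>synonym`, one synonym per row.
#'
#' @param path TSV path.
#' @return named list mapping entity id to a character vector of synonyms,
#'   suitable for [entity_catalog()]'s `synonyms` argument.
#' @export
read_dictionary <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  split(tab[[2]], factor(tab[[1]], levels = unique(tab[[1]])))
}
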
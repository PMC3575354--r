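## Shared fixtures and independent brute-force oracles. The oracles never
## call the code paths they check: subsumption walks raw descriptor slots,
## type queries filter by that walk, coreference chaining closes a boolean
## adjacency matrix, and calendar arithmetic goes through lubridate.

worked_text <- paste0("Chief complaint: severe cough and fever. ",
                      "Cough started 2 days ago, no expectoration.")

## ---- random schema registries ----

random_registry <- function(seed, n = 25) {
  set.seed(seed)
  reg <- schemaRegistry()
  sup_of <- list()
  spanned_of <- c(SPAN_ROOT = TRUE, TOP = FALSE)
  made <- character()
  for (i in seq_len(n)) {
    ns <- sample(clinNamespaces(), 1)
    nm <- sprintf("%s.T%d", ns, i)
    sup <- if (!length(made) || stats::runif(1) < 0.3)
      sample(c("SPAN_ROOT", "TOP"), 1) else sample(made, 1)
    reg <- registerType(reg, typeDescriptor(nm, sup,
                                            spanned = spanned_of[[sup]]))
    sup_of[[nm]] <- sup
    spanned_of[[nm]] <- spanned_of[[sup]]
    made <- c(made, nm)
  }
  list(registry = reg, supertypes = sup_of, types = made)
}

## supertype-chain walk over the raw supertype map
oracle_subsumes <- function(sup_of, ancestor, descendant) {
  cur <- descendant
  repeat {
    if (identical(cur, ancestor)) return(TRUE)
    cur <- sup_of[[cur]]
    if (is.null(cur) || cur %in% c("SPAN_ROOT", "TOP")) return(FALSE)
  }
}

## ---- random document stores over the shipped registry ----

random_store <- function(seed, nInstances = 12) {
  set.seed(seed)
  text <- paste(rep("lorem ipsum", 10), collapse = " ")
  store <- documentStore(text)
  spanned_types <- c("textsem.EventMention", "textsem.EntityMention",
                     "textsem.Modifier", "textspan.Sentence",
                     "syntax.WordToken", "syntax.NumToken")
  unspanned_types <- c("refsem.Severity", "refsem.EventProperties",
                       "util.Pair")
  for (i in seq_len(nInstances)) {
    if (stats::runif(1) < 0.8) {
      tn <- sample(spanned_types, 1)
      b <- sample.int(nchar(text) - 10L, 1) - 1L
      store <- addAnnotation(store, tn, b, b + sample.int(10L, 1))
    } else {
      store <- addAnnotation(store, sample(unspanned_types, 1))
    }
  }
  store
}

## brute-force type query: filter every instance by an oracle chain walk
## over the registry descriptors, then sort like the contract says
brute_get_by_type <- function(store, typeName) {
  reg <- store@registry
  walk <- function(tn) {
    out <- tn
    repeat {
      st <- reg@types[[tn]]@supertype
      if (st %in% c("SPAN_ROOT", "TOP")) return(out)
      out <- c(out, st)
      tn <- st
    }
  }
  hits <- Filter(function(x) typeName %in% walk(x@typeName),
                 store@instances)
  hits <- unname(hits)
  if (!length(hits)) return(hits)
  b <- vapply(hits, function(x)
    if (is.na(x@begin)) .Machine$integer.max else x@begin, integer(1))
  e <- vapply(hits, function(x)
    if (is.na(x@end)) .Machine$integer.max else x@end, integer(1))
  i <- vapply(hits, function(x) x@id, integer(1))
  hits[order(b, e, i)]
}

instance_ids <- function(insts) vapply(insts, function(x) x@id, integer(1))

## ---- coreference: boolean transitive closure ----

closure_chains <- function(ids, edges) {
  n <- length(ids)
  A <- diag(n) > 0
  if (length(edges))
    for (e in edges) {
      i <- match(e[1], ids); j <- match(e[2], ids)
      A[i, j] <- A[j, i] <- TRUE
    }
  repeat {
    B <- (A %*% A) > 0 | A
    if (identical(B, A)) break
    A <- B
  }
  comps <- unique(apply(A, 1, function(r) paste(which(r), collapse = ",")))
  lapply(comps, function(key)
    sort(ids[as.integer(strsplit(key, ",")[[1]])]))
}

## tiny store of n event mentions (one char each) + given coref pairs
mention_graph_store <- function(n, pairs) {
  store <- documentStore(paste(rep("m", n), collapse = " "))
  mids <- integer(n)
  for (i in seq_len(n)) {
    store <- addAnnotation(store, "textsem.EventMention",
                           (i - 1L) * 2L, (i - 1L) * 2L + 1L,
                           list(typeID = 3L))
    mids[i] <- lastId(store)
  }
  for (p in pairs) {
    store <- addAnnotation(store, "relation.RelationArgument",
                           features = list(argument = clinRef(mids[p[1]])))
    a1 <- lastId(store)
    store <- addAnnotation(store, "relation.RelationArgument",
                           features = list(argument = clinRef(mids[p[2]])))
    a2 <- lastId(store)
    store <- addAnnotation(store, "relation.CoreferenceRelation",
                           features = list(arg1 = clinRef(a1),
                                           arg2 = clinRef(a2)))
  }
  list(store = store, mentionIds = mids)
}

## ---- calendar oracle (lubridate's rollback arithmetic) ----

lubridate_oracle <- function(n, unit, date) {
  d <- switch(unit,
    day = date - n,
    week = date - 7 * n,
    month = lubridate::`%m-%`(date, lubridate::period(n, "months")),
    year = lubridate::`%m-%`(date, lubridate::period(n, "years")))
  list(day = as.integer(format(d, "%d")),
       month = as.integer(format(d, "%m")),
       year = as.integer(format(d, "%Y")))
}

## a small helper used by several files
expect_no_violations <- function(store) {
  expect_identical(validateStore(store), character(0))
}
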
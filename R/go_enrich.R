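#' Parse an OBO 1.2 ontology file into a DAG
#'
#' Reads `[Term]` stanzas: id, name, namespace, `is_a` parents, optional
#' `relationship: part_of` parents, `alt_id` aliases. Obsolete terms are
#' skipped; alt_ids resolve to their primary term. The graph is checked to
#' be acyclic and free of dangling parents, and ancestor sets are
#' precomputed in topological order.
#'
#' @param path OBO file.
#' @param include_part_of treat `part_of` edges as parent edges (default
#'   FALSE: `is_a` only).
#' @return A list of class `go_dag`: `terms`, `name`, `namespace`,
#'   `parents` (named list), `ancestors` (named list, excluding the term
#'   itself), `level` (1 = root; 1 + longest path from a root otherwise),
#'   `alt` (alt_id -> primary).
#' @export
parse_obo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  id <- nm <- ns <- character(0)
  parents <- list(); alt <- character(0)
  for (i in seq_along(starts)) {
    blk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[!grepl("^\\[", blk)]
    field <- function(key) sub(paste0("^", key, ": *"), "",
                               grep(paste0("^", key, ": "), blk, value = TRUE))
    if (length(field("is_obsolete")) && any(field("is_obsolete") == "true"))
      next
    tid <- field("id")[1]
    if (is.na(tid) || !length(tid)) next
    pa <- sub(" *!.*$", "", field("is_a"))
    if (include_part_of) {
      rel <- field("relationship")
      po <- sub(" *!.*$", "", sub("^part_of +", "", grep("^part_of ", rel,
                                                         value = TRUE)))
      pa <- c(pa, po)
    }
    id <- c(id, tid)
    nm <- c(nm, if (length(field("name"))) field("name")[1] else tid)
    ns <- c(ns, if (length(field("namespace"))) field("namespace")[1]
            else NA_character_)
    parents[[tid]] <- unique(pa)
    for (a in field("alt_id")) alt[a] <- tid
  }
  names(nm) <- names(ns) <- id
  dangling <- setdiff(unlist(parents), id)
  if (length(dangling))
    stop("dangling parent term(s): ", paste(dangling, collapse = ", "))

  # Kahn topological order (roots first); detects cycles.
  indeg <- setNames(lengths(parents)[id], id)
  children <- lapply(setNames(id, id), function(x) character(0))
  for (t in id) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)
  queue <- id[indeg == 0L]
  topo <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(id)) stop("cycle detected in ontology")

  anc <- vector("list", length(id)); names(anc) <- id
  lev <- setNames(integer(length(id)), id)
  for (t in topo) {
    pa <- parents[[t]]
    anc[[t]] <- unique(c(pa, unlist(anc[pa], use.names = FALSE)))
    lev[t] <- if (length(pa)) 1L + max(lev[pa]) else 1L
  }
  structure(list(terms = id, name = nm, namespace = ns, parents = parents,
                 children = children, ancestors = anc, level = lev,
                 alt = alt),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms (%s), max depth %d\n", length(x$terms),
              paste(names(table(x$namespace)), collapse = "/"),
              max(x$level)))
  invisible(x)
}

#' Resolve a term id (following alt_id aliases)
#' @param dag a [parse_obo()] DAG.
#' @param ids character vector of term ids or alt_ids.
#' @return Primary ids (`NA` for unknown terms).
#' @export
resolve_term <- function(dag, ids) {
  out <- ifelse(ids %in% dag$terms, ids, unname(dag$alt[ids]))
  out
}

#' Ancestors of a term (excluding itself)
#' @inheritParams resolve_term
#' @param id a single term id.
#' @return Character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, id) {
  id <- resolve_term(dag, id)
  if (is.na(id)) stop("unknown term")
  dag$ancestors[[id]]
}

#' Build a gene-to-GO map by merging annotation sources
#'
#' Sources (e.g. a pipeline-derived annotation plus ortholog-transferred
#' annotations) are unioned per gene; term ids are resolved against the DAG
#' with alt_ids mapped to primaries and unresolvable ids dropped (counted in
#' attribute `n_dropped`). With `propagate = TRUE` each gene is annotated to
#' every ancestor of its direct terms, the standard preparation for
#' overrepresentation testing.
#'
#' @param sources a data.frame with columns `gene`, `term`, or a list of
#'   such data.frames.
#' @param dag a [parse_obo()] DAG.
#' @param propagate annotate genes to ancestors (default TRUE).
#' @return A named list (gene -> character vector of term ids) of class
#'   `gene2go`, with attributes `n_dropped` and `propagated`.
#' @export
build_gene2go <- function(sources, dag, propagate = TRUE) {
  if (is.data.frame(sources)) sources <- list(sources)
  tab <- rbindlist(lapply(sources, function(s)
    data.table(gene = as.character(s$gene), term = as.character(s$term))))
  tab[, term := resolve_term(dag, term)]
  n_dropped <- sum(is.na(tab$term))
  tab <- tab[!is.na(term)]
  direct <- lapply(split(tab$term, tab$gene), unique)
  out <- if (propagate) {
    lapply(direct, function(ts)
      unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE))))
  } else direct
  structure(out, n_dropped = n_dropped, propagated = propagate,
            class = "gene2go")
}

#' One-sided Fisher overrepresentation p-value
#'
#' Upper-tail hypergeometric probability `P[X >= k]` for observing `k` study
#' genes annotated to a term, given `n` study genes, `K` annotated genes and
#' a universe of `N` — the classic GO enrichment test.
#'
#' @param k study genes carrying the term.
#' @param n study size.
#' @param K universe genes carrying the term.
#' @param N universe size.
#' @return The p-value.
#' @export
fisher_overrep <- function(k, n, K, N) {
  if (any(k > pmin(n, K)) || any(K > N) || any(n > N) || any(k < 0))
    stop("inconsistent contingency counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term overrepresentation (classic Fisher and elim)
#'
#' Tests every term of a namespace for overrepresentation in a study gene
#' set against a universe, on ancestor-propagated annotations. `classic`
#' tests each term independently. `elim` decorrelates the DAG: terms are
#' tested from the most specific level upward, and when a term reaches
#' `p <= elim_cutoff` its remaining annotated genes are eliminated from all
#' its ancestors before those are tested, so parents are not flagged merely
#' for containing a significant child. Terms with fewer than `min_genes`
#' annotated universe genes are excluded before testing; Bonferroni
#' correction multiplies by the number of tested terms (capped at 1).
#'
#' @param study character vector of study genes (must be within `universe`).
#' @param universe character vector of background genes; genes without a
#'   namespace annotation are dropped from both sets.
#' @param g2g a propagated [build_gene2go()] map.
#' @param dag a [parse_obo()] DAG.
#' @param algorithm `"classic"` or `"elim"`.
#' @param namespace ontology namespace to test (default
#'   `"biological_process"`; abbreviations BP/MF/CC accepted).
#' @param min_genes minimum annotated universe genes per tested term
#'   (default 10).
#' @param elim_cutoff elimination threshold for `elim` (default 0.01).
#' @return data.table sorted by `p_raw`: `term`, `name`, `annotated`,
#'   `significant`, `expected`, `p_raw`, `p_bonferroni`, `algorithm`;
#'   attribute `n_tested` holds the post-filter term count, and
#'   `n_universe` / `n_study` the annotated set sizes actually used.
#' @export
run_enrichment <- function(study, universe, g2g, dag,
                           algorithm = c("classic", "elim"),
                           namespace = "biological_process",
                           min_genes = 10L, elim_cutoff = 0.01) {
  algorithm <- match.arg(algorithm)
  ns_full <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  if (namespace %in% names(ns_full)) namespace <- ns_full[[namespace]]
  if (!length(study) || !length(universe))
    stop("empty study or universe")
  if (length(setdiff(study, universe)))
    stop("study genes outside the universe: ",
         paste(head(setdiff(study, universe), 5), collapse = ", "))
  if (!isTRUE(attr(g2g, "propagated")))
    stop("g2g must be ancestor-propagated (build_gene2go(propagate = TRUE))")

  ns_terms <- dag$terms[!is.na(dag$namespace) & dag$namespace == namespace]
  ann <- lapply(g2g, intersect, ns_terms)
  annotated_genes <- names(ann)[lengths(ann) > 0L]
  universe <- intersect(universe, annotated_genes)
  study <- intersect(study, universe)
  if (!length(study) || !length(universe))
    stop("no annotated genes in study or universe for namespace ", namespace)

  term_genes <- split(
    rep(universe, lengths(ann[universe])),
    unlist(ann[universe], use.names = FALSE))
  term_genes <- lapply(term_genes, unique)
  term_genes <- term_genes[lengths(term_genes) >= min_genes]
  terms <- names(term_genes)
  if (!length(terms)) stop("no terms pass the min_genes filter")
  N <- length(universe); n <- length(study)

  K_all <- lengths(term_genes)
  if (algorithm == "classic") {
    k_all <- vapply(term_genes, function(g) length(intersect(g, study)),
                    integer(1))
    p <- fisher_overrep(k_all, n, K_all, N)
  } else {
    elim <- new.env(parent = emptyenv())
    p <- setNames(numeric(length(terms)), terms)
    k_all <- setNames(integer(length(terms)), terms)
    lev <- dag$level[terms]
    for (L in sort(unique(lev), decreasing = TRUE)) {
      this_level <- terms[lev == L]
      newly_sig <- character(0)
      for (t in this_level) {
        g <- term_genes[[t]]
        ex <- get0(t, envir = elim, ifnotfound = NULL)
        if (!is.null(ex)) g <- setdiff(g, ex)
        k <- length(intersect(g, study))
        p[t] <- fisher_overrep(k, n, length(g), N)
        k_all[t] <- k
        if (p[t] <= elim_cutoff) newly_sig <- c(newly_sig, t)
      }
      for (t in newly_sig) {
        g <- setdiff(term_genes[[t]],
                     get0(t, envir = elim, ifnotfound = character(0)))
        for (a in intersect(dag$ancestors[[t]], terms))
          assign(a, union(get0(a, envir = elim,
                               ifnotfound = character(0)), g),
                 envir = elim)
      }
    }
  }

  out <- data.table(term = terms,
                    name = unname(dag$name[terms]),
                    annotated = as.integer(K_all),
                    significant = as.integer(k_all),
                    expected = n * K_all / N,
                    p_raw = as.numeric(p),
                    p_bonferroni = pmin(1, as.numeric(p) * length(terms)),
                    algorithm = algorithm)
  setorder(out, p_raw)
  attr(out, "n_tested") <- length(terms)
  attr(out, "n_universe") <- N
  attr(out, "n_study") <- n
  out[]
}
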
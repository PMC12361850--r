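#' Build a terminology (concepts, synonyms, is-a hierarchy)
#'
#' A desk-scale stand-in for a clinical terminology snapshot: a set of
#' concept identifiers, each with one or more synonym strings, plus a rooted
#' acyclic is-a multi-hierarchy (a concept may have several parents). Depth
#' queries measure the shortest child-to-parent chain to the root.
#'
#' @param synonyms named list: concept_id -> non-empty character vector of
#'   synonym terms.
#' @param edges data.frame with columns `child`, `parent`; every endpoint
#'   must be a known concept and the graph must be acyclic.
#' @param root_id the root concept; it must have no parent and every concept
#'   must be able to reach it along is-a edges.
#' @return an `el_terminology` object (list with elements `concept_ids`,
#'   `synonyms`, `edges`, `root_id`, `graph`).
#' @export
#' @examples
#' terminology(
#'   synonyms = list(R = "root", A = c("acute pain", "pain, acute"), B = "headache"),
#'   edges = data.frame(child = c("A", "B"), parent = c("R", "A")),
#'   root_id = "R"
#' )
terminology <- function(synonyms, edges, root_id) {
  if (!length(synonyms) || is.null(names(synonyms)) || any(!nzchar(names(synonyms)))) {
    stopf("synonyms must be a non-empty named list keyed by concept_id")
  }
  synonyms <- lapply(synonyms, function(s) {
    s <- as.character(s)
    if (!length(s) || any(is.na(s)) || any(!nzchar(s))) {
      stopf("every concept needs at least one non-empty synonym")
    }
    s
  })
  concept_ids <- names(synonyms)
  if (anyDuplicated(concept_ids)) stopf("duplicate concept_id in synonyms")
  root_id <- as.character(root_id)
  if (!root_id %in% concept_ids) stopf("root_id '%s' not among concepts", root_id)

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (!all(c("child", "parent") %in% names(edges))) {
      stopf("edges must have columns child, parent")
    }
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(unique(c(edges$child, edges$parent)), concept_ids)
    if (length(unknown)) {
      stopf("is-a edge endpoint(s) missing from the synonym table: %s",
            paste(unknown, collapse = ", "))
    }
    if (root_id %in% edges$child) stopf("root concept must have no parent")
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }

  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = concept_ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) stopf("is-a graph contains a cycle")

  structure(
    list(concept_ids = concept_ids, synonyms = synonyms, edges = edges,
         root_id = root_id, graph = g),
    class = "el_terminology"
  )
}

#' @export
print.el_terminology <- function(x, ...) {
  cat(sprintf("<terminology: %d concepts, %d is-a edges, root '%s'>\n",
              length(x$concept_ids), nrow(x$edges), x$root_id))
  invisible(x)
}

#' Read a terminology from the two-table TSV snapshot format
#'
#' @param synonyms_path TSV with header `concept_id<TAB>term`, one row per
#'   synonym (several rows per concept allowed).
#' @param edges_path TSV with header `child_id<TAB>parent_id`, one is-a edge
#'   per row.
#' @param root_id identifier of the root concept.
#' @return an [terminology()] object.
#' @export
read_terminology <- function(synonyms_path, edges_path, root_id) {
  syn <- utils::read.delim(synonyms_path, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (!all(c("concept_id", "term") %in% names(syn))) {
    stopf("%s: expected columns concept_id, term", synonyms_path)
  }
  rel <- utils::read.delim(edges_path, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (!all(c("child_id", "parent_id") %in% names(rel))) {
    stopf("%s: expected columns child_id, parent_id", edges_path)
  }
  synonyms <- split(syn$term, syn$concept_id)
  edges <- data.frame(child = rel$child_id, parent = rel$parent_id,
                      stringsAsFactors = FALSE)
  terminology(synonyms, edges, root_id)
}

#' Write a terminology to the two-table TSV snapshot format
#'
#' @param term an [terminology()] object.
#' @param synonyms_path,edges_path output TSV files.
#' @return invisibly, the two paths.
#' @export
write_terminology <- function(term, synonyms_path, edges_path) {
  stopifnot(inherits(term, "el_terminology"))
  syn <- data.frame(
    concept_id = rep(names(term$synonyms), lengths(term$synonyms)),
    term = unlist(term$synonyms, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(syn, synonyms_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  rel <- data.frame(child_id = term$edges$child, parent_id = term$edges$parent,
                    stringsAsFactors = FALSE)
  utils::write.table(rel, edges_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(synonyms_path, edges_path))
}

#' Depth of concepts in the is-a hierarchy
#'
#' Depth is the length, in edges, of the shortest chain of is-a
#' relationships from the concept to the root; the root has depth 0. In a
#' multi-hierarchy the shortest of the available chains wins.
#'
#' @param term an [terminology()] object.
#' @param concept_id character vector of concept identifiers.
#' @return integer vector of depths.
#' @export
#' @examples
#' t <- terminology(list(R = "r", A = "a", B = "b"),
#'                  data.frame(child = c("A", "B"), parent = c("R", "A")), "R")
#' concept_depth(t, c("R", "B"))  # 0 2
concept_depth <- function(term, concept_id) {
  stopifnot(inherits(term, "el_terminology"))
  concept_id <- as.character(concept_id)
  unknown <- setdiff(concept_id, term$concept_ids)
  if (length(unknown)) {
    stopf("concept(s) not in terminology: %s", paste(unknown, collapse = ", "))
  }
  uq <- unique(concept_id)
  d <- igraph::distances(term$graph, v = uq, to = term$root_id,
                         mode = "out")[, 1L]
  names(d) <- uq
  if (any(is.infinite(d))) {
    stopf("concept(s) cannot reach the root: %s",
          paste(names(d)[is.infinite(d)], collapse = ", "))
  }
  as.integer(d[concept_id])
}
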
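#' Breeding pedigree graph
#'
#' A pedigree is a DAG of accessions with at most two recorded parents per
#' node and a breeding role for every node: `exotic_founder` (introduced
#' germplasm with no recorded parents), `backbone` (historically reused cross
#' parent), `elite` (improved derived line) or `hybrid` (unnamed intermediate
#' inserted so composite crosses keep <= 2 parents per node).
#'
#' @param nodes data.frame with columns `id` and `role`.
#' @param edges data.frame with columns `parent` and `child`.
#' @return A `pedigree` object (list with `nodes`, `edges`).
#' @seealso [read_pedigree()], [validate_pedigree()], [example_pedigree()]
#' @export
pedigree_graph <- function(nodes, edges) {
  roles <- c("exotic_founder", "backbone", "elite", "hybrid")
  nodes <- data.frame(id = as.character(nodes$id),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate accession ids")
  bad <- setdiff(nodes$role, roles)
  if (length(bad)) stop("unknown role: ", bad[1])
  unknown <- setdiff(c(edges$parent, edges$child), nodes$id)
  if (length(unknown)) stop("edge references unknown accession: ", unknown[1])
  np <- table(edges$child)
  if (any(np > 2)) {
    stop("accession with more than two recorded parents: ",
         names(np)[which(np > 2)[1]])
  }
  structure(list(nodes = nodes, edges = edges), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$nodes), "accessions,", nrow(x$edges), "parent edges\n")
  print(table(x$nodes$role))
  invisible(x)
}

#' Read a pedigree from TSV
#'
#' Expected columns: `child`, `parent1`, `parent2`, `role`; a blank parent
#' means unknown. Parents that appear only in parent columns are added as
#' nodes with role `exotic_founder`.
#'
#' @param path TSV file.
#' @return a `pedigree` object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", na.strings = c("", "NA"))
  need <- c("child", "parent1", "parent2", "role")
  if (!all(need %in% names(df))) {
    stop("pedigree file needs columns: ", paste(need, collapse = ", "))
  }
  parents <- stats::na.omit(c(df$parent1, df$parent2))
  extra <- setdiff(parents, df$child)
  nodes <- data.frame(id = c(df$child, extra),
                      role = c(df$role, rep("exotic_founder", length(extra))))
  e1 <- df[!is.na(df$parent1), c("parent1", "child")]
  e2 <- df[!is.na(df$parent2), c("parent2", "child")]
  names(e1) <- names(e2) <- c("parent", "child")
  pedigree_graph(nodes, rbind(e1, e2))
}

#' @rdname read_pedigree
#' @param ped a `pedigree` object.
#' @export
write_pedigree <- function(ped, path) {
  par <- parents_of(ped)
  df <- data.frame(child = ped$nodes$id,
                   parent1 = vapply(ped$nodes$id, function(i)
                     if (length(par[[i]]) >= 1) par[[i]][1] else "", ""),
                   parent2 = vapply(ped$nodes$id, function(i)
                     if (length(par[[i]]) >= 2) par[[i]][2] else "", ""),
                   role = ped$nodes$role)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: named list id -> character vector of recorded parents
parents_of <- function(ped) {
  out <- lapply(stats::setNames(ped$nodes$id, ped$nodes$id), function(i)
    ped$edges$parent[ped$edges$child == i])
  out
}

#' Validate a pedigree and return a topological order
#'
#' Checks acyclicity and the two-parent bound and returns an accession order
#' in which every parent precedes all of its children (founders first).
#'
#' @param ped a `pedigree` object.
#' @return character vector of accession ids in topological order.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (nrow(ped$nodes) == 0) stop("empty pedigree")
  ids <- ped$nodes$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(ped$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  queue <- ids[indeg == 0]
  order <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    kids <- ped$edges$child[ped$edges$parent == v]
    for (k in kids) {
      indeg2[k] <- indeg2[k] - 1L
      if (indeg2[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < length(ids)) {
    rem <- setdiff(ids, order)
    e <- ped$edges[ped$edges$parent %in% rem & ped$edges$child %in% rem, ]
    stop("pedigree contains a cycle through edge ",
         e$parent[1], " -> ", e$child[1])
  }
  order
}

#' Ancestors of an accession
#' @param ped a `pedigree`.
#' @param id accession id.
#' @return character vector of all recorded ancestors (transitive closure).
#' @export
pedigree_ancestors <- function(ped, id) {
  stopifnot(id %in% ped$nodes$id)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    par <- unique(ped$edges$parent[ped$edges$child %in% frontier])
    new <- setdiff(par, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  seen
}

#' All parent-to-child paths between two accessions
#'
#' Enumerates every directed path from `from` (an ancestor) down to `to`
#' through recorded parent edges; used by chained-mode IBD tracing, where a
#' region must be transmitted at every link of some path.
#'
#' @param ped a `pedigree`.
#' @param from,to accession ids.
#' @return list of character vectors, each a path `from, ..., to`.
#' @export
pedigree_paths <- function(ped, from, to) {
  stopifnot(from %in% ped$nodes$id, to %in% ped$nodes$id)
  out <- list()
  walk <- function(node, path) {
    if (node == to) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (k in ped$edges$child[ped$edges$parent == node]) {
      walk(k, c(path, k))
    }
  }
  walk(from, from)
  out
}

#' Example cotton breeding pedigree
#'
#' A 26-accession Upland cotton pedigree centred on the cultivar Ekangmian 9:
#' five exotic/older founders (Lone Star, Deltapine 15, Stoneville 2B,
#' Guannong 1, 52-128), fourteen backbone parents bred from them (including
#' Ejing 1, Zhong 7263 and MO-3, the three recorded contributors of
#' Ekangmian 9, joined through one unnamed intermediate hybrid so every node
#' keeps at most two parents) and seven elite lines derived from Ekangmian 9.
#' Shipped as a TSV fixture under `extdata`.
#'
#' @return a `pedigree` object.
#' @export
example_pedigree <- function() {
  read_pedigree(system.file("extdata", "pedigree_ekangmian9.tsv",
                            package = "pedflow", mustWork = TRUE))
}
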
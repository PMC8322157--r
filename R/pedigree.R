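# Selfing pedigrees: construction, validation, divergence times.

#' Construct a pedigree object
#'
#' A pedigree is a rooted tree of selfing generations: a single founder, one
#' parent per non-founder, one selfing generation per edge. Sequenced plants
#' are flagged; by the single-seed-descent design they are typically sibling
#' leaves of the propagation chain (one sib is sequenced, the other
#' propagates the line).
#'
#' @param nodes data.frame with columns `id`, `parent` (`NA` for the
#'   founder), `generation` (founder 0), `sequenced` (logical).
#' @return Validated data.table of class `pedigree`.
#' @export
pedigree <- function(nodes) {
  nodes <- data.table::as.data.table(nodes)
  req <- c("id", "parent", "generation", "sequenced")
  if (!all(req %in% names(nodes))) stop("pedigree needs columns: ",
                                        paste(req, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  founder <- nodes$id[is.na(nodes$parent)]
  if (length(founder) != 1L) stop("pedigree must have exactly one founder")
  bad <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$id)
  if (length(bad)) stop("parent ids not in pedigree: ", paste(bad, collapse = ", "))
  gen <- stats::setNames(nodes$generation, nodes$id)
  kids <- nodes[!is.na(parent)]
  if (any(gen[kids$id] != gen[kids$parent] + 1L))
    stop("generation(child) must equal generation(parent) + 1")
  # acyclicity: walking up from every node must reach the founder
  for (id in nodes$id) {
    seen <- character()
    cur <- id
    while (!is.na(p <- nodes$parent[match(cur, nodes$id)])) {
      if (p %in% seen) stop("cycle detected in pedigree at node ", p)
      seen <- c(seen, cur)
      cur <- p
    }
  }
  data.table::setattr(nodes, "class", c("pedigree", class(nodes)))
  nodes[]
}

.ancestor_path <- function(ped, id) {
  # node itself first, founder last
  path <- character()
  cur <- id
  repeat {
    path <- c(path, cur)
    p <- ped$parent[match(cur, ped$id)]
    if (is.na(p)) break
    cur <- p
  }
  path
}

#' Divergence time between two sequenced plants
#'
#' The number of independent selfing generations separating `i` and `j`
#' through their most recent common ancestor:
#' `delta_t = dist(i, MRCA) + dist(j, MRCA)`.
#'
#' @param ped A [pedigree()].
#' @param i,j Node ids.
#' @return List with `t_i`, `t_j` (edges from each node up to the MRCA),
#'   `delta_t = t_i + t_j`, and `mrca`.
#' @export
delta_t <- function(ped, i, j) {
  if (!all(c(i, j) %in% ped$id))
    stop("node not in pedigree: ", paste(setdiff(c(i, j), ped$id), collapse = ", "))
  if (identical(i, j)) stop("i and j must differ")
  pi_ <- .ancestor_path(ped, i)
  pj <- .ancestor_path(ped, j)
  mrca <- pi_[match(TRUE, pi_ %in% pj)]
  t_i <- match(mrca, pi_) - 1L
  t_j <- match(mrca, pj) - 1L
  list(t_i = t_i, t_j = t_j, delta_t = t_i + t_j, mrca = mrca)
}

#' Sequenced node ids of a pedigree
#' @param ped A [pedigree()].
#' @return Character vector.
#' @export
sequenced_samples <- function(ped) ped$id[ped$sequenced]
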
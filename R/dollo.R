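# Dollo parsimony reconstruction of intron gain/loss events on a rooted
# species tree.
#
# Under the Dollo criterion each derived state (an intron position
# character) arises exactly once; any number of subsequent losses is
# allowed.  For a character with possessor set S the minimal reconstruction
# places the gain on the branch above MRCA(S), sets state 1 on every node of
# the subtree of MRCA(S) that still has a possessor below it, and charges
# one loss per maximal possessor-free subtree hanging off that spanning
# structure.  This is provably the minimum number of events given a single
# origin, which the package's oracle tests verify by exhaustive enumeration
# on small trees.

#' Read and prepare a rooted species tree
#'
#' Parses Newick (from a file or a literal string), checks rootedness and
#' label uniqueness, and deterministically labels unnamed internal nodes by
#' the sorted tuple of their descendant leaf names so that event reports
#' are stable across runs.  Named internal nodes keep their names.
#'
#' @param x Path to a Newick file, or a Newick string, or an `ape` `phylo`
#'   object.
#' @return A rooted `phylo` object with complete, unique node labels, of
#'   class `c("species_tree", "phylo")`.
#' @export
read_species_tree <- function(x) {
  tr <- if (inherits(x, "phylo")) x
        else if (length(x) == 1L && grepl("(", x, fixed = TRUE))
          ape::read.tree(text = x)
        else ape::read.tree(x)
  if (is.null(tr)) stop("could not parse Newick input")
  if (!ape::is.rooted(tr)) stop("species tree must be rooted")
  if (ape::Ntip(tr) < 2L) stop("species tree must have at least 2 leaves")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  nnode <- tr$Nnode
  lab <- tr$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  need <- which(is.na(lab) | lab == "")
  if (length(need)) {
    for (i in need) {
      node <- ape::Ntip(tr) + i
      tips <- tr$tip.label[descendant_tips(tr, node)]
      lab[i] <- paste(sort(tips), collapse = "+")
    }
  }
  if (anyDuplicated(c(tr$tip.label, lab)))
    stop("duplicate node labels in tree")
  tr$node.label <- lab
  class(tr) <- c("species_tree", "phylo")
  tr
}

## indices of tip nodes below (or equal to) `node`
descendant_tips <- function(tr, node) {
  ntip <- ape::Ntip(tr)
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1L] == node, 2L]
  unlist(lapply(kids, descendant_tips, tr = tr))
}

node_id <- function(tr, label) {
  all_lab <- c(tr$tip.label, tr$node.label)
  id <- match(label, all_lab)
  if (anyNA(id))
    stop(sprintf("node label(s) not in tree: %s",
                 paste(label[is.na(id)], collapse = ", ")))
  id
}

node_label <- function(tr, id) c(tr$tip.label, tr$node.label)[id]

## parent vector: parent_of[child] = parent node id (0 for root)
parent_vector <- function(tr) {
  n <- ape::Ntip(tr) + tr$Nnode
  p <- integer(n)
  p[tr$edge[, 2L]] <- tr$edge[, 1L]
  p
}

is_ancestor <- function(tr, ancestor, descendant) {
  p <- parent_vector(tr)
  node <- descendant
  while (node != 0L) {
    if (node == ancestor) return(TRUE)
    node <- p[node]
  }
  FALSE
}

#' Dollo parsimony reconstruction of intron gains and losses
#'
#' Fits the minimal single-origin scenario for every character of a binary
#' presence/absence matrix on a rooted species tree: one gain per character
#' (on the branch above the most recent common ancestor of its possessors;
#' on the root itself when all leaves possess it, reported as child = root)
#' and the minimum number of losses.  Singleton characters are assigned a
#' gain on their terminal branch and flagged as weak evidence.
#' Multifurcations are allowed; each possessor-free child subtree of a
#' state-1 node counts as one loss.
#'
#' @param tree A rooted tree accepted by [read_species_tree()].
#' @param matrix Binary matrix from [build_presence_matrix()] (rows = taxa
#'   exactly matching the tree's leaves, columns = characters, every
#'   character with at least one possessor).
#' @return An object of class `"dollo"` with components:
#'   \describe{
#'     \item{tree}{the labelled `species_tree`}
#'     \item{states}{binary matrix, (tips + internal nodes) x characters,
#'       rows named by node label}
#'     \item{events}{data frame `child`, `character`, `type`
#'       (`"gain"`/`"loss"`): each event lives on the branch above `child`}
#'     \item{gain_node}{named character vector: gain branch (child label)
#'       per character}
#'     \item{n_losses}{named integer vector per character}
#'     \item{singletons}{character ids possessed by a single taxon}
#'   }
#' @examples
#' tr <- read_species_tree("((A,B),(C,D));")
#' m <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), "x"))
#' fit <- dollo_reconstruct(tr, m)
#' fit$n_losses  # x: 0
#' @export
dollo_reconstruct <- function(tree, matrix) {
  tr <- read_species_tree(tree)
  ntip <- ape::Ntip(tr)
  if (!setequal(rownames(matrix), tr$tip.label) ||
      nrow(matrix) != ntip)
    stop("matrix taxa must exactly cover the tree's leaves")
  if (length(matrix) && !all(matrix %in% c(0L, 1L)))
    stop("presence matrix must be binary")
  if (ncol(matrix) && any(colSums(matrix) == 0L))
    stop(sprintf("character(s) with no possessor: %s",
                 paste(colnames(matrix)[colSums(matrix) == 0L],
                       collapse = ", ")))
  m <- matrix[tr$tip.label, , drop = FALSE]
  nnode <- ntip + tr$Nnode
  chars <- colnames(m)
  states <- matrix(0L, nrow = nnode, ncol = ncol(m),
                   dimnames = list(node_label(tr, seq_len(nnode)), chars))
  events <- list()
  gain_node <- character(ncol(m))
  n_losses <- integer(ncol(m))
  ## postorder edge traversal for possessor counts below each node
  post <- ape::reorder.phylo(tr, "postorder")$edge
  for (j in seq_len(ncol(m))) {
    poss <- integer(nnode)
    poss[seq_len(ntip)] <- m[, j]
    for (e in seq_len(nrow(post)))
      poss[post[e, 1L]] <- poss[post[e, 1L]] + poss[post[e, 2L]]
    tips_j <- which(m[, j] == 1L)
    mrca <- if (length(tips_j) == 1L) tips_j else ape::getMRCA(tr, tips_j)
    ## state 1 on nodes under (and incl.) the MRCA that retain a possessor
    st <- integer(nnode)
    below <- c(mrca, if (mrca > ntip) unlist(descendants_all(tr, mrca)))
    st[below[poss[below] > 0L]] <- 1L
    states[, j] <- st
    gain_node[j] <- node_label(tr, mrca)
    events[[length(events) + 1L]] <-
      data.frame(child = gain_node[j], character = chars[j], type = "gain",
                 stringsAsFactors = FALSE)
    ## losses: state-0 children of state-1 parents
    loss_children <- tr$edge[st[tr$edge[, 1L]] == 1L &
                             st[tr$edge[, 2L]] == 0L, 2L]
    n_losses[j] <- length(loss_children)
    if (length(loss_children))
      events[[length(events) + 1L]] <-
        data.frame(child = node_label(tr, loss_children),
                   character = chars[j], type = "loss",
                   stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(child = character(), character = character(),
               type = character())
  structure(list(tree = tr, states = states, events = events,
                 gain_node = stats::setNames(gain_node, chars),
                 n_losses = stats::setNames(n_losses, chars),
                 singletons = chars[colSums(m) == 1L]),
            class = "dollo")
}

## all node ids strictly below `node`
descendants_all <- function(tr, node) {
  kids <- tr$edge[tr$edge[, 1L] == node, 2L]
  c(kids, unlist(lapply(kids, function(k)
    if (k > ape::Ntip(tr)) descendants_all(tr, k) else NULL)))
}

#' @export
print.dollo <- function(x, ...) {
  cat(sprintf("Dollo reconstruction: %d character(s) on %d leaves\n",
              ncol(x$states), ape::Ntip(x$tree)))
  cat(sprintf("  gains: %d, losses: %d (total events %d)\n",
              ncol(x$states), sum(x$n_losses),
              ncol(x$states) + sum(x$n_losses)))
  if (length(x$singletons))
    cat(sprintf("  singleton character(s), weak evidence: %s\n",
                paste(x$singletons, collapse = ", ")))
  invisible(x)
}

#' @export
summary.dollo <- function(object, ...) {
  d <- data.frame(character = colnames(object$states),
                  gain_branch = unname(object$gain_node),
                  losses = unname(object$n_losses),
                  possessors = colSums(object$states[seq_len(
                    ape::Ntip(object$tree)), , drop = FALSE]),
                  row.names = NULL)
  class(d) <- c("summary.dollo", "data.frame")
  d
}

#' Total number of events in a Dollo reconstruction
#'
#' @param fit A `"dollo"` object.
#' @return Integer: one gain per character plus all losses.
#' @export
total_events <- function(fit) {
  stopifnot(inherits(fit, "dollo"))
  as.integer(ncol(fit$states) + sum(fit$n_losses))
}

#' Count intron gains between two nodes
#'
#' Number of characters absent at `ancestor` and present at `descendant` in
#' the reconstructed ancestral states — the introns gained along that path.
#'
#' @param fit A `"dollo"` object.
#' @param ancestor,descendant Node labels (leaf names or internal labels);
#'   `ancestor` must be an ancestor of (or equal to) `descendant`.
#' @return Integer count.
#' @export
gains_between <- function(fit, ancestor, descendant) {
  stopifnot(inherits(fit, "dollo"))
  tr <- fit$tree
  a <- node_id(tr, ancestor); d <- node_id(tr, descendant)
  if (!is_ancestor(tr, a, d))
    stop(sprintf("'%s' is not an ancestor of '%s'", ancestor, descendant))
  sum(fit$states[node_label(tr, a), ] == 0L &
      fit$states[node_label(tr, d), ] == 1L)
}

#' Reconstructed exon count at a node
#'
#' The number of coding exons implied by the ancestral states: introns
#' present at the node (optionally restricted to one gene family's
#' characters) plus one.
#'
#' @param fit A `"dollo"` object.
#' @param node Node label.
#' @param characters Optional character ids to count (e.g. one family's);
#'   defaults to all.
#' @return Integer exon count.
#' @export
exon_count_at <- function(fit, node, characters = NULL) {
  stopifnot(inherits(fit, "dollo"))
  st <- fit$states[node_label(fit$tree, node_id(fit$tree, node)), ]
  if (!is.null(characters)) {
    miss <- setdiff(characters, names(st))
    if (length(miss))
      stop(sprintf("unknown character(s): %s", paste(miss, collapse = ", ")))
    st <- st[characters]
  }
  as.integer(sum(st) + 1L)
}

#' Compare Dollo event totals across alternative topologies
#'
#' Reconstructs the same character matrix on two or more candidate species
#' trees and reports total events (one gain per character plus losses) per
#' topology, identifying the most parsimonious one.  Used to contrast
#' alternative phylogenetic hypotheses (e.g. alternative placements of
#' Galaxiiformes within Euteleostei).
#'
#' @param trees Named list of trees accepted by [read_species_tree()], all
#'   sharing the matrix's leaf set.
#' @param matrix Binary presence/absence matrix.
#' @return List of class `"dollo_comparison"`: `$totals` (data frame
#'   `topology`, `gains`, `losses`, `total`), `$best` (name of the
#'   minimal-event topology), `$fits` (the per-topology `"dollo"` objects).
#' @export
compare_topologies <- function(trees, matrix) {
  if (length(trees) < 2L) stop("need at least two topologies")
  if (is.null(names(trees)) || any(names(trees) == ""))
    names(trees) <- paste0("topology", seq_along(trees))
  fits <- lapply(trees, function(tr) dollo_reconstruct(tr, matrix))
  totals <- data.frame(
    topology = names(trees),
    gains = vapply(fits, function(f) ncol(f$states), 0L),
    losses = vapply(fits, function(f) as.integer(sum(f$n_losses)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  totals$total <- totals$gains + totals$losses
  structure(list(totals = totals,
                 best = totals$topology[which.min(totals$total)],
                 fits = fits),
            class = "dollo_comparison")
}

#' @export
print.dollo_comparison <- function(x, ...) {
  print(x$totals, row.names = FALSE)
  cat(sprintf("most parsimonious topology: %s\n", x$best))
  invisible(x)
}

#' Write Dollo events and ancestral states
#'
#' @param fit A `"dollo"` object.
#' @param events_path,states_path Optional TSV paths.
#' @param json_path Optional JSON path for the event map.
#' @export
write_dollo_report <- function(fit, events_path = NULL, states_path = NULL,
                               json_path = NULL) {
  stopifnot(inherits(fit, "dollo"))
  if (!is.null(events_path))
    utils::write.table(fit$events, events_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(states_path)) {
    d <- data.frame(node = rownames(fit$states), fit$states,
                    check.names = FALSE)
    utils::write.table(d, states_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(
      list(gain_node = as.list(fit$gain_node),
           n_losses = as.list(fit$n_losses),
           events = fit$events),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}
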
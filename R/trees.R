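#' Read a rooted tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces unique tip labels.
#' Branch lengths are optional at read time; operations that need them
#' (UniFrac, patristic distances, Faith's PD) reject trees without lengths.
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Optional Newick string (used instead of `path`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
                        call. = FALSE)
  tree
}

#' Write a tree to a Newick file
#' @param tree An [ape::phylo] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Build a tip-name map
#'
#' Maps tree tip labels to study taxon labels, e.g. when a study taxon is
#' represented in the reference phylogeny by its closest available
#' relative. The map must be injective on the tips it is applied to.
#'
#' @param from Character vector of tree tip labels.
#' @param to Character vector of study taxon labels (same length).
#' @return A named character vector (`from -> to`) of class `tip_name_map`.
#' @export
tip_name_map <- function(from, to) {
  stopifnot(is.character(from), is.character(to), length(from) == length(to))
  if (anyDuplicated(from)) stop("map source labels must be unique", call. = FALSE)
  if (anyDuplicated(to)) stop("map target labels must be unique (injective map)",
                              call. = FALSE)
  structure(stats::setNames(to, from), class = "tip_name_map")
}

#' Prune a tree to a taxon set, optionally renaming tips
#'
#' Tips named in `map` are first renamed (tree label to study label), then
#' the tree is pruned to exactly the taxa in `keep`. Path lengths between
#' retained tips are unchanged by pruning.
#'
#' @param tree An [ape::phylo] tree.
#' @param keep Character vector of taxa to retain (post-renaming labels).
#' @param map Optional [tip_name_map()].
#' @return The pruned, renamed [ape::phylo] tree.
#' @export
prune_and_rename <- function(tree, keep, map = NULL) {
  if (!is.null(map)) {
    idx <- match(names(map), tree$tip.label)
    hit <- !is.na(idx)
    tree$tip.label[idx[hit]] <- unname(map[hit])
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    if (length(dup)) stop("renaming produced duplicate tip(s): ",
                          paste(dup, collapse = ", "), call. = FALSE)
  }
  missing_taxa <- setdiff(keep, tree$tip.label)
  if (length(missing_taxa)) {
    stop("taxa not present in tree: ", paste(missing_taxa, collapse = ", "),
         call. = FALSE)
  }
  ape::keep.tip(tree, keep)
}

#' Patristic distances between tree tips
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A [distance_matrix()] over the tip labels.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; patristic distances undefined", call. = FALSE)
  }
  distance_matrix(ape::cophenetic.phylo(tree))
}
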
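# Phylogeny handling.  Trees are ape "phylo" objects wrapped together with
# a per-edge foreground/background tag vector (the branch-model dialect
# marks foreground branches with "#1" labels, following the convention of
# the codeml tool family).  Likelihoods are invariant to root placement
# for these reversible models, so unrooted (basal multifurcation) inputs
# are used as parsed.

#' Read a Newick tree with optional foreground branch tags
#'
#' Parses a Newick string or file via \pkg{ape} and extracts `#1`-style
#' branch tags: a tip labelled `name#1` or an internal node labelled `#1`
#' marks the branch leading to it as foreground.  Alternatively a list of
#' clades (leaf sets) can be supplied, whose stem branches are tagged.
#'
#' @param input Newick text (contains `(` or `;`) or a file path.
#' @param tag_dialect `"hash"` to parse `#1` labels (default), `"none"`
#'   to ignore them.
#' @param clades optional list of character vectors of leaf labels; the
#'   stem branch of each clade's MRCA is tagged foreground (applied after
#'   any hash tags).
#' @param default_length branch length used, with a warning, for branches
#'   whose length is absent (default 0.1).
#' @return A `tagged_phylo`: list with `tree` (ape `phylo`, tag markers
#'   stripped from labels) and `fore` (logical per edge, in
#'   `tree$edge` row order).
#' @examples
#' tr <- read_newick("((A:0.1,B:0.1)#1:0.05,C:0.2);")
#' sum(tr$fore)  # 1
#' @export
read_newick <- function(input, tag_dialect = c("hash", "none"),
                        clades = NULL, default_length = 0.1) {
  tag_dialect <- match.arg(tag_dialect)
  if (length(input) == 1L && !grepl("[(;]", input)) {
    if (!file.exists(input)) stop("tree file not found: ", input)
    input <- paste(readLines(input, warn = FALSE), collapse = "")
  } else {
    input <- paste(input, collapse = "")
  }
  check_newick_syntax(input)
  tree <- tryCatch(ape::read.tree(text = input),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(sub("#\\d+$", "", tree$tip.label))) {
    stop("duplicate leaf labels in tree")
  }
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to ",
            default_length)
    tree$edge.length <- rep(default_length, n_edge)
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch length(s) defaulted to ", default_length)
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  fore <- rep(FALSE, n_edge)
  if (tag_dialect == "hash") {
    n_tip <- length(tree$tip.label)
    tip_tag <- grepl("#\\d+$", tree$tip.label)
    tree$tip.label <- sub("#\\d+$", "", tree$tip.label)
    node_tag <- rep(FALSE, tree$Nnode)
    if (!is.null(tree$node.label)) {
      node_tag <- grepl("^#\\d+$", tree$node.label)
      tree$node.label <- sub("#\\d+$", "", tree$node.label)
    }
    tagged_nodes <- c(which(tip_tag), n_tip + which(node_tag))
    fore <- tree$edge[, 2] %in% tagged_nodes
  }
  out <- structure(list(tree = tree, fore = fore), class = "tagged_phylo")
  if (!is.null(clades)) {
    for (cl in clades) out <- tag_foreground(out, cl)
  }
  out
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  }
  if (!grepl(";", text)) {
    stop("Newick parse error: missing terminating ';'")
  }
  invisible(TRUE)
}

#' Tag the stem branch of a clade as foreground
#'
#' @param x a `tagged_phylo` or ape `phylo`.
#' @param leaves character vector of leaf labels; their MRCA's stem
#'   branch is tagged (a single leaf tags its terminal branch).
#' @return the updated `tagged_phylo`.
#' @export
tag_foreground <- function(x, leaves) {
  x <- as_tagged_phylo(x)
  tree <- x$tree
  miss <- setdiff(leaves, tree$tip.label)
  if (length(miss)) {
    stop("clade leaves not in tree: ", paste(miss, collapse = ", "))
  }
  node <- if (length(leaves) == 1L) {
    match(leaves, tree$tip.label)
  } else {
    ape::getMRCA(tree, leaves)
  }
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) == 0L) {
    stop("clade spans the root; its stem branch does not exist")
  }
  x$fore[edge] <- TRUE
  x
}

#' Coerce to a tagged phylogeny
#'
#' @param x a `tagged_phylo` (returned unchanged) or ape `phylo`
#'   (all branches tagged background).
#' @return a `tagged_phylo`.
#' @export
as_tagged_phylo <- function(x) {
  if (inherits(x, "tagged_phylo")) return(x)
  if (!inherits(x, "phylo")) stop("expected a phylo or tagged_phylo")
  structure(list(tree = x, fore = rep(FALSE, nrow(x$edge))),
            class = "tagged_phylo")
}

#' @export
print.tagged_phylo <- function(x, ...) {
  cat("<tagged_phylo> ", length(x$tree$tip.label), " leaves, ",
      nrow(x$tree$edge), " branches (", sum(x$fore),
      " foreground)\n", sep = "")
  invisible(x)
}

# internal: postorder traversal bundle used by the pruning engine.
# Returns edges in postorder together with the matching fore tags.
traversal <- function(tp) {
  tp <- as_tagged_phylo(tp)
  tree <- tp$tree
  ord <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  list(edge = tree$edge[ord, , drop = FALSE],
       length = tree$edge.length[ord],
       fore = tp$fore[ord],
       n_tip = length(tree$tip.label),
       n_node = tree$Nnode,
       root = length(tree$tip.label) + 1L,
       tip_label = tree$tip.label)
}

# internal: rescale all branch lengths by a factor
scale_branches <- function(tp, factor) {
  tp <- as_tagged_phylo(tp)
  tp$tree$edge.length <- tp$tree$edge.length * factor
  tp
}
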
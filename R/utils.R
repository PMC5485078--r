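# Shared internal helpers: seeded evaluation, tree bookkeeping, and the
# pruning engine used by both the contrasts and the BM likelihood code paths.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user scripts.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

check_phylo <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape 'phylo' object.")
  }
  if (require_lengths) {
    if (is.null(tree$edge.length)) {
      abort("`tree` must have branch lengths (durations in Myr).")
    }
    if (any(tree$edge.length <= 0)) {
      abort("All branch durations must be positive.")
    }
  }
  invisible(tree)
}

is_binary_tree <- function(tree) {
  ape::Ntip(tree) >= 2 && tree$Nnode == ape::Ntip(tree) - 1L
}

check_binary <- function(tree) {
  if (!is_binary_tree(tree)) {
    abort("Tree must be strictly binary (resolve polytomies upstream).")
  }
  invisible(tree)
}

# Age of the root in Ma before present. Uses tree$root.time when set
# (paleo convention), otherwise assumes the youngest tip is extant (age 0).
root_time <- function(tree) {
  if (!is.null(tree$root.time)) {
    return(tree$root.time)
  }
  max(ape::node.depth.edgelength(tree))
}

#' Node and tip ages of a time-scaled tree
#'
#' Ages are in Ma before present, derived from `tree$root.time` when present
#' (the usual convention for non-ultrametric fossil trees) and otherwise from
#' the assumption that the youngest tip is extant.
#'
#' @param tree a time-scaled `phylo` tree (branch lengths in Myr).
#' @return A tibble with one row per node: `node` (ape node number), `label`
#'   (tip label or `NA`), `age` (Ma), and `is_tip`.
#' @export
node_ages <- function(tree) {
  check_phylo(tree)
  depth <- ape::node.depth.edgelength(tree)
  age <- root_time(tree) - depth
  ntip <- ape::Ntip(tree)
  tibble(
    node = seq_along(age),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    age = age,
    is_tip = seq_along(age) <= ntip
  )
}

#' Find the most recent common ancestor node of a set of tips
#'
#' @param tree a `phylo` tree.
#' @param tips character vector of two or more tip labels.
#' @return The ape node number of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Tips not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(tips) < 2) {
    abort("Need at least two tip labels to define a clade.")
  }
  ape::getMRCA(tree, tips)
}

# All descendant nodes (internal and tips) of `node`, excluding `node`.
descendant_nodes <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) {
    return(integer(0))
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- kids
  for (k in kids) out <- c(out, descendant_nodes(tree, k))
  out
}

# Logical vector over edges: TRUE if the edge belongs to the clade rooted at
# `node`. With include_stem the edge subtending `node` is counted in.
clade_edge_flags <- function(tree, node, include_stem = TRUE) {
  inside <- c(node, descendant_nodes(tree, node))
  flags <- tree$edge[, 2] %in% setdiff(inside, node)
  if (include_stem) {
    flags <- flags | tree$edge[, 2] == node
  }
  flags
}

#' Branch partition by clade membership
#'
#' Labels every branch of the tree by whether it lies inside the clade
#' defined by the MRCA of `tips`. Following common practice the clade's stem
#' branch is included by default.
#'
#' @param tree a `phylo` tree.
#' @param tips tip labels whose MRCA defines the clade, or a single node id.
#' @param include_stem include the clade's stem branch? Default `TRUE`.
#' @return A tibble with columns `edge` (row index into `tree$edge`), `child`
#'   (child node), and `in_clade` (logical).
#' @export
clade_partition <- function(tree, tips, include_stem = TRUE) {
  node <- if (is.character(tips)) mrca_node(tree, tips) else as.integer(tips)
  flags <- clade_edge_flags(tree, node, include_stem = include_stem)
  tibble(
    edge = seq_len(nrow(tree$edge)),
    child = tree$edge[, 2],
    in_clade = flags
  )
}

# Postorder edge ordering in which the two child edges of each internal node
# are adjacent; the pair layout is asserted, not assumed.
postorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  e <- po$edge
  if (nrow(e) %% 2L != 0L) {
    abort("Internal error: odd edge count on a binary tree.")
  }
  odd <- seq(1L, nrow(e), by = 2L)
  if (!all(e[odd, 1] == e[odd + 1L, 1])) {
    abort("Internal error: postorder edges not paired by parent.")
  }
  list(edge = e, length = po$edge.length)
}

# Map a named trait vector (or 2-column data frame) onto tree tip order.
tip_values <- function(tree, x) {
  if (is.data.frame(x)) {
    if (!all(c("taxon_id") %in% names(x)) || ncol(x) < 2) {
      abort("Trait data frame needs a `taxon_id` column plus one value column.")
    }
    val_col <- setdiff(names(x), "taxon_id")[1]
    x <- setNames(x[[val_col]], x$taxon_id)
  }
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree)) {
      abort("Unnamed trait vector must match the number of tips.")
    }
    return(as.numeric(x))
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss) > 0) {
    abort(paste0("No trait value for tips: ", paste(head(miss, 5), collapse = ", ")))
  }
  as.numeric(x[tree$tip.label])
}

# Prune the tree to tips with non-missing trait values; returns the pruned
# tree and the aligned value vector. Per-trait pruning keeps every trait's
# analysis on the largest usable taxon set.
prune_to_trait <- function(tree, data, trait) {
  if (anyDuplicated(data$taxon_id)) {
    abort("`data` must contain one row per taxon (a single replicate).")
  }
  vals <- data[[trait]]
  names(vals) <- data$taxon_id
  vals <- vals[names(vals) %in% tree$tip.label]
  keep <- names(vals)[!is.na(vals)]
  if (length(keep) < 2) {
    abort(paste0("Fewer than two tips have data for `", trait, "`."))
  }
  drop <- setdiff(tree$tip.label, keep)
  if (length(drop) > 0) {
    ages <- node_ages(tree)
    pruned <- ape::drop.tip(tree, drop)
    # restore the root age: any retained tip anchors the depth-to-age map
    anchor <- pruned$tip.label[1]
    tip_age <- ages$age[match(anchor, ages$label)]
    depth <- ape::node.depth.edgelength(pruned)[match(anchor, pruned$tip.label)]
    pruned$root.time <- tip_age + depth
  } else {
    pruned <- tree
  }
  list(tree = pruned, values = vals[pruned$tip.label])
}

# Felsenstein pruning pass. Returns contrasts, their expected SDs, ancestral
# (weighted-mean) node estimates and the per-node adjusted branch extension.
pic_engine <- function(tree, x) {
  check_phylo(tree)
  check_binary(tree)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  po <- postorder_edges(tree)
  e <- po$edge
  el <- po$length
  xv <- c(as.numeric(x), rep(NA_real_, nnode))
  vv <- numeric(ntip + nnode)
  node_id <- integer(nnode)
  contrast <- sdev <- anc <- numeric(nnode)
  j <- 0L
  for (i in seq(1L, nrow(e), by = 2L)) {
    p <- e[i, 1]
    c1 <- e[i, 2]
    c2 <- e[i + 1L, 2]
    v1 <- el[i] + vv[c1]
    v2 <- el[i + 1L] + vv[c2]
    j <- j + 1L
    node_id[j] <- p
    contrast[j] <- xv[c1] - xv[c2]
    sdev[j] <- sqrt(v1 + v2)
    anc[j] <- (xv[c1] * v2 + xv[c2] * v1) / (v1 + v2)
    xv[p] <- anc[j]
    vv[p] <- v1 * v2 / (v1 + v2)
  }
  ord <- order(node_id)
  list(
    node = node_id[ord],
    contrast = contrast[ord],
    sd = sdev[ord],
    node_estimate = anc[ord]
  )
}
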
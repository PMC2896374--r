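# Tree handling: Newick/Nexus I/O, rooting, pruning, phylogenetic
# covariance, and majority-rule consensus over tree samples.
#
# Trees are represented as ape "phylo" objects throughout; a sample of
# trees is an ape "multiPhylo" (or plain list of "phylo").

#' Validate a phylogenetic tree
#'
#' Checks the structural invariants required by the rest of the package:
#' a single root, unique non-empty leaf labels, and non-negative branch
#' lengths (when present). Polytomies are allowed.
#'
#' @param tree An object of class \code{phylo}.
#' @param require_lengths If \code{TRUE}, branch lengths must be present
#'   and complete.
#' @return The tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree <- function(tree, require_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree object", call. = FALSE)
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    stop("duplicate leaf label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(labs))) stop("empty leaf label", call. = FALSE)
  ntip <- length(labs)
  # exactly one root: one node id never appearing as a child
  internal <- (ntip + 1):(ntip + tree$Nnode)
  roots <- setdiff(internal, tree$edge[, 2])
  if (length(roots) != 1L) stop("tree must have exactly one root", call. = FALSE)
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length)) {
      if (require_lengths) stop("tree has missing branch lengths", call. = FALSE)
    } else if (any(tree$edge.length < 0)) {
      stop("negative branch length", call. = FALSE)
    }
  } else if (require_lengths) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  invisible(tree)
}

# root node id of a phylo
root_node <- function(tree) length(tree$tip.label) + 1L

# list of child node ids per node (index = node id)
child_map <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

# protect single-quoted Newick labels (with '' escapes) so that the
# parser below can treat the remaining text as plain Newick
shield_quotes <- function(text) {
  out <- character(0)
  repl <- character(0)
  i <- 1L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  buf <- character(0)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "'") {
      j <- i + 1L
      lab <- character(0)
      while (j <= n) {
        if (chars[j] == "'") {
          if (j < n && chars[j + 1L] == "'") { # escaped quote
            lab <- c(lab, "'"); j <- j + 2L
          } else { j <- j + 1L; break }
        } else { lab <- c(lab, chars[j]); j <- j + 1L }
      }
      key <- sprintf("QLBL%04dX", length(repl) + 1L)
      repl <- c(repl, paste(lab, collapse = ""))
      names(repl)[length(repl)] <- key
      buf <- c(buf, key)
      i <- j
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  list(text = paste(buf, collapse = ""), labels = repl)
}

#' Parse a Newick string into a tree
#'
#' Accepts the common Newick dialect: optional branch lengths (missing
#' lengths stay absent, they are never silently set to zero), scientific
#' notation, single-quoted labels, internal node labels, and a tolerated
#' missing trailing semicolon. Malformed parentheses are reported with
#' the character offset of the first imbalance.
#'
#' @param text A single Newick string.
#' @return A \code{phylo} tree.
#' @seealso [write_newick()], [read_trees()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string", call. = FALSE)
  sh <- shield_quotes(text)
  plain <- sh$text
  # balance check with offset (on the quote-shielded text)
  depth <- 0L
  chars <- strsplit(plain, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error: unmatched ')' at character %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("Newick parse error: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  }
  if (!endsWith(plain, ";")) plain <- paste0(plain, ";")
  tr <- tryCatch(ape::read.tree(text = plain),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("Newick parse error: malformed tree string", call. = FALSE)
  if (length(sh$labels)) {
    restore <- function(x) {
      for (k in names(sh$labels)) x[x == k] <- sh$labels[[k]]
      x
    }
    tr$tip.label <- restore(tr$tip.label)
    if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  }
  validate_tree(tr)
  tr
}

needs_quote <- function(lab) grepl("[][(),:;'\" \t]", lab)

quote_label <- function(lab) {
  ifelse(needs_quote(lab),
         paste0("'", gsub("'", "''", lab, fixed = TRUE), "'"),
         lab)
}

fmt_num <- function(x, digits = 12) {
  s <- formatC(x, digits = digits, format = "g", width = -1)
  trimws(s)
}

#' Write a tree as a canonical Newick string
#'
#' The output is deterministic: at every internal node the children are
#' ordered by their lexicographically smallest descendant leaf label, so
#' two topologically identical trees always serialize identically.
#' Internal node labels (e.g. consensus supports) are emitted when
#' present; labels needing it are single-quoted.
#'
#' @param tree A \code{phylo} tree.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string with trailing semicolon.
#' @export
write_newick <- function(tree, digits = 12) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  kids <- child_map(tree)
  has_len <- !is.null(tree$edge.length)
  len_of <- rep(NA_real_, ntip + tree$Nnode)
  if (has_len) len_of[tree$edge[, 2]] <- tree$edge.length
  nlab <- tree$node.label
  rec <- function(node) {
    if (node <= ntip) {
      lab <- quote_label(tree$tip.label[node])
      str <- lab
      key <- tree$tip.label[node]
    } else {
      parts <- lapply(kids[[node]], rec)
      ord <- order(vapply(parts, `[[`, "", "key"))
      parts <- parts[ord]
      ilab <- ""
      if (!is.null(nlab)) {
        l <- nlab[node - ntip]
        if (!is.na(l) && nzchar(l)) ilab <- quote_label(l)
      }
      str <- paste0("(", paste(vapply(parts, `[[`, "", "str"), collapse = ","),
                    ")", ilab)
      key <- parts[[1]]$key
    }
    if (has_len && !is.na(len_of[node])) {
      str <- paste0(str, ":", fmt_num(len_of[node], digits))
    }
    list(str = str, key = key)
  }
  paste0(rec(root_node(tree))$str, ";")
}

#' Read one or more trees from a Newick or Nexus file
#'
#' Newick files hold one tree per line. Nexus input is detected by the
#' \code{#NEXUS} header; only the \code{trees} block (with its optional
#' \code{translate} table) is used, all other blocks are ignored.
#'
#' @param path Path to the tree file.
#' @return A \code{multiPhylo} list of trees (length 1 for a single tree).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
    trees <- ape::read.nexus(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    trees <- lapply(lines, parse_newick)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  trees
}

#' Root a tree on an outgroup taxon
#'
#' Returns a tree whose root separates the outgroup leaf from everything
#' else. Already-rooted-on-outgroup trees are returned unchanged.
#'
#' @param tree A \code{phylo} tree.
#' @param outgroup Leaf label to root on.
#' @return A rooted \code{phylo} tree with the outgroup as one child of
#'   the root.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  validate_tree(tree)
  tipid <- match(outgroup, tree$tip.label)
  if (is.na(tipid)) {
    stop("outgroup '", outgroup, "' is not a leaf of the tree", call. = FALSE)
  }
  root_kids <- tree$edge[tree$edge[, 1] == root_node(tree), 2]
  if (ape::is.rooted(tree) && tipid %in% root_kids && length(root_kids) == 2L) {
    return(tree)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Prune a tree down to a set of leaves
#'
#' Removes all leaves not in \code{keep}; internal nodes left with a
#' single child are suppressed and their branch lengths summed, so
#' path lengths among retained leaves are preserved. The stem branch
#' above the retained clade's most recent common ancestor is discarded
#' (the MRCA becomes the new root at depth zero).
#'
#' @param tree A \code{phylo} tree.
#' @param keep Character vector of leaf labels to retain (at least 2).
#' @return The pruned \code{phylo} tree.
#' @export
prune_tree <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("label(s) not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 leaves to keep", call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths from the root down to the
#' most recent common ancestor of leaves i and j; the diagonal holds
#' root-to-tip distances. This is the expected trait covariance under
#' Brownian motion along the tree (up to the rate constant).
#'
#' @param tree A \code{phylo} tree with complete branch lengths.
#' @param label_order Optional character vector giving the row/column
#'   order of the result; defaults to the tree's tip order.
#' @return A symmetric positive semi-definite numeric matrix with
#'   dimnames equal to \code{label_order}.
#' @export
vcv_matrix <- function(tree, label_order = NULL) {
  validate_tree(tree, require_lengths = TRUE)
  V <- ape::vcv(tree)
  if (!is.null(label_order)) {
    miss <- setdiff(label_order, rownames(V))
    if (length(miss)) {
      stop("label(s) not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    V <- V[label_order, label_order, drop = FALSE]
  }
  V
}

#' Discard the burn-in portion of a tree sample
#'
#' Removes the first \code{ceiling(fraction * N)} trees of an ordered
#' sample (e.g. an MCMC chain thinned to sampled topologies), keeping
#' the original order of the rest.
#'
#' @param trees A \code{multiPhylo} or list of \code{phylo} trees.
#' @param fraction Fraction in [0, 1) of the sample to discard.
#' @return The retained trees as \code{multiPhylo}.
#' @export
discard_burnin <- function(trees, fraction) {
  trees <- as_tree_list(trees)
  n <- length(trees)
  if (n == 0L) stop("empty tree sample", call. = FALSE)
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction < 1)
  drop <- ceiling(fraction * n)
  if (drop >= n) stop("burn-in removes the whole sample", call. = FALSE)
  out <- trees[(drop + 1L):n]
  class(out) <- "multiPhylo"
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) return(structure(list(), class = "multiPhylo"))
  trees <- unclass(trees)
  ok <- vapply(trees, inherits, logical(1), what = "phylo")
  if (!all(ok)) stop("tree sample must contain only 'phylo' objects", call. = FALSE)
  structure(trees, class = "multiPhylo")
}

# sorted tip-label set under every node of a tree (index = node id)
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(eo))) {
    sets[[eo[r, 1]]] <- c(sets[[eo[r, 1]]], sets[[eo[r, 2]]])
  }
  lapply(sets, sort)
}

#' Clades of a rooted tree as canonical label sets
#'
#' Returns the set of non-trivial clades (internal nodes other than the
#' root) of a rooted tree, each encoded as its sorted leaf labels. This
#' is the bipartition representation used by the consensus machinery:
#' on a rooted tree each internal edge splits the leaves into the clade
#' below it and everything else.
#'
#' @param tree A \code{phylo} tree.
#' @return A character vector, one element per non-trivial clade, each
#'   the sorted leaf labels joined by commas.
#' @export
tree_clades <- function(tree) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  sets <- tips_under(tree)
  ids <- setdiff((ntip + 1L):(ntip + tree$Nnode), root_node(tree))
  sort(vapply(sets[ids], paste, "", collapse = ","))
}

#' Majority-rule consensus of a tree sample
#'
#' Builds the rooted majority-rule consensus: the tree containing
#' exactly those clades whose frequency in the sample strictly exceeds
#' \code{threshold} (plain majority rule; compatible minority clades
#' are never greedily added). Each retained internal node carries its
#' sample frequency as a support label, regions without a majority
#' resolution become polytomies, and each retained branch gets the mean
#' length of the corresponding edge over the trees that contain it.
#'
#' @param trees A \code{multiPhylo} or list of rooted \code{phylo}
#'   trees over an identical leaf set.
#' @param threshold Retention threshold in [0.5, 1); a clade is kept
#'   only if its frequency is strictly greater than this.
#' @return A \code{phylo} consensus tree; internal \code{node.label}s
#'   hold supports (frequencies rounded to 3 decimals).
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  trees <- as_tree_list(trees)
  N <- length(trees)
  if (N == 0L) stop("empty tree sample", call. = FALSE)
  stopifnot(threshold >= 0.5, threshold < 1)
  leaves <- sort(trees[[1]]$tip.label)
  ntip <- length(leaves)
  count <- new.env(parent = emptyenv())
  lensum <- new.env(parent = emptyenv())
  lencnt <- new.env(parent = emptyenv())
  bump <- function(env, key, by) {
    assign(key, (if (is.null(env[[key]])) 0 else env[[key]]) + by, envir = env)
  }
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), leaves)) {
      stop("trees in the sample have mismatched leaf sets", call. = FALSE)
    }
    sets <- tips_under(tr)
    nt <- length(tr$tip.label)
    len_of <- rep(NA_real_, nt + tr$Nnode)
    if (!is.null(tr$edge.length)) len_of[tr$edge[, 2]] <- tr$edge.length
    for (node in seq_len(nt + tr$Nnode)) {
      key <- paste(sets[[node]], collapse = "\r")
      bump(count, key, 1)
      if (!is.na(len_of[node])) {
        bump(lensum, key, len_of[node])
        bump(lencnt, key, 1)
      }
    }
  }
  keys <- ls(count)
  sizes <- lengths(strsplit(keys, "\r", fixed = TRUE))
  freq <- vapply(keys, function(k) count[[k]], 0) / N
  keep <- sizes == 1L | sizes == ntip | freq > threshold
  keys <- keys[keep]; sizes <- sizes[keep]; freq <- freq[keep]
  ord <- order(-sizes)
  keys <- keys[ord]; sizes <- sizes[ord]; freq <- freq[ord]
  tipsets <- strsplit(keys, "\r", fixed = TRUE)
  # parent of clade i = the smallest retained clade strictly containing it
  parent <- integer(length(keys))
  for (i in seq_along(keys)) {
    if (sizes[i] == ntip) { parent[i] <- 0L; next }
    cand <- which(sizes > sizes[i])
    cand <- cand[vapply(cand, function(j) all(tipsets[[i]] %in% tipsets[[j]]),
                        logical(1))]
    parent[i] <- cand[which.min(sizes[cand])]
  }
  mean_len <- function(i) {
    k <- keys[i]
    if (is.null(lencnt[[k]]) || lencnt[[k]] == 0) NA_real_
    else lensum[[k]] / lencnt[[k]]
  }
  rec <- function(i) {
    ch <- which(parent == i)
    if (sizes[i] == 1L) {
      str <- quote_label(tipsets[[i]][1])
    } else {
      parts <- sort(vapply(ch, rec, ""))
      str <- paste0("(", paste(parts, collapse = ","), ")")
      if (sizes[i] < ntip) str <- paste0(str, as.character(round(freq[i], 3)))
    }
    ln <- mean_len(i)
    if (sizes[i] < ntip && !is.na(ln)) str <- paste0(str, ":", fmt_num(ln))
    str
  }
  rt <- which(sizes == ntip)[1]
  parse_newick(paste0(rec(rt), ";"))
}

#' Numeric node supports from internal node labels
#'
#' Interprets internal node labels as clade supports: values already in
#' [0, 1] are taken as-is, values in (1, 100] are read as percentages
#' and divided by 100, anything non-numeric becomes \code{NA}.
#'
#' @param tree A \code{phylo} tree.
#' @return Numeric vector of length \code{tree$Nnode} of supports in
#'   [0, 1] (or \code{NA}).
#' @export
node_support <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  x <- suppressWarnings(as.numeric(tree$node.label))
  big <- !is.na(x) & x > 1 & x <= 100
  x[big] <- x[big] / 100
  x[!is.na(x) & (x < 0 | x > 1)] <- NA_real_
  x
}
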
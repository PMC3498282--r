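# Dated-tree plumbing: parsing, validation, pruning, rescaling, branching
# times and lineage-through-time series.  All ages are measured backward from
# the present (tips at age 0), in the time units of the branch lengths
# (millions of years throughout the package examples).

#' Parse a Newick string into a dated tree
#'
#' Thin validating wrapper around [ape::read.tree()].  Accepts unquoted and
#' single-quoted labels; square-bracket comments are stripped; internal node
#' labels are ignored downstream.  Every non-root edge must carry a branch
#' length.  The tree is not required to be ultrametric at this stage --
#' ultrametricity is checked separately by [check_ultrametric()] and enforced
#' by [branching_times()].
#'
#' @param newick_text Length-one character vector holding one Newick tree,
#'   terminated by `;`.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @seealso [check_ultrametric()], [crown_age()], [write_newick()]
#' @export
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' crown_age(tr)  # 2
parse_tree <- function(newick_text) {
  if (!is.character(newick_text) || length(newick_text) != 1L || is.na(newick_text))
    stop("'newick_text' must be a single character string")
  txt <- gsub("\\[[^][]*\\]", "", newick_text)  # drop comments
  .check_newick_syntax(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree))
    stop("Newick parse error: string could not be read as a tree")
  if (ape::Ntip(tree) < 2L)
    stop("tree must have at least 2 tips")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all non-root edges must carry one")
  if (anyNA(tree$edge.length))
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree
}

# Bracket-balance scan with position reporting; quotes protect their content.
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (in_quote) stop("Newick parse error: unterminated quoted label")
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of string")
  if (!grepl(";", txt, fixed = TRUE))
    stop("Newick parse error: missing terminating ';'")
  invisible(TRUE)
}

#' Read a single Newick tree from a file
#'
#' @param path Path to a file containing one Newick tree.
#' @return A `"phylo"` object.
#' @export
read_tree_file <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_tree(txt)
}

#' Write a tree as Newick with 10-significant-digit branch lengths
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Crown age of a rooted dated tree
#'
#' The maximum root-to-tip path length.  For an ultrametric tree this is the
#' age of the most recent common ancestor of all tips.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric scalar (same units as the branch lengths).
#' @export
crown_age <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_len(ape::Ntip(tree))])
}

#' Test whether a dated tree is ultrametric
#'
#' All root-to-tip distances must agree within `rel_tol` times the crown age.
#' Dated trees are ultrametric by construction; deviations beyond a small
#' numerical tolerance signal an input problem, so downstream consumers
#' ([branching_times()]) reject rather than average them away.
#'
#' @param tree A `"phylo"` object.
#' @param rel_tol Relative tolerance (fraction of crown age); default `1e-6`.
#' @return Logical scalar.
#' @export
#' @examples
#' check_ultrametric(parse_tree("((A:1,B:1):1,C:2);"))    # TRUE
#' check_ultrametric(parse_tree("((A:1,B:1):1,C:2.5);"))  # FALSE
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  span <- max(depths) - min(depths)
  span <= rel_tol * max(depths)
}

#' Prune a dated tree to a named clade
#'
#' Returns the induced subtree on the kept tips; unary internal nodes are
#' suppressed with branch lengths summed, so the result is ultrametric with
#' crown age equal to the age of the most recent common ancestor of the kept
#' tips.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 3).
#' @return A `"phylo"` object on the kept tips.
#' @export
prune_to_clade <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("unknown tip labels: ", paste(missing, collapse = ", "))
  if (length(keep) < 3L)
    stop("need at least 3 tips to analyse a clade; got ", length(keep))
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- NULL  # stem below the clade MRCA is not part of the clade
  out
}

#' Rescale a dated tree to a target crown age
#'
#' Multiplies every branch length by `target_age / crown_age(tree)`.  Used to
#' re-root the basal age of a pruned clade to an externally estimated node
#' age (e.g. fixing a clade crown to a dated value such as 11.1 Myr).
#'
#' @param tree An ultrametric `"phylo"` object.
#' @param target_age Positive crown age to rescale to.
#' @return The rescaled `"phylo"` object.
#' @export
rescale_root_age <- function(tree, target_age) {
  if (!is.numeric(target_age) || length(target_age) != 1L || !is.finite(target_age) ||
      target_age <= 0)
    stop("'target_age' must be a positive number")
  if (!check_ultrametric(tree))
    stop("tree is not ultrametric; refusing to rescale")
  f <- target_age / crown_age(tree)
  tree$edge.length <- tree$edge.length * f
  if (!is.null(tree$root.edge)) tree$root.edge <- tree$root.edge * f
  tree
}

#' Branching times of an ultrametric tree
#'
#' Internal-node ages measured backward from the present, sorted
#' non-increasing, so that the first element is the crown age and the i-th
#' element is the age at which the reconstructed tree first has i+1 lineages.
#' These n-1 ages are the sufficient statistic for every diversification
#' model in the package.
#'
#' The tree must be binary (polytomies are rejected: silently resolving them
#' would change the branching times) and ultrametric within `rel_tol`.
#' Tied node ages (zero-length internal branches) are allowed.
#'
#' @param tree A `"phylo"` object with at least 3 tips, or an existing
#'   `"branching_times"` object (returned unchanged).
#' @param rel_tol Relative ultrametricity tolerance; default `1e-6`.
#' @return An object of class `"branching_times"`: a list with `n_tips`,
#'   `ages` (length `n_tips - 1`, non-increasing) and `crown_age`.
#' @export
#' @examples
#' branching_times(parse_tree("((A:1,B:1):1,C:2);"))$ages  # c(2, 1)
branching_times <- function(tree, rel_tol = 1e-6) {
  if (inherits(tree, "branching_times")) return(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("need at least 3 tips; got ", n)
  if (tree$Nnode != n - 1L)   # a rooted binary tree has n - 1 internal nodes
    stop("tree contains polytomies (or an unrooted basal trifurcation); ",
         "resolve them explicitly before analysis")
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_len(n)]
  crown <- max(tip_depths)
  dev <- crown - min(tip_depths)
  if (dev > rel_tol * crown)
    stop(sprintf(
      "tree is not ultrametric: max root-to-tip deviation %.6g exceeds tolerance %.3g * crown age",
      dev, rel_tol))
  ages <- crown - depths[(n + 1L):(2L * n - 1L)]
  ages[ages < 0 & ages > -rel_tol * crown] <- 0
  ages <- sort(ages, decreasing = TRUE)
  if (any(ages <= 0))
    stop("internal node at age <= 0: degenerate zero-length cherry at the present")
  as_branching_times(ages)
}

#' Construct a branching-times object from a vector of node ages
#'
#' @param ages Numeric vector of internal-node ages (backward from present),
#'   strictly positive, sorted non-increasing (will be sorted if not).
#' @return A `"branching_times"` object.
#' @export
as_branching_times <- function(ages) {
  if (inherits(ages, "branching_times")) return(ages)
  ages <- as.numeric(ages)
  if (length(ages) < 2L)
    stop("need at least 2 branching times (3 tips)")
  if (anyNA(ages) || any(!is.finite(ages)) || any(ages <= 0))
    stop("branching times must be finite and strictly positive")
  ages <- sort(ages, decreasing = TRUE)
  structure(list(n_tips = length(ages) + 1L, ages = ages, crown_age = ages[1L]),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat("Branching times:", x$n_tips, "tips, crown age",
      format(x$crown_age, digits = 6), "\n")
  print(x$ages, ...)
  invisible(x)
}

#' Lineage-through-time series from branching times
#'
#' Step series of reconstructed lineage count against age: the count k
#' applies on the age interval (x_k, x_(k+1)]; a final segment down to age 0
#' carries `n_tips` lineages.
#'
#' @param bt A `"branching_times"` object (or a tree coercible via
#'   [branching_times()]).
#' @return A data frame of class `"ltt_series"` with columns `age`
#'   (non-increasing, ending at 0), `count` and `log_count` (natural log).
#' @export
#' @examples
#' ltt(as_branching_times(c(2, 1)))
ltt <- function(bt) {
  bt <- branching_times(bt)
  n <- bt$n_tips
  out <- data.frame(age = c(bt$ages, 0),
                    count = c(2:n, n))
  out$log_count <- log(out$count)
  class(out) <- c("ltt_series", "data.frame")
  out
}

#' Export an LTT series as TSV
#'
#' Columns `age`, `count`, `log_count`.
#'
#' @param x An `"ltt_series"` data frame from [ltt()].
#' @param file Output path.
#' @export
write_ltt_tsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
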
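## Tree representation, Newick I/O, phylogenetic covariance, and the
## branch-length / covariance transforms that all model fitting consumes.
## Trees are ape "phylo" objects validated against the package invariants:
## one root, unique tip labels, finite non-negative branch lengths.

#' Validate a phylogeny against the package invariants
#'
#' Checks that `tree` is a rooted `phylo` object with unique tip labels and
#' finite, non-negative branch lengths. Called by every function that accepts
#' a tree; exported so input checking can be run standalone.
#'
#' @param tree An [ape::read.tree()]-style `phylo` object.
#' @return `tree`, invisibly, if valid. Otherwise an error naming the
#'   offending tip label or branch.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
  if (length(bad)) {
    child <- tree$edge[bad[1L], 2L]
    lab <- if (child <= ape::Ntip(tree)) tree$tip.label[child]
           else paste0("node ", child)
    stop("negative or non-finite branch length (", tree$edge.length[bad[1L]],
         ") on the branch leading to ", lab, call. = FALSE)
  }
  ## a basal polytomy is accepted as a rooted polytomy: the stored basal
  ## node is taken as the root (path-sum covariance is well defined there)
  invisible(tree)
}

#' Parse a Newick string into a validated phylogeny
#'
#' @param text A single Newick statement ending in `;`. Unlabeled internal
#'   nodes are permitted; polytomies are preserved.
#' @return A validated `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text))
    stop("Newick parse error: no terminating ';' in input", call. = FALSE)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE))
  if (is.null(tree))
    stop("Newick parse error: malformed statement (check parentheses)",
         call. = FALSE)
  validate_tree(tree)
  tree
}

#' Read a Newick file
#' @param path Path to a file containing one Newick statement.
#' @return A validated `phylo` object.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree as Newick
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @return `path` invisibly, or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read a tab-separated trait table
#'
#' First column must hold tip labels (used as row names); remaining columns
#' are traits. Missing values are allowed per column.
#'
#' @param path TSV file with a header row.
#' @return A data frame with tip labels as row names.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("trait table needs a label column plus at least one trait column",
         call. = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate tip labels in trait table", call. = FALSE)
  rownames(df) <- as.character(df[[1L]])
  df[, -1L, drop = FALSE]
}

#' Write a trait table as TSV
#' @param traits Data frame with tip labels as row names.
#' @param path Output path.
#' @param label_col Name for the label column.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path, label_col = "tip") {
  out <- cbind(stats::setNames(data.frame(rownames(traits),
                                          stringsAsFactors = FALSE),
                               label_col),
               traits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the summed branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' This is the expected trait covariance (per unit rate) under Brownian
#' motion and the base object for all transformed covariances.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param floor_terminal Zero-length terminal branches are raised to this
#'   value (default `1e-8`) so the matrix stays invertible; set to 0 to
#'   disable. A message is emitted when the floor is applied.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree, floor_terminal = 1e-8) {
  validate_tree(tree)
  tree <- floor_terminal_branches(tree, floor_terminal)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

floor_terminal_branches <- function(tree, floor = 1e-8) {
  if (floor <= 0) return(tree)
  term <- tree$edge[, 2L] <= ape::Ntip(tree)
  zero <- term & tree$edge.length == 0
  if (any(zero)) {
    message(sum(zero), " zero-length terminal branch(es) floored at ", floor)
    tree$edge.length[zero] <- floor
  }
  tree
}

#' Root-to-tip distances
#' @param tree A rooted `phylo` object.
#' @return Named vector of root-to-tip path lengths, in tip-label order.
#' @export
tip_heights <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving tip variances
#' unchanged. `lambda = 0` removes all phylogenetic covariance; `lambda = 1`
#' is the identity (Brownian motion).
#'
#' @param C Covariance matrix from [phylo_vcv()].
#' @param lambda Signal multiplier, in `[0, lambda_max]`.
#' @param lambda_max Upper bound, default 1.
#' @return Transformed covariance matrix.
#' @export
transform_lambda <- function(C, lambda, lambda_max = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0)
    stop("lambda must be a single number >= 0", call. = FALSE)
  if (lambda > lambda_max)
    stop("lambda (", lambda, ") exceeds lambda_max (", lambda_max, ")",
         call. = FALSE)
  d <- diag(C)
  out <- C * lambda
  diag(out) <- d
  out
}

#' Pagel's kappa transform of branch lengths
#'
#' Raises every branch length to the power `kappa`, with `0^kappa = 0`.
#' `kappa = 0` sets every positive branch to 1 (a punctuational clock:
#' change is proportional to the number of splits, not to branch length).
#'
#' @param tree A rooted `phylo` object.
#' @param kappa Exponent, `>= 0`.
#' @return A tree with transformed branch lengths.
#' @export
transform_kappa <- function(tree, kappa) {
  validate_tree(tree)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop("kappa must be a single number >= 0", call. = FALSE)
  b <- tree$edge.length
  if (kappa == 0) {
    tree$edge.length <- ifelse(b > 0, 1, 0)
  } else {
    tree$edge.length <- b^kappa
  }
  tree
}

#' Pagel's delta transform of a covariance matrix
#'
#' Raises each entry (a shared root-path length, i.e. a node depth) to the
#' power `delta`, with `0^delta = 0`. `delta > 1` concentrates trait change
#' late in the tree (tipward acceleration); `delta < 1` early.
#'
#' @param C Covariance matrix from [phylo_vcv()].
#' @param delta Exponent in `(0, delta_max]`.
#' @param delta_max Upper bound, default 3 (conventional cap).
#' @return Transformed covariance matrix.
#' @export
transform_delta <- function(C, delta, delta_max = 3) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("delta must be a single number > 0", call. = FALSE)
  if (delta > delta_max)
    stop("delta (", delta, ") exceeds delta_max (", delta_max, ")",
         call. = FALSE)
  C^delta
}

#' Ornstein-Uhlenbeck trait covariance
#'
#' Covariance of tip traits under an OU process with attraction strength
#' `alpha` and diffusion rate `sigma2`, in the non-ultrametric form
#' `V[i,j] = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha s_ij))`
#' where `s_ij` is the root-to-MRCA path length and `d_ij` the patristic
#' distance between tips i and j. Reduces to the familiar expression on
#' ultrametric trees and to `sigma2 * C` as `alpha -> 0`.
#'
#' @param tree A rooted `phylo` object.
#' @param alpha Attraction strength, `> 0` (the `alpha -> 0` limit is the
#'   Brownian model, fitted separately).
#' @param sigma2 Diffusion rate, `> 0`.
#' @return Covariance matrix with tip labels as dimnames.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single number > 0", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  S <- phylo_vcv(tree)
  h <- diag(S)
  D <- outer(h, h, "+") - 2 * S        # patristic distances
  V <- (sigma2 / (2 * alpha)) * exp(-alpha * D) * (-expm1(-2 * alpha * S))
  dimnames(V) <- dimnames(S)
  V
}

#' Early-Burst trait covariance
#'
#' Brownian motion whose instantaneous rate decays (or is constant)
#' exponentially from the root: `r(t) = sigma2 * exp(a t)`. A branch segment
#' `[t1, t2]` contributes `sigma2 * (exp(a t2) - exp(a t1)) / a` (for
#' `a != 0`; `sigma2 * (t2 - t1)` at `a = 0`), summed over the shared
#' root-to-MRCA path, giving `V[i,j] = sigma2 * expm1(a * s_ij) / a`.
#'
#' @param tree A rooted `phylo` object.
#' @param a Rate-change exponent, `<= 0` (0 reduces to Brownian motion).
#' @param sigma2 Rate at the root, `> 0`.
#' @return Covariance matrix with tip labels as dimnames.
#' @export
eb_covariance <- function(tree, a, sigma2 = 1) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a > 0)
    stop("a must be a single number <= 0", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  S <- phylo_vcv(tree)
  if (a == 0) return(sigma2 * S)
  sigma2 * expm1(a * S) / a
}

## Trend-diffusion covariance: rate sigma0^2 + slope * t, integrated along
## shared root paths. Internal; exposed through fit_trend/simulate_trait.
trend_covariance <- function(tree, sigma0sq, slope) {
  S <- phylo_vcv(tree)
  if (sigma0sq + slope * max(S) < 0)
    stop("trend rate goes negative within the tree depth", call. = FALSE)
  sigma0sq * S + (slope / 2) * S * S
}

#' Align a tree with a trait column
#'
#' Prunes tips lacking the trait (merging the branch segments around any
#' resulting degree-2 nodes) and returns the tree together with the trait
#' vector in tip-label order.
#'
#' @param tree A rooted `phylo` object.
#' @param traits Data frame with tip labels as row names (see
#'   [read_trait_table()]).
#' @param column Trait column name.
#' @return List with `tree`, `y` (named vector in `tree$tip.label` order) and
#'   `dropped` (labels pruned from the tree).
#' @export
align_tree_and_traits <- function(tree, traits, column) {
  validate_tree(tree)
  if (!column %in% colnames(traits))
    stop("trait column '", column, "' not found", call. = FALSE)
  v <- traits[[column]]
  names(v) <- rownames(traits)
  v <- v[!is.na(v)]
  keep <- intersect(tree$tip.label, names(v))
  if (length(keep) < 3L)
    stop("fewer than 3 tips with both tree and '", column,
         "' data; no model is fittable", call. = FALSE)
  dropped <- setdiff(tree$tip.label, keep)
  if (length(dropped)) {
    message("dropping ", length(dropped), " tip(s) lacking '", column, "'")
    tree <- ape::keep.tip(tree, keep)
  }
  list(tree = tree, y = v[tree$tip.label], dropped = dropped)
}
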
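# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: covariances come from explicit root-path
# enumeration, likelihoods from dense solve()/determinant(), codon site
# counts from brute-force enumeration of all nine single-base mutations.

# --- tree / covariance oracles ---------------------------------------

# edge list of (node path to root) for one tip, as row indices into edge
root_path_edges <- function(tree, tip) {
  path <- integer(0)
  node <- tip
  repeat {
    row <- which(tree$edge[, 2L] == node)
    if (!length(row)) break
    path <- c(path, row)
    node <- tree$edge[row, 1L]
  }
  path
}

# BM covariance by explicit enumeration: shared edges on two root paths
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(i) root_path_edges(tree, i))
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- C[j, i] <- sum(tree$edge.length[shared])
  }
  C
}

# dense multivariate-normal log density, no Cholesky
mvn_loglik_oracle <- function(y, mu, Sigma) {
  n <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  r <- y - mu
  -0.5 * n * log(2 * pi) - 0.5 * ld -
    0.5 * drop(t(r) %*% solve(Sigma) %*% r)
}

# OU covariance from the formula, scalar loops only
ou_oracle <- function(tree, alpha, sigma2) {
  C <- vcv_oracle(tree)
  h <- diag(C)
  n <- nrow(C)
  V <- matrix(0, n, n, dimnames = dimnames(C))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- C[i, j]
    d <- h[i] + h[j] - 2 * s
    V[i, j] <- sigma2 / (2 * alpha) * exp(-alpha * d) *
      (1 - exp(-2 * alpha * s))
  }
  V
}

# EB covariance by numerical quadrature of the decaying rate along the
# shared root path [0, s_ij]
eb_oracle <- function(tree, a, sigma2) {
  C <- vcv_oracle(tree)
  n <- nrow(C)
  V <- matrix(0, n, n, dimnames = dimnames(C))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- C[i, j]
    V[i, j] <- if (s == 0) 0 else
      stats::integrate(function(t) sigma2 * exp(a * t), 0, s,
                       rel.tol = 1e-10)$value
  }
  V
}

# covariance/mean reconstruction for each fitted model, from first
# principles, used to cross-check fit log-likelihoods
fit_moments_oracle <- function(model, params, tree) {
  C <- vcv_oracle(tree)
  n <- nrow(C)
  h <- diag(C)
  mu <- rep(params$z0, n)
  V <- switch(model,
    "BM" = params$sigma2 * C,
    "white-noise" = params$sigma2 * diag(n),
    "lambda" = {
      L <- params$sigma2 * params$lambda * C
      diag(L) <- params$sigma2 * h
      L
    },
    "OU" = ou_oracle(tree, params$alpha, params$sigma2),
    "EB" = eb_oracle(tree, params$a, params$sigma2),
    "trend" = params$sigma0sq * C + params$slope / 2 * C * C,
    "drift" = {
      mu <- params$z0 + params$drift * h
      params$sigma2 * C
    },
    stop("no oracle for model ", model))
  list(mu = mu, V = V)
}

# --- codon oracles ----------------------------------------------------

# genetic code from Biostrings, an independent source of the translation
# table (names are DNA codons)
genetic_code_oracle <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      code <<- stats::setNames(as.character(gc), names(gc))
    }
    code
  }
})

# synonymous site count of one codon: enumerate all nine single-base
# mutations; a change is synonymous iff it keeps the amino acid and does
# not create a stop
syn_sites_oracle <- function(codon) {
  code <- genetic_code_oracle()
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, pos, pos)) next
    mut <- codon
    substr(mut, pos, pos) <- b
    if (code[[mut]] == aa && code[[mut]] != "*") s <- s + 1 / 3
  }
  s
}

# classify the single difference of a codon pair (used for constructed
# pairs where codons differ at exactly one position)
single_diff_class_oracle <- function(ca, cb) {
  code <- genetic_code_oracle()
  stopifnot(sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]]) == 1L)
  if (code[[ca]] == code[[cb]]) "syn" else "nonsyn"
}

# --- misc helpers -----------------------------------------------------

# a fixed small non-ultrametric test tree
small_tree <- function() {
  pcmkit::parse_newick(
    "(((A:0.4,B:0.7):0.6,C:1.1):0.5,(D:0.9,E:1.3):0.8);")
}

# star phylogeny with equal tip heights
star_tree <- function(n, height = 1) {
  labs <- paste0("s", seq_len(n))
  pcmkit::parse_newick(
    paste0("(", paste0(labs, ":", height, collapse = ","), ");"))
}

random_codon_pair <- function(n_codons, n_mut, seed) {
  set.seed(seed)
  code <- genetic_code_oracle()
  ok <- names(code)[code != "*"]
  a <- sample(ok, n_codons, replace = TRUE)
  b <- a
  pos <- sample.int(3L * n_codons, n_mut)
  for (p in pos) {
    ci <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    repeat {
      nb <- sample(c("A", "C", "G", "T"), 1L)
      cand <- b[ci]
      substr(cand, off, off) <- nb
      if (code[[cand]] != "*") { b[ci] <- cand; break }
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
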
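## Seeded generators for every input the analysis modules consume: Yule
## trees (with optional branch-length jitter to emulate non-clocklike
## substitution trees), traits drawn from the exact model covariances,
## regression datasets with phylogenetically correlated residuals, pairwise
## dN/dS tables with known survival fractions, and codon-alignment pairs
## with known substitution counts. Every generator is a pure function of
## its arguments including the seed.

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation: two lineages from the root, each splitting at rate
#' `birth_rate`; once the `n_tips`-th lineage appears the process runs for
#' one further waiting time (rate `n_tips * birth_rate`) so pendant edges
#' are positive, giving an ultrametric tree of depth
#' `sum_{k=2}^{n} Exp(k b)`. An
#' optional multiplicative log-normal jitter roughens branch lengths to
#' emulate a substitutions-per-site (non-ultrametric) tree.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (default 1).
#' @param seed Mandatory RNG seed.
#' @param jitter_sd SD of log-normal branch-length jitter (default 0 = off).
#' @return A validated `phylo` object with tips `t1..tn`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed, jitter_sd = 0) {
  stopifnot(n_tips >= 2L, birth_rate > 0)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  with_seed(seed, {
    parent <- c(NA_integer_, 1L, 1L)   # node 1 = root, at time 0
    time <- c(0, NA_real_, NA_real_)
    active <- c(2L, 3L)
    t_now <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1L, rate = k * birth_rate)
      i <- active[sample.int(k, 1L)]
      time[i] <- t_now
      id <- length(parent) + c(1L, 2L)
      parent <- c(parent, i, i)
      time <- c(time, NA_real_, NA_real_)
      active <- c(setdiff(active, i), id)
    }
    ## run one more waiting time at rate n*b so pendant edges are positive;
    ## depth is then sum_{k=2}^{n} Exp(k b)
    t_now <- t_now + stats::rexp(1L, rate = n_tips * birth_rate)
    time[active] <- t_now
    is_tip <- seq_along(parent) %in% active
    newick <- build_newick(1L, parent, time, is_tip)
    tree <- parse_newick(paste0(newick, ";"))
    if (jitter_sd > 0)
      tree$edge.length <- tree$edge.length *
        exp(stats::rnorm(length(tree$edge.length), 0, jitter_sd) -
              jitter_sd^2 / 2)
    tree
  })
}

build_newick <- function(node, parent, time, is_tip, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  kids <- which(!is.na(parent) & parent == node)
  if (!length(kids)) {
    counter$i <- counter$i + 1L
    return(paste0("t", counter$i))
  }
  sub <- vapply(kids, function(k) {
    paste0(build_newick(k, parent, time, is_tip, counter),
           ":", format(time[k] - time[node], digits = 12))
  }, "")
  paste0("(", paste(sub, collapse = ","), ")")
}

## Mean vector and covariance implied by a named model and parameter list.
model_moments <- function(tree, model, params) {
  p <- params
  sigma2 <- if (!is.null(p$sigma2)) p$sigma2 else 1
  z0 <- if (!is.null(p$z0)) p$z0 else 0
  C <- phylo_vcv(tree)
  n <- nrow(C)
  mu <- rep(z0, n)
  V <- switch(model,
    bm = sigma2 * C,
    white = sigma2 * diag(n),
    lambda = sigma2 * transform_lambda(C, p$lambda),
    kappa = sigma2 * phylo_vcv(transform_kappa(tree, p$kappa)),
    delta = sigma2 * transform_delta(C, p$delta),
    ou = ou_covariance(tree, p$alpha, sigma2),
    eb = eb_covariance(tree, p$a, sigma2),
    trend = trend_covariance(tree, sigma2, p$slope),
    drift = {mu <- z0 + p$drift * diag(C); sigma2 * C},
    stop("unknown model '", model, "'", call. = FALSE))
  if (model == "white") dimnames(V) <- dimnames(C)
  list(mu = stats::setNames(mu, rownames(C)), V = V)
}

#' Simulate a continuous trait under a named evolution model
#'
#' Draws one tip vector from the exact multivariate normal implied by the
#' model: mean `z0` (plus `drift * height` for the drift model) and
#' covariance assembled by the tree/covariance module, sampled through a
#' Cholesky factor.
#'
#' @param tree A rooted `phylo` object.
#' @param model One of `"bm"`, `"white"`, `"lambda"`, `"kappa"`, `"delta"`,
#'   `"ou"`, `"eb"`, `"trend"`, `"drift"`.
#' @param params Named list of model parameters (`sigma2`, `z0`, plus the
#'   model-specific `lambda`, `kappa`, `delta`, `alpha`, `a`, `slope`,
#'   `drift`).
#' @param seed Mandatory RNG seed.
#' @return Named trait vector in tip-label order.
#' @export
simulate_trait <- function(tree, model = "bm", params = list(), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  validate_tree(tree)
  mm <- model_moments(tree, model, params)
  n <- length(mm$mu)
  sigma2 <- if (!is.null(params$sigma2)) params$sigma2 else 1
  if (sigma2 == 0) return(mm$mu)
  ## eigenfactor rather than Cholesky: model covariances can be numerically
  ## PSD-but-singular (e.g. strong Early-Burst collapses recent splits)
  eg <- eigen(mm$V, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  fac <- eg$vectors %*% (sqrt(ev) * t(eg$vectors))
  with_seed(seed, mm$mu + drop(fac %*% stats::rnorm(n)))
}

#' Simulate a regression dataset with phylogenetic residuals
#'
#' `y = X beta + eps` with `eps ~ N(0, resid_sigma2 * C_lambda)` where
#' `C_lambda` is the lambda-transformed Brownian covariance of the tree.
#' Predictor columns are iid standard normal or Brownian traits.
#'
#' @param tree A rooted `phylo` object.
#' @param beta Coefficient vector; first entry is the intercept.
#' @param resid_lambda Residual signal lambda in `[0, 1]`.
#' @param resid_sigma2 Residual variance scale.
#' @param x_type `"iid"` or `"bm"` predictors.
#' @param seed Mandatory RNG seed.
#' @return List with named response `y`, design matrix `X` (with intercept
#'   column) and the generating values.
#' @export
simulate_regression <- function(tree, beta = c(0, 1), resid_lambda = 1,
                                resid_sigma2 = 1, x_type = c("iid", "bm"),
                                seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  x_type <- match.arg(x_type)
  validate_tree(tree)
  n <- ape::Ntip(tree)
  p <- length(beta) - 1L
  stopifnot(p >= 1L)
  C <- phylo_vcv(tree)
  with_seed(seed, {
    X <- matrix(1, n, p + 1L,
                dimnames = list(tree$tip.label,
                                c("(Intercept)", paste0("x", seq_len(p)))))
    for (j in seq_len(p)) {
      X[, j + 1L] <- if (x_type == "iid") stats::rnorm(n)
        else drop(crossprod(chol(C), stats::rnorm(n)))
    }
    eps <- if (resid_sigma2 == 0) numeric(n)
      else drop(crossprod(chol(resid_sigma2 *
                                 transform_lambda(C, resid_lambda)),
                          stats::rnorm(n)))
    y <- stats::setNames(drop(X %*% beta) + eps, tree$tip.label)
    list(y = y, X = X, beta = beta, resid_lambda = resid_lambda,
         resid_sigma2 = resid_sigma2)
  })
}

#' Simulate a pairwise dN/dS table
#'
#' Emulates the long-format output of a pairwise ML dN/dS run: all
#' within-genus genome pairs, `dS` uniform on `ds_range` and `omega`
#' log-normal (defaults centred near 0.1, typical of purifying selection in
#' conserved bacterial marker genes), `dN = omega * dS`.
#'
#' @param n_genera Number of genera.
#' @param genomes_per_genus Genomes per genus (all pairs are emitted).
#' @param seed Mandatory RNG seed.
#' @param ds_range Range of the uniform dS draw (default `c(0, 2.5)`,
#'   spanning both filter thresholds).
#' @param omega_meanlog,omega_sdlog Log-normal omega parameters (defaults
#'   `log(0.1)`, 0.5).
#' @return A `PairwiseDnDs`-shaped data frame (`genus`, `genome_a`,
#'   `genome_b`, `dN`, `dS`, `omega`).
#' @export
simulate_pairwise_dnds <- function(n_genera, genomes_per_genus, seed,
                                   ds_range = c(0, 2.5),
                                   omega_meanlog = log(0.1),
                                   omega_sdlog = 0.5) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_genera >= 1L, genomes_per_genus >= 2L)
  with_seed(seed, {
    rows <- lapply(seq_len(n_genera), function(g) {
      genus <- sprintf("G%03d", g)
      acc <- sprintf("%s.%02d", genus, seq_len(genomes_per_genus))
      idx <- utils::combn(genomes_per_genus, 2L)
      m <- ncol(idx)
      dS <- stats::runif(m, ds_range[1L], ds_range[2L])
      omega <- stats::rlnorm(m, omega_meanlog, omega_sdlog)
      data.frame(genus = genus, genome_a = acc[idx[1L, ]],
                 genome_b = acc[idx[2L, ]], dN = omega * dS, dS = dS,
                 omega = omega, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

## codons with a synonymous third-position partner and a safe (non-stop,
## nonsynonymous) first-position T->G or A->G change
SAFE_CODONS <- c("GCT", "GGT", "CGT", "ACT", "CCT", "GTT", "TCT", "CTT")

#' Construct a codon-alignment pair with known substitution counts
#'
#' Builds two gap-free sequences differing by exactly `n_syn` synonymous
#' third-position changes and `n_nonsyn` nonsynonymous first-position
#' changes, at distinct codons, so counting estimators can be checked
#' against ground truth.
#'
#' @param n_codons Alignment length in codons.
#' @param n_syn,n_nonsyn Requested substitution counts
#'   (`n_syn + n_nonsyn <= n_codons`).
#' @param seed Mandatory RNG seed.
#' @return List with sequences `a` and `b` and the realized counts.
#' @export
make_codon_pair <- function(n_codons, n_syn = 0L, n_nonsyn = 0L, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_syn + n_nonsyn <= n_codons)
  with_seed(seed, {
    base <- sample(SAFE_CODONS, n_codons, replace = TRUE)
    other <- base
    idx <- sample.int(n_codons, n_syn + n_nonsyn)
    syn_idx <- idx[seq_len(n_syn)]
    non_idx <- idx[seq_len(n_nonsyn) + n_syn]
    for (i in syn_idx)                       # NNT -> NNC: always synonymous
      substr(other[i], 3L, 3L) <- "C"
    for (i in non_idx) {                     # first position -> A
      repl <- if (substr(other[i], 1L, 1L) == "A") "G" else "A"
      substr(other[i], 1L, 1L) <- repl
    }
    list(a = paste(base, collapse = ""), b = paste(other, collapse = ""),
         n_syn = n_syn, n_nonsyn = n_nonsyn,
         syn_codons = sort(syn_idx), nonsyn_codons = sort(non_idx))
  })
}

#' Write a two-sequence FASTA file
#' @param pair List with sequences `a` and `b` (see [make_codon_pair()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_pair_fasta <- function(pair, path) {
  writeLines(c(">seq_a", pair$a, ">seq_b", pair$b), path)
  invisible(path)
}

#' Read a two-sequence FASTA codon alignment
#' @param path FASTA file with exactly two gap-free sequences.
#' @return List with sequences `a` and `b`.
#' @export
read_codon_pair_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2L)
    stop("expected exactly two sequences in ", path, call. = FALSE)
  seqs <- vapply(seq_along(hdr), function(i) {
    end <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    paste(lines[(hdr[i] + 1L):end], collapse = "")
  }, "")
  list(a = seqs[1L], b = seqs[2L])
}
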
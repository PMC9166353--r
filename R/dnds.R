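## Pairwise dN/dS protocol: saturation / same-population / artifact filters,
## per-genome support counts, per-genus medians, the GTDB-style genome
## selection filter, and a self-contained Nei-Gojobori (1986) counting
## estimator with Jukes-Cantor correction so the pipeline is testable
## without external ML estimators (whose output tables are accepted as
## input in the same long format).

check_pairwise <- function(pairs) {
  need <- c("genus", "genome_a", "genome_b", "dN", "dS")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss))
    stop("pairwise table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(pairs$dN < 0, na.rm = TRUE) || any(pairs$dS < 0, na.rm = TRUE))
    stop("negative dN or dS in pairwise table", call. = FALSE)
  if (!"omega" %in% colnames(pairs))
    pairs$omega <- ifelse(pairs$dS > 0, pairs$dN / pairs$dS, NA_real_)
  pairs
}

#' Filter pairwise dN/dS estimates
#'
#' Applies, in order: (1) drop pairs with `dS > 1.5` (synonymous-site
#' saturation), (2) drop pairs with `dS < 0.1` (likely same-population
#' comparisons), (3) drop pairs with `omega > 10` (artifactual ratios).
#' Inequalities are strict, so rows exactly at 0.1, 1.5 or 10 survive.
#'
#' @param pairs Data frame with columns `genus`, `genome_a`, `genome_b`,
#'   `dN`, `dS` and optionally `omega` (computed as `dN/dS` if absent).
#' @param ds_max,ds_min,omega_max Filter thresholds (defaults 1.5, 0.1, 10).
#' @return List with `kept` (surviving rows) and `log`, a per-rule count of
#'   removed rows in application order.
#' @export
filter_pairwise <- function(pairs, ds_max = 1.5, ds_min = 0.1,
                            omega_max = 10) {
  pairs <- check_pairwise(pairs)
  n0 <- nrow(pairs)
  sat <- pairs$dS > ds_max
  pairs1 <- pairs[!sat, , drop = FALSE]
  low <- pairs1$dS < ds_min
  pairs2 <- pairs1[!low, , drop = FALSE]
  art <- !is.na(pairs2$omega) & pairs2$omega > omega_max
  kept <- pairs2[!art, , drop = FALSE]
  list(kept = kept,
       log = data.frame(
         rule = c("dS > 1.5 (saturation)", "dS < 0.1 (same population)",
                  "omega > 10 (artifact)"),
         removed = c(sum(sat), sum(low), sum(art)),
         stringsAsFactors = FALSE),
       n_input = n0, n_kept = nrow(kept))
}

#' Genomes with sufficient surviving dN/dS estimates
#'
#' A genome is retained iff it appears (as either member of a pair) in at
#' least `min_estimates` surviving pairwise comparisons. Applied once — the
#' rule is not iterated after genome removal; the pair counts are returned
#' so the cascade is auditable.
#'
#' @param kept Filtered pairwise table (see [filter_pairwise()]).
#' @param min_estimates Minimum pair count (default 25).
#' @return Character vector of retained accessions, with per-genome counts
#'   in attribute `"counts"`.
#' @export
genome_min_support <- function(kept, min_estimates = 25L) {
  kept <- check_pairwise(kept)
  counts <- table(c(kept$genome_a, kept$genome_b))
  retained <- names(counts)[counts >= min_estimates]
  structure(retained, counts = counts)
}

#' Per-genus median dN/dS attached to representative genomes
#'
#' For each genus, the median of `omega` over surviving pairs (midpoint
#' convention for even counts), reported against the genus representative's
#' tip label.
#'
#' @param kept Filtered pairwise table.
#' @param representatives Named character vector, genus -> representative
#'   accession / tip label. Genera absent from it are reported under their
#'   genus name.
#' @param genomes Optional character vector (e.g. from
#'   [genome_min_support()]); when given, only pairs whose two genomes are
#'   both retained contribute.
#' @return Data frame with columns `tip`, `genus`, `dnds_median`, `n_pairs`.
#' @export
median_dnds <- function(kept, representatives = NULL, genomes = NULL) {
  kept <- check_pairwise(kept)
  if (!is.null(genomes))
    kept <- kept[kept$genome_a %in% genomes & kept$genome_b %in% genomes, ,
                 drop = FALSE]
  sp <- split(kept$omega, kept$genus)
  med <- vapply(sp, function(o) stats::median(o, na.rm = TRUE), 0)
  npair <- vapply(sp, function(o) sum(!is.na(o)), 0L)
  genus <- names(sp)
  tip <- if (is.null(representatives)) genus
         else ifelse(genus %in% names(representatives),
                     unname(representatives[genus]), genus)
  data.frame(tip = tip, genus = genus, dnds_median = unname(med),
             n_pairs = unname(npair), row.names = NULL,
             stringsAsFactors = FALSE)
}

## ---- Nei-Gojobori (1986) counting estimator --------------------------

GENETIC_CODE_STD <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

BASES <- c("T", "C", "A", "G")

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length not divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop("sequence contains characters other than A, C, G, T ",
         "(gaps and ambiguity codes are rejected)", call. = FALSE)
  codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  if (any(GENETIC_CODE_STD[codons] == "*"))
    stop("internal stop codon in sequence", call. = FALSE)
  codons
}

## Synonymous site count of one codon: at each position, the fraction of the
## three possible substitutions that preserve the amino acid (changes to
## stop codons count as nonsynonymous).
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_STD[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENETIC_CODE_STD[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

## Average synonymous/nonsynonymous differences between two codons over all
## single-step mutational pathways; pathways crossing a stop codon are
## excluded (unless all do, in which case all are used).
codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (k == 1L) list(pos) else
    lapply(split_perms(k), function(ord) pos[ord])
  score <- function(ord) {
    cur <- ca
    sy <- ns <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (GENETIC_CODE_STD[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE_STD[[nxt]] == GENETIC_CODE_STD[[cur]]) sy <- sy + 1
      else ns <- ns + 1
      cur <- nxt
    }
    c(sy, ns)
  }
  res <- Filter(Negate(is.null), lapply(paths, score))
  if (!length(res)) {    # all pathways cross a stop: count them anyway
    score2 <- function(ord) {
      cur <- ca
      sy <- ns <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (GENETIC_CODE_STD[[nxt]] == GENETIC_CODE_STD[[cur]]) sy <- sy + 1
        else ns <- ns + 1
        cur <- nxt
      }
      c(sy, ns)
    }
    res <- lapply(paths, score2)
  }
  m <- Reduce(`+`, res) / length(res)
  c(syn = m[1L], nonsyn = m[2L])
}

split_perms <- function(k) {
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  ## k == 3
  idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  lapply(idx, as.integer)
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counting estimator on a gap-free codon alignment of two sequences:
#' synonymous and nonsynonymous site counts per the 1/3-fraction rule
#' (averaged over the two sequences), observed differences averaged over
#' single-step mutational pathways, and Jukes-Cantor correction
#' `d = -3/4 log(1 - 4/3 p)` applied to each proportion.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (A/C/G/T only, length
#'   divisible by 3, no internal stop codons).
#' @return List with `dN`, `dS`, `omega` (`NA` with a flag when `dS = 0`),
#'   site counts `N`, `S` and difference counts `Nd`, `Sd`.
#' @export
ng86_dnds <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences differ in length", call. = FALSE)
  S <- (sum(vapply(ca, codon_syn_sites, 0)) +
        sum(vapply(cb, codon_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  d <- mapply(function(a, b) codon_diffs(a, b), ca, cb)
  Sd <- sum(d["syn", ])
  Nd <- sum(d["nonsyn", ])
  jc <- function(p, what) {
    if (p == 0) return(0)
    if (p >= 3 / 4)
      stop("proportion of ", what, " differences (", signif(p, 3),
           ") at or beyond the Jukes-Cantor saturation limit 3/4",
           call. = FALSE)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(Sd / S, "synonymous")
  dN <- jc(Nd / N, "nonsynonymous")
  omega <- if (dS > 0) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, N = N, S = S, Nd = Nd, Sd = Sd,
       omega_defined = dS > 0)
}

#' GTDB-style genome selection filter
#'
#' Applies, in order: (1) completeness/contamination filter — non-CPR
#' genomes need completeness >= 95 and contamination <= 5, CPR
#' (Patescibacteria) genomes completeness >= 80 and contamination <= 5
#' (bounds inclusive); (2) classes with more than `class_cap` surviving
#' genomes are randomly downsampled to `class_cap` (seeded, without
#' replacement); (3) genera left with fewer than two genomes are discarded.
#'
#' @param metadata Data frame with columns `accession`, `genus`, `class`,
#'   `completeness`, `contamination`, `is_cpr`.
#' @param seed Seed for the downsampling step.
#' @param class_cap Per-class cap (default 500).
#' @return List with `accessions` (retained) and `log` (per-rule counts).
#' @export
select_genomes <- function(metadata, seed, class_cap = 500L) {
  need <- c("accession", "genus", "class", "completeness", "contamination",
            "is_cpr")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(metadata$completeness < 0 | metadata$completeness > 100))
    stop("completeness outside [0, 100]", call. = FALSE)
  if (any(metadata$contamination < 0))
    stop("negative contamination", call. = FALSE)
  n0 <- nrow(metadata)
  qc <- ifelse(metadata$is_cpr,
               metadata$completeness >= 80 & metadata$contamination <= 5,
               metadata$completeness >= 95 & metadata$contamination <= 5)
  m1 <- metadata[qc, , drop = FALSE]
  keep <- with_seed(seed, {
    unlist(lapply(split(m1$accession, m1$class), function(acc) {
      if (length(acc) > class_cap) sample(acc, class_cap) else acc
    }), use.names = FALSE)
  })
  m2 <- m1[m1$accession %in% keep, , drop = FALSE]
  gsize <- table(m2$genus)
  m3 <- m2[m2$genus %in% names(gsize)[gsize >= 2L], , drop = FALSE]
  list(accessions = m3$accession,
       log = data.frame(
         rule = c("completeness/contamination", "class downsampling",
                  "genus singletons"),
         removed = c(n0 - nrow(m1), nrow(m1) - nrow(m2),
                     nrow(m2) - nrow(m3)),
         remaining = c(nrow(m1), nrow(m2), nrow(m3)),
         stringsAsFactors = FALSE))
}
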
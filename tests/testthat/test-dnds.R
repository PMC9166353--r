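# Pairwise filtering rules, support counting, medians, the NG86 counting
# estimator (against enumeration oracles), and the genome-selection filter.

pair_row <- function(genus = "g", a = "A", b = "B", dN = 0.1, dS = 0.5) {
  data.frame(genus = genus, genome_a = a, genome_b = b, dN = dN, dS = dS,
             stringsAsFactors = FALSE)
}

test_that("filter_pairwise applies strict boundaries in order", {
  tab <- do.call(rbind, lapply(seq_along(c(0.05, 0.1, 0.8, 1.5, 1.6)),
    function(i) pair_row(a = paste0("A", i), b = paste0("B", i),
                         dN = 0.01, dS = c(0.05, 0.1, 0.8, 1.5, 1.6)[i])))
  fl <- filter_pairwise(tab)
  expect_setequal(fl$kept$dS, c(0.1, 0.8, 1.5))   # boundary values survive
  expect_equal(fl$log$removed, c(1, 1, 0))

  art <- rbind(tab, pair_row(a = "A9", b = "B9", dN = 6, dS = 0.5))  # w=12
  fl2 <- filter_pairwise(art)
  expect_equal(fl2$log$removed[3], 1)
  expect_false(any(fl2$kept$omega > 10))

  keepme <- pair_row(dN = 5, dS = 0.5)            # omega exactly 10 stays
  expect_equal(filter_pairwise(keepme)$n_kept, 1)

  expect_error(filter_pairwise(pair_row(dN = -0.1)), "negative")
})

test_that("filter_pairwise matches a predicate oracle and is idempotent", {
  set.seed(10)
  n <- 1000
  tab <- data.frame(genus = sample(letters[1:5], n, TRUE),
                    genome_a = sprintf("a%04d", 1:n),
                    genome_b = sprintf("b%04d", 1:n),
                    dN = runif(n, 0, 3), dS = runif(n, 0, 2.5))
  tab$omega <- ifelse(tab$dS > 0, tab$dN / tab$dS, NA)
  fl <- filter_pairwise(tab)
  keep_oracle <- with(tab, dS <= 1.5 & dS >= 0.1 & dN / dS <= 10)
  expect_equal(fl$n_kept, sum(keep_oracle))
  expect_equal(sort(fl$kept$genome_a), sort(tab$genome_a[keep_oracle]))

  fl2 <- filter_pairwise(fl$kept)
  expect_equal(fl2$kept, fl$kept)
  expect_equal(fl2$log$removed, c(0, 0, 0))
})

test_that("genome_min_support applies the >= threshold once", {
  mk <- function(g, n) do.call(rbind, lapply(seq_len(n), function(i)
    pair_row(a = g, b = paste0(g, "_partner", i))))
  tab <- rbind(mk("G24", 24), mk("G25", 25))
  got <- genome_min_support(tab, 25L)
  expect_false("G24" %in% got)
  expect_true("G25" %in% got)

  set.seed(11)
  sim <- simulate_pairwise_dnds(4, 30, seed = 12)
  kept <- filter_pairwise(sim)$kept
  got2 <- genome_min_support(kept, 25L)
  counts_oracle <- table(c(kept$genome_a, kept$genome_b))
  expect_setequal(got2, names(counts_oracle)[counts_oracle >= 25])
})

test_that("median_dnds uses the midpoint convention and ignores ordering", {
  tab <- rbind(pair_row(genus = "g1", a = "A", b = "B", dN = 0.01, dS = 0.1),
               pair_row(genus = "g1", a = "A", b = "C", dN = 0.02, dS = 0.1),
               pair_row(genus = "g1", a = "B", b = "C", dN = 0.09, dS = 0.1))
  tab$omega <- tab$dN / tab$dS
  med <- median_dnds(tab)
  expect_equal(med$dnds_median, 0.2)   # odd count: middle value

  tab2 <- tab[1:2, ]
  expect_equal(median_dnds(tab2)$dnds_median, 0.15)  # even: midpoint

  # row order and pair orientation do not matter
  flip <- tab[c(3, 1, 2), ]
  tmp <- flip$genome_a
  flip$genome_a <- flip$genome_b
  flip$genome_b <- tmp
  expect_equal(median_dnds(flip)$dnds_median, 0.2)

  # representative mapping relabels the output tips
  med2 <- median_dnds(tab, representatives = c(g1 = "TIP_1"))
  expect_equal(med2$tip, "TIP_1")

  # sort-and-pick oracle on random genera
  set.seed(13)
  sim <- simulate_pairwise_dnds(6, 8, seed = 14)
  med3 <- median_dnds(sim)
  for (g in med3$genus) {
    o <- sort(sim$omega[sim$genus == g])
    m <- if (length(o) %% 2 == 1) o[(length(o) + 1) / 2]
         else mean(o[length(o) / 2 + 0:1])
    expect_equal(med3$dnds_median[med3$genus == g], m)
  }
})

test_that("ng86_dnds handles identical sequences and the single-codon
           hand case", {
  p <- make_codon_pair(50, 0, 0, seed = 20)
  r0 <- ng86_dnds(p$a, p$a)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))
  expect_false(r0$omega_defined)

  # TTT vs TTC (Phe/Phe) padded with ten identical GCT codons:
  # S = 1/3 (TTT or TTC) + 10 * 1 (GCT, fourfold third position) = 31/3
  pad <- strrep("GCT", 10)
  r <- ng86_dnds(paste0("TTT", pad), paste0("TTC", pad))
  expect_equal(r$S, 31 / 3)
  expect_equal(r$N, 33 - 31 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dS, -3 / 4 * log(1 - 4 / 3 * (1 / (31 / 3))))
  expect_equal(r$dN, 0)
})

test_that("ng86_dnds is symmetric and rejects bad input", {
  p <- make_codon_pair(60, 4, 3, seed = 21)
  r1 <- ng86_dnds(p$a, p$b)
  r2 <- ng86_dnds(p$b, p$a)
  expect_equal(r1$dN, r2$dN)
  expect_equal(r1$dS, r2$dS)

  expect_error(ng86_dnds("ATGC", "ATGC"), "divisible")
  expect_error(ng86_dnds("AT-", "ATG"), "gaps and ambiguity")
  expect_error(ng86_dnds("ATGTAA", "ATGTAA"), "stop codon")
  # saturated: all three positions differ nonsynonymously in one codon
  expect_error(ng86_dnds("TTT", "AGG"), "saturation")
})

test_that("ng86 site counts match exhaustive per-codon enumeration", {
  for (seed in 1:8) {
    p <- random_codon_pair(40, 12, seed = 100 + seed)
    r <- ng86_dnds(p$a, p$b)
    codons_a <- substring(p$a, seq(1, nchar(p$a), 3), seq(3, nchar(p$a), 3))
    codons_b <- substring(p$b, seq(1, nchar(p$b), 3), seq(3, nchar(p$b), 3))
    S_oracle <- (sum(vapply(codons_a, syn_sites_oracle, 0)) +
                 sum(vapply(codons_b, syn_sites_oracle, 0))) / 2
    expect_equal(r$S, S_oracle, tolerance = 1e-12)
    expect_equal(r$N, 3 * 40 - S_oracle, tolerance = 1e-12)
  }
})

test_that("constructed pairs yield exactly the requested difference
           counts", {
  p <- make_codon_pair(100, 3, 0, seed = 22)
  r <- ng86_dnds(p$a, p$b)
  expect_equal(r$Sd, 3)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)

  p2 <- make_codon_pair(100, 5, 7, seed = 23)
  r2 <- ng86_dnds(p2$a, p2$b)
  expect_equal(r2$Sd, 5)
  expect_equal(r2$Nd, 7)
  expect_gt(r2$omega, 0)
})

test_that("ng86 is invariant to identical synonymous recoding of both
           sequences", {
  p <- make_codon_pair(80, 6, 4, seed = 24)
  r <- ng86_dnds(p$a, p$b)
  recode <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    codons <- ifelse(codons == "GCT", "GCC", codons)  # Ala fourfold swap
    paste(codons, collapse = "")
  }
  # only recode codons identical in both sequences
  ca <- substring(p$a, seq(1, nchar(p$a), 3), seq(3, nchar(p$a), 3))
  cb <- substring(p$b, seq(1, nchar(p$b), 3), seq(3, nchar(p$b), 3))
  same <- ca == cb & ca == "GCT"
  ca[same] <- "GCC"
  cb[same] <- "GCC"
  r2 <- ng86_dnds(paste(ca, collapse = ""), paste(cb, collapse = ""))
  expect_equal(r2$dN, r$dN, tolerance = 1e-12)
  expect_equal(r2$dS, r$dS, tolerance = 1e-12)
})

test_that("select_genomes applies inclusive thresholds, the CPR exception,
           downsampling and the singleton rule", {
  meta <- data.frame(
    accession = c("edge1", "cpr82", "reg82", "bad_cont"),
    genus = c("g1", "g1", "g2", "g2"),
    class = "c1",
    completeness = c(95, 82, 82, 99),
    contamination = c(5, 5, 1, 5.1),
    is_cpr = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  sel <- select_genomes(meta, seed = 1)
  expect_true("edge1" %in% sel$accessions)   # 95 / 5 inclusive
  expect_true("cpr82" %in% sel$accessions)   # CPR relaxed completeness
  expect_false("reg82" %in% sel$accessions)
  expect_false("bad_cont" %in% sel$accessions)
  # g1 retains two genomes; g2 loses both, so no singleton remains
  expect_setequal(sel$accessions, c("edge1", "cpr82"))
})

test_that("select_genomes downsampling matches a recount oracle and is
           seed-reproducible", {
  set.seed(30)
  n <- 2000
  meta <- data.frame(
    accession = sprintf("A%04d", seq_len(n)),
    genus = sample(sprintf("g%03d", 1:300), n, TRUE),
    class = rep(c("c1", "c2", "c3"), c(700, 600, 700)),
    completeness = runif(n, 85, 100),
    contamination = runif(n, 0, 10),
    is_cpr = FALSE,
    stringsAsFactors = FALSE)
  sel <- select_genomes(meta, seed = 42, class_cap = 300)
  # oracle recount: QC filter, then cap per class, then genus >= 2
  qc <- meta[meta$completeness >= 95 & meta$contamination <= 5, ]
  expect_equal(sel$log$remaining[1], nrow(qc))
  expect_true(all(table(meta$class[meta$accession %in% sel$accessions])
                  <= 300))
  expect_true(all(sel$accessions %in% qc$accession))
  gs <- table(meta$genus[meta$accession %in% sel$accessions])
  expect_true(all(gs >= 2))

  sel2 <- select_genomes(meta, seed = 42, class_cap = 300)
  expect_identical(sel$accessions, sel2$accessions)
  sel3 <- select_genomes(meta, seed = 43, class_cap = 300)
  # QC rule is seed-free
  expect_equal(sel3$log$remaining[1], sel$log$remaining[1])
})
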
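## Config-driven end-to-end runner: signal statistics -> model-comparison
## table -> GLS/PGLS regression table -> optional per-group signal, with a
## machine-readable provenance log (input hashes, seed, filters, boundary
## hits). Reports are TSV with fixed column order so reruns diff cleanly.

#' Read a run configuration
#'
#' JSON (always) or YAML (when the `yaml` package is installed). Relative
#' paths are resolved against the config file's directory.
#'
#' @param path Config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config given but the 'yaml' package is not installed; ",
           "use JSON", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("tree", "traits", "pairs", "metadata")) {
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  }
  as_run_config(cfg)
}

#' Construct a run configuration from a list
#'
#' @param cfg Named list with at least `tree`, `traits`, `seed` and
#'   `outdir`. Optional: `pairs`, `metadata`, `columns` (mapping
#'   `genome_size`, `dnds`, `rrn16s` to trait-table column names),
#'   `group_column`, `models`, `n_perm`.
#' @return A validated `run_config` list.
#' @export
as_run_config <- function(cfg) {
  for (f in c("tree", "traits", "seed", "outdir"))
    if (is.null(cfg[[f]]))
      stop("config field '", f, "' is mandatory", call. = FALSE)
  defaults <- list(
    columns = list(genome_size = "genome_size", dnds = "dnds_median",
                   rrn16s = "rrn16s_copies"),
    models = c("bm", "white", "lambda", "ou", "eb", "trend", "drift"),
    n_perm = 999L)
  for (f in names(defaults))
    if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm)
  structure(cfg, class = "run_config")
}

#' Validate pipeline inputs without fitting anything
#'
#' Checks file existence, tree invariants, trait-table shape, tip overlap
#' and (when pairwise data are supplied) previews the filter consequences.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @return List of validation facts; errors on violated invariants.
#' @export
validate_inputs <- function(config) {
  for (f in c("tree", "traits"))
    if (!file.exists(config[[f]]))
      stop("input file not found: ", config[[f]], call. = FALSE)
  tree <- read_newick(config$tree)
  traits <- read_trait_table(config$traits)
  cols <- config$columns
  missing_cols <- setdiff(unlist(cols), colnames(traits))
  if (length(missing_cols))
    stop("trait column(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  overlap <- intersect(tree$tip.label, rownames(traits))
  out <- list(n_tips = ape::Ntip(tree),
              n_trait_rows = nrow(traits),
              n_overlap = length(overlap),
              per_column_complete = vapply(
                unlist(cols), function(cn)
                  sum(!is.na(traits[overlap, cn])), 0L))
  if (length(overlap) < 3L)
    stop("only ", length(overlap),
         " tips shared between tree and traits; cannot fit any model",
         call. = FALSE)
  if (!is.null(config$pairs)) {
    pairs <- utils::read.delim(config$pairs, stringsAsFactors = FALSE)
    fl <- filter_pairwise(pairs)
    out$pairs_filter_preview <- fl$log
    out$pairs_kept <- fl$n_kept
  }
  out
}

reg_row <- function(label, fit, r2_kind) {
  tr <- fit$transforms
  fmt_tr <- function(nm) {
    t <- tr[[nm]]
    if (is.null(t)) return(NA_character_)
    if (!all(is.na(t$ci)))
      sprintf("%.3g (%.3g-%.3g)", t$value, t$ci[1L], t$ci[2L])
    else sprintf("%.3g (fixed)", t$value)
  }
  slopes <- setdiff(names(fit$coefficients), "(Intercept)")
  data.frame(
    model = label, method = fit$method,
    predictors = paste(slopes, collapse = " + "),
    kappa = fmt_tr("kappa"), lambda = fmt_tr("lambda"),
    delta = fmt_tr("delta"),
    slope = paste(sprintf("%.4g", fit$coefficients[slopes]),
                  collapse = "/"),
    intercept = sprintf("%.4g", fit$coefficients[["(Intercept)"]]),
    p_value = fit$p_model, AIC = fit$AIC,
    R2 = if (r2_kind == "nagelkerke") fit$r2_nagelkerke
         else fit$r2_multiple,
    R2_kind = r2_kind,
    R2_nagelkerke = fit$r2_nagelkerke, R2_multiple = fit$r2_multiple,
    logLik = fit$loglik, n = fit$n, stringsAsFactors = FALSE)
}

model_table_row <- function(fit) {
  pars <- paste(sprintf("%s = %.4g", names(fit$params),
                        unlist(fit$params)), collapse = "; ")
  data.frame(model = fit$model, logLik = fit$loglik, k = fit$k,
             AIC = fit$AIC, parameters = pars,
             boundary = paste(fit$boundary, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Run the full comparative analysis
#'
#' Reproduces the analysis workflow end to end: (1) trait-evolution model
#' table for genome size; (2) phylogenetic-signal statistics (Blomberg's K
#' with permutations, Pagel's lambda with CI, marginal kappa and delta) for
#' genome size and lambda for dN/dS; (3) GLS and PGLS regressions of genome
#' size on dN/dS and 16S copy number (individually and additively), a
#' BM-residual PGLS for 16S, and the nested ANOVA; (4) optional per-group
#' signal; plus a JSON provenance log. If a pairwise dN/dS table is
#' supplied it is filtered and aggregated to per-genus medians first.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the report paths and the in-memory
#'   objects.
#' @export
run_comparative_analysis <- function(config) {
  config <- as_run_config(unclass(config))
  val <- validate_inputs(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  tree <- read_newick(config$tree)
  traits <- read_trait_table(config$traits)
  cols <- config$columns
  seed <- config$seed
  log <- list(seed = seed,
              inputs = lapply(config[c("tree", "traits", "pairs",
                                       "metadata")],
                              function(p) if (is.null(p)) NULL else
                                list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
              validation = val)

  ## optional upstream: pairwise dN/dS filtering -> per-genus medians
  if (!is.null(config$pairs)) {
    pairs <- utils::read.delim(config$pairs, stringsAsFactors = FALSE)
    fl <- filter_pairwise(pairs)
    supported <- genome_min_support(fl$kept,
                                    min_estimates = config$min_estimates %||% 25L)
    med <- median_dnds(fl$kept, genomes = supported)
    utils::write.table(med, file.path(config$outdir, "dnds_medians.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log$pairwise_filter <- fl$log
    log$genomes_retained <- length(supported)
  }

  ## (1) model table on genome size
  al <- align_tree_and_traits(tree, traits, cols$genome_size)
  log$dropped_tips <- al$dropped
  fits <- fit_models(al$tree, al$y, models = config$models)
  cmp <- compare_models(fits)
  mt <- do.call(rbind, lapply(fits[match(cmp$model,
                                         vapply(fits, `[[`, "", "model"))],
                              model_table_row))
  mt <- cbind(mt, cmp[, c("dAIC", "LRT_vs_BM", "LRT_p", "best")])
  utils::write.table(mt, file.path(config$outdir, "model_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## (2) signal statistics
  K <- blomberg_k(al$tree, al$y, n_perm = config$n_perm, seed = seed)
  L <- lambda_signal(al$tree, al$y)
  kd <- kappa_delta(al$tree, al$y)
  sig <- data.frame(
    trait = cols$genome_size,
    statistic = c("K", "lambda", "kappa", "delta"),
    estimate = c(K$estimate, L$estimate, kd$kappa$estimate,
                 kd$delta$estimate),
    ci_lo = c(NA, L$ci[1L], kd$kappa$ci[1L], kd$delta$ci[1L]),
    ci_hi = c(NA, L$ci[2L], kd$kappa$ci[2L], kd$delta$ci[2L]),
    p_value = c(K$p_value, L$p_value, NA, NA),
    boundary = c(FALSE, L$boundary, kd$kappa$boundary, kd$delta$boundary),
    n = c(K$n, L$n, kd$kappa$n, kd$delta$n), stringsAsFactors = FALSE)
  if (!is.null(cols$dnds) && cols$dnds %in% colnames(traits)) {
    ald <- align_tree_and_traits(tree, traits, cols$dnds)
    Ld <- lambda_signal(ald$tree, ald$y)
    sig <- rbind(sig, data.frame(
      trait = cols$dnds, statistic = "lambda", estimate = Ld$estimate,
      ci_lo = Ld$ci[1L], ci_hi = Ld$ci[2L], p_value = Ld$p_value,
      boundary = Ld$boundary, n = Ld$n, stringsAsFactors = FALSE))
  }
  utils::write.table(sig, file.path(config$outdir, "signal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## per-group signal
  if (!is.null(config$group_column) &&
      config$group_column %in% colnames(traits)) {
    grouping <- stats::setNames(as.character(traits[[config$group_column]]),
                                rownames(traits))
    bg <- signal_by_group(tree, traits, cols$genome_size, grouping,
                          n_perm = config$n_perm, seed = seed)
    utils::write.table(bg, file.path(config$outdir, "signal_by_group.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## (3) regression table
  make_xy <- function(pred_cols) {
    use <- c(cols$genome_size, pred_cols)
    ok <- rownames(traits)[stats::complete.cases(traits[, use, drop = FALSE])]
    keep <- intersect(tree$tip.label, ok)
    tr2 <- ape::keep.tip(tree, keep)
    y <- stats::setNames(traits[tr2$tip.label, cols$genome_size],
                         tr2$tip.label)
    X <- cbind("(Intercept)" = 1,
               as.matrix(traits[tr2$tip.label, pred_cols, drop = FALSE]))
    rownames(X) <- tr2$tip.label
    list(tree = tr2, y = y, X = X)
  }
  ml3 <- list(kappa = "ML", lambda = "ML", delta = "ML")
  have <- function(cn) !is.null(cn) && cn %in% colnames(traits)
  specs <- list()
  if (have(cols$dnds))
    specs <- c(specs, list(list(label = "genome_size ~ dnds",
                                pred = cols$dnds)))
  if (have(cols$rrn16s))
    specs <- c(specs, list(list(label = "genome_size ~ rrn16s",
                                pred = cols$rrn16s)))
  if (have(cols$dnds) && have(cols$rrn16s))
    specs <- c(specs, list(list(label = "genome_size ~ dnds + rrn16s",
                                pred = c(cols$dnds, cols$rrn16s))))
  rows <- list(); pg <- list()
  for (s in specs) {
    d <- make_xy(s$pred)
    g <- gls_fit(d$y, d$X, response = cols$genome_size)
    rows[[paste0("gls:", s$label)]] <- reg_row(s$label, g, "nagelkerke")
  }
  for (s in specs) {
    d <- make_xy(s$pred)
    p <- pgls_fit(d$tree, d$y, d$X, transforms = ml3,
                  response = cols$genome_size)
    pg[[s$label]] <- p
    rows[[paste0("pgls:", s$label)]] <- reg_row(s$label, p, "multiple")
  }
  an <- NULL
  if (have(cols$rrn16s)) {
    d16 <- make_xy(cols$rrn16s)
    bm16 <- pgls_fit_bm(d16$tree, d16$y, d16$X, response = cols$genome_size)
    rows[["pgls_bm:genome_size ~ rrn16s"]] <-
      reg_row("genome_size ~ rrn16s (BM residuals)", bm16, "nagelkerke")
  }
  reg <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(reg, file.path(config$outdir, "regression_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## nested ANOVA: 16S-only vs 16S + dN/dS (on their common tip set)
  if (have(cols$dnds) && have(cols$rrn16s)) {
    dboth <- make_xy(c(cols$dnds, cols$rrn16s))
    f_small <- pgls_fit(dboth$tree, dboth$y,
                        dboth$X[, c("(Intercept)", cols$rrn16s)],
                        transforms = ml3, response = cols$genome_size,
                        ci = FALSE)
    an <- anova_nested(f_small, pg[["genome_size ~ dnds + rrn16s"]])
    log$anova_16s_vs_both <- an[c("F", "df1", "df2", "p_value", "lrt",
                                  "p_lrt")]
  }
  log$boundary_hits <- lapply(fits, `[[`, "boundary")
  jsonlite::write_json(log, file.path(config$outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(list(
    paths = file.path(config$outdir,
                      c("model_table.tsv", "signal.tsv",
                        "regression_table.tsv", "run_log.json")),
    model_table = mt, signal = sig, regression = reg, anova = an,
    fits = fits, pgls = pg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
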
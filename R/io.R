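#' Read survival outcomes from a delimited text file
#'
#' Expects columns `sample_id`, `time`, `status`. The delimiter is chosen
#' by extension: comma for `.csv`, tab otherwise.
#'
#' @param path File path.
#' @return A [survival_outcome()] with sample IDs attached.
#' @export
read_outcome <- function(path) {
  d <- read_delimited(path)
  need <- c("sample_id", "time", "status")
  if (!all(need %in% names(d)))
    stop("outcome file must have columns sample_id, time, status")
  tm <- suppressWarnings(as.numeric(d$time))
  st <- suppressWarnings(as.numeric(d$status))
  if (anyNA(tm)) stop("non-numeric time for sample ",
                      d$sample_id[which(is.na(tm))[1L]])
  if (any(tm <= 0)) stop("non-positive time for sample ",
                         d$sample_id[which(tm <= 0)[1L]])
  if (anyNA(st) || !all(st %in% c(0, 1)))
    stop("status must be 0/1 (sample ",
         d$sample_id[which(is.na(st) | !(st %in% c(0, 1)))[1L]], ")")
  survival_outcome(tm, st, id = as.character(d$sample_id))
}

#' Read a sample-by-variable matrix from a delimited text file
#'
#' Expects a header row of variable IDs, a first column `sample_id`, and
#' one row per sample. Missing or non-numeric entries are rejected (no
#' imputation).
#'
#' @param path File path.
#' @return Numeric matrix with sample IDs as row names.
#' @export
read_matrix <- function(path) {
  d <- read_delimited(path)
  if (names(d)[1L] != "sample_id")
    stop("first column must be sample_id")
  ids <- as.character(d[[1L]])
  M <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!vapply(d[, -1L, drop = FALSE], is.numeric, logical(1)))[1L]
    stop("non-numeric entries in column '", names(d)[-1L][bad], "'")
  }
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop("missing value at sample ", ids[idx[1L]], ", variable ",
         colnames(M)[idx[2L]], " (no imputation is performed)")
  }
  rownames(M) <- ids
  M
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read and align fine-mapping inputs
#'
#' Reads a genotype matrix, an outcome file, and optionally a covariate
#' matrix, and aligns all of them by `sample_id` (a hard error if the ID
#' sets differ). If the genotype file's sample IDs instead match the
#' outcome IDs in its header, the file was probably written with variants
#' as rows and the error says so.
#'
#' @param genotype_path,outcome_path,covariate_path File paths
#'   (`covariate_path` optional).
#' @return List with `X`, `outcome`, and `Z` (`NULL` if no covariates).
#' @export
read_inputs <- function(genotype_path, outcome_path,
                        covariate_path = NULL) {
  outcome <- read_outcome(outcome_path)
  X <- read_matrix(genotype_path)
  if (!setequal(rownames(X), outcome$id)) {
    if (any(outcome$id %in% colnames(X)))
      stop("genotype sample IDs do not match the outcome file, but the ",
           "genotype header contains outcome sample IDs: the genotype ",
           "file appears to store variants as rows; transpose it")
    stop("sample IDs in the genotype file do not match the outcome file")
  }
  X <- X[match(outcome$id, rownames(X)), , drop = FALSE]
  Z <- NULL
  if (!is.null(covariate_path)) {
    Z <- read_matrix(covariate_path)
    if (!setequal(rownames(Z), outcome$id))
      stop("sample IDs in the covariate file do not match the outcome file")
    Z <- Z[match(outcome$id, rownames(Z)), , drop = FALSE]
  }
  list(X = X, outcome = outcome, Z = Z)
}

#' Write fit results to a directory
#'
#' Writes `pip.csv` (variant ID, PIP, and per-effect inclusion weights),
#' `credible_sets.csv` (the [credible_sets()] table), and `manifest.json`
#' recording the call configuration, seed, package version, iteration
#' count and convergence flag — enough to replay the run.
#'
#' @param fit A [coxph_susie()] fit.
#' @param outdir Output directory (created if missing).
#' @param cs_list Credible sets to write (default `fit$sets`).
#' @param config Optional named list recorded verbatim in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, outdir, cs_list = fit$sets, config = NULL) {
  stopifnot(inherits(fit, "coxph_susie"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pip_path <- file.path(outdir, "pip.csv")
  alpha_t <- t(fit$alpha)
  colnames(alpha_t) <- paste0("alpha_l", seq_len(fit$L))
  pip_tab <- data.frame(variant_id = fit$variable_names,
                        pip = unname(fit$pip),
                        alpha_t, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write.csv(pip_tab, pip_path, row.names = FALSE)
  cs_path <- file.path(outdir, "credible_sets.csv")
  write.csv(as.data.frame(cs_list), cs_path, row.names = FALSE)
  manifest <- list(
    package = "coxsusie",
    version = as.character(packageVersion("coxsusie")),
    config = config,
    L = fit$L, n = fit$n, p = fit$p,
    sigma0sq = fit$sigma0sq,
    estimate_sigma0sq = fit$estimate_sigma0sq,
    ties = fit$ties, rho = fit$rho, min_purity = fit$min_purity,
    n_iter = fit$n_iter, converged = fit$converged,
    null_effect = fit$null_effect)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(pip = pip_path, cs = cs_path, manifest = manifest_path))
}

#' Write simulated data in the package's interchange format
#'
#' Companion to [make_finemap_dataset()]: writes `genotypes.csv`,
#' `outcome.csv` and `truth.csv` under `outdir` in the formats accepted by
#' [read_inputs()].
#'
#' @param dat A [make_finemap_dataset()] result.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dat, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- paste0("s", seq_len(nrow(dat$X)))
  g <- data.frame(sample_id = ids, dat$X, check.names = FALSE)
  gp <- file.path(outdir, "genotypes.csv")
  write.csv(g, gp, row.names = FALSE)
  o <- data.frame(sample_id = ids, time = dat$outcome$time,
                  status = dat$outcome$status)
  op <- file.path(outdir, "outcome.csv")
  write.csv(o, op, row.names = FALSE)
  tr <- data.frame(variant_id = colnames(dat$X),
                   causal = as.integer(dat$truth))
  tp <- file.path(outdir, "truth.csv")
  write.csv(tr, tp, row.names = FALSE)
  invisible(c(genotypes = gp, outcome = op, truth = tp))
}
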
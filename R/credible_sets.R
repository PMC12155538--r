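#' Build a level-rho credible set from an inclusion vector
#'
#' A level-\eqn{\rho} credible set is a set of variables with posterior
#' probability at least \eqn{\rho} of containing the effect variable. It is
#' constructed greedily: sort variables by decreasing \eqn{\alpha_j} (ties
#' broken by ascending index) and take the shortest prefix whose cumulative
#' probability reaches \eqn{\rho}.
#'
#' @param alpha Probability vector summing to 1 (tolerance 1e-8).
#' @param rho Credible level in (0, 1).
#' @return Integer vector of member indices, in decreasing-\eqn{\alpha}
#'   order.
#' @export
build_credible_set <- function(alpha, rho = 0.95) {
  stopifnot(rho > 0, rho < 1)
  if (abs(sum(alpha) - 1) > 1e-8)
    stop("'alpha' must sum to 1")
  ord <- order(-alpha, seq_along(alpha))
  k <- which(cumsum(alpha[ord]) >= rho - 1e-12)[1L]
  if (is.na(k)) k <- length(alpha)   # guard against rounding at rho ~ 1
  ord[seq_len(k)]
}

#' Purity of a credible set
#'
#' The smallest absolute Pearson correlation among all pairs of member
#' columns of `X`. A singleton set has purity 1 by convention (the filter
#' never removes it). A zero-variance member contributes correlation 0 to
#' each of its pairs (with a warning), so sets containing monomorphic
#' variables are heavily penalized.
#'
#' @param members Integer vector of column indices.
#' @param X Numeric `n x p` matrix.
#' @return Purity in `[0, 1]`.
#' @export
cs_purity <- function(members, X) {
  members <- as.integer(members)
  if (length(members) == 0L) stop("empty credible set")
  if (any(members < 1L | members > ncol(X))) stop("member index out of range")
  if (length(members) == 1L) return(1)
  Xm <- X[, members, drop = FALSE]
  v <- apply(Xm, 2L, stats::var)
  if (any(v == 0)) {
    warning("zero-variance member column; treating its correlations as 0")
    return(0)
  }
  r <- abs(cor(Xm))
  min(r[upper.tri(r)])
}

# mean absolute pairwise correlation (the MAS statistic); singleton -> 1
cs_mas <- function(members, X) {
  if (length(members) == 1L) return(1)
  Xm <- X[, members, drop = FALSE]
  if (any(apply(Xm, 2L, stats::var) == 0)) return(0)
  r <- abs(cor(Xm))
  mean(r[upper.tri(r)])
}

#' Extract purity-filtered credible sets from a CoxPH-SuSiE fit
#'
#' Builds one candidate level-`rho` credible set per active (non-null)
#' single effect, drops sets with purity below `min_purity` (default 0.5),
#' deduplicates identical member sets (keeping the lowest effect index),
#' and labels retained sets `L1, L2, ...` in effect order. Each set records
#' its sentinel variable — the member with the largest within-effect
#' \eqn{\alpha} (ties broken by ascending index) — and the sentinel's
#' overall PIP.
#'
#' @param fit A [coxph_susie()] fit.
#' @param X The covariate matrix used for fitting (for purity).
#' @param rho Credible level.
#' @param min_purity Minimum purity for a set to be retained.
#' @return An object of class `"credible_set_list"`: a list of credible
#'   sets, each a list with `label`, `effect_index`, `members`, `rho`,
#'   `attained_mass`, `purity`, `sentinel`, `sentinel_name`,
#'   `sentinel_pip`. Coerce with `as.data.frame()` for a report table.
#' @export
credible_sets <- function(fit, X, rho = 0.95, min_purity = 0.5) {
  stopifnot(inherits(fit, "coxph_susie"))
  X <- as.matrix(X)
  if (ncol(X) != fit$p) stop("X has wrong number of columns")
  out <- list()
  seen <- character(0)
  for (l in seq_len(fit$L)) {
    if (fit$null_effect[l]) next
    a <- fit$alpha[l, ]
    members <- build_credible_set(a, rho)
    key <- paste(sort(members), collapse = ",")
    if (key %in% seen) next
    pur <- cs_purity(members, X)
    if (pur < min_purity) next
    seen <- c(seen, key)
    sentinel <- members[order(-a[members], members)][1L]
    out[[length(out) + 1L]] <- list(
      label = paste0("L", length(out) + 1L),
      effect_index = l,
      members = members,
      rho = rho,
      attained_mass = sum(a[members]),
      purity = pur,
      sentinel = sentinel,
      sentinel_name = fit$variable_names[sentinel],
      sentinel_pip = unname(fit$pip[sentinel] %||%
                              compute_pip(fit)[sentinel]))
  }
  structure(out, class = "credible_set_list")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.credible_set_list <- function(x, ...) {
  if (length(x) == 0L) {
    cat("No credible sets retained.\n")
    return(invisible(x))
  }
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.credible_set_list <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(label = character(0), effect = integer(0),
                      size = integer(0), purity = numeric(0),
                      sentinel_id = character(0), sentinel_pip = numeric(0),
                      attained_mass = numeric(0), members = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(x, function(cs) data.frame(
    label = cs$label,
    effect = cs$effect_index,
    size = length(cs$members),
    purity = cs$purity,
    sentinel_id = cs$sentinel_name %||% as.character(cs$sentinel),
    sentinel_pip = cs$sentinel_pip,
    attained_mass = cs$attained_mass,
    members = paste(cs$members, collapse = ";"),
    stringsAsFactors = FALSE)))
}
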
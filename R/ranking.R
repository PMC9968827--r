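# Multi-dipole source configurations and ranking against empirical
# topographies.

#' Enumerate all non-empty source configurations
#'
#' All `2^n - 1` non-empty subsets of the candidate source labels, in a
#' deterministic order (by increasing bitmask; subsets of earlier labels
#' first).
#'
#' @param labels character vector of candidate source labels (1 to 16).
#' @return list of character vectors.
#' @examples
#' length(enumerateConfigurations(c("V4", "lusV4", "LIP", "7a", "FEF")))  # 31
#' @export
enumerateConfigurations <- function(labels) {
  n <- length(labels)
  if (n < 1L) stop("at least one source label is required")
  if (n > 16L) stop("at most 16 sources are supported")
  lapply(seq_len(2^n - 1L), function(maskIdx)
    labels[bitwAnd(maskIdx, bitwShiftL(1L, seq_len(n) - 1L)) > 0L])
}

#' @noRd
checkSameMontage <- function(a, b) {
  if (!identical(a@labels, b@labels))
    stop("topographies use different montages")
}

#' Sum scalp topographies electrode-wise
#'
#' Voltages of a combined source configuration: the electrode-wise sum of the
#' member sources' topographies (identical montages required).
#'
#' @param topos list of \linkS4class{ScalpTopography} objects.
#' @param condition condition tag for the result.
#' @return a \linkS4class{ScalpTopography}.
#' @export
sumTopographies <- function(topos, condition = "sum") {
  if (!length(topos)) stop("no topographies to sum")
  out <- topos[[1]]
  if (length(topos) > 1L) for (tp in topos[-1]) {
    checkSameMontage(out, tp)
    if (!all(dim(tp@values) == dim(out@values)))
      stop("topographies have mismatched dimensions")
    out@values <- out@values + tp@values
  }
  out@condition <- condition
  out
}

#' Difference topography (contra minus ipsi)
#'
#' @param contra,ipsi \linkS4class{ScalpTopography} objects on the same
#'   montage.
#' @return a \linkS4class{ScalpTopography} tagged `"difference"`.
#' @export
differenceTopography <- function(contra, ipsi) {
  checkSameMontage(contra, ipsi)
  if (!all(dim(contra@values) == dim(ipsi@values)))
    stop("topographies have mismatched dimensions")
  out <- contra
  out@values <- contra@values - ipsi@values
  out@condition <- "difference"
  out
}

#' Average a topography over a time window
#'
#' @param topo a \linkS4class{ScalpTopography} with a time axis.
#' @param window length-2 window in ms (default 150-190, the N2pc epoch).
#' @return a static \linkS4class{ScalpTopography} (one column).
#' @export
windowTopography <- function(topo, window = c(150, 190)) {
  if (topo@dt <= 0) return(topo)
  tt <- timeAxisOf(ncol(topo@values), topo@dt)
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop("the window contains no samples")
  topo@values <- matrix(rowMeans(topo@values[, sel, drop = FALSE]), ncol = 1L)
  topo@dt <- 0
  topo
}

#' Rank source configurations against an empirical topography
#'
#' For every non-empty combination of the candidate sources, sums the
#' per-session modeled maps of its members, pools electrodes across sessions
#' into a single Pearson correlation with the empirical map
#' (`n_elec x n_sessions` points per configuration), and ranks configurations
#' by R-squared. Negatively correlated configurations are not considered
#' (their R-squared is recorded as 0). Significance uses a Bonferroni
#' correction over the number of configurations.
#'
#' @param modeled named list, one entry per candidate source, each an
#'   (n_elec x n_sessions) matrix of per-session modeled maps (uV), rows in
#'   the order of `empirical`.
#' @param empirical numeric vector of the empirical per-electrode map (uV).
#' @param alpha family-wise significance level (default 0.05).
#' @return a \linkS4class{ConfigurationRanking}.
#' @export
rankAgainstEmpirical <- function(modeled, empirical, alpha = 0.05) {
  if (is.null(names(modeled)) || anyDuplicated(names(modeled)))
    stop("modeled must be a named list with unique source labels")
  nelec <- length(empirical)
  nses <- unique(vapply(modeled, ncol, 1L))
  if (length(nses) != 1L) stop("all sources must have the same session count")
  if (nses < 2L) stop("at least 2 sessions are required")
  if (any(vapply(modeled, nrow, 1L) != nelec))
    stop("modeled maps and the empirical map use different montages")
  if (nelec * nses < 3L) stop("fewer than 3 pooled points")
  if (sd(empirical) == 0) stop("the empirical map has zero variance")

  configs <- enumerateConfigurations(names(modeled))
  empPooled <- rep(empirical, nses)
  rows <- lapply(configs, function(cfg) {
    mdl <- Reduce(`+`, modeled[cfg])
    if (sd(as.vector(mdl)) == 0) stop("a modeled configuration has zero variance")
    ct <- cor.test(empPooled, as.vector(mdl), method = "pearson",
                   alternative = "two.sided")
    data.frame(configuration = paste(cfg, collapse = "+"),
               nSources = length(cfg), r = unname(ct$estimate),
               R2 = if (ct$estimate >= 0) unname(ct$estimate)^2 else 0,
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$r >= 0 & (tab$p * nrow(tab) <= alpha)
  tab <- tab[order(-tab$R2, tab$configuration), ]
  rownames(tab) <- NULL
  new("ConfigurationRanking", table = tab,
      winner = strsplit(tab$configuration[1], "+", fixed = TRUE)[[1]],
      alpha = alpha, nSessions = as.integer(nses))
}
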
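## Relative expression by the 2^-ddCt method and the Mann-Whitney rank-sum
## comparison used to contrast groups of relative-expression values.

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, `delta_ct = target Ct - reference Ct` (reference gene
#' normalization, e.g. GAPDH), `ddct = delta_ct - delta_ct(calibrator)`,
#' and `rq = 2^-ddct`. The calibrator is either a named sample (whose `rq`
#' is then exactly 1) or the mean `delta_ct` of a named group; the default
#' calibrates to the mean of the primary-tumour (pCRC) group so that `rq`
#' expresses fold change of metastatic over primary expression.
#'
#' @param records data.frame with columns `sample_id`, `group`,
#'   `target_ct`, `reference_ct`
#' @param calibrator a sample id present in `records`, or
#'   `"group:<name>"` to use a group's mean delta Ct (default
#'   `"group:pCRC"`)
#' @return data.frame with columns `sample_id`, `group`, `delta_ct`,
#'   `ddct`, `rq`.
#' @export
ddct <- function(records, calibrator = "group:pCRC") {
  need <- c("sample_id", "group", "target_ct", "reference_ct")
  missing <- setdiff(need, names(records))
  if (length(missing))
    .stopf("ddct: required column(s) absent: %s", paste(missing, collapse = ", "))
  if (anyNA(records$reference_ct))
    .stopf("ddct: missing reference Ct for sample(s): %s",
           paste(records$sample_id[is.na(records$reference_ct)], collapse = ", "))
  if (anyNA(records$target_ct))
    .stopf("ddct: missing target Ct for sample(s): %s",
           paste(records$sample_id[is.na(records$target_ct)], collapse = ", "))
  dct <- records$target_ct - records$reference_ct
  if (startsWith(calibrator, "group:")) {
    grp <- sub("^group:", "", calibrator)
    sel <- records$group == grp
    if (!any(sel)) .stopf("ddct: calibrator group '%s' has no samples", grp)
    cal <- mean(dct[sel])
  } else {
    sel <- records$sample_id == calibrator
    if (!any(sel)) .stopf("ddct: calibrator sample '%s' not found", calibrator)
    cal <- dct[which(sel)[1]]
  }
  dd <- dct - cal
  data.frame(sample_id = records$sample_id, group = records$group,
             delta_ct = dct, ddct = dd, rq = 2^(-dd),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with mid-ranks for ties. The two-sided p-value is exact by
#' complete enumeration of all labelings when `length(x) + length(y) <= 12`
#' (exactness holds with ties because the permutation distribution of the
#' mid-rank U is enumerated directly); otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty
#' @return list with `U` (for `x`), `p` (two-sided) and `method`.
#'   When every value in both groups is identical the test is degenerate:
#'   `p = 1` is returned with a warning.
#' @export
rankSumTest <- function(x, y) {
  if (!length(x) || !length(y)) .stopf("rankSumTest: both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; degenerate data, p = 1")
    return(list(U = nx * ny / 2, p = 1, method = "degenerate"))
  }
  r <- rank(pooled)  # mid-ranks
  Ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= 12L) {
    ## enumerate U over all choose(n, nx) labelings of the mid-ranks
    combos <- combn(n, nx)
    Us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(Ux - mu) - 1e-9)
    return(list(U = Ux, p = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (Ux - mu - sign(Ux - mu) * 0.5) / sqrt(sigma2)
  list(U = Ux, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}
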
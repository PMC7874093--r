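#' Vovk-Sellke maximum Bayes factor bound
#'
#' The largest Bayes factor in favour of H1 attainable from a p value:
#' `-1 / (e * p * log(p))` for `p < 1/e`, and 1 otherwise. Strictly
#' decreasing on (0, 1/e).
#'
#' @param p P value(s) in (0, 1].
#' @return The bound (vectorised).
#' @export
#' @examples
#' round(vovk_sellke(0.05), 2)  # 2.46
vovk_sellke <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("`p` must lie in (0, 1]", call. = FALSE)
  ifelse(p < exp(-1), -1 / (exp(1) * p * log(p)), 1)
}

#' Invert the Vovk-Sellke bound
#'
#' Finds the unique `p < 1/e` whose Vovk-Sellke bound equals `bf`
#' (monotone root finding); `inverse_vovk_sellke(1)` is `1/e`.
#'
#' @param bf Bound value(s) `>= 1`.
#' @return P value(s).
#' @export
#' @examples
#' inverse_vovk_sellke(vovk_sellke(0.01))  # 0.01
inverse_vovk_sellke <- function(bf) {
  if (any(!is.finite(bf)) || any(bf < 1))
    stop("`bf` must be >= 1", call. = FALSE)
  one <- function(b) {
    if (b == 1) return(exp(-1))
    exp(uniroot(function(lp) log(vovk_sellke(exp(lp))) - log(b),
                lower = log(1e-300), upper = -1, tol = 1e-14)$root)
  }
  vapply(bf, one, 0)
}

#' Configuration of the Bayes-factor FDR procedure
#'
#' Bundles the parameters of the multiplicity correction: the family size
#' `m`, the false discovery rate `q`, and the candidacy screens — the
#' Bayes factors corresponding to `p = alpha_anchor` under the
#' Vovk-Sellke bound (`screen_h1`, about 2.46 at the 0.05 anchor) and its
#' reciprocal (`screen_h0`, about 0.406). Results with BF10 between the
#' screens are inconclusive and never retained.
#'
#' @param m Number of tests in the family (default 7).
#' @param q False discovery rate (default 0.25).
#' @param alpha_anchor P value anchoring the screens (default 0.05).
#' @param method `"per_rank"` (default): each candidate is compared with
#'   the critical Bayes factor of its own rank; `"step_up"`: the
#'   classical Benjamini-Hochberg walk retaining all candidates up to the
#'   largest passing rank.
#' @return A `multiplicity_config` object.
#' @export
multiplicity_config <- function(m = 7, q = 0.25, alpha_anchor = 0.05,
                                method = c("per_rank", "step_up")) {
  method <- match.arg(method)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  if (alpha_anchor <= 0 || alpha_anchor >= 1)
    stop("`alpha_anchor` must lie in (0, 1)", call. = FALSE)
  screen_h1 <- vovk_sellke(alpha_anchor)
  structure(list(m = as.integer(m), q = q, alpha_anchor = alpha_anchor,
                 screen_h1 = screen_h1, screen_h0 = 1 / screen_h1,
                 method = method),
            class = "multiplicity_config")
}

#' @export
print.multiplicity_config <- function(x, ...) {
  cat(sprintf(paste0("FDR B-H correction of Bayes factors: m = %d, ",
                     "q = %g, screens %.3g / %.3g (p = %g anchor), %s\n"),
              x$m, x$q, x$screen_h1, x$screen_h0, x$alpha_anchor,
              x$method))
  invisible(x)
}

#' Rank-specific critical Bayes factor
#'
#' The Benjamini-Hochberg critical p value at rank `k` is
#' `p_k = (k / m) * q`; converted back through the Vovk-Sellke bound it
#' becomes the critical Bayes factor: `VS(p_k)` for the H1 branch and its
#' reciprocal for the H0 branch.
#'
#' @param rank Rank `k` within the sorted branch, `1 <= k <= m`.
#' @param config A [multiplicity_config()].
#' @param branch `"H1"` or `"H0"`.
#' @return The critical Bayes factor.
#' @export
bh_critical_bf <- function(rank, config = multiplicity_config(),
                           branch = c("H1", "H0")) {
  branch <- match.arg(branch)
  stopifnot(inherits(config, "multiplicity_config"))
  if (any(rank < 1) || any(rank > config$m))
    stop("`rank` must lie in 1..m", call. = FALSE)
  crit <- vovk_sellke(rank / config$m * config$q)
  if (branch == "H1") crit else 1 / crit
}

#' FDR filtering of a family of Bayes factors
#'
#' Screens each test into an H1 candidate (`bf10 >= screen_h1`), an H0
#' candidate (`bf10 <= screen_h0`) or inconclusive; sorts H1 candidates in
#' descending and H0 candidates in ascending order of BF10 (ties broken
#' by test id for determinism); assigns each candidate the critical Bayes
#' factor of its rank ([bh_critical_bf()]); and retains a candidate when
#' its BF10 is at least (H1) or at most (H0) its critical value.
#' Candidates failing their critical value are flagged as false positives
#' (`retained = FALSE`); inconclusive tests are never retained.
#'
#' @param results Data frame with columns `test_id` (unique labels) and
#'   `bf10`.
#' @param config A [multiplicity_config()]; its `m` must be at least the
#'   number of tests supplied.
#' @return Data frame in the input row order with columns `test_id`,
#'   `bf10`, `branch`, `rank`, `critical_bf`, `retained`.
#' @export
#' @examples
#' fam <- data.frame(test_id = paste0("t", 1:7),
#'                   bf10 = c(13.7, 6.2, 0.3, 0.3, 15.3, 0.3, 0.3))
#' fdr_filter(fam, multiplicity_config(m = 7, q = 0.25))
fdr_filter <- function(results, config = multiplicity_config()) {
  stopifnot(inherits(config, "multiplicity_config"))
  if (!all(c("test_id", "bf10") %in% names(results)))
    stop("`results` must have columns `test_id` and `bf10`", call. = FALSE)
  if (nrow(results) == 0) stop("`results` is empty", call. = FALSE)
  if (anyDuplicated(results$test_id))
    stop("duplicate test ids", call. = FALSE)
  if (any(results$bf10 <= 0))
    stop("Bayes factors must be positive", call. = FALSE)
  if (nrow(results) > config$m)
    stop("more tests than the family size m", call. = FALSE)

  out <- data.frame(test_id = results$test_id, bf10 = results$bf10,
                    branch = "inconclusive", rank = NA_integer_,
                    critical_bf = NA_real_, retained = FALSE,
                    stringsAsFactors = FALSE)
  out$branch[out$bf10 >= config$screen_h1] <- "H1"
  out$branch[out$bf10 <= config$screen_h0] <- "H0"

  for (br in c("H1", "H0")) {
    idx <- which(out$branch == br)
    if (!length(idx)) next
    ord <- order(if (br == "H1") -out$bf10[idx] else out$bf10[idx],
                 out$test_id[idx])
    idx <- idx[ord]
    k <- seq_along(idx)
    crit <- bh_critical_bf(k, config, br)
    pass <- if (br == "H1") out$bf10[idx] >= crit else out$bf10[idx] <= crit
    if (config$method == "step_up") {
      last <- if (any(pass)) max(which(pass)) else 0L
      pass <- k <= last
    }
    out$rank[idx] <- k
    out$critical_bf[idx] <- crit
    out$retained[idx] <- pass
  }
  out
}
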
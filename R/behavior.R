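#' Composite attitude score
#'
#' Sum of four binary items about the commercial offer, each coded 1
#' (unfavourable pole) or 2 (favourable pole), giving an integer from 4
#' (highest disfavour) to 8 (highest favour).
#'
#' @param item_a,item_b,item_c,item_d Item codes in `{1, 2}` (vectorised).
#' @return Integer vector of composite scores in `[4, 8]`.
#' @export
#' @examples
#' attitude_score(1, 1, 1, 1)  # 4
#' attitude_score(2, 2, 2, 2)  # 8
attitude_score <- function(item_a, item_b, item_c, item_d) {
  items <- cbind(item_a, item_b, item_c, item_d)
  if (!all(items %in% c(1, 2)))
    stop("attitude items must be coded 1 or 2", call. = FALSE)
  as.integer(rowSums(items))
}

#' Investment percentage
#'
#' The amount invested divided by the wallet won in the preceding gambling
#' game, times 100 — normalising willingness to pay across participants.
#'
#' @param invested Invested amount (currency units), `0 <= invested <=
#'   wallet`.
#' @param wallet Wallet total (currency units), strictly positive.
#' @return Percentage in `[0, 100]` (vectorised).
#' @export
#' @examples
#' investment_pct(25000, 50000)  # 50
investment_pct <- function(invested, wallet) {
  if (any(!is.finite(wallet)) || any(wallet <= 0))
    stop("wallet must be positive", call. = FALSE)
  if (any(!is.finite(invested)) || any(invested < 0))
    stop("invested must be non-negative", call. = FALSE)
  if (any(invested > wallet))
    stop("invested cannot exceed the wallet", call. = FALSE)
  100 * invested / wallet
}

#' Score a behavioural response table
#'
#' Appends the composite `attitude` and `investment_pct` columns to a raw
#' behavioural table (as produced by [generate_behavior()] or read from
#' CSV).
#'
#' @param df Data frame with columns `item_a` .. `item_d`, `wallet`,
#'   `invested`.
#' @return The data frame with `attitude` and `investment_pct` appended.
#' @export
score_behavior <- function(df) {
  need <- c("item_a", "item_b", "item_c", "item_d", "wallet", "invested")
  if (!all(need %in% names(df)))
    stop("behaviour table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df$attitude <- attitude_score(df$item_a, df$item_b, df$item_c, df$item_d)
  df$investment_pct <- investment_pct(df$invested, df$wallet)
  df
}
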
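# Population monitoring indices: chewcard interference (CCI), its arcsine
# transform (tCCI), card-weighted block reductions with back-transformed
# asymmetric errors, the residual trap catch index (RTCI), and bait QA.

#' Arcsine-square-root index of a proportion
#'
#' `arcsine_index(p)` returns `arcsin(sqrt(p))` in degrees (0-90). Applied
#' to the chewcard interference proportion it yields the tCCI, a more
#' nearly linear index of population density than the raw CCI, which
#' saturates as interference approaches 100%. `back_transform()` is its
#' exact inverse.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param t transformed value(s) in degrees, \[0, 90\].
#' @return Degrees in \[0, 90\] (or, for `back_transform`, a proportion).
#' @examples
#' arcsine_index(c(0, 0.5, 1)) # 0, 45, 90
#' back_transform(arcsine_index(0.37)) # 0.37
#' @export
arcsine_index <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p)) * 180 / pi
}

#' @rdname arcsine_index
#' @export
back_transform <- function(t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 90))
    stop("transformed values must lie in [0, 90] degrees", call. = FALSE)
  sin(t * pi / 180)^2
}

#' Per-line chewcard index for one session and species
#'
#' The CCI is the percentage of cards on the line interfered with by the
#' species over the session; the tCCI is its arcsine-square-root transform
#' in degrees.
#'
#' @param records chewcard records for a single line and session: a data
#'   frame with a 0/1 column named after `species`.
#' @param species species column to index (e.g. `"possum"`).
#' @return A one-row data frame: `line_id`, `species`, `n_cards`, `cci`,
#'   `tcci`.
#' @examples
#' rec <- data.frame(card_id = 1:20, line_id = "CL01",
#'                   possum = rep(c(1, 0), c(5, 15)))
#' line_cci(rec, "possum") # CCI 25, tCCI 30 degrees
#' @export
line_cci <- function(records, species) {
  if (nrow(records) == 0)
    stop("no chewcard records supplied for this line", call. = FALSE)
  if (!species %in% names(records))
    stop("no column '", species, "' in records", call. = FALSE)
  if (length(unique(records$line_id)) > 1)
    stop("records span more than one line", call. = FALSE)
  cci <- 100 * mean(records[[species]] > 0)
  data.frame(line_id = records$line_id[1], species = species,
             n_cards = nrow(records), cci = cci,
             tcci = arcsine_index(cci / 100))
}

#' Per-line indices for every line in a survey
#'
#' Convenience wrapper applying [line_cci()] across the lines of one
#' session's records.
#'
#' @param records chewcard records for one session (any number of lines).
#' @param species species column to index.
#' @return A data frame with one row per line.
#' @export
line_indices <- function(records, species) {
  out <- lapply(split(records, records$line_id),
                function(r) line_cci(r, species))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$line_id), , drop = FALSE]
}

#' Percentage reduction in tCCI between two sessions of one line
#'
#' `100 * (pre - post) / pre` on the tCCI scale. The ratio is invariant to
#' the angular units used. A line with a pre-control tCCI of zero carries no
#' information about reduction; it is returned as `NA` with
#' `usable = FALSE` and is excluded from block means.
#'
#' @param pre,post one-row [line_cci()] results for the same line.
#' @return A one-row data frame: `line_id`, `species`, `n_cards` (pre),
#'   `reduction_pct`, `usable`.
#' @export
line_reduction <- function(pre, post) {
  if (pre$line_id != post$line_id)
    stop("pre and post indices are for different lines", call. = FALSE)
  usable <- pre$tcci > 0
  data.frame(line_id = pre$line_id, species = pre$species,
             n_cards = pre$n_cards,
             reduction_pct = if (usable)
               100 * (pre$tcci - post$tcci) / pre$tcci else NA_real_,
             usable = usable)
}

#' Card-weighted block-level population reduction
#'
#' Pairs pre- and post-control line indices by `line_id`, computes per-line
#' percentage reductions in tCCI, and combines them as a weighted mean with
#' weights equal to the pre-session card count of each line (lines differ
#' in length, so longer lines carry more information). The standard error
#' is the weighted SE of the mean over lines.
#'
#' Display bounds are asymmetric: the card-weighted mean tCCI of each
#' session, plus and minus one weighted SE, is back-transformed to the
#' proportion scale and the reduction is recomputed from the favourable and
#' unfavourable pairings of those bounds. Back-transforming from the angle
#' scale makes the bounds asymmetric about the mean.
#'
#' @param pre,post [line_indices()] results for the two sessions of one
#'   block and species.
#' @param block_id label for the block (defaults to `"block"`).
#' @return An object of class `block_reduction`: a list with the weighted
#'   `mean_reduction`, `se` (over lines), asymmetric `se_lower`/`se_upper`
#'   display offsets, the per-line table (`lines`), the number of usable
#'   lines, and any lines excluded for zero pre-control tCCI (`excluded`).
#' @export
block_reduction <- function(pre, post, block_id = "block") {
  merged <- merge(pre, post, by = c("line_id", "species"),
                  suffixes = c("_pre", "_post"))
  if (nrow(merged) == 0)
    stop("no lines shared between sessions for block ", block_id,
         call. = FALSE)
  per_line <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    line_reduction(
      data.frame(line_id = m$line_id, species = m$species,
                 n_cards = m$n_cards_pre, cci = m$cci_pre, tcci = m$tcci_pre),
      data.frame(line_id = m$line_id, species = m$species,
                 n_cards = m$n_cards_post, cci = m$cci_post,
                 tcci = m$tcci_post))
  }))
  usable <- per_line[per_line$usable, , drop = FALSE]
  if (nrow(usable) < 2)
    stop("block ", block_id, " has fewer than 2 usable lines ",
         "(pre-control tCCI > 0)", call. = FALSE)
  w <- usable$n_cards
  est <- weighted_mean_se(usable$reduction_pct, w)

  keep <- merged$line_id %in% usable$line_id
  lvl_pre <- weighted_mean_se(merged$tcci_pre[keep], w)
  lvl_post <- weighted_mean_se(merged$tcci_post[keep], w)
  bnd <- function(tp, tq) {
    pp <- back_transform(min(max(tp, 0), 90))
    qq <- back_transform(min(max(tq, 0), 90))
    if (pp <= 0) return(NA_real_)
    100 * (1 - qq / pp)
  }
  red_hi <- bnd(lvl_pre$mean + lvl_pre$se, lvl_post$mean - lvl_post$se)
  red_lo <- bnd(lvl_pre$mean - lvl_pre$se, lvl_post$mean + lvl_post$se)
  red_mid <- bnd(lvl_pre$mean, lvl_post$mean)

  structure(list(block_id = block_id, species = usable$species[1],
                 mean_reduction = est$mean, se = est$se,
                 se_lower = red_mid - red_lo, se_upper = red_hi - red_mid,
                 n_lines = nrow(usable), n_cards = sum(w),
                 lines = per_line,
                 excluded = per_line$line_id[!per_line$usable]),
            class = "block_reduction")
}

#' @export
print.block_reduction <- function(x, ...) {
  cat(sprintf("<block_reduction> %s / %s: %.1f%% (-%.1f/+%.1f, over-line SE %.2f), %d lines, %d cards\n",
              x$block_id, x$species, x$mean_reduction, x$se_lower,
              x$se_upper, x$se, x$n_lines, x$n_cards))
  if (length(x$excluded) > 0)
    cat("  excluded (pre tCCI = 0):", paste(x$excluded, collapse = ", "),
        "\n")
  invisible(x)
}

#' Residual trap catch index
#'
#' Possum captures per 100 available trap nights, expressed as a
#' percentage. Traps inactivated by a non-target capture or by being
#' sprung without a catch are only partly available, so half a trap night
#' is deducted for each such record.
#'
#' @param records trap-night records with an `outcome` column in
#'   `{possum_capture, nontarget_or_sprung, empty}` (one row per trap per
#'   night).
#' @return RTCI, percent.
#' @examples
#' rec <- data.frame(outcome = rep(c("possum_capture", "nontarget_or_sprung",
#'                                   "empty"), c(24, 4, 212)))
#' rtci(rec) # 24 / (240 - 2) * 100 = 10.08
#' @export
rtci <- function(records) {
  if (nrow(records) == 0) stop("no trap-night records", call. = FALSE)
  bad <- setdiff(unique(records$outcome),
                 c("possum_capture", "nontarget_or_sprung", "empty"))
  if (length(bad) > 0)
    stop("unknown trap outcomes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  captures <- sum(records$outcome == "possum_capture")
  penalised <- sum(records$outcome == "nontarget_or_sprung")
  denom <- nrow(records) - 0.5 * penalised
  if (denom <= 0)
    stop("corrected trap-night denominator is not positive", call. = FALSE)
  100 * captures / denom
}

#' Deviation of assayed toxin loading from specification
#'
#' Signed percentage deviation of an assayed toxin concentration from its
#' label specification, rounded to the whole percent as reported in bait QA
#' summaries.
#'
#' @param assay_pct assayed concentration, percent wt:wt.
#' @param spec_pct specified concentration, percent wt:wt (> 0).
#' @return Signed integer percent deviation.
#' @examples
#' toxin_loading_deviation(0.16, 0.15) # +7
#' toxin_loading_deviation(0.13, 0.15) # -13
#' toxin_loading_deviation(0.72, 0.80) # -10
#' @export
toxin_loading_deviation <- function(assay_pct, spec_pct) {
  if (any(spec_pct <= 0))
    stop("specified concentration must be positive", call. = FALSE)
  round(100 * (assay_pct - spec_pct) / spec_pct)
}
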
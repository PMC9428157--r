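#' Spread potential of a conjugative plasmid
#'
#' The spread potential (SP) estimates transconjugants per recipient from
#' three ddPCR concentrations:
#' \deqn{SP = (C_{gfp} - C_{dsRed}) / (C_{16S}/k - C_{dsRed})}
#' where `C_gfp` counts plasmid copies (donors plus transconjugants),
#' `C_dsRed` counts donors, `C_16S / k` estimates total bacteria (with `k`
#' the assumed 16S rRNA copies per cell, default 4; rRNA databases put the
#' average at about 4.1 — both divisors are supported), and the denominator
#' is therefore the recipient pool.
#'
#' A numerator below zero (measurement noise making `C_gfp < C_dsRed`) is
#' clamped to 0 and flagged `"clamped_numerator"`; a non-positive denominator
#' yields `NA` with flag `"invalid_denominator"`.
#'
#' @param c_gfp,c_dsred,c_16s Concentrations in copies/g dry weight (>= 0).
#'   Vectorized.
#' @param copies_per_cell Assumed 16S rRNA gene copies per bacterium (> 0).
#' @return A data frame with the inputs, `copies_per_cell`, `sp`
#'   (transconjugants per recipient) and `flag`.
#' @examples
#' spread_potential(2e6, 1e6, 4e9)$sp  # ~1e-3
#' @export
spread_potential <- function(c_gfp, c_dsred, c_16s, copies_per_cell = 4) {
  if (copies_per_cell <= 0) stop_values("copies_per_cell must be > 0")
  if (any(c_gfp < 0) || any(c_dsred < 0) || any(c_16s < 0))
    stop_values("concentrations must be >= 0")
  num <- c_gfp - c_dsred
  den <- c_16s / copies_per_cell - c_dsred
  flag <- rep("ok", length(num))
  flag[num < 0] <- "clamped_numerator"
  num <- pmax(num, 0)
  sp <- num / den
  bad <- den <= 0
  sp[bad] <- NA_real_
  flag[bad] <- "invalid_denominator"
  data.frame(c_gfp = c_gfp, c_dsred = c_dsred, c_16s = c_16s,
             copies_per_cell = copies_per_cell, sp = sp, flag = flag,
             stringsAsFactors = FALSE)
}

#' Spread-potential time series from an abundance table
#'
#' Computes one spread potential per (treatment, replicate, day) from the
#' three marker genes of an abundance table. Samples missing any of the
#' three genes (or with an unusable concentration) are kept in the output
#' with flag `"missing_gene"` rather than silently dropped.
#'
#' @param abundance Abundance data frame (columns `treatment`, `replicate`,
#'   `day`, `gene`, `copies_per_g_dw`).
#' @param copies_per_cell Passed to [spread_potential()].
#' @return A data frame ordered by treatment, day, replicate with columns
#'   `sample_id`, `treatment`, `replicate`, `day`, the three concentrations,
#'   `sp` and `flag`; the attribute `"summary"` holds per-treatment x day
#'   geometric means of valid SP values (SP spans orders of magnitude, so an
#'   arithmetic mean would be dominated by single replicates).
#' @seealso [sp_summary()]
#' @export
sp_timeseries <- function(abundance, copies_per_cell = 4) {
  keys <- unique(abundance[, c("treatment", "replicate", "day")])
  keys <- keys[order(keys$treatment, keys$day, keys$replicate), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- abundance[abundance$treatment == k$treatment &
                     abundance$replicate == k$replicate &
                     abundance$day == k$day, ]
    get1 <- function(g) {
      v <- sub$copies_per_g_dw[sub$gene == g]
      if (length(v) == 1L && is.finite(v)) v else NA_real_
    }
    cg <- get1("gfp"); cd <- get1("dsRed"); cs <- get1("16S")
    base <- data.frame(sample_id = sprintf("%s_r%d_d%g", k$treatment,
                                           k$replicate, k$day),
                       treatment = k$treatment, replicate = k$replicate,
                       day = k$day, stringsAsFactors = FALSE)
    if (anyNA(c(cg, cd, cs))) {
      cbind(base, data.frame(c_gfp = cg, c_dsred = cd, c_16s = cs,
                             copies_per_cell = copies_per_cell,
                             sp = NA_real_, flag = "missing_gene",
                             stringsAsFactors = FALSE))
    } else {
      cbind(base, spread_potential(cg, cd, cs, copies_per_cell))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  valid <- out[!is.na(out$sp) & out$sp > 0, ]
  summ <- if (nrow(valid) > 0) {
    agg <- stats::aggregate(sp ~ treatment + day, data = valid,
                            FUN = geometric_mean)
    names(agg)[names(agg) == "sp"] <- "sp_geomean"
    agg[order(agg$treatment, agg$day), ]
  } else {
    data.frame(treatment = character(), day = numeric(),
               sp_geomean = numeric())
  }
  attr(out, "summary") <- summ
  out
}

#' Per-treatment geometric-mean SP summary
#'
#' @param sp_series Output of [sp_timeseries()].
#' @return The per-treatment x day geometric-mean table.
#' @export
sp_summary <- function(sp_series) attr(sp_series, "summary")
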
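# Per-site variant score: four empirical log-odds components over the
# mismatch bases of a cross-section, each normalized by the coverage,
# plus the log empirical quantile of the mismatch rate,
#
#   S = Delta_Q + Delta_P + Delta_R + Delta_H + log q(delta).
#
# Only mismatching bases contribute to the components; a cross-section
# with no mismatch is excluded from every part of the model.

# clamp base-correctness probabilities away from 0 and 1 so the quality
# log-odds stays finite (Phred 30+ maps very close to 1)
.QUAL_CLAMP <- c(0.001, 0.9999)

.clamp_qual <- function(q) pmin(pmax(q, .QUAL_CLAMP[1]), .QUAL_CLAMP[2])

.single_site <- function(cs) {
  if (nrow(unique(cs[, .(chrom, pos)])) != 1L) {
    stop("expected the rows of a single cross-section")
  }
  invisible(cs)
}

#' Base-quality score component
#'
#' Mean (over the coverage) log-odds of the mismatch bases' correctness
#' probabilities: `(1/|C|) * sum_{x in Mbar} log(Q_x / (1 - Q_x))`.
#' Qualities are clamped into `[0.001, 0.9999]` first.
#'
#' @param cs Pileup rows of one cross-section with at least one
#'   mismatch.
#' @return The component value.
#' @export
delta_Q <- function(cs) {
  .single_site(cs)
  q <- .clamp_qual(cs$qual[cs$is_mismatch])
  sum(.logodds(q)) / nrow(cs)
}

#' Read-position score component
#'
#' Mean log-odds of the match probability at the mismatch bases' binned
#' relative read positions, rescaled by the maximally attained match and
#' mismatch probabilities:
#' `(1/|C|) * sum_{x in Mbar} [log odds Pr(M|P_x) + log(P_Mbar / P_M)]`.
#'
#' @param cs Pileup rows of one cross-section with >= 1 mismatch.
#' @param table The `P` `conditional_table` of a background model.
#' @return The component value.
#' @export
delta_P <- function(cs, table) {
  .single_site(cs)
  stopifnot(table$kind == "P")
  p <- ct_lookup(table, cs$read_pos[cs$is_mismatch] /
                          cs$read_len[cs$is_mismatch])
  (sum(.logodds(p)) + sum(cs$is_mismatch) * log(table$p_Mbar / table$p_M)) /
    nrow(cs)
}

#' Read-error score component
#'
#' Mean log-odds of the match probability conditional on the mismatch
#' bases' per-read alignment edit distance:
#' `(1/|C|) * sum_{x in Mbar} log odds Pr(M|R_x)`.
#'
#' @param cs Pileup rows of one cross-section with >= 1 mismatch.
#' @param table The `R` `conditional_table` of a background model.
#' @return The component value.
#' @export
delta_R <- function(cs, table) {
  .single_site(cs)
  stopifnot(table$kind == "R")
  p <- ct_lookup(table, cs$read_errors[cs$is_mismatch])
  sum(.logodds(p)) / nrow(cs)
}

#' Multiple-hit score component
#'
#' As [delta_R()], with the per-read alignment multiplicity `H` in place
#' of the edit distance.
#'
#' @param cs Pileup rows of one cross-section with >= 1 mismatch.
#' @param table The `H` `conditional_table` of a background model.
#' @return The component value.
#' @export
delta_H <- function(cs, table) {
  .single_site(cs)
  stopifnot(table$kind == "H")
  p <- ct_lookup(table, cs$read_hits[cs$is_mismatch])
  sum(.logodds(p)) / nrow(cs)
}

#' Score a single cross-section
#'
#' @param cs Pileup rows of one cross-section.
#' @param model A `background_model`.
#' @return A one-row `data.table` (see [score_pileup()] for the
#'   columns), or `NULL` when the cross-section has no mismatch and is
#'   therefore excluded from the model.
#' @export
score_site <- function(cs, model) {
  stopifnot(inherits(model, "background_model"))
  .single_site(cs)
  if (!any(cs$is_mismatch)) {
    return(NULL)
  }
  score_pileup(cs, model)
}

#' Score every mismatch-carrying site of a pileup
#'
#' Computes, for each cross-section with at least one mismatching base,
#' the four log-odds components, the log empirical quantile of the
#' mismatch rate, and their total. All-match sites are excluded.
#'
#' @param pb A pileup `data.table`.
#' @param model A `background_model`.
#' @return A keyed `data.table` with one row per scored site: `chrom`,
#'   `pos`, `ref`, `alt` (modal mismatch base, ties broken
#'   alphabetically), `other_alts` (remaining observed mismatch bases,
#'   comma-separated, `""` if none), `coverage`, `n_mismatch`, `delta`,
#'   `d_Q`, `d_P`, `d_R`, `d_H`, `log_q`, `score`.
#' @export
score_pileup <- function(pb, model) {
  stopifnot(is.data.table(pb), inherits(model, "background_model"))
  ss <- site_summary(pb)
  ss <- ss[n_mismatch >= 1L]
  if (nrow(ss) == 0L) {
    return(.empty_sitescore())
  }
  tabs <- model$tables
  mm <- pb[is_mismatch == TRUE]
  mm[, `:=`(
    lq = .logodds(.clamp_qual(qual)),
    lp = .logodds(ct_lookup(tabs$P, read_pos / read_len)),
    lr = .logodds(ct_lookup(tabs$R, read_errors)),
    lh = .logodds(ct_lookup(tabs$H, read_hits))
  )]
  agg <- mm[, .(sQ = sum(lq), sP = sum(lp), sR = sum(lr), sH = sum(lh)),
            by = .(chrom, pos)]
  # modal mismatch base, ties alphabetical; remaining alts comma-joined
  ac <- mm[, .N, by = .(chrom, pos, base)]
  setorder(ac, chrom, pos, -N, base)
  alts <- ac[, .(alt = base[1L],
                 other_alts = paste(base[-1L], collapse = ",")),
             by = .(chrom, pos)]
  out <- ss[agg, on = c("chrom", "pos")][alts, on = c("chrom", "pos")]
  rescale_P <- log(tabs$P$p_Mbar / tabs$P$p_M)
  out[, `:=`(
    d_Q = sQ / coverage,
    d_P = (sP + n_mismatch * rescale_P) / coverage,
    d_R = sR / coverage,
    d_H = sH / coverage,
    log_q = log(q_delta(model$ecdf, delta))
  )]
  out[, score := d_Q + d_P + d_R + d_H + log_q]
  out[, c("sQ", "sP", "sR", "sH", "n_match") := NULL]
  setcolorder(out, c("chrom", "pos", "ref", "alt", "other_alts",
                     "coverage", "n_mismatch", "delta",
                     "d_Q", "d_P", "d_R", "d_H", "log_q", "score"))
  setkey(out, chrom, pos)
  out[]
}

.empty_sitescore <- function() {
  dt <- data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), other_alts = character(), coverage = integer(),
    n_mismatch = integer(), delta = numeric(), d_Q = numeric(),
    d_P = numeric(), d_R = numeric(), d_H = numeric(),
    log_q = numeric(), score = numeric()
  )
  setkey(dt, chrom, pos)
  dt[]
}

#' Write a scored-site table
#'
#' Tab-separated audit table with one row per scored site (every site
#' that entered the score histogram), including the component
#' breakdown.
#'
#' @param sites A site-score `data.table` from [score_pileup()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  fwrite(sites, path, sep = "\t")
  invisible(path)
}
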
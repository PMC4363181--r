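# Background error model: the empirical distribution of the per-site
# mismatch rate delta, and conditional match-probability tables over the
# relative read position P, the per-read alignment errors R, and the
# per-read alignment multiplicity H, all estimated from a uniform sample
# of low-mismatch sites (0 < delta < 0.5).

#' Build the empirical distribution function of the mismatch rate
#'
#' Tabulates the cumulative frequencies of the per-site mismatch rate
#' `delta` so that `q(delta)` — the empirical quantile of an observed
#' mismatch rate — can be read off. The inclusive ("<=") convention is
#' used, so every observed value has `q > 0`; a query below every
#' tabulated value is floored at `1 / (n_sites + 1)`.
#'
#' By default all covered sites enter the tabulation, including
#' `delta = 0` sites, so that any site with at least one mismatch
#' already ranks above the invariant bulk.
#'
#' @param delta Numeric vector of per-site mismatch rates, or a site
#'   summary `data.table` with a `delta` column.
#' @param include_zero Keep `delta = 0` sites in the tabulation
#'   (default `TRUE`).
#' @return An object of class `delta_ecdf`.
#' @seealso [q_delta()]
#' @export
build_delta_ecdf <- function(delta, include_zero = TRUE) {
  if (is.data.frame(delta)) delta <- delta$delta
  stopifnot(is.numeric(delta))
  if (!include_zero) delta <- delta[delta > 0]
  if (!length(delta)) {
    stop("no sites to tabulate: cannot build the mismatch-rate ECDF")
  }
  support <- sort(unique(delta))
  counts <- tabulate(match(delta, support), nbins = length(support))
  structure(
    list(support = support,
         cum = cumsum(as.numeric(counts)),
         n = length(delta),
         include_zero = include_zero),
    class = "delta_ecdf"
  )
}

#' Empirical quantile of a mismatch rate
#'
#' @param ecdf A `delta_ecdf` from [build_delta_ecdf()].
#' @param delta Numeric vector of mismatch rates to look up.
#' @return `q(delta) = #\{delta' <= delta\} / n`, floored at
#'   `1 / (n + 1)` below the observed support, so the log-quantile used
#'   in the score is always finite.
#' @export
q_delta <- function(ecdf, delta) {
  stopifnot(inherits(ecdf, "delta_ecdf"))
  i <- findInterval(delta, ecdf$support)
  q <- numeric(length(delta))
  inside <- i > 0L
  q[inside] <- ecdf$cum[i[inside]] / ecdf$n
  q[!inside] <- 1 / (ecdf$n + 1)
  q
}

#' @export
print.delta_ecdf <- function(x, ...) {
  cat("delta_ecdf: ", x$n, " sites, ", length(x$support),
      " distinct mismatch rates, max delta ",
      format(max(x$support)), "\n", sep = "")
  invisible(x)
}

#' Sample background sites from a pileup
#'
#' Draws a uniform sample without replacement from the sites with
#' `0 < delta < 0.5`, whose mismatches are assumed to be of technical
#' origin; their base observations estimate the background conditional
#' tables. If fewer than `n` sites qualify, all of them are returned
#' with a warning.
#'
#' @param pb A pileup `data.table` ([read_pileup()]).
#' @param n Number of sites to sample (default 100000).
#' @param seed Integer seed making the draw reproducible.
#' @return The pileup rows of the sampled sites; the sampled site keys
#'   are attached as attribute `"sites"`.
#' @export
sample_background_sites <- function(pb, n = 100000L, seed = 1L) {
  stopifnot(is.data.table(pb), n >= 1L)
  ss <- site_summary(pb)
  qual <- ss[delta > 0 & delta < 0.5, .(chrom, pos)]
  if (nrow(qual) == 0L) {
    stop("no background estimable: no sites with 0 < delta < 0.5")
  }
  if (nrow(qual) <= n) {
    if (nrow(qual) < n) {
      warning("only ", nrow(qual), " sites qualify for the background ",
              "sample (requested ", n, "); using all of them")
    }
    sel <- qual
  } else {
    idx <- with_seed(seed, sample.int(nrow(qual), n))
    sel <- qual[sort(idx)]
  }
  setkey(sel, chrom, pos)
  out <- pb[sel, on = c("chrom", "pos")]
  setattr(out, "sites", sel)
  out
}

# bin indices for each characteristic --------------------------------------

# P in (0,1] -> 1..p_bins (equal width)
.bin_P <- function(p, p_bins) {
  pmin(pmax(ceiling(p * p_bins), 1L), p_bins)
}

# R in 0..Inf -> 1..(r_max+2): value r maps to r+1, overflow pooled
.bin_R <- function(r, r_max) {
  pmin(r, r_max + 1L) + 1L
}

# H in 1..Inf -> 1..(h_max+1): value h maps to h, overflow pooled
.bin_H <- function(h, h_max) {
  pmin(h, h_max + 1L)
}

.table_kinds <- c(P = "P", R = "R", H = "H")

# raw per-bin match/mismatch counts for one characteristic
.count_bins <- function(bin, is_mismatch, n_bins) {
  list(match = tabulate(bin[!is_mismatch], nbins = n_bins),
       mismatch = tabulate(bin[is_mismatch], nbins = n_bins))
}

# counts for all three characteristics from a pileup chunk
.count_characteristics <- function(pb, p_bins, r_max, h_max) {
  list(
    P = .count_bins(.bin_P(pb$read_pos / pb$read_len, p_bins),
                    pb$is_mismatch, p_bins),
    R = .count_bins(.bin_R(pb$read_errors, r_max), pb$is_mismatch,
                    r_max + 2L),
    H = .count_bins(.bin_H(pb$read_hits, h_max), pb$is_mismatch,
                    h_max + 1L)
  )
}

.add_counts <- function(a, b) {
  if (is.null(a)) return(b)
  for (k in names(a)) {
    a[[k]]$match <- a[[k]]$match + b[[k]]$match
    a[[k]]$mismatch <- a[[k]]$mismatch + b[[k]]$mismatch
  }
  a
}

# turn raw counts into conditional_table objects
.finalize_tables <- function(counts, p_bins, pseudocount, r_max, h_max) {
  mk <- function(kind, cnt, values) {
    total <- cnt$match + cnt$mismatch
    prob <- (cnt$match + pseudocount) / (total + 2 * pseudocount)
    tab <- structure(
      list(kind = kind, values = values,
           match = cnt$match, mismatch = cnt$mismatch, prob = prob,
           p_bins = p_bins, r_max = r_max, h_max = h_max,
           pseudocount = pseudocount),
      class = "conditional_table"
    )
    if (kind == "P") {
      occ <- total > 0
      if (!any(occ)) stop("empty background sample: no occupied P bins")
      tab$p_M <- max(prob[occ])
      tab$p_Mbar <- max(1 - prob[occ])
    }
    tab
  }
  list(
    P = mk("P", counts$P, seq_len(p_bins) / p_bins),
    R = mk("R", counts$R, c(0:r_max, NA_integer_)),  # NA = overflow bin
    H = mk("H", counts$H, c(1:h_max, NA_integer_))
  )
}

#' Estimate the conditional match-probability tables
#'
#' Tabulates, over every base of every supplied cross-section, the
#' occurrence of matches for each binned value of the relative read
#' position `P`, the read edit distance `R`, and the alignment
#' multiplicity `H`. Additive smoothing with pseudocount `alpha` keeps
#' every probability strictly inside `(0, 1)`:
#' `Pr(M|bin) = (match + alpha) / (total + 2 alpha)`. For the `P` table
#' the maxima `P_M = max_P Pr(M|P)` and `P_Mbar = max_P Pr(Mbar|P)`
#' are recorded over occupied bins; they rescale the read-position
#' log-odds in the score.
#'
#' @param pb Pileup rows of the background sample
#'   ([sample_background_sites()]).
#' @param p_bins Number of equal-width bins over `(0, 1]` for `P`
#'   (default 50).
#' @param pseudocount Additive smoothing constant (default 0.5,
#'   a Jeffreys prior).
#' @param r_max,h_max Largest distinct value of `R` / `H`; larger values
#'   are pooled into an overflow bin (defaults 20 and 50).
#' @return Named list of `conditional_table` objects (`P`, `R`, `H`).
#' @export
estimate_conditional_tables <- function(pb, p_bins = 50L,
                                        pseudocount = 0.5,
                                        r_max = 20L, h_max = 50L) {
  stopifnot(is.data.table(pb), nrow(pb) >= 1L)
  counts <- .count_characteristics(pb, p_bins, r_max, h_max)
  .finalize_tables(counts, p_bins, pseudocount, r_max, h_max)
}

# smoothed Pr(M | characteristic value) lookups
ct_lookup <- function(tab, x) {
  stopifnot(inherits(tab, "conditional_table"))
  bin <- switch(tab$kind,
                P = .bin_P(x, tab$p_bins),
                R = .bin_R(x, tab$r_max),
                H = .bin_H(x, tab$h_max))
  tab$prob[bin]
}

#' @export
print.conditional_table <- function(x, ...) {
  occ <- sum((x$match + x$mismatch) > 0)
  cat("conditional_table Pr(M|", x$kind, "): ", length(x$prob),
      " bins (", occ, " occupied), ",
      sum(x$match) + sum(x$mismatch), " base observations\n", sep = "")
  if (x$kind == "P") {
    cat("  P_M = ", format(x$p_M), ", P_Mbar = ", format(x$p_Mbar),
        "\n", sep = "")
  }
  invisible(x)
}

#' Build a background model from an in-memory pileup
#'
#' Convenience wrapper combining [build_delta_ecdf()],
#' [sample_background_sites()] and [estimate_conditional_tables()].
#' For whole-genome runs that should not hold the full per-base table in
#' memory, use [run_build()], which streams the alignments and produces
#' the same model.
#'
#' @param pb A pileup `data.table`.
#' @param sample_size Background sample size (default 100000).
#' @param seed Integer seed for the background draw.
#' @param include_zero_delta Tabulate `delta = 0` sites in the ECDF.
#' @inheritParams estimate_conditional_tables
#' @return An object of class `background_model` with elements `ecdf`,
#'   `tables`, sampling metadata and the binning parameters.
#' @export
build_background_model <- function(pb, sample_size = 100000L, seed = 1L,
                                   p_bins = 50L, pseudocount = 0.5,
                                   r_max = 20L, h_max = 50L,
                                   include_zero_delta = TRUE) {
  ss <- site_summary(pb)
  if (nrow(ss) == 0L) stop("no cross-sections in input")
  ecdf <- build_delta_ecdf(ss, include_zero = include_zero_delta)
  bg <- sample_background_sites(pb, n = sample_size, seed = seed)
  tables <- estimate_conditional_tables(bg, p_bins = p_bins,
                                        pseudocount = pseudocount,
                                        r_max = r_max, h_max = h_max)
  structure(
    list(ecdf = ecdf, tables = tables,
         sample_size = as.integer(sample_size),
         n_sampled = nrow(attr(bg, "sites")),
         n_sites = nrow(ss),
         n_qualifying = nrow(ss[delta > 0 & delta < 0.5]),
         seed = as.integer(seed),
         p_bins = as.integer(p_bins), pseudocount = pseudocount,
         r_max = as.integer(r_max), h_max = as.integer(h_max),
         include_zero_delta = include_zero_delta,
         contigs = NULL,
         version = 1L),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat("background_model (version ", x$version, ")\n", sep = "")
  cat("  sites tabulated: ", x$n_sites, " (", x$n_qualifying,
      " qualifying, ", x$n_sampled, " sampled, seed ", x$seed, ")\n",
      sep = "")
  print(x$ecdf)
  for (k in names(x$tables)) print(x$tables[[k]])
  invisible(x)
}

#' Serialize a background model to a plain-text sidecar file
#'
#' The model is written as versioned JSON at full numeric precision, so
#' a reload reproduces every lookup bit-identically.
#'
#' @param model A `background_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_background_model <- function(model, path) {
  stopifnot(inherits(model, "background_model"))
  x <- unclass(model)
  x$ecdf <- unclass(x$ecdf)
  x$tables <- lapply(x$tables, unclass)
  # named atomic vectors lose their names in JSON arrays; keep contig
  # names by serializing as an object
  if (!is.null(x$contigs)) x$contigs <- as.list(x$contigs)
  # 17 significant digits round-trip IEEE doubles exactly, so a reload
  # reproduces every lookup bit-identically
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a background model written by [write_background_model()]
#'
#' @param path Path to the sidecar file.
#' @return A `background_model`.
#' @export
read_background_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version) || x$version != 1L) {
    stop("unsupported background model file version: ",
         if (is.null(x$version)) "<missing>" else x$version)
  }
  x$ecdf <- structure(x$ecdf, class = "delta_ecdf")
  x$tables <- lapply(x$tables, function(t) {
    t$values <- unlist(t$values)
    structure(t, class = "conditional_table")
  })
  for (f in c("sample_size", "n_sampled", "n_sites", "n_qualifying",
              "seed", "p_bins", "r_max", "h_max", "version")) {
    x[[f]] <- as.integer(x[[f]])
  }
  if (!is.null(x$contigs)) {
    x$contigs <- vapply(x$contigs, as.integer, integer(1))
  }
  structure(x, class = "background_model")
}
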
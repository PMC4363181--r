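#' @import data.table
#' @importFrom methods is
NULL

# Columns of a pileup table (one row per aligned base observation):
#   chrom       reference sequence name
#   pos         1-based reference coordinate
#   ref         reference base (A/C/G/T)
#   base        observed base (A/C/G/T; N bases are dropped)
#   phred       Phred-scaled base quality
#   qual        probability of the base call being correct, 1 - 10^(-phred/10)
#   read_pos    1-based offset of the base within the aligned part of its read
#   read_len    aligned read length (query bases consumed by M/=/X/I ops)
#   read_errors per-read alignment edit distance (NM tag by default)
#   read_hits   per-read number of reported alignments (NH tag by default)
#   is_mismatch base != ref

# expand one scanBam record list into per-base rows; refs is a function
# (chrom, start, end) -> raw vector of reference bases
.expand_bam_chunk <- function(b, get_ref, window = NULL,
                              min_base_quality = 0L,
                              nm_tag = "NM", nh_tag = "NH",
                              missing_tag = c("default", "fail")) {
  missing_tag <- match.arg(missing_tag)
  keep <- !is.na(b$pos) & !is.na(b$cigar)
  nr <- sum(keep)
  if (nr == 0L) {
    return(.empty_pileup())
  }
  pos0 <- b$pos[keep]
  cigar <- b$cigar[keep]
  rname <- as.character(b$rname[keep])
  seqs <- b$seq[keep]
  quals <- b$qual[keep]

  nm <- b$tag[[nm_tag]]
  nh <- b$tag[[nh_tag]]
  if (is.null(nm)) nm <- rep(NA_integer_, length(b$pos))
  if (is.null(nh)) nh <- rep(NA_integer_, length(b$pos))
  nm <- nm[keep]
  nh <- nh[keep]
  if (anyNA(nm)) {
    if (missing_tag == "fail") {
      stop("alignment record(s) missing edit-distance tag '", nm_tag, "'")
    }
    warning("missing '", nm_tag, "' tag on ", sum(is.na(nm)),
            " read(s); defaulting read_errors = 0")
    nm[is.na(nm)] <- 0L
  }
  if (anyNA(nh)) {
    if (missing_tag == "fail") {
      stop("alignment record(s) missing hit-count tag '", nh_tag, "'")
    }
    warning("missing '", nh_tag, "' tag on ", sum(is.na(nh)),
            " read(s); defaulting read_hits = 1")
    nh[is.na(nh)] <- 1L
  }

  ops <- GenomicAlignments::explodeCigarOps(cigar)
  opl <- GenomicAlignments::explodeCigarOpLengths(cigar)
  nop <- lengths(ops)
  opv <- unlist(ops, use.names = FALSE)
  oplv <- unlist(opl, use.names = FALSE)
  rid <- rep(seq_len(nr), nop)

  # per-op consumption of query, reference, and the aligned part of the
  # query (soft clips consume query but are not part of the alignment)
  cq <- oplv * (opv %in% c("M", "=", "X", "I", "S"))
  cr <- oplv * (opv %in% c("M", "=", "X", "D", "N"))
  ca <- oplv * (opv %in% c("M", "=", "X", "I"))
  cum_before <- function(x) {
    cs <- cumsum(x)
    before <- cs - x
    first <- !duplicated(rid)
    before - rep(before[first], nop)
  }
  qb <- cum_before(cq)
  rb <- cum_before(cr)
  ab <- cum_before(ca)
  aln_len <- as.integer(rowsum(ca, rid)[, 1L])

  emit <- opv %in% c("M", "=", "X")
  if (!any(emit)) {
    return(.empty_pileup())
  }
  bl_rid <- rid[emit]
  bl_len <- oplv[emit]
  expand_id <- rep(seq_along(bl_rid), bl_len)
  off <- sequence(bl_len) - 1L
  brid <- bl_rid[expand_id]
  bpos <- (pos0[bl_rid] + rb[emit])[expand_id] + off
  bq <- (1L + qb[emit])[expand_id] + off   # index into SEQ
  bk <- (1L + ab[emit])[expand_id] + off   # offset within aligned part

  seq_off <- cumsum(Biostrings::width(seqs)) - Biostrings::width(seqs)
  sraw <- charToRaw(as.character(BiocGenerics::unlist(seqs)))
  qraw <- charToRaw(as.character(BiocGenerics::unlist(
    methods::as(quals, "BStringSet"))))
  gidx <- seq_off[brid] + bq
  base_raw <- sraw[gidx]
  phred <- as.integer(qraw[gidx]) - 33L

  # reference bases, fetched per chromosome
  ref_raw <- raw(length(bpos))
  for (ch in unique(rname)) {
    sel <- rname[brid] == ch
    p <- bpos[sel]
    lo <- min(p)
    hi <- max(p)
    rr <- get_ref(ch, lo, hi)
    ref_raw[sel] <- rr[p - lo + 1L]
  }

  dt <- data.table(
    chrom = rname[brid],
    pos = bpos,
    ref_raw = ref_raw,
    base_raw = base_raw,
    phred = phred,
    read_pos = bk,
    read_len = aln_len[brid],
    read_errors = as.integer(nm[brid]),
    read_hits = as.integer(nh[brid])
  )
  if (!is.null(window)) {
    dt <- dt[pos >= GenomicRanges::start(window) &
               pos <= GenomicRanges::end(window)]
  }
  acgt <- charToRaw("ACGT")
  dt <- dt[base_raw %in% acgt & ref_raw %in% acgt &
             phred >= max(1L, as.integer(min_base_quality))]
  if (nrow(dt) == 0L) {
    return(.empty_pileup())
  }
  dt[, `:=`(
    ref = strsplit(rawToChar(ref_raw), "", fixed = TRUE)[[1]],
    base = strsplit(rawToChar(base_raw), "", fixed = TRUE)[[1]]
  )]
  dt[, `:=`(ref_raw = NULL, base_raw = NULL)]
  dt[, qual := phred_to_prob(phred)]
  dt[, is_mismatch := base != ref]
  setcolorder(dt, c("chrom", "pos", "ref", "base", "phred", "qual",
                    "read_pos", "read_len", "read_errors", "read_hits",
                    "is_mismatch"))
  setkey(dt, chrom, pos)
  dt[]
}

.empty_pileup <- function() {
  dt <- data.table(
    chrom = character(), pos = integer(), ref = character(),
    base = character(), phred = integer(), qual = numeric(),
    read_pos = integer(), read_len = integer(), read_errors = integer(),
    read_hits = integer(), is_mismatch = logical()
  )
  setkey(dt, chrom, pos)
  dt[]
}

.scanbam_what <- c("rname", "pos", "cigar", "seq", "qual")

.scanbam_flag <- Rsamtools::scanBamFlag(
  isUnmappedQuery = FALSE,
  isSecondaryAlignment = FALSE,
  isNotPassingQualityControls = FALSE
)

# reference accessor backed by an indexed FaFile, caching the current
# chromosome as a raw vector
.make_ref_accessor <- function(fa) {
  cache_chrom <- NULL
  cache_raw <- NULL
  function(chrom, lo, hi) {
    if (is.null(cache_chrom) || cache_chrom != chrom) {
      idx <- Rsamtools::scanFaIndex(fa)
      hit <- which(as.character(GenomeInfoDb::seqnames(idx)) == chrom)
      if (!length(hit)) {
        stop("chromosome absent from reference FASTA: ", chrom)
      }
      s <- Rsamtools::scanFa(fa, idx[hit])[[1]]
      cache_raw <<- charToRaw(toupper(as.character(s)))
      cache_chrom <<- chrom
    }
    cache_raw[lo:hi]
  }
}

#' Read a per-base pileup table from alignments
#'
#' Builds the cross-section representation used by the caller: one row
#' per aligned base observation, annotated with the four site
#' characteristics (base quality `Q`, relative read position `k/m`,
#' per-read alignment errors `R`, per-read alignment multiplicity `H`).
#' Insertions contribute no rows (they consume read bases and extend the
#' aligned read length), deletions and reference skips contribute no
#' rows, and soft-clipped bases are excluded from the aligned length.
#' `N` bases, bases over non-ACGT reference positions, and bases with
#' Phred quality 0 carry no allele evidence and are dropped.
#'
#' Reads flagged unmapped, secondary, or failing QC are skipped;
#' multiplicity information from secondary alignments enters only
#' through the hit-count tag of the primary record.
#'
#' @param file Path to a coordinate-sorted SAM or BAM file. SAM input is
#'   converted on the fly; BAM input is indexed if needed.
#' @param fasta Path to the reference FASTA (indexed on the fly).
#' @param region Optional region as `"chrom"` or `"chrom:start-end"`, or
#'   a `GRanges` of length 1.
#' @param min_base_quality Minimum Phred quality for a base to be kept
#'   (default 0; quality-0 bases are always dropped).
#' @param nm_tag,nh_tag Names of the per-read edit-distance and
#'   hit-count tags (defaults `"NM"` and `"NH"`).
#' @param missing_tag Policy when a tag is absent: `"default"` fills
#'   `read_errors = 0` / `read_hits = 1` with a warning, `"fail"` stops.
#' @return A keyed `data.table` with columns `chrom`, `pos`, `ref`,
#'   `base`, `phred`, `qual`, `read_pos`, `read_len`, `read_errors`,
#'   `read_hits`, `is_mismatch`, ordered by coordinate.
#' @seealso [site_summary()], [pileup_apply()]
#' @export
read_pileup <- function(file, fasta, region = NULL,
                        min_base_quality = 0L,
                        nm_tag = "NM", nh_tag = "NH",
                        missing_tag = c("default", "fail")) {
  missing_tag <- match.arg(missing_tag)
  bam <- ensure_bam(file)
  fa <- ensure_fasta(fasta)
  sl <- .bam_seqlengths(bam)
  .check_contigs(sl, fa)
  get_ref <- .make_ref_accessor(fa)
  if (!is.null(region)) {
    gr <- .parse_region(region, sl)
    param <- Rsamtools::ScanBamParam(what = .scanbam_what,
                                     tag = c(nm_tag, nh_tag),
                                     flag = .scanbam_flag, which = gr)
    b <- Rsamtools::scanBam(bam, param = param)[[1]]
    return(.expand_bam_chunk(b, get_ref, window = gr,
                             min_base_quality = min_base_quality,
                             nm_tag = nm_tag, nh_tag = nh_tag,
                             missing_tag = missing_tag))
  }
  param <- Rsamtools::ScanBamParam(what = .scanbam_what,
                                   tag = c(nm_tag, nh_tag),
                                   flag = .scanbam_flag)
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  .expand_bam_chunk(b, get_ref, window = NULL,
                    min_base_quality = min_base_quality,
                    nm_tag = nm_tag, nh_tag = nh_tag,
                    missing_tag = missing_tag)
}

#' Apply a function over pileup chunks of a BAM file
#'
#' Streams the alignments window by window (so whole-genome runs never
#' hold the full per-base table in memory) and calls `fun(pb)` on each
#' non-empty pileup chunk. Each base observation is assigned to exactly
#' one window, so per-site aggregates computed chunk-wise are exact.
#'
#' @inheritParams read_pileup
#' @param fun Function of one argument (a pileup `data.table`).
#' @param chunk_width Window width in bp (default 100000; lower it for very deep coverage to bound memory).
#' @return List of the non-NULL values returned by `fun`.
#' @export
pileup_apply <- function(file, fasta, fun, chunk_width = 100000L,
                         region = NULL, min_base_quality = 0L,
                         nm_tag = "NM", nh_tag = "NH",
                         missing_tag = c("default", "fail")) {
  missing_tag <- match.arg(missing_tag)
  bam <- ensure_bam(file)
  fa <- ensure_fasta(fasta)
  sl <- .bam_seqlengths(bam)
  .check_contigs(sl, fa)
  get_ref <- .make_ref_accessor(fa)
  if (!is.null(region)) {
    gr <- .parse_region(region, sl)
    tiles <- unlist(GenomicRanges::slidingWindows(gr, width = chunk_width,
                                                  step = chunk_width))
  } else {
    full <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, unname(sl)))
    tiles <- unlist(GenomicRanges::slidingWindows(full, width = chunk_width,
                                                  step = chunk_width))
  }
  out <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    w <- tiles[i]
    param <- Rsamtools::ScanBamParam(what = .scanbam_what,
                                     tag = c(nm_tag, nh_tag),
                                     flag = .scanbam_flag, which = w)
    b <- Rsamtools::scanBam(bam, param = param)[[1]]
    pb <- .expand_bam_chunk(b, get_ref, window = w,
                            min_base_quality = min_base_quality,
                            nm_tag = nm_tag, nh_tag = nh_tag,
                            missing_tag = missing_tag)
    if (nrow(pb)) out[[i]] <- fun(pb)
    rm(b, pb)
    gc(FALSE)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Summarize a pileup into per-site cross-section statistics
#'
#' @param pb A pileup `data.table` from [read_pileup()].
#' @return A keyed `data.table` with one row per covered site: `chrom`,
#'   `pos`, `ref`, `coverage`, `n_match`, `n_mismatch`, `delta` (the
#'   mismatch rate `n_mismatch / coverage`).
#' @export
site_summary <- function(pb) {
  stopifnot(is.data.table(pb))
  ss <- pb[, .(ref = ref[1L], coverage = .N,
               n_mismatch = sum(is_mismatch)),
           by = .(chrom, pos)]
  ss[, n_match := coverage - n_mismatch]
  ss[, delta := n_mismatch / coverage]
  setcolorder(ss, c("chrom", "pos", "ref", "coverage", "n_match",
                    "n_mismatch", "delta"))
  setkey(ss, chrom, pos)
  ss[]
}

#' Mismatch rate of a single cross-section
#'
#' The observed number of mismatching bases divided by the coverage.
#'
#' @param cs Pileup rows of exactly one site (one `(chrom, pos)`).
#' @return The mismatch rate, a number in `[0, 1]`.
#' @export
mismatch_rate <- function(cs) {
  stopifnot(is.data.table(cs), nrow(cs) >= 1L)
  if (nrow(unique(cs[, .(chrom, pos)])) != 1L) {
    stop("mismatch_rate() expects the rows of a single cross-section")
  }
  sum(cs$is_mismatch) / nrow(cs)
}
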
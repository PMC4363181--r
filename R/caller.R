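# Two-pass pipeline orchestration: `run_build` streams the alignments to
# estimate the background model and writes it to a plain-text sidecar
# file; `run_call` streams them again to score every mismatch-carrying
# site, chooses the adaptive threshold and emits VCF, a site table and a
# threshold report.

#' Build the background model from a BAM file (pass one)
#'
#' Streams the alignments window by window: a first sweep tabulates the
#' per-site mismatch rates (for the ECDF) and records the qualifying
#' background sites (`0 < delta < 0.5`); a uniform sample of those is
#' drawn; a second sweep accumulates the conditional match-probability
#' tables from the sampled sites only.
#'
#' @inheritParams read_pileup
#' @param model_out Optional path for the serialized model sidecar.
#' @param sample_size Background sample size (default 100000).
#' @param seed Integer seed for the background draw.
#' @param include_zero_delta Tabulate `delta = 0` sites in the ECDF
#'   (default `TRUE`).
#' @inheritParams estimate_conditional_tables
#' @param chunk_width Streaming window width in bp.
#' @param verbose Log progress counters per contig.
#' @return A `background_model` (invisibly if `model_out` is given) with
#'   the BAM contigs recorded for compatibility checks in [run_call()].
#' @export
run_build <- function(file, fasta, model_out = NULL,
                      sample_size = 100000L, seed = 1L,
                      p_bins = 50L, pseudocount = 0.5,
                      r_max = 20L, h_max = 50L,
                      include_zero_delta = TRUE,
                      min_base_quality = 0L, region = NULL,
                      chunk_width = 100000L,
                      nm_tag = "NM", nh_tag = "NH",
                      missing_tag = c("default", "fail"),
                      verbose = FALSE) {
  missing_tag <- match.arg(missing_tag)
  bam <- ensure_bam(file)
  contigs <- .bam_seqlengths(bam)

  # sweep 1: per-site mismatch rates and qualifying site keys
  chunks <- pileup_apply(
    bam, fasta, function(pb) {
      ss <- site_summary(pb)
      list(delta = ss$delta,
           qual = ss[delta > 0 & delta < 0.5, .(chrom, pos)],
           n = nrow(ss))
    },
    chunk_width = chunk_width, region = region,
    min_base_quality = min_base_quality,
    nm_tag = nm_tag, nh_tag = nh_tag, missing_tag = missing_tag
  )
  if (!length(chunks)) {
    stop("no cross-sections: the alignment file covers no reference site")
  }
  delta <- unlist(lapply(chunks, `[[`, "delta"), use.names = FALSE)
  qualifying <- rbindlist(lapply(chunks, `[[`, "qual"))
  n_sites <- length(delta)
  if (verbose) {
    message("tabulated ", n_sites, " sites; ", nrow(qualifying),
            " qualify for the background sample")
  }
  if (nrow(qualifying) == 0L) {
    stop("no background estimable: no sites with 0 < delta < 0.5")
  }
  ecdf <- build_delta_ecdf(delta, include_zero = include_zero_delta)

  if (nrow(qualifying) <= sample_size) {
    if (nrow(qualifying) < sample_size) {
      warning("only ", nrow(qualifying), " sites qualify for the ",
              "background sample (requested ", sample_size,
              "); using all of them")
    }
    sel <- qualifying
  } else {
    idx <- with_seed(seed, sample.int(nrow(qualifying), sample_size))
    sel <- qualifying[sort(idx)]
  }
  setkey(sel, chrom, pos)

  # sweep 2: conditional tables from the sampled sites
  counts <- NULL
  pileup_apply(
    bam, fasta, function(pb) {
      sub <- pb[sel, on = c("chrom", "pos"), nomatch = NULL]
      if (nrow(sub)) {
        counts <<- .add_counts(counts,
                               .count_characteristics(sub, p_bins,
                                                      r_max, h_max))
      }
      NULL
    },
    chunk_width = chunk_width, region = region,
    min_base_quality = min_base_quality,
    nm_tag = nm_tag, nh_tag = nh_tag, missing_tag = missing_tag
  )
  tables <- .finalize_tables(counts, p_bins, pseudocount, r_max, h_max)

  model <- structure(
    list(ecdf = ecdf, tables = tables,
         sample_size = as.integer(sample_size),
         n_sampled = nrow(sel), n_sites = n_sites,
         n_qualifying = nrow(qualifying),
         seed = as.integer(seed),
         p_bins = as.integer(p_bins), pseudocount = pseudocount,
         r_max = as.integer(r_max), h_max = as.integer(h_max),
         include_zero_delta = include_zero_delta,
         contigs = contigs, version = 1L),
    class = "background_model"
  )
  if (verbose) {
    message("sampled ", model$n_sampled, " background sites (seed ",
            seed, ")")
  }
  if (!is.null(model_out)) {
    write_background_model(model, model_out)
    return(invisible(model))
  }
  model
}

#' Score, threshold and call variants from a BAM file (pass two)
#'
#' Streams the alignments, scores every cross-section with at least one
#' mismatch against the background model, fits the positive-score
#' density, chooses the adaptive cutoff and declares every site whose
#' score exceeds it to be variant.
#'
#' @inheritParams run_build
#' @param model A `background_model` or the path to a model sidecar
#'   file.
#' @param vcf_out,sites_out,report_out Optional output paths for the
#'   VCF, the tab-separated scored-site table and the JSON threshold
#'   report.
#' @param n_bins,df,min_scores,fallback_quantile Passed to
#'   [choose_threshold()].
#' @param ge Call sites with `score >= S*` instead of the default strict
#'   `score > S*`.
#' @return A list of class `snv_calls`: `calls` and `sites` (site-score
#'   `data.table`s), `threshold` (a `threshold_result`), `model`, and
#'   the output paths that were written.
#' @export
run_call <- function(file, fasta, model, vcf_out = NULL,
                     sites_out = NULL, report_out = NULL,
                     n_bins = 100L, df = 7L, min_scores = 200L,
                     fallback_quantile = 0.95, ge = FALSE,
                     min_base_quality = 0L, region = NULL,
                     chunk_width = 100000L,
                     nm_tag = "NM", nh_tag = "NH",
                     missing_tag = c("default", "fail"),
                     verbose = FALSE) {
  missing_tag <- match.arg(missing_tag)
  if (is.character(model)) {
    model <- read_background_model(model)
  }
  stopifnot(inherits(model, "background_model"))
  bam <- ensure_bam(file)
  contigs <- .bam_seqlengths(bam)
  if (!is.null(model$contigs)) {
    same <- length(model$contigs) == length(contigs) &&
      setequal(names(model$contigs), names(contigs)) &&
      all(model$contigs[names(contigs)] == contigs)
    if (!same) {
      stop("model/BAM contig mismatch; model: ",
           paste(names(model$contigs), model$contigs, sep = ":",
                 collapse = ", "),
           "; BAM: ",
           paste(names(contigs), contigs, sep = ":", collapse = ", "))
    }
  }

  pieces <- pileup_apply(
    bam, fasta, function(pb) score_pileup(pb, model),
    chunk_width = chunk_width, region = region,
    min_base_quality = min_base_quality,
    nm_tag = nm_tag, nh_tag = nh_tag, missing_tag = missing_tag
  )
  sites <- if (length(pieces)) rbindlist(pieces) else .empty_sitescore()
  setkey(sites, chrom, pos)
  if (nrow(sites) == 0L) {
    stop("no scored sites: every cross-section is mismatch-free")
  }
  if (verbose) {
    message("scored ", nrow(sites), " sites (",
            sum(sites$score > 0), " with positive score)")
  }

  threshold <- choose_threshold(sites$score, n_bins = n_bins, df = df,
                                min_scores = min_scores,
                                fallback_quantile = fallback_quantile)
  calls <- if (ge) sites[score >= threshold$s_star] else
    sites[score > threshold$s_star]
  if (verbose) {
    message("S* = ", format(threshold$s_star), " (", threshold$rule,
            "); ", nrow(calls), " variant calls")
  }

  if (!is.null(vcf_out)) {
    write_calls_vcf(calls, threshold$s_star, contigs, vcf_out,
                    params = list(rule = threshold$rule,
                                  ge = ge, df = df, n_bins = n_bins,
                                  fallback_quantile = fallback_quantile,
                                  model_seed = model$seed,
                                  sample_size = model$sample_size))
  }
  if (!is.null(sites_out)) write_site_table(sites, sites_out)
  if (!is.null(report_out)) write_threshold_report(threshold, report_out)

  structure(list(calls = calls, sites = sites, threshold = threshold,
                 model = model, vcf = vcf_out, site_table = sites_out,
                 report = report_out),
            class = "snv_calls")
}

#' @export
print.snv_calls <- function(x, ...) {
  cat("snv_calls: ", nrow(x$calls), " calls from ", nrow(x$sites),
      " scored sites; ", sep = "")
  print(x$threshold)
  invisible(x)
}

#' Write variant calls as VCF
#'
#' The QUAL column carries the score rescaled to a non-negative value
#' (`S - S*`, floored at 0); the raw score and its component breakdown
#' go to INFO fields. Multi-allelic sites emit a single record with the
#' modal mismatch base as ALT; the other observed mismatch bases are
#' listed in the `OA` INFO field.
#'
#' @param calls A site-score `data.table` of the called sites.
#' @param s_star The threshold used.
#' @param contigs Named integer vector of contig lengths.
#' @param path Output path.
#' @param params Optional named list echoed into the header for
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, s_star, contigs, path,
                            params = NULL) {
  n <- nrow(calls)
  sl <- structure(as.integer(contigs), names = names(contigs))
  if (n) {
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, width = 1L),
                                 seqlengths = sl)
    fixed <- S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(calls$ref),
      ALT = Biostrings::DNAStringSetList(as.list(calls$alt)),
      QUAL = pmax(calls$score - s_star, 0),
      FILTER = rep("PASS", n)
    )
    oa <- calls$other_alts
    oa[!nzchar(oa)] <- "."
    info <- S4Vectors::DataFrame(
      HZS = calls$score, HZQ = calls$d_Q, HZP = calls$d_P,
      HZR = calls$d_R, HZH = calls$d_H, HZLQ = calls$log_q,
      DP = calls$coverage, NMM = calls$n_mismatch, MR = calls$delta,
      OA = oa
    )
  } else {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
    fixed <- S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(),
      ALT = Biostrings::DNAStringSetList(),
      QUAL = numeric(), FILTER = character()
    )
    info <- S4Vectors::DataFrame(
      HZS = numeric(), HZQ = numeric(), HZP = numeric(),
      HZR = numeric(), HZH = numeric(), HZLQ = numeric(),
      DP = integer(), NMM = integer(), MR = numeric(), OA = character()
    )
  }
  hdr_info <- S4Vectors::DataFrame(
    Number = c(rep("1", 9), "."),
    Type = c(rep("Float", 6), "Integer", "Integer", "Float", "String"),
    Description = c(
      "total site score S",
      "base-quality component",
      "read-position component",
      "read-error component",
      "multiple-hit component",
      "log empirical quantile of the mismatch rate",
      "coverage",
      "number of mismatching bases",
      "mismatch rate",
      "other observed mismatch bases"
    ),
    row.names = c("HZS", "HZQ", "HZP", "HZR", "HZH", "HZLQ", "DP",
                  "NMM", "MR", "OA")
  )
  meta <- list(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"),
    source = S4Vectors::DataFrame(
      Value = paste0("snvadapt ",
                     as.character(utils::packageVersion("snvadapt"))),
      row.names = "source")
  )
  if (!is.null(params)) {
    meta$snvadaptParams <- S4Vectors::DataFrame(
      Value = paste(names(params), vapply(params, format, character(1)),
                    sep = "=", collapse = ","),
      row.names = "snvadaptParams")
  }
  meta$snvadaptThreshold <- S4Vectors::DataFrame(
    Value = format(s_star), row.names = "snvadaptThreshold")
  hdr <- VariantAnnotation::VCFHeader(
    samples = character(),
    header = do.call(IRanges::DataFrameList, c(meta, list(INFO = hdr_info)))
  )
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
                                info = info, collapsed = TRUE)
  S4Vectors::metadata(vcf)$header <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

# coerce calls/truth inputs (data.frame, VCF path, BED path, GRanges)
# into a data.table of (chrom, pos) keys
.as_site_keys <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.vcf(\\.gz|\\.bgz)?$", x, ignore.case = TRUE)) {
      v <- VariantAnnotation::readVcf(x)
      gr <- SummarizedExperiment::rowRanges(v)
      x <- data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      pos = GenomicRanges::start(gr))
    } else if (grepl("\\.bed$", x, ignore.case = TRUE)) {
      gr <- rtracklayer::import(x, format = "BED")
      x <- data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      pos = GenomicRanges::start(gr))
    } else {
      stop("cannot read site keys from: ", x)
    }
  } else if (methods::is(x, "GRanges")) {
    x <- data.table(chrom = as.character(GenomeInfoDb::seqnames(x)),
                    pos = GenomicRanges::start(x))
  } else if (is.data.frame(x)) {
    x <- as.data.table(x)[, .(chrom = as.character(chrom),
                              pos = as.integer(pos))]
  } else {
    stop("unsupported site collection of class ", class(x)[1])
  }
  unique(x[, .(chrom, pos)])
}

#' Compare variant calls against a truth set
#'
#' Computes the confusion counts and the two headline metrics: the
#' recall (sensitivity) `SENS = TP / (TP + FN)` and the positive
#' predictive value `PPV = TP / (TP + FP)`. True negatives are the
#' scored sites that are neither truth nor called; they are `NA` when no
#' scored-site collection is supplied.
#'
#' @param calls Called sites: a `data.table`/`data.frame` with `chrom`
#'   and `pos`, a `GRanges`, or a path to a VCF or BED file.
#' @param truth The truth set, in any of the same forms.
#' @param scored Optional collection of all scored sites (same forms),
#'   needed for `TN`.
#' @return A list of class `snv_eval` with `TP`, `FP`, `FN`, `TN`,
#'   `SENS` and `PPV` (`NA` where the denominator is zero).
#' @export
evaluate_calls <- function(calls, truth, scored = NULL) {
  ck <- .as_site_keys(calls)
  tk <- .as_site_keys(truth)
  tp <- nrow(ck[tk, on = c("chrom", "pos"), nomatch = NULL])
  fp <- nrow(ck) - tp
  fn <- nrow(tk) - tp
  tn <- NA_integer_
  if (!is.null(scored)) {
    sk <- .as_site_keys(scored)
    nontruth <- nrow(sk) - nrow(sk[tk, on = c("chrom", "pos"),
                                   nomatch = NULL])
    fp_scored <- nrow(sk[ck, on = c("chrom", "pos"), nomatch = NULL]) -
      nrow(sk[ck, on = c("chrom", "pos"), nomatch = NULL][
        tk, on = c("chrom", "pos"), nomatch = NULL])
    tn <- nontruth - fp_scored
  }
  structure(
    list(TP = tp, FP = fp, FN = fn, TN = tn,
         SENS = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_),
    class = "snv_eval"
  )
}

#' @export
print.snv_eval <- function(x, ...) {
  cat(sprintf(
    "snv_eval: TP=%d FP=%d FN=%d TN=%s  SENS=%s PPV=%s\n",
    x$TP, x$FP, x$FN, format(x$TN),
    format(x$SENS, digits = 4), format(x$PPV, digits = 4)))
  invisible(x)
}
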
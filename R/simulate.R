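# Read simulator: generates a uniform random reference, uniformly placed
# error-prone reads carrying planted variant alleles, and the matching
# truth set, written as FASTA + coordinate-sorted indexed BAM (or SAM) +
# BED/VCF truth files. It exercises every input of the calling model
# (base qualities, read positions, per-read edit distance and
# multiplicity annotations) without requiring a read mapper.

#' Simulation configuration
#'
#' @param genome_length Reference length in bp.
#' @param coverage Target mean coverage; the number of reads is
#'   `ceiling(coverage * genome_length / read_length)`.
#' @param read_length Read length in bp (default 100).
#' @param n_variants Number of variant sites planted.
#' @param beta Variant allele fraction, a scalar in `(0, 1]` or one
#'   value per variant site: each read overlapping a variant site
#'   carries the alternative allele independently with probability
#'   `beta`.
#' @param error_rate Mean per-base technical error rate `epsilon` in
#'   `[0, 0.5)`. Each base is corrupted to a uniformly chosen other base
#'   with its own probability `e_b = error_rate * w_b * profile(k)`,
#'   where `w_b` is a unit-mean lognormal weight (spread
#'   `error_sdlog`) emulating the quality heterogeneity of a sequencer.
#' @param error_profile Position dependence of the error rate along the
#'   read: `"flat"` (none) or `"linear"` (a unit-mean ramp rising
#'   towards the read end by factor `ramp_factor` from start to end).
#' @param ramp_factor End/start error-rate ratio of the linear profile
#'   (default 3).
#' @param error_sdlog Lognormal sd (log scale) of the per-base error
#'   weight (default 0.8; 0 gives a homogeneous error rate).
#' @param calibrated_quality When `TRUE` (default) the reported Phred
#'   quality of every base encodes its own error probability
#'   (`10^(-phred/10) = e_b`), so erroneous calls are enriched at low
#'   qualities as in real sequencers; when `FALSE` all bases report
#'   `uninformative_phred`, isolating the model components that do not
#'   use quality.
#' @param uninformative_phred Constant Phred value used when
#'   `calibrated_quality = FALSE` (default 30).
#' @param extra_error_frac Fraction of reads given extra edit-distance
#'   counts on top of their realized mismatches, emulating alignment
#'   errors that are not base substitutions (default 0.02).
#' @param extra_error_max Largest extra edit-distance increment
#'   (default 3).
#' @param multi_frac Fraction of reads annotated as multi-mapping
#'   (default 0.05).
#' @param multi_max Largest hit count assigned to a multi-mapping read
#'   (default 10); hit counts are drawn uniformly from `2:multi_max`.
#' @param mismap_frac Fraction of reads whose sequence is taken from a
#'   uniformly chosen wrong location while keeping the reported
#'   placement, emulating mismapping (default 0); such reads keep their
#'   true edit distance (computed against the reported placement) and
#'   are annotated as multi-mapping.
#' @param seed Integer seed; the whole dataset is reproducible given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, coverage = 30L,
                       read_length = 100L, n_variants = 100L,
                       beta = 0.5, error_rate = 0.01,
                       error_profile = c("flat", "linear"),
                       ramp_factor = 3, error_sdlog = 0.8,
                       calibrated_quality = TRUE,
                       uninformative_phred = 30L,
                       extra_error_frac = 0.02, extra_error_max = 3L,
                       multi_frac = 0.05, multi_max = 10L,
                       mismap_frac = 0, seed = 1L) {
  error_profile <- match.arg(error_profile)
  stopifnot(genome_length >= read_length,
            coverage >= 1,
            read_length >= 1L,
            n_variants >= 0L,
            all(beta > 0), all(beta <= 1),
            length(beta) == 1L || length(beta) == n_variants,
            error_rate >= 0, error_rate < 0.5,
            ramp_factor > 0, error_sdlog >= 0,
            extra_error_frac >= 0, extra_error_frac <= 1,
            multi_frac >= 0, multi_frac <= 1,
            mismap_frac >= 0, mismap_frac <= 1)
  if (n_variants > genome_length) {
    stop("n_variants exceeds genome_length")
  }
  structure(
    list(genome_length = as.integer(genome_length),
         coverage = coverage, read_length = as.integer(read_length),
         n_variants = as.integer(n_variants), beta = beta,
         error_rate = error_rate, error_profile = error_profile,
         ramp_factor = ramp_factor, error_sdlog = error_sdlog,
         calibrated_quality = calibrated_quality,
         uninformative_phred = as.integer(uninformative_phred),
         extra_error_frac = extra_error_frac,
         extra_error_max = as.integer(extra_error_max),
         multi_frac = multi_frac, multi_max = as.integer(multi_max),
         mismap_frac = mismap_frac, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$genome_length, " bp, ", x$coverage, "x, ",
      x$n_variants, " variants (beta ",
      paste(format(unique(x$beta)), collapse = "/"),
      "), error_rate ", format(x$error_rate), " (", x$error_profile,
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

.ACGT_RAW <- charToRaw("ACGT")

# unit-mean positional error profile over read positions 1..rl
.position_profile <- function(cfg) {
  rl <- cfg$read_length
  if (cfg$error_profile == "flat" || rl == 1L) {
    return(rep(1, rl))
  }
  r <- cfg$ramp_factor
  raw <- 1 + (r - 1) * (seq_len(rl) - 1) / (rl - 1)
  raw / mean(raw)
}

#' Simulate a sequencing dataset with known variants
#'
#' Generates an i.i.d. uniform-nucleotide reference, plants
#' `n_variants` single-nucleotide variants, places reads uniformly, and
#' corrupts bases according to the configured error structure. The
#' alignments are written directly as already-placed SAM (true
#' placements, CIGAR all-match), bypassing a read mapper; per-read edit
#' distance and hit count annotations carry the alignment-error and
#' repetitiveness information the calling model consumes.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the output files (default `"sim"`); the
#'   single reference sequence is named `"sim1"`.
#' @param write_bam Convert the SAM to a coordinate-sorted indexed BAM
#'   (default `TRUE`).
#' @param return_pileup Also return the generator's own per-site
#'   cross-section table (`pos`, `coverage`, `n_mismatch`), computed
#'   from its internal state independently of any SAM parsing
#'   (default `FALSE`; intended for validation at small scales).
#' @return An object of class `sim_dataset`: the config, file paths
#'   (`fasta`, `bam` and/or `sam`, `truth_bed`, `truth_vcf`), `n_reads`,
#'   the truth `data.table` (`chrom`, `pos`, `ref`, `alt`, `beta`, plus
#'   realized `alt_count` and `coverage`), and optionally `pileup`.
#' @export
simulate_dataset <- function(cfg, dir = tempfile("simdata"),
                             name = "sim", write_bam = TRUE,
                             return_pileup = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom <- "sim1"
  L <- cfg$genome_length
  rl <- cfg$read_length
  with_seed(cfg$seed, {
    genome_raw <- .ACGT_RAW[sample.int(4L, L, replace = TRUE)]

    # truth set
    if (cfg$n_variants > 0L) {
      vpos <- sort(sample.int(L, cfg$n_variants))
      vref <- genome_raw[vpos]
      valt <- vapply(vref, function(r) {
        sample(.ACGT_RAW[.ACGT_RAW != r], 1L)
      }, raw(1))
      vbeta <- rep_len(cfg$beta, cfg$n_variants)
    } else {
      vpos <- integer()
      vref <- raw()
      valt <- raw()
      vbeta <- numeric()
    }

    n_reads <- as.integer(ceiling(cfg$coverage * L / rl))
    starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
    profile <- .position_profile(cfg)

    sam <- file.path(dir, paste0(name, ".sam"))
    con <- file(sam, open = "wb")
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 paste0("@SQ\tSN:", chrom, "\tLN:", L)), con)

    alt_count <- integer(length(vpos))
    var_cov <- integer(length(vpos))
    cov_cnt <- if (return_pileup) integer(L) else NULL
    mm_cnt <- if (return_pileup) integer(L) else NULL

    batch <- max(1L, as.integer(ceiling(1e7 / rl)))
    for (b0 in seq(1L, n_reads, by = batch)) {
      b1 <- min(b0 + batch - 1L, n_reads)
      nb <- b1 - b0 + 1L
      st <- starts[b0:b1]
      gidx <- rep(st - 1L, each = rl) + seq_len(rl)
      raws <- genome_raw[gidx]

      # mismapped reads: sequence from elsewhere, reported placement kept
      mismap <- if (cfg$mismap_frac > 0) {
        which(stats::runif(nb) < cfg$mismap_frac)
      } else {
        integer()
      }
      if (length(mismap)) {
        wrong <- sample.int(L - rl + 1L, length(mismap), replace = TRUE)
        widx <- rep(wrong - 1L, each = rl) + seq_len(rl)
        cells <- rep((mismap - 1L) * rl, each = rl) + seq_len(rl)
        raws[cells] <- genome_raw[widx]
      }

      # plant variant alleles on overlapping reads with probability beta
      if (length(vpos)) {
        lo <- findInterval(vpos - rl, st) + 1L
        hi <- findInterval(vpos, st)
        nov <- pmax(hi - lo + 1L, 0L)
        vsel <- which(nov > 0L)
        if (length(vsel)) {
          vid <- rep(vsel, nov[vsel])
          ridx <- unlist(lapply(vsel, function(v) lo[v]:hi[v]),
                         use.names = FALSE)
          offs <- vpos[vid] - st[ridx] + 1L
          ok <- !(ridx %in% mismap)
          carry <- ok & (stats::runif(length(vid)) < vbeta[vid])
          cells <- (ridx[carry] - 1L) * rl + offs[carry]
          raws[cells] <- valt[vid[carry]]
        }
      }

      # per-base error probabilities and corruption
      eb <- rep(cfg$error_rate * profile, nb)
      if (cfg$error_sdlog > 0) {
        s <- cfg$error_sdlog
        eb <- eb * stats::rlnorm(nb * rl, meanlog = -s^2 / 2, sdlog = s)
      }
      eb <- pmin(eb, 0.75)
      err <- stats::runif(nb * rl) < eb
      ne <- sum(err)
      if (ne) {
        sub <- .ACGT_RAW[sample.int(4L, ne, replace = TRUE)]
        clash <- sub == raws[err]
        while (any(clash)) {
          sub[clash] <- .ACGT_RAW[sample.int(4L, sum(clash),
                                             replace = TRUE)]
          clash <- sub == raws[err]
        }
        raws[err] <- sub
      }

      # qualities
      if (cfg$calibrated_quality) {
        # floor keeps error-free bases (eb = 0) at the maximum quality
        phred <- pmin(pmax(as.integer(round(prob_to_phred(
          pmax(eb, 1e-6)))), 2L), 41L)
      } else {
        phred <- rep(cfg$uninformative_phred, nb * rl)
      }
      qraw <- as.raw(phred + 33L)

      # per-read edit distance vs the reported placement
      mism <- raws != genome_raw[gidx]
      nm <- as.integer(colSums(matrix(mism, nrow = rl)))
      if (cfg$extra_error_frac > 0) {
        xr <- stats::runif(nb) < cfg$extra_error_frac
        nm[xr] <- nm[xr] + sample.int(cfg$extra_error_max, sum(xr),
                                      replace = TRUE)
      }

      # hit counts
      nh <- rep(1L, nb)
      multi <- stats::runif(nb) < cfg$multi_frac
      multi[mismap] <- TRUE
      if (any(multi)) {
        nh[multi] <- if (cfg$multi_max > 2L) {
          sample(2:cfg$multi_max, sum(multi), replace = TRUE)
        } else {
          rep(2L, sum(multi))
        }
      }

      # realized truth statistics
      if (length(vpos)) {
        inb <- which(nov > 0L)
        if (length(inb)) {
          vid2 <- rep(inb, nov[inb])
          ridx2 <- unlist(lapply(inb, function(v) lo[v]:hi[v]),
                          use.names = FALSE)
          offs2 <- vpos[vid2] - st[ridx2] + 1L
          cells2 <- (ridx2 - 1L) * rl + offs2
          hit <- raws[cells2] == valt[vid2]
          alt_count <- alt_count + tabulate(vid2[hit],
                                            nbins = length(vpos))
          var_cov <- var_cov + tabulate(vid2, nbins = length(vpos))
        }
      }
      if (return_pileup) {
        cov_cnt <- cov_cnt + tabulate(gidx, nbins = L)
        mm_cnt <- mm_cnt + tabulate(gidx[mism], nbins = L)
      }

      seq_str <- substring(rawToChar(raws),
                           (seq_len(nb) - 1L) * rl + 1L,
                           seq_len(nb) * rl)
      qual_str <- substring(rawToChar(qraw),
                            (seq_len(nb) - 1L) * rl + 1L,
                            seq_len(nb) * rl)
      lines <- paste(paste0("read", b0:b1), 0L, chrom, st, 60L,
                     paste0(rl, "M"), "*", 0L, 0L, seq_str, qual_str,
                     paste0("NM:i:", nm), paste0("NH:i:", nh),
                     sep = "\t")
      writeLines(lines, con)
    }
    close(con)

    # reference FASTA (+ index)
    fasta <- file.path(dir, paste0(name, ".fa"))
    gseq <- Biostrings::DNAStringSet(rawToChar(genome_raw))
    names(gseq) <- chrom
    Biostrings::writeXStringSet(gseq, fasta, width = 70L)
    Rsamtools::indexFa(fasta)

    truth <- data.table(
      chrom = rep(chrom, length(vpos)), pos = vpos,
      ref = strsplit(rawToChar(vref), "", fixed = TRUE)[[1]] %||% character(),
      alt = strsplit(rawToChar(valt), "", fixed = TRUE)[[1]] %||% character(),
      beta = vbeta, alt_count = alt_count, coverage = var_cov
    )
    setkey(truth, chrom, pos)

    out <- list(cfg = cfg, dir = dir, fasta = fasta, sam = sam,
                bam = NULL, truth = truth, n_reads = n_reads,
                chrom = chrom)
    if (write_bam) {
      out$bam <- Rsamtools::asBam(sam, file.path(dir, name),
                                  overwrite = TRUE,
                                  indexDestination = TRUE)
    }
    out$truth_bed <- file.path(dir, paste0(name, ".truth.bed"))
    .write_truth_bed(truth, L, out$truth_bed)
    out$truth_vcf <- file.path(dir, paste0(name, ".truth.vcf"))
    .write_truth_vcf(truth, chrom, L, out$truth_vcf)
    if (return_pileup) {
      covered <- which(cov_cnt > 0L)
      out$pileup <- data.table(chrom = chrom, pos = covered,
                               coverage = cov_cnt[covered],
                               n_mismatch = mm_cnt[covered])
      setkey(out$pileup, chrom, pos)
    }
    structure(out, class = "sim_dataset")
  })
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

.write_truth_bed <- function(truth, L, path) {
  if (nrow(truth)) {
    gr <- GenomicRanges::GRanges(
      truth$chrom, IRanges::IRanges(truth$pos, width = 1L),
      name = paste0(truth$ref, ">", truth$alt),
      score = truth$beta
    )
    GenomeInfoDb::seqlengths(gr) <- structure(L, names = truth$chrom[1])
    rtracklayer::export(gr, path, format = "BED")
  } else {
    file.create(path)
  }
  invisible(path)
}

.write_truth_vcf <- function(truth, chrom, L, path) {
  sl <- structure(as.integer(L), names = chrom)
  if (nrow(truth)) {
    gr <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$pos, width = 1L),
                                 seqlengths = sl)
    fixed <- S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(truth$ref),
      ALT = Biostrings::DNAStringSetList(as.list(truth$alt)),
      QUAL = rep(NA_real_, nrow(truth)),
      FILTER = rep("PASS", nrow(truth))
    )
    info <- S4Vectors::DataFrame(BETA = truth$beta)
  } else {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
    fixed <- S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(), ALT = Biostrings::DNAStringSetList(),
      QUAL = numeric(), FILTER = character()
    )
    info <- S4Vectors::DataFrame(BETA = numeric())
  }
  hdr_info <- S4Vectors::DataFrame(
    Number = "1", Type = "Float",
    Description = "simulated variant allele fraction",
    row.names = "BETA"
  )
  hdr <- VariantAnnotation::VCFHeader(
    samples = character(),
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      INFO = hdr_info
    )
  )
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
                                info = info, collapsed = TRUE)
  S4Vectors::metadata(vcf)$header <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Standard simulation grids
#'
#' The main study grid crosses coverages 10, 20, 30, 50, 100 and 200
#' with variant allele fractions 0.2 and 0.5 (12 cells), and the
#' low-frequency grid crosses the same coverages with allele fractions
#' 0.05 and 0.1, all on a 1 Mbp toy genome with 1000 planted variants
#' and a 1% mean error rate. Each config is named after its cell, e.g.
#' `cov50_beta0.2`. Low-frequency cells carry a `sample_size_hint`
#' attribute suggesting a larger background sample, since fewer sites
#' separate cleanly at small allele fractions.
#'
#' @param genome_length Toy genome size (default 1e6 bp).
#' @param n_variants Planted variants per dataset (default 1000).
#' @param error_rate Mean technical error rate (default 0.01).
#' @param seed Base seed; each cell uses `seed` plus a distinct offset.
#' @return A list with elements `main` and `low_freq`, each a named list
#'   of [sim_config()] objects.
#' @export
standard_fixtures <- function(genome_length = 1e6, n_variants = 1000L,
                              error_rate = 0.01, seed = 1L) {
  coverages <- c(10L, 20L, 30L, 50L, 100L, 200L)
  grid <- function(betas, hint = NULL, offset = 0L) {
    cells <- list()
    i <- 0L
    for (beta in betas) {
      for (cov in coverages) {
        i <- i + 1L
        cfg <- sim_config(genome_length = genome_length, coverage = cov,
                          n_variants = n_variants, beta = beta,
                          error_rate = error_rate,
                          seed = seed + offset + i)
        if (!is.null(hint)) attr(cfg, "sample_size_hint") <- hint
        cells[[paste0("cov", cov, "_beta", beta)]] <- cfg
      }
    }
    cells
  }
  list(main = grid(c(0.2, 0.5)),
       low_freq = grid(c(0.05, 0.1), hint = 200000L, offset = 100L))
}
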
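#' Convert Phred scores to probabilities of a correct base call
#'
#' A Phred score of `phred` corresponds to an error probability of
#' `10^(-phred/10)`; the probability of the call being correct is its
#' complement.
#'
#' @param phred Numeric vector of Phred-scaled quality scores.
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @examples
#' phred_to_prob(20)  # 0.99
#' @export
phred_to_prob <- function(phred) {
  1 - 10^(-phred / 10)
}

#' Convert error probabilities to Phred scores
#'
#' @param prob Numeric vector of per-base error probabilities in `(0, 1]`.
#' @return Numeric vector of Phred-scaled scores.
#' @export
prob_to_phred <- function(prob) {
  -10 * log10(prob)
}

# log-odds of a probability
.logodds <- function(p) log(p / (1 - p))

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# parse "chrom" or "chrom:start-end" into a GRanges, using seqlengths
# from `si` (a named integer vector) to complete open-ended regions
.parse_region <- function(region, si) {
  if (methods::is(region, "GRanges")) {
    return(region)
  }
  stopifnot(is.character(region), length(region) == 1L)
  if (grepl(":", region, fixed = TRUE)) {
    chrom <- sub(":.*$", "", region)
    rng <- sub("^[^:]*:", "", region)
    start <- as.integer(sub("-.*$", "", rng))
    end <- as.integer(sub("^.*-", "", rng))
  } else {
    chrom <- region
    start <- 1L
    end <- NA_integer_
  }
  if (!chrom %in% names(si)) {
    stop("region chromosome not in alignment header: ", chrom)
  }
  if (is.na(end)) end <- si[[chrom]]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

# Ensure `file` is an indexed, coordinate-sorted BAM. SAM input is
# converted (and sorted) next to a tempfile; BAM input is indexed in
# place when no .bai is present. Returns the BAM path.
ensure_bam <- function(file) {
  stopifnot(file.exists(file))
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(file, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", file))) {
    Rsamtools::indexBam(file)
  }
  file
}

# Ensure `fasta` has a .fai index; returns an open FaFile.
ensure_fasta <- function(fasta) {
  stopifnot(file.exists(fasta))
  if (!file.exists(paste0(fasta, ".fai"))) {
    Rsamtools::indexFa(fasta)
  }
  Rsamtools::FaFile(fasta)
}

# seqlengths of a BAM as a named integer vector
.bam_seqlengths <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  h
}

# check every BAM contig is present in the FASTA index; fail naming the
# offending contigs
.check_contigs <- function(bam_sl, fa) {
  fa_sl <- Rsamtools::scanFaIndex(fa)
  fa_names <- as.character(GenomeInfoDb::seqnames(fa_sl))
  missing <- setdiff(names(bam_sl), fa_names)
  if (length(missing)) {
    stop("chromosome(s) absent from reference FASTA: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
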
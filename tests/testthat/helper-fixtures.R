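library(data.table)

phred_chars <- function(phred) rawToChar(as.raw(phred + 33L))

write_test_fasta <- function(seqs, dir = tempfile("ref")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, fa)
  fa
}

# reads: data.frame with qname, pos, cigar, seq, qual (SAM-encoded string),
# nm, nh and optionally flag/rname; must be coordinate sorted
write_test_sam <- function(reads, seqlens, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(seqlens), "\tLN:", seqlens))
  if (nrow(reads) == 0L) {
    writeLines(hdr, path)
    return(path)
  }
  flag <- if (is.null(reads$flag)) rep(0L, nrow(reads)) else reads$flag
  rname <- if (is.null(reads$rname)) rep(names(seqlens)[1], nrow(reads)) else
    reads$rname
  lines <- paste(reads$qname, flag, rname, reads$pos, 60L, reads$cigar,
                 "*", 0L, 0L, reads$seq, reads$qual,
                 paste0("NM:i:", reads$nm), paste0("NH:i:", reads$nh),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  path
}

# Three 5 bp reads over a 20 bp ACGT-repeat reference; at position 5
# (ref A) the observed bases are A, A, C.
three_read_fixture <- function() {
  ref <- strrep("ACGT", 5)
  fa <- write_test_fasta(c(t1 = ref))
  reads <- data.frame(
    qname = c("r1", "r2", "r3"),
    pos = 1:3,
    cigar = "5M",
    seq = c("ACGTA", "CGTAC", "GTCCG"),
    qual = phred_chars(rep(30L, 5)) |> rep(3),
    nm = c(0L, 0L, 1L),
    nh = 1L
  )
  sam <- write_test_sam(reads, c(t1 = nchar(ref)))
  list(fasta = fa, sam = sam, ref = ref)
}

# build a single-site pileup table directly (bypassing SAM parsing)
make_cs <- function(base, ref = "A", qual = 0.99, read_pos = 50L,
                    read_len = 100L, read_errors = 1L, read_hits = 1L,
                    chrom = "c1", pos = 100L) {
  n <- length(base)
  dt <- data.table(
    chrom = rep(chrom, n), pos = rep(as.integer(pos), n),
    ref = rep(ref, n), base = base,
    phred = rep(NA_integer_, n),
    qual = rep_len(qual, n),
    read_pos = as.integer(rep_len(read_pos, n)),
    read_len = as.integer(rep_len(read_len, n)),
    read_errors = as.integer(rep_len(read_errors, n)),
    read_hits = as.integer(rep_len(read_hits, n)),
    is_mismatch = base != rep(ref, n)
  )
  setkey(dt, chrom, pos)
  dt[]
}

# small simulated dataset + background model, cached per test run
.fixture_env <- new.env(parent = emptyenv())

small_sim_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(genome_length = 60000L, coverage = 40,
                      n_variants = 400L, beta = 0.5, error_rate = 0.01,
                      seed = 424242L)
    ds <- simulate_dataset(cfg, dir = file.path(tempdir(), "fix_small"),
                           return_pileup = TRUE)
    pb <- read_pileup(ds$bam, ds$fasta)
    model <- suppressWarnings(
      build_background_model(pb, sample_size = 100000L, seed = 9L)
    )
    .fixture_env$small <- list(ds = ds, pb = pb, model = model)
  }
  .fixture_env$small
}

# study-condition fixtures for the end-to-end checks (1 Mbp toy genome)
cov50_fixture <- function() {
  if (is.null(.fixture_env$cov50)) {
    cfg <- sim_config(genome_length = 1e6L, coverage = 50,
                      n_variants = 1000L, beta = 0.5, error_rate = 0.01,
                      seed = 20260901L)
    ds <- simulate_dataset(cfg, dir = file.path(tempdir(), "fix_cov50"))
    model <- run_build(ds$bam, ds$fasta, sample_size = 100000L,
                       seed = 101L)
    res <- run_call(ds$bam, ds$fasta, model,
                    vcf_out = file.path(ds$dir, "calls.vcf"),
                    sites_out = file.path(ds$dir, "sites.tsv"))
    .fixture_env$cov50 <- list(ds = ds, model = model, res = res)
  }
  .fixture_env$cov50
}

cov10_lowfreq_fixture <- function() {
  if (is.null(.fixture_env$cov10)) {
    cfg <- sim_config(genome_length = 1e6L, coverage = 10,
                      n_variants = 1000L, beta = 0.05,
                      error_rate = 0.01, seed = 20260902L)
    ds <- simulate_dataset(cfg, dir = file.path(tempdir(), "fix_cov10"))
    model <- suppressWarnings(
      run_build(ds$bam, ds$fasta, sample_size = 200000L, seed = 102L)
    )
    res <- suppressWarnings(
      run_call(ds$bam, ds$fasta, model,
               vcf_out = file.path(ds$dir, "calls.vcf"))
    )
    .fixture_env$cov10 <- list(ds = ds, model = model, res = res)
  }
  .fixture_env$cov10
}

# independent straight-line recomputation of all score terms for one
# cross-section (plain loops, explicit binning)
oracle_score <- function(cs, model) {
  C <- nrow(cs)
  mm <- cs[cs$is_mismatch == TRUE, ]
  tP <- model$tables$P
  tR <- model$tables$R
  tH <- model$tables$H
  dQ <- dP <- dR <- dH <- 0
  for (i in seq_len(nrow(mm))) {
    q <- min(max(mm$qual[i], 0.001), 0.9999)
    dQ <- dQ + log(q / (1 - q))
    P <- mm$read_pos[i] / mm$read_len[i]
    b <- min(max(ceiling(P * tP$p_bins), 1L), tP$p_bins)
    p <- tP$prob[b]
    dP <- dP + log(p / (1 - p)) + log(tP$p_Mbar / tP$p_M)
    r <- min(mm$read_errors[i], tR$r_max + 1L)
    p <- tR$prob[r + 1L]
    dR <- dR + log(p / (1 - p))
    h <- min(mm$read_hits[i], tH$h_max + 1L)
    p <- tH$prob[h]
    dH <- dH + log(p / (1 - p))
  }
  delta <- nrow(mm) / C
  n <- model$ecdf$n
  below <- sum(model$ecdf$support <= delta)
  qd <- if (below == 0L) 1 / (n + 1) else model$ecdf$cum[below] / n
  list(d_Q = dQ / C, d_P = dP / C, d_R = dR / C, d_H = dH / C,
       delta = delta, log_q = log(qd),
       total = dQ / C + dP / C + dR / C + dH / C + log(qd))
}
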
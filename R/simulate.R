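# Synthetic data: circular quadripartite plastomes, noisy long reads,
# fosmid-end (FES) mate pairs, and nuclear background with plastid-derived
# insertions (NUPTs). Every generated object comes with ground truth so that
# downstream stages can be scored.

#' Simulation configuration
#'
#' Defaults emulate a typical plant plastome sequenced as a by-product of a
#' low-coverage nuclear SMRT run: a 150 kb circular genome (83 kb LSC, two
#' 25 kb inverted repeats, 17 kb SSC), long reads with ~11 % random errors
#' (insertion:deletion:substitution = 5:3:3), subread lengths log-normal with
#' mean 3213 bp and N50 4713 bp, and Sanger fosmid-end pairs spanning
#' ~40 kb inserts with 700 bp end reads.
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp.
#' @param read_error_rate total per-base error rate of simulated long reads.
#' @param error_mix length-3 numeric (insertion, deletion, substitution)
#'   fractions of the total error rate; must sum to 1.
#' @param length_mean,length_n50 target mean and N50 of subread lengths (bp).
#' @param min_read_len shortest emitted read (instrument-style floor), bp.
#' @param fes_insert_mean,fes_insert_sd fosmid insert size distribution (bp).
#' @param fes_read_len length of each Sanger end read (bp).
#' @param fes_error_rate per-base substitution rate of FES reads.
#' @param nuclear_len length of the simulated nuclear background (bp).
#' @param nupt_count number of plastid-derived insertions in the background.
#' @param seed integer seed; all simulator streams derive from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(lsc_len = 83000L, ir_len = 25000L, ssc_len = 17000L,
                       read_error_rate = 0.11,
                       error_mix = c(ins = 5 / 11, del = 3 / 11, sub = 3 / 11),
                       length_mean = 3213, length_n50 = 4713,
                       min_read_len = 100L,
                       fes_insert_mean = 40000, fes_insert_sd = 3000,
                       fes_read_len = 700L, fes_error_rate = 5e-4,
                       nuclear_len = 300000L, nupt_count = 3L, seed = 1L) {
  stopifnot(lsc_len > 0, ir_len >= 0, ssc_len > 0,
            read_error_rate >= 0, read_error_rate < 1,
            abs(sum(error_mix) - 1) < 1e-9,
            length_mean > 0, length_n50 >= length_mean,
            fes_insert_mean > 0, fes_read_len > 0, nuclear_len > 0)
  structure(list(
    lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
    ssc_len = as.integer(ssc_len), read_error_rate = read_error_rate,
    error_mix = error_mix, length_mean = length_mean, length_n50 = length_n50,
    min_read_len = as.integer(min_read_len),
    fes_insert_mean = fes_insert_mean, fes_insert_sd = fes_insert_sd,
    fes_read_len = as.integer(fes_read_len), fes_error_rate = fes_error_rate,
    nuclear_len = as.integer(nuclear_len), nupt_count = as.integer(nupt_count),
    seed = as.integer(seed)), class = "sim_config")
}

# log-normal (mu, sigma) with given mean and theoretical N50. The N50 of a
# log-normal is the median of its length-biased version, exp(mu + sigma^2),
# while the mean is exp(mu + sigma^2 / 2); both invert in closed form.
lognormal_params <- function(mean_len, n50_len) {
  sigma2 <- 2 * (log(n50_len) - log(mean_len))
  mu <- log(mean_len) - sigma2 / 2
  c(mu = mu, sigma = sqrt(max(sigma2, 0)))
}

#' Simulate a circular quadripartite plastome
#'
#' Layout is LSC, IRa, SSC, IRb with IRb the exact reverse complement of IRa;
#' base composition is i.i.d. uniform. With `ir_len = 0` the sequence is a
#' plain circle and downstream structure detection reports no quadripartite
#' partition.
#'
#' @param config a [sim_config()].
#' @return a `plastome` object (see [plastome()]); regions are recorded in
#'   0-based half-open coordinates.
#' @export
make_plastome <- function(config = sim_config()) {
  op_seed(config$seed, "plastome")
  lsc <- random_dna(config$lsc_len)
  ssc <- random_dna(config$ssc_len)
  if (config$ir_len > 0) {
    ira <- random_dna(config$ir_len)
    seq <- paste0(lsc, ira, ssc, revcomp(ira))
    regions <- data.frame(
      region = c("LSC", "IRa", "SSC", "IRb"),
      start = c(0L, config$lsc_len, config$lsc_len + config$ir_len,
                config$lsc_len + config$ir_len + config$ssc_len),
      end = c(config$lsc_len, config$lsc_len + config$ir_len,
              config$lsc_len + config$ir_len + config$ssc_len,
              config$lsc_len + 2L * config$ir_len + config$ssc_len),
      stringsAsFactors = FALSE)
  } else {
    seq <- paste0(lsc, ssc)
    regions <- NULL
  }
  plastome(seq, circular = TRUE, regions = regions)
}

#' Simulate noisy long reads from a (circular) genome
#'
#' Read starts are uniform on the circle (reads crossing the origin wrap),
#' lengths are log-normal parameterized by the configured mean and N50,
#' strands are random, and errors are i.i.d. per base with the configured
#' insertion/deletion/substitution mix. Identifiers follow the subread
#' convention `sim_movie/<n>/0_<len>`.
#'
#' @param genome DNA string (or `plastome`).
#' @param coverage target fold coverage (alternative to `n_reads`).
#' @param n_reads exact number of reads (overrides `coverage`).
#' @param config a [sim_config()].
#' @param circular treat the genome as circular (default TRUE).
#' @param movie movie name used in read ids.
#' @param source label recorded in the truth table.
#' @return list with `reads` (data.frame id/seq/qual) and `truth`
#'   (data.frame id/source/start/end/strand/n_errors; `end = start +
#'   template length`, not wrapped).
#' @export
simulate_long_reads <- function(genome, coverage = NULL, n_reads = NULL,
                                config = sim_config(), circular = TRUE,
                                movie = "sim_movie", source = "plastid") {
  if (inherits(genome, "plastome")) genome <- genome$seq
  L <- nchar(genome)
  if (is.null(n_reads)) {
    stopifnot(!is.null(coverage), coverage > 0)
    n_reads <- max(1L, as.integer(round(coverage * L / config$length_mean)))
  }
  op_seed(config$seed, "reads")
  lp <- lognormal_params(config$length_mean, config$length_n50)
  lens <- pmax(config$min_read_len,
               as.integer(round(rlnorm(n_reads, lp[["mu"]], lp[["sigma"]]))))
  if (!circular) lens <- pmin(lens, L)
  starts <- sample.int(L, n_reads, replace = TRUE) - 1L
  if (!circular) starts <- pmin(starts, L - lens)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  genome2 <- if (circular) paste0(genome, genome) else genome
  lens <- pmin(lens, L) # a read never exceeds one full turn
  ids <- character(n_reads)
  seqs <- character(n_reads)
  nerr <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    tmpl <- substr(genome2, starts[i] + 1L, starts[i] + lens[i])
    if (strands[i] == "-") tmpl <- revcomp(tmpl)
    mut <- mutate_seq(tmpl, config$read_error_rate, config$error_mix)
    seqs[i] <- mut$seq
    nerr[i] <- mut$n_edits
    ids[i] <- sprintf("%s/%d/0_%d", movie, i, nchar(mut$seq))
  }
  reads <- data.frame(id = ids, seq = seqs,
                      qual = strrep("+", nchar(seqs)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, source = source, start = starts,
                      end = starts + lens, strand = strands, n_errors = nerr,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate fosmid-end (FES) mate pairs
#'
#' Inserts are placed uniformly on the circle with Gaussian insert sizes;
#' the two mates are `fes_read_len` bases from the two insert ends and face
#' inward: the forward mate reads the left insert end on '+', the reverse
#' mate the right end on '-'. Names follow `<clone>-fw` / `<clone>-rv`.
#'
#' @param genome DNA string or `plastome`.
#' @param n_pairs number of pairs.
#' @param config a [sim_config()].
#' @return list with `reads` (2 * n_pairs records) and `truth` (per-pair
#'   clone, insert start, insert length; positions 0-based on the circle).
#' @export
simulate_fes_pairs <- function(genome, n_pairs, config = sim_config()) {
  if (inherits(genome, "plastome")) genome <- genome$seq
  L <- nchar(genome)
  stopifnot(config$fes_insert_mean + 2 * config$fes_read_len < L)
  if (n_pairs == 0) {
    return(list(reads = data.frame(id = character(0), seq = character(0),
                                   qual = character(0), stringsAsFactors = FALSE),
                truth = data.frame(clone = character(0), insert_start = integer(0),
                                   insert_len = integer(0), stringsAsFactors = FALSE)))
  }
  op_seed(config$seed, "fes")
  ins_len <- pmax(4L * config$fes_read_len,
                  as.integer(round(rnorm(n_pairs, config$fes_insert_mean,
                                         config$fes_insert_sd))))
  u <- sample.int(L, n_pairs, replace = TRUE) - 1L
  genome2 <- paste0(genome, genome)
  rl <- config$fes_read_len
  ids <- character(2L * n_pairs); seqs <- character(2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    clone <- sprintf("fes%04d", i)
    fw <- substr(genome2, u[i] + 1L, u[i] + rl)
    rv_start <- u[i] + ins_len[i] - rl
    rv <- revcomp(substr(genome2, rv_start + 1L, rv_start + rl))
    if (config$fes_error_rate > 0) {
      fw <- mutate_seq(fw, config$fes_error_rate, c(0, 0, 1))$seq
      rv <- mutate_seq(rv, config$fes_error_rate, c(0, 0, 1))$seq
    }
    ids[2 * i - 1] <- paste0(clone, "-fw"); seqs[2 * i - 1] <- fw
    ids[2 * i] <- paste0(clone, "-rv"); seqs[2 * i] <- rv
  }
  reads <- data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(clone = sprintf("fes%04d", seq_len(n_pairs)),
                      insert_start = u %% L, insert_len = ins_len,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a nuclear background with embedded plastid fragments (NUPTs)
#'
#' The background is i.i.d. random DNA; `nupt_count` fragments copied from
#' random plastome intervals, diverged by 2-10 % substitutions, are embedded
#' at recorded positions. NUPTs are the contamination mode of homology-based
#' read extraction: reads from them can pass the identity filter.
#'
#' @param config a [sim_config()].
#' @param plastome a `plastome` (source of the inserted fragments).
#' @param nupt_len_range fragment length range (bp).
#' @return list with `genome` (DNA string) and `truth` (data.frame of NUPT
#'   intervals in background coordinates plus source interval and divergence).
#' @export
simulate_background <- function(config = sim_config(), plastome = NULL,
                                nupt_len_range = c(2000L, 8000L)) {
  op_seed(config$seed, "background")
  genome <- random_dna(config$nuclear_len)
  n <- config$nupt_count
  if (n == 0 || is.null(plastome)) {
    return(list(genome = genome,
                truth = data.frame(start = integer(0), end = integer(0),
                                   src_start = integer(0), src_end = integer(0),
                                   divergence = numeric(0), stringsAsFactors = FALSE)))
  }
  pseq <- if (inherits(plastome, "plastome")) plastome$seq else plastome
  Lp <- nchar(pseq)
  flen <- sample(seq(nupt_len_range[1], nupt_len_range[2]), n, replace = TRUE)
  div <- runif(n, 0.02, 0.10)
  # non-overlapping slots in the background
  slot <- as.integer(seq(1, config$nuclear_len - max(flen) - 1,
                         length.out = n + 1))[seq_len(n)]
  src <- vapply(flen, function(l) sample.int(Lp - l, 1), 1L)
  out <- genome
  truth <- data.frame(start = integer(n), end = integer(n),
                      src_start = integer(n), src_end = integer(n),
                      divergence = div, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    frag <- substr(pseq, src[i] + 1L, src[i] + flen[i])
    frag <- mutate_seq(frag, div[i], c(0, 0, 1))$seq
    substr(out, slot[i] + 1L, slot[i] + nchar(frag)) <- frag
    truth$start[i] <- slot[i]
    truth$end[i] <- slot[i] + nchar(frag)
    truth$src_start[i] <- src[i]
    truth$src_end[i] <- src[i] + flen[i]
  }
  list(genome = out, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits reads as FASTQ, plastome and FES as FASTA, the truth tables as TSV
#' and the quadripartite partition as BED (0-based half-open).
#'
#' @param sim list as produced by the simulate functions.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$plastome)) {
    write_sequences(data.frame(id = "plastome", seq = sim$plastome$seq,
                               stringsAsFactors = FALSE),
                    file.path(dir, "plastome.fasta"))
    if (!is.null(sim$plastome$regions)) {
      bed <- sim$plastome$regions
      write.table(data.frame("plastome", bed$start, bed$end, bed$region),
                  file.path(dir, "regions.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  if (!is.null(sim$reads)) {
    write_sequences(sim$reads, file.path(dir, "reads.fastq"), "fastq")
    write.table(sim$truth, file.path(dir, "reads_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$fes)) {
    write_sequences(sim$fes$reads, file.path(dir, "fes.fasta"))
    write.table(sim$fes$truth, file.path(dir, "fes_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
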
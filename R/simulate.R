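# Seeded synthetic-data generators. They give every other module a
# ground-truth test surface without controlled-access WGS data: read sets
# with a known telomeric fraction and per-base substitution error, and
# cohort delta-T vectors with known mixture structure.

#' Parameters for the synthetic read generator
#'
#' @param n_reads Number of reads to emit.
#' @param read_length Read length in bp (default 100, typical short-read
#'   WGS).
#' @param telomere_fraction Fraction of reads drawn from the telomeric
#'   tandem array, in `[0, 1]`. Exactly `round(n_reads *
#'   telomere_fraction)` reads are telomeric.
#' @param error_rate Per-base substitution probability in `[0, 1)`; no
#'   indels are simulated.
#' @param genome_length Length of the toy reference the background reads
#'   notionally come from (used for coverage arithmetic downstream).
#' @param seed Integer RNG seed; identical parameters and seed give
#'   byte-identical output.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(n_reads, read_length = 100L,
                            telomere_fraction = 0, error_rate = 0,
                            genome_length = 1e6, seed = 1L) {
  n_reads <- as.integer(n_reads); read_length <- as.integer(read_length)
  stopifnot(n_reads > 0L, read_length > 0L, genome_length > 0,
            telomere_fraction >= 0, telomere_fraction <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(n_reads = n_reads, read_length = read_length,
                 telomere_fraction = telomere_fraction,
                 error_rate = error_rate,
                 genome_length = as.numeric(genome_length),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

.BASES <- c("A", "C", "G", "T")

# n x L character matrix -> character vector of sequences
.paste_rows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.apply_substitutions <- function(m, error_rate) {
  if (error_rate <= 0) return(m)
  hit <- which(runif(length(m)) < error_rate)
  if (length(hit)) {
    old <- match(m[hit], .BASES)
    m[hit] <- .BASES[(old + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L]
  }
  m
}

#' Simulate a WGS read set with known telomeric content
#'
#' Emits `n_reads` reads of `read_length` bp. Exactly `round(n_reads *
#' telomere_fraction)` reads (at randomized positions in the file) are
#' windows into an infinite `TTAGGG` tandem array with random phase, half
#' of them reverse-complemented (windows into the `CCCTAA` array) so both
#' search orientations are exercised. The remaining reads are i.i.d.
#' uniform background. Substitution errors are then applied to every base
#' independently at `error_rate`. Quality strings are a constant `I`;
#' qualities are never used by the counter.
#'
#' @param params A [read_sim_params()].
#' @param file Optional output FASTQ path (`.gz` suffix gzips). When
#'   `NULL`, reads are returned in memory only.
#' @return A list with `reads` (a read-record data frame as from
#'   [read_reads()]), `file` (path or `NULL`), and `manifest`: the
#'   parameters, `true_telomeric_reads`, `emitted_bases`, per-read
#'   ground-truth `is_telomeric` labels, and the file's md5 `checksum`
#'   when written.
#' @examples
#' sim <- simulate_reads(read_sim_params(n_reads = 100,
#'   telomere_fraction = 0.1, seed = 7))
#' sim$manifest$true_telomeric_reads
#' @export
simulate_reads <- function(params, file = NULL) {
  stopifnot(inherits(params, "read_sim_params"))
  L <- params$read_length
  n <- params$n_reads
  if (L < 24L)
    warning("read_length ", L, " is shorter than the default 24-bp motif; ",
            "telomeric reads may be undetectable downstream")
  set.seed(params$seed)

  n_tel <- round(n * params$telomere_fraction)
  tel_rows <- if (n_tel > 0L) sort(sample.int(n, n_tel)) else integer(0)

  m <- matrix(sample(.BASES, as.numeric(n) * L, replace = TRUE), nrow = n)
  if (n_tel > 0L) {
    reps <- ceiling((L + 6L) / 6L) + 1L
    arr_fwd <- strrep("TTAGGG", reps)
    arr_rev <- strrep("CCCTAA", reps)
    phase <- sample.int(6L, n_tel, replace = TRUE)
    rc <- runif(n_tel) < 0.5
    tel_seq <- ifelse(rc, substring(arr_rev, phase, phase + L - 1L),
                      substring(arr_fwd, phase, phase + L - 1L))
    m[tel_rows, ] <- matrix(unlist(strsplit(tel_seq, "", fixed = TRUE),
                                   use.names = FALSE),
                            nrow = n_tel, byrow = TRUE)
  }
  m <- .apply_substitutions(m, params$error_rate)
  seqs <- .paste_rows(m)

  is_tel <- logical(n)
  is_tel[tel_rows] <- TRUE
  ids <- sprintf("sim_%07d", seq_len(n))
  reads <- data.frame(read_id = ids, sequence = seqs,
                      is_duplicate = logical(n), is_qc_fail = logical(n),
                      is_secondary_or_supplementary = logical(n),
                      is_unmapped = logical(n), mapped_length = integer(n),
                      stringsAsFactors = FALSE)
  checksum <- NULL
  if (!is.null(file)) {
    con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", strrep("I", L)), con,
               sep = "\n")
    close(con)
    checksum <- unname(tools::md5sum(file))
  }
  list(reads = reads, file = file,
       manifest = list(params = params, true_telomeric_reads = n_tel,
                       emitted_bases = as.numeric(n) * L,
                       is_telomeric = is_tel, checksum = checksum))
}

#' Simulate a matched tumor/normal pair
#'
#' The tumor read set reuses every parameter of the normal except the
#' telomeric fraction, which is multiplied by `tumor_fraction_multiplier`
#' (so the ground-truth delta-T at equal coverage is
#' `log2(multiplier)`), and the seed, offset by `seed_offset` so the two
#' libraries are independent draws.
#'
#' @param normal_params A [read_sim_params()] for the normal sample.
#' @param tumor_fraction_multiplier Positive factor applied to the normal
#'   telomere fraction; the product must stay within `[0, 1]`.
#' @param seed_offset Added to the normal seed for the tumor library.
#' @param normal_file,tumor_file Optional FASTQ output paths.
#' @return A list with elements `normal` and `tumor`, each as returned by
#'   [simulate_reads()].
#' @export
simulate_pair <- function(normal_params, tumor_fraction_multiplier,
                          seed_offset = 1L, normal_file = NULL,
                          tumor_file = NULL) {
  stopifnot(inherits(normal_params, "read_sim_params"))
  if (!(tumor_fraction_multiplier > 0))
    stop("`tumor_fraction_multiplier` must be positive", call. = FALSE)
  tf <- normal_params$telomere_fraction * tumor_fraction_multiplier
  if (tf > 1)
    stop("tumor telomere fraction ", signif(tf, 4),
         " exceeds 1; lower the multiplier or the normal fraction",
         call. = FALSE)
  tumor_params <- read_sim_params(
    n_reads = normal_params$n_reads, read_length = normal_params$read_length,
    telomere_fraction = tf, error_rate = normal_params$error_rate,
    genome_length = normal_params$genome_length,
    seed = normal_params$seed + as.integer(seed_offset))
  list(normal = simulate_reads(normal_params, normal_file),
       tumor = simulate_reads(tumor_params, tumor_file))
}

#' Parameters for the cohort delta-T generator
#'
#' @param n_samples Cohort size.
#' @param means Two component means (log2 units), distinct.
#' @param sigma Common component standard deviation (> 0).
#' @param weight_low Mixing weight of the lower-mean component, in (0, 1).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_samples, means = c(-0.5, 1.0), sigma = 0.3,
                              weight_low = 0.7, seed = 1L) {
  stopifnot(n_samples >= 1, length(means) == 2L, means[1] != means[2],
            sigma > 0, weight_low > 0, weight_low < 1)
  structure(list(n_samples = as.integer(n_samples),
                 means = sort(as.numeric(means)), sigma = as.numeric(sigma),
                 weight_low = as.numeric(weight_low), seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Simulate a cohort of delta-T values with known mixture structure
#'
#' Draws each sample's component (1 = lower mean with probability
#' `weight_low`, else 2) and then its delta-T from the corresponding
#' Gaussian. Component labels are returned for recovery scoring.
#'
#' @param params A [cohort_sim_params()].
#' @return A list with `delta_t` (numeric vector), `component` (integer
#'   labels, 1 = lower mean), and `params`.
#' @examples
#' sim <- simulate_cohort_deltas(cohort_sim_params(235, seed = 3))
#' table(sim$component)
#' @export
simulate_cohort_deltas <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  comp <- 1L + rbinom(params$n_samples, 1L, 1 - params$weight_low)
  list(delta_t = rnorm(params$n_samples, params$means[comp], params$sigma),
       component = comp, params = params)
}
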
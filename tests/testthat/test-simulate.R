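test_that("identical parameters and seed give byte-identical FASTQ", {
  p <- read_sim_params(n_reads = 500, telomere_fraction = 0.05,
                       error_rate = 0.01, seed = 7)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  s1 <- simulate_reads(p, file = f1)
  s2 <- simulate_reads(p, file = f2)
  expect_identical(s1$manifest$checksum, s2$manifest$checksum)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  p2 <- read_sim_params(n_reads = 500, telomere_fraction = 0.05,
                        error_rate = 0.01, seed = 8)
  s3 <- simulate_reads(p2, file = tempfile(fileext = ".fastq"))
  expect_false(identical(s1$manifest$checksum, s3$manifest$checksum))
})

test_that("error-free manifests are exact and every telomeric read is detectable", {
  sim <- simulate_reads(read_sim_params(n_reads = 1000,
                                        telomere_fraction = 0.1, seed = 7))
  expect_equal(sim$manifest$true_telomeric_reads, 100)
  expect_equal(sum(sim$manifest$is_telomeric), 100)
  tel <- sim$reads$sequence[sim$manifest$is_telomeric]
  expect_true(all(contains_telomere_motif(tel)))
  # at zero error the count equals the manifest exactly (background hits
  # have probability ~ n*(L-23)*2*4^-24)
  expect_equal(count_telomeric_reads(sim$reads)$telomeric_reads, 100)
  expect_equal(sim$manifest$emitted_bases, 1000 * 100)
})

test_that("a zero-fraction library contains only chance motif hits", {
  sim <- simulate_reads(read_sim_params(n_reads = 5000,
                                        telomere_fraction = 0, seed = 23))
  ct <- count_telomeric_reads(sim$reads)
  expect_identical(ct$telomeric_reads, sum(naive_motif_hits(sim$reads$sequence)))
  expect_equal(ct$telomeric_reads, 0)
})

test_that("both motif orientations are emitted", {
  sim <- simulate_reads(read_sim_params(n_reads = 400,
                                        telomere_fraction = 0.5, seed = 3))
  tel <- sim$reads$sequence[sim$manifest$is_telomeric]
  fwd <- grepl("TTAGGGTTAGGG", tel, fixed = TRUE)
  rev <- grepl("CCCTAACCCTAA", tel, fixed = TRUE)
  expect_gt(sum(fwd), 50)
  expect_gt(sum(rev), 50)
})

test_that("background base composition is uniform", {
  sim <- simulate_reads(read_sim_params(n_reads = 2000,
                                        telomere_fraction = 0, seed = 29))
  tab <- table(strsplit(paste(sim$reads$sequence, collapse = ""), "")[[1]])
  expect_setequal(names(tab), c("A", "C", "G", "T"))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("pair simulation scales the tumor fraction and offsets the seed", {
  p <- read_sim_params(n_reads = 1000, telomere_fraction = 0.05, seed = 5)
  pr <- simulate_pair(p, tumor_fraction_multiplier = 2)
  expect_equal(pr$tumor$manifest$params$telomere_fraction, 0.1)
  expect_equal(pr$tumor$manifest$params$seed, 6)
  expect_equal(pr$tumor$manifest$true_telomeric_reads, 100)
  expect_equal(pr$normal$manifest$true_telomeric_reads, 50)
  expect_error(simulate_pair(p, 25), "exceeds 1")
  expect_error(simulate_pair(p, 0), "positive")
})

test_that("simulated FASTQ round-trips through the reader", {
  fq <- tempfile(fileext = ".fastq.gz")
  sim <- simulate_reads(read_sim_params(n_reads = 200,
                                        telomere_fraction = 0.1, seed = 2),
                        file = fq)
  back <- read_reads(fq)
  expect_equal(back$sequence, sim$reads$sequence)
  expect_equal(back$read_id, sim$reads$read_id)
})

test_that("cohort delta-T generator is deterministic with recorded labels", {
  p <- cohort_sim_params(235, seed = 3)
  a <- simulate_cohort_deltas(p)
  b <- simulate_cohort_deltas(p)
  expect_identical(a$delta_t, b$delta_t)
  expect_identical(a$component, b$component)
  expect_length(a$delta_t, 235)
  # lower-mean component dominates at weight 0.7
  expect_gt(mean(a$component == 1L), 0.6)
  # labels match the generating component
  expect_lt(mean(a$delta_t[a$component == 1L]), mean(a$delta_t[a$component == 2L]))
  expect_error(cohort_sim_params(10, sigma = 0), "sigma")
  expect_error(cohort_sim_params(10, means = c(1, 1)), "means")
})

test_that("short reads trigger a detectability warning, not an error", {
  expect_warning(simulate_reads(read_sim_params(n_reads = 10, read_length = 20,
                                                telomere_fraction = 0.5,
                                                seed = 1)),
                 "undetectable")
})
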
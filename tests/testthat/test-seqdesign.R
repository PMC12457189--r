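test_that("the amino-acid code mapping is a bijection", {
  codes <- matrix(0:19, nrow = 1)
  aa <- codes_to_aa(codes)
  expect_equal(nchar(aa), 20)
  expect_equal(length(unique(strsplit(aa, "")[[1]])), 20)
  expect_identical(aa_to_codes(aa), codes)
  expect_error(aa_to_codes("AXB"), "non-canonical")
  expect_error(codes_to_aa(c(0, 20)), "0..19")
})

test_that("sequence spaces validate lengths and fixed positions", {
  sp <- sequence_space(10, fixed = c(1, 2))
  expect_equal(sp$d, 10)
  expect_equal(sp$fixed, c(1L, 2L))
  expect_true(space_contains(sp, rep(0, 10)))
  expect_error(sequence_space(3, fixed = 1:3), "degenerate")
})

test_that("sequence expansion mutates only free positions", {
  sp <- sequence_space(10, fixed = c(1, 2))
  root <- rep(5, 10)
  leaves <- with_seed(1, sequence_expand(root, sp))
  expect_equal(nrow(leaves), 10)
  M <- as.matrix(leaves[paste0("x", 1:10)])
  expect_true(all(M >= 0 & M <= 19))
  expect_true(all(M[, 1] == 5) && all(M[, 2] == 5))  # hotspots untouched
  expect_true(all(rowSums(M != matrix(root, 10, 10, byrow = TRUE)) >= 1))

  # forced fresh-sequence strategy: free positions are uniform draws
  fresh <- with_seed(2, sequence_expand(rep(5, 8), sequence_space(8),
                                        nte_config(expand = "sequence",
                                                   p_fresh = 1)))
  expect_equal(nrow(fresh), 8)
  expect_true(all(as.matrix(fresh[paste0("x", 1:8)]) %in% 0:19))
})

test_that("the synthetic binder oracle peaks exactly at its hidden sequence", {
  oracle <- fx$binder$oracle
  best <- label_candidates(oracle, matrix(oracle$hidden, 1))
  expect_equal(best, oracle$optimum$value)
  # all L*19 single mutants are strictly below the maximum
  expect_true(all(fx$binder$single_mutants$target < best))
  # deterministic given the seed
  o2 <- synthetic_binder_oracle(6, seed = 42)
  expect_identical(o2$hidden, oracle$hidden)
  X <- with_seed(5, as.matrix(random_candidates(fx$binder$space, 20)))
  expect_identical(label_candidates(oracle, X), label_candidates(o2, X))
})

test_that("binder scores decompose as sc * dsasa / 100 with bounded sc", {
  oracle <- fx$binder$oracle
  X <- with_seed(6, as.matrix(random_candidates(fx$binder$space, 50)))
  comp <- oracle$score_components(X)
  expect_true(all(comp$sc > 0 & comp$sc < 1))
  expect_true(all(comp$dsasa > 0))
  expect_equal(comp$target, comp$sc * comp$dsasa / 100)
  # a fully mismatched sequence scores near zero complementarity
  anti <- (oracle$hidden + 10) %% 20
  expect_lt(oracle$score_components(matrix(anti, 1))$sc, 0.1)
})

test_that("FASTA round-trips preserve the integer encoding", {
  f <- withr::local_tempfile(fileext = ".fasta")
  X <- with_seed(7, as.matrix(random_candidates(sequence_space(9), 5)))
  ids <- write_batch_fasta(X, f, run = "t", iteration = 3)
  expect_equal(ids, sprintf("t/3/%d", 1:5))
  back <- read_batch_fasta(f)
  expect_equal(back$ids, ids)
  expect_equal(back$codes, unname(X), ignore_attr = TRUE)
})

test_that("the external oracle adapter round-trips scores by record id", {
  wd <- withr::local_tempdir()
  stub <- file.path(wd, "len_oracle.R")
  writeLines(c(
    "#!/usr/bin/env Rscript",
    "a <- commandArgs(TRUE)",
    "l <- readLines(a[1])",
    "ids <- sub('^>', '', l[grepl('^>', l)])",
    "seqs <- l[!grepl('^>', l)]",
    "writeLines(sprintf('%s\\t%d', ids, nchar(seqs)), a[2])"), stub)
  Sys.chmod(stub, "0755")
  X <- with_seed(8, as.matrix(random_candidates(sequence_space(7), 4)))
  y <- external_oracle_adapter(X, stub, workdir = wd)
  expect_equal(as.numeric(y), rep(7, 4))  # stub scores = sequence length
  expect_length(attr(y, "failed"), 0)
})

test_that("missing and malformed oracle outputs are surfaced", {
  wd <- withr::local_tempdir()
  drop1 <- file.path(wd, "drop_first.R")
  writeLines(c(
    "#!/usr/bin/env Rscript",
    "a <- commandArgs(TRUE)",
    "l <- readLines(a[1])",
    "ids <- sub('^>', '', l[grepl('^>', l)])",
    "writeLines(sprintf('%s\\t1.5', ids[-1]), a[2])"), drop1)
  Sys.chmod(drop1, "0755")
  X <- with_seed(9, as.matrix(random_candidates(sequence_space(6), 3)))
  expect_warning(y <- external_oracle_adapter(X, drop1, workdir = wd),
                 "missing from the score table")
  expect_equal(attr(y, "failed"), 1L)
  expect_true(is.na(y[1]) && !anyNA(y[-1]))

  bad <- file.path(wd, "bad.R")
  writeLines(c("#!/usr/bin/env Rscript",
               "writeLines('one-column-only', commandArgs(TRUE)[2])"), bad)
  Sys.chmod(bad, "0755")
  expect_error(external_oracle_adapter(X, bad, workdir = wd), "malformed")
  expect_error(external_oracle_adapter(X, file.path(wd, "absent.sh")),
               "not found")
})
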
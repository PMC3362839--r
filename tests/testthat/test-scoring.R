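make_peaks <- function(heights, reps = data.frame(sample = character(),
                                                  replicate = character())) {
  aflp_peaks(heights, seq(50, 500, length.out = ncol(heights)), reps)
}

test_that("phenotype calling obeys retention and calling thresholds", {
  h <- matrix(c(500, 500, 40, 500, 500, 60, 30, 20, 450), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("bin", 1:3)))
  peaks <- make_peaks(h)

  ## all heights above both thresholds -> all ones
  all_on <- call_phenotypes(make_peaks(h * 0 + 400),
                            scoring_thresholds(100, "absolute", 200))
  expect_true(all(all_on$calls == 1))

  ## retention above the global max mean -> explicit error
  expect_error(call_phenotypes(peaks, scoring_thresholds(1e5, "absolute", 10)),
               "drops every locus")

  ## absolute mode calling
  calls <- call_phenotypes(peaks, scoring_thresholds(0, "absolute", 250))
  expect_equal(unname(calls$calls[, 1]), c(1L, 1L, 0L))
  expect_equal(unname(calls$calls[, 3]), c(0L, 0L, 1L))

  ## relative mode: threshold is a fraction of the locus mean
  rel <- call_phenotypes(peaks, scoring_thresholds(0, "relative", 0.5))
  lm <- colMeans(h)
  expect_equal(unname(rel$calls), unname((h >= rep(0.5 * lm,
                                                   each = 3)) * 1L))

  ## retention monotonicity
  n_ret <- sapply(c(0, 100, 200, 400), function(r)
    tryCatch(ncol(call_phenotypes(peaks,
      scoring_thresholds(r, "absolute", 250))$calls),
      error = function(e) 0L))
  expect_true(all(diff(n_ret) <= 0))
})

test_that("mismatch error rates follow the replicate-discordance definition", {
  calls <- aflp_binary(
    matrix(c(1L,0L,1L,0L,  1L,1L,1L,0L), 2, 4, byrow = TRUE,
           dimnames = list(c("a", "a_rep"), paste0("L", 1:4))),
    species = c(a = "spA"), replicates = "a_rep")
  pairs <- data.frame(sample = "a", replicate = "a_rep")
  rep <- estimate_mismatch_error_rate(calls, pairs)
  ## disagreement at exactly 1 of 4 loci
  expect_equal(rep$overall_error, 0.25)
  expect_equal(rep$pair_mean_error, 0.25)
  expect_equal(unname(rep$per_locus_error), c(0, 1, 0, 0))

  ## identical replicates -> zero error
  calls2 <- aflp_binary(
    matrix(c(1L,0L,1L,0L, 1L,0L,1L,0L), 2, 4, byrow = TRUE,
           dimnames = list(c("a", "a_rep"), paste0("L", 1:4))),
    species = c(a = "spA"), replicates = "a_rep")
  expect_equal(estimate_mismatch_error_rate(calls2, pairs)$overall_error, 0)

  expect_error(estimate_mismatch_error_rate(calls, pairs[0, ]),
               "at least one replicate pair")
})

test_that("threshold optimization equals a brute-force grid argmin", {
  truth <- toy_peaks(seed = 6, noise_sd = 60, dropout = 0.08)
  peaks <- truth$peaks
  grid <- threshold_grid(retention = seq(0, 400, length.out = 5),
                         relative = c(0.2, 0.35, 0.5),
                         absolute = c(150, 275, 400))
  opt <- optimize_thresholds(peaks, grid, min_retained_frac = 0.1)

  ## independent brute-force loop over every grid point
  best <- NULL
  for (ret in grid$retention)
    for (mode in c("absolute", "relative"))
      for (cc in grid[[if (mode == "absolute") "absolute" else "relative"]]) {
        th <- scoring_thresholds(ret, mode, cc)
        calls <- tryCatch(call_phenotypes(peaks, th),
                          error = function(e) NULL)
        if (is.null(calls)) next
        if (ncol(calls$calls) / ncol(peaks$heights) < 0.1) next
        err <- estimate_mismatch_error_rate(
          calls, peaks$replicate_pairs)$overall_error
        cand <- list(err = err, n = ncol(calls$calls), ret = ret,
                     mode = mode, cc = cc)
        if (is.null(best) ||
            err < best$err - 1e-15 ||
            (err == best$err && (cand$n > best$n ||
              (cand$n == best$n && (ret < best$ret ||
                (ret == best$ret && cc < best$cc))))))
          best <- cand
      }
  expect_equal(opt$report$overall_error, best$err)
  expect_equal(opt$report$n_retained_loci, best$n)

  ## noise-free world: some grid point reaches error 0 and is selected
  clean <- toy_peaks(seed = 2, noise_sd = 0, dropout = 0)
  opt0 <- optimize_thresholds(clean$peaks,
                              threshold_grid(retention = c(0, 100),
                                             relative = c(0.3, 0.6),
                                             absolute = c(275)))
  expect_equal(opt0$report$overall_error, 0)

  ## single-point grid -> that point returned
  g1 <- threshold_grid(retention = 0, relative = NULL, absolute = 275)
  opt1 <- optimize_thresholds(clean$peaks, g1)
  expect_equal(opt1$thresholds$calling_threshold, 275)
  expect_equal(opt1$thresholds$calling_mode, "absolute")

  ## infeasible retention floor -> explicit error
  expect_error(
    optimize_thresholds(peaks, threshold_grid(retention = 1e5,
                                              relative = c(0.3),
                                              absolute = NULL)),
    "infeasible")
})

test_that("filter_unique_loci removes monomorphic and duplicate columns", {
  m <- matrix(c(1L,1L,1L,  0L,1L,0L,  0L,1L,0L,  1L,0L,1L), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("L", 1:4)))
  x <- aflp_binary(m, setNames(paste0("sp", 1:3), paste0("s", 1:3)))
  f <- filter_unique_loci(x)
  expect_equal(colnames(f$calls), c("L2", "L4"))
  expect_equal(attr(f, "collapse_map"), list(L2 = "L3"))

  ## idempotence
  f2 <- filter_unique_loci(f)
  expect_identical(f2$calls, f$calls)

  ## hash-set oracle on a larger random matrix
  set.seed(30)
  big <- matrix(rbinom(38 * 700, 1, 0.3), 38, 700,
                dimnames = list(sprintf("s%02d", 1:38),
                                sprintf("L%03d", 1:700)))
  xb <- aflp_binary(big, setNames(rep("spA", 38), rownames(big)))
  expect_equal(ncol(filter_unique_loci(xb)$calls), count_unique_loci(big))
})

test_that("noise-free score -> filter chain recovers the ground truth", {
  truth <- toy_peaks(seed = 31, noise_sd = 0, dropout = 0)
  calls <- call_phenotypes(truth$peaks, scoring_thresholds(0, "absolute", 275))
  rep <- estimate_mismatch_error_rate(calls, truth$peaks$replicate_pairs)
  expect_equal(rep$overall_error, 0)
  primary <- rownames(truth$matrix$calls)
  expect_equal(unname(calls$calls[primary, ]), unname(truth$matrix$calls))
})
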